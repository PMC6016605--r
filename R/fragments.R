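# Fragment ingestion: the two small RNA input forms are (a) unique-fragment
# tables (sequence + clonal frequency) and (b) raw FASTQ reads. Filters
# follow strict inequalities throughout: table fragments are kept at length
# 15-28 nt with clonal frequency > 9 (i.e. >= 10); FASTQ reads are discarded
# if any base has Phred quality < 28, then collapsed to unique sequences and
# kept at length 15-100 nt with frequency > 100 (i.e. >= 101).

#' Sample metadata
#'
#' @param species species name (required, non-empty).
#' @param tissue tissue or library description.
#' @param gsm GEO sample accession, or `""`.
#' @param pmid PubMed identifier, or `""`.
#' @return a list of class `sample_meta`.
#' @export
sample_meta <- function(species, tissue = "", gsm = "", pmid = "") {
  if (!is.character(species) || length(species) != 1L || !nzchar(species)) {
    stop("species must be a non-empty string", call. = FALSE)
  }
  structure(list(species = species, tissue = tissue, gsm = gsm, pmid = pmid),
            class = "sample_meta")
}

fragment_frame <- function(sequence, frequency, sample) {
  data.frame(
    sequence = sequence, frequency = as.integer(frequency),
    species = sample$species, tissue = sample$tissue,
    gsm = sample$gsm, pmid = sample$pmid, stringsAsFactors = FALSE
  )
}

# Collapse identical sequences (summing counts) and sort by
# (frequency desc, sequence asc) for deterministic output.
collapse_fragments <- function(sequence, frequency) {
  agg <- rowsum(as.numeric(frequency), group = sequence, reorder = TRUE)
  out <- data.frame(sequence = rownames(agg), frequency = as.integer(agg[, 1L]),
                    stringsAsFactors = FALSE)
  out[order_radix(-out$frequency, out$sequence), , drop = FALSE]
}

#' Load a unique-fragment table
#'
#' Reads a TSV of `sequence<TAB>count` (header optional), normalises U to T,
#' drops rows with characters outside A/C/G/T/U or unparseable counts
#' (tallied and reported), collapses duplicate sequences by summing counts,
#' and applies the length and clonal-frequency filters. Defaults keep
#' fragments of length 15-28 nt with frequency > 9.
#'
#' @param path TSV path.
#' @param sample a [sample_meta()].
#' @param min_len,max_len inclusive length bounds (default 15 and 28).
#' @param min_freq minimum clonal frequency kept (default 10, i.e. "> 9").
#' @return a `data.frame` of fragments (`sequence`, `frequency`, sample
#'   columns), sorted by frequency descending then sequence; filter tallies
#'   in `attr(, "stats")`.
#' @export
load_fragment_table <- function(path, sample, min_len = 15L, max_len = 28L,
                                min_freq = 10L) {
  if (!file.exists(path)) stop("fragment table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  stats <- c(rows = 0L, malformed = 0L, bad_alphabet = 0L,
             length_filtered = 0L, freq_filtered = 0L, kept = 0L)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    out <- fragment_frame(character(0), integer(0), sample)
    attr(out, "stats") <- stats
    return(out)
  }
  # optional header: first row whose count field is non-numeric
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L])))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  stats["rows"] <- nrow(raw)
  seqs <- normalize_dna(raw[[1L]])
  freq <- suppressWarnings(as.integer(raw[[2L]]))
  bad_row <- is.na(freq) | freq < 1L | !nzchar(seqs)
  stats["malformed"] <- sum(bad_row)
  if (any(bad_row)) {
    warning(sum(bad_row), " unparseable row(s) skipped in ", path,
            call. = FALSE)
    seqs <- seqs[!bad_row]; freq <- freq[!bad_row]
  }
  bad_alpha <- !is_dna(seqs)
  stats["bad_alphabet"] <- sum(bad_alpha)
  if (any(bad_alpha)) {
    message(sum(bad_alpha), " row(s) with non-ACGTU characters dropped")
    seqs <- seqs[!bad_alpha]; freq <- freq[!bad_alpha]
  }
  col <- collapse_fragments(seqs, freq)
  len_ok <- nchar(col$sequence) >= min_len & nchar(col$sequence) <= max_len
  stats["length_filtered"] <- sum(!len_ok)
  col <- col[len_ok, , drop = FALSE]
  freq_ok <- col$frequency >= min_freq
  stats["freq_filtered"] <- sum(!freq_ok)
  col <- col[freq_ok, , drop = FALSE]
  stats["kept"] <- nrow(col)
  out <- fragment_frame(col$sequence, col$frequency, sample)
  attr(out, "stats") <- stats
  out
}

#' Trim a 3' adapter from reads
#'
#' Minimal exact-match trimming: the read suffix starting at the leftmost
#' exact occurrence of the full adapter is removed; if the full adapter is
#' absent, an adapter prefix of length >= 8 at the read's 3' end is removed.
#' Reads without either are returned unchanged. Quality strings, when given,
#' are trimmed in lockstep. This is deliberate plumbing, not an
#' error-tolerant adapter aligner.
#'
#' @param sequence character vector of read sequences.
#' @param quality optional character vector of quality strings (same lengths).
#' @param adapter non-empty adapter sequence.
#' @return a list with trimmed `sequence` and `quality`.
#' @export
trim_adapter <- function(sequence, quality = NULL, adapter) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    stop("adapter must be a non-empty string", call. = FALSE)
  }
  adapter <- normalize_dna(adapter)
  cut <- regexpr(adapter, sequence, fixed = TRUE)  # leftmost full occurrence
  miss <- cut < 0L
  if (any(miss) && nchar(adapter) - 1L >= 8L) {
    n <- nchar(sequence[miss])
    cut_miss <- rep(-1L, sum(miss))
    for (k in seq(nchar(adapter) - 1L, 8L)) {  # longest prefix wins
      pre <- substr(adapter, 1L, k)
      hit <- cut_miss < 0L & n > k &
        substr(sequence[miss], n - k + 1L, n) == pre
      cut_miss[hit] <- n[hit] - k + 1L
    }
    cut[miss] <- cut_miss
  }
  keep_to <- ifelse(cut > 0L, cut - 1L, nchar(sequence))
  out_seq <- substr(sequence, 1L, keep_to)
  out_qual <- if (is.null(quality)) NULL else substr(quality, 1L, keep_to)
  list(sequence = out_seq, quality = out_qual)
}

# Minimum Phred+33 base quality per read.
min_phred <- function(quality) {
  vapply(quality,
         function(q) if (nchar(q) == 0L) Inf else min(utf8ToInt(q)) - 33,
         numeric(1), USE.NAMES = FALSE)
}

#' Load and filter raw FASTQ reads
#'
#' Reads Phred+33 FASTQ (optionally gzipped), optionally trims a 3' adapter,
#' discards reads containing `N` or any base with quality below `min_q`,
#' collapses survivors to unique sequences with clonal frequencies, and keeps
#' sequences of length `[min_len, max_len]` with frequency `>= min_freq`.
#' Defaults encode the strict rules: quality < 28 at any position discards
#' the read; kept reads are 15-100 nt with frequency > 100.
#'
#' @param path FASTQ path (`.gz` accepted). Phred+64 input must be converted
#'   beforehand.
#' @param sample a [sample_meta()].
#' @param adapter optional 3' adapter to trim (see [trim_adapter()]).
#' @param min_q minimum per-base Phred quality (default 28).
#' @param min_len,max_len inclusive length bounds (default 15 and 100).
#' @param min_freq minimum clonal frequency kept (default 101, i.e. "> 100").
#' @return as [load_fragment_table()].
#' @export
load_fastq <- function(path, sample, adapter = NULL, min_q = 28L,
                       min_len = 15L, max_len = 100L, min_freq = 101L) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  fastq_validate(path)
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e) {
      stop("malformed FASTQ ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- suppressWarnings(as.character(x))
  quals <- suppressWarnings(as.character(Biostrings::quality(x)))
  bad_len <- nchar(seqs) != nchar(quals)
  if (any(bad_len)) {
    stop("FASTQ record ", which(bad_len)[1L],
         ": sequence and quality lengths differ", call. = FALSE)
  }
  stats <- c(reads = length(seqs), n_discarded = 0L, quality_discarded = 0L,
             length_filtered = 0L, freq_filtered = 0L, kept = 0L)
  if (!is.null(adapter)) {
    tr <- trim_adapter(seqs, quals, adapter)
    seqs <- tr$sequence; quals <- tr$quality
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  stats["n_discarded"] <- sum(has_n)
  seqs <- seqs[!has_n]; quals <- quals[!has_n]
  lowq <- min_phred(quals) < min_q
  stats["quality_discarded"] <- sum(lowq)
  seqs <- seqs[!lowq]
  if (length(seqs) == 0L) {
    out <- fragment_frame(character(0), integer(0), sample)
    attr(out, "stats") <- stats
    return(out)
  }
  col <- collapse_fragments(seqs, rep(1L, length(seqs)))
  len_ok <- nchar(col$sequence) >= min_len & nchar(col$sequence) <= max_len
  stats["length_filtered"] <- sum(!len_ok)
  col <- col[len_ok, , drop = FALSE]
  freq_ok <- col$frequency >= min_freq
  stats["freq_filtered"] <- sum(!freq_ok)
  col <- col[freq_ok, , drop = FALSE]
  stats["kept"] <- nrow(col)
  out <- fragment_frame(col$sequence, col$frequency, sample)
  attr(out, "stats") <- stats
  out
}

# Structural pre-check of 4-line FASTQ records: marker lines in place and
# sequence/quality lengths equal per record. Content parsing proper is done
# by Biostrings; this pass exists to fail hard with the record index.
fastq_validate <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  n <- length(lines)
  nrec <- n %/% 4L
  if (n %% 4L != 0L) {
    stop("malformed FASTQ ", path, ": truncated record ", nrec + 1L,
         call. = FALSE)
  }
  b <- (seq_len(nrec) - 1L) * 4L
  bad_marker <- !startsWith(lines[b + 1L], "@") | !startsWith(lines[b + 3L], "+")
  if (any(bad_marker)) {
    stop("malformed FASTQ ", path, ": record ", which(bad_marker)[1L],
         " lacks @/+ markers", call. = FALSE)
  }
  bad_len <- nchar(lines[b + 2L]) != nchar(lines[b + 4L])
  if (any(bad_len)) {
    stop("malformed FASTQ ", path, ": record ", which(bad_len)[1L],
         " has mismatched sequence and quality lengths", call. = FALSE)
  }
  invisible(nrec)
}

#' Write a collapsed-fragment table
#'
#' TSV with the fragment columns plus the applied-filter tallies as a
#' commented provenance header.
#'
#' @param fragments a fragment `data.frame` from [load_fragment_table()] or
#'   [load_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  st <- attr(fragments, "stats")
  if (!is.null(st)) {
    writeLines(paste0("# filter ", names(st), "=", st), con)
  }
  utils::write.table(fragments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
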