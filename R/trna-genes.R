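# tRNA gene annotations: an in-memory table of tRNA gene loci with optional
# intron intervals, plus readers for BED6 and tRNAscan-SE tabular output.
# All coordinates are 1-based inclusive internally; BED input (0-based
# half-open) is converted on read.

#' Construct a table of tRNA gene loci
#'
#' Validates and assembles tRNA gene annotations into the data frame used by
#' [build_reference()]. Coordinates are 1-based inclusive on the genomic plus
#' strand; `strand` gives the transcription strand. Introns, when present, are
#' genomic intervals strictly inside `[start, end]`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive genomic positions, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param amino_acid three-letter isotype code (e.g. `"Ala"`).
#' @param anticodon 3-nt anticodon (U accepted, stored as T).
#' @param introns optional list, one element per gene: `NULL` or a two-column
#'   matrix of 1-based inclusive `(start, end)` intron intervals.
#' @return a `data.frame` of class `trna_genes` with a list column `introns`.
#' @export
trna_genes <- function(gene_id, chrom, start, end, strand,
                       amino_acid = "Xxx", anticodon = "NNN",
                       introns = NULL) {
  n <- length(gene_id)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(end < start)) {
    stop("end < start for gene(s): ",
         paste(gene_id[end < start], collapse = ", "), call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  anticodon <- normalize_dna(anticodon)
  bad_ac <- nchar(anticodon) != 3L | !is_dna(anticodon) & anticodon != "NNN"
  if (any(bad_ac)) {
    stop("invalid anticodon for gene(s): ",
         paste(gene_id[bad_ac], collapse = ", "), call. = FALSE)
  }
  if (is.null(introns)) {
    introns <- rep(list(NULL), n)
  }
  stopifnot(length(introns) == n)
  for (i in seq_len(n)) {
    iv <- introns[[i]]
    if (is.null(iv) || nrow(iv) == 0L) {
      introns[i] <- list(NULL)
      next
    }
    iv <- matrix(as.integer(iv), ncol = 2L)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] <= start[i]) || any(iv[, 2L] >= end[i]) ||
        any(iv[, 2L] < iv[, 1L]) ||
        (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))) {
      stop("introns of gene ", gene_id[i],
           " must be non-overlapping and strictly inside [start, end]",
           call. = FALSE)
    }
    introns[[i]] <- iv
  }
  out <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = start, end = end, strand = as.character(strand),
    amino_acid = as.character(amino_acid), anticodon = anticodon,
    stringsAsFactors = FALSE
  )
  out$introns <- introns
  class(out) <- c("trna_genes", "data.frame")
  out
}

#' Read tRNA gene annotations from a BED6 file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention. Isotype and anticodon are parsed from names
#' of the GtRNAdb form `tRNA-Ala-AGC-1-1` when present.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return a `trna_genes` table.
#' @export
read_trna_bed <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("BED6 requires 6 columns", call. = FALSE)
  name <- as.character(bed[[4L]])
  m <- regmatches(name, regexec("tRNA-([A-Za-z]{3})-([ACGTUacgtu]{3})", name))
  aa <- vapply(m, function(x) if (length(x) == 3L) x[2L] else "Xxx", "")
  ac <- vapply(m, function(x) if (length(x) == 3L) x[3L] else "NNN", "")
  trna_genes(
    gene_id = name, chrom = bed[[1L]],
    start = bed[[2L]] + 1L, end = bed[[3L]],
    strand = bed[[6L]], amino_acid = aa, anticodon = ac
  )
}

#' Read tRNA gene annotations from tRNAscan-SE tabular output
#'
#' Parses the whitespace-delimited `.out` dialect (sequence name, tRNA number,
#' begin, end, type, anticodon, intron begin, intron end, score). Minus-strand
#' genes are encoded by begin > end and are flipped on read; intron
#' coordinates of 0 mean "no intron".
#'
#' @param path tRNAscan-SE output file; the three-line header, if present, is
#'   skipped.
#' @return a `trna_genes` table.
#' @export
read_trnascan <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(Sequence|Name|----|\\s*$)", lines)]
  if (length(lines) == 0L) {
    return(trna_genes(character(0), character(0), integer(0), integer(0),
                      character(0)))
  }
  f <- strsplit(trimws(lines), "\\s+")
  get <- function(i) vapply(f, `[[`, "", i)
  chrom <- get(1L); num <- get(2L)
  b <- as.integer(get(3L)); e <- as.integer(get(4L))
  aa <- get(5L); ac <- get(6L)
  ib <- as.integer(get(7L)); ie <- as.integer(get(8L))
  strand <- ifelse(b <= e, "+", "-")
  start <- pmin(b, e); end <- pmax(b, e)
  introns <- lapply(seq_along(b), function(i) {
    if (ib[i] == 0L || ie[i] == 0L) NULL
    else matrix(c(min(ib[i], ie[i]), max(ib[i], ie[i])), ncol = 2L)
  })
  trna_genes(
    gene_id = paste0(chrom, ".trna", num, "-", aa, ac),
    chrom = chrom, start = start, end = end, strand = strand,
    amino_acid = aa, anticodon = ac, introns = introns
  )
}

#' Write tRNA gene annotations as BED6
#' @param genes a `trna_genes` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trna_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end,
                    genes$gene_id, 0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Genomic exon intervals of a gene (plus-strand sorted): [start, end] minus
# its introns. Returns a 2-column matrix.
exon_blocks <- function(start, end, introns) {
  if (is.null(introns) || nrow(introns) == 0L) {
    return(matrix(c(start, end), ncol = 2L))
  }
  starts <- c(start, introns[, 2L] + 1L)
  ends <- c(introns[, 1L] - 1L, end)
  cbind(starts, ends)
}
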