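# tRF classification from hit coordinates. Types are defined by terminal
# anchoring: tRF-5 starts at position 1 of a mature tRNA; tRF-3 ends at the
# mature 3' terminus (which includes the appended CCA); tRF-1 starts at the
# first base of the pre-tRNA 3' trailer. Only fragments of 15-28 nt are
# classified. Hits anchored at neither terminus yield no record and are
# tallied by the pipeline.

TRF_TYPES <- c("tRF-5", "tRF-3", "tRF-1")

# Map a transcript-coordinate interval on a mature tRNA to genomic
# coordinates through the gene's exon structure. Returns c(gstart, gend)
# (plus-strand span across spliced blocks).
mature_span_to_genomic <- function(gene, introns, t1, t2) {
  blocks <- exon_blocks(gene$start, gene$end, introns)
  if (gene$strand == "-") {
    blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  }
  widths <- blocks[, 2L] - blocks[, 1L] + 1L
  offs <- cumsum(c(0L, widths[-length(widths)]))
  map1 <- function(p) {
    b <- findInterval(p - 1L, offs)  # block containing transcript pos p
    o <- p - offs[b]
    if (gene$strand == "+") blocks[b, 1L] + o - 1L else blocks[b, 2L] - o + 1L
  }
  g <- vapply(t1:t2, map1, integer(1))
  c(min(g), max(g))
}

pre_pos_to_genomic <- function(gene, up_flank, p) {
  if (gene$strand == "+") gene$start - up_flank + p - 1L
  else gene$end + up_flank - p + 1L
}

#' Classify resolved hits into tRF records
#'
#' Applies the anchoring rules to every hit and lifts reference coordinates
#' back to the genome:
#' \itemize{
#'   \item mature hit with `sstart == 1` -> tRF-5;
#'   \item mature hit with `send == mature_length` -> tRF-3 (the terminus
#'     includes the non-templated CCA; matched CCA bases have no genomic
#'     coordinates, so `genomic_location` covers templated bases only and
#'     `cca_overlap` counts the rest);
#'   \item pre-tRNA hit with `sstart == trailer_start` -> tRF-1;
#'   \item anything else, or a fragment outside `[min_len, max_len]` -> no
#'     record.
#' }
#' A fragment spanning the whole mature tRNA (both termini anchored, only
#' possible when the mature length is at most `max_len`) is classified tRF-5
#' with `full_length_ambiguous = TRUE`.
#'
#' @param hits a hits `data.frame` that already passed
#'   [resolve_mature_precursor()].
#' @param reference the `trf_reference` the hits were mapped against.
#' @param min_len,max_len inclusive tRF length bounds (default 15 and 28).
#' @return a catalog `data.frame` of tRF records (one row per classified
#'   hit): species, trf_type, sequence, length, anticodon, amino_acid,
#'   source_ref, genomic_location, cca_overlap, frequency, tissue, gsm, pmid,
#'   full_length_ambiguous. Unclassified-hit count in `attr(, "n_unanchored")`.
#' @export
classify_hits <- function(hits, reference, min_len = 15L, max_len = 28L) {
  entries <- reference$entries
  genes <- reference$genes
  if (nrow(hits) == 0L) {
    out <- empty_catalog()
    attr(out, "n_unanchored") <- 0L
    return(out)
  }
  ei <- match(hits$ref_id, entries$ref_id)
  if (anyNA(ei)) stop("hits reference unknown ref_id(s)", call. = FALSE)
  len <- nchar(hits$sequence)
  kind <- entries$kind[ei]
  mlen <- entries$mature_length[ei]
  tstart <- entries$trailer_start[ei]
  if (any(kind == "pre" & is.na(tstart))) {
    stop("pre-tRNA entry without trailer_start", call. = FALSE)
  }
  type <- rep(NA_character_, nrow(hits))
  full_len <- kind == "mature" & hits$sstart == 1L & hits$send == mlen
  type[kind == "mature" & hits$send == mlen] <- "tRF-3"
  type[kind == "mature" & hits$sstart == 1L] <- "tRF-5"  # tie -> tRF-5
  type[kind == "pre" & hits$sstart == tstart] <- "tRF-1"
  type[len < min_len | len > max_len] <- NA_character_
  keep <- which(!is.na(type))
  n_unanchored <- sum(is.na(type) & len >= min_len & len <= max_len)
  if (any(full_len[keep])) {
    message(sum(full_len[keep]),
            " full-length mature match(es) classified tRF-5 (ambiguous)")
  }
  rows <- lapply(keep, function(i) {
    e <- entries[ei[i], ]
    gi <- match(e$gene_id, genes$gene_id)
    g <- genes[gi, ]
    introns <- genes$introns[[gi]]
    if (type[i] == "tRF-1") {
      g1 <- pre_pos_to_genomic(g, e$up_flank, hits$sstart[i])
      g2 <- pre_pos_to_genomic(g, e$up_flank, hits$send[i])
      span <- c(min(g1, g2), max(g1, g2))
      cca <- 0L
    } else {
      templated_end <- min(hits$send[i], mlen[i] - 3L)
      cca <- hits$send[i] - templated_end
      span <- mature_span_to_genomic(g, introns, hits$sstart[i], templated_end)
    }
    data.frame(
      species = hits$species[i], trf_type = type[i],
      sequence = hits$sequence[i], length = len[i],
      anticodon = e$anticodon, amino_acid = e$amino_acid,
      source_ref = e$ref_id,
      genomic_location = paste0(e$chrom, ":", span[1L], "-", span[2L],
                                "(", g$strand, ")"),
      cca_overlap = as.integer(cca), frequency = hits$frequency[i],
      tissue = hits$tissue[i], gsm = hits$gsm[i], pmid = hits$pmid[i],
      full_length_ambiguous = full_len[i], stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_catalog()
  rownames(out) <- NULL
  attr(out, "n_unanchored") <- n_unanchored
  out
}

empty_catalog <- function() {
  data.frame(
    species = character(0), trf_type = character(0), sequence = character(0),
    length = integer(0), anticodon = character(0), amino_acid = character(0),
    source_ref = character(0), genomic_location = character(0),
    cca_overlap = integer(0), frequency = integer(0), tissue = character(0),
    gsm = character(0), pmid = character(0),
    full_length_ambiguous = logical(0), stringsAsFactors = FALSE
  )
}

#' Count catalog entries and unique tRF sequences
#'
#' Entries are sample-level records; uniqueness is counted at the
#' (species, type, sequence) level, mirroring the entries-versus-unique
#' distinction of tRF catalogs.
#'
#' @param catalog a catalog `data.frame` from [classify_hits()].
#' @return a list with `total_entries`, `entries_by_type`,
#'   `unique_by_species_type` (data frame), `unique_by_type` and
#'   `unique_total`.
#' @export
count_unique <- function(catalog) {
  by_type <- table(factor(catalog$trf_type, levels = TRF_TYPES))
  u <- unique(catalog[, c("species", "trf_type", "sequence")])
  ut <- table(factor(u$trf_type, levels = TRF_TYPES))
  ust <- expand.grid(species = sort(unique(u$species)), trf_type = TRF_TYPES,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ust$unique_sequences <- as.integer(mapply(
    function(s, t) sum(u$species == s & u$trf_type == t),
    ust$species, ust$trf_type))
  list(
    total_entries = nrow(catalog),
    entries_by_type = stats::setNames(as.integer(by_type), TRF_TYPES),
    unique_by_species_type = ust[order_radix(ust$species, ust$trf_type), ],
    unique_by_type = stats::setNames(as.integer(ut), TRF_TYPES),
    unique_total = nrow(u)
  )
}

#' Write the tRF catalog TSV
#'
#' Rows are sorted by (species, trf_type, sequence) for reproducible diffs.
#'
#' @param catalog a catalog `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  cat_sorted <- catalog[order_radix(catalog$species, catalog$trf_type,
                                    catalog$sequence, catalog$source_ref), ]
  utils::write.table(cat_sorted, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the catalog as FASTA
#'
#' Record ids are the MD5 of `sequence|type|species`, so identical tRFs get
#' stable ids across runs.
#'
#' @inheritParams write_catalog
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  u <- unique(catalog[, c("species", "trf_type", "sequence")])
  u <- u[order_radix(u$species, u$trf_type, u$sequence), , drop = FALSE]
  ids <- vapply(paste(u$sequence, u$trf_type, u$species, sep = "|"),
                function(s) {
                  tf <- tempfile(); writeLines(s, tf)
                  on.exit(unlink(tf))
                  unname(tools::md5sum(tf))
                }, "")
  ss <- Biostrings::DNAStringSet(u$sequence)
  names(ss) <- paste0(ids, " ", u$trf_type, " ", u$species)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
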