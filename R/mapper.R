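# Exact plus-strand mapping. The acceptance rule for alignments — full query
# length, 100% identity, zero gaps, plus strand of the reference only —
# makes heuristic alignment unnecessary: the set of valid alignments is
# exactly the set of exact substring occurrences. Matching is therefore done
# with deterministic all-occurrence (overlap-aware) substring search; BLAST
# word-size/E-value behaviour is deliberately not emulated.

#' Build an exact-substring index over a reference
#'
#' @param reference a `trf_reference` from [build_reference()] (or its
#'   `entries` data frame).
#' @return an object of class `substring_index` supporting all-occurrence
#'   exact lookup via [map_fragments()].
#' @export
build_index <- function(reference) {
  entries <- if (inherits(reference, "trf_reference")) reference$entries
             else reference
  if (is.null(entries$sequence) || nrow(entries) == 0L) {
    stop("cannot index an empty reference", call. = FALSE)
  }
  subject <- Biostrings::DNAStringSet(entries$sequence)
  names(subject) <- entries$ref_id
  structure(list(subject = subject, entries = entries),
            class = "substring_index")
}

#' @export
print.substring_index <- function(x, ...) {
  cat("substring_index over", length(x$subject), "reference sequences (",
      sum(Biostrings::width(x$subject)), "nt )\n")
  invisible(x)
}

empty_hits <- function() {
  data.frame(sequence = character(0), frequency = integer(0),
             species = character(0), tissue = character(0),
             gsm = character(0), pmid = character(0),
             ref_id = character(0), kind = character(0),
             gene_id = character(0), sstart = integer(0), send = integer(0),
             stringsAsFactors = FALSE)
}

#' Map fragments to the reference by exact full-length match
#'
#' Reports every occurrence of every fragment on every reference sequence:
#' plus strand only (the reference already carries the transcribed strand, so
#' no reverse-complement search is performed), 100% identity, no gaps, the
#' full fragment length. Overlapping occurrences are all reported. Output is
#' ordered by fragment input order, then `ref_id`, then `sstart`.
#'
#' @param fragments a fragment `data.frame` (see [load_fragment_table()]).
#' @param index a `substring_index` from [build_index()].
#' @return a hits `data.frame`: fragment columns plus `ref_id`, `kind`,
#'   `gene_id`, `sstart`, `send` (1-based inclusive match coordinates on the
#'   reference). Fragments without any occurrence yield no rows.
#' @export
map_fragments <- function(fragments, index) {
  stopifnot(inherits(index, "substring_index"))
  if (is.null(fragments) || nrow(fragments) == 0L) return(empty_hits())
  ord_ref <- order_radix(index$entries$ref_id)
  pieces <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    q <- fragments$sequence[i]
    m <- Biostrings::vmatchPattern(q, index$subject, fixed = TRUE)
    counts <- lengths(m)
    if (sum(counts) == 0L) next
    starts <- unlist(IRanges::start(m), use.names = FALSE)
    ref_row <- rep.int(seq_along(counts), counts)
    o <- order_radix(index$entries$ref_id[ref_row], starts)
    ref_row <- ref_row[o]; starts <- starts[o]
    pieces[[i]] <- data.frame(
      fragments[rep.int(i, length(starts)),
                c("sequence", "frequency", "species", "tissue", "gsm", "pmid"),
                drop = FALSE],
      ref_id = index$entries$ref_id[ref_row],
      kind = index$entries$kind[ref_row],
      gene_id = index$entries$gene_id[ref_row],
      sstart = starts, send = starts + nchar(q) - 1L,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(empty_hits())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Resolve mature-versus-precursor hits
#'
#' A precursor sequence contains its own mature sequence (except the 3' CCA),
#' so a fragment from a mature tRNA body also matches the pre-tRNA entry of
#' the same gene. For each fragment, pre-tRNA hits on a gene are discarded
#' when the same fragment also hit that gene's mature entry; fragments
#' hitting only pre-tRNA entries (e.g. trailer fragments) keep their hits.
#' Resolution is gene-local: a mature hit on one gene never suppresses a pre
#' hit on a different gene.
#'
#' @param hits a hits `data.frame` from [map_fragments()].
#' @return the filtered hits `data.frame`; the number of removed rows is in
#'   `attr(, "n_shadowed")`.
#' @export
resolve_mature_precursor <- function(hits) {
  if (nrow(hits) == 0L) {
    attr(hits, "n_shadowed") <- 0L
    return(hits)
  }
  key <- paste(hits$sequence, hits$species, hits$gene_id, sep = "\r")
  mature_keys <- unique(key[hits$kind == "mature"])
  drop <- hits$kind == "pre" & key %in% mature_keys
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shadowed") <- sum(drop)
  out
}

#' Write a hits table
#'
#' Fixed column order: fragment sequence, frequency, sample columns, ref_id,
#' kind, gene_id, sstart, send.
#'
#' @param hits a hits `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- c("sequence", "frequency", "species", "tissue", "gsm", "pmid",
            "ref_id", "kind", "gene_id", "sstart", "send")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
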