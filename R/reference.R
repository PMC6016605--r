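# Reference construction: for each tRNA gene, a mature entry (genomic slice
# in transcript orientation, introns spliced out, "CCA" appended — the CCA is
# added post-transcriptionally by tRNA nucleotidyltransferase and is absent
# from the genome) and a pre-tRNA entry (gene plus flanking leader/trailer,
# default 40 nt each side, unspliced, no CCA). Both are stored on the
# transcribed strand so downstream mapping needs the plus strand only.

slice_chrom <- function(genome, gene_id, chrom, from, to) {
  if (!chrom %in% names(genome)) {
    stop("gene ", gene_id, ": chromosome '", chrom,
         "' not present in genome", call. = FALSE)
  }
  chr <- genome[[chrom]]
  if (from < 1L || to > length(chr)) {
    stop("gene ", gene_id, ": coordinates ", from, "-", to,
         " outside chromosome '", chrom, "' (length ", length(chr), ")",
         call. = FALSE)
  }
  as.character(Biostrings::subseq(chr, from, to))
}

ref_entry_row <- function(gene, species, kind, sequence, mature_length = NA_integer_,
                          trailer_start = NA_integer_, up_flank = NA_integer_,
                          down_flank = NA_integer_) {
  data.frame(
    ref_id = paste(species, gene$gene_id, kind, sep = "_"),
    kind = kind, gene_id = gene$gene_id, species = species,
    chrom = gene$chrom, start = gene$start, end = gene$end,
    strand = gene$strand, amino_acid = gene$amino_acid,
    anticodon = gene$anticodon, length = nchar(sequence),
    mature_length = mature_length, trailer_start = trailer_start,
    up_flank = up_flank, down_flank = down_flank,
    sequence = sequence, stringsAsFactors = FALSE
  )
}

#' Extract a mature tRNA reference sequence
#'
#' Takes the genomic slice of the gene, splices out annotated introns,
#' reverse-complements minus-strand genes into transcript orientation and
#' appends the non-templated 3' `CCA`.
#'
#' @param gene a one-row `trna_genes` table (or a list with the same fields).
#' @param genome a named `DNAStringSet` (see [read_genome()]).
#' @param species species label used in `ref_id`.
#' @param splice splice out annotated introns (default `TRUE`).
#' @return a one-row reference-entry `data.frame` with `kind = "mature"` and
#'   `mature_length` = spliced gene length + 3.
#' @export
extract_mature <- function(gene, genome, species = "species", splice = TRUE) {
  g <- as.list(gene[1L, , drop = FALSE])
  g$introns <- gene$introns[[1L]]
  plus <- slice_chrom(genome, g$gene_id, g$chrom, g$start, g$end)
  if (splice && !is.null(g$introns)) {
    blocks <- exon_blocks(g$start, g$end, g$introns)
    plus <- paste(substring(plus, blocks[, 1L] - g$start + 1L,
                            blocks[, 2L] - g$start + 1L), collapse = "")
  }
  tx <- if (g$strand == "-") revcomp(plus) else plus
  seq <- paste0(tx, "CCA")
  ref_entry_row(g, species, "mature", seq, mature_length = nchar(seq))
}

#' Extract a pre-tRNA reference sequence
#'
#' The precursor is modelled as the unspliced gene plus flanking genomic
#' sequence: `upstream` nt of 5' leader and `downstream` nt of 3' trailer in
#' transcript orientation (for minus-strand genes the 5' leader lies at
#' higher genomic coordinates). Flanks are clipped at chromosome boundaries
#' and the actual sizes recorded; no CCA is appended. `trailer_start` is the
#' 1-based position within the precursor of the first trailer base:
#' `actual_upstream + gene_length + 1`.
#'
#' @inheritParams extract_mature
#' @param upstream,downstream requested flank sizes in nt (default 40).
#' @return a one-row reference-entry `data.frame` with `kind = "pre"`.
#' @export
extract_pre <- function(gene, genome, species = "species",
                        upstream = 40L, downstream = 40L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  g <- as.list(gene[1L, , drop = FALSE])
  g$introns <- gene$introns[[1L]]
  if (!g$chrom %in% names(genome)) {
    stop("gene ", g$gene_id, ": chromosome '", g$chrom,
         "' not present in genome", call. = FALSE)
  }
  chrlen <- length(genome[[g$chrom]])
  if (g$start < 1L || g$end > chrlen) {
    stop("gene ", g$gene_id, ": coordinates outside chromosome '", g$chrom,
         "'", call. = FALSE)
  }
  # flank sizes in genomic orientation, then relabel by transcript sense
  left <- min(upstream * (g$strand == "+") + downstream * (g$strand == "-"),
              g$start - 1L)
  right <- min(downstream * (g$strand == "+") + upstream * (g$strand == "-"),
               chrlen - g$end)
  plus <- slice_chrom(genome, g$gene_id, g$chrom, g$start - left, g$end + right)
  if (g$strand == "+") {
    up <- left; down <- right
    seq <- plus
  } else {
    up <- right; down <- left
    seq <- revcomp(plus)
  }
  glen <- g$end - g$start + 1L
  ref_entry_row(g, species, "pre", seq,
                trailer_start = up + glen + 1L,
                up_flank = up, down_flank = down)
}

empty_entries <- function() {
  data.frame(
    ref_id = character(0), kind = character(0), gene_id = character(0),
    species = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), amino_acid = character(0),
    anticodon = character(0), length = integer(0),
    mature_length = integer(0), trailer_start = integer(0),
    up_flank = integer(0), down_flank = integer(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
}

#' Build the combined mature + pre-tRNA mapping reference
#'
#' For every gene, one mature and one pre-tRNA entry are produced (mature
#' first), in input gene order. The combined set is the mapping reference for
#' [map_fragments()].
#'
#' @param genes a `trna_genes` table with unique `gene_id`s.
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param species species label recorded in each `ref_id`.
#' @param upstream,downstream pre-tRNA flank sizes (default 40/40).
#' @param splice splice introns out of mature entries (default `TRUE`).
#' @return an object of class `trf_reference`: a list with `entries` (one row
#'   per reference sequence) and the source `genes` table.
#' @export
build_reference <- function(genes, genome, species = "species",
                            upstream = 40L, downstream = 40L, splice = TRUE) {
  genome <- read_genome(genome)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation", call. = FALSE)
  }
  if (nrow(genes) == 0L) {
    warning("no tRNA genes supplied; reference is empty", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    rbind(extract_mature(g, genome, species, splice = splice),
          extract_pre(g, genome, species, upstream, downstream))
  })
  entries <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  rownames(entries) <- NULL
  structure(list(entries = entries, genes = genes, species = species),
            class = "trf_reference")
}

#' @export
print.trf_reference <- function(x, ...) {
  cat("trf_reference:", nrow(x$genes), "tRNA genes,",
      nrow(x$entries), "entries (species:", x$species, ")\n")
  invisible(x)
}

ref_fasta_header <- function(e) {
  paste0(e$ref_id, "|", e$kind, "|", e$amino_acid, "|", e$anticodon, "|",
         e$chrom, ":", e$start, "-", e$end, "(", e$strand, ")")
}

#' Write the combined reference as FASTA
#'
#' Headers have the fixed form
#' `refid|kind|aa|anticodon|chrom:start-end(strand)` so downstream joins can
#' parse them exactly.
#'
#' @param reference a `trf_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  e <- reference$entries
  ss <- Biostrings::DNAStringSet(e$sequence)
  names(ss) <- ref_fasta_header(e)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the reference manifest TSV
#'
#' One row per entry: `ref_id`, `kind`, `gene_id`, lengths, `mature_length`,
#' `trailer_start` and actual flank sizes.
#'
#' @inheritParams write_reference_fasta
#' @return `path`, invisibly.
#' @export
write_reference_manifest <- function(reference, path) {
  cols <- c("ref_id", "kind", "gene_id", "species", "chrom", "start", "end",
            "strand", "amino_acid", "anticodon", "length", "mature_length",
            "trailer_start", "up_flank", "down_flank")
  utils::write.table(reference$entries[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
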