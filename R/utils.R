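#' @keywords internal
"_PACKAGE"

# Internal string helpers shared across modules. Sequences are handled as
# uppercase DNA character vectors; Biostrings does the heavy lifting where a
# vectorised or overlap-aware primitive is needed.

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalise RNA/DNA input to uppercase DNA
#'
#' Uppercases and maps U to T. Does not validate the alphabet; see
#' [is_dna()].
#' @param x character vector.
#' @keywords internal
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Test for a strict A/C/G/T alphabet
#' @param x character vector (already normalised).
#' @return logical vector.
#' @keywords internal
is_dna <- function(x) {
  !grepl("[^ACGT]", x)
}

#' Deterministic, locale-independent ordering
#'
#' Wrapper around [order()] with radix sorting so that character sort order
#' (and hence every written output) does not depend on the session locale.
#' @keywords internal
order_radix <- function(...) {
  order(..., method = "radix")
}

#' Random DNA string
#' @param n length in nt.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Load a genome as a DNAStringSet
#'
#' Accepts a FASTA path or an existing `DNAStringSet` (returned unchanged
#' apart from header trimming). Sequence names are truncated at the first
#' whitespace so they match chromosome names in annotations.
#'
#' @param genome path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome)) {
      stop("genome FASTA not found: ", genome, call. = FALSE)
    }
    gs <- Biostrings::readDNAStringSet(genome)
  } else {
    stop("`genome` must be a FASTA path or a DNAStringSet", call. = FALSE)
  }
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

# Standard tRNA isotypes with one representative anticodon per codon family;
# the fixture generator samples from this table.
TRNA_ISOTYPES <- data.frame(
  amino_acid = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val"),
  anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC", "GCC",
                "GTG", "AAT", "AAG", "TTT", "CAT", "GAA", "AGG", "AGA",
                "AGT", "CCA", "GTA", "TAC"),
  stringsAsFactors = FALSE
)
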