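# Independent brute-force oracles and tiny hand-built inputs shared across
# tests. These deliberately avoid the package's own code paths: sequence
# assembly is character-by-character, substring search is a sliding window.

# Complement/reverse done by hand (no Biostrings) for oracle independence.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Character-by-character mature builder: slice, drop intron bases, reverse
# complement for minus strand, append CCA.
oracle_mature <- function(chrom_seq, start, end, strand, introns = NULL) {
  chars <- strsplit(chrom_seq, "")[[1]][start:end]
  pos <- start:end
  if (!is.null(introns)) {
    drop <- unlist(lapply(seq_len(nrow(introns)),
                          function(i) introns[i, 1]:introns[i, 2]))
    chars <- chars[!(pos %in% drop)]
  }
  s <- paste(chars, collapse = "")
  if (strand == "-") s <- oracle_revcomp(s)
  paste0(s, "CCA")
}

# All-occurrence sliding-window substring scan (overlap-aware).
oracle_occurrences <- function(query, subject) {
  n <- nchar(subject); m <- nchar(query)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(subject, starts, starts + m - 1L) == query]
}

# Random genome with one planted gene at known coordinates; returns the
# pieces needed to call extract_* directly.
random_gene_case <- function(gene_len = sample(60:90, 1), strand = sample(c("+", "-"), 1),
                             chrom_len = 600L, introns = NULL) {
  chrom <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
  start <- sample(100:(chrom_len - gene_len - 100L), 1)
  genes <- trna_genes("g1", "chrZ", start, start + gene_len - 1L, strand,
                      "Ala", "AGC",
                      introns = if (is.null(introns)) NULL else list(introns))
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom, "chrZ"))
  list(chrom = chrom, genes = genes, genome = genome,
       start = start, end = start + gene_len - 1L, strand = strand)
}

# Minimal FASTQ writer for hand-made records.
write_fastq <- function(path, seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# One fragment-table file from sequence/count vectors.
write_frag_table <- function(path, seqs, counts, header = FALSE) {
  lines <- paste(seqs, counts, sep = "\t")
  if (header) lines <- c("sequence\tcount", lines)
  writeLines(lines, path)
  path
}

test_sample <- function(species = "Testus plantus") sample_meta(species, "leaf", "GSM1", "1")

# Shared fixture pipeline run used by several test files.
run_fixture_pipeline <- function(seed, type = "table", plan = spike_plan(seed = seed)) {
  fx <- make_genome(plan)
  lib <- make_library(fx)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  p <- write_fixtures(fx, dir, lib)
  samples <- data.frame(
    species = plan$species, tissue = "leaf", gsm = "GSM1", pmid = "1",
    path = unname(p[[if (type == "table") "frags" else "reads"]]),
    type = type, stringsAsFactors = FALSE
  )
  run <- run_pipeline(p[["genome"]], p[["genes"]], samples,
                      adapter = if (type == "fastq") plan$adapter else NULL)
  list(fx = fx, lib = lib, run = run, paths = p, samples = samples)
}

# The ledger's kept set for a given input path, as "sequence type" keys.
ledger_kept <- function(lib, type = "table") {
  fate <- if (type == "table") lib$ledger$fate_table else lib$ledger$fate_fastq
  keep <- !is.na(fate) & startsWith(fate, "kept:")
  paste(lib$ledger$sequence[keep], sub("^kept:", "", fate[keep]))
}
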