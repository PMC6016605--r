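# Reference construction: mature = spliced gene + CCA in transcript
# orientation; pre = gene +/- 40 nt flanks, unspliced, with trailer_start
# marking the first trailer base.

make_toy_genome <- function(chr1) {
  Biostrings::DNAStringSet(stats::setNames(chr1, "chr1"))
}

test_that("mature extraction appends CCA and respects strand", {
  # gene body GGGAAA planted at 11..16 inside a fixed background
  chrom <- paste0(strrep("T", 10), "GGGAAA", strrep("T", 10))
  genome <- make_toy_genome(chrom)
  plus <- trna_genes("g+", "chr1", 11, 16, "+", "Ala", "AGC")
  minus <- trna_genes("g-", "chr1", 11, 16, "-", "Ala", "AGC")
  m_plus <- extract_mature(plus, genome)
  m_minus <- extract_mature(minus, genome)
  expect_equal(m_plus$sequence, "GGGAAACCA")
  expect_equal(m_plus$mature_length, 9L)
  expect_equal(m_minus$sequence, "TTTCCCCCA")  # revcomp(GGGAAA) + CCA
  expect_equal(m_minus$kind, "mature")
})

test_that("mature extraction matches a character-by-character oracle", {
  set.seed(41)
  for (i in 1:40) {
    gl <- sample(60:90, 1)
    case <- random_gene_case(gene_len = gl)
    got <- extract_mature(case$genes, case$genome)
    want <- oracle_mature(case$chrom, case$start, case$end, case$strand)
    expect_identical(got$sequence, want)
    expect_identical(got$mature_length, gl + 3L)
  }
})

test_that("intron splicing removes intron bases from mature but not pre", {
  set.seed(42)
  case <- random_gene_case(gene_len = 80)
  istart <- case$start + 35L; iend <- istart + 11L
  genes <- trna_genes("g1", "chrZ", case$start, case$end, case$strand,
                      "Tyr", "GTA", introns = list(cbind(istart, iend)))
  got <- extract_mature(genes, case$genome)
  want <- oracle_mature(case$chrom, case$start, case$end, case$strand,
                        introns = cbind(istart, iend))
  expect_identical(got$sequence, want)
  expect_identical(got$mature_length, 80L - 12L + 3L)
  # --no-splice behaviour reproduces the unspliced reading
  unspliced <- extract_mature(genes, case$genome, splice = FALSE)
  expect_identical(unspliced$sequence,
                   oracle_mature(case$chrom, case$start, case$end, case$strand))
  # pre entry is never spliced
  pre <- extract_pre(genes, case$genome)
  expect_identical(pre$length, 40L + 80L + 40L)
})

test_that("pre-tRNA entries have correct flanks, trailer_start and clipping", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  genome <- make_toy_genome(chrom)
  g <- trna_genes("g1", "chr1", 101, 172, "+", "Ala", "AGC")  # length 72
  pre <- extract_pre(g, genome)
  expect_equal(pre$length, 152L)
  expect_equal(pre$trailer_start, 113L)  # 40 + 72 + 1
  # gene starting at position 10: upstream flank clipped to 9
  g2 <- trna_genes("g2", "chr1", 10, 81, "+", "Ala", "AGC")
  pre2 <- extract_pre(g2, genome)
  expect_equal(pre2$up_flank, 9L)
  expect_equal(pre2$length, 9L + 72L + 40L)
  expect_equal(pre2$trailer_start, 9L + 72L + 1L)
  # trailer_start == length - actual_downstream + 1 in both cases
  expect_equal(pre$trailer_start, pre$length - pre$down_flank + 1L)
  expect_equal(pre2$trailer_start, pre2$length - pre2$down_flank + 1L)
})

test_that("minus-strand pre-tRNA equals revcomp of the genomic window", {
  set.seed(43)
  for (i in 1:20) {
    case <- random_gene_case(strand = "-")
    pre <- extract_pre(case$genes, case$genome)
    # transcript 5' flank of a minus-strand gene lies at higher genomic coords
    window <- substr(case$chrom, case$start - 40L, case$end + 40L)
    expect_identical(pre$sequence, oracle_revcomp(window))
    expect_identical(pre$trailer_start, 40L + (case$end - case$start + 1L) + 1L)
  }
})

test_that("out-of-bounds and unknown chromosomes raise named errors", {
  genome <- make_toy_genome(strrep("A", 50))
  g <- trna_genes("gX", "chr1", 10, 80, "+", "Ala", "AGC")
  expect_error(extract_mature(g, genome), "gX")
  g2 <- trna_genes("gY", "chrMissing", 1, 20, "+", "Ala", "AGC")
  expect_error(extract_mature(g2, genome), "chrMissing")
})

test_that("build_reference emits mature+pre per gene in deterministic order", {
  set.seed(44)
  chrom <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
  genome <- make_toy_genome(chrom)
  starts <- seq(100, 4500, by = 900)[1:5]
  genes <- trna_genes(paste0("g", 1:5), "chr1", starts, starts + 71,
                      rep(c("+", "-"), length.out = 5), "Gly", "GCC")
  ref <- build_reference(genes, genome, species = "toy")
  expect_equal(nrow(ref$entries), 10L)
  expect_equal(ref$entries$kind, rep(c("mature", "pre"), 5))
  expect_equal(ref$entries$gene_id, rep(paste0("g", 1:5), each = 2))
  # mature minus CCA sits at pre positions [41, 40+L] for unclipped flanks
  for (i in 1:5) {
    mat <- ref$entries$sequence[2 * i - 1]
    pre <- ref$entries$sequence[2 * i]
    L <- nchar(mat) - 3L
    expect_identical(paste0(substr(pre, 41, 40 + L), "CCA"), mat)
  }
  expect_error(build_reference(genes[c(1, 1), ], genome), "duplicate")
  expect_warning(ref0 <- build_reference(genes[0, ], genome), "empty")
  expect_equal(nrow(ref0$entries), 0L)
})

test_that("building from a mirrored genome gives identical transcripts", {
  # reverse-complement the chromosome and flip the annotation: transcript
  # sequences must be unchanged
  set.seed(45)
  case <- random_gene_case()
  n <- nchar(case$chrom)
  mirror <- oracle_revcomp(case$chrom)
  flip_start <- n - case$end + 1L
  flip_end <- n - case$start + 1L
  flip_strand <- if (case$strand == "+") "-" else "+"
  g2 <- trna_genes("g1", "chrZ", flip_start, flip_end, flip_strand,
                   "Ala", "AGC")
  genome2 <- Biostrings::DNAStringSet(stats::setNames(mirror, "chrZ"))
  expect_identical(extract_mature(g2, genome2)$sequence,
                   extract_mature(case$genes, case$genome)$sequence)
  expect_identical(extract_pre(g2, genome2)$sequence,
                   extract_pre(case$genes, case$genome)$sequence)
})

test_that("reference FASTA headers carry the parse-exact join fields", {
  chrom <- paste0(strrep("A", 60), strrep("C", 72), strrep("A", 60))
  genome <- make_toy_genome(chrom)
  genes <- trna_genes("g1", "chr1", 61, 132, "+", "Ala", "AGC")
  ref <- build_reference(genes, genome, species = "sp")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa)
  headers <- grep("^>", readLines(fa), value = TRUE)
  expect_equal(headers[1], ">sp_g1_mature|mature|Ala|AGC|chr1:61-132(+)")
  expect_equal(headers[2], ">sp_g1_pre|pre|Ala|AGC|chr1:61-132(+)")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_reference_manifest(ref, tsv)
  man <- read.delim(tsv)
  expect_equal(man$trailer_start[man$kind == "pre"], 40L + 72L + 1L)
})

test_that("annotation readers convert coordinates correctly", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t172\ttRNA-Ala-AGC-1-1\t0\t-", bed)
  g <- read_trna_bed(bed)
  expect_equal(g$start, 101L)  # 0-based half-open -> 1-based inclusive
  expect_equal(g$end, 172L)
  expect_equal(g$strand, "-")
  expect_equal(g$amino_acid, "Ala")
  expect_equal(g$anticodon, "AGC")
  ts <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "Sequence\t\ttRNA\tBounds\t",
    "Name    \ttRNA #\tBegin\tEnd",
    "--------\t------\t-----\t---",
    "chr1 \t1\t300\t228\tTyr\tGTA\t250\t261\t55.8",
    "chr1 \t2\t400\t471\tAla\tAGC\t0\t0\t60.1"
  ), ts)
  g2 <- read_trnascan(ts)
  expect_equal(g2$strand, c("-", "+"))
  expect_equal(g2$start, c(228L, 400L))
  expect_equal(g2$end, c(300L, 471L))
  expect_equal(g2$introns[[1]], cbind(250L, 261L))
  expect_null(g2$introns[[2]])
})
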