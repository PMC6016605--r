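# Classification rules: tRF-5 anchors at mature position 1, tRF-3 at the
# mature 3' terminus (CCA included), tRF-1 at the first trailer base of the
# pre-tRNA; 15-28 nt only; genome lift-over covers templated bases only.

# Build a real reference around one planted gene so coordinates are honest.
planted_case <- function(strand = "+", gene_len = 76L, seed = 21) {
  set.seed(seed)
  case <- random_gene_case(gene_len = gene_len, strand = strand)
  ref <- build_reference(case$genes, case$genome, species = "sp")
  c(case, list(ref = ref,
               mature = ref$entries$sequence[1],
               pre = ref$entries$sequence[2]))
}

hit_row <- function(case, ref_row, sstart, send) {
  e <- case$ref$entries[ref_row, ]
  frag <- substr(e$sequence, sstart, send)
  data.frame(sequence = frag, frequency = 200L, species = "sp",
             tissue = "leaf", gsm = "", pmid = "", ref_id = e$ref_id,
             kind = e$kind, gene_id = e$gene_id, sstart = sstart,
             send = send, stringsAsFactors = FALSE)
}

test_that("terminal anchoring decides the tRF type", {
  case <- planted_case()
  mlen <- 76L + 3L
  cat5 <- classify_hits(hit_row(case, 1, 1, 20), case$ref)
  expect_equal(cat5$trf_type, "tRF-5")
  expect_equal(cat5$length, 20L)
  cat3 <- classify_hits(hit_row(case, 1, mlen - 19L, mlen), case$ref)
  expect_equal(cat3$trf_type, "tRF-3")
  expect_equal(cat3$cca_overlap, 3L)
  ts <- case$ref$entries$trailer_start[2]
  cat1 <- classify_hits(hit_row(case, 2, ts, ts + 17L), case$ref)
  expect_equal(cat1$trf_type, "tRF-1")
  expect_equal(cat1$length, 18L)
  # internal hit: anchored at neither terminus
  none <- classify_hits(hit_row(case, 1, 5, 24), case$ref)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_unanchored"), 1L)
  # a 5'-anchored pre-tRNA (leader-containing) hit is not a tRF
  leader <- classify_hits(hit_row(case, 2, 1, 20), case$ref)
  expect_equal(nrow(leader), 0L)
})

test_that("the 15-28 nt length rule bounds classification", {
  case <- planted_case()
  expect_equal(nrow(classify_hits(hit_row(case, 1, 1, 29), case$ref)), 0L)
  expect_equal(nrow(classify_hits(hit_row(case, 1, 1, 14), case$ref)), 0L)
  expect_equal(classify_hits(hit_row(case, 1, 1, 28), case$ref)$trf_type, "tRF-5")
  expect_equal(classify_hits(hit_row(case, 1, 1, 15), case$ref)$trf_type, "tRF-5")
})

test_that("a full-length mature match takes the tRF-5 tie rule with a flag", {
  case <- planted_case(gene_len = 24L)  # mature length 27 <= 28
  mlen <- 24L + 3L
  expect_message(cat <- classify_hits(hit_row(case, 1, 1, mlen), case$ref),
                 "ambiguous")
  expect_equal(cat$trf_type, "tRF-5")
  expect_true(cat$full_length_ambiguous)
})

test_that("genomic lift-over re-extracts the templated fragment bases", {
  for (strand in c("+", "-")) {
    case <- planted_case(strand = strand, seed = 22 + (strand == "-"))
    mlen <- 79L
    ts <- case$ref$entries$trailer_start[2]
    hits <- rbind(hit_row(case, 1, 1, 20),            # tRF-5
                  hit_row(case, 1, mlen - 19L, mlen), # tRF-3 over CCA
                  hit_row(case, 2, ts, ts + 17L))     # tRF-1
    cat <- classify_hits(hits, case$ref)
    expect_equal(nrow(cat), 3L)
    for (i in seq_len(nrow(cat))) {
      loc <- cat$genomic_location[i]
      m <- regmatches(loc, regexec("^(.+):(\\d+)-(\\d+)\\(([+-])\\)$", loc))[[1]]
      gstart <- as.integer(m[3]); gend <- as.integer(m[4])
      slice <- substr(case$chrom, gstart, gend)
      if (m[5] == "-") slice <- oracle_revcomp(slice)
      templated <- substr(cat$sequence[i], 1,
                          cat$length[i] - cat$cca_overlap[i])
      expect_identical(slice, templated)
      # location width covers exactly the templated bases
      expect_equal(gend - gstart + 1L, cat$length[i] - cat$cca_overlap[i])
    }
    # tRF-1 lies strictly downstream (transcript sense) of the gene body
    t1 <- cat[cat$trf_type == "tRF-1", ]
    m <- regmatches(t1$genomic_location,
                    regexec(":(\\d+)-(\\d+)", t1$genomic_location))[[1]]
    if (strand == "+") {
      expect_gt(as.integer(m[2]), case$end)
    } else {
      expect_lt(as.integer(m[3]), case$start)
    }
  }
})

test_that("lift-over across a spliced intron spans the genomic gap", {
  set.seed(30)
  case <- random_gene_case(gene_len = 80)
  istart <- case$start + 10L; iend <- istart + 11L
  genes <- trna_genes("g1", "chrZ", case$start, case$end, case$strand,
                      "Tyr", "GTA", introns = list(cbind(istart, iend)))
  ref <- build_reference(genes, case$genome, species = "sp")
  e <- ref$entries[1, ]
  hit <- data.frame(sequence = substr(e$sequence, 1, 20), frequency = 200L,
                    species = "sp", tissue = "", gsm = "", pmid = "",
                    ref_id = e$ref_id, kind = "mature", gene_id = "g1",
                    sstart = 1L, send = 20L, stringsAsFactors = FALSE)
  cat <- classify_hits(hit, ref)
  m <- regmatches(cat$genomic_location,
                  regexec(":(\\d+)-(\\d+)", cat$genomic_location))[[1]]
  width <- as.integer(m[3]) - as.integer(m[2]) + 1L
  expect_equal(width, 20L + 12L)  # fragment crosses the 12 nt intron
})

test_that("catalog records join metadata and spiked types are recovered", {
  plan <- spike_plan(seed = 5L, n_trf5 = 3L, n_trf3 = 2L, n_trf1 = 1L,
                     n_decoys = 50L,
                     decoy_kinds = c("internal", "off_by_one_5p",
                                     "off_by_one_3p", "mismatch", "revcomp",
                                     "non_trna"))
  fx <- make_genome(plan)
  lib <- make_library(fx)
  ref <- build_reference(fx$genes, fx$genome, species = plan$species)
  sm <- sample_meta(plan$species, "root", "GSM77", "99")
  frags <- data.frame(sequence = lib$ledger$sequence,
                      frequency = lib$ledger$freq_table,
                      species = sm$species, tissue = sm$tissue, gsm = sm$gsm,
                      pmid = sm$pmid, stringsAsFactors = FALSE)
  hits <- resolve_mature_precursor(map_fragments(frags, build_index(ref)))
  cat <- classify_hits(hits, ref)
  expect_equal(sum(cat$trf_type == "tRF-5"), 3L)
  expect_equal(sum(cat$trf_type == "tRF-3"), 2L)
  expect_equal(sum(cat$trf_type == "tRF-1"), 1L)
  expect_true(all(cat$gsm == "GSM77"))
  expect_true(all(cat$length >= 15L & cat$length <= 28L))
  # anticodon/isotype flow from the reference entries
  m <- match(cat$source_ref, ref$entries$ref_id)
  expect_equal(cat$anticodon, ref$entries$anticodon[m])
  # empty input degenerates cleanly
  expect_equal(nrow(classify_hits(hits[0, ], ref)), 0L)
})

test_that("entries-versus-unique accounting follows the species/type rule", {
  rec <- function(sp, type, seq) {
    data.frame(species = sp, trf_type = type, sequence = seq,
               length = nchar(seq), anticodon = "AGC", amino_acid = "Ala",
               source_ref = "r", genomic_location = "chr1:1-20(+)",
               cca_overlap = 0L, frequency = 50L, tissue = "t", gsm = "",
               pmid = "", full_length_ambiguous = FALSE,
               stringsAsFactors = FALSE)
  }
  s <- strrep("ACGTG", 4)
  s2 <- strrep("TTGCA", 4)
  cat <- rbind(rec("A", "tRF-5", s), rec("A", "tRF-5", s),  # two samples
               rec("B", "tRF-5", s2))
  cu <- count_unique(cat)
  expect_equal(cu$total_entries, 3L)
  expect_equal(unname(cu$entries_by_type["tRF-5"]), 3L)
  expect_equal(cu$unique_by_type[["tRF-5"]], 2L)  # unique per species+type
  expect_equal(cu$unique_total, 2L)
  # disjoint sequence sets across species add up
  cat2 <- rbind(rec("A", "tRF-3", s), rec("B", "tRF-3", s2))
  expect_equal(count_unique(cat2)$unique_by_type[["tRF-3"]], 2L)
})
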