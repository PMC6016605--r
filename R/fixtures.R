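# Synthetic fixtures: toy genomes with planted tRNA genes and spiked small
# RNA libraries with a machine-readable ground-truth ledger. Every generated
# fragment carries an intended pipeline fate (kept as a tRF type, or
# rejected with a reason), which end-to-end tests compare against the
# pipeline's actual output. Gene bodies are random DNA (realistic tRNA
# covariance-model sequences are out of scope); what matters for the
# pipeline is coordinates, strands, anchors and thresholds.
#
# RNG discipline: a single integer seed governs everything, with one derived
# stream per artifact (genome layout, library spikes) so that changing one
# artifact's knobs does not shift the other's draws.

#' Describe a synthetic fixture
#'
#' @param seed integer seed governing all randomness.
#' @param n_genes number of planted tRNA genes.
#' @param n_contigs number of genome contigs (1 or 2).
#' @param contig_length length of each contig in nt.
#' @param gene_length_range inclusive range of gene lengths (nt).
#' @param n_trf5,n_trf3,n_trf1 numbers of spiked true fragments per type.
#' @param trf_length_range inclusive spiked-fragment length range, within
#'   15-28 nt.
#' @param n_decoys number of decoy fragments, spread round-robin over
#'   `decoy_kinds`.
#' @param decoy_kinds decoy classes to generate: `internal` (unanchored
#'   mature-body fragment), `off_by_one_5p`/`off_by_one_3p` (anchor shifted
#'   by one), `low_freq` (valid anchor at the failing frequency boundaries 9
#'   and 100), `mismatch` (single substitution), `revcomp` (reverse
#'   complement of a true fragment), `non_trna` (random sequence),
#'   `low_quality` (valid anchor, one base below Q28; FASTQ only).
#' @param freq_range clonal-frequency range for fragments meant to pass both
#'   the table (> 9) and FASTQ (> 100) thresholds.
#' @param adapter 3' adapter appended to FASTQ reads.
#' @param read_length FASTQ read cycle length.
#' @param species species label for the fixture.
#' @return a list of class `spike_plan`.
#' @export
spike_plan <- function(seed = 1L, n_genes = 10L, n_contigs = 1L,
                       contig_length = 20000L,
                       gene_length_range = c(70L, 90L),
                       n_trf5 = 5L, n_trf3 = 4L, n_trf1 = 3L,
                       trf_length_range = c(15L, 28L),
                       n_decoys = 49L,
                       decoy_kinds = c("internal", "off_by_one_5p",
                                       "off_by_one_3p", "low_freq",
                                       "mismatch", "revcomp", "non_trna",
                                       "low_quality"),
                       freq_range = c(101L, 400L),
                       adapter = "AGATCGGAAGAGC",
                       read_length = 50L,
                       species = "Planta synthetica") {
  stopifnot(seed >= 0, n_genes >= 0, n_trf5 >= 0, n_trf3 >= 0, n_trf1 >= 0,
            n_decoys >= 0, diff(gene_length_range) >= 0,
            trf_length_range[1L] >= 15L, trf_length_range[2L] <= 28L,
            diff(trf_length_range) >= 0, n_contigs %in% c(1L, 2L))
  structure(as.list(environment()), class = "spike_plan")
}

# Derived per-artifact seeds, kept below 2^31.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Generate a toy genome with planted tRNA genes
#'
#' Emits random contigs, plants `n_genes` non-overlapping tRNA genes on both
#' strands (anticodons drawn from the standard isotype table) and records
#' the ground truth: gene coordinates, the mature sequence (transcript +
#' CCA, built directly from the planted transcript, independently of
#' [build_reference()]), and the 40 nt leader and trailer sequences in
#' transcript orientation.
#'
#' @param plan a [spike_plan()].
#' @return a list of class `trf_fixture`: `genome` (`DNAStringSet`), `genes`
#'   (a `trna_genes` table) and `truth` (a data frame with `gene_id`,
#'   `mature`, `leader`, `trailer`).
#' @export
make_genome <- function(plan) {
  stopifnot(inherits(plan, "spike_plan"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(plan$seed, 1L))
  contigs <- vapply(seq_len(plan$n_contigs),
                    function(i) random_dna(plan$contig_length), "")
  names(contigs) <- paste0("chr", seq_len(plan$n_contigs))
  margin <- 60L  # keeps 40 nt flanks clear of contig ends and other genes
  placed <- list()
  occupied <- lapply(contigs, function(x) integer(0))
  for (i in seq_len(plan$n_genes)) {
    L <- sample(plan$gene_length_range[1L]:plan$gene_length_range[2L], 1L)
    ok <- FALSE
    for (try in 1:200) {
      chrom <- sample(names(contigs), 1L)
      start <- sample(seq(margin + 1L, plan$contig_length - L - margin), 1L)
      span <- (start - margin):(start + L - 1L + margin)
      if (!any(span %in% occupied[[chrom]])) {
        occupied[[chrom]] <- c(occupied[[chrom]], span)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", plan$n_genes, " non-overlapping genes; ",
           "increase contig_length", call. = FALSE)
    }
    strand <- sample(c("+", "-"), 1L)
    iso <- TRNA_ISOTYPES[sample(nrow(TRNA_ISOTYPES), 1L), ]
    tx <- random_dna(L)
    placed[[i]] <- list(gene_id = sprintf("tRNA%03d", i), chrom = chrom,
                        start = start, end = start + L - 1L, strand = strand,
                        amino_acid = iso$amino_acid,
                        anticodon = iso$anticodon, tx = tx)
  }
  # plant the genes: plus-strand slice is the transcript (or its revcomp)
  for (p in placed) {
    plus <- if (p$strand == "-") revcomp(p$tx) else p$tx
    substr(contigs[p$chrom], p$start, p$end) <- plus
  }
  get1 <- function(f) vapply(placed, `[[`, vector(mode(placed[[1L]][[f]]), 1L), f)
  genes <- if (length(placed)) {
    trna_genes(gene_id = get1("gene_id"), chrom = get1("chrom"),
               start = get1("start"), end = get1("end"),
               strand = get1("strand"), amino_acid = get1("amino_acid"),
               anticodon = get1("anticodon"))
  } else {
    trna_genes(character(0), character(0), integer(0), integer(0), character(0))
  }
  flank40 <- function(p, which) {
    chrom <- contigs[[p$chrom]]
    if (p$strand == "+") {
      s <- if (which == "leader") substr(chrom, p$start - 40L, p$start - 1L)
           else substr(chrom, p$end + 1L, p$end + 40L)
      s
    } else {
      s <- if (which == "leader") substr(chrom, p$end + 1L, p$end + 40L)
           else substr(chrom, p$start - 40L, p$start - 1L)
      revcomp(s)
    }
  }
  truth <- data.frame(
    gene_id = if (length(placed)) get1("gene_id") else character(0),
    mature = vapply(placed, function(p) paste0(p$tx, "CCA"), ""),
    leader = vapply(placed, function(p) flank40(p, "leader"), ""),
    trailer = vapply(placed, function(p) flank40(p, "trailer"), ""),
    stringsAsFactors = FALSE
  )
  structure(list(genome = Biostrings::DNAStringSet(contigs), genes = genes,
                 truth = truth, plan = plan),
            class = "trf_fixture")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# All forward substring checks used to guard decoy fates against chance
# collisions with the reference.
occurs_in_any <- function(seq, refs) {
  any(vapply(refs, function(r) grepl(seq, r, fixed = TRUE), logical(1)))
}

#' Spike a small RNA library with ground-truth fragments and decoys
#'
#' Generates true tRF-5/tRF-3/tRF-1 fragments (correct terminal anchors,
#' frequencies above both the table and FASTQ thresholds) and decoys per
#' `plan$decoy_kinds`, then records every fragment in a ledger with its
#' intended fate on each input path (`fate_table` for the unique-fragment
#' table, `fate_fastq` for the FASTQ path). Fates differ between paths only
#' where the thresholds differ: a frequency-100 fragment passes the table
#' rule (> 9) but fails the FASTQ rule (> 100), and low-quality reads exist
#' only on the FASTQ path. Decoy sequences are checked against the reference
#' (and regenerated on collision) so that ledger fates hold by construction.
#'
#' @param fixture a `trf_fixture` from [make_genome()].
#' @return a list of class `spike_library`: `ledger` (one row per fragment:
#'   sequence, class, source gene, frequency, per-path fates), `table`
#'   (sequence + count rows for the fragment-table path) and `reads`
#'   (sequence/quality vectors for the FASTQ path).
#' @export
make_library <- function(fixture) {
  stopifnot(inherits(fixture, "trf_fixture"))
  plan <- fixture$plan
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(plan$seed, 2L))
  truth <- fixture$truth
  genes <- fixture$genes
  if (nrow(truth) == 0L) stop("fixture has no genes to spike from", call. = FALSE)
  # forward reference strings (mature with CCA; pre = leader+gene+trailer)
  mature <- truth$mature
  pre <- paste0(truth$leader,
                vapply(seq_len(nrow(truth)),
                       function(i) substr(mature[i], 1L, nchar(mature[i]) - 3L),
                       ""),
                truth$trailer)
  refs <- c(mature, pre)
  rand_len <- function() {
    sample(plan$trf_length_range[1L]:plan$trf_length_range[2L], 1L)
  }
  rand_freq <- function() sample(plan$freq_range[1L]:plan$freq_range[2L], 1L)
  taken <- character(0)
  ledger <- list()
  add <- function(class, sequence, source_gene, freq_table, n_reads,
                  fate_table, fate_fastq, min_qual = 40L) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      id = sprintf("frag%03d", length(ledger) + 1L), class = class,
      sequence = sequence, length = nchar(sequence),
      source_gene = source_gene, freq_table = freq_table, n_reads = n_reads,
      min_qual = min_qual, fate_table = fate_table, fate_fastq = fate_fastq,
      stringsAsFactors = FALSE
    )
    taken <<- c(taken, sequence)
  }
  # draw a fragment of a given anchored class from a random gene, retrying
  # until it is unique in the library and its fate cannot be confounded
  draw_anchored <- function(anchor) {
    for (try in 1:100) {
      gi <- sample(nrow(truth), 1L)
      len <- rand_len()
      m <- mature[gi]; L <- nchar(m)
      seq <- switch(anchor,
        trf5 = substr(m, 1L, len),
        trf3 = substr(m, L - len + 1L, L),
        trf1 = substr(truth$trailer[gi], 1L, len),
        internal = if (L >= len + 4L) substr(m, 3L, 3L + len - 1L) else NA,
        off5 = substr(m, 2L, 2L + len - 1L),
        off3 = substr(m, L - len, L - 1L)
      )
      if (is.na(seq) || nchar(seq) != len) next
      if (seq %in% taken) next
      # guard against chance anchoring elsewhere: each class must anchor
      # exactly once, at its intended terminus only
      n5 <- sum(startsWith(mature, seq))
      n3 <- sum(endsWith(mature, seq))
      n1 <- sum(startsWith(truth$trailer, seq))
      ok <- switch(anchor,
        trf5 = n5 == 1L && n3 == 0L && n1 == 0L,
        trf3 = n3 == 1L && n5 == 0L && n1 == 0L,
        trf1 = n1 == 1L && n5 == 0L && n3 == 0L,
        internal = , off5 = , off3 = n5 + n3 + n1 == 0L
      )
      if (ok) return(list(seq = seq, gene = truth$gene_id[gi]))
    }
    stop("could not draw a '", anchor, "' fragment; widen the plan",
         call. = FALSE)
  }
  draw_absent <- function(maker) {
    for (try in 1:100) {
      s <- maker()
      if (!is.na(s) && !(s %in% taken) && !occurs_in_any(s, refs)) return(s)
    }
    stop("could not draw a reference-absent decoy", call. = FALSE)
  }
  for (i in seq_len(plan$n_trf5)) {
    d <- draw_anchored("trf5"); f <- rand_freq()
    add("spike_trf5", d$seq, d$gene, f, f, "kept:tRF-5", "kept:tRF-5")
  }
  for (i in seq_len(plan$n_trf3)) {
    d <- draw_anchored("trf3"); f <- rand_freq()
    add("spike_trf3", d$seq, d$gene, f, f, "kept:tRF-3", "kept:tRF-3")
  }
  for (i in seq_len(plan$n_trf1)) {
    d <- draw_anchored("trf1"); f <- rand_freq()
    add("spike_trf1", d$seq, d$gene, f, f, "kept:tRF-1", "kept:tRF-1")
  }
  kinds <- rep_len(plan$decoy_kinds, length.out = plan$n_decoys)
  low_freq_at_9 <- TRUE
  for (kind in kinds) {
    if (kind == "internal") {
      d <- draw_anchored("internal"); f <- rand_freq()
      add("decoy_internal", d$seq, d$gene, f, f,
          "rejected:unanchored", "rejected:unanchored")
    } else if (kind == "off_by_one_5p") {
      d <- draw_anchored("off5"); f <- rand_freq()
      add("decoy_off_by_one_5p", d$seq, d$gene, f, f,
          "rejected:unanchored", "rejected:unanchored")
    } else if (kind == "off_by_one_3p") {
      d <- draw_anchored("off3"); f <- rand_freq()
      add("decoy_off_by_one_3p", d$seq, d$gene, f, f,
          "rejected:unanchored", "rejected:unanchored")
    } else if (kind == "low_freq") {
      d <- draw_anchored("trf5")
      if (low_freq_at_9) {
        # fails the table rule (> 9) and a fortiori the FASTQ rule
        add("decoy_freq9", d$seq, d$gene, 9L, 9L,
            "rejected:low_frequency", "rejected:low_frequency")
      } else {
        # passes the table rule but sits exactly at the failing FASTQ bound
        add("decoy_freq100", d$seq, d$gene, 100L, 100L,
            "kept:tRF-5", "rejected:low_frequency")
      }
      low_freq_at_9 <- !low_freq_at_9
    } else if (kind == "mismatch") {
      base <- draw_anchored("trf5")$seq
      s <- draw_absent(function() {
        pos <- sample(seq(2L, nchar(base) - 1L), 1L)
        old_b <- substr(base, pos, pos)
        new_b <- sample(setdiff(c("A", "C", "G", "T"), old_b), 1L)
        paste0(substr(base, 1L, pos - 1L), new_b,
               substr(base, pos + 1L, nchar(base)))
      })
      f <- rand_freq()
      add("decoy_mismatch", s, "", f, f,
          "rejected:no_exact_match", "rejected:no_exact_match")
    } else if (kind == "revcomp") {
      s <- draw_absent(function() revcomp(draw_anchored("trf5")$seq))
      f <- rand_freq()
      add("decoy_revcomp", s, "", f, f,
          "rejected:no_exact_match", "rejected:no_exact_match")
    } else if (kind == "non_trna") {
      s <- draw_absent(function() random_dna(rand_len()))
      f <- rand_freq()
      add("decoy_non_trna", s, "", f, f,
          "rejected:no_exact_match", "rejected:no_exact_match")
    } else if (kind == "low_quality") {
      d <- draw_anchored("trf5"); f <- rand_freq()
      add("decoy_low_quality", d$seq, d$gene, NA_integer_, f,
          "absent", "rejected:low_quality", min_qual = 27L)
    } else {
      stop("unknown decoy kind: ", kind, call. = FALSE)
    }
  }
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  # fragment table (low_quality decoys are FASTQ-only)
  tab <- ledger[!is.na(ledger$freq_table),
                c("sequence", "freq_table"), drop = FALSE]
  names(tab) <- c("sequence", "count")
  # FASTQ reads: fragment + adapter + random fill to read_length, qualities
  # Q40 except the planted sub-28 base of low-quality fragments
  reads_seq <- character(0); reads_qual <- character(0); reads_id <- character(0)
  for (i in seq_len(nrow(ledger))) {
    frag <- ledger$sequence[i]
    flen <- nchar(frag)
    read <- paste0(frag, plan$adapter)
    if (nchar(read) < plan$read_length) {
      read <- paste0(read, random_dna(plan$read_length - nchar(read)))
    }
    read <- substr(read, 1L, plan$read_length)
    # the planted adapter must be the leftmost occurrence for clean trimming
    stopifnot(regexpr(plan$adapter, read, fixed = TRUE) %in% c(-1L, flen + 1L))
    qual <- strrep(rawToChar(as.raw(40L + 33L)), nchar(read))
    if (ledger$min_qual[i] < 40L) {
      pos <- sample(flen, 1L)  # inside the fragment so it survives trimming
      substr(qual, pos, pos) <- rawToChar(as.raw(ledger$min_qual[i] + 33L))
    }
    n <- ledger$n_reads[i]
    reads_seq <- c(reads_seq, rep(read, n))
    reads_qual <- c(reads_qual, rep(qual, n))
    reads_id <- c(reads_id, sprintf("%s_r%04d", ledger$id[i], seq_len(n)))
  }
  structure(list(ledger = ledger, table = tab,
                 reads = data.frame(id = reads_id, sequence = reads_seq,
                                    quality = reads_qual,
                                    stringsAsFactors = FALSE),
                 plan = plan),
            class = "spike_library")
}

#' Write fixture and library files
#'
#' Writes `genome.fa`, `genes.bed`, `truth.json`, and when a library is
#' given, `frags.tsv`, `reads.fastq` and `spikes.json`.
#'
#' @param fixture a `trf_fixture`.
#' @param dir output directory (created if needed).
#' @param library optional `spike_library`.
#' @return named vector of written paths, invisibly.
#' @export
write_fixtures <- function(fixture, dir, library = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(fixture$genome, paths[["genome"]])
  write_trna_bed(fixture$genes, paths[["genes"]])
  jsonlite::write_json(fixture$truth, paths[["truth"]], dataframe = "rows")
  if (!is.null(library)) {
    paths <- c(paths, frags = file.path(dir, "frags.tsv"),
               reads = file.path(dir, "reads.fastq"),
               spikes = file.path(dir, "spikes.json"))
    utils::write.table(library$table, paths[["frags"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fq <- rbind(paste0("@", library$reads$id), library$reads$sequence,
                "+", library$reads$quality)
    writeLines(as.vector(fq), paths[["reads"]])
    jsonlite::write_json(library$ledger, paths[["spikes"]],
                         dataframe = "rows")
  }
  invisible(paths)
}
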