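# Pipeline orchestration: reference construction, per-sample ingestion and
# filtering, exact mapping, mature-over-precursor resolution, classification
# and summary reporting, with telescoping stage counts collected into a run
# report.

#' Run the full tRF identification pipeline
#'
#' Executes build reference -> load/filter each sample -> map -> resolve ->
#' classify -> summarise. Samples are described by a manifest data frame
#' with columns `species`, `tissue`, `gsm`, `pmid`, `path` and `type`
#' (`"table"` for unique-fragment TSVs, `"fastq"` for raw reads).
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param genes a `trna_genes` table, or path to a BED6 file.
#' @param samples the sample manifest data frame (or path to a TSV with the
#'   same columns).
#' @param out_dir optional output directory; when given, intermediate and
#'   final TSVs plus a JSON run report are written.
#' @param species species label for the reference (defaults to the first
#'   sample's species).
#' @param min_len,max_len tRF length bounds (default 15/28).
#' @param min_frag_freq clonal-frequency floor for table input (default 10).
#' @param min_read_freq clonal-frequency floor for FASTQ input (default 101).
#' @param min_q per-base Phred floor for FASTQ input (default 28).
#' @param max_read_len maximum collapsed read length kept from FASTQ
#'   (default 100).
#' @param adapter optional 3' adapter trimmed from FASTQ reads.
#' @param upstream,downstream pre-tRNA flank sizes (default 40/40).
#' @param splice splice introns out of mature references (default `TRUE`).
#' @return an object of class `trf_run`: list with `catalog`, `summary`
#'   (per-species table), `counts` (from [count_unique()]), `report` (the
#'   telescoping stage counts) and `reference`.
#' @export
run_pipeline <- function(genome, genes, samples, out_dir = NULL,
                         species = NULL, min_len = 15L, max_len = 28L,
                         min_frag_freq = 10L, min_read_freq = 101L,
                         min_q = 28L, max_read_len = 100L, adapter = NULL,
                         upstream = 40L, downstream = 40L, splice = TRUE) {
  if (is.character(genes)) genes <- read_trna_bed(genes)
  if (is.character(samples)) {
    if (!file.exists(samples)) {
      stop("samples manifest not found: ", samples, call. = FALSE)
    }
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  need <- c("species", "path", "type")
  if (!all(need %in% names(samples))) {
    stop("samples manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tissue", "gsm", "pmid")) {
    if (is.null(samples[[col]])) samples[[col]] <- ""
  }
  missing_files <- samples$path[!file.exists(samples$path)]
  if (length(missing_files)) {
    stop("sample input not found: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(species)) species <- samples$species[1L]
  reference <- build_reference(genes, genome, species = species,
                               upstream = upstream, downstream = downstream,
                               splice = splice)
  index <- build_index(reference)
  frag_list <- vector("list", nrow(samples))
  stage <- c(input_units = 0L, quality_discarded = 0L, filtered_out = 0L,
             fragments_kept = 0L)
  for (i in seq_len(nrow(samples))) {
    sm <- sample_meta(samples$species[i], samples$tissue[i],
                      samples$gsm[i], samples$pmid[i])
    fr <- if (samples$type[i] == "fastq") {
      load_fastq(samples$path[i], sm, adapter = adapter, min_q = min_q,
                 min_len = min_len, max_len = max_read_len,
                 min_freq = min_read_freq)
    } else {
      load_fragment_table(samples$path[i], sm, min_len = min_len,
                          max_len = max_len, min_freq = min_frag_freq)
    }
    st <- attr(fr, "stats")
    stage["input_units"] <- stage["input_units"] + st[[1L]]
    stage["quality_discarded"] <- stage["quality_discarded"] +
      sum(st[c("n_discarded", "quality_discarded")], na.rm = TRUE)
    stage["filtered_out"] <- stage["filtered_out"] +
      sum(st[c("malformed", "bad_alphabet", "length_filtered",
               "freq_filtered")], na.rm = TRUE)
    stage["fragments_kept"] <- stage["fragments_kept"] + nrow(fr)
    frag_list[[i]] <- fr
  }
  fragments <- do.call(rbind, frag_list)
  hits <- map_fragments(fragments, index)
  frag_key <- function(d) paste(d$sequence, d$species, d$tissue, d$gsm,
                                d$pmid, sep = "\r")
  mapped_frags <- if (is.null(fragments)) 0L else
    sum(frag_key(fragments) %in% frag_key(hits))
  resolved <- resolve_mature_precursor(hits)
  catalog <- classify_hits(resolved, reference, min_len = min_len,
                           max_len = max_len)
  catalog <- catalog[order_radix(catalog$species, catalog$trf_type,
                                 catalog$sequence, catalog$source_ref), ,
                     drop = FALSE]
  rownames(catalog) <- NULL
  counts <- count_unique(catalog)
  summary_tab <- summarize_catalog(catalog)
  report <- list(
    parameters = list(min_len = min_len, max_len = max_len,
                      min_frag_freq = min_frag_freq,
                      min_read_freq = min_read_freq, min_q = min_q,
                      upstream = upstream, downstream = downstream,
                      splice = splice, adapter = adapter,
                      version = as.character(utils::packageVersion("ptrfkit"))),
    n_samples = nrow(samples),
    input_units = unname(stage["input_units"]),
    quality_discarded = unname(stage["quality_discarded"]),
    filtered_out = unname(stage["filtered_out"]),
    fragments_kept = unname(stage["fragments_kept"]),
    fragments_mapped = mapped_frags,
    fragments_unmapped = unname(stage["fragments_kept"]) - mapped_frags,
    hits_total = nrow(hits),
    hits_shadowed_pre = attr(resolved, "n_shadowed"),
    hits_after_resolve = nrow(resolved),
    hits_unanchored = attr(catalog, "n_unanchored"),
    records = counts$total_entries,
    records_by_type = as.list(counts$entries_by_type)
  )
  if (report$records == 0L) {
    warning("pipeline finished with zero classified tRF records",
            call. = FALSE)
  }
  run <- structure(list(catalog = catalog, summary = summary_tab,
                        counts = counts, report = report,
                        reference = reference, hits = resolved),
                   class = "trf_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference_fasta(reference, file.path(out_dir, "reference.fa"))
    write_reference_manifest(reference, file.path(out_dir, "reference.tsv"))
    write_hits(resolved, file.path(out_dir, "hits.tsv"))
    write_catalog(catalog, file.path(out_dir, "catalog.tsv"))
    write_catalog_fasta(catalog, file.path(out_dir, "catalog.fa"))
    utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  run
}

#' @export
print.trf_run <- function(x, ...) {
  r <- x$report
  cat("tRF pipeline run\n")
  cat("  input units:        ", r$input_units, "\n")
  cat("  fragments kept:     ", r$fragments_kept,
      "(", r$quality_discarded, "quality-discarded,",
      r$filtered_out, "filtered )\n")
  cat("  mapped fragments:   ", r$fragments_mapped,
      "(", r$fragments_unmapped, "unmapped )\n")
  cat("  hits:               ", r$hits_total, "->", r$hits_after_resolve,
      "after mature/pre resolution\n")
  cat("  tRF records:        ", r$records,
      sprintf("(tRF-5 %d, tRF-3 %d, tRF-1 %d)\n",
              r$records_by_type[["tRF-5"]], r$records_by_type[["tRF-3"]],
              r$records_by_type[["tRF-1"]]))
  invisible(x)
}

#' Check that run-report counts telescope
#'
#' Each stage's output must equal the next stage's input: kept fragments
#' split into mapped + unmapped; total hits into resolved + shadowed;
#' resolved hits into classified records + unanchored hits.
#'
#' @param report the `report` element of a `trf_run` (or the run itself).
#' @return `TRUE` if all identities hold, otherwise a character vector of
#'   violated identities.
#' @export
validate_report <- function(report) {
  if (inherits(report, "trf_run")) report <- report$report
  bad <- character(0)
  if (report$fragments_kept !=
      report$fragments_mapped + report$fragments_unmapped) {
    bad <- c(bad, "fragments_kept != mapped + unmapped")
  }
  if (report$hits_total !=
      report$hits_after_resolve + report$hits_shadowed_pre) {
    bad <- c(bad, "hits_total != after_resolve + shadowed")
  }
  if (report$hits_after_resolve !=
      report$records + report$hits_unanchored) {
    bad <- c(bad, "hits_after_resolve != records + unanchored")
  }
  if (report$records != sum(unlist(report$records_by_type))) {
    bad <- c(bad, "records != sum of per-type records")
  }
  if (length(bad)) bad else TRUE
}

#' Summarise a tRF catalog per species
#'
#' One row per species: total entries, total unique sequences and unique
#' sequences per type — the shape of a per-species distribution table.
#'
#' @param catalog a catalog `data.frame`.
#' @return a `data.frame` with columns `species`, `entries`, `unique_total`,
#'   `tRF.5`, `tRF.3`, `tRF.1`.
#' @export
summarize_catalog <- function(catalog) {
  species <- sort(unique(catalog$species))
  rows <- lapply(species, function(sp) {
    part <- catalog[catalog$species == sp, , drop = FALSE]
    u <- unique(part[, c("trf_type", "sequence")])
    data.frame(
      species = sp, entries = nrow(part), unique_total = nrow(u),
      tRF.5 = sum(u$trf_type == "tRF-5"),
      tRF.3 = sum(u$trf_type == "tRF-3"),
      tRF.1 = sum(u$trf_type == "tRF-1"),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), entries = integer(0),
               unique_total = integer(0), tRF.5 = integer(0),
               tRF.3 = integer(0), tRF.1 = integer(0))
}

#' Length histogram of unique tRF sequences
#'
#' Bins are fixed at 15-28 nt regardless of the data, per type or per
#' species.
#'
#' @param catalog a catalog `data.frame`.
#' @param by `"type"` or `"species"`.
#' @return an integer matrix, one column per group, rows named 15..28.
#' @export
length_histogram <- function(catalog, by = c("type", "species")) {
  by <- match.arg(by)
  u <- unique(catalog[, c("species", "trf_type", "sequence", "length")])
  group <- if (by == "type") factor(u$trf_type, levels = TRF_TYPES)
           else factor(u$species)
  tab <- table(factor(u$length, levels = 15:28), group)
  m <- matrix(as.integer(tab), nrow = 14L,
              dimnames = list(15:28, colnames(tab)))
  m
}

#' Plot length distributions of unique tRFs
#'
#' Barplot of the 15-28 nt length histogram per tRF type.
#'
#' @param catalog a catalog `data.frame`.
#' @param ... passed to [graphics::barplot()].
#' @return the histogram matrix, invisibly.
#' @export
plot_length_distribution <- function(catalog, ...) {
  m <- length_histogram(catalog, by = "type")
  graphics::barplot(t(m), beside = TRUE, legend.text = colnames(m),
                    xlab = "tRF length (nt)", ylab = "unique sequences", ...)
  invisible(m)
}
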