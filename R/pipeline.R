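# End-to-end driver wiring the four stages -- pre-process, cluster, filter,
# taxonomy -- into one deterministic run over a config list. Also the
# surface behind the thin command-line script shipped in inst/cli/.

#' Pipeline configuration
#'
#' @param input FASTQ path of raw reads, or a reads tibble.
#' @param sheet A [sample_sheet()] (required for `single_barcode` input).
#' @param out_dir Output directory for artifacts (created if missing).
#' @param platform `"iontorrent"` (inline barcode, demultiplex) or
#'   `"illumina"` (reads already labeled).
#' @param barcode_edits,primer_edits,max_len,mode,min_len Pre-processing
#'   parameters, see [demux_single()].
#' @param max_ee Expected-error cap for the clustering input.
#' @param id_threshold,min_size,chimera_check Clustering parameters.
#' @param filter Run mock-based tag-switch filtering?
#' @param mock_sample,mock_fasta Spike-in sample name and mock reference
#'   FASTA path (or reads tibble) when `filter = TRUE`.
#' @param bleed Optional user-supplied bleed rate overriding estimation.
#' @param taxonomy Run taxonomy assignment?
#' @param refdb Path to a reference FASTA (or a [refdb()]) when
#'   `taxonomy = TRUE`.
#' @param seed Integer seed for all stochastic steps.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, sheet = NULL, out_dir = tempfile("mycoamp_run_"),
                            platform = c("iontorrent", "illumina"),
                            barcode_edits = 0L, primer_edits = 2L,
                            max_len = 300L, mode = "fulllength", min_len = 50L,
                            max_ee = 1.0, id_threshold = 0.97, min_size = 2L,
                            chimera_check = TRUE,
                            filter = FALSE, mock_sample = NULL, mock_fasta = NULL,
                            bleed = NULL, taxonomy = FALSE, refdb = NULL,
                            seed = 1L) {
  platform <- match.arg(platform)
  if (platform == "iontorrent" && is.null(sheet)) {
    abort("iontorrent input requires a sample sheet")
  }
  if (filter && (is.null(mock_sample) || is.null(mock_fasta))) {
    abort("filtering requires mock_sample and mock_fasta; pass both or set filter = FALSE")
  }
  if (taxonomy && is.null(refdb)) abort("taxonomy requires a reference database")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages in order: demultiplex/pre-process; expected-error filter and
#' dereplicate for clustering only; greedy OTU clustering; OTU table from
#' the pre-filter demultiplexed reads; optional mock-calibrated
#' tag-switching filter; optional taxonomy. Artifacts written to
#' `config$out_dir`: `demux.fastq`, `otus.fasta`, `otu_table.tsv`,
#' `filtered.tsv` (when filtering), `taxonomy.tsv` (when assigning),
#' `report.tsv`. Identical config + seed gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list with `otus`, `table`, `filtered`, `taxonomy`, `bleed`,
#'   `stats`, `report` and the artifact paths (`paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    demux = file.path(config$out_dir, "demux.fastq"),
    otus = file.path(config$out_dir, "otus.fasta"),
    table = file.path(config$out_dir, "otu_table.tsv"),
    filtered = file.path(config$out_dir, "filtered.tsv"),
    taxonomy = file.path(config$out_dir, "taxonomy.tsv"),
    report = file.path(config$out_dir, "report.tsv")
  )
  report <- list()
  note <- function(stage, key, value) {
    report[[length(report) + 1L]] <<- tibble(stage = stage, key = key,
                                             value = as.character(value))
  }

  reads <- if (is.data.frame(config$input)) config$input else read_fastq(config$input)
  note("input", "reads", nrow(reads))

  if (config$platform == "iontorrent") {
    dm <- demux_single(reads, config$sheet, barcode_edits = config$barcode_edits,
                       primer_edits = config$primer_edits, max_len = config$max_len,
                       mode = config$mode, min_len = config$min_len)
    demuxed <- dm$reads
    stats <- dm$stats
  } else {
    if (nrow(reads) && anyNA(reads$sample)) abort("illumina input must carry sample labels")
    if (!is.null(config$sheet)) {
      st <- strip_primers(reads, attr(config$sheet, "fwd_primer"),
                          attr(config$sheet, "rev_primer"), config$primer_edits)
      reads <- st$reads
    } else if (!"rev_primer_found" %in% names(reads)) {
      reads$rev_primer_found <- TRUE
    }
    demuxed <- trim_reads(reads, max_len = config$max_len, mode = config$mode)
    stats <- demux_stats_tbl(table(demuxed$sample), integer(0))
  }
  note("preprocess", "demuxed_reads", nrow(demuxed))
  write_fastq(demuxed, paths$demux)

  clustering_input <- filter_by_ee(demuxed, config$max_ee)
  note("cluster", "post_ee_reads", nrow(clustering_input))
  uniques <- dereplicate(clustering_input)
  otus <- cluster_otus(uniques, id_threshold = config$id_threshold,
                       min_size = config$min_size,
                       chimera_check = config$chimera_check)
  note("cluster", "otus", nrow(otus))
  write_fasta(reads_tbl(id = otus$otu_id, seq = otus$centroid), paths$otus)

  table <- map_reads_to_otus(demuxed, otus, id_threshold = config$id_threshold)
  write_otu_table(table, paths$table)
  note("table", "reads_in_table", sum(otu_counts(table)))

  filtered <- NULL; bleed <- NULL
  if (config$filter) {
    mock_ref <- if (is.data.frame(config$mock_fasta)) config$mock_fasta else read_fasta(config$mock_fasta)
    mm <- map_otus_to_mock(otus, mock_ref)
    bleed <- estimate_bleed(table, config$mock_sample, mm)
    rate <- config$bleed %||% bleed$applied
    note("filter", "applied_bleed", sprintf("%.6f", rate))
    filtered <- filter_table(table, rate, mock_map = mm,
                             mock_sample = config$mock_sample, drop_mock = TRUE)
    write_otu_table(filtered, paths$filtered)
    note("filter", "otus_after_filter", nrow(filtered))
  }

  taxonomy <- NULL
  if (config$taxonomy) {
    db <- if (inherits(config$refdb, "refdb")) config$refdb else read_refdb(config$refdb)
    taxonomy <- assign_taxonomy(otus, db, seed = config$seed)
    utils::write.table(taxonomy, paths$taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
    note("taxonomy", "assigned", nrow(taxonomy))
  }

  report <- bind_rows(report)
  utils::write.table(report, paths$report, sep = "\t", quote = FALSE, row.names = FALSE)
  list(otus = otus, table = table, filtered = filtered, taxonomy = taxonomy,
       bleed = bleed, stats = stats, report = report, paths = paths)
}
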