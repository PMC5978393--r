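# Spike-in mock-community calibration: map OTUs to the mock reference,
# measure the pipeline error rate, estimate tag-switching (index-bleed) in
# both directions, and zero out OTU-table cells that fall within the range
# attributable to tag-switching.

#' Classify OTUs against a spike-in mock reference
#'
#' Every centroid is globally aligned against every mock reference sequence.
#' Classes: `mock_hit` (best identity >= `hit_id`), `mock_variant`
#' (identity in `[variant_id, hit_id)`), `chimera_suspect` (below the
#' variant band but flagged by [flag_chimera()] against the mock
#' references), else `non_mock`.
#'
#' @param otus Tibble with `otu_id` and `centroid` (from [cluster_otus()]).
#' @param mock_ref A reads tibble of mock reference sequences (e.g. from
#'   [read_fasta()] of the SynMock FASTA), or a named character vector.
#' @param hit_id Identity threshold for a mock hit (default 0.97).
#' @param variant_id Lower identity bound for a mock variant (default 0.90).
#' @return A `mock_map` tibble: `otu_id`, `class`, `best_ref`, `identity`,
#'   `mismatches` (substitution + gap columns vs the best reference),
#'   `aligned_bp` (alignment columns).
#' @export
map_otus_to_mock <- function(otus, mock_ref, hit_id = 0.97, variant_id = 0.90) {
  refs <- if (is.data.frame(mock_ref)) setNames(mock_ref$seq, mock_ref$id) else mock_ref
  if (!length(refs)) abort("empty mock reference")
  rows <- vector("list", nrow(otus))
  for (i in seq_len(nrow(otus))) {
    st <- nw_stats(unname(refs), otus$centroid[i])
    best <- which.max(st$identity)
    cls <- if (st$identity[best] >= hit_id) {
      "mock_hit"
    } else if (st$identity[best] >= variant_id) {
      "mock_variant"
    } else if (flag_chimera(otus$centroid[i], unname(refs))) {
      "chimera_suspect"
    } else {
      "non_mock"
    }
    rows[[i]] <- tibble(
      otu_id = otus$otu_id[i], class = cls, best_ref = names(refs)[best],
      identity = st$identity[best], mismatches = st$mismatches[best],
      aligned_bp = st$columns[best]
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("mock_map", class(out))
  out
}

#' Mock-community error rate
#'
#' `100 * sum(mismatches) / sum(aligned_bp)` over the OTUs classed as mock
#' hits (optionally including variants): the percentage of erroneous
#' alignment columns accumulated by the pipeline against the known truth.
#'
#' @param mock_map Output of [map_otus_to_mock()].
#' @param include_variants Also include `mock_variant` OTUs (default
#'   `FALSE`).
#' @return Error rate as a percentage.
#' @export
error_rate <- function(mock_map, include_variants = FALSE) {
  cls <- c("mock_hit", if (include_variants) "mock_variant")
  mm <- mock_map[mock_map$class %in% cls, ]
  if (!nrow(mm)) abort("no mock OTUs to compute an error rate over")
  100 * sum(mm$mismatches) / sum(mm$aligned_bp)
}

#' Estimate tag-switching (index-bleed) from a spike-in sample
#'
#' Two directional rates are measured on the OTU table:
#' * `rate_in`: reads in the mock sample that belong to non-mock OTUs,
#'   divided by the total reads in the mock sample (bleed into the
#'   spike-in);
#' * `rate_out`: reads of `mock_hit` OTUs found in non-mock samples,
#'   divided by the total reads of `mock_hit` OTUs (bleed out of the
#'   spike-in). Mock variants are excluded from `rate_out` as they may be
#'   chimeric artifacts rather than switched tags.
#'
#' The `applied` rate used for filtering combines the two (default: the
#' conservative maximum).
#'
#' @param table An OTU table tibble.
#' @param mock_sample Name of the spike-in sample column.
#' @param mock_map Output of [map_otus_to_mock()].
#' @param combine One of `"max"`, `"mean"`, `"in"`, `"out"`.
#' @param variants_as_mock_in Count `mock_variant` OTUs as mock when
#'   computing `rate_in`'s foreign reads (default `TRUE`).
#' @return A `bleed_estimate` object (list with `rate_in`, `rate_out`,
#'   `applied`, `combine`, plus the read tallies); see [tidy.bleed_estimate()].
#' @export
estimate_bleed <- function(table, mock_sample, mock_map,
                           combine = c("max", "mean", "in", "out"),
                           variants_as_mock_in = TRUE) {
  combine <- match.arg(combine)
  table <- validate_otu_table(table)
  if (!mock_sample %in% names(table)) {
    abort(sprintf("mock sample '%s' not found in OTU table", mock_sample))
  }
  hit_ids <- mock_map$otu_id[mock_map$class == "mock_hit"]
  if (!length(hit_ids)) {
    abort("no mock OTUs found in the table; check that the mock reference FASTA matches the spike-in")
  }
  mock_in_ids <- mock_map$otu_id[mock_map$class %in%
                                   c("mock_hit", if (variants_as_mock_in) "mock_variant")]
  m <- otu_counts(table)
  mock_col <- m[, mock_sample]
  is_mock_row <- rownames(m) %in% mock_in_ids
  total_in_mock <- sum(mock_col)
  foreign_in_mock <- sum(mock_col[!is_mock_row])
  rate_in <- if (total_in_mock > 0) foreign_in_mock / total_in_mock else 0

  hit_rows <- rownames(m) %in% hit_ids
  hit_total <- sum(m[hit_rows, , drop = FALSE])
  hit_outside <- sum(m[hit_rows, setdiff(colnames(m), mock_sample), drop = FALSE])
  rate_out <- if (hit_total > 0) hit_outside / hit_total else 0

  applied <- switch(combine,
    max = max(rate_in, rate_out),
    mean = mean(c(rate_in, rate_out)),
    `in` = rate_in,
    out = rate_out
  )
  structure(
    list(rate_in = rate_in, rate_out = rate_out, applied = applied,
         combine = combine, mock_sample = mock_sample,
         foreign_reads_in_mock = foreign_in_mock,
         mock_reads_in_mock_sample = total_in_mock,
         mock_hit_reads_total = hit_total,
         mock_hit_reads_outside = hit_outside),
    class = "bleed_estimate"
  )
}

#' @export
print.bleed_estimate <- function(x, ...) {
  cat(sprintf("Tag-switching estimate (mock sample '%s')\n", x$mock_sample))
  cat(sprintf("  into mock : %.4f%% (%d / %d reads)\n", 100 * x$rate_in,
              x$foreign_reads_in_mock, x$mock_reads_in_mock_sample))
  cat(sprintf("  out of mock: %.4f%% (%d / %d reads)\n", 100 * x$rate_out,
              x$mock_hit_reads_outside, x$mock_hit_reads_total))
  cat(sprintf("  applied    : %.4f%% (combine = %s)\n", 100 * x$applied, x$combine))
  invisible(x)
}

#' Tidy a bleed estimate
#'
#' @param x A `bleed_estimate`.
#' @param ... Unused.
#' @return `tidy()` gives one row per directional rate; `glance()` a
#'   one-row summary with the applied rate.
#' @export
tidy.bleed_estimate <- function(x, ...) {
  tibble(
    direction = c("into_mock", "out_of_mock"),
    rate = c(x$rate_in, x$rate_out),
    reads = c(x$foreign_reads_in_mock, x$mock_hit_reads_outside),
    total = c(x$mock_reads_in_mock_sample, x$mock_hit_reads_total)
  )
}

#' @rdname tidy.bleed_estimate
#' @export
glance.bleed_estimate <- function(x, ...) {
  tibble(rate_in = x$rate_in, rate_out = x$rate_out,
         applied = x$applied, combine = x$combine)
}

#' Filter an OTU table at a tag-switching rate
#'
#' Per OTU, the threshold is `t_o = ceiling(rate * total reads of that OTU
#' across all samples)` computed on the *original* table (which makes the
#' filter idempotent). Cells with `0 < count < t_o` are set to zero; cells
#' at or above `t_o` are unchanged -- so low-abundance OTUs are never
#' dropped wholesale, only cells in the bleed-attributable range. With
#' `drop_mock`, mock OTU rows (`mock_hit`/`mock_variant`) and the mock
#' sample column are removed after filtering.
#'
#' @param table An OTU table tibble.
#' @param rate Tag-switching rate in `[0, 1]` (e.g. `estimate$applied`, or a
#'   user-supplied value for runs without a spike-in).
#' @param mock_map,mock_sample Needed only when `drop_mock = TRUE`.
#' @param drop_mock Remove mock rows and the mock sample column (default
#'   `TRUE` when `mock_map` is supplied).
#' @return The filtered OTU table tibble.
#' @export
filter_table <- function(table, rate, mock_map = NULL, mock_sample = NULL,
                         drop_mock = !is.null(mock_map)) {
  table <- validate_otu_table(table)
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  m <- otu_counts(table)
  if (nrow(m)) {
    t_o <- ceiling(rate * rowSums(m))
    below <- m > 0L & m < t_o
    m[below] <- 0L
  }
  if (drop_mock) {
    if (is.null(mock_map) || is.null(mock_sample)) {
      abort("drop_mock requires mock_map and mock_sample")
    }
    mock_rows <- rownames(m) %in%
      mock_map$otu_id[mock_map$class %in% c("mock_hit", "mock_variant")]
    m <- m[!mock_rows, setdiff(colnames(m), mock_sample), drop = FALSE]
  }
  validate_otu_table(otu_table_from_matrix(m))
}
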