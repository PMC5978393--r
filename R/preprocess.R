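# Pre-processing: demultiplexing, primer removal, lossless trimming,
# paired-end merging and expected-error filtering.
#
# The defining behaviors for variable-length amplicons:
#   * barcodes are matched anchored at the 5' end with 0 edits by default;
#   * primers tolerate 2 edits by default;
#   * trimming is lossless -- reads longer than `max_len` are truncated,
#     shorter reads are kept (full length) provided their reverse primer was
#     seen, so short real amplicons are never thrown away;
#   * expected-error filtering is applied only to the clustering input,
#     never to the reads that are counted into the OTU table.

.reject_reasons <- c("no_barcode", "ambiguous_barcode", "no_fwd_primer",
                     "too_short", "no_rev_primer_short")

# Anchored edit distance between a barcode and the 5' end of reads.
# With max_edits = 0 this is an exact prefix comparison (vectorized);
# otherwise the minimum edit distance over prefixes of length lb +/- e.
anchored_barcode_edits <- function(seqs, barcode, max_edits) {
  lb <- nchar(barcode)
  if (max_edits == 0L) {
    return(ifelse(substr(seqs, 1L, lb) == barcode, 0L, NA_integer_))
  }
  lens <- max(1L, lb - max_edits):(lb + max_edits)
  d <- rep(Inf, length(seqs))
  for (L in lens) {
    d <- pmin(d, utils::adist(barcode, substr(seqs, 1L, L))[1L, ])
  }
  ifelse(d <= max_edits, as.integer(d), NA_integer_)
}

demux_stats_tbl <- function(kept, rejected) {
  tibble(
    category = c(rep("kept", length(kept)), rep("rejected", length(rejected))),
    name = c(names(kept), names(rejected)),
    reads = as.integer(c(kept, rejected))
  )
}

#' Demultiplex single-end barcoded reads
#'
#' Platform layout: `barcode + forward primer + insert + rc(reverse primer)
#' [+ rc(3' barcode)]`. A read is kept only if a barcode matches anchored at
#' position 1 within `barcode_edits` (default 0) and the forward primer is
#' found within `primer_edits` (default 2). Reads tying two barcodes at the
#' same best edit distance are rejected as ambiguous. Barcode and primers are
#' removed; the reverse primer (searched as its reverse complement) is
#' trimmed when present and its presence recorded in `rev_primer_found`.
#' Lossless trimming is then applied via [trim_reads()].
#'
#' @param reads A reads tibble (unlabeled).
#' @param sheet A [sample_sheet()] carrying `fwd_primer`/`rev_primer`.
#' @param barcode_edits Barcode mismatch tolerance (default 0).
#' @param primer_edits Primer edit tolerance (default 2).
#' @param max_len Maximum retained length in bp (default 300).
#' @param mode Trimming mode: `"fulllength"` (truncate long, keep short with
#'   reverse primer), `"pad"` (truncate long, N-pad short) or `"truncate"`
#'   (truncate long, discard short).
#' @param min_len Reads shorter than this after primer removal are rejected
#'   as `too_short` (default 50).
#' @param keep_no_revprimer Keep short reads lacking a reverse primer
#'   (default `FALSE`).
#' @param indel_primers Count indels in primer edits (default `TRUE`).
#' @return A list with `reads` (labeled, trimmed tibble carrying
#'   `rev_primer_found`) and `stats` (kept/rejected audit tibble satisfying
#'   kept + rejected = input).
#' @export
demux_single <- function(reads, sheet, barcode_edits = 0L, primer_edits = 2L,
                         max_len = 300L, mode = c("fulllength", "pad", "truncate"),
                         min_len = 50L, keep_no_revprimer = FALSE,
                         indel_primers = TRUE) {
  mode <- match.arg(mode)
  reads <- validate_reads(reads)
  if (!inherits(sheet, "sample_sheet")) abort("`sheet` must be a sample_sheet")
  fwd_primer <- attr(sheet, "fwd_primer")
  rev_primer <- attr(sheet, "rev_primer")
  if (is.null(fwd_primer) || is.null(rev_primer)) {
    abort("sample sheet must carry fwd_primer and rev_primer")
  }
  bcs <- sheet$fwd_barcode
  if (anyNA(bcs)) abort("single-end demultiplexing requires fwd_barcode for every sample")
  n <- nrow(reads)
  rejected <- setNames(integer(length(.reject_reasons)), .reject_reasons)

  # barcode assignment (anchored)
  ed <- matrix(NA_integer_, nrow = n, ncol = length(bcs))
  for (j in seq_along(bcs)) ed[, j] <- anchored_barcode_edits(reads$seq, bcs[j], barcode_edits)
  big <- 1e9
  edf <- replace(ed, is.na(ed), big)
  best <- do.call(pmin, lapply(seq_len(ncol(edf)), function(j) edf[, j]))
  nbest <- rowSums(edf == best)
  no_bc <- best >= big
  ambig <- !no_bc & nbest >= 2L
  rejected["no_barcode"] <- sum(no_bc)
  rejected["ambiguous_barcode"] <- sum(ambig)
  keep <- !no_bc & !ambig
  which_bc <- ifelse(keep, max.col(-edf, ties.method = "first"), NA_integer_)

  out <- reads[keep, ]
  out$sample <- sheet$sample[which_bc[keep]]
  bclen <- nchar(bcs)[which_bc[keep]]
  out$seq <- substr(out$seq, bclen + 1L, nchar(out$seq))
  out$qual <- ifelse(is.na(out$qual), out$qual,
                     substr(out$qual, bclen + 1L, nchar(out$qual)))

  strip <- strip_primers(out, fwd_primer, rev_primer, primer_edits,
                         indels = indel_primers, rev_barcodes = sheet$rev_barcode)
  rejected["no_fwd_primer"] <- strip$n_no_fwd
  out <- strip$reads

  short <- nchar(out$seq) < min_len
  rejected["too_short"] <- sum(short)
  out <- out[!short, ]

  trim <- trim_reads(out, max_len = max_len, mode = mode,
                     keep_no_revprimer = keep_no_revprimer)
  rejected["no_rev_primer_short"] <- nrow(out) - nrow(trim)
  out <- trim

  kept <- setNames(integer(nrow(sheet)), sheet$sample)
  if (nrow(out)) {
    tab <- table(out$sample)
    kept[names(tab)] <- as.integer(tab)
  }
  stopifnot(sum(kept) + sum(rejected) == n)
  list(reads = out, stats = demux_stats_tbl(kept, rejected))
}

# Remove forward primer (required) and reverse primer / trailing 3' barcode
# (optional) from sample-labeled reads. Adds `rev_primer_found`.
strip_primers <- function(reads, fwd_primer, rev_primer, primer_edits = 2L,
                          indels = TRUE, rev_barcodes = NULL) {
  n <- nrow(reads)
  if (!n) {
    reads$rev_primer_found <- logical(0)
    return(list(reads = reads, n_no_fwd = 0L))
  }
  fwd_rx <- paste0("^", iupac_regex(fwd_primer))
  rc_rev <- revcomp(rev_primer)
  rev_rx <- iupac_regex(rc_rev)

  # fast path: exact forward primer right at the 5' end
  m_fwd <- regexpr(fwd_rx, reads$seq)
  fwd_end <- ifelse(m_fwd > 0L, attr(m_fwd, "match.length"), NA_integer_)
  slow <- which(is.na(fwd_end))
  for (i in slow) {
    hit <- find_primer(reads$seq[i], fwd_primer, primer_edits, indels = indels)
    # anchored layout: the primer must begin within the edit budget of pos 1
    if (!is.null(hit) && hit$start <= primer_edits + 1L) fwd_end[i] <- hit$end
  }
  has_fwd <- !is.na(fwd_end)
  n_no_fwd <- sum(!has_fwd)
  reads <- reads[has_fwd, ]
  fwd_end <- fwd_end[has_fwd]
  reads$seq <- substr(reads$seq, fwd_end + 1L, nchar(reads$seq))
  reads$qual <- ifelse(is.na(reads$qual), reads$qual,
                       substr(reads$qual, fwd_end + 1L, nchar(reads$qual)))

  # reverse primer: exact regex first, then edit-tolerant search
  m_rev <- regexpr(rev_rx, reads$seq)
  rev_start <- ifelse(m_rev > 0L, as.integer(m_rev), NA_integer_)
  for (i in which(is.na(rev_start) & nzchar(reads$seq))) {
    hit <- find_primer(reads$seq[i], rc_rev, primer_edits, indels = indels)
    if (!is.null(hit)) rev_start[i] <- hit$start
  }
  found <- !is.na(rev_start)
  reads$rev_primer_found <- found
  reads$seq[found] <- substr(reads$seq[found], 1L, rev_start[found] - 1L)
  reads$qual[found] <- ifelse(is.na(reads$qual[found]), reads$qual[found],
                              substr(reads$qual[found], 1L, rev_start[found] - 1L))
  reads <- reads[nzchar(reads$seq), ]
  list(reads = reads, n_no_fwd = n_no_fwd)
}

#' Lossless trimming of a primer-stripped read
#'
#' Reads longer than `max_len` are truncated to exactly `max_len`; reads at
#' or under `max_len` are returned unchanged when their reverse primer was
#' found, and rejected otherwise (a short read without its reverse primer is
#' an artifact, not a short amplicon).
#'
#' @param read One-row reads tibble.
#' @param max_len Length threshold (> 0).
#' @param rev_primer_found Was the reverse primer located before stripping?
#' @return The trimmed one-row tibble, or `NULL` if rejected.
#' @export
trim_lossless <- function(read, max_len, rev_primer_found) {
  if (max_len <= 0L) abort("max_len must be positive")
  len <- nchar(read$seq)
  if (len > max_len) {
    read$seq <- substr(read$seq, 1L, max_len)
    read$qual <- ifelse(is.na(read$qual), read$qual, substr(read$qual, 1L, max_len))
    return(read)
  }
  if (rev_primer_found) read else NULL
}

#' Pad or truncate a sequence to a fixed length
#'
#' Shorter inputs receive 3' `N` padding; longer inputs are truncated, so
#' stripping trailing `N`s recovers the retained prefix.
#'
#' @param seq Character vector of DNA sequences.
#' @param L Target length (> 0).
#' @return Character vector, all of length `L`.
#' @export
pad_to_length <- function(seq, L) {
  if (L <= 0L) abort("L must be positive")
  len <- nchar(seq)
  out <- substr(seq, 1L, L)
  short <- len < L
  out[short] <- paste0(out[short], strrep("N", L - len[short]))
  out
}

#' Apply a trimming mode to primer-stripped reads
#'
#' Vectorized driver over the three pre-clustering modes: `fulllength`
#' (lossless: truncate long, keep short reads whose reverse primer was seen),
#' `pad` (as fulllength, then N-pad short reads to `max_len`; padded bases
#' carry a neutral high quality so the expected-error statistic is not
#' distorted) and `truncate` (hard truncation: discard every read shorter
#' than `max_len`).
#'
#' @inheritParams demux_single
#' @param reads Reads tibble carrying a logical `rev_primer_found` column
#'   (assumed `TRUE` when absent).
#' @return The trimmed reads tibble.
#' @export
trim_reads <- function(reads, max_len = 300L, mode = c("fulllength", "pad", "truncate"),
                       keep_no_revprimer = FALSE) {
  mode <- match.arg(mode)
  if (max_len <= 0L) abort("max_len must be positive")
  if (!nrow(reads)) return(reads)
  rpf <- if ("rev_primer_found" %in% names(reads)) reads$rev_primer_found else rep(TRUE, nrow(reads))
  len <- nchar(reads$seq)
  if (mode == "truncate") {
    keep <- len >= max_len
  } else {
    keep <- len > max_len | rpf | keep_no_revprimer
  }
  reads <- reads[keep, ]
  len <- nchar(reads$seq)
  long <- len > max_len
  reads$seq[long] <- substr(reads$seq[long], 1L, max_len)
  reads$qual[long] <- ifelse(is.na(reads$qual[long]), reads$qual[long],
                             substr(reads$qual[long], 1L, max_len))
  if (mode == "pad") {
    len <- nchar(reads$seq)
    short <- len < max_len
    reads$seq[short] <- pad_to_length(reads$seq[short], max_len)
    pad_q <- function(q, k) if (is.na(q)) q else paste0(q, strrep("I", k))
    reads$qual[short] <- mapply(pad_q, reads$qual[short], max_len - len[short],
                                USE.NAMES = FALSE)
  }
  reads
}

# ---- paired-end merging -----------------------------------------------------

#' Merge a read pair by ungapped overlap
#'
#' The reverse read is reverse-complemented, then the best ungapped overlap
#' of length >= `min_overlap` with mismatch percentage <= `max_diff_pct` is
#' taken (most matching bases wins; ties go to the longer overlap). In the
#' overlap the consensus takes the base with the higher Phred score at each
#' disagreement and the higher of the two quality scores everywhere.
#'
#' @param fwd,rev One-row reads tibbles (forward and reverse mates).
#' @param min_overlap Minimum overlap length (default 12).
#' @param max_diff_pct Maximum mismatch percentage in the overlap (default 5).
#' @return The merged one-row reads tibble, or `NULL` when no qualifying
#'   overlap exists.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 12L, max_diff_pct = 5) {
  f <- fwd$seq
  r <- revcomp(rev$seq)
  fq <- if (is.na(fwd$qual)) strrep("I", nchar(f)) else fwd$qual
  rq <- if (is.na(rev$qual)) strrep("I", nchar(r)) else rev$qual
  rq <- paste(rev(strsplit(rq, "")[[1]]), collapse = "")
  lf <- nchar(f); lr <- nchar(r)
  if (min(lf, lr) < min_overlap) return(NULL)
  fc <- strsplit(f, "")[[1]]; rc <- strsplit(r, "")[[1]]
  best <- NULL
  for (o in seq(min(lf, lr), min_overlap)) {
    ft <- fc[(lf - o + 1L):lf]
    rh <- rc[1:o]
    mm <- sum(ft != rh)
    if (100 * mm / o > max_diff_pct) next
    sc <- o - mm
    if (is.null(best) || sc > best$sc) best <- list(o = o, sc = sc)
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  fqi <- utf8ToInt(fq) - .phred_offset
  rqi <- utf8ToInt(rq) - .phred_offset
  ov_idx_f <- (lf - o + 1L):lf
  cons <- fc[ov_idx_f]
  use_r <- rc[1:o] != cons & rqi[1:o] > fqi[ov_idx_f]
  cons[use_r] <- rc[1:o][use_r]
  cons_q <- pmax(fqi[ov_idx_f], rqi[1:o])
  seq_out <- paste0(substr(f, 1L, lf - o), paste(cons, collapse = ""),
                    substr(r, o + 1L, lr))
  q_out <- c(fqi[seq_len(lf - o)], cons_q, rqi[seq(o + 1L, length.out = lr - o)])
  tibble(id = fwd$id, sample = fwd$sample, seq = seq_out, qual = int_to_qual(q_out))
}

#' @rdname merge_pairs
#' @param fwd_reads,rev_reads Reads tibbles of mates in matching order.
#' @return `merge_read_pairs()` returns the merged reads tibble (unmergeable
#'   pairs dropped, count reported via message).
#' @export
merge_read_pairs <- function(fwd_reads, rev_reads, min_overlap = 12L, max_diff_pct = 5) {
  stopifnot(nrow(fwd_reads) == nrow(rev_reads))
  out <- vector("list", nrow(fwd_reads))
  for (i in seq_len(nrow(fwd_reads))) {
    out[[i]] <- merge_pairs(fwd_reads[i, ], rev_reads[i, ], min_overlap, max_diff_pct)
  }
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped) inform(sprintf("merge_read_pairs: %d pair(s) had no qualifying overlap", dropped))
  bind_rows(out)
}

# ---- expected errors --------------------------------------------------------

.ee_lut <- 10^(-(0:93) / 10)

#' Expected errors of a read
#'
#' `EE = sum_i 10^(-q_i / 10)` over the Phred scores of a read: the expected
#' number of erroneous bases implied by the qualities.
#'
#' @param qual Phred+33 quality string(s) (vectorized) or an integer vector
#'   of Phred scores.
#' @return Numeric vector of expected errors.
#' @examples
#' expected_errors(int_to_qual(rep(20L, 100))) # 1.0
#' @export
expected_errors <- function(qual) {
  if (is.numeric(qual)) return(sum(10^(-qual / 10)))
  vapply(qual, function(q) {
    if (is.na(q)) return(NA_real_)
    sum(.ee_lut[utf8ToInt(q) - .phred_offset + 1L])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads by expected errors
#'
#' Removes reads whose expected error exceeds `max_ee`. Used only to select
#' the clustering input; the OTU table is always counted from the
#' pre-filter demultiplexed reads.
#'
#' @param reads A reads tibble with qualities.
#' @param max_ee Maximum expected errors (default 1.0).
#' @return The filtered reads tibble.
#' @export
filter_by_ee <- function(reads, max_ee = 1.0) {
  reads[expected_errors(reads$qual) <= max_ee, ]
}
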