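# Sequencing-run simulator with per-read truth. Emulates: per-template PCR
# bias (log-normal multiplicative factor per template and run), platform
# read errors (substitutions everywhere, +/-1 bp indels next to homopolymer
# runs >= 3), per-sample barcoding (inline 5' barcode or dual index), and
# tag-switching injected as post-hoc sample-label reassignment at a known
# small rate -- the observable consequence of index bleed, without
# committing to a mechanism.

.default_barcodes <- c(
  "ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG",
  "ATCAGACACG", "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC",
  "TAGTCGGACA", "TCTATCGGAC", "TGATACGTCT", "TACGTAGCAG",
  "CATGACGCTA", "CGAGATGTAC", "GTACAGCTGA", "GATCGTGCTA"
)

#' Default inline barcode set
#'
#' Sixteen 10 bp barcodes with pairwise Hamming distance >= 3, in the style
#' of platform barcode kits.
#'
#' @param n Number of barcodes (<= 16).
#' @return Character vector of barcodes.
#' @export
default_barcodes <- function(n = 16L) {
  if (n > length(.default_barcodes)) abort("at most 16 built-in barcodes")
  .default_barcodes[seq_len(n)]
}

#' Specification of a simulated sequencing run
#'
#' @param templates Reads tibble (or named character vector) of template
#'   sequences -- the amplicon inserts between the primers.
#' @param samples Named list: per sample, a named numeric composition over
#'   template ids summing to 1.
#' @param reads_per_sample Reads to draw per sample (>= 1).
#' @param fwd_primer,rev_primer Concrete primer sequences attached to each
#'   read (defaults: the fITS7 expansion written by the designer, and ITS4).
#' @param pcr_bias_sigma SD of the per-template log-normal bias factor
#'   (0 = unbiased).
#' @param sub_rate Per-base substitution rate.
#' @param hp_indel_rate Per-site +/-1 bp indel rate at bases adjacent to
#'   homopolymer runs >= 3.
#' @param bleed_rate Fraction of reads whose observed sample is reassigned
#'   uniformly among the other samples (tag-switching).
#' @param platform `"single_barcode"` (inline 5' barcode, reads come back
#'   unlabeled and must be demultiplexed) or `"dual_index"`
#'   (pre-demultiplexed; reads carry their observed sample label).
#' @param barcodes Barcode vector for `single_barcode` (one per sample).
#' @param shared_i7_boost For `dual_index`: multiply bleed probability
#'   toward samples sharing the i7 index (default 1 = off).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `run_spec` list.
#' @export
run_spec <- function(templates, samples, reads_per_sample,
                     fwd_primer = "GTGAATCATCGAATCTTTG",
                     rev_primer = its_primers()[["ITS4"]],
                     pcr_bias_sigma = 0, sub_rate = 0, hp_indel_rate = 0,
                     bleed_rate = 0, platform = c("single_barcode", "dual_index"),
                     barcodes = NULL, shared_i7_boost = 1, seed = 1L) {
  platform <- match.arg(platform)
  tpl <- if (is.data.frame(templates)) setNames(templates$seq, templates$id) else templates
  if (!length(tpl) || is.null(names(tpl))) abort("templates must be named sequences")
  if (is.null(names(samples)) || !length(samples)) abort("samples must be a named list")
  for (s in names(samples)) {
    comp <- samples[[s]]
    if (abs(sum(comp) - 1) > 1e-9) abort(sprintf("composition of sample '%s' does not sum to 1", s))
    if (!all(names(comp) %in% names(tpl))) abort("composition references unknown template")
  }
  for (r in c(sub_rate, hp_indel_rate, bleed_rate)) {
    if (r < 0 || r >= 1) abort("rates must be in [0, 1)")
  }
  if (pcr_bias_sigma < 0) abort("pcr_bias_sigma must be >= 0")
  if (reads_per_sample < 1L) abort("reads_per_sample must be >= 1")
  if (platform == "single_barcode") {
    barcodes <- barcodes %||% default_barcodes(length(samples))
    if (length(barcodes) < length(samples)) abort("need one barcode per sample")
    barcodes <- setNames(barcodes[seq_along(samples)], names(samples))
  }
  structure(list(
    templates = tpl, samples = samples,
    reads_per_sample = as.integer(reads_per_sample),
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    pcr_bias_sigma = pcr_bias_sigma, sub_rate = sub_rate,
    hp_indel_rate = hp_indel_rate, bleed_rate = bleed_rate,
    platform = platform, barcodes = barcodes,
    shared_i7_boost = shared_i7_boost, seed = as.integer(seed)
  ), class = "run_spec")
}

# indices (1-based) of bases adjacent to a homopolymer run of length >= 3
hp_adjacent_sites <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 3L
  unique(pmax(1L, pmin(nchar(seq), c(starts[keep] - 1L, ends[keep] + 1L))))
}

mutate_read <- function(seq, n_sub, indel_sites, hp_indel_rate) {
  chars <- strsplit(seq, "")[[1]]
  err_pos <- integer(0)
  if (n_sub > 0L) {
    pos <- sample.int(length(chars), n_sub)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    err_pos <- pos
  }
  n_ind <- 0L
  if (length(indel_sites) && hp_indel_rate > 0) {
    hit <- indel_sites[runif(length(indel_sites)) < hp_indel_rate]
    for (p in sort(hit, decreasing = TRUE)) {
      if (p > length(chars)) next
      if (runif(1) < 0.5) {
        chars <- append(chars, chars[p], after = p) # +1 duplication
      } else {
        chars <- chars[-p] # -1 deletion
      }
      n_ind <- n_ind + 1L
      err_pos <- c(err_pos, min(p, length(chars)))
    }
  }
  list(seq = paste(chars, collapse = ""), err_pos = unique(pmin(err_pos, length(chars))),
       n_indels = n_ind)
}

#' Simulate a sequencing run with known truth
#'
#' Per sample, template draw probabilities are `composition x bias` where
#' `bias = exp(N(0, pcr_bias_sigma))` is drawn once per template for the
#' run, renormalized; counts are multinomial. Each read is a template copy
#' with binomial substitutions and homopolymer-adjacent indels; erroneous
#' bases receive low Phred scores (Q3) on an otherwise high-quality
#' background (Q38), so expected-error filtering behaves as it would on
#' real data. A `bleed_rate` binomial fraction of reads has its observed
#' sample reassigned uniformly among the other samples. For the
#' `single_barcode` platform each read is written as
#' `barcode + fwd_primer + insert + rc(rev_primer)` and left unlabeled for
#' demultiplexing; for `dual_index` reads are returned pre-demultiplexed
#' with primers still attached.
#'
#' @param spec A [run_spec()].
#' @return A list:
#' * `reads`: reads tibble (unlabeled for `single_barcode`);
#' * `truth`: list with `per_read` (id, true/observed sample, template,
#'   `n_subs`, `n_indels`), `sample_template_counts` (drawn counts by true
#'   sample), and `bias` (the per-template factors);
#' * `sheet`: a [sample_sheet()] ready for [demux_single()].
#' @export
simulate_run <- function(spec) {
  if (!inherits(spec, "run_spec")) abort("spec must be a run_spec")
  tpl <- spec$templates
  tpl_names <- names(tpl)
  samples <- names(spec$samples)
  withr::with_seed(spec$seed, {
    bias <- exp(rnorm(length(tpl), 0, spec$pcr_bias_sigma))
    names(bias) <- tpl_names
    read_tpl <- character(0); true_sample <- character(0)
    counts_rows <- list()
    for (s in samples) {
      comp <- spec$samples[[s]]
      p <- comp * bias[names(comp)]
      p <- p / sum(p)
      cnt <- as.integer(rmultinom(1L, spec$reads_per_sample, p))
      counts_rows[[s]] <- tibble(sample = s, template = names(comp), count = cnt)
      read_tpl <- c(read_tpl, rep(names(comp), cnt))
      true_sample <- c(true_sample, rep(s, spec$reads_per_sample))
    }
    n <- length(read_tpl)
    observed <- true_sample
    n_bleed <- rbinom(1L, n, spec$bleed_rate)
    bleed_idx <- if (n_bleed > 0L) sample.int(n, n_bleed) else integer(0)
    if (length(bleed_idx) && length(samples) > 1L) {
      for (i in bleed_idx) {
        observed[i] <- sample(setdiff(samples, true_sample[i]), 1L)
      }
    }
    ins <- unname(tpl[read_tpl])
    n_subs <- if (spec$sub_rate > 0) rbinom(n, nchar(ins), spec$sub_rate) else integer(n)
    n_ind <- integer(n)
    err_pos <- vector("list", n)
    need_mut <- which(n_subs > 0L | spec$hp_indel_rate > 0)
    if (length(need_mut)) {
      hp_sites <- lapply(tpl, hp_adjacent_sites)
      for (i in need_mut) {
        mu <- mutate_read(ins[i], n_subs[i], hp_sites[[read_tpl[i]]], spec$hp_indel_rate)
        ins[i] <- mu$seq
        err_pos[[i]] <- mu$err_pos
        n_ind[i] <- mu$n_indels
      }
    }
    ids <- sprintf("read_%07d", seq_len(n))
    rc_rev <- revcomp(spec$rev_primer)
    if (spec$platform == "single_barcode") {
      bc <- unname(spec$barcodes[observed])
      seqs <- paste0(bc, spec$fwd_primer, ins, rc_rev)
      scaff5 <- nchar(bc) + nchar(spec$fwd_primer)
      sample_col <- NA_character_
    } else {
      seqs <- paste0(spec$fwd_primer, ins, rc_rev)
      scaff5 <- rep(nchar(spec$fwd_primer), n)
      sample_col <- observed
    }
    # qualities: constant Q38 background, Q3 at planted-error positions
    quals <- strrep("G", nchar(seqs))
    err_reads <- which(lengths(err_pos) > 0L)
    for (i in err_reads) {
      q <- strsplit(quals[i], "")[[1]]
      q[pmin(err_pos[[i]] + scaff5[i], length(q))] <- "$"
      quals[i] <- paste(q, collapse = "")
    }
  })
  reads <- tibble(id = ids, sample = sample_col, seq = seqs, qual = quals)
  sheet_tbl <- tibble(
    sample = samples,
    fwd_barcode = if (spec$platform == "single_barcode") unname(spec$barcodes) else NA_character_,
    rev_barcode = NA_character_,
    i5 = if (spec$platform == "dual_index") paste0("I5_", seq_along(samples)) else NA_character_,
    i7 = if (spec$platform == "dual_index") paste0("I7_", seq_along(samples)) else NA_character_
  )
  sheet <- sample_sheet(sheet_tbl, fwd_primer = spec$fwd_primer, rev_primer = spec$rev_primer)
  truth <- list(
    per_read = tibble(read_id = ids, true_sample = true_sample,
                      observed_sample = observed, template = read_tpl,
                      n_subs = as.integer(n_subs), n_indels = n_ind),
    sample_template_counts = bind_rows(counts_rows),
    bias = bias
  )
  list(reads = validate_reads(reads), truth = truth, sheet = sheet)
}

#' Truth OTU-style count matrix of a simulated run
#'
#' Counts of reads per (template, observed sample): what a perfect pipeline
#' should reconstruct from the demultiplexed data.
#'
#' @param truth The `truth` component of [simulate_run()].
#' @return A wide tibble `otu_id` (template name) x samples.
#' @export
truth_count_table <- function(truth) {
  pr <- truth$per_read
  tab <- table(pr$template, pr$observed_sample)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  validate_otu_table(otu_table_from_matrix(m))
}

#' Generate a biological-mock-like template fixture
#'
#' A synthetic stand-in emulating a plasmid mock community of cloned fungal
#' ITS fragments: `n` templates spanning lengths 237-548 bp and GC content
#' 0.438-0.684 (assigned as ladders across members), including exactly one
#' pair at ~96% mutual identity (two intragenomic ITS variants of one
#' isolate) and one member carrying two 9 bp homopolymer runs. All other
#' pairs are below 90% identity. Deterministic per seed.
#'
#' @param n Number of templates (default 26).
#' @param seed Integer seed.
#' @return A reads tibble of templates (`BioMockSyn01`, ...).
#' @export
make_biomock_fixture <- function(n = 26L, seed = 7L) {
  if (n < 3L) abort("n must be >= 3")
  lens <- as.integer(round(seq(237L, 548L, length.out = n)))
  gcs <- seq(0.438, 0.684, length.out = n)
  seqs <- character(n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      if (i == 2L) next # member 2 is derived from member 1 below
      plant <- if (i == 3L) 9L else NULL
      repeat {
        s <- sample_region(lens[i], gcs[i] + c(-0.02, 0.02), 6L, plant = plant)
        if (i == 3L) {
          # add the second 9 bp run
          base <- sample(c("A", "C", "G", "T"), 1L)
          pos <- as.integer(nchar(s) * 0.7)
          s <- paste0(substr(s, 1L, pos - 1L), strrep(base, 9L),
                      substr(s, pos + 9L, nchar(s)))
        }
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (j == 2L || !nzchar(seqs[j])) next
          if (global_identity(seqs[j], s) >= 0.90) { ok <- FALSE; break }
        }
        if (ok) break
      }
      seqs[i] <- s
    }
    # member 2: ~4% diverged copy of member 1 (intragenomic variant pair)
    repeat {
      chars <- strsplit(seqs[1L], "")[[1]]
      k <- max(1L, round(0.04 * length(chars)))
      pos <- sample.int(length(chars), k)
      for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      s2 <- paste(chars, collapse = "")
      idv <- global_identity(seqs[1L], s2)
      if (idv >= 0.955 && idv <= 0.965) { seqs[2L] <- s2; break }
    }
  })
  reads_tbl(id = sprintf("BioMockSyn%02d", seq_len(n)), seq = seqs)
}
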