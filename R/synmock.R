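# SynMock design: non-biological ITS-like spike-in sequences. Each member is
#   ssu_anchor + ITS1_i + r58s + ITS2_i + lsu_anchor
# where the anchors carry real conserved priming sites (ITS1-F/ITS1 in the
# SSU anchor; ITS2/ITS3/fITS7-compatible 5.8S segment; ITS4 site, reverse
# complemented, opening the LSU anchor) and the ITS1/ITS2 regions are random
# sequences with constrained length, GC and homopolymer content. Because the
# variable regions are random, the members behave like real ITS amplicons in
# every pipeline stage yet cannot occur in environmental samples, which is
# what makes them usable to measure tag-switching.

#' Canonical ITS primer sequences
#'
#' The conserved fungal ITS priming sites used throughout the package
#' (5'->3', IUPAC): `ITS1-F`, `ITS1`, `ITS2`, `ITS3`, `fITS7`, `ITS4`.
#'
#' @return A named character vector.
#' @export
its_primers <- function() {
  c(
    "ITS1-F" = "CTTGGTCATTTAGAGGAAGTAA",
    "ITS1"   = "TCCGTAGGTGAACCTGCGG",
    "ITS2"   = "GCTGCGTTCTTCATCGATGC",
    "ITS3"   = "GCATCGATGAAGAACGCAGC",
    "fITS7"  = "GTGARTCATCGAATCTTTG",
    "ITS4"   = "TCCTCCGCTTATTGATATGC"
  )
}

default_anchors <- function() {
  p <- its_primers()
  list(
    # ITS1-F then ITS1 at the SSU 3' end: the ITS1 site's end is exactly
    # where the ITS1 random region begins.
    ssu_anchor = paste0(p[["ITS1-F"]], p[["ITS1"]]),
    # 5.8S segment: opens with the ITS3 site (= reverse complement of the
    # ITS2 priming site) and closes with a concrete expansion of fITS7
    # (R -> A), so ITS1 extraction ends here and ITS2 extraction starts
    # right after.
    r58s = paste0(p[["ITS3"]], "GTGAATCATCGAATCTTTG"),
    # LSU opens with the reverse complement of ITS4.
    lsu_anchor = revcomp(p[["ITS4"]])
  )
}

#' Specification for a SynMock design
#'
#' Defaults give a 12-member community whose ITS1/ITS2 lengths ladder across
#' ranges representative of curated fungal ITS databases (including a short
#' ~140-160 bp ITS2 member and a long member near platform limits), GC
#' between 0.40 and 0.65, homopolymers capped at 5 bp except deliberately
#' planted 7 bp and 9 bp runs, and all pairwise identities over the variable
#' regions at most 0.90.
#'
#' @param n_members Number of members (>= 2; default 12).
#' @param its1_len_range,its2_len_range Length ranges in bp.
#' @param gc_range GC-content range (fractions).
#' @param max_homopolymer Longest allowed run in the random regions.
#' @param planted_homopolymers List of `c(length, count)` runs planted
#'   across designated members.
#' @param min_pairwise_divergence Minimum divergence (1 - identity) between
#'   any two members' concatenated variable regions.
#' @param seed Integer seed (design is deterministic given the seed).
#' @param anchors List with `ssu_anchor`, `r58s`, `lsu_anchor`.
#' @param max_attempts Rejection-sampling cap per region.
#' @return A `synmock_spec` list.
#' @export
synmock_spec <- function(n_members = 12L,
                         its1_len_range = c(150L, 300L),
                         its2_len_range = c(140L, 360L),
                         gc_range = c(0.40, 0.65),
                         max_homopolymer = 5L,
                         planted_homopolymers = list(c(7L, 1L), c(9L, 1L)),
                         min_pairwise_divergence = 0.10,
                         seed = 42L,
                         anchors = default_anchors(),
                         max_attempts = 10000L) {
  if (n_members < 2L) abort("n_members must be >= 2")
  for (r in list(its1_len_range, its2_len_range, gc_range)) {
    if (length(r) != 2L || r[1] > r[2]) abort("ranges must be c(min, max) with min <= max")
  }
  if (min_pairwise_divergence <= 0 || min_pairwise_divergence >= 1) {
    abort("min_pairwise_divergence must be in (0, 1)")
  }
  structure(list(
    n_members = as.integer(n_members),
    its1_len_range = as.integer(its1_len_range),
    its2_len_range = as.integer(its2_len_range),
    gc_range = gc_range, max_homopolymer = as.integer(max_homopolymer),
    planted_homopolymers = planted_homopolymers,
    min_pairwise_divergence = min_pairwise_divergence,
    seed = as.integer(seed), anchors = anchors,
    max_attempts = as.integer(max_attempts)
  ), class = "synmock_spec")
}

gc_frac <- function(seq) {
  vapply(strsplit(seq, ""), function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

max_run <- function(seq) {
  vapply(strsplit(seq, ""), function(ch) max(rle(ch)$lengths), numeric(1))
}

# One random region: fixed length, GC within range, no homopolymer beyond
# max_hp (planted run inserted afterwards, then re-checked).
sample_region <- function(len, gc_range, max_hp, plant = NULL, max_attempts = 10000L) {
  gc_target <- runif(1, gc_range[1], gc_range[2])
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2, G = gc_target / 2, T = (1 - gc_target) / 2)
  for (attempt in seq_len(max_attempts)) {
    s <- paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    if (!is.null(plant)) {
      base <- sample(c("A", "C", "G", "T"), 1L)
      pos <- sample.int(len - plant - 1L, 1L) + 1L
      s <- paste0(substr(s, 1L, pos - 1L), strrep(base, plant),
                  substr(s, pos + plant, len))
    }
    gc <- gc_frac(s)
    runs <- rle(strsplit(s, "")[[1]])$lengths
    hp_ok <- if (is.null(plant)) {
      max(runs) <= max_hp
    } else {
      sum(runs > max_hp) == 1L && max(runs) == plant
    }
    if (gc >= gc_range[1] && gc <= gc_range[2] && hp_ok) return(s)
  }
  abort(sprintf(
    "could not sample a %d bp region satisfying GC in [%.2f, %.2f] and homopolymer <= %d after %d attempts",
    len, gc_range[1], gc_range[2], max_hp, max_attempts))
}

#' Design a SynMock community
#'
#' Generates `n_members` non-biological ITS-like sequences by constrained
#' rejection sampling under the given [synmock_spec()]. Region lengths are
#' assigned as an evenly spaced ladder across each range (ITS1 ascending,
#' ITS2 descending) so the set always spans short and long amplicons.
#' Deterministic for a given spec seed.
#'
#' @param spec A [synmock_spec()].
#' @return A reads tibble (`id`, `seq`, `qual = NA`) of the designed
#'   members, with the spec attached as attribute `"spec"`.
#' @export
design_synmock <- function(spec = synmock_spec()) {
  if (!inherits(spec, "synmock_spec")) abort("spec must be a synmock_spec")
  n <- spec$n_members
  len1 <- as.integer(round(seq(spec$its1_len_range[1], spec$its1_len_range[2], length.out = n)))
  len2 <- as.integer(round(seq(spec$its2_len_range[2], spec$its2_len_range[1], length.out = n)))
  # planted homopolymer runs go to distinct members, longest runs first,
  # alternating between the ITS1 and ITS2 regions
  plants <- unlist(lapply(spec$planted_homopolymers, function(x) rep(x[1], x[2])))
  plants <- sort(as.integer(plants), decreasing = TRUE)
  plant1 <- rep(NA_integer_, n); plant2 <- rep(NA_integer_, n)
  for (i in seq_along(plants)) {
    member <- ((i - 1L) %% n) + 1L
    if (i %% 2L == 1L) plant1[member] <- plants[i] else plant2[member] <- plants[i]
  }
  withr::with_seed(spec$seed, {
    its1 <- character(n); its2 <- character(n)
    for (i in seq_len(n)) {
      for (attempt in seq_len(spec$max_attempts)) {
        r1 <- sample_region(len1[i], spec$gc_range, spec$max_homopolymer,
                            plant = if (is.na(plant1[i])) NULL else plant1[i],
                            max_attempts = spec$max_attempts)
        r2 <- sample_region(len2[i], spec$gc_range, spec$max_homopolymer,
                            plant = if (is.na(plant2[i])) NULL else plant2[i],
                            max_attempts = spec$max_attempts)
        cat_i <- paste0(r1, r2)
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (global_identity(paste0(its1[j], its2[j]), cat_i) >
              1 - spec$min_pairwise_divergence) {
            ok <- FALSE
            break
          }
        }
        if (ok) break
        if (attempt == spec$max_attempts) {
          abort("could not satisfy min_pairwise_divergence; relax the constraint")
        }
      }
      its1[i] <- r1; its2[i] <- r2
    }
  })
  seqs <- paste0(spec$anchors$ssu_anchor, its1, spec$anchors$r58s, its2,
                 spec$anchors$lsu_anchor)
  out <- reads_tbl(id = sprintf("SynMock%02d", seq_len(n)), seq = seqs)
  attr(out, "spec") <- spec
  attr(out, "its1") <- its1
  attr(out, "its2") <- its2
  out
}

#' Find homopolymer runs
#'
#' All maximal runs of a single base with length >= `min_len`, in order of
#' position.
#'
#' @param seq A single DNA sequence.
#' @param min_len Minimum run length to report (default 7, i.e. runs longer
#'   than 6 bp, the conventional flow-platform trouble threshold).
#' @return A tibble `base`, `start` (1-based), `length`.
#' @export
find_homopolymers <- function(seq, min_len = 7L) {
  r <- rle(strsplit(seq, "")[[1]])
  start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  keep <- r$lengths >= min_len
  tibble(base = r$values[keep], start = start[keep], length = as.integer(r$lengths[keep]))
}

#' Extract an amplicon subregion between two priming sites
#'
#' For each sequence containing the forward primer and, downstream of it,
#' the reverse-complemented reverse primer, the inter-primer subsequence is
#' returned (primers excluded). Sequences lacking either site are skipped
#' and counted in attribute `"skipped"`.
#'
#' @param seqs A reads tibble (or named character vector).
#' @param fwd_primer,rev_primer Primers in sense orientation (IUPAC; the
#'   reverse primer is matched against the reverse-complement strand).
#' @param max_edits Edit tolerance per primer (default 2).
#' @return A reads tibble of extracted regions with attribute `skipped`.
#' @export
extract_subregion <- function(seqs, fwd_primer, rev_primer, max_edits = 2L) {
  tbl <- if (is.data.frame(seqs)) seqs else tibble(id = names(seqs), seq = unname(seqs))
  ids <- character(0); regions <- character(0); skipped <- 0L
  rc_rev <- revcomp(rev_primer)
  for (i in seq_len(nrow(tbl))) {
    fh <- find_primer(tbl$seq[i], fwd_primer, max_edits)
    if (is.null(fh)) { skipped <- skipped + 1L; next }
    rest <- substr(tbl$seq[i], fh$end + 1L, nchar(tbl$seq[i]))
    rh <- find_primer(rest, rc_rev, max_edits)
    if (is.null(rh) || rh$start <= 1L) { skipped <- skipped + 1L; next }
    ids <- c(ids, tbl$id[i])
    regions <- c(regions, substr(rest, 1L, rh$start - 1L))
  }
  out <- if (length(ids)) reads_tbl(id = ids, seq = regions) else reads_tbl(character(), character())[0, ]
  attr(out, "skipped") <- skipped
  out
}

#' Length and homopolymer summary of a sequence set
#'
#' The audit used to characterize reference databases and designed mock
#' communities: number of sequences, mean length, the percentage containing
#' any homopolymer run longer than each threshold, and the percentage longer
#' than `long_cutoff` (platform length limit).
#'
#' @param seqs A reads tibble or character vector of sequences.
#' @param hp_thresholds Homopolymer thresholds (default `c(6, 8)`, i.e.
#'   runs > 6 bp and > 8 bp).
#' @param long_cutoff Length cutoff in bp (default 450).
#' @return A one-row tibble: `n`, `avg_length` (rounded bp), one
#'   `pct_hp_gt_<t>` column per threshold, `pct_gt_<long_cutoff>`.
#' @export
summarize_lengths <- function(seqs, hp_thresholds = c(6L, 8L), long_cutoff = 450L) {
  sq <- if (is.data.frame(seqs)) seqs$seq else as.character(seqs)
  n <- length(sq)
  runs <- max_run(sq)
  out <- tibble(n = n, avg_length = as.integer(round(mean(nchar(sq)))))
  for (t in hp_thresholds) {
    out[[paste0("pct_hp_gt_", t)]] <- 100 * mean(runs > t)
  }
  out[[paste0("pct_gt_", long_cutoff)]] <- 100 * mean(nchar(sq) > long_cutoff)
  out
}
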