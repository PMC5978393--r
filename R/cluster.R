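# Greedy centroid OTU clustering (UPARSE-style order) and OTU-table
# construction from the *pre-quality-filter* demultiplexed reads, so read
# counts reflect what was in each sample, not what survived filtering.

#' Dereplicate reads into unique sequences
#'
#' @param reads A reads tibble (or anything with a `seq` column).
#' @return A tibble `seq`, `size` sorted by size descending, ties broken
#'   lexicographically by sequence; `sum(size)` equals the input read count.
#' @export
dereplicate <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (!length(seqs)) return(tibble(seq = character(), size = integer()))
  tab <- table(seqs)
  out <- tibble(seq = names(tab), size = as.integer(tab))
  arrange(out, desc(.data$size), .data$seq)
}

# Upper bound on global identity from lengths alone: matches <= min(la, lb)
# and columns >= max(la, lb). Used to skip hopeless alignments.
identity_upper_bound <- function(la, lb) pmin(la, lb) / pmax(la, lb)

#' Greedy centroid clustering at an identity threshold
#'
#' Unique sequences are processed in abundance order (size descending, ties
#' lexicographic). Uniques below `min_size` are skipped as centroid seeds
#' (singleton noise), though their reads still count in the OTU table via
#' [map_reads_to_otus()]. Each candidate joins the first existing centroid
#' with global identity >= `id_threshold` (inclusive); otherwise, unless
#' flagged as a two-parent chimera, it founds a new OTU. All centroid pairs
#' are therefore below the threshold.
#'
#' @param uniques Output of [dereplicate()].
#' @param id_threshold Identity threshold in (0.5, 1] (default 0.97).
#' @param min_size Minimum abundance to seed/extend clustering (default 2).
#' @param chimera_check Run [flag_chimera()] on non-matching candidates
#'   (default `TRUE`).
#' @return A tibble `otu_id` (`OTU_1`, ...), `centroid`, `size` (summed
#'   abundance of uniques absorbed during clustering).
#' @export
cluster_otus <- function(uniques, id_threshold = 0.97, min_size = 2L,
                         chimera_check = TRUE) {
  if (id_threshold <= 0.5 || id_threshold > 1) abort("id_threshold must be in (0.5, 1]")
  cents <- character(0)
  sizes <- integer(0)
  for (i in seq_len(nrow(uniques))) {
    if (uniques$size[i] < min_size) next
    s <- uniques$seq[i]
    joined <- FALSE
    if (length(cents)) {
      cand <- which(identity_upper_bound(nchar(s), nchar(cents)) >= id_threshold)
      for (j in cand) {
        if (global_identity(cents[j], s) >= id_threshold) {
          sizes[j] <- sizes[j] + uniques$size[i]
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      if (chimera_check && length(cents) >= 2L && flag_chimera(s, cents)) next
      cents <- c(cents, s)
      sizes <- c(sizes, uniques$size[i])
    }
  }
  tibble(otu_id = paste0("OTU_", seq_along(cents)), centroid = cents, size = sizes)
}

#' Flag a candidate as a two-parent crossover chimera
#'
#' A deliberately simple bipartite test (not UCHIME): the candidate is
#' chimeric when some split point leaves its left segment matching one
#' centroid's prefix and its right segment matching a *different* centroid's
#' suffix, each at >= `seg_id` ungapped identity, while the full-length
#' global identity to every single centroid stays below `full_id`. Segments
#' shorter than `min_seg` bases are not considered.
#'
#' @param candidate A DNA sequence.
#' @param centroids Character vector of current centroids (>= 2, else
#'   `FALSE` is returned).
#' @param seg_id Per-segment identity floor (default 0.99).
#' @param full_id Full-length identity ceiling (default 0.97).
#' @param min_seg Minimum segment length (default 30).
#' @return `TRUE` when the crossover pattern is detected.
#' @export
flag_chimera <- function(candidate, centroids, seg_id = 0.99, full_id = 0.97,
                         min_seg = 30L) {
  if (length(centroids) < 2L) return(FALSE)
  n <- nchar(candidate)
  if (n < 2L * min_seg) return(FALSE)
  ub <- identity_upper_bound(n, nchar(centroids))
  full <- numeric(length(centroids))
  chk <- ub >= full_id
  full[chk] <- global_identity(centroids[chk], candidate)
  if (any(full >= full_id)) return(FALSE)

  cc <- strsplit(candidate, "")[[1]]
  splits <- min_seg:(n - min_seg)
  best_left <- matrix(0, nrow = length(splits), ncol = length(centroids))
  best_right <- best_left
  for (j in seq_along(centroids)) {
    pc <- strsplit(centroids[j], "")[[1]]
    m <- min(n, length(pc))
    # ungapped prefix identity at every split
    pref_match <- cumsum(c(cc[1:m] == pc[1:m], rep(FALSE, n - m)))
    best_left[, j] <- pref_match[splits] / splits
    # ungapped suffix identity: align 3' ends
    suf_eq <- rev(rev(cc)[1:m] == rev(pc)[1:m])
    suf_match <- rev(cumsum(rev(c(rep(FALSE, n - m), suf_eq))))
    best_right[, j] <- suf_match[splits + 1L] / (n - splits)
  }
  for (k in seq_along(splits)) {
    lj <- which(best_left[k, ] >= seg_id)
    rj <- which(best_right[k, ] >= seg_id)
    if (length(lj) && length(rj) &&
        !(length(lj) == 1L && length(rj) == 1L && lj == rj)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Build an OTU table by mapping demultiplexed reads to centroids
#'
#' Each read is assigned to the best centroid with global identity >=
#' `id_threshold` (ties broken by centroid order, i.e. abundance rank);
#' unassigned reads are dropped. The input must be the pre-quality-filter
#' demultiplexed read set so that counts reflect sample content.
#' Internally reads are dereplicated first so each distinct sequence is
#' aligned once.
#'
#' @param demuxed_reads A sample-labeled reads tibble.
#' @param otus Output of [cluster_otus()].
#' @param id_threshold Mapping identity threshold (default 0.97, inclusive).
#' @param samples Optional character vector fixing the table's sample
#'   columns (useful for empty inputs); defaults to the samples present.
#' @return A wide OTU-table tibble (`otu_id` + one integer column per
#'   sample).
#' @export
map_reads_to_otus <- function(demuxed_reads, otus, id_threshold = 0.97,
                              samples = NULL) {
  if (nrow(demuxed_reads) && anyNA(demuxed_reads$sample)) {
    abort("map_reads_to_otus: every read must carry a sample label")
  }
  samples <- samples %||% unique(demuxed_reads$sample)
  cents <- otus$centroid
  m <- matrix(0L, nrow = nrow(otus), ncol = length(samples),
              dimnames = list(otus$otu_id, samples))
  if (nrow(demuxed_reads) && nrow(otus)) {
    uniq <- unique(demuxed_reads$seq)
    assign <- match(uniq, cents) # exact-match fast path
    todo <- which(is.na(assign))
    for (i in todo) {
      ub <- identity_upper_bound(nchar(uniq[i]), nchar(cents))
      cand <- which(ub >= id_threshold)
      if (!length(cand)) next
      ids <- global_identity(cents[cand], uniq[i])
      ok <- ids >= id_threshold
      if (any(ok)) {
        best <- max(ids[ok])
        assign[i] <- cand[ok][which(ids[ok] == best)[1L]]
      }
    }
    read_otu <- assign[match(demuxed_reads$seq, uniq)]
    hit <- !is.na(read_otu)
    if (any(hit)) {
      tab <- table(factor(otus$otu_id[read_otu[hit]], levels = otus$otu_id),
                   factor(demuxed_reads$sample[hit], levels = samples))
      m <- m + unclass(tab)
    }
  }
  validate_otu_table(otu_table_from_matrix(m))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each sample column with total >= `depth` is replaced by a
#' without-replacement subsample of its reads summing exactly to `depth`;
#' samples below the depth are dropped with a message. Deterministic for a
#' given `seed`. Provided for comparability with common practice; note that
#' amplicon read abundances are already a poor proxy for template abundance,
#' so rarefied counts inherit that caveat.
#'
#' @param table An OTU table tibble.
#' @param depth Target depth per sample (> 0).
#' @param seed Integer seed.
#' @return The rarefied OTU table.
#' @export
rarefy <- function(table, depth, seed) {
  table <- validate_otu_table(table)
  if (depth <= 0L) abort("depth must be positive")
  m <- otu_counts(table)
  tot <- colSums(m)
  drop <- names(tot)[tot < depth]
  if (length(drop)) {
    inform(paste("rarefy: dropping sample(s) below depth:", paste(drop, collapse = ", ")))
  }
  keep <- tot >= depth
  m <- m[, keep, drop = FALSE]
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) == depth) next
      pool <- rep(seq_len(nrow(m)), m[, j])
      take <- sample(pool, depth, replace = FALSE)
      m[, j] <- tabulate(take, nbins = nrow(m))
    }
  })
  validate_otu_table(otu_table_from_matrix(m))
}
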