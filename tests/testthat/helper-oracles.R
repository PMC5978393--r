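# Independent brute-force oracles. These deliberately share no code with the
# package: plain-R dynamic programming and scans, used only to freeze or
# cross-check expected values.

random_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample.int(length(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# --- global alignment oracle -------------------------------------------------
# Cell-by-cell Needleman-Wunsch (match +1, mismatch -1, gap -2, end gaps
# penalized). Returns the optimal score plus the exact set of
# (matches, columns) pairs realized by *all* co-optimal alignments, so the
# implementation's identity must be one of matches/columns.
nw_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, ] <- -2 * (0:m); F[, 1] <- -2 * (0:n)
  for (i in 1:n) for (j in 1:m) {
    s <- if (A[i] == B[j]) 1 else -1
    F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] - 2, F[i + 1, j] - 2)
  }
  # enumerate (matches, cols) over co-optimal paths, backwards with memo
  memo <- new.env(parent = emptyenv())
  paths <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i == 0 && j == 0) {
      res <- matrix(c(0, 0), ncol = 2)
    } else {
      acc <- NULL
      if (i > 0 && j > 0) {
        s <- if (A[i] == B[j]) 1 else -1
        if (F[i, j] + s == F[i + 1, j + 1]) {
          p <- paths(i - 1, j - 1)
          acc <- rbind(acc, cbind(p[, 1] + (s == 1), p[, 2] + 1))
        }
      }
      if (i > 0 && F[i, j + 1] - 2 == F[i + 1, j + 1]) {
        p <- paths(i - 1, j)
        acc <- rbind(acc, cbind(p[, 1], p[, 2] + 1))
      }
      if (j > 0 && F[i + 1, j] - 2 == F[i + 1, j + 1]) {
        p <- paths(i, j - 1)
        acc <- rbind(acc, cbind(p[, 1], p[, 2] + 1))
      }
      res <- unique(acc)
    }
    memo[[key]] <- res
    res
  }
  pc <- paths(n, m)
  list(score = F[n + 1, m + 1], identities = unique(pc[, 1] / pc[, 2]))
}

# --- semi-global primer oracle -----------------------------------------------
# Edit distance of the primer aligned in full against any substring of the
# read (free read ends); IUPAC codes in the primer match expansions at cost
# 0. Returns the minimal edit distance (Inf if > max allowed by caller).
iupac_match_oracle <- function(p, s) {
  exp <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  s %in% exp[[p]]
}

semiglobal_edits_oracle <- function(read, primer) {
  P <- strsplit(primer, "")[[1]]; S <- strsplit(read, "")[[1]]
  np <- length(P); ns <- length(S)
  # rows: primer prefix (global); cols: read position (free start, free end)
  D <- matrix(0L, np + 1, ns + 1)
  D[, 1] <- 0:np
  D[1, ] <- 0L
  for (i in 1:np) for (j in 1:ns) {
    cost <- if (iupac_match_oracle(P[i], S[j])) 0L else 1L
    D[i + 1, j + 1] <- min(D[i, j] + cost, D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  min(D[np + 1, ])
}

# --- homopolymer oracle ------------------------------------------------------
hp_oracle <- function(seq, min_len) {
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  for (start in seq_along(ch)) {
    len <- 0
    while (start + len <= length(ch) && ch[start + len] == ch[start]) len <- len + 1
    maximal <- (start == 1 || ch[start - 1] != ch[start]) &&
      (start + len > length(ch) || ch[start + len] != ch[start])
    if (maximal && len >= min_len) {
      out[[length(out) + 1]] <- data.frame(base = ch[start], start = start, length = len)
    }
  }
  if (!length(out)) {
    data.frame(base = character(), start = integer(), length = integer())
  } else {
    do.call(rbind, out)
  }
}

# --- lineage prefix oracle ---------------------------------------------------
lca_oracle <- function(a, b) {
  out <- rep(NA_character_, 7)
  for (r in 1:7) {
    if (is.na(a[r]) || is.na(b[r]) || a[r] != b[r]) break
    out[r] <- a[r]
  }
  out
}

random_lineage <- function(pool = 2) {
  depth <- sample(0:7, 1)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  out <- stats::setNames(rep(NA_character_, 7), ranks)
  if (depth > 0) out[1:depth] <- paste0(substr(ranks[1:depth], 1, 1), sample(pool, depth, replace = TRUE))
  out
}
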