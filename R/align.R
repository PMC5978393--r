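# Alignment primitives shared by clustering, mock mapping and taxonomy.
# Global alignment is Needleman-Wunsch with match +1, mismatch -1, linear
# gap -2 and *penalized terminal gaps*: with variable-length amplicons the
# terminal overhang is real signal, so identity is matches / alignment
# columns including end gaps.

.nw_mat <- NULL

nw_submat <- function() {
  if (is.null(.nw_mat)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
    utils::assignInMyNamespace(".nw_mat", m)
  }
  .nw_mat
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of IUPAC DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorized global alignment of many `a` against one `b`.
# Returns tibble(identity, matches, columns, mismatches) where mismatches
# counts substitution plus gap columns.
nw_stats <- function(a, b) {
  if (!length(a)) {
    return(tibble(identity = double(), matches = integer(),
                  columns = integer(), mismatches = integer()))
  }
  if (any(!nzchar(a)) || !nzchar(b)) abort("global alignment requires non-empty sequences")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(a),
    subject = Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = nw_submat(),
    gapOpening = 0, gapExtension = 2
  )
  # columns = matches + substitutions + gap columns; with
  # la + lb = 2*matches + 2*substitutions + gapcols this reduces to:
  m <- Biostrings::nmatch(aln)
  x <- Biostrings::nmismatch(aln)
  cols <- nchar(a) + nchar(b) - m - x
  tibble(identity = m / cols, matches = as.integer(m),
         columns = as.integer(cols), mismatches = as.integer(cols - m))
}

#' Global pairwise identity
#'
#' Fraction of identical columns in the optimal global (Needleman-Wunsch)
#' alignment of `a` and `b`; terminal gaps are penalized and count in the
#' denominator, so a short sequence can never score high against a long one.
#'
#' @param a Character vector of DNA sequences (vectorized).
#' @param b A single DNA sequence.
#' @return Numeric vector of identities in `[0, 1]`.
#' @examples
#' global_identity("ACGTACGT", "ACGAACGT") # 7/8
#' @export
global_identity <- function(a, b) {
  idx <- which(a == b)
  out <- numeric(length(a))
  out[idx] <- 1
  rest <- setdiff(seq_along(a), idx)
  if (length(rest)) out[rest] <- nw_stats(a[rest], b)$identity
  out
}

# ---- primer search ----------------------------------------------------------

# Regex matching a primer with IUPAC ambiguity codes expanded to classes
# (exact-match fast path used by demultiplexing).
iupac_regex <- function(primer) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
           B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(primer), "")[[1]]
  unknown <- setdiff(chars, names(map))
  if (length(unknown)) abort(paste("non-IUPAC letter in primer:", paste(unknown, collapse = "")))
  paste0(map[chars], collapse = "")
}

#' Locate a primer in a read by semi-global alignment
#'
#' The primer is aligned in full with free ends on the read (semi-global);
#' IUPAC ambiguity codes in the primer match their expansions at zero cost.
#' The hit with the fewest edits wins; among equal-edit hits the leftmost is
#' returned. By default edits are full edit distance (substitutions and
#' indels); `indels = FALSE` restricts to substitutions only.
#'
#' @param read_seq A single DNA sequence to search.
#' @param primer Primer sequence (length >= 10 recommended; must be non-empty).
#' @param max_edits Maximum allowed edits (default 2, the conventional primer
#'   mismatch tolerance).
#' @param indels Count indels as edits (default `TRUE`).
#' @return A one-row tibble `start`, `end` (1-based inclusive), `edits`, or
#'   `NULL` when no qualifying hit exists.
#' @export
find_primer <- function(read_seq, primer, max_edits = 2L, indels = TRUE) {
  if (is.null(primer) || !nzchar(primer)) abort("empty primer")
  if (!nzchar(read_seq)) return(NULL)
  primer <- toupper(primer)
  if (nchar(primer) > nchar(read_seq) + max_edits) return(NULL)
  subj <- Biostrings::DNAString(read_seq)
  pat <- Biostrings::DNAString(primer)
  for (k in 0:max_edits) {
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = k,
                                     with.indels = indels, fixed = FALSE)
    if (length(hits)) {
      r <- IRanges::ranges(hits)
      i <- which.min(BiocGenerics::start(r))
      return(tibble(start = BiocGenerics::start(r)[i],
                    end = BiocGenerics::end(r)[i], edits = k))
    }
  }
  NULL
}
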