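# Taxonomy assignment: global-alignment top hit, a k-mer bootstrap
# classifier, and the hybrid rule that combines them --
#   (i)  top-hit identity > 97%  -> keep the alignment top hit;
#   (ii) otherwise               -> use the classifier's lineage;
#   (iii) if the two lineages disagree at any rank both have set ->
#         fall back to their least common ancestor.

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
.rank_letters <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species")

empty_lineage <- function() setNames(rep(NA_character_, 7L), .tax_ranks)

# Enforce the prefix invariant: no rank set below an unset one.
as_lineage <- function(x) {
  ln <- empty_lineage()
  ln[names(x)[names(x) %in% .tax_ranks]] <- unname(x[names(x) %in% .tax_ranks])
  ln[!nzchar(ln) | is.na(ln)] <- NA_character_
  first_na <- which(is.na(ln))[1]
  if (!is.na(first_na)) ln[first_na:7L] <- NA_character_
  ln
}

parse_lineage_header <- function(header) {
  if (grepl(";tax=", header, fixed = TRUE)) {
    # UTAX/SINTAX dialect: >ID;tax=k:Fungi,p:Ascomycota,...
    tax <- sub("^.*;tax=", "", header)
    parts <- strsplit(tax, ",", fixed = TRUE)[[1]]
    key <- substr(parts, 1L, 1L)
    val <- sub("^.:", "", parts)
    ln <- setNames(val, .rank_letters[key])
  } else if (grepl("__", header, fixed = TRUE)) {
    # QIIME dialect: >ID k__Fungi;p__Ascomycota;...
    tax <- sub("^\\S+\\s+", "", header)
    parts <- strsplit(tax, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    key <- substr(parts, 1L, 1L)
    val <- sub("^.__", "", parts)
    ln <- setNames(val, .rank_letters[key])
  } else {
    ln <- character(0)
  }
  as_lineage(ln)
}

#' Load a taxonomy reference database from FASTA
#'
#' Headers may use the UTAX/SINTAX dialect
#' (`>ID;tax=k:Fungi,p:...,g:...,s:...`) or the QIIME dialect
#' (`>ID k__Fungi;p__...`); the dialect is auto-detected per record.
#'
#' @param path Path to the reference FASTA.
#' @return A `refdb` object: a tibble with `id`, `seq` and the seven rank
#'   columns `kingdom` ... `species`.
#' @export
read_refdb <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort("empty reference database")
  ids <- sub("[;\\s].*$", "", names(set), perl = TRUE)
  if (anyDuplicated(ids)) abort("duplicate ids in reference database")
  lin <- t(vapply(names(set), parse_lineage_header, empty_lineage()))
  out <- dplyr::bind_cols(
    tibble(id = ids, seq = normalize_dna(as.character(set))),
    as_tibble(lin)
  )
  refdb(out)
}

#' @rdname read_refdb
#' @param entries Tibble with `id`, `seq` and rank columns.
#' @export
refdb <- function(entries) {
  entries <- as_tibble(entries)
  miss <- setdiff(c("id", "seq", .tax_ranks), names(entries))
  if (length(miss)) abort(paste("refdb lacks column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(entries$id)) abort("duplicate ids in reference database")
  entries <- arrange(entries, .data$id)
  class(entries) <- c("refdb", class(entries))
  entries
}

db_lineage <- function(db, ref_id) {
  as_lineage(unlist(db[db$id == ref_id, .tax_ranks][1, ]))
}

#' Global-alignment top hit against a reference database
#'
#' Exhaustive global alignment of the query against every reference; the
#' entry with the highest identity wins, ties going to the lexicographically
#' smallest `ref_id`.
#'
#' @param query A DNA sequence.
#' @param db A [refdb()].
#' @return A list with `ref_id` and `identity`.
#' @export
top_hit_global <- function(query, db) {
  ids <- global_identity(db$seq, query)
  best <- which(ids == max(ids))
  best <- best[order(db$id[best])][1L] # db is id-sorted, but be explicit
  list(ref_id = db$id[best], identity = ids[best])
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' k-mer bootstrap classifier
#'
#' For each of `B` bootstrap iterations, `m` k-mers are drawn uniformly with
#' replacement from the query's k-mer set; each reference is scored by how
#' many drawn k-mers (with multiplicity) it shares, and the top-scoring
#' reference's lineage is recorded (ties to the smallest `ref_id`). The
#' candidate lineage is the modal winner's; confidence at a rank is the
#' fraction of bootstraps whose winner agrees with the candidate on all
#' ranks down to that one (hence non-increasing). The reported lineage is
#' truncated at the deepest rank with confidence >= `cutoff`.
#'
#' @param query A DNA sequence.
#' @param db A [refdb()].
#' @param k k-mer size (default 8).
#' @param m k-mers drawn per bootstrap (default 32).
#' @param B Number of bootstraps (default 100).
#' @param seed Integer seed (classification is deterministic given it).
#' @param cutoff Confidence cutoff for reporting (default 0.8).
#' @return A list with `ranks` (named 7-vector, `NA` below the cutoff
#'   depth), `conf` (named confidence vector over set ranks) and
#'   `method = "CLF"`.
#' @export
classify_kmer_bootstrap <- function(query, db, k = 8L, m = 32L, B = 100L,
                                    seed = 1L, cutoff = 0.8) {
  qk <- seq_kmers(query, k)
  if (!length(qk)) {
    return(list(ranks = empty_lineage(), conf = numeric(0), method = "CLF"))
  }
  # membership matrix: query k-mers x refs, via precomputed reference k-mer sets
  ref_sets <- lapply(db$seq, seq_kmers, k = k)
  M <- vapply(ref_sets, function(s) qk %in% s, logical(length(qk)))
  if (is.null(dim(M))) M <- matrix(M, ncol = nrow(db))
  winners <- integer(B)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      draw <- tabulate(sample.int(length(qk), m, replace = TRUE), nbins = length(qk))
      scores <- as.numeric(crossprod(M, draw))
      if (max(scores) == 0) { winners[b] <- NA_integer_; next }
      winners[b] <- which(scores == max(scores))[1L] # db id-sorted: smallest id
    }
  })
  if (all(is.na(winners))) {
    return(list(ranks = empty_lineage(), conf = numeric(0), method = "CLF"))
  }
  win_lin <- lapply(db$id[winners[!is.na(winners)]], db_lineage, db = db)
  modal_id <- names(sort(table(db$id[winners[!is.na(winners)]]), decreasing = TRUE))[1L]
  cand <- db_lineage(db, modal_id)
  conf <- numeric(0)
  agree <- rep(TRUE, length(win_lin))
  denom <- B
  ranks_out <- empty_lineage()
  for (r in seq_along(.tax_ranks)) {
    if (is.na(cand[r])) break
    agree <- agree & vapply(win_lin, function(l) identical(l[[r]], cand[[r]]), logical(1))
    cr <- sum(agree) / denom
    if (cr < cutoff) break
    ranks_out[r] <- cand[r]
    conf[.tax_ranks[r]] <- cr
  }
  list(ranks = ranks_out, conf = conf, method = "CLF")
}

#' Least common ancestor of two lineages
#'
#' The longest common prefix of the set ranks; confidences are dropped.
#'
#' @param a,b Lineages (named 7-vectors or lists with `$ranks`).
#' @return A list with `ranks`, `conf = numeric(0)`, `method = "LCA"`.
#' @export
lca <- function(a, b) {
  ra <- if (is.list(a)) as_lineage(a$ranks) else as_lineage(a)
  rb <- if (is.list(b)) as_lineage(b$ranks) else as_lineage(b)
  out <- empty_lineage()
  for (r in seq_along(.tax_ranks)) {
    if (is.na(ra[r]) || is.na(rb[r]) || ra[[r]] != rb[[r]]) break
    out[r] <- ra[r]
  }
  list(ranks = out, conf = numeric(0), method = "LCA")
}

lineages_disagree <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  any(a[both] != b[both])
}

#' Hybrid taxonomy assignment
#'
#' Combines the global-alignment top hit with the k-mer classifier:
#' identity strictly above 0.97 keeps the top hit's lineage (method `GA`);
#' otherwise the classifier's lineage is used (method `CLF`), unless the two
#' lineages disagree at a rank both have set, in which case their least
#' common ancestor is reported (method `LCA`).
#'
#' @param ga Output of [top_hit_global()] (list `ref_id`, `identity`).
#' @param clf Output of [classify_kmer_bootstrap()].
#' @param db The [refdb()] used for both.
#' @param ga_threshold Identity above which the top hit wins outright
#'   (strict `>`; default 0.97).
#' @return A list `ranks`, `conf`, `method` (one of `GA`, `CLF`, `LCA`).
#' @export
hybrid_assign <- function(ga, clf, db, ga_threshold = 0.97) {
  ga_lin <- db_lineage(db, ga$ref_id)
  if (ga$identity > ga_threshold) {
    return(list(ranks = ga_lin, conf = setNames(rep(ga$identity, sum(!is.na(ga_lin))),
                                                .tax_ranks[!is.na(ga_lin)]),
                method = "GA"))
  }
  if (lineages_disagree(ga_lin, clf$ranks)) {
    return(lca(ga_lin, clf$ranks))
  }
  list(ranks = clf$ranks, conf = clf$conf, method = "CLF")
}

#' Assign taxonomy to a set of OTUs
#'
#' Table-level driver running [top_hit_global()], [classify_kmer_bootstrap()]
#' and [hybrid_assign()] per centroid.
#'
#' @param otus Tibble with `otu_id` and `centroid` (or `seq`).
#' @param db A [refdb()].
#' @param seed Integer seed for the classifier.
#' @param ... Passed to [classify_kmer_bootstrap()].
#' @return A tibble: `otu_id`, `method`, `best_hit`, `identity`, the seven
#'   rank columns, and `confidence` (deepest reported rank's confidence).
#' @export
assign_taxonomy <- function(otus, db, seed = 1L, ...) {
  seq_col <- if ("centroid" %in% names(otus)) "centroid" else "seq"
  rows <- vector("list", nrow(otus))
  for (i in seq_len(nrow(otus))) {
    q <- otus[[seq_col]][i]
    ga <- top_hit_global(q, db)
    clf <- classify_kmer_bootstrap(q, db, seed = seed + i, ...)
    hy <- hybrid_assign(ga, clf, db)
    conf <- if (length(hy$conf)) unname(hy$conf[length(hy$conf)]) else NA_real_
    rows[[i]] <- dplyr::bind_cols(
      tibble(otu_id = otus$otu_id[i], method = hy$method,
             best_hit = ga$ref_id, identity = ga$identity),
      as_tibble(as.list(hy$ranks)),
      tibble(confidence = conf)
    )
  }
  bind_rows(rows)
}
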