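test_that("global identity handles identity, substitution and symmetric cases", {
  withr::local_seed(21)
  for (i in 1:10) {
    x <- random_dna(sample(10:60, 1))
    expect_equal(global_identity(x, x), 1.0)
  }
  expect_equal(global_identity("ACGTACGT", "ACGAACGT"), 7 / 8)
  expect_equal(global_identity("ACGTACGT", "ACGAACGT"),
               global_identity("ACGAACGT", "ACGTACGT"))
  expect_error(global_identity("", "ACGT"), "non-empty")
})

test_that("global identity matches a brute-force DP oracle on random pairs", {
  withr::local_seed(22)
  for (case in 1:250) {
    la <- sample(5:25, 1)
    a <- random_dna(la)
    b <- if (runif(1) < 0.5) random_dna(sample(5:25, 1)) else {
      mutate_subs(a, sample(0:4, 1))
    }
    oracle <- nw_oracle(a, b)
    got <- global_identity(a, b)
    # identity must be realized by some optimal-score alignment
    expect_true(any(abs(oracle$identities - got) < 1e-12),
                label = sprintf("identity %f in co-optimal set for %s / %s", got, a, b))
  }
})

test_that("dereplication preserves total abundance and sort order", {
  rd <- reads_tbl(id = c("a", "b", "c"), seq = c("AAA", "AAA", "CCC"))
  u <- dereplicate(rd)
  expect_equal(u$seq, c("AAA", "CCC"))
  expect_equal(u$size, c(2L, 1L))

  withr::local_seed(23)
  seqs <- replicate(50, random_dna(12))
  u2 <- dereplicate(tibble::tibble(seq = seqs))
  expect_equal(sum(u2$size), 50L)
  expect_true(all(diff(u2$size) <= 0))
  # ties broken lexicographically
  ties <- u2$size == 1
  expect_false(is.unsorted(u2$seq[ties]))
  # sizes match the truth multiset
  expect_equal(sort(u2$size), sort(as.integer(table(seqs))))
})

test_that("clustering joins above the 97% threshold and separates below it", {
  withr::local_seed(24)
  base <- random_dna(200)
  near <- mutate_subs(base, 2) # 99% identical
  u <- dereplicate(tibble::tibble(seq = rep(c(base, near), c(5, 3))))
  expect_equal(nrow(cluster_otus(u)), 1L)

  # boundary: 96% vs 97% divergence on length-100 sequences
  base100 <- random_dna(100)
  at97 <- mutate_subs(base100, 3) # identity 0.97 -> joins (inclusive)
  at96 <- mutate_subs(base100, 4) # identity 0.96 -> separate OTU
  u97 <- dereplicate(tibble::tibble(seq = rep(c(base100, at97), c(5, 3))))
  u96 <- dereplicate(tibble::tibble(seq = rep(c(base100, at96), c(5, 3))))
  expect_equal(nrow(cluster_otus(u97, chimera_check = FALSE)), 1L)
  expect_equal(nrow(cluster_otus(u96, chimera_check = FALSE)), 2L)

  expect_error(cluster_otus(u97, id_threshold = 0.4), "id_threshold")
})

test_that("min_size excludes singleton uniques from seeding OTUs", {
  withr::local_seed(25)
  a <- random_dna(150); b <- random_dna(150)
  u <- dereplicate(tibble::tibble(seq = c(rep(a, 5), b)))
  ot <- cluster_otus(u)
  expect_equal(nrow(ot), 1L)
  expect_equal(ot$centroid, a)
  # ...but the singleton's reads still count in the table by mapping
  tb <- map_reads_to_otus(tibble::tibble(id = "r", sample = "S1", seq = b, qual = NA), ot)
  expect_equal(sum(tb$S1), 0L) # b is unrelated to the centroid: dropped
  tb_a <- map_reads_to_otus(tibble::tibble(id = "r", sample = "S1", seq = a, qual = NA), ot)
  expect_equal(tb_a$S1, 1L)
})

test_that("abundant error-free reads from divergent references give one OTU each", {
  sm <- synmock_its2()
  reads <- tibble::tibble(seq = rep(sm$seq, each = 5))
  ot <- cluster_otus(dereplicate(reads))
  expect_equal(nrow(ot), nrow(sm)) # all 12 recovered
  expect_setequal(ot$centroid, sm$seq)
})

test_that("reads at 1% error still recover all references as centroids", {
  withr::local_seed(26)
  refs <- random_refs(20, sample(150:300, 20, replace = TRUE))
  reads <- list()
  for (i in seq_len(nrow(refs))) {
    n_err <- rbinom(120, nchar(refs$seq[i]), 0.01)
    reads[[i]] <- tibble::tibble(
      seq = vapply(n_err, function(k) mutate_subs(refs$seq[i], k), character(1))
    )
  }
  ot <- cluster_otus(dereplicate(dplyr::bind_rows(reads)))
  expect_equal(nrow(ot), 20L)
  best <- vapply(ot$centroid, function(cent) {
    max(vapply(refs$seq, function(r) global_identity(cent, r), numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.99))
})

test_that("two-parent chimeras are flagged, real sequences are not", {
  sm <- synmock_its2()
  cents <- sm$seq
  expect_false(flag_chimera(cents[1], cents))
  withr::local_seed(27)
  n_flag <- 0
  for (i in 1:50) {
    ab <- sample(nrow(sm), 2)
    a <- cents[ab[1]]; b <- cents[ab[2]]
    chim <- paste0(substr(a, 1, nchar(a) %/% 2),
                   substr(b, nchar(b) %/% 2 + 1, nchar(b)))
    if (flag_chimera(chim, cents)) n_flag <- n_flag + 1
  }
  expect_gte(n_flag / 50, 0.9)
})

test_that("read mapping reproduces simulation truth and drops sub-threshold reads", {
  sm <- synmock_its2()
  comp <- stats::setNames(rep(1 / nrow(sm), nrow(sm)), sm$id)
  spec <- run_spec(sm, samples = list(S1 = comp, S2 = comp),
                   reads_per_sample = 400, seed = 99)
  run <- simulate_run(spec)
  dm <- demux_single(run$reads, run$sheet, max_len = 400)
  ot <- cluster_otus(dereplicate(filter_by_ee(dm$reads)))
  tb <- map_reads_to_otus(dm$reads, ot)
  truth <- truth_count_table(run$truth)
  # align truth template names to centroid OTU ids through exact sequences
  ref_of_otu <- sm$id[match(ot$centroid, sm$seq)]
  tb$otu_id <- ref_of_otu
  expect_tables_equal(tb, truth)

  # a read at ~96% identity to its nearest centroid is not counted
  far <- mutate_subs(ot$centroid[1], ceiling(0.04 * nchar(ot$centroid[1])))
  tb2 <- map_reads_to_otus(
    tibble::tibble(id = "far", sample = "S1", seq = far, qual = NA), ot,
    samples = c("S1")
  )
  expect_equal(sum(tb2$S1), 0L)

  # empty read set -> all-zero table with the requested samples
  tb3 <- map_reads_to_otus(tibble::tibble(id = character(), sample = character(),
                                          seq = character(), qual = character()),
                           ot, samples = c("S1", "S2"))
  expect_equal(names(tb3), c("otu_id", "S1", "S2"))
  expect_equal(sum(as.matrix(tb3[-1])), 0L)

  expect_error(map_reads_to_otus(tibble::tibble(id = "x", sample = NA_character_,
                                                seq = "ACGT", qual = NA), ot),
               "sample label")
})

test_that("rarefaction is exact, deterministic and hypergeometric in expectation", {
  tb <- tibble::tibble(otu_id = paste0("OTU_", 1:3),
                       S1 = c(60L, 30L, 10L), S2 = c(5L, 3L, 2L), S3 = c(50L, 0L, 0L))
  expect_message(r1 <- rarefy(tb, 50, seed = 1), "dropping")
  expect_false("S2" %in% names(r1))
  expect_true(all(colSums(as.matrix(r1[-1])) == 50))
  # column already at depth is unchanged
  expect_equal(r1$S3, c(50L, 0L, 0L))
  # deterministic given seed
  expect_equal(rarefy(tb, 50, seed = 1), r1)
  expect_false(isTRUE(all.equal(rarefy(tb, 50, seed = 2)$S1, r1$S1)) &&
                 isTRUE(all.equal(rarefy(tb, 50, seed = 3)$S1, r1$S1)))

  # expectation: OTU at fraction p keeps ~ p * depth (hypergeometric mean)
  one_col <- tb[, c("otu_id", "S1")]
  means <- rowMeans(vapply(1:200, function(s) rarefy(one_col, 50, seed = s)$S1,
                           numeric(3)))
  p <- c(60, 30, 10) / 100
  se <- sqrt(50 * p * (1 - p) * (100 - 50) / (100 - 1)) / sqrt(200)
  expect_true(all(abs(means - 50 * p) <= 3 * se + 1e-9))
})

test_that("OTU table column sums never exceed demultiplexed read counts", {
  sm <- synmock_its2()
  comp <- stats::setNames(rep(1 / nrow(sm), nrow(sm)), sm$id)
  spec <- run_spec(sm, samples = list(S1 = comp, S2 = comp),
                   reads_per_sample = 200, sub_rate = 0.01, seed = 5)
  run <- simulate_run(spec)
  dm <- demux_single(run$reads, run$sheet, max_len = 400)
  ot <- cluster_otus(dereplicate(filter_by_ee(dm$reads)))
  tb <- map_reads_to_otus(dm$reads, ot)
  demux_counts <- table(dm$reads$sample)
  for (s in names(demux_counts)) {
    expect_lte(sum(tb[[s]]), as.integer(demux_counts[[s]]))
  }
})
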