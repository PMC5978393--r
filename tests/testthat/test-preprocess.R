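p_fwd <- its_primers()[["fITS7"]] # GTGARTCATCGAATCTTTG
p_rev <- its_primers()[["ITS4"]]

test_that("find_primer locates exact and mismatched sites within tolerance", {
  insert <- "TTTTACACACGTGTGTTTTTACGGATCC"
  read <- paste0("GTGAATCATCGAATCTTTG", insert)
  hit <- find_primer(read, p_fwd, 2)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 19L)
  expect_equal(hit$edits, 0L)

  # 2 substitutions in the primer site: found at edits = 2
  mut <- paste0("GTGAATCATGGAATCTTAG", insert)
  hit2 <- find_primer(mut, p_fwd, 2)
  expect_equal(hit2$edits, 2L)
  # 3 substitutions: no hit at max_edits = 2
  mut3 <- paste0("GTGAATCTTGGAATCTTAG", insert)
  expect_null(find_primer(mut3, p_fwd, 2))

  expect_error(find_primer(read, ""), "empty primer")
})

test_that("find_primer agrees with a brute-force semi-global DP oracle", {
  withr::local_seed(202)
  n_found <- 0
  for (case in 1:500) {
    read <- random_dna(30)
    primer <- if (runif(1) < 0.5) random_dna(15) else {
      # plant the primer with 0-3 edits so hits actually occur
      pr <- random_dna(15)
      pl <- mutate_subs(pr, sample(0:3, 1))
      pos <- sample(1:15, 1)
      substr(read, pos, pos + 14) <- pl
      pr
    }
    oracle_min <- semiglobal_edits_oracle(read, primer)
    hit <- find_primer(read, primer, max_edits = 2)
    if (oracle_min <= 2) {
      expect_false(is.null(hit))
      expect_equal(hit$edits, oracle_min)
      # the reported window really is at the reported edit distance
      win <- substr(read, hit$start, hit$end)
      expect_equal(semiglobal_edits_oracle(win, primer), hit$edits)
      n_found <- n_found + 1
    } else {
      expect_null(hit)
    }
  }
  expect_gt(n_found, 100) # the planted cases must actually exercise hits
})

make_perfect_read <- function(barcode, insert, fwd = "GTGAATCATCGAATCTTTG",
                              rev = p_rev) {
  paste0(barcode, fwd, insert, mycoamp::revcomp(rev))
}

demo_sheet <- function() {
  sample_sheet(
    tibble::tibble(sample = c("S1", "S2"),
                   fwd_barcode = c("ACGAGTGCGT", "ACGCTCGACA"),
                   rev_barcode = NA, i5 = NA, i7 = NA),
    fwd_primer = p_fwd, rev_primer = p_rev
  )
}

test_that("demultiplexing enforces the 0-mismatch barcode default", {
  withr::local_seed(7)
  insert <- random_dna(120)
  sheet <- demo_sheet()
  perfect <- reads_tbl(id = "ok", seq = make_perfect_read("ACGAGTGCGT", insert))
  res <- demux_single(perfect, sheet)
  expect_equal(res$reads$sample, "S1")
  expect_equal(res$reads$seq, insert)
  expect_true(res$reads$rev_primer_found)

  # one barcode error -> rejected at the default 0 tolerance
  bc_err <- reads_tbl(id = "bad", seq = make_perfect_read("TCGAGTGCGT", insert))
  res2 <- demux_single(bc_err, sheet)
  expect_equal(nrow(res2$reads), 0L)
  expect_equal(res2$stats$reads[res2$stats$name == "no_barcode"], 1L)
  # ...but kept when one edit is allowed
  res3 <- demux_single(bc_err, sheet, barcode_edits = 1L)
  expect_equal(res3$reads$sample, "S1")

  # equal-distance tie between barcodes -> ambiguous
  sheet_tie <- sample_sheet(
    tibble::tibble(sample = c("A", "B"),
                   fwd_barcode = c("AAAAAAAAAA", "AAAAAAAAAT"),
                   rev_barcode = NA, i5 = NA, i7 = NA),
    fwd_primer = p_fwd, rev_primer = p_rev
  )
  tie_read <- reads_tbl(id = "t", seq = make_perfect_read("AAAAAAAAAC", insert))
  res4 <- demux_single(tie_read, sheet_tie, barcode_edits = 1L)
  expect_equal(res4$stats$reads[res4$stats$name == "ambiguous_barcode"], 1L)
})

test_that("demultiplexing enforces the 2-edit primer default at the boundary", {
  withr::local_seed(8)
  insert <- random_dna(120)
  sheet <- demo_sheet()
  for (edits in 0:3) {
    fwd <- mutate_subs("GTGAATCATCGAATCTTTG", edits)
    # avoid edits that happen to fall on the IUPAC R position making them free
    rd <- reads_tbl(id = "x", seq = make_perfect_read("ACGAGTGCGT", insert, fwd = fwd))
    res <- demux_single(rd, sheet)
    oracle <- semiglobal_edits_oracle(fwd, p_fwd)
    if (oracle <= 2) {
      expect_equal(nrow(res$reads), 1L)
    } else {
      expect_equal(res$stats$reads[res$stats$name == "no_fwd_primer"], 1L)
    }
  }
})

test_that("demultiplexing conserves reads and matches simulation truth", {
  sm <- synmock_its2()
  comp <- stats::setNames(rep(1 / nrow(sm), nrow(sm)), sm$id)
  spec <- run_spec(sm, samples = list(S1 = comp, S2 = comp, S3 = comp),
                   reads_per_sample = 300, seed = 41)
  run <- simulate_run(spec)
  res <- demux_single(run$reads, run$sheet)
  total <- sum(res$stats$reads)
  expect_equal(total, nrow(run$reads))
  truth_kept <- table(run$truth$per_read$observed_sample)
  kept <- res$stats[res$stats$category == "kept", ]
  expect_equal(stats::setNames(kept$reads, kept$name),
               stats::setNames(as.integer(truth_kept), names(truth_kept)))
})

test_that("lossless trimming truncates long reads and keeps short ones with a reverse primer", {
  long <- reads_tbl(id = "a", seq = random_dna(550))
  out <- trim_lossless(long, 300, rev_primer_found = FALSE)
  expect_equal(nchar(out$seq), 300L)
  expect_equal(out$seq, substr(long$seq, 1, 300)) # lossless: retained bases unaltered

  short <- reads_tbl(id = "b", seq = random_dna(161))
  expect_equal(trim_lossless(short, 300, TRUE)$seq, short$seq)
  expect_null(trim_lossless(short, 300, FALSE))
  expect_error(trim_lossless(short, 0, TRUE), "positive")
})

test_that("padding pads with 3' Ns and truncation recovers the prefix", {
  expect_equal(pad_to_length("ACGT", 6), "ACGTNN")
  expect_equal(pad_to_length("ACGTACGT", 6), "ACGTAC")
  withr::local_seed(5)
  for (i in 1:20) {
    x <- random_dna(sample(1:40, 1))
    padded <- pad_to_length(x, 40)
    expect_equal(nchar(padded), 40L)
    expect_equal(sub("N+$", "", padded), sub("N+$", "", x))
  }
})

test_that("paired-end merging takes the best overlap and consensus quality", {
  f <- reads_tbl(id = "p", seq = "AAAACCCC", qual = "IIIIIIII")
  r <- reads_tbl(id = "p", seq = revcomp("CCCCGGGG"), qual = "IIIIIIII")
  m <- merge_pairs(f, r, min_overlap = 4)
  expect_equal(m$seq, "AAAACCCCGGGG")

  # identical full-length pair merges to itself
  x <- reads_tbl(id = "q", seq = random_dna(60), qual = strrep("I", 60))
  xr <- reads_tbl(id = "q", seq = revcomp(x$seq), qual = strrep("I", 60))
  expect_equal(merge_pairs(x, xr)$seq, x$seq)

  # disagreement resolved toward the higher-quality base, max quality kept
  base <- random_dna(60)
  rseq <- base
  substr(rseq, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(base, 30, 30))[1]
  f2 <- reads_tbl(id = "d", seq = base, qual = int_to_qual(rep(20, 60)))
  r2 <- reads_tbl(id = "d", seq = revcomp(rseq), qual = int_to_qual(rep(35, 60)))
  m2 <- merge_pairs(f2, r2)
  expect_equal(substr(m2$seq, 30, 30), substr(rseq, 30, 30))
  expect_equal(qual_to_int(m2$qual)[30], 35)
})

test_that("simulated read pairs from 220 bp templates merge at high rate", {
  withr::local_seed(33)
  n_ok <- 0; n_exact_len <- 0; n_errorfree <- 0; n_errorfree_len <- 0
  for (i in 1:60) {
    tpl <- random_dna(220)
    fwd <- substr(tpl, 1, 150)
    rev <- revcomp(substr(tpl, 71, 220))
    nf <- rbinom(1, 150, 0.005); nr <- rbinom(1, 150, 0.005)
    f <- reads_tbl(id = "m", seq = mutate_subs(fwd, nf), qual = strrep("I", 150))
    r <- reads_tbl(id = "m", seq = mutate_subs(rev, nr), qual = strrep("I", 150))
    m <- merge_pairs(f, r)
    if (!is.null(m)) n_ok <- n_ok + 1
    if (nf + nr == 0) {
      n_errorfree <- n_errorfree + 1
      if (!is.null(m) && nchar(m$seq) == 220) n_errorfree_len <- n_errorfree_len + 1
    }
  }
  expect_gte(n_ok / 60, 0.95)
  expect_equal(n_errorfree_len, n_errorfree) # error-free pairs merge to truth length
})

test_that("expected errors follow the Phred closed form and a summation oracle", {
  expect_equal(expected_errors(int_to_qual(rep(20, 100))), 1.0)
  expect_equal(expected_errors(int_to_qual(rep(40, 250))), 0.025)
  withr::local_seed(12)
  for (i in 1:50) {
    q <- sample(0:41, sample(10:300, 1), replace = TRUE)
    expect_equal(expected_errors(int_to_qual(q)), sum(10^(-q / 10)), tolerance = 1e-9)
  }
  # monotone non-increasing in any single quality value
  q <- sample(5:35, 50, replace = TRUE)
  ee0 <- expected_errors(int_to_qual(q))
  q[25] <- q[25] + 5
  expect_lt(expected_errors(int_to_qual(q)), ee0)
})

test_that("EE filtering drops high-error reads but demux counting never uses it", {
  reads <- reads_tbl(id = c("good", "bad"), seq = c(strrep("A", 100), strrep("A", 100)),
                     qual = c(int_to_qual(rep(40, 100)), int_to_qual(rep(10, 100))))
  kept <- filter_by_ee(reads, 1.0)
  expect_equal(kept$id, "good")
})
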