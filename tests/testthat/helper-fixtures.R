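# Shared fixtures built once per test run: the default SynMock design, its
# ITS2 amplicon regions (the usual sequencing template), and a tiny
# taxonomy database.

synmock_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- mycoamp::design_synmock()
    }
    val
  }
})

synmock_its2 <- function() {
  sm <- synmock_fixture()
  p <- mycoamp::its_primers()
  mycoamp::extract_subregion(sm, p[["fITS7"]], p[["ITS4"]])
}

# n well-separated random references (pairwise identity upper-bounded by
# construction: distinct random sequences of the given lengths).
random_refs <- function(n, lens, prefix = "ref") {
  mycoamp::reads_tbl(
    id = sprintf("%s%02d", prefix, seq_len(n)),
    seq = vapply(lens, random_dna, character(1))
  )
}

# small taxonomy db: n_genera genera x n_sp species, random 200 bp sequences
make_test_db <- function(n_genera = 5, n_sp = 2, len = 200, seed = 11) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_genera)) for (s in seq_len(n_sp)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("REF_%02d_%02d", g, s),
        seq = random_dna(len),
        kingdom = "Fungi", phylum = paste0("Phylum", (g - 1) %/% 3 + 1),
        class = paste0("Class", (g - 1) %/% 2 + 1),
        order = paste0("Order", g), family = paste0("Family", g),
        genus = paste0("Genus", g), species = sprintf("Genus%d sp%d", g, s)
      )
    }
    mycoamp::refdb(dplyr::bind_rows(rows))
  })
}

# hand-built OTU table with known bleed structure: 3 mock OTUs + 2
# environmental OTUs across the mock sample and 3 others
bleed_table <- function() {
  tibble::tibble(
    otu_id = c("M1", "M2", "M3", "E1", "E2"),
    SynMock = c(400L, 300L, 295L, 3L, 2L),
    S1 = c(2L, 0L, 1L, 5000L, 800L),
    S2 = c(1L, 0L, 0L, 200L, 7000L),
    S3 = c(1L, 0L, 0L, 900L, 4000L)
  )
}

fake_mock_map <- function() {
  tibble::tibble(
    otu_id = c("M1", "M2", "M3", "E1", "E2"),
    class = c("mock_hit", "mock_hit", "mock_hit", "non_mock", "non_mock"),
    best_ref = c("r1", "r2", "r3", "r1", "r2"),
    identity = c(1, 1, 1, 0.5, 0.5),
    mismatches = c(0L, 0L, 0L, 200L, 200L), aligned_bp = rep(400L, 5)
  )
}

expect_tables_equal <- function(a, b) {
  a <- a[order(a$otu_id), c("otu_id", sort(setdiff(names(a), "otu_id")))]
  b <- b[order(b$otu_id), c("otu_id", sort(setdiff(names(b), "otu_id")))]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
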