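# mycoamp

Processing, spike-in calibration and taxonomy of variable-length fungal ITS
amplicons, in R.

## The problem

Metabarcoding of the fungal rRNA internal transcribed spacer (ITS) breaks
two assumptions that 16S-oriented pipelines rely on. First, ITS1/ITS2
amplicons vary widely in length, so the common "truncate to L, discard
shorter" pre-processing step silently deletes real short taxa from the
community. Second, a small fraction of reads carries the wrong sample
barcode ("tag-switching" / "index bleed"), inflating apparent diversity —
especially damaging because amplicon read counts are a poor proxy for
abundance, pushing analyses toward presence/absence metrics where every
spurious cell counts.

mycoamp is a self-contained toolkit for mycobiome researchers that
addresses both:

* **lossless pre-processing** — anchored barcode demultiplexing (0
  mismatches by default), primer removal at ≤ 2 edits, and lossless
  trimming: reads longer than `max_len` (default 300 bp) are truncated,
  shorter reads are kept whenever their reverse primer was found; padding
  and hard-truncation modes are provided for comparison;
* **greedy centroid OTU clustering at 97% identity** (Needleman–Wunsch
  global alignment, terminal gaps penalized), with the OTU table counted
  from the *pre-quality-filter* demultiplexed reads so expected-error
  filtering never distorts abundances;
* **spike-in calibrated tag-switch filtering** — OTUs are mapped to a mock
  community reference, the switching rate is measured both into and out of
  the spike-in sample, and per-OTU, every table cell below
  `ceiling(rate × OTU total)` is zeroed (cells above are untouched, so
  low-abundance OTUs are never dropped wholesale);
* **hybrid taxonomy** — global-alignment top hit (> 97% identity wins), a
  k-mer bootstrap classifier otherwise, and a least-common-ancestor
  fallback on disagreement;
* a **SynMock designer** that generates non-biological ITS-like spike-in
  sequences (real ITS1-F/ITS1/ITS2/ITS3/fITS7/ITS4 priming sites around
  random, GC/length/homopolymer-constrained variable regions) — sequences
  that behave like ITS amplicons but cannot occur in nature, making
  tag-switching measurable;
* a **sequencing-run simulator** (PCR bias, substitution and homopolymer
  indel errors, barcode scaffolds, injected tag-switching) with per-read
  truth, so the whole chain is testable end to end.

Everything is tidyverse-native: reads, OTU tables, mock maps and truth
tables are tibbles; results chain with the pipe; `tidy()`/`glance()` and
`autoplot()` methods cover the fitted objects.

## Worked example

Design a spike-in, simulate a small run with 0.5% injected tag-switching,
process it, and filter the table:

```r
library(mycoamp)

sm   <- design_synmock()                    # 12 non-biological members
p    <- its_primers()
mock <- extract_subregion(sm, p[["fITS7"]], p[["ITS4"]])  # ITS2 amplicons

# six synthetic "environmental" templates, 200-330 bp
set.seed(10)
env <- reads_tbl(id = sprintf("env%02d", 1:6),
                 seq = vapply(as.integer(seq(200, 330, length.out = 6)),
                              function(L) paste(sample(c("A", "C", "G", "T"),
                                                       L, TRUE), collapse = ""),
                              character(1)))

# simulate: SynMock sample + two environmental samples, 5000 reads each
comp_mock <- setNames(rep(1/12, 12), mock$id)
spec <- run_spec(dplyr::bind_rows(mock, env), samples = list(
          SynMock = comp_mock,
          S1 = setNames(rep(1/3, 3), env$id[1:3]),
          S2 = setNames(rep(1/3, 3), env$id[4:6])),
        reads_per_sample = 5000, bleed_rate = 0.005, seed = 42)
run <- simulate_run(spec)

dm   <- demux_single(run$reads, run$sheet, max_len = 400)
otus <- cluster_otus(dereplicate(filter_by_ee(dm$reads)))
tab  <- map_reads_to_otus(dm$reads, otus)   # pre-filter reads are counted
mm   <- map_otus_to_mock(otus, mock)
est  <- estimate_bleed(tab, "SynMock", mm)
est
#> Tag-switching estimate (mock sample 'SynMock')
#>   into mock : 0.5196% (26 / 5004 reads)
#>   out of mock: 0.4400% (22 / 5000 reads)
#>   applied    : 0.5196% (combine = max)

filt <- filter_table(tab, est$applied, mock_map = mm, mock_sample = "SynMock")
```

The run recovers 18 OTUs, 12 of them mock hits at a 0.000% mock error rate;
the estimate re-measures the injected 0.5% switching as 0.52% into and
0.44% out of the spike-in, and the filtered table keeps the 6 environmental
OTUs across the 2 environmental samples with the bleed-range cells zeroed
and the mock rows/column removed. `glance(est)` returns the same rates as a
one-row tibble, and `autoplot(est)`, `plot_otu_heatmap(tab)` and
`plot_length_distribution(sm)` give quick ggplot views.

A thin command-line wrapper over the same functions ships in
`inst/cli/mycoamp.R` with subcommands `demux`, `cluster`, `filter`,
`taxonomy`, `synmock`, `simulate`, `hp`, `extract`, `lenstats` and `run`.

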