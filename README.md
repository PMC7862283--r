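# larvalstate

Quantitative pipeline for studying **lethargy-like behavior and delayed
emergence from anesthesia in larval zebrafish**, for behavioral
neuroscientists and zebrafish pharmacogenetics labs. The package covers
the full chain from raw lane videos to statistics:

* **Tracking** — background-subtraction centroid tracking of larvae in
  lanes, with the background (per-pixel median) re-estimated every ~1000
  frames to cancel slow environmental drift.
* **Bout analysis** — hysteresis segmentation of trajectories into swim
  bouts and dwell intervals (the lethargy readout is the dwell-time
  distribution), plus lap-swimming amplitude/period/duration and
  temporal clustering of laps.
* **Dose-response** — scoring of three behavioral endpoints (spontaneous
  swimming in light, visual-motor response to a dark transition, tap
  response), baseline normalization and constrained four-parameter
  logistic fits:
  `y = bottom + (top − bottom) / (1 + 10^((logEC50 − log10 d)·hill))`,
  with the Hill slope bounded and EC50 = 10^logEC50.
* **Emergence** — checkpointed post-washout response tables to
  first-passage emergence times (5-min grid, right-censoring), compared
  by Kruskal–Wallis + Dunn and by Kaplan–Meier + log-rank.
* **Statistics** — self-contained tie-corrected implementations of every
  procedure above (exact/normal Mann–Whitney U, Kruskal–Wallis H, Dunn
  z, product-limit estimator, k-group log-rank, Benjamini–Hochberg FDR,
  Type-II two-way ANOVA with Šidák contrasts), each unit-tested against
  an independent oracle.
* **Activity mapping** — voxel-wise comparison of registered pERK/tERK
  ratio stacks between fish groups via Mann–Whitney Z scores, FDR (or
  fixed p = 5×10⁻⁵) thresholding, signed median-difference rendering
  (0–65535, saturating at 60% of the maximum), and per-ROI
  genotype × condition summaries.
* **Synthetic data** — seeded generators for every input above
  (renewal-process trajectories, rendered videos with background drift,
  binomial dose-response counts, censored emergence tables, stack pairs
  with planted ROI effects), so the whole pipeline is testable without
  any recordings.

## Worked example

Simulate six 30-min lane recordings per genotype, segment bouts, and
compare dwell times; then analyze a simulated emergence experiment:

```r
library(larvalstate)
presets <- genotypePresets()
sib <- unlist(lapply(1:6, function(i) dwellTimes(segmentBouts(
  simulateTrajectory(presets$sibling, 1800, 65, seed = 100 + i)))))
mut <- unlist(lapply(1:6, function(i) dwellTimes(segmentBouts(
  simulateTrajectory(presets$glyt1, 1800, 65, seed = 200 + i)))))
distributionSummary(sib)[c("n", "median", "iqr")]
#> sibling dwells: n=1251 median=5.0 s IQR=[2.6, 10.0]
#> mutant  dwells: n=646  median=9.8 s IQR=[4.6, 19.6]
mannWhitney(sib, mut, mode = "normal")
#> U = 2.702e+05, z = -11.84, p = 2.352e-32 (n = 1251/646, tie-corrected)

rec <- simulateEmergenceTimes(c(wt = 30, het = 30, mut = 60),
                              nPerGroup = 20, seed = 5)
ce <- compareEmergence(rec)
ce$summary
#>          H          kwP comparison meanRankDiff        dunnP
#> 1 42.12328 7.129267e-10 het vs mut      -26.000 5.975419e-06
#> 2 42.12328 7.129267e-10  het vs wt        7.925 4.419012e-01
#> 3 42.12328 7.129267e-10  mut vs wt       33.925 1.657821e-09
ce$logRank[c("chisq", "df", "p")]
#> log-rank chi2 = 57.7 (df 2), p = 3.01e-13
```

The mutant preset initiates bouts half as often (dwell median ~10 s vs
~5 s; bout sizes identical by construction), and the planted 2× emergence
delay is picked up by both the rank tests and the failure-time analysis —
the mutant-vs-wildtype mean-rank difference (33.9 of a possible ~30–40)
reflects near-complete separation of the two groups, while the
heterozygote is indistinguishable from wild type.

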