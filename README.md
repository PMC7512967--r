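# rrsampen

Sample Entropy and time-domain analysis of RR-interval (inter-beat) series.

Heart-rate variability work usually summarizes an RR recording by its level
(av-RR, the mean interval in ms) and its variability (SDNN, the standard
deviation in ms). Those two numbers miss a third dimension — how
*predictable* the fluctuations are. Sample Entropy (SampEn) measures that
irregularity: for templates of length `m` that match within a tolerance `r`
(Chebyshev distance, self-matches excluded),

```
SampEn(m, r, N) = -ln( A / B )
```

where `B` counts template pairs similar for `m` points and `A` counts those
that remain similar at point `m + 1`. Low SampEn means a regular,
predictable rhythm; high SampEn means erratic beat-to-beat dynamics. The
package uses the short-recording conventions `m = 2` and
`r = 0.5 × SDNN of the analyzed segment`, which keep the estimator stable
on segments of a few hundred beats while preserving the ordering of
processes with different degrees of order.

`rrsampen` provides the full analysis chain for psychophysiology-style HRV
studies:

* **I/O** — plain RR text (one ms value per line, `#` comments) and
  delimited tables (`rr_ms` plus optional `subject`/`condition` columns):
  `read_rr()`, `write_rr()`.
* **Artifact screening** — relative-jump rule
  `|RR_i − RR_{i−1}| ≥ 0.7 × RR_{i−1}` with a whole-sequence rejection
  policy: `detect_artifacts()`, `is_clean()`, `drop_artifacts()`.
* **Indexes** — `av_rr()`, `sdnn()`, `sample_entropy()`,
  `approximate_entropy()`, `hrv_summary()`.
* **Segmentation** — fixed 5-minute sections (`hrv_by_segment()`) and
  100-beat windows shifted by 10 (`hrv_by_window()`).
* **Synthetic RR generators** — AR(1), MIX(p), respiratory sinus
  arrhythmia, artifact injection, and calibrated multi-subject experiment
  designs: `gen_ar1_rr()`, `gen_mix_rr()`, `gen_rsa_rr()`,
  `inject_artifacts()`, `gen_experiment()`, `experiment_presets()`.
* **Comparison workflow** — Shapiro–Wilk-gated routing to Wilcoxon /
  Mann–Whitney / t-tests, Friedman trend tests, Spearman correlation, and
  publication-shaped report tables: `compare_paired()`,
  `repeated_trend()`, `experiment_report()`.

A thin command-line wrapper (`rr_cli()`, launcher in `inst/cli/rrsampen`)
exposes `simulate`, `filter`, `entropy`, `window`, `segment` and `compare`
subcommands over the same functions.

## Worked example

Simulate a resting-style recording, summarize it, then emulate a paired
two-condition experiment (n = 29 subjects; SampEn targets 1.12 vs 1.30
with identical level and variance) and run the paired report:

```r
library(rrsampen)

s <- gen_ar1_rr(300, mean_rr = 800, sd_rr = 50, phi = 0.6, seed = 42)
hrv_summary(s)
#>   n_beats av_rr_ms  sdnn_ms   sampen     r_ms
#> 1     300 797.8617 46.84024 1.154779 23.42012

exp  <- gen_experiment(experiment_presets("language_paired"), seed = 42)
summ <- summarize_experiment(exp)
rep  <- experiment_report(summ, "paired")
rep$tests
#>      index        comparison            test statistic     z  p_value  n significant
#> 1   sampen native vs foreign wilcoxon_paired    12.000 4.444 2.61e-07 29        TRUE
#> 2 av_rr_ms native vs foreign    ttest_paired    -0.326    NA 7.47e-01 29       FALSE
#> 3  sdnn_ms native vs foreign wilcoxon_paired   186.000 0.681 5.08e-01 29       FALSE
```

The report shows the dissociation the irregularity index is designed to
capture: SampEn separates the two conditions decisively (Wilcoxon
matched-pairs T = 12, Z = 4.44, p < 0.001) while the level (av-RR) and
variability (SDNN) comparisons stay null — the conditions differ in how
*predictable* the rhythm is, not in how fast or how variable. In
`rep$descriptives`, indexes routed nonparametrically carry median/Q1/Q3
and the parametric branch carries mean ± SE.

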