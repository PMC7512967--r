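---
title: "Quantifying heart-rate irregularity with rrsampen: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heart-rate irregularity with rrsampen: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsampen)
```

## The problem

The interval between consecutive heartbeats (the RR interval, in
milliseconds) fluctuates continuously. Classical heart-rate-variability
(HRV) indexes summarize the *level* (av-RR, the mean interval) and the
*amount* of fluctuation (SDNN, the standard deviation), but two recordings
with identical SDNN can differ dramatically in how *predictable* their
fluctuations are: a deep, breathing-locked oscillation is large but
regular, while the same variance spread over erratic beat-to-beat changes
is irregular. Sample Entropy (SampEn) quantifies this irregularity
dimension, and a growing psychophysiology literature uses it to track
states — stress, alcohol, task demands, the onset of learning — that move
irregularity without necessarily moving level or variance.

`rrsampen` implements that analysis chain as a tested pipeline: RR input
and validation, artifact screening, time-domain indexes, Sample Entropy
with the tolerance conventions used in short-recording work, two
segmentation schemes (fixed 5-minute sections and 100-beat sliding
windows), seedable synthetic RR generators, and a normality-gated
nonparametric comparison workflow.

## Sample Entropy

For a series $x_1,\dots,x_N$, embed templates of length $m$,
$\mathbf{x}_m(i) = (x_i,\dots,x_{i+m-1})$, and call two templates similar
when their Chebyshev distance is at most $r$. Over unordered pairs
$i<j$ with $i,j \in \{1,\dots,N-m\}$ let $B$ be the number of similar
length-$m$ pairs and $A$ the number of those pairs that remain similar
when both templates are extended to length $m+1$. Then

$$\mathrm{SampEn}(m, r, N) = -\ln\frac{A}{B},$$

the negative log of the conditional probability that sequences similar for
$m$ points remain similar at the next point. Self-matches are excluded
(that is what distinguishes SampEn from Approximate Entropy and removes
most of ApEn's regularity bias); `approximate_entropy()` is provided for
cross-metric comparisons. Conventions fixed in this implementation:

* **Template range.** Both counts range over the $N-m$ templates that
  possess an $(m{+}1)$-th extension, which makes $A \le B$ — and hence
  $\mathrm{SampEn} \ge 0$ — structural rather than accidental.
* **Distance and comparison.** Chebyshev (max-norm) distance with
  non-strict inequality $d \le r$, the standard choice.
* **Undefined values.** If $B = 0$ or $A = 0$ the conditional probability
  is undefined. `sample_entropy()` returns `NA` carrying the counts and a
  reason attribute; segment tables report missingness instead of
  infinities.
* **Counting core.** An O(N²m) pair scan in C++; the test suite proves it
  exactly equal to an independent brute-force double-loop oracle over
  random series, and equal to `pracma::sample_entropy` on shared
  parameter settings.

### Tolerance

The tolerance is `r = r_coeff × SDNN` of the **exact segment being
analyzed** (default `r_coeff = 0.5`, `m = 2`). Two consequences matter:

* **Scale invariance.** Because $r$ scales with the segment's SDNN,
  SampEn is invariant to rescaling the series — verified exactly in the
  tests for power-of-two scalings.
* **Variance vs. discrimination.** `r = 0.5 × SDNN` yields markedly lower
  estimator dispersion on short segments than the more common
  `0.2 × SDNN`, at some cost in discrimination. The ordering of processes
  with different degrees of order is preserved across both choices
  (*relative consistency*); the acceptance suite demonstrates this on
  MIX processes at both tolerances.

Per-window analyses resolve `r` from each window's own SDNN; an absolute
tolerance (`r_mode = "absolute"`) is available when a session-level `r` is
preferred. A constant segment has SDNN 0 and therefore no usable
fractional tolerance; that is an error by design, not a zero.

For i.i.d. data the conditional match probability is independent of $m$
and SampEn tends to $-\ln P(|X - X'| \le r)$. Two closed forms anchor the
estimator in the tests: Gaussian data at $r = 0.5\sigma$ give
$-\ln\!\left(2\Phi(0.5/\sqrt{2}) - 1\right) \approx 1.2862$, and uniform
noise gives $-\ln\!\left(1 - (1 - r/(2\sqrt{3}\sigma))^2\right) \approx
1.3174$.

## Artifact screening

Ectopic beats, coughs and motion artifacts appear as abrupt relative jumps
between successive intervals. The default screen flags beat $i$ ($i \ge
2$; the first beat has no predecessor and is never flagged) when

$$|RR_i - RR_{i-1}| \ge c \cdot RR_{i-1}, \qquad c = 0.7 .$$

The local-level reference is the *preceding* interval, deliberately
excluding the tested beat: a symmetric variant that references the pair
mean $(RR_i + RR_{i-1})/2$ lets a large artifact inflate its own
threshold, so a multiplicative spike escapes until its factor exceeds
$(2+c)/(2-c) \approx 2.08$, whereas the one-sided rule catches any spike
with factor $\ge 1 + c = 1.7$. Whether the local level should instead be
a running mean over a longer context is genuinely open; only the
single-predecessor form is implemented and the choice is documented here
rather than resolved silently. On clean, realistically autocorrelated
series (AR(1), $\phi = 0.9$, SDNN 30 ms) successive differences are an
order of magnitude below threshold, and the measured false-flag rate over
10,000 beats is ~0.

A `"literal"` mode reproduces, verbatim, a signed-difference form of the
inequality that circulates in print
($|RR_i - RR_{i-1}| < c\,(RR_i - RR_{i-1})/2$). Its right-hand side is
non-positive whenever the difference is, so the condition fails for every
nonzero successive difference: the mode flags every beat of any
non-constant series. It exists to make that pathology demonstrable, and a
regression test keeps the demonstration honest.

The default policy is whole-sequence: a series with any flagged beat is
rejected (`is_clean()`), matching the conservative practice for short
task recordings; `drop_artifacts()` is the explicit opt-in alternative.

## Segmentation

* **Fixed-duration sections** (`duration_spec()`, default 300 s) assign
  beat $k$ to section $\lfloor t_k / T \rfloor$ by the cumulative time
  elapsed *before* the beat. Sections are defined by wall time, not beat
  count, because mean RR differs across conditions; a trailing partial
  section is dropped by default. The sections partition the retained
  beats — a property test asserts no beat is lost or duplicated.
* **Sliding windows** (`window_spec()`, default 100 beats shifted by 10)
  start at offsets $0, S, 2S, \dots$, giving
  $\lfloor (N-L)/S \rfloor + 1$ windows; 150 beats yield the six sections
  labeled 1–100, 11–110, …, 51–150 (1-based inclusive labels).

## Synthetic data: what it emulates and what it does not

No RR recordings ship with the package; every analysis is exercised on
generators whose statistical structure matches what the pipeline assumes.
All generators are bit-reproducible under a seed, restore the caller's RNG
state, and enforce RR positivity by resampling (counted, though never
triggered at realistic parameters).

* `gen_ar1_rr()` — stationary AR(1): the irregularity dial. Larger $\phi$
  at fixed marginal SDNN means more predictability, hence lower SampEn.
* `gen_mix_rr()` — the MIX($p$) benchmark: sinusoid with proportion $p$
  of i.i.d. uniform replacements; SampEn increases monotonically in $p$
  from 0 (periodic) to the uniform i.i.d. limit.
* `gen_rsa_rr()` — respiratory sinus arrhythmia: a 0.25 Hz sinusoidal
  modulation plus white noise. With no noise it has large SDNN
  ($\approx$ amplitude$/\sqrt{2}$) but near-zero SampEn — the
  dissociation that motivates carrying both indexes.
* `inject_artifacts()` — multiplicative spikes or ectopic short-long
  pairs (0.6×/1.4× the local mean) with a ground-truth mask for scoring
  the screen.

### Calibrated experiment designs

`gen_experiment()` emulates four design shapes (paired two-condition,
independent groups, two-arm time course over 5-minute segments, and a
single-arm learning-onset window design). Irregularity is controlled
through $\phi$, never by inverting SampEn analytically: a
simulation-built table (`inst/extdata/ar1_sampen_calibration_n300.csv`,
rebuilt by `calibrate_ar1_sampen()`; 300 replicates of 300-beat segments
per grid point) maps $\phi$ to expected SampEn, and subject-by-condition
targets are translated through its monotone inverse. Paired designs share
subject-level random effects (SD 0.10 on the SampEn target, 60 ms on
av-RR, 8 ms on SDNN — spreads of the order of published interquartile
ranges) plus a per-condition jitter (SD 0.05).

The presets in `experiment_presets()` encode the emulated conditions:
a language-task contrast (SampEn 1.12 vs 1.30, identical level and
variance, n = 29), a vocabulary contrast (0.97 vs 1.09, n = 35), an
alcohol/control time course (treated-arm SampEn declining 0.97 → 0.85
across six 5-minute segments with falling av-RR; control SampEn flat at
1.06 — a time course's printed per-segment wiggle is modeled as real only
where its trend tested significant, otherwise as sampling noise around a
flat level), a rest/stress contrast (0.77 vs 0.58 with av-RR and SDNN
both dropping, n = 13), and a learning-onset design (SampEn/SDNN dipping
after the first ~100 beats, n = 26).

**Known limitations.** (1) The AR(1)-Gaussian dial cannot exceed the
i.i.d. SampEn ceiling (~1.289 at `r = 0.5 × SDNN`, N = 300), so condition
targets at that ceiling (the 1.30 language target) are reproduced with
compression: the realized median paired contrast is ~0.134 rather than
the nominal 0.18. The qualitative dissociation — SampEn separating at
high power while av-RR/SDNN stay null — is unaffected. (2) The
calibration is built at 300-beat segments; SampEn's weak length
dependence makes it serviceable for the 100–900-beat series the presets
generate, but targets for 100-beat windows are approximate. (3) Generated
series are stationary within segments, with clean Gaussian margins; real
RR data carry drifts, multiscale structure and non-Gaussian tails, so
passing tests validate the *pipeline*, not any physiological claim.

## The comparison workflow

All inference delegates to the standard R routines; the pipeline only
routes and formats. `normality_gate()` applies Shapiro–Wilk at
$\alpha = 0.05$; normal-looking samples (for paired designs, the paired
*differences* — what the paired t-test assumes normal) go to t-tests,
everything else to Wilcoxon matched-pairs or Mann–Whitney.
`repeated_trend()` wraps the Friedman test (a fully tied matrix is
reported as a degenerate null, statistic 0, p = 1, rather than NaN);
`correlate_spearman()` wraps Spearman's rank correlation. Alongside the
delegated p-value the paired comparison reports the matched-pairs
reporting style T (the smaller signed-rank sum over nonzero differences)
and its normal-approximation Z; the independent comparison reports
U = min(U_x, U_y) and Z. `experiment_report()` assembles per-condition
medians/quartiles (or means ± SE on the parametric branch) with the
design's tests; per-segment pairwise tests in time-course reports are
uncorrected by default — replicating the emulated workflow — with
`p_adjust = "holm"` as the rigor opt-in.

Zero-variance inputs (all-tied differences, constant samples) are
returned as flagged degenerate results, never silent numbers.

## Problem sizes and numerical checks

The test and acceptance workloads were sized to desk-scale runs: oracle
equivalence on 100 random series of 30–300 beats with random
$m \in \{1,2,3\}$ and random $r$; the Gaussian analytic limit on 100
series of 2,000 beats (mean within ±0.03 of 1.2862); MIX relative
consistency on 100 seeded replicate pairs at N = 500; screen operating
characteristics on 10,000-beat series with 5% injected 1.8× spikes
(≥95% recovery, <1% false flags); paired-design power on 200 replicates
of the language preset (SampEn rejected at p < 0.01 in ≥80%, level and
variance indexes at ≤10%); and type-I control on 400 identical-condition
replicates (Wilcoxon rejection within the binomial 95% interval of 0.05).
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.
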