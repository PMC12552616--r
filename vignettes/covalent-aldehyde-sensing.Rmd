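---
title: "Covalent nanopore sensing of aldehydes: model, simulator and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent nanopore sensing of aldehydes: model, simulator and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porevoc)
```

## The sensing chemistry and its kinetic model

An engineered α-hemolysin heteroheptamer carries a single cysteine inside its
β-barrel. Aldehydes entering the pore react reversibly with the thiol to form
a hemithioacetal adduct, which partially occludes the ionic current. A
recording at fixed potential therefore alternates between exactly two levels:
the open pore at current $I_P$ (about −129 pA at −50 mV in 2 M KCl for the
reference pore) and an adduct level characterised by its residual current
percentage,

$$I_{res}\% = \frac{I_{res}}{I_P} \times 100,$$

a ratio of like-signed currents and hence positive. Because there is a single
reactive cysteine, double occupancy is impossible and the latent process is a
two-state continuous-time Markov chain:

* association (open → adduct) is bimolecular: $v_{on} = k_{on}\,[\mathrm{ald}]_{tot}$,
  so open dwell times are exponential with rate $\sum_i v_{on,i}$ when several
  aldehydes compete, and the entering species is chosen with probability
  $v_{on,i} / \sum_j v_{on,j}$ (the competing-exponentials property);
* dissociation (adduct → open) is unimolecular and concentration-independent:
  $v_{off} = k_{off}$, so blockade durations are exponential with the
  diastereomer-specific $k_{off}$.

Aldehydes hydrate in water to thiol-unreactive *gem*-diols. With the hydration
equilibrium constant $K_{hyd} = [\mathrm{hydrate}]/[\mathrm{free}]$ (measured
by ^1^H NMR as a peak-integral ratio, `khyd_from_nmr()`), the free-aldehyde
concentration is $[\mathrm{ald}]_{tot}/(1 + K_{hyd})$ (`free_fraction()`) and
the rate constant against free aldehyde is

$$k_{on}' = k_{on}\,(1 + K_{hyd})$$

(`correct_kon()`). The two forms of the rate law,
$v_{on} = k_{on} [\mathrm{ald}]_{tot} = k_{on}' [\mathrm{ald}]_{ald}$, are
algebraically identical; the test suite asserts this identity for every
packaged analyte.

Hemithioacetal formation creates a stereocentre, so each analyte can produce
two diastereomeric adducts ("A" and "B", with A assigned the larger
$I_{res}\%$ by convention). The branching ratio of the two forms is not an
observable we have a measured value for; the fixtures default to 0.5/0.5 and
expose the fraction in the YAML so users can change it. Per-diastereomer
dissociation rates are likewise not separately established; fixtures assign
the analyte-level $k_{off}$ to both forms.

## Packaged parameter fixtures

`load_pore_fixture()` reads YAML parameter sets for four pore variants:
`ag_t115c` (the reference sensor, ten aldehydes), `mk_t115c`, `ag_g137c` and
`ag_g137c_ala3` (engineered variants with enhanced diastereomer resolution).
Every number carries a provenance flag: `printed` values are taken from the
published characterisation (e.g. propanal $I_{res}\% = 98.7$, ethanal
$k_{off} = 9.4\ \mathrm{s^{-1}}$); `interpolated` values fill gaps using the
~0.7 %-per-CH~2~ level rule or smooth trends (e.g. the ethanal and pentanal
levels, all $K_{hyd}$ values, which are literature-typical magnitudes chosen
so the corrected rate constants reproduce the published ~0.5 → ~0.3
mM^−1^s^−1^ trend); `derived` values are computed from published quantities
(butanal $k_{off} = 1/0.130\ \mathrm{s}$ from the ~130 ms mean lifetime;
butanal $k_{on} = 0.31\ \mathrm{mM^{-1}s^{-1}}$ from ~500 events per 10 min
at 3 mM via the renewal cycle length $T/(1/v_{on} + 1/k_{off})$; the B-level
of heptanal from the printed 0.29 % split). Concentrations are mM throughout
and association rate constants mM^−1^s^−1^.

## What the simulator emulates — and what it does not

`sample_dwells()` draws the latent alternating dwell path by Gillespie
sampling; segment boundaries (emulating mid-experiment solution replacement)
truncate the current dwell and redraw with the new concentrations, which is
exact because exponentials are memoryless. `render_trace()` converts dwells
to a 50 kHz sampled current: levels at $I_P$ and $I_{res}\%/100 \times I_P$,
edges smoothed by a linear-phase Gaussian FIR whose −3 dB point matches the
10 kHz acquisition Bessel filter (σ~t~ = √(ln 2)/(2π f~c~); a Gaussian FIR
has no ringing and a deterministic, compact kernel, which is all that matters
for rise-time and dead-time behaviour), then white Gaussian noise of standard
deviation `rms_noise` (default 1 pA) added per sample *after* filtering.

The simulator deliberately omits: 1/f and amplifier-specific noise spectra,
baseline drift, gating or spurious blockades, analyte-specific excess noise
during blockades, imine side reactions, pH dependence (all fixtures describe
pH 6.8) and aldehyde solubility limits. Consequently, passing tests
demonstrate that the estimators recover the parameters of *this* generative
model; on real recordings, drift and excess event noise would add variance
that the synthetic benchmarks do not probe. One visible consequence of the
white-noise model is that the per-event mean $I_{res}\%$ error shrinks as
$1/\sqrt{n_{samples}}$, so long events separate almost perfectly; real
event-level spreads (~0.1 %) have additional event-to-event components, and
classification accuracies measured here are therefore upper-end.

`simulate_labeled_events()` synthesizes classification feature sets directly
from the same statistical model (shifted-exponential durations, level plus
$\mathcal{N}(0, \sigma/\sqrt{n})$ event means, χ-distributed RMS estimates)
without rendering tens of millions of samples; it is distributionally
consistent with the simulate-then-idealize path because the added noise is
white at the sampling rate.

## Idealization

`idealize()` applies an additional 1 kHz analysis filter (between the 100 Hz
display filter and the 10 kHz acquisition filter: enough smoothing to make
threshold crossings reliable, enough bandwidth to resolve millisecond
dwells), normalizes by the robust baseline from `estimate_baseline()`
(median of samples within three robust SDs of the dominant level — valid
while occupancy stays below one half), and segments at a threshold placed by
default midway between the open level and the shallowest expected adduct
level (`auto_threshold()`), which maximizes the margin for the closest pair.
Runs shorter than the dead time (default 0.5 ms) are absorbed into their
neighbours, shortest first, so noise blips neither create nor split events.
Event means exclude three filter time constants at each edge to avoid
rise-time bias toward the baseline; events too short to keep three interior
samples are flagged rather than silently dropped.

With the default 1 pA noise, the analysis-filtered trace has ~0.2 pA RMS, so
the default threshold sits ≳4σ from both levels for adduct levels of 98.7 %
and deeper. Shallower levels (the ethanal level at 99.4 %) need a lower
analysis cutoff for reliable detection — a known limitation; the
classification benchmarks for ethanal therefore use the feature synthesizer
rather than trace idealization.

## Kinetic estimators

Durations observed above a dead time τ are left-truncated exponentials; by
memorylessness the MLE is

$$\hat{k} = \frac{n}{\sum_i (t_i - \tau)}, \qquad \mathrm{SE} = \hat{k}/\sqrt{n}$$

(`fit_exponential()`), which reduces *exactly* to the naive estimator at
τ = 0. A full missed-event convolution correction is unnecessary here:
with $k_{off} \lesssim 10\ \mathrm{s^{-1}}$ and τ = 0.5 ms, fewer than 0.5 %
of dwells are lost and the truncation bias is below 1 %.

`estimate_von()` divides the event count by the *open* time (total minus
blockaded minus one dead time per event): the association clock only runs
while the cysteine is free. At the occupancies typical here (<20 %) this
differs from a total-time rate by less than the sampling uncertainty, but it
is the consistent choice and makes the estimator invert exactly to the raw
event count. `fit_kon()` fits the origin-constrained slope of $v_{on}$
against concentration by inverse-variance weighted least squares, because
event counts (hence standard errors) differ across concentrations.

## Classification and quantification

Three features describe each event: $I_{res}\%$, duration, and within-event
RMS noise. Duration and RMS are log-transformed before fitting (both are
positive and right-skewed). The reference classifier is a fully specified
gaussian-per-class baseline (per-class mean and full covariance, maximum
posterior under equal priors — equal because benchmark sets are balanced at
~1000 events per class); a random forest (`ranger`) mirrors the ensemble
used for the headline multi-analyte accuracy. The baseline is verified in
the tests against an independently written brute-force posterior oracle,
and a singular class covariance falls back to its diagonal with a warning.

`quantify_events()` inverts the rate law per label:
$[\mathrm{ald}]_{tot} = v_{on}/k_{on}$ with a delta-method standard error.
Quantification deliberately uses the *observed* $k_{on}$ and total
concentration, so no hydration constant is needed at this step.
`ratio_profile()` applies this per segment of a recording whose mixture
changed mid-experiment; segment boundaries are taken as known (solution
replacement times are recorded in an experiment), so change-point detection
is out of scope.

## Problem sizes, seeds and numerical choices

All randomness flows from one integer seed expanded into per-stage seeds by
a fixed splitting rule (`derive_seed()`), so stages rerun alone reproduce
their stream and identical scenarios are bit-identical. Dwell intervals are
half-open $[t, t+\Delta)$ in seconds starting at 0; trace length is
`round(duration × sampling_rate)` samples.

The benchmark scripts and tests run at desk scale on one CPU: 10-minute
recordings at 50 kHz (30 M samples) for the event-count, lifetime and
mixture-quantification checks; 220–660 s recordings for the level-recovery
checks (a few hundred events suffice, since the standard error of a mean
event level is far below the 0.1 % band); 1000 events per class for the
7-aldehyde classification benchmark; and 20 seeded replicates of ~300 s
dwell-level scenarios for estimator-calibration coverage. The diastereomer
split is measured on events ≥ 10 ms, whose level error (≤0.04 %) is small
against the 0.29 % gap, using two-group k-means.

## Known limitations

* The baseline estimator assumes occupancy below ~50 %; saturating
  concentrations would need a different approach.
* Adduct levels shallower than ~99 % approach the detection threshold at the
  default analysis bandwidth.
* Fixture values flagged `interpolated` are modelling choices, not
  measurements; conclusions that depend on them (e.g. absolute $K_{hyd}$
  effects) should be treated accordingly.
* The white post-filter noise model understates event-to-event level spread
  relative to real recordings; classification accuracies are upper-end.
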