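# porevoc

Single-molecule covalent sensing of volatile aldehydes with engineered
α-hemolysin nanopores — simulation, event detection, kinetics, event
classification and ratiometric quantification, in one tested R package.

## The problem and the model

A heteroheptameric αHL pore with a single cysteine in its β-barrel detects
aldehydes through reversible hemithioacetal formation: each adduct partially
blocks the ionic current, so a recording at −50 mV alternates between the
open-pore level *I*<sub>P</sub> (≈ −129 pA) and an analyte-specific blockade
level, reported as the residual current percentage
*I*<sub>res</sub>% = *I*<sub>res</sub>/*I*<sub>P</sub> × 100. The latent
process is a two-state continuous-time Markov chain:

- association is bimolecular, *v*<sub>on</sub> = *k*<sub>on</sub>·[ald]<sub>tot</sub>
  (competing exponentials across a mixture decide which analyte reacts);
- dissociation is unimolecular, *v*<sub>off</sub> = *k*<sub>off</sub>, with
  exponential blockade durations;
- hydration removes reactive aldehyde: with
  *K*<sub>hyd</sub> = [hydrate]/[free], the free concentration is
  [ald]<sub>tot</sub>/(1 + *K*<sub>hyd</sub>) and the corrected association
  constant is *k*<sub>on</sub>′ = *k*<sub>on</sub>(1 + *K*<sub>hyd</sub>).

The package simulates such recordings (50 kHz sampling, 10 kHz anti-alias
filtering, Gaussian noise, optional mid-experiment concentration changes),
idealizes them back into events by robust-baseline thresholding with
dead-time handling, estimates rates by left-truncated exponential maximum
likelihood, classifies events from the (*I*<sub>res</sub>%, duration, RMS
noise) features with a gaussian baseline or a random forest, and converts
labeled event frequencies into concentrations via
[ald]<sub>tot</sub> = *v*<sub>on</sub>/*k*<sub>on</sub>. Parameter fixtures
for four pore variants and ten aldehydes ship in `inst/extdata/fixtures/`,
each value flagged `printed`, `interpolated` or `derived`.

## Worked example

Two minutes of 3 mM butanal on the reference pore, then recover the kinetics
and the concentration:

```r
library(porevoc)

fx <- load_pore_fixture("ag_t115c")
sc <- simulation_scenario(fx$pore, mixture_spec(fx$analytes$butanal, 3),
                          duration = 120, seed = 42)
sim <- simulate_trace(sc)
ev  <- idealize(sim$trace, idealization_config(),
                levels = fixture_levels(fx, "butanal"))
ev
#> Event table: 117 blockade events over 120.0 s (baseline -129.0 pA)
#>   mean I_res% 97.90, mean duration 130.4 ms

estimate_koff(ev)
#> k_off = 7.699 +/- 0.712 s^-1 (n = 117 dwells, dead time 0.0005 s)
estimate_von(ev)
#> v_on = 1.118 +/- 0.103 s^-1 (n = 117 dwells, dead time 0.0005 s)

ev$label <- "butanal"
quantify_events(ev, fx$analytes["butanal"])
#>   analyte  conc_mM stderr_mM upper95_mM     v_on k_on n_events
#> 1 butanal 3.605246 0.3333051         NA 1.117626 0.31      117
```

The mean event level sits on the butanal fixture level (97.9 %), the fitted
dissociation rate 7.70 ± 0.71 s⁻¹ matches the configured 1/0.130 s adduct
lifetime, and the recovered concentration 3.6 ± 0.33 mM brackets the true
3 mM within two standard errors of this short recording; longer recordings
tighten it (the benchmark below uses 10 minutes).

A config-driven end-to-end run (simulate → detect → classify → fit →
quantify, with a digest manifest) is available as `run_pipeline(config,
out_dir)` or through the thin CLI at `inst/cli/porevoc.R`; see
`vignettes/covalent-aldehyde-sensing.Rmd` for the model, estimator and
design details.

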