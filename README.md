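# herclock

Hybrid stochastic–deterministic modelling of the zebrafish somite
segmentation clock, for researchers studying how noisy gene regulation
degrades — and Notch signalling restores — the synchrony of cellular
oscillators in the presomitic mesoderm (PSM).

Each cell is a delayed negative-feedback oscillator: the *her1/7* genes are
transcribed with delay τ<sub>mh</sub>, translated with delays
τ<sub>ph1/7</sub>, and the Her1 (homodimer) and Her7:Hes6 (heterodimer)
proteins repress their own transcription.  mRNA and protein follow delay
differential equations,

&nbsp;&nbsp;dm/dt = α·G(t−τ<sub>mh</sub>)/2 − λ m,&nbsp;&nbsp;&nbsp;
dp/dt = β·m(t−τ<sub>ph</sub>) − λ p,

while the occupancy of the four gene copies (G ∈ {0,1,2} active copies per
gene) is an exact jump process: repressor and NICD dimers bind free copies
with propensities k<sub>on</sub>·p², and anything bound dissociates at
k<sub>off</sub> — the clock's key noise parameter (≈ 1/3 min⁻¹).  Event
times are drawn with a delayed direct-method Gillespie sampler whose
propensities vary continuously between events (the cumulative hazard
∫a₀(s)ds is inverted at an exponential threshold).  On a periodic hexagonal
lattice, Delta–Notch signalling couples each cell to its six neighbours:
Her represses *delta*; delayed neighbour Delta produces NICD; NICD competes
with the repressors for *her1/7* DNA and holds genes active.

On top of the simulator the package implements the two quantification
procedures of this analysis pipeline:

* a desynchronisation detector — sliding two-sample Kolmogorov–Smirnov
  comparison of Her1 distributions half a period apart; desynchronisation
  is declared when the p-value clears 0.1 over a full cycle
  (`ks_pvalue_series()`, `desync_time()`, `desync_summary()`);
* an inter-allele expression-delay estimator — from spatial profiles of
  nuclei with one vs two active *her1* transcription sites, via
  rising-edge inflection points and the conversion
  δt = T₀·δx / (S(x) − v(x)·S₀), with non-parametric bootstrap inference
  on per-embryo delay samples (`estimate_embryo_delay()`,
  `bootstrap_delay()`).

Synthetic-data generators (`generate_embryo_profile()`,
`generate_delay_cohort()`, `generate_phase_ensemble()`) supply every input
with known ground truth.

## Worked example

```r
library(herclock)

# 100 uncoupled cells, identical initial conditions, measured koff
p <- make_default_params("hybrid")      # koff = 1/3 min^-1
tr <- simulate_ensemble(p, n_cells = 100, t_end = 700, seed = 1)
desync_summary(tr)[c("period", "desynchronised", "time", "oscillation")]
#> $period
#> [1] 33
#> $desynchronised
#> [1] TRUE
#> $time
#> [1] 521
#> $oscillation
#> [1] 16
```

The ensemble oscillates with a ~33-minute period and, for this seed, the
across-cell Her1 distribution becomes stationary (salt-and-pepper phase
mosaic) 521 minutes in — individual cells keep oscillating, but their mean
decays as neighbours drift apart.  Seed-to-seed spread is several cycles;
ensemble medians over ≥ 5 seeds are the meaningful statistic.

```r
# inter-allele delay from a synthetic embryo at known truth (0.1 T0 = 3 min)
pr <- generate_embryo_profile(true_delay = 0.10, seed = 2)
est <- estimate_embryo_delay(pr)
round(c(minutes = est$delay_min, frac_T0 = est$delay_frac), 3)
#> minutes frac_T0
#>   2.875   0.096

# bootstrap population inference on a 13-embryo delay sample
ds <- read_delay_sample(system.file("extdata", "synthetic_delay_sample.csv",
                                    package = "herclock"))
bt <- bootstrap_delay(ds, B = 10000, seed = 1)
round(c(mean = bt$mean, sd = bt$sd, lo = bt$ci[1], hi = bt$ci[2]), 4)
#>   mean     sd     lo     hi
#> 0.1088 0.0591 0.0817 0.1369
```

(The packaged sample is synthetic — see the vignette — so these bootstrap
numbers describe that synthetic sample.)

Experiment bundles (sweeps, variability runs, Notch lattices) can be run
from a YAML config with `run_experiment()` or the thin wrapper in
`inst/scripts/run_experiment.R`.

## Layout

* `R/`, `src/engine.cpp` — model core, hybrid DDE–Gillespie engine,
  lattice, variability, desynchronisation metric, delay quantification,
  synthetic data, experiment orchestration
* `vignettes/segmentation-clock-methods.Rmd` — model, assumptions,
  calibration choices, estimator details, limitations
* `tests/testthat/` — unit, property and acceptance tests
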