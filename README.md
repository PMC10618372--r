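# pvngate

Single-channel kinetic analysis of thermosensitive Trpv4-like channels and
a stochastic model of paraventricular nucleus (PVN) neurone firing.

Hypothalamic PVN neurones fire *faster* when cooled, even though the
warm-activated, Ca²⁺-permeable TRP channels on their membranes close.
`pvngate` packages the computational chain that connects those two
observations for ion-channel biophysicists and computational
neurophysiologists:

- **Kinetic schemes.** A channel is a continuous-time Markov chain with
  generator Q (1/ms) over open/closed states. The package provides
  equilibrium theory (`equilibrium()`: π Q = 0, Po = Σ π_open), analytic
  dwell-time mixtures from the within-class sub-generator spectra
  (`dwell_pdf()`), Q10 temperature scaling of open-ward rates
  (`scale_rates_q10()`), and construction of schemes from published
  dwell-time mixtures (`scheme_from_mixtures()`). The default Trpv4-like
  channel (59.7 pS, V_rev −18.89 mV) is a 3-closed/3-open chain whose
  closed mixtures at 22/32/37 °C are the tabulated maximum-likelihood
  values (e.g. 0.58/5.26/71.22 ms at 58/30/12 % at 22 °C).
- **Synthetic cell-attached records.** Exact stochastic gating
  trajectories rendered as 5 kHz digitized traces after a 1 kHz low-pass,
  with seed-exact reproducibility (`simulate_gating()`, `render_trace()`).
- **Idealization and dwell analysis.** All-points amplitude histograms,
  segmental-k-means idealization, 0.3 ms dead-time imposition, Sigworth–
  Sine log-binned displays, maximum-likelihood fitting of dead-time-
  truncated exponential mixtures and likelihood-ratio selection of the
  number of components (`skm_idealize()`, `apply_dead_time()`,
  `fit_mixture()`, `select_components()`).
- **MIL rate estimation.** Maximum-interval-likelihood fitting of
  transition rates from idealized records with first-order missed-event
  correction via dead-time-corrected operators (`interval_loglik()`,
  `fit_rates()`).
- **Stochastic neurone model.** A single-compartment PVN neurone with
  Hodgkin–Huxley spike machinery, stochastic Kv/Trpv4-like/Trpm2-like/SK
  channel populations, a TRP→SK Ca²⁺ microdomain, Poisson synaptic drive
  with an inhibitory interneurone stage, temperature sweeps and
  pharmacological block experiments (`run_neuron()`,
  `temperature_sweep()`, `apply_drug()`).

See `vignettes/pvngate-methods.Rmd` for the model assumptions, parameter
conventions (ms, mV, pA, pS, µM, °C) and design decisions.

## Worked example

Build the 22 °C channel from the printed closed mixture, simulate and
analyse a synthetic record, and compare with the generator truth:

```r
library(pvngate)

sch <- trpv4_scheme(22)
equilibrium(sch)$po
#> [1] 0.2741

ev  <- simulate_gating(sch, duration = 120, seed = 7)      # seconds
cfg <- trace_config(duration = 120, noise_sd = 0.3,
                    holding_potential = -70, seed = 8)
tr  <- render_trace(ev, sch, cfg)

am <- fit_amplitude_model(tr)
am
#> <amplitude_model: closed -0.00278 pA (sd 0.29), open -3.03 pA (sd 0.319), SNR 9.95>

id <- apply_dead_time(skm_idealize(tr, am), dead_time = 0.3)
fit_mixture(dwells_of_class(id, "closed"), 3, dead_time = 0.3)
#> <mixture_fit: 5512 closed dwells, 3 component(s), logLik -15802.30, dead time 0.3 ms>
#>       tau_ms area_pct
#> 1  0.6147142 49.62667
#> 2  5.0994583 35.77913
#> 3 69.9550597 14.59420
```

The three fitted closed time constants (0.61/5.10/69.96 ms) recover the
generator's 0.58/5.26/71.22 ms from a two-minute noisy record after
idealization and dead-time truncation; the fitted record Po (0.282)
matches the analytic 0.274.

The neurone model predicts the inverse temperature dependence of firing:

```r
sw <- temperature_sweep(neuron_config(), temps = c(37, 32, 27, 22),
                        n_runs = 5, duration = 60, seed = 1)
aggregate(acf_hz ~ temperature_C, sw, mean)
```

gives mean action-current frequencies that rise monotonically as the bath
cools from 37 °C to 22 °C (≈0.1 Hz at 37 °C to ≈3 Hz at 22 °C with the
default calibration), with the rise abolished when the SK population is
removed and reshaped in the characteristic ways under the
gadolinium-like (Trpv4 block) and econazole-like (Trpm2 block) analogues.

A thin command-line driver covers the same pipeline
(`inst/cli/pvngate.R`; subcommands `simulate-channel`, `idealize`,
`fit-dwells`, `fit-rates`, `simulate-neuron`, `temperature-sweep`,
`drug-sweep`, `reproduce`), writing a JSON manifest (command, config,
seeds, package version) next to every output.

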