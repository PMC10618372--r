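---
title: "Single-channel kinetics and a stochastic thermosensitive PVN neurone model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel kinetics and a stochastic thermosensitive PVN neurone model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`pvngate` implements a complete computational pipeline for thermosensitive
single-channel kinetics and its downstream use in a stochastic neurone
model. The package covers, end to end:

1. continuous-time Markov kinetic schemes with temperature (Q10) scaling
   and dwell-time theory (`kinetic_scheme()`, `equilibrium()`,
   `dwell_pdf()`, `scheme_from_mixtures()`);
2. a synthetic-data generator emulating cell-attached patch-clamp
   acquisition (`simulate_gating()`, `render_trace()`,
   `make_temperature_dataset()`, `make_spike_trace()`);
3. idealization of noisy traces by segmental k-means with dead-time
   imposition (`fit_amplitude_model()`, `skm_idealize()`,
   `apply_dead_time()`);
4. dwell-time statistics: log-binned displays, maximum-likelihood fitting
   of dead-time-truncated exponential mixtures, likelihood-ratio selection
   of the number of components (`log_bin()`, `fit_mixture()`,
   `select_components()`, `po_and_means()`);
5. maximum-interval-likelihood (MIL) estimation of transition rates with
   first-order missed-event correction (`interval_loglik()`,
   `fit_rates()`);
6. a stochastic single-compartment model of a paraventricular nucleus
   (PVN) neurone coupling TRP-channel Ca^2+^ influx to SK channels through
   a membrane microdomain (`neuron_config()`, `run_neuron()`,
   `temperature_sweep()`, `apply_drug()`,
   `detect_action_currents()`).

All interchange objects (event tables, schemes, mixtures, traces,
manifests) have plain-text readers and writers, and a thin command-line
driver ships in `inst/cli/pvngate.R`.

## Kinetic schemes and dwell-time theory

A channel is a continuous-time Markov chain on a small set of states, each
labelled open or closed, with generator matrix $Q$ (rates in 1/ms,
off-diagonals non-negative, rows summing to zero, connectivity
irreducible). The stationary distribution $\pi$ solves $\pi Q = 0$; the
open probability is the stationary mass on the open aggregate and the mean
class dwell times follow from the stationary exit flux of each aggregate.

For an aggregated class with sub-generator $Q_{CC}$ and stationary entry
distribution $\phi$, the dwell-time density is
$f(t) = \phi\, e^{Q_{CC} t}(-Q_{CC})\mathbf 1$: a mixture of exponentials
whose time constants are $-1/\lambda_k$ for the eigenvalues $\lambda_k$ of
$Q_{CC}$, with areas from the entry-weighted spectral projections. The
package exposes both the mixture form (`dwell_pdf()`, which validates that
the spectrum is real and the areas non-negative) and the exact matrix CDF
(`dwell_cdf_fun()`, valid for any irreducible scheme and used as the
reference distribution in simulation cross-checks).

### The default Trpv4-like channel

The default channel is a 3-closed/3-open chain
$C_3\!-\!C_2\!-\!C_1\!-\!O_1\!-\!O_2\!-\!O_3$ with unitary conductance
59.7 pS and reversal potential $-18.89$ mV. The closed dwell mixtures at
22, 32 and 37 °C are the tabulated maximum-likelihood values for the
PVN Trpv4-like channel:

| °C | $\tau_{C1}$ (ms) | % | $\tau_{C2}$ | % | $\tau_{C3}$ | % |
|----|------|----|------|----|-------|----|
| 22 | 0.58 | 58 | 5.26 | 30 | 71.22 | 12 |
| 32 | 0.75 | 65 | 5.87 | 27 | 49.96 | 7  |
| 37 | 1.24 | 69 | 7.28 | 24 | 82.19 | 7  |

The open-side mixtures are **not** measured values: only the closed rows
are tabulated for this channel. They are package configuration constants
chosen once on two qualitative constraints — the fast open component is
temperature-insensitive while the two slower components shorten on
cooling, and the resulting open probability falls markedly on cooling,
driven by the mean open time (not the closed times):

| °C | $\tau_{O1}$ (ms) | % | $\tau_{O2}$ | % | $\tau_{O3}$ | % |
|----|-----|----|----|----|----|----|
| 22 | 1.5 | 50 | 4  | 30 | 10 | 20 |
| 32 | 1.5 | 30 | 8  | 40 | 25 | 30 |
| 37 | 1.5 | 15 | 12 | 35 | 60 | 50 |

With these defaults the analytic open probability is 0.27 / 0.66 / 0.80 at
22 / 32 / 37 °C. Any conclusion that depends on the open-side values
should treat them as free parameters.

### Building schemes from printed mixtures

`scheme_from_mixtures()` inverts a pair of dwell mixtures into chain
rates. The chain topology was chosen because it is the minimal uncoupled
scheme able to produce $n$ closed plus $m$ open exponentials, and because
its single gateway makes the two class sub-chains independently
identifiable: each sub-chain has $2k-1$ free rates against exactly $2k-1$
mixture constraints ($k$ time constants, $k-1$ free areas). Because entry
into a class always occurs at the gateway state, the closed fit does not
depend on the open rates (and vice versa).

The inversion is a penalized least-squares fit in log-rate space
(objective: squared log-tau errors plus squared area errors), run with a
deterministic heuristic start plus up to 25 seeded random restarts
(`nlminb` then a BFGS polish). The fit is *verified*: the constructed
scheme's analytic mixtures must reproduce the inputs to a relative tau
error of 1e-4 and an absolute area error of 1e-3, otherwise an error
reports the best residual. Mixture-to-rates inversion is not unique in
general; the chain parameterisation plus the verified round-trip is the
package's resolution of that ambiguity.

### Temperature handling

Two mechanisms coexist. Generic schemes carry a designated set of
"forward" (open-ward) transitions and a Q10; `scale_rates_q10()`
multiplies each forward rate by $Q_{10}^{(T-T_{ref})/10}$. The default
Trpv4-like channel instead interpolates between its three *measured*
schemes: each transition rate is regressed log-linearly on temperature
across 22/32/37 °C and intermediate temperatures (e.g. 27 °C) use the
regression line — an effective per-transition Q10 (`trpv4_q10()`). This
honours the measured endpoints exactly while keeping the Q10 mechanism for
interpolation. Notably the fitted per-transition Q10 values on the closed
side are below 1 (closed dwells lengthen slightly on warming); the strong
warmth activation lives on the open side.

## The synthetic-data generator

`simulate_gating()` draws exact trajectories (exponential waiting times,
embedded-chain jumps; initial state from equilibrium) and collapses them
to alternating class dwells. Event times are continuous; discretization
only happens at rendering, so ground truth stays exact for recovery
tests.

`render_trace()` emulates the acquisition chain: the piecewise-constant
pipette current (closed level 0, open level $g(V - V_{rev})$, inward
negative) is built on a 2x oversampled grid, Gaussian noise is added, a
4-pole Butterworth low-pass at 1 kHz stands in for the analogue (Bessel)
filter, and the result is decimated to 5 kHz. The injected noise is
pre-scaled by the filter's noise gain so that `noise_sd` is the SD seen in
the digitized record — the quantity an experimenter reads off a trace.
Because the cell's resting potential is unknown in cell-attached mode,
the membrane and pipette potentials are collapsed into a single driving
potential (the Fig-style temperature series defaults to $-70$ mV).

What the generator deliberately does **not** emulate: capacitance
transients, baseline drift, line interference, filter-correlated noise
statistics beyond the single low-pass, sub-conductance levels, and
multi-channel stacking artefacts beyond simple superposition
(`n_channels_in_patch`). Passing recovery tests on these traces therefore
shows the estimators are correct for the stated noise model, not that they
are robust to every artefact of real recordings.

## Idealization

`fit_amplitude_model()` fits the all-points amplitude histogram with a
two-component Gaussian mixture (mclust's variable-variance EM over a
deterministic k-means split seeded at the 10th/90th percentiles),
followed by a trimmed refinement (samples within 2.5 SD of their level)
that removes the bias filter-attenuated brief events put on the component
means. A record is declared effectively unimodal — no openings — when the
component separation is under 3 times the mean component SD.

`skm_idealize()` is the segmental-k-means idealizer: it alternates a
two-state Viterbi pass (Gaussian emissions) with re-estimation of levels,
SDs and transition probabilities from the assignment, stopping when fewer
than 0.1 % of samples change class (cap 50 iterations; these settings are
package choices — the method's originators specify the procedure, not the
constants). A half-amplitude threshold idealizer
(`threshold_idealize()`) is provided as a fast cross-check.

`apply_dead_time()` imposes the resolution dead time (default 0.3 ms):
dwells shorter than the dead time are absorbed into the ongoing resolved
dwell, preserving total record duration and alternation. Boundary dwells
are censored and excluded from dwell fitting downstream.

## Dwell-time analysis

Fitting works on unbinned dwells; log-binned histograms (`log_bin()`,
square-root ordinate, peaks at the time constants) are display-only. This
avoids binning bias and matches maximum-likelihood practice.

A mixture of exponentials left-truncated at the dead time $t_d$ is, after
shifting by $t_d$, again a mixture of exponentials with reweighted areas
($w_k \propto a_k e^{-t_d/\tau_k}$). `fit_mixture()` therefore runs EM on
the shifted dwells (closed-form M-step, 10 deterministic restarts, ties
broken by likelihood) and maps the weights back, reporting the parameters
of the *untruncated* distribution. The single-component case uses the
closed form $\hat\tau = \bar t - t_d$.

`select_components()` adds components while twice the log-likelihood gain
exceeds the $\chi^2$ critical value at the 0.95 confidence level with 2
degrees of freedom per added component (one tau, one area) — the d.f.
convention is a package decision; only the confidence level is inherited
from standard practice.

The recovered fast time constants carry a small upward bias (of order
10 % for the 22 °C fast closed component) because openings shorter than
the dead time merge adjacent closed dwells; this is inherent to
dead-time-imposed idealization, is shared by the experimental pipeline
being emulated, and stays inside the 15 % recovery band used by the
acceptance suite.

## MIL rate estimation with missed events

`interval_loglik()` evaluates the likelihood of the alternating interval
sequence with the first-order dead-time-corrected operators: within-class
sub-generators
$\tilde Q_{AA} = Q_{AA} + Q_{AB}(I - e^{Q_{BB} t_d})(-Q_{BB})^{-1} Q_{BA}$
(brief excursions into the opposite class are absorbed into the observed
dwell) and switch operators $Q_{AB}e^{Q_{BB} t_d}$ (the entered class must
itself survive the dead time). Each observed dwell of duration $t$
contributes $e^{\tilde Q_{AA}(t - t_d)}$; the final dwell contributes its
survival only; at $t_d = 0$ everything reduces exactly to the plain
interval likelihood. Propagation runs in compiled code over the spectral
factors of the two sub-generators, with per-dwell rescaling against
underflow.

`fit_rates()` maximises this likelihood over log-rates (bounded in
$[10^{-6}, 10^3]$/ms) for chain topologies, initialised from
dwell-mixture fits of the data, with standard errors from the observed
information; flat directions are reported, never silently pinned. The
first-order correction is accurate when the dead time is small against
the mean dwell of the opposite class ($k\,t_d \lesssim 0.1$); the
bias-removal property test runs in that regime. At the aggressive end
(0.3 ms dead time against a 0.5 ms time constant) a residual
underestimate of a few percent remains — the known cost of a first-order
treatment.

## The stochastic PVN neurone model

The model is a single compartment (15 pF) with classic deterministic
Hodgkin–Huxley spike conductances, plus stochastic channel populations
updated by per-transition binomial draws on a 0.1 ms channel substep
(membrane step 0.025 ms, Euler): a 5-state delayed-rectifier Kv
population, the measured Trpv4-like 6-state scheme, a hypothetical
2-state Trpm2-like channel, and Ca^2+^-activated SK channels. Channel
counts are conserved exactly at every step, and every run is reproducible
from its seed.

Temperature enters *only* through the TRP channels: Trpv4-like via the
per-temperature measured schemes, Trpm2-like via a Q10 of 15.6 on its
opening rate (base rates at 37 °C are free parameters — the channel is
hypothetical by construction). Everything else is temperature-insensitive,
so the count-zero control is flat by construction.

Ca^2+^ handling is a two-compartment microdomain model rather than a
spatial reaction–diffusion mesh: open TRP channels deposit the
GHK-fraction of their current (PCa/PNa = 6 for Trpv4-like, 0.7 for
Trpm2-like, computed from the GHK flux equations at the instantaneous
voltage) into a small sub-membrane domain (0.3 fL, buffer capacity 15)
that exchanges with the bulk (rate 1/ms); the bulk relaxes to a 50 nM
rest. This captures the premise the model needs — large local transients
at the TRP–SK complex with negligible global change (the bulk stays
within a factor of two of rest in the invariant suite) — without a mesh.

SK channels use a two-state Ca^2+^-dependent scheme of the
Moczydlowski–Latorre form, $\alpha = \bar a/(1 + K_1/[Ca]_{md})$,
$\beta = \bar b/(1 + [Ca]_{md}/K_2)$, with the voltage-dependence
exponents set to zero because SK channels are voltage-independent;
$K_1 = 30\ \mu$M and $K_2 = 2.5\ \mu$M place the activation flank across
the 1–15 µM range the microdomain spans between 22 and 37 °C.

Synaptic drive is a direct excitatory Poisson train (AMPA-like, 3 ms
decay) plus an excitatory train driving a threshold-linear inhibitory
interneurone (GABA-like, 10 ms decay); the two mean rates receive
per-run lognormal jitter (SD 0.08 in log units) emulating run-to-run
variability. "Action currents" are modelled as spikes: threshold
crossings of the membrane potential at $-20$ mV with a 3 ms lockout. An
adaptive-threshold detector on current traces
(`detect_action_currents()`: running-median baseline, MAD noise scale,
refractory lockout) is provided for parity with the experimental
observable and validated against `make_spike_trace()` ground truth.

### Calibration of the free magnitudes

Absolute channel counts, microdomain constants and drive rates are not
reported quantities; they were calibrated **once** to the qualitative
operating regime the biology dictates — sparse firing (< 1 Hz) at 37 °C
rising several-fold by 22 °C with monotone intermediate temperatures —
and then frozen as the versioned defaults of `neuron_config()`
(3 Trpv4-like, 200 Trpm2-like at 25 pS, 1500 SK at 10 pS, 100 Kv;
excitatory drive 40 Hz at 0.8 nS). Two structural facts shaped the
calibration and are worth recording. First, with a GHK Ca^2+^ fraction of
only ~7 % (PCa/PNa = 0.7), a Trpm2-like population is net-inhibitory
(through SK) only where the SK activation curve is steep, so the
operating points at 37 °C must sit on the flank, not the plateau.
Second, the 37→27 °C thermosensitivity is carried almost entirely by the
Q10-15.6 Trpm2-like population while the 27→22 °C step is carried by the
measured Trpv4-like schemes — which is exactly what makes the
gadolinium-analogue (Trpv4 block) flatten only the cold end, and the
econazole-analogue (Trpm2 block) disinhibit the warm end. With the
default magnitudes the directional suite (cooling raises firing;
monotonicity; count-zero flatness; SK-removal abolition; both drug
directions) passes as paired-seed comparisons over 5 x 60 s runs; the
model makes no claim about absolute experimental firing rates, which are
figure-only quantities.

## Numerical choices and degenerate inputs

- Equilibria solve the augmented linear system by QR; schemes whose
  within-class spectra are complex (possible for non-reversible graphs)
  are rejected by `dwell_pdf()` with a diagnostic but still served by
  `dwell_cdf_fun()` and the simulator.
- EM restarts, optimizer restarts and all simulations are seeded;
  repeated calls are bit-identical. RNG state of the caller is always
  restored.
- Dead-time imposition handles an unresolvable leading dwell by merging
  it forward; a record with no resolvable dwell at all errors.
- All-closed traces return an amplitude model flagged `open_detected =
  FALSE` (with a warning) and refuse idealization.
- The neurone integrator aborts with a diagnostic if |V| exceeds 200 mV.
- Problem sizes in the test-suite were chosen to keep the default run on
  one CPU comfortable: dwell-recovery runs accumulate 5e4 closed dwells
  from chunked 120 s renderings; the oracle-equivalence suite uses 100
  random reversible schemes at 1e5 transitions each; sweeps use 5 x 60 s
  runs per condition.

## Known limitations

- The open-side dwell mixtures of the default channel are configured, not
  measured; every downstream quantity that depends on them (Po magnitudes,
  Trpv4 current budgets in the neurone model) inherits that uncertainty.
- The missed-event correction is first-order; heavily censored records
  (dead time comparable to the fastest time constant) retain a residual
  bias of a few percent in the fastest rates.
- The microdomain is a lumped two-compartment model; spatial gradients,
  multiple independent domains and stochastic single-domain Ca^2+^ noise
  are not represented.
- The neurone model's absolute firing rates, channel counts and drive
  magnitudes are calibration constants; only directions and fold-changes
  across temperature and drug conditions are meaningful model outputs.
- Serial correlation between successive dwells of aggregated Markov
  chains means dwell samples are not i.i.d.; distributional cross-checks
  thin the dwell sequence before applying Kolmogorov–Smirnov tests.
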