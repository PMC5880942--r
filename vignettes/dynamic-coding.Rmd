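---
title: "Dynamic coding with dynamic synapses: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic coding with dynamic synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synadapt)
```

`synadapt` simulates how a sensory network that adapts to a sustained
stimulus can hand the stimulus information over from firing *rates* to weak
synchronized *correlations*, and how a balanced downstream neuron reads that
correlation code out. This vignette is the package's account of the model,
the estimators, and every place where a design decision had to be made.

## The model

**Sensory network.** `n_e` excitatory (E) and `n_i` inhibitory (I) leaky
integrate-and-fire neurons, sparsely and randomly connected (each ordered
pair in the classes E→E, E→I and I→E is a directed edge independently with
probability `p`; there are no I→I edges and no self-edges). The membrane
follows

    tau_m dV/dt = -(V - E_L) + R_m (I_syn - I_adp),

with a spike when `V` crosses the class threshold (`-55` mV for E, `-57` mV
for I) and reset to `E_L = -65` mV. There is no refractory period and no
conduction delay. `I_syn = I_ext + I_rec`, where `I_ext = mu + sigma_ext
eta(t)` is a white-noise external drive whose mean `mu` is `mu_ext` for E
neurons inside the stimulus window and `mu_b` otherwise.

**Adaptation.** E neurons (only) carry an adaptation current

    tau_a dI_adp/dt = -I_adp + A_p (V - E_L) + A_s sum_k delta(t - t_k),

combining a subthreshold voltage-tracking term (`A_p`) and a spike-triggered
term (`A_s`). It is subtracted from the synaptic drive, so sustained firing
self-limits on the `tau_a = 250` ms time scale.

**Short-term plasticity.** Each E neuron carries one presynaptic state pair
`(u, x)` shared by all its outgoing E→E synapses: `u` (release probability)
facilitates toward 1 on each spike with increment `U(1-u)` and relaxes to 0
with time constant `tau_f`; `x` (available resources) is depleted by release
and recovers to 1 with `tau_d`. A spike transmits `u'x` (facilitation first,
then release, then depletion), and the postsynaptic current jumps by
`J_EE u'x` (or by the fixed `J_s` in the static-synapse model). I-mediated
couplings (`J_EI`, `J_IE`) are static. Defaults (`U = 0.00525`,
`tau_f = 400` ms, `tau_d = 1000` ms) put the synapses in the weakly
facilitating, slowly depressing regime typical of sensory cortex.

**Read-out.** Every sensory neuron projects to a single downstream LIF unit
driven by `R_m (J_EO I_E - J_IO I_I)`, where `I_E`, `I_I` are the population
spike counts filtered with the synaptic time constant `tau_s`. With
`N_E = 4 N_I` and `J_IO = 2 J_EO`, the mean drive cancels whenever the
inhibitory rate is about twice the excitatory rate, which is what the two
thresholds produce in the background state: the read-out then sits just
below threshold and responds only to *fluctuations*, i.e. to synchronized
volleys.

## Conventions the equations leave open

Several delta-function terms in the state equations admit two readings;
these are explicit switches in `network_params()`:

* **Jump size** (`delta_convention`). The standard Tsodyks–Markram
  bookkeeping takes the per-spike jump equal to the equation coefficient
  (`Delta u = U(1-u)`, `Delta I_adp = A_s`, `Delta I_rec = J u'x`); the
  strict ODE reading divides each jump by its relaxation time constant.
  The default is jump-equals-coefficient: under the strict reading, with
  `U = 0.00525` a spike would move `u` by about `1.3e-5`, and no visible
  facilitation could develop at physiological rates. Both conventions are
  implemented.
* **White-noise normalization** (`noise_delta_unit`). A delta-correlated
  noise needs a time unit. With the delta per *millisecond* the per-step
  noise is `sigma_ext z / sqrt(dt)`; the resulting stationary membrane SD is
  `R_m sigma_ext / sqrt(2 tau_m)` ≈ 0.19 mV, which against a 10 mV threshold
  gap leaves the network permanently silent — no background activity, no
  onset response, nothing to analyze. With the delta per *second* (the
  default) the per-step noise is `sigma_ext z sqrt(1000/dt)`, the membrane
  SD is ≈ 6 mV, and the network settles into the intended noise-driven
  background state (E ≈ 7 Hz, I ≈ 14 Hz — almost exactly the 1:2 ratio the
  read-out weights are balanced for). We therefore read `sigma_ext` as the
  noise density per second; the millisecond reading remains available.
* **Stimulus composition** (`stimulus_mode`). During the stimulus the
  external mean for E neurons is `mu_ext` *replacing* `mu_b` (both are
  means of the same external input); an additive mode is available.
* **Read-out drive** (`readout_drive`). "Summation of spikes" is realized
  as `tau_s`-filtered unit jumps per spike (default); raw per-spike voltage
  kicks are available behind the flag.

## Integration

Explicit Euler with `dt = 0.1` ms. All right-hand sides are evaluated at
start-of-step state; threshold tests happen after the update, spike times
are reported at the end of the step, and a spike first reaches other
neurons in the following step. Between spikes the auxiliary variables
(`u`, `x`, `I_rec`, the read-out filters) are advanced with *exact*
exponential factors, which is cheap and unconditionally stable, so only
the membrane update carries the O(dt) Euler error (verified in the tests:
halving `dt` halves the subthreshold error). Simultaneous spikes superpose
linearly. The trial spans `[-2500, 2500)` ms with stimulus onset at 0; the
first half is a warm-up under background drive from the deterministic
initial state (`V = E_L`, `u = 0`, `x = 1`), long relative to `tau_f` and
`tau_d`, so the stimulated epoch starts from the stochastic stationary
state.

Per-trial noise comes from a self-contained PCG32 + Box–Muller stream
seeded by `seed + 1000003`; the connectivity graph is drawn from R's RNG
seeded by `seed`. Recordings are therefore bit-reproducible from
`(params, seed)`, and conditions sharing a seed share topology *and* noise,
which is what makes the paired period comparisons across conditions valid.
Input currents `s_i = I_syn,i - I_adp,i`, the population mean `u·x`, the
read-out membrane and the balanced drive are recorded as 1-ms frame
averages.

## Protocol and estimators

Three 800-ms analysis periods are fixed relative to the stimulus
(`default_periods()`): Pre-adp `[-900, -100)`, Adp `[500, 1300)` (late in
the 1500-ms stimulus, after rates have adapted), Post-adp `[1600, 2400)`.

* **Correlation.** Currents are averaged into 5-ms bins per period; the
  mean pairwise covariance over all unordered pairs (`sigma_s^2 alpha` in
  the dichotomized Gaussian model) is computed with the variance-of-sum
  identity in O(NT), with the explicit O(N²) pair loop retained as a test
  oracle. `sigma_s` is the mean per-neuron SD of the binned currents.
* **Shuffling control.** Per neuron and trial, the 5-ms bins of `s_i` are
  independently permuted (analysis-time only, never fed back into the
  dynamics). Means are preserved exactly; temporal and cross-neuron
  structure is destroyed.
* **Synchrony.** The fraction of distinct E neurons firing per `t_w = 5` ms
  bin, its survival function, and the dichotomized Gaussian fit: `mu_s`,
  `sigma_s`, `alpha` come from the current traces and only the threshold
  `h` is fitted, to the observed mean fraction
  (`h = mu_s - sigma_s Phi^{-1}(rate)`).
* **Density.** The population-rate density is derived by the exact change
  of variables from the shared factor: with
  `q(eps) = Phi((mu_s + sigma_s sqrt(alpha) eps - h)/(sigma_s sqrt(1-alpha)))`,
  `p(r) = phi(eps)/q'(eps)` at `eps = q^{-1}(r)`. Closed-form expressions
  for this density are easy to mis-transcribe (`sqrt(alpha)` vs `alpha`,
  the sign of the exponent), so the derivation plus the Monte Carlo sampler
  (`dg_sample()`) are treated as authoritative; the sampler-vs-density
  agreement is part of the acceptance suite. At finite population size the
  observed fractions are the large-N density smeared by binomial sampling;
  `dg_rate_pmf()` implements this finite-N correction exactly (kept out of
  the default density, used where the comparison target is itself a
  finite population).
* **Statistics.** Period contrasts are paired two-sided t tests across
  trials (trials are seed-paired; a Wilcoxon signed-rank alternative is a
  flag). The significance threshold is 0.05 with no multiple-comparison
  correction; reports carry raw p-values so any correction can be applied
  downstream. Zero-variance difference vectors are handled exactly
  (p = 1 when all differences vanish).
* **Adaptation timing.** On the trial-averaged E-population PSTH (100-ms
  windows), the background band is the mean ± 2 SD across trials of the
  per-trial Pre-adp mean rate; reported are the first post-onset window
  back inside the band and the rise-to-return length. The band is defined
  from per-trial Pre-adp means (not per-window rates) so that it reflects
  trial-to-trial variability of the baseline rather than within-trial
  counting noise; 100-ms windows are used for both timing quantities
  because finer windows make the band-crossing detection flicker on
  single-window noise.

## Problem sizes

The shipped experiments use the full 2000 + 500 neuron network and 5000-ms
trials. Batches are 10 trials for the PSTH time course and 30 paired trials
per condition for the period statistics — enough for the paired tests to
resolve the read-out and efficacy effects, chosen as a compact study size.
The unit tests exercise the same code paths on smaller networks.

## What the default parameter regime does and does not produce

Everything below is measured by the package's own test suite and
acceptance script on the default configuration.

* The background state is noise-driven (membrane SD ≈ 6 mV against a 10 mV
  gap), with E ≈ 7 Hz and I ≈ 14 Hz, and the read-out drive mean is small
  relative to its SD, as intended for a balanced read-out.
* The stimulus raises the E-neuron mean drive by `R_m (mu_ext - mu_b)` =
  0.2 mV — only ~3% of the membrane noise SD. The onset rate transient is
  correspondingly modest (~5%), and the spike-triggered adaptation loop
  (gain ≈ 0.3 at these rates) cancels only part of it: the trial-averaged
  rate stays a few percent above the background band for the whole
  stimulus instead of re-entering it a few hundred milliseconds after
  onset. The *qualitative* adaptation signature (onset rise, partial decay,
  offset undershoot) is present; the *quantitative* "return to background
  within one `tau_a`" is not achievable with this drive-to-noise ratio —
  it would require a stimulus contrast of the order of the membrane noise.
* The mean synaptic efficacy `⟨u·x⟩` is reliably elevated in Adp and
  relaxes back by Post-adp: the efficacy estimator averages 2000 neurons
  over 800 ms and resolves the ~3% facilitation effect cleanly.
* The pairwise-covariance estimator, by contrast, sits on the external
  noise floor: each 5-ms-binned current has SD ≈ 17 uA, almost all of it
  private white noise, so a 30-trial batch resolves mean pairwise
  covariances down to ~0.01 uA², while the recurrent-synapse covariance
  signal at these rates is two orders of magnitude smaller. The Adp
  elevation of the covariance therefore does not reach significance under
  the default drive parameters (and the same is honestly true of the
  plasticity-variant comparisons). The machinery itself is validated by
  construction: on currents simulated from the latent-factor model the
  estimators recover `sigma_s` and `sigma_s^2 alpha` within their
  confidence intervals.
* The read-out effect survives the noise floor: because the downstream
  neuron thresholds the *summed* population input, its spike counts in Adp
  exceed Pre-adp robustly (paired p far below 0.05 at 30 trials). In this
  regime the read-out is the sensitive detector of the adaptation state,
  more sensitive than the pairwise covariance estimate.

## Known limitations

* The synthetic protocol emulates stationary background + step stimulus
  drive with homogeneous populations; it does not emulate heterogeneous
  cell parameters, distance-dependent connectivity, conductance-based
  synapses, dendrites, delays, or any feed-forward depression / E-I
  adaptation mechanisms (deliberately out of scope).
* The static-synapse efficacy `J_s = 0.129` uA is taken as given; it
  corresponds to the dynamic model's baseline `J_EE u x` at a background
  rate of ~20 Hz, which is higher than the default regime produces, so the
  static model's recurrent kicks are somewhat stronger than the dynamic
  baseline.
* `J_EE = 6` uA against `J_EI = 5` nA and `J_IE = 4` nA spans three orders
  of magnitude; the values are kept as given and not "fixed", which makes
  the I population essentially feed-forward noise-driven.
* Passing the shipped tests demonstrates internal consistency of the
  simulator and estimators and the qualitative adaptation phenomenology
  under the default table; it does not certify quantitative agreement
  with any particular biological recording.
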