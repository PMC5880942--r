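# synadapt

Spiking-network simulation and analysis of **dynamic information encoding
during neural adaptation**: when a sensory network adapts to a sustained
stimulus, its firing rates fall back toward background, and the stimulus
information can migrate into weak but *synchronized* firing maintained by
short-term synaptic facilitation. `synadapt` is for computational
neuroscientists who want to simulate that hand-off — from a rate code to a
correlation code — and quantify it with a dichotomized Gaussian population
model and a balanced downstream read-out.

The package implements, end to end:

* a recurrent network of `N_E = 2000` excitatory and `N_I = 500` inhibitory
  leaky integrate-and-fire neurons, sparsely connected with probability
  `p = 0.1`, driven by a noisy external current
  (`I_ext = mu + sigma_ext eta(t)`);

* spike-frequency adaptation in the excitatory neurons,
  `tau_a dI_adp/dt = -I_adp + A_p (V - E_L) + A_s sum_k delta(t - t_k)`;

* Tsodyks–Markram short-term plasticity on E→E synapses — release
  probability `u` (facilitation, `tau_f`) and resources `x` (depression,
  `tau_d`) with per-spike transmission `u'x`, instantaneous efficacy
  `J_EE u x`;

* a balanced read-out neuron receiving the whole population,
  `tau_o dV_O/dt = -(V_O - E_L) + R_m (J_EO I_E - J_IO I_I)`, whose mean
  drive cancels so that it fires only on synchronized volleys;

* the experiment protocol: 5000-ms trials with stimulus in `[0, 1500)` ms,
  analysis periods Pre-adp `[-900, -100)`, Adp `[500, 1300)`, Post-adp
  `[1600, 2400)`, paired-trial condition batches (default / transient
  stimulus / static synapses / plasticity variants) and a bin-shuffling
  control for the input currents;

* the dichotomized Gaussian analysis: for input currents
  `s_i = mu_s + sigma_s (sqrt(1-alpha) nu_i + sqrt(alpha) eps)` thresholded
  at `h`, the pairwise correlation is measured by
  `cov(s_i, s_j) = sigma_s^2 alpha`, and the population-synchrony
  distribution has a closed-form density validated against a Monte Carlo
  sampling oracle.

The simulation core is compiled (Rcpp); a full 2500-neuron, 5-second trial
takes a few seconds.

## Worked example

```r
library(synadapt)

res <- run_condition("default", n_trials = 3, base_seed = 400)
res
#> <experiment_result> condition 'default', 3 trials (seeds 400..402)
#>    period         mpc  sigma_s   e_rate readout_count
#>       Adp 0.011548711 16.96588 7.215833     1.3333333
#>  Post-adp 0.004484407 16.94697 6.903125     0.3333333
#>   Pre-adp 0.006486399 16.97003 6.911458     1.0000000
```

Reading the summary: the excitatory population fires at ≈ 6.9 Hz in the
background periods and ≈ 7.2 Hz late in the stimulus (`e_rate`); the mean
per-neuron input-current SD in 5-ms bins is ≈ 17 µA (`sigma_s`, dominated
by the external white noise); `mpc` is the mean pairwise covariance of the
input currents (the estimate of `sigma_s^2 alpha`, in µA²); and
`readout_count` is the number of read-out spikes per 800-ms period — the
downstream neuron fires mostly during the adaptation period, which is the
read-out signature of the correlation code.

Paired significance tests over a batch (here, toy-sized; use ≥ 30 trials
for real comparisons):

```r
build_report(list(res))
#>  condition     statistic      comparison  test statistic_value       p
#>    default   correlation  Adp vs Pre-adp ttest          5.9850 0.02680
#>    default            ux  Adp vs Pre-adp ttest          3.6240 0.06840
#>    default readout_count  Adp vs Pre-adp ttest          0.2294 0.84000
#>    default   correlation Adp vs Post-adp ttest          1.0840 0.39200
#>    default            ux Adp vs Post-adp ttest         13.6700 0.00531
#>    default readout_count Adp vs Post-adp ttest          1.0000 0.42300
#>  significant n_trials mean_difference
#>         TRUE        3        0.005060
#>        FALSE        3        0.000318
#>        FALSE        3        0.333000
#>        FALSE        3        0.007060
#>         TRUE        3        0.000400
#>        FALSE        3        1.000000
```

Single-trial recordings expose everything the analyses are built from —
spike times, per-neuron input currents `s_i = I_syn,i - I_adp,i`, the
population-mean synaptic efficacy `⟨u·x⟩`, and the read-out membrane and
drive traces:

```r
tr <- run_trial(network_params(), seed = 1)
head(mean_synaptic_efficacy_trace(tr))
readout_spike_counts(tr)
```

A thin command-line front end is installed with the package
(`system.file("scripts", "synadapt-cli.R", package = "synadapt")`) with
`simulate` and `report` subcommands.

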