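# ribbonsyn

Kinetic modelling and simulation-based Bayesian inference for glutamate
release at photoreceptor ribbon synapses.

Cone photoreceptors release glutamate tonically through ribbon synapses, and
terminals of the *same* cone type can be tuned very differently depending on
where they sit in the retina — more transient in some regions, more sustained
in others. `ribbonsyn` is for researchers who record paired presynaptic
calcium and glutamate signals from single terminals (two-photon imaging with
a red calcium indicator and a glutamate sensor) and want to explain those
recordings mechanistically: which combination of vesicle-pool sizes, refill
rates and calcium sensitivity produces a given calcium-to-glutamate transfer
function?

## The model

A terminal is a cascade of three vesicle pools — reserve (RP), intermediate /
ribbon-tethered (IP), readily releasable (RRP) — with occupancy-dependent
transfer, a recycling compartment (Exo), and release gated by calcium
through a logistic non-linearity:

```
r = r_max (1 - IP/IP_max) RP/RP_max          RP -> IP
i = i_max (1 - RRP/RRP_max) IP/IP_max        IP -> RRP
e = e_max f(Ca) RRP/RRP_max                  release,  f(Ca) = 1/(1 + exp(-k (Ca - x0)))
d = d_max Exo                                recycling
```

Seven parameters are free: `(r_max, i_max, e_max, k, x0, IP_max, RRP_max)`.
Around the model the package provides:

- a fast adaptive Runge–Kutta 3(2) simulator (C++) plus an independent
  algebraic steady-state solver;
- a linear–nonlinear light-to-calcium cascade `Ca = k2 * exp(k1 * s)`;
- preprocessing of raw fluorescence (baseline correction, bright-interval
  z-scoring, zero-phase Butterworth, Wiener deconvolution of the indicator
  kernel);
- response indices: transience, on/off event-detection indices, a
  high-frequency index;
- a 14-feature summary statistic and weighted "relevant loss";
- sequential neural posterior estimation with a mixture-density network
  conditioned on the loss (half-uniform/half-Gaussian calibration kernel,
  percentile pseudo-observations, early stopping);
- time-resolved first-order Sobol sensitivity indices;
- a ridge-regression baseline from lagged calcium to glutamate;
- a synthetic-recording generator so the entire pipeline runs and is tested
  without any experimental data.

## Worked example

Simulate the standard stimulus protocol (5 s adaptation at 50% contrast,
then three 3 s bright / 3 s dark full-contrast UV flashes) for a reference
parameter set, and quantify the flash responses:

```r
library(ribbonsyn)

p <- ribbon_params(r_max = 2.5, i_max = 2.5, e_max = 10, k = 14,
                   x0 = 0.5, IP_max = 13.8, RRP_max = 4)
proto <- make_flash_protocol(n_flashes = 3)
ca <- light_to_calcium(proto$stimulus,
                       make_biphasic_kernel(proto$stimulus$dt),
                       make_double_exp_kernel(0.3, proto$stimulus$dt),
                       range = c(0, 1))
traj <- simulate_release(p, ca)
traj
#> <pool_trajectory> 2300 samples over 23 s; final release 0.6872 v.u./s

max_sustain_transience(traj$release, proto$annotations$dark_onsets)
#>     max sustain transience defined
#> 1 3.913   0.639      0.837       1
#> 2 3.886   0.631      0.838       1
#> 3 3.868   0.628      0.838       1
```

Release jumps at each light offset (the cone is an OFF cell: dark raises
calcium) to a ~3.9 v.u./s peak, then decays towards a ~0.64 v.u./s sustained
plateau as the releasable pool drains faster than it refills — a transience
index of ~0.84 for every flash. The summary features used for fitting
include that peak, the vesicles released per activation and the decay
kinetics:

```r
round(extract_features(traj$release, proto$annotations)[
  c("first_max", "int_first", "decay_tau")], 3)
#> first_max int_first decay_tau
#>     4.248     3.940     0.516
```

Synthetic "recordings" with regionally tuned presets reproduce the
qualitative regional ordering of transience:

```r
for (z in c("az", "nasal", "dorsal")) {
  rec <- generate_recording(synthetic_study(zone_preset(z)), seed = 8)
  tz <- max_sustain_transience(rec$truth$release, rec$annotations$dark_onsets)
  cat(sprintf("%-7s transience (first flash): %.3f\n", z, tz$transience[1]))
}
#> az      transience (first flash): 0.754
#> nasal   transience (first flash): 0.503
#> dorsal  transience (first flash): 0.895
```

The full workflow — synthetic recording, preprocessing, feature
normalisation, sequential inference, posterior predictive check, indices,
ridge baseline, Sobol analysis — is chained by `run_pipeline()`; see the
vignette `vignettes/ribbon-release-modelling.Rmd` for the model, the
inference scheme and every numerical choice.

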