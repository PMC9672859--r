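# flimr

Poisson maximum-likelihood fitting of fluorescence lifetime (FLIM/TCSPC)
decays, and a two-stage segmented analysis pipeline for FRET tension-sensor
imaging in vivo.

## The problem

FRET-based tension sensors report molecular forces through the lifetime of
their donor fluorophore: stretching the sensor lowers FRET and raises the
donor lifetime. Measuring that lifetime in live tissue is hard — strong
autofluorescence, scattered background light, and low per-nucleus photon
counts all push conventional least-squares decay fitting off the true
value. `flimr` addresses each obstacle explicitly:

* **Poisson likelihood**, the correct counting statistic at low photon
  numbers, instead of Gaussian least squares;
* an **instrument-response-convolved** bi-exponential model (FFT-accelerated
  convolution on a uniform grid), separating fast autofluorescence from the
  sensor signal;
* **automatic endpoint selection** that treats the data cutoff as a fit
  variable, excluding late background-dominated bins without manual bias;
* **automatic mono/bi model-order selection** (amplitude-fraction, lifetime
  separation and BIC rules);
* a **two-stage pipeline**: autofluorescence lifetime and IRF are calibrated
  once on the full field of view, then frozen while each segmented nuclear
  envelope is fit for its signal lifetime alone — so per-segment fits stay
  well-posed at photon counts where a joint six-parameter fit is not.

## The model

The measured decay is modelled as

    m(t) = IRF(mu, sigma) * [ A_auto exp(-t / tau_auto) + A_signal exp(-t / tau_signal) ]

with `*` denoting convolution and the IRF a narrow Gaussian (a measured IRF
histogram may be substituted). Parameters are estimated by minimising the
Poisson negative log-likelihood

    NLL = sum_i ( m_i - n_i log m_i )

over bins `i`, with the endpoint (last bin used) chosen by maximising a
goodness-of-fit statistic over candidate truncations. Repetition-rate
wrap-around of long-lived emission is modelled exactly during fitting by a
periodic (circular) convolution over the laser period. Details, including
the endpoint statistic and its analysis, are in the methods vignette
(`vignettes/flim-decay-fitting.Rmd`).

## Worked example

Fit a single simulated decay (ground truth: lifetime 2.5 ns, IRF mu 1 ns,
sigma 0.1 ns, 20k photons):

```r
library(flimr)
truth <- simulation_truth(tau_signal = 2.5, fraction_auto = 0, n_photons = 2e4)
hist  <- simulate_decay(truth, seed = 1)
fit   <- fit_decay(hist, fit_config(model_order = "mono"))
fit
#> <flim_fit: mono-exponential convolution fit>
#>   signal lifetime: 2.4953 ns
#>   IRF: mu = 0.9977 ns, sigma = 0.0986 ns
#>   NLL: -80003.9439 over 250 of 250 bins
```

The fitted lifetime (2.4953 ns) recovers the 2.5 ns truth within 0.2%, and
with no background in the data the endpoint sweep keeps all 250 bins.
`tidy(fit)`, `glance(fit)` and `autoplot(fit)` give the parameter table, a
one-row summary, and the fit plot; `plot_endpoint_sweep(fit)` shows the
goodness-of-fit trace used to place the cutoff.

Run the full segmented pipeline on a synthetic scene of ten nuclear-envelope
rings whose signal lifetimes ramp from 2.0 to 3.2 ns (a proximodistal-style
gradient), 10k photons each over six timepoints:

```r
scene <- gradient_scene(n_rings = 10, photons_per_ring = 1e4)
sim   <- simulate_scene(scene, seed = 7)
pipe  <- run_flim_pipeline(sim$images, sim$mask, fit_config(seed = 7))
pipe$calibration
#> <field_calibration: bi-exponential full-field fit>
#>   autofluorescence lifetime: 0.4371 ns
#>   IRF: mu = 0.9979 ns, sigma = 0.0977 ns
tidy(pipe)[, c("segment_label", "tau_signal_ns", "photon_count", "qc_accepted")]
#> # A tibble: 10 × 4
#>    segment_label tau_signal_ns photon_count qc_accepted
#>  1             1          2.01        10000 TRUE
#>  2             2          2.13        10000 TRUE
#>  ...
#> 10            10          3.20        10000 TRUE
```

The calibration recovers the simulated autofluorescence (0.4 ns) and IRF
(1.0/0.1 ns) from the pooled field, and the per-segment lifetimes (2.01 …
3.20 ns) track the simulated gradient in exact rank order. The results
table carries lifetimes, IRF parameters, NLL, endpoint, photon counts,
ellipse shape metrics (aspect ratio, roundness) and QC decisions per
segment; `write_results_csv()` exports it.

## Command line

A thin CLI wraps the same functions (`inst/cli/flimr` after installation):

```sh
flimr simulate --out-dir scene --rings 10 --photons 10000 --seed 7 --ptu
flimr pipeline --ptu scene --mask scene/mask.tif --out-dir results
flimr fit decay.csv --model auto --mode convolution
```

`fit` takes a two-column CSV decay histogram; `pipeline` takes PicoQuant PTU
event files (PicoHarp T3) plus a 16-bit TIFF label mask and writes the
results CSV, a rejection log and a reproducibility manifest. Exit codes: 0
success, 1 computation failed (e.g. unconverged fit), 2 usage or input
error.

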