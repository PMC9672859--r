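---
title: "Fitting in vivo FLIM decays: model, endpoint selection, and the two-stage segmented pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting in vivo FLIM decays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimr)
```

## The measurement and the model

Time-correlated single photon counting (TCSPC) histograms the delay between
each laser pulse and the next detected photon. For a FRET-based tension
sensor imaged in vivo, the photons reaching the detector mix two
fluorescence populations plus stray light:

* a **fast autofluorescence** component, endogenous fluorophores unrelated to
  the sensor, with lifetime $\tau_{\mathrm{auto}}$ (a few hundred ps);
* the **sensor signal** (the mTFP donor), lifetime $\tau_{\mathrm{signal}}$
  (a few ns); this is the quantity of interest — donor lifetime rises as
  FRET drops, i.e. as tension stretches the sensor;
* **background**: scattered and ambient photons, approximately uniform over
  the TCSPC window.

The emission model is a bi-exponential,
$d(t) = A_{\mathrm{auto}} e^{-t/\tau_{\mathrm{auto}}} +
A_{\mathrm{signal}} e^{-t/\tau_{\mathrm{signal}}}$, with amplitudes in
expected counts multiplying unnormalised exponentials. What the instrument
records is this decay blurred by the instrument response function (IRF),
modelled as a narrow Gaussian with centre $\mu$ and width $\sigma$; a
measured IRF histogram can be substituted (`measured_irf()`), but in our
testing the Gaussian gives equivalent signal lifetimes. The expected curve
is the convolution of decay and IRF, computed by FFT on a uniform time grid.

Fitting is by maximum likelihood under per-bin Poisson statistics,
minimising the negative log-likelihood
$\mathrm{NLL} = \sum_i \left( m_i - n_i \ln m_i \right)$
(`poisson_nll()`), where $m_i$ is the model-expected and $n_i$ the observed
count; the $\ln n_i!$ constant is dropped. The Poisson assumption, rather
than the Gaussian one implicit in least squares, matters precisely in the
low-count regime this package targets.

## Numerical construction of the model curve

Three numerical choices matter and are worth stating exactly.

**Bin-integrated decay.** The exponential has a step at its origin. Sampling
it at bin centres gives a discrete convolution with $O(\Delta t)$ error at
the rising edge, which is where $\mu$ and $\sigma$ are determined. We
therefore represent the decay by its exact integral over each bin divided by
the bin width; this treats the step exactly and leaves only $O(\Delta t^2)$
error from the kernel discretisation. `model_curve()` agrees with the
analytic exponentially-modified-Gaussian (EMG) closed form
(`emg_curve()`, kept strictly outside the fitting path as an independent
oracle) to better than $10^{-4}$ relative at fine binning wherever the curve
carries at least $10^{-3}$ of its peak — below that, in the deep left tail
of the Gaussian, relative precision is meaningless for a counting model.

**Zero-padded versus periodic convolution.** The public `model_curve()`
zero-pads to the next power of two above twice the grid length, so circular
wrap-around cannot corrupt the rising edge, and conserves total counts to
$10^{-6}$ relative whenever the IRF mass and the decayed signal lie inside
the grid. The *fitting* path defaults to a **periodic** model
(`fit_config(periodic = TRUE)`): pulsed excitation repeats every sync
period, so long-lived emission from earlier pulses appears as a pedestal
ahead of the rising edge. The geometric sum of an exponential over all
previous pulses is the same exponential scaled by
$1/(1 - e^{-W/\tau})$ ($W$ the laser period, equal to the grid span), so the
periodic curve is computed exactly by circular convolution over the full
grid. This is not a cosmetic choice: on simulated data with realistic
wrap-around, the single-pulse model biases the full-field autofluorescence
lifetime by tens of percent and breaks model-order selection, while the
periodic model recovers all parameters to a few percent. Endpoint
truncation never changes the wrap period: the curve is always evaluated on
the full grid and then truncated.

**Decay origin.** In convolution mode the decay origin is pinned to the
start of the grid and the IRF centre $\mu$ carries the time shift, removing
the degenerate $(t_0, \mu)$ parameter pair. Tail mode (`mode = "tail"`)
fits the unconvolved exponential from an explicit or derived start time
(default: peak bin plus $5\hat\sigma_0$, beyond IRF influence).

## Optimisation

Positivity of lifetimes, amplitudes and $\sigma$ is enforced by a log
transform; $\mu$ is unconstrained. Minimisation is Nelder–Mead with a
polishing restart, with deterministic multistart (default 3) perturbing the
free lifetimes by factors $\{1, 0.5, 2\}$; the best NLL wins and ties break
toward the smaller signal lifetime. Initial values are cheap, scale-aware
statistics of the data: $\mu_0$ at the peak bin, $\sigma_0$ from the
rising-edge half width at half maximum divided by 1.177, $\tau_0$ from the
mean arrival time past the peak, and amplitudes from total counts (split
20/80 autofluorescence/signal in bi mode). Everything is deterministic
given the configuration, so identical inputs produce bit-identical fits;
frozen parameters (`fixed =`) pass through to the result untouched, to the
last bit. In two-component fits the shorter-lifetime component is by
convention the autofluorescence; when both lifetimes are free the components
are swapped if needed to keep that ordering.

Lifetimes below one bin width are physically unresolvable; a warm-start
chain in the endpoint sweep that drifts into such a spike is restarted from
data-driven initial values, and the final refit compares a warm start
against a cold start and keeps the better likelihood.

## Endpoint selection

Late TCSPC bins are dominated by background and scattered light, which
drags lifetime fits upward. The cutoff bin (endpoint) is therefore treated
as a fit variable: the decay is refit at candidate endpoints (every 16 bins
from peak + 30 bins to the end, then refined at stride 2 around the best
candidate, each refit warm-started from its neighbour) and a selection
statistic is evaluated per candidate.

The statistic deserves care, because the obvious ratio of the raw NLL to
$\sqrt{N}$ is degenerate: with the $\ln n!$ constant dropped the NLL is
large and negative, its magnitude grows with the data, and the ratio is
optimised at the boundary of the candidate range for essentially any data —
it never actually cuts. The scale-free quantity is the Poisson deviance,
$D = 2(\mathrm{NLL} - \mathrm{NLL}_{\mathrm{sat}})$, the NLL measured
against the saturated model on the same bins. The default criterion
(`endpoint_criterion = "gof_sqrt"`) maximises
$$ \frac{N - D/2}{\sqrt{N}}, $$
the saturated-relative log-likelihood, mean-adjusted by the expected
per-bin deviance ($E[D] \approx N$ for a well-specified fit), per square
root of the number of points. Under a good fit the score grows like
$\sqrt{N}/2$, so clean data keeps the full range; differentiating shows the
score turns down where the marginal per-bin deviance exceeds about 1.5, so
the sweep cuts where background misfit starts. In simulation (uniform
background at 5% of the peak, 1e4 photons), selected endpoints fall at
roughly bins 176–229 of 250 and reduce the mean lifetime error by ~20–60%
relative to full-range fits, while background-free data selects the last
decile of bins. The literal raw-NLL ratio (`"nll_sqrt"`), the deviance
ratio (`"deviance_sqrt"`) and per-bin deviance (`"per_bin"`) remain
available; the sweep trace is kept on the fit object for plotting
(`plot_endpoint_sweep()`).

One subtlety: the sweep itself always fits the single-pulse model. The
periodic wrap term can imitate a uniform background floor at short windows,
which would let contaminated short-window fits score as well as clean ones
and collapse the selection to the minimum window (we measured exactly this).
The rigid single-pulse model surfaces background as misfit; the selected
endpoint is then refit under the configured (periodic) model for the
reported parameters.

## Model-order selection

The full field is fit both mono- and bi-exponentially at the same endpoint
and the bi-exponential is retained only if it looks genuinely
two-component (`assess_model_order()`): each amplitude fraction at least
1%, lifetime ratio at least 1.5, and a BIC on the Poisson likelihood
(penalising the two extra parameters by $2\ln N$) favouring it. The
separation rule is what resolves the unidentifiability of two equal fitted
lifetimes, and BIC protects low-count data where the bi fit is ill-posed.
At $10^5$ photons, simulated mono data selects mono and simulated bi data
(0.4/2.8 ns, 30/70) selects bi in 100% of 40 seeded runs each.

## The two-stage segmented pipeline

Per-nucleus photon counts in vivo are rarely sufficient for a six-parameter
fit. The pipeline therefore decouples what is global from what is local:

1. **Aggregate** (`aggregate_timepoints()`): photons are summed bin-wise per
   segment across all timepoints (default six frames at 2-minute intervals),
   and over every pixel — including non-segmented tissue — for the full
   field. All sums are exact integer arithmetic.
2. **Calibrate** (`calibrate_field()`): the full field is fit in convolution
   mode with automatic model order, establishing
   $\tau_{\mathrm{auto}}, \mu, \sigma$. Autofluorescence is unrelated to the
   sensor, so the entire field of view legitimately informs it; this
   maximises the data behind the hardest part of the fit. A non-convergent
   calibration is a hard pipeline failure. If the field selects mono, there
   is no separable autofluorescence and segments are fit mono with only
   $\mu, \sigma$ frozen.
3. **Fit segments** (`fit_segment()`): each segment is fit with
   $\tau_{\mathrm{auto}}, \mu, \sigma$ frozen, leaving the signal lifetime
   and two amplitudes free, with the endpoint chosen per segment. In
   simulation (2e3 photons/segment, calibration from a 5e5-photon field)
   this recovers signal lifetimes with lower RMSE and lower variance than
   joint per-segment fits — the package's reason to exist.
4. **QC filter** (`qc_filter()`): segments are rejected, with logged
   reasons, for photon count below 1000, non-convergence, fitted lifetime
   outside 0.1–10 ns, or an endpoint window under 30 bins.
5. **Export**: a per-segment results table (CSV) with lifetimes, IRF
   parameters, NLL, endpoint, photon count and shape metrics.

At most 15 segments per image are analysed (the brightest first), mirroring
a practical per-image target while bounding runtime; `normalize_group()`
divides lifetimes by their experiment's grand mean so sessions can be
pooled.

Per-segment counts below 1000 are a QC outcome (`status = "low_counts"`),
not an exception: with three free parameters under Poisson noise, fits
below roughly that count were empirically unstable in our simulations.

## Shape metrics and axis splitting

Nuclear envelope segments come in as integer label masks (16-bit TIFF).
Each label is one record; shape metrics come from the second central
moments of the pixel coordinates: the image-moment ellipse, with axis
lengths $4\sqrt{\lambda}$ from the covariance eigenvalues, orientation
measured from the image row axis in $(-\pi/2, \pi/2]$, aspect ratio
major/minor and roundness its reciprocal (the isoperimetric $4\pi A/P^2$ is
available behind a flag; the axis ratio matches the length/width language
used for nuclear shape). Degenerate (collinear) pixel sets get an infinite
aspect ratio and are left to QC. Envelope pixels split into long-axis and
short-axis arcs by whether the pixel direction from the centroid lies
within 45° of the major axis — equivalently, by comparing the magnitudes of
its projections on the two axes — a symmetric, parameter-free rule that
always partitions the pixel set; below aspect ratio 1.05 the axes are
ill-defined and a warning is attached.

## The synthetic-data generator

Every fitting and pipeline claim above is tested against
`simulation_truth()` / `simulate_scene()`, which generate what the model
family describes plus the two realities that stress it: photons pick a
component (autofluorescence / signal / uniform background) by mixture
fractions, exponential components get Gaussian IRF jitter, and arrival
times past the window **wrap modulo the window** by default, emulating
repetition-rate wrap-around (clipping is available). Scenes place
elliptical-ring ROIs — stand-ins for optical sections of nuclear envelopes
— on a field, each with its own truth and photon budget split exactly
across six timepoints, with non-ROI pixels fed by a field-background truth.

Defaults ($\tau_{\mathrm{auto}} = 0.4$ ns, $\tau_{\mathrm{signal}} = 2.8$
ns, $\sigma = 0.1$ ns, $\mu = 1$ ns, 12.5 ns window, 250 bins) are
plausible for an mTFP donor on an 80 MHz pulsed system. What the generator
does **not** emulate — detector afterpulsing, dead time, pile-up, optical
blur of the rings, motion between timepoints — bounds what passing tests
show: they validate the estimator against its own statistical model plus
background and wrap-around, not against every instrumental artefact of real
hardware.

## Problem sizes and runtime

The shipped tests and the acceptance script use: 50 seeded replicates for
estimator calibration at $10^3$–$10^5$ photons; 5 seeds × 30 segments at
2×10^3 photons against a 5×10^5-photon calibration field for the
decoupling comparison; 20 seeds for the background/endpoint study; 40 runs
per truth for model-order rates; and a 10-ring gradient scene at $10^4$
photons per segment end to end. These sizes give stable aggregates (rates
within a few percent across seeds) while a full run of either suite stays
in the minutes range on one core.

## A worked example

```{r example, eval = FALSE}
library(flimr)

scene <- gradient_scene(n_rings = 10, photons_per_ring = 1e4)
sim <- simulate_scene(scene, seed = 7)
pipe <- run_flim_pipeline(sim$images, sim$mask, fit_config(seed = 7))
tidy(pipe)
glance(pipe)
autoplot(pipe)
```

## Known limitations

* Two exponential components at most; stretched exponentials, three or more
  components, and phasor analysis are out of scope.
* No global multi-curve fitting of shared lifetimes: the calibration/freeze
  scheme is the (cheaper, more robust at low counts) alternative.
* The uniform-background model exists only in the generator and in the
  endpoint criterion's rationale; the fitted model carries no background
  term, by design — background is excluded by cutting, not modelled.
* PicoHarp T3 is the supported PTU record type; marker-bit conventions vary
  by acquisition software and are configuration (`marker_config()`), never
  hard-coded.
* FRET efficiency and force conversion are out of scope: they require a
  sensor calibration curve this package does not own.
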