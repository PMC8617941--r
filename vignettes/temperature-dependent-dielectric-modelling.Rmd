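---
title: "Temperature-dependent Cole-Cole modelling of muscle permittivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent Cole-Cole modelling of muscle permittivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieltemp)
```

## The model

Biological tissue in the microwave band is dominated by the gamma
dispersion, the relaxation of free water. Over 0.5--40 GHz a single-pole
Cole-Cole model with a static-conductivity term describes a high-water
tissue such as skeletal muscle:

$$\epsilon(f) = \epsilon' - j\epsilon'' = \epsilon_\infty +
\frac{\Delta\epsilon}{1 + (j 2\pi f \tau)^{1-\alpha}} +
\frac{\sigma_s}{j 2\pi f \epsilon_0},$$

with $\epsilon_\infty$ the permittivity above the modelled relaxation,
$\Delta\epsilon$ the dispersion increment, $\tau$ the relaxation time
(picoseconds in tabulated form, seconds internally), $\alpha \in [0,1)$ the
symmetric broadening exponent ($\alpha = 0$ is Debye) and $\sigma_s$ the
static ionic conductivity in S/m. `evaluate_permittivity()` implements this
for any number of poles; the sign convention makes the conductivity term
contribute $+\sigma_s/(2\pi f\epsilon_0)$ to the loss $\epsilon''$, and
$\epsilon_0$ is fixed at the CODATA value so printed-precision checks are
platform independent.

Tissue temperature moves all five parameters. The package's central object,
a `temperature_model`, gives each parameter a polynomial law in temperature
(degrees Celsius) over a stated validity range, here 20--45 °C:
first-order laws $p_0 + p_1 T$ by default, second-order as an alternative.
The packaged muscle laws are:

```{r}
muscle_temperature_model()
model_at_temperature(muscle_temperature_model(), 37)
```

Two consequences of the fitted laws are worth noting. First,
$\epsilon_\infty(T)$ falls below 1 above roughly 40 °C (0.3959 at 45 °C);
the package therefore bounds $\epsilon_\infty$ at 0, not at the physical
vacuum limit of 1, since a bound of 1 would reject the fitted model itself.
$\epsilon_\infty$ here is an effective low-inertia limit of a band-limited
fit, not a physical optical permittivity. Second, the real-permittivity
curves at two temperatures intersect: `crossover_frequency()` locates the
crossover by bisection (relative tolerance 1e-9) after a log-spaced scan
for sign changes. For the packaged model the 20/45 °C crossover sits at
6.53 GHz, and all 28 temperature-pair crossovers fall between about 6.1 and
7.1 GHz, so the model predicts a sharp crossover in a narrow band rather
than the broader crossover zone seen in measurements of water-rich tissue.

## Two-stage inference

`fit_single_pole()` fits one complex sweep by bounded Levenberg-Marquardt
least squares on the stacked residual
$[\epsilon'_{model}-\epsilon'_{data},\ \epsilon''_{model}-\epsilon''_{data}]$
with equal unit weight for the two parts and no frequency weighting.
Choices that matter:

* **Bounds** (defaults): $\epsilon_\infty \in [0,20]$,
  $\sigma_s \in [0,10]$ S/m, $\Delta\epsilon \in [0,200]$,
  $\tau \in [0.1,100]$ ps, $\alpha \in [0,0.5]$ — generous envelopes around
  every published muscle model. Returned parameters always respect them.
* **Start**: the literature gamma-dispersion point
  ($\epsilon_\infty = 4$, $\sigma_s = 0.2$, $\Delta\epsilon = 50$,
  $\tau = 7.23$ ps, $\alpha = 0.1$), a reproducible, in-bounds default.
* **Scaling**: $\tau$ is optimized in picoseconds so Jacobian columns are
  comparably scaled; results are reported in SI.
* **Tolerances**: cost and step tolerances 1e-10, at most 5000 residual
  evaluations. Non-convergence is flagged on the result, never thrown.
* `residual_norm` on a fit result is the final cost (sum of squared stacked
  residuals). In degenerate cases (e.g. a constant sweep, where
  $\Delta\epsilon$ sits on its lower bound and $\tau$, $\alpha$ lose
  identifiability) the optimizer stalls at a cost near machine precision
  while the gradient is flat; the cost, not the step size, is the honest
  convergence measure there.

`fit_parameter_polynomials()` then regresses each of the five per-sweep
parameters on the *recorded* sample temperature — the temperature at the
moment of measurement, not the water-bath setpoint — by ordinary least
squares, reporting $R^2 = 1 - SS_{res}/SS_{tot}$ per parameter. By default
every sweep contributes one point (replicate scatter is information);
`aggregate = "per_temperature"` first averages replicates, for study
designs that prefer it. Because the quadratic law nests the linear one, the
order-2 $R^2$ can never be smaller on the same points, which the tests
assert on every generated dataset.

A law fitted to noisy or misspecified data can stray marginally outside
its parameter's admissible range near the edge of the temperature interval
(a slightly negative $\epsilon_\infty$ at 45 °C, say). Such laws are
accepted with a warning at the fitting stage, and `model_at_temperature()`
clamps evaluated values into the admissible range (again with a warning)
so an instantiated model is always physical. `run_fit()` additionally
requires the number of distinct *set* temperatures, not the jitter-spread
actual ones, to support the requested polynomial order: jitter within one
setpoint is no basis for a temperature law.

`model_rmse()` scores a temperature model against a campaign by pooling
real-part and imaginary-part residuals over all frequencies of all sweeps
with equal weight and taking the root mean square.

## Uncertainty budget

`combined_uncertainty()` implements a standard root-sum-of-squares budget
at the permittivity level from pre/post validation sweeps on a reference
liquid, per frequency and separately for $\epsilon'$ and $\epsilon''$:
random (pooled sample standard deviation across all validation sweeps),
systematic (absolute deviation of the grand mean from the reference-model
evaluation), drift (absolute difference of post-run and pre-run means), and
$s_{comb} = \sqrt{random^2 + systematic^2 + drift^2}$. The decomposition is
isolated behind this one function so an alternative budget is a drop-in.
Both the drift and systematic terms are taken as absolute values, and the
reference permittivity is a required input (any `cole_cole_model`): the
package ships no saline model and the synthetic generator produces
validation sweeps from a known model instead. Error bars are
$\pm 1\, s_{comb}$, and `significant_difference()` calls two measurements
different where those bars do not overlap — touching bars do not count.

One statistical note: a per-frequency sample standard deviation estimated
from 20 validation sweeps has a relative dispersion of about
$1/\sqrt{2 \cdot 19} \approx 16\%$, so a recovery check of a known noise
scale can only be tight on an across-frequency aggregate; the tests check
the across-frequency median within 15% and give individual frequencies a
loose sanity band.

## What the synthetic generator emulates

`generate_campaign()` reproduces the statistical structure of a controlled
probe campaign: 8 set temperatures (20, 25, 30, 35, 37, 40, 43, 45 °C),
3 samples × 3 probing sites per temperature (72 sweeps), a 0.5--40 GHz
grid in 25 MHz steps (1581 points, serialized as exact integers in Hz).
Per sweep it draws an actual temperature around the setpoint
(default jitter 0.5 °C — a configuration default chosen at the scale of
reported set-vs-actual deviations, not a published number), evaluates the
truth model, optionally adds an unmodelled slow dispersion pole
(`default_delta_tail()`: $\Delta\epsilon = 7000$, $\tau = 353.68$ ns,
$\alpha = 0.1$; relaxation frequency 0.45 MHz), applies a multiplicative
contact-pressure effect $1 - 0.003\,(p - 15\,\mathrm{kPa})$ with pressure
drawn as $14.6 \pm 0.61$ kPa, and adds independent Gaussian noise to both
parts (default scale 0.5, again a configuration default at the order of
magnitude of reported measurement scatter — every test states the value it
uses). Campaign metadata (room humidity $71.4 \pm 0.9\%$, room temperature
$20.6 \pm 0.4$ °C, sample weights with relative loss below 1% up to 40 °C
and up to 6% above) is drawn to emulate an environment log; dehydration
affects only the recorded weights unless an explicit coupling is switched
on. Everything is bit-reproducible from the design seed.

What it does **not** emulate: probe electromagnetics and calibration error
structure (frequency-correlated, not i.i.d.), tissue heterogeneity across
sites, dispersions below 0.5 GHz beyond the single optional tail pole, and
dehydration kinetics. Passing recovery tests therefore demonstrate that the
inference machinery is unbiased and well-conditioned under the stated
noise model — not that real tissue data would be recovered equally well.

## The misspecification experiment

Fitting a single gamma pole to data whose low end carries the tail of a
slow dispersion skews the fit in a characteristic way: $\epsilon_\infty$
drops while $\Delta\epsilon$ and $\alpha$ rise to absorb the extra
$\epsilon'$, and $\sigma_s$ rises to absorb the extra loss. The package
reproduces all four directions on a delta-contaminated campaign, and the
second-order temperature laws then score a lower campaign RMSE than the
first-order ones. This experiment is run **noise-free** (tail and
temperature jitter only): at the default noise scale of 0.5 the two RMSEs
differ by a few parts in 10^5 and their ordering is decided by noise, not
by the model — isolating the misspecification effect is the point of the
experiment. A genuine two-pole fit of measured-band data remains available
behind `fit_single_pole(..., two_pole = TRUE)` but is deliberately not the
default: 0.5 GHz and up contains too little information on a 0.45 MHz
relaxation for its parameters to mean anything.

## Numerical choices and degenerate inputs

* Frequencies in Hz and $\tau$ in seconds internally; picoseconds and
  nanoseconds only at tabulated boundaries. One SI convention prevents
  silent $10^{12}$ errors.
* `crossover_frequency()` scans 4096 log-spaced points; zero sign changes
  return `NA` (identical or non-crossing curves), multiple sign changes
  raise an error listing the sub-brackets rather than silently picking one.
* Sweeps need at least 10 points; a grid spanning less than a decade warns.
* Empty campaigns, mismatched validation grids, too few distinct
  temperatures, and out-of-range evaluation without `force` are errors.
* Campaign directories are written to a staging directory and moved into
  place, so a failed write never leaves a half-campaign; outputs carry a
  deterministic configuration hash in their header for traceability.

## Problem sizes

The test-suite simulations use the full 72-sweep, 1581-point design where
the property under test concerns the design itself (structure, noise-scale
recovery at over 2×10^5 pooled residuals, stochastic parameter recovery
over 5 seeds) and coarser grids (0.25--2 GHz steps) or reduced replication
elsewhere, chosen so each property is measured at the smallest size where
it is informative. A full 72-sweep fit-and-refit round trip runs in about
a second.

## Known limitations

* The packaged 37 °C single-pole row of the literature registry does not
  exactly equal the first-order laws evaluated at 37 °C (printed
  $\epsilon_\infty$ 1.23 vs 0.99, $\Delta\epsilon$ 53.73 vs 54.04,
  $\tau$ 7.21 vs 7.18 ps); only $\sigma_s$ and $\alpha$ agree to printed
  precision. The registry stores the row as printed; consistency checks
  use only $\sigma_s$ and $\alpha$.
* Laws are polynomials in °C with no physical constraint beyond range
  admissibility; extrapolation outside 20--45 °C is linear/quadratic and
  warned about, nothing more.
* The uncertainty budget treats sweeps as exchangeable and noise as
  uncorrelated across frequency; calibration drift within a run is only
  captured as the pre/post mean difference.
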