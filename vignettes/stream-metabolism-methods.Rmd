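---
title: "Reach-scale stream metabolism: models, processing choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reach-scale stream metabolism: models, processing choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachmetab)
```

`reachmetab` quantifies the metabolism of lowland stream reaches from two
complementary measurements: aquatic eddy covariance (AEC) for the benthic
compartment and in situ bottle incubations for the water column. This
vignette explains the models and processing decisions behind each stage,
the parameters a user may want to change, what the synthetic-data
generators do and do not emulate, and the known limitations.

## The benthic flux model

AEC estimates the oxygen exchange of the streambed without enclosing it.
An acoustic Doppler velocimeter samples the three velocity components at
8–64 Hz in a small volume 10–20 cm above the bed, paired with a fast
oxygen microelectrode. After Reynolds decomposition of vertical velocity
and oxygen concentration into means and turbulent fluctuations, the
turbulent flux is the covariance

$$F_{EC} = \overline{w'C'},$$

converted to mmol m^-2^ h^-1^ (with $C'$ in mmol m^-3^ and $w'$ in m/s,
the factor is 3600 s/h). Positive fluxes are upward throughout the
package — oxygen released by the benthos. Published figures in this field
often plot production as positive too, so the convention matches, but it
is stated once here and applied everywhere.

The raw series passes through a fixed chain, in this order:

1. **Quality filtering.** Samples with beam correlation < 50% or SNR
   < 10 dB are replaced by linear interpolation; the gap fraction is
   reported and a window whose gaps exceed 5% (configurable) errors out
   rather than producing a silently degraded flux.
2. **Block averaging** to 8 Hz, reducing electrode noise.
3. **Despiking** with an iterative 3-D phase-space method: the signal,
   its first and its second difference define an ellipsoid with
   semi-axes $\sqrt{2\ln n}\,\sigma$ (the universal threshold); points
   outside any of the three coordinate-plane ellipses (the
   signal/second-difference plane rotated by its principal angle) are
   replaced by linear interpolation until convergence. Replacement by
   interpolation is one of several options used in practice; it keeps
   the series on a uniform grid, which the covariance step requires.
4. **Double rotation**: a yaw then a pitch rotation zero the mean
   transverse and vertical velocities, correcting instrument tilt. Both
   are proper rotations, so per-sample speed is preserved exactly — a
   property the test suite asserts to 1e-12 relative.
5. **Reynolds decomposition by linear detrending** in consecutive 5-min
   windows. Five minutes retains the low-frequency turbulent flux while
   excluding non-turbulent variability (diel trends, passing clouds);
   the window is a parameter, and a sensitivity sweep is a one-line
   loop over `detrend_fluctuations(series, window = w)`. The package
   does not auto-tune it.
6. **Time-shift correction.** The electrode sits ~0.5 cm downstream of
   the velocity volume and has a finite response time, so $C'$ lags
   $w'$. The lag maximizing $|\mathrm{cov}(w', C')|$ over non-negative
   integer-sample lags up to 2 s is applied. Restricting the search to
   non-negative lags matters: on uncorrelated noise a two-sided search
   over many lags picks the largest spurious covariance and biases the
   flux away from zero (lag-fishing); the one-sided bounded search
   keeps the null case honest, which the suite checks on white noise.
7. **Storage correction.** Oxygen accumulating or draining in the water
   between bed and sensor biases $F_{EC}$. Under the well-mixed
   assumption the storage integral collapses to $(dC/dt)\,h$, with
   $dC/dt$ from first differences of hourly-mean oxygen; each hour gets
   the mean of its adjacent boundary gradients (exact for linear
   trends). A depth-profile version would replace the product with a
   numerical integral; the uniform form is the default because the
   target streams are shallow and well mixed. Then
   $F_{benthic} = F_{EC} + F_{storage}$.
8. **Hourly binning** of the 5-min fluxes, with a flag for hours covered
   by fewer than half their windows.

Diagnostics derived alongside: friction velocity
$u_* = \sqrt{-\overline{u'w'}}$ (negative-stress windows are floored at
zero and flagged — physically $u_*^2$ cannot be negative, and flooring a
noisy window is preferable to an imaginary value), roughness length
$z_0 = h\,e^{-\kappa U/u_*}$ ($\kappa = 0.41$), drag coefficient
$C_D = (u_*/U)^2$, and a 90%-flux footprint. The footprint uses a
law-of-the-wall parameterization: the time to mix bed-released solute up
to the sensor, $h/(\kappa u_*)$, times the log-profile advection speed
gives a length scale $h\ln(h/z_0)/\kappa^2$; fixed coefficients scale
this to the 90% distance and to a lateral width. The coefficients live
in a single internal table (`footprint_constants`) so they can be
recalibrated against a published footprint model without touching any
caller; only monotonicity (longer with $h$, shorter with $z_0$) and a
field-plausible envelope are treated as load-bearing.

## Water-column rates

Clear and dark bottles incubated in the stream give volumetric rates by
linear regression of oxygen against time, split at the night threshold
PAR < 2 µmol quanta m^-2^ s^-1^ (a boundary sample counts as day). Fits
with R² ≤ 0.8 are flagged rather than discarded. Clear-bottle slopes are
averaged across depth positions because vertical differences are
typically insignificant in these shallow, well-mixed reaches (the
per-position slopes are still reported); dark-bottle day and night
slopes are averaged with equal weight to give the night rate. Areal
rates follow by multiplying with mean stream depth:

* $ER_w = |r_{night}| \cdot 24 \cdot z$
* $GPP_w = (r_{day} - r_{night}) \cdot t_{day} \cdot z$, floored at 0
* $NEM_w = (r_{day} t_{day} + r_{night} t_{night}) \cdot z$

with a 0.1 mmol m^-2^ d^-1^ detection floor rendered as `"<0.1"` in
reports and stored as 0 for arithmetic. When the daytime rate is
undetectable, $NEM_w$ falls back to the night rate scaled to 24 h.

## Budgets and the NEM identity

The benthic daily budget uses the same arithmetic on campaign-mean
hourly fluxes: $ER = |f_{night}| \cdot 24$ (respiration assumed
light-independent, which makes GPP a conservative minimum),
$GPP = (f_{day} - f_{night}) t_{day}$ floored at zero, and
$NEM = f_{day} t_{day} + f_{night} t_{night}$. Whenever the floor is not
triggered and day + night hours sum to 24, $NEM = GPP - ER$ holds as an
algebraic identity; the tests assert this property over randomized
inputs. Compartments combine by element-wise sums; annual means average
exactly four seasons, and a missing season must be substituted
explicitly (e.g. re-using an autumn water-column rate for an unsampled
winter) — never silently. A short production peak is extrapolated over a
season with an explicit weighting,
$(w_{peak} p + (w_{tot} - w_{peak}) b)/w_{tot}$.

The packaged campaign table (`avon_campaigns()`) carries seasonal
summaries from three reaches on clay, Greensand and Chalk sub-catchments
of a spring-fed southern-England river. The reported areal water-column
rates are kept as published because a few cells cannot be reconstructed
exactly from the printed volumetric rates — the intermediate precision
is unknown, and the package does not chase those cells. Oxygen-based
rates can be re-expressed in carbon units via a user-supplied
photosynthetic/respiratory quotient; the default is 1.0, i.e. rates are
reported as oxygen equivalents unless the user states otherwise.

## Photosynthesis–irradiance response

Hourly benthic fluxes against PAR are fitted with the saturating
response $P = P_{max}\tanh(E/E_k) - R$ by Levenberg–Marquardt least
squares. Starting values are $P_{max,0} = \max P - \min P$, $R_0$ from
nighttime fluxes, and several $E_k$ candidates spanning the irradiance
range (the saturation scale is the poorly identified parameter; the best
of the multi-start fits is kept). The saturating form is only *reported*
when saturation is actually identifiable: fitted $E_k < 0.8\max E$ and
at least a 5% residual-sum-of-squares improvement over the straight line
$P = \alpha E - R$. Both thresholds are package choices — the underlying
rule ("use a linear fit in light-limited conditions") is qualitative —
and they are exposed as arguments of `saturation_check()`. With no
usable light at all the fit degenerates to $P = -R$. The compensation
irradiance $E_c = E_k \operatorname{atanh}(R/P_{max})$ is defined only
for $0 < R < P_{max}$; a community with $R \ge P_{max}$ never
compensates and `NA` is returned rather than an extrapolated number.

## Hydrology drivers

Discharge comes from the midsection method over cross-sectional velocity
transects. Base flow is separated by the UK smoothed-minima procedure:
5-day block minima, a 0.9 turning-point factor, linear interpolation
between turning points, capped at the observed discharge. Both constants
are arguments. Two consequences worth knowing: on a convex recession the
interpolated chord sits marginally (sub-percent) below the curve, so a
recession-only base-flow ratio is ~1 rather than exactly 1; and the
separation is anchored at the first/last block minima, so the first few
days of a record carry a flat extrapolation.

The base-flow ratio (BFR) over a window is the equally weighted mean of
daily base-flow/discharge, with the window ending on the campaign's last
day. `window_scan()` recomputes BFR for window lengths of 2–30 d and
reports the OLS R² profile of NEM against BFR; the argmax estimates the
timescale over which hydrology imprints reach carbon turnover. The
combined driver model is additive linear,
$NEM = a\,\mathrm{PAR} + b\,\mathrm{BFR} + c$ — the functional form is a
package choice (the source analyses never write the equation); an
interaction or standardized form is a one-line change on the returned
`lm` object. Because the single-driver models nest inside it, its R²
can never fall below either single-driver R², which doubles as a test
invariant.

On the packaged 12 site-season points the light regression yields
R² ≈ 0.68 with a heterotrophy/autotrophy crossing near 12.5 mol quanta
m^-2^ d^-1^ and slope ≈ 4.6 mmol m^-2^ d^-1^ per mol quanta m^-2^ d^-1^
— these are recomputed, not stored, and the acceptance tests assert
them. The two documented substitutions (one-week spring bloom weighted
over a 12-week season; autumn water-column rate standing in for the
unsampled winter) are applied by `driver_points()` exactly as the
campaign table's footnotes direct.

## What the synthetic generators emulate — and what they do not

`gen_turbulence()` builds $u'$, $w'$, $C'$ as linear combinations of
independent unit-variance AR(1) processes (integral timescale 1 s by
default), so the population covariances equal the requested
$-u_*^2$ and flux exactly; sample covariances then converge at
$1/\sqrt{n}$. On top it layers the instrument artefacts the pipeline
must undo: a linear storage trend, whole-sample sensor lag, white noise,
isolated 5–10σ spikes, quality-channel dropouts, and a static tilt. All
seeds are explicit arguments; nothing reads or leaves hidden RNG state.
The generator does **not** emulate a realistic turbulence spectrum
(an AR(1) spectrum is first-order, not inertial-subrange), ADV beam
geometry, electrode aging, wave contamination, or flow unsteadiness —
so passing recovery tests demonstrate that the processing chain is
correct and unbiased under stationary conditions, not that it is robust
to every field pathology.

`gen_bottles()` produces linear oxygen drifts under a half-sinusoid PAR
cycle with Gaussian sensor noise; real incubations can curve as
communities acclimate, which the linear-fit stage would average over.
`gen_hydrograph()` sums a slowly recessing base flow and fast-recessing
storm pulses with a known decomposition; `gen_driver_ensemble()` builds
site ensembles whose NEM depends on the true 9-day BFR, with storms
scattered through the month before each campaign so that windowed BFRs
decorrelate across window lengths and the construction window is
identifiable. With a field-strength light term included, a BFR-only
scan at a dozen-odd sites is not expected to localize the window — the
scan-recovery tests therefore use a light-free ensemble.

## Problem sizes and numerical choices

The test suite runs 3-h synthetic deployments at 8 Hz (86 400 samples),
200-replicate P–E noise studies at 48 points, and 24-site driver
ensembles over 60-day hydrographs — sizes chosen so each property is
measured well inside its Monte-Carlo error while the whole suite stays
interactive. Numerical conventions: time-shift lags are whole samples;
detrending windows are whole numbers of samples and trailing partial
windows are dropped; negative Reynolds stress floors $u_*$ at 0 with a
flag; rank-deficient driver designs error out rather than returning
aliased coefficients; and all budget arithmetic is carried at full
precision with table-style rounding applied only when formatting.

## Limitations

* No planar-fit rotation, spectral (ogive) corrections, or
  wave-affected processing — appropriate for sheltered lowland streams,
  not for wavy or strongly non-stationary sites.
* No gas-exchange/reaeration modeling: this is a benthic + bottle
  pipeline, not an open-channel single-station method.
* The footprint parameterization is an order-of-magnitude diagnostic,
  not a calibrated transport model.
* GPP estimates are conservative minima because daytime respiration is
  assumed equal to nighttime respiration.
* Winkler titration chemistry, nutrient dynamics, photoinhibition and
  temperature-dependent respiration are out of scope.
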