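---
title: "Quantifying swarm-mediated phage transport: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying swarm-mediated phage transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmphage)
```

## The problem

Phages find their bacterial hosts by transport. A free phage capsid tens of
nanometres across diffuses slowly — by Stokes–Einstein,
$D = k_B T / (6 \pi \eta r)$, a 30-nm capsid moves ~30-fold slower than a
1-nm antibiotic molecule — and a curli-fibre biofilm matrix blocks it almost
entirely. Motile bacterial swarms change this picture: the wetting fluid a
gliding swarm secretes flows along the swarm's direction of motion and can
carry non-host phages with it, turning slow diffusion into advection at the
swarm's linear speed. `swarmphage` implements the complete quantitative
chain for such experiments:

1. **Motion statistics** on single-particle tracks of fluorescent phages
   (MSD, anomalous exponent $\alpha$, Einstein-relation diffusivity, speed).
2. **Transport prediction** with 1-D Fickian and advection–diffusion
   solvers, plus the Stokes–Einstein and swarm-geometry calculations that
   supply their parameters.
3. **Image quantification** of prey-colony biomass clearance (timelapse)
   and phage penetration depth (confocal z-stacks).
4. **Synthetic data** for all of the above with known ground truth, so the
   estimators are validated end to end without raw microscopy.

## Motion statistics

### MSD definition and averaging modes

For an ensemble of 2-D tracks, the MSD at lag $\tau = k\,\Delta t$ is the
mean of $|\mathbf r(t+\tau) - \mathbf r(t)|^2$ over valid
(trajectory, start time) pairs. `ensemble_msd()` offers two modes:

* **`ensemble`** (default): one displacement per particle per lag, measured
  from each particle's first detection. This matches how an ensemble MSD of
  many short experimental tracks is usually reported, and keeps each
  particle's weight equal.
* **`time_averaged`**: every admissible start time contributes. Smoother on
  long synthetic tracks; used in the validation suite.

A lag pair is valid if and only if both endpoint detections exist. Tracks
with dropped detections keep their gaps (flagged per trajectory); no
positions are ever interpolated, because interpolation systematically
deflates the MSD at short lags. Lags are truncated at
`max_lag_fraction` (default 0.25) of the shortest track's duration: beyond
that the per-lag pair count collapses and the curve is noise-dominated.

### Exponent and diffusivity

`fit_msd_power_law()` fits $\log \mathrm{MSD}$ against $\log \tau$ by
ordinary least squares; the slope is the anomalous exponent $\alpha$
($\alpha = 1$ diffusive, $>1$ superdiffusive/active, $<1$ subdiffusive).
`classify_motion()` applies a configurable diffusive band, default
$(0.9, 1.1)$, bracketing the theoretical boundary $\alpha = 1$ — the
classification threshold is a judgment call, so the band is exposed rather
than hard-coded.

`diffusion_from_msd()` uses the Einstein relation. In $n$ dimensions
simple diffusion gives $\langle \Delta r^2\rangle = 2 n D \tau$, so $D$ is
the through-origin slope of MSD versus lag divided by $2n$ (4 for planar
tracking). Some reports divide $\langle \Delta r^2 \rangle / \tau$ by $n$
alone, which doubles the 2-D result; that convention is selectable
(`convention = "n_dt"`) but the $2n$ form is the default because it is the
only one consistent with the Brownian closed form the generators sample
from. A negative fitted slope (possible on tiny noisy ensembles) is clamped
to $D = 0$ with a warning rather than returned as an unphysical negative.

Per-track speed is total path length over duration, in µm/min. Path-length
speed is translation- and rotation-invariant, but on a diffusing particle
it grows with localization noise; an optional boxcar smoothing window is
provided for noisy detections.

## Transport model

### Parameters from first principles

* `stokes_einstein_diffusivity(r, T, eta)` evaluates
  $k_B T / (6\pi\eta r)$; default $T = 298$ K, water viscosity $10^{-3}$
  Pa·s. `diffusivity_ratio(r_small, r_large)` gives the slow-down factor of
  the larger particle, $r_{\text{large}}/r_{\text{small}}$ — temperature
  and viscosity cancel, so the 30-fold phage/antibiotic ratio is
  temperature-independent.
* `swarm_linear_speed(s1)`: a swarm circulating at speed $s_1$ along a
  circle of circumference $c = 2\pi r$ completes a revolution in $c/s_1$
  and advances one diameter $2r$ per revolution, so the front's linear
  speed is $s_2 = 2 r s_1 / c = s_1/\pi$ — independent of the vortex
  radius. $s_1 = 20$ µm/min gives $s_2 = 6.37$ µm/min.

### The solver

`simulate_transport_1d()` evolves
$\partial C/\partial t = D\,\partial^2 C/\partial x^2 - v_d\,\partial C/\partial x$
on $[0, L]$ with zero-flux boundaries, explicit in time: centred second
differences for diffusion and first-order upwind for advection, assembled
in conservative flux form so total mass is conserved to machine precision
(the test suite asserts $10^{-6}$ relative). Stability is checked, not
assumed: $D\,\Delta t/\Delta x^2 \le 1/2$ and $|v_d|\,\Delta t/\Delta x \le 1$,
with the violated bound and the maximal admissible $\Delta t$ named in the
error. The default $\Delta t$ is half the tighter bound.

The initial condition is a unit point mass in the first cell ($x = 0$), a
deliberate idealization of a localized inoculum; an arbitrary profile can
be supplied instead (the Gaussian-oracle tests release mid-domain to avoid
the reflecting wall).

Upwind advection is monotone and positivity-preserving but numerically
diffusive, with an effective added diffusivity of order $v_d \Delta x / 2$.
At the default $\Delta x = 1$ µm and swarm-scale speeds this smears the
front by a few micrometres over hours — immaterial for a read-out rounded
to 100 µm, which is why the scheme was chosen over higher-order
alternatives that can undershoot into negative concentrations. The
consequence, verified in the tests, is that the raw front position moves
~10 µm when the grid is halved while the reported distance does not; the
package treats the nearest-100-µm figure as the scientifically meaningful
resolution of this prediction.

### Front read-out

`front_distance()` reports the largest $x$ where $C$ still reaches a
fraction (default 1%) of the current profile maximum. The criterion is a
modelling choice — experimental "arrival" depends on detection sensitivity
— so it is an explicit parameter. For a Gaussian profile the 1% front sits
$\sqrt{2\ln 100}\,\sigma \approx 3.035\sigma$ beyond the centre, which is
the closed-form oracle the solver is tested against.
`predict_travel_distance(D = 0.228, v_d = 6.36, t = 3.3)` reproduces the
~1,500 µm front used to position prey colonies 1 mm from the inoculum.

One caveat follows directly from the model: the diffusive range is
monotone **increasing** in $D$ (at fixed criterion,
front $\propto \sqrt{2Dt}$). Any pair of reported ranges in which the
fluid with the larger measured $D$ travels the shorter distance cannot be
reproduced by pure Fickian spreading under a single read-out criterion;
the package therefore does not treat any such pair as a validation target.

## Image quantification

`segment_fluorescence()` thresholds a plane by Otsu's method (256-bin
histogram over the observed intensity range) or a fixed value, then drops
connected components smaller than `min_object_px` (default 9 px) to reject
sub-diffraction speckle. Area is foreground count × pixel area, and is
monotone non-increasing in the threshold.

Two thresholding policies, on purpose:

* **Timelapse (`biomass_timeseries()`)**: Otsu **per frame**, so slow
  illumination drift over a 21-h acquisition does not read as biomass
  change.
* **Z-stacks (`phage_depth_profile()`)**: a **single global** Otsu over the
  whole stack, because per-slice thresholds would renormalize away the very
  axial intensity differences the depth profile measures. Coverage is the
  fraction of all pixels in the slice above threshold, with depth
  $z = \text{slice} \times \Delta z$ (top slice $z = 0$); a global-Otsu
  profile is invariant to uniform intensity rescaling. Ties for the peak
  resolve to the shallowest slice and are flagged.

`fit_quadratic_trend()` fits $A(t) = a_0 + a_1 t + a_2 t^2$ by OLS with the
standard pointwise 95% confidence band of the predicted mean ($t$
distribution, $n-3$ df); noiseless input recovers coefficients exactly with
a zero-width band, and the band's empirical coverage is checked by
simulation in the test suite.

`clearance_rate()` reports the **endpoint** rate on the normalized series,
$(A_0^{\mathrm{norm}} - A_T^{\mathrm{norm}})/T$, as the primary number,
with the quadratic initial slope $-a_1$ alongside: the endpoint definition
makes no shape assumption and is what a "rate increased $k$-fold" claim
compares. `clearance_rate_ratio()` flags (rather than divides by) a
non-positive control rate.

## Synthetic data: what it emulates, and what it does not

`gen_trajectories()` produces the three regimes the motion estimators must
distinguish: Brownian steps of variance $2D\Delta t$ per axis; fractional
Brownian motion with Hurst $H = \alpha/2$, synthesized exactly from the
fBm covariance $D(s^\alpha + t^\alpha - |t-s|^\alpha)$ by Cholesky
factorization so the ensemble MSD is $4D\tau^\alpha$ by construction; and
Brownian-plus-drift, with a fixed or steadily rotating heading
(`"swarm-circular"`). fBm was chosen over a continuous-time random walk
because its ensemble exponent is set directly by one parameter — exactly
the quantity the analysis estimates. Defaults (300 tracks × 200 steps,
$\Delta t = 1$ s, $D = 0.041$ µm²/s) are the validation problem size used
throughout the tests; they give the MSD exponent a sampling error well
inside the ±0.1 acceptance band.

`gen_colony_timelapse()` renders a centred disc whose normalized area
decays as $\mathrm{clip}(1 - a_1 t - a_2 t^2,\,0,\,1)$ under Gaussian pixel
noise. Defaults emulate the hourly, 21-frame observation window of a
phage-delivery experiment: 50% biomass loss over 20 h for the experimental
condition, a ten-fold slower control (`a1`, `a2` scaled by 0.1), and a
foreground/noise contrast of 10.

`gen_biofilm_zstack()` renders 36 slices at a 3-µm z-step (0–105 µm) with
Poisson spot counts per slice proportional to a depth law: a Gaussian
peaked at `mu_z` (default 50 µm — mid-biofilm delivery) or a surface
exponential (the control, peak at $z = 0$). The default band width
($\sigma_z = 5$ µm) and peak density (600 expected spots/slice) were fixed
by a power calculation, not by eye: for the coverage argmax to be reliable
at the slice spacing, the expected-count drop between slices 3 µm apart
near the peak must exceed roughly four Poisson standard deviations, which
these defaults satisfy with margin. This is the one place where the
generator is deliberately sharper than a worst-case experiment; a broad,
sparse depth distribution would need replicate averaging (as real
experiments use) before its argmax is meaningful.

All generators are bit-reproducible under `(parameters, seed)` and emit
their ground truth alongside the data (`write_ground_truth_json()`), so
recovery tests compare to recorded truth rather than re-deriving it.

**What passing these tests does and does not show.** The scenes capture the
statistical structure the estimators consume — displacement distributions,
quadratic area decay, depth-dependent spot density, Poisson/Gaussian noise
— but not optical blur beyond the spot kernel, axial attenuation,
illumination gradients, segmentation-relevant texture inside colonies, or
phage–bacterium interaction dynamics. Recovery on synthetic data therefore
validates the estimators, not any particular microscope's imaging model;
on real data the segmentation method remains the dominant unquantified
choice, which is why Otsu-based results are claimed only at
synthetic-recovery accuracy, never pixel-for-pixel.

## Numerical choices and degenerate inputs

* Through-origin slope for the Einstein fit (the MSD of pure diffusion has
  no intercept); log–log OLS for $\alpha$ with a hard error on zero MSD
  values (log undefined) or fewer than 3 lag points.
* Otsu on a constant image is a degenerate histogram → error, not a
  threshold of convenience.
* A control series that never decays makes the clearance ratio `NA` with a
  flag, never `Inf`.
* TIFF stacks round-trip at the 32-bit writer's ~1e-7 tolerance;
  coordinates round-trip CSV/XML at printing precision (asserted 1e-9 µm).
* Problem sizes in the test suite (300×200-step ensembles, 20-seed image
  batches, ≤ 800-µm oracle domains) were chosen so the whole suite runs in
  well under a minute of numerics while keeping every stochastic assertion
  ≥ 3 sigma from its threshold.

## Known limitations

* The PDE is 1-D: it predicts reach, not the 2-D plume shape or the vortex
  flow field itself.
* First-order upwind limits front *sharpness*; positions finer than the
  grid-smearing scale ($\sim v_d \Delta x/2 \times$ hours) should not be
  read from it.
* Per-track $\alpha$ distributions, velocity autocorrelation and drift
  subtraction are out of scope; the ensemble exponent is the unit of
  inference.
* The depth profile divides by all pixels per slice; a biofilm-mask option
  would be needed for strongly non-rectangular biofilm cross-sections.
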