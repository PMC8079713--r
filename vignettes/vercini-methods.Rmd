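---
title: "Quantifying FtsZ treadmilling and septal constriction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FtsZ treadmilling and septal constriction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vercini)
```

## The measurement problem

During division, rod-shaped bacteria assemble a ring of short treadmilling
FtsZ filaments at mid-cell (the Z-ring), which condenses from a diffuse
nascent band into a thin mature ring and then constricts as the septal
cell-wall plate is built inward. Imaging the septum end-on — trapping cells
vertically so the division plane lies in the focal plane (the VerCINI
geometry) — turns filament motion into motion around a circle, and the whole
analysis becomes a chain of well-posed estimation problems:

1. locate the ring with sub-pixel precision in each frame and separate it
   from the out-of-focus cytoplasmic background;
2. read intensity around the circumference over time (a kymograph), where a
   treadmilling filament appears as a sloped ridge;
3. convert annotated ridge trajectories into speeds, lifetimes and arc
   distances, and classify immobile filaments;
4. in side-on (horizontal) imaging, measure ring diameter, axial thickness
   and septal density from 1-D line profiles;
5. detect the condensation step in axial-thickness time series and classify
   division stages;
6. fit a constriction-kinetics model to diameter trajectories;
7. summarise everything with estimation statistics.

Each stage lives in this package as ordinary functions; the `analysis/`
scripts chain them over simulated data, and every stage is validated
against the bundled synthetic-data generator whose ground truth is known by
construction.

## The septal image model

A vertically imaged septum is modelled as the sum of a signal and a
background term, `F(x, y) = Signal(x, y) + Bg(x, y)`. The signal is a
twelve-sector annulus evaluated in polar coordinates about the sub-pixel
centre `(x0, y0)`:

$$\mathrm{Signal}(r, \theta) = A_i(\theta)\,
  \exp\!\left(-\frac{(r - R_0)^2}{2\sigma^2}\right),$$

with one free amplitude per 30° sector (sector `i` covers
`[30(i-1), 30i)°`), ring radius `R0` and radial width `sigma`. The
cytoplasmic background is a central Gaussian plus a long-tailed Cauchy term
plus a constant:

$$\mathrm{Bg}(x, y) = a\,e^{-\rho^2 / 2\sigma_{bg1}^2}
  + b\,\frac{\sigma_{bg2}^2}{\rho^2 + \sigma_{bg2}^2} + c,
  \qquad \rho^2 = (x - x_0)^2 + (y - y_0)^2 .$$

The twenty-one parameters are fitted per frame by bounded
Levenberg–Marquardt least squares (`minpack.lm`). The coordinate convention
is: pixel centres at integer coordinates, origin top-left, x rightward, y
downward, polar angle counterclockwise (as displayed) from +x.

**Initialisation** (the fit is deterministic given a start): the centre
comes from the intensity centroid, the background from a background-only
pre-fit of the five `Bg` parameters, and the ring radius from the maxima of
the background-subtracted radial mean profile. When the annulus is weak —
single frames of a sparse nascent ring — the residual profile can have a
central bump that rivals the true annulus peak, so all local maxima within
40% of the strongest are tried as starts and the lowest-RSS fit wins. A
fitted model whose sector amplitudes are indistinguishable from the
residual noise floor raises a "no ring detected" error rather than
returning a junk geometry.

**Per-movie strategy.** Frames are fitted independently, warm-started from
the previous frame; the first start is a fit of the time-averaged movie
frame, where treadmilling has spread the filament signal into a filled
annulus that pins the geometry far better than any single sparse frame. On
these time scales the ring is stationary, so a per-frame fit whose radius
leaves a ±25% band around the time-average geometry is treated as a failed
fit (sparse frames do not constrain the annulus) and the latest usable fit
is carried forward. Whether the radial width `sigma` is fitted or fixed is
selectable; fitted is the default.

One systematic effect is worth knowing: a circle convolved with a Gaussian
PSF has its radial intensity peak slightly *inside* the true radius (by
roughly `sigma^2 / 2 R0`, about 2–3% here), so fitted radii on
point-filament synthetic data sit a few percent below the generator value.
This is a property of the optics, not a defect of the fit, and it is well
inside the 10% tolerance used for end-to-end speed recovery.

## Kymographs and filament speeds

For each frame the fitted background is subtracted on the pixel grid and
the residual is sampled by bilinear interpolation along the fitted circle,
one column per degree by default. Rows are frames; frames without a usable
fit become `NA` rows (never interpolated). For display the columns may be
doubled to 0–720° so trajectories crossing the 0/360° boundary stay
readable. The per-ring intensity summary is the median over all kymograph
pixels of the first 60 frames. The arc-length conversion uses the median
fitted radius across frames — robust to occasional fit failures.

The ridge filter used to aid annotation is a Gaussian blur at the feature
scale (2 px = 130 nm at 65 nm/px) followed by the Hessian's major
eigenvalue per pixel — the eigenvalue of largest absolute value, computed
from central finite differences, with periodic boundary in angle and
replicate boundary in time. Bright ridges give strongly negative
centreline responses; the sign is preserved so thresholds remain
meaningful, with a `bright_ridges` display option that negates the output.

Automated filament tracking is deliberately absent: at cellular filament
densities trackers fragment trajectories and miss immobile filaments, so
traces enter as annotations (line ROIs in long-format CSV) or, for
simulated movies, via ground-truth-guided measurement: for each simulated
filament the kymograph row is measured at the intensity-weighted centroid
within a ±12° window around the known angle, and the measured positions —
not the ground truth — form the trace. Speed is the absolute total
unwrapped angular displacement (minimal consistent step between
consecutive points) converted to arc length at the fitted radius, divided
by the trace lifetime; multi-segment annotations therefore reduce to total
displacement over total time, the same convention a single line ROI
implies. A filament is immobile when its speed is below 10 nm/s (strictly;
10 nm/s counts as mobile).

## Horizontal-cell line profiles

Side-on images are rotated about the ring centroid so the septal axis is
horizontal (bilinear interpolation), and profiles are averaged over ±2 px
(five rows). The ring diameter comes from the lateral profile via the
tilted-circle model: the line-of-sight projection of a circle of uniform
intensity viewed edge-on, `1/sqrt((d/2)^2 - u^2)` for `|u| < d/2`,
convolved with a Gaussian PSF and offset by a baseline. The projection
integrates to a constant independent of `d`, and its edge singularities
make the two profile maxima converge to ±d/2 as the PSF narrows. The
convolution is evaluated by Gauss–Legendre quadrature after substituting
`u = (d/2) sin t`, which removes the singularities; the PSF width may be
fixed or fitted (fitted by default). Axial thickness is the FWHM of a
super-Gaussian fit,

$$A\,\exp\!\left[-\left(\frac{(x - x_0)^2}{2\sigma^2}\right)^{P}\,\right] + \mathrm{baseline},
  \qquad \mathrm{FWHM} = 2\sqrt{2}\,\sigma\,(\ln 2)^{1/2P},$$

with `P >= 1` fitted freely from a Gaussian start (`P = 1`). Septal
density is the baseline-subtracted total lateral intensity divided by the
ring circumference `pi d`.

## Division states and the condensation step

Stage labels follow fixed thresholds: nascent when axial thickness exceeds
400 nm; otherwise mature when relative diameter is at least 0.9 and
constricting below that. The thresholds are strict inequalities in their
original statement, leaving equality undefined; here 400 nm takes the
non-nascent branch and 0.9 counts as mature, so the plane is partitioned.
The relative-diameter reference is the median diameter over the
trajectory's own pre-constriction portion (falling back to 1100 nm, the
physiological unconstricted septum). Labels are per-frame; no smoothing or
hysteresis is applied.

Condensation is a single change point in the axial-thickness series,
driven by the change in standard deviation: every admissible split is
scored with the Gaussian variance-change cost
`n1 log(sd1) + n2 log(sd2)` (population SDs, segments of at least two
points, SDs floored at 1e-8 to keep degenerate segments finite) and the
global minimiser is taken — an exhaustive search, cheap at these series
lengths, and verified in the tests against an independently written
brute-force loop. A two-state result is accepted only when the segment
means differ by at least 50 nm; otherwise one state is reported. The cost
depends only on deviations, so segmentation is invariant to adding a
constant to the series. Partially condensed rings (the GTPase-deficient
mutant phenotype) lack this step; they are instead scored by whether
thickness drops below 356 nm — one SD above the condensed wild-type mean —
for at least one frame before constriction starts.

## Constriction kinetics

Assuming outside-in synthesis of a flat septal plate at constant total
synthesis rate around the leading edge, the diameter follows

$$d(t) = \begin{cases} d_0, & t < t_0 \\
  \sqrt{d_0^2 - \tfrac{4k}{\pi}(t - t_0)}, & t \ge t_0 \end{cases}$$

clamped at zero beyond `t0 + pi d0^2 / 4k`. Equivalently, the plate area
`pi/4 (d0^2 - d^2)` grows linearly at rate `k`. The three parameters are
fitted by Levenberg–Marquardt; `t0` is initialised at the first time the
median-smoothed trajectory drops below 95% of its maximum and `k` from a
two-point slope of `d^2`. Diameters below the resolution floor are
retained — the model, not the data, is clamped. A flat trajectory leaves
`t0` unidentifiable and is flagged rather than fitted. Post-treatment
fits use only samples from the treatment time onward, and trailing samples
after the completion-intensity drop can be excluded by index.

Two summary times are exposed and must not be conflated: the conventional
effective constriction time `t_eff = 2 pi d0^2 / k`, and the model's
geometric completion time `pi d0^2 / (4 k)`. The conventional form is
exactly 8 times the geometric one; both are computed and labelled, and
between-condition comparisons are ratios, which the convention cancels
out of. `t_eff` is invariant under the scaling `d0 -> a d0, k -> a^2 k`.

## Estimation statistics

Summaries follow the estimation-statistics style: medians with 95%
percentile-bootstrap confidence intervals (2.5/97.5 percentiles of 10,000
resampled medians by default), median differences between conditions from
independent resampling of both samples, and fold changes as bootstrap
ratios of medians. Quartiles use the linear-interpolation convention
(R type 7); violin summaries report median, quartiles and adjacent values —
the extreme sample values within 1.5 IQR of the quartiles, always actual
data points. All bootstrap results are bit-reproducible under a fixed
seed, which is part of the returned object.

## What the generator emulates — and what it does not

The synthetic-data generator defines the conditions every recovery test
runs under. Filament counts per ring per frame are Poisson; the population
is a continuous-time birth–death process (births at rate
density/lifetime, exponential lifetimes with mean 30 s) initialised in its
stationary state, so the long-run mean count equals the configured
density. The four density presets (1.3, 3.3, 6.5, 37.5 filaments per ring
per frame) span nascent to heavily loaded mature rings. Each filament
gets a uniform initial angle, a ±1 treadmilling direction with equal
probability (no directional bias is modelled), and is immobile with
probability 0.35 by default — immobile meaning a residual speed drawn
uniformly below the 10 nm/s threshold rather than exactly zero, matching
the operational definition. Mobile speeds default to a lognormal with
median 28 nm/s and IQR 16 nm/s, parameterised so those targets are exact;
an empirical table can be bootstrap-resampled instead. Rendering places an
isotropic Gaussian PSF (sigma 130 nm, 2 px at the 65 nm/px pixel size) of
400 photons per filament per frame on the Gaussian–Cauchy background, and
the camera model applies Poisson shot noise, 2 ADU/photon gain, 3 ADU read
noise and a 100 ADU offset, quantised and floored at zero. Movies are
bit-reproducible from the config seed.

Real data differ in ways the generator does not attempt: filaments have
finite length and curvature (not points), collide and aggregate, rings
drift and tilt, cells photobleach, and backgrounds fluctuate. Passing the
recovery tests therefore demonstrates that the estimation chain is
correct and unbiased under the stated imaging model — not that any real
dataset meets that model. Constriction traces are the kinetic model plus
i.i.d. Gaussian noise (default 30 nm) truncated at zero; thickness series
are two Gaussian segments.

## Numerical choices and problem sizes

Fits use `minpack.lm::nls.lm` with box bounds enforcing parameter
invariants and tight tolerances (`ftol = ptol = 1e-12`); any least-squares
engine meeting the recovery tolerances would be conforming. Bilinear
interpolation is used for all off-grid sampling; out-of-field filament
light is silently clipped. Gaussian blurs use separable kernels truncated
at 3 sigma with per-axis boundary rules.

The validation suite runs at sizes chosen to make its statistical
tolerances comfortable rather than marginal: 40 movies of 300 frames at
density 1.3 for end-to-end speed recovery (several hundred traces; the
10% median-speed and 5-point immobile-fraction tolerances sit at roughly
three standard errors), 100 seeded replicates for noisy constriction
recovery, 500 random series for the change-point/brute-force equivalence,
and 1000 replicates at 1000 bootstrap resamples for CI coverage. The
`scripts/acceptance.R` entry point re-runs the same computations from
scratch under a caller-supplied seed.

## Known limitations

- Ring geometry is assumed stationary within a movie; slow septal drift
  would need per-frame geometry freed from the ±25% radius guard.
- The 12-sector annulus cannot represent azimuthal structure finer than
  30°; sector amplitudes are summaries, not filament counts.
- The tilted-circle model is a reconstruction from its verbal description
  (uniform-intensity circle viewed edge-on, Gaussian optics); its exact
  original parameterisation is not public, so the PSF-fixed mode is
  provided for sensitivity checks.
- Guided trace measurement needs ground truth and therefore applies only
  to simulated movies; real kymographs require manual annotation.
- The change-point detector fits exactly one candidate change point (one
  or two states), by design.
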