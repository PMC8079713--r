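# vercini

Quantitative analysis of bacterial cell-division imaging in the
vertical-cell (VerCINI) geometry: rod-shaped cells are trapped upright so
the division septum lies in the imaging plane, and the dynamics of the
FtsZ ring — treadmilling filament speeds, condensation, and septal
constriction — become measurable as motion around a circle.

The package is aimed at microscopists and quantitative biologists analysing
single-ring fluorescence movies (or validating such analyses), and it ships
a full synthetic-data generator so every stage can be tested against known
ground truth.

## What it computes

- **Septal ring fitting.** Each frame is fitted to a joint model
  `F(x,y) = Signal + Bg`: a twelve-sector annulus
  `Signal(r,θ) = A_i(θ) exp(−(r−R0)²/2σ²)` about a sub-pixel centre, on a
  Gaussian-plus-Cauchy cytoplasmic background
  `Bg = a e^{−ρ²/2σ_bg1²} + b σ_bg2²/(ρ² + σ_bg2²) + c`
  (bounded Levenberg–Marquardt, 21 parameters).
- **Kymographs.** Background-subtracted intensity sampled around the fitted
  circle per frame (1°/column), optionally doubled to 0–720° for display;
  Hessian ridge filtering (Gaussian blur at a 2 px feature scale, then the
  major eigenvalue per pixel) to enhance filament trajectories.
- **Filament metrics.** Trace speed = |total unwrapped angular
  displacement| × radius / lifetime; arc distance; lifetime; immobile
  classification at < 10 nm/s.
- **Horizontal-cell profiles.** Ring diameter from a tilted-circle model
  (edge-on projection of a uniform circle, `1/√((d/2)²−u²)`, convolved with
  a Gaussian PSF); axial thickness as the FWHM of a super-Gaussian fit,
  `FWHM = 2√2 σ (ln 2)^{1/2P}`; septal density = total septal intensity /
  (π d).
- **Division states.** Nascent / mature / constricting classification
  (400 nm thickness, 0.9 relative diameter); condensation step detection by
  a global variance-change change point with a 50 nm minimum step; the
  356 nm low-thickness rule for partially condensed rings.
- **Constriction kinetics.** The constant-synthesis model
  `d(t) = √(d0² − (4k/π)(t−t0))` for `t ≥ t0` (else `d0`), fitted over
  `(d0, t0, k)`; effective constriction time `t_eff = 2π d0²/k` alongside
  the geometric completion time `π d0²/(4k)`.
- **Estimation statistics.** Medians, median differences and fold changes
  with 95% percentile-bootstrap confidence intervals; violin summaries
  (median, IQR, adjacent values).

## Worked example

```r
library(vercini)

# simulate a mature-ring movie: 3.3 filaments/ring/frame, 15% immobile
cfg <- sim_config(filament_density = 3.3, immobile_fraction = 0.15, seed = 8)
sim <- simulate_ring_movie(cfg)

fits <- fit_ring_movie(sim$movie, every = 30L)
kymo <- extract_kymograph(sim$movie, fits)
print(kymo)
#> kymograph: 120 frames x 360 angles, radius 530 nm, 1 s/frame

traces  <- guided_traces(kymo, sim$truth, cfg$ring_diameter)
metrics <- do.call(rbind, lapply(traces, trace_metrics))
violin_summary(metrics$speed_nm_s)
#> median 22.69, IQR [18.99, 31.33], adjacent [13.58, 42.62], n = 11
bootstrap_median_ci(metrics$speed_nm_s, seed = 1)
#> 22.69, 95% CI [16.49, 31.42] (n_boot 10000)

tr <- simulate_constriction_trace(1100, 300, 1000, noise_sd = 30,
                                  dt = 15, n = 100, seed = 2)
fit_constriction(tr)
#> constriction fit (full): d0 1106 nm, t0 292.9 s, k 1007.3 nm^2/s, t_eff 127.1 min
```

The fitted ring diameter (2 × 530 nm) sits a few percent below the 1100 nm
ground truth: the radial peak of a PSF-convolved circle lies slightly
inside the true radius (≈ σ²/2R0), a property of the optics discussed in
the methods vignette. The constriction fit recovers the generating
parameters (d0 = 1100 nm, t0 = 300 s, k = 1000 nm²/s) to within ~1% under
30 nm diameter noise.

## Analysis workflow

Numbered drivers under `analysis/` chain the package over simulated study
data and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | movies at the four density presets (1.3, 3.3, 6.5, 37.5 filaments/ring/frame), constriction trajectories, thickness series |
| `02_ring_fits.R` | per-frame ring fits, kymographs, geometry summary |
| `03_filament_speeds.R` | guided traces, speed violins, immobile fractions, median-difference effect sizes |
| `04_division_states.R` | condensation step detection, state labels, low-thickness rule |
| `05_constriction.R` | kinetics fits, completion times, two-condition fold change |
| `06_report.R` | collates `results/summary.csv` |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

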