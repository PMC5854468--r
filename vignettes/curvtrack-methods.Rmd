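---
title: "curvtrack: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{curvtrack: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvtrack)
```

This vignette is the package's account of its science: the orientation
energy model, the trajectory and contour statistics, what the synthetic
data emulate, and the choices made where the design was genuinely open.

## 1. The orientation energy model

### Physical picture

MreB-like filaments polymerize on the inner face of the membrane as bent,
antiparallel double protofilaments whose preferred radius of curvature
(~100 nm) is much smaller than a bacterial cell's (~450 nm). On a surface
with principal curvatures $\kappa_1$ (long axis) and $\kappa_2$
(circumference), the curvature available to a filament bound along
direction $\theta$ is Euler's normal curvature
$\kappa_n(\theta) = \kappa_1\cos^2\theta + \kappa_2\sin^2\theta$
(`normal_curvature()`). Curvatures are signed, negative toward the cell
interior: a rod's inner wall is $(0, -1/R)$, a sphere's
$(-1/R, -1/R)$, and a neck has opposite signs. A bent filament that cannot
deform the membrane lowers its bending energy by aligning with the most
negative $\kappa_n$, i.e. circumferentially on a rod.

### Energy terms

`filament_energy()` evaluates, in kT at 300 K:

* **Beam bending** $\tfrac{B}{2} L (\kappa_{\mathrm{adopt}} + \kappa_0)^2$
  with $B = E I$, $I = \pi r^4/4$ for a solid circular cross-section
  (radius 2.5 nm, the two protofilaments idealized as one rod), and
  $\kappa_{\mathrm{adopt}} = \kappa_n(\theta) - 8a/L^2$: the filament's
  curvature is the surface's normal curvature plus the extra bow gained by
  indenting the membrane to depth $a$ (circular-arc sagitta over length
  $L$). The preferred signed curvature is $-\kappa_0$ (toward the
  interior). The signed form matters only at saddles: on cylinders and
  spheres, where $\kappa_n \le 0$, it reduces to the familiar
  $(|\kappa_n| - \kappa_0)^2$ penalty, but at a neck the positive
  $\kappa_1$ makes binding along the axis *worse* than on a flat wall —
  which is what makes necks the strongest aligners in
  `alignment_energy_map()`.
* **Adhesion** $-\epsilon_{\mathrm{bind}} L/\delta$ with
  $\epsilon_{\mathrm{bind}} = 10$ kT per monomer and rise
  $\delta = 5$ nm. Binding is modeled full-length, so adhesion is a
  $\theta$-independent offset; it anchors the filament but does not by
  itself pick an angle.
* **Membrane deformation**: the indentation is a Gaussian-profile groove
  of depth $a$ and lateral scale $w$ equal to the filament diameter.
  Small-gradient Helfrich bending gives
  $\tfrac{\kappa_m}{2} L \tfrac{3\sqrt\pi}{4} a^2/w^3$ and tension
  $\tfrac{\sigma}{2} L \tfrac{\sqrt\pi}{2} a^2/w$ — both quadratic in $a$.
* **Pressure–volume work** $P \cdot L a w \sqrt{2\pi}$, linear in $a$:
  turgor resists any inward displacement of membrane.

The exact deformation ansatz is a modeling choice; the verifiable core is
the rigid-membrane limit, where the minimizer must reproduce the closed
form $\Delta E(\theta) = \tfrac{BL}{2}[(|\kappa_n(\theta)| - \kappa_0)^2
- (1/R - \kappa_0)^2]$, and the test suite holds the numeric landscape to
within $10^{-3}$ kT of it.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `eps_bind` | 10 | kT/monomer | membrane-interaction estimate from the residues involved |
| `monomer_rise` | 5 | nm | actin-family subunit rise |
| `young_modulus` | 2e9 | Pa | actin-like stiffness |
| `filament_radius_geom` | 2.5 | nm | protofilament radius |
| `preferred_curvature` | 10 | 1/µm | 200 nm diameter adopted on deformable liposomes |
| `filament_length` | 250 | nm | ~50 monomers, mid-range filament |
| `membrane_bending_modulus` | 20 | kT | standard lipid bilayer |
| `membrane_tension` | 0 | kT/nm² | negligible at these scales |
| `osmotic_pressure` | 1e6 (cell) / 0 (liposome) | Pa | Gram-positive turgor scale vs pressure-free vesicle |
| `cell_radius` | 0.45 | µm | ~900 nm diameter cell |

The two regimes bracket the biology: at high pressure the membrane is
effectively rigid, the filament conforms to it and *senses* curvature; at
zero pressure with a floppy membrane the filament deforms the membrane
toward its own preferred curvature and *creates* it (the landscape
flattens, consistent with filaments tubulating vesicles rather than
reading their shape).

### Numerical choices

`energy_profile()` evaluates a $\le 1°$ grid on $[0°, 90°]$ (the landscape
is symmetric about both $0°$ and $90°$ on quadrics) and minimizes over the
indentation amplitude at each angle with Brent's method on
$[0, 10 \times \texttt{filament\_radius\_geom}]$ (= 25 nm by default),
checking both interval endpoints because the optimum sits at $a = 0$
whenever turgor dominates; the inner tolerance corresponds to well below
$10^{-6}$ kT at the default stiffnesses. Note the amplitude bound caps how
far a long filament can bow: with the default $L = 250$ nm the fully
conformal liposome limit is reachable only for shorter filaments
($\kappa_0 L^2/8 \le 25$ nm requires $L \lesssim 140$ nm), which is why
the pressure-free limit test uses $L = 100$ nm. Grid argmin ties (e.g. on
a sphere, where the landscape is flat) resolve to the first grid point.
`sensitivity_sweep()` re-runs the profile along one-parameter grids and
records the argmin, the well depth $\Delta E(0°)$, and whether it exceeds
1 kT.

## 2. Trajectory statistics

Tracks are fitted by orthogonal least squares (PCA): the line angle is the
first principal axis (axial, mod 180°), the fit quality the explained
variance fraction, the displacement the end-to-end difference of the
projections on that axis. MSD fits use the time-averaged MSD per lag.
The drift model $\mathrm{MSD}(t) = 4Dt + (Vt)^2$ is fit to the first 80 %
of lags (later lags average few pairs); with non-negativity constraints
the model is linear in $(4D, V^2)$, so the fit is solved exactly by
active-set enumeration rather than iteratively — it cannot fail to
converge. The single-molecule variants ($+4\sigma^2$ noise floor;
$C t^\alpha + 4\sigma^2$) use lags up to half the track length; the
power-law variant is the one genuinely nonlinear fit
(Levenberg–Marquardt, started from the log–log line). The exponent
$\alpha$ is always also estimated as the slope of log MSD vs log t with
its own $R^2$. For very long tracks `max_lag` caps the lag range, since a
single trajectory's time-averaged MSD carries almost no information at
lags comparable to its length.

Filters follow the standard directional cutoffs (strict inequalities):
$R^2_{\mathrm{orth}} > 0.9$, displacement $> 0.2$ µm, velocity
$> 10^{-9}$ µm/s, log–log $R^2 > 0.6$, $\ge 5$ frames. The
single-molecule policy replaces these with a 10–120 frame window, log–log
$R^2 > 0.95$ and velocity $> 5\times10^{-5}$ nm/s. Both velocity
thresholds are honored verbatim as named policies despite their odd
magnitudes — they act as near-zero guards, not tuned cutoffs.

All angle arithmetic is axial: differences are folded to $[0°, 90°]$ by
the two-step transform (add 180° if negative; reflect about 90° if above
it), which is idempotent. The alignment summary
$\sigma_{90} = \sqrt{\sum_i (x_i - 90)^2/N}$ is 0 for perfect
circumferential alignment and $90/\sqrt 3 \approx 51.96°$ for isotropic
angles. Pairwise statistics use distances between mean track positions;
the dot product $\cos(\theta_i - \theta_j)$ is computed on the raw axial
angles with no folding or absolute value (it can be negative), while the
angle difference is folded; tracks qualify only with $\ge 3$ neighbors
within 5 µm, and pairs are binned in 0.5 µm bins to 3 µm (an average cell
length); the bin width is our choice, the 3 µm cap is the method's.
The nearest midline station (for the track-to-midline angle) and the 10
nearest stations (for the local width) are found by Euclidean distance
from the track's mean position, ties to the lower station index.

## 3. Contour geometry

Sidewall curvature is the signed circumscribed-circle curvature of each
triple of successive vertices (collinear triples give 0; repeated vertices
are rejected), boxcar-smoothed over a two-pixel arc-length window
(`pixel_size`, default 0.065 µm/px); on contours whose vertex spacing
exceeds the window the smoothing is a no-op, which is the correct reading
for synthetic polylines. Positive = locally convex outward; the
bulged-sphere neck is the canonical negative region.

The midline/width extraction ("pill mesh") places stations along the
contour's principal axis and measures the perpendicular polygon chord at
each: midpoints form the midline, the maximum chord is the cell width.
This principal-axis sweep is exact for straight rods and rectangles and
was chosen over a Voronoi/distance-transform skeleton, which requires
rasterization and pruning heuristics and adds nothing for the straight
synthetic shapes in scope; strongly bent cells are a known limitation
(below). Contours with principal-extent aspect ratio $\le 1.1$ are
declared round: no midline, and the width falls back to the maximum
inscribed diameter (grid search over interior points). The 1.1 threshold
is our choice of where "no measurable width axis" begins.

The principal-curvature ratio divides the mean flank sidewall curvature
(stations excluding 10 % of the axial extent at each pole, to avoid cap
curvature) by the radial curvature $\kappa_2 = 1/(\text{width}/2)$:
1 on circles, ~0 on ideal rod flanks. Tangent correlation
$G(l) = \langle\cos(\theta_{i+n} - \theta_i)\rangle$ uses full tangent
directions from the two-argument arctangent of edge vectors — not the
arctangent of slopes — because only the full direction gives the analytic
$G(l) = \cos(l/r)$ on circles that anchors the implementation; separations
are converted to arc length with the mean edge length (vertex spacing is
near-uniform for generated and pixel-sampled contours alike). Doubling
times come from the least-squares slope of log area vs time
($t_2 = \ln 2 / \text{slope}$); non-positive slopes are flagged
non-growing rather than reported as negative times.

## 4. What the synthetic data do and do not emulate

The generator reproduces the *statistical structure* the analyses assume:
straight directional tracks with von Mises angular noise about the
circumferential direction (a single-parameter circular noise model; the
concentration $\kappa \approx 4$ gives $\sigma_{90}$ near 30–34°, the
scale seen for real filament populations), isotropic and uniform-axial
null populations, Brownian and ballistic MSD fixtures with optional
Gaussian localization noise, and ideal rod/sphere/bulged-sphere outlines.
The random-angle null carries its defining constants — 1 µm displacement,
25 nm/s, a 100 × 100 µm field — and a *recorded* fit quality of 0.95 in
the track metadata rather than noise calibrated to produce 0.95, because
the downstream statistic (angle differences) is independent of that noise
while the filters only need the recorded value to behave as specified.

Not emulated: photophysics (blinking, bleaching), detection/linking errors
(tracks are given, not detected), curved or septating cells, contour
noise beyond vertex jitter, and any coupling between track motion and
wall synthesis. Passing tests therefore demonstrate correctness of the
*statistics pipeline* under its stated assumptions, not robustness to
every failure mode of real microscopy.

## 5. Problem sizes and determinism

Every stochastic operation takes an explicit integer seed, and identical
(scenario, seed) pairs are bit-identical. The test suite and acceptance
script use 1000-track null fields (~0.5 M pairs), $10^4$-step diffusive
fixtures, 128–256-vertex contours, and 1°-grid energy profiles — sizes at
which every sampling-based tolerance in the tests (e.g. the ±1° band on
the null median) is comfortably met by the corresponding estimator's
standard error.

## 6. Package shape

The package exposes its two model-like cores in the classic R modelling
idiom — `fit_msd()` returns a classed `msd_fit` with `coef`, `predict`,
`residuals`, `print` and `plot` methods, `energy_profile()` a classed
object with `print`, `summary`, `plot` and `as.data.frame` — while the
pipeline stages (generators, contour geometry, filters, pairwise
statistics, I/O) remain plain functions over small S3 containers
(`track`, `track_set`, `cell_contour`, `width_profile`,
`filter_policy`, ...). Internals are base R; `minpack.lm` supplies the
one nonlinear fit and `jsonlite` the JSON I/O.

## 7. Known limitations

* The membrane-deformation ansatz (Gaussian groove, arc-sagitta bowing,
  full-length adhesion independent of amplitude) is one defensible
  reconstruction of the energy functional; alternatives (partial binding,
  other groove profiles) would change well depths quantitatively but not
  the argmin structure, which is fixed by the beam term.
* The amplitude bound (25 nm default) intentionally excludes large-scale
  membrane remodeling such as full tubulation; the liposome regime is
  represented only by the flattening of the landscape.
* The pill mesh assumes a straight long axis; banana-shaped cells would
  need a skeleton-based midline.
* `fit_msd()` on a single track cannot distinguish slow drift from
  diffusion at short track lengths; the filters, not the fit, carry that
  burden, exactly as in the source analyses.
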