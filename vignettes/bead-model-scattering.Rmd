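---
title: "Simulating small-angle scattering from bead models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating small-angle scattering from bead models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasbead)
```

## The model

Small-angle scattering (SAXS/SANS) measures the orientation-averaged
interference pattern of nm-scale particles in solution. `sasbead`
represents a particle as a cloud of $N$ point scatterers filling one or
more geometric subunits (spheres, cylinders, ellipsoids, hollow bodies,
rings, boxes) at constant point density. Each point $j$ carries an excess
scattering length $\Delta b_j = \mathrm{\Delta SLD}_i \cdot V$, where
$\mathrm{\Delta SLD}_i$ is the contrast of its subunit relative to the
solvent and $V = V_p / N$ is the effective volume of one scatterer
($V_p$ = total particle volume). The dilute-solution intensity is the
Debye double sum over scatterer pairs,

$$ I_{\mathrm{norm}}(q) \propto \sum_{j,k} \Delta b_j \Delta b_k
   \frac{\sin(q r_{jk})}{q r_{jk}}, $$

which the package accelerates by first binning all $N(N-1)/2$ pair
distances into a contrast-weighted histogram $p_i$ (the discrete pair
distance distribution $p(r)$) and then evaluating one sinc term per bin:

$$ I_{\mathrm{norm}}(q) = \frac{\sum_i p_i \,\mathrm{sinc}(q r_i)}
   {\sum_i p_i}, \qquad I_{\mathrm{norm}}(0) = 1 .$$

Self terms ($j = k$) are excluded; they vanish in the continuum limit and
$p(0) = 0$ is prepended by convention. $D_\max$ is reported as the largest
sampled pair distance (an underestimate of the true support by
$O(N^{-1/3})$), and

$$ R_g^2 = \frac{\sum_i p_i r_i^2}{2\sum_i p_i + \sum_j \Delta b_j^2}, $$

where the squared-weight term restores the excluded self pairs so the
estimate is exact for the discrete point set (a two-point dumbbell gives
exactly $d/2$) and converges to the familiar
$\sum p r^2 / (2 \sum p)$ as $N \to \infty$.

### Point generation and overlaps

Points are drawn by rejection sampling from each subunit's bounding box,
which is exactly uniform. Subunit $i$ receives
$n_i \approx N V_i / \sum V$ points (largest-remainder rounding, so counts
sum to $N$ and the density is constant across subunits to within one
point). Subunits are ordered by precedence: with overlap exclusion on,
points of a later subunit falling inside an earlier one are deleted and
*not* resampled — deletion keeps the density exactly uniform in the
surviving region, whereas resampling would raise the later subunit's
density. This is how multi-contrast particles are built: a $-1$ core
cylinder listed before a $+1$ outer cylinder yields a core–shell particle.
Without exclusion, overlapping regions scatter with the *sum* of the
overlapping contrasts.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `n_points` | 3000 | — | scatterers per particle; cost is $O(N^2)$, precision of $I(q)$ at high $q$ improves with $N$ |
| `n_bins` | 200 | — | histogram bins over $[0, D_\max]$; 200 keeps binning error below point-sampling noise at $N = 3000$ |
| q grid | 400 log-spaced in $[10^{-3}, 0.5]$ | 1/Å | typical SAXS range |
| `sigma_s` | 0 | — | Gaussian size polydispersity, must be $< 1/3$ |
| `eta` | 0.01 | — | volume fraction (concentration proxy) |
| `exposure` | 1 | — | relative exposure time; 1 ≈ synchrotron, 0.1 ≈ lab source |
| `sigma_rough` | 0 | Å | interface roughness |
| `noise_c`, `noise_k` | 0.85, 4500 | a.u. | error-model constants (below) |

Coordinate conventions: right-handed Cartesian, cylinder/ring axes along
z, ellipsoid semi-axes $a, b, c$ along x, y, z; subunits are only
translated (center-of-mass displacement), never rotated. Containment is
boundary-inclusive — immaterial at float precision but fixed for
determinism. A disc is a cylinder with $L < R$ by convention (same
mathematics, not enforced).

## Polydispersity

A Gaussian distribution of a dimensionless size factor $s$ (mean 1,
standard deviation $\sigma_s$) rescales all distances, $r \to s r$. Each
scale contributes with weight $G(s; 1, \sigma_s)\, v_s^2$ with
$v_s = s^3$, because scattering is proportional to the squared particle
volume (exact for spheres, an approximation for other shapes). The
average runs over $s \in [1 - 3\sigma_s,\, 1 + 3\sigma_s]$ — hence the
requirement $\sigma_s < 1/3$ — with a 21-point trapezoid rule, rescaling
the histogram rather than regenerating points ($O(M)$ per scale). The
ensemble intensity is normalized to 1 at $q \to 0$ *after* averaging.
Polydispersity in a single dimension (e.g. length only) and non-Gaussian
distributions are out of scope.

## Structure factors

Interparticle interference multiplies the intensity; $p(r)$ always remains
that of the non-interacting particle. Two analytic structure factors are
provided:

* **Hard sphere** (Percus–Yevick): repulsion between particles of
  interaction radius $R_{hs}$ at volume fraction $\eta \in (0, 0.74)$.
  The small-$q$ limit is evaluated through a series expansion so the
  compressibility limit $S(0) = (1-\eta)^4/(1+2\eta)^2$ is exact.
* **2D fractal aggregates**: $S_{agg}(q) = 1 + (N_{agg}-1)/(1 +
  (qR_{e\!f\!f})^2 N_{agg}/3)$ for aggregates of $N_{agg}$ particles with
  effective radius $R_{e\!f\!f}$, mixed as
  $S = 1 + f\,(S_{agg}-1)$ for an aggregated fraction $f$.

For non-spherical particles the decoupling approximation damps the
structure factor, $S_{e\!f\!f} = 1 + \beta(q)(S-1)$ with
$\beta = \langle F\rangle^2 / \langle|F|^2\rangle \in [0, 1]$, computed
from the bead model itself: the orientation-averaged amplitude uses point
distances from the $|\Delta b|$-weighted centroid (robust when the net
contrast is nearly zero — the plain contrast-weighted centroid is
undefined there). $\beta$ is computed from the monodisperse point model;
no ensemble recipe is attempted for polydisperse systems (documented
limitation). $S_{e\!f\!f}$ is floored at $10^{-6}$ so numerical noise in
$\beta$ can never produce negative intensities.

## The virtual experiment

Interface roughness multiplies the intensity by
$\exp(-(q\sigma_{rough})^2)$ (equivalently $\exp(-(q\sigma)^2/2)$ on the
amplitude; both conventions exist in the literature — this one is fixed
here and configurable upstream of the data). The forward scattering

$$ I(0) = \eta\, \Big(\sum_j \Delta b_j\Big)^2 / V_p $$

scales linearly with concentration and quadratically with contrast, and
reduces to $\eta\, \Delta\rho^2 V_p$ for uniform contrast. Intensities
are in arbitrary units; no absolute-scale calibration is attempted. The
1-sigma errors follow an empirical SAXS variance model

$$ \sigma^2(q) = \frac{I(q) + c}{k\, q\, t}, $$

with exposure time $t$ (so $\sigma \propto 1/\sqrt{t}$ exactly, the
Poisson-like scaling), a background floor $c$ and overall level $k$. The
constants $c = 0.85$, $k = 4500$ were set so the signal-to-noise profile
of a dilute protein-sized particle at default settings resembles a typical
synchrotron SAXS measurement; both are configurable. Data are drawn
independently per point from $\mathcal{N}(I(q), \sigma(q))$ — negative
draws are kept, as in real buffer-subtracted data. The error model is
applied after structure factor and roughness (noise acts on the measured
curve); SANS resolution smearing and incoherent backgrounds are out of
scope.

## Analytic reference models and fitting

For validation, closed-form orientation-averaged form factors are
provided: sphere, cylinder, ellipsoid of revolution and core–shell
cylinder (shell of uniform thickness on the sides and both end caps).
Cylindrical kinds are averaged over orientation by 64-point
Gauss–Legendre quadrature in $\cos\alpha$, verified against a 512-point
reference to better than $10^{-4}$ relative. `fit_weighted()` minimizes
$\sum ((I_{sim} - I_{model})/\sigma)^2$ with Levenberg–Marquardt under
positivity bounds, with three jittered starts to escape the shallow minima
that contrast-degenerate models exhibit; scale and background are free
unless fixed. Standard errors come from the unscaled covariance
$(J^\top J)^{-1}$ of the sigma-weighted residuals.

## What the generator does and does not emulate

The synthetic data emulate: dilute-solution Debye scattering from rigid
homogeneous-contrast bodies, simple Gaussian size polydispersity,
hard-sphere repulsion or 2D fractal aggregation, smooth interface
roughness, and synchrotron-like Gaussian noise. They do **not** emulate:
atomic structure or hydration layers, instrument resolution smearing,
incoherent (SANS) backgrounds, inter-curve systematic errors, or
concentration-dependent $p(r)$. Passing tests therefore demonstrate the
internal consistency of the Monte Carlo engine and its agreement with
analytic theory — not agreement with any measured dataset.

## Numerical choices and Monte Carlo noise

* sinc is evaluated by its series for $qr < 10^{-4}$ (no 0/0).
* A bead model is a *random* object: its intensity carries sampling noise
  that is small near $q \to 0$ and grows where the form factor is small.
  At the deep minima of centrosymmetric shapes (a sphere's analytic form
  factor touches $\sim 10^{-6}$) an $N = 5000$ cloud has an absolute noise
  floor near $10^{-4}$, so *relative* deviations there are large for every
  seed, and on the steep shoulders the cloud's $\sim 0.3\%$ effective-size
  jitter is amplified into relative deviations of several percent to tens
  of percent. Comparisons in the test suite therefore bound relative
  deviations away from the minima and absolute deviations (relative to
  forward scattering) everywhere.
* Problem sizes in the test suite were chosen so the quantity under test
  is resolved above this noise: the two construction routes of the
  core–shell cylinder are compared at $N = 20000$, where bead noise in
  $p(r)$ ($\approx 1.5\%$ of peak, scaling as $N^{-1/2}$) sits below the
  3% agreement band; the histogram-vs-direct-sum equivalence uses 2000
  bins so discretization error ($\le 0.3\%$) stays below the 0.5% bound.
* The parameter-recovery experiment averages fits over ten virtual
  experiments because the seed-to-seed scatter of the fitted shell
  contrast (standard deviation $\approx 0.03$) would make a smaller
  ensemble's mean unnecessarily noisy.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
# core-shell cylinder by overlap exclusion: -1 core takes precedence
spec <- model_spec(list(
  subunit("cylinder", c(20, 360), delta_sld = -1),
  subunit("cylinder", c(40, 400), delta_sld = +1)
), n_points = 3000)
model <- build_point_model(spec)
res <- simulate_experiment(model)
fit <- fit_weighted(res$dataset, "core_shell_cylinder",
                    start = list(r_core = 20, l_core = 360, t_shell = 20,
                                 sld_shell = 1, scale = res$i0,
                                 background = 0),
                    fixed = list(sld_core = -1))
fit
```

## Known limitations

* Subunits translate but do not rotate; arbitrary meshes are not
  supported.
* $D_\max$ is the largest *sampled* distance, a slight underestimate.
* $\beta(q)$ ignores polydispersity.
* The fitted parameter standard errors take the simulated $\sigma$ at face
  value; bead-model sampling systematics are not propagated, so reduced
  $\chi^2 \gg 1$ is expected when fitting analytic models to bead-model
  data at small $\sigma$.
* Overlap-built particles report $V_p$ as the sum of subunit volumes
  (pre-exclusion), which only affects the arbitrary intensity scale.
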