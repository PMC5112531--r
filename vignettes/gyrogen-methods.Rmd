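---
title: "Growth, buckling and where gyri form: the models behind gyrogen"
author: "gyrogen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, buckling and where gyri form: the models behind gyrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gyrogen studies a simple question about cortical folding: if the cortical
plate buckles because it grows faster than the tissue beneath it, what makes
a *particular* location end up as a gyrus (outward ridge) rather than a
sulcus (inward groove)?  The package approaches the question from two sides:
a morphoelastic simulator of a growing soft bilayer, and a surface-analysis
pipeline that relates folding patterns to cortical thickness growth on
longitudinal surface data.  This vignette records the models, the defaults,
and the judgement calls.

## The mechanical model

### Kinematics of growth

Growth is modelled with the multiplicative decomposition of the deformation
gradient,

$$ F = A\,G, \qquad G = g\,I , $$

where $G$ describes stress-free isotropic volume addition with growth
multiplier $g \ge 1$ and the elastic tensor $A = F G^{-1}$ carries all
stress.  Growth is *differential*: only the thin outer layer (the cortical
plate) grows; the core — a lumped stand-in for subplate, intermediate and
ventricular zones — keeps $g = 1$.  In the heterogeneous ("fast patch")
mode a centred special area grows at `patchMultiplier` (default 1.2) times
the cortical rate, i.e. $g_{\text{patch}} = 1 + 1.2\,(g - 1)$, so both
regions start from the shared stress-free state and the patch accumulates
growth 1.2 times faster.

### Constitutive law

Both layers are the same nearly incompressible neo-Hookean solid.  Per unit
grown volume,

$$ W(A) = \tfrac{\mu}{2}\left(\lambda_1^2 + \dots + \lambda_d^2 - d -
   2\log J\right) + \tfrac{\kappa}{2}(J-1)^2 , \qquad J = \det A , $$

with shear modulus $\mu = 330$ Pa in cortex and core alike (the folded
pattern depends only on the modulus ratio, which is 1).  The $\kappa$-term
is a volumetric penalty standing in for the incompressibility pressure; the
reported pressure is $p = \kappa(J-1)$ and the Cauchy stress is
$\sigma = \mu(B - I)/J + pI$ with $B = AA^{\mathsf T}$.  The default
penalty is $\kappa = 400\mu$.  A smaller penalty (e.g. $100\mu$) lets
$|\det A - 1|$ drift to 0.04 and beyond during folding, violating the
incompressibility budget this package enforces ($|\det A - 1| \le 0.02$ at
every recorded frame); $400\mu$ keeps frame values near 0.01 at acceptable
cost.

### Discretisation and relaxation

The plate is a structured total-Lagrangian mesh of bilinear quadrilaterals
(2D cross-section, the default) or trilinear hexahedra (3D), with $2^d$
Gauss points and an F-bar treatment of the volumetric term to avoid locking
at high $\kappa$.  The cortex carries the fine mesh (element size
`elemSize`, default 1 mm, at least two layers through the 2 mm cortex);
core layers coarsen geometrically towards the bottom until the deep core is
at least twice as coarse.  Quasi-statics are obtained by damped explicit
relaxation: central-difference steps with mass-proportional damping, and
per-element mass scaling so every element shares one stable time step
(density is a free numerical parameter because only the quasi-static limit
matters).  The kinetic/strain energy ratio is recorded at every frame and
stays below $10^{-3}$ at the states used for classification.

Boundary conditions, unstated in the source problem, are the minimal
confinement that forces cortical compression: the bottom face is fixed
vertically and the lateral faces roll (zero normal displacement).
Constraints are stored as per-node directions, so the whole problem can be
rigidly rotated to exercise objectivity.

### Perturbations, instability, and the classification stage

A seeded, zero-mean uniform perturbation (default amplitude 2.5% of the
cortex thickness) is applied to the top-surface reference geometry.  As the
cortical growth ramps linearly (36 000 steps to `growthMax` = 1.7),
the confined cortex passes its buckling threshold around $g \approx
1.5$–$1.6$ and wrinkles with a ~14 mm wavelength.  Because the two layers
have equal moduli, the post-buckling path is subcritical: wrinkles localise
into cusped sulcal creases with broad smooth gyri between them — and the
localisation snaps through dynamically, skipping any quasi-static state of
intermediate amplitude.

Runs therefore stop at the *established wrinkle stage*: once the detrended
fold amplitude of the top profile reaches `stopAmplitudeFactor` (default
0.6) times the cortex thickness.  The fold sites are selected at this
stage; letting the run continue merely sharpens sulci into creases and, for
a stiff patch, re-nucleates the crease at the patch boundary.  Runs that
never reach the amplitude stop ramp to `growthMax` and then relax until
the kinetic energy is negligible ($\mathrm{KE} < 10^{-7}\,\mathrm{SE}$); if
their final amplitude is below 10% of the cortex thickness they are flagged
`no_instability`.

The three study modes are:

* `homogeneous` — uniform cortical growth; fold positions are decided by
  the perturbation alone, so the plate centre lands on a gyrus, a bank or a
  sulcus essentially at random;
* `fast_patch` — a centred special area (width `patchWidth`, default
  14 mm = one buckling wavelength) grows 1.2× faster and consistently
  bulges outward into a gyrus;
* `stiff_patch` — growth is homogeneous but the special area's shear
  modulus ramps linearly in growth from $\mu$ to `stiffFinal`
  $\times\,\mu$ (2, 4 or 8); the stiff area resists bending, transmits its
  compression to the core, and sinks — a sulcus.

### Outcome classification

`classifyCenter` operationalises the visual trichotomy "top of a gyrus /
wall / sulcus".  The profile is linearly detrended and the height
percentile of the centre point among the window samples decides: ≥ 75 →
gyrus, ≤ 25 → sulcus, otherwise bank.  For a sinusoid sampled at a random
phase the percentile is uniformly distributed, so the rule's ideal class
shares are 25/50/25 regardless of waveform.  The default window is the
whole profile rather than a single wavelength: a one-wavelength window
mislabels a dome or dip whose apex sits a few millimetres off the query
point (as the fast patch's dome routinely does), while the global height
percentile is robust to that offset and leaves the cosine-phase behaviour
unchanged.  Profiles whose amplitude is below 10% of the cortex thickness
raise a "no instability" error instead of a label.

## The surface-analysis pipeline

The longitudinal pipeline mirrors a standard fetal-surface workflow, on
synthetic data built so that every stage's ground truth is known:

1. **Thickness** — for each white-surface vertex, the Euclidean distance to
   the nearest pial vertex (the vertex-to-vertex definition;
   a point-to-triangle projection variant sits behind
   `method = "projection"`).
2. **MPC** — maximal principal curvature by quadric fitting over the 2-ring
   neighbourhood in the tangent frame of the outward vertex normal; the
   convention makes convex (outward-bulging) regions positive, and
   "maximal" is read as the principal curvature of larger magnitude,
   keeping its sign (the algebraically-larger reading is available via
   `convention = "signed"`).
3. **Growth rate** — per-vertex ordinary least squares of thickness against
   week; the slope profiles the growth rate.
4. **Filtering** — vertices with $R^2 \ge 0.6$ are kept ("above 0.6" read
   inclusively; `strict = TRUE` switches to a strict inequality).  A
   zero-variance trajectory has $R^2$ defined as 0.
5. **Grouping and testing** — vertices split by MPC sign (exact zeros and
   NAs belong to neither group) and compared with a pooled-variance
   Student t test implemented from the textbook formula, with `stats::pt`
   as the verified CDF; the right tail tests that gyral growth exceeds
   sulcal growth.

### The synthetic generator

`makeSurfaceSeries` emulates longitudinal white/pial surface pairs over
pseudo-gestational weeks 25–31 on one shared mesh topology, so vertex
correspondence across time is the identity — the stand-in for longitudinal
spherical registration, which is out of scope.  The white surface is an
egg-carton corrugation $z = A\sin(kx+\varphi)\sin(ky+\varphi)$ (amplitude
5 mm, wavelength 30 mm, a 100 × 100 mm sheet, 55 × 55 ≈ 3000 vertices; the
fixed phase $\varphi = \pi/7$ keeps nodal lines off the vertex grid).
Ridges (positive analytic curvature) are gyral, valleys sulcal.  Vertex
thickness at week $w$ is

$$ t_v(w) = t_0 + s_v\,(w - 25) + \varepsilon, \qquad
   \varepsilon \sim \mathcal N(0, \sigma^2), $$

with $t_0 = 2$ mm (a plausible cortical-plate thickness at 25 weeks),
gyral slope $s = 0.35$ mm/week, sulcal slope $0.10$ mm/week and residual
$\sigma = 0.26$ mm — the group statistics the pipeline is asked to
recover.  The pial surface offsets the white surface along outward vertex
normals by that thickness (floored at 0.1 mm); offsets that would exceed a
valley's radius of curvature are rejected as degenerate.  Noise is i.i.d.
per vertex and timepoint; everything is deterministic given the seed, via a
private RNG stream that does not disturb the caller's.

What the generator does *not* emulate: registration error and temporally
correlated correspondence drift, smooth (non-binary) regional thickness
gradients, curvature-dependent measurement noise, and real cortical
geometry.  Passing tests therefore show that the pipeline's estimators are
correct and that the group structure survives realistic noise — not that
real fetal data would behave this cleanly.

### Two deliberate biases worth knowing about

**R² selection truncates the sulcal slope distribution.**  With 7
timepoints and $\sigma = 0.26$, a vertex's slope estimate has standard
error $\sigma/\sqrt{28} \approx 0.05$.  Keeping only $R^2 \ge 0.6$ keeps
essentially every gyral vertex (slope 0.35) but only ≈ 34% of sulcal
vertices (slope 0.10) — those whose *estimated* slope happens to be large —
so the kept sulcal group mean is ≈ 0.14, not 0.10.  A further ≈ 0.02 of
upward shift comes from the few near-nodal vertices whose MPC sign is
estimated wrong: mislabelled gyral vertices carry slope 0.35 and pass the
filter with near certainty.  This is a property of selecting on goodness of
fit, not an estimator bug; the gyral group, which the filter barely
touches, is recovered within its standard error.

**Closest-vertex thickness underestimates across sharp steps.**  On the
default 55 × 55 grid the thickness field steps from ≈ 4.1 mm (gyral) to
≈ 2.6 mm (sulcal) across a nodal line, and a white vertex within
$\sqrt{t_g^2 - t_s^2} \approx 3$ mm of the boundary finds the thinner
region's pial vertex closer than its own offset.  Re-measuring synthetic
thickness with the closest-vertex rule therefore shortens a band of gyral
trajectories.  Because the generator's declared output already includes the
per-vertex thickness trajectories, `growthRatePipeline` consumes those when
they are attached (`thickness = "auto"`) and reserves closest-vertex
measurement for plain surface pairs; the measurement operation keeps its
own exhaustive-search oracle tests.

## Numerical choices and degenerate inputs

* Explicit step: per-element mass scaling to a common step with safety
  factor `dtSafety` = 0.35 on the dilatational wave speed; damping
  `damping` = 0.01 per step (near-critical for the plate's slowest mode).
* Element inversion ($\det A \le 0$, or $\det F \le 0$) aborts the run
  with the element index; batches record the failure and continue.
* Ties in the percentile rule resolve upward (`<=`), so a perfectly flat
  window reads 100 and classification demands a minimum amplitude first.
* The FFT wavelength estimator returns the plate length divided by the
  dominant nonzero frequency; profiles are detrended first.
* Quadric fitting needs ≥ 5 neighbours; vertices with smaller 2-rings get
  `NA` MPC and are excluded downstream.
* Degenerate YAML configs, patches wider than the plate, growth
  multipliers below 1, and singular growth tensors all error early with
  specific messages.

## Problem sizes

The shipped study conditions are desk-scale by design: batches of 20 runs
per growth mode (10 per stiffness level) on the 100 × 25 mm plate
(≈ 1000 elements, ≈ 2–3 s per run), and synthetic series of ≈ 3000
vertices.  The full-scale 300 × 300 × 50 mm plate remains available
through `simConfig(dims = c(300, 300, 50), dimension = 3)` for users with
time to spend.

## Known limitations

* The 2D cross-section model captures where folds form along one section;
  3D pattern selection (Y-junctions, labyrinths) is out of its reach, and
  the 3D mode is small-scale.
* Self-contact of deeply folded sulci is not modelled; runs classify the
  wrinkle-stage pattern and stop well before contact.
* Equal-modulus layers place the model in the creasing regime; the
  wrinkle-stage statistics are robust, but crease-stage morphology (cusp
  spacing, depth) is mesh-sensitive and should not be over-interpreted.
* The pooled t test inherits the usual equal-variance assumption; with
  filtered groups of very different sizes its p-values are approximate.
* The sulcal growth-rate group mean is structurally biased upward by the
  R² filter under the stated noise level (see above); comparisons against
  the generative 0.10 must account for that selection effect.
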