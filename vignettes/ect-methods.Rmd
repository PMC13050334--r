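---
title: "Euler characteristic transforms of curves: exact computation, stability, and estimation from noisy samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euler characteristic transforms of curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ect1d)
```

## Shapes and their discrete representation

The objects of study are finite one-dimensional CW complexes embedded in
`R^d`: a finite vertex set `Z_0` and a finite multiset of edges, each edge
carrying a parametrised curve whose endpoints are glued to vertices. Loops
and parallel edges are allowed, so circles, segments, trees and arbitrary
curve networks are all covered. In this package a curve is always a *sampled
chain*: a strictly increasing parameter grid on `[0, 1]` with one coordinate
vector per parameter (`sampled_curve()`), and an `embedded_complex()` couples
the combinatorics with vertex coordinates and one chain per edge.

Working with dense polylines instead of symbolic curves is not a
compromise: the piecewise-linear approximation bound below quantifies
exactly how much the ECT of the chord interpolation can deviate from the
ECT of the smooth shape, and every operation downstream of the sampling is
*exact* on the polyline.

Differential quantities are estimated from the chain:

* **Arc length** is the polygonal length of the chain.
* **Constant-velocity reparametrisation** resamples the chain at equal
  arc-length spacing; it preserves endpoints exactly and the polyline image
  up to resampling.
* **Curvature** is estimated by second differences of an
  arc-length-uniform resampling. The stencil is *strided* so that its span
  stays well above the input resolution: a second difference taken at the
  raw spacing divides the chord "sawtooth" of the polyline (amplitude
  `~ κ h²/8` for input spacing `h`) by the squared stencil width, which
  turns a vanishing positional error into an `O(1)` relative curvature
  error. With the strided stencil the estimate is within 1% on a densely
  sampled circle and within 2% at the tip of a 2:1 ellipse. Certification
  harnesses inflate the estimate by 5% before using it as the bound `M`,
  since the stability theory needs a true upper bound.

## The transform and its exact arithmetic

For a direction `v` and level `t`, the sublevel set of a piecewise-linear
shape is cut out of vertices and chords, and because the projection is
affine on each chord, its extrema sit at chord endpoints. The PL Euler
characteristic is therefore the exact count

```
ECT^A(v, t) = #{i : ⟨b_i, v⟩ ≤ t} − #{(i, j) ∈ E : max(⟨b_i, v⟩, ⟨b_j, v⟩) ≤ t},
```

where `A` is a *compatible subset* (all vertices plus at least one interior
point per edge, so that removing `A` cuts the complex into open arcs) and
`E` is the induced sub-edge multiset. `build_compatible_subset()` subdivides
each edge at equal arc-length until every sub-arc is shorter than a target
`eps`.

Three representation choices make every downstream quantity exact rather
than quadrature-based:

* **ECCs are right-continuous step functions** whose breakpoints sit at the
  projection values. The sublevel convention is `≤ t`, so the jump happens
  *at* the projection value. Ties — several samples projecting to the same
  level, as happens at symmetry axes — are merged by summing jumps, never
  perturbed; the gluing and decomposition identities hold almost
  everywhere, so measure-zero tie instants cannot affect any L1 quantity.
* **L1 distances between step functions** are computed by merging
  breakpoint lists and summing `|Δvalue| × width`.
* **The SECT** integrates the mean-centred ECC in closed form, giving a
  piecewise-linear function that vanishes at both ends of `[-a, a]`; L1
  distances between piecewise-linear functions split each merged segment at
  its sign change.

The bounding radius `a` defaults to 1.05 times the largest point norm; when
two fields are compared, the larger radius wins and the other field is
zero-extended (exact, since every ECC is constant beyond its own bound).
The supremum over the sphere in the norm is replaced by a maximum over a
finite direction grid (default: 64 evenly spaced planar directions). This
under-estimates the true supremum; all "distance ≤ bound" certificates in
the package remain valid because only the left-hand side is
under-estimated. Direction counts coprime to any subdivision count avoid
flattering alignment accidents (a direction grid that hits polygon vertices
exactly makes the measured distance unrepresentatively small; the
refinement test uses 37 directions for this reason).

Internal conservation checks: every directional ECC reaches
`χ = #vertices − #sub-edges` at the top of the filtration, is 0 below the
bottom, and the whole field is equivariant under joint rotation of shape
and directions.

## Stability: what replaces Hausdorff closeness

Hausdorff closeness does not control the ECT: `make_wave_and_line(eps)`
builds the canonical counterexample, a wave of amplitude `eps` with
`⌈1/eps⌉` oscillations whose bottom-up ECC stays at L1 distance at least 1
from the straight line's. (The number of "amplitudes" is read as full
oscillations; that many already realises the separation.)

The metric that does control the ECT compares two embeddings of the *same*
complex through constant-velocity parametrisations: the larger of the
sup-distance and the worst per-edge arc-length difference. The package
computes an upper estimate (`cw_distance_upper()`) that fixes the
caller-supplied edge correspondence and optimises only over per-edge
orientation; the true infimum over all parametrising homeomorphisms is not
computable, and an upper estimate is exactly what the certification
harnesses need, since it only makes their inequalities harder to satisfy.

The closed-form bounds (`ect_stability_bound()`, `near_straight_bound()`,
`stability_envelope()`, `chord_lower_bound()`, `pl_approx_bound()`,
`sect_lipschitz_factor()`) are evaluated literally as stated, with two
policy decisions:

* the per-edge piece count is floored at 1 so that straight edges
  (`M = 0`) do not crash the evaluation;
* branch predicates are strict (`L/n > 2eps` selects the square-root
  branch); at equality the linear branch applies.

Each bound ships with an empirical certification harness in the test
suite: constructed pairs with measured `eps` (inflated by `1e-9`, since the
stability statement takes the metric strictly below `eps`) must keep their
measured ECT distance under the bound. The directional envelope function is
even and `π`-periodic; a stronger quarter-period symmetry sometimes quoted
for it does not hold for the four-term expression (the two square-root
terms do not treat sine and cosine symmetrically), so only the true
symmetries are asserted — the envelope's branch bounds themselves verify
numerically over a log-grid of `(L, eps)`.

## Gaussian-process estimation from noisy samples

Real outlines come as noisy point samples. The estimator assumes the
homeomorphism type is known, observes each coordinate at sample locations
equally spaced in arc length (a compatible subset; locations on a
degenerate, point-like edge fall back to parameter spacing), perturbed by
independent centred Gaussian noise, and smooths each coordinate with a
zero-mean Gaussian-process regression:

```
mean: K(q, x) (K(x, x) + σ² I)⁻¹ y
cov:  K(q, q) − K(q, x) (K(x, x) + σ² I)⁻¹ K(x, q)
```

Noise is parametrised by its **variance** `σ²` everywhere in the
interfaces. For closed curves the kernel is the 2π-periodic sine-squared
exponential `k(s, t) = exp(−2 sin²((s − t)/2))`, whose RKHS contains all
finite trigonometric polynomials — in particular every curve produced by
`make_fourier_curve()`. Open edges can use the squared-exponential kernel
on `[0, 1]`, and `pullback_kernel()` composes any PSD kernel on `R^d` with
a map from the parameter interval (derivatives then fall back to central
finite differences, step `1e-5`, and the model is flagged as reduced
precision). All analytic kernel partials are generated symbolically with
base R's `D()` rather than hand-coded.

Two quantities drive the consistency argument and are exposed directly:

* the **derivative-process variance**
  `v'_n(t) = k_xy(t, t) − K_x(t, x) B⁻¹ K_y(x, t)`, which is monotonically
  nonincreasing as observations are appended (checked for 30 sequential
  observations in the tests), and
* the **entropy integral** `J(Z, d_k) = ∫ √(log N(Z, eps, d_k)) d(eps)`
  under the canonical kernel metric
  `d_k(s, t) = √(k(s,s) + k(t,t) − 2k(s,t))`; finiteness of `J` is the
  hypothesis for consistency. `covering_integral()` either integrates an
  analytic covering-number function or greedily covers a finite dense
  sampling (an upper bound on the minimal cover, hence on `J`). For the
  circle with the angular metric, `N(eps) = ⌈π/eps⌉` gives `J ≤ 2π`, and
  `d_k` is dominated by the angular metric, so the sine-squared kernel
  inherits a finite entropy integral.

The full estimator (`estimate_ect()`) chains smoothing, per-edge
constant-velocity reparametrisation of the posterior mean, and the exact PL
ECT/SECT on `m` interpolation points. `m` defaults to `max(4n, 256)`: the
theory leaves the interpolation fineness as a free schedule in `n`, and
this default keeps the interpolation error well below the smoothing error
at the sample sizes studied here; it is a heuristic, not a theorem.
Reference transforms of the true shape use a 10× finer interpolation of the
truth.

### Numerical choices

* Gram factorisations use Cholesky with a jitter ladder
  (`0 → 1e-10 → 1e-8 → 1e-6`); failure beyond the ladder raises a
  conditioning error. The sine-squared kernel's spectrum decays
  factorially, so its Gram matrices have numerical rank ~15–20: posterior
  means are conditioning-limited to roughly `1e-5`–`1e-4` absolute accuracy
  in double precision regardless of how small the noise is. This is why
  near-noiseless checks in the tests assert at `1e-4`/`1e-3`, not machine
  precision.
* Loop edges evaluate their final point at parameter 0 (the same point of
  the complex), so smoothed loops close *exactly* instead of to within a
  tolerance amplified by the ill-conditioned solve.
* Posterior curve draws use one seeded stream; coordinates are drawn
  independently, matching the model's independent-coordinate assumption.

## The simulation study and the synthetic shapes

`consistency_experiment()` reproduces the design of the reference
simulation at desk scale: a seeded closed curve, per-coordinate noise
`σ = 0.002`, sample sizes 20/50/100, SECT distances of the posterior-mean
estimate (and optionally of posterior draws) to the truth, tabulated per
replicate. The default curve is `fourier_spec()`: the unit-circle harmonic
`c₁ = 1` plus seeded complex Gaussian harmonics for `|k| ≤ 5` with
magnitude decay `|k|⁻³` and scale 0.15 — a simple (non-self-intersecting)
gently deformed circle with curvature bound ≈ 2.8 and length ≈ 6.37,
representative of segmented-outline data. The coefficients of the curve
used in the original study are not published, so distances here are not
comparable value-for-value; what the experiment (and the acceptance suite)
checks is the *monotone decrease* of the median SECT distance in the sample
size, over 20 seeded replicates per sample size, with 64 directions and
`m = max(4n, 256)` interpolation points — sizes chosen so the whole
experiment is a desk-scale computation.

What the generators deliberately do not emulate: outliers and heavy-tailed
noise, correlated (e.g. tangential) perturbations, unknown topology, and
open-curve networks with shared noisy vertices beyond simple averaging of
edge-end estimates. Passing tests therefore say nothing about topology
inference or robustness to non-Gaussian corruption; they certify exactness
of the transform arithmetic, validity of the closed-form bounds on smooth
curves, and consistency of the smoothing pipeline under the stated noise
model.

## Known limitations

* Shapes of dimension ≥ 2 (meshes) are out of scope; so is persistent
  homology and shape reconstruction from the transform.
* The embedding-metric infimum is only upper-estimated; harnesses that need
  the metric use constructed pairs where it is measurable.
* The direction-grid supremum under-estimates the true norm; certificates
  are one-sided by design.
* No kernel hyperparameter optimisation and no low-rank Gram
  approximations; sample sizes are expected to stay in the hundreds.
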