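# ect1d

Euler characteristic transforms of one-dimensional shapes, with
curvature-controlled stability bounds and a Gaussian-process estimator for
noisy point samples.

## The problem

Outlines and curve networks extracted from segmented images — cell
boundaries, leaf contours, vessel traces — are one-dimensional shapes
embedded in Euclidean space. The **Euler characteristic transform (ECT)**
summarises such a shape `X ⊂ R^d` by the integer-valued function

```
ECT_X(v, t) = χ({x ∈ X : ⟨x, v⟩ ≤ t}),    v ∈ S^{d-1}, t ∈ [-a, a],
```

the Euler characteristic of the part of the shape inside every closed
half-space. Fixing the direction `v` gives the Euler characteristic curve
(ECC); integrating the mean-centred ECC over `t` gives the **smooth ECT
(SECT)**, a continuous, Hilbert-space-valued signature suited to downstream
statistics. Distances between transforms use the norm

```
‖ECT_X‖ = sup_v ∫ |ECT_X(v, t)| dt
```

(the supremum approximated by a finite direction grid).

The ECT is fast and injective on a large class of shapes, but it is
**unstable under the Hausdorff distance**: a wave of tiny amplitude `ε`
hugging a straight line keeps their ECC distance at or above 1 however small
`ε` is, as long as the wave oscillates often enough. This package implements
machinery that makes ECT comparisons trustworthy for one-dimensional shapes:

1. **Exact piecewise-linear ECT/SECT** of a sampled embedded complex
   (vertices + parametrised edge curves), via eps-dense compatible subsets:
   `χ = #vertices below t − #chords fully below t`, with exact step-function
   and piecewise-linear arithmetic throughout (no quadrature).
2. **Stability bounds controlled by curvature rather than triangulation
   size.** If two embeddings of the same complex are within `ε` in a metric
   combining sup-distance and per-edge arc-length differences of
   constant-velocity parametrisations, and one embedding has curvature at
   most `M`, then

   ```
   ‖ECT_X − ECT_Y‖ ≤ |Z₀| ε + Σ_λ G_λ(ε),
   G_λ(ε) = 8 √(L_λ n_λ ε) + n_λ ε   (if L_λ/n_λ > 2ε; 11 n_λ ε otherwise),
   n_λ = max(⌈(M² L_λ³ / 24ε)^{1/3}⌉, ⌈L_λ M / π⌉),
   ```

   plus the companion bounds: `8√(Lε)` for near-straight curves,
   `M L ε / √12` for the PL interpolation error of an eps-dense subset,
   `(2/M) sin(Mε/2)` for chord lengths under a curvature cap, and the
   `(2a + 1)` SECT/ECT Lipschitz factor. All are evaluated in closed form
   and certified empirically against computed distances.
3. **A consistent estimator from noisy samples.** Coordinates observed at
   dense sample locations with independent Gaussian noise are smoothed by
   Gaussian-process regression (for closed curves: the periodic sine-squared
   exponential kernel `k(s,t) = exp(-2 sin²((s−t)/2))`); the posterior-mean
   curve is reparametrised to constant velocity and its PL ECT/SECT computed.
   The derivative-process variance, its monotone decrease in the sample size,
   and the covering-number entropy integral `J(Z, d_k)` — the hypothesis
   under which the smoothing is consistent — are all computable.

## Worked example

```r
library(ect1d)

# a smooth closed outline: unit-circle harmonic plus seeded small harmonics
shape <- make_fourier_curve(fourier_spec())

E <- ect_field(shape, eps = 0.05, directions = direction_set(64))
E
#> <ect_field> 64 directions | a = 1.331567 | chi = 0

# how far is this outline from a circle, as the ECT sees it?
ref <- analytic_circle_ect(1, direction_set(64), a = E$a)
ect_distance(E, ref)
#> [1] 0.4908182

# the stability certificate for this shape at eps = 0.05
bound_report(M = curvature_max(shape$curves$e1),
             lengths = arc_length(shape$curves$e1), eps = 0.05, n_vertices = 1)
#> <bound_report> eps = 0.05  M = 2.834432
#>   per-edge pieces: 13
#>   stability bound: 16.97563
#>   PL interpolation bound: 0.260512

# estimate the SECT from 50 noisy samples (sd 0.002 per coordinate)
obs <- sample_noisy(shape, n = 50, sigma = 0.002, seed = 1)
a   <- 1.1 * 1.331567 / 1.05   # any radius covering the shape
est <- estimate_ect(obs, kernel_sine_squared(), a = 1.465,
                    reference = NULL)
est
#> <ect_estimate> n = 50 samples, m = 256 interpolation points
est$lengths
#>       e1
#> 6.369203   # true arc length is 6.367696
```

The `chi = 0` field is the Euler characteristic of the closed curve, which
every directional ECC reaches at the top of the filtration — an internal
conservation check. The 0.49 circle distance says the outline's harmonics
move about half a unit of integrated Euler characteristic in the worst
direction. The bound report gives the worst-case ECT movement (16.98) allowed
for *any* shape this curved under an `eps = 0.05` perturbation, and the much
smaller PL interpolation error (0.26) of the 0.05-dense chord approximation.
With 50 noisy samples the estimated arc length 6.3692 is within 2e-3 of the
truth; `consistency_experiment()` tabulates how the SECT distance to the true
shape shrinks as the sample size grows.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ect1d`:

```sh
ect1d simulate --shape fourier --out shape.json
ect1d ect --input shape.json --eps 0.05 --dirs 64 --out ect.csv
ect1d bounds --M 1 --lengths 6.28 --eps 0.01 --n0 1
```

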