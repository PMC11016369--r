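---
title: "Aligning density maps in a wavelet Wasserstein metric: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning density maps in a wavelet Wasserstein metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wembo)
```

## The model

Two cubic density maps `f1`, `f2` (real-valued voxel arrays, possibly
with negative background values) are assumed to be rigid transforms of
each other up to noise:

    f2(x) = f1( R' (x − t) ),   R ∈ SO(3) (or O(3) with handedness),
                                 t ∈ R³.

The assumptions behind the pipeline are worth stating explicitly:

* **Compact support.** Both molecules fit inside their boxes with room to
  spare, so rotations about the grid center and (periodic) Fourier
  shifts do not clip or wrap appreciable mass. `make_pair` enforces this
  for synthetic data (error at > 2% mass loss).
* **Comparable density scales.** No intensity normalization is applied;
  the WEMD is well defined for maps of unequal mass, but grossly
  different scalings would distort both losses. A `normalize` flag on
  `wavelet_signature` is available.
* **Near-identical shapes.** The method targets homogeneous pairs (two
  reconstructions of one conformation). For heterogeneous pairs the
  transport loss can prefer a visibly wrong alignment — mass in the
  differing region is cheaper to transport under a small rotation — which
  is why the refinement stage deliberately switches to the Euclidean
  loss, and why `make_loss(kind = "custom")` exposes the loss slot for
  experimentation.

### Why a transport loss

For a pure translation the 1-Wasserstein distance satisfies
`W1(f, shift(f, v)) = ‖v‖` — a convex function of `v` with a single
minimum — and perturbation bounds for rotations carry a moment factor
rather than the Euclidean loss's oscillatory overlap structure. In
practice this buys a much wider basin of attraction around the true
rotation for irregular molecules. The package ships a diagnostic
(`landscape_scan`) that evaluates a self-alignment loss along a rotation
slice; on the shipped 4-lobe phantom the region where the WEMD stays
below half of its 90-degree value is about 34 degrees wide, versus about
21 degrees for the Euclidean loss. Notably this *irregularity* matters:
for a smooth ellipsoid the WEMD slice actually peaks near 45 degrees and
is not monotone on [0°, 90°], and the same width comparison comes out
reversed — the flat-basin advantage is a statement about molecule-like
shapes, not about all volumes.

### The WEMD

With `w_{j,k}` the coefficients of a 3D orthonormal wavelet expansion of
`f − g` at dyadic scale `j` (convention `ψ_{j,k}(x) = 2^{jd/2} ψ(2^j x −
k)`, larger `j` finer, `d = 3`):

    WEMD(f, g) = Σ_{j,k} 2^{−j(1+d/2)} |w_{j,k}|

is metrically equivalent to `W1` and costs `O(n³)`. Implementation
choices, all pinned for reproducibility:

* **Wavelet**: `sym3`, decomposed by a separable 3D analysis bank
  written directly in the package (no wavelet dependency); the filter
  bank reproduces PyWavelets' `mode = "zero"` decomposition exactly.
* **Boundary**: zero padding. Maps are compactly supported in-box, so
  padding adds no spurious coefficients; the mode matters only for
  bit-reproducibility.
* **Depth** `J`: default 6; depths with `2^(J−1) > n` are refused as
  coarser than the box. In the signature, the detail level `l` (1 =
  finest) carries weight `2^{(l−1)(1+d/2)}` — coarse scales are weighted
  up because moving mass far costs more — i.e. the finest resolvable
  grid scale is indexed `j = 0` in the formula above.
* **Approximation band**: the coarsest scaling band is kept, at the
  coarsest-level weight. Dropping it (as is common when both inputs are
  mass-normalized and mean-subtracted) makes the distance blind to bulk
  displacement of the total mass, which the alignment loss needs.
* **No mass normalization** by default: the approximation is defined for
  signed, non-unit-mass maps.

The approximation tracks the exact translation identity only up to its
equivalence constants: measured on an isotropic Gaussian blob with
σ = n/8 in a 64³ box at `J = 7`, the ratio `WEMD(f, shift(f,v))/‖v‖` is
constant to a ~4–5% coefficient of variation over `‖v‖ = 1..5` voxels;
for small blobs in small boxes at shallower depths the fine scales
saturate and the spread grows to ~8–10%. The signature cost is linear in
the voxel count, so deeper decompositions are essentially free.

## The optimizer

Centering reduces the search to SO(3). Bayesian optimization is used
because the WEMD is cheap to *evaluate* but awkward to differentiate:

1. Candidates start at the identity (`R₁ = I`).
2. A zero-mean Gaussian process with squared-exponential covariance on
   the Frobenius embedding, `k(R1,R2) = σ² exp(−‖R1−R2‖²_F / 2ℓ²)`, is
   conditioned on the history `(R_i, y_i)`; the kriging mean
   `m(R) = k_n(R)' (K + εI)^{-1} y` is the acquisition function (GP-UCB
   with no exploration term; early stopping of its minimization plays
   the exploratory role).
3. `m` is minimized by Riemannian steepest descent from one Haar-random
   start: Euclidean gradient `Σ w_i k(R,R_i)(R_i − R)/ℓ²` projected to
   the tangent space, QR retraction, backtracking (Armijo) line search,
   stop when both the Riemannian gradient norm and the step size drop
   below 0.1 or after 100 inner iterations.
4. The new candidate's loss is evaluated and appended; after `N`
   evaluations the best-observed candidate is returned (first occurrence
   on ties).

### Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `iterations` (N) | 200 | total loss evaluations of the BO loop |
| `downsample` (m) | 32 | Fourier-crop size before the search (voxels per axis) |
| `lengthscale` (ℓ) | 0.75 (WEMD), 1.0 (L2) | kernel lengthscale in Frobenius units (SO(3) diameter is 2√2) |
| `nugget` (ε) | 1e-4 | kernel diagonal regularizer |
| `grad_tol`, `step_tol` | 0.1 | early-stop thresholds of the surrogate minimization |
| `refine` | TRUE | Nelder–Mead L2 polish |
| `refine_downsample` | 32 | grid size of the refinement stage |
| `handedness` | FALSE | also try the reflected moving map (doubles cost) |
| `depth` (J) | 6 | WEMD decomposition depth |
| `backend` | "fourier" | volume-rotation interpolation backend |

σ² is fixed at 1: the interpolant is independent of it (it cancels
between `k_n` and `K⁻¹`), so it is not exposed as a knob. The nugget
value is a stability default (the interpolation-property test passes at
1e-8 with ε = 0 on well-separated candidates); duplicate proposals are
additionally guarded by a 1-degree random perturbation when a candidate
lands within 1e-6 Frobenius distance of the history.

### Refinement and handedness

The BO stage localizes the rotation to a few degrees; Nelder–Mead then
minimizes the Euclidean loss over a 3-parameter rotation-vector
perturbation `δ ↦ ‖f1 − rotate(f2, exp(δ)·R_bo)‖₂` from `δ = 0`, at
downsampling 32 regardless of the BO level. The Euclidean loss is used
here deliberately: near the optimum its narrowness is an asset, and it
is less sensitive than transport distances to small differences between
the two reconstructions. Because Nelder–Mead returns its best vertex and
the start is a vertex, the refined loss never exceeds the loss at the BO
estimate.

Handedness is handled by reflecting the moving map (array flip through
the grid center) and rerunning the whole pipeline, keeping the branch
with the smaller final loss — equivalent in effect to optimizing over
O(3) but simpler, at exactly twice the cost.

### Numerical choices

* **Rotation convention**: `rotate_map(f, R)` computes `f(R'x)` about
  the grid center (0-based index `n %/% 2`), so the generative model
  `f2 = shift(rotate_map(f1, R_true), t)` is recovered directly;
  internally the loop searches in the inverse ("moving-map")
  parametrization and the result carries both (`rotation` forward,
  `rotation_bo`/`rotation_refined` internal).
* **Volume rotation**: zero-padded-FFT 2x upsampling followed by
  tricubic (Catmull–Rom) sampling of the rotated coordinates, with a
  trilinear fallback in the one-voxel boundary shell — a gridding
  approximation to evaluating the map's Fourier series on the rotated
  grid. Exact at the identity; ~1e-4 relative error for well-sampled
  blobs; mass preserved to well under 0.5%. A plain real-space
  `trilinear` backend (agreement within ~2–3% relative L2) removes the
  upsampling cost where speed matters more than accuracy.
* **Shifts** are Fourier phase shifts under the periodic convention;
  out-of-support wrap-around is accepted because inputs are compact.
  Sub-voxel shifts are exact for band-limited content (the unpaired
  Nyquist mode on even grids limits invertibility to ~1e-8 for
  adequately sampled maps).
* **Downsampling** keeps the central block of the centered spectrum and
  rescales so the mean voxel value is preserved.
* **Centering** thresholds the map (user contour, else the 80th
  percentile of positive voxels — a stand-in for the deposition's
  recommended contour level, which MRC files do not reliably carry),
  computes the center of mass on the thresholded copy, and applies the
  shift to the unthresholded map. The shift between the two maps is
  recovered at centering time (`t = com(f2) − R·com(f1)`) and not
  re-estimated after refinement.
* **Haar sampling** normalizes a 4D standard Gaussian to a unit
  quaternion — exactly uniform, seed-reproducible. `acos` arguments are
  clamped to [−1, 1]; the rotation-vector logarithm at 180° returns one
  of the two antipodal axes (tie broken by first nonzero component
  positive).
* **Degenerate inputs**: non-cubic arrays, non-finite values,
  nonpositive thresholded mass, singular matrices in the polar
  projection, duplicated candidates at zero nugget, and infeasible
  decomposition depths all raise immediate errors rather than
  propagating.

## The synthetic generator

`synthetic_spec()` defines a 4-lobe anisotropic Gaussian mixture:
centers inside the central half-box (so any rotation keeps support
in-grid), all pairwise center distances distinct (no rotational
symmetry, hence a unique global alignment), lobe standard deviations
0.055–0.088·n (1.8–2.8 voxels at n = 32 — adequately sampled, molecule
scale), weights 1/0.8/0.65/0.5. `make_pair` applies a Haar-random
rotation, an optional uniform shift (half-width 5 voxels where used, the
scale of "approximately centered" deposited maps), and i.i.d. Gaussian
voxel noise on the *transformed* copy with variance `mean(f1²)/SNR` —
SNR is defined as mean squared signal over noise variance.

What it emulates: a compact, asymmetric, smooth molecule at typical
working downsampling, under rigid transformation and shot-like voxel
noise. What it does not: CTF envelopes and B-factor decay, masks,
reconstruction correlations in the noise, or conformational
heterogeneity. Passing the shipped benchmarks therefore demonstrates
correct recovery under the stated generative model, not robustness to
everything a real deposition can contain; the real-data protocol (EMDB
entry EMD-3683) is wired into the test suite for users who download that
map.

## Problem sizes used in the shipped checks

The package's own experiments run at phantom size 32³ with N = 200
evaluations and 20 trials for the headline benchmark (minutes on one
CPU), 16³/N = 100 against a 1000-sample random-search oracle, 64³ for
the SNR calibration and shift-proportionality checks, and 1° resolution
for the landscape slices. These sizes were chosen so the full suite
documents the method's behavior at realistic working resolutions while
remaining quick to re-run.

## Known limitations

* Centering-based translation recovery degrades at high noise (the
  center of mass is a non-robust statistic); joint rotation-translation
  search is deliberately out of scope.
* The WEMD's advantage inverts for near-ellipsoidal volumes (see the
  landscape discussion above) and can prefer wrong alignments for
  heterogeneous pairs; the custom-loss hook is the intended escape
  hatch.
* Only cubic grids and MRC mode-2 (32-bit float) I/O are supported;
  resampling between voxel sizes, masking and segmentation belong to
  upstream tools.
* `relative_angle_deg` near 0° and 180° inherits the ~√eps precision of
  `acos`; errors below ~1e-5 degrees are not resolvable.
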