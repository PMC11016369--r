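# wembo

Rigid alignment of 3D density maps — such as cryo-EM reconstructions — by
minimizing a wavelet approximation of the 1-Wasserstein distance over the
rotation group with Gaussian-process Bayesian optimization.

## The problem

Two reconstructions of the same molecule come out of a cryo-EM pipeline in
arbitrary relative orientation: the second map is (approximately) a
rotated, shifted — and sometimes mirror-flipped — copy of the first,

```
f2(x) = f1( R' (x − t) ),    R ∈ SO(3), t ∈ R^3 .
```

Recovering `(R, t)` is a prerequisite for comparison, averaging and
conformational analysis, and has to be done many times, so it should be
fast and should not need a manual initial alignment. The Euclidean loss
`‖f1 − rotate(f2, R)‖₂` has a very narrow basin of attraction around the
true rotation for irregularly shaped molecules; transport (Wasserstein)
distances reflect rigid motions much more faithfully — for a pure
translation, `W1(f, shift(f, v)) = ‖v‖` exactly — and give a loss
landscape that a global optimizer can actually navigate.

## The method

1. **Translation** is removed up front: both maps are centered at the
   center of mass of their thresholded densities (`center_map`), which
   reduces the problem to a rotation search.
2. **Loss.** Exact `W1` costs `O(n^6 log n)` per evaluation on an `n³`
   grid; instead the package uses the wavelet earth mover's distance
   (`wemd`): with `w_{j,k}` the 3D sym3 wavelet coefficients of `f − g`
   at dyadic scale `j` (larger j = finer),

   `WEMD(f, g) = Σ_{j,k} 2^{−j(1 + d/2)} |w_{j,k}|,  d = 3`,

   a metric equivalent to `W1`, computable in `O(n³)`, and well defined
   even for maps with negative values.
3. **Search.** Bayesian optimization over SO(3) (`bo_align`): a zero-mean
   Gaussian process with squared-exponential covariance on the Frobenius
   embedding, `k(R1, R2) = σ² exp(−‖R1−R2‖²_F / 2ℓ²)`, is conditioned on
   all loss values seen so far; its kriging mean (plus a small nugget) is
   minimized by Riemannian steepest descent with a QR retraction and
   early stopping (gradient norm and step < 0.1) to propose the next
   rotation to evaluate. After `N` evaluations (default 200, starting
   from the identity) the best candidate is returned.
4. **Refinement** (optional, default on): Nelder–Mead over a 3-parameter
   rotation-vector perturbation, minimizing the *Euclidean* loss at
   downsampling 32 — a narrower but more perturbation-robust local
   metric (`refine_nelder_mead`).
5. **Handedness** (optional): the whole search is repeated against the
   reflected moving map and the better branch is reported with a
   `reflected` flag.

Maps are Fourier-cropped to 32³ (configurable) before the search; volume
rotation uses trigonometric (zero-padded FFT) upsampling plus tricubic
sampling, a gridding approximation of nonuniform Fourier evaluation on
the rotated grid.

## Worked example

```r
library(wembo)

# a reproducible asymmetric 4-lobe phantom and a transformed noisy copy
f1   <- gaussian_mixture_map(synthetic_spec(32))
R    <- random_rotation(seed = 9)
pair <- make_pair(f1, R, t = c(2.4, -3.1, 1.2), snr = 10, seed = 9)

res <- align_volumes(pair$f1, pair$f2,
                     align_config(iterations = 200, seed = 1))
res
#> alignment_result
#>   rotation (forward, f1 -> f2):
#>       0.85980 -0.13499  0.49246
#>       0.48079 -0.11082 -0.86980
#>       0.17199  0.98463 -0.03038
#>   shift (voxels): 2.054, -2.865, 1.052
#>   reflected: FALSE
#>   best BO loss: 43.8896 after 200 evaluations
#>   refined L2 loss: 0.0224907 (202 extra evaluations)

recovery_error(res$rotation, R)      # rotation error, degrees
#> [1] 0.868027
sqrt(sum((res$shift - c(2.4, -3.1, 1.2))^2))  # shift error, voxels
#> [1] 0.4434635
```

The rotation error is the relative angle (geodesic distance on SO(3))
between estimate and truth. At SNR 10 the noise biases the center of
mass by a fraction of a voxel and leaves the rotation within a degree;
on clean pairs the pipeline typically lands well under 0.1 degrees after
refinement with shift error in the hundredths of a voxel.

For files on disk, the same pipeline is available from the shell:

```sh
exec/wembo align --fixed A.mrc --moving B.mrc --seed 1 --out result.json
exec/wembo bench --trials 5 --iters 100          # seeded synthetic benchmark
exec/wembo synth --out-prefix demo --snr 10      # generate a test pair
```

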