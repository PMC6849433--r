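# oatv

Model-based 2D optoacoustic (photoacoustic) tomography reconstruction with
adaptive anisotropic total-variation (A²TV) regularization.

Optoacoustic images of tissue are dominated by blood vessels: long, thin,
branching, *non-convex* structures. Reconstructing them from noisy or
sparse-view tomographic data needs regularization, but isotropic total
variation penalizes boundary length and therefore rounds complex vessel
boundaries into convex blobs when pushed hard. `oatv` implements the
adaptive anisotropic alternative for researchers working on model-based
inversion: a per-pixel tensor `A(x)`, derived from the structure tensor of
a current estimate, steers the TV penalty so that it stays isotropic in
flat regions but nearly vanishes *across* detected edges:

```
u* = argmin_u  Σ_x ||A(x) ∇u(x)||₂  +  (λ/2) ||M u − p||₂²
A(x) = V diag(c(μ₁/μ₁_avg; k), 1) Vᵀ ,   c(s;k) = 1 − exp(−c_m (s/k)^(−m))
```

with `(μ₁, V)` the leading eigen-pair of the smoothed structure tensor,
`c_m = 3.31488`, `m = 4`, and `k ∈ (0, 1]` controlling how much of the
image is treated anisotropically. The tensor starts as the identity and is
re-estimated from each solution (alternating outer loop, Chambolle–Pock
primal-dual inner solver).

The package is self-contained:

* **Forward model** — sparse system matrix for arc detection geometries:
  circular-arc spherical means with bilinear pixel interpolation and a
  time-derivative stencil (`build_model_matrix`, `forward_project`,
  `adjoint_project`, `normalize_model_matrix`).
* **Phantoms & degradations** — random-walk vessel phantoms, analytic
  disks, Gaussian projection noise at a fraction of `max|p|`, uniform
  sparse-view subsampling (`generate_vessel_phantom`,
  `add_projection_noise`, `subsample_projections`).
* **Solvers** — LSQR, Tikhonov, TV-L1 (with an orthonormal Daubechies-4
  wavelet sparsity term) and A²TV (`reconstruct_lsqr`,
  `reconstruct_tikhonov`, `reconstruct_tv_l1`, `reconstruct_a2tv`).
* **Metrics & experiments** — mean absolute distance (MAD), relative L2
  error, slice profiles, and a reproducible experiment runner
  (`image_mad`, `run_experiment`).

## Worked example

A 64×64 vessel phantom, 64 detectors on a 270° arc of radius 40 mm, heavy
projection noise (std = 0.6 × max |p|):

```r
library(oatv)
grid  <- image_grid(64, 64, 0.1)                 # 0.1 mm pixels
geom  <- detection_geometry(40, 270, 64)
M     <- normalize_model_matrix(build_model_matrix(grid, geom))
truth <- generate_vessel_phantom(grid, vessel_phantom_params(seed = 1))
p     <- add_projection_noise(forward_project(M, truth), 0.6, seed = 2)

fit_ls <- reconstruct_lsqr(M, p, n_iter = 50)
fit_a2 <- reconstruct_a2tv(M, p, solver_config("a2tv", lam = 0.2, k = 0.1,
                                               n_iter = 300, n_outer = 2))
round(c(lsqr = image_mad(truth, fit_ls$image),
        a2tv = image_mad(truth, fit_a2$image)), 3)
#>  lsqr  a2tv
#> 1.173 0.390
```

MAD is the mean absolute per-pixel distance to the ground truth (in the
phantom's arbitrary intensity units, range [0, 1]): the unregularized
least-squares image is dominated by noise, while the A²TV reconstruction
recovers the vessel tree with roughly a quarter of the error. Lower `k`
increases anisotropy; lower `lam` increases overall regularization.

A command-line front end (`inst/cli/oatv.R`) exposes `simulate`,
`build-matrix`, `reconstruct`, `evaluate`, `run-experiment` and
`make-fixtures` subcommands over the same functions.

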