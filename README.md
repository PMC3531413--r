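# cytoremodel

Simulation and analysis of stretch-induced actin cytoskeleton remodeling in
fibroblasts embedded in 3D engineered tissue constructs (ETCs).

When a cell-populated collagen ring is rapidly stretched and held, the
fibroblasts inside respond over the following half hour by remodeling their
stress fibers: some cells reinforce monotonically, some retract and then
reinforce, and some retract without recovery, with reinforcement directed
predominantly along the stretch.  `cytoremodel` packages the computational
chain needed to study this behavior for people working on cell mechanics
and mechanobiology:

- **Strain kinematics** — a nominal-to-local strain calibration for
  anisotropic ring constructs, the orientation-resolved fiber strain
  `eps(theta) = eps_o (cos^2 theta − nu sin^2 theta)` (which at the
  measured effective Poisson ratio `nu ≈ 1` becomes `eps_o cos 2 theta`),
  and affine strain estimation from tracked bead displacements.
- **A stress-fiber sector model** — a cell as 36 oriented sectors with
  random pre-stretch `lambda_pre` drawn from a truncated normal.  A sector
  depolymerizes when its total stretch
  `lambda = lambda_pre (1 + eps(theta))` leaves the allowable window
  `[lambda_min, lambda_max]` (tensile rupture above, compressive buckling
  below); intact sectors whose adhesion stress
  `s = k rho max(lambda − 1, 0) · load_share` falls in an intermediate band
  polymerize towards a saturating density.  Rupture of tensile fibers
  lowers `load_share`, releasing adhesion stress globally — the mechanism
  that converts high pre-stretch variability into monotonic retraction.
- **Fibrosity** — a band-pass statistic on the 2D power spectral density of
  a fluorescence image that grows linearly with the total contour length of
  features in the stress-fiber thickness band (default 0.3–1.0 µm), after
  luminosity adjustment; plus z-stack collapse, integer-pixel alignment,
  and signed subtraction images.
- **Response analysis** — classification of normalized fibrosity traces
  into the three temporal classes, contingency-table statistics (Pearson
  chi-square, Fisher's exact test), and active contractile force per cell
  from isometric force traces.
- **Synthetic data** — seeded generators for fibrous-cell image series
  (with F-actin reservoir blobs and flux conservation), bead fields, and
  force traces, so every stage of the pipeline is testable end to end.

## Worked example

Simulate one low-variability cell under the 10% nominal (5% local)
stretch protocol, render its predicted image series, and measure it back:

```r
library(cytoremodel)

local_strain(0.10)           # 10% nominal ETC stretch reaches the cells as...
#> [1] 0.05                  # ...5% local strain

p   <- sim_params(sigma_pre = 0.01, seed = 5)
sim <- simulate_remodeling(p, eps_o = local_strain(0.10),
                           keep_densities = TRUE)
sim
#> <sim_output> circular cell, eps_o = 0.050: monotonic_reinforcement
#>   fibrosity 1.00 -> 1.191 (min 1.000); 0/36 sectors depolymerized

ser <- render_cell_series(sim, render_spec(seed = 9))
tr  <- fibrosity_trace(ser$images, times = ser$times)
round(tr$values, 3)
#> [1] 1.000 1.214 1.231 1.229 1.231 1.230 1.231
as.character(classify_trace(tr))
#> [1] "monotonic_reinforcement"
```

No fiber leaves the allowable window at this low pre-stretch variability,
stretch-aligned sectors polymerize, and the image-side fibrosity trace
rises ~20% and classifies as monotonic reinforcement — the image pipeline
recovers the model's own verdict.  Sweeping the pre-stretch spread
reproduces all three temporal classes, each dominant at one level:

```r
sw <- sweep_prestretch_sd(c(0.01, 0.045, 0.5), n_reps = 20,
                          base_params = sim_params(seed = 1), eps_o = 0.05)
sw$frequencies
#>        class
#> sigma   monotonic_reinforcement retraction_then_reinforcement
#>   0.01                     1.00                          0.00
#>   0.045                    0.15                          0.55
#>   0.5                      0.00                          0.35
#>        class
#> sigma   monotonic_retraction flat
#>   0.01                  0.00    0
#>   0.045                 0.30    0
#>   0.5                   0.65    0
```

The strain-estimation side closes its own loop: bead fields generated
under the `nu = 1` deformation gradient give back the strains and the
effective Poisson ratio,

```r
est <- estimate_affine(gen_beads(50, diag(c(1.05, 0.95)),
                                 noise_sd = 0.1, seed = 3))
round(c(axial = est$axial, transverse = est$transverse,
        nu = poisson_ratio(est$axial, est$transverse)), 4)
#>      axial transverse         nu
#>     0.0499    -0.0499     0.9996
```

See `vignette("cytoremodel-methods")` for the model assumptions, parameter
defaults and their calibration, and the design of the fibrosity statistic.

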