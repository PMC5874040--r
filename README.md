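# embryoalign

Automated spatiotemporal alignment of 4D fluorescence movies of
developing *C. elegans* embryos, from pre-morphogenesis to the onset of
muscle twitching.

## The problem

A *C. elegans* embryo develops inside a rigid, prolate eggshell
(roughly 50 × 25 × 25 µm). Movies of two different embryos cannot be
compared voxel-to-voxel because each embryo:

- starts being imaged at a different developmental time,
- differs a few percent in eggshell length and width,
- sits at an arbitrary position and orientation in the camera frame, and
- **rotates as a bulk about its long axis** during morphogenesis, by an
  amount and schedule unique to each individual.

`embryoalign` estimates all four factors from two fluorescence
channels — a pan-nuclear marker (all nuclei) and a sparse, spatially
asymmetric fiducial nuclear marker — and composes them into a single
rigid-plus-anisotropic-scaling map that carries any point of a test
embryo, at any matched timepoint, into a reference embryo's intrinsic
coordinate frame. That makes structures such as the forming nerve ring
directly superimposable across individuals.

## How it works

1. **Temporal alignment.** Nuclear counts (a monotone proxy for
   developmental stage) are interpolated 5× with a monotone
   Fritsch–Carlson Hermite spline; the offset between two embryos is
   the minimizer of the per-point-normalized squared difference between
   their count curves. Cell-count plateaus (≈200- and ≈330-cell stages)
   are detected by an adaptive percent-change threshold as independent
   staging landmarks.
2. **Intrinsic axes.** The long axis P1 is the smallest-moment
   eigenvector of the inertia tensor of the uniform-density **convex
   hull** of the segmented nuclei, computed analytically by exact
   tetrahedral decomposition (no rasterization). The anterior sign and
   the perpendicular axes P2/P3 come from the fiducial channel's
   spatial asymmetry.
3. **Scale factors.** With `a` the smallest principal moment and `b`
   the mean of the two larger, `q1 = a_ref/a_test` and
   `q2 = (b_ref − a_ref/2)/(b_test − a_test/2)` give closed-form
   length and width factors `r_l = q1^(−1/5) q2^(2/5)`,
   `r_s = q1^(3/10) q2^(−1/10)` (exact for uniform ellipsoids; moments
   scale as the 5th power of an isotropic scale).
4. **Rotation tracking.** Fiducial voxels at consecutive fast-phase
   timepoints are projected onto the (P2, P3) plane and registered with
   **coherent point drift** (CPD: Gaussian-mixture EM with a uniform
   outlier component and deterministic annealing; a rotation-damped
   variant is provided). The translation is replaced by a frame-center
   correction, so each step is a pure signed rotation about P1; steps
   accumulate into each embryo's rotation track.
5. **Mapping and refinement.** Coarse orientation match between frames,
   a 2D CPD refinement at an early timepoint (failure flagged above
   40°), composition of both rotation tracks, and an optional capped 3D
   rigid CPD polish per timepoint.
6. **Quantification.** Bidirectional 1-µm overlap fractions between
   masks after each ablation stage (`none` → `long_axis` → `indirect`
   → `full`), plus nerve-ring geometry: plane fits by
   geometric-median vector decomposition, centroid and plane-angle
   dispersion.

A synthetic embryo-movie generator (`simulate_embryo()`) with full
ground truth (offsets, scales, per-step rotations, ring geometry)
validates every stage end to end. See the methods vignette
(`vignettes/embryo-alignment.Rmd`) for the model, parameter rationale,
and numerical pitfalls (voxel-lattice locking of annealed registration,
subnormal-underflow in Gaussian kernels, raw-vs-normalized offset
criteria).

## Worked example

Simulate a reference embryo and a test embryo that lags it by 10
minutes, is 3% longer and 1% narrower, and rotates 30° about its long
axis over the fast phase — then recover all of that blind (scaled-down
grid so it runs in about a minute):

```r
library(embryoalign)

grid <- acquisition_grid(voxel_size_um = 0.65, shape_voxels = c(96, 48, 48),
                         fast_count = 16)

ref <- simulate_embryo(synthetic_embryo_spec(
  seed = 101, grid = grid, temporal_offset_min = 0, theta0_deg = 20,
  reporter_timepoints = fast_timepoints(grid)))
tst <- simulate_embryo(synthetic_embryo_spec(
  seed = 202, grid = grid, temporal_offset_min = -10,
  total_rotation_deg = 30, length_scale = 1.03, width_scale = 0.99,
  reporter_timepoints = max(fast_timepoints(grid))))

res <- align_embryo(tst, ref, align_config(seed = 9, n_sample = 1200))
glance(res)
```

```
# A tibble: 1 × 12
  embryo_id   offset_min   r_l   r_s coarse_p2_rotation_deg early_refinement_deg
  <chr>            <dbl> <dbl> <dbl>                  <dbl>                <dbl>
1 synthetic-…        -10 0.964  1.00                   154.                0.510
```

The temporal offset is recovered exactly (−10 min). The reference
embryo carries its own small scale jitter, so the true ratios are
r_l = 0.96368 and r_s = 0.99812; the estimates are 0.96377 (0.01% off)
and 1.00268 (0.46% off). The cumulative rotation estimate is 30.70°
against a 30° truth. Per-timepoint refinements stay small and uncapped
(`tidy(res)`: angles 0.2–1.5°, shifts ≈ 0.1 µm). The composed map puts
the synthetic nerve-ring centroid where it belongs in the reference:

```r
k  <- nrow(res$pairs); tp <- res$pairs$t_test[k]
mapped <- map_points(res, matrix(true_ring_centroid(tst, tp), 1), tp, "full")
sqrt(sum((mapped - true_ring_centroid(ref, res$pairs$t_ref[k]))^2))
#> ring centroid error (um): 0.0619137
```

and overlap improves monotonically across the ablation stages:

```r
overlap_by_stage(tst, ref, res, channels = "fiducial")
```

```
# A tibble: 4 × 5
  stage     channel  frac_test_near_ref frac_ref_near_test overlap
1 none      fiducial              0.269              0.261   0.265
2 long_axis fiducial              0.269              0.261   0.265
3 indirect  fiducial              1                  1       1
4 full      fiducial              1                  1       1
```

(`none` and `long_axis` coincide here because both simulated eggshells
already share the camera-frame long axis; the jump at `indirect` is the
rotation tracking doing its job.)

A thin command-line wrapper over the same functions lives at
`inst/cli/embryoalign.R` (subcommands `simulate`, `temporal`, `axes`,
`rotations`, `align`, `run`), driven by a YAML config via
`run_pipeline()`.

## Scope and limitations

The map is rigid-plus-anisotropic-scaling: it is meaningful only up to
twitching onset, tracks rotation about the long axis only, and requires
an asymmetric, anterior-biased fiducial marker (symmetric markers are
rejected as ambiguous rather than guessed). The synthetic generator
emulates acquisition geometry, count dynamics, rotation statistics and
reporter geometry, but not segmentation noise or non-rigid
deformation — see the vignette for details.
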