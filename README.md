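# cerebropwv

Global intracranial pulse wave velocity (PWV) from cardiac-gated 4D flow
MRI.

Arterial stiffening speeds up the systolic pressure pulse. In the brain the
transit delays between measurable sites are only a few milliseconds — far
below the ~50 ms frame spacing of a gated 4D flow acquisition — so no pair
of sites yields a usable transit time. `cerebropwv` instead pools *every*
detectable arterial cross-section of the cerebral tree: each site `i`
contributes a normalized velocity waveform `v_i·`, an ROI area, and a
vascular path distance `r_i` from the internal-carotid roots, and a single
global PWV is estimated jointly with the shared waveform shape `V` by
weighted maximum likelihood:

    (PWV, V) = argmin  Σ_i W_i Σ_j ( Ṽ(t_j − r_i/PWV; V) − v_ij )²,
    W_i = area_i / scaling_i²,

where `Ṽ(t; V)` interpolates linearly (with periodic wraparound over the
cardiac cycle) between knots placed at the `M = 20` frame times, and
`scaling_i` is the reciprocal SD used to normalize waveform `i`. The
package is aimed at researchers working with intracranial 4D flow data or
developing transit-time methods, and ships a digital flow phantom so the
whole chain is testable without scan data.

The pipeline: complex-difference angiogram (`CD = m·sin θ`,
`θ = π‖v‖/venc` truncated to `[0, π/2]`) → multiscale Hessian vesselness
(τ = 1) → global 2.5% binarization → topology-preserving 3D thinning into a
branch-labeled centerline tree → per-voxel perpendicular cross-sections
(2× upsampled planes, 50%-of-peak lumen ROI, through-plane velocity via dot
product with the local direction) → multi-source shortest-path distances
from the carotid seeds → joint PWV/waveform fit.

## Worked example

Simulate 500 cross-sections from the estimator's model (true PWV 10 m/s,
depths 50–300 mm, Gaussian noise SD 0.3 on unit-SD waveforms) and fit:

```r
library(cerebropwv)

spec <- phantom_spec(true_pwv = 10, mode = "knot", seed = 1)
sim  <- simulate_waveform_set(spec, N = 500, distance_range = c(50, 300),
                              noise_sd = 0.3)
fit  <- pwv_fit(sim$records)
fit
#> <pwv_fit> PWV = 9.910 m/s (N = 500 cross-sections)
#>   objective: 7116.17, converged: TRUE, function evals: 152
#>   distance spread: 248.6 mm, delay span: 0.53 frames
```

The fitted PWV (9.91 m/s) recovers the injected 10 m/s to within 1%; the
delay span of 0.53 frames shows how little temporal shift the estimator is
working with. The independent grid oracle — exact weighted least squares in
`V` at each fixed PWV — lands on the same optimum, and splitting the
cross-sections into alternating halves by depth gives two concordant
estimates:

```r
profile_fit_oracle(sim$records)$best_pwv
#> [1] 9.9
split_half_consistency(sim$records)[c("pwv_odd", "pwv_even")]
#> $pwv_odd
#> [1] 10.79
#> $pwv_even
#> [1] 9.15
```

`tidy()`, `glance()`, and `autoplot()` work on fitted objects;
`plot_waveform_fan()` shows the depth-colored waveforms;
`run_pipeline(list(phantom = phantom_spec(seed = 42)))` executes the whole
imaging chain on a noise-free Y-tree phantom volume. A thin command-line
dispatcher over these functions lives at `inst/cli/cerebropwv.R`
(`simulate`, `run`, `fit`, `cohort`).

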