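# smtpipe

Single-molecule tracking (SMT) analysis and simulation for live-cell
imaging of nuclear proteins.

High-throughput SMT images sparse, fluorescently labeled protein molecules
in live cell nuclei at ~100 Hz and reconstructs their motion; the
distribution of diffusion coefficients then reports how a perturbation —
for example a small-molecule inhibitor that traps its target on chromatin
— changes the protein's behavior: the chromatin-bound fraction rises and
the nuclear spot density falls as the target is trapped or degraded.
`smtpipe` implements the full analysis chain for such experiments,
together with a ground-truthed movie simulator so every stage can be
validated without microscope data.

## The method

For each field of view (one tracking movie plus one nuclear-stain movie):

1. **Detection.** Every 11 × 11 pixel tile is tested for a Gaussian spot
   (σ_w = 1.5 px) against a white-noise background with a generalized
   log-likelihood ratio,

   LLR = −(w²/2) log[1 − (Σ X G)² / (Σ X² − (Σ X)²/w²)],

   computed densely via frequency-domain convolution; local maxima with
   LLR ≥ 14 are called spots.
2. **Subpixel localization.** Each spot is fit with the 2-D integrated
   Gaussian PSF model f_ij = I·Δx_i·Δy_j + b by damped
   Levenberg–Marquardt (γ = 0.3, α = 10⁻⁴, ≤ 8 iterations), initialized by
   the radial-symmetry method.
3. **Linking.** Detections within 1.25 µm and 3 frames form a candidate
   graph; marginal link probabilities are inferred jointly with per-spot
   diffusion coefficients under a Brownian model, and a hill-climbing
   search selects the conflict-free link set maximizing the summed log
   marginals; connected components are trajectories.
4. **Nuclei.** The stain movie's mean projection is segmented
   (smooth/Otsu/watershed) and each trajectory is assigned to at most one
   nucleus.
5. **State arrays.** Per FOV, trajectory occupations are inferred on a
   grid of 100 diffusion coefficients (0.01–100 µm²/s, log-spaced) × 31
   localization errors (0.02–0.08 µm) with the likelihood of regular
   Brownian motion with localization error (RBME); the error axis is
   marginalized out, giving the diffusion-coefficient distribution from
   which mean D, bound/slow/fast fractions, and nuclear spot density
   derive.

See `vignettes/smt-methods.Rmd` for the models, defaults and numerical
conventions in detail.

## A worked example

Simulate one field with two diffusive states (bound 0.05 µm²/s at 30%,
free 3.0 µm²/s at 70%), run the full pipeline in memory, and inspect the
per-FOV summary:

```r
library(smtpipe)

cfg <- sim_config(n_frames = 100L, image_shape = c(256L, 256L),
                  n_nuclei = 2L, seed = 42L)
sim <- simulate_fov(cfg)
res <- process_fov(sim$movie, sim$hoechst_movie,
                   pipeline_config(n_frames = 100L))
print(res$summary, row.names = FALSE)
#>   plate well fov n_nuclei n_trajectories   mean_D bound_fraction slow_fraction
#>  plate1   A1   1        2             58 1.138198      0.3485676     0.1813232
#>  fast_fraction spot_density
#>      0.4701092   0.03098825
```

Here 58 trajectories in 2 nuclei give an occupation-weighted mean
diffusion coefficient of ≈ 1.1 µm²/s, a chromatin-bound fraction of
≈ 0.35 (occupation mass at D ≤ 0.1 µm²/s, against a generating bound
occupancy of 30%), and a nuclear spot density of ≈ 0.031 detections
µm⁻² frame⁻¹.
`plot_state_array(res$posterior)` draws the occupation histogram over
log D. A matched treated/control pair emulating chromatin trapping comes
from `make_condition_pair()`, and `aggregate_condition()` averages FOV
summaries per condition with optional normalization to the control.

File-based runs use `simulate_fov_to_dir()` to write TIFF/CSV fixtures and
`run_pipeline()` (or `Rscript scripts/run_pipeline.R`) to process a table
of movie paths into per-FOV CSV artifacts plus a JSON manifest.

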