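---
title: "Methods: single-molecule tracking analysis in smtpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule tracking analysis in smtpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smtpipe analyzes live-cell single-molecule tracking (SMT) movies of
sparsely labeled nuclear proteins and summarizes each field of view (FOV)
by the distribution of diffusion coefficients of the tracked molecules.
This vignette documents the models, the numerical choices, and the limits
of what the accompanying tests demonstrate.

## The measurement model

A tracking movie is a stack of short-exposure frames (default 150 frames at
100 Hz, with a 407 µs stroboscopic excitation pulse) in which individual
fluorophores appear as diffraction-limited spots on a noisy camera
background. The pipeline runs in five stages.

### Spot detection (GLRT)

For every 11 × 11 pixel tile we compare two hypotheses: pure white Gaussian
noise, versus noise plus a Gaussian spot of fixed width $\sigma_w = 1.5$
px whose template $G$ is normalized to zero mean and unit energy.
Evaluating both at their maximum-likelihood parameters gives the
generalized log-likelihood ratio

$$\mathrm{LLR} = -\frac{w^2}{2}\,\log\!\left[1 -
  \frac{\left(\sum_{ij} X_{ij} G_{ij}\right)^2}
       {\sum_{ij} X_{ij}^2 - \tfrac{1}{w^2}\left(\sum_{ij} X_{ij}\right)^2}
  \right],\qquad w = 11 .$$

The three tile sums are computed for all tiles at once by frequency-domain
convolution; the map is evaluated densely (a tile centered on every pixel)
and spots are called as local maxima with $\mathrm{LLR} \ge 14$, the
threshold balancing recall against false detections. Non-maximum
suppression with a 3 px radius prevents one emitter from being counted in
several adjacent supra-threshold tiles; the radius is configurable since
reasonable implementations may deduplicate differently.

Numerical conventions: a constant tile has an undefined ratio and is
assigned LLR 0 (no evidence of a spot); when rounding drives the log
argument to zero or below it is clamped at $10^{-12}$, capping the map at a
finite value while preserving ordering; no detections are reported within
$w\,\mathrm{div}\,2 = 5$ px of the frame edge, where the tile does not fit.

### Subpixel localization

Each detection is refined by fitting the 2-D integrated Gaussian PSF
model: the Gaussian is integrated over each pixel's unit square, so with
$\Delta x_i = \tfrac12[\mathrm{erf}((x_i - x_0 + \tfrac12)/\sqrt{2}\sigma_w)
- \mathrm{erf}((x_i - x_0 - \tfrac12)/\sqrt{2}\sigma_w)]$ and $\Delta y_j$
analogous, the model is $f_{ij} = I\,\Delta x_i \Delta y_j + b$ over
$\theta = (x_0, y_0, I, b)$, with $\sigma_w$ held at 1.5 px. The fit is a
damped Levenberg–Marquardt iteration

$$\theta^{(t+1)} = \theta^{(t)} + \gamma\,(J^\top J + \alpha
I)^{-1} J^\top (X - f(\theta^{(t)})),$$

with $\gamma = 0.3$, $\alpha = 10^{-4}$, at most 8 iterations, and
convergence called when $x_0$ and $y_0$ both move by less than $10^{-4}$
(pixel units; the natural reading of a position tolerance). This is the
standard damped Gauss–Newton step written with $J$ the Jacobian of the
model; the equivalent formulation with the residual Jacobian flips the
sign in front of $\gamma$. The identity scaling $\alpha I$ is used exactly
as written rather than Marquardt's diagonal scaling. The position is
initialized by the radial-symmetry method (gradient lines of a radially
symmetric spot intersect at its center; we minimize the weighted squared
distance to the gradient lines computed on the half-pixel dual lattice),
which on noiseless model spots is itself accurate to better than
$10^{-4}$ px. Intensity starts at $\sum(\text{tile} - \min)$ and offset at
the tile-border median — cheap, robust choices the model is insensitive
to. If the normal matrix is singular or the position leaves the tile, the
initialization is returned flagged unconverged.

Positions are continuous, in pixel units, origin at the center of the
first pixel (row = $y$, col = $x$); micron coordinates multiply by the
pixel size (default 0.1083 µm/px, the ratio of the camera field 187.14 µm
/ 1728 px).

### Trajectory linking

Candidate links join any two detections separated by at most 1.25 µm and
at most 3 frames. Link probabilities are inferred jointly with a per-spot
diffusion coefficient: a link's likelihood is the 2-D Gaussian density of
its displacement with per-axis variance $2\bar{D}\,\delta\Delta t +
2\sigma_{loc}^2$ ($\bar D$ averages the source and target estimates,
$\delta$ the frame gap), and each detection carries a constant-density
no-link alternative (birth/death), uniform over the 1.25 µm search disc:
$c = 1/(\pi \cdot 1.25^2)$ µm$^{-2}$. Marginal link probabilities are the
responsibilities over each detection's alternatives, symmetrized between
the outgoing and incoming sides by sum-product message passing on the
one-link-per-detection constraint graph; for small connected components
(≤ 10 candidate links) the marginals are computed exactly by enumerating
conflict-free configurations under the same model, so the approximation
only operates where enumeration would be costly. Per-spot diffusion
coefficients are re-estimated from probability-weighted squared
displacements (initialized at 0.5 µm²/s, mid-range on the log grid; the
estimate is insensitive to this after iteration) and the scheme iterates
to a $10^{-4}$ tolerance or 20 rounds.

The final link set maximizes the sum of log marginal probabilities of the
selected links plus the log no-link masses of unmatched detections — the
no-link terms matter, because all $\log p \le 0$ and without them the
empty matching would be trivially optimal. A hill-climbing search with
add, remove, swap, and rotation moves (a swap that reconnects the
displaced endpoints through another candidate) finds a local optimum that,
on every small instance we enumerate, is the global one. Trajectories are
the connected components of the selected subgraph; gaps up to 3 frames are
retained inside a trajectory.

Linking accuracy on ground truth is essentially perfect at sparse
densities except for one intrinsic failure mode: when two fast molecules'
paths interleave within the search radius for many frames, their
identities can swap — positions alone cannot distinguish crossing from
non-crossing Brownian paths, so no displacement-likelihood tracker
resolves these. Such exchanges, not proximity misassignments, account for
nearly all wrong links in our simulations (typically ~1% of links at 0.02
emitters/µm², more at higher density).

### Nuclear segmentation and assignment

The nuclear-stain movie is averaged into a mean projection and segmented
classically: Gaussian smoothing, Otsu threshold, hole filling,
distance-transform watershed to split touching nuclei, and removal of
components below 20 µm². The learned segmenter used on real microscopes
has no published weights or training data, so this package deliberately
ships the classical pipeline behind the identical image → label-mask
contract; a learned model can be dropped in without touching anything
else. Each localization takes the label of the pixel containing it;
trajectories take the majority label of their localizations (a rule is
needed because a gap-spanning trajectory can straddle a boundary), and
trajectories whose majority is background are excluded from state
inference (configurable).

### State-array inference

Dynamics are summarized per FOV by Bayesian inference on a fixed state
grid: 100 diffusion coefficients log-spaced from 0.01 to 100 µm²/s (the
four-decade span makes log spacing the only sensible choice; linear
spacing would spend 95 points above 5 µm²/s) crossed with 31 localization
errors linearly spaced from 0.02 to 0.08 µm (1-D RMSD). The trajectory
likelihood is regular Brownian motion with localization error (RBME): the
observed positions are true Brownian positions plus independent
localization errors, so per axis the jump sequence of a trajectory is
multivariate Gaussian with variance $2D\,\delta_k\Delta t + 2\sigma^2$ per
jump and covariance $-\sigma^2$ between consecutive jumps, which share the
error of their common endpoint. This anticorrelation is essential: with
independent-jump likelihoods, $(D, \sigma)$ is degenerate along the ridge
$2D\Delta t + 2\sigma^2 = \text{const}$ and slow states cannot be pinned
down (we measured the marginal mode 11 grid cells off at
$D = 0.02$ µm²/s under the independent-jump approximation). The
tridiagonal covariance is factorized in $O(L)$ per trajectory and grid
point.

Occupations are estimated by expectation-maximization over the 3100-state
mixture: uniform initialization, responsibilities $\propto$ occupation
$\times$ likelihood, M-step weighted by each trajectory's jump count so
long trajectories contribute in proportion to their evidence, convergence
at a $10^{-6}$ maximum occupation change or 1000 iterations. EM with a
flat starting point is our choice where the aggregation scheme is
under-determined; no claim of equivalence to any particular
variational-Bayes implementation is made. Localization error is then
marginalized out, giving the one-dimensional occupation distribution over
$D$ per FOV, from which the endpoints derive: the occupation-weighted
arithmetic mean diffusion coefficient; and bound / slow / fast fractions
with default cutoffs 0.1 and 1.0 µm²/s (the published classification
figure is schematic, so the cutoffs are configurable; these defaults put
chromatin-bound molecules comfortably below and freely diffusing
molecules comfortably above).

Deliberate simplifications, each with a clear upgrade path: no motion-blur
covariance term (the 407 µs pulse at 10 ms spacing makes within-pulse
displacement under 0.07 px even at 5 µm²/s); no defocalization or
out-of-plane-loss correction; no within-trajectory state switching (a
hidden-Markov layer would be the natural extension).

## The synthetic-data generator

Because raw SMT movies are microscope-bound and no public deposit exists
for this assay type, every stage is validated against a simulator whose
ground truth is known exactly. It emulates: elliptical, non-overlapping
nuclei rendered into a Hoechst-like stain image; emitters placed in nuclei
in proportion to area, assigned a diffusive state from configured
occupancies (default: bound 0.05 µm²/s at 30%, free 3.0 µm²/s at 70%),
moving by 2-D Brownian motion with reflection at the nuclear boundary
(the ellipse is mapped to the unit disc, the radial overshoot mirrored,
and mapped back — reflection keeps each emitter assignable to one nucleus);
irreversible photobleaching with per-frame survival 0.9 (mean track length
10 frames) balanced by new appearances so the visible density stays near
`emitter_density` (default 0.05 µm⁻²) throughout the movie; and rendering
as pixel-integrated Gaussian spots (σ 1.5 px) with Poisson shot noise on
signal plus background (default 100 counts) and Gaussian read noise
(default 2 counts). Positions are rendered at the pulse midpoint — at
these pulse/interval ratios motion blur is negligible, so none is
rendered. Optional per-frame state re-sampling (`switching`) exists for
robustness experiments and is off by default, matching the static-state
analysis model.

The default photon budget of 500 photons/spot was set while
characterizing the generator so that the empirical 1-D localization RMSD
(≈ 0.03 µm) falls inside the 0.02–0.08 µm range that the state-array grid
marginalizes over, with detection recall near unity on isolated spots;
the dye-concentration regime of the real assay (10–40 pM, sparse
labeling) is emulated qualitatively by the density default, and both
remain configurable.

What the simulator does not emulate — and therefore what passing tests do
*not* demonstrate about real data: 3-D motion and defocus, sCMOS
pixel-dependent noise, fluorophore blinking, nucleolar substructure and
anisotropic nuclear environments, drift, and non-Brownian motion
(confinement, directed transport). Results on synthetic data bound the
algorithmic error of the pipeline, not the biological error of the assay.

`make_condition_pair()` generates matched control/treated fields differing
only in state occupancies and emitter density, emulating the SMT signature
of a compound that traps its target on chromatin (bound fraction up, spot
density down); both members run from the same seed so every difference is
attributable to the effect.

## Problem sizes and reproducibility

Simulated fields default to 256 × 256 px (a crop of the 1728 × 2304 px
camera field at the same pixel size); test and acceptance runs use 60–100
frame movies, 500-trajectory single-state recoveries, a 1000-trajectory
two-state mixture, and three condition pairs — sizes chosen so the whole
verification cycle completes comfortably on one CPU while keeping the
statistical assertions well-powered. All randomness flows from explicit
seeds; a fixed seed reproduces simulations, intermediate tables, and
pipeline outputs byte for byte.

Two measured caveats are recorded here rather than asserted away. First,
at $D = 0.05$ µm²/s with σ ≈ 0.03 µm localization error and ~8-jump
tracks, the bound state is error-dominated and the fraction of posterior
mass within ±1 grid cell of the true $D$ fluctuates around 0.8 across
seeds (0.64–0.83 measured); within ±2 cells it is stable (≥ 0.89). The
tests therefore assert the marginal *mode* within one grid cell and ≥ 80%
of mass within ±2 cells. Second, for the slowest grid states the mode
itself is only reliably recoverable when localization error is small
relative to per-frame motion: at $D = 0.02$ µm²/s with σ = 0.03 µm the
mode wanders up to several cells along the $(D, \sigma)$ ridge, while at
σ = 0.02 µm with ~11-jump tracks it stays within one cell across every
probe seed. The single-state recovery tests run at the latter conditions
— an identifiability limit of the slow regime, not an implementation
artifact, and worth remembering when interpreting bound-state positions
from noisy data.

## Plate-normalized signals

For screening workflows the package includes the percent-signal
normalization used with plate controls,
$\%S = (T - C_{pos})/(C_{pos} - C_{neg}) \times 100$, exactly as printed
in its source protocol — note it reads 0 at the positive control and
−100 at the negative control, the reverse of the conventional scale. Since
the intended orientation is ambiguous, the conventional form
$(T - C_{neg})/(C_{pos} - C_{neg}) \times 100$ ships behind
`form = "conventional"`; the printed form is the default.
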