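#' Configuration for the synthetic SMT movie generator
#'
#' Bundles the acquisition constants and ground-truth motion model used to
#' generate synthetic single-molecule tracking data: sparse point emitters
#' undergoing multi-state 2-D Brownian motion inside nucleus-shaped masks,
#' imaged stroboscopically as diffraction-limited integrated-Gaussian spots
#' on a noisy camera background, with photobleaching.
#'
#' Acquisition defaults mirror a high-throughput live-cell SMT assay:
#' 150 frames at 100 Hz with a 407-microsecond laser pulse and a pixel size
#' of 0.1083 um/px (the full camera field is 1728 x 2304 px; simulated
#' fields default to a 256 x 256 px crop so test problems stay small).
#' The pulse is so much shorter than the frame interval that within-pulse
#' motion blur is negligible and positions are rendered at the pulse
#' midpoint.
#'
#' @param n_frames Number of movie frames (default 150).
#' @param frame_interval Seconds between frames (default 0.01, i.e. 100 Hz).
#' @param pulse_width Stroboscopic pulse length in seconds (default 407e-6).
#' @param pixel_size Micrometers per pixel (default 0.1083).
#' @param image_shape Integer `c(rows, cols)` of the frame (default 256, 256).
#' @param psf_sigma PSF width in pixels (default 1.5).
#' @param states Two-column matrix or data.frame: diffusion coefficient
#'   (um^2/s) and occupancy fraction per diffusive state. Occupancies must
#'   sum to 1. Default: bound state 0.05 um^2/s at 30%, free state
#'   3.0 um^2/s at 70%.
#' @param switching Per-frame probability that an emitter re-draws its state
#'   from the occupancy distribution (default 0 = static states).
#' @param n_nuclei Number of nuclei to place (default 3).
#' @param nucleus_radius_um Mean nuclear semi-axis in micrometers
#'   (default 4.5).
#' @param emitter_density Emitters per um^2 of nuclear area (default 0.05).
#' @param photons_per_spot Mean photons collected per spot per frame
#'   (default 500, tuned with the default background so the empirical 1-D
#'   localization RMSD falls inside the 0.02-0.08 um range assumed by the
#'   state-array grid).
#' @param background Camera background level in counts (default 100).
#' @param read_noise_sd Gaussian read noise s.d. in counts (default 2).
#' @param bleach_survival Per-frame survival probability of a fluorophore
#'   (default 0.9, i.e. a mean track length of 10 frames). Emitters also
#'   appear at a per-frame rate that balances bleaching, so the expected
#'   number of visible emitters stays near `emitter_density` times the
#'   nuclear area throughout the movie.
#' @param localization_error_target Nominal 1-D localization RMSD in um that
#'   the photon budget is tuned to produce (default 0.04; informational).
#' @param seed Integer RNG seed or `NULL`.
#' @return Validated list of class `smt_sim_config`.
#' @export
sim_config <- function(n_frames = 150L, frame_interval = 0.01,
                       pulse_width = 407e-6, pixel_size = 0.1083,
                       image_shape = c(256L, 256L), psf_sigma = 1.5,
                       states = cbind(D = c(0.05, 3.0), occ = c(0.3, 0.7)),
                       switching = 0, n_nuclei = 3L, nucleus_radius_um = 4.5,
                       emitter_density = 0.05, photons_per_spot = 500,
                       background = 100, read_noise_sd = 2,
                       bleach_survival = 0.9,
                       localization_error_target = 0.04, seed = NULL) {
  states <- as.matrix(as.data.frame(states))
  colnames(states) <- c("D", "occ")
  cfg <- list(n_frames = as.integer(n_frames),
              frame_interval = frame_interval, pulse_width = pulse_width,
              pixel_size = pixel_size, image_shape = as.integer(image_shape),
              psf_sigma = psf_sigma, states = states, switching = switching,
              n_nuclei = as.integer(n_nuclei),
              nucleus_radius_um = nucleus_radius_um,
              emitter_density = emitter_density,
              photons_per_spot = photons_per_spot, background = background,
              read_noise_sd = read_noise_sd,
              bleach_survival = bleach_survival,
              localization_error_target = localization_error_target,
              seed = seed)
  class(cfg) <- "smt_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  s <- cfg$states
  if (abs(sum(s[, "occ"]) - 1) > 1e-9)
    stop("state occupancies must sum to 1")
  if (any(s[, "D"] <= 0)) stop("all diffusion coefficients must be > 0")
  if (any(s[, "occ"] < 0)) stop("occupancies must be non-negative")
  if (!(cfg$frame_interval > cfg$pulse_width && cfg$pulse_width > 0))
    stop("need frame_interval > pulse_width > 0")
  if (cfg$psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape <= 0L))
    stop("image_shape must be two positive integers")
  if (cfg$switching < 0 || cfg$switching > 1)
    stop("switching must be a probability")
  if (cfg$bleach_survival < 0 || cfg$bleach_survival > 1)
    stop("bleach_survival must be a probability")
  invisible(cfg)
}

#' Simulate nuclei and a nuclear-stain image
#'
#' Places `n_nuclei` non-overlapping ellipses in the field, returning a
#' label mask (0 = background, k > 0 = nucleus k) and a synthetic
#' Hoechst-like image: bright inside nuclei, Gaussian-blurred, with Poisson
#' and read noise.
#'
#' @param config `smt_sim_config`.
#' @param n_nuclei Number of nuclei (default `config$n_nuclei`).
#' @return List: `mask` (integer label matrix), `hoechst` (numeric matrix),
#'   `nuclei` data.frame with per-nucleus center (`cx_px`, `cy_px`, 0-based
#'   pixel coordinates), semi-axes (`rx_px`, `ry_px`) and area (`area_um2`).
#' @export
simulate_nuclei <- function(config, n_nuclei = config$n_nuclei) {
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  mask <- matrix(0L, nr, nc)
  nuc <- data.frame(label = integer(), cx_px = numeric(), cy_px = numeric(),
                    rx_px = numeric(), ry_px = numeric(), area_um2 = numeric())
  if (n_nuclei > 0L) {
    r0 <- config$nucleus_radius_um / config$pixel_size
    placed <- 0L
    for (k in seq_len(n_nuclei)) {
      ok <- FALSE
      for (try in 1:200) {
        rx <- r0 * stats::runif(1, 0.75, 1.1)
        ry <- r0 * stats::runif(1, 0.75, 1.1)
        if (rx + 2 >= nc - 1 - rx - 2 || ry + 2 >= nr - 1 - ry - 2) next
        cx <- stats::runif(1, rx + 2, nc - 1 - rx - 2)
        cy <- stats::runif(1, ry + 2, nr - 1 - ry - 2)
        if (placed == 0L ||
            all(sqrt((nuc$cx_px - cx)^2 + (nuc$cy_px - cy)^2) >
                (pmax(nuc$rx_px, nuc$ry_px) + max(rx, ry) + 3))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place ", n_nuclei, " non-overlapping nuclei in a ",
             nr, " x ", nc, " field")
      placed <- placed + 1L
      nuc[placed, ] <- list(placed, cx, cy, rx, ry, NA_real_)
    }
    # rasterize: pixel (i, j) has coordinates x = j - 1, y = i - 1
    xg <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
    yg <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
    for (k in seq_len(nrow(nuc))) {
      inside <- ((xg - nuc$cx_px[k]) / nuc$rx_px[k])^2 +
                ((yg - nuc$cy_px[k]) / nuc$ry_px[k])^2 <= 1
      mask[inside] <- k
      nuc$area_um2[k] <- sum(inside) * config$pixel_size^2
    }
  }
  signal <- matrix(0, nr, nc)
  signal[mask > 0L] <- 1500
  blurred <- as.matrix(EBImage::gblur(signal, sigma = 2))
  hoechst <- stats::rpois(nr * nc, as.vector(blurred) + config$background) +
    stats::rnorm(nr * nc, 0, config$read_noise_sd)
  hoechst <- matrix(pmax(hoechst, 0), nr, nc)
  list(mask = mask, hoechst = hoechst, nuclei = nuc)
}

# reflect a point into the unit disc of normalized ellipse coordinates
reflect_into_ellipse <- function(u, v) {
  for (i in 1:20) {
    r <- sqrt(u^2 + v^2)
    if (r <= 1) return(c(u, v))
    # mirror the radial overshoot across the boundary
    rnew <- 2 - r
    if (rnew < 0) rnew <- abs(rnew)  # pathological huge step
    if (rnew > 1) rnew <- 2 - rnew
    u <- u * rnew / r; v <- v * rnew / r
  }
  c(u / r, v / r)
}

#' Simulate ground-truth emitter trajectories
#'
#' Emitters are distributed over nuclei in proportion to nuclear area, given
#' a diffusive state drawn from the configured occupancies, and propagated by
#' isotropic 2-D Brownian motion: per-axis displacement over one frame is
#' Gaussian with mean 0 and variance `2 * D * frame_interval`. Emitters
#' reflect at the nuclear (ellipse) boundary and bleach irreversibly with
#' per-frame survival probability `bleach_survival`; a bleached emitter
#' emits nothing thereafter and contributes no further ground-truth rows.
#' An initial cohort of `emitter_density * area` emitters is visible at
#' frame 1, and new emitters appear at the per-frame rate that balances
#' bleaching losses, holding the expected visible density steady across the
#' movie.
#'
#' @param config `smt_sim_config`.
#' @param nuclei Output of [simulate_nuclei()].
#' @return `data.frame` ground truth, one row per alive emitter-frame:
#'   `emitter`, `frame`, `x_um`, `y_um`, `state`, `nucleus`.
#' @export
simulate_trajectories <- function(config, nuclei) {
  empty <- data.frame(emitter = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(), state = integer(),
                      nucleus = integer())
  nuc <- nuclei$nuclei
  if (nrow(nuc) == 0L) return(empty)
  total_area <- sum(nuc$area_um2)
  n0 <- stats::rpois(1, config$emitter_density * total_area)
  birth_rate <- config$emitter_density * total_area *
    (1 - config$bleach_survival)
  births <- c(rep(1L, n0),
              rep(2:config$n_frames,
                  stats::rpois(config$n_frames - 1L, birth_rate)))
  if (length(births) == 0L) return(empty)
  occ <- config$states[, "occ"]
  Ds <- config$states[, "D"]
  px <- config$pixel_size
  dt <- config$frame_interval
  out <- vector("list", length(births))
  for (e in seq_along(births)) {
    k <- sample.int(nrow(nuc), 1L, prob = nuc$area_um2)
    state <- sample.int(length(occ), 1L, prob = occ)
    # uniform start inside the ellipse
    repeat {
      u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
      if (u^2 + v^2 <= 1) break
    }
    lifetime <- stats::rgeom(1, prob = 1 - config$bleach_survival) + 1L
    frames <- births[e]:min(config$n_frames, births[e] + lifetime - 1L)
    n_alive <- length(frames)
    xs <- numeric(n_alive); ys <- numeric(n_alive); st <- integer(n_alive)
    for (t in seq_len(n_alive)) {
      if (t > 1L) {
        if (config$switching > 0 && stats::runif(1) < config$switching)
          state <- sample.int(length(occ), 1L, prob = occ)
        sd_um <- sqrt(2 * Ds[state] * dt)
        u <- u + stats::rnorm(1, 0, sd_um) / (nuc$rx_px[k] * px)
        v <- v + stats::rnorm(1, 0, sd_um) / (nuc$ry_px[k] * px)
        uv <- reflect_into_ellipse(u, v)
        u <- uv[1L]; v <- uv[2L]
      }
      xs[t] <- (nuc$cx_px[k] + u * nuc$rx_px[k]) * px
      ys[t] <- (nuc$cy_px[k] + v * nuc$ry_px[k]) * px
      st[t] <- state
    }
    out[[e]] <- data.frame(emitter = e, frame = frames,
                           x_um = xs, y_um = ys, state = st, nucleus = k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a ground truth into a synthetic SMT movie
#'
#' Each alive emitter deposits `photons_per_spot` photons into its frame as
#' a 2-D integrated Gaussian of width `psf_sigma` centered at its true
#' subpixel position; pixel `(i, j)` covers the unit square centered on its
#' integer coordinates. Shot noise is Poisson on signal plus background and
#' read noise is additive Gaussian. Within-pulse motion blur is not rendered
#' (the stroboscopic pulse is ~25x shorter than the frame interval).
#' Emitters outside the image are silently clipped.
#'
#' @param truth Ground-truth `data.frame` from [simulate_trajectories()].
#' @param config `smt_sim_config`.
#' @param noise Add Poisson + read noise (default TRUE). With `noise =
#'   FALSE` the returned frames are exact model intensities
#'   (background + photons * kernel).
#' @return List of numeric matrices, one per frame (counts).
#' @export
render_movie <- function(truth, config, noise = TRUE) {
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  px <- config$pixel_size
  half <- max(5L, ceiling(5 * config$psf_sigma))
  frames <- vector("list", config$n_frames)
  for (t in seq_len(config$n_frames)) {
    signal <- matrix(0, nr, nc)
    rows_t <- truth[truth$frame == t, , drop = FALSE]
    for (e in seq_len(nrow(rows_t))) {
      x <- rows_t$x_um[e] / px   # 0-based pixel coordinates
      y <- rows_t$y_um[e] / px
      j0 <- round(x) + 1L; i0 <- round(y) + 1L
      jj <- max(1L, j0 - half):min(nc, j0 + half)
      ii <- max(1L, i0 - half):min(nr, i0 + half)
      if (length(jj) == 0L || length(ii) == 0L || j0 < 1L - half ||
          j0 > nc + half || i0 < 1L - half || i0 > nr + half) next
      s <- sqrt(2) * config$psf_sigma
      dx <- (erf((jj - 1L - x + 0.5) / s) - erf((jj - 1L - x - 0.5) / s)) / 2
      dy <- (erf((ii - 1L - y + 0.5) / s) - erf((ii - 1L - y - 0.5) / s)) / 2
      signal[ii, jj] <- signal[ii, jj] +
        config$photons_per_spot * outer(dy, dx)
    }
    if (noise) {
      v <- stats::rpois(nr * nc, as.vector(signal) + config$background) +
        stats::rnorm(nr * nc, 0, config$read_noise_sd)
      frames[[t]] <- matrix(pmax(v, 0), nr, nc)
    } else {
      frames[[t]] <- signal + config$background
    }
  }
  frames
}

#' Simulate one complete field of view
#'
#' Runs nucleus placement, trajectory simulation and movie rendering with a
#' reproducible RNG state, and also renders a short nuclear-stain movie for
#' the segmentation stage.
#'
#' @param config `smt_sim_config`.
#' @param n_hoechst_frames Frames in the nuclear-stain movie (default 3).
#' @return List: `movie` (list of matrices), `hoechst_movie`, `mask`,
#'   `nuclei`, `truth`, `config`.
#' @export
simulate_fov <- function(config = sim_config(), n_hoechst_frames = 3L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nucs <- simulate_nuclei(config)
  truth <- simulate_trajectories(config, nucs)
  movie <- render_movie(truth, config)
  hm <- vector("list", n_hoechst_frames)
  nrp <- config$image_shape[1L]; ncp <- config$image_shape[2L]
  signal <- matrix(0, nrp, ncp); signal[nucs$mask > 0L] <- 1500
  blurred <- as.matrix(EBImage::gblur(signal, sigma = 2))
  for (t in seq_len(n_hoechst_frames)) {
    v <- stats::rpois(nrp * ncp, as.vector(blurred) + config$background) +
      stats::rnorm(nrp * ncp, 0, config$read_noise_sd)
    hm[[t]] <- matrix(pmax(v, 0), nrp, ncp)
  }
  list(movie = movie, hoechst_movie = hm, mask = nucs$mask,
       nuclei = nucs$nuclei, truth = truth, config = config)
}

#' Generate a matched control/treated pair of synthetic fields
#'
#' Produces two simulated fields differing only in state occupancies and
#' emitter density, emulating the SMT signature of an inhibitor that traps
#' its target on chromatin: the treated condition has a higher bound-state
#' occupancy and (optionally) a lower emitter density. Both fields are
#' generated from the same seed so differences are attributable to the
#' effect.
#'
#' @param config Control-condition `smt_sim_config` (its first state is
#'   taken as the bound state).
#' @param effect List with `bound_occupancy` (treated occupancy of state 1,
#'   in `[0, 1]`) and `density_multiplier` (treated emitter density as a
#'   fraction of control, default 1).
#' @return List with `control` and `treated`, each as returned by
#'   [simulate_fov()].
#' @export
make_condition_pair <- function(config = sim_config(),
                                effect = list(bound_occupancy = 0.5,
                                              density_multiplier = 0.6)) {
  bo <- effect$bound_occupancy
  dm <- if (is.null(effect$density_multiplier)) 1 else effect$density_multiplier
  if (is.null(bo)) bo <- config$states[1L, "occ"]
  if (bo < 0 || bo > 1) stop("bound_occupancy must be in [0, 1]")
  if (dm < 0) stop("density_multiplier must be >= 0")
  treated_cfg <- config
  occ <- config$states[, "occ"]
  rest <- sum(occ[-1L])
  occ_new <- occ
  occ_new[1L] <- bo
  occ_new[-1L] <- if (rest > 0) occ[-1L] * (1 - bo) / rest else
    rep((1 - bo) / (length(occ) - 1L), length(occ) - 1L)
  treated_cfg$states[, "occ"] <- occ_new
  treated_cfg$emitter_density <- config$emitter_density * dm
  validate_sim_config(treated_cfg)
  list(control = simulate_fov(config), treated = simulate_fov(treated_cfg))
}
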