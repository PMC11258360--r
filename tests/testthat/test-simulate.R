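test_that("simulation config validation enforces its invariants", {
  expect_error(sim_config(states = cbind(D = c(1, 2), occ = c(0.5, 0.6))),
               "sum to 1")
  expect_error(sim_config(states = cbind(D = c(-1, 2), occ = c(0.3, 0.7))))
  expect_error(sim_config(frame_interval = 1e-4, pulse_width = 407e-6))
  expect_error(sim_config(psf_sigma = 0))
  expect_error(sim_config(image_shape = c(0, 128)))
  expect_error(sim_config(bleach_survival = 1.2))
  cfg <- sim_config()
  expect_s3_class(cfg, "smt_sim_config")
  expect_equal(cfg$n_frames, 150L)
  expect_equal(cfg$frame_interval, 0.01)
  expect_equal(cfg$pulse_width, 407e-6)
  expect_equal(cfg$pixel_size, 0.1083)
})

test_that("nucleus placement produces disjoint labeled ellipses", {
  cfg <- sim_config(image_shape = c(200L, 200L), n_nuclei = 2L)
  set.seed(201)
  # zero nuclei: background-only field
  n0 <- simulate_nuclei(cfg, n_nuclei = 0L)
  expect_true(all(n0$mask == 0L))
  # two disjoint nuclei carry exactly labels {1, 2}
  n2 <- simulate_nuclei(cfg)
  expect_setequal(unique(as.vector(n2$mask[n2$mask > 0])), c(1L, 2L))
  # impossible request errors out
  tiny <- sim_config(image_shape = c(64L, 64L), n_nuclei = 20L)
  expect_error(simulate_nuclei(tiny), "non-overlapping")
})

test_that("segmentation recovers simulated nuclei from the stain image", {
  cfg <- sim_config(image_shape = c(360L, 360L), n_nuclei = 5L)
  set.seed(7)
  nucs <- simulate_nuclei(cfg)
  m <- segment_nuclei(nucs$hoechst, pixel_size = cfg$pixel_size)
  expect_equal(nrow(m$table), 5L)
  for (k in 1:5) {
    d <- sqrt((m$table$centroid_x_px - nucs$nuclei$cx_px[k])^2 +
              (m$table$centroid_y_px - nucs$nuclei$cy_px[k])^2)
    expect_lt(min(d), 2)
  }
})

test_that("Brownian ground truth has the prescribed jump statistics", {
  # single state: per-axis squared displacement averages 2 D dt, checked
  # in a nucleus large enough that boundary reflections are negligible
  cfg <- sim_config(image_shape = c(640L, 640L), n_nuclei = 1L,
                    nucleus_radius_um = 30, emitter_density = 0.1,
                    n_frames = 40L, bleach_survival = 0.99,
                    states = cbind(D = 1.0, occ = 1))
  set.seed(202)
  nucs <- simulate_nuclei(cfg)
  tru <- simulate_trajectories(cfg, nucs)
  sp <- split(tru, tru$emitter)
  jumps <- unlist(lapply(sp, function(p) c(diff(p$x_um), diff(p$y_um))))
  expect_gt(length(jumps), 8000)
  se <- sd(jumps^2) / sqrt(length(jumps))
  expect_lt(abs(mean(jumps^2) - 2 * 1.0 * 0.01), 3 * se)

  # occupancies are respected without switching
  cfg2 <- sim_config(image_shape = c(400L, 400L), n_nuclei = 2L,
                     emitter_density = 0.3, n_frames = 20L,
                     states = cbind(D = c(0.05, 5), occ = c(0.3, 0.7)))
  set.seed(203)
  nucs2 <- simulate_nuclei(cfg2)
  tru2 <- simulate_trajectories(cfg2, nucs2)
  first <- tru2[!duplicated(tru2$emitter), ]
  n <- nrow(first)
  phat <- mean(first$state == 1L)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # no emitter switches state
  expect_true(all(tapply(tru2$state, tru2$emitter,
                         function(s) length(unique(s))) == 1L))

  # emitters stay inside their nucleus
  px <- cfg2$pixel_size
  for (k in 1:2) {
    nu <- nucs2$nuclei[k, ]
    sub <- tru2[tru2$nucleus == k, ]
    r2 <- ((sub$x_um / px - nu$cx_px) / nu$rx_px)^2 +
          ((sub$y_um / px - nu$cy_px) / nu$ry_px)^2
    expect_true(all(r2 <= 1 + 1e-9))
  }
})

test_that("near-zero diffusion freezes emitters in place", {
  cfg <- sim_config(image_shape = c(200L, 200L), n_nuclei = 1L,
                    n_frames = 15L,
                    states = cbind(D = 1e-12, occ = 1))
  set.seed(204)
  nucs <- simulate_nuclei(cfg)
  tru <- simulate_trajectories(cfg, nucs)
  drift <- tapply(tru$x_um, tru$emitter, function(x) max(x) - min(x))
  expect_true(all(drift < 1e-4))
})

test_that("rendering deposits integrated-Gaussian photons on background", {
  cfg <- sim_config(image_shape = c(64L, 64L), n_frames = 1L,
                    photons_per_spot = 2000, background = 100)
  px <- cfg$pixel_size
  truth <- data.frame(emitter = 1L, frame = 1L, x_um = 31 * px,
                      y_um = 31 * px, state = 1L, nucleus = 1L)
  # noise-free: background plus the pixel-integrated kernel, symmetric
  fr <- render_movie(truth, cfg, noise = FALSE)[[1]]
  expected <- 100 + 2000 * ig_shape(64, 64, 31, 31, 1.5)
  # the renderer clips the stamp beyond ~6 px where the kernel mass is
  # below 1e-4 counts
  expect_lt(max(abs(fr - expected)), 1e-3)
  expect_equal(fr[30, 30], fr[34, 34], tolerance = 1e-12)
  # photometry: photons recovered within shot noise
  set.seed(205)
  fr <- render_movie(truth, cfg)[[1]]
  tot <- sum(fr[22:42, 22:42] - 100)
  expect_lt(abs(tot - 2000), 4 * sqrt(2000 + 441 * 104))
  # zero-photon movie is background only
  cfg0 <- sim_config(image_shape = c(64L, 64L), n_frames = 1L,
                     photons_per_spot = 0)
  fr0 <- render_movie(truth, cfg0, noise = FALSE)[[1]]
  expect_true(all(fr0 == cfg0$background))
  # subpixel truth recovered by the fitter from a rendered noisy frame
  set.seed(206)
  truth$x_um <- 31.37 * px; truth$y_um <- 30.62 * px
  fr <- render_movie(truth, cfg)[[1]]
  det <- detect_movie(list(fr))
  loc <- localize_spots(list(fr), det, pixel_size = px)
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$x_px - 31.37), 0.05 + 3 * 0.05)
  expect_lt(abs(loc$y_px - 30.62), 0.05 + 3 * 0.05)
})

test_that("fixed seeds reproduce simulations bit for bit", {
  cfg <- sim_config(image_shape = c(96L, 96L), n_frames = 6L, seed = 33L,
                    n_nuclei = 1L)
  a <- simulate_fov(cfg)
  b <- simulate_fov(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$movie, b$movie)
  expect_identical(a$mask, b$mask)
})

test_that("condition pairs differ only through the prescribed effect", {
  cfg <- sim_config(image_shape = c(128L, 128L), n_frames = 10L, seed = 51L,
                    n_nuclei = 1L,
                    states = cbind(D = c(0.05, 3), occ = c(0.2, 0.8)))
  # identity effect: equal occupancies
  pair <- make_condition_pair(cfg, effect = list(bound_occupancy = 0.2,
                                                 density_multiplier = 1))
  expect_equal(pair$control$config$states, pair$treated$config$states)
  # bound-fraction shift is applied exactly, remainder renormalized
  pair <- make_condition_pair(cfg, effect = list(bound_occupancy = 0.5))
  expect_equal(unname(pair$treated$config$states[, "occ"]), c(0.5, 0.5))
  expect_error(make_condition_pair(cfg, effect = list(bound_occupancy = 1.3)),
               "bound_occupancy")
  # density multiplier scales the emitter count (binomial tolerance)
  cfg2 <- sim_config(image_shape = c(320L, 320L), n_frames = 12L, seed = 52L,
                     n_nuclei = 3L, emitter_density = 0.3)
  pair <- make_condition_pair(cfg2, effect = list(bound_occupancy = 0.3,
                                                  density_multiplier = 0.5))
  nc <- length(unique(pair$control$truth$emitter))
  nt <- length(unique(pair$treated$truth$emitter))
  expect_lt(abs(nt / nc - 0.5), 4 * sqrt(1 / nc + 1 / max(nt, 1)))
})
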