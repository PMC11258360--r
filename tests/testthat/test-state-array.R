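test_that("the state grid has the printed axes", {
  g <- state_grid()
  expect_length(g$D, 100L)
  expect_length(g$sigma, 31L)
  expect_equal(g$D[1], 0.01)
  expect_equal(g$D[100], 100.0)
  expect_equal(g$sigma[1], 0.02)
  expect_equal(g$sigma[31], 0.08)
  expect_true(all(diff(g$D) > 0))
  expect_true(all(diff(g$sigma) > 0))
  # log spacing on D, linear on sigma
  expect_equal(sd(diff(log(g$D))), 0, tolerance = 1e-10)
  expect_equal(sd(diff(g$sigma)), 0, tolerance = 1e-10)
})

test_that("RBME likelihood matches closed forms and a dense-covariance
          oracle", {
  # single zero jump: -log(2 pi v)
  j <- data.frame(dx_um = 0, dy_um = 0, delta = 1L, d2_um2 = 0)
  v <- 2 * 1 * 0.01 + 2 * 0.03^2
  expect_equal(rbme_log_likelihood(j, 1, 0.03, 0.01), -log(2 * pi * v),
               tolerance = 1e-12)
  # rotation invariance of the trajectory likelihood
  set.seed(501)
  th <- 0.7
  jumps <- data.frame(dx_um = rnorm(6, 0, 0.1), dy_um = rnorm(6, 0, 0.1),
                      delta = c(1L, 1L, 2L, 1L, 3L, 1L))
  rot <- data.frame(dx_um = cos(th) * jumps$dx_um - sin(th) * jumps$dy_um,
                    dy_um = sin(th) * jumps$dx_um + cos(th) * jumps$dy_um,
                    delta = jumps$delta)
  expect_equal(rbme_log_likelihood(jumps, 0.5, 0.04, 0.01),
               rbme_log_likelihood(rot, 0.5, 0.04, 0.01), tolerance = 1e-9)
  # dense-covariance oracle across grid points and gap structures
  for (r in 1:5) {
    L <- sample(2:7, 1)
    jumps <- data.frame(dx_um = rnorm(L, 0, 0.2), dy_um = rnorm(L, 0, 0.2),
                        delta = sample(1:3, L, replace = TRUE))
    for (D in c(0.02, 1, 30)) for (sig in c(0.02, 0.05, 0.08)) {
      expect_equal(rbme_log_likelihood(jumps, D, sig, 0.01),
                   rbme_dense_oracle(jumps, D, sig, 0.01),
                   tolerance = 1e-8)
    }
  }
  expect_error(rbme_log_likelihood(j, -1, 0.03, 0.01))
})

test_that("the grid likelihood identifies the generating jump variance", {
  # many independent single jumps at D = 1, sigma = 0.03: the maximizing
  # grid point has per-axis variance within one grid cell of 2 D dt + 2 s^2
  set.seed(502)
  dt <- 0.01
  v_true <- 2 * 1 * dt + 2 * 0.03^2
  n <- 10000L
  dx <- rnorm(n, 0, sqrt(v_true)); dy <- rnorm(n, 0, sqrt(v_true))
  jumps <- data.frame(trajectory = seq_len(n), dx_um = dx, dy_um = dy,
                      delta = 1L, dt_s = dt, d2_um2 = dx^2 + dy^2)
  tr <- structure(list(points = NULL, jumps = jumps),
                  class = "smt_trajectories")
  g <- state_grid()
  lm <- likelihood_matrix(tr, g, dt, nuclei_only = FALSE)
  total <- colSums(lm$log_lik)
  kbest <- which.max(total)
  iD <- (kbest - 1L) %/% 31L + 1L
  iS <- (kbest - 1L) %% 31L + 1L
  v_best <- 2 * g$D[iD] * dt + 2 * g$sigma[iS]^2
  v_neighbors <- 2 * g$D[pmax(iD - 1, 1):pmin(iD + 1, 100)] * dt +
    2 * g$sigma[iS]^2
  expect_lt(abs(v_best - v_true), max(abs(diff(v_neighbors))) + 1e-4)
})

test_that("likelihood matrix has grid shape and matches per-cell loops", {
  set.seed(503)
  tr <- make_direct_trajs(3, 0.5, 0.03)
  g <- state_grid()
  lm <- likelihood_matrix(tr, g, 0.01, nuclei_only = FALSE)
  expect_equal(dim(lm$log_lik), c(3L, 100L * 31L))
  expect_true(all(is.finite(lm$log_lik)))
  # duplicated trajectory gives identical rows
  dup <- tr
  dup$points <- rbind(tr$points,
                      transform(tr$points[tr$points$trajectory == 1, ],
                                trajectory = 99L))
  dup$jumps <- smtpipe:::compute_jumps(dup$points, 0.01)
  lmd <- likelihood_matrix(dup, g, 0.01, nuclei_only = FALSE)
  expect_equal(lmd$log_lik[1, ], lmd$log_lik[4, ])
  # spot-check cells against scalar evaluation
  j1 <- tr$jumps[tr$jumps$trajectory == 2, ]
  for (iD in c(1L, 37L, 100L)) for (iS in c(1L, 16L, 31L)) {
    col <- (iD - 1L) * 31L + iS
    expect_equal(unname(lm$log_lik[2, col]),
                 rbme_log_likelihood(j1, g$D[iD], g$sigma[iS], 0.01),
                 tolerance = 1e-10)
  }
  # filtering everything out returns an explicit empty result
  none <- tr
  none$jumps <- none$jumps[0, ]
  lm0 <- likelihood_matrix(none, g, 0.01, nuclei_only = FALSE)
  expect_equal(nrow(lm0$log_lik), 0L)
  post0 <- infer_occupations(lm0)
  expect_equal(post0$n_trajectories, 0L)
  expect_null(post0$mass)
})

test_that("EM occupations conserve mass and recover generating states", {
  g <- state_grid()
  # uniform likelihood is a fixed point
  lm <- structure(list(log_lik = matrix(0, 4, 3100),
                       jump_counts = c(2L, 3L, 4L, 5L),
                       trajectory_ids = 1:4, grid = g, dt = 0.01),
                  class = "smt_likelihood_matrix")
  post <- infer_occupations(lm)
  expect_equal(as.vector(post$mass), rep(1 / 3100, 3100), tolerance = 1e-12)
  expect_equal(sum(post$mass), 1, tolerance = 1e-9)
  # single-state recovery: mode within one grid cell, mass concentrated
  set.seed(504)
  tr <- make_direct_trajs(300, 1.0, 0.03)
  post <- infer_occupations(likelihood_matrix(tr, g, 0.01,
                                              nuclei_only = FALSE))
  expect_equal(sum(post$mass), 1, tolerance = 1e-9)
  marg <- marginalize_error(post)
  expect_equal(sum(marg), 1, tolerance = 1e-9)
  near <- which.min(abs(log(g$D) - log(1.0)))
  expect_lte(abs(which.max(marg) - near), 1L)
  expect_gte(sum(marg[(near - 2):(near + 2)]), 0.8)
})

test_that("error marginalization and derived endpoints are exact sums", {
  g <- state_grid()
  # indicator posterior
  mass <- matrix(0, 100, 31)
  mass[40, 12] <- 1
  post <- structure(list(mass = mass, marginal_D = rowSums(mass), grid = g,
                         n_trajectories = 10L, n_jumps = 50L,
                         n_iterations = 1L), class = "smt_posterior")
  marg <- marginalize_error(post)
  expect_equal(which.max(marg), 40L)
  expect_equal(sum(marg), 1)
  expect_equal(mean_diffusion_coefficient(marg), g$D[40])
  # axis-sum oracle on a random normalized posterior
  set.seed(505)
  mass <- matrix(rexp(3100), 100, 31)
  mass <- mass / sum(mass)
  post$mass <- mass
  marg <- marginalize_error(post)
  direct <- apply(mass, 1L, sum)
  expect_equal(as.vector(marg), direct)
  expect_equal(sum(marg), 1, tolerance = 1e-9)
})

test_that("state classification partitions the marginal by cutoffs", {
  g <- state_grid()
  # all mass at the slowest grid point is bound
  marg <- c(1, rep(0, 99))
  attr(marg, "D") <- g$D
  fr <- classify_fractions(marg)
  expect_equal(unname(fr["bound"]), 1.0)
  # uniform marginal: fractions equal band cell counts / 100
  marg <- rep(1 / 100, 100)
  attr(marg, "D") <- g$D
  fr <- classify_fractions(marg)
  expect_equal(unname(fr["bound"]), sum(g$D <= 0.1) / 100)
  expect_equal(unname(fr["fast"]), sum(g$D >= 1.0) / 100)
  expect_equal(sum(fr), 1)
  expect_error(classify_fractions(marg, t_bound = 2, t_fast = 1), "t_bound")
  # two equal deltas at the extremes average to 50.005
  marg2 <- rep(0, 100)
  marg2[c(1, 100)] <- 0.5
  attr(marg2, "D") <- g$D
  expect_equal(mean_diffusion_coefficient(marg2), 50.005)
})
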