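#' The state-array grid of diffusion coefficients and localization errors
#'
#' Fixed inference grid: 100 diffusion coefficients log-spaced from 0.01 to
#' 100.0 um^2/s and 31 localization-error magnitudes linearly spaced from
#' 0.02 to 0.08 um (1-D RMSD). The four-decade span of the diffusion axis
#' makes log spacing the natural choice; endpoints are exact.
#'
#' @param n_D,D_min,D_max Diffusion axis (defaults 100, 0.01, 100).
#' @param n_sigma,sigma_min,sigma_max Localization-error axis
#'   (defaults 31, 0.02, 0.08).
#' @return List of class `smt_state_grid` with `D` (um^2/s) and `sigma`
#'   (um), both strictly increasing.
#' @export
state_grid <- function(n_D = 100L, D_min = 0.01, D_max = 100.0,
                       n_sigma = 31L, sigma_min = 0.02, sigma_max = 0.08) {
  D <- exp(seq(log(D_min), log(D_max), length.out = n_D))
  D[1L] <- D_min; D[n_D] <- D_max
  sigma <- seq(sigma_min, sigma_max, length.out = n_sigma)
  structure(list(D = D, sigma = sigma), class = "smt_state_grid")
}

#' Log-likelihood of a trajectory under regular Brownian motion with
#' localization error
#'
#' The RBME likelihood: the observed positions are true Brownian positions
#' plus independent localization errors, so the sequence of jumps of one
#' trajectory is, per axis, a zero-mean Gaussian vector with tridiagonal
#' covariance — variance `2 * D * (delta_k * dt) + 2 * sigma_loc^2` for the
#' k-th jump (a gap jump spanning `delta` frames uses `delta * dt`) and
#' covariance `-sigma_loc^2` between consecutive jumps, which share the
#' localization error of their common endpoint. The x and y axes are
#' independent and identically distributed. For a single jump this reduces
#' to the familiar 2-D Gaussian with per-axis variance
#' `2 D dt + 2 sigma_loc^2`; for longer trajectories the anticorrelation is
#' what lets the inference separate slow diffusion from localization error.
#'
#' @param jumps `data.frame` with columns `dx_um`, `dy_um` and `delta`
#'   (frame gap), rows in temporal order — e.g. one trajectory's rows from
#'   `smt_trajectories$jumps`.
#' @param D Diffusion coefficient (um^2/s), scalar or vector.
#' @param sigma_loc Localization error 1-D RMSD (um), same length as `D` or
#'   scalar.
#' @param dt Frame interval (s).
#' @return Log-likelihood, vectorized over `(D, sigma_loc)` pairs.
#' @export
rbme_log_likelihood <- function(jumps, D, sigma_loc, dt) {
  stopifnot(all(D > 0), all(sigma_loc > 0), dt > 0, nrow(jumps) >= 1L)
  L <- nrow(jumps)
  G <- max(length(D), length(sigma_loc))
  D <- rep_len(D, G); sigma_loc <- rep_len(sigma_loc, G)
  a <- outer(2 * jumps$delta * dt, D) +
    matrix(2 * sigma_loc^2, L, G, byrow = TRUE)   # diagonal of Sigma
  b <- -sigma_loc^2                                # off-diagonal (shared endpoint)
  # LDL' factorization of the tridiagonal covariance, vectorized over the
  # grid: d_k = a_k - b^2 / d_{k-1}; z_k = y_k - (b / d_{k-1}) z_{k-1};
  # per-axis loglik = -(L/2) log(2 pi) - 1/2 sum log d_k - 1/2 sum z_k^2/d_k
  ll <- rep(-L * log(2 * pi), G)
  for (axis in c("dx_um", "dy_um")) {
    y <- jumps[[axis]]
    d_prev <- a[1L, ]
    z_prev <- rep(y[1L], G)
    acc <- -0.5 * (log(d_prev) + z_prev^2 / d_prev)
    if (L > 1L) for (k in 2:L) {
      lk <- b / d_prev
      d_k <- a[k, ] - b * lk
      z_k <- y[k] - lk * z_prev
      acc <- acc - 0.5 * (log(d_k) + z_k^2 / d_k)
      d_prev <- d_k; z_prev <- z_k
    }
    ll <- ll + acc
  }
  ll
}

#' Evaluate the RBME log-likelihood of every trajectory on the state grid
#'
#' @param trajectories `smt_trajectories`; only trajectories with at least
#'   one jump (and, if `nuclei_only`, assigned to a nucleus) are used.
#' @param grid `smt_state_grid`.
#' @param dt Frame interval (s).
#' @param nuclei_only Drop trajectories not assigned to a nucleus
#'   (default TRUE when assignments are present).
#' @return List of class `smt_likelihood_matrix`: `log_lik` (matrix
#'   n_traj x (n_D * n_sigma), row-major over the grid with sigma fastest),
#'   `jump_counts`, `trajectory_ids`, `grid`, `dt`. When no trajectory
#'   survives filtering, a zero-row matrix is returned (an explicit
#'   "no data" result).
#' @export
likelihood_matrix <- function(trajectories, grid = state_grid(), dt,
                              nuclei_only = TRUE) {
  stopifnot(inherits(trajectories, "smt_trajectories"))
  jumps <- trajectories$jumps
  keep_ids <- unique(jumps$trajectory)
  if (nuclei_only && !is.null(trajectories$trajectory_nucleus)) {
    nuc <- trajectories$trajectory_nucleus
    in_nuc <- as.integer(names(nuc)[nuc > 0L])
    keep_ids <- intersect(keep_ids, in_nuc)
  }
  nD <- length(grid$D); nS <- length(grid$sigma)
  Dv <- rep(grid$D, each = nS)
  Sv <- rep(grid$sigma, times = nD)
  ll <- matrix(numeric(0), nrow = 0L, ncol = nD * nS)
  counts <- integer(0)
  if (length(keep_ids) > 0L) {
    sp <- split(jumps, jumps$trajectory)
    sp <- sp[as.character(keep_ids)]
    ll <- t(vapply(sp, function(j) rbme_log_likelihood(j, Dv, Sv, dt),
                   numeric(nD * nS)))
    counts <- vapply(sp, nrow, integer(1))
  }
  structure(list(log_lik = ll, jump_counts = as.integer(counts),
                 trajectory_ids = as.integer(keep_ids), grid = grid,
                 dt = dt),
            class = "smt_likelihood_matrix")
}

#' Infer state-array occupations by expectation-maximization
#'
#' Treats the grid of `(D, sigma)` states as mixture components with
#' unknown occupations. The E-step computes per-trajectory responsibilities
#' proportional to `occupation * exp(log_lik)`; the M-step updates the
#' occupations as responsibility sums weighted by each trajectory's jump
#' count, so long trajectories contribute in proportion to their evidence.
#' Initialization is uniform; iteration stops when the largest occupation
#' change drops below `tol` (default 1e-6) or after `max_iter` rounds.
#'
#' @param lmat `smt_likelihood_matrix` from [likelihood_matrix()].
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List of class `smt_posterior`: `mass` (n_D x n_sigma matrix
#'   summing to 1), `marginal_D` (length n_D), `grid`, `n_trajectories`,
#'   `n_jumps`, `n_iterations`. With zero trajectories, `mass` is `NULL`
#'   and `n_trajectories` is 0 (an explicit "no data" posterior).
#' @export
infer_occupations <- function(lmat, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(lmat, "smt_likelihood_matrix"))
  nD <- length(lmat$grid$D); nS <- length(lmat$grid$sigma)
  K <- nD * nS
  n <- nrow(lmat$log_lik)
  if (n == 0L)
    return(structure(list(mass = NULL, marginal_D = NULL, grid = lmat$grid,
                          n_trajectories = 0L, n_jumps = 0L,
                          n_iterations = 0L),
                     class = "smt_posterior"))
  # shift per trajectory for numerical stability, exponentiate once
  shifted <- lmat$log_lik - apply(lmat$log_lik, 1L, max)
  A <- exp(shifted)
  wts <- lmat$jump_counts / sum(lmat$jump_counts)
  occ <- rep(1 / K, K)
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E+M collapsed into two mat-vecs: occ'_k = occ_k * sum_t w_t A_tk / (A occ)_t
    rs <- as.vector(A %*% occ)
    occ_new <- occ * as.vector(crossprod(A, wts / rs))
    occ_new <- occ_new / sum(occ_new)
    delta <- max(abs(occ_new - occ))
    occ <- occ_new
    if (delta < tol) break
  }
  # column index runs sigma-fastest (see likelihood_matrix): reshape
  mass <- matrix(occ, nrow = nS, ncol = nD)  # [sigma, D]
  mass <- t(mass)                            # [D, sigma]
  structure(list(mass = mass, marginal_D = rowSums(mass), grid = lmat$grid,
                 n_trajectories = n, n_jumps = sum(lmat$jump_counts),
                 n_iterations = it),
            class = "smt_posterior")
}

#' Marginalize localization error out of a state-array posterior
#'
#' Sums the posterior mass over the localization-error axis, yielding the
#' one-dimensional occupation distribution over the diffusion coefficient.
#'
#' @param posterior `smt_posterior` from [infer_occupations()].
#' @return Numeric vector of length `n_D` summing to 1, with the grid `D`
#'   values as names attribute `D`.
#' @export
marginalize_error <- function(posterior) {
  stopifnot(inherits(posterior, "smt_posterior"))
  if (is.null(posterior$mass)) return(NULL)
  m <- rowSums(posterior$mass)
  attr(m, "D") <- posterior$grid$D
  m
}

#' Classify the diffusion-coefficient marginal into bound / slow / fast
#' fractions
#'
#' The chromatin-bound fraction is the occupation mass at diffusion
#' coefficients at or below `t_bound`; the fast (freely diffusing) fraction
#' is the mass at or above `t_fast`; the slow fraction is the remainder.
#'
#' @param marginal Normalized marginal over D (from [marginalize_error()]),
#'   with attribute `D`, or a plain vector with `D` supplied.
#' @param t_bound Bound-state threshold in um^2/s (default 0.1).
#' @param t_fast Fast-state threshold in um^2/s (default 1.0).
#' @param D Grid values (defaults to `attr(marginal, "D")`).
#' @return Named numeric `c(bound, slow, fast)` summing to 1.
#' @export
classify_fractions <- function(marginal, t_bound = 0.1, t_fast = 1.0,
                               D = attr(marginal, "D")) {
  if (t_bound >= t_fast) stop("need t_bound < t_fast")
  if (is.null(D)) stop("grid D values required")
  bound <- sum(marginal[D <= t_bound])
  fast <- sum(marginal[D >= t_fast])
  c(bound = bound, slow = max(sum(marginal) - bound - fast, 0), fast = fast)
}

#' Occupation-weighted mean diffusion coefficient
#'
#' Arithmetic mean of the grid diffusion coefficients weighted by the
#' marginal occupations — the per-FOV "mean diffusion coefficient" endpoint.
#'
#' @inheritParams classify_fractions
#' @return Mean diffusion coefficient in um^2/s.
#' @export
mean_diffusion_coefficient <- function(marginal, D = attr(marginal, "D")) {
  if (is.null(D)) stop("grid D values required")
  sum(marginal * D) / sum(marginal)
}

#' Plot a state-array histogram
#'
#' Occupations versus diffusion coefficient on a log axis — the standard
#' state-array readout of diffusive-state structure.
#'
#' @param marginal Marginal over D with attribute `D`, or `smt_posterior`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_state_array <- function(marginal, ...) {
  if (inherits(marginal, "smt_posterior")) marginal <- marginalize_error(marginal)
  D <- attr(marginal, "D")
  graphics::plot(D, marginal, type = "h", log = "x",
                 xlab = expression(paste("Diffusion coefficient (", mu,
                                         m^2, "/s)")),
                 ylab = "Occupation", ...)
  invisible(NULL)
}
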