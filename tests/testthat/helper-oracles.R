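# Independent oracles used across tests. These deliberately use naive,
# direct computations (per-tile sums, exhaustive enumeration, dense grid
# search, full covariance matrices) so they share no code path with the
# package implementations they check.

# direct per-tile evaluation of the GLRT statistic at pixel (i, j)
llr_direct <- function(frame, kern, i, j) {
  w <- kern$w
  half <- (w - 1L) %/% 2L
  X <- frame[(i - half):(i + half), (j - half):(j + half)]
  num <- sum(X * kern$values)^2
  den <- sum(X^2) - sum(X)^2 / w^2
  if (den <= 1e-10) return(0)
  -(w^2 / 2) * log(max(1 - num / den, 1e-12))
}

# all conflict-free link subsets of an edge list
enum_matchings <- function(ne, src, dst) {
  res <- list()
  rec <- function(k, chosen) {
    if (k > ne) {
      res[[length(res) + 1L]] <<- chosen
      return()
    }
    rec(k + 1L, chosen)
    if (!(src[k] %in% src[chosen]) && !(dst[k] %in% dst[chosen]))
      rec(k + 1L, c(chosen, k))
  }
  rec(1L, integer(0))
  res
}

# exact marginal link probabilities by enumeration: every detection with
# outgoing candidates either takes one link (likelihood factor) or dies
# (no-link density factor)
enum_link_marginals <- function(graph) {
  e <- graph$edges
  lik <- exp(e$log_lik)
  cdens <- graph$nolink_density
  has_out <- unique(e$src)
  ms <- enum_matchings(nrow(e), e$src, e$dst)
  W <- vapply(ms, function(m)
    prod(lik[m]) * cdens^length(setdiff(has_out, e$src[m])), numeric(1))
  vapply(seq_len(nrow(e)), function(k)
    sum(W[vapply(ms, function(m) k %in% m, logical(1))]) / sum(W),
    numeric(1))
}

# exhaustive optimum of the matching objective
enum_best_objective <- function(graph) {
  ms <- enum_matchings(nrow(graph$edges), graph$edges$src, graph$edges$dst)
  max(vapply(ms, function(m) smtpipe:::matching_objective(graph, m),
             numeric(1)))
}

# brute-force candidate-pair enumeration (O(n^2))
brute_force_pairs <- function(loc, max_dist = 1.25, max_gap = 3L) {
  n <- nrow(loc)
  out <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    gap <- loc$frame[b] - loc$frame[a]
    if (gap < 1L || gap > max_gap) next
    d <- sqrt((loc$x_um[a] - loc$x_um[b])^2 + (loc$y_um[a] - loc$y_um[b])^2)
    if (d <= max_dist) out[[length(out) + 1L]] <- c(a, b, gap)
  }
  if (length(out) == 0L)
    return(data.frame(src = integer(), dst = integer(), delta = integer()))
  m <- do.call(rbind, out)
  data.frame(src = m[, 1L], dst = m[, 2L], delta = m[, 3L])
}

# dense grid search for the least-squares integrated-Gaussian position: at
# each candidate (x0, y0) the optimal (I, b) follow in closed form from the
# 2x2 normal equations, and the grid is refined coarse-to-fine down to
# `step` (default 1e-3 px)
grid_fit_oracle <- function(tile, sigma_w = 1.5, center, span = 0.6,
                            step = 1e-3) {
  w <- nrow(tile)
  n <- w * w
  tv <- as.vector(tile)
  Tsum <- sum(tv)
  sse_at <- function(x0, y0) {
    shape <- as.vector(ig_shape(w, w, x0, y0, sigma_w))
    S1 <- sum(shape); S2 <- sum(shape^2); Sy <- sum(shape * tv)
    det <- S2 * n - S1^2
    I <- (Sy * n - S1 * Tsum) / det
    b <- (S2 * Tsum - S1 * Sy) / det
    # residual sum of squares at the optimal (I, b)
    sum(tv^2) - I * Sy - b * Tsum
  }
  best <- center
  for (stage in list(c(span, 0.05), c(0.06, 0.005), c(0.006, step))) {
    xs <- seq(best[1] - stage[1], best[1] + stage[1], by = stage[2])
    ys <- seq(best[2] - stage[1], best[2] + stage[1], by = stage[2])
    best_rss <- Inf
    for (x in xs) for (y in ys) {
      r <- sse_at(x, y)
      if (r < best_rss) { best_rss <- r; best <- c(x, y) }
    }
  }
  best
}

# RBME log-likelihood via an explicit dense covariance matrix per axis
rbme_dense_oracle <- function(jumps, D, sigma_loc, dt) {
  L <- nrow(jumps)
  S <- matrix(0, L, L)
  diag(S) <- 2 * D * jumps$delta * dt + 2 * sigma_loc^2
  if (L > 1L) for (k in 1:(L - 1L)) S[k, k + 1L] <- S[k + 1L, k] <- -sigma_loc^2
  ll <- 0
  for (y in list(jumps$dx_um, jumps$dy_um)) {
    ch <- chol(S)
    z <- backsolve(ch, y, transpose = TRUE)
    ll <- ll - (L / 2) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  }
  ll
}

# direct trajectory generator for state-inference tests: Brownian motion
# plus independent per-position localization noise
make_direct_trajs <- function(n, D, sigma, dt = 0.01, mean_len = 8,
                              id0 = 0L) {
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    len <- max(2L, stats::rpois(1, mean_len))
    x <- cumsum(c(0, stats::rnorm(len - 1L, 0, sqrt(2 * D * dt)))) +
      stats::rnorm(len, 0, sigma)
    y <- cumsum(c(0, stats::rnorm(len - 1L, 0, sqrt(2 * D * dt)))) +
      stats::rnorm(len, 0, sigma)
    pts[[i]] <- data.frame(trajectory = id0 + i, frame = seq_len(len),
                           x_um = x, y_um = y)
  }
  pts <- do.call(rbind, pts)
  structure(list(points = pts, jumps = smtpipe:::compute_jumps(pts, dt)),
            class = "smt_trajectories")
}

merge_trajs <- function(a, b) {
  structure(list(points = rbind(a$points, b$points),
                 jumps = rbind(a$jumps, b$jumps)),
            class = "smt_trajectories")
}

# render one noisy frame with isolated integrated-Gaussian spots at given
# 0-based positions
render_test_frame <- function(nr, nc, xs, ys, photons, background = 100,
                              read_sd = 2, sigma_w = 1.5, noise = TRUE) {
  signal <- matrix(0, nr, nc)
  for (k in seq_along(xs)) {
    signal <- signal +
      photons * ig_shape(nr, nc, xs[k], ys[k], sigma_w)
  }
  if (!noise) return(signal + background)
  matrix(pmax(stats::rpois(nr * nc, as.vector(signal) + background) +
                stats::rnorm(nr * nc, 0, read_sd), 0), nr, nc)
}

ig_shape <- function(nr, nc, x, y, sigma_w) {
  s <- sqrt(2) * sigma_w
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  dx <- (erf((0:(nc - 1L) - x + 0.5) / s) - erf((0:(nc - 1L) - x - 0.5) / s)) / 2
  dy <- (erf((0:(nr - 1L) - y + 0.5) / s) - erf((0:(nr - 1L) - y - 0.5) / s)) / 2
  outer(dy, dx)
}
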