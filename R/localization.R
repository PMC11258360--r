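erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Evaluate the 2-D integrated Gaussian spot model on a tile
#'
#' The point-spread function is modeled as a symmetric 2-D Gaussian of width
#' `sigma_w` integrated over the unit area of each pixel, so the model value
#' at pixel `(x_i, y_j)` is `f_ij = I * dx_i * dy_j + b` with
#' `dx_i = (erf((x_i - x0 + 1/2) / sqrt(2) sigma_w) -
#'          erf((x_i - x0 - 1/2) / sqrt(2) sigma_w)) / 2`
#' and `dy_j` defined analogously. Pixel `(i, j)` covers the unit square
#' centered on its integer coordinates.
#'
#' @param theta Numeric vector `c(x0, y0, I, b)`: subpixel center
#'   (column = x, row = y, in tile pixel coordinates, 0-based at the first
#'   pixel's center), integrated intensity, and constant offset.
#' @param w Tile width in pixels.
#' @param sigma_w PSF width in pixels (default 1.5).
#' @return `w` x `w` matrix of model values (rows = y, columns = x).
#' @export
integrated_gaussian <- function(theta, w = 11L, sigma_w = 1.5) {
  stopifnot(sigma_w > 0, length(theta) == 4L)
  x0 <- theta[1L]; y0 <- theta[2L]; I <- theta[3L]; b <- theta[4L]
  coords <- seq_len(w) - 1
  s <- sqrt(2) * sigma_w
  dx <- (erf((coords - x0 + 0.5) / s) - erf((coords - x0 - 0.5) / s)) / 2
  dy <- (erf((coords - y0 + 0.5) / s) - erf((coords - y0 - 0.5) / s)) / 2
  I * outer(dy, dx) + b
}

# d(dx_i)/d(x0): derivative of the pixel-integrated Gaussian w.r.t. center
ig_marginal_deriv <- function(coords, c0, sigma_w) {
  s2 <- 2 * sigma_w^2
  (exp(-(coords - c0 - 0.5)^2 / s2) - exp(-(coords - c0 + 0.5)^2 / s2)) /
    sqrt(2 * pi * sigma_w^2)
}

#' Radial-symmetry estimate of a spot center
#'
#' Non-iterative initializer for the spot fit: intensity gradients of a
#' radially symmetric spot all point at (or away from) its center, so the
#' center is estimated as the point minimizing the weighted sum of squared
#' perpendicular distances to the gradient lines. Gradients are taken on the
#' half-pixel dual lattice from diagonal differences, lightly smoothed, and
#' weighted by squared magnitude over distance to the gradient-weighted
#' centroid. Falls back to the tile center when all gradients vanish.
#'
#' @param tile Numeric matrix (rows = y, columns = x).
#' @return Numeric `c(x0, y0)` in tile pixel coordinates (0-based at the
#'   center of the first pixel).
#' @export
radial_symmetry_init <- function(tile) {
  tile <- as.matrix(tile)
  nr <- nrow(tile); nc <- ncol(tile)
  ctr <- c((nc - 1) / 2, (nr - 1) / 2)
  if (nr < 2L || nc < 2L) return(ctr)
  # diagonal differences on the (nr-1) x (nc-1) midpoint lattice
  du <- tile[-nr, -1L] - tile[-1L, -nc]   # along (+x, -y) diagonal
  dv <- tile[-nr, -nc] - tile[-1L, -1L]   # along (-x, -y) diagonal
  smooth3 <- function(m) {
    if (nrow(m) < 3L || ncol(m) < 3L) return(m)
    p <- rbind(m[1L, ], m, m[nrow(m), ])
    p <- cbind(p[, 1L], p, p[, ncol(p)])
    (p[1:nrow(m), 1:ncol(m)] + p[1:nrow(m), 2:(ncol(m) + 1L)] +
     p[1:nrow(m), 3:(ncol(m) + 2L)] +
     p[2:(nrow(m) + 1L), 1:ncol(m)] + p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] +
     p[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)] +
     p[3:(nrow(m) + 2L), 1:ncol(m)] + p[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] +
     p[3:(nrow(m) + 2L), 3:(ncol(m) + 2L)]) / 9
  }
  du <- smooth3(du); dv <- smooth3(dv)
  gx <- (du - dv) / sqrt(2)
  gy <- (-du - dv) / sqrt(2)
  g2 <- gx^2 + gy^2
  if (sum(g2) <= 0) return(ctr)
  # midpoint coordinates (0-based pixel frame), column-major like as.vector
  xk <- rep(seq_len(nc - 1L) - 0.5, each = nr - 1L)
  yk <- rep(seq_len(nr - 1L) - 0.5, times = nc - 1L)
  gxv <- as.vector(gx); gyv <- as.vector(gy); g2v <- as.vector(g2)
  gm <- sqrt(g2v)
  ok <- gm > 0
  ux <- ifelse(ok, gxv / pmax(gm, .Machine$double.eps), 0)
  uy <- ifelse(ok, gyv / pmax(gm, .Machine$double.eps), 0)
  # weight: |g|^2 / distance to the magnitude-weighted centroid
  xc <- sum(xk * g2v) / sum(g2v); yc <- sum(yk * g2v) / sum(g2v)
  dc <- sqrt((xk - xc)^2 + (yk - yc)^2)
  wgt <- g2v / pmax(dc, 0.1)
  # minimize sum w ((x - xk) uy - (y - yk) ux)^2
  A <- sum(wgt * uy^2); B <- -sum(wgt * ux * uy); C <- sum(wgt * ux^2)
  rhs1 <- sum(wgt * uy * (xk * uy - yk * ux))
  rhs2 <- sum(wgt * ux * (xk * uy - yk * ux))
  # system: A x + B y = rhs1 ; B x + C y = -rhs2
  det <- A * C - B * B
  if (!is.finite(det) || abs(det) < 1e-12 * max(A * C, 1e-300)) return(ctr)
  x0 <- (C * rhs1 + B * rhs2) / det
  y0 <- (-A * rhs2 - B * rhs1) / det
  if (!is.finite(x0) || !is.finite(y0)) return(ctr)
  c(x0, y0)
}

#' Fit the integrated Gaussian spot model to a tile
#'
#' Refines a detection to subpixel precision with a damped Levenberg-
#' Marquardt scheme over `theta = (x0, y0, I, b)`:
#' `theta <- theta + gamma * solve(J'J + alpha*diag(4), J' r)` where `J` is
#' the model Jacobian and `r = X - f(theta)` the residual, with fixed
#' `gamma = 0.3`, `alpha = 1e-4`, and the PSF width constrained to
#' `sigma_w = 1.5` px. At most `max_iter = 8` iterations are run; convergence
#' is called when both `x0` and `y0` move by less than `1e-4` px in an
#' iteration. Intensity and offset start at `sum(tile - min(tile))` and the
#' median of the tile border; the position starts from `init` (typically the
#' radial-symmetry estimate). If the normal matrix is singular or the fitted
#' position leaves the tile, the initialization is returned flagged
#' unconverged.
#'
#' @param tile Numeric `w` x `w` matrix.
#' @param init Optional numeric `c(x0, y0)` starting position (tile
#'   coordinates). Defaults to [radial_symmetry_init()].
#' @param sigma_w PSF width in px (default 1.5).
#' @param gamma Step damping factor (default 0.3).
#' @param alpha Levenberg-Marquardt regularization (default 1e-4).
#' @param max_iter Maximum iterations (default 8).
#' @param tol Convergence tolerance on the position change in px
#'   (default 1e-4).
#' @return List of class `smt_spotfit`: `x0`, `y0` (tile px), `I`, `b`,
#'   `n_iterations`, `converged`, `init_x0`, `init_y0`.
#' @export
fit_spot <- function(tile, init = NULL, sigma_w = 1.5, gamma = 0.3,
                     alpha = 1e-4, max_iter = 8L, tol = 1e-4) {
  tile <- as.matrix(tile)
  w <- nrow(tile)
  stopifnot(ncol(tile) == w)
  if (is.null(init)) init <- radial_symmetry_init(tile)
  border <- c(tile[1L, ], tile[w, ], tile[-c(1L, w), 1L], tile[-c(1L, w), w])
  theta <- c(init[1L], init[2L], sum(tile - min(tile)), stats::median(border))
  fallback <- structure(list(x0 = init[1L], y0 = init[2L], I = theta[3L],
                             b = theta[4L], n_iterations = 0L,
                             converged = FALSE, init_x0 = init[1L],
                             init_y0 = init[2L]), class = "smt_spotfit")
  coords <- seq_len(w) - 1
  s <- sqrt(2) * sigma_w
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(max_iter)) {
    iter <- t
    x0 <- theta[1L]; y0 <- theta[2L]; I <- theta[3L]
    dx <- (erf((coords - x0 + 0.5) / s) - erf((coords - x0 - 0.5) / s)) / 2
    dy <- (erf((coords - y0 + 0.5) / s) - erf((coords - y0 - 0.5) / s)) / 2
    ddx <- ig_marginal_deriv(coords, x0, sigma_w)
    ddy <- ig_marginal_deriv(coords, y0, sigma_w)
    f <- I * outer(dy, dx) + theta[4L]
    r <- as.vector(tile - f)
    J <- cbind(as.vector(I * outer(dy, ddx)),    # d f / d x0
               as.vector(I * outer(ddy, dx)),    # d f / d y0
               as.vector(outer(dy, dx)),         # d f / d I
               1)                                # d f / d b
    H <- crossprod(J) + alpha * diag(4)
    step <- tryCatch(solve(H, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(fallback)
    theta <- theta + gamma * as.vector(step)
    if (theta[1L] < -0.5 || theta[1L] > w - 0.5 ||
        theta[2L] < -0.5 || theta[2L] > w - 0.5) return(fallback)
    if (abs(gamma * step[1L]) < tol && abs(gamma * step[2L]) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(x0 = theta[1L], y0 = theta[2L], I = theta[3L], b = theta[4L],
                 n_iterations = iter, converged = converged,
                 init_x0 = init[1L], init_y0 = init[2L]),
            class = "smt_spotfit")
}

#' Localize detected spots in a movie to subpixel precision
#'
#' Extracts the `w` x `w` tile around every detection, runs
#' [radial_symmetry_init()] then [fit_spot()], and reports positions in image
#' coordinates. The coordinate convention is: positions are continuous, in
#' pixel units, with the origin at the center of pixel `(row = 1, col = 1)`;
#' `y = row - 1`, `x = col - 1` for integer pixels. Micron coordinates
#' multiply by `pixel_size`.
#'
#' @param movie Matrix, list of matrices or 3-D array.
#' @param detections `data.frame` from [detect_movie()] /
#'   [detect_spots()].
#' @param w Tile width (default 11; must match the detection kernel).
#' @param sigma_w PSF width in px (default 1.5).
#' @param pixel_size Pixel size in micrometers (default 0.1083).
#' @param ... Passed to [fit_spot()].
#' @return `data.frame` with columns `frame`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `intensity`, `offset`, `llr`, `converged`.
#' @export
localize_spots <- function(movie, detections, w = 11L, sigma_w = 1.5,
                           pixel_size = 0.1083, ...) {
  frames <- movie_frames(movie)
  half <- (w - 1L) %/% 2L
  n <- nrow(detections)
  out <- data.frame(frame = integer(n), x_px = numeric(n), y_px = numeric(n),
                    x_um = numeric(n), y_um = numeric(n),
                    intensity = numeric(n), offset = numeric(n),
                    llr = numeric(n), converged = logical(n))
  keep <- logical(n)
  for (k in seq_len(n)) {
    fr <- detections$frame[k]; i <- detections$row[k]; j <- detections$col[k]
    f <- frames[[fr]]
    if (i - half < 1L || i + half > nrow(f) || j - half < 1L || j + half > ncol(f))
      next
    tile <- f[(i - half):(i + half), (j - half):(j + half)]
    fit <- fit_spot(tile, sigma_w = sigma_w, ...)
    x_px <- fit$x0 + (j - half - 1L)   # tile -> image frame, 0-based px
    y_px <- fit$y0 + (i - half - 1L)
    out[k, ] <- list(fr, x_px, y_px, x_px * pixel_size, y_px * pixel_size,
                     fit$I, fit$b, detections$llr[k], fit$converged)
    keep[k] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
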