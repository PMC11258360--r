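#' Build the Gaussian detection kernel
#'
#' Constructs the `w` x `w` template used by the generalized
#' log-likelihood-ratio (GLRT) spot detector: a 2-D Gaussian of width
#' `sigma_w` sampled at pixel centers, then mean-subtracted ("mean 0") and
#' scaled to unit energy (sum of squares 1). The zero-mean/unit-energy
#' normalization is what makes the LLR statistic below independent of the
#' local background level and noise scale.
#'
#' @param w Odd integer tile width in pixels (default 11).
#' @param sigma_w Gaussian width in pixels (default 1.5).
#' @return An object of class `smt_kernel`: list with `w`, `sigma_w`, and the
#'   `w` x `w` matrix `values` satisfying `sum(values) == 0` and
#'   `sum(values^2) == 1` to machine precision.
#' @examples
#' k <- make_kernel()
#' sum(k$values)    # ~0
#' sum(k$values^2)  # 1
#' @export
make_kernel <- function(w = 11L, sigma_w = 1.5) {
  w <- as.integer(w)
  if (length(w) != 1L || is.na(w) || w <= 0L || w %% 2L == 0L)
    stop("'w' must be a positive odd integer (a tile needs a unique center pixel)")
  if (!is.numeric(sigma_w) || length(sigma_w) != 1L || sigma_w <= 0)
    stop("'sigma_w' must be a positive number")
  half <- (w - 1L) / 2L
  r <- seq(-half, half)
  g1 <- exp(-r^2 / (2 * sigma_w^2))
  g <- outer(g1, g1)
  g <- g - mean(g)
  g <- g / sqrt(sum(g^2))
  structure(list(w = w, sigma_w = sigma_w, values = g), class = "smt_kernel")
}

# Same-size 2-D correlation via FFT. The kernel is symmetric under 180-degree
# rotation for every kernel used here (Gaussian template, box), so correlation
# and convolution coincide. Circular wrap-around only contaminates a border of
# width w%/%2, which the LLR map leaves undefined anyway.
fft_filter <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  w <- nrow(kern)
  half <- (w - 1L) %/% 2L
  kp <- matrix(0, nr, nc)
  kp[1:w, 1:w] <- kern
  # center the kernel at (1,1) so the output is aligned with the input
  kp <- kp[c((half + 1L):nr, seq_len(half)), c((half + 1L):nc, seq_len(half))]
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(kp)), inverse = TRUE)) / (nr * nc)
}

#' Compute the per-pixel log-likelihood-ratio map of a frame
#'
#' For every pixel whose `w` x `w` tile lies entirely inside the frame,
#' evaluates the GLRT statistic comparing a Gaussian-spot-plus-white-noise
#' hypothesis against white noise alone:
#' \deqn{LLR = -\frac{w^2}{2}\log\left[1 -
#'   \frac{(\sum X G)^2}{\sum X^2 - (\sum X)^2/w^2}\right]}
#' where the sums run over the tile `X` and `G` is the zero-mean, unit-energy
#' kernel. The three tile sums are computed for all tiles at once by
#' frequency-domain convolution.
#'
#' Numerical conventions: a constant tile (zero-variance denominator) carries
#' no evidence of a spot and gets `LLR = 0`; when rounding pushes the log
#' argument to or below zero, it is clamped at `1e-12`, capping the LLR at
#' `-(w^2/2) * log(1e-12)` while preserving ordering. Pixels within
#' `w %/% 2` of the border are `NA` (the tile does not fit).
#'
#' @param frame Numeric matrix (single movie frame, rows x cols).
#' @param kernel A `smt_kernel` from [make_kernel()].
#' @return Numeric matrix of the same size as `frame` with the LLR per pixel
#'   (`NA` in the border band), with attribute `llr_cap`.
#' @export
llr_map <- function(frame, kernel = make_kernel()) {
  stopifnot(inherits(kernel, "smt_kernel"))
  frame <- as.matrix(frame)
  w <- kernel$w
  if (nrow(frame) < w || ncol(frame) < w)
    stop("frame must be at least ", w, " x ", w)
  half <- (w - 1L) %/% 2L
  box <- matrix(1, w, w)
  sxg <- fft_filter(frame, kernel$values)
  sx  <- fft_filter(frame, box)
  sx2 <- fft_filter(frame^2, box)
  den <- sx2 - sx^2 / w^2
  ratio <- ifelse(den > 1e-10, sxg^2 / pmax(den, 1e-10), 0)
  arg <- pmax(1 - ratio, 1e-12)
  llr <- -(w^2 / 2) * log(arg)
  llr[den <= 1e-10] <- 0
  llr <- pmax(llr, 0)
  # border band: tile does not fit
  nr <- nrow(frame); nc <- ncol(frame)
  border <- c(seq_len(half), (nr - half + 1L):nr)
  llr[border, ] <- NA_real_
  llr[, c(seq_len(half), (nc - half + 1L):nc)] <- NA_real_
  attr(llr, "llr_cap") <- -(w^2 / 2) * log(1e-12)
  llr
}

#' Detect spots as thresholded local maxima of an LLR map
#'
#' Returns the pixels that are (i) local maxima of the LLR map within a 3x3
#' neighborhood, (ii) at or above `threshold`, and (iii) at least `min_sep`
#' pixels from any stronger accepted detection (non-maximum suppression, so
#' one emitter straddling several supra-threshold tiles is counted once).
#'
#' @param llr Matrix from [llr_map()].
#' @param threshold Minimum LLR to call a spot (default 14).
#' @param min_sep Minimum separation between detections in pixels (default 3).
#' @param frame_index Frame number recorded in the output (default 1).
#' @return `data.frame` with columns `frame`, `row`, `col`, `llr`, sorted by
#'   `(frame, row, col)`. Rows/cols are 1-based integer pixel indices.
#' @export
detect_spots <- function(llr, threshold = 14, min_sep = 3, frame_index = 1L) {
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  nr <- nrow(llr); nc <- ncol(llr)
  v <- llr
  v[is.na(v)] <- -Inf
  cand <- which(v >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(frame = integer(), row = integer(), col = integer(),
                      llr = numeric()))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    nb <- v[max(1L, i - 1L):min(nr, i + 1L), max(1L, j - 1L):min(nc, j + 1L)]
    keep[k] <- v[i, j] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(frame = integer(), row = integer(), col = integer(),
                      llr = numeric()))
  sc <- v[cand]
  # greedy NMS, strongest first; deterministic tie-break by (row, col)
  ord <- order(-sc, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  taken_r <- numeric(0); taken_c <- numeric(0)
  sel <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (length(taken_r) == 0L ||
        all(pmax(abs(taken_r - cand[k, 1L]), abs(taken_c - cand[k, 2L])) >= min_sep)) {
      sel[k] <- TRUE
      taken_r <- c(taken_r, cand[k, 1L]); taken_c <- c(taken_c, cand[k, 2L])
    }
  }
  out <- data.frame(frame = as.integer(frame_index),
                    row = as.integer(cand[sel, 1L]),
                    col = as.integer(cand[sel, 2L]),
                    llr = sc[sel])
  out[order(out$frame, out$row, out$col), , drop = FALSE]
}

#' Detect spots in every frame of a movie
#'
#' @param movie 3-D array (rows x cols x frames) or list of matrices.
#' @inheritParams detect_spots
#' @param kernel Detection kernel (default [make_kernel()]).
#' @return Combined `data.frame` of detections across frames.
#' @export
detect_movie <- function(movie, kernel = make_kernel(), threshold = 14,
                         min_sep = 3) {
  frames <- movie_frames(movie)
  res <- lapply(seq_along(frames), function(t) {
    detect_spots(llr_map(frames[[t]], kernel), threshold = threshold,
                 min_sep = min_sep, frame_index = t)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Accept either a list of matrices or a rows x cols x frames array.
movie_frames <- function(movie) {
  if (is.list(movie)) return(movie)
  if (is.array(movie) && length(dim(movie)) == 3L)
    return(lapply(seq_len(dim(movie)[3]), function(t) movie[, , t]))
  if (is.matrix(movie)) return(list(movie))
  stop("movie must be a matrix, a list of matrices, or a 3-D array")
}
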