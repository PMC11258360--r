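#' Mean projection of a movie
#'
#' Per-pixel arithmetic mean across all frames of the nuclear-stain movie,
#' used as the input to nuclear segmentation.
#'
#' @param movie Matrix, list of matrices, or rows x cols x frames array.
#' @return Numeric matrix.
#' @export
mean_projection <- function(movie) {
  frames <- movie_frames(movie)
  if (length(frames) == 0L) stop("movie has no frames")
  Reduce(`+`, frames) / length(frames)
}

#' Segment nuclei in a nuclear-stain image
#'
#' Classical segmentation pipeline with the same image -> label-mask
#' contract as a learned segmenter: Gaussian smoothing, global Otsu
#' threshold, hole filling, distance-transform watershed to split touching
#' nuclei, and removal of components smaller than `min_area_um2`. Labels
#' are relabeled to consecutive integers `1..K`.
#'
#' @param image 2-D numeric matrix (e.g. from [mean_projection()]).
#' @param pixel_size Micrometers per pixel (default 0.1083).
#' @param smooth_sigma Smoothing width in px (default 2).
#' @param min_area_um2 Minimum nucleus area in um^2 (default 20).
#' @return List of class `smt_nucleus_mask`: `labels` (integer matrix,
#'   0 = background), `table` (`data.frame`: `label`, `area_um2`,
#'   `centroid_x_px`, `centroid_y_px`, 0-based pixel coordinates),
#'   `pixel_size`.
#' @export
segment_nuclei <- function(image, pixel_size = 0.1083, smooth_sigma = 2,
                           min_area_um2 = 20) {
  img <- as.matrix(image)
  rng <- range(img)
  if (diff(rng) <= 0) {
    labels <- matrix(0L, nrow(img), ncol(img))
    return(new_nucleus_mask(labels, pixel_size))
  }
  norm <- (img - rng[1L]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(norm, sigma = smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- EBImage::fillHull(sm > thr)
  dm <- EBImage::distmap(bin)
  labels <- as.matrix(EBImage::imageData(EBImage::watershed(dm, tolerance = 2)))
  # drop small components, relabel consecutively
  px_area <- pixel_size^2
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[as.numeric(tab) * px_area >= min_area_um2])
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  pos <- labels > 0
  out[pos] <- relab[labels[pos]]
  new_nucleus_mask(out, pixel_size)
}

new_nucleus_mask <- function(labels, pixel_size) {
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) > 0L) {
    nr <- nrow(labels)
    idx <- which(labels > 0)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    tab <- data.frame(
      label = ks,
      area_um2 = as.numeric(table(factor(lab, levels = ks))) * pixel_size^2,
      centroid_x_px = as.numeric(tapply(cols - 1L, factor(lab, levels = ks), mean)),
      centroid_y_px = as.numeric(tapply(rows - 1L, factor(lab, levels = ks), mean)))
  } else {
    tab <- data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x_px = numeric(), centroid_y_px = numeric())
  }
  structure(list(labels = labels, table = tab, pixel_size = pixel_size),
            class = "smt_nucleus_mask")
}

#' Assign localizations and trajectories to nuclei
#'
#' Each localization takes the label of the mask pixel containing its
#' subpixel position (rounded to the nearest pixel center); positions
#' outside the image are unassigned (label 0). A trajectory's label is the
#' majority label over its localizations, set to unassigned when the
#' majority is background. Trajectories outside all nuclei are excluded
#' from downstream state inference when `drop_unassigned` trajectories are
#' requested there.
#'
#' @param trajectories `smt_trajectories` from [assemble_trajectories()],
#'   or a localization `data.frame` with `x_um`, `y_um`.
#' @param mask `smt_nucleus_mask` from [segment_nuclei()].
#' @return Input with `nucleus` columns added (per point, and per
#'   trajectory via majority vote when applicable).
#' @export
assign_to_nuclei <- function(trajectories, mask) {
  stopifnot(inherits(mask, "smt_nucleus_mask"))
  lab_of <- function(pts) {
    i <- round(pts$y_um / mask$pixel_size) + 1L  # row
    j <- round(pts$x_um / mask$pixel_size) + 1L  # col
    ok <- i >= 1L & i <= nrow(mask$labels) & j >= 1L & j <= ncol(mask$labels)
    lab <- integer(nrow(pts))
    lab[ok] <- mask$labels[cbind(i[ok], j[ok])]
    lab
  }
  if (inherits(trajectories, "smt_trajectories")) {
    pts <- trajectories$points
    pts$nucleus_point <- lab_of(pts)
    maj <- vapply(split(pts$nucleus_point, pts$trajectory), function(v) {
      tb <- sort(table(v), decreasing = TRUE)
      as.integer(names(tb)[1L])
    }, integer(1))
    pts$nucleus <- maj[as.character(pts$trajectory)]
    trajectories$points <- pts
    trajectories$trajectory_nucleus <- maj
    trajectories
  } else {
    pts <- as.data.frame(trajectories)
    pts$nucleus <- lab_of(pts)
    pts
  }
}
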