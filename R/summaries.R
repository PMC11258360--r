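#' Nuclear spot density
#'
#' Detections falling inside any nucleus per square micrometer of nuclear
#' area per frame. Counts detections (not trajectories): the most direct
#' reading of a per-frame "molecule spot density"; set
#' `unit = "trajectories"` to count trajectories instead.
#'
#' @param localizations Localization `data.frame` with `x_um`, `y_um` (and
#'   `trajectory` if `unit = "trajectories"`).
#' @param mask `smt_nucleus_mask`.
#' @param n_frames Number of movie frames.
#' @param unit `"detections"` (default) or `"trajectories"`.
#' @return Density in um^-2 frame^-1 (`NA` with a warning when the mask is
#'   empty).
#' @export
spot_density <- function(localizations, mask, n_frames,
                         unit = c("detections", "trajectories")) {
  unit <- match.arg(unit)
  stopifnot(inherits(mask, "smt_nucleus_mask"), n_frames >= 1L)
  area <- sum(mask$table$area_um2)
  if (area <= 0) {
    warning("empty nucleus mask: spot density undefined")
    return(NA_real_)
  }
  pts <- assign_to_nuclei(as.data.frame(localizations), mask)
  inside <- pts$nucleus > 0L
  n <- if (unit == "detections") sum(inside) else
    length(unique(pts$trajectory[inside]))
  n / (area * n_frames)
}

#' Plate-normalized percent signal
#'
#' Normalizes a measured signal `T` against positive and negative plate
#' controls. The default form is
#' `%S = (T - C_pos) / (C_pos - C_neg) * 100`, which reads 0 at the
#' positive control and -100 at the negative control; `form =
#' "conventional"` switches to `(T - C_neg) / (C_pos - C_neg) * 100`
#' (0 at the negative control, 100 at the positive control).
#'
#' @param T Measured signal (vectorized).
#' @param C_pos Positive-control signal.
#' @param C_neg Negative-control signal.
#' @param form `"printed"` (default) or `"conventional"`.
#' @return Percent signal.
#' @export
normalize_percent_signal <- function(T, C_pos, C_neg,
                                     form = c("printed", "conventional")) {
  form <- match.arg(form)
  if (C_pos == C_neg) stop("C_pos and C_neg must differ")
  if (form == "printed") (T - C_pos) / (C_pos - C_neg) * 100
  else (T - C_neg) / (C_pos - C_neg) * 100
}

#' Summarize one field of view
#'
#' Computes the per-FOV endpoints from a processed field: number of nuclei
#' and trajectories used, occupation-weighted mean diffusion coefficient,
#' bound/slow/fast fractions, and nuclear spot density.
#'
#' @param posterior `smt_posterior` for the FOV.
#' @param localizations Localization table for the FOV.
#' @param mask `smt_nucleus_mask`.
#' @param n_frames Number of movie frames.
#' @param t_bound,t_fast State-classification thresholds (um^2/s).
#' @param plate,well,fov Optional identifiers.
#' @return One-row `data.frame` (class `smt_fov_summary` rows): ids,
#'   `n_nuclei`, `n_trajectories`, `mean_D`, `bound_fraction`,
#'   `slow_fraction`, `fast_fraction`, `spot_density`.
#' @export
summarize_fov <- function(posterior, localizations, mask, n_frames,
                          t_bound = 0.1, t_fast = 1.0, plate = "plate1",
                          well = "A1", fov = 1L) {
  marg <- marginalize_error(posterior)
  if (is.null(marg)) {
    fr <- c(bound = NA_real_, slow = NA_real_, fast = NA_real_)
    mD <- NA_real_
  } else {
    fr <- classify_fractions(marg, t_bound = t_bound, t_fast = t_fast)
    mD <- mean_diffusion_coefficient(marg)
  }
  data.frame(plate = plate, well = well, fov = fov,
             n_nuclei = nrow(mask$table),
             n_trajectories = posterior$n_trajectories,
             mean_D = mD,
             bound_fraction = unname(fr["bound"]),
             slow_fraction = unname(fr["slow"]),
             fast_fraction = unname(fr["fast"]),
             spot_density = spot_density(localizations, mask, n_frames))
}

#' Aggregate FOV summaries into condition-level endpoints
#'
#' Reported condition averages are the mean over all FOVs collected, with
#' s.d. and s.e.m.; optionally each metric is normalized to the control
#' condition's mean.
#'
#' @param fov_summaries `data.frame` of per-FOV rows (from
#'   [summarize_fov()]) with a `condition` column.
#' @param normalize_to Optional control condition label; when given, each
#'   metric mean is divided by the control mean (the control itself reads
#'   1).
#' @return `data.frame` with one row per condition and metric: `condition`,
#'   `metric`, `mean`, `sd`, `sem`, `n_fov`, and `normalized` when
#'   requested.
#' @export
aggregate_condition <- function(fov_summaries, normalize_to = NULL) {
  df <- as.data.frame(fov_summaries)
  stopifnot("condition" %in% names(df), nrow(df) >= 1L)
  metrics <- intersect(c("mean_D", "bound_fraction", "slow_fraction",
                         "fast_fraction", "spot_density", "n_trajectories"),
                       names(df))
  out <- do.call(rbind, lapply(split(df, df$condition), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]][!is.na(g[[m]])]
      data.frame(condition = g$condition[1L], metric = m,
                 mean = mean(v), sd = stats::sd(v),
                 sem = stats::sd(v) / sqrt(length(v)), n_fov = length(v))
    }))
  }))
  rownames(out) <- NULL
  if (!is.null(normalize_to)) {
    if (!normalize_to %in% df$condition)
      stop("unknown control condition '", normalize_to, "'")
    ctrl <- out[out$condition == normalize_to, c("metric", "mean")]
    out$normalized <- out$mean / ctrl$mean[match(out$metric, ctrl$metric)]
  }
  out
}
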