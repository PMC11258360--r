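#' Write a movie as a 16-bit multi-page TIFF
#'
#' @param movie List of numeric matrices (counts) or 3-D array.
#' @param path Output path.
#' @param max_count Full-scale count mapped to 65535 (default 65535, i.e.
#'   counts stored directly).
#' @export
write_movie_tiff <- function(movie, path, max_count = 65535) {
  frames <- movie_frames(movie)
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), max_count) / max_count)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a list of count matrices
#'
#' @param path TIFF path.
#' @param max_count Full-scale count corresponding to 65535 (default 65535).
#' @return List of numeric matrices.
#' @export
read_movie_tiff <- function(path, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * max_count
  })
}

#' Run the default pipeline parameter set
#'
#' All stage parameters with their defaults: the detection tile and kernel
#' (11 px, sigma 1.5 px, LLR threshold 14), the Levenberg-Marquardt settings
#' (gamma 0.3, alpha 1e-4, at most 8 iterations, position tolerance 1e-4
#' px), the candidate-link bounds (1.25 um, 3 frames), the state grid (100
#' diffusion coefficients 0.01-100 um^2/s by 31 localization errors
#' 0.02-0.08 um), state-classification cutoffs (0.1 and 1.0 um^2/s), and
#' acquisition constants (0.1083 um/px, 0.01 s frame interval, 150 frames).
#'
#' @param ... Overrides for any listed element.
#' @return Validated named list of class `smt_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(w = 11L, sigma_w = 1.5, threshold = 14, min_sep = 3,
              gamma = 0.3, alpha = 1e-4, max_iter = 8L, fit_tol = 1e-4,
              max_dist = 1.25, max_gap = 3L, sigma_loc = 0.035,
              t_bound = 0.1, t_fast = 1.0, min_area_um2 = 20,
              pixel_size = 0.1083, frame_interval = 0.01, n_frames = 150L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$w %% 2L == 1L, cfg$sigma_w > 0, cfg$threshold > 0,
            cfg$max_dist > 0, cfg$max_gap >= 1L, cfg$pixel_size > 0,
            cfg$frame_interval > 0, cfg$t_bound < cfg$t_fast)
  class(cfg) <- "smt_pipeline_config"
  cfg
}

#' Process one field of view in memory
#'
#' Runs the full analysis chain on one tracking movie plus one
#' nuclear-stain movie: detection, subpixel localization, trajectory
#' linking, nuclear segmentation and assignment, state-array inference,
#' and FOV summary.
#'
#' @param movie Tracking movie (list of matrices or 3-D array).
#' @param hoechst_movie Nuclear-stain movie.
#' @param config `smt_pipeline_config`.
#' @param plate,well,fov Identifiers carried into the summary.
#' @return List: `detections`, `localizations`, `trajectories`, `mask`,
#'   `posterior`, `marginal`, `summary`.
#' @export
process_fov <- function(movie, hoechst_movie, config = pipeline_config(),
                        plate = "plate1", well = "A1", fov = 1L) {
  kernel <- make_kernel(config$w, config$sigma_w)
  det <- detect_movie(movie, kernel, threshold = config$threshold,
                      min_sep = config$min_sep)
  loc <- localize_spots(movie, det, w = config$w, sigma_w = config$sigma_w,
                        pixel_size = config$pixel_size, gamma = config$gamma,
                        alpha = config$alpha, max_iter = config$max_iter,
                        tol = config$fit_tol)
  trajs <- link_trajectories(loc, dt = config$frame_interval,
                             max_dist = config$max_dist,
                             max_gap = config$max_gap,
                             sigma_loc = config$sigma_loc)
  mask <- segment_nuclei(mean_projection(hoechst_movie),
                         pixel_size = config$pixel_size,
                         min_area_um2 = config$min_area_um2)
  trajs <- assign_to_nuclei(trajs, mask)
  lmat <- likelihood_matrix(trajs, state_grid(), dt = config$frame_interval)
  post <- infer_occupations(lmat)
  n_frames <- length(movie_frames(movie))
  summ <- summarize_fov(post, trajs$points, mask, n_frames,
                        t_bound = config$t_bound, t_fast = config$t_fast,
                        plate = plate, well = well, fov = fov)
  list(detections = det, localizations = loc, trajectories = trajs,
       mask = mask, posterior = post, marginal = marginalize_error(post),
       summary = summ)
}

#' Run the pipeline over movie files on disk
#'
#' For each field of view, reads the tracking and nuclear-stain TIFFs,
#' processes them with [process_fov()], and writes all intermediate and
#' final artifacts (CSV tables, label-mask TIFF, posterior and marginal
#' CSVs, FOV summary CSV) plus a JSON manifest. A field whose movie fails
#' to read is recorded as failed and the run continues. Rerunning with the
#' same inputs, config and seed reproduces identical outputs.
#'
#' @param fovs `data.frame` with columns `movie`, `hoechst` (TIFF paths)
#'   and optionally `plate`, `well`, `fov`.
#' @param out_dir Output directory (created if missing).
#' @param config `smt_pipeline_config`.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(fovs, out_dir, config = pipeline_config()) {
  fovs <- as.data.frame(fovs)
  stopifnot(all(c("movie", "hoechst") %in% names(fovs)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(fovs$plate)) fovs$plate <- "plate1"
  if (is.null(fovs$well)) fovs$well <- "A1"
  if (is.null(fovs$fov)) fovs$fov <- seq_len(nrow(fovs))
  set.seed(config$seed)
  manifest <- list(config = unclass(config), fovs = list(),
                   package_version = as.character(utils::packageVersion("smtpipe")))
  summaries <- list()
  for (k in seq_len(nrow(fovs))) {
    tag <- sprintf("%s_%s_fov%d", fovs$plate[k], fovs$well[k], fovs$fov[k])
    res <- tryCatch({
      movie <- read_movie_tiff(fovs$movie[k])
      hoechst <- read_movie_tiff(fovs$hoechst[k])
      process_fov(movie, hoechst, config, plate = fovs$plate[k],
                  well = fovs$well[k], fov = fovs$fov[k])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$fovs[[tag]] <- list(status = "failed",
                                   error = conditionMessage(res))
      next
    }
    files <- c(detections = file.path(out_dir, paste0(tag, "_detections.csv")),
               localizations = file.path(out_dir, paste0(tag, "_localizations.csv")),
               trajectories = file.path(out_dir, paste0(tag, "_trajectories.csv")),
               mask = file.path(out_dir, paste0(tag, "_mask.tif")),
               nuclei = file.path(out_dir, paste0(tag, "_nuclei.csv")),
               posterior = file.path(out_dir, paste0(tag, "_posterior.csv")),
               marginal = file.path(out_dir, paste0(tag, "_marginal.csv")))
    utils::write.csv(res$detections, files["detections"], row.names = FALSE)
    utils::write.csv(res$localizations, files["localizations"],
                     row.names = FALSE)
    tp <- res$trajectories$points
    utils::write.csv(tp[, intersect(c("trajectory", "frame", "x_um", "y_um",
                                      "nucleus"), names(tp))],
                     files["trajectories"], row.names = FALSE)
    tiff::writeTIFF(res$mask$labels / 65535, files["mask"],
                    bits.per.sample = 16L)
    utils::write.csv(res$mask$table, files["nuclei"], row.names = FALSE)
    if (!is.null(res$posterior$mass)) {
      g <- res$posterior$grid
      utils::write.csv(data.frame(D = rep(g$D, times = length(g$sigma)),
                                  sigma = rep(g$sigma, each = length(g$D)),
                                  mass = as.vector(res$posterior$mass)),
                       files["posterior"], row.names = FALSE)
      utils::write.csv(data.frame(D = g$D, mass = res$marginal),
                       files["marginal"], row.names = FALSE)
    }
    summaries[[tag]] <- res$summary
    manifest$fovs[[tag]] <- list(status = "ok", files = as.list(files),
                                 n_detections = nrow(res$detections),
                                 n_trajectories = res$posterior$n_trajectories)
  }
  if (length(summaries) > 0L) {
    summ <- do.call(rbind, summaries)
    rownames(summ) <- NULL
    utils::write.csv(summ, file.path(out_dir, "fov_summaries.csv"),
                     row.names = FALSE)
    manifest$summary_file <- "fov_summaries.csv"
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a field of view and write it as a fixture directory
#'
#' Wraps the synthetic-data generator end to end: writes the tracking movie
#' and nuclear-stain movie as 16-bit TIFFs, the ground truth as CSV, the
#' label mask as a 16-bit label TIFF, and the configuration as JSON.
#'
#' @param config `smt_sim_config`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default "fov1").
#' @return Invisibly, named vector of file paths.
#' @export
simulate_fov_to_dir <- function(config = sim_config(), dir, prefix = "fov1") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_fov(config)
  paths <- c(movie = file.path(dir, paste0(prefix, "_movie.tif")),
             hoechst = file.path(dir, paste0(prefix, "_hoechst.tif")),
             mask = file.path(dir, paste0(prefix, "_mask.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")),
             config = file.path(dir, paste0(prefix, "_config.json")))
  write_movie_tiff(sim$movie, paths["movie"])
  write_movie_tiff(sim$hoechst_movie, paths["hoechst"])
  tiff::writeTIFF(sim$mask / 65535, paths["mask"], bits.per.sample = 16L)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  cfg <- unclass(config)
  cfg$states <- as.data.frame(cfg$states)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
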