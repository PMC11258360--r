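#!/usr/bin/env Rscript

# Thin command-line wrapper over smtpipe::run_pipeline() /
# smtpipe::simulate_fov_to_dir().
#
#   Simulate a fixture field of view:
#     Rscript scripts/run_pipeline.R simulate --out <dir> [--seed <int>]
#   Process fields of view listed in a CSV (columns: movie, hoechst,
#   optionally plate, well, fov):
#     Rscript scripts/run_pipeline.R run --fovs <csv> --out <dir>
#       [--seed <int>] [--threshold <llr>] [--pixel-size <um>]
#       [--frame-interval <s>] [--n-frames <int>]

suppressMessages(library(smtpipe))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: run_pipeline.R simulate|run [options]")
cmd <- args[1L]
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

out_dir <- opt("--out", "smtpipe_out")
seed <- as.integer(opt("--seed", "1"))

if (cmd == "simulate") {
  cfg <- sim_config(seed = seed,
                    n_frames = as.integer(opt("--n-frames", "150")))
  paths <- simulate_fov_to_dir(cfg, out_dir)
  cat("wrote fixture:\n")
  for (p in paths) cat(" ", p, "\n")
} else if (cmd == "run") {
  fovs_csv <- opt("--fovs", NA)
  if (is.na(fovs_csv)) stop("run requires --fovs <csv>")
  fovs <- utils::read.csv(fovs_csv)
  pc <- pipeline_config(
    seed = seed,
    threshold = as.numeric(opt("--threshold", "14")),
    pixel_size = as.numeric(opt("--pixel-size", "0.1083")),
    frame_interval = as.numeric(opt("--frame-interval", "0.01")),
    n_frames = as.integer(opt("--n-frames", "150")))
  man <- run_pipeline(fovs, out_dir, pc)
  status <- vapply(man$fovs, `[[`, "", "status")
  cat(sprintf("processed %d FOV(s): %d ok, %d failed; outputs in %s\n",
              length(status), sum(status == "ok"),
              sum(status != "ok"), out_dir))
} else {
  stop("unknown command '", cmd, "' (expected simulate or run)")
}
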