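# End-to-end pipeline driver, configuration handling and paired-dataset
# export. Every run is deterministic given its configuration seeds, logs at
# interval granularity, and tolerates per-interval failures: one bad
# interval is recorded and the run continues.

#' Default pipeline configuration
#'
#' A flat, namespaced key-value document collecting every tunable of the
#' pipeline. Unknown keys are rejected by [pipeline_config()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    tracking.min_len = 8L,
    tracking.strict_gt = FALSE,
    tracking.tol_step = 1.5,
    tracking.tol_total = 3.0,
    tracking.seed_point = NULL,      # c(x, y); NULL = take from manifest
    tracking.lk_err_max = 15,
    register.theta_range = c(-5, 5),
    register.shift_range = c(-30, 30),
    register.coarse_step = 0.5,
    register.smooth_sigma = 2,
    register.log_intensity = TRUE,
    register.reject_below_ncc = NA,  # NA = no outlier rejection
    quality.thresholds = c(snr = 70, cnr = 3, enl = 10),
    quality.n_layers = 5L,
    quality.roi_background = c(32, 32),
    quality.roi_homogeneous = c(16, 8),
    quality.roi_contrast = c(96, 12),
    export.fractions = c(train = 0.7, val = 0.1, test = 0.2)
  )
}

#' Build a validated pipeline configuration
#'
#' @param ... overrides of [default_config()] keys (unknown keys raise an
#'   error).
#' @return named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    ioct_stop("ioct_invalid_input", "unknown config keys: %s",
              paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

read_config_yaml <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

list_frames <- function(dir, prefix) {
  sort(list.files(file.path(dir, "frames"),
                  pattern = sprintf("^%s_\\d+\\.png$", prefix),
                  full.names = TRUE))
}

#' Run the full HR-estimation pipeline on a frame directory
#'
#' Stages: scan-marker detection and feature tracking on the microscope
#' views, stationary-interval extraction, rigid registration and temporal
#' fusion of each interval's B-scans, layer segmentation (external masks
#' when present, heuristic otherwise), ROI placement, SNR/ENL/CNR
#' computation and gating. Writes all per-stage artefacts plus a summary
#' and the fully resolved configuration next to the outputs.
#'
#' @param input_dir directory with `frames/scene_%05d.png`,
#'   `frames/bscan_%05d.png`, optionally `masks/mask_%05d.png` and
#'   `manifest.json` (used for the feature seed point when
#'   `tracking.seed_point` is `NULL`).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly (also written as `summary.json`):
#'   `n_frames`, `n_intervals`, `n_fused`, `n_accepted`, per-interval
#'   records and any per-interval errors.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  scene_paths <- list_frames(input_dir, "scene")
  bscan_paths <- list_frames(input_dir, "bscan")
  if (!length(scene_paths) || !length(bscan_paths)) {
    ioct_stop("ioct_invalid_input", "no scene/bscan frames under %s", input_dir)
  }
  if (length(scene_paths) != length(bscan_paths)) {
    ioct_stop("ioct_invalid_input", "scene/bscan frame counts differ")
  }
  dir.create(file.path(out_dir, "hr", "accepted"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "hr", "rejected"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "lr"), recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(config, file.path(out_dir, "config.yaml"))

  seed_point <- config$tracking.seed_point
  manifest <- NULL
  if (file.exists(file.path(input_dir, "manifest.json"))) {
    manifest <- read_manifest(input_dir)
  }
  if (is.null(seed_point)) {
    if (is.null(manifest)) {
      ioct_stop("ioct_invalid_input",
                "tracking.seed_point not set and no manifest.json present")
    }
    seed_point <- manifest$frames[[1]]$feature_point
  }
  opts <- tracking_options(lk_err_max = config$tracking.lk_err_max)
  scenes <- lapply(scene_paths, read_rgb_png)
  track <- build_scan_track(scenes, seed_point, opts)
  write_track(track, file.path(out_dir, "track.json"))
  intervals <- find_stable_intervals(track,
                                     min_len = config$tracking.min_len,
                                     tol_step = config$tracking.tol_step,
                                     tol_total = config$tracking.tol_total,
                                     strict_gt = config$tracking.strict_gt)
  write_intervals(intervals, file.path(out_dir, "intervals.json"))

  roi_sizes <- list(background = config$quality.roi_background,
                    homogeneous = config$quality.roi_homogeneous,
                    contrast = config$quality.roi_contrast)
  records <- list()
  n_fused <- 0L; n_accepted <- 0L
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    rec <- list(interval = k - 1L, start = iv$start, end = iv$end,
                n_frames = iv$n_frames)
    res <- tryCatch({
      idx <- (iv$start:iv$end) + 1L
      bscans <- lapply(bscan_paths[idx], read_gray_png)
      fused <- fuse_interval(bscans, transforms = "estimate",
                             reject_below_ncc = config$register.reject_below_ncc,
                             theta_range = config$register.theta_range,
                             shift_range = config$register.shift_range,
                             coarse_step = config$register.coarse_step,
                             smooth_sigma = config$register.smooth_sigma,
                             log_intensity = config$register.log_intensity)
      mask_path <- file.path(input_dir, "masks",
                             sprintf("mask_%05d.png", iv$start))
      mask <- if (file.exists(mask_path)) read_mask_png(mask_path) else NULL
      qr <- assess_quality(fused$hr_estimate, mask = mask,
                           thresholds = config$quality.thresholds,
                           roi_sizes = roi_sizes,
                           rng_seed = config$seed + k,
                           n_layers = config$quality.n_layers)
      sub <- if (qr$accepted) "accepted" else "rejected"
      hr_name <- sprintf("hr_%04d.png", k - 1L)
      write_gray_png(fused$hr_estimate, file.path(out_dir, "hr", sub, hr_name))
      write_gray_png(fused$lr_reference,
                     file.path(out_dir, "lr", sprintf("lr_%04d.png", k - 1L)))
      list(fused = fused, qr = qr)
    }, ioct_error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
    } else {
      n_fused <- n_fused + 1L
      rec$n_dropped <- length(res$fused$dropped)
      rec$transforms <- lapply(res$fused$transforms, unclass)
      rec$snr <- res$qr$snr; rec$cnr <- res$qr$cnr; rec$enl <- res$qr$enl
      rec$accepted <- res$qr$accepted
      if (res$qr$accepted) n_accepted <- n_accepted + 1L
    }
    records[[k]] <- rec
  }
  summary <- list(n_frames = length(scene_paths),
                  n_intervals = length(intervals),
                  n_fused = n_fused,
                  n_accepted = n_accepted,
                  intervals = records)
  json_write(summary, file.path(out_dir, "summary.json"))
  json_write(records, file.path(out_dir, "fusion_report.json"))
  invisible(summary)
}

# largest-remainder apportionment of n into fractions
split_sizes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # distribute leftovers by largest fractional remainder; ties in the
    # order given (train, val, test)
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Export accepted LR/HR pairs into a train/val/test split
#'
#' Writes `train/ val/ test/` directories, each with `lr/` and `hr/`
#' subdirectories holding stem-matched copies. Split sizes are the
#' largest-remainder rounding of `fractions`; the assignment of pairs to
#' splits is uniformly random under `rng_seed`.
#'
#' @param pairs data frame with columns `lr` and `hr` (file paths), e.g.
#'   from a [run_pipeline()] output directory.
#' @param out_dir export root.
#' @param fractions split fractions, must sum to 1.
#' @param rng_seed shuffle seed.
#' @return data frame of class `paired_dataset`: `lr`, `hr`, `split`,
#'   invisibly. An empty `pairs` produces empty directories and a warning.
#' @export
export_pairs <- function(pairs, out_dir,
                         fractions = c(train = 0.7, val = 0.1, test = 0.2),
                         rng_seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    ioct_stop("ioct_invalid_input", "split fractions must sum to 1")
  }
  splits <- c("train", "val", "test")
  for (s in splits) {
    dir.create(file.path(out_dir, s, "lr"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, s, "hr"), recursive = TRUE, showWarnings = FALSE)
  }
  n <- nrow(pairs)
  if (is.null(n) || n == 0) {
    warning("no accepted pairs to export; split directories left empty")
    out <- data.frame(lr = character(0), hr = character(0), split = character(0))
    class(out) <- c("paired_dataset", "data.frame")
    return(invisible(out))
  }
  sizes <- split_sizes(n, fractions)
  assign <- rep(splits, times = sizes)
  perm <- with_seed(rng_seed, sample.int(n))
  split_of <- character(n)
  split_of[perm] <- assign
  for (i in seq_len(n)) {
    stem_lr <- basename(pairs$lr[i])
    stem_hr <- basename(pairs$hr[i])
    file.copy(pairs$lr[i], file.path(out_dir, split_of[i], "lr", stem_lr))
    file.copy(pairs$hr[i], file.path(out_dir, split_of[i], "hr", stem_hr))
  }
  out <- data.frame(lr = pairs$lr, hr = pairs$hr, split = split_of,
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_dataset", "data.frame")
  invisible(out)
}

#' Collect accepted LR/HR pairs from a pipeline output directory
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return data frame with `lr` and `hr` path columns (stem-matched by
#'   interval index).
#' @export
collect_accepted_pairs <- function(run_dir) {
  hr <- sort(list.files(file.path(run_dir, "hr", "accepted"), full.names = TRUE))
  if (!length(hr)) return(data.frame(lr = character(0), hr = character(0)))
  idx <- sub("^hr_(\\d+)\\.png$", "\\1", basename(hr))
  lr <- file.path(run_dir, "lr", sprintf("lr_%s.png", idx))
  keep <- file.exists(lr)
  data.frame(lr = lr[keep], hr = hr[keep], stringsAsFactors = FALSE)
}
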