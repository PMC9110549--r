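# Speckle-statistics quality assessment of fused B-scans: ROI placement from
# a retinal-layer mask and the SNR / ENL / CNR gate.
#
# The three metrics are
#   SNR = 10 log10( max{F^2} / var_b )            [dB]
#   ENL = (1/H) sum_h  mu_h^2 / var_h             [H = 2 homogeneous ROIs]
#   CNR = (1/R) sum_r (mu_r - mu_b)/sqrt(var_r + var_b)   [R = 4 ROIs]
# with F the linear-intensity image, b the background ROI, and population
# (1/n) variances throughout. Values are computed on the stored 0..255
# intensity scale, assumed linear; SNR and the two ratios are invariant to a
# global rescaling, but clipping or log-compression of the stored image does
# change them.

#' Heuristic retinal-layer segmentation of a B-scan
#'
#' A deliberately simple intensity-profile segmenter used when no external
#' layer mask is supplied. Per column of the Gaussian-smoothed image, the
#' retina top is the first crossing above an adaptive threshold
#' (background estimate plus `thresh_frac` of the dynamic range) and the
#' retina bottom is the last crossing; the interior is divided into
#' `n_layers` bands at fixed fractional depths. Columns without a crossing
#' are interpolated from their neighbours.
#'
#' @param bscan grayscale matrix (0..255).
#' @param n_layers number of bands to label.
#' @param fractions interior band fractions (length `n_layers - 1`); `NULL`
#'   gives equal-thickness bands.
#' @param smooth_sigma_axial,smooth_sigma_lateral Gaussian smoothing (px)
#'   applied before profiling.
#' @param thresh_frac adaptive threshold position within the dynamic range.
#' @return A `layer_mask`: integer matrix (0 = background, 1..n_layers top to
#'   bottom) with attributes `top_curve`, `bottom_curve` (per-column y) and
#'   `provenance = "heuristic"`.
#' @export
segment_layers_heuristic <- function(bscan, n_layers = 5, fractions = NULL,
                                     smooth_sigma_axial = 2,
                                     smooth_sigma_lateral = 4,
                                     thresh_frac = 0.08) {
  if (!is_image(bscan)) ioct_stop("ioct_invalid_input", "bscan must be a numeric matrix")
  if (is.null(fractions)) fractions <- seq_len(n_layers - 1) / n_layers
  S <- gauss_smooth(bscan, smooth_sigma_axial, smooth_sigma_lateral)
  bg <- stats::quantile(S, 0.25, names = FALSE)
  thr <- bg + thresh_frac * (max(S) - bg)
  if (max(S) - bg < 1e-6 || !any(S >= thr)) {
    ioct_stop("ioct_segmentation_failed", "no column crosses the intensity threshold")
  }
  h <- nrow(bscan); w <- ncol(bscan)
  top <- bottom <- rep(NA_real_, w)
  for (cx in seq_len(w)) {
    above <- which(S[, cx] >= thr)
    if (length(above)) {
      top[cx] <- above[1] - 1
      bottom[cx] <- above[length(above)] - 1
    }
  }
  if (all(is.na(top))) {
    ioct_stop("ioct_segmentation_failed", "no column crosses the intensity threshold")
  }
  fill_na <- function(v) {
    ok <- which(!is.na(v))
    stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  top <- fill_na(top); bottom <- fill_na(bottom)
  bad <- bottom <= top
  if (any(bad)) {
    bottom[bad] <- top[bad] + 1
  }
  mask <- matrix(0L, h, w)
  fr <- c(0, fractions, 1)
  y <- 0:(h - 1)
  for (cx in seq_len(w)) {
    cuts <- top[cx] + fr * (bottom[cx] - top[cx])
    lab <- findInterval(y, cuts)
    lab[lab > n_layers] <- 0L
    mask[, cx] <- lab
  }
  structure(mask, top_curve = top, bottom_curve = bottom,
            provenance = "heuristic", class = c("layer_mask", "matrix", "array"))
}

#' Place the five quality-assessment ROIs from a layer mask
#'
#' One background ROI wholly inside the background (label 0), two small
#' homogeneous ROIs wholly inside the second and the last retinal layer, and
#' two large contrast ROIs wholly inside the first and the last layer. ROI
#' centres are drawn uniformly from the valid placements under the given
#' seed (rejection sampling over the target label's pixels).
#'
#' @param mask integer label matrix (0 background, 1..K layers).
#' @param sizes list with `background`, `homogeneous`, `contrast`, each
#'   c(width, height) in pixels.
#' @param rng_seed placement seed.
#' @param max_attempts rejection-sampling cap per ROI.
#' @return An object of class `roi_set`: list with `background` (one ROI),
#'   `homogeneous` (2 ROIs), `contrast` (2 ROIs) and `rng_seed`; each ROI is
#'   a list (x, y, w, h, role, target_label) with 0-based top-left (x, y).
#' @export
place_rois <- function(mask,
                       sizes = list(background = c(32, 32),
                                    homogeneous = c(16, 8),
                                    contrast = c(96, 12)),
                       rng_seed = 1L, max_attempts = 2000) {
  K <- max(mask)
  if (K < 2 || !any(mask == 0L)) {
    ioct_stop("ioct_invalid_input",
              "mask needs a background and at least two layer labels")
  }
  h <- nrow(mask); w <- ncol(mask)
  g <- image_grid(h, w)
  place_one <- function(label, size, role) {
    rw <- size[1]; rh <- size[2]
    cand <- which(mask == label)
    if (!length(cand) || rw > w || rh > h) {
      ioct_stop("ioct_placement_failed", "no valid placement for %s ROI", role)
    }
    for (i in seq_len(max_attempts)) {
      idx <- cand[sample.int(length(cand), 1)]
      cx <- g$x[idx]; cy <- g$y[idx]
      x0 <- cx - floor((rw - 1) / 2); y0 <- cy - floor((rh - 1) / 2)
      if (x0 < 0 || y0 < 0 || x0 + rw > w || y0 + rh > h) next
      sub <- mask[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw)]
      if (all(sub == label)) {
        return(list(x = x0, y = y0, w = rw, h = rh, role = role,
                    target_label = label))
      }
    }
    ioct_stop("ioct_placement_failed", "no valid placement for %s ROI", role)
  }
  with_seed(rng_seed, {
    bgr <- place_one(0L, sizes$background, "background")
    hom <- list(place_one(2L, sizes$homogeneous, "homogeneous"),
                place_one(K, sizes$homogeneous, "homogeneous"))
    con <- list(place_one(1L, sizes$contrast, "contrast"),
                place_one(K, sizes$contrast, "contrast"))
    structure(list(background = bgr, homogeneous = hom, contrast = con,
                   rng_seed = as.integer(rng_seed)), class = "roi_set")
  })
}

#' Extract the pixels covered by an ROI
#' @param image matrix.
#' @param roi ROI list from [place_rois()].
#' @return numeric vector of covered pixel intensities.
#' @export
roi_pixels <- function(image, roi) {
  image[(roi$y + 1):(roi$y + roi$h), (roi$x + 1):(roi$x + roi$w)]
}

#' Signal-to-noise ratio of an image against a background ROI
#'
#' `10 * log10(max(F^2) / var_b)` where the maximum runs over the whole
#' image and `var_b` is the population variance inside the background ROI.
#'
#' @param image grayscale matrix (linear intensities, 0..255).
#' @param background_roi background ROI.
#' @return SNR in dB.
#' @export
compute_snr <- function(image, background_roi) {
  px <- roi_pixels(image, background_roi)
  if (length(px) < 2) ioct_stop("ioct_invalid_input", "background ROI too small")
  v <- pvar(px)
  if (v == 0) ioct_stop("ioct_degenerate_background", "background ROI is constant")
  10 * log10(max(image^2) / v)
}

#' Equivalent number of looks over homogeneous ROIs
#'
#' Mean of `mu_h^2 / var_h` over the homogeneous ROIs (population variance).
#' For fully-developed L-look speckle this estimates L.
#'
#' @param image grayscale matrix.
#' @param homogeneous_rois list of ROIs.
#' @return dimensionless ENL.
#' @export
compute_enl <- function(image, homogeneous_rois) {
  vals <- vapply(homogeneous_rois, function(r) {
    px <- roi_pixels(image, r)
    if (length(px) < 2) ioct_stop("ioct_invalid_input", "homogeneous ROI too small")
    v <- pvar(px)
    if (v == 0) ioct_stop("ioct_degenerate_region", "homogeneous ROI is constant")
    mean(px)^2 / v
  }, numeric(1))
  mean(vals)
}

#' Contrast-to-noise ratio of feature ROIs against a background ROI
#'
#' Mean over the region ROIs of `(mu_r - mu_b) / sqrt(var_r + var_b)` with
#' signed numerator and population variances.
#'
#' @param image grayscale matrix.
#' @param region_rois list of ROIs (the R regions).
#' @param background_roi background ROI.
#' @return dimensionless CNR.
#' @export
compute_cnr <- function(image, region_rois, background_roi) {
  pb <- roi_pixels(image, background_roi)
  mb <- mean(pb); vb <- pvar(pb)
  vals <- vapply(region_rois, function(r) {
    px <- roi_pixels(image, r)
    vr <- pvar(px)
    if (vr + vb == 0) ioct_stop("ioct_degenerate_region", "zero pooled variance")
    (mean(px) - mb) / sqrt(vr + vb)
  }, numeric(1))
  mean(vals)
}

#' Gate a fused image on the SNR / CNR / ENL thresholds
#'
#' @param snr,cnr,enl metric values.
#' @param thresholds named numeric vector `c(snr=, cnr=, enl=)`; the
#'   defaults are the empirical acceptance thresholds 70.0, 3.0 and 10.0.
#'   Comparison is inclusive (a value equal to its threshold passes).
#' @param roi_set optional [place_rois()] result to attach.
#' @return An object of class `quality_report`: list with the metric values,
#'   thresholds, `accepted`, and the ROI set (or `NULL`).
#' @export
gate_quality <- function(snr, cnr, enl,
                         thresholds = c(snr = 70, cnr = 3, enl = 10),
                         roi_set = NULL) {
  vals <- c(snr = snr, cnr = cnr, enl = enl)
  if (any(is.na(vals)) || any(!is.finite(vals) & vals < 0)) {
    ioct_stop("ioct_invalid_metric", "metric values must be finite (NaN given)")
  }
  accepted <- snr >= thresholds[["snr"]] && cnr >= thresholds[["cnr"]] &&
    enl >= thresholds[["enl"]]
  structure(list(snr = snr, cnr = cnr, enl = enl,
                 thresholds = thresholds, accepted = accepted,
                 roi_set = roi_set), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality report: SNR %.2f dB, CNR %.3f, ENL %.2f -> %s\n",
              x$snr, x$cnr, x$enl,
              if (x$accepted) "ACCEPTED" else "rejected"))
  cat(sprintf("  thresholds: SNR >= %.1f, CNR >= %.1f, ENL >= %.1f\n",
              x$thresholds[["snr"]], x$thresholds[["cnr"]], x$thresholds[["enl"]]))
  invisible(x)
}

#' Assess the quality of a B-scan or fused HR estimate
#'
#' Convenience wrapper: segments layers (unless a mask is given), places the
#' five ROIs, computes SNR/ENL/CNR and applies the gate. The CNR uses R = 4
#' regions: the two large contrast ROIs plus the two small homogeneous ROIs.
#'
#' @param image grayscale matrix.
#' @param mask optional integer layer mask; `NULL` runs
#'   [segment_layers_heuristic()].
#' @param thresholds gate thresholds, see [gate_quality()].
#' @param roi_sizes ROI size configuration, see [place_rois()].
#' @param rng_seed ROI placement seed.
#' @param n_layers passed to the heuristic segmenter when `mask` is `NULL`.
#' @return A `quality_report`.
#' @export
assess_quality <- function(image, mask = NULL,
                           thresholds = c(snr = 70, cnr = 3, enl = 10),
                           roi_sizes = list(background = c(32, 32),
                                            homogeneous = c(16, 8),
                                            contrast = c(96, 12)),
                           rng_seed = 1L, n_layers = 5) {
  if (is.null(mask)) mask <- segment_layers_heuristic(image, n_layers = n_layers)
  rois <- place_rois(mask, sizes = roi_sizes, rng_seed = rng_seed)
  snr <- compute_snr(image, rois$background)
  enl <- compute_enl(image, rois$homogeneous)
  cnr <- compute_cnr(image, c(rois$contrast, rois$homogeneous), rois$background)
  gate_quality(snr, cnr, enl, thresholds = thresholds, roi_set = rois)
}
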