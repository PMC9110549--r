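# Full-reference (PSNR, SSIM) and no-reference (GCF) image-quality metrics
# used in the quantitative evaluation of super-resolved B-scans.

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(max_val^2 / MSE)`; identical images give `Inf`.
#'
#' @param a,b equal-size numeric matrices.
#' @param max_val peak value of the dynamic range (255 for 8-bit).
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
compute_psnr <- function(a, b, max_val = 255) {
  if (!all(dim(a) == dim(b))) ioct_stop("ioct_shape_error", "image size mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Structural similarity index between two images
#'
#' Mean local SSIM with the reference parameterization: 11 x 11 Gaussian
#' window (sigma 1.5), K1 = 0.01, K2 = 0.03, dynamic range `max_val`.
#' Local statistics are computed with 'valid' convolution (no padding), so
#' a border of 5 pixels does not contribute.
#'
#' @param a,b equal-size matrices with min dimension >= 11.
#' @param max_val dynamic range (255 for 8-bit).
#' @param K1,K2 stabilization constants.
#' @param sigma,win Gaussian window sd and side length.
#' @return mean SSIM in [-1, 1].
#' @export
compute_ssim <- function(a, b, max_val = 255, K1 = 0.01, K2 = 0.03,
                         sigma = 1.5, win = 11) {
  if (!all(dim(a) == dim(b))) ioct_stop("ioct_shape_error", "image size mismatch")
  if (min(dim(a)) < win) {
    ioct_stop("ioct_invalid_input", "image smaller than the %dx%d SSIM window", win, win)
  }
  r <- (win - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  C1 <- (K1 * max_val)^2
  C2 <- (K2 * max_val)^2
  mu_a <- conv_sep_valid(a, k)
  mu_b <- conv_sep_valid(b, k)
  s_aa <- conv_sep_valid(a * a, k) - mu_a^2
  s_bb <- conv_sep_valid(b * b, k) - mu_b^2
  s_ab <- conv_sep_valid(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

# GCF resolution-level weights: the published weight polynomial
# w_i = (-0.406385 * i/9 + 0.334573) * i/9 + 0.0877526, i = 1..9
gcf_weights <- function(n_levels = 9) {
  i <- seq_len(n_levels) / 9
  (-0.406385 * i + 0.334573) * i + 0.0877526
}

# 2x superpixel downsampling by averaging; with odd dimensions the ragged
# edge row/column is averaged into the last superpixel
superpixel_down <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2 || w < 2) return(NULL)
  gr <- pmin(ceiling(seq_len(h) / 2), floor(h / 2))
  gc <- pmin(ceiling(seq_len(w) / 2), floor(w / 2))
  sums <- rowsum(t(rowsum(img, gr)), gc)     # (w/2) x (h/2)
  cnt <- outer(tabulate(gc), tabulate(gr))
  t(sums / cnt)
}

# mean absolute difference to existing 4-neighbours, averaged over pixels
mean_local_contrast <- function(L) {
  h <- nrow(L); w <- ncol(L)
  if (h * w <= 1) return(0)
  sumdiff <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  if (h > 1) {
    d <- abs(L[-1, , drop = FALSE] - L[-h, , drop = FALSE])
    sumdiff[-h, ] <- sumdiff[-h, ] + d; cnt[-h, ] <- cnt[-h, ] + 1
    sumdiff[-1, ] <- sumdiff[-1, ] + d; cnt[-1, ] <- cnt[-1, ] + 1
  }
  if (w > 1) {
    d <- abs(L[, -1, drop = FALSE] - L[, -w, drop = FALSE])
    sumdiff[, -w] <- sumdiff[, -w] + d; cnt[, -w] <- cnt[, -w] + 1
    sumdiff[, -1] <- sumdiff[, -1] + d; cnt[, -1] <- cnt[, -1] + 1
  }
  mean(sumdiff / pmax(cnt, 1))
}

#' Global contrast factor of a grayscale image
#'
#' Multi-resolution contrast measure: the image is gamma-linearized
#' (`l = (pix/255)^2.2`), converted to perceptual luminance `100 * sqrt(l)`,
#' and the mean absolute difference to 4-neighbours is averaged per pixel at
#' 9 resolution levels obtained by successive 2x superpixel averaging of the
#' linearized image. GCF is the weighted sum of the per-level contrasts with
#' the published resolution-weight polynomial (see source).
#'
#' @param image grayscale matrix on the 0..255 scale.
#' @param n_levels number of resolution levels.
#' @return GCF score (>= 0); 0 for a constant image.
#' @export
compute_gcf <- function(image, n_levels = 9) {
  if (!is_image(image) || length(image) == 0) {
    ioct_stop("ioct_invalid_input", "empty image")
  }
  wts <- gcf_weights(n_levels)
  lin <- (image / 255)^2.2
  total <- 0
  for (lev in seq_len(n_levels)) {
    if (!is.null(lin)) {
      L <- 100 * sqrt(lin)
      total <- total + wts[lev] * mean_local_contrast(L)
      lin <- superpixel_down(lin)
    }
  }
  total
}

#' Per-image metric report over paired image sets
#'
#' Computes PSNR and SSIM of each test image against its reference, plus
#' no-reference GCF and (when a model is given) NIQE, and aggregates
#' mean and standard deviation per metric.
#'
#' @param images named list of grayscale matrices to score.
#' @param references optional named list of reference images (stem-matched
#'   by name); `NULL` skips the full-reference metrics (reported as `NA`).
#' @param niqe_model optional [niqe_fit()] model; `NULL` skips NIQE.
#' @return An object of class `metric_report`: data frame with one row per
#'   image (`psnr`, `ssim`, `gcf`, `niqe`) and an `aggregate` attribute
#'   (mean and sd per metric).
#' @export
metric_report <- function(images, references = NULL, niqe_model = NULL) {
  nm <- names(images)
  if (is.null(nm)) nm <- sprintf("img_%03d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    ref <- if (!is.null(references)) references[[nm[i]]] else NULL
    data.frame(
      image = nm[i],
      psnr = if (!is.null(ref)) compute_psnr(img, ref) else NA_real_,
      ssim = if (!is.null(ref)) compute_ssim(img, ref) else NA_real_,
      gcf = compute_gcf(img),
      niqe = if (!is.null(niqe_model)) niqe_score(img, niqe_model) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  agg <- sapply(c("psnr", "ssim", "gcf", "niqe"), function(mname) {
    v <- out[[mname]][is.finite(out[[mname]])]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  attr(out, "aggregate") <- agg
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report over %d images (mean +/- sd):\n", nrow(x)))
  agg <- attr(x, "aggregate")
  for (mname in colnames(agg)) {
    if (is.finite(agg["mean", mname])) {
      cat(sprintf("  %-5s %8.4f +/- %.4f\n", mname, agg["mean", mname],
                  agg["sd", mname]))
    }
  }
  invisible(x)
}
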