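# Rigid registration of stability-interval B-scans to the interval's first
# frame and temporal averaging into the estimated high-resolution image.
# Rigid means rotation + translation only: scale and shear are excluded so no
# unrealistic deformation can be introduced by the alignment step.

#' Create a rigid transform object
#'
#' @param theta rotation in degrees, counter-clockwise about the image
#'   centre in x-right/y-down coordinates.
#' @param tx,ty translation in pixels.
#' @param score normalized cross-correlation achieved at this transform
#'   (`NA` when not estimated).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, score = NA_real_) {
  structure(list(theta = theta, tx = tx, ty = ty, score = score),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: theta = %.4f deg, t = (%.3f, %.3f) px, NCC = %s\n",
              x$theta, x$tx, x$ty,
              if (is.na(x$score)) "NA" else sprintf("%.4f", x$score)))
  invisible(x)
}

# NCC over pixels finite in both images; `erode` shrinks the valid overlap
# by that many pixels along both axes, discarding boundary pixels whose
# neighbourhood straddles the overlap edge (needed when images were
# pre-smoothed, since smoothing bleeds out-of-support values inward)
ncc <- function(a, b, erode = 0) {
  ok <- is.finite(a) & is.finite(b)
  if (erode > 0) {
    r <- as.integer(erode)
    h <- nrow(ok); w <- ncol(ok)
    sh <- function(m, dy, dx) {
      out <- matrix(FALSE, h, w)
      ys <- max(1, 1 + dy):min(h, h + dy)
      xs <- max(1, 1 + dx):min(w, w + dx)
      out[ys, xs] <- m[ys - dy, xs - dx]
      out
    }
    ok <- ok & sh(ok, r, 0) & sh(ok, -r, 0) & sh(ok, 0, r) & sh(ok, 0, -r)
    ok[c(1:r, (h - r + 1):h), ] <- FALSE
    ok[, c(1:r, (w - r + 1):w)] <- FALSE
  }
  if (sum(ok) < 16) return(-1)
  av <- a[ok]; bv <- b[ok]
  av <- av - mean(av); bv <- bv - mean(bv)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den <= 0) return(-1)
  sum(av * bv) / den
}

hann2 <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(h - 1)) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  outer(wy, wx)
}

# integer-pixel translation aligning `moving` to `fixed` by phase correlation
phase_correlate <- function(fixed, moving, max_shift = c(30, 30)) {
  h <- nrow(fixed); w <- ncol(fixed)
  win <- hann2(h, w)
  f1 <- stats::fft(win * (fixed - mean(fixed)))
  f2 <- stats::fft(win * (moving - mean(moving)))
  cp <- f1 * Conj(f2)
  mag <- Mod(cp)
  mag[mag < 1e-12] <- 1e-12
  r <- Re(stats::fft(cp / mag, inverse = TRUE))
  # wrap to signed shifts and mask out-of-range shifts
  sy <- c(0:(h - 1)); sy[sy > h / 2] <- sy[sy > h / 2] - h
  sx <- c(0:(w - 1)); sx[sx > w / 2] <- sx[sx > w / 2] - w
  ok <- outer(abs(sy) <= max_shift[2], abs(sx) <= max_shift[1])
  r[!ok] <- -Inf
  idx <- which.max(r)
  iy <- (idx - 1) %% h + 1
  ix <- (idx - 1) %/% h + 1
  c(tx = sx[ix], ty = sy[iy])
}

half_image <- function(img) {
  h <- nrow(img); w <- ncol(img)
  img[seq(1, h - h %% 2, by = 2), seq(1, w - w %% 2, by = 2), drop = FALSE] / 4 +
    img[seq(2, h, by = 2), seq(1, w - w %% 2, by = 2), drop = FALSE] / 4 +
    img[seq(1, h - h %% 2, by = 2), seq(2, w, by = 2), drop = FALSE] / 4 +
    img[seq(2, h, by = 2), seq(2, w, by = 2), drop = FALSE] / 4
}

#' Estimate the rigid transform aligning one B-scan onto another
#'
#' Maximizes the normalized cross-correlation (NCC) between the warped
#' moving image and the fixed image. Strategy: a coarse rotation grid
#' (`coarse_step` degrees) with per-rotation translation by phase
#' correlation, evaluated at half resolution, followed by Nelder-Mead
#' refinement of (theta, tx, ty) on the full-resolution NCC. Deterministic
#' for fixed inputs.
#'
#' @param moving,fixed grayscale matrices of equal size.
#' @param theta_range rotation search range in degrees.
#' @param shift_range translation search range in pixels.
#' @param coarse_step rotation grid step in degrees.
#' @param smooth_sigma Gaussian pre-smoothing (pixels) applied to both
#'   images before correlation; suppresses speckle noise in the objective
#'   without moving its optimum (0 disables).
#' @param log_intensity correlate `log(1 + F)` instead of `F` (homomorphic
#'   registration): the log turns multiplicative speckle into approximately
#'   signal-independent additive noise, so bright layers no longer dominate
#'   the noise budget of the objective. The reported `score` is always the
#'   NCC of the original intensities.
#' @return a [rigid_transform()] whose `score` is the attained NCC.
#' @export
register_rigid <- function(moving, fixed,
                           theta_range = c(-5, 5), shift_range = c(-30, 30),
                           coarse_step = 0.5, smooth_sigma = 2,
                           log_intensity = TRUE) {
  if (!all(dim(moving) == dim(fixed))) {
    ioct_stop("ioct_shape_error", "moving and fixed must have equal dimensions")
  }
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0) {
    ioct_stop("ioct_degenerate_image", "constant image cannot be registered")
  }
  moving_w <- if (log_intensity) log1p(pmax(moving, 0)) else moving
  fixed_w <- if (log_intensity) log1p(pmax(fixed, 0)) else fixed
  moving_s <- if (smooth_sigma > 0) gauss_smooth(moving_w, smooth_sigma) else moving_w
  fixed_s <- if (smooth_sigma > 0) gauss_smooth(fixed_w, smooth_sigma) else fixed_w
  use_half <- min(dim(fixed)) >= 128
  f_c <- if (use_half) half_image(fixed_s) else fixed_s
  m_c <- if (use_half) half_image(moving_s) else moving_s
  sc <- if (use_half) 2 else 1
  max_s <- max(abs(shift_range)) / sc
  er_f <- if (smooth_sigma > 0) ceiling(2 * smooth_sigma) else 0
  er_c <- max(1, ceiling(er_f / sc))
  thetas <- seq(theta_range[1], theta_range[2], by = coarse_step)
  fillv <- mean(m_c)
  best <- NULL; best_ncc <- -Inf
  for (th in thetas) {
    rot <- warp_rigid(m_c, th, 0, 0, fill = fillv)
    tsh <- phase_correlate(f_c, rot, max_shift = c(max_s, max_s))
    cand <- warp_rigid(m_c, th, tsh[1], tsh[2])
    s <- ncc(cand, f_c, erode = er_c)
    if (s > best_ncc) { best_ncc <- s; best <- c(th, tsh[1] * sc, tsh[2] * sc) }
  }
  penalty <- function(p) {
    pen <- 0
    if (p[1] < theta_range[1]) pen <- pen + (theta_range[1] - p[1])^2
    if (p[1] > theta_range[2]) pen <- pen + (p[1] - theta_range[2])^2
    for (k in 2:3) {
      if (p[k] < shift_range[1]) pen <- pen + (shift_range[1] - p[k])^2
      if (p[k] > shift_range[2]) pen <- pen + (p[k] - shift_range[2])^2
    }
    pen
  }
  # refinement at half resolution (cheap), then a short full-resolution polish
  obj_c <- function(p) {
    -ncc(warp_rigid(m_c, p[1], p[2] / sc, p[3] / sc), f_c, erode = er_c) + penalty(p)
  }
  op <- stats::optim(best, obj_c, method = "Nelder-Mead",
                     control = list(maxit = 250, reltol = 1e-10,
                                    parscale = c(0.25, 1, 1)))
  obj_f <- function(p) {
    -ncc(warp_rigid(moving_s, p[1], p[2], p[3]), fixed_s, erode = er_f) + penalty(p)
  }
  op2 <- stats::optim(op$par, obj_f, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10,
                                     parscale = c(0.1, 0.4, 0.4)))
  p <- op2$par
  rigid_transform(p[1], p[2], p[3],
                  score = ncc(warp_rigid(moving, p[1], p[2], p[3]), fixed))
}

#' Fuse the B-scans of a stability interval into an HR estimate
#'
#' Warps every B-scan into the grid of the first frame (bilinear
#' interpolation) and averages per pixel over the frames that cover it.
#' The first frame contributes with the identity transform. Pixels covered
#' by no warped frame (impossible when the reference is included) would be
#' copied from the reference and show 0 in `coverage_map`.
#'
#' @param bscans list of grayscale matrices of equal size (the interval's
#'   frames, first = reference).
#' @param transforms `"estimate"` (run [register_rigid()] against the first
#'   frame), `"identity"`, or a list of [rigid_transform()] (first entry is
#'   ignored and replaced by identity).
#' @param reject_below_ncc optional NCC floor; estimated frames scoring
#'   below it are dropped from the average (`NA` disables, the default).
#' @param ... passed to [register_rigid()].
#' @return object of class `ioct_fused` with `lr_reference`, `hr_estimate`
#'   (float matrix), `n_fused`, `transforms`, `coverage_map` and `dropped`
#'   (0-based indices of rejected frames).
#' @export
fuse_interval <- function(bscans, transforms = "estimate",
                          reject_below_ncc = NA, ...) {
  if (length(bscans) == 0) ioct_stop("ioct_invalid_input", "no B-scans to fuse")
  dims <- dim(bscans[[1]])
  for (b in bscans) {
    if (!all(dim(b) == dims)) ioct_stop("ioct_shape_error", "B-scan size mismatch")
  }
  n <- length(bscans)
  if (identical(transforms, "identity")) {
    transforms <- replicate(n, rigid_transform(), simplify = FALSE)
  } else if (identical(transforms, "estimate")) {
    tl <- vector("list", n)
    tl[[1]] <- rigid_transform(score = 1)
    if (n > 1) {
      for (i in 2:n) tl[[i]] <- register_rigid(bscans[[i]], bscans[[1]], ...)
    }
    transforms <- tl
  } else if (length(transforms) != n) {
    ioct_stop("ioct_invalid_input", "need one transform per B-scan")
  }
  transforms[[1]] <- rigid_transform(transforms[[1]]$theta * 0, 0, 0,
                                     score = transforms[[1]]$score)
  dropped <- integer(0)
  acc <- matrix(0, dims[1], dims[2])
  cov <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(n)) {
    tf <- transforms[[i]]
    if (i > 1 && !is.na(reject_below_ncc) && !is.na(tf$score) &&
        tf$score < reject_below_ncc) {
      dropped <- c(dropped, i - 1L)
      next
    }
    wimg <- if (tf$theta == 0 && tf$tx == 0 && tf$ty == 0) bscans[[i]]
            else warp_rigid(bscans[[i]], tf$theta, tf$tx, tf$ty)
    ok <- is.finite(wimg)
    acc[ok] <- acc[ok] + wimg[ok]
    cov <- cov + ok
  }
  hr <- acc
  pos <- cov > 0
  hr[pos] <- acc[pos] / cov[pos]
  hr[!pos] <- bscans[[1]][!pos]
  structure(list(lr_reference = bscans[[1]], hr_estimate = hr,
                 n_fused = n, transforms = transforms,
                 coverage_map = cov, dropped = dropped),
            class = "ioct_fused")
}

#' @export
print.ioct_fused <- function(x, ...) {
  cat(sprintf("fused HR estimate: %d x %d px from %d frames (%d dropped), full coverage %.1f%%\n",
              nrow(x$hr_estimate), ncol(x$hr_estimate), x$n_fused,
              length(x$dropped),
              100 * mean(x$coverage_map == x$n_fused - length(x$dropped))))
  invisible(x)
}
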