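# Internal numeric and I/O helpers shared by all modules.
#
# Image convention used throughout the package:
#   * a grayscale image is a numeric matrix, rows = y (depth, downward),
#     cols = x (lateral, rightward), intensities on the 0..255 scale;
#   * an RGB image is an h x w x 3 array on the same scale;
#   * pixel coordinates are 0-based pixel centres, x right / y down, so the
#     matrix element img[r, c] is the pixel at (x = c - 1, y = r - 1);
#   * sub-pixel coordinates are allowed everywhere.

ioct_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ioct_error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# population (1/n) variance -- the convention of the SNR/ENL/CNR equations
pvar <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

is_image <- function(x) is.matrix(x) && is.numeric(x)

rgb_to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# --- sampling and rigid warping -------------------------------------------

#' Bilinear sampling at sub-pixel coordinates
#'
#' @param img grayscale image matrix.
#' @param x,y numeric vectors of 0-based pixel-centre coordinates.
#' @return numeric vector of samples; `NA` outside the image support.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  dx <- x - x0; dy <- y - y0
  inside <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1 &
    is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  x0i <- pmax(pmin(x0[inside], w - 1), 0)
  y0i <- pmax(pmin(y0[inside], h - 1), 0)
  x1i <- pmin(x0i + 1, w - 1)
  y1i <- pmin(y0i + 1, h - 1)
  dxi <- dx[inside]; dyi <- dy[inside]
  # linear index of (x, y) in column-major storage
  id <- function(yy, xx) xx * h + yy + 1
  v00 <- img[id(y0i, x0i)]
  v01 <- img[id(y0i, x1i)]
  v10 <- img[id(y1i, x0i)]
  v11 <- img[id(y1i, x1i)]
  out[inside] <- (1 - dyi) * ((1 - dxi) * v00 + dxi * v01) +
    dyi * ((1 - dxi) * v10 + dxi * v11)
  out
}

image_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

#' Apply a rigid transform to points
#'
#' The forward transform rotates by `theta` degrees counter-clockwise about
#' the image centre `centre` (in x-right/y-down coordinates a positive theta
#' appears clockwise on screen), then translates by `(tx, ty)` pixels.
#'
#' @param pts n x 2 matrix of (x, y) points.
#' @param theta rotation in degrees.
#' @param tx,ty translation in pixels.
#' @param centre length-2 centre of rotation.
#' @return n x 2 matrix of transformed points.
#' @keywords internal
rigid_apply <- function(pts, theta, tx, ty, centre) {
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  px <- pts[, 1] - centre[1]
  py <- pts[, 2] - centre[2]
  cbind(ca * px - sa * py + centre[1] + tx,
        sa * px + ca * py + centre[2] + ty)
}

#' Warp an image by a rigid transform (inverse mapping, bilinear)
#'
#' `warp_rigid(img, th, tx, ty)[p] = img[T^{-1}(p)]` where `T` is the forward
#' transform of [rigid_apply()]; i.e. the output shows `img` moved by `T`.
#'
#' @param img grayscale image matrix.
#' @param theta degrees; `tx`,`ty` pixels.
#' @param fill value for pixels mapping outside the source (`NA` default).
#' @return warped matrix, same size as `img`.
#' @keywords internal
warp_rigid <- function(img, theta, tx, ty, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  centre <- c((w - 1) / 2, (h - 1) / 2)
  g <- image_grid(h, w)
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  # inverse: undo translation, rotate by -theta about centre
  px <- g$x - centre[1] - tx
  py <- g$y - centre[2] - ty
  sx <- ca * px + sa * py + centre[1]
  sy <- -sa * px + ca * py + centre[2]
  out <- bilinear_sample(img, as.vector(sx), as.vector(sy))
  if (!is.na(fill)) out[is.na(out)] <- fill
  matrix(out, h, w)
}

# nearest-neighbour variant for label images
warp_rigid_nn <- function(img, theta, tx, ty, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  centre <- c((w - 1) / 2, (h - 1) / 2)
  g <- image_grid(h, w)
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  px <- g$x - centre[1] - tx
  py <- g$y - centre[2] - ty
  sx <- round(ca * px + sa * py + centre[1])
  sy <- round(-sa * px + ca * py + centre[2])
  inside <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  out <- matrix(fill, h, w)
  out[inside] <- img[sx[inside] * h + sy[inside] + 1]
  out
}

# --- separable Gaussian filtering (replicate borders) ----------------------

gauss_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# full-size separable convolution with replicated edges
conv_sep_replicate <- function(img, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  padc <- img[, c(rep(1, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * padc[, i:(i + w - 1), drop = FALSE]
  }
  padr <- out[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * padr[i:(i + h - 1), , drop = FALSE]
  }
  out2
}

# 'valid' separable convolution: output is (h-2r) x (w-2r)
conv_sep_valid <- function(img, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  wo <- w - 2 * r
  ho <- h - 2 * r
  stopifnot(wo >= 1, ho >= 1)
  out <- matrix(0, h, wo)
  for (i in seq_along(k)) {
    out <- out + k[i] * img[, i:(i + wo - 1), drop = FALSE]
  }
  out2 <- matrix(0, ho, wo)
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * out[i:(i + ho - 1), , drop = FALSE]
  }
  out2
}

gauss_smooth <- function(img, sigma_y, sigma_x = sigma_y) {
  out <- img
  if (sigma_x > 0) {
    kx <- gauss_kernel1d(sigma_x)
    r <- (length(kx) - 1) / 2
    w <- ncol(out)
    padc <- out[, c(rep(1, r), seq_len(w), rep(w, r)), drop = FALSE]
    acc <- matrix(0, nrow(out), w)
    for (i in seq_along(kx)) acc <- acc + kx[i] * padc[, i:(i + w - 1), drop = FALSE]
    out <- acc
  }
  if (sigma_y > 0) {
    ky <- gauss_kernel1d(sigma_y)
    r <- (length(ky) - 1) / 2
    h <- nrow(out)
    padr <- out[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
    acc <- matrix(0, h, ncol(out))
    for (i in seq_along(ky)) acc <- acc + ky[i] * padr[i:(i + h - 1), , drop = FALSE]
    out <- acc
  }
  out
}

# blur + 2x subsample, used by the optical-flow pyramid
pyr_down <- function(img) {
  s <- gauss_smooth(img, 1.0)
  s[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

# --- PNG I/O ----------------------------------------------------------------

#' Read a grayscale image from PNG
#'
#' @param path file path.
#' @return numeric matrix on the 0..255 scale (RGB input is converted via
#'   Rec.601 luminance).
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a * 255
}

#' Write a grayscale image to 8-bit PNG
#'
#' Intensities are clipped to 0..255 and rounded half-to-even before
#' quantization.
#'
#' @param img numeric matrix on the 0..255 scale.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(round(clip01(img)) / 255, path)
  invisible(path)
}

#' Read an RGB image from PNG
#' @param path file path.
#' @return h x w x 3 numeric array on the 0..255 scale.
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  a * 255
}

#' Write an RGB image to 8-bit PNG
#' @param img h x w x 3 array on the 0..255 scale.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(round(clip01(img)) / 255, path)
  invisible(path)
}

# integer label masks stored as 8-bit gray PNG, value = label
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 255)
}

write_mask_png <- function(mask, path) {
  stopifnot(max(mask) <= 255)
  png::writePNG(mask / 255, path)
  invisible(path)
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

json_read <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
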