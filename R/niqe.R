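# Natural Image Quality Evaluator (NIQE), fitted on a user-supplied corpus.
#
# An image is MSCN-normalized (local mean subtracted, local sd divided),
# per-patch statistical features are extracted — a symmetric generalized
# Gaussian (GGD) fit of the MSCN coefficients and asymmetric generalized
# Gaussian (AGGD) fits of the four orientation pairwise products — at two
# scales, and the model is the mean vector and covariance of the pooled
# features. The score of an image is the Mahalanobis-type distance between
# its feature statistics and the model under the pooled covariance; lower
# means more similar to the fitting corpus.

# precomputed r(alpha) lookup for GGD/AGGD shape estimation;
# grid recorded here for reproducibility: alpha in [0.2, 10] step 0.001
niqe_alpha_grid <- function() {
  env <- .ioct_cache
  if (is.null(env$alpha_grid)) {
    a <- seq(0.2, 10, by = 0.001)
    env$alpha_grid <- list(
      alpha = a,
      # GGD: r(a) = gamma(1/a) gamma(3/a) / gamma(2/a)^2  (inverse of rhat)
      r_gam = gamma(1 / a) * gamma(3 / a) / gamma(2 / a)^2)
  }
  env$alpha_grid
}

.ioct_cache <- new.env(parent = emptyenv())

# symmetric GGD moment-matching fit: returns (alpha, sigma^2)
ggd_fit <- function(x) {
  g <- niqe_alpha_grid()
  sigma_sq <- mean(x^2)
  E_abs <- mean(abs(x))
  rho <- sigma_sq / max(E_abs^2, 1e-12)
  idx <- which.min(abs(g$r_gam - rho))
  c(alpha = g$alpha[idx], sigma_sq = sigma_sq)
}

# asymmetric GGD fit: returns (alpha, mean eta, bl^2, br^2)
aggd_fit <- function(x) {
  g <- niqe_alpha_grid()
  xl <- x[x < 0]; xr <- x[x >= 0]
  bl <- sqrt(mean(xl^2))
  br <- sqrt(mean(xr^2))
  if (!is.finite(bl) || bl == 0) bl <- 1e-6
  if (!is.finite(br) || br == 0) br <- 1e-6
  gam <- bl / br
  E_abs <- mean(abs(x))
  rhat <- E_abs^2 / mean(x^2)
  Rhat <- rhat * (gam^3 + 1) * (gam + 1) / (gam^2 + 1)^2
  idx <- which.min(abs(1 / g$r_gam - Rhat))
  a <- g$alpha[idx]
  eta <- (br - bl) * gamma(2 / a) / gamma(1 / a)
  c(alpha = a, eta = eta, bl_sq = bl^2, br_sq = br^2)
}

# MSCN transform; returns list(mscn, sigma_map)
mscn_transform <- function(img, ksigma = 7 / 6, kradius = 3) {
  k <- gauss_kernel1d(ksigma, kradius)
  mu <- conv_sep_replicate(img, k)
  sigma <- sqrt(pmax(conv_sep_replicate(img * img, k) - mu^2, 0))
  list(mscn = (img - mu) / (sigma + 1), sigma_map = sigma)
}

# 18 features of one MSCN patch: GGD of coefficients + AGGD of the four
# pairwise products (horizontal, vertical, two diagonals)
patch_features <- function(p) {
  f <- ggd_fit(as.vector(p))
  h <- nrow(p); w <- ncol(p)
  prods <- list(
    p[, -w] * p[, -1],                       # horizontal
    p[-h, ] * p[-1, ],                       # vertical
    p[-h, -w] * p[-1, -1],                   # main diagonal
    p[-1, -w] * p[-h, -1])                   # anti-diagonal
  for (pr in prods) f <- c(f, aggd_fit(as.vector(pr)))
  unname(f)
}

# feature matrix of one image: rows = selected patches, 36 columns
# (18 per scale, two scales); sharpness selection keeps patches whose mean
# local sd exceeds `sharp_frac` of the maximum patch sharpness
niqe_image_features <- function(img, patch_size = 96, sharp_frac = 0.75) {
  h <- nrow(img); w <- ncol(img)
  if (min(h, w) < patch_size) {
    ioct_stop("ioct_invalid_input",
              "image (%d x %d) smaller than the %d px NIQE patch", h, w, patch_size)
  }
  ny <- floor(h / patch_size); nx <- floor(w / patch_size)
  m1 <- mscn_transform(img)
  img2 <- half_image(img[seq_len(ny * patch_size), seq_len(nx * patch_size),
                         drop = FALSE])
  m2 <- mscn_transform(img2)
  ps2 <- patch_size / 2
  sharp <- matrix(0, ny, nx)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    ys <- (iy - 1) * patch_size + seq_len(patch_size)
    xs <- (ix - 1) * patch_size + seq_len(patch_size)
    sharp[iy, ix] <- mean(m1$sigma_map[ys, xs])
  }
  keep <- sharp >= sharp_frac * max(sharp)
  feats <- NULL
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (!keep[iy, ix]) next
    ys <- (iy - 1) * patch_size + seq_len(patch_size)
    xs <- (ix - 1) * patch_size + seq_len(patch_size)
    f1 <- patch_features(m1$mscn[ys, xs])
    ys2 <- (iy - 1) * ps2 + seq_len(ps2)
    xs2 <- (ix - 1) * ps2 + seq_len(ps2)
    f2 <- patch_features(m2$mscn[ys2, xs2])
    feats <- rbind(feats, c(f1, f2))
  }
  feats
}

#' Fit a multivariate Gaussian to a feature matrix
#'
#' The estimation core of [niqe_fit()], exposed so the fit can be checked
#' directly on synthetic feature draws.
#'
#' @param features numeric matrix, rows = observations.
#' @return list with `mu` (column means) and `cov` (sample covariance).
#' @export
niqe_fit_features <- function(features) {
  list(mu = colMeans(features), cov = stats::cov(features))
}

#' Fit a NIQE model on a corpus of images
#'
#' @param corpus list of >= 2 grayscale matrices, each at least
#'   `patch_size` pixels in both dimensions.
#' @param patch_size NIQE patch side length in pixels.
#' @param sharp_frac sharpness-selection fraction: patches whose mean local
#'   sd is below this fraction of the sharpest patch are discarded.
#' @return An object of class `niqe_model`: `mu`, `cov`, `patch_size`,
#'   `n_images`, `n_patches`, `feature_dim`.
#' @export
niqe_fit <- function(corpus, patch_size = 96, sharp_frac = 0.75) {
  if (length(corpus) < 2) {
    ioct_stop("ioct_insufficient_corpus",
              "NIQE fitting needs at least 2 images, got %d", length(corpus))
  }
  feats <- do.call(rbind, lapply(corpus, niqe_image_features,
                                 patch_size = patch_size,
                                 sharp_frac = sharp_frac))
  fit <- niqe_fit_features(feats)
  structure(list(mu = fit$mu, cov = fit$cov, patch_size = patch_size,
                 sharp_frac = sharp_frac,
                 n_images = length(corpus), n_patches = nrow(feats),
                 feature_dim = ncol(feats)), class = "niqe_model")
}

#' @export
print.niqe_model <- function(x, ...) {
  cat(sprintf("NIQE model: %d features from %d patches of %d images (patch %d px)\n",
              x$feature_dim, x$n_patches, x$n_images, x$patch_size))
  invisible(x)
}

#' Score an image against a NIQE model
#'
#' Mahalanobis-type distance `sqrt(d' ((C1 + C2)/2)^-1 d)` between the
#' model's feature mean and the image's, under the pooled covariance.
#' Lower is better (closer to the fitting corpus). A singular pooled
#' covariance is ridge-regularized (1e-6 on the diagonal) with a warning.
#'
#' @param image grayscale matrix, at least `model$patch_size` px per side.
#' @param model a [niqe_fit()] model.
#' @return non-negative NIQE score.
#' @export
niqe_score <- function(image, model) {
  feats <- niqe_image_features(image, patch_size = model$patch_size,
                               sharp_frac = model$sharp_frac)
  mu2 <- colMeans(feats)
  cov2 <- if (nrow(feats) > 1) stats::cov(feats) else matrix(0, ncol(feats), ncol(feats))
  pooled <- (model$cov + cov2) / 2
  d <- model$mu - mu2
  sol <- tryCatch(solve(pooled, d), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular pooled covariance in NIQE score; ridge-regularizing")
    pooled <- pooled + diag(1e-6, nrow(pooled))
    sol <- solve(pooled, d)
  }
  val <- sum(d * sol)
  sqrt(max(val, 0))
}

#' Serialize / load a NIQE model as JSON
#' @param model `niqe_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_niqe_model <- function(model, path) {
  json_write(unclass(model), path)
}

#' @rdname write_niqe_model
#' @export
read_niqe_model <- function(path) {
  x <- json_read(path)
  x$mu <- as.numeric(x$mu)
  x$cov <- matrix(unlist(x$cov), nrow = x$feature_dim)
  structure(x, class = "niqe_model")
}
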