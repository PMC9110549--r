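# Full-reference and no-reference image-quality metrics.

test_that("PSNR matches hand values, the brute-force oracle, and Inf at zero error", {
  a <- matrix(runif(32 * 32, 0, 255), 32)
  expect_identical(compute_psnr(a, a), Inf)
  expect_equal(compute_psnr(matrix(c(0, 0), 1), matrix(c(0, 255), 1)),
               10 * log10(255^2 / 32512.5))
  expect_error(compute_psnr(a, matrix(0, 3, 3)), class = "ioct_shape_error")
  set.seed(31)
  for (i in 1:100) {
    x <- matrix(runif(24 * 24, 0, 255), 24)
    y <- matrix(runif(24 * 24, 0, 255), 24)
    expect_equal(compute_psnr(x, y), oracle_psnr(x, y), tolerance = 1e-12)
  }
})

test_that("PSNR strictly decreases along a noise sweep", {
  set.seed(32)
  ref <- make_bscan_phantom(phantom_spec(width = 64, height = 64,
                                         speckle_looks = Inf))$image
  ps <- sapply(c(5, 15, 40), function(s) {
    compute_psnr(ioctfuse:::clip01(ref + matrix(rnorm(64^2, 0, s), 64)), ref)
  })
  expect_true(all(diff(ps) < 0))
})

test_that("SSIM is 1 for identical images, symmetric, bounded, and matches an
           independent windowed implementation", {
  set.seed(33)
  a <- matrix(runif(48 * 48, 0, 255), 48)
  b <- ioctfuse:::clip01(a + matrix(rnorm(48^2, 0, 25), 48))
  expect_equal(compute_ssim(a, a), 1, tolerance = 1e-9)
  expect_equal(compute_ssim(a, b), compute_ssim(b, a), tolerance = 1e-12)
  expect_error(compute_ssim(matrix(0, 8, 8), matrix(0, 8, 8)),
               class = "ioct_invalid_input")
  for (i in 1:10) {
    x <- matrix(runif(32 * 32, 0, 255), 32)
    y <- ioctfuse:::clip01(x + matrix(rnorm(32^2, 0, runif(1, 5, 60)), 32))
    s <- compute_ssim(x, y)
    expect_gte(s, -1); expect_lte(s, 1)
    expect_equal(s, oracle_ssim(x, y), tolerance = 1e-6)
  }
})

test_that("SSIM decreases along a noise sweep", {
  set.seed(34)
  ref <- make_bscan_phantom(phantom_spec(width = 64, height = 64,
                                         speckle_looks = Inf))$image
  ss <- sapply(c(5, 15, 40), function(s) {
    compute_ssim(ioctfuse:::clip01(ref + matrix(rnorm(64^2, 0, s), 64)), ref)
  })
  expect_true(all(diff(ss) < 0))
})

test_that("GCF is zero for constants and matches the direct implementation", {
  expect_equal(compute_gcf(matrix(77, 40, 40)), 0)
  expect_error(compute_gcf(matrix(numeric(0), 0, 0)),
               class = "ioct_invalid_input")
  cb <- outer(1:64, 1:64, function(i, j) ((i + j) %% 2) * 255)
  expect_equal(compute_gcf(cb), oracle_gcf(cb), tolerance = 1e-9)
  set.seed(35)
  for (i in 1:5) {
    x <- matrix(runif(40 * 56, 0, 255), 40)   # non-square, odd level sizes
    expect_equal(compute_gcf(x), oracle_gcf(x), tolerance = 1e-9)
  }
})

test_that("GCF increases under a linear contrast stretch", {
  ph <- make_bscan_phantom(phantom_spec(speckle_looks = 4, rng_seed = 6))$image
  stretched <- ioctfuse:::clip01((ph - mean(ph)) * 1.5 + mean(ph))
  expect_gt(compute_gcf(stretched), compute_gcf(ph))
})

test_that("GCF is invariant to whole-superpixel translations at the coarsest scales", {
  set.seed(36)
  base <- matrix(runif(96 * 96, 0, 255), 96)
  shifted <- base[c(33:96, 1:32), ]        # translation by 32 = whole
  # superpixels at levels 1..6; coarser levels see a cyclic permutation
  g1 <- compute_gcf(base, n_levels = 5)
  g2 <- compute_gcf(shifted, n_levels = 5)
  expect_equal(g1, g2, tolerance = 0.02 * abs(g1))
})

test_that("NIQE model fitting recovers known Gaussian feature statistics", {
  set.seed(37)
  mu <- runif(6, -1, 2)
  A <- matrix(rnorm(36), 6)
  Sigma <- crossprod(A) + diag(0.5, 6)
  n <- 5000
  X <- matrix(rnorm(n * 6), n) %*% chol(Sigma)
  X <- sweep(X, 2, mu, `+`)
  fit <- niqe_fit_features(X)
  # sampling error of the mean is ~ sqrt(diag(Sigma)/n) per coordinate
  expect_lt(max(abs(fit$mu - mu)), 4 * sqrt(max(diag(Sigma)) / n))
  expect_lt(max(abs(fit$cov - Sigma)) / max(abs(Sigma)), 0.05)
})

test_that("NIQE fitting demands a corpus and duplicates average to themselves", {
  img <- make_bscan_phantom(phantom_spec(speckle_looks = 16, rng_seed = 1))$image
  expect_error(niqe_fit(list(img)), class = "ioct_insufficient_corpus")
  m2 <- niqe_fit(list(img, img))
  f1 <- colMeans(ioctfuse:::niqe_image_features(img, 96, 0.75))
  expect_equal(unname(m2$mu), unname(f1), tolerance = 1e-12)
})

test_that("NIQE scores are non-negative, deterministic, and rank noise above corpus", {
  corpus <- lapply(1:4, function(s) {
    make_bscan_phantom(phantom_spec(speckle_looks = 16, rng_seed = s))$image
  })
  model <- suppressWarnings(niqe_fit(corpus))
  s_clean <- suppressWarnings(niqe_score(corpus[[1]], model))
  noisy <- ioctfuse:::clip01(corpus[[1]] +
    ioctfuse:::with_seed(9, matrix(rnorm(length(corpus[[1]]), 0, 30),
                                   nrow(corpus[[1]]))))
  s_noisy <- suppressWarnings(niqe_score(noisy, model))
  expect_gte(s_clean, 0)
  expect_lt(s_clean, s_noisy)
  model2 <- suppressWarnings(niqe_fit(corpus))
  expect_equal(suppressWarnings(niqe_score(corpus[[2]], model2)),
               suppressWarnings(niqe_score(corpus[[2]], model)),
               tolerance = 1e-9)
})

test_that("NIQE models round-trip through JSON", {
  corpus <- lapply(1:2, function(s) {
    make_bscan_phantom(phantom_spec(speckle_looks = 16, rng_seed = s))$image
  })
  model <- niqe_fit(corpus)
  p <- tempfile(fileext = ".json")
  write_niqe_model(model, p)
  m2 <- read_niqe_model(p)
  expect_equal(m2$mu, unname(model$mu), tolerance = 1e-12)
  expect_equal(m2$cov, unname(model$cov), tolerance = 1e-12, ignore_attr = TRUE)
  img <- corpus[[1]]
  expect_equal(suppressWarnings(niqe_score(img, m2)),
               suppressWarnings(niqe_score(img, model)), tolerance = 1e-9)
})

test_that("metric reports aggregate per-image values faithfully", {
  set.seed(38)
  refs <- lapply(1:3, function(k) matrix(runif(32 * 32, 0, 255), 32))
  imgs <- lapply(refs, function(r) ioctfuse:::clip01(r + matrix(rnorm(1024, 0, 10), 32)))
  names(imgs) <- names(refs) <- c("a", "b", "c")
  rep <- metric_report(imgs, refs)
  agg <- attr(rep, "aggregate")
  expect_equal(unname(agg["mean", "psnr"]), mean(rep$psnr))
  expect_equal(unname(agg["sd", "ssim"]), sd(rep$ssim))
  expect_true(all(is.na(rep$niqe)))   # explicitly null, never dropped
})
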