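# ROI placement, SNR/ENL/CNR computation and quality gating.

test_that("heuristic segmentation agrees with the generator mask", {
  ph <- make_bscan_phantom(phantom_spec(speckle_looks = Inf))
  m <- segment_layers_heuristic(ph$image)
  expect_gte(mean(m == ph$mask), 0.95)
})

test_that("heuristic segmentation fails cleanly on empty scenes", {
  expect_error(segment_layers_heuristic(matrix(0, 60, 60)),
               class = "ioct_segmentation_failed")
})

test_that("the top surface is recovered within 3 px RMS under L = 4 speckle", {
  rms <- sapply(1:3, function(s) {
    ph <- make_bscan_phantom(phantom_spec(speckle_looks = 4, rng_seed = s))
    m <- segment_layers_heuristic(ph$image)
    sqrt(mean((attr(m, "top_curve") - ph$boundaries[1, ])^2))
  })
  expect_true(all(rms < 3))
})

test_that("all five ROIs satisfy the containment constraints", {
  ph <- make_bscan_phantom(phantom_spec(rng_seed = 2))
  K <- ph$spec$n_layers
  for (seed in 1:2) {
    rs <- place_rois(ph$mask, rng_seed = seed)
    expect_true(all(roi_pixels(ph$mask, rs$background) == 0))
    expect_equal(sapply(rs$homogeneous, `[[`, "target_label"), c(2, K))
    expect_equal(sapply(rs$contrast, `[[`, "target_label"), c(1, K))
    for (r in c(rs$homogeneous, rs$contrast)) {
      expect_true(all(roi_pixels(ph$mask, r) == r$target_label))
      expect_true(r$x >= 0 && r$y >= 0 &&
                  r$x + r$w <= ncol(ph$mask) && r$y + r$h <= nrow(ph$mask))
    }
  }
  r1 <- place_rois(ph$mask, rng_seed = 1)
  r2 <- place_rois(ph$mask, rng_seed = 2)
  expect_false(identical(c(r1$background$x, r1$background$y),
                         c(r2$background$x, r2$background$y)))
  expect_identical(place_rois(ph$mask, rng_seed = 1)$background, r1$background)
})

test_that("impossible placements raise a named placement error", {
  mask <- matrix(1L, 60, 60)
  mask[1:3, 1:3] <- 0L            # background smaller than its ROI
  mask[40:60, ] <- 2L
  err <- tryCatch(place_rois(mask), error = function(e) e)
  expect_s3_class(err, "ioct_placement_failed")
  expect_match(conditionMessage(err), "background")
})

test_that("SNR matches its hand-computed and brute-force values", {
  # peak 10, background alternating {0,2}: 10 log10(100 / 1) = 20 dB
  img <- matrix(c(0, 2, 0, 2, 10, 0), 2, 3)
  roi <- list(x = 0, y = 0, w = 2, h = 2)
  expect_equal(compute_snr(img, roi), 20)
  expect_error(compute_snr(matrix(5, 4, 4), list(x = 0, y = 0, w = 2, h = 2)),
               class = "ioct_degenerate_background")
  set.seed(21)
  for (i in 1:100) {
    im <- matrix(runif(64 * 64, 0, 255), 64)
    roi <- random_roi(64, 64, sample(4:16, 1), sample(4:16, 1))
    expect_equal(compute_snr(im, roi),
                 oracle_snr(im, roi_pixels(im, roi)), tolerance = 1e-12)
  }
})

test_that("ENL matches its hand-computed and brute-force values", {
  # regions with (mu 4, sd 2) and (mu 6, sd 3): both ratios are 4
  r1 <- matrix(c(2, 6, 2, 6), 2)   # mean 4, pvar 4
  r2 <- matrix(c(3, 9, 3, 9), 2)   # mean 6, pvar 9
  img <- cbind(r1, r2)
  rois <- list(list(x = 0, y = 0, w = 2, h = 2), list(x = 2, y = 0, w = 2, h = 2))
  expect_equal(compute_enl(img, rois), 4)
  expect_error(compute_enl(matrix(5, 4, 4), list(list(x = 0, y = 0, w = 2, h = 2))),
               class = "ioct_degenerate_region")
  set.seed(22)
  for (i in 1:100) {
    im <- matrix(runif(64 * 64, 1, 255), 64)
    rois <- list(random_roi(64, 64, 8, 8), random_roi(64, 64, 12, 6))
    expect_equal(compute_enl(im, rois),
                 oracle_enl(lapply(rois, roi_pixels, image = im)),
                 tolerance = 1e-12)
  }
})

test_that("CNR matches its hand-computed and brute-force values", {
  # single region mu 3 sd 1 vs background mu 1 sd 1: 2 / sqrt(2)
  reg <- matrix(c(2, 4, 2, 4), 2)
  bg <- matrix(c(0, 2, 0, 2), 2)
  img <- cbind(reg, bg)
  r_roi <- list(x = 0, y = 0, w = 2, h = 2)
  b_roi <- list(x = 2, y = 0, w = 2, h = 2)
  expect_equal(compute_cnr(img, list(r_roi), b_roi), 2 / sqrt(2),
               tolerance = 1e-12)
  # equal means give zero CNR regardless of variance
  set.seed(5)
  u <- matrix(sample(c(1, 3), 64, TRUE), 8)
  expect_equal(compute_cnr(cbind(u, u), list(list(x = 0, y = 0, w = 8, h = 8)),
                           list(x = 8, y = 0, w = 8, h = 8)), 0)
  set.seed(23)
  for (i in 1:100) {
    im <- matrix(runif(64 * 64, 0, 255), 64)
    rois <- lapply(1:4, function(k) random_roi(64, 64, 10, 6))
    bg <- random_roi(64, 64, 12, 12)
    expect_equal(compute_cnr(im, rois, bg),
                 oracle_cnr(lapply(rois, roi_pixels, image = im),
                            roi_pixels(im, bg)),
                 tolerance = 1e-12)
  }
})

test_that("the quality gate applies inclusive thresholds", {
  expect_true(gate_quality(71, 3.5, 12)$accepted)
  expect_false(gate_quality(69.9, 5, 50)$accepted)
  expect_true(gate_quality(70, 3, 10)$accepted)     # boundary inclusive
  expect_false(gate_quality(70, 2.999, 10)$accepted)
  expect_error(gate_quality(NaN, 3, 10), class = "ioct_invalid_metric")
  custom <- gate_quality(40, 2, 5, thresholds = c(snr = 35, cnr = 1, enl = 4))
  expect_true(custom$accepted)
})

test_that("SNR is non-increasing in added background noise", {
  base <- make_bscan_phantom(phantom_spec(speckle_looks = Inf))$image
  roi <- list(x = 4, y = 4, w = 32, h = 32)
  snrs <- sapply(c(0.5, 1, 2, 4, 8), function(s) {
    noisy <- base + ioctfuse:::with_seed(42,
      matrix(stats::rnorm(length(base), 0, s), nrow(base)))
    compute_snr(noisy, roi)
  })
  expect_true(all(diff(snrs) < 0))
})

test_that("ROI ENL of an L-look phantom recovers L through the mask pipeline", {
  # links the gate to the speckle physics using generator masks; moderate
  # reflectivities keep 8-bit clipping (which inflates ENL) negligible
  for (L in c(4, 16)) {
    enls <- sapply(1:10, function(s) {
      ph <- make_bscan_phantom(
        phantom_spec(speckle_looks = L, lateral_texture_amp = 0,
                     layer_reflectivities = c(40, 80, 60, 70, 90),
                     rng_seed = s))
      compute_enl(ph$image, place_rois(ph$mask, rng_seed = s)$homogeneous)
    })
    expect_gt(mean(enls), 0.8 * L)
    expect_lt(mean(enls), 1.25 * L)
  }
})

test_that("a planted pass/fail image set is gated exactly", {
  pg <- planted_gate_images(k_pass = 3, m_fail = 2)
  verdicts <- c(
    sapply(pg$pass, function(ph) {
      assess_quality(ph$image, mask = ph$mask, rng_seed = 7)$accepted
    }),
    sapply(pg$fail, function(ph) {
      assess_quality(ph$image, mask = ph$mask, rng_seed = 7)$accepted
    }))
  expect_equal(sum(verdicts), 3)
  expect_equal(unname(verdicts), c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
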