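# Scan-marker detection, arrow localization, Lucas-Kanade feature tracking
# and stationary-interval extraction.

test_that("scan rectangle is detected within 1 px of the manifest", {
  tv <- tracking_video()
  truth <- tv$manifest$frames[[1]]$rect_corners
  got <- detect_scan_rectangle(tv$frames[[1]])
  expect_lt(max(abs(got - truth)), 1)
})

test_that("rectangle detection survives a bright distractor line", {
  tv <- tracking_video()
  fr <- tv$frames[[1]]
  fr[118:119, 8:300, ] <- 255  # horizontal distractor through the scene
  got <- detect_scan_rectangle(fr)
  expect_lt(max(abs(got - tv$manifest$frames[[1]]$rect_corners)), 1)
})

test_that("rectangle detection is invariant to global brightness scaling", {
  tv <- tracking_video()
  truth <- tv$manifest$frames[[1]]$rect_corners
  for (s in c(0.8, 1.0, 1.2)) {
    got <- detect_scan_rectangle(pmin(pmax(tv$frames[[1]] * s, 0), 255))
    expect_lt(max(abs(got - truth)), 1)
  }
})

test_that("structureless frames raise a no-scan-region error", {
  expect_error(detect_scan_rectangle(array(0, c(80, 100, 3))),
               class = "ioct_no_scan_region")
  expect_error(detect_scan_rectangle(array(128, c(80, 100, 3))),
               class = "ioct_no_scan_region")
})

test_that("arrow points land within 1 px of the manifest centroids", {
  tv <- tracking_video()
  rc <- detect_scan_rectangle(tv$frames[[1]])
  ar <- detect_arrow_points(tv$frames[[1]], rc)
  m1 <- tv$manifest$frames[[1]]
  expect_lt(max(abs(ar$cyan_point - m1$cyan_point)), 1)
  expect_lt(max(abs(ar$magenta_point - m1$magenta_point)), 1)
  # and within 2 px under +/-20% brightness scaling
  for (s in c(0.8, 1.2)) {
    fs <- pmin(pmax(tv$frames[[1]] * s, 0), 255)
    ars <- detect_arrow_points(fs, detect_scan_rectangle(fs))
    expect_lt(max(abs(ars$cyan_point - m1$cyan_point)), 2)
    expect_lt(max(abs(ars$magenta_point - m1$magenta_point)), 2)
  }
})

test_that("a missing arrow colour is reported by name", {
  tv <- tracking_video()
  fr <- tv$frames[[1]]
  # repaint cyan pixels gray so only magenta remains
  cy <- fr[, , 1] < 100 & fr[, , 2] > 200 & fr[, , 3] > 200
  for (ch in 1:3) { p <- fr[, , ch]; p[cy] <- 120; fr[, , ch] <- p }
  err <- tryCatch(detect_arrow_points(fr, detect_scan_rectangle(fr)),
                  error = function(e) e)
  expect_s3_class(err, "ioct_arrow_not_found")
  expect_match(conditionMessage(err), "cyan")
})

test_that("a static feature tracks with negligible drift", {
  tv <- tracking_video()
  frames <- rep(tv$frames[1], 20)
  p0 <- tv$manifest$frames[[1]]$feature_point
  tr <- track_feature(frames, p0)
  expect_true(all(tr$status))
  expect_lt(max(sqrt(rowSums((tr$points - rep(p0, each = 20))^2))), 0.1)
})

test_that("a drifting feature is tracked within 0.5 px of the manifest", {
  tv <- tracking_video()
  truth <- t(sapply(tv$manifest$frames, function(f) f$feature_point))
  tr <- track_feature(tv$frames, truth[1, ])
  expect_true(all(tr$status))
  expect_lt(max(sqrt(rowSums((tr$points - truth)^2))), 0.5)
})

test_that("an occluded feature is declared lost and stays lost", {
  tv <- tracking_video()
  frames <- tv$frames
  p0 <- tv$manifest$frames[[1]]$feature_point
  for (t in 10:20) {
    fr <- frames[[t]]
    ys <- pmax(1, round(p0[2]) - 14):min(dim(fr)[1], round(p0[2]) + 16)
    xs <- pmax(1, round(p0[1]) - 14):min(dim(fr)[2], round(p0[1]) + 16)
    fr[ys, xs, ] <- 150
    frames[[t]] <- fr
  }
  tr <- track_feature(frames, p0)
  expect_true(any(!tr$status))
  lost_at <- which(!tr$status)[1]
  expect_gte(lost_at, 10)
  expect_true(all(!tr$status[lost_at:20]))
})

test_that("tracking an empty frame sequence fails cleanly", {
  expect_error(track_feature(list(), c(0, 0)), class = "ioct_invalid_input")
  expect_error(track_feature(list(matrix(0, 5, 5)), c(50, 50)),
               class = "ioct_invalid_input")
})

test_that("stability intervals follow the scripted stationary segments", {
  tv <- tracking_video()
  track <- build_scan_track(tv$frames, tv$manifest$frames[[1]]$feature_point)
  iv <- find_stable_intervals(track)
  expect_length(iv, 1)
  expect_equal(c(iv[[1]]$start, iv[[1]]$end), tv$script$stationary_segments[[1]])
  expect_equal(iv[[1]]$n_frames, 12)
  expect_lte(iv[[1]]$max_scan_deviation, 3)
  # a synthetic track: 10 stationary frames then 5 after a jump, min_len 8
  n <- 20
  pts <- matrix(5, n, 2)
  pts[11:15, ] <- 60
  pts[16:20, ] <- matrix(seq(70, 110, length.out = 5) + rep(c(0, 5), each = 5), 5, 2)
  syn <- data.frame(frame = 0:(n - 1),
                    cyan_x = pts[, 1], cyan_y = pts[, 2],
                    mag_x = pts[, 1] + 30, mag_y = pts[, 2],
                    scan_valid = TRUE,
                    feat_x = pts[, 1] + 10, feat_y = pts[, 2] + 40,
                    feat_ok = TRUE)
  iv2 <- find_stable_intervals(syn, min_len = 8)
  expect_length(iv2, 1)
  expect_equal(c(iv2[[1]]$start, iv2[[1]]$end), c(0, 9))
})

test_that("stable-interval edge cases: static track, empty track, strict rule", {
  tr <- data.frame(frame = 0:19, cyan_x = 1, cyan_y = 1, mag_x = 9, mag_y = 1,
                   scan_valid = TRUE, feat_x = 5, feat_y = 5, feat_ok = TRUE)
  iv <- find_stable_intervals(tr, min_len = 8)
  expect_length(iv, 1)
  expect_equal(c(iv[[1]]$start, iv[[1]]$end), c(0, 19))
  expect_length(find_stable_intervals(tr[0, ], min_len = 8), 0)
  # strictly-greater reading: 8 frames no longer qualify
  tr8 <- tr[1:8, ]
  expect_length(find_stable_intervals(tr8, min_len = 8), 1)
  expect_length(find_stable_intervals(tr8, min_len = 8, strict_gt = TRUE), 0)
  # invalid frames break intervals: frame 9 invalid splits [0,19] in two
  tr$scan_valid[10] <- FALSE
  iv3 <- find_stable_intervals(tr, min_len = 8)
  expect_length(iv3, 2)
  expect_equal(c(iv3[[1]]$start, iv3[[1]]$end), c(0, 8))
  expect_equal(c(iv3[[2]]$start, iv3[[2]]$end), c(10, 19))
})

test_that("returned intervals are disjoint, sorted and respect their bounds", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    base <- cumsum(sample(c(0, 0, 0, 0, 3), n, replace = TRUE))
    pts <- cbind(base + runif(n, -0.3, 0.3), base + runif(n, -0.3, 0.3))
    tr <- data.frame(frame = 0:(n - 1),
                     cyan_x = pts[, 1], cyan_y = pts[, 2],
                     mag_x = pts[, 1] + 20, mag_y = pts[, 2],
                     scan_valid = TRUE,
                     feat_x = pts[, 1] - 15, feat_y = pts[, 2] + 10,
                     feat_ok = TRUE)
    iv <- find_stable_intervals(tr, min_len = 4)
    if (length(iv) > 1) {
      starts <- sapply(iv, `[[`, "start")
      ends <- sapply(iv, `[[`, "end")
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1] > ends[-length(ends)]))
    }
    for (v in iv) {
      expect_gte(v$n_frames, 4)
      idx <- (v$start:v$end) + 1
      for (cols in list(c("cyan_x", "cyan_y"), c("mag_x", "mag_y"),
                        c("feat_x", "feat_y"))) {
        p <- as.matrix(tr[idx, cols])
        step <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
        tot <- sqrt(rowSums((p - rep(p[1, ], each = nrow(p)))^2))
        expect_true(all(step <= 1.5 + 1e-9))
        expect_true(all(tot <= 3 + 1e-9))
      }
    }
  }
})

test_that("tracks and intervals round-trip through JSON", {
  tv <- tracking_video()
  track <- build_scan_track(tv$frames[1:6], tv$manifest$frames[[1]]$feature_point)
  p <- tempfile(fileext = ".json")
  write_track(track, p)
  tr2 <- read_track(p)
  expect_equal(as.data.frame(track), as.data.frame(tr2), tolerance = 1e-12)
  iv <- list(list(start = 0L, end = 9L, n_frames = 10L,
                  max_scan_deviation = 0.5, max_feature_deviation = 0.25))
  p2 <- tempfile(fileext = ".json")
  write_intervals(iv, p2)
  expect_equal(read_intervals(p2), iv, tolerance = 1e-12)
})
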