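# Scan-marker detection and retinal-feature tracking on microscope views.
#
# The iOCT scan position is shown as a bright rectangle on the microscope
# view; its position plus a tracked retinal feature decide which frame runs
# are stationary enough for B-scan fusion.

#' Options controlling scan-marker detection and feature tracking
#'
#' @param thresh_frac binary threshold as a fraction of the frame's maximum
#'   grayscale intensity.
#' @param hough_theta_deg half-width (degrees) of the angle bands around
#'   vertical and horizontal scanned by the Hough transform.
#' @param hough_min_votes minimum accumulator votes for a candidate line.
#' @param min_side minimum rectangle side length in pixels.
#' @param cyan_hue,magenta_hue hue ranges in degrees (0-360) of the arrow
#'   glyph colours; `sat_min`/`val_min` are minimum HSV saturation and value
#'   (0-1 scale).
#' @param arrow_margin dilation margin (px) of the rectangle interior within
#'   which arrow blobs are accepted.
#' @param lk_levels,lk_window,lk_max_iter,lk_eps pyramidal Lucas-Kanade
#'   settings: pyramid levels, odd window size, iteration cap, convergence
#'   step in pixels.
#' @param lk_err_max mean absolute window residual (intensity units) above
#'   which a track is declared lost.
#' @return list of options.
#' @export
tracking_options <- function(thresh_frac = 0.9,
                             hough_theta_deg = 8, hough_min_votes = 15,
                             min_side = 20,
                             cyan_hue = c(170, 210), magenta_hue = c(280, 340),
                             sat_min = 0.4, val_min = 0.4,
                             arrow_margin = 2,
                             lk_levels = 3, lk_window = 21,
                             lk_max_iter = 30, lk_eps = 0.01,
                             lk_err_max = 15) {
  list(thresh_frac = thresh_frac, hough_theta_deg = hough_theta_deg,
       hough_min_votes = hough_min_votes, min_side = min_side,
       cyan_hue = cyan_hue, magenta_hue = magenta_hue,
       sat_min = sat_min, val_min = val_min, arrow_margin = arrow_margin,
       lk_levels = lk_levels, lk_window = lk_window,
       lk_max_iter = lk_max_iter, lk_eps = lk_eps, lk_err_max = lk_err_max)
}

# Hough transform of edge points over an angle band; returns peak lines
# (theta radians, rho px, votes) after 1D non-maximum suppression in rho
hough_lines <- function(ex, ey, thetas, min_votes, rho_merge = 3) {
  lines <- list()
  for (th in thetas) {
    rho <- round(ex * cos(th) + ey * sin(th))
    tb <- table(rho)
    keep <- tb >= min_votes
    if (!any(keep)) next
    for (i in which(keep)) {
      lines[[length(lines) + 1]] <- c(theta = th,
                                      rho = as.numeric(names(tb)[i]),
                                      votes = as.numeric(tb[i]))
    }
  }
  if (!length(lines)) return(NULL)
  m <- do.call(rbind, lines)
  m <- m[order(-m[, "votes"]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(m))) {
    if (nrow(kept) == 0 ||
        all(abs(kept[, 2] - m[i, "rho"]) > rho_merge |
            abs(kept[, 1] - m[i, "theta"]) > 6 * pi / 180)) {
      kept <- rbind(kept, m[i, ])
    }
  }
  colnames(kept) <- c("theta", "rho", "votes")
  kept
}

# refine a near-vertical (orient="v") or near-horizontal line by total least
# squares over bright pixels within 2 px of the Hough line
refine_line <- function(ex, ey, theta, rho, orient) {
  d <- abs(ex * cos(theta) + ey * sin(theta) - rho)
  sel <- d <= 2
  if (sum(sel) < 5) return(c(theta, rho))
  x <- ex[sel]; y <- ey[sel]
  if (orient == "v") {
    fit <- stats::lm.fit(cbind(1, y), x)  # x = a + b*y
    b <- fit$coefficients[2]; a <- fit$coefficients[1]
    th <- atan2(-b, 1)                     # x*cos + y*sin = rho form
    c(th, a * cos(th))
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)  # y = a + b*x
    b <- fit$coefficients[2]; a <- fit$coefficients[1]
    th <- pi / 2 - atan(b)
    c(th, a * sin(th))
  }
}

line_intersect <- function(l1, l2) {
  A <- rbind(c(cos(l1[1]), sin(l1[1])), c(cos(l2[1]), sin(l2[1])))
  if (abs(det(A)) < 1e-9) return(c(NA, NA))
  as.vector(solve(A, c(l1[2], l2[2])))
}

#' Detect the iOCT scan rectangle in a microscope view
#'
#' Pipeline: grayscale conversion, binary thresholding at
#' `thresh_frac * max`, boundary (edge) extraction, Hough transform over
#' near-vertical and near-horizontal angle bands, and scoring of every
#' candidate quadrilateral formed by a pair of vertical and a pair of
#' horizontal lines by the fraction of its perimeter lying on
#' thresholded-bright pixels (near-complete coverage ties broken by larger
#' area, which rejects bright distractor lines crossing the marker). Chosen
#' lines are refined to sub-pixel by least squares on the thresholded
#' pixels before intersecting into corners.
#'
#' @param scene_frame RGB array (h x w x 3, 0..255).
#' @param opts [tracking_options()].
#' @return 4 x 2 matrix of (x, y) corners, clockwise from top-left, 0-based
#'   pixel coordinates.
#' @export
detect_scan_rectangle <- function(scene_frame, opts = tracking_options()) {
  if (length(dim(scene_frame)) != 3) {
    ioct_stop("ioct_invalid_input", "scene_frame must be an RGB array")
  }
  gray <- rgb_to_gray(scene_frame)
  mx <- max(gray)
  if (mx <= 0) ioct_stop("ioct_no_scan_region", "frame is black")
  bw <- gray >= opts$thresh_frac * mx
  if (sum(bw) < 4 * opts$min_side) {
    ioct_stop("ioct_no_scan_region", "too few bright pixels for a scan marker")
  }
  if (mean(bw) > 0.25) {
    ioct_stop("ioct_no_scan_region",
              "no distinct bright marker (near-uniform frame)")
  }
  # edge pixels: bright pixels with a non-bright 4-neighbour
  h <- nrow(bw); w <- ncol(bw)
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- bw
  nb <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- bw & !nb
  g <- image_grid(h, w)
  ex <- g$x[edge]; ey <- g$y[edge]
  band <- opts$hough_theta_deg * pi / 180
  th_step <- pi / 180
  vlines <- hough_lines(ex, ey, seq(-band, band, th_step),
                        opts$hough_min_votes)
  hlines <- hough_lines(ex, ey, seq(pi / 2 - band, pi / 2 + band, th_step),
                        opts$hough_min_votes)
  if (is.null(vlines) || nrow(vlines) < 2 || is.null(hlines) || nrow(hlines) < 2) {
    ioct_stop("ioct_no_scan_region", "no rectangle-forming lines detected")
  }
  vlines <- vlines[seq_len(min(6, nrow(vlines))), , drop = FALSE]
  hlines <- hlines[seq_len(min(6, nrow(hlines))), , drop = FALSE]
  bwn <- bw * 1  # numeric copy for bilinear perimeter sampling
  best <- NULL; best_score <- -Inf; best_area <- -Inf
  for (i in seq_len(nrow(vlines) - 1)) for (j in (i + 1):nrow(vlines)) {
    for (k in seq_len(nrow(hlines) - 1)) for (l in (k + 1):nrow(hlines)) {
      vv <- list(vlines[i, ], vlines[j, ])
      hh <- list(hlines[k, ], hlines[l, ])
      c1 <- line_intersect(vv[[1]], hh[[1]])
      c2 <- line_intersect(vv[[2]], hh[[1]])
      c3 <- line_intersect(vv[[2]], hh[[2]])
      c4 <- line_intersect(vv[[1]], hh[[2]])
      quad <- rbind(c1, c2, c3, c4)
      if (any(!is.finite(quad))) next
      if (any(quad[, 1] < -1 | quad[, 1] > w | quad[, 2] < -1 | quad[, 2] > h)) next
      side_w <- sqrt(sum((c2 - c1)^2)); side_h <- sqrt(sum((c4 - c1)^2))
      if (side_w < opts$min_side || side_h < opts$min_side) next
      score <- perimeter_brightness(bwn, quad)
      area <- side_w * side_h
      # score = fraction of the perimeter lying on thresholded-bright
      # pixels; near-complete coverage ties are broken by larger area
      if (score > best_score + 0.02 ||
          (abs(score - best_score) <= 0.02 && area > best_area)) {
        best <- quad; best_score <- score; best_area <- area
        best_lines <- list(v = vv, h = hh)
      }
    }
  }
  if (is.null(best)) ioct_stop("ioct_no_scan_region", "no valid quadrilateral found")
  # sub-pixel refinement of the four winning lines on the bright pixels
  bx <- g$x[bw]; by <- g$y[bw]
  rv1 <- refine_line(bx, by, best_lines$v[[1]][1], best_lines$v[[1]][2], "v")
  rv2 <- refine_line(bx, by, best_lines$v[[2]][1], best_lines$v[[2]][2], "v")
  rh1 <- refine_line(bx, by, best_lines$h[[1]][1], best_lines$h[[1]][2], "h")
  rh2 <- refine_line(bx, by, best_lines$h[[2]][1], best_lines$h[[2]][2], "h")
  corners <- rbind(line_intersect(rv1, rh1), line_intersect(rv2, rh1),
                   line_intersect(rv2, rh2), line_intersect(rv1, rh2))
  if (any(!is.finite(corners))) corners <- best
  order_corners(corners)
}

perimeter_brightness <- function(bwn, quad) {
  pts <- NULL
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[if (i == 4) 1 else i + 1, ]
    n <- max(2, ceiling(sqrt(sum((b - a)^2))))
    tt <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2])))
  }
  v <- bilinear_sample(bwn, pts[, 1], pts[, 2])
  mean(v > 0.5, na.rm = TRUE)
}

order_corners <- function(corners) {
  cx <- mean(corners[, 1]); cy <- mean(corners[, 2])
  ang <- atan2(corners[, 2] - cy, corners[, 1] - cx)
  ord <- order(ang)  # increasing angle = clockwise when y points down
  corners <- corners[ord, , drop = FALSE]
  first <- which.min(corners[, 1] + corners[, 2])
  corners[((first - 1 + 0:3) %% 4) + 1, , drop = FALSE]
}

#' Locate the cyan and magenta arrow glyphs inside the scan rectangle
#'
#' Each arrow point is the value-weighted centroid of the pixels whose HSV
#' colour falls in the configured hue/saturation/value range, restricted to
#' the rectangle interior dilated by `arrow_margin` pixels.
#'
#' @param scene_frame RGB array (0..255).
#' @param rect_corners 4 x 2 corner matrix from [detect_scan_rectangle()].
#' @param opts [tracking_options()].
#' @return list with `cyan_point` and `magenta_point`, each (x, y) sub-pixel.
#' @export
detect_arrow_points <- function(scene_frame, rect_corners,
                                opts = tracking_options()) {
  h <- dim(scene_frame)[1]; w <- dim(scene_frame)[2]
  g <- image_grid(h, w)
  inside <- point_in_quad(g$x, g$y, rect_corners, opts$arrow_margin)
  hsv <- grDevices::rgb2hsv(as.vector(scene_frame[, , 1]),
                            as.vector(scene_frame[, , 2]),
                            as.vector(scene_frame[, , 3]), maxColorValue = 255)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]
  centroid_of <- function(hue_range, name) {
    m <- inside & hue >= hue_range[1] & hue <= hue_range[2] &
      sat >= opts$sat_min & val >= opts$val_min
    if (!any(m)) {
      ioct_stop("ioct_arrow_not_found", "no %s arrow inside the scan rectangle", name)
    }
    wgt <- val[m]
    c(sum(g$x[m] * wgt) / sum(wgt), sum(g$y[m] * wgt) / sum(wgt))
  }
  list(cyan_point = centroid_of(opts$cyan_hue, "cyan"),
       magenta_point = centroid_of(opts$magenta_hue, "magenta"))
}

# vectorized point-in-convex-quad (corners clockwise), dilated by margin
point_in_quad <- function(x, y, corners, margin = 0) {
  cx <- mean(corners[, 1]); cy <- mean(corners[, 2])
  inside <- rep(TRUE, length(x))
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[if (i == 4) 1 else i + 1, ]
    e <- b - a; len <- sqrt(sum(e^2))
    # inward normal: centre must satisfy the same inequality
    nx <- -e[2] / len; ny <- e[1] / len
    s_c <- sign((cx - a[1]) * nx + (cy - a[2]) * ny)
    inside <- inside & (s_c * ((x - a[1]) * nx + (y - a[2]) * ny) >= -margin)
  }
  inside
}

# --- pyramidal Lucas-Kanade single-point tracking --------------------------

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) pyr[[l + 1]] <- pyr_down(pyr[[l]])
  pyr
}

# one LK solve of point p (0-based) from image A to image B at a single level
lk_level <- function(A, B, p, guess, win, max_iter, eps) {
  r <- (win - 1) / 2
  ox <- rep(-r:r, times = win)
  oy <- rep(-r:r, each = win)
  gx <- p[1] + ox; gy <- p[2] + oy
  Tw  <- bilinear_sample(A, gx, gy)
  Ix <- (bilinear_sample(A, gx + 1, gy) - bilinear_sample(A, gx - 1, gy)) / 2
  Iy <- (bilinear_sample(A, gx, gy + 1) - bilinear_sample(A, gx, gy - 1)) / 2
  ok <- is.finite(Tw) & is.finite(Ix) & is.finite(Iy)
  if (mean(ok) < 0.5) return(list(v = guess, ok = FALSE, err = Inf))
  Gxx <- sum(Ix[ok]^2); Gxy <- sum(Ix[ok] * Iy[ok]); Gyy <- sum(Iy[ok]^2)
  dt <- Gxx * Gyy - Gxy^2
  if (dt < 1e-6) return(list(v = guess, ok = FALSE, err = Inf))
  v <- guess
  err <- Inf
  for (it in seq_len(max_iter)) {
    Iw <- bilinear_sample(B, gx + v[1], gy + v[2])
    ok2 <- ok & is.finite(Iw)
    if (mean(ok2) < 0.5) return(list(v = v, ok = FALSE, err = Inf))
    d <- Tw[ok2] - Iw[ok2]
    bx <- sum(d * Ix[ok2]); by <- sum(d * Iy[ok2])
    dv <- c(Gyy * bx - Gxy * by, -Gxy * bx + Gxx * by) / dt
    v <- v + dv
    err <- mean(abs(d))
    if (sqrt(sum(dv^2)) < eps) break
  }
  list(v = v, ok = TRUE, err = err)
}

lk_track_point <- function(prev, cur, p, opts,
                           pa = build_pyramid(prev, opts$lk_levels),
                           pb = build_pyramid(cur, opts$lk_levels)) {
  levels <- opts$lk_levels
  g <- c(0, 0)
  err <- Inf
  for (l in levels:1) {
    pl <- p / 2^(l - 1)
    res <- lk_level(pa[[l]], pb[[l]], pl, g, opts$lk_window,
                    opts$lk_max_iter, opts$lk_eps)
    if (!res$ok) return(list(p = p + g * 2^(l - 1), ok = FALSE, err = Inf))
    err <- res$err
    g <- if (l > 1) 2 * res$v else res$v
  }
  list(p = p + g, ok = err <= opts$lk_err_max, err = err)
}

#' Track a single retinal feature point with pyramidal Lucas-Kanade flow
#'
#' @param frames list of grayscale matrices (0..255) or RGB arrays.
#' @param seed_point (x, y) 0-based position of the feature in the first
#'   frame.
#' @param opts [tracking_options()].
#' @return list with `points` (n x 2 matrix) and `status` (logical vector,
#'   `FALSE` once the track is lost; a lost track stays lost).
#' @export
track_feature <- function(frames, seed_point, opts = tracking_options()) {
  if (length(frames) == 0) ioct_stop("ioct_invalid_input", "no frames to track")
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) rgb_to_gray(f) else f)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  if (seed_point[1] < 0 || seed_point[1] > w - 1 ||
      seed_point[2] < 0 || seed_point[2] > h - 1) {
    ioct_stop("ioct_invalid_input", "seed_point outside the first frame")
  }
  n <- length(frames)
  pts <- matrix(NA_real_, n, 2)
  status <- logical(n)
  pts[1, ] <- seed_point; status[1] <- TRUE
  p <- seed_point
  alive <- TRUE
  pyr_prev <- build_pyramid(frames[[1]], opts$lk_levels)
  for (t in seq_len(n)[-1]) {
    pyr_cur <- build_pyramid(frames[[t]], opts$lk_levels)
    if (!alive) {
      pts[t, ] <- pts[t - 1, ]; status[t] <- FALSE
      pyr_prev <- pyr_cur
      next
    }
    res <- lk_track_point(frames[[t - 1]], frames[[t]], p, opts,
                          pa = pyr_prev, pb = pyr_cur)
    pyr_prev <- pyr_cur
    p <- res$p
    out <- p[1] < 0 || p[1] > w - 1 || p[2] < 0 || p[2] > h - 1
    alive <- res$ok && !out
    pts[t, ] <- p
    status[t] <- alive
  }
  list(points = pts, status = status)
}

# --- scan track assembly and stability analysis ----------------------------

#' Build a full scan track from a sequence of microscope views
#'
#' Runs rectangle and arrow detection on every frame and Lucas-Kanade
#' tracking of the retinal feature; per-frame detection failures are recorded
#' as invalid rather than raised.
#'
#' @param scene_frames list of RGB arrays, or a directory containing
#'   `scene_%05d.png` frames.
#' @param seed_point (x, y) feature position in the first frame.
#' @param opts [tracking_options()].
#' @return An object of class `ioct_track`: data frame with 0-based `frame`,
#'   arrow point coordinates, `scan_valid`, feature coordinates and
#'   `feat_ok`.
#' @export
build_scan_track <- function(scene_frames, seed_point,
                             opts = tracking_options()) {
  if (is.character(scene_frames)) {
    paths <- sort(list.files(scene_frames, pattern = "^scene_\\d+\\.png$",
                             full.names = TRUE))
    if (!length(paths)) ioct_stop("ioct_invalid_input", "no scene frames in %s", scene_frames)
    scene_frames <- lapply(paths, read_rgb_png)
  }
  n <- length(scene_frames)
  if (n == 0) ioct_stop("ioct_invalid_input", "no frames")
  cyan <- mag <- matrix(NA_real_, n, 2)
  valid <- logical(n)
  for (t in seq_len(n)) {
    res <- tryCatch({
      rc <- detect_scan_rectangle(scene_frames[[t]], opts)
      ar <- detect_arrow_points(scene_frames[[t]], rc, opts)
      list(ok = TRUE, ar = ar)
    }, ioct_error = function(e) list(ok = FALSE))
    if (res$ok) {
      cyan[t, ] <- res$ar$cyan_point
      mag[t, ] <- res$ar$magenta_point
      valid[t] <- TRUE
    }
  }
  ft <- track_feature(scene_frames, seed_point, opts)
  out <- data.frame(frame = 0:(n - 1),
                    cyan_x = cyan[, 1], cyan_y = cyan[, 2],
                    mag_x = mag[, 1], mag_y = mag[, 2],
                    scan_valid = valid,
                    feat_x = ft$points[, 1], feat_y = ft$points[, 2],
                    feat_ok = ft$status)
  class(out) <- c("ioct_track", "data.frame")
  out
}

#' @export
print.ioct_track <- function(x, ...) {
  cat(sprintf("ioct scan track: %d frames, %d with valid scan marker, %d with live feature\n",
              nrow(x), sum(x$scan_valid), sum(x$feat_ok)))
  invisible(x)
}

#' Extract stationary frame intervals from a scan track
#'
#' A frame continues the current interval when both arrow points and the
#' feature point each move at most `tol_step` pixels from the previous frame
#' and at most `tol_total` pixels from the interval's first frame; frames
#' with an invalid scan marker or a lost feature break intervals. Maximal
#' disjoint runs of at least `min_len` frames are returned.
#'
#' @param track an `ioct_track` from [build_scan_track()] (or a data frame
#'   with the same columns).
#' @param min_len minimum interval length in frames; the "more than eight
#'   consecutive frames" rule maps to the default 8 (inclusive); set
#'   `strict_gt = TRUE` for the strictly-greater reading (>= 9).
#' @param tol_step per-frame position tolerance in pixels.
#' @param tol_total tolerance against the interval's first frame in pixels.
#' @param strict_gt if `TRUE`, requires strictly more than `min_len` frames.
#' @return list of intervals; each has 0-based inclusive `start`, `end`,
#'   `n_frames`, `max_scan_deviation`, `max_feature_deviation`.
#' @export
find_stable_intervals <- function(track, min_len = 8, tol_step = 1.5,
                                  tol_total = 3, strict_gt = FALSE) {
  if (min_len < 2) ioct_stop("ioct_invalid_input", "min_len must be >= 2")
  n <- nrow(track)
  out <- list()
  if (is.null(n) || n == 0) return(out)
  need <- if (strict_gt) min_len + 1 else min_len
  pts <- function(t) rbind(c(track$cyan_x[t], track$cyan_y[t]),
                           c(track$mag_x[t], track$mag_y[t]),
                           c(track$feat_x[t], track$feat_y[t]))
  ok <- track$scan_valid & track$feat_ok
  dev <- function(a, b) sqrt(rowSums((a - b)^2))
  t <- 1
  while (t <= n) {
    if (!ok[t]) { t <- t + 1; next }
    s <- t
    p0 <- pts(s)
    max_scan <- 0; max_feat <- 0
    e <- s
    while (e + 1 <= n && ok[e + 1]) {
      step_d <- dev(pts(e + 1), pts(e))
      tot_d <- dev(pts(e + 1), p0)
      if (max(step_d) > tol_step || max(tot_d) > tol_total) break
      e <- e + 1
      max_scan <- max(max_scan, tot_d[1:2])
      max_feat <- max(max_feat, tot_d[3])
    }
    if (e - s + 1 >= need) {
      out[[length(out) + 1]] <- list(
        start = track$frame[s], end = track$frame[e], n_frames = e - s + 1,
        max_scan_deviation = max_scan, max_feature_deviation = max_feat)
    }
    t <- e + 1
  }
  out
}

#' Write / read a scan track as JSON
#' @param track `ioct_track` data frame.
#' @param path output path.
#' @return `path` (write) or the track (read).
#' @export
write_track <- function(track, path) {
  json_write(as.list(as.data.frame(track)), path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  x <- as.data.frame(json_read(path))
  class(x) <- c("ioct_track", "data.frame")
  x
}

#' Write / read stability intervals as JSON
#' @param intervals list from [find_stable_intervals()].
#' @param path output path.
#' @return `path` (write) or the interval list (read).
#' @export
write_intervals <- function(intervals, path) {
  json_write(intervals, path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  x <- json_read(path)
  lapply(seq_len(if (is.data.frame(x)) nrow(x) else length(x)), function(i) {
    if (is.data.frame(x)) as.list(x[i, ]) else x[[i]]
  })
}
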