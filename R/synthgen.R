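#' Specification of a layered retinal B-scan phantom
#'
#' Describes a piecewise-constant reflectivity cross-section: a stack of
#' `n_layers` retinal layers bounded above by a smoothly curved top surface
#' (low-order sinusoids emulating retinal curvature) over a dark background,
#' degraded by fully-developed multiplicative speckle. Speckle is gamma
#' distributed with shape `speckle_looks` (the number of looks L) and unit
#' mean, applied to the linear reflectivity map and clipped to 0..255;
#' `speckle_looks = Inf` gives the noise-free map.
#'
#' @param width,height phantom size in pixels.
#' @param n_layers number of retinal layers (>= 2).
#' @param layer_reflectivities mean linear intensity per layer, top to bottom,
#'   each in 0..255; length `n_layers`.
#' @param background_level background (vitreous) intensity.
#' @param top_depth_frac depth of the mean top surface as a fraction of height.
#' @param thickness_frac total retina thickness as a fraction of height.
#' @param curve_amplitudes,curve_freqs,curve_phases sinusoid parameters of the
#'   surface curve: `sum(amp * sin(2*pi*freq*x/width + phase))` pixels.
#' @param layer_fractions interior boundary depths as fractions of the retina
#'   thickness (length `n_layers - 1`, increasing, in (0,1)); `NULL` gives
#'   equal-thickness layers.
#' @param lateral_texture_amp amplitude of the smooth multiplicative lateral
#'   reflectivity modulation applied to the retina (not the background),
#'   emulating vessel shadows and tissue heterogeneity; 0 disables. Without
#'   lateral structure a layered phantom is nearly degenerate for the
#'   lateral component of rigid registration, which real B-scans are not.
#' @param lateral_texture_freqs,lateral_texture_phases frequencies
#'   (cycles/width) and phases of the two modulation harmonics.
#' @param speckle_looks gamma shape L > 0 of the multiplicative speckle;
#'   `Inf` disables noise.
#' @param speckle_background if `FALSE` the background keeps its clean level
#'   plus additive Gaussian noise of sd `background_sigma` instead of speckle;
#'   used to construct high-SNR phantoms.
#' @param background_sigma additive background noise sd when
#'   `speckle_background = FALSE`.
#' @param rng_seed integer seed controlling the speckle realization only; the
#'   geometry is seed-independent.
#' @return An object of class `phantom_spec`.
#' @seealso [make_bscan_phantom()]
#' @export
phantom_spec <- function(width = 440, height = 300, n_layers = 5,
                         layer_reflectivities = c(40, 170, 90, 120, 200),
                         background_level = 8,
                         top_depth_frac = 0.22, thickness_frac = 0.55,
                         curve_amplitudes = c(10, 4),
                         curve_freqs = c(1, 2.3),
                         curve_phases = c(0.3, 1.1),
                         layer_fractions = NULL,
                         lateral_texture_amp = 0.2,
                         lateral_texture_freqs = c(3.3, 8.1),
                         lateral_texture_phases = c(0.7, 2.1),
                         speckle_looks = 1,
                         speckle_background = TRUE,
                         background_sigma = 0.25,
                         rng_seed = 1L) {
  if (!is.numeric(width) || !is.numeric(height) || width < 1 || height < 1) {
    ioct_stop("ioct_invalid_spec", "phantom dimensions must be positive")
  }
  if (n_layers < 2) {
    ioct_stop("ioct_invalid_spec", "n_layers must be >= 2, got %d", n_layers)
  }
  if (length(layer_reflectivities) != n_layers ||
      any(layer_reflectivities < 0 | layer_reflectivities > 255)) {
    ioct_stop("ioct_invalid_spec",
              "layer_reflectivities must have length n_layers with values in [0,255]")
  }
  if (!is.numeric(speckle_looks) || is.na(speckle_looks) || speckle_looks <= 0) {
    ioct_stop("ioct_invalid_spec", "speckle_looks must be > 0 (Inf for noise-free)")
  }
  if (is.null(layer_fractions)) {
    layer_fractions <- seq_len(n_layers - 1) / n_layers
  }
  if (length(layer_fractions) != n_layers - 1 ||
      is.unsorted(layer_fractions, strictly = TRUE) ||
      any(layer_fractions <= 0 | layer_fractions >= 1)) {
    ioct_stop("ioct_invalid_spec",
              "layer_fractions must be strictly increasing inside (0,1)")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_layers = as.integer(n_layers),
    layer_reflectivities = as.numeric(layer_reflectivities),
    background_level = background_level,
    top_depth_frac = top_depth_frac, thickness_frac = thickness_frac,
    curve_amplitudes = curve_amplitudes, curve_freqs = curve_freqs,
    curve_phases = curve_phases,
    layer_fractions = as.numeric(layer_fractions),
    lateral_texture_amp = lateral_texture_amp,
    lateral_texture_freqs = lateral_texture_freqs,
    lateral_texture_phases = lateral_texture_phases,
    speckle_looks = speckle_looks,
    speckle_background = isTRUE(speckle_background),
    background_sigma = background_sigma,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
}

# boundary curves: (n_layers + 1) x width matrix of y positions; row b is the
# upper boundary of layer b (row n_layers + 1 the retina bottom)
phantom_boundaries <- function(spec) {
  x <- 0:(spec$width - 1)
  top <- spec$height * spec$top_depth_frac
  for (i in seq_along(spec$curve_amplitudes)) {
    top <- top + spec$curve_amplitudes[i] *
      sin(2 * pi * spec$curve_freqs[i] * x / spec$width + spec$curve_phases[i])
  }
  thick <- spec$height * spec$thickness_frac
  fr <- c(0, spec$layer_fractions, 1)
  t(outer(top, fr * thick, `+`))  # (n_layers+1) x width
}

# clean reflectivity map and integer label mask from boundary curves
phantom_clean <- function(spec, boundaries = phantom_boundaries(spec)) {
  h <- spec$height; w <- spec$width
  mask <- matrix(0L, h, w)
  y <- 0:(h - 1)
  for (cx in seq_len(w)) {
    lab <- findInterval(y, boundaries[, cx])
    lab[lab > spec$n_layers] <- 0L
    mask[, cx] <- lab
  }
  lut <- c(spec$background_level, spec$layer_reflectivities)
  refl <- matrix(lut[mask + 1L], h, w)
  if (!is.null(spec$lateral_texture_amp) && spec$lateral_texture_amp > 0) {
    x <- 0:(w - 1)
    f <- spec$lateral_texture_freqs; p <- spec$lateral_texture_phases
    mod <- 1 + spec$lateral_texture_amp *
      (0.7 * sin(2 * pi * f[1] * x / w + p[1]) +
       0.3 * sin(2 * pi * f[2] * x / w + p[2]))
    modm <- matrix(mod, h, w, byrow = TRUE)
    tissue <- mask > 0L
    refl[tissue] <- refl[tissue] * modm[tissue]
  }
  list(refl = refl, mask = mask)
}

# multiply a clean map by unit-mean gamma speckle; optionally keep the
# background clean with small additive noise (uses current RNG state)
speckle_apply <- function(refl, mask, spec) {
  if (is.infinite(spec$speckle_looks) && spec$speckle_background) return(clip01(refl))
  h <- nrow(refl); w <- ncol(refl)
  img <- refl
  if (!is.infinite(spec$speckle_looks)) {
    g <- matrix(stats::rgamma(h * w, shape = spec$speckle_looks,
                              rate = spec$speckle_looks), h, w)
    img <- refl * g
  }
  if (!spec$speckle_background) {
    bg <- mask == 0L
    img[bg] <- refl[bg] + stats::rnorm(sum(bg), sd = spec$background_sigma)
  }
  clip01(img)
}

#' Render a speckled B-scan phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ioct_phantom` with elements `image` (float matrix,
#'   0..255), `mask` (integer label matrix, 0 = background, 1..n_layers top to
#'   bottom), `boundaries` ((n_layers+1) x width matrix of boundary-curve y
#'   positions) and `spec`.
#' @examples
#' ph <- make_bscan_phantom(phantom_spec(width = 64, height = 64))
#' range(ph$image)
#' @export
make_bscan_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    ioct_stop("ioct_invalid_spec", "spec must be a phantom_spec object")
  }
  b <- phantom_boundaries(spec)
  cl <- phantom_clean(spec, b)
  img <- with_seed(spec$rng_seed, speckle_apply(cl$refl, cl$mask, spec))
  structure(list(image = img, mask = cl$mask, boundaries = b, spec = spec),
            class = "ioct_phantom")
}

#' @export
print.ioct_phantom <- function(x, ...) {
  cat(sprintf("ioct phantom: %dx%d px, %d layers, L = %s, seed %d\n",
              x$spec$width, x$spec$height, x$spec$n_layers,
              format(x$spec$speckle_looks), x$spec$rng_seed))
  invisible(x)
}

#' Script the motion of a synthetic surgical scene
#'
#' Builds per-frame nominal poses for the microscope view and the underlying
#' retina: the scan rectangle, the arrow glyphs, the trackable retinal
#' feature, and the true rigid transform of each B-scan all follow one
#' translation track that is constant within `stationary_segments` and drifts
#' linearly in between (direction drawn once per moving gap from `rng_seed`).
#'
#' @param n_frames number of frames (>= 1).
#' @param scene_width,scene_height microscope-view size in pixels.
#' @param rect_centre,rect_size scan-rectangle centre and (w, h) in pixels at
#'   pose zero.
#' @param feature_offset feature position relative to the rectangle centre.
#' @param stationary_segments list of 0-based inclusive `c(start, end)` frame
#'   ranges with constant pose.
#' @param step_px drift speed (pixels/frame) outside stationary segments.
#' @param theta_per_px degrees of B-scan rotation per pixel of lateral drift.
#' @param jitter_px bound of the uniform sub-pixel jitter added inside
#'   stationary segments when rendering (0 disables).
#' @param rng_seed seed for drift directions (geometry of the script).
#' @return An object of class `scene_script`.
#' @export
scene_script <- function(n_frames = 60, scene_width = 480, scene_height = 360,
                         rect_centre = c(240, 150), rect_size = c(200, 60),
                         feature_offset = c(10, 95),
                         stationary_segments = list(c(10, 24), c(40, 52)),
                         step_px = 2, theta_per_px = 0.08,
                         jitter_px = 0.2, rng_seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 1) {
    ioct_stop("ioct_invalid_script", "n_frames must be >= 1")
  }
  n_frames <- as.integer(n_frames)
  segs <- lapply(stationary_segments, function(s) as.integer(s[1:2]))
  for (s in segs) {
    if (s[1] > s[2] || s[1] < 0 || s[2] >= n_frames) {
      ioct_stop("ioct_invalid_script",
                "stationary segment [%d,%d] outside [0,%d)", s[1], s[2], n_frames)
    }
  }
  in_seg <- rep(FALSE, n_frames)
  for (s in segs) in_seg[(s[1] + 1):(s[2] + 1)] <- TRUE
  pose <- matrix(0, n_frames, 2)  # (dx, dy) per frame
  bound <- c(scene_width * 0.12, scene_height * 0.12)
  dir <- c(1, 0)
  was_moving <- FALSE
  with_seed(rng_seed, {
    for (t in seq_len(n_frames)[-1]) {
      moving <- !(in_seg[t] && in_seg[t - 1])
      if (moving) {
        if (!was_moving) {
          ang <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(ang), sin(ang))
        }
        nxt <- pose[t - 1, ] + step_px * dir
        # reflect off the view margin so motion never stalls into a fake
        # stationary run
        for (k in 1:2) {
          if (abs(nxt[k]) > bound[k]) {
            dir[k] <- -dir[k]
            nxt[k] <- pose[t - 1, k] + step_px * dir[k]
          }
        }
        pose[t, ] <- nxt
        was_moving <- TRUE
      } else {
        pose[t, ] <- pose[t - 1, ]
        was_moving <- FALSE
      }
    }
  })
  structure(list(
    n_frames = n_frames, scene_width = as.integer(scene_width),
    scene_height = as.integer(scene_height),
    rect_centre = rect_centre, rect_size = rect_size,
    feature_offset = feature_offset,
    stationary_segments = segs, step_px = step_px,
    theta_per_px = theta_per_px, jitter_px = jitter_px,
    pose = pose, rng_seed = as.integer(rng_seed)), class = "scene_script")
}

# rectangle corners (4 x 2, clockwise from top-left) for a pose offset
script_rect_corners <- function(script, off) {
  cx <- script$rect_centre[1] + off[1]
  cy <- script$rect_centre[2] + off[2]
  hw <- script$rect_size[1] / 2
  hh <- script$rect_size[2] / 2
  rbind(c(cx - hw, cy - hh), c(cx + hw, cy - hh),
        c(cx + hw, cy + hh), c(cx - hw, cy + hh))
}

# --- scene rendering -------------------------------------------------------

# deterministic fundus-like texture for one scene; geometry depends only on
# the texture seed, rendered with the pose shift applied
scene_texture <- function(w, h, seed) {
  with_seed(seed, {
    pad <- 80
    n <- matrix(stats::runif((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad, w + 2 * pad)
    tex <- gauss_smooth(n, 6)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    tex
  })
}

render_scene_frame <- function(script, off, tex, cyan_tip, magenta_tip,
                               feature_pt) {
  h <- script$scene_height; w <- script$scene_width
  pad <- 80
  # shifted crop of the big texture (retina moves with the pose)
  rows <- seq_len(h) + pad - round(off[2])
  cols <- seq_len(w) + pad - round(off[1])
  t0 <- tex[rows, cols]
  r <- clip01(185 + 26 * t0)
  g <- clip01(110 + 20 * t0)
  b <- clip01(60 + 14 * t0)
  gr <- image_grid(h, w)
  # dark vessel: sinusoid across the view, moving with the pose
  vy <- 0.62 * h + 18 * sin(2 * pi * (gr$x - off[1]) / w * 1.7) + off[2]
  vd <- exp(-(gr$y - vy)^2 / (2 * 2.2^2))
  r <- r * (1 - 0.55 * vd); g <- g * (1 - 0.6 * vd); b <- b * (1 - 0.6 * vd)
  # trackable feature: smooth dark spot (vessel-bifurcation-like)
  fd <- exp(-((gr$x - feature_pt[1])^2 + (gr$y - feature_pt[2])^2) / (2 * 3^2))
  r <- r * (1 - 0.8 * fd); g <- g * (1 - 0.85 * fd); b <- b * (1 - 0.85 * fd)
  # white scan-rectangle outline, ~1.5 px stroke centred on the ideal border
  cr <- script_rect_corners(script, off)
  x1 <- cr[1, 1]; x2 <- cr[2, 1]; y1 <- cr[1, 2]; y2 <- cr[3, 2]
  on_v <- (abs(gr$x - x1) <= 0.75 | abs(gr$x - x2) <= 0.75) &
    gr$y >= y1 - 0.75 & gr$y <= y2 + 0.75
  on_h <- (abs(gr$y - y1) <= 0.75 | abs(gr$y - y2) <= 0.75) &
    gr$x >= x1 - 0.75 & gr$x <= x2 + 0.75
  outline <- on_v | on_h
  r[outline] <- 255; g[outline] <- 255; b[outline] <- 255
  # arrow glyphs: filled triangles, pure cyan / magenta, tip at *_tip
  draw_tri <- function(chan_r, chan_g, chan_b, tip, dirsign, col) {
    # triangle pointing along +x (dirsign=1) or -x (-1); base 12 px, len 14 px
    v1 <- tip
    v2 <- c(tip[1] - dirsign * 14, tip[2] - 6)
    v3 <- c(tip[1] - dirsign * 14, tip[2] + 6)
    inside <- point_in_triangle(gr$x, gr$y, v1, v2, v3)
    chan_r[inside] <- col[1]; chan_g[inside] <- col[2]; chan_b[inside] <- col[3]
    list(chan_r, chan_g, chan_b, inside)
  }
  dc <- draw_tri(r, g, b, cyan_tip, 1, c(0, 255, 255))
  r <- dc[[1]]; g <- dc[[2]]; b <- dc[[3]]; cy_mask <- dc[[4]]
  dm <- draw_tri(r, g, b, magenta_tip, -1, c(255, 0, 255))
  r <- dm[[1]]; g <- dm[[2]]; b <- dm[[3]]; mg_mask <- dm[[4]]
  img <- array(0, c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  list(image = img,
       cyan_centroid = mask_centroid(cy_mask),
       magenta_centroid = mask_centroid(mg_mask))
}

point_in_triangle <- function(x, y, v1, v2, v3) {
  s <- function(ax, ay, bx, by) (x - ax) * (by - ay) - (y - ay) * (bx - ax)
  d1 <- s(v1[1], v1[2], v2[1], v2[2])
  d2 <- s(v2[1], v2[2], v3[1], v3[2])
  d3 <- s(v3[1], v3[2], v1[1], v1[2])
  (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
}

mask_centroid <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  g <- image_grid(h, w)
  c(mean(g$x[mask]), mean(g$y[mask]))
}

#' Generate a paired microscope-view / B-scan synthetic video
#'
#' Writes, for every frame of `script`: an RGB microscope view
#' (`frames/scene_%05d.png`) containing the white scan rectangle, cyan and
#' magenta arrow glyphs and a trackable dark retinal feature over a textured
#' fundus; a grayscale B-scan (`frames/bscan_%05d.png`) — the phantom rigidly
#' moved by the frame's true transform and independently re-speckled — and an
#' integer label mask (`masks/mask_%05d.png`). Ground truth goes to
#' `manifest.json`.
#'
#' @param phantom_spec a [phantom_spec()].
#' @param script a [scene_script()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly a list (also written as JSON); frame
#'   indices in the manifest are 0-based.
#' @export
make_surgery_video <- function(phantom_spec, script, out_dir) {
  if (!inherits(script, "scene_script")) {
    ioct_stop("ioct_invalid_script", "script must be a scene_script object")
  }
  if (script$n_frames < 1) ioct_stop("ioct_invalid_script", "empty script")
  ok <- dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "frames"))) {
    ioct_stop("ioct_io_error", "cannot create output directory %s", out_dir)
  }
  n <- script$n_frames
  b <- phantom_boundaries(phantom_spec)
  cl <- phantom_clean(phantom_spec, b)
  tex <- scene_texture(script$scene_width, script$scene_height, script$rng_seed)

  in_seg <- rep(FALSE, n)
  for (s in script$stationary_segments) in_seg[(s[1] + 1):(s[2] + 1)] <- TRUE

  frames <- vector("list", n)
  with_seed(phantom_spec$rng_seed, {
    for (t in seq_len(n)) {
      off <- script$pose[t, ]
      if (script$jitter_px > 0) {
        off <- off + stats::runif(2, -script$jitter_px, script$jitter_px)
      }
      # true B-scan rigid transform, a deterministic function of the pose
      theta <- clip01(script$theta_per_px * off[1], -3, 3)
      tx <- clip01(off[1], -15, 15)
      ty <- clip01(off[2] * 0.6, -12, 12)
      # scene geometry for this frame
      cr <- script_rect_corners(script, off)
      hw <- script$rect_size[1] / 2
      cx <- script$rect_centre[1] + off[1]; cy <- script$rect_centre[2] + off[2]
      cyan_tip <- c(cx - hw + 34, cy)
      magenta_tip <- c(cx + hw - 34, cy)
      feature_pt <- c(cx + script$feature_offset[1], cy + script$feature_offset[2])
      sc <- render_scene_frame(script, off, tex, cyan_tip, magenta_tip, feature_pt)
      # B-scan: warp clean map, re-speckle independently every frame
      refl_t <- warp_rigid(cl$refl, theta, tx, ty, fill = phantom_spec$background_level)
      mask_t <- warp_rigid_nn(cl$mask, theta, tx, ty, fill = 0L)
      bs <- speckle_apply(refl_t, mask_t, phantom_spec)
      i <- t - 1
      write_rgb_png(sc$image, file.path(out_dir, "frames", sprintf("scene_%05d.png", i)))
      write_gray_png(bs, file.path(out_dir, "frames", sprintf("bscan_%05d.png", i)))
      write_mask_png(mask_t, file.path(out_dir, "masks", sprintf("mask_%05d.png", i)))
      frames[[t]] <- list(
        frame = i,
        transform = list(theta = theta, tx = tx, ty = ty),
        rect_corners = cr,
        cyan_point = sc$cyan_centroid,
        magenta_point = sc$magenta_centroid,
        feature_point = feature_pt,
        mask_path = sprintf("masks/mask_%05d.png", i))
    }
  })
  manifest <- list(
    n_frames = n,
    scene_size = c(script$scene_width, script$scene_height),
    bscan_size = c(phantom_spec$width, phantom_spec$height),
    base_boundaries = b,
    stationary_segments = script$stationary_segments,
    jitter_px = script$jitter_px,
    frames = frames)
  json_write(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a synthetic-video manifest back from JSON
#' @param path path to `manifest.json` or its directory.
#' @return manifest list with per-frame entries.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- json_read(path)
  m$frames <- lapply(seq_len(nrow(m$frames$transform)), function(i) {
    list(frame = m$frames$frame[i],
         transform = as.list(m$frames$transform[i, ]),
         rect_corners = matrix(unlist(m$frames$rect_corners[[i]]), ncol = 2),
         cyan_point = unlist(m$frames$cyan_point[[i]]),
         magenta_point = unlist(m$frames$magenta_point[[i]]),
         feature_point = unlist(m$frames$feature_point[[i]]),
         mask_path = m$frames$mask_path[i])
  })
  if (is.list(m$base_boundaries)) {
    m$base_boundaries <- matrix(unlist(m$base_boundaries),
                                ncol = length(m$base_boundaries))
  }
  ss <- m$stationary_segments
  if (is.matrix(ss)) {
    ss <- lapply(seq_len(nrow(ss)), function(i) as.integer(ss[i, ]))
  } else if (is.list(ss)) {
    ss <- lapply(ss, as.integer)
  } else if (length(ss)) {
    ss <- list(as.integer(ss))
  } else {
    ss <- list()
  }
  m$stationary_segments <- ss
  m
}

#' Layer-boundary curves of a manifest frame
#'
#' Applies the frame's true rigid transform to the base boundary curves.
#' For the small rotations scripted here the transformed curves are still
#' single-valued in x and are returned resampled on the pixel grid.
#'
#' @param manifest manifest list (from [make_surgery_video()] or
#'   [read_manifest()]).
#' @param frame 0-based frame index.
#' @return (n_layers + 1) x width matrix of boundary y positions.
#' @export
manifest_boundaries <- function(manifest, frame) {
  fr <- manifest$frames[[frame + 1]]
  b <- manifest$base_boundaries
  if (is.list(b)) b <- matrix(unlist(b), ncol = length(b))
  w <- ncol(b)
  h <- manifest$bscan_size[2]
  centre <- c((w - 1) / 2, (h - 1) / 2)
  tf <- fr$transform
  out <- matrix(NA_real_, nrow(b), w)
  xg <- 0:(w - 1)
  for (k in seq_len(nrow(b))) {
    p <- rigid_apply(cbind(xg, b[k, ]), tf$theta, tf$tx, tf$ty, centre)
    out[k, ] <- stats::approx(p[, 1], p[, 2], xout = xg, rule = 2)$y
  }
  out
}
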