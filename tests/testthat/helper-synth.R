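# Shared synthetic fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a homogeneous single-reflectivity phantom spec for speckle-statistics tests;
# reflectivity 60 keeps 8-bit clipping of L = 1 speckle to ~1.5% of samples
homog_spec <- function(L, seed, size = 120) {
  phantom_spec(width = size, height = size, n_layers = 2,
               layer_reflectivities = c(60, 60),
               top_depth_frac = 0.05, thickness_frac = 0.9,
               curve_amplitudes = 0, lateral_texture_amp = 0,
               speckle_looks = L, rng_seed = seed)
}

# interior 64 x 64 region of a homogeneous phantom image
homog_region <- function(img) img[29:92, 29:92]

# small phantom + scripted scene video used by the tracking tests
tracking_video <- function() {
  fixture("tracking_video", function() {
    sc <- scene_script(n_frames = 20, scene_width = 320, scene_height = 240,
                       rect_centre = c(160, 100), rect_size = c(140, 44),
                       feature_offset = c(6, 64),
                       stationary_segments = list(c(0, 11)),
                       rng_seed = 5)
    dir <- file.path(tempdir(), "ioct_tracking_video")
    manifest <- make_surgery_video(
      phantom_spec(width = 160, height = 110, curve_amplitudes = c(4, 2),
                   rng_seed = 1),
      sc, dir)
    frames <- lapply(sort(list.files(file.path(dir, "frames"),
                                     pattern = "^scene_", full.names = TRUE)),
                     read_rgb_png)
    list(dir = dir, manifest = manifest, frames = frames, script = sc)
  })
}

# spliced planted video: three stationary intervals; the first two carry
# high-quality B-scans (L = 16 speckle, near-clean background), the third
# low-SNR fully speckled ones, so gating at 70/3/10 accepts exactly two
planted_video <- function() {
  fixture("planted_video", function() {
    mk <- function(L, clean_bg) {
      phantom_spec(width = 220, height = 150, speckle_looks = L,
                   speckle_background = !clean_bg, background_sigma = 0.25,
                   curve_amplitudes = c(5, 2), rng_seed = 1)
    }
    segs <- list(c(4, 11), c(16, 23), c(28, 35))
    sc <- scene_script(n_frames = 40, scene_width = 360, scene_height = 270,
                       rect_centre = c(180, 110), rect_size = c(150, 46),
                       feature_offset = c(8, 72),
                       stationary_segments = segs, rng_seed = 7)
    dA <- file.path(tempdir(), "ioct_planted_A")
    dB <- file.path(tempdir(), "ioct_planted_B")
    mA <- make_surgery_video(mk(16, TRUE), sc, dA)
    make_surgery_video(mk(1, FALSE), sc, dB)
    for (t in 28:35) {
      for (p in c("frames/bscan_%05d.png", "masks/mask_%05d.png")) {
        file.copy(file.path(dB, sprintf(p, t)), file.path(dA, sprintf(p, t)),
                  overwrite = TRUE)
      }
    }
    list(dir = dA, manifest = mA, script = sc, segments = segs)
  })
}

planted_config <- function(seed = 1) {
  pipeline_config(seed = seed,
                  register.theta_range = c(-2, 2), register.coarse_step = 1,
                  quality.roi_background = c(24, 24),
                  quality.roi_homogeneous = c(12, 6),
                  quality.roi_contrast = c(48, 8))
}

# run_pipeline on the planted video, cached (reused by several tests)
planted_run <- function() {
  fixture("planted_run", function() {
    pv <- planted_video()
    out <- file.path(tempdir(), "ioct_planted_run1")
    summary <- run_pipeline(pv$dir, out, planted_config())
    list(out = out, summary = summary)
  })
}

# a directory of n stem-matched LR/HR PNG pairs
make_fake_pairs <- function(n) {
  src <- file.path(tempdir(), sprintf("ioct_pairs_%d", n))
  unlink(src, recursive = TRUE)
  dir.create(file.path(src, "lr"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(src, "hr"), recursive = TRUE, showWarnings = FALSE)
  img <- matrix(seq(0, 255, length.out = 16 * 16), 16)
  for (i in seq_len(n)) {
    write_gray_png(img, file.path(src, "lr", sprintf("pair_%03d.png", i)))
    write_gray_png(img, file.path(src, "hr", sprintf("pair_%03d.png", i)))
  }
  data.frame(lr = list.files(file.path(src, "lr"), full.names = TRUE),
             hr = list.files(file.path(src, "hr"), full.names = TRUE),
             stringsAsFactors = FALSE)
}

# in-memory float phantoms engineered to pass / fail the 70/3/10 gate
planted_gate_images <- function(k_pass = 3, m_fail = 2) {
  pass <- lapply(seq_len(k_pass), function(s) {
    make_bscan_phantom(phantom_spec(speckle_looks = 16,
                                    speckle_background = FALSE,
                                    background_sigma = 0.05,
                                    rng_seed = 100 + s))
  })
  fail <- lapply(seq_len(m_fail), function(s) {
    make_bscan_phantom(phantom_spec(speckle_looks = 1, rng_seed = 200 + s))
  })
  list(pass = pass, fail = fail)
}
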