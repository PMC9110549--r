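# Independent brute-force oracle implementations of every metric, kept
# deliberately separate from the package's code paths: direct evaluation of
# each formula, loops instead of convolutions where the package vectorizes.

oracle_snr <- function(image, px) {
  10 * log10(max(image^2) / mean((px - mean(px))^2))
}

oracle_enl <- function(regions) {
  mean(sapply(regions, function(px) mean(px)^2 / mean((px - mean(px))^2)))
}

oracle_cnr <- function(regions, bg) {
  mb <- mean(bg); vb <- mean((bg - mb)^2)
  mean(sapply(regions, function(px) {
    (mean(px) - mb) / sqrt(mean((px - mean(px))^2) + vb)
  }))
}

oracle_psnr <- function(a, b, maxv = 255) {
  10 * log10(maxv^2 / mean((a - b)^2))
}

# windowed-loop SSIM with independently constructed Gaussian weights
oracle_ssim <- function(a, b, sigma = 1.5, win = 11, maxv = 255) {
  r <- (win - 1) / 2
  w <- outer(stats::dnorm(-r:r, sd = sigma), stats::dnorm(-r:r, sd = sigma))
  w <- w / sum(w)
  C1 <- (0.01 * maxv)^2; C2 <- (0.03 * maxv)^2
  H <- nrow(a) - win + 1; W <- ncol(a) - win + 1
  acc <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pa <- a[i:(i + win - 1), j:(j + win - 1)]
    pb <- b[i:(i + win - 1), j:(j + win - 1)]
    mua <- sum(w * pa); mub <- sum(w * pb)
    va <- sum(w * pa * pa) - mua^2
    vb <- sum(w * pb * pb) - mub^2
    cab <- sum(w * pa * pb) - mua * mub
    acc <- acc + ((2 * mua * mub + C1) * (2 * cab + C2)) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2))
  }
  acc / (H * W)
}

# direct GCF: explicit per-level loops, shared constants written out
oracle_gcf <- function(image) {
  lin <- (image / 255)^2.2
  total <- 0
  for (lev in 1:9) {
    if (is.null(lin)) break
    L <- 100 * sqrt(lin)
    h <- nrow(L); w <- ncol(L)
    if (h * w > 1) {
      csum <- 0
      for (i in seq_len(h)) for (j in seq_len(w)) {
        d <- 0; n <- 0
        if (i > 1) { d <- d + abs(L[i, j] - L[i - 1, j]); n <- n + 1 }
        if (i < h) { d <- d + abs(L[i, j] - L[i + 1, j]); n <- n + 1 }
        if (j > 1) { d <- d + abs(L[i, j] - L[i, j - 1]); n <- n + 1 }
        if (j < w) { d <- d + abs(L[i, j] - L[i, j + 1]); n <- n + 1 }
        csum <- csum + d / n
      }
      wi <- (-0.406385 * lev / 9 + 0.334573) * lev / 9 + 0.0877526
      total <- total + wi * csum / (h * w)
    }
    # superpixel downsampling, ragged edge folded into the last superpixel
    h2 <- floor(h / 2); w2 <- floor(w / 2)
    if (h2 < 1 || w2 < 1) { lin <- NULL; next }
    nxt <- matrix(0, h2, w2)
    for (i in seq_len(h2)) for (j in seq_len(w2)) {
      rows <- if (i == h2) (2 * i - 1):h else (2 * i - 1):(2 * i)
      cols <- if (j == w2) (2 * j - 1):w else (2 * j - 1):(2 * j)
      nxt[i, j] <- mean(lin[rows, cols])
    }
    lin <- nxt
  }
  total
}

# sample ENL of a pixel region
enl_of <- function(px) mean(px)^2 / mean((px - mean(px))^2)

# random ROI inside an h x w image
random_roi <- function(h, w, rw, rh) {
  list(x = sample.int(w - rw, 1) - 1, y = sample.int(h - rh, 1) - 1,
       w = rw, h = rh, role = "test", target_label = NA)
}
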