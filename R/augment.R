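# On-the-fly augmentation for training samples. All randomness comes from
# the calling RNG stream (train_model seeds it), keeping training
# deterministic under a fixed configuration seed.

# Bilinear rotation of a square matrix about its centre; out-of-extent
# pixels take `fill`.
rotate_bilinear <- function(m, angle, fill) {
  if (angle == 0) return(m)
  n <- nrow(m)
  c0 <- (n + 1) / 2
  idx <- seq_len(n) - c0
  X <- matrix(idx, n, n, byrow = TRUE)
  Y <- matrix(idx, n, n)
  # inverse mapping: sample source at the back-rotated target coordinate
  xs <- cos(angle) * X + sin(angle) * Y + c0
  ys <- -sin(angle) * X + cos(angle) * Y + c0
  i0 <- floor(ys)
  j0 <- floor(xs)
  fi <- ys - i0
  fj <- xs - j0
  ok <- i0 >= 1 & i0 < n & j0 >= 1 & j0 < n
  i0c <- pmin(pmax(i0, 1), n - 1)
  j0c <- pmin(pmax(j0, 1), n - 1)
  g <- function(di, dj) m[cbind(as.vector(i0c + di), as.vector(j0c + dj))]
  out <- (1 - fi) * (1 - fj) * g(0, 0) + (1 - fi) * fj * g(0, 1) +
    fi * (1 - fj) * g(1, 0) + fi * fj * g(1, 1)
  out[!ok] <- fill
  matrix(out, n, n)
}

# Integer translation with fill.
translate_fill <- function(m, di, dj, fill) {
  if (di == 0 && dj == 0) return(m)
  n <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, n, w)
  si <- seq_len(n) - di
  sj <- seq_len(w) - dj
  oki <- si >= 1 & si <= n
  okj <- sj >= 1 & sj <= w
  out[which(oki), which(okj)] <- m[si[oki], sj[okj]]
  out
}

# Apply one random augmentation draw to a (HU plane, logical mask) pair.
augment_sample <- function(values, mask, cfg) {
  stopifnot(inherits(cfg, "augmentation_config"))
  mnum <- mask * 1.0
  if (cfg$flip_horizontal && runif(1) < 0.5) {
    values <- values[, rev(seq_len(ncol(values)))]
    mnum <- mnum[, rev(seq_len(ncol(mnum)))]
  }
  if (cfg$flip_vertical && runif(1) < 0.5) {
    values <- values[rev(seq_len(nrow(values))), ]
    mnum <- mnum[rev(seq_len(nrow(mnum))), ]
  }
  if (cfg$rotation_max > 0) {
    ang <- runif(1, -cfg$rotation_max, cfg$rotation_max) * pi / 180
    values <- rotate_bilinear(values, ang, fill = -1024)
    mnum <- rotate_bilinear(mnum, ang, fill = 0)
  }
  if (cfg$translation_max > 0) {
    di <- sample.int(2 * cfg$translation_max + 1L, 1) - cfg$translation_max - 1L
    dj <- sample.int(2 * cfg$translation_max + 1L, 1) - cfg$translation_max - 1L
    values <- translate_fill(values, di, dj, fill = -1024)
    mnum <- translate_fill(mnum, di, dj, fill = 0)
  }
  if (cfg$intensity_shift_sd > 0) {
    values <- values + rnorm(1, 0, cfg$intensity_shift_sd)
  }
  list(values = values, mask = mnum >= 0.5)
}
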