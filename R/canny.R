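# Canny edge detection on small rasters: Gaussian smoothing, Sobel
# gradients, non-maximum suppression, hysteresis. Written for [0, 1]
# probability maps; gradients are per-pixel derivatives (Sobel / 8), so a
# unit step blurred at sigma = 1 px peaks near 0.4.

# shift with edge replication (used for smoothing/gradients)
shift_clamp <- function(m, di, dj) {
  n <- nrow(m)
  w <- ncol(m)
  m[pmin(pmax(seq_len(n) - di, 1), n), pmin(pmax(seq_len(w) - dj, 1), w)]
}

# shift with zero fill (used for NMS neighbour comparison)
shift_zero <- function(m, di, dj) {
  n <- nrow(m)
  w <- ncol(m)
  out <- matrix(0, n, w)
  si <- seq_len(n) - di
  sj <- seq_len(w) - dj
  oki <- si >= 1 & si <= n
  okj <- sj >= 1 & sj <= w
  out[which(oki), which(okj)] <- m[si[oki], sj[okj]]
  out
}

gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (o in -r:r) out <- out + k[o + r + 1] * shift_clamp(m, o, 0)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (o in -r:r) out <- out + k[o + r + 1] * shift_clamp(m2, 0, o)
  out
}

sobel_gradients <- function(m) {
  e <- shift_clamp(m, 0, -1)   # value of pixel (i, j+1) ... shifted into (i,j)
  w <- shift_clamp(m, 0, 1)
  n <- shift_clamp(m, 1, 0)
  s <- shift_clamp(m, -1, 0)
  ne <- shift_clamp(m, 1, -1)
  nw <- shift_clamp(m, 1, 1)
  se <- shift_clamp(m, -1, -1)
  sw <- shift_clamp(m, -1, 1)
  gx <- (ne + 2 * e + se - nw - 2 * w - sw) / 8
  gy <- (se + 2 * s + sw - ne - 2 * n - nw) / 8
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detection
#'
#' @param values Numeric matrix (typically a probability map in `[0, 1]`).
#' @param sigma Gaussian smoothing SD, pixels.
#' @param low,high Hysteresis thresholds on the gradient magnitude.
#' @return Logical edge matrix.
#' @export
canny_edges <- function(values, sigma = 1, low = 0.1, high = 0.2) {
  sm <- gaussian_blur(values, sigma)
  g <- sobel_gradients(sm)
  # quantize the gradient direction into 4 sectors and keep local maxima
  q <- ((round(atan2(g$gy, g$gx) * 4 / pi) %% 4) + 4) %% 4
  nb <- list(
    list(c(0, 1), c(0, -1)),    # gradient along x
    list(c(1, 1), c(-1, -1)),   # diagonal
    list(c(1, 0), c(-1, 0)),    # along y
    list(c(1, -1), c(-1, 1))    # anti-diagonal
  )
  keep <- matrix(FALSE, nrow(values), ncol(values))
  for (d in 0:3) {
    n1 <- shift_zero(g$mag, -nb[[d + 1]][[1]][1], -nb[[d + 1]][[1]][2])
    n2 <- shift_zero(g$mag, -nb[[d + 1]][[2]][1], -nb[[d + 1]][[2]][2])
    keep <- keep | (q == d & g$mag >= n1 & g$mag >= n2)
  }
  nms <- g$mag * keep
  strong <- nms >= high
  weak <- nms >= low
  # grow strong edges through connected weak pixels
  repeat {
    dil <- strong
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di || dj) dil <- dil | shift_zero(strong, di, dj) > 0
      }
    }
    nxt <- weak & dil
    if (identical(nxt, strong)) break
    strong <- nxt
  }
  strong
}
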