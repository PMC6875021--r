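#' Annulus measurement (area and perimeter)
#'
#' @param area Area, mm^2 (> 0).
#' @param perimeter Perimeter, mm (> 0). Must satisfy the isoperimetric
#'   inequality `perimeter^2 >= 4 * pi * area`.
#' @return Object of class `measurement`.
#' @export
measurement <- function(area, perimeter) {
  if (!is_scalar_num(area) || area <= 0) {
    stop_invariant("`area` must be a positive scalar (mm^2)")
  }
  if (!is_scalar_num(perimeter) || perimeter <= 0) {
    stop_invariant("`perimeter` must be a positive scalar (mm)")
  }
  if (perimeter^2 < 4 * pi * area * (1 - 1e-9)) {
    stop_invariant("isoperimetric inequality violated: pathological contour")
  }
  structure(list(area = area, perimeter = perimeter), class = "measurement")
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf("<measurement> area %.2f mm^2, perimeter %.2f mm\n",
              x$area, x$perimeter))
  invisible(x)
}

#' Area and perimeter of a closed contour
#'
#' Area by the shoelace formula (absolute value), perimeter as the closed
#' polyline arc length, both in the mm frame of the contour.
#'
#' @param contour An [annulus_contour()].
#' @return A [measurement()].
#' @export
measure_contour <- function(contour) {
  contour <- annulus_contour(contour)
  x <- contour[, 1]
  y <- contour[, 2]
  n <- length(x)
  nx <- c(x[-1], x[1])
  ny <- c(y[-1], y[1])
  area <- abs(sum(x * ny - nx * y)) / 2
  if (area <= 0) stop_invariant("degenerate (zero-area) contour")
  perimeter <- sum(sqrt((nx - x)^2 + (ny - y)^2))
  measurement(area, perimeter)
}

shoelace_signed <- function(x, y) {
  nx <- c(x[-1], x[1])
  ny <- c(y[-1], y[1])
  sum(x * ny - nx * y) / 2
}

# circular moving average of contour vertices
smooth_closed <- function(xy, window) {
  if (window <= 1) return(xy)
  n <- nrow(xy)
  if (n <= window) return(xy)
  r <- (window - 1) %/% 2
  out <- xy * 0
  for (o in -r:r) {
    idx <- ((seq_len(n) - 1 + o) %% n) + 1
    out <- out + xy[idx, , drop = FALSE]
  }
  out / (2 * r + 1)
}

#' Fuse the two resolution probability maps
#'
#' Resamples the coarse map bilinearly onto the fine grid over the shared
#' extent and combines the two maps. `"mean"` (default) averages and
#' clamps to `[0, 1]`; `"minmax"` first rescales each map to `[0, 1]` by
#' its own min/max, then averages. The output lives on the fine grid.
#' Fusion is symmetric in its two inputs once both live on the fine grid.
#'
#' @param coarse [probability_map()] at the coarse resolution.
#' @param fine [probability_map()] at the fine resolution; its extent must
#'   lie inside the coarse extent and the two maps must be concentric.
#' @param mode `"mean"` or `"minmax"`.
#' @return A [probability_map()] on the fine grid.
#' @export
fuse_probability_maps <- function(coarse, fine, mode = c("mean", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(coarse, "probability_map"), inherits(fine, "probability_map"))
  if (fine$spacing[1] >= coarse$spacing[1]) {
    stop_invariant("`fine` must have smaller spacing than `coarse`")
  }
  centre_of <- function(m) {
    m$origin + (c(ncol(m$values), nrow(m$values)) - 1) / 2 * m$spacing
  }
  if (any(abs(centre_of(coarse) - centre_of(fine)) > coarse$spacing[1] + 1e-9)) {
    stop_invariant("probability map grids are not concentric")
  }
  cc <- plane_coords(fine)
  ext_x <- range(plane_coords(coarse)$x)
  ext_y <- range(plane_coords(coarse)$y)
  if (min(cc$x) < ext_x[1] - 1e-9 || max(cc$x) > ext_x[2] + 1e-9 ||
      min(cc$y) < ext_y[1] - 1e-9 || max(cc$y) > ext_y[2] + 1e-9) {
    stop_invariant("fine map extends beyond the coarse map extent")
  }
  # bilinear sample of the coarse map at the fine pixel centres
  sx <- coarse$spacing[1]
  sy <- coarse$spacing[2]
  jx <- (cc$x - coarse$origin[1]) / sx  # 0-based fractional column
  iy <- (cc$y - coarse$origin[2]) / sy
  j0 <- pmin(pmax(floor(jx), 0), ncol(coarse$values) - 2)
  i0 <- pmin(pmax(floor(iy), 0), nrow(coarse$values) - 2)
  fj <- jx - j0
  fi <- iy - i0
  h <- nrow(fine$values)
  w <- ncol(fine$values)
  I0 <- matrix(i0 + 1, h, w)
  J0 <- matrix(j0 + 1, h, w, byrow = TRUE)
  FI <- matrix(fi, h, w)
  FJ <- matrix(fj, h, w, byrow = TRUE)
  g <- function(di, dj) {
    matrix(coarse$values[cbind(as.vector(I0 + di), as.vector(J0 + dj))], h, w)
  }
  cvals <- (1 - FI) * (1 - FJ) * g(0, 0) + (1 - FI) * FJ * g(0, 1) +
    FI * (1 - FJ) * g(1, 0) + FI * FJ * g(1, 1)
  fvals <- fine$values
  if (mode == "minmax") {
    rescale <- function(v) {
      r <- range(v)
      if (r[2] - r[1] < 1e-12) v * 0 else (v - r[1]) / (r[2] - r[1])
    }
    cvals <- rescale(cvals)
    fvals <- rescale(fvals)
  }
  fused <- pmin(pmax((cvals + fvals) / 2, 0), 1)
  probability_map(fused, fine$spacing, fine$origin)
}

#' Extract the annulus contour from a probability map
#'
#' Runs canny edge detection on the probability map and links each
#' 8-connected edge component into a polygon by angular-sector radial
#' averaging: the component's pixels are partitioned into equal angular
#' sectors about their centroid and each occupied sector contributes one
#' vertex at the mean position of its pixels. This collapses double edges
#' and pixel staircase jitter, so vertices trace the mid-boundary. A
#' component whose occupied sectors cover less than `min_coverage` of the
#' full circle is an open trace (e.g. an arc cut by the image border) and
#' is rejected. Among the closed loops, the one enclosing the greatest
#' area is returned as a counterclockwise polygon in mm.
#'
#' @param prob A [probability_map()] containing at least one value >= 0.5.
#' @param sigma,low,high Canny parameters (see [canny_edges()]).
#' @param smooth_window Odd vertex-smoothing window applied after linking
#'   (default 1 = disabled: the sector averaging already denoises, and
#'   further smoothing of an inscribed polygon biases area/perimeter low).
#' @param min_coverage Minimum fraction of angular sectors that must be
#'   occupied for a loop to count as closed.
#' @return An [annulus_contour()].
#' @export
extract_contour <- function(prob, sigma = 1, low = 0.1, high = 0.2,
                            smooth_window = 1, min_coverage = 0.9) {
  stopifnot(inherits(prob, "probability_map"))
  if (!any(prob$values >= 0.5)) {
    stop_invariant("no annulus detected (no probability >= 0.5)")
  }
  edges <- canny_edges(prob$values, sigma = sigma, low = low, high = high)
  if (!any(edges)) {
    stop_invariant("open contour (no edges found by canny)")
  }
  lab <- cpp_label_components(edges)
  best <- NULL
  best_area <- -Inf
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l, arr.ind = TRUE)
    if (nrow(pix) < 8) next
    # mm coordinates of the edge pixels
    x <- prob$origin[1] + (pix[, 2] - 1) * prob$spacing[1]
    y <- prob$origin[2] + (pix[, 1] - 1) * prob$spacing[2]
    cx <- mean(x)
    cy <- mean(y)
    ang <- atan2(y - cy, x - cx)
    # one vertex per occupied angular sector (mean of its pixels); sector
    # count scales with the component size so each sector holds a few
    # pixels even for small loops
    n_bins <- max(16L, min(72L, nrow(pix) %/% 4L))
    bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins), n_bins - 1)
    if (length(unique(bin)) / n_bins < min_coverage) next  # open trace
    bx <- tapply(x, bin, mean)
    by <- tapply(y, bin, mean)
    ord <- order(as.numeric(names(bx)))
    vx <- as.numeric(bx[ord])
    vy <- as.numeric(by[ord])
    area <- abs(shoelace_signed(vx, vy))
    if (area > best_area) {
      best_area <- area
      best <- cbind(vx, vy)
    }
  }
  if (is.null(best)) {
    stop_invariant("open contour (no closable edge loop)")
  }
  if (shoelace_signed(best[, 1], best[, 2]) < 0) {
    best <- best[rev(seq_len(nrow(best))), ]
  }
  for (w in unique(c(smooth_window, 2 * smooth_window + 1))) {
    sm <- smooth_closed(best, w)
    if (cpp_polygon_simple(sm[, 1], sm[, 2])) {
      return(annulus_contour(sm, check_simple = FALSE))
    }
  }
  stop_invariant("open contour (edge trace does not form a simple polygon)")
}

#' End-to-end annulus detection on one raw plane
#'
#' Composes the pipeline: dual-resolution preprocessing, prediction with
#' both models, probability fusion, contour extraction and measurement.
#' All intermediates are returned for audit. Deterministic given fixed
#' weights; errors name the stage that raised them.
#'
#' @param plane A raw [annular_plane()] (pre-resampling) with
#'   annulus-centre metadata.
#' @param model_coarse Trained model at the coarse (1.0 mm) resolution.
#' @param model_fine Trained model at the fine (0.5 mm) resolution.
#' @param fusion `"mean"` or `"minmax"` (see [fuse_probability_maps()]).
#' @param ... Passed to [extract_contour()].
#' @return List of class `annulus_detection` with elements `probability`
#'   (fused map), `contour`, `measurement`, and `intermediates` (prepared
#'   planes and per-model maps).
#' @export
detect <- function(plane, model_coarse, model_fine,
                   fusion = c("mean", "minmax"), ...) {
  fusion <- match.arg(fusion)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("detect[%s]: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  prep <- stage("preprocess", prepare_sample(
    plane, spacings = c(model_coarse$resolution, model_fine$resolution)
  ))
  p_coarse <- stage("predict_coarse", predict_map(model_coarse, prep[[1]]$plane))
  p_fine <- stage("predict_fine", predict_map(model_fine, prep[[2]]$plane))
  fused <- stage("fuse", fuse_probability_maps(p_coarse, p_fine, mode = fusion))
  contour <- stage("contour", extract_contour(fused, ...))
  meas <- stage("measure", measure_contour(contour))
  structure(
    list(
      probability = fused, contour = contour, measurement = meas,
      intermediates = list(
        plane_coarse = prep[[1]]$plane, plane_fine = prep[[2]]$plane,
        prob_coarse = p_coarse, prob_fine = p_fine
      )
    ),
    class = "annulus_detection"
  )
}

#' @export
print.annulus_detection <- function(x, ...) {
  cat(sprintf("<annulus_detection> area %.2f mm^2, perimeter %.2f mm\n",
              x$measurement$area, x$measurement$perimeter))
  invisible(x)
}
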