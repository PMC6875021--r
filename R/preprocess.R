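#' Binary segmentation mask
#'
#' Logical raster on the same grid contract as [annular_plane()].
#'
#' @param values Logical matrix.
#' @param spacing,origin Grid geometry as in [annular_plane()].
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.logical(values) || any(dim(values) == 0L)) {
    stop_invariant("mask `values` must be a non-empty logical matrix")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

#' Area of a binary mask
#'
#' Pixel count times pixel area.
#'
#' @param mask A [binary_mask()].
#' @return Area in mm^2.
#' @export
mask_area <- function(mask) {
  sum(mask$values) * prod(mask$spacing)
}

#' Resample a plane to an isotropic grid
#'
#' Separable cubic-spline interpolation (exact on constant and affine
#' rasters), preserving the original Hounsfield units. The output grid
#' starts at the input origin and covers the input extent at
#' `target_spacing`. The origin and annulus centre are unchanged in mm
#' coordinates. No extrapolation is performed: the output extent never
#' exceeds the input extent (padding, where needed, happens at the clip
#' step).
#'
#' @param plane An [annular_plane()] (possibly anisotropic).
#' @param target_spacing Target isotropic spacing, mm/pixel.
#' @return An [annular_plane()] at `target_spacing`.
#' @export
resample_plane <- function(plane, target_spacing = 1.0) {
  stopifnot(inherits(plane, "annular_plane"))
  if (!is_scalar_num(target_spacing) || target_spacing <= 0) {
    stop_invariant("`target_spacing` must be positive")
  }
  v <- plane$values
  if (nrow(v) < 4L || ncol(v) < 4L) {
    stop_invariant("raster smaller than 4 x 4: cubic spline underdetermined")
  }
  sx <- plane$spacing[1]
  sy <- plane$spacing[2]
  if (abs(sx - target_spacing) < 1e-12 && abs(sy - target_spacing) < 1e-12) {
    return(plane)
  }
  xs <- plane$origin[1] + (seq_len(ncol(v)) - 1) * sx
  ys <- plane$origin[2] + (seq_len(nrow(v)) - 1) * sy
  xs_new <- seq(xs[1], xs[length(xs)] + 1e-9, by = target_spacing)
  ys_new <- seq(ys[1], ys[length(ys)] + 1e-9, by = target_spacing)
  # along x (within each row), then along y (within each column)
  tmp <- t(apply(v, 1, function(row) {
    spline(xs, row, xout = xs_new, method = "fmm")$y
  }))
  out <- apply(tmp, 2, function(col) {
    spline(ys, col, xout = ys_new, method = "fmm")$y
  })
  out <- matrix(out, nrow = length(ys_new), ncol = length(xs_new))
  annular_plane(out, target_spacing, plane$origin, plane$center)
}

#' Clip a plane to a fixed window around the annulus centre
#'
#' Extracts a `size_px x size_px` window such that the source pixel
#' nearest the annulus centre lands at index `size_px / 2` (0-based) in
#' both dimensions. Regions outside the source extent are padded with
#' -1024 HU (air). The annulus centre is retained in the output mm frame.
#' Clipping is idempotent.
#'
#' @param plane An isotropic [annular_plane()].
#' @param size_px Output window size in pixels (even).
#' @return A `size_px x size_px` [annular_plane()].
#' @export
clip_plane <- function(plane, size_px = 128L) {
  stopifnot(inherits(plane, "annular_plane"))
  if (!is_isotropic(plane)) {
    stop_invariant("clip_plane requires an isotropically spaced plane")
  }
  if (!is_count(size_px) || size_px < 2 || size_px %% 2 != 0) {
    stop_invariant("`size_px` must be a positive even count")
  }
  s <- plane$spacing[1]
  half <- size_px / 2
  # 0-based index of the source pixel nearest the annulus centre
  jc <- round((plane$center[1] - plane$origin[1]) / s)
  ic <- round((plane$center[2] - plane$origin[2]) / s)
  out <- matrix(-1024, size_px, size_px)
  src_i <- (ic - half):(ic + half - 1)  # 0-based source rows
  src_j <- (jc - half):(jc + half - 1)
  ok_i <- src_i >= 0 & src_i < nrow(plane$values)
  ok_j <- src_j >= 0 & src_j < ncol(plane$values)
  if (any(ok_i) && any(ok_j)) {
    out[which(ok_i), which(ok_j)] <-
      plane$values[src_i[ok_i] + 1, src_j[ok_j] + 1]
  }
  origin <- c(
    plane$origin[1] + (jc - half) * s,
    plane$origin[2] + (ic - half) * s
  )
  annular_plane(out, s, origin, plane$center)
}

#' Rasterize a contour into a binary mask
#'
#' A pixel is inside iff its centre lies inside the polygon under the
#' even-odd rule.
#'
#' @param contour An [annulus_contour()] (closed, simple, >= 3 distinct
#'   vertices).
#' @param grid An [annular_plane()] (or any object with `values`,
#'   `spacing`, `origin` grid fields, e.g. a [probability_map()])
#'   supplying the target grid.
#' @return A [binary_mask()] aligned with `grid`.
#' @export
rasterize_mask <- function(contour, grid) {
  contour <- annulus_contour(contour)  # validates
  if (!all(c("values", "spacing", "origin") %in% names(grid))) {
    stop_invariant("`grid` must carry values/spacing/origin fields")
  }
  cc <- plane_coords(grid)
  h <- nrow(grid$values)
  w <- ncol(grid$values)
  px <- rep(cc$x, each = h)
  py <- rep(cc$y, times = w)
  inside <- cpp_points_in_polygon(px, py, contour[, 1], contour[, 2])
  binary_mask(matrix(inside, h, w), grid$spacing, grid$origin)
}

#' Prepare the dual-resolution network inputs
#'
#' Resamples and clips a raw annular plane to the two network resolutions
#' (by default 1.0 mm and 0.5 mm, both `size_px` wide, so the fine plane
#' covers the central quarter of the coarse field of view) and, when a
#' ground-truth contour is supplied, rasterizes the matching binary masks.
#'
#' @param plane A raw [annular_plane()] with annulus-centre metadata.
#' @param contour Optional [annulus_contour()] ground truth.
#' @param spacings Numeric vector of target spacings, mm (coarse first).
#' @param size_px Window size at each resolution.
#' @return List of per-resolution lists, named `r<spacing>` (e.g. `r1`,
#'   `r0.5`), each with elements `plane` and `mask` (`NULL` without a
#'   contour).
#' @export
prepare_sample <- function(plane, contour = NULL,
                           spacings = c(1.0, 0.5), size_px = 128L) {
  out <- lapply(spacings, function(sp) {
    clipped <- clip_plane(resample_plane(plane, sp), size_px)
    mask <- if (!is.null(contour)) rasterize_mask(contour, clipped)
    list(plane = clipped, mask = mask)
  })
  names(out) <- paste0("r", spacings)
  out
}

#' Standardize HU values for network input
#'
#' Clamps to `[-1024, 1500]` HU then maps linearly to `[-1, 1]`.
#'
#' @param values Numeric matrix or vector of HU.
#' @return Standardized values, same shape.
#' @export
standardize_hu <- function(values) {
  v <- pmin(pmax(values, -1024), 1500)
  (v + 1024) / (1500 + 1024) * 2 - 1
}
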