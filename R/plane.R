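#' Aortic annular plane raster
#'
#' The basic image container of the pipeline: a 2-D raster of Hounsfield
#' units (HU) on a regular grid, together with its pixel spacing, the mm
#' coordinates of the first pixel centre, and the mm coordinates of the
#' aortic annulus centre. Matrix rows run along y, columns along x: pixel
#' `(i, j)` (1-based) has centre
#' `origin + ((j - 1) * spacing_x, (i - 1) * spacing_y)`.
#'
#' @param values Numeric matrix of HU values.
#' @param spacing Pixel spacing in mm/pixel; a scalar for isotropic grids or
#'   a length-2 vector `(x, y)`.
#' @param origin Length-2 numeric, mm coordinates `(x, y)` of the centre of
#'   pixel `(1, 1)`.
#' @param center Length-2 numeric, mm coordinates of the annulus centre.
#' @return An object of class `annular_plane`.
#' @export
annular_plane <- function(values, spacing, origin = c(0, 0), center = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values) || any(dim(values) == 0L)) {
    stop_invariant("`values` must be a non-empty numeric matrix")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_invariant("`spacing` must be positive (mm/pixel)")
  }
  origin <- as.numeric(origin)
  center <- as.numeric(center)
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop_invariant("`origin` must be two finite mm coordinates")
  }
  if (length(center) != 2L || any(!is.finite(center))) {
    stop_invariant("`annulus_center` must be two finite mm coordinates")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, center = center),
    class = "annular_plane"
  )
}

#' @export
print.annular_plane <- function(x, ...) {
  cat(sprintf(
    "<annular_plane> %d x %d px, spacing %.3g x %.3g mm, annulus centre (%.2f, %.2f) mm\n",
    nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
    x$center[1], x$center[2]
  ))
  invisible(x)
}

is_isotropic <- function(plane, tol = 1e-9) {
  abs(plane$spacing[1] - plane$spacing[2]) <= tol * max(plane$spacing)
}

#' Pixel-centre coordinates of a plane
#'
#' @param plane An [annular_plane()] (or any object with the same grid
#'   fields, e.g. a probability map or mask).
#' @return List with numeric vectors `x` (length `ncol`) and `y`
#'   (length `nrow`) of pixel-centre mm coordinates.
#' @export
plane_coords <- function(plane) {
  list(
    x = plane$origin[1] + (seq_len(ncol(plane$values)) - 1) * plane$spacing[1],
    y = plane$origin[2] + (seq_len(nrow(plane$values)) - 1) * plane$spacing[2]
  )
}

#' Closed annulus contour polygon
#'
#' An ordered, closed polygon in mm coordinates (first vertex not
#' repeated; closure is implicit). Vertices are stored as an `n x 2`
#' matrix with columns `x_mm`, `y_mm`.
#'
#' @param vertices Numeric `n x 2` matrix (or data frame) of mm coordinates.
#' @param check_simple Verify that the polygon does not self-intersect.
#' @return An object of class `annulus_contour`.
#' @export
annulus_contour <- function(vertices, check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L) {
    stop_invariant("contour vertices must be an n x 2 numeric matrix")
  }
  if (any(!is.finite(vertices))) {
    stop_invariant("contour vertices must be finite")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
  }
  if (nrow(unique(vertices)) < 3L) {
    stop_invariant("contour must have at least 3 distinct vertices")
  }
  if (check_simple && !cpp_polygon_simple(vertices[, 1], vertices[, 2])) {
    stop_invariant("contour is self-intersecting")
  }
  colnames(vertices) <- c("x_mm", "y_mm")
  structure(vertices, class = c("annulus_contour", "matrix", "array"))
}

#' @export
print.annulus_contour <- function(x, ...) {
  cat(sprintf("<annulus_contour> %d vertices (closed)\n", nrow(x)))
  invisible(x)
}

plane_sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$|\\.png$", "", path), ".json")
}

#' Write an annular plane to disk
#'
#' NIfTI output (`.nii` / `.nii.gz`) stores the raster and pixel spacing in
#' the NIfTI header; 16-bit PNG output stores HU shifted by `hu_offset`.
#' Both carry a JSON sidecar `<base>.json` with the grid metadata
#' (`spacing_mm`, `origin_mm`, `annulus_center_mm`, and for PNG
#' `hu_offset`).
#'
#' @param plane An [annular_plane()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.png`.
#' @param hu_offset Offset added to HU before 16-bit PNG encoding.
#' @return `path`, invisibly.
#' @export
write_plane <- function(plane, path, hu_offset = 1024) {
  meta <- list(
    spacing_mm = plane$spacing,
    origin_mm = plane$origin,
    annulus_center_mm = plane$center
  )
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(plane$values, pixdim = plane$spacing)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.png$", path)) {
    meta$hu_offset <- hu_offset
    v <- plane$values + hu_offset
    if (any(v < 0) || any(v >= 65536)) {
      stop_invariant("HU values out of 16-bit PNG range for this hu_offset")
    }
    png::writePNG(v / 65535, path, dpi = NULL)
  } else {
    stop_invariant("unsupported plane format: ", path)
  }
  jsonlite::write_json(meta, plane_sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an annular plane written by [write_plane()]
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.png` plane file with its
#'   JSON sidecar alongside.
#' @return An [annular_plane()].
#' @export
read_plane <- function(path) {
  sidecar <- plane_sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop_invariant("missing JSON sidecar: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    values <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else if (grepl("\\.png$", path)) {
    values <- png::readPNG(path) * 65535 - meta$hu_offset
  } else {
    stop_invariant("unsupported plane format: ", path)
  }
  annular_plane(values, meta$spacing_mm, meta$origin_mm, meta$annulus_center_mm)
}

#' Write / read contour CSV
#'
#' Plain CSV with header `x_mm,y_mm`, one vertex per row, closure implicit.
#'
#' @param contour An [annulus_contour()].
#' @param path CSV path.
#' @return `path` (write) or an [annulus_contour()] (read).
#' @export
write_contour_csv <- function(contour, path) {
  write.csv(as.data.frame(unclass(contour)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    stop_invariant("contour CSV must have columns x_mm,y_mm")
  }
  annulus_contour(as.matrix(df[, c("x_mm", "y_mm")]))
}
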