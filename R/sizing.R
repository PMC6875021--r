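#' Prosthesis sizing chart
#'
#' An ordered sequence of contiguous, non-overlapping half-open bands
#' `[lower, upper)` mapping a measured parameter (annulus area in mm^2 or
#' perimeter in mm) to a device size label. Contiguity (no overlaps, no
#' gaps) follows the manufacturers' guidance of leaving interpretation of
#' borderline values to the physician rather than proposing two sizes.
#'
#' @param device_family Device family label (e.g. `"Edwards Sapien 3"`).
#' @param parameter `"area_mm2"` or `"perimeter_mm"`.
#' @param bands Data frame with columns `lower`, `upper`, `size` (ordered
#'   or orderable by `lower`).
#' @return Object of class `sizing_chart`.
#' @export
sizing_chart <- function(device_family, parameter, bands) {
  parameter <- match.arg(parameter, c("area_mm2", "perimeter_mm"))
  bands <- as.data.frame(bands)
  if (!all(c("lower", "upper", "size") %in% names(bands)) || nrow(bands) < 1) {
    stop_invariant("`bands` needs columns lower, upper, size")
  }
  bands <- bands[order(bands$lower), , drop = FALSE]
  bands$size <- as.character(bands$size)
  if (any(bands$lower >= bands$upper)) {
    bad <- which(bands$lower >= bands$upper)[1]
    stop_invariant(sprintf("band '%s' has lower >= upper", bands$size[bad]))
  }
  if (nrow(bands) > 1) {
    for (i in seq_len(nrow(bands) - 1)) {
      lo_next <- bands$lower[i + 1]
      up_this <- bands$upper[i]
      if (lo_next < up_this) {
        stop_invariant(sprintf(
          "overlapping bands: '%s' [%g, %g) and '%s' [%g, %g)",
          bands$size[i], bands$lower[i], up_this,
          bands$size[i + 1], lo_next, bands$upper[i + 1]
        ))
      }
      if (lo_next > up_this) {
        stop_invariant(sprintf(
          "gap between bands: '%s' [%g, %g) and '%s' [%g, %g)",
          bands$size[i], bands$lower[i], up_this,
          bands$size[i + 1], lo_next, bands$upper[i + 1]
        ))
      }
    }
  }
  rownames(bands) <- NULL
  structure(
    list(device_family = device_family, parameter = parameter, bands = bands),
    class = "sizing_chart"
  )
}

#' @export
print.sizing_chart <- function(x, ...) {
  cat(sprintf("<sizing_chart> %s (%s), %d bands [%g, %g)\n",
              x$device_family, x$parameter, nrow(x$bands),
              min(x$bands$lower), max(x$bands$upper)))
  invisible(x)
}

#' Load a sizing chart from YAML
#'
#' Expected layout: `device_family`, `parameter` (`area_mm2` or
#' `perimeter_mm`) and `bands`, a list of `{lower, upper, size}` entries.
#' Charts violating the contiguity/non-overlap invariants are rejected
#' with a message naming the offending band pair.
#'
#' @param path YAML chart file.
#' @return A [sizing_chart()].
#' @export
load_chart <- function(path) {
  if (!file.exists(path)) stop_invariant("chart file not found: ", path)
  y <- yaml::read_yaml(path)
  bands <- do.call(rbind, lapply(y$bands, function(b) {
    data.frame(lower = b$lower, upper = b$upper, size = as.character(b$size))
  }))
  sizing_chart(y$device_family, y$parameter, bands)
}

#' Bundled default sizing charts
#'
#' Paths to the non-overlapping default charts shipped with the package:
#' annulus-area bands for the balloon-expandable Edwards Sapien 3 and
#' annulus-perimeter bands for the self-expanding Medtronic Evolut. The
#' numeric bands are transcriptions from publicly available manufacturer
#' sizing documents, provided as editable defaults; they are configuration
#' data, not validated clinical ground truth.
#'
#' @param device `"sapien3"` or `"evolut"`.
#' @return Path to the bundled YAML chart.
#' @export
default_chart_path <- function(device = c("sapien3", "evolut")) {
  device <- match.arg(device)
  system.file("extdata",
              paste0(device, "_chart.yaml"),
              package = "tavisize", mustWork = TRUE)
}

#' Select a device size for a measured value
#'
#' Returns the unique band whose half-open interval `[lower, upper)`
#' contains `value`; values below every band give `OUT_OF_RANGE_LOW`, at
#' or above the top give `OUT_OF_RANGE_HIGH`. Selection is monotone
#' non-decreasing in `value`.
#'
#' @param value Measured value (> 0), in the chart's parameter units.
#' @param chart A [sizing_chart()].
#' @return Object of class `device_selection` with fields
#'   `device_family`, `size_label`, `input_value`.
#' @export
select_size <- function(value, chart) {
  stopifnot(inherits(chart, "sizing_chart"))
  if (!is_scalar_num(value) || value <= 0) {
    stop_invariant("`value` must be a positive scalar")
  }
  b <- chart$bands
  label <- if (value < b$lower[1]) {
    "OUT_OF_RANGE_LOW"
  } else if (value >= b$upper[nrow(b)]) {
    "OUT_OF_RANGE_HIGH"
  } else {
    b$size[value >= b$lower & value < b$upper]
  }
  structure(
    list(device_family = chart$device_family, size_label = label,
         input_value = value),
    class = "device_selection"
  )
}

#' @export
print.device_selection <- function(x, ...) {
  cat(sprintf("<device_selection> %s: %s (input %.2f)\n",
              x$device_family, x$size_label, x$input_value))
  invisible(x)
}

#' Size one case for both device families
#'
#' Area selects the area-sized device (Sapien 3 chart), perimeter the
#' perimeter-sized device (Evolut chart). Out-of-range sentinels are
#' propagated, never coerced to a nearest size.
#'
#' @param meas A [measurement()].
#' @param sapien_chart Area-based [sizing_chart()].
#' @param evolut_chart Perimeter-based [sizing_chart()].
#' @return List with elements `sapien3` and `evolut`, each a
#'   `device_selection`.
#' @export
size_case <- function(meas, sapien_chart, evolut_chart) {
  stopifnot(inherits(meas, "measurement"))
  if (sapien_chart$parameter != "area_mm2") {
    stop_invariant("the area device chart must use parameter area_mm2")
  }
  if (evolut_chart$parameter != "perimeter_mm") {
    stop_invariant("the perimeter device chart must use parameter perimeter_mm")
  }
  list(
    sapien3 = select_size(meas$area, sapien_chart),
    evolut = select_size(meas$perimeter, evolut_chart)
  )
}
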