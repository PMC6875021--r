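#' Full agreement report for one paired series
#'
#' Combines the paired-difference summary, Bland-Altman limits of
#' agreement, Pearson correlation and a Shapiro-Wilk normality test of
#' the differences. Degenerate inputs (all differences zero) yield bias 0,
#' limits of agreement (0, 0), `wilcoxon_p = 1` and `NA` for the
#' statistics that are undefined on constant data.
#'
#' @param series A [paired_series()].
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  pd <- paired_difference(series)
  ba <- bland_altman(series)
  r <- tryCatch(pearson(series), error = function(e) NA_real_)
  sh <- tryCatch(shapiro_wilk(series$values_a - series$values_b)$p,
                 error = function(e) NA_real_)
  structure(
    list(
      label_a = series$label_a, label_b = series$label_b,
      n = length(series$values_a),
      mean_diff = pd$mean_diff, sd_diff = pd$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      pearson_r = r, wilcoxon_p = pd$wilcoxon_p, shapiro_p = sh,
      degenerate = pd$degenerate, pairs = ba$pairs
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_report> %s vs %s (n = %d)\n",
           "  paired diff %.3g +/- %.3g, LoA [%.3g, %.3g]\n",
           "  pearson r %.3f, wilcoxon p %.3g, shapiro p %.3g\n"),
    x$label_a, x$label_b, x$n, x$mean_diff, x$sd_diff,
    x$loa_low, x$loa_high, x$pearson_r, x$wilcoxon_p, x$shapiro_p
  ))
  invisible(x)
}

#' Evaluate a detection cohort against ground truth
#'
#' Matches the two measurement tables by `case_id` and produces the full
#' validation battery: agreement reports for area and perimeter, per-case
#' and mean Dice (when masks are supplied) and device-size agreement for
#' both device families (when charts are supplied).
#'
#' @param measurements_a,measurements_b Data frames with columns
#'   `case_id`, `area_mm2`, `perimeter_mm` (a = model, b = reference).
#' @param masks_a,masks_b Optional named lists of [binary_mask()] keyed by
#'   case id.
#' @param sapien_chart,evolut_chart Optional [sizing_chart()] objects.
#' @param label_a,label_b Source names for the reports.
#' @return Object of class `cohort_report`: list with `area`, `perimeter`
#'   ([agreement_report()]), `dice` (list with `mean` and `per_case`) and
#'   `sapien3` / `evolut` ([size_agreement()] results), plus `case_ids`.
#' @export
evaluate_cohort <- function(measurements_a, measurements_b,
                            masks_a = NULL, masks_b = NULL,
                            sapien_chart = NULL, evolut_chart = NULL,
                            label_a = "model", label_b = "observer1") {
  need <- c("case_id", "area_mm2", "perimeter_mm")
  for (df in list(measurements_a, measurements_b)) {
    if (!all(need %in% names(df))) {
      stop_invariant("measurement tables need columns ",
                     paste(need, collapse = ", "))
    }
  }
  ids_a <- as.character(measurements_a$case_id)
  ids_b <- as.character(measurements_b$case_id)
  unmatched <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(unmatched)) {
    stop_invariant("unmatched case ids: ", paste(unmatched, collapse = ", "))
  }
  mb <- measurements_b[match(ids_a, ids_b), ]
  out <- list(
    case_ids = ids_a,
    area = agreement_report(paired_series(
      measurements_a$area_mm2, mb$area_mm2, label_a, label_b
    )),
    perimeter = agreement_report(paired_series(
      measurements_a$perimeter_mm, mb$perimeter_mm, label_a, label_b
    ))
  )
  if (!is.null(masks_a) && !is.null(masks_b)) {
    dvals <- vapply(ids_a, function(id) {
      if (is.null(masks_a[[id]]) || is.null(masks_b[[id]])) {
        stop_invariant("missing mask for case ", id)
      }
      dice(masks_a[[id]], masks_b[[id]])
    }, 0)
    out$dice <- list(mean = mean(dvals), per_case = dvals)
  }
  if (!is.null(sapien_chart) && !is.null(evolut_chart)) {
    sel <- function(df) {
      lapply(seq_len(nrow(df)), function(i) {
        size_case(measurement(df$area_mm2[i], df$perimeter_mm[i]),
                  sapien_chart, evolut_chart)
      })
    }
    sa <- sel(measurements_a)
    sb <- sel(mb)
    out$sapien3 <- size_agreement(lapply(sa, `[[`, "sapien3"),
                                  lapply(sb, `[[`, "sapien3"))
    out$evolut <- size_agreement(lapply(sa, `[[`, "evolut"),
                                 lapply(sb, `[[`, "evolut"))
  }
  structure(out, class = "cohort_report")
}

report_to_list <- function(report) {
  num_fields <- c("n", "mean_diff", "sd_diff", "loa_low", "loa_high",
                  "pearson_r", "wilcoxon_p", "shapiro_p")
  strip <- function(ar) c(ar[num_fields], list(degenerate = ar$degenerate))
  out <- list(area = strip(report$area), perimeter = strip(report$perimeter))
  if (!is.null(report$dice)) {
    out$dice <- list(mean = report$dice$mean,
                     per_case = unname(report$dice$per_case))
  }
  for (dev in c("sapien3", "evolut")) {
    if (!is.null(report[[dev]])) {
      out[[dev]] <- list(
        ratio = report[[dev]]$ratio,
        n = report[[dev]]$n,
        n_under = report[[dev]]$n_under,
        n_over = report[[dev]]$n_over,
        confusion = as.data.frame(report[[dev]]$confusion)
      )
    }
  }
  out
}

#' Write a cohort report as JSON
#'
#' @param report A `cohort_report` from [evaluate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Bland-Altman plot
#'
#' Mean-difference scatter with bias and limits of agreement.
#'
#' @param report An [agreement_report()].
#' @param path Optional PNG path; when given, the plot is written there.
#' @param main Plot title.
#' @param units Axis unit label.
#' @return `path` (or `NULL` when plotting to the active device),
#'   invisibly.
#' @export
plot_bland_altman <- function(report, path = NULL, main = NULL, units = "") {
  stopifnot(inherits(report, "agreement_report"))
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  p <- report$pairs
  ylim <- range(c(p$diff, report$loa_low, report$loa_high))
  plot(p$mean, p$diff,
       xlab = paste("Mean of pair", units), ylab = paste("Difference", units),
       main = main %||% sprintf("Bland-Altman: %s vs %s",
                                report$label_a, report$label_b),
       pch = 19, col = "#00000088", ylim = ylim + c(-1, 1) * diff(ylim) * 0.05)
  graphics::abline(h = report$mean_diff, col = "blue")
  graphics::abline(h = c(report$loa_low, report$loa_high),
                   col = "red", lty = 2)
  invisible(path)
}

#' Correlation scatter plot of a paired series
#'
#' @param series A [paired_series()].
#' @param path Optional PNG path.
#' @param units Axis unit label.
#' @return `path`, invisibly.
#' @export
plot_scatter <- function(series, path = NULL, units = "") {
  stopifnot(inherits(series, "paired_series"))
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  plot(series$values_b, series$values_a,
       xlab = paste(series$label_b, units), ylab = paste(series$label_a, units),
       main = sprintf("r = %.3f", pearson(series)),
       pch = 19, col = "#00000088")
  graphics::abline(0, 1, col = "gray")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
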