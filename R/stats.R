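#' Paired measurement series
#'
#' Two equal-length sequences of per-case measurements from two sources
#' (e.g. model vs observer 1), the unit of every agreement analysis.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 3,
#'   finite).
#' @param label_a,label_b Source names.
#' @return Object of class `paired_series`.
#' @export
paired_series <- function(values_a, values_b,
                          label_a = "a", label_b = "b") {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) != length(values_b)) {
    stop_invariant("paired series must have equal length")
  }
  if (length(values_a) < 3) {
    stop_invariant("paired series needs at least 3 cases")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop_invariant("paired series must be finite")
  }
  structure(
    list(values_a = values_a, values_b = values_b,
         label_a = label_a, label_b = label_b),
    class = "paired_series"
  )
}

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b [binary_mask()] objects or logical matrices of identical
#'   shape, not both empty.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  va <- if (inherits(a, "binary_mask")) a$values else a
  vb <- if (inherits(b, "binary_mask")) b$values else b
  if (!is.logical(va) || !is.logical(vb)) {
    stop_invariant("dice() expects logical masks")
  }
  if (!all(dim(va) == dim(vb))) stop_invariant("mask shapes differ")
  s <- sum(va) + sum(vb)
  if (s == 0) stop_invariant("dice undefined: both masks empty")
  2 * sum(va & vb) / s
}

# Exact null distribution of the signed-rank statistic W+ for ranks
# 1..n (dynamic programme over the 2^n sign assignments).
signed_rank_null <- function(n) {
  f <- 1
  for (r in seq_len(n)) {
    g <- c(f, numeric(r)) + c(numeric(r), f)
    f <- g
  }
  f / 2^n  # density over W+ = 0 .. n(n+1)/2
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided test on `a - b`. Zeros are handled by Pratt's method (ranked
#' with the rest, then dropped from the statistic) and ties by average
#' ranks. The p-value is exact (full null distribution of the rank sum)
#' when there are no zeros or ties and `n <= exact_limit`; otherwise a
#' normal approximation with continuity, zero and tie corrections is used.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for the exact distribution.
#' @return List with `statistic` (W+), `p`, `exact` flag and `degenerate`
#'   flag (TRUE when every difference is zero, in which case `p = 1`).
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 25) {
  d <- as.numeric(d)
  if (length(d) < 1 || any(!is.finite(d))) {
    stop_invariant("differences must be finite and non-empty")
  }
  if (all(d == 0)) {
    return(list(statistic = 0, p = 1, exact = FALSE, degenerate = TRUE))
  }
  n <- length(d)
  r <- rank(abs(d))           # Pratt: zeros participate in the ranking
  w_plus <- sum(r[d > 0])
  n_zero <- sum(d == 0)
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n_zero == 0 && !has_ties && n <= exact_limit) {
    dens <- signed_rank_null(n)
    lower <- sum(dens[seq_len(w_plus + 1)])            # P(W <= w)
    upper <- sum(dens[(w_plus + 1):length(dens)])      # P(W >= w)
    mu <- n * (n + 1) / 4
    p <- if (w_plus > mu) min(1, 2 * upper) else min(1, 2 * lower)
    return(list(statistic = w_plus, p = p, exact = TRUE, degenerate = FALSE))
  }
  # normal approximation with Pratt zero correction and tie correction
  z <- n_zero
  mu <- (n * (n + 1) - z * (z + 1)) / 4
  tie_tab <- table(abs(d[d != 0]))
  sigma2 <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    return(list(statistic = w_plus, p = 1, exact = FALSE, degenerate = TRUE))
  }
  cc <- sign(w_plus - mu) * 0.5
  zstat <- (w_plus - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(zstat)))
  list(statistic = w_plus, p = p, exact = FALSE, degenerate = FALSE)
}

#' Paired difference summary
#'
#' Differences `a - b`: mean, sample SD (n - 1 denominator) and the
#' two-sided Wilcoxon signed-rank p-value.
#'
#' @param series A [paired_series()].
#' @return List with `mean_diff`, `sd_diff`, `wilcoxon_p`, `degenerate`.
#' @export
paired_difference <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$values_a - series$values_b
  w <- wilcoxon_signed_rank(d)
  list(
    mean_diff = mean(d),
    sd_diff = sd(d),
    wilcoxon_p = w$p,
    degenerate = w$degenerate
  )
}

#' Bland-Altman agreement analysis
#'
#' Per-pair means `(a + b) / 2` against differences `a - b`; bias is the
#' mean difference and the limits of agreement are
#' `bias +/- 1.96 * sd(differences)`.
#'
#' @param series A [paired_series()].
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high` and `pairs`
#'   (data frame of the plotted mean/difference pairs).
#' @export
bland_altman <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$values_a - series$values_b
  m <- (series$values_a + series$values_b) / 2
  bias <- mean(d)
  s <- sd(d)
  list(
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    pairs = data.frame(mean = m, diff = d)
  )
}

#' Pearson correlation of a paired series
#'
#' @param series A [paired_series()]; both sequences must be non-constant.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (sd(series$values_a) == 0 || sd(series$values_b) == 0) {
    stop_invariant("pearson undefined for constant series")
  }
  cor(series$values_a, series$values_b)
}

#' Shapiro-Wilk normality test
#'
#' Royston's AS R94 statistic and p-value (via [stats::shapiro.test()]).
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3 || length(values) > 5000) {
    stop_invariant("shapiro_wilk requires 3 <= n <= 5000")
  }
  if (sd(values) == 0) stop_invariant("shapiro_wilk undefined for constant input")
  r <- shapiro.test(values)
  list(statistic = unname(r$statistic), p = r$p.value)
}

size_label_rank <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  rank_val <- num
  rank_val[labels == "OUT_OF_RANGE_LOW"] <- -Inf
  rank_val[labels == "OUT_OF_RANGE_HIGH"] <- Inf
  if (any(is.na(rank_val))) {
    stop_invariant("unrecognized size labels: ",
                   paste(unique(labels[is.na(rank_val)]), collapse = ", "))
  }
  rank_val
}

#' Device-size agreement ratio and confusion table
#'
#' Fraction of exactly equal size labels between two selection sequences
#' of the same device family, with a full confusion table (sentinels
#' included) and under-/over-estimation counts from the label ordering
#' (`OUT_OF_RANGE_LOW` < numeric sizes < `OUT_OF_RANGE_HIGH`).
#'
#' @param selections_a,selections_b Equal-length lists of
#'   `device_selection` objects of the same family.
#' @return List with `ratio`, `confusion` (table, rows = a), `n_under`,
#'   `n_over` (a below/above b) and `n`.
#' @export
size_agreement <- function(selections_a, selections_b) {
  if (length(selections_a) == 0 || length(selections_a) != length(selections_b)) {
    stop_invariant("selection sequences must be non-empty and equal length")
  }
  fam_a <- unique(vapply(selections_a, `[[`, "", "device_family"))
  fam_b <- unique(vapply(selections_b, `[[`, "", "device_family"))
  if (length(fam_a) != 1 || !identical(fam_a, fam_b)) {
    stop_invariant("device family mismatch between selection sequences")
  }
  la <- vapply(selections_a, `[[`, "", "size_label")
  lb <- vapply(selections_b, `[[`, "", "size_label")
  lev <- unique(c(la, lb))
  lev <- lev[order(size_label_rank(lev))]
  ra <- size_label_rank(la)
  rb <- size_label_rank(lb)
  list(
    ratio = mean(la == lb),
    confusion = table(a = factor(la, lev), b = factor(lb, lev)),
    n_under = sum(ra < rb),
    n_over = sum(ra > rb),
    n = length(la)
  )
}
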