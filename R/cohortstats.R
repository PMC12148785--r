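# Chronological change detection: squared-deviation (Q.DEV) series and the
# one-tailed Mann-Whitney-Wilcoxon U test, run on both the raw metric
# series and its per-group squared deviations (location shift vs dispersion
# reduction).

#' Chronological series
#'
#' @param values metric values in export (chronological) order.
#' @param change_index first index of the AFTER group (`1 < change_index <=
#'   length(values)`).
#' @param label metric name + units, for rendering.
#' @return a `chrono_series` object.
#' @export
chrono_series <- function(values, change_index, label = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("series values must be finite")
  change_index <- as.integer(change_index)
  if (change_index <= 1L || change_index > length(values))
    stop("change_index must split the series into two non-empty groups")
  structure(list(values = values, change_index = change_index,
                 label = label), class = "chrono_series")
}

#' Squared deviations from the mean (Q.DEV)
#'
#' `qdev(x) = (f(x) - <f>)^2` where `<f>` is the arithmetic mean over the
#' chosen scope: `PER_GROUP` (default) uses each group's own mean, which is
#' what a dispersion comparison between the groups needs; `WHOLE` uses the
#' grand mean.
#'
#' @param series a [chrono_series()] (or numeric vector with
#'   `change_index`).
#' @param mean_scope `"PER_GROUP"` or `"WHOLE"`.
#' @param change_index used when `series` is a bare numeric vector.
#' @return a `chrono_series` of squared deviations (same change point).
#' @export
qdev <- function(series, mean_scope = c("PER_GROUP", "WHOLE"),
                 change_index = NULL) {
  mean_scope <- match.arg(mean_scope)
  if (!inherits(series, "chrono_series"))
    series <- chrono_series(series, change_index)
  v <- series$values
  ci <- series$change_index
  if (mean_scope == "WHOLE") {
    out <- (v - mean(v))^2
  } else {
    before <- v[seq_len(ci - 1L)]
    after <- v[ci:length(v)]
    if (length(before) < 2L || length(after) < 2L)
      stop("PER_GROUP Q.DEV needs >= 2 points in each group")
    out <- c((before - mean(before))^2, (after - mean(after))^2)
  }
  chrono_series(out, ci, label = paste0("Q.DEV(", series$label, ")"))
}

#' One-tailed Mann-Whitney-Wilcoxon U test
#'
#' U is the Mann-Whitney statistic of the AFTER sample (number of
#' (before, after) pairs with after > before, counting ties 1/2). With
#' `n_before + n_after <= 12` and no ties the p-value is the exact
#' enumeration probability; otherwise the normal approximation with
#' midrank tie correction and 0.5 continuity correction is used.
#'
#' @param before,after numeric samples (each non-empty).
#' @param alternative `"AFTER_LOWER"` or `"AFTER_HIGHER"` (one-tailed).
#' @return an `mww_result`: `u_statistic`, `p_one_tail`, `n_before`,
#'   `n_after`, `alternative`, `method`.
#' @export
mww_utest <- function(before, after,
                      alternative = c("AFTER_LOWER", "AFTER_HIGHER")) {
  alternative <- match.arg(alternative)
  n1 <- length(before); n2 <- length(after)
  stopifnot(n1 >= 1L, n2 >= 1L)
  x <- c(before, after)
  r <- rank(x)
  u_after <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  ties <- any(duplicated(x))
  if (!ties && n1 + n2 <= 12L) {
    # exact null distribution of U (pwilcox: P(U <= q) for sample sizes
    # m = after, n = before)
    p <- if (alternative == "AFTER_LOWER")
      stats::pwilcox(u_after, n2, n1)
    else 1 - stats::pwilcox(u_after - 1, n2, n1)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(x)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    z <- if (alternative == "AFTER_LOWER") (u_after + 0.5 - mu) / sigma
         else (u_after - 0.5 - mu) / sigma
    p <- if (alternative == "AFTER_LOWER") stats::pnorm(z)
         else stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_approx"
  }
  structure(list(u_statistic = u_after, p_one_tail = min(max(p, 0), 1),
                 n_before = n1, n_after = n2, alternative = alternative,
                 method = method),
            class = "mww_result")
}

#' Change detection on a chronological series
#'
#' Splits the series at its change point and runs the one-tailed MWW test
#' twice: on the raw values (did the metric improve?) and on the PER_GROUP
#' Q.DEV values with alternative AFTER_LOWER (did dispersion shrink?).
#' The raw-value alternative must be chosen by the caller from the metric's
#' worse direction: AFTER_LOWER for GREATER_IS_WORSE metrics.
#'
#' @param series a [chrono_series()].
#' @param alternative alternative for the raw-value test.
#' @param qdev_scope mean scope passed to [qdev()].
#' @return a `change_detection` list: `values_test` and `qdev_test`
#'   (`mww_result`s) plus per-group `n`, `mean`, `sd`.
#' @export
change_detection <- function(series,
                             alternative = c("AFTER_LOWER", "AFTER_HIGHER"),
                             qdev_scope = "PER_GROUP") {
  alternative <- match.arg(alternative)
  stopifnot(inherits(series, "chrono_series"))
  ci <- series$change_index
  v <- series$values
  before <- v[seq_len(ci - 1L)]
  after <- v[ci:length(v)]
  qd <- qdev(series, mean_scope = qdev_scope)
  qb <- qd$values[seq_len(ci - 1L)]
  qa <- qd$values[ci:length(v)]
  structure(list(
    values_test = mww_utest(before, after, alternative),
    qdev_test = mww_utest(qb, qa, "AFTER_LOWER"),
    groups = data.frame(
      group = c("BEFORE", "AFTER"),
      n = c(length(before), length(after)),
      mean = c(mean(before), mean(after)),
      sd = c(stats::sd(before), stats::sd(after))),
    label = series$label),
    class = "change_detection")
}
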