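# Plan scoring: the protocol fulfilment score (percent of evaluated PTV +
# Main-OAR constraints met, extended table), the per-metric community score
# (percent of comparable library plans doing strictly worse), and the
# inspector statistics behind the data-inspector views.

#' Protocol fulfilment score
#'
#' Percent of evaluated PTV and Main-OAR constraints (standard and extra
#' alike) whose status is GREEN or YELLOW, rounded to the nearest integer.
#' YELLOW counts as fulfilled because it means the mandatory limit was met;
#' `NOT_EVALUATED` constraints and the Other-OAR group are excluded from
#' both numerator and denominator. 0 means no constraint satisfied, 100 all.
#'
#' @param evaluation a `plan_evaluation` from [evaluate_plan()], or a bare
#'   list of `constraint_result`s.
#' @return integer percent in `[0, 100]`.
#' @export
protocol_score <- function(evaluation) {
  results <- if (inherits(evaluation, "plan_evaluation")) evaluation$results
             else evaluation
  in_scope <- Filter(function(r)
    r$constraint$group %in% c("PTV", "MAIN_OAR") &&
    r$status != "NOT_EVALUATED", results)
  if (length(in_scope) == 0L)
    stop("no evaluated PTV / Main-OAR constraint to score")
  ok <- vapply(in_scope, function(r) r$status %in% c("GREEN", "YELLOW"),
               logical(1))
  as.integer(round(100 * sum(ok) / length(ok)))
}

#' Direction in which a constrained metric worsens
#'
#' @param constraint a [dose_constraint()].
#' @return `"GREATER_IS_WORSE"` for upper (LE) limits, `"SMALLER_IS_WORSE"`
#'   for lower (GE, coverage) limits.
#' @export
worse_direction <- function(constraint) {
  stopifnot(inherits(constraint, "dose_constraint"))
  if (constraint$comparator == "LE") "GREATER_IS_WORSE"
  else "SMALLER_IS_WORSE"
}

#' Community score
#'
#' Percent of comparable library plans whose value is strictly worse than
#' the query value, floored to an integer: `floor(100 * n_worse / n)`.
#' Ties with the query count as not-worse. Higher is better (100 = better
#' than every library plan). An empty library yields `NA` with an
#' attribute `n = 0` rather than an error.
#'
#' @param value query plan's metric value.
#' @param direction `"GREATER_IS_WORSE"` or `"SMALLER_IS_WORSE"`.
#' @param library_values metric values of the comparable library plans.
#' @return integer percent, or `NA` when the library is empty.
#' @export
community_score <- function(value, direction, library_values) {
  direction <- match.arg(direction,
                         c("GREATER_IS_WORSE", "SMALLER_IS_WORSE"))
  library_values <- library_values[!is.na(library_values)]
  n <- length(library_values)
  if (n == 0L) return(structure(NA_integer_, n = 0L))
  worse <- if (direction == "GREATER_IS_WORSE") library_values > value
           else library_values < value
  structure(as.integer(floor(100 * sum(worse) / n)), n = n)
}

#' Inspector statistics for a metric over comparable plans
#'
#' Sample statistics, a histogram (bin count `ceil(sqrt(n))` clamped to
#' 5..20), the community score of the query value, and the dashed-bar flags
#' (query above the community mean / above mean + 1 SD, in the metric's
#' worse direction).
#'
#' @param values metric values of the comparable library plans.
#' @param query_value the plan under review's value.
#' @param direction worse direction (see [worse_direction()]).
#' @return an `inspector_stats` list with `n`, `min`, `max`, `mean`, `sd`,
#'   `histogram` (`breaks`, `counts`), `cb_score`, `above_mean`,
#'   `above_mean_plus_sd`.
#' @export
inspector_stats <- function(values, query_value,
                            direction = "GREATER_IS_WORSE") {
  direction <- match.arg(direction,
                         c("GREATER_IS_WORSE", "SMALLER_IS_WORSE"))
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L)
    return(structure(list(n = 0L, min = NA_real_, max = NA_real_,
                          mean = NA_real_, sd = NA_real_, histogram = NULL,
                          cb_score = structure(NA_integer_, n = 0L),
                          above_mean = NA, above_mean_plus_sd = NA),
                     class = "inspector_stats"))
  m <- mean(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  nbins <- min(20L, max(5L, as.integer(ceiling(sqrt(n)))))
  rng <- range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- as.integer(table(cut(values, breaks, include.lowest = TRUE)))
  beyond <- function(x, ref) {
    if (direction == "GREATER_IS_WORSE") x > ref + 1e-12
    else x < ref - 1e-12
  }
  structure(list(
    n = n, min = min(values), max = max(values), mean = m, sd = s,
    histogram = list(breaks = breaks, counts = counts),
    cb_score = community_score(query_value, direction, values),
    above_mean = beyond(query_value, m),
    above_mean_plus_sd = if (is.na(s)) NA
      else beyond(query_value,
                  m + if (direction == "GREATER_IS_WORSE") s else -s)),
    class = "inspector_stats")
}
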