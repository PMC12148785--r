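# Plan sanity check: structural plausibility of the beam table (isocenter
# count, MU sum, dose rates, jaw widths for modulated beams, setup-beam
# couch rotation), plus the MU-Sum community inspection.

#' Sanity-check rule set
#'
#' All thresholds are site-configurable (preferences file `[sanity]`
#' section); these defaults are deliberately conservative.
#'
#' @param max_isocenters maximum distinct isocenters (default 1).
#' @param mu_sum_range allowed `[lo, hi]` for the per-fraction MU sum.
#' @param dose_rates allowed nominal dose rates, MU/min.
#' @param jaw_x_max maximum X-jaw width for IMRT/VMAT beams, mm. (The X jaw
#'   is the checked dimension; tangential modulated breast fields seldom
#'   need wide X apertures.)
#' @param couch_tol setup-beam couch rotation tolerance, degrees.
#' @return a `sanity_rules` list.
#' @export
sanity_rules <- function(max_isocenters = 1L, mu_sum_range = c(50, 1500),
                         dose_rates = c(400, 600), jaw_x_max = 150,
                         couch_tol = 0.5) {
  structure(list(max_isocenters = as.integer(max_isocenters),
                 mu_sum_range = as.numeric(mu_sum_range),
                 dose_rates = as.numeric(dose_rates),
                 jaw_x_max = as.numeric(jaw_x_max),
                 couch_tol = as.numeric(couch_tol)),
            class = "sanity_rules")
}

#' @rdname sanity_rules
#' @param prefs preferences list from [read_preferences()]; `sanity.*` keys
#'   override the defaults (comma-separated for ranges/sets).
#' @export
sanity_rules_from_prefs <- function(prefs) {
  num <- function(key, default) {
    v <- prefs[[paste0("sanity.", key)]]
    if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1]])
  }
  sanity_rules(max_isocenters = num("max_isocenters", 1),
               mu_sum_range = num("mu_sum_range", c(50, 1500)),
               dose_rates = num("dose_rates", c(400, 600)),
               jaw_x_max = num("jaw_x_max", 150),
               couch_tol = num("couch_tol", 0.5))
}

.check <- function(name, status, observed, rule) {
  list(name = name, status = status, observed = observed, rule = rule)
}

#' Plan sanity check
#'
#' Beam-level checks are `SKIPPED` for plan sums and beam-less (dose-only)
#' plans; findings are FAIL statuses, never exceptions. The MU sum is the
#' algebraic sum of treatment-beam monitor units (setup beams excluded).
#'
#' @param plan a [plan_info()].
#' @param properties a `plan_properties` (technique gates the jaw check).
#' @param rules a [sanity_rules()].
#' @return a `sanity_report`: list of checks, `mu_sum`, and `overall`
#'   (`"PASS"` iff no check failed).
#' @export
sanity_check <- function(plan, properties = NULL, rules = sanity_rules()) {
  checks <- list()
  tb <- Filter(function(b) !b$is_setup, plan$beams)
  sb <- Filter(function(b) b$is_setup, plan$beams)
  mu_sum <- sum(vapply(tb, function(b) b$mu, numeric(1)))
  skip_beams <- plan$is_plan_sum || length(plan$beams) == 0L
  if (skip_beams) {
    why <- if (plan$is_plan_sum) "plan sum" else "no beams"
    for (nm in c("isocenter_count", "mu_sum", "dose_rate", "jaw_x_width",
                 "setup_couch"))
      checks[[length(checks) + 1L]] <- .check(nm, "SKIPPED", NA, why)
  } else {
    isos <- unique(t(vapply(tb, function(b) round(b$isocenter, 1),
                            numeric(3))))
    n_iso <- nrow(isos)
    checks[[length(checks) + 1L]] <- .check(
      "isocenter_count", if (n_iso <= rules$max_isocenters) "PASS" else "FAIL",
      n_iso, sprintf("<= %d", rules$max_isocenters))
    in_rng <- mu_sum >= rules$mu_sum_range[1] &&
      mu_sum <= rules$mu_sum_range[2]
    checks[[length(checks) + 1L]] <- .check(
      "mu_sum", if (in_rng) "PASS" else "FAIL", mu_sum,
      sprintf("in [%g, %g]", rules$mu_sum_range[1], rules$mu_sum_range[2]))
    rates <- vapply(tb, function(b) b$dose_rate, numeric(1))
    rate_ok <- all(is.na(rates) | rates %in% rules$dose_rates)
    checks[[length(checks) + 1L]] <- .check(
      "dose_rate", if (rate_ok) "PASS" else "FAIL",
      paste(unique(rates), collapse = ","),
      sprintf("in {%s} MU/min", paste(rules$dose_rates, collapse = ", ")))
    modulated <- !is.null(properties) &&
      properties$technique %in% c("IMRT", "VMAT", "HYBRID")
    if (modulated) {
      jx <- vapply(tb, function(b) b$jaw_x_width, numeric(1))
      jaw_ok <- all(is.na(jx) | jx <= rules$jaw_x_max + 1e-9)
      checks[[length(checks) + 1L]] <- .check(
        "jaw_x_width", if (jaw_ok) "PASS" else "FAIL",
        paste(jx, collapse = ","), sprintf("<= %g mm", rules$jaw_x_max))
    } else {
      checks[[length(checks) + 1L]] <- .check(
        "jaw_x_width", "SKIPPED", NA, "non-modulated technique")
    }
    if (length(sb) > 0L) {
      couch <- vapply(sb, function(b) b$couch_rotation, numeric(1))
      dev <- pmin(abs(couch) %% 360, 360 - abs(couch) %% 360)
      couch_ok <- all(dev <= rules$couch_tol + 1e-9)
      checks[[length(checks) + 1L]] <- .check(
        "setup_couch", if (couch_ok) "PASS" else "FAIL",
        paste(couch, collapse = ","),
        sprintf("0 deg +/- %g", rules$couch_tol))
    } else {
      checks[[length(checks) + 1L]] <- .check(
        "setup_couch", "SKIPPED", NA, "no setup beams")
    }
  }
  statuses <- vapply(checks, function(c.) c.$status, character(1))
  structure(list(checks = checks, mu_sum = mu_sum,
                 overall = if (any(statuses == "FAIL")) "FAIL" else "PASS"),
            class = "sanity_report")
}

#' MU-Sum community inspection
#'
#' Compares a plan's MU sum with the MU sums of similarity-filtered library
#' plans; higher MU means more modulation, so the worse direction is
#' GREATER_IS_WORSE.
#'
#' @param mu_sum the plan's treatment-beam MU sum.
#' @param records similarity-filtered records from [filter_similar()].
#' @return an [inspector_stats()] result (with `n = 0` when no comparable
#'   plans exist).
#' @export
mu_sum_inspect <- function(mu_sum, records) {
  vals <- if (is.data.frame(records)) records$mu_sum else as.numeric(records)
  inspector_stats(vals, mu_sum, direction = "GREATER_IS_WORSE")
}
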