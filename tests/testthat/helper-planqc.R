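# Shared fixture builders. Everything is generated in code; no binary
# fixtures live in the repository.

# constraint-result shorthand for scoring tests
cres <- function(status, group = "MAIN_OAR", comparator = "LE",
                 role = "HEART", metric = "Dmean[Gy]", value = 1,
                 is_extra = FALSE) {
  structure(list(
    constraint = dose_constraint(role, metric, comparator,
                                 mandatory_limit = 2, is_extra = is_extra,
                                 group = group),
    value = value, status = status,
    display_tier = if (is_extra) "EXTRA" else "STANDARD"),
    class = "constraint_result")
}

# a curve with uniform dose (everything at `dose` Gy), binned like
# compute_dvh output
uniform_curve <- function(dose, name = "uniform", bw = 0.05,
                          total_cc = 100) {
  k <- round(dose / bw)
  edges <- (0:(k + 1)) * bw
  cum <- c(rep(100, k + 1), 0)
  dvh_curve(name, edges, cum, cum_volume_cc = cum / 100 * total_cc,
            total_volume_cc = total_cc, bin_width = bw)
}

# phantom with structures straddling a dose boundary: "halfbox" is
# symmetric about it (V at the mid dose is exactly 50%), "skewbox" has
# fractional in-plane edges aligned to the supersample-3 sub-lattice
# (offsets in multiples of dx/3 from voxel boundaries), where 3x3
# subsampling resolves the overlap exactly
offset_box_spec <- function() {
  phantom_spec(
    shape = c(20, 20, 10), spacing = c(2, 2, 2), origin = c(0, 0, 0),
    regions = list(list(extent = c(-1, 19, -1, 39, -1, 19), dose = 10)),
    structures = list(
      list(name = "halfbox", extent = c(8.6, 29.4, 5, 33, 1, 17)),
      list(name = "skewbox", extent = c(7 + 2 / 3, 25, 5 + 2 / 3, 33,
                                        1, 17))))
}

# exhaustive-enumeration oracle for the one-tailed MWW test (no ties)
enum_mww_p <- function(before, after, alternative) {
  pool <- c(before, after)
  n2 <- length(after)
  u_of <- function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq(length(before) + 1, length(pool)))
  us <- apply(utils::combn(length(pool), n2), 2, u_of)
  if (alternative == "AFTER_HIGHER") mean(us >= u_obs)
  else mean(us <= u_obs)
}

lib_tmpfile <- function() tempfile(fileext = ".csv")

# minimal evaluation object for library/record tests, built on the
# FAST_FORWARD protocol with all values green
tiny_evaluation <- function(protocol = load_protocols()$FAST_FORWARD) {
  results <- lapply(protocol$constraints, function(c.) {
    good <- if (c.$comparator == "LE")
      min(c.$mandatory_limit, c.$optimal_limit, na.rm = TRUE) * 0.5
    else c.$mandatory_limit + 1
    evaluate_constraint(good, c.)
  })
  props <- structure(list(laterality = "RIGHT", has_boost = FALSE,
                          has_nodes = FALSE, breast_modifier = "NONE",
                          technique = "VMAT",
                          technique_modifiers = character(0),
                          bolus = "NONE"),
                     class = "plan_properties")
  ev <- structure(list(protocol = protocol, properties = props,
                       mapping = NULL, results = results,
                       score_pct = NA_real_),
                  class = "plan_evaluation")
  ev$score_pct <- protocol_score(ev)
  ev
}
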