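# Ready-made synthetic specifications: a right-breast box phantom sized for
# the 26 Gy / 5 fraction protocol, in three variants, and a matching set of
# library metric distributions. Used by the CLI generators, the test suite
# and the acceptance script.

#' Demo phantom specification
#'
#' A 40x40x20 grid at 2 mm pitch with a 26 Gy "breast" region (PTV fully
#' inside), a 3 Gy ipsilateral-lung region, a 1 Gy heart region and
#' zero-dose contralateral structures; the plan delivers 5 x 5.2 Gy with
#' two 600 MU/min arcs of 200.1 and 196.2 MU (MU sum 396.3) plus a setup
#' field.
#'
#' @param variant `"clean"` (all constraints green, sanity pass),
#'   `"one_red"` (the contralateral lung sits in a 3.5 Gy bath, violating
#'   its V3Gy ceiling and nothing else), or `"sanity_fail"` (setup beam
#'   couch rotated 90 degrees).
#' @return a [phantom_spec()].
#' @export
demo_phantom_spec <- function(variant = c("clean", "one_red",
                                          "sanity_fail")) {
  variant <- match.arg(variant)
  regions <- list(
    list(extent = c(9, 39, 9, 39, -1, 39), dose = 26),    # breast PTV bath
    list(extent = c(41, 61, 9, 39, -1, 39), dose = 3),    # ipsi lung bath
    list(extent = c(41, 55, 41, 55, -1, 39), dose = 1))   # heart bath
  if (variant == "one_red")
    regions <- c(regions,
                 list(list(extent = c(-1, 7, 9, 39, -1, 39), dose = 3.5)))
  beams <- list(
    list(id = "arc1", mu = 200.1, dose_rate = 600, jaw_x = 120,
         jaw_y = 180, isocenter = c(24, 24, 19), technique = "ARC"),
    list(id = "arc2", mu = 196.2, dose_rate = 600, jaw_x = 120,
         jaw_y = 180, isocenter = c(24, 24, 19), technique = "ARC"),
    list(id = "setup", mu = 0, is_setup = TRUE,
         couch = if (variant == "sanity_fail") 90 else 0,
         isocenter = c(24, 24, 19), technique = "STATIC"))
  phantom_spec(
    shape = c(40, 40, 20), spacing = c(2, 2, 2), origin = c(0, 0, 0),
    regions = regions,
    structures = list(
      list(name = "PTV_breast DX", extent = c(11, 37, 11, 37, 3, 35)),
      list(name = "Polmone DX", extent = c(43, 59, 11, 37, 3, 35)),
      list(name = "Cuore", extent = c(43, 53, 43, 53, 7, 31)),
      list(name = "Polmone SX", extent = c(-1, 7, 11, 37, 3, 35)),
      list(name = "Breast SX", extent = c(-1, 7, 57, 71, 7, 31))),
    plan = list(plan_id = "demo_right_breast", patient_id = "PHANTOM-001",
                dose_per_fraction_gy = 5.2, n_fractions = 5L,
                beams = beams))
}

#' Demo library metric distributions
#'
#' Distributions for the metric columns of a 26 Gy / 5 fraction community
#' library, centred where a well-optimized clinic would sit (lung V16
#' around 13%, contralateral lung V3 low and skewed, heart mean dose about
#' 1.5 Gy).
#'
#' @return named list of distribution specs for [make_library()].
#' @export
demo_library_metrics <- function() {
  list(
    "LUNG_IPSI V16Gy[%]" = list(dist = "normal", mean = 13, sd = 3),
    "LUNG_CONTRA V3Gy[%]" = list(dist = "lognormal", meanlog = 1.5,
                                 sdlog = 0.5),
    "HEART Dmean[Gy]" = list(dist = "normal", mean = 1.5, sd = 0.4))
}
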