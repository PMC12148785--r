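# Protocol definitions (selection rules + extended constraint tables),
# text-file parsing/formatting, and plan evaluation with traffic lights.

#' Dose constraint
#'
#' @param role structure role (see `STRUCTURE_ROLES`).
#' @param metric a [metric_spec()] or grammar string.
#' @param comparator `"LE"` or `"GE"`.
#' @param mandatory_limit mandatory limit (red below/above).
#' @param optimal_limit optional stricter limit driving the yellow tier.
#' @param is_extra logical; extra (starred) constraint.
#' @param group `"PTV"`, `"MAIN_OAR"` or `"OTHER_OAR"` (default from role).
#' @return a `dose_constraint` object.
#' @export
dose_constraint <- function(role, metric, comparator = c("LE", "GE"),
                            mandatory_limit, optimal_limit = NA_real_,
                            is_extra = FALSE, group = NULL) {
  role <- match.arg(role, STRUCTURE_ROLES)
  comparator <- match.arg(comparator)
  if (is.character(metric)) metric <- parse_metric(metric)
  if (is.null(group)) group <- unname(ROLE_GROUPS[role])
  group <- match.arg(group, c("PTV", "MAIN_OAR", "OTHER_OAR"))
  if (mandatory_limit < 0) stop("limits must be >= 0")
  if (!is.na(optimal_limit)) {
    stricter <- if (comparator == "LE") optimal_limit < mandatory_limit
                else optimal_limit > mandatory_limit
    if (!stricter)
      stop("optimal limit must be stricter than mandatory under ", comparator)
  }
  structure(list(role = role, metric = metric, comparator = comparator,
                 mandatory_limit = as.numeric(mandatory_limit),
                 optimal_limit = as.numeric(optimal_limit),
                 is_extra = isTRUE(is_extra), group = group),
            class = "dose_constraint")
}

.parse_range <- function(s) {
  p <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
  if (length(p) == 1L) c(p, p) else p[1:2]
}

#' Parse / format a protocol definition file
#'
#' Format: `key = value` header lines (`name`, one or more
#' `schedule = <fx[-fx]> x <gy/fx>-<gy/fx>` rules or `schedule = none`,
#' `min_ptvs`, `max_ptvs`) followed by one constraint per line:
#' `role | metric | LE/GE | mandatory | optimal or - | std/extra | group`.
#' `#` starts a comment.
#'
#' @param path protocol file (or `text =` a character vector of lines).
#' @param text alternative to `path`.
#' @return a `protocol` object.
#' @export
parse_protocol <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL; schedules <- list(); min_ptvs <- 1L; max_ptvs <- 3L
  constraints <- list()
  for (ln in lines) {
    if (grepl("=", ln, fixed = TRUE) && !grepl("|", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (key == "name") name <- val
      else if (key == "schedule") {
        if (val != "none") {
          xp <- trimws(strsplit(val, "x", fixed = TRUE)[[1]])
          schedules[[length(schedules) + 1L]] <-
            list(fractions = .parse_range(xp[1]),
                 dose_per_fx = .parse_range(xp[2]))
        }
      } else if (key == "min_ptvs") min_ptvs <- as.integer(val)
      else if (key == "max_ptvs") max_ptvs <- as.integer(val)
      else stop("unknown protocol header key: ", key)
    } else {
      f <- trimws(strsplit(ln, "|", fixed = TRUE)[[1]])
      if (length(f) != 7L)
        stop("malformed constraint line (need 7 |-separated fields): ", ln)
      constraints[[length(constraints) + 1L]] <- dose_constraint(
        role = f[1], metric = f[2], comparator = f[3],
        mandatory_limit = as.numeric(f[4]),
        optimal_limit = if (f[5] == "-") NA_real_ else as.numeric(f[5]),
        is_extra = identical(f[6], "extra"), group = f[7])
    }
  }
  if (is.null(name)) stop("protocol file lacks a name")
  structure(list(name = name, schedules = schedules,
                 min_ptvs = min_ptvs, max_ptvs = max_ptvs,
                 constraints = constraints),
            class = "protocol")
}

#' @rdname parse_protocol
#' @param protocol a `protocol` object.
#' @export
format_protocol <- function(protocol) {
  .rng <- function(r) if (r[1] == r[2]) .fmt_num(r[1])
                      else paste0(.fmt_num(r[1]), "-", .fmt_num(r[2]))
  hdr <- c(paste("name =", protocol$name),
           if (length(protocol$schedules) == 0L) "schedule = none"
           else vapply(protocol$schedules, function(s)
             sprintf("schedule = %s x %s", .rng(s$fractions),
                     .rng(s$dose_per_fx)), character(1)),
           paste("min_ptvs =", protocol$min_ptvs),
           paste("max_ptvs =", protocol$max_ptvs))
  body <- vapply(protocol$constraints, function(c.) {
    sprintf("%s | %s | %s | %s | %s | %s | %s", c.$role,
            format_metric(c.$metric), c.$comparator,
            .fmt_num(c.$mandatory_limit),
            if (is.na(c.$optimal_limit)) "-" else .fmt_num(c.$optimal_limit),
            if (c.$is_extra) "extra" else "std", c.$group)
  }, character(1))
  c(hdr, body)
}

#' Load the shipped protocol set
#'
#' @param dir directory of protocol files; default the shipped tables.
#' @return named list of `protocol` objects.
#' @export
load_protocols <- function(dir = system.file("extdata", "protocols",
                                             package = "planqc")) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  out <- lapply(files, parse_protocol)
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Select the protocol matching a plan
#'
#' Matches (dose per fraction, fraction count, PTV count) against each
#' protocol's selection schedules; an explicit override wins. With no match
#' an error lists the near-misses (protocols whose fraction count matched).
#'
#' @param plan a [plan_info()].
#' @param n_ptvs number of PTVs found in the structure set.
#' @param protocols protocol set from [load_protocols()].
#' @param override protocol name to force, or `NULL`.
#' @return the selected `protocol`.
#' @export
select_protocol <- function(plan, n_ptvs = 1L, protocols = load_protocols(),
                            override = NULL) {
  if (!is.null(override)) {
    if (!override %in% names(protocols))
      stop("unknown protocol override '", override, "'; available: ",
           paste(names(protocols), collapse = ", "))
    return(protocols[[override]])
  }
  dpf <- plan$prescription_dose / plan$n_fractions
  hits <- character(0); near <- character(0)
  for (p in protocols) {
    fx_ok <- any(vapply(p$schedules, function(s)
      plan$n_fractions >= s$fractions[1] &&
      plan$n_fractions <= s$fractions[2], logical(1)))
    full_ok <- any(vapply(p$schedules, function(s)
      plan$n_fractions >= s$fractions[1] &&
      plan$n_fractions <= s$fractions[2] &&
      dpf >= s$dose_per_fx[1] - 1e-9 &&
      dpf <= s$dose_per_fx[2] + 1e-9, logical(1)))
    ptv_ok <- n_ptvs >= p$min_ptvs && n_ptvs <= p$max_ptvs
    if (full_ok && ptv_ok) hits <- c(hits, p$name)
    else if (fx_ok) near <- c(near, p$name)
  }
  if (length(hits) == 0L)
    stop(sprintf(paste0("no protocol matches %.3g Gy/fx in %d fractions ",
                        "with %d PTV(s); near-misses: %s"),
                 dpf, plan$n_fractions, n_ptvs,
                 if (length(near)) paste(near, collapse = ", ") else "none"))
  if (length(hits) > 1L)
    stop("ambiguous protocol selection: ", paste(hits, collapse = ", "))
  protocols[[hits]]
}

#' Evaluate one dose constraint
#'
#' Comparisons are inclusive and applied after rounding the value to the
#' 1-decimal display precision, so a value of exactly 10.04 passes a
#' `<= 10` limit while 10.05 fails. Status is `RED` iff the mandatory limit
#' is violated; `YELLOW` only when an optimal limit exists, is violated,
#' and the mandatory limit is met; `NOT_EVALUATED` propagates.
#'
#' @param value metric value in the constraint's unit, or `NA` for
#'   not-evaluated.
#' @param constraint a [dose_constraint()].
#' @return a `constraint_result` list with `constraint`, `value`, `status`
#'   and `display_tier`.
#' @export
evaluate_constraint <- function(value, constraint) {
  stopifnot(inherits(constraint, "dose_constraint"))
  tier <- if (constraint$is_extra) "EXTRA" else "STANDARD"
  if (is.null(value) || is.na(value)) {
    return(structure(list(constraint = constraint, value = NA_real_,
                          status = "NOT_EVALUATED", display_tier = tier),
                     class = "constraint_result"))
  }
  v <- round(value, 1)
  pass <- function(limit) {
    if (constraint$comparator == "LE") v <= limit + 1e-9
    else v >= limit - 1e-9
  }
  status <- if (!pass(constraint$mandatory_limit)) "RED"
    else if (!is.na(constraint$optimal_limit) &&
             !pass(constraint$optimal_limit)) "YELLOW"
    else "GREEN"
  structure(list(constraint = constraint, value = value, status = status,
                 display_tier = tier),
            class = "constraint_result")
}

#' Evaluate a plan's DVH set against a protocol
#'
#' Computes each constraint's metric on the mapped structure's curve;
#' unmapped roles (or curves lacking the needed absolute volume) yield
#' `NOT_EVALUATED` results. Results are ordered PTVs, Main OARs, Other
#' OARs.
#'
#' @param curves list of [dvh_curve()] objects (names are structure names).
#' @param mapping a `structure_mapping` from [match_structures()].
#' @param protocol a `protocol`.
#' @param properties a `plan_properties` (carried into the evaluation).
#' @param prescription optional prescription dose in Gy.
#' @return a `plan_evaluation` with the ordered `results` list and the
#'   protocol fulfilment `score_pct` (see [protocol_score()]).
#' @export
evaluate_plan <- function(curves, mapping, protocol, properties = NULL,
                          prescription = NULL) {
  by_name <- stats::setNames(
    curves, vapply(curves, function(c.) c.$structure_name, character(1)))
  if (is.na(.mapped_structure(mapping, "PTV_BREAST")))
    stop("evaluation requires a mapped PTV_BREAST structure")
  order_key <- c(PTV = 1L, MAIN_OAR = 2L, OTHER_OAR = 3L)
  cons <- protocol$constraints[
    order(order_key[vapply(protocol$constraints, function(c.) c.$group,
                           character(1))])]
  results <- lapply(cons, function(c.) {
    sname <- .mapped_structure(mapping, c.$role)
    value <- NA_real_
    if (!is.na(sname) && sname %in% names(by_name)) {
      value <- tryCatch(
        metric_value(by_name[[sname]], c.$metric, prescription),
        error = function(e) NA_real_)
    }
    evaluate_constraint(value, c.)
  })
  ev <- structure(list(protocol = protocol, properties = properties,
                       mapping = mapping, results = results,
                       score_pct = NA_real_),
                  class = "plan_evaluation")
  ev$score_pct <- tryCatch(protocol_score(ev), error = function(e) NA_real_)
  ev
}
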