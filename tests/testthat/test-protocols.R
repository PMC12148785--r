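# Protocol selection, constraint evaluation semantics, file round-trips.

protos <- load_protocols()

test_that("shipped protocol set parses and auto windows are disjoint", {
  expect_setequal(names(protos), c("RTOG1005", "FAST_FORWARD", "FAST",
                                   "EUROPA_PBI", "EUROPA_WBI"))
  # pairwise disjoint (fractions, dose/fx) windows across protocols
  scheds <- do.call(rbind, lapply(protos, function(p)
    do.call(rbind, lapply(p$schedules, function(s)
      data.frame(name = p$name, f1 = s$fractions[1], f2 = s$fractions[2],
                 d1 = s$dose_per_fx[1], d2 = s$dose_per_fx[2])))))
  for (i in seq_len(nrow(scheds))) for (j in seq_len(nrow(scheds))) {
    if (i >= j || scheds$name[i] == scheds$name[j]) next
    overlap <- scheds$f1[i] <= scheds$f2[j] && scheds$f1[j] <= scheds$f2[i] &&
      scheds$d1[i] <= scheds$d2[j] && scheds$d1[j] <= scheds$d2[i]
    expect_false(overlap,
                 label = paste("windows of", scheds$name[i], "and",
                               scheds$name[j], "overlap"))
  }
})

test_that("selection follows the shipped dose/fractionation table", {
  plan <- function(rx, fx) plan_info("p", prescription_dose = rx,
                                     n_fractions = fx)
  expect_equal(select_protocol(plan(26, 5), 1, protos)$name, "FAST_FORWARD")
  expect_equal(select_protocol(plan(28.5, 5), 1, protos)$name, "FAST")
  expect_equal(select_protocol(plan(30, 5), 1, protos)$name, "EUROPA_PBI")
  expect_equal(select_protocol(plan(40.05, 15), 1, protos)$name, "RTOG1005")
  expect_equal(select_protocol(plan(50, 25), 1, protos)$name, "RTOG1005")
  err <- tryCatch(select_protocol(plan(33, 7), 1, protos),
                  error = conditionMessage)
  expect_match(err, "no protocol matches")
  # override wins even against the auto-match
  expect_equal(select_protocol(plan(26, 5), 1, protos,
                               override = "EUROPA_WBI")$name, "EUROPA_WBI")
  expect_error(select_protocol(plan(26, 5), 1, protos, override = "NOPE"),
               "unknown protocol")
})

test_that("protocol files round-trip through format/parse", {
  for (p in protos) {
    back <- parse_protocol(text = format_protocol(p))
    expect_equal(back, p, ignore_attr = TRUE)
  }
})

test_that("traffic lights: green/yellow/red tiers and inclusive bounds", {
  lung <- dose_constraint("LUNG_IPSI", "V16Gy[%]", "LE", 20)
  expect_equal(evaluate_constraint(15, lung)$status, "GREEN")
  expect_equal(evaluate_constraint(20, lung)$status, "GREEN")   # inclusive
  expect_equal(evaluate_constraint(20.04, lung)$status, "GREEN") # display rounding
  expect_equal(evaluate_constraint(20.1, lung)$status, "RED")
  heart <- dose_constraint("HEART", "Dmean[Gy]", "LE", 2, is_extra = TRUE)
  r <- evaluate_constraint(2.4, heart)
  expect_equal(r$status, "RED")
  expect_equal(r$display_tier, "EXTRA")
  contra <- dose_constraint("LUNG_CONTRA", "V3Gy[%]", "LE", 10,
                            is_extra = TRUE)
  expect_equal(evaluate_constraint(10, contra)$status, "GREEN")
  # yellow needs an optimal/mandatory pair with only the optimal violated
  pair <- dose_constraint("LUNG_IPSI", "V16Gy[%]", "LE", 20,
                          optimal_limit = 15)
  expect_equal(evaluate_constraint(14, pair)$status, "GREEN")
  expect_equal(evaluate_constraint(17, pair)$status, "YELLOW")
  expect_equal(evaluate_constraint(21, pair)$status, "RED")
  cov <- dose_constraint("PTV_BREAST", "V24.7Gy[%]", "GE", 90,
                         optimal_limit = 95)
  expect_equal(evaluate_constraint(96, cov)$status, "GREEN")
  expect_equal(evaluate_constraint(92, cov)$status, "YELLOW")
  expect_equal(evaluate_constraint(89, cov)$status, "RED")
  expect_equal(evaluate_constraint(NA, cov)$status, "NOT_EVALUATED")
})

test_that("status is monotone in the worsening direction", {
  pair <- dose_constraint("LUNG_IPSI", "V16Gy[%]", "LE", 20,
                          optimal_limit = 15)
  rank <- c(GREEN = 1, YELLOW = 2, RED = 3)
  vals <- seq(0, 40, by = 0.7)
  st <- rank[vapply(vals, function(v) evaluate_constraint(v, pair)$status,
                    character(1))]
  expect_true(all(diff(st) >= 0))
})

test_that("optimal limit must be stricter than mandatory", {
  expect_error(dose_constraint("HEART", "Dmean[Gy]", "LE", 2,
                               optimal_limit = 3), "stricter")
  expect_error(dose_constraint("PTV_BREAST", "V24.7Gy[%]", "GE", 95,
                               optimal_limit = 90), "stricter")
})

test_that("evaluate_plan: ordering, one-red fixture, unmapped exclusion", {
  res <- make_phantom(demo_phantom_spec("one_red"), tempfile())
  grid <- read_rtdose(res$paths[["rtdose"]])
  structs <- read_rtstruct(res$paths[["rtstruct"]])
  plan <- read_rtplan(res$paths[["rtplan"]])
  props <- detect_properties(plan, structs)
  mapping <- match_structures(structs, props$laterality)
  curves <- lapply(structs, function(s) compute_dvh(grid, s))
  ev <- evaluate_plan(curves, mapping, protos$FAST_FORWARD, props)
  groups <- vapply(ev$results, function(r) r$constraint$group, character(1))
  expect_true(all(diff(match(groups, c("PTV", "MAIN_OAR", "OTHER_OAR")))
                  >= 0))
  statuses <- vapply(ev$results, function(r) r$status, character(1))
  expect_equal(sum(statuses == "RED"), 1L)
  red <- ev$results[[which(statuses == "RED")]]
  expect_equal(metric_column(red$constraint), "LUNG_CONTRA V3Gy[%]")
  # unmapped other-OARs are NOT_EVALUATED and excluded from the score
  expect_true(all(statuses[groups == "OTHER_OAR"] == "NOT_EVALUATED"))
  expect_equal(ev$score_pct, protocol_score(ev))
  # mandatory PTV mapping
  mapping_no_ptv <- mapping
  mapping_no_ptv$structure[mapping_no_ptv$role == "PTV_BREAST"] <- NA
  expect_error(evaluate_plan(curves, mapping_no_ptv, protos$FAST_FORWARD),
               "PTV_BREAST")
})
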