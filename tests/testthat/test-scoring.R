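# Scoring: fulfilment-score anchors, community-score semantics against a
# brute-force oracle, inspector statistics.

test_that("fulfilment score anchors at 100 and 0 and counts evaluated only", {
  all_green <- replicate(8, cres("GREEN"), simplify = FALSE)
  expect_equal(protocol_score(all_green), 100)
  all_red <- replicate(8, cres("RED"), simplify = FALSE)
  expect_equal(protocol_score(all_red), 0)
  # 3 green of 4 -> 75 (direct count oracle)
  expect_equal(protocol_score(c(replicate(3, cres("GREEN"),
                                          simplify = FALSE),
                                list(cres("RED")))), 75)
  # yellow counts as fulfilled; other-OAR and NOT_EVALUATED excluded
  mixed <- list(cres("GREEN"), cres("YELLOW"),
                cres("RED", group = "OTHER_OAR", role = "LIVER"),
                cres("NOT_EVALUATED", value = NA))
  expect_equal(protocol_score(mixed), 100)
  expect_error(protocol_score(list(cres("RED", group = "OTHER_OAR",
                                        role = "LIVER"))), "no evaluated")
})

test_that("fulfilment score is invariant under result permutation", {
  set.seed(11)
  results <- c(replicate(5, cres("GREEN"), simplify = FALSE),
               replicate(2, cres("RED"), simplify = FALSE),
               replicate(3, cres("YELLOW"), simplify = FALSE))
  base <- protocol_score(results)
  expect_equal(base, 80)
  for (i in 1:5) expect_equal(protocol_score(sample(results)), base)
})

test_that("worse_direction follows the comparator", {
  expect_equal(worse_direction(dose_constraint("LUNG_IPSI", "V16Gy[%]",
                                               "LE", 20)),
               "GREATER_IS_WORSE")
  expect_equal(worse_direction(dose_constraint("PTV_BREAST", "V24.7Gy[%]",
                                               "GE", 95)),
               "SMALLER_IS_WORSE")
  expect_equal(worse_direction(dose_constraint("HEART", "Dmean[Gy]",
                                               "LE", 2)),
               "GREATER_IS_WORSE")
})

test_that("community score: worked 3-of-24 case and the extremes", {
  lib <- c(runif(21, 5, 14.9), 16.2, 17.8, 19.3)   # exactly 3 above 15
  expect_equal(as.integer(community_score(15, "GREATER_IS_WORSE", lib)), 12L)
  expect_equal(as.integer(community_score(100, "GREATER_IS_WORSE", lib)), 0L)
  expect_equal(as.integer(community_score(0, "GREATER_IS_WORSE", lib)), 100L)
  # ties count as not-worse
  expect_equal(as.integer(community_score(5, "GREATER_IS_WORSE",
                                          c(5, 5, 5, 6))), 25L)
  # empty library: NA with n = 0, not an exception
  empty <- community_score(1, "GREATER_IS_WORSE", numeric(0))
  expect_true(is.na(empty))
  expect_equal(attr(empty, "n"), 0L)
})

test_that("community score equals the brute-force count oracle (property)", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(1:1000, 1)
    lib <- round(rnorm(n, 10, 4), sample(0:3, 1))
    q <- round(rnorm(1, 10, 4), 2)
    dir <- sample(c("GREATER_IS_WORSE", "SMALLER_IS_WORSE"), 1)
    worse <- if (dir == "GREATER_IS_WORSE") sum(lib > q) else sum(lib < q)
    expect_identical(as.integer(community_score(q, dir, lib)),
                     as.integer(floor(100 * worse / n)))
  }
})

test_that("community score is monotone as the query improves", {
  set.seed(5)
  lib <- rnorm(200, 10, 3)
  qs <- seq(20, 0, by = -0.5)   # improving under GREATER_IS_WORSE
  sc <- vapply(qs, function(q)
    as.integer(community_score(q, "GREATER_IS_WORSE", lib)), integer(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("inspector stats: degenerate, flags, internal consistency", {
  st <- inspector_stats(rep(4, 10), 4)
  expect_equal(st$mean, 4); expect_equal(st$sd, 0)
  expect_false(st$above_mean)
  # n = 1: no sd, flags beyond min/max unavailable
  st1 <- inspector_stats(7, 8)
  expect_true(is.na(st1$sd)); expect_true(is.na(st1$above_mean_plus_sd))
  # query above mean + 1 sd of a generated library -> flag true
  set.seed(9)
  vals <- rnorm(100, 10, 2)
  stq <- inspector_stats(vals, mean(vals) + 1.5 * sd(vals))
  expect_true(stq$above_mean); expect_true(stq$above_mean_plus_sd)
  stm <- inspector_stats(vals, mean(vals) + 0.5 * sd(vals))
  expect_true(stm$above_mean); expect_false(stm$above_mean_plus_sd)
  # embedded community score equals the direct call
  expect_identical(as.integer(stq$cb_score),
                   as.integer(community_score(mean(vals) + 1.5 * sd(vals),
                                              "GREATER_IS_WORSE", vals)))
  # histogram bin count rule
  expect_length(inspector_stats(rnorm(9), 0)$histogram$counts, 5L)
  expect_length(inspector_stats(rnorm(100), 0)$histogram$counts, 10L)
  expect_length(inspector_stats(rnorm(900), 0)$histogram$counts, 20L)
  expect_equal(sum(inspector_stats(vals, 0)$histogram$counts), 100L)
})

test_that("parameter recovery: library mean within 3 sd/sqrt(n) of spec", {
  for (seed in 1:5) {
    lib <- make_library(n = 200, seed = seed,
                        metrics = list(m = list(dist = "normal", mean = 12,
                                                sd = 3)))
    st <- inspector_stats(lib$m, 12)
    expect_lt(abs(st$mean - 12), 3 * 3 / sqrt(200))
  }
})
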