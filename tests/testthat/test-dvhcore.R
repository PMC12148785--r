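# DVH engine against the analytic box oracle, metric evaluation, and the
# metric grammar.

res_clean <- make_phantom(demo_phantom_spec("clean"), tempfile())
grid_clean <- read_rtdose(res_clean$paths[["rtdose"]])
structs_clean <- read_rtstruct(res_clean$paths[["rtstruct"]])
names(structs_clean) <- vapply(structs_clean, function(s) s$name,
                               character(1))

test_that("uniform-dose limit: V below dose is 100, above is 0, Dmean = dose", {
  cv <- compute_dvh(grid_clean, structs_clean[["PTV_breast DX"]])
  expect_equal(metric_value(cv, "V3Gy[%]"), 100)
  expect_equal(metric_value(cv, "V26Gy[%]"), 100)
  expect_equal(metric_value(cv, "V26.5Gy[%]"), 0)
  expect_equal(metric_value(cv, "Dmean[Gy]"), 26, tolerance = 0.05)
  expect_equal(metric_value(cv, "Dmax[Gy]"), 26, tolerance = 0.05)
  expect_equal(metric_value(cv, "Dmin[Gy]"), 26, tolerance = 0.05)
})

test_that("every analytic table entry matches the computed DVH (boxes)", {
  for (phat in list(res_clean,
                    make_phantom(offset_box_spec(), tempfile()))) {
    grid <- read_rtdose(phat$paths[["rtdose"]])
    structs <- read_rtstruct(phat$paths[["rtstruct"]])
    names(structs) <- vapply(structs, function(s) s$name, character(1))
    curves <- lapply(structs, compute_dvh, grid = grid, supersample = 3L)
    a <- phat$analytic
    for (i in seq_len(nrow(a))) {
      cv <- curves[[a$structure[i]]]
      m <- a$metric[i]
      comp <- if (m == "volume_cc") cv$total_volume_cc
              else metric_value(cv, m)
      tol <- if (m == "volume_cc") 0.05 * max(1, a$value[i])
             else if (startsWith(m, "V")) 0.5 else 0.05
      expect_lt(abs(comp - a$value[i]), tol + 1e-9,
                label = sprintf("|%s %s: %.4g - %.4g|", a$structure[i], m,
                                comp, a$value[i]))
    }
  }
})

test_that("supersampling converges to the analytic fractional overlap", {
  res <- make_phantom(offset_box_spec(), tempfile())
  grid <- read_rtdose(res$paths[["rtdose"]])
  st <- read_rtstruct(res$paths[["rtstruct"]])
  skew <- st[[which(vapply(st, function(s) s$name, character(1)) ==
                      "skewbox")]]
  a <- res$analytic
  truth_vol <- a$value[a$structure == "skewbox" & a$metric == "volume_cc"]
  errs <- vapply(c(1L, 3L), function(s) {
    cv <- compute_dvh(grid, skew, supersample = s)
    abs(cv$total_volume_cc - truth_vol)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2] / truth_vol, 0.005)
  # the symmetric half box: error shrinks with supersampling too
  half <- st[[which(vapply(st, function(s) s$name, character(1)) ==
                      "halfbox")]]
  truth_half <- a$value[a$structure == "halfbox" & a$metric == "volume_cc"]
  e1 <- abs(compute_dvh(grid, half, supersample = 1L)$total_volume_cc -
              truth_half)
  e3 <- abs(compute_dvh(grid, half, supersample = 3L)$total_volume_cc -
              truth_half)
  expect_lt(e3, e1)
})

test_that("computed DVH matches a brute-force voxel-membership oracle", {
  # oracle: voxel centers against the same box definition, no contours
  set.seed(42)
  for (rep in 1:4) {
    # voxel-boundary-aligned boxes: per-voxel membership is exact, so the
    # oracle isolates the polygon-classification path
    ext <- sort(sample(seq(1, 37, 2), 2)); eyt <- sort(sample(seq(1, 37, 2), 2))
    spec <- phantom_spec(
      shape = c(20, 20, 8), spacing = c(2, 2, 2),
      regions = list(list(extent = c(-1, 19, -1, 39, -1, 15), dose = 8),
                     list(extent = c(19, 39, -1, 39, -1, 15), dose = 2)),
      structures = list(list(name = "r", extent = c(ext[1], ext[2],
                                                    eyt[1], eyt[2], 1, 13))))
    res <- make_phantom(spec, tempfile())
    grid <- read_rtdose(res$paths[["rtdose"]])
    st <- read_rtstruct(res$paths[["rtstruct"]])[[1]]
    cv <- compute_dvh(grid, st, supersample = 3L)
    # brute force: per-voxel-center membership at fine supersampling
    cx <- (0:19) * 2; cy <- (0:19) * 2; cz <- (0:7) * 2
    sub <- seq(-0.9, 0.9, by = 0.2)
    xs <- as.vector(outer(cx, sub, "+")); ys <- as.vector(outer(cy, sub, "+"))
    inx <- xs >= ext[1] & xs <= ext[2]
    iny <- ys >= eyt[1] & ys <= eyt[2]
    inz <- cz >= 1 & cz <= 13
    wx <- tapply(inx, rep(seq_along(cx), length(sub)), mean)
    wy <- tapply(iny, rep(seq_along(cy), length(sub)), mean)
    w <- outer(outer(wx, wy), as.numeric(inz))
    doses <- res$dose_array
    for (d in c(1, 2, 5, 8)) {
      vol_ge <- sum(w[doses >= d]) / sum(w) * 100
      expect_lt(abs(metric_value(cv, sprintf("V%dGy[%%]", d)) - vol_ge), 0.5)
    }
  }
})

test_that("structures outside the grid or with no contours error loudly", {
  st_out <- rt_structure("far", list(matrix(c(0, 0, 999, 10, 0, 999,
                                              10, 10, 999), ncol = 3,
                                            byrow = TRUE)))
  expect_error(compute_dvh(grid_clean, st_out), "no dose coverage")
  expect_error(compute_dvh(grid_clean, rt_structure("none", list())),
               "valid contours")
})

test_that("even-odd rule subtracts inner contours (holes)", {
  outer_sq <- matrix(c(1, 1, 10, 37, 1, 10, 37, 37, 10, 1, 37, 10),
                     ncol = 3, byrow = TRUE)
  inner_sq <- matrix(c(11, 11, 10, 27, 11, 10, 27, 27, 10, 11, 27, 10),
                     ncol = 3, byrow = TRUE)
  solid <- rt_structure("solid", list(outer_sq))
  ring <- rt_structure("ring", list(outer_sq, inner_sq))
  v_solid <- compute_dvh(grid_clean, solid, supersample = 2L)$total_volume_cc
  v_ring <- compute_dvh(grid_clean, ring, supersample = 2L)$total_volume_cc
  expect_equal(v_solid - v_ring, 16 * 16 * 2 / 1000, tolerance = 0.01)
})

test_that("metric_value handles inverse lookups, means and conventions", {
  u26 <- uniform_curve(26)
  expect_equal(metric_value(u26, "V16Gy[%]"), 100)
  expect_equal(metric_value(u26, "D50%[Gy]"), 26, tolerance = 0.05)
  # D at 0% -> Dmax, at 100% -> Dmin
  expect_equal(metric_value(u26, "D0%[Gy]"), metric_value(u26, "Dmax[Gy]"))
  expect_equal(metric_value(u26, "D100%[Gy]"), metric_value(u26, "Dmin[Gy]"))
  # two-level curve: half at 10, half at 2 -> Dmean 6 (brute-force oracle:
  # mean(c(10, 2)) over equal volumes)
  edges <- (0:201) * 0.05
  cum <- ifelse(edges <= 2, 100, ifelse(edges <= 10, 50, 0))
  two <- dvh_curve("two", edges, cum, total_volume_cc = 50, bin_width = 0.05)
  expect_equal(metric_value(two, "Dmean[Gy]"), 6, tolerance = 0.05)
  # flat run exactly at the queried volume: tie resolves to the lowest dose
  # achieving it (the run's first edge, 2.05 with 0.05 Gy bins)
  expect_equal(metric_value(two, "D50%[Gy]"), 2.05, tolerance = 1e-6)
  expect_equal(metric_value(two, "D49%[Gy]"), 10, tolerance = 0.11)
  # cc-based threshold: D25cc on the 50 cc structure = D50%
  expect_equal(metric_value(two, "D25cc[Gy]"),
               metric_value(two, "D50%[Gy]"))
  expect_equal(metric_value(two, "V5Gy[cc]"), 25, tolerance = 0.05)
})

test_that("V is non-increasing in dose and Dmin <= Dmean <= Dmax", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    cum <- c(100, sort(runif(n - 1, 0, 100), decreasing = TRUE))
    cv <- dvh_curve("r", (0:(n - 1)) * 0.5, cum, bin_width = 0.5)
    d <- sort(runif(5, 0, n * 0.5))
    vs <- vapply(d, function(x)
      metric_value(cv, metric_spec("V_DOSE", x)), numeric(1))
    expect_true(all(diff(vs) <= 1e-9))
    expect_lte(metric_value(cv, "Dmin[Gy]"),
               metric_value(cv, "Dmean[Gy]") + 1e-9)
    expect_lte(metric_value(cv, "Dmean[Gy]"),
               metric_value(cv, "Dmax[Gy]") + 1e-9)
  }
})

test_that("metric grammar parses, canonicalizes and round-trips", {
  s <- parse_metric("V3Gy[%]")
  expect_equal(s$kind, "V_DOSE"); expect_equal(s$threshold, 3)
  expect_equal(s$unit_out, "PCT")
  expect_equal(parse_metric("Dmean[Gy]")$kind, "DMEAN")
  expect_equal(parse_metric("V16Gy[%]")$threshold, 16)
  # canonicalization of case/whitespace and defaults
  for (t in c(" v16gy[%] ", "V16Gy", "V16Gy[%]"))
    expect_equal(format_metric(parse_metric(t)), "V16Gy[%]")
  for (t in c("V3Gy[cc]", "D95%[Gy]", "D2cc[Gy]", "Dmean[Gy]", "Dmax[Gy]",
              "Dmin[Gy]", "V24.7Gy[%]"))
    expect_identical(format_metric(parse_metric(t)), t)
  expect_error(parse_metric("Q17"), "grammar")
  expect_error(parse_metric("VGy[%]"), "grammar")
})
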