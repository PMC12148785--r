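# Reader contracts: generator round-trips, modality guards, DVH-table
# validation.

phantom <- make_phantom(demo_phantom_spec("clean"), tempfile())

test_that("RTDOSE round-trips geometry and scaled dose", {
  grid <- read_rtdose(phantom$paths[["rtdose"]])
  expect_equal(dim(grid$values), c(40, 40, 20))
  expect_equal(grid$spacing, c(2, 2, 2), tolerance = 1e-6)
  expect_equal(grid$origin, c(0, 0, 0), tolerance = 1e-6)
  # scaling applied, never rescaled: stored int * file scaling
  expect_equal(sort(unique(round(as.vector(grid$values), 6))),
               c(0, 1, 3, 26), tolerance = 1e-4)
  expect_equal(grid$values, phantom$dose_array, tolerance = 1e-4)
})

test_that("RTDOSE shape follows the written grid", {
  spec <- phantom_spec(shape = c(20, 20, 10), spacing = c(2, 2, 2),
                       regions = list(list(extent = c(-1, 39, -1, 39, -1, 19),
                                           dose = 10)),
                       structures = list(list(name = "box",
                                              extent = c(1, 9, 1, 9, 1, 9))))
  res <- make_phantom(spec, tempfile())
  grid <- read_rtdose(res$paths[["rtdose"]])
  expect_equal(dim(grid$values), c(20, 20, 10))
})

test_that("modality mismatches raise format errors naming the expectation", {
  expect_error(read_rtdose(phantom$paths[["rtstruct"]]), "RTDOSE")
  expect_error(read_rtstruct(phantom$paths[["rtdose"]]), "RTSTRUCT")
  expect_error(read_rtplan(phantom$paths[["rtdose"]]), "RTPLAN")
})

test_that("RTSTRUCT preserves names and geometry verbatim", {
  structs <- read_rtstruct(phantom$paths[["rtstruct"]])
  expect_setequal(vapply(structs, function(s) s$name, character(1)),
                  c("PTV_breast DX", "Polmone DX", "Cuore", "Polmone SX",
                    "Breast SX"))
  ptv <- structs[[which(vapply(structs, function(s) s$name, character(1)) ==
                          "PTV_breast DX")]]
  expect_true(ptv$evaluable)
  expect_equal(range(vapply(ptv$contours, function(p) p[1, 3], numeric(1))),
               c(4, 34))
  expect_equal(ptv$contours[[1]][, 1:2],
               matrix(c(11, 11, 37, 11, 37, 37, 11, 37), ncol = 2,
                      byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("degenerate and empty ROIs are flagged, not fatal", {
  spec <- phantom_spec(
    shape = c(10, 10, 5), spacing = c(2, 2, 2),
    regions = list(list(extent = c(-1, 19, -1, 19, -1, 9), dose = 5)),
    structures = list(list(name = "dot", extent = c(4, 4, 4, 4, 4, 4),
                           point = TRUE)))
  res <- make_phantom(spec, tempfile())
  expect_warning(structs <- read_rtstruct(res$paths[["rtstruct"]]),
                 "non-evaluable|degenerate")
  expect_false(structs[[1]]$evaluable)
  # empty structure set: an empty list, not an error
  spec2 <- phantom_spec(shape = c(10, 10, 5), spacing = c(2, 2, 2),
                        regions = list(), structures = list())
  res2 <- make_phantom(spec2, tempfile())
  expect_length(read_rtstruct(res2$paths[["rtstruct"]]), 0L)
})

test_that("RTPLAN carries prescription, fractions, beams and setup flags", {
  plan <- read_rtplan(phantom$paths[["rtplan"]])
  expect_equal(plan$prescription_dose, 26, tolerance = 1e-9)
  expect_equal(plan$n_fractions, 5L)
  expect_length(plan$beams, 3L)
  expect_equal(sum(vapply(plan$beams, function(b) b$is_setup, logical(1))),
               1L)
  arcs <- Filter(function(b) !b$is_setup, plan$beams)
  expect_equal(vapply(arcs, function(b) b$mu, numeric(1)), c(200.1, 196.2))
  expect_equal(vapply(arcs, function(b) b$technique_hint, character(1)),
               c("ARC", "ARC"))
  expect_equal(arcs[[1]]$dose_rate, 600)
  expect_equal(arcs[[1]]$jaw_x_width, 120, tolerance = 1e-6)
  expect_equal(arcs[[1]]$isocenter, c(24, 24, 19), tolerance = 1e-6)
})

test_that("plans with two isocenters are read intact (PSC decides later)", {
  spec <- demo_phantom_spec("clean")
  spec$plan$beams[[2]]$isocenter <- c(0, 0, 0)
  res <- make_phantom(spec, tempfile())
  plan <- read_rtplan(res$paths[["rtplan"]])
  isos <- unique(t(vapply(Filter(function(b) !b$is_setup, plan$beams),
                          function(b) b$isocenter, numeric(3))))
  expect_equal(nrow(isos), 2L)
})

test_that("DVH tables parse, validate monotonicity and flag missing cm3", {
  path <- tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(structure = "A", dose_gy = c(0, 1, 2),
               volume_pct = c(100, 50, 0), volume_cc = c(30, 15, 0)),
    data.frame(structure = "B", dose_gy = c(0, 1, 2),
               volume_pct = c(100, 100, 100), volume_cc = NA))
  write.csv(df, path, row.names = FALSE)
  curves <- read_dvh_table(path)
  expect_length(curves, 2L)
  expect_equal(curves[[1]]$total_volume_cc, 30)
  # absolute-volume metric on the cc-less curve errors cleanly
  expect_error(metric_value(curves[[2]], "D2cc[Gy]"), "absolute volume")
  # non-monotone curve: validation error naming the structure
  bad <- data.frame(structure = "C", dose_gy = c(0, 1, 2),
                    volume_pct = c(100, 40, 60), volume_cc = NA)
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_dvh_table(path), "C")
  # missing columns
  write.csv(data.frame(structure = "A", dose_gy = 0), path,
            row.names = FALSE)
  expect_error(read_dvh_table(path), "columns")
})
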