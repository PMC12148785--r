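# Synthetic fixtures: box phantoms written as DICOM-RT triplets with an
# analytic metric table (the oracle for the DVH engine), and seeded
# community libraries with specified metric distributions. Axis-aligned
# boxes keep every DVH metric exactly computable; anatomical realism is a
# non-goal.

#' Box-phantom specification
#'
#' @param shape grid size `c(nx, ny, nz)` (voxels).
#' @param spacing voxel pitch `c(dx, dy, dz)`, mm.
#' @param origin first voxel center, mm.
#' @param regions list of `list(extent = c(x0,x1,y0,y1,z0,z1), dose = Gy)`;
#'   later regions overwrite earlier ones where they overlap. Extents snap
#'   to voxel boundaries and doses to the 0.05 Gy DVH bin, so that the
#'   analytic table is exact and robust to the file's integer dose scaling.
#' @param structures list of `list(name, extent)`; extents need not snap
#'   (fractional in-plane overlap is what the supersampling tests exercise).
#' @param plan list: `plan_id`, `patient_id`, `dose_per_fraction_gy`,
#'   `n_fractions`, and `beams` (each `list(id, mu, dose_rate, jaw_x,
#'   jaw_y, isocenter, is_setup, couch, technique)` with technique one of
#'   STATIC / DYNAMIC / ARC; jaw values are full widths in mm).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(40, 40, 20), spacing = c(2, 2, 2),
                         origin = c(0, 0, 0), regions = list(),
                         structures = list(), plan = NULL) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), regions = regions,
                 structures = structures, plan = plan),
            class = "phantom_spec")
}

.snap_idx <- function(lo, hi, origin, d, n) {
  # voxel boundaries sit at origin + (k - 0.5) d, k = 0..n; return the
  # 1-based voxel index range covered after snapping
  k0 <- round((lo - origin) / d + 0.5)
  k1 <- round((hi - origin) / d + 0.5)
  c(max(k0, 0L) + 1L, min(k1, n))
}

.rasterize_regions <- function(spec) {
  arr <- array(0, dim = spec$shape)
  for (rg in spec$regions) {
    e <- rg$extent
    ix <- .snap_idx(e[1], e[2], spec$origin[1], spec$spacing[1], spec$shape[1])
    iy <- .snap_idx(e[3], e[4], spec$origin[2], spec$spacing[2], spec$shape[2])
    iz <- .snap_idx(e[5], e[6], spec$origin[3], spec$spacing[3], spec$shape[3])
    if (ix[1] > ix[2] || iy[1] > iy[2] || iz[1] > iz[2]) next
    arr[ix[1]:ix[2], iy[1]:iy[2], iz[1]:iz[2]] <- round(rg$dose / 0.05) * 0.05
  }
  arr
}

.analytic_metrics <- function(spec, arr) {
  rows <- list()
  doses_all <- sort(unique(as.vector(arr)))
  for (st in spec$structures) {
    e <- st$extent
    ov1 <- function(centers, d, lo, hi)
      pmax(0, pmin(centers + d / 2, hi) - pmax(centers - d / 2, lo))
    cx <- spec$origin[1] + (seq_len(spec$shape[1]) - 1L) * spec$spacing[1]
    cy <- spec$origin[2] + (seq_len(spec$shape[2]) - 1L) * spec$spacing[2]
    cz <- spec$origin[3] + (seq_len(spec$shape[3]) - 1L) * spec$spacing[3]
    wx <- ov1(cx, spec$spacing[1], e[1], e[2])
    wy <- ov1(cy, spec$spacing[2], e[3], e[4])
    # slab model in z: a grid plane whose center lies inside the box
    # contributes a full dz-thick slab (planar-contour convention)
    wz <- ifelse(cz >= e[5] - 1e-9 & cz <= e[6] + 1e-9, spec$spacing[3], 0)
    w <- outer(outer(wx, wy), wz)      # mm^3 per voxel
    tot <- sum(w)
    if (tot <= 0) next
    dmean <- sum(w * arr) / tot
    dvals <- arr[w > 0]
    wvals <- w[w > 0]
    add <- function(metric, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        structure = st$name, metric = metric, value = value)
    add("volume_cc", tot / 1000)
    add("Dmean[Gy]", dmean)
    add("Dmax[Gy]", max(dvals))
    add("Dmin[Gy]", min(dvals))
    thresholds <- sort(unique(c(
      doses_all[doses_all > 0],
      (head(doses_all, -1) + doses_all[-1]) / 2)))
    for (d in thresholds)
      add(sprintf("V%sGy[%%]", .fmt_num(d)),
          100 * sum(wvals[dvals >= d - 1e-9]) / tot)
  }
  do.call(rbind, rows)
}

.rect_contour <- function(e, z) {
  matrix(c(e[1], e[3], z,  e[2], e[3], z,  e[2], e[4], z,  e[1], e[4], z),
         ncol = 3, byrow = TRUE)
}

.dose_dataset <- function(spec, arr, uid) {
  scaling <- 2^-15
  stored <- as.integer(ceiling(arr / scaling - 1e-9))
  nz <- spec$shape[3]
  list(
    dcm_el(0x0008, 0x0016, "UI", SOP_RTDOSE),
    dcm_el(0x0008, 0x0018, "UI", uid()),
    dcm_el(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_el(0x0020, 0x0032, "DS", spec$origin),
    dcm_el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    dcm_el(0x0020, 0x0052, "UI", uid()),
    dcm_el(0x0028, 0x0002, "US", 1L),
    dcm_el(0x0028, 0x0008, "IS", nz),
    dcm_el(0x0028, 0x0010, "US", spec$shape[2]),
    dcm_el(0x0028, 0x0011, "US", spec$shape[1]),
    dcm_el(0x0028, 0x0030, "DS", c(spec$spacing[2], spec$spacing[1])),
    dcm_el(0x0028, 0x0100, "US", 32L),
    dcm_el(0x0028, 0x0103, "US", 0L),
    dcm_el(0x3004, 0x0002, "CS", "GY"),
    dcm_el(0x3004, 0x000A, "CS", "PLAN"),
    dcm_el(0x3004, 0x000C, "DS", (seq_len(nz) - 1L) * spec$spacing[3]),
    dcm_el(0x3004, 0x000E, "DS", scaling),
    dcm_el(0x7FE0, 0x0010, "OW",
           writeBin(as.vector(stored), raw(), size = 4, endian = "little")))
}

.struct_dataset <- function(spec, uid) {
  cz <- spec$origin[3] + (seq_len(spec$shape[3]) - 1L) * spec$spacing[3]
  roi_items <- list(); con_items <- list()
  for (i in seq_along(spec$structures)) {
    st <- spec$structures[[i]]
    roi_items[[i]] <- list(dcm_el(0x3006, 0x0022, "IS", i),
                           dcm_el(0x3006, 0x0026, "LO", st$name))
    e <- st$extent
    planes <- cz[cz >= e[5] - 1e-9 & cz <= e[6] + 1e-9]
    cseq <- lapply(planes, function(z) {
      pts <- .rect_contour(e, z)
      list(dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
           dcm_el(0x3006, 0x0046, "IS", nrow(pts)),
           dcm_el(0x3006, 0x0050, "DS", as.vector(t(pts))))
    })
    if (!is.null(st$point) && isTRUE(st$point)) {
      cseq <- list(list(dcm_el(0x3006, 0x0042, "CS", "POINT"),
                        dcm_el(0x3006, 0x0046, "IS", 1L),
                        dcm_el(0x3006, 0x0050, "DS",
                               c(e[1], e[3], e[5]))))
    }
    con_items[[i]] <- c(list(dcm_el(0x3006, 0x0084, "IS", i),
                             dcm_el(0x3006, 0x002A, "IS", c(255L, 0L, 0L))),
                        if (length(cseq))
                          list(dcm_el(0x3006, 0x0040, "SQ", cseq)))
  }
  list(dcm_el(0x0008, 0x0016, "UI", SOP_RTSTRUCT),
       dcm_el(0x0008, 0x0018, "UI", uid()),
       dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
       dcm_el(0x3006, 0x0020, "SQ", roi_items),
       dcm_el(0x3006, 0x0039, "SQ", con_items))
}

.plan_dataset <- function(plan, uid) {
  beams <- plan$beams %||% list()
  beam_items <- list(); ref_items <- list()
  for (i in seq_along(beams)) {
    b <- beams[[i]]
    tech <- b$technique %||% "STATIC"
    jaw <- function(width) if (is.null(width) || is.na(width)) NULL
      else c(-width / 2, width / 2)
    bld <- list()
    if (!is.null(jaw(b$jaw_x)))
      bld <- c(bld, list(list(dcm_el(0x300A, 0x00B8, "CS", "X"),
                              dcm_el(0x300A, 0x011C, "DS", jaw(b$jaw_x)))))
    if (!is.null(jaw(b$jaw_y)))
      bld <- c(bld, list(list(dcm_el(0x300A, 0x00B8, "CS", "Y"),
                              dcm_el(0x300A, 0x011C, "DS", jaw(b$jaw_y)))))
    cp <- c(list(dcm_el(0x300A, 0x0112, "IS", 0L),
                 dcm_el(0x300A, 0x0115, "DS", b$dose_rate %||% 600),
                 dcm_el(0x300A, 0x011E, "DS", b$gantry %||% 0),
                 dcm_el(0x300A, 0x011F, "CS",
                        if (tech == "ARC") "CW" else "NONE"),
                 dcm_el(0x300A, 0x0122, "DS", b$couch %||% 0),
                 dcm_el(0x300A, 0x012C, "DS",
                        b$isocenter %||% c(0, 0, 0))),
            if (length(bld)) list(dcm_el(0x300A, 0x011A, "SQ", bld)))
    beam_items[[i]] <- list(
      dcm_el(0x300A, 0x00C0, "IS", i),
      dcm_el(0x300A, 0x00C2, "LO", b$id %||% sprintf("beam%d", i)),
      dcm_el(0x300A, 0x00C4, "CS",
             if (tech == "DYNAMIC") "DYNAMIC" else "STATIC"),
      dcm_el(0x300A, 0x00C6, "CS", "PHOTON"),
      dcm_el(0x300A, 0x00CE, "CS",
             if (isTRUE(b$is_setup)) "SETUP" else "TREATMENT"),
      dcm_el(0x300A, 0x0111, "SQ", list(cp)))
    if (!isTRUE(b$is_setup))
      ref_items[[length(ref_items) + 1L]] <- list(
        dcm_el(0x300C, 0x0006, "IS", i),
        dcm_el(0x300A, 0x0084, "DS",
               plan$dose_per_fraction_gy / max(1, sum(!vapply(
                 beams, function(x) isTRUE(x$is_setup), logical(1))))),
        dcm_el(0x300A, 0x0086, "DS", b$mu %||% 0))
  }
  fg <- c(list(dcm_el(0x300A, 0x0078, "IS", plan$n_fractions),
               dcm_el(0x300A, 0x0071, "IS", 1L)),
          if (length(ref_items))
            list(dcm_el(0x300C, 0x0004, "SQ", ref_items)))
  dr <- list(list(dcm_el(0x300A, 0x0026, "DS",
                         plan$dose_per_fraction_gy * plan$n_fractions)))
  c(list(dcm_el(0x0008, 0x0016, "UI", SOP_RTPLAN),
         dcm_el(0x0008, 0x0018, "UI", uid()),
         dcm_el(0x0008, 0x0060, "CS", "RTPLAN"),
         dcm_el(0x0010, 0x0020, "LO", plan$patient_id %||% "PHANTOM"),
         dcm_el(0x300A, 0x0002, "SH", plan$plan_id %||% "phantom_plan"),
         dcm_el(0x300A, 0x0010, "SQ", dr),
         dcm_el(0x300A, 0x0070, "SQ", list(fg))),
    if (length(beam_items)) list(dcm_el(0x300A, 0x00B0, "SQ", beam_items)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a box phantom as a DICOM-RT triplet + analytic metric table
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with file `paths` (rtdose, rtstruct, rtplan,
#'   analytic_metrics) and the in-memory `analytic` table; running the same
#'   spec twice produces byte-identical files (UIDs are deterministic).
#' @export
make_phantom <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uid <- .uid_factory()
  arr <- .rasterize_regions(spec)
  paths <- c(rtdose = file.path(out_dir, "rtdose.dcm"),
             rtstruct = file.path(out_dir, "rtstruct.dcm"),
             rtplan = file.path(out_dir, "rtplan.dcm"),
             analytic = file.path(out_dir, "analytic_metrics.csv"))
  dcm_write(paths[["rtdose"]], .dose_dataset(spec, arr, uid))
  dcm_write(paths[["rtstruct"]], .struct_dataset(spec, uid))
  if (!is.null(spec$plan))
    dcm_write(paths[["rtplan"]], .plan_dataset(spec$plan, uid))
  analytic <- .analytic_metrics(spec, arr)
  utils::write.csv(analytic, paths[["analytic"]], row.names = FALSE)
  list(paths = paths, analytic = analytic, dose_array = arr)
}

.rdist <- function(n, d) {
  if (!is.null(d$values)) {
    stopifnot(length(d$values) == n)
    return(d$values)
  }
  switch(d$dist,
    normal = stats::rnorm(n, if (length(d$mean) == n) d$mean else d$mean[1],
                          d$sd),
    lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
    uniform = stats::runif(n, d$min, d$max),
    stop("unknown distribution: ", d$dist))
}

#' Generate a seeded community plan library
#'
#' Emulates, at desk scale, a library accumulated by a small community of
#' planners. Categorical mixes and metric distributions are configurable;
#' an explicit `values` vector in a metric spec bypasses the distribution
#' (used to construct exact-count harnesses).
#'
#' @param n number of records.
#' @param out_path library CSV path.
#' @param seed RNG seed (single global seed; draws are made column-wise in
#'   a fixed order, so records are reproducible).
#' @param protocol protocol name stamped on all records.
#' @param users named probability vector of user names (or plain character
#'   vector for a uniform mix).
#' @param laterality,technique named probability vectors.
#' @param boost_p,nodes_p,bh_p probabilities of boost / nodes / breath-hold.
#' @param metrics named list of metric-column specs:
#'   `list(dist = "normal", mean =, sd =)` (mean may be a length-`n`
#'   vector), `list(dist = "uniform", min =, max =)`,
#'   `list(dist = "lognormal", meanlog =, sdlog =)` or
#'   `list(values = <length-n vector>)`.
#' @param mu_sum distribution spec for the MU sum column.
#' @param start_time ISO-8601 timestamp of the first record; successive
#'   records step 97 minutes.
#' @return invisibly, the library as a data.frame (also written to
#'   `out_path` when non-`NULL`).
#' @export
make_library <- function(n, out_path = NULL, seed = 1L,
                         protocol = "FAST_FORWARD",
                         users = c(alice = 0.5, bob = 0.5),
                         laterality = c(RIGHT = 0.5, LEFT = 0.5),
                         technique = c(VMAT = 0.6, THREE_DCRT = 0.4),
                         boost_p = 0.3, nodes_p = 0.1, bh_p = 0.2,
                         metrics = list(), mu_sum = list(dist = "normal",
                                                        mean = 400, sd = 60),
                         start_time = "2024-01-01T08:00:00") {
  stopifnot(n >= 1L)
  set.seed(seed)
  if (is.null(names(users))) users <- stats::setNames(
    rep(1 / length(users), length(users)), users)
  pick <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  t0 <- as.POSIXct(start_time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df <- data.frame(
    timestamp = format(t0 + (seq_len(n) - 1L) * 97 * 60,
                       "%Y-%m-%dT%H:%M:%S"),
    user = pick(users),
    patient_key = vapply(seq_len(n), function(i)
      patient_key(sprintf("synthetic-%d-%d", seed, i)), character(1)),
    plan_id = sprintf("plan%03d", seq_len(n)),
    protocol = protocol,
    laterality = pick(laterality),
    boost = c("false", "true")[stats::rbinom(n, 1, boost_p) + 1L],
    nodes = c("false", "true")[stats::rbinom(n, 1, nodes_p) + 1L],
    breast_mod = "NONE",
    technique = pick(technique),
    tech_mods = c("", "BH")[stats::rbinom(n, 1, bh_p) + 1L],
    bolus = "NONE",
    mu_sum = round(.rdist(n, mu_sum), 1),
    score_pct = round(stats::runif(n, 70, 100)),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(metrics)) {
    vals <- .rdist(n, metrics[[nm]])
    df[[nm]] <- round(vals, 3)
    d <- metrics[[nm]]
    if (is.null(d$values) && identical(d$dist, "normal") &&
        length(d$mean) == 1L && n >= 4L) {
      tol <- 4 * d$sd / sqrt(n)
      if (abs(mean(vals) - d$mean) > tol)
        warning("library self-check: empirical mean of ", nm,
                " deviates more than 4*sd/sqrt(n) from specification")
    }
  }
  if (!is.null(out_path)) {
    lines <- c(LIB_SCHEMA_LINE, paste(names(df), collapse = ","),
               do.call(paste, c(lapply(df, as.character), sep = ",")))
    writeLines(lines, out_path)
  }
  invisible(df)
}
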