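# Cumulative DVH computation from a dose grid + planar contours, and the
# metric grammar (VxGy / Dv% / Dvcc / Dmean / Dmax / Dmin) evaluated on
# cumulative curves.
#
# Conventions (documented in the methods vignette):
#  * membership by even-odd point-in-polygon on voxel (sub)centers, contours
#    assigned to the nearest grid plane within dz/2 (slab model in z);
#  * cumulative value at a bin edge d is the volume with dose >= d;
#  * Dmean/Dmax use the bin-center convention on the differential rebinning,
#    so both carry at most half-bin (0.025 Gy at defaults) discretization.

#' Cumulative DVH curve
#'
#' @param structure_name structure the curve belongs to.
#' @param dose_bins ascending bin edges, Gy.
#' @param cum_volume_pct percent of structure volume receiving at least the
#'   edge dose; monotone non-increasing, starts at 100.
#' @param cum_volume_cc same in cm3 (optional).
#' @param total_volume_cc structure volume in cm3 (optional).
#' @param bin_width bin width in Gy (NA for imported curves with uneven bins).
#' @return a `dvh_curve` object.
#' @export
dvh_curve <- function(structure_name, dose_bins, cum_volume_pct,
                      cum_volume_cc = NULL, total_volume_cc = NA_real_,
                      bin_width = NA_real_) {
  stopifnot(length(dose_bins) == length(cum_volume_pct))
  if (is.unsorted(dose_bins, strictly = TRUE))
    stop("dose_bins must be strictly ascending")
  if (any(diff(cum_volume_pct) > 1e-9))
    stop("cum_volume_pct must be monotone non-increasing")
  if (abs(cum_volume_pct[1] - 100) > 1e-9)
    stop("cumulative curve must start at 100% at dose 0")
  if (any(cum_volume_pct < -1e-9 | cum_volume_pct > 100 + 1e-9))
    stop("cum_volume_pct out of [0, 100]")
  structure(list(structure_name = structure_name,
                 dose_bins = as.numeric(dose_bins),
                 cum_volume_pct = pmin(pmax(cum_volume_pct, 0), 100),
                 cum_volume_cc = cum_volume_cc,
                 total_volume_cc = total_volume_cc,
                 bin_width = bin_width),
            class = "dvh_curve")
}

# Even-odd (crossing-number) point-in-polygon, vectorized over points.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Compute a cumulative DVH
#'
#' Voxel (sub)centers are classified against the structure's contours on the
#' nearest grid plane (tolerance dz/2) with the even-odd rule, so an inner
#' contour subtracts (holes). In-plane supersampling subdivides each voxel
#' `supersample` times per axis; the z direction keeps the one-slab-per-plane
#' model of planar contours.
#'
#' @param grid a [dose_grid()].
#' @param structure an [rt_structure()] with at least one valid polygon
#'   overlapping the grid.
#' @param bin_width DVH bin width, Gy. Default 0.05 Gy resolves well below
#'   any shipped constraint threshold.
#' @param supersample in-plane subdivision factor per axis (default 2).
#' @return a [dvh_curve()] with absolute volumes in cm3.
#' @export
compute_dvh <- function(grid, structure, bin_width = 0.05, supersample = 2L) {
  stopifnot(inherits(grid, "dose_grid"), inherits(structure, "rt_structure"))
  if (!structure$evaluable || length(structure$contours) == 0L)
    stop("structure '", structure$name, "' has no valid contours")
  s <- as.integer(supersample)
  stopifnot(s >= 1L, bin_width > 0)
  dims <- dim(grid$values)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]; dz <- grid$spacing[3]
  zs <- grid$origin[3] + (seq_len(nz) - 1L) * dz
  # group polygons by nearest plane index
  polys_by_plane <- vector("list", nz)
  any_assigned <- FALSE
  for (p in structure$contours) {
    zc <- p[1, 3]
    iz <- round((zc - grid$origin[3]) / dz) + 1L
    if (iz < 1L || iz > nz || abs(zs[iz] - zc) > dz / 2 + 1e-9) next
    polys_by_plane[[iz]] <- c(polys_by_plane[[iz]], list(p))
    any_assigned <- TRUE
  }
  if (!any_assigned)
    stop("structure '", structure$name, "' has no dose coverage ",
         "(entirely outside the dose grid)")
  off <- ((seq_len(s) - 0.5) / s - 0.5)   # subcenter offsets in voxel units
  subx <- rep(grid$origin[1] + (seq_len(nx) - 1L) * dx, each = s) +
    rep(off * dx, times = nx)
  suby <- rep(grid$origin[2] + (seq_len(ny) - 1L) * dy, each = s) +
    rep(off * dy, times = ny)
  px <- rep(subx, times = ny * s)
  py <- rep(suby, each = nx * s)
  frac_dose <- list()
  for (iz in seq_len(nz)) {
    polys <- polys_by_plane[[iz]]
    if (is.null(polys)) next
    inside <- rep(FALSE, length(px))
    for (p in polys)
      inside <- xor(inside, .points_in_polygon(px, py, p[, 1], p[, 2]))
    if (!any(inside)) next
    # collapse subpoints to per-voxel fractions
    m <- array(inside, dim = c(s, nx, s, ny))
    frac <- apply(m, c(2, 4), sum) / (s * s)
    nzv <- which(frac > 0)
    if (length(nzv) == 0L) next
    frac_dose[[length(frac_dose) + 1L]] <-
      cbind(frac = frac[nzv], dose = grid$values[, , iz][nzv])
  }
  if (length(frac_dose) == 0L)
    stop("structure '", structure$name, "' has zero computed volume ",
         "on the dose grid")
  fd <- do.call(rbind, frac_dose)
  voxel_cc <- dx * dy * dz / 1000
  total_cc <- sum(fd[, "frac"]) * voxel_cc
  dmax <- max(fd[, "dose"])
  # bin index by division with a relative fuzz so a dose lying exactly on a
  # bin edge (up to float noise) is counted in the bin starting at that
  # edge; seq()-built edges alone would misplace such doses
  kmax <- floor(dmax / bin_width + 1e-9) + 1L
  edges <- (0:kmax) * bin_width
  idx <- pmin(floor(fd[, "dose"] / bin_width + 1e-9) + 1L, kmax)
  w <- vapply(seq_along(edges), function(i) sum(fd[idx == i, "frac"]),
              numeric(1))
  cum <- rev(cumsum(rev(w)))
  dvh_curve(structure_name = structure$name, dose_bins = edges,
            cum_volume_pct = 100 * cum / sum(w),
            cum_volume_cc = cum * voxel_cc,
            total_volume_cc = total_cc, bin_width = bin_width)
}

#' Metric specification
#'
#' @param kind one of `V_DOSE`, `D_VOLPCT`, `D_VOLCC`, `DMEAN`, `DMAX`,
#'   `DMIN`.
#' @param threshold Gy for `V_DOSE`; % or cm3 for `D_VOLPCT`/`D_VOLCC`;
#'   unused otherwise.
#' @param unit_out `"PCT"`, `"CC"` or `"GY"`; must be consistent with `kind`.
#' @return a `metric_spec` object.
#' @export
metric_spec <- function(kind, threshold = NA_real_, unit_out = NULL) {
  kinds <- c("V_DOSE", "D_VOLPCT", "D_VOLCC", "DMEAN", "DMAX", "DMIN")
  kind <- match.arg(kind, kinds)
  if (is.null(unit_out))
    unit_out <- if (kind == "V_DOSE") "PCT" else "GY"
  ok <- if (kind == "V_DOSE") unit_out %in% c("PCT", "CC")
        else unit_out == "GY"
  if (!ok) stop("unit_out ", unit_out, " inconsistent with kind ", kind)
  if (kind %in% c("V_DOSE", "D_VOLPCT", "D_VOLCC")) {
    if (is.na(threshold) || threshold < 0)
      stop("threshold must be >= 0 for ", kind)
  }
  structure(list(kind = kind, threshold = as.numeric(threshold),
                 unit_out = unit_out), class = "metric_spec")
}

.fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))

#' Parse / format metric grammar strings
#'
#' Grammar (case-insensitive, whitespace ignored):
#' `V<dose>Gy[%|cc] | D<vol>%[Gy] | D<vol>cc[Gy] | Dmean[Gy] | Dmax[Gy] |
#' Dmin[Gy]`. The bracketed suffix is the output unit and may be omitted
#' (defaults: `%` for V-metrics, `Gy` for D-metrics).
#'
#' @param text metric string, e.g. `"V16Gy[%]"`, `"D95%[Gy]"`, `"Dmean[Gy]"`.
#' @return [parse_metric()]: a [metric_spec()]; [format_metric()]: the
#'   canonical string (round-trip identity).
#' @export
parse_metric <- function(text) {
  t <- gsub("[[:space:]]", "", text)
  tl <- tolower(t)
  num <- "([0-9]+\\.?[0-9]*)"
  m <- regmatches(tl, regexec(paste0("^v", num, "gy(\\[(%|cc)\\])?$"), tl))[[1]]
  if (length(m)) {
    unit <- if (m[4] == "" || m[4] == "%") "PCT" else "CC"
    return(metric_spec("V_DOSE", as.numeric(m[2]), unit))
  }
  m <- regmatches(tl, regexec(paste0("^d", num, "(%|cc)(\\[gy\\])?$"), tl))[[1]]
  if (length(m)) {
    kind <- if (m[3] == "%") "D_VOLPCT" else "D_VOLCC"
    return(metric_spec(kind, as.numeric(m[2]), "GY"))
  }
  m <- regmatches(tl, regexec("^d(mean|max|min)(\\[gy\\])?$", tl))[[1]]
  if (length(m))
    return(metric_spec(paste0("D", toupper(m[2])), NA_real_, "GY"))
  stop("cannot parse metric '", text, "'; grammar is ",
       "V<dose>Gy[%|cc] | D<vol>%[Gy] | D<vol>cc[Gy] | Dmean[Gy] | ",
       "Dmax[Gy] | Dmin[Gy]")
}

#' @rdname parse_metric
#' @param spec a [metric_spec()].
#' @export
format_metric <- function(spec) {
  switch(spec$kind,
    V_DOSE = sprintf("V%sGy[%s]", .fmt_num(spec$threshold),
                     if (spec$unit_out == "PCT") "%" else "cc"),
    D_VOLPCT = sprintf("D%s%%[Gy]", .fmt_num(spec$threshold)),
    D_VOLCC = sprintf("D%scc[Gy]", .fmt_num(spec$threshold)),
    DMEAN = "Dmean[Gy]", DMAX = "Dmax[Gy]", DMIN = "Dmin[Gy]")
}

.half_bin <- function(curve, i) {
  d <- curve$dose_bins
  if (!is.na(curve$bin_width)) return(curve$bin_width / 2)
  if (i < length(d)) (d[i + 1L] - d[i]) / 2 else 0
}

.curve_dmax <- function(curve) {
  nz <- which(curve$cum_volume_pct > 1e-12)
  i <- nz[length(nz)]
  # bin-center convention; a curve truncated above 0% keeps its last edge
  if (i == length(curve$dose_bins)) curve$dose_bins[i]
  else curve$dose_bins[i] + .half_bin(curve, i)
}

.curve_dmin <- function(curve) {
  below100 <- which(curve$cum_volume_pct < 100 - 1e-9)
  if (length(below100) == 0L) return(curve$dose_bins[length(curve$dose_bins)])
  i <- below100[1] - 1L
  curve$dose_bins[i] + .half_bin(curve, i)
}

.curve_dmean <- function(curve) {
  d <- curve$dose_bins
  v <- curve$cum_volume_pct
  # differential mass in [d_i, d_{i+1}) placed at the interval center; any
  # residual mass above the last edge (truncated curve) stays at that edge
  diffm <- -diff(c(v, 0))
  centers <- c((d[-length(d)] + d[-1]) / 2, d[length(d)])
  sum(diffm * centers) / sum(diffm)
}

.inv_lookup <- function(curve, vol_pct) {
  d <- curve$dose_bins
  v <- curve$cum_volume_pct
  if (vol_pct <= 0) return(.curve_dmax(curve))
  if (vol_pct >= 100) return(.curve_dmin(curve))
  i <- which(v <= vol_pct + 1e-12)[1]   # first edge at or below target
  if (is.na(i)) return(.curve_dmax(curve))
  # a flat run exactly at the target resolves to the lowest dose achieving
  # the volume (the run's first edge)
  if (abs(v[i] - vol_pct) <= 1e-12) return(d[i])
  v0 <- v[i - 1L]; v1 <- v[i]
  d[i - 1L] + (v0 - vol_pct) / (v0 - v1) * (d[i] - d[i - 1L])
}

#' Evaluate a dose metric on a cumulative DVH curve
#'
#' V-metrics interpolate the cumulative curve linearly at the threshold dose
#' (0 beyond the curve's support). D-metrics invert the curve with linear
#' interpolation; D at 0% returns Dmax, D at 100% returns Dmin, and flat
#' ties resolve to the lowest dose achieving the volume.
#'
#' @param curve a [dvh_curve()].
#' @param spec a [metric_spec()] (or grammar string).
#' @param prescription optional prescription dose in Gy (reserved for
#'   relative-dose metrics; unused by the shipped grammar).
#' @return scalar metric value in `spec$unit_out` units.
#' @export
metric_value <- function(curve, spec, prescription = NULL) {
  if (is.character(spec)) spec <- parse_metric(spec)
  stopifnot(inherits(curve, "dvh_curve"), inherits(spec, "metric_spec"))
  need_cc <- spec$unit_out == "CC" || spec$kind == "D_VOLCC"
  if (need_cc && (is.null(curve$total_volume_cc) ||
                  is.na(curve$total_volume_cc)))
    stop("metric ", format_metric(spec), " needs absolute volume (cm3), ",
         "which curve '", curve$structure_name, "' does not carry")
  d <- curve$dose_bins
  v <- curve$cum_volume_pct
  switch(spec$kind,
    V_DOSE = {
      pct <- if (spec$threshold > d[length(d)]) 0
      else if (spec$threshold <= d[1]) v[1]
      else stats::approx(d, v, xout = spec$threshold)$y
      if (spec$unit_out == "PCT") pct
      else pct / 100 * curve$total_volume_cc
    },
    D_VOLPCT = .inv_lookup(curve, spec$threshold),
    D_VOLCC = .inv_lookup(curve,
                          100 * spec$threshold / curve$total_volume_cc),
    DMEAN = .curve_dmean(curve),
    DMAX = .curve_dmax(curve),
    DMIN = .curve_dmin(curve))
}
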