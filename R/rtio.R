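# Readers for DICOM-RT objects and tabular DVH exports, plus the internal
# data model (dose grid, structure, beam, plan). Geometry convention: DICOM
# patient space, mm, voxel-center origin, axial identity-orientation grids
# only — anything else is rejected loudly rather than silently misread.

#' Dose grid
#'
#' 3-D absorbed-dose array with geometry. `values` is indexed
#' `[ix, iy, iz]` (x varies fastest, matching DICOM row-major frames read
#' column-major into R), in Gy.
#'
#' @param values 3-D numeric array, Gy, all `>= 0`.
#' @param origin patient-space position of the first voxel center, mm (x,y,z).
#' @param spacing voxel pitch (dx, dy, dz), mm, strictly positive.
#' @param orientation direction cosines (row, column), length 6.
#' @param frame_of_reference identifier string.
#' @return a `dose_grid` object.
#' @export
dose_grid <- function(values, origin, spacing,
                      orientation = c(1, 0, 0, 0, 1, 0),
                      frame_of_reference = "") {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(origin) == 3L, length(spacing) == 3L)
  if (any(values < 0)) stop("dose values must be non-negative")
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (length(values) == 0L) stop("dose array is empty")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 orientation = as.numeric(orientation),
                 frame_of_reference = frame_of_reference),
            class = "dose_grid")
}

#' Contoured structure
#'
#' @param name structure name (verbatim; role matching happens later).
#' @param contours list of closed planar polygons: each a matrix with columns
#'   x, y, z (mm, patient space, constant z per polygon). Polygons are
#'   normalized so the first vertex is not repeated at the end.
#' @param color optional display color.
#' @return an `rt_structure` object; degenerate contour sets (any polygon
#'   with fewer than 3 vertices) mark the structure non-evaluable.
#' @export
rt_structure <- function(name, contours = list(), color = NULL) {
  contours <- lapply(contours, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 3L)
    n <- nrow(p)
    if (n > 1L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    p
  })
  evaluable <- length(contours) > 0L &&
    all(vapply(contours, nrow, integer(1)) >= 3L)
  structure(list(name = name, contours = contours, color = color,
                 evaluable = evaluable),
            class = "rt_structure")
}

#' Beam description
#'
#' @param id beam identifier.
#' @param mu monitor units (>= 0; 0 for setup beams).
#' @param dose_rate nominal dose rate, MU/min.
#' @param jaw_x_width,jaw_y_width field aperture extents, mm.
#' @param isocenter (x, y, z), mm.
#' @param is_setup logical; setup/imaging beam.
#' @param couch_rotation patient support angle, degrees.
#' @param technique_hint one of `"STATIC"`, `"DYNAMIC_MLC"`, `"ARC"`.
#' @return a `beam_info` object.
#' @export
beam_info <- function(id, mu = 0, dose_rate = NA_real_,
                      jaw_x_width = NA_real_, jaw_y_width = NA_real_,
                      isocenter = c(0, 0, 0), is_setup = FALSE,
                      couch_rotation = 0,
                      technique_hint = c("STATIC", "DYNAMIC_MLC", "ARC")) {
  technique_hint <- match.arg(technique_hint)
  if (!is_setup && (is.na(mu) || mu < 0))
    stop("treatment beam must have mu >= 0")
  structure(list(id = as.character(id), mu = as.numeric(mu),
                 dose_rate = as.numeric(dose_rate),
                 jaw_x_width = as.numeric(jaw_x_width),
                 jaw_y_width = as.numeric(jaw_y_width),
                 isocenter = as.numeric(isocenter),
                 is_setup = isTRUE(is_setup),
                 couch_rotation = as.numeric(couch_rotation),
                 technique_hint = technique_hint),
            class = "beam_info")
}

#' Plan description
#'
#' @param plan_id plan label.
#' @param patient_key pseudonymized patient identifier.
#' @param prescription_dose total prescribed dose, Gy (> 0).
#' @param n_fractions number of fractions (>= 1 for single plans).
#' @param beams list of [beam_info()] objects.
#' @param is_plan_sum logical; composite dose without beam-level data.
#' @return a `plan_info` object.
#' @export
plan_info <- function(plan_id, patient_key = "", prescription_dose,
                      n_fractions = 1L, beams = list(),
                      is_plan_sum = FALSE) {
  if (!is.na(prescription_dose) && prescription_dose <= 0)
    stop("prescription_dose must be positive")
  if (!is_plan_sum && n_fractions < 1L)
    stop("n_fractions must be >= 1")
  structure(list(plan_id = as.character(plan_id),
                 patient_key = as.character(patient_key),
                 prescription_dose = as.numeric(prescription_dose),
                 n_fractions = as.integer(n_fractions),
                 beams = beams, is_plan_sum = isTRUE(is_plan_sum)),
            class = "plan_info")
}

.require_modality <- function(ds, expected, path) {
  mod <- dcm_get(ds, 0x0008, 0x0060, "<missing>")
  if (!identical(mod, expected))
    stop(sprintf("%s: expected modality %s, found %s", path, expected, mod))
}

#' Read a DICOM RTDOSE object
#'
#' Applies the file's dose-grid scaling so returned values are physical dose
#' in Gy; per-fraction dose cubes (`DoseSummationType = "FRACTION"`) are
#' scaled to plan totals when `n_fractions` is supplied.
#'
#' @param path RTDOSE file path.
#' @param n_fractions fraction count used to scale per-fraction cubes;
#'   ignored for `PLAN` summation.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(path, n_fractions = NULL) {
  ds <- dcm_read(path)
  .require_modality(ds, "RTDOSE", path)
  scaling <- dcm_get(ds, 0x3004, 0x000E)
  if (is.null(scaling)) stop(path, ": missing DoseGridScaling (3004,000E)")
  orient <- dcm_get(ds, 0x0020, 0x0037, c(1, 0, 0, 0, 1, 0))
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop(path, ": unsupported non-axial grid orientation ",
         paste(orient, collapse = "\\"))
  rows <- dcm_get(ds, 0x0028, 0x0010)
  cols <- dcm_get(ds, 0x0028, 0x0011)
  nframes <- dcm_get(ds, 0x0028, 0x0008, 1L)
  ps <- dcm_get(ds, 0x0028, 0x0030)       # (row pitch = dy, col pitch = dx)
  ipp <- dcm_get(ds, 0x0020, 0x0032)
  gfov <- dcm_get(ds, 0x3004, 0x000C)
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(ipp) ||
      is.null(gfov))
    stop(path, ": incomplete dose-grid geometry")
  dz <- if (length(gfov) > 1L) diff(gfov[1:2]) else 1
  if (length(gfov) > 2L && max(abs(diff(diff(gfov)))) > 1e-6)
    stop(path, ": non-uniform grid frame offsets are not supported")
  bits <- dcm_get(ds, 0x0028, 0x0100, 32L)
  if (bits != 32L) stop(path, ": only 32-bit dose grids are supported")
  px <- dcm_get(ds, 0x7FE0, 0x0010)
  stored <- readBin(px, "integer", n = length(px) %/% 4L, size = 4,
                    endian = "little")
  if (length(stored) != rows * cols * nframes)
    stop(path, ": pixel data size does not match Rows*Columns*Frames")
  # frames are stored row-major (x fastest within a row); reorder to [x,y,z]
  arr <- aperm(array(stored, dim = c(cols, rows, nframes)), c(1, 2, 3))
  values <- arr * scaling
  summation <- dcm_get(ds, 0x3004, 0x000A, "PLAN")
  if (identical(summation, "FRACTION")) {
    if (is.null(n_fractions))
      stop(path, ": per-fraction dose cube; supply n_fractions to scale ",
           "to plan total")
    values <- values * n_fractions
  }
  dose_grid(values, origin = ipp + c(0, 0, gfov[1]),
            spacing = c(ps[2], ps[1], dz),
            orientation = orient,
            frame_of_reference = dcm_get(ds, 0x0020, 0x0052, ""))
}

#' Read a DICOM RTSTRUCT object
#'
#' @param path RTSTRUCT file path.
#' @return list of [rt_structure()] objects, one per ROI (possibly with an
#'   empty contour list, in which case a warning is raised and the structure
#'   is flagged non-evaluable).
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read(path)
  .require_modality(ds, "RTSTRUCT", path)
  roi_seq <- dcm_get(ds, 0x3006, 0x0020, list())
  con_seq <- dcm_get(ds, 0x3006, 0x0039, list())
  names_by_num <- list()
  for (item in roi_seq) {
    num <- dcm_get(item, 0x3006, 0x0022)
    names_by_num[[as.character(num)]] <- dcm_get(item, 0x3006, 0x0026, "")
  }
  contours_by_num <- list()
  colors_by_num <- list()
  for (item in con_seq) {
    num <- as.character(dcm_get(item, 0x3006, 0x0084))
    colors_by_num[[num]] <- dcm_get(item, 0x3006, 0x002A)
    polys <- list()
    for (cnt in dcm_get(item, 0x3006, 0x0040, list())) {
      xyz <- dcm_get(cnt, 0x3006, 0x0050)
      if (is.null(xyz) || length(xyz) < 3L) next
      polys[[length(polys) + 1L]] <-
        matrix(xyz, ncol = 3L, byrow = TRUE,
               dimnames = list(NULL, c("x", "y", "z")))
    }
    contours_by_num[[num]] <- polys
  }
  out <- list()
  for (num in names(names_by_num)) {
    polys <- contours_by_num[[num]]
    if (is.null(polys) || length(polys) == 0L) {
      warning("ROI '", names_by_num[[num]], "' has no geometric contours")
      polys <- list()
    }
    s <- rt_structure(names_by_num[[num]], polys,
                      color = colors_by_num[[num]])
    if (length(polys) > 0L && !s$evaluable)
      warning("ROI '", s$name, "' has degenerate contours; ",
              "flagged non-evaluable")
    out[[length(out) + 1L]] <- s
  }
  out
}

.classify_beam <- function(beam_item, mu_by_number, nfx) {
  cp <- dcm_get(beam_item, 0x300A, 0x0111, list())
  cp1 <- if (length(cp) > 0L) cp[[1]] else list()
  rot <- dcm_get(cp1, 0x300A, 0x011F, "NONE")
  btype <- dcm_get(beam_item, 0x300A, 0x00C4, "STATIC")
  hint <- if (!identical(rot, "NONE")) "ARC"
          else if (identical(btype, "DYNAMIC")) "DYNAMIC_MLC" else "STATIC"
  jaw_w <- c(x = NA_real_, y = NA_real_)
  for (bld in dcm_get(cp1, 0x300A, 0x011A, list())) {
    dev <- dcm_get(bld, 0x300A, 0x00B8, "")
    pos <- dcm_get(bld, 0x300A, 0x011C, numeric(0))
    if (length(pos) >= 2L) {
      w <- abs(pos[2] - pos[1])
      if (dev %in% c("X", "ASYMX")) jaw_w["x"] <- w
      if (dev %in% c("Y", "ASYMY")) jaw_w["y"] <- w
    }
  }
  num <- dcm_get(beam_item, 0x300A, 0x00C0)
  delivery <- dcm_get(beam_item, 0x300A, 0x00CE, "TREATMENT")
  mu_fx <- mu_by_number[[as.character(num)]]
  beam_info(
    id = dcm_get(beam_item, 0x300A, 0x00C2,
                 default = as.character(num)),
    mu = if (is.null(mu_fx)) 0 else mu_fx,
    dose_rate = dcm_get(cp1, 0x300A, 0x0115, NA_real_),
    jaw_x_width = jaw_w[["x"]], jaw_y_width = jaw_w[["y"]],
    isocenter = dcm_get(cp1, 0x300A, 0x012C, c(NA_real_, NA_real_, NA_real_)),
    is_setup = identical(delivery, "SETUP"),
    couch_rotation = dcm_get(cp1, 0x300A, 0x0122, 0),
    technique_hint = hint)
}

#' Read a DICOM RTPLAN object
#'
#' The total prescription is taken from the first fraction group: target
#' prescription dose when a dose reference carries one, otherwise the sum of
#' per-fraction beam doses times the planned fraction count. Beam monitor
#' units are per fraction in the file and reported per fraction here
#' (MU-Sum checks compare per-fraction delivery, as treatment consoles do).
#'
#' @param path RTPLAN file path.
#' @return a [plan_info()].
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read(path)
  .require_modality(ds, "RTPLAN", path)
  fg_seq <- dcm_get(ds, 0x300A, 0x0070, list())
  if (length(fg_seq) == 0L)
    stop(path, ": RTPLAN has no fraction group sequence")
  fg <- fg_seq[[1]]
  nfx <- dcm_get(fg, 0x300A, 0x0078, 1L)
  mu_by_number <- list()
  beam_dose_fx <- 0
  for (rb in dcm_get(fg, 0x300C, 0x0004, list())) {
    num <- dcm_get(rb, 0x300C, 0x0006)
    mu_by_number[[as.character(num)]] <- dcm_get(rb, 0x300A, 0x0086, 0)
    beam_dose_fx <- beam_dose_fx + dcm_get(rb, 0x300A, 0x0084, 0)
  }
  rx <- NULL
  for (dr in dcm_get(ds, 0x300A, 0x0010, list())) {
    tpd <- dcm_get(dr, 0x300A, 0x0026)
    if (!is.null(tpd)) { rx <- tpd; break }
  }
  if (is.null(rx)) rx <- beam_dose_fx * nfx
  beams <- lapply(dcm_get(ds, 0x300A, 0x00B0, list()),
                  .classify_beam, mu_by_number = mu_by_number, nfx = nfx)
  plan_info(plan_id = dcm_get(ds, 0x300A, 0x0002, ""),
            patient_key = dcm_get(ds, 0x0010, 0x0020, ""),
            prescription_dose = rx, n_fractions = nfx, beams = beams)
}

#' Read a tabular cumulative-DVH export
#'
#' Long format, UTF-8, "." decimal: header
#' `structure,dose_gy,volume_pct,volume_cc`, one row per (structure, dose
#' bin). `volume_cc` may be entirely blank for a structure, in which case
#' absolute-volume metrics are unavailable for it.
#'
#' @param path CSV path.
#' @return list of [dvh_curve()] objects.
#' @export
read_dvh_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "dose_gy", "volume_pct")
  if (!all(need %in% names(df)))
    stop(path, ": DVH table must have columns ",
         paste(c(need, "volume_cc"), collapse = ", "))
  has_cc <- "volume_cc" %in% names(df)
  out <- list()
  for (nm in unique(df$structure)) {
    sub <- df[df$structure == nm, , drop = FALSE]
    sub <- sub[order(sub$dose_gy), , drop = FALSE]
    if (any(diff(sub$volume_pct) > 1e-9))
      stop("DVH curve for structure '", nm,
           "' is not monotone non-increasing")
    cc <- if (has_cc && !all(is.na(sub$volume_cc))) sub$volume_cc else NULL
    total_cc <- if (!is.null(cc)) max(cc) else NA_real_
    bw <- if (nrow(sub) > 1L) stats::median(diff(sub$dose_gy)) else NA_real_
    out[[length(out) + 1L]] <- dvh_curve(
      structure_name = nm, dose_bins = sub$dose_gy,
      cum_volume_pct = sub$volume_pct, cum_volume_cc = cc,
      total_volume_cc = total_cc, bin_width = bw)
  }
  out
}
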