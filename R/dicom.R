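# Minimal DICOM codec: Explicit VR Little Endian only, defined lengths only.
# Covers the subset of the standard needed for RTDOSE / RTSTRUCT / RTPLAN
# round-trips between the synthetic generator and the readers. Not a general
# DICOM implementation; files from other writers are supported only insofar
# as they use the same transfer syntax and defined-length sequences.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1456"

SOP_RTDOSE   <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_RTPLAN   <- "1.2.840.10008.5.1.4.1.1.481.5"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                 "PN", "SH", "ST", "TM", "UI", "UT")

#' Construct a DICOM data element
#'
#' @param group,element tag halves (integers, e.g. `0x3004`, `0x000E`).
#' @param vr two-letter value representation string.
#' @param value element value: character/numeric vector for string VRs,
#'   integer vector for US/UL, double for FL/FD, raw for OB/OW, and a list
#'   of item datasets (each itself a list of elements) for SQ.
#' @return a `dcm_element` list.
#' @keywords internal
dcm_el <- function(group, element, vr, value) {
  structure(list(group = as.integer(group), element = as.integer(element),
                 vr = vr, value = value), class = "dcm_element")
}

.dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dcm_num_str <- function(x) {
  # DS values: shortest decimal that round-trips exactly (15 digits, then
  # 17); geometry and scaling must survive write -> read unchanged
  vapply(x, function(v) {
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

.dcm_encode_value <- function(vr, value) {
  if (vr == "SQ") {
    out <- raw(0)
    for (item in value) {
      body <- .dcm_encode_dataset(item)
      out <- c(out, writeBin(c(0xFFFEL, 0xE000L), raw(), size = 2,
                             endian = "little"),
               writeBin(length(body), raw(), size = 4, endian = "little"),
               body)
    }
    return(out)
  }
  if (vr %in% c("OB", "OW")) {
    stopifnot(is.raw(value))
    return(.dcm_pad(value, as.raw(0)))
  }
  if (vr %in% c("US", "UL")) {
    size <- if (vr == "US") 2L else 4L
    return(writeBin(as.integer(value), raw(), size = size, endian = "little"))
  }
  if (vr %in% c("FL", "FD")) {
    size <- if (vr == "FL") 4L else 8L
    return(writeBin(as.double(value), raw(), size = size, endian = "little"))
  }
  if (vr %in% .string_vrs) {
    s <- if (vr == "DS" && is.numeric(value)) .dcm_num_str(value)
         else if (vr == "IS" && is.numeric(value)) sprintf("%d", as.integer(value))
         else as.character(value)
    bytes <- charToRaw(paste(s, collapse = "\\"))
    pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
    return(.dcm_pad(bytes, pad))
  }
  stop("unsupported VR for encoding: ", vr)
}

.dcm_encode_element <- function(el) {
  body <- .dcm_encode_value(el$vr, el$value)
  tag <- writeBin(c(el$group, el$element), raw(), size = 2, endian = "little")
  vrb <- charToRaw(el$vr)
  if (el$vr %in% .long_vrs) {
    c(tag, vrb, as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    if (length(body) > 65534L) stop("value too long for short-form VR ", el$vr)
    c(tag, vrb, writeBin(length(body), raw(), size = 2, endian = "little"),
      body)
  }
}

.dcm_encode_dataset <- function(ds) {
  key <- vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1))
  ds <- ds[order(key)]
  do.call(c, lapply(ds, .dcm_encode_element))
}

#' Write a DICOM file (Explicit VR Little Endian)
#'
#' Prepends the 128-byte preamble, "DICM" magic and a file meta group built
#' from the dataset's SOP class/instance UIDs.
#'
#' @param path output path.
#' @param dataset list of [dcm_el()] elements (any order; sorted on write).
#' @keywords internal
dcm_write <- function(path, dataset) {
  get1 <- function(g, e) {
    el <- dcm_find(dataset, g, e)
    if (is.null(el)) stop("dataset lacks required tag for file meta")
    el$value[1]
  }
  meta <- list(
    dcm_el(0x0002, 0x0002, "UI", get1(0x0008, 0x0016)),
    dcm_el(0x0002, 0x0003, "UI", get1(0x0008, 0x0018)),
    dcm_el(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE)
  )
  meta_body <- .dcm_encode_dataset(meta)
  meta_len <- dcm_el(0x0002, 0x0000, "UL", length(meta_body))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.dcm_encode_element(meta_len), con)
  writeBin(meta_body, con)
  writeBin(.dcm_encode_dataset(dataset), con)
  invisible(path)
}

.read_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
.read_u32 <- function(buf, pos) {
  # returns NA for 0xFFFFFFFF (undefined length)
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4, endian = "little")
  if (v == -1L) NA_integer_ else if (v < 0L) stop("length overflow") else v
}

.dcm_decode_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW")) return(bytes)
  if (vr %in% c("US", "UL")) {
    size <- if (vr == "US") 2L else 4L
    return(readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
                   signed = (vr == "UL"), endian = "little"))
  }
  if (vr %in% c("FL", "FD")) {
    size <- if (vr == "FL") 4L else 8L
    return(readBin(bytes, "double", n = length(bytes) %/% size, size = size,
                   endian = "little"))
  }
  s <- rawToChar(bytes[bytes != as.raw(0)])
  s <- sub("[ ]+$", "", s)
  parts <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else character(0)
  parts <- trimws(parts)
  if (vr == "DS") return(as.numeric(parts))
  if (vr == "IS") return(as.integer(parts))
  parts
}

.dcm_parse_sq <- function(buf, pos, end) {
  items <- list()
  while (pos < end) {
    g <- .read_u16(buf, pos); e <- .read_u16(buf, pos + 2L)
    if (g != 0xFFFE || e != 0xE000) stop("malformed sequence item tag")
    len <- .read_u32(buf, pos + 4L)
    if (is.na(len)) stop("undefined-length sequence items are not supported")
    pos <- pos + 8L
    items[[length(items) + 1L]] <- .dcm_parse_dataset(buf, pos, pos + len)
    pos <- pos + len
  }
  items
}

.dcm_parse_dataset <- function(buf, pos, end) {
  out <- list()
  while (pos < end) {
    g <- .read_u16(buf, pos); e <- .read_u16(buf, pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .read_u32(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .read_u16(buf, pos + 6L)
      pos <- pos + 8L
    }
    if (is.na(len)) stop("undefined-length elements are not supported ",
                         sprintf("(tag %04X,%04X)", g, e))
    value <- if (vr == "SQ") .dcm_parse_sq(buf, pos, pos + len)
             else .dcm_decode_value(vr, if (len > 0L) buf[pos:(pos + len - 1L)]
                                        else raw(0))
    out[[length(out) + 1L]] <- dcm_el(g, e, vr, value)
    pos <- pos + len
  }
  out
}

#' Read a DICOM file written in Explicit VR Little Endian
#'
#' @param path file path.
#' @return list of `dcm_element`s (file meta group excluded).
#' @keywords internal
dcm_read <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  # file meta group: always explicit LE; group length element first
  if (.read_u16(buf, pos) != 0x0002)
    stop("file meta information group not found")
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  stopifnot(vr == "UL")
  glen_len <- .read_u16(buf, pos + 6L)
  glen <- readBin(buf[(pos + 8L):(pos + 11L)], "integer", size = 4,
                  endian = "little")
  pos <- pos + 8L + glen_len
  meta <- .dcm_parse_dataset(buf, pos, pos + glen)
  ts <- dcm_get(meta, 0x0002, 0x0010)
  if (is.null(ts) || ts != DCM_TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", if (is.null(ts)) "<missing>" else ts,
         " (only Explicit VR Little Endian is supported)")
  .dcm_parse_dataset(buf, pos + glen, length(buf) + 1L)
}

#' Find / fetch an element in a parsed dataset
#' @keywords internal
dcm_find <- function(ds, group, element) {
  for (el in ds) if (el$group == group && el$element == element) return(el)
  NULL
}

#' @rdname dcm_find
#' @keywords internal
dcm_get <- function(ds, group, element, default = NULL) {
  el <- dcm_find(ds, group, element)
  if (is.null(el)) default else el$value
}

# Deterministic UID factory: root + stream id + counter (no RNG so that
# generated fixtures are byte-identical run to run).
.uid_factory <- function(stream = 1L) {
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste(DCM_UID_ROOT, stream, counter, sep = ".")
  }
}
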