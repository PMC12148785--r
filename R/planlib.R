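# Community plan library: a versioned CSV (one row per export event) plus
# similarity filtering. Dialect: UTF-8, comma separator, "." decimal,
# ISO-8601 timestamps, first line `#schema=1`, fixed prefix columns then
# one role-qualified metric column per protocol constraint.

LIB_SCHEMA_LINE <- "#schema=1"
LIB_PREFIX_COLS <- c("timestamp", "user", "patient_key", "plan_id",
                     "protocol", "laterality", "boost", "nodes",
                     "breast_mod", "technique", "tech_mods", "bolus",
                     "mu_sum", "score_pct")

#' Pseudonymize a patient identifier
#'
#' Salted 32-bit FNV-1a hash rendered as 8 hex digits. The library file
#' never stores the raw identifier.
#'
#' @param id raw identifier string.
#' @param salt site-specific salt (set once in the preferences file).
#' @return 8-character hex string.
#' @export
patient_key <- function(id, salt = "planqc") {
  bytes <- utf8ToInt(paste0(salt, ":", id))
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    h <- .mul32(h, 16777619)
  }
  # h is a double holding a 32-bit value; %x needs integers, so split it
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

.xor32 <- function(a, b) {
  # xor on doubles holding 32-bit unsigned values
  r <- 0; bit <- 1
  for (i in 1:32) {
    if ((a %% 2) != (b %% 2)) r <- r + bit
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
  }
  r
}

.mul32 <- function(a, b) {
  lo <- a %% 65536; hi <- (a - lo) / 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
}

#' Build a library record from an evaluation
#'
#' @param evaluation a `plan_evaluation`.
#' @param plan a [plan_info()].
#' @param user exporting user name.
#' @param mu_sum treatment-beam MU sum (see [sanity_check()]).
#' @param timestamp ISO-8601 export time (default: now, UTC).
#' @param salt pseudonymization salt.
#' @return named character vector, one element per library column.
#' @export
plan_record <- function(evaluation, plan, user, mu_sum = NA_real_,
                        timestamp = NULL, salt = "planqc") {
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  props <- evaluation$properties
  clean <- function(x) gsub(",", ";", as.character(x))
  rec <- c(timestamp = timestamp, user = clean(user),
           patient_key = patient_key(plan$patient_key, salt),
           plan_id = clean(plan$plan_id),
           protocol = evaluation$protocol$name,
           laterality = props$laterality,
           boost = tolower(as.character(props$has_boost)),
           nodes = tolower(as.character(props$has_nodes)),
           breast_mod = props$breast_modifier,
           technique = props$technique,
           tech_mods = paste(props$technique_modifiers, collapse = "+"),
           bolus = props$bolus,
           mu_sum = if (is.na(mu_sum)) "" else .fmt_num(mu_sum),
           score_pct = as.character(evaluation$score_pct))
  for (r in evaluation$results) {
    col <- metric_column(r$constraint)
    rec[col] <- if (is.na(r$value)) "" else sprintf("%.6g", r$value)
  }
  rec
}

#' Library column name of a constraint's metric
#'
#' Role-qualified metric-grammar string, e.g. `"LUNG_IPSI V16Gy[%]"`.
#'
#' @param constraint a [dose_constraint()].
#' @return column name string.
#' @export
metric_column <- function(constraint) {
  paste(constraint$role, format_metric(constraint$metric))
}

.lib_header <- function(record) paste(names(record), collapse = ",")

#' Append a record to the community plan library
#'
#' Creates the file (schema line + header) when absent; otherwise the
#' header must match exactly, or a versioning error points at migration.
#' The append is guarded by a lock directory with retry, then fails.
#'
#' @param library_path CSV path.
#' @param record named character vector from [plan_record()].
#' @param retries lock acquisition attempts (0.1 s apart).
#' @return invisibly, `c(own, total)` record counts for the record's user.
#' @export
append_record <- function(library_path, record, retries = 20L) {
  lock <- paste0(library_path, ".lock")
  got <- FALSE
  for (i in seq_len(retries)) {
    if (dir.create(lock, showWarnings = FALSE)) { got <- TRUE; break }
    Sys.sleep(0.1)
  }
  if (!got) stop("could not lock library ", library_path,
                 " (stale ", lock, "?)")
  on.exit(unlink(lock, recursive = TRUE))
  line <- paste(unname(record), collapse = ",")
  if (!file.exists(library_path)) {
    writeLines(c(LIB_SCHEMA_LINE, .lib_header(record), line), library_path)
  } else {
    lines <- readLines(library_path, warn = FALSE)
    if (length(lines) < 2L || lines[1] != LIB_SCHEMA_LINE)
      stop(library_path, ": not a schema=1 library file")
    if (lines[2] != .lib_header(record))
      stop(library_path, ": header mismatch between library and record ",
           "(library schema differs; migrate the file or export to a new ",
           "library)")
    cat(line, "\n", sep = "", file = library_path, append = TRUE)
  }
  lib <- load_library(library_path, privilege = "ALL")
  own <- sum(lib$user == record[["user"]])
  invisible(c(own = own, total = nrow(lib)))
}

#' Load the community plan library
#'
#' @param library_path CSV path.
#' @param privilege `"ALL"` or `"OWN_ONLY"` (the preferences privilege key).
#' @param user current user, required for `OWN_ONLY`.
#' @return data.frame of records (character prefix columns, numeric
#'   `mu_sum`, `score_pct` and metric columns), ordered as stored.
#'   Malformed rows are skipped with a warning giving the count.
#' @export
load_library <- function(library_path, privilege = c("ALL", "OWN_ONLY"),
                         user = NULL) {
  privilege <- match.arg(privilege)
  if (!file.exists(library_path))
    stop("library file not found: ", library_path)
  lines <- readLines(library_path, warn = FALSE)
  if (length(lines) < 2L || lines[1] != LIB_SCHEMA_LINE)
    stop(library_path, ": not a schema=1 library file")
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  # strsplit drops trailing empty fields; pad to the comma count
  nfield <- vapply(gregexpr(",", body, fixed = TRUE), function(m)
    if (m[1] == -1L) 1L else length(m) + 1L, integer(1))
  parts <- Map(function(p, k) c(p, rep("", k - length(p))), parts, nfield)
  ok <- nfield == length(header)
  if (any(!ok))
    warning("skipped ", sum(!ok), " malformed library row(s)")
  parts <- parts[ok]
  df <- as.data.frame(
    do.call(rbind, c(parts, list(matrix(character(0), 0, length(header))))),
    stringsAsFactors = FALSE)
  names(df) <- header
  num_cols <- setdiff(header, LIB_PREFIX_COLS[1:12])
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  if (privilege == "OWN_ONLY") {
    if (is.null(user)) stop("OWN_ONLY privilege requires a user name")
    df <- df[df$user == user, , drop = FALSE]
  }
  df
}

#' Similarity filter
#'
#' Conjunction of predicates used to fetch comparable plans. All fields but
#' `protocol` are optional; `NA` (the default) means "any".
#'
#' @param protocol protocol name (required).
#' @param laterality,technique,breast_mod exact-match fields or `NA`.
#' @param boost,nodes tri-state: `TRUE`, `FALSE` or `NA` (any).
#' @param require_modifiers,forbid_modifiers technique-modifier token sets
#'   (e.g. `forbid_modifiers = "BH"` excludes breath-hold plans).
#' @param user user name to restrict to, or `NA` (the privilege gate is
#'   applied at load time, this is an additional narrowing).
#' @return a `library_filter` list.
#' @export
library_filter <- function(protocol, laterality = NA, boost = NA,
                           nodes = NA, breast_mod = NA, technique = NA,
                           require_modifiers = character(0),
                           forbid_modifiers = character(0), user = NA) {
  structure(list(protocol = protocol, laterality = laterality,
                 boost = boost, nodes = nodes, breast_mod = breast_mod,
                 technique = technique,
                 require_modifiers = require_modifiers,
                 forbid_modifiers = forbid_modifiers, user = user),
            class = "library_filter")
}

#' Fetch comparable plans from loaded records
#'
#' @param records data.frame from [load_library()].
#' @param filter a [library_filter()].
#' @return the matching subset, ordered by timestamp ascending.
#' @export
filter_similar <- function(records, filter) {
  stopifnot(inherits(filter, "library_filter"))
  keep <- records$protocol == filter$protocol
  eqf <- function(col, want) if (is.na(want)) TRUE else records[[col]] == want
  keep <- keep & eqf("laterality", filter$laterality)
  keep <- keep & eqf("technique", filter$technique)
  keep <- keep & eqf("breast_mod", filter$breast_mod)
  keep <- keep & eqf("user", filter$user)
  tri <- function(col, want) {
    if (is.na(want)) TRUE
    else records[[col]] == tolower(as.character(want))
  }
  keep <- keep & tri("boost", filter$boost)
  keep <- keep & tri("nodes", filter$nodes)
  mods <- strsplit(records$tech_mods, "+", fixed = TRUE)
  for (m in filter$require_modifiers)
    keep <- keep & vapply(mods, function(x) m %in% x, logical(1))
  for (m in filter$forbid_modifiers)
    keep <- keep & !vapply(mods, function(x) m %in% x, logical(1))
  out <- records[keep & !is.na(keep), , drop = FALSE]
  out[order(out$timestamp), , drop = FALSE]
}

#' Read a preferences file
#'
#' Plain text `key = value` lines with optional `[section]` headers;
#' sectioned keys come back as `section.key`. Recognized keys include
#' `user`, `privilege` (ALL / OWN_ONLY), `export_drawer`, `salt`, and the
#' `[sanity]` rule thresholds (see [sanity_rules()]).
#'
#' @param path preferences file path.
#' @return named list of string values.
#' @export
read_preferences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list(); section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- paste0(sub("^\\[(.*)\\]$", "\\1", ln), ".")
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[paste0(section, trimws(kv[1]))]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}
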