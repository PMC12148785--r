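# Plan-property detection (laterality, targets, technique, bolus) and
# structure-to-role matching by name tokens. The lexicon is configuration,
# not code: structure naming differs per clinic, so the shipped English +
# Italian token table (inst/extdata/lexicon.txt) is a starting point users
# are expected to edit.

STRUCTURE_ROLES <- c("PTV_BREAST", "PTV_BOOST", "PTV_NODES",
                     "LUNG_IPSI", "LUNG_CONTRA", "HEART", "LAD",
                     "BREAST_CONTRA", "ESOPHAGUS", "STOMACH", "LIVER",
                     "THYROID", "SKIN")

ROLE_GROUPS <- c(PTV_BREAST = "PTV", PTV_BOOST = "PTV", PTV_NODES = "PTV",
                 LUNG_IPSI = "MAIN_OAR", LUNG_CONTRA = "MAIN_OAR",
                 HEART = "MAIN_OAR", LAD = "MAIN_OAR",
                 BREAST_CONTRA = "MAIN_OAR",
                 ESOPHAGUS = "OTHER_OAR", STOMACH = "OTHER_OAR",
                 LIVER = "OTHER_OAR", THYROID = "OTHER_OAR",
                 SKIN = "OTHER_OAR")

#' Read a structure-name lexicon
#'
#' Plain-text format: one `ROLE: token1, token2, ...` line per role.
#' Besides the mapped roles, the special rows `LEFT` and `RIGHT` list
#' laterality tokens and `LUNG`/`BREAST` list the side-neutral organ tokens
#' used for ipsi/contra resolution.
#'
#' @param path lexicon file; default is the shipped English + Italian table.
#' @return named list of lowercase token character vectors.
#' @export
read_lexicon <- function(path = system.file("extdata", "lexicon.txt",
                                            package = "planqc")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed lexicon line: ", ln)
    toks <- tolower(trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
    out[[trimws(kv[1])]] <- toks[nzchar(toks)]
  }
  out
}

# tokens match case-insensitively as substrings on a word-ish boundary:
# "dx" matches "Polmone DX" and "polmone_dx" but not "index".
.name_has_token <- function(name, token) {
  n <- tolower(name)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", token)
  grepl(paste0("(^|[^a-z])", esc, "([^a-z]|$)"), n)
}

.match_score <- function(name, tokens) {
  hits <- tokens[vapply(tokens, function(t) .name_has_token(name, t),
                        logical(1))]
  if (length(hits) == 0L) 0L else max(nchar(hits))
}

#' Match structures to protocol roles by name
#'
#' Case-insensitive token matching against the lexicon; the ipsilateral /
#' contralateral lung and the contralateral breast are resolved using the
#' plan laterality. Ties break by longest matched token, then alphabetically
#' by structure name; two identically named candidates raise an ambiguity
#' error. Unmatched roles stay empty and their constraints are reported
#' NOT_EVALUATED downstream.
#'
#' @param structures list of [rt_structure()] (or character names).
#' @param laterality `"LEFT"`, `"RIGHT"` or `"BILATERAL"`.
#' @param lexicon token table from [read_lexicon()].
#' @param overrides named character vector `role = structure name`; entries
#'   win over auto-matching and are flagged `source = "USER"`.
#' @return a `structure_mapping`: data.frame with columns `role`,
#'   `structure`, `source`.
#' @export
match_structures <- function(structures, laterality,
                             lexicon = read_lexicon(),
                             overrides = character(0)) {
  names_ <- if (is.character(structures)) structures
            else vapply(structures, function(s) s$name, character(1))
  laterality <- match.arg(laterality, c("LEFT", "RIGHT", "BILATERAL"))
  ipsi_tok <- if (laterality == "RIGHT") lexicon$RIGHT else lexicon$LEFT
  contra_tok <- if (laterality == "RIGHT") lexicon$LEFT else lexicon$RIGHT

  side_score <- function(nm, side_tokens) .match_score(nm, side_tokens)

  role_tokens <- function(role) {
    switch(role,
      LUNG_IPSI = , LUNG_CONTRA = lexicon$LUNG,
      BREAST_CONTRA = lexicon$BREAST,
      lexicon[[role]])
  }

  pick <- function(role) {
    toks <- role_tokens(role)
    if (is.null(toks)) return(NA_character_)
    sc <- vapply(names_, .match_score, integer(1) * 1L, tokens = toks)
    sc <- as.integer(sc)
    if (role %in% c("LUNG_IPSI", "LUNG_CONTRA", "BREAST_CONTRA")) {
      side <- if (role == "LUNG_IPSI") ipsi_tok else contra_tok
      has_side <- vapply(names_, side_score, integer(1) * 1L,
                         side_tokens = side) > 0L
      sc[!has_side] <- 0L
      if (role == "BREAST_CONTRA") {
        # a PTV is never the contralateral breast OAR
        is_ptv <- vapply(names_, .match_score, integer(1) * 1L,
                         tokens = lexicon$PTV_BREAST) > 0L
        sc[is_ptv] <- 0L
      }
    }
    if (all(sc == 0L)) return(NA_character_)
    best <- which(sc == max(sc))
    cand <- sort(names_[best])
    if (length(cand) > 1L && cand[1] == cand[2])
      stop("ambiguous match for role ", role, ": candidates ",
           paste(unique(names_[best]), collapse = ", "))
    cand[1]
  }

  mapped <- vapply(STRUCTURE_ROLES, pick, character(1))
  src <- ifelse(is.na(mapped), NA_character_, "AUTO")
  for (role in names(overrides)) {
    role <- match.arg(role, STRUCTURE_ROLES)
    mapped[role] <- overrides[[role]]
    src[match(role, STRUCTURE_ROLES)] <- "USER"
  }
  # a structure name maps to at most one role: first (role-order) wins,
  # user overrides exempt their structure from the uniqueness sweep
  seen <- character(0)
  for (i in seq_along(mapped)) {
    if (is.na(mapped[i])) next
    if (mapped[i] %in% seen && src[i] == "AUTO") {
      mapped[i] <- NA_character_; src[i] <- NA_character_
    } else seen <- c(seen, mapped[i])
  }
  structure(data.frame(role = STRUCTURE_ROLES, structure = unname(mapped),
                       source = unname(src), stringsAsFactors = FALSE),
            class = c("structure_mapping", "data.frame"))
}

.mapped_structure <- function(mapping, role) {
  s <- mapping$structure[mapping$role == role]
  if (length(s) == 0L || is.na(s)) NA_character_ else s
}

#' Detect plan properties
#'
#' Laterality comes from side tokens in target (PTV) structure names (both
#' sides present means BILATERAL); targets from the matched boost / nodes
#' PTVs; technique from the beam mix (all static open fields: 3DCRT;
#' dynamic-MLC static gantry: IMRT; arcs: VMAT; static fields plus arcs or
#' dynamic fields: HYBRID). Field-wise overrides always win.
#'
#' @param plan a [plan_info()].
#' @param structures list of [rt_structure()] or character names.
#' @param overrides named list overriding any of `laterality`, `has_boost`,
#'   `has_nodes`, `breast_modifier`, `technique`, `technique_modifiers`,
#'   `bolus`.
#' @param lexicon token table from [read_lexicon()].
#' @return a `plan_properties` list.
#' @export
detect_properties <- function(plan, structures, overrides = list(),
                              lexicon = read_lexicon()) {
  names_ <- if (is.character(structures)) structures
            else vapply(structures, function(s) s$name, character(1))
  if (length(names_) == 0L) stop("no structures supplied")
  is_target <- vapply(names_, function(n) {
    .match_score(n, c(lexicon$PTV_BREAST, lexicon$PTV_BOOST,
                      lexicon$PTV_NODES, "ptv")) > 0
  }, logical(1))
  tnames <- names_[is_target]
  has_left <- any(vapply(tnames, .match_score, integer(1) * 1L,
                         tokens = lexicon$LEFT) > 0)
  has_right <- any(vapply(tnames, .match_score, integer(1) * 1L,
                          tokens = lexicon$RIGHT) > 0)
  laterality <- if (!is.null(overrides$laterality)) overrides$laterality
    else if (has_left && has_right) "BILATERAL"
    else if (has_left) "LEFT"
    else if (has_right) "RIGHT"
    else stop("cannot detect laterality from target names (",
              paste(tnames, collapse = ", "),
              "); supply overrides$laterality")
  laterality <- match.arg(laterality, c("LEFT", "RIGHT", "BILATERAL"))

  mapping <- match_structures(names_, laterality, lexicon)
  has_boost <- !is.na(.mapped_structure(mapping, "PTV_BOOST"))
  has_nodes <- !is.na(.mapped_structure(mapping, "PTV_NODES"))

  breast_modifier <- "NONE"
  bname <- .mapped_structure(mapping, "PTV_BREAST")
  if (!is.na(bname)) {
    nl <- tolower(bname)
    if (grepl("exp.?hs|hs.?exp", nl)) breast_modifier <- "EXP_HS"
    else if (.match_score(bname, c("exp", "expander", "impianto",
                                   "implant")) > 0)
      breast_modifier <- "EXP"
    else if (.match_score(bname, c("cw", "chw", "chestwall", "parete",
                                   "chest")) > 0)
      breast_modifier <- "CHESTWALL"
  }

  tb <- Filter(function(b) !b$is_setup, plan$beams)
  hints <- vapply(tb, function(b) b$technique_hint, character(1))
  technique <- if (!is.null(overrides$technique)) overrides$technique
    else if (length(hints) == 0L) "THREE_DCRT"
    else if (any(hints == "STATIC") && any(hints != "STATIC")) "HYBRID"
    else if (any(hints == "ARC")) "VMAT"
    else if (any(hints == "DYNAMIC_MLC")) "IMRT"
    else "THREE_DCRT"
  technique <- match.arg(technique, c("THREE_DCRT", "IMRT", "VMAT", "HYBRID"))

  props <- list(
    laterality = laterality,
    has_boost = if (!is.null(overrides$has_boost)) overrides$has_boost
                else has_boost,
    has_nodes = if (!is.null(overrides$has_nodes)) overrides$has_nodes
                else has_nodes,
    breast_modifier = if (!is.null(overrides$breast_modifier))
      overrides$breast_modifier else breast_modifier,
    technique = technique,
    technique_modifiers = if (!is.null(overrides$technique_modifiers))
      overrides$technique_modifiers else character(0),
    bolus = if (!is.null(overrides$bolus)) overrides$bolus else "NONE")
  props$breast_modifier <- match.arg(props$breast_modifier,
                                     c("NONE", "CHESTWALL", "EXP", "EXP_HS"))
  props$bolus <- match.arg(props$bolus, c("NONE", "ALL", "PARTIAL"))
  stopifnot(all(props$technique_modifiers %in% c("BH", "AP", "TANG")))
  structure(props, class = "plan_properties")
}
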