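#' @title ODM domain model: definitions and the positional metadata tree
#'
#' @description
#' An ODM study defines its case report form structure as a set of reusable
#' definitions (study events, forms, item groups, items, code lists), each
#' identified by a locally unique OID, wired together by ordered references
#' carrying a mandatory flag. Because one definition may be referenced from
#' several places, analysis operates on *positional* elements: one node per
#' placement, identified by the full OID path from the study event down.
#' A form referenced under two study events is analyzed as two separate
#' forms.
#'
#' @name odm_model
#' @keywords internal
NULL

#' Create an item definition
#'
#' @param oid Locally unique identifier (non-empty string).
#' @param name Human-readable item name.
#' @param data_type One of the ODM value types (`"boolean"`, `"string"`,
#'   `"text"`, `"integer"`, `"float"`, `"double"`, `"date"`, `"time"`,
#'   `"datetime"`), or a recognized-but-unsupported ODM type name
#'   (e.g. `"partialDate"`), which marks the item as unanalyzable.
#' @param question Optional question text shown on the CRF.
#' @param codelist_oid OID of an attached code list, or `NULL`. When set,
#'   the item is categorized as ordinal regardless of `data_type`;
#'   `data_type` then records the list's base type.
#' @return An object of class `odm_item_def`.
#' @export
odm_item_def <- function(oid, name = oid, data_type = "string",
                         question = NULL, codelist_oid = NULL) {
  stopifnot(is_oid(oid))
  if (!data_type %in% c(SUPPORTED_DATA_TYPES, KNOWN_UNSUPPORTED_TYPES))
    stop("unknown ODM data type: ", data_type)
  structure(list(oid = oid, name = name, question = question,
                 data_type = data_type, codelist_oid = codelist_oid),
            class = "odm_item_def")
}

#' Create a code list definition
#'
#' @param oid Locally unique identifier.
#' @param options Data frame with columns `coded_value` and `decode`
#'   (decode labels may repeat; coded values must be unique), or a character
#'   vector of coded values (decodes default to the codes).
#' @param data_type Base type of the coded values.
#' @param name Display name.
#' @return An object of class `odm_codelist_def`.
#' @export
odm_codelist_def <- function(oid, options, data_type = "string", name = oid) {
  stopifnot(is_oid(oid))
  if (is.character(options))
    options <- data.frame(coded_value = options, decode = options,
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(options),
            all(c("coded_value", "decode") %in% names(options)))
  if (nrow(options) == 0L) stop("code list must be non-empty: ", oid)
  if (anyDuplicated(options$coded_value))
    stop("duplicated coded values in code list ", oid)
  structure(list(oid = oid, name = name, data_type = data_type,
                 options = options),
            class = "odm_codelist_def")
}

#' Create an element reference
#'
#' A reference places a definition inside a parent and carries the
#' positional mandatory flag: a parent instance is considered incomplete
#' without an instance of a mandatory child.
#'
#' @param target_oid OID of the referenced definition.
#' @param mandatory Logical mandatory flag.
#' @param order Non-negative integer preserving document order.
#' @return An object of class `odm_element_ref`.
#' @export
odm_element_ref <- function(target_oid, mandatory = FALSE, order = 0L) {
  stopifnot(is_oid(target_oid), is.logical(mandatory), length(mandatory) == 1L)
  structure(list(target_oid = target_oid, mandatory = isTRUE(mandatory),
                 order = as.integer(order)),
            class = "odm_element_ref")
}

# Normalize a refs argument: list of odm_element_ref, or character vector
# (all non-mandatory), or named logical vector (names = OIDs, values =
# mandatory flags).
as_ref_list <- function(refs) {
  if (is.null(refs)) return(list())
  if (is.character(refs))
    refs <- lapply(refs, odm_element_ref)
  else if (is.logical(refs) && !is.null(names(refs)))
    refs <- Map(odm_element_ref, names(refs), unname(refs))
  refs <- unname(refs)
  stopifnot(all(vapply(refs, inherits, TRUE, "odm_element_ref")))
  for (i in seq_along(refs)) refs[[i]]$order <- i - 1L
  refs
}

#' Create a definition registry set
#'
#' @param events,forms,groups Named lists of definitions; each definition is
#'   a list with at least `oid`, `name`, and a `refs` list of
#'   [odm_element_ref()] pointing one level down (`events` reference forms,
#'   `forms` reference item groups, `groups` reference items). Group
#'   definitions may carry `repeating = TRUE`.
#' @param items Named list of [odm_item_def()].
#' @param codelists Named list of [odm_codelist_def()].
#' @return An object of class `odm_definitions`.
#' @export
odm_definitions <- function(events = list(), forms = list(), groups = list(),
                            items = list(), codelists = list()) {
  name_by_oid <- function(defs) {
    if (length(defs) == 0L) return(defs)
    stats::setNames(defs, vapply(defs, function(d) d$oid, ""))
  }
  for (nm in c("events", "forms", "groups")) {
    defs <- get(nm)
    for (i in seq_along(defs)) defs[[i]]$refs <- as_ref_list(defs[[i]]$refs)
    assign(nm, defs)
  }
  structure(list(events = name_by_oid(events), forms = name_by_oid(forms),
                 groups = name_by_oid(groups), items = name_by_oid(items),
                 codelists = name_by_oid(codelists)),
            class = "odm_definitions")
}

registry_for_level <- function(level) {
  switch(level, study_event = "events", form = "forms",
         item_group = "groups", item = "items")
}

child_level <- function(level) {
  i <- match(level, ODM_LEVELS)
  if (i < length(ODM_LEVELS)) ODM_LEVELS[i + 1L] else NA_character_
}

#' Build the positional metadata tree
#'
#' Expands the reference graph into a tree in which every placement of a
#' definition is a distinct positional element identified by its OID path.
#' Within one parent each child OID may appear at most once; a duplicate is
#' rejected as a structural error, as is an unresolvable target OID.
#'
#' @param defs An [odm_definitions()] registry set.
#' @param study_refs List of [odm_element_ref()] selecting the study events
#'   (the study-level protocol), or a character vector / named logical
#'   vector shorthand as in [odm_element_ref()].
#' @param study_oid,study_name Study identity carried on the tree.
#' @return An object of class `odm_metadata_tree` with fields `study_oid`,
#'   `study_name`, `events` (ordered positional elements), `defs`, and an
#'   internal path index. Each positional element has `path` (OID vector),
#'   `level`, `oid`, `mandatory`, `def`, and ordered `children`.
#' @export
build_positional_tree <- function(defs, study_refs,
                                  study_oid = "ST", study_name = study_oid) {
  stopifnot(inherits(defs, "odm_definitions"))
  study_refs <- as_ref_list(study_refs)
  index <- new.env(parent = emptyenv())

  expand <- function(ref, level, parent_path) {
    reg <- defs[[registry_for_level(level)]]
    def <- reg[[ref$target_oid]]
    if (is.null(def))
      stop_structural(sprintf("reference to undefined %s OID '%s'",
                              level, ref$target_oid),
                      xml_path = path_key(c(parent_path, ref$target_oid)))
    path <- c(parent_path, ref$target_oid)
    children <- list()
    nxt <- child_level(level)
    if (!is.na(nxt)) {
      refs <- def$refs %||% list()
      seen <- character()
      for (r in refs) {
        if (r$target_oid %in% seen)
          stop_structural(sprintf(
            "OID '%s' referenced more than once inside '%s'",
            r$target_oid, ref$target_oid),
            xml_path = path_key(path))
        seen <- c(seen, r$target_oid)
        children[[length(children) + 1L]] <- expand(r, nxt, path)
      }
    }
    el <- structure(list(path = path, level = level, oid = ref$target_oid,
                         mandatory = ref$mandatory, def = def,
                         children = children),
                    class = "odm_positional_element")
    assign(path_key(path), el, envir = index)
    el
  }

  seen <- character()
  events <- list()
  for (ref in study_refs) {
    if (ref$target_oid %in% seen)
      stop_structural(sprintf(
        "study event OID '%s' referenced more than once in the protocol",
        ref$target_oid))
    seen <- c(seen, ref$target_oid)
    events[[length(events) + 1L]] <- expand(ref, "study_event", character())
  }
  structure(list(study_oid = study_oid, study_name = study_name,
                 events = events, defs = defs, index = index),
            class = "odm_metadata_tree")
}

#' Resolve an instance path against the metadata tree
#'
#' @param tree An `odm_metadata_tree`.
#' @param path Character vector of OIDs from the study event down (an
#'   instance's metadata path; repeat keys are never part of it).
#' @return The matching positional element, or `NULL` when the path is not
#'   defined in the tree (a not-found state, consumed by content
#'   validation — never an error).
#' @export
resolve_instance_path <- function(tree, path) {
  stopifnot(inherits(tree, "odm_metadata_tree"))
  key <- path_key(path)
  if (exists(key, envir = tree$index, inherits = FALSE))
    get(key, envir = tree$index)
  else NULL
}

#' Flatten the positional tree into document order
#'
#' @param tree An `odm_metadata_tree`.
#' @param levels Levels to keep (default: all four).
#' @return List of positional elements, depth-first in metadata order.
#' @export
positional_elements <- function(tree, levels = ODM_LEVELS) {
  out <- list()
  walk <- function(el) {
    if (el$level %in% levels) out[[length(out) + 1L]] <<- el
    for (ch in el$children) walk(ch)
  }
  for (ev in tree$events) walk(ev)
  out
}

#' @export
print.odm_metadata_tree <- function(x, ...) {
  els <- positional_elements(x)
  lv <- vapply(els, function(e) e$level, "")
  cat(sprintf("ODM metadata tree for study '%s' (%s)\n", x$study_oid,
              x$study_name))
  cat(sprintf("  %d study events, %d forms, %d item groups, %d items\n",
              sum(lv == "study_event"), sum(lv == "form"),
              sum(lv == "item_group"), sum(lv == "item")))
  invisible(x)
}

#' Construct an empty clinical dataset
#'
#' Clinical data mirrors the metadata hierarchy: per subject, instances of
#' study events, forms, item groups and items, each discriminated by repeat
#' keys (opaque strings). The dataset is stored as one table per level;
#' every row is one instance, keyed by subject, the OID path and the
#' repeat keys accumulated along it.
#'
#' @param events,forms,groups,items Data frames (see
#'   [clinical_dataset_columns()] for the column contract).
#' @param subject_keys Character vector of all subject keys present in the
#'   file (subjects with no data still count towards totals).
#' @return An object of class `odm_clinical_dataset`.
#' @export
odm_clinical_dataset <- function(events = NULL, forms = NULL, groups = NULL,
                                 items = NULL, subject_keys = character()) {
  cols <- clinical_dataset_columns()
  mk <- function(df, level) {
    want <- cols[[level]]
    if (is.null(df))
      df <- as.data.frame(stats::setNames(
        rep(list(character()), length(want)), want),
        stringsAsFactors = FALSE)
    stopifnot(all(want %in% names(df)))
    df[, c(want, setdiff(names(df), want)), drop = FALSE]
  }
  if (anyDuplicated(subject_keys))
    stop("subject keys must be unique within one file")
  structure(list(events = mk(events, "events"), forms = mk(forms, "forms"),
                 groups = mk(groups, "groups"), items = mk(items, "items"),
                 subject_keys = subject_keys),
            class = "odm_clinical_dataset")
}

#' Column contract of the clinical dataset tables
#'
#' @return Named list of required column names per level table. Repeat-key
#'   columns hold `NA` when the source data carried no repeat key; `value`
#'   holds `NA` for an item tag whose value attribute was absent or empty
#'   (a missing value, distinct from any actual string).
#' @export
clinical_dataset_columns <- function() {
  ev <- c("subject_key", "se_oid", "se_rk")
  fo <- c(ev, "form_oid", "form_rk")
  gr <- c(fo, "group_oid", "group_rk")
  it <- c(gr, "item_oid", "value")
  list(events = ev, forms = fo, groups = gr, items = it)
}

#' @export
print.odm_clinical_dataset <- function(x, ...) {
  cat(sprintf(
    "ODM clinical dataset: %d subjects, %d event / %d form / %d group / %d item instances\n",
    length(x$subject_keys), nrow(x$events), nrow(x$forms), nrow(x$groups),
    nrow(x$items)))
  invisible(x)
}

# Metadata paths of instance rows, as key strings, per level.
instance_path_keys <- function(df, level) {
  switch(level,
    events = df$se_oid,
    forms = paste(df$se_oid, df$form_oid, sep = "/"),
    groups = paste(df$se_oid, df$form_oid, df$group_oid, sep = "/"),
    items = paste(df$se_oid, df$form_oid, df$group_oid, df$item_oid,
                  sep = "/"))
}

# Instance identity keys (path + subject + repeat keys) per level; parent_of
# gives the containing instance's key one level up.
instance_keys <- function(df, level) {
  rk <- function(x) ifelse(is.na(x), "", x)
  ev <- paste(df$subject_key, df$se_oid, rk(df$se_rk), sep = "\r")
  if (level == "events") return(ev)
  fo <- paste(ev, df$form_oid, rk(df$form_rk), sep = "\r")
  if (level == "forms") return(fo)
  gr <- paste(fo, df$group_oid, rk(df$group_rk), sep = "\r")
  if (level == "groups") return(gr)
  paste(gr, df$item_oid, sep = "\r")
}

parent_instance_keys <- function(df, level) {
  switch(level,
    events = df$subject_key,
    forms = instance_keys(df, "events"),
    groups = instance_keys(df, "forms"),
    items = instance_keys(df, "groups"))
}
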