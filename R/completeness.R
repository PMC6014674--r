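#' @title Hierarchical data completeness
#'
#' @description
#' Two completeness measures, both computed recursively from items up to
#' the subject level on the cleaned dataset.
#'
#' An item instance is *complete* iff it carries a non-empty value. A
#' non-leaf instance (item group, form, study event) is complete iff
#' (a) for every child element that is mandatory under the chosen mode at
#' least one child instance exists inside it, and (b) every child instance
#' that *is* present — mandatory or not — is itself complete. A subject is
#' complete under the same rule applied to its study events.
#'
#' For an element C placed under parent P, the expected count is the
#' number of C instances present, plus — when C is mandatory under the
#' mode — the number of P instances containing no C instance (each of
#' those should have had one). The percentage is
#' `100 * completed / expected`, undefined (`NA`, rendered "n/a") when
#' nothing was expected.
#'
#' The `mandatory_flag` mode uses the mandatory flags on the element
#' references (positional, as everywhere else); `all_mandatory` treats
#' every element as mandatory, a stricter measure for files whose flags
#' were not maintained, to be interpreted with care for optional and
#' conditional items.
#'
#' @name completeness
#' @keywords internal
NULL

norm_mode <- function(mode) {
  mode <- match.arg(mode, c("mandatory_flag", "all_mandatory"))
  mode
}

is_mandatory <- function(element, mode) {
  if (mode == "all_mandatory") TRUE else isTRUE(element$mandatory)
}

#' Compute a completeness report
#'
#' @param tree `odm_metadata_tree`.
#' @param clean Cleaned `odm_clinical_dataset` (invalid entries already
#'   excluded; a type-invalid value therefore counts as absent).
#' @param mode `"mandatory_flag"` or `"all_mandatory"`.
#' @return An object of class `odm_completeness_report`: `mode`, `roots`
#'   (per-event node trees; each node has `path`, `level`, `oid`, `name`,
#'   `mandatory`, `expected`, `completed`, `percentage`, `children`),
#'   `completed_subjects`, `total_subjects`, and `nodes` (flat list in
#'   metadata order).
#' @export
compute_completeness <- function(tree, clean,
                                 mode = c("mandatory_flag",
                                          "all_mandatory")) {
  mode <- norm_mode(mode)
  stopifnot(inherits(tree, "odm_metadata_tree"),
            inherits(clean, "odm_clinical_dataset"))

  tabs <- list(events = clean$events, forms = clean$forms,
               groups = clean$groups, items = clean$items)
  keys <- lapply(names(tabs), function(lv) instance_keys(tabs[[lv]], lv))
  names(keys) <- names(tabs)
  pkeys <- lapply(names(tabs), function(lv)
    parent_instance_keys(tabs[[lv]], lv))
  names(pkeys) <- names(tabs)
  paths <- lapply(names(tabs), function(lv)
    instance_path_keys(tabs[[lv]], lv))
  names(paths) <- names(tabs)
  oids <- list(events = tabs$events$se_oid, forms = tabs$forms$form_oid,
               groups = tabs$groups$group_oid, items = tabs$items$item_oid)

  complete <- list(items = !is.na(tabs$items$value))

  # bottom-up instance completeness for groups, forms, events
  child_of <- c(groups = "items", forms = "groups", events = "forms")
  for (lv in c("groups", "forms", "events")) {
    ch <- child_of[[lv]]
    df <- tabs[[lv]]
    n <- nrow(df)
    comp <- rep(TRUE, n)
    if (n > 0L) {
      ch_ok_by_parent <- tapply(complete[[ch]], pkeys[[ch]], all,
                                simplify = FALSE)
      ch_oids_by_parent <- split(oids[[ch]], pkeys[[ch]])
      # mandatory child OIDs per positional path at this level
      mand_by_path <- new.env(parent = emptyenv())
      mandatory_children <- function(pk) {
        if (!exists(pk, envir = mand_by_path, inherits = FALSE)) {
          el <- get(pk, envir = tree$index)
          m <- vapply(el$children, function(c2)
            if (is_mandatory(c2, mode)) c2$oid else NA_character_, "")
          assign(pk, m[!is.na(m)], envir = mand_by_path)
        }
        get(pk, envir = mand_by_path, inherits = FALSE)
      }
      for (i in seq_len(n)) {
        k <- keys[[lv]][i]
        ok <- ch_ok_by_parent[[k]]
        if (!is.null(ok) && !is.na(ok) && !ok) { comp[i] <- FALSE; next }
        m <- mandatory_children(paths[[lv]][i])
        if (length(m) > 0L) {
          present <- ch_oids_by_parent[[k]]
          if (is.null(present) || !all(m %in% present)) comp[i] <- FALSE
        }
      }
    }
    complete[[lv]] <- comp
  }

  # subject completeness over study events
  mand_events <- vapply(tree$events, function(e)
    if (is_mandatory(e, mode)) e$oid else NA_character_, "")
  mand_events <- mand_events[!is.na(mand_events)]
  ev_ok_by_subj <- tapply(complete$events, tabs$events$subject_key, all,
                          simplify = FALSE)
  ev_oids_by_subj <- split(tabs$events$se_oid, tabs$events$subject_key)
  subj_complete <- vapply(clean$subject_keys, function(sk) {
    ok <- ev_ok_by_subj[[sk]]
    if (!is.null(ok) && !is.na(ok) && !ok) return(FALSE)
    if (length(mand_events) == 0L) return(TRUE)
    present <- ev_oids_by_subj[[sk]]
    !is.null(present) && all(mand_events %in% present)
  }, TRUE)

  # per-element expected / completed, recursively mirroring the tree
  n_parents_at <- function(level, parent_path) {
    if (level == "study_event") return(length(clean$subject_keys))
    plv <- switch(level, form = "events", item_group = "forms",
                  item = "groups")
    sum(paths[[plv]] == path_key(parent_path))
  }

  nodes_flat <- list()
  build_node <- function(el) {
    lv <- level_table(el$level)
    hit <- paths[[lv]] == path_key(el$path)
    n_inst <- sum(hit)
    expected <- n_inst
    if (is_mandatory(el, mode)) {
      parent_path <- el$path[-length(el$path)]
      n_par <- n_parents_at(el$level, parent_path)
      if (el$level == "study_event") {
        with_inst <- length(unique(tabs[[lv]]$subject_key[hit]))
      } else {
        with_inst <- length(unique(pkeys[[lv]][hit]))
      }
      expected <- n_inst + (n_par - with_inst)
    }
    completed <- sum(complete[[lv]][hit])
    node <- list(path = el$path, level = el$level, oid = el$oid,
                 name = el$def$name,
                 mandatory = is_mandatory(el, mode),
                 expected = as.integer(expected),
                 completed = as.integer(completed),
                 percentage = if (expected > 0)
                   100 * completed / expected else NA_real_,
                 children = lapply(el$children, build_node))
    nodes_flat[[length(nodes_flat) + 1L]] <<-
      node[setdiff(names(node), "children")]
    node
  }
  roots <- lapply(tree$events, build_node)

  structure(list(mode = mode, roots = roots,
                 completed_subjects = as.integer(sum(subj_complete)),
                 total_subjects = length(clean$subject_keys),
                 nodes = nodes_flat),
            class = "odm_completeness_report")
}

#' @export
print.odm_completeness_report <- function(x, ...) {
  cat(sprintf("ODM completeness (%s): %d of %d subjects complete\n",
              x$mode, x$completed_subjects, x$total_subjects))
  for (n in utils::head(x$nodes, 25)) {
    pct <- if (is.na(n$percentage)) "n/a" else sprintf("%.1f%%",
                                                       n$percentage)
    cat(sprintf("  %-40s %d/%d (%s)\n", path_key(n$path), n$completed,
                n$expected, pct))
  }
  invisible(x)
}

#' Compare mandatory-flag and all-mandatory completeness reports
#'
#' The all-mandatory measure can never report more completed instances,
#' nor fewer expected ones, than the mandatory-flag measure; elements
#' whose percentage drops are typically optional or conditional parts of
#' the CRF.
#'
#' @param report_flag Report computed with mode `"mandatory_flag"`.
#' @param report_all Report computed with mode `"all_mandatory"`.
#' @return Data frame, one row per positional element, with expected,
#'   completed and percentage under both modes, the percentage delta, and
#'   a logical `drops` marking elements whose percentage decreases.
#' @export
compare_modes <- function(report_flag, report_all) {
  stopifnot(identical(report_flag$mode, "mandatory_flag"),
            identical(report_all$mode, "all_mandatory"))
  stopifnot(length(report_flag$nodes) == length(report_all$nodes))
  rows <- Map(function(a, b) {
    stopifnot(identical(a$path, b$path))
    data.frame(path = path_key(a$path), level = a$level,
               expected_flag = a$expected, completed_flag = a$completed,
               pct_flag = a$percentage,
               expected_all = b$expected, completed_all = b$completed,
               pct_all = b$percentage,
               stringsAsFactors = FALSE)
  }, report_flag$nodes, report_all$nodes)
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  df$pct_delta <- df$pct_all - df$pct_flag
  df$drops <- !is.na(df$pct_delta) & df$pct_delta < 0
  df
}
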