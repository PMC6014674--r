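#' @title Synthetic ODM fixture generation
#'
#' @description
#' Deterministic generator of ODM 1.3.2 files with controllable structure,
#' data-type mix, repeat keys, missingness and injected errors, plus a
#' ground-truth manifest describing exactly what was emitted (per-element
#' counts, per-item valid value multisets, completeness under both modes,
#' and the injected-error ledger). No public ODM study exports exist, so
#' every other module is exercised against these fixtures; the manifest is
#' computed directly from the generator's in-memory records, independent
#' of the parsing/validation/statistics code paths it is used to check.
#'
#' What the generator emulates: the hierarchical metadata (study events,
#' forms, item groups with optional repetition, items of all supported
#' data types, code lists), per-subject clinical data with realistic
#' missingness (absent subtrees and empty values), and the four semantic
#' error classes. What it does not emulate: realistic medical content,
#' vendor extensions, transaction semantics, or EDC export quirks.
#'
#' @name fixture_gen
#' @keywords internal
NULL

#' Specification of a synthetic fixture
#'
#' Defaults describe a small but structurally complete study: two study
#' events, two forms each, two item groups per form (one repeating), four
#' items per group drawn from all supported types, 20 subjects, 10%
#' missing values, and half of all references flagged mandatory.
#'
#' @param seed RNG seed; the same spec always yields identical file bytes.
#' @param subjects Number of subjects.
#' @param events,forms_per_event,groups_per_form,items_per_group Structure.
#' @param type_weights Named weights over item kinds
#'   (`boolean`, `string`, `text`, `integer`, `float`, `double`, `date`,
#'   `time`, `datetime`, `codelist`).
#' @param codelist_size Options per generated code list.
#' @param repeat_prob Probability that a repeating item group gets more
#'   than one instance in a subject's form; extra instances are uniform on
#'   `2..max_repeats`. Repeat keys are emitted as `"1"`, `"2"`, ... but
#'   treated as opaque strings downstream.
#' @param max_repeats Maximum instances of a repeating group.
#' @param presence_prob Probability that a subject instantiates a study
#'   event / form / group at all (absent subtrees drive completeness).
#' @param missing_rate Probability that an item carries no value (half of
#'   those are emitted as an ItemData tag with an empty value, half are
#'   omitted entirely; both count as missing).
#' @param mandatory_density Probability that a reference is flagged
#'   mandatory.
#' @param invalid_plan Named integer vector of injections, e.g.
#'   `c(TYPE_MISMATCH = 3, NOT_IN_CODELIST = 2, UNDEFINED_REFERENCE = 1,
#'   UNSUPPORTED_TYPE = 2)`.
#' @param structural_faults Character vector of structural faults to
#'   inject into the XML: any of `"foreign_namespace"`, `"missing_oid"`,
#'   `"bad_version"`.
#' @return An object of class `odm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, subjects = 20L, events = 2L,
                         forms_per_event = 2L, groups_per_form = 2L,
                         items_per_group = 4L,
                         type_weights = c(boolean = 1, string = 1, text = 0.5,
                                          integer = 1, float = 1, double = 0.5,
                                          date = 1, time = 0.5, datetime = 1,
                                          codelist = 1.5),
                         codelist_size = 4L, repeat_prob = 0.2,
                         max_repeats = 3L, presence_prob = 0.9,
                         missing_rate = 0.1, mandatory_density = 0.5,
                         invalid_plan = integer(),
                         structural_faults = character()) {
  stopifnot(subjects >= 0L, events >= 0L, codelist_size >= 1L,
            repeat_prob >= 0, repeat_prob <= 1,
            missing_rate >= 0, missing_rate <= 1,
            presence_prob >= 0, presence_prob <= 1,
            mandatory_density >= 0, mandatory_density <= 1,
            max_repeats >= 1L)
  if (length(invalid_plan) > 0L)
    stopifnot(!is.null(names(invalid_plan)),
              all(names(invalid_plan) %in%
                    c("TYPE_MISMATCH", "NOT_IN_CODELIST",
                      "UNDEFINED_REFERENCE", "UNSUPPORTED_TYPE")))
  structure(as.list(environment()), class = "odm_fixture_spec")
}

# ---- XML writer -----------------------------------------------------------

# Nested fixture representation:
#   meta: list(study_oid, study_name, events=[ev]), ev = (oid, name,
#     repeating, mandatory, forms=[form]), form = (oid, name, repeating,
#     mandatory, groups=[group]), group = (oid, name, repeating, mandatory,
#     items=[item]), item = (oid, name, data_type, mandatory,
#     codelist_oid); meta$codelists = [(oid, name, data_type, options df)]
#   subjects: [(key, events=[(oid, rk, forms=[(oid, rk, groups=[(oid, rk,
#     items=[(oid, value)])])])])]; value NA -> ItemData without Value.

fixture_xml <- function(meta, subjects, odm_version = "1.3.2",
                        structural_faults = character()) {
  a <- function(name, val) sprintf(' %s="%s"', name, xml_escape(val))
  yn <- function(x) if (isTRUE(x)) "Yes" else "No"
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)

  add('<?xml version="1.0" encoding="UTF-8"?>')
  v <- if ("bad_version" %in% structural_faults) "1.2" else odm_version
  add('<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3"',
      if ("foreign_namespace" %in% structural_faults)
        ' xmlns:ext="http://example.org/ext"' else "",
      a("FileOID", paste0("FILE.", meta$study_oid)),
      a("FileType", "Snapshot"),
      a("CreationDateTime", "2020-01-01T00:00:00"),
      a("ODMVersion", v), ">")

  add(" <Study", a("OID", meta$study_oid), ">")
  add("  <GlobalVariables>")
  add("   <StudyName>", xml_escape(meta$study_name), "</StudyName>")
  add("   <StudyDescription>synthetic fixture</StudyDescription>")
  add("   <ProtocolName>", xml_escape(meta$study_oid), "</ProtocolName>")
  add("  </GlobalVariables>")
  add("  <MetaDataVersion", a("OID", "MDV.1"), a("Name", "v1"), ">")
  if ("foreign_namespace" %in% structural_faults)
    add("   <ext:Extension>not allowed</ext:Extension>")

  add("   <Protocol>")
  for (ev in meta$events)
    add("    <StudyEventRef", a("StudyEventOID", ev$oid),
        a("Mandatory", yn(ev$mandatory)), "/>")
  add("   </Protocol>")

  seen <- new.env(parent = emptyenv())
  once <- function(oid) {
    if (exists(oid, envir = seen, inherits = FALSE)) return(FALSE)
    assign(oid, TRUE, envir = seen); TRUE
  }
  for (ev in meta$events) if (once(ev$oid)) {
    add("   <StudyEventDef", a("OID", ev$oid), a("Name", ev$name),
        a("Repeating", yn(ev$repeating)), a("Type", "Scheduled"), ">")
    for (f in ev$forms)
      add("    <FormRef", a("FormOID", f$oid),
          a("Mandatory", yn(f$mandatory)), "/>")
    add("   </StudyEventDef>")
  }
  for (ev in meta$events) for (f in ev$forms) if (once(f$oid)) {
    add("   <FormDef", a("OID", f$oid), a("Name", f$name),
        a("Repeating", yn(f$repeating)), ">")
    for (g in f$groups)
      add("    <ItemGroupRef", a("ItemGroupOID", g$oid),
          a("Mandatory", yn(g$mandatory)), "/>")
    add("   </FormDef>")
  }
  for (ev in meta$events) for (f in ev$forms) for (g in f$groups)
    if (once(g$oid)) {
      add("   <ItemGroupDef", a("OID", g$oid), a("Name", g$name),
          a("Repeating", yn(g$repeating)), ">")
      for (it in g$items)
        add("    <ItemRef", a("ItemOID", it$oid),
            a("Mandatory", yn(it$mandatory)), "/>")
      add("   </ItemGroupDef>")
    }
  for (ev in meta$events) for (f in ev$forms) for (g in f$groups)
    for (it in g$items) if (once(it$oid)) {
      oid_attr <- if ("missing_oid" %in% structural_faults &&
                      !exists(".oid_dropped", envir = seen,
                              inherits = FALSE)) {
        assign(".oid_dropped", TRUE, envir = seen); ""
      } else a("OID", it$oid)
      add("   <ItemDef", oid_attr, a("Name", it$name),
          a("DataType", it$data_type), ">")
      add("    <Question><TranslatedText>", xml_escape(it$name),
          "?</TranslatedText></Question>")
      if (!is.null(it$codelist_oid))
        add("    <CodeListRef", a("CodeListOID", it$codelist_oid), "/>")
      add("   </ItemDef>")
    }
  for (cl in meta$codelists %||% list()) {
    add("   <CodeList", a("OID", cl$oid), a("Name", cl$name),
        a("DataType", cl$data_type), ">")
    for (i in seq_len(nrow(cl$options))) {
      add("    <CodeListItem", a("CodedValue", cl$options$coded_value[i]),
          ">")
      add("     <Decode><TranslatedText>",
          xml_escape(cl$options$decode[i]),
          "</TranslatedText></Decode>")
      add("    </CodeListItem>")
    }
    add("   </CodeList>")
  }
  add("  </MetaDataVersion>")
  add(" </Study>")

  add(" <ClinicalData", a("StudyOID", meta$study_oid),
      a("MetaDataVersionOID", "MDV.1"), ">")
  rk <- function(name, val) if (is.na(val)) "" else a(name, val)
  for (s in subjects) {
    add("  <SubjectData", a("SubjectKey", s$key), ">")
    for (ev in s$events) {
      add("   <StudyEventData", a("StudyEventOID", ev$oid),
          rk("StudyEventRepeatKey", ev$rk), ">")
      for (f in ev$forms) {
        add("    <FormData", a("FormOID", f$oid),
            rk("FormRepeatKey", f$rk), ">")
        for (g in f$groups) {
          add("     <ItemGroupData", a("ItemGroupOID", g$oid),
              rk("ItemGroupRepeatKey", g$rk), ">")
          for (it in g$items) {
            add("      <ItemData", a("ItemOID", it$oid),
                if (is.na(it$value)) "" else a("Value", it$value), "/>")
          }
          add("     </ItemGroupData>")
        }
        add("    </FormData>")
      }
      add("   </StudyEventData>")
    }
    add("  </SubjectData>")
  }
  add(" </ClinicalData>")
  add("</ODM>")
  paste(L, collapse = "\n")
}

# ---- value sampling -------------------------------------------------------

NOMINAL_VOCAB <- c("red", "green", "blue", "yellow", "black", "white",
                   "orange", "purple")
TEXT_VOCAB <- c("no complaints", "mild headache", "nausea after intake",
                "see previous visit", "patient reports improvement")

sample_value <- function(data_type, codelist = NULL) {
  if (!is.null(codelist))
    return(sample(codelist$options$coded_value, 1L))
  switch(data_type,
    boolean = sample(c("true", "false", "1", "0"), 1L),
    string = sample(NOMINAL_VOCAB, 1L),
    text = sample(TEXT_VOCAB, 1L),
    integer = as.character(sample.int(100L, 1L) - 1L),
    float = ,
    double = sprintf("%.2f", stats::runif(1L, 0, 100)),
    date = format(as.Date("2000-01-01") + sample.int(7000L, 1L),
                  "%Y-%m-%d"),
    time = {
      s <- sample.int(86400L, 1L) - 1L
      sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
    },
    datetime = {
      d <- format(as.Date("2000-01-01") + sample.int(7000L, 1L),
                  "%Y-%m-%d")
      s <- sample.int(86400L, 1L) - 1L
      sprintf("%sT%02d:%02d:%02d", d, s %/% 3600, (s %% 3600) %/% 60,
              s %% 60)
    },
    stop("cannot sample type ", data_type))
}

# ---- generation -----------------------------------------------------------

#' Generate a synthetic ODM fixture with ground-truth manifest
#'
#' @param spec An [fixture_spec()].
#' @return List with `xml` (the file as a single string), `manifest` (see
#'   Details) and `spec`. The manifest contains `counts` (per positional
#'   path: reference/subject counts and repeat flag on the post-exclusion
#'   data), `item_values` (valid value multisets per item path),
#'   `item_meta` (category, data type, code list), `completeness`
#'   (expected/completed per path for both modes, via an independent
#'   recursive oracle over the generator's records), `injected` (the
#'   error ledger) and subject bookkeeping.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "odm_fixture_spec"))
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  kinds <- names(spec$type_weights)
  codelists <- list()
  item_counter <- 0L

  make_item <- function(gi) {
    item_counter <<- item_counter + 1L
    kind <- sample(kinds, 1L, prob = spec$type_weights)
    oid <- sprintf("I%03d", item_counter)
    cl_oid <- NULL
    data_type <- kind
    if (kind == "codelist") {
      cl_oid <- sprintf("CL%03d", item_counter)
      base <- sample(c("string", "integer"), 1L)
      codes <- if (base == "integer") as.character(seq_len(spec$codelist_size))
               else paste0("OPT", LETTERS[seq_len(spec$codelist_size)])
      codelists[[length(codelists) + 1L]] <<- list(
        oid = cl_oid, name = cl_oid, data_type = base,
        options = data.frame(coded_value = codes,
                             decode = paste0("label ", codes),
                             stringsAsFactors = FALSE))
      data_type <- base
    }
    list(oid = oid, name = paste0("Item ", item_counter),
         data_type = data_type,
         mandatory = stats::runif(1) < spec$mandatory_density,
         codelist_oid = cl_oid)
  }

  gi <- 0L
  events <- lapply(seq_len(spec$events), function(e) {
    forms <- lapply(seq_len(spec$forms_per_event), function(f) {
      groups <- lapply(seq_len(spec$groups_per_form), function(g) {
        gi <<- gi + 1L
        items <- lapply(seq_len(spec$items_per_group),
                        function(i) make_item(gi))
        list(oid = sprintf("IG%03d", gi), name = sprintf("Group %d", gi),
             repeating = g == 1L && spec$repeat_prob > 0,
             mandatory = stats::runif(1) < spec$mandatory_density,
             items = items)
      })
      list(oid = sprintf("F%d.%d", e, f), name = sprintf("Form %d.%d", e, f),
           repeating = FALSE,
           mandatory = stats::runif(1) < spec$mandatory_density,
           groups = groups)
    })
    list(oid = sprintf("SE%d", e), name = sprintf("Event %d", e),
         repeating = FALSE,
         mandatory = stats::runif(1) < spec$mandatory_density,
         forms = forms)
  })
  meta <- list(study_oid = "ST.SYN", study_name = "Synthetic study",
               events = events, codelists = codelists)
  cl_by_oid <- stats::setNames(codelists,
                               vapply(codelists, `[[`, "", "oid"))

  subjects <- lapply(seq_len(spec$subjects), function(si) {
    key <- sprintf("S%04d", si)
    evs <- list()
    for (ev in meta$events) {
      if (stats::runif(1) > spec$presence_prob) next
      fms <- list()
      for (f in ev$forms) {
        if (stats::runif(1) > spec$presence_prob) next
        grs <- list()
        for (g in f$groups) {
          if (stats::runif(1) > spec$presence_prob) next
          n_inst <- 1L
          if (g$repeating && spec$max_repeats >= 2L &&
              stats::runif(1) < spec$repeat_prob)
            n_inst <- 1L + sample.int(spec$max_repeats - 1L, 1L)
          for (k in seq_len(n_inst)) {
            its <- list()
            for (it in g$items) {
              if (stats::runif(1) < spec$missing_rate) {
                # half emitted as empty-value tags, half omitted entirely
                if (stats::runif(1) < 0.5)
                  its[[length(its) + 1L]] <- list(oid = it$oid,
                                                  value = NA_character_)
                next
              }
              its[[length(its) + 1L]] <- list(
                oid = it$oid,
                value = sample_value(it$data_type,
                                     cl_by_oid[[it$codelist_oid %||% ""]]))
            }
            grs[[length(grs) + 1L]] <- list(
              oid = g$oid,
              rk = if (g$repeating) as.character(k) else NA_character_,
              items = its)
          }
        }
        fms[[length(fms) + 1L]] <- list(oid = f$oid, rk = NA_character_,
                                        groups = grs)
      }
      evs[[length(evs) + 1L]] <- list(oid = ev$oid, rk = NA_character_,
                                      forms = fms)
    }
    list(key = key, events = evs)
  })

  inj <- inject_invalid(meta, subjects, spec)
  meta <- inj$meta; subjects <- inj$subjects

  manifest <- build_manifest(meta, subjects, inj$ledger,
                             n_subjects = spec$subjects)
  xml <- fixture_xml(meta, subjects,
                     structural_faults = spec$structural_faults)
  list(xml = xml, manifest = manifest, spec = spec)
}

# Inject semantic errors according to the plan; returns modified records
# plus the ledger of exact locations.
inject_invalid <- function(meta, subjects, spec) {
  ledger <- list()
  plan <- spec$invalid_plan
  note <- function(reason, sk, ev, f, g, item_oid, raw) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      reason = reason, subject_key = sk, se_oid = ev$oid, se_rk = ev$rk,
      form_oid = f$oid, form_rk = f$rk, group_oid = g$oid, group_rk = g$rk,
      item_oid = item_oid, raw_value = raw, stringsAsFactors = FALSE)
  }

  # enumerate filled item slots as (subject, ev idx, form idx, group idx,
  # item idx) eligible per reason
  item_defs <- new.env(parent = emptyenv())
  for (ev in meta$events) for (f in ev$forms) for (g in f$groups)
    for (it in g$items) assign(it$oid, it, envir = item_defs)

  slots <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    for (ei in seq_along(s$events)) for (fi in seq_along(s$events[[ei]]$forms))
      for (gi2 in seq_along(s$events[[ei]]$forms[[fi]]$groups)) {
        grp <- s$events[[ei]]$forms[[fi]]$groups[[gi2]]
        for (ii in seq_along(grp$items)) {
          it <- grp$items[[ii]]
          if (is.na(it$value)) next
          def <- get(it$oid, envir = item_defs)
          slots[[length(slots) + 1L]] <- list(
            si = si, ei = ei, fi = fi, gi = gi2, ii = ii,
            has_cl = !is.null(def$codelist_oid),
            dt = def$data_type)
        }
      }
  }

  pick <- function(eligible, n) {
    idx <- which(eligible)
    if (length(idx) == 0L || n == 0L) return(integer())
    idx[sample.int(length(idx), min(n, length(idx)))]
  }
  used <- rep(FALSE, length(slots))

  apply_mutation <- function(slot, value, reason) {
    s <- subjects[[slot$si]]
    ev <- s$events[[slot$ei]]; f <- ev$forms[[slot$fi]]
    g <- f$groups[[slot$gi]]
    old <- g$items[[slot$ii]]
    subjects[[slot$si]]$events[[slot$ei]]$forms[[slot$fi]]$
      groups[[slot$gi]]$items[[slot$ii]]$value <<- value
    note(reason, s$key, ev, f, g, old$oid, value)
  }

  if (!is.na(plan["TYPE_MISMATCH"] %||% NA)) {
    elig <- vapply(slots, function(sl)
      !sl$has_cl && !sl$dt %in% c("string", "text"), TRUE) & !used
    for (i in pick(elig, plan[["TYPE_MISMATCH"]])) {
      used[i] <- TRUE
      apply_mutation(slots[[i]], "not-a-value!", "TYPE_MISMATCH")
    }
  }
  if (!is.na(plan["NOT_IN_CODELIST"] %||% NA)) {
    elig <- vapply(slots, function(sl) sl$has_cl, TRUE) & !used
    for (i in pick(elig, plan[["NOT_IN_CODELIST"]])) {
      used[i] <- TRUE
      sl <- slots[[i]]
      bad <- if (sl$dt == "integer") "9999" else "OPTZZZ"
      apply_mutation(sl, bad, "NOT_IN_CODELIST")
    }
  }
  if (!is.na(plan["UNDEFINED_REFERENCE"] %||% NA)) {
    n <- plan[["UNDEFINED_REFERENCE"]]
    # append ItemData with unknown OIDs into random existing group
    # instances
    spots <- list()
    for (si in seq_along(subjects)) {
      s <- subjects[[si]]
      for (ei in seq_along(s$events))
        for (fi in seq_along(s$events[[ei]]$forms))
          for (gi2 in seq_along(s$events[[ei]]$forms[[fi]]$groups))
            spots[[length(spots) + 1L]] <- c(si, ei, fi, gi2)
    }
    if (length(spots) > 0L) {
      for (j in seq_len(n)) {
        sp <- spots[[sample.int(length(spots), 1L)]]
        oid <- sprintf("UNDEF%03d", j)
        s <- subjects[[sp[1]]]
        ev <- s$events[[sp[2]]]; f <- ev$forms[[sp[3]]]
        g <- f$groups[[sp[4]]]
        subjects[[sp[1]]]$events[[sp[2]]]$forms[[sp[3]]]$
          groups[[sp[4]]]$items[[length(g$items) + 1L]] <-
          list(oid = oid, value = "1")
        note("UNDEFINED_REFERENCE", s$key, ev, f, g, oid, "1")
      }
    }
  }
  if (!is.na(plan["UNSUPPORTED_TYPE"] %||% NA)) {
    n <- plan[["UNSUPPORTED_TYPE"]]
    # declare a partial-date item in the first group and fill it for the
    # first n subjects that instantiate that group
    pit <- list(oid = "I.PARTIAL", name = "Partial date item",
                data_type = "partialDate", mandatory = FALSE,
                codelist_oid = NULL)
    meta$events[[1]]$forms[[1]]$groups[[1]]$items <-
      c(meta$events[[1]]$forms[[1]]$groups[[1]]$items, list(pit))
    g_oid <- meta$events[[1]]$forms[[1]]$groups[[1]]$oid
    placed <- 0L
    for (si in seq_along(subjects)) {
      if (placed >= n) break
      s <- subjects[[si]]
      for (ei in seq_along(s$events)) {
        if (placed >= n) break
        if (s$events[[ei]]$oid != meta$events[[1]]$oid) next
        for (fi in seq_along(s$events[[ei]]$forms)) {
          if (placed >= n) break
          f <- s$events[[ei]]$forms[[fi]]
          if (f$oid != meta$events[[1]]$forms[[1]]$oid) next
          for (gi2 in seq_along(f$groups)) {
            if (placed >= n) break
            g <- f$groups[[gi2]]
            if (g$oid != g_oid) next
            subjects[[si]]$events[[ei]]$forms[[fi]]$groups[[gi2]]$
              items[[length(g$items) + 1L]] <-
              list(oid = "I.PARTIAL", value = "2020-01")
            note("UNSUPPORTED_TYPE", s$key, s$events[[ei]], f, g,
                 "I.PARTIAL", "2020-01")
            placed <- placed + 1L
          }
        }
      }
    }
  }

  ledger_df <- if (length(ledger) > 0L) do.call(rbind, ledger) else
    data.frame(reason = character(), subject_key = character(),
               se_oid = character(), se_rk = character(),
               form_oid = character(), form_rk = character(),
               group_oid = character(), group_rk = character(),
               item_oid = character(), raw_value = character(),
               stringsAsFactors = FALSE)
  list(meta = meta, subjects = subjects, ledger = ledger_df)
}

# ---- manifest (independent ground truth) ----------------------------------

build_manifest <- function(meta, subjects, ledger, n_subjects) {
  item_defs <- new.env(parent = emptyenv())
  for (ev in meta$events) for (f in ev$forms) for (g in f$groups)
    for (it in g$items) assign(it$oid, it, envir = item_defs)
  cl_by_oid <- stats::setNames(meta$codelists,
                               vapply(meta$codelists, `[[`, "", "oid"))
  bad_key <- function(sk, ev_oid, ev_rk, f_oid, f_rk, g_oid, g_rk, i_oid)
    paste(sk, ev_oid, ev_rk %||% "", f_oid, f_rk %||% "", g_oid,
          g_rk %||% "", i_oid, sep = "\r")
  non <- function(x) ifelse(is.na(x), "", x)
  injected_keys <- if (nrow(ledger) > 0L)
    paste(ledger$subject_key, ledger$se_oid, non(ledger$se_rk),
          ledger$form_oid, non(ledger$form_rk), ledger$group_oid,
          non(ledger$group_rk), ledger$item_oid, sep = "\r")
  else character()

  # strip invalid-injected items from the records: downstream they are
  # excluded, and the manifest describes the post-exclusion truth
  clean_subjects <- lapply(subjects, function(s) {
    s$events <- lapply(s$events, function(ev) {
      ev$forms <- lapply(ev$forms, function(f) {
        f$groups <- lapply(f$groups, function(g) {
          g$items <- Filter(function(it)
            !(paste(s$key, ev$oid, non(ev$rk), f$oid, non(f$rk), g$oid,
                    non(g$rk), it$oid, sep = "\r") %in% injected_keys),
            g$items)
          g
        })
        f
      })
      ev
    })
    s
  })

  # flat instance lists per positional path
  refs <- list()   # path -> list(subject, n...) tally
  values <- list()
  tally <- function(path, sk) {
    e <- refs[[path]] %||% list(n = 0L, subjects = character())
    e$n <- e$n + 1L
    e$subjects <- c(e$subjects, sk)
    refs[[path]] <<- e
  }
  for (s in clean_subjects) for (ev in s$events) {
    p1 <- ev$oid; tally(p1, s$key)
    for (f in ev$forms) {
      p2 <- paste(p1, f$oid, sep = "/"); tally(p2, s$key)
      for (g in f$groups) {
        p3 <- paste(p2, g$oid, sep = "/"); tally(p3, s$key)
        for (it in g$items) {
          p4 <- paste(p3, it$oid, sep = "/"); tally(p4, s$key)
          if (!is.na(it$value))
            values[[p4]] <- c(values[[p4]], it$value)
        }
      }
    }
  }
  counts <- do.call(rbind, lapply(names(refs), function(p) {
    e <- refs[[p]]
    data.frame(path = p, n_segments = length(strsplit(p, "/")[[1]]),
               reference_count = e$n,
               subject_count = length(unique(e$subjects)),
               repeat_warning = anyDuplicated(e$subjects) > 0L,
               stringsAsFactors = FALSE)
  })) %||% data.frame()

  item_meta <- list()
  for (ev in meta$events) for (f in ev$forms) for (g in f$groups)
    for (it in g$items) {
      p <- paste(ev$oid, f$oid, g$oid, it$oid, sep = "/")
      cl <- cl_by_oid[[it$codelist_oid %||% ""]]
      item_meta[[p]] <- list(
        data_type = it$data_type,
        category = if (!is.null(cl)) "ordinal" else switch(it$data_type,
          boolean = "dichotomous", string = , text = "nominal",
          time = , date = , datetime = "interval",
          integer = , float = , double = "ratio", "unsupported"),
        codelist = cl)
    }

  comp <- list(
    mandatory_flag = oracle_completeness(meta, clean_subjects,
                                         n_subjects, "mandatory_flag"),
    all_mandatory = oracle_completeness(meta, clean_subjects,
                                        n_subjects, "all_mandatory"))

  list(study_oid = meta$study_oid, n_subjects = n_subjects,
       subject_keys = vapply(subjects, `[[`, "", "key"),
       counts = counts, item_values = values, item_meta = item_meta,
       completeness = comp, injected = ledger)
}

# Independent recursive completeness oracle over the generator's nested
# records (never touches the parser/validator data structures).
oracle_completeness <- function(meta, subjects, n_subjects, mode) {
  mand <- function(x) if (mode == "all_mandatory") TRUE else isTRUE(x)
  rows <- list()
  emit <- function(path, level, expected, completed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, level = level, expected = expected,
      completed = completed,
      percentage = if (expected > 0) 100 * completed / expected else
        NA_real_,
      stringsAsFactors = FALSE)
  }

  inst_complete <- function(level, mel, inst) {
    if (level == "item") return(!is.na(inst$value))
    ch_level <- switch(level, study_event = "form", form = "item_group",
                       item_group = "item")
    ch_field <- switch(ch_level, form = "forms", item_group = "groups",
                       item = "items")
    mels <- switch(ch_level, form = mel$forms, item_group = mel$groups,
                   item = mel$items)
    insts <- inst[[ch_field]]
    got <- vapply(insts, `[[`, "", "oid")
    for (cm in mels) {
      mine <- insts[got == cm$oid]
      if (mand(cm$mandatory) && length(mine) == 0L) return(FALSE)
      for (ci in mine)
        if (!inst_complete(ch_level, cm, ci)) return(FALSE)
    }
    # child instances never defined in metadata were stripped upstream
    TRUE
  }

  walk <- function(mel, level, path, insts, n_parents) {
    n <- length(insts)
    expected <- n
    if (mand(mel$mandatory)) {
      owners <- unique(vapply(insts, function(x) x$.owner, ""))
      expected <- n + (n_parents - length(owners))
    }
    completed <- sum(vapply(insts, function(i)
      inst_complete(level, mel, i), TRUE))
    emit(path, level, expected, completed)
    ch_level <- switch(level, study_event = "form", form = "item_group",
                       item_group = "item", item = NA_character_)
    if (is.na(ch_level)) return()
    ch_field <- switch(ch_level, form = "forms", item_group = "groups",
                       item = "items")
    mels <- switch(ch_level, form = mel$forms, item_group = mel$groups,
                   item = mel$items)
    for (cm in mels) {
      kids <- list()
      for (i in insts) {
        for (ci in i[[ch_field]]) if (ci$oid == cm$oid) {
          ci$.owner <- paste(i$.owner, i$oid, i$rk %||% "", sep = "\r")
          if (ch_level == "item" && is.null(ci$rk)) ci$rk <- NA_character_
          kids[[length(kids) + 1L]] <- ci
        }
      }
      walk(cm, ch_level, paste(path, cm$oid, sep = "/"), kids, n)
    }
  }

  subj_complete <- vapply(subjects, function(s) {
    got <- vapply(s$events, `[[`, "", "oid")
    for (em in meta$events) {
      mine <- s$events[got == em$oid]
      if (mand(em$mandatory) && length(mine) == 0L) return(FALSE)
      for (ei in mine) if (!inst_complete("study_event", em, ei))
        return(FALSE)
    }
    TRUE
  }, TRUE)
  # subjects with no data at all still count toward the totals
  n_total <- n_subjects
  n_complete <- sum(subj_complete) +
    (n_total - length(subjects)) * as.integer(
      !any(vapply(meta$events, function(e) mand(e$mandatory), TRUE)))

  for (em in meta$events) {
    insts <- list()
    for (s in subjects) for (ei in s$events) if (ei$oid == em$oid) {
      ei$.owner <- s$key
      insts[[length(insts) + 1L]] <- ei
    }
    walk(em, "study_event", em$oid, insts, n_total)
  }

  list(nodes = do.call(rbind, rows) %||% data.frame(),
       completed_subjects = as.integer(n_complete),
       total_subjects = n_total)
}
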