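#' Fixed worked-example fixtures
#'
#' A set of small, deterministic ODM files encoding the canonical worked
#' examples used throughout the documentation and acceptance tests:
#'
#' * `completeness_40`: one subject whose item group is instantiated five
#'   times while its mandatory date item carries a value in only two
#'   instances — the item node is 40% complete and 2 of 5 group instances
#'   are complete under mandatory-flag mode.
#' * `ordinal_15`: a 15-option code list with every option observed — the
#'   bar chart must show the top nine options plus one "others" bar.
#' * `ordinal_yesnomaybe`: a 3-option Yes/No/Maybe list with counts 8/4/3.
#' * `boolean_5545`: a boolean item with 55 true and 45 false values.
#' * `nominal_topk`: a free-text item with 22 distinct strings, the top
#'   three being red (9), green (7), blue (5).
#' * `interval_range`: a datetime item whose extremes are
#'   1920-05-05T13:54:47 and 2010-06-09T20:11:59.
#' * `ratio_basic`: a float item with a handful of values.
#' * `no_mandatory_sparse`: sparse data, no mandatory flags anywhere —
#'   every subject counts as complete.
#' * `all_mandatory_sparse`: the same sparse data assessed with every
#'   element treated as mandatory — no subject is complete.
#'
#' @return Named list; each entry has `name`, `xml` (the ODM file as a
#'   string) and `expected` (the printed values the scenario encodes).
#' @export
paper_scenarios <- function() {
  out <- list()

  single_item_study <- function(item_oid, data_type, values,
                                codelist = NULL, mandatory_item = FALSE) {
    # one event / form / group; one subject per value
    items <- list(list(oid = item_oid, name = item_oid,
                       data_type = if (is.null(codelist)) data_type else
                         codelist$data_type,
                       mandatory = mandatory_item,
                       codelist_oid = codelist$oid %||% NULL))
    meta <- list(
      study_oid = "ST.SCEN", study_name = "Worked example",
      events = list(list(
        oid = "SE1", name = "Event", repeating = FALSE, mandatory = FALSE,
        forms = list(list(
          oid = "F1", name = "Form", repeating = FALSE, mandatory = FALSE,
          groups = list(list(
            oid = "IG1", name = "Group", repeating = FALSE,
            mandatory = FALSE, items = items)))))),
      codelists = if (is.null(codelist)) list() else list(codelist))
    subjects <- lapply(seq_along(values), function(i) list(
      key = sprintf("S%04d", i),
      events = list(list(oid = "SE1", rk = NA_character_,
        forms = list(list(oid = "F1", rk = NA_character_,
          groups = list(list(oid = "IG1", rk = NA_character_,
            items = list(list(oid = item_oid, value = values[i]))))))))))
    fixture_xml(meta, subjects)
  }

  # -- completeness worked example: group 5x, mandatory date item in 2 ----
  comp_meta <- list(
    study_oid = "ST.COMP", study_name = "Completeness example",
    events = list(list(
      oid = "SE1", name = "Visit", repeating = FALSE, mandatory = TRUE,
      forms = list(list(
        oid = "F1", name = "Adverse events form", repeating = FALSE,
        mandatory = TRUE,
        groups = list(list(
          oid = "IG.AE", name = "Adverse events", repeating = TRUE,
          mandatory = FALSE,
          items = list(list(oid = "I.DATE", name = "Date of event",
                            data_type = "date", mandatory = TRUE,
                            codelist_oid = NULL)))))))),
    codelists = list())
  ae_dates <- c("2019-03-01", "2019-04-12", NA, NA, NA)
  comp_subjects <- list(list(
    key = "S0001",
    events = list(list(oid = "SE1", rk = NA_character_,
      forms = list(list(oid = "F1", rk = NA_character_,
        groups = lapply(1:5, function(k) list(
          oid = "IG.AE", rk = as.character(k),
          items = if (is.na(ae_dates[k])) list() else
            list(list(oid = "I.DATE", value = ae_dates[k]))))))))))
  out$completeness_40 <- list(
    name = "completeness_40",
    xml = fixture_xml(comp_meta, comp_subjects),
    expected = list(item_path = "SE1/F1/IG.AE/I.DATE",
                    group_path = "SE1/F1/IG.AE",
                    item_percentage = 40, item_expected = 5L,
                    item_completed = 2L, group_expected = 5L,
                    group_completed = 2L))

  # -- ordinal with 15 observed options ----------------------------------
  codes15 <- sprintf("O%02d", 1:15)
  cl15 <- list(oid = "CL15", name = "CL15", data_type = "string",
               options = data.frame(coded_value = codes15,
                                    decode = paste("Option", 1:15),
                                    stringsAsFactors = FALSE))
  counts15 <- c(9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
  vals15 <- rep(codes15, counts15)
  # one subject contributing through a repeating group keeps the file small
  meta15 <- list(
    study_oid = "ST.SCEN", study_name = "Worked example",
    events = list(list(
      oid = "SE1", name = "Event", repeating = FALSE, mandatory = FALSE,
      forms = list(list(
        oid = "F1", name = "Form", repeating = FALSE, mandatory = FALSE,
        groups = list(list(
          oid = "IG1", name = "Group", repeating = TRUE, mandatory = FALSE,
          items = list(list(oid = "I.ORD15", name = "I.ORD15",
                            data_type = cl15$data_type, mandatory = FALSE,
                            codelist_oid = cl15$oid)))))))),
    codelists = list(cl15))
  subj15 <- list(list(
    key = "S0001",
    events = list(list(oid = "SE1", rk = NA_character_,
      forms = list(list(oid = "F1", rk = NA_character_,
        groups = lapply(seq_along(vals15), function(k) list(
          oid = "IG1", rk = as.character(k),
          items = list(list(oid = "I.ORD15", value = vals15[k]))))))))))
  out$ordinal_15 <- list(
    name = "ordinal_15",
    xml = fixture_xml(meta15, subj15),
    expected = list(item_path = "SE1/F1/IG1/I.ORD15", n = length(vals15),
                    n_bars = 10L, labelled = 9L,
                    others_count = sum(counts15) -
                      sum(sort(counts15, decreasing = TRUE)[1:9])))

  # -- ordinal Yes/No/Maybe 8/4/3 ----------------------------------------
  clynm <- list(oid = "CL.YNM", name = "CL.YNM", data_type = "string",
                options = data.frame(
                  coded_value = c("Yes", "No", "Maybe"),
                  decode = c("Yes", "No", "Maybe"),
                  stringsAsFactors = FALSE))
  out$ordinal_yesnomaybe <- list(
    name = "ordinal_yesnomaybe",
    xml = single_item_study("I.YNM", "string",
                            rep(c("Yes", "No", "Maybe"), c(8, 4, 3)),
                            codelist = clynm),
    expected = list(
      item_path = "SE1/F1/IG1/I.YNM",
      rendered = "Diversity: 3/3 - Top3: 1. Yes (8) | 2. No (4) | 3. Maybe (3)"))

  # -- boolean 55 true / 45 false ----------------------------------------
  out$boolean_5545 <- list(
    name = "boolean_5545",
    xml = single_item_study("I.BOOL", "boolean",
                            rep(c("true", "false"), c(55, 45))),
    expected = list(item_path = "SE1/F1/IG1/I.BOOL",
                    rendered = "True: 55 - False: 45"))

  # -- nominal: diversity 22, top3 red(9) green(7) blue(5) ---------------
  fillers <- sprintf("entry %02d", 1:19)
  vals_nom <- c(rep("red", 9), rep("green", 7), rep("blue", 5), fillers)
  out$nominal_topk <- list(
    name = "nominal_topk",
    xml = single_item_study("I.NOM", "string", vals_nom),
    expected = list(
      item_path = "SE1/F1/IG1/I.NOM",
      rendered = "Diversity: 22 - Top3: 1. red (9) | 2. green (7) | 3. blue (5)"))

  # -- interval: datetime range ------------------------------------------
  out$interval_range <- list(
    name = "interval_range",
    xml = single_item_study("I.DTM", "datetime",
                            c("1920-05-05T13:54:47", "1988-01-15T08:30:00",
                              "2010-06-09T20:11:59")),
    expected = list(
      item_path = "SE1/F1/IG1/I.DTM",
      rendered = "Range: 13:54:47 on 05 May 1920 - 20:11:59 on 09 June 2010"))

  # -- ratio: shape of the five-number summary ---------------------------
  ratio_vals <- c("1.1", "3.2", "4.4", "5.6", "8.8")
  out$ratio_basic <- list(
    name = "ratio_basic",
    xml = single_item_study("I.NUM", "float", ratio_vals),
    expected = list(item_path = "SE1/F1/IG1/I.NUM",
                    values = as.numeric(ratio_vals)))

  # -- sparse data, two completeness philosophies ------------------------
  sparse_meta <- list(
    study_oid = "ST.SPARSE", study_name = "Sparse study",
    events = list(list(
      oid = "SE1", name = "Visit", repeating = FALSE, mandatory = FALSE,
      forms = list(list(
        oid = "F1", name = "Form", repeating = FALSE, mandatory = FALSE,
        groups = list(list(
          oid = "IG1", name = "Group", repeating = FALSE,
          mandatory = FALSE,
          items = list(
            list(oid = "I.A", name = "A", data_type = "integer",
                 mandatory = FALSE, codelist_oid = NULL),
            list(oid = "I.DOD", name = "Date of death",
                 data_type = "date", mandatory = FALSE,
                 codelist_oid = NULL)))))))),
    codelists = list())
  # each subject misses at least one item (absent tags, not empty values)
  sparse_subjects <- lapply(1:4, function(i) list(
    key = sprintf("S%04d", i),
    events = list(list(oid = "SE1", rk = NA_character_,
      forms = list(list(oid = "F1", rk = NA_character_,
        groups = list(list(oid = "IG1", rk = NA_character_,
          items = if (i == 1L) list() else
            list(list(oid = "I.A", value = as.character(i)))))))))))
  sparse_xml <- fixture_xml(sparse_meta, sparse_subjects)
  out$no_mandatory_sparse <- list(
    name = "no_mandatory_sparse", xml = sparse_xml,
    expected = list(mode = "mandatory_flag", completed_subjects = 4L,
                    total_subjects = 4L))
  out$all_mandatory_sparse <- list(
    name = "all_mandatory_sparse", xml = sparse_xml,
    expected = list(mode = "all_mandatory", completed_subjects = 0L,
                    total_subjects = 4L))

  out
}
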