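#' @title Semantic validation of clinical values
#'
#' @description
#' Second-stage validation, run after the document has passed structural
#' checks: every clinical instance path is resolved against the positional
#' metadata tree, every item value is converted to the data type its
#' definition declares, and code-list membership is enforced. Findings
#' never abort the analysis; each invalid entry is excluded from further
#' processing and reported as one record carrying the full clinical
#' location (path plus repeat keys) and a typed reason.
#'
#' Reason codes: `UNDEFINED_REFERENCE` (path not defined in the metadata;
#' the whole subtree under the offending instance is excluded, one record
#' per cause), `TYPE_MISMATCH` (value string does not convert to the
#' declared type), `NOT_IN_CODELIST` (converted value is not one of the
#' list's coded values), `UNSUPPORTED_TYPE` (item declared with an ODM type
#' outside the supported set, e.g. partial dates).
#'
#' @name content_validation
#' @keywords internal
NULL

invalid_reason <- function(code, detail = "") {
  structure(list(code = code, detail = detail), class = "odm_invalid_reason")
}

typed_value <- function(kind, payload, num = NA_real_) {
  structure(list(kind = kind, payload = payload, num = num),
            class = "odm_typed_value")
}

# Lexical forms accepted per type. Whitespace is never trimmed: values are
# compared and converted exactly as exported.
RX_INTEGER <- "^[+-]?[0-9]+$"
RX_DECIMAL <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
RX_DATE <- "^([0-9]{4})-([0-9]{2})-([0-9]{2})$"
RX_TIME <- "^([0-9]{2}):([0-9]{2}):([0-9]{2})(\\.[0-9]+)?$"
RX_ZONE <- "(Z|[+-][0-9]{2}:[0-9]{2})?$"

parse_date_num <- function(raw) {
  m <- regmatches(raw, regexec(RX_DATE, raw))[[1]]
  if (length(m) == 0L) return(NA_real_)
  d <- as.Date(raw, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != raw) return(NA_real_)
  as.numeric(d)  # days since 1970-01-01
}

parse_time_num <- function(raw) {
  m <- regmatches(raw, regexec(RX_TIME, raw))[[1]]
  if (length(m) == 0L) return(NA_real_)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3]); s <- as.numeric(m[4])
  frac <- if (nzchar(m[5])) as.numeric(m[5]) else 0
  if (h > 23 || mi > 59 || s > 59) return(NA_real_)
  h * 3600 + mi * 60 + s + frac  # seconds since midnight
}

parse_datetime_num <- function(raw) {
  # date "T" time with optional zone; comparisons use the normalized
  # instant (seconds since epoch, UTC)
  rx <- paste0("^([0-9]{4}-[0-9]{2}-[0-9]{2})T",
               "([0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?)", RX_ZONE)
  m <- regmatches(raw, regexec(rx, raw))[[1]]
  if (length(m) == 0L) return(NA_real_)
  d <- parse_date_num(m[2]); t <- parse_time_num(m[3])
  if (is.na(d) || is.na(t)) return(NA_real_)
  off <- 0
  zone <- m[5]
  if (nzchar(zone) && zone != "Z") {
    sgn <- if (substr(zone, 1, 1) == "-") -1 else 1
    off <- sgn * (as.numeric(substr(zone, 2, 3)) * 3600 +
                  as.numeric(substr(zone, 5, 6)) * 60)
  }
  d * 86400 + t - off
}

convert_raw <- function(data_type, raw) {
  switch(data_type,
    boolean = {
      if (raw %in% c("true", "1")) return(typed_value("boolean", TRUE, 1))
      if (raw %in% c("false", "0")) return(typed_value("boolean", FALSE, 0))
      NULL
    },
    integer = {
      if (grepl(RX_INTEGER, raw))
        return(typed_value("number", as.numeric(raw), as.numeric(raw)))
      NULL
    },
    float = ,
    double = {
      if (grepl(RX_DECIMAL, raw))
        return(typed_value("number", as.numeric(raw), as.numeric(raw)))
      NULL
    },
    date = {
      n <- parse_date_num(raw)
      if (!is.na(n)) return(typed_value("timepoint", raw, n))
      NULL
    },
    time = {
      n <- parse_time_num(raw)
      if (!is.na(n)) return(typed_value("timepoint", raw, n))
      NULL
    },
    datetime = {
      n <- parse_datetime_num(raw)
      if (!is.na(n)) return(typed_value("timepoint", raw, n))
      NULL
    },
    string = ,
    text = typed_value("text", raw),
    NULL)
}

#' Validate a single clinical value against its item definition
#'
#' Conversion runs first, then code-list membership; the first failure is
#' reported. Boolean accepts exactly `true`, `false`, `1`, `0`
#' (case-sensitive); integers are optional-sign digit strings; float and
#' double accept decimal notation; date, time and datetime accept ISO 8601
#' lexical forms (timezone designators on datetimes are accepted and the
#' comparison instant is normalized to UTC); string and text accept
#' anything. Values are never trimmed or normalized before checking.
#'
#' @param item An [odm_item_def()].
#' @param raw The value string as present in the file.
#' @param codelist The [odm_codelist_def()] attached to the item, when
#'   `item$codelist_oid` is set.
#' @return An `odm_typed_value` (`kind`, `payload`, and `num`, a numeric
#'   encoding for number/timepoint kinds) on success, otherwise an
#'   `odm_invalid_reason` (`code`, `detail`). Never throws.
#' @export
validate_value <- function(item, raw, codelist = NULL) {
  stopifnot(inherits(item, "odm_item_def"), is.character(raw),
            length(raw) == 1L, !is.na(raw))
  if (item$data_type %in% KNOWN_UNSUPPORTED_TYPES)
    return(invalid_reason("UNSUPPORTED_TYPE",
                          sprintf("ODM data type '%s' is not analyzable",
                                  item$data_type)))
  tv <- convert_raw(item$data_type, raw)
  if (is.null(tv))
    return(invalid_reason("TYPE_MISMATCH",
                          sprintf("value does not conform to type '%s'",
                                  item$data_type)))
  if (!is.null(item$codelist_oid)) {
    if (is.null(codelist))
      stop("item ", item$oid, " references code list ", item$codelist_oid,
           " but none was supplied")
    if (!raw %in% codelist$options$coded_value)
      return(invalid_reason("NOT_IN_CODELIST",
                            sprintf("value not among the %d options of code list '%s'",
                                    nrow(codelist$options), codelist$oid)))
    return(typed_value("code", raw, tv$num))
  }
  tv
}

invalid_record_frame <- function() {
  data.frame(subject_key = character(), se_oid = character(),
             se_rk = character(), form_oid = character(),
             form_rk = character(), group_oid = character(),
             group_rk = character(), item_oid = character(),
             raw_value = character(), reason = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Validate a clinical dataset against the metadata tree
#'
#' Resolves every instance path; an unresolvable instance yields one
#' `UNDEFINED_REFERENCE` record and its whole subtree is excluded. Every
#' present item value then passes through [validate_value()]; failures are
#' excluded and recorded. Items whose value attribute was absent or empty
#' remain in the clean dataset as missing values (they are instances, but
#' carry no value).
#'
#' @param tree An `odm_metadata_tree`.
#' @param clinical An `odm_clinical_dataset` from [parse_odm()].
#' @return List with `clean` (an `odm_clinical_dataset`; its `items` table
#'   gains `typed_kind`, `typed_num` and `typed_bool` columns for valid
#'   values) and `invalid` (data frame, one row per finding, with the full
#'   hierarchical location, the raw value, `reason` and `detail`).
#' @export
validate_dataset <- function(tree, clinical) {
  stopifnot(inherits(tree, "odm_metadata_tree"),
            inherits(clinical, "odm_clinical_dataset"))
  invalid <- list()
  note <- function(row, reason, detail, raw = NA_character_) {
    rec <- list(subject_key = row$subject_key,
                se_oid = row$se_oid %||% NA_character_,
                se_rk = row$se_rk %||% NA_character_,
                form_oid = row$form_oid %||% NA_character_,
                form_rk = row$form_rk %||% NA_character_,
                group_oid = row$group_oid %||% NA_character_,
                group_rk = row$group_rk %||% NA_character_,
                item_oid = row$item_oid %||% NA_character_,
                raw_value = raw, reason = reason, detail = detail)
    invalid[[length(invalid) + 1L]] <<- rec
  }

  tabs <- list(events = clinical$events, forms = clinical$forms,
               groups = clinical$groups, items = clinical$items)
  excluded_parents <- character(0)  # instance keys of excluded subtrees

  for (level in c("events", "forms", "groups", "items")) {
    df <- tabs[[level]]
    if (nrow(df) == 0L) next
    keys <- instance_keys(df, level)
    pkeys <- parent_instance_keys(df, level)
    drop <- pkeys %in% excluded_parents
    resolved <- vapply(instance_path_keys(df, level), function(k)
      exists(k, envir = tree$index, inherits = FALSE), TRUE,
      USE.NAMES = FALSE)
    unres <- !drop & !resolved
    for (i in which(unres))
      note(df[i, ], "UNDEFINED_REFERENCE",
           sprintf("no %s defined at this position",
                   sub("s$", "", level)),
           raw = if (level == "items") df$value[i] else NA_character_)
    excluded_parents <- c(excluded_parents, keys[drop | unres])
    tabs[[level]] <- df[!(drop | unres), , drop = FALSE]
  }

  # type / code-list validation of present item values
  it <- tabs$items
  it[["typed_kind"]] <- rep(NA_character_, nrow(it))
  it[["typed_num"]] <- rep(NA_real_, nrow(it))
  it[["typed_bool"]] <- rep(NA, nrow(it))
  keep <- rep(TRUE, nrow(it))
  if (nrow(it) > 0L) {
    for (i in seq_len(nrow(it))) {
      raw <- it$value[i]
      if (is.na(raw)) next  # missing value: instance without value
      el <- resolve_instance_path(
        tree, c(it$se_oid[i], it$form_oid[i], it$group_oid[i],
                it$item_oid[i]))
      def <- el$def
      cl <- if (!is.null(def$codelist_oid))
        tree$defs$codelists[[def$codelist_oid]] else NULL
      res <- validate_value(def, raw, cl)
      if (inherits(res, "odm_invalid_reason")) {
        note(it[i, ], res$code, res$detail, raw = raw)
        keep[i] <- FALSE
      } else {
        it$typed_kind[i] <- res$kind
        it$typed_num[i] <- res$num
        if (res$kind == "boolean") it$typed_bool[i] <- res$payload
      }
    }
  }
  it <- it[keep, , drop = FALSE]

  inv_df <- invalid_record_frame()
  if (length(invalid) > 0L)
    inv_df <- do.call(rbind, lapply(invalid, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))

  clean <- odm_clinical_dataset(events = tabs$events, forms = tabs$forms,
                                groups = tabs$groups, items = it,
                                subject_keys = clinical$subject_keys)
  list(clean = clean, invalid = inv_df)
}

#' Export invalid-value records as CSV
#'
#' RFC 4180 CSV (all text fields quoted, CRLF line endings, UTF-8) with a
#' header row; one row per record, so the list can be used to correct the
#' source data and re-export.
#'
#' @param invalid The `invalid` data frame from [validate_dataset()].
#' @param path Output file path or connection.
#' @return Number of data rows written, invisibly.
#' @export
export_invalid_csv <- function(invalid, path) {
  out <- invalid
  names(out) <- c("subject_key", "study_event_oid", "event_repeat_key",
                  "form_oid", "form_repeat_key", "itemgroup_oid",
                  "group_repeat_key", "item_oid", "raw_value", "reason",
                  "detail")
  utils::write.table(out, path, sep = ",", qmethod = "double", quote = TRUE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     eol = "\r\n", fileEncoding = "UTF-8")
  invisible(nrow(out))
}
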