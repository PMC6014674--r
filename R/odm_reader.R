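#' @title Reading and structurally validating ODM files
#'
#' @description
#' First-stage processing of a CDISC ODM 1.3.x export: well-formedness,
#' version detection, validation against an explicit grammar of the
#' supported ODM element subset (required attributes, allowed children and
#' their order, attribute lexical forms, no foreign-namespace content), and
#' extraction of the metadata tree plus the clinical dataset. Structural
#' failure aborts the analysis; semantic checks on values happen later in
#' [validate_dataset()].
#'
#' @name odm_reader
#' @keywords internal
NULL

ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"
ODM_VERSIONS <- c("1.3.0", "1.3.1", "1.3.2")

structural_error_frame <- function(line = integer(), xml_path = character(),
                                   message = character()) {
  data.frame(line = as.integer(line), xml_path = as.character(xml_path),
             message = as.character(message), stringsAsFactors = FALSE)
}

# Grammar of the supported ODM subset. For each element: required
# attributes, optional attributes, and allowed children in schema order
# (children must appear grouped in non-decreasing order of this list).
odm_grammar <- function() {
  g <- list(
    ODM = list(
      req = c("FileOID", "FileType", "CreationDateTime", "ODMVersion"),
      opt = c("Granularity", "AsOfDateTime", "PriorFileOID", "Originator",
              "SourceSystem", "SourceSystemVersion", "Archival",
              "Description", "ID"),
      children = c("Study", "ClinicalData")),
    Study = list(req = "OID", opt = character(),
                 children = c("GlobalVariables", "MetaDataVersion")),
    GlobalVariables = list(req = character(), opt = character(),
                           children = c("StudyName", "StudyDescription",
                                        "ProtocolName")),
    StudyName = list(req = character(), opt = character(),
                     children = character()),
    StudyDescription = list(req = character(), opt = character(),
                            children = character()),
    ProtocolName = list(req = character(), opt = character(),
                        children = character()),
    MetaDataVersion = list(
      req = c("OID", "Name"), opt = "Description",
      children = c("Protocol", "StudyEventDef", "FormDef", "ItemGroupDef",
                   "ItemDef", "CodeList")),
    Protocol = list(req = character(), opt = character(),
                    children = "StudyEventRef"),
    StudyEventRef = list(
      req = c("StudyEventOID", "Mandatory"),
      opt = c("OrderNumber", "CollectionExceptionConditionOID"),
      children = character()),
    StudyEventDef = list(
      req = c("OID", "Name", "Repeating", "Type"), opt = "Category",
      children = "FormRef"),
    FormRef = list(
      req = c("FormOID", "Mandatory"),
      opt = c("OrderNumber", "CollectionExceptionConditionOID"),
      children = character()),
    FormDef = list(req = c("OID", "Name", "Repeating"), opt = character(),
                   children = "ItemGroupRef"),
    ItemGroupRef = list(req = c("ItemGroupOID", "Mandatory"),
                        opt = "OrderNumber", children = character()),
    ItemGroupDef = list(
      req = c("OID", "Name", "Repeating"),
      opt = c("IsReferenceData", "SASDatasetName", "Domain", "Origin",
              "Purpose", "Comment"),
      children = "ItemRef"),
    ItemRef = list(
      req = c("ItemOID", "Mandatory"),
      opt = c("OrderNumber", "KeySequence", "MethodOID",
              "ImputationMethodOID", "Role", "RoleCodeListOID"),
      children = character()),
    ItemDef = list(
      req = c("OID", "Name", "DataType"),
      opt = c("Length", "SignificantDigits", "SASFieldName", "SDSVarName",
              "Origin", "Comment"),
      children = c("Question", "CodeListRef")),
    Question = list(req = character(), opt = character(),
                    children = "TranslatedText"),
    TranslatedText = list(req = character(), opt = "xml:lang",
                          children = character()),
    CodeListRef = list(req = "CodeListOID", opt = character(),
                       children = character()),
    CodeList = list(req = c("OID", "Name", "DataType"), opt = "SASFormatName",
                    children = "CodeListItem"),
    CodeListItem = list(req = "CodedValue", opt = c("Rank", "OrderNumber"),
                        children = "Decode"),
    Decode = list(req = character(), opt = character(),
                  children = "TranslatedText"),
    ClinicalData = list(req = c("StudyOID", "MetaDataVersionOID"),
                        opt = character(), children = "SubjectData"),
    SubjectData = list(req = "SubjectKey", opt = "TransactionType",
                       children = "StudyEventData"),
    StudyEventData = list(
      req = "StudyEventOID", opt = c("StudyEventRepeatKey", "TransactionType"),
      children = "FormData"),
    FormData = list(req = "FormOID", opt = c("FormRepeatKey", "TransactionType"),
                    children = "ItemGroupData"),
    ItemGroupData = list(
      req = "ItemGroupOID", opt = c("ItemGroupRepeatKey", "TransactionType"),
      children = "ItemData"),
    ItemData = list(req = "ItemOID", opt = c("Value", "IsNull",
                                             "TransactionType"),
                    children = character())
  )
  g
}

# Lexical checks for attribute values; each returns TRUE or an error string.
attr_lexical_check <- function(elem, attr, value) {
  oid_attrs <- c("OID", "StudyEventOID", "FormOID", "ItemGroupOID", "ItemOID",
                 "CodeListOID", "StudyOID", "MetaDataVersionOID", "FileOID",
                 "SubjectKey", "CodedValue")
  if (attr %in% oid_attrs && !nzchar(value))
    return(sprintf("attribute %s must be a non-empty token", attr))
  if (attr %in% c("Mandatory", "Repeating", "IsNull", "Archival",
                  "IsReferenceData") && !value %in% c("Yes", "No"))
    return(sprintf("attribute %s must be 'Yes' or 'No', got '%s'",
                   attr, value))
  if (attr == "Type" && elem == "StudyEventDef" &&
      !value %in% c("Scheduled", "Unscheduled", "Common"))
    return(sprintf("invalid StudyEventDef Type '%s'", value))
  if (attr == "FileType" && !value %in% c("Snapshot", "Transactional"))
    return(sprintf("invalid FileType '%s'", value))
  if (attr == "DataType" &&
      !value %in% c(SUPPORTED_DATA_TYPES, KNOWN_UNSUPPORTED_TYPES))
    return(sprintf("unknown ODM DataType '%s'", value))
  if (attr %in% c("OrderNumber", "KeySequence", "Rank") &&
      !grepl("^-?[0-9]+$", value))
    return(sprintf("attribute %s must be an integer, got '%s'", attr, value))
  TRUE
}

read_input_bytes <- function(input) {
  if (is.raw(input)) return(input)
  if (inherits(input, "connection"))
    return(readBin(input, "raw", n = 64L * 1024L * 1024L))
  if (is.character(input) && length(input) == 1L) {
    if (file.exists(input))
      return(readBin(input, "raw", n = file.size(input)))
    return(charToRaw(input))  # literal XML string
  }
  stop("input must be a file path, XML string, raw vector or connection")
}

check_declared_encoding <- function(bytes) {
  head <- rawToChar(bytes[seq_len(min(length(bytes), 200L))])
  Encoding(head) <- "bytes"
  m <- regmatches(head, regexec("encoding\\s*=\\s*[\"']([^\"']+)[\"']", head))[[1]]
  if (length(m) == 2L && !toupper(m[2]) %in% c("UTF-8", "UTF8"))
    return(m[2])
  NULL
}

#' Detect the declared ODM version
#'
#' @param x A parsed `xml_document`, or anything [parse_odm()] accepts.
#' @return The version string (`"1.3.0"`, `"1.3.1"` or `"1.3.2"`), or `NA`
#'   with attribute `error` describing why detection failed.
#' @export
detect_version <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else
    tryCatch(xml2::read_xml(read_input_bytes(x)), error = function(e) NULL)
  fail <- function(msg) structure(NA_character_, error = msg)
  if (is.null(doc)) return(fail("document is not well-formed XML"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "ODM")
    return(fail(sprintf("root element is '%s', expected 'ODM'",
                        xml2::xml_name(root))))
  v <- xml2::xml_attr(root, "ODMVersion")
  if (is.na(v)) return(fail("missing ODMVersion attribute"))
  if (!v %in% ODM_VERSIONS)
    return(fail(sprintf("unsupported ODM version '%s' (supported: %s)", v,
                        paste(ODM_VERSIONS, collapse = ", "))))
  v
}

#' Validate an ODM document against the supported-element grammar
#'
#' Structural (schema-level) validation only: element names and nesting,
#' child order, required attributes and their lexical forms, and absence of
#' any element or attribute outside the ODM namespace. Semantic content
#' (reference resolution, value types, code-list membership) is checked
#' later by [validate_dataset()].
#'
#' @param x File path, XML string, raw vector, connection, or parsed
#'   `xml_document`.
#' @return Data frame of structural errors with columns `line`, `xml_path`,
#'   `message`; zero rows for a conformant document.
#' @export
validate_structure <- function(x) {
  errors <- structural_error_frame()
  add <- function(msg, xp = "", line = NA_integer_) {
    errors[nrow(errors) + 1L, ] <<- list(line, xp, msg)
  }

  if (!inherits(x, "xml_document")) {
    bytes <- read_input_bytes(x)
    bad_enc <- check_declared_encoding(bytes)
    if (!is.null(bad_enc)) {
      add(sprintf("unsupported character encoding '%s' (UTF-8 required)",
                  bad_enc))
      return(errors)
    }
    x <- tryCatch(xml2::read_xml(bytes), error = function(e) {
      msg <- conditionMessage(e)
      ln <- regmatches(msg, regexec("\\[(\\d+)\\]", msg))[[1]]
      add(paste("XML parse failure:", msg), "/",
          if (length(ln) == 2L) as.integer(ln[2]) else NA_integer_)
      NULL
    })
    if (is.null(x)) return(errors)
  }

  root <- xml2::xml_root(x)
  v <- detect_version(x)
  if (is.na(v)) add(attr(v, "error"), xml2::xml_path(root))
  root_uri <- xml2::xml_find_chr(root, "namespace-uri(.)")
  if (!identical(root_uri, ODM_NS))
    add(sprintf("root namespace is '%s', expected '%s'", root_uri, ODM_NS),
        xml2::xml_path(root))

  grammar <- odm_grammar()
  doc_ns <- xml2::xml_ns(x)
  nsmap <- c(structure(as.character(doc_ns), names = names(doc_ns)),
             xml = "http://www.w3.org/XML/1998/namespace")

  check_node <- function(node, expected_name) {
    name <- xml2::xml_name(node)
    xp <- xml2::xml_path(node)
    rule <- grammar[[name]]

    # attributes: required present, none unknown, lexical forms valid
    attrs <- xml2::xml_attrs(node, ns = nsmap)
    attrs <- attrs[!grepl("^xmlns(:|$)", names(attrs))]
    anames <- names(attrs)
    # xml2 reports foreign-namespace attributes with their prefix
    foreign <- anames[grepl(":", anames) & !anames %in% rule$opt]
    for (fa in foreign)
      add(sprintf("attribute '%s' outside the ODM namespace on <%s>",
                  fa, name), xp)
    plain <- setdiff(anames, foreign)
    for (req in rule$req)
      if (!req %in% plain)
        add(sprintf("<%s> is missing required attribute %s", name, req), xp)
    for (a in setdiff(plain, c(rule$req, rule$opt)))
      add(sprintf("unexpected attribute %s on <%s>", a, name), xp)
    for (a in intersect(plain, c(rule$req, rule$opt))) {
      chk <- attr_lexical_check(name, a, attrs[[a]])
      if (!isTRUE(chk)) add(sprintf("<%s>: %s", name, chk), xp)
    }

    # children: known, in ODM namespace, in schema order
    kids <- xml2::xml_children(node)
    last_rank <- 0L
    for (kid in kids) {
      kname <- xml2::xml_name(kid)
      kuri <- xml2::xml_find_chr(kid, "namespace-uri(.)")
      if (!identical(kuri, ODM_NS)) {
        add(sprintf("element <%s> outside the ODM namespace (XML extensions are not allowed)",
                    kname), xml2::xml_path(kid))
        next
      }
      rank <- match(kname, rule$children)
      if (is.na(rank)) {
        add(sprintf("unexpected element <%s> inside <%s>", kname, name),
            xml2::xml_path(kid))
        next
      }
      if (rank < last_rank)
        add(sprintf("element <%s> out of order inside <%s>", kname, name),
            xml2::xml_path(kid))
      last_rank <- max(last_rank, rank)
      check_node(kid, kname)
    }
  }

  if (xml2::xml_name(root) == "ODM") check_node(root, "ODM")
  errors
}

#' Parse an ODM file into metadata tree and clinical dataset
#'
#' Runs structural validation first; on any structural error the result
#' carries the error list and no data (analysis is aborted). On success the
#' first Study and its first MetaDataVersion are processed (extra ones are
#' skipped with a warning recorded), the positional metadata tree is built,
#' and all clinical data for that study is collected. TransactionType
#' attributes are ignored; an ItemData whose Value attribute is absent,
#' empty, or nulled via IsNull is recorded as a missing value.
#'
#' @param input File path, XML string, raw vector, or connection.
#' @return An object of class `odm_parse_result`: list with `version`,
#'   `metadata` (`odm_metadata_tree` or `NULL`), `clinical`
#'   (`odm_clinical_dataset` or `NULL`), `structural_errors` (data frame),
#'   `warnings` (character).
#' @export
parse_odm <- function(input) {
  result <- function(version = NA_character_, metadata = NULL,
                     clinical = NULL, errors = structural_error_frame(),
                     warnings = character()) {
    structure(list(version = version, metadata = metadata,
                   clinical = clinical, structural_errors = errors,
                   warnings = warnings),
              class = "odm_parse_result")
  }

  bytes <- read_input_bytes(input)
  errors <- validate_structure(bytes)
  if (nrow(errors) > 0L) return(result(errors = errors))

  doc <- xml2::read_xml(bytes)
  version <- detect_version(doc)
  warnings <- character()
  ns <- c(d1 = ODM_NS)

  studies <- xml2::xml_find_all(doc, "./d1:Study", ns)
  if (length(studies) == 0L)
    return(result(version, errors = structural_error_frame(
      NA_integer_, "/ODM", "file contains no Study element")))
  if (length(studies) > 1L)
    warnings <- c(warnings, sprintf(
      "file declares %d Study elements; only the first is analyzed",
      length(studies)))
  study <- studies[[1]]
  study_oid <- xml2::xml_attr(study, "OID")
  study_name <- xml2::xml_text(
    xml2::xml_find_first(study, "./d1:GlobalVariables/d1:StudyName", ns))
  if (is.na(study_name)) study_name <- study_oid

  mdvs <- xml2::xml_find_all(study, "./d1:MetaDataVersion", ns)
  if (length(mdvs) == 0L)
    return(result(version, errors = structural_error_frame(
      NA_integer_, xml2::xml_path(study),
      "Study contains no MetaDataVersion")))
  if (length(mdvs) > 1L)
    warnings <- c(warnings, sprintf(
      "Study declares %d MetaDataVersions; only the first is used",
      length(mdvs)))
  mdv <- mdvs[[1]]

  extract <- extract_definitions(mdv, ns)
  tree <- tryCatch(
    build_positional_tree(extract$defs, extract$study_refs,
                          study_oid = study_oid, study_name = study_name),
    odm_structural_error = function(e) e)
  if (inherits(tree, "odm_structural_error"))
    return(result(version, errors = structural_error_frame(
      NA_integer_, tree$xml_path %||% "", conditionMessage(tree))))
  clinical <- extract_clinical_data(doc, study_oid, ns)
  warnings <- c(warnings, clinical$warnings)
  result(version, tree, clinical$dataset, warnings = warnings)
}

#' @export
print.odm_parse_result <- function(x, ...) {
  if (nrow(x$structural_errors) > 0L) {
    cat(sprintf("ODM parse failed: %d structural error(s)\n",
                nrow(x$structural_errors)))
    utils::head(x$structural_errors, 10)
  } else {
    cat(sprintf("ODM %s parse result\n", x$version))
    print(x$metadata)
    print(x$clinical)
  }
  invisible(x)
}

extract_definitions <- function(mdv, ns) {
  attr1 <- xml2::xml_attr
  ref_list <- function(node, elem, oid_attr) {
    refs <- xml2::xml_find_all(node, paste0("./d1:", elem), ns)
    lapply(refs, function(r)
      odm_element_ref(attr1(r, oid_attr),
                      identical(attr1(r, "Mandatory"), "Yes")))
  }

  events <- lapply(xml2::xml_find_all(mdv, "./d1:StudyEventDef", ns),
                   function(n) list(
                     oid = attr1(n, "OID"), name = attr1(n, "Name"),
                     repeating = identical(attr1(n, "Repeating"), "Yes"),
                     refs = ref_list(n, "FormRef", "FormOID")))
  forms <- lapply(xml2::xml_find_all(mdv, "./d1:FormDef", ns),
                  function(n) list(
                    oid = attr1(n, "OID"), name = attr1(n, "Name"),
                    repeating = identical(attr1(n, "Repeating"), "Yes"),
                    refs = ref_list(n, "ItemGroupRef", "ItemGroupOID")))
  groups <- lapply(xml2::xml_find_all(mdv, "./d1:ItemGroupDef", ns),
                   function(n) list(
                     oid = attr1(n, "OID"), name = attr1(n, "Name"),
                     repeating = identical(attr1(n, "Repeating"), "Yes"),
                     refs = ref_list(n, "ItemRef", "ItemOID")))
  items <- lapply(xml2::xml_find_all(mdv, "./d1:ItemDef", ns), function(n) {
    clref <- xml2::xml_find_first(n, "./d1:CodeListRef", ns)
    q <- xml2::xml_find_first(n, "./d1:Question/d1:TranslatedText", ns)
    odm_item_def(
      oid = attr1(n, "OID"), name = attr1(n, "Name"),
      data_type = attr1(n, "DataType"),
      question = if (inherits(q, "xml_node")) xml2::xml_text(q) else NULL,
      codelist_oid = if (inherits(clref, "xml_node"))
        attr1(clref, "CodeListOID") else NULL)
  })
  codelists <- lapply(xml2::xml_find_all(mdv, "./d1:CodeList", ns),
                      function(n) {
    cli <- xml2::xml_find_all(n, "./d1:CodeListItem", ns)
    coded <- vapply(cli, attr1, "", "CodedValue")
    dec <- vapply(cli, function(ci) {
      t <- xml2::xml_find_first(ci, "./d1:Decode/d1:TranslatedText", ns)
      if (inherits(t, "xml_node")) xml2::xml_text(t) else NA_character_
    }, "")
    dec <- ifelse(is.na(dec), coded, dec)
    odm_codelist_def(attr1(n, "OID"),
                     data.frame(coded_value = coded, decode = dec,
                                stringsAsFactors = FALSE),
                     data_type = attr1(n, "DataType"),
                     name = attr1(n, "Name"))
  })

  study_refs <- unlist(lapply(
    xml2::xml_find_all(mdv, "./d1:Protocol", ns),
    function(p) ref_list(p, "StudyEventRef", "StudyEventOID")),
    recursive = FALSE) %||% list()

  list(defs = odm_definitions(events, forms, groups, items, codelists),
       study_refs = study_refs)
}

extract_clinical_data <- function(doc, study_oid, ns) {
  cd_all <- xml2::xml_find_all(doc, "./d1:ClinicalData", ns)
  keep <- vapply(cd_all, function(n)
    identical(xml2::xml_attr(n, "StudyOID"), study_oid), TRUE)
  warnings <- character()
  if (any(!keep))
    warnings <- c(warnings, sprintf(
      "%d ClinicalData block(s) for other studies were skipped",
      sum(!keep)))
  cd_all <- cd_all[keep]

  rows <- list(events = list(), forms = list(), groups = list(),
               items = list())
  subject_keys <- character()
  attr1 <- xml2::xml_attr

  for (cd in cd_all) {
    for (sd in xml2::xml_find_all(cd, "./d1:SubjectData", ns)) {
      sk <- attr1(sd, "SubjectKey")
      subject_keys <- c(subject_keys, sk)
      for (se in xml2::xml_find_all(sd, "./d1:StudyEventData", ns)) {
        se_oid <- attr1(se, "StudyEventOID")
        se_rk <- attr1(se, "StudyEventRepeatKey")
        rows$events[[length(rows$events) + 1L]] <- c(sk, se_oid, se_rk)
        for (fd in xml2::xml_find_all(se, "./d1:FormData", ns)) {
          f_oid <- attr1(fd, "FormOID"); f_rk <- attr1(fd, "FormRepeatKey")
          rows$forms[[length(rows$forms) + 1L]] <-
            c(sk, se_oid, se_rk, f_oid, f_rk)
          for (gd in xml2::xml_find_all(fd, "./d1:ItemGroupData", ns)) {
            g_oid <- attr1(gd, "ItemGroupOID")
            g_rk <- attr1(gd, "ItemGroupRepeatKey")
            rows$groups[[length(rows$groups) + 1L]] <-
              c(sk, se_oid, se_rk, f_oid, f_rk, g_oid, g_rk)
            for (id in xml2::xml_find_all(gd, "./d1:ItemData", ns)) {
              val <- attr1(id, "Value")
              if (identical(attr1(id, "IsNull"), "Yes") ||
                  (!is.na(val) && !nzchar(val)))
                val <- NA_character_
              rows$items[[length(rows$items) + 1L]] <-
                c(sk, se_oid, se_rk, f_oid, f_rk, g_oid, g_rk,
                  attr1(id, "ItemOID"), val)
            }
          }
        }
      }
    }
  }

  cols <- clinical_dataset_columns()
  to_df <- function(lst, level) {
    want <- cols[[level]]
    if (length(lst) == 0L)
      return(NULL)
    m <- do.call(rbind, lst)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- want
    df
  }
  ds <- odm_clinical_dataset(
    events = to_df(rows$events, "events"),
    forms = to_df(rows$forms, "forms"),
    groups = to_df(rows$groups, "groups"),
    items = to_df(rows$items, "items"),
    subject_keys = unique(subject_keys))
  list(dataset = ds, warnings = warnings)
}
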