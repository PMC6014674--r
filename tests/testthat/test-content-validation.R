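test_that("validate_value implements the type lexical spaces", {
  iv <- function(dt) odm_item_def("I1", data_type = dt)
  ok <- function(x) expect_s3_class(x, "odm_typed_value")
  bad <- function(x, code) {
    expect_s3_class(x, "odm_invalid_reason")
    expect_identical(x$code, code)
  }

  # boolean: exactly the four XML literals, case-sensitive
  b <- validate_value(iv("boolean"), "1")
  ok(b); expect_true(b$payload)
  expect_false(validate_value(iv("boolean"), "0")$payload)
  bad(validate_value(iv("boolean"), "TRUE"), "TYPE_MISMATCH")
  bad(validate_value(iv("boolean"), " true"), "TYPE_MISMATCH")

  # integer / float
  ok(validate_value(iv("integer"), "-17"))
  bad(validate_value(iv("integer"), "4.2"), "TYPE_MISMATCH")
  ok(validate_value(iv("float"), "4.2"))
  ok(validate_value(iv("double"), "-.5e3"))
  bad(validate_value(iv("float"), "4,2"), "TYPE_MISMATCH")

  # ISO 8601 timepoints
  d <- validate_value(iv("date"), "2020-02-29")
  ok(d); expect_identical(d$num, as.numeric(as.Date("2020-02-29")))
  bad(validate_value(iv("date"), "2019-02-29"), "TYPE_MISMATCH")
  bad(validate_value(iv("date"), "2020-13-01"), "TYPE_MISMATCH")
  ok(validate_value(iv("time"), "23:59:59.5"))
  bad(validate_value(iv("time"), "24:00:00"), "TYPE_MISMATCH")
  dt1 <- validate_value(iv("datetime"), "2020-01-01T00:00:00+01:00")
  dt2 <- validate_value(iv("datetime"), "2019-12-31T23:00:00Z")
  ok(dt1); ok(dt2)
  expect_identical(dt1$num, dt2$num)  # zone-normalized instants

  # string accepts anything; unsupported types are flagged, never raise
  ok(validate_value(iv("string"), "  anything, at all "))
  bad(validate_value(iv("partialDate"), "2020-01"), "UNSUPPORTED_TYPE")
})

test_that("code-list items: conversion first, then membership", {
  cl <- odm_codelist_def("CL1", c("1", "2", "3"), data_type = "integer")
  it <- odm_item_def("I1", data_type = "integer", codelist_oid = "CL1")
  good <- validate_value(it, "2", cl)
  expect_s3_class(good, "odm_typed_value")
  expect_identical(good$kind, "code")
  r <- validate_value(it, "5", cl)
  expect_identical(r$code, "NOT_IN_CODELIST")
  r2 <- validate_value(it, "x", cl)
  expect_identical(r2$code, "TYPE_MISMATCH")  # first failure reported
})

test_that("validate_value is pure", {
  it <- odm_item_def("I1", data_type = "float")
  expect_identical(validate_value(it, "3.14"), validate_value(it, "3.14"))
  expect_identical(validate_value(it, "zzz"), validate_value(it, "zzz"))
})

test_that("validate_dataset recovers injected errors exactly and conserves values", {
  spec <- fixture_spec(seed = 21L, subjects = 12L,
                       invalid_plan = c(TYPE_MISMATCH = 4L,
                                        NOT_IN_CODELIST = 3L,
                                        UNDEFINED_REFERENCE = 2L,
                                        UNSUPPORTED_TYPE = 2L))
  fx <- generate_fixture(spec)
  p <- parse_odm(fx$xml)
  vd <- validate_dataset(p$metadata, p$clinical)

  got <- table(vd$invalid$reason)
  want <- table(fx$manifest$injected$reason)
  expect_identical(as.list(got)[sort(names(got))],
                   as.list(want)[sort(names(want))])

  # each record pinpoints the injected location
  key <- function(df) paste(df$subject_key, df$se_oid, df$group_oid,
                            df$item_oid, df$raw_value)
  expect_setequal(key(vd$invalid), key(fx$manifest$injected))

  # conservation: present values = clean valid values + invalid records
  # (this fixture injects only item-level faults)
  n_present <- sum(!is.na(p$clinical$items$value))
  n_clean <- sum(!is.na(vd$clean$items$value))
  expect_identical(n_present, n_clean + nrow(vd$invalid))
})

test_that("clean datasets pass through unchanged (idempotence)", {
  fx <- generate_fixture(fixture_spec(seed = 22L, subjects = 8L))
  p <- parse_odm(fx$xml)
  vd <- validate_dataset(p$metadata, p$clinical)
  expect_identical(nrow(vd$invalid), 0L)
  vd2 <- validate_dataset(p$metadata, vd$clean)
  expect_identical(nrow(vd2$invalid), 0L)
  expect_identical(vd2$clean$items$value, vd$clean$items$value)
  expect_identical(vd2$clean$events, vd$clean$events)
})

test_that("undefined reference at group level excludes the subtree with one record", {
  xml <- mini_odm()
  xml <- sub('<ItemGroupData ItemGroupOID="IG1">',
             '<ItemGroupData ItemGroupOID="IG9">', xml, fixed = TRUE)
  p <- parse_odm(xml)
  vd <- validate_dataset(p$metadata, p$clinical)
  expect_identical(nrow(vd$invalid), 1L)
  expect_identical(vd$invalid$reason, "UNDEFINED_REFERENCE")
  expect_identical(vd$invalid$group_oid, "IG9")
  expect_true(is.na(vd$invalid$item_oid))  # one cause, one row
  expect_identical(nrow(vd$clean$items), 0L)
  expect_identical(nrow(vd$clean$groups), 0L)
  expect_identical(nrow(vd$clean$forms), 1L)  # parent levels survive
})

test_that("export_invalid_csv writes RFC 4180 round-trippable output", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  empty <- validate_dataset(
    parse_odm(mini_odm())$metadata,
    parse_odm(mini_odm())$clinical)$invalid
  expect_identical(export_invalid_csv(empty, tmp), 0L)
  expect_identical(length(readLines(tmp)), 1L)  # header only

  inv <- data.frame(
    subject_key = c("S1", "S2", "S3"), se_oid = "SE1", se_rk = NA,
    form_oid = "F1", form_rk = NA, group_oid = "IG1",
    group_rk = c("1", "2", NA), item_oid = "I1",
    raw_value = c('has,comma', 'has"quote', "plain"),
    reason = "TYPE_MISMATCH", detail = "d", stringsAsFactors = FALSE)
  expect_identical(export_invalid_csv(inv, tmp), 3L)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 3L)
  expect_identical(back$raw_value, inv$raw_value)
  expect_identical(names(back)[1:3],
                   c("subject_key", "study_event_oid", "event_repeat_key"))
})
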