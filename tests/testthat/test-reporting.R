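test_that("sections are present iff the corresponding option was enabled", {
  xml <- mini_odm()
  r <- run_analysis(xml, statistics = TRUE, completeness = FALSE)
  expect_false(is.null(r$statistics))
  expect_null(r$completeness)
  r2 <- run_analysis(xml, statistics = FALSE, completeness = TRUE,
                     completeness_mode = "both")
  expect_null(r2$statistics)
  expect_named(r2$completeness, c("mandatory_flag", "all_mandatory"))
  expect_error(render_document(r2, tempfile(fileext = ".html")),
               "requires the statistics")
})

test_that("structural failure aborts with status 2 and no analysis sections", {
  fx <- generate_fixture(fixture_spec(seed = 61L, subjects = 2L,
                                      structural_faults = "bad_version"))
  r <- run_analysis(fx$xml, statistics = TRUE, completeness = TRUE)
  expect_identical(r$status, 2L)
  expect_null(r$statistics)
  expect_null(r$completeness)
  # serializable even in the error state
  json <- serialize_report(r)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_identical(parsed$status, 2L)
  expect_gt(length(parsed$structural_errors), 0L)
})

test_that("serialization is deterministic and round-trips byte-identically", {
  fx <- generate_fixture(fixture_spec(
    seed = 62L, subjects = 6L,
    invalid_plan = c(TYPE_MISMATCH = 2L, NOT_IN_CODELIST = 1L)))
  r1 <- run_analysis(fx$xml, statistics = TRUE, completeness = TRUE,
                     completeness_mode = "both")
  r2 <- run_analysis(fx$xml, statistics = TRUE, completeness = TRUE,
                     completeness_mode = "both")
  j1 <- serialize_report(r1)
  expect_identical(j1, serialize_report(r2))

  tmp <- withr::local_tempfile(fileext = ".json")
  serialize_report(r1, tmp)
  back <- jsonlite::toJSON(deserialize_report(tmp), auto_unbox = TRUE,
                           digits = NA, null = "null")
  expect_identical(as.character(back), j1)

  parsed <- deserialize_report(tmp)
  expect_identical(parsed$completeness$mandatory_flag$total_subjects, 6L)
  expect_true("invalid_values" %in% names(parsed))
})

test_that("reports without invalid values omit that section", {
  r <- run_analysis(mini_odm(), statistics = TRUE)
  parsed <- jsonlite::fromJSON(serialize_report(r),
                               simplifyVector = FALSE)
  expect_false("invalid_values" %in% names(parsed))
})

test_that("the rendered document has one section per item", {
  fx <- generate_fixture(fixture_spec(seed = 63L, subjects = 4L))
  r <- run_analysis(fx$xml, statistics = TRUE)
  n_items <- length(item_stats_by_path(r))
  tmp <- withr::local_tempfile(fileext = ".html")
  expect_identical(render_document(r, tmp), n_items)
  html <- readLines(tmp)
  expect_identical(sum(lengths(regmatches(
    html, gregexpr("<section>", html, fixed = TRUE)))), n_items)

  # zero analyzable items -> header only
  fx0 <- generate_fixture(fixture_spec(seed = 64L, subjects = 2L,
                                       events = 0L))
  r0 <- run_analysis(fx0$xml, statistics = TRUE)
  expect_identical(render_document(r0, tmp), 0L)
})

test_that("chart PNG renderer writes one file per charted item", {
  fx <- generate_fixture(fixture_spec(seed = 65L, subjects = 4L,
                                      events = 1L, forms_per_event = 1L))
  r <- run_analysis(fx$xml, statistics = TRUE)
  dir <- withr::local_tempdir()
  files <- render_charts(r, dir)
  n_charted <- sum(vapply(item_stats_by_path(r), function(e)
    !is.null(e$chart), TRUE))
  expect_length(files, n_charted)
  expect_true(all(file.exists(files)))
})

test_that("the CLI honours the documented exit codes", {
  fx <- generate_fixture(fixture_spec(seed = 66L, subjects = 3L))
  good <- withr::local_tempfile(fileext = ".xml")
  writeLines(fx$xml, good)
  out_json <- withr::local_tempfile(fileext = ".json")
  expect_identical(suppressMessages(odm_insight_cli(
    c(good, "--statistics", "--completeness",
      "--report-json", out_json, "--log-level", "error"))), 0L)
  expect_true(file.exists(out_json))

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(generate_fixture(fixture_spec(
    seed = 66L, subjects = 2L,
    structural_faults = "foreign_namespace"))$xml, bad)
  expect_identical(odm_insight_cli(c(bad, "--statistics",
                                     "--log-level", "error")), 2L)

  # usage errors: missing input, report-doc without statistics
  expect_identical(odm_insight_cli(c("--statistics",
                                     "--log-level", "error")), 1L)
  expect_identical(odm_insight_cli(
    c(good, "--report-doc", "x.html", "--log-level", "error")), 1L)
  expect_identical(odm_insight_cli(
    c("/nonexistent.xml", "--statistics", "--log-level", "error")), 1L)
})
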