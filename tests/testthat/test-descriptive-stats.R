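test_that("categorize maps data types onto the extended Stevens scale", {
  expect_identical(categorize(odm_item_def("a", data_type = "boolean")),
                   "dichotomous")
  expect_identical(categorize(odm_item_def("a", data_type = "text")),
                   "nominal")
  expect_identical(categorize(odm_item_def("a", data_type = "datetime")),
                   "interval")
  expect_identical(categorize(odm_item_def("a", data_type = "double")),
                   "ratio")
  # a code list wins over the base type
  expect_identical(
    categorize(odm_item_def("a", data_type = "integer",
                            codelist_oid = "CL1")), "ordinal")
  expect_identical(categorize(odm_item_def("a", data_type = "partialDate")),
                   "unsupported")
})

test_that("nominal top-3 uses exact matching and ranked counts", {
  s <- stats_nominal(c("a", "b", "a", "c", "a", "b"))
  expect_identical(s$diversity, 3L)
  expect_identical(s$entries$value, c("a", "b", "c"))
  expect_identical(s$entries$count, c(3L, 2L, 1L))
  expect_null(s$chart)

  expect_identical(stats_nominal("x")$entries$value, "x")
  expect_identical(stats_nominal(c("A", "a"))$diversity, 2L)  # case matters

  # ties break by code point, independent of input order
  set.seed(99)
  vals <- c("b", "a", "c")
  for (i in 1:5) {
    perm <- sample(vals)
    expect_identical(stats_nominal(perm)$entries$value, c("a", "b", "c"))
  }
})

test_that("nominal and dichotomous tallies equal brute-force oracles", {
  set.seed(101)
  for (i in 1:25) {
    vocab <- replicate(sample(1:8, 1),
                       paste(sample(letters, 3), collapse = ""))
    vals <- sample(vocab, sample(1:60, 1), replace = TRUE)
    s <- stats_nominal(vals)
    fr <- oracle_freqs(vals)
    expect_identical(s$diversity, length(fr))
    top <- sort(as.integer(fr), decreasing = TRUE)
    expect_identical(s$entries$count,
                     top[seq_len(min(3, length(top)))])

    raws <- sample(c("true", "false", "1", "0"), sample(0:40, 1),
                   replace = TRUE)
    tal <- oracle_bool_tally(raws)
    d <- stats_dichotomous(raws %in% c("true", "1"))
    expect_identical(c(d$true_count, d$false_count),
                     as.integer(unname(tal)))
    expect_identical(d$true_count + d$false_count, length(raws))
  }
})

test_that("ordinal bar chart follows the at-most-ten rule", {
  cl10 <- odm_codelist_def("CL", sprintf("O%02d", 1:10))
  vals <- rep(c("O01", "O05"), c(4, 2))
  s <- stats_ordinal(vals, cl10)
  # boundary: exactly 10 options -> all labelled, in list order, no others
  expect_identical(s$chart$labels, sprintf("O%02d", 1:10))
  expect_identical(sum(s$chart$counts), length(vals))
  expect_identical(s$chart$counts[1], 4L)
  expect_identical(s$diversity, 2L)
  expect_identical(s$diversity_total, 10L)

  cl15 <- odm_codelist_def("CL", sprintf("O%02d", 1:15))
  vals15 <- rep(sprintf("O%02d", 1:15), 16 - (1:15))
  s15 <- stats_ordinal(vals15, cl15)
  expect_length(s15$chart$labels, 10L)
  expect_identical(s15$chart$labels[10], "others")
  expect_identical(s15$chart$counts[10],
                   as.integer(length(vals15) -
                                sum(sort(16 - (1:15),
                                         decreasing = TRUE)[1:9])))
  expect_identical(sum(s15$chart$counts), length(vals15))

  # the others bar is always last, never re-ranked among the top nine
  expect_identical(s15$chart$labels[1:9], sprintf("O%02d", 1:9))
})

test_that("histogram binning matches an independent O(n*bins) oracle", {
  h <- make_histogram(0:9, 10L)
  expect_identical(h$counts, rep(1L, 10))
  expect_identical(h$breaks[1], 0); expect_identical(h$breaks[11], 9)
  expect_type(h$breaks, "double")

  # degenerate range: one bin holding everything
  h1 <- make_histogram(rep(3.3, 7), 10L)
  expect_identical(h1$counts, 7L)
  expect_identical(h1$breaks, c(3.3, 3.3))

  # the maximum lands in the last (closed) bin
  h2 <- make_histogram(c(0, 10), 5L)
  expect_identical(h2$counts[5], 1L)

  set.seed(202)
  for (i in 1:10) {
    vals <- stats::runif(1000, -50, 50)
    nb <- sample(2:20, 1)
    h <- make_histogram(vals, nb)
    expect_identical(h$counts, oracle_hist_counts(vals, h$breaks))
    expect_identical(sum(h$counts), length(vals))
    expect_true(all(diff(h$breaks) > 0))
  }
})

test_that("ratio summary matches the closed-form oracle", {
  s1 <- stats_ratio(5.0)
  expect_identical(c(s1$min, s1$max, s1$mean, s1$median), rep(5, 4))
  expect_identical(s1$stddev, 0)  # n = 1 convention

  # frozen expected values, recomputed from the definition:
  # mean 40/8 = 5, median (4+5)/2, sum of squared deviations 32, n-1 = 7
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  s <- stats_ratio(x)
  expect_identical(s$mean, 5)
  expect_identical(s$median, 4.5)
  expect_identical(s$min, 2); expect_identical(s$max, 9)
  expect_equal(s$stddev, sqrt(32 / 7), tolerance = 1e-12)
  expect_match(s$rendered,
               "^Min: -?[0-9.]+ \\| Max: -?[0-9.]+ \\| Mean: -?[0-9.]+ \\| Median: -?[0-9.]+ \\| StdDev: [0-9.]+$")

  set.seed(303)
  for (i in 1:15) {
    vals <- round(stats::rnorm(sample(1:40, 1), 10, 4), 3)
    s <- stats_ratio(vals)
    o <- oracle_ratio(vals)
    for (f in c("min", "max", "mean", "median", "stddev"))
      expect_equal(s[[f]], o[[f]], tolerance = 1e-12)
  }
})

test_that("interval statistics report the chronological range only", {
  one <- stats_interval(as.numeric(as.Date("2020-05-01")), "date")
  expect_identical(one$min, one$max)
  expect_identical(one$rendered, "Range: 01 May 2020 - 01 May 2020")
  expect_null(stats_interval(numeric(), "date")$chart)
  expect_false("mean" %in% names(one))  # no average for timepoints

  set.seed(404)
  dates <- as.numeric(as.Date("2000-01-01") + sample(0:7000, 100, TRUE))
  s <- stats_interval(dates, "date", n_bins = 10L)
  expect_identical(s$min, min(dates))
  expect_identical(s$max, max(dates))
  expect_identical(s$chart$counts, oracle_hist_counts(dates,
                                                      s$chart$breaks))
})

test_that("reference counts and repeat flags on a repeated group", {
  # one subject, group repeated 3x -> (3, 1) and a repeat warning
  xml <- mini_odm()
  rep3 <- paste0(
    '     <ItemGroupData ItemGroupOID="IG1" ItemGroupRepeatKey="', 1:3,
    '">\n      <ItemData ItemOID="I1" Value="', 1:3,
    '"/>\n     </ItemGroupData>\n', collapse = "")
  xml <- sub('     <ItemGroupData ItemGroupOID="IG1">\n      <ItemData ItemOID="I1" Value="5"/>\n     </ItemGroupData>\n',
             rep3, xml, fixed = TRUE)
  p <- parse_odm(xml)
  vd <- validate_dataset(p$metadata, p$clinical)
  g <- resolve_instance_path(p$metadata, c("SE1", "F1", "IG1"))
  expect_identical(count_references(g, vd$clean),
                   list(reference_count = 3L, subject_count = 1L))
  expect_true(flag_repeat_keys(g, vd$clean))

  ev <- resolve_instance_path(p$metadata, "SE1")
  expect_identical(count_references(ev, vd$clean)$reference_count, 1L)
  expect_false(flag_repeat_keys(ev, vd$clean))

  # an element never referenced in the data
  p0 <- parse_odm(mini_odm())
  empty <- validate_dataset(p0$metadata, p0$clinical)$clean
  empty$items <- empty$items[0, ]
  it <- resolve_instance_path(p0$metadata, c("SE1", "F1", "IG1", "I1"))
  expect_identical(count_references(it, empty),
                   list(reference_count = 0L, subject_count = 0L))
})

test_that("a form placed under two events is analyzed positionally", {
  v1 <- as.character(1:4)          # SE1 data
  v2 <- as.character(11:16)        # SE2 data
  r <- run_analysis(shared_form_odm(v1, v2), statistics = TRUE)
  items <- item_stats_by_path(r)
  s1 <- items[["SE1/F1/IG1/I1"]]
  s2 <- items[["SE2/F1/IG1/I1"]]
  expect_identical(s1$n_valid, length(v1))
  expect_identical(s2$n_valid, length(v2))
  expect_identical(s1$summary$mean, mean(as.numeric(v1)))
  expect_identical(s2$summary$mean, mean(as.numeric(v2)))

  # merging both placements' data reproduces a single-placement analysis
  ru <- run_analysis(shared_form_odm(c(v1, v2), character()),
                     statistics = TRUE)
  su <- item_stats_by_path(ru)[["SE1/F1/IG1/I1"]]
  o <- oracle_ratio(as.numeric(c(v1, v2)))
  expect_equal(su$summary$mean, o$mean, tolerance = 1e-12)
  expect_equal(su$summary$stddev, o$stddev, tolerance = 1e-12)
})

test_that("items with zero valid values stay visible with (0, 0) counts", {
  xml <- sub('Value="5"', 'Value=""', mini_odm())
  r <- run_analysis(xml, statistics = TRUE)
  it <- item_stats_by_path(r)[["SE1/F1/IG1/I1"]]
  expect_identical(it$n_valid, 0L)
  expect_identical(it$rendered, "No data")
  expect_identical(it$counts$reference_count, 1L)  # the tag is an instance
  expect_null(it$chart)
})
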