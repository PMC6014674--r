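#' @title Scale-of-measurement descriptive statistics
#'
#' @description
#' Every item is assigned one of five categories following the Stevens
#' scale of measurement, extended with a dichotomous class, and each
#' category gets its own summary and chart:
#'
#' | category    | ODM types             | chart     |
#' |-------------|-----------------------|-----------|
#' | dichotomous | boolean               | pie       |
#' | nominal     | string, text          | none      |
#' | ordinal     | any code-list item    | bar       |
#' | interval    | time, date, datetime  | histogram |
#' | ratio       | integer, float, double| histogram |
#'
#' All values are used, including several values contributed by the same
#' subject through repeat keys; multi-contribution is never averaged away
#' but flagged with a repeat-key warning so the reader treats the summary
#' with care. Statistics are computed on the cleaned dataset (invalid
#' entries excluded); the invalid-value warning flag keeps those locations
#' visible.
#'
#' @name descriptive_stats
#' @keywords internal
NULL

#' Categorize an item onto the extended Stevens scale
#'
#' A code list wins over the base type: any code-list backed item is
#' ordinal regardless of whether the codes are character or numeric.
#'
#' @param item An [odm_item_def()].
#' @return One of `"dichotomous"`, `"nominal"`, `"ordinal"`, `"interval"`,
#'   `"ratio"`, or `"unsupported"` for ODM types outside the supported set
#'   (such items are skipped and reported).
#' @export
categorize <- function(item) {
  stopifnot(inherits(item, "odm_item_def"))
  if (!is.null(item$codelist_oid)) return("ordinal")
  switch(item$data_type,
    boolean = "dichotomous",
    string = , text = "nominal",
    time = , date = , datetime = "interval",
    integer = , float = , double = "ratio",
    "unsupported")
}

#' Count clinical references and contributing subjects for an element
#'
#' @param element A positional element from the metadata tree.
#' @param clean A (cleaned) `odm_clinical_dataset`.
#' @return List with `reference_count` (instances at this positional path
#'   across all subjects and repeat keys) and `subject_count` (distinct
#'   subjects with at least one instance). References may exceed subjects
#'   when repeat keys are present.
#' @export
count_references <- function(element, clean) {
  lv <- level_table(element$level)
  df <- clean[[lv]]
  hit <- instance_path_keys(df, lv) == path_key(element$path)
  list(reference_count = sum(hit),
       subject_count = length(unique(df$subject_key[hit])))
}

level_table <- function(level) {
  switch(level, study_event = "events", form = "forms",
         item_group = "groups", item = "items")
}

#' Tally a dichotomous (boolean) item
#'
#' @param values Logical vector of valid values.
#' @return List with `true_count`, `false_count`, `chart` (pie with two
#'   slices; `NULL` when no values), and `rendered` summary string.
#' @export
stats_dichotomous <- function(values) {
  tc <- sum(values); fc <- sum(!values)
  chart <- if (length(values) > 0L)
    list(kind = "pie", labels = c("true", "false"), counts = c(tc, fc))
  list(true_count = tc, false_count = fc, chart = chart,
       rendered = if (length(values) == 0L) "No data"
                  else sprintf("True: %d - False: %d", tc, fc))
}

# Frequency table with deterministic tie-break: count descending, then
# value ascending by code point.
ranked_counts <- function(values) {
  if (length(values) == 0L)
    return(data.frame(value = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(values)
  df <- data.frame(value = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  o <- order(-df$count, rank_by_codepoint(df$value))
  df[o, , drop = FALSE]
}

rank_by_codepoint <- function(x) {
  prev <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  xtfrm(x)
}

render_top <- function(entries) {
  if (nrow(entries) == 0L) return("")
  paste(sprintf("%d. %s (%d)", seq_len(nrow(entries)), entries$value,
                entries$count), collapse = " | ")
}

#' Top-three summary of a nominal (free-text) item
#'
#' Exact, byte-equal string matching with no pre-processing; no chart is
#' produced since the number of distinct free-text values is unbounded.
#'
#' @param values Character vector of valid values.
#' @return List with `entries` (up to three rows of `value`, `count`,
#'   sorted by count descending, ties by code point), `diversity`
#'   (distinct strings), `chart = NULL` and `rendered` string of the form
#'   `"Diversity: 22 - Top3: 1. red (9) | 2. green (7) | 3. blue (5)"`.
#' @export
stats_nominal <- function(values) {
  rc <- ranked_counts(values)
  entries <- utils::head(rc, 3L)
  list(entries = entries, diversity = nrow(rc), chart = NULL,
       rendered = if (length(values) == 0L) "No data"
                  else sprintf("Diversity: %d - Top3: %s", nrow(rc),
                               render_top(entries)))
}

#' Top-three summary and bar chart of an ordinal (code-list) item
#'
#' Diversity is reported as observed distinct options over the list size.
#' The bar chart shows at most ten bars: all options (in list order,
#' including unobserved ones) when the list has ten or fewer, otherwise
#' the top nine by count plus one `others` bar summing the remaining
#' options' counts.
#'
#' @param values Character vector of coded values (already validated as
#'   list members).
#' @param codelist The [odm_codelist_def()].
#' @return List with `entries`, `diversity`, `diversity_total`, `chart`
#'   (kind `"bar"`, with `labels` = coded values, `decodes`, `counts`) and
#'   `rendered`.
#' @export
stats_ordinal <- function(values, codelist) {
  stopifnot(inherits(codelist, "odm_codelist_def"))
  opts <- codelist$options
  rc <- ranked_counts(values)
  entries <- utils::head(rc, 3L)
  counts_all <- stats::setNames(integer(nrow(opts)), opts$coded_value)
  counts_all[rc$value] <- rc$count

  if (nrow(opts) <= 10L) {
    chart <- list(kind = "bar", labels = opts$coded_value,
                  decodes = opts$decode,
                  counts = as.integer(unname(counts_all)))
  } else {
    full <- data.frame(value = opts$coded_value,
                       count = as.integer(unname(counts_all)),
                       decode = opts$decode, stringsAsFactors = FALSE)
    o <- order(-full$count, rank_by_codepoint(full$value))
    full <- full[o, , drop = FALSE]
    top9 <- utils::head(full, 9L)
    chart <- list(kind = "bar",
                  labels = c(top9$value, "others"),
                  decodes = c(top9$decode, "others"),
                  counts = c(top9$count,
                             as.integer(length(values) - sum(top9$count))))
  }
  list(entries = entries, diversity = nrow(rc),
       diversity_total = nrow(opts), chart = chart,
       rendered = if (length(values) == 0L) "No data"
                  else sprintf("Diversity: %d/%d - Top3: %s", nrow(rc),
                               nrow(opts), render_top(entries)))
}

MONTHS_EN <- c("January", "February", "March", "April", "May", "June",
               "July", "August", "September", "October", "November",
               "December")

format_timepoint <- function(num, data_type) {
  # locale-independent rendering of the numeric encodings used for
  # interval statistics
  fmt_time <- function(secs) {
    secs <- round(secs)
    sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60,
            secs %% 60)
  }
  fmt_date <- function(days) {
    d <- as.POSIXlt(as.Date(days, origin = "1970-01-01"))
    sprintf("%02d %s %d", d$mday, MONTHS_EN[d$mon + 1L], d$year + 1900L)
  }
  switch(data_type,
    time = fmt_time(num),
    date = fmt_date(num),
    datetime = {
      days <- floor(num / 86400)
      sprintf("%s on %s", fmt_time(num - days * 86400), fmt_date(days))
    })
}

#' Range and histogram of an interval (timepoint) item
#'
#' Only the chronological minimum and maximum are reported — a mean of
#' calendar dates carries no insight — together with a histogram of the
#' distribution over a numeric encoding (days since epoch for dates,
#' seconds since midnight for times, seconds since epoch, normalized to
#' UTC, for datetimes).
#'
#' @param nums Numeric encodings of the valid values.
#' @param data_type `"time"`, `"date"` or `"datetime"` (drives rendering).
#' @param n_bins Number of histogram bins.
#' @return List with `min`, `max` (numeric encodings), `min_display`,
#'   `max_display`, `chart` (histogram) and `rendered` string, e.g.
#'   `"Range: 13:54:47 on 05 May 1920 - 20:11:59 on 09 June 2010"`.
#' @export
stats_interval <- function(nums, data_type, n_bins = 10L) {
  if (length(nums) == 0L)
    return(list(min = NA_real_, max = NA_real_, min_display = NA_character_,
                max_display = NA_character_, chart = NULL,
                rendered = "No data"))
  lo <- min(nums); hi <- max(nums)
  lo_d <- format_timepoint(lo, data_type)
  hi_d <- format_timepoint(hi, data_type)
  list(min = lo, max = hi, min_display = lo_d, max_display = hi_d,
       chart = make_histogram(nums, n_bins),
       rendered = sprintf("Range: %s - %s", lo_d, hi_d))
}

#' Five-number summary and histogram of a ratio (numeric) item
#'
#' All values are treated as doubles. The median is the middle order
#' statistic (odd n) or the mean of the two central ones (even n); the
#' standard deviation uses the sample (n - 1) denominator, with the n = 1
#' convention of 0.
#'
#' @param values Numeric vector of valid values.
#' @param n_bins Number of histogram bins.
#' @return List with `min`, `max`, `mean`, `median`, `stddev`, `n`,
#'   `chart` (histogram) and `rendered` string in the shape
#'   `"Min: 1.1 | Max: 8.8 | Mean: 4.9 | Median: 4.4 | StdDev: 2.6"`
#'   (one decimal in the display; full precision in the fields).
#' @export
stats_ratio <- function(values, n_bins = 10L) {
  if (length(values) == 0L)
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                median = NA_real_, stddev = NA_real_, n = 0L,
                chart = NULL, rendered = "No data"))
  values <- as.numeric(values)
  sdev <- if (length(values) == 1L) 0 else stats::sd(values)
  list(min = min(values), max = max(values), mean = mean(values),
       median = stats::median(values), stddev = sdev,
       n = length(values), chart = make_histogram(values, n_bins),
       rendered = sprintf(
         "Min: %.1f | Max: %.1f | Mean: %.1f | Median: %.1f | StdDev: %.1f",
         min(values), max(values), mean(values), stats::median(values),
         sdev))
}

#' Equal-width histogram chart data
#'
#' Bins span exactly `[min, max]`; every bin is left-closed and the
#' rightmost bin is closed on both sides, so counts always sum to the
#' number of values. A degenerate range (all values identical) yields a
#' single bin holding everything. Borders are reported as doubles even for
#' integer-valued input.
#'
#' @param values Numeric vector, length >= 1.
#' @param n_bins Number of bins (>= 1).
#' @return List with `kind = "histogram"`, `breaks` (length bins + 1,
#'   strictly increasing) and `counts`.
#' @export
make_histogram <- function(values, n_bins = 10L) {
  stopifnot(length(values) >= 1L, n_bins >= 1L)
  lo <- min(values); hi <- max(values)
  if (lo == hi)
    return(list(kind = "histogram", breaks = as.numeric(c(lo, hi)),
                counts = length(values)))
  width <- (hi - lo) / n_bins
  breaks <- as.numeric(lo + width * (0:n_bins))
  breaks[n_bins + 1L] <- hi  # guard the right edge against FP drift
  # bin membership by comparison against the emitted borders, so a value
  # sitting exactly on a border always lands in the bin to its right
  # (except the maximum, which closes the last bin)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(kind = "histogram", breaks = breaks,
       counts = as.integer(counts))
}

#' Does any subject contribute more than one instance to an element?
#'
#' @param element A positional element.
#' @param clean A cleaned `odm_clinical_dataset`.
#' @return `TRUE` iff some subject has two or more instances at this
#'   positional path (repeat keys anywhere along the path), i.e. the
#'   element's statistics mix multiple contributions of one subject.
#' @export
flag_repeat_keys <- function(element, clean) {
  lv <- level_table(element$level)
  df <- clean[[lv]]
  hit <- instance_path_keys(df, lv) == path_key(element$path)
  any(duplicated(df$subject_key[hit]))
}

#' Compute statistics for every positional element
#'
#' @param tree `odm_metadata_tree`.
#' @param clean Cleaned dataset from [validate_dataset()].
#' @param invalid Invalid-record data frame from [validate_dataset()]
#'   (drives the invalid-value warning flags); may be `NULL`.
#' @param n_bins Histogram bin count (default 10).
#' @return An object of class `odm_statistics`: list of per-element
#'   records in metadata order. Every element carries `path`, `level`,
#'   `name`, `counts` and `repeat_key_warning`; items additionally carry
#'   `category`, `summary`, `chart`, `rendered`, `n_valid` and
#'   `invalid_value_warning`. Items with unsupported data types are
#'   reported with `category = "unsupported"` and no summary.
#' @export
compute_statistics <- function(tree, clean, invalid = NULL, n_bins = 10L) {
  els <- positional_elements(tree)
  inv_paths <- character()
  if (!is.null(invalid) && nrow(invalid) > 0L) {
    oid_cols <- invalid[, c("se_oid", "form_oid", "group_oid", "item_oid")]
    inv_paths <- apply(oid_cols, 1L, function(r)
      path_key(r[!is.na(r)]))
  }

  items_df <- clean$items
  item_pkeys <- instance_path_keys(items_df, "items")

  out <- lapply(els, function(el) {
    rec <- list(path = el$path, level = el$level, oid = el$oid,
                name = el$def$name,
                counts = count_references(el, clean),
                repeat_key_warning = flag_repeat_keys(el, clean),
                invalid_value_warning = any(startsWith(
                  inv_paths, path_key(el$path))))
    if (el$level != "item") return(rec)

    rec$category <- categorize(el$def)
    rows <- items_df[item_pkeys == path_key(el$path) &
                       !is.na(items_df$value), , drop = FALSE]
    rec$n_valid <- nrow(rows)
    s <- switch(rec$category,
      dichotomous = stats_dichotomous(rows$typed_bool),
      nominal = stats_nominal(rows$value),
      ordinal = stats_ordinal(rows$value,
                              tree$defs$codelists[[el$def$codelist_oid]]),
      interval = stats_interval(rows$typed_num, el$def$data_type, n_bins),
      ratio = stats_ratio(rows$typed_num, n_bins),
      list(chart = NULL,
           rendered = sprintf("Unsupported data type '%s'",
                              el$def$data_type)))
    rec$chart <- s$chart
    rec$rendered <- s$rendered
    rec$summary <- s[setdiff(names(s), c("chart", "rendered"))]
    rec
  })
  structure(list(elements = out, n_bins = n_bins), class = "odm_statistics")
}

#' @export
print.odm_statistics <- function(x, ...) {
  items <- Filter(function(e) e$level == "item", x$elements)
  cat(sprintf("ODM statistics: %d elements, %d items\n",
              length(x$elements), length(items)))
  for (e in utils::head(items, 20)) {
    cat(sprintf("  %s [%s] refs=%d subjects=%d%s\n    %s\n",
                path_key(e$path), e$category, e$counts$reference_count,
                e$counts$subject_count,
                if (e$repeat_key_warning) " (repeat keys)" else "",
                e$rendered))
  }
  invisible(x)
}
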