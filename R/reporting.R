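#' @title Analysis orchestration and report output
#'
#' @description
#' [run_analysis()] drives the whole pipeline — parse, structural gate,
#' semantic validation, then the enabled analyses — and returns a single
#' report object. Sections are present iff the corresponding option was
#' enabled. The report can be serialized losslessly to JSON
#' ([serialize_report()]), rendered as a paginated HTML document with one
#' section per item ([render_document()]), and the invalid-value list can
#' be exported as CSV. Structural failure aborts the analysis: the report
#' then carries only the error list and `status = 2`.
#'
#' @name reporting
#' @keywords internal
NULL

#' Run the full ODM analysis
#'
#' @param input ODM file path, XML string or raw vector.
#' @param statistics Compute per-element counts and item statistics.
#' @param completeness Compute completeness report(s).
#' @param completeness_mode `"mandatory"`, `"all"` or `"both"`.
#' @param n_bins Histogram bin count.
#' @return An object of class `odm_analysis_report`: `status` (0 on
#'   success, 2 on structural failure), `tool`, `study`, `odm_version`,
#'   `options`, `warnings`, `structural_errors`, and — as enabled —
#'   `statistics`, `completeness` (named list by mode), plus always (on
#'   structural success) `invalid` records and `subject` totals.
#' @export
run_analysis <- function(input, statistics = TRUE, completeness = FALSE,
                         completeness_mode = c("mandatory", "all", "both"),
                         n_bins = 10L) {
  completeness_mode <- match.arg(completeness_mode)
  parsed <- parse_odm(input)
  report <- list(
    tool = list(name = "odminsight",
                version = as.character(utils::packageVersion("odminsight"))),
    status = 0L,
    odm_version = parsed$version,
    options = list(statistics = statistics, completeness = completeness,
                   completeness_mode = completeness_mode,
                   n_bins = as.integer(n_bins)),
    warnings = as.list(parsed$warnings),
    structural_errors = parsed$structural_errors)
  if (nrow(parsed$structural_errors) > 0L) {
    report$status <- 2L
    class(report) <- "odm_analysis_report"
    return(report)
  }

  tree <- parsed$metadata
  report$study <- list(oid = tree$study_oid, name = tree$study_name)
  vd <- validate_dataset(tree, parsed$clinical)
  report$invalid <- vd$invalid
  report$subjects <- list(total = length(vd$clean$subject_keys))

  if (statistics)
    report$statistics <- compute_statistics(tree, vd$clean, vd$invalid,
                                            n_bins = n_bins)
  if (completeness) {
    modes <- switch(completeness_mode,
                    mandatory = "mandatory_flag",
                    all = "all_mandatory",
                    both = c("mandatory_flag", "all_mandatory"))
    report$completeness <- stats::setNames(
      lapply(modes, function(m) compute_completeness(tree, vd$clean, m)),
      modes)
  }
  report$clean <- vd$clean
  report$tree <- tree
  class(report) <- "odm_analysis_report"
  report
}

#' @export
print.odm_analysis_report <- function(x, ...) {
  if (x$status != 0L) {
    cat("Analysis aborted by structural validation:\n")
    print(x$structural_errors)
    return(invisible(x))
  }
  cat(sprintf("ODM analysis of study '%s' (%s), ODM %s\n", x$study$oid,
              x$study$name, x$odm_version))
  cat(sprintf("  %d subjects, %d invalid value record(s)\n",
              x$subjects$total, nrow(x$invalid)))
  if (!is.null(x$statistics)) print(x$statistics)
  for (cp in x$completeness) print(cp)
  invisible(x)
}

# --- JSON serialization ----------------------------------------------------

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v)
      jsonlite::unbox(if (is.na(v)) "" else v))
  })
}

chart_to_list <- function(chart) {
  if (is.null(chart)) return(NULL)
  out <- list(kind = jsonlite::unbox(chart$kind))
  for (f in c("labels", "decodes"))
    if (!is.null(chart[[f]])) out[[f]] <- as.character(chart[[f]])
  if (!is.null(chart$breaks)) out$breaks <- as.numeric(chart$breaks)
  out$counts <- as.integer(chart$counts)
  out
}

num_or_na <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) jsonlite::unbox("n/a")
  else jsonlite::unbox(as.numeric(x))
}

stats_to_list <- function(st) {
  list(n_bins = jsonlite::unbox(st$n_bins),
       elements = lapply(st$elements, function(e) {
    out <- list(
      path = as.character(e$path),
      level = jsonlite::unbox(e$level),
      oid = jsonlite::unbox(e$oid),
      name = jsonlite::unbox(e$name),
      reference_count = jsonlite::unbox(e$counts$reference_count),
      subject_count = jsonlite::unbox(e$counts$subject_count),
      repeat_key_warning = jsonlite::unbox(e$repeat_key_warning),
      invalid_value_warning = jsonlite::unbox(e$invalid_value_warning))
    if (!is.null(e$category)) {
      out$category <- jsonlite::unbox(e$category)
      out$n_valid <- jsonlite::unbox(e$n_valid)
      out$rendered <- jsonlite::unbox(e$rendered)
      s <- e$summary
      out$summary <- switch(e$category,
        dichotomous = list(true_count = jsonlite::unbox(s$true_count),
                           false_count = jsonlite::unbox(s$false_count)),
        nominal = list(diversity = jsonlite::unbox(s$diversity),
                       top = df_to_rows(s$entries)),
        ordinal = list(diversity = jsonlite::unbox(s$diversity),
                       diversity_total = jsonlite::unbox(s$diversity_total),
                       top = df_to_rows(s$entries)),
        interval = list(min = num_or_na(s$min), max = num_or_na(s$max),
                        min_display = jsonlite::unbox(
                          s$min_display %||% "n/a"),
                        max_display = jsonlite::unbox(
                          s$max_display %||% "n/a")),
        ratio = list(min = num_or_na(s$min), max = num_or_na(s$max),
                     mean = num_or_na(s$mean), median = num_or_na(s$median),
                     stddev = num_or_na(s$stddev),
                     n = jsonlite::unbox(s$n)),
        list())
      ch <- chart_to_list(e$chart)
      if (!is.null(ch)) out$chart <- ch
    }
    out
  }))
}

completeness_to_list <- function(cp) {
  list(mode = jsonlite::unbox(cp$mode),
       total_subjects = jsonlite::unbox(cp$total_subjects),
       completed_subjects = jsonlite::unbox(cp$completed_subjects),
       nodes = lapply(cp$nodes, function(n) list(
         path = as.character(n$path),
         level = jsonlite::unbox(n$level),
         name = jsonlite::unbox(n$name),
         mandatory = jsonlite::unbox(n$mandatory),
         expected = jsonlite::unbox(n$expected),
         completed = jsonlite::unbox(n$completed),
         percentage = num_or_na(n$percentage))))
}

report_to_list <- function(report) {
  out <- list(
    tool = lapply(report$tool, jsonlite::unbox),
    status = jsonlite::unbox(report$status),
    odm_version = jsonlite::unbox(
      if (is.na(report$odm_version)) "unknown" else report$odm_version),
    options = lapply(report$options, jsonlite::unbox),
    warnings = lapply(report$warnings, jsonlite::unbox))
  if (nrow(report$structural_errors) > 0L) {
    se <- report$structural_errors
    se$line <- ifelse(is.na(se$line), -1L, se$line)
    out$structural_errors <- df_to_rows(se)
    return(out)
  }
  out$study <- lapply(report$study, jsonlite::unbox)
  out$subjects <- lapply(report$subjects, jsonlite::unbox)
  if (!is.null(report$invalid) && nrow(report$invalid) > 0L)
    out$invalid_values <- df_to_rows(report$invalid)
  if (!is.null(report$statistics))
    out$statistics <- stats_to_list(report$statistics)
  if (!is.null(report$completeness))
    out$completeness <- lapply(report$completeness, completeness_to_list)
  out
}

#' Serialize an analysis report to JSON
#'
#' A stable, machine-readable capture of every number in the report (full
#' precision; rendered strings included). The same report always
#' serializes to the same bytes; a report with no invalid values omits
#' that section.
#'
#' @param report `odm_analysis_report` from [run_analysis()].
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
serialize_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "odm_analysis_report"))
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = FALSE,
                           digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read back a serialized report
#'
#' @param path JSON file written by [serialize_report()].
#' @return Nested list mirroring the JSON structure.
#' @export
deserialize_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# --- paginated document ----------------------------------------------------

html_escape <- function(x) xml_escape(x)

chart_svg <- function(chart, width = 420, height = 220) {
  if (is.null(chart)) return("")
  counts <- as.numeric(chart$counts)
  if (length(counts) == 0L || sum(counts) == 0) return("")
  pad <- 30; w <- width - 2 * pad; h <- height - 2 * pad
  parts <- c(sprintf(
    "<svg viewBox='0 0 %d %d' width='%d' height='%d' role='img'>",
    width, height, width, height))
  if (chart$kind == "pie") {
    cx <- width / 2; cy <- height / 2; r <- min(w, h) / 2
    ang <- 2 * pi * cumsum(c(0, counts)) / sum(counts)
    cols <- c("#4878a8", "#d08050", "#6aa868", "#a868a8", "#c8b050")
    for (i in seq_along(counts)) {
      if (counts[i] == 0) next
      a0 <- ang[i] - pi / 2; a1 <- ang[i + 1] - pi / 2
      large <- as.integer((a1 - a0) > pi)
      if (abs((a1 - a0) - 2 * pi) < 1e-9) {
        parts <- c(parts, sprintf(
          "<circle cx='%.1f' cy='%.1f' r='%.1f' fill='%s'/>", cx, cy, r,
          cols[(i - 1) %% length(cols) + 1]))
      } else {
        parts <- c(parts, sprintf(
          "<path d='M%.1f,%.1f L%.1f,%.1f A%.1f,%.1f 0 %d 1 %.1f,%.1f Z' fill='%s'/>",
          cx, cy, cx + r * cos(a0), cy + r * sin(a0), r, r, large,
          cx + r * cos(a1), cy + r * sin(a1),
          cols[(i - 1) %% length(cols) + 1]))
      }
    }
  } else {
    n <- length(counts)
    bw <- w / n
    mx <- max(counts)
    for (i in seq_len(n)) {
      bh <- if (mx > 0) h * counts[i] / mx else 0
      parts <- c(parts, sprintf(
        "<rect x='%.1f' y='%.1f' width='%.1f' height='%.1f' fill='#4878a8'/>",
        pad + (i - 1) * bw + 1, pad + h - bh, bw - 2, bh))
      lab <- if (!is.null(chart$labels)) chart$labels[i] else ""
      if (nzchar(lab))
        parts <- c(parts, sprintf(
          "<text x='%.1f' y='%d' font-size='9' text-anchor='middle'>%s</text>",
          pad + (i - 0.5) * bw, height - pad + 12,
          html_escape(substr(lab, 1, 8))))
    }
  }
  paste(c(parts, "</svg>"), collapse = "")
}

#' Render the paginated analysis document
#'
#' One section per analyzed item, in metadata order (events, then forms,
#' groups, items), each showing counts, the category summary string,
#' warning markers and the chart (inline SVG). Written as a single-file
#' HTML document; the content — not the container format — is the
#' contract, and all numbers equal those in the serialized report.
#'
#' @param report `odm_analysis_report` with a statistics section.
#' @param path Output `.html` path.
#' @return Number of item sections written, invisibly.
#' @export
render_document <- function(report, path) {
  stopifnot(inherits(report, "odm_analysis_report"))
  if (is.null(report$statistics))
    stop("render_document requires the statistics section; ",
         "run the analysis with statistics enabled")
  items <- Filter(function(e) e$level == "item",
                  report$statistics$elements)
  head_html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'>",
    sprintf("<title>ODM analysis: %s</title>",
            html_escape(report$study$name)),
    "<style>body{font-family:sans-serif;margin:2em}",
    "section{page-break-after:always;border-bottom:1px solid #ccc;",
    "padding:1em 0}.warn{color:#b00}.key{color:#a80}</style></head><body>",
    sprintf("<h1>ODM analysis of study %s (%s)</h1>",
            html_escape(report$study$oid), html_escape(report$study$name)),
    sprintf("<p>%d subjects; %d invalid value record(s).</p>",
            report$subjects$total, nrow(report$invalid)))
  sections <- vapply(items, function(e) {
    marks <- paste0(
      if (e$repeat_key_warning)
        "<span class='key'> [repeat keys]</span>" else "",
      if (e$invalid_value_warning)
        "<span class='warn'> [invalid values]</span>" else "")
    paste0(
      "<section><h2>", html_escape(path_key(e$path)), marks, "</h2>",
      sprintf("<p>%s (%s) &mdash; references: %d, subjects: %d</p>",
              html_escape(e$name), e$category,
              e$counts$reference_count, e$counts$subject_count),
      "<p><b>", html_escape(e$rendered), "</b></p>",
      chart_svg(e$chart), "</section>")
  }, "")
  writeLines(c(head_html, sections, "</body></html>"), path,
             useBytes = TRUE)
  invisible(length(items))
}

#' Render chart PNG files, one per item
#'
#' @param report `odm_analysis_report` with statistics.
#' @param dir Output directory (created if needed); files are named by the
#'   positional path.
#' @return Character vector of files written, invisibly.
#' @export
render_charts <- function(report, dir) {
  stopifnot(inherits(report, "odm_analysis_report"),
            !is.null(report$statistics))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (e in report$statistics$elements) {
    if (e$level != "item" || is.null(e$chart)) next
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                    path_key(e$path)), ".png"))
    grDevices::png(f, width = 640, height = 400)
    ch <- e$chart
    tryCatch({
      if (ch$kind == "pie") {
        graphics::pie(ch$counts, labels = sprintf("%s (%d)", ch$labels,
                                                  ch$counts),
                      main = path_key(e$path))
      } else if (ch$kind == "bar") {
        graphics::barplot(ch$counts, names.arg = ch$labels,
                          main = path_key(e$path), las = 2)
      } else {
        mids <- (utils::head(ch$breaks, -1) + utils::tail(ch$breaks, -1)) / 2
        graphics::barplot(ch$counts,
                          names.arg = sprintf("%.3g", mids),
                          main = path_key(e$path), space = 0, las = 2)
      }
    }, finally = grDevices::dev.off())
    written <- c(written, f)
  }
  invisible(written)
}
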