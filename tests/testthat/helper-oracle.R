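# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, base-R date handling, direct formulas.

oracle_bool_tally <- function(raws) {
  tc <- 0L; fc <- 0L
  for (v in raws) {
    if (v == "true" || v == "1") tc <- tc + 1L
    else if (v == "false" || v == "0") fc <- fc + 1L
    else stop("not a boolean literal: ", v)
  }
  c(true = tc, false = fc)
}

oracle_freqs <- function(values) {
  out <- list()
  for (v in values) out[[v]] <- (out[[v]] %||% 0L) + 1L
  unlist(out) %||% integer()
}

freq_of <- function(fr, v) if (v %in% names(fr)) fr[[v]] else 0L

# numeric encodings via base R, not the package's parsers
oracle_encode <- function(values, data_type) {
  switch(data_type,
    date = as.numeric(as.Date(values)),
    time = {
      p <- strsplit(values, "[:.]")
      vapply(p, function(x) as.numeric(x[1]) * 3600 +
               as.numeric(x[2]) * 60 + as.numeric(x[3]) +
               if (length(x) > 3) as.numeric(paste0("0.", x[4])) else 0, 0)
    },
    datetime = as.numeric(as.POSIXct(values, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%S")),
    as.numeric(values))
}

oracle_ratio <- function(x) {
  n <- length(x)
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  m <- sum(x) / n
  sdev <- if (n == 1) 0 else sqrt(sum((x - m)^2) / (n - 1))
  list(min = s[1], max = s[n], mean = m, median = med, stddev = sdev)
}

# O(n * bins) membership bucketing; every bin [b_i, b_{i+1}), last closed
oracle_hist_counts <- function(values, breaks) {
  nb <- length(breaks) - 1L
  counts <- integer(nb)
  for (v in values) {
    for (b in seq_len(nb)) {
      hi_ok <- if (b == nb) v <= breaks[b + 1L] else v < breaks[b + 1L]
      if (v >= breaks[b] && hi_ok) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# Check one item's computed statistics against the manifest's raw value
# multiset, using only oracle arithmetic. Returns NULL or a message.
check_item_against_oracle <- function(item_stat, vals, meta) {
  cat_ <- meta$category
  msg <- function(...) sprintf("%s: %s", paste(item_stat$path,
                                               collapse = "/"),
                               sprintf(...))
  if (!identical(item_stat$category, cat_))
    return(msg("category %s != %s", item_stat$category, cat_))
  if (item_stat$n_valid != length(vals))
    return(msg("n_valid %d != %d", item_stat$n_valid, length(vals)))
  s <- item_stat$summary
  if (cat_ == "dichotomous") {
    tal <- oracle_bool_tally(vals)
    if (s$true_count != tal["true"] || s$false_count != tal["false"])
      return(msg("bool tally mismatch"))
    if (length(vals) > 0 &&
        !identical(as.integer(item_stat$chart$counts),
                   as.integer(unname(tal))))
      return(msg("pie counts mismatch"))
  } else if (cat_ %in% c("nominal", "ordinal")) {
    fr <- oracle_freqs(vals)
    if (s$diversity != length(fr)) return(msg("diversity mismatch"))
    want_top <- sort(as.integer(fr), decreasing = TRUE)
    want_top <- want_top[seq_len(min(3, length(want_top)))]
    if (!identical(as.integer(s$entries$count), want_top))
      return(msg("top-3 counts mismatch"))
    for (i in seq_len(nrow(s$entries)))
      if (freq_of(fr, s$entries$value[i]) != s$entries$count[i])
        return(msg("top-3 entry count wrong for %s", s$entries$value[i]))
    if (cat_ == "ordinal") {
      cl <- meta$codelist
      if (s$diversity_total != nrow(cl$options))
        return(msg("diversity_total mismatch"))
      ch <- item_stat$chart
      if (sum(ch$counts) != length(vals))
        return(msg("bar conservation"))
      if (nrow(cl$options) <= 10) {
        if (!identical(ch$labels, cl$options$coded_value))
          return(msg("bar labels should be full option list"))
        for (i in seq_along(ch$labels))
          if (ch$counts[i] != freq_of(fr, ch$labels[i]))
            return(msg("bar count wrong for %s", ch$labels[i]))
      } else {
        if (length(ch$labels) != 10 || ch$labels[10] != "others")
          return(msg("expected 9 + others bars"))
        all_counts <- vapply(cl$options$coded_value,
                             function(o) freq_of(fr, o), 0L)
        top9 <- sum(sort(all_counts, decreasing = TRUE)[1:9])
        if (ch$counts[10] != length(vals) - top9)
          return(msg("others count mismatch"))
      }
    }
  } else if (cat_ == "interval") {
    enc <- oracle_encode(vals, meta$data_type)
    if (length(vals) == 0) {
      if (!is.na(s$min)) return(msg("expected no-data"))
    } else {
      if (s$min != min(enc) || s$max != max(enc))
        return(msg("interval range mismatch"))
      ch <- item_stat$chart
      if (sum(ch$counts) != length(vals))
        return(msg("histogram conservation"))
      if (!identical(as.integer(oracle_hist_counts(enc, ch$breaks)),
                     as.integer(ch$counts)))
        return(msg("histogram counts mismatch"))
    }
  } else if (cat_ == "ratio") {
    if (length(vals) == 0) {
      if (s$n != 0) return(msg("expected no-data"))
    } else {
      x <- as.numeric(vals)
      o <- oracle_ratio(x)
      for (f in c("min", "max", "mean", "median", "stddev"))
        if (abs(s[[f]] - o[[f]]) > 1e-9 * max(1, abs(o[[f]])))
          return(msg("ratio %s mismatch (%g vs %g)", f, s[[f]], o[[f]]))
      ch <- item_stat$chart
      if (sum(ch$counts) != length(vals))
        return(msg("histogram conservation"))
      if (!identical(as.integer(oracle_hist_counts(x, ch$breaks)),
                     as.integer(ch$counts)))
        return(msg("histogram counts mismatch"))
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
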