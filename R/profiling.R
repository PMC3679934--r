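#' Per-type and total error rates
#'
#' The error rate is the fraction of wrong bases among all exon bases
#' analyzed: each event contributes its length in bases (a deletion
#' contributes the number of deleted reference bases). Per-type rates sum
#' to the total by construction.
#'
#' @param errors Tibble of events classified `error` (columns `type`,
#'   `length`); events of other classes are ignored if a `class` column
#'   is present.
#' @param total_bases Total exon bases analyzed (> 0).
#' @return One-row tibble: erroneous bases and events, per-type rates,
#'   mean event lengths per type, total rate, plus percent versions
#'   rounded for report parity (`*_pct`, 2 decimals).
#' @export
compute_error_rates <- function(errors, total_bases) {
  if (total_bases <= 0) abort("total_bases must be > 0")
  errors <- only_errors(errors)
  by_type <- function(t) {
    e <- errors[errors$type == t, , drop = FALSE]
    list(bases = sum(e$length), events = nrow(e),
         mean_len = if (nrow(e)) mean(e$length) else NA_real_)
  }
  i <- by_type("ins"); d <- by_type("del"); s <- by_type("sub")
  bases <- i$bases + d$bases + s$bases
  tibble(
    total_bases = total_bases,
    erroneous_bases = bases,
    error_events = nrow(errors),
    insertion_rate = i$bases / total_bases,
    deletion_rate = d$bases / total_bases,
    substitution_rate = s$bases / total_bases,
    total_rate = bases / total_bases,
    mean_length_ins = i$mean_len,
    mean_length_del = d$mean_len,
    mean_length_sub = s$mean_len,
    mean_length_all = if (nrow(errors)) mean(errors$length) else NA_real_,
    insertion_rate_pct = round(100 * .data$insertion_rate, 2),
    deletion_rate_pct = round(100 * .data$deletion_rate, 2),
    substitution_rate_pct = round(100 * .data$substitution_rate, 2),
    total_rate_pct = round(100 * .data$total_rate, 2)
  )
}

only_errors <- function(events) {
  if ("class" %in% names(events)) {
    events[events$class == "error", , drop = FALSE]
  } else {
    events
  }
}

#' Per-read error statistics
#'
#' Fraction of reads carrying at least one error and the distribution of
#' errors per read. Both tallies are reported: error-event occurrences
#' per read and distinct event keys per read.
#'
#' @param errors Error events (with `read_id`).
#' @param reads Reads tibble of all reads analyzed.
#' @return A list: `summary` (one-row tibble) and `per_read`
#'   (errors-per-read distribution over erroneous reads).
#' @export
per_read_stats <- function(errors, reads) {
  errors <- only_errors(errors)
  n_reads <- nrow(reads)
  per_read <- errors %>%
    mutate(.key = variant_key(errors)) %>%
    group_by(.data$read_id) %>%
    summarise(
      n_errors = n(),
      n_error_keys = n_distinct(.data$.key),
      error_bases = sum(.data$length),
      .groups = "drop"
    )
  n_err_reads <- nrow(per_read)
  summary <- tibble(
    reads_analyzed = n_reads,
    reads_with_errors = n_err_reads,
    fraction_reads_with_errors = n_err_reads / n_reads,
    fraction_pct = round(100 * n_err_reads / n_reads, 1),
    mean_errors_per_erroneous_read =
      if (n_err_reads) mean(per_read$n_errors) else NA_real_,
    mean_error_bases_per_erroneous_read =
      if (n_err_reads) mean(per_read$error_bases) else NA_real_,
    mean_errors_per_read = nrow(errors) / n_reads,
    fraction_lt3_errors =
      if (n_err_reads) mean(per_read$n_errors < 3) else NA_real_
  )
  list(summary = summary, per_read = per_read)
}

#' Errors reproduced in every run
#'
#' Intersects error event keys across runs. An error is reproducible when
#' the same (amplicon, position, type, bases) key is observed in all runs
#' of the library. The associated base count sums the events' lengths over
#' all runs; the fraction is relative to all erroneous bases.
#'
#' @param errors Error events with `run_id`.
#' @param runs Runs to intersect; default all runs present (>= 2 required).
#' @return A list: `keys` (character), `n_keys`, `base_count`, `fraction`
#'   (of erroneous bases) and `fraction_events`.
#' @export
reproducible_errors <- function(errors, runs = NULL) {
  errors <- only_errors(errors)
  if (is.null(runs)) runs <- unique(errors$run_id)
  if (length(runs) < 2) abort("reproducibility needs at least 2 runs")
  keysets <- lapply(runs, function(r) unique(variant_key(errors[errors$run_id == r, ])))
  shared <- Reduce(intersect, keysets)
  key <- variant_key(errors)
  in_shared <- key %in% shared
  list(
    keys = shared,
    n_keys = length(shared),
    base_count = sum(errors$length[in_shared]),
    fraction = sum(errors$length[in_shared]) / sum(errors$length),
    fraction_events = mean(in_shared)
  )
}

#' Positional distribution of errors along reads
#'
#' Histogram of error events per sequencing cycle, overall and for
#' non-homopolymer-associated errors, optionally normalized by
#' per-cycle coverage (number of reads reaching that cycle).
#'
#' @param errors Error events with `cycle`; if annotated with
#'   `hp_length`, the non-homopolymer histogram uses `hp_length == 1`.
#' @param reads Optional reads tibble (with `length` or `orig_length`)
#'   for coverage normalization.
#' @return A list: `histogram` tibble (`position`, `n_total`, `n_non_hp`,
#'   `coverage`, `rate`) and `median_position` (of all error events;
#'   `NA` when there are none).
#' @export
positional_distribution <- function(errors, reads = NULL) {
  errors <- only_errors(errors)
  if (nrow(errors) == 0) {
    return(list(histogram = tibble(position = integer(), n_total = integer(),
                                   n_non_hp = integer(), coverage = integer(),
                                   rate = numeric()),
                median_position = NA_real_))
  }
  has_hp <- "hp_length" %in% names(errors)
  max_pos <- max(errors$cycle)
  cov <- NULL
  if (!is.null(reads)) {
    len <- if ("orig_length" %in% names(reads)) reads$orig_length else reads$length
    max_pos <- max(max_pos, len)
    cov <- vapply(seq_len(max_pos), function(p) sum(len >= p), integer(1))
  }
  hist <- tibble(position = seq_len(max_pos)) %>%
    left_join(count(errors, position = .data$cycle, name = "n_total"),
              by = "position") %>%
    mutate(n_total = if_else(is.na(.data$n_total), 0L, as.integer(.data$n_total)))
  if (has_hp) {
    hist <- hist %>%
      left_join(count(filter(errors, .data$hp_length == 1),
                      position = .data$cycle, name = "n_non_hp"),
                by = "position") %>%
      mutate(n_non_hp = if_else(is.na(.data$n_non_hp), 0L, as.integer(.data$n_non_hp)))
  } else {
    hist$n_non_hp <- NA_integer_
  }
  if (!is.null(cov)) {
    hist$coverage <- cov
    hist$rate <- hist$n_total / pmax(cov, 1L)
  } else {
    hist$coverage <- NA_integer_
    hist$rate <- NA_real_
  }
  list(histogram = hist, median_position = median(errors$cycle))
}

#' Per-run read metrics
#'
#' Reads passed, median and average read length, and bases per run, plus
#' grand means across runs.
#'
#' @param reads Reads tibble with `run_id` and `length`.
#' @return A list: `per_run` tibble and `overall` one-row tibble
#'   (`total_reads`, `total_bases`, `mean_reads_per_run`,
#'   `avg_read_length`).
#' @export
run_summary <- function(reads) {
  len <- if ("orig_length" %in% names(reads)) reads$orig_length else reads$length
  x <- mutate(reads, .len = len)
  per_run <- x %>%
    group_by(.data$run_id) %>%
    summarise(
      n_reads = n(),
      median_length = median(.data$.len),
      avg_length = mean(.data$.len),
      bases = sum(.data$.len),
      .groups = "drop"
    )
  list(per_run = per_run,
       overall = summarize_run_counts(per_run$n_reads, per_run$bases))
}

#' Run metrics from pre-aggregated counts
#'
#' Same grand means as [run_summary()] when only per-run read and base
#' totals are available (e.g. from an instrument report table).
#'
#' @param n_reads Integer vector of reads per run.
#' @param n_bases Numeric vector of bases per run (same length), or a
#'   single grand total.
#' @return One-row tibble with `total_reads`, `total_bases`,
#'   `mean_reads_per_run` and `avg_read_length`.
#' @export
summarize_run_counts <- function(n_reads, n_bases) {
  total_reads <- sum(n_reads)
  total_bases <- sum(n_bases)
  tibble(
    n_runs = length(n_reads),
    total_reads = total_reads,
    total_bases = total_bases,
    mean_reads_per_run = mean(n_reads),
    avg_read_length = total_bases / total_reads
  )
}

#' Aggregate an error profile
#'
#' One-stop aggregation of classified events into the headline error
#' statistics: rates by type, per-read statistics, cross-run
#' reproducibility (when >= 2 runs) and the positional error histogram.
#'
#' @param classified Classified events from [classify_variants()].
#' @param reads Reads tibble of the reads analyzed.
#' @param total_bases Total exon bases analyzed (e.g.
#'   `sum(clipped$reads$n_exon_bases)`).
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(classified, reads, total_bases) {
  errors <- only_errors(classified)
  rates <- compute_error_rates(errors, total_bases)
  prs <- per_read_stats(errors, reads)
  runs <- unique(reads$run_id)
  repro <- if (length(runs) >= 2 && nrow(errors) > 0) {
    reproducible_errors(errors, runs)
  } else {
    NULL
  }
  pos <- positional_distribution(errors, reads)
  structure(
    list(
      rates = rates,
      per_read = prs,
      reproducible = repro,
      positional = pos,
      class_counts = if ("class" %in% names(classified)) {
        count(classified, .data$class)
      } else {
        tibble(class = "error", n = nrow(classified))
      },
      n_runs = length(runs)
    ),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  r <- x$rates
  s <- x$per_read$summary
  cat("<error_profile>\n")
  cat(sprintf("  exon bases analyzed : %s\n", format(r$total_bases, big.mark = ",")))
  cat(sprintf("  erroneous bases     : %s (%.2f%%)\n",
              format(r$erroneous_bases, big.mark = ","), 100 * r$total_rate))
  cat(sprintf("  rates  ins/del/sub  : %.2f%% / %.2f%% / %.2f%%\n",
              100 * r$insertion_rate, 100 * r$deletion_rate,
              100 * r$substitution_rate))
  cat(sprintf("  reads with errors   : %d / %d (%.1f%%)\n",
              s$reads_with_errors, s$reads_analyzed,
              100 * s$fraction_reads_with_errors))
  if (!is.null(x$reproducible)) {
    cat(sprintf("  reproducible errors : %d keys in all %d runs (%.2f%% of erroneous bases)\n",
                x$reproducible$n_keys, x$n_runs, 100 * x$reproducible$fraction))
  }
  cat(sprintf("  median error cycle  : %s\n", x$positional$median_position))
  invisible(x)
}

#' Tidy an error profile
#'
#' @param x An `error_profile`.
#' @param ... Unused.
#' @return A tibble with one row per error type (`type`, `events`,
#'   `bases`, `rate`, `mean_length`).
#' @export
tidy.error_profile <- function(x, ...) {
  r <- x$rates
  tibble(
    type = c("ins", "del", "sub"),
    bases = c(r$insertion_rate, r$deletion_rate, r$substitution_rate) * r$total_bases,
    rate = c(r$insertion_rate, r$deletion_rate, r$substitution_rate),
    mean_length = c(r$mean_length_ins, r$mean_length_del, r$mean_length_sub)
  )
}

#' Glance at an error profile
#'
#' @param x An `error_profile`.
#' @param ... Unused.
#' @return One-row tibble of headline statistics.
#' @export
glance.error_profile <- function(x, ...) {
  tibble(
    total_bases = x$rates$total_bases,
    erroneous_bases = x$rates$erroneous_bases,
    total_rate = x$rates$total_rate,
    fraction_reads_with_errors = x$per_read$summary$fraction_reads_with_errors,
    mean_errors_per_erroneous_read = x$per_read$summary$mean_errors_per_erroneous_read,
    reproducible_fraction = if (is.null(x$reproducible)) NA_real_ else x$reproducible$fraction,
    median_error_position = x$positional$median_position
  )
}
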