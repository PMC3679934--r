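#' Quality at error positions versus their neighborhood
#'
#' For every event, collects the reported quality of the error base(s) and
#' of the `n_neighbors` read bases closest to the event (excluding the
#' event's own bases; distance ties broken upstream). Deletions have no
#' read base, so their two flanks are the nearest neighbors and the event
#' quality is the flank mean carried by the event. All means are computed
#' in error-rate space via [average_quality()].
#'
#' @param events Event tibble from [extract_variants()] (optionally
#'   annotated with `hp_length`).
#' @param reads Reads tibble with the qualities used at alignment time.
#' @param n_neighbors Neighborhood size in bases.
#' @return A list: `per_event` tibble (`q_error`, `q_neighborhood`,
#'   `truncated`), `by_run` and `overall` summaries, and — when events are
#'   annotated — `by_hp_length` quartile summaries of error-base quality.
#' @export
error_neighborhood_quality <- function(events, reads, n_neighbors = 5) {
  if (nrow(events) == 0) abort("no events supplied")
  qmap <- reads_quality_map(reads, unique(events$read_id))
  n <- nrow(events)
  q_nb <- numeric(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    q <- qmap[[events$read_id[i]]]
    if (events$type[i] == "del") {
      span_lo <- events$read_pos[i] + 1L
      span_hi <- events$read_pos[i]
    } else {
      span_lo <- events$read_pos[i]
      span_hi <- events$read_pos[i] + events$length[i] - 1L
    }
    cand <- setdiff(seq_along(q), span_lo:span_hi)
    if (span_hi < span_lo) cand <- seq_along(q) # empty own span (deletion)
    dist <- if_else(cand < span_lo, span_lo - cand, cand - span_hi)
    ord <- order(dist, cand)
    pick <- cand[ord][seq_len(min(n_neighbors, length(cand)))]
    trunc[i] <- length(cand) < n_neighbors
    q_nb[i] <- average_quality(q[pick])
  }
  per_event <- events %>%
    select(dplyr::any_of(c("read_id", "run_id", "amplicon_id", "type",
                           "hp_length"))) %>%
    mutate(q_error = events$q_event, q_neighborhood = q_nb, truncated = trunc)

  by_run <- per_event %>%
    group_by(.data$run_id) %>%
    summarise(
      n = n(),
      mean_q_error = average_quality(.data$q_error, na.rm = TRUE),
      mean_q_neighborhood = average_quality(.data$q_neighborhood),
      .groups = "drop"
    )
  overall <- tibble(
    n = nrow(per_event),
    mean_q_error = average_quality(per_event$q_error, na.rm = TRUE),
    mean_q_neighborhood = average_quality(per_event$q_neighborhood)
  )
  out <- list(per_event = per_event, by_run = by_run, overall = overall)
  if ("hp_length" %in% names(per_event)) {
    out$by_hp_length <- per_event %>%
      mutate(hp_class = hp_class(.data$hp_length, 6)) %>%
      group_by(.data$hp_class) %>%
      summarise(
        n = n(),
        q25 = stats::quantile(.data$q_error, 0.25, na.rm = TRUE),
        median = median(.data$q_error, na.rm = TRUE),
        q75 = stats::quantile(.data$q_error, 0.75, na.rm = TRUE),
        .groups = "drop"
      )
  }
  out
}

#' Per-base error labels from simulator truth records
#'
#' Expands injected substitution and insertion events to the as-sequenced
#' base positions they occupy, for calibration analysis. Deleted bases do
#' not exist on the read and carry no label.
#'
#' @param truth_events Truth tibble from [simulate_run()] (forward
#'   orientation read positions).
#' @param reads The simulated reads (for strand and length).
#' @return Tibble `read_id`, `pos` (position in the stored read) of
#'   erroneous bases.
#' @export
truth_base_labels <- function(truth_events, reads) {
  ev <- filter(truth_events, .data$type %in% c("sub", "ins"))
  if (nrow(ev) == 0) return(tibble(read_id = character(), pos = integer()))
  ev <- left_join(ev,
                  select(reads, "read_id", "strand", read_len = "length"),
                  by = "read_id")
  ev %>%
    tidyr::uncount(.data$length, .id = "offset") %>%
    mutate(
      fwd_pos = .data$read_pos + .data$offset - 1L,
      pos = if_else(.data$strand == "+", .data$fwd_pos,
                    .data$read_len - .data$fwd_pos + 1L)
    ) %>%
    select("read_id", "pos")
}

#' Estimated versus empirical quality calibration
#'
#' Bins every base by its reported (estimated) integer quality and
#' recomputes the empirical quality from the observed error frequency in
#' each bin: `Q_emp = -10 log10(errors / bases)`. Bins with zero observed
#' errors get `NA` empirical quality and are flagged. The deviation
#' (estimated - empirical) exposes miscalibration: a positive deviation
#' means the instrument overestimates its own performance.
#'
#' @param reads Reads tibble (`read_id`, `qual`).
#' @param error_positions Tibble of erroneous base positions
#'   (`read_id`, `pos`, as stored), e.g. from [truth_base_labels()].
#' @return A tibble of class `calibration_table`: `estimated_q`,
#'   `n_bases`, `n_errors`, `empirical_q`, `deviation`, `undefined`.
#' @export
calibration_curve <- function(reads, error_positions) {
  qs <- decode_quality(reads$qual)
  allq <- unlist(qs, use.names = FALSE)
  n_bases <- tabulate(allq + 1L, nbins = 42L)

  # reported q of each labeled error base
  idx <- match(error_positions$read_id, reads$read_id)
  if (any(is.na(idx))) abort("error positions refer to unknown reads")
  errq <- if (nrow(error_positions) == 0) {
    integer(0)
  } else {
    mapply(function(i, p) qs[[i]][p], idx, error_positions$pos)
  }
  n_errors <- tabulate(errq + 1L, nbins = 42L)

  out <- tibble(
    estimated_q = 0:41,
    n_bases = n_bases,
    n_errors = n_errors
  ) %>%
    filter(.data$n_bases > 0) %>%
    mutate(
      empirical_q = error_to_phred(if_else(.data$n_errors > 0,
                                           .data$n_errors / .data$n_bases,
                                           NA_real_)),
      deviation = .data$estimated_q - .data$empirical_q,
      undefined = .data$n_errors == 0
    )
  class(out) <- c("calibration_table", class(out))
  out
}

#' Mean reported quality per read position
#'
#' Error-rate-space average of reported quality at each sequencing cycle,
#' over all reads covering that cycle.
#'
#' @param reads Reads tibble.
#' @return Tibble `position`, `mean_q`, `n` (reads covering the position).
#' @export
per_position_quality <- function(reads) {
  qs <- decode_quality(reads$qual)
  lens <- lengths(qs)
  pos <- sequence(lens)
  p <- phred_to_error(unlist(qs, use.names = FALSE))
  msum <- rowsum(p, pos)
  n <- tabulate(pos)
  tibble(
    position = as.integer(rownames(msum)),
    mean_q = unname(error_to_phred(msum[, 1] / n)),
    n = n
  )
}

#' Correlation between homopolymer length and error-site quality
#'
#' Pearson product-moment correlation of (associated homopolymer length,
#' reported quality at the error) pairs with a two-sided t-test.
#'
#' @param events Events annotated with `hp_length` and carrying `q_event`.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `n`.
#' @export
quality_homopolymer_correlation <- function(events) {
  if (!all(c("hp_length", "q_event") %in% names(events))) {
    abort("events must carry hp_length (annotate_error_context) and q_event")
  }
  x <- events$hp_length
  y <- events$q_event
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance; correlation undefined")
    return(tibble(estimate = NA_real_, statistic = NA_real_,
                  p.value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, n = length(x))
}
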