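#' Scan a sequence for homopolymer runs
#'
#' A homopolymer is a maximal run of identical consecutive nucleotides.
#' Runs tile the sequence exactly: the run lengths sum to the sequence
#' length, and length-1 "runs" are single bases outside any homopolymer.
#'
#' @param sequence A single DNA string over `{A,C,G,T}`.
#' @return A tibble with columns `start` (1-based), `length` and `base`.
#' @examples
#' scan_homopolymers("AAACCT")
#' @export
scan_homopolymers <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) {
    return(tibble(start = integer(), length = integer(), base = character()))
  }
  if (grepl("[^ACGT]", sequence)) abort("sequence must be over {A,C,G,T}")
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  tibble(
    start = c(1L, head(cumsum(r$lengths), -1) + 1L),
    length = as.integer(r$lengths),
    base = r$values
  )
}

# per-base lookup: length of the homopolymer run covering each position
hp_length_per_base <- function(sequence) {
  runs <- scan_homopolymers(sequence)
  rep(runs$length, runs$length)
}

#' Background homopolymer length distribution of reference sequences
#'
#' Fraction of reference bases lying in homopolymer runs of each length
#' class. This is the null distribution against which error-associated
#' homopolymer lengths are compared: under "errors ignore context", the
#' class of a uniformly drawn error position follows these fractions.
#'
#' @param references A tibble with at least a `sequence` column (one row per
#'   reference amplicon), or a character vector of sequences.
#' @param max_class Lengths greater than `max_class` are combined into one
#'   `">max_class"` class.
#' @return A tibble with `hp_class`, `n_bases` and `fraction` (summing to 1).
#' @export
background_distribution <- function(references, max_class = 5) {
  seqs <- if (is.character(references)) references else references$sequence
  len <- unlist(lapply(seqs, hp_length_per_base))
  if (length(len) == 0) abort("no reference bases to scan")
  cls <- hp_class(len, max_class)
  tibble(hp_class = levels(cls)) %>%
    left_join(
      tibble(hp_class = as.character(cls)) %>% count(.data$hp_class, name = "n_bases"),
      by = "hp_class"
    ) %>%
    mutate(
      n_bases = if_else(is.na(.data$n_bases), 0L, as.integer(.data$n_bases)),
      fraction = .data$n_bases / sum(.data$n_bases)
    )
}

hp_class <- function(length, max_class = 5) {
  lev <- c(as.character(seq_len(max_class)), paste0(">", max_class))
  factor(if_else(length > max_class, paste0(">", max_class), as.character(length)),
         levels = lev)
}

#' Annotate variant events with their homopolymer context
#'
#' Each event is assigned the length of the longest homopolymer run
#' overlapping its reference footprint extended by `window` bases on both
#' sides ("adjacent" context). Events overlapping only single bases get
#' length 1, i.e. no homopolymer association.
#'
#' @param events A variant event tibble (see [extract_variants()]) with
#'   `amplicon_id`, `ref_pos`, `type` and `length` columns.
#' @param references Reference tibble with `amplicon_id` and `sequence`.
#' @param window Adjacency window in bases (default 1).
#' @return `events` with an added integer `hp_length` column.
#' @export
annotate_error_context <- function(events, references, window = 1) {
  lookup <- setNames(
    lapply(references$sequence, hp_length_per_base),
    references$amplicon_id
  )
  n <- nrow(events)
  hp <- integer(n)
  # reference footprint: subs/dels cover `length` bases, insertions sit
  # between anchor and anchor+1 so both flanks are in the window
  ref_len <- if_else(events$type == "ins", 1L, as.integer(events$length))
  lo <- events$ref_pos - window
  hi <- events$ref_pos + ref_len - 1L + window + if_else(events$type == "ins", 1L, 0L)
  for (i in seq_len(n)) {
    v <- lookup[[events$amplicon_id[i]]]
    if (is.null(v)) abort(paste0("unknown amplicon: ", events$amplicon_id[i]))
    idx <- max(1L, lo[i]):min(length(v), hi[i])
    hp[i] <- max(v[idx])
  }
  mutate(events, hp_length = hp)
}

#' Distribution of error events across homopolymer length classes
#'
#' @param events Events annotated by [annotate_error_context()].
#' @param max_class Combine lengths above this into one class.
#' @return Tibble with `hp_class`, `n` and `fraction`.
#' @export
error_context_distribution <- function(events, max_class = 5) {
  if (!"hp_length" %in% names(events)) {
    abort("events must be annotated with annotate_error_context() first")
  }
  cls <- hp_class(events$hp_length, max_class)
  tibble(hp_class = levels(cls)) %>%
    left_join(
      tibble(hp_class = as.character(cls)) %>% count(.data$hp_class),
      by = "hp_class"
    ) %>%
    mutate(
      n = if_else(is.na(.data$n), 0L, as.integer(.data$n)),
      fraction = .data$n / sum(.data$n)
    )
}

#' Chi-square test of error association with homopolymer context
#'
#' Goodness-of-fit test of observed error counts per homopolymer length
#' class against expected counts from the background (reference) class
#' fractions. Classes with expected count below `min_expected` are pooled
#' into their lower neighbor, from the longest class downward, before the
#' test (the usual validity rule for the chi-square approximation).
#'
#' @param observed Integer vector of error counts per class, ordered by
#'   class, or the tibble returned by [error_context_distribution()].
#' @param background Numeric vector of background fractions (same order,
#'   summing to 1), or the tibble from [background_distribution()].
#' @param min_expected Pooling threshold for expected counts.
#' @return One-row tibble with `statistic`, `df`, `p.value` and `n_classes`
#'   (after pooling).
#' @export
association_test <- function(observed, background, min_expected = 5) {
  if (is.data.frame(observed)) observed <- observed$n
  if (is.data.frame(background)) background <- background$fraction
  stopifnot(length(observed) == length(background))
  total <- sum(observed)
  if (total < 1) abort("association_test needs at least one observed error")
  if (abs(sum(background) - 1) > 1e-8) abort("background fractions must sum to 1")

  obs <- as.numeric(observed)
  p <- as.numeric(background)
  # pool sparse classes from the top down
  while (length(obs) > 1 && min(p * total) < min_expected) {
    i <- max(which(p * total < min_expected))
    j <- if (i == length(obs)) i - 1L else i + 1L
    obs[j] <- obs[j] + obs[i]
    p[j] <- p[j] + p[i]
    obs <- obs[-i]
    p <- p[-i]
  }
  stat <- sum((obs - p * total)^2 / (p * total))
  df <- length(obs) - 1
  if (df < 1) abort("all classes pooled; cannot test association")
  tibble(
    statistic = stat,
    df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    n_classes = length(obs)
  )
}
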