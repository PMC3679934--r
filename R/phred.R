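#' Convert between phred quality scores and error probabilities
#'
#' Phred scores encode per-base error probabilities on a log scale,
#' `Q = -10 * log10(p)`. `phred_to_error()` and `error_to_phred()` are exact
#' inverses; `phred_accuracy()` returns the base-call accuracy `1 - p` as a
#' percentage.
#'
#' @param q Numeric vector of phred scores (>= 0).
#' @param p Numeric vector of error probabilities in (0, 1].
#' @return Numeric vector: error probabilities, phred scores, or accuracies
#'   in percent.
#' @examples
#' phred_to_error(10)      # 0.1
#' error_to_phred(0.001)   # 30
#' phred_accuracy(16.08)   # 97.53...
#' @export
phred_to_error <- function(q) {
  if (any(q < 0, na.rm = TRUE)) abort("phred scores must be >= 0")
  10^(-q / 10)
}

#' @rdname phred_to_error
#' @export
error_to_phred <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("error probabilities must lie in (0, 1]")
  }
  -10 * log10(p)
}

#' @rdname phred_to_error
#' @export
phred_accuracy <- function(q) {
  100 * (1 - phred_to_error(q))
}

#' Average phred scores in error-rate space
#'
#' Quality scores are averaged by translating them to error rates, averaging
#' the rates, and translating the mean back to a phred score. This is the
#' correct aggregation for log-scaled qualities: a direct arithmetic mean of
#' Q values systematically overstates the joint accuracy.
#'
#' @param q Numeric vector of phred scores; must be nonempty.
#' @param na.rm Drop missing values first.
#' @return A single phred score, always within `[min(q), max(q)]`.
#' @examples
#' average_quality(c(20, 20))  # 20
#' average_quality(c(10, 30))  # 12.97
#' @export
average_quality <- function(q, na.rm = FALSE) {
  if (na.rm) q <- q[!is.na(q)]
  if (length(q) == 0) abort("cannot average an empty quality vector")
  error_to_phred(mean(phred_to_error(q)))
}

# phred+33 string <-> integer vector helpers (Sanger FASTQ encoding)
decode_quality <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

encode_quality <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1))
}
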