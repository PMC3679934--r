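#' Extract variant events from exon-clipped alignments
#'
#' Merges each maximal run of same-type discrepant alignment columns into
#' one variant event: reference-adjacent mismatches become a multi-base
#' substitution, adjacent gap columns a multi-base insertion or deletion.
#' Mixed-type adjacent discrepancies stay separate events, preserving
#' per-type rate accounting. Events carry the phred scores of the read
#' bases involved; a deletion, which has no read base, carries the
#' error-rate-space mean of its two flanking read bases.
#'
#' @param alignments A (preferably exon-clipped) [align_reads()] result.
#' @param reads Reads tibble supplying the per-base qualities the
#'   alignment was computed from (forward orientation, e.g. from
#'   [trim_primers()]).
#' @return A tibble of events: `amplicon_id`, `run_id`, `read_id`,
#'   `strand`, `ref_pos` (event start; insertions anchored at the base to
#'   their left), `read_pos` (first involved read base; deletions: left
#'   flank), `cycle` (sequencing cycle of `read_pos`), `type`
#'   (`ins`/`del`/`sub`), `length`, `ref`, `alt`, `q_event` and `q_bases`.
#' @export
extract_variants <- function(alignments, reads) {
  stopifnot(inherits(alignments, "read_alignments"))
  disc <- alignments$discrepancies
  if (nrow(disc) == 0) {
    return(empty_variant_events())
  }

  merged <- disc %>%
    arrange(.data$read_id, .data$ref_pos, .data$read_pos) %>%
    group_by(.data$read_id) %>%
    mutate(
      new_event = row_number() == 1 |
        .data$type != lag(.data$type) |
        case_when(
          .data$type == "sub" ~ .data$ref_pos != lag(.data$ref_pos) + lag(.data$length) |
            .data$read_pos != lag(.data$read_pos) + lag(.data$length),
          .data$type == "del" ~ .data$ref_pos != lag(.data$ref_pos) + lag(.data$length),
          .data$type == "ins" ~ .data$ref_pos != lag(.data$ref_pos)
        )
    ) %>%
    mutate(event_id = cumsum(if_else(is.na(.data$new_event), TRUE, .data$new_event))) %>%
    group_by(.data$read_id, .data$event_id) %>%
    summarise(
      amplicon_id = first(.data$amplicon_id),
      run_id = first(.data$run_id),
      strand = first(.data$strand),
      type = first(.data$type),
      ref_pos = first(.data$ref_pos),
      read_pos = first(.data$read_pos),
      length = sum(.data$length),
      ref = paste(.data$ref, collapse = ""),
      alt = paste(.data$alt, collapse = ""),
      .groups = "drop"
    ) %>%
    select(-"event_id")

  # site qualities from the reads
  qmap <- reads_quality_map(reads, unique(merged$read_id))
  qe <- numeric(nrow(merged))
  qb <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    q <- qmap[[merged$read_id[i]]]
    if (is.null(q)) {
      qe[i] <- NA_real_
      qb[[i]] <- numeric(0)
      next
    }
    if (merged$type[i] == "del") {
      idx <- c(merged$read_pos[i], merged$read_pos[i] + 1L)
    } else {
      idx <- merged$read_pos[i]:(merged$read_pos[i] + merged$length[i] - 1L)
    }
    idx <- idx[idx >= 1 & idx <= length(q)]
    qb[[i]] <- q[idx]
    qe[i] <- if (length(idx)) average_quality(q[idx]) else NA_real_
  }
  merged$q_event <- qe
  merged$q_bases <- qb

  # sequencing cycle of the event (read_pos is in trimmed forward
  # orientation; minus-strand reads run backwards through the template)
  meta <- alignments$reads
  has_cycle_info <- all(c("orig_length", "lead_trim") %in% names(meta))
  merged <- left_join(
    merged,
    select(meta, "read_id",
           dplyr::any_of(c("orig_length", "lead_trim", "read_length"))),
    by = "read_id"
  )
  if (has_cycle_info) {
    merged <- mutate(
      merged,
      cycle = if_else(.data$strand == "+",
                      .data$lead_trim + .data$read_pos,
                      .data$orig_length - (.data$lead_trim + .data$read_pos) + 1L)
    )
  } else {
    merged <- mutate(
      merged,
      cycle = if_else(.data$strand == "+", .data$read_pos,
                      .data$read_length - .data$read_pos + 1L)
    )
  }
  merged %>%
    select("amplicon_id", "run_id", "read_id", "strand", "ref_pos",
           "read_pos", "cycle", "type", "length", "ref", "alt",
           "q_event", "q_bases")
}

empty_variant_events <- function() {
  tibble(
    amplicon_id = character(), run_id = character(), read_id = character(),
    strand = character(), ref_pos = integer(), read_pos = integer(),
    cycle = integer(), type = character(), length = integer(),
    ref = character(), alt = character(), q_event = numeric(),
    q_bases = list()
  )
}

# forward-orientation per-base qualities for the given read ids
reads_quality_map <- function(reads, ids) {
  sel <- reads[reads$read_id %in% ids, , drop = FALSE]
  q <- decode_quality(sel$qual)
  setNames(q, sel$read_id)
}

#' Event identity key
#'
#' The key under which events are compared across reads, runs and against
#' the truth set: amplicon, left-aligned reference position, type, and
#' the substituted/inserted bases (deletions: the deletion length).
#'
#' @param events An event tibble.
#' @return Character vector of keys.
#' @export
variant_key <- function(events) {
  paste(events$amplicon_id, events$ref_pos, events$type,
        if_else(events$type == "del", as.character(events$length), events$alt),
        sep = "|")
}

truth_key <- function(truth) {
  len <- if ("length" %in% names(truth)) truth$length else rep(1L, nrow(truth))
  paste(truth$amplicon_id, truth$ref_pos, truth$type,
        if_else(truth$type == "del", as.character(len), truth$alt),
        sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a truth set
#'
#' @param variants Tibble of expected allelic variants
#'   (`amplicon_id`, `ref_pos`, `type`, `ref`, `alt`).
#' @param pseudogene Tibble of pseudogene difference keys, same columns.
#' @return A `truth_set` list.
#' @export
truth_set <- function(variants, pseudogene = NULL) {
  empty <- tibble(amplicon_id = character(), ref_pos = integer(),
                  type = character(), ref = character(), alt = character())
  structure(
    list(variants = as_tibble(variants %||% empty),
         pseudogene = as_tibble(pseudogene %||% empty)),
    class = "truth_set"
  )
}

#' Partition variant events into true variants, pseudogene products and errors
#'
#' An event whose identity key matches an expected variant is a
#' `true_variant`; one matching a known pseudogene difference is a
#' `pseudogene_product` (side-products of co-amplified homologous loci are
#' not sequencing errors); everything else is an `error`. The partition is
#' a total function of the event key, so identical keys always receive the
#' same class, and it is idempotent and order-independent.
#'
#' @param events Event tibble from [extract_variants()].
#' @param truth A `truth_set`.
#' @param amplicons Optional character vector of known amplicons; events
#'   for amplicons outside it raise an error.
#' @return `events` with a `class` column.
#' @export
classify_variants <- function(events, truth, amplicons = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!is.null(amplicons) && !all(events$amplicon_id %in% amplicons)) {
    bad <- setdiff(unique(events$amplicon_id), amplicons)
    abort(paste0("events for unknown amplicon(s): ", paste(bad, collapse = ", ")))
  }
  key <- variant_key(events)
  vkeys <- truth_key(truth$variants)
  pkeys <- truth_key(truth$pseudogene)
  mutate(events, class = case_when(
    key %in% vkeys ~ "true_variant",
    key %in% pkeys ~ "pseudogene_product",
    TRUE ~ "error"
  ))
}

#' Bidirectional strand support of variant keys
#'
#' For each distinct event key, checks whether it was observed on at
#' least one forward and one reverse read.
#'
#' @param events Event tibble with `strand`.
#' @return A list with `per_key` (tibble: key, counts per strand,
#'   `bidirectional`), `n_keys`, `n_bidirectional` and `fraction`.
#' @export
bidirectional_support <- function(events) {
  if (nrow(events) == 0) {
    return(list(per_key = tibble(key = character(), n_fwd = integer(),
                                 n_rev = integer(), bidirectional = logical()),
                n_keys = 0L, n_bidirectional = 0L, fraction = NA_real_))
  }
  per_key <- events %>%
    mutate(key = variant_key(events)) %>%
    group_by(.data$key) %>%
    summarise(
      n_fwd = sum(.data$strand == "+"),
      n_rev = sum(.data$strand == "-"),
      .groups = "drop"
    ) %>%
    mutate(bidirectional = .data$n_fwd > 0 & .data$n_rev > 0)
  list(
    per_key = per_key,
    n_keys = nrow(per_key),
    n_bidirectional = sum(per_key$bidirectional),
    fraction = mean(per_key$bidirectional)
  )
}
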