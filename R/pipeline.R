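#' Configure an end-to-end profiling pipeline
#'
#' Exactly one of `simulation` (a [sim_config()]) or `paths` (a named list
#' with `references`, `annotation`, `fastq`, `run_ids`, `truth`) must be
#' supplied.
#'
#' @param simulation Optional [sim_config()] for a fully synthetic run.
#' @param paths Optional named list of input file paths.
#' @param scoring Alignment scoring, see [align_scoring()].
#' @param max_primer_mismatch Mismatches tolerated when trimming primers.
#' @param hp_window Homopolymer adjacency window (bases).
#' @param hp_max_class Homopolymer length class cap for context tables.
#' @param n_neighbors Neighborhood size for error-site quality.
#' @param correction Correction hook mode, see [correction_hook()].
#' @param correction_fraction Fraction for `drop_erroneous_fraction` mode.
#' @param seed Seed recorded in outputs; defaults to the simulation seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            scoring = align_scoring(),
                            max_primer_mismatch = 1,
                            hp_window = 1, hp_max_class = 5,
                            n_neighbors = 5,
                            correction = c("none", "drop_erroneous_fraction",
                                           "external_ids"),
                            correction_fraction = 0,
                            seed = NULL) {
  if (is.null(simulation) == is.null(paths)) {
    abort("exactly one of `simulation` or `paths` must be given")
  }
  if (!is.null(paths)) {
    need <- c("references", "annotation", "fastq")
    if (!all(need %in% names(paths))) {
      abort(paste0("paths must name: ", paste(need, collapse = ", ")))
    }
    missing <- unlist(paths[need])
    missing <- missing[!file.exists(missing)]
    if (length(missing)) {
      abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
    }
  }
  if (is.null(seed)) seed <- if (!is.null(simulation)) simulation$seed else 1L
  structure(
    list(simulation = simulation, paths = paths, scoring = scoring,
         max_primer_mismatch = max_primer_mismatch,
         hp_window = hp_window, hp_max_class = hp_max_class,
         n_neighbors = n_neighbors,
         correction = match.arg(correction),
         correction_fraction = correction_fraction,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full error-profiling pipeline
#'
#' Simulates or loads reads, trims primers, aligns semi-globally, clips to
#' exons, extracts and classifies variant events, and aggregates the error
#' profile, homopolymer context and quality analytics. With a fixed seed
#' and config the result is deterministic.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for TSV report tables and a
#'   JSON summary.
#' @return A list of class `pipeline_result` with every intermediate and
#'   final product (see elements `profile`, `context`, `quality`,
#'   `summary`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    references <- sim$panel$references
    reads <- sim$reads
    truth <- sim$truth_set
  } else {
    sim <- NULL
    references <- read_references(config$paths$references, config$paths$annotation)
    reads <- read_reads(config$paths$fastq, config$paths$run_ids)
    truth <- if (!is.null(config$paths$truth)) {
      read_truth_set(config$paths$truth)
    } else {
      truth_set(NULL)
    }
    bad <- setdiff(unique(reads$amplicon_id), references$amplicon_id)
    if (length(bad)) {
      abort(paste0("reads reference unknown amplicon(s): ",
                   paste(bad, collapse = ", ")))
    }
  }

  trimmed <- trim_primers(reads, references, config$max_primer_mismatch)
  aln <- align_reads(trimmed, references, config$scoring)
  clipped <- clip_to_exon(aln, references)
  analyzed_ids <- clipped$reads$read_id
  analyzed <- filter(trimmed, .data$read_id %in% analyzed_ids)
  total_bases <- sum(clipped$reads$n_exon_bases)

  events <- extract_variants(clipped, trimmed)
  classified <- classify_variants(events, truth,
                                  amplicons = references$amplicon_id)
  classified <- annotate_error_context(classified, references,
                                       window = config$hp_window)
  errors <- filter(classified, .data$class == "error")

  profile <- error_profile(classified, analyzed, total_bases)
  background <- background_distribution(references, config$hp_max_class)
  err_ctx <- error_context_distribution(errors, config$hp_max_class)
  assoc <- if (nrow(errors) > 0) association_test(err_ctx, background) else NULL
  nbq <- if (nrow(errors) > 0) {
    error_neighborhood_quality(errors, trimmed, config$n_neighbors)
  } else {
    NULL
  }
  hp_cor <- if (nrow(errors) >= 3 && n_distinct(errors$hp_length) > 1) {
    quality_homopolymer_correlation(errors)
  } else {
    NULL
  }
  ppq <- per_position_quality(reads)
  calib <- if (!is.null(sim)) {
    calibration_curve(reads, truth_base_labels(sim$truth_events, reads))
  } else {
    NULL
  }
  bidir <- bidirectional_support(classified)
  correction <- correction_hook(analyzed, classified, config$correction,
                                fraction = config$correction_fraction)
  rsum <- run_summary(reads)
  retention <- exon_retention(clipped, reads)

  summary <- build_summary(config, profile, assoc, hp_cor, bidir, retention,
                           rsum, correction)

  result <- structure(
    list(
      config = config, sim = sim, references = references,
      reads = reads, trimmed = trimmed, alignments = clipped,
      events = classified, profile = profile,
      context = list(background = background, errors = err_ctx,
                     association = assoc, correlation = hp_cor),
      quality = list(neighborhood = nbq, per_position = ppq,
                     calibration = calib),
      bidirectional = bidir, correction = correction,
      run_summary = rsum, retention = retention, summary = summary
    ),
    class = "pipeline_result"
  )
  if (!is.null(outdir)) write_reports(result, outdir)
  result
}

build_summary <- function(config, profile, assoc, hp_cor, bidir, retention,
                          rsum, correction) {
  g <- glance(profile)
  list(
    seed = config$seed,
    total_exon_bases = g$total_bases,
    erroneous_bases = g$erroneous_bases,
    total_error_rate_pct = round(100 * g$total_rate, 2),
    insertion_rate_pct = profile$rates$insertion_rate_pct,
    deletion_rate_pct = profile$rates$deletion_rate_pct,
    substitution_rate_pct = profile$rates$substitution_rate_pct,
    reads_analyzed = profile$per_read$summary$reads_analyzed,
    reads_with_errors_pct = profile$per_read$summary$fraction_pct,
    mean_errors_per_erroneous_read = g$mean_errors_per_erroneous_read,
    reproducible_error_fraction_pct =
      if (is.na(g$reproducible_fraction)) NA else round(100 * g$reproducible_fraction, 2),
    median_error_position = g$median_error_position,
    exon_retention_pct = round(100 * retention$retention, 1),
    avg_read_length = rsum$overall$avg_read_length,
    mean_reads_per_run = rsum$overall$mean_reads_per_run,
    association_p = if (is.null(assoc)) NA else assoc$p.value,
    hp_quality_correlation = if (is.null(hp_cor)) NA else hp_cor$estimate,
    bidirectional_fraction = bidir$fraction,
    correction_mode = config$correction,
    recovered_reads_pct = correction$recovered_pct
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$profile)
  invisible(x)
}

write_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
  }
  w(select(result$events, -"q_bases"), "classified_events")
  w(result$profile$rates, "error_rates")
  w(result$profile$per_read$summary, "per_read_stats")
  w(result$profile$positional$histogram, "positional_errors")
  w(result$run_summary$per_run, "run_summary")
  w(result$context$background, "hp_background")
  w(result$context$errors, "hp_error_context")
  if (!is.null(result$quality$neighborhood)) {
    w(result$quality$neighborhood$by_run, "neighborhood_quality")
  }
  w(result$quality$per_position, "per_position_quality")
  if (!is.null(result$quality$calibration)) {
    w(result$quality$calibration, "calibration")
  }
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Error-correction hook
#'
#' Isolates an (external) read error-corrector behind a simple contract:
#' reads in, filtered/corrected read set out, with before/after erroneous
#' read fractions and the recovered-read percentage. `none` passes reads
#' through; `drop_erroneous_fraction` removes the given fraction of
#' erroneous reads (a stand-in for a corrector of that efficacy);
#' `external_ids` keeps the supplied read ids.
#'
#' @param reads Reads analyzed.
#' @param classified Classified events for those reads.
#' @param mode One of `none`, `drop_erroneous_fraction`, `external_ids`.
#' @param fraction For `drop_erroneous_fraction`.
#' @param keep_ids For `external_ids`: read ids retained by the corrector.
#' @return One-row tibble of class `correction_delta`:
#'   `before_pct`, `after_pct`, `recovered_pct`, read counts; the retained
#'   reads are attached as `attr(, "reads")`.
#' @export
correction_hook <- function(reads, classified,
                            mode = c("none", "drop_erroneous_fraction",
                                     "external_ids"),
                            fraction = 0, keep_ids = NULL) {
  mode <- match.arg(mode)
  errors <- only_errors(classified)
  err_reads <- unique(errors$read_id)
  before <- length(err_reads) / nrow(reads)

  kept <- switch(mode,
    none = reads,
    drop_erroneous_fraction = {
      if (fraction < 0 || fraction > 1) abort("fraction must be in [0,1]")
      drop <- err_reads[seq_len(floor(fraction * length(err_reads)))]
      filter(reads, !.data$read_id %in% drop)
    },
    external_ids = {
      if (is.null(keep_ids)) abort("external_ids mode needs keep_ids")
      unknown <- setdiff(keep_ids, reads$read_id)
      if (length(unknown)) {
        abort(paste0("unknown read ids in correction set: ",
                     paste(head(unknown, 3), collapse = ", ")))
      }
      filter(reads, .data$read_id %in% keep_ids)
    }
  )
  after <- sum(kept$read_id %in% err_reads) / nrow(reads)
  out <- tibble(
    mode = mode,
    reads_before = nrow(reads),
    reads_after = nrow(kept),
    before_pct = round(100 * before, 1),
    after_pct = round(100 * after, 1),
    recovered_pct = round(100 * before, 1) - round(100 * after, 1)
  )
  attr(out, "reads") <- kept
  class(out) <- c("correction_delta", class(out))
  out
}
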