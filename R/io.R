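#' Write a simulated dataset to standard files
#'
#' Writes references as FASTA plus an amplicon annotation TSV, reads as one
#' Sanger-encoded (phred+33) FASTQ per run, truth records as TSV, and the
#' configuration as JSON.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- sim$panel$references

  fasta <- file.path(dir, "references.fasta")
  dna <- Biostrings::DNAStringSet(setNames(refs$sequence, refs$amplicon_id))
  Biostrings::writeXStringSet(dna, fasta)

  anno <- file.path(dir, "amplicons.tsv")
  readr::write_tsv(
    select(refs, "amplicon_id", "locus", "exon_start", "exon_end",
           "primer_f", "primer_r"),
    anno
  )

  fastqs <- character(0)
  for (run in unique(sim$reads$run_id)) {
    rr <- filter(sim$reads, .data$run_id == run)
    path <- file.path(dir, paste0(run, ".fastq"))
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(rr$seq, rr$read_id)),
      Biostrings::PhredQuality(rr$qual)
    )
    # writeXStringSet warns about dropping the metadata columns that
    # QualityScaledDNAStringSet carries internally; nothing is lost
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(qs, path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    fastqs <- c(fastqs, path)
  }

  truth <- file.path(dir, "truth_events.tsv")
  readr::write_tsv(
    sim$truth_events %>%
      select(read_id = "read_id", amplicon_id = "amplicon_id",
             run_id = "run_id", event_pos = "ref_pos",
             event_type = "type", event_len = "length",
             ref = "ref", bases = "alt", read_pos = "read_pos"),
    truth
  )

  truth_set <- file.path(dir, "truth_set.tsv")
  readr::write_tsv(
    bind_rows(
      mutate(sim$truth_set$variants, class = "true_variant"),
      mutate(sim$truth_set$pseudogene, class = "pseudogene_product")
    ),
    truth_set
  )

  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cfg, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(fasta = fasta, amplicons = anno, fastq = fastqs,
                 truth = truth, truth_set = truth_set, config = cfg))
}

#' Read reference amplicons from FASTA plus annotation TSV
#'
#' The annotation TSV must carry `amplicon_id`, `locus`, `exon_start`,
#' `exon_end` (1-based closed on the reference), `primer_f` and `primer_r`.
#'
#' @param fasta Path to the reference FASTA.
#' @param annotation Path to the amplicon annotation TSV.
#' @return A references tibble as produced by [generate_references()].
#' @export
read_references <- function(fasta, annotation) {
  dna <- Biostrings::readDNAStringSet(fasta)
  anno <- readr::read_tsv(annotation, show_col_types = FALSE)
  need <- c("amplicon_id", "locus", "exon_start", "exon_end", "primer_f", "primer_r")
  if (!all(need %in% names(anno))) {
    abort(paste0("annotation must have columns: ", paste(need, collapse = ", ")))
  }
  seqs <- tibble(amplicon_id = names(dna),
                 sequence = unname(as.character(dna)))
  out <- left_join(as_tibble(anno), seqs, by = "amplicon_id")
  if (any(is.na(out$sequence))) abort("annotation refers to amplicons missing from FASTA")
  if (any(out$exon_end > nchar(out$sequence)) || any(out$exon_start < 1)) {
    abort("exon interval outside reference bounds")
  }
  out
}

#' Read quality-scored reads from FASTQ files
#'
#' @param files FASTQ paths (Sanger phred+33), one per run.
#' @param run_ids Run tag per file; defaults to the file base name.
#' @param amplicon_ids Optional amplicon tag per read; by default parsed
#'   from headers of the form `runid:ampliconid:index/strand`.
#' @return A reads tibble (`read_id`, `run_id`, `amplicon_id`, `seq`,
#'   `qual`, `length`).
#' @export
read_reads <- function(files, run_ids = NULL, amplicon_ids = NULL) {
  if (is.null(run_ids)) run_ids <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(files))
  stopifnot(length(run_ids) == length(files))
  out <- purrr::map2(files, run_ids, function(f, run) {
    # the reader warns when dropping the metadata columns FASTQ cannot
    # carry; harmless here
    qs <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(f),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    tibble(
      read_id = names(qs),
      run_id = run,
      seq = unname(as.character(qs)),
      qual = unname(as.character(Biostrings::quality(qs))),
      length = Biostrings::width(qs)
    )
  })
  out <- bind_rows(out)
  if (is.null(amplicon_ids)) {
    out$amplicon_id <- stringr::str_split_i(out$read_id, ":", 2)
  } else {
    out$amplicon_id <- amplicon_ids
  }
  select(out, "read_id", "run_id", "amplicon_id", "seq", "qual", "length")
}

#' Read a truth set from TSV
#'
#' Expects columns `amplicon_id`, `ref_pos`, `type`, `ref`, `alt` and
#' `class` (`true_variant` or `pseudogene_product`).
#'
#' @param path TSV path.
#' @return A `truth_set` list.
#' @export
read_truth_set <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  structure(
    list(
      variants = filter(x, .data$class == "true_variant") %>% select(-"class"),
      pseudogene = filter(x, .data$class == "pseudogene_product") %>% select(-"class")
    ),
    class = "truth_set"
  )
}

#' Export alignments as SAM
#'
#' Minimal single-end SAM with standard CIGAR (`M`/`I`/`D`), one `@SQ`
#' line per reference. Reverse-strand reads carry flag 16 and are stored,
#' as SAM requires, in reference-forward orientation.
#'
#' @param alignments A [align_reads()] result.
#' @param reads The reads tibble the alignments were computed from.
#' @param references References tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_sam <- function(alignments, reads, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_len(nrow(references))) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", references$amplicon_id[i],
                       nchar(references$sequence[i])), con)
  }
  per_read <- alignments$reads
  disc <- alignments$discrepancies
  rd <- left_join(per_read, select(reads, "read_id", "seq", "qual"), by = "read_id")
  for (i in seq_len(nrow(rd))) {
    r <- rd[i, ]
    if (!r$aligned) {
      writeLines(paste(r$read_id, 4, "*", 0, 0, "*", "*", 0, 0, r$seq, r$qual,
                       sep = "\t"), con)
      next
    }
    d <- filter(disc, .data$read_id == r$read_id)
    cig <- build_cigar(r$ref_start, r$ref_end, d)
    flag <- if (r$strand == "-") 16L else 0L
    writeLines(paste(r$read_id, flag, r$amplicon_id, r$ref_start, 60, cig,
                     "*", 0, 0, r$seq, r$qual, sep = "\t"), con)
  }
  invisible(path)
}

# CIGAR from the discrepancy table: mismatches are M, so only indels break
# the match blocks
build_cigar <- function(ref_start, ref_end, disc) {
  d <- filter(disc, .data$type != "sub") %>% arrange(.data$ref_pos, .data$type)
  ops <- character(0)
  cur <- ref_start
  for (i in seq_len(nrow(d))) {
    if (d$type[i] == "ins") {
      m <- d$ref_pos[i] - cur + 1L # anchor base is consumed as M first
      if (m > 0) ops <- c(ops, paste0(m, "M"))
      ops <- c(ops, paste0(d$length[i], "I"))
      cur <- d$ref_pos[i] + 1L
    } else {
      m <- d$ref_pos[i] - cur
      if (m > 0) ops <- c(ops, paste0(m, "M"))
      ops <- c(ops, paste0(d$length[i], "D"))
      cur <- d$ref_pos[i] + d$length[i]
    }
  }
  if (ref_end >= cur) ops <- c(ops, paste0(ref_end - cur + 1L, "M"))
  paste(ops, collapse = "")
}

#' Export classified variant events as TSV or minimal VCF-like records
#'
#' The VCF flavor uses `CHROM` = amplicon id, 1-based `POS` (indels
#' anchored at the base preceding the event, VCF style), and an `INFO`
#' field carrying class, run, strand and type.
#'
#' @param events Classified events from [classify_variants()].
#' @param references References tibble (for anchor bases).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_variants_vcf <- function(events, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"variant class\">",
               "##INFO=<ID=RUN,Number=1,Type=String,Description=\"run id\">",
               "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"read strand\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  seqs <- setNames(references$sequence, references$amplicon_id)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    anchor_pos <- if (e$type == "sub") e$ref_pos else max(e$ref_pos, 1L)
    if (e$type == "sub") {
      ref <- e$ref
      alt <- e$alt
      pos <- e$ref_pos
    } else if (e$type == "ins") {
      pos <- max(e$ref_pos, 1L)
      anchor <- substr(seqs[[e$amplicon_id]], pos, pos)
      ref <- anchor
      alt <- paste0(anchor, e$alt)
    } else {
      pos <- max(e$ref_pos - 1L, 1L)
      anchor <- substr(seqs[[e$amplicon_id]], pos, pos)
      ref <- paste0(anchor, e$ref)
      alt <- anchor
    }
    cls <- if ("class" %in% names(events)) e$class else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tCLASS=%s;RUN=%s;STRAND=%s",
                       e$amplicon_id, pos, e$read_id, ref, alt, cls,
                       e$run_id, e$strand), con)
  }
  invisible(path)
}
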