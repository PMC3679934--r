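#' Default alignment scoring
#'
#' Semi-global scoring used by [align_reads()]: free end gaps on the
#' reference, affine gaps on both sequences (a gap of length L costs
#' `gap_open + L * gap_extend`). Reads whose best score falls below
#' `min_score` are flagged unalignable.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param min_score Alignment score floor.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, min_score = 0) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, min_score = min_score)
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Trim primers off amplicon reads
#'
#' Resolves read orientation from the 5' primer (forward primer for plus
#' strand reads, reverse primer for minus strand reads; at most
#' `max_mismatch` mismatches), removes both primer segments, and returns
#' reads in reference-forward orientation with qualities trimmed in
#' lockstep. Reads shorter than the two primers combined, or with no
#' recognizable 5' primer, are rejected with a reason; the rejected reads
#' are attached as `attr(result, "rejected")`.
#'
#' @param reads Reads tibble (`read_id`, `amplicon_id`, `seq`, `qual`, ...).
#' @param references References tibble with `primer_f`/`primer_r`.
#' @param max_mismatch Mismatches tolerated per primer.
#' @return Tibble of trimmed reads with `strand`, `orig_length` and
#'   `lead_trim` columns (the latter two map trimmed positions back to
#'   sequencing cycles).
#' @export
trim_primers <- function(reads, references, max_mismatch = 1) {
  refp <- select(references, "amplicon_id", "primer_f", "primer_r")
  x <- left_join(reads, refp, by = "amplicon_id")
  if (any(is.na(x$primer_f))) abort("reads reference amplicons missing from references")

  n <- nrow(x)
  keep <- logical(n)
  reason <- character(n)
  strand <- character(n)
  seq_out <- character(n)
  qual_out <- character(n)
  lead <- integer(n)

  for (i in seq_len(n)) {
    s <- x$seq[i]
    plf <- nchar(x$primer_f[i])
    plr <- nchar(x$primer_r[i])
    len <- nchar(s)
    if (len < plf + plr + 1) {
      reason[i] <- "too_short"
      next
    }
    rc_pr <- revcomp(x$primer_r[i])
    if (hamming(substr(s, 1, plf), x$primer_f[i]) <= max_mismatch) {
      strand[i] <- "+"
      fwd <- s
      q <- x$qual[i]
    } else if (hamming(substr(s, 1, plr), x$primer_r[i]) <= max_mismatch) {
      strand[i] <- "-"
      fwd <- revcomp(s)
      q <- paste(rev(strsplit(x$qual[i], "")[[1]]), collapse = "")
    } else {
      reason[i] <- "primer_mismatch"
      next
    }
    # trailing primer (reference-forward orientation ends with revcomp(primer_r))
    if (hamming(substr(fwd, len - plr + 1, len), rc_pr) > max_mismatch) {
      reason[i] <- "primer_mismatch"
      next
    }
    keep[i] <- TRUE
    seq_out[i] <- substr(fwd, plf + 1, len - plr)
    qual_out[i] <- substr(q, plf + 1, len - plr)
    lead[i] <- plf
  }

  out <- x[keep, setdiff(names(x), c("primer_f", "primer_r", "strand", "seq", "qual", "length"))]
  out$strand <- strand[keep]
  out$seq <- seq_out[keep]
  out$qual <- qual_out[keep]
  out$length <- nchar(out$seq)
  out$orig_length <- x$length[keep]
  out$lead_trim <- lead[keep]
  rejected <- x[!keep, c("read_id", "run_id", "amplicon_id")]
  rejected$reason <- reason[!keep]
  attr(out, "rejected") <- rejected
  out
}

#' Align reads semi-globally to their reference amplicons
#'
#' Each read is aligned over its full length to its reference with free
#' end gaps on the reference (the read is contained in the amplicon).
#' If the reads carry no `strand` column both orientations are tried and
#' the higher-scoring one kept. Indels are subsequently left-normalized
#' within homopolymer runs so recurrent errors map to canonical reference
#' coordinates. The heavy lifting is done by [Biostrings::pairwiseAlignment()].
#'
#' @param reads Reads tibble in reference-forward orientation (from
#'   [trim_primers()]) or raw reads with unknown strand.
#' @param references References tibble.
#' @param scoring See [align_scoring()].
#' @return A list of class `read_alignments`: `$reads` (per-read span,
#'   score, `aligned` flag), `$discrepancies` (per-base mismatches and
#'   left-normalized indels), `$scoring`, and `$discards`.
#' @export
align_reads <- function(reads, references, scoring = align_scoring()) {
  stopifnot(nrow(reads) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE
  )
  has_strand <- "strand" %in% names(reads)

  per_amp <- split(reads, reads$amplicon_id)
  res_reads <- vector("list", length(per_amp))
  res_disc <- vector("list", length(per_amp))

  for (a in seq_along(per_amp)) {
    rr <- per_amp[[a]]
    ref_row <- references[references$amplicon_id == rr$amplicon_id[1], ]
    if (nrow(ref_row) == 0) abort(paste0("no reference for amplicon ", rr$amplicon_id[1]))
    subject <- Biostrings::DNAString(ref_row$sequence)

    if (has_strand) {
      seqs <- rr$seq
      strands <- rr$strand
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs), subject, type = "global-local",
        substitutionMatrix = mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend
      )
    } else {
      fwd <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(rr$seq), subject, type = "global-local",
        substitutionMatrix = mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend
      )
      rev_ <- Biostrings::pairwiseAlignment(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(rr$seq)),
        subject, type = "global-local",
        substitutionMatrix = mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend
      )
      use_rev <- Biostrings::score(rev_) > Biostrings::score(fwd)
      strands <- if_else(use_rev, "-", "+")
      # re-align as a single set in the winning orientation
      seqs <- if_else(use_rev, revcomp(rr$seq), rr$seq)
      rr$seq <- seqs
      rr$qual <- if_else(
        use_rev,
        vapply(rr$qual, function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1)),
        rr$qual
      )
      rr$strand <- strands
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs), subject, type = "global-local",
        substitutionMatrix = mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend
      )
    }

    dec <- decode_alignments(aln, rr, ref_row$sequence)
    per_read <- tibble(
      read_id = rr$read_id,
      run_id = if ("run_id" %in% names(rr)) rr$run_id else NA_character_,
      amplicon_id = rr$amplicon_id,
      strand = rr$strand,
      score = Biostrings::score(aln),
      aligned = Biostrings::score(aln) >= scoring$min_score,
      ref_start = dec$ref_start,
      ref_end = dec$ref_end,
      read_start = 1L,
      read_length = nchar(rr$seq)
    )
    for (extra in c("orig_length", "lead_trim")) {
      if (extra %in% names(rr)) per_read[[extra]] <- rr[[extra]]
    }
    res_reads[[a]] <- per_read
    res_disc[[a]] <- dec$disc
  }

  reads_tbl <- bind_rows(res_reads)
  disc <- bind_rows(res_disc)
  disc <- disc[disc$read_id %in% reads_tbl$read_id[reads_tbl$aligned], , drop = FALSE]
  structure(
    list(
      reads = reads_tbl,
      discrepancies = disc,
      scoring = scoring,
      clipped = FALSE,
      discards = filter(reads_tbl, !.data$aligned) %>%
        select("read_id", "amplicon_id") %>% mutate(reason = "below_score_floor")
    ),
    class = "read_alignments"
  )
}

# Turn PairwiseAlignments compact accessors into a per-base discrepancy
# table with left-normalized indels. Gap ranges are reported in alignment
# column coordinates; mismatches in original pattern/subject coordinates.
decode_alignments <- function(aln, rr, ref_seq) {
  n <- length(aln)
  ref_start <- IRanges::start(Biostrings::subject(aln))
  ref_end <- IRanges::end(Biostrings::subject(aln))
  del_rg <- Biostrings::indel(Biostrings::pattern(aln)) # gaps in read
  ins_rg <- Biostrings::indel(Biostrings::subject(aln)) # gaps in reference
  mm <- Biostrings::mismatchTable(aln)
  ref_chars <- strsplit(ref_seq, "")[[1]]

  out <- vector("list", n)
  for (i in seq_len(n)) {
    dels <- del_rg[[i]]
    inss <- ins_rg[[i]]
    nd <- length(dels)
    ni <- length(inss)
    if (nd + ni == 0) next
    read_chars <- strsplit(rr$seq[i], "")[[1]]
    ds <- IRanges::start(dels); dw <- IRanges::width(dels)
    is_ <- IRanges::start(inss); iw <- IRanges::width(inss)

    recs <- vector("list", nd + ni)
    for (j in seq_len(nd)) {
      ins_before <- if (ni) sum(iw[is_ < ds[j]]) else 0L
      del_before <- if (j > 1) sum(dw[seq_len(j - 1)]) else 0L
      s <- ref_start[i] + ds[j] - 1L - ins_before
      e <- s + dw[j] - 1L
      flank <- ds[j] - 1L - del_before
      # left-normalize within homopolymer context
      while (s - 1L >= ref_start[i] && flank >= 1L &&
             ref_chars[s - 1L] == ref_chars[e] &&
             read_chars[flank] == ref_chars[s - 1L]) {
        s <- s - 1L; e <- e - 1L; flank <- flank - 1L
      }
      recs[[j]] <- tibble(
        type = "del", ref_pos = s, read_pos = flank,
        length = dw[j],
        ref = paste(ref_chars[s:e], collapse = ""), alt = ""
      )
    }
    for (j in seq_len(ni)) {
      ins_before <- if (j > 1) sum(iw[seq_len(j - 1)]) else 0L
      del_before <- if (nd) sum(dw[ds < is_[j]]) else 0L
      rp <- is_[j] - del_before
      a <- ref_start[i] - 1L + (is_[j] - 1L - ins_before)
      ii <- rp; jj <- rp + iw[j] - 1L
      while (a >= ref_start[i] && ii > 1L &&
             read_chars[ii - 1L] == read_chars[jj] &&
             ref_chars[a] == read_chars[jj]) {
        a <- a - 1L; ii <- ii - 1L; jj <- jj - 1L
      }
      recs[[nd + j]] <- tibble(
        type = "ins", ref_pos = a, read_pos = ii,
        length = iw[j],
        ref = "", alt = paste(read_chars[ii:jj], collapse = "")
      )
    }
    out[[i]] <- mutate(bind_rows(recs), read_idx = i)
  }

  disc <- bind_rows(out)
  if (nrow(mm) > 0) {
    disc <- bind_rows(disc, tibble(
      type = "sub",
      ref_pos = as.integer(mm$SubjectStart),
      read_pos = as.integer(mm$PatternStart),
      length = 1L,
      ref = as.character(mm$SubjectSubstring),
      alt = as.character(mm$PatternSubstring),
      read_idx = as.integer(mm$PatternId)
    ))
  }
  if (nrow(disc) == 0) {
    disc <- tibble(type = character(), ref_pos = integer(),
                   read_pos = integer(), length = integer(),
                   ref = character(), alt = character(), read_idx = integer())
  }
  disc <- disc %>%
    mutate(
      read_id = rr$read_id[.data$read_idx],
      run_id = if ("run_id" %in% names(rr)) rr$run_id[.data$read_idx] else NA_character_,
      amplicon_id = rr$amplicon_id[.data$read_idx],
      strand = rr$strand[.data$read_idx]
    ) %>%
    select(-"read_idx") %>%
    arrange(.data$read_id, .data$ref_pos, .data$read_pos)
  list(ref_start = ref_start, ref_end = ref_end, disc = disc)
}

#' Clip alignments to the exon interval
#'
#' Removes alignment content whose reference position lies outside the
#' exon. Insertions at the boundary are kept iff anchored to an in-exon
#' reference base (left-neighbor rule); deletions are truncated to their
#' in-exon part. Reads with no exon overlap are excluded and tallied in
#' `$discards`. Adds `n_exon_bases` (read bases aligned within the exon)
#' per read. Idempotent.
#'
#' @param alignments A [align_reads()] result.
#' @param references References tibble with `exon_start`/`exon_end`.
#' @return The clipped `read_alignments` object.
#' @export
clip_to_exon <- function(alignments, references) {
  stopifnot(inherits(alignments, "read_alignments"))
  ex <- select(references, "amplicon_id", "exon_start", "exon_end")
  rd <- left_join(alignments$reads, ex, by = "amplicon_id") %>%
    mutate(
      clip_start = pmax(.data$ref_start, .data$exon_start),
      clip_end = pmin(.data$ref_end, .data$exon_end),
      overlaps = .data$aligned & .data$clip_start <= .data$clip_end
    )

  disc <- alignments$discrepancies %>%
    left_join(ex, by = "amplicon_id") %>%
    filter(.data$read_id %in% rd$read_id[rd$overlaps])

  # read position aligned at the clip start (needed to map columns back
  # to read coordinates after clipping)
  pre <- disc %>%
    left_join(select(rd, "read_id", "clip_start"), by = "read_id") %>%
    group_by(.data$read_id) %>%
    summarise(
      ins_before = sum(.data$length[.data$type == "ins" &
                                      .data$ref_pos < .data$clip_start]),
      del_before = sum(pmax(0L, pmin(.data$ref_pos + .data$length - 1L,
                                     .data$clip_start - 1L) -
                              .data$ref_pos + 1L)[.data$type == "del"])
    )

  subs <- filter(disc, .data$type == "sub",
                 .data$ref_pos >= .data$exon_start,
                 .data$ref_pos <= .data$exon_end)
  ins <- filter(disc, .data$type == "ins",
                .data$ref_pos >= .data$exon_start,
                .data$ref_pos <= .data$exon_end)
  del <- filter(disc, .data$type == "del") %>%
    mutate(
      new_s = pmax(.data$ref_pos, .data$exon_start),
      new_e = pmin(.data$ref_pos + .data$length - 1L, .data$exon_end)
    ) %>%
    filter(.data$new_s <= .data$new_e) %>%
    mutate(
      ref = substr(.data$ref, .data$new_s - .data$ref_pos + 1L,
                   .data$new_e - .data$ref_pos + 1L),
      length = .data$new_e - .data$new_s + 1L,
      ref_pos = .data$new_s
    ) %>%
    select(-"new_s", -"new_e")

  clipped_disc <- bind_rows(subs, ins, del) %>%
    arrange(.data$read_id, .data$ref_pos, .data$read_pos)

  # read bases aligned inside the exon: in-exon reference columns minus
  # deleted reference bases plus kept inserted bases
  del_bases <- del %>% group_by(.data$read_id) %>%
    summarise(nd = sum(.data$length))
  ins_bases <- ins %>% group_by(.data$read_id) %>%
    summarise(ni = sum(.data$length))
  rd <- rd %>%
    left_join(del_bases, by = "read_id") %>%
    left_join(ins_bases, by = "read_id") %>%
    mutate(
      nd = if_else(is.na(.data$nd), 0L, as.integer(.data$nd)),
      ni = if_else(is.na(.data$ni), 0L, as.integer(.data$ni)),
      n_exon_bases = if_else(.data$overlaps,
                             .data$clip_end - .data$clip_start + 1L - .data$nd + .data$ni,
                             0L)
    )

  discards <- bind_rows(
    alignments$discards,
    filter(rd, .data$aligned & !.data$overlaps) %>%
      select("read_id", "amplicon_id") %>% mutate(reason = "no_exon_overlap")
  )

  out <- alignments
  out$reads <- rd %>%
    filter(.data$overlaps) %>%
    left_join(pre, by = "read_id") %>%
    mutate(
      ins_before = if_else(is.na(.data$ins_before), 0L, as.integer(.data$ins_before)),
      del_before = if_else(is.na(.data$del_before), 0L, as.integer(.data$del_before)),
      read_start = .data$read_start + (.data$clip_start - .data$ref_start) -
        .data$del_before + .data$ins_before,
      ref_start = .data$clip_start, ref_end = .data$clip_end
    ) %>%
    select(-"clip_start", -"clip_end", -"overlaps", -"nd", -"ni",
           -"exon_start", -"exon_end", -"ins_before", -"del_before")
  out$discrepancies <- select(clipped_disc, -"exon_start", -"exon_end")
  out$clipped <- TRUE
  out$discards <- discards
  out
}

#' Materialize the aligned column list for one read
#'
#' Reconstructs the pairwise alignment of a single read as a tibble of
#' aligned columns (reference position or gap, read position or gap),
#' mostly useful for inspection and testing.
#'
#' @param alignments A [align_reads()] result.
#' @param read_id The read to materialize.
#' @return Tibble with `ref_pos`, `read_pos`, `ref_base`, `read_base`
#'   (`NA` marks a gap; no column is a gap on both sides).
#' @param references References tibble.
#' @export
alignment_columns <- function(alignments, read_id, references) {
  r <- filter(alignments$reads, .data$read_id == .env$read_id)
  if (nrow(r) != 1) abort("read_id not found in alignments")
  d <- filter(alignments$discrepancies, .data$read_id == .env$read_id,
              .data$type != "sub") %>% arrange(.data$ref_pos)
  ref_chars <- strsplit(references$sequence[references$amplicon_id == r$amplicon_id], "")[[1]]

  cols <- list()
  ref_cursor <- r$ref_start
  read_cursor <- r$read_start
  subs <- filter(alignments$discrepancies, .data$read_id == .env$read_id,
                 .data$type == "sub")
  sub_alt <- setNames(subs$alt, subs$ref_pos)

  emit <- function(ref_pos, read_pos, ref_base, read_base) {
    cols[[length(cols) + 1]] <<- tibble(
      ref_pos = ref_pos, read_pos = read_pos,
      ref_base = ref_base, read_base = read_base
    )
  }
  di <- 1L
  while (ref_cursor <= r$ref_end) {
    if (di <= nrow(d) && d$type[di] == "ins" && d$ref_pos[di] == ref_cursor - 1L &&
        d$read_pos[di] == read_cursor) {
      for (k in seq_len(d$length[di])) {
        emit(NA_integer_, read_cursor, NA_character_,
             substr(d$alt[di], k, k))
        read_cursor <- read_cursor + 1L
      }
      di <- di + 1L
      next
    }
    if (di <= nrow(d) && d$type[di] == "del" && d$ref_pos[di] == ref_cursor) {
      for (k in seq_len(d$length[di])) {
        emit(ref_cursor, NA_integer_, ref_chars[ref_cursor], NA_character_)
        ref_cursor <- ref_cursor + 1L
      }
      di <- di + 1L
      next
    }
    rb <- ref_chars[ref_cursor]
    bb <- unname(sub_alt[as.character(ref_cursor)])
    if (is.na(bb)) bb <- rb
    emit(ref_cursor, read_cursor, rb, bb)
    ref_cursor <- ref_cursor + 1L
    read_cursor <- read_cursor + 1L
  }
  # trailing insertion anchored at ref_end
  if (di <= nrow(d) && d$type[di] == "ins" && d$ref_pos[di] == r$ref_end) {
    for (k in seq_len(d$length[di])) {
      emit(NA_integer_, read_cursor, NA_character_, substr(d$alt[di], k, k))
      read_cursor <- read_cursor + 1L
    }
  }
  bind_rows(cols)
}

#' Fraction of read bases retained after exon clipping
#'
#' @param clipped A clipped [read_alignments()] object.
#' @param reads The original (untrimmed) reads tibble.
#' @return One-row tibble with total bases, exon bases and retention.
#' @export
exon_retention <- function(clipped, reads) {
  stopifnot(isTRUE(clipped$clipped))
  total <- sum(reads$length)
  kept <- sum(clipped$reads$n_exon_bases)
  tibble(
    total_bases = total,
    exon_bases = kept,
    retention = kept / total
  )
}
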