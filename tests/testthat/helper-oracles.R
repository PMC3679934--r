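# Independent oracles and fixture builders used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force optimal semi-global alignment score (free end gaps on the
# reference, affine gaps: a gap of length L costs gap_open + L * gap_ext).
# Memoized recursion over (read index, ref index, previous-gap state);
# written independently of the aligner under test.
brute_align_score <- function(read, ref, match = 2, mismatch = -3,
                              gap_open = 5, gap_ext = 2) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  n <- length(rd)
  m <- length(rf)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j, prev) {
    if (i > n) return(0) # remaining reference is a free end gap
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (j <= m) {
      s <- if (rd[i] == rf[j]) match else mismatch
      best <- max(best, s + f(i + 1, j + 1, 0L))
      best <- max(best, -gap_ext - (if (prev == 2L) 0 else gap_open) +
                    f(i, j + 1, 2L)) # gap in read (deletion)
    }
    best <- max(best, -gap_ext - (if (prev == 1L) 0 else gap_open) +
                  f(i + 1, j, 1L)) # gap in reference (insertion)
    memo[[key]] <- best
    best
  }
  max(vapply(seq_len(m + 1), function(j0) f(1L, j0, 0L), numeric(1)))
}

# Alignment score implied by a read's injected truth events: every base
# not part of an event matches the reference.
truth_implied_score <- function(read_len, events, match = 2, mismatch = -3,
                                gap_open = 5, gap_ext = 2) {
  if (nrow(events) == 0) return(match * read_len)
  sub_len <- sum(events$length[events$type == "sub"])
  ins_len <- sum(events$length[events$type == "ins"])
  gaps <- events[events$type %in% c("ins", "del"), , drop = FALSE]
  matched <- read_len - ins_len - sub_len
  match * matched + mismatch * sub_len -
    sum(gap_open + gap_ext * gaps$length)
}

# Truth events restricted to what an exon-clipped extractor can observe:
# substitutions and deletions inside the exon, insertions anchored to an
# in-exon base.
truth_in_exon <- function(truth_events, references) {
  x <- dplyr::left_join(
    truth_events,
    references[, c("amplicon_id", "exon_start", "exon_end")],
    by = "amplicon_id"
  )
  dplyr::filter(
    x,
    (.data$type != "ins" & .data$ref_pos >= .data$exon_start &
       .data$ref_pos + .data$length - 1 <= .data$exon_end) |
      (.data$type == "ins" & .data$ref_pos >= .data$exon_start &
         .data$ref_pos <= .data$exon_end)
  )
}

event_key_with_read <- function(x) {
  paste(x$read_id, x$amplicon_id, x$ref_pos, x$type,
        ifelse(x$type == "del", x$length, x$alt))
}

# per-base homopolymer run length, computed independently of
# scan_homopolymers (left+right scan per base)
brute_hp_length <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  vapply(seq_len(n), function(i) {
    l <- i
    while (l > 1L) { if (ch[l - 1L] == ch[i]) l <- l - 1L else break }
    r <- i
    while (r < n) { if (ch[r + 1L] == ch[i]) r <- r + 1L else break }
    r - l + 1L
  }, integer(1))
}

# a tiny single-amplicon reference tibble built by hand
tiny_reference <- function(sequence = "ACGTACGGTACCGATCGATTACG",
                           exon_start = 7L, exon_end = 18L,
                           primer_f = "ACGT", primer_r = "CGTA") {
  tibble::tibble(
    amplicon_id = "AMP1", locus = "AMP1", sequence = sequence,
    exon_start = exon_start, exon_end = exon_end,
    primer_f = primer_f, primer_r = primer_r, hp_weight = 1
  )
}

# reads tibble from raw sequences with constant quality
make_reads <- function(seqs, q = 30, strand = NULL, amplicon_id = "AMP1",
                       run_id = "run1") {
  qual <- vapply(nchar(seqs), function(n) intToUtf8(rep(q + 33L, n)), character(1))
  x <- tibble::tibble(
    read_id = paste0("r", seq_along(seqs)),
    run_id = run_id, amplicon_id = amplicon_id,
    seq = seqs, qual = qual, length = nchar(seqs)
  )
  if (!is.null(strand)) x$strand <- strand
  x
}

rc <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
}
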