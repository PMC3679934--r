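test_that("primer trimming handles both strands, mismatches and rejects", {
  ref <- tiny_reference(
    sequence = paste0("ACGTAACC", "TTGACTGACTGG", "GGCCACGT"),
    exon_start = 9L, exon_end = 20L,
    primer_f = "ACGTAACC", primer_r = rc("GGCCACGT")
  )
  insert <- "TTGACTGACTGG"
  full <- paste0("ACGTAACC", insert, "GGCCACGT")
  reads <- make_reads(c(full, rc(full)), q = 25)
  out <- trim_primers(reads, ref)
  expect_equal(out$seq, c(insert, insert))
  expect_equal(out$strand, c("+", "-"))
  expect_equal(out$lead_trim, c(8L, 8L))
  expect_equal(nchar(out$qual), nchar(out$seq))

  # one mismatch in the forward primer still trims identically
  mm <- paste0("ACGTATCC", insert, "GGCCACGT")
  out_mm <- trim_primers(make_reads(mm), ref)
  expect_equal(out_mm$seq, insert)

  # too-short and unrecognizable reads are rejected with a reason
  bad <- make_reads(c("ACGTA", paste0("TTTTTTTT", insert, "GGCCACGT")))
  out_bad <- trim_primers(bad, ref)
  expect_equal(nrow(out_bad), 0)
  rej <- attr(out_bad, "rejected")
  expect_equal(sort(rej$reason), c("primer_mismatch", "too_short"))
})

test_that("identical reads align with no discrepancies and full score", {
  ref <- tiny_reference()
  insert <- substr(ref$sequence, 5, 19)
  aln <- align_reads(make_reads(insert, strand = "+"), ref)
  expect_equal(nrow(aln$discrepancies), 0)
  expect_equal(aln$reads$score, 2 * nchar(insert))
  expect_equal(aln$reads$ref_start, 5L)
  expect_equal(aln$reads$ref_end, 19L)
})

test_that("homopolymer indels are left-aligned to canonical coordinates", {
  # reference ...GG AAA C..., read with an extra A: anchor is the base
  # left of the run after maximal left shift
  ref <- tiny_reference(sequence = "TTGGAAACGGTTCAG",
                        exon_start = 1L, exon_end = 15L)
  read_ins <- "TTGGAAAACGGTTCAG" # insertion in the A-run
  aln <- align_reads(make_reads(read_ins, strand = "+"), ref)
  d <- aln$discrepancies
  expect_equal(d$type, "ins")
  expect_equal(d$ref_pos, 4L) # anchored at the G before the AAA run
  expect_equal(d$read_pos, 5L)
  expect_equal(d$alt, "A")

  read_del <- "TTGGAACGGTTCAG" # deletion in the A-run
  aln2 <- align_reads(make_reads(read_del, strand = "+"), ref)
  d2 <- aln2$discrepancies
  expect_equal(d2$type, "del")
  expect_equal(d2$ref_pos, 5L) # leftmost base of the run
  expect_equal(d2$length, 1L)
})

test_that("reverse-complement reads resolve strand and map to forward events", {
  ref <- tiny_reference(sequence = "TTGGAAACGGTTCAG",
                        exon_start = 1L, exon_end = 15L)
  read_fwd <- "TTGGAAACGGATCAG" # sub T->A at ref pos 11
  aln_f <- align_reads(make_reads(read_fwd, strand = "+"), ref)
  aln_r <- align_reads(make_reads(rc(read_fwd)), ref) # strand auto
  expect_equal(aln_r$reads$strand, "-")
  expect_equal(aln_r$discrepancies$ref_pos, aln_f$discrepancies$ref_pos)
  expect_equal(aln_r$discrepancies$alt, aln_f$discrepancies$alt)
  expect_equal(aln_f$discrepancies$ref_pos, 11L)
})

test_that("alignment scores equal the brute-force optimum on short reads", {
  set.seed(99)
  cases <- 0
  for (i in 1:40) {
    m <- sample(8:15, 1)
    ref_seq <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    n <- sample(4:min(12, m), 1)
    start <- sample(seq_len(m - n + 1), 1)
    rd <- strsplit(substr(ref_seq, start, start + n - 1), "")[[1]]
    # random edits
    k <- sample(0:2, 1)
    for (e in seq_len(k)) {
      op <- sample(c("sub", "ins", "del"), 1)
      p <- sample(length(rd), 1)
      if (op == "sub") rd[p] <- sample(c("A", "C", "G", "T"), 1)
      if (op == "ins") rd <- append(rd, sample(c("A", "C", "G", "T"), 1), p)
      if (op == "del" && length(rd) > 4) rd <- rd[-p]
    }
    read <- paste(rd, collapse = "")
    ref <- tiny_reference(sequence = ref_seq, exon_start = 1L,
                          exon_end = nchar(ref_seq))
    aln <- align_reads(make_reads(read, strand = "+"), ref,
                       align_scoring(min_score = -1e9))
    expect_equal(aln$reads$score, brute_align_score(read, ref_seq),
                 tolerance = 1e-9)
    cases <- cases + 1
  }
  expect_equal(cases, 40)
})

test_that("exon clipping removes out-of-exon content and is idempotent", {
  # exon covers positions 7..18 of a 23 bp reference
  ref <- tiny_reference()
  insert <- ref$sequence # read spans the whole reference
  aln <- align_reads(make_reads(insert, strand = "+"), ref)
  clipped <- clip_to_exon(aln, ref)
  expect_true(clipped$clipped)
  expect_equal(clipped$reads$ref_start, 7L)
  expect_equal(clipped$reads$ref_end, 18L)
  expect_equal(clipped$reads$read_start, 7L)
  expect_equal(clipped$reads$n_exon_bases, 12L)

  clipped2 <- clip_to_exon(clipped, ref)
  expect_equal(clipped2$reads, clipped$reads)
  expect_equal(clipped2$discrepancies, clipped$discrepancies)

  # columns materialize consistently after clipping
  cols <- alignment_columns(clipped, clipped$reads$read_id[1], ref)
  expect_equal(nrow(cols), 12)
  expect_equal(cols$ref_pos, 7:18)
  expect_equal(cols$read_pos, 7:18)
  expect_false(any(is.na(cols$ref_pos) & is.na(cols$read_pos)))

  # a read aligned entirely outside the exon is discarded and tallied
  intron_read <- substr(ref$sequence, 1, 6)
  aln2 <- align_reads(make_reads(intron_read, strand = "+"), ref)
  clipped3 <- clip_to_exon(aln2, ref)
  expect_equal(nrow(clipped3$reads), 0)
  expect_equal(clipped3$discards$reason, "no_exon_overlap")
})

test_that("clipping drops pre-exon discrepancies and keeps quality in sync", {
  # sub at position 3 (intron) and position 10 (exon)
  ref <- tiny_reference(sequence = "ACGTACGGTACCGATCGATTACG")
  rd <- strsplit(ref$sequence, "")[[1]]
  rd[3] <- setdiff(c("A", "C", "G", "T"), rd[3])[1]
  rd[10] <- setdiff(c("A", "C", "G", "T"), rd[10])[1]
  read <- paste(rd, collapse = "")
  aln <- align_reads(make_reads(read, strand = "+"), ref)
  expect_equal(nrow(aln$discrepancies), 2)
  clipped <- clip_to_exon(aln, ref)
  expect_equal(clipped$discrepancies$ref_pos, 10L)

  # boundary insertions: kept iff anchored to an in-exon base
  # (anchor = exon_end keeps, anchor = exon_start - 1 drops)
  ins_at_end <- paste0(substr(ref$sequence, 1, 18), "X", substr(ref$sequence, 19, 23))
  ins_at_end <- sub("X", "T", ins_at_end) # inserted after exon_end = 18
  aln3 <- align_reads(make_reads(ins_at_end, strand = "+"), ref,
                      align_scoring(min_score = -100))
  cl3 <- clip_to_exon(aln3, ref)
  ins_events <- dplyr::filter(cl3$discrepancies, type == "ins")
  if (nrow(ins_events) > 0) expect_true(all(ins_events$ref_pos >= 7 & ins_events$ref_pos <= 18))
})

test_that("exon retention accounts for all discarded bases", {
  set.seed(12)
  cfg <- sim_config(n_runs = 1, reads_per_amplicon = 20, seed = 12)
  sim <- simulate_dataset(cfg)
  refs <- sim$panel$references
  trimmed <- trim_primers(sim$reads, refs)
  aln <- align_reads(trimmed, refs)
  clipped <- clip_to_exon(aln, refs)
  ret <- exon_retention(clipped, sim$reads)
  expect_gt(ret$retention, 0.7)
  expect_lt(ret$retention, 0.95)
  expect_equal(ret$retention, 1 - (ret$total_bases - ret$exon_bases) / ret$total_bases)
})
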