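align_one <- function(read, ref, q = 30) {
  aln <- align_reads(make_reads(read, q = q, strand = "+"), ref,
                     align_scoring(min_score = -1e9))
  clip_to_exon(aln, ref)
}

test_that("discrepancies merge into canonical variant events", {
  # deletion: ref ACGT / read ACT inside flanking context
  ref <- tiny_reference(sequence = "TTCCAACGTGGATTCC",
                        exon_start = 1L, exon_end = 16L)
  cl <- align_one("TTCCAACTGGATTCC", ref)
  ev <- extract_variants(cl, make_reads("TTCCAACTGGATTCC", strand = "+"))
  expect_equal(ev$type, "del")
  expect_equal(ev$ref_pos, 8L) # the G of ACGT
  expect_equal(ev$ref, "G")
  expect_equal(ev$length, 1L)

  # identical sequences: no events
  cl0 <- align_one(ref$sequence, ref)
  ev0 <- extract_variants(cl0, make_reads(ref$sequence, strand = "+"))
  expect_equal(nrow(ev0), 0)

  # adjacent mismatches merge into one substitution event of length 2
  rd <- strsplit(ref$sequence, "")[[1]]
  rd[10] <- c(A = "C", C = "A", G = "T", T = "G")[[rd[10]]]
  rd[11] <- c(A = "C", C = "A", G = "T", T = "G")[[rd[11]]]
  read2 <- paste(rd, collapse = "")
  cl2 <- align_one(read2, ref)
  ev2 <- extract_variants(cl2, make_reads(read2, strand = "+"))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$type, "sub")
  expect_equal(ev2$length, 2L)
  expect_equal(nchar(ev2$ref), 2L)
})

test_that("event qualities come from the involved read bases", {
  ref <- tiny_reference(sequence = "TTCCAACGTGGATTCC",
                        exon_start = 1L, exon_end = 16L)
  # substitution at read pos 10 with a distinctive quality
  rd <- strsplit(ref$sequence, "")[[1]]
  rd[10] <- c(A = "C", C = "A", G = "T", T = "G")[[rd[10]]]
  read <- paste(rd, collapse = "")
  reads <- make_reads(read, q = 30, strand = "+")
  qv <- rep(30L, nchar(read)); qv[10] <- 7L
  reads$qual <- pyroprofile:::encode_quality(list(qv))
  cl <- align_one(read, ref)
  ev <- extract_variants(cl, reads)
  expect_equal(ev$q_event, 7)

  # deletion quality: error-rate-space mean of the two flanking bases
  del_read <- "TTCCAACTGGATTCC" # G deleted; flanks at read pos 7, 8
  dreads <- make_reads(del_read, strand = "+")
  qv2 <- rep(30L, nchar(del_read)); qv2[7] <- 10L; qv2[8] <- 30L
  dreads$qual <- pyroprofile:::encode_quality(list(qv2))
  cl2 <- align_one(del_read, ref)
  ev2 <- extract_variants(cl2, dreads)
  expect_equal(ev2$q_event, average_quality(c(10, 30)))
  expect_equal(sort(ev2$q_bases[[1]]), c(10, 30))
})

test_that("classification partitions events by truth keys", {
  ev <- tibble::tibble(
    amplicon_id = c("A", "A", "A", "B"),
    run_id = "run1",
    read_id = c("r1", "r2", "r3", "r4"),
    strand = c("+", "-", "+", "+"),
    ref_pos = c(10L, 20L, 30L, 10L),
    read_pos = 1L, cycle = 1L,
    type = c("sub", "sub", "del", "sub"),
    length = c(1L, 1L, 2L, 1L),
    ref = c("A", "C", "GG", "T"),
    alt = c("G", "T", "", "A"),
    q_event = 20, q_bases = list(20, 20, 20, 20)
  )
  ts <- truth_set(
    variants = tibble::tibble(amplicon_id = "A", ref_pos = 10L,
                              type = "sub", ref = "A", alt = "G"),
    pseudogene = tibble::tibble(amplicon_id = "A", ref_pos = 20L,
                                type = "sub", ref = "C", alt = "T")
  )
  out <- classify_variants(ev, ts)
  expect_equal(out$class, c("true_variant", "pseudogene_product", "error", "error"))

  # partition completeness
  expect_equal(sum(table(out$class)), nrow(ev))
  # idempotent and order-independent
  out2 <- classify_variants(out[sample(nrow(out)), ], ts)
  expect_equal(sort(variant_key(out2[out2$class == "error", ])),
               sort(variant_key(out[out$class == "error", ])))
  # unknown amplicon triggers a lookup error when coverage is declared
  expect_error(classify_variants(ev, ts, amplicons = "A"), "unknown amplicon")
})

test_that("no pseudogene class appears when pseudogene fraction is zero", {
  cfg <- sim_config(n_runs = 1, reads_per_amplicon = 25,
                    pseudogene_fraction = 0, seed = 6)
  sim <- simulate_dataset(cfg)
  refs <- sim$panel$references
  trimmed <- trim_primers(sim$reads, refs)
  cl <- clip_to_exon(align_reads(trimmed, refs), refs)
  ev <- extract_variants(cl, trimmed)
  out <- classify_variants(ev, sim$truth_set)
  expect_false(any(out$class == "pseudogene_product"))
})

test_that("bidirectional support counts keys seen on both strands", {
  base <- tibble::tibble(
    amplicon_id = "A", ref_pos = 5L, type = "sub", length = 1L,
    ref = "A", alt = "T"
  )
  all_fwd <- dplyr::bind_rows(base, base) %>%
    dplyr::mutate(strand = "+", read_id = c("r1", "r2"))
  expect_equal(bidirectional_support(all_fwd)$fraction, 0)

  both <- dplyr::bind_rows(base, base) %>%
    dplyr::mutate(strand = c("+", "-"), read_id = c("r1", "r2"))
  res <- bidirectional_support(both)
  expect_equal(res$n_bidirectional, 1L)
  expect_equal(res$fraction, 1)

  # closed form vs monte-carlo: strand-balanced errors at rate r per
  # read, coverage c -> P(both strands | observed)
  set.seed(303)
  r <- 0.12; c_cov <- 40
  hits <- 0; both_hits <- 0
  for (i in 1:2000) {
    fwd <- rbinom(1, c_cov / 2, r) > 0
    rev <- rbinom(1, c_cov / 2, r) > 0
    if (fwd || rev) hits <- hits + 1
    if (fwd && rev) both_hits <- both_hits + 1
  }
  p_one <- 1 - (1 - r)^(c_cov / 2)
  expected <- p_one^2 / (1 - (1 - r)^c_cov)
  observed <- both_hits / hits
  se <- sqrt(expected * (1 - expected) / hits)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("variant events export as VCF-style records", {
  ref <- tiny_reference(sequence = "TTCCAACGTGGATTCC",
                        exon_start = 1L, exon_end = 16L)
  cl <- align_one("TTCCAACTGGATTCC", ref)
  ev <- extract_variants(cl, make_reads("TTCCAACTGGATTCC", strand = "+"))
  ev$class <- "error"
  path <- tempfile(fileext = ".vcf")
  export_variants_vcf(ev, ref, path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat", lines)))
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(rec[1], "AMP1")
  expect_equal(rec[2], "7") # deletion anchored at the previous base
  expect_equal(nchar(rec[4]), 2L)
  unlink(path)
})
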