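spec2 <- function(weight = 1) {
  tibble::tibble(locus = c("L1", "L2"), exon_length = 120L,
                 primer_length = 15L, hp_weight = weight)
}

test_that("reference generation honors homopolymer enrichment settings", {
  cfg0 <- sim_config(amplicon_specs = spec2(weight = 0), seed = 3)
  panel0 <- generate_references(cfg0)
  expect_equal(nrow(panel0$references), 2)
  for (s in panel0$references$sequence) {
    expect_lte(max(scan_homopolymers(s)$length), 3)
  }

  cfg1 <- sim_config(amplicon_specs = spec2(weight = 1), seed = 3)
  panel1 <- generate_references(cfg1)
  for (i in 1:2) {
    r <- panel1$references[i, ]
    exon <- substr(r$sequence, r$exon_start, r$exon_end)
    expect_gte(max(scan_homopolymers(exon)$length), 4)
  }

  # determinism
  panel1b <- generate_references(cfg1)
  expect_identical(panel1$references$sequence, panel1b$references$sequence)

  expect_error(sim_config(amplicon_specs = tibble::tibble(
    locus = "X", exon_length = 20L, primer_length = 15L, hp_weight = 1
  )), ">= 50")
  expect_error(sim_config(amplicon_specs = spec2(weight = -1)), ">= 0")
})

test_that("haplotypes differ from the reference only where intended", {
  cfg <- sim_config(true_variant_count = 3, pseudogene_fraction = 0.25, seed = 9)
  panel <- generate_references(cfg)
  for (amp in panel$references$amplicon_id) {
    ref <- panel$references$sequence[panel$references$amplicon_id == amp]
    haps <- dplyr::filter(panel$haplotypes, amplicon_id == amp)
    for (k in seq_len(nrow(haps))) {
      hs <- haps$sequence[k]
      expect_equal(nchar(hs), nchar(ref))
      diffs <- which(strsplit(ref, "")[[1]] != strsplit(hs, "")[[1]])
      tv <- dplyr::filter(panel$truth_variants, amplicon_id == amp,
                          source == switch(haps$role[k],
                                           reference = "none",
                                           allele = "allele",
                                           pseudogene = "pseudogene"))
      if (haps$role[k] == "reference") {
        expect_equal(length(diffs), 0)
      } else {
        expect_equal(diffs, tv$ref_pos)
        if (haps$role[k] == "pseudogene") expect_gte(length(diffs), 3)
      }
    }
  }
  # exon boundaries never sit inside a homopolymer run
  for (i in seq_len(nrow(panel$references))) {
    r <- panel$references[i, ]
    ch <- strsplit(r$sequence, "")[[1]]
    expect_false(ch[r$exon_start - 1] == ch[r$exon_start])
    expect_false(ch[r$exon_end] == ch[r$exon_end + 1])
  }
})

test_that("zero error rates give error-free reads; seed gives identical output", {
  cfg <- sim_config(n_runs = 1, reads_per_amplicon = 10,
                    amplicon_specs = spec2(), substitution_rate = 0,
                    indel_base_rate = 0, seed = 4)
  panel <- generate_references(cfg)
  run <- simulate_run(panel, cfg, 1)
  expect_equal(nrow(run$truth), 0)
  expect_equal(nrow(run$reads), 20)
  # reads are exact haplotype copies
  fwd <- ifelse(run$reads$strand == "+", run$reads$seq, rc(run$reads$seq))
  ok <- mapply(function(s, amp) {
    s %in% panel$haplotypes$sequence[panel$haplotypes$amplicon_id == amp]
  }, fwd, run$reads$amplicon_id)
  expect_true(all(ok))

  cfg2 <- sim_config(n_runs = 2, reads_per_amplicon = 5, seed = 77)
  a <- simulate_dataset(cfg2)
  b <- simulate_dataset(cfg2)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth_events, b$truth_events)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(a, d1); write_simulation(b, d2)
  f1 <- file.path(d1, "run1.fastq"); f2 <- file.path(d2, "run1.fastq")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("injected event positions stay within the read span", {
  cfg <- sim_config(n_runs = 1, reads_per_amplicon = 40, seed = 21)
  sim <- simulate_dataset(cfg)
  tr <- dplyr::left_join(
    sim$truth_events,
    dplyr::select(sim$reads, read_id, read_len = length),
    by = "read_id"
  )
  expect_true(all(tr$read_pos >= 1 & tr$read_pos <= tr$read_len))
  # reads with no events are exactly the error-free reads
  with_ev <- unique(sim$truth_events$read_id)
  panel_haps <- sim$panel$haplotypes
  clean <- dplyr::filter(sim$reads, !read_id %in% with_ev)
  fwd <- ifelse(clean$strand == "+", clean$seq, rc(clean$seq))
  ok <- mapply(function(s, amp) s %in% panel_haps$sequence[panel_haps$amplicon_id == amp],
               fwd, clean$amplicon_id)
  expect_true(all(ok))
})

test_that("reported qualities are clamped to [0, 40] and miscalibration applies", {
  cfg <- sim_config(n_runs = 1, reads_per_amplicon = 5, seed = 2,
                    quality_profile = list(q_start = 2, q_plateau = 39,
                                           ramp_end = 20, decay_onset = 100,
                                           q_end = 2))
  sim <- simulate_dataset(cfg)
  q <- unlist(pyroprofile:::decode_quality(sim$reads$qual))
  expect_true(all(q >= 0 & q <= 40))

  expect_equal(pyroprofile:::apply_miscalibration(
    c(25, 30, 35), list(type = "step", threshold = 30, above = 3, below = -2)),
    c(23, 30, 38))
  expect_equal(pyroprofile:::apply_miscalibration(10, list(type = "identity")), 10)
})

test_that("monte-carlo rates match configuration within 3 binomial SD", {
  # substitutions at a flat profile over ~1e6 eligible bases
  flat <- list(q_start = 30, q_plateau = 30, ramp_end = 1,
               decay_onset = 1000, q_end = 30)
  cfg <- sim_config(
    n_runs = 1, reads_per_amplicon = 1500,
    amplicon_specs = tibble::tibble(locus = c("L1", "L2"), exon_length = 320L,
                                    primer_length = 15L, hp_weight = 1),
    substitution_rate = 0.002, indel_base_rate = 0, pseudogene_fraction = 0,
    true_variant_count = 0, quality_profile = flat, seed = 13
  )
  sim <- simulate_dataset(cfg)
  eligible <- sum(sim$reads$length - 2 * 15)
  n_sub <- sum(sim$truth_events$type == "sub")
  expect_gt(eligible, 1e6)
  expected <- 0.002 * eligible
  expect_lt(abs(n_sub - expected), 3 * sqrt(expected))

  # indel probability at a known homopolymer: base rate x slope^(L-1),
  # on a hand-built reference with exactly two length-4 runs
  primer_f <- "GACTGACTGACTGAC"
  primer_r <- "TGCATGCATGCATGC" # reference right end = revcomp of this
  exon <- paste0(strrep("ACGT", 15), "AAAA", strrep("CGTA", 15), "G",
                 "CCCC", strrep("GTAC", 15))
  ref_seq <- paste0(primer_f, "ACGTACGTAC", exon, "ACGTACGTAC", rc(primer_r))
  panel <- structure(list(
    references = tibble::tibble(
      amplicon_id = "HP4", locus = "HP4", sequence = ref_seq,
      exon_start = nchar(primer_f) + 11L,
      exon_end = nchar(primer_f) + 10L + nchar(exon),
      primer_f = primer_f, primer_r = primer_r, hp_weight = 1
    ),
    haplotypes = tibble::tibble(
      amplicon_id = "HP4", hap_id = "HP4*ref", role = "reference",
      sequence = ref_seq
    ),
    truth_variants = tibble::tibble(
      amplicon_id = character(), ref_pos = integer(), type = character(),
      ref = character(), alt = character(), source = character()
    )
  ), class = "amplicon_panel")
  cfg2 <- sim_config(n_runs = 1, reads_per_amplicon = 4000,
                     amplicon_specs = spec2(), substitution_rate = 0,
                     indel_base_rate = 0.001, indel_length_slope = 2,
                     pseudogene_fraction = 0, true_variant_count = 0,
                     seed = 31)
  run4 <- scan_homopolymers(ref_seq)
  starts4 <- run4$start[run4$length == 4]
  expect_equal(length(starts4), 2)
  sim2 <- simulate_run(panel, cfg2, 1)
  tr <- dplyr::filter(sim2$truth, type %in% c("ins", "del")) %>%
    dplyr::mutate(run_start = dplyr::if_else(type == "ins", ref_pos + 1L, ref_pos))
  tr4 <- dplyr::filter(tr, run_start %in% starts4)
  traversals <- 4000 * 2
  p_base <- 0.001 * 2^3
  expected_bases <- traversals * 4 * p_base
  observed_bases <- sum(tr4$length)
  expect_lt(abs(observed_bases - expected_bases), 3 * sqrt(expected_bases))
})

test_that("emitted bases are conserved in the run summary", {
  cfg <- sim_config(n_runs = 2, reads_per_amplicon = 15, seed = 8)
  sim <- simulate_dataset(cfg)
  rs <- run_summary(sim$reads)
  expect_equal(rs$overall$total_bases, sum(nchar(sim$reads$seq)))
  expect_equal(rs$overall$total_reads, nrow(sim$reads))
  expect_equal(sum(rs$per_run$bases), sum(sim$reads$length))
})
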