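#' Configure a synthetic 454-style amplicon sequencing experiment
#'
#' Builds the configuration for the read simulator. The defaults emulate a
#' multi-run HLA-exon amplicon study on a 454 GS Junior class instrument:
#' six independent runs of one pooled library over six loci, a pseudogene
#' co-amplified at 25% for the first locus, homopolymer-length-dependent
#' indel errors, uniform substitution errors modulated by a positional
#' quality profile with a decay starting near 300 bp, quality valleys at
#' error positions, and a step miscalibration in which the instrument
#' overestimates its own performance above Q30.
#'
#' @param n_runs Number of independent sequencing runs of the same library.
#' @param reads_per_amplicon Reads per amplicon per run.
#' @param amplicon_specs Tibble with one row per amplicon: `locus`,
#'   `exon_length` (bp, >= 50), `primer_length` (bp) and `hp_weight`
#'   (homopolymer enrichment weight, >= 0; 0 caps reference homopolymers at
#'   length 3).
#' @param intron_length Intronic pad between each primer and the exon (bp).
#' @param substitution_rate Mean per-base substitution probability. The
#'   per-cycle probability follows the quality profile in error-rate space
#'   and averages to this value over the read.
#' @param indel_base_rate Per-base indel probability at homopolymer length 1.
#' @param indel_length_slope Multiplicative indel rate increase per extra
#'   homopolymer base: at a run of length L the per-base rate is
#'   `indel_base_rate * indel_length_slope^(L-1)`.
#' @param overcall_fraction Fraction of homopolymer indel errors that are
#'   overcalls (insertions); pyrosequencing overcalls more often than it
#'   undercalls.
#' @param pseudogene_fraction Fraction of reads of `pseudogene_locus` drawn
#'   from a co-amplified pseudogene haplotype (in `[0,1)`).
#' @param pseudogene_locus Locus carrying the pseudogene side-product;
#'   default is the first locus in `amplicon_specs`.
#' @param pseudogene_diff_count Substitution differences between pseudogene
#'   and reference (>= 3).
#' @param true_variant_count True (allelic) substitution variants per
#'   amplicon; reads are drawn heterozygously from reference and allele.
#' @param quality_profile List with `q_start`, `q_plateau`, `ramp_end`,
#'   `decay_onset` (bp) and `q_end`: a piecewise-linear per-cycle quality
#'   curve (rise to plateau, then decay after the onset).
#' @param error_site_q_penalty Phred points subtracted from the true
#'   quality at simulated error sites (the "quality valley").
#' @param miscalibration Mapping from true quality to reported quality:
#'   `list(type = "identity")`, `list(type = "offset", offset = x)`, or the
#'   default `list(type = "step", threshold = 30, above = 3, below = -2)`
#'   (reported Q inflated by 3 above the threshold, deflated by 2 below).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_runs = 6,
                       reads_per_amplicon = 100,
                       amplicon_specs = default_amplicon_specs(),
                       intron_length = 10,
                       substitution_rate = 5e-4,
                       indel_base_rate = 4e-4,
                       indel_length_slope = 2.5,
                       overcall_fraction = 0.65,
                       pseudogene_fraction = 0.25,
                       pseudogene_locus = NULL,
                       pseudogene_diff_count = 5,
                       true_variant_count = 2,
                       quality_profile = list(q_start = 25, q_plateau = 35,
                                              ramp_end = 20, decay_onset = 300,
                                              q_end = 20),
                       error_site_q_penalty = 5,
                       miscalibration = list(type = "step", threshold = 30,
                                             above = 3, below = -2),
                       seed = 1L) {
  amplicon_specs <- as_tibble(amplicon_specs)
  needed <- c("locus", "exon_length", "primer_length", "hp_weight")
  if (nrow(amplicon_specs) == 0 || !all(needed %in% names(amplicon_specs))) {
    abort("amplicon_specs must be nonempty with columns locus, exon_length, primer_length, hp_weight")
  }
  if (any(amplicon_specs$exon_length < 50)) abort("exon lengths must be >= 50")
  if (any(amplicon_specs$hp_weight < 0)) abort("homopolymer enrichment weights must be >= 0")
  if (any(amplicon_specs$primer_length < 5)) abort("primer lengths must be >= 5")
  for (p in c(substitution_rate, indel_base_rate)) {
    if (p < 0 || p > 1) abort("rates must be probabilities in [0,1]")
  }
  if (pseudogene_fraction < 0 || pseudogene_fraction >= 1) {
    abort("pseudogene_fraction must lie in [0,1)")
  }
  if (indel_length_slope <= 0) abort("indel_length_slope must be positive")
  if (is.null(pseudogene_locus)) pseudogene_locus <- amplicon_specs$locus[1]
  cfg <- list(
    n_runs = as.integer(n_runs),
    reads_per_amplicon = as.integer(reads_per_amplicon),
    amplicon_specs = amplicon_specs,
    intron_length = as.integer(intron_length),
    substitution_rate = substitution_rate,
    indel_base_rate = indel_base_rate,
    indel_length_slope = indel_length_slope,
    overcall_fraction = overcall_fraction,
    pseudogene_fraction = pseudogene_fraction,
    pseudogene_locus = pseudogene_locus,
    pseudogene_diff_count = as.integer(pseudogene_diff_count),
    true_variant_count = as.integer(true_variant_count),
    quality_profile = quality_profile,
    error_site_q_penalty = error_site_q_penalty,
    miscalibration = miscalibration,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_amplicon_specs <- function() {
  tibble(
    locus = c("HLA-A", "HLA-B", "HLA-C", "DQB1", "DRB1", "DPB1"),
    exon_length = 330L,
    primer_length = 20L,
    hp_weight = 1
  )
}

BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# Random sequence with tunable homopolymer enrichment. weight 0 caps runs
# at length 3; weight > 0 raises the probability of repeating the previous
# base.
random_sequence <- function(n, hp_weight = 1, max_run = Inf) {
  p_rep <- min(0.25 + 0.05 * hp_weight, 0.85)
  out <- character(n)
  out[1] <- sample(BASES, 1)
  run <- 1L
  for (i in seq_len(n)[-1]) {
    prev <- out[i - 1]
    if (run < max_run && runif(1) < p_rep) {
      out[i] <- prev
    } else {
      out[i] <- sample(setdiff(BASES, prev), 1)
      # when capped, a uniform redraw could still repeat; setdiff never does
    }
    run <- if (out[i] == prev) run + 1L else 1L
  }
  paste(out, collapse = "")
}

# force chr[i] to differ from both neighbors (keeps runs maximal at a
# boundary without creating new long runs)
break_run_at <- function(chars, i) {
  nb <- c(if (i > 1) chars[i - 1], if (i < length(chars)) chars[i + 1])
  chars[i] <- sample(setdiff(BASES, c(chars[i], nb)), 1)
  chars
}

#' Generate reference amplicons, allele and pseudogene haplotypes
#'
#' Creates one reference sequence per amplicon
#' (`primer_f | intron | exon | intron | revcomp(primer_r)`), a
#' heterozygous allele haplotype differing from the reference only at the
#' configured true-variant positions, and — for the designated locus — a
#' pseudogene haplotype differing at `pseudogene_diff_count` positions.
#' Exon boundaries are guarded so no homopolymer run straddles them, which
#' keeps left-aligned indel coordinates on one side of the exon.
#'
#' @param config A [sim_config()].
#' @return A list of class `amplicon_panel` with tibbles `references`
#'   (`amplicon_id`, `locus`, `sequence`, `exon_start`, `exon_end`,
#'   `primer_f`, `primer_r`, `hp_weight`), `haplotypes` (`amplicon_id`,
#'   `hap_id`, `role`, `sequence`) and `truth_variants` (`amplicon_id`,
#'   `ref_pos`, `type`, `ref`, `alt`, `source`).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specs <- config$amplicon_specs
  refs <- vector("list", nrow(specs))
  haps <- list()
  truths <- list()

  locus_count <- table(specs$locus)
  locus_idx <- integer(0)

  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    locus_idx[sp$locus] <- sum(c(locus_idx[sp$locus], 0), 1, na.rm = TRUE)
    amp_id <- if (locus_count[[sp$locus]] > 1) {
      paste0(sp$locus, ".", locus_idx[[sp$locus]])
    } else {
      sp$locus
    }

    pl <- sp$primer_length
    il <- config$intron_length
    el <- sp$exon_length
    max_run <- if (sp$hp_weight == 0) 3 else 7
    primer_f <- random_sequence(pl, hp_weight = 0, max_run = 2)
    primer_r <- random_sequence(pl, hp_weight = 0, max_run = 2)
    insert <- random_sequence(2 * il + el, sp$hp_weight, max_run = max_run)

    seq_chars <- strsplit(paste0(primer_f, insert, revcomp(primer_r)), "")[[1]]
    exon_start <- pl + il + 1L
    exon_end <- pl + il + el

    # guarantee a homopolymer of length >= 4 inside the exon when enriched
    if (sp$hp_weight > 0) {
      exon_seq <- paste(seq_chars[exon_start:exon_end], collapse = "")
      if (max(scan_homopolymers(exon_seq)$length) < 4) {
        mid <- exon_start + el %/% 2
        seq_chars[mid:(mid + 3)] <- seq_chars[mid]
      }
    }
    # exon boundary guard: no run may straddle the exon interval
    if (seq_chars[exon_start - 1] == seq_chars[exon_start]) {
      seq_chars <- break_run_at(seq_chars, exon_start - 1L)
    }
    if (seq_chars[exon_end + 1] == seq_chars[exon_end]) {
      seq_chars <- break_run_at(seq_chars, exon_end + 1L)
    }
    ref_seq <- paste(seq_chars, collapse = "")

    refs[[k]] <- tibble(
      amplicon_id = amp_id, locus = sp$locus, sequence = ref_seq,
      exon_start = exon_start, exon_end = exon_end,
      primer_f = primer_f, primer_r = primer_r, hp_weight = sp$hp_weight
    )
    haps[[length(haps) + 1]] <- tibble(
      amplicon_id = amp_id, hap_id = paste0(amp_id, "*ref"),
      role = "reference", sequence = ref_seq
    )

    # allele haplotype: heterozygous true variants (substitutions)
    used <- integer(0)
    if (config$true_variant_count > 0) {
      v <- pick_variant_sites(seq_chars, exon_start, exon_end,
                              config$true_variant_count, used)
      used <- c(used, v$pos)
      allele_chars <- seq_chars
      allele_chars[v$pos] <- v$alt
      haps[[length(haps) + 1]] <- tibble(
        amplicon_id = amp_id, hap_id = paste0(amp_id, "*var"),
        role = "allele", sequence = paste(allele_chars, collapse = "")
      )
      truths[[length(truths) + 1]] <- tibble(
        amplicon_id = amp_id, ref_pos = v$pos, type = "sub",
        ref = seq_chars[v$pos], alt = v$alt, source = "allele"
      )
    }

    # pseudogene side-product for the designated locus
    if (sp$locus == config$pseudogene_locus && config$pseudogene_fraction > 0) {
      v <- pick_variant_sites(seq_chars, exon_start, exon_end,
                              max(3L, config$pseudogene_diff_count), used)
      pg_chars <- seq_chars
      pg_chars[v$pos] <- v$alt
      haps[[length(haps) + 1]] <- tibble(
        amplicon_id = amp_id, hap_id = paste0(amp_id, "*pseudo"),
        role = "pseudogene", sequence = paste(pg_chars, collapse = "")
      )
      truths[[length(truths) + 1]] <- tibble(
        amplicon_id = amp_id, ref_pos = v$pos, type = "sub",
        ref = seq_chars[v$pos], alt = v$alt, source = "pseudogene"
      )
    }
  }

  structure(
    list(
      references = bind_rows(refs),
      haplotypes = bind_rows(haps),
      truth_variants = if (length(truths)) bind_rows(truths) else
        tibble(amplicon_id = character(), ref_pos = integer(),
               type = character(), ref = character(), alt = character(),
               source = character())
    ),
    class = "amplicon_panel"
  )
}

# substitution sites >= 3 bp apart, alt base differing from both neighbors
# (so a variant never extends an adjacent homopolymer run)
pick_variant_sites <- function(chars, exon_start, exon_end, n, exclude) {
  cand <- setdiff(seq(exon_start + 1L, exon_end - 1L), exclude)
  cand <- cand[!cand %in% c(exclude - 1L, exclude + 1L, exclude - 2L, exclude + 2L)]
  pos <- integer(0)
  cand <- sample(cand)
  for (p in cand) {
    if (length(pos) == n) break
    if (all(abs(pos - p) >= 3)) pos <- c(pos, p)
  }
  pos <- sort(pos)
  alt <- vapply(pos, function(p) {
    sample(setdiff(BASES, c(chars[p - 1], chars[p], chars[p + 1])), 1)
  }, character(1))
  list(pos = pos, alt = alt)
}

#' Truth set of expected variants and pseudogene differences
#'
#' Converts panel ground truth into the lookup used by
#' [classify_variants()]: expected allelic variant keys per amplicon and
#' pseudogene difference keys for the affected locus.
#'
#' @param panel An [generate_references()] panel.
#' @return A list of class `truth_set` with tibbles `variants` and
#'   `pseudogene` (columns `amplicon_id`, `ref_pos`, `type`, `ref`, `alt`).
#' @export
truth_set_from_panel <- function(panel) {
  tv <- panel$truth_variants
  structure(
    list(
      variants = filter(tv, .data$source == "allele") %>% select(-"source"),
      pseudogene = filter(tv, .data$source == "pseudogene") %>% select(-"source")
    ),
    class = "truth_set"
  )
}

# ---- quality model -------------------------------------------------------

# piecewise-linear per-cycle quality curve (rise, plateau, decay)
profile_quality <- function(cycle, read_len, profile) {
  ramp <- min(profile$ramp_end, read_len)
  onset <- min(profile$decay_onset, read_len)
  q <- numeric(length(cycle))
  up <- cycle <= ramp
  q[up] <- profile$q_start +
    (profile$q_plateau - profile$q_start) * (cycle[up] - 1) / max(ramp - 1, 1)
  mid <- cycle > ramp & cycle <= onset
  q[mid] <- profile$q_plateau
  dn <- cycle > onset
  q[dn] <- profile$q_plateau +
    (profile$q_end - profile$q_plateau) * (cycle[dn] - onset) / max(read_len - onset, 1)
  q
}

# positional weight in error-rate space, normalized to mean 1 over the
# cycles where errors can be injected (so the configured mean rate is
# realized on the analyzed, primer-free part of the read)
profile_weight <- function(read_len, profile, norm_cycles = NULL) {
  p <- phred_to_error(profile_quality(seq_len(read_len), read_len, profile))
  if (is.null(norm_cycles)) norm_cycles <- seq_len(read_len)
  p / mean(p[norm_cycles])
}

apply_miscalibration <- function(q, spec) {
  switch(spec$type,
    identity = q,
    offset = q + spec$offset,
    step = dplyr::case_when(q > spec$threshold ~ q + spec$above,
                            q < spec$threshold ~ q + spec$below,
                            TRUE ~ q),
    abort(paste0("unknown miscalibration type: ", spec$type))
  )
}

empty_truth_events <- function() {
  tibble(
    read_id = character(), run_id = character(), amplicon_id = character(),
    ref_pos = integer(), read_pos = integer(), type = character(),
    length = integer(), ref = character(), alt = character()
  )
}

# ---- read simulation -----------------------------------------------------

#' Simulate one sequencing run
#'
#' Draws `reads_per_amplicon` reads per amplicon. Each read is a full
#' haplotype traversal (primer to primer). Indel errors arise per
#' homopolymer run with per-base probability
#' `indel_base_rate * slope^(L-1)`, realized as a net length-1 over/under
#' call per trial, left-aligned at the run start. Substitution errors arise
#' per reference-derived base with cycle-dependent probability averaging
#' `substitution_rate`. Reported qualities follow the quality profile,
#' minus `error_site_q_penalty` at error sites, passed through the
#' configured miscalibration and clamped to `[0, 40]`.
#'
#' @param panel Panel from [generate_references()].
#' @param config The [sim_config()].
#' @param run_index 1-based run number (`<= n_runs`).
#' @return List with tibbles `reads` (`read_id`, `run_id`, `amplicon_id`,
#'   `strand`, `seq`, `qual`, `length`, `source_hap`; `seq`/`qual` in
#'   as-sequenced orientation) and `truth` (injected events with reference
#'   coordinates and forward-orientation read positions).
#' @export
simulate_run <- function(panel, config, run_index) {
  stopifnot(inherits(config, "sim_config"))
  if (run_index > config$n_runs) abort("run_index exceeds n_runs")
  set.seed(config$seed + 7919L * as.integer(run_index))
  run_id <- paste0("run", run_index)

  refs <- panel$references
  reads_out <- vector("list", nrow(refs))
  truth_out <- vector("list", nrow(refs))

  for (k in seq_len(nrow(refs))) {
    ref <- refs[k, ]
    hp <- filter(panel$haplotypes, .data$amplicon_id == ref$amplicon_id)
    sim <- simulate_amplicon_reads(ref, hp, config, run_id)
    reads_out[[k]] <- sim$reads
    truth_out[[k]] <- sim$truth
  }
  list(reads = bind_rows(reads_out), truth = bind_rows(truth_out))
}

simulate_amplicon_reads <- function(ref, haps, config, run_id) {
  n <- config$reads_per_amplicon
  prof <- config$quality_profile
  pen <- config$error_site_q_penalty
  is_pg_locus <- ref$locus == config$pseudogene_locus &&
    any(haps$role == "pseudogene")

  # choose source haplotype per read
  roles <- character(n)
  if (is_pg_locus && config$pseudogene_fraction > 0) {
    pg <- runif(n) < config$pseudogene_fraction
  } else {
    pg <- rep(FALSE, n)
  }
  has_allele <- any(haps$role == "allele")
  roles[pg] <- "pseudogene"
  roles[!pg] <- if (has_allele) {
    sample(c("reference", "allele"), sum(!pg), replace = TRUE)
  } else {
    "reference"
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)

  # per-haplotype precomputation: chars, interior homopolymer runs, rates
  hinfo <- lapply(seq_len(nrow(haps)), function(i) {
    chars <- strsplit(haps$sequence[i], "")[[1]]
    L <- length(chars)
    pl <- nchar(ref$primer_f)
    pr <- nchar(ref$primer_r)
    runs <- scan_homopolymers(haps$sequence[i])
    runs$end <- runs$start + runs$length - 1L
    interior <- runs$start > pl & runs$end <= (L - pr)
    runs <- runs[interior, , drop = FALSE]
    runs$p <- pmin(config$indel_base_rate *
                     config$indel_length_slope^(runs$length - 1), 0.45)
    int_lo <- pl + 1L
    int_hi <- L - pr
    w <- profile_weight(L, prof, int_lo:int_hi)
    list(chars = chars, len = L, runs = runs, w = w,
         int_lo = int_lo, int_hi = int_hi)
  })
  names(hinfo) <- haps$role

  seqs <- character(n)
  quals <- character(n)
  ids <- paste0(run_id, ":", ref$amplicon_id, ":", seq_len(n), "/", strands)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    h <- hinfo[[roles[i]]]
    rd <- simulate_one_read(h, ref, config, strands[i])
    seqs[i] <- rd$seq
    quals[i] <- rd$qual
    if (length(rd$tr_type) > 0) {
      truths[[i]] <- list(read_id = rep(ids[i], length(rd$tr_type)),
                          ref_pos = rd$tr_ref_pos, read_pos = rd$tr_read_pos,
                          type = rd$tr_type, length = rd$tr_len,
                          ref = rd$tr_ref, alt = rd$tr_alt)
    }
  }
  truths <- truths[!vapply(truths, is.null, logical(1))]
  truth <- if (length(truths)) {
    tibble(
      read_id = unlist(lapply(truths, `[[`, "read_id")),
      run_id = run_id,
      amplicon_id = ref$amplicon_id,
      ref_pos = as.integer(unlist(lapply(truths, `[[`, "ref_pos"))),
      read_pos = as.integer(unlist(lapply(truths, `[[`, "read_pos"))),
      type = unlist(lapply(truths, `[[`, "type")),
      length = as.integer(unlist(lapply(truths, `[[`, "length"))),
      ref = unlist(lapply(truths, `[[`, "ref")),
      alt = unlist(lapply(truths, `[[`, "alt"))
    )
  } else {
    empty_truth_events()
  }
  list(
    reads = tibble(
      read_id = ids, run_id = run_id, amplicon_id = ref$amplicon_id,
      strand = strands, seq = seqs, qual = quals,
      length = nchar(seqs), source_hap = roles
    ),
    truth = select(truth, "read_id", "run_id", "amplicon_id", "ref_pos",
                   "read_pos", "type", "length", "ref", "alt")
  )
}

simulate_one_read <- function(h, ref, config, strand) {
  chars <- h$chars
  hap_len <- h$len
  runs <- h$runs

  # 1) net indel per interior homopolymer run: each base of a run of
  #    length L is an independent trial at rate p(L), half over-, half
  #    undercalls; the net is one left-aligned event
  net <- integer(nrow(runs))
  if (nrow(runs) > 0) {
    fo <- config$overcall_fraction
    k_ins <- rbinom(nrow(runs), runs$length, runs$p * fo)
    k_del <- rbinom(nrow(runs), runs$length, runs$p * (1 - fo))
    net <- k_ins - k_del
  }
  edited <- which(net != 0)

  ref_map <- seq_len(hap_len)
  bases <- chars
  ind_pos <- integer(0); ind_rpos <- integer(0); ind_type <- character(0)
  ind_len <- integer(0); ind_ref <- character(0); ind_alt <- character(0)
  if (length(edited) > 0) {
    for (j in rev(edited)) { # right-to-left keeps indices valid
      s <- runs$start[j]
      b <- runs$base[j]
      d <- net[j]
      idx <- match(s, ref_map)
      if (d > 0) {
        ref_map <- append(ref_map, rep(NA_integer_, d), after = idx - 1L)
        bases <- append(bases, rep(b, d), after = idx - 1L)
      } else {
        drop <- idx:(idx - d - 1L)
        ref_map <- ref_map[-drop]
        bases <- bases[-drop]
      }
    }
    for (j in edited) {
      s <- runs$start[j]
      b <- runs$base[j]
      d <- net[j]
      if (d > 0) {
        first_kept <- match(s, ref_map)
        ind_pos <- c(ind_pos, s - 1L)
        ind_rpos <- c(ind_rpos, first_kept - d)
        ind_type <- c(ind_type, "ins")
        ind_len <- c(ind_len, d)
        ind_ref <- c(ind_ref, "")
        ind_alt <- c(ind_alt, strrep(b, d))
      } else {
        first_kept <- which(ref_map >= s - d)[1] # first surviving base right of the cut
        ind_pos <- c(ind_pos, s)
        ind_rpos <- c(ind_rpos, first_kept - 1L)
        ind_type <- c(ind_type, "del")
        ind_len <- c(ind_len, -d)
        ind_ref <- c(ind_ref, strrep(b, -d))
        ind_alt <- c(ind_alt, "")
      }
    }
  }

  em_len <- length(bases)
  cycle <- if (strand == "+") seq_len(em_len) else rev(seq_len(em_len))
  w <- if (em_len == hap_len) {
    h$w
  } else {
    profile_weight(em_len, config$quality_profile,
                   h$int_lo:(em_len - (hap_len - h$int_hi)))
  }
  p_sub <- config$substitution_rate * w[cycle]

  # 2) substitutions on reference-derived interior bases
  eligible <- !is.na(ref_map) & ref_map >= h$int_lo & ref_map <= h$int_hi
  hit <- which(eligible & runif(em_len) < p_sub)
  sub_old <- character(0); sub_new <- character(0)
  if (length(hit) > 0) {
    sub_old <- bases[hit]
    sub_new <- vapply(sub_old, function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
    bases[hit] <- sub_new
  }

  # 3) qualities: true Q from the per-base error probability (positional
  #    substitution risk plus the homopolymer indel risk of the base's
  #    run, so long homopolymers read out at lower quality), valley at
  #    error sites, then miscalibration and clamping
  rl <- rle(bases)
  run_len <- rep.int(rl$lengths, rl$lengths)
  p_ind <- pmin(config$indel_base_rate *
                  config$indel_length_slope^(run_len - 1), 0.45)
  q_true <- error_to_phred(pmin(pmax(p_sub + p_ind, 1e-8), 0.999))
  err_sites <- hit
  if (length(ind_type) > 0) {
    for (r in seq_along(ind_type)) {
      err_sites <- c(err_sites, if (ind_type[r] == "ins") {
        ind_rpos[r]:(ind_rpos[r] + ind_len[r] - 1L)
      } else {
        ind_rpos[r]
      })
    }
  }
  err_sites <- err_sites[err_sites >= 1 & err_sites <= em_len]
  if (length(err_sites) > 0) {
    q_true[err_sites] <- q_true[err_sites] - config$error_site_q_penalty
  }
  q_rep <- round(apply_miscalibration(q_true, config$miscalibration))
  q_rep <- as.integer(pmin(pmax(q_rep, 0), 40))

  tr_ref_pos <- c(ind_pos, ref_map[hit])
  tr_read_pos <- c(ind_rpos, hit)
  tr_type <- c(ind_type, rep("sub", length(hit)))
  tr_len <- c(ind_len, rep(1L, length(hit)))
  tr_ref <- c(ind_ref, sub_old)
  tr_alt <- c(ind_alt, sub_new)
  ord <- order(tr_ref_pos)

  seq_fwd <- paste(bases, collapse = "")
  if (strand == "+") {
    seq_out <- seq_fwd
    qual_out <- intToUtf8(q_rep + 33L)
  } else {
    seq_out <- revcomp(seq_fwd)
    qual_out <- intToUtf8(rev(q_rep) + 33L)
  }
  list(seq = seq_out, qual = qual_out,
       tr_ref_pos = tr_ref_pos[ord], tr_read_pos = tr_read_pos[ord],
       tr_type = tr_type[ord], tr_len = tr_len[ord],
       tr_ref = tr_ref[ord], tr_alt = tr_alt[ord])
}

#' Simulate a complete multi-run dataset
#'
#' Runs [generate_references()] once and [simulate_run()] for every run,
#' returning everything downstream stages need, including ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `config`, `panel`, `reads`,
#'   `truth_events` and `truth_set`.
#' @export
simulate_dataset <- function(config) {
  panel <- generate_references(config)
  runs <- lapply(seq_len(config$n_runs), function(r) simulate_run(panel, config, r))
  structure(
    list(
      config = config,
      panel = panel,
      reads = bind_rows(lapply(runs, `[[`, "reads")),
      truth_events = bind_rows(lapply(runs, `[[`, "truth")),
      truth_set = truth_set_from_panel(panel)
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  cat(" ", nrow(x$panel$references), "amplicons,",
      length(unique(x$reads$run_id)), "runs,",
      nrow(x$reads), "reads,",
      nrow(x$truth_events), "injected error events\n")
  invisible(x)
}
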