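# pyroprofile

Error profiling for 454-style amplicon pyrosequencing.

Flow-based pyrosequencers call homopolymer lengths from light intensity,
which gives amplicon data a characteristic error profile: insertions and
deletions concentrated at homopolymer runs, rare substitutions, quality
decay along the read, and a "quality valley" at erroneous bases. For
diagnostic amplicon assays (the motivating case is HLA exon typing, where
samples with Sanger-verified genotypes are resequenced repeatedly), the
relevant questions are quantitative: what fraction of exon bases is wrong,
of which error type, at which read positions, how reproducible across runs
of the same library, and how well calibrated are the instrument's quality
scores?

`pyroprofile` answers these with a tested end-to-end pipeline plus a
synthetic read generator that stands in for raw sequencing data:

* **Simulation** — multi-run amplicon libraries over several loci with
  true allelic variants, a co-amplified pseudogene at a set fraction,
  homopolymer-length-dependent indel errors
  (rate `r * slope^(L-1)` per base of a length-`L` run), positionally
  modulated substitutions, piecewise-linear quality decay, error-site
  quality penalties and configurable estimated-vs-true quality
  miscalibration. Ground truth (per-read injected events) is retained.
* **Alignment** — primer trimming, strand resolution, semi-global
  alignment to the reference amplicon (free end gaps on the reference;
  match +2, mismatch −3, gap open −5, gap extend −2), left-normalization
  of indels in homopolymers, exon clipping.
* **Variants** — merged insertion/deletion/substitution events keyed by
  (amplicon, left-aligned position, type, bases), partitioned against a
  truth set into `true_variant` / `pseudogene_product` / `error`;
  bidirectional strand support per key.
* **Profiling** — per-type error rates (wrong bases over total exon
  bases), per-read statistics, cross-run reproducible errors, positional
  error histograms, per-run read metrics.
* **Quality analytics** — error-rate-space quality averaging
  (`Q = -10 log10(p)`), error-site vs 5-base-neighborhood quality,
  homopolymer background vs error-context distributions with a
  chi-square association test, homopolymer-length/quality correlation,
  estimated-vs-empirical quality calibration, per-position quality.

Everything is tibble-in/tibble-out and pipe-friendly; fitted profiles have
`tidy()`/`glance()` methods and `plot_*()`/`autoplot()` builders.

## Worked example

Simulate a three-run library over six HLA-like loci and profile it end to
end:

```r
library(pyroprofile)

cfg <- sim_config(n_runs = 3, reads_per_amplicon = 50, seed = 1)
res <- run_pipeline(pipeline_config(simulation = cfg), outdir = "reports")
res$profile
#> <error_profile>
#>   exon bases analyzed : 297,175
#>   erroneous bases     : 635 (0.21%)
#>   rates  ins/del/sub  : 0.11% / 0.05% / 0.05%
#>   reads with errors   : 445 / 900 (49.4%)
#>   reproducible errors : 20 keys in all 3 runs (30.08% of erroneous bases)
#>   median error cycle  : 220
```

The per-type breakdown and one-row summary follow broom conventions:

```r
tidy(res$profile)
#> # A tibble: 3 × 4
#>   type  bases     rate mean_length
#>   <chr> <dbl>    <dbl>       <dbl>
#> 1 ins     335 0.00113         1.02
#> 2 del     160 0.000538        1
#> 3 sub     140 0.000471        1.02
```

Insertions dominate (overcalls at homopolymers), events are ~1 base long,
and about half the reads carry at least one exon error at these rates.
Quality at error sites sits well below the surrounding bases — the
5-base-neighborhood comparison and the homopolymer-length correlation:

```r
res$quality$neighborhood$overall
#> # A tibble: 1 × 3
#>       n mean_q_error mean_q_neighborhood
#>   <int>        <dbl>               <dbl>
#> 1   625         9.76                17.8

res$context$correlation
#> # A tibble: 1 × 4
#>   estimate statistic  p.value     n
#>      <dbl>     <dbl>    <dbl> <int>
#> 1   -0.687     -23.6 1.81e-88   625
```

i.e. erroneous bases are flagged by a quality valley, and quality drops
significantly with the length of the associated homopolymer. `reports/`
receives TSV tables (classified events, rates, positional histogram,
calibration, context classes, run summary) and a `summary.json` with every
headline number; `plot_positional_errors()`, `plot_calibration()`,
`plot_context_distribution()`, `plot_position_quality()` and
`plot_error_quality()` draw the standard figures.

File-based inputs work the same way: FASTA references plus an amplicon
annotation TSV, per-run FASTQ, and an optional truth TSV
(`pipeline_config(paths = list(...))`). A thin command-line wrapper with
`simulate` and `profile` subcommands is installed at
`inst/cli/ampprofile.R`.

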