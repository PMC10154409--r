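# subteloscan

Telomere-proximity analyses for epigenomics: do upregulated transposable
elements, lost heterochromatin, new retrotransposon insertions and extra
chromatin contacts concentrate near chromosome ends?

Critically short telomeres — as in late-generation telomerase-knockout
(*Terc⁻/⁻*) mouse embryonic stem cells — are associated with derepression of
subtelomeric retrotransposons, loss of H3K9me3 from telomeres, new LINE1
insertions, elevated SNV/indel burdens and a shift of Hi-C contacts toward
chromosome ends. Each of those observations is, computationally, a
distance-to-chromosome-end analysis over standard genomics files. subteloscan
implements that family of analyses as tidy, seed-reproducible building
blocks for anyone studying positional effects relative to telomeres:

* **TE enrichment** — filter a differential TE-instance table (fold change
  > 1.5, p < 0.05, ≥ 5 uniquely mapped reads), split instances into
  subtelomere-adjacent vs non-adjacent at a distance threshold, and test
  enrichment against the superfamily's genomic density. For DE counts
  *a*/*b* (subtelomeric/not) and background *c*/*d*, the expected count is
  *n*<sub>DE</sub>(*a*+*c*)/(*a*+*b*+*c*+*d*) and significance is the
  two-sided exact hypergeometric probability-mass test, scanned over
  thresholds (1/20/50 Mb at mouse scale) with Benjamini–Hochberg adjustment.
* **Variant spectra** — wild-type baseline subtraction by exact allele,
  genomic-category spectra (promoter ±2 kb of TSS; 5′/3′ proximal and
  distal flanks; gene desert > 100 kb), 12- or 6-class single-base
  substitution spectra, and strict `depth > 10` CNV filtering.
* **Retrotransposition** — classify SV insertion sequences against a TE
  consensus library by k-mer seed coverage (k = 15, identity ≥ 0.5),
  subtract a baseline sample within a 100 bp breakpoint window, annotate
  insertion sites, and compare burdens with a conditional exact binomial
  test.
* **Telomeric reads & peaks** — phase-aware (TTAGGG)ₙ read classification
  (either strand, coverage ≥ 0.7 of the read), per-million normalisation,
  H3K9me3 peak classification into retrotransposon/subtelomere classes, and
  a flanking-gene median-log2FC metagene.
* **Hi-C subtelomeres** — parse Hi-C-Pro allValidPairs, count pairs into
  per-arm windows (5–60 Mb ladder, 100 kb terminal exclusion), normalise to
  percentages, and compare against chromosome-center windows.
* **Synthetic data** — a generator that plants recoverable ground truth
  (positional TE bias ρ, DE enrichment factor, telomeric read fraction,
  Hi-C distance decay with subtelomeric boost β, shared-baseline variant and
  insertion sets) behind a single master seed.

Everything takes and returns tibbles, pipes with dplyr, and has
`tidy()`/`glance()`/`autoplot()` where a fitted object warrants it.

## Worked example

Simulate a miniature genome (5 chromosomes, 6–20 Mb, thresholds scaled from
mouse proportions) with a planted 5-fold subtelomeric DE enrichment, then run
the enrichment scan:

```r
library(subteloscan)

cfg <- sim_config(seed = 42)
ds  <- simulate_dataset(cfg)

scan <- enrichment_scan(ds$de_table, cfg$genome,
                        thresholds = scale_threshold(c(1e6, 20e6, 50e6),
                                                     cfg$genome))
dplyr::filter(tidy(scan), direction == "up")
#> # A tibble: 9 × 9
#>   superfamily direction threshold observed  n_de expected odds_ratio   p_value adjusted_p
#>   <chr>       <chr>         <dbl>    <int> <int>    <dbl>      <dbl>     <dbl>      <dbl>
#> 1 LINE        up           92308.        9   155     2.56      4.42  0.000707    0.00424
#> 2 LINE        up         1846154.       50   155    45.5       1.16  0.413       0.892
#> 3 LINE        up         4615385.      110   155   105.        1.18  0.377       0.892
#> 4 LTR         up           92308.        6    98     1.13      7.57  0.000561    0.00424
#> 5 LTR         up         1846154.       28    98    28.9       0.953 0.909       1
#> 6 LTR         up         4615385.       62    98    66.4       0.809 0.319       0.892
#> 7 SINE        up           92308.       11   133     2.44      6.27  0.0000147   0.000264
#> 8 SINE        up         1846154.       41   133    37.9       1.13  0.553       0.952
#> 9 SINE        up         4615385.       85   133    89.3       0.857 0.446       0.892
```

The planted signal behaves like the real phenomenon: at the (scaled) 1 Mb
threshold every superfamily shows far more upregulated instances at
subtelomeres than the genomic density predicts (e.g. LINE: 9 observed vs
2.56 expected, adjusted p ≈ 0.004), and the enrichment dissolves as the
window widens to 20 and 50 Mb equivalents — observed ≈ expected, odds
ratios near 1.

The same dataset feeds the other stages:

```r
telomeric_read_rate(ds$reads$sequence)
#> # A tibble: 1 × 3
#>   telomeric_count total_count per_million
#> 1             180       50000        3600

v <- subtract_baseline(ds$variants_case, ds$variants_control)
variant_category_counts(v, ds$genes, ds$genome)
#> # A tibble: 9 × 3      (intron-heavy, as planted)
#>   category               SNV indel
#> 1 promoter                27     7
#> 2 five_prime_proximal     29    14
#> 3 five_prime_distal       57    14
#> 4 exon                    50    18
#> 5 intron                 151    43
#> ...
```

`run_pipeline(cfg, out_dir = "out")` runs every stage and writes the
simulated inputs plus one provenance-stamped TSV per result table;
identical seeds give byte-identical output. A thin CLI over the same
functions lives at `inst/scripts/subteloscan.R`
(`simulate`, `run-all`, `te-enrich`, `var-annotate`, `rt-classify`,
`chip-telo`, `hic-subtelo`).

## Vignette

`vignettes/subteloscan-methods.Rmd` documents the models, every tunable
parameter with its default and rationale, what the synthetic generator does
and does not emulate, and the numerical conventions (boundary rules,
tie-breaks, the two-sided exact-test convention, threshold scaling).
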