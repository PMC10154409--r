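---
title: "Telomere-proximity analyses: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere-proximity analyses: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subteloscan)
```

subteloscan implements the computational core of a telomere-proximity study
design: when telomeres become critically short (for example in
late-generation telomerase-knockout embryonic stem cells), transposable
elements (TEs) near chromosome ends become derepressed, heterochromatin
(H3K9me3) is lost from telomeres and subtelomeres, chromatin contacts
concentrate at chromosome ends, and new retrotransposition events and
mutations accumulate. Each of those claims rests on a specific, fairly
simple computation over standard file formats, and this package makes those
computations explicit, testable and reusable. This vignette documents the
models and the decisions behind them.

## The coordinate frame

All internal coordinates are 0-based half-open (BED convention); VCF and
valid-pair positions (1-based) are converted on ingest. A genome is a
tibble of chromosome lengths; the distance of a 0-based position $p$ to the
nearest end of a chromosome of length $L$ is $\min(p,\ L-1-p)$, so both
terminal bases are at distance 0. Mouse chromosomes are acrocentric and the
analyses treat the two ends of every chromosome identically; there is no
centromere model.

Three conventions are configurable but fixed by default, because the
underlying study does not state them:

* **Interval reference point.** An interval is subtelomeric if its *start*
  (5'-most genomic coordinate) is within the threshold. The start is stable
  across feature lengths; midpoint or any-overlap rules change counts only
  for features straddling the boundary.
* **Boundary rule.** "Within $X$ Mb" is strict: distance $< X$. An
  instance starting exactly $X$ bp from an end is not subtelomeric.
* **Arm assignment.** A position belongs to the left arm iff
  $p \le L/2$; the exact midpoint (possible only for even $L$) goes left.

## Genomic categories

Positions are classified against gene models with the precedence
promoter > exon > intron > flank-of-nearest-gene > gene desert:

| category | window |
|---|---|
| promoter | ±2 kb around any TSS, strand-independent |
| 5' proximal / distal | 2–10 kb / 10–100 kb upstream of the nearest gene |
| 3' proximal / distal | 0–10 kb / 10–100 kb downstream of the nearest gene |
| gene desert | > 100 kb from the nearest gene |

"Upstream" and "downstream" are strand-aware relative to the nearest gene;
unstranded genes are treated as `+` with a warning. Intergenic positions
within 100 kb of a gene that fall outside every named flank window get the
explicit `intergenic_other` label rather than being silently dropped; with
the default widths that bin is empty (the flank windows tile 0–100 kb on
both sides), but it becomes reachable when the windows are narrowed.
Nearest-gene ties (equal gap to two genes) are broken by input order, which
makes the classification reproducible; the test suite checks the
interval-index implementation against a brute-force per-gene scan at every
position it tries. Variants and insertions are classified at their leftmost
affected reference base; input alleles are assumed left-normalised, and no
re-alignment is attempted.

## Subtelomeric TE enrichment

The headline statistic asks whether upregulated TE instances concentrate
near chromosome ends. Instances are filtered the way the study filters
them: coverage of at least 5 uniquely mapped reads (instances below this
are removed from the analysis entirely, including the background), fold
change above 1.5 in the tested direction, and p below 0.05. For each
superfamily, direction and distance threshold the 2×2 table

|  | subtelomeric | not |
|---|---|---|
| DE instances | a | b |
| expressed non-DE instances | c | d |

is tested with a two-sided exact hypergeometric test, and the expected
count is the genomic-density baseline $n_{DE} \cdot (a+c)/(a+b+c+d)$. Two
points deserve notes:

* **Background universe.** The default background is the *expressed*
  instances of the superfamily (those passing the coverage filter), because
  the coverage filter is defined per superfamily before any positional
  classification; the full annotated universe is available via
  `background = "annotated"`. Both are implemented because the distinction
  genuinely changes the denominator on real data.
* **Two-sided convention.** The p-value is the sum of hypergeometric
  probabilities of all tables (at fixed margins) whose probability does not
  exceed the observed table's, with a relative tie tolerance of $10^{-7}$
  — the convention of the common exact-test implementations, and the one a
  reader will reproduce with `fisher.test()`. The odds ratio reported is
  the sample cross-product $ad/bc$ (infinite when $bc = 0$), not the
  conditional MLE.

The scan runs over thresholds of 1, 20 and 50 Mb on a mouse-scale genome
(monotone widening; enrichment present at 1 Mb and gone by 50 Mb is the
signature of a telomere-proximal effect) and adjusts p-values with
Benjamini–Hochberg across all tests of the scan; the adjustment method is a
choice, since the source analyses report only "adjusted P". Pooling is
genome-wide; a per-chromosome breakdown can be obtained by filtering the
input table, but the default follows the pooled design.

## Variant spectra

Case variant calls are normalised to a matched wild-type baseline by exact
allele identity (chromosome, position, ref, alt); a position-only mode
exists for indel representation drift between callers. Single-base
substitutions are reported either as 12 directional classes or collapsed to
the 6-class pyrimidine-reference convention (purine-reference classes are
mapped to their reverse complement); both are provided because heatmaps in
this literature use either. CNV segments are filtered by mean depth with a
strict `depth > 10` rule, exactly as printed.

## Insertion classification

Structural-variant insertions (VCF `SVTYPE=INS`, sequence from ALT or
`INFO/SVINSSEQ`) are assigned to TE families against a consensus library
by k-mer evidence: the identity score of an insertion against a family is
the fraction of insertion bases covered by at least one shared k-mer
(forward or reverse complement, better of the two), with defaults $k = 15$
and call threshold 0.5. An exact consensus substring scores 1 for any
$k$ up to its length; a uniform-random sequence scores ≈ 0 against any
realistic library. Seed *coverage* rather than the raw shared-k-mer
fraction is used deliberately: isolated substitutions each destroy up to
$k$ overlapping k-mers, so the raw fraction collapses to
$(1-e)^k \approx 0.46$ at a per-base divergence of $e = 0.05$ — below any
sensible call threshold — while the covered fraction stays near 0.8 and
degrades gracefully with divergence. Ties between families are broken by
the longer consensus, then name. Baseline (e.g. MEF) subtraction for
insertion calls uses a 100 bp window, reflecting long-read breakpoint
jitter.

The case/control burden comparison is a conditional exact binomial test:
given $n$ events split $x$ vs $n-x$ under equal exposure, the two-sided
p-value of $x \sim \mathrm{Binomial}(n, 1/2)$ (probability-mass method;
exposure ratio configurable). The source analyses do not name their test,
so this choice is documented rather than inherited, and the printed
p-values of the original figure are not reproduction targets.

## Telomeric reads

The study defines telomeric reads operationally through an aligner run
against a (TTAGGG)$_n$ reference. Aligner seed parameters do not transfer
to a reimplementation, so the package re-specifies the rule in an
aligner-free, phase-aware form: a read is telomeric when, in the best of
the 6 phase offsets on the forward strand or the 6 on the reverse
complement, whole in-frame repeat units matching with at most
`max_mismatches_per_unit` mismatches (default 0) cover at least
`min_coverage_fraction` (default 0.7) of the read length. The defaults
make pure repeat reads of any phase pass, allow one substitution per unit
when the mismatch budget is raised to 1, and push the false-positive rate
on uniform-random 150-mers below $10^{-4}$ (empirically 0 in $10^5$
reads). Rates are normalised to reads per million.

H3K9me3 peaks are classified by two independent labels — overlapping a TE
instance by ≥ 1 bp, and having a subtelomeric start — whose conjunction is
the subtelomeric-retrotransposon class; all four 2×2 cells are reported.
Any-overlap (not containment) is used because the overlap convention is
unstated in the source; with planted compositions the tally arithmetic
reproduces printed percentages exactly (200 of 512 → 39.06 %). The
flanking-gene metagene takes, per peak direction, genomic side (left/right
of the peak, not gene strand) and window $w$, all genes whose TSS is within
$(0, w]$ of the peak boundary, a gene contributing once per peak, and
reports the median expression log2 fold change; window sizes are a required
user parameter because the source figure does not state them.

## Hi-C subtelomere profiling

Valid pairs (Hi-C-Pro allValidPairs dialect) are counted into per-
chromosome, per-arm windows: a pair is counted in cell (chromosome, arm,
$w$) when at least one end lies at distance $[e, w)$ from that chromosome
end, where $e$ is the terminal exclusion (100 kb at mouse scale — the
heterochromatic terminus yields few reads). A pair with both ends in the
same cell counts once ("interactions within the region"); ends in
different cells credit each cell once; trans pairs count toward the arm
their end touches ("with other regions"), with a cis-only flag. Counts are
normalised as percentages of the total pair count, and the same rule
applied to a window centred at $L/2$ gives the chromosome-center baseline.
Raw valid pairs are counted directly — no binning, no ICE balancing — as
the windowed analysis operates upstream of matrix construction.

## The synthetic-data generator

Every analysis is exercised on generated data with planted, recoverable
truth. The miniature genome is 5 chromosomes of 20/16/12/9/6 Mb; every
distance parameter of the analyses is scaled by the ratio of the
assembly's median chromosome (12 Mb) to a 130 Mb reference median, so
1 Mb → ≈ 92 kb, 100 kb → ≈ 9.2 kb and the 5–60 Mb Hi-C ladder scales
proportionally. Defaults: 8 genes/Mb with random exon structure; eight TE
families across LINE/LTR/SINE with 500–1500 copies each; reads of 125 bp
with a telomeric fraction of 0.3 % (the order of magnitude a wild-type
H3K9me3 sample shows); $5\times10^4$ valid pairs with distance-decay
exponent $\alpha = 1$ and a 2-fold subtelomeric boost; 300 shared + 500
case-specific variants with an intron-heavy category weight profile; 60
case vs 20 control insertions drawn from the young-LINE1-heavy family mix,
fragment lengths 200–3000 bp at 5 % per-base substitution. Each
sub-simulator draws from its own stream derived from the master seed, so
adding a generator never perturbs the others, and same-seed runs are
byte-identical down to the serialized files.

Three planting mechanisms matter for interpretation:

* **TE positional bias** uses the mixture rule: a copy lands in the
  subtelomeric zone (fraction $f$ of the genome) with probability
  $\rho f / (\rho f + 1 - f)$, so $\rho = 5$, $f = 0.1$ gives ≈ 35.7 %
  subtelomeric copies.
* **DE-label enrichment** multiplies the baseline up-label probability by
  the enrichment factor inside the zone (capped at 1). Labeled instances
  receive fold changes and p-values that pass the study filters and are
  always expressed; unlabeled instances fail the filters and are expressed
  with probability 0.8. Coupling labels to expression keeps the planted DE
  count interpretable; it slightly enriches the expressed universe for
  labeled instances, which is immaterial for the tests built on it.
* **Hi-C boost** composes the cis sample from decay-model candidates so
  that the zone-touching pair fraction is exactly $\beta$ times the
  baseline fraction. An earlier per-anchor multiplier design recovered
  only ≈ 1.8 of a planted 2 because the unboosted second end dilutes the
  pair-level union; composing the sample at the pair level removes that
  bias, and a $\beta = 2$ run against a $\beta = 1$ run recovers the
  boost within ~1 % at $10^5$ pairs.

The generator emulates coordinates, labels and sequence content, not
sequencing physics: no alignment artifacts, mappability, PCR duplicates,
GC bias, or real consensus sequences (the library is random sequence under
familiar family names, which is sufficient because classification only
requires internal consistency between library and insertions). Passing
tests therefore demonstrate that the *computations* are correct and
well-calibrated on data with known structure — not that any biological
conclusion transfers to a particular real dataset.

## Calibration and test scales

The exact test's null calibration is checked in a near-continuous regime:
uniform 10 Mb chromosomes with a 500 kb zone (10 % of the genome), 2000
instances per superfamily and a 15 % baseline DE rate, i.e. ≈ 300 DE
instances per replicate. The regime was chosen by computing the exact
rejection probability of the test at nominal 0.05 over candidate margins:
exact tests are conservative under discreteness, and with expected
subtelomeric DE counts below ~10 the true size drops to 0.02–0.03, which
says nothing about the implementation. At the chosen margins the
theoretical size is 0.049 and 1000 simulated replicates land within a
percent of it. Power is checked at the study-like condition of ≈ 50 DE
instances with a planted 5-fold enrichment (detection ≈ 0.99 at
p < 0.05). Simulation scales throughout the suite (1000 null replicates,
200 power replicates, $10^5$ reads/pairs, 500 insertions, $10^4$ classifier
positions) are the package's chosen verification sizes; they keep the full
suite in the minutes range on a single core while leaving standard errors
well inside the asserted bands.

## Known limitations

* The genomic-category classifier assigns flank categories from the single
  nearest gene; a position 9 kb downstream of gene A and 9.5 kb upstream of
  gene B is 3' proximal of A, even though a promoter-centric view might
  prefer B. Only the promoter label aggregates over all genes.
* Baseline subtraction is identity-based, not likelihood-based; shared
  variants called with slightly different alleles in case and control
  survive subtraction unless position-only matching is enabled.
* The telomeric-read rule scores whole in-frame units only; a read with a
  single-base indel inside the repeat tract shifts frame and can fail at a
  strict coverage threshold. Raising the mismatch budget does not rescue
  indels.
* `run_pipeline()` covers the stages whose inputs the simulator generates;
  peak-based analyses (classification, metagene) are exercised directly in
  the test suite with constructed peak tables, since the generator does not
  emit a peak caller's output.
* Valid-pair parsing keeps the whole file in memory; at the intended desk
  scale (≤ a few million pairs) this is a non-issue, but chromosome-scale
  production data would want a chunked reader.
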