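---
title: "Methods: consensus reconstruction from degraded reads, node dating, and meristic morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus reconstruction from degraded reads, node dating, and meristic morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem this package addresses

Wet-collection museum specimens are often the only source of genetic
material for rare or extinct taxa, but decades in alcohol (sometimes after
formalin fixation) leave DNA fragmented into short molecules, chemically
damaged, and swamped by microbial contamination. Recognising a distinct
lineage from such a specimen requires three things to work together:

1. recovering a usable mitochondrial sequence from a low-endogenous-content
   short-read library, by iterative reference-guided mapping and
   majority-rule consensus calling;
2. placing the recovered sequence on a time scale, via Bayesian node dating
   on a fixed topology under a relaxed molecular clock with near-fixed
   secondary calibrations; and
3. corroborating the molecular signal with meristic morphology — scale
   counts compared between populations with chi-squared / Fisher / ANOVA /
   ANCOVA tests and visualised by a standardised PCA.

`museomics` implements all three stages, plus a synthetic-data module that
generates every input the pipeline needs, so the whole workflow is testable
end to end without any sequence downloads.

# Synthetic data: what is emulated, and what is not

`simulate_reads()` emulates a single-end 75 bp shotgun library from a
degraded extract. Fragment lengths are lognormal (the conventional
assumption for archival DNA; no empirical length distribution is available
for this kind of material), truncated to `[20, 2 * read_len]`; the mean/SD
default of 60/25 bp reflects typical fluid-preserved tissue. Endogenous
fragments are drawn until the emitted bases reach `coverage * genome
length`; contaminant fragments from a user-supplied unrelated genome are
added to hit the requested endogenous read fraction. Each read carries
truth metadata (source, coordinates, strand), so realised endogenous
fractions and mapping accuracy are exactly computable.

Cytosine-deamination damage follows the standard terminal signature:
C→T at the 5' end with probability `delta5 * decay_lambda^i` at offset
`i`, and symmetrically G→A at the 3' end. It is disabled by default
because uracil-excision (UDG) treatment removes this damage class
enzymatically in the laboratory protocol the simulator mirrors; enabling
it lets the mapper's and caller's tolerance to residual damage be
exercised. Damage is applied to endogenous fragments only — the
contaminant background is modelled as modern (microbial) DNA.

Not emulated: paired-end reads, per-cycle quality profiles, indels,
chimeric fragments, and index hopping. Consequently a green test suite
demonstrates correctness of the algorithms under these assumptions, not
robustness to, say, heavy indel error or adapter read-through beyond the
modelled form.

`simulate_morphology()` draws integer scale counts as rounded normals per
population-by-sex group, clamped to the published observed range of each
character. Clamping (rather than resampling) keeps symmetric ranges
unbiased and is transparent; for asymmetric ranges it shifts the mean by a
few hundredths of a scale row, which is far below the between-population
differences of interest. The default group parameters are the published
rinkhals summaries (e.g. Zimbabwe female ventrals 128 ± 1.6, range
126–130); the default group sizes mirror the published sample (6/14 SA
females/males, 6/5 ZW). Body sizes (`svl`, `tl`) use a sexually dimorphic
tail-to-body ratio (0.21 male, 0.19 female, matching the type specimens'
proportions) so the ANCOVA workflow has realistic structure. Characters
are drawn independently within groups — real scale counts are weakly
correlated within populations, so synthetic PCA variance shares are driven
by between-group separation only.

# Read QC

`trim_adapter()` removes, per read, the longest suffix exactly matching a
prefix of the adapter (minimum one base, the single-base-overlap setting
used for short-fragment libraries); a full internal adapter occurrence
removes the occurrence and everything 3' of it. Matching is exact by
default; a `max_error_rate` is exposed but off. Note that with a one-base
minimum overlap, a read whose last base happens to equal the adapter's
first base loses that base — an unavoidable property of single-base
trimming, and the reason the downstream 30 bp length filter
(`length_filter()`) exists.

# Mapping

`map_reads()` is an ungapped seed-and-extend mapper sized for mitogenome
work. A placement is admissible when its mismatch count is within
`floor(max_mismatch_frac * L)`; `N` mismatches everything. This budget is
simpler than the expected-error integral used by `bwa aln -n`, which is
acceptable because stringency is used comparatively (a sweep across
0.04/0.01/0.001), not as a calibrated error model. Ungapped alignment is a
deliberate restriction: at 75 bp on mitochondrial DNA, indel handling adds
little, and deletions relative to the reference simply appear as coverage
gaps.

Seeding is provably lossless: the read is partitioned into `budget + 1`
blocks with one exact seed per block, so by pigeonhole any placement
within budget yields at least one exact seed hit. When `(budget + 1) * k`
exceeds the read length the seed length is reduced (minimum 4), and if
even that cannot fit, the mapper falls back to an exhaustive scan. The
test suite holds the mapper to exact equality with an exhaustive-scan
oracle, including mismatch counts and mapping qualities.

Mapping quality is a defined deterministic function, not an estimator:
60 when no admissible competitor exists, 0 for an exact tie, otherwise
`min(60, 30 * (second_best - best))`. The quality-30 filter
(`filter_mapq()`) therefore keeps exactly the reads whose best placement
beats all competitors by at least one mismatch — the "unique-ish
placement" semantics of the conventional `-Q 30` filter. Ties are resolved
deterministically (plus strand first, then smallest start) so runs are
reproducible. Circular references are handled by a wrap-around extension
of `read_len - 1` bases, with starts reported modulo the reference length
and pileups wrapping accordingly.

`remove_duplicates()` keeps one alignment per `(start, end, strand)` key —
the classical PCR-duplicate criterion for single-end data — preferring the
highest mapping quality, then the lexicographically first read id.

# Consensus reconstruction

`build_pileup()` counts A/C/G/T per column; depth is the sum of those four
counts, so `N` read bases carry no evidence. `call_consensus()` applies a
majority rule per column: below `min_depth` the call is `N`, except that a
column with exactly zero coverage may take the reference base when
reference fill is on ("retaining the reference for regions lacking mapped
reads" is read as depth == 0 exactly; depths 1..min_depth-1 yield `N`).
Otherwise the modal base is called iff its frequency reaches the threshold
— comparisons use `>=`, so a 17/20 = 0.85 column is called at threshold
0.85; this boundary convention is declared and tested because the original
GUI tool's behaviour is undocumented. Ties among modal bases give `N`, not
IUPAC codes, because downstream alignment treats ambiguity as missing
data.

`iterative_refine()` is the heart of the pipeline: map all reads with a
permissive budget (0.10 — generous enough that reads from a source several
percent diverged from the starting reference still seed round one), call
a 50% majority consensus with reference fill and minimum depth 1, and use
it as the next mapping reference; stop when the mapped read-id set
stabilises or after 10 rounds. Whether the original procedure applied a
minimum depth during iteration is unstated; depth 1 with zero-depth
reference fill is the most permissive faithful reading and converges in
2–4 rounds in practice. The returned consensus is called from the final
alignment under the stringent rule (90%, depth 3, no fill).
`final_stringent_call()` then re-maps everything with the strict budget
(0.04) and calls an 85%/depth-10 consensus, so every surviving base rests
on at least ten independent observations. `extract_regions()` reports
maximal runs of depth >= 3 — the rule used to decide which parts of a
sparse historical alignment are trustworthy — in 0-based half-open
coordinates (BED on disk; 1-based inclusive in printed reports).

Insertions relative to the reference are not representable (ungapped
mapper); two identical mitochondrial control regions, as many snakes
carry, would fold onto one locus and are outside scope.

# Node dating

`log_likelihood()` is Felsenstein pruning over compressed site patterns,
per partition, with GTR exchangeabilities entering through the
eigensystem of the symmetrised rate matrix (scaled to one expected
substitution per unit branch length). Rate variation uses four
equal-probability discrete-gamma category means; invariant sites are a
plain zero-rate mixture class with weight `p_inv` (no re-scaling of the
gamma mean — the convention is declared here because implementations
differ). Gaps and `N` are missing data. The kernel is verified three ways:
closed forms (zero-length trees, two-taxon transition probabilities),
exhaustive summation over ancestral states for every rooted topology with
up to five tips, and an independent likelihood implementation on larger
trees.

`run_mcmc()` samples on a fixed topology — the study design treats the
tree as known (highly supported, constrained) and asks only for node ages.
The model: node ages under a Yule prior with declared normalisation
`(n - 1) log(lambda) - lambda * sum(ages)`; per-branch lognormal rate
multipliers with real-space mean 1 and log-sd `clock_sd` (the uncorrelated
relaxed clock); a mean clock rate; normal calibrations on MRCA ages
(default sd 0.01 Myr, which effectively pins a node while keeping the
posterior proper); and hyperpriors `lambda ~ Lognormal(0, 2)`,
`clock_sd ~ Exp(1)`, `clock_rate ~ Lognormal(0, 5)`, gamma shape
`~ Lognormal(0, 1.5)`, flat `p_inv`, and lognormal exchangeabilities with
the A–G rate fixed at 1 for identifiability. Base frequencies are fixed
empirical, estimated from each partition with a single pseudocount.

Proposals are node-age moves (a coarse uniform draw within the node's
current age bounds, plus a fine Gaussian step whose scale matches the
smallest calibration sd, so near-fixed nodes still mix), a root-age scale,
a whole-tree scale, and multiplicative scales for the scalar parameters.
Node-age bounds depend only on neighbouring ages, making the uniform
within-bounds draw symmetric. Initial ages come from topological node
heights scaled to 1.25 times the oldest calibration, with calibrated
nodes pinned to their prior means and order repaired; a state that cannot
be repaired is an error.

Chain lengths: the production-scale default is 500,000 generations
sampled every 100 (20 million generations are a flag away), with a 10%
burn-in. The package's own validation experiments use scaled-down chains
— 8 taxa, 1 kb, 100,000 generations thinned to every 25th sample with a
30% burn-in (short chains spend proportionally longer in their transient,
hence the larger discard) — under which 95% HPD intervals cover true
strict-clock node ages in ≈ 95% of node-by-replicate checks, and a run on
an all-missing alignment returns the calibration prior to within
Monte-Carlo error. `summarize_trace()` reports, per parameter, the
posterior mean, the shortest 95% interval, and an effective sample size
`n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
first non-positive term (a constant trace has ESS `n` by convention).

`concatenate()` assembles the partitioned matrix: per-gene blocks, taxa
missing from a gene padded with `N` (the historical specimen contributes
only the two ribosomal fragments), and protein-coding genes split into
codon-position partitions with the frame restarting at each gene boundary.

# Morphometrics

All test statistics are computed from first principles and cross-checked
against the standard R implementations in the test suite. The chi-squared
test is Pearson's statistic with the Yates correction behind a flag
(default off — whether the original analysis used it is not stated, so
both variants are available). Fisher's exact test enumerates the
hypergeometric support directly, with the customary `1 + 1e-7` tolerance
when comparing table probabilities; larger-than-2x2 tables get a
Monte-Carlo version via `r2dtable`. ANOVA and ANCOVA use sequential
(Type I) sums of squares via QR projections, effects ordered population,
sex, interaction (covariate first for the ANCOVA) — the convention of
common statistical environments, stated explicitly because meristic
samples are unbalanced and the SS type changes F values; a constant
factor degenerates gracefully to the lower-way analysis. An empty cell in
the two-way layout drops the interaction with a warning.

`pca_standardized()` standardises each character to zero mean and unit
(n-1) SD and eigendecomposes the covariance of the standardised data (the
correlation matrix), so eigenvalues sum to the number of characters —
a built-in numerical check. Specimens missing any selected character are
excluded (complete-case), mirroring how preservation-limited data shrink
the ordination sample. Eigenvector signs are fixed so each component's
largest-magnitude loading is positive, making loadings comparable across
runs and software.

# Numerical and engineering notes

* Mapper, pileup and pruning inner loops are in C++ (Rcpp); everything
  else is vectorised R on tibbles.
* Pruning partials are rescaled per pattern when they drop below 1e-200;
  transition probabilities are clamped at zero before use.
* All coordinates are 0-based half-open internally; only printed reports
  are 1-based inclusive.
* Every simulator takes an explicit integer seed and is byte-reproducible;
  the MCMC is reproducible for a fixed seed.
* Known limitations: no gapped alignment, no IUPAC ambiguity output, no
  topology inference (fixed-tree dating only), no BEAST XML
  interoperability, and the +I convention noted above.
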