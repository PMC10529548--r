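# museomics

An integrative species-delimitation toolkit for museum genomics, built for
the situation where the only tissue of a candidate species is a decades-old
fluid-preserved specimen: DNA fragmented to tens of base pairs, mostly
microbial, and no close reference genome. The package covers the three
analysis stages such a study needs, plus a synthetic-data module that
generates every input, so the whole workflow runs and is tested without any
downloads.

**Who it is for:** systematists and museum-genomics practitioners who want a
scriptable, fully reproducible R version of the standard
degraded-specimen workflow — and a sandbox in which each stage can be
validated against ground truth.

## What it implements

**1. Mitochondrial consensus from degraded reads.** Adapter trimming
(single-base overlap) and a 30 bp length filter; an ungapped seed-and-extend
mapper with a mismatch budget `floor(f · L)` per read, deterministic mapping
qualities (60 unique / 0 tied / `min(60, 30·gap)` between), quality-30
filtering and PCR-duplicate removal; endogenous-content assessment by a
stringency sweep (f = 0.04, 0.01, 0.001). Reconstruction is iterative
majority-rule refinement: map at a permissive budget, call a 50% consensus
(reference-filled at zero depth), remap against the new consensus until the
mapped read set stabilises (≤ 10 rounds), then a stringent 90%/depth-3 call
and a final strict remap with an 85%/depth-10 call. Trustworthy stretches
are maximal runs of depth ≥ 3 (`extract_regions()`, BED output).

**2. Bayesian node dating on a fixed topology.** Partitioned GTR+Γ(+I)
pruning likelihood (codon-position partitions for protein-coding genes,
missing loci padded with N), an uncorrelated lognormal relaxed clock
(real-space mean 1, log-sd σ), a Yule tree prior, normal node calibrations
(sd 0.01 Myr pins a node), and Metropolis–Hastings MCMC over node ages,
clock rate, branch-rate multipliers and substitution-model parameters.
Summaries are posterior means, shortest 95% HPD intervals, and ESS
`n / (1 + 2 Σ ρ_k)`.

**3. Meristic morphometrics.** Pearson chi-squared (optional Yates),
Fisher's exact test by hypergeometric enumeration, two-way ANOVA and
SVL-covariate ANCOVA with sequential (Type I) sums of squares, and PCA of
characters standardised to zero mean and unit SD (eigenvalues sum to the
number of characters; complete-case specimens; sign-stabilised loadings).

Everything returns tibbles (or tidy-able objects with `tidy()` / `glance()`
/ `augment()` / `autoplot()` methods) and chains with the pipe.

## Worked example

Simulate a degraded library (25× endogenous coverage at 30% endogenous
fraction against a bacterial background), assess purity, and rebuild the
mitogenome starting from a 6%-divergent reference:

```r
library(museomics)

mt     <- simulate_reference(8000, gc = 0.42, seed = 11, id = "mt")
contam <- simulate_reference(40000, gc = 0.5, seed = 12, id = "bact")
cfg    <- read_sim_config(coverage = 25, endogenous_fraction = 0.3,
                          contaminant_ref = contam, seed = 13)
lib    <- simulate_reads(mt, cfg)

reads <- lib$reads |> trim_adapter() |> length_filter(30)
endogenous_sweep(reads, mt)
#> # A tibble: 3 × 4
#>   stringency n_mapped n_total fraction_mapped
#>        <dbl>    <int>   <int>           <dbl>
#> 1      0.04      3382   11337           0.298
#> 2      0.01      3222   11337           0.284
#> 3      0.001     3222   11337           0.284
```

The sweep recovers the simulated 30% endogenous fraction, shrinking as the
mismatch budget tightens. Refinement from a divergent starting reference
converges in four rounds:

```r
start_ref <- mutate_sequence(mt, 0.06, seed = 14)
res <- iterative_refine(reads, start_ref)
res$log
#> # A tibble: 4 × 4
#>   iteration n_mapped n_changed converged
#>       <int>    <int>     <int> <lgl>
#> 1         1     3024       500 FALSE
#> 2         2     3412         4 FALSE
#> 3         3     3415         0 FALSE
#> 4         4     3415         0 TRUE

fin <- final_stringent_call(reads, res$consensus)
extract_regions(fin$pileup, min_depth = 3)
#> # A tibble: 1 × 4
#>   ref_id start   end mean_depth
#>   <chr>  <int> <int>      <dbl>
#> 1 mt         5  7996       24.2
```

The strict 85%/depth-10 call covers 99.6% of sites and is 100% identical to
the simulation truth over called sites. Morphology runs the same way:

```r
m <- simulate_morphology(seed = 15)   # two-population scale-count table
two_way_anova(m, "subcaudals")
#> # A tibble: 3 × 5
#>   term              df statistic   p_value method
#>   <chr>          <int>     <dbl>     <dbl> <chr>
#> 1 population         1    22.5   0.0000603 two-way ANOVA
#> 2 sex                1     1.38  0.250     two-way ANOVA
#> 3 population:sex     1     0.151 0.701     two-way ANOVA

glance(pca_standardized(m))
#> # A tibble: 1 × 4
#>   n_specimens n_characters pc1_percent pc2_percent
#>         <int>        <int>       <dbl>       <dbl>
#> 1          31            4        52.9        21.1
```

The subcaudal count separates the populations decisively (F = 22.5 on
1 and 27 df) while sex and the interaction do not, and the first principal
component — higher counts in all four characters — carries half the
standardised variance. For dating, see `?run_mcmc` and the methods
vignette (`vignettes/museomics-methods.Rmd`).

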