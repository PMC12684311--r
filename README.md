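# gfchrono

Temporal gene-flow and demography from pool-sequenced population genomes.

## The problem

Fragmentation of a species' habitat cuts gene flow between the remaining
populations, but large populations lose genetic variation so slowly that
today's diversity and differentiation statistics mostly reflect the past.
`gfchrono` reconstructs *when* gene flow between population pairs changed:
it fits a two-population isolation-with-migration (IM) model to the folded
joint site frequency spectrum (2dSFS) repeatedly, each time splitting gene
flow into a recent epoch `[0, X)` and an older epoch `[X, T_split)`, scans
the breakpoint X across a grid (100 to 14,000 generations in steps of 100
at full scale), and then deconvolves the integrated recent-epoch estimates
t2(X) into per-interval rates.

The deconvolution rests on the nesting of the estimates: t2 at X is the
mean of the actual per-interval rates over the `n = X/100` intervals it
integrates,

    Fit_X = (Act_1 + ... + Act_n) / n
    Act_n = Fit_X * n - (Act_1 + ... + Act_{n-1})

so, for example, fitted values of 0.003 at X = 500 and 0.0035 at X = 600
imply a rate of `6 x 0.0035 - 5 x 0.003 = 0.006` in the 500–600 generation
interval. Confidence bands come from bootstrapping population pairs
(10,000 replicates at full scale).

Around that core the package provides: pooled-VCF site filtering (indel
flanks, depth bounds, biallelic-only, BED masks) with per-rule removal
tallies; Nei nucleotide diversity `2pq·n/(n−1)` and pairwise Fst on allele
frequencies; folded and joint SFS construction with hypergeometric
down-projection; isolation-by-distance regression (haversine distances,
OLS) and UPGMA clustering; a fast two-deme structured-coalescent engine
(C++) with piecewise migration and piecewise-exponential sizes; aggregation
of step-function Ne trajectories (z-transform, cross-population mean,
population-level bootstrap); and a synthetic-data module that generates
pooled VCFs, masks, Ne trajectories and scan fixtures with known truth.

## A worked example

Everything below runs on synthetic data with known truth — no downloads.

```r
library(gfchrono)

truth <- im_model(5000, 5000, 20000, t_split = 20000, x_break = 20000,
                  m_recent = 5e-5, m_old = 5e-5)
ds <- generate_pooled_dataset(truth, out_dir = tempfile(), sites = 2000, seed = 1)
pools <- lapply(ds$vcf_paths, read_pooled_vcf, pool_n = 100)
pools <- lapply(pools, filter_sites)

sapply(pools, population_pi)
#>      pop1      pop2
#> 0.1739993 0.1746560
pairwise_fst(pools[[1]], pools[[2]])
#> [1] 0.1903443
```

The diversity values are per emitted site on the synthetic frequency scale
(the generator writes variant-enriched sites, not a full genome, hence the
large values); the Fst of ~0.19 reflects a split two coalescent time units
ago with moderate migration. Fitting at desk scale:

```r
obs <- simulate_observed_sfs(truth, 8, 8, seed = 2, n_loci = 200,
                             locus_len = 1e5, mu = 2.5e-9)
cfg <- search_config(n_starts = 3, n_reps_likelihood = 800,
                     max_iterations = 200, seed = 3)
fit <- fit_im_pair(obs, x_break = 5000, cfg)
fit
#> <im_fit> X = 5000 generations, log composite likelihood 45836.54
#>   N1=6584 N2=5567 NAnc=9317 t_split=50127 m_recent=4.13e-05 m_old=2.44e-05
```

The recent-epoch rate — the quantity the downstream chronology uses —
lands close to the generating 5e-5; the split time and ancestral size show
the factor-2-scale uncertainty expected of composite likelihoods on folded
spectra (they sit on a size/split-time ridge, as the methods vignette
discusses). A scan over X plus `smooth_t2()`,
`deconvolve_intervals()` and `bootstrap_band()` then turns per-breakpoint
fits into a dated gene-flow trajectory; `autoplot()` methods exist for
every result type, and `tidy()`/`glance()` give tibble summaries.

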