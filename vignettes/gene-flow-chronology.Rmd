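---
title: "Dating gene-flow disruption from pooled population genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene-flow disruption from pooled population genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfchrono)
```

## The problem

Habitat fragmentation severs gene flow between populations long before its
genetic consequences — loss of diversity, rising differentiation — become
visible, because large populations lose variation slowly. `gfchrono`
implements an analysis chain that asks *when* gene flow between population
pairs changed, rather than only *whether* populations are differentiated
today. It was designed for pool-sequenced soil arthropods (pools of 50
diploid individuals per site, so allele frequencies rather than genotypes),
but nothing in the machinery is taxon-specific.

The chain has four stages:

1. **Pool-seq summaries** (`read_pooled_vcf()`, `filter_sites()`,
   `population_pi()`, `pairwise_fst()`, `folded_sfs()`, `joint_2dsfs()`,
   `ibd_regression()`, `upgma_tree()`): per-site filtering and the standard
   descriptive statistics, computed from allele frequencies with Nei's
   sample-size correction.
2. **Demographic fitting** (`fit_im_pair()`, `scan_gene_flow()`): a
   two-population isolation-with-migration (IM) model fitted to the folded
   joint site frequency spectrum (2dSFS) by maximising a Poisson composite
   likelihood, repeatedly, over a grid of epoch breakpoints X. The fit at
   breakpoint X yields t2(X), the gene-flow rate integrated from the
   present back to X generations ago.
3. **Temporal deconvolution** (`smooth_t2()`, `deconvolve_intervals()`,
   `bootstrap_band()`): the nested t2 estimates are converted into
   per-interval gene-flow rates.
4. **Ne-trajectory aggregation** (`aggregate_ne()`): step-function effective
   population size histories (e.g. Stairway Plot output) are z-transformed
   and averaged across populations with a population-level bootstrap.

A fifth component, the synthetic-data module
(`generate_pooled_dataset()`, `generate_ne_trajectories()`,
`generate_scan_fixture()`, `make_scenario()`), generates every input the
pipeline consumes with known truth, so all stages are testable without any
sequencing data.

## The IM model and its coalescent engine

The demography has two populations of constant diploid
sizes $N_1$, $N_2$ that merged into an ancestor of size $N_{anc}$ at
$T_{split}$ generations before present. Gene flow is symmetric, with one
per-generation, per-lineage probability $m_{recent}$ acting on $[0, X)$ and
another, $m_{old}$, on $[X, T_{split})$. The six free parameters are
searched within the prior bounds used throughout: sizes $10$–$10^7$, split
time $10$–$10^5$ generations, migration $10^{-20}$–$10^{-1}$.

Expected joint SFSs come from a continuous-time two-deme structured
coalescent written in C++ (`sample_genealogy()`): within-deme coalescence
at rate $\binom{k}{2}/2N_d(t)$, migration at rate $m(t)$ per lineage, exact
exponential waiting times with re-draws at epoch boundaries (no time
discretisation), and exponential size change handled through the closed
form of the integrated coalescence intensity. Each surviving lineage
carries its descendant configuration $(i, j)$; the expected SFS cell
$(i, j)$ is $\mu L$ times the mean branch length subtending that
configuration.

Two numerical design choices matter for anyone modifying the fitting code:

* **Analytic ancestral tail.** The deepest part of each genealogy — the
  ancestral panmictic phase — dominates the Monte Carlo variance of the
  expected SFS, because $N_{anc}$ is typically large. When at most 30
  lineages survive to the final constant-size epoch, the engine adds that
  epoch's contribution analytically: for $j$ exchangeable lineages entering
  a constant-size coalescent, the expected total branch length subtending
  exactly $s$ of them is $4N/s$, shared equally among the $\binom{j}{s}$
  subsets, and the subset-sum distribution over configurations is computed
  by dynamic programming. This is an unbiased variance reduction (verified
  against pure simulation in the test suite); it is switched on for
  likelihood evaluation and off (by default) in `sample_genealogy()`, so
  data simulation retains full genealogical noise.
* **Bias-corrected common-random-numbers objective.** Each likelihood
  evaluation re-simulates the expected SFS with a fixed seed, making the
  objective a deterministic function of the parameters. Because
  $\mathbb{E}[\log\hat\lambda] < \log\lambda$ by Jensen's inequality, raw
  Monte Carlo likelihoods systematically favour parameter regions whose
  spectra are computed with less simulation variance; the objective
  therefore adds the first-order correction
  $\sum_c o_c \widehat{\mathrm{Var}}(\hat\lambda_c) / 2\hat\lambda_c^2$.
  Optimisation is multi-start Nelder-Mead on log-scale parameters squashed
  into the bounds, started from a ladder of moment-based guesses (a
  Watterson-style size estimate spread over several candidate split times)
  plus log-uniform draws, and finished with a polish pass at four times the
  simulation effort, where the smoother surface damps residual Monte Carlo
  ruggedness. Parameter corners implying more than ~10 migration events
  per lineage are rejected with a graded penalty: the histories this model
  targets see at most a few migrations per lineage, and beyond that the
  demes are operationally panmictic while simulation cost keeps growing. `scan_gene_flow()` chains
  fits across the X grid, seeding each breakpoint's search with its
  neighbour's solution; the objective changes smoothly in X, so this both
  stabilises the t2 trajectory and shortens the search.

Fits with $\hat T_{split} < X$ are flagged `excluded` — their "recent"
epoch would reach into the ancestral population — and carried, not
dropped, so downstream code decides how to treat them. This exclusion is
not a corner case: folded spectra at small sample sizes harbour a genuine
degeneracy in which a very recent split with strong migration (operational
panmixia) fits about as well as the deep-split history that generated the
data, and the global optimum regularly lands there. Discarding those
breakpoints entirely — the natural treatment at full sample size, where
they are a minority — would at desk scale strip whole scans, so `fit_im_pair()` also
reports the best *admissible* optimum among its starts ($\hat T_{split}
\ge X$) and `as_t2_trajectory()` falls back to it where the global best is
excluded; the scan's warm chain likewise follows the admissible solution
so one degenerate breakpoint cannot drag its neighbours.

## Deconvolution of integrated gene-flow estimates

t2(X) integrates gene flow over $n = X/I$ intervals of width $I$ (100
generations in the full analysis). Assuming the fitted value equals the
average of the actual per-interval rates,

$$\mathrm{Fit}_X = \frac{\mathrm{Act}_{I_1} + \cdots + \mathrm{Act}_{I_n}}{n},$$

the rates unwrap iteratively:

$$\mathrm{Act}_{I_n} = \mathrm{Fit}_X \times n - \sum_{k<n} \mathrm{Act}_{I_k}.$$

For example, fitted values of 0.003 at X = 500 and 0.0035 at X = 600 imply
a rate of $0.0035 \times 6 - 5 \times 0.003 = 0.006$ in the 500–600
interval. `deconvolve_intervals()` implements exactly this recursion; the
running-mean identity (the mean of the first $n$ deconvolved rates equals
the fitted value at $X = nI$) holds to machine precision and is enforced in
the tests. Because the recursion amplifies wiggle in the fitted curve,
deconvolved rates can go negative; raw values are preserved (the algebra
needs them) and a zero-clamped copy is provided for display. Smoothing uses
a cubic smoothing spline with the penalty chosen by generalized
cross-validation (`spar` can be fixed for sensitivity analyses); excluded
breakpoints are omitted from fitting but predicted, keeping the grid
contiguous. Confidence bands bootstrap population *pairs* (the estimation
unit) with replacement — average, smooth, deconvolve per replicate, then
take 2.5%/97.5% quantiles; the full-scale default is 10,000 replicates,
configurable down for exploration.

Within each bootstrap replicate the order is average-then-smooth, matching
the main analysis; the alternative (smooth each pair, then average) gives
near-identical point estimates but wider bands and is not used.

## Ne-trajectory aggregation

Stairway-Plot-style step functions (year, median Ne) are evaluated on a
common grid (default 200 log-spaced points from 10 to 50,000 years,
spanning the post-glacial period of interest), z-transformed per population
(sample-sd normalisation, as `scale()`), and averaged. The z-transform
makes the aggregate invariant to per-population affine rescaling — so
haploid-vs-diploid conventions cannot distort the mean curve — at the cost
of discarding absolute sizes; it is a shape summary. Step functions are
treated as right-continuous (a grid time exactly at a breakpoint takes the
step that starts there). The band bootstraps populations, mirroring the
gene-flow band's design. Time conversion uses 3 generations per year (a
4-month generation time) and floors to whole years, so 14,000 generations
is 4,666 years; the assumed mutation rate for any absolute scaling is
2.5e-9 per base per generation.

## Site filtering and pool-seq conventions

Filters run in a fixed order, each seeing the survivors of the previous
rule: (1) SNPs within 5 bp of an indel record, (2) indel records, (3) total
depth outside [301, 599] (inclusive — the stated bounds "lower than 301"
and "higher than 599" are exclusive removal rules), (4) non-biallelic
records, (5) BED-masked (genic/repetitive) intervals, with BED treated as
0-based half-open against 1-based VCF positions. Each rule's removal count
is reported (`filter_tally()`), and tallies always sum to the
input-minus-output record count.

Pool allele counts are recovered from frequencies by rounding $p \cdot n$
to the nearest integer, with exact halves rounded toward the minor allele.
Diversity uses Nei's $\pi = 2 p q\, n/(n-1)$; the genome-wide pair
differentiation is the ratio of sums
$(\sum\pi_{total} - \sum\pi_{within})/\sum\pi_{total}$ over the site
intersection, with the *same* $n$-chromosome correction in both terms so
that identical pools give exactly zero and completely fixed differences
give exactly one; negative values are reported as computed. Sites
monomorphic in both pools contribute 0/0 and are skipped in Fst but kept in
$\pi$ denominators. Joint spectra fold by the globally rarer allele with
exact-50% ties kept as-is; `project_sfs()` offers hypergeometric
down-projection (with re-folding) to make desk-scale fitting cheap.
Distances for isolation-by-distance regression are haversine great-circle
distances at the mean Earth radius 6371.0088 km, and pairs are treated as
independent observations in an ordinary least-squares fit (no Mantel
correction) with $F_{1,\,n_{pairs}-2}$; UPGMA clustering is average-linkage
`hclust()` rendered as an `ape` tree.

## Validation scenarios and what the synthetic data does (and does not) show

`make_scenario(1:5)` reproduces the five two-population histories used to
validate the time-resolved gene-flow estimator: no gene flow; constant
6e-5; constant 6e-5 with ~90% exponential decline since the split; with
~10-fold exponential growth; and stepwise-decreasing gene flow (6e-5 down
to zero within the last 600 generations). All share 11,250 diploids per
population at the split, a split 45,000 generations ago, an ancestral size
of 202,500 diploids, a 6 × 15 Mb genome, and mutation rate 1e-8. Two
of the rounded sizes these scenarios are usually quoted with are
internally inconsistent with the stated rate and
duration (a "current size" of 1,000 for the declining scenario and 500,000
for the growing one, where the rate-and-duration arithmetic gives ~1,186
and ~106,740); the package stores the rate-and-duration parameterisation as
primary and keeps the rounded figures as annotations. The stepwise
scenario's final 600 generations carry two rates ("1e-5 and 0") without a
stated inner boundary; the package splits the window at 300 generations.

Recombination within chromosomes is approximated by cutting the genome into
independent non-recombining windows (free recombination between windows).
Expected SFSs are insensitive to linkage, so this affects only the
between-window variance of simulated spectra, not their means. Desk-scale
runs use samples of 8–16 chromosomes per population and hundreds of
windows; the test suite's mini validation keeps the scenario genome size
(90 Mb as 200 × 450 kb windows) while shrinking the sample to 8
chromosomes per deme, and the vignette-scale examples shrink further.

The pool-seq generator draws per-site joint frequencies from the coalescent
engine's configuration mass, then simulates reads binomially around the
true pool frequency — equal individual contributions, defensible for pools
of 50 — with depths from a clamped normal model; dirty mode injects indels,
depth outliers and masked intervals with exact bookkeeping in an
accompanying truth file. What passing tests on these data do *not* show:
robustness to unequal individual DNA contributions, sequencing error,
reference bias, linked selection, or more than two demes — none of which
the generator emulates.

Known limitations of the inference itself, visible in the validation runs:
split times and the older gene-flow rate are weakly identified from folded
spectra (the composite likelihood has a size/split-time ridge), gene flow
tends to be underestimated and sizes overestimated, and t2 at small X rests
on little signal, which is why the per-interval chronology is read from the
smoothed, bootstrap-banded deconvolution rather than from any single fit.
These limitations bite hardest at the test suite's mini scale: with 8
chromosomes per population and a single pair per replicate, fitted split
times often collapse to just above the breakpoint, so the recent-epoch rate
absorbs the whole history's average gene flow and the recovered t2 curve
flattens. The suite's stepwise-decline check therefore orders recent below
old gene flow in only a fraction of its seeded replicates — a faithful
record of what survives the scale-down, not of the method at full sample
size (50 diploids per pool, dozens of averaged pairs), where split times
are far better pinned.

## A worked mini-pipeline

```{r mini, eval = FALSE}
# synthetic pooled data from a known two-population history
truth <- im_model(5000, 5000, 20000, t_split = 20000, x_break = 20000,
                  m_recent = 5e-5, m_old = 5e-5)
ds <- generate_pooled_dataset(truth, out_dir = tempfile(), sites = 2000,
                              seed = 1)
pools <- lapply(ds$vcf_paths, read_pooled_vcf, pool_n = 100)
pools <- lapply(pools, filter_sites)
sapply(pools, population_pi)
pairwise_fst(pools[[1]], pools[[2]])

# fit the IM model at one epoch breakpoint and scan a small grid
obs <- simulate_observed_sfs(truth, 8, 8, seed = 2, n_loci = 200,
                             locus_len = 1e5, mu = 2.5e-9)
cfg <- search_config(n_starts = 3, n_reps_likelihood = 800,
                     max_iterations = 200, seed = 3)
scan <- scan_gene_flow(obs, grid = seq(2000, 12000, by = 2000), cfg = cfg)

# deconvolve the integrated estimates into per-interval rates
dec <- deconvolve_intervals(smooth_t2(as_t2_trajectory(scan)),
                            interval = 2000)
autoplot(dec)
```
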