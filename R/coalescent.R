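#' Sample genealogies under an isolation-with-migration model
#'
#' Continuous-time two-deme structured coalescent: within-deme coalescence
#' at rate choose(k, 2) / (2 N(t)) and symmetric migration at the model's
#' per-lineage rate, with exact exponential waiting times re-drawn at epoch
#' boundaries (no time stepping). The returned tally gives, for each
#' descendant configuration (i, j) — i descendants in the sample from
#' population 1, j from population 2 — the branch length subtending that
#' configuration, averaged over replicate genealogies. A mutation falling on
#' such a branch produces a variant at joint frequency (i, j), so this tally
#' is the genealogical skeleton of the expected joint SFS.
#'
#' @param model An [im_model].
#' @param k1,k2 Haploid sample sizes from the two populations.
#' @param n_reps Number of replicate genealogies.
#' @param seed Integer seed; replicate r uses stream `seed XOR r`.
#' @param analytic_ancestral Replace the final constant-size ancestral
#'   epoch's contribution by its exact expectation when at most 30 lineages
#'   survive to it (an unbiased variance reduction for expected-SFS use;
#'   leave `FALSE` to simulate every epoch).
#' @return A `genealogy_tally` list: `mean_tally` and `var_tally`
#'   ((k1+1) x (k2+1) matrices, generations), `mean_tmrca`,
#'   `mean_total_length`, their variances, `k1`, `k2`, `n_reps`.
#' @export
sample_genealogy <- function(model, k1, k2, n_reps = 1000, seed = 1,
                             analytic_ancestral = FALSE) {
  stopifnot(inherits(model, "im_model"), k1 >= 0, k2 >= 0, k1 + k2 >= 2)
  res <- .sim_branch_tally(model_epochs(model), as.integer(k1),
                           as.integer(k2), as.integer(n_reps),
                           as.numeric(seed), isTRUE(analytic_ancestral))
  res$k1 <- as.integer(k1)
  res$k2 <- as.integer(k2)
  structure(res, class = "genealogy_tally")
}

#' Expected joint SFS under an isolation-with-migration model
#'
#' Cell (i, j) is `mu * seq_len` times the mean branch length subtending
#' configuration (i, j) over replicate genealogies (infinite-sites
#' expectation). Real-valued; use [simulate_observed_sfs()] for integer
#' data-like spectra.
#'
#' @inheritParams sample_genealogy
#' @param seq_len Total sequence length in bases.
#' @param mu Mutation rate per base per generation.
#' @param fold Fold onto the global minor allele?
#' @return A `joint_sfs` with expected (real-valued) cell masses.
#' @export
expected_joint_sfs <- function(model, k1, k2, seq_len, mu, n_reps = 1000,
                               seed = 1, fold = FALSE,
                               analytic_ancestral = TRUE) {
  stopifnot(n_reps >= 1, seq_len > 0, mu >= 0)
  tal <- sample_genealogy(model, k1, k2, n_reps, seed, analytic_ancestral)
  counts <- mu * seq_len * tal$mean_tally
  counts[1, 1] <- 0
  counts[k1 + 1, k2 + 1] <- 0
  if (fold) counts <- fold_joint_counts(counts)
  new_joint_sfs(counts, k1, k2, folded = fold, seq_len = seq_len, mu = mu)
}

#' Simulate an observed joint SFS from a validation scenario
#'
#' The genome is represented as independent non-recombining windows (free
#' recombination between them); one genealogy is drawn per window and cell
#' counts are Poisson around the accumulated expected mutation mass. By
#' default a scenario's 15 Mb chromosomes are split into 100 kb windows.
#'
#' @param scenario An `im_scenario` from [make_scenario()], or an
#'   [im_model] (then `mu` must be given).
#' @param k1,k2 Haploid sample sizes.
#' @param seed Integer seed.
#' @param n_loci Number of independent windows (default: scenario genome at
#'   100 kb windows).
#' @param locus_len Window length in bases.
#' @param mu Mutation rate; defaults to the scenario's.
#' @param fold Fold onto the global minor allele? (Default `TRUE`, the
#'   convention for data with unknown ancestral states.)
#' @return A `joint_sfs` with integer counts; `seq_len` and `mu` metadata
#'   record the simulated genome.
#' @export
simulate_observed_sfs <- function(scenario, k1, k2, seed = 1, n_loci = NULL,
                                  locus_len = 1e5, mu = NULL, fold = TRUE) {
  if (inherits(scenario, "im_scenario")) {
    model <- scenario$model
    if (is.null(mu)) mu <- scenario$mutation_rate
    if (is.null(n_loci)) {
      n_loci <- as.integer(scenario$n_chromosomes_genome *
                             ceiling(scenario$chrom_len / locus_len))
    }
  } else {
    stopifnot(inherits(scenario, "im_model"))
    model <- scenario
    if (is.null(mu)) stop("mu must be supplied when simulating from a bare model")
    if (is.null(n_loci)) stop("n_loci must be supplied when simulating from a bare model")
  }
  seeds <- derive_seeds(seed, 2)
  tal <- sample_genealogy(model, k1, k2, n_reps = n_loci, seed = seeds[1])
  lambda <- mu * locus_len * tal$mean_tally * n_loci  # total branch mass
  lambda[1, 1] <- 0
  lambda[k1 + 1, k2 + 1] <- 0
  counts <- with_seed(seeds[2], {
    matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  })
  if (fold) counts <- fold_joint_counts(counts)
  new_joint_sfs(counts, k1, k2, folded = fold,
                seq_len = n_loci * locus_len, mu = mu)
}
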