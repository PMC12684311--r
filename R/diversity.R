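#' Nei per-site nucleotide diversity with sample-size correction
#'
#' For a biallelic site with allele frequencies `p` and `1 - p` estimated
#' from a pool of `n` chromosomes, pi = 2 p (1 - p) n / (n - 1). The factor
#' n/(n - 1) corrects the small-sample bias of the plug-in heterozygosity.
#'
#' @param p Allele frequency (vectorised), in \[0, 1\].
#' @param n Number of chromosomes in the pool (>= 2).
#' @return Per-site diversity values.
#' @export
nei_pi_site <- function(p, n) {
  if (any(n < 2)) stop("n must be at least 2 chromosomes")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  2 * p * (1 - p) * n / (n - 1)
}

#' Population nucleotide diversity
#'
#' Mean of [nei_pi_site()] over all retained sites. Monomorphic sites
#' contribute zero to the numerator but stay in the denominator, so the
#' table passed in must include them (diversity is per screened site, not
#' per variant site).
#'
#' @param table A filtered [pooled_sites] table, invariant sites included.
#' @return Mean per-site diversity (a single number).
#' @export
population_pi <- function(table) {
  stopifnot(inherits(table, "pooled_sites"))
  if (nrow(table) == 0) stop("cannot compute diversity of an empty table")
  mean(nei_pi_site(table$alt_freq, n_chromosomes(table)))
}

#' Pairwise Fst between two population pools
#'
#' Per shared site, within-pool diversity is the mean of the two pools'
#' [nei_pi_site()] values and total diversity is [nei_pi_site()] at the
#' mean of the two allele frequencies, using the same sample-size
#' correction as the within terms (so identical pools give exactly zero and
#' the correction factors cancel from the ratio). Fst is the genome-wide
#' ratio of sums (sum pi_total - sum pi_within) / sum pi_total over the
#' intersection of the two site sets. Sites monomorphic in both pools
#' contribute 0/0 and are skipped. Negative per-site contributions are not
#' clamped.
#'
#' @param a,b [pooled_sites] tables with equal pool sizes.
#' @return Fst (single number); `NA` when the total diversity sum is zero.
#' @export
pairwise_fst <- function(a, b) {
  stopifnot(inherits(a, "pooled_sites"), inherits(b, "pooled_sites"))
  n <- n_chromosomes(a)
  if (n != n_chromosomes(b)) stop("pools must have equal n_chromosomes")
  keyed <- dplyr::inner_join(
    as_tibble(a)[c("chrom", "pos", "alt_freq")],
    as_tibble(b)[c("chrom", "pos", "alt_freq")],
    by = c("chrom", "pos"), suffix = c("_a", "_b"))
  if (nrow(keyed) == 0) stop("no shared sites between the two pools")
  p_bar <- (keyed$alt_freq_a + keyed$alt_freq_b) / 2
  pi_within <- (nei_pi_site(keyed$alt_freq_a, n) +
                  nei_pi_site(keyed$alt_freq_b, n)) / 2
  pi_total <- nei_pi_site(p_bar, n)
  tot <- sum(pi_total)
  if (tot == 0) return(NA_real_)
  (tot - sum(pi_within)) / tot
}

#' All pairwise Fst values for a set of pools
#'
#' @param pools Named list of [pooled_sites] tables (names become
#'   population ids; unnamed lists use each table's own id).
#' @return An `fst_matrix`: symmetric matrix with zero diagonal, plus a
#'   matching matrix of shared-site counts in attribute `n_sites`.
#' @export
fst_matrix <- function(pools) {
  stopifnot(is.list(pools), length(pools) >= 2)
  ids <- names(pools)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(pools, attr, character(1), "population_id")
  }
  k <- length(pools)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  ns <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- pairwise_fst(pools[[i]], pools[[j]])
      shared <- dplyr::inner_join(as_tibble(pools[[i]])[c("chrom", "pos")],
                                  as_tibble(pools[[j]])[c("chrom", "pos")],
                                  by = c("chrom", "pos"))
      ns[i, j] <- ns[j, i] <- nrow(shared)
    }
  }
  structure(m, n_sites = ns, class = c("fst_matrix", "matrix", "array"))
}

#' @export
tidy.fst_matrix <- function(x, ...) {
  ids <- rownames(x)
  ns <- attr(x, "n_sites")
  pairs <- utils::combn(seq_along(ids), 2)
  tibble(pop_a = ids[pairs[1, ]], pop_b = ids[pairs[2, ]],
         fst = x[t(pairs)], n_sites = as.integer(ns[t(pairs)]))
}
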