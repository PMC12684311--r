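#' Round a pooled allele frequency onto a chromosome count
#'
#' Allele counts are recovered from pool frequencies by rounding `p * n` to
#' the nearest integer; an exact half rounds toward the minor allele (down
#' when the alternate allele is the minor one, up when it is the major one).
#'
#' @param p Alternate-allele frequency in \[0, 1\].
#' @param n Chromosomes in the pool.
#' @return Integer alternate-allele counts.
#' @export
round_allele_count <- function(p, n) {
  x <- p * n
  frac_half <- abs(x - floor(x) - 0.5) < 1e-9
  out <- floor(x + 0.5)
  # ties: push toward the rarer allele; at exactly n/2 keep the lower count
  out[frac_half] <- ifelse(x[frac_half] > n / 2, ceiling(x[frac_half]),
                           floor(x[frac_half]))
  as.integer(out)
}

#' Folded site frequency spectrum of one pool
#'
#' Tallies sites by minor-allele count (0 .. floor(n/2)). With
#' `exclude_singletons`, the singleton bin is dropped from the output (the
#' choice is recorded in the `singletons_excluded` attribute); this mirrors
#' the usual practice for SFS-based demographic inference where singleton
#' calls are the least reliable.
#'
#' @param table A filtered biallelic [pooled_sites] table.
#' @param exclude_singletons Drop the minor-count-1 bin?
#' @return A `folded_sfs` tibble with columns `minor_count`, `n_sites`.
#' @export
folded_sfs <- function(table, exclude_singletons = FALSE) {
  stopifnot(inherits(table, "pooled_sites"))
  n <- n_chromosomes(table)
  alt <- round_allele_count(table$alt_freq, n)
  minor <- pmin(alt, n - alt)
  bins <- 0:(n %/% 2)
  counts <- tabulate(minor + 1L, nbins = length(bins))
  out <- tibble(minor_count = bins, n_sites = counts)
  if (exclude_singletons) out <- out[out$minor_count != 1L, ]
  structure(out, class = c("folded_sfs", class(tibble())),
            n_chromosomes = n, singletons_excluded = isTRUE(exclude_singletons))
}

new_joint_sfs <- function(counts, n1, n2, folded, seq_len = NA_real_,
                          mu = NA_real_) {
  stopifnot(nrow(counts) == n1 + 1, ncol(counts) == n2 + 1, all(counts >= 0))
  structure(list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
                 folded = isTRUE(folded), seq_len = seq_len, mu = mu),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> %d x %d chromosomes, %s, total mass %.4g\n",
              x$n1, x$n2, if (x$folded) "folded (minor allele)" else "unfolded",
              sum(x$counts)))
  invisible(x)
}

#' @export
tidy.joint_sfs <- function(x, ...) {
  tidyr::expand_grid(count1 = 0:x$n1, count2 = 0:x$n2) |>
    dplyr::mutate(n_sites = as.vector(t(x$counts)))
}

# Fold a (n1+1) x (n2+1) cell matrix onto the global minor allele: mass in a
# cell whose summed count exceeds (n1+n2)/2 moves to the mirror cell; an exact
# tie stays where it is.
fold_joint_counts <- function(counts) {
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  half <- (n1 + n2) / 2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) {
    for (j in 0:n2) {
      if (i + j > half) out[n1 - i + 1L, n2 - j + 1L] <-
          out[n1 - i + 1L, n2 - j + 1L] + counts[i + 1L, j + 1L]
      else out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + counts[i + 1L, j + 1L]
    }
  }
  out
}

#' Joint (2d) site frequency spectrum for a population pair
#'
#' Tallies shared sites into an (n1+1) x (n2+1) matrix of per-population
#' allele counts recovered with [round_allele_count()]. With `fold = TRUE`
#' each site is oriented by the globally rarer allele, the convention used
#' when the ancestral state is unknown.
#'
#' @param a,b [pooled_sites] tables; the site intersection is used.
#' @param fold Orient sites by global minor allele?
#' @return A `joint_sfs` object.
#' @export
joint_2dsfs <- function(a, b, fold = TRUE) {
  stopifnot(inherits(a, "pooled_sites"), inherits(b, "pooled_sites"))
  n1 <- n_chromosomes(a)
  n2 <- n_chromosomes(b)
  keyed <- dplyr::inner_join(
    as_tibble(a)[c("chrom", "pos", "alt_freq")],
    as_tibble(b)[c("chrom", "pos", "alt_freq")],
    by = c("chrom", "pos"), suffix = c("_a", "_b"))
  if (nrow(keyed) == 0) stop("no shared sites between the two pools")
  i <- round_allele_count(keyed$alt_freq_a, n1)
  j <- round_allele_count(keyed$alt_freq_b, n2)
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  for (k in seq_along(i)) {
    counts[i[k] + 1L, j[k] + 1L] <- counts[i[k] + 1L, j[k] + 1L] + 1
  }
  if (fold) counts <- fold_joint_counts(counts)
  new_joint_sfs(counts, n1, n2, folded = fold)
}

#' Project a joint SFS down to smaller sample sizes
#'
#' Hypergeometric down-projection of expected cell mass, independently per
#' margin: the expected spectrum of a subsample of `m` chromosomes drawn
#' without replacement from `n`. Total mass is conserved. Projection of an
#' unfolded spectrum commutes with folding on symmetric inputs.
#'
#' @param sfs A `joint_sfs`.
#' @param m1,m2 Target chromosome counts (2 <= m <= n).
#' @return A `joint_sfs` with real-valued expected counts.
#' @export
project_sfs <- function(sfs, m1, m2) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (m1 < 2 || m2 < 2) stop("projection targets must be at least 2 chromosomes")
  if (m1 > sfs$n1 || m2 > sfs$n2) stop("cannot project up (m > n)")
  proj <- function(n, m) {
    # P[a minor copies in subsample of m | i copies in n]
    outer(0:m, 0:n, function(a, i) stats::dhyper(a, i, n - i, m))
  }
  counts <- proj(sfs$n1, m1) %*% sfs$counts %*% t(proj(sfs$n2, m2))
  # subsampling can push minor-oriented sites past the new midpoint, so a
  # folded spectrum is re-folded to restore its orientation invariant
  if (sfs$folded) counts <- fold_joint_counts(counts)
  new_joint_sfs(counts, m1, m2, folded = sfs$folded,
                seq_len = sfs$seq_len, mu = sfs$mu)
}

#' Write / read the dense TSV dialect for joint SFS matrices
#'
#' Rows are population-1 allele counts (0..n1), columns population-2 counts.
#'
#' @param sfs A `joint_sfs`.
#' @param path Output path.
#' @return `path`, invisibly (`write_joint_sfs`); a `joint_sfs`
#'   (`read_joint_sfs`).
#' @export
write_joint_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  header <- sprintf("# joint_sfs n1=%d n2=%d folded=%s seq_len=%s mu=%s",
                    sfs$n1, sfs$n2, sfs$folded,
                    format(sfs$seq_len), format(sfs$mu))
  lines <- c(header, apply(sfs$counts, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_joint_sfs
#' @export
read_joint_sfs <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# joint_sfs ", "", lines[1]), " ")[[1]]
  kv <- setNames(sub("^[^=]+=", "", meta), sub("=.*$", "", meta))
  counts <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  new_joint_sfs(counts, as.integer(kv["n1"]), as.integer(kv["n2"]),
                folded = kv["folded"] == "TRUE",
                seq_len = suppressWarnings(as.numeric(kv["seq_len"])),
                mu = suppressWarnings(as.numeric(kv["mu"])))
}
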