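#' Great-circle distances between populations
#'
#' Haversine distance on a sphere with the mean Earth radius 6371.0088 km.
#'
#' @param coords Data frame with columns `id`, `lat`, `lon` (decimal
#'   degrees, WGS84).
#' @return Tibble of unordered pairs with `pop_a`, `pop_b`, `distance_km`.
#' @export
population_distances <- function(coords) {
  stopifnot(all(c("id", "lat", "lon") %in% names(coords)))
  if (nrow(coords) < 2) stop("need at least two populations")
  pairs <- utils::combn(nrow(coords), 2)
  d <- geosphere::distHaversine(
    as.matrix(coords[pairs[1, ], c("lon", "lat")]),
    as.matrix(coords[pairs[2, ], c("lon", "lat")]),
    r = 6371008.8) / 1000
  tibble(pop_a = coords$id[pairs[1, ]], pop_b = coords$id[pairs[2, ]],
         distance_km = d)
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of pairwise Fst on great-circle distance over all
#' unordered population pairs. Pairs are treated as independent
#' observations, so the F test has (1, n_pairs - 2) degrees of freedom; no
#' Mantel-style permutation correction is applied.
#'
#' @param fst An [fst_matrix()].
#' @param coords Data frame with columns `id`, `lat`, `lon`; ids must match
#'   the Fst matrix.
#' @return An `ibd_fit` object wrapping the `lm` fit and the pair table;
#'   see [tidy()] and [glance()] methods.
#' @export
ibd_regression <- function(fst, coords) {
  stopifnot(inherits(fst, "fst_matrix"))
  if (nrow(coords) < 3) stop("need at least three populations for IBD regression")
  missing_ids <- setdiff(rownames(fst), coords$id)
  if (length(missing_ids) > 0) {
    stop("coordinates missing for: ", paste(missing_ids, collapse = ", "))
  }
  coords <- coords[match(rownames(fst), coords$id), ]
  pairs <- dplyr::inner_join(tidy(fst), population_distances(coords),
                             by = c("pop_a", "pop_b"))
  if (length(unique(pairs$distance_km)) < 2) {
    stop("all pairwise distances are equal; IBD design is degenerate")
  }
  fit <- lm(fst ~ distance_km, data = pairs)
  structure(list(lm = fit, pairs = as_tibble(pairs)), class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ibd_fit> Fst ~ distance over %d pairs: slope %.3g per km, R2_adj %.3f, F(%d,%d) = %.2f, p = %.3g\n",
    nrow(x$pairs), g$slope, g$adj_r_squared, g$df, g$df_residual, g$statistic,
    g$p_value))
  invisible(x)
}

#' @export
tidy.ibd_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.ibd_fit <- function(x, ...) {
  s <- summary(x$lm)
  fstat <- s$fstatistic
  tibble(slope = unname(stats::coef(x$lm)[2]),
         intercept = unname(stats::coef(x$lm)[1]),
         r_squared = s$r.squared,
         adj_r_squared = s$adj.r.squared,
         statistic = unname(fstat[1]),
         df = as.integer(fstat[2]),
         df_residual = as.integer(fstat[3]),
         p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
         n_pairs = nrow(x$pairs))
}

#' UPGMA cladogram from an Fst matrix
#'
#' Average-linkage hierarchical clustering of populations on pairwise Fst,
#' returning a rooted ultrametric tree.
#'
#' @param fst An [fst_matrix()] (or any symmetric distance matrix with
#'   labelled rows).
#' @return An [ape::phylo] tree; serialise with [ape::write.tree()].
#' @export
upgma_tree <- function(fst) {
  m <- unclass(fst)
  attr(m, "n_sites") <- NULL
  if (anyNA(m)) stop("Fst matrix contains missing values")
  if (nrow(m) < 2) stop("need at least two populations")
  hc <- hclust(as.dist(m), method = "average")
  ape::as.phylo(hc)
}
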