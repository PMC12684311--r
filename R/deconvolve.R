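#' Build a t2 trajectory
#'
#' A `t2_trajectory` holds time-integrated recent gene-flow estimates: for
#' each breakpoint X on the grid, the estimated mean migration rate from the
#' present back to X (the `m_recent` column of a [scan_gene_flow()] result).
#'
#' @param x Breakpoints in generations, strictly increasing.
#' @param t2 Integrated gene-flow estimates (rates >= 0, or `NA`).
#' @param excluded Logical flags for estimates to drop from smoothing
#'   (e.g. fits with `t_split < X`).
#' @param pair_id Label.
#' @return A `t2_trajectory` tibble.
#' @export
t2_trajectory <- function(x, t2, excluded = rep(FALSE, length(x)),
                          pair_id = "pair") {
  stopifnot(length(x) == length(t2), length(excluded) == length(x),
            all(diff(x) > 0))
  if (any(t2 < 0, na.rm = TRUE)) stop("t2 rates must be non-negative")
  structure(tibble(x = as.numeric(x), t2 = as.numeric(t2),
                   excluded = as.logical(excluded) | is.na(t2)),
            class = c("t2_trajectory", class(tibble())), pair_id = pair_id)
}

#' @rdname t2_trajectory
#' @param scan A [scan_gene_flow()] result.
#' @param prefer_admissible When the global-best fit at a breakpoint is
#'   excluded (`t_split < X`) but an admissible start was found, use the
#'   admissible estimate instead of dropping the breakpoint.
#' @export
as_t2_trajectory <- function(scan, prefer_admissible = TRUE) {
  stopifnot(inherits(scan, "gene_flow_scan"))
  t2 <- scan$m_recent
  excl <- scan$excluded
  if (prefer_admissible && "m_recent_adm" %in% names(scan)) {
    swap <- excl & scan$has_admissible
    t2[swap] <- scan$m_recent_adm[swap]
    excl <- excl & !scan$has_admissible
  }
  t2_trajectory(scan$x, t2, excluded = excl,
                pair_id = attr(scan, "pair_id") %||% "pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth a t2 trajectory onto its full grid
#'
#' Cubic smoothing spline fitted to the non-excluded estimates, with the
#' penalty chosen by generalized cross-validation (overridable via `spar`),
#' then evaluated at every grid X — including excluded ones, so the
#' downstream interval deconvolution sees a contiguous grid.
#'
#' @param traj A [t2_trajectory].
#' @param spar Optional fixed smoothing parameter (passed to
#'   [stats::smooth.spline()]); `NULL` for GCV.
#' @return Tibble with columns `x`, `fit`.
#' @export
smooth_t2 <- function(traj, spar = NULL) {
  stopifnot(inherits(traj, "t2_trajectory"))
  use <- !traj$excluded
  if (sum(use) < 4) stop("need at least 4 non-excluded points to smooth")
  args <- list(x = traj$x[use], y = traj$t2[use], cv = FALSE)
  if (!is.null(spar)) args$spar <- spar
  sp <- do.call(smooth.spline, args)
  tibble(x = traj$x, fit = predict(sp, traj$x)$y)
}

#' Deconvolve integrated gene-flow estimates into per-interval rates
#'
#' Each fitted value Fit_X is the mean of the actual per-interval rates over
#' the n = X / 100 intervals it integrates, so the rates unwrap iteratively:
#' Act_1 = Fit_100 and Act_n = Fit_X * n - (Act_1 + ... + Act_{n-1}). The
#' raw rates can be negative when the fitted curve wiggles; a zero-clamped
#' copy is provided for display and the raw values are kept for the
#' algebra (the running-mean identity holds only for the raw rates).
#'
#' @param fitted Tibble with columns `x`, `fit` on a contiguous grid
#'   starting at the interval width (default 100 generations) with constant
#'   step, e.g. from [smooth_t2()].
#' @param interval Interval width in generations.
#' @return A `deconvolution` tibble: `interval_start`, `interval_end`,
#'   `fit`, `act_raw`, `act_clamped`.
#' @export
deconvolve_intervals <- function(fitted, interval = 100) {
  stopifnot(all(c("x", "fit") %in% names(fitted)))
  x <- fitted$x
  if (length(x) < 1 || abs(x[1] - interval) > 1e-9 ||
      (length(x) > 1 && any(abs(diff(x) - interval) > 1e-9))) {
    stop("fitted curve must sit on a contiguous grid: ", interval, ", ",
         2 * interval, ", ... generations")
  }
  n <- length(x)
  act <- numeric(n)
  act[1] <- fitted$fit[1]
  for (k in seq_len(n)[-1]) {
    act[k] <- fitted$fit[k] * k - sum(act[seq_len(k - 1)])
  }
  structure(tibble(interval_start = x - interval, interval_end = x,
                   fit = fitted$fit, act_raw = act,
                   act_clamped = pmax(act, 0)),
            class = c("deconvolution", class(tibble())))
}

# Inverse of deconvolve_intervals: running mean of per-interval rates.
running_mean <- function(act) cumsum(act) / seq_along(act)

#' Bootstrap confidence band for deconvolved gene-flow rates
#'
#' Resamples population pairs with replacement; per replicate the surviving
#' t2 estimates are averaged across the resampled pairs at each X, smoothed,
#' and deconvolved. The band is the 2.5%/97.5% empirical quantile of the raw
#' per-interval rate at each interval.
#'
#' @param per_pair List of [t2_trajectory] objects on a common grid.
#' @param B Number of bootstrap replicates (10,000 in a full analysis;
#'   smaller values are fine for exploration).
#' @param seed Integer seed.
#' @param spar Optional fixed smoothing parameter (see [smooth_t2()]).
#' @param interval Interval width in generations.
#' @return A `geneflow_band` tibble: `interval_start`, `interval_end`,
#'   `act_raw`, `act_clamped`, `ci_low`, `ci_high`, with attribute `B`.
#' @export
bootstrap_band <- function(per_pair, B = 10000, seed = 1, spar = NULL,
                           interval = 100) {
  stopifnot(is.list(per_pair), length(per_pair) >= 1, B >= 1)
  grid <- per_pair[[1]]$x
  for (tr in per_pair) {
    if (!isTRUE(all.equal(tr$x, grid))) stop("trajectories must share one grid")
  }
  average_pairs <- function(idx) {
    t2s <- vapply(per_pair[idx], function(tr) {
      ifelse(tr$excluded, NA_real_, tr$t2)
    }, numeric(length(grid)))
    mean_t2 <- rowMeans(matrix(t2s, nrow = length(grid)), na.rm = TRUE)
    t2_trajectory(grid, pmax(mean_t2, 0), excluded = is.nan(mean_t2),
                  pair_id = "averaged")
  }
  point <- deconvolve_intervals(smooth_t2(average_pairs(seq_along(per_pair)),
                                          spar = spar), interval)
  draws <- with_seed(seed, {
    matrix(sample.int(length(per_pair), length(per_pair) * B, replace = TRUE),
           nrow = B)
  })
  acts <- matrix(NA_real_, nrow = B, ncol = length(grid))
  for (b in seq_len(B)) {
    rep_traj <- average_pairs(draws[b, ])
    acts[b, ] <- deconvolve_intervals(smooth_t2(rep_traj, spar = spar),
                                      interval)$act_raw
  }
  qs <- apply(acts, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  structure(tibble(interval_start = point$interval_start,
                   interval_end = point$interval_end,
                   act_raw = point$act_raw,
                   act_clamped = point$act_clamped,
                   ci_low = qs[1, ], ci_high = qs[2, ]),
            class = c("geneflow_band", class(tibble())), B = as.integer(B))
}
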