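#' Search configuration for IM-model fitting
#'
#' Bounds follow the demographic priors used throughout: diploid population
#' sizes in \[10, 1e7\], split time in \[10, 1e5\] generations, and
#' per-generation gene-flow probability in \[1e-20, 1e-1\]. The composite
#' likelihood is maximised by multi-start Nelder-Mead over log-scale
#' parameters; every evaluation re-simulates the expected SFS with the same
#' seed (common random numbers), so the objective is a deterministic
#' function of the parameters.
#'
#' @param size_bounds,t_split_bounds,migration_bounds Length-2 numeric
#'   bounds (lower, upper).
#' @param n_starts Number of optimisation starts (log-uniform draws within
#'   bounds).
#' @param n_reps_likelihood Genealogies per likelihood evaluation.
#' @param max_iterations Nelder-Mead iteration cap per start.
#' @param seed Seed for the common-random-number stream and start draws.
#' @param mask_singletons Also mask the (1,0) and (0,1) cells? Default
#'   `FALSE` (singletons retained).
#' @return A `search_config` list.
#' @export
search_config <- function(size_bounds = c(10, 1e7),
                          t_split_bounds = c(10, 1e5),
                          migration_bounds = c(1e-20, 1e-1),
                          n_starts = 8, n_reps_likelihood = 2000,
                          max_iterations = 200, seed = 1,
                          mask_singletons = FALSE) {
  stopifnot(n_starts >= 1, n_reps_likelihood >= 1, max_iterations >= 1,
            length(size_bounds) == 2, length(t_split_bounds) == 2,
            length(migration_bounds) == 2)
  structure(list(size_bounds = size_bounds, t_split_bounds = t_split_bounds,
                 migration_bounds = migration_bounds,
                 n_starts = as.integer(n_starts),
                 n_reps_likelihood = as.integer(n_reps_likelihood),
                 max_iterations = as.integer(max_iterations),
                 seed = seed, mask_singletons = isTRUE(mask_singletons)),
            class = "search_config")
}

# Cells ignored by the composite likelihood: the invariant (0,0) cell, the
# fully fixed (n1,n2) cell, and optionally the two singleton cells.
loglik_mask <- function(n1, n2, mask_singletons = FALSE) {
  m <- matrix(FALSE, n1 + 1, n2 + 1)
  m[1, 1] <- TRUE
  m[n1 + 1, n2 + 1] <- TRUE
  if (mask_singletons) {
    m[2, 1] <- TRUE
    m[1, 2] <- TRUE
  }
  m
}

#' Poisson composite log-likelihood of an observed joint SFS
#'
#' Sum over unmasked cells of the Poisson log-density of the observed count
#' at the expected cell mass (floored at 1e-12). The invariant (0,0) cell
#' and the fully fixed cell are always masked; cells are treated as
#' independent, so this is a composite likelihood, not a full one.
#'
#' @param observed,expected `joint_sfs` objects of identical shape and
#'   folding.
#' @param mask_singletons Also ignore the two singleton cells?
#' @return Log composite likelihood (a single number).
#' @export
composite_loglik <- function(observed, expected, mask_singletons = FALSE) {
  stopifnot(inherits(observed, "joint_sfs"), inherits(expected, "joint_sfs"))
  if (observed$n1 != expected$n1 || observed$n2 != expected$n2) {
    stop("observed and expected SFS have different shapes")
  }
  if (observed$folded != expected$folded) {
    stop("observed and expected SFS have different folding")
  }
  keep <- !loglik_mask(observed$n1, observed$n2, mask_singletons)
  lam <- pmax(expected$counts[keep], 1e-12)
  obs <- observed$counts[keep]
  sum(obs * log(lam) - lam - lgamma(obs + 1))
}

# Map unconstrained optimiser coordinates to bounded parameters on the log
# scale (logistic squashing), and back.
theta_to_params <- function(theta, cfg) {
  lo <- log(c(cfg$size_bounds[1], cfg$size_bounds[1], cfg$size_bounds[1],
              cfg$t_split_bounds[1], cfg$migration_bounds[1],
              cfg$migration_bounds[1]))
  hi <- log(c(cfg$size_bounds[2], cfg$size_bounds[2], cfg$size_bounds[2],
              cfg$t_split_bounds[2], cfg$migration_bounds[2],
              cfg$migration_bounds[2]))
  p <- exp(lo + (hi - lo) * plogis(theta))
  names(p) <- c("n1", "n2", "n_ancestral", "t_split", "m_recent", "m_old")
  p
}

fit_model_from_params <- function(p, x_break) {
  xb <- min(x_break, p[["t_split"]])
  im_model(p[["n1"]], p[["n2"]], p[["n_ancestral"]], p[["t_split"]],
           x_break = xb, m_recent = p[["m_recent"]], m_old = p[["m_old"]])
}

# Epoch matrix for a constant-size two-epoch IM parameter vector, built
# without tibble overhead (this sits inside the optimiser's hot loop).
fast_epochs <- function(p, x_break) {
  xb <- min(x_break, p[[4]])
  rows <- NULL
  if (xb > 0 && xb < p[[4]]) {
    rows <- rbind(c(0, xb, 1, p[[5]], p[[1]], 0, p[[2]], 0),
                  c(xb, p[[4]], 1, p[[6]], p[[1]], 0, p[[2]], 0))
  } else if (p[[4]] > 0) {
    m <- if (xb >= p[[4]]) p[[5]] else p[[6]]
    rows <- rbind(c(0, p[[4]], 1, m, p[[1]], 0, p[[2]], 0))
  }
  rbind(rows, c(if (is.null(rows)) 0 else p[[4]], 1e300, 0, 0, p[[3]], 0, 1, 0))
}

# Fast Poisson composite negative log-likelihood factory with common random
# numbers: `seed` is fixed across evaluations so the objective is a
# deterministic function of the parameters. Two numerical safeguards:
# (1) log(lambda-hat) is biased low by half the relative Monte Carlo
# variance of lambda-hat (Jensen), which would systematically favour
# parameter regions whose expected SFS is computed with less simulation
# variance; the first-order correction obs * Var(lambda-hat) / (2 lambda^2)
# is added back. (2) Parameter corners whose expected migration-event count
# exceeds ~10 per lineage (the histories this model targets see at most a
# few migrations per lineage; beyond that the demes are effectively
# panmictic and simulation cost grows linearly in m) are rejected with a
# graded penalty so the search backs away instead of stalling.
make_negloglik <- function(observed, x_break, cfg, seq_len, mu) {
  k1 <- observed$n1
  k2 <- observed$n2
  keep <- !loglik_mask(k1, k2, cfg$mask_singletons)
  fold_from <- fold_to <- integer(0)
  if (observed$folded) {
    idx <- which(outer(0:k1, 0:k2, `+`) > (k1 + k2) / 2)
    mirror <- function(i) {
      r <- (i - 1) %% (k1 + 1)
      c <- (i - 1) %/% (k1 + 1)
      (k2 - c) * (k1 + 1) + (k1 - r) + 1
    }
    fold_from <- idx
    fold_to <- mirror(idx)
  }
  obs <- observed$counts[keep]
  scale <- mu * seq_len
  max_mig_events <- 10 * (k1 + k2)
  function(theta) {
    p <- theta_to_params(theta, cfg)
    expected_migrations <- max(p[[5]], p[[6]]) * (k1 + k2) * p[[4]]
    if (expected_migrations > max_mig_events) {
      return(1e12 * (1 + log(expected_migrations / max_mig_events)))
    }
    tal <- .sim_branch_tally(fast_epochs(p, x_break), k1, k2,
                             cfg$n_reps_likelihood,
                             as.numeric(cfg$seed), TRUE)
    lam <- scale * tal$mean_tally
    vm <- scale^2 * tal$var_tally / cfg$n_reps_likelihood
    lam[1] <- 0
    lam[length(lam)] <- 0
    vm[1] <- 0
    vm[length(vm)] <- 0
    if (length(fold_from)) {
      lam[fold_to] <- lam[fold_to] + lam[fold_from]
      lam[fold_from] <- 0
      vm[fold_to] <- vm[fold_to] + vm[fold_from]
      vm[fold_from] <- 0
    }
    l <- pmax(lam[keep], 1e-12)
    -sum(obs * log(l) - l + obs * vm[keep] / (2 * l^2))
  }
}

# Inverse of theta_to_params, clamped slightly inside the bounds.
params_to_theta <- function(p, cfg) {
  lo <- log(c(cfg$size_bounds[1], cfg$size_bounds[1], cfg$size_bounds[1],
              cfg$t_split_bounds[1], cfg$migration_bounds[1],
              cfg$migration_bounds[1]))
  hi <- log(c(cfg$size_bounds[2], cfg$size_bounds[2], cfg$size_bounds[2],
              cfg$t_split_bounds[2], cfg$migration_bounds[2],
              cfg$migration_bounds[2]))
  stats::qlogis(pmin(pmax((log(p) - lo) / (hi - lo), 1e-6), 1 - 1e-6))
}

# Moment-based starting points: a Watterson-style size estimate from the
# total segregating-site count, spread over a ladder of split times. These
# put at least one simplex in the right basin of the (size, split-time)
# ridge that log-uniform draws often miss.
heuristic_starts <- function(observed, cfg, seq_len, mu) {
  k <- observed$n1 + observed$n2
  s_tot <- sum(observed$counts) -
    observed$counts[1, 1] -
    observed$counts[observed$n1 + 1, observed$n2 + 1]
  a_k <- sum(1 / seq_len(k - 1))
  n_hat <- max(s_tot / (4 * mu * seq_len * a_k), cfg$size_bounds[1] * 2)
  clamp_t <- function(t) {
    pmin(pmax(t, cfg$t_split_bounds[1] * 2), cfg$t_split_bounds[2] / 2)
  }
  rows <- list(
    c(n_hat / 3, n_hat / 3, n_hat, clamp_t(1000), 1e-5, 1e-5),
    c(n_hat / 3, n_hat / 3, n_hat, clamp_t(10000), 1e-5, 1e-5),
    c(n_hat / 3, n_hat / 3, n_hat, clamp_t(50000), 1e-5, 1e-5),
    c(n_hat, n_hat, n_hat, clamp_t(10000), 1e-12, 1e-12))
  do.call(rbind, lapply(rows, params_to_theta, cfg = cfg))
}

#' Fit an isolation-with-migration model to an observed joint SFS
#'
#' Maximises the Poisson composite likelihood over six parameters (two
#' current sizes, ancestral size, split time, and the gene-flow rates of the
#' two epochs split at `x_break`), searched on the log scale within the
#' configured bounds by multi-start Nelder-Mead. A fit whose estimated split
#' time falls inside the recent epoch (`t_split < x_break`) is flagged
#' `excluded`: its "recent" rate would actually describe the ancestral
#' population.
#'
#' Folded spectra at small sample sizes carry a genuine model degeneracy: a
#' very recent split with strong migration (effectively one panmictic
#' population) can fit almost as well as — sometimes better than — deeper
#' histories. Such optima are precisely the fits the exclusion rule
#' removes. Because discarding the whole breakpoint wastes grid coverage,
#' the result also records the best *admissible* start (one with
#' `t_split >= x_break`) in `$admissible`, which downstream scans can fall
#' back to; `NULL` when no start produced an admissible optimum.
#'
#' @param observed A `joint_sfs` of integer counts, folded to the minor
#'   allele, carrying `seq_len`/`mu` metadata (or pass them explicitly).
#' @param x_break Epoch boundary in generations (fixed during the fit).
#' @param cfg A [search_config()].
#' @param seq_len,mu Genome size and mutation rate used to scale expected
#'   spectra; default to the metadata on `observed`.
#' @param extra_starts Optional matrix of additional start points on the
#'   optimiser's unconstrained scale (rows), e.g. a neighbouring
#'   breakpoint's solution when scanning.
#' @return An `im_fit` object; see [tidy()]/[glance()] methods.
#' @export
fit_im_pair <- function(observed, x_break, cfg = search_config(),
                        seq_len = observed$seq_len, mu = observed$mu,
                        extra_starts = NULL) {
  stopifnot(inherits(observed, "joint_sfs"), inherits(cfg, "search_config"))
  if (is.na(seq_len) || is.na(mu)) {
    stop("observed SFS carries no seq_len/mu metadata; pass them explicitly")
  }
  negloglik <- make_negloglik(observed, x_break, cfg, seq_len, mu)
  starts <- rbind(
    heuristic_starts(observed, cfg, seq_len, mu),
    with_seed(cfg$seed, matrix(stats::qlogis(runif(cfg$n_starts * 6)),
                               ncol = 6)))[seq_len(cfg$n_starts), , drop = FALSE]
  if (!is.null(extra_starts)) starts <- rbind(extra_starts, starts)
  is_admissible <- function(par) {
    theta_to_params(par, cfg)[["t_split"]] >= x_break
  }
  best <- best_adm <- NULL
  converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    f0 <- negloglik(starts[s, ])
    fit <- tryCatch(
      optim(starts[s, ], negloglik, method = "Nelder-Mead",
            control = list(maxit = cfg$max_iterations)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$value < f0) converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
    if (is_admissible(fit$par) &&
        (is.null(best_adm) || fit$value < best_adm$value)) best_adm <- fit
  }
  if (is.null(best)) {
    best <- list(par = starts[1, ], value = negloglik(starts[1, ]))
    converged <- FALSE
  } else {
    # polish: restart the simplex from the incumbent optimum on a smoother
    # objective (4x the genealogies), which damps the residual Monte Carlo
    # ruggedness that multi-start search can latch onto
    cfg_hi <- cfg
    cfg_hi$n_reps_likelihood <- 4L * cfg$n_reps_likelihood
    negloglik_hi <- make_negloglik(observed, x_break, cfg_hi, seq_len, mu)
    polish_from <- function(cand) {
      out <- tryCatch(
        optim(cand$par, negloglik_hi, method = "Nelder-Mead",
              control = list(maxit = cfg$max_iterations)),
        error = function(e) NULL)
      if (is.null(out)) list(par = cand$par, value = negloglik_hi(cand$par))
      else out
    }
    separate_adm <- !is.null(best_adm) && !identical(best_adm$par, best$par)
    best <- polish_from(best)
    if (separate_adm) {
      best_adm <- polish_from(best_adm)
      if (!is_admissible(best_adm$par)) best_adm <- NULL
    } else {
      best_adm <- if (is_admissible(best$par)) best else NULL
    }
    # the polished global best may itself have become admissible and better
    if (is_admissible(best$par) &&
        (is.null(best_adm) || best$value < best_adm$value)) best_adm <- best
  }
  p <- theta_to_params(best$par, cfg)
  frac <- plogis(best$par)
  at_bound <- frac < 1e-3 | frac > 1 - 1e-3
  names(at_bound) <- names(p)
  admissible <- NULL
  if (!is.null(best_adm)) {
    admissible <- list(params = theta_to_params(best_adm$par, cfg),
                       loglik = -best_adm$value, theta = best_adm$par)
  }
  structure(list(params = p, x_break = x_break,
                 model = fit_model_from_params(p, x_break),
                 loglik = -best$value,
                 excluded = unname(p[["t_split"]] < x_break),
                 at_bound = at_bound, converged = converged,
                 theta = best$par, admissible = admissible,
                 cfg = cfg, seq_len = seq_len, mu = mu),
            class = "im_fit")
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<im_fit> X = %.6g generations, log composite likelihood %.2f%s\n",
    "  N1=%.4g N2=%.4g NAnc=%.4g t_split=%.5g m_recent=%.3g m_old=%.3g\n"),
    x$x_break, x$loglik,
    if (x$excluded) " [EXCLUDED: t_split < X]" else "",
    x$params[["n1"]], x$params[["n2"]], x$params[["n_ancestral"]],
    x$params[["t_split"]], x$params[["m_recent"]], x$params[["m_old"]]))
  if (x$excluded && !is.null(x$admissible)) {
    cat(sprintf("  best admissible: t_split=%.5g m_recent=%.3g m_old=%.3g\n",
                x$admissible$params[["t_split"]],
                x$admissible$params[["m_recent"]],
                x$admissible$params[["m_old"]]))
  }
  invisible(x)
}

#' @export
tidy.im_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params),
         at_bound = unname(x$at_bound))
}

#' @export
glance.im_fit <- function(x, ...) {
  tibble(x_break = x$x_break, loglik = x$loglik, excluded = x$excluded,
         converged = x$converged, any_at_bound = any(x$at_bound))
}

#' Scan gene flow over a grid of epoch breakpoints
#'
#' Repeats [fit_im_pair()] for every breakpoint X on the grid (default 100
#' to 14,000 generations in steps of 100). The recent-epoch rate of the fit
#' at breakpoint X estimates gene flow integrated from the present back to
#' X; the grid of such estimates is the input to
#' [deconvolve_intervals()]-based dating of gene-flow change. Fits with
#' `t_split < X` are carried but flagged excluded.
#'
#' @param observed A folded minor-allele `joint_sfs`.
#' @param grid Strictly increasing breakpoints in generations.
#' @param cfg A [search_config()].
#' @param pair_id Label for the population pair.
#' @param warm_start Chain the scan: seed each breakpoint's search with the
#'   previous breakpoint's solution (recommended; the objective changes
#'   smoothly in X, so this stabilises the t2 trajectory and speeds up the
#'   scan).
#' @inheritParams fit_im_pair
#' @return A `gene_flow_scan` tibble: one row per X with the six estimates,
#'   log-likelihood and flags.
#' @export
scan_gene_flow <- function(observed, grid = seq(100, 14000, by = 100),
                           cfg = search_config(), pair_id = "pair",
                           seq_len = observed$seq_len, mu = observed$mu,
                           warm_start = TRUE) {
  stopifnot(all(diff(grid) > 0), length(grid) >= 1)
  prev_theta <- NULL
  rows <- purrr::map(grid, function(x) {
    f <- fit_im_pair(observed, x, cfg, seq_len = seq_len, mu = mu,
                     extra_starts = if (warm_start) prev_theta)
    if (warm_start) {
      # chain from the admissible solution when one exists, so a degenerate
      # (excluded) optimum at one breakpoint does not drag the whole scan
      prev_theta <<- matrix(if (is.null(f$admissible)) f$theta
                            else f$admissible$theta, nrow = 1)
    }
    adm <- f$admissible
    tibble(x = x,
           n1 = f$params[["n1"]], n2 = f$params[["n2"]],
           n_ancestral = f$params[["n_ancestral"]],
           t_split = f$params[["t_split"]],
           m_recent = f$params[["m_recent"]], m_old = f$params[["m_old"]],
           loglik = f$loglik, excluded = f$excluded,
           converged = f$converged, any_at_bound = any(f$at_bound),
           has_admissible = !is.null(adm),
           m_recent_adm = if (is.null(adm)) NA_real_ else
             adm$params[["m_recent"]],
           t_split_adm = if (is.null(adm)) NA_real_ else
             adm$params[["t_split"]])
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("gene_flow_scan", class(tibble())),
            pair_id = pair_id)
}

#' Write / read a gene-flow scan as TSV
#'
#' @param scan A `gene_flow_scan` (or compatible data frame).
#' @param path File path.
#' @return `path` invisibly; `read_scan()` returns a `gene_flow_scan`.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(as_tibble(scan), path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  structure(as_tibble(out), class = c("gene_flow_scan", class(tibble())),
            pair_id = sub("\\.tsv$", "", basename(path)))
}
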