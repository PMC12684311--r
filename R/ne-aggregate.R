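#' Convert generations to whole years
#'
#' Floor of generations divided by generations per year; with the default 3
#' generations per year (a 4-month generation time), 14,000 generations is
#' 4,666 years.
#'
#' @param g Generations before present (vectorised, >= 0).
#' @param generations_per_year Generations per year.
#' @return Whole years before present.
#' @export
generations_to_years <- function(g, generations_per_year = 3) {
  stopifnot(all(g >= 0), generations_per_year > 0)
  floor(g / generations_per_year)
}

#' Time-scale configuration
#'
#' @param mutation_rate Per-base, per-generation mutation rate.
#' @param generations_per_year Generations per calendar year.
#' @return A `time_scale_config` list.
#' @export
time_scale_config <- function(mutation_rate = 2.5e-9,
                              generations_per_year = 3) {
  stopifnot(mutation_rate > 0, generations_per_year > 0)
  structure(list(mutation_rate = mutation_rate,
                 generations_per_year = generations_per_year),
            class = "time_scale_config")
}

#' Step-function Ne trajectory
#'
#' A right-continuous step function of diploid effective size against time
#' before present: the value at time t is the Ne of the step whose start is
#' the largest breakpoint not exceeding t.
#'
#' @param time Step start times, strictly increasing, first at 0.
#' @param ne Diploid effective sizes per step (> 0).
#' @param population_id Label.
#' @param time_unit `"years"` or `"generations"`.
#' @return An `ne_trajectory` tibble.
#' @export
ne_trajectory <- function(time, ne, population_id = "pop",
                          time_unit = c("years", "generations")) {
  time_unit <- match.arg(time_unit)
  stopifnot(length(time) == length(ne), length(time) >= 1,
            all(diff(time) > 0), all(ne > 0), time[1] >= 0)
  structure(tibble(time = as.numeric(time), ne = as.numeric(ne)),
            class = c("ne_trajectory", class(tibble())),
            population_id = population_id, time_unit = time_unit)
}

#' Read an Ne trajectory TSV
#'
#' The canonical dialect is two columns (`year`, `Ne_median`). Files in the
#' Stairway Plot `.final.summary` layout are also accepted: the reader looks
#' for a year column and an `Ne_median` column by name and skips everything
#' else.
#'
#' @param path TSV path.
#' @param population_id Label; defaults to the file's base name.
#' @return An [ne_trajectory].
#' @export
read_ne_trajectory <- function(path, population_id = NULL) {
  if (is.null(population_id)) {
    population_id <- sub("\\.(tsv|txt|summary)$", "", basename(path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  year_col <- intersect(c("year", "Year", "time", "year_from_present"),
                        names(x))[1]
  ne_col <- intersect(c("Ne_median", "ne", "Ne", "ne_median", "Ne_Median"),
                      names(x))[1]
  if (is.na(year_col) || is.na(ne_col)) {
    stop("could not find year/Ne columns in ", path)
  }
  d <- dplyr::distinct(
    dplyr::arrange(tibble(time = x[[year_col]], ne = x[[ne_col]]), .data$time),
    .data$time, .keep_all = TRUE)
  ne_trajectory(d$time, d$ne, population_id = population_id)
}

#' Evaluate a step trajectory on a time grid
#'
#' Step-function evaluation: each grid time takes the Ne of the step
#' containing it; times beyond the last breakpoint take the last value.
#'
#' @param traj An [ne_trajectory].
#' @param grid Times (same unit as the trajectory), >= 0.
#' @return Numeric Ne values on the grid.
#' @export
to_grid <- function(traj, grid) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (nrow(traj) == 0) stop("empty trajectory")
  idx <- findInterval(grid, traj$time)
  traj$ne[pmax(idx, 1L)]
}

#' z-transform a vector
#'
#' Centring and scaling with the sample (n - 1) standard deviation, as
#' `scale()` does.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return z-scores with mean 0 and sd 1.
#' @export
z_transform <- function(values) {
  if (length(values) < 2 || sd(values) == 0) {
    stop("z-transform needs at least two distinct values (zero variance)")
  }
  as.numeric(scale(values))
}

#' Aggregate Ne trajectories across populations
#'
#' Each population's trajectory is evaluated on a common time grid and
#' z-transformed (so the aggregate tracks the common shape of demographic
#' change, not absolute sizes, and is invariant to per-population scale
#' conventions). The mean z-score across populations is reported per grid
#' time, with a population-level bootstrap band (2.5%/97.5% quantiles of the
#' bootstrap means).
#'
#' @param trajs List of [ne_trajectory] objects.
#' @param grid Common time grid; default 200 log-spaced points from 10 to
#'   50,000 years.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @return An `ne_aggregate` tibble: `time`, `mean_z`, `ci_low`, `ci_high`;
#'   per-population z-scores in attribute `z_matrix`.
#' @export
aggregate_ne <- function(trajs, grid = 10^seq(1, log10(50000), length.out = 200),
                         B = 1000, seed = 1) {
  stopifnot(is.list(trajs), length(trajs) >= 1, B >= 1)
  z <- vapply(trajs, function(tr) z_transform(to_grid(tr, grid)),
              numeric(length(grid)))
  z <- matrix(z, nrow = length(grid))
  colnames(z) <- vapply(trajs, attr, character(1), "population_id")
  mean_z <- rowMeans(z)
  draws <- with_seed(seed, {
    matrix(sample.int(length(trajs), length(trajs) * B, replace = TRUE),
           nrow = B)
  })
  boots <- t(apply(draws, 1, function(idx) {
    rowMeans(z[, idx, drop = FALSE])
  }))
  qs <- apply(boots, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(tibble(time = grid, mean_z = mean_z,
                   ci_low = qs[1, ], ci_high = qs[2, ]),
            class = c("ne_aggregate", class(tibble())),
            z_matrix = z, B = as.integer(B))
}
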