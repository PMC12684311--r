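#' Read-depth model for pool sequencing
#'
#' Per-site total depths are drawn from a normal distribution (rounded) and,
#' in clean mode, clamped inside the depth-filter bounds so every emitted
#' SNP survives filtering. In dirty mode a stated fraction of records is
#' pushed outside the bounds to exercise the depth filter.
#'
#' @param mean_depth,dispersion Mean and standard deviation of per-site depth.
#' @param min_depth,max_depth Clamp bounds for clean records.
#' @param out_of_bounds_fraction Fraction of records pushed outside the
#'   bounds (dirty mode); 0 for clean data.
#' @return A `depth_model` list.
#' @export
depth_model <- function(mean_depth = 450, dispersion = 40, min_depth = 301,
                        max_depth = 599, out_of_bounds_fraction = 0) {
  stopifnot(mean_depth > 0, dispersion >= 0,
            out_of_bounds_fraction >= 0, out_of_bounds_fraction <= 1,
            mean_depth >= min_depth, mean_depth <= max_depth)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 min_depth = min_depth, max_depth = max_depth,
                 out_of_bounds_fraction = out_of_bounds_fraction),
            class = "depth_model")
}

# Clean in-bounds depths; out-of-bounds injection is handled by the caller
# so it can avoid sites that earlier filter rules would already remove.
draw_depths <- function(n, dm) {
  pmin(pmax(round(stats::rnorm(n, dm$mean_depth, dm$dispersion)),
            dm$min_depth), dm$max_depth)
}

inject_bad_depths <- function(d, dm, allowed) {
  n_bad <- round(dm$out_of_bounds_fraction * length(d))
  idx <- integer(0)
  if (n_bad > 0 && any(allowed)) {
    idx <- sample(which(allowed), min(n_bad, sum(allowed)))
    low <- sample(c(TRUE, FALSE), length(idx), replace = TRUE)
    d[idx] <- ifelse(low,
                     sample(seq(50, dm$min_depth - 1), length(idx),
                            replace = TRUE),
                     sample(seq(dm$max_depth + 1, dm$max_depth + 300),
                            length(idx), replace = TRUE))
  }
  list(depths = d, idx = idx)
}

format_vcf_records <- function(rec) {
  sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tDP=%d\tDP:AD\t%d:%d,%d",
          rec$chrom, rec$pos, rec$ref, rec$alt, rec$depth, rec$depth,
          rec$ref_reads, rec$alt_reads)
}

vcf_header <- function(population_id) {
  c("##fileformat=VCFv4.2",
    "##source=gfchrono synthetic pooled data",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           population_id))
}

write_truth <- function(truth, path) {
  lines <- vapply(names(truth), function(k) {
    paste0(k, "=", paste(format(truth[[k]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(z) {
    v <- strsplit(z[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  })
  setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Generate a synthetic pooled-sequencing dataset with known truth
#'
#' Draws per-site joint allele frequencies for two populations from the
#' structured coalescent under the given demography, then simulates pooled
#' reads: each population is a pool of `pool_n` chromosomes and per-site
#' read counts are binomial around the true pool frequency (all individuals
#' contributing equally). Writes one VCF 4.2 file per population (with
#' `DP`/`AD`), a BED mask, a coordinates table, and a truth file recording
#' the generating parameters and per-site true frequencies.
#'
#' In dirty mode, indel records (plus nearby SNPs), out-of-depth records and
#' masked intervals are injected at stated fractions so every site-filter
#' rule fires.
#'
#' @param model An [im_model] (or `im_scenario`) generating the site
#'   frequencies.
#' @param out_dir Output directory (created if missing).
#' @param sites Target number of variant records per population.
#' @param depth A [depth_model()].
#' @param pool_n Chromosomes per pool (50 diploids = 100).
#' @param mu Mutation rate (defaults to 2.5e-9, or the scenario's rate).
#' @param dirty Inject filter-violating records and masks?
#' @param indel_fraction,masked_fraction Fractions of extra dirty records.
#' @param seed Integer seed; the same seed reproduces the files byte for
#'   byte.
#' @return List with `vcf_paths`, `bed_path`, `coords_path`, `truth_path`
#'   and the `truth` list.
#' @export
generate_pooled_dataset <- function(model, out_dir, sites = 2000,
                                    depth = depth_model(), pool_n = 100,
                                    mu = NULL, dirty = FALSE,
                                    indel_fraction = 0.02,
                                    masked_fraction = 0.05, seed = 1) {
  if (inherits(model, "im_scenario")) {
    if (is.null(mu)) mu <- model$mutation_rate
    model <- model$model
  }
  stopifnot(inherits(model, "im_model"))
  if (is.null(mu)) mu <- 2.5e-9
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 3)

  # joint frequency distribution of variant sites: branch-length mass per
  # descendant configuration under the demography
  tal <- sample_genealogy(model, pool_n, pool_n,
                          n_reps = max(200, ceiling(2e4 / pool_n)),
                          seed = seeds[1])
  mass <- tal$mean_tally
  mass[1, 1] <- 0
  mass[pool_n + 1, pool_n + 1] <- 0
  cells <- which(mass > 0, arr.ind = TRUE)
  probs <- mass[cells] / sum(mass[cells])

  genome_len <- max(sites * 500, 1e6)
  out <- with_seed(seeds[2], {
    pick <- sample.int(nrow(cells), sites, replace = TRUE, prob = probs)
    pos <- sort(sample.int(genome_len, sites))
    tibble(chrom = "chr1", pos = pos,
           p1 = (cells[pick, 1] - 1) / pool_n,
           p2 = (cells[pick, 2] - 1) / pool_n)
  })

  pops <- c("pop1", "pop2")
  coords <- tibble(id = pops, lat = c(56.1, 56.6), lon = c(9.5, 10.2))
  vcf_paths <- file.path(out_dir, paste0(pops, ".vcf"))
  bed_path <- file.path(out_dir, "mask.bed")
  mask <- tibble(chrom = character(), start = numeric(), end = numeric())

  truth <- list(seed = seed, sites = sites, pool_n = pool_n, mu = mu,
                n1 = model$n1, n2 = model$n2,
                n_ancestral = model$n_ancestral, t_split = model$t_split,
                m_recent = model$m_recent, m_old = model$m_old,
                dirty = as.integer(dirty),
                pos = out$pos, p1 = out$p1, p2 = out$p2)

  with_seed(seeds[3], {
    indel_pos <- integer(0)
    if (dirty) {
      n_indel <- max(1L, round(indel_fraction * sites))
      indel_pos <- sort(sample(setdiff(seq(10, genome_len - 10), out$pos),
                               n_indel))
      n_mask <- max(1L, round(masked_fraction * sites / 10))
      mask_start <- sort(sample.int(genome_len - 2000, n_mask))
      mask <- tibble(chrom = "chr1", start = mask_start,
                     end = mask_start + 1500)
      truth$indel_pos <- indel_pos
    }
    # depth outliers go only to SNPs outside any indel flank, so the depth
    # rule's removal tally equals the injected count exactly
    clear_of_indels <- if (length(indel_pos) == 0) {
      rep(TRUE, nrow(out))
    } else {
      vapply(out$pos, function(p) all(abs(p - indel_pos) > 5), logical(1))
    }
    for (k in 1:2) {
      p <- if (k == 1) out$p1 else out$p2
      dm <- depth
      inj <- inject_bad_depths(draw_depths(length(p), dm), dm,
                               allowed = clear_of_indels)
      d <- inj$depths
      truth[[paste0("depth_out_", pops[k])]] <- sort(out$pos[inj$idx])
      alt_reads <- stats::rbinom(length(p), d, p)
      rec <- tibble(chrom = out$chrom, pos = out$pos, ref = "A", alt = "C",
                    depth = d, ref_reads = d - alt_reads,
                    alt_reads = alt_reads)
      if (dirty) {
        di <- draw_depths(length(indel_pos),
                          depth_model(dm$mean_depth, dm$dispersion,
                                      dm$min_depth, dm$max_depth, 0))
        ai <- stats::rbinom(length(indel_pos), di, 0.3)
        rec <- dplyr::bind_rows(rec,
          tibble(chrom = "chr1", pos = indel_pos, ref = "AT", alt = "A",
                 depth = di, ref_reads = di - ai, alt_reads = ai))
        rec <- dplyr::arrange(rec, .data$pos)
      }
      writeLines(c(vcf_header(pops[k]), format_vcf_records(rec)),
                 vcf_paths[k])
    }
  })

  readr::write_tsv(mask, bed_path, col_names = FALSE)
  coords_path <- file.path(out_dir, "coordinates.tsv")
  readr::write_tsv(dplyr::mutate(coords, vcf_path = vcf_paths), coords_path)
  truth_path <- file.path(out_dir, "truth.txt")
  write_truth(truth, truth_path)
  list(vcf_paths = setNames(vcf_paths, pops), bed_path = bed_path,
       coords_path = coords_path, truth_path = truth_path, truth = truth)
}

#' Generate synthetic Ne step trajectories
#'
#' Emulates post-glacial demographic histories: a rise in effective size
#' after the glacial retraction followed by a recent drop
#' (`"postglacial-rise-then-fall"`), a flat history (`"constant"`), or the
#' rise-and-fall shape with multiplicative log-normal noise (`"noisy"`).
#'
#' @param n_pops Number of populations.
#' @param shape One of `"postglacial-rise-then-fall"`, `"constant"`,
#'   `"noisy"`.
#' @param seed Integer seed.
#' @param noise_sd Log-scale noise SD for the `"noisy"` shape.
#' @param out_dir Optional directory: writes one `(year, Ne_median)` TSV per
#'   population plus a truth file.
#' @return List with `trajectories` (list of [ne_trajectory]) and `truth`.
#' @export
generate_ne_trajectories <- function(n_pops, shape = "postglacial-rise-then-fall",
                                     seed = 1, noise_sd = 0.2,
                                     out_dir = NULL) {
  shapes <- c("postglacial-rise-then-fall", "constant", "noisy")
  shape <- match.arg(shape, shapes)
  stopifnot(n_pops >= 1)
  times <- c(0, 500, 1000, 2000, 4000, 8000, 15000, 25000, 40000)
  base <- switch(shape,
    "constant" = rep(1e5, length(times)),
    # backwards in time: recent drop, mid-Holocene high, glacial low
    c(4e4, 6e4, 1.2e5, 2e5, 2.2e5, 1.8e5, 8e4, 3e4, 2e4))
  sdlog <- if (shape == "noisy") noise_sd else 0
  trajs <- with_seed(seed, {
    lapply(seq_len(n_pops), function(k) {
      ne <- base * exp(stats::rnorm(length(base), 0, sdlog))
      ne_trajectory(times, ne, population_id = paste0("pop", k))
    })
  })
  truth <- list(shape = shape, seed = seed, n_pops = n_pops,
                noise_sd = sdlog, time = times, ne_base = base)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tr in trajs) {
      readr::write_tsv(tibble(year = tr$time, Ne_median = tr$ne),
                       file.path(out_dir, paste0(attr(tr, "population_id"),
                                                 ".tsv")))
    }
    write_truth(truth, file.path(out_dir, "truth.txt"))
  }
  list(trajectories = trajs, truth = truth)
}

#' Per-interval gene-flow schedule of a model
#'
#' True migration rate in each 100-generation interval up to `max_x`
#' (evaluated at the interval midpoint; rates are constant within the
#' model's migration steps).
#'
#' @param model An [im_model] or `im_scenario`.
#' @param max_x Oldest interval end, generations.
#' @param interval Interval width.
#' @return Tibble `interval_start`, `interval_end`, `rate`.
#' @export
gene_flow_schedule <- function(model, max_x = 14000, interval = 100) {
  if (inherits(model, "im_scenario")) model <- model$model
  ends <- seq(interval, max_x, by = interval)
  tibble(interval_start = ends - interval, interval_end = ends,
         rate = migration_at(model, ends - interval / 2))
}

#' Generate synthetic t2 scan trajectories from a known schedule
#'
#' Builds per-pair integrated gene-flow trajectories consistent with the
#' running-mean model: t2 at breakpoint X equals the mean of the true
#' per-interval rates from the present back to X, plus optional Gaussian
#' noise (truncated at zero). The generating schedule is returned as truth,
#' so recovery tests can compare deconvolved rates against it.
#'
#' @param schedule Tibble from [gene_flow_schedule()] (columns
#'   `interval_end`, `rate`), defined on the full contiguous grid.
#' @param noise_sd SD of additive Gaussian noise on each t2 value.
#' @param n_pairs Number of population pairs to emit.
#' @param seed Integer seed.
#' @return List with `pairs` (list of [t2_trajectory]) and `truth`.
#' @export
generate_scan_fixture <- function(schedule, noise_sd = 0, n_pairs = 1,
                                  seed = 1) {
  stopifnot(all(c("interval_end", "rate") %in% names(schedule)),
            n_pairs >= 1)
  x <- schedule$interval_end
  if (any(diff(x) != diff(x)[1])) stop("schedule grid must be contiguous")
  t2_true <- running_mean(schedule$rate)
  pairs <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(k) {
      t2 <- pmax(t2_true + stats::rnorm(length(x), 0, noise_sd), 0)
      t2_trajectory(x, t2, pair_id = paste0("pair", k))
    })
  })
  list(pairs = pairs,
       truth = list(seed = seed, noise_sd = noise_sd, n_pairs = n_pairs,
                    interval_end = x, act = schedule$rate, t2 = t2_true))
}
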