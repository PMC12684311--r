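#' Site-filter configuration
#'
#' Defaults reproduce the pooled-data filtering used for all downstream
#' statistics: drop sites within 5 bp of an indel, drop the indels
#' themselves, keep total depth inside \[301, 599\] (inclusive at both ends),
#' keep only biallelic sites, and mask genic/repetitive intervals.
#'
#' @param indel_flank_bp Flank around indel records to remove, in bp.
#' @param min_depth,max_depth Inclusive depth bounds for retained sites.
#' @param biallelic_only Drop records with more than two alleles?
#' @param mask_regions Tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`), e.g. from [read_mask_bed()]; `NULL` for none.
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(indel_flank_bp = 5L, min_depth = 301L,
                               max_depth = 599L, biallelic_only = TRUE,
                               mask_regions = NULL) {
  stopifnot(indel_flank_bp >= 0, min_depth <= max_depth)
  structure(list(indel_flank_bp = as.integer(indel_flank_bp),
                 min_depth = as.numeric(min_depth),
                 max_depth = as.numeric(max_depth),
                 biallelic_only = isTRUE(biallelic_only),
                 mask_regions = mask_regions),
            class = "site_filter_config")
}

#' Filter pooled variant sites
#'
#' Applies the site filters in a fixed order, each rule seeing only the
#' survivors of the previous one: (1) SNPs within `indel_flank_bp` of an
#' indel record, (2) indel records themselves, (3) depth outside
#' \[`min_depth`, `max_depth`\], (4) non-biallelic records, (5) records inside
#' mask intervals. The per-rule removal tally is attached as the `removals`
#' attribute (also via [filter_tally()]).
#'
#' @param table A [pooled_sites] table.
#' @param cfg A [site_filter_config].
#' @return The surviving [pooled_sites] rows, with a `removals` attribute.
#' @export
filter_sites <- function(table, cfg = site_filter_config()) {
  stopifnot(inherits(table, "pooled_sites"), inherits(cfg, "site_filter_config"))
  x <- as_tibble(table)
  tally <- c(indel_flank = 0L, indel = 0L, depth = 0L,
             multiallelic = 0L, masked = 0L)

  # (1) proximity to an indel; indel records themselves are judged by rule 2
  indels <- dplyr::filter(x, .data$is_indel)
  if (nrow(indels) > 0 && cfg$indel_flank_bp > 0) {
    near <- rep(FALSE, nrow(x))
    for (ch in unique(indels$chrom)) {
      on_ch <- x$chrom == ch
      ipos <- sort(indels$pos[indels$chrom == ch])
      idx <- findInterval(x$pos[on_ch], ipos - cfg$indel_flank_bp)
      lower <- findInterval(x$pos[on_ch], ipos + cfg$indel_flank_bp + 1L)
      near[on_ch] <- idx > lower
    }
    near <- near & !x$is_indel
    tally["indel_flank"] <- sum(near)
    x <- x[!near, ]
  }

  # (2) indels
  tally["indel"] <- sum(x$is_indel)
  x <- dplyr::filter(x, !.data$is_indel)

  # (3) depth bounds, inclusive
  bad_depth <- x$depth < cfg$min_depth | x$depth > cfg$max_depth
  tally["depth"] <- sum(bad_depth)
  x <- x[!bad_depth, ]

  # (4) biallelic only
  if (cfg$biallelic_only) {
    multi <- x$n_alleles > 2L
    tally["multiallelic"] <- sum(multi)
    x <- x[!multi, ]
  }

  # (5) masks (BED convention: 0-based half-open vs 1-based VCF positions)
  if (!is.null(cfg$mask_regions) && nrow(cfg$mask_regions) > 0 && nrow(x) > 0) {
    masked <- rep(FALSE, nrow(x))
    for (ch in unique(cfg$mask_regions$chrom)) {
      on_ch <- x$chrom == ch
      if (!any(on_ch)) next
      iv <- cfg$mask_regions[cfg$mask_regions$chrom == ch, ]
      p0 <- x$pos[on_ch] - 1L  # to 0-based
      hit <- vapply(p0, function(p) any(p >= iv$start & p < iv$end), logical(1))
      masked[on_ch] <- hit
    }
    tally["masked"] <- sum(masked)
    x <- x[!masked, ]
  }

  out <- restore_pooled(x, table)
  attr(out, "removals") <- tally
  out
}

#' Per-rule removal tally from a filtered table
#'
#' @param table Output of [filter_sites()].
#' @return Tibble with columns `rule` and `n_removed`.
#' @export
filter_tally <- function(table) {
  tally <- attr(table, "removals")
  if (is.null(tally)) stop("table carries no removal tally; run filter_sites() first")
  tibble(rule = names(tally), n_removed = as.integer(tally))
}
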