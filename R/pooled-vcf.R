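#' Construct a pooled-site table
#'
#' A `pooled_sites` object is a tibble of per-site records from one
#' population pool, carrying the pool metadata (population id, number of
#' chromosomes in the pool, sampling coordinates) as attributes. Each row is
#' one variant-call record with its total read depth and the alternate-allele
#' frequency observed in the pooled reads.
#'
#' @param records Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `depth`, `alt_freq`, `is_indel`, `n_alleles`.
#' @param population_id Label for the population pool.
#' @param n_chromosomes Number of chromosomes in the pool (50 diploids = 100).
#' @param lat,lon Sampling coordinates in decimal degrees (WGS84), optional.
#' @return A `pooled_sites` tibble sorted by (`chrom`, `pos`).
#' @export
pooled_sites <- function(records, population_id, n_chromosomes = 100L,
                         lat = NA_real_, lon = NA_real_) {
  stopifnot(n_chromosomes >= 2)
  needed <- c("chrom", "pos", "ref", "alt", "depth", "alt_freq",
              "is_indel", "n_alleles")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as_tibble(records)[needed]
  if (any(x$pos < 1)) stop("positions must be 1-based (pos >= 1)")
  if (any(x$depth < 0)) stop("depth must be non-negative")
  bad_freq <- !is.na(x$alt_freq) & (x$alt_freq < 0 | x$alt_freq > 1)
  if (any(bad_freq)) stop("alt_freq must lie in [0, 1]")
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  structure(x,
            class = c("pooled_sites", class(tibble())),
            population_id = as.character(population_id),
            n_chromosomes = as.integer(n_chromosomes),
            coordinates = c(lat = lat, lon = lon))
}

#' @export
print.pooled_sites <- function(x, ...) {
  cat(sprintf("<pooled_sites> population %s: %d sites, pool of %d chromosomes\n",
              attr(x, "population_id"), nrow(x), attr(x, "n_chromosomes")))
  NextMethod()
}

n_chromosomes <- function(x) attr(x, "n_chromosomes")

# Rebuild a pooled_sites object after a dplyr verb stripped its attributes.
restore_pooled <- function(records, template) {
  pooled_sites(records,
               population_id = attr(template, "population_id"),
               n_chromosomes = attr(template, "n_chromosomes"),
               lat = attr(template, "coordinates")[["lat"]],
               lon = attr(template, "coordinates")[["lon"]])
}

#' Read a pooled VCF into a site table
#'
#' Parses a VCF (4.x) of pooled variant calls for one population. The
#' alternate-allele frequency is taken from the per-sample allelic depths
#' (`AD`) when present, otherwise from `INFO/AF`; total depth comes from the
#' sample `DP`, the sum of `AD`, or `INFO/DP`, in that order of preference.
#' Multi-allelic records are kept, with the allele count recorded, so the
#' site filter can remove them later; for those records `alt_freq` is the
#' combined frequency of all non-reference alleles.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param pool_n Number of chromosomes in the pool.
#' @param population_id Pool label; defaults to the file's base name.
#' @param lat,lon Optional sampling coordinates (decimal degrees).
#' @return A [pooled_sites] tibble, one row per VCF record.
#' @export
read_pooled_vcf <- function(path, pool_n = 100L, population_id = NULL,
                            lat = NA_real_, lon = NA_real_) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  if (is.null(population_id)) {
    population_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) stop("VCF contains no records: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_split <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alt_split)
  is_indel <- mapply(function(r, as) {
    nchar(r) != 1L || any(nchar(as) != 1L) || any(as == "*")
  }, ref, alt_split, USE.NAMES = FALSE)

  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  dp_fmt <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
  info_af <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF")))

  ref_reads <- alt_reads <- rep(NA_real_, n)
  if (!is.null(ad)) {
    counts <- strsplit(ifelse(is.na(ad[, 1]), "", ad[, 1]), ",", fixed = TRUE)
    ref_reads <- vapply(counts, function(z) {
      if (length(z) < 2) NA_real_ else suppressWarnings(as.numeric(z[1]))
    }, numeric(1))
    alt_reads <- vapply(counts, function(z) {
      if (length(z) < 2) NA_real_ else sum(suppressWarnings(as.numeric(z[-1])))
    }, numeric(1))
  }
  depth <- if (!is.null(dp_fmt)) dp_fmt[, 1] else rep(NA_real_, n)
  depth <- ifelse(is.na(depth), ref_reads + alt_reads, depth)
  depth <- ifelse(is.na(depth), info_dp, depth)
  if (anyNA(depth)) {
    stop("VCF record(s) without a usable depth field (sample DP, AD or INFO/DP): ",
         path, " record ", which(is.na(depth))[1])
  }
  alt_freq <- ifelse(!is.na(alt_reads) & (ref_reads + alt_reads) > 0,
                     alt_reads / (ref_reads + alt_reads), NA_real_)
  alt_freq <- ifelse(is.na(alt_freq), info_af, alt_freq)
  if (anyNA(alt_freq)) {
    stop("VCF record(s) without AD or INFO/AF to derive allele frequency: ",
         path, " record ", which(is.na(alt_freq))[1])
  }

  pooled_sites(
    tibble(chrom = fix[, "CHROM"],
           pos = as.integer(fix[, "POS"]),
           ref = ref, alt = alt,
           depth = unname(as.numeric(depth)),
           alt_freq = unname(pmin(pmax(alt_freq, 0), 1)),
           is_indel = is_indel,
           n_alleles = n_alleles),
    population_id = population_id, n_chromosomes = pool_n,
    lat = lat, lon = lon)
}

# Cheap structural pass over the raw lines so a malformed record is reported
# with its line number, which vcfR does not do.
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield < 8)) {
    bad <- body[which(nfield < 8)[1]]
    stop("malformed VCF record at line ", bad, " of ", path,
         " (fewer than 8 tab-separated fields)")
  }
  pos <- suppressWarnings(as.integer(
    vapply(strsplit(lines[body], "\t", fixed = TRUE), `[`, character(1), 2)))
  if (anyNA(pos)) {
    bad <- body[which(is.na(pos))[1]]
    stop("malformed VCF record at line ", bad, " of ", path,
         " (POS is not an integer)")
  }
  invisible(TRUE)
}

#' Read a BED file of mask intervals
#'
#' BED intervals are 0-based, half-open; they are used to mask genic and
#' repetitive regions during site filtering.
#'
#' @param path Path to a 3+ column BED file.
#' @return Tibble with columns `chrom`, `start` (0-based), `end` (exclusive).
#' @export
read_mask_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE, comment = "#")
  if (ncol(x) < 3) stop("BED file needs at least 3 columns: ", path)
  tibble(chrom = as.character(x[[1]]),
         start = as.numeric(x[[2]]),
         end = as.numeric(x[[3]]))
}
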