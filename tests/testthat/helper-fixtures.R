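# Fixtures built in code: a pooled VCF with hand-enumerated filter fates,
# plus small constructors used across test files.

# 12-record pooled VCF exercising every site-filter rule (defaults: 5 bp
# indel flank, depth in [301, 599], biallelic only, mask chr1:2000-2100
# 0-based half-open). Hand-enumerated fates:
#   pos 100  SNP depth 400          keep
#   pos 150  indel (AT>A)           removed: indel
#   pos 153  SNP, 3 bp from indel   removed: indel_flank
#   pos 160  SNP, 10 bp from indel  keep
#   pos 300  SNP depth 300          removed: depth (300 < 301)
#   pos 301  SNP depth 301          keep (inclusive bound)
#   pos 400  SNP depth 599          keep (inclusive bound)
#   pos 401  SNP depth 600          removed: depth
#   pos 500  SNP with 2 ALTs        removed: multiallelic
#   pos 2050 SNP                    removed: masked (0-based 2049)
#   pos 2100 SNP                    removed: masked (0-based 2099)
#   pos 2101 SNP                    keep (0-based 2100, interval end open)
# Survivors: 100, 160, 301, 400, 2101; tally: flank 1, indel 1, depth 2,
# multiallelic 1, masked 2.
write_filter_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rec <- function(pos, ref, alt, dp, ad) {
    sprintf("chr1\t%d\t.\t%s\t%s\t100\tPASS\tDP=%d\tDP:AD\t%d:%s",
            pos, ref, alt, dp, dp, ad)
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool",
    rec(100, "A", "C", 400, "300,100"),
    rec(150, "AT", "A", 400, "250,150"),
    rec(153, "G", "T", 400, "200,200"),
    rec(160, "C", "G", 400, "390,10"),
    rec(300, "A", "C", 300, "120,180"),
    rec(301, "A", "C", 301, "200,101"),
    rec(400, "T", "A", 599, "400,199"),
    rec(401, "T", "A", 600, "300,300"),
    rec(500, "A", "C,T", 400, "200,100,100"),
    rec(2050, "G", "A", 400, "350,50"),
    rec(2100, "G", "A", 400, "100,300"),
    rec(2101, "G", "A", 400, "100,300"))
  vcf <- file.path(dir, "fixture.vcf")
  writeLines(lines, vcf)
  bed <- file.path(dir, "mask.bed")
  writeLines("chr1\t2000\t2100", bed)
  list(vcf = vcf, bed = bed,
       survivors = c(100L, 160L, 301L, 400L, 2101L),
       tally = c(indel_flank = 1L, indel = 1L, depth = 2L,
                 multiallelic = 1L, masked = 2L))
}

# Bare pooled_sites table from frequency vectors (depth constant, SNPs only).
freq_table <- function(p, n = 100L, id = "pop", pos = seq_along(p) * 10L,
                       lat = NA_real_, lon = NA_real_) {
  pooled_sites(
    tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "C",
                   depth = 450, alt_freq = p, is_indel = FALSE,
                   n_alleles = 2L),
    population_id = id, n_chromosomes = n, lat = lat, lon = lon)
}

# Small symmetric Fst-like matrix with labels.
named_dist <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  structure(m, n_sites = matrix(1L, nrow(m), ncol(m), dimnames = list(ids, ids)),
            class = c("fst_matrix", "matrix", "array"))
}
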