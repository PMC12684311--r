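test_that("pooled VCF parsing recovers positions, depths and frequencies", {
  fx <- write_filter_fixture()
  tab <- read_pooled_vcf(fx$vcf, pool_n = 100)
  expect_s3_class(tab, "pooled_sites")
  expect_equal(nrow(tab), 12)
  expect_equal(tab$pos[1:3], c(100L, 150L, 153L))
  # AD = 120,180 at depth 300 gives alt_freq 0.6
  expect_equal(tab$alt_freq[tab$pos == 300], 0.6)
  # two ALT alleles recorded, not dropped
  expect_equal(tab$n_alleles[tab$pos == 500], 3L)
  expect_true(tab$is_indel[tab$pos == 150])
  expect_false(any(tab$is_indel[tab$pos != 150]))
})

test_that("malformed or depth-less VCF records are reported with context", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC",
               "chr1\t200\t.\tA\tC\t50\tPASS\t."), bad)
  expect_error(read_pooled_vcf(bad), "line 3")

  nodp <- file.path(dir, "nodp.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC\t50\tPASS\tAF=0.5"), nodp)
  expect_error(read_pooled_vcf(nodp), "depth")
})

test_that("site filters remove the hand-enumerated records in order", {
  fx <- write_filter_fixture()
  tab <- read_pooled_vcf(fx$vcf, pool_n = 100)
  cfg <- site_filter_config(mask_regions = read_mask_bed(fx$bed))
  kept <- filter_sites(tab, cfg)
  expect_equal(kept$pos, fx$survivors)
  tally <- filter_tally(kept)
  expect_equal(setNames(tally$n_removed, tally$rule),
               setNames(as.integer(fx$tally), names(fx$tally)))
  # removal tallies account exactly for the input/output difference
  expect_equal(sum(tally$n_removed), nrow(tab) - nrow(kept))
})

test_that("depth bounds are inclusive and the indel flank is 5 bp", {
  tab <- pooled_sites(
    tibble::tibble(chrom = "chr1",
                   pos = c(100L, 103L, 106L, 200L, 201L),
                   ref = c("AT", "A", "A", "A", "A"),
                   alt = c("A", "C", "C", "C", "C"),
                   depth = c(400, 400, 400, 300, 301),
                   alt_freq = 0.5,
                   is_indel = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                   n_alleles = 2L),
    "p", 100)
  kept <- filter_sites(tab, site_filter_config())
  # 103 is 3 bp from the indel (removed), 106 is 6 bp away (kept);
  # depth 300 fails the lower bound, 301 passes
  expect_equal(kept$pos, c(106L, 201L))
})

test_that("Nei per-site diversity matches the closed form", {
  expect_equal(nei_pi_site(0, 100), 0)
  expect_equal(nei_pi_site(0.5, 100), 2 * 0.25 * 100 / 99)
  expect_equal(nei_pi_site(0.1, 100), 2 * 0.09 * 100 / 99)
  expect_error(nei_pi_site(0.5, 1), "at least 2")
  # symmetric in p <-> 1 - p and maximal at 0.5
  p <- seq(0, 1, by = 0.05)
  expect_equal(nei_pi_site(p, 50), nei_pi_site(1 - p, 50))
  expect_equal(which.max(nei_pi_site(p, 50)), which(p == 0.5))
  # tends to 2 p (1 - p) for large n
  expect_equal(nei_pi_site(0.3, 1e8), 2 * 0.3 * 0.7, tolerance = 1e-6)
})

test_that("population diversity averages over all retained sites", {
  expect_equal(population_pi(freq_table(rep(0, 5))), 0)
  expect_equal(population_pi(freq_table(c(0, 0.5))),
               mean(c(0, 2 * 0.25 * 100 / 99)))
  expect_error(population_pi(freq_table(numeric(0))), "empty")
  # site-loop oracle on 100 random frequencies
  set.seed(42)
  p <- runif(100)
  oracle <- mean(vapply(p, function(x) 2 * x * (1 - x) * 100 / 99, 1))
  expect_equal(population_pi(freq_table(p)), oracle)
})

test_that("pairwise Fst follows the within/total diversity decomposition", {
  a <- freq_table(c(0.2, 0.5, 0.9), id = "a")
  expect_equal(pairwise_fst(a, freq_table(c(0.2, 0.5, 0.9), id = "b")), 0)
  expect_equal(pairwise_fst(freq_table(0), freq_table(1)), 1)
  expect_error(pairwise_fst(freq_table(0.5, pos = 10L),
                            freq_table(0.5, pos = 20L)), "shared")
  expect_true(is.na(pairwise_fst(freq_table(c(0, 0)), freq_table(c(0, 0)))))
  # 5-site hand-computed oracle
  pa <- c(0.1, 0.4, 0.8, 0.0, 1.0)
  pb <- c(0.3, 0.4, 0.2, 0.0, 0.0)
  n <- 100
  pi_a <- 2 * pa * (1 - pa) * n / (n - 1)
  pi_b <- 2 * pb * (1 - pb) * n / (n - 1)
  pbar <- (pa + pb) / 2
  pi_tot <- 2 * pbar * (1 - pbar) * n / (n - 1)
  oracle <- (sum(pi_tot) - sum((pi_a + pi_b) / 2)) / sum(pi_tot)
  expect_equal(pairwise_fst(freq_table(pa), freq_table(pb)), oracle)
})

test_that("folded SFS tallies minor-allele counts and can drop singletons", {
  tab <- freq_table(c(0.1, 0.9, 0.2), n = 10)  # minor counts 1, 1, 2
  sfs <- folded_sfs(tab)
  expect_equal(sfs$n_sites[sfs$minor_count == 1], 2)
  expect_equal(sfs$n_sites[sfs$minor_count == 2], 1)
  expect_equal(sum(sfs$n_sites), nrow(tab))
  no_single <- folded_sfs(tab, exclude_singletons = TRUE)
  expect_false(1 %in% no_single$minor_count)
  expect_true(attr(no_single, "singletons_excluded"))
  expect_equal(no_single$n_sites[no_single$minor_count == 2], 1)
  mono <- folded_sfs(freq_table(rep(0, 4), n = 10))
  expect_equal(mono$n_sites[mono$minor_count == 0], 4)
})

test_that("allele-count rounding sends exact halves toward the minor allele", {
  # p * n = 4.5 on n = 10: minor side, rounds down
  expect_equal(round_allele_count(0.45, 10), 4L)
  # p * n = 5.5 on n = 10: major side, rounds up (minor count rounds down)
  expect_equal(round_allele_count(0.55, 10), 6L)
  expect_equal(round_allele_count(c(0, 1, 0.5), 10), c(0L, 10L, 5L))
})

test_that("joint 2d SFS tallies shared sites and folds by global minor allele", {
  pa <- c(0.0, 0.2, 1.0, 0.9)
  pb <- c(0.0, 0.1, 1.0, 1.0)
  a <- freq_table(pa, n = 10, id = "a")
  b <- freq_table(pb, n = 10, id = "b")
  unfolded <- joint_2dsfs(a, b, fold = FALSE)
  # hand enumeration: (0,0), (2,1), (10,10), (9,10)
  expect_equal(unfolded$counts[1, 1], 1)
  expect_equal(unfolded$counts[3, 2], 1)
  expect_equal(unfolded$counts[11, 11], 1)
  expect_equal(unfolded$counts[10, 11], 1)
  expect_equal(sum(unfolded$counts), 4)
  folded <- joint_2dsfs(a, b, fold = TRUE)
  # (10,10) -> (0,0); (9,10) -> (1,0); (2,1) stays (sum 3 <= 10)
  expect_equal(folded$counts[1, 1], 2)
  expect_equal(folded$counts[2, 1], 1)
  expect_equal(folded$counts[3, 2], 1)
  expect_equal(sum(folded$counts), 4)
  expect_error(joint_2dsfs(freq_table(0.5, pos = 1L),
                           freq_table(0.5, pos = 2L)), "shared")
})

test_that("hypergeometric projection conserves mass and matches the sum oracle", {
  set.seed(7)
  counts <- matrix(rpois(25, 4), 5, 5)
  sfs <- gfchrono:::new_joint_sfs(counts, 4, 4, folded = FALSE)
  expect_equal(project_sfs(sfs, 4, 4)$counts, counts)
  proj <- project_sfs(sfs, 3, 3)
  expect_equal(sum(proj$counts), sum(counts), tolerance = 1e-9)
  # explicit double-hypergeometric oracle
  oracle <- matrix(0, 4, 4)
  for (a in 0:3) for (b in 0:3) {
    s <- 0
    for (i in 0:4) for (j in 0:4) {
      s <- s + counts[i + 1, j + 1] *
        dhyper(a, i, 4 - i, 3) * dhyper(b, j, 4 - j, 3)
    }
    oracle[a + 1, b + 1] <- s
  }
  expect_equal(proj$counts, oracle, tolerance = 1e-12)
  # a site fixed in both pools stays fixed
  fixed <- gfchrono:::new_joint_sfs(
    matrix(c(rep(0, 24), 1), 5, 5), 4, 4, folded = FALSE)
  pf <- project_sfs(fixed, 2, 2)
  expect_equal(pf$counts[3, 3], 1, tolerance = 1e-12)
  expect_error(project_sfs(sfs, 1, 3), "at least 2")
  # projection commutes with folding on a symmetric spectrum, up to the
  # orientation of the exact-50% tie diagonal (ties are kept as-is, so the
  # two orders distribute tie-cell mass differently but identically in sum)
  sym <- counts + counts[5:1, 5:1]
  sfs_sym <- gfchrono:::new_joint_sfs(sym, 4, 4, folded = FALSE)
  p_then_f <- gfchrono:::fold_joint_counts(project_sfs(sfs_sym, 3, 3)$counts)
  f_then_p <- project_sfs(gfchrono:::new_joint_sfs(
    gfchrono:::fold_joint_counts(sym), 4, 4, folded = TRUE), 3, 3)$counts
  ties <- outer(0:3, 0:3, `+`) == 3
  expect_equal(p_then_f[!ties], f_then_p[!ties], tolerance = 1e-9)
  expect_equal(sum(p_then_f[ties]), sum(f_then_p[ties]), tolerance = 1e-9)
  expect_equal(sum(f_then_p), sum(sym), tolerance = 1e-9)
})

test_that("isolation-by-distance regression on a constructed linear system", {
  coords <- tibble::tibble(id = c("a", "b", "c", "d"),
                           lat = c(0, 0, 0, 0.5),
                           lon = c(0, 1, 2, 0.5))
  d <- population_distances(coords)
  # 1 degree along the equator at mean Earth radius 6371.0088 km
  expect_equal(d$distance_km[d$pop_a == "a" & d$pop_b == "b"],
               6371.0088 * pi / 180, tolerance = 1e-6)
  # construct Fst exactly linear in distance: fst = 1e-4 * km + 0.01
  m <- matrix(0, 4, 4, dimnames = list(coords$id, coords$id))
  for (k in seq_len(nrow(d))) {
    v <- 1e-4 * d$distance_km[k] + 0.01
    m[d$pop_a[k], d$pop_b[k]] <- m[d$pop_b[k], d$pop_a[k]] <- v
  }
  fst <- named_dist(m, coords$id)
  # an exact linear relationship provokes lm's perfect-fit warning
  fit <- suppressWarnings(ibd_regression(fst, coords))
  g <- suppressWarnings(glance(fit))
  expect_equal(g$slope, 1e-4, tolerance = 1e-8)
  expect_equal(g$intercept, 0.01, tolerance = 1e-8)
  expect_equal(g$r_squared, 1, tolerance = 1e-9)
  expect_equal(g$df, 1L)
  expect_equal(g$df_residual, nrow(d) - 2L)
  # constant Fst: zero slope
  const <- named_dist(matrix(0.05, 4, 4) - diag(0.05, 4), coords$id)
  expect_equal(suppressWarnings(glance(ibd_regression(const, coords))$slope),
               0, tolerance = 1e-12)
  expect_error(ibd_regression(fst, coords[1:2, ]), "three")
  same <- tibble::tibble(id = c("a", "b", "c"), lat = 0, lon = 0)
  expect_error(
    ibd_regression(named_dist(matrix(0.1, 3, 3) - diag(0.1, 3), same$id),
                   same), "degenerate|equal")
})

test_that("UPGMA trees are ultrametric with average-linkage heights", {
  two <- upgma_tree(named_dist(matrix(c(0, 6, 6, 0), 2), c("A", "B")))
  expect_equal(sort(two$edge.length), c(3, 3))
  tri <- upgma_tree(named_dist(
    matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3), c("A", "B", "C")))
  # ((A,B),C): A and B join at height 1, root at height 4
  depths <- ape::node.depth.edgelength(tri)
  tips <- depths[seq_len(3)]
  expect_equal(tips, rep(4, 3))  # ultrametric at root height 4
  ab_mrca <- ape::getMRCA(tri, c("A", "B"))
  expect_equal(max(depths) - depths[ab_mrca], 1)
  expect_true(grepl("^\\(", ape::write.tree(tri)))
  # random matrices stay ultrametric
  set.seed(11)
  for (r in 1:5) {
    k <- 5
    d <- matrix(0, k, k)
    d[upper.tri(d)] <- runif(k * (k - 1) / 2, 0.01, 1)
    d <- d + t(d)
    tr <- upgma_tree(named_dist(d, letters[1:5]))
    dep <- ape::node.depth.edgelength(tr)[seq_len(k)]
    expect_lt(diff(range(dep)), 1e-9)
  }
  expect_error(upgma_tree(named_dist(matrix(c(0, NA, NA, 0), 2),
                                     c("A", "B"))), "missing")
})
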