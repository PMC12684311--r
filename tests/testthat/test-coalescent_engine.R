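# Single constant-size population: closed-form coalescent expectations
# (E[TMRCA] for k = 2 is 2N, E[total length] is 4N sum 1/i, E[xi_i]
# proportional to 1/i) serve as the independent oracle for the simulator.

single_pop <- function(n) im_model(n, n, n, t_split = 0)

test_that("branch-length bookkeeping is exact and seeded streams reproduce", {
  m <- im_model(2000, 1000, 5000, t_split = 8000, x_break = 3000,
                m_recent = 1e-4, m_old = 2e-5)
  g <- sample_genealogy(m, 5, 4, n_reps = 200, seed = 42)
  expect_equal(sum(g$mean_tally), g$mean_total_length, tolerance = 1e-9)
  g2 <- sample_genealogy(m, 5, 4, n_reps = 200, seed = 42)
  expect_identical(g$mean_tally, g2$mean_tally)
  g3 <- sample_genealogy(m, 5, 4, n_reps = 200, seed = 43)
  expect_false(identical(g$mean_tally, g3$mean_tally))
  # bookkeeping also exact with the analytic ancestral tail
  ga <- sample_genealogy(m, 5, 4, n_reps = 200, seed = 42,
                         analytic_ancestral = TRUE)
  expect_equal(sum(ga$mean_tally), ga$mean_total_length, tolerance = 1e-9)
})

test_that("pair coalescence times match 2N within Monte Carlo error", {
  n <- 1000
  g <- sample_genealogy(single_pop(n), 2, 0, n_reps = 5000, seed = 7)
  se_t <- sqrt(g$var_tmrca / g$n_reps)
  expect_lt(abs(g$mean_tmrca - 2 * n), 3 * se_t)
  se_l <- sqrt(g$var_total_length / g$n_reps)
  expect_lt(abs(g$mean_total_length - 4 * n), 3 * se_l)
})

test_that("single-deme marginal SFS follows theta over i for k up to 6", {
  n <- 1000
  mu <- 1e-8
  L <- 1e6
  theta <- 4 * n * mu * L
  for (k in c(4, 6)) {
    g <- sample_genealogy(single_pop(n), k, 0, n_reps = 5000, seed = 11 + k)
    xi <- mu * L * g$mean_tally[2:k, 1]
    se <- mu * L * sqrt(g$var_tally[2:k, 1] / g$n_reps)
    expect_true(all(abs(xi - theta / (1:(k - 1))) < 3 * se))
  }
  # expected pairwise diversity: E[pi] = 4 N mu per site
  g2 <- sample_genealogy(single_pop(n), 2, 0, n_reps = 5000, seed = 3)
  pi_hat <- mu * g2$mean_tally[2, 1]
  se2 <- mu * sqrt(g2$var_tally[2, 1] / g2$n_reps)
  expect_lt(abs(pi_hat - 4 * n * mu), 3 * se2)
})

test_that("the analytic ancestral tail agrees with pure simulation", {
  m <- im_model(11250, 11250, 202500, t_split = 45000, x_break = 45000,
                m_recent = 6e-5, m_old = 6e-5)
  sim <- sample_genealogy(m, 4, 4, n_reps = 8000, seed = 5)
  ana <- sample_genealogy(m, 4, 4, n_reps = 4000, seed = 11,
                          analytic_ancestral = TRUE)
  se <- sqrt(sim$var_tally / sim$n_reps + ana$var_tally / ana$n_reps)
  z <- abs(sim$mean_tally - ana$mean_tally) / pmax(se, 1e-9)
  expect_lt(max(z[is.finite(z)]), 4.5)
})

test_that("without migration, shared polymorphism arises only from the ancestor", {
  # shrink the ancestral population so its branches are negligible: interior
  # cells (variants present in both samples but fixed in neither) then carry
  # essentially no mass
  m <- im_model(5000, 5000, 1, t_split = 50000, x_break = 50000,
                m_recent = 0, m_old = 0)
  g <- sample_genealogy(m, 4, 4, n_reps = 2000, seed = 9)
  interior <- g$mean_tally[2:4, 2:4]
  expect_lt(sum(interior), 1e-4 * sum(g$mean_tally))
})

test_that("recent migration monotonically builds shared polymorphism", {
  shared_mass <- vapply(c(0, 2e-5, 2e-4), function(m) {
    mod <- im_model(5000, 5000, 5000, t_split = 30000, x_break = 30000,
                    m_recent = m, m_old = m)
    s <- expected_joint_sfs(mod, 4, 4, seq_len = 1e6, mu = 1e-8,
                            n_reps = 4000, seed = 13)
    sum(s$counts[2:4, 2:4])
  }, 1)
  expect_true(all(diff(shared_mass) > 0))
})

test_that("expected spectra are linear in sequence length", {
  mod <- single_pop(2000)
  s1 <- expected_joint_sfs(mod, 4, 0, seq_len = 1e6, mu = 1e-8,
                           n_reps = 50, seed = 2)
  s2 <- expected_joint_sfs(mod, 4, 0, seq_len = 2e6, mu = 1e-8,
                           n_reps = 50, seed = 2)
  expect_equal(s2$counts, 2 * s1$counts, tolerance = 1e-12)
})

test_that("validation scenarios carry the printed parameterisation", {
  for (id in 1:5) {
    sc <- make_scenario(id)
    expect_equal(sc$model$n_ancestral, 202500)
    expect_equal(sc$model$t_split, 45000)
    expect_equal(sc$n_chromosomes_genome, 6L)
    expect_equal(sc$chrom_len, 15e6)
    expect_equal(sc$recombination_rate, 1e-8)
    expect_equal(sc$mutation_rate, 1e-8)
  }
  expect_error(make_scenario(6), "1, 2, 3, 4 or 5")
  s1 <- make_scenario(1)
  expect_equal(s1$model$m_recent, 0)
  expect_equal(s1$model$m_old, 0)
  expect_equal(s1$model$n1, 11250)
  expect_equal(make_scenario(2)$model$m_recent, 6e-5)
  # scenario 3: ~90% exponential decline from the split-time size
  s3 <- make_scenario(3)
  expect_equal(s3$model$n1 / 11250, exp(-5e-5 * 45000), tolerance = 1e-12)
  expect_equal(s3$annotations$printed_current_diploid, 1000)
  # scenario 4: ~10-fold exponential growth
  s4 <- make_scenario(4)
  expect_equal(s4$model$n1 / 11250, exp(5e-5 * 45000), tolerance = 1e-12)
  expect_equal(s4$annotations$printed_current_diploid, 500000)
  # scenario 5 migration steps, oldest to newest
  s5 <- make_scenario(5)
  expect_equal(migration_at(s5$model, c(13000, 10000, 7000, 4000, 1000, 400,
                                        100)),
               c(6e-5, 5e-5, 4e-5, 3e-5, 2e-5, 1e-5, 0))
  expect_equal(migration_at(s5$model, 46000), 0)  # beyond the split
  # scenarios export as key-value text
  path <- withr::local_tempfile(fileext = ".txt")
  write_scenario(s5, path)
  kv <- readLines(path)
  expect_true("scenario_id=5" %in% kv)
  expect_true(any(grepl("^migration_step_rate=0,1e-05,2e-05", kv)))
  expect_true("t_split_generations=45000" %in% kv)
})

test_that("observed spectra are Poisson draws around the expected spectrum", {
  mod <- im_model(3000, 3000, 10000, t_split = 10000, x_break = 10000,
                  m_recent = 1e-4, m_old = 1e-4)
  obs1 <- simulate_observed_sfs(mod, 4, 4, seed = 21, n_loci = 300,
                                locus_len = 1e5, mu = 1e-8)
  obs2 <- simulate_observed_sfs(mod, 4, 4, seed = 21, n_loci = 300,
                                locus_len = 1e5, mu = 1e-8)
  expect_identical(obs1$counts, obs2$counts)
  expect_true(all(obs1$counts == floor(obs1$counts)))
  expect_equal(obs1$seq_len, 3e7)
  # total count within a few relative percent of the expected total
  expe <- expected_joint_sfs(mod, 4, 4, seq_len = 3e7, mu = 1e-8,
                             n_reps = 4000, seed = 5, fold = TRUE)
  expect_lt(abs(sum(obs1$counts) - sum(expe$counts)) / sum(expe$counts), 0.1)
})
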