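test_that("yule simulation matches the branching-process expectation", {
  set.seed(61)
  b <- bd_params(t0 = 1.5, lambda = 1, mu = 0, psi = 0, r = 1, rho = 1)
  n <- replicate(2000, {
    tr <- simulate_bd_tree(b)
    if (is.null(tr)) 0 else tree_statistics(tr)$n_tips
  })
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(1.5)), 3 * se)
})

test_that("removal probability one forbids sampled ancestors", {
  set.seed(62)
  b <- bd_params(t0 = 2, lambda = 1.3, mu = 0.2, psi = 0.8, r = 1)
  sa <- replicate(300, {
    tr <- simulate_bd_tree(b, condition_min_samples = 1)
    tree_statistics(tr)$n_sampled_ancestors
  })
  expect_true(all(sa == 0))
})

test_that("sampled-ancestor yield decreases with the removal probability", {
  set.seed(63)
  means <- vapply(c(0, 0.5, 1), function(r) {
    b <- bd_params(t0 = 2, lambda = 1.3, mu = 0.2, psi = 0.8, r = r)
    mean(replicate(400, {
      tr <- simulate_bd_tree(b, condition_min_samples = 1)
      tree_statistics(tr)$n_sampled_ancestors
    }))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_gt(means[1], means[3])
})

test_that("unsampled processes return NULL and conditioning retries", {
  set.seed(64)
  ## rho = 0 and psi = 0 is rejected outright at construction
  expect_error(bd_params(t0 = 1, lambda = 1, psi = 0, rho = 0))
  b <- bd_params(t0 = 0.5, lambda = 0.5, mu = 2, psi = 0.3, r = 1)
  out <- replicate(200, is.null(simulate_bd_tree(b)))
  expect_gt(mean(out), 0.5)      # mostly unsampled at these rates
  tr <- simulate_bd_tree(b, condition_min_samples = 1)
  expect_s3_class(tr, "timetree")
  expect_gte(attr(tr, "tries"), 1L)
})

test_that("coalescent simulator matches closed-form expectations", {
  set.seed(65)
  t2 <- replicate(3000, tree_statistics(
    simulate_coalescent_tree(c(a = 0, b = 0), 2))$root_height)
  expect_lt(abs(mean(t2) - 2), 3 * stats::sd(t2) / sqrt(3000))
  t50 <- replicate(600, tree_statistics(
    simulate_coalescent_tree(rep(0, 50), 1))$root_height)
  expect_lt(abs(mean(t50) - 2 * (1 - 1 / 50)),
            3 * stats::sd(t50) / sqrt(600))
  ## simulated 2-tip root heights follow the analytic density
  expect_gt(stats::ks.test(t2, function(q) stats::pexp(q, 1 / 2))$p.value,
            0.01)
})

test_that("msc pair divergence exceeds speciation by 2 Ne generations", {
  set.seed(66)
  d <- simulate_msc_pair(tau = 100, Ne = 50, n = 20000)
  excess <- (d - 100) / 50
  expect_lt(abs(mean(excess) - 2), 3 * stats::sd(excess) / sqrt(length(d)))
  expect_equal(min(d) >= 100, TRUE)
  ## tau = 0 reduces to the plain pairwise coalescent
  d0 <- simulate_msc_pair(0, 50, 5000)
  expect_lt(abs(mean(d0) - 100), 3 * stats::sd(d0) / sqrt(5000))
  ## Ne -> 0: divergence collapses onto the speciation time
  expect_lt(max(simulate_msc_pair(7, 1e-9, 100)) - 7, 1e-6)
})

test_that("sequence simulation reproduces the jukes-cantor distance", {
  set.seed(67)
  tr <- timetree(c(3L, 3L, 0L), c(0, 0, 0.5), c("A", "B", NA))
  aln <- simulate_sequences(tr, site_model("111111"),
                            clock_model("strict", 1), 10000)
  pdiff <- mean(strsplit(aln$seqs[["A"]], "")[[1]] !=
                  strsplit(aln$seqs[["B"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 / 3))
  expect_lt(abs(pdiff - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
  ## zero rate: all sequences identical
  aln0 <- simulate_sequences(tr, site_model("111111"),
                             clock_model("strict", 0), 50)
  expect_equal(aln0$seqs[["A"]], aln0$seqs[["B"]])
})

test_that("the true parameters beat perturbed ones in average likelihood", {
  set.seed(68)
  site <- site_model("121121", group_rates = c(1, 4))
  clock <- clock_model("strict", 0.5)
  wins <- replicate(20, {
    tr <- random_serial_tree(6)
    aln <- simulate_sequences(tr, site, clock, 300)
    pat <- compress_patterns(aln)
    log_likelihood(pat, tr, site, clock) >
      log_likelihood(pat, tr, site, clock_model("strict", 1.5))
  })
  expect_gt(mean(wins), 0.7)
})

test_that("posterior-predictive p-values follow the counting rule", {
  set.seed(69)
  draws <- data.frame(t0 = rep(1.5, 60), lambda = 1.2)
  fixed <- list(mu = 0.2, psi = 0.6, r = 0.5)
  rep1 <- posterior_predictive_check(draws, fixed, observed = 1e9,
                                     statistic = "tree_length", n_sims = 50)
  expect_equal(rep1$p_value, 2 / 51)
  rep2 <- posterior_predictive_check(draws, fixed, observed = 1.0,
                                     statistic = "root_height", n_sims = 1)
  expect_equal(rep2$p_value, 1)
  ## an observation from the same model gives an unremarkable p-value
  obs <- simulate_bd_tree(do.call(bd_params, c(list(t0 = 1.5, lambda = 1.2),
                                               fixed)),
                          condition_min_samples = 1)
  rep3 <- posterior_predictive_check(draws, fixed, observed = obs,
                                     statistic = "root_height", n_sims = 60)
  expect_gte(rep3$p_value, 2 / 61)
  expect_lte(rep3$p_value, 1)
})

test_that("seeded simulations are bit-reproducible", {
  b <- bd_params(t0 = 2, lambda = 1.2, mu = 0.3, psi = 0.5, r = 0.4)
  set.seed(70); a1 <- simulate_bd_tree(b, condition_min_samples = 3)
  set.seed(70); a2 <- simulate_bd_tree(b, condition_min_samples = 3)
  expect_identical(a1, a2)
  set.seed(71); s1 <- simulate_sequences(a1, site_model("111111"),
                                         clock_model("strict", 1), 20)
  set.seed(71); s2 <- simulate_sequences(a1, site_model("111111"),
                                         clock_model("strict", 1), 20)
  expect_identical(s1, s2)
})
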