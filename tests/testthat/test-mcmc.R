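test_that("the kernel reproduces a known scalar distribution", {
  ## flat likelihood + Exponential(1) prior sampled with the scale operator
  st <- list(params = list(x = 1))
  res <- run_mcmc(st, function(s) stats::dexp(s$params$x, log = TRUE),
                  list(op_scale_param("x", 1, width = 1.5)),
                  chain_length = 40000, log_every = 20, seed = 101,
                  sample_trees = FALSE)
  xs <- res$trace$x[-(1:200)]
  expect_gt(stats::ks.test(xs[seq(1, length(xs), 5)], "pexp")$p.value, 0.01)
  expect_equal(mean(xs), 1, tolerance = 0.1)
})

test_that("chains are bit-reproducible given the seed", {
  st <- list(params = list(x = 1))
  lt <- function(s) stats::dexp(s$params$x, log = TRUE)
  ops <- list(op_scale_param("x", 1))
  a <- run_mcmc(st, lt, ops, 2000, log_every = 10, seed = 7, sample_trees = FALSE)
  b <- run_mcmc(st, lt, ops, 2000, log_every = 10, seed = 7, sample_trees = FALSE)
  expect_identical(a$trace, b$trace)
})

test_that("a non-finite starting posterior is refused with advice", {
  st <- list(params = list(x = -1))
  expect_error(run_mcmc(st, function(s) stats::dexp(s$params$x, log = TRUE),
                        list(op_scale_param("x", 1)), 100,
                        sample_trees = FALSE),
               "different starting state")
})

test_that("every sampled tree satisfies the structural invariants", {
  set.seed(31)
  b <- bd_params(t0 = 2, lambda = 1.3, mu = 0.2, psi = 0.8, r = 0.3)
  tr0 <- sim_bd_conditioned(b, 4, 1)[[1]]
  tr0$origin <- NA
  res <- mcmc_prior_trees(tr0, function(tr) bd_serial_log_density(tr, b),
                          chain_length = 8000, seed = 32, t0 = b$t0,
                          log_every = 40)
  for (tr in res$trees) expect_silent(validate_timetree(tr))
  ## acceptance bookkeeping covers every operator
  expect_true(all(res$acceptance$accepted + res$acceptance$rejected >= 0))
  expect_equal(sum(res$acceptance$accepted + res$acceptance$rejected), 8000)
})

test_that("wilson-balding explores labeled 3-taxon topologies uniformly", {
  tr0 <- parse_newick("((A:1,B:1):1,C:2);")
  b <- bd_params(t0 = 5, lambda = 1, mu = 0, psi = 0, r = 1, rho = 1)
  res <- mcmc_prior_trees(tr0, function(tr) bd_serial_log_density(tr, b),
                          chain_length = 60000, seed = 33, t0 = b$t0,
                          tips_sampled = FALSE, sa_moves = FALSE,
                          log_every = 20)
  cherries <- vapply(res$trees[-(1:500)], function(t) {
    nd <- which(lengths(t$children) == 2L & t$parent > 0L)
    paste(sort(t$taxon[t$children[[nd[1]]]]), collapse = "")
  }, character(1))
  counts <- table(factor(cherries, levels = c("AB", "AC", "BC")))
  expect_true(all(counts > 0))
  expect_gt(stats::chisq.test(counts[seq_along(counts)])$p.value, 0.001)
})

test_that("effective sample size behaves across dependence regimes", {
  set.seed(34)
  expect_gt(compute_ess(stats::rnorm(10000)), 8500)
  expect_lt(compute_ess(stats::rnorm(10000)), 11500)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), 20000))
  expect_equal(compute_ess(ar), 20000 / 3, tolerance = 0.15)
  expect_equal(compute_ess(rep(3.2, 100)), 0)
  expect_error(compute_ess(1:5), "at least 10")
})

test_that("hpd intervals are the shortest covering intervals", {
  set.seed(35)
  x <- stats::rnorm(20000)
  h <- hpd_interval(x, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.08)
  expect_equal(h[2], 1.96, tolerance = 0.08)
  ## skewed sample: HPD must beat the central interval in width
  y <- stats::rlnorm(20000)
  h2 <- hpd_interval(y, 0.9)
  ci <- stats::quantile(y, c(0.05, 0.95))
  expect_lt(diff(h2), diff(ci))
})

test_that("credible model sets follow the cumulative rule with tie-breaks", {
  codes <- c(rep("111111", 60), rep("121121", 30), rep("123456", 10))
  cs <- credible_model_set(codes, 0.95)
  expect_equal(cs$code, c("111111", "121121", "123456"))
  cs2 <- credible_model_set(codes, 0.9)
  expect_equal(cs2$code, c("111111", "121121"))
  expect_equal(credible_model_set(rep("121121", 5))$code, "121121")
  ## brute-force subset oracle on a synthetic frequency table
  set.seed(36)
  draw <- sample(c("111122", "111111", "121121", "121123", "123456"),
                 2000, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
  cs3 <- credible_model_set(draw, 0.95)
  tab <- sort(table(draw) / 2000, decreasing = TRUE)
  k <- min(which(cumsum(tab) >= 0.95))
  expect_equal(nrow(cs3), k)
})

test_that("clade supports and the mcc summary match hand counts", {
  t1 <- parse_newick("((A:1,B:1):1,C:2);")
  t2 <- parse_newick("((A:1,C:1):1,B:2);")
  sup <- clade_supports(list(t1, t1, t2))
  expect_equal(unname(sup["A,B"]), 2 / 3)
  expect_equal(unname(sup["A,C"]), 1 / 3)
  expect_equal(unname(sup["A,B,C"]), 1)
  mcc <- summarize_mcc(list(t1, t1, t2))
  expect_true(trees_isomorphic(mcc, t1))
  ann <- attr(mcc, "node_annotations")
  expect_true(all(c("support", "mean_height", "hpd_lower") %in% names(ann)))
  ## single repeated tree: all supports 1
  sup1 <- clade_supports(list(t1, t1))
  expect_true(all(sup1 == 1))
  expect_error(clade_supports(list()), "empty")
})
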