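jc_strict <- function() list(site = site_model("111111"),
                             clock = clock_model("strict", 1))

test_that("two-taxon limiting cases match hand calculations", {
  m <- jc_strict()
  tr0 <- timetree(c(3L, 3L, 0L), c(0, 0, 0), c("A", "B", NA))
  aln <- phylomc:::make_alignment(c(A = "A", B = "A"))
  expect_equal(log_likelihood(compress_patterns(aln), tr0, m$site, m$clock),
               log(0.25), tolerance = 1e-12)
  ## infinite distance: states independent, P -> 1/16
  trX <- timetree(c(3L, 3L, 0L), c(0, 0, 500), c("A", "B", NA))
  alnX <- phylomc:::make_alignment(c(A = "A", B = "C"))
  expect_equal(log_likelihood(compress_patterns(alnX), trX, m$site, m$clock),
               log(1 / 16), tolerance = 1e-8)
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  set.seed(11)
  for (rep in 1:6) {
    ntips <- sample(3:5, 1)
    tr <- random_serial_tree(ntips)
    aln <- random_alignment(paste0("t", seq_len(ntips)), 8)
    site <- site_model(sample(c("111111", "121121", "123456"), 1),
                       group_rates = NULL,
                       base_freqs = stats::rexp(4) + 0.2,
                       use_gamma = rep %% 2 == 0, gamma_shape = 0.7,
                       n_categories = 3,
                       use_inv = rep %% 3 == 0, p_inv = 0.25)
    k <- max(phylomc:::code_groups(site$code))
    site$group_rates <- stats::rexp(k) + 0.2
    clock <- clock_model("strict", stats::runif(1, 0.3, 1.5))
    f <- log_likelihood(compress_patterns(aln), tr, site, clock)
    expect_equal(f, enum_loglik(aln, tr, site, clock), tolerance = 1e-9)
  }
})

test_that("fast invariable-sites path agrees with the naive mixture", {
  set.seed(12)
  for (rep in 1:5) {
    tr <- random_serial_tree(6)
    aln <- random_alignment(paste0("t", 1:6), 60)
    site <- site_model("121121", group_rates = c(1, 3),
                       use_gamma = TRUE, gamma_shape = 0.5, n_categories = 4,
                       use_inv = TRUE, p_inv = 0.3)
    clock <- clock_model("strict", 0.6)
    expect_equal(log_likelihood(compress_patterns(aln), tr, site, clock),
                 log_likelihood_naive(aln, tr, site, clock),
                 tolerance = 1e-10)
  }
  ## p_inv = 0: the invariable class contributes exactly nothing
  site0 <- site_model("121121", group_rates = c(1, 3))
  site1 <- site_model("121121", group_rates = c(1, 3), use_inv = TRUE,
                      p_inv = 0)
  tr <- random_serial_tree(4)
  aln <- random_alignment(paste0("t", 1:4), 30)
  expect_identical(log_likelihood(compress_patterns(aln), tr, site0,
                                  clock_model("strict", 1)),
                   log_likelihood(compress_patterns(aln), tr, site1,
                                  clock_model("strict", 1)))
})

test_that("all-constant data at zero distance collapse to base frequencies", {
  site <- site_model("111111", base_freqs = c(0.4, 0.3, 0.2, 0.1),
                     use_inv = TRUE, p_inv = 0.3)
  tr <- timetree(c(3L, 3L, 0L), c(0, 0, 0), c("A", "B", NA))
  aln <- phylomc:::make_alignment(c(A = "ACG", B = "ACG"))
  expect_equal(log_likelihood(compress_patterns(aln), tr, site,
                              clock_model("strict", 1)),
               log(0.4) + log(0.3) + log(0.2), tolerance = 1e-12)
})

test_that("sampled-ancestor nodes act as internal state constraints", {
  tr <- parse_newick("((A:1,B:0):1,C:2);", "sampled_ancestor")
  aln <- phylomc:::make_alignment(c(A = "ACGT", B = "ACGA", C = "GCGT"))
  site <- site_model("121121", group_rates = c(1, 2.5),
                     base_freqs = c(0.3, 0.2, 0.25, 0.25))
  clock <- clock_model("strict", 0.8)
  f <- log_likelihood(compress_patterns(aln), tr, site, clock)
  expect_equal(f, enum_loglik(aln, tr, site, clock), tolerance = 1e-10)
})

test_that("likelihood is invariant to root placement along a branch (pulley)", {
  ## same unrooted substitution-length tree, three root positions
  ## unrooted star: A-center = a, B-center = b, center-C = clen; the root
  ## slides along the center-C edge at distance d from the center
  a <- 0.2; b <- 0.3; clen <- 2.1
  set.seed(13)
  aln <- random_alignment(c("A", "B", "C"), 40)
  m <- site_model("121121", group_rates = c(1, 4),
                  base_freqs = c(0.35, 0.15, 0.3, 0.2))
  ck <- clock_model("strict", 1)
  vals <- vapply(c(0.2, 0.5, 0.9), function(d) {
    hcen <- clen - 2 * d; hroot <- clen - d
    tr <- timetree(c(4L, 4L, 5L, 5L, 0L),
                   c(hcen - a, hcen - b, 0, hcen, hroot),
                   c("A", "B", "C", NA, NA))
    log_likelihood(compress_patterns(aln), tr, m, ck)
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-10)
})

test_that("branch rates follow the clock contracts", {
  tr <- random_serial_tree(5)
  strict <- branch_rates(clock_model("strict", 0.01), tr)
  expect_true(all(strict[-tr$root] == 0.01))
  ## degenerate relaxed clock equals the strict clock
  r0 <- branch_rates(clock_model("relaxed_lognormal", 0.02, sigma = 0), tr)
  expect_true(all(r0[-tr$root] == 0.02))
  ## discretized quantile set has mean 1 before scaling
  q <- phylomc:::relaxed_quantile_rates(1, 100)
  expect_equal(mean(q), 1, tolerance = 1e-12)
  expect_error(clock_model("strict", sigma = -1), "sigma")
})

test_that("missing taxa are reported", {
  tr <- random_serial_tree(3)
  aln <- random_alignment(c("t1", "t2", "zz"), 5)
  m <- jc_strict()
  expect_error(log_likelihood(compress_patterns(aln), tr, m$site, m$clock),
               "zz")
})
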