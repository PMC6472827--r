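test_that("epidemiological reparameterization follows the printed identities", {
  e <- epi_params(Re = 2, delta = 1, p = 0.5, r = 0)
  b <- epi_to_canonical(e)
  expect_equal(b[c("lambda", "psi", "mu")], list(lambda = 2, psi = 0.5, mu = 1))
  e2 <- epi_params(Re = 2, delta = 1, p = 0.5, r = 1)
  b2 <- epi_to_canonical(e2)
  expect_equal(b2$mu, 0.5)
  back <- canonical_to_epi(c(b2, list(t0 = 1)))
  expect_equal(back[c("Re", "delta", "p", "r")],
               list(Re = 2, delta = 1, p = 0.5, r = 1))
  ## FBD-like boundary and the infeasible corner
  expect_equal(epi_to_canonical(epi_params(1, 1, p = 1, r = 1))$mu, 0)
  expect_error(epi_to_canonical(list(Re = 1, delta = 1, p = 0.9, r = 1.2)),
               "negative death rate")
  expect_error(canonical_to_epi(list(lambda = 1, mu = 0, psi = 0.5, r = 0)),
               "delta")
  ## psi = 0 collapses to p = 0, delta = mu
  e3 <- canonical_to_epi(list(lambda = 2, mu = 1, psi = 0, r = 0.4))
  expect_equal(e3$p, 0); expect_equal(e3$delta, 1); expect_equal(e3$Re, 2)
})

test_that("random epi/canonical round trips are exact", {
  set.seed(21)
  for (i in 1:200) {
    e <- epi_params(Re = stats::rlnorm(1), delta = stats::rlnorm(1),
                    p = stats::runif(1), r = stats::runif(1))
    b <- epi_to_canonical(e)
    back <- canonical_to_epi(b)
    expect_equal(unlist(back[c("Re", "delta", "p", "r")]),
                 unlist(e[c("Re", "delta", "p", "r")]), tolerance = 1e-12)
  }
})

test_that("coalescent density matches closed forms", {
  two <- function(h) timetree(c(3L, 3L, 0L), c(0, 0, h), c("A", "B", NA))
  for (Ne in c(0.5, 2)) for (h in c(0.3, 1.7))
    expect_equal(coalescent_log_density(two(h), coalescent_params(Ne)),
                 -h / Ne - log(Ne), tolerance = 1e-12)
  ## 3 contemporaneous tips, coalescences at h1 < h2
  h1 <- 0.4; h2 <- 1.1; Ne <- 0.8
  tr3 <- timetree(c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, h1, h2),
                  c("A", "B", "C", NA, NA))
  hand <- -3 * h1 / Ne - log(Ne) - (h2 - h1) / Ne - log(Ne)
  expect_equal(coalescent_log_density(tr3, coalescent_params(Ne)), hand,
               tolerance = 1e-12)
  ## scaling heights and Ne by c shifts log density by -(n-1) log c
  cs <- 2.5
  tr3s <- timetree(c(4L, 4L, 5L, 5L, 0L), cs * c(0, 0, 0, h1, h2),
                   c("A", "B", "C", NA, NA))
  expect_equal(coalescent_log_density(tr3s, coalescent_params(cs * Ne)),
               hand - 2 * log(cs), tolerance = 1e-12)
  ## sampled ancestors are outside the model
  sa <- parse_newick("((A:1,B:0):1,C:2);", "sampled_ancestor")
  expect_error(coalescent_log_density(sa, coalescent_params(1)),
               "sampled ancestors")
})

test_that("coalescent 2-tip density integrates to one over root height", {
  f <- function(h) vapply(h, function(hh)
    exp(coalescent_log_density(
      timetree(c(3L, 3L, 0L), c(0, 0.2, hh), c("A", "B", NA)),
      coalescent_params(0.7))), numeric(1))
  expect_equal(stats::integrate(f, 0.2, Inf, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-4)
})

test_that("with psi = 0 the birth-death density does not depend on r", {
  set.seed(22)
  for (i in 1:50) {
    b0 <- bd_params(t0 = 3, lambda = 1.2, mu = 0.4, psi = 0, r = 0, rho = 1)
    tr <- simulate_bd_tree(b0, condition_min_samples = 2)
    vals <- vapply(c(0, 0.3, 1), function(r)
      bd_serial_log_density(tr, bd_params(3, 1.2, 0.4, 0, r, 1)), numeric(1))
    expect_lt(max(vals) - min(vals), 1e-12)
  }
})

test_that("single-interval skyline equals the constant-rate closed form", {
  set.seed(23)
  b <- bd_params(t0 = 2.5, lambda = 1.3, mu = 0.3, psi = 0.6, r = 0.4,
                 rho = 0.3)
  s <- skyline_params(2.5, numeric(0), 1.3, 0.3, 0.6, 0.4, 0.3)
  for (i in 1:60) {
    tr <- simulate_bd_tree(b, condition_min_samples = 2)
    expect_equal(bdsky_log_density(tr, s), bd_serial_log_density(tr, b),
                 tolerance = 1e-10)
  }
})

test_that("merging identical skyline intervals leaves the density unchanged", {
  set.seed(24)
  b <- bd_params(t0 = 2, lambda = 1.4, mu = 0.2, psi = 0.7, r = 0.2)
  one <- skyline_params(2, numeric(0), 1.4, 0.2, 0.7, 0.2)
  two <- skyline_params(2, 0.8, c(1.4, 1.4), c(0.2, 0.2), c(0.7, 0.7), 0.2)
  three <- skyline_params(2, c(0.5, 1.3), 1.4, 0.2, 0.7, 0.2)
  for (i in 1:40) {
    tr <- simulate_bd_tree(b, condition_min_samples = 2)
    expect_equal(bdsky_log_density(tr, two), bdsky_log_density(tr, one),
                 tolerance = 1e-10)
    expect_equal(bdsky_log_density(tr, three), bdsky_log_density(tr, one),
                 tolerance = 1e-10)
  }
})

test_that("skyline probability functions match numerical ODE integration", {
  ## independent oracle: integrate dp/dt = mu - (l+m+s) p + l p^2 and
  ## d(log q)/dt = -(l+m+s) + 2 l p across a generic 3-interval skyline
  s <- skyline_params(t0 = 3, change_times = c(0.7, 1.8),
                      lambda = c(2, 1.1, 0.8), mu = c(0.5, 0.3, 0.9),
                      psi = c(0.4, 0.9, 0.2), r = 0.3, rho = 0.4)
  pq <- phylomc:::skyline_pq(s)
  bounds <- c(0, s$change_times, s$t0)
  rate_at <- function(t) {
    i <- min(max(findInterval(t, bounds, left.open = TRUE), 1), s$k)
    c(s$lambda[i], s$mu[i], s$psi[i])
  }
  deriv <- function(t, y, parms) {
    rt <- rate_at(t)
    list(c(rt[2] - sum(rt) * y[1] + rt[1] * y[1]^2,
           -sum(rt) + 2 * rt[1] * y[1]))
  }
  ts <- seq(0, 3, length.out = 61)
  sol <- deSolve::lsoda(c(p = 1 - s$rho, logq = 0), ts, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(pq$p(ts) - sol[, "p"])), 1e-7)
  expect_lt(max(abs(pq$logq(ts) - sol[, "logq"])), 1e-6)
})

test_that("yule conditional root-height density matches the analytic form", {
  ## for 2 extant rho=1 tips the conditional density of the root height is
  ## lambda exp(-lambda x) / (1 - exp(-lambda t0))
  b <- bd_params(t0 = 1.5, lambda = 0.9, mu = 0, psi = 0, r = 1, rho = 1)
  grid <- seq(0.002, 1.498, length.out = 400)
  lf <- vapply(grid, function(x)
    bd_serial_log_density(timetree(c(3L, 3L, 0L), c(0, 0, x),
                                   c("t1", "t2", NA)), b), numeric(1))
  dens <- exp(lf)
  dx <- grid[2] - grid[1]
  Z <- sum((dens[-1] + dens[-length(dens)]) / 2) * dx   # trapezoid norm
  dens <- dens / Z
  ana <- b$lambda * exp(-b$lambda * grid) / (1 - exp(-b$lambda * b$t0))
  expect_lt(max(abs(dens - ana)), 1e-2)
})

test_that("degenerate and invalid inputs are handled", {
  sa <- parse_newick("((A:1,B:0):1,C:2);", "sampled_ancestor")
  b1 <- bd_params(t0 = 3, lambda = 1, mu = 0.1, psi = 0.5, r = 1)
  expect_identical(bd_serial_log_density(sa, b1), -Inf)   # SA with r = 1
  b2 <- bd_params(t0 = 3, lambda = 1, mu = 0.1, psi = 0.5, r = 0)
  expect_true(is.finite(bd_serial_log_density(sa, b2)))
  expect_error(bd_params(t0 = 2, lambda = 1, psi = 0, rho = 0), "psi, rho")
  expect_error(skyline_params(2, 2.5, lambda = c(1, 1), psi = 0.5),
               "strictly between")
  b3 <- bd_params(t0 = 0.5, lambda = 1, psi = 0.5)
  expect_identical(bd_serial_log_density(sa, b3), -Inf)   # root above origin
  ## critical case lambda = mu, psi = 0 stays finite
  bc <- bd_params(t0 = 2, lambda = 1, mu = 1, psi = 0, r = 1, rho = 0.8)
  tr <- timetree(c(3L, 3L, 0L), c(0, 0, 1), c("A", "B", NA))
  expect_true(is.finite(bd_serial_log_density(tr, bc)))
})
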