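#' Tree prior parameterizations
#'
#' The birth-death sampling process starts from a single lineage at the
#' origin height `t0`.  Each lineage bifurcates at rate `lambda`, dies at
#' rate `mu`, and is sampled serially at rate `psi`; on sampling the lineage
#' is removed with probability `r` (so `r < 1` admits sampled ancestors).
#' Extant lineages at height 0 are sampled with probability `rho`.  The
#' epidemiological reparameterization uses the effective reproductive number
#' `Re = lambda/delta`, the becoming-noninfectious rate `delta = mu + psi*r`,
#' and the sampling proportion `p = psi/delta`.  Setting `r = 0` gives the
#' fossilized birth-death process.
#'
#' @param t0 origin height (> root height of any tree scored)
#' @param lambda birth rate > 0
#' @param mu death rate >= 0
#' @param psi serial sampling rate >= 0
#' @param r removal-on-sampling probability in [0, 1]
#' @param rho present-day sampling probability in [0, 1]
#' @return object of class `bd_params`
#' @export
bd_params <- function(t0, lambda, mu = 0, psi = 0, r = 1, rho = 0) {
  stopifnot(t0 > 0, lambda > 0, mu >= 0, psi >= 0, r >= 0, r <= 1,
            rho >= 0, rho <= 1)
  if (psi == 0 && rho == 0) stop("at least one of psi, rho must be positive")
  structure(list(t0 = t0, lambda = lambda, mu = mu, psi = psi, r = r,
                 rho = rho), class = "bd_params")
}

#' @rdname bd_params
#' @param Re effective reproductive number > 0
#' @param delta becoming-noninfectious rate > 0
#' @param p sampling proportion in [0, 1]
#' @export
epi_params <- function(Re, delta, p, r = 1) {
  stopifnot(Re > 0, delta > 0, p >= 0, p <= 1, r >= 0, r <= 1)
  structure(list(Re = Re, delta = delta, p = p, r = r), class = "epi_params")
}

#' Convert epidemiological to canonical birth-death parameters
#'
#' Applies `psi = p * delta`, `lambda = Re * delta`, `mu = delta - psi * r`.
#'
#' @param e an `epi_params`
#' @return list with `lambda`, `mu`, `psi`, `r`
#' @export
epi_to_canonical <- function(e) {
  psi <- e$p * e$delta
  mu <- e$delta - psi * e$r
  if (mu < 0) stop("p * r > 1 implies a negative death rate")
  list(lambda = e$Re * e$delta, mu = mu, psi = psi, r = e$r)
}

#' Convert canonical to epidemiological parameters
#'
#' Exact inverse of [epi_to_canonical()]: `delta = mu + psi*r`,
#' `Re = lambda/delta`, `p = psi/delta`.
#'
#' @param b a `bd_params` (or list with lambda, mu, psi, r)
#' @return an `epi_params`
#' @export
canonical_to_epi <- function(b) {
  delta <- b$mu + b$psi * b$r
  if (delta <= 0) stop("delta = mu + psi*r must be positive")
  epi_params(Re = b$lambda / delta, delta = delta, p = b$psi / delta, r = b$r)
}

#' Piecewise-constant (skyline) birth-death parameters
#'
#' Time is partitioned into intervals by `change_times` (increasing heights
#' strictly inside `(0, t0)`); interval 1 touches the present.  Rates are
#' constant within an interval; `r` and `rho` are shared across intervals.
#'
#' @param t0 origin height
#' @param change_times increasing heights in (0, t0); may be empty
#' @param lambda,mu,psi per-interval rate vectors (length = K intervals);
#'   scalars are recycled
#' @param r,rho shared removal and present-day sampling probabilities
#' @return object of class `skyline_params`
#' @export
skyline_params <- function(t0, change_times = numeric(0), lambda, mu = 0,
                           psi = 0, r = 1, rho = 0) {
  k <- length(change_times) + 1L
  if (any(diff(change_times) <= 0)) stop("change_times must be increasing")
  if (length(change_times) && (min(change_times) <= 0 || max(change_times) >= t0))
    stop("change times must lie strictly between 0 and the origin t0")
  lambda <- rep_len(lambda, k); mu <- rep_len(mu, k); psi <- rep_len(psi, k)
  stopifnot(all(lambda > 0), all(mu >= 0), all(psi >= 0),
            r >= 0, r <= 1, rho >= 0, rho <= 1)
  if (all(psi == 0) && rho == 0) stop("at least one of psi, rho must be positive")
  structure(list(t0 = t0, change_times = as.numeric(change_times),
                 lambda = lambda, mu = mu, psi = psi, r = r, rho = rho,
                 k = k), class = "skyline_params")
}

#' Constant-size coalescent parameters
#'
#' @param Ne effective population size in tree time units (pairwise
#'   coalescence rate `1/Ne`)
#' @return object of class `coalescent_params`
#' @export
coalescent_params <- function(Ne) {
  stopifnot(is.finite(Ne), Ne > 0)
  structure(list(Ne = Ne), class = "coalescent_params")
}

## ---- coalescent density ---------------------------------------------------

#' Serial coalescent log-density of a time tree
#'
#' Standard heterochronous coalescent: with `k` lineages extant in an
#' inter-event interval of length `dt`, the waiting contribution is
#' `exp(-k(k-1)/2 * dt/Ne)`, and each coalescence multiplies by `1/Ne`.
#' Sampled-ancestor nodes are outside the model's support.
#'
#' @param tree a binary `timetree`
#' @param c a `coalescent_params`
#' @return log-density
#' @export
coalescent_log_density <- function(tree, c) {
  deg <- lengths(tree$children)
  if (any(deg == 1L)) stop("coalescent prior does not allow sampled ancestors")
  ev <- data.frame(h = tree$height, type = ifelse(deg == 2L, 1L, -1L))
  ev <- ev[order(ev$h, ev$type), ]   # at ties, process samples first
  ## sweep from present: samples add a lineage, coalescences remove one
  k <- 0L
  h <- 0
  logf <- 0
  for (i in seq_len(nrow(ev))) {
    dt <- ev$h[i] - h
    logf <- logf - k * (k - 1) / 2 * dt / c$Ne
    if (ev$type[i] < 0) k <- k + 1L else { logf <- logf - log(c$Ne); k <- k - 1L }
    h <- ev$h[i]
  }
  logf
}

## ---- birth-death with serial sampling and sampled ancestors ---------------

## classify tree events; a tip is a rho-sample iff rho > 0 and its height is
## numerically zero relative to the tree scale
bd_tree_events <- function(tree, rho) {
  deg <- lengths(tree$children)
  eps <- 1e-9 * max(tree$height, 1)
  tips <- which(deg == 0L)
  is_rho <- rho > 0 & tree$height[tips] <= eps
  list(x = tree$height[deg == 2L],                       # bifurcations
       y = tree$height[tips[!is_rho]],                   # psi-sampled tips
       z = tree$height[deg == 1L & !is.na(tree$taxon)],  # sampled ancestors
       n_rho = sum(is_rho))
}

## p and log-q machinery for one constant-rate interval.
## p(t): probability a lineage at height t leaves no sample;
## q(t): per-lineage density factor, normalized to 1 at the interval start.
## Both solve  p' = mu - (lambda+mu+psi) p + lambda p^2  and
## (log q)' = -(lambda+mu+psi) + 2 lambda p, in height t.
interval_pq <- function(lambda, mu, psi, p_init) {
  if (psi == 0 && abs(lambda - mu) < 1e-12 * max(lambda, 1)) {
    ## critical case A = 0: p = 1 - 1/(1/(1-p0) + lambda*dt)
    list(p = function(dt) {
      g <- 1 / (1 - p_init) + lambda * dt
      1 - 1 / g
    },
    logq = function(dt) -2 * log1p((1 - p_init) * lambda * dt))
  } else {
    A <- sqrt((lambda - mu - psi)^2 + 4 * lambda * psi)
    B <- ((1 - 2 * p_init) * lambda + mu + psi) / A
    list(p = function(dt) {
      e <- exp(-A * dt)
      (lambda + mu + psi -
         A * ((1 + B) - (1 - B) * e) / ((1 + B) + (1 - B) * e)) / (2 * lambda)
    },
    logq = function(dt) {
      e <- exp(-A * dt)
      log(4) - A * dt - 2 * log((1 + B) + (1 - B) * e)
    })
  }
}

## per-height p(t) and cumulative log q(t) across skyline intervals
skyline_pq <- function(s) {
  bounds <- c(0, s$change_times, s$t0)
  k <- s$k
  fns <- vector("list", k)
  p_at <- numeric(k + 1)   # p at interval starts
  logq_at <- numeric(k + 1)
  p_at[1] <- 1 - s$rho
  for (i in seq_len(k)) {
    fns[[i]] <- interval_pq(s$lambda[i], s$mu[i], s$psi[i], p_at[i])
    p_at[i + 1] <- fns[[i]]$p(bounds[i + 1] - bounds[i])
    logq_at[i + 1] <- logq_at[i] + fns[[i]]$logq(bounds[i + 1] - bounds[i])
  }
  idx <- function(t) pmin(pmax(findInterval(t, bounds, left.open = TRUE), 1L), k)
  list(
    p = function(t) {
      i <- idx(t)
      vapply(seq_along(t), function(j) fns[[i[j]]]$p(t[j] - bounds[i[j]]),
             numeric(1))
    },
    logq = function(t) {
      i <- idx(t)
      vapply(seq_along(t), function(j)
        logq_at[i[j]] + fns[[i[j]]]$logq(t[j] - bounds[i[j]]), numeric(1))
    },
    rate_at = function(t, what) s[[what]][idx(t)])
}

#' Birth-death skyline log-density of a sampled tree
#'
#' Piecewise-constant generalization of the serial-sampling birth-death
#' density with sampled ancestors: bifurcations at height `x` contribute
#' `2*lambda(x)*q(x)`, psi-sampled tips at `y` contribute
#' `psi(y) * (r + (1-r) p(y)) / q(y)`, sampled-ancestor nodes at `z`
#' contribute `psi(z) * (1-r)`, rho-sampled tips contribute `rho`, and the
#' origin stem contributes `q(t0)`.  The density is conditioned on the origin
#' and on observing at least one sample, and is normalized for labeled trees
#' (the factor 2 per bifurcation absorbs branch orientation, so trees of
#' different sampled-ancestor counts are weighted consistently).
#'
#' @param tree a `timetree` (origin not required on the tree; `s$t0` is used)
#' @param s a `skyline_params`
#' @return log-density (may be `-Inf`, e.g. a sampled ancestor with `r = 1`)
#' @export
bdsky_log_density <- function(tree, s) {
  if (tree$height[tree$root] >= s$t0) return(-Inf)
  pq <- skyline_pq(s)
  ev <- bd_tree_events(tree, s$rho)
  logf <- pq$logq(s$t0) - log1p(-pq$p(s$t0))
  if (length(ev$x))
    logf <- logf + sum(log(2 * pq$rate_at(ev$x, "lambda")) + pq$logq(ev$x))
  if (length(ev$y)) {
    psi_y <- pq$rate_at(ev$y, "psi")
    if (any(psi_y == 0)) return(-Inf)
    logf <- logf + sum(log(psi_y) + log(s$r + (1 - s$r) * pq$p(ev$y)) -
                         pq$logq(ev$y))
  }
  if (length(ev$z)) {
    psi_z <- pq$rate_at(ev$z, "psi")
    if (any(psi_z == 0) || s$r == 1) return(-Inf)
    logf <- logf + sum(log(psi_z) + log(1 - s$r))
  }
  if (ev$n_rho > 0) {
    if (s$rho == 0) return(-Inf)
    logf <- logf + ev$n_rho * log(s$rho)
  }
  logf
}

#' Birth-death serial-sampling log-density (constant rates)
#'
#' Closed-form constant-rate density of a sampled tree with optional sampled
#' ancestors, conditioned on the origin and on at least one sample.  Uses the
#' classic `c1`/`c2` closed form; equals [bdsky_log_density()] with a single
#' interval.
#'
#' @param tree a `timetree`
#' @param b a `bd_params` (must carry the origin `t0`)
#' @return log-density
#' @export
bd_serial_log_density <- function(tree, b) {
  if (is.null(b$t0) || is.na(b$t0)) stop("bd_params must carry an origin t0")
  if (tree$height[tree$root] >= b$t0) return(-Inf)
  fns <- interval_pq(b$lambda, b$mu, b$psi, 1 - b$rho)
  ev <- bd_tree_events(tree, b$rho)
  logf <- fns$logq(b$t0) - log1p(-fns$p(b$t0))
  if (length(ev$x))
    logf <- logf + sum(log(2 * b$lambda) + fns$logq(ev$x))
  if (length(ev$y)) {
    if (b$psi == 0) return(-Inf)
    logf <- logf + sum(log(b$psi) + log(b$r + (1 - b$r) * fns$p(ev$y)) -
                         fns$logq(ev$y))
  }
  if (length(ev$z)) {
    if (b$psi == 0 || b$r == 1) return(-Inf)
    logf <- logf + length(ev$z) * (log(b$psi) + log(1 - b$r))
  }
  if (ev$n_rho > 0) {
    if (b$rho == 0) return(-Inf)
    logf <- logf + ev$n_rho * log(b$rho)
  }
  logf
}

#' Generic tree-prior log density
#'
#' Dispatch helper used by the MCMC engine: accepts any of the three prior
#' parameter classes.
#'
#' @param tree a `timetree`
#' @param params `bd_params`, `skyline_params` or `coalescent_params`
#' @return log-density
#' @export
tree_prior_log_density <- function(tree, params) {
  switch(class(params)[1],
         bd_params = bd_serial_log_density(tree, params),
         skyline_params = bdsky_log_density(tree, params),
         coalescent_params = coalescent_log_density(tree, params),
         stop("unknown tree prior class: ", class(params)[1]))
}
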