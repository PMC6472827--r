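#' Posterior specification for marginal-likelihood estimators
#'
#' A minimal interface shared by nested sampling, path sampling and
#' stepping-stone: a sampleable proper prior, an evaluable likelihood, and a
#' set of MCMC operators for moving through parameter space.
#'
#' @param log_prior function(state) -> log prior density
#' @param log_lik function(state) -> log likelihood
#' @param sample_prior function() -> a state drawn from the prior
#' @param operators operator list (see [operators]) acting on the state
#' @return object of class `posterior_spec`
#' @export
posterior_spec <- function(log_prior, log_lik, sample_prior, operators) {
  structure(list(log_prior = log_prior, log_lik = log_lik,
                 sample_prior = sample_prior, operators = operators),
            class = "posterior_spec")
}

#' Marginal likelihood by nested sampling
#'
#' Classic nested-sampling recursion: the worst of `n_live` live points is
#' replaced by a draw from the prior constrained to higher likelihood
#' (obtained by a likelihood-thresholded MCMC subchain started from a random
#' survivor), prior volume shrinking geometrically as
#' `E[log X_i] = -i/n_live`.  Returns the log marginal likelihood, its
#' uncertainty `sqrt(H/n_live)` (H the information), and the weighted
#' posterior sample accumulated along the way.
#'
#' @param spec a `posterior_spec`
#' @param n_live number of live points (>= 2)
#' @param subchain_length constrained-prior MCMC steps per replacement
#' @param max_iter iteration cap
#' @param tol terminate when the remaining-evidence bound
#'   `max(live L) * X_i` drops below `tol` times the accumulated evidence
#' @param seed RNG seed
#' @return list with `logZ`, `stderr`, `H`, `n_iter`, `posterior` (list of
#'   states), `weights`, `failures` (subchains that never moved)
#' @export
nested_sampling <- function(spec, n_live = 100, subchain_length = 20,
                            max_iter = 100000, tol = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_live >= 2)
  live <- lapply(seq_len(n_live), function(i) spec$sample_prior())
  liveL <- vapply(live, spec$log_lik, numeric(1))
  logLs <- numeric(0)
  saved <- list()
  failures <- 0L
  logZ <- -Inf
  i <- 0L
  repeat {
    i <- i + 1L
    worst <- which.min(liveL)
    Lw <- liveL[worst]
    logLs[i] <- Lw
    saved[[i]] <- live[[worst]]
    ## log of w_i = X_{i-1} - X_i
    logw <- log(exp(-(i - 1) / n_live) - exp(-i / n_live))
    logZ <- logsumexp(c(logZ, Lw + logw))
    ## replacement: constrained-prior subchain from a random survivor
    from <- sample.int(n_live, 1L)
    while (from == worst && n_live > 1L) from <- sample.int(n_live, 1L)
    st <- live[[from]]
    lpr <- spec$log_prior(st)
    stL <- liveL[from]
    moved <- FALSE
    for (s in seq_len(subchain_length)) {
      op <- spec$operators[[sample.int(length(spec$operators), 1L)]]
      prop <- op$propose(st)
      if (is.null(prop)) next
      lpr2 <- spec$log_prior(prop$state)
      if (lpr2 == -Inf) next
      if (log(stats::runif(1)) < lpr2 - lpr + prop$log_hr) {
        L2 <- spec$log_lik(prop$state)
        if (L2 > Lw) {      # hard likelihood constraint
          st <- prop$state; lpr <- lpr2; stL <- L2; moved <- TRUE
        }
      }
    }
    if (!moved) failures <- failures + 1L
    live[[worst]] <- st
    liveL[worst] <- stL
    remain <- max(liveL) - i / n_live
    if (i >= max_iter || remain < log(tol) + logZ) break
  }
  ## add the remaining live points at volume X_i / n_live each
  logw_live <- -i / n_live - log(n_live)
  for (j in seq_len(n_live)) {
    logLs <- c(logLs, liveL[j])
    saved[[length(saved) + 1L]] <- live[[j]]
  }
  logws <- c(log(exp(-(seq_len(i) - 1) / n_live) - exp(-seq_len(i) / n_live)),
             rep(logw_live, n_live))
  logZ <- logsumexp(logLs + logws)
  wpost <- exp(logLs + logws - logZ)
  H <- sum(ifelse(wpost > 0, wpost * (logLs - logZ), 0))
  list(logZ = logZ, stderr = sqrt(max(H, 0) / n_live), H = H, n_iter = i,
       posterior = saved, weights = wpost, failures = failures)
}

## power-posterior schedule: Beta(0.3, 1)-spaced quantiles of [0, 1]
power_schedule <- function(n_steps, a = 0.3) {
  (seq(0, 1, length.out = n_steps))^(1 / a)
}

## MCMC under the power posterior prior * L^beta; returns logL samples
power_posterior_samples <- function(spec, beta, chain_length, sample_every,
                                    state0 = NULL) {
  st <- if (is.null(state0)) spec$sample_prior() else state0
  lt <- function(s) spec$log_prior(s) + if (beta > 0) beta * spec$log_lik(s) else 0
  lp <- lt(st)
  out <- numeric(0)
  for (it in seq_len(chain_length)) {
    op <- spec$operators[[sample.int(length(spec$operators), 1L)]]
    prop <- op$propose(st)
    if (!is.null(prop)) {
      lp2 <- lt(prop$state)
      if (lp2 > -Inf && log(stats::runif(1)) < lp2 - lp + prop$log_hr) {
        st <- prop$state; lp <- lp2
      }
    }
    if (it %% sample_every == 0L) out <- c(out, spec$log_lik(st))
  }
  list(logL = out, state = st)
}

#' Marginal likelihood by path sampling and stepping-stone
#'
#' Runs MCMC under power posteriors `prior * L^beta` along a Beta(0.3,1)-
#' spaced schedule (dense near the prior).  Path sampling integrates
#' `E_beta[log L]` over beta by the trapezoid rule; stepping-stone multiplies
#' importance ratios between adjacent rungs estimated from the lower rung's
#' samples.  Rungs are run consecutively, each seeded from the previous
#' rung's final state.
#'
#' @param spec a `posterior_spec`
#' @param n_steps number of beta rungs
#' @param chain_length MCMC proposals per rung
#' @param sample_every thinning interval within a rung
#' @param burnin_frac fraction of each rung's samples discarded
#' @param seed RNG seed
#' @return list with `logZ_path`, `logZ_ss`, `betas`, `mean_logL`
#' @export
path_sampling <- function(spec, n_steps = 16, chain_length = 4000,
                          sample_every = 5, burnin_frac = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  betas <- power_schedule(n_steps)
  samples <- vector("list", n_steps)
  st <- NULL
  for (k in seq_len(n_steps)) {
    res <- power_posterior_samples(spec, betas[k], chain_length, sample_every, st)
    st <- res$state
    drop <- seq_len(floor(length(res$logL) * burnin_frac))
    samples[[k]] <- res$logL[-drop]
    if (!all(is.finite(samples[[k]])))
      stop("non-finite power-posterior expectation at beta = ", betas[k])
  }
  mean_logL <- vapply(samples, mean, numeric(1))
  logZ_path <- sum(diff(betas) * (mean_logL[-1] + mean_logL[-n_steps]) / 2)
  logZ_ss <- 0
  for (k in seq_len(n_steps - 1)) {
    d <- betas[k + 1] - betas[k]
    logZ_ss <- logZ_ss + logsumexp(d * samples[[k]]) - log(length(samples[[k]]))
  }
  list(logZ_path = logZ_path, logZ_ss = logZ_ss, betas = betas,
       mean_logL = mean_logL)
}
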