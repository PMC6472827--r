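#' Well-calibrated simulation study
#'
#' The validation doctrine for a Bayesian phylodynamic engine: for each
#' replicate, parameters are drawn from the same distributions used as
#' priors during inference, a sampled tree is simulated from them
#' (conditioned, like the inference density, on at least one sample), the
#' tree is treated as observed data, and MCMC recovers the parameters.  If
#' prior, simulator, density and sampler are all mutually consistent, each
#' parameter's nominal 95 percent HPD interval covers the truth 95 percent
#' of the time, up to binomial noise.
#'
#' @param priors named list; each element is `list(sample = function(),
#'   log_density = function(x))` for one inferred scalar parameter of
#'   `bd_params` (e.g. `lambda`, `t0`)
#' @param fixed named list of the remaining `bd_params` arguments
#' @param n_replicates number of study replicates
#' @param chain_length,log_every,burnin_frac MCMC settings per replicate
#' @param level HPD level assessed
#' @param seed RNG seed
#' @param max_failure_frac abort threshold on the fraction of failed
#'   replicates (simulation or inference errors)
#' @return list with `coverage` (data.frame: parameter, successes, n,
#'   coverage, exact binomial 99 percent CI) and `failures`
#' @export
well_calibrated_study <- function(priors, fixed = list(),
                                  n_replicates = 100, chain_length = 20000,
                                  log_every = 20, burnin_frac = 0.1,
                                  level = 0.95, seed = NULL,
                                  max_failure_frac = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  pnames <- names(priors)
  hits <- matrix(NA, n_replicates, length(pnames),
                 dimnames = list(NULL, pnames))
  failures <- 0L
  make_bd <- function(params) do.call(bd_params, c(params, fixed))
  for (rep in seq_len(n_replicates)) {
    ok <- try({
      truth <- lapply(priors, function(p) p$sample())
      tree <- simulate_bd_tree(make_bd(truth), condition_min_samples = 1L,
                               max_tries = 100000L)
      tree$origin <- NA
      lt <- function(s) {
        lp <- sum(vapply(pnames, function(nm)
          priors[[nm]]$log_density(s$params[[nm]]), numeric(1)))
        if (!is.finite(lp)) return(-Inf)
        b <- try(make_bd(s$params), silent = TRUE)
        if (inherits(b, "try-error")) return(-Inf)
        lp + bd_serial_log_density(s$tree, b)
      }
      ops <- lapply(pnames, function(nm) op_scale_param(nm, 1, width = 0.4))
      res <- run_mcmc(list(tree = tree, params = truth), lt, ops,
                      chain_length = chain_length, log_every = log_every,
                      sample_trees = FALSE)
      trc <- res$trace[-seq_len(ceiling(nrow(res$trace) * burnin_frac)), ]
      for (nm in pnames) {
        hpd <- hpd_interval(trc[[nm]], level)
        hits[rep, nm] <- truth[[nm]] >= hpd[1] && truth[[nm]] <= hpd[2]
      }
    }, silent = TRUE)
    if (inherits(ok, "try-error")) failures <- failures + 1L
  }
  if (failures > max_failure_frac * n_replicates)
    stop("well-calibrated study failed: ", failures, " of ", n_replicates,
         " replicates errored")
  cov <- do.call(rbind, lapply(pnames, function(nm) {
    h <- hits[, nm]; h <- h[!is.na(h)]
    bt <- stats::binom.test(sum(h), length(h), p = level, conf.level = 0.99)
    data.frame(parameter = nm, successes = sum(h), n = length(h),
               coverage = mean(h),
               ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  }))
  list(coverage = cov, failures = failures)
}

#' Posterior-predictive model adequacy check
#'
#' Simulates trees from parameter vectors drawn from a posterior sample and
#' compares a tree statistic against its observed value, reporting the
#' two-sided posterior-predictive p-value with a +1 continuity correction
#' (`p = 2 * min(Pr(sim <= obs), Pr(sim >= obs))`, each tail probability
#' estimated as `(1 + count)/(n_sims + 1)`, capped at 1).
#'
#' @param posterior_draws data.frame of posterior parameter samples whose
#'   columns name `bd_params` arguments (e.g. `lambda`, `t0`)
#' @param fixed named list of remaining `bd_params` arguments
#' @param observed observed value of the statistic (or a `timetree`, from
#'   which the statistic is computed)
#' @param statistic `"root_height"` or `"tree_length"`
#' @param n_sims number of posterior-predictive simulations
#' @param retry_cap resimulation cap for unsampled replicates
#' @return object of class `adequacy_report`: list with `statistic`,
#'   `observed`, `sims`, `p_value`
#' @export
posterior_predictive_check <- function(posterior_draws, fixed = list(),
                                       observed, statistic = c("root_height",
                                                               "tree_length"),
                                       n_sims = 100, retry_cap = 1000L) {
  statistic <- match.arg(statistic)
  if (inherits(observed, "timetree"))
    observed <- tree_statistics(observed)[[statistic]]
  if (nrow(posterior_draws) < n_sims)
    stop("need at least n_sims posterior draws")
  rows <- sample.int(nrow(posterior_draws), n_sims)
  sims <- vapply(rows, function(i) {
    b <- do.call(bd_params, c(as.list(posterior_draws[i, , drop = FALSE]),
                              fixed))
    tr <- simulate_bd_tree(b, condition_min_samples = 1L,
                           max_tries = retry_cap)
    tree_statistics(tr)[[statistic]]
  }, numeric(1))
  lo <- (1 + sum(sims <= observed)) / (n_sims + 1)
  hi <- (1 + sum(sims >= observed)) / (n_sims + 1)
  structure(list(statistic = statistic, observed = observed, sims = sims,
                 p_value = min(1, 2 * min(lo, hi))),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("posterior predictive check of %s: observed %.4g, %d sims in [%.4g, %.4g], p = %.4g\n",
              x$statistic, x$observed, length(x$sims), min(x$sims),
              max(x$sims), x$p_value))
  invisible(x)
}
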