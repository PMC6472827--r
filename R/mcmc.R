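#' Metropolis-Hastings MCMC over trees and parameters
#'
#' The engine is deliberately generic: a state is a list (typically with
#' elements `tree`, `params`, `site`, `clock`), the target is any function
#' returning a log-density for a state, and operators are proposal factories
#' built by the `op_*` functions.  Acceptance uses
#' `min(1, posterior-ratio x Hastings-ratio)` where each operator reports its
#' log Hastings ratio (Jacobian included).  A single RNG stream drives every
#' stochastic choice, so runs are bit-reproducible given the seed.
#'
#' @param state0 initial state list
#' @param log_target function(state) -> log posterior density
#' @param operators list of operators from the `op_*` factories
#' @param chain_length number of proposals
#' @param log_every sampling interval for the trace and tree log
#' @param seed integer RNG seed (`NULL` to continue the current stream)
#' @param monitor optional function(state) -> named numeric vector added to
#'   the trace
#' @param sample_trees store the tree at each logged state
#' @param tune auto-tune tunable operators toward 0.234 acceptance during the
#'   first 10 percent of the chain
#' @param check_every recompute the cached posterior from scratch this often
#'   and stop if it drifted (numerical-consistency guard)
#' @return list with `trace` (data.frame, first column `Sample`), `trees`
#'   (list of `timetree` or `NULL`), `acceptance` (per-operator counts), and
#'   `final_state`
#' @export
run_mcmc <- function(state0, log_target, operators, chain_length,
                     log_every = 100L, seed = NULL, monitor = NULL,
                     sample_trees = !is.null(state0$tree), tune = TRUE,
                     check_every = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  ## operators auto-tune through their environments; snapshot and restore so
  ## that repeated runs with the same seed are bit-identical
  snapshots <- lapply(operators, function(o) as.list(o$env))
  on.exit(for (k in seq_along(operators)) {
    rm(list = ls(operators[[k]]$env), envir = operators[[k]]$env)
    for (nm in names(snapshots[[k]]))
      assign(nm, snapshots[[k]][[nm]], envir = operators[[k]]$env)
  }, add = TRUE)
  state <- state0
  lp <- log_target(state)
  if (!is.finite(lp))
    stop("initial state has non-finite log-posterior (", lp,
         "); choose a different starting state")
  w <- vapply(operators, function(o) o$weight, numeric(1))
  stopifnot(all(w > 0))
  w <- w / sum(w)
  nops <- length(operators)
  acc <- rej <- integer(nops)
  default_monitor <- function(s) {
    out <- c(posterior = lp)
    if (!is.null(s$params)) out <- c(out, unlist(s$params))
    if (!is.null(s$tree)) {
      st <- tree_statistics(s$tree)
      out <- c(out, root_height = st$root_height, tree_length = st$tree_length,
               sa_count = st$n_sampled_ancestors)
    }
    if (!is.null(s$site)) {
      out <- c(out, model_code = as.numeric(s$site$code),
               p_inv = s$site$p_inv, gamma_shape = s$site$gamma_shape)
    }
    out
  }
  rows <- list()
  trees <- list()
  take <- function(it) {
    v <- default_monitor(state)
    if (!is.null(monitor)) v <- c(v, monitor(state))
    rows[[length(rows) + 1L]] <<- c(Sample = it, v)
    if (sample_trees) trees[[length(trees) + 1L]] <<- state$tree
  }
  take(0L)
  tune_until <- if (tune) floor(chain_length / 10) else 0L
  for (it in seq_len(chain_length)) {
    k <- sample.int(nops, 1L, prob = w)
    op <- operators[[k]]
    prop <- op$propose(state)
    accepted <- FALSE
    if (!is.null(prop)) {
      lp2 <- log_target(prop$state)
      if (lp2 > -Inf &&
          (lp2 - lp + prop$log_hr >= 0 ||
           log(stats::runif(1)) < lp2 - lp + prop$log_hr)) {
        state <- prop$state
        lp <- lp2
        accepted <- TRUE
      }
    }
    if (accepted) acc[k] <- acc[k] + 1L else rej[k] <- rej[k] + 1L
    if (it <= tune_until && isTRUE(op$tunable)) {
      n <- acc[k] + rej[k]
      op$env$log_width <- op$env$log_width +
        (if (accepted) 1 - 0.234 else -0.234) / sqrt(n)
    }
    if (it %% check_every == 0L) {
      fresh <- log_target(state)
      if (!isTRUE(all.equal(fresh, lp, tolerance = 1e-8)))
        stop("cached posterior drifted from fresh recomputation: ",
             lp, " vs ", fresh)
      lp <- fresh
    }
    if (it %% log_every == 0L) take(it)
  }
  trace <- as.data.frame(do.call(rbind, rows))
  list(trace = trace,
       trees = if (sample_trees) trees else NULL,
       acceptance = data.frame(
         operator = vapply(operators, function(o) o$name, character(1)),
         accepted = acc, rejected = rej,
         rate = acc / pmax(acc + rej, 1L)),
       final_state = state)
}

#' Write a trace as a BEAST-compatible tab-separated log
#'
#' @param trace data.frame whose first column is `Sample`
#' @param path output file
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated trace log
#'
#' @param path file path
#' @param burnin_frac fraction of rows to discard from the start
#' @return data.frame
#' @export
read_trace <- function(path, burnin_frac = 0) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (burnin_frac > 0) tr <- tr[-seq_len(floor(nrow(tr) * burnin_frac)), ]
  tr
}

#' Effective sample size of a trace column
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' the initial-positive-sequence rule (summation stops when a consecutive
#' pair of autocorrelations turns non-positive).  A constant column has ESS 0
#' by convention.
#'
#' @param x numeric vector (>= 10 values)
#' @return effective sample size
#' @export
compute_ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (stats::var(x) == 0) return(0)
  rho <- stats::acf(x, lag.max = min(n - 2, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + (if (k + 1L <= length(rho)) rho[k + 1L] else 0)
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Highest-posterior-density interval
#'
#' Smallest interval containing a fraction `level` of the sample.
#'
#' @param x numeric sample
#' @param level probability content
#' @return numeric vector `c(lower, upper)`
#' @export
hpd_interval <- function(x, level = 0.95) {
  sx <- sort(x)
  n <- length(sx)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(sx[1], sx[n]))
  widths <- sx[(m + 1):n] - sx[1:(n - m)]
  i <- which.min(widths)
  c(sx[i], sx[i + m])
}

#' Credible set of substitution models from a trace
#'
#' Smallest set of model codes whose posterior frequencies sum to at least
#' `level`; ties in frequency are broken lexicographically by code.
#'
#' @param codes character (or numeric 6-digit) vector of sampled model codes
#' @param level credible level
#' @return data.frame with `code`, `freq`, `cumfreq`, restricted to the set
#' @export
credible_model_set <- function(codes, level = 0.95) {
  codes <- sprintf("%06d", as.numeric(codes))
  tab <- table(codes) / length(codes)
  df <- data.frame(code = names(tab), freq = as.numeric(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$freq, df$code), ]
  df$cumfreq <- cumsum(df$freq)
  keep <- seq_len(min(which(df$cumfreq >= level - 1e-12)))
  rownames(df) <- NULL
  df[keep, ]
}
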