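#' Molecular clock models
#'
#' `strict` assigns every branch the same rate.  `relaxed_lognormal` is the
#' discretized uncorrelated lognormal clock: each branch carries an integer
#' category, and category `k` of `K` maps to the `(k - 0.5)/K` quantile of a
#' lognormal with mean 1 (meanlog = -sigma^2/2), the quantile set being
#' renormalized so its mean is exactly 1 before scaling by `mean_rate`.
#'
#' @param kind `"strict"` or `"relaxed_lognormal"`
#' @param mean_rate positive mean rate (substitutions/site/time)
#' @param sigma log-standard deviation of the relaxed clock (>= 0)
#' @param n_categories number of discrete rate categories (relaxed only)
#' @param categories integer category per branch, indexed by child node id
#'   (`NA` for the root slot); defaults to the middle category everywhere
#' @return object of class `clock_model`
#' @export
clock_model <- function(kind = c("strict", "relaxed_lognormal"),
                        mean_rate = 1, sigma = 0, n_categories = 20L,
                        categories = NULL) {
  kind <- match.arg(kind)
  if (mean_rate < 0) stop("mean_rate must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = kind, mean_rate = mean_rate, sigma = sigma,
                 n_categories = as.integer(n_categories),
                 categories = categories),
            class = "clock_model")
}

## quantile rates of the discretized lognormal, mean exactly 1
relaxed_quantile_rates <- function(sigma, ncat) {
  if (sigma == 0) return(rep(1, ncat))
  q <- stats::qlnorm((seq_len(ncat) - 0.5) / ncat, -sigma^2 / 2, sigma)
  q / mean(q)
}

#' Per-branch clock rates
#'
#' @param clock a `clock_model`
#' @param tree a `timetree`
#' @return numeric vector indexed by node id: rate of the branch above each
#'   node (`NA` at the root)
#' @export
branch_rates <- function(clock, tree) {
  n <- length(tree$parent)
  if (clock$kind == "strict") {
    r <- rep(clock$mean_rate, n)
  } else {
    cats <- clock$categories
    if (is.null(cats)) cats <- rep((clock$n_categories + 1L) %/% 2L, n)
    if (length(cats) != n) stop("need one rate category per node")
    q <- relaxed_quantile_rates(clock$sigma, clock$n_categories)
    r <- clock$mean_rate * q[cats]
  }
  r[tree$root] <- NA_real_
  r
}

## npat x 4 indicator partials for one observed (ambiguous) state column
tip_partials <- function(states) {
  out <- matrix(0, length(states), 4)
  for (k in seq_along(states)) out[k, match(IUPAC[[states[k]]], NUC)] <- 1
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes `log P(D | T, theta)` over compressed site patterns, with
#' discrete-gamma rate heterogeneity and a fast proportion-of-invariable-
#' sites path: the rate-zero class contributes `p_inv * sum(pi[x])` over the
#' nucleotides compatible with the whole column, evaluated only for
#' invariant-capable patterns, so no extra pruning pass is needed.
#' Sampled-ancestor nodes enter as observed-state constraints at their
#' degree-2 node.  Per-pattern rescaling guards against underflow on tall
#' trees.
#'
#' @param patterns a `site_patterns` object
#' @param tree a `timetree` containing every pattern taxon
#' @param site a `site_model`
#' @param clock a `clock_model`
#' @return log-likelihood (finite, or error)
#' @export
log_likelihood <- function(patterns, tree, site, clock) {
  rm <- build_rate_matrix(site)
  rates <- branch_rates(clock, tree)
  mix <- site_rate_mixture(site)
  npat <- length(patterns$weights)
  taxlab <- patterns$taxa$label
  node_of <- match(taxlab, tree$taxon)
  if (anyNA(node_of))
    stop("taxa missing from tree: ", paste(taxlab[is.na(node_of)], collapse = ", "))
  tips <- vector("list", length(tree$parent))
  for (k in seq_along(taxlab)) tips[[node_of[k]]] <- tip_partials(patterns$states[k, ])
  ord <- postorder(tree)
  logL_cat <- matrix(NA_real_, npat, length(mix$rates))
  for (ci in seq_along(mix$rates)) {
    partial <- vector("list", length(tree$parent))
    scaler <- numeric(npat)
    for (nd in ord) {
      ch <- tree$children[[nd]]
      pp <- matrix(1, npat, 4)
      for (j in ch) {
        t_sub <- (tree$height[nd] - tree$height[j]) * rates[j] * mix$rates[ci]
        P <- transition_probabilities(rm, t_sub)
        pp <- pp * (partial[[j]] %*% t(P))
        partial[j] <- list(NULL)
      }
      if (!is.null(tips[[nd]])) pp <- pp * tips[[nd]]
      mx <- pmax(apply(pp, 1, max), 0)
      low <- which(mx < 1e-200 & mx > 0)
      if (length(low)) {
        pp[low, ] <- pp[low, , drop = FALSE] / mx[low]
        scaler[low] <- scaler[low] + log(mx[low])
      }
      partial[[nd]] <- pp
    }
    logL_cat[, ci] <- log(as.vector(partial[[tree$root]] %*% rm$pi)) + scaler
  }
  ## mix categories and the invariable class in log space
  loglik_pat <- vapply(seq_len(npat), function(p) {
    terms <- log(mix$weights) + logL_cat[p, ]
    if (mix$p_inv > 0) {
      linv <- sum(rm$pi[patterns$invariant_capable[, p]])
      if (linv > 0) terms <- c(terms, log(mix$p_inv) + log(linv))
    }
    logsumexp(terms)
  }, numeric(1))
  bad <- which(is.nan(loglik_pat))
  if (length(bad)) stop("non-finite likelihood at pattern ", bad[1])
  sum(patterns$weights * loglik_pat)
}

#' Reference log-likelihood without compression or invariant shortcut
#'
#' Recomputes the same quantity as [log_likelihood()] site by site on the
#' uncompressed alignment, treating the invariable class as an explicit
#' rate-zero mixture category.  Serves as the correctness oracle for the
#' pattern-compressed fast path.
#'
#' @param aln an `alignment`
#' @inheritParams log_likelihood
#' @return log-likelihood
#' @export
log_likelihood_naive <- function(aln, tree, site, clock) {
  rm <- build_rate_matrix(site)
  rates <- branch_rates(clock, tree)
  mix <- site_rate_mixture(site)
  cat_rates <- mix$rates
  cat_w <- mix$weights
  if (mix$p_inv > 0) { cat_rates <- c(cat_rates, 0); cat_w <- c(cat_w, mix$p_inv) }
  node_of <- match(aln$taxa$label, tree$taxon)
  if (anyNA(node_of))
    stop("taxa missing from tree: ",
         paste(aln$taxa$label[is.na(node_of)], collapse = ", "))
  chars <- do.call(rbind, strsplit(aln$seqs, ""))
  ord <- postorder(tree)
  total <- 0
  for (s in seq_len(aln$length)) {
    Ls <- 0
    for (ci in seq_along(cat_rates)) {
      partial <- vector("list", length(tree$parent))
      for (nd in ord) {
        pp <- rep(1, 4)
        for (j in tree$children[[nd]]) {
          t_sub <- (tree$height[nd] - tree$height[j]) * rates[j] * cat_rates[ci]
          P <- transition_probabilities(rm, t_sub)
          pp <- pp * as.vector(P %*% partial[[j]])
        }
        k <- match(nd, node_of)
        if (!is.na(k)) {
          ind <- rep(0, 4)
          ind[match(IUPAC[[chars[k, s]]], NUC)] <- 1
          pp <- pp * ind
        }
        partial[[nd]] <- pp
      }
      Ls <- Ls + cat_w[ci] * sum(rm$pi * partial[[tree$root]])
    }
    total <- total + log(Ls)
  }
  total
}
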