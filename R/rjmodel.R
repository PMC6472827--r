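#' Reversible-jump moves over substitution-model space
#'
#' The chain moves along the partition lattice of the six exchangeability
#' rates: a split divides one rate group in two (the new group's rate drawn
#' from its prior, which cancels neatly in the acceptance ratio), a merge
#' pools two groups into the surviving group's rate.  Moves are restricted
#' to a model set (all 203 reversible partitions, or the
#' transition/transversion-respecting subset); proposals leaving the set are
#' auto-rejected.  Indicator toggles for frequency equality, gamma
#' heterogeneity, and the invariable-site class are separate symmetric
#' flips over a saturated parameter space.
#'
#' @name rj_sitemodel
NULL

## canonicalize digits and permute group rates to match the relabeling
normalize_site_groups <- function(digits, rates) {
  first <- unique(digits)
  list(code = paste(match(digits, first), collapse = ""),
       rates = rates[first])
}

## neighbors of a code reachable by one split or one merge, within a set
#' @rdname rj_sitemodel
#' @param code canonical model code
#' @param model_set character vector of admissible codes
#' @return `model_neighbors`: character vector of codes adjacent to `code`
#' @export
model_neighbors <- function(code, model_set) {
  g <- code_groups(code)
  k <- max(g)
  out <- character(0)
  ## merges
  if (k >= 2) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    gg <- g; gg[gg == b] <- a
    out <- c(out, canonical_code(gg))
  }
  ## splits
  for (grp in 1:k) {
    pos <- which(g == grp)
    m <- length(pos)
    if (m < 2) next
    for (mask in 1:(2^m - 2)) {
      sel <- pos[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      gg <- g; gg[sel] <- k + 1L
      out <- c(out, canonical_code(gg))
    }
  }
  sort(unique(intersect(out, model_set)))
}

#' Split/merge operator on the substitution-model code
#'
#' With probability 1/2 proposes a split (new group rate drawn from an
#' Exponential(1) prior; the prior density cancels against the rate-prior
#' term of the target) and otherwise a merge (the absorbed group's rate is
#' deleted, the surviving group keeps its rate).  The Hastings ratio counts
#' splittable groups, subset choices and ordered merge pairs; proposals
#' outside `model_set` are auto-rejected.
#'
#' @param model_set character vector of admissible canonical codes
#' @param weight operator weight
#' @return an operator for states carrying `state$site`
#' @export
op_rj_split_merge <- function(model_set, weight = 1) {
  make_op("rjSplitMerge", weight, function(state) {
    site <- state$site
    g <- code_groups(site$code)
    k <- max(g)
    n_split <- function(gv) sum(tabulate(gv) >= 2)
    go_split <- stats::runif(1) < 0.5
    if (go_split) {
      ns <- n_split(g)
      if (ns == 0) return(NULL)
      sizes <- tabulate(g)
      grp <- which(sizes >= 2)[sample.int(ns, 1L)]
      pos <- which(g == grp)
      m <- length(pos)
      mask <- sample.int(2^m - 2, 1L)
      sel <- pos[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      gg <- g; gg[sel] <- k + 1L
      rnew <- stats::rexp(1)
      nz <- normalize_site_groups(gg, c(site$group_rates, rnew))
      if (!(nz$code %in% model_set)) return(NULL)
      state$site$code <- nz$code
      state$site$group_rates <- nz$rates
      ## q_merge / q_split; the -dexp(rnew) proposal term cancels against
      ## the new rate's Exponential(1) prior factor inside the target ratio
      log_hr <- -log(k * (k + 1)) + log(ns) + log(2^m - 2) -
        stats::dexp(rnew, log = TRUE)
      list(state = state, log_hr = log_hr)
    } else {
      if (k < 2) return(NULL)
      ab <- sample.int(k, 2L)      # ordered: ab[1] survives, ab[2] dies
      gg <- g
      gg[gg == ab[2]] <- ab[1]
      rdie <- site$group_rates[ab[2]]
      rates <- site$group_rates[-ab[2]]
      ## relabel remaining groups compactly before canonicalizing
      gg <- match(gg, sort(unique(gg)))
      nz <- normalize_site_groups(gg, rates)
      if (!(nz$code %in% model_set)) return(NULL)
      merged_sizes <- tabulate(code_groups(nz$code))
      mprime <- sum(g %in% ab)     # size of the merged group
      nsp <- sum(merged_sizes >= 2)
      state$site$code <- nz$code
      state$site$group_rates <- nz$rates
      log_hr <- log(k * (k - 1)) - log(nsp) - log(2^mprime - 2) +
        stats::dexp(rdie, log = TRUE)
      list(state = state, log_hr = log_hr)
    }
  })
}

#' Scale operator on one substitution rate group
#'
#' @param weight operator weight
#' @param width scale half-width
#' @export
op_rate_scale <- function(weight = 1, width = 0.5) {
  env <- new.env(); env$log_width <- log(width)
  make_op("rateScale", weight, function(state) {
    k <- length(state$site$group_rates)
    j <- sample.int(k, 1L)
    s <- draw_scale(env)
    state$site$group_rates[j] <- state$site$group_rates[j] * s
    list(state = state, log_hr = log(s))
  }, env, tunable = TRUE)
}

#' Indicator flip operators for the site model
#'
#' Symmetric toggles of `freqs_equal`, `use_gamma` and `use_inv` over a
#' saturated space: the underlying parameters (`base_freqs`, `gamma_shape`,
#' `p_inv`) keep their values and priors while switched off, so the
#' Hastings ratio is 1.
#'
#' @param which one of `"freqs_equal"`, `"use_gamma"`, `"use_inv"`
#' @param weight operator weight
#' @export
op_flip_indicator <- function(which = c("freqs_equal", "use_gamma", "use_inv"),
                              weight = 1) {
  which <- match.arg(which)
  make_op(paste0("flip.", which), weight, function(state) {
    state$site[[which]] <- !state$site[[which]]
    list(state = state, log_hr = 0)
  })
}

#' Log-prior of a site model under the model-averaging defaults
#'
#' Uniform over the admissible code set, iid Exponential(1) on group rates,
#' Bernoulli(1/2) on each indicator, Dirichlet(4,4,4,4) on frequencies,
#' Exponential(1) on the gamma shape and Uniform(0,1) on `p_inv` (the latter
#' three always applied: the space is saturated so indicator flips are
#' dimension-neutral).
#'
#' @param site a `site_model`
#' @param model_set admissible codes
#' @return log prior density
#' @export
site_model_log_prior <- function(site, model_set) {
  if (!(site$code %in% model_set)) return(-Inf)
  lp <- sum(stats::dexp(site$group_rates, log = TRUE))
  lp <- lp + sum((4 - 1) * log(site$base_freqs)) + lgamma(16) - 4 * lgamma(4)
  lp <- lp + stats::dexp(site$gamma_shape, log = TRUE)
  lp   # uniform code prior, Bernoulli(1/2) indicators, U(0,1) p_inv: constants
}
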