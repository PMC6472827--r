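#' Forward (Gillespie) simulation of a birth-death sampled tree
#'
#' Simulates the birth-death sampling process from one lineage at the origin
#' `t0`: bifurcation at rate `lambda`, death at `mu`, serial sampling at
#' `psi` with removal probability `r`, and binomial `rho`-sampling of extant
#' lineages at height 0.  Rates may be piecewise-constant (`skyline_params`).
#' The returned tree is pruned to sampled nodes and their connecting
#' branches; serially sampled individuals that are ancestral to later
#' samples appear as degree-2 sampled-ancestor nodes.
#'
#' @param b a `bd_params` or `skyline_params`
#' @param condition_min_samples resimulate until at least this many samples
#'   (0 disables conditioning beyond returning `NULL` for unsampled runs)
#' @param max_tries cap on resimulation attempts
#' @param pop_cap abort a replicate whose living population exceeds this
#' @return a `timetree` with `origin = t0`, carrying attribute `tries`, or
#'   `NULL` if no individual was sampled (only when unconditioned)
#' @export
simulate_bd_tree <- function(b, condition_min_samples = 0L, max_tries = 10000L,
                             pop_cap = 1e6) {
  s <- if (inherits(b, "bd_params"))
    skyline_params(b$t0, numeric(0), b$lambda, b$mu, b$psi, b$r, b$rho)
  else b
  for (try in seq_len(max(max_tries, 1L))) {
    tr <- sim_bd_once(s, pop_cap)
    nsamp <- if (is.null(tr)) 0L else sum(!is.na(tr$taxon))
    if (nsamp >= max(condition_min_samples, 1L) ||
        (condition_min_samples == 0L && try == 1L)) {
      if (!is.null(tr)) attr(tr, "tries") <- try
      return(tr)
    }
  }
  stop("no replicate reached ", condition_min_samples, " samples in ",
       max_tries, " tries")
}

## one unconditioned forward pass; NULL if nothing sampled
sim_bd_once <- function(s, pop_cap) {
  bounds <- c(0, s$change_times, s$t0)
  par <- integer(0); hei <- numeric(0); typ <- character(0)
  newn <- function(p, h, ty) {
    par[[length(par) + 1L]] <<- p; hei[[length(hei) + 1L]] <<- h
    typ[[length(typ) + 1L]] <<- ty
    length(par)
  }
  active <- 0L   # parent node id of each open lineage (0 = origin stem)
  h <- s$t0
  while (h > 0 && length(active)) {
    if (length(active) > pop_cap) stop("population cap exceeded during simulation")
    i <- max(findInterval(h, bounds, left.open = TRUE), 1L)
    i <- min(i, s$k)
    lam <- s$lambda[i]; mu <- s$mu[i]; psi <- s$psi[i]
    tot <- length(active) * (lam + mu + psi)
    hnew <- if (tot > 0) h - stats::rexp(1, tot) else -Inf
    lower <- bounds[i]
    if (hnew <= lower) { h <- lower; next }   # crossed a change time; redraw
    h <- hnew
    j <- sample.int(length(active), 1L)
    ev <- sample(c("birth", "death", "psi"), 1L, prob = c(lam, mu, psi))
    if (ev == "birth") {
      nd <- newn(active[j], h, "birth")
      active <- c(active[-j], nd, nd)
    } else if (ev == "death") {
      newn(active[j], h, "death")
      active <- active[-j]
    } else if (stats::runif(1) < s$r) {
      newn(active[j], h, "tip")           # sampled and removed
      active <- active[-j]
    } else {
      nd <- newn(active[j], h, "sa")      # sampled, lineage continues
      active[j] <- nd
    }
  }
  for (p in active)
    newn(p, 0, if (stats::runif(1) < s$rho) "tip" else "ghost")
  prune_sampled(par, hei, typ, s$t0)
}

## keep sampled nodes and connecting structure; returns timetree or NULL
prune_sampled <- function(par, hei, typ, t0) {
  n <- length(par)
  if (n == 0L) return(NULL)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (par[i] > 0L) kids[[par[i]]] <- c(kids[[par[i]]], i)
  ord <- order(hei)                      # children strictly below parents
  opar <- integer(0); ohei <- numeric(0); osam <- logical(0)
  add <- function(h, sampled, ch) {
    opar[[length(opar) + 1L]] <<- 0L
    ohei[[length(ohei) + 1L]] <<- h
    osam[[length(osam) + 1L]] <<- sampled
    id <- length(opar)
    for (c in ch) opar[[c]] <<- id
    id
  }
  pr <- integer(n)                       # output id representing each node
  for (i in ord) {
    ch <- kids[[i]]
    sub <- pr[ch]; sub <- sub[sub > 0L]
    pr[i] <- switch(typ[i],
      death = 0L, ghost = 0L,
      tip = add(hei[i], TRUE, integer(0)),
      sa = if (length(sub)) add(hei[i], TRUE, sub) else add(hei[i], TRUE, integer(0)),
      birth = if (length(sub) == 2L) add(hei[i], FALSE, sub)
              else if (length(sub) == 1L) sub else 0L)
  }
  root <- pr[which(par == 0L)]
  if (root == 0L) return(NULL)
  ## label sampled nodes in sampling order (oldest first)
  taxon <- rep(NA_character_, length(opar))
  sidx <- which(osam)
  taxon[sidx[order(-ohei[sidx])]] <- paste0("t", seq_along(sidx))
  timetree(opar, ohei, taxon, origin = t0)
}

#' Simulate a serial coalescent tree
#'
#' Standard heterochronous coalescent with pairwise merger rate `1/Ne`:
#' going back in time, `k` active lineages coalesce at total rate
#' `k (k-1) / 2 / Ne`, with sampled tips joining as their heights are passed.
#'
#' @param tip_times numeric heights of the tips (>= 0); names become labels
#' @param Ne effective population size (tree time units)
#' @return a `timetree`
#' @export
simulate_coalescent_tree <- function(tip_times, Ne) {
  n <- length(tip_times)
  stopifnot(n >= 2, Ne > 0)
  labs <- names(tip_times)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  ord <- order(tip_times)
  par <- rep(0L, n); hei <- as.numeric(tip_times); tax <- labs
  newn <- function(h, ch) {
    par[[length(par) + 1L]] <<- 0L
    hei[[length(hei) + 1L]] <<- h
    tax[[length(tax) + 1L]] <<- NA_character_
    id <- length(par)
    for (c in ch) par[[c]] <<- id
    id
  }
  h <- tip_times[ord[1]]
  active <- ord[1]
  nxt <- 2L
  repeat {
    k <- length(active)
    rate <- k * (k - 1) / 2 / Ne
    wait <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (nxt <= n && tip_times[ord[nxt]] < h + wait) {
      h <- tip_times[ord[nxt]]
      active <- c(active, ord[nxt])
      nxt <- nxt + 1L
      next
    }
    if (!is.finite(wait) && nxt > n && k == 1L) break
    h <- h + wait
    pick <- sample.int(k, 2L)
    nd <- newn(h, active[pick])
    active <- c(active[-pick], nd)
  }
  timetree(par, hei, tax)
}

#' Simulate two-species gene divergence under the multispecies coalescent
#'
#' One gene lineage per species: after the speciation time `tau` (looking
#' backwards, in generations) the two lineages enter the ancestral
#' population and coalesce at rate `1/(2*Ne)` per generation (diploid
#' convention), so the expected divergence exceeds the speciation time by
#' `2*Ne` generations.
#'
#' @param tau speciation time in generations
#' @param Ne diploid effective size of the ancestral population
#' @param n number of replicate divergence times
#' @return numeric vector of gene divergence times (generations)
#' @export
simulate_msc_pair <- function(tau, Ne, n = 1L) {
  stopifnot(tau >= 0, Ne > 0)
  tau + stats::rexp(n, rate = 1 / (2 * Ne))
}

#' Simulate sequences down a time tree
#'
#' Root states are drawn from the equilibrium frequencies; states evolve
#' down each branch with transition probabilities `P(rate * dt)`.  Each site
#' is assigned a gamma rate category (and, with probability `p_inv`, the
#' invariable class with rate 0).
#'
#' @param tree a `timetree`
#' @param site a `site_model`
#' @param clock a `clock_model`
#' @param length number of sites
#' @return an `alignment` over the tree's taxa
#' @export
simulate_sequences <- function(tree, site, clock, length) {
  rm <- build_rate_matrix(site)
  rates <- branch_rates(clock, tree)
  gam <- if (site$use_gamma)
    discrete_gamma_rates(site$gamma_shape, site$n_categories) else 1
  cat_of <- sample.int(length(gam), length, replace = TRUE)
  siterate <- gam[cat_of]
  if (site$p_inv > 0)
    siterate[stats::runif(length) < site$p_inv] <- 0
  n <- length(tree$parent)
  states <- matrix(0L, n, length)
  states[tree$root, ] <- sample.int(4, length, replace = TRUE, prob = rm$pi)
  ucat <- sort(unique(siterate))
  for (nd in rev(postorder(tree))) {
    p <- tree$parent[nd]
    if (p == 0L) next
    dt <- (tree$height[p] - tree$height[nd]) * rates[nd]
    for (rt in ucat) {
      sel <- which(siterate == rt)
      P <- transition_probabilities(rm, dt * rt)
      for (a in 1:4) {
        ss <- sel[states[p, sel] == a]
        if (length(ss))
          states[nd, ss] <- sample.int(4, length(ss), replace = TRUE, prob = P[a, ])
      }
    }
  }
  idx <- which(!is.na(tree$taxon))
  seqs <- stats::setNames(
    vapply(idx, function(i) paste(NUC[states[i, ]], collapse = ""), character(1)),
    tree$taxon[idx])
  make_alignment(seqs, stats::setNames(tree$height[idx], tree$taxon[idx]))
}
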