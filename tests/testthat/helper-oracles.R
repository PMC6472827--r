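## Independent oracles and fixture builders used across the test files.
## Everything here is deliberately written the slow, obvious way so it stays
## independent of the implementation paths it checks.

## exhaustive likelihood: sum over all joint state assignments of every node
enum_loglik <- function(aln, tree, site, clock) {
  rm <- build_rate_matrix(site)
  rates <- branch_rates(clock, tree)
  gam <- if (site$use_gamma) discrete_gamma_rates(site$gamma_shape,
                                                  site$n_categories) else 1
  pinv <- if (site$use_inv) site$p_inv else 0
  cr <- c(gam, if (pinv > 0) 0)
  cw <- c(rep((1 - pinv) / length(gam), length(gam)), if (pinv > 0) pinv)
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
                "?" = c("A", "C", "G", "T"))
  nuc <- c("A", "C", "G", "T")
  chars <- do.call(rbind, strsplit(aln$seqs, ""))
  node_of <- match(aln$taxa$label, tree$taxon)
  n <- length(tree$parent)
  total <- 0
  for (s in seq_len(ncol(chars))) {
    Ls <- 0
    for (ci in seq_along(cr)) {
      Ps <- lapply(seq_len(n), function(j) {
        if (tree$parent[j] == 0L) return(NULL)
        dt <- (tree$height[tree$parent[j]] - tree$height[j]) * rates[j] * cr[ci]
        transition_probabilities(rm, dt)
      })
      allowed <- lapply(seq_len(n), function(j) {
        k <- match(j, node_of)
        if (is.na(k)) 1:4 else match(iupac[[chars[k, s]]], nuc)
      })
      grid <- expand.grid(allowed)
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- as.integer(grid[g, ])
        pr <- rm$pi[st[tree$root]]
        for (j in seq_len(n)) if (tree$parent[j] > 0L)
          pr <- pr * Ps[[j]][st[tree$parent[j]], st[j]]
        tot <- tot + pr
      }
      Ls <- Ls + cw[ci] * tot
    }
    total <- total + log(Ls)
  }
  total
}

## brute-force canonical set-partition enumeration of n items (first-
## appearance relabeling of all label assignments)
brute_partitions <- function(n) {
  grids <- do.call(expand.grid, rep(list(seq_len(n)), n))
  codes <- apply(grids, 1, function(g) {
    first <- unique(as.integer(g))
    paste(match(as.integer(g), first), collapse = "")
  })
  sort(unique(codes))
}

## random serial time tree for property checks (no sampled ancestors)
random_serial_tree <- function(ntips, max_tip_height = 1, seedless = TRUE) {
  tips <- stats::runif(ntips, 0, max_tip_height)
  tips[sample.int(ntips, 1)] <- 0   # anchor the height-zero convention
  names(tips) <- paste0("t", seq_len(ntips))
  simulate_coalescent_tree(tips, 1)
}

## random nucleotide alignment with occasional ambiguity and gap codes
random_alignment <- function(labels, nsites, amb_prob = 0.05) {
  pool <- c("A", "C", "G", "T")
  amb <- c("R", "Y", "N", "-")
  seqs <- vapply(labels, function(l) {
    ch <- sample(pool, nsites, replace = TRUE)
    k <- which(stats::runif(nsites) < amb_prob)
    ch[k] <- sample(amb, length(k), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  phylomc:::make_alignment(stats::setNames(seqs, labels))
}

## forward-simulate conditioned on a total sample count (triangle tests)
sim_bd_conditioned <- function(b, n_samples, n_trees, max_tries = 5e5) {
  out <- vector("list", n_trees)
  got <- 0L
  for (i in seq_len(max_tries)) {
    tr <- simulate_bd_tree(b)
    if (is.null(tr)) next
    st <- tree_statistics(tr)
    if (st$n_tips + st$n_sampled_ancestors == n_samples) {
      got <- got + 1L
      out[[got]] <- tr
      if (got == n_trees) return(out)
    }
  }
  stop("conditioned simulation too inefficient for these parameters")
}

## two-sample KS p-value; ties between thinned MCMC draws are expected and
## only make the test conservative, so the tie warning is silenced
ks_p <- function(x, y) suppressWarnings(stats::ks.test(x, y)$p.value)

tree_stat_matrix <- function(trees) {
  t(vapply(trees, function(tr) {
    st <- tree_statistics(tr)
    c(root_height = st$root_height, tree_length = st$tree_length,
      sa_count = st$n_sampled_ancestors)
  }, numeric(3)))
}

## MCMC prior sampling of a tree prior conditioned on the taxon set of tr0
mcmc_prior_trees <- function(tr0, log_density, chain_length, seed,
                             tips_sampled = TRUE, sa_moves = TRUE,
                             t0 = NULL, log_every = 100L) {
  ops <- list(op_uniform_height(15), op_root_height(10), op_exchange(15),
              op_wilson_balding(15))
  if (tips_sampled) ops <- c(ops, list(op_tip_height(15)))
  if (sa_moves) ops <- c(ops, list(op_sa_jump(10)))
  st0 <- list(tree = tr0, params = if (is.null(t0)) list() else list(t0 = t0))
  run_mcmc(st0, function(s) log_density(s$tree), ops,
           chain_length = chain_length, log_every = log_every, seed = seed)
}
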