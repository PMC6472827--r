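#' MCMC proposal operators
#'
#' Each factory returns a list with `name`, `weight`, a `propose` function
#' mapping a state to either `NULL` (auto-reject: no valid move exists or a
#' height constraint failed) or `list(state, log_hr)` with the log Hastings
#' ratio including any Jacobian, an `env` holding tunable settings, and a
#' `tunable` flag.
#'
#' @name operators
NULL

make_op <- function(name, weight, propose, env = new.env(), tunable = FALSE) {
  list(name = name, weight = weight, propose = propose, env = env,
       tunable = tunable)
}

## log-uniform scale multiplier; HR for scaling m coordinates is m*log(s)
draw_scale <- function(env) exp((2 * stats::runif(1) - 1) * exp(env$log_width))

#' Scale operator on a scalar parameter
#'
#' Multiplies `state$params[[name]]` by `s` drawn log-uniformly from
#' `[1/S, S]`; the Hastings ratio (with Jacobian) is `s`.
#'
#' @param name parameter name inside `state$params`
#' @param weight operator weight
#' @param width initial half-width of `log(s)`
#' @return an operator
#' @export
op_scale_param <- function(name, weight = 1, width = 0.5) {
  env <- new.env(); env$log_width <- log(width)
  make_op(paste0("scale.", name), weight, function(state) {
    s <- draw_scale(env)
    state$params[[name]] <- state$params[[name]] * s
    list(state = state, log_hr = log(s))
  }, env, tunable = TRUE)
}

#' Reflected random-walk operator on a bounded scalar parameter
#'
#' Symmetric proposal (Hastings ratio 1) with reflection at the bounds.
#'
#' @inheritParams op_scale_param
#' @param lower,upper reflection bounds
#' @export
op_rw_param <- function(name, weight = 1, width = 0.1, lower = -Inf,
                        upper = Inf) {
  env <- new.env(); env$log_width <- log(width)
  make_op(paste0("rw.", name), weight, function(state) {
    x <- state$params[[name]] + stats::runif(1, -1, 1) * exp(env$log_width)
    for (rep in 1:100) {
      if (x < lower) x <- 2 * lower - x
      else if (x > upper) x <- 2 * upper - x
      else break
    }
    if (x < lower || x > upper) return(NULL)
    state$params[[name]] <- x
    list(state = state, log_hr = 0)
  }, env, tunable = TRUE)
}

## ---- tree operators -------------------------------------------------------

## nodes of the subtree rooted at i (including i)
subtree_nodes <- function(tree, i) {
  out <- integer(0); stack <- i
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, nd); stack <- c(stack, tree$children[[nd]])
  }
  out
}

## rebuild the children lists after editing $parent (keeps ids stable)
relink <- function(tree) {
  n <- length(tree$parent)
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  for (i in seq_len(n)) if (tree$parent[i] > 0L)
    ch[[tree$parent[i]]] <- c(ch[[tree$parent[i]]], i)
  tree$children <- ch
  tree$root <- which(tree$parent == 0L)
  tree
}

## default origin lookup used by operators that need an upper height bound
state_origin <- function(state) {
  if (!is.null(state$params$t0)) return(state$params$t0)
  if (!is.null(state$tree$origin) && !is.na(state$tree$origin))
    return(state$tree$origin)
  NA_real_
}

#' Uniform height move on an unsampled internal node
#'
#' Redraws the height of a random binary, unsampled, non-root node uniformly
#' between its highest child and its parent (Hastings ratio 1).
#'
#' @param weight operator weight
#' @export
op_uniform_height <- function(weight = 1) {
  make_op("uniformHeight", weight, function(state) {
    tree <- state$tree
    deg <- lengths(tree$children)
    el <- which(deg == 2L & is.na(tree$taxon) & tree$parent > 0L)
    if (!length(el)) return(NULL)
    nd <- el[sample.int(length(el), 1L)]
    lo <- max(tree$height[tree$children[[nd]]])
    hi <- tree$height[tree$parent[nd]]
    if (hi <= lo) return(NULL)
    state$tree$height[nd] <- stats::runif(1, lo, hi)
    list(state = state, log_hr = 0)
  })
}

#' Root height move
#'
#' With an origin available (from `params$t0` or the tree), redraws the root
#' height uniformly between its highest child and the origin; otherwise
#' scales the root's offset above its highest child (Hastings ratio `s`).
#'
#' @param weight operator weight
#' @param width scale half-width for the origin-free case
#' @export
op_root_height <- function(weight = 1, width = 0.5) {
  env <- new.env(); env$log_width <- log(width)
  make_op("rootHeight", weight, function(state) {
    tree <- state$tree
    r <- tree$root
    if (!is.na(tree$taxon[r])) return(NULL)   # sampled-ancestor root is fixed
    lo <- max(tree$height[tree$children[[r]]])
    up <- state_origin(state)
    if (is.finite(up)) {
      if (up <= lo) return(NULL)
      state$tree$height[r] <- stats::runif(1, lo, up)
      list(state = state, log_hr = 0)
    } else {
      s <- draw_scale(env)
      state$tree$height[r] <- lo + (tree$height[r] - lo) * s
      list(state = state, log_hr = log(s))
    }
  }, env, tunable = FALSE)
}

#' Whole-tree scale operator
#'
#' Scales every unsampled internal node height by a common log-uniform
#' factor; sampled node heights (tips, sampled ancestors) stay fixed.
#' Hastings ratio `s^m` for `m` scaled nodes; proposals that violate height
#' ordering or exceed the origin are rejected.
#'
#' @param weight operator weight
#' @param width scale half-width
#' @export
op_tree_scale <- function(weight = 1, width = 0.3) {
  env <- new.env(); env$log_width <- log(width)
  make_op("treeScale", weight, function(state) {
    tree <- state$tree
    free <- which(is.na(tree$taxon) & lengths(tree$children) > 0L)
    if (!length(free)) return(NULL)
    s <- draw_scale(env)
    tree$height[free] <- tree$height[free] * s
    up <- state_origin(state)
    if (is.finite(up) && tree$height[tree$root] >= up) return(NULL)
    haspar <- tree$parent > 0L
    if (any(tree$height[tree$parent[haspar]] < tree$height[haspar]))
      return(NULL)
    state$tree <- tree
    list(state = state, log_hr = length(free) * log(s))
  }, env, tunable = TRUE)
}

#' Wide exchange operator
#'
#' Picks an unordered pair of non-root nodes, neither ancestral to the
#' other, and swaps their subtrees; rejected if a parent would end up below
#' its new child.  The move is an involution, so the Hastings ratio is 1.
#'
#' @param weight operator weight
#' @export
op_exchange <- function(weight = 1) {
  make_op("exchangeWide", weight, function(state) {
    tree <- state$tree
    nonroot <- which(tree$parent > 0L)
    if (length(nonroot) < 2L) return(NULL)
    ij <- sample(nonroot, 2L)
    i <- ij[1]; j <- ij[2]
    pi <- tree$parent[i]; pj <- tree$parent[j]
    if (pi == pj) return(NULL)
    if (j %in% subtree_nodes(tree, i) || i %in% subtree_nodes(tree, j))
      return(NULL)
    if (tree$height[pj] <= tree$height[i] || tree$height[pi] <= tree$height[j])
      return(NULL)
    tree$parent[i] <- pj; tree$parent[j] <- pi
    state$tree <- relink(tree)
    list(state = state, log_hr = 0)
  })
}

#' Wilson-Balding subtree prune-and-regraft
#'
#' Detaches a subtree (excising its binary parent), regrafts it onto a
#' uniformly chosen eligible edge at a uniform height, allowing regrafting
#' above the root when an origin bound is available.  The Hastings ratio
#' accounts for the candidate-node counts and attachment-interval lengths in
#' both directions.
#'
#' @param weight operator weight
#' @export
op_wilson_balding <- function(weight = 1) {
  candidates <- function(tree) {
    deg <- lengths(tree$children)
    idx <- which(tree$parent > 0L)
    idx[deg[tree$parent[idx]] == 2L]
  }
  make_op("wilsonBalding", weight, function(state) {
    tree <- state$tree
    up <- state_origin(state)
    cand <- candidates(tree)
    if (!length(cand)) return(NULL)
    i <- cand[sample.int(length(cand), 1L)]
    p <- tree$parent[i]
    sib <- setdiff(tree$children[[p]], i)
    g <- tree$parent[p]
    ## reverse attachment interval (old position of p)
    rev_lo <- max(tree$height[i], tree$height[sib])
    rev_hi <- if (g > 0L) tree$height[g] else up
    if (!is.finite(rev_hi)) return(NULL)
    ## excise p: sib takes p's place
    t2 <- tree
    t2$parent[sib] <- g
    t2$parent[p] <- -1L   # parked
    t2 <- relink(t2)
    t2$root <- which(t2$parent == 0L)
    ## destination edges in the excised tree, outside subtree(i)
    excl <- c(subtree_nodes(tree, i), p)
    nodes2 <- setdiff(seq_along(t2$parent), excl)
    edges <- lapply(nodes2, function(j) {
      pj <- t2$parent[j]
      hi <- if (pj > 0L) t2$height[pj] else up   # root edge bounded by origin
      if (!is.finite(hi)) return(NULL)
      lo <- max(t2$height[j], tree$height[i])
      if (hi <= lo) return(NULL)
      c(j, lo, hi)
    })
    edges <- edges[!vapply(edges, is.null, logical(1))]
    if (!length(edges)) return(NULL)
    e <- edges[[sample.int(length(edges), 1L)]]
    j <- e[1]; x <- stats::runif(1, e[2], e[3])
    ## regraft p (with child i) onto edge above j
    pj <- t2$parent[j]
    t2$parent[j] <- p
    t2$parent[i] <- p
    t2$parent[p] <- pj
    t2$height[p] <- x
    t2 <- relink(t2)
    ## Hastings: candidate counts and interval lengths
    n_fwd <- length(cand)
    n_rev <- length(candidates(t2))
    if (rev_hi <= rev_lo) return(NULL)
    log_hr <- log(n_fwd) - log(n_rev) +
      log(e[3] - e[2]) - log(rev_hi - rev_lo)
    state$tree <- t2
    list(state = state, log_hr = log_hr)
  })
}

#' Sampled-node height move
#'
#' Redraws the height of a serially sampled node (tip or sampled ancestor)
#' uniformly inside its local constraints.  Used when tip dates are part of
#' the sampled state, notably for sampling tree priors that generate random
#' sampling times.  Height-zero tips (present-day samples) are not moved.
#'
#' @param weight operator weight
#' @export
op_tip_height <- function(weight = 1) {
  make_op("tipHeight", weight, function(state) {
    tree <- state$tree
    el <- which(!is.na(tree$taxon) & tree$height > 1e-12 & tree$parent > 0L)
    ## also allow a sampled-ancestor root when an origin bound exists
    up0 <- state_origin(state)
    if (is.finite(up0)) {
      r <- tree$root
      if (!is.na(tree$taxon[r]) && tree$height[r] > 1e-12) el <- c(el, r)
    }
    if (!length(el)) return(NULL)
    nd <- el[sample.int(length(el), 1L)]
    ch <- tree$children[[nd]]
    lo <- if (length(ch)) max(tree$height[ch]) else 0
    hi <- if (tree$parent[nd] > 0L) tree$height[tree$parent[nd]] else up0
    if (hi <= lo) return(NULL)
    state$tree$height[nd] <- stats::runif(1, lo, hi)
    list(state = state, log_hr = 0)
  })
}

#' Sampled-ancestor jump operator
#'
#' Toggles a serially sampled node between a leaf on a positive pendant
#' branch and a degree-2 sampled ancestor.  Collapsing a leaf deletes its
#' parent bifurcation (removing that height coordinate); expanding a sampled
#' ancestor draws the new bifurcation height uniformly between the sampled
#' node and its parent (or the origin).  The log Hastings ratio is minus/plus
#' the log length of that attachment interval.
#'
#' @param weight operator weight
#' @export
op_sa_jump <- function(weight = 1) {
  make_op("saJump", weight, function(state) {
    tree <- state$tree
    el <- which(!is.na(tree$taxon) & tree$height > 1e-12)
    if (!length(el)) return(NULL)
    u <- el[sample.int(length(el), 1L)]
    up0 <- state_origin(state)
    deg <- lengths(tree$children)
    if (deg[u] == 0L) {
      ## leaf -> sampled ancestor (collapse parent p)
      p <- tree$parent[u]
      if (p == 0L || deg[p] != 2L) return(NULL)
      sib <- setdiff(tree$children[[p]], u)
      if (tree$height[sib] >= tree$height[u]) return(NULL)
      g <- tree$parent[p]
      upper <- if (g > 0L) tree$height[g] else up0
      if (!is.finite(upper)) return(NULL)
      tree$parent[sib] <- u
      tree$parent[u] <- g
      tree$parent[p] <- -1L
      keep <- setdiff(seq_along(tree$parent), p)
      tree <- relink(tree)
      state$tree <- compact_tree(tree, keep)
      list(state = state, log_hr = -log(upper - tree$height[u]))
    } else if (deg[u] == 1L) {
      ## sampled ancestor -> leaf (insert bifurcation p at height x)
      cdown <- tree$children[[u]]
      g <- tree$parent[u]
      upper <- if (g > 0L) tree$height[g] else up0
      if (!is.finite(upper) || upper <= tree$height[u]) return(NULL)
      x <- stats::runif(1, tree$height[u], upper)
      newid <- length(tree$parent) + 1L
      tree$parent <- c(tree$parent, g)
      tree$height <- c(tree$height, x)
      tree$taxon <- c(tree$taxon, NA_character_)
      tree$parent[u] <- newid
      tree$parent[cdown] <- newid
      state$tree <- relink(tree)
      list(state = state, log_hr = log(upper - tree$height[u]))
    } else NULL
  })
}

## renumber a tree to the kept node ids (after deleting parked nodes)
compact_tree <- function(tree, keep) {
  map <- integer(length(tree$parent)); map[keep] <- seq_along(keep)
  par <- tree$parent[keep]
  par[par > 0L] <- map[par[par > 0L]]
  par[par < 0L] <- 0L
  timetree(par, tree$height[keep], tree$taxon[keep], tree$origin)
}

#' Default operator schedule for tree-space sampling
#'
#' Tree moves carry most of the weight, scalar moves and the
#' sampled-ancestor jump the rest; pass `tips_sampled = TRUE` to include the
#' sampled-node height move for analyses where sampling times are random.
#'
#' @param scalars character vector of `state$params` names to receive scale
#'   operators
#' @param tips_sampled include [op_tip_height()]
#' @param sa_moves include [op_sa_jump()]
#' @return list of operators
#' @export
default_tree_operators <- function(scalars = character(0),
                                   tips_sampled = FALSE, sa_moves = FALSE) {
  ops <- list(op_uniform_height(15), op_root_height(10), op_tree_scale(5),
              op_exchange(15), op_wilson_balding(15))
  if (tips_sampled) ops <- c(ops, list(op_tip_height(10)))
  if (sa_moves) ops <- c(ops, list(op_sa_jump(5)))
  for (s in scalars) ops <- c(ops, list(op_scale_param(s, 5)))
  ops
}
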