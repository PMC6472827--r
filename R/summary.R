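#' Clade support frequencies from a posterior tree sample
#'
#' A clade is the set of taxa at or below a node (sampled-ancestor taxa
#' included); supports are the fraction of sampled trees containing each
#' clade of two or more taxa.
#'
#' @param trees list of `timetree` objects (post burn-in)
#' @return named numeric vector of frequencies, names are comma-joined
#'   sorted taxon labels
#' @export
clade_supports <- function(trees) {
  if (!length(trees)) stop("empty tree log")
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (key in tree_clades(tr)$key) {
      prev <- if (is.null(counts[[key]])) 0 else counts[[key]]
      counts[[key]] <- prev + 1
    }
  }
  keys <- ls(counts)
  out <- vapply(keys, function(k) counts[[k]], numeric(1)) / length(trees)
  sort(out, decreasing = TRUE)
}

## clade keys (>= 2 taxa) with node ids and heights for one tree
tree_clades <- function(tree) {
  n <- length(tree$parent)
  sets <- vector("list", n)
  for (nd in postorder(tree)) {
    s <- unlist(lapply(tree$children[[nd]], function(c) sets[[c]]))
    if (!is.na(tree$taxon[nd])) s <- c(s, tree$taxon[nd])
    sets[[nd]] <- s
  }
  keep <- which(lengths(sets) >= 2L)
  data.frame(node = keep,
             key = vapply(sets[keep], function(s)
               paste(sort(s), collapse = ","), character(1)),
             height = tree$height[keep], stringsAsFactors = FALSE)
}

#' Maximum clade credibility tree with height annotations
#'
#' Picks the sampled tree maximizing the product of its clade support
#' frequencies (ties broken by first occurrence in the log) and annotates
#' each clade's node with the mean and 95 percent HPD of its height across
#' the sampled trees containing it.
#'
#' @param trees list of `timetree` objects (post burn-in)
#' @return the MCC `timetree`, with a data.frame attribute
#'   `"node_annotations"` (node, support, mean_height, hpd_lower, hpd_upper)
#' @export
summarize_mcc <- function(trees) {
  sup <- clade_supports(trees)
  score <- vapply(trees, function(tr) {
    sum(log(sup[tree_clades(tr)$key]))
  }, numeric(1))
  best <- which.max(score)   # ties: first occurrence
  mcc <- trees[[best]]
  cl <- tree_clades(mcc)
  heights <- lapply(cl$key, function(k) {
    unlist(lapply(trees, function(tr) {
      tc <- tree_clades(tr)
      tc$height[tc$key == k]
    }))
  })
  ann <- data.frame(node = cl$node, support = unname(sup[cl$key]),
                    mean_height = vapply(heights, mean, numeric(1)),
                    hpd_lower = vapply(heights, function(h) hpd_interval(h)[1],
                                       numeric(1)),
                    hpd_upper = vapply(heights, function(h) hpd_interval(h)[2],
                                       numeric(1)))
  attr(mcc, "node_annotations") <- ann
  mcc
}
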