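#' Rooted time trees with sampled-ancestor nodes
#'
#' A `timetree` is a rooted tree whose node ages ("heights") are measured
#' backwards in time from the latest sampled tip (height 0).  Edge length is
#' always `height[parent] - height[child]`.  Sampled individuals that are
#' direct ancestors of other samples are represented as degree-2 nodes
#' (exactly one child) carrying a taxon label, the convention used for
#' serially sampled epidemics and for fossilized birth-death analyses.
#'
#' Internally a tree is a list of parallel vectors indexed by stable integer
#' node ids:
#' \describe{
#'   \item{parent}{integer; 0 for the root}
#'   \item{children}{list of integer vectors (0, 1 or 2 children)}
#'   \item{height}{numeric, non-negative}
#'   \item{taxon}{character; `NA` for unsampled internal nodes}
#'   \item{root}{integer id of the root}
#'   \item{origin}{height of the origin of the process, or `NA`; must exceed
#'     the root height when present}
#' }
#'
#' @param parent integer vector of parent ids (0 for the root)
#' @param height numeric vector of node heights
#' @param taxon character vector of taxon labels (`NA` for unsampled nodes)
#' @param origin optional origin height (`NA` to omit)
#' @return an object of class `timetree`
#' @export
timetree <- function(parent, height, taxon, origin = NA_real_) {
  n <- length(parent)
  stopifnot(length(height) == n, length(taxon) == n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  root <- 0L
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p == 0L) {
      root <- i
    } else {
      children[[p]] <- c(children[[p]], i)
    }
  }
  tr <- structure(list(parent = as.integer(parent), children = children,
                       height = as.numeric(height),
                       taxon = as.character(taxon),
                       root = root, origin = as.numeric(origin)),
                  class = "timetree")
  validate_timetree(tr)
  tr
}

#' Validate a time tree
#'
#' Checks the structural invariants: a single root, parent heights not below
#' child heights, binary internal nodes except degree-2 sampled ancestors
#' (which must carry a taxon), leaves carrying taxa, unique taxon labels, and
#' `origin > root height` when an origin is set.
#'
#' @param tree a `timetree`
#' @param tol numeric slack allowed on the parent-above-child check
#' @return `tree`, invisibly; stops on violation
#' @export
validate_timetree <- function(tree, tol = 1e-9) {
  n <- length(tree$parent)
  nroot <- sum(tree$parent == 0L)
  if (nroot != 1L) stop("timetree must have exactly one root, found ", nroot)
  ndeg <- lengths(tree$children)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p > 0L) {
      if (tree$height[p] < tree$height[i] - tol)
        stop("parent height below child height at node ", i)
      if (!(i %in% tree$children[[p]]))
        stop("inconsistent parent/children links at node ", i)
    }
    if (ndeg[i] == 0L && is.na(tree$taxon[i]))
      stop("leaf node ", i, " carries no taxon")
    if (ndeg[i] == 1L && is.na(tree$taxon[i]))
      stop("degree-2 node ", i, " is not a sampled ancestor (no taxon)")
    if (ndeg[i] > 2L) stop("node ", i, " has more than 2 children")
  }
  labs <- tree$taxon[!is.na(tree$taxon)]
  if (anyDuplicated(labs)) stop("duplicate taxon labels: ",
                                paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (any(!is.finite(tree$height)) || any(tree$height < -tol))
    stop("node heights must be finite and non-negative")
  if (!is.na(tree$origin) && tree$origin <= tree$height[tree$root])
    stop("origin height must exceed root height")
  invisible(tree)
}

is_leaf <- function(tree, i) lengths(tree$children)[i] == 0L
is_sampled_ancestor <- function(tree, i) {
  lengths(tree$children)[i] == 1L & !is.na(tree$taxon[i])
}

#' @export
print.timetree <- function(x, ...) {
  st <- tree_statistics(x)
  cat(sprintf("timetree: %d tips, %d sampled ancestors, root height %.4g%s\n",
              st$n_tips, st$n_sampled_ancestors, st$root_height,
              if (is.na(x$origin)) "" else sprintf(", origin %.4g", x$origin)))
  invisible(x)
}

## node ids in postorder (children before parents)
postorder <- function(tree) {
  out <- integer(0)
  stack <- tree$root
  seen <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, nd)
    stack <- c(stack, tree$children[[nd]])
  }
  rev(seen)
}

#' Summary statistics of a time tree
#'
#' @param tree a `timetree`
#' @return list with `root_height`, `origin_height` (`NA` if unset),
#'   `tree_length` (sum of all edge lengths, excluding the origin stem),
#'   `n_tips`, and `n_sampled_ancestors`
#' @export
tree_statistics <- function(tree) {
  deg <- lengths(tree$children)
  haspar <- tree$parent > 0L
  elen <- tree$height[tree$parent[haspar]] - tree$height[haspar]
  list(root_height = tree$height[tree$root],
       origin_height = tree$origin,
       tree_length = sum(elen),
       n_tips = sum(deg == 0L),
       n_sampled_ancestors = sum(deg == 1L & !is.na(tree$taxon)))
}

#' Taxon table of a tree
#'
#' @param tree a `timetree`
#' @return data.frame with columns `label` and `sampling_time` (= node height)
#' @export
tree_taxa <- function(tree) {
  idx <- which(!is.na(tree$taxon))
  data.frame(label = tree$taxon[idx], sampling_time = tree$height[idx],
             stringsAsFactors = FALSE)
}

## ---- Newick ---------------------------------------------------------------

#' Parse a Newick string into a time tree
#'
#' Heights are computed from branch lengths: the deepest tip gets height 0.
#' In the `sampled_ancestor` dialect a terminal branch of (numerically) zero
#' length attached to a binary node is decoded as a degree-2 sampled-ancestor
#' node, the usual zero-branch interchange convention for such trees.
#'
#' @param text Newick string (must end with `;` or be a bare subtree)
#' @param dialect `"binary"` to keep zero branches as ordinary tips,
#'   `"sampled_ancestor"` to decode them
#' @param zero_tol relative tolerance (fraction of root height) below which a
#'   terminal branch counts as zero
#' @return a `timetree`
#' @export
parse_newick <- function(text, dialect = c("binary", "sampled_ancestor"),
                         zero_tol = 1e-10) {
  dialect <- match.arg(dialect)
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  fail <- function(msg) stop(sprintf("newick parse error at position %d: %s", pos, msg),
                             call. = FALSE)
  ## node accumulator
  labs <- character(0); lens <- numeric(0); pars <- integer(0)
  new_node <- function(par) {
    labs[[length(labs) + 1L]] <<- NA_character_
    lens[[length(lens) + 1L]] <<- 0
    pars[[length(pars) + 1L]] <<- par
    length(labs)
  }
  read_label <- function() {
    start <- pos
    while (pos <= n && !(peek() %in% c(",", ")", "(", ":", ";"))) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_clade <- function(par) {
    me <- new_node(par)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        read_clade(me)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    lab <- read_label()
    if (nzchar(lab)) labs[[me]] <<- lab
    if (peek() == ":") {
      pos <<- pos + 1L
      numstr <- ""
      while (pos <= n && grepl("[0-9eE+.\\-]", peek())) {
        numstr <- paste0(numstr, peek()); pos <<- pos + 1L
      }
      bl <- suppressWarnings(as.numeric(numstr))
      if (is.na(bl)) fail("bad branch length")
      if (bl < 0) stop("negative branch length in newick input", call. = FALSE)
      lens[[me]] <<- bl
    }
    me
  }
  if (peek() == "") fail("empty input")
  root <- read_clade(0L)
  if (peek() == ";") pos <- pos + 1L
  if (pos <= n) fail("trailing characters")
  m <- length(labs)
  ## depths from root (parents are created before children), then heights
  depth <- numeric(m)
  for (i in seq_len(m)) {
    depth[i] <- if (pars[i] == 0L) 0 else depth[pars[i]] + lens[i]
  }
  nch <- tabulate(pars[pars > 0L], nbins = m)
  if (any(nch > 2L)) stop("polytomy in newick input; only binary trees supported",
                          call. = FALSE)
  leaves <- which(nch == 0L)
  if (any(is.na(labs[leaves]))) fail("unlabeled leaf")
  height <- max(depth[leaves]) - depth
  tr <- timetree(pars, height, labs)
  if (dialect == "sampled_ancestor") tr <- decode_sampled_ancestors(tr, zero_tol)
  tr
}

## zero-length pendant tips attached to a binary node become degree-2 SA nodes
decode_sampled_ancestors <- function(tree, zero_tol = 1e-10) {
  rooth <- tree$height[tree$root]
  tol <- max(zero_tol * max(rooth, 1), 1e-300)
  repeat {
    deg <- lengths(tree$children)
    hit <- 0L
    for (i in seq_along(tree$parent)) {
      p <- tree$parent[i]
      if (deg[i] == 0L && p > 0L && deg[p] == 2L && is.na(tree$taxon[p]) &&
          (tree$height[p] - tree$height[i]) <= tol) { hit <- i; break }
    }
    if (hit == 0L) return(tree)
    p <- tree$parent[hit]
    ## parent p becomes the sampled-ancestor node carrying hit's taxon
    tree$taxon[p] <- tree$taxon[hit]
    tree$children[[p]] <- setdiff(tree$children[[p]], hit)
    tree <- drop_nodes(tree, hit)
  }
}

## remove nodes (must be unlinked leaves of the structure) and renumber
drop_nodes <- function(tree, drop) {
  keep <- setdiff(seq_along(tree$parent), drop)
  map <- integer(length(tree$parent)); map[keep] <- seq_along(keep)
  par <- tree$parent[keep]
  par[par > 0L] <- map[par[par > 0L]]
  timetree(par, tree$height[keep], tree$taxon[keep], tree$origin)
}

#' Serialize a time tree to Newick
#'
#' Sampled-ancestor nodes are emitted as zero-length terminal branches
#' attached at the ancestor's height, so that
#' `parse_newick(write_newick(t), "sampled_ancestor")` round-trips.
#'
#' @param tree a `timetree`
#' @param digits significant digits for branch lengths
#' @return Newick string terminated by `;`
#' @export
write_newick <- function(tree, digits = 12) {
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(i) {
    ch <- tree$children[[i]]
    lab <- if (is.na(tree$taxon[i])) "" else tree$taxon[i]
    if (length(ch) == 0L) return(lab)
    inner <- vapply(ch, function(j) {
      paste0(rec(j), ":", fmt(tree$height[i] - tree$height[j]))
    }, character(1))
    if (length(ch) == 1L) inner <- c(inner, paste0(lab, ":0"))  # SA as zero tip
    paste0("(", paste(inner, collapse = ","), ")",
           if (length(ch) == 2L) lab else "")
  }
  paste0(rec(tree$root), ";")
}

#' Write a BEAST-style NEXUS tree log
#'
#' One tree per sampled state, with a `Translate` block mapping integer
#' indices to taxon labels.
#'
#' @param trees list of `timetree` objects sharing a taxon set
#' @param path output file
#' @param states integer state indices (defaults to 0, 1, ...)
#' @export
write_nexus_trees <- function(trees, path, states = seq_along(trees) - 1L) {
  taxa <- sort(tree_taxa(trees[[1]])$label)
  idx <- stats::setNames(seq_along(taxa), taxa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "Begin trees;", "\tTranslate"), con)
  writeLines(paste0("\t\t", idx, " ", taxa,
                    ifelse(seq_along(taxa) < length(taxa), ",", "")), con)
  writeLines("\t\t;", con)
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    tr$taxon <- ifelse(is.na(tr$taxon), NA, as.character(idx[tr$taxon]))
    writeLines(sprintf("tree STATE_%d = %s", states[k], write_newick(tr)), con)
  }
  writeLines("End;", con)
  invisible(path)
}

#' Read a NEXUS tree log written by [write_nexus_trees()]
#'
#' @param path file path
#' @param dialect passed to [parse_newick()]
#' @return list of `timetree` objects
#' @export
read_nexus_trees <- function(path, dialect = "sampled_ancestor") {
  ln <- readLines(path)
  tl <- grep("^\t\t[0-9]+ ", ln, value = TRUE)
  tl <- sub(",$", "", trimws(tl))
  idx <- strsplit(tl, " ")
  lab <- stats::setNames(vapply(idx, `[`, "", 2), vapply(idx, `[`, "", 1))
  out <- list()
  for (s in grep("^tree ", ln, value = TRUE)) {
    nwk <- sub("^tree [^=]*= *", "", s)
    tr <- parse_newick(nwk, dialect)
    tr$taxon <- ifelse(is.na(tr$taxon), NA, unname(lab[tr$taxon]))
    out[[length(out) + 1L]] <- tr
  }
  out
}

## deep structural copy with renumbering is never needed (R copies on write);
## isomorphism check used by tests and round-trip contracts
#' Test whether two time trees are the same tree
#'
#' Compares the labeled shapes (clades identified by taxon sets, including
#' sampled-ancestor attachment) and node heights to a relative tolerance.
#'
#' @param a,b `timetree` objects
#' @param tol relative height tolerance
#' @return logical
#' @export
trees_isomorphic <- function(a, b, tol = 1e-9) {
  sig <- function(tree) {
    keys <- character(0); hts <- numeric(0)
    rec <- function(i) {
      ch <- tree$children[[i]]
      labs <- unlist(lapply(ch, rec))
      if (!is.na(tree$taxon[i])) labs <- c(labs, tree$taxon[i])
      labs <- sort(labs)
      keys[[length(keys) + 1L]] <<-
        paste0(paste(labs, collapse = ","), "#", length(ch),
               if (!is.na(tree$taxon[i])) paste0("!", tree$taxon[i]) else "")
      hts[[length(hts) + 1L]] <<- tree$height[i]
      labs
    }
    rec(tree$root)
    ord <- order(keys)
    list(keys = keys[ord], heights = hts[ord])
  }
  sa <- sig(a); sb <- sig(b)
  if (length(sa$keys) != length(sb$keys) || any(sa$keys != sb$keys)) return(FALSE)
  scale <- max(abs(a$height), 1)
  all(abs(sa$heights - sb$heights) <= tol * scale)
}
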