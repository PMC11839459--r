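#' Read a rooted somatic phylogeny from Newick text
#'
#' Branch lengths are interpreted as mutation counts (molecular time). The
#' tree must be rooted, have named tips, and carry a branch length on every
#' non-root edge.
#'
#' @param newick a Newick string, or the path of a file containing one.
#' @return an [ape::phylo] tree (internal nodes without labels are given
#'   stable labels `Node<k>`).
#' @export
#' @examples
#' tr <- read_phylogeny("((S1:10,S2:10)N2:10,(S3:10,S4:10)N3:10)R;")
read_phylogeny <- function(newick) {
  txt <- newick
  if (length(txt) == 1 && !grepl(";", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick string")
  if (is.null(tr$edge.length)) stop("Newick must carry branch lengths")
  if (anyNA(tr$edge.length)) stop("every non-root edge needs a branch length")
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  blank <- !nzchar(tr$node.label)
  tr$node.label[blank] <- paste0("Node", which(blank))
  if (anyDuplicated(c(tr$tip.label, tr$node.label)))
    stop("duplicate node labels")
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_phylogeny <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Internal flat index of a phylo object: parent/child arrays, per-node branch
# length, molecular time from root, tips under each node.  Node numbering is
# ape's (tips 1..n, internals n+1..).  Root has parent 0 and branch length 0.
tree_index <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  blen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  ord <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2])  # root-to-tip
  time <- numeric(nn)
  for (v in ord) time[v] <- time[parent[v]] + blen[v]
  tips_under <- vector("list", nn)
  for (v in seq_len(n)) tips_under[[v]] <- v
  for (v in rev(ord)) {
    if (v > n) tips_under[[v]] <- sort(unlist(children[[v]] |> lapply(\(c) tips_under[[c]])))
  }
  tips_under[[root]] <- seq_len(n)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) paste0("Node", seq_len(tree$Nnode))
              else tree$node.label)
  list(tree = tree, n = n, nn = nn, root = root, parent = parent,
       children = children, blen = blen, time = time,
       tips_under = tips_under, labels = labels)
}

# Resolve a node given as label or integer index to the ape integer index.
resolve_node <- function(idx, node) {
  if (is.character(node)) {
    i <- match(node, idx$labels)
    if (anyNA(i)) stop("unknown node(s): ", paste(node[is.na(i)], collapse = ", "))
    return(i)
  }
  node <- as.integer(node)
  if (any(node < 1 | node > idx$nn)) stop("node index out of range")
  node
}

as_index <- function(tree) if (inherits(tree, "phylo")) tree_index(tree) else tree

#' Molecular time of a node
#'
#' Sum of branch lengths (mutations) from the root to `node`.
#'
#' @param tree an `ape::phylo` tree (or an internal tree index).
#' @param node node label(s) or integer index(es); the root has time 0.
#' @return numeric vector of molecular times.
#' @export
molecular_time <- function(tree, node) {
  idx <- as_index(tree)
  idx$time[resolve_node(idx, node)]
}

#' Tips descending from a node
#'
#' @inheritParams molecular_time
#' @return character vector of sample ids (tip labels) in the node's clade.
#' @export
clade_tips <- function(tree, node) {
  idx <- as_index(tree)
  v <- resolve_node(idx, node)
  stopifnot(length(v) == 1)
  idx$labels[idx$tips_under[[v]]]
}

#' Is node `a` within the clade of node `b`?
#'
#' `a` is within `b` if `b` lies on the path from `a` to the root
#' (a node is within its own clade).
#'
#' @inheritParams molecular_time
#' @param a,b node labels or integer indexes.
#' @return logical flag.
#' @export
is_within <- function(tree, a, b) {
  idx <- as_index(tree)
  a <- resolve_node(idx, a); b <- resolve_node(idx, b)
  stopifnot(length(a) == 1, length(b) == 1)
  v <- a
  repeat {
    if (v == b) return(TRUE)
    if (v == idx$root) return(FALSE)
    v <- idx$parent[v]
  }
}

#' Most recent common ancestor of a set of nodes
#'
#' @inheritParams molecular_time
#' @param nodes vector of node labels or integer indexes; the MRCA of a
#'   single node is the node itself.
#' @return the MRCA's label.
#' @export
mrca_node <- function(tree, nodes) {
  idx <- as_index(tree)
  v <- resolve_node(idx, nodes)
  anc <- function(x) { # path to root, inclusive
    out <- x
    while (x != idx$root) { x <- idx$parent[x]; out <- c(out, x) }
    out
  }
  common <- Reduce(intersect, lapply(v, anc))
  idx$labels[common[1]]
}

#' Maximum-likelihood assignment of a variant to a branch
#'
#' Scores every branch of the tree (each branch is identified by its child
#' node; the root stands for the stem branch whose clade is all tips) with a
#' binomial likelihood: carrier tips inside the candidate clade have success
#' probability `het_vaf`, tips outside have `error_rate`. Ties are broken
#' toward the branch with the smallest clade, then lexicographically by node
#' label. The reported p-value is the probability of the observed read counts
#' under the winning assignment.
#'
#' @param tree an `ape::phylo` tree or index.
#' @param mtr,dep named integer vectors of variant reads and total depth per
#'   sample; names must cover all tips.
#' @param config a [pipeline_config()].
#' @return list with `branch` (node label), `node` (integer index),
#'   `loglik`, `pval`, and the full per-branch log-likelihood vector.
#' @export
assign_branch <- function(tree, mtr, dep, config = pipeline_config()) {
  idx <- as_index(tree)
  tips <- idx$labels[seq_len(idx$n)]
  if (!all(tips %in% names(mtr)) || !all(tips %in% names(dep)))
    stop("mtr/dep must be named and cover all tips")
  mtr <- as.numeric(mtr[tips]); dep <- as.numeric(dep[tips])
  if (any(mtr > dep)) stop("variant reads exceed depth")
  if (all(dep == 0)) stop("zero depth in every sample: no information")
  ll_in <- dbinom(mtr, dep, config$het_vaf, log = TRUE)
  ll_out <- dbinom(mtr, dep, config$error_rate, log = TRUE)
  base <- sum(ll_out)
  gain <- ll_in - ll_out
  ll <- vapply(seq_len(idx$nn),
               function(v) base + sum(gain[idx$tips_under[[v]]]),
               numeric(1))
  best <- which(ll >= max(ll) - 1e-9)
  if (length(best) > 1) {
    sz <- lengths(idx$tips_under)[best]
    best <- best[sz == min(sz)]
    if (length(best) > 1) best <- best[order(idx$labels[best])][1]
  }
  best <- best[1]
  list(branch = idx$labels[best], node = best,
       loglik = ll[best], pval = exp(ll[best]),
       loglik_all = setNames(ll, idx$labels))
}

#' Count post-development coalescences
#'
#' Number of internal nodes (excluding the root) whose molecular time is at
#' least the developmental cutoff (default 50 mutations) -- the denominator
#' of per-node MAV rates.
#'
#' @inheritParams assign_branch
#' @param include_root count the root as a coalescence (default `FALSE`).
#' @return integer count.
#' @export
count_post_development_nodes <- function(tree, config = pipeline_config(),
                                         include_root = FALSE) {
  idx <- as_index(tree)
  internal <- setdiff((idx$n + 1L):idx$nn, if (include_root) integer(0) else idx$root)
  sum(idx$time[internal] >= config$development_cutoff)
}
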