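# Shared fixture trees (branch lengths are mutation counts).
TREE_A_NWK <- "((S1:10,S2:10)N2:10,(S3:10,S4:10)N3:10)R;"
TREE_B_NWK <- "(((S1:5,S2:5)N3:5,S3:5)N2:5,S4:5)R;"
TREE_C_NWK <- "((S1:10,(S2:10,(S3:10,S4:10)N4:10)N3:10)N2:10,S5:10)R;"

tree_a <- function() read_phylogeny(TREE_A_NWK)
tree_b <- function() read_phylogeny(TREE_B_NWK)
tree_c <- function() read_phylogeny(TREE_C_NWK)

# Named read-count vectors for a set of positive tips on a tree.
counts_for <- function(tree, positive, dep = 30, mtr = 15) {
  tips <- tree$tip.label
  m <- setNames(rep(0, length(tips)), tips)
  m[positive] <- mtr
  list(mtr = m, dep = setNames(rep(dep, length(tips)), tips))
}

# Random coalescent-ish fixture trees with <= 12 tips for oracle sweeps.
random_small_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) sample(1:20, n, replace = TRUE))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}
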