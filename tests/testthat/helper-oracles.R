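# Independent brute-force oracles.  These re-derive tree relations directly
# from the ape edge matrix and never call the package's internal index.

oracle_parent <- function(tree, node_label) {
  labs <- c(tree$tip.label, tree$node.label)
  v <- match(node_label, labs)
  e <- tree$edge[tree$edge[, 2] == v, 1]
  if (!length(e)) NA_character_ else labs[e]
}

oracle_tips_under <- function(tree, node_label) {
  labs <- c(tree$tip.label, tree$node.label)
  v <- match(node_label, labs)
  n <- length(tree$tip.label)
  acc <- c()
  stack <- v
  while (length(stack)) {
    x <- stack[1]; stack <- stack[-1]
    if (x <= n) acc <- c(acc, x)
    stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
  }
  sort(labs[acc])
}

oracle_ancestors <- function(tree, node_label) {
  labs <- c(tree$tip.label, tree$node.label)
  v <- match(node_label, labs)
  out <- c()
  repeat {
    e <- tree$edge[tree$edge[, 2] == v, 1]
    if (!length(e)) break
    out <- c(out, e); v <- e
  }
  labs[out]
}

# Exhaustive per-branch binomial likelihood scan (candidates: every node,
# the root standing for the stem).
oracle_assign_branch <- function(tree, mtr, dep, het = 0.5, eps = 1e-6) {
  labs <- c(tree$tip.label, tree$node.label)
  best <- NULL; best_ll <- -Inf; best_size <- Inf
  for (lab in labs) {
    inside <- tree$tip.label %in% oracle_tips_under(tree, lab)
    p <- ifelse(inside, het, eps)
    ll <- sum(dbinom(mtr[tree$tip.label], dep[tree$tip.label], p, log = TRUE))
    size <- sum(inside)
    if (ll > best_ll + 1e-9 ||
        (abs(ll - best_ll) <= 1e-9 &&
         (size < best_size || (size == best_size && lab < best)))) {
      best <- lab; best_ll <- ll; best_size <- size
    }
  }
  list(branch = best, loglik = best_ll)
}

# Oracle lesion-path walk on noise-free genotypes (alt1 = clade(b1),
# alt2 = clade(b2), ref elsewhere): descend through the unique child whose
# subtree census holds >= 2 alleles, recording uniform subclades, and count
# reference-only subclades shed between the first and last mutant subclades.
oracle_intervening_refs <- function(tree, b1, b2, lesion) {
  labs <- c(tree$tip.label, tree$node.label)
  g <- setNames(rep("ref", length(tree$tip.label)), tree$tip.label)
  g[oracle_tips_under(tree, b1)] <- "alt1"
  g[oracle_tips_under(tree, b2)] <- "alt2"
  census <- function(l) unique(g[intersect(oracle_tips_under(tree, l),
                                           tree$tip.label)])
  v <- lesion; depth <- 0L
  rec <- data.frame(allele = character(0), depth = integer(0))
  repeat {
    depth <- depth + 1L
    kids <- labs[tree$edge[tree$edge[, 1] == match(v, labs), 2]]
    if (!length(kids)) break
    sizes <- vapply(kids, function(k) length(census(k)), numeric(1))
    for (k in kids[sizes == 1]) {
      rec <- rbind(rec, data.frame(allele = census(k), depth = depth))
    }
    mixed <- kids[sizes >= 2]
    if (length(mixed) != 1) break
    v <- mixed
  }
  alt_d <- rec$depth[rec$allele != "ref"]
  if (length(alt_d) < 2) return(0L)
  sum(rec$allele == "ref" & rec$depth >= min(alt_d) & rec$depth <= max(alt_d))
}

# MAV category from adjacency relations directly; set `reclassify = TRUE` to
# apply the >= 2-intervening-reference-subclade demotion via the census walk.
oracle_classify_mav <- function(tree, b1, b2, reclassify = FALSE) {
  if (b1 == b2) return("unrelated")
  root <- c(tree$tip.label, tree$node.label)[setdiff(tree$edge[, 1], tree$edge[, 2])]
  if (b1 == root || b2 == root) return("unrelated")
  p1 <- oracle_parent(tree, b1); p2 <- oracle_parent(tree, b2)
  if (identical(p1, p2)) return("simple")
  a1 <- c(b1, oracle_ancestors(tree, b1)); a2 <- c(b2, oracle_ancestors(tree, b2))
  if (b1 %in% a2 || b2 %in% a1) return("unrelated")
  lesion <- if (p2 %in% a1 && p1 %in% a2) {
    if (p1 %in% c(p2, oracle_ancestors(tree, p2))) p2 else p1
  } else if (p2 %in% a1) p2 else if (p1 %in% a2) p1 else NA
  if (is.na(lesion)) return("unrelated")
  if (reclassify && oracle_intervening_refs(tree, b1, b2, lesion) >= 2)
    return("unrelated")
  "separated"
}

# Dense 2-D grid scan for the ML beta-binomial rho: coarse log-spaced pass,
# then a fine linear pass around the coarse optimum.
oracle_rho_scan <- function(k, n, p_grid = seq(0.001, 0.999, length.out = 400)) {
  ll_bb <- function(p, rho) {
    a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
    sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  scan <- function(rho_grid) {
    lls <- vapply(rho_grid, function(r)
      max(vapply(p_grid, function(p) ll_bb(p, r), numeric(1))), numeric(1))
    rho_grid[which.max(lls)]
  }
  coarse <- exp(seq(log(1e-6), log(0.89), length.out = 120))
  r1 <- scan(coarse)
  i <- which(coarse == r1)
  lo <- coarse[max(1, i - 1)]; hi <- coarse[min(length(coarse), i + 1)]
  scan(seq(lo, hi, length.out = 80))
}

# Exact category distribution of length-weighted unordered distinct branch
# pairs: P(i, j) proportional to l_i * l_j.
oracle_enumerate_pairs <- function(tree) {
  labs <- c(tree$tip.label, tree$node.label)
  root <- labs[setdiff(tree$edge[, 1], tree$edge[, 2])]
  branches <- labs[tree$edge[, 2]]
  len <- setNames(tree$edge.length, branches)
  out <- c(simple = 0, separated = 0, unrelated = 0)
  tot <- 0
  for (a in seq_along(branches)) {
    for (b in seq_along(branches)) {
      if (b <= a) next
      w <- len[a] * len[b]
      if (w == 0) next
      cat3 <- oracle_classify_mav(tree, branches[a], branches[b],
                                  reclassify = TRUE)
      out[cat3] <- out[cat3] + w
      tot <- tot + w
    }
  }
  out / tot
}

# Exhaustive subtree allele census used to verify lesion-path walks.
oracle_subtree_alleles <- function(tree, node_label, genotypes) {
  tips <- oracle_tips_under(tree, node_label)
  unique(genotypes[tips][genotypes[tips] != "unknown"])
}
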