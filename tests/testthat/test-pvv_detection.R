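test_that("fit_beta_binomial_rho matches the worked examples and a grid-scan oracle", {
  # no dispersion: all-zero counts sit at the lower boundary
  expect_lt(fit_beta_binomial_rho(rep(0, 10), rep(30, 10))$rho, 0.01)
  # half 15/30, half 0/30: strong overdispersion
  expect_gte(fit_beta_binomial_rho(c(rep(15, 10), rep(0, 10)), rep(30, 20))$rho, 0.1)
  # seeded binomial draws: low rho
  set.seed(11)
  expect_lt(fit_beta_binomial_rho(rbinom(20, 30, 0.5), rep(30, 20))$rho, 0.1)
  expect_error(fit_beta_binomial_rho(0, 30), ">= 2 samples")

  # oracle: dense 2-D scan on 50 random small inputs, |rho - oracle| < 0.01
  set.seed(99)
  for (r in 1:50) {
    ns <- sample(4:12, 1)
    dep <- rpois(ns, 30) + 1L
    p_true <- runif(1, 0.05, 0.6)
    mix <- runif(1) < 0.5
    mtr <- if (mix) ifelse(runif(ns) < 0.5, rbinom(ns, dep, p_true), 0)
    else rbinom(ns, dep, p_true)
    fit <- fit_beta_binomial_rho(mtr, dep)
    want <- oracle_rho_scan(mtr, dep)
    expect_lt(abs(fit$rho - want), 0.01, label = paste("case", r))
  }
})

test_that("subclade genotyping applies the pooled thresholds", {
  tr <- tree_a()
  cnt <- counts_for(tr, c("S1", "S2"))
  expect_equal(subclade_genotype(tr, "N2", cnt$mtr, cnt$dep)$label, "positive")
  expect_equal(subclade_genotype(tr, "N3", cnt$mtr, cnt$dep)$label, "negative")
  expect_equal(subclade_genotype(tr, "R", cnt$mtr, cnt$dep)$label, "mixed")
  # low depth is indeterminate, not negative
  dep_low <- setNames(rep(4, 4), tr$tip.label)
  mtr0 <- setNames(rep(0, 4), tr$tip.label)
  expect_equal(subclade_genotype(tr, "S3", mtr0, dep_low)$label, "indeterminate")
  # pooled low-depth negatives become negative at adequate pooled depth
  expect_equal(subclade_genotype(tr, "N3", mtr0, dep_low)$label, "indeterminate")
  dep7 <- setNames(rep(7, 4), tr$tip.label)
  expect_equal(subclade_genotype(tr, "N3", mtr0, dep7)$label, "negative")
})

test_that("screen_pvv_candidate flags TREE-C and rejects clean or terminal variants", {
  tr <- tree_c()
  cnt <- counts_for(tr, c("S1", "S3", "S4"))
  a <- assign_branch(tr, cnt$mtr, cnt$dep)
  sc <- screen_pvv_candidate(tr, cnt$mtr, cnt$dep, a$branch)
  expect_true(sc$candidate)
  expect_gte(sc$rho_within, 0.1)
  expect_match(sc$reason, "within-clade")

  # clean clade variant is not a candidate
  cnt2 <- counts_for(tr, c("S3", "S4"))
  a2 <- assign_branch(tr, cnt2$mtr, cnt2$dep)
  expect_equal(a2$branch, "N4")
  expect_false(screen_pvv_candidate(tr, cnt2$mtr, cnt2$dep, a2$branch)$candidate)

  # terminal-branch variants are excluded regardless of counts
  cnt3 <- counts_for(tr, "S5")
  sc3 <- screen_pvv_candidate(tr, cnt3$mtr, cnt3$dep, "S5")
  expect_false(sc3$candidate)
  expect_equal(sc3$reason, "terminal branch")
})

test_that("find_lesion_node returns the minimal covering ancestor", {
  tr <- tree_c()
  cnt <- counts_for(tr, c("S1", "S3", "S4"))
  expect_equal(find_lesion_node(tr, cnt$mtr, cnt$dep, "N2")$lesion_node, "N2")
  # positives {S2,S3,S4} assigned at N4 -> N3 (exhaustive covering check)
  cnt2 <- counts_for(tr, c("S2", "S3", "S4"))
  got <- find_lesion_node(tr, cnt2$mtr, cnt2$dep, "N4")$lesion_node
  expect_equal(got, "N3")
  labs <- c(tr$tip.label, tr$node.label)
  covering <- labs[vapply(labs, function(l)
    all(c("S2", "S3", "S4") %in% oracle_tips_under(tr, l)), logical(1))]
  sizes <- vapply(covering, function(l) length(oracle_tips_under(tr, l)), numeric(1))
  expect_equal(got, covering[which.min(sizes)])
})

test_that("walk_lesion_path passes TREE-C and fails interleaved or suffix patterns", {
  tr <- tree_c()
  cnt <- counts_for(tr, c("S1", "S3", "S4"))
  w <- walk_lesion_path(tr, cnt$mtr, cnt$dep, "N2")
  expect_equal(w$status, "pass")
  expect_equal(w$path, c("N2", "N3"))
  expect_equal(w$repair_node, "N3")
  expect_equal(w$mmld, 10)
  expect_equal(w$subclades$label, c("positive", "negative", "positive"))
  expect_equal(pvv_mmld(w, tr), 10)

  # census oracle: every path node's subtree holds both genotype states
  g <- setNames(ifelse(tr$tip.label %in% c("S1", "S3", "S4"), "alt1", "ref"),
                tr$tip.label)
  for (nd in w$path) {
    expect_gte(length(oracle_subtree_alleles(tr, nd, g)), 2)
  }

  # mutation + loss pattern (positives {S1,S2}): screened, but the walk
  # records positive, positive, negative and does not pass
  cnt2 <- counts_for(tr, c("S1", "S2"))
  a2 <- assign_branch(tr, cnt2$mtr, cnt2$dep)
  w2 <- walk_lesion_path(tr, cnt2$mtr, cnt2$dep, "N2")
  expect_equal(w2$subclades$label, c("positive", "positive", "negative"))
  expect_equal(w2$status, "fail")

  # both children of the lesion node mixed -> fail
  tr2 <- read_phylogeny(
    "(((S1:10,S2:10)N3:10,(S3:10,S4:10)N4:10)N2:10,S5:10)R;")
  cnt3 <- counts_for(tr2, c("S1", "S3"))
  w3 <- walk_lesion_path(tr2, cnt3$mtr, cnt3$dep, "N2")
  expect_equal(w3$status, "fail")

  # positives before all negatives (mutation + loss pattern): no pass
  trc <- read_phylogeny(
    "((S1:10,(S2:10,(S3:10,S4:10)N4:10)N3:10)N2:10,S5:10)R;")
  cnt4 <- counts_for(trc, c("S1", "S2"))
  w4 <- walk_lesion_path(trc, cnt4$mtr, cnt4$dep, "N2")
  expect_false(identical(w4$status, "pass"))

  expect_error(pvv_mmld(w3, tr2), "pass calls only")
})

test_that("pvv_mmld sums branch lengths between lesion and repair nodes", {
  # two-branch path with lengths 12 and 9 -> 21 (the published median scale)
  tr <- read_phylogeny(
    "((S1:10,(S2:10,(S3:10,S4:10)N4:9)N3:12)N2:10,S5:10)R;")
  cnt <- counts_for(tr, c("S1", "S3", "S4"))
  w <- walk_lesion_path(tr, cnt$mtr, cnt$dep, "N2")
  expect_equal(w$status, "pass")
  expect_equal(pvv_mmld(w, tr), 12)
  # the full lesion-node to deepest-mutant-node span: N2 -> N4 over 12 + 9
  expect_equal(molecular_time(tr, "N4") - molecular_time(tr, "N2"), 21)
})

test_that("detect_pvv recovers implanted lesions end to end", {
  hits <- 0L; n_rep <- 10L
  for (seed in seq_len(n_rep)) {
    tre <- generate_genealogy(16, age = 75, seed = seed + 40)
    sm <- sprinkle_mutations(tre, 15, seed = seed)
    les <- tryCatch(implant_persistent_lesion(tre, "pvv", seed = seed),
                    error = function(e) NULL)
    if (is.null(les)) next
    cnt <- emit_read_counts(les$carriers, 30, seed = seed)
    vcm <- variant_call_matrix(les$variants, cnt$mtr, cnt$dep, sm$tree_mut)
    res <- detect_pvv(sm$tree_mut, vcm)
    want_mmld <- molecular_time(sm$tree_mut, les$truth$repair_node) -
      molecular_time(sm$tree_mut, les$truth$lesion_node)
    if (res$status[1] == "pass" && res$lesion_node[1] == les$truth$lesion_node &&
        res$mmld[1] == want_mmld) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("screening rate on lesion-free data stays below 1/200", {
  tre <- generate_genealogy(20, age = 20, seed = 77)
  sm <- sprinkle_mutations(tre, 15, seed = 78)
  idx <- lesionphylo:::tree_index(sm$tree_mut)
  internal_labels <- sm$tree_mut$node.label
  keep <- sm$truth$branch %in% internal_labels
  v <- sm$variants[keep, , drop = FALSE]
  branches <- sm$truth$branch[keep]
  tips <- sm$tree_mut$tip.label
  carriers <- t(vapply(branches, function(b) tips %in% clade_tips(idx, b),
                       logical(length(tips))))
  cnt <- emit_read_counts(carriers, 30, seed = 79)
  colnames(cnt$mtr) <- colnames(cnt$dep) <- tips
  n_cand <- 0L
  for (i in seq_len(nrow(v))) {
    a <- assign_branch(idx, cnt$mtr[i, ], cnt$dep[i, ])
    if (a$node <= idx$n) next
    sc <- screen_pvv_candidate(idx, cnt$mtr[i, ], cnt$dep[i, ], a$branch)
    if (sc$candidate) n_cand <- n_cand + 1L
  }
  expect_lt(n_cand / nrow(v), 1 / 200)
})
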