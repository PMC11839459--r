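#' Null-simulation configuration
#'
#' Defaults follow the published calibration: 50,000 branch-pair draws for
#' the MAV null, 10,000 full-pipeline independent-mutation replicates and
#' 2,000 somatic-reversion replicates per phylogeny, with per-sample depths
#' drawn Poisson at the cohort mean depth (~30x) and non-carriers at the
#' error distribution.
#'
#' @param reps_mav,reps_pvv,reps_reversion replicate counts.
#' @param mean_depth Poisson mean sequencing depth.
#' @param error_rate per-read error probability.
#' @param seed integer seed.
#' @return a named list of class `lp_nullsim_config`.
#' @export
null_sim_config <- function(reps_mav = 50000, reps_pvv = 10000,
                            reps_reversion = 2000, mean_depth = 30,
                            error_rate = 1e-6, seed = 1L) {
  stopifnot(reps_mav > 0, reps_pvv > 0, reps_reversion > 0, mean_depth > 0)
  structure(list(reps_mav = reps_mav, reps_pvv = reps_pvv,
                 reps_reversion = reps_reversion, mean_depth = mean_depth,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "lp_nullsim_config")
}

# Draw n unordered distinct branch pairs with P(i,j) proportional to
# l_i * l_j: two i.i.d. length-weighted draws, rejecting equal pairs.
draw_branch_pairs <- function(len, n) {
  stopifnot(sum(len > 0) >= 2)
  i <- sample.int(length(len), n, replace = TRUE, prob = len)
  j <- sample.int(length(len), n, replace = TRUE, prob = len)
  bad <- which(i == j)
  while (length(bad)) {
    i[bad] <- sample.int(length(len), length(bad), replace = TRUE, prob = len)
    j[bad] <- sample.int(length(len), length(bad), replace = TRUE, prob = len)
    bad <- bad[i[bad] == j[bad]]
  }
  cbind(pmin(i, j), pmax(i, j))
}

#' MAV null model: random length-weighted branch pairs
#'
#' Draws `n` unordered pairs of distinct branches with probability
#' proportional to branch length and classifies each pair with
#' [classify_mav()] (including the reclassification of separated pairs with
#' two or more intervening reference subclades), estimating the expected
#' category proportions when MAVs arise from two independent mutations.
#'
#' @param tree phylogeny.
#' @param n number of draws (default 50,000).
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @return list: `proportions` over simple/separated/unrelated, `counts`,
#'   `n`.
#' @export
sample_branch_pairs <- function(tree, n = 50000, seed = 1L,
                                config = pipeline_config()) {
  if (n <= 0) stop("n must be positive")
  idx <- as_index(tree)
  len <- idx$blen
  len[idx$root] <- 0                 # the stem is not a drawable branch
  set.seed(seed)
  pr <- draw_branch_pairs(len, n)
  key <- paste(pr[, 1], pr[, 2])
  tab <- table(key)
  uniq <- do.call(rbind, strsplit(names(tab), " "))
  cat3 <- vapply(seq_len(nrow(uniq)), function(r) {
    classify_mav(idx, as.integer(uniq[r, 1]), as.integer(uniq[r, 2]),
                 config = config)$category
  }, character(1))
  counts <- c(simple = 0, separated = 0, unrelated = 0)
  for (cc in c("simple", "separated", "unrelated"))
    counts[cc] <- sum(as.integer(tab)[cat3 == cc])
  list(proportions = counts / n, counts = counts, n = n)
}

# Observation model shared by the null simulations: Poisson depth, binomial
# variant reads at 0.5 for carriers and at the error rate otherwise.
simulate_counts <- function(carrier, mean_depth, error_rate, het_vaf = 0.5) {
  dep <- rpois(length(carrier), mean_depth)
  p <- ifelse(carrier, het_vaf, error_rate)
  mtr <- rbinom(length(carrier), dep, p)
  list(mtr = setNames(mtr, names(carrier)), dep = setNames(dep, names(carrier)))
}

run_null_pipeline <- function(idx, carrier, cfg, config) {
  cnt <- simulate_counts(carrier, cfg$mean_depth, cfg$error_rate, config$het_vaf)
  if (all(cnt$dep == 0) || all(cnt$mtr == 0))
    return(list(category = "not_detected", mmld = NA_real_))
  a <- assign_branch(idx, cnt$mtr, cnt$dep, config)
  if (a$node <= idx$n)
    return(list(category = "terminal", mmld = NA_real_))
  sc <- screen_pvv_candidate(idx, cnt$mtr, cnt$dep, a$branch, config)
  if (!sc$candidate)
    return(list(category = "not_detected", mmld = NA_real_))
  ln <- find_lesion_node(idx, cnt$mtr, cnt$dep, a$branch, config)
  call <- walk_lesion_path(idx, cnt$mtr, cnt$dep, ln$lesion_node, config)
  if (identical(call$status, "pass"))
    list(category = "pass", mmld = call$mmld)
  else list(category = "fail", mmld = NA_real_)
}

#' PVV null model: two independent co-occurring mutations
#'
#' Per replicate, two distinct branches are drawn length-weighted; every tip
#' inside either clade is a carrier; per-sample depths are Poisson draws at
#' the mean depth with binomial variant reads (0.5 for carriers, the error
#' rate otherwise); the full assignment / overdispersion screen / lesion
#' walk pipeline is applied and the outcome recorded.
#'
#' @param tree phylogeny.
#' @param cfg a [null_sim_config()]; `cfg$reps_pvv` replicates are run.
#' @param config a [pipeline_config()].
#' @return data.frame: rep, branch ids, category
#'   (`terminal`/`not_detected`/`fail`/`pass`), mmld.
#' @export
simulate_independent_pvv <- function(tree, cfg = null_sim_config(),
                                     config = pipeline_config()) {
  idx <- as_index(tree)
  len <- idx$blen; len[idx$root] <- 0
  set.seed(cfg$seed)
  pr <- draw_branch_pairs(len, cfg$reps_pvv)
  tips <- idx$labels[seq_len(idx$n)]
  out <- vector("list", cfg$reps_pvv)
  for (r in seq_len(cfg$reps_pvv)) {
    carrier <- setNames(logical(idx$n), tips)
    carrier[c(idx$tips_under[[pr[r, 1]]], idx$tips_under[[pr[r, 2]]])] <- TRUE
    res <- run_null_pipeline(idx, carrier, cfg, config)
    out[[r]] <- data.frame(rep = r, branch1 = idx$labels[pr[r, 1]],
                           branch2 = idx$labels[pr[r, 2]],
                           category = res$category, mmld = res$mmld,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' PVV null model: somatic reversion
#'
#' Per replicate, a mutation branch is drawn with probability proportional to
#' its branch length times the summed branch length within its clade, and a
#' reversion branch is drawn length-weighted from the branches strictly
#' within that clade; carriers are the mutation clade minus the reversion
#' clade; read counts and the detection pipeline are as in
#' [simulate_independent_pvv()].
#'
#' @inheritParams simulate_independent_pvv
#' @return data.frame: rep, mutation and reversion branches, category, mmld.
#' @export
simulate_reversion <- function(tree, cfg = null_sim_config(),
                               config = pipeline_config()) {
  idx <- as_index(tree)
  len <- idx$blen; len[idx$root] <- 0
  desc_branches <- lapply(seq_len(idx$nn), function(v) {
    if (v <= idx$n) return(integer(0))
    d <- which(vapply(seq_len(idx$nn), function(u)
      u != v && is_within(idx, u, v), logical(1)))
    d[len[d] > 0]
  })
  inner_len <- vapply(desc_branches, function(d) sum(len[d]), numeric(1))
  w <- len * inner_len
  if (all(w == 0)) stop("no internal branch with descendant branches")
  set.seed(cfg$seed)
  tips <- idx$labels[seq_len(idx$n)]
  out <- vector("list", cfg$reps_reversion)
  for (r in seq_len(cfg$reps_reversion)) {
    mb <- sample.int(idx$nn, 1, prob = w)
    rb <- dsc <- desc_branches[[mb]]
    rb <- if (length(dsc) == 1) dsc else sample(dsc, 1, prob = len[dsc])
    carrier <- setNames(logical(idx$n), tips)
    carrier[idx$tips_under[[mb]]] <- TRUE
    carrier[idx$tips_under[[rb]]] <- FALSE
    res <- run_null_pipeline(idx, carrier, cfg, config)
    out[[r]] <- data.frame(rep = r, mutation_branch = idx$labels[mb],
                           reversion_branch = idx$labels[rb],
                           category = res$category, mmld = res$mmld,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pool simulated category proportions across phylogenies
#'
#' Weighted mean of per-phylogeny simulated proportions using the observed
#' per-phylogeny call counts as weights.
#'
#' @param proportions matrix (phylogenies x categories) or list of named
#'   vectors.
#' @param weights observed counts per phylogeny.
#' @return named vector of pooled proportions.
#' @export
weighted_contamination <- function(proportions, weights) {
  if (is.list(proportions)) proportions <- do.call(rbind, proportions)
  weights <- as.numeric(weights)
  stopifnot(nrow(proportions) == length(weights))
  if (all(weights == 0)) stop("all weights are zero")
  colSums(proportions * weights) / sum(weights)
}
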