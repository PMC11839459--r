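# Beta-binomial log-likelihood with mean p and overdispersion rho
# (alpha = p(1-rho)/rho, beta = (1-p)(1-rho)/rho); rho -> 0 is binomial.
bb_loglik <- function(k, n, p, rho) {
  if (rho < 1e-9) return(sum(dbinom(k, n, p, log = TRUE)))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Maximum-likelihood beta-binomial overdispersion
#'
#' Jointly maximizes the beta-binomial likelihood over the mean `p` and the
#' overdispersion `rho` for a set of variant-read/depth pairs. `rho` is
#' searched on `[1e-6, 0.89]` by a log-spaced grid followed by local
#' refinement; `p` is profiled out at each `rho` by 1-D optimization. The
#' fit is deterministic for a fixed input.
#'
#' @param mtr,dep integer vectors of variant reads and depths (>= 2 samples
#'   with depth > 0).
#' @return list: `rho`, `p_hat`, `loglik`.
#' @export
#' @examples
#' fit_beta_binomial_rho(c(15, 15, 0, 0), c(30, 30, 30, 30))$rho
fit_beta_binomial_rho <- function(mtr, dep) {
  keep <- dep > 0
  k <- as.numeric(mtr[keep]); n <- as.numeric(dep[keep])
  if (length(k) < 2) stop("need >= 2 samples with depth > 0")
  prof <- function(rho) {
    o <- optimize(function(p) bb_loglik(k, n, p, rho),
                  interval = c(1e-7, 1 - 1e-7), maximum = TRUE, tol = 1e-8)
    c(ll = o$objective, p = o$maximum)
  }
  lo <- 1e-6; hi <- 0.89
  grid <- exp(seq(log(lo), log(hi), length.out = 40))
  lls <- vapply(grid, function(r) prof(r)["ll"], numeric(1))
  # ties (flat likelihood, e.g. all-zero counts) resolve to the smallest rho
  i <- which(lls >= max(lls) - 1e-3)[1]
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  o <- optimize(function(r) prof(r)["ll"], interval = bracket,
                maximum = TRUE, tol = 1e-7)
  rho <- if (o$objective > lls[i] + 1e-9) o$maximum else grid[i]
  if (prof(lo)["ll"] >= bb_loglik(k, n, prof(rho)["p"], rho) - 1e-3) rho <- lo
  pr <- prof(rho)
  list(rho = rho, p_hat = unname(pr["p"]), loglik = unname(pr["ll"]))
}

#' Genotype a subclade from pooled read counts
#'
#' A subclade is *positive* when its pooled VAF and variant reads clear the
#' configured thresholds and no tip inside is confidently negative;
#' *negative* when it has zero variant reads at adequate pooled depth;
#' *mixed* when it contains both a confidently positive and a confidently
#' negative tip; *indeterminate* otherwise.
#'
#' @param tree phylogeny.
#' @param node subclade root (label or index).
#' @param mtr,dep named per-sample counts for one variant.
#' @param config a [pipeline_config()].
#' @return list: `node`, `label`, `mtr`, `dep` (pooled counts).
#' @export
subclade_genotype <- function(tree, node, mtr, dep, config = pipeline_config()) {
  idx <- as_index(tree)
  v <- resolve_node(idx, node)
  tips <- idx$labels[idx$tips_under[[v]]]
  m <- as.numeric(mtr[tips]); d <- as.numeric(dep[tips])
  vaf <- ifelse(d > 0, m / d, 0)
  tip_pos <- m >= config$positive_subclade_min_reads &
    vaf >= config$positive_subclade_min_vaf
  tip_neg <- m == 0 & d >= config$negative_subclade_min_depth
  M <- sum(m); D <- sum(d)
  label <- if (any(tip_pos) && any(tip_neg)) "mixed"
  else if (M == 0 && D >= config$negative_subclade_min_depth) "negative"
  else if (D > 0 && M >= config$positive_subclade_min_reads &&
           M / D >= config$positive_subclade_min_vaf && !any(tip_neg)) "positive"
  else "indeterminate"
  list(node = idx$labels[v], label = label, mtr = M, dep = D)
}

subclade_label <- function(idx, v, mtr, dep, config) {
  subclade_genotype(idx, v, mtr, dep, config)$label
}

#' Screen internal-branch mutations for phylogeny violation
#'
#' A mutation assigned to an internal branch becomes a PVV candidate when the
#' beta-binomial overdispersion of its read counts is high (`rho >=
#' rho_threshold`) *within* the assigned clade together with at least one
#' confidently negative subclade inside it, or high *outside* the assigned
#' clade together with at least one confidently positive subclade outside.
#'
#' @param tree phylogeny.
#' @param mtr,dep named per-sample counts for one variant.
#' @param assigned_branch the branch assignment (label or index); computed
#'   with [assign_branch()] when `NULL`.
#' @param config a [pipeline_config()].
#' @return list: `candidate` flag, `assigned_branch`, `rho_within`,
#'   `rho_outside`, `reason`.
#' @export
screen_pvv_candidate <- function(tree, mtr, dep, assigned_branch = NULL,
                                 config = pipeline_config()) {
  idx <- as_index(tree)
  if (is.null(assigned_branch))
    assigned_branch <- assign_branch(idx, mtr, dep, config)$branch
  v <- resolve_node(idx, assigned_branch)
  out <- list(candidate = FALSE, assigned_branch = idx$labels[v],
              rho_within = NA_real_, rho_outside = NA_real_,
              reason = NA_character_)
  if (v <= idx$n) { out$reason <- "terminal branch"; return(out) }
  tips <- idx$labels[seq_len(idx$n)]
  inside <- tips %in% idx$labels[idx$tips_under[[v]]]
  labs_all <- vapply(seq_len(idx$nn), function(u)
    subclade_label(idx, u, mtr, dep, config), character(1))
  desc <- setdiff(which(vapply(seq_len(idx$nn), function(u)
    is_within(idx, u, v), logical(1))), v)
  outside_nodes <- which(!vapply(seq_len(idx$nn), function(u)
    is_within(idx, u, v) || is_within(idx, v, u), logical(1)))
  hit_within <- hit_outside <- FALSE
  # the rho fit is only informative when the corresponding subclade evidence
  # exists, so it is skipped otherwise (cheap path for tree-consistent variants)
  if (any(labs_all[desc] == "negative") && sum(inside & dep[tips] > 0) >= 2) {
    out$rho_within <- fit_beta_binomial_rho(mtr[tips][inside], dep[tips][inside])$rho
    hit_within <- out$rho_within >= config$rho_threshold
  }
  if (any(labs_all[outside_nodes] == "positive") && sum(!inside & dep[tips] > 0) >= 2) {
    out$rho_outside <- fit_beta_binomial_rho(mtr[tips][!inside], dep[tips][!inside])$rho
    hit_outside <- out$rho_outside >= config$rho_threshold
  }
  out$candidate <- hit_within || hit_outside
  out$reason <- if (out$candidate) {
    paste(c(if (hit_within) "within-clade overdispersion + negative subclade",
            if (hit_outside) "outside-clade overdispersion + positive subclade"),
          collapse = "; ")
  } else "no overdispersion signal"
  out
}

#' Locate the lesion node of a PVV candidate
#'
#' Travels node-by-node up from the assigned branch until no confidently
#' positive subclade lies outside the clade: the minimal ancestor whose clade
#' contains every positive subclade.
#'
#' @inheritParams screen_pvv_candidate
#' @param assigned_branch the assigned branch (label or index).
#' @return list: `lesion_node`, `spans_root` flag.
#' @export
find_lesion_node <- function(tree, mtr, dep, assigned_branch,
                             config = pipeline_config()) {
  idx <- as_index(tree)
  v <- resolve_node(idx, assigned_branch)
  tips <- idx$labels[seq_len(idx$n)]
  m <- as.numeric(mtr[tips]); d <- as.numeric(dep[tips])
  vaf <- ifelse(d > 0, m / d, 0)
  pos_tip <- which(m >= config$positive_subclade_min_reads &
                     vaf >= config$positive_subclade_min_vaf)
  target <- unique(c(idx$tips_under[[v]], pos_tip))
  lesion <- resolve_node(idx, mrca_node(idx, target))
  # walk up from the assigned node to the covering ancestor (equivalent to the
  # iterative climb; mrca gives it directly)
  list(lesion_node = idx$labels[lesion], spans_root = lesion == idx$root)
}

#' Walk the lesion path of a PVV and emit a pass/fail call
#'
#' From the lesion node, descends through the unique mixed child, recording
#' each uniform sibling subclade's genotype in path order (children in tree
#' order within a node), and stops at the first node whose children are all
#' uniform (the repair-or-loss node). The call *fails* when two mixed
#' children occur at any step; it *passes* when the recorded uniform
#' sequence contains positive, negative, positive as a subsequence -- two
#' mutant subclades separated by a wild-type subclade. An indeterminate
#' subclade at a decision point flags the call indeterminate.
#'
#' @inheritParams screen_pvv_candidate
#' @param lesion_node the lesion node (label or index).
#' @return an `lp_pvv_call` list: `status` (`pass`/`fail`/`indeterminate`),
#'   `lesion_node`, `repair_node`, `path`, `subclades` (node, label, depth),
#'   `mmld`.
#' @export
walk_lesion_path <- function(tree, mtr, dep, lesion_node,
                             config = pipeline_config()) {
  idx <- as_index(tree)
  v <- resolve_node(idx, lesion_node)
  path <- idx$labels[v]
  sub <- list(); depth <- 0L
  status <- NA_character_
  repeat {
    depth <- depth + 1L
    kids <- idx$children[[v]]
    if (is.null(kids)) break
    labs <- vapply(kids, function(u) subclade_label(idx, u, mtr, dep, config),
                   character(1))
    mixed <- which(labs == "mixed")
    uni <- which(labs %in% c("positive", "negative"))
    indet <- which(labs == "indeterminate")
    for (u in uni) {
      sub[[length(sub) + 1]] <- data.frame(node = idx$labels[kids[u]],
                                           label = labs[u], depth = depth,
                                           stringsAsFactors = FALSE)
    }
    if (length(mixed) >= 2) { status <- "fail"; break }
    if (length(indet) && length(mixed) == 0 && length(uni) < length(kids)) {
      status <- "indeterminate"; break
    }
    if (length(mixed) == 0) break          # all children uniform: repair node
    v <- kids[mixed]
    path <- c(path, idx$labels[v])
  }
  subclades <- if (length(sub)) do.call(rbind, sub)
  else data.frame(node = character(0), label = character(0), depth = integer(0))
  repair <- if (is.na(status)) path[length(path)] else NA_character_
  if (is.na(status)) {
    # sandwich rule: the recorded uniform sequence (path order; children in
    # tree order within a node) must contain positive, negative, positive
    lab <- subclades$label
    p1 <- match("positive", lab)
    ok <- FALSE
    if (!is.na(p1)) {
      n1 <- which(lab == "negative" & seq_along(lab) > p1)[1]
      if (!is.na(n1)) ok <- any(lab == "positive" & seq_along(lab) > n1)
    }
    status <- if (ok) "pass" else "fail"
  }
  mmld <- if (status == "pass")
    molecular_time(idx, repair) - molecular_time(idx, lesion_node) else NA_real_
  structure(list(status = status, lesion_node = idx$labels[resolve_node(idx, lesion_node)],
                 repair_node = repair, path = path, subclades = subclades,
                 mmld = mmld), class = "lp_pvv_call")
}

#' Minimum molecular lesion duration of a PVV call
#'
#' @param call an `lp_pvv_call` from [walk_lesion_path()].
#' @param tree phylogeny.
#' @return MMLD in mutations; error for non-pass calls.
#' @export
pvv_mmld <- function(call, tree) {
  if (!identical(call$status, "pass")) stop("MMLD is defined for pass calls only")
  idx <- as_index(tree)
  molecular_time(idx, call$repair_node) - molecular_time(idx, call$lesion_node)
}

#' PVV detection pipeline
#'
#' Assigns every variant to a branch, screens internal-branch mutations for
#' overdispersion, locates lesion nodes, walks lesion paths, and returns one
#' row per assessed variant.
#'
#' @param tree phylogeny.
#' @param vcm a [variant_call_matrix()].
#' @param config a [pipeline_config()].
#' @return data.frame: variant id, class, assigned branch, rho within /
#'   outside, status (`not_candidate` / `terminal` / `pass` / `fail` /
#'   `indeterminate`), lesion and repair nodes, mmld.
#' @export
detect_pvv <- function(tree, vcm, config = pipeline_config()) {
  idx <- as_index(tree)
  rows <- lapply(seq_len(nrow(vcm$variants)), function(i) {
    mtr <- vcm$mtr[i, ]; dep <- vcm$dep[i, ]
    row <- data.frame(id = variant_id(vcm$variants)[i],
                      class = vcm$variants$class[i],
                      branch = NA_character_, rho_within = NA_real_,
                      rho_outside = NA_real_, status = NA_character_,
                      lesion_node = NA_character_, repair_node = NA_character_,
                      mmld = NA_real_, stringsAsFactors = FALSE)
    if (all(dep == 0)) { row$status <- "no_data"; return(row) }
    a <- assign_branch(idx, mtr, dep, config)
    row$branch <- a$branch
    sc <- screen_pvv_candidate(idx, mtr, dep, a$branch, config)
    row$rho_within <- sc$rho_within; row$rho_outside <- sc$rho_outside
    if (identical(sc$reason, "terminal branch")) { row$status <- "terminal"; return(row) }
    if (!sc$candidate) { row$status <- "not_candidate"; return(row) }
    ln <- find_lesion_node(idx, mtr, dep, a$branch, config)
    call <- walk_lesion_path(idx, mtr, dep, ln$lesion_node, config)
    row$status <- call$status
    row$lesion_node <- call$lesion_node
    row$repair_node <- call$repair_node
    row$mmld <- call$mmld
    row
  })
  do.call(rbind, rows)
}
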