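#' Strand states of a branch's SNVs
#'
#' The state of each SNV is the reference strand carrying the pyrimidine of
#' the mutated base pair: `"+"` when the reference base is C or T, `"-"`
#' when it is G or A. Mutations are ordered by position within chromosome.
#'
#' @param variants SNV table with `chrom`, `pos`, `ref`.
#' @return data.frame `chrom`, `pos`, `state`, sorted.
#' @export
strand_states <- function(variants) {
  if (!is.null(variants$class) && any(variants$class != "SNV"))
    stop("strand states are defined for SNVs only")
  st <- ifelse(toupper(variants$ref) %in% c("C", "T"), "+", "-")
  out <- data.frame(chrom = variants$chrom, pos = variants$pos, state = st,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), ]
}

run_lengths <- function(states, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep(1L, length(states))
  out <- integer(0)
  for (ch in unique(chrom)) {
    r <- rle(states[chrom == ch])
    out <- c(out, r$lengths)
  }
  out
}

#' Wald-Wolfowitz runs test for strand clustering
#'
#' Two-sided normal-approximation runs test: with `n1` and `n2` states of
#' each kind, the number of runs has mean `1 + 2 n1 n2 / n` and variance
#' `2 n1 n2 (2 n1 n2 - n) / (n^2 (n - 1))`. Runs never span chromosome
#' boundaries; the run count is summed over chromosomes.
#'
#' @param states character/logical vector of strand states in genomic order.
#' @param chrom optional chromosome of each state.
#' @return list: `p` (two-sided), `runs`, `z`.
#' @export
runs_test <- function(states, chrom = NULL) {
  n <- length(states)
  tab <- table(states)
  if (n < 2 || length(tab) < 2) stop("need both states present")
  n1 <- tab[1]; n2 <- tab[2]
  runs <- length(run_lengths(states, chrom))
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(p = unname(2 * pnorm(-abs(z))), runs = runs, z = unname(z))
}

#' Run-length statistic rl20
#'
#' Sorts strand runs by decreasing length and accumulates mutations until at
#' least 20% of all mutations are covered; rl20 is the length of the last
#' (shortest) run included. Runs are computed per chromosome and never span
#' boundaries.
#'
#' @inheritParams runs_test
#' @param frac fraction of mutations to cover (default 0.2).
#' @return integer rl20.
#' @export
rl20 <- function(states, chrom = NULL, frac = 0.2) {
  if (!length(states)) stop("empty input")
  rl <- sort(run_lengths(states, chrom), decreasing = TRUE)
  need <- frac * length(states)
  cum <- cumsum(rl)
  rl[which(cum >= need)[1]]
}

#' Lesion-segregation test across phylogeny branches
#'
#' Per branch with at least `min_mutations` SNVs: a two-sided binomial test
#' of the strand-state counts, the Wald-Wolfowitz runs test, and rl20.
#' P-values are Benjamini-Hochberg adjusted across branches separately per
#' test family; a branch is called positive when rl20 >= 6 and at least one
#' adjusted p-value is < 0.05.
#'
#' @param branch_variants named list of SNV tables (one per branch), each
#'   with `chrom`, `pos`, `ref`.
#' @param min_mutations minimum SNVs per branch (default 20; smaller
#'   branches are reported as skipped).
#' @param rl20_min,alpha positivity thresholds.
#' @return data.frame: branch, n, p_binomial, p_runs, rl20, adjusted
#'   p-values, `positive`, `skipped`.
#' @export
test_branches <- function(branch_variants, min_mutations = 20,
                          rl20_min = 6, alpha = 0.05) {
  rows <- lapply(names(branch_variants), function(b) {
    v <- branch_variants[[b]]
    n <- nrow(v)
    if (n < min_mutations) {
      return(data.frame(branch = b, n = n, p_binomial = NA_real_,
                        p_runs = NA_real_, rl20 = NA_integer_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    ss <- strand_states(v)
    npos <- sum(ss$state == "+")
    pb <- binomial_matching_test(npos, n)
    prr <- if (length(unique(ss$state)) < 2) 1 else runs_test(ss$state, ss$chrom)$p
    data.frame(branch = b, n = n, p_binomial = pb, p_runs = prr,
               rl20 = rl20(ss$state, ss$chrom), skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj_binomial <- NA_real_
  out$padj_runs <- NA_real_
  k <- !out$skipped
  out$padj_binomial[k] <- p.adjust(out$p_binomial[k], "BH")
  out$padj_runs[k] <- p.adjust(out$p_runs[k], "BH")
  out$positive <- !out$skipped & out$rl20 >= rl20_min &
    (out$padj_binomial < alpha | out$padj_runs < alpha)
  out$positive[is.na(out$positive)] <- FALSE
  out
}
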