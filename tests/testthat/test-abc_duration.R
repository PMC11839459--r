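test_that("simulate_population gives the right census and is deterministic", {
  p <- population_sim_params(N = 100, age = 5, seed = 1)
  tr <- simulate_population(p)
  expect_equal(length(tr$tip.label), 100)
  expect_equal(tr$Nnode, 99)
  # tips are contemporaneous; the tree roots at the first division, so the
  # root-to-tip depth is the age minus the (positive) first-division time
  idx <- lesionphylo:::tree_index(tr)
  tip_depth <- idx$time[seq_len(100)]
  expect_lt(diff(range(tip_depth)), 1e-9)
  expect_lte(tip_depth[1], 5)
  expect_gt(tip_depth[1], 5 - p$growth_years)
  # determinism
  tr2 <- simulate_population(p)
  expect_identical(write_phylogeny(tr), write_phylogeny(tr2))
  expect_error(population_sim_params(N = 1e7), "cap")
})

test_that("constant-phase edge length grows at the analytic coalescent rate", {
  # backward from the present the lineage count follows k(t) ~ N/(1 + beta*t),
  # so total length grows between ages T1 < T2 by (N/beta) log((1+b*T2)/(1+b*T1))
  # -- approaching N per year as beta*T -> 0
  N <- 400; b <- 0.02; tg <- 2
  lens <- vapply(c(10, 20), function(age) {
    p <- population_sim_params(N = N, age = age, turnover_rate = b,
                               growth_years = tg, seed = 7)
    sum(simulate_population(p)$edge.length)
  }, numeric(1))
  slope <- (lens[2] - lens[1]) / 10
  analytic <- (N / b) * log((1 + b * (20 - tg)) / (1 + b * (10 - tg))) / 10
  expect_equal(slope, analytic, tolerance = 0.1)
  expect_gt(slope, 0.6 * N)
  expect_lt(slope, 1.05 * N)
})

test_that("implant_lesions honours the duration model and lineage bookkeeping", {
  p <- population_sim_params(N = 1000, age = 40, seed = 2)
  pop <- lesionphylo:::pop_index(simulate_population(p))
  set.seed(5)
  les <- implant_lesions(pop, mu = 2, n = 20000)
  expect_equal(mean(les$duration), 2, tolerance = 0.05)
  expect_true(all(les$end - les$birth - les$duration < 1e-9))
  # spans only internal divisions before the lesion end
  k <- which(les$n_span > 0)
  expect_true(all(les$div_node[cbind(k, 1)] > pop$n))
  expect_true(all(pop$time[les$div_node[cbind(k, 1)]] < les$end[k]))
  # zero-duration lesions span nothing
  les0 <- implant_lesions(pop, mu = 1e-9, n = 50)
  expect_true(all(les0$n_span == 0))
})

test_that("theoretical_detectability is the M,W,M subsequence rule", {
  expect_false(theoretical_detectability(c("M", "M")))
  expect_true(theoretical_detectability(c("M", "W", "M")))
  expect_true(theoretical_detectability(c("W", "M", "W", "M")))
  expect_false(theoretical_detectability(c("M", "W", "W")))
  expect_false(theoretical_detectability(character(0)))
  expect_true(theoretical_detectability(c(1L, 0L, 1L)))
})

test_that("down-sampling to all cells equals theoretical detectability", {
  p <- population_sim_params(N = 500, age = 40, seed = 3)
  pop <- lesionphylo:::pop_index(simulate_population(p))
  set.seed(9)
  les <- implant_lesions(pop, mu = 3, n = 20000)
  theo <- theoretical_detectability(les)
  dd <- downsample_and_detect(les, n_tips = pop$n,
                              sampled_tips = seq_len(pop$n),
                              mmld_cap = Inf)
  expect_equal(dd$detected, theo)
  # conservation: every lesion classified exactly once
  expect_equal(length(dd$detected), 20000)

  # detected fraction decreases as the sample shrinks (in expectation)
  fr <- vapply(c(500, 120, 30), function(nt) {
    set.seed(31)
    mean(downsample_and_detect(les, n_tips = nt, mmld_cap = Inf)$detected)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  # a lesion whose mutant subclades lose all sampled tips goes undetected
  expect_lt(fr[3], fr[1])
  expect_error(downsample_and_detect(les, n_tips = 2), "at least 3")
})

test_that("summary_stats is the intercept-only gamma GLM", {
  expect_equal(unname(summary_stats(c(21, 21, 21))),
               c(21, 0), tolerance = 1e-12)
  # shape-1 gamma (exponential) sample: dispersion ~ 1
  set.seed(4)
  x <- rexp(4000, 1 / 30); x <- x[x <= 200]
  st <- summary_stats(x)
  expect_equal(unname(st["dispersion"]), 1, tolerance = 0.15)
  # matches glm(..., family = Gamma) moment dispersion on a small sample
  y <- c(12, 40, 33, 25, 70, 8)
  g <- glm(y ~ 1, family = Gamma(link = "identity"))
  expect_equal(unname(summary_stats(y)["mean"]), unname(coef(g)[1]),
               tolerance = 1e-6)
  expect_equal(unname(summary_stats(y)["dispersion"]),
               sum(((y - mean(y)) / mean(y))^2) / (length(y) - 1))
  # the cap filter is applied before fitting
  expect_equal(summary_stats(c(10, 20, 30, 250)), summary_stats(c(10, 20, 30)))
  expect_error(summary_stats(c(10, 20)), "at least 3")
})

test_that("abc_reject accepts the nearest tolerance quantile", {
  tab <- data.frame(mu = rep(seq(0.5, 5, by = 0.5), each = 10))
  set.seed(6)
  tab$mean <- 10 * tab$mu + rnorm(nrow(tab), 0, 1)
  tab$dispersion <- 1 + rnorm(nrow(tab), 0, 0.05)
  # observed equal to one run's stats, tiny tolerance: posterior is that mu
  obs <- c(mean = tab$mean[37], dispersion = tab$dispersion[37])
  r <- suppressWarnings(abc_reject(obs, tab, tolerance = 1 / nrow(tab)))
  expect_equal(r$posterior, tab$mu[37])
  # tolerance 1: posterior equals the prior (all runs accepted)
  r1 <- abc_reject(obs, tab, tolerance = 1)
  expect_equal(sort(r1$posterior), sort(tab$mu))
  # sane interval around the true value
  obs2 <- c(mean = 10 * 2.5, dispersion = 1)
  r2 <- abc_reject(obs2, tab, tolerance = 0.2)
  expect_true(r2$ci95[1] <= 2.5 && 2.5 <= r2$ci95[2])
  expect_warning(abc_reject(obs, tab, tolerance = 1 / nrow(tab)), "fewer than 20")
})

test_that("reference table is monotone in mu and supports prevalence inference", {
  pops <- lapply(1:2, function(s) lesionphylo:::pop_index(
    simulate_population(population_sim_params(N = 1000, age = 60, seed = s))))
  cfg <- abc_config(grid = c(1, 2, 3, 4), target_tips = c(60, 60),
                    target_pvvs = c(8, 8), runs_per_mu = 3, pops_per_run = 2,
                    lesion_cap = 4e5, batch_size = 1e5, min_detected = 4)
  tab <- build_reference_table(pops, cfg, seed = 8)
  expect_true(all(c("mu", "mean", "dispersion", "n_lesions",
                    "lineage_days") %in% names(tab)))
  agg <- aggregate(mean ~ mu, tab, mean)
  expect_gt(cor(agg$mu, agg$mean, method = "spearman"), 0.9)

  # lesions-per-cell closed form and linearity
  acc <- data.frame(mu = c(2, 2), n_lesions = c(100, 200),
                    lineage_days = c(1000 * 730, 1000 * 730))
  lpc <- lesions_per_cell(acc)
  expect_equal(lpc[1], 100 / (1000 * 730) * 2 * 365)
  expect_equal(lpc[2], 2 * lpc[1])
  expect_error(lesions_per_cell(data.frame(mu = 1, n_lesions = 1,
                                           lineage_days = 0)), "zero lineage")

  # posterior predictive on a point-mass posterior reflects simulation noise
  pp <- posterior_predictive(rep(2, 5), pops, cfg, n_runs = 4, seed = 11)
  expect_equal(nrow(pp), 4)
  expect_true(all(pp$mu == 2))
  expect_error(posterior_predictive(rep(2, 5), pops, cfg, n_runs = 0), "positive")
})
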