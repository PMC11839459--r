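test_that("spectrum_96 folds onto the pyrimidine strand", {
  # G>A at A-G-T: pyrimidine strand is the reverse complement A-C-T, C>T
  v <- data.frame(chrom = "chr1", pos = 1L, ref = "G", alt = "A",
                  class = "SNV", context = "AGT")
  s <- spectrum_96(v)
  expect_equal(unname(s["A[C>T]T"]), 1)
  expect_equal(sum(s), 1)

  expect_equal(sum(spectrum_96(v[0, ])), 0)

  # 96 distinct variants covering each channel once -> uniform counts
  chans <- sbs96_channels()
  v96 <- data.frame(chrom = "chr1", pos = seq_len(96),
                    ref = substr(chans, 3, 3), alt = substr(chans, 5, 5),
                    class = "SNV",
                    context = paste0(substr(chans, 1, 1), substr(chans, 3, 3),
                                     substr(chans, 7, 7)))
  expect_true(all(spectrum_96(v96) == 1))

  # strand-folding property: reverse-complemented input gives the same spectrum
  vrc <- v96
  vrc$ref <- chartr("ACGT", "TGCA", v96$ref)
  vrc$alt <- chartr("ACGT", "TGCA", v96$alt)
  vrc$context <- vapply(v96$context, function(x)
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = "")),
    character(1))
  expect_equal(spectrum_96(vrc), spectrum_96(v96))

  expect_error(spectrum_96(data.frame(chrom = "c", pos = 1L, ref = "C",
                                      alt = "T", class = "SNV",
                                      context = NA)), "context")
})

test_that("expected_mav_signature applies the pairwise-likelihood formula", {
  f <- uniform_trinuc_freqs <- lesionphylo:::uniform_trinuc_freqs()
  # mass only on two channels at one context: all profile mass on that combo
  sig <- setNames(numeric(96), sbs96_channels())
  sig["A[C>T]A"] <- 1; sig["A[C>G]A"] <- 1
  prof <- expected_mav_signature(sig, f)
  expect_equal(unname(prof["A[C>G/C>T]A"]), 1)
  expect_equal(sum(prof), 1)

  # uniform signature, uniform frequencies -> uniform profile
  u <- lesionphylo:::flat_signature()
  prof_u <- expected_mav_signature(u, f)
  expect_equal(unname(prof_u), rep(1 / 96, 96), tolerance = 1e-12)

  # a single-alternate signature cannot form a pair
  sig1 <- setNames(numeric(96), sbs96_channels())
  sig1[grep("C>T", names(sig1))] <- 1 / 16
  expect_warning(prof1 <- expected_mav_signature(sig1, f), "two distinct")
  expect_equal(sum(prof1), 0)

  # scale invariance
  sig2 <- u * 37
  expect_equal(expected_mav_signature(sig2, f), prof_u)

  # identity: summed pair weights at a fixed context equal
  # freq * ((sum L)^2 - sum L^2) / 2 before normalization
  set.seed(8)
  sigr <- setNames(runif(96), sbs96_channels())
  L <- likelihood_signature(sigr, f)
  raw <- expected_mav_signature(sigr, f)
  for (ctx in c("ACA", "TTG")) {
    refb <- substr(ctx, 2, 2)
    combos <- grep(paste0("^", substr(ctx, 1, 1), "\\[", refb, ".*",
                          substr(ctx, 3, 3), "$"), mav96_channels(), value = TRUE)
    chs <- grep(paste0("^", substr(ctx, 1, 1), "\\[", refb, ">.\\]",
                       substr(ctx, 3, 3), "$"), sbs96_channels(), value = TRUE)
    lhs <- sum(raw[combos])
    want <- (f[ctx] / 32 * 0 + f[ctx]) * ((sum(L[chs]))^2 - sum(L[chs]^2)) / 2
    # compare as proportions of the unnormalized totals
    tot <- sum(vapply(unique(lesionphylo:::channel_context()), function(cc) {
      cb <- substr(cc, 2, 2)
      ch2 <- grep(paste0("^", substr(cc, 1, 1), "\\[", cb, ">.\\]",
                         substr(cc, 3, 3), "$"), sbs96_channels(), value = TRUE)
      f[cc] * ((sum(L[ch2]))^2 - sum(L[ch2]^2)) / 2
    }, numeric(1)))
    expect_equal(lhs, unname(want / tot), tolerance = 1e-10)
  }
})

test_that("expected_independent_pvv_signature squares the likelihood", {
  f <- lesionphylo:::uniform_trinuc_freqs()
  # delta signature -> delta output
  sig <- setNames(numeric(96), sbs96_channels()); sig["A[C>T]G"] <- 1
  out <- expected_independent_pvv_signature(sig, f)
  expect_equal(unname(out["A[C>T]G"]), 1)

  # hand-computed: two equal spectrum channels, genome freqs 1:4.
  # L proportional to s/f, output proportional to L^2 * f = s^2 / f, so the
  # rarer context gets 4x the mass.
  f2 <- lesionphylo:::uniform_trinuc_freqs()
  f2[] <- 1
  f2["ACA"] <- 1; f2["GCG"] <- 4
  f2 <- f2 / sum(f2)
  sig2 <- setNames(numeric(96), sbs96_channels())
  sig2["A[C>T]A"] <- 1; sig2["G[C>T]G"] <- 1
  out2 <- expected_independent_pvv_signature(sig2, f2)
  expect_equal(unname(out2["A[C>T]A"] / out2["G[C>T]G"]), 4, tolerance = 1e-10)

  # blood-like clock signature: C>T at CpG dominates the expected spectrum
  fg <- lesionphylo:::uniform_trinuc_freqs()
  blood <- lesionphylo:::flat_signature()
  cpg <- c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")
  blood[cpg] <- blood[cpg] * 12            # CpG deamination excess
  outb <- expected_independent_pvv_signature(blood, fg)
  expect_equal(names(sort(outb, decreasing = TRUE))[1:4][order(names(sort(outb, decreasing = TRUE))[1:4])],
               sort(cpg))
  expect_gt(sum(outb[cpg]), 0.5)
})

test_that("expected_reversion_signature chains forward and reverse likelihoods", {
  f <- lesionphylo:::uniform_trinuc_freqs()
  # a supported channel pair forms chains in both directions; with uniform
  # frequencies the mass splits evenly between the two reversion channels
  sig <- setNames(numeric(96), sbs96_channels())
  sig["A[C>T]G"] <- 1; sig["A[T>C]G"] <- 1
  out <- expected_reversion_signature(sig, f)
  expect_equal(unname(out["A[T>C]G"]), 0.5)
  expect_equal(unname(out["A[C>T]G"]), 0.5)
  expect_equal(sum(out), 1)

  # no reverse support -> zero vector with a warning
  sig0 <- setNames(numeric(96), sbs96_channels()); sig0["A[C>T]G"] <- 1
  expect_warning(out0 <- expected_reversion_signature(sig0, f), "no reverse")
  expect_equal(sum(out0), 0)

  # blood-like clock signature over CpG-depleted genome frequencies peaks at
  # T>C in ATG (the published qualitative anchor)
  fg <- lesionphylo:::uniform_trinuc_freqs()
  cpg_ctx <- c("ACG", "CCG", "GCG", "TCG")
  fg[cpg_ctx] <- fg[cpg_ctx] / 5        # CpG depletion
  fg <- fg / sum(fg)
  blood <- lesionphylo:::flat_signature()
  cpg <- c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")
  blood[cpg] <- blood[cpg] * 12
  outb <- expected_reversion_signature(blood, fg)
  expect_equal(names(which.max(outb)), "A[T>C]G")
  # and the aggregate T>C-at-NTG mass dominates its C>T-at-NCG counterpart
  ntg <- c("A[T>C]G", "C[T>C]G", "G[T>C]G", "T[T>C]G")
  expect_gt(sum(outb[ntg]), sum(outb[cpg]))
})

test_that("cosine_similarity and strand_bias_test behave", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:2, 1:3))

  expect_equal(strand_bias_test(10, 10), 1)
  expect_equal(strand_bias_test(0, 10), 2 * 0.5^10)
  expect_gt(strand_bias_test(11, 10), 0.9)
})

test_that("fit_exposures recovers non-negative mixtures", {
  set.seed(12)
  r1 <- lesionphylo:::flat_signature()
  r2 <- setNames(runif(96), sbs96_channels()); r2 <- r2 / sum(r2)
  R <- cbind(sig1 = r1, sig2 = r2)
  target <- 0.3 * r1 + 0.7 * r2
  fit <- fit_exposures(target, R)
  expect_equal(unname(fit$exposures), c(0.3, 0.7), tolerance = 1e-4)
  expect_lt(fit$residual, 1e-6)

  # orthogonal target: zero exposure
  ref <- c(1, 0, 0, 0); tgt <- c(0, 1, 0, 0)
  expect_equal(unname(fit_exposures(tgt, matrix(ref))$exposures), 0,
               tolerance = 1e-6)

  # noisy mixture: within 0.05 of truth
  noisy <- pmax(target + rnorm(96, 0, 0.002), 0)
  fitn <- fit_exposures(noisy, R)
  expect_lt(max(abs(fitn$exposures - c(0.3, 0.7))), 0.05)

  expect_error(fit_exposures(1:10, R), "mismatch")
})

test_that("tabulate_deletions counts by deletion length", {
  v <- data.frame(chrom = "c", pos = 1:4,
                  ref = c("CT", "CTTT", "C", "CA"),
                  alt = c("C", "C", "CT", "C"),
                  class = c("indel", "indel", "indel", "indel"))
  t <- tabulate_deletions(v)
  expect_equal(unname(t[["1"]]), 2)
  expect_equal(unname(t[["3"]]), 1)
})
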