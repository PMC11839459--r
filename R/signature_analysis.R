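BASES <- c("A", "C", "G", "T")
SUBS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' 96-channel and MAV-profile channel labels
#'
#' Channels follow the COSMIC pyrimidine-strand convention, ordered by
#' substitution (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank
#' (A, C, G, T). The MAV profile pairs the two SNVs of a multi-allelic
#' variant: 6 unordered alternate-allele combinations per pyrimidine
#' reference base x 16 flank combinations.
#'
#' @return character vector of 96 labels.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (s in SUBS6) for (f5 in BASES) for (f3 in BASES) {
    out <- c(out, paste0(f5, "[", s, "]", f3))
  }
  out
}

MAV_COMBOS <- list(c("C>A", "C>G"), c("C>A", "C>T"), c("C>G", "C>T"),
                   c("T>A", "T>C"), c("T>A", "T>G"), c("T>C", "T>G"))

#' @rdname sbs96_channels
#' @export
mav96_channels <- function() {
  out <- character(0)
  for (cb in MAV_COMBOS) for (f5 in BASES) for (f3 in BASES) {
    out <- c(out, paste0(f5, "[", cb[1], "/", cb[2], "]", f3))
  }
  out
}

# Fold a (context, ref, alt) triple onto the pyrimidine strand; context is
# the reference trinucleotide centred on the mutated base.
fold_pyrimidine <- function(context, ref, alt) {
  pur <- ref %in% c("A", "G")
  context[pur] <- revcomp(context[pur])
  ref[pur] <- chartr("AG", "TC", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  list(context = context, ref = ref, alt = alt)
}

channel_of <- function(context, ref, alt) {
  f <- fold_pyrimidine(context, ref, alt)
  paste0(substr(f$context, 1, 1), "[", f$ref, ">", f$alt, "]",
         substr(f$context, 3, 3))
}

#' 96-channel SNV spectrum
#'
#' Counts SNVs per trinucleotide channel, reverse-complementing
#' purine-reference variants onto the pyrimidine strand.
#'
#' @param variants variant table restricted to SNVs with a `context` column
#'   (reference trinucleotide centred on the mutated base).
#' @param normalize divide by the total (default `FALSE`: raw counts).
#' @return named numeric vector over [sbs96_channels()].
#' @export
spectrum_96 <- function(variants, normalize = FALSE) {
  v <- variants[variants$class == "SNV", , drop = FALSE]
  out <- setNames(numeric(96), sbs96_channels())
  if (nrow(v)) {
    if (is.null(v$context) || anyNA(v$context))
      stop("SNVs need a trinucleotide context")
    ch <- channel_of(toupper(v$context), toupper(v$ref), toupper(v$alt))
    bad <- !(ch %in% names(out))
    if (any(bad)) stop("invalid context/ref/alt: ", paste(ch[bad], collapse = ", "))
    t <- table(ch)
    out[names(t)] <- as.numeric(t)
  }
  if (normalize && sum(out) > 0) out <- out / sum(out)
  out
}

channel_context <- function(channels = sbs96_channels()) {
  paste0(substr(channels, 1, 1), substr(channels, 3, 3), substr(channels, 7, 7))
}

norm_freqs <- function(genome_freqs) {
  f <- genome_freqs / sum(genome_freqs)
  ctx <- channel_context()
  if (!all(ctx %in% names(f)))
    stop("genome_freqs must cover all 32 pyrimidine-centred trinucleotides")
  f
}

#' Per-site mutation likelihood signature
#'
#' Divides a 96-channel spectrum by the genome frequency of each channel's
#' trinucleotide context and renormalizes, giving the relative likelihood
#' that any single genomic site in a given context acquires each mutation.
#'
#' @param sig named 96-channel spectrum (any scale).
#' @param genome_freqs named frequencies of the 32 pyrimidine-centred
#'   trinucleotides (any scale).
#' @return named 96-vector summing to 1.
#' @export
likelihood_signature <- function(sig, genome_freqs) {
  sig <- as.numeric(sig[sbs96_channels()])
  f <- as.numeric(norm_freqs(genome_freqs)[channel_context()])
  L <- ifelse(f > 0, sig / f, 0)
  if (sum(L) == 0) stop("empty signature")
  setNames(L / sum(L), sbs96_channels())
}

#' Expected MAV signature from an SNV signature
#'
#' The expected multi-allelic pair profile when persistent lesions template
#' two different misincorporations: for each context, the weight of an
#' unordered alternate-allele pair is proportional to the product of the two
#' SNVs' per-site likelihoods times the genomic abundance of the context.
#'
#' @inheritParams likelihood_signature
#' @return named 96-vector over [mav96_channels()], summing to 1 (all-zero
#'   with a warning when no context supports two distinct alternates).
#' @export
expected_mav_signature <- function(sig, genome_freqs) {
  L <- likelihood_signature(sig, genome_freqs)
  f <- norm_freqs(genome_freqs)
  out <- setNames(numeric(96), mav96_channels())
  k <- 0
  for (cb in MAV_COMBOS) for (f5 in BASES) for (f3 in BASES) {
    k <- k + 1
    refb <- substr(cb[1], 1, 1)
    ctx <- paste0(f5, refb, f3)
    ch1 <- paste0(f5, "[", cb[1], "]", f3)
    ch2 <- paste0(f5, "[", cb[2], "]", f3)
    out[k] <- L[ch1] * L[ch2] * f[ctx]
  }
  if (sum(out) == 0) {
    warning("signature supports no context with two distinct alternate alleles")
    return(out)
  }
  out / sum(out)
}

#' Expected signature of PVVs from two independent identical mutations
#'
#' The same mutation must occur twice at one site, so each channel's
#' per-site likelihood is squared before weighting by the genomic context
#' frequency. On a blood-like clock signature this is dominated by C>T at
#' CpG (ACG in particular).
#'
#' @inheritParams likelihood_signature
#' @return named 96-vector summing to 1.
#' @export
expected_independent_pvv_signature <- function(sig, genome_freqs) {
  L <- likelihood_signature(sig, genome_freqs)
  f <- as.numeric(norm_freqs(genome_freqs)[channel_context()])
  out <- setNames(as.numeric(L)^2 * f, sbs96_channels())
  if (sum(out) == 0) stop("empty signature")
  out / sum(out)
}

#' Expected signature of PVVs from somatic reversion
#'
#' A mutation followed by its exact back-mutation: the forward likelihood is
#' multiplied by the likelihood of the reverse mutation *in the mutated
#' context* (a C>T at ACG must be reverted by a T>C at ATG), weighted by the
#' genomic frequency of the reversion-site context, and the mass is assigned
#' to the reversion mutation's channel. On a blood-like signature over
#' CpG-depleted genome frequencies the result peaks at T>C at ATG.
#'
#' @inheritParams likelihood_signature
#' @return named 96-vector summing to 1 (all-zero with a warning when no
#'   reverse mutation has support).
#' @export
expected_reversion_signature <- function(sig, genome_freqs) {
  L <- likelihood_signature(sig, genome_freqs)
  f <- norm_freqs(genome_freqs)
  chans <- sbs96_channels()
  out <- setNames(numeric(96), chans)
  for (ch in chans) {
    Lf <- L[ch]
    if (Lf == 0) next
    f5 <- substr(ch, 1, 1); f3 <- substr(ch, 7, 7)
    refb <- substr(ch, 3, 3); altb <- substr(ch, 5, 5)
    mut_ctx <- paste0(f5, altb, f3)                 # context after the mutation
    rev_ch <- channel_of(mut_ctx, altb, refb)       # the back-mutation, folded
    Lr <- L[rev_ch]
    if (Lr == 0) next
    fold_ctx <- channel_context(rev_ch)             # pyrimidine-folded context
    out[rev_ch] <- out[rev_ch] + Lf * Lr * f[fold_ctx]
  }
  if (sum(out) == 0) {
    warning("no reverse mutation has non-zero likelihood")
    return(out)
  }
  out / sum(out)
}

#' Cosine similarity
#'
#' @param a,b equal-length non-negative vectors with non-zero norm.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector")
  sum(a * b) / (na * nb)
}

#' Two-sided test for transcriptional strand bias
#'
#' Conditional on the total, an exact two-sided binomial test of the
#' transcribed-strand count against probability 0.5 (doubled smaller tail).
#'
#' @param n_transcribed,n_untranscribed mutation counts by strand.
#' @return two-sided p-value.
#' @export
strand_bias_test <- function(n_transcribed, n_untranscribed) {
  binomial_matching_test(n_transcribed, n_transcribed + n_untranscribed)
}

#' Non-negative exposure fitting against reference signatures
#'
#' Least-squares decomposition of a target spectrum into non-negative
#' exposures on reference signatures (L-BFGS-B with zero lower bounds).
#'
#' @param target 96-channel spectrum.
#' @param references matrix (96 x k) of reference signatures, or a single
#'   vector.
#' @return list: `exposures` (named when references are), `residual` (root
#'   mean squared reconstruction error), `fitted`.
#' @export
fit_exposures <- function(target, references) {
  R <- as.matrix(references)
  if (nrow(R) != length(target)) stop("dimension mismatch")
  k <- ncol(R)
  fn <- function(w) sum((target - R %*% w)^2)
  gr <- function(w) as.numeric(-2 * t(R) %*% (target - R %*% w))
  w0 <- rep(sum(target) / max(k, 1), k)
  o <- optim(w0, fn, gr, method = "L-BFGS-B", lower = rep(0, k),
             control = list(maxit = 500, factr = 1e4))
  w <- o$par
  names(w) <- colnames(R)
  list(exposures = w, residual = sqrt(o$value / length(target)),
       fitted = as.numeric(R %*% w))
}

#' Tabulate deletions by length
#'
#' Plain reporting tabulation of deletion lengths (reference length minus
#' alternate length, for indels with longer reference).
#'
#' @param variants variant table.
#' @return table of deletion lengths.
#' @export
tabulate_deletions <- function(variants) {
  v <- variants[variants$class == "indel" &
                  nchar(variants$ref) > nchar(variants$alt), , drop = FALSE]
  table(nchar(v$ref) - nchar(v$alt))
}
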