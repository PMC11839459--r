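#' Heterozygous SNPs usable for phasing a variant
#'
#' @param variant list or one-row data.frame with `chrom` and `pos`.
#' @param het_snps data.frame of confirmed heterozygous SNPs with columns
#'   `chrom`, `pos`, `a1`, `a2` (the two alleles).
#' @param max_dist maximum distance in bp (closed interval; default 1000).
#' @return the subset of `het_snps` within range on the same chromosome.
#' @export
find_phasing_snps <- function(variant, het_snps, max_dist = 1000) {
  het_snps[het_snps$chrom == variant$chrom &
             abs(het_snps$pos - variant$pos) <= max_dist, , drop = FALSE]
}

# Tally the SNP bases supported by read pairs carrying a given base at the
# variant locus.  obs: data.frame(sample, var_base, snp_base).
snp_base_support <- function(obs, var_base) {
  table(obs$snp_base[obs$var_base == var_base])
}

#' Phase the two alleles of a MAV against a heterozygous SNP
#'
#' In `clonal` mode an allele phases to a SNP base either directly (read
#' pairs carrying the variant base and that SNP base) or via the reference
#' base (read pairs carrying the reference base and the *other* SNP base,
#' which places the variant on the complementary haplotype). In `lcm` mode
#' (microdissection; non-clonal samples) only direct variant-base evidence is
#' used. The verdict is `matching` when both alleles phase to the same SNP
#' base, `conflicting` when they phase to different bases, `uninformative`
#' otherwise.
#'
#' @param obs_alt1,obs_alt2 data.frames of read-pair observations (`sample`,
#'   `var_base`, `snp_base`) from samples carrying allele 1 / allele 2.
#' @param alt1,alt2 the two alternate bases; `ref` the reference base.
#' @param snp_alleles length-2 character vector of the SNP's alleles.
#' @param mode `"clonal"` or `"lcm"`.
#' @return list: `result` (`matching`/`conflicting`/`uninformative`),
#'   `phase1`, `phase2` (SNP base each allele phases to, or NA), evidence
#'   counts.
#' @export
phase_pair <- function(obs_alt1, obs_alt2, alt1, alt2, ref, snp_alleles,
                       mode = c("clonal", "lcm")) {
  mode <- match.arg(mode)
  phase_one <- function(obs, alt) {
    direct <- snp_base_support(obs, alt)
    direct <- direct[names(direct) %in% snp_alleles]
    hit <- names(direct)[direct > 0]
    if (length(hit) == 1) return(list(base = hit, n = unname(direct[hit])))
    if (length(hit) > 1) return(list(base = "ambiguous", n = sum(direct)))
    if (mode == "clonal") {
      via_ref <- snp_base_support(obs, ref)
      via_ref <- via_ref[names(via_ref) %in% snp_alleles]
      hit <- names(via_ref)[via_ref > 0]
      if (length(hit) == 1) {
        other <- setdiff(snp_alleles, hit)
        return(list(base = other, n = unname(via_ref[hit])))
      }
    }
    list(base = NA_character_, n = 0L)
  }
  p1 <- phase_one(obs_alt1, alt1)
  p2 <- phase_one(obs_alt2, alt2)
  result <- if (is.na(p1$base) || is.na(p2$base) ||
                identical(p1$base, "ambiguous") || identical(p2$base, "ambiguous"))
    "uninformative"
  else if (p1$base == p2$base) "matching" else "conflicting"
  list(result = result, phase1 = p1$base, phase2 = p2$base,
       n1 = p1$n, n2 = p2$n, mode = mode)
}

#' Phase the positive subclades of a PVV
#'
#' With more than two positive subclades, phasing is confirmed when any
#' subclade pair phases to the same SNP base; the verdict is conflicting when
#' some pair demonstrably differs and none match.
#'
#' @param subclade_obs named list of observation data.frames (`sample`,
#'   `var_base`, `snp_base`), one per positive subclade.
#' @param alt the PVV's alternate base; `ref` the reference base.
#' @param snp_alleles length-2 character vector of SNP alleles.
#' @param mode `"clonal"` or `"lcm"`.
#' @return list: `result`, per-subclade phased bases.
#' @export
phase_pvv_subclades <- function(subclade_obs, alt, ref, snp_alleles,
                                mode = "clonal") {
  if (length(subclade_obs) < 2)
    return(list(result = "uninformative", phases = character(0)))
  phases <- vapply(subclade_obs, function(o)
    phase_pair(o, o, alt, alt, ref, snp_alleles, mode)$phase1, character(1))
  informative <- phases[!is.na(phases) & phases != "ambiguous"]
  if (length(informative) < 2)
    return(list(result = "uninformative", phases = phases))
  result <- if (any(table(informative) >= 2)) "matching"
  else if (length(unique(informative)) > 1) "conflicting"
  else "uninformative"
  list(result = result, phases = phases)
}

#' Read-based loss-of-heterozygosity check for a PVV's negative subclade
#'
#' After phasing the mutation to one SNP allele, the colonies of the negative
#' subclade are interrogated for reads reporting that SNP allele together
#' with the reference base at the variant locus: their presence shows the
#' parental chromosome that carried the mutation is still present (`no_loh`);
#' their absence at adequate depth indicates `loh`; otherwise `unassessable`.
#'
#' @param neg_obs data.frame of read-pair observations (`sample`,
#'   `var_base`, `snp_base`) from negative-subclade samples.
#' @param phased_base the SNP base the mutation phases to.
#' @param ref the reference base at the variant locus.
#' @param min_depth minimum informative read pairs for an `loh` verdict
#'   (default 13, the negative-subclade depth threshold).
#' @return `"no_loh"`, `"loh"` or `"unassessable"`.
#' @export
read_based_loh_check <- function(neg_obs, phased_base, ref, min_depth = 13) {
  support <- sum(neg_obs$snp_base == phased_base & neg_obs$var_base == ref)
  depth <- nrow(neg_obs)
  if (support > 0) return("no_loh")
  if (depth >= min_depth) return("loh")
  "unassessable"
}

#' Exact two-sided binomial test of phasing concordance
#'
#' Tests `n_matching` of `n_total` against probability 0.5 by doubling the
#' smaller exact tail (capped at 1).
#'
#' @param n_matching,n_total counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' binomial_matching_test(78, 81)   # ~7e-20
binomial_matching_test <- function(n_matching, n_total) {
  stopifnot(n_total >= 1, n_matching >= 0, n_matching <= n_total)
  lower <- pbinom(n_matching, n_total, 0.5)
  upper <- pbinom(n_matching - 1, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
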