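#' Pipeline configuration
#'
#' Bundles the thresholds shared across MAV/PVV detection, genotyping of
#' subclades, and molecular-time conversion. Defaults follow the published
#' haematopoietic-colony analysis: heterozygous variants are expected at
#' VAF 0.5 on diploid autosomes, sequencing error is modelled at 1e-6, the
#' beta-binomial overdispersion screen uses rho >= 0.1, a subclade counts as
#' confidently positive at pooled VAF >= 0.25 with >= 3 variant reads, as
#' confidently negative with zero variant reads at pooled depth >= 13, nodes
#' before 50 mutations of molecular time are treated as developmental
#' (in utero), and molecular time converts to years at 15 mutations/year.
#'
#' @param het_vaf expected variant allele fraction of a true heterozygous
#'   variant in carrier samples.
#' @param error_rate per-read error probability used for non-carriers.
#' @param rho_threshold beta-binomial overdispersion threshold for the PVV
#'   screen.
#' @param positive_subclade_min_vaf,positive_subclade_min_reads pooled VAF and
#'   variant-read minima for a confidently positive subclade.
#' @param negative_subclade_min_depth pooled depth minimum for a confidently
#'   negative (zero variant reads) subclade.
#' @param development_cutoff molecular time (mutations) below which a node is
#'   classified as developmental/in utero.
#' @param mutation_rate_per_year clock rate used to convert molecular time to
#'   chronological time.
#' @param seed integer seed recorded with results.
#' @return an object of class `lp_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$rho_threshold
pipeline_config <- function(het_vaf = 0.5,
                            error_rate = 1e-6,
                            rho_threshold = 0.1,
                            positive_subclade_min_vaf = 0.25,
                            positive_subclade_min_reads = 3,
                            negative_subclade_min_depth = 13,
                            development_cutoff = 50,
                            mutation_rate_per_year = 15,
                            seed = 1L) {
  stopifnot(het_vaf > 0, het_vaf <= 1,
            error_rate >= 0, error_rate < het_vaf,
            rho_threshold >= 0, rho_threshold <= 1,
            positive_subclade_min_vaf > 0, positive_subclade_min_vaf <= 1,
            positive_subclade_min_reads >= 0,
            negative_subclade_min_depth >= 0,
            development_cutoff >= 0,
            mutation_rate_per_year > 0)
  structure(list(
    het_vaf = het_vaf,
    error_rate = error_rate,
    rho_threshold = rho_threshold,
    positive_subclade_min_vaf = positive_subclade_min_vaf,
    positive_subclade_min_reads = positive_subclade_min_reads,
    negative_subclade_min_depth = negative_subclade_min_depth,
    development_cutoff = development_cutoff,
    mutation_rate_per_year = mutation_rate_per_year,
    seed = as.integer(seed)
  ), class = "lp_config")
}

#' @export
print.lp_config <- function(x, ...) {
  cat("lesionphylo pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
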