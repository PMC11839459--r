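#' Generate a sampled stem-cell genealogy
#'
#' Coalescent sample of `n_tips` cells from the population model of
#' [simulate_population()] (exponential expansion, then constant-size
#' turnover), giving the aged-haematopoiesis topology: most coalescences
#' near the root, long terminal branches. Branch lengths are in years.
#'
#' @param n_tips number of sampled cells (>= 3).
#' @param age donor age in years.
#' @param N population size of the underlying model.
#' @param turnover_rate,growth_years population dynamics (see
#'   [population_sim_params()]).
#' @param seed integer seed.
#' @return an `ape::phylo` tree with `n_tips` tips labelled `C1..`.
#' @export
generate_genealogy <- function(n_tips, age = 75, N = 20000,
                               turnover_rate = 1, growth_years = 5,
                               seed = 1L) {
  if (n_tips < 3) stop("need at least 3 tips")
  params <- population_sim_params(N = N, age = age,
                                  turnover_rate = turnover_rate,
                                  growth_years = growth_years, seed = seed)
  set.seed(seed)
  coalescent_tree(params, k0 = as.integer(n_tips))
}

# Flat default SNV signature used when none is supplied.
flat_signature <- function() setNames(rep(1 / 96, 96), sbs96_channels())

# Uniform trinucleotide frequencies over the 32 pyrimidine-centred contexts.
uniform_trinuc_freqs <- function() {
  ctx <- unique(channel_context())
  setNames(rep(1 / length(ctx), length(ctx)), ctx)
}

parse_channel <- function(ch) {
  list(f5 = substr(ch, 1, 1), ref = substr(ch, 3, 3),
       alt = substr(ch, 5, 5), f3 = substr(ch, 7, 7))
}

# Random SNV records drawn from a 96-channel signature on a synthetic
# two-chromosome genome; strand_flip folds half onto the purine strand.
draw_snvs <- function(n, signature = flat_signature(), strand_flip = TRUE,
                      chrom_len = 5e7) {
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), context = character(0)))
  }
  ch <- sample(names(signature), n, replace = TRUE, prob = signature)
  p <- parse_channel(ch)
  ctx <- paste0(p$f5, p$ref, p$f3)
  ref <- p$ref; alt <- p$alt
  if (strand_flip) {
    fl <- runif(n) < 0.5
    ctx[fl] <- revcomp(ctx[fl])
    ref[fl] <- chartr("ACGT", "TGCA", ref[fl])
    alt[fl] <- chartr("ACGT", "TGCA", alt[fl])
  }
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos = sample.int(chrom_len, n, replace = FALSE),
             ref = ref, alt = alt, class = "SNV", context = ctx,
             stringsAsFactors = FALSE)
}

#' Sprinkle clock-like mutations onto a genealogy
#'
#' Per-branch Poisson mutation counts at `rate_per_year` over the branch's
#' years, with trinucleotide contexts drawn from the supplied signature.
#' Returns the variant table with ground-truth branch assignments and the
#' genealogy rescaled to molecular time (branch lengths = simulated
#' mutation counts).
#'
#' @param tree genealogy with branch lengths in years.
#' @param rate_per_year mutations per year (> 0).
#' @param signature named 96-channel signature (default flat).
#' @param seed integer seed.
#' @return list: `variants`, `truth` (id, branch), `tree_mut` (molecular
#'   time), `counts_per_branch`.
#' @export
sprinkle_mutations <- function(tree, rate_per_year, signature = flat_signature(),
                               seed = 1L) {
  if (rate_per_year <= 0) stop("rate must be positive")
  set.seed(seed)
  idx <- tree_index(tree)
  nodes <- which(seq_len(idx$nn) != idx$root)
  counts <- rpois(length(nodes), rate_per_year * idx$blen[nodes])
  v <- draw_snvs(sum(counts), signature)
  branch <- rep(idx$labels[nodes], counts)
  tree_mut <- tree
  m <- match(tree$edge[, 2], nodes)
  tree_mut$edge.length <- counts[m]
  list(variants = v,
       truth = data.frame(id = variant_id(v), branch = branch,
                          stringsAsFactors = FALSE),
       tree_mut = tree_mut,
       counts_per_branch = setNames(counts, idx$labels[nodes]))
}

# Internal chains D1 -> D2 (-> D3) of internal nodes, child links, avoiding
# the root as D1 so the lesion node has a branch above it.
internal_chains <- function(idx, len) {
  res <- list()
  for (v in (idx$n + 1L):idx$nn) {
    if (v == idx$root) next
    chain <- v
    while (length(chain) < len) {
      kids <- idx$children[[chain[length(chain)]]]
      int_kids <- kids[kids > idx$n]
      if (!length(int_kids)) break
      chain <- c(chain, int_kids[1])
    }
    if (length(chain) == len) res[[length(res) + 1]] <- chain
  }
  res
}

#' Implant a persistent lesion into a genealogy's variant set
#'
#' Annotates the genealogy with a lesion of the requested kind without
#' altering the topology. `kind = "mav"` places two alternate alleles: a
#' *simple* MAV assigns them to the two children of one node; a *separated*
#' MAV places them on subclades shed at consecutive divisions. `kind =
#' "pvv"` places one allele on the subclades shed at the first and third
#' division of an internal chain (mutant, wild-type, mutant), the minimal
#' detectable geometry. Ground truth records the expected category, lesion
#' and repair nodes, carriers and haplotype.
#'
#' @param tree genealogy (years or molecular time; only topology and the
#'   node times matter).
#' @param kind `"mav"` or `"pvv"`.
#' @param separated for MAVs: separated (`TRUE`) or simple geometry.
#' @param seed integer seed.
#' @param signature channel signature for the variant contexts.
#' @return list: `variants` (1 row for PVV, 2 for MAV), `carriers` (logical
#'   matrix variants x tips), `truth` (expected category, lesion_node,
#'   repair_node, haplotype).
#' @export
implant_persistent_lesion <- function(tree, kind = c("mav", "pvv"),
                                      separated = FALSE, seed = 1L,
                                      signature = flat_signature()) {
  kind <- match.arg(kind)
  idx <- as_index(tree)
  set.seed(seed)
  need <- if (kind == "pvv") 3L else if (separated) 2L else 1L
  chains <- internal_chains(idx, need)
  if (!length(chains))
    stop("tree has no internal chain long enough for this lesion kind")
  chain <- chains[[sample.int(length(chains), 1)]]
  other_child <- function(v, keep) setdiff(idx$children[[v]], keep)
  tips <- idx$labels[seq_len(idx$n)]
  carr <- function(nodes) tips %in% idx$labels[unlist(idx$tips_under[nodes])]
  if (kind == "mav" && !separated) {
    kids <- idx$children[[chain[1]]]
    v <- draw_snvs(2, signature)
    v$chrom[2] <- v$chrom[1]; v$pos[2] <- v$pos[1]
    v$ref[2] <- v$ref[1]; v$context[2] <- v$context[1]
    alts <- setdiff(c("A", "C", "G", "T"), v$ref[1])
    v$alt <- alts[1:2]
    carriers <- rbind(carr(kids[1]), carr(kids[2]))
    truth <- list(category = "simple", lesion_node = idx$labels[chain[1]],
                  repair_node = idx$labels[chain[1]], haplotype = "same")
  } else if (kind == "mav") {
    s1 <- other_child(chain[1], chain[2])
    s2kids <- idx$children[[chain[2]]]
    s2 <- s2kids[sample.int(length(s2kids), 1)]
    v <- draw_snvs(2, signature)
    v$chrom[2] <- v$chrom[1]; v$pos[2] <- v$pos[1]
    v$ref[2] <- v$ref[1]; v$context[2] <- v$context[1]
    alts <- setdiff(c("A", "C", "G", "T"), v$ref[1])
    v$alt <- alts[1:2]
    carriers <- rbind(carr(s1), carr(s2))
    truth <- list(category = "separated", lesion_node = idx$labels[chain[1]],
                  repair_node = idx$labels[chain[2]], haplotype = "same")
  } else {
    # prefer chains whose two mutant subclades carry >= 3 tips in total:
    # with only two carrier tips the branch-assignment likelihood can favour
    # a terminal branch, making the lesion undetectable by the pipeline
    pick <- function(chain) {
      s1 <- other_child(chain[1], chain[2])
      s3kids <- idx$children[[chain[3]]]
      s3 <- s3kids[sample.int(length(s3kids), 1)]
      list(s1 = s1, s3 = s3,
           n_carr = length(idx$tips_under[[s1]]) + length(idx$tips_under[[s3]]))
    }
    sel <- lapply(chains, pick)
    strong <- which(vapply(sel, `[[`, numeric(1), "n_carr") >= 3)
    use <- if (length(strong)) sample(strong, 1) else sample(seq_along(sel), 1)
    chain <- chains[[use]]
    s1 <- sel[[use]]$s1; s3 <- sel[[use]]$s3
    v <- draw_snvs(1, signature)
    carriers <- rbind(carr(c(s1, s3)))
    truth <- list(category = "pass", lesion_node = idx$labels[chain[1]],
                  repair_node = idx$labels[chain[3]], haplotype = "same")
  }
  colnames(carriers) <- tips
  rownames(carriers) <- variant_id(v)
  list(variants = v, carriers = carriers, truth = truth)
}

#' Simulate read counts for a variant set
#'
#' Depth is Poisson at the target coverage per sample; carriers draw variant
#' reads binomially at VAF 0.5, non-carriers at the error rate.
#'
#' @param carriers logical matrix, variants x samples.
#' @param coverage mean sequencing depth (default 30).
#' @param error_rate per-read error probability.
#' @param het_vaf carrier VAF.
#' @param seed integer seed.
#' @return list of integer matrices `mtr`, `dep`.
#' @export
emit_read_counts <- function(carriers, coverage = 30, error_rate = 1e-6,
                             het_vaf = 0.5, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  set.seed(seed)
  dims <- dim(carriers)
  dep <- matrix(rpois(prod(dims), coverage), dims[1], dims[2],
                dimnames = dimnames(carriers))
  p <- ifelse(carriers, het_vaf, error_rate)
  mtr <- matrix(rbinom(prod(dims), as.vector(dep), as.vector(p)),
                dims[1], dims[2], dimnames = dimnames(carriers))
  list(mtr = mtr, dep = dep)
}

#' Simulate heterozygous-SNP phasing evidence for a MAV or PVV
#'
#' Places a germline heterozygous SNP within 1 kb of the variant locus and
#' emits read-pair observations consistent with the truth haplotypes: reads
#' carrying a variant base report the SNP base of the haplotype that carries
#' the lesion; reads carrying the reference base report either SNP base.
#'
#' @param variants variant table (the alleles being phased share a locus).
#' @param carriers logical matrix variants x samples.
#' @param haplotype `"same"` (both alleles on one parental haplotype) or
#'   `"opposite"`.
#' @param pairs_per_sample mean informative read pairs per carrier sample.
#' @param snp_offset SNP distance from the variant (<= 1000).
#' @param seed integer seed.
#' @return list: `het_snps` (chrom, pos, a1, a2), `observations`
#'   (sample, chrom, var_pos, var_base, snp_pos, snp_base).
#' @export
emit_phasing_evidence <- function(variants, carriers, haplotype = "same",
                                  pairs_per_sample = 4, snp_offset = 400,
                                  seed = 1L) {
  set.seed(seed)
  chrom <- variants$chrom[1]; vpos <- variants$pos[1]
  snp <- data.frame(chrom = chrom, pos = vpos + snp_offset,
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  hap_base <- c("A", "G")            # haplotype 1 carries A, haplotype 2 G
  obs <- list()
  emit <- function(sample, var_base, snp_base, n) {
    if (n <= 0) return()
    obs[[length(obs) + 1]] <<- data.frame(
      sample = sample, chrom = chrom, var_pos = vpos, var_base = var_base,
      snp_pos = snp$pos, snp_base = snp_base, stringsAsFactors = FALSE)[
        rep(1, n), , drop = FALSE]
  }
  for (i in seq_len(nrow(variants))) {
    hap <- if (i == 1 || haplotype == "same") 1L else 2L
    for (s in colnames(carriers)) {
      n <- rpois(1, pairs_per_sample)
      if (carriers[i, s]) {
        n_alt <- rbinom(1, n, 0.5)
        emit(s, variants$alt[i], hap_base[hap], n_alt)
        emit(s, variants$ref[i], hap_base[3L - hap], n - n_alt)
      } else if (i == 1) {
        emit(s, variants$ref[i], sample(hap_base, 1), n)
      }
    }
  }
  list(het_snps = snp,
       observations = if (length(obs)) do.call(rbind, obs)
       else data.frame(sample = character(0), chrom = character(0),
                       var_pos = integer(0), var_base = character(0),
                       snp_pos = integer(0), snp_base = character(0)))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' One call produces a genealogy, clock-like background mutations, implanted
#' persistent lesions (simple MAV, separated MAV, detectable PVV), read
#' counts at ~30x, and phasing evidence, with machine-readable truth.
#' Presets vary donor age and mutation rate: `adult-hspc` (75 y, 15/y),
#' `fetal` (0.4 y, 60/y in utero-weighted), `chemo` and `bronchus-apobec`
#' (higher rates emulating exposed tissues).
#'
#' @param preset dataset preset.
#' @param n_tips number of colonies.
#' @param seed integer seed.
#' @param coverage mean depth.
#' @param dir optional directory: when given, tree.nwk, variants.tsv,
#'   mtr.tsv, dep.tsv, snps.tsv, readpairs.tsv and truth.json are written.
#' @return list: `tree` (molecular time), `tree_years`, `vcm`, `truth`,
#'   `phasing`, `config`.
#' @export
synth_dataset <- function(preset = c("adult-hspc", "fetal", "chemo",
                                     "bronchus-apobec"),
                          n_tips = 24, seed = 1L, coverage = 30,
                          dir = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
              "adult-hspc" = list(age = 75, rate = 15),
              "fetal" = list(age = 0.4, rate = 120),
              "chemo" = list(age = 60, rate = 60),
              "bronchus-apobec" = list(age = 60, rate = 50))
  tre <- generate_genealogy(n_tips, age = p$age, seed = seed)
  bg <- sprinkle_mutations(tre, p$rate, seed = seed + 1L)
  lesions <- list(
    simple_mav = implant_persistent_lesion(tre, "mav", separated = FALSE,
                                           seed = seed + 2L),
    separated_mav = tryCatch(
      implant_persistent_lesion(tre, "mav", separated = TRUE, seed = seed + 3L),
      error = function(e) NULL),
    pvv = tryCatch(
      implant_persistent_lesion(tre, "pvv", seed = seed + 4L),
      error = function(e) NULL))
  lesions <- Filter(Negate(is.null), lesions)
  idx <- tree_index(bg$tree_mut)
  tips <- idx$labels[seq_len(idx$n)]
  bg_carriers <- t(vapply(bg$truth$branch, function(b)
    tips %in% clade_tips(idx, b), logical(length(tips))))
  les_variants <- do.call(rbind, lapply(lesions, `[[`, "variants"))
  les_carriers <- do.call(rbind, lapply(lesions, `[[`, "carriers"))
  variants <- rbind(bg$variants, les_variants)
  carriers <- rbind(bg_carriers, les_carriers)
  colnames(carriers) <- tips
  cnt <- emit_read_counts(carriers, coverage, seed = seed + 5L)
  rownames(cnt$mtr) <- rownames(cnt$dep) <- variant_id(variants)
  vcm <- variant_call_matrix(variants, cnt$mtr, cnt$dep, bg$tree_mut)
  mav <- lesions$simple_mav
  phasing <- emit_phasing_evidence(mav$variants, mav$carriers,
                                   haplotype = "same", seed = seed + 6L)
  truth <- list(preset = preset, seed = seed,
                background = bg$truth,
                lesions = lapply(lesions, function(l)
                  c(l$truth, list(ids = rownames(l$carriers)))))
  out <- list(tree = bg$tree_mut, tree_years = tre, vcm = vcm, truth = truth,
              phasing = phasing,
              config = list(preset = preset, seed = seed, coverage = coverage,
                            age = p$age, rate = p$rate))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_phylogeny(bg$tree_mut, file.path(dir, "tree.nwk"))
    write_variant_data(vcm, dir)
    write.table(phasing$het_snps, file.path(dir, "snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(phasing$observations, file.path(dir, "readpairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
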