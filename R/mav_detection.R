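#' Find candidate multi-allelic variant (MAV) pairs
#'
#' A MAV is a locus mutated to two different mutant alleles in the same
#' individual. SNV pairs qualify when they share chrom+pos with different
#' alternate alleles; deletions and MNVs qualify on any overlap of their
#' reference-coordinate intervals.
#'
#' @param variants variant table (see [variant_call_matrix()]).
#' @return data.frame of candidate pairs (`i`, `j` row indexes plus ids);
#'   zero rows when none.
#' @export
find_multiallelic_sites <- function(variants) {
  iv <- variant_interval(variants$chrom, variants$pos, variants$ref,
                         variants$alt, variants$class)
  ids <- variant_id(variants)
  out <- list()
  for (ch in unique(variants$chrom)) {
    k <- which(variants$chrom == ch)
    if (length(k) < 2) next
    k <- k[order(iv[k, "start"])]
    for (a in seq_along(k)[-length(k)]) {
      for (b in (a + 1):length(k)) {
        i <- k[a]; j <- k[b]
        if (iv[j, "start"] > iv[i, "end"]) break
        same_alt <- variants$alt[i] == variants$alt[j] &&
          variants$pos[i] == variants$pos[j] &&
          variants$ref[i] == variants$ref[j]
        if (!same_alt) out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0),
                      id1 = character(0), id2 = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], id1 = ids[m[, 1]], id2 = ids[m[, 2]],
             stringsAsFactors = FALSE)
}

# Per-tip genotype calls at a MAV locus from read counts, using the shared
# positive/negative subclade thresholds.  Values: ref / alt1 / alt2 / unknown.
mav_genotypes <- function(mtr1, dep1, mtr2, dep2, config = pipeline_config()) {
  vaf1 <- ifelse(dep1 > 0, mtr1 / dep1, 0)
  vaf2 <- ifelse(dep2 > 0, mtr2 / dep2, 0)
  pos1 <- mtr1 >= config$positive_subclade_min_reads & vaf1 >= config$positive_subclade_min_vaf
  pos2 <- mtr2 >= config$positive_subclade_min_reads & vaf2 >= config$positive_subclade_min_vaf
  neg1 <- mtr1 == 0 & dep1 >= config$negative_subclade_min_depth
  neg2 <- mtr2 == 0 & dep2 >= config$negative_subclade_min_depth
  g <- rep("unknown", length(mtr1))
  g[pos1 & !pos2] <- "alt1"
  g[pos2 & !pos1] <- "alt2"
  g[neg1 & neg2] <- "ref"
  names(g) <- names(mtr1)
  g
}

#' Classify a MAV pair as simple, separated or unrelated
#'
#' Hierarchical rule on the two branch assignments: branches sharing a parent
#' node give a *simple* MAV with that parent as lesion node; otherwise, if
#' one assigned branch lies within the clade of the other's parent, the pair
#' is *separated* with the encompassing parent as lesion node; everything
#' else -- including ancestor-nested assignments, which a single lesion on
#' one strand cannot generate -- is *unrelated*. Separated pairs whose lesion
#' path sheds two or more reference-only uniform subclades between the two
#' mutant subclades are reclassified unrelated (they are more probably two
#' independent mutations).
#'
#' @param tree phylogeny.
#' @param branch1,branch2 assigned branches (node labels or indexes).
#' @param genotypes optional named per-tip genotype vector with values
#'   `ref`/`alt1`/`alt2`/`unknown` used for path tracing; when `NULL` a
#'   noise-free genotype set is derived from the two assigned clades.
#' @param config a [pipeline_config()].
#' @return list: `category`, `lesion_node`, `repair_node`, `path`
#'   (node labels), `mmld`, `flag` (NA or a problem description).
#' @export
classify_mav <- function(tree, branch1, branch2, genotypes = NULL,
                         config = pipeline_config()) {
  idx <- as_index(tree)
  v1 <- resolve_node(idx, branch1); v2 <- resolve_node(idx, branch2)
  res <- list(category = "unrelated", lesion_node = NA_character_,
              repair_node = NA_character_, path = character(0),
              mmld = NA_real_, flag = NA_character_)
  if (v1 == v2) { res$flag <- "identical branches"; return(res) }
  if (v1 == idx$root || v2 == idx$root) return(res)      # stem: nested with all
  p1 <- idx$parent[v1]; p2 <- idx$parent[v2]
  if (is.null(genotypes)) {
    g <- rep("ref", idx$n)
    g[idx$tips_under[[v1]]] <- "alt1"
    g[idx$tips_under[[v2]]] <- "alt2"
    names(g) <- idx$labels[seq_len(idx$n)]
    genotypes <- g
  }
  if (p1 == p2) {
    res$category <- "simple"
    res$lesion_node <- idx$labels[p1]
    res$repair_node <- res$lesion_node
    res$path <- res$lesion_node
    res$mmld <- 0
    return(res)
  }
  if (is_within(idx, v1, v2) || is_within(idx, v2, v1)) return(res)
  cand <- integer(0)
  if (is_within(idx, v1, p2) && is_within(idx, v2, p2)) cand <- c(cand, p2)
  if (is_within(idx, v1, p1) && is_within(idx, v2, p1)) cand <- c(cand, p1)
  if (!length(cand)) return(res)
  lesion <- cand[which.min(lengths(idx$tips_under)[cand])]
  tr <- trace_mav_lesion_path(idx, idx$labels[lesion], genotypes)
  if (!is.na(tr$flag)) { res$flag <- tr$flag; return(res) }
  # reference-only uniform subclades shed between the first and last mutant
  # subclades along the path
  sub <- tr$subclades
  alt_d <- sub$depth[sub$allele %in% c("alt1", "alt2")]
  if (length(alt_d) >= 2) {
    n_ref_between <- sum(sub$allele == "ref" &
                           sub$depth >= min(alt_d) & sub$depth <= max(alt_d))
    if (n_ref_between >= 2) {
      res$flag <- "two or more intervening reference subclades"
      return(res)
    }
  }
  res$category <- "separated"
  res$lesion_node <- idx$labels[lesion]
  res$repair_node <- tr$repair_node
  res$path <- tr$path
  res$mmld <- mav_mmld_nodes(idx, res$lesion_node, res$repair_node)
  res
}

#' Trace the lesion path of a separated MAV
#'
#' Starting from the lesion node, descends stepwise through the unique child
#' whose clade contains at least two distinct alleles (the reference allele
#' counts; unknown genotypes are ignored), shedding uniform sibling subclades
#' on the way. The last node encompassing two different alleles is the lesion
#' repair node.
#'
#' @param tree phylogeny.
#' @param lesion_node the lesion node (label or index).
#' @param genotypes named per-tip genotype vector (`ref`/`alt1`/`alt2`/
#'   `unknown`).
#' @return list: `path` (labels from lesion node to repair node),
#'   `repair_node`, `subclades` (data.frame: node, allele, depth), `flag`
#'   (NA, or `"two mixed children"` when the configuration is inconsistent
#'   with a single lesion).
#' @export
trace_mav_lesion_path <- function(tree, lesion_node, genotypes) {
  idx <- as_index(tree)
  v <- resolve_node(idx, lesion_node)
  g <- genotypes[idx$labels[seq_len(idx$n)]]
  alleles_under <- function(u) unique(g[idx$tips_under[[u]]][
    g[idx$tips_under[[u]]] != "unknown"])
  path <- idx$labels[v]
  sub <- list()
  depth <- 0L
  repeat {
    depth <- depth + 1L
    kids <- idx$children[[v]]
    if (is.null(kids)) break                       # reached a tip
    al <- lapply(kids, alleles_under)
    mixed <- which(lengths(al) >= 2)
    uni <- which(lengths(al) == 1)
    for (u in uni) {
      sub[[length(sub) + 1]] <- data.frame(node = idx$labels[kids[u]],
                                           allele = al[[u]], depth = depth,
                                           stringsAsFactors = FALSE)
    }
    if (length(mixed) >= 2) {
      return(list(path = path, repair_node = NA_character_,
                  subclades = do.call(rbind, sub), flag = "two mixed children"))
    }
    if (length(mixed) == 0) break
    v <- kids[mixed]
    path <- c(path, idx$labels[v])
  }
  list(path = path, repair_node = path[length(path)],
       subclades = if (length(sub)) do.call(rbind, sub)
                   else data.frame(node = character(0), allele = character(0),
                                   depth = integer(0)),
       flag = NA_character_)
}

mav_mmld_nodes <- function(idx, lesion, repair) {
  molecular_time(idx, repair) - molecular_time(idx, lesion)
}

#' Minimum molecular lesion duration of a MAV
#'
#' Sum of branch lengths between the lesion node and the lesion repair node;
#' 0 for simple MAVs.
#'
#' @param mav a classification result from [classify_mav()].
#' @param tree phylogeny.
#' @return MMLD in mutations (NA for unrelated pairs).
#' @export
mav_mmld <- function(mav, tree) {
  if (mav$category == "simple") return(0)
  if (mav$category != "separated") return(NA_real_)
  mav_mmld_nodes(as_index(tree), mav$lesion_node, mav$repair_node)
}

#' MAVs per post-development node
#'
#' @param tree phylogeny.
#' @param mavs data.frame of classified MAVs (needs a `category` column) or a
#'   plain count of simple+separated MAVs.
#' @param config a [pipeline_config()].
#' @return rate, or NA (with a warning) when the tree has no
#'   post-development nodes.
#' @export
mavs_per_node <- function(tree, mavs, config = pipeline_config()) {
  n_mav <- if (is.data.frame(mavs)) sum(mavs$category %in% c("simple", "separated"))
           else as.numeric(mavs)
  n_node <- count_post_development_nodes(tree, config)
  if (n_node == 0) {
    warning("no post-development nodes; MAV rate undefined")
    return(NA_real_)
  }
  n_mav / n_node
}

#' MAV detection pipeline
#'
#' Finds multi-allelic candidate pairs, assigns each member variant to a
#' branch, derives per-tip genotypes from the read counts, and classifies
#' every pair.
#'
#' @param tree phylogeny.
#' @param vcm an [variant_call_matrix()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per candidate pair.
#' @export
detect_mav <- function(tree, vcm, config = pipeline_config()) {
  idx <- as_index(tree)
  cand <- find_multiallelic_sites(vcm$variants)
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    i <- cand$i[r]; j <- cand$j[r]
    a1 <- assign_branch(idx, vcm$mtr[i, ], vcm$dep[i, ], config)
    a2 <- assign_branch(idx, vcm$mtr[j, ], vcm$dep[j, ], config)
    g <- mav_genotypes(vcm$mtr[i, ], vcm$dep[i, ],
                       vcm$mtr[j, ], vcm$dep[j, ], config)
    cl <- classify_mav(idx, a1$branch, a2$branch, g, config)
    data.frame(id1 = cand$id1[r], id2 = cand$id2[r],
               branch1 = a1$branch, branch2 = a2$branch,
               category = cl$category, lesion_node = cl$lesion_node,
               repair_node = cl$repair_node, mmld = cl$mmld,
               flag = cl$flag, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      branch1 = character(0), branch2 = character(0),
                      category = character(0), lesion_node = character(0),
                      repair_node = character(0), mmld = numeric(0),
                      flag = character(0)))
  }
  do.call(rbind, rows)
}
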