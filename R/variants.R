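#' Construct a variant call matrix
#'
#' Couples a variant table (1-based VCF-style coordinates) with per-sample
#' variant-read (MTR) and total-depth (DEP) matrices.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `class` (one of `"SNV"`, `"indel"`, `"MNV"`); an optional
#'   `context` column holds the trinucleotide context of SNVs.
#' @param mtr,dep integer matrices, variants x samples, with identical
#'   dimnames; `0 <= mtr <= dep` elementwise.
#' @param tree optional phylogeny; when given, the sample set must equal the
#'   tip set.
#' @return an object of class `lp_vcm`.
#' @export
variant_call_matrix <- function(variants, mtr, dep, tree = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "class")
  if (!all(need %in% names(variants)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  if (!all(variants$class %in% c("SNV", "indel", "MNV")))
    stop("variant class must be SNV, indel or MNV")
  mtr <- as.matrix(mtr); dep <- as.matrix(dep)
  if (!identical(dim(mtr), dim(dep))) stop("MTR/DEP dimensions differ")
  if (nrow(mtr) != nrow(variants)) stop("matrix rows must match variant table")
  if (is.null(colnames(mtr)) || !identical(colnames(mtr), colnames(dep)))
    stop("MTR/DEP need identical sample (column) names")
  if (any(mtr < 0) || any(dep < 0) || any(mtr > dep))
    stop("need 0 <= MTR <= DEP elementwise")
  if (!is.null(tree)) {
    tips <- if (inherits(tree, "phylo")) tree$tip.label else tree$labels[seq_len(tree$n)]
    if (!setequal(colnames(mtr), tips))
      stop("sample set must equal the phylogeny tip set")
  }
  if (is.null(rownames(mtr)))
    rownames(mtr) <- rownames(dep) <- variant_id(variants)
  structure(list(variants = variants, mtr = mtr, dep = dep), class = "lp_vcm")
}

variant_id <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' @export
print.lp_vcm <- function(x, ...) {
  cat(sprintf("lp_vcm: %d variants x %d samples (%s)\n",
              nrow(x$variants), ncol(x$mtr),
              paste(names(table(x$variants$class)), table(x$variants$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read / write the variant table and count matrices
#'
#' Plain-TSV external representation: the variant table has the header
#' `chrom pos ref alt class` (optional `context`), the MTR/DEP matrices are
#' variants x samples with a header row of sample names.
#'
#' @param variants_tsv,mtr_tsv,dep_tsv file paths.
#' @param tree optional phylogeny for sample-set validation.
#' @return an `lp_vcm`.
#' @export
read_variant_data <- function(variants_tsv, mtr_tsv, dep_tsv, tree = NULL) {
  v <- read.delim(variants_tsv, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(read.delim(mtr_tsv, check.names = FALSE))
  d <- as.matrix(read.delim(dep_tsv, check.names = FALSE))
  variant_call_matrix(v, m, d, tree)
}

#' @rdname read_variant_data
#' @param vcm an `lp_vcm`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_variant_data <- function(vcm, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, f))
  write.table(vcm$variants, p("variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(vcm$mtr, p("mtr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(vcm$dep, p("dep.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p("variants.tsv"), p("mtr.tsv"), p("dep.tsv")))
}

# Reference-coordinate interval occupied by a variant (1-based inclusive).
# SNV: the single base; deletion/MNV: the changed reference stretch starting
# at `pos`; insertions occupy the anchor base only.
variant_interval <- function(chrom, pos, ref, alt, class) {
  end <- pos + pmax(nchar(ref), 1L) - 1L
  cbind(start = pos, end = end)
}
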