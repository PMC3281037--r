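#' Genotype matrix container
#'
#' SNP dosages in \{0,1,2\} (minor-allele counts) with positions and minor
#' allele frequencies. The stored `maf` is the folded allele frequency
#' computed from the dosage matrix itself, so the two always agree.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, and
#'   optionally `maf` (recomputed from dosages if absent).
#' @param dosage numeric matrix SNPs x samples with values in \{0,1,2\};
#'   rownames must match `snp_id`, colnames are sample ids.
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(snps, dosage) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  dosage <- as.matrix(dosage)
  if (nrow(snps) != nrow(dosage)) stop("snps and dosage row counts differ")
  if (is.null(rownames(dosage))) rownames(dosage) <- snps$snp_id
  if (nrow(dosage) > 0 &&
      !identical(rownames(dosage), as.character(snps$snp_id)))
    stop("dosage rownames must equal snp ids")
  f <- rowMeans(dosage) / 2
  snps$maf <- pmin(f, 1 - f)
  structure(list(snps = snps, dosage = dosage), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$snps), "SNPs x", ncol(x$dosage), "samples\n")
  cat("  MAF range:", paste(signif(range(x$snps$maf), 3), collapse = " - "), "\n")
  invisible(x)
}

subset_snps <- function(geno, keep) {
  geno_matrix(geno$snps[keep, , drop = FALSE], geno$dosage[keep, , drop = FALSE])
}

#' Expression matrix container
#'
#' Real-valued features x samples matrix together with feature metadata
#' (owning gene, exon index, genomic interval, platform) and sample metadata
#' (population, sex).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param features data.frame with columns `feature_id`, `gene_id`,
#'   `exon_index`, `chrom`, `start`, `end`, `platform` (missing metadata
#'   columns are filled with NA).
#' @param samples data.frame with columns `sample_id`, `population`, `sex`.
#' @return Object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, features, samples) {
  values <- as.matrix(values)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (cn in c("gene_id", "exon_index", "chrom", "start", "end", "platform"))
    if (is.null(features[[cn]])) features[[cn]] <- NA
  if (anyDuplicated(features$feature_id)) stop("duplicated feature ids")
  if (nrow(features) != nrow(values)) stop("features and values row counts differ")
  if (nrow(samples) != ncol(values)) stop("samples and values column counts differ")
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, features = features, samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "features x", ncol(x$values), "samples\n")
  pl <- unique(x$features$platform)
  cat("  platform:", paste(pl, collapse = ", "),
      "| populations:", paste(unique(x$samples$population), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix to a set of samples
#'
#' @param expr an [expr_matrix()].
#' @param sample_ids character vector of sample ids to keep.
#' @return An `expr_matrix` restricted to those samples.
#' @export
subset_samples <- function(expr, sample_ids) {
  keep <- expr$samples$sample_id %in% sample_ids
  expr_matrix(expr$values[, keep, drop = FALSE], expr$features,
              expr$samples[keep, , drop = FALSE])
}

# genotype matrix restricted to a sample subset (MAF recomputed there)
subset_geno_samples <- function(geno, sample_ids) {
  keep <- colnames(geno$dosage) %in% sample_ids
  geno_matrix(geno$snps[, c("snp_id", "chrom", "pos")],
              geno$dosage[, keep, drop = FALSE])
}

#' Subset an expression matrix to a set of features
#'
#' Retained features keep their original order.
#'
#' @param expr an [expr_matrix()].
#' @param feature_ids character vector of feature ids to keep.
#' @return An `expr_matrix` with the retained features.
#' @export
subset_features <- function(expr, feature_ids) {
  keep <- expr$features$feature_id %in% feature_ids
  expr_matrix(expr$values[keep, , drop = FALSE],
              expr$features[keep, , drop = FALSE],
              expr$samples)
}
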