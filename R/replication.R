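#' Classify an eQTN into one of five exclusive positional categories
#'
#' Categories relative to the target gene: `first`, `internal`, `last`
#' (exon membership in transcription order), `intron`, `intergenic`.
#' In a single-exon gene the exon counts as `last` (the exon ending at the
#' TES).
#'
#' @param pos SNP position (bp).
#' @param gene one-row gene record (from a [gene_models()] `genes` table).
#' @param exons the gene's exon table.
#' @return Character scalar: the category.
#' @export
classify_eqtn_category <- function(pos, gene, exons) {
  ann <- annotate_snps(pos, gene, exons)
  if (ann$last_exon) "last"
  else if (ann$first_exon) "first"
  else if (ann$internal_exon) "internal"
  else if (ann$intron) "intron"
  else "intergenic"
}

# vectorized categorization of an assignment table
categorize_eqtns <- function(assignments, genes) {
  vapply(seq_len(nrow(assignments)), function(i) {
    gene <- gene_record(genes, assignments$gene_id[i])
    ex <- gene_exons(genes, assignments$gene_id[i])
    classify_eqtn_category(assignments$pos[i], gene, ex)
  }, character(1))
}

#' Test platform-A eQTNs in platform-B data at gene and exon level
#'
#' For each eQTN: a gene-level association test against the identified
#' gene's expression in the second platform, and one exon-level test per
#' exon residual of that gene lying within 10 kb of the eQTN (each treated
#' as an independent test). Samples are the intersection of the second
#' platform's samples with the genotyped samples.
#'
#' @param eqtns data.frame of eQTNs with `gene_id`, `snp_id`, and
#'   `category` (see [categorize_eqtns()]).
#' @param gene_expr second-platform gene-level [expr_matrix()]
#'   (feature ids = gene ids).
#' @param exon_res second-platform exon-residual [expr_matrix()] (from
#'   [exon_residual_matrix()]; intervals are exon intervals).
#' @param genotypes a [geno_matrix()].
#' @return Replication table: data.frame with `gene_id`, `snp_id`,
#'   `category`, `level` (`"gene"`/`"exon"`), `feature_id`, `p`, `missing`.
#' @export
cross_platform_test <- function(eqtns, gene_expr, exon_res, genotypes) {
  shared <- intersect(colnames(gene_expr$values), colnames(genotypes$dosage))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  out <- vector("list", nrow(eqtns))
  for (i in seq_len(nrow(eqtns))) {
    gid <- eqtns$gene_id[i]; snp <- eqtns$snp_id[i]
    g <- genotypes$dosage[snp, shared]
    rows <- list()
    gi <- which(gene_expr$features$gene_id == gid)
    if (length(gi) == 0) {
      rows$gene <- data.frame(level = "gene", feature_id = NA_character_,
                              p = NA_real_, missing = TRUE)
    } else {
      p <- tryCatch(test_association(gene_expr$values[gi[1], shared], g)$p,
                    error = function(e) NA_real_)
      rows$gene <- data.frame(level = "gene",
                              feature_id = gene_expr$features$feature_id[gi[1]],
                              p = p, missing = FALSE)
    }
    pos <- genotypes$snps$pos[match(snp, genotypes$snps$snp_id)]
    ef <- exon_res$features
    near <- which(ef$gene_id == gid &
                    pos >= ef$start - 10000 & pos < ef$end + 10000)
    if (length(near)) {
      pe <- vapply(near, function(r)
        tryCatch(test_association(exon_res$values[r, shared], g)$p,
                 error = function(e) NA_real_), numeric(1))
      rows$exon <- data.frame(level = "exon", feature_id = ef$feature_id[near],
                              p = pe, missing = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$gene_id <- gid; tab$snp_id <- snp; tab$category <- eqtns$category[i]
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "snp_id", "category", "level", "feature_id", "p",
          "missing")]
}

#' QQ summary of replication p-values by category
#'
#' Observed order statistics of -log10(p) against uniform expectations
#' `-log10((i - 0.5) / n)` per category.
#'
#' @param p numeric vector of p-values.
#' @param category factor/character of the same length.
#' @return data.frame with `category`, `expected`, `observed`, `n`.
#' @export
qq_summary <- function(p, category) {
  category <- as.factor(category)
  ok <- !is.na(p)
  p <- p[ok]; category <- category[ok]
  out <- lapply(split(p, category), function(pp) {
    n <- length(pp)
    if (n == 0) return(NULL)   # category emptied by NA removal
    data.frame(expected = -log10((seq_len(n) - 0.5) / n),
               observed = sort(-log10(pp), decreasing = TRUE), n = n)
  })
  empty <- names(out)[vapply(out, is.null, logical(1))]
  if (length(empty)) message("empty categories skipped: ",
                             paste(empty, collapse = ", "))
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, Map(cbind, category = names(out), out))
  rownames(res) <- NULL
  res
}

#' Restrict platform-A probes to exons shared with platform B
#'
#' Keeps every A feature whose (gene, exon) pair hosts at least one B
#' feature — the shared-exon filtering experiment: restricting a uniform
#' per-exon platform to the exons probed by a 3'-biased platform
#' concentrates the retained probes in last exons.
#'
#' @param features_a,features_b feature data.frames (or [expr_matrix()]s)
#'   carrying `gene_id` and `exon_index`.
#' @return Character vector of retained A feature ids (original order).
#' @export
restrict_to_shared_exons <- function(features_a, features_b) {
  if (inherits(features_a, "expr_matrix")) features_a <- features_a$features
  if (inherits(features_b, "expr_matrix")) features_b <- features_b$features
  key_a <- paste(features_a$gene_id, features_a$exon_index)
  key_b <- unique(paste(features_b$gene_id, features_b$exon_index))
  features_a$feature_id[key_a %in% key_b]
}
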