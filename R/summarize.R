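#' Median polish of a two-way layout
#'
#' Fits the additive model `value = overall + row + column + residual`
#' robustly by iteratively removing row medians then column medians (rows
#' first), with medians of the effect vectors absorbed into the overall
#' term. Convergence: maximum absolute change in fitted values below `tol`,
#' with an iteration cap. The decomposition identity
#' `input = overall + row + column + residual` holds exactly at every
#' iteration.
#'
#' @param x numeric matrix (at least 1 x 1, finite entries).
#' @param tol convergence tolerance on fitted values.
#' @param max_iter iteration cap.
#' @param center_rows absorb the median of the row effects into the overall
#'   term (default). Disabling it leaves the row effects uncentered, so the
#'   overall + column-effect profile is exactly unaffected by a constant
#'   shift of any single row.
#' @return Object of class `median_polish`: list with `overall`, `row`,
#'   `col`, `residuals`, `iterations`, `converged`.
#' @export
median_polish <- function(x, tol = 1e-6, max_iter = 100, center_rows = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite entries")
  nr <- nrow(x); nc <- ncol(x)
  overall <- 0
  row_eff <- rep(0, nr)
  col_eff <- rep(0, nc)
  r <- x
  fitted_old <- matrix(0, nr, nc)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    rd <- apply(r, 1, median)
    r <- r - rd
    row_eff <- row_eff + rd
    d <- median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    cd <- apply(r, 2, median)
    r <- sweep(r, 2, cd)
    col_eff <- col_eff + cd
    if (center_rows) {
      d <- median(row_eff)
      row_eff <- row_eff - d
      overall <- overall + d
    }
    fitted <- overall + outer(row_eff, col_eff, "+")
    if (max(abs(fitted - fitted_old)) < tol) { converged <- TRUE; break }
    fitted_old <- fitted
  }
  structure(list(overall = overall, row = row_eff, col = col_eff,
                 residuals = r, iterations = iter, converged = converged),
            class = "median_polish")
}

#' @export
print.median_polish <- function(x, ...) {
  cat("median_polish:", length(x$row), "rows x", length(x$col), "columns;",
      x$iterations, "iterations", if (x$converged) "(converged)" else
        "(iteration cap reached)", "\n")
  cat("  overall:", format(x$overall, digits = 6), "\n")
  invisible(x)
}

# polish a gene's features-x-samples block (probes/exons in rows, samples
# in columns). The probe dimension is swept first, so a constant offset on
# any single probe (its affinity) is absorbed into that probe's effect
# exactly and can never leak into the gene level. Optionally polishes
# within exons first.
polish_gene <- function(values, exon_index = NULL, strategy = c("gene", "exon_first"),
                        tol = 1e-6, max_iter = 100) {
  strategy <- match.arg(strategy)
  if (strategy == "exon_first" && !is.null(exon_index) &&
      length(unique(exon_index)) < length(exon_index)) {
    # summarize probes to exon level first, then polish exons x samples
    ex_levels <- unique(exon_index)
    exmat <- t(vapply(ex_levels, function(e) {
      block <- values[exon_index == e, , drop = FALSE]
      mp <- median_polish(block, tol, max_iter, center_rows = FALSE)
      mp$overall + mp$col
    }, numeric(ncol(values))))
    median_polish(exmat, tol, max_iter, center_rows = FALSE)
  } else {
    median_polish(values, tol, max_iter, center_rows = FALSE)
  }
}

#' Gene-level expression by median polish
#'
#' The gene's probes/exons x samples matrix is median polished and the
#' gene level of sample i is the overall term plus sample i's effect. The
#' probe dimension is swept first and its effect vector is left uncentered,
#' so per-probe affinity offsets are absorbed into the probe effects
#' exactly: adding a constant to any single probe leaves the gene levels
#' unchanged. A single-probe gene's levels are that probe's values.
#'
#' @param values numeric matrix, the gene's features (probes or exons) in
#'   rows and samples in columns.
#' @param exon_index optional per-feature exon index (used by the
#'   `exon_first` strategy).
#' @param strategy `"gene"` (one polish over all probes, default) or
#'   `"exon_first"` (summarize probes to exons first, then polish).
#' @return Numeric vector of per-sample gene expression levels.
#' @export
gene_expression <- function(values, exon_index = NULL,
                            strategy = c("gene", "exon_first")) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("gene has no expression features")
  if (nrow(values) == 1) return(as.vector(values))  # the probe is the gene
  mp <- polish_gene(values, exon_index, strategy)
  mp$overall + mp$col
}

#' Exon-specific expression as median-polish residuals
#'
#' Residuals of the gene-level median polish, indexed by exon and sample;
#' a shared (gene-level) genetic effect is absorbed into the sample
#' effects while exon-specific effects remain in the residuals.
#'
#' @param values numeric matrix, the gene's exons in rows, samples in
#'   columns; at least 2 exons.
#' @return Numeric matrix (exons x samples) of exon-specific levels.
#' @export
exon_residuals <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2)
    stop("sQTN analysis requires at least 2 exons with expression measurements")
  polish_gene(values)$residuals
}

#' Summarize an exon/probe-level matrix to gene level
#'
#' @param expr an [expr_matrix()] of exon- or probe-level features.
#' @param genes a [gene_models()] object (for gene spans in the output
#'   feature metadata).
#' @param strategy passed to [gene_expression()].
#' @return An [expr_matrix()] with one feature per gene (interval = the
#'   transcript span), platform suffixed with `"_gene"`.
#' @export
summarize_genes <- function(expr, genes,
                            strategy = c("gene", "exon_first")) {
  strategy <- match.arg(strategy)
  feats <- expr$features
  gids <- unique(feats$gene_id)
  vals <- matrix(0, length(gids), ncol(expr$values))
  for (i in seq_along(gids)) {
    rows <- which(feats$gene_id == gids[i])
    vals[i, ] <- gene_expression(expr$values[rows, , drop = FALSE],
                                 feats$exon_index[rows], strategy)
  }
  g <- genes$genes[match(gids, genes$genes$gene_id), ]
  features <- data.frame(feature_id = gids, gene_id = gids, exon_index = NA,
                         chrom = g$chrom, start = g$tx_start, end = g$tx_end,
                         platform = paste0(feats$platform[1], "_gene"),
                         stringsAsFactors = FALSE)
  expr_matrix(vals, features, expr$samples)
}

#' Exon-specific expression matrix for sQTN mapping
#'
#' Applies [exon_residuals()] gene by gene; only genes with at least
#' `min_exons` measured exons are retained (single-exon genes are excluded
#' from the splicing analysis). Feature intervals are reset to the exon
#' intervals from the gene models so that the 10 kb exon windows apply.
#'
#' @param expr an [expr_matrix()] of exon-level features (one feature per
#'   exon).
#' @param genes a [gene_models()] object.
#' @param min_exons minimum measured exons per gene (default 2).
#' @return An [expr_matrix()] of exon residuals, platform suffixed
#'   `"_exonres"`.
#' @export
exon_residual_matrix <- function(expr, genes, min_exons = 2) {
  feats <- expr$features
  counts <- table(feats$gene_id)
  keep_genes <- names(counts)[counts >= min_exons]
  rows_all <- which(feats$gene_id %in% keep_genes)
  vals <- expr$values[rows_all, , drop = FALSE]
  f <- feats[rows_all, , drop = FALSE]
  for (gid in keep_genes) {
    rows <- which(f$gene_id == gid)
    vals[rows, ] <- exon_residuals(vals[rows, , drop = FALSE])
  }
  key <- paste(f$gene_id, f$exon_index)
  ex <- genes$exons
  mi <- match(key, paste(ex$gene_id, ex$exon_index))
  f$start <- ex$start[mi]
  f$end <- ex$end[mi]
  f$platform <- paste0(f$platform[1], "_exonres")
  expr_matrix(vals, f, expr$samples)
}
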