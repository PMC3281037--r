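#' Candidate cis SNPs for a feature
#'
#' Gene level: SNPs inside the transcript or within 100 kb of either end.
#' Exon level: SNPs within 10 kb of either exon end. Regions are half-open
#' (`[start - w, end + w)`), floored at 0.
#'
#' @param feature list or one-row data.frame with `chrom`, `start`, `end`.
#' @param genotypes a [geno_matrix()].
#' @param level `"gene"` (100 kb window) or `"exon"` (10 kb window).
#' @param window override the window size in bp.
#' @return Character vector of candidate SNP ids (possibly empty).
#' @export
cis_window_snps <- function(feature, genotypes, level = c("gene", "exon"),
                            window = NULL) {
  level <- match.arg(level)
  w <- if (!is.null(window)) window else if (level == "gene") 100000 else 10000
  lo <- max(0, feature$start - w)
  hi <- feature$end + w
  sel <- genotypes$snps$chrom == feature$chrom &
    genotypes$snps$pos >= lo & genotypes$snps$pos < hi
  genotypes$snps$snp_id[sel]
}

#' Single-SNP association test
#'
#' Ordinary least squares of a sample phenotype on a dosage vector, with the
#' two-sided p-value from the t distribution on n-2 degrees of freedom.
#' Pairs with a missing value in either vector are dropped first.
#'
#' @param y numeric phenotype vector.
#' @param g numeric dosage vector of the same length.
#' @return data.frame with `slope`, `se`, `t`, `p`, `n`, `perfect_fit`.
#' @export
test_association <- function(y, g) {
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations")
  if (var(g) == 0) stop("monomorphic dosage")
  st <- assoc_scan(matrix(g, nrow = 1), y)
  data.frame(slope = st$slope, se = st$se, t = st$t, p = st$p, n = n,
             perfect_fit = st$perfect_fit)
}

# vectorized OLS of y against every row of G; returns per-SNP statistics.
# sigma2 <= 0 (within rounding) marks a perfect fit: p = 0, flagged.
assoc_scan <- function(G, y) {
  n <- length(y)
  y0 <- y - mean(y)
  G0 <- G - rowMeans(G)
  sxx <- rowSums(G0^2)
  syy <- sum(y0^2)
  sxy <- as.vector(G0 %*% y0)
  mono <- sxx == 0
  slope <- ifelse(mono, NA_real_, sxy / sxx)
  sigma2 <- (syy - slope * sxy) / (n - 2)
  perfect <- !mono & sigma2 <= 1e-12 * syy / (n - 2)
  se <- sqrt(pmax(sigma2, 0) / sxx)
  tt <- slope / se
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[perfect] <- 0
  tt[perfect] <- ifelse(slope[perfect] >= 0, Inf, -Inf)
  se[perfect] <- 0
  list(slope = slope, se = se, t = tt, p = p, monomorphic = mono,
       perfect_fit = perfect)
}

# binary-search lookup over per-chromosome sorted positions; returns a
# function(chrom, lo, hi) giving row indices with pos in [lo, hi)
snp_lookup <- function(genotypes) {
  by_chrom <- split(seq_len(nrow(genotypes$snps)), genotypes$snps$chrom)
  by_chrom <- lapply(by_chrom, function(i)
    i[order(genotypes$snps$pos[i])])
  pos <- genotypes$snps$pos
  function(chrom, lo, hi) {
    idx <- by_chrom[[chrom]]
    if (is.null(idx)) return(integer(0))
    p <- pos[idx]
    from <- findInterval(lo - 0.5, p) + 1L
    to <- findInterval(hi - 0.5, p)
    if (from > to) integer(0) else idx[from:to]
  }
}

# candidate SNP row indices per feature (list), using the level's window
candidate_index <- function(features, genotypes, level, window = NULL) {
  w <- if (!is.null(window)) window else if (level == "gene") 100000 else 10000
  look <- snp_lookup(genotypes)
  lapply(seq_len(nrow(features)), function(i) {
    look(features$chrom[i], max(0, features$start[i] - w),
         features$end[i] + w)
  })
}

# minimum valid p per feature for a (possibly permuted) value matrix
feature_min_p <- function(values, dosage, cand) {
  vapply(seq_along(cand), function(i) {
    idx <- cand[[i]]
    if (length(idx) == 0) return(NA_real_)
    st <- assoc_scan(dosage[idx, , drop = FALSE], values[i, ])
    p <- st$p[!st$monomorphic]
    if (length(p) == 0) NA_real_ else min(p)
  }, numeric(1))
}

#' Exhaustive cis-window association mapping
#'
#' Tests every candidate SNP against every feature with standard linear
#' regression. At the exon level each exon is windowed and tested
#' independently; no per-gene aggregation is applied. Expression is assumed
#' already normalized and confounder-corrected.
#'
#' @param expr an [expr_matrix()] (features at the chosen level).
#' @param genotypes a [geno_matrix()].
#' @param level `"gene"` or `"exon"` (sets the default window).
#' @param window override window size in bp.
#' @return Object of class `cis_map`: list with `results` (per-test rows:
#'   `feature_id`, `gene_id`, `snp_id`, `slope`, `se`, `t`, `p`, `n`,
#'   `monomorphic`, `perfect_fit`), `min_p` (per-feature minimum valid p;
#'   features with an empty candidate set are absent and listed in
#'   `skipped`), plus the `level` and `window` used.
#' @export
map_cis_qtls <- function(expr, genotypes, level = c("gene", "exon"),
                         window = NULL) {
  level <- match.arg(level)
  feats <- expr$features
  cand <- candidate_index(feats, genotypes, level, window)
  res <- vector("list", nrow(feats))
  minp <- rep(NA_real_, nrow(feats))
  n <- ncol(expr$values)
  for (i in seq_len(nrow(feats))) {
    idx <- cand[[i]]
    if (length(idx) == 0) next
    st <- assoc_scan(genotypes$dosage[idx, , drop = FALSE], expr$values[i, ])
    res[[i]] <- data.frame(feature_id = feats$feature_id[i],
                           gene_id = feats$gene_id[i],
                           snp_id = genotypes$snps$snp_id[idx],
                           slope = st$slope, se = st$se, t = st$t, p = st$p,
                           n = n, monomorphic = st$monomorphic,
                           perfect_fit = st$perfect_fit,
                           stringsAsFactors = FALSE)
    ok <- !st$monomorphic
    if (any(ok)) minp[i] <- min(st$p[ok])
  }
  have <- !vapply(res, is.null, logical(1)) & !is.na(minp)
  min_p <- data.frame(feature_id = feats$feature_id[have],
                      gene_id = feats$gene_id[have],
                      min_p = minp[have], stringsAsFactors = FALSE)
  skipped <- feats$feature_id[!have]
  if (length(skipped)) message(length(skipped), " feature(s) had no valid test")
  structure(list(results = do.call(rbind, res[have]), min_p = min_p,
                 skipped = skipped, level = level,
                 window = if (!is.null(window)) window
                          else if (level == "gene") 100000 else 10000),
            class = "cis_map")
}

#' @export
print.cis_map <- function(x, ...) {
  cat("cis_map (", x$level, " level, window ", x$window, " bp): ",
      nrow(x$min_p), " features, ", nrow(x$results), " tests\n", sep = "")
  invisible(x)
}

#' Tie-shared best-SNP (eQTN) weights for one feature
#'
#' All SNPs attaining the exact minimum p-value (ties compared after
#' rounding to 12 significant digits) share the probability of being the
#' major eQTN equally.
#'
#' @param results per-test rows for one feature (as in `cis_map$results`).
#' @return data.frame `snp_id`, `weight` (summing to 1 over the tied best
#'   set, 0 elsewhere), `min_p`.
#' @export
best_snp_weights <- function(results) {
  ok <- !results$monomorphic
  if (!any(ok)) stop("no valid test")
  p <- signif(results$p, 12)
  pmin_ <- min(p[ok])
  best <- ok & p == pmin_
  data.frame(snp_id = results$snp_id, weight = ifelse(best, 1 / sum(best), 0),
             min_p = min(results$p[ok]), stringsAsFactors = FALSE)
}

#' eQTN assignments for a set of significant features
#'
#' @param map a `cis_map` from [map_cis_qtls()].
#' @param feature_ids features to assign (typically the significant set from
#'   [empirical_fdr_threshold()]); defaults to all mapped features.
#' @return data.frame with columns `feature_id`, `gene_id`, `snp_id`,
#'   `weight`, `min_p`; only rows with positive weight are kept.
#' @export
eqtn_assignments <- function(map, feature_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- map$min_p$feature_id
  res <- map$results[map$results$feature_id %in% feature_ids, , drop = FALSE]
  out <- lapply(split(res, res$feature_id), function(r) {
    w <- best_snp_weights(r)
    keep <- w$weight > 0
    data.frame(feature_id = r$feature_id[1], gene_id = r$gene_id[1],
               snp_id = w$snp_id[keep], weight = w$weight[keep],
               min_p = w$min_p[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$feature_id, feature_ids)), , drop = FALSE]
}

#' Permutation-based empirical FDR threshold
#'
#' The null distribution of per-feature minimum p-values is built by
#' permuting sample labels of the expression matrix within population
#' (jointly across features, preserving their correlation) and re-running
#' the cis scan. `FDR(t)` = (mean null count of min-p <= t) / (observed
#' count <= t); the cutoff is the largest observed min-p with
#' `FDR(t) <= target`.
#'
#' @param expr an [expr_matrix()].
#' @param genotypes a [geno_matrix()].
#' @param level `"gene"` or `"exon"`.
#' @param n_perm number of permutations (>= 1).
#' @param target FDR target (default 0.05).
#' @param seed integer seed for the permutations.
#' @param map optionally a precomputed `cis_map` for `expr` (saves the
#'   observed scan).
#' @param window override window size in bp.
#' @return Object of class `fdr_result`: list with `cutoff` (NA if no
#'   feature passes), `significant` (feature ids), `fdr_table`, `n_perm`,
#'   `target`, and the observed `map`.
#' @export
empirical_fdr_threshold <- function(expr, genotypes, level = c("gene", "exon"),
                                    n_perm = 10, target = 0.05, seed = 1L,
                                    map = NULL, window = NULL) {
  level <- match.arg(level)
  stopifnot(n_perm >= 1)
  if (is.null(map)) map <- map_cis_qtls(expr, genotypes, level, window)
  cand <- candidate_index(expr$features, genotypes, level, window)
  obs <- setNames(rep(NA_real_, nrow(expr$features)), expr$features$feature_id)
  obs[map$min_p$feature_id] <- map$min_p$min_p
  obs_p <- obs[!is.na(obs)]
  set.seed(seed)
  pop <- expr$samples$population
  null_p <- numeric(0)
  for (b in seq_len(n_perm)) {
    perm <- stats::ave(seq_along(pop), pop, FUN = sample)
    np <- feature_min_p(expr$values[, perm, drop = FALSE], genotypes$dosage, cand)
    null_p <- c(null_p, np[!is.na(np)])
  }
  ts <- sort(unique(obs_p))
  n_obs <- vapply(ts, function(t) sum(obs_p <= t), numeric(1))
  n_null <- (1 + vapply(ts, function(t) sum(null_p <= t), numeric(1))) /
    (n_perm + 1)
  fdr <- n_null / n_obs
  fdr_table <- data.frame(threshold = ts, n_observed = n_obs,
                          mean_null = n_null, fdr = fdr)
  pass <- which(fdr <= target)
  cutoff <- if (length(pass)) max(ts[pass]) else NA_real_
  significant <- if (is.na(cutoff)) character(0) else
    names(obs_p)[obs_p <= cutoff]
  structure(list(cutoff = cutoff, significant = significant,
                 fdr_table = fdr_table, n_perm = n_perm, target = target,
                 map = map),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("empirical FDR at target", x$target, "(", x$n_perm, "permutations )\n")
  if (is.na(x$cutoff)) cat("  no feature passes; cutoff undefined\n")
  else cat("  cutoff p <=", format(x$cutoff, digits = 4), ":",
           length(x$significant), "significant features\n")
  invisible(x)
}
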