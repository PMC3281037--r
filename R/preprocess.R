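#' Remove features whose footprint overlaps a known variant
#'
#' A feature is dropped iff any variant position (or interval) intersects
#' its half-open genomic interval `[start, end)`. Retained features keep
#' their original order.
#'
#' @param features feature data.frame (needs `feature_id`, `chrom`, `start`,
#'   `end`) or an [expr_matrix()].
#' @param variants data.frame with `chrom` and `pos` (point variants) and
#'   optionally `end` for interval variants (half-open, e.g. indels/CNVs).
#' @return Character vector of retained feature ids.
#' @export
filter_probes_overlapping_variants <- function(features, variants) {
  if (inherits(features, "expr_matrix")) features <- features$features
  if (any(is.na(features$start) | is.na(features$end)))
    stop("features lack genomic intervals: ",
         paste(features$feature_id[is.na(features$start) | is.na(features$end)],
               collapse = ", "))
  if (is.null(variants) || nrow(variants) == 0) return(features$feature_id)
  v_start <- variants$pos
  v_end <- if (!is.null(variants$end)) variants$end else variants$pos + 1
  drop <- vapply(seq_len(nrow(features)), function(i) {
    any(variants$chrom == features$chrom[i] &
          v_start < features$end[i] & v_end > features$start[i])
  }, logical(1))
  features$feature_id[!drop]
}

#' Remove non-expressed features
#'
#' Three platform-appropriate rules:
#' * `mad`: drop features whose median absolute deviation (across all
#'   samples) is below `threshold`; by default the threshold is the 25th
#'   percentile of all feature MADs (the low-MAD population of probes).
#' * `median_level`: drop a feature iff its median is below `threshold`
#'   within every population.
#' * `zero_median_count`: drop a feature iff its within-population median
#'   count is 0 in every population.
#'
#' @param expr an [expr_matrix()].
#' @param method filtering rule (see above).
#' @param threshold numeric cutoff; required for `median_level`, optional
#'   for `mad`.
#' @return Character vector of retained feature ids (original order).
#' @export
filter_non_expressed <- function(expr,
                                 method = c("mad", "median_level",
                                            "zero_median_count"),
                                 threshold = NULL) {
  method <- match.arg(method)
  v <- expr$values
  pop <- expr$samples$population
  if (method == "mad") {
    m <- apply(v, 1, mad)
    if (is.null(threshold)) threshold <- quantile(m, 0.25)
    keep <- m >= threshold
  } else if (method == "median_level") {
    if (is.null(threshold)) stop("median_level requires a threshold")
    med <- vapply(unique(pop), function(p)
      apply(v[, pop == p, drop = FALSE], 1, median), numeric(nrow(v)))
    keep <- apply(med >= threshold, 1, any)
  } else {
    med <- vapply(unique(pop), function(p)
      apply(v[, pop == p, drop = FALSE], 1, median), numeric(nrow(v)))
    keep <- apply(med > 0, 1, any)
  }
  expr$features$feature_id[keep]
}

#' Quantile normalize to a standard normal within populations
#'
#' Within each population, each feature's values are replaced by normal
#' scores `qnorm(rank / (n + 1))`; ties receive the average of their rank
#' scores.
#'
#' @param expr an [expr_matrix()].
#' @return An [expr_matrix()] of normal scores.
#' @export
quantile_normalize <- function(expr) {
  pop <- expr$samples$population
  v <- expr$values
  for (p in unique(pop)) {
    cols <- pop == p
    n <- sum(cols)
    if (n < 2) stop("population ", p, " has fewer than 2 samples")
    v[, cols] <- t(apply(v[, cols, drop = FALSE], 1, function(x)
      qnorm(rank(x, ties.method = "average") / (n + 1))))
  }
  expr_matrix(v, expr$features, expr$samples)
}

#' Center expression by population mean
#'
#' Subtracts, per feature, the mean within each population, bringing all
#' populations to mean zero.
#'
#' @param expr an [expr_matrix()].
#' @return An [expr_matrix()] with population means removed.
#' @export
center_by_population <- function(expr) {
  pop <- expr$samples$population
  v <- expr$values
  for (p in unique(pop)) {
    cols <- pop == p
    v[, cols] <- v[, cols, drop = FALSE] -
      rowMeans(v[, cols, drop = FALSE])
  }
  expr_matrix(v, expr$features, expr$samples)
}

#' Select the number of expression PCs by a permutation eigenvalue null
#'
#' Principal components are computed on the (feature-centered) expression
#' matrix with samples as observations. The null eigenvalue distribution is
#' built by independently permuting each feature's values across samples
#' (destroying inter-feature correlation, preserving marginals) and
#' re-computing the eigenvalues. K is the length of the leading contiguous
#' run of observed eigenvalues exceeding the per-rank upper envelope (the
#' "last PC" whose observed eigenvalue exceeds the null, reading the run
#' from the top).
#'
#' @param expr an [expr_matrix()] (typically population-centered first).
#' @param n_perm number of permutations (default 100).
#' @param upper_quantile envelope quantile per rank (default 0.975).
#' @param seed integer seed for the permutations.
#' @return Object of class `factor_correction`: list with `K`,
#'   `eigenvalues`, `envelope`, `n_perm`, `upper_quantile`.
#' @export
select_num_pcs <- function(expr, n_perm = 100, upper_quantile = 0.975,
                           seed = 1L) {
  stopifnot(n_perm >= 1)
  v <- expr$values
  n <- ncol(v)
  if (n < 3) stop("need at least 3 samples")
  eig <- function(m) {
    m <- m - rowMeans(m)
    d <- svd(m, nu = 0, nv = 0)$d
    d^2 / (n - 1)
  }
  obs <- eig(v)
  set.seed(seed)
  null_eig <- matrix(0, n_perm, length(obs))
  for (b in seq_len(n_perm)) {
    vp <- t(apply(v, 1, sample))
    null_eig[b, ] <- eig(vp)
  }
  env <- apply(null_eig, 2, quantile, probs = upper_quantile)
  above <- obs > env
  K <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(K = as.integer(K), eigenvalues = obs, envelope = env,
                 n_perm = n_perm, upper_quantile = upper_quantile),
            class = "factor_correction")
}

#' @export
print.factor_correction <- function(x, ...) {
  cat("factor_correction: K =", x$K, "PCs retained (",
      x$n_perm, "permutations, envelope quantile", x$upper_quantile, ")\n")
  invisible(x)
}

#' Regress hidden factors out of each feature by elastic net
#'
#' Per feature, an elastic-net regression of its values on the top-K
#' expression PCs plus covariates (population and sex indicators). The
#' ridge penalty lambda2 is chosen over a discrete grid by minimal
#' leave-one-out cross-validated residual sum of squares; the lasso penalty
#' lambda1 is selected on a path by the same criterion. The output is the
#' residual matrix from each feature's optimal fit.
#'
#' @param expr an [expr_matrix()] (centered scale).
#' @param K number of PCs to remove (e.g. from [select_num_pcs()]).
#' @param covariates character subset of `c("population", "sex")`.
#' @param lambda2_grid 6-point grid spanning near-lasso to near-ridge.
#' @param n_lambda1 length of the lambda1 path.
#' @param nfolds cross-validation folds; default `ncol(expr$values)`
#'   (leave-one-out).
#' @param seed seed for fold assignment when `nfolds` < n.
#' @return An [expr_matrix()] of residuals, with attributes
#'   `chosen_lambda2` and `chosen_lambda1` (per feature).
#' @export
regress_out_factors <- function(expr, K, covariates = c("population", "sex"),
                                lambda2_grid = c(1e-2, 1e-1, 1, 10, 100, 1000),
                                n_lambda1 = 20, nfolds = NULL, seed = 1L) {
  v <- expr$values
  n <- ncol(v)
  covariates <- intersect(covariates, c("population", "sex"))
  X_cov <- NULL
  if (length(covariates)) {
    df <- expr$samples[, covariates, drop = FALSE]
    df <- df[, vapply(df, function(x) length(unique(x)) > 1, logical(1)),
             drop = FALSE]
    if (ncol(df)) {
      X_cov <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
    }
  }
  n_cov <- if (is.null(X_cov)) 0 else ncol(X_cov)
  if (K > n - n_cov) stop("K exceeds sample count minus covariate count")
  X_pc <- NULL
  if (K > 0) {
    ctr <- v - rowMeans(v)
    sv <- svd(ctr, nu = 0, nv = K)
    X_pc <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
    colnames(X_pc) <- paste0("PC", seq_len(K))
  }
  X <- cbind(X_pc, X_cov)
  if (is.null(X) || ncol(X) == 0) {
    res <- v - rowMeans(v)
    out <- expr_matrix(res, expr$features, expr$samples)
    attr(out, "chosen_lambda2") <- rep(NA_real_, nrow(v))
    return(out)
  }
  if (is.null(nfolds)) nfolds <- n
  if (nfolds >= n) {
    foldid <- seq_len(n)
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), n))
  }
  fit <- elnet_residualize_cpp(X, t(v), as.numeric(lambda2_grid),
                               as.integer(n_lambda1), 1e-3,
                               as.integer(foldid - 1L), 1000L, 1e-9)
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(v)
  out <- expr_matrix(res, expr$features, expr$samples)
  attr(out, "chosen_lambda2") <- lambda2_grid[fit$lambda2_index + 1]
  attr(out, "chosen_lambda1") <- fit$lambda1
  out
}

#' Standard preprocessing chain
#'
#' Quantile normalization within population, population mean centering,
#' permutation-calibrated PC selection and elastic-net residualization.
#'
#' @param expr an [expr_matrix()].
#' @param n_perm,upper_quantile,seed passed to [select_num_pcs()].
#' @param ... passed to [regress_out_factors()].
#' @return list with the corrected `expr` and the `factor_correction`.
#' @export
preprocess_expression <- function(expr, n_perm = 100, upper_quantile = 0.975,
                                  seed = 1L, ...) {
  qn <- quantile_normalize(expr)
  ctr <- center_by_population(qn)
  fc <- select_num_pcs(ctr, n_perm = n_perm, upper_quantile = upper_quantile,
                       seed = seed)
  corrected <- regress_out_factors(ctr, K = fc$K, seed = seed, ...)
  list(expr = corrected, factor_correction = fc)
}
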