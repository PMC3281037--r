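#' Signed TSS-distance bin scheme
#'
#' Distances are signed and transcription-oriented (negative = upstream of
#' the TSS). Bin edges are at +/- 0, 1, 5, 10, 25, 50, 100 kb with
#' open-ended bins beyond, giving 14 bins; bin 1 is the most upstream and is
#' the default reference (coefficient fixed at 0) in the positional model.
#'
#' @return Numeric vector of bin breaks in bp (length 15, includes
#'   `-Inf`/`Inf`).
#' @export
annotation_bins <- function() {
  c(-Inf, -1e5, -5e4, -2.5e4, -1e4, -5e3, -1e3, 0,
    1e3, 5e3, 1e4, 2.5e4, 5e4, 1e5, Inf)
}

n_distance_bins <- function() length(annotation_bins()) - 1L

#' Annotate SNP positions relative to one gene model
#'
#' Computes the signed transcription-oriented distance bin from the TSS and
#' the positional flags: intragenic, exon/intron, and first/internal/last
#' exon (in transcription order). In a single-exon gene the exon counts as
#' both first and last; it is treated as "last" (the exon ending at the
#' TES) wherever an exclusive category is needed.
#'
#' @param positions integer vector of SNP positions (bp, 0-based).
#' @param gene one-row data.frame for the gene (from a [gene_models()]
#'   `genes` table, with `tss`, `tes`, `strand`, `tx_start`, `tx_end`).
#' @param exons the gene's exon table (`exon_index`, `start`, `end`).
#' @return data.frame with columns `distance`, `distance_bin`, `intragenic`,
#'   `exon`, `intron`, `first_exon`, `internal_exon`, `last_exon`.
#' @export
annotate_snps <- function(positions, gene, exons) {
  lo <- max(0, gene$tx_start - 100000)
  if (any(positions < lo | positions >= gene$tx_end + 100000))
    stop("SNP outside the gene's candidate cis region")
  d <- if (gene$strand == "+") positions - gene$tss else gene$tss - positions
  bin <- .bincode(d, annotation_bins(), right = TRUE, include.lowest = TRUE)
  intragenic <- positions >= gene$tx_start & positions < gene$tx_end
  k <- max(exons$exon_index)
  exon_of <- rep(0L, length(positions))
  for (i in seq_len(nrow(exons))) {
    hit <- positions >= exons$start[i] & positions < exons$end[i]
    exon_of[hit] <- exons$exon_index[i]
  }
  in_exon <- exon_of > 0L
  last <- exon_of == k
  first <- in_exon & exon_of == 1L & !last     # single-exon gene counts as last
  data.frame(distance = d, distance_bin = bin, intragenic = intragenic,
             exon = in_exon, intron = intragenic & !in_exon,
             first_exon = first, internal_exon = in_exon & !first & !last,
             last_exon = last)
}

#' Assemble annotated candidate data for the positional model
#'
#' For each gene in `assignments`, annotates every candidate cis SNP
#' (gene-level 100 kb window) and records the tie-shared eQTN weights.
#' Candidate SNPs falling in the same (distance bin, annotation class) of
#' the same gene are exchangeable under the softmax prior, so they are
#' collapsed into one row carrying the class multiplicity `m` and the
#' class's total eQTN weight `w`; the likelihood is unchanged and fitting
#' cost drops by an order of magnitude.
#'
#' @param assignments eQTN assignments from [eqtn_assignments()] (gene-level
#'   features; `gene_id`, `snp_id`, `weight`).
#' @param genes a [gene_models()] object.
#' @param genotypes a [geno_matrix()].
#'
#' @return Object of class `positional_data`: list with the collapsed
#'   annotation table `ann` (flags, multiplicity `m`, weight `w`), the
#'   `gene` factor, vectors `w` and `m`, and `n_genes`.
#' @export
positional_data <- function(assignments, genes, genotypes) {
  gids <- unique(assignments$gene_id)
  rows <- vector("list", length(gids))
  look <- snp_lookup(genotypes)
  gene_row <- match(gids, genes$genes$gene_id)
  exons_by_gene <- split(genes$exons, genes$exons$gene_id)
  asn_by_gene <- split(assignments[!is.na(assignments$snp_id),
                                   c("snp_id", "weight")],
                       assignments$gene_id[!is.na(assignments$snp_id)])
  for (i in seq_along(gids)) {
    gene <- genes$genes[gene_row[i], ]
    ex <- exons_by_gene[[gids[i]]]
    hit <- look(gene$chrom, max(0, gene$tx_start - 100000),
                gene$tx_end + 100000)
    if (length(hit) == 0) {
      warning("gene ", gids[i], " has no candidate SNPs; excluded")
      next
    }
    cand <- genotypes$snps$snp_id[hit]
    pos <- genotypes$snps$pos[hit]
    ann <- annotate_snps(pos, gene, ex)
    w <- numeric(length(cand))
    a <- asn_by_gene[[gids[i]]]
    if (!is.null(a)) w[match(a$snp_id, cand)] <- a$weight
    # integer class code: distance bin x annotation flags
    code <- ann$distance_bin * 16L + 8L * ann$intragenic + 4L * ann$intron +
      2L * (ann$exon & !ann$last_exon) + ann$last_exon
    first <- which(!duplicated(code))
    grp <- match(code, code[first])
    agg <- ann[first, c("distance_bin", "intragenic", "exon", "intron",
                        "last_exon"), drop = FALSE]
    agg$m <- tabulate(grp, length(first))
    agg$w <- as.vector(rowsum(w, grp))
    agg$gene <- gids[i]
    rows[[i]] <- agg
  }
  ann <- do.call(rbind, rows)
  ann <- ann[!is.na(ann$distance_bin), , drop = FALSE]
  structure(list(ann = ann, gene = factor(ann$gene),
                 w = ann$w, m = ann$m, n_genes = length(unique(ann$gene))),
            class = "positional_data")
}

#' Redraw eQTN placements from a ground-truth prior
#'
#' Given an assembled candidate frame, draws one eQTN per gene from the
#' softmax placement prior defined by a `lambda_true`-style list (see
#' [sim_config()]), replacing the eQTN weights. Collapsed class rows are
#' sampled with probability proportional to `m * exp(eta)`, which is
#' exactly the per-SNP softmax. Used for placement-level parameter-recovery
#' and model-selection replicates, where only the eQTN draw varies between
#' replicates.
#'
#' @param pd a [positional_data()] object.
#' @param lambda_true list with `distance` (length 14), `intron`, `exon`,
#'   `last_exon` (set `last_exon = exon` for a truth without a special
#'   last-exon effect).
#' @param seed integer seed.
#' @return `pd` with resampled weights `w`.
#' @export
resample_eqtn_placement <- function(pd, lambda_true, seed = 1L) {
  set.seed(seed)
  ann <- pd$ann
  eta <- lambda_true$distance[ann$distance_bin] +
    lambda_true$intron * ann$intron +
    lambda_true$exon * (ann$exon & !ann$last_exon) +
    lambda_true$last_exon * ann$last_exon
  w <- numeric(nrow(ann))
  for (idx in split(seq_len(nrow(ann)), pd$gene)) {
    pr <- ann$m[idx] * exp(eta[idx] - max(eta[idx]))
    w[idx[sample.int(length(idx), 1, prob = pr)]] <- 1
  }
  pd$w <- w
  pd$ann$w <- w
  pd
}

# design matrix for one of the nested models M0..M3.
# Distance-bin dummies for every non-empty bin except the reference (the
# most upstream non-empty bin); annotation columns per model.
positional_design <- function(pd, model = c("M0", "M1", "M2", "M3")) {
  model <- match.arg(model)
  ann <- pd$ann
  present <- sort(unique(ann$distance_bin))
  ref <- present[1]
  cols <- list()
  for (b in setdiff(present, ref))
    cols[[paste0("dist_b", b)]] <- as.numeric(ann$distance_bin == b)
  if (model == "M1") cols[["intragenic"]] <- as.numeric(ann$intragenic)
  if (model == "M2") {
    cols[["intron"]] <- as.numeric(ann$intron)
    cols[["exon"]] <- as.numeric(ann$exon)
  }
  if (model == "M3") {
    cols[["intron"]] <- as.numeric(ann$intron)
    cols[["exon_not_last"]] <- as.numeric(ann$exon & !ann$last_exon)
    cols[["last_exon"]] <- as.numeric(ann$last_exon)
  }
  A <- do.call(cbind, cols)
  keep <- colSums(A != 0) > 0
  A[, keep, drop = FALSE]
}

#' Weighted-multinomial log-likelihood of eQTN position
#'
#' Under coefficient vector `lambda`, the prior that SNP j of gene g is the
#' eQTN is the softmax `pi_gj = exp(lambda' a_gj) / sum_k exp(lambda' a_gk)`
#' over the gene's candidate SNPs. The log-likelihood sums, over genes,
#' the log of the weight-mixed prior `sum_j w_gj pi_gj` with `w` the
#' tie-shared best-SNP weights.
#'
#' @param lambda coefficient vector (one entry per design column).
#' @param A design matrix (stacked candidates x parameters).
#' @param gene factor assigning rows of `A` to genes.
#' @param w eQTN weight vector (nonnegative, summing to 1 within gene).
#' @param m multiplicity of each row (collapsed exchangeable candidates;
#'   default 1 for per-SNP rows).
#' @param split_idx optional precomputed `split(seq_len(nrow(A)), gene)`,
#'   reused across optimizer iterations.
#' @return list with `loglik` and `gradient`.
#' @export
model_loglik <- function(lambda, A, gene, w, m = 1, split_idx = NULL) {
  if (length(m) == 1) m <- rep(m, nrow(A))
  eta <- as.vector(A %*% lambda)
  if (max(eta) - min(eta) < 600) {
    # no overflow possible; skip the per-gene stabilization
    e <- exp(eta - max(eta))
  } else {
    idx <- if (is.null(split_idx)) split(seq_along(eta), gene) else split_idx
    gmax <- vapply(idx, function(i) max(eta[i]), numeric(1))
    e <- exp(eta - gmax[as.integer(gene)])
  }
  S <- as.vector(rowsum(m * e, gene))
  We <- as.vector(rowsum(w * e, gene))
  if (any(We <= 0)) stop("gene with zero eQTN weight mass")
  ll <- sum(log(We) - log(S))
  coefv <- (w * e) / We[as.integer(gene)] - (m * e) / S[as.integer(gene)]
  grad <- as.vector(crossprod(A, coefv))
  list(loglik = ll, gradient = grad)
}

#' Fit the hierarchical multinomial positional model
#'
#' Maximizes the weighted-multinomial likelihood of eQTN location by
#' quasi-Newton optimization (L-BFGS-B, started at 0, coefficients bounded
#' at +/- 15 to cap separation). The reference distance bin is fixed at 0
#' for identifiability. Wald 95% confidence intervals come from the inverse
#' observed information; annotation odds-ratio contrasts use the delta
#' method.
#'
#' The four nested models are: M0 distance from TSS only; M1 + intragenic;
#' M2 the intragenic annotation split into exclusive intron and exon
#' categories; M3 the exon category split into non-last and last exon.
#'
#' @param pd a [positional_data()] object.
#' @param model one of `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @param max_iter optimizer iteration cap.
#' @return Object of class `eqtn_posfit` with coefficients, `logLik`, `k`,
#'   `AIC`, covariance matrix, and an odds-ratio table with 95% CIs.
#' @export
fit_positional_model <- function(pd, model = c("M0", "M1", "M2", "M3"),
                                 max_iter = 500) {
  model <- match.arg(model)
  A <- positional_design(pd, model)
  gene <- pd$gene; w <- pd$w; m <- pd$m
  if (is.null(m)) m <- rep(1, nrow(A))
  sidx <- split(seq_len(nrow(A)), gene)
  negll <- function(l) -model_loglik(l, A, gene, w, m, sidx)$loglik
  neggr <- function(l) -model_loglik(l, A, gene, w, m, sidx)$gradient
  p <- ncol(A)
  opt <- optim(rep(0, p), negll, neggr, method = "L-BFGS-B",
               lower = rep(-15, p), upper = rep(15, p),
               control = list(maxit = max_iter))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("positional model did not converge: ", opt$message,
         " (code ", opt$convergence, ")")
  lambda <- setNames(opt$par, colnames(A))
  if (any(abs(lambda) >= 15 - 1e-6))
    warning("separation: coefficient(s) capped at +/-15: ",
            paste(names(lambda)[abs(lambda) >= 15 - 1e-6], collapse = ", "))
  H <- optimHess(opt$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  dimnames(V) <- list(colnames(A), colnames(A))
  ll <- -opt$value
  aic <- 2 * p - 2 * ll
  or_table <- positional_or_table(model, lambda, V)
  structure(list(model = model, coefficients = lambda, vcov = V,
                 loglik = ll, k = p, AIC = aic, or_table = or_table,
                 n_genes = pd$n_genes, convergence = opt$convergence),
            class = "eqtn_posfit")
}

# odds-ratio contrasts with Wald 95% CIs (delta method on the log scale)
positional_or_table <- function(model, lambda, V) {
  contrasts <- switch(model,
    M0 = list(),
    M1 = list("intragenic/intergenic" = c(intragenic = 1)),
    M2 = list("exon/intron" = c(exon = 1, intron = -1)),
    M3 = list("exon (except last)/intron" = c(exon_not_last = 1, intron = -1),
              "last exon/intron" = c(last_exon = 1, intron = -1)))
  if (!length(contrasts))
    return(data.frame(contrast = character(0), or = numeric(0),
                      lo = numeric(0), hi = numeric(0)))
  rows <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    cvec <- setNames(rep(0, length(lambda)), names(lambda))
    cvec[names(cc)] <- cc
    est <- sum(cvec * lambda)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(contrast = nm, or = exp(est),
               lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se))
  })
  do.call(rbind, rows)
}

#' @export
print.eqtn_posfit <- function(x, ...) {
  cat("Positional eQTN model", x$model, "(", x$n_genes, "genes )\n")
  cat("  logLik", format(x$loglik, digits = 6), " k =", x$k,
      " AIC", format(x$AIC, digits = 6), "\n")
  if (nrow(x$or_table)) {
    cat("  odds ratios [95% CI]:\n")
    for (i in seq_len(nrow(x$or_table)))
      cat(sprintf("    %-26s %6.2f [%.2f, %.2f]\n", x$or_table$contrast[i],
                  x$or_table$or[i], x$or_table$lo[i], x$or_table$hi[i]))
  }
  invisible(x)
}

#' @export
summary.eqtn_posfit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coef_table <- data.frame(estimate = object$coefficients, se = se,
                           z = object$coefficients / se)
  out <- list(model = object$model, coef_table = coef_table,
              or_table = object$or_table, loglik = object$loglik,
              k = object$k, AIC = object$AIC, n_genes = object$n_genes)
  class(out) <- "summary.eqtn_posfit"
  out
}

#' @export
print.summary.eqtn_posfit <- function(x, ...) {
  cat("Positional eQTN model", x$model, "\n")
  print(round(x$coef_table, 4))
  cat("logLik", x$loglik, " k", x$k, " AIC", x$AIC, "\n")
  if (nrow(x$or_table)) print(x$or_table)
  invisible(x)
}

#' @export
coef.eqtn_posfit <- function(object, ...) object$coefficients

#' @export
vcov.eqtn_posfit <- function(object, ...) object$vcov

#' @export
logLik.eqtn_posfit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_genes,
            class = "logLik")
}

#' @export
confint.eqtn_posfit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Compare positional models by AIC
#'
#' @param fits list of `eqtn_posfit` objects fitted on identical data.
#' @return Object of class `eqtn_posaic`: data.frame (`model`, `k`,
#'   `loglik`, `AIC`, `dAIC`) with the best model (dAIC = 0) in attribute
#'   `best`.
#' @export
compare_models <- function(fits) {
  ng <- unique(vapply(fits, function(f) f$n_genes, numeric(1)))
  if (length(ng) != 1) stop("fits use different gene sets")
  tab <- data.frame(model = vapply(fits, function(f) f$model, character(1)),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  attr(tab, "best") <- tab$model[which.min(tab$AIC)]
  class(tab) <- c("eqtn_posaic", "data.frame")
  tab
}

#' @export
print.eqtn_posaic <- function(x, ...) {
  cat("AIC comparison (best:", attr(x, "best"), ")\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Fig-1-style eQTN location histogram
#'
#' eQTN weight mass binned by location relative to the target gene: outside
#' the transcript, physical-distance bins from the TSS (upstream) or TES
#' (downstream); inside, fractional-position bins. For plotting, the gene
#' body is rendered at the average gene length of the data.
#'
#' @param assignments eQTN assignments ([eqtn_assignments()]).
#' @param genes a [gene_models()] object.
#' @param genotypes a [geno_matrix()] (for SNP positions).
#' @param outside_bin_width physical bin width outside the gene (bp).
#' @param n_fractional_bins number of fractional bins inside the gene.
#' @param flank extent of the outside region (bp, matches the cis window).
#' @return Object of class `eqtn_poshist`: data.frame with `region`
#'   (upstream/gene/downstream), `bin`, `x_lo`, `x_hi` (plot coordinates,
#'   gene body scaled to the average gene length), and `mass`; total mass
#'   equals the summed assignment weight (one per gene).
#' @export
position_histogram <- function(assignments, genes, genotypes,
                               outside_bin_width = 10000,
                               n_fractional_bins = 20, flank = 100000) {
  n_out <- ceiling(flank / outside_bin_width)
  up <- rep(0, n_out); inside <- rep(0, n_fractional_bins); down <- rep(0, n_out)
  mean_len <- mean(genes$genes$tx_end - genes$genes$tx_start)
  for (i in seq_len(nrow(assignments))) {
    gene <- gene_record(genes, assignments$gene_id[i])
    pos <- genotypes$snps$pos[match(assignments$snp_id[i], genotypes$snps$snp_id)]
    wgt <- assignments$weight[i]
    if (pos >= gene$tx_start && pos < gene$tx_end) {
      q <- if (gene$strand == "+") (pos - gene$tss) / (gene$tes - gene$tss)
           else (gene$tss - pos) / (gene$tss - gene$tes)
      b <- min(n_fractional_bins, 1 + floor(q * n_fractional_bins))
      inside[b] <- inside[b] + wgt
    } else {
      d_tss <- signed_tss_distance(pos, gene)
      if (d_tss < 0) {
        b <- min(n_out, 1 + floor(-d_tss / outside_bin_width))
        up[n_out - b + 1] <- up[n_out - b + 1] + wgt
      } else {
        d_tes <- if (gene$strand == "+") pos - gene$tes else gene$tes - pos
        b <- min(n_out, 1 + floor(d_tes / outside_bin_width))
        down[b] <- down[b] + wgt
      }
    }
  }
  xg <- seq(0, mean_len, length.out = n_fractional_bins + 1)
  out <- rbind(
    data.frame(region = "upstream", bin = seq_len(n_out),
               x_lo = -rev(seq_len(n_out)) * outside_bin_width,
               x_hi = -rev(seq_len(n_out) - 1) * outside_bin_width,
               mass = up),
    data.frame(region = "gene", bin = seq_len(n_fractional_bins),
               x_lo = xg[-length(xg)], x_hi = xg[-1], mass = inside),
    data.frame(region = "downstream", bin = seq_len(n_out),
               x_lo = mean_len + (seq_len(n_out) - 1) * outside_bin_width,
               x_hi = mean_len + seq_len(n_out) * outside_bin_width,
               mass = down))
  class(out) <- c("eqtn_poshist", "data.frame")
  attr(out, "mean_gene_length") <- mean_len
  out
}

#' @export
plot.eqtn_poshist <- function(x, main = "eQTN location distribution", ...) {
  dens <- x$mass / (x$x_hi - x$x_lo)
  graphics::plot(NA, xlim = range(c(x$x_lo, x$x_hi)), ylim = c(0, max(dens) * 1.05),
                 xlab = "position relative to gene (bp; gene scaled to mean length)",
                 ylab = "eQTN density", main = main, ...)
  graphics::rect(x$x_lo, 0, x$x_hi, dens,
                 col = c(upstream = "grey80", gene = "steelblue",
                         downstream = "grey80")[x$region], border = NA)
  mg <- attr(x, "mean_gene_length")
  graphics::abline(v = c(0, mg), lty = 2)
  graphics::mtext(c("TSS", "TES"), at = c(0, mg), side = 3, line = 0, cex = 0.8)
  invisible(x)
}
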