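test_that("SNP annotation flags respect strand and exon structure", {
  gm <- toy_genes()
  gA <- gm$genes[1, ]; exA <- gm$exons[gm$exons$gene_id == "gA", ]
  gB <- gm$genes[2, ]; exB <- gm$exons[gm$exons$gene_id == "gB", ]

  # inside the final exon: exon + last_exon + intragenic, not intron
  a <- annotate_snps(3600, gA, exA)
  expect_true(a$exon && a$last_exon && a$intragenic && !a$intron)
  # between exon 1 and exon 2: intron
  a2 <- annotate_snps(1500, gA, exA)
  expect_true(a2$intron && !a2$exon)
  # 50 kb upstream of a minus-strand gene: negative distance, no flags
  a3 <- annotate_snps(gB$tss + 50000 - 1, gB, exB)
  expect_lt(a3$distance, 0)
  expect_false(a3$intragenic || a3$exon || a3$intron)
  # minus-strand first exon is the genomically rightmost
  a4 <- annotate_snps(55500, gB, exB)
  expect_true(a4$first_exon && !a4$last_exon)
  a5 <- annotate_snps(50500, gB, exB)
  expect_true(a5$last_exon)
  # outside the candidate region
  expect_error(annotate_snps(gA$tx_end + 100000, gA, exA), "outside")
  # flag consistency on many random positions
  pos <- seq(0, gA$tx_end + 99999, by = 37)
  aa <- annotate_snps(pos, gA, exA)
  expect_true(all(aa$intragenic == (aa$exon | aa$intron)))
  expect_true(all(aa$exon == (aa$first_exon | aa$internal_exon | aa$last_exon)))
  expect_true(all(!aa$last_exon | aa$exon))
})

test_that("the weighted-multinomial log-likelihood matches hand algebra", {
  # one gene, two same-bin SNPs, lambda = 0 -> log(1/2)
  A <- matrix(0, 2, 1); gene <- factor(c("g", "g")); w <- c(1, 0)
  expect_equal(model_loglik(0, A, gene, w)$loglik, log(1 / 2))
  # exonic vs intronic SNP in the same bin, contrast log 2, weight on exon
  A2 <- matrix(c(1, 0), 2, 1)  # exon indicator; lambda = log 2
  expect_equal(model_loglik(log(2), A2, gene, c(1, 0))$loglik, log(2 / 3))
  # multiplicities reproduce expanded rows
  A3 <- matrix(c(1, 0), 2, 1)
  ll_collapsed <- model_loglik(0.7, A3, gene, c(1, 0), m = c(2, 3))$loglik
  A3x <- matrix(c(1, 1, 0, 0, 0), 5, 1)
  gx <- factor(rep("g", 5))
  ll_full <- model_loglik(0.7, A3x, gx, c(0.5, 0.5, 0, 0, 0))$loglik
  expect_equal(ll_collapsed, ll_full)
  # shift invariance over distance-bin coefficients
  set.seed(8)
  cfg <- fast_sim_config()
  st <- simulate_study(cfg, platforms = character(0))
  truth <- st$truth[!is.na(st$truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  pd <- positional_data(asn, st$genes, st$genotypes)
  # in the full (unreduced) parameterization, adding a constant to every
  # distance-bin coefficient leaves the likelihood unchanged
  bins <- sort(unique(pd$ann$distance_bin))
  Afull <- vapply(bins, function(b) as.numeric(pd$ann$distance_bin == b),
                  numeric(nrow(pd$ann)))
  l0 <- rnorm(ncol(Afull))
  ll0 <- model_loglik(l0, Afull, pd$gene, pd$w, pd$m)$loglik
  ll1 <- model_loglik(l0 + 3, Afull, pd$gene, pd$w, pd$m)$loglik
  expect_equal(ll0, ll1, tolerance = 1e-9)
  # with the reference bin fixed at zero the flat direction is gone
  Ad <- eqtnpos:::positional_design(pd, "M2")
  dist_cols <- grepl("^dist_", colnames(Ad))
  l2 <- rnorm(ncol(Ad))
  l3 <- l2; l3[dist_cols] <- l3[dist_cols] + 3
  expect_false(isTRUE(all.equal(
    model_loglik(l2, Ad, pd$gene, pd$w, pd$m)$loglik,
    model_loglik(l3, Ad, pd$gene, pd$w, pd$m)$loglik)))
})

test_that("gradient of the log-likelihood matches finite differences", {
  set.seed(17)
  cfg <- fast_sim_config()
  st <- simulate_study(cfg, platforms = character(0))
  truth <- st$truth[!is.na(st$truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  pd <- positional_data(asn, st$genes, st$genotypes)
  A <- eqtnpos:::positional_design(pd, "M3")
  l <- rnorm(ncol(A), 0, 0.5)
  gr <- model_loglik(l, A, pd$gene, pd$w, pd$m)$gradient
  eps <- 1e-6
  gr_num <- vapply(seq_along(l), function(j) {
    lp <- l; lp[j] <- lp[j] + eps
    lm_ <- l; lm_[j] <- lm_[j] - eps
    (model_loglik(lp, A, pd$gene, pd$w, pd$m)$loglik -
       model_loglik(lm_, A, pd$gene, pd$w, pd$m)$loglik) / (2 * eps)
  }, numeric(1))
  expect_equal(gr, gr_num, tolerance = 1e-5)
})

test_that("nested fits are ordered and AIC follows its definition", {
  cfg <- sim_config(n_genes = 150, n_samples = c(P = 6), prop_qtl = 1,
                    prop_exon_specific = 0, seed = 19)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)
  truth <- truth[!is.na(truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  pd <- positional_data(asn, genes, geno)
  fits <- lapply(c("M0", "M1", "M2", "M3"), function(m)
    fit_positional_model(pd, m))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))  # nesting: M0 <= M1 <= M2 <= M3
  for (f in fits) expect_equal(f$AIC, 2 * f$k - 2 * f$loglik)
  cmp <- compare_models(fits)
  expect_equal(min(cmp$dAIC), 0)
  expect_equal(attr(cmp, "best"), cmp$model[which.min(cmp$AIC)])
  # logLik/AIC methods are consistent
  expect_equal(AIC(fits[[2]]), fits[[2]]$AIC)
  expect_equal(unname(coef(fits[[2]])["intragenic"]),
               unname(fits[[2]]$coefficients["intragenic"]))
  ci <- confint(fits[[2]])
  expect_true(all(ci[, 1] <= coef(fits[[2]]) & coef(fits[[2]]) <= ci[, 2]))
})

test_that("parameter recovery: exon/intron odds ratio is identified", {
  cfg <- sim_config(n_genes = 500, n_samples = c(P = 6), prop_qtl = 1,
                    prop_exon_specific = 0, seed = 23)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)  # truth exon/intron OR = 12
  truth <- truth[!is.na(truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  pd <- positional_data(asn, genes, geno)
  fit <- fit_positional_model(pd, "M2")
  or <- fit$or_table$or[fit$or_table$contrast == "exon/intron"]
  expect_gt(or, 7); expect_lt(or, 20)
  # Hessian nonsingular: finite standard errors
  expect_true(all(is.finite(sqrt(diag(fit$vcov)))))
})

test_that("position histogram conserves eQTN weight mass", {
  cfg <- fast_sim_config()
  st <- simulate_study(cfg, platforms = character(0))
  truth <- st$truth[!is.na(st$truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  h <- position_histogram(asn, st$genes, st$genotypes)
  expect_equal(sum(h$mass), nrow(asn))
  # all mass adjacent to the TSS when eQTNs sit at the TSS
  asn2 <- asn[1:5, ]
  for (i in 1:5) {
    gene <- st$genes$genes[st$genes$genes$gene_id == asn2$gene_id[i], ]
    tss_snp <- st$genotypes$snps[st$genotypes$snps$pos >= gene$tx_start &
                                   st$genotypes$snps$pos < gene$tx_end, ]
    asn2$snp_id[i] <- tss_snp$snp_id[which.min(abs(tss_snp$pos - gene$tss))]
  }
  h2 <- position_histogram(asn2, st$genes, st$genotypes)
  # mass concentrates in the TSS-adjacent bins (first quarter of the gene
  # body or the nearest upstream bin)
  inside <- h2[h2$region == "gene", ]
  up <- h2[h2$region == "upstream", ]
  near_tss <- sum(inside$mass[seq_len(ceiling(nrow(inside) / 4))]) +
    up$mass[nrow(up)]
  expect_gte(near_tss, 4)
})

test_that("placement resampling reproduces the requested enrichment", {
  cfg <- sim_config(n_genes = 300, n_samples = c(P = 6), prop_qtl = 1,
                    prop_exon_specific = 0, seed = 29)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)
  truth <- truth[!is.na(truth$qtn), ]
  asn <- data.frame(feature_id = truth$gene_id, gene_id = truth$gene_id,
                    snp_id = truth$qtn, weight = 1, min_p = 0)
  pd <- positional_data(asn, genes, geno)
  lt <- list(distance = default_lambda_true()$distance, intron = log(5),
             exon = log(5) + log(12), last_exon = log(5) + log(12))
  ors <- vapply(1:10, function(s) {
    pd2 <- resample_eqtn_placement(pd, lt, seed = s)
    fit_positional_model(pd2, "M2")$or_table$or[1]
  }, numeric(1))
  expect_gt(mean(ors), 8); expect_lt(mean(ors), 18)
})
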