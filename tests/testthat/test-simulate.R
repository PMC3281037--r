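test_that("gene model simulation honours fixed architecture and determinism", {
  # single-exon degenerate case: first exon == last exon
  cfg1 <- sim_config(n_genes = 10, exon_count_fixed = 1, seed = 3)
  gm1 <- simulate_gene_models(cfg1)
  expect_true(all(gm1$genes$n_exons == 1))

  # fixed 5 x 200 bp exons with 1 kb introns give an exact span of
  # 5*200 + 4*1000 = 5000 bp
  cfg2 <- sim_config(n_genes = 8, exon_count_fixed = 5,
                     exon_length_fixed = 200, intron_length_fixed = 1000,
                     seed = 3)
  gm2 <- simulate_gene_models(cfg2)
  expect_true(all(gm2$genes$tx_end - gm2$genes$tx_start == 5000))
  expect_setequal(unique(gm2$genes$strand), c("+", "-"))

  # same seed twice -> identical; different seed -> different coordinates
  gm2b <- simulate_gene_models(cfg2)
  expect_identical(gm2, gm2b)
  cfg3 <- sim_config(n_genes = 8, exon_count_fixed = 5,
                     exon_length_fixed = 200, intron_length_fixed = 1000,
                     seed = 4)
  expect_false(identical(simulate_gene_models(cfg3)$genes$tx_start,
                         gm2$genes$tx_start))
})

test_that("minus-strand gene models keep transcription order coherent", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  gm <- simulate_gene_models(cfg)
  neg <- gm$genes[gm$genes$strand == "-", ]
  expect_gt(nrow(neg), 0)
  for (gid in neg$gene_id[1:min(5, nrow(neg))]) {
    g <- gm$genes[gm$genes$gene_id == gid, ]
    ex <- gm$exons[gm$exons$gene_id == gid, ]
    ex <- ex[order(ex$exon_index), ]
    expect_gt(g$tss, g$tes)  # minus strand: TSS at larger genomic coord
    # first transcribed exon is genomically rightmost
    if (nrow(ex) > 1) expect_true(ex$start[1] > ex$start[nrow(ex)])
  }
})

test_that("genotype simulation matches Binomial(2, maf) and enforces the MAF floor", {
  cfg <- sim_config(n_genes = 4, n_samples = c(P = 500),
                    maf_spectrum = "fixed", maf_fixed = 0.5, seed = 21)
  g <- simulate_genotypes(cfg, simulate_gene_models(cfg))
  expect_true(abs(mean(g$dosage) - 1) < 0.02)  # Binomial(2, 0.5) mean = 1

  # Hardy-Weinberg class frequencies at maf 0.2, n = 10000
  cfg2 <- sim_config(n_genes = 1, n_samples = c(P = 10000),
                     maf_spectrum = "fixed", maf_fixed = 0.2, seed = 22)
  g2 <- simulate_genotypes(cfg2, simulate_gene_models(cfg2))
  n <- ncol(g2$dosage)
  exp_freq <- c(0.64, 0.32, 0.04)
  for (snp in sample(nrow(g2$dosage), 20)) {
    obs <- tabulate(g2$dosage[snp, ] + 1, 3) / n
    tol <- 3 * sqrt(exp_freq * (1 - exp_freq) / n)
    expect_true(all(abs(obs - exp_freq) <= tol))
  }

  # requested maf below the floor: no SNP emitted
  cfg3 <- sim_config(n_genes = 2, maf_spectrum = "fixed", maf_fixed = 0.005,
                     seed = 23)
  expect_equal(nrow(simulate_genotypes(cfg3, simulate_gene_models(cfg3))$snps), 0)

  # stored maf equals folded empirical frequency; floor holds
  expect_equal(g2$snps$maf, unname(pmin(rowMeans(g2$dosage) / 2,
                                        1 - rowMeans(g2$dosage) / 2)))
  expect_true(all(g$snps$maf > 0.01))

  # zero density warns and returns an empty matrix
  cfg4 <- sim_config(n_genes = 2, snp_density = 0, seed = 2)
  expect_warning(g4 <- simulate_genotypes(cfg4, simulate_gene_models(cfg4)),
                 "empty")
  expect_equal(nrow(g4$snps), 0)
})

test_that("eQTN placement follows the softmax prior", {
  # lambda = 0: placement uniform over candidates (chi-square GOF)
  lt0 <- list(distance = rep(0, 14), intron = 0, exon = 0, last_exon = 0)
  cfg <- sim_config(n_genes = 150, n_samples = c(P = 10), prop_qtl = 1,
                    prop_exon_specific = 0, lambda_true = lt0,
                    exon_count_fixed = 3, exon_length_fixed = 300,
                    intron_length_fixed = 2000, snp_density = 0.5, seed = 31)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  # repeat placement over many seeds on the same genes for a GOF test
  draws <- unlist(lapply(1:40, function(s) {
    cfg_s <- cfg; cfg_s$seed <- 1000L + s
    place_eqtns(genes, geno, cfg_s)$qtn
  }))
  # uniformity within one gene's candidate set
  gid <- genes$genes$gene_id[1]
  cand <- cis_window_snps(list(chrom = "chrS",
                               start = genes$genes$tx_start[1],
                               end = genes$genes$tx_end[1]), geno, "gene")
  hits <- draws[draws %in% cand]
  counts <- table(factor(hits, levels = cand))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("degenerate placement probabilities give last-exon exon-specific QTLs", {
  cfg <- sim_config(n_genes = 30, n_samples = c(P = 10), prop_qtl = 1,
                    prop_exon_specific = 1, last_exon_bias = 1, seed = 33)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)
  planted <- truth[!is.na(truth$qtn), ]
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$effect_type == "exon_specific"))
  expect_equal(planted$target_exon,
               genes$genes$n_exons[match(planted$gene_id,
                                         genes$genes$gene_id)])
})

test_that("exon/intron placement odds approach the configured enrichment", {
  # same-distance-bin exonic vs intronic candidates; enrichment log(12)
  lt <- list(distance = rep(0, 14), intron = 0, exon = log(12),
             last_exon = log(12))
  cfg <- sim_config(n_genes = 300, n_samples = c(P = 8), prop_qtl = 1,
                    prop_exon_specific = 0, lambda_true = lt,
                    snp_density = 1.5, seed = 35)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  ex_hits <- in_hits <- ex_cand <- in_cand <- 0
  for (s in 1:12) {
    cfg_s <- cfg; cfg_s$seed <- 5000L + s
    truth <- place_eqtns(genes, geno, cfg_s)
    planted <- truth[!is.na(truth$qtn), ]
    for (i in seq_len(nrow(planted))) {
      gene <- genes$genes[genes$genes$gene_id == planted$gene_id[i], ]
      exd <- genes$exons[genes$exons$gene_id == planted$gene_id[i], ]
      pos <- geno$snps$pos[match(planted$qtn[i], geno$snps$snp_id)]
      ann <- annotate_snps(pos, gene, exd)
      if (ann$exon) ex_hits <- ex_hits + 1
      if (ann$intron) in_hits <- in_hits + 1
    }
  }
  # candidate-count baseline over all genes
  for (j in seq_len(nrow(genes$genes))) {
    gene <- genes$genes[j, ]
    exd <- genes$exons[genes$exons$gene_id == gene$gene_id, ]
    cand <- cis_window_snps(list(chrom = gene$chrom, start = gene$tx_start,
                                 end = gene$tx_end), geno, "gene")
    pos <- geno$snps$pos[match(cand, geno$snps$snp_id)]
    ann <- annotate_snps(pos, gene, exd)
    ex_cand <- ex_cand + sum(ann$exon)
    in_cand <- in_cand + sum(ann$intron)
  }
  odds <- (ex_hits / ex_cand) / (in_hits / in_cand)
  expect_gt(odds, 7)
  expect_lt(odds, 20)
})

test_that("expression simulation adds effects where the truth says", {
  cfg <- sim_config(n_genes = 12, n_samples = c(P1 = 8, P2 = 8),
                    n_factors = 0, noise_sd = 0, prop_qtl = 1, seed = 41)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)
  expr <- simulate_expression(genes, geno, truth, cfg)

  null_genes <- truth$gene_id[is.na(truth$qtn)]
  gl <- truth[!is.na(truth$qtn) & truth$effect_type == "gene_level", ]
  es <- truth[!is.na(truth$qtn) & truth$effect_type == "exon_specific", ]

  # no variance sources for unplanted genes
  for (gid in null_genes) {
    rows <- expr$features$gene_id == gid
    expect_equal(max(apply(expr$values[rows, , drop = FALSE], 1, sd)), 0)
  }
  # gene-level QTL: identical dosage effect on every exon
  if (nrow(gl) > 0) {
    i <- 1
    rows <- which(expr$features$gene_id == gl$gene_id[i])
    dos <- geno$dosage[gl$qtn[i], ]
    for (r in rows) {
      fit <- stats::lm(expr$values[r, ] ~ dos)
      expect_equal(unname(coef(fit)[2]), gl$effect_size[i], tolerance = 1e-8)
    }
  }
  # exon-specific QTL: only the target exon varies with dosage
  if (nrow(es) > 0) {
    i <- 1
    rows <- which(expr$features$gene_id == es$gene_id[i])
    tgt <- rows[expr$features$exon_index[rows] == es$target_exon[i]]
    oth <- setdiff(rows, tgt)
    expect_gt(sd(expr$values[tgt, ]), 0)
    if (length(oth)) expect_equal(max(apply(expr$values[oth, , drop = FALSE],
                                            1, sd)), 0)
  }
})

test_that("platform rendering respects probe placement and consistency", {
  cfg <- sim_config(n_genes = 400, n_samples = c(P = 6), probe_noise_sd = 0,
                    n_factors = 0, noise_sd = 0.5, prop_qtl = 0, seed = 51)
  genes <- simulate_gene_models(cfg)
  geno <- simulate_genotypes(cfg, genes)
  truth <- place_eqtns(genes, geno, cfg)
  expr <- simulate_expression(genes, geno, truth, cfg)

  # ~85% of single probes land in the last exon (binomial tolerance)
  tp <- render_platform(expr, "three_prime_probe", cfg)
  n_exons <- genes$genes$n_exons[match(tp$features$gene_id,
                                       genes$genes$gene_id)]
  frac_last <- mean(tp$features$exon_index == n_exons)
  multi <- n_exons > 1  # single-exon genes are always "last"
  expect_gt(frac_last, 0.85 - 3 * sqrt(0.85 * 0.15 / 400))
  expect_equal(nrow(tp$features), nrow(genes$genes))

  # exon_array: one probe per exon; zero probe noise reproduces the truth
  ea <- render_platform(expr, "exon_array", cfg)
  expect_equal(nrow(ea$values), nrow(expr$values))
  expect_equal(unname(ea$values), unname(expr$values))
  g5 <- genes$genes$gene_id[genes$genes$n_exons == 5][1]
  if (!is.na(g5)) expect_equal(sum(ea$features$gene_id == g5), 5)

  # counts platform: nonnegative integers, rate guard holds
  ec <- render_platform(expr, "exon_counts", cfg)
  expect_true(all(ec$values >= 0))
  expect_true(all(ec$values == round(ec$values)))

  expect_error(render_platform(expr, "spliced_junction", cfg))
})

test_that("the whole generator is reproducible from the config seed", {
  cfg <- fast_sim_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
})
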