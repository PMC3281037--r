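# Small fixtures shared across test files, built in code.

# a hand-laid two-gene model set: one 3-exon plus-strand gene, one
# 2-exon minus-strand gene
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chrT",
    strand = c("+", "-"),
    tx_start = c(1000, 50000),
    tx_end = c(4000, 56000))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    exon_index = c(1, 2, 3, 1, 2),
    start = c(1000, 2000, 3500, 55000, 50000),
    end = c(1200, 2300, 4000, 56000, 50800))
  gene_models(genes, exons)
}

# genotype matrix with SNPs at chosen positions and simple dosages
toy_geno <- function(positions, n_samples = 6, seed = 1) {
  set.seed(seed)
  dos <- matrix(rbinom(length(positions) * n_samples, 2, 0.4),
                nrow = length(positions))
  # guard against monomorphic rows in tiny fixtures
  dos[, 1] <- 0; dos[, 2] <- 1
  positions <- as.integer(positions)
  snps <- data.frame(snp_id = paste0("s", positions), chrom = "chrT",
                     pos = positions)
  rownames(dos) <- snps$snp_id
  colnames(dos) <- paste0("smp", seq_len(n_samples))
  geno_matrix(snps, dos)
}

toy_expr <- function(values, gene_id = "gA", exon_index = NULL,
                     starts = NULL, ends = NULL, populations = NULL) {
  m <- as.matrix(values)
  nf <- nrow(m); ns <- ncol(m)
  if (is.null(exon_index)) exon_index <- seq_len(nf)
  if (is.null(populations)) populations <- rep("P1", ns)
  features <- data.frame(
    feature_id = paste0("f", seq_len(nf)),
    gene_id = gene_id, exon_index = exon_index, chrom = "chrT",
    start = if (is.null(starts)) 100 * seq_len(nf) else starts,
    end = if (is.null(ends)) 100 * seq_len(nf) + 50 else ends,
    platform = "test")
  samples <- data.frame(sample_id = paste0("smp", seq_len(ns)),
                        population = populations,
                        sex = rep(c("F", "M"), length.out = ns))
  expr_matrix(m, features, samples)
}

# small fast config for end-to-end style tests
fast_sim_config <- function(...) {
  sim_config(n_genes = 25, n_samples = c(P1 = 25, P2 = 25),
             exon_count_lambda = 4, snp_density = 1, n_factors = 0,
             noise_sd = 0.6, seed = 42, ...)
}
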