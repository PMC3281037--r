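#' Simulation configuration
#'
#' Collects every knob of the synthetic cis-eQTL study: cohort layout, gene
#' architecture, SNP density and allele-frequency spectrum, the ground-truth
#' positional prior used to place eQTNs, effect sizes, the hidden-factor
#' confounding structure, and the three platform observation models.
#'
#' Defaults emulate the statistical structure of a two-population
#' lymphoblastoid cohort measured on a single-3'-probe array, a per-exon
#' array, and per-exon read counts: 210 samples in four populations
#' (60 + 60 + 45 + 45), shifted-Poisson exon
#' counts (mean ~9), lognormal exon/intron lengths (median 150 bp / 1.5 kb),
#' 2 unlinked common SNPs per kb with a 1/f MAF spectrum floored at 1%,
#' a TSS-peaked placement prior with a 12-fold exon/intron enrichment, and
#' 85% of single 3' probes sitting in the last exon.
#'
#' @param n_samples named integer vector: samples per population.
#' @param n_genes number of genes on the synthetic chromosome.
#' @param exon_count_lambda mean extra exons; counts are `1 + Poisson(lambda)`.
#' @param exon_count_fixed if non-NULL, every gene has exactly this many exons.
#' @param exon_length_meanlog,exon_length_sdlog lognormal exon length (bp)
#'   for non-terminal exons.
#' @param last_exon_meanlog,last_exon_sdlog lognormal length of the last
#'   (transcription-order) exon, which contains the 3' UTR and is several
#'   times longer than internal exons in real gene models; ignored when
#'   `exon_length_fixed` is set.
#' @param exon_length_fixed if non-NULL, fixed length for every exon (bp).
#' @param intron_length_meanlog,intron_length_sdlog lognormal intron length (bp).
#' @param intron_length_fixed if non-NULL, fixed intron length (bp).
#' @param snp_density SNPs per kb over each gene's transcript + 100 kb flanks.
#' @param maf_spectrum `"one_over_f"` (density proportional to 1/f on
#'   `[0.01, 0.5]`) or `"fixed"`.
#' @param maf_fixed the fixed minor allele frequency when
#'   `maf_spectrum = "fixed"`.
#' @param lambda_true ground-truth placement prior: a list with elements
#'   `distance` (numeric of length 14, one log-enrichment per signed TSS
#'   distance bin, see [annotation_bins()]), `intron`, `exon` (non-last
#'   exons) and `last_exon` (log-enrichments relative to intergenic SNPs in
#'   the same distance bin).
#' @param beta_gene gene-level QTL effect size (sd units per dosage unit).
#' @param beta_exon exon-specific QTL effect size.
#' @param prop_qtl fraction of genes carrying any cis-QTL.
#' @param prop_exon_specific fraction of QTL genes whose QTL is exon-specific.
#' @param last_exon_bias probability an exon-specific QTL targets the last exon.
#' @param sqtn_in_exon probability the exon-specific QTN lies inside its
#'   target exon (UTR/splice-element variants), rather than anywhere in the
#'   10 kb window around it.
#' @param n_factors number of hidden confounding factors.
#' @param factor_sd,noise_sd standard deviations of factors and residual noise.
#' @param baseline_mean,baseline_sd per-gene baseline expression level.
#' @param probe_last_exon_frac fraction of single-probe genes whose probe
#'   sits in the last exon (0.85 for a 3'-biased array).
#' @param probe_noise_sd measurement noise added by array probes.
#' @param probe_length probe footprint in bp (for variant-overlap filtering).
#' @param count_scale multiplier for the Poisson count platform rate; the
#'   default gives median per-exon counts in the single digits for short
#'   internal exons and a few dozen for terminal exons.
#' @param seed integer seed; every simulation operation derives its stream
#'   from it, so identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(CEU = 60, YRI = 60, CHB = 45, JPT = 45),
                       n_genes = 200,
                       exon_count_lambda = 8,
                       exon_count_fixed = NULL,
                       exon_length_meanlog = log(150),
                       exon_length_sdlog = 0.5,
                       last_exon_meanlog = log(1000),
                       last_exon_sdlog = 0.5,
                       exon_length_fixed = NULL,
                       intron_length_meanlog = log(1500),
                       intron_length_sdlog = 0.7,
                       intron_length_fixed = NULL,
                       snp_density = 2,
                       maf_spectrum = c("one_over_f", "fixed"),
                       maf_fixed = 0.25,
                       lambda_true = default_lambda_true(),
                       beta_gene = 1,
                       beta_exon = 2,
                       prop_qtl = 0.5,
                       prop_exon_specific = 0.4,
                       last_exon_bias = 0.85,
                       sqtn_in_exon = 0.9,
                       n_factors = 3,
                       factor_sd = 1,
                       noise_sd = 1,
                       baseline_mean = 2,
                       baseline_sd = 1,
                       probe_last_exon_frac = 0.85,
                       probe_noise_sd = 0.25,
                       probe_length = 25,
                       count_scale = 5,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              exon_count_lambda = exon_count_lambda,
              exon_count_fixed = exon_count_fixed,
              exon_length_meanlog = exon_length_meanlog,
              exon_length_sdlog = exon_length_sdlog,
              last_exon_meanlog = last_exon_meanlog,
              last_exon_sdlog = last_exon_sdlog,
              exon_length_fixed = exon_length_fixed,
              intron_length_meanlog = intron_length_meanlog,
              intron_length_sdlog = intron_length_sdlog,
              intron_length_fixed = intron_length_fixed,
              snp_density = snp_density,
              maf_spectrum = match.arg(maf_spectrum), maf_fixed = maf_fixed,
              lambda_true = lambda_true,
              beta_gene = beta_gene, beta_exon = beta_exon,
              prop_qtl = prop_qtl, prop_exon_specific = prop_exon_specific,
              last_exon_bias = last_exon_bias, sqtn_in_exon = sqtn_in_exon,
              n_factors = n_factors, factor_sd = factor_sd, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              probe_last_exon_frac = probe_last_exon_frac,
              probe_noise_sd = probe_noise_sd, probe_length = probe_length,
              count_scale = count_scale, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$prop_qtl, cfg$prop_exon_specific, cfg$last_exon_bias,
             cfg$sqtn_in_exon, cfg$probe_last_exon_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (is.null(names(cfg$n_samples)) || any(cfg$n_samples < 2))
    stop("n_samples must be a named vector with >= 2 samples per population")
  if (!is.null(cfg$exon_length_fixed) && cfg$exon_length_fixed < 1)
    stop("exon length support must exclude zero")
  if (!is.null(cfg$intron_length_fixed) && cfg$intron_length_fixed < 1)
    stop("intron length support must exclude zero")
  if (!is.null(cfg$exon_count_fixed) && cfg$exon_count_fixed < 1)
    stop("exon count must be >= 1")
  if (cfg$maf_spectrum == "fixed" && (cfg$maf_fixed <= 0 || cfg$maf_fixed > 0.5))
    stop("maf_fixed must be in (0, 0.5]")
  lt <- cfg$lambda_true
  if (!is.list(lt) || length(lt$distance) != n_distance_bins() ||
      is.null(lt$intron) || is.null(lt$exon) || is.null(lt$last_exon))
    stop("lambda_true must list 'distance' (length ", n_distance_bins(),
         "), 'intron', 'exon', 'last_exon'")
  cfg
}

#' Default ground-truth placement prior
#'
#' A TSS-peaked distance profile with a 5-fold intron enrichment over
#' intergenic SNPs and a 12-fold exon/intron enrichment; the last exon gets
#' no special effect beyond other exons (so any last-exon signal seen
#' downstream must come from exon-specific QTLs or probe placement, not from
#' the gene-level placement prior).
#'
#' @return A list suitable for the `lambda_true` field of [sim_config()].
#' @export
default_lambda_true <- function() {
  dist <- c(0, 0.3, 0.6, 1.0, 1.5, 2.0, 3.0, 3.0, 2.0, 1.5, 1.0, 0.6, 0.3, 0)
  list(distance = dist, intron = log(5),
       exon = log(5) + log(12), last_exon = log(5) + log(12))
}

sim_samples <- function(config) {
  set.seed(config$seed + 11L)
  pops <- rep(names(config$n_samples), config$n_samples)
  ids <- unlist(lapply(names(config$n_samples), function(p)
    sprintf("%s_%03d", p, seq_len(config$n_samples[[p]]))))
  data.frame(sample_id = ids, population = pops,
             sex = sample(c("F", "M"), length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate gene models on a synthetic chromosome
#'
#' Genes are laid out non-overlapping with both strands represented; gaps
#' exceed 210 kb so that the 100 kb cis windows of neighbouring genes never
#' share SNPs.
#'
#' @param config a [sim_config()].
#' @return A [gene_models()] object with `config$n_genes` genes.
#' @export
simulate_gene_models <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  counts <- if (!is.null(config$exon_count_fixed)) rep(config$exon_count_fixed, n)
            else 1L + rpois(n, config$exon_count_lambda)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  genes <- vector("list", n); exons <- vector("list", n)
  cur <- 100000
  for (j in seq_len(n)) {
    k <- counts[j]
    ex_len <- if (!is.null(config$exon_length_fixed)) {
      rep(config$exon_length_fixed, k)
    } else {
      len <- pmax(25, round(stats::rlnorm(k, config$exon_length_meanlog,
                                          config$exon_length_sdlog)))
      # terminal exon carries the 3' UTR and is much longer
      len[k] <- pmax(100, round(stats::rlnorm(1, config$last_exon_meanlog,
                                              config$last_exon_sdlog)))
      len
    }
    in_len <- if (k == 1) integer(0)
              else if (!is.null(config$intron_length_fixed)) rep(config$intron_length_fixed, k - 1)
              else pmax(60, round(stats::rlnorm(k - 1, config$intron_length_meanlog,
                                                config$intron_length_sdlog)))
    span <- sum(ex_len) + sum(in_len)
    gid <- sprintf("g%04d", j)
    # genomic order of transcribed pieces: forward on +, reversed on -
    glen <- if (strands[j] == "+") ex_len else rev(ex_len)
    gint <- if (strands[j] == "+") in_len else rev(in_len)
    starts <- cur + cumsum(c(0, head(glen, -1) + gint))
    idx <- if (strands[j] == "+") seq_len(k) else rev(seq_len(k))
    exons[[j]] <- data.frame(gene_id = gid, exon_index = idx,
                             start = starts, end = starts + glen,
                             stringsAsFactors = FALSE)
    genes[[j]] <- data.frame(gene_id = gid, chrom = "chrS", strand = strands[j],
                             tx_start = cur, tx_end = cur + span,
                             stringsAsFactors = FALSE)
    cur <- cur + span + round(runif(1, 210000, 260000))
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' Simulate cis genotypes around each gene
#'
#' SNPs are placed uniformly over each gene's transcript plus 100 kb flanks;
#' dosages are Binomial(2, maf) per sample (no LD). The stored MAF is the
#' folded empirical frequency of the drawn dosages; SNPs whose requested or
#' realized MAF is at or below 1%, or that are monomorphic, are excluded.
#'
#' @param config a [sim_config()].
#' @param genes a [gene_models()] object.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(config, genes) {
  set.seed(config$seed + 2L)
  samples <- sim_samples(config)
  m <- nrow(samples)
  if (config$snp_density <= 0) {
    warning("snp_density is 0: returning an empty genotype matrix")
    return(geno_matrix(data.frame(snp_id = character(0), chrom = character(0),
                                  pos = integer(0)),
                       matrix(0, 0, m, dimnames = list(NULL, samples$sample_id))))
  }
  pos_all <- integer(0)
  g <- genes$genes
  for (j in seq_len(nrow(g))) {
    lo <- max(0, g$tx_start[j] - 100000); hi <- g$tx_end[j] + 100000
    nsnp <- rpois(1, config$snp_density * (hi - lo) / 1000)
    nsnp <- min(nsnp, hi - lo)
    if (nsnp > 0)
      pos_all <- c(pos_all,
                   as.integer(lo) + sort(sample.int(hi - lo, nsnp)) - 1L)
  }
  n <- length(pos_all)
  p <- if (config$maf_spectrum == "fixed") rep(config$maf_fixed, n)
       else 0.01 * (0.5 / 0.01)^runif(n)   # density ~ 1/f on [0.01, 0.5]
  keep <- p > 0.01
  pos_all <- pos_all[keep]; p <- p[keep]; n <- length(p)
  dosage <- matrix(rbinom(n * m, 2, p), nrow = n, ncol = m)
  f <- rowMeans(dosage) / 2
  emp_maf <- pmin(f, 1 - f)
  keep <- emp_maf > 0.01
  pos_all <- pos_all[keep]; dosage <- dosage[keep, , drop = FALSE]
  snps <- data.frame(snp_id = paste0("s", pos_all, recycle0 = TRUE),
                     chrom = rep("chrS", length(pos_all)),
                     pos = pos_all, stringsAsFactors = FALSE)
  rownames(dosage) <- snps$snp_id
  colnames(dosage) <- samples$sample_id
  geno_matrix(snps, dosage)
}

# ground-truth linear predictor of the placement prior for one gene's candidates
truth_eta <- function(positions, gene, exons, lambda_true) {
  ann <- annotate_snps(positions, gene, exons)
  lambda_true$distance[ann$distance_bin] +
    lambda_true$intron * ann$intron +
    lambda_true$exon * (ann$exon & !ann$last_exon) +
    lambda_true$last_exon * ann$last_exon
}

#' Plant eQTNs under the ground-truth positional prior
#'
#' Each gene carries a QTL with probability `prop_qtl`. Gene-level eQTNs are
#' drawn from the softmax prior `pi_j` proportional to `exp(lambda' a_j)`
#' over the gene's candidate cis SNPs. Exon-specific QTLs first pick a
#' target exon (the last exon with probability `last_exon_bias`); their QTN
#' lies inside that exon with probability `sqtn_in_exon` (variants in
#' UTRs, splice elements or miRNA sites act from within the exon they
#' affect), and otherwise is drawn from the softmax restricted to
#' candidates within 10 kb of the exon, reflecting that exon-level QTNs
#' concentrate near the affected exon.
#'
#' @param genes a [gene_models()] object.
#' @param genotypes a [geno_matrix()].
#' @param config a [sim_config()].
#' @return A truth table: data.frame with one row per gene (`gene_id`,
#'   `qtn`, `effect_type`, `target_exon`, `effect_size`); genes without a
#'   QTL (or without candidate SNPs) have `qtn = NA`.
#' @export
place_eqtns <- function(genes, genotypes, config) {
  set.seed(config$seed + 3L)
  g <- genes$genes
  lt <- config$lambda_true
  out <- lapply(seq_len(nrow(g)), function(j) {
    gene <- g[j, ]
    res <- data.frame(gene_id = gene$gene_id, qtn = NA_character_,
                      effect_type = NA_character_, target_exon = NA_integer_,
                      effect_size = NA_real_, stringsAsFactors = FALSE)
    if (runif(1) > config$prop_qtl) return(res)
    cand <- cis_window_snps(list(chrom = gene$chrom, start = gene$tx_start,
                                 end = gene$tx_end), genotypes, level = "gene")
    if (length(cand) == 0) return(res)
    pos <- genotypes$snps$pos[match(cand, genotypes$snps$snp_id)]
    ex <- gene_exons(genes, gene$gene_id)
    exon_specific <- runif(1) < config$prop_exon_specific
    if (exon_specific) {
      k <- nrow(ex)
      target <- if (k == 1 || runif(1) < config$last_exon_bias) k
                else sample.int(k - 1, 1)
      te <- ex[ex$exon_index == target, ]
      near <- pos >= te$start - 10000 & pos < te$end + 10000
      if (!any(near)) return(res)
      in_ex <- pos >= te$start & pos < te$end
      if (any(in_ex) && runif(1) < config$sqtn_in_exon) {
        pick <- cand[in_ex][sample.int(sum(in_ex), 1)]
      } else {
        eta <- truth_eta(pos[near], gene, ex, lt)
        pick <- cand[near][sample.int(sum(near), 1, prob = softmax(eta))]
      }
      res$qtn <- pick; res$effect_type <- "exon_specific"
      res$target_exon <- target; res$effect_size <- config$beta_exon
    } else {
      eta <- truth_eta(pos, gene, ex, lt)
      pick <- cand[sample.int(length(cand), 1, prob = softmax(eta))]
      res$qtn <- pick; res$effect_type <- "gene_level"
      res$effect_size <- config$beta_gene
    }
    res
  })
  do.call(rbind, out)
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Simulate true exon-level expression
#'
#' Each exon value is gene baseline + low-rank confounding
#' (per-gene Gaussian loadings on `n_factors` Gaussian factors) + genetic
#' term + Gaussian noise. A gene-level QTL adds `effect_size * dosage` to
#' every exon of the gene; an exon-specific QTL only to its target exon.
#'
#' @param genes a [gene_models()] object.
#' @param genotypes a [geno_matrix()].
#' @param truth truth table from [place_eqtns()].
#' @param config a [sim_config()].
#' @return An [expr_matrix()] of true exon levels (platform `"true_exon"`).
#' @export
simulate_expression <- function(genes, genotypes, truth, config) {
  set.seed(config$seed + 4L)
  samples <- sim_samples(config)
  m <- nrow(samples)
  ex <- genes$exons[order(genes$exons$gene_id, genes$exons$exon_index), ]
  gids <- genes$genes$gene_id
  baseline <- setNames(rnorm(length(gids), config$baseline_mean, config$baseline_sd), gids)
  nf <- config$n_factors
  fac <- if (nf > 0) matrix(rnorm(nf * m, 0, config$factor_sd), nf, m) else NULL
  load <- if (nf > 0) matrix(rnorm(length(gids) * nf), length(gids), nf,
                             dimnames = list(gids, NULL)) else NULL
  vals <- matrix(0, nrow(ex), m)
  gene_term <- matrix(0, length(gids), m, dimnames = list(gids, NULL))
  gene_term[] <- baseline[gids]
  if (nf > 0) gene_term <- gene_term + load %*% fac
  vals <- gene_term[ex$gene_id, , drop = FALSE]
  for (i in which(!is.na(truth$qtn))) {
    dos <- genotypes$dosage[truth$qtn[i], ]
    rows <- which(ex$gene_id == truth$gene_id[i])
    if (truth$effect_type[i] == "gene_level") {
      vals[rows, ] <- vals[rows, ] + rep(truth$effect_size[i] * dos,
                                         each = length(rows))
    } else {
      r <- rows[ex$exon_index[rows] == truth$target_exon[i]]
      vals[r, ] <- vals[r, ] + truth$effect_size[i] * dos
    }
  }
  if (config$noise_sd > 0) vals <- vals + rnorm(length(vals), 0, config$noise_sd)
  chrom <- genes$genes$chrom[match(ex$gene_id, genes$genes$gene_id)]
  features <- data.frame(feature_id = paste0(ex$gene_id, "_e", ex$exon_index),
                         gene_id = ex$gene_id, exon_index = ex$exon_index,
                         chrom = chrom, start = ex$start, end = ex$end,
                         platform = "true_exon", stringsAsFactors = FALSE)
  expr_matrix(vals, features, samples)
}

#' Render true exon expression through a platform observation model
#'
#' * `three_prime_probe`: exactly one probe per gene, placed in the last
#'   exon with probability `probe_last_exon_frac` (else a uniformly chosen
#'   exon); value = that exon's level + probe noise.
#' * `exon_array`: one probe per exon + probe noise.
#' * `exon_counts`: per-exon counts `Poisson(exp(level) * exon_kb * scale)`.
#'
#' Features carry genomic intervals (probe footprints for arrays, exon
#' intervals for counts) so that variant-overlap filtering and window logic
#' apply downstream.
#'
#' @param true_exons [expr_matrix()] from [simulate_expression()].
#' @param platform one of `"three_prime_probe"`, `"exon_array"`,
#'   `"exon_counts"`.
#' @param config a [sim_config()].
#' @return An [expr_matrix()] for the platform.
#' @export
render_platform <- function(true_exons,
                            platform = c("three_prime_probe", "exon_array",
                                         "exon_counts"),
                            config) {
  platform <- match.arg(platform)
  feats <- true_exons$features
  vals <- true_exons$values
  if (platform == "three_prime_probe") {
    set.seed(config$seed + 5L)
    rows <- unlist(lapply(split(seq_len(nrow(feats)), feats$gene_id), function(idx) {
      k <- length(idx)
      last_row <- idx[which.max(feats$exon_index[idx])]
      if (runif(1) < config$probe_last_exon_frac) last_row
      else idx[sample.int(k, 1)]
    }))
    rows <- rows[order(match(feats$gene_id[rows], unique(feats$gene_id)))]
    v <- vals[rows, , drop = FALSE] +
      rnorm(length(rows) * ncol(vals), 0, config$probe_noise_sd)
    f <- feats[rows, , drop = FALSE]
    pl <- pmin(config$probe_length, f$end - f$start)
    off <- floor(runif(nrow(f)) * (f$end - f$start - pl + 1))
    f$start <- f$start + off; f$end <- f$start + pl
    f$feature_id <- paste0(f$gene_id, "_probe")
    f$platform <- platform
    expr_matrix(v, f, true_exons$samples)
  } else if (platform == "exon_array") {
    set.seed(config$seed + 6L)
    v <- vals + rnorm(length(vals), 0, config$probe_noise_sd)
    f <- feats
    pl <- pmin(config$probe_length, f$end - f$start)
    off <- floor(runif(nrow(f)) * (f$end - f$start - pl + 1))
    f$start <- f$start + off; f$end <- f$start + pl
    f$feature_id <- paste0(f$feature_id, "_p")
    f$platform <- platform
    expr_matrix(v, f, true_exons$samples)
  } else {
    set.seed(config$seed + 7L)
    len <- feats$end - feats$start
    if (any(len <= 0)) stop("zero-length exon cannot be rendered as counts")
    rate <- exp(pmax(pmin(vals, 30), -30)) * (len / 1000) * config$count_scale
    v <- matrix(rpois(length(rate), rate), nrow(rate), ncol(rate))
    f <- feats
    f$feature_id <- paste0(f$feature_id, "_c")
    f$platform <- platform
    expr_matrix(v, f, true_exons$samples)
  }
}

#' Simulate a complete study
#'
#' Convenience wrapper running the five generator stages in order.
#'
#' @param config a [sim_config()].
#' @param platforms character vector of platforms to render.
#' @return list with `genes`, `genotypes`, `truth`, `true_exons`, and one
#'   rendered [expr_matrix()] per requested platform.
#' @export
simulate_study <- function(config,
                           platforms = c("three_prime_probe", "exon_array",
                                         "exon_counts")) {
  genes <- simulate_gene_models(config)
  genotypes <- simulate_genotypes(config, genes)
  truth <- place_eqtns(genes, genotypes, config)
  true_exons <- simulate_expression(genes, genotypes, truth, config)
  rendered <- lapply(platforms, render_platform, true_exons = true_exons,
                     config = config)
  names(rendered) <- platforms
  c(list(genes = genes, genotypes = genotypes, truth = truth,
         true_exons = true_exons), rendered)
}
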