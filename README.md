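# eqtnpos

Positional analysis of cis-eQTLs across expression platforms.

## The problem

Mapping expression quantitative trait loci (eQTLs) in cis asks where the
variants that move a gene's expression sit relative to that gene. On
single-probe 3' expression arrays, an apparent second peak of eQTLs appears
just upstream of the transcription end site (TES) — but a platform that
measures a gene only through a probe in its last exon cannot distinguish a
whole-gene eQTL from a variant that changes the inclusion or stability of
the last exon alone (an exon-specific or "splicing" QTL). `eqtnpos` is for
statistical geneticists who want to study — and stress-test — how eQTN
positional inferences depend on the measurement platform. It provides an
end-to-end, fully synthetic-testable pipeline:

* a **synthetic-data generator** with known ground truth: gene models with
  3'UTR-bearing terminal exons, unlinked cis SNPs with a 1/f MAF spectrum,
  planted gene-level and exon-specific QTLs, low-rank confounding, and
  three observation models (single 3' probe, per-exon array, per-exon
  counts);
* **preprocessing**: within-population quantile normalization to normal
  scores, population mean centering, permutation-calibrated selection of
  expression PCs, and per-feature elastic-net residualization (compiled,
  leave-one-out cross-validated);
* **summarization**: robust gene levels by median polish, with
  exon-specific levels as the polish residuals;
* **cis-QTL mapping**: exhaustive linear-regression scans in a 100 kb
  gene window (10 kb per exon), tie-shared best-SNP (eQTN) assignment, and
  a permutation-based empirical FDR;
* the **positional model**: a weighted multinomial (softmax) prior over
  each gene's candidate SNPs with TSS-distance bins and
  intragenic/intron/exon/last-exon annotations, four nested
  parameterizations (M0–M3) compared by AIC, and annotation odds ratios
  with Wald 95% CIs;
* **cross-platform replication**: classify eQTNs into five positional
  categories and test them at gene and exon level in a second platform.

The model: for gene $g$ with candidate SNPs $j$ carrying annotation
vectors $a_{gj}$, the prior that SNP $j$ is the eQTN is
$\pi_{gj} \propto \exp(\lambda^\top a_{gj})$, and the likelihood over
significant genes is $\sum_g \log \sum_j w_{gj}\pi_{gj}$ with $w$ the
tie-shared best-SNP weights. Model M3's extra last-exon parameter, judged
by AIC, is the formal test for "is the last exon special?".

## Worked example

Plant eQTNs under a known positional prior (exon/intron enrichment 12,
no special last-exon effect), then refit the four nested models:

```r
library(eqtnpos)
cfg <- sim_config(n_genes = 300, n_samples = c(P = 4), prop_qtl = 1,
                  prop_exon_specific = 0, seed = 42)
genes <- simulate_gene_models(cfg)
geno  <- simulate_genotypes(cfg, genes)
truth <- place_eqtns(genes, geno, cfg)
planted <- truth[!is.na(truth$qtn), ]
asn <- data.frame(feature_id = planted$gene_id, gene_id = planted$gene_id,
                  snp_id = planted$qtn, weight = 1, min_p = 0)
pd <- positional_data(asn, genes, geno)
fits <- lapply(c("M0", "M1", "M2", "M3"), function(m) fit_positional_model(pd, m))
compare_models(fits)
fits[[3]]
```

```
AIC comparison (best: M2 )
  model  k   loglik     AIC       dAIC
1    M0 12 -1269.52 2563.05 413.809233
2    M1 13 -1207.16 2440.33 291.084770
3    M2 14 -1060.62 2149.24   0.000000
4    M3 15 -1059.96 2149.93   0.687381
Positional eQTN model M2 ( 300 genes )
  logLik -1060.62  k = 14  AIC 2149.24 
  odds ratios [95% CI]:
    exon/intron                 15.70 [11.39, 21.65]
```

Reading this: distance alone (M0) is a poor description; allowing
transcribed-region and then exon/intron enrichment improves the fit
enormously (dAIC 414 → 291 → 0); splitting off the last exon (M3) buys
nothing — correctly, since the truth had no last-exon effect — and its
dAIC of ~0.7 is within the expected price of one wasted parameter. The
estimated exon/intron odds ratio (15.7, CI [11.4, 21.7]) covers the
planted enrichment of 12.

The full demonstration — render the same ground truth through a single
3'-probe platform versus gene-level summarized exon counts and watch the
3' platform (and only it) select the last-exon model — is
`platform_artifact_experiment()`; `run_pipeline()` writes every stage
(gene models as BED12, genotypes, eQTN weights, AIC tables, odds ratios,
location histograms, replication table) to a directory of TSVs.

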