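---
title: "Where do cis-eQTNs sit? Methods and design of eqtnpos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Where do cis-eQTNs sit? Methods and design of eqtnpos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Cis-acting expression QTLs cluster around their target genes, with peak
density at the transcription start site (TSS). Expression arrays that probe
each gene with a single 3' probe have additionally shown an intriguing
second peak of eQTLs just upstream of the transcription end site (TES).
`eqtnpos` implements the analysis that disentangles this signal: when a
platform measures a gene only through its last exon, a variant that changes
the inclusion or stability of that exon alone (an exon-specific or
"splicing" QTL, sQTL) is indistinguishable from a whole-gene eQTL. The
package provides the full chain needed to demonstrate — on synthetic data
with known ground truth — that single-3'-probe platforms convert
last-exon-specific QTLs into a spurious TES peak, while per-exon platforms
summarized to gene level do not show it.

## The positional model

For each gene $g$ with a significant cis association, the most significant
SNP is taken as the putative eQTN; when several SNPs tie at the minimum
p-value (compared after rounding to 12 significant digits), they share the
eQTN probability equally (weights $w_{gj}$). Given candidate SNPs $j$ with
annotation vectors $a_{gj}$, the prior that SNP $j$ is the eQTN is the
multinomial softmax

$$\pi_{gj}(\lambda) = \frac{\exp(\lambda^\top a_{gj})}
{\sum_k \exp(\lambda^\top a_{gk})},$$

and the model log-likelihood is $\sum_g \log \sum_j w_{gj}\,\pi_{gj}$.
Annotations comprise a signed, transcription-oriented TSS-distance bin
(edges at ±0, 1, 5, 10, 25, 50, 100 kb; 14 bins; the most upstream
non-empty bin is the reference with coefficient 0) plus, in four nested
parameterizations:

* **M0** — distance only;
* **M1** — + intragenic indicator;
* **M2** — intragenic split into exclusive *intron* and *exon*;
* **M3** — exon split into *exon-except-last* and *last exon*.

Models are compared by AIC ($2k - 2\log L$). Coefficient contrasts are
reported as odds ratios — e.g. $\exp(\lambda_{\text{exon}} -
\lambda_{\text{intron}})$, the relative odds that an exonic SNP is the eQTN
versus an intronic SNP in the same distance bin — with Wald 95% CIs from
the inverse observed information and the delta method.

Numerical details: the likelihood is maximized by L-BFGS-B from
$\lambda = 0$ with coefficients bounded at ±15; hitting a bound flags
separation (an annotation perfectly predicting all eQTNs). Candidate SNPs
of a gene that share a (distance bin × annotation) class are exchangeable
under the softmax, so they are collapsed to one row with a multiplicity;
this leaves the likelihood unchanged and makes fitting cost independent of
SNP density. Because each candidate carries exactly one distance-bin
indicator, an un-anchored distance parameterization has a flat direction
(adding a constant to every bin coefficient); fixing the reference bin
removes it, and recovery simulations confirm a nonsingular Hessian.

## The synthetic study

`sim_config()` fixes the study conditions; they were chosen once, on
field knowledge, and the same defaults drive the acceptance analyses.

* **Cohort**: 210 samples in four populations (60 + 60 + 45 + 45), the
  size and structure of the standard multi-population lymphoblastoid
  reference panels profiled on single-probe arrays, with per-sample sex
  labels.
* **Gene architecture**: exon count $1 + \text{Poisson}(8)$ (mean 9,
  the human annotation average); internal exon
  lengths lognormal with median 150 bp; *terminal* exons lognormal with
  median 1 kb — the last exon contains the 3' UTR and is several-fold
  longer than internal exons in real annotation, which is precisely why 3'
  probes sit there and why cis SNPs can fall inside it at all; introns
  lognormal with median 1.5 kb. Both strands; genes non-overlapping, with
  > 210 kb gaps so neighbouring 100 kb cis windows never share SNPs.
* **Genotypes**: unlinked SNPs at 2 per kb over each transcript ± 100 kb,
  MAF from a 1/f spectrum on [0.01, 0.5] (the neutral site-frequency
  shape), dosages Binomial(2, MAF). Without LD, 2 independent SNPs/kb
  carry more mapping information than the denser but highly correlated
  real SNP set; the stored MAF is the folded empirical frequency and SNPs
  at or below 1% MAF are excluded, matching the mapping filter.
* **Planted effects**: half the genes carry a QTL; 40% of QTLs are
  exon-specific, the rest gene-level (so the majority of detected QTLs
  remain gene-level, as observed on single-probe arrays). Gene-level eQTNs
  are placed by the softmax prior itself (TSS-peaked distance profile,
  intron enrichment 5, exon enrichment 12 **with no extra last-exon
  effect** — so any last-exon signal downstream is an artifact of
  observation, not of placement). Exon-specific QTLs target the last exon
  with probability 0.85 (terminal exons are the most sQTL-prone) and their
  QTN lies inside the target exon with probability 0.9 (3' UTR, splice
  element and miRNA-site variants act from within the exon they affect),
  otherwise within 10 kb of it. Effect sizes: 1.0 sd (gene) and 2.0 sd (exon) per
  dosage unit — large, as detected QTLs are; exemplar exon-level
  associations on arrays reach p ~ 1e-11 at this cohort size.
* **Confounding and noise**: 3 Gaussian hidden factors with per-gene
  Gaussian loadings (sd 1 each), plus iid Gaussian noise (sd 1), matching
  the PCA-based correction the pipeline applies.
* **Observation models**: `three_prime_probe` (one probe per gene, in the
  last exon with probability 0.85 — the 3'-biased design — plus
  measurement noise sd 0.25); `exon_array` (one probe per exon, same
  noise); `exon_counts` (Poisson with rate $e^{\text{level}} \times
  \text{exon kb} \times 5$). Probe footprints (25 bp) carry genomic
  intervals so variant-overlap filtering is exercised.

What the generator does **not** emulate: linkage disequilibrium (the
mapping treats the best SNP as the eQTN proxy, so LD realism is not needed
for recovery; an LD-free panel also makes "the planted SNP wins" checks
exact), allele-frequency–effect-size coupling, overdispersed counts
(Poisson only; the platform artifact is qualitative), isoform-level
complexity beyond one exon deviating, population structure beyond labelled
groups, and trans effects. Passing tests therefore validate the machinery
and the qualitative platform artifact, not quantitative agreement with any
particular human dataset.

## Preprocessing

Each platform matrix is quantile-normalized to a standard normal within
population (scores $\Phi^{-1}(r/(n+1))$, ties averaged), population-mean
centered, and cleaned of hidden structure: PCA eigenvalues are compared to
a null built from 100 independent per-feature permutations, $K$ = length
of the leading run of observed eigenvalues above the per-rank 97.5%
envelope ("the last PC exceeding the null", read as a contiguous run so an
isolated deep-rank exceedance cannot inflate $K$). The top-$K$ PCs plus
population and sex covariates are then regressed out feature by feature
with an elastic net: the ridge penalty $\lambda_2$ runs over the 6-point
grid $\{10^{-2}, 10^{-1}, 1, 10, 10^2, 10^3\}$ (near-lasso to near-ridge),
the lasso penalty over a 20-point log path, and both are chosen by
leave-one-out cross-validated prediction error. The reported fit is a
relaxed refit — OLS on the support the chosen elastic net selects — so a
feature exactly spanned by the retained PCs yields exactly zero residuals,
and independent features keep their variance. The solver is a compiled
coordinate descent over downdated Gram sums (cost per fold independent of
$n$), cross-checked in the tests against `glmnet` through the exact
penalty correspondence.

Non-expressed features are removable by three rules: MAD below a threshold
(default: the 25th percentile of feature MADs — the field's usual
visual-inspection cutoff on the MAD scatter is not reproducible, so a
quartile rule stands in; override `threshold` to use a platform-specific
value), median level below a required threshold in all
populations (the array intensity cutoff is dataset-specific and therefore
a required argument), or within-population median count of zero in every
population.

## Summarization

Gene expression is the per-sample effect plus overall term of a median
polish of the gene's probes × samples matrix. The probe dimension is swept
first and its effect vector is left uncentered: a constant offset on any
single probe (its affinity) is then absorbed into that probe's effect
*exactly* and can never shift the gene levels — with the opposite sweep
order a large single-probe offset moves the sample medians by an
order-statistic gap. A single-probe gene's levels are simply that probe's
values. Iteration stops when fitted values change by less than `tol`
(1e-6) or at `max_iter` (100); the decomposition identity
`input = overall + row + col + residual` is exact at every iteration by
construction, and the generic `median_polish()` keeps the conventional
fully-centered form. Exon-specific ("splicing") expression is the residual
matrix of the gene-level polish: a gene-level genetic effect is absorbed
into the sample effects while a single deviating exon stays in the
residuals; note the absorption is exact only in the noise-free limit — for
a gene with k measured exons, shifting one exon moves each sample's median
by an order-statistic gap, which is why gene-level analyses of few-exon
genes retain a trace of strong exon-specific QTLs (visible in the
platform-artifact experiment, and the reason its counts arm requires at
least two measured exons per gene). Genes need at least two measured exons
to enter the sQTN analysis. An optional `exon_first` strategy polishes
probes to exon level before the gene-level polish.

## Mapping and FDR

Association is ordinary least squares of (corrected) expression on dosage,
p-values two-sided from $t$ on $n-2$ df; every reported p equals the
correlation-test closed form, which the tests assert to $10^{-12}$.
Candidate windows: transcript ± 100 kb at gene level, exon ± 10 kb at exon
level, all intervals half-open. The empirical FDR permutes sample labels
within population (jointly across features, preserving their correlation —
the standard min-p permutation estimator; the within-population scheme
also preserves population means so structure cannot masquerade as signal),
recomputes per-feature minimum p-values, and reports the largest observed
min-p threshold $t$ with
$\widehat{\text{FDR}}(t) = \frac{(1 + \#\text{null} \le t)/(B+1)}
{\#\text{obs} \le t} \le \text{target}$ (default 5%); the add-one
numerator is the finite-permutation correction that keeps a single lucky
observed minimum from claiming an FDR of zero at small $B$.

## Problem sizes

The acceptance analyses run at sizes chosen to give each property clear
resolution on a single core: PC selection at 50 features × 40 samples over
100 seeds; FDR control at 500 null genes × 10 permutations × 20 seeds;
odds-ratio recovery at 2 000 significant genes × 100 placement
replicates (model selection at 500)
(the candidate frame is built once and only the eQTN draw varies —
placement, not expression, is what those replicates test); the
platform-artifact experiment at 600 genes × 210 samples through the full
expression pipeline.

## Known limitations

* The likelihood uses tie-shared best-SNP weights, not per-SNP Bayes
  factors; with LD-free genotypes the best SNP is almost always the causal
  one, but on real, LD-structured data a Bayes-factor weighting would be
  preferable.
* AIC differences between nested models with one extra parameter hover
  near the 2-unit penalty when the effect is absent; "weakly disfavored by
  ~2 units" is the expected behaviour, not evidence against a model.
* The empirical FDR needs enough permutations for a stable null at small
  targets; the default of 10 suits the simulation scale, not a
  genome-wide study.
* Single-exon genes cannot host an exon-specific QTL distinct from a
  gene-level one; their exon is categorized as "last" (it ends at the
  TES), which is a convention, not an inference.
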