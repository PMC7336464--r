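---
title: "Models and methods behind dyneqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyneqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the design decisions that were
genuinely open when the package was built. It states no empirical result
that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## 1. The mixed model and P3D variance components

For one gene's transformed expression vector $y$ ($n$ samples, one
condition) the scan fits

$$ y = W\alpha + u + e, \qquad u \sim N(0, \sigma^2_g K), \qquad
   e \sim N(0, \sigma^2_e I), $$

where $W$ stacks an intercept, genotype principal components (population
structure) and hidden expression factors, and $K$ is the
identity-by-state kinship. We profile the REML log-likelihood over the
variance ratio $\delta = \sigma^2_e / \sigma^2_g$ after a single
eigendecomposition $K = U D U^\top$: a 101-point grid on
$\log_{10}\delta \in [-5, 5]$ followed by golden-section refinement in
the bracketing interval. The fitted $\hat\delta$ is reused for every SNP
of that gene ("population parameters previously determined"); each SNP
is then a generalized-least-squares Wald test in the rotated system,
with degrees of freedom $n - \operatorname{rank}(W) - 1$ and partial
determination coefficient $t^2 / (t^2 + \mathrm{df})$, the quantity we
report as an eQTL's effect size. The published analysis never defines
"determination coefficient" operationally; lead-SNP partial $r^2$ from
the MLM is our interpretation. With $K = I$ the whole machinery
collapses to per-SNP OLS exactly (a unit test asserts agreement to
1e-8), which pins the rotation and weighting code.

Missing dosages are mean-imputed per SNP before testing (so monomorphic
columns are skipped); samples with missing expression are dropped per
gene and the null model re-fit on the subset. A non-positive-definite
kinship receives a 1e-6 ridge and is flagged.

**Significance.** p-values are pooled genome-wide *within* a condition
and the Benjamini–Hochberg step-up cutoff is computed over that pool —
matching the single per-condition rejection thresholds the study design
implies. An enumeration oracle and `p.adjust` serve as independent
cross-checks in the tests.

## 2. Kinship at desk scale

The prescribed kinship uses one SNP per 10-kb window (the least-missing
one). On a genome-wide panel that yields tens of thousands of SNPs and
each locus carries negligible weight in $K$. On a single simulated
chromosome of a few hundred kb, however, the same rule leaves only
~75 SNPs, so the SNPs tagging any causal locus contribute several
percent of $K$; REML then attributes the local genetic variance to the
random effect and the scan loses the very signal it is testing
(proximal contamination). `run_study_analysis(kinship = "all")`
therefore builds $K$ from *all* QC'd SNPs for desk-scale panels — the
analogue of the genome-wide thinned set, where per-locus weight is again
negligible — while `thin_snps_by_window()` implements and tests the
windowing rule itself. Analyses of genome-scale panels should use
`kinship = "thinned"`.

## 3. Hidden factors and their scale limits

Hidden confounders are estimated PEER-style: each gene is residualized
on the structure covariates, and the top $k$ sample-space principal
components of the residual matrix enter $W$ as fixed effects. The
study-scale default is $k = 14$ — appropriate when factors are estimated
from tens of thousands of genes. From a simulated panel of ~100 genes,
however, residual PCs overfit individual high-variance genes and, more
damagingly, capture the shared expression variance of a TF's target set
— which *is* the TF-mediated genetic signal — so distant effects vanish
from the scan. End-to-end synthetic analyses therefore use $k = 2$
(configurable), keeping the factor count proportionate to the simulated
gene count; the calibration study (50 null genes) uses $k = 14$ as a
stress test of the correction stack. This is a property of factor
estimation at small gene counts, not of the mixed model: passing
recovery tests at $k = 2$ says nothing about how many factors a real
transcriptome-scale dataset needs.

## 4. eQTL consolidation and classification

Within an etrait-condition, SNPs passing the genome-wide cutoff are
consolidated in three steps: (1) single-linkage chaining of SNPs closer
than 5 kb; (2) transitive merging of clusters whose lead SNPs are in LD
($r^2 > 0.1$, dosage correlation over samples non-missing in both)
within 250 kb; (3) merging of clusters whose leads fall inside the same
gene body. Leads are elected by minimum p, ties broken by larger partial
$r^2$, then smaller position, making outputs deterministic. The
≥3-significant-SNP support rule is applied per etrait-condition *before*
grouping — our reading of "detected in association with each treatment";
a per-cluster variant is available via `min_snps_scope = "cluster"`.
A brute-force rule-application oracle checks the whole chain on 1000
random instances.

Locality anchors the ±20-kb window on the gene *body* (start − 20 kb to
end + 20 kb), not the TSS. Cross-condition locus identity — needed for
static/dynamic classification but undefined in the source analysis — is
declared when lead SNPs lie within 5 kb of each other *or* share
$r^2 > 0.1$: the same tolerances used within a condition. Static means
detected in every condition; the `stress_only` flag marks loci detected
under stress but not in the well-watered reference. Percentages are
rounded half-up to one decimal, the convention that reproduces published
count arithmetic exactly.

## 5. Network hierarchy

Every distant eQTL whose lead lies inside a TF gene body contributes a
directed TF → etrait edge (deduplicated per pair, condition sets
unioned). The hierarchy height $h = (O - I)/(O + I)$ counts out-edges
$O$ to any target and in-edges $I$ from other TFs. Tier boundaries are
an interpretation — the source analysis never defines its cutoffs — so
the default cuts min–max-normalized height into equal thirds
([2/3, 1] top tier), with a quantile mode as the alternative.
Family-level scores sum $O$ and $I$ over members before the ratio.

## 6. Mendelian randomization

With instrument $z$ (the gene's most significant eQTL lead SNP in that
condition, additive dosage, hets = 1), exposure $x$ (the same
condition's transformed expression) and outcome $y$ (the
condition-independent phenotype),

$$ \hat b_{xy} = \frac{\hat b_{zy}}{\hat b_{zx}}, \qquad
   \operatorname{var}(\hat b_{xy}) =
   \frac{\operatorname{var}(y)\,(1 - R^2_{xy})}
        {n \, \operatorname{var}(x) \, R^2_{zx}}, \qquad
   T_{MR} = \frac{\hat b_{xy}^2}{\operatorname{var}(\hat b_{xy})}
   \sim \chi^2_1 . $$

Sample variances use the $n-1$ denominator; samples missing any of
$z, x, y$ are dropped per test. The experiment-wise threshold defaults
to the **reciprocal** convention $1/n_{\text{tests}}$ (which reproduces
a printed $3.33 \times 10^{-5}$ at 30,006 tests); an orthodox
$0.05/n_{\text{tests}}$ Bonferroni is available. Each (gene, condition)
with a called eQTL is one test; the per-gene best record (minimum p
across conditions) drives the positive/negative direction split.

Two estimator properties worth knowing: the $(1 - R^2_{xy})$ factor
assumes the null marginal $x$–$y$ correlation is small — when
confounding induces a substantial marginal correlation the test becomes
anticonservative, so the calibration suite realizes its null with the
confounder loading on the exposure only; and weak instruments
($R^2_{zx} \to 0$) inflate the estimator's dispersion, which a test
asserts as a monotone relation.

## 7. The synthetic-data generator

The generator emulates the structure of a diverse inbred panel under
three watering regimes; its defaults are the study conditions.

* **Genotypes.** Three subpopulations under the Balding–Nichols model
  ($F_{st} = 0.1$; ancestral frequencies uniform on [0.05, 0.5]).
  Ancestral and subpopulation frequencies follow AR(1) latents along the
  chromosome (Beta marginals preserved through `qbeta` of correlated
  normals) so nearby loci are frequency-coherent, and alleles share a
  latent-uniform copying process with copy probability
  $\exp(-d / 2L)$, which together make measured $r^2$ decay on the
  configured scale $L$ (default 1,600 bp, the published panel
  estimate). Samples are inbred (hom calls) with 1% residual hets and
  2% missingness. Default SNP spacing is 250 bp — genic marker density
  for a 1.28M-SNP maize panel. One chromosome by default; genes are
  tiled 4-kb bodies, 10% flagged as TFs.
* **Causal architecture.** Local effects anchor on a SNP within 20 kb
  of the gene, restricted to *taggable* variants (≥2 neighbours at
  $r^2 \ge 0.5$): published eQTLs are conditioned on multi-SNP support,
  so the planted truth mirrors that survivorship. Effect sizes are
  calibrated so a planted effect explains its configured share of the
  gene's non-genetic variance (verified by a Monte-Carlo decomposition
  test). A `frac_static` share (default 0.27, the published static
  fraction) is active in all conditions, the rest in a random 1–2
  subset. Distant effects are transmitted through the regulator TF's own
  simulated expression — not its raw genotype — so the network stage has
  a recoverable causal chain; regulator TFs get constitutive cis effects
  from the upper half of the effect range (hotspot behaviour, and the
  distant link's dynamics then reflect the link itself, not the
  mediator), and targets are disjoint from local-eQTL genes so every
  planted effect has an unambiguous recovery signature.
* **Confounding.** 14 hidden factors with sparse loadings (80% zeros),
  plus an optional infinitesimal polygenic background
  (`polygenic_var`) used by the calibration studies to create genuine
  structure-driven inflation.
* **Phenotype.** $y$ is a linear combination of a few genes'
  transformed severe-stress expression plus noise, affinely mapped into
  [0, 1] (a survival-rate emulation). The ledger records both raw
  coefficients and the realized slopes after the mapping — recovery
  checks target the latter, since that is the slope actually present in
  the returned vector.

What the generator does *not* emulate: recombination maps and
block-structured historical LD, selection, read-level noise,
multi-allelic variation, and transcriptome-scale gene counts. Passing
recovery tests therefore demonstrates the pipeline's correctness on
panels with these simplified properties, not its power on real data.

## 8. Study sizes used by the tests and acceptance script

Calibration uses 200 samples × 5,000 SNPs × 50 null genes with a 50%
polygenic variance share (genomic inflation ~1.4 uncorrected and ~1.0
corrected at those conditions). End-to-end recovery uses 200 samples ×
3,000 SNPs × 100 genes with 30 planted local (variance share 0.2–0.4)
and 12 TF-mediated distant effects (0.4–0.6 on the mediator scale, the
attenuation arithmetic in §7 making the mediated SNP-level signal
comparable to the local one), over 10 generator seeds in the test suite
and 6 in the acceptance script. MR calibration uses 10,000 null
replicates at $n = 200$ and 200 effect-recovery replicates at
$n = 500$. These sizes are the package's chosen desk-scale study
conditions.

## 9. Numerical conventions

* Coordinates are 1-based inclusive everywhere inside the package; BED
  export is the single 0-based half-open boundary, converted exactly.
* The inverse normal transform uses the `qqnorm` offset ($a = 3/8$ for
  $n \le 10$, $a = 1/2$ otherwise) with average ranks for ties; constant
  genes transform to zeros and are flagged.
* Quantile normalization delegates to `limma::normalizeQuantiles`
  (ties receive the mean of the spanned reference quantiles).
* k-means profiles (25 restarts) are relabeled canonically by
  descending centroid slope over the condition gradient, so cluster 1
  is the most induced profile and cluster $k$ the most repressed; for
  $k = 3$ the middle cluster holds flat/variable profiles.
* PCA signs are fixed by making each loading vector's
  largest-magnitude element positive.
* Percentage reporting rounds half away from zero at one decimal.
* All simulation and analysis entry points are deterministic given
  their seeds; eigendecompositions are shared across genes when
  expression is complete, and per-gene otherwise.

## 10. Known limitations

Single-instrument MR only (no IVW/Egger/pleiotropy diagnostics);
no conditional or stepwise multi-signal dissection within an eQTL;
no fine-mapping or colocalization; the DEG rule substitutes a
fold-change-fraction + paired-Wilcoxon test for a count-model
differential test, because the pipeline's canonical input is an
abundance matrix without within-accession replicates — the 20%-of-
accessions aggregation and FDR gate are retained verbatim. The
haplotype module defines groups by exact allele strings; near-identical
strings are not collapsed.
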