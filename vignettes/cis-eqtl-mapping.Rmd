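---
title: "Refining GWAS loci with cis-eQTL mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining GWAS loci with cis-eQTL mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies nominate disease loci — for chronic
obstructive pulmonary disease, regions such as 4q22 (*FAM13A*), 4q31
(*HHIP*) and 19q13 (*EGLN2* and neighbours) — but rarely the causal gene.
One way to refine a locus is to ask which genes in the region have
expression levels under genetic control there: map cis-acting expression
quantitative trait loci (eQTLs) in a disease-relevant tissue, then check
whether the eQTL-SNPs are the GWAS SNPs themselves or in linkage
disequilibrium (LD) with them. `ciseqtl` packages that refinement procedure
as a reusable, tested pipeline, together with a simulator that generates
multi-cohort genotype/expression data with the statistical structure the
analysis assumes, so every stage can be validated without access to any
consortium data.

## The procedure

For each cohort and locus the pipeline runs five stages.

**1. Locus windows.** A locus is defined by its GWAS SNPs: the tested window
runs from 1 Mb below the lowest associated position to 1 Mb above the
highest (`build_locus_window()`, `flank_bp` configurable, floored at
position 1). Probesets enter a locus through an explicit probeset → gene →
locus map; no coordinate-based gene assignment is attempted, because the
probe annotation of a custom array is an input, not something the pipeline
should guess.

**2. Covariate adjustment.** Each expression trait $y$ is regressed on age,
sex and smoking status (two indicator contrasts, ex-vs-never and
current-vs-never) by Huber M-estimation:
$$\hat\beta = \arg\min_\beta \sum_i \rho_c\!\left(\frac{y_i - x_i^\top\beta}{\hat\sigma}\right),$$
solved by iteratively reweighted least squares with weights
$w(u) = \min(1, c/|u|)$, $c = 1.345$ (95% Gaussian efficiency — the
conventional default of the classic `rlm` routine, since neither $c$ nor the
$\psi$-function is dictated by the procedure itself). The scale
$\hat\sigma = \mathrm{median}(|r|)/0.6745$ is re-estimated every iteration —
the MAD-about-zero convention of that same routine, chosen deliberately so
an independent reference implementation converges to the same fixed point
(our oracle test demands agreement to 1e-6; it measures ~1e-12). Iteration
stops when the largest coefficient change falls below 1e-8, capped at 50
iterations. Samples missing the trait or any covariate are dropped for that
trait; there is no imputation, so the per-test $n$ varies across traits,
as it does in real cohorts.

**3. Outlier filtering.** Residuals deviating from the median by more than
three standard deviations are masked. Two readings were possible and we fix
one: the spread is the *classical sample SD* of the residual vector (not the
MAD), centred at the median as stated, computed in a *single pass* — the
mask is never re-estimated after removal. Single-pass filtering is the
conservative reading; recursive filtering can cascade on heavy-tailed
traits. If all residuals are equal (SD = 0) nothing is masked.

**4. Association scan.** Every SNP–probeset pair in the window is tested by
simple linear regression of the adjusted residual on allele dosage
(0/1/2 copies of the counted allele): $\hat\beta = S_{xy}/S_{xx}$, Wald
statistic $t = \hat\beta/\mathrm{SE}$ referred to a Student-$t$ with $n-2$
degrees of freedom, two-sided. "Asymptotic Wald p-values" underdetermines
the reference distribution; $t_{n-2}$ is the finite-sample choice that
converges to the asymptotic normal and matches the quantitative-trait test
of the standard genetics toolkit. The variance explained is the squared
Pearson correlation $r^2(g, y)$, which equals regression SS over total SS
(asserted to 1e-12). Deletion is pairwise-complete per test. Degenerate
cases are flagged, never coerced: a monomorphic SNP or constant trait is
`untestable` (not $p = 1$), perfect collinearity is `degenerate` with the
smallest representable positive $p$. No MAF or call-rate filter is applied
by default because the procedure specifies none.

**5. Multiple testing, replication, LD linkage.** The per-locus
significance threshold is a Bonferroni correction over the *effective*
numbers of tests in both dimensions,
$$\alpha_\mathrm{locus} = \frac{\alpha}{M_\mathrm{eff,SNP}\times M_\mathrm{eff,probe}},\qquad
M_\mathrm{eff} = \sum_i \big[I(|\lambda_i|\ge 1) + (|\lambda_i| - \lfloor |\lambda_i|\rfloor)\big],$$
with $\lambda_i$ the eigenvalues of the correlation matrix (Li–Ji
estimator). SNP correlations are signed Pearson correlations of dosages on
pairwise-complete samples; probeset correlations are taken on *adjusted*
residuals (whether the original analysis used raw or adjusted expression is
unstated; residuals are what is actually tested). Monomorphic SNPs and
constant traits are excluded from the matrix and counted as one independent
test each. Pairwise-complete estimation can break positive
semi-definiteness, so eigenvalues numerically below zero are clipped to
zero, and the final sum is clamped to $[1, M]$ (float noise can exceed $M$
by ~1e-15). Meff is carried at full precision; only display values are
rounded.

Discovery-significant pairs are then checked in each replication cohort at
nominal $p < 0.05$ (two-sided, matching discovery; one-sidedness is
unstated in the source procedure and asymmetric treatment would be hard to
justify). Direction of effect is recorded and reported but *not* required
for replication by default — same-direction non-significant patterns are
descriptively meaningful — with `require_direction = TRUE` available as a
strict mode. Finally, each significant eQTL-SNP is linked to the locus'
GWAS SNPs by composite LD: the squared Pearson correlation of unphased
dosages, with `linked = (max r² > 0.5)`. We use composite (dosage) r²
rather than an EM haplotype-frequency estimate because the data are
unphased and the pipeline has no phase model; GWAS SNPs absent from the
genotyping panel are reported as `not_genotyped` rather than silently
dropped.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults state the world the pipeline is meant for:

* **Cohorts** — three, of 409, 339 and 363 samples (discovery + two
  replication), the sizes of the lung study the defaults mimic.
* **Covariates** — age normal (63.3 ± 9.9 years in the discovery cohort,
  truncated to 18–95), ~56% male, smoking multinomial dominated by
  ex-smokers, with per-cohort missingness (0 / 15.3% / 5.8%) so the
  complete-case machinery is exercised.
* **Genotypes** — 700 SNPs in 10 independent blocks; each individual draws
  two haplotypes per block from a shared pool of 8. Small pools give strong
  blocky within-block LD and exact {0,1,2} dosages; blocks are independent
  by construction, giving a clean null for between-block LD tests. Pools
  are shared across cohorts so cross-cohort LD is consistent. A
  haplotype-pool mosaic was chosen over a Gaussian copula precisely because
  it is exact, discrete and trivially reproducible. Pool columns are kept
  segregating (for pools of ≥ 2 haplotypes) because genotyping panels
  target polymorphic SNPs; a single-haplotype pool still yields monomorphic
  SNPs, as it must.
* **Planted eQTLs** — a ladder of variance-explained values from 0.05 to
  0.57, the range spanned by the headline signals of the motivating study
  (strongest: ~50–57% for the *PPM1K*-class signal; weakest replicated:
  ~5–12%). The genetic effect is scaled to the realized genotype variance
  so that $h^2 = \mathrm{Var}(\beta g)/(\mathrm{Var}(\beta g)+\sigma^2)$
  holds on the covariate-adjusted scale — which is the scale the scan
  estimates.
* **Outliers** — 1% of expression values per trait receive extra noise of
  SD 5 (against a unit noise SD), giving the 3-SD filter genuine gross
  errors to remove.

Not emulated: population structure and relatedness, genotyping or
imputation uncertainty beyond random missingness, probe cross-hybridization,
cell-type heterogeneity of bulk tissue, and any realistic recombination
gradient within blocks. A green pipeline run on simulated data therefore
establishes the statistical machinery (calibration, power, bookkeeping,
determinism), not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Ties in result ordering are broken by SNP then probeset ID, so reports
  are byte-identical across reruns; no output carries a timestamp.
* p-values are floored at the smallest representable positive double —
  the contract is $p \in (0, 1]$.
* Missing data use `NA` throughout; all coordinates are 1-based inclusive
  internally, with BED-style inputs converted at the read boundary.
* Rank-deficient adjustment designs abort naming the collinear column;
  fewer than 10 complete samples for a trait aborts rather than fitting.
* An empty locus window warns and produces empty (header-only) reports,
  exiting successfully — absence of SNPs is a data condition, not a bug.

## Known limitations

The composite dosage r² underestimates haplotype r² when phase matters; the
Li–Ji threshold is approximately conservative rather than exact (our
permutation-oracle test only brackets it within a factor of 3); and the
replication classifier treats cohorts symmetrically, with no meta-analysis
across them — fixed- or random-effects pooling was deliberately left out of
scope.
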