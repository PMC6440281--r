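---
title: "Identifying mediated trans-eQTLs with multiple cis-mediators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying mediated trans-eQTLs with multiple cis-mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtrans)
```

# The scientific question

Trans-eQTLs — variants associated with the expression of genes more than
1 Mb away or on other chromosomes — often act indirectly: the variant
perturbs a nearby (cis) gene whose product then regulates the distant gene.
Mediation analysis formalizes this, but the common single-mediator version
is fragile: cis-genes are correlated, and when a second cis-gene both
responds to the variant and acts on the trans-gene, the one-mediator model
is misspecified. `medtrans` fits the joint model with an arbitrary number
of mediators and correlated mediator errors, and provides three bootstrap
tests whose contrast is the heart of the method.

# Model and estimands

For subject $i$, trans-gene expression $Y_i$, minor-allele dosage $X_i \in
\{0,1,2\}$, mediators $M_i \in \mathbb{R}^p$ and covariates $C_i \in
\mathbb{R}^q$:

$$Y_i = \beta_0 + X_i\beta_X + M_i^\top\beta_M + C_i^\top\beta_C + \varepsilon_{Y_i},
\qquad \varepsilon_{Y_i} \sim N(0, \sigma^2)$$
$$M_{ij} = \alpha_{0j} + X_i\alpha_{Xj} + C_i^\top\alpha_{Cj} + \varepsilon_{M_{ij}},
\qquad \varepsilon_{M_i} \sim N_p(\mathbf{0}, \Sigma)$$

$\varepsilon_Y$ is independent of $\varepsilon_M$, but $\Sigma$ has free
off-diagonals: mediator errors may be correlated, which is exactly the
feature the single-mediator model cannot accommodate. Estimation is two
stages of ordinary least squares (`fit_mediation()`); the estimands are the
products

- total mediation effect $\Delta = \alpha_X^\top \beta_M$ (`tme()`),
- component-wise effects $\delta_j = \alpha_{Xj}\beta_{M_j}$ (`cme()`),

with $\Delta = \sum_j \delta_j$ holding identically on every fit. The
hypotheses differ in scope: $H_0\!: \Delta = 0$ is a broader null than
$H_0\!: \delta = \mathbf{0}$ — components of opposite sign can cancel in
the sum. That *cancellation effect* is why both tests exist: the CME test
retains power where the TME statistic sits at zero by construction.

## Bootstrap inference

All three tests use nonparametric case resampling: whole rows
$(Y_i, X_i, M_i, C_i)$ are drawn with replacement, the model refitted, and
the two-sided percentile p-value computed as

$$p = \min\!\Big(1,\; 2\min\big(\tfrac{1 + \#\{\hat\theta^* \le 0\}}{B+1},\;
\tfrac{1 + \#\{\hat\theta^* \ge 0\}}{B+1}\big)\Big),$$

bounded below by $1/(B+1)$ and above by 1. Case resampling was chosen over
residual or parametric schemes because it makes no distributional
assumption about the errors and is the common choice in applied mediation
work; the add-one correction keeps p-values strictly positive and mildly
conservative.

- **TME** (`bootstrap_test_tme()`): percentile p of $\Delta^*$.
- **CME** (`bootstrap_test_cme()`): per-component percentile p-values
  combined by Bonferroni, $p = \min(1, p\,\min_j p_j)$. The literature the
  component-wise null comes from does not pin down a unique combination
  rule; Bonferroni controls the composite null, reduces exactly to the TME
  test at $p = 1$, and its behavior is validated empirically by the type-I
  and power tests in this package rather than assumed.
- **SME** (`bootstrap_test_sme()`): the product statistic from the model
  containing only mediator $j$ — deliberately misspecified when other
  mediators act on $Y$, because quantifying that misspecification is the
  point. `sme_any()` runs all $p$ single-mediator tests and, by default,
  rejects when any of them rejects (an explicitly uncorrected rule, kept
  because it mirrors how single-mediator analyses are used in practice; a
  Bonferroni switch is provided).

Resamples on which the dosage is constant admit no fit and are redrawn
rather than dropped, keeping $B$ fixed; the redraw count is reported. The
default $B = 1000$ for trio analysis (and 500 inside simulations, where the
replicate dimension supplies additional averaging) balances the p-value
floor against runtime; no canonical resample count exists for this design,
so these are package defaults.

# The discovery pipeline

**Genotype QC** (`qc_filter()`) applies, in order: sample call rate
$\ge 0.97$; SNP missing rate $< 0.08$; MAF strictly $> 0.10$; exact
Hardy-Weinberg p $\ge 10^{-5}$. The order matters — SNP statistics are
computed on the retained samples — and matches the order in which such
filters are conventionally narrated. The HWE test is the exact conditional
test (enumeration of the heterozygote-count distribution given allele
counts) rather than the chi-square approximation, because the $10^{-5}$
threshold lives in the far tail where the approximation is unreliable.
Retained SNPs are recoded so dosages count the minor allele
(`orient_minor_allele()`), making effect signs comparable across SNPs.
`dedup_complete_ld()` collapses groups of SNPs with pairwise $r^2 = 1$ or
identical coordinates to a single representative; the default
representative is deterministic (lowest position, then id) for
reproducibility, with a seeded random mode for fidelity to the original
random choice.

**Expression normalization**: `quantile_normalize()` (classic across-sample
quantile normalization via `limma::normalizeQuantiles`, ties receiving the
mean of the tied reference values — the microarray convention) reduces
inter-individual distributional differences; `inverse_normal_transform()`
(Blom offsets, $(r - 3/8)/(n + 1/4)$, ties mid-ranked) is applied per probe
before mediation testing so values approximate normality.

**eQTL scan** (`eqtl_scan()`): every SNP-probe pair is tested by OLS of
expression on dosage and covariates, complete-case in the dosage (dropping
samples rather than imputing keeps the $t$ reference distribution exact; a
mean-imputation scan would be slightly more powerful but approximate). A
pair is *cis* when the SNP lies within 1 Mb of the probe interval on the
same chromosome — distance is to the interval, zero if inside — and
*trans* otherwise. BH q-values are computed separately within the cis and
trans classes over the whole scan (the genome-wide reading of "FDR");
perfect fits report the machine-epsilon p floor with a `degenerate` flag
instead of an exact zero.

**Trio construction** (`build_trios()`): a trio is formed for each
(SNP, trans-probe) pair with trans $p < 10^{-6}$ (strict) whose SNP has at
least one cis-gene at $q \le 0.05$; mediators are ordered by ascending cis
p-value and truncated to five. Truncation by smallest p is a package
choice — only the "at most 5" bound is inherited.

# The simulation study

`scenario_config()` + `run_scenario()` implement a three-scenario
misspecification study with two mediators throughout:

| parameter | value |
|---|---|
| SNP MAF | 0.3 |
| $\alpha_{X1}$ | grid $\{0.2, 0.4, 0.6, 0.8, 1.0\}$ |
| $\alpha_{X2}$ | 0.6 |
| $\alpha_{01}, \alpha_{02}, \beta_0$ | 0.5 |
| $\beta_X$ | 0.3 |
| mediator errors | bivariate normal, variance 1, correlation 0.2 |
| outcome error | standard normal |
| $n$ | 100 or 300 |

Scenario I sets $\beta_{M_1} = 0.1, \beta_{M_2} = 0$ (power) — only the
first mediator is real, so the joint model carries an irrelevant variable
and the single-mediator test of $M_1$ is the true model. Scenario II sets
$\beta_{M_2} = +0.1$ (same-direction effects), Scenario III
$\beta_{M_2} = -0.1$ (opposite direction; the total effect cancels exactly
at $\alpha_{X1} = 0.6$). Under `mode = "type1"` both outcome effects are
zero — the one configuration under which the three scenarios share a null,
which is the reading required for them to be reported jointly.

Three structural choices deserve a note. The default $\alpha_{X1}$ grid is
$\{0.2, \dots, 1.0\}$ in steps of 0.2: five points are enough to resolve
the qualitative curve shapes — including the Scenario III power minimum at
the cancellation point — at a fifth of the cost of a fine grid. In Scenario I the SME entry tests only
the true mediator (that is what "correctly specified" means there); in
Scenarios II/III it tests both mediators and rejects if either does — an
intentionally anti-conservative rule (two 5%-level tests) whose level is
therefore *not* asserted to sit in the 5% band, while TME and CME are.
Replicates run serially under one master seed, so a fixed seed yields
bit-identical tables regardless of the hardware's parallelism.

The per-replicate hot path (tens of thousands of small least-squares fits
per grid point) runs in compiled code (`RcppArmadillo`); the observed-data
fits go through the R implementation, which is property-tested against a
normal-equations oracle, and a dedicated test pins the compiled statistics
to the R fit on identity resamples.

# Enrichment analyses

`permutation_enrichment_test()` asks whether a query SNP set (e.g.
trans-eQTLs) is enriched for association with multiple cis-genes: each of
$B$ draws samples a MAF-matched background set (bins of width 0.05 —
matching is on MAF only, the one feature the procedure names; the width is
configurable) and the empirical p is $(1 + \#\{stat^* \ge obs\})/(B+1)$.
`fisher_exact_2x2()` tests trait-association enrichment in mediated
trans-eQTLs; it reports the sample odds ratio $(ad)/(bc)$ and a two-sided
exact p (the sum-of-smaller-probabilities convention, which is also how
the reference software reports such tables; a one-sided mode exists).

# Synthetic fixtures: what they do and do not show

`fixture_spec()` and its generators produce genotype, expression and
covariate tables with planted structure: HWE-consistent dosages with MAF
uniform on a configurable range, mediator probes placed within the cis
window of their SNP on one of two synthetic chromosomes, trans probes on
the other chromosome, mediators and trans-genes generated by the forward
mediation model with exchangeable error correlation, plus pure-noise
probes. Planted effect sizes default to $\alpha_X = 0.8$, $\beta_M = 0.3$
at $n = 300$ — deliberately stronger than the simulation study's marginal
effects, because the fixture's job is reliable end-to-end detection at
desk scale, not power measurement.

What the fixtures do **not** emulate: linkage disequilibrium between
distinct SNPs, population structure and admixture, batch effects or hidden
expression factors (covariates are consumed, never estimated), isoform
structure, or heavy-tailed expression noise. Pipeline tests passing on
fixtures therefore demonstrate the statistical machinery and its plumbing,
not robustness to those real-data complications; covariate adjustment is
exercised mechanically but its adequacy on real confounding cannot be
established here.

# Numerical conventions and degenerate inputs

- Missing dosage tokens `NA`, `.`, `-9`, empty are accepted on read; `NA`
  written out. Dosages outside $\{0,1,2\}$ are hard errors naming the SNP.
- Coordinates are 1-based inclusive everywhere; probe intervals are
  orientation-free.
- Complete-LD detection uses $|r| \ge 1 - 10^{-9}$ on shared non-missing
  samples, catching reversed allele codings as well as identical vectors.
- Rank-deficient designs are refused with the offending columns named —
  including the unidentifiable limit where mediators are deterministic
  functions of the dosage.
- Exact-test tie comparisons (`hwe_exact_test`) use a $1 + 10^{-10}$
  relative guard so floating-point noise cannot split tied outcomes.
- Constant-dosage SNPs are skipped (scan) or redrawn (bootstrap), never
  silently imputed.

# Problem sizes in the test suite

The shipped tests run the type-I study at $n = 100$ with 1000 replicates
and $B = 500$; the power-shape comparisons at $n = 300$ with 200
replicates per grid point; parameter-recovery at 500 replicates; and the
end-to-end pipeline over 50 fixture seeds with $B = 300$. These sizes were
chosen so the orderings under test are resolvable at 2 Monte-Carlo
standard errors; all acceptance claims are recomputed at run time rather
than asserted from stored values.

# Limitations

- Mediation here explains association; no causal claim survives unmeasured
  mediator-outcome confounding, and no sensitivity analysis for such
  confounding is provided.
- Mediator selection is data-driven (cis FDR), so trios inherit selection
  effects; the simulation's Scenario I quantifies the cost of a falsely
  included mediator but not of a missed one.
- The CME combination rule and the uncorrected SME-any rule are documented
  conventions, not derived optima.
- High-dimensional mediator settings ($p \gg n$) are out of scope; the trio
  builder caps mediators at five.
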