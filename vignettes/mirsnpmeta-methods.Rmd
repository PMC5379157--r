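---
title: "Methods: cross-phenotype meta-analysis of MirSNP associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-phenotype meta-analysis of MirSNP associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnpmeta)
```

## Scope and the two entry modes

`mirsnpmeta` analyses a panel of SNPs in microRNA genes across several
case-control studies of different phenotypes. The original genotype data
for this kind of analysis live behind controlled access, so the package
draws a hard line between two surfaces:

* **Summary mode** starts from published per-study odds ratios with 95%
  CIs and p-values. Everything downstream of the association fits —
  heterogeneity testing, pooling, the CPMA statistic, FDR adjustment,
  Begg's test — is exactly reproducible from those numbers, and the
  packaged nine-SNP × eight-cancer grid ships with the package.
* **Cohort mode** starts from individual-level genotypes (a documented TSV
  dialect, or the built-in simulator) and additionally exercises the
  logistic association stage and the subsample robustness procedure.

## Association model

Each study is fit separately with the additive (trend) logistic model

$$\operatorname{logit} P(\text{case}) = \alpha + \beta g + \gamma^\top z,$$

where $g \in \{0,1,2\}$ counts copies of the effect allele and $z$ holds
the covariates: the top ancestry principal components, gender, and cohort
dummies when a study carries more than one cohort label. $\beta$ is the
one-degree-of-freedom per-allele log odds ratio; the reported interval is
the Wald construction $\exp(\beta \pm 1.959964\,\mathrm{se})$ and the
p-value the two-sided normal tail of $\beta/\mathrm{se}$, matching the
conventions of standard GWAS tooling.

Numerical choices: IRLS with convergence declared when the absolute
log-likelihood change falls below $10^{-10}(|\ell| + 0.1)$, capped at 50
iterations; the weight $\mu(1-\mu)$ floored at $10^{-12}$; an estimate
with $|\beta| > 15$ is flagged as probable complete separation rather than
reported as a huge finite effect. Rows with missing genotype are dropped
listwise (`n_used` is reported); constant or collinear covariate columns
are dropped with a message — the genotype column itself is never dropped,
and its collinearity with the covariates is an error.

Ancestry PCs follow the genotype-PCA recipe for stratification
correction: mean-impute missing calls, centre each SNP column, scale by
$\sqrt{\hat p(1-\hat p)}$ with the posterior frequency
$\hat p = (1 + \sum g)/(2 + 2n)$, and take left singular vectors. The
original analysis chose the number of PCs per study by eyeballing the
scree plot; that is not algorithmically specified, so the package uses a
fixed, configurable `k_pcs` (default 10). One quirk is deliberate and
worth knowing: in cohort mode the PCs are computed from the analysis panel
itself, which has only nine SNPs, whereas the original used genome-wide
chips. `assoc_grid()` therefore caps `k_pcs` at (informative SNPs − 1)
and logs the cap; with so few SNPs the PCs mop up little ancestry signal
and can approach collinearity with the tested genotype, so simulations
that want clean PC-recovery use a larger synthetic panel.

## Meta-analysis and model choice

Per SNP, with study estimates $b_i$ and standard errors $s_i$
(reconstructed from published CIs by
$s = (\ln U - \ln L)/(2 \times 1.959964)$ when needed):

* fixed effect: inverse-variance weights $w_i = 1/s_i^2$;
* heterogeneity: Cochran's $Q = \sum w_i (b_i - \hat b_F)^2$ on $k-1$ df;
* random effects: DerSimonian–Laird
  $\hat\tau^2 = \max\{0, (Q - df)/C\}$, $C = \sum w_i - \sum w_i^2/\sum w_i$,
  re-weighting by $1/(s_i^2 + \hat\tau^2)$.

The random-effects model is selected iff the heterogeneity p-value is
below 0.05 (configurable); at $Q \le df$ the DL result collapses to the
fixed-effect result exactly, which the tests assert field-for-field.
Pooled intervals use the plain normal approximation (no Knapp–Hartung),
matching the behaviour of the Review-Manager-style tooling this pipeline
mirrors. One caveat is recorded rather than resolved: the source methods
text names both "inverse-variance" and "Mantel–Haenszel" fixed-effect
pooling. Count-based Mantel–Haenszel is not computable from OR/CI
summaries — the only inputs ever published — so the package implements
inverse-variance pooling only.

## The CPMA statistic

The cross-phenotype statistic asks whether a SNP's p-values across $n$
phenotypes collectively deviate from uniformity. Under the global null,
$x_i = -\ln p_i$ are i.i.d. Exponential(1). The alternative keeps the
exponential family but frees the rate; the MLE is
$\hat\lambda = n/\sum x_i$ and the likelihood ratio

$$\mathrm{CPMA} = 2\left[n \ln \hat\lambda + (1 - \hat\lambda)\sum x_i\right]$$

is referred to the full upper tail of $\chi^2_1$. The statistic is zero
iff $\hat\lambda = 1$, permutation-invariant, and depends on the ORs only
through their p-values — hence "agnostic to the direction of effect",
which is the point: a SNP that raises risk in one cancer and lowers it in
another can be strongly non-null here while its pooled OR sits at 1.

Two design points were genuinely open and were settled as follows:

* **Reference distribution.** A one-sided alternative ($\lambda < 1$,
  enrichment of small p-values) would argue for the boundary mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. The four published worked
  examples (1.11E-03, 2.05E-03, 0.0165, 0.0284) are reproduced by the
  *full* $\chi^2_1$ tail and not by the mixture, so the full tail is the
  default; the mixture is available via `reference = "mixture"`.
* **Inputs.** Raw per-phenotype p-values, not FDR-adjusted ones — again
  required to reproduce the published values.

Edge handling: p-values are clipped into $[10^{-300}, 1 - 10^{-16}]$ with
a warning before taking logs; an all-ones input makes the rate MLE diverge
and returns a flagged `invalid` result rather than a number. The
$\chi^2_1$ reference is an asymptotic approximation; at $n = 8$ the
acceptance suite measures the realized type-I error at $\alpha = 0.05$
over 20000 uniform draws and requires it to land in $[0.03, 0.07]$.

## Multiple testing

"FDR correction" is implemented as Benjamini–Hochberg step-up with
monotonicity enforcement: sort ascending, form $p_{(j)} m / j$, take
suffix minima. Reverse-engineering the published adjusted values
identifies both the variant and the families: one family over all 72
association cells jointly, a second over the nine CPMA p-values. The
step-up minimum is visible in the published numbers — three cells with
raw p of 0.0182/0.0213/0.0219 share the adjusted value 0.1971 (the rank-8
candidate), and the smallest CPMA p-value 1.11E-03 adjusts to 9.22E-03,
the *rank-2* candidate $2.05\text{E-}03 \times 9/2$. One published cell
(rs6505162/RCC, printed 0.6665) is inconsistent with the step-up
arithmetic and with the monotonicity of its neighbouring ranks; the
package reproduces every other printed value and treats that one as an
erratum (it is retained in the fixture's `p_fdr_printed` column).

At $q \le 0.05$ the packaged grid yields exactly five significant
association cells. On the CPMA side, three SNPs survive adjustment
(9.22E-03 twice, 0.0495) while the fourth headline SNP, rs895819, adjusts
to 0.0639 — the package reports the arithmetic as computed.

## Begg's test

Publication bias is probed per SNP by the Begg–Mazumdar rank correlation:
standardized deviates $t_i = (b_i - \hat b_F)/\sqrt{v_i - 1/\sum v_j^{-1}}$
against variances $v_i$, Kendall score $s$, continuity-corrected
$z = \max(0, |s|-1)/\sqrt{n(n-1)(2n+5)/18}$ (tie-corrected variance when
ties occur), two-sided normal p. Effects enter on the log-OR scale with
variances squared from the CI-derived standard errors. At $n = 8$ the
score-to-p mapping is coarse ($|s| = 8 \mapsto 0.386$,
$6 \mapsto 0.536$, $12 \mapsto 0.174$; $|s| \le 1 \mapsto 1.000$), and
because the packaged inputs are rounded to 2–3 significant figures a
single rank flip moves between adjacent published values; four of the
nine rows reproduce the published p exactly and all nine agree that no
bias is detectable. The normal approximation is checked against an exact
permutation oracle at $n = 4$ in the tests.

## The synthetic cohort generator

`simulate_cohort()` states a world and sticks to it:

* **Sample sizes** default to the eight published study arms (16399 cases
  / 21779 controls in total) via `default_study_design()`.
* **Allele frequencies** are not published per study; the panel defaults
  (0.15–0.45) were chosen once as typical common-variant frequencies and
  are simulation parameters, not estimates.
* **Ancestry** follows the Balding–Nichols model: each of two
  subpopulations draws its SNP frequency from
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ around the ancestral $p$;
  $F_{st} = 0$ (the default) disables structure. Genotypes are
  Hardy–Weinberg within subpopulation. Draws are clipped away from 0/1.
* **Disease** follows the additive logistic model with intercept
  calibrated to a 10% source-population prevalence at the covariate
  means; a large source population is simulated and cases/controls are
  sampled without replacement to the exact design counts, reproducing
  case-control ascertainment (the intercept is distorted, the per-allele
  log-OR is not). Gender is Bernoulli(0.5) with an optional effect
  (default 0) so covariate adjustment is exercisable.
* **Missingness** defaults to 0; an optional missing rate produces `NA`
  genotypes that the association stage drops listwise.

What the simulator does *not* emulate: linkage disequilibrium between
panel SNPs (the nine MirSNPs sit on different chromosomes), imputation
dosage uncertainty (several published SNPs were imputed; the simulator
only produces hard calls), genotyping batch effects, and relatedness. A
green cohort-mode test therefore establishes that the statistical
machinery is correct under its stated model — not that the published
per-cancer ORs are recoverable, which they are not without the original
genotypes.

## The resampling procedure

Robustness of a single-study association is assessed by refitting on
`b = 1000` random subsamples containing 70% of cases and 70% of controls
(stratified, without replacement — the more specific of the two published
phrasings; an unstratified mode exists), recomputing PCs on each
subsample. The published criterion "test $P_{random} \ge 0.05$" cites an
unspecified procedure, so the report is deliberately transparent: it
exposes the full replicate p-value distribution, the proportion
significant at $\alpha$, empirical quantiles, and a one-sided exact
binomial test of the significance probability against 0.5. Replicate
failures (e.g. a subsample going monomorphic) are counted and a report
with more than 5% failures is flagged. `fraction = 1` reuses the full
sample in original row order, so all replicates equal the full-sample fit
bit-for-bit.

One interpretive note baked into the tests: "the proportion significant
approximates $\alpha$ under the null" is a statement about the *marginal*
replicate distribution. Conditional on one realized cohort the subsample
p-values are strongly dependent (they shrink toward the full-sample
result), so the null-calibration check averages over independent cohorts
rather than over replicates of a single one.

## Budget-driven scaling in the tests

Calibration checks that do not depend on absolute sample size run at
reduced n so the suite stays fast: the null-FDR pipeline oracle uses the
full 8 × 9 design at 80/80 per arm over 100 seeds, the CPMA power oracle
400/400 over five studies, and the resampling acceptance checks 1000/1000
(null) and 3000/3000 (strong effect, $\ln 1.4$) rather than the published
arm sizes. The printed-value checks (CPMA, FDR, Begg, totals) use the
packaged grid at full fidelity.

## Known limitations

* Fixed-effect pooling is inverse-variance only (see above); pooled
  estimates for the packaged grid have no published numeric counterpart
  to regress against, so pooling is verified by oracle identities and
  properties, not by printed values.
* The CPMA $\chi^2_1$ reference is asymptotic in the number of
  phenotypes; at $n = 8$ its type-I error is verified empirically but the
  statistic should not be pushed below $n \approx 4$.
* The eight cancer strata are treated as independent; overlapping
  controls between source GWAS would correlate the p-values feeding CPMA,
  and no covariance-aware extension is implemented.
* Cohort mode computes ancestry PCs from the analysis panel itself — fine
  for the simulator's stated world, too few SNPs for real ancestry
  inference.
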