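---
title: "Screening paediatric diabetes clinics for monogenic diabetes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening paediatric diabetes clinics for monogenic diabetes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grstriage)
```

## The screening problem

Monogenic diabetes — diabetes caused by a defect in a single gene — accounts
for a small percentage of childhood diabetes but changes management
profoundly. Clinical guidelines centre on dominantly inherited MODY genes
(*GCK*, *HNF1A*, *HNF4A*) and select children for testing on MODY-style
features. In populations with high rates of parental consanguinity, however,
recessively inherited causes (*WFS1*, *SLC19A2* and other, often syndromic,
genes) are expected to be far more common, and MODY-focused selection
criteria may miss them entirely.

A phenotype-independent way to find candidates is to exploit the polygenic
architecture of type 1 diabetes. A child whose diabetes is truly autoimmune
almost always carries substantial polygenic type 1 diabetes risk; a child
with a low polygenic risk score and no islet autoantibodies most likely has
something else — including, possibly, monogenic diabetes. `grstriage`
implements this screening chain end to end, together with the exact
small-sample statistics needed to evaluate clinical selection criteria
against the confirmed cases, and a synthetic cohort generator so the whole
pipeline can be exercised and validated without patient data.

## The genetic risk score

For SNP $i$ with risk-allele dosage $d_i \in \{0, 1, 2\}$ and log odds-ratio
weight $w_i > 0$, the score of a child is

$$\mathrm{GRS} = \frac{\sum_i w_i d_i}{2 \sum_i w_i} \in [0, 1],$$

with both sums restricted to the child's non-missing SNPs. Renormalising the
denominator over observed SNPs avoids imputation: the score with SNP $i$
missing is identical to the score computed on the weight table with SNP $i$
removed. Children missing more than 20% of the weight-table SNPs (the
`missing_ceiling`) are flagged and receive an undefined score rather than a
deflated one. The additive form treats all 30 SNPs independently; the
dominant HLA interaction encoding used by some published scores is not
modelled — the pipeline's validity requires only a monotone score with
calibrated centiles, and the interaction coefficients are not part of this
package's inputs.

Risk categories come from centiles of a reference distribution of
gold-standard type 1 diabetes scores: **low** below the 5th centile,
**moderate** from the 5th to the 50th, **high** above the 50th. The package
defaults to the published threshold pair (0.234, 0.280) when no reference
scores are supplied; `calibrate_thresholds()` derives them empirically
otherwise, using the linear-interpolation ("type 7") quantile convention,
stated explicitly because the choice moves tail centiles at reference sizes
of a few thousand. Both thresholds belong to the **moderate** category
(closed interval), matching the printed category definitions; at least 100
reference scores are required before a 5th centile is considered stable.

## Triage for genetic testing

Eligibility is diabetes onset between 6 months and 20 years, both bounds
inclusive (the source wording does not state open/closed; inclusive is the
reading consistent with the printed totals). The selection rule on
(category, antibody status) is:

| GRS category | antibody status | tested |
|---|---|---|
| low | any (incl. missing) | yes |
| moderate | negative | yes |
| moderate | positive or missing | no |
| high | any | no |

Antibody-missing children in the low category are tested — low-risk children
were tested *irrespective* of antibody status — whereas missing status in
the moderate category blocks testing, the only reading consistent with the
printed partition (111 low + 125 moderate antibody-negative tested; 516
high, 208 moderate antibody-positive and 133 moderate antibody-missing
untested). Ineligible children are retained in outputs with reason
`ineligible` for auditability. `printed_partition_fixture()` reproduces this
partition deterministically.

## Inheritance classification and prevalence

Confirmed pathogenic variants are classified purely by zygosity: monoallelic
calls are autosomal dominant, biallelic calls (homozygous or compound
heterozygous — phasing is out of scope) autosomal recessive, mitochondrial
variants "other". A child carrying both a monoallelic and a biallelic
pathogenic call — not observed in practice — is classified by the biallelic
call with a warning, keeping the rule total while favouring the recessive
finding the screen exists to detect. Genes absent from the panel are an
error naming the gene.

Prevalence is the case count over the full clinic cohort with a
Clopper–Pearson exact binomial interval (beta-quantile inversion). Because
only the triaged subset is tested, the estimate is a *minimum* prevalence;
`project_prevalence()` adds $k$ hypothetical cases to the numerator only, to
quantify what testing the untested subgroups might have added.

## Exact statistics

All criterion evaluation runs on 2×2 tables (criterion present/absent ×
target-group case/rest of cohort) with small case margins, so everything is
exact and conditional:

* **Fisher's test** enumerates the hypergeometric support; the two-sided p
  is the total probability of tables no more probable than the observed one
  (probability-mass convention, relative tie tolerance $10^{-7}$ — the
  common statistical-package behaviour).
* **Odds ratios** use the conditional maximum-likelihood estimate under the
  noncentral hypergeometric model, with confidence limits inverting the two
  one-sided exact tests at $\alpha/2$ each, by root-finding to $10^{-8}$ on
  the log-odds scale. A single zero cell yields a one-sided interval with
  the other limit 0 or $\infty$; a zero margin is an explicit error. The
  sample cross-product odds ratio is reported alongside for transparency.
* **Mann–Whitney** p values are exact (full enumeration of the conditional
  rank-sum distribution via a subset-sum dynamic programme over doubled
  mid-ranks, so ties are exact too) whenever $n_x n_y \le 400$; larger
  samples use the tie-corrected normal approximation without continuity
  correction. The exact two-sided p is twice the smaller tail, capped at 1.
* **Kolmogorov–Smirnov** uses the supremum ECDF distance with the exact
  conditional p for $n_x n_y \le 400$ and the asymptotic distribution
  otherwise.
* The **two-sample proportion test** is the pooled-variance z without
  continuity correction. On the published prevalence counts it gives
  p = 0.41 where 0.40 was printed; the printed variant is unstated and the
  difference is rounding-level.

The MODY-probability criterion thresholds at $\ge 10\%$ (the detailed
wording; an alternative strict reading ">10%" appears in the source's
summary and differs only for children at exactly 0.10). HbA1c thresholds at
$\le 58$ mmol/mol (7.5%); conversion between units uses the DCCT formula and
is display-only.

## The synthetic cohort generator

`generate_cohort()` draws a clinic population with the structure the
analysis assumes. Defaults are the study conditions: 1093 children, 3.1%
monogenic of which 41% recessive and 3% mitochondrial/other, a 1963-score
reference cohort, and the published criterion odds ratios.

**Classes and antibodies.** Children are a mixture of definite type 1
diabetes (antibody-positive; rate 0.446 among non-monogenic children, which
centres the class at the observed 472 of 1093), antibody-negative/missing
non-monogenic diabetes, and the three monogenic classes. A single antibody
missingness rate of 0.12 applies to all non-definite classes; the real
cohort's 133 antibody-missing children among moderates likely also reflect
risk-score–antibody correlation that the generator does not model.

**Genotypes.** Polygenic type 1 diabetes classes draw risk-allele dosages
from case-enriched frequencies; monogenic classes draw from background
frequencies, encoding the screen's premise that monogenic cases carry
ordinary population-level type 1 diabetes risk. The bundled 30-SNP weight
table and frequency fixture are synthetic, calibrated jointly so the
simulated reference cohort's median lands at 0.280 with interquartile range
(0.262, 0.298) and 5th centile 0.234 — the published reference geometry.
Under the background frequencies about two-thirds of monogenic children
score low and under 2% score high, so roughly 94% of them fall inside the
tested triage subset; the residual ~6% is why the recovered minimum
prevalence averages just below the generative 3.1%.

**Criteria.** Each binary criterion is drawn conditionally independent given
class: the target class (dominant or recessive) at the odds-transformed rate
$p = \mathrm{OR}\,\omega_0 / (1 + \mathrm{OR}\,\omega_0)$ with
$\omega_0 = p_0/(1-p_0)$, every other class at the baseline rate $p_0$.
Applying the baseline uniformly — including a ~1% non-insulin-treated
fraction within the definite type 1 diabetes class, as occurs clinically
during the honeymoon phase — keeps the marginal case-versus-rest odds ratio
exactly at the configured value, which is what the odds-ratio recovery
checks require. Baseline rates (0.01 non-insulin, 0.15 parent with diabetes,
0.10 HbA1c ≤ 58, 0.02 MODY probability ≥ 10%, 0.02 extra-pancreatic
features, 0.20 consanguinity — the population's reported consanguinity
rate) are free parameters chosen once for non-degenerate cell counts; they
are not published values. Continuous HbA1c and MODY probability are drawn
consistent with their binary thresholds; extra-pancreatic feature codes are
sampled from a vocabulary weighted toward deafness, anaemia and
developmental delay, the features reported in most recessive cases.

**What passing tests show — and do not.** The generator omits linkage
disequilibrium between SNPs, family structure, criterion–criterion
correlation within class, risk-score–antibody correlation, and any
phenotype–genotype correlation beyond the class structure. Recovery results
therefore validate the *pipeline arithmetic* (triage conservation, exact
interval coverage, odds-ratio estimation) under the stated generative model,
not the epidemiology of any real clinic population.

## Numerical choices and problem sizes

Determinism: every stochastic stage is governed by the `seed` field of
`generator_params()`; identical parameters reproduce byte-identical cohorts.
Validation uses exhaustive enumeration against independent brute-force
oracles for every 2×2 table with total ≤ 40, permutation enumeration for
rank tests with $n_x n_y \le 36$, grid inversion to $10^{-4}$ for 100 random
odds-ratio intervals, 10,000-replicate binomial simulations for
Clopper–Pearson coverage at $n = 1000$, and 200 replicate synthetic cohorts
for odds-ratio coverage (expected in the 89–99% band for exact, hence
conservative, intervals) and prevalence recovery. These sizes keep the full
suite under half a minute on one core while leaving Monte-Carlo error well
below the tolerances tested.

## Known limitations

* The bundled SNP weights, allele frequencies and 50-gene panel are
  synthetic fixtures (real tables are user-suppliable); the published
  thresholds are configuration, not re-derivations.
* No multiple-testing adjustment is applied across criteria, matching the
  source analysis.
* The exact confidence interval inverts two one-sided tests while the
  two-sided p uses the probability-mass convention, so an interval excluding
  1 at 95% implies p < 0.05 but not exactly the converse near the boundary.
* X-linked inheritance is representable in the panel but has no dedicated
  classification rule; calls in such genes follow the zygosity rule.
* C-peptide, BMI centiles and the internals of the composite MODY
  probability model are out of scope; the MODY probability is consumed as a
  precomputed column.
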