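---
title: "A family-level social vulnerability framework for SUDI research: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A family-level social vulnerability framework for SUDI research: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfscore)
```

## The problem and the measurement model

Sudden unexpected death in infancy (SUDI) is strongly socially patterned, yet
most studies of its social gradient rely on a single economic marker (area
deprivation, occupation, or education). `svfscore` implements a
multidimensional alternative: a family-level social vulnerability score built
from 32 operational indicators spanning income and material resources,
employment, housing, health and healthcare access, crime and safety,
transport, family and social relationships, and intergenerational
disadvantage.

Two scores are produced for each family:

* **Simple summation score** $S \in \{0,\dots,32\}$ — one point per
  indicator on which *any* member of the immediate family displays the
  characteristic.
* **Family-weighted composite score** $W \in [0, 63]$ — each indicator
  contributes according to a method-specific weighting rule that encodes
  three premises: (1) vulnerability deepens as more family members display a
  characteristic; (2) a single unsupported parent experiences a burden
  comparable to a couple in which *both* partners are affected; (3)
  persistent disadvantage is worse than point-in-time disadvantage.

The weighting rules, declared per indicator in a machine-readable ledger
(`svf_ledger()`), are:

| method | rule | max |
|---|---|---|
| `BINARY_1` | 1 if present | 1 |
| `BINARY_2` | whole-family exposure: 2 if present | 2 |
| `PARENT_WEIGHTED` | 1 if one of two parents; 2 if both or a sole parent | 2 |
| `SIBLING_WEIGHTED` | 1 if one sibling; 2 if two or more | 2 |
| `EVENT_PREVALENCE` | 1 for one event; 2 for two or more | 2 |
| `REMOTENESS_WEIGHTED` | 1 outer regional; 2 remote/very remote | 2 |
| `LONGITUDINAL` | 1 past, 2 current, 3 persistent | 3 |
| `PARENT_WEIGHTED_LONGITUDINAL` | longitudinal scale given any parent affected | 3 |
| `CONTINUOUS_OCCUPATION` | $1 - 3p$ for occupational percentile $p \le 0.25$, else 0 | 1 |

The per-method maxima sum to 63 over the 32 indicators; `svf_max_scores()`
verifies both ceilings by exhaustive enumeration of admissible observation
states rather than trusting the ledger arithmetic. Missing information about
an indicator is scored as the characteristic being absent — the convention
used when indicators are abstracted from narrative administrative records.
This makes scores conservative (a family about whom little is recorded looks
less vulnerable); `svf_score(flag_missing = TRUE)` surfaces per-family
unobserved-indicator counts for sensitivity analyses.

Design choices where the framework leaves room:

* The sibling and event-prevalence scales saturate at 2, mirroring the
  parent scale, so that every non-longitudinal indicator tops out at the
  whole-family value 2 and the composite ceiling is exactly 63.
* Remoteness uses the minimal monotone integer weighting (1 outer regional,
  2 remote or very remote).
* The occupational indicator uses the higher-status parent's percentile and
  maps it linearly from 1 (lowest status) down to 0.25 at the 25th
  percentile, 0 above the cut.
* Stressful life events count qualifying items in the past year, with two
  or more items treated as the saturated state.

## Vulnerability types: factor analysis of the binary indicators

`svf_efa()` fits a $k$-factor model (default $k = 3$) to the families ×
indicators presence/absence matrix to recover *types* of vulnerability:
**chaotic lifestyle** (substance and alcohol misuse, offending, domestic
violence, child protection involvement, family instability),
**socioeconomic** (unemployment, low-status occupation, transport and
care-access barriers), and **psychosocial** (homelessness, parental chronic
and mental ill-health, sex work, domestic violence in previous
relationships).

Numerical choices:

* **Extraction** is iterated principal-axis factoring of the indicator
  correlation matrix (squared multiple correlations as initial
  communalities; communalities capped at 0.995). Pearson (phi) correlations
  are the default; tetrachoric correlations — pairwise maximum-likelihood
  with thresholds fixed at the margins, followed by an eigenvalue repair to
  the nearest positive semi-definite correlation matrix — are available with
  `correlation = "tetrachoric"` and are the natural choice when the binary
  indicators are viewed as thresholded continuous liabilities.
* **Rotation** is orthogonal varimax on the raw loadings, deliberately
  *without* Kaiser row normalization. With 32 indicators of very unequal
  communality, Kaiser normalization inflates near-zero-communality rows —
  which carry mostly sampling noise — to full rotational weight; in
  simulation this destabilised the orientation of the weakest factor from
  seed to seed, while the un-normalized criterion recovered all three
  planted factors (congruence ≥ 0.92 at $n = 2000$ in every seed tested).
* **Factor labels** are assigned by maximum Tucker congruence against the
  packaged reference loading pattern (`svf_reference_loadings()`), with sign
  flips so each type points toward vulnerability; labels are therefore
  stable under the permutation and reflection indeterminacy of factor
  solutions. The per-factor congruence is stored on the fit.
* **Inclusion rule**: an indicator is part of the typing if its maximum
  absolute loading is at least 0.40. The comparison is `>=`, not `>`, so
  indicators loading exactly 0.40 are included; on the packaged reference
  matrix the rule selects 21 of 32 indicators.
* **Number of factors** is a configuration value; the eigenvalues of the
  full correlation matrix are returned for scree inspection but $k$ is never
  auto-selected.
* **Scores**: families are scored by the regression (Thomson) method and the
  fitted cohort's score columns are then re-standardised by symmetric (ZCA)
  whitening — the minimal linear transformation giving each column mean 0,
  standard deviation 1, *and* zero cross-correlation. Plain per-column
  standardisation leaves regression scores of an orthogonal solution with
  residual correlations ($\widehat{\mathrm{cor}} = \Lambda' R^{-1}\Lambda$,
  about 0.15 here), which would contradict the interpretation of the types
  as independent; whitening removes them exactly. Out-of-sample scoring
  applies the stored training standardisation and is not re-whitened.

## Risk-factor associations

`svf_associations()` contrasts the family-weighted score and each type score
across the strata of a 12-item SUDI risk-factor panel (Indigenous status,
area socioeconomic tertile, smoking in pregnancy, small-for-gestational-age
category, preterm birth, breastfeeding, sleep position, surface sharing,
solitary sleep, soft sleep surface, pillows, excess bedding):

* the **group test** is the Wilcoxon rank-sum test for two strata (exact
  enumeration when both groups have ≤ 10 untied observations, otherwise the
  normal approximation with mid-rank tie correction) and Kruskal–Wallis for
  three; the choice of Kruskal–Wallis over a trend test for ordered
  three-level factors is an assumption, recorded here;
* the **effect size** is the Hodges–Lehmann shift — the median of all
  pairwise differences between a stratum and its reference — with a
  distribution-free Moses confidence interval cut from the ordered pairwise
  differences at the Mann–Whitney critical value (exact for small samples,
  normal-approximation ordering beyond 2 500 pairs);
* **solitary sleep** is structurally defined only for infants not sharing a
  sleep surface; surface-sharing families are excluded from that contrast
  and counted in `n_excluded`;
* missing values are excluded listwise per risk factor with counts logged;
  unadjusted P values are reported (matching the primary analysis
  convention) alongside a Benjamini–Hochberg column for transparency;
* parametric sensitivity estimates (Welch *t* contrasts) are emitted next to
  each nonparametric shift.

`svf_risk_regression()` fits the cumulative model
$\text{score} = \alpha + \beta \cdot \text{(count of modifiable risk
factors)}$ by ordinary least squares; the default count panel (smoking, not
breastfed, non-supine position, surface sharing, solitary sleep, soft
surface, pillows, excess bedding, preterm, SGA ≤ 10th percentile) ships as
`svf_count_panel()` and can be redefined.

## What the synthetic cohort emulates — and what it does not

Real coronial SUDI records are confidential, so the package carries a
generator (`svf_simulate()`) whose defaults encode the statistical structure
the analysis assumes:

* three **orthogonal latent vulnerability factors** per family,
  $z \sim N(0, I_3)$;
* indicator presence through a **probit threshold model**,
  $x^*_j = \lambda_j' z + \sqrt{1 - \lVert\lambda_j\rVert^2}\,\varepsilon$,
  present iff $x^*_j$ exceeds the quantile of the configured base rate — so
  the planted loadings are exactly the tetrachoric structure and marginal
  prevalences equal the base rates (a logistic link is available);
* planted loadings default to the packaged reference pattern; base rates
  default to 0.05–0.35 (mean ≈ 0.18, consistent with a high-adversity
  cohort whose median simple score is around 6 of 32);
* family structure: sole parent with probability 0.35, Poisson(1.5)
  siblings; persistence states {past 0.3, current 0.5, persistent 0.2}
  given presence; within-couple spread (both parents affected with
  probability 0.3 given presence);
* risk factors through logistic (baseline-category for three-level factors)
  models on the latent factors, with coefficient signs matching the
  directions reported for the family-weighted score and types (e.g.
  positive chaotic/socioeconomic coupling for smoking, surface sharing and
  excess bedding; negative for prone sleeping and solitary sleep;
  Indigenous status positive on chaotic and socioeconomic, negative on
  psychosocial); 2% of risk-factor cells are set missing completely at
  random.

The generator does **not** emulate: narrative-text abstraction and its
subjectivity, record linkage, missing-not-at-random mechanisms,
cause-of-death classification, or the real cohort's observed medians and
shift magnitudes (which are data-dependent and unreachable without the
records). Passing recovery tests on synthetic cohorts therefore shows that
the pipeline is *correct and calibrated under its own assumptions* — not
that those assumptions hold in coronial data.

## Degenerate inputs and numerical tolerances

* Constant indicator columns are dropped from the EFA with a warning;
  requesting more factors than the remaining indicators support is an
  error.
* Factor-score standardisation is asserted to 1e-8; whitening falls back to
  per-column scaling if the score covariance is numerically singular.
* Tetrachoric estimates are clamped to (−0.999, 0.999) and degenerate
  margins (all-0/all-1) return 0; the pairwise matrix is repaired to the
  nearest positive semi-definite correlation matrix when needed.
* Exact rank-test and interval paths are used only for small untied
  samples (both $n \le 10$ for the test; ≤ 2 500 pairs for the interval);
  beyond that, normal approximations with tie correction.
* Scoring validation rejects more affected parents than parents,
  percentiles outside [0, 1], negative counts, and unknown temporal or
  remoteness states; observation columns for unknown indicators are an
  error, not silently ignored.

## Problem sizes used by the test-suite

The packaged tests exercise: exact oracle agreement of the scorer on 10 000
randomised families; factor recovery on five seeds of 2 000-family cohorts
(congruence ≥ 0.90 per factor); rank-test calibration against full
enumeration (group sizes ≤ 10) and a 1 000-replicate null simulation at
$\alpha = 0.05$; Hodges–Lehmann agreement with the all-pairwise-differences
oracle up to 30×30 samples; and slope recovery of the cumulative
risk-factor regression at $n = 1000$ over ten seeds. These sizes were chosen
to make Monte-Carlo error small relative to the assertions while keeping the
default test run fast.

## Known limitations

* The ledger's per-indicator method assignment is the unique assignment
  consistent with the framework's published annotations and the composite
  ceiling of 63, but individual binary indicators' whole-family weighting
  (1 vs 2) could be assigned differently by other analysts; the ledger is
  data, not code, so alternative assignments can be supplied as a CSV.
* Phi-coefficient factor analysis of rare binary indicators attenuates
  loadings; the tetrachoric option mitigates this at extra computational
  cost and some pairwise-estimation noise.
* The association suite reports unadjusted P values by design; with 48
  tests per run, the logged Benjamini–Hochberg column should inform any
  confirmatory reading.
* Scores treat absence of information as absence of vulnerability;
  cohorts with systematically thinner documentation will be scored as less
  vulnerable.
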