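---
title: "Discriminant risk scoring for central compartment lymph node metastasis"
author: "CLNMscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant risk scoring for central compartment lymph node metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CLNMscore)
```

## The clinical problem

Papillary thyroid cancer (PTC) metastasizes first and most often to the
central compartment (level VI) lymph nodes, yet preoperative ultrasound is
poor at seeing disease there (sensitivity on the order of 30%, against
>90% in the lateral neck). Whether to dissect the central compartment in a
clinically node-negative patient therefore leans on clinical risk factors.
`CLNMscore` implements a discriminant score built from six such factors —
sex, age, tumor diameter (TD), capsular invasion (CI), multifocality, and
tumor location (TL) — fitted from a class-conditional frequency table of a
surgical cohort with pathology-confirmed nodal status.

## The model

Write $Y_g$ for the nodal status ($g = +$ metastatic, $g = -$ not) and
$X_{kj}$ for "factor $k$ falls in category $j$". From a frequency table we
estimate the class-conditional frequencies

$$P(X_{kj} \mid Y_g) = \frac{n(k, j, g)}{N_g},$$

where $N_g$ is the number of patients in class $g$. Assuming the six
factors independent given the class, the class likelihood of a patient is
the product $P_g = \prod_k P(X_{k j_k} \mid Y_g)$, and the
maximum-likelihood rule picks the class with the larger $P_g$ —
equivalently with the larger $\lg P_g$. Each per-category log-frequency is
turned into an additive **score**

$$s(k, j, g) = \left(\log_{10} P(X_{kj} \mid Y_g) + 1\right) \times 10,$$

so a category frequency of 1 is worth 10 points, 0.1 is worth 0, and
frequencies below 0.1 score negative. A patient's class totals are plain
sums, $S_g = \sum_k s(k, j_k, g)$, and since
$S_g = (\lg P_g + K) \times 10$ with $K$ the number of factors, comparing
$S_+$ with $S_-$ is exactly the likelihood comparison (a test in the suite
verifies this equivalence on all 320 enumerable profiles). The rule is
prior-free; an optional prior term ($10 \log_{10} \pi_g$ added per class)
converts it to a maximum-posterior rule and is off by default.

```{r}
tab <- ptcFrequencyTable()   # bundled counts: 197 metastatic, 215 not
fitScoreTable(tab)
```

## Precision: why sums use the displayed scores by default

Score tables are printed at one decimal place, and clinicians sum those
printed numbers. `scorePatients(..., precision = "display")` (the
default) reproduces that arithmetic: scores are rounded to 1 dp, then
summed. The bundled reference example — a 28-year-old man with a unifocal
1.6 cm lower-pole tumor and no capsular invasion — gives $S_+ = 37.0$ and
$S_- = 30.2$ under display precision, matching the published totals. With
`precision = "full"` the unrounded transform is summed instead; the same
patient then lands at $S_- = 30.125 \to 30.1$, revealing that the
published totals were computed from the rounded table. Full precision is
the better choice when the score table is an intermediate quantity (e.g.
in the simulation loop below); display precision is the faithful
replication of scoring as practised, so it is the default. The two differ
by at most 0.05 points per factor and essentially never change the call.

```{r}
patient <- binPatients(data.frame(
    sex = "male", age = 28, diameter = 1.6, capsular_invasion = "N",
    multifocality = "N", location = "lower pole"))
scorePatients(patient, fitScoreTable(tab))
```

## Numerical and design choices

* **Logarithm base.** The transform uses $\log_{10}$; back-deriving the
  bundled score table from its counts (e.g. $53/197 \to 4.3$) confirms
  the base, which is therefore fixed, not configurable.
* **Display rounding** is half-away-from-zero at 1 dp
  (`roundDisplay()`). On the bundled tables every cell agrees under
  half-even rounding too, so the choice is cosmetic there; it matters
  only for user tables with cells landing exactly on a .x5 boundary.
* **Binning.** The printed diameter bins overlap at their edges
  ("0.7-1.0, 1.0-1.5, ..."); they are implemented as half-open intervals
  $[0, 0.7), [0.7, 1.0), [1.0, 1.5), [1.5, 2.0), [2.0, \infty)$ cm so
  that binning is total and unique — 1.6 cm lands in 1.5-2.0 cm as the
  reference example requires, and boundary values fall into the bin whose
  label claims them ($\geq$). Age splits as $[0, 45)$ vs $[45, \infty)$
  years. A tumor spanning thirds of the gland has no defined location in
  the source vocabulary; callers must resolve it to one of the four
  levels before binning.
* **Ties.** $S_+ = S_-$ is predicted positive by default — the clinically
  conservative direction, since a missed metastasis costs more than an
  extra dissection — and flagged in `tieBroken`; the policy is an
  argument everywhere it matters.
* **Zero counts.** The bundled table has none; a zero cell makes the log
  undefined and is a hard error naming the cell. For user tables,
  `fitScoreTable(..., smoothing = a)` applies additive smoothing
  $P = (n + a) / (N_g + a J_k)$ per factor block ($J_k$ categories); 0.5
  is the conventional constant. Smoothing is continuous: as $a \to 0$ on
  a strictly positive table the scores converge to the unsmoothed ones
  (tested down to $a = 10^{-8}$).
* **Unknown categories** at scoring time are an error, never silently
  imputed.

## The synthetic cohort generator and its oracle

The cohort behind the bundled tables is not available at patient level,
so the package generates cohorts from the model's own generative
assumption: a true class drawn Bernoulli(prevalence), then one category
per factor drawn independently from that class's conditional
frequencies. Defaults mirror the reference cohort — prevalence $197/412
\approx 0.478$ (the retrospective metastatic rate; $41/104$ is the
prospective alternative) with the bundled frequency table as the sampling
distribution. The draw order — labels first, then factors in scheme order
— is part of the reproducibility contract: a `CohortSpec` (table,
prevalence, n, seed) maps to exactly one cohort, byte for byte.

`enumerateExpectedPerformance()` computes the classifier's exact expected
per-class coincidence rates under that generative model by enumerating
all category combinations ($2 \times 2 \times 5 \times 2 \times 2 \times
4 = 320$ for the bundled scheme; a cap of $10^6$ combinations guards
against accidental combinatorial blow-ups). It is the sampling-free
oracle the Monte-Carlo cohorts must converge to, and the test suite holds
`generateCohort()` to it at $n = 100{,}000$ within three binomial
standard errors; the same cohort size is used for the
generate → recover → refit check, which must return every score to
within 0.5 points of the generating table. These sizes keep the whole
suite in the seconds range while leaving the binomial tolerances tight.

What the generator deliberately does **not** model: factor–factor
dependence within a class (real risk factors are correlated),
measurement error in the raw attributes, or covariates outside the six
factors (Hashimoto's thyroiditis and TSH level are known omissions of
the scoring model itself). Consequently the enumeration's expected mean
coincidence rate under independence need not equal — and should not be
compared to — the real-cohort discriminative accuracies of ~72%; those
arise from a joint distribution the published tables do not determine.
Passing simulation tests show the implementation is internally
consistent, not that the independence assumption holds in patients.

## Evaluation conventions

`coincidenceRates()` reports per-class agreement between discriminant and
pathology: $100 \cdot tp/(tp+fn)$ and $100 \cdot tn/(fp+tn)$. The **mean
coincidence rate** is their unweighted (macro) average — on the bundled
retrospective confusion matrix $(65.5 + 78.1)/2 = 71.8$, which is what
the reference reports, whereas overall accuracy $297/412 = 72.1$ is not —
so the macro reading is implemented, with overall accuracy reported
alongside for transparency. One printed inconsistency is preserved as
documentation: the prospective positive rate $28/41 = 68.29\%$ rounds to
68.3 but is printed as 68.2; the package reports the computed value and
the fixture test asserts agreement within 0.1.

## Limitations

The package reproduces and probes a published scoring rule; it does not
validate it. No ROC/AUC, calibration or cross-validation machinery is
included (the source defines only coincidence rates), the discriminant is
strictly binary, and the retrospective confusion matrix cannot be
re-derived from the bundled tables because it depends on the unpublished
patient-level joint distribution — any attempt to match it from marginals
would be guessing.
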