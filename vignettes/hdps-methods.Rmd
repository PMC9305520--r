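---
title: "High-dimensional propensity scores: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional propensity scores: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdps)
```

## The problem and the procedure

Healthcare databases record treatment decisions whose drivers — frailty,
severity, health-seeking behaviour — are mostly unmeasured, but leave
traces in coded events. The HDPS procedure adjusts for those traces. Its
five steps, as implemented here:

1. **Declare data dimensions.** Each dimension is a long-format table of
   (patient, code, date) events capturing one aspect of care. The package
   never interprets the codes; it only requires that events carry
   ISO-8601 calendar dates and that every patient appears in the cohort
   table.
2. **Generate pre-exposure features.** Events are restricted to the
   half-open window `[index − lookback, index)`. Records dated on the
   index day itself are *excluded*: a same-day code cannot be ordered
   reliably against exposure start, and including it risks adjusting for
   a consequence of treatment. Within each dimension, codes are ranked by
   the number of distinct patients recorded with them and the top `n_top`
   (default 200) are kept. A variant that ranks by closeness of prevalence
   to 50% is available (`rank_by = "deviation"`) but is not the default:
   "most common" is the standard filter, and the variant's benefit is
   debated.
3. **Assess recurrence.** Each feature becomes up to three binary
   covariates: count ≥ 1 (`once`), ≥ median, ≥ 75th percentile. Both
   percentiles are **nearest-rank** (no interpolation), computed **among
   patients with at least one occurrence**. Computed over the whole cohort
   instead, the median is 0 for any code under 50% prevalence and every
   cut-off collapses to `once`, which would defeat the point of recurrence
   assessment. Columns that are *exactly* equal as vectors (threshold
   equality is not enough) are collapsed, keeping the least stringent
   cut-off name and recording the merge.
4. **Prioritise.** For every covariate we tabulate prevalence in exposed
   and unexposed groups, the exposure prevalence ratio
   $RR_{CE} = p_{c1}/p_{c0}$, and the outcome risk ratio $RR_{CD}$ from
   the binary event indicator. The Bross bias multiplier
   $$B = \frac{p_{c1}(RR-1)+1}{p_{c0}(RR-1)+1},\qquad
     RR = \max(RR_{CD}, 1/RR_{CD})$$
   bounds the multiplicative confounding a binary covariate with those
   margins could exert; covariates are ranked by $|\log B|$. The
   $RR \to \max(RR, 1/RR)$ inversion matters: without it a strongly
   *protective* confounder scores near zero and ranks last. Where outcome
   events are too sparse for stable $RR_{CD}$, `ranking = "exposure_only"`
   ranks by $|\log RR_{CE}|$ instead; we use the absolute log (rather than
   distance of the ratio from 1) so protective and harmful associations of
   equal strength rank equally.
5. **Estimate.** The propensity score is a maximum-likelihood logistic
   regression of exposure on pre-defined plus selected HDPS covariates.
   ATE weights are `1/ps` (exposed) and `1/(1−ps)` (unexposed); the
   treatment effect comes from a weighted Cox model with exposure as the
   sole term and a robust sandwich variance.

## Numerical and statistical choices

* **Zero cells.** Whenever a 2×2 table behind a ratio contains an empty
  cell, 0.1 is added to each of its four cells before that ratio is
  computed (the convention of the original HDPS implementation). The same
  correction backs prevalence-ratio values for covariates absent in one
  group.
* **Ties.** All rankings break ties lexicographically by covariate name,
  making every ordering deterministic. Event-time ties in the Cox model
  use the Efron approximation.
* **Robust variance.** The sandwich estimator treats the weights as fixed;
  the uncertainty in estimating the propensity score is not propagated.
  This is standard practice and conservative in the usual IPTW setting,
  which our coverage simulations confirm (≈95% empirical coverage).
* **Stabilized weights** multiply by the marginal exposure probability of
  the patient's own group. For the weighted Cox partial likelihood this is
  *not* an exact invariance: risk sets mix the two groups, so within-group
  rescaling perturbs the estimate slightly (we observe differences of
  order 10⁻⁴ on the log HR). A global rescaling of all weights leaves the
  estimate unchanged exactly. The default is unstabilized weights; the
  flag exists because stabilization tames weight variability in poorly
  overlapping samples.
* **Trimming** removes patients outside chosen percentiles of the pooled
  PS distribution (nearest-rank percentiles). The default is no trimming;
  the propensity model is not re-estimated on the trimmed sample.
* **Separation.** Fitted scores at machine 0/1 abort the fit with advice
  to trim or reduce the covariate set — weights would be unbounded and
  the estimand undefined under positivity violation.
* **Weighted ASD.** Weighted prevalences use `Σwx/Σw` per group, but the
  denominator keeps the *unweighted* pooled variance, so the unweighted
  and weighted columns share a scale and differences reflect movement of
  the means only. A flag switches to fully weighted variances.
* **Overlap coefficient** integrates the pointwise minimum of the two
  group densities on 100 equal-width bins over [0, 1] (configurable).
* **Near-IV rule.** A covariate is flagged iff
  $|\log RR_{CE}| > \tau_e$ **and** $|\log RR_{CD}| < \tau_o$, natural
  logs, with presets $\tau_e \in \{1.5, 1.1\}$ and $\tau_o = 0.5$. The
  published cut-off expressions are typographically garbled; we read them
  as absolute-value thresholds on the log scale because that direction is
  the only one consistent with the reported removal counts (the 1.1
  threshold removes more covariates than 1.5, i.e. it is the *laxer*
  exposure condition). The default preset is 1.1 — the more inclusive
  flag — since the rule's purpose is screening for manual review. Both
  presets nest by construction.
* **Sensitivity analyses never re-rank.** `vary_k`, `incremental_curve`
  and `remove_and_refit` all reuse the prioritisation computed once by
  `hdps()`; scenarios differ only in which covariates enter the PS model,
  and each scenario re-estimates the PS and weights from scratch (weights
  are never recycled across covariate sets). Whether the original
  incremental analysis re-ranked at each k is not documented; a fixed
  ranking makes the curve interpretable as "adding covariates in priority
  order" and keeps scenarios comparable.
* **Stabilisation summary.** Because "the curve has stabilised" is a
  visual judgement, `incremental_curve` also reports
  max |Δ log HR| over the upper half of the k grid as a number that can
  be tracked across studies.

## The synthetic claims simulator

`generate_study()` emulates the structure the HDPS assumes: codes as noisy
proxies of latent constructs. Per patient, latent confounders
$U_j \sim N(0,1)$ enter both the logistic exposure model and the
exponential outcome hazard with coefficient `confounding_log_hr`; an
exposure-only latent $V \sim N(0,1)$ enters the exposure model alone.
Confounder-proxy codes are Poisson with log-rate
$\log(\text{base}) + \lambda U_j$; instrument-like codes load on $V$;
noise codes have constant rates. Counts expand to dated events uniform in
the lookback window. Follow-up is exponential with administrative
censoring — the simplest censoring scheme consistent with a weighted Cox
analysis. Measured covariates (age, sex, smoking) carry small effects on
both exposure and outcome and serve as the pre-defined set.

Default parameters are fixed once and define the package's reference
scenario: 5000 patients, three dimensions of 40 codes (25 proxies, 5
instrument-like, 10 noise each), proxy loading 1.0, true log HR 0, and
`confounding_log_hr = 0.33`, which produces a crude hazard ratio near 1.2
— an amount of confounding comparable to what motivated the original
reanalysis — that HDPS adjustment removes almost entirely. Internal
constants were chosen so the planted structure behaves like its real
counterpart: the instrument latent has a moderate exposure coefficient
(1.0) so overlap remains adequate for weighting, while instrument-like
codes are rarer (base rates 0.03–0.12 vs 0.05–0.4) and more strongly
loaded (loading factor 2.8 × `proxy_loading`) so their exposure
associations clear the near-IV detection thresholds the way true
prescribing-channel codes do. Setting `proxy_loading = 0` makes every
code uninformative (instrument loadings scale with it).

What the simulator does **not** emulate: disease natural histories, code
co-occurrence beyond the shared latents, calendar-time trends, informative
dropout, and realistic coding-system marginals. Passing tests therefore
demonstrate the *procedure's* correctness and its operating
characteristics under known confounding — not performance guarantees on
any particular real database.

## Problem sizes used in validation

The package's simulation-based checks use: 100 replicated studies of
n = 3000 for parameter recovery (mean absolute log-HR error of the
weighted estimator vs the crude one, and CI coverage of the true null);
50 replicated default-scenario studies for near-IV detection operating
characteristics; and the single default-scenario study for the balance
benchmark (all selected covariates below 10% weighted ASD). Unit and
property tests run on miniature studies of a few hundred patients.

## Known limitations

* Recurrence cut-offs ignore event timing within the window (no
  proximity-to-exposure variants).
* Prioritisation is univariate; covariates that confound only
  conditionally can be mis-ranked, and machine-learning prioritisation is
  out of scope.
* The estimand is the ATE via IPTW; matching, fine stratification and
  doubly robust estimators are not provided.
* Free-text features and vendor database extracts are not handled; inputs
  must be pre-formatted delimited text.
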