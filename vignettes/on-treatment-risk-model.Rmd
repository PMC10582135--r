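---
title: "The on-treatment risk model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The on-treatment risk model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpflare)
```

## The clinical problem

First-line immunotherapy combinations (IO/IO or IO/TKI) for advanced renal
cell carcinoma help many patients and fail some primarily; the first
radiological assessment that settles the question typically comes around
week 12. Two signals are available much earlier and at no extra cost:
serum C-reactive protein (CRP), drawn routinely at each administration, and
the timing of the first treatment-related adverse event (TRAE). Both are
read as downstream reflections of an activated immune system. This package
implements a rule-based risk model over these two signals, together with the
inference machinery such analyses are reported with, and a cohort simulator
that makes the whole pipeline testable.

## CRP kinetics classification

For a patient with baseline CRP $B$ and on-treatment measurements
$c(t)$ at weeks $t$:

* **flare-response**: $\exists\, t_1 \in (0, w_f]$ with
  $c(t_1) \ge \delta B$ and $\exists\, t_2 \in (t_1, w_a]$ with
  $c(t_2) < B$;
* **response**: no $t \in (0, w_f]$ with $c(t) \ge \delta B$, and
  $\exists\, t \in (0, w_a]$ with $c(t) \le \rho B$;
* **non-response**: otherwise.

Defaults: doubling factor $\delta = 2$, response fraction $\rho = 0.7$
(a 30% decrease), flare window $w_f = 4$ weeks ("first month"), assessment
window $w_a = 12$ weeks ("three months"). All four are arguments of
`kinetics_params()`.

Decisions the verbal rule leaves open, and how they are fixed here:

* **Boundary conventions.** A value exactly at $2B$ counts as a doubling and
  exactly at $0.7B$ as a response (weak inequalities on the named side); the
  post-flare drop is strictly below baseline. A value at the threshold thus
  counts as the named event, and every rule is decidable.
* **The drop is below baseline**, not merely below the flare peak, matching
  the flare's original description as a doubling *followed by a drop below
  baseline*.
* **A flare-window doubling without a later drop blocks "response"**: such
  patients are non-responders even if CRP later falls to $0.7B$ — the
  response class is defined *without prior flare*, read as without prior
  doubling. (A doubling after the flare window does not block anything.)
* **Windows are half-open intervals $(0, w]$**, so a measurement exactly at
  week 4 is inside the flare window — the same convention as the TRAE
  threshold below.
* **Baseline** is the pre-treatment value closest to treatment start within
  a 4-week lookback, clamped from below at a 1 mg/L detection floor so that
  fold-changes stay defined for undetectable baselines. Duplicate draws at
  the same time resolve to their maximum (conservative for flare detection);
  the earliest qualifying time is recorded when several qualify.

One subtle property worth stating: multiplying all on-treatment values of a
non-response trajectory by a constant $k \ge 1$ can never produce a
*response* (doublings are preserved or created, and values above $0.7B$
stay above), but it **can** produce a flare-response — a near-doubling pushed
over $2B$ while another value sits between $0.7B$ and $B/k$. The test suite
pins this edge case explicitly rather than asserting a false monotonicity.

## The TRAE factor and the risk model

The early-TRAE factor is `first onset <= 4 weeks`, with all CTCAE grades
counting (the threshold is an argument everywhere it appears, and
`mean_time_to_first_trae()` re-derives a cohort-specific threshold the way
the original rule was motivated). An onset exactly at 4 weeks is early, so
the two strata partition the cohort. Patients without any recorded event
are valid and count as late/no onset.

`assign_risk_group()` maps the two binary factors to three tiers: both
present → low risk, exactly one → intermediate, neither → high. The mapping
is symmetric in which single factor is present. Cross-tabs against the
primary treatment response pool PR and CR into one objective-response
column.

## Association inference

`freeman_halton_exact()` implements the exact conditional test for r×c
tables: conditioning on both margins, the two-sided p-value sums the
multivariate-hypergeometric probabilities of all tables whose probability
does not exceed the observed one. This "sum of less-likely tables"
definition is the convention shared by SPSS and `stats::fisher.test`; a
relative tolerance of 1e-9 keeps floating-point ties in the rejection set.
Enumeration is exhaustive (recursive over free cells with feasibility
bounds; the last cell of each row and the last row are forced by the
margins). Above a configurable cap (default 5×10⁷ tables, far beyond any
table in this setting) the function either raises a resource error or, on
request, switches to a Monte-Carlo estimate over `stats::r2dtable()` draws,
reporting its seed and standard error and including the observed table in
the reference set. On 2×2 tables the function coincides with
`fisher_exact_2x2()`, which shares the same machinery.

`lr_chisq_test()` computes the likelihood-ratio chi-square
$G^2 = 2\sum O \log(O/E)$ with $(r-1)(c-1)$ degrees of freedom. Both
statistics are carried through every report deliberately: the SPSS
crosstabs output prints "Fisher's Exact Test" and "Likelihood Ratio" in
adjacent rows, and published tables captioned as exact tests sometimes
carry the likelihood-ratio numbers. Having both computed side by side makes
such discrepancies visible instead of mysterious — on the anchor
cross-tabulations shipped with the acceptance script the two differ by up
to 0.07, and it is the likelihood-ratio column that reproduces the
published values at printed precision.

`odds_ratio_2x2()` returns the crude odds ratio with the Woolf (log-Wald)
interval; zero cells are an error unless the Haldane–Anscombe 0.5
correction is requested, because an OR silently computed from a degenerate
table is worse than none. `logistic_fit()` is the model-based counterpart:
an IRLS maximum-likelihood fit (deviance tolerance 1e-12, 100 iterations)
reporting Wald intervals, the likelihood-ratio chi-square against the
intercept-only model, and Nagelkerke's
$R^2_N = \bigl[1 - (L_0/L_1)^{2/n}\bigr] / \bigl[1 - L_0^{2/n}\bigr]$.
Separation is detected from diverging coefficients and raised as an error
naming the predictor — Wald output under separation would be noise.
`stepwise_select()` performs forward selection / backward elimination over
predictor blocks (a factor moves with all its dummies) using
likelihood-ratio p-values, entry at 0.05 and removal at 0.10; a removed
block may re-enter only with a strictly improved p-value, which rules out
cycling.

## Survival machinery

PFS runs from treatment initiation to progression or death.
`km_estimate()` wraps the product-limit estimator with log-log pointwise
bands; the median confidence interval inverts that band
(Brookmeyer–Crowley). `gehan_wilcoxon_test()` is implemented directly: a
weighted logrank statistic with weight equal to the number at risk at each
distinct event time — the Gehan–Breslow generalized Wilcoxon, which is what
"Wilcoxon test" means for censored group comparison in the SPSS family.
(It is implemented by hand because `survival::survdiff(rho = 1)` is the
Peto–Peto variant, which weights by the survival estimate instead.) The
covariance uses the standard hypergeometric form and the statistic
$U^\top V^{-1} U$ over the first $k-1$ groups is referred to
$\chi^2_{k-1}$, with an eigenvalue-based generalized inverse when ties
make $V$ singular. `cox_univariable()` fits the partial likelihood with
Breslow tie handling by default (Efron behind an argument), rejects
constant covariates, and flags monotone likelihood. Early-weighted tests
fit this setting: the model's factors are early signals, and differences
between risk groups are expected early in follow-up.

## The synthetic cohort generator

`generate_cohort()` draws, per patient:

1. the joint (CRP factor × TRAE factor) cell — defaults 15/57, 16/57,
   16/57, 10/57 for both / CRP-only / TRAE-only / neither. These are the
   unique probabilities consistent with the anchor margins (31/57 per
   factor) and risk-group sizes (15/32/10) except for the single-factor
   split, which the margins do not determine; 16/16 is the symmetric choice
   and is configurable;
2. the kinetics class within the CRP factor (9/31 flare, 22/31 response;
   non-factor patients are non-responders), assumed independent of the
   TRAE factor within the CRP factor;
3. a baseline CRP from lognormal(log 30, 0.8) — spanning the clinically
   plausible range from a few mg/L to a few hundred; the anchor study does
   not report its baseline distribution;
4. a CRP trajectory realizing the class on the visit schedule
   (−1, 2, 6, 10 weeks): flare peaks at 3× baseline then settles at
   0.5–0.7×; response declines from 0.85× to 0.5×; non-response stays in
   1.0–1.3×. Multiplicative lognormal noise (sd 0.1) is applied to every
   draw, baseline included. The noise-free margins are wide enough that
   default-noise misclassification is rare (well under 1%), and zero-noise
   recovery is exact by construction;
5. adverse events: the first onset from a lognormal (untruncated mean
   4 weeks, log-sd 0.9) truncated to (0, 4] for early patients and
   (4, 28] for late ones — so the early flag is exact by construction and
   the cohort mean lands near 4 weeks — plus a Poisson number of later
   events with Table-style category and grade frequencies;
6. the RECIST outcome, conditional on the joint (kinetics class × TRAE)
   stratum via `default_response_probs()`. Conditioning on the class alone
   cannot reproduce the anchor study's risk-group outcome rows (it would
   give a 31% progression rate in the high-risk stratum instead of the
   observed 60%), because in that cohort the TRAE factor predicts outcome
   beyond the kinetics class. The six stratum-conditional distributions
   are derived by solving the margin equations of all three outcome
   cross-tabs at once (kinetics rows, TRAE rows, risk rows); the system is
   exactly consistent, the low-risk stratum's zero progression count forces
   zero progression probability in both early CRP-factor strata, and the
   one remaining free parameter is set to the boundary solution (early
   flare patients: certain objective response). PR vs CR within the pooled
   column is 28:1;
7. PFS as exponential per ground-truth risk group (medians 49 / 101 / 21
   weeks) with administrative censoring at 178 weeks (≈ 41 months of
   follow-up). The exponential is a deliberate simplification; a
   non-constant hazard would change medians little at these sizes.

The generator is deterministic given its seed, and every ground-truth label
is returned alongside the observable tables.

What the generator does **not** emulate: irregular per-patient visit
schedules and missing draws, correlation between baseline CRP and outcome
or IMDC class, per-regimen (IO/IO vs IO/TKI) trajectory differences,
grade-dependent event timing, and informative censoring. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers a known
data-generating process of this structure — not that the model is valid on
real patients.

## Numerical and testing choices

* Probability comparisons in exact tests use relative tolerance 1e-9;
  enumerated probabilities are checked to sum to 1 within 1e-10.
* Probability blocks in the simulation config must sum to 1 within 1e-12.
* Logistic and Cox fits run to deviance/gradient tolerances of 1e-12 with
  100-iteration caps; separation and monotone likelihood are reported, not
  papered over.
* Undefined statistics (an unreached survival median, an event-free
  patient's onset) propagate as `NA` and serialize as JSON `null`.
* Test problem sizes: the classifier properties run on 1000 random series
  against an exhaustive pairwise oracle; exact tests are checked against a
  brute-force enumeration oracle on 200+ random tables with margins ≤ 12;
  parameter recovery uses n = 2000 (logistic), n = 1000 (Cox) and n = 400
  (Kaplan–Meier); the end-to-end generator checks use n = 5700 (100× the
  anchor cohort) with ±0.02 / ±0.03 tolerances chosen from binomial
  standard errors at that size.

## Limitations

The model consumes RECIST response, IMDC class and CTCAE grades as given
labels and does not compute them. Profile-likelihood intervals, exact
logistic regression, multivariable Cox models and multiple-testing
correction are out of scope. The exact-test enumeration is exponential in
table size; beyond the cap the seeded Monte-Carlo fallback is the supported
path. The kinetics rule is sensitive to assay noise near its thresholds by
construction; the simulator quantifies this (misclassification is monotone
in noise), but choosing thresholds robust to a laboratory's analytic
variation is a study-design question the package does not answer.
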