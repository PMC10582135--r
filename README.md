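# crpflare

On-treatment risk stratification for advanced renal cell carcinoma (aRCC)
from two early, routinely available signals: the kinetics of C-reactive
protein (CRP) over the first three months of first-line immunotherapy
combinations, and the timing of the first treatment-related adverse event
(TRAE). The package is written for biostatisticians and clinical researchers
who want to apply, stress-test or simulate this class of on-treatment risk
model.

## The model

Each patient's longitudinal CRP series (mg/L, weeks relative to treatment
start) is classified against the baseline value *B* (the latest
pre-treatment draw, clamped at a 1 mg/L detection floor):

* **CRP flare-response** — some CRP(t₁) ≥ 2·*B* with t₁ ∈ (0, 4] weeks,
  followed by CRP(t₂) < *B* with t₂ ∈ (t₁, 12];
* **CRP response** — no such doubling in (0, 4], and some CRP(t) ≤ 0.7·*B*
  with t ∈ (0, 12];
* **CRP non-response** — everything else.

The second factor is early TRAE onset: first adverse event (any CTCAE
grade) at ≤ 4 weeks. The risk model combines the binary CRP factor
(flare-response or response) with the binary TRAE factor:

| CRP factor | early TRAE | risk group         |
|-----------:|-----------:|--------------------|
| yes        | yes        | low (favorable)    |
| exactly one of the two | | intermediate       |
| no         | no         | high (poor)        |

Around the model the package provides the inference toolbox such analyses
use: Fisher / Freeman–Halton exact tests by full fixed-margin enumeration
(with a seeded Monte-Carlo fallback above a configurable cap), the
likelihood-ratio chi-square, odds ratios with Woolf intervals, binomial
logistic regression with Nagelkerke R² and stepwise block selection,
Kaplan–Meier curves with Brookmeyer–Crowley median intervals, the
Gehan–Breslow generalized Wilcoxon test, and univariable Cox regression
(Breslow ties). A synthetic-cohort generator produces complete, labelled
cohorts with the joint statistical structure the analysis assumes, so the
whole pipeline is testable without patient-level data.

## Worked example

```r
library(crpflare)

s <- data.frame(time_weeks = c(-1, 2, 6, 10),
                crp_mg_per_l = c(52, 130, 31, 24))
b <- compute_baseline(s)          # 52
classify_patient(s, b)
#> CRP kinetics: flare_response (baseline 52 mg/L, 3 on-treatment values)
```

CRP at week 2 reached 130 ≥ 2·52 (a flare) and fell below baseline by week
6, so the patient is a flare-responder. A full simulated cohort, end to end:

```r
rep <- run_pipeline(pipeline_config(simulation = simulation_config(),
                                    seed = 42))
rep
#> On-treatment risk pipeline report
#>   cohort: 57 patients (simulation)
#>   CRP kinetics: flare_response 8, response 16, non_response 33
#>   early TRAE: 30 / 57
#>   risk groups: low 14, intermediate 26, high 17
#>   risk model vs response: exact p = 4.657e-06, LR p = 1.018e-06
```

At the default cohort size of 57, the three kinetics classes, the early-TRAE
split and the risk groups land near their configured expectations (9/22/26,
31/57 and 15/32/10); the exact test confirms the built-in association
between risk group and primary treatment response. The report also carries
the logistic summary (here Nagelkerke R² = 0.207) and per-group
Kaplan–Meier medians (here 48.4 / 73.8 / 21.5 weeks against configured
medians of 49 / 101 / 21; the intermediate group is the most variable
because its exponential median is the longest relative to follow-up).

Exact and asymptotic association tests are available directly on counts:

```r
risk_tab <- matrix(c(0, 5, 10, 4, 13, 15, 6, 0, 4), 3, 3, byrow = TRUE)
freeman_halton_exact(risk_tab)$p_value   # 0.00176 (full enumeration)
lr_chisq_test(risk_tab)$p_value          # 0.000465 (likelihood ratio)
```

Both statistics are reported throughout because published cross-tabs
captioned "Fisher's exact test" do not always carry the exact-test number:
the SPSS crosstabs output prints the exact test next to the likelihood-ratio
chi-square, and the rows are easily confused in reporting. The vignette
(`vignettes/on-treatment-risk-model.Rmd`) discusses this and all other
methodological choices.

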