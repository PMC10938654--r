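# kampovig

Pharmacovigilance toolkit for **drug-induced interstitial lung disease
(DIILD) after Japanese herbal (Kampo) medicine exposure**, built around
spontaneous-report data in the four-table JADER dialect. It is written for
pharmacoepidemiologists and drug-safety analysts who need the whole chain —
from raw relational CSV tables to signal tables, adjusted odds ratios,
matched cohorts and onset profiles — as tested, reusable functions rather
than one-off scripts.

## What it computes

* **Reporting odds ratio (ROR) signal detection.** For exposed cases *a*,
  exposed non-cases *b* and unexposed cells *c*, *d* by subtraction from the
  whole-database margins:

  ROR = (a/c)/(b/d),  95% CI = exp( ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d) )

  (Woolf interval). A signal requires the lower bound above 1 with at least
  3 cases; below 2 cases the flag is "not evaluated".
* **Crude-drug exposure reconstruction** from a formulation registry:
  grams/day of Scutellariae radix (SR), Bupleuri radix (BR) and Pinelliae
  tuber (PT) per report, and classification into the 2³ exposure groups.
* **Multivariate logistic modelling** with forward–backward stepwise
  selection by likelihood-ratio tests, interaction hierarchy, and adjusted
  RORs (delta-method intervals for combined interaction effects).
* **Propensity-score matching**: 1:1 greedy nearest-neighbor within a
  0.2·SD(logit PS) caliper, standardized-mean-difference balance checks
  (< 0.1 = balanced), and post-match RORs.
* **Dose–response and ROC cutoffs**: per-gram crude RORs, trapezoid AUC
  (= Mann–Whitney concordance), Youden-J intake cutoffs.
* **Weibull time-to-onset profiling**: median (IQR) of onset days within a
  365-day window, maximum-likelihood scale/shape with log-scale Wald
  intervals, and hazard-type classification (shape β > 1 with CI excluding
  1 → wear-out; β < 1 → initial failure; else random failure).
* **A synthetic JADER-dialect generator** (four CSV tables with configurable
  association strengths, demographics, missingness, duplicate submissions
  and Weibull onset structure), so every stage is testable with known truth.

## Worked example

```r
library(kampovig)

# -- signal detection from published report counts --------------------------
sig <- compute_ror(contingency_from_margins(103, 307))  # Bofutsushosan cells
sig
#> 2x2 table: a=103 b=307 c=36642 d=793027
#> ROR (subtracted): 7.3 (5.8 − 9.1)
detect_signal(sig)
#> [1] TRUE

# -- the same machinery end-to-end on generated data ------------------------
cfg <- sim_config(20000, drug_catalog = list(
  drug_spec("Shosaikoto", 0.02, 8, onset_alpha = 40, onset_beta = 1.36),
  drug_spec("Yokukansan", 0.03, 1.2)), seed = 1)
paths <- generate_tables(cfg, tempfile())
reports <- filter_suspected(integrate_reports(
  read_tables(paths$demo, paths$drug, paths$reac, paths$hist)))
event <- flag_diild(reports)
form <- load_formulary(system.file("extdata", "kampo_formulary_synthetic.csv",
                                   package = "kampovig"))
signal_table(reports, form, event, level = "product",
             n_case_total = sum(event), n_noncase_total = sum(!event))
#>   label      total  case noncase ror_ci           signal
#> 1 Shosaikoto   400   119     281 9.3 (7.4 − 11.7) TRUE
#> 2 Yokukansan   613    39     574 1.3 (1.0 − 1.9)  FALSE

fit_weibull(extract_durations(reports, drug = "Shosaikoto", event = event))
#> Weibull fit (n = 102): alpha = 40.08 (34.56–46.48) days,
#>   beta = 1.39 (1.20–1.60) [wear_out]
```

Reading the output: the planted 8-fold association is recovered as a
flagged signal (ROR 9.3, lower bound 7.4 > 1), the near-null drug is not
(lower bound 1.0), and the configured Weibull(40, 1.36) onset process is
recovered with an increasing-hazard ("wear-out") classification. The full
orchestration — signals, stratified tables, stepwise model, matching,
dose–response, onset profiles, underlying-disease table — is
`run_pipeline(pipeline_config(...))`, which writes one CSV per table and
logs every exclusion count.

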