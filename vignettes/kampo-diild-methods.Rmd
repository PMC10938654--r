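---
title: "Methods: signal detection and risk modelling for herbal-medicine DIILD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal detection and risk modelling for herbal-medicine DIILD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kampovig)
```

## The problem

Drug-induced interstitial lung disease (DIILD) is a severe adverse event long
associated with Japanese herbal (Kampo) medicines, particularly those
containing the crude drugs Scutellariae radix (SR, "ogon"), Bupleuri radix
(BR, "saiko") and Pinelliae tuber (PT, "hange"). Spontaneous-report databases
in the JADER dialect — four relational CSV tables (patient demographics,
drug records with role codes, adverse events, primary illness) joined on a
case id — allow disproportionality analysis of this association, but every
inferential step beyond counting needs care: exposure must be reconstructed
from formulation registries, reports carry heavy missingness, and the
reporting process breaks the usual cohort assumptions.

`kampovig` implements that full pipeline — ingestion and cleaning, crude-drug
exposure reconstruction, reporting-odds-ratio (ROR) signal detection,
multivariate logistic modelling, propensity-score (PS) matching,
dose–response with ROC cutoffs, and Weibull time-to-onset profiling —
together with a synthetic four-table generator so that every stage is
testable with known ground truth and no download.

## Data model and cleaning rules

Integration produces one report per case id. The cleaning conventions are:

* **Resubmissions.** Regulators update a report in place when corrections
  arrive; in a flat extract this appears as a repeated case id. The *last*
  demographic row in file order wins. This is an assumption (the extract
  does not say how versions were collapsed) and is logged per run.
* **Orphan child rows** (drug/reaction/history rows with a case id absent
  from the demographics) are dropped with a count: anonymized public
  extracts contain such rows.
* **Sentinels.** Sex `"unknown"` and age `"unknown"`/`"aged"` map to
  missing; exact ages never exist in the dialect, only decade strings.
* **Dose strings** lose a trailing unit token (`g`, full-width `ｇ`) and
  parse as decimals; anything else becomes missing and is counted, never
  silently dropped.
* **Partial dates** (`YYYY`, `YYYY-MM`) become missing dates but are counted
  separately — they drive the time-to-onset exclusions.
* **Role codes.** Only "suspected" drugs enter exposure definitions; reports
  left with no suspected drug stay in the denominator, because the 2×2
  background is the whole database.

## Exposure reconstruction

Each product's registry row gives grams of each crude drug per full daily
dose. A report's daily intake of crude drug $k$ is

$$D_k \;=\; \sum_{p \in \text{Kampo}} c_{pk}\, \frac{d_p}{f_p},$$

where $c_{pk}$ is the registry content, $d_p$ the reported daily product
dose and $f_p$ the full daily product dose. Intake is linear in dose and
additive across products; a missing Kampo dose makes the report's intake
missing (excluded from dose-based analyses, with a count).

Products are classified into the $2^3 = 8$ groups by SR/BR/PT membership. A
report whose suspected Kampo all share one group counts once for that group;
reports spanning groups are `MIXED` and are excluded from group-level counts
entirely (not multi-counted) — the counting examples in the source only say
such combinations are "not counted as one case", so full exclusion is a
choice, kept configurable by filtering on the classification yourself.
Per-product rows use simple membership, independent of grouping.

The shipped registry is **synthetic**: real product names with placeholder
compositions (the Shosaikoto row preserves the published BR : PT : SR
proportion 3.5 : 2.5 : 1.5). The published composition list for Shosaikoto
names seven crude drugs against six proportion numbers — an apparent
omission in the source — so only the SR/BR/PT ratios are relied on anywhere.
Substantive analyses must supply manufacturer-specific registries
(`inst/extdata/formulary_schema.md`).

## Reporting odds ratio

For exposed cases $a$, exposed non-cases $b$ and unexposed cells $c, d$
obtained by subtraction from the database margins,

$$\mathrm{ROR} = \frac{a/c}{b/d}, \qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right)\!,$$

the Woolf interval. A second, "marginal" convention divides by the margins
including the exposed ($a/(a+c)$ vs $b/(b+d)$); it reproduces the
worked-example arithmetic `(103/36745)/(307/793334)` which evaluates to
7.24, while the subtracted form gives 7.26 — both print "7.3" only via the
subtracted rounding. The subtracted form is the default because it
reproduces the published tables (e.g. the male stratum 10.2, where the
marginal form gives 10.0).

A zero cell makes the ROR undefined (reported as a dash), matching the
published convention; a Haldane 0.5 continuity correction exists but is off
by default. A signal requires the lower CI bound above 1 **and** at least
`min_cases = 3` cases; below 2 cases the signal is "not evaluated" (`NA`).
The source text asks for "more than 2" reports while its table suppresses
only counts below 2; the default follows the text and the threshold is an
argument.

Re-deriving every complete published table row from its printed counts
reproduces all 52 ROR point estimates exactly at one decimal. Seven of the
104 CI bounds differ by one unit in the last printed digit (one by two);
they sit at rounding boundaries of the source's own arithmetic, and the
regression test asserts that frozen set exactly rather than loosening the
comparison.

## Multivariate model and adjusted RORs

The risk model is

$$\log(\text{odds}) = \beta_0 + \beta_1 Y + \beta_2 D_1 + \beta_3 D_2 +
\beta_4 S + \beta_5 A + \beta_6 D_1 A + \beta_7 D_1 D_2,$$

with $Y$ the reporting year, $D_1, D_2$ the SR and PT daily intakes (g/day),
$S$ male sex, and $A$ the age-60 indicator. Age enters dichotomized from
decade strings ("60s" and older → 1); the decade-to-indicator map is a
package choice, since only the dichotomy itself is stated in the field's
reports. Fits use iteratively reweighted least squares (`stats::glm`,
relative tolerance `1e-10`, 100 iterations); separation is flagged, never
silently returned.

Stepwise selection is forward–backward with likelihood-ratio p-values and
the same entry/stay threshold (default 0.05). Hierarchy is enforced: an
interaction enters only while both components are present, and a main
effect cannot leave while its interaction remains. Wald p-values are used
nowhere in selection.

Adjusted RORs exponentiate coefficients. For an interaction row the
reported quantity is the **combined** effect
$\exp(\beta_2 + \beta_5 + \beta_6)$ (exposure effect at the moderator's
level), with a delta-method interval on the summed linear combination. This
rule is reverse-engineered: the published interaction row (3.35) is
reproduced by the component sum $\exp(0.38 + 0.65 + 0.17) = 3.32$ at
coefficient-rounding precision, while the bare interaction coefficient
$\exp(0.17) = 1.19$ cannot produce it.

Which analysis subset the published model used (the dose-complete matched
input of about 4,240 reports is implied but not stated) is not decidable;
the model functions therefore take the analysis set as an explicit argument
and the pipeline states its subset in the log.

## Propensity-score matching

The PS is the fitted probability of crude-drug exposure given sex, the age
indicator, and the other two crude-drug intakes. Matching is 1:1 greedy
nearest-neighbor without replacement on the logit PS, processed in
descending logit order, within a caliper of 0.2 standard deviations of the
logit PS. Ratio, replacement and ordering are not stated in the field's
descriptions; these are the most common conventions and all are arguments.
The only randomness is exact-distance tie-breaking (seeded). Balance is
assessed by standardized mean differences (SMD; below 0.1 = balanced) with
χ²/t p-values per covariate — which tests produced the published balance
p-values is unstated, so the choice is labelled. Post-match RORs are plain
unpaired 2×2 estimates, as in the published comparison.

Matching without replacement can only balance when controls comfortably
outnumber exposed. The synthetic confounded cohort therefore fixes its
exposure prevalence near 28%, the regime of the real matched cohorts
(26–37% exposed); at a prevalence near 50% the control reservoir is
exhausted and residual imbalance persists at any sample size — a structural
limit of the design, not an estimation error. Balance checks run on cohorts
of n = 8,000, where the sampling noise of an SMD (≈ 0.02) is well below the
0.1 threshold being asserted.

## Dose–response and ROC cutoffs

Per crude drug, `log(odds) = b0 + b1 D` gives the per-gram crude ROR
$\exp(b_1)$. The empirical ROC over all distinct intake thresholds
(positive when intake ≥ threshold) yields the AUC by the trapezoid rule —
identical to Mann–Whitney concordance, asserted against an $O(n^2)$
enumeration oracle in the tests — and the cutoff maximizing Youden's
$J = \text{sens} + \text{spec} - 1$, ties resolved toward the smaller
threshold. Youden's J operationalizes "highest sensitivity while keeping
high specificity"; the closest-to-(0,1) rule is available by flag.

## Time-to-onset and Weibull profiling

Durations are onset date − drug start date in whole days, within a 365-day
window. Duplicate (drug, start-date) rows collapse to one; partial dates
exclude the report (counted); nonpositive durations are excluded as
inconsistent rather than clamped to 1 (the source states no convention;
`extract_durations` counts them separately so the alternative is easy to
apply). All observations are treated as events — a spontaneous report
exists only because the event occurred — so the window truncates, it does
not censor, and the Kaplan–Meier estimate equals the empirical survival
function.

The Weibull fit maximizes the uncensored two-parameter likelihood: Newton
iteration on the profile score for the shape β (tolerance `1e-10`), scale α
in closed form, then Wald 95% intervals on the log-parameter scale from the
observed information — deterministic and standard for shape-parameter
reporting; a profile-likelihood interval was considered and not adopted.
Hazard classification: β > 1 with CI excluding 1 → increasing hazard
(wear-out failure); β < 1 with CI excluding 1 → decreasing (initial
failure); otherwise constant (random failure). Fits refuse fewer than 10
durations and flag degenerate (all-equal) inputs, where β diverges.

## The synthetic generator: what it does and does not emulate

`generate_tables()` emits the four-table dialect with: per-drug exposure
probabilities and a logistic event model (log-odds = logit(background rate)
+ Σ log(odds multiplier) × exposure), so realized RORs converge to the
configured multipliers; per-drug Weibull onset delays (whole days, minimum
1); decade-string ages with "unknown"/"aged" sentinels; partial-date
emission at a configurable rate; duplicate case-id resubmissions; and dose
strings with occasional unit suffixes. Four RNG streams derived from one
seed drive the demographic, drug, reaction and history stages; identical
config + seed reproduces byte-identical files. The default background
event rate 0.044 is the target event's share of the real database margins
(36,745 / 830,079).

It does **not** emulate: the regulator's correction/versioning cycle,
Japanese free-text drug-name variants, event-dependent reporting
propensity, co-prescription correlation structure, or calendar trends in
reporting. Passing tests on synthetic data therefore demonstrate
*algorithmic* correctness under the stated generative model, not fidelity
of any substantive estimate to the real database; the only real-data
quantities asserted anywhere are the published contingency counts shipped
as `diild_reference_counts()`. The partial-date rate is a free parameter
(default 0.10) — the real frequency of partial dates is not documented.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to make each property sharp at
modest cost: 200,000 reports for the strong-association 2×2 recovery;
100 replicates × n = 50,000 for coefficient-interval coverage of the full
interaction model (coverage ≥ 90/100 per term); 100 seeds × n = 1,000 for
Weibull shape coverage; 50 replicates × n = 8,000 confounded cohorts for
matching (null-effect CI covering 1 in ≥ 90%, all post-match SMDs < 0.1);
50 random instances ≤ 200 points for the AUC oracle; n = 2,000 for the
Kaplan–Meier/DKW band. Stepwise power uses 10 replicates at n = 30,000 with
a pass threshold of 8/10, the binomial slack of a 95% per-replicate rate.

Other numerics: CI multiplier fixed at 1.96 for the ROR Woolf intervals
(matching the published arithmetic) and `qnorm(0.975)` elsewhere; quantiles
by linear rank interpolation (`stats::quantile` type 7); matching caliper
computed over all subjects' logit scores; logit scores clamped to
$(10^{-12}, 1-10^{-12})$ before transformation.

## Known limitations

* Disproportionality measures quantify reporting, not risk; nothing here
  corrects for under/over-reporting or the missing denominator of an SRS.
* The registry shipped is synthetic; substantive intake reconstruction
  requires manufacturer compositions, which differ across companies.
* The adjusted-ROR combination rule for interactions is reverse-engineered
  from published values, as documented above.
* `MIXED` reports are excluded from group counts; whether the source
  excluded or multi-counted them is not decidable from its text.
* The Weibull window choice changes hazard-trend conclusions; 365 days is
  the package default, not a recommendation.
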