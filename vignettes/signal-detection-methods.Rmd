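---
title: "Methods: disproportionality signal detection for antifungal DILI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for antifungal DILI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilisignal)
```

## The problem

Spontaneous reporting databases (FAERS and its international
counterparts) accumulate reports of suspected adverse drug reactions
without any record of how many patients took each drug. Absolute risks
are therefore not estimable; instead, pharmacovigilance screens for
*disproportionality* — whether an event is reported more often with a
drug than the rest of the database would predict. `dilisignal`
implements that screen for drug-induced liver injury (DILI) and eleven
systemic antifungals: eight azoles (ketoconazole, miconazole,
clotrimazole, fluconazole, voriconazole, itraconazole, isavuconazole,
posaconazole) and three echinocandins (caspofungin, micafungin,
anidulafungin).

## Data model and case selection

A report set is relational, mirroring the source extract: a
demographics row per report (`primaryid` = case id + version) plus
drug, reaction and outcome child tables. Reading normalises ages to
years (MON/12, DY/365.25, DEC×10, …; values above 120 years are set
missing), parses `yyyymmdd` dates, and resolves partial dates to
mid-period (`yyyymm` → the 15th, `yyyy` → July 1) so that onset
arithmetic remains defined. Missing sex, reporter and country map to
explicit `Unknown` categories: published cohort tables report unknowns
as first-class rows, so they are never dropped.

Cases are re-submitted over time as new versions. `deduplicate()`
retains, per case id, the version with the greatest
(receipt date, version id) under lexicographic comparison — the latest
information wins, and the version id breaks receipt-date ties. The
source data never states a retention rule; this is the package's
declared default, and the count of removed versions is always reported.

A report is a **DILI case** when any reaction preferred term (PT),
after normalisation (uppercase, whitespace collapsed), is in the
packaged 52-term liver-event dictionary
(`extdata/liver_event_pts.txt`); there is no MedDRA hierarchy
traversal, the list is explicit and editable. A report is **exposed**
when a drug record whose role code is in the configured set matches a
lexicon synonym by token-boundary, case-insensitive containment. The
default role set is `{PS, SS}` (primary and secondary suspect):
suspect-only counting is the common pharmacovigilance default, and
concomitant/interacting records mostly reflect co-medication, not
suspicion. Free text that matches no synonym is left unmatched — no
fuzzy matching, to avoid silent false positives. A report naming
*k* study drugs is one case but contributes to each drug's table; the
count of such reports is surfaced (`flow$n_multi_drug`) so attribution
inflation is visible.

## The four statistics

For one drug, with `a` = drug∧DILI, `b` = other-drugs∧DILI, `c` =
drug∧other-reaction, `d` = other∧other, `N = a+b+c+d`, and the shared
log-scale standard error `se = sqrt(1/a + 1/b + 1/c + 1/d)`:

* `ROR = (a/b)/(c/d)`, 95% CI `= exp(ln ROR ± 1.96 se)`;
  signal iff lower bound > 1 and `n = a ≥ 2`.
* `PRR = (a/(a+c))/(b/(b+d))`, with Pearson `χ²`;
  signal iff `PRR ≥ 2`, `χ² ≥ 4`, `n ≥ 3`.
* `IC = log2(aN/((a+c)(a+b)))`, `IC025 = IC·exp(−1.96 se)`;
  signal iff `IC025 > 0`.
* `EBGM = aN/((a+c)(a+b))`, `EBGM05 = EBGM·exp(−1.64 se)`;
  signal iff `EBGM05 ≥ 2`, `n > 0`.

Two deliberate interpretation points:

**As-printed vs. literature bounds.** The IC and EBGM here are the
*unshrunk* observed/expected ratios — no BCPNN prior, no gamma-Poisson
shrinkage — and the default (`mode = "printed"`) lower bounds are the
multiplicative forms above, exactly as published tables of this kind
print them. Support for that reading: such tables leave IC025 blank
whenever IC is negative, which is only explicable if the bound takes
`ln(IC)` (undefined for `IC ≤ 0`). Two consequences follow and are
worth knowing. First, `EBGM = 2^IC` identically, so the two "Bayesian"
columns are one quantity on two scales (a property test asserts this on
10,000 random tables). Second, `IC·exp(−1.96·se) > 0` exactly when
`IC > 0`, so the printed-form IC criterion degenerates to `IC > 0` and
fires for roughly half of all null drugs — it is not a calibrated test.
`mode = "literature"` provides the conventional additive bound on the
log2 scale, `IC − 1.96·se/ln 2`, which is defined for negative IC and
approximately calibrated. The default remains "printed" because
reproducing the published computation is this package's contract;
calibration claims in the tests are made on the ROR criterion.

**χ² scope.** The published formula names only cell `a` in the
`Σ(O−E)²/E` sum, but the magnitudes in published signal tables are
consistent with the four-cell Pearson statistic, which is also the
field standard; the default sums all four cells
(`chi2_cells = "four-cell"`), with `"single-cell"` available. Yates
continuity correction is off by default and switchable.

**Degenerate tables.** The default zero-cell policy is `"undefined"`:
any metric whose cells are zero is `NA`, its flag is false, and batch
runs continue (a zero-case drug still gets its row). The
Haldane–Anscombe alternative (`"haldane"`) adds 0.5 to all four cells
of any zero-containing table before computing; the count gates
(`n ≥ 2`, `n ≥ 3`, `n > 0`) always use the raw count.

## Descriptive summaries

Demographic summaries count every cohort report exactly once per
dimension (age band, sex, reporter, receipt year, reporting area), with
unknowns as their own category, and report percentages of the full
cohort size rounded half-up to two decimals — the rounding that
reproduces published percentages exactly. Age bands are `<18`, `18–44`,
`45–64`, `65–74`, `75–84`, `≥85`, `Unknown`.

Time to onset is the whole-day difference from the drug's earliest
therapy start to the event date; negative differences (event recorded
before therapy start, which occurs in spontaneous data) and missing
dates yield a missing onset rather than a negative one. The interval is
first-start-to-event — the source never states first vs. last dose, so
this is a documented default. Per-drug medians and IQRs use type-7
(linear-interpolation) quantiles: published onset tables with
fractional IQR bounds such as 2.5–45.75 are consistent with an
interpolating rule, and a brute-force oracle test pins the
implementation on all small samples. Across-drug comparison uses
Kruskal–Wallis overall and unadjusted two-sided Wilcoxon rank-sum
pairwise — the usual nonparametric choices for skewed onset data; the
source names no test, so these are swappable defaults.

Outcome summaries count a report once per outcome category it carries
(death, life-threatening, hospitalization, disability, congenital
anomaly, required intervention, other serious), so category percentages
can sum above 100. The mortality denominator is the number of the
drug's case reports with *at least one* recorded outcome code —
published outcome tables imply a denominator smaller than the drug's
total case count (e.g. 19 deaths printed as 50.00% against 39 total
reports). Death proportions across drugs are compared by a χ² test.

## The synthetic generator

`synthetic_config()` + `generate_reports()` produce a FAERS-like
population with known ground truth, so every downstream stage has an
exact bookkeeping oracle. Per report:

* **Drugs:** `1 + Poisson(λ = 1.5)` distinct drugs (multi-drug reports
  are the FAERS norm; no distribution is published, so λ is a realism
  choice), sampled by lexicon weight; the first is primary suspect, the
  rest secondary suspect or concomitant (0.6/0.4). The default lexicon
  holds the 11 antifungals at weight 0.03 each against 60 common
  background drugs at weight 1, putting each antifungal in roughly
  0.1% of reports — a realistic prevalence for a niche systemic
  antifungal.
* **Event:** the report is a liver-event report with probability
  `min(1, baseline_event_prob × max(true_rr over its suspect drugs))`;
  `baseline_event_prob` defaults to 0.02 (liver events are a few
  percent of all reports). `true_rr` is therefore a *reporting-rate
  ratio*: at rate ratio 5 and baseline 0.02 the implied odds ratio —
  what ROR estimates — is 5 × 0.98/0.90 ≈ 5.44, slightly above 5. Event
  reports carry 1–3 dictionary PTs; others carry 1–3 of 60 non-hepatic
  decoy PTs.
* **Onset and dates:** onset days are `round(exp(N(μ, σ)))` per the
  primary-suspect drug (log-normal right-skew is the standard
  time-to-onset shape; day 0 = same-day onset is allowed, as published
  IQRs reaching 0 require); the receipt date is sampled inside the
  configured reporting year and the event/start dates are derived
  backwards, so the year marginal is exact.
* **Outcomes:** a report has any recorded outcome with probability
  `p_any` (default 0.6); given that, death occurs with probability
  `p_death` — by construction `p_death` *is* the expected mortality
  rate on the reports-with-outcome denominator, which makes the
  generator-oracle mortality test exact — and 1–2 non-death codes are
  drawn from a categorical, reproducing the >100% column sums of
  multi-outcome reports.
* **Duplicates:** a `duplicate_rate` fraction of cases (default 0.07)
  is emitted twice with a bumped version and a receipt date 30 days
  later; the injected count must equal `deduplicate()`'s removal count.

`make_paper_like_config()` sets the demographic marginals to the
packaged published-cohort proportions, the per-antifungal rate ratios
to the published ROR point estimates, onset log-normals centred on the
published per-drug medians (σ = 1.1), and per-drug death probabilities
at the published mortality rates. This *emulates* the published study
conditions; it is not a reconstruction of the real joint distribution —
dimensions are generated independently, there is no indication
channeling (the real-world reason echinocandins accrue liver-event
reports from already-ill patients), no reporting-quality drift over
years, and drug names are clean lexicon entries rather than messy free
text. Passing tests therefore demonstrate correctness of the
*computation* on data with this structure, not robustness to real-world
confounding.

## Validation studies and what they show

The test suite runs two simulation studies at the study's own scale,
alongside exact oracles (closed-form worked table, round-trip identity,
ground-truth bookkeeping equality, quantile brute force):

* **Null calibration** — 200 seeds × 50,000 reports with all rate
  ratios 1: the ROR criterion (CI lower bound > 1 ∧ n ≥ 2) fires for
  about 3% of drug tests, below its 5% nominal ceiling, as expected for
  a two-sided-CI lower-bound rule (asymptotically a 2.5% one-sided
  test) further deflated by the count gate at small co-occurrence
  counts. The printed-form IC criterion is excluded from calibration
  claims for the structural reason given above.
* **Parameter recovery** — 100 seeds × 200,000 reports with a five-fold
  signal injected on one drug at the 2% baseline: the estimated ROR's
  95% CI covers the injected ratio, and all four criteria flag the
  drug, in well over 90% of seeds. Coverage of the *rate* ratio 5 sits
  a few points below the nominal 95% because the estimand (odds ratio
  ≈ 5.44) is slightly larger, as noted above.

`scripts/acceptance.R` re-runs both studies plus the worked-table and
fixture-cohort computations from a single `--seed` and writes the
resulting numbers as JSON.

## Known limitations

* Exposure matching is lexicon-driven token containment; misspelled or
  exotic free-text drug names in real extracts will be missed unless
  synonyms are added to the (plain-text, editable) lexicon.
* The pre-2012 legacy extract schema and archive downloading are out of
  scope; inputs must be in the modern dialect handled by
  `faers_dialect()`.
* No stratified or time-sliced disproportionality and no
  multiple-comparison adjustment are provided, matching the analysis
  this package reproduces.
* Causality assessment (e.g. RUCAM) and DILI biochemical subtyping
  (hepatocellular/cholestatic/mixed) are deliberately absent: case
  status here is reported-term membership, nothing stronger.
* Disproportionality on spontaneous reports measures reporting
  association, not incidence or risk; indication bias can inflate or
  deflate any of these statistics.
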