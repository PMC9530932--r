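---
title: "ROR-based signal screening: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROR-based signal screening: model, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The case/non-case model

Spontaneous-reporting databases have no exposure denominator, so absolute
risks cannot be estimated. The case/non-case design works entirely within
the database: for a target drug *P* and target adverse event *R*, reports
with *R* are "cases" and all other reports are "non-cases", and the screen
asks whether drug *P* is over-represented among the cases. Each report of
the analysis universe contributes exactly once to exactly one cell of the
2×2 table (a, b, c, d) by set membership of *P* in its drug set and *R* in
its event set — the counting unit is the report, not the drug–event
mention, because one patient's report may list several drugs and several
events.

The reporting odds ratio is `ROR = (a·d)/(c·b)`, i.e. the odds of the event
among reports exposed to the drug divided by the same odds among reports not
exposed. Under the null hypothesis that the event is reported independently
of the drug, ROR = 1.

### Confidence interval

`compute_ror()` uses the Woolf (log-normal) interval,
`exp(ln ROR ± z·SE)` with `SE = sqrt(1/a + 1/b + 1/c + 1/d)` and `z = 1.96`
for a 95% interval. This is the standard choice in ROR-based screening
systems; both `z` and the interval behaviour near zero cells are exposed as
arguments rather than hard-wired. The interval is asymptotic: `ln ROR` is
approximately normal when all four cells are moderately large, and visibly
skewed when the smallest cell is of order 10 (this matters for the
calibration study below).

### Decision rule and strata

A pair is a signal of disproportionate reporting (SDR) when the lower bound
of the interval exceeds 1 **and** the pair has at least `min_a = 3` case
reports — the minimum-case rule screens out pairs whose entire evidence is
one or two reports. Intensity strata separate `3 ≤ a < 5` from `a ≥ 5`
signals, since the weaker stratum is more sensitive to duplicate or
coincidental reporting.

### Zero-cell conventions

Three degenerate configurations arise in sparse databases and are handled
explicitly rather than corrected silently:

* `c = 0` — every report with the event lists the drug. The ratio is
  undefined by division; the ROR is set to the sentinel value **99.9** with
  status `sentinel_c_zero` and no interval. Such a pair with `a ≥ 3` is
  flagged as a possible SDR in its own stratum (`a>=3_c=0`). The sentinel
  is a marker, not an estimate: downstream numeric summaries should filter
  on the status field, which is why the status travels with every result.
* `a = 0` — no information on the pair; never emitted by the screen.
* `b = 0` or `d = 0` (with `c > 0`) — the interval is uncomputable; the
  pair is reported with status `undefined` and never flagged.

A Haldane–Anscombe 0.5 correction (`correction = "haldane"`) is available
for sensitivity analyses but is off by default: the default behaviour
surfaces the zero-cell conventions instead of inventing a continuity
assumption.

## The analysis universe

`apply_filters()` applies the inclusion rules: an inclusive calendar
window, at least one drug code matching the ATC prefix of the target class
(`J01` for systemic antibacterials), and exclusion of medication-error
notifications (the error flag is report-level — the whole notification is
about an error, so the whole notification leaves).

One genuinely open design point is the denominator: when a database extract
is pulled by drug class, "reports not listing drug P" means *other drugs of
the class*, not the whole database. The default therefore drops
class-external drug mentions from retained reports, so c and d are counted
against the class subset; `keep_nonmatching_drugs = TRUE` keeps
co-medications as comparators for sensitivity analyses. Both behaviours are
exact with respect to the same report universe; only the interpretation of
"other drugs" changes.

Term handling is deliberately minimal and auditable: drug codes are
upper-cased and trimmed, event terms case-folded with internal whitespace
collapsed, mentions deduplicated into sets. No fuzzy matching, no
vocabulary mapping — the input is assumed ATC-coded and
Preferred-Term-coded.

## The synthetic report generator

`generate_reports()` draws reports from a fully specified generative model:
each drug is mentioned independently with its marginal probability; each
event is mentioned with its baseline probability, **modified on the odds
scale** by the multiplier of any injected signal whose drug is present.
Working on the odds scale rather than the probability scale means an
injected `odds_multiplier` of 5 *is* the true odds ratio that the screen
estimates, so recovery tests have an exact target. Multiple signals hitting
the same event multiply. Dates are uniform over the configured window and
the medication-error flag is report-level Bernoulli. One global stream
seeded from the config drives all draws in a fixed order, so identical
configurations reproduce identical collections bit-for-bit.

`expected_contingency()` computes the exact expected a/b/c/d under this
model by enumerating the joint presence patterns of the drugs carrying
signals into the target event — the analytic oracle used by the
consistency and recovery tests.

What the generator deliberately does **not** model: reporting biases
(notoriety, stimulated reporting), duplicate submissions, under-reporting
dynamics, term hierarchies, or correlated co-prescription. Passing tests on
synthetic data therefore validate the *statistical machinery* — counting,
estimation, calibration, conventions — not robustness to the messiness of
real pharmacovigilance data.

## Validation design and numerical choices

The test suite validates the screen at four levels; the problem sizes are
the package's chosen study conditions.

* **Oracle equivalence.** On over 1,000 randomized positive-cell tables
  arising from small synthetic universes, `compute_ror()` must equal an
  independent brute-force computation that loops over raw report sets and
  forms the odds ratio as a ratio of odds (tolerance 1e-13, i.e. floating
  precision over the two different operation orders).
* **Exhaustive invariants.** Over every table with `n ≤ 40`: swapping the
  drug and event roles (b ↔ c) leaves the ROR unchanged, and with all
  margins fixed, one more case strictly increases it.
* **Null calibration.** 200 universes of 20,000 reports, 10 drugs × 20
  events, no injected association. The fraction of eligible pairs (a ≥ 3,
  all cells positive) flagged SDR must lie within 3 Monte-Carlo standard
  errors of the nominal one-sided 2.5%, with the standard error taken
  across replicates because pairs within one universe share reports and
  are correlated. Marginal reporting frequencies (drugs 0.10–0.25, events
  0.05–0.15) are set so the smallest pair has expected a ≈ 100: the
  calibration claim is asymptotic, and below expected a ≈ 30 the Woolf
  interval's one-sided error is genuinely inflated (≈3% at expected
  a = 20) — a property of the statistic, not of the implementation, which
  a calibration test run in that regime would conflate with a defect.
* **Parameter recovery.** 500 replicates of 5,000 reports with one injected
  pair at true OR = 5 and expected a ≈ 30 (drug marginal 0.1, event
  baseline 0.0125). The 95% interval must cover the truth at 95% within
  Monte-Carlo tolerance and mean ln ROR must sit within 3 standard errors
  of ln 5.

End-to-end, `run_pipeline()` must be byte-deterministic (identical inputs
give identical CSVs) and its JSON run log — reports read, reports surviving
each filter, pairs with a ≥ 1, pairs excluded by the minimum-case rule,
pairs screened, SDRs found — must match independent enumeration from the
raw reports. Output ordering is fixed (radix/byte order on drug code, then
event term) so diffs are reproducible across locales.

## Classification and annotation

ATC level-5 validity is a lexical check (letter, two digits, two letters,
two digits). The packaged AWaRe table maps the commonly screened J01
substances to Access / Watch / Reserve and is plain versioned data the user
can replace as WHO revises the list; codes missing from the table are
annotated `"unclassified"` rather than raising an error, because
classification is an annotation, not a gate.

Label knowledge is likewise user-supplied data: a CSV of (drug, event)
pairs already described in the product label. `annotate_labelled()` is
tri-state — `TRUE` (on label), `FALSE` (drug curated, event not on label: a
candidate new signal), `NA` (drug not curated). Keeping "unknown" distinct
from "not on label" prevents incomplete curation from manufacturing
new-signal claims. Literature corroboration of unlabelled signals is a
manual step outside this package's scope.

## Known limitations

* The screen is frequentist disproportionality only: no PRR, no Bayesian
  shrinkage (IC/BCPNN, EBGM), and no multiple-comparison adjustment — at
  typical screening scale a 2.5% one-sided error over hundreds of pairs
  guarantees some false signals, which is why SDRs are screening
  hypotheses, not causal findings.
* Duplicate-report detection, free-text drug-name mapping and MedDRA
  hierarchy handling are out of scope; inputs are assumed coded.
* The sentinel 99.9 is comparable across pairs only as a flag, never as a
  magnitude.
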