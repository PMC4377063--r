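---
title: "From parental illness reports to infectious episodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From parental illness reports to infectious episodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episodizer)
```

## The problem

Diary-based infection surveillance in young children produces a stream of
dated reports — ICD-10 symptom/diagnosis codes and yes/no fever answers —
in which one infection typically generates several entries.  `episodizer`
reduces that stream to infectious episodes in four classes (respiratory,
gastrointestinal, other, unknown febrile), then computes person-time
incidence rates and covariate rate ratios.  This vignette documents the
model, its tunable parameters, and the design decisions taken where the
protocol's verbal description left genuine choices open.

## The category catalog

Codes are classified by longest-prefix match against an editable catalog
of numbered categories, each carrying one of five code classes
(`RESPIRATORY`, `GASTROINTESTINAL`, `GI_SYMPTOM`, `FEVER_MARKER`,
`OTHER`).  The shipped default is a *reconstruction*: the category names
and their arrangement into episode classes are published, but the
underlying code lists are not, so the default assigns each named category
an expert ICD-10 reading (e.g. J00/J06 to common cold, A00–A09 to
infective gastroenteritis, R50 to the fever marker, R11/R19.7/K52.9 to
gastroenteritis symptoms).  Any analysis that has an authoritative
mapping should supply its own file; classification behaviour, not the
particular code lists, is what the rest of the package depends on.
Codes are normalized by uppercasing and stripping the dot, since ICD-10
dialects differ on dot usage.  A Fahrenheit fever threshold in a catalog
file is converted to Celsius at load (101&nbsp;°F → 38.33&nbsp;°C), so a
single Celsius threshold (default 38.0&nbsp;°C) travels with the catalog.

## The merging procedure

Per child, sorted by (onset date, report id):

1. **Respiratory chaining.** Respiratory-class reports whose successive
   gaps are at most `merge_gap_days` (default 5) form one episode.  The
   phrase "within the same week, at most five days in between reports"
   admits two readings — a 5-day window anchored at the first report, or
   pairwise gaps between successive reports.  We implement *consecutive-gap
   chaining*: it is the only reading that handles week-spanning symptom
   sequences, and the window reading is recoverable by configuration
   of the gap parameter.
2. **Gastro-symptom absorption.** Gastroenteritis-*symptom* reports
   (category 8 — nausea, vomiting, unspecified gastroenteritis) within
   `merge_gap_days` of any current member of a respiratory episode are
   absorbed into it, because these symptoms frequently accompany
   respiratory infection in young children.  Absorption can extend the
   episode's span, so the scan repeats to a fixed point with immediate
   member updates; a symptom report can therefore bridge into range of a
   later symptom report.  When two respiratory episodes are equally
   close, the earlier-onset episode wins (then lower index) — a
   deterministic tie-break the verbal rule does not specify.  Category-7
   infective-gastroenteritis codes are *never* absorbed; only symptom
   codes are.
3. **Gastrointestinal chaining.** Remaining category-7 and unabsorbed
   category-8 reports chain under the same gap rule.
4. **Other.** Every remaining other-class code is its own episode, even
   identical codes on adjacent days.  This is the rule's literal content;
   it can overcount multi-report "other" illnesses and we do not
   second-guess it.
5. **Fever resolution.** Fever reports — standalone "yes" answers *and*
   fever-symptom codes (category 1, R50) — attach to the episode whose
   nearest member lies within `fever_window_days` (default 5).  Ties go
   respiratory &gt; gastrointestinal &gt; other, then earlier onset: a fever
   eligible for several episodes attaches to exactly one, since attaching
   it to all would double-count febrile episodes.  Distances are measured
   to coded members only, so an attached fever never widens another
   fever's attachment window.  An unattached fever with no infection code
   within `fever_search_days` (default 7) on either side becomes an
   unknown-febrile episode.

Treating coded fever-symptom reports as fevers for step 5 — including as
seeds of unknown-febrile episodes — follows from the category's
definition ("fever without any ICD-10 code within a week prior or
after") and from the published accounting: solitary yes-answers alone
number only a few hundred, far short of the several thousand
unknown-febrile episodes reported, so the bulk must arise from
fever-coded reports.  Consequently an unknown-febrile episode carries
`n_codes = 1` when seeded by an R50 report and 0 when seeded by a bare
yes-answer.

Two windows, one word "week": merging uses 5-day gaps while the
unknown-febrile lookaround is 7 days, mirroring the protocol's two
phrasings.  Both are `episode_params()` fields; the asymmetry creates a
gap: a fever 6–7 days from the nearest infection code is neither
attachable nor unknown-febrile.  Such fevers are dropped and logged
(`dropped_fever_ids`), and the partition property — every report in
exactly one episode or the dropped log — is enforced by tests.

An episode's onset is its earliest *coded* member date (the fever date
for unknown-febrile episodes); it is febrile iff any member carries a
fever flag or an attached fever.  Episode construction is per-child,
order-invariant (sorting plus id tie-breaks) and translation-invariant in
time; `oracle_build_episodes()` re-implements the rules by exhaustive
pairwise scanning and the test suite holds the two implementations equal
over thousands of randomized report sets.

## Rates and the Poisson model

Calendar conventions are fixed for reproducibility: one month is
30.4375 days (365.25/12), one year 365.25 days, follow-up is capped at 48
months (1461 days), and age bins are half-open `[k, k+3)` months.
Person-time runs from birth to capped follow-up end regardless of missed
visits — the eligibility filter (no two consecutive missed visits, full
four-year follow-up) already guarantees near-complete observation, and
the published per-person-year rates are consistent with undeducted
person-time.  Seasons are meteorological quarters anchored on winter =
December–February; the source protocol never defines its seasons, so this
documented convention is configurable in spirit (monthly stratification
is also available).

Rate ratios come from a maximum-likelihood log-link Poisson regression of
per-child episode counts with `log(person_years)` offset — per-child
aggregation is likelihood-equivalent to per-interval rows under this
model, and exact per-child exposures handle censored synthetic children.
Reference levels are pinned (site US-Colorado, female, no first-degree
relative, HLA DR4-DQ8/DR4-DQ8).  Confidence intervals are Wald on the log
scale; per-factor inference is a joint Wald chi-square with levels−1
degrees of freedom (internally consistent with the squared z-statistic at
1 df).  No overdispersion adjustment is applied, matching the plain
Poisson analysis being reproduced; a quasi-Poisson variant is a
documented extension, not a default.  A factor level with zero events is
reported with an infinite confidence bound and a warning rather than a
spurious finite interval.  Convergence: deviance tolerance 1e-8, at most
100 iterations.

## The synthetic cohort generator

`sim_config()` encodes the study conditions: site mix proportional to the
published cohort (Finland 815, Germany 164, Sweden 1271, Colorado 545,
Georgia 285, Washington 383 of 3463), 11% with a first-degree relative
with T1D, an HLA genotype mix typical of high-risk screening (20/39/19/17/5%,
a plausible choice since exact frequencies are unpublished), base class
rates 3.8/0.7/0.3/0.4 episodes per person-year, covariate log rate ratios
from the published panel-A estimates (e.g. Finland 1.50, male 1.04), a
piecewise log-linear age profile over knots at 0/6/9/18/48 months
(relative heights 0.55/1.35/1.40/1.25/0.55, normalized to mean one —
peaking at 6–9 months, declining after 18), winter-peaked sinusoidal
seasonality on respiratory (amplitude 0.35) and gastrointestinal (0.25)
classes only, a 1–5-support reports-per-episode distribution with mean
1.60, per-class febrile fractions 41.5/36.6/54/100%, and a 5.5% share of
unknown-febrile events reported as bare yes-answers (285 of 5141).
Within-episode report timing is not described anywhere, so offsets are
uniform over `0..report_spread_days` with the first report at onset — a
stated modeling choice.

Episodes are simulated per child and class as nonhomogeneous Poisson
processes by thinning, then thinned again to enforce a refractory
`min_spacing_days` (default 8) between same-class events.  Three
consequences are worth stating plainly:

* **Separability arithmetic.** Truth clusters are separable by the 5-day
  rule only when `min_spacing_days > report_spread_days +
  merge_gap_days`.  The default spread is therefore 2 days (8 &gt; 2 + 5);
  with a 5-day spread an 8-day spacing would *not* prevent adjacent
  truths from merging.  Other-class truths emit exactly one code, since
  the "each code is an episode" rule would otherwise split them.
* **Dead-time bias.** An 8-day refractory period depresses realized
  rates below the configured intensity by roughly `1/(1 + rate × 8d)` —
  about 8% for the respiratory class.  Rate- and share-calibration
  checks therefore run with `min_spacing_days = 0` ("hard mode", the
  plain Poisson process), while exact-reconstruction checks run with the
  spacing on; each property is tested under the conditions that make it
  true, and the two settings are the same flag the generator exposes to
  users.
* **Unknown-febrile placement.** Unknown-febrile truths must sit more
  than `fever_search_days` from any code; conflicting draws are
  resampled (up to 100 attempts) rather than discarded, so the realized
  unknown-febrile rate stays near its configured value.

Noise processes append non-infectious codes (dropped at classification),
chronic-flagged codes (dropped before building, echoing the rare
chronic-section contamination of real diary data) and, optionally,
isolated fever answers.  What the generator does *not* emulate: reporting
compliance drift, family-level clustering beyond the covariates,
pathogen identity, code misassignment across categories, and
within-country site heterogeneity.  Passing reconstruction tests
therefore demonstrate the *protocol's* correctness on data matching its
assumptions, not robustness to real-world reporting behaviour — the
"hard mode" flag exists precisely to study behaviour when the
separability assumption fails.

## Problem sizes and numerical checks

The test suite verifies builder–reference equivalence on 1,300+
randomized report sets, exact end-to-end reconstruction at 2,000
children, parameter recovery over 200 replicates of 2,000 children
(mean log-rate-ratio within 3 Monte-Carlo standard errors; 95% CI
coverage within [91%, 99%]), and closed-form agreement of one-factor
fits with crude rate ratios to 1e-6 relative — sizes chosen to give
tight Monte-Carlo error while keeping the default run desk-scale.  The
acceptance script uses 500 reference sets, a 1,000-child reconstruction
cohort and a 2,000-child recovery cohort.

## Known limitations

* The default catalog is a reconstruction; analyses with an
  authoritative mapping must supply it.
* Fevers 6–7 days from a code are dropped by the two-window design;
  alternative window choices change unknown-febrile counts.
* Whether gastro-symptom absorption may bridge respiratory chains is
  unspecified in the verbal rule; the fixed-point implementation can
  extend spans, which is the more inclusive reading.
* The Poisson model ignores overdispersion and within-family
  correlation; rate-ratio point estimates are unbiased under the
  generator, but real-data standard errors would likely be anticonservative.
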