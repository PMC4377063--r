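# episodizer

Prospective birth cohorts that track early-childhood infections often rely
on parental diaries: between clinic visits, parents record symptoms,
diagnoses and fever, and study nurses translate the entries into ICD-10
codes.  A single infection routinely produces several such reports —
common cold one day, middle-ear infection two days later, fever alongside
— so counting raw code reports overestimates the number of microbial
exposures.  `episodizer` implements the full protocol for reducing such a
report stream into **time-bound infectious episodes** and for analysing
their incidence, aimed at epidemiologists working with diary- or
registry-based pediatric infection data.

The core data reduction classifies every ICD-10 code through an editable
category catalog and merges reports into four episode classes:

* **Respiratory** — respiratory-category codes reported with at most a
  5-day gap between successive reports form one episode; gastroenteritis
  *symptom* codes (nausea/vomiting) occurring alongside are absorbed into
  the respiratory episode rather than counted as gastrointestinal.
* **Gastrointestinal** — infective-gastroenteritis and unabsorbed
  gastro-symptom codes, chained with the same 5-day gap rule.
* **Other** — every remaining infection code is its own episode.
* **Unknown febrile** — fever reports with no infection code within a
  week before or after.

Fever reports within 5 days of an episode mark it febrile.  Incidence is
then analysed as episodes per person-year, stratified by age or season,
and modeled with a log-link Poisson regression with a `log(person-years)`
offset:

```
log E[count_i] = log(py_i) + beta_site + beta_sex + beta_FDR + beta_HLA
```

whose exponentiated coefficients are rate ratios with Wald 95% CIs and
per-factor Wald chi-square tests.

Because the cohort data this protocol was developed on are not public,
the package ships a seeded synthetic cohort generator
(nonhomogeneous-Poisson episode processes with age, season and covariate
effects, plus report emission and noise) with ground-truth labels, and an
exhaustive reference implementation of the merging rules, so every stage
is verifiable end to end.

## Worked example

```r
library(episodizer)

catalog <- load_catalog()                      # shipped default catalog
cfg <- sim_config(n_children = 50, seed = 42)  # synthetic cohort
sim <- simulate_cohort(cfg)

ext <- extract_infection_reports(sim$reports, catalog)
built <- build_episodes(ext$classified, sim$children)
built$summary$per_class
#>      episode_class   n share_pct febrile_pct rate
#> 1      RESPIRATORY 892 72.816327    45.40359   NA
#> 2 GASTROINTESTINAL 168 13.714286    45.23810   NA
#> 3            OTHER  78  6.367347    55.12821   NA
#> 4  UNKNOWN_FEBRILE  87  7.102041   100.00000   NA
```

2,003 infection reports were reduced to 1,225 episodes; about 73% are
respiratory and all unknown-febrile episodes are febrile by definition.
Comparing against the generator's ground truth:

```r
ev <- evaluate_reconstruction(sim$truth, built$episodes, sim$reports)
ev$count_ratio     # 1      — one built episode per true episode
ev$onset_mae_days  # 0      — onset dates recovered exactly
```

Rate ratios from a per-child count frame:

```r
frame <- aggregate_model_frame(built$episodes, sim$children, "all")
fit_poisson_rate_model(frame, factors = c("site", "sex"))
```

A command-line front end wraps the same functions
(`exec/episodizer <simulate|episodes|rates|model|all> --config cfg.yaml`);
an annotated config ships in `inst/extdata/example_config.yaml`.

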