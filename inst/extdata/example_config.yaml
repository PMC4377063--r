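# Annotated pipeline configuration.  Every entry shown with its default;
# omit a key to accept the default.
paths:
  # catalog: my_catalog.yaml        # omit for the shipped default catalog
  children: out/children.csv        # cohort roster (written by `simulate`)
  visits: out/visits.csv            # attendance table (optional for `episodes`)
  reports: out/reports.csv          # illness-report stream
  out_dir: out                      # where outputs and manifest.json go
episode_params:
  merge_gap_days: 5                 # max day gap chained into one episode
  fever_window_days: 5              # fever-to-episode attachment window
  fever_search_days: 7              # unknown-febrile lookaround window
rates:
  bin_months: 3                     # age-bin width for rates and reporting %
  split_febrile: true               # also write febrile / nonfebrile rows
model:
  factors: [site, sex, fdr, hla_group]
sim:
  seed: 1                           # mandatory for `simulate`
  n_children: 500
  # any sim_config() field may be set here, e.g.:
  # min_spacing_days: 8             # 0 = "hard mode" (overlapping truths)
  # report_spread_days: 2
  # noise_noninfectious_rate: 0.3   # per person-year
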