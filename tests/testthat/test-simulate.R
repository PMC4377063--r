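test_that("roster simulation respects config probabilities and the seed", {
  expect_equal(nrow(simulate_children(sim_config(0, seed = 1))$children), 0)
  cfg <- sim_config(n_children = 10000, seed = 5)
  a <- simulate_children(cfg)
  b <- simulate_children(cfg)
  expect_identical(a, b)
  # binomial check on sex at p = 0.5
  p_male <- mean(a$children$sex == "male")
  expect_lt(abs(p_male - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(a$children$followup_end - a$children$birth_date == 1461))
  expect_equal(nrow(a$visits), 10000 * 16)
  expect_error(sim_config(10, seed = 2, sex_probs = c(0.6, 0.6)),
               class = "config_error")
  expect_error(sim_config(10), class = "config_error")
  # generated tables pass the package's own readers unchanged
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(a$children[1:50, ], f1, row.names = FALSE)
  utils::write.csv(a$visits[1:800, ], f2, row.names = FALSE)
  expect_equal(nrow(read_children(f1)), 50)
  expect_equal(nrow(read_visits(f2)), 800)
})

test_that("true episode counts follow the configured intensity", {
  # flat age curve, no seasonality, no refractory spacing: plain Poisson
  cfg <- sim_config(
    n_children = 1000, seed = 9,
    base_rates = c(RESPIRATORY = 5.2, GASTROINTESTINAL = 0,
                   OTHER = 0, UNKNOWN_FEBRILE = 0),
    age_values = c(1, 1, 1, 1, 1),
    seasonal_amplitude = c(RESPIRATORY = 0, GASTROINTESTINAL = 0,
                           OTHER = 0, UNKNOWN_FEBRILE = 0),
    log_rr = list(site = c("US-Colorado" = 0, "US-Georgia" = 0,
                           "US-Washington" = 0, "Europe-Finland" = 0,
                           "Europe-Germany" = 0, "Europe-Sweden" = 0),
                  sex = c(female = 0, male = 0), fdr = c(no = 0, yes = 0),
                  hla_group = c("DR4-DQ8/DR4-DQ8" = 0,
                                "DR3-DQ2/DR4-DQ8" = 0,
                                "DR4-DQ8/DR8-DQ4" = 0,
                                "DR3-DQ2/DR3-DQ2" = 0,
                                "HLA-FDR-specific" = 0)),
    min_spacing_days = 0)
  roster <- simulate_children(cfg)
  truth <- simulate_true_episodes(roster, cfg)
  per_child <- table(factor(truth$child_id,
                            levels = roster$children$child_id))
  m <- mean(per_child)
  se <- sd(per_child) / sqrt(length(per_child))
  expect_lt(abs(m - 20.8), 3 * se)
  # no seasonal amplitude: monthly counts flat up to month length and
  # sampling noise
  mo <- as.integer(format(truth$true_onset_date, "%m"))
  month_days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  gof <- suppressWarnings(chisq.test(tabulate(mo, 12),
                                     p = month_days / sum(month_days)))
  expect_gt(gof$p.value, 0.001)
  # zero rates -> zero episodes
  cfg0 <- sim_config(n_children = 50, seed = 9,
                     base_rates = c(RESPIRATORY = 0, GASTROINTESTINAL = 0,
                                    OTHER = 0, UNKNOWN_FEBRILE = 0))
  expect_equal(nrow(simulate_true_episodes(simulate_children(cfg0), cfg0)),
               0)
})

test_that("report emission matches the configured per-episode distribution", {
  catalog <- load_catalog()
  cfg <- sim_config(n_children = 400, seed = 13,
                    noise_noninfectious_rate = 0, noise_chronic_rate = 0,
                    standalone_fever_prob = 0)
  roster <- simulate_children(cfg)
  truth <- simulate_true_episodes(roster, cfg)
  em <- emit_reports(truth, roster, catalog, cfg)
  # reports validate under the package's reader
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(em$reports, f, row.names = FALSE)
  expect_equal(nrow(read_reports(f)), nrow(em$reports))

  # mean reports per respiratory/gastro episode ~ 1.6
  multi <- truth$true_class %in% c("RESPIRATORY", "GASTROINTESTINAL")
  k <- lengths(strsplit(em$truth$report_ids[multi], ";"))
  mu <- sum(1:5 * cfg$reports_per_episode_probs)
  expect_lt(abs(mean(k) - mu), 3 * sd(k) / sqrt(length(k)))

  # emission support: GI episodes never emit respiratory-category codes
  cls <- classify_code(catalog, em$reports$icd10_code[
    !is.na(em$reports$icd10_code)])
  lookup <- setNames(cls$episode_class, em$reports$report_id[
    !is.na(em$reports$icd10_code)])
  gi_ids <- unlist(strsplit(em$truth$report_ids[
    em$truth$true_class == "GASTROINTESTINAL"], ";"))
  gi_cls <- lookup[intersect(gi_ids, names(lookup))]
  expect_true(all(gi_cls %in% c("GASTROINTESTINAL", "GI_SYMPTOM")))

  # degenerate single-report emission: one report per coded truth
  cfg1 <- sim_config(n_children = 100, seed = 14,
                     reports_per_episode_probs = c(1, 0, 0, 0, 0),
                     noise_noninfectious_rate = 0, noise_chronic_rate = 0,
                     standalone_fever_prob = 0)
  roster1 <- simulate_children(cfg1)
  truth1 <- simulate_true_episodes(roster1, cfg1)
  em1 <- emit_reports(truth1, roster1, catalog, cfg1)
  expect_equal(nrow(em1$reports), nrow(truth1))
})

test_that("separable simulations reconstruct exactly; evaluation is honest", {
  catalog <- load_catalog()
  cfg <- sim_config(n_children = 300, seed = 21,
                    noise_noninfectious_rate = 0, noise_chronic_rate = 0)
  sim <- simulate_cohort(cfg)
  ext <- extract_infection_reports(sim$reports, catalog)
  built <- build_episodes(ext$classified, sim$children)
  ev <- evaluate_reconstruction(sim$truth, built$episodes, sim$reports)
  expect_equal(ev$count_ratio, 1)
  expect_equal(ev$onset_mae_days, 0)
  off_diag <- sum(ev$confusion) - sum(diag(ev$confusion[, 1:4]))
  expect_equal(off_diag, 0)
  expect_gt(ev$febrile_accuracy, 0.98)

  # empty inputs give zero metrics
  ev0 <- evaluate_reconstruction(sim$truth[0, ], built$episodes[0, ])
  expect_equal(ev0$count_ratio, 0)
  expect_equal(sum(ev0$confusion), 0)

  # noise-born episodes are counted as unmatched built episodes
  cfgn <- sim_config(n_children = 300, seed = 21,
                     noise_noninfectious_rate = 0, noise_chronic_rate = 0,
                     noise_fever_rate = 0.2)
  simn <- simulate_cohort(cfgn)
  extn <- extract_infection_reports(simn$reports, catalog)
  builtn <- build_episodes(extn$classified, simn$children)
  evn <- evaluate_reconstruction(simn$truth, builtn$episodes, simn$reports)
  expect_gt(evn$n_unmatched_built, 0)
})
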