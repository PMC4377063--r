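#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a large multinational birth
#' cohort followed three-monthly to age four: site mix proportional to the
#' published cohort composition, overall episode rate about 5.2 per
#' person-year split 3.8 / 0.7 / 0.3 / 0.4 across respiratory /
#' gastrointestinal / other / unknown-febrile classes at reference
#' covariates, an age profile peaking at 6--9 months and declining after
#' 18 months, a winter-peaked seasonal sinusoid on the respiratory and
#' gastrointestinal classes, covariate rate ratios matching the published
#' panel-A estimates, about 1.6 reports per respiratory or
#' gastrointestinal episode, and per-class febrile fractions of
#' 41.5 / 36.6 / 54 / 100 percent.
#'
#' `min_spacing_days` (default 8) is a refractory gap between same-class
#' true episodes of one child that makes ground truth separable under the
#' 5-day merging rule; setting it to 0 is the "hard mode" in which true
#' episodes may overlap and merge.  `report_spread_days` (default 2,
#' support 0..5) bounds within-episode report offsets; separability
#' requires `min_spacing_days > report_spread_days + merge_gap_days`.
#'
#' @param n_children Number of children to simulate.
#' @param seed Mandatory integer seed; every stage derives its own
#'   sub-stream from it.
#' @param ... Overrides for any default field (see the vignette for the
#'   full field list and units).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_children = 500L, seed, ...) {
  if (missing(seed)) stop_input("sim_config: seed is mandatory",
                                class = "config_error")
  cfg <- list(
    n_children = as.integer(n_children),
    seed = as.integer(seed),
    birth_window = as.Date(c("2005-01-01", "2008-12-31")),
    site_probs = c("US-Colorado" = 545, "US-Georgia" = 285,
                   "US-Washington" = 383, "Europe-Finland" = 815,
                   "Europe-Germany" = 164, "Europe-Sweden" = 1271) / 3463,
    sex_probs = c(female = 0.5, male = 0.5),
    fdr_prob = 385 / 3463,
    hla_probs = c("DR4-DQ8/DR4-DQ8" = 0.20, "DR3-DQ2/DR4-DQ8" = 0.39,
                  "DR4-DQ8/DR8-DQ4" = 0.19, "DR3-DQ2/DR3-DQ2" = 0.17,
                  "HLA-FDR-specific" = 0.05),
    base_rates = c(RESPIRATORY = 3.8, GASTROINTESTINAL = 0.7,
                   OTHER = 0.3, UNKNOWN_FEBRILE = 0.4),
    age_knots_months = c(0, 6, 9, 18, 48),
    age_values = c(0.55, 1.35, 1.40, 1.25, 0.55),
    seasonal_amplitude = c(RESPIRATORY = 0.35, GASTROINTESTINAL = 0.25,
                           OTHER = 0, UNKNOWN_FEBRILE = 0),
    log_rr = list(
      site = log(c("US-Colorado" = 1, "US-Georgia" = 1.18,
                   "US-Washington" = 1.05, "Europe-Finland" = 1.50,
                   "Europe-Germany" = 1.40, "Europe-Sweden" = 1.42)),
      sex = log(c(female = 1, male = 1.04)),
      fdr = log(c(no = 1, yes = 1.01)),
      hla_group = log(c("DR4-DQ8/DR4-DQ8" = 1, "DR3-DQ2/DR4-DQ8" = 1.02,
                        "DR4-DQ8/DR8-DQ4" = 0.97,
                        "DR3-DQ2/DR3-DQ2" = 0.99,
                        "HLA-FDR-specific" = 0.98))),
    reports_per_episode_probs = c(0.62, 0.23, 0.10, 0.03, 0.02),
    report_spread_days = 2L,
    min_spacing_days = 8L,
    fever_probs = c(RESPIRATORY = 0.415, GASTROINTESTINAL = 0.366,
                    OTHER = 0.54, UNKNOWN_FEBRILE = 1),
    standalone_fever_prob = 0.3,
    uf_yes_only_prob = 285 / 5141,
    gi_symptom_share = 0,
    noise_noninfectious_rate = 0.3,
    noise_chronic_rate = 0.01,
    noise_fever_rate = 0,
    censor_prob = 0,
    miss_visit_prob = 0.02,
    professional_dx_prob = 0.7)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_input("sim_config: unknown fields ",
               paste(unknown, collapse = ", "), class = "config_error")
  }
  cfg[names(dots)] <- dots
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_input("sim_config: ", what,
                 " must be nonnegative and sum to 1", class = "config_error")
    }
  }
  check_probs(cfg$site_probs, "site_probs")
  check_probs(cfg$sex_probs, "sex_probs")
  check_probs(cfg$hla_probs, "hla_probs")
  check_probs(cfg$reports_per_episode_probs, "reports_per_episode_probs")
  for (p in c("fdr_prob", "standalone_fever_prob", "uf_yes_only_prob",
              "gi_symptom_share", "censor_prob", "miss_visit_prob",
              "professional_dx_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_input("sim_config: ", p, " must be in [0, 1]",
                 class = "config_error")
    }
  }
  if (any(cfg$base_rates < 0) || any(cfg$seasonal_amplitude < 0) ||
      any(cfg$seasonal_amplitude >= 1)) {
    stop_input("sim_config: rates must be >= 0 and amplitudes in [0, 1)",
               class = "config_error")
  }
  if (any(cfg$fever_probs < 0 | cfg$fever_probs > 1)) {
    stop_input("sim_config: fever_probs must be probabilities",
               class = "config_error")
  }
  if (cfg$report_spread_days < 0 || cfg$report_spread_days > 5) {
    stop_input("sim_config: report_spread_days must be in 0..5",
               class = "config_error")
  }
  cfg
}

# Relative hazard by age: piecewise log-linear over the configured knots,
# normalized so its average over 0-48 months is 1 (base rates then read as
# marginal per-person-year rates at reference covariates).
age_multiplier <- function(age_m, cfg) {
  f <- stats::approxfun(cfg$age_knots_months, log(cfg$age_values),
                        rule = 2)
  grid <- seq(0, 48, by = 0.1)
  norm <- mean(exp(f(grid)))
  exp(f(age_m)) / norm
}

season_multiplier <- function(dates, amplitude) {
  doy <- as.integer(format(dates, "%j"))
  1 + amplitude * cos(2 * pi * (doy - 15) / DAYS_PER_YEAR)
}

child_log_rr <- function(children, cfg) {
  cfg$log_rr$site[children$site] + cfg$log_rr$sex[children$sex] +
    cfg$log_rr$fdr[children$fdr] + cfg$log_rr$hla_group[children$hla_group]
}

#' Simulate a cohort roster with visit attendance
#'
#' Demographic levels are drawn from the configured probabilities; birth
#' dates are uniform over the configured calendar window; follow-up runs
#' from birth (the diary records illnesses from birth) to 48 months unless
#' censored.  Attendance at the 3-monthly visits is Bernoulli with the
#' configured miss probability; visits scheduled after a censored child's
#' follow-up end are unattended.
#'
#' @param config A [sim_config()].
#' @return list with `children` and `visits` data.frames.
#' @export
simulate_children <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_children
  if (n == 0) {
    return(list(children = read_children_empty(), visits = data.frame(
      child_id = character(0), scheduled_age_months = integer(0),
      attended = logical(0))))
  }
  span <- as.integer(diff(config$birth_window))
  birth <- config$birth_window[1] + sample.int(span + 1L, n, TRUE) - 1L
  children <- data.frame(
    child_id = sprintf("C%05d", seq_len(n)),
    birth_date = birth,
    site = sample(names(config$site_probs), n, TRUE, config$site_probs),
    sex = sample(names(config$sex_probs), n, TRUE, config$sex_probs),
    fdr = ifelse(stats::rbinom(n, 1, config$fdr_prob) == 1, "yes", "no"),
    hla_group = sample(names(config$hla_probs), n, TRUE, config$hla_probs),
    followup_start = birth,
    stringsAsFactors = FALSE)
  end_days <- rep(FOLLOWUP_CAP_DAYS, n)
  cens <- stats::rbinom(n, 1, config$censor_prob) == 1
  end_days[cens] <- sample(183:(FOLLOWUP_CAP_DAYS - 1), sum(cens), TRUE)
  children$followup_end <- birth + end_days
  ages <- seq(3L, 48L, by = 3L)
  visits <- data.frame(
    child_id = rep(children$child_id, each = length(ages)),
    scheduled_age_months = rep(ages, n), stringsAsFactors = FALSE)
  visit_day <- visits$scheduled_age_months * DAYS_PER_MONTH
  visits$attended <- stats::rbinom(nrow(visits), 1,
                                   1 - config$miss_visit_prob) == 1 &
    visit_day <= rep(end_days, each = length(ages))
  list(children = children, visits = visits)
}

read_children_empty <- function() {
  data.frame(child_id = character(0), birth_date = as.Date(character(0)),
             site = character(0), sex = character(0), fdr = character(0),
             hla_group = character(0),
             followup_start = as.Date(character(0)),
             followup_end = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth infectious episodes
#'
#' Per child and episode class, a nonhomogeneous Poisson process with
#' intensity `base_rate x age-profile x season-factor x exp(covariate
#' log-rate-ratios)` is simulated by thinning over the (48-month-capped)
#' follow-up window.  Same-class events closer than `min_spacing_days` are
#' then thinned greedily (earliest kept), giving the refractory spacing
#' that makes truth separable; unknown-febrile events falling too close to
#' any coded event of the same child (within `fever_search + spread + 1`
#' days) are resampled by repeated thinning draws and dropped after 100
#' failed attempts.
#'
#' @param roster Output of [simulate_children()] (the `children` element or
#'   the full list).
#' @param config A [sim_config()].
#' @return data.frame of true episodes: `true_id`, `child_id`,
#'   `true_class`, `true_onset_date`, `febrile_truth`.
#' @export
simulate_true_episodes <- function(roster, config) {
  stopifnot(inherits(config, "sim_config"))
  children <- if (is.data.frame(roster)) roster else roster$children
  set.seed(stage_seed(config$seed, 2L))
  n <- nrow(children)
  empty <- data.frame(true_id = character(0), child_id = character(0),
                      true_class = character(0),
                      true_onset_date = as.Date(character(0)),
                      febrile_truth = logical(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  T_days <- followup_days_capped(children)
  lp <- child_log_rr(children, config)
  max_age <- max(age_multiplier(seq(0, 48, by = 0.1), config))

  draw_class <- function(cl) {
    base <- config$base_rates[[cl]]
    if (base <= 0) return(NULL)
    A <- config$seasonal_amplitude[[cl]]
    lam_max <- base * max_age * (1 + A) * exp(lp) / DAYS_PER_YEAR # per day
    N <- stats::rpois(n, lam_max * T_days)
    if (sum(N) == 0) return(NULL)
    ci <- rep(seq_len(n), N)
    t_day <- stats::runif(sum(N), 0, T_days[ci])
    date <- children$birth_date[ci] + floor(t_day)
    lam <- base * age_multiplier(t_day / DAYS_PER_MONTH, config) *
      season_multiplier(date, A) * exp(lp[ci]) / DAYS_PER_YEAR
    keep <- stats::runif(sum(N)) < lam / lam_max[ci]
    data.frame(child = ci[keep], day = floor(t_day[keep]),
               stringsAsFactors = FALSE)
  }

  enforce_spacing <- function(df) {
    if (is.null(df) || nrow(df) == 0 || config$min_spacing_days <= 0) {
      return(df)
    }
    df <- df[order(df$child, df$day), , drop = FALSE]
    keep <- logical(nrow(df))
    last_child <- -1L
    last_day <- -Inf
    for (i in seq_len(nrow(df))) {
      if (df$child[i] != last_child ||
          df$day[i] - last_day >= config$min_spacing_days) {
        keep[i] <- TRUE
        last_child <- df$child[i]
        last_day <- df$day[i]
      }
    }
    df[keep, , drop = FALSE]
  }

  coded_events <- list()
  for (cl in c("RESPIRATORY", "GASTROINTESTINAL", "OTHER")) {
    df <- enforce_spacing(draw_class(cl))
    if (!is.null(df) && nrow(df)) {
      df$true_class <- cl
      coded_events[[cl]] <- df
    }
  }
  coded <- do.call(rbind, coded_events)

  uf <- enforce_spacing(draw_class("UNKNOWN_FEBRILE"))
  if (!is.null(uf) && nrow(uf)) {
    margin <- 7 + config$report_spread_days + 1
    coded_days_by_child <- if (!is.null(coded)) {
      split(coded$day, coded$child)
    } else list()
    ok <- function(child, day) {
      cd <- coded_days_by_child[[as.character(child)]]
      is.null(cd) || all(abs(cd - day) >= margin)
    }
    keep <- logical(nrow(uf))
    for (i in seq_len(nrow(uf))) {
      child <- uf$child[i]
      day <- uf$day[i]
      tries <- 0L
      while (!ok(child, day) && tries < 100L) {
        day <- floor(stats::runif(1, 0, T_days[child]))
        tries <- tries + 1L
      }
      uf$day[i] <- day
      keep[i] <- ok(child, day)
    }
    uf <- enforce_spacing(uf[keep, , drop = FALSE])
    if (nrow(uf)) uf$true_class <- "UNKNOWN_FEBRILE"
  }
  events <- rbind(coded, if (!is.null(uf) && nrow(uf)) uf)
  if (is.null(events) || nrow(events) == 0) return(empty)

  events$child_id <- children$child_id[events$child]
  events$true_onset_date <- children$birth_date[events$child] + events$day
  events <- events[order(events$child_id, events$true_onset_date,
                         events$true_class), , drop = FALSE]
  events$febrile_truth <- stats::runif(nrow(events)) <
    config$fever_probs[events$true_class]
  data.frame(true_id = sprintf("T%06d", seq_len(nrow(events))),
             child_id = events$child_id, true_class = events$true_class,
             true_onset_date = events$true_onset_date,
             febrile_truth = events$febrile_truth,
             stringsAsFactors = FALSE)
}

#' Emit a parental report stream from true episodes
#'
#' Each respiratory or gastrointestinal truth emits 1--5 code reports
#' (configured distribution, mean about 1.6); other-class truths emit
#' exactly one (the protocol counts every such code as its own episode, so
#' a single code keeps truth and reconstruction in one-to-one
#' correspondence).  The first report sits on the onset date, the rest at
#' uniform offsets within `report_spread_days`.  Codes are drawn uniformly
#' from the catalog prefixes of the truth's class (gastrointestinal truths
#' draw gastroenteritis-symptom codes with probability
#' `gi_symptom_share`, default 0).  Febrile truths set the fever flag on
#' their first report and additionally emit a standalone "yes"-fever
#' answer with probability `standalone_fever_prob`; unknown-febrile truths
#' emit a single fever report, coded as the fever symptom except with
#' probability `uf_yes_only_prob` (a code-free "yes" answer).  Poisson
#' noise processes append non-infectious codes, chronic-flagged codes and
#' (optionally) isolated fever answers.
#'
#' @param truth Output of [simulate_true_episodes()].
#' @param roster Roster (`children` data.frame or the [simulate_children()]
#'   list) — needed for the per-child noise processes.
#' @param catalog An `infection_catalog` covering all generated classes.
#' @param config A [sim_config()].
#' @return list with `reports` (validating under [read_reports()]'s
#'   schema) and `truth` with a `report_ids` column (semicolon-joined).
#' @export
emit_reports <- function(truth, roster, catalog, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(catalog, "infection_catalog"))
  children <- if (is.data.frame(roster)) roster else roster$children
  set.seed(stage_seed(config$seed, 3L))
  pool <- split(catalog$patterns$pattern, catalog$patterns$episode_class)
  for (cl in c("RESPIRATORY", "GASTROINTESTINAL", "OTHER")) {
    if (any(truth$true_class == cl) && !length(pool[[cl]])) {
      stop_input("catalog has no codes for generated class ", cl,
                 class = "config_error")
    }
  }
  spread <- config$report_spread_days
  nt <- nrow(truth)
  rows <- list()
  truth$report_ids <- rep("", max(nt, 0))

  if (nt > 0) {
    multi <- truth$true_class %in% c("RESPIRATORY", "GASTROINTESTINAL")
    K <- rep(1L, nt)
    if (any(multi)) {
      K[multi] <- sample(seq_along(config$reports_per_episode_probs),
                         sum(multi), TRUE,
                         config$reports_per_episode_probs)
    }
    is_uf <- truth$true_class == "UNKNOWN_FEBRILE"
    idx <- rep(seq_len(nt), K)
    first <- !duplicated(idx)
    offs <- ifelse(first, 0L, sample(0:max(spread, 0), length(idx), TRUE))
    code <- character(length(idx))
    for (cl in c("RESPIRATORY", "OTHER")) {
      sel <- truth$true_class[idx] == cl
      if (any(sel)) code[sel] <- sample(pool[[cl]], sum(sel), TRUE)
    }
    sel <- truth$true_class[idx] == "GASTROINTESTINAL"
    if (any(sel)) {
      use8 <- stats::runif(sum(sel)) < config$gi_symptom_share &
        length(pool[["GI_SYMPTOM"]]) > 0
      g <- character(sum(sel))
      if (any(!use8)) {
        g[!use8] <- sample(pool[["GASTROINTESTINAL"]], sum(!use8), TRUE)
      }
      if (any(use8)) g[use8] <- sample(pool[["GI_SYMPTOM"]], sum(use8), TRUE)
      code[sel] <- g
    }
    sel <- is_uf[idx]
    if (any(sel)) {
      yes_only <- stats::runif(sum(sel)) < config$uf_yes_only_prob
      code[sel] <- ifelse(yes_only, NA_character_, "R50")
    }
    fever <- (first & truth$febrile_truth[idx] & !is_uf[idx]) | is_uf[idx]
    rows[["episodes"]] <- data.frame(
      truth_idx = idx,
      child_id = truth$child_id[idx],
      onset_date = truth$true_onset_date[idx] + offs,
      icd10_code = code, fever_flag = fever, chronic_flag = FALSE,
      stringsAsFactors = FALSE)

    extra <- which(!is_uf & truth$febrile_truth &
                     stats::runif(nt) < config$standalone_fever_prob)
    if (length(extra)) {
      rows[["standalone"]] <- data.frame(
        truth_idx = extra,
        child_id = truth$child_id[extra],
        onset_date = truth$true_onset_date[extra] +
          sample(0:max(spread, 0), length(extra), TRUE),
        icd10_code = NA_character_, fever_flag = TRUE,
        chronic_flag = FALSE, stringsAsFactors = FALSE)
    }
  }

  # noise processes: per-child Poisson counts over follow-up
  T_years <- followup_days_capped(children) / DAYS_PER_YEAR
  noise_rows <- function(rate, codes, fever, chronic) {
    N <- stats::rpois(nrow(children), rate * T_years)
    if (sum(N) == 0) return(NULL)
    ci <- rep(seq_len(nrow(children)), N)
    data.frame(
      truth_idx = NA_integer_,
      child_id = children$child_id[ci],
      onset_date = children$birth_date[ci] +
        floor(stats::runif(sum(N), 0,
                           rep(followup_days_capped(children), N))),
      icd10_code = if (is.null(codes)) NA_character_
                   else sample(codes, sum(N), TRUE),
      fever_flag = fever, chronic_flag = chronic, stringsAsFactors = FALSE)
  }
  if (nrow(children)) {
    rows[["noninfectious"]] <- noise_rows(config$noise_noninfectious_rate,
                                          c("Z00", "Z23", "R05", "S000"),
                                          FALSE, FALSE)
    rows[["chronic"]] <- noise_rows(config$noise_chronic_rate,
                                    c("H663", "H664", "B181"), FALSE, TRUE)
    rows[["fevernoise"]] <- noise_rows(config$noise_fever_rate, NULL,
                                       TRUE, FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    reports <- data.frame(report_id = character(0), child_id = character(0),
                          onset_date = as.Date(character(0)),
                          icd10_code = character(0), fever_flag = logical(0),
                          chronic_flag = logical(0),
                          professional_dx = logical(0),
                          stringsAsFactors = FALSE)
    return(list(reports = reports, truth = truth))
  }
  all_rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  all_rows$report_id <- sprintf("R%07d", seq_len(nrow(all_rows)))
  all_rows$professional_dx <- !is.na(all_rows$icd10_code) &
    stats::runif(nrow(all_rows)) < config$professional_dx_prob

  if (nt > 0) {
    by_truth <- split(all_rows$report_id, all_rows$truth_idx)
    got <- as.integer(names(by_truth))
    truth$report_ids[got] <- vapply(by_truth, paste, "", collapse = ";")
  }
  ord <- order(all_rows$child_id, all_rows$onset_date, all_rows$report_id)
  reports <- all_rows[ord, c("report_id", "child_id", "onset_date",
                             "icd10_code", "fever_flag", "chronic_flag",
                             "professional_dx")]
  rownames(reports) <- NULL
  list(reports = reports, truth = truth)
}

#' Simulate a complete cohort: roster, visits, reports and truth
#'
#' Convenience wrapper chaining [simulate_children()],
#' [simulate_true_episodes()] and [emit_reports()] under one seed.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog used for code emission (default: shipped
#'   default).
#' @return list with `children`, `visits`, `reports`, `truth`, `config`.
#' @export
simulate_cohort <- function(config, catalog = load_catalog()) {
  roster <- simulate_children(config)
  truth <- simulate_true_episodes(roster, config)
  emitted <- emit_reports(truth, roster, catalog, config)
  list(children = roster$children, visits = roster$visits,
       reports = emitted$reports, truth = emitted$truth, config = config)
}

#' Simulate per-child episode counts at the model level
#'
#' Draws each child's total episode count directly from the Poisson
#' distribution implied by the generator's intensity aggregated over
#' follow-up: mean `sum(base_rates) x person_years x exp(covariate
#' log-rate-ratios)` (the normalized age profile integrates to one over a
#' full follow-up).  This is the count distribution the rate-ratio
#' regression models, and is the workhorse of parameter-recovery checks.
#'
#' @param children Roster data.frame.
#' @param config A [sim_config()].
#' @param rep_seed Optional seed override for replicate loops.
#' @return Model frame as from [aggregate_model_frame()].
#' @export
simulate_episode_counts <- function(children, config, rep_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(rep_seed %||% stage_seed(config$seed, 4L))
  py <- followup_days_capped(children) / DAYS_PER_YEAR
  mu <- sum(config$base_rates) * py * exp(child_log_rr(children, config))
  data.frame(child_id = children$child_id,
             count = stats::rpois(nrow(children), mu),
             person_years = py, site = children$site, sex = children$sex,
             fdr = children$fdr, hla_group = children$hla_group,
             stringsAsFactors = FALSE)
}
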