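followup_days_capped <- function(children) {
  pmin(as.numeric(children$followup_end - children$birth_date),
       FOLLOWUP_CAP_DAYS)
}

#' Person-time at risk by age bin
#'
#' Each child contributes the overlap of `[birth, min(followup_end,
#' 48 months))` with each age bin, in 365.25-day years.  Person-time runs
#' from birth regardless of missed visits (eligibility already requires no
#' two consecutive misses, and the protocol counts full follow-up time).
#' Age-bin boundaries use the fixed 30.4375-day month.
#'
#' @param children Roster data.frame.
#' @param bin_months Bin width in months; must divide 48.
#' @return data.frame with `age_bin_start_months`, `age_bin_end_months`,
#'   `person_years`.
#' @export
person_time <- function(children, bin_months = 3L) {
  if (48 %% bin_months != 0) stop_input("bin_months must divide 48")
  starts <- seq(0, 48 - bin_months, by = bin_months)
  if (nrow(children) == 0) {
    return(data.frame(age_bin_start_months = numeric(0),
                      age_bin_end_months = numeric(0),
                      person_years = numeric(0)))
  }
  fup <- followup_days_capped(children)
  py <- vapply(starts, function(s) {
    lo <- s * DAYS_PER_MONTH
    hi <- (s + bin_months) * DAYS_PER_MONTH
    sum(pmax(0, pmin(fup, hi) - lo)) / DAYS_PER_YEAR
  }, numeric(1))
  data.frame(age_bin_start_months = starts,
             age_bin_end_months = starts + bin_months,
             person_years = py)
}

check_episodes_in_followup <- function(episodes, children) {
  idx <- match(episodes$child_id, children$child_id)
  if (anyNA(idx)) {
    stop_input("episode refers to unrostered child '",
               episodes$child_id[which(is.na(idx))[1]], "'",
               class = "contract_error")
  }
  birth <- children$birth_date[idx]
  endd <- children$followup_end[idx]
  bad <- which(episodes$onset_date < birth | episodes$onset_date > endd)
  if (length(bad)) {
    stop_input("episode ", episodes$episode_id[bad[1]],
               " has onset outside the child's follow-up window",
               class = "contract_error")
  }
  invisible(idx)
}

calendar_month_person_years <- function(children) {
  py <- numeric(12)
  for (i in seq_len(nrow(children))) {
    birth <- children$birth_date[i]
    endd <- birth + followup_days_capped(children[i, , drop = FALSE])
    first <- as.Date(format(birth, "%Y-%m-01"))
    bounds <- seq(first, by = "month", length.out =
                    ceiling(as.numeric(endd - first) / 28) + 2)
    for (k in seq_len(length(bounds) - 1)) {
      ov <- as.numeric(min(endd, bounds[k + 1]) - max(birth, bounds[k]))
      if (ov > 0) {
        m <- as.integer(format(bounds[k], "%m"))
        py[m] <- py[m] + ov / DAYS_PER_YEAR
      }
    }
  }
  py
}

#' Episode incidence rates by stratum
#'
#' Rates are episodes per person-year.  An episode belongs to the stratum
#' containing its onset date: age at onset for age bins, the onset's
#' calendar month for monthly/seasonal stratifications.  Denominators are
#' the person-years each child spends in the stratum (age-bin overlap, or
#' calendar-month overlap of the follow-up window).  Seasons are Dec-Feb /
#' Mar-May / Jun-Aug / Sep-Nov.
#'
#' @param episodes Episode table.
#' @param children Roster data.frame.
#' @param stratify_by `"age_bin"`, `"calendar_month"` or `"season"`.
#' @param split_febrile Also emit febrile-only and nonfebrile-only rows?
#' @param bin_months Age-bin width when `stratify_by = "age_bin"`.
#' @return data.frame with `stratum`, `episode_class` (per class plus
#'   `"ALL"`), `febrile` (`"all"`, and with `split_febrile` also
#'   `"febrile"`/`"nonfebrile"`), `n_episodes`, `person_years`, `rate`.
#' @export
episode_rates <- function(episodes, children,
                          stratify_by = c("age_bin", "calendar_month",
                                          "season"),
                          split_febrile = FALSE, bin_months = 3L) {
  stratify_by <- match.arg(stratify_by)
  idx <- check_episodes_in_followup(episodes, children)
  if (stratify_by == "age_bin") {
    pt <- person_time(children, bin_months)
    strata <- pt$age_bin_start_months
    person_years <- pt$person_years
    age_m <- age_months(episodes$onset_date, children$birth_date[idx])
    ep_stratum <- pmin(floor(age_m / bin_months) * bin_months,
                       48 - bin_months)
  } else {
    monthly <- calendar_month_person_years(children)
    ep_month <- as.integer(format(episodes$onset_date, "%m"))
    if (stratify_by == "calendar_month") {
      strata <- 1:12
      person_years <- monthly
      ep_stratum <- ep_month
    } else {
      strata <- SEASON_LEVELS
      person_years <- vapply(SEASON_LEVELS, function(s) {
        sum(monthly[which(as.character(month_to_season(1:12)) == s)])
      }, numeric(1))
      ep_stratum <- as.character(month_to_season(ep_month))
    }
  }
  groups <- if (split_febrile) c("all", "febrile", "nonfebrile") else "all"
  classes <- c("ALL", EPISODE_CLASSES)
  rows <- list()
  for (g in groups) {
    sel <- switch(g, all = rep(TRUE, nrow(episodes)),
                  febrile = episodes$febrile,
                  nonfebrile = !episodes$febrile)
    for (cl in classes) {
      cl_sel <- sel & (cl == "ALL" | episodes$episode_class == cl)
      n <- vapply(strata, function(s) sum(cl_sel & ep_stratum == s), 0)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = strata, episode_class = cl, febrile = g,
        n_episodes = as.integer(n), person_years = person_years,
        rate = ifelse(person_years > 0, n / person_years, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent of children reporting an episode, per 3-month age bin
#'
#' For each age bin the denominator is the number of children under
#' follow-up for the entire bin (follow-up covering the bin on both ends);
#' the numerator counts children with at least one episode onset in the
#' bin.
#'
#' @param episodes Episode table.
#' @param children Roster data.frame.
#' @param bin_months Bin width in months (default 3).
#' @return data.frame with `age_bin_start_months`, `age_bin_end_months`,
#'   `n_children`, `n_reporting`, `percent`.
#' @export
percent_reporting <- function(episodes, children, bin_months = 3L) {
  if (48 %% bin_months != 0) stop_input("bin_months must divide 48")
  starts <- seq(0, 48 - bin_months, by = bin_months)
  idx <- if (nrow(episodes)) check_episodes_in_followup(episodes, children)
         else integer(0)
  age_m <- if (nrow(episodes)) {
    age_months(episodes$onset_date, children$birth_date[idx])
  } else numeric(0)
  start_off <- as.numeric(children$followup_start - children$birth_date)
  fup <- followup_days_capped(children)
  out <- lapply(starts, function(s) {
    lo <- s * DAYS_PER_MONTH
    hi <- (s + bin_months) * DAYS_PER_MONTH
    denom_ids <- children$child_id[start_off <= lo & fup >= hi]
    in_bin <- age_m >= s & age_m < s + bin_months
    num <- length(intersect(unique(episodes$child_id[in_bin]), denom_ids))
    data.frame(age_bin_start_months = s,
               age_bin_end_months = s + bin_months,
               n_children = length(denom_ids), n_reporting = num,
               percent = if (length(denom_ids)) 100 * num /
                 length(denom_ids) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-child model frame for rate-ratio regression
#'
#' One row per rostered child: episode count under the requested febrile
#' filter, exact person-years (birth to capped follow-up end), and the
#' modeled covariates.
#'
#' @param episodes Episode table.
#' @param children Roster data.frame.
#' @param febrile_filter `"all"`, `"febrile"` or `"nonfebrile"`.
#' @return data.frame with `child_id`, `count`, `person_years`, `site`,
#'   `sex`, `fdr`, `hla_group`.
#' @export
aggregate_model_frame <- function(episodes, children,
                                  febrile_filter = c("all", "febrile",
                                                     "nonfebrile")) {
  febrile_filter <- match.arg(febrile_filter)
  if (nrow(episodes)) check_episodes_in_followup(episodes, children)
  sel <- switch(febrile_filter,
                all = rep(TRUE, nrow(episodes)),
                febrile = episodes$febrile,
                nonfebrile = !episodes$febrile)
  counts <- table(factor(episodes$child_id[sel],
                         levels = children$child_id))
  data.frame(child_id = children$child_id,
             count = as.integer(counts[children$child_id]),
             person_years = followup_days_capped(children) / DAYS_PER_YEAR,
             site = children$site, sex = children$sex, fdr = children$fdr,
             hla_group = children$hla_group, stringsAsFactors = FALSE)
}
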