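read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop_input("input file not found: ", path, class = "io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input(path, ": missing columns ", paste(missing, collapse = ", "),
               class = "schema_error")
  }
  df
}

parse_date_col <- function(x, path, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop_input(path, " row ", bad[1], ": column ", col,
               " is not an ISO-8601 date ('", x[bad[1]], "')",
               class = "validation_error")
  }
  d
}

parse_logical_col <- function(x) {
  tolower(trimws(x)) %in% c("true", "t", "1", "yes")
}

#' Read a cohort roster
#'
#' Expects `children.csv` columns `child_id, birth_date, site, sex, fdr,
#' hla_group, followup_start, followup_end`.  Levels of `site`, `sex`,
#' `fdr` and `hla_group` are validated against the study's factor levels;
#' dates must satisfy `birth_date <= followup_start < followup_end`, with
#' follow-up capped at 48 months for the four-year analysis.  All
#' validation failures name the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of child records, one row per child.
#' @export
read_children <- function(path) {
  df <- read_csv_checked(path, c("child_id", "birth_date", "site", "sex",
                                 "fdr", "hla_group", "followup_start",
                                 "followup_end"))
  out <- data.frame(child_id = df$child_id, stringsAsFactors = FALSE)
  out$birth_date <- parse_date_col(df$birth_date, path, "birth_date")
  levels_map <- list(site = SITE_LEVELS, sex = SEX_LEVELS, fdr = FDR_LEVELS,
                     hla_group = HLA_LEVELS)
  for (col in names(levels_map)) {
    bad <- which(!df[[col]] %in% levels_map[[col]])
    if (length(bad)) {
      stop_input(path, " row ", bad[1], ": unknown ", col, " '",
                 df[[col]][bad[1]], "' (allowed: ",
                 paste(levels_map[[col]], collapse = ", "), ")",
                 class = "value_error")
    }
    out[[col]] <- df[[col]]
  }
  out$followup_start <- parse_date_col(df$followup_start, path,
                                       "followup_start")
  out$followup_end <- parse_date_col(df$followup_end, path, "followup_end")
  bad <- which(!(out$birth_date <= out$followup_start &
                   out$followup_start < out$followup_end))
  if (length(bad)) {
    stop_input(path, " row ", bad[1],
               ": dates must satisfy birth <= followup_start < followup_end",
               class = "validation_error")
  }
  dup <- which(duplicated(out$child_id))
  if (length(dup)) {
    stop_input(path, " row ", dup[1], ": duplicate child_id '",
               out$child_id[dup[1]], "'", class = "validation_error")
  }
  out
}

#' Read the visit-attendance table
#'
#' Expects `visits.csv` columns `child_id, scheduled_age_months, attended`;
#' scheduled ages are the 3-monthly protocol visits (3, 6, ..., 48 months).
#'
#' @param path CSV file path.
#' @return data.frame with `child_id`, `scheduled_age_months` (integer),
#'   `attended` (logical).
#' @export
read_visits <- function(path) {
  df <- read_csv_checked(path, c("child_id", "scheduled_age_months",
                                 "attended"))
  age <- suppressWarnings(as.integer(df$scheduled_age_months))
  bad <- which(is.na(age) | age %% 3L != 0L | age < 3L | age > 48L)
  if (length(bad)) {
    stop_input(path, " row ", bad[1],
               ": scheduled_age_months must be a multiple of 3 in 3..48",
               class = "validation_error")
  }
  data.frame(child_id = df$child_id, scheduled_age_months = age,
             attended = parse_logical_col(df$attended),
             stringsAsFactors = FALSE)
}

#' Read an illness-report stream
#'
#' Expects `reports.csv` columns `report_id, child_id, onset_date,
#' icd10_code, fever_flag, chronic_flag, professional_dx`.  ICD-10 codes
#' are normalized (uppercased, dot stripped); an empty `icd10_code` is a
#' standalone "yes"-fever answer and must carry `fever_flag = TRUE` — a row
#' with neither a code nor a fever answer is rejected.
#'
#' @param path CSV file path.
#' @return data.frame of illness reports, order-preserving.
#' @export
read_reports <- function(path) {
  df <- read_csv_checked(path, c("report_id", "child_id", "onset_date",
                                 "icd10_code", "fever_flag", "chronic_flag",
                                 "professional_dx"))
  code <- normalize_icd10(df$icd10_code)
  code[is.na(code) | !nzchar(code) | code == "NA"] <- NA_character_
  fever <- parse_logical_col(df$fever_flag)
  bad <- which(is.na(code) & !fever)
  if (length(bad)) {
    stop_input(path, " row ", bad[1],
               ": report has neither an ICD-10 code nor a fever answer",
               class = "validation_error")
  }
  bad <- which(!is.na(code) & !grepl(ICD10_SHAPE, code))
  if (length(bad)) {
    stop_input(path, " row ", bad[1], ": '", code[bad[1]],
               "' is not ICD-10 shaped", class = "validation_error")
  }
  dup <- which(duplicated(df$report_id))
  if (length(dup)) {
    stop_input(path, " row ", dup[1], ": duplicate report_id '",
               df$report_id[dup[1]], "'", class = "validation_error")
  }
  data.frame(report_id = df$report_id, child_id = df$child_id,
             onset_date = parse_date_col(df$onset_date, path, "onset_date"),
             icd10_code = code, fever_flag = fever,
             chronic_flag = parse_logical_col(df$chronic_flag),
             professional_dx = parse_logical_col(df$professional_dx),
             stringsAsFactors = FALSE)
}

#' Apply the cohort-eligibility filter
#'
#' A child is excluded iff (a) any two consecutive scheduled visits were
#' both unattended, or (b) follow-up ends before 48 months of age.  The
#' filter is idempotent; the exclusion log gives a per-child reason.
#'
#' @param children Roster from [read_children()].
#' @param visits Attendance table from [read_visits()]; every child must
#'   have a row for every scheduled age.
#' @return list with `children` (eligible subset) and `exclusions`
#'   (data.frame `child_id`, `reason`).
#' @export
apply_cohort_filter <- function(children, visits) {
  ages <- seq(3L, 48L, by = 3L)
  reasons <- character(0)
  ids <- character(0)
  vis_split <- split(visits, visits$child_id)
  for (i in seq_len(nrow(children))) {
    child <- children[i, ]
    v <- vis_split[[child$child_id]]
    if (is.null(v) || !all(ages %in% v$scheduled_age_months)) {
      stop_input("child '", child$child_id,
                 "' is missing visit rows for some scheduled ages",
                 class = "input_error")
    }
    att <- v$attended[match(ages, v$scheduled_age_months)]
    reason <- NA_character_
    if (as.numeric(child$followup_end - child$birth_date) <
        FOLLOWUP_CAP_DAYS) {
      reason <- "follow-up ended before 48 months"
    } else if (any(!att[-length(att)] & !att[-1])) {
      reason <- "two consecutive missed visits"
    }
    if (!is.na(reason)) {
      ids <- c(ids, child$child_id)
      reasons <- c(reasons, reason)
    }
  }
  list(children = children[!children$child_id %in% ids, , drop = FALSE],
       exclusions = data.frame(child_id = ids, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Write / read an episode table
#'
#' Episodes round-trip losslessly through CSV; member report ids are
#' serialized as a semicolon-joined list.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param path Output CSV path.
#' @return `path` invisibly (write); episode data.frame (read).
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes[, c("episode_id", "child_id", "episode_class",
                      "onset_date", "febrile", "n_codes",
                      "member_report_ids")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  df <- read_csv_checked(path, c("episode_id", "child_id", "episode_class",
                                 "onset_date", "febrile", "n_codes",
                                 "member_report_ids"))
  data.frame(episode_id = df$episode_id, child_id = df$child_id,
             episode_class = df$episode_class,
             onset_date = parse_date_col(df$onset_date, path, "onset_date"),
             febrile = parse_logical_col(df$febrile),
             n_codes = as.integer(df$n_codes),
             member_report_ids = df$member_report_ids,
             stringsAsFactors = FALSE)
}

#' Write / read a rate table
#'
#' @param rates Rate table from [episode_rates()].
#' @param path Output CSV path.
#' @return `path` invisibly (write); rate data.frame (read).
#' @export
write_rates <- function(rates, path) {
  out <- rates
  for (col in c("person_years", "rate")) {
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}
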