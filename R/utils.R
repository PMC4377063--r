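# Calendar conventions used throughout: ages are measured in days and
# converted to months with a fixed 30.4375-day month (365.25/12), so that
# 48 months is exactly 1461 days = 4 x 365.25 days.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
FOLLOWUP_CAP_DAYS <- 1461L # 48 months

CODE_CLASSES <- c("RESPIRATORY", "GASTROINTESTINAL", "OTHER",
                  "FEVER_MARKER", "GI_SYMPTOM")
EPISODE_CLASSES <- c("RESPIRATORY", "GASTROINTESTINAL", "OTHER",
                     "UNKNOWN_FEBRILE")

SITE_LEVELS <- c("US-Colorado", "US-Georgia", "US-Washington",
                 "Europe-Finland", "Europe-Germany", "Europe-Sweden")
SEX_LEVELS <- c("female", "male")
FDR_LEVELS <- c("no", "yes")
HLA_LEVELS <- c("DR4-DQ8/DR4-DQ8", "DR3-DQ2/DR4-DQ8", "DR4-DQ8/DR8-DQ4",
                "DR3-DQ2/DR3-DQ2", "HLA-FDR-specific")

SEASON_LEVELS <- c("Dec-Feb", "Mar-May", "Jun-Aug", "Sep-Nov")

#' Map calendar months to meteorological seasons
#'
#' Seasons are meteorological quarters anchored on winter = December to
#' February, the convention used for all seasonal stratifications in this
#' package.
#'
#' @param month Integer vector of calendar months (1--12).
#' @return Factor with levels `"Dec-Feb"`, `"Mar-May"`, `"Jun-Aug"`,
#'   `"Sep-Nov"`.
#' @export
month_to_season <- function(month) {
  stopifnot(all(month %in% 1:12))
  idx <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[month]
  factor(SEASON_LEVELS[idx], levels = SEASON_LEVELS)
}

age_months <- function(dates, birth) {
  as.numeric(dates - birth) / DAYS_PER_MONTH
}

# Deterministic per-stage seeds derived from a single user seed; kept well
# below 2^31 so they are valid R integer seeds.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(..., class = "episodizer_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
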