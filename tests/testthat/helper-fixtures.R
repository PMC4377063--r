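# Fixture builders shared across test files.  All randomness is seeded by
# the caller.

toy_children <- function(n = 2, birth = as.Date("2010-01-01"),
                         followup_months = 48) {
  data.frame(
    child_id = sprintf("c%d", seq_len(n)),
    birth_date = rep(birth, n),
    site = rep_len(c("US-Colorado", "Europe-Finland"), n),
    sex = rep_len(c("female", "male"), n),
    fdr = rep_len(c("no", "yes"), n),
    hla_group = rep_len(c("DR4-DQ8/DR4-DQ8", "DR3-DQ2/DR4-DQ8"), n),
    followup_start = rep(birth, n),
    followup_end = rep(birth, n) +
      round(rep_len(followup_months, n) * 30.4375),
    stringsAsFactors = FALSE)
}

full_visits <- function(children, missed = list()) {
  ages <- seq(3L, 48L, by = 3L)
  v <- data.frame(
    child_id = rep(children$child_id, each = length(ages)),
    scheduled_age_months = rep(ages, nrow(children)),
    attended = TRUE, stringsAsFactors = FALSE)
  for (id in names(missed)) {
    v$attended[v$child_id == id &
                 v$scheduled_age_months %in% missed[[id]]] <- FALSE
  }
  v
}

# A classified report set for one child: mix of all report classes at
# random day offsets, in shuffled row order with shuffled ids, so tests
# exercise the sort-and-tie-break path.
random_classified_reports <- function(n, seed, child_id = "c1",
                                      origin = as.Date("2010-01-01"),
                                      day_range = 0:40) {
  set.seed(seed)
  if (n == 0) {
    return(classified_from(integer(0), character(0), child_id = child_id))
  }
  cls <- sample(c("RESPIRATORY", "GASTROINTESTINAL", "GI_SYMPTOM", "OTHER",
                  "FEVER_MARKER", "STANDALONE_FEVER"), n, TRUE,
                prob = c(0.35, 0.15, 0.12, 0.13, 0.10, 0.15))
  code <- c(RESPIRATORY = "J00", GASTROINTESTINAL = "A09",
            GI_SYMPTOM = "R11", OTHER = "B01", FEVER_MARKER = "R50",
            STANDALONE_FEVER = NA)[cls]
  data.frame(
    report_id = sprintf("r%03d", sample(n)),
    child_id = child_id,
    onset_date = origin + sample(day_range, n, TRUE),
    icd10_code = unname(code),
    fever_flag = cls %in% c("FEVER_MARKER", "STANDALONE_FEVER") |
      stats::runif(n) < 0.3,
    chronic_flag = FALSE, professional_dx = TRUE,
    category_id = NA_character_, episode_class = cls,
    stringsAsFactors = FALSE)
}

# Classified reports from explicit (day, class) pairs, ids in given order.
classified_from <- function(days, classes, child_id = "c1",
                            fever = NULL, origin = as.Date("2010-01-01")) {
  code <- c(RESPIRATORY = "J00", GASTROINTESTINAL = "A09",
            GI_SYMPTOM = "R11", OTHER = "B01", FEVER_MARKER = "R50",
            STANDALONE_FEVER = NA)[classes]
  data.frame(
    report_id = sprintf("r%02d", seq_along(days)),
    child_id = rep_len(child_id, length(days)),
    onset_date = origin + days,
    icd10_code = unname(code),
    fever_flag = rep_len(fever %||%
      (classes %in% c("FEVER_MARKER", "STANDALONE_FEVER")),
      length(days)),
    chronic_flag = rep(FALSE, length(days)),
    professional_dx = rep(TRUE, length(days)),
    category_id = rep(NA_character_, length(days)),
    episode_class = classes,
    stringsAsFactors = FALSE)
}

episodes_equal <- function(a, b) {
  rownames(a) <- rownames(b) <- NULL
  da <- sort(attr(a, "dropped_fever_ids") %||% character(0))
  db <- sort(attr(b, "dropped_fever_ids") %||% character(0))
  isTRUE(all.equal(a, b, check.attributes = FALSE)) && identical(da, db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
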