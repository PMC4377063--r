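#' Episode-merging parameters
#'
#' `merge_gap_days` is the maximum day gap allowed between successive
#' reports merged into one respiratory or gastrointestinal episode ("within
#' the same week", read as pairwise gaps of at most five days).
#' `fever_window_days` is how far a fever report may sit from an episode
#' member and still be attached to that episode.  `fever_search_days` is
#' the lookaround used by the unknown-febrile test: a fever with no
#' infection code within this many days before or after becomes its own
#' unknown-febrile episode.  The two fever windows default to different
#' values (5 and 7) because the protocol phrases one as the merging week
#' and the other as "a week prior or after"; both are configurable.
#'
#' @param merge_gap_days Nonnegative integer, default 5.
#' @param fever_window_days Nonnegative integer, default 5.
#' @param fever_search_days Nonnegative integer, default 7.
#' @return Object of class `episode_params`.
#' @export
episode_params <- function(merge_gap_days = 5L, fever_window_days = 5L,
                           fever_search_days = 7L) {
  p <- list(merge_gap_days = as.numeric(merge_gap_days),
            fever_window_days = as.numeric(fever_window_days),
            fever_search_days = as.numeric(fever_search_days))
  if (any(vapply(p, function(x) !is.finite(x) || x < 0, TRUE))) {
    stop_input("episode parameters must be nonnegative")
  }
  structure(p, class = "episode_params")
}

#' Extract classifiable infection reports from a report stream
#'
#' Drops chronic-flagged reports (the acute-illness section is the input
#' universe; chronic-section contamination is rare and logged) and reports
#' whose code maps to no infection category.  Surviving rows carry a
#' category classification; rows with no code at all are standalone
#' "yes"-fever answers and get class `STANDALONE_FEVER`.
#'
#' @param reports Validated report stream from [read_reports()].
#' @param catalog An `infection_catalog`.
#' @return list with `classified` (data.frame of surviving reports plus
#'   `category_id` and `episode_class`), `n_dropped_chronic` and
#'   `n_dropped_noninfectious`.
#' @export
extract_infection_reports <- function(reports, catalog) {
  chronic <- reports$chronic_flag
  acute <- reports[!chronic, , drop = FALSE]
  category_id <- rep(NA_character_, nrow(acute))
  episode_class <- rep("STANDALONE_FEVER", nrow(acute))
  coded <- !is.na(acute$icd10_code)
  if (any(coded)) {
    cls <- classify_code(catalog, acute$icd10_code[coded])
    category_id[coded] <- cls$category_id
    episode_class[coded] <- cls$episode_class
  }
  keep <- episode_class != "NOT_INFECTIOUS"
  classified <- acute[keep, , drop = FALSE]
  classified$category_id <- category_id[keep]
  classified$episode_class <- episode_class[keep]
  rownames(classified) <- NULL
  list(classified = classified,
       n_dropped_chronic = sum(chronic),
       n_dropped_noninfectious = sum(!keep))
}

empty_episode_df <- function() {
  data.frame(child_id = character(0), episode_class = character(0),
             onset_date = as.Date(character(0)), febrile = logical(0),
             n_codes = integer(0), member_report_ids = character(0),
             stringsAsFactors = FALSE)
}

#' Build infectious episodes for one child
#'
#' Deterministic five-step reduction of one child's classified reports:
#' \enumerate{
#'   \item sort by (onset date, report id);
#'   \item chain `RESPIRATORY` reports with successive gaps of at most
#'     `merge_gap_days`; each maximal chain is one respiratory episode;
#'     then absorb gastroenteritis-symptom reports (category 8) lying
#'     within the gap of any current member of a respiratory episode —
#'     absorption can extend the episode's span, so the scan repeats until
#'     a fixed point (a gastro symptom alongside respiratory illness is not
#'     counted as gastrointestinal);
#'   \item chain the remaining infective-gastroenteritis (category 7) and
#'     unabsorbed category-8 reports with the same gap rule into
#'     gastrointestinal episodes;
#'   \item every remaining `OTHER`-class report is its own episode;
#'   \item fever reports — standalone "yes" answers and fever-symptom
#'     codes (category 1) alike — attach to the episode with the nearest
#'     member date within `fever_window_days` (ties: respiratory over
#'     gastrointestinal over other, then earlier onset); a fever left
#'     unattached becomes an unknown-febrile episode iff no infection code
#'     lies within `fever_search_days` before or after, and is otherwise
#'     dropped (logged in the `dropped_fever_ids` attribute).
#' }
#' An episode is febrile iff any member carries a fever flag or has a fever
#' report attached.  Episode onset is the earliest member code date (the
#' fever report's date for unknown-febrile episodes); `n_codes` counts
#' coded members, so a code-free "yes"-fever unknown-febrile episode has
#' `n_codes = 0` while a fever-symptom-code one has 1.
#'
#' @param classified One child's rows from [extract_infection_reports()].
#' @param params An [episode_params()] object.
#' @return data.frame of episodes (see [build_episodes()] for columns),
#'   with attribute `dropped_fever_ids`.
#' @export
build_episodes_for_child <- function(classified, params = episode_params()) {
  if (nrow(classified) == 0) {
    out <- empty_episode_df()
    attr(out, "dropped_fever_ids") <- character(0)
    return(out)
  }
  if (length(unique(classified$child_id)) != 1) {
    stop_input("build_episodes_for_child received reports from ",
               length(unique(classified$child_id)), " children",
               class = "contract_error")
  }
  x <- classified[order(classified$onset_date, classified$report_id), ,
                  drop = FALSE]
  day <- as.numeric(x$onset_date)
  cls <- x$episode_class
  gap <- params$merge_gap_days
  is_fever <- cls %in% c("STANDALONE_FEVER", "FEVER_MARKER")

  members <- list()
  ep_class <- character(0)
  add_episode <- function(idx, what) {
    members[[length(members) + 1]] <<- idx
    ep_class <<- c(ep_class, what)
  }

  chain <- function(idx) {
    if (!length(idx)) return(list())
    grp <- cumsum(c(1, diff(day[idx]) > gap))
    unname(split(idx, grp))
  }

  for (g in chain(which(cls == "RESPIRATORY"))) add_episode(g, "RESPIRATORY")
  resp_eps <- seq_along(members)

  # fixed-point absorption of gastro-symptom reports into respiratory
  # episodes; member sets are updated immediately so one absorption can
  # bring the next symptom report into range within the same pass
  gs <- which(cls == "GI_SYMPTOM")
  absorbed <- logical(length(gs))
  if (length(gs) && length(resp_eps)) {
    repeat {
      changed <- FALSE
      for (j in seq_along(gs)) {
        if (absorbed[j]) next
        d <- vapply(resp_eps,
                    function(e) min(abs(day[members[[e]]] - day[gs[j]])),
                    numeric(1))
        if (min(d) <= gap) {
          cand <- resp_eps[d == min(d)]
          if (length(cand) > 1) {
            onset <- vapply(cand, function(e) min(day[members[[e]]]),
                            numeric(1))
            cand <- cand[order(onset, cand)]
          }
          e <- cand[1]
          members[[e]] <- sort(c(members[[e]], gs[j]))
          absorbed[j] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  gi_pool <- sort(c(which(cls == "GASTROINTESTINAL"), gs[!absorbed]))
  for (g in chain(gi_pool)) add_episode(g, "GASTROINTESTINAL")
  for (i in which(cls == "OTHER")) add_episode(i, "OTHER")

  # fever attachment: distances are measured to coded (non-fever) members
  # only, so an attached fever never extends another fever's window
  attached <- rep(list(integer(0)), length(members))
  uf <- integer(0)
  dropped <- character(0)
  code_days <- day[!is_fever]
  prio <- c(RESPIRATORY = 1, GASTROINTESTINAL = 2, OTHER = 3)
  for (f in which(is_fever)) {
    att <- FALSE
    if (length(members)) {
      d <- vapply(members,
                  function(m) min(abs(day[m] - day[f])), numeric(1))
      if (min(d) <= params$fever_window_days) {
        cand <- which(d == min(d))
        if (length(cand) > 1) {
          onset <- vapply(cand, function(e) min(day[members[[e]]]),
                          numeric(1))
          cand <- cand[order(prio[ep_class[cand]], onset, cand)]
        }
        e <- cand[1]
        attached[[e]] <- c(attached[[e]], f)
        att <- TRUE
      }
    }
    if (!att) {
      if (!length(code_days) ||
          min(abs(code_days - day[f])) > params$fever_search_days) {
        uf <- c(uf, f)
      } else {
        dropped <- c(dropped, x$report_id[f])
      }
    }
  }

  rows <- vector("list", length(members) + length(uf))
  for (e in seq_along(members)) {
    mem <- sort(c(members[[e]], attached[[e]]))
    has_code <- !is.na(x$icd10_code[mem])
    rows[[e]] <- data.frame(
      child_id = x$child_id[1],
      episode_class = ep_class[e],
      onset_date = x$onset_date[mem[has_code]][
        which.min(day[mem[has_code]])],
      febrile = any(x$fever_flag[mem]) || length(attached[[e]]) > 0,
      n_codes = sum(has_code),
      member_report_ids = paste(x$report_id[mem], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(uf)) {
    f <- uf[k]
    rows[[length(members) + k]] <- data.frame(
      child_id = x$child_id[1],
      episode_class = "UNKNOWN_FEBRILE",
      onset_date = x$onset_date[f],
      febrile = TRUE,
      n_codes = as.integer(!is.na(x$icd10_code[f])),
      member_report_ids = x$report_id[f],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_episode_df()
  out <- out[order(out$onset_date, out$member_report_ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_fever_ids") <- dropped
  out
}

#' Build episodes for a whole cohort and summarize them
#'
#' Runs [build_episodes_for_child()] independently per child (reports
#' outside the child's follow-up window, and after the 48-month cap, are
#' excluded first) and concatenates the results, assigning global episode
#' ids.
#'
#' @param classified Output `classified` of [extract_infection_reports()].
#' @param children Roster data.frame; only reports of rostered children are
#'   used, truncated to `[birth, min(followup_end, birth + 48 months)]`.
#' @param params An [episode_params()] object.
#' @return list with `episodes` (data.frame: `episode_id`, `child_id`,
#'   `episode_class`, `onset_date`, `febrile`, `n_codes`,
#'   `member_report_ids`), `summary` (see [summarize_episodes()]) and
#'   `n_dropped_fevers`.
#' @export
build_episodes <- function(classified, children,
                           params = episode_params()) {
  keep <- classified$child_id %in% children$child_id
  cl <- classified[keep, , drop = FALSE]
  birth <- children$birth_date[match(cl$child_id, children$child_id)]
  endd <- pmin(children$followup_end[match(cl$child_id, children$child_id)],
               birth + FOLLOWUP_CAP_DAYS)
  in_window <- cl$onset_date >= birth & cl$onset_date <= endd
  cl <- cl[in_window, , drop = FALSE]
  pieces <- lapply(split(cl, cl$child_id), build_episodes_for_child,
                   params = params)
  dropped <- unlist(lapply(pieces, attr, "dropped_fever_ids"))
  episodes <- if (length(pieces)) {
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(episodes) || nrow(episodes) == 0) episodes <- empty_episode_df()
  episodes <- episodes[order(episodes$child_id, episodes$onset_date,
                             episodes$member_report_ids), , drop = FALSE]
  rownames(episodes) <- NULL
  episodes <- cbind(episode_id = sprintf("E%06d", seq_len(nrow(episodes))),
                    episodes, stringsAsFactors = FALSE)
  n_code_reports <- sum(!is.na(cl$icd10_code))
  list(episodes = episodes,
       summary = summarize_episodes(episodes,
                                    n_code_reports = n_code_reports),
       n_dropped_fevers = length(dropped))
}

#' Summarize an episode table
#'
#' Per-class episode counts, percentage shares of the total, percent
#' febrile per class, the mean number of ICD-10 code reports per episode,
#' and (when `person_years` is supplied) overall and per-class episode
#' rates per person-year.
#'
#' @param episodes Episode table (needs `episode_class`; `febrile` and
#'   `n_codes` are used when present).
#' @param n_code_reports Total ICD-10 code reports behind the table;
#'   defaults to `sum(episodes$n_codes)`.
#' @param person_years Optional total person-years at risk.
#' @return list with `n_episodes`, `n_code_reports`, `codes_per_episode`,
#'   `per_class` (data.frame: class, n, share_pct, febrile_pct, rate) and
#'   `rate_overall` (NA without `person_years`).
#' @export
summarize_episodes <- function(episodes, n_code_reports = NULL,
                               person_years = NULL) {
  n <- nrow(episodes)
  if (is.null(n_code_reports)) {
    n_code_reports <- if ("n_codes" %in% names(episodes)) {
      sum(episodes$n_codes)
    } else NA_real_
  }
  counts <- vapply(EPISODE_CLASSES,
                   function(cl) sum(episodes$episode_class == cl), 0)
  febrile_pct <- vapply(EPISODE_CLASSES, function(cl) {
    idx <- episodes$episode_class == cl
    if (!any(idx) || !"febrile" %in% names(episodes)) return(NA_real_)
    100 * mean(episodes$febrile[idx])
  }, numeric(1))
  per_class <- data.frame(
    episode_class = EPISODE_CLASSES,
    n = as.integer(counts),
    share_pct = if (n > 0) 100 * counts / n else rep(NA_real_, 4),
    febrile_pct = febrile_pct,
    rate = if (!is.null(person_years)) counts / person_years
           else rep(NA_real_, 4),
    stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  list(n_episodes = n,
       n_code_reports = n_code_reports,
       codes_per_episode = if (n > 0) n_code_reports / n else NA_real_,
       per_class = per_class,
       rate_overall = if (!is.null(person_years)) n / person_years
                      else NA_real_)
}
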