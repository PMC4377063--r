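#' Reference implementation of the episode-merging rules
#'
#' A deliberately naive re-implementation used to verify
#' [build_episodes_for_child()]: clusters are grown by exhaustive pairwise
#' scanning (merge any two same-pool clusters whose closest pair of
#' members is within the gap, repeat until nothing merges) instead of
#' sorted chaining, and every distance is recomputed with explicit loops.
#' Tie-break rules are identical by definition — they are part of the
#' procedure, not of its implementation.  Intended for small inputs
#' (tens of reports per child).
#'
#' @inheritParams build_episodes_for_child
#' @return Episode data.frame in the same format as
#'   [build_episodes_for_child()], with attribute `dropped_fever_ids`.
#' @export
oracle_build_episodes <- function(classified, params = episode_params()) {
  if (nrow(classified) == 0) {
    out <- empty_episode_df()
    attr(out, "dropped_fever_ids") <- character(0)
    return(out)
  }
  if (length(unique(classified$child_id)) != 1) {
    stop_input("oracle_build_episodes received reports from several children",
               class = "contract_error")
  }
  x <- classified[order(classified$onset_date, classified$report_id), ,
                  drop = FALSE]
  day <- as.numeric(x$onset_date)
  cls <- x$episode_class
  gap <- params$merge_gap_days
  is_fever <- cls %in% c("STANDALONE_FEVER", "FEVER_MARKER")

  min_cross_gap <- function(a, b) {
    best <- Inf
    for (i in a) for (j in b) best <- min(best, abs(day[i] - day[j]))
    best
  }
  merge_components <- function(idx) {
    clusters <- lapply(idx, function(i) i)
    repeat {
      merged <- FALSE
      for (a in seq_along(clusters)) {
        if (merged) break
        for (b in seq_along(clusters)) {
          if (a >= b) next
          if (min_cross_gap(clusters[[a]], clusters[[b]]) <= gap) {
            clusters[[a]] <- sort(c(clusters[[a]], clusters[[b]]))
            clusters[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    clusters
  }

  members <- list()
  ep_class <- character(0)
  for (g in merge_components(which(cls == "RESPIRATORY"))) {
    members[[length(members) + 1]] <- g
    ep_class <- c(ep_class, "RESPIRATORY")
  }
  resp_eps <- seq_along(members)

  gs <- which(cls == "GI_SYMPTOM")
  absorbed <- logical(length(gs))
  if (length(gs) && length(resp_eps)) {
    repeat {
      changed <- FALSE
      for (j in seq_along(gs)) {
        if (absorbed[j]) next
        best_d <- Inf
        best_e <- NA_integer_
        for (e in resp_eps) {
          d <- min_cross_gap(members[[e]], gs[j])
          onset_e <- min(day[members[[e]]])
          if (d < best_d) {
            best_d <- d
            best_e <- e
          } else if (d == best_d && !is.na(best_e)) {
            onset_best <- min(day[members[[best_e]]])
            if (onset_e < onset_best ||
                (onset_e == onset_best && e < best_e)) {
              best_e <- e
            }
          }
        }
        if (best_d <= gap) {
          members[[best_e]] <- sort(c(members[[best_e]], gs[j]))
          absorbed[j] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  gi_pool <- sort(c(which(cls == "GASTROINTESTINAL"), gs[!absorbed]))
  for (g in merge_components(gi_pool)) {
    members[[length(members) + 1]] <- g
    ep_class <- c(ep_class, "GASTROINTESTINAL")
  }
  for (i in which(cls == "OTHER")) {
    members[[length(members) + 1]] <- i
    ep_class <- c(ep_class, "OTHER")
  }

  attached <- rep(list(integer(0)), length(members))
  uf <- integer(0)
  dropped <- character(0)
  prio <- c(RESPIRATORY = 1, GASTROINTESTINAL = 2, OTHER = 3)
  for (f in which(is_fever)) {
    best_d <- Inf
    best_e <- NA_integer_
    for (e in seq_along(members)) {
      d <- min_cross_gap(members[[e]], f)
      if (d < best_d) {
        best_d <- d
        best_e <- e
      } else if (d == best_d && !is.na(best_e)) {
        pe <- prio[[ep_class[e]]]
        pb <- prio[[ep_class[best_e]]]
        oe <- min(day[members[[e]]])
        ob <- min(day[members[[best_e]]])
        if (pe < pb || (pe == pb && (oe < ob || (oe == ob && e < best_e)))) {
          best_e <- e
        }
      }
    }
    if (is.finite(best_d) && best_d <= params$fever_window_days) {
      attached[[best_e]] <- c(attached[[best_e]], f)
    } else {
      near_code <- FALSE
      for (i in which(!is_fever)) {
        if (abs(day[i] - day[f]) <= params$fever_search_days) {
          near_code <- TRUE
        }
      }
      if (near_code) dropped <- c(dropped, x$report_id[f]) else uf <- c(uf, f)
    }
  }

  rows <- list()
  for (e in seq_along(members)) {
    mem <- sort(c(members[[e]], attached[[e]]))
    has_code <- !is.na(x$icd10_code[mem])
    coded_days <- day[mem[has_code]]
    rows[[length(rows) + 1]] <- data.frame(
      child_id = x$child_id[1],
      episode_class = ep_class[e],
      onset_date = x$onset_date[mem[has_code][which.min(coded_days)]],
      febrile = any(x$fever_flag[mem]) || length(attached[[e]]) > 0,
      n_codes = sum(has_code),
      member_report_ids = paste(x$report_id[mem], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (f in uf) {
    rows[[length(rows) + 1]] <- data.frame(
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
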