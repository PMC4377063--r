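#' Compare reconstructed episodes with simulated ground truth
#'
#' Each true episode is matched to the built episode holding the largest
#' number of its emitted reports (ties to the earliest built episode);
#' truths whose reports survive in no episode, and built episodes matched
#' by no truth (noise-born), are counted as unmatched.
#'
#' When the emitted report stream is supplied, matching uses only a
#' truth's coded reports (its fever answers are ancillary and may
#' legitimately attach to a concurrent episode of another class); truths
#' with no coded report — unknown-febrile ones — still match through
#' their fever report.
#'
#' @param truth Truth table from [emit_reports()] (with `report_ids`).
#' @param episodes Built episode table from [build_episodes()].
#' @param reports Optional report stream from [emit_reports()], used to
#'   restrict matching to coded reports.
#' @return list with `count_ratio` (built / true episode count),
#'   `confusion` (table true class x built class, plus an `UNMATCHED`
#'   column), `onset_mae_days`, `febrile_accuracy`, `n_unmatched_truth`,
#'   `n_unmatched_built`.
#' @export
evaluate_reconstruction <- function(truth, episodes, reports = NULL) {
  classes <- EPISODE_CLASSES
  confusion <- matrix(0L, nrow = length(classes),
                      ncol = length(classes) + 1,
                      dimnames = list(true = classes,
                                      built = c(classes, "UNMATCHED")))
  if (nrow(truth) == 0 || nrow(episodes) == 0) {
    return(list(count_ratio = if (nrow(truth)) 0 else
                  ifelse(nrow(episodes) == 0, 0, Inf),
                confusion = as.table(confusion), onset_mae_days = 0,
                febrile_accuracy = 0,
                n_unmatched_truth = nrow(truth),
                n_unmatched_built = nrow(episodes)))
  }
  built_ids <- strsplit(episodes$member_report_ids, ";", fixed = TRUE)
  report_to_built <- rep(seq_len(nrow(episodes)), lengths(built_ids))
  names(report_to_built) <- unlist(built_ids)

  coded_ids <- if (!is.null(reports)) {
    reports$report_id[!is.na(reports$icd10_code)]
  } else NULL

  matched_built <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ids <- strsplit(truth$report_ids[i], ";", fixed = TRUE)[[1]]
    if (!is.null(coded_ids)) {
      coded <- ids[ids %in% coded_ids]
      if (length(coded)) ids <- coded
    }
    hits <- report_to_built[ids[ids %in% names(report_to_built)]]
    if (!length(hits)) {
      matched_built[i] <- NA_integer_
      next
    }
    tab <- table(hits)
    best <- as.integer(names(tab)[tab == max(tab)])
    matched_built[i] <- min(best)
  }
  for (i in seq_len(nrow(truth))) {
    tc <- truth$true_class[i]
    if (is.na(matched_built[i])) {
      confusion[tc, "UNMATCHED"] <- confusion[tc, "UNMATCHED"] + 1L
    } else {
      bc <- episodes$episode_class[matched_built[i]]
      confusion[tc, bc] <- confusion[tc, bc] + 1L
    }
  }
  ok <- !is.na(matched_built)
  onset_mae <- if (any(ok)) {
    mean(abs(as.numeric(episodes$onset_date[matched_built[ok]] -
                          truth$true_onset_date[ok])))
  } else NA_real_
  feb_acc <- if (any(ok)) {
    mean(episodes$febrile[matched_built[ok]] == truth$febrile_truth[ok])
  } else NA_real_
  list(count_ratio = nrow(episodes) / nrow(truth),
       confusion = as.table(confusion),
       onset_mae_days = onset_mae,
       febrile_accuracy = feb_acc,
       n_unmatched_truth = sum(!ok),
       n_unmatched_built = sum(!seq_len(nrow(episodes)) %in%
                                 matched_built[ok]))
}
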