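#' Remove duplicate surveys
#'
#' Surveys occurring strictly within 5 minutes of the previous retained
#' survey of the same patient are removed (sequential scan in time order;
#' the earlier survey is kept).  A gap of exactly 5 minutes keeps both.
#' The rule is idempotent.
#'
#' @param surveys data.frame with \code{patient_id} and \code{timestamp}.
#' @param min_gap_s minimum gap, seconds (default 300).
#' @return the data.frame with duplicates removed, in time order per patient.
#' @export
deduplicate <- function(surveys, min_gap_s = 300) {
  keep <- logical(nrow(surveys))
  for (pid in unique(surveys$patient_id)) {
    rows <- which(surveys$patient_id == pid)
    rows <- rows[order(surveys$timestamp[rows])]
    last_kept <- -Inf
    for (r in rows) {
      if (surveys$timestamp[r] - last_kept < min_gap_s) next
      keep[r] <- TRUE
      last_kept <- surveys$timestamp[r]
    }
  }
  out <- surveys[keep, , drop = FALSE]
  out[order(out$patient_id, out$timestamp), , drop = FALSE]
}

#' Derive binary agitation outcomes from PAS item scores
#'
#' Overall agitation is positive iff the PAS total (sum of the four item
#' scores) exceeds 0; motor and verbal agitation are positive iff the motor
#' and vocalization subscores exceed 0 respectively.  A survey can be both
#' motor- and verbal-agitated ("both" type).
#'
#' @param surveys data.frame with \code{pas_vocal}, \code{pas_motor},
#'   \code{pas_aggr}, \code{pas_resist} integer columns (0-4).
#' @return the data.frame with added integer columns \code{agitated},
#'   \code{motor_agitated}, \code{verbal_agitated}.
#' @export
binarize_outcomes <- function(surveys) {
  total <- surveys$pas_vocal + surveys$pas_motor +
    surveys$pas_aggr + surveys$pas_resist
  surveys$agitated <- as.integer(total > 0)
  surveys$motor_agitated <- as.integer(surveys$pas_motor > 0)
  surveys$verbal_agitated <- as.integer(surveys$pas_vocal > 0)
  surveys
}

#' Apply the per-modality patient inclusion rule
#'
#' Patients contributing fewer than two kept surveys for a modality are
#' removed from that modality's analysis only; other modalities are
#' untouched.
#'
#' @param tab data.frame with \code{patient_id} and \code{modality} columns,
#'   one row per kept survey-window (or per feature row).
#' @param min_surveys minimum kept surveys per patient per modality.
#' @return filtered data.frame.
#' @export
apply_inclusion_rules <- function(tab, min_surveys = 2L) {
  key <- interaction(tab$patient_id, tab$modality, drop = TRUE)
  # count distinct surveys per patient x modality
  cnt <- tapply(tab$survey_id, key, function(s) length(unique(s)))
  ok <- cnt[as.character(key)] >= min_surveys
  tab[as.logical(ok), , drop = FALSE]
}

#' Select the consistent-availability visualization subset
#'
#' Patients with at least \code{min_each} agitated and \code{min_each}
#' non-agitated kept surveys for every agitation type (overall, motor,
#' verbal) and every sensor modality, in deterministic (sorted) order.
#' Used for per-patient median-difference displays.
#'
#' @param tab data.frame with one row per kept survey-window, columns
#'   \code{patient_id}, \code{modality}, \code{survey_id},
#'   \code{agitated}, \code{motor_agitated}, \code{verbal_agitated}.
#' @param min_each minimum count in each cell (default 2).
#' @param n_patients maximum number of patients returned (default 5),
#'   preferring those with the most kept surveys.
#' @return character vector of patient ids (possibly empty, with a warning).
#' @export
select_visualization_subset <- function(tab, min_each = 2L, n_patients = 5L) {
  outcomes <- c("agitated", "motor_agitated", "verbal_agitated")
  modalities <- unique(tab$modality)
  ok_patients <- character(0)
  totals <- numeric(0)
  for (pid in sort(unique(tab$patient_id))) {
    sub <- tab[tab$patient_id == pid, , drop = FALSE]
    ok <- TRUE
    for (m in modalities) {
      sm <- sub[sub$modality == m, , drop = FALSE]
      sm <- sm[!duplicated(sm$survey_id), , drop = FALSE]
      for (oc in outcomes) {
        if (sum(sm[[oc]] == 1L) < min_each || sum(sm[[oc]] == 0L) < min_each) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      ok_patients <- c(ok_patients, pid)
      totals <- c(totals, length(unique(sub$survey_id)))
    }
  }
  if (length(ok_patients) == 0L) {
    warning("no patient satisfies the visualization-subset criteria")
    return(character(0))
  }
  ok_patients[order(-totals, ok_patients)][seq_len(min(n_patients, length(ok_patients)))]
}
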