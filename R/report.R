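#' Proportion of agitated surveys per time block
#'
#' Per patient and clock block, the share of agitated surveys among that
#' patient's surveys in the block.  Blocks in which a patient has no surveys
#' are reported missing (NA), not zero.
#'
#' @param surveys cleaned survey table with \code{patient_id},
#'   \code{agitated}, and \code{time_group} columns.
#' @return data.frame patient_id x time_group with \code{n_surveys},
#'   \code{n_agitated}, \code{proportion}.
#' @export
proportion_by_time_group <- function(surveys) {
  pats <- sort(unique(surveys$patient_id))
  out <- expand.grid(patient_id = pats, time_group = 1:4,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_surveys <- 0L; out$n_agitated <- 0L; out$proportion <- NA_real_
  for (i in seq_len(nrow(out))) {
    sub <- surveys$patient_id == out$patient_id[i] &
      surveys$time_group == out$time_group[i]
    n <- sum(sub)
    out$n_surveys[i] <- n
    if (n > 0) {
      out$n_agitated[i] <- sum(surveys$agitated[sub])
      out$proportion[i] <- out$n_agitated[i] / n
    }
  }
  out[order(out$patient_id, out$time_group), ]
}

#' Median standardized feature differences against the non-agitated state
#'
#' For each feature, the median standardized value in a group of agitated
#' surveys minus the median in the non-agitated reference group.  Grouping
#' \code{"agitation_type"} compares motor-agitated and verbal-agitated
#' surveys (a survey with both subtypes enters both groups) against all
#' non-agitated surveys; grouping \code{"patient"} compares each patient's
#' agitated vs non-agitated surveys, normally on the
#' consistent-availability subset.  No significance tests and no
#' confounder adjustment are applied to these summaries by design.
#'
#' @param rows model-row table from \code{\link{run_pipeline}}.
#' @param grouping \code{"agitation_type"} or \code{"patient"}.
#' @param patients optional patient ids to restrict to (e.g. from
#'   \code{\link{select_visualization_subset}}).
#' @return data.frame with group, modality, signal, feature, group and
#'   reference medians and sizes, and \code{difference}; groups with fewer
#'   than 2 surveys are flagged \code{small_group = TRUE}.
#' @export
median_difference_table <- function(rows,
                                    grouping = c("agitation_type", "patient"),
                                    patients = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(patients)) rows <- rows[rows$patient_id %in% patients, ]
  rows <- rows[!is.na(rows$z), ]
  combos <- unique(rows[c("modality", "signal", "feature")])
  combos <- combos[order(combos$modality, combos$signal, combos$feature), ]
  res <- list(); k <- 0L
  groups <- if (grouping == "agitation_type") c("motor", "verbal")
            else sort(unique(rows$patient_id))
  for (i in seq_len(nrow(combos))) {
    sub <- rows[rows$modality == combos$modality[i] &
                  rows$signal == combos$signal[i] &
                  rows$feature == combos$feature[i], ]
    for (g in groups) {
      if (grouping == "agitation_type") {
        gcol <- if (g == "motor") "motor_agitated" else "verbal_agitated"
        in_group <- sub[[gcol]] == 1L
        ref <- sub$agitated == 0L
      } else {
        in_group <- sub$patient_id == g & sub$agitated == 1L
        ref <- sub$patient_id == g & sub$agitated == 0L
      }
      n_g <- sum(in_group); n_r <- sum(ref)
      med_g <- if (n_g > 0) stats::median(sub$z[in_group]) else NA_real_
      med_r <- if (n_r > 0) stats::median(sub$z[ref]) else NA_real_
      k <- k + 1L
      res[[k]] <- data.frame(group = g, modality = combos$modality[i],
                             signal = combos$signal[i],
                             feature = combos$feature[i],
                             n_group = n_g, n_reference = n_r,
                             median_group = med_g, median_reference = med_r,
                             difference = med_g - med_r,
                             small_group = n_g < 2L || n_r < 2L,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return "***" for p < .001, "**" for p < .01, "*" for p < .05, else "".
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Coefficient table for the feature screen
#'
#' Formats the per-feature GLMM screen as the data behind a forest-style
#' display: estimates, standard errors, Wald p-values and significance
#' stars, grouped by modality in the fixed order acc, eda, hr, st.
#'
#' @param fits result of \code{\link{run_feature_screen}}.
#' @return the table with added \code{stars} and \code{ci_lo}/\code{ci_hi}
#'   (Wald 95\%), deterministically ordered.
#' @export
coefficient_table <- function(fits) {
  fits$stars <- significance_stars(fits$p)
  fits$ci_lo <- fits$estimate - 1.96 * fits$se
  fits$ci_hi <- fits$estimate + 1.96 * fits$se
  mod_order <- match(fits$modality, c("acc", "eda", "hr", "st"))
  fits[order(mod_order, fits$signal, fits$feature, fits$outcome), ]
}
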