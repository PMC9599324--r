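# Dominance / codominance community typing and longitudinal shift counting.

#' Classify one sample into a dominance group
#'
#' A sample is codominant (`CRISP_INERS_CODOM`) when the L. crispatus and
#' L. iners groups each exceed 10% relative abundance and together exceed
#' 50%; codominance takes precedence over single dominance. Otherwise a
#' sample is dominated by its most abundant taxon if that taxon exceeds
#' 40%: the crispatus and iners groups map to their own labels, the other
#' Lactobacillus subgenus groups (gasseri/jensenii/pasteurii) are merged
#' into `OTHER_LACTO_DOM`, and any non-Lactobacillus taxon — or no taxon
#' above 40% at all — yields `NON_LACTO`.
#'
#' Thresholds are strict by default ("exceeds"); `inclusive = TRUE` turns
#' them into `>=` comparisons, reproducing the alternative reading in which
#' an abundance of exactly 40% counts as dominant. Ties at the top abundance
#' are broken alphabetically by taxon name for determinism.
#'
#' @param composition named relative abundance vector at subgenus-group (or
#'   genus) level, summing to 1.
#' @param inclusive use `>=` instead of `>` for the 40/10/50% thresholds.
#' @return One of [DOMINANCE_GROUPS].
#' @export
classify_sample <- function(composition, inclusive = FALSE) {
  if (is.null(names(composition)))
    vd_stop("composition must be a named vector", "vagidyn_validation_error")
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-6)
    vd_stop("composition must be nonnegative and sum to 1",
            "vagidyn_validation_error")
  gt <- if (inclusive) `>=` else `>`
  crisp <- if ("L_crispatus_group" %in% names(composition))
    unname(composition[["L_crispatus_group"]]) else 0
  iners <- if ("L_iners_group" %in% names(composition))
    unname(composition[["L_iners_group"]]) else 0
  if (gt(crisp, 0.10) && gt(iners, 0.10) && gt(crisp + iners, 0.50))
    return("CRISP_INERS_CODOM")
  m <- max(composition)
  if (!gt(m, 0.40)) return("NON_LACTO")
  top <- sort(names(composition)[composition == m])[1]
  switch(top,
         L_crispatus_group = "CRISPATUS_DOM",
         L_iners_group = "INERS_DOM",
         L_gasseri_group = ,
         L_jensenii_group = ,
         L_pasteurii_group = "OTHER_LACTO_DOM",
         "NON_LACTO")
}

#' Classify every sample of a cohort
#'
#' @param table relative [abundance_table()] aggregated to subgenus-group
#'   level (see [aggregate_taxa()]).
#' @param design a [study_design()] covering all samples of the table.
#' @param inclusive passed to [classify_sample()].
#' @return Data frame with columns `sample_id`, `participant_id`,
#'   `timepoint`, `arm`, `group`, ordered by (participant, time point).
#' @export
classify_cohort <- function(table, design, inclusive = FALSE) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "study_design"))
  if (table$mode != "relative")
    vd_stop("classification requires a relative table", "vagidyn_usage_error")
  missing <- setdiff(colnames(table$values), design$sample_id)
  if (length(missing))
    vd_stop(sprintf("sample '%s' absent from the study design", missing[1]),
            "vagidyn_validation_error")
  groups <- vapply(colnames(table$values), function(s)
    classify_sample(table$values[, s], inclusive = inclusive), "")
  out <- as.data.frame(design)[design$sample_id %in% names(groups),
                               c("sample_id", "participant_id", "timepoint",
                                 "arm")]
  out$group <- unname(groups[out$sample_id])
  out <- out[order(out$participant_id, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize dominance shifts for one participant
#'
#' Two notions of "shift" are reported because the literature conflates
#' them: `n_transitions` counts adjacent unequal label pairs in time order,
#' and `n_deviations` counts samples whose label differs from the
#' participant's modal label (ties between modal candidates broken toward
#' the earliest-occurring one). A participant is `stable` iff all labels are
#' identical, which makes both counts zero.
#'
#' @param labels character vector of dominance labels in chronological
#'   order, missing time points already removed.
#' @return List with `labels`, `n_transitions`, `n_deviations`, `stable`.
#' @export
shift_summary <- function(labels) {
  if (length(labels) == 0)
    vd_stop("empty label sequence", "vagidyn_validation_error")
  n_transitions <- if (length(labels) > 1)
    sum(labels[-1] != labels[-length(labels)]) else 0L
  counts <- table(labels)
  modal_set <- names(counts)[counts == max(counts)]
  modal <- labels[labels %in% modal_set][1]  # earliest-occurring modal label
  n_dev <- sum(labels != modal)
  list(labels = labels, n_transitions = as.integer(n_transitions),
       n_deviations = as.integer(n_dev),
       modal = modal, stable = n_transitions == 0L)
}

#' Shift summaries for all participants
#'
#' @param labels_df output of [classify_cohort()].
#' @return Data frame with one row per participant: `participant_id`, `arm`,
#'   `n_samples`, `n_transitions`, `n_deviations`, `modal`, `stable`.
#' @export
cohort_shifts <- function(labels_df) {
  sp <- split(labels_df[order(labels_df$timepoint), , drop = FALSE],
              labels_df$participant_id[order(labels_df$timepoint)])
  rows <- lapply(sp, function(d) {
    s <- shift_summary(d$group)
    data.frame(participant_id = d$participant_id[1], arm = d$arm[1],
               n_samples = nrow(d), n_transitions = s$n_transitions,
               n_deviations = s$n_deviations, modal = s$modal,
               stable = s$stable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominance group prevalence
#'
#' Counts and percentages of each dominance group over all samples,
#' optionally stratified by treatment arm. Percentages are
#' `100 * count / stratum total`, reported rounded half away from zero
#' (matching conventional reporting: 50/101 prints as 50%, 65/200 as 33%);
#' the raw fraction is retained alongside.
#'
#' @param labels_df output of [classify_cohort()].
#' @param stratify_by_arm split counts by arm.
#' @return Data frame with columns (`arm`,) `group`, `count`, `total`,
#'   `fraction`, `percent`.
#' @export
dominance_prevalence <- function(labels_df, stratify_by_arm = FALSE) {
  one <- function(d, arm = NULL) {
    cnt <- table(factor(d$group, levels = DOMINANCE_GROUPS))
    out <- data.frame(group = names(cnt), count = as.integer(cnt),
                      total = nrow(d), stringsAsFactors = FALSE)
    if (nrow(d) > 0) {
      out$fraction <- out$count / out$total
      out$percent <- report_percent(out$count, out$total)
    } else {
      out$fraction <- NA_real_
      out$percent <- NA_real_
    }
    if (!is.null(arm)) out <- cbind(arm = arm, out)
    out
  }
  if (!stratify_by_arm) return(one(labels_df))
  out <- do.call(rbind, lapply(ARMS, function(a)
    one(labels_df[labels_df$arm == a, , drop = FALSE], arm = a)))
  rownames(out) <- NULL
  out
}
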