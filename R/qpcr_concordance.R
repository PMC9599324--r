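# Dominant-taxon prediction from the species-specific qPCR panel, and
# agreement scoring against 16S-based community typing.

#' Predict the dominance group from a qPCR panel entry
#'
#' If the two highest concentrations belong to L. crispatus and L. iners
#' (either order) and differ by less than 2-fold, the sample is predicted
#' codominant; otherwise the single most abundant species maps to its
#' dominance group (gasseri and jensenii both to `OTHER_LACTO_DOM`). The
#' ratio test is direction-free (larger over smaller, strictly below 2) and
#' the prediction depends only on concentration ranks plus that ratio, so
#' it is invariant to rescaling all four values. The panel contains only
#' lactobacilli, so `NON_LACTO` is never predicted; a panel with no
#' positive measurement returns `"NO_CALL"`.
#'
#' @param conc named numeric vector over [QPCR_SPECIES] (CFU/mL); `NA`
#'   marks an unmeasured species.
#' @return One of `CRISPATUS_DOM`, `INERS_DOM`, `CRISP_INERS_CODOM`,
#'   `OTHER_LACTO_DOM`, or `"NO_CALL"`.
#' @export
predict_group_from_qpcr <- function(conc) {
  bad <- setdiff(names(conc), QPCR_SPECIES)
  if (length(bad))
    vd_stop(sprintf("unknown panel species '%s'", bad[1]),
            "vagidyn_validation_error")
  conc <- conc[!is.na(conc) & conc > 0]
  if (!length(conc)) return("NO_CALL")
  ord <- names(sort(conc, decreasing = TRUE))
  if (length(conc) >= 2 &&
      setequal(ord[1:2], c("L_crispatus", "L_iners"))) {
    ratio <- max(conc[ord[1:2]]) / min(conc[ord[1:2]])
    if (ratio < 2) return("CRISP_INERS_CODOM")
  }
  switch(ord[1],
         L_crispatus = "CRISPATUS_DOM",
         L_iners = "INERS_DOM",
         L_gasseri = ,
         L_jensenii = "OTHER_LACTO_DOM")
}

#' Predict dominance groups for every sample of a qPCR panel
#'
#' @param panel a [qpcr_panel()].
#' @return Named character vector, sample id -> predicted group.
#' @export
predict_groups_from_qpcr <- function(panel) {
  stopifnot(inherits(panel, "qpcr_panel"))
  sp <- split(panel, panel$sample_id)
  out <- vapply(sp, function(d) {
    conc <- d$cfu_per_ml
    names(conc) <- d$taxon
    predict_group_from_qpcr(conc)
  }, "")
  out
}

#' Concordance between 16S typing and qPCR prediction
#'
#' Agreement is scored over samples whose 16S dominance group is
#' Lactobacillus-typed: samples typed `NON_LACTO` by 16S are excluded from
#' the default denominator because the four-species panel cannot express
#' that class (they are reported separately, and an alternative agreement
#' including them as automatic disagreements is also returned). qPCR
#' no-calls are excluded and counted.
#'
#' @param labels_16s named character vector (sample id -> dominance group
#'   from 16S), or the data frame from [classify_cohort()].
#' @param labels_qpcr named character vector of qPCR predictions from
#'   [predict_groups_from_qpcr()]; must cover the same samples.
#' @return A `concordance_report` list: `n_samples`, `n_no_call`,
#'   `n_non_lacto_16s`, `n_scored`, `n_agree`, `agreement_fraction`,
#'   `agreement_including_non_lacto`, and a 5x5 `confusion` table
#'   (16S group x qPCR-predicted group).
#' @export
concordance <- function(labels_16s, labels_qpcr) {
  if (is.data.frame(labels_16s)) {
    v <- labels_16s$group
    names(v) <- labels_16s$sample_id
    labels_16s <- v
  }
  common <- intersect(names(labels_16s), names(labels_qpcr))
  if (!length(common))
    vd_stop("16S and qPCR label sets share no samples",
            "vagidyn_validation_error")
  a <- labels_16s[common]
  b <- labels_qpcr[common]
  no_call <- b == "NO_CALL"
  a <- a[!no_call]; b <- b[!no_call]
  confusion <- table(factor(a, levels = DOMINANCE_GROUPS),
                     factor(b, levels = DOMINANCE_GROUPS),
                     dnn = c("16S", "qPCR"))
  lacto <- a != "NON_LACTO"
  n_scored <- sum(lacto)
  n_agree <- sum(a[lacto] == b[lacto])
  structure(list(
    n_samples = length(common),
    n_no_call = sum(no_call),
    n_non_lacto_16s = sum(!lacto),
    n_scored = n_scored,
    n_agree = n_agree,
    agreement_fraction = if (n_scored > 0) n_agree / n_scored else NA_real_,
    agreement_including_non_lacto =
      if (length(a) > 0) n_agree / length(a) else NA_real_,
    confusion = confusion), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d samples, %d no-call, %d non-Lactobacillus 16S\n",
    x$n_samples, x$n_no_call, x$n_non_lacto_16s))
  if (is.na(x$agreement_fraction))
    cat("agreement undefined (no scorable samples)\n")
  else
    cat(sprintf("agreement %d/%d = %.3f over Lactobacillus-typed samples\n",
                x$n_agree, x$n_scored, x$agreement_fraction))
  invisible(x)
}
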