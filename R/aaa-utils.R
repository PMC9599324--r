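# Shared constants and small helpers.

#' Canonical study time points
#'
#' The six sampling time points of the cycle-anchored design, in
#' chronological order: V1 (baseline, just after menstruation, day 0),
#' D7/D14/D21 (self-sampled, days 7/14/21), V2 (day 28, again just after
#' menstruation) and V3 (day 42).
#'
#' @format Character vector of length 6.
#' @export
TIMEPOINTS <- c("V1", "D7", "D14", "D21", "V2", "V3")

#' Study days of the canonical time points
#'
#' @format Named integer vector mapping time point to study day.
#' @export
TIMEPOINT_DAYS <- c(V1 = 0L, D7 = 7L, D14 = 14L, D21 = 21L, V2 = 28L, V3 = 42L)

#' Treatment arms
#' @format Character vector of length 2.
#' @export
ARMS <- c("placebo", "treatment")

#' Dominance group labels
#'
#' The five community types used throughout: samples dominated by the
#' L. crispatus group, by the L. iners group, codominated by both, dominated
#' by another Lactobacillus subgenus group (gasseri/jensenii/pasteurii), or
#' not dominated by any Lactobacillus.
#'
#' @format Character vector of length 5.
#' @export
DOMINANCE_GROUPS <- c("CRISPATUS_DOM", "INERS_DOM", "CRISP_INERS_CODOM",
                      "OTHER_LACTO_DOM", "NON_LACTO")

#' Lactobacillus subgenus group labels
#' @format Character vector of length 5.
#' @export
LACTO_GROUPS <- c("L_crispatus_group", "L_iners_group", "L_gasseri_group",
                  "L_jensenii_group", "L_pasteurii_group")

#' Species of the diagnostic qPCR panel
#' @format Character vector of length 4.
#' @export
QPCR_SPECIES <- c("L_crispatus", "L_iners", "L_gasseri", "L_jensenii")

# qPCR species -> the subgenus group carrying its 16S signal
QPCR_SPECIES_GROUP <- c(L_crispatus = "L_crispatus_group",
                        L_iners     = "L_iners_group",
                        L_gasseri   = "L_gasseri_group",
                        L_jensenii  = "L_jensenii_group")

#' Round half away from zero
#'
#' Rounding used for all reported percentages (e.g. 65/200 prints as 33%,
#' not 32%); base [round()] rounds half to even and would disagree with the
#' conventional reporting style.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Integer percentage for reporting
#'
#' `100 * count / total` rounded half away from zero, matching the style in
#' which prevalences are conventionally printed (50/101 -> 50, 65/200 -> 33).
#'
#' @param count numerator count(s).
#' @param total denominator total(s).
#' @return Integer-valued numeric percentage(s).
#' @export
report_percent <- function(count, total) {
  stopifnot(all(total > 0), all(count >= 0))
  round_half_away(100 * count / total)
}

# stop() with a class so tests can assert on error types
vd_stop <- function(msg, class = "vagidyn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
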