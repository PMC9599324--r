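# Relative abundance difference (RAD) statistics: per-participant paired
# differences between time points, median-RAD matrices with signed-rank
# tests and Benjamini-Yekutieli correction, and differential RADs between
# arms via the Hodges-Lehmann estimator.

#' Per-participant relative abundance differences
#'
#' The RAD of a taxon for one participant between two time points is its
#' relative abundance at the later time point minus that at the earlier
#' one, so a positive RAD means the taxon increased. Only participants with
#' both samples contribute (pairwise-complete); a taxon absent in both
#' samples yields an informative RAD of 0.
#'
#' @param table relative [abundance_table()] aggregated so that `taxon` is
#'   a row.
#' @param design a [study_design()].
#' @param taxon taxon id (e.g. `"Lactobacillus"` at genus level,
#'   `"L_crispatus_group"` at subgenus level).
#' @param t1,t2 time points, `t1` chronologically before `t2`.
#' @param arm optional arm filter (`"placebo"` or `"treatment"`).
#' @return Data frame with columns `participant_id`, `taxon`,
#'   `timepoint_from`, `timepoint_to`, `ra_from`, `ra_to`, `rad`.
#' @export
compute_rads <- function(table, design, taxon, t1, t2, arm = NULL) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "study_design"))
  if (!t1 %in% TIMEPOINTS || !t2 %in% TIMEPOINTS)
    vd_stop("unknown time point", "vagidyn_usage_error")
  if (t1 == t2) vd_stop("t1 and t2 must differ", "vagidyn_usage_error")
  if (match(t1, TIMEPOINTS) > match(t2, TIMEPOINTS))
    vd_stop("t1 must be chronologically before t2", "vagidyn_usage_error")
  ra <- taxon_row(table, taxon)
  des <- as.data.frame(design)
  if (!is.null(arm)) des <- des[des$arm == arm, , drop = FALSE]
  des <- des[des$sample_id %in% names(ra), , drop = FALSE]
  s1 <- des[des$timepoint == t1, ]
  s2 <- des[des$timepoint == t2, ]
  common <- sort(intersect(s1$participant_id, s2$participant_id))
  if (!length(common))
    return(data.frame(participant_id = character(), taxon = character(),
                      timepoint_from = character(),
                      timepoint_to = character(), ra_from = numeric(),
                      ra_to = numeric(), rad = numeric(),
                      stringsAsFactors = FALSE))
  id1 <- s1$sample_id[match(common, s1$participant_id)]
  id2 <- s2$sample_id[match(common, s2$participant_id)]
  data.frame(participant_id = common, taxon = taxon,
             timepoint_from = t1, timepoint_to = t2,
             ra_from = unname(ra[id1]), ra_to = unname(ra[id2]),
             rad = unname(ra[id2] - ra[id1]),
             stringsAsFactors = FALSE)
}

# Two-sided Wilcoxon signed-rank p on paired values. Exact enumeration for
# n <= exact_max without ties or zeros; otherwise normal approximation with
# continuity correction. Zero differences are dropped (Wilcoxon's
# convention) or kept in the ranking (Pratt).
signed_rank_p <- function(x, y, exact_max = 25,
                          zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- x - y
  if (all(d == 0)) return(1)
  if (zero_method == "wilcoxon") {
    n <- sum(d != 0)
    exact <- n <= exact_max && !any(duplicated(abs(d[d != 0])))
    suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                         correct = TRUE)$p.value)
  } else {
    # Pratt: rank |d| including zeros, then drop the zero ranks from W.
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    nz <- d != 0
    mu <- (sum(r[nz])) / 2
    ties <- table(r[nz])
    sigma2 <- sum(r[nz]^2) / 4
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
}

#' Median-RAD matrix across all time-point pairs
#'
#' For each of the 15 ordered time-point pairs: the median RAD across
#' pairwise-complete participants, a two-sided Wilcoxon signed-rank test of
#' the paired abundances, and Benjamini-Yekutieli adjustment across exactly
#' the tested cells. The matrix is oriented so that entry `[t1, t2]` (t1
#' earlier) is positive when the taxon is more abundant at `t2`. Cells with
#' fewer than `min_n` complete pairs are left untested (`NA`).
#'
#' @inheritParams compute_rads
#' @param arm optional arm filter.
#' @param min_n minimum number of complete pairs to test a cell (default 2).
#' @param zero_method handling of zero paired differences: drop them
#'   (`"wilcoxon"`, the default) or keep them in the ranking (`"pratt"`).
#' @return A `rad_matrix` object: list with `taxon`, `arm`, 6x6 matrices
#'   `median_rad`, `n_pairs`, `p_raw`, `p_adjusted` (upper triangle filled,
#'   diagonal 0 for the median and untested).
#' @export
median_rad_matrix <- function(table, design, taxon, arm = NULL, min_n = 2,
                              zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  k <- length(TIMEPOINTS)
  tmpl <- matrix(NA_real_, k, k, dimnames = list(TIMEPOINTS, TIMEPOINTS))
  med <- tmpl; p <- tmpl
  np <- matrix(0L, k, k, dimnames = dimnames(tmpl))
  diag(med) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      obs <- compute_rads(table, design, taxon, TIMEPOINTS[i], TIMEPOINTS[j],
                          arm = arm)
      np[i, j] <- nrow(obs)
      if (nrow(obs) < min_n) next
      med[i, j] <- stats::median(obs$rad)
      p[i, j] <- signed_rank_p(obs$ra_to, obs$ra_from,
                               zero_method = zero_method)
    }
  }
  tested <- which(!is.na(p))
  padj <- tmpl
  if (length(tested)) padj[tested] <- by_adjust(p[tested])
  else warning("no testable time-point pair (all cells below min_n)")
  structure(list(taxon = taxon, arm = arm, timepoints = TIMEPOINTS,
                 median_rad = med, n_pairs = np, p_raw = p,
                 p_adjusted = padj, zero_method = zero_method),
            class = "rad_matrix")
}

#' @export
print.rad_matrix <- function(x, ...) {
  cat(sprintf("<rad_matrix> taxon %s%s\n", x$taxon,
              if (!is.null(x$arm)) paste0(", arm ", x$arm) else ""))
  cat("median RAD (upper triangle):\n")
  print(round(x$median_rad, 4))
  invisible(x)
}

#' @export
as.data.frame.rad_matrix <- function(x, ...) {
  k <- length(x$timepoints)
  idx <- which(upper.tri(x$median_rad), arr.ind = TRUE)
  data.frame(taxon = x$taxon,
             t1 = x$timepoints[idx[, 1]], t2 = x$timepoints[idx[, 2]],
             n = x$n_pairs[idx], estimate = x$median_rad[idx],
             p_raw = x$p_raw[idx], p_adj = x$p_adjusted[idx],
             stringsAsFactors = FALSE)
}

#' Hodges-Lehmann shift estimate between two samples
#'
#' The median of all `length(x) * length(y)` pairwise differences
#' `x_i - y_j` (mean of the two central order statistics for even counts):
#' the robust location-shift estimate naturally paired with the Wilcoxon
#' rank-sum test.
#'
#' @param x,y nonempty numeric vectors.
#' @return Numeric scalar estimate of the shift of `x` relative to `y`.
#' @export
hodges_lehmann <- function(x, y) {
  if (!length(x) || !length(y))
    vd_stop("both inputs must be nonempty", "vagidyn_validation_error")
  stats::median(as.vector(outer(x, y, "-")))
}

# Two-sided Wilcoxon rank-sum p; exact for small tie-free samples.
rank_sum_p <- function(x, y, exact_min = 10) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  if (length(unique(c(x, y))) == 1) return(1)  # no rank information at all
  exact <- min(length(x), length(y)) <= exact_min &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Differential RAD matrix between treatment arms
#'
#' For each time-point pair, compares the per-participant RADs of the
#' treatment arm with those of the placebo arm: the effect size is the
#' Hodges-Lehmann estimate of the between-arm difference, significance a
#' two-sided Wilcoxon rank-sum test, with Benjamini-Yekutieli adjustment
#' across the tested cells. Under the default `treatment_minus_placebo`
#' convention a positive estimate means the taxon increased more (or
#' decreased less) in the treatment arm; the opposite convention simply
#' negates the estimates and leaves the p-values unchanged.
#'
#' @inheritParams compute_rads
#' @param convention `"treatment_minus_placebo"` (default) or
#'   `"placebo_minus_treatment"`.
#' @param min_n minimum participants per arm for a cell to be tested.
#' @return A `differential_rad_matrix` object with 6x6 `hl_estimate`,
#'   `n_treatment`, `n_placebo`, `p_raw`, `p_adjusted`.
#' @export
differential_rad_matrix <- function(table, design, taxon,
                                    convention = c("treatment_minus_placebo",
                                                   "placebo_minus_treatment"),
                                    min_n = 1) {
  convention <- match.arg(convention)
  k <- length(TIMEPOINTS)
  tmpl <- matrix(NA_real_, k, k, dimnames = list(TIMEPOINTS, TIMEPOINTS))
  hl <- tmpl; p <- tmpl
  nt <- matrix(0L, k, k, dimnames = dimnames(tmpl))
  npl <- nt
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rt <- compute_rads(table, design, taxon, TIMEPOINTS[i], TIMEPOINTS[j],
                         arm = "treatment")$rad
      rp <- compute_rads(table, design, taxon, TIMEPOINTS[i], TIMEPOINTS[j],
                         arm = "placebo")$rad
      nt[i, j] <- length(rt); npl[i, j] <- length(rp)
      if (length(rt) < min_n || length(rp) < min_n) next
      est <- hodges_lehmann(rt, rp)
      if (convention == "placebo_minus_treatment") est <- -est
      hl[i, j] <- est
      p[i, j] <- rank_sum_p(rt, rp)
    }
  }
  tested <- which(!is.na(p))
  padj <- tmpl
  if (length(tested)) padj[tested] <- by_adjust(p[tested])
  structure(list(taxon = taxon, convention = convention,
                 timepoints = TIMEPOINTS, hl_estimate = hl,
                 n_treatment = nt, n_placebo = npl,
                 p_raw = p, p_adjusted = padj),
            class = "differential_rad_matrix")
}

#' @export
print.differential_rad_matrix <- function(x, ...) {
  cat(sprintf("<differential_rad_matrix> taxon %s (%s)\n", x$taxon,
              x$convention))
  print(round(x$hl_estimate, 4))
  invisible(x)
}

#' @export
as.data.frame.differential_rad_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$hl_estimate), arr.ind = TRUE)
  data.frame(taxon = x$taxon,
             t1 = x$timepoints[idx[, 1]], t2 = x$timepoints[idx[, 2]],
             n_treatment = x$n_treatment[idx], n_placebo = x$n_placebo[idx],
             estimate = x$hl_estimate[idx],
             p_raw = x$p_raw[idx], p_adj = x$p_adjusted[idx],
             stringsAsFactors = FALSE)
}

#' Cross-sectional comparison of arms at one time point
#'
#' Kruskal-Wallis rank test comparing a quantity between treatment groups
#' at a single visit (with two groups, asymptotically equivalent to the
#' Wilcoxon rank-sum test).
#'
#' @param x an [abundance_table()], or a numeric vector of values (with
#'   `groups` supplied).
#' @param ... passed to methods.
#' @return An object of class `htest` from [stats::kruskal.test()].
#' @export
cross_sectional_test <- function(x, ...) UseMethod("cross_sectional_test")

#' @rdname cross_sectional_test
#' @param groups group membership vector, same length as `x`; at least two
#'   groups, each nonempty.
#' @export
cross_sectional_test.default <- function(x, groups, ...) {
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) == 0))
    vd_stop("need >= 2 nonempty groups", "vagidyn_validation_error")
  stats::kruskal.test(x, g)
}

#' @rdname cross_sectional_test
#' @param design a [study_design()].
#' @param taxon taxon id present in the table.
#' @param timepoint one of the canonical time points.
#' @export
cross_sectional_test.abundance_table <- function(x, design, taxon,
                                                 timepoint, ...) {
  stopifnot(inherits(design, "study_design"))
  if (!timepoint %in% TIMEPOINTS)
    vd_stop("unknown time point", "vagidyn_usage_error")
  ra <- taxon_row(x, taxon)
  des <- as.data.frame(design)
  des <- des[des$timepoint == timepoint & des$sample_id %in% names(ra), ]
  cross_sectional_test(unname(ra[des$sample_id]), des$arm)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false discovery rate control valid under arbitrary dependence:
#' the Benjamini-Hochberg procedure inflated by the harmonic-number
#' constant `c(m) = sum(1/(1:m))`. Adjusted values dominate the raw ones
#' elementwise and are capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    vd_stop("p-values must lie in [0, 1]", "vagidyn_validation_error")
  stats::p.adjust(p, method = "BY")
}
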