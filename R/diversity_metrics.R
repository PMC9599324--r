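# Alpha diversity, Bray-Curtis dissimilarity, baseline-referenced beta
# diversity, and the neighbour-distance-minimizing sample ordering.

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` over the positive entries of a relative abundance
#' vector: the effective number of equally abundant taxa. Ranges from 1
#' (single taxon) to the number of positive taxa (perfect evenness).
#'
#' @param composition relative abundance vector summing to 1.
#' @return Numeric scalar >= 1.
#' @export
inverse_simpson <- function(composition) {
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-6)
    vd_stop("composition must be nonnegative and sum to 1",
            "vagidyn_validation_error")
  1 / sum(composition[composition > 0]^2)
}

#' Taxon richness
#'
#' Number of taxa observed (count > 0). Only defined on counts: richness on
#' relative abundances would silently confound sequencing depth.
#'
#' @param counts integer count vector for one sample.
#' @return Integer richness.
#' @export
richness <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    vd_stop("richness requires a counts-mode vector",
            "vagidyn_validation_error")
  sum(counts > 0)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' For relative abundance vectors on the same taxon universe this equals
#' half the L1 distance, bounded in `[0, 1]`. A semimetric: symmetric with
#' zero self-distance, but no triangle inequality.
#'
#' @param x,y named relative abundance vectors over the same taxa.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y) ||
      (!is.null(names(x)) && !is.null(names(y)) &&
       !identical(sort(names(x)), sort(names(y)))))
    vd_stop("samples must share one taxon universe",
            "vagidyn_validation_error")
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  if (abs(sum(x) - 1) > 1e-6 || abs(sum(y) - 1) > 1e-6 ||
      any(x < 0) || any(y < 0))
    vd_stop("inputs must be relative abundances summing to 1",
            "vagidyn_validation_error")
  sum(abs(x - y)) / 2
}

#' Bray-Curtis distance matrix of a relative table
#'
#' @param table relative-mode [abundance_table()].
#' @return Symmetric matrix of pairwise dissimilarities with zero diagonal,
#'   sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative")
    vd_stop("Bray-Curtis requires a relative table", "vagidyn_usage_error")
  d <- as.matrix(stats::dist(t(table$values), method = "manhattan")) / 2
  dimnames(d) <- list(colnames(table$values), colnames(table$values))
  d
}

# Exact minimum-cost Hamiltonian path via Held-Karp dynamic programming.
# Feasible up to ~10 samples; returns 1-based vertex order.
held_karp_path <- function(d) {
  n <- nrow(d)
  if (n == 1) return(1L)
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, nrow = full, ncol = n)
  par <- matrix(NA_integer_, nrow = full, ncol = n)
  for (i in seq_len(n)) dp[bitwShiftL(1L, i - 1L), i] <- 0
  for (mask in seq_len(full)) {
    for (i in seq_len(n)) {
      if (!bitwAnd(mask, bitwShiftL(1L, i - 1L)) || !is.finite(dp[mask, i]))
        next
      for (j in seq_len(n)) {
        bj <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bj)) next
        nm <- bitwOr(mask, bj)
        cand <- dp[mask, i] + d[i, j]
        if (cand < dp[nm, j]) {
          dp[nm, j] <- cand
          par[nm, j] <- i
        }
      }
    }
  }
  last <- which.min(dp[full, ])
  path <- integer(n)
  mask <- full
  for (k in n:1) {
    path[k] <- last
    prev <- par[mask, last]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, last - 1L)))
    last <- prev
  }
  path
}

path_cost <- function(d, ord) {
  if (length(ord) < 2) return(0)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# Greedy nearest-neighbour from every start, then 2-opt refinement
# (segment reversal) until no improving move remains.
greedy_two_opt <- function(d) {
  n <- nrow(d)
  best <- NULL; best_cost <- Inf
  for (s in seq_len(n)) {
    ord <- integer(n); used <- logical(n)
    ord[1] <- s; used[s] <- TRUE
    for (k in 2:n) {
      cand <- d[ord[k - 1], ]
      cand[used] <- Inf
      ord[k] <- which.min(cand)
      used[ord[k]] <- TRUE
    }
    cost <- path_cost(d, ord)
    if (cost < best_cost) { best <- ord; best_cost <- cost }
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # reversing ord[i..j] only changes the two boundary edges
        delta <- 0
        if (i > 1) delta <- delta + d[best[i - 1], best[j]] -
            d[best[i - 1], best[i]]
        if (j < n) delta <- delta + d[best[i], best[j + 1]] -
            d[best[j], best[j + 1]]
        if (delta < -1e-12) {
          best[i:j] <- best[j:i]
          best_cost <- best_cost + delta
          improved <- TRUE
        }
      }
    }
  }
  best
}

#' Order samples by minimizing neighbour Bray-Curtis distance
#'
#' Finds a Hamiltonian-path ordering of the samples that minimizes the sum
#' of Bray-Curtis distances between adjacent samples — the ordering used to
#' lay out community composition bar plots so that similar samples sit next
#' to each other. Exact (Held-Karp dynamic programming) for up to `exact_n`
#' samples; beyond that, greedy nearest-neighbour from the best start
#' refined by 2-opt. A path and its reversal are equivalent, so the
#' orientation with the lexicographically smaller first sample id is
#' returned; the result is deterministic.
#'
#' @param table relative-mode [abundance_table()].
#' @param exact_n largest sample count solved exactly (default 10).
#' @return Character vector: sample ids in visiting order.
#' @export
order_by_neighbor_distance <- function(table, exact_n = 10) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- colnames(table$values)
  n <- length(ids)
  if (n <= 2) return(ids[order(ids)[seq_len(n)]])
  d <- bray_curtis_matrix(table)
  ord <- if (n <= exact_n) held_karp_path(d) else greedy_two_opt(d)
  if (ids[ord[length(ord)]] < ids[ord[1]]) ord <- rev(ord)
  ids[ord]
}

#' Bray-Curtis distance to each participant's baseline sample
#'
#' For every sample, the Bray-Curtis dissimilarity to the V1 (baseline)
#' sample of the same participant; the V1 sample itself maps to 0.
#' Participants without a V1 sample get `NA` with a warning.
#'
#' @param table relative-mode [abundance_table()].
#' @param design a [study_design()].
#' @return Data frame with columns `sample_id`, `participant_id`,
#'   `timepoint`, `bc_to_baseline`.
#' @export
distance_to_baseline <- function(table, design) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "study_design"))
  if (table$mode != "relative")
    vd_stop("distance_to_baseline requires a relative table",
            "vagidyn_usage_error")
  des <- as.data.frame(design)
  des <- des[des$sample_id %in% colnames(table$values), , drop = FALSE]
  base <- des$sample_id[des$timepoint == "V1"]
  names(base) <- des$participant_id[des$timepoint == "V1"]
  vals <- vapply(seq_len(nrow(des)), function(k) {
    b <- base[des$participant_id[k]]
    if (is.na(b)) return(NA_real_)
    bray_curtis(table$values[, des$sample_id[k]], table$values[, b])
  }, 0)
  if (anyNA(vals))
    warning(sprintf("%d sample(s) have no V1 baseline; distance set to NA",
                    sum(is.na(vals))))
  data.frame(sample_id = des$sample_id, participant_id = des$participant_id,
             timepoint = as.character(des$timepoint),
             bc_to_baseline = vals, stringsAsFactors = FALSE)
}

#' Per-sample diversity table
#'
#' Inverse Simpson (on ASV-level relative abundances), richness (on ASV
#' counts) and Bray-Curtis distance to the participant's baseline, in one
#' data frame.
#'
#' @param counts counts-mode ASV-level [abundance_table()].
#' @param design a [study_design()].
#' @return Data frame with columns `sample_id`, `participant_id`,
#'   `timepoint`, `inv_simpson`, `richness`, `bc_to_baseline`.
#' @export
diversity_table <- function(counts, design) {
  stopifnot(inherits(counts, "abundance_table"))
  if (counts$mode != "counts")
    vd_stop("diversity_table expects a counts table", "vagidyn_usage_error")
  rel <- to_relative(counts)
  base <- distance_to_baseline(rel, design)
  base$inv_simpson <- vapply(base$sample_id, function(s)
    inverse_simpson(rel$values[, s]), 0)
  base$richness <- vapply(base$sample_id, function(s)
    richness(counts$values[, s]), 0L)
  base[, c("sample_id", "participant_id", "timepoint", "inv_simpson",
           "richness", "bc_to_baseline")]
}
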