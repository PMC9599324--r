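# End-to-end orchestration: simulate or load a cohort, type communities,
# compute diversity, RAD and differential-RAD matrices, score qPCR
# concordance, and write a reproducible report bundle.

#' Pipeline run configuration
#'
#' Either simulates a cohort (`simulate = TRUE`, using `cohort`) or reads
#' input files (`counts_path`, `taxonomy_path`, `metadata_path`, optional
#' `qpcr_path`).
#'
#' @param simulate generate a synthetic cohort instead of reading files.
#' @param cohort a [cohort_config()] used when `simulate = TRUE`.
#' @param counts_path,taxonomy_path,metadata_path,qpcr_path input TSVs used
#'   when `simulate = FALSE` (`qpcr_path` optional).
#' @param rad_taxa taxa for which RAD and differential-RAD matrices are
#'   computed; genus-level names use the genus aggregation, subgenus-group
#'   names the subgenus aggregation.
#' @param convention sign convention of the differential matrices.
#' @param inclusive_thresholds use `>=` instead of `>` in the dominance
#'   rules.
#' @param alpha significance level for counting significant cells.
#' @param seed integer seed (forwarded to the simulation).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, cohort = cohort_config(),
                       counts_path = NULL, taxonomy_path = NULL,
                       metadata_path = NULL, qpcr_path = NULL,
                       rad_taxa = c("Lactobacillus", "L_crispatus_group",
                                    "L_iners_group", "Gardnerella",
                                    "Prevotella", "Streptococcus"),
                       convention = c("treatment_minus_placebo",
                                      "placebo_minus_treatment"),
                       inclusive_thresholds = FALSE,
                       alpha = 0.05, seed = 1L) {
  convention <- match.arg(convention)
  if (alpha <= 0 || alpha >= 1)
    vd_stop("alpha must lie in (0, 1)", "vagidyn_validation_error")
  if (!length(rad_taxa))
    vd_stop("rad_taxa must be nonempty", "vagidyn_validation_error")
  if (!simulate && (is.null(counts_path) || is.null(metadata_path)))
    vd_stop("counts_path and metadata_path are required unless simulating",
            "vagidyn_validation_error")
  if (simulate) cohort$seed <- as.integer(seed)
  structure(list(simulate = simulate, cohort = cohort,
                 counts_path = counts_path, taxonomy_path = taxonomy_path,
                 metadata_path = metadata_path, qpcr_path = qpcr_path,
                 rad_taxa = rad_taxa, convention = convention,
                 inclusive_thresholds = inclusive_thresholds,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `cohort` key
#' holds [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- cohort
  do.call(run_config, args)
}

shift_distribution <- function(shifts) {
  brk <- cut(shifts$n_transitions, c(-1, 0, 1, 2, Inf),
             labels = c("0", "1", "2", "3+"))
  cnt <- table(brk)
  data.frame(n_shifts = names(cnt), count = as.integer(cnt),
             total = nrow(shifts),
             percent = report_percent(as.integer(cnt), nrow(shifts)),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> aggregate -> classify -> shifts & prevalence ->
#' diversity -> RAD matrices -> differential RAD -> qPCR concordance, then
#' write `labels.tsv`, `shifts.tsv`, `prevalence.tsv`, `diversity.tsv`,
#' `baseline_order.txt`, per-taxon `rad_*.tsv` / `rad_diff_*.tsv`,
#' `concordance.tsv` and a consolidated `report.json`. Identical config and
#' seed produce a byte-identical bundle.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the bundle.
#' @return Invisibly, a list with all intermediate results and the report.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$simulate) {
    cohort <- generate_cohort(config$cohort)
    counts <- cohort$counts
    design <- cohort$design
    qpcr <- cohort$qpcr
  } else {
    counts <- read_count_table(config$counts_path, config$taxonomy_path)
    design <- read_metadata(config$metadata_path)
    qpcr <- if (!is.null(config$qpcr_path)) read_qpcr(config$qpcr_path)
    cohort <- NULL
  }

  rel_sub <- to_relative(aggregate_taxa(counts, "subgenus_group"))
  rel_gen <- to_relative(aggregate_taxa(counts, "genus"))

  labels <- classify_cohort(rel_sub, design,
                            inclusive = config$inclusive_thresholds)
  shifts <- cohort_shifts(labels)
  prevalence <- rbind(
    cbind(arm = "combined", dominance_prevalence(labels)),
    dominance_prevalence(labels, stratify_by_arm = TRUE))
  diversity <- diversity_table(counts, design)

  # neighbour-distance ordering of the baseline samples, as used to lay
  # out the baseline composition figure
  v1 <- design$sample_id[design$timepoint == "V1"]
  rel_asv <- to_relative(counts)
  v1_table <- abundance_table(rel_asv$values[, v1, drop = FALSE],
                              mode = "relative",
                              taxonomy = rel_asv$taxonomy)
  baseline_order <- order_by_neighbor_distance(v1_table)

  pick_table <- function(taxon) {
    if (taxon %in% rownames(rel_gen$values) &&
        !taxon %in% rownames(rel_sub$values)) rel_gen else rel_sub
  }
  rad <- lapply(config$rad_taxa, function(tx)
    median_rad_matrix(pick_table(tx), design, tx))
  names(rad) <- config$rad_taxa
  rad_diff <- lapply(config$rad_taxa, function(tx)
    differential_rad_matrix(pick_table(tx), design, tx,
                            convention = config$convention))
  names(rad_diff) <- config$rad_taxa

  conc <- if (!is.null(qpcr)) concordance(labels, predict_groups_from_qpcr(qpcr))

  n_sig <- vapply(rad, function(m)
    sum(m$p_adjusted < config$alpha, na.rm = TRUE), 0L)
  n_sig_diff <- vapply(rad_diff, function(m)
    sum(m$p_adjusted < config$alpha, na.rm = TRUE), 0L)

  report <- list(
    seed = config$seed,
    alpha = config$alpha,
    n_samples = nrow(design),
    n_participants = length(unique(design$participant_id)),
    stable_count = sum(shifts$stable),
    stable_percent = report_percent(sum(shifts$stable), nrow(shifts)),
    shifted_percent = report_percent(sum(!shifts$stable), nrow(shifts)),
    shift_distribution = shift_distribution(shifts),
    prevalence = prevalence,
    significant_rad_cells = as.list(n_sig),
    significant_differential_cells = as.list(n_sig_diff),
    differential_convention = config$convention,
    qpcr_agreement = if (!is.null(conc)) conc$agreement_fraction,
    qpcr_no_call = if (!is.null(conc)) conc$n_no_call)

  bundle <- list(config = config, cohort = cohort, counts = counts,
                 design = design, qpcr = qpcr, labels = labels,
                 shifts = shifts, prevalence = prevalence,
                 diversity = diversity, baseline_order = baseline_order,
                 rad = rad, rad_diff = rad_diff, concordance = conc,
                 report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(labels, "labels.tsv")
    wt(shifts, "shifts.tsv")
    wt(prevalence, "prevalence.tsv")
    wt(diversity, "diversity.tsv")
    writeLines(baseline_order, file.path(out_dir, "baseline_order.txt"))
    for (tx in config$rad_taxa) {
      wt(as.data.frame(rad[[tx]]), sprintf("rad_%s.tsv", tx))
      wt(as.data.frame(rad_diff[[tx]]), sprintf("rad_diff_%s.tsv", tx))
    }
    if (!is.null(conc))
      wt(as.data.frame(conc$confusion), "concordance.tsv")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(bundle)
}
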