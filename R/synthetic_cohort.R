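# Synthetic longitudinal cohort generator: Dirichlet-multinomial communities
# with menstrual and treatment perturbations on the logit scale.

#' Community archetype specification
#'
#' @param name archetype label.
#' @param base_composition named vector of mean relative abundances over the
#'   taxon universe; must sum to 1.
#' @param dirichlet_concentration positive scalar controlling
#'   between-participant variability around the archetype mean (larger =
#'   tighter).
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(name, base_composition, dirichlet_concentration) {
  if (abs(sum(base_composition) - 1) > 1e-9 || any(base_composition < 0))
    vd_stop(sprintf("archetype '%s': base composition must be a point on the simplex",
                    name), "vagidyn_validation_error")
  if (dirichlet_concentration <= 0)
    vd_stop("dirichlet_concentration must be positive",
            "vagidyn_validation_error")
  structure(list(name = name, base_composition = base_composition,
                 dirichlet_concentration = dirichlet_concentration),
            class = "archetype_spec")
}

# Taxon universe of the generator, at subgenus-group/genus resolution.
SIM_TAXA <- c(LACTO_GROUPS, "Gardnerella", "Prevotella", "Streptococcus",
              "Bifidobacterium")

sim_base <- function(...) {
  v <- c(...)
  stopifnot(abs(sum(v) - 1) < 1e-9)
  names(v) <- SIM_TAXA
  v
}

default_archetypes <- function(concentration = 60) {
  list(
    crispatus = archetype_spec("crispatus",
      sim_base(0.82, 0.05, 0.01, 0.01, 0.005, 0.025, 0.03, 0.03, 0.02),
      concentration),
    iners = archetype_spec("iners",
      sim_base(0.05, 0.82, 0.01, 0.01, 0.005, 0.025, 0.03, 0.03, 0.02),
      concentration),
    codominant = archetype_spec("codominant",
      sim_base(0.38, 0.38, 0.02, 0.01, 0.005, 0.06, 0.06, 0.05, 0.035),
      concentration),
    other_lacto = archetype_spec("other_lacto",
      sim_base(0.08, 0.08, 0.65, 0.05, 0.01, 0.04, 0.04, 0.04, 0.01),
      concentration),
    non_lacto = archetype_spec("non_lacto",
      sim_base(0.08, 0.12, 0.03, 0.02, 0.01, 0.24, 0.22, 0.15, 0.13),
      concentration)
  )
}

# Within-group splits of subgenus groups into ASVs (crispatus is carried by
# three ASVs, as commonly observed; the rest by one each).
SIM_ASV_SPLIT <- list(
  L_crispatus_group = c(Lactobacillus_ASV_2 = 0.6, Lactobacillus_ASV_4 = 0.3,
                        Lactobacillus_ASV_6 = 0.1),
  L_iners_group     = c(Lactobacillus_ASV_1 = 1),
  L_gasseri_group   = c(Lactobacillus_ASV_3 = 1),
  L_jensenii_group  = c(Lactobacillus_ASV_5 = 1),
  L_pasteurii_group = c(Lactobacillus_ASV_7 = 1),
  Gardnerella       = c(Gardnerella_ASV_1 = 1),
  Prevotella        = c(Prevotella_ASV_1 = 1),
  Streptococcus     = c(Streptococcus_ASV_1 = 1),
  Bifidobacterium   = c(Bifidobacterium_ASV_1 = 1)
)

sim_taxonomy <- function() {
  rows <- lapply(names(SIM_ASV_SPLIT), function(g) {
    asvs <- names(SIM_ASV_SPLIT[[g]])
    lacto <- g %in% LACTO_GROUPS
    data.frame(taxon_id = asvs,
               genus = if (lacto) "Lactobacillus" else g,
               subgenus_group = if (lacto) g else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the design of the motivating trial: 18 placebo and 34
#' probiotic participants sampled at the six canonical time points, with
#' archetype frequencies matching the observed baseline community types
#' (15/52 crispatus-dominated, 15/52 iners-dominated, 12/52 codominant,
#' 3/52 other-Lactobacillus, 7/52 non-Lactobacillus), a post-menstrual
#' drop of the L. crispatus group at V1 and V2 (logit shift -0.5, about a
#' 7-12 percentage-point drop over the typical abundance range) with a
#' concomitant rise of Gardnerella and Streptococcus, about 4% missing
#' samples, and qPCR loads centred on ~10^9.8 CFU/mL.
#'
#' @param n_placebo,n_treatment participants per arm.
#' @param archetype_probabilities named probabilities over the five
#'   archetypes; must sum to 1.
#' @param archetypes list of [archetype_spec()]s (defaults cover the five
#'   community types).
#' @param menses_effect_crispatus additive logit shift (<= 0) applied to the
#'   L. crispatus group at V1 and V2.
#' @param menses_effect_pathobiont additive logit shift (>= 0) applied
#'   jointly to Gardnerella and Streptococcus at V1 and V2.
#' @param treatment_effect_lactobacillus logit shift applied to the summed
#'   Lactobacillus mass in the treatment arm at every post-baseline time
#'   point (supplementation starts right after the V1 swab).
#' @param treatment_effect_prevotella logit shift applied to Prevotella in
#'   the treatment arm post-baseline.
#' @param read_depth multinomial reads per sample (>= 100).
#' @param missing_rate independent per-sample dropout probability in
#'   `[0, 1)`; a participant's series is never deleted entirely (the V1
#'   sample is retained if all six would drop).
#' @param within_concentration Dirichlet concentration for time-point-level
#'   variability around each participant's personal composition.
#' @param arm_archetype_bias log-odds bias (>= 0) reproducing the baseline
#'   confound of the motivating study: placebo assignment is tilted toward
#'   the crispatus archetype and treatment toward iners.
#' @param total_load_log10_mean,total_load_log10_sd lognormal parameters of
#'   the per-sample total bacterial load (CFU/mL) used for qPCR simulation.
#' @param qpcr_noise_log10_sd multiplicative measurement noise of the qPCR
#'   panel, on the log10 scale.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_placebo = 18, n_treatment = 34,
                          archetype_probabilities = c(
                            crispatus = 15, iners = 15, codominant = 12,
                            other_lacto = 3, non_lacto = 7) / 52,
                          archetypes = default_archetypes(),
                          menses_effect_crispatus = -0.5,
                          menses_effect_pathobiont = 0.4,
                          treatment_effect_lactobacillus = 0,
                          treatment_effect_prevotella = 0,
                          read_depth = 10000,
                          missing_rate = 11 / 312,
                          within_concentration = 150,
                          arm_archetype_bias = 0,
                          total_load_log10_mean = 9.8,
                          total_load_log10_sd = 0.5,
                          qpcr_noise_log10_sd = 0.2,
                          seed = 1L) {
  cfg <- list(n_placebo = n_placebo, n_treatment = n_treatment,
              archetype_probabilities = archetype_probabilities,
              archetypes = archetypes,
              menses_effect_crispatus = menses_effect_crispatus,
              menses_effect_pathobiont = menses_effect_pathobiont,
              treatment_effect_lactobacillus = treatment_effect_lactobacillus,
              treatment_effect_prevotella = treatment_effect_prevotella,
              read_depth = read_depth, missing_rate = missing_rate,
              within_concentration = within_concentration,
              arm_archetype_bias = arm_archetype_bias,
              total_load_log10_mean = total_load_log10_mean,
              total_load_log10_sd = total_load_log10_sd,
              qpcr_noise_log10_sd = qpcr_noise_log10_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_placebo + cfg$n_treatment < 2)
    vd_stop("need at least 2 participants", "vagidyn_validation_error")
  if (abs(sum(cfg$archetype_probabilities) - 1) > 1e-9 ||
      any(cfg$archetype_probabilities < 0))
    vd_stop("archetype probabilities must be nonnegative and sum to 1",
            "vagidyn_validation_error")
  if (!setequal(names(cfg$archetype_probabilities), names(cfg$archetypes)))
    vd_stop("archetype probabilities must match the archetype set",
            "vagidyn_validation_error")
  if (cfg$read_depth < 100)
    vd_stop("read_depth must be >= 100", "vagidyn_validation_error")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    vd_stop("missing_rate must be in [0, 1)", "vagidyn_validation_error")
  if (cfg$menses_effect_crispatus > 0)
    vd_stop("menses_effect_crispatus must be <= 0", "vagidyn_validation_error")
  if (cfg$menses_effect_pathobiont < 0)
    vd_stop("menses_effect_pathobiont must be >= 0",
            "vagidyn_validation_error")
  if (cfg$within_concentration <= 0 || cfg$qpcr_noise_log10_sd < 0 ||
      cfg$total_load_log10_sd < 0 || cfg$arm_archetype_bias < 0)
    vd_stop("invalid noise/concentration parameter",
            "vagidyn_validation_error")
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  p <- g / sum(g)
  names(p) <- names(alpha)
  p
}

#' Shift a taxon's relative abundance on the logit scale
#'
#' The target abundance `p` becomes `plogis(qlogis(p) + delta)`; all other
#' taxa are rescaled proportionally so the composition stays on the simplex.
#' If `taxon` names several taxa their summed mass is shifted and the
#' members keep their relative proportions.
#'
#' @param composition named relative abundance vector summing to 1.
#' @param taxon taxon name(s) present in `composition`.
#' @param delta additive shift on the logit scale.
#' @return Shifted composition, summing to 1.
#' @export
apply_logit_shift <- function(composition, taxon, delta) {
  if (abs(sum(composition) - 1) > 1e-6)
    vd_stop("composition must sum to 1", "vagidyn_validation_error")
  if (!all(taxon %in% names(composition)))
    vd_stop(sprintf("taxon '%s' absent from composition",
                    setdiff(taxon, names(composition))[1]),
            "vagidyn_degenerate_error")
  idx <- names(composition) %in% taxon
  p <- sum(composition[idx])
  if (p <= 0 || p >= 1)
    vd_stop("target abundance must lie strictly inside (0, 1)",
            "vagidyn_degenerate_error")
  if (delta == 0) return(composition)
  p2 <- stats::plogis(stats::qlogis(p) + delta)
  out <- composition
  out[idx] <- composition[idx] * (p2 / p)
  out[!idx] <- composition[!idx] * ((1 - p2) / (1 - p))
  out
}

#' Generate a synthetic longitudinal cohort
#'
#' Per participant: an archetype is drawn, a personal base composition is
#' drawn from a Dirichlet around the archetype mean, and each time point
#' draws a fresh Dirichlet composition around that base. Menstrual effects
#' (crispatus down, Gardnerella/Streptococcus up) act at V1 and V2 only;
#' treatment effects act in the treatment arm at post-baseline time points.
#' Reads are multinomial at `read_depth`; samples drop out independently at
#' `missing_rate`; qPCR concentrations are total load times species
#' abundance times lognormal noise.
#'
#' Each participant consumes an RNG stream derived from `(seed,
#' participant index)`, so a participant's draws do not depend on the
#' others. The caller's RNG state is left untouched. Identical configs give
#' bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return List with elements `counts` (ASV-level counts
#'   [abundance_table()]), `design` ([study_design()]), `qpcr`
#'   ([qpcr_panel()]) and `truth` (per-sample latent compositions,
#'   archetypes and latent dominance labels, including dropped samples
#'   flagged by `retained`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_placebo + config$n_treatment
  pid <- sprintf("P%03d", seq_len(n))
  arm <- rep(ARMS, c(config$n_placebo, config$n_treatment))
  anames <- names(config$archetype_probabilities)
  asv_ids <- unlist(lapply(SIM_ASV_SPLIT, names), use.names = FALSE)

  meta <- list(); truth <- list(); qpcr <- list()
  counts <- matrix(0L, nrow = length(asv_ids), ncol = 0,
                   dimnames = list(asv_ids, NULL))
  cmat <- list()

  for (i in seq_len(n)) {
    child <- (as.numeric(config$seed) * 65537 + i * 97561) %% 2147483647
    res <- with_local_seed(child, {
      probs <- config$archetype_probabilities
      if (config$arm_archetype_bias > 0) {
        w <- rep(1, length(probs)); names(w) <- anames
        if (arm[i] == "placebo") w["crispatus"] <- exp(config$arm_archetype_bias)
        else w["iners"] <- exp(config$arm_archetype_bias)
        probs <- probs * w / sum(probs * w)
      }
      atype <- sample(anames, 1, prob = probs)
      spec <- config$archetypes[[atype]]
      base <- rdirichlet1(spec$dirichlet_concentration *
                            spec$base_composition)
      samples <- vector("list", length(TIMEPOINTS))
      for (t in seq_along(TIMEPOINTS)) {
        tp <- TIMEPOINTS[t]
        comp <- rdirichlet1(config$within_concentration * base)
        if (tp %in% c("V1", "V2")) {
          if (config$menses_effect_crispatus != 0)
            comp <- apply_logit_shift(comp, "L_crispatus_group",
                                      config$menses_effect_crispatus)
          if (config$menses_effect_pathobiont != 0)
            comp <- apply_logit_shift(comp, c("Gardnerella", "Streptococcus"),
                                      config$menses_effect_pathobiont)
        }
        if (arm[i] == "treatment" && tp != "V1") {
          if (config$treatment_effect_lactobacillus != 0)
            comp <- apply_logit_shift(comp, LACTO_GROUPS,
                                      config$treatment_effect_lactobacillus)
          if (config$treatment_effect_prevotella != 0)
            comp <- apply_logit_shift(comp, "Prevotella",
                                      config$treatment_effect_prevotella)
        }
        asv_comp <- unlist(lapply(names(SIM_ASV_SPLIT), function(g)
          comp[[g]] * SIM_ASV_SPLIT[[g]]))
        names(asv_comp) <- asv_ids
        cnt <- as.integer(stats::rmultinom(1, config$read_depth, asv_comp))
        load <- 10^stats::rnorm(1, config$total_load_log10_mean,
                                config$total_load_log10_sd)
        conc <- load * comp[QPCR_SPECIES_GROUP] *
          10^stats::rnorm(length(QPCR_SPECIES), 0, config$qpcr_noise_log10_sd)
        samples[[t]] <- list(comp = comp, counts = cnt, conc = unname(conc))
      }
      drop <- stats::runif(length(TIMEPOINTS)) < config$missing_rate
      if (all(drop)) drop[1] <- FALSE
      list(atype = atype, samples = samples, drop = drop)
    })

    for (t in seq_along(TIMEPOINTS)) {
      sid <- paste0(pid[i], "_", TIMEPOINTS[t])
      s <- res$samples[[t]]
      truth[[sid]] <- data.frame(
        sample_id = sid, participant_id = pid[i], arm = arm[i],
        timepoint = TIMEPOINTS[t], archetype = res$atype,
        retained = !res$drop[t],
        latent_group = classify_sample(s$comp),
        t(s$comp), check.names = FALSE, stringsAsFactors = FALSE)
      if (res$drop[t]) next
      meta[[sid]] <- data.frame(
        sample_id = sid, participant_id = pid[i], arm = arm[i],
        timepoint = TIMEPOINTS[t],
        day = unname(TIMEPOINT_DAYS[TIMEPOINTS[t]]),
        stringsAsFactors = FALSE)
      cmat[[sid]] <- s$counts
      qpcr[[sid]] <- data.frame(sample_id = sid, taxon = QPCR_SPECIES,
                                cfu_per_ml = s$conc,
                                stringsAsFactors = FALSE)
    }
  }

  values <- do.call(cbind, cmat)
  dimnames(values) <- list(asv_ids, names(cmat))
  list(counts = abundance_table(values, mode = "counts",
                                taxonomy = sim_taxonomy()),
       design = study_design(do.call(rbind, meta)),
       qpcr = qpcr_panel(do.call(rbind, qpcr)),
       truth = {
         tr <- do.call(rbind, truth); rownames(tr) <- NULL; tr
       })
}

#' Write a simulated cohort to a directory
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `qpcr.tsv` and
#' `truth.tsv` in the formats the readers of this package expect.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  tx <- cohort$counts$taxonomy
  utils::write.table(
    data.frame(asv_id = tx$taxon_id, genus = tx$genus,
               subgenus_group = ifelse(is.na(tx$subgenus_group), "",
                                       tx$subgenus_group)),
    file.path(dir, "taxonomy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$design),
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$qpcr), file.path(dir, "qpcr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
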