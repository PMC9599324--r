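test_that("dominance rules classify the canonical cases", {
  expect_equal(classify_sample(c(L_crispatus_group = 0.60,
                                 L_iners_group = 0.05,
                                 Gardnerella = 0.35)),
               "CRISPATUS_DOM")
  expect_equal(classify_sample(c(L_crispatus_group = 0.35,
                                 L_iners_group = 0.30,
                                 Gardnerella = 0.35)),
               "CRISP_INERS_CODOM")
  expect_equal(classify_sample(c(Gardnerella = 0.45,
                                 L_crispatus_group = 0.30,
                                 Prevotella = 0.25)),
               "NON_LACTO")
  # codominance takes precedence over single dominance
  expect_equal(classify_sample(c(L_crispatus_group = 0.45,
                                 L_iners_group = 0.12,
                                 Gardnerella = 0.43)),
               "CRISP_INERS_CODOM")
  # gasseri/jensenii/pasteurii merge into one group
  expect_equal(classify_sample(c(L_gasseri_group = 0.50,
                                 L_crispatus_group = 0.30,
                                 Gardnerella = 0.20)),
               "OTHER_LACTO_DOM")
  expect_equal(classify_sample(c(L_jensenii_group = 0.41,
                                 Prevotella = 0.59)),
               "NON_LACTO")  # jensenii not the top taxon
  # nothing above 40%: not Lactobacillus dominated
  expect_equal(classify_sample(c(L_crispatus_group = 0.35,
                                 Gardnerella = 0.35,
                                 Prevotella = 0.30)),
               "NON_LACTO")
})

test_that("thresholds are strict by default and inclusive on demand", {
  # exactly 40% does not dominate ("exceeded")
  x <- c(L_crispatus_group = 0.40, L_iners_group = 0.05, Gardnerella = 0.55)
  expect_equal(classify_sample(x), "NON_LACTO")
  expect_equal(classify_sample(x, inclusive = TRUE), "NON_LACTO")
  y <- c(L_crispatus_group = 0.40, L_iners_group = 0.05, Gardnerella = 0.30,
         Prevotella = 0.25)
  expect_equal(classify_sample(y), "NON_LACTO")
  expect_equal(classify_sample(y, inclusive = TRUE), "CRISPATUS_DOM")

  # exactly 10%/50% do not trigger codominance under strict reading
  z <- c(L_crispatus_group = 0.50, L_iners_group = 0.10, Gardnerella = 0.40)
  expect_equal(classify_sample(z), "CRISPATUS_DOM")
  expect_equal(classify_sample(z, inclusive = TRUE), "CRISP_INERS_CODOM")
  w <- c(L_crispatus_group = 0.30, L_iners_group = 0.20, Gardnerella = 0.50)
  expect_equal(classify_sample(w), "NON_LACTO")
  expect_equal(classify_sample(w, inclusive = TRUE), "CRISP_INERS_CODOM")
})

test_that("classification partitions the simplex and ignores taxon order", {
  taxa <- c(LACTO_GROUPS, "Gardnerella", "Prevotella", "Streptococcus")
  withr::with_seed(21, {
    for (i in 1:500) {
      p <- rsimplex(length(taxa))
      names(p) <- taxa
      lab <- classify_sample(p)
      expect_true(lab %in% DOMINANCE_GROUPS)
      shuffled <- p[sample(taxa)]
      expect_identical(classify_sample(shuffled), lab)
    }
  })
  expect_error(classify_sample(c(L_crispatus_group = 0.8)),
               class = "vagidyn_validation_error")
})

test_that("shift summaries count transitions and majority deviations", {
  s <- shift_summary(rep("A", 6))
  expect_equal(s$n_transitions, 0L)
  expect_equal(s$n_deviations, 0L)
  expect_true(s$stable)

  s <- shift_summary(c("A", "A", "B", "B", "B", "B"))
  expect_equal(s$n_transitions, 1L)
  expect_equal(s$n_deviations, 2L)
  expect_false(s$stable)

  # majority tie broken toward the earliest-occurring modal label
  s <- shift_summary(c("A", "B", "A", "B", "A", "B"))
  expect_equal(s$n_transitions, 5L)
  expect_equal(s$modal, "A")
  expect_equal(s$n_deviations, 3L)

  expect_error(shift_summary(character()),
               class = "vagidyn_validation_error")
})

test_that("transitions and deviations respect their structural bounds", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:6, 1)
      labs <- sample(DOMINANCE_GROUPS, n, replace = TRUE)
      s <- shift_summary(labs)
      expect_lte(s$n_transitions, n - 1)
      expect_lte(s$n_deviations, n - 1)
      expect_equal(s$stable,
                   s$n_transitions == 0 && s$n_deviations == 0)
    }
  })
})

test_that("cohort classification covers samples and matches archetypes", {
  # noise-free construction: archetype means classify as their own label
  co <- generate_cohort(cohort_config(seed = 13))
  rel <- to_relative(aggregate_taxa(co$counts, "subgenus_group"))
  lab <- classify_cohort(rel, co$design)
  expect_equal(nrow(lab), ncol(rel$values))
  expect_true(all(lab$group %in% DOMINANCE_GROUPS))
  expect_equal(lab$sample_id,
               lab$sample_id[order(lab$participant_id, lab$timepoint)])

  expected <- c(crispatus = "CRISPATUS_DOM", iners = "INERS_DOM",
                codominant = "CRISP_INERS_CODOM",
                other_lacto = "OTHER_LACTO_DOM", non_lacto = "NON_LACTO")
  for (a in names(expected)) {
    spec <- cohort_config()$archetypes[[a]]
    expect_equal(classify_sample(spec$base_composition),
                 unname(expected[a]))
  }

  d2 <- co$design[co$design$sample_id != colnames(rel$values)[1], ]
  class(d2) <- class(co$design)
  expect_error(classify_cohort(rel, d2), "absent from the study design",
               class = "vagidyn_validation_error")
})

test_that("archetype label frequencies recover the assignment weights", {
  cfg <- cohort_config(n_placebo = 100, n_treatment = 100,
                       menses_effect_crispatus = 0,
                       menses_effect_pathobiont = 0,
                       missing_rate = 0, seed = 77)
  co <- generate_cohort(cfg)
  rel <- to_relative(aggregate_taxa(co$counts, "subgenus_group"))
  lab <- classify_cohort(rel, co$design)
  freq <- table(factor(lab$group, DOMINANCE_GROUPS)) / nrow(lab)
  # observed label frequencies track the realized archetype draws closely
  # (typing on noisy compositions is ~95% pure per archetype)
  arch_freq <- table(co$truth$archetype[co$truth$timepoint == "V1"]) / 200
  map <- c(crispatus = "CRISPATUS_DOM", iners = "INERS_DOM",
           codominant = "CRISP_INERS_CODOM",
           other_lacto = "OTHER_LACTO_DOM", non_lacto = "NON_LACTO")
  for (a in names(map)) {
    expect_lt(abs(freq[[map[[a]]]] - arch_freq[[a]]), 0.05)
  }
  # and the archetype draws themselves track the configured weights
  probs <- cfg$archetype_probabilities
  for (a in names(probs)) {
    expect_lt(abs(arch_freq[[a]] - probs[[a]]), 0.08)
  }
})

test_that("prevalence reporting reproduces printed-percentage arithmetic", {
  labels_df <- data.frame(
    sample_id = sprintf("s%03d", 1:101),
    participant_id = sprintf("p%03d", 1:101),
    timepoint = "V1", arm = "placebo",
    group = rep(DOMINANCE_GROUPS, c(50, 14, 17, 3, 17)),
    stringsAsFactors = FALSE)
  prev <- dominance_prevalence(labels_df)
  expect_equal(prev$percent[prev$group == "CRISPATUS_DOM"], 50)  # 50/101
  expect_equal(prev$percent[prev$group == "INERS_DOM"], 14)      # 14/101
  expect_equal(prev$percent[prev$group == "CRISP_INERS_CODOM"], 17)
  expect_equal(sum(prev$count), 101)
  expect_equal(sum(prev$fraction), 1)

  byarm <- dominance_prevalence(rbind(
    labels_df,
    within(labels_df, {
      arm <- "treatment"; sample_id <- paste0(sample_id, "t")
    })), stratify_by_arm = TRUE)
  expect_equal(sort(unique(byarm$arm)), ARMS)
  expect_equal(byarm$total[byarm$arm == "placebo"][1], 101)
})
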