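make_rad_fixture <- function() {
  # 3 participants x 2 timepoints, hand-chosen crispatus abundances
  ra <- list(
    A_V1 = comp(L_crispatus_group = 0.80, L_iners_group = 0.10,
                Gardnerella = 0.10),
    A_D7 = comp(L_crispatus_group = 0.90, L_iners_group = 0.05,
                Gardnerella = 0.05),
    B_V1 = comp(L_crispatus_group = 0.50, L_iners_group = 0.30,
                Gardnerella = 0.20),
    B_D7 = comp(L_crispatus_group = 0.55, L_iners_group = 0.25,
                Gardnerella = 0.20),
    C_V1 = comp(L_crispatus_group = 0.40, L_iners_group = 0.40,
                Gardnerella = 0.20),
    C_D7 = comp(L_crispatus_group = 0.60, L_iners_group = 0.20,
                Gardnerella = 0.20))
  tab <- toy_table(ra)
  des <- study_design(data.frame(
    sample_id = names(ra),
    participant_id = rep(c("A", "B", "C"), each = 2),
    arm = rep(c("placebo", "placebo", "treatment"), each = 2),
    timepoint = rep(c("V1", "D7"), 3), stringsAsFactors = FALSE))
  list(tab = tab, des = des)
}

test_that("RADs are later-minus-earlier over pairwise-complete participants", {
  f <- make_rad_fixture()
  obs <- compute_rads(f$tab, f$des, "L_crispatus_group", "V1", "D7")
  expect_equal(obs$participant_id, c("A", "B", "C"))
  expect_equal(obs$rad, c(0.10, 0.05, 0.20), tolerance = 1e-12)
  expect_equal(stats::median(obs$rad), 0.10, tolerance = 1e-12)

  # participant missing one sample is omitted
  des2 <- f$des[f$des$sample_id != "B_D7", ]
  class(des2) <- class(f$des)
  obs2 <- compute_rads(f$tab, f$des, "L_crispatus_group", "V1", "D7")
  obs2 <- compute_rads(f$tab, des2, "L_crispatus_group", "V1", "D7")
  expect_equal(obs2$participant_id, c("A", "C"))

  expect_error(compute_rads(f$tab, f$des, "L_crispatus_group", "V1", "V1"),
               class = "vagidyn_usage_error")
  expect_error(compute_rads(f$tab, f$des, "L_crispatus_group", "D7", "V1"),
               class = "vagidyn_usage_error")

  # taxon absent in both samples contributes an informative zero
  zero <- compute_rads(f$tab, f$des, "L_iners_group", "V1", "D7",
                       arm = "placebo")
  expect_equal(nrow(zero), 2)
  all_zero <- toy_table(list(
    A_V1 = comp(L_crispatus_group = 1, Prevotella = 0),
    A_D7 = comp(L_crispatus_group = 1, Prevotella = 0)))
  des3 <- study_design(data.frame(
    sample_id = c("A_V1", "A_D7"), participant_id = "A", arm = "placebo",
    timepoint = c("V1", "D7"), stringsAsFactors = FALSE))
  z <- compute_rads(all_zero, des3, "Prevotella", "V1", "D7")
  expect_equal(z$rad, 0)
})

test_that("exact signed-rank p for five uniformly positive differences", {
  # 2/2^5 sign patterns are as extreme as all-positive: p = 0.0625
  x <- c(0.15, 0.05, 0.20, 0.10, 0.08)
  p <- stats::wilcox.test(x, exact = TRUE)$p.value
  expect_equal(p, 0.0625, tolerance = 1e-12)

  des <- study_design(data.frame(
    sample_id = paste0(rep(LETTERS[1:5], each = 2), "_",
                       rep(c("V1", "D7"), 5)),
    participant_id = rep(LETTERS[1:5], each = 2), arm = "placebo",
    timepoint = rep(c("V1", "D7"), 5), stringsAsFactors = FALSE))
  base <- c(0.50, 0.40, 0.30, 0.55, 0.60)
  comps <- list()
  for (i in 1:5) {
    comps[[paste0(LETTERS[i], "_V1")]] <-
      comp(L_crispatus_group = base[i], Gardnerella = 1 - base[i])
    comps[[paste0(LETTERS[i], "_D7")]] <-
      comp(L_crispatus_group = base[i] + x[i],
           Gardnerella = 1 - base[i] - x[i])
  }
  m <- median_rad_matrix(toy_table(comps), des, "L_crispatus_group")
  expect_equal(m$p_raw["V1", "D7"], 0.0625, tolerance = 1e-12)
  expect_equal(m$median_rad["V1", "D7"], 0.10, tolerance = 1e-12)
  expect_equal(m$n_pairs["V1", "D7"], 5L)
  # single tested cell: BY adjustment is the identity
  expect_equal(m$p_adjusted["V1", "D7"], 0.0625, tolerance = 1e-12)
})

test_that("median-RAD matrices are antisymmetric under reorientation", {
  co <- generate_cohort(cohort_config(n_placebo = 10, n_treatment = 10,
                                      seed = 55))
  rel <- to_relative(aggregate_taxa(co$counts, "subgenus_group"))
  ra <- rel$values["L_crispatus_group", ]
  des <- as.data.frame(co$design)
  fwd <- compute_rads(rel, co$design, "L_crispatus_group", "D7", "V2")
  # recomputed with reversed orientation by hand
  expect_equal(stats::median(fwd$ra_from - fwd$ra_to),
               -stats::median(fwd$rad), tolerance = 1e-12)
  # paired-test consistency: p from RADs equals p from paired columns
  p_cols <- suppressWarnings(
    stats::wilcox.test(fwd$ra_to, fwd$ra_from, paired = TRUE,
                       exact = FALSE, correct = TRUE)$p.value)
  p_rads <- suppressWarnings(
    stats::wilcox.test(fwd$rad, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(p_cols, p_rads, tolerance = 1e-12)
})

test_that("Hodges-Lehmann equals the brute-force pairwise-difference median", {
  expect_equal(hodges_lehmann(c(1, 2, 3), c(0, 1)), 1.5)
  expect_equal(hodges_lehmann(5, 5), 0)
  expect_error(hodges_lehmann(numeric(), 1),
               class = "vagidyn_validation_error")

  withr::with_seed(29, {
    for (i in 1:25) {
      n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      diffs <- numeric(0)
      for (xi in x) for (yj in y) diffs <- c(diffs, xi - yj)
      expect_equal(hodges_lehmann(x, y), stats::median(diffs),
                   tolerance = 1e-12)
      # translation equivariance
      delta <- rnorm(1)
      expect_equal(hodges_lehmann(x + delta, y),
                   hodges_lehmann(x, y) + delta, tolerance = 1e-12)
    }
  })

  # cross-check against the conf.int machinery of wilcox.test
  withr::with_seed(31, {
    x <- rnorm(12); y <- rnorm(9)
    ref <- unname(stats::wilcox.test(x, y, conf.int = TRUE)$estimate)
    expect_equal(hodges_lehmann(x, y), ref, tolerance = 1e-6)
  })
})

test_that("differential RAD matrices honour the sign convention", {
  f <- make_rad_fixture()
  dm <- differential_rad_matrix(f$tab, f$des, "L_crispatus_group")
  # treatment arm: C (rad 0.20); placebo: A, B (0.10, 0.05)
  expect_equal(dm$hl_estimate["V1", "D7"],
               stats::median(c(0.20 - 0.10, 0.20 - 0.05)),
               tolerance = 1e-12)
  flipped <- differential_rad_matrix(f$tab, f$des, "L_crispatus_group",
                                     convention = "placebo_minus_treatment")
  expect_equal(flipped$hl_estimate, -dm$hl_estimate)
  expect_equal(flipped$p_raw, dm$p_raw)

  # identical RAD distributions in both arms: estimate 0, p = 1
  ra <- list(
    A_V1 = comp(L_crispatus_group = 0.5, Gardnerella = 0.5),
    A_D7 = comp(L_crispatus_group = 0.6, Gardnerella = 0.4),
    B_V1 = comp(L_crispatus_group = 0.5, Gardnerella = 0.5),
    B_D7 = comp(L_crispatus_group = 0.6, Gardnerella = 0.4))
  des <- study_design(data.frame(
    sample_id = names(ra), participant_id = rep(c("A", "B"), each = 2),
    arm = rep(c("placebo", "treatment"), each = 2),
    timepoint = rep(c("V1", "D7"), 2), stringsAsFactors = FALSE))
  dm0 <- differential_rad_matrix(toy_table(ra), des, "L_crispatus_group")
  expect_equal(dm0$hl_estimate["V1", "D7"], 0)
  expect_equal(dm0$p_raw["V1", "D7"], 1)
})

test_that("Kruskal-Wallis cross-sectional comparisons match closed forms", {
  h <- cross_sectional_test(c(1, 2, 3, 4, 5, 6),
                            rep(c("a", "b"), each = 3))
  expect_equal(unname(h$statistic), 3.857, tolerance = 1e-3)

  same <- cross_sectional_test(rep(c(1, 2, 3), 2),
                               rep(c("a", "b"), each = 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  expect_error(cross_sectional_test(1:3, rep("a", 3)),
               class = "vagidyn_validation_error")

  # two-group KW is asymptotically the rank-sum test
  withr::with_seed(41, {
    x <- rnorm(15); y <- rnorm(15)
    kw <- cross_sectional_test(c(x, y), rep(c("a", "b"), each = 15))$p.value
    rs <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(kw, rs, tolerance = 1e-6)
  })

  # table method: arms differ at one visit
  f <- make_rad_fixture()
  h2 <- cross_sectional_test(f$tab, f$des, "L_crispatus_group", "V1")
  expect_s3_class(h2, "htest")
  expect_true(h2$p.value >= 0 && h2$p.value <= 1)
})

test_that("Benjamini-Yekutieli adjustment matches the step-up formula", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.05)),
               c(0.0550, 0.0550, 11 / 120), tolerance = 1e-10)
  expect_equal(by_adjust(0.03), 0.03)
  expect_error(by_adjust(c(0.5, 1.2)), class = "vagidyn_validation_error")

  # independent step-up oracle
  by_oracle <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    adj <- pmin(1, p[o] * m * cm / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  withr::with_seed(59, {
    for (i in 1:200) {
      p <- runif(sample(1:20, 1))
      got <- by_adjust(p)
      expect_equal(got, by_oracle(p), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-12) && all(got <= 1 + 1e-12))
      # permutation invariance
      perm <- sample(length(p))
      expect_equal(by_adjust(p[perm]), got[perm], tolerance = 1e-12)
    }
  })
})

test_that("adjusted p dominates raw p across a whole RAD matrix", {
  co <- generate_cohort(cohort_config(n_placebo = 8, n_treatment = 8,
                                      seed = 61))
  rel <- to_relative(aggregate_taxa(co$counts, "genus"))
  m <- median_rad_matrix(rel, co$design, "Lactobacillus")
  tested <- !is.na(m$p_raw)
  expect_equal(sum(tested), 15)
  expect_true(all(m$p_adjusted[tested] >= m$p_raw[tested] - 1e-12))
  expect_true(all(m$p_adjusted[tested] <= 1))
  expect_true(all(m$n_pairs[tested] >= 2))
  df <- as.data.frame(m)
  expect_equal(nrow(df), 15)
})
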