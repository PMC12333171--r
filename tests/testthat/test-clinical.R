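test_that("rubric sub-scores reproduce the printed bins with half-open edges", {
  # weight: <5 -> 0, 5-9.99 -> 1, 10-14.99 -> 2, >=15 or death -> 3
  expect_equal(score_weight(12), 2L)
  expect_equal(score_weight(5.0), 1L)          # boundary, half-open
  expect_equal(score_weight(c(-2, 4.99, 9.99, 14.99, 15)),
               c(0L, 0L, 1L, 2L, 3L))
  expect_equal(score_weight(2, dead = TRUE), 3L)
  # strength: no loss -> 0, <10 -> 1, 10-19.99 -> 2, 20-29.99 -> 3, >=30 -> 4
  expect_equal(score_strength(25), 3L)
  expect_equal(score_strength(-3), 0L)         # gain from training
  expect_equal(score_strength(c(0, 9.99, 10, 29.99, 30)),
               c(0L, 1L, 2L, 3L, 4L))
  expect_equal(score_strength(0, dead = TRUE), 4L)
  # inverted grid: 60 -> 0, 45-59 -> 1, 30-44 -> 2, <30 or death -> 3
  expect_equal(score_grid(60), 0L)
  expect_equal(score_grid(40), 2L)
  expect_equal(score_grid(c(59.9, 45, 44.9, 30, 29.9)),
               c(1L, 1L, 2L, 2L, 3L))
  expect_equal(score_grid(60, dead = TRUE), 3L)
  expect_error(score_grid(61), "\\[0, 60\\]")
  # weight-loss percentage arithmetic
  expect_equal(weight_loss_pct(18, 20), 10)
  expect_equal(weight_loss_pct(20, 20), 0)
  expect_error(weight_loss_pct(18, 0), "positive")
})

test_that("the global clinical score follows the composite formula and bounds", {
  expect_equal(global_clinical_score(2, 3, 2, 1), 6.5)
  expect_equal(global_clinical_score(0, 0, 0, 0), 0)
  expect_equal(global_clinical_score(3, 4, 3, 3), 10)  # dead animal maxima
  # monotone in every sub-score
  base <- global_clinical_score(1, 1, 1, 1)
  expect_gt(global_clinical_score(2, 1, 1, 1), base)
  expect_gt(global_clinical_score(1, 2, 1, 1), base)
  expect_gt(global_clinical_score(1, 1, 2, 1), base)
  expect_gt(global_clinical_score(1, 1, 1, 1.5), base)
  # the printed behavior scale skips 2.5
  expect_error(global_clinical_score(1, 1, 1, 2.5), "behavior")
})

test_that("baseline normalization supports ratio and difference modes", {
  scores <- data.frame(animal = rep(c("A", "B"), each = 3),
                       week = rep(2:4, 2),
                       gcs = c(3, 6, 6, 2, 2, 4))
  r <- normalize_gcs(scores, baseline_week = 2, mode = "ratio")
  expect_equal(r$normalized_gcs, c(1, 2, 2, 1, 1, 2))
  d <- normalize_gcs(scores, baseline_week = 2, mode = "difference")
  expect_equal(d$normalized_gcs, c(0, 3, 3, 0, 0, 2))
  # de-normalization recovers gcs
  expect_equal(r$normalized_gcs * r$baseline_gcs, scores$gcs,
               tolerance = 1e-12)
  # missing baseline names the animal; zero baseline suggests difference
  expect_error(normalize_gcs(scores[scores$week > 2, ]), "A")
  zero <- scores; zero$gcs[1] <- 0
  expect_error(normalize_gcs(zero), "difference")
})

test_that("humanization filter excludes sub-threshold animals", {
  # the printed cohort structure: 27 mice, 9 per arm, one failed placebo
  cohort <- data.frame(
    animal = sprintf("M%02d", 1:27),
    arm = rep(c("placebo", "rMSC", "cMSC"), each = 9),
    cd45_pct = rep(2.5, 27))
  cohort$cd45_pct[5] <- 0.3
  hf <- humanization_filter(cohort)
  expect_equal(unname(hf$group_sizes["placebo"]), 8L)
  expect_equal(unname(hf$group_sizes["rMSC"]), 9L)
  expect_equal(hf$excluded$animal, "M05")
  # no exclusions when everybody clears the threshold
  all_ok <- humanization_filter(cohort[-5, ])
  expect_equal(nrow(all_ok$excluded), 0L)
  # exclusion list matches a brute-force scan on a random cohort
  set.seed(77)
  rc <- data.frame(animal = sprintf("R%02d", 1:40),
                   arm = "placebo",
                   cd45_pct = round(runif(40, 0, 2), 3))
  hf2 <- humanization_filter(rc)
  expect_setequal(hf2$excluded$animal, rc$animal[rc$cd45_pct < 0.4])
})

test_that("cohort scoring carries the terminal maximum forward or drops it", {
  cohort <- data.frame(animal = "A", arm = "placebo", week = 0:3,
                       weight = c(25, 25, 24, 24), grip = c(100, 100, 90, 90),
                       grid_time = c(60, 60, 50, 50),
                       behavior = c(0, 0, 0.5, 0.5),
                       alive = c(TRUE, TRUE, FALSE, FALSE))
  cf <- score_cohort(cohort, 25, 100)
  expect_equal(cf$gcs[cf$week >= 2], c(10, 10))  # dead weeks at the maximum
  dr <- score_cohort(cohort, 25, 100, death = "drop")
  expect_equal(dr$week, 0:2)  # first dead week kept, later ones dropped
  expect_equal(dr$gcs[3], 10)
})

test_that("group comparison is null on duplicated arms and finds a halved severity", {
  # two arms built from identical animal trajectories: all Tukey p ~ 1
  set.seed(123)
  base <- expand.grid(animal = sprintf("A%d", 1:6), week = 2:5)
  base$gcs <- 2 + 0.5 * base$week + rep(rnorm(6, 0, 0.3), 4)
  twin <- base
  twin$animal <- sub("A", "B", twin$animal)
  both <- rbind(cbind(base, arm = "placebo"), cbind(twin, arm = "cMSC"))
  norm <- normalize_gcs(both, baseline_week = 2)
  cg <- compare_groups(norm)
  expect_true(all(cg$pairwise$p_adj > 0.99))
  expect_equal(nrow(cg$summary), 2 * 4)

  # defaults (9 animals/arm, cMSC multiplier 0.5): cMSC vs placebo
  # significant in the majority of seeded replicates
  sig <- vapply(1:3, function(s) {
    sim <- simulate_cohort(seed = 400 + s)
    scored <- score_cohort(sim$cohort, sim$weight_reference,
                           sim$grip_reference)
    norm <- normalize_gcs(scored, baseline_week = 2)
    cg <- suppressMessages(compare_groups(norm, excluded_weeks = c(3, 7)))
    pw <- cg$pairwise[grepl("cMSC", cg$pairwise$contrast) &
                        grepl("placebo", cg$pairwise$contrast) &
                        cg$pairwise$week > 2, ]
    any(pw$p_adj < 0.05)
  }, logical(1))
  expect_true(mean(sig) > 0.5)

  # permuting arm labels destroys the effect
  sim <- simulate_cohort(seed = 500)
  scored <- score_cohort(sim$cohort, sim$weight_reference,
                         sim$grip_reference)
  norm <- normalize_gcs(scored, baseline_week = 2)
  set.seed(1)
  animals <- unique(norm$animal)
  relabel <- setNames(sample(norm$arm[match(animals, norm$animal)]), animals)
  norm$arm <- unname(relabel[norm$animal])
  cgp <- suppressMessages(compare_groups(norm, excluded_weeks = c(3, 7)))
  expect_gt(min(cgp$pairwise$p_adj), 0.05)

  expect_error(compare_groups(norm[norm$arm == "placebo", ]), "two")
})

test_that("a planted multiplicative treatment effect is recovered from scores", {
  # single replicates at n = 50/arm scatter with sd ~ 0.04, so the recovery
  # claim is checked on the Monte-Carlo mean over five replicates
  est <- vapply(1:5, function(s)
    estimate_treatment_effect(simulate_cohort(n_per_arm = 50,
                                              seed = 600 + s)),
    numeric(1))
  expect_equal(mean(est), 0.5, tolerance = 0.1)
})
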