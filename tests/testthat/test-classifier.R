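test_that("reference table fixture loads 78 unique profiles from 79 listings", {
  fx <- load_table1_fixture()
  expect_equal(nrow(fx), 78L)
  expect_equal(attr(fx, "n_listings"), 79L)
  egf <- fx[fx$protein == "EGF", ]
  expect_equal(unlist(egf[, c("med", "pbmc", "rmsc", "coc", "d3")]),
               c(med = 5.08, pbmc = 5.33, rmsc = 2.33, coc = 2.06, d3 = 1.65))
  il6 <- fx[fx$protein == "IL6", ]
  expect_equal(unlist(il6[, c("med", "pbmc", "rmsc", "coc", "d3")]),
               c(med = 1.29, pbmc = 3.70, rmsc = 9.65, coc = 11.63,
                 d3 = 11.89))
  expect_equal(fx$sections[fx$protein == "CCL17"], "b;c")
  # QC: printed subtractions that disagree with rounded-mean arithmetic are
  # flagged (the source rounded from unrounded inputs), never corrected
  qc <- attr(fx, "qc_mismatch")
  expect_true(nrow(qc) > 0)
  egf_d3 <- qc[qc$protein == "EGF" & qc$column == "sub4", ]
  expect_equal(egf_d3$printed, 3.42)
  expect_equal(egf_d3$recomputed, 3.43)
  expect_true(all(abs(qc$printed - qc$recomputed) <= 0.01 + 1e-9))
})

test_that("single-profile rules reproduce the printed category calls", {
  # consumed is terminal even though the inhibited rule also fires
  egf <- classify_protein(profile_row("EGF", 5.08, 5.33, 2.33, 2.06, 1.65))
  expect_identical(egf$labels, "consumed")
  # the dual-printed chemokine carries both labels
  ccl17 <- classify_protein(profile_row("CCL17", 4.92, 5.30, 5.24, 5.82, 4.42))
  expect_setequal(ccl17$labels, c("conditioning", "inhibited"))
  il6 <- classify_protein(profile_row("IL6", 1.29, 3.70, 9.65, 11.63, 11.89))
  expect_identical(il6$labels, "immunomodulatory")
  # D3 deficit below coculture beyond delta_coc blocks immunomodulatory
  stc1 <- classify_protein(profile_row("STC1", 0.61, 0.86, 2.83, 4.04, 3.49))
  expect_identical(stc1$labels, "conditioning")
  # flat profile is unclassified
  flat <- classify_protein(profile_row("X", 2, 2, 2, 2, 2))
  expect_identical(flat$labels, "unclassified")
  # constitutive fires only in the absence of the other labels
  cons <- classify_protein(profile_row("HGFlike", 1, 1.2, 4.4, 4.3, 4.5))
  expect_identical(cons$labels, "constitutive")
  # missing condition -> unclassified with a margin note
  miss <- classify_protein(data.frame(protein = "Y", med = 1, pbmc = 1,
                                      rmsc = 1, coc = 1, d3 = NA))
  expect_identical(miss$labels, "unclassified")
  expect_true("missing_condition" %in% names(miss$margins))
  # non-finite mean errors with the protein name
  expect_error(classify_protein(profile_row("Z", Inf, 1, 1, 1, 1)), "Z")
})

test_that("classification of the reference table recovers the printed counts", {
  fx <- load_table1_fixture()
  rep <- classify_all(fx)
  expect_equal(unname(rep$counts["consumed"]), 7L)
  expect_equal(unname(rep$counts["conditioning"]), 22L)
  expect_equal(unname(rep$counts["immunomodulatory"]), 40L)
  # every printed section membership is recovered by its rule
  expect_setequal(rep$members$consumed,
                  fx$protein[grepl("a", fx$sections)])
  expect_setequal(rep$members$conditioning,
                  fx$protein[grepl("b", fx$sections)])
  expect_setequal(rep$members$immunomodulatory,
                  fx$protein[grepl("d", fx$sections)])
  expect_true(all(fx$protein[grepl("c", fx$sections)] %in%
                    rep$members$inhibited))
  # empty input gives an empty report
  empty <- classify_all(fx[0, ])
  expect_true(all(empty$counts == 0))
})

test_that("classifier invariants: order invariance, monotonicity, exclusivity", {
  profs <- random_profiles(1000, seed = 9)
  rep1 <- classify_all(profs)
  # order invariance
  perm <- sample(nrow(profs))
  rep2 <- classify_all(profs[perm, ])
  for (p in profs$protein)
    expect_identical(sort(rep1$assignments[[p]]$labels),
                     sort(rep2$assignments[[p]]$labels))
  # consumed exclusivity
  for (a in rep1$assignments) {
    if ("consumed" %in% a$labels) expect_length(a$labels, 1L)
    if ("unclassified" %in% a$labels) expect_length(a$labels, 1L)
  }
  # raising any tau never enlarges its category
  base_cfg <- classifier_config()
  for (par in c("tau_consumed", "tau_conditioning", "tau_inhibited",
                "tau_immuno")) {
    cat_ <- sub("tau_", "", par)
    cat_ <- c(consumed = "consumed", conditioning = "conditioning",
              inhibited = "inhibited", immuno = "immunomodulatory")[[cat_]]
    args <- unclass(base_cfg); args[[par]] <- args[[par]] + 1
    up <- classify_all(profs, do.call(classifier_config, args))
    expect_true(all(up$members[[cat_]] %in% rep1$members[[cat_]]))
  }
  # at huge thresholds everything is unclassified
  sky <- classifier_config(tau_consumed = 1e6, tau_conditioning = 1e6,
                           tau_inhibited = 1e6, tau_immuno = 1e6,
                           tau_constitutive = 1e6)
  all_un <- classify_all(profs, sky)
  expect_equal(unname(all_un$counts["unclassified"]), nrow(profs))
})

test_that("threshold calibration prefers conservative ties and recovers the table", {
  fx <- load_table1_fixture()
  rep <- classify_all(fx)
  # truth = the default-config assignments; a grid containing the defaults
  # must reproduce sections a, b and d exactly
  fx$labels <- vapply(fx$protein, function(p)
    paste(sort(rep$assignments[[p]]$labels), collapse = ";"), character(1))
  grid <- data.frame(tau_consumed = c(0.1, 0.4, 2.0),
                     tau_conditioning = c(0.05, 0.3, 2.0),
                     tau_inhibited = c(0.05, 0.2, 2.0),
                     tau_immuno = c(0.05, 0.25, 2.0))
  cal <- calibrate_thresholds(fx, grid)
  best <- classify_all(fx, cal$config)
  expect_setequal(best$members$consumed, fx$protein[grepl("a", fx$sections)])
  expect_setequal(best$members$conditioning,
                  fx$protein[grepl("b", fx$sections)])
  expect_setequal(best$members$immunomodulatory,
                  fx$protein[grepl("d", fx$sections)])
  # single profile, single grid point -> that point is returned
  one <- fx[1, ]; one$labels <- "consumed"
  cal1 <- calibrate_thresholds(one, data.frame(tau_consumed = 0.7))
  expect_equal(cal1$config$tau_consumed, 0.7)
  expect_equal(cal1$agreement, 1)
  # constructed separability: any threshold below the planted margin is
  # perfect; the tie-break picks the largest
  sep <- rbind(profile_row("C1", 5, 5, 1, 1, 1),    # consumed, margin 4
               profile_row("U1", 2, 2, 2, 2, 2))    # unclassified
  sep$labels <- c("consumed", "unclassified")
  gridsep <- data.frame(tau_consumed = c(0.2, 0.8, 3.0))
  calsep <- calibrate_thresholds(sep, gridsep)
  expect_equal(calsep$config$tau_consumed, 3.0)
  expect_equal(calsep$agreement, 1)
  expect_error(calibrate_thresholds(sep, data.frame()), "non-empty")
})

test_that("planted categories are recovered from synthetic NPX panels", {
  # noiseless limit: exact recovery of every planted category
  sim0 <- simulate_npx_panel(n_proteins = 200, sigma = 0, seed = 31)
  cm0 <- condition_means(sim0$matrix)
  rep0 <- classify_all(cm0)
  for (i in seq_len(nrow(cm0))) {
    truth <- sim0$truth$category[i]
    expect_true(truth %in% rep0$assignments[[cm0$protein[i]]]$labels,
                label = paste("noiseless recovery of", truth))
  }
  # default noise: macro-averaged recall across categories >= 0.95
  recalls <- vapply(1:3, function(s) {
    sim <- simulate_npx_panel(seed = s)
    rep <- classify_all(condition_means(sim$matrix))
    per_cat <- vapply(unique(sim$truth$category), function(cat) {
      idx <- sim$truth$protein[sim$truth$category == cat]
      mean(vapply(idx, function(p)
        cat %in% rep$assignments[[p]]$labels, logical(1)))
    }, numeric(1))
    mean(per_cat)
  }, numeric(1))
  expect_true(all(recalls >= 0.95))
})
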