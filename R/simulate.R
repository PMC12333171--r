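# Category-specific condition offsets (log2 NPX) planted by the NPX
# generator, mirroring the margin structure of the reference table.
# Rows: med, pbmc, rmsc, coc, d3.
NPX_TEMPLATES <- list(
  consumed         = c(med = 1.5, pbmc = 1.5, rmsc = 0.0, coc = 0.0, d3 = 0.0),
  constitutive     = c(med = 0.0, pbmc = 0.0, rmsc = 1.2, coc = 1.2, d3 = 1.2),
  conditioning     = c(med = 0.0, pbmc = 0.8, rmsc = 0.0, coc = 1.5, d3 = 0.0),
  inhibited        = c(med = 1.0, pbmc = 1.0, rmsc = 1.0, coc = 1.0, d3 = 0.0),
  immunomodulatory = c(med = 0.0, pbmc = 0.0, rmsc = 0.5, coc = 1.4, d3 = 1.5),
  unclassified     = c(med = 0.0, pbmc = 0.0, rmsc = 0.0, coc = 0.0, d3 = 0.0))

# Default planted category mix: the study's printed category sizes out of
# its 609-protein panel; the remainder is null/unclassified.
NPX_DEFAULT_FRACTIONS <- c(consumed = 7, constitutive = 65, conditioning = 22,
                           inhibited = 10, immunomodulatory = 40) / 609

#' Simulate an NPX secretome panel with planted categories
#'
#' Draws per-protein baselines, applies category-specific condition offsets
#' (scaled by `margin_scale`), and adds Gaussian per-sample noise. Defaults
#' reproduce the study conditions: 609 proteins, category sizes as printed,
#' sample sizes 2/3/4/4/4 across Medium/PBMC/rMSC/Coculture/D3-cMSC, noise
#' sd 0.15 log2 units. `margin_scale = 0` gives a pure null panel.
#'
#' @param n_proteins number of proteins (default 609).
#' @param category_fractions named fractions for the five effect
#'   categories; must sum to <= 1, the remainder is unclassified.
#' @param margin_scale multiplier on all planted offsets (default 1).
#' @param sigma per-sample Gaussian noise sd in log2 NPX units
#'   (default 0.15).
#' @param n_per_condition named integer vector of samples per condition.
#' @param baseline_range range of the uniform per-protein baseline level.
#' @param seed integer seed; all randomness flows through it.
#' @return list with `matrix` (an [npx_matrix()]) and `truth` (data frame
#'   `protein`, `category`).
#' @export
simulate_npx_panel <- function(n_proteins = 609,
                               category_fractions = NPX_DEFAULT_FRACTIONS,
                               margin_scale = 1, sigma = 0.15,
                               n_per_condition = c(Medium = 2, PBMC = 3,
                                                   rMSC = 4, Coculture = 4,
                                                   D3cMSC = 4),
                               baseline_range = c(1, 8), seed = 1) {
  if (any(category_fractions < 0) || sum(category_fractions) > 1 + NPX_EPS)
    stop("category fractions must be non-negative and sum to <= 1")
  bad <- setdiff(names(category_fractions), names(NPX_TEMPLATES))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  set.seed(seed)
  counts <- round(category_fractions * n_proteins)
  counts <- c(counts, unclassified = n_proteins - sum(counts))
  category <- rep(names(counts), counts)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  samples <- unlist(lapply(names(n_per_condition), function(cn)
    paste0(cn, "_", seq_len(n_per_condition[[cn]]))))
  design <- stats::setNames(rep(names(n_per_condition), n_per_condition),
                            samples)
  baseline <- stats::runif(n_proteins, baseline_range[1], baseline_range[2])
  cond_short <- c(Medium = "med", PBMC = "pbmc", rMSC = "rmsc",
                  Coculture = "coc", D3cMSC = "d3")
  vals <- matrix(NA_real_, n_proteins, length(samples),
                 dimnames = list(proteins, samples))
  for (j in seq_along(samples)) {
    off <- vapply(category, function(cat)
      NPX_TEMPLATES[[cat]][[cond_short[[design[j]]]]], numeric(1))
    vals[, j] <- baseline + margin_scale * off +
      stats::rnorm(n_proteins, 0, sigma)
  }
  list(matrix = npx_matrix(vals, design),
       truth = data.frame(protein = proteins, category = category,
                          stringsAsFactors = FALSE))
}

# Expected (noise-free) severity of the default placebo arm by week.
DEFAULT_SEVERITY_CURVE <- c(`0` = 0.05, `1` = 0.15, `2` = 0.25, `3` = 0.35,
                            `4` = 0.45, `5` = 0.55, `6` = 0.65)

#' Simulate an NSG-MG-style longitudinal cohort
#'
#' Generates weight, grip, inverted-grid and behavior trajectories whose
#' rubric sub-scores track a latent severity. Severity follows the placebo
#' curve up to the injection week, after which each arm's curve is
#' multiplied by its treatment effect (the conditioned-cell arm halves
#' severity by default). Deaths occur with weekly probability
#' `death_hazard * expected severity`; humanization failures receive a
#' CD45+ fraction below the 0.4\% positivity threshold.
#'
#' Severity-to-measure maps are chosen so each sub-score is, in
#' expectation, proportional to severity (rubric bin edges sit at
#' half-step offsets), which makes the arm ratio of normalized GCS a
#' consistent estimator of the planted multiplier.
#'
#' @param n_per_arm animals per treatment arm (default 9, as in the study).
#' @param weeks observation weeks (default 0..6).
#' @param placebo_severity_curve named severity per week for the placebo
#'   arm (values in `[0, 1]`).
#' @param effect_multiplier named multipliers per arm; applied to severity
#'   after `treatment_week`.
#' @param treatment_week week of cell injection (default 2).
#' @param noise_sd sd of the per-animal-week severity noise (default 0.03).
#' @param death_hazard scale of the weekly death probability (default 0.05).
#' @param humanization_fail_rate per-animal probability of a sub-threshold
#'   CD45+ fraction (default 1/27, one failure expected in the printed
#'   27-mouse cohort).
#' @param seed integer seed.
#' @return list with `cohort` (data frame `animal, arm, week, weight, grip,
#'   grid_time, behavior, alive, cd45_pct`), `truth` (per-animal-week
#'   expected severity and per-arm multipliers) and the references
#'   `weight_reference` (sham weight, g) and `grip_reference` (habituation
#'   grip, arbitrary force units).
#' @export
simulate_cohort <- function(n_per_arm = 9, weeks = 0:6,
                            placebo_severity_curve = DEFAULT_SEVERITY_CURVE,
                            effect_multiplier = c(placebo = 1.0, rMSC = 0.9,
                                                  cMSC = 0.5),
                            treatment_week = 2, noise_sd = 0.03,
                            death_hazard = 0.05,
                            humanization_fail_rate = 1 / 27, seed = 1) {
  if (any(placebo_severity_curve < 0)) stop("severity curve must be >= 0")
  set.seed(seed)
  ref_weight <- 25    # sham-group mean body weight, g
  ref_grip <- 100     # habituation grip force, arbitrary units
  arms <- names(effect_multiplier)
  rows <- list()
  truth <- list()
  animal_id <- 0L
  for (arm in arms) {
    for (a in seq_len(n_per_arm)) {
      animal_id <- animal_id + 1L
      id <- sprintf("M%02d", animal_id)
      fail_humanization <- stats::runif(1) < humanization_fail_rate
      cd45 <- if (fail_humanization) stats::runif(1, 0.05, 0.35)
              else exp(stats::rnorm(1, log(3), 0.5))
      alive <- TRUE
      for (w in weeks) {
        mult <- if (w > treatment_week) effect_multiplier[[arm]] else 1.0
        sev_true <- placebo_severity_curve[[as.character(w)]] * mult
        if (alive && w > treatment_week &&
            stats::runif(1) < death_hazard * sev_true)
          alive <- FALSE
        s <- max(0, sev_true + stats::rnorm(1, 0, noise_sd))
        # measure maps: rubric bin edges at half-step offsets in severity
        weight <- ref_weight * (1 - (20 * s + 2.5) / 100) +
          stats::rnorm(1, 0, 0.6)
        grip <- ref_grip * (1 - (40 * s - 5) / 100) + stats::rnorm(1, 0, 5)
        grid_time <- min(60, max(0, 67.5 - 45 * s + stats::rnorm(1, 0, 3)))
        sb <- s + stats::rnorm(1, 0, 0.05)
        behavior <- BEHAVIOR_GRADES[
          1L + findInterval(sb, c(1, 3, 5, 7, 10) / 12)]
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id, arm = arm, week = w,
          weight = round(weight, 2), grip = round(grip, 2),
          grid_time = round(grid_time, 1), behavior = behavior,
          alive = alive, cd45_pct = round(cd45, 3),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          animal = id, arm = arm, week = w, severity = sev_true,
          multiplier = effect_multiplier[[arm]],
          humanized = !fail_humanization, stringsAsFactors = FALSE)
      }
    }
  }
  list(cohort = do.call(rbind, rows), truth = do.call(rbind, truth),
       weight_reference = ref_weight, grip_reference = ref_grip)
}

#' Estimate the treatment-effect multiplier from a scored cohort
#'
#' Ratio, between a treated arm and the reference arm, of the arm-mean GCS
#' over the post-treatment weeks normalized by the arm-mean GCS at the
#' baseline week. Normalizing at arm level (rather than per animal) avoids
#' the instability of per-animal baseline ratios; post-death weeks are
#' dropped so that censoring does not bias the multiplicative-effect
#' estimate.
#'
#' @param sim a [simulate_cohort()] result (or any list with the same
#'   elements).
#' @param arm treatment arm to compare against `reference_arm`.
#' @param reference_arm baseline arm (default `"placebo"`).
#' @param baseline_week normalization week (default 2).
#' @return the estimated multiplier (ratio of mean normalized GCS).
#' @export
estimate_treatment_effect <- function(sim, arm = "cMSC",
                                      reference_arm = "placebo",
                                      baseline_week = 2) {
  scored <- score_cohort(sim$cohort, sim$weight_reference,
                         sim$grip_reference, death = "drop")
  scored <- scored[scored$alive, ]
  arm_norm <- function(a) {
    base <- scored$gcs[scored$arm == a & scored$week == baseline_week]
    post <- scored$gcs[scored$arm == a & scored$week > baseline_week]
    if (!length(base) || abs(mean(base)) < NPX_EPS)
      stop("arm ", a, " has no usable baseline at week ", baseline_week)
    mean(post) / mean(base)
  }
  arm_norm(arm) / arm_norm(reference_arm)
}

#' Simulate barcoded mass-cytometry events
#'
#' Singlets get `Normal(mu_pos, sigma_pos)` intensities on their code
#' channels and `Normal(mu_bg, sigma_bg)` elsewhere (transformed scale);
#' doublets are channel-wise maxima of two random singlets and are labelled
#' `"DOUBLET"` in the truth.
#'
#' @param scheme a [design_scheme()] result.
#' @param n_per_sample singlet events per sample (default 100).
#' @param mu_pos,sigma_pos positive-channel intensity mean and sd
#'   (defaults 6 and 0.8).
#' @param mu_bg,sigma_bg background intensity mean and sd (defaults 1
#'   and 0.8); `mu_pos` must exceed `mu_bg`.
#' @param doublet_rate fraction of additional doublet events relative to
#'   the singlet total (default 0.05).
#' @param seed integer seed.
#' @return list with `events` (matrix, events x channels) and `truth`
#'   (character vector of sample labels).
#' @export
simulate_barcoded_events <- function(scheme, n_per_sample = 100,
                                     mu_pos = 6, sigma_pos = 0.8,
                                     mu_bg = 1, sigma_bg = 0.8,
                                     doublet_rate = 0.05, seed = 1) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (mu_pos <= mu_bg) stop("mu_pos must exceed mu_bg")
  set.seed(seed)
  chans <- scheme$channels
  ids <- names(scheme$codes)
  n_singlet <- n_per_sample * length(ids)
  make_singlet <- function(sample_id) {
    x <- stats::rnorm(length(chans), mu_bg, sigma_bg)
    pos <- chans %in% scheme$codes[[sample_id]]
    x[pos] <- stats::rnorm(sum(pos), mu_pos, sigma_pos)
    x
  }
  truth <- rep(ids, each = n_per_sample)
  events <- t(vapply(truth, make_singlet, numeric(length(chans))))
  n_doublet <- round(doublet_rate * n_singlet)
  if (n_doublet > 0) {
    i <- sample.int(n_singlet, n_doublet, replace = TRUE)
    j <- sample.int(n_singlet, n_doublet, replace = TRUE)
    doublets <- pmax(events[i, , drop = FALSE], events[j, , drop = FALSE])
    events <- rbind(events, doublets)
    truth <- c(truth, rep("DOUBLET", n_doublet))
  }
  colnames(events) <- chans
  rownames(events) <- NULL
  perm <- sample.int(nrow(events))
  list(events = events[perm, , drop = FALSE], truth = truth[perm])
}

#' Simulate matched CFSE samples
#'
#' Builds a CFSE generation ladder on the log10 scale: the undivided peak
#' sits at `undivided_mean` and each daughter generation one
#' `class_spacing` (one dye halving) lower. Emits a matched non-activated
#' control (all undivided), an activated control, and one treated sample
#' per entry of `divided_fraction`; divided events are spread uniformly
#' over the `division_classes` generations.
#'
#' @param n_events events per sample (default 10000).
#' @param division_classes number of daughter generations (default 5, the
#'   maximum observed in the source study).
#' @param undivided_mean log10 intensity of the undivided peak
#'   (default 4).
#' @param class_spacing per-division decrement (default `log10(2)`).
#' @param peak_sigma within-generation sd (default 0.05).
#' @param divided_fraction named divided fractions of the activated control
#'   and treated arms; defaults mirror the study's ordering (the
#'   conditioned supernatant inhibits most).
#' @param seed integer seed.
#' @return list with `samples` (named list of log10 intensity vectors,
#'   including `non_activated`) and `truth` (the planted divided
#'   fractions).
#' @export
simulate_cfse <- function(n_events = 10000, division_classes = 5,
                          undivided_mean = 4, class_spacing = log10(2),
                          peak_sigma = 0.05,
                          divided_fraction = c(activated = 0.60,
                                               rMSC = 0.42, gMSC = 0.40,
                                               D3cMSC = 0.25),
                          seed = 1) {
  if (division_classes < 0) stop("division_classes must be >= 0")
  if (any(divided_fraction < 0 | divided_fraction > 1))
    stop("divided fractions must lie in [0, 1]")
  set.seed(seed)
  draw <- function(frac) {
    gen <- if (division_classes == 0) rep(0L, n_events) else
      ifelse(stats::runif(n_events) < frac,
             sample.int(division_classes, n_events, replace = TRUE), 0L)
    stats::rnorm(n_events, undivided_mean - gen * class_spacing, peak_sigma)
  }
  samples <- c(list(non_activated = draw(0)),
               lapply(as.list(divided_fraction), draw))
  list(samples = samples,
       truth = list(divided_fraction = divided_fraction,
                    division_classes = division_classes,
                    undivided_mean = undivided_mean,
                    class_spacing = class_spacing))
}
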