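BEHAVIOR_GRADES <- c(0, 0.5, 1, 1.5, 2, 3)
TREATMENT_ARMS <- c("placebo", "rMSC", "cMSC")

#' Percent weight loss versus a reference
#'
#' @param weight observed body weight (g).
#' @param reference_weight reference weight (g), typically the sham-group
#'   mean at the matching week; must be positive.
#' @return percent loss; negative values indicate gain.
#' @export
weight_loss_pct <- function(weight, reference_weight) {
  if (any(reference_weight <= 0)) stop("reference weight must be positive")
  100 * (reference_weight - weight) / reference_weight
}

#' Weight-loss sub-score
#'
#' Bins the percent loss into 0-3 using half-open intervals:
#' below 5\% scores 0, 5-9.99\% scores 1, 10-14.99\% scores 2, 15\% or more
#' (and death) scores 3.
#'
#' @param pct_loss percent weight loss.
#' @param dead logical; a dead animal scores the maximum.
#' @return integer score in 0..3.
#' @export
score_weight <- function(pct_loss, dead = FALSE) {
  score <- findInterval(pct_loss, c(5, 10, 15))
  ifelse(rep_len(dead, length(score)), 3L, score)
}

#' Strength-loss sub-score
#'
#' No loss (or gain from training) scores 0; a loss under 10\% scores 1,
#' 10-19.99\% scores 2, 20-29.99\% scores 3, 30\% or more (and death)
#' scores 4.
#'
#' @param pct_loss percent grip-strength loss versus habituation.
#' @param dead logical; a dead animal scores the maximum.
#' @return integer score in 0..4.
#' @export
score_strength <- function(pct_loss, dead = FALSE) {
  score <- ifelse(pct_loss <= 0, 0L,
                  1L + findInterval(pct_loss, c(10, 20, 30)))
  ifelse(rep_len(dead, length(score)), 4L, score)
}

#' Inverted-grid sub-score
#'
#' The full 60 s hold scores 0; 45-59 s scores 1, 30-44 s scores 2, under
#' 30 s (and death) scores 3.
#'
#' @param Tr time (s) the animal resisted falling from the inverted grid,
#'   in `[0, 60]`.
#' @param dead logical; a dead animal scores the maximum.
#' @return integer score in 0..3.
#' @export
score_grid <- function(Tr, dead = FALSE) {
  if (any(!is.na(Tr) & (Tr < 0 | Tr > 60)))
    stop("Tr must lie in [0, 60] seconds")
  score <- ifelse(Tr >= 60, 0L, ifelse(Tr >= 45, 1L, ifelse(Tr >= 30, 2L, 3L)))
  ifelse(rep_len(dead, length(score)), 3L, score)
}

check_behavior <- function(grade) {
  ok <- is.na(grade) |
    vapply(grade, function(g) any(abs(g - BEHAVIOR_GRADES) < NPX_EPS),
           logical(1))
  if (!all(ok))
    stop("behavior grade must be one of ",
         paste(BEHAVIOR_GRADES, collapse = ", "), "; got ",
         paste(unique(grade[!ok]), collapse = ", "))
  grade
}

#' Global clinical score
#'
#' `GCS = weight score + strength score + (behavior score + grid score)/2`,
#' ranging 0 (healthy) to 10 (maximal severity / death).
#'
#' @param weight_score 0..3, from [score_weight()].
#' @param strength_score 0..4, from [score_strength()].
#' @param grid_score 0..3, from [score_grid()].
#' @param behavior_score one of 0, 0.5, 1, 1.5, 2, 3.
#' @return numeric GCS in `[0, 10]`.
#' @export
global_clinical_score <- function(weight_score, strength_score,
                                  grid_score, behavior_score) {
  stopifnot(all(weight_score %in% 0:3), all(strength_score %in% 0:4),
            all(grid_score %in% 0:3))
  check_behavior(behavior_score)
  weight_score + strength_score + (behavior_score + grid_score) / 2
}

#' Score a longitudinal cohort
#'
#' Computes the four sub-scores and the global clinical score for every
#' animal-week of a cohort table. Dead animal-weeks score the maxima; by
#' default the terminal maximal score is carried forward to later weeks
#' (`death = "carry-forward"`), or those weeks can be dropped
#' (`death = "drop"`).
#'
#' @param cohort data frame with columns `animal`, `arm`, `week`, `weight`,
#'   `grip`, `grid_time`, `behavior`, `alive` (logical) and optionally
#'   `cd45_pct`.
#' @param weight_reference reference weight (g): a single value, or a named
#'   vector indexed by week (sham mean per week).
#' @param grip_reference habituation grip force: a single value, or a named
#'   vector indexed by animal.
#' @param death `"carry-forward"` or `"drop"`.
#' @return the cohort with added columns `weight_score`, `strength_score`,
#'   `grid_score`, `behavior_score`, `gcs`.
#' @export
score_cohort <- function(cohort, weight_reference, grip_reference,
                         death = c("carry-forward", "drop")) {
  death <- match.arg(death)
  need <- c("animal", "arm", "week", "weight", "grip", "grid_time",
            "behavior", "alive")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  wr <- if (length(weight_reference) == 1L)
    rep_len(weight_reference, nrow(cohort))
  else weight_reference[as.character(cohort$week)]
  gr <- if (length(grip_reference) == 1L)
    rep_len(grip_reference, nrow(cohort))
  else grip_reference[as.character(cohort$animal)]
  dead <- !cohort$alive
  if (death == "drop") {
    # keep the first dead week (terminal maximum), drop subsequent ones
    ord <- order(cohort$animal, cohort$week)
    cohort <- cohort[ord, ]; wr <- wr[ord]; gr <- gr[ord]; dead <- dead[ord]
    prev_dead <- stats::ave(dead, cohort$animal, FUN = function(d)
      c(FALSE, utils::head(cumsum(d), -1) > 0))
    keep <- !as.logical(prev_dead)
    cohort <- cohort[keep, ]; wr <- wr[keep]; gr <- gr[keep]
    dead <- dead[keep]
  }
  wl <- ifelse(dead, NA_real_, weight_loss_pct(cohort$weight, wr))
  sl <- ifelse(dead, NA_real_, weight_loss_pct(cohort$grip, gr))
  cohort$weight_score <- ifelse(dead, 3L, score_weight(wl))
  cohort$strength_score <- ifelse(dead, 4L, score_strength(sl))
  cohort$grid_score <- ifelse(dead, 3L, score_grid(cohort$grid_time))
  cohort$behavior_score <- ifelse(dead, 3, check_behavior(cohort$behavior))
  cohort$gcs <- global_clinical_score(cohort$weight_score,
                                      cohort$strength_score,
                                      cohort$grid_score,
                                      cohort$behavior_score)
  rownames(cohort) <- NULL
  cohort
}

#' Normalize GCS to each animal's baseline
#'
#' Divides (ratio mode) or subtracts (difference mode) each animal's weekly
#' GCS by its score at the baseline week (the week of cell injection,
#' week 2 in the source study).
#'
#' @param scores data frame with columns `animal`, `week`, `gcs` (e.g. from
#'   [score_cohort()]).
#' @param baseline_week the reference week (default 2).
#' @param mode `"ratio"` or `"difference"`.
#' @return `scores` with added columns `baseline_gcs` and `normalized_gcs`;
#'   the mode is recorded in attribute `"mode"`.
#' @export
normalize_gcs <- function(scores, baseline_week = 2,
                          mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  base <- scores[scores$week == baseline_week, ]
  missing <- setdiff(unique(scores$animal), unique(base$animal))
  if (length(missing))
    stop("no baseline (week ", baseline_week, ") record for animal(s): ",
         paste(missing, collapse = ", "))
  b <- stats::setNames(base$gcs, base$animal)[as.character(scores$animal)]
  if (mode == "ratio" && any(abs(b) < NPX_EPS)) {
    zero <- unique(scores$animal[abs(b) < NPX_EPS])
    stop("zero baseline GCS for animal(s) ", paste(zero, collapse = ", "),
         "; use mode = \"difference\"")
  }
  scores$baseline_gcs <- unname(b)
  scores$normalized_gcs <- if (mode == "ratio") scores$gcs / b
                           else scores$gcs - b
  attr(scores, "mode") <- mode
  scores
}

#' Humanization filter
#'
#' Removes animals whose human CD45+ fraction at sacrifice is below the
#' positivity threshold (0.4\% of live blood cells in the source study).
#'
#' @param cohort data frame with columns `animal`, `arm` and `cd45_pct`
#'   (one value per animal; for longitudinal tables the per-animal value is
#'   taken from its last row).
#' @param threshold positivity threshold in percent (default 0.4).
#' @return list with `cohort` (retained rows), `excluded` (data frame of
#'   removed animals and their CD45+ values) and `group_sizes` (retained
#'   animals per arm).
#' @export
humanization_filter <- function(cohort, threshold = 0.4) {
  if (is.null(cohort$cd45_pct)) stop("cohort lacks a 'cd45_pct' column")
  last <- cohort[!duplicated(cohort$animal, fromLast = TRUE), ]
  bad <- last$cd45_pct < threshold - NPX_EPS
  excluded <- data.frame(animal = last$animal[bad], arm = last$arm[bad],
                         cd45_pct = last$cd45_pct[bad],
                         stringsAsFactors = FALSE)
  kept <- cohort[!(cohort$animal %in% excluded$animal), ]
  kept_animals <- kept[!duplicated(kept$animal), ]
  list(cohort = kept,
       excluded = excluded,
       group_sizes = table(factor(kept_animals$arm,
                                  levels = unique(last$arm))))
}

#' Compare treatment arms over time
#'
#' Summarizes normalized GCS per arm and week (mean +/- SEM) and tests arm
#' differences with a two-way ANOVA (arm x week) followed by Tukey-adjusted
#' pairwise arm contrasts within each week.
#'
#' @param scores data frame with columns `animal`, `arm`, `week` and
#'   `normalized_gcs` (from [normalize_gcs()]).
#' @param excluded_weeks integer vector of weeks to drop before analysis
#'   (the source study excluded weeks 3 and 7).
#' @return list with `summary` (arm x week mean, SEM, n), `anova` (the
#'   two-way ANOVA table) and `pairwise` (per-week Tukey-adjusted arm
#'   contrasts).
#' @export
compare_groups <- function(scores, excluded_weeks = integer()) {
  scores <- scores[!scores$week %in% excluded_weeks, ]
  scores$arm <- factor(scores$arm)
  if (nlevels(scores$arm) < 2L)
    stop("at least two treatment arms are required")
  if (any(table(scores$arm[!duplicated(scores$animal)]) < 2L))
    stop("each arm needs at least two animals")
  scores$weekf <- factor(scores$week)
  agg <- stats::aggregate(normalized_gcs ~ arm + weekf, data = scores,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v)),
                                              n = length(v)))
  summary_df <- data.frame(arm = agg$arm,
                           week = as.numeric(as.character(agg$weekf)),
                           mean = agg$normalized_gcs[, "mean"],
                           sem = agg$normalized_gcs[, "sem"],
                           n = agg$normalized_gcs[, "n"])
  summary_df <- summary_df[order(summary_df$week, summary_df$arm), ]
  rownames(summary_df) <- NULL
  fit <- stats::lm(normalized_gcs ~ arm * weekf, data = scores)
  em <- emmeans::emmeans(fit, ~ arm | weekf)
  prs <- summary(graphics::pairs(em, adjust = "tukey"))
  pairwise <- data.frame(week = as.numeric(as.character(prs$weekf)),
                         contrast = as.character(prs$contrast),
                         estimate = prs$estimate,
                         p_adj = prs$p.value,
                         stringsAsFactors = FALSE)
  list(summary = summary_df,
       anova = stats::anova(fit),
       pairwise = pairwise)
}
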