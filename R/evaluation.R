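# Scoring of model predictions against observed competition trials:
# observed log-ratio advantage with a +1 extinction correction, binary
# winners, low-density replicate dropping, bootstrap proportion tests,
# reversal counting via median sign change and predicted-observed
# correlation.

#' Observed competitive advantage from a pair of densities
#'
#' `R_obs = ln((density_a + 1) / (density_b + 1))`; one cell is added to
#' each density so that trials where one species went locally extinct
#' remain finite (double extinction scores a tie).
#'
#' @param density_a,density_b cell densities (cells mL^-1, >= 0),
#'   vectorised.
#' @return the observed log-ratio advantage of species a.
#' @export
observed_R <- function(density_a, density_b) {
  if (any(density_a < 0) || any(density_b < 0))
    stopf("densities must be >= 0")
  log((density_a + 1) / (density_b + 1))
}

#' Binary winner from a competitive advantage
#'
#' @param R competitive advantage (observed or predicted), vectorised.
#' @return `"a"` for `R > 0`, `"b"` for `R < 0`, `NA` for an exact zero
#'   (indeterminate; excluded from scoring).
#' @export
binary_winner <- function(R) {
  ifelse(R > 0, "a", ifelse(R < 0, "b", NA_character_))
}

#' Drop replicates whose total density is too low to call a winner
#'
#' Marks replicate-level observations with
#' `density_a + density_b < threshold` as dropped; dropped rows are excluded
#' from every downstream summary. Conditions (pair x temperature x nutrient
#' x day) in which every replicate was dropped are reported as untestable.
#'
#' @param observations data frame in the `competition_counts.csv` schema.
#' @param threshold_cells_per_mL total-density cutoff (default 500, five
#'   times a 100 cells mL^-1 inoculum: near-inoculum stasis means the trial
#'   carries no usable signal).
#' @return the observations with logical column `dropped` (and
#'   `drop_reason`), plus attributes `n_dropped` and `untestable` (data
#'   frame of fully dropped conditions).
#' @export
drop_low_density <- function(observations, threshold_cells_per_mL = 500) {
  if (threshold_cells_per_mL < 0) stopf("threshold must be >= 0")
  check_columns(observations, c("density_a", "density_b"), "observations")
  total <- observations$density_a + observations$density_b
  observations$dropped <- total < threshold_cells_per_mL
  observations$drop_reason <- ifelse(observations$dropped,
                                     "total density below threshold",
                                     NA_character_)
  key_cols <- intersect(c("species_a", "species_b", "temperature_C",
                          "phosphate_umol_L", "day"), names(observations))
  untestable <- if (length(key_cols) > 0 && any(observations$dropped)) {
    conditions <- unique(observations[observations$dropped, key_cols,
                                      drop = FALSE])
    keep <- vapply(seq_len(nrow(conditions)), function(i) {
      sel <- rep(TRUE, nrow(observations))
      for (k in key_cols) sel <- sel & observations[[k]] == conditions[[k]][i]
      all(observations$dropped[sel])
    }, logical(1))
    conditions[keep, , drop = FALSE]
  } else observations[0, key_cols, drop = FALSE]
  attr(observations, "n_dropped") <- sum(observations$dropped)
  attr(observations, "untestable") <- untestable
  observations
}

#' One-sided bootstrap test of a proportion against chance
#'
#' Nonparametric bootstrap of replicate-level correct/incorrect indicators:
#' the indicators are resampled with replacement `B` times and the p-value
#' is the (add-one-adjusted) fraction of bootstrap proportions at or below
#' 0.5, testing H0 "the model does no better than a coin flip". For 0/1
#' indicators the resampled proportion is exactly Binomial(n, phat)/n,
#' which is how the resampling is computed.
#'
#' @param correct logical vector of replicate-level outcomes (NAs removed).
#' @param B number of bootstrap resamples (default 10000).
#' @param seed integer seed; the p-value is deterministic given the seed.
#' @return list with `proportion`, `n`, `p_value`, `B`.
#' @export
bootstrap_proportion_test <- function(correct, B = 10000, seed = NULL) {
  correct <- correct[!is.na(correct)]
  n <- length(correct)
  if (n == 0) stopf("no usable outcomes to test")
  phat <- mean(correct)
  boot <- with_seed(seed, rbinom(B, n, phat) / n)
  list(proportion = phat, n = n,
       p_value = (1 + sum(boot <= 0.5)) / (B + 1), B = B)
}

normalise_pair <- function(df, value_cols_swap, sign_cols = character(),
                           winner_cols = character()) {
  flip <- df$species_a > df$species_b
  if (!any(flip)) return(df)
  tmp <- df$species_a[flip]
  df$species_a[flip] <- df$species_b[flip]
  df$species_b[flip] <- tmp
  for (pair in value_cols_swap) {
    tmp <- df[[pair[1]]][flip]
    df[[pair[1]]][flip] <- df[[pair[2]]][flip]
    df[[pair[2]]][flip] <- tmp
  }
  for (cc in sign_cols) df[[cc]][flip] <- -df[[cc]][flip]
  for (cc in winner_cols)
    df[[cc]][flip] <- c(a = "b", b = "a")[df[[cc]][flip]]
  df
}

#' Join predictions to replicate-level observations
#'
#' Builds the replicate-level comparison table: observed advantage
#' ([observed_R()]) and winner per replicate at the evaluation day, matched
#' to the predicted advantage and winner for the same pair and condition.
#' Predictions in `"Rinf"` mode (no nutrient axis) are matched on pair and
#' temperature only. Pair orientation is normalised alphabetically in both
#' tables first, so either orientation may be supplied.
#'
#' @param predictions data frame from [prediction_grid()].
#' @param observations data frame in the `competition_counts.csv` schema,
#'   optionally carrying a `dropped` column from [drop_low_density()].
#' @param day evaluation day (default 14).
#' @return comparison data frame with one row per surviving replicate:
#'   condition keys, densities, `R_obs`, `observed_winner`, `predicted_R`,
#'   `predicted_winner`, `mode`, `correct` (`NA` when the observed outcome
#'   is an exact tie).
#' @export
compare_predictions <- function(predictions, observations, day = 14) {
  check_columns(predictions, c("species_a", "species_b", "temperature_C",
                               "mode", "R", "winner"), "predictions")
  check_columns(observations, c("species_a", "species_b", "temperature_C",
                                "phosphate_umol_L", "replicate", "day",
                                "density_a", "density_b"), "observations")
  mode <- unique(predictions$mode)
  if (length(mode) != 1) stopf("predictions must be a single mode, got: %s",
                               paste(mode, collapse = ", "))
  obs <- observations[observations$day == day, ]
  if ("dropped" %in% names(obs)) obs <- obs[!obs$dropped, ]
  if (nrow(obs) == 0) stopf("no observations at day %g survive the drops", day)
  obs <- normalise_pair(obs, list(c("density_a", "density_b")))
  pred <- normalise_pair(predictions, list(), sign_cols = "R",
                         winner_cols = "winner")
  obs$R_obs <- observed_R(obs$density_a, obs$density_b)
  obs$observed_winner <- binary_winner(obs$R_obs)

  keys <- c("species_a", "species_b", "temperature_C")
  if (mode == "R") keys <- c(keys, "phosphate_umol_L")
  pred_cols <- pred[, c(keys, "R", "winner")]
  names(pred_cols)[names(pred_cols) == "R"] <- "predicted_R"
  names(pred_cols)[names(pred_cols) == "winner"] <- "predicted_winner"
  cmp <- merge(obs, pred_cols, by = keys, sort = FALSE)
  if (nrow(cmp) == 0) stopf("predictions and observations share no conditions")
  cmp$mode <- mode
  cmp$correct <- ifelse(is.na(cmp$observed_winner) |
                          cmp$predicted_winner == "tie", NA,
                        cmp$observed_winner == cmp$predicted_winner)
  cmp
}

#' Proportion of competitive outcomes correctly predicted
#'
#' Scores the fraction of non-dropped replicates whose observed binary
#' winner matches the model's prediction, with a one-sided bootstrap
#' p-value against chance ([bootstrap_proportion_test()]). An optional
#' subset restricts scoring, e.g. to one temperature, one nutrient level,
#' or all pairs involving one species.
#'
#' @param predictions,observations,day as in [compare_predictions()]. A
#'   precomputed comparison table can be passed as `predictions` with
#'   `observations = NULL`.
#' @param subset `NULL` for the full dataset, or a named list with any of
#'   `temperature_C`, `phosphate_umol_L`, `species` (matching either member
#'   of the pair).
#' @param label subset label recorded in the output row.
#' @param B,seed bootstrap resamples and seed.
#' @return one-row data frame: `subset`, `mode`, `proportion_correct`, `n`,
#'   `p_value`. `proportion_correct * n` is always an integer count.
#' @export
proportion_correct <- function(predictions, observations = NULL,
                               subset = NULL, label = "full", day = 14,
                               B = 10000, seed = NULL) {
  cmp <- if (is.null(observations)) predictions
         else compare_predictions(predictions, observations, day = day)
  if (!is.null(subset)) {
    if (!is.null(subset$temperature_C))
      cmp <- cmp[cmp$temperature_C == subset$temperature_C, ]
    if (!is.null(subset$phosphate_umol_L))
      cmp <- cmp[cmp$phosphate_umol_L == subset$phosphate_umol_L, ]
    if (!is.null(subset$species))
      cmp <- cmp[cmp$species_a == subset$species |
                   cmp$species_b == subset$species, ]
  }
  cmp <- cmp[!is.na(cmp$correct), ]
  if (nrow(cmp) == 0)
    return(data.frame(subset = label, mode = NA_character_,
                      proportion_correct = NA_real_, n = 0L,
                      p_value = NA_real_, stringsAsFactors = FALSE))
  bt <- bootstrap_proportion_test(cmp$correct, B = B, seed = seed)
  data.frame(subset = label, mode = cmp$mode[1],
             proportion_correct = bt$proportion, n = bt$n,
             p_value = bt$p_value, stringsAsFactors = FALSE)
}

#' Subset-structured evaluation summary
#'
#' Scores the full dataset, then each temperature, each nutrient level and
#' each species in turn — the standard presentation of proportion-correct
#' results for a two-temperature by three-nutrient pairwise design.
#'
#' @inheritParams proportion_correct
#' @return data frame of [proportion_correct()] rows.
#' @export
evaluation_table <- function(predictions, observations, day = 14, B = 10000,
                             seed = NULL) {
  cmp <- compare_predictions(predictions, observations, day = day)
  rows <- list(proportion_correct(cmp, subset = NULL, label = "full",
                                  B = B, seed = substream_seed(seed, 1)))
  i <- 1
  for (T_C in sort(unique(cmp$temperature_C))) {
    i <- i + 1
    rows[[length(rows) + 1]] <- proportion_correct(
      cmp, subset = list(temperature_C = T_C),
      label = sprintf("T=%g", T_C), B = B, seed = substream_seed(seed, i))
  }
  for (S in sort(unique(cmp$phosphate_umol_L))) {
    i <- i + 1
    rows[[length(rows) + 1]] <- proportion_correct(
      cmp, subset = list(phosphate_umol_L = S),
      label = sprintf("P=%g", S), B = B, seed = substream_seed(seed, i))
  }
  for (sp in sort(unique(c(cmp$species_a, cmp$species_b)))) {
    i <- i + 1
    rows[[length(rows) + 1]] <- proportion_correct(
      cmp, subset = list(species = sp), label = sp,
      B = B, seed = substream_seed(seed, i))
  }
  do.call(rbind, rows)
}

#' Observed and predicted competitive reversals between two temperatures
#'
#' An observed reversal is qualified when the median observed advantage of
#' a pair across replicates changes sign between the two temperatures (a
#' median of exactly zero is indeterminate and excluded). The predicted
#' reversal compares the sign of the predicted advantage at the same two
#' temperatures, per nutrient level.
#'
#' @param observations `competition_counts.csv`-schema data frame
#'   (optionally with `dropped`).
#' @param predictions data frame from [prediction_grid()] (single mode).
#' @param day evaluation day (default 14).
#' @return data frame with one row per pair x nutrient level:
#'   `species_a`, `species_b`, `phosphate_umol_L`, the two median observed
#'   advantages, `observed` (logical, `NA` indeterminate), `predicted`
#'   (logical, `NA` indeterminate or missing prediction), and attribute-free
#'   counts retrievable via [reversal_summary()].
#' @export
count_reversals <- function(observations, predictions, day = 14) {
  check_columns(observations, c("species_a", "species_b", "temperature_C",
                                "phosphate_umol_L", "replicate", "day",
                                "density_a", "density_b"), "observations")
  obs <- observations[observations$day == day, ]
  if ("dropped" %in% names(obs)) obs <- obs[!obs$dropped, ]
  obs <- normalise_pair(obs, list(c("density_a", "density_b")))
  pred <- normalise_pair(predictions, list(), sign_cols = "R",
                         winner_cols = "winner")
  mode <- unique(pred$mode)
  temps <- sort(unique(obs$temperature_C))
  if (length(temps) != 2)
    stopf("reversal counting needs exactly 2 temperatures, found %d",
          length(temps))
  obs$R_obs <- observed_R(obs$density_a, obs$density_b)

  cells <- unique(obs[, c("species_a", "species_b", "phosphate_umol_L")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sel <- obs$species_a == cell$species_a & obs$species_b == cell$species_b &
      obs$phosphate_umol_L == cell$phosphate_umol_L
    med <- vapply(temps, function(T_C) {
      v <- obs$R_obs[sel & obs$temperature_C == T_C]
      if (length(v) == 0) NA_real_ else median(v)
    }, numeric(1))
    observed <- if (any(is.na(med)) || any(med == 0)) NA
                else sign(med[1]) != sign(med[2])
    psel <- pred$species_a == cell$species_a &
      pred$species_b == cell$species_b &
      (mode == "Rinf" | pred$phosphate_umol_L == cell$phosphate_umol_L)
    pR <- vapply(temps, function(T_C) {
      v <- pred$R[psel & pred$temperature_C == T_C]
      if (length(v) == 0) NA_real_ else v[1]
    }, numeric(1))
    predicted <- if (any(is.na(pR)) || any(abs(pR) < TIE_TOLERANCE)) NA
                 else sign(pR[1]) != sign(pR[2])
    data.frame(species_a = cell$species_a, species_b = cell$species_b,
               phosphate_umol_L = cell$phosphate_umol_L,
               median_R_low_T = med[1], median_R_high_T = med[2],
               observed = observed, predicted = predicted,
               mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise a reversal table
#'
#' Counts observed reversals and the proportion of them the model also
#' predicted, for the full table and per nutrient level.
#'
#' @param reversals data frame from [count_reversals()].
#' @return data frame with `subset`, `observed_yes`, `observed_no`,
#'   `predicted_among_observed`, `proportion_predicted`.
#' @export
reversal_summary <- function(reversals) {
  summarise_one <- function(d, label) {
    det <- d[!is.na(d$observed), ]
    obs_yes <- det[det$observed, ]
    hit <- sum(obs_yes$predicted, na.rm = TRUE)
    data.frame(subset = label,
               observed_yes = nrow(obs_yes),
               observed_no = sum(!det$observed),
               predicted_among_observed = hit,
               proportion_predicted = if (nrow(obs_yes) > 0)
                 hit / nrow(obs_yes) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list(summarise_one(reversals, "full"))
  for (S in sort(unique(reversals$phosphate_umol_L)))
    rows[[length(rows) + 1]] <-
      summarise_one(reversals[reversals$phosphate_umol_L == S, ],
                    sprintf("P=%g", S))
  do.call(rbind, rows)
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Correlation between predicted and observed advantage
#'
#' Pearson correlation over replicate-level pairs of predicted and observed
#' advantage, with a 95% Fisher-z confidence interval.
#'
#' @inheritParams compare_predictions
#' @return list with `r`, `ci` (length-2), `n`.
#' @export
correlate_pred_obs <- function(predictions, observations, day = 14) {
  cmp <- compare_predictions(predictions, observations, day = day)
  x <- cmp$predicted_R; y <- cmp$R_obs
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("zero variance in predicted or observed advantage")
  r <- cor(x, y)
  list(r = r, ci = fisher_ci(r, length(x)), n = length(x))
}

#' Day-to-day persistence of the observed advantage
#'
#' Pearson correlation between observed advantages at two sampling days,
#' paired by pair x temperature x nutrient x replicate — the check that an
#' early exponential-phase advantage persists to later census days.
#'
#' @param observations `competition_counts.csv`-schema data frame.
#' @param day1,day2 the two sampling days to correlate.
#' @return list with `r`, `ci`, `n`.
#' @export
day_persistence <- function(observations, day1 = 5, day2 = 14) {
  obs <- observations
  if ("dropped" %in% names(obs)) obs <- obs[!obs$dropped, ]
  obs$R_obs <- observed_R(obs$density_a, obs$density_b)
  keys <- c("species_a", "species_b", "temperature_C", "phosphate_umol_L",
            "replicate")
  d1 <- obs[obs$day == day1, c(keys, "R_obs")]
  d2 <- obs[obs$day == day2, c(keys, "R_obs")]
  m <- merge(d1, d2, by = keys, suffixes = c("_1", "_2"))
  if (nrow(m) < 3) stopf("need at least 3 paired replicates")
  r <- cor(m$R_obs_1, m$R_obs_2)
  list(r = r, ci = fisher_ci(r, nrow(m)), n = nrow(m))
}
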