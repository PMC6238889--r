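#' Parameters of the synthetic cohort generator
#'
#' The generator emulates the marginal structure of a large online
#' within-subjects study of adults with type 2 diabetes: HbA1c distribution,
#' pre/post drawn outcome-expectancy AUC decreases, 7-point walking
#' intentions with post-measurement missingness, weekly walking minutes
#' (reported vs planned), and a contaminated subpopulation whose drawings
#' carry heavy-tailed noise ("non-understanders").
#'
#' Post-simulation expectancies are generated by shrinking each
#' participant's pre-simulation expectancy toward their own simulated AUC
#' reduction — the mechanism by which an interactive simulation shifts
#' beliefs toward what it shows. Default shrinkage weight and noise SD are
#' calibrated so the post column's marginal mean/SD match the study values
#' (see the methods vignette).
#'
#' @param n Number of participants (default 1335).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param hba1c_mean,hba1c_sd,hba1c_min,hba1c_max Parent mean/SD and
#'   truncation bounds of the HbA1c distribution (the bounds are the range
#'   the curve bank supports).
#' @param pre_expectancy_mean,pre_expectancy_sd Gaussian core of the
#'   pre-simulation AUC decrease (mg/dl x min).
#' @param shrinkage_weight Weight on the participant's own simulated
#'   reduction in the post-simulation expectancy.
#' @param expectancy_noise_sd SD of the post-simulation drawing noise.
#' @param intention_pre_mean,intention_pre_sd,intention_gain,intention_post_sd
#'   Latent-Gaussian parameters of the paired 1-7 intention ratings
#'   (clamped to the scale after generation).
#' @param intention_missing Missing-completely-at-random rate of the
#'   post-simulation intention rating.
#' @param minutes_pre_mean,minutes_pre_sd Gamma marginal of minutes walked
#'   last week.
#' @param minutes_planned_mean,minutes_planned_sd Gamma marginal of planned
#'   minutes for the coming week.
#' @param pair_cor Latent within-person correlation for paired measures.
#' @param contamination Fraction of non-understanders.
#' @param contamination_scale,contamination_df Scale and degrees of freedom
#'   of the Student-t drawing noise added to contaminated rows.
#' @param walk_start,walk_duration The simulated walk shown to every
#'   participant (default 9 AM, 30 minutes).
#' @param curve,effect [curve_config()] and [effect_config()] used for the
#'   per-participant simulation.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n = 1335,
                          seed = 20251,
                          hba1c_mean = 7.3, hba1c_sd = 1.2,
                          hba1c_min = 5.9, hba1c_max = 10.1,
                          pre_expectancy_mean = 12265,
                          pre_expectancy_sd = 20253,
                          shrinkage_weight = 0.2568,
                          expectancy_noise_sd = 11775,
                          intention_pre_mean = 5.16,
                          intention_pre_sd = 1.8,
                          intention_gain = 0.31,
                          intention_post_sd = 1.6,
                          intention_missing = 0.25,
                          minutes_pre_mean = 67.1, minutes_pre_sd = 88.0,
                          minutes_planned_mean = 100.5,
                          minutes_planned_sd = 100.4,
                          pair_cor = 0.5,
                          contamination = 0.106,
                          contamination_scale = 15000,
                          contamination_df = 4,
                          walk_start = 540, walk_duration = 30,
                          curve = curve_config(),
                          effect = effect_config()) {
  if (intention_missing < 0 || intention_missing > 1 ||
      contamination < 0 || contamination > 1) {
    stopf("rates must lie in [0, 1]", class = "glywalk_bad_config")
  }
  if (any(c(hba1c_sd, pre_expectancy_sd, expectancy_noise_sd,
            intention_pre_sd, intention_post_sd, minutes_pre_sd,
            minutes_planned_sd) < 0)) {
    stopf("SDs must be >= 0", class = "glywalk_bad_config")
  }
  if (abs(pair_cor) > 1) stopf("pair_cor must be in [-1, 1]",
                               class = "glywalk_bad_config")
  structure(as.list(environment()), class = "cohort_params")
}

# correlated standard-normal pair
bivnorm <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

#' Generate a synthetic participant table
#'
#' Returns one row per participant with the study's per-person measures:
#' HbA1c, pre/post expectancy AUC decreases, the participant's own simulated
#' AUC reduction for the default walk, paired intention ratings (post
#' possibly missing), reported and planned walking minutes, and the
#' non-understander flag. Deterministic given `params$seed`.
#'
#' @param params A [cohort_params()].
#' @return `data.frame`, one row per participant.
#' @export
#' @examples
#' head(generate_cohort(cohort_params(n = 10, seed = 1)))
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    stopf("params must come from cohort_params()", class = "glywalk_bad_input")
  }
  n <- params$n
  if (is.null(n) || n < 2) {
    stopf("n must be >= 2 (paired tests are undefined otherwise)",
          class = "glywalk_bad_input")
  }
  plan <- walk_plan(params$walk_start, params$walk_duration)
  with_seed(params$seed, {
    hba1c <- rtruncnorm(n, params$hba1c_mean, params$hba1c_sd,
                        params$hba1c_min, params$hba1c_max)
    sim_noise <- rnorm(n, 0, params$effect$noise_sd)
    sim <- reduction_for_cohort(hba1c, plan, params$curve,
                                params$effect, sim_noise)
    pre <- rnorm(n, params$pre_expectancy_mean, params$pre_expectancy_sd)
    w <- params$shrinkage_weight
    post <- (1 - w) * pre + w * sim +
      rnorm(n, 0, params$expectancy_noise_sd)
    contaminated <- runif(n) < params$contamination
    k <- sum(contaminated)
    if (k) {
      pre[contaminated] <- pre[contaminated] +
        params$contamination_scale * rt(k, params$contamination_df)
      post[contaminated] <- post[contaminated] +
        params$contamination_scale * rt(k, params$contamination_df)
    }
    zi <- bivnorm(n, params$pair_cor)
    intention_pre <- pmin(pmax(params$intention_pre_mean +
                                 params$intention_pre_sd * zi[, 1], 1), 7)
    intention_post <- pmin(pmax(params$intention_pre_mean +
                                  params$intention_gain +
                                  params$intention_post_sd * zi[, 2], 1), 7)
    intention_post[runif(n) < params$intention_missing] <- NA_real_
    zm <- bivnorm(n, params$pair_cor)
    sh1 <- (params$minutes_pre_mean / params$minutes_pre_sd)^2
    sc1 <- params$minutes_pre_sd^2 / params$minutes_pre_mean
    sh2 <- (params$minutes_planned_mean / params$minutes_planned_sd)^2
    sc2 <- params$minutes_planned_sd^2 / params$minutes_planned_mean
    minutes_last_week <- qgamma(pnorm(zm[, 1]), shape = sh1, scale = sc1)
    minutes_planned <- qgamma(pnorm(zm[, 2]), shape = sh2, scale = sc2)
    data.frame(id = seq_len(n),
               hba1c = hba1c,
               pre_expectancy_auc_decrease = pre,
               post_expectancy_auc_decrease = post,
               sim_auc_reduction = sim,
               intention_pre = intention_pre,
               intention_post = intention_post,
               minutes_last_week = minutes_last_week,
               minutes_planned = minutes_planned,
               excluded_candidate = contaminated)
  })
}

COHORT_NUMERIC <- c("id", "hba1c", "pre_expectancy_auc_decrease",
                    "post_expectancy_auc_decrease", "sim_auc_reduction",
                    "intention_pre", "intention_post",
                    "minutes_last_week", "minutes_planned")

#' Write / read a cohort table as CSV
#'
#' Numeric fields are written with 17 significant digits so the CSV
#' round-trip is lossless; a missing post-simulation intention is an empty
#' cell.
#'
#' @param cohort A cohort `data.frame` as from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the table; `write_cohort()` the path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in intersect(COHORT_NUMERIC, names(out))) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- ""
    out[[col]] <- v
  }
  out$excluded_candidate <- ifelse(cohort$excluded_candidate, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  missing_cols <- setdiff(c(COHORT_NUMERIC, "excluded_candidate"), names(raw))
  if (length(missing_cols)) {
    stopf("cohort file is missing column(s): %s",
          paste(missing_cols, collapse = ", "), class = "glywalk_parse_error")
  }
  for (col in COHORT_NUMERIC) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & nzchar(trimws(v)))
    if (length(bad)) {
      stopf("non-numeric value '%s' in column '%s' at row %d",
            v[bad[1]], col, bad[1], class = "glywalk_parse_error")
    }
    raw[[col]] <- num
  }
  raw$id <- as.integer(raw$id)
  raw$excluded_candidate <- raw$excluded_candidate == "TRUE"
  raw
}
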