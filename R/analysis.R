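#' Paired t test on two same-length measurement vectors
#'
#' Classical paired t on d = y - x after pairwise deletion of incomplete
#' pairs: t = mean(d) / (sd(d) / sqrt(n)), df = n - 1, two-sided p from the
#' t distribution.
#'
#' @param x,y Numeric vectors of equal length (pre and post measurements);
#'   pairs with a missing value in either are dropped.
#' @param measure Optional label carried into the result.
#' @return Object of class `paired_test` with `n`, `mean_difference`,
#'   `sd_of_differences`, `t`, `df` and `p.value`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 3, 5, 5))
paired_t <- function(x, y, measure = NULL) {
  if (length(x) != length(y)) {
    stopf("x and y must have equal length", class = "glywalk_bad_input")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) {
    stopf("need at least 2 complete pairs (got %d)", n,
          class = "glywalk_insufficient_data")
  }
  n <- as.integer(n)
  d <- y - x
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- 2 * pt(-abs(t), df = n - 1)
  structure(list(n = n, mean_difference = m, sd_of_differences = s,
                 t = t, df = n - 1L, p.value = p,
                 measure = measure %||% "paired difference"),
            class = "paired_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Difference-of-differences test for belief shift
#'
#' Tests whether drawn outcome expectancies moved toward the simulated
#' outcome: a paired t test on (pre - sim) versus (post - sim), i.e. on the
#' gap between each drawing and the participant's own simulation. The mean
#' difference equals mean(pre) - mean(post) algebraically — the simulation
#' column cancels from the mean (though not from its SD).
#'
#' @param pre_minus_sim Per-participant pre-drawing AUC decrease minus
#'   simulated AUC reduction.
#' @param post_minus_sim Same for the post drawing.
#' @return A `paired_test`; positive `mean_difference` means expectancies
#'   moved toward the simulation.
#' @export
diff_of_diffs <- function(pre_minus_sim, post_minus_sim) {
  res <- paired_t(post_minus_sim, pre_minus_sim,
                  measure = "expectancy shift toward simulation")
  res
}

#' Missing-data sensitivity suite for a paired comparison
#'
#' Runs the paired t test under three strategies for missing post values:
#' complete-case deletion, imputing the mean of the observed post values,
#' and carrying the participant's own pre value forward (under which that
#' participant contributes a zero difference). Reports all three and selects
#' the most conservative, operationalised as the smallest |t|.
#'
#' @param pre Complete pre-measurement vector.
#' @param post Post-measurement vector, possibly with missing values.
#' @return List with elements `complete_case`, `mean_imputation`,
#'   `carry_forward` (each a `paired_test`), `most_conservative` (the name
#'   of the selected strategy) and `selected` (its result).
#' @export
imputation_suite <- function(pre, post) {
  if (length(pre) != length(post)) {
    stopf("pre and post must have equal length", class = "glywalk_bad_input")
  }
  ok_pre <- is.finite(pre)
  pre <- pre[ok_pre]; post <- post[ok_pre]
  miss <- !is.finite(post)
  post_mean <- post
  post_mean[miss] <- mean(post[!miss])
  post_locf <- post
  post_locf[miss] <- pre[miss]
  res <- list(complete_case = paired_t(pre, post, "complete case"),
              mean_imputation = paired_t(pre, post_mean, "mean imputation"),
              carry_forward = paired_t(pre, post_locf, "pre carried forward"))
  pick <- which.min(vapply(res, function(r) abs(r$t), numeric(1)))
  c(res, list(most_conservative = names(res)[pick], selected = res[[pick]]))
}

#' Apply the subset-exclusion rules to a cohort
#'
#' Removes participants whose drawings are extreme under the
#' [outlier_rule()] on *both* the pre and post drawing, or who are marked as
#' self-reported non-understanders (`excluded_candidate`).
#'
#' @param cohort A cohort `data.frame`.
#' @param rule An [outlier_rule()].
#' @return List with `cohort` (retained rows) and `report` (named counts:
#'   input, retained, excluded, and per-reason counts; reasons can overlap).
#' @export
subset_filter <- function(cohort, rule = outlier_rule()) {
  out_both <- flag_outlier(cohort$pre_expectancy_auc_decrease, rule) &
    flag_outlier(cohort$post_expectancy_auc_decrease, rule)
  self <- cohort$excluded_candidate %in% TRUE
  drop <- out_both | self
  list(cohort = cohort[!drop, , drop = FALSE],
       report = list(n_input = nrow(cohort),
                     n_retained = sum(!drop),
                     n_excluded = sum(drop),
                     n_outlier_both_drawings = sum(out_both),
                     n_self_reported = sum(self)))
}

measure_row <- function(pre, post) {
  list(pre_mean = mean(pre, na.rm = TRUE), pre_sd = sd(pre[is.finite(pre)]),
       post_mean = mean(post, na.rm = TRUE),
       post_sd = sd(post[is.finite(post)]))
}

analyse_sample <- function(cohort) {
  list(n = nrow(cohort),
       expectancy = measure_row(cohort$pre_expectancy_auc_decrease,
                                cohort$post_expectancy_auc_decrease),
       intention = measure_row(cohort$intention_pre, cohort$intention_post),
       minutes = measure_row(cohort$minutes_last_week,
                             cohort$minutes_planned),
       expectancy_shift = diff_of_diffs(
         cohort$pre_expectancy_auc_decrease - cohort$sim_auc_reduction,
         cohort$post_expectancy_auc_decrease - cohort$sim_auc_reduction),
       intention_tests = imputation_suite(cohort$intention_pre,
                                          cohort$intention_post),
       minutes_test = paired_t(cohort$minutes_last_week,
                               cohort$minutes_planned,
                               "planned minus reported minutes"))
}

#' Summarise a study cohort: pre/post tables and the three paired analyses
#'
#' Produces the study's headline summary for the full sample and for the
#' subset retained after exclusion: per-measure pre/post means and SDs, the
#' difference-of-differences test on expectancies, the intention paired test
#' with missing-data sensitivity (most conservative reported), and the
#' reported-vs-planned minutes paired test.
#'
#' @param cohort A cohort `data.frame`.
#' @param rule An [outlier_rule()] for the subset analysis.
#' @return Object of class `study_summary` with elements `full`, `subset`
#'   and `exclusions`.
#' @export
summarize_study <- function(cohort, rule = outlier_rule()) {
  sub <- subset_filter(cohort, rule)
  structure(list(full = analyse_sample(cohort),
                 subset = analyse_sample(sub$cohort),
                 exclusions = sub$report),
            class = "study_summary")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t test (%s)\n", x$measure))
  cat(sprintf("  n = %d pairs; mean difference = %.4g (SD of differences %.4g)\n",
              x$n, x$mean_difference, x$sd_of_differences))
  cat(sprintf("  t(%d) = %.3f, two-sided p = %.3g\n", x$df, x$t, x$p.value))
  invisible(x)
}

print_sample <- function(s, label) {
  cat(sprintf("%s (n = %d)\n", label, s$n))
  cat(sprintf("  Outcome expectancy (AUC decrease): %.0f (%.0f) -> %.0f (%.0f) mg/dl x min\n",
              s$expectancy$pre_mean, s$expectancy$pre_sd,
              s$expectancy$post_mean, s$expectancy$post_sd))
  es <- s$expectancy_shift
  cat(sprintf("    shift toward simulation: %.1f, t(%d) = %.2f, p = %.3g\n",
              es$mean_difference, es$df, es$t, es$p.value))
  cat(sprintf("  Intention (1-7): %.2f (%.2f) -> %.2f (%.2f)\n",
              s$intention$pre_mean, s$intention$pre_sd,
              s$intention$post_mean, s$intention$post_sd))
  it <- s$intention_tests$selected
  cat(sprintf("    gain %.3f, t(%d) = %.2f, p = %.3g [%s]\n",
              it$mean_difference, it$df, it$t, it$p.value,
              s$intention_tests$most_conservative))
  cat(sprintf("  Minutes walking: %.1f (%.1f) reported -> %.1f (%.1f) planned\n",
              s$minutes$pre_mean, s$minutes$pre_sd,
              s$minutes$post_mean, s$minutes$post_sd))
  mt <- s$minutes_test
  cat(sprintf("    gain %.1f min, t(%d) = %.2f, p = %.3g\n",
              mt$mean_difference, mt$df, mt$t, mt$p.value))
}

#' @export
print.study_summary <- function(x, ...) {
  print_sample(x$full, "Full sample")
  cat(sprintf("Exclusions: %d of %d (%d extreme on both drawings, %d self-reported)\n",
              x$exclusions$n_excluded, x$exclusions$n_input,
              x$exclusions$n_outlier_both_drawings,
              x$exclusions$n_self_reported))
  print_sample(x$subset, "Retained subset")
  invisible(x)
}
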