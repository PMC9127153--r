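#' Participant demographic summaries by sex
#'
#' Printed group summaries (mean, SD, n per sex) for the study demographics
#' and maximal-test outcomes, as inputs to the summary-level independent
#' t-tests of [t_from_summary()]. The `height_m` row is known not to
#' reproduce its originally printed t statistic from these rounded summaries
#' (pooled t gives 3.65) and is flagged by `reproducible = FALSE`.
#'
#' @return data.frame with columns `variable, male_mean, male_sd, female_mean,
#'   female_sd, n_per_group, reproducible`.
#' @export
demographics_summary <- function() {
  data.frame(
    variable    = c("age_yr", "height_m", "weight_kg", "bmi", "sbp", "dbp",
                    "treadmill_vo2", "cycle_vo2", "arm_vo2",
                    "squat_1rm_kg", "bench_1rm_kg", "biceps_1rm_kg"),
    male_mean   = c(24.00, 1.73, 73.94, 24.73, 117.00, 75.14,
                    50.60, 34.59, 32.34, 101.83, 76.86, 47.02),
    male_sd     = c(3.56, 0.05, 7.60, 2.19, 9.07, 7.49,
                    5.21, 10.16, 10.43, 43.04, 16.18, 21.36),
    female_mean = c(22.00, 1.60, 64.41, 25.21, 109.57, 73.00,
                    35.91, 29.41, 25.13, 64.86, 34.70, 20.43),
    female_sd   = c(1.63, 0.08, 12.37, 4.57, 7.59, 6.51,
                    7.95, 7.99, 7.43, 17.08, 7.26, 4.73),
    n_per_group = 7L,
    reproducible = c(TRUE, FALSE, rep(TRUE, 10L))
  )
}

#' Sex-difference t-tests from the demographic summaries
#'
#' Runs [t_from_summary()] on every row of [demographics_summary()].
#' @return data.frame with `variable, t, df, p, reproducible`.
#' @export
demographic_t_tests <- function() {
  tab <- demographics_summary()
  res <- lapply(seq_len(nrow(tab)), function(i) {
    tt <- t_from_summary(tab$male_mean[i], tab$male_sd[i], tab$n_per_group[i],
                         tab$female_mean[i], tab$female_sd[i], tab$n_per_group[i])
    data.frame(variable = tab$variable[i], t = tt$t, df = tt$df, p = tt$p,
               reproducible = tab$reproducible[i])
  })
  do.call(rbind, res)
}
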