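test_that("canonical waveform honours period arithmetic, determinism and positivity", {
  w <- canonical_waveform(60, 128)
  expect_equal(w$period, 1.0)
  expect_length(w$v, 128)
  expect_equal(w$t, (0:127) / 128)
  expect_identical(canonical_waveform(60, 128)$v, w$v)
  expect_gt(min(w$v), 0)                       # no retrograde flow
  expect_equal(mean(w$v), 1, tolerance = 1e-14) # unit-mean normalisation
  # shape has a dominant systolic peak and a later secondary (dicrotic) wave
  peak <- which.max(w$v)
  expect_lt(w$t[peak], 0.3 * w$period)
  after <- w$v[(peak + 10):128]
  expect_true(any(diff(after) > 0))            # local rebound after the notch
  expect_error(canonical_waveform(20), "30")
  expect_error(canonical_waveform(70, 32), "64")
})

test_that("calibrate_scale is exact by linearity", {
  base <- canonical_waveform(70)
  g <- default_geometry(); b <- default_blood()
  base_ess <- ess_waveform(base, g, b)$mean_ess
  expect_equal(calibrate_scale(base_ess, base, g, b), 1, tolerance = 1e-12)
  expect_equal(calibrate_scale(2 * base_ess, base, g, b), 2, tolerance = 1e-12)
  sc <- calibrate_scale(84.7, base, g, b)
  scaled <- velocity_waveform(base$v * sc, base$period)
  expect_equal(ess_waveform(scaled, g, b)$mean_ess, 84.7, tolerance = 1e-6)
  expect_error(calibrate_scale(-1, base, g, b), "positive")
})

test_that("generate_study has the declared design arithmetic and sex balance", {
  st <- generate_study(seed = 3, build_waveforms = FALSE)
  tt <- truth_table(st)
  expect_equal(nrow(tt), 14 * 20)              # 18 exercise + 2 baseline records
  expect_equal(length(unique(tt$participant_id)), 14)
  sex_by_pid <- unique(tt[, c("participant_id", "sex")])
  expect_equal(sort(as.vector(table(sex_by_pid$sex))), c(7, 7))
  per_pid <- table(tt$participant_id)
  expect_true(all(per_pid == 20))
  expect_true(all(tt$true_ess_dyn_cm2 > 0))
})

test_that("a fixed seed reproduces the study byte-for-byte; seeds differ", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  export_waveforms(generate_study(seed = 7, samples = 64), f1)
  export_waveforms(generate_study(seed = 7, samples = 64), f2)
  expect_identical(readLines(f1), readLines(f2))
  export_waveforms(generate_study(seed = 8, samples = 64), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
  unlink(c(f1, f2))
})

test_that("degenerate calibration (icc = 0, SD = 0) pins every target to the mean", {
  cal <- default_calibration()
  cal$ess_sd <- 0
  tt <- truth_table(generate_study(calibration = cal, icc = 0, seed = 1,
                                   build_waveforms = FALSE))
  by_cond <- split(tt$true_ess_dyn_cm2, paste(tt$modality, tt$intensity))
  for (cond in names(by_cond)) expect_equal(diff(range(by_cond[[cond]])), 0)
  m <- merge(unique(tt[, c("modality", "intensity")]), cal)
  got <- tt$true_ess_dyn_cm2[match(paste(m$modality, m$intensity),
                                   paste(tt$modality, tt$intensity))]
  expect_equal(got, m$ess_mean)
})

test_that("the pipeline recovers every generating-truth ESS (end-to-end identity)", {
  st <- generate_study(design = study_design(4), seed = 11, samples = 64)
  res <- compute_ess_table(waveform_table(st))
  tt <- truth_table(st)
  m <- merge(as.data.frame(res), as.data.frame(tt),
             by = c("participant_id", "sex", "modality", "intensity"))
  expect_equal(nrow(m), nrow(tt))
  expect_lt(max(abs(m$ess_mean_dyn_cm2 - m$true_ess_dyn_cm2) / m$true_ess_dyn_cm2), 1e-9)
})

test_that("waveform and truth CSVs round-trip numerically", {
  st <- generate_study(design = study_design(2), seed = 5, samples = 64)
  f <- tempfile(fileext = ".csv")
  export_waveforms(st, f)
  back <- read_waveforms(f)
  orig <- waveform_table(st)
  for (col in c("time_s", "velocity_m_s", "diameter_m", "hematocrit", "period_s"))
    expect_equal(back[[col]], orig[[col]], tolerance = 1e-12)
  ft <- tempfile(fileext = ".csv")
  export_truth(st, ft)
  tt <- data.table::fread(ft)
  expect_equal(tt$true_ess_dyn_cm2, truth_table(st)$true_ess_dyn_cm2, tolerance = 1e-12)
  unlink(c(f, ft))
})

test_that("replicate grand means recover the calibration targets (Monte-Carlo)", {
  reps <- 80
  gm <- vapply(seq_len(reps), function(s) {
    tt <- truth_table(generate_study(seed = 300 + s, build_waveforms = FALSE))
    mean(tt$true_ess_dyn_cm2[tt$modality == "Treadmill" & tt$intensity == "high"])
  }, numeric(1))
  se <- sd(gm) / sqrt(reps)
  expect_lt(abs(mean(gm) - 84.7), 3 * se)
})

test_that("the between/within variance split tracks the requested icc", {
  # one-way layout: constant SD across conditions so ICC1 is well-defined
  cal <- null_calibration(mean = 50, sd = 10)
  cal <- cal[cal$intensity != "rest" | cal$modality == "Baseline", ]
  for (icc_true in c(0.2, 0.5)) {
    icc_hat <- vapply(1:60, function(s) {
      tt <- truth_long(900 + s, calibration = cal, icc = icc_true)
      tt <- tt[tt$intensity != "rest", ]
      k <- length(unique(paste(tt$modality, tt$intensity)))
      ms <- anova(stats::lm(ess_mean_dyn_cm2 ~ participant_id, data = tt))
      msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
      (msb - msw) / (msb + (k - 1) * msw)
    }, numeric(1))
    expect_equal(mean(icc_hat), icc_true, tolerance = 0.06)
  }
})

test_that("default calibration keeps exercise turbulent and baselines below threshold", {
  # condition-level expectation, pooled over a few replicate studies
  res <- data.table::rbindlist(lapply(1:4, function(s) {
    compute_ess_table(waveform_table(generate_study(seed = 40 + s, samples = 64)))
  }))
  res <- as.data.frame(res)
  ex <- res[res$intensity != "rest", ]
  cond_means <- tapply(ex$reynolds, paste(ex$modality, ex$intensity), mean)
  expect_true(all(cond_means > 2000))
  base_means <- tapply(res$reynolds[res$intensity == "rest"],
                       res$modality[res$intensity == "rest"], mean)
  expect_true(all(base_means < 2000))
})
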