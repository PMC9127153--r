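# Synthetic carotid Doppler study generator.
#
# The generator emulates the repeated-measures structure of an
# exercise-modality study: n participants (balanced by sex), a complete
# modality x intensity crossing plus two resting baseline visits, with
# per-condition ESS targets drawn around published condition means and a
# participant random intercept controlling the within-person correlation.
# Waveforms are noise-free canonical shapes rescaled so that the Womersley
# pipeline recovers each drawn target exactly (ESS is linear in velocity).

#' Default study design
#'
#' @param n_participants total participants (balanced male/female; default 14).
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_participants = 14L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L) stop("need at least 2 participants")
  structure(list(
    n_participants = n_participants,
    modalities = c("Treadmill", "Cycle-ergometer", "Arm-ergometer",
                   "Squat", "Bench", "Biceps"),
    intensities = c("low", "moderate", "high"),
    baselines = c("Baseline", "Baseline2")
  ), class = "study_design")
}

#' Default condition calibration table
#'
#' Condition-level ESS targets (dyn/cm^2) for every exercise modality x
#' intensity cell and the two resting baselines, with the heart-rate schedule
#' used to set each waveform's period. ESS means/SDs are the published
#' condition summaries this generator is calibrated to; heart rates are
#' physiological defaults (rest 65, low 100, moderate 140, high 175 bpm).
#'
#' @return data.frame with columns `modality`, `intensity`, `ess_mean`,
#'   `ess_sd`, `heart_rate`.
#' @export
default_calibration <- function() {
  hr <- c(rest = 65, low = 100, moderate = 140, high = 175)
  ex <- data.frame(
    modality = rep(c("Arm-ergometer", "Cycle-ergometer", "Treadmill",
                     "Bench", "Biceps", "Squat"), each = 3L),
    intensity = rep(c("low", "moderate", "high"), times = 6L),
    ess_mean = c(39.4, 47.8, 57.8,
                 48.0, 62.6, 77.5,
                 47.5, 67.3, 84.7,
                 34.8, 42.1, 45.6,
                 37.3, 41.3, 50.7,
                 44.1, 48.8, 56.8),
    ess_sd   = c(10.7, 12.1, 20.7,
                 10.8, 19.4, 20.3,
                 13.1, 17.9,  9.7,
                 13.0, 12.0, 13.7,
                 13.3, 12.8, 14.7,
                 14.4, 16.4, 13.57))
  base <- data.frame(
    modality = c("Baseline", "Baseline2"),
    intensity = "rest",
    ess_mean = c(23.8, 26.5),
    ess_sd = c(4.8, 3.3))
  out <- rbind(ex, base)
  out$heart_rate <- hr[out$intensity]
  stopifnot(all(out$ess_mean > 0), all(out$ess_sd < out$ess_mean))
  rownames(out) <- NULL
  out
}

#' Canonical carotid-like velocity waveform (unit mean)
#'
#' Deterministic single-cycle centerline velocity shape with a sharp systolic
#' peak, a dicrotic notch and a secondary dicrotic wave, built from three
#' wrapped-Gaussian pulses on a positive diastolic baseline and normalised so
#' the sampled cycle mean is exactly 1 m/s. The shape is fixed in cardiac
#' phase; heart rate only sets the period.
#'
#' @param heart_rate beats per minute, in `[30, 220]`.
#' @param samples samples per cycle (>= 64; default 128).
#' @return a [velocity_waveform()] with sample mean exactly 1.
#' @export
canonical_waveform <- function(heart_rate, samples = 128L) {
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L ||
      heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must lie in [30, 220] bpm")
  samples <- as.integer(samples)
  if (samples < 64L) stop("need at least 64 samples per cycle")
  period <- 60 / heart_rate
  x <- (seq_len(samples) - 1L) / samples  # cardiac phase in [0, 1)
  wrapped_gauss <- function(x, center, width) {
    g <- 0
    for (m in -1:1) g <- g + exp(-0.5 * ((x - center + m) / width)^2)
    g
  }
  v <- 0.50 +
    1.80 * wrapped_gauss(x, 0.16, 0.055) +   # systolic peak
    0.70 * wrapped_gauss(x, 0.33, 0.080) +   # late-systolic shoulder
    0.45 * wrapped_gauss(x, 0.50, 0.045)     # dicrotic wave
  v <- v / mean(v)
  velocity_waveform(v, period)
}

#' Velocity scale factor reproducing a target mean ESS
#'
#' ESS is linear in a uniform velocity scaling, so the factor is exact:
#' applying it to the base waveform makes the pipeline's cycle-mean ESS equal
#' the target to numerical precision.
#'
#' @param target_ess target cycle-mean ESS (dyn/cm^2, > 0).
#' @param base a [velocity_waveform()].
#' @param geometry a [vessel_geometry()].
#' @param blood a [blood_properties()].
#' @return positive scalar scale factor.
#' @export
calibrate_scale <- function(target_ess, base, geometry, blood) {
  if (!is.numeric(target_ess) || length(target_ess) != 1L || target_ess <= 0)
    stop("target ESS must be a single positive number")
  base_ess <- ess_waveform(base, geometry, blood)$mean_ess
  if (base_ess <= 0) stop("base waveform has non-positive mean ESS; cannot calibrate")
  target_ess / base_ess
}

# Truncated-normal draws via inverse-CDF so one uniform is consumed per
# variate regardless of the bounds.
rtrunc_norm <- function(n, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo), stats::pnorm(hi)))
}

rtrunc3 <- function(n, mean = 0, sd = 1) {
  mean + sd * rtrunc_norm(n, -3, 3)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic repeated-measures carotid study
#'
#' For each participant, draws hematocrit (sex-specific mean), a carotid
#' diameter, and a standardised random intercept; for every condition the
#' participant's ESS target is
#' `mean + sd * (sqrt(icc) * b_i + sqrt(1 - icc) * eps)`, so the marginal SD
#' matches the calibration SD and the intraclass correlation of the intercept
#' share is `icc`. All normal draws are truncated at +-3 SD, and the residual
#' is drawn conditionally on the intercept so the combined deviate cannot
#' push a target below 5% of its condition mean (no negative ESS targets).
#' The record's waveform is the canonical shape at the condition's
#' heart rate, scaled so the Womersley pipeline recovers the target exactly.
#' Randomness is fully determined by `seed`: each participant consumes an
#' independent substream derived from it.
#'
#' @param design a [study_design()].
#' @param calibration calibration table as from [default_calibration()].
#' @param icc intraclass correlation of the participant intercept in `[0, 1)`
#'   (default 0.5).
#' @param seed integer master seed.
#' @param samples waveform samples per cycle (default 128).
#' @param diameter_mean,diameter_sd between-participant carotid lumen
#'   diameter distribution (m); defaults 6.3 mm +- 0.4 mm.
#' @param hct_mean_male,hct_mean_female,hct_sd hematocrit distributions by
#'   sex (fractions).
#' @param build_waveforms if `FALSE`, skip waveform construction and return
#'   records with `waveform = NULL`; the drawn ESS targets are unchanged.
#'   Fast path for statistical Monte-Carlo studies (the full waveform path
#'   recovers the same targets to numerical precision, which is tested as an
#'   invariant of the pipeline).
#' @return Object of class `synthetic_study`: list with `records` (one list
#'   per condition record), `design`, `calibration`, `icc`, `seed`.
#' @export
generate_study <- function(design = study_design(),
                           calibration = default_calibration(),
                           icc = 0.5, seed = 1L, samples = 128L,
                           diameter_mean = 6.3e-3, diameter_sd = 0.4e-3,
                           hct_mean_male = 0.45, hct_mean_female = 0.40,
                           hct_sd = 0.03, build_waveforms = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (icc < 0 || icc >= 1) stop("icc must lie in [0, 1)")
  req <- c("modality", "intensity", "ess_mean", "ess_sd", "heart_rate")
  if (!all(req %in% names(calibration))) stop("calibration table lacks columns: ",
                                              paste(setdiff(req, names(calibration)), collapse = ", "))
  seed <- as.integer(seed)
  n <- design$n_participants
  sexes <- rep(c("M", "F"), length.out = n)
  # condition rows in design order: baselines first, then modality x intensity
  cond <- calibration[order(match(calibration$modality,
                                  c(design$baselines, design$modalities))), ]
  # canonical base shapes, one per distinct heart rate
  base_by_hr <- NULL
  if (build_waveforms) {
    hr_levels <- unique(cond$heart_rate)
    base_by_hr <- stats::setNames(
      lapply(hr_levels, function(h) canonical_waveform(h, samples)),
      as.character(hr_levels))
  }
  records <- vector("list", n * nrow(cond))
  k <- 0L
  for (i in seq_len(n)) {
    sub_seed <- (seed %% 100000L) * 20011L + i  # < 2^31, distinct per participant
    draws <- with_seed(sub_seed, {
      d <- list(hct = rtrunc3(1, if (sexes[i] == "M") hct_mean_male else hct_mean_female, hct_sd),
                diam = rtrunc3(1, diameter_mean, diameter_sd),
                b = rtrunc3(1))
      # combined standardized deviate z = sqrt(icc) b + sqrt(1-icc) eps is
      # kept in [z_lo, 3]: the residual is drawn conditionally on b so no
      # condition target can fall below 5% of its mean (the naive per-draw
      # +-3 SD rule still allows a combined -4.2 SD excursion).
      z_lo <- pmax(-3, -0.95 * cond$ess_mean / ifelse(cond$ess_sd > 0, cond$ess_sd, Inf))
      s_b <- sqrt(icc) * d$b
      s_e <- sqrt(1 - icc)
      eps <- rtrunc_norm(nrow(cond), (z_lo - s_b) / s_e, (3 - s_b) / s_e)
      d$z <- pmin(3, pmax(z_lo, s_b + s_e * eps))
      d
    })
    geom <- vessel_geometry(draws$diam)
    blood <- blood_properties(hematocrit = draws$hct)
    pid <- sprintf("P%02d", i)
    for (j in seq_len(nrow(cond))) {
      target <- cond$ess_mean[j] + cond$ess_sd[j] * draws$z[j]
      wf <- NULL
      if (build_waveforms) {
        base <- base_by_hr[[as.character(cond$heart_rate[j])]]
        sc <- calibrate_scale(target, base, geom, blood)
        wf <- velocity_waveform(base$v * sc, base$period)
      }
      k <- k + 1L
      records[[k]] <- list(participant_id = pid, sex = sexes[i],
                           modality = cond$modality[j], intensity = cond$intensity[j],
                           waveform = wf, diameter = draws$diam, hematocrit = draws$hct,
                           heart_rate = cond$heart_rate[j], true_ess = target)
    }
  }
  structure(list(records = records, design = design, calibration = calibration,
                 icc = icc, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants, %d records (seed %d, icc %.2f)\n",
              x$design$n_participants, length(x$records), x$seed, x$icc))
  invisible(x)
}

#' Long sample table of a synthetic study
#'
#' One row per waveform sample, in the waveform CSV schema shared with
#' [compute_ess_table()].
#' @param study a `synthetic_study`.
#' @return data.table with columns `participant_id, sex, modality, intensity,
#'   time_s, velocity_m_s, diameter_m, hematocrit, period_s`.
#' @export
waveform_table <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  data.table::rbindlist(lapply(study$records, function(r) {
    data.table::data.table(
      participant_id = r$participant_id, sex = r$sex,
      modality = r$modality, intensity = r$intensity,
      time_s = r$waveform$t, velocity_m_s = r$waveform$v,
      diameter_m = r$diameter, hematocrit = r$hematocrit,
      period_s = r$waveform$period)
  }))
}

#' Generating-truth table of a synthetic study
#'
#' @param study a `synthetic_study`.
#' @return data.table with one row per condition record:
#'   `participant_id, sex, modality, intensity, true_ess_dyn_cm2`.
#' @export
truth_table <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  data.table::rbindlist(lapply(study$records, function(r) {
    data.table::data.table(participant_id = r$participant_id, sex = r$sex,
                           modality = r$modality, intensity = r$intensity,
                           true_ess_dyn_cm2 = r$true_ess)
  }))
}

#' Write waveform samples to CSV
#' @param study a `synthetic_study`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_waveforms <- function(study, path) {
  data.table::fwrite(waveform_table(study), path)
  invisible(path)
}

#' Write generating truth to CSV
#' @param study a `synthetic_study`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_truth <- function(study, path) {
  data.table::fwrite(truth_table(study), path)
  invisible(path)
}

#' Read a waveform CSV
#'
#' Validates the schema and field types; a malformed row is reported by its
#' line number (header = line 1).
#' @param path CSV in the waveform schema.
#' @return data.table of samples.
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = c("participant_id", "sex", "modality", "intensity")))
  req <- c("participant_id", "sex", "modality", "intensity", "time_s",
           "velocity_m_s", "diameter_m", "hematocrit", "period_s")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("waveform CSV lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("time_s", "velocity_m_s", "diameter_m", "period_s")) {
    vals <- dt[[col]]
    if (!is.numeric(vals)) vals <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop("malformed value in column '", col, "' at line ", bad[1L] + 1L, " of ", path)
    data.table::set(dt, j = col, value = vals)
  }
  dt
}
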