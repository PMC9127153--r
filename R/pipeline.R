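# simulate -> compute-ess -> analyze orchestration.
#
# Everything is plain CSV/YAML/JSON; a manifest records seed, config hash and
# package version so a run can be reproduced from its output directory alone.

#' Build a run configuration
#'
#' Defaults merged with an optional YAML file. Recognised keys: `seed`,
#' `n_participants`, `icc`, `n_harmonics`, `samples`, `bootstrap_reps`,
#' `outdir`, `calibration` (path to a CSV with columns
#' `modality, intensity, ess_mean, ess_sd, heart_rate`; omit for the built-in
#' defaults).
#'
#' @param path optional YAML config file.
#' @param ... named overrides applied after the file.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, n_participants = 14L, icc = 0.5, n_harmonics = 8L,
              samples = 128L, bootstrap_reps = 10000L, outdir = "carotidflow-run",
              calibration = NULL)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (!is.numeric(cfg$seed) || cfg$seed < 0) stop("seed must be a non-negative integer")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$calibration) && !file.exists(cfg$calibration))
    stop("calibration file not found: ", cfg$calibration)
  structure(cfg, class = "run_config")
}

load_calibration <- function(cfg) {
  if (is.null(cfg$calibration)) return(default_calibration())
  as.data.frame(data.table::fread(cfg$calibration))
}

write_manifest <- function(cfg, outdir, step) {
  cfg_plain <- unclass(cfg)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_plain, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(step = step,
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version = as.character(utils::packageVersion("carotidflow")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a synthetic study to disk
#'
#' Writes `waveforms.csv` (per-sample) and `truth.csv` (per-record) plus a
#' manifest into `cfg$outdir`.
#' @param cfg a [run_config()].
#' @return invisibly, the list of written paths.
#' @export
cmd_simulate <- function(cfg = run_config()) {
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  study <- generate_study(design = study_design(cfg$n_participants),
                          calibration = load_calibration(cfg),
                          icc = cfg$icc, seed = cfg$seed, samples = cfg$samples)
  paths <- list(waveforms = file.path(outdir, "waveforms.csv"),
                truth = file.path(outdir, "truth.csv"))
  export_waveforms(study, paths$waveforms)
  export_truth(study, paths$truth)
  write_manifest(cfg, outdir, "simulate")
  invisible(paths)
}

#' Compute ESS and Reynolds number for every waveform record
#'
#' Groups the sample table by (participant, modality, intensity), runs the
#' Womersley ESS estimation on each record's cycle, and computes the
#' Reynolds number from the cycle-averaged centerline velocity.
#'
#' @param samples waveform sample table ([read_waveforms()] output or
#'   [waveform_table()]).
#' @param n_harmonics harmonics for the ESS computation (default 8).
#' @return data.table in the long results schema: `participant_id, sex,
#'   modality, intensity, ess_mean_dyn_cm2, ess_peak_dyn_cm2, reynolds,
#'   regime`.
#' @export
compute_ess_table <- function(samples, n_harmonics = 8L) {
  samples <- data.table::as.data.table(samples)
  empty <- data.table::data.table(participant_id = character(), sex = character(),
                                  modality = character(), intensity = character(),
                                  ess_mean_dyn_cm2 = numeric(), ess_peak_dyn_cm2 = numeric(),
                                  reynolds = numeric(), regime = character())
  if (nrow(samples) == 0L) return(empty)
  participant_id <- modality <- intensity <- NULL  # NSE note for R CMD check
  samples[, {
    w <- velocity_waveform(velocity_m_s, period_s[1L], t = time_s)
    geom <- vessel_geometry(diameter_m[1L])
    blood <- blood_properties(hematocrit = hematocrit[1L])
    sr <- ess_waveform(w, geom, blood, n_harmonics)
    re <- reynolds_number(mean(abs(w$v)), geom$diameter, blood$density, blood$viscosity)
    list(sex = sex[1L], ess_mean_dyn_cm2 = sr$mean_ess, ess_peak_dyn_cm2 = sr$peak_ess,
         reynolds = re, regime = classify_flow(re)$regime)
  }, by = c("participant_id", "modality", "intensity")]
}

#' Compute ESS/Re results from a waveform CSV
#'
#' @param cfg a [run_config()]; reads `waveforms.csv` from `cfg$outdir` (or
#'   `input` if given) and writes `results.csv` there.
#' @param input optional explicit waveform CSV path.
#' @return invisibly, the results CSV path.
#' @export
cmd_compute <- function(cfg = run_config(), input = NULL) {
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- if (is.null(input)) file.path(outdir, "waveforms.csv") else input
  res <- compute_ess_table(read_waveforms(path), n_harmonics = cfg$n_harmonics)
  out <- file.path(outdir, "results.csv")
  data.table::fwrite(res, out)
  write_manifest(cfg, outdir, "compute")
  invisible(out)
}

#' Run the full statistical analysis on a long results table
#'
#' Exercise records (intensity other than `"rest"`) feed the mixed model,
#' both pairwise-comparison families and the Reynolds CI summary; baseline
#' records (`"rest"`) feed the reliability CVs. Writes `anova.csv`,
#' `pairwise_within.csv`, `pairwise_between.csv`, `reliability.csv`,
#' `re_summary.csv` and `report.md` into `outdir`.
#'
#' @param results long results data.frame (or path to `results.csv`).
#' @param outdir output directory.
#' @param seed RNG seed for the reliability bootstrap.
#' @param bootstrap_reps bootstrap replicates (default 10000).
#' @return invisibly, a list with all result objects.
#' @export
analyze_results <- function(results, outdir, seed = 1L, bootstrap_reps = 10000L) {
  if (is.character(results)) {
    if (!file.exists(results)) stop("results file not found: ", results)
    results <- data.table::fread(results)
  }
  results <- as.data.frame(results)
  req <- c("participant_id", "sex", "modality", "intensity",
           "ess_mean_dyn_cm2", "reynolds")
  miss <- setdiff(req, names(results))
  if (length(miss)) stop("results table lacks columns: ", paste(miss, collapse = ", "))
  if (length(unique(results$participant_id)) < 2L)
    stop("analysis needs at least 2 participants")
  exercise <- results[results$intensity != "rest", ]
  baseline <- results[results$intensity == "rest", ]

  model <- fit_mixed_model(exercise)
  pw_within <- pairwise_comparisons(exercise, "within_modality")
  pw_between <- pairwise_comparisons(exercise, "between_modality_at_intensity")
  re_sum <- re_ci_summary(exercise)
  reliability <- NULL
  if (nrow(baseline) >= 3L) {
    cv_ess <- cv_with_ci(baseline$ess_mean_dyn_cm2, B = bootstrap_reps, seed = seed)
    cv_re <- cv_with_ci(baseline$reynolds, B = bootstrap_reps, seed = seed + 1L)
    reliability <- data.frame(measure = c("ess", "reynolds"),
                              cv = c(cv_ess$cv, cv_re$cv),
                              ci_lower = c(cv_ess$ci_lower, cv_re$ci_lower),
                              ci_upper = c(cv_ess$ci_upper, cv_re$ci_upper),
                              band = c(cv_ess$band, cv_re$band))
  }
  norm <- normality_check(stats::residuals(model$fit))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(model$anova, file.path(outdir, "anova.csv"))
  data.table::fwrite(pw_within, file.path(outdir, "pairwise_within.csv"))
  data.table::fwrite(pw_between, file.path(outdir, "pairwise_between.csv"))
  if (!is.null(reliability))
    data.table::fwrite(reliability, file.path(outdir, "reliability.csv"))
  data.table::fwrite(re_sum, file.path(outdir, "re_summary.csv"))
  out <- list(model = model, pairwise_within = pw_within,
              pairwise_between = pw_between, reliability = reliability,
              re_summary = re_sum, normality = norm)
  writeLines(render_report(out), file.path(outdir, "report.md"))
  invisible(out)
}

#' @rdname analyze_results
#' @param cfg a [run_config()]; reads `results.csv` from `cfg$outdir`.
#' @export
cmd_analyze <- function(cfg = run_config()) {
  res <- analyze_results(file.path(cfg$outdir, "results.csv"), cfg$outdir,
                         seed = cfg$seed, bootstrap_reps = cfg$bootstrap_reps)
  write_manifest(cfg, cfg$outdir, "analyze")
  invisible(res)
}

render_report <- function(x) {
  fmt_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))
  lines <- c("# Carotid blood-flow analysis report", "",
             "## Mixed-effects model (Type-III F, Satterthwaite ddf)", "")
  a <- x$model$anova
  lines <- c(lines, "| term | F | df1 | df2 | p |", "|---|---|---|---|---|",
             sprintf("| %s | %.2f | %d | %.1f | %s |",
                     a$term, a$F, a$df1, a$df2, fmt_p(a$p)),
             "",
             sprintf("Random intercept variance %.2f, residual variance %.2f (LRT p %s).",
                     x$model$varcor[1L], x$model$varcor[2L], fmt_p(x$model$ranef_test$p)),
             sprintf("Shapiro-Wilk on residuals: W = %.3f, p %s.",
                     x$normality$W, fmt_p(x$normality$p)), "")
  if (!is.null(x$reliability)) {
    r <- x$reliability
    lines <- c(lines, "## Baseline reliability", "",
               sprintf("- %s: CV = %.1f%% (95%% CI %.1f-%.1f), %s",
                       r$measure, r$cv, r$ci_lower, r$ci_upper, r$band), "")
  }
  re <- x$re_summary
  n_turb <- sum(re$turbulent)
  lines <- c(lines, "## Flow regime", "",
             sprintf("%d of %d exercise conditions have their entire 95%% CI above Re = 2000.",
                     n_turb, nrow(re)),
             sprintf("Minimum condition-mean Re: %.0f (%s, %s).",
                     min(re$mean_re), re$modality[which.min(re$mean_re)],
                     re$intensity[which.min(re$mean_re)]), "")
  sig <- x$pairwise_within[x$pairwise_within$p_holm < 0.05, ]
  lines <- c(lines, "## Pairwise (within modality, Holm-adjusted)", "",
             sprintf("%d of %d intensity contrasts significant at p.adj < 0.05.",
                     nrow(sig), nrow(x$pairwise_within)))
  lines
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `compute-ess`, `analyze`, `report`. Common
#' flags: `--config <yaml>`, `--seed <int>`, `--outdir <dir>`, `--verbose`.
#' A typical full run:
#' ```
#' carotidflow simulate --seed 7 --outdir run
#' carotidflow compute-ess --outdir run
#' carotidflow analyze --seed 7 --outdir run
#' ```
#' @param args character vector of CLI arguments (defaults to the process
#'   command line).
#' @return exit status 0 invisibly; stops with a message on usage errors.
#' @export
cf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: carotidflow <simulate|compute-ess|analyze|report> [--config F] [--seed N] [--outdir D] [--verbose]"
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option("--verbose", action = "store_true", default = FALSE)))
  opt <- optparse::parse_args(parser, args = args[-1L])
  overrides <- Filter(Negate(is.null), list(seed = opt$seed, outdir = opt$outdir))
  cfg <- do.call(run_config, c(list(path = opt$config), overrides))
  say <- function(...) if (opt$verbose) message(...)
  switch(cmd,
    "simulate" = {
      say("simulating study (seed ", cfg$seed, ") into ", cfg$outdir)
      cmd_simulate(cfg)
    },
    "compute-ess" = {
      say("computing ESS/Re from ", file.path(cfg$outdir, "waveforms.csv"))
      cmd_compute(cfg)
    },
    "analyze" = ,
    "report" = {
      say("analyzing ", file.path(cfg$outdir, "results.csv"))
      cmd_analyze(cfg)
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  invisible(0L)
}
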