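#' Paired Hedges' g
#'
#' Standardised mean difference for paired samples: Cohen's d on the
#' difference scores, `d = mean(x - y) / sd(x - y)` (sample SD, n - 1),
#' multiplied by the small-sample bias correction
#' `J = 1 - 3 / (4 * (n - 1) - 1)` with paired df `n - 1`.
#'
#' @param x,y paired numeric vectors of equal length, `n >= 3`.
#' @return Hedges' g (signed).
#' @examples
#' hedges_g_paired(c(1, 2, 3), c(2, 3, 5))  # -1.3197
#' @export
hedges_g_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 3L) stop("paired effect size needs n >= 3")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("effect size undefined: difference scores have zero variance")
  (mean(d) / s) * (1 - 3 / (4 * (n - 1) - 1))
}

#' Interpret an effect-size magnitude
#'
#' Magnitude bands for |g|: below 0.2 "very small", 0.2 to below 0.5
#' "small", 0.5 to below 0.8 "moderate", 0.8 and above "large".
#'
#' @param g Hedges' g value(s).
#' @return character vector of magnitude labels.
#' @examples
#' interpret_effect(c(0, -2.16, 0.5))
#' @export
interpret_effect <- function(g) {
  a <- abs(g)
  ifelse(a < 0.2, "very small",
  ifelse(a < 0.5, "small",
  ifelse(a < 0.8, "moderate", "large")))
}

#' Pairwise paired comparisons with Holm correction
#'
#' Paired t-tests between condition levels, with the Holm-Bonferroni
#' adjustment applied within each family and Hedges' g attached. Two family
#' layouts are supported: `within_modality` compares intensities inside each
#' modality (one Holm family per modality), `between_modality_at_intensity`
#' compares modalities at each intensity (one family per intensity).
#'
#' @param data long data.frame with `participant_id`, `modality`,
#'   `intensity` and the response column; one row per participant and cell.
#' @param family `"within_modality"` or `"between_modality_at_intensity"`.
#' @param response response column name (default `ess_mean_dyn_cm2`).
#' @return data.frame with columns `family, level1, level2, t, df, p_raw,
#'   p_holm, hedges_g, magnitude`.
#' @export
pairwise_comparisons <- function(data,
                                 family = c("within_modality", "between_modality_at_intensity"),
                                 response = "ess_mean_dyn_cm2") {
  family <- match.arg(family)
  data <- as.data.frame(data)
  req <- c("participant_id", "modality", "intensity", response)
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  cell_values <- function(d, col, lev) {
    sub <- d[d[[col]] == lev, ]
    if (anyDuplicated(sub$participant_id))
      stop("duplicate rows per participant in cell '", lev, "'")
    stats::setNames(sub[[response]], sub$participant_id)
  }
  compare <- function(d, col, l1, l2, fam) {
    v1 <- cell_values(d, col, l1)
    v2 <- cell_values(d, col, l2)
    ids <- intersect(names(v1), names(v2))
    if (length(ids) != length(v1) || length(ids) != length(v2))
      stop("unpaired participants in comparison ", l1, " vs ", l2, " (family ", fam, ")")
    dvec <- v1[ids] - v2[ids]
    if (stats::sd(dvec) == 0 && all(dvec == 0)) {
      # identical paired vectors: no evidence of any difference
      return(data.frame(family = fam, level1 = l1, level2 = l2,
                        t = 0, df = length(ids) - 1L, p_raw = 1, hedges_g = 0))
    }
    tt <- stats::t.test(v1[ids], v2[ids], paired = TRUE)
    data.frame(family = fam, level1 = l1, level2 = l2,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               hedges_g = hedges_g_paired(v1[ids], v2[ids]))
  }

  out <- list()
  if (family == "within_modality") {
    for (m in unique(data$modality)) {
      d <- data[data$modality == m, ]
      levs <- unique(d$intensity)
      rows <- list()
      for (i in seq_along(levs)) for (j in seq_along(levs)) {
        if (j <= i) next
        rows[[length(rows) + 1L]] <- compare(d, "intensity", levs[i], levs[j], m)
      }
      fam_tab <- do.call(rbind, rows)
      fam_tab$p_holm <- stats::p.adjust(fam_tab$p_raw, method = "holm")
      out[[length(out) + 1L]] <- fam_tab
    }
  } else {
    for (ity in unique(data$intensity)) {
      d <- data[data$intensity == ity, ]
      levs <- unique(d$modality)
      rows <- list()
      for (i in seq_along(levs)) for (j in seq_along(levs)) {
        if (j <= i) next
        rows[[length(rows) + 1L]] <- compare(d, "modality", levs[i], levs[j], ity)
      }
      fam_tab <- do.call(rbind, rows)
      fam_tab$p_holm <- stats::p.adjust(fam_tab$p_raw, method = "holm")
      out[[length(out) + 1L]] <- fam_tab
    }
  }
  res <- do.call(rbind, out)
  res$magnitude <- interpret_effect(res$hedges_g)
  rownames(res) <- NULL
  res[, c("family", "level1", "level2", "t", "df", "p_raw", "p_holm",
          "hedges_g", "magnitude")]
}

#' Pooled two-sample t-test from group summaries
#'
#' Classical pooled-variance independent-samples t from printed means, SDs
#' and group sizes, with `df = n1 + n2 - 2` and a two-sided p-value.
#'
#' @param m1,sd1,n1 mean, SD, size of group 1.
#' @param m2,sd2,n2 mean, SD, size of group 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' t_from_summary(76.86, 16.18, 7, 34.70, 7.26, 7)$t  # ~6.29
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    stop("degenerate variance: SDs must be non-negative and not both zero")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Coefficient of variation with bootstrap confidence interval
#'
#' `CV = 100 * sd / mean` (percent), with a seeded percentile bootstrap 95%
#' CI and a reliability interpretation band: below 10% "very good", 10-20%
#' "good", 20-30% "acceptable", above 30% "poor".
#'
#' @param values positive-mean numeric vector, `n >= 3` (a degenerate
#'   constant vector is allowed and gives CV = 0 with a point CI).
#' @param B bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param conf confidence level (default 0.95).
#' @return list with `cv`, `ci_lower`, `ci_upper`, `band`, `n`, `B`.
#' @examples
#' cv_with_ci(c(10, 12), B = 200)$cv  # 12.86
#' @export
cv_with_ci <- function(values, B = 10000L, seed = 1L, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("CV needs at least 2 values")
  if (mean(values) <= 0) stop("CV undefined for non-positive mean")
  cv <- 100 * stats::sd(values) / mean(values)
  boot <- with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      s <- sample(values, n, replace = TRUE)
      m <- mean(s)
      if (m <= 0) return(NA_real_)
      100 * stats::sd(s) / m
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  a <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), names = FALSE, type = 7)
  band <- if (cv < 10) "very good" else if (cv <= 20) "good"
          else if (cv <= 30) "acceptable" else "poor"
  list(cv = cv, ci_lower = min(ci[1L], cv), ci_upper = max(ci[2L], cv),
       band = band, n = n, B = B)
}

#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper returning the W statistic and p-value.
#' @param residuals numeric vector, 3 to 5000 values, not all identical.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3L) stop("normality check needs at least 3 values")
  if (stats::sd(residuals) == 0) stop("normality check undefined for constant input")
  sw <- stats::shapiro.test(residuals)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Per-condition Reynolds-number confidence summary
#'
#' t-based 95% confidence interval of each condition's mean Reynolds number,
#' with a turbulence flag set when the entire interval lies above the
#' turbulent threshold (CI lower bound > 2000).
#'
#' @param data long data.frame with `modality`, `intensity` and a `reynolds`
#'   column; at least 2 observations per condition.
#' @param conf confidence level (default 0.95).
#' @return data.frame `modality, intensity, n, mean_re, ci_lower, ci_upper,
#'   turbulent`.
#' @export
re_ci_summary <- function(data, conf = 0.95) {
  data <- as.data.frame(data)
  req <- c("modality", "intensity", "reynolds")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cells <- unique(data[, c("modality", "intensity")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- data$modality == cells$modality[i] & data$intensity == cells$intensity[i]
    re <- data$reynolds[sel]
    if (length(re) < 2L)
      stop("condition ", cells$modality[i], "/", cells$intensity[i],
           " has a single observation; cannot form a confidence interval")
    m <- mean(re)
    half <- stats::qt(1 - (1 - conf) / 2, length(re) - 1L) * stats::sd(re) / sqrt(length(re))
    data.frame(modality = cells$modality[i], intensity = cells$intensity[i],
               n = length(re), mean_re = m,
               ci_lower = m - half, ci_upper = m + half,
               turbulent = (m - half) > 2000)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
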