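# Linear mixed model with a participant random intercept.
#
# Variance components are estimated by REML via lme4; Type-III F tests with
# Satterthwaite denominator df are computed in-package. With a single
# random-intercept grouping factor, V = ve*I + vb*Z Z' admits closed-form
# (Woodbury) inverses per participant block, so the REML criterion, the
# fixed-effect covariance Sigma_beta(phi) and all finite-difference
# derivatives needed by the Satterthwaite recipe are cheap and exact.

# Multiply V(phi)^{-1} by a matrix, blockwise over the grouping factor.
vinv_mult <- function(M, group, phi) {
  vb <- phi[1L]; ve <- phi[2L]
  M <- as.matrix(M)
  S <- rowsum(M, group)                       # per-group column sums
  m_g <- tabulate(group)                      # group sizes (group is a factor)
  f <- vb / (ve * (ve + m_g * vb))            # Woodbury factor per group
  M / ve - (f * S)[as.integer(group), , drop = FALSE]
}

# REML -2 log-likelihood (up to an additive constant) at phi = (vb, ve).
reml_crit <- function(phi, X, y, group) {
  vb <- phi[1L]; ve <- phi[2L]
  if (ve <= 0 || vb < 0) return(Inf)
  m_g <- tabulate(group)
  logdetV <- sum((m_g - 1) * log(ve) + log(ve + m_g * vb))
  W <- vinv_mult(cbind(X, y), group, phi)
  p <- ncol(X)
  XtViX <- crossprod(X, W[, seq_len(p), drop = FALSE])
  XtViy <- crossprod(X, W[, p + 1L])
  yViy <- sum(y * W[, p + 1L])
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  logdetV + 2 * sum(log(diag(ch))) + (yViy - sum(XtViy * beta))
}

sigma_beta <- function(phi, X, group) {
  solve(crossprod(X, vinv_mult(X, group, phi)))
}

# Central-difference gradient/Hessian helpers (2-parameter functions).
fd_grad <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

fd_hessian <- function(f, x, h) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(k)) {
      if (j <= i) next
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the repeated-measures mixed-effects model
#'
#' Restricted-maximum-likelihood fit of
#' `response ~ fixed effects + (1 | participant)` with Type-III F tests
#' (sum-to-zero factor coding) and Satterthwaite denominator degrees of
#' freedom, following the conventional recipe: the covariance of the REML
#' variance-component estimates comes from the finite-difference Hessian of
#' the REML criterion, and each multi-df F denominator df pools the
#' per-eigencontrast Satterthwaite dfs. A likelihood-ratio test of the
#' random intercept (0.5 chi^2_0 + 0.5 chi^2_1 boundary mixture) is also
#' reported.
#'
#' @param data data.frame with the response, factor columns named in `fixed`,
#'   and a participant identifier column.
#' @param fixed one-sided formula of fixed effects, default
#'   `~ modality + intensity + sex + modality:intensity`.
#' @param response name of the response column (default `ess_mean_dyn_cm2`).
#' @param participant name of the grouping column (default `participant_id`).
#' @param ddf `"satterthwaite"` (default) or `"residual"` (containment-style
#'   fallback, df = n - rank(X)).
#' @return Object of class `mixed_model_result`: `anova` (term, F, df1, df2,
#'   p), `varcor` (random-intercept and residual variances), `ranef_test`
#'   (LRT statistic and p), `beta`, and the underlying `lme4` fit.
#' @export
fit_mixed_model <- function(data,
                            fixed = ~ modality + intensity + sex + modality:intensity,
                            response = "ess_mean_dyn_cm2",
                            participant = "participant_id",
                            ddf = c("satterthwaite", "residual")) {
  ddf <- match.arg(ddf)
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column '", response, "' not found")
  if (!participant %in% names(data)) stop("participant column '", participant, "' not found")
  if (anyNA(data[[response]])) stop("missing values in the response are not allowed")
  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("fixed-effect columns not found: ", paste(miss, collapse = ", "))
  group <- factor(data[[participant]])
  if (nlevels(group) < 2L) stop("need at least 2 participants")
  if (any(table(group) < 2L)) stop("every participant must appear in at least 2 conditions")
  for (v in vars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2L)
      stop("fixed-effect factor '", v, "' has fewer than 2 levels")
  }
  y <- as.numeric(data[[response]])

  contr <- stats::setNames(rep(list("contr.sum"), length(vars)), vars)
  X <- stats::model.matrix(fixed, data, contrasts.arg = contr)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effects design: model did not converge to a full-rank fit")

  lfor <- stats::as.formula(paste(response, "~",
                                  paste(attr(stats::terms(fixed), "term.labels"), collapse = " + "),
                                  "+ (1 |", participant, ")"))
  data[[participant]] <- group
  fit <- tryCatch(
    lme4::lmer(lfor, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) stop("mixed model did not converge: ", conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == participant][1L]
  ve <- stats::sigma(fit)^2
  phi <- c(vb, ve)

  n <- length(y); p <- ncol(X)
  Sb <- sigma_beta(phi, X, group)
  W <- vinv_mult(cbind(X, y), group, phi)
  beta <- drop(Sb %*% crossprod(X, W[, p + 1L]))
  names(beta) <- colnames(X)

  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fixed), "term.labels")

  vcov_phi <- NULL
  if (ddf == "satterthwaite") {
    h <- pmax(1e-4 * abs(phi), 1e-10)
    H <- fd_hessian(function(ph) reml_crit(ph, X, y, group), phi, h)
    vcov_phi <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov_phi) && any(!is.finite(vcov_phi))) vcov_phi <- NULL
  }

  anova_rows <- lapply(seq_along(labels), function(ti) {
    idx <- which(asgn == ti)
    q <- length(idx)
    Lb <- beta[idx]
    VL <- Sb[idx, idx, drop = FALSE]
    eg <- eigen(VL, symmetric = TRUE)
    Fval <- sum((crossprod(eg$vectors, Lb))^2 / eg$values) / q
    df2 <- n - p
    if (!is.null(vcov_phi)) {
      nu <- vapply(seq_len(q), function(i) {
        li <- numeric(p)
        li[idx] <- eg$vectors[, i]
        gfun <- function(ph) drop(t(li) %*% sigma_beta(ph, X, group) %*% li)
        gr <- fd_grad(gfun, phi, pmax(1e-4 * abs(phi), 1e-10))
        den <- drop(t(gr) %*% vcov_phi %*% gr)
        if (den <= 0) return(Inf)
        2 * eg$values[i]^2 / den
      }, numeric(1))
      E <- sum(ifelse(nu > 2, nu / (nu - 2), Inf))
      df2 <- if (is.finite(E) && E > q) 2 * E / (E - q) else n - p
    }
    data.frame(term = labels[ti], F = Fval, df1 = q, df2 = df2,
               p = stats::pf(Fval, q, df2, lower.tail = FALSE))
  })
  anova_tab <- do.call(rbind, anova_rows)
  rownames(anova_tab) <- NULL

  # REML LRT for the random intercept against the fixed-effects-only model
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  r0 <- reml_crit(c(0, rss / (n - p)), X, y, group)
  r1 <- reml_crit(phi, X, y, group)
  lrt <- max(0, r0 - r1)
  ranef_p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(anova = anova_tab,
                 varcor = c(intercept_var = vb, residual_var = ve),
                 ranef_test = list(lrt = lrt, p = ranef_p),
                 beta = beta, ddf = ddf, n = n, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> Type-III F tests (", x$ddf, " ddf), n = ", x$n, "\n", sep = "")
  tab <- x$anova
  tab$F <- round(tab$F, 2); tab$df2 <- round(tab$df2, 1)
  tab$p <- format.pval(tab$p, digits = 3, eps = 1e-16)
  print(tab, row.names = FALSE)
  cat(sprintf("random intercept var %.3f, residual var %.3f; LRT p %s\n",
              x$varcor[1L], x$varcor[2L],
              format.pval(x$ranef_test$p, digits = 3, eps = 1e-16)))
  invisible(x)
}
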