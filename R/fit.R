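# Adjusted analysis: linear mixed model with a participant random
# intercept, the package's central estimator.

#' Fit the adjusted mobility model
#'
#' Fits the linear mixed model used for the adjusted analysis of one
#' outcome at one site: fixed effects for intervention level (categorical,
#' level 0 reference), gender, age, study year (2019 reference), weekend,
#' temperature, humidity, one harmonic sine/cosine pair, and
#' weekend-by-level interactions; plus a random intercept per participant
#' capturing within-person correlation of daily outcomes. Estimation is by
#' REML (\code{lme4}); inference is by Wald statistics with normal
#' critical values, matching the symmetric 95\% confidence intervals the
#' adjusted analysis reports.
#'
#' Rows with any missing covariate are dropped list-wise and counted.
#' With \code{random_intercept = FALSE} the same fixed-effect design is
#' fit by ordinary least squares -- the zero between-participant variance
#' limit of the model.
#'
#' @param data Analysis table from \code{\link{annotate_days}}.
#' @param outcome \code{"fraction_home"} or \code{"total_steps"}.
#' @param site Optional site label to subset to (the adjusted analysis is
#'   run per country).
#' @param random_intercept Include the per-participant random intercept.
#' @param reml Use REML (default) rather than ML.
#' @return An object of class \code{mobility_fit}; see
#'   \code{\link{summary.mobility_fit}}, \code{\link{level_contrasts}}.
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' cfg$sites$Greece <- NULL
#' cfg$sites$Cyprus$n_participants <- 12
#' co <- simulate_cohort(cfg, intervals = FALSE)
#' tab <- annotate_days(truth_to_daily(co$truth), co$participants,
#'                      co$weather)
#' fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
#' coef(fit)["level1"]
#' @export
fit_mobility_model <- function(data,
                               outcome = c("fraction_home", "total_steps"),
                               site = NULL, random_intercept = TRUE,
                               reml = TRUE) {
  outcome <- match.arg(outcome)
  if (!is.null(site)) data <- data[data$site %in% site, , drop = FALSE]
  covars <- c("level", "gender", "age_years", "year", "weekend", "temp_c",
              "rh_pct", "sin_t", "cos_t", "participant_id")
  missing_cols <- setdiff(c(outcome, covars), names(data))
  if (length(missing_cols)) {
    stop("analysis table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$level <- factor(data$level, levels = 0:3)
  data$level <- droplevels(data$level)
  if (!is.factor(data$year)) data$year <- factor(data$year)
  complete <- stats::complete.cases(data[, c(outcome, covars)])
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (nrow(data) < 2 || length(unique(data$participant_id)) < 2) {
    stop("need >= 2 observations on >= 2 participants", call. = FALSE)
  }

  # factors that do not vary in the (possibly subset) data cannot enter
  terms <- c("level", "gender", "age_years", "year", "weekend", "temp_c",
             "rh_pct", "sin_t", "cos_t")
  varies <- vapply(terms, function(t) length(unique(data[[t]])) > 1,
                   logical(1))
  if (!varies[["level"]]) {
    stop("intervention level does not vary in the data", call. = FALSE)
  }
  terms <- terms[varies]
  if (all(c("level", "weekend") %in% terms)) {
    terms <- c(terms, "weekend:level")
  }
  fe <- paste(outcome, "~", paste(terms, collapse = " + "))
  if (random_intercept) {
    form <- stats::as.formula(paste(fe, "+ (1 | participant_id)"))
    fit <- lme4::lmer(form, data = data, REML = reml)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_participant <- vc$vcov[vc$grp == "participant_id"]
    var_residual <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    method <- if (reml) "REML" else "ML"
  } else {
    form <- stats::as.formula(fe)
    fit <- stats::lm(form, data = data)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    var_participant <- 0
    var_residual <- summary(fit)$sigma^2
    singular <- FALSE
    conv <- TRUE
    method <- "OLS"
  }
  # drop aliased terms (rank deficiency) with their names surfaced
  aliased <- is.na(beta)
  if (any(aliased)) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(beta)[aliased], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(V))
  z <- beta / se
  ct <- data.frame(
    term = names(beta),
    estimate = as.numeric(beta),
    se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  rownames(ct) <- NULL
  structure(list(
    call = match.call(),
    outcome = outcome,
    site = site,
    formula = form,
    coefficients = ct,
    vcov = V,
    varcor = c(participant = var_participant, residual = var_residual),
    n_obs = nrow(data),
    n_participants = length(unique(data$participant_id)),
    n_dropped = n_dropped,
    converged = conv,
    singular = singular,
    method = method,
    fit = fit
  ), class = "mobility_fit")
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat("Mobility mixed model (", x$method, "), outcome: ", x$outcome,
      if (!is.null(x$site)) paste0(", site: ", paste(x$site, collapse = "+")),
      "\n", sep = "")
  cat(sprintf("  %d observations, %d participants (%d rows dropped for missing covariates)\n",
              x$n_obs, x$n_participants, x$n_dropped))
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  if (x$singular) cat("  note: random-effects variance at boundary (singular fit)\n")
  ct <- x$coefficients
  ct[, -1] <- lapply(ct[, -1], function(v) signif(v, 4))
  print(ct, row.names = FALSE)
  cat(sprintf("  Random intercept var: %.4g  Residual var: %.4g\n",
              x$varcor["participant"], x$varcor["residual"]))
  invisible(x)
}

#' Summary of a mobility model fit
#'
#' @param object A \code{mobility_fit}.
#' @param ... Unused.
#' @return The object, invisibly, after printing the coefficient table,
#'   variance components and fit diagnostics.
#' @export
summary.mobility_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.mobility_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.mobility_fit <- function(object, ...) object$vcov

#' @export
confint.mobility_fit <- function(object, parm, level = 0.95, ...) {
  ct <- object$coefficients
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(ct$estimate - q * ct$se, ct$estimate + q * ct$se)
  dimnames(out) <- list(ct$term,
                        paste0(format(100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2)), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.mobility_fit <- function(object, newdata = NULL, ...) {
  if (object$method == "OLS") {
    stats::predict(object$fit, newdata = newdata, ...)
  } else if (is.null(newdata)) {
    stats::predict(object$fit, ...)
  } else {
    stats::predict(object$fit, newdata = newdata, ...)
  }
}

#' @export
residuals.mobility_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.mobility_fit <- function(object, ...) stats::fitted(object$fit)

#' Wald contrasts between intervention levels
#'
#' Computes, from a fitted \code{mobility_fit}, the adjusted change of the
#' outcome for each level versus baseline and versus the previous level,
#' with Wald standard errors from the fitted covariance and Bonferroni
#' adjustment over the contrast family (p-values capped at 1).
#'
#' Contrast estimates are linear in the level coefficients: level k vs
#' baseline is the level-k coefficient itself; level k vs k-1 is the
#' difference of the two coefficients.
#'
#' @param fit A \code{mobility_fit} with categorical level terms.
#' @param pairs Optional list of length-2 integer vectors \code{c(k, j)}
#'   requesting the contrast of level k versus level j (0 = baseline).
#'   Default: each present level versus baseline and versus the previous
#'   level.
#' @param adjust \code{"bonferroni"} (default) or \code{"none"}.
#' @return Data frame with \code{comparison}, \code{estimate}, \code{se},
#'   \code{p}, \code{p_adj}, \code{adjustment}.
#' @export
level_contrasts <- function(fit, pairs = NULL,
                            adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "mobility_fit"))
  beta <- coef(fit)
  V <- fit$vcov
  terms <- names(beta)
  lev_terms <- paste0("level", 0:3)   # level0 never a column (reference)
  present <- c(TRUE, paste0("level", 1:3) %in% terms)
  if (!any(present[-1])) stop("no level terms in the fit", call. = FALSE)
  weight_for <- function(k) as.numeric(terms == paste0("level", k))
  contrast_row <- function(label, w) {
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(est / se))
    data.frame(comparison = label, estimate = est, se = se, p = p,
               stringsAsFactors = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- c(lapply(1:3, function(k) c(k, 0L)),
               lapply(2:3, function(k) c(k, k - 1L)))
  }
  rows <- list()
  for (pr in pairs) {
    k <- pr[1]; j <- pr[2]
    if (!present[k + 1] || !present[j + 1]) {
      warning("level ", k, " or ", j,
              " absent from the data; contrast skipped", call. = FALSE)
      next
    }
    lab <- sprintf("level %d vs %s", k,
                   if (j == 0) "baseline" else paste("level", j))
    rows[[lab]] <- contrast_row(lab, weight_for(k) - weight_for(j))
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, out$p * m) else out$p
  out$adjustment <- adjust
  rownames(out) <- NULL
  out
}
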