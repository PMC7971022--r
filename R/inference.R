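# Unadjusted statistics: cohort descriptives and observed per-level
# summaries with ANOVA and Bonferroni pairwise comparisons.

#' Cohort demographics and asthma severity groups
#'
#' Summarises the roster per site: age mean (sd), gender counts, and
#' asthma severity groups defined by the number of eligibility criteria
#' beyond the physician diagnosis (daily preventive medication, wheezing
#' episodes, unscheduled visits, emergency-room visits): severity 1 = one
#' further criterion, severity 2 = two, severity 3 = three or more.
#' Participants with no criterion beyond the diagnosis do not meet the
#' eligibility definition and are rejected with a warning.
#'
#' @param participants Roster with \code{site}, \code{age_years},
#'   \code{gender} and logical columns \code{wheezing},
#'   \code{preventive_medication}, \code{unscheduled_visits},
#'   \code{er_visits}.
#' @return List with \code{summary} (one row per site) and
#'   \code{participants} (the eligible roster with a \code{severity}
#'   column).
#' @export
describe_cohort <- function(participants) {
  crit_cols <- c("wheezing", "preventive_medication", "unscheduled_visits",
                 "er_visits")
  if (!all(crit_cols %in% names(participants))) {
    stop("roster lacks eligibility columns: ",
         paste(setdiff(crit_cols, names(participants)), collapse = ", "),
         call. = FALSE)
  }
  n_crit <- rowSums(participants[, crit_cols] == TRUE)
  ineligible <- n_crit == 0
  if (any(ineligible)) {
    warning(sprintf("rejecting %d participant(s) with no eligibility criterion beyond diagnosis",
                    sum(ineligible)), call. = FALSE)
    participants <- participants[!ineligible, , drop = FALSE]
    n_crit <- n_crit[!ineligible]
  }
  participants$severity <- pmin(n_crit, 3)
  sites <- unique(participants$site)
  rows <- lapply(sites, function(s) {
    p <- participants[participants$site == s, , drop = FALSE]
    data.frame(
      site = s,
      n = nrow(p),
      age_mean = mean(p$age_years),
      age_sd = stats::sd(p$age_years),
      n_male = sum(p$gender == "M"),
      pct_male = 100 * mean(p$gender == "M"),
      n_severity1 = sum(p$severity == 1),
      n_severity2 = sum(p$severity == 2),
      n_severity3 = sum(p$severity == 3),
      stringsAsFactors = FALSE
    )
  })
  list(summary = do.call(rbind, rows), participants = participants)
}

#' Observed per-level means with ANOVA and pairwise comparisons
#'
#' The unadjusted analysis: for one outcome at one site (optionally within
#' one asthma-severity stratum), the mean of participant-day values per
#' intervention level with a normal-theory 95\% confidence interval, a
#' one-way ANOVA across levels, and pairwise level comparisons (pooled-SD
#' t tests) with Bonferroni adjustment capped at 1. Daily observations are
#' pooled across participants, ignoring clustering -- this is the
#' unadjusted companion to \code{\link{fit_mobility_model}}.
#'
#' @param data Analysis table with \code{level} plus the outcome column.
#' @param outcome \code{"fraction_home"} or \code{"total_steps"}.
#' @param site Optional site label to subset to.
#' @param severity Optional severity stratum (requires a \code{severity}
#'   column, e.g. merged from \code{\link{describe_cohort}}).
#' @return Data frame with one row per level: \code{n}, \code{mean},
#'   \code{ci95_low}, \code{ci95_high}, \code{p_vs_baseline},
#'   \code{p_vs_previous} (both Bonferroni-adjusted over all pairwise
#'   level comparisons). ANOVA F and p are attached as attributes
#'   \code{"anova_F"}, \code{"anova_p"}.
#' @export
level_means <- function(data, outcome = c("fraction_home", "total_steps"),
                        site = NULL, severity = NULL) {
  outcome <- match.arg(outcome)
  if (!is.null(site)) data <- data[data$site %in% site, , drop = FALSE]
  if (!is.null(severity)) {
    if (!"severity" %in% names(data)) {
      stop("no severity column in data", call. = FALSE)
    }
    data <- data[data$severity %in% severity, , drop = FALSE]
  }
  if (nrow(data) == 0) {
    warning("empty stratum; no rows to summarise", call. = FALSE)
    return(NULL)
  }
  y <- data[[outcome]]
  g <- factor(as.integer(as.character(factor(data$level))), levels = 0:3)
  g <- droplevels(g)
  levs <- as.integer(levels(g))
  if (length(levs) < 2) stop("need >= 2 levels with data", call. = FALSE)

  stats_per <- t(vapply(levels(g), function(l) {
    v <- y[g == l]
    m <- mean(v)
    se <- stats::sd(v) / sqrt(length(v))
    c(n = length(v), mean = m,
      ci95_low = m - stats::qnorm(0.975) * se,
      ci95_high = m + stats::qnorm(0.975) * se)
  }, numeric(4)))

  av <- stats::aov(y ~ g)
  s <- summary(av)[[1]]
  # pairwise pooled-SD t tests, Bonferroni over all level pairs
  pw <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                               pool.sd = TRUE)
  m_comp <- choose(length(levs), 2)
  get_p <- function(a, b) {
    # pairwise.t.test matrix is lower-triangular, rows > cols
    la <- as.character(a); lb <- as.character(b)
    M <- pw$p.value
    p <- NA_real_
    if (la %in% rownames(M) && lb %in% colnames(M)) p <- M[la, lb]
    if (is.na(p) && lb %in% rownames(M) && la %in% colnames(M)) p <- M[lb, la]
    # degenerate case: zero pooled variance with equal means => no effect
    if (is.na(p) || is.nan(p)) {
      p <- if (isTRUE(all.equal(mean(y[g == la]), mean(y[g == lb])))) 1 else NA_real_
    }
    min(1, p * m_comp)
  }
  out <- data.frame(
    site = if (is.null(site)) NA_character_ else paste(site, collapse = "+"),
    outcome = outcome,
    level = levs,
    n = as.integer(stats_per[, "n"]),
    mean = stats_per[, "mean"],
    ci95_low = stats_per[, "ci95_low"],
    ci95_high = stats_per[, "ci95_high"],
    stringsAsFactors = FALSE
  )
  base <- min(levs)
  out$p_vs_baseline <- NA_real_
  out$p_vs_previous <- NA_real_
  for (i in seq_along(levs)) {
    if (levs[i] == base) next
    out$p_vs_baseline[i] <- get_p(levs[i], base)
    prev <- max(levs[levs < levs[i]])
    out$p_vs_previous[i] <- get_p(levs[i], prev)
  }
  if (!is.null(severity)) out$severity <- paste(severity, collapse = "+")
  rownames(out) <- NULL
  attr(out, "anova_F") <- s[["F value"]][1]
  attr(out, "anova_p") <- s[["Pr(>F)"]][1]
  out
}
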