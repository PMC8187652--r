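.score_vector <- function(scores) {
  if (inherits(scores, "sig_scores")) {
    stats::setNames(scores$score, scores$sample_id)
  } else if (is.numeric(scores)) {
    scores
  } else {
    stop("expected a 'sig_scores' object or a numeric vector", call. = FALSE)
  }
}

#' Two-group comparison of signature scores
#'
#' Welch two-sample t-test (two-sided) of scores between the two levels of
#' a factor, reporting group means alongside the test.
#'
#' @param scores A `sig_scores` object or named numeric vector.
#' @param labels Two-level factor/character vector, aligned with scores.
#' @return A list with `groups`, `n`, `means`, `t`, `p_value`.
#' @export
compare_groups <- function(scores, labels) {
  s <- .score_vector(scores)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(s))
  keep <- !is.na(labels) & !is.na(s)
  s <- s[keep]; labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    stop("compare_groups: exactly two groups required", call. = FALSE)
  }
  n <- table(factor(labels, levels = lev))
  if (any(n < 2)) {
    stop(sprintf("compare_groups: group '%s' has fewer than 2 samples",
                 names(n)[which(n < 2)[1]]), call. = FALSE)
  }
  tt <- stats::t.test(s[labels == lev[1]], s[labels == lev[2]])
  list(groups = lev, n = as.integer(n),
       means = c(mean(s[labels == lev[1]]), mean(s[labels == lev[2]])),
       t = unname(tt$statistic), p_value = tt$p.value)
}

#' Multi-group comparison of signature scores
#'
#' One-way ANOVA across all levels plus a Welch t-test of the level of
#' interest (default "CMS1" when present, else the first level) against all
#' other levels pooled. Empty levels are dropped with a warning.
#'
#' @param scores A `sig_scores` object or numeric vector.
#' @param labels Factor with k >= 2 levels.
#' @param focus Level of interest for the focus-vs-rest test.
#' @return A list with `levels` (per-level n and mean), `anova_p`, `focus`,
#'   `focus_t`, `focus_p`.
#' @export
compare_multi <- function(scores, labels, focus = NULL) {
  s <- .score_vector(scores)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(s))
  keep <- !is.na(labels) & !is.na(s)
  if (any(!keep)) warning("compare_multi: dropping samples with missing label or score")
  s <- s[keep]; labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("compare_multi: need >= 2 non-empty levels", call. = FALSE)
  f <- factor(labels, levels = lev)
  fit <- stats::aov(s ~ f)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (is.null(focus)) focus <- if ("CMS1" %in% lev) "CMS1" else lev[1]
  if (!focus %in% lev) stop(sprintf("compare_multi: focus level '%s' absent", focus),
                            call. = FALSE)
  tt <- stats::t.test(s[labels == focus], s[labels != focus])
  list(
    levels = data.frame(level = lev,
                        n = as.integer(table(f)),
                        mean = as.numeric(tapply(s, f, mean)),
                        stringsAsFactors = FALSE),
    anova_p = anova_p, focus = focus,
    focus_t = unname(tt$statistic), focus_p = tt$p.value
  )
}

#' Pearson correlation between two signature score vectors
#'
#' Computed on the intersection of sample ids; the two-sided p-value comes
#' from the t distribution.
#'
#' @param a,b `sig_scores` objects (or named numeric vectors).
#' @return A list with `r`, `p_value`, `n`.
#' @export
correlate_signatures <- function(a, b) {
  sa <- .score_vector(a); sb <- .score_vector(b)
  if (is.null(names(sa)) || is.null(names(sb))) {
    stop("correlate_signatures: score vectors must carry sample ids", call. = FALSE)
  }
  shared <- intersect(names(sa), names(sb))
  if (length(shared) < 3) {
    stop("correlate_signatures: fewer than 3 shared samples", call. = FALSE)
  }
  ct <- stats::cor.test(sa[shared], sb[shared], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Median-split survival analysis of a signature score
#'
#' Samples strictly above the median score form the "high" group (ties at
#' the median go to "low"). Reports Kaplan-Meier curves per group, the Cox
#' log hazard ratio of high vs low (Efron ties) with its two-sided Wald
#' p-value, and the log-rank p-value.
#'
#' @param scores A `sig_scores` object or numeric vector.
#' @param surv_time Follow-up times (>= 0).
#' @param surv_event Event indicators (0 censored / 1 event).
#' @return A list of class `survival_result` with `threshold`, `n_high`,
#'   `n_low`, `km` (data frame: group, time, n_risk, surv), `log_hr`, `hr`,
#'   `wald_p`, `logrank_p`.
#' @export
survival_stratify <- function(scores, surv_time, surv_event) {
  s <- .score_vector(scores)
  stopifnot(length(surv_time) == length(s), length(surv_event) == length(s))
  if (any(surv_time < 0, na.rm = TRUE)) {
    stop("survival_stratify: negative survival time", call. = FALSE)
  }
  if (sum(surv_event, na.rm = TRUE) == 0) {
    stop("survival_stratify: no events in the cohort", call. = FALSE)
  }
  med <- stats::median(s)
  high <- s > med
  if (!any(high) || all(high)) {
    stop(paste("survival_stratify: median split is degenerate (all scores on",
               "one side of the median); cannot form two groups"), call. = FALSE)
  }
  ev <- tapply(surv_event, high, sum)
  if (any(ev < 2)) {
    stop("survival_stratify: fewer than 2 events in one score group", call. = FALSE)
  }
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sobj <- survival::Surv(surv_time, surv_event)
  km_fit <- survival::survfit(sobj ~ grp)
  strata <- rep(sub("^grp=", "", names(km_fit$strata)), km_fit$strata)
  km <- data.frame(group = strata, time = km_fit$time,
                   n_risk = km_fit$n.risk, surv = km_fit$surv,
                   stringsAsFactors = FALSE)
  cox <- survival::coxph(sobj ~ grp, ties = "efron")
  sc <- summary(cox)
  lr <- survival::survdiff(sobj ~ grp)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  structure(list(
    threshold = med, n_high = sum(high), n_low = sum(!high), km = km,
    log_hr = unname(stats::coef(cox)), hr = unname(exp(stats::coef(cox))),
    wald_p = sc$coefficients[1, "Pr(>|z|)"], logrank_p = logrank_p
  ), class = "survival_result")
}

#' Cox association of a continuous signature score with survival
#'
#' Univariable Cox proportional-hazards model on the (optionally
#' standardized) score, Efron ties; complements the median-split analysis
#' with an estimate on the per-SD scale.
#'
#' @param scores A `sig_scores` object or numeric vector.
#' @param surv_time,surv_event Follow-up times and event indicators.
#' @param standardize Scale the score to SD 1 first (default TRUE).
#' @return A list with `log_hr` (per SD if standardized), `hr`, `wald_p`.
#' @export
cox_score_association <- function(scores, surv_time, surv_event,
                                  standardize = TRUE) {
  s <- .score_vector(scores)
  if (standardize) s <- as.numeric(scale(s))
  fit <- survival::coxph(survival::Surv(surv_time, surv_event) ~ s,
                         ties = "efron")
  sm <- summary(fit)
  list(log_hr = unname(stats::coef(fit)), hr = unname(exp(stats::coef(fit))),
       wald_p = sm$coefficients[1, "Pr(>|z|)"])
}
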