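#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return Tibble step function: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (non-increasing, `S(0) = 1` implicitly).
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) abort("Need >= 1 observation.", class = "prtf_usage_error")
  if (any(times < 0)) abort("Negative follow-up time.", class = "prtf_data_error")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square statistic over the pooled event times, with
#' `k - 1` degrees of freedom, via [survival::survdiff()].
#'
#' @inheritParams kaplan_meier
#' @param groups Per-subject group labels (>= 2 non-empty groups).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) {
    abort("Log-rank test needs >= 2 groups.", class = "prtf_usage_error")
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ g,
    data = data.frame(times = times, events = events, g = groups)
  )
  df <- length(sd$n) - 1L
  tibble(statistic = sd$chisq, df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         n_groups = length(sd$n))
}

#' Cox proportional-hazards fit for cohort covariates
#'
#' Fits a Cox model (Efron tie handling, the `survival` default) of overall
#' or relapse-free survival on the requested covariates — typically the
#' continuous P and R enrichment scores plus stage (single ordinal term),
#' age (continuous) and gender (binary indicator). Per-covariate hazard
#' ratios, asymptotic 95% confidence intervals and Wald p-values are
#' reported.
#'
#' @param clinical Data frame with columns `<outcome>_time`, `<outcome>_event`
#'   and one column per covariate.
#' @param covariates Character vector of covariate column names.
#' @param outcome `"os"` (overall survival) or `"rfs"` (relapse-free).
#' @return Object of class `pr_cox` wrapping the [survival::coxph()] fit;
#'   use [tidy.pr_cox()] / [glance.pr_cox()] for tabular views.
#' @export
cox_fit <- function(clinical, covariates, outcome = c("os", "rfs")) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  need <- c(tcol, ecol, covariates)
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols)) {
    abort(sprintf("Clinical table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "prtf_usage_error")
  }
  dat <- as.data.frame(clinical[need])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  const <- covariates[vapply(dat[covariates],
                             function(x) length(unique(x)) < 2L, logical(1))]
  if (length(const)) {
    abort(sprintf("Constant covariate(s): %s", paste(const, collapse = ", ")),
          class = "prtf_usage_error")
  }
  n_events <- sum(dat[[ecol]] == 1)
  if (n_events < 1L) abort("No events in the data.", class = "prtf_data_error")
  if (n_events < length(covariates)) {
    warn(sprintf("Only %d event(s) for %d covariate(s); estimates unstable.",
                 n_events, length(covariates)))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", tcol, ", ", ecol, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (anyNA(stats::coef(fit))) {
    warn("Collinear covariates: some coefficients are not identifiable (NA).")
  }
  s <- summary(fit)
  tab <- tibble(
    term = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci95_low = unname(s$conf.int[, "lower .95"]),
    ci95_high = unname(s$conf.int[, "upper .95"]),
    wald_p = unname(s$coefficients[, "Pr(>|z|)"])
  )
  structure(
    list(fit = fit, table = tab, outcome = outcome,
         n = s$n, n_events = s$nevent,
         loglik = fit$loglik[length(fit$loglik)]),
    class = "pr_cox"
  )
}

#' @export
print.pr_cox <- function(x, ...) {
  cat(sprintf("<pr_cox: %s, n = %d, events = %d>\n",
              toupper(x$outcome), x$n, x$n_events))
  print(x$table)
  invisible(x)
}

#' Tidy / glance methods for Cox fits
#'
#' @param x `pr_cox` object.
#' @param ... Unused.
#' @return `tidy()`: per-covariate tibble (`term`, `hazard_ratio`,
#'   `ci95_low`, `ci95_high`, `wald_p`); `glance()`: one-row model summary.
#' @method tidy pr_cox
#' @export
tidy.pr_cox <- function(x, ...) x$table

#' @rdname tidy.pr_cox
#' @method glance pr_cox
#' @export
glance.pr_cox <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n, n_events = x$n_events,
         loglik = x$loglik)
}
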