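#' Kaplan-Meier product-limit estimate
#'
#' @param times event/censoring times in days (strictly positive).
#' @param events logical event indicators (TRUE = event observed).
#' @return an object of class \code{"km_curve"}: \code{event_times}
#'   (ordered observed event times), \code{survival_prob} (the step
#'   function values at those times), \code{at_risk} and \code{events}
#'   per event time. Censored-only input yields a flat curve at 1.
#' @examples
#' km_fit(c(1, 2), c(TRUE, TRUE))$survival_prob  # 0.5, 0
#' @export
km_fit <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (any(times <= 0)) stop("survival times must be strictly positive")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival_prob = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$event_times), "event times, S(end) =",
      format(if (length(x$survival_prob)) min(x$survival_prob) else 1,
             digits = 4), "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 df,
#' symmetric in group order. Identical groups give statistic 0 and
#' p = 1; with no events anywhere the test is undefined and p = 1 is
#' returned with a flag.
#'
#' @param times,events pooled survival data.
#' @param group logical or two-level factor assigning each patient to a
#'   group.
#' @return list with \code{chi2}, \code{p}, \code{flag}.
#' @export
logrank <- function(times, events, group) {
  events <- as.logical(events)
  g <- as.factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("log-rank test needs two non-empty groups")
  if (!any(events))
    return(list(chi2 = 0, p = 1, flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       flag = NULL)
}

#' Cox proportional-hazards models (univariate and multivariate)
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' days. \code{mode = "univariate"} fits one model per covariate column;
#' \code{mode = "multivariate"} fits them jointly. Hazard ratios are
#' \eqn{e^\beta} with Wald 95\% confidence intervals and p-values.
#' Non-convergence or a monotone likelihood (perfect separation) is
#' flagged and the confidence interval reported as unbounded.
#'
#' @param covariates data.frame of covariates (numeric, logical or
#'   two-level factors); no missing values.
#' @param times,events the survival endpoint (e.g. RFS or OS).
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @return an object of class \code{"cox_result"}: data.frame with one
#'   row per covariate — \code{covariate}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{flag} — plus attribute
#'   \code{"mode"}.
#' @export
cox_fit <- function(covariates, times, events,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("missing covariate values are not allowed")
  surv <- survival::Surv(times, as.logical(events))
  fit_one <- function(df) {
    fml <- stats::as.formula(paste("surv ~", paste(
      paste0("`", names(df), "`"), collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = "efron"),
      warning = function(w) invokeRestart("muffleWarning"))
    sm <- summary(fit)
    beta <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    infinite <- !is.finite(beta) | se > 50 | abs(beta) > 20
    data.frame(
      covariate = names(df),
      hr = exp(beta),
      ci_low = ifelse(infinite, 0, exp(beta - 1.96 * se)),
      ci_high = ifelse(infinite, Inf, exp(beta + 1.96 * se)),
      p = sm$coefficients[, "Pr(>|z|)"],
      flag = ifelse(infinite, "separation", ""),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  cov_num <- as.data.frame(lapply(covariates, function(v) {
    if (is.logical(v)) as.numeric(v)
    else if (is.character(v) || is.factor(v)) as.numeric(as.factor(v)) - 1
    else as.numeric(v)
  }), check.names = FALSE)
  res <- if (mode == "univariate") {
    do.call(rbind, lapply(names(cov_num), function(nm)
      fit_one(cov_num[, nm, drop = FALSE])))
  } else {
    fit_one(cov_num)
  }
  attr(res, "mode") <- mode
  class(res) <- c("cox_result", "data.frame")
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards (", attr(x, "mode"), ", Efron ties)\n",
      sep = "")
  df <- as.data.frame(x)
  df$hr <- signif(df$hr, 4); df$ci_low <- signif(df$ci_low, 4)
  df$ci_high <- signif(df$ci_high, 4); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select covariates for the multivariate model by univariate hazard
#' ratio
#'
#' Covariates whose univariate hazard ratio is at least
#' \code{hr_threshold} (default 2, the entry rule used for the
#' recurrence-free-survival analysis) are carried into the joint model,
#' preserving input order.
#'
#' @param univariate a univariate \code{\link{cox_fit}} result.
#' @param hr_threshold minimum univariate HR for entry.
#' @return character vector of covariate names (possibly empty, with a
#'   message).
#' @examples
#' # HR pattern where the index, lymph metastasis, CA19-9 and CEA enter:
#' uv <- data.frame(covariate = c("index", "age", "lymph", "ca19_9", "cea"),
#'                  hr = c(9.711, 1.022, 2.648, 2.444, 2.682))
#' multivariate_select(uv)
#' @export
multivariate_select <- function(univariate, hr_threshold = 2.0) {
  sel <- univariate$covariate[univariate$hr >= hr_threshold]
  if (!length(sel)) message("no covariate reaches HR >= ", hr_threshold,
                            "; multivariate model skipped")
  sel
}
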