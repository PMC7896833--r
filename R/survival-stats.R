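#' Validate survival records
#'
#' @param time Follow-up time in months (> 0).
#' @param event 1 = event observed, 0 = censored.
#' @return Data frame with columns `time`, `event`.
#' @export
surv_records <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  stopifnot(length(time) == length(event), all(event %in% 0:1))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  data.frame(time = time, event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects at an event time remain at risk for the event at that
#' time (the standard convention). Greenwood standard errors accompany the
#' survival probabilities, and the curve starts at S(0) = 1.
#'
#' @inheritParams surv_records
#' @return A `km_curve`: data frame with `time`, `n_risk`, `n_event`,
#'   `surv`, `se`.
#' @export
km_estimate <- function(time, event) {
  r <- surv_records(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = r,
                           conf.type = "none")
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(fit$n, fit$n.risk),
                    n_event = c(0, fit$n.event),
                    surv = c(1, fit$surv),
                    se = c(0, fit$surv * fit$std.err))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$time, x$surv, type = "s", ylim = c(0, 1),
                 xlab = "months", ylab = "survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the distinct event times, referred to
#' a chi-square distribution with 1 df.
#'
#' @param time_a,event_a Records of group A.
#' @param time_b,event_b Records of group B.
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  a <- surv_records(time_a, event_a); b <- surv_records(time_b, event_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be non-empty")
  if (sum(a$event) + sum(b$event) == 0)
    stop("log-rank test undefined: no events in either group")
  dat <- rbind(cbind(a, group = "A"), cbind(b, group = "B"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chi2 <- as.numeric(sd_$chisq)
  list(chi2 = chi2, df = 1,
       p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Left-continuous and right-continuous evaluation of a KM step function.
km_stepfun <- function(times, surv) {
  function(t, left = FALSE) {
    k <- findInterval(t, times, left.open = left)
    c(1, surv)[k + 1]
  }
}

#' Time-dependent ROC curve and AUC
#'
#' Cumulative-cases / dynamic-controls estimator at horizon `t_eval` with
#' inverse-probability-of-censoring weights (IPCW) from the Kaplan-Meier
#' estimate of the censoring distribution. Cases are subjects with an
#' observed event at or before `t_eval`; controls are subjects still under
#' observation beyond `t_eval`. Tied marker values count one half.
#'
#' @param marker Numeric risk marker (higher = higher risk).
#' @inheritParams surv_records
#' @param t_eval Evaluation horizon (months), within the observed range.
#' @return List with `auc`, `roc` (data frame of `threshold`,
#'   `sensitivity`, `one_minus_specificity`), `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(marker, time, event, t_eval = 24) {
  r <- surv_records(time, event)
  stopifnot(length(marker) == nrow(r))
  if (t_eval <= 0 || t_eval > max(r$time))
    stop("t_eval must lie within the observed time range")
  cases <- which(r$time <= t_eval & r$event == 1)
  controls <- which(r$time > t_eval)
  if (length(cases) == 0) stop("no cases at the evaluation horizon")
  if (length(controls) == 0) stop("no controls at the evaluation horizon")

  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = r,
                            conf.type = "none")
  G <- km_stepfun(cfit$time, cfit$surv)
  w_case <- 1 / pmax(G(r$time[cases], left = TRUE), 1e-12)
  w_ctrl <- rep(1 / max(G(t_eval), 1e-12), length(controls))

  mc <- marker[cases]; mk <- marker[controls]
  cmp <- outer(mc, mk, function(a, b) (a > b) + 0.5 * (a == b))
  wmat <- outer(w_case, w_ctrl)
  auc <- sum(cmp * wmat) / sum(wmat)

  thr <- sort(unique(marker), decreasing = TRUE)
  roc <- t(vapply(thr, function(cth) {
    c(sum(w_case[mc > cth]) / sum(w_case),
      sum(w_ctrl[mk > cth]) / sum(w_ctrl))
  }, numeric(2)))
  roc <- rbind(c(0, 0), roc, c(1, 1))
  roc_df <- data.frame(threshold = c(Inf, thr, -Inf),
                       sensitivity = roc[, 1],
                       one_minus_specificity = roc[, 2])
  list(auc = auc, roc = roc_df,
       n_cases = length(cases), n_controls = length(controls))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling) and reports
#' per-covariate hazard ratios with Wald 95% confidence intervals and
#' p-values.
#'
#' @param covariates Data frame of covariates (no constant columns).
#' @inheritParams surv_records
#' @return A `cox_fit_result`: list with `table` (term, hr, ci_lo, ci_hi,
#'   p), `loglik`, `converged`.
#' @export
cox_fit <- function(covariates, time, event) {
  r <- surv_records(time, event)
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(r))
  const <- vapply(covariates, function(v) length(unique(v)) < 2,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  if (sum(r$event) < ncol(covariates))
    warning("fewer events than covariates; estimates may be unstable")
  dat <- cbind(covariates, .time = r$time, .event = r$event)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        stop("Cox fit failed (separation or non-convergence): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("singular information matrix (collinear covariates): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  tab <- data.frame(term = names(cf), coef = as.numeric(cf),
                    hr = exp(cf), ci_lo = exp(cf - z * se),
                    ci_hi = exp(cf + z * se),
                    p = 2 * pnorm(-abs(cf / se)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2], converged = TRUE),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  print(transform(x$table, hr = round(hr, 3), ci_lo = round(ci_lo, 3),
                  ci_hi = round(ci_hi, 3), p = signif(p, 3)))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a dichotomous prediction
#'
#' The positive class is relapse; predicted positive means the high-PSI
#' group. Values are returned in percent.
#'
#' @param predicted Binary/logical vector (1 = predicted positive).
#' @param truth Binary/logical vector (1 = relapse within the horizon).
#' @return Named list: `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
classification_metrics <- function(predicted, truth) {
  predicted <- as.integer(as.logical(predicted))
  truth <- as.integer(as.logical(truth))
  stopifnot(length(predicted) == length(truth))
  if (sum(truth) == 0)
    stop("no true positives: sensitivity is undefined")
  if (sum(truth) == length(truth))
    stop("no true negatives: specificity is undefined")
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / length(truth))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' the observed table's.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return The two-sided p-value (1, with a warning, for an empty margin).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-8))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin: Fisher p-value set to 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Univariate log-rank screening with median cutoffs
#'
#' Continuous variables are dichotomized at their median (or a supplied
#' cutoff) and categorical variables used as-is; each variable is screened
#' with a log-rank test. No multiplicity adjustment is applied.
#'
#' @param variables Data frame of candidate prognostic variables.
#' @inheritParams surv_records
#' @param cutoffs Optional named list of cutoffs for continuous variables.
#' @return Data frame with `variable`, `type`, `cutoff`, `p`.
#' @export
univariate_screen <- function(variables, time, event, cutoffs = NULL) {
  r <- surv_records(time, event)
  stopifnot(is.data.frame(variables), nrow(variables) == nrow(r))
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    if (length(unique(v)) < 2) {
      warning("skipping constant variable ", nm)
      return(NULL)
    }
    if (is.numeric(v) && length(unique(v)) > 2) {
      cut <- if (!is.null(cutoffs) && nm %in% names(cutoffs))
        cutoffs[[nm]] else median(v)
      g <- v > cut
      if (length(unique(g)) < 2) {
        warning("skipping ", nm, ": cutoff yields a single group")
        return(NULL)
      }
      type <- "continuous"
    } else {
      g <- as.factor(v)
      cut <- NA_real_
      type <- "categorical"
    }
    dat <- data.frame(time = r$time, event = r$event, g = g)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
    df <- length(unique(g)) - 1
    data.frame(variable = nm, type = type, cutoff = as.numeric(cut),
               p = pchisq(as.numeric(sd_$chisq), df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
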