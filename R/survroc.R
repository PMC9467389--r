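#' Nearest-neighbour time-dependent ROC for a survival marker
#'
#' Heagerty-Lumley-Pepe estimator of time-dependent sensitivity and
#' specificity at a horizon `t`: the conditional survival `S(t | X = x)` is
#' estimated by a Kaplan-Meier fit over a nearest-neighbour window in marker
#' percentile space (half-width `span`), giving a smoothed bivariate survival
#' function
#' `S(c, t) = (1/n) sum_{x_i > c} S(t | x_i)`. Sensitivity and 1-specificity
#' at each marker cutpoint are
#' `TPR(c) = ((1 - F(c)) - S(c, t)) / (1 - S(t))` and
#' `FPR(c) = S(c, t) / S(t)`, both monotone in `c` by construction, and the
#' AUC is the trapezoid rule over the swept curve.
#'
#' @param scores numeric marker per subject (higher = higher risk).
#' @param time,event follow-up time and event flag.
#' @param horizon evaluation time `t` (must not precede every event).
#' @param span neighbourhood half-width as a fraction of the sample; default
#'   `0.25 * n^(-0.2)`.
#' @return object of class `nne_roc`: data frame `curve` (`cutoff`, `tpr`,
#'   `fpr`), `auc`, `horizon`, `span`, and the marker values (`scores`).
#' @export
nne_roc <- function(scores, time, event, horizon, span = NULL) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (!any(event == 1 & time <= horizon)) {
    stopf("no events at or before the horizon (t = %g)", horizon)
  }
  if (is.null(span)) span <- 0.25 * n^(-0.2)
  pct <- rank(scores, ties.method = "average") / n
  # conditional survival S(t | x_i): KM on the percentile neighbourhood of i
  s_cond <- vapply(seq_len(n), function(i) {
    nb <- which(abs(pct - pct[i]) <= span)
    km_at(time[nb], event[nb], horizon)
  }, 0)
  s_marg <- mean(s_cond)
  cuts <- sort(unique(scores))
  denom_tp <- 1 - s_marg
  tpr <- vapply(cuts, function(c) sum((scores > c) * (1 - s_cond)) / n / denom_tp, 0)
  fpr <- vapply(cuts, function(c) sum((scores > c) * s_cond) / n / s_marg, 0)
  curve <- data.frame(cutoff = c(-Inf, cuts), tpr = c(1, pmin(pmax(tpr, 0), 1)),
                      fpr = c(1, pmin(pmax(fpr, 0), 1)))
  ord <- order(curve$fpr, curve$tpr)
  auc <- sum(diff(curve$fpr[ord]) * (utils::head(curve$tpr[ord], -1) +
                                       utils::tail(curve$tpr[ord], -1)) / 2)
  structure(list(curve = curve, auc = auc, horizon = horizon, span = span,
                 scores = scores),
            class = "nne_roc")
}

# Kaplan-Meier survival probability at a single time point.
km_at <- function(time, event, t) {
  dt <- sort(unique(time[event == 1 & time <= t]))
  s <- 1
  for (d in dt) {
    at_risk <- sum(time >= d)
    died <- sum(time == d & event == 1)
    if (at_risk > 0) s <- s * (1 - died / at_risk)
  }
  s
}

#' @export
print.nne_roc <- function(x, ...) {
  cat(sprintf("<nne_roc> horizon %g, span %.4f, AUC %.3f (%d cutpoints)\n",
              x$horizon, x$span, x$auc, nrow(x$curve)))
  invisible(x)
}

#' Choose a score cutoff from an NNE ROC curve
#'
#' Cutpoint maximizing the Youden index `TPR - FPR`; among ties, the cutpoint
#' nearest the marker median. A flat curve (no cutpoint improves on chance)
#' yields the median with a warning.
#'
#' @param roc an `nne_roc`.
#' @return scalar cutoff on the score scale.
#' @export
select_cutoff <- function(roc) {
  cv <- roc$curve
  fin <- is.finite(cv$cutoff)
  youden <- cv$tpr[fin] - cv$fpr[fin]
  cuts <- cv$cutoff[fin]
  if (max(youden) <= 1e-12) {
    warnf("flat ROC curve; using the median score as cutoff")
    return(stats::median(roc$scores))
  }
  best <- which(youden >= max(youden) - 1e-12)
  med <- stats::median(roc$scores)
  cuts[best][which.min(abs(cuts[best] - med))]
}

#' Kaplan-Meier strata and log-rank comparison
#'
#' Product-limit survival estimate per stratum and the log-rank chi-square
#' test (k - 1 df) between strata.
#'
#' @param time,event follow-up time and event flag.
#' @param group stratum per subject (each stratum non-empty).
#' @return list of class `km_result`: `table` (stratum, time, n_risk,
#'   n_event, survival), `chisq`, `df`, `p`, and the underlying `survfit`.
#' @export
kaplan_meier <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 1 || any(table(group) == 0)) stopf("each stratum must be non-empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tab <- data.frame(stratum = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv,
                    stringsAsFactors = FALSE)
  chisq <- NA_real_; p <- NA_real_; df <- nlevels(group) - 1
  if (nlevels(group) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  }
  structure(list(table = tab, chisq = chisq, df = df, p = p, fit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d strata; log-rank chisq %.3f (df %d), p %.4g\n",
              length(unique(x$table$stratum)), x$chisq, x$df, x$p))
  invisible(x)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Cox regression (Efron tie handling) of the survival outcome on a covariate
#' table, reporting per covariate the log hazard `beta`, its SE, the hazard
#' ratio `exp(beta)` with 95% CI `exp(beta +- 1.96 SE)`, the Wald p-value,
#' plus the model's Harrell C-index.
#'
#' @param time,event follow-up time and event flag.
#' @param covariates data frame of covariates (e.g. risk-group indicator,
#'   bacterial score, clinical score).
#' @return object of class `cox_result`: data frame `table` (`term`, `beta`,
#'   `se`, `HR`, `ci_lower`, `ci_upper`, `p`), `c_index`, `n_events`, `ties`.
#' @export
cox_fit <- function(time, event, covariates) {
  if (sum(event) < ncol(covariates) + 1) {
    warnf("fewer events (%d) than covariates + 1 (%d); estimates may be unstable",
          sum(event), ncol(covariates) + 1)
  }
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "efron", control = survival::coxph.control(iter.max = 100))
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("singular information matrix; inestimable term(s): %s",
          paste(bad, collapse = ", "))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    HR = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - 1.96 * unname(se)),
                    ci_upper = exp(unname(beta) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, c_index = unname(fit$concordance["concordance"]),
                 n_events = sum(event), ties = "efron", fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %d events; C-index %.3f (ties: %s)\n",
              x$n_events, x$c_index, x$ties))
  print(transform(x$table, beta = round(beta, 4), se = round(se, 4),
                  HR = round(HR, 3), ci_lower = round(ci_lower, 4),
                  ci_upper = round(ci_upper, 4), p = signif(p, 4)))
  invisible(x)
}

#' Bootstrap optimism-corrected performance of the risk pipeline
#'
#' Harrell's optimism correction: the entire pipeline (screening, LASSO path,
#' cross-validated lambda, scoring) is refit on each bootstrap resample of the
#' subjects, the performance gap between the resample and the original data is
#' averaged, and that optimism is subtracted from the apparent metrics
#' (horizon AUC and Harrell C-index). Resamples without events are redrawn.
#' `n_boot = 0` returns the apparent metrics unchanged.
#'
#' @inheritParams viral_risk
#' @param n_boot number of bootstrap resamples.
#' @return list: `apparent`, `optimism`, `corrected` (each with `auc` and
#'   `c_index`), `n_boot`, `n_failed` (resamples where the pipeline could not
#'   be refit, e.g. nothing passed screening).
#' @export
internal_validation <- function(rel, time, event, horizon = 12, n_boot = 200,
                                seed = 1L, ...) {
  fit0 <- viral_risk(rel, time, event, horizon = horizon, seed = seed, ...)
  metric <- function(scores, time, event) {
    auc <- nne_roc(scores, time, event, horizon = horizon)$auc
    cidx <- if (stats::sd(scores) > 0) {
      unname(survival::concordance(survival::Surv(time, event) ~ scores,
                                   reverse = TRUE)$concordance)
    } else 0.5
    c(auc = auc, c_index = cidx)
  }
  apparent <- metric(fit0$scores, time, event)
  if (n_boot == 0) {
    return(list(apparent = as.list(apparent), optimism = list(auc = 0, c_index = 0),
                corrected = as.list(apparent), n_boot = 0, n_failed = 0))
  }
  n <- length(time)
  opt <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("auc", "c_index")))
  n_failed <- 0
  with_seed(derive_seed(seed, "boot"), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) >= 2 && any(event[idx] == 1 & time[idx] <= horizon)) break
      }
      fb <- tryCatch(
        suppressWarnings(viral_risk(rel[idx, , drop = FALSE], time[idx], event[idx],
                                    horizon = horizon, seed = seed, ...)),
        error = function(e) NULL)
      if (is.null(fb) || !length(fb$coefficients)) {
        n_failed <- n_failed + 1
        next
      }
      boot_app <- metric(fb$scores, time[idx], event[idx])
      orig <- metric(predict(fb, rel), time, event)
      opt[b, ] <- boot_app - orig
    }
  })
  optimism <- colMeans(opt, na.rm = TRUE)
  optimism[is.nan(optimism)] <- 0
  list(apparent = as.list(apparent),
       optimism = as.list(optimism),
       corrected = as.list(apparent - optimism),
       n_boot = n_boot, n_failed = n_failed)
}
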