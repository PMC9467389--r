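#' Screen candidate taxa for the recurrence model
#'
#' Per-taxon two-group Wilcoxon rank-sum test (recurrence vs no recurrence)
#' with BH adjustment; taxa with `q < q_max` (strict) are retained as
#' candidates for the penalized Cox fit.
#'
#' @param features numeric matrix, samples x taxa (any monotone abundance
#'   scale; the test is rank-based).
#' @param groups two-level vector aligned with rows (e.g. the event flag).
#' @param q_max BH-adjusted p-value cutoff (exclusive).
#' @return character vector of retained taxa; the full per-taxon table
#'   (`taxon`, `p`, `q`) is attached as attribute `table`.
#' @export
screen_candidates <- function(features, groups, q_max = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 2)) {
    stopf("need two groups with n >= 2 each")
  }
  a <- groups == levels(groups)[1]
  p <- vapply(seq_len(ncol(features)), function(j) {
    wilcoxon_rank_sum(features[a, j], features[!a, j])$p.value
  }, 0)
  q <- bh_adjust(p)
  tab <- data.frame(taxon = colnames(features), p = p, q = q, stringsAsFactors = FALSE)
  keep <- tab$taxon[tab$q < q_max]
  if (!length(keep)) warnf("no taxa pass the screening cutoff q < %g", q_max)
  attr(keep, "table") <- tab
  keep
}

# log10(relative abundance + pseudo), column z-scored; returns the matrix with
# the centering/scaling recorded for reuse on new data.
standardize_features <- function(rel, pseudo = 1e-6, center = NULL, scale = NULL) {
  x <- log10(rel + pseudo)
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  }
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  attr(z, "pseudo") <- pseudo
  z
}

#' LASSO-penalized Cox coefficient path
#'
#' L1-penalized Cox partial-likelihood fit over a decreasing lambda grid
#' (coordinate descent with warm starts via glmnet, Breslow tie handling).
#' The first grid point is the smallest lambda with an all-zero solution.
#'
#' @param x numeric matrix, samples x features (standardize beforehand, e.g.
#'   with the transform used by [viral_risk()]).
#' @param time,event survival outcome (months, 0/1); at least one event.
#' @param nlambda grid length.
#' @param standardize let the solver standardize internally (default `FALSE`:
#'   the pipeline feeds z-scored features).
#' @return object of class `lasso_cox_path`: `lambda`, `beta`
#'   (features x lambda), and the underlying fit.
#' @export
lasso_cox_path <- function(x, time, event, nlambda = 100, standardize = FALSE) {
  if (sum(event) < 1) stopf("no events; cannot fit a Cox model")
  y <- survival::Surv(time, event)
  fit <- glmnet::glmnet(x, y, family = "cox", nlambda = nlambda,
                        standardize = standardize)
  structure(list(lambda = fit$lambda, beta = as.matrix(fit$beta), fit = fit),
            class = "lasso_cox_path")
}

#' @export
print.lasso_cox_path <- function(x, ...) {
  cat(sprintf("<lasso_cox_path> %d features, %d lambda values (max %.4g)\n",
              nrow(x$beta), length(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Cross-validated lambda selection for the penalized Cox fit
#'
#' K-fold cross-validation on the held-out partial-likelihood deviance, with
#' folds stratified on the event indicator so every fold sees events.
#' Returns both the deviance-minimizing lambda and the 1-SE lambda (largest
#' lambda within one standard error of the minimum). Deterministic given
#' `seed`.
#'
#' @inheritParams lasso_cox_path
#' @param k_folds number of folds (reduced with a warning if events are few).
#' @param seed integer seed for the fold assignment.
#' @return list: `lambda_min`, `lambda_1se`, `lambda`, `cvm`, `cvsd`.
#' @export
cv_select_lambda <- function(x, time, event, k_folds = 10, seed = 1L) {
  n_events <- sum(event)
  if (n_events < 2) stopf("need at least 2 events for cross-validation")
  if (k_folds > n_events) {
    warnf("reducing k_folds from %d to %d (number of events)", k_folds, n_events)
    k_folds <- n_events
  }
  foldid <- with_seed(seed, {
    f <- integer(length(event))
    for (g in c(0, 1)) {
      idx <- which(event == g)
      f[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(x, survival::Surv(time, event), family = "cox",
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  list(lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd, foldid = foldid)
}

#' Compute the viral score for a coefficient set
#'
#' Linear combination of the selected taxa weighted by their coefficients, on
#' the standardized scale used in fitting: `score_i = sum_j coef_j * z_ij`.
#'
#' @param coefs named numeric vector of (nonzero) coefficients.
#' @param z standardized feature matrix, samples x taxa, covering the
#'   coefficient names.
#' @return numeric vector of per-sample scores.
#' @export
viral_score <- function(coefs, z) {
  miss <- setdiff(names(coefs), colnames(z))
  if (length(miss)) stopf("feature matrix lacks selected taxa: %s",
                          paste(miss, collapse = ", "))
  if (!length(coefs)) return(stats::setNames(rep(0, nrow(z)), rownames(z)))
  as.vector(z[, names(coefs), drop = FALSE] %*% coefs)
}

#' Fit the viral recurrence risk model
#'
#' The full risk pipeline as a single fitting function: taxa are transformed
#' to `log10(relative abundance + 1e-6)` and z-scored, screened by Wilcoxon
#' rank-sum between recurrence groups (`q < q_screen`), a LASSO-penalized Cox
#' path is fit on the candidates with lambda chosen by stratified
#' cross-validation (1-SE rule by default), the viral score is the linear
#' combination of the retained taxa, and the score is evaluated by a
#' nearest-neighbour time-dependent ROC at `horizon` months whose Youden
#' cutoff splits patients into high/low risk strata compared by log-rank.
#'
#' @param rel numeric matrix of relative abundances, samples x viral taxa
#'   (rows aligned with `time`/`event`).
#' @param time,event follow-up months and recurrence flag per sample.
#' @param horizon ROC evaluation horizon in months.
#' @param q_screen screening cutoff.
#' @param lambda `"1se"` (default, sparser) or `"min"`.
#' @param k_folds,seed cross-validation folds and seed.
#' @param pseudo pseudo-count inside the log transform.
#' @return object of class `viral_risk` with elements `taxa` (selected),
#'   `coefficients`, `lambda`, `scores`, `cutoff`, `roc` ([nne_roc()] result),
#'   `km` ([kaplan_meier()] result for the two risk strata), `screening`,
#'   `path`, `cv`, `transform`, and the call.
#' @seealso [predict.viral_risk()], [internal_validation()]
#' @export
viral_risk <- function(rel, time, event, horizon = 12, q_screen = 0.05,
                       lambda = c("1se", "min"), k_folds = 10, seed = 1L,
                       pseudo = 1e-6) {
  lambda <- match.arg(lambda)
  stopifnot(nrow(rel) == length(time), length(time) == length(event))
  z <- standardize_features(rel, pseudo = pseudo)
  candidates <- screen_candidates(z, factor(event, levels = c(0, 1)), q_max = q_screen)
  screening <- attr(candidates, "table")
  if (!length(candidates)) {
    stopf("no candidate taxa passed screening; cannot fit the risk model")
  }
  xs <- z[, candidates, drop = FALSE]
  if (length(candidates) == 1) {
    # nothing to select: unpenalized univariate Cox coefficient
    cph <- survival::coxph(survival::Surv(time, event) ~ xs)
    coefs <- stats::setNames(unname(stats::coef(cph)), candidates)
    path <- NULL
    cv <- list(lambda_min = NA_real_, lambda_1se = NA_real_)
    lam <- NA_real_
  } else {
    path <- lasso_cox_path(xs, time, event)
    cv <- cv_select_lambda(xs, time, event, k_folds = k_folds,
                           seed = derive_seed(seed, "cv"))
    lam <- if (lambda == "1se") cv$lambda_1se else cv$lambda_min
    beta <- as.vector(glmnet::coef.glmnet(path$fit, s = lam))
    names(beta) <- rownames(glmnet::coef.glmnet(path$fit, s = lam))
    coefs <- beta[beta != 0]
    if (!length(coefs) && lambda == "1se") {
      warnf("empty model at lambda_1se; falling back to lambda_min")
      lam <- cv$lambda_min
      beta <- as.vector(glmnet::coef.glmnet(path$fit, s = lam))
      names(beta) <- colnames(xs)
      coefs <- beta[beta != 0]
    }
  }
  scores <- viral_score(coefs, z)
  names(scores) <- rownames(rel)
  roc <- nne_roc(scores, time, event, horizon = horizon)
  cutoff <- select_cutoff(roc)
  risk_group <- factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
  km <- if (nlevels(droplevels(risk_group)) == 2) {
    kaplan_meier(time, event, risk_group)
  } else NULL
  structure(list(taxa = names(coefs), coefficients = coefs, lambda = lam,
                 lambda_min = cv$lambda_min, lambda_1se = cv$lambda_1se,
                 scores = scores, cutoff = cutoff, risk_group = risk_group,
                 roc = roc, km = km, screening = screening, path = path, cv = cv,
                 horizon = horizon,
                 transform = list(center = attr(z, "center"), scale = attr(z, "scale"),
                                  pseudo = pseudo),
                 call = match.call()),
            class = "viral_risk")
}

#' @export
print.viral_risk <- function(x, ...) {
  cat(sprintf("<viral_risk> %d taxa selected (lambda = %.4g)\n",
              length(x$taxa), x$lambda))
  cat(sprintf("  %d-month NNE AUC %.3f | cutoff %.4f | high risk: %d / %d\n",
              x$horizon, x$roc$auc, x$cutoff, sum(x$risk_group == "high"),
              length(x$scores)))
  if (!is.null(x$km)) cat(sprintf("  log-rank p = %.4g\n", x$km$p))
  invisible(x)
}

#' @export
coef.viral_risk <- function(object, ...) object$coefficients

#' Predict viral scores or risk groups for new samples
#'
#' @param object a fitted `viral_risk`.
#' @param newdata relative-abundance matrix, samples x taxa, covering the
#'   model's taxa (transformed with the training centering/scaling).
#' @param type `"score"` (linear predictor) or `"risk"` (high/low by the
#'   fitted cutoff).
#' @param ... unused.
#' @return numeric scores or a factor of risk groups.
#' @export
predict.viral_risk <- function(object, newdata, type = c("score", "risk"), ...) {
  type <- match.arg(type)
  tr <- object$transform
  miss <- setdiff(object$taxa, colnames(newdata))
  if (length(miss)) stopf("newdata lacks model taxa: %s", paste(miss, collapse = ", "))
  cols <- names(tr$center)[names(tr$center) %in% colnames(newdata)]
  z <- standardize_features(newdata[, cols, drop = FALSE], pseudo = tr$pseudo,
                            center = tr$center[cols], scale = tr$scale[cols])
  s <- viral_score(object$coefficients, z)
  names(s) <- rownames(newdata)
  if (type == "score") s else factor(ifelse(s > object$cutoff, "high", "low"),
                                     levels = c("low", "high"))
}

#' @export
summary.viral_risk <- function(object, covariates = NULL, ...) {
  cat("Viral recurrence risk model\n")
  cat(sprintf("Screened candidates: %d | selected taxa: %d\n",
              nrow(object$screening), length(object$taxa)))
  if (length(object$coefficients)) {
    print(round(sort(object$coefficients), 4))
  }
  cat(sprintf("lambda: %.4g (min %.4g, 1se %.4g)\n",
              object$lambda, object$lambda_min, object$lambda_1se))
  cat(sprintf("%d-month NNE AUC: %.3f | score cutoff: %.4f\n",
              object$horizon, object$roc$auc, object$cutoff))
  if (!is.null(object$km)) {
    cat(sprintf("log-rank (high vs low risk): chisq %.3f, p %.4g\n",
                object$km$chisq, object$km$p))
  }
  invisible(object)
}
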