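sim_surv <- function(n, beta, x = NULL, h0 = 0.05, cmax = 30, seed = 1) {
  set.seed(seed)
  if (is.null(x)) x <- matrix(rnorm(n * length(beta)), n,
                              dimnames = list(paste0("p", 1:n), names(beta)))
  lp <- as.vector(x %*% beta)
  t_ev <- rexp(n, h0 * exp(lp))
  cc <- runif(n, 0, cmax)
  list(x = x, time = pmin(t_ev, cc), event = as.integer(t_ev <= cc))
}

test_that("candidate screening applies a strict q cutoff", {
  set.seed(20)
  n <- 40
  x <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("t", 1:30)))
  g <- rep(0:1, each = n / 2)
  x[g == 1, 1:4] <- x[g == 1, 1:4] + 2.5
  keep <- screen_candidates(x, g)
  expect_true(all(paste0("t", 1:4) %in% keep))
  expect_lte(length(setdiff(keep, paste0("t", 1:4))), 2)
  # identical groups: empty set
  x2 <- rbind(x[g == 0, ], x[g == 0, ])
  expect_warning(k2 <- screen_candidates(x2, g), "no taxa")
  expect_length(k2, 0)
})

test_that("penalty dominance, oracle equivalence and path ordering hold", {
  d <- sim_surv(40, c(f1 = 1.2, f2 = -0.8), seed = 2)
  path <- lasso_cox_path(d$x, d$time, d$event)
  # at lambda >= lambda_max every coefficient is zero
  b_top <- as.vector(glmnet::coef.glmnet(path$fit, s = max(path$lambda) * 1.5))
  expect_true(all(b_top == 0))
  # lambda -> 0 approaches the unpenalized (Breslow) Cox fit
  fit0 <- glmnet::glmnet(d$x, survival::Surv(d$time, d$event), family = "cox",
                         lambda = c(0.05, 1e-6), thresh = 1e-14)
  b_small <- as.vector(glmnet::coef.glmnet(fit0, s = 1e-6))
  cph <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x, ties = "breslow")
  expect_equal(b_small, unname(coef(cph)), tolerance = 1e-4)
})

test_that("a single strong feature survives longest along the path", {
  last <- vapply(1:20, function(s) {
    d <- sim_surv(60, c(strong = 1.5, n1 = 0, n2 = 0, n3 = 0), seed = s)
    path <- lasso_cox_path(d$x, d$time, d$event)
    nz <- path$beta != 0
    first_nz <- apply(nz, 1, function(r) if (any(r)) which(r)[1] else Inf)
    names(which.min(first_nz)) == "strong"
  }, TRUE)
  expect_gte(mean(last), 0.9)
})

test_that("cross-validated lambda selection is ordered, sparse under noise, deterministic", {
  d <- sim_surv(100, stats::setNames(rep(0, 15), paste0("n", 1:15)), seed = 3)
  cv1 <- cv_select_lambda(d$x, d$time, d$event, seed = 4)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  cv2 <- cv_select_lambda(d$x, d$time, d$event, seed = 4)
  expect_identical(cv1$foldid, cv2$foldid)
  expect_equal(cv1$lambda_1se, cv2$lambda_1se)
  empty <- vapply(1:20, function(s) {
    dn <- sim_surv(80, stats::setNames(rep(0, 10), paste0("n", 1:10)), seed = 100 + s)
    path <- lasso_cox_path(dn$x, dn$time, dn$event)
    cv <- cv_select_lambda(dn$x, dn$time, dn$event, seed = s)
    all(glmnet::coef.glmnet(path$fit, s = cv$lambda_1se) == 0)
  }, TRUE)
  expect_gte(mean(empty), 0.8)
})

test_that("viral score is the exact linear combination of selected taxa", {
  z <- matrix(c(1.5, -2, 0.3, 1), 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(viral_score(c(t1 = 2), z), c(3.0, -4))
  expect_equal(viral_score(stats::setNames(numeric(0), character(0)), z),
               c(a = 0, b = 0))
  # unselected features do not affect the score
  z2 <- z; z2[, "t2"] <- 99
  expect_equal(viral_score(c(t1 = 2), z2), viral_score(c(t1 = 2), z))
  expect_error(viral_score(c(missing = 1), z), "lacks")
})

test_that("NNE ROC is correct for perfect, null-free and sign-flipped markers", {
  # perfect marker, no censoring: events ordered by score
  n <- 60
  score <- seq_len(n)
  time <- 40 - 0.5 * score          # high score -> early event
  roc <- nne_roc(score, time, rep(1, n), horizon = 20)
  expect_gte(roc$auc, 0.99)
  expect_true(all(roc$curve$tpr >= 0 & roc$curve$tpr <= 1))
  expect_true(all(diff(roc$curve$tpr) <= 1e-9))  # monotone along cutoffs
  expect_true(all(diff(roc$curve$fpr) <= 1e-9))
  # flipping the marker maps AUC to 1 - AUC
  roc_f <- nne_roc(-score, time, rep(1, n), horizon = 20)
  expect_equal(roc_f$auc, 1 - roc$auc, tolerance = 1e-9)
  expect_error(nne_roc(score, time + 100, rep(1, n), horizon = 20), "no events")
})

test_that("cutoff selection maximizes Youden and recovers a planted boundary", {
  set.seed(21)
  n <- 100
  grp <- rep(0:1, each = n / 2)
  score <- ifelse(grp == 1, rnorm(n, 2, 0.5), rnorm(n, -2, 0.5))
  time <- ifelse(grp == 1, rexp(n, 0.2), rexp(n, 0.01))
  event <- rbinom(n, 1, ifelse(grp == 1, 0.9, 0.3))
  roc <- nne_roc(score, time, event, horizon = 10)
  cut <- select_cutoff(roc)
  expect_gt(cut, max(score[grp == 0]) - 0.5)
  expect_lt(cut, min(score[grp == 1]) + 0.5)
})

test_that("Kaplan-Meier steps and log-rank behave on canonical cases", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("all", 4))
  expect_equal(km$table$survival, c(0.75, 0.5, 0.25, 0))
  # identical strata: chisq ~ 0, p ~ 1
  km2 <- kaplan_meier(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                      rep(c("a", "b"), each = 3))
  expect_lt(km2$chisq, 1e-9)
  expect_gt(km2$p, 0.99)
  # all censored: survival identically 1
  km3 <- kaplan_meier(c(2, 5, 9), c(0, 0, 0), rep("a", 3))
  expect_true(all(km3$table$survival == 1))
})

test_that("Cox fit matches a grid-search oracle and reports exact CI arithmetic", {
  # hand-built small dataset
  time <- c(2, 4, 5, 7, 9, 11, 12, 15)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0)
  x <- c(1, 1, 0, 1, 0, 0, 0, 1)
  fit <- cox_fit(time, event, data.frame(x = x))
  expect_equal(fit$table$beta, cox_grid_oracle(time, event, x), tolerance = 1e-3)
  expect_equal(fit$table$ci_lower, exp(fit$table$beta - 1.96 * fit$table$se))
  expect_equal(fit$table$ci_upper, exp(fit$table$beta + 1.96 * fit$table$se))
  expect_true(fit$table$HR > 0)
  # duplicated covariate: singular information
  expect_error(suppressWarnings(cox_fit(time, event, data.frame(x = x, x2 = x))),
               "singular|inestimable")
})

test_that("full risk fit selects signal taxa and stratifies survival", {
  ch <- generate_cohort(cohort_config(
    n_control = 5, n_paf = 100, n_psaf_short = 2, n_psaf_long = 2,
    n_ablated = 100, n_viruses = 120, n_bacteria = 25, seed = 31))
  rel <- t(unclass(to_relative(ch$virus_counts))[, ch$survival$sample])
  fit <- suppressWarnings(viral_risk(rel, ch$survival$time_months, ch$survival$event,
                                     seed = 7))
  expect_s3_class(fit, "viral_risk")
  expect_gte(sum(ch$truth$causal_viruses %in% fit$taxa), 1)
  expect_gt(fit$roc$auc, 0.6)
  expect_equal(unname(fit$scores),
               unname(viral_score(fit$coefficients,
                                  standardize_features(rel)[, , drop = FALSE])))
  # predict on the training matrix reproduces the fitted scores
  expect_equal(unname(predict(fit, rel)), unname(fit$scores), tolerance = 1e-12)
  expect_identical(levels(predict(fit, rel, type = "risk")), c("low", "high"))
  if (!is.null(fit$km)) expect_lt(fit$km$p, 0.05)
})

test_that("bootstrap optimism correction shrinks inflated apparent AUC", {
  set.seed(41)
  n <- 60
  rel <- matrix(rexp(n * 40), n, dimnames = list(paste0("p", 1:n), paste0("v", 1:40)))
  rel <- rel / rowSums(rel)
  time <- rexp(n, 0.08); event <- rbinom(n, 1, 0.5)
  iv0 <- tryCatch(
    suppressWarnings(internal_validation(rel, time, event, n_boot = 0, q_screen = 0.9)),
    error = function(e) NULL)
  skip_if(is.null(iv0), "null pipeline produced no model")
  expect_equal(iv0$corrected$auc, iv0$apparent$auc)
  iv <- suppressWarnings(internal_validation(rel, time, event, n_boot = 25,
                                             q_screen = 0.9, seed = 5))
  expect_lte(iv$corrected$auc, iv$apparent$auc + 0.02)
  expect_lt(abs(iv$corrected$auc - 0.5), 0.2)
})
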