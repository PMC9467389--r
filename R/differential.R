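#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over features
#' of the ratio of its count to the feature's geometric mean across samples,
#' using only features with strictly positive counts in every sample. If no
#' such feature exists, the geometric means are computed over the positive
#' entries of each feature instead (logged via a message). Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts count `abund_matrix` or numeric matrix (features x samples).
#' @return named positive numeric vector, one factor per sample, with
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  k <- unclass(counts)
  all_pos <- rowSums(k > 0) == ncol(k)
  if (any(all_pos)) {
    logk <- log(k[all_pos, , drop = FALSE])
    loggm <- rowMeans(logk)
    s <- apply(logk - loggm, 2, function(v) exp(stats::median(v)))
  } else {
    message("size_factors: no feature positive in all samples; using positive-subset geometric means")
    pos <- k > 0
    usable <- rowSums(pos) >= 2
    if (!any(usable)) stopf("no usable features for size factors; consider adding a pseudo-count")
    loggm <- vapply(which(usable), function(i) mean(log(k[i, pos[i, ]])), 0)
    s <- vapply(seq_len(ncol(k)), function(j) {
      r <- log(k[usable, j]) - loggm
      r <- r[is.finite(r)]
      if (!length(r)) return(NA_real_)
      exp(stats::median(r))
    }, 0)
    if (anyNA(s)) stopf("some samples share no positive features with the usable set")
  }
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(k))
}

#' Negative-binomial Wald test for differential abundance
#'
#' A two-group Wald test on counts in the DESeq mould: counts are normalized
#' by median-of-ratios size factors, a per-feature NB dispersion is estimated
#' by method of moments on the normalized counts (floored at 1e-8, no
#' shrinkage trend — a deliberate simplification), and the log2 fold change
#' (group B vs A) is tested with `z = log2FC / SE` where the SE comes from the
#' delta method under the NB variance `mu + alpha mu^2`. A pseudo-count of 0.5
#' is added to a group mean only when it is zero (otherwise the fold change
#' would be infinite). P-values are two-sided normal and BH-adjusted.
#'
#' @param counts count `abund_matrix` or matrix (features x samples).
#' @param groups factor/vector of two group labels aligned with samples; the
#'   second level is the numerator (B) of the fold change.
#' @param sf optional size factors; computed from `counts` if omitted.
#' @return data frame of class `differential_result`: `feature`, `baseMean`,
#'   `log2FC`, `SE`, `stat`, `p`, `q`, `pass` (filled by
#'   [filter_differential()], initially `NA`). All-zero features are excluded
#'   and listed in the `excluded` attribute.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL) {
  k <- unclass(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  if (is.null(sf)) sf <- size_factors(k)
  zero <- rowSums(k) == 0
  excluded <- rownames(k)[zero]
  k <- k[!zero, , drop = FALSE]
  norm <- sweep(k, 2, sf, "/")
  a_idx <- groups == levels(groups)[1]
  b_idx <- !a_idx
  n_a <- sum(a_idx); n_b <- sum(b_idx)
  m_a <- rowMeans(norm[, a_idx, drop = FALSE])
  m_b <- rowMeans(norm[, b_idx, drop = FALSE])
  base_mean <- rowMeans(norm)

  # within-group method-of-moments dispersion, pooled across the two groups
  v_a <- apply(norm[, a_idx, drop = FALSE], 1, stats::var)
  v_b <- apply(norm[, b_idx, drop = FALSE], 1, stats::var)
  pooled_var <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  # E[var of normalized counts] ~ mu * mean(1/s) + alpha * mu^2
  mean_inv_sf <- mean(1 / sf)
  mu <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  alpha <- pmax((pooled_var - mu * mean_inv_sf) / mu^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8

  fc_a <- ifelse(m_a == 0 | m_b == 0, m_a + 0.5, m_a)
  fc_b <- ifelse(m_a == 0 | m_b == 0, m_b + 0.5, m_b)
  log2fc <- log2(fc_b / fc_a)

  var_mean <- function(mu_g, idx) {
    # Var of the mean of normalized counts: (1/n^2) sum_j (mu/s_j + alpha mu^2)
    n_g <- sum(idx)
    rowSums(outer(mu_g, 1 / sf[idx])) / n_g^2 + alpha * mu_g^2 / n_g
  }
  se2 <- var_mean(fc_a, a_idx) / (fc_a^2) + var_mean(fc_b, b_idx) / (fc_b^2)
  se_log2 <- sqrt(se2) / log(2)
  z <- log2fc / se_log2
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_adjust(p)
  out <- data.frame(feature = rownames(k), baseMean = base_mean, log2FC = log2fc,
                    SE = se_log2, stat = z, p = p, q = q, pass = NA,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "dispersion") <- alpha
  class(out) <- c("differential_result", class(out))
  out
}

#' Moderated t-test for log-scale functional abundances
#'
#' Empirical-Bayes moderated two-sample t-test: the per-feature sample
#' variance is shrunk toward a prior `s0^2` with `d0` prior degrees of
#' freedom, `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the t
#' statistic is referred to a t distribution with `d0 + d_g` df. The prior is
#' estimated by moment-matching the log sample variances to a scaled
#' log-F distribution (`var(log s^2) = trigamma(d_g/2) + trigamma(d0/2)`),
#' the standard empirical-Bayes device for stabilizing variances when
#' thousands of features share a few dozen samples.
#'
#' @param log_abundance numeric matrix (features x samples) on a log scale.
#' @param groups two-group factor aligned with columns; second level minus
#'   first is the reported effect.
#' @return data frame: `feature`, `logFC`, `t`, `df`, `p`, `q`, plus
#'   attributes `d0` and `s02`.
#' @export
moderated_t_test <- function(log_abundance, groups) {
  x <- unclass(log_abundance)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  a <- groups == levels(groups)[1]
  b <- !a
  n_a <- sum(a); n_b <- sum(b)
  d_g <- n_a + n_b - 2
  m_a <- rowMeans(x[, a, drop = FALSE])
  m_b <- rowMeans(x[, b, drop = FALSE])
  s2 <- ((n_a - 1) * apply(x[, a, drop = FALSE], 1, stats::var) +
           (n_b - 1) * apply(x[, b, drop = FALSE], 1, stats::var)) / d_g
  prior <- fit_variance_prior(s2, d_g)
  d0 <- prior$d0; s02 <- prior$s02
  if (is.finite(d0)) {
    s2_tilde <- (d0 * s02 + d_g * s2) / (d0 + d_g)
    df <- d0 + d_g
  } else {
    s2_tilde <- rep(s02, length(s2))
    df <- Inf
  }
  tstat <- (m_b - m_a) / sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  q <- bh_adjust(p)
  out <- data.frame(feature = rownames(x), logFC = m_b - m_a, t = tstat,
                    df = df, p = p, q = q, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

# Moment-match log sample variances to estimate the inverse-chi-square prior
# (d0, s02). Returns d0 = Inf when the observed spread of log variances is no
# larger than the sampling spread alone.
fit_variance_prior <- function(s2, d_g) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2) return(list(d0 = Inf, s02 = stats::median(s2[ok])))
  ev <- trigamma(d_g / 2)
  excess <- stats::var(z) - ev
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d_g / 2) + log(d_g / 2))
  } else {
    # solve trigamma(d0/2) = excess
    f <- function(d0) trigamma(d0 / 2) - excess
    d0 <- tryCatch(stats::uniroot(f, c(1e-3, 1e6))$root, error = function(e) Inf)
    s02 <- if (is.finite(d0)) {
      exp(mean(z) + digamma(d0 / 2) - digamma(d_g / 2) - log(d0 / d_g))
    } else {
      exp(mean(z) - digamma(d_g / 2) + log(d_g / 2))
    }
  }
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control:
#' `q_i = min over {j : p_j >= p_i} of p_j * m / rank_j`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the differential-abundance effect filter
#'
#' Flags features passing strict thresholds `q < q_max` and
#' `|log2FC| > lfc_min` (both inequalities strict: a feature at exactly the
#' threshold is excluded) and returns the flagged subset.
#'
#' @param res a `differential_result` from [nb_wald_test()].
#' @param q_max adjusted p-value cutoff (exclusive).
#' @param lfc_min absolute log2 fold-change cutoff (exclusive).
#' @return the subset of `res` with `pass = TRUE`; the full table with the
#'   `pass` column filled is available as attribute `full`.
#' @export
filter_differential <- function(res, q_max = 0.05, lfc_min = 2) {
  res$pass <- res$q < q_max & abs(res$log2FC) > lfc_min
  out <- res[res$pass, , drop = FALSE]
  attr(out, "full") <- res
  out
}
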