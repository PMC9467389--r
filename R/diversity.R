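#' Alpha diversity indices per sample
#'
#' Computes richness (features with abundance > 0), Shannon `H = -sum(p log p)`
#' in nats, Simpson `D = 1 - sum(p^2)`, Pielou evenness `J = H / log(S)`
#' (undefined for `S <= 1`), and — when a companion count matrix is supplied —
#' the Chao1 richness estimate `S + F1^2 / (2 F2)` from singleton (`F1`) and
#' doubleton (`F2`) counts, with the `F2 = 0` fallback `S + F1 (F1 - 1) / 2`.
#' Empty samples get `NA` for every index.
#'
#' @param m relative `abund_matrix` (features x samples).
#' @param counts optional integer count `abund_matrix` with the same
#'   dimensions, used only for Chao1 (which needs singletons/doubletons).
#' @return data frame, one row per sample: `sample`, `richness`, `shannon`,
#'   `simpson`, `pielou`, `chao1`.
#' @examples
#' m <- abundance_matrix(matrix(rep(0.25, 4), 4,
#'        dimnames = list(letters[1:4], "s1")), kind = "relative", kingdom = "virus")
#' alpha_diversity(m)
#' @export
alpha_diversity <- function(m, counts = NULL) {
  if (abund_kind(m) != "relative") stopf("alpha_diversity expects a relative matrix")
  res <- lapply(seq_len(ncol(m)), function(j) {
    p <- unclass(m)[, j]
    p <- p[p > 0]
    s <- length(p)
    if (s == 0) {
      return(data.frame(richness = NA_real_, shannon = NA_real_, simpson = NA_real_,
                        pielou = NA_real_, chao1 = NA_real_))
    }
    h <- -sum(p * log(p))
    d <- 1 - sum(p^2)
    j_e <- if (s > 1) h / log(s) else NA_real_
    chao <- NA_real_
    if (!is.null(counts)) {
      k <- unclass(counts)[, j]
      sc <- sum(k > 0)
      f1 <- sum(k == 1)
      f2 <- sum(k == 2)
      chao <- if (f2 > 0) sc + f1^2 / (2 * f2) else sc + f1 * (f1 - 1) / 2
    }
    data.frame(richness = s, shannon = h, simpson = d, pielou = j_e, chao1 = chao)
  })
  cbind(data.frame(sample = colnames(m), stringsAsFactors = FALSE), do.call(rbind, res))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, computed for every sample pair.
#' A pair of all-zero samples is undefined under the formula and is reported
#' as 0 with a warning (identical empty profiles).
#'
#' @param m an `abund_matrix` (any kind; samples in columns).
#' @return symmetric numeric matrix of dissimilarities in `[0, 1]` with zero
#'   diagonal.
#' @export
bray_curtis <- function(m) {
  if (ncol(m) < 2) stopf("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(t(unclass(m)), method = "bray"))
  if (anyNA(d)) {
    warnf("all-zero sample pair(s): Bray-Curtis set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's NMDS (stress-1) with multiple restarts: the first configuration
#' starts from classical metric scaling, subsequent restarts are random, and
#' the lowest-stress solution is returned (vegan's `metaMDS` engine on a
#' precomputed dissimilarity). Deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k embedding dimension.
#' @param n_restarts number of random restarts.
#' @param max_iter maximum iterations per restart.
#' @param seed integer seed.
#' @return list of class `nmds_ordination`: `points` (n x k, centered),
#'   `stress` (Kruskal stress-1, in `[0, 1]`), `converged`, `n_restarts`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, max_iter = 500, seed = 1L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) stopf("NMDS needs at least 3 samples")
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  ))
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = fit$stress, converged = fit$converged > 0,
                 n_restarts = n_restarts),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("<nmds_ordination> %d points, k=%d, stress=%.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Sample-accumulation rarefaction curve
#'
#' For each sample count `s` from 1 to the number of samples, draws `s`
#' samples (with replacement by default, mirroring repeated random sampling of
#' the patient population) `n_perm` times and averages the number of distinct
#' features observed. Deterministic given `seed`.
#'
#' @param m an `abund_matrix`.
#' @param n_perm number of random draws per sample count.
#' @param seed integer seed.
#' @param replace draw samples with replacement (`TRUE`, default) or without.
#' @return data frame with `n_samples` and `mean_features`.
#' @export
rarefaction_curve <- function(m, n_perm = 100, seed = 1L, replace = TRUE) {
  n <- ncol(m)
  present <- unclass(m) > 0
  with_seed(seed, {
    means <- vapply(seq_len(n), function(s) {
      mean(vapply(seq_len(n_perm), function(i) {
        cols <- sample.int(n, s, replace = replace)
        sum(rowSums(present[, cols, drop = FALSE]) > 0)
      }, 0))
    }, 0)
    data.frame(n_samples = seq_len(n), mean_features = means)
  })
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with average ranks for ties; exact p by enumeration when the
#' combined sample size is at most 12 and there are no ties, otherwise the
#' normal approximation with tie and continuity correction. Two completely
#' identical groups give `p = 1`.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = !ties && (length(x) + length(y)) <= 12, correct = TRUE
  ))
  list(statistic = unname(wt$statistic), p.value = min(wt$p.value, 1))
}

#' Confounder-adjusted group association of a diversity index
#'
#' Ordinary least squares of a per-sample index on the AF-group indicator plus
#' clinical covariates, reporting Wald t-tests per term. The design matrix is
#' checked for rank deficiency and the offending columns are named.
#'
#' @param index numeric per-sample values, aligned with `metadata` rows.
#' @param metadata data frame of covariates.
#' @param group_col name of the group column in `metadata` (first term).
#' @param covariates character vector of covariate column names.
#' @return data frame with `term`, `estimate`, `se`, `t`, `p`.
#' @export
adjust_confounders <- function(index, metadata, group_col = "af",
                               covariates = c("age", "sex_female", "bmi", "htn",
                                              "t2dm", "tc", "medication")) {
  covariates <- intersect(covariates, colnames(metadata))
  terms <- c(group_col, covariates)
  df <- metadata[, terms, drop = FALSE]
  keep <- vapply(df, function(v) length(unique(v)) > 1, TRUE)
  df <- df[, keep, drop = FALSE]
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm(index ~ ., data = cbind(index = index, df))
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE)
}
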