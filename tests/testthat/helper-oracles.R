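# Independent brute-force oracles used to validate the package's statistics.
# Each is written from the defining formula, not by calling the code under
# test (nor the same library routine it wraps).

# Average ranks computed by sorting, without rank().
avg_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman correlation as the Pearson product-moment formula on average ranks.
spearman_oracle <- function(x, y) {
  rx <- avg_ranks(x); ry <- avg_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# BH step-up from the definition: q_i = min over {j: p_j >= p_i} of p_j*m/rank_j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_in_order <- integer(m)
  rank_in_order[ord] <- seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- which(p >= p[i] - 1e-15)
    q[i] <- min(pmin(p[cand] * m / rank_in_order[cand], 1))
  }
  q
}

# Natural connectivity via the matrix exponential trace: ln(tr(expm(A))/N).
nc_expm_oracle <- function(adj) {
  e <- Matrix::expm(Matrix::Matrix(adj, sparse = FALSE))
  log(sum(Matrix::diag(e)) / nrow(adj))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every group assignment.
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- avg_ranks(v)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Efron-tie Cox partial log-likelihood for a single covariate.
cox_pll_efron <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t0 & event == 1)
    r_idx <- which(time >= t0)
    d <- length(d_idx)
    sum_r <- sum(exp(eta[r_idx]))
    sum_d <- sum(exp(eta[d_idx]))
    ll <- ll + sum(eta[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5, tol = 1e-4) {
  stats::optimize(function(b) -cox_pll_efron(b, time, event, x),
                  c(lo, hi), tol = tol)$minimum
}

# Random simple undirected graph as a 0/1 adjacency matrix.
random_adjacency <- function(n, p_edge = 0.3) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  on <- up[stats::runif(length(up)) < p_edge]
  a[on] <- 1
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

# Wrap an adjacency matrix as a cooccurrence_network (all nodes one kingdom
# unless kingdoms are supplied).
net_from_adjacency <- function(adj, kingdoms = NULL) {
  ids <- rownames(adj)
  if (is.null(kingdoms)) kingdoms <- rep("virus", nrow(adj))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                      rho = rep(0.9, nrow(idx)), q = rep(0.001, nrow(idx)),
                      sign = rep("positive", nrow(idx)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = ids, kingdom = kingdoms,
                      mean_abundance = 1 / nrow(adj), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_network")
}

# Tiny contig table used across abundance tests.
make_contig_table <- function() {
  data.frame(contig_id = c("c1", "c2", "c3", "c4"),
             length = c(2000, 1000, 4000, 1500),
             virus = c("vA", "vA", "vB", NA),
             s1 = c(1000, 50, 200, 10),
             s2 = c(0, 25, 400, 0),
             stringsAsFactors = FALSE)
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(n_control = 15, n_paf = 9, n_psaf_short = 4,
                                n_psaf_long = 2, n_viruses = 60, n_bacteria = 60,
                                n_ablated = 12, seed = seed, ...))
}
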