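rel2 <- function(vals, ids, samples, kingdom = "virus") {
  m <- matrix(vals, length(ids), length(samples), dimnames = list(ids, samples))
  m <- sweep(m, 2, colSums(m), "/")
  abundance_matrix(m, kind = "relative", kingdom = kingdom)
}

test_that("top-taxa selection sorts by mean abundance with lexicographic ties", {
  v <- rel2(c(0.5, 0.3, 0.2), c("A", "B", "C"), c("s1", "s2"))
  b <- rel2(c(0.4, 0.4, 0.2), c("zB", "aB", "mB"), c("s1", "s2"), "bacteria")
  suppressWarnings(top <- select_top_taxa(v, b, k = 2))
  expect_identical(top$taxon[top$kingdom == "virus"], c("A", "B"))
  # exact tie at rank k: lexicographically smaller id kept
  expect_identical(top$taxon[top$kingdom == "bacteria"], c("aB", "zB"))
  suppressWarnings(all3 <- select_top_taxa(v, b, k = 10))
  expect_equal(nrow(all3), 6)
})

test_that("Spearman matrix matches the brute-force rank-correlation oracle", {
  set.seed(11)
  x <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  sm <- spearman_matrix(x)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(sm$rho[i, j], spearman_oracle(x[i, ], x[j, ]), tolerance = 1e-12)
  }
  # strictly monotone pair
  y <- rbind(a = 1:10, b = (1:10)^3, c = rnorm(10))
  colnames(y) <- paste0("s", 1:10)
  expect_equal(spearman_matrix(y)$rho["a", "b"], 1)
  # constant feature excluded
  z <- rbind(a = rep(1, 6), b = rnorm(6), c = rnorm(6))
  colnames(z) <- paste0("s", 1:6)
  expect_warning(smz <- spearman_matrix(z), "constant")
  expect_true(all(is.na(smz$rho["a", c("b", "c")])))
  expect_error(spearman_matrix(x[, 1:3]), "at least 4")
})

test_that("null Spearman p-values are calibrated", {
  set.seed(12)
  x <- matrix(rnorm(46 * 50), 46, 50,
              dimnames = list(paste0("f", 1:46), paste0("s", 1:50)))
  sm <- spearman_matrix(x)  # 1035 pairs
  frac <- mean(sm$p[upper.tri(sm$p)] < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("network edges respect both cutoffs and isolated nodes drop", {
  ids <- c("v1", "v2", "b1")
  rho <- matrix(c(1, 0.69, -0.8, 0.69, 1, 0.2, -0.8, 0.2, 1), 3, 3,
                dimnames = list(ids, ids))
  q <- matrix(c(NA, 0.001, 1e-4, 0.001, NA, 0.5, 1e-4, 0.5, NA), 3, 3,
              dimnames = list(ids, ids))
  meta <- data.frame(taxon = ids, kingdom = c("virus", "virus", "bacteria"),
                     mean_abundance = c(0.2, 0.1, 0.3))
  net <- build_network(list(rho = rho, q = q), meta)
  expect_equal(nrow(net$edges), 1)                    # only v1-b1 passes
  expect_identical(net$edges$sign, "negative")
  expect_identical(sort(net$nodes$taxon), c("b1", "v1"))  # v2 isolated, dropped
  # |rho| = rho_min passes (inclusive), q = q_max does not (exclusive)
  net2 <- build_network(list(rho = rho, q = q), meta, rho_min = 0.69, q_max = 0.001)
  expect_equal(nrow(net2$edges), 1)
  # empty result allowed
  net3 <- build_network(list(rho = rho, q = q), meta, rho_min = 0.99)
  expect_equal(nrow(net3$edges), 0)
  expect_equal(nrow(net3$nodes), 0)
})

test_that("network metrics match hand-computed worked examples", {
  # triangle K3: eigenvalues {2, -1, -1}
  a3 <- matrix(1, 3, 3) - diag(3)
  dimnames(a3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  net <- net_from_adjacency(a3)
  met <- network_metrics(net)
  expect_equal(met$natural_connectivity, log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(met$degree_entropy, 0)
  expect_equal(met$density, 1)
  expect_equal(met$n_linkages, 0)
  # linkage counting on a mixed-kingdom path v - b - v
  a_path <- matrix(0, 3, 3, dimnames = list(c("v1", "b1", "v2"), c("v1", "b1", "v2")))
  a_path["v1", "b1"] <- a_path["b1", "v1"] <- 1
  a_path["b1", "v2"] <- a_path["v2", "b1"] <- 1
  netp <- net_from_adjacency(a_path, kingdoms = c("virus", "bacteria", "virus"))
  metp <- network_metrics(netp)
  expect_equal(metp$n_linkages, 2)
  expect_equal(unname(metp$betweenness["b1"]), 1)
  expect_gt(metp$degree_entropy, 0)
})

test_that("density and natural connectivity agree with independent oracles", {
  skip_if_not_installed("Matrix")
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    adj <- random_adjacency(n)
    net <- net_from_adjacency(adj)
    met <- network_metrics(net)
    expect_equal(met$density, 2 * met$n_edges / (met$n_nodes * (met$n_nodes - 1)),
                 tolerance = 1e-12)
    expect_equal(met$natural_connectivity, nc_expm_oracle(adj), tolerance = 1e-9)
    expect_gte(met$natural_connectivity, 0)
    expect_lte(met$degree_entropy, log(length(unique(met$degrees))) + 1e-12)
  }
})

test_that("robustness curve starts at the intact value and decays on K10", {
  a <- matrix(1, 10, 10) - diag(10)
  dimnames(a) <- list(paste0("n", 1:10), paste0("n", 1:10))
  net <- net_from_adjacency(a)
  rc <- robustness_curve(net, fractions = seq(0, 0.5, 0.1), n_reps = 30, seed = 2)
  expect_equal(rc$mean_nc[rc$fraction == 0], natural_connectivity(a))
  expect_true(all(diff(rc$mean_nc) < 1e-9))
  expect_error(robustness_curve(net, fractions = c(0, 1)), "fractions")
  # empty graph: natural connectivity 0 at every fraction
  a0 <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  net0 <- net_from_adjacency(a0)
  rc0 <- robustness_curve(net0, fractions = c(0, 0.2, 0.4), n_reps = 5, seed = 1)
  expect_true(all(rc0$mean_nc == 0))
  # determinism
  rc2 <- robustness_curve(net, fractions = seq(0, 0.5, 0.1), n_reps = 30, seed = 2)
  expect_identical(rc, rc2)
})

test_that("trans-kingdom diversity correlations detect coupling per group", {
  set.seed(15)
  n <- 30
  samples <- paste0("s", 1:(2 * n))
  grp <- stats::setNames(rep(c("CTR", "AF"), each = n), samples)
  sh <- rnorm(2 * n)
  av <- data.frame(sample = samples, richness = rpois(2 * n, 50), shannon = sh,
                   simpson = runif(2 * n), pielou = runif(2 * n))
  # bacterial shannon copies viral shannon in CTR, independent in AF
  bsh <- c(sh[1:n], rnorm(n))
  ab <- data.frame(sample = samples, richness = rpois(2 * n, 50), shannon = bsh,
                   simpson = runif(2 * n), pielou = runif(2 * n))
  tk <- transkingdom_diversity_correlation(av, ab, grp)
  ctr_rho <- tk$rho[tk$group == "CTR" & tk$virus_index == "shannon" & tk$bact_index == "shannon"]
  af_rho <- tk$rho[tk$group == "AF" & tk$virus_index == "shannon" & tk$bact_index == "shannon"]
  expect_equal(ctr_rho, 1)
  expect_gt(ctr_rho, af_rho)
  expect_warning(transkingdom_diversity_correlation(av[1:3, ], ab[1:3, ], grp[1:3]),
                 "fewer than 4")
})

test_that("network export round-trips and writes header-only files when empty", {
  adj <- random_adjacency(6, 0.5)
  net <- net_from_adjacency(adj, kingdoms = rep(c("virus", "bacteria"), 3))
  dir <- withr::local_tempdir()
  paths <- export_network(net, file.path(dir, "toy"))
  expect_true(all(file.exists(paths)))
  back <- import_network(file.path(dir, "toy"))
  expect_identical(back$nodes$taxon, net$nodes$taxon)
  expect_equal(back$edges[order(back$edges$source, back$edges$target), c("source", "target")],
               net$edges[order(net$edges$source, net$edges$target), c("source", "target")],
               ignore_attr = TRUE)
  # empty network
  a0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  net0 <- net_from_adjacency(a0)
  p0 <- export_network(net0, file.path(dir, "empty"))
  expect_equal(length(readLines(p0["edges"])), 1)  # header only
  back0 <- import_network(file.path(dir, "empty"))
  expect_equal(nrow(back0$edges), 0)
})
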