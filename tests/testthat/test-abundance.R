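test_that("contig length filter is strictly greater-than", {
  tab <- data.frame(contig_id = c("a", "b", "c"), length = c(999, 1000, 1001),
                    virus = NA, s1 = c(1, 1, 1))
  out <- filter_contigs(tab, min_len = 1000)
  expect_identical(out$contig_id, "c")
  expect_identical(filter_contigs(tab, min_len = 0), tab)
  empty <- tab[0, ]
  expect_equal(nrow(filter_contigs(empty)), 0)
})

test_that("RPKM follows reads / (kb * millions) and is scale invariant", {
  tab <- data.frame(contig_id = "c1", length = 2000, virus = "v", s1 = 1000)
  r <- compute_rpkm(tab, c(s1 = 1e7))
  expect_equal(unname(unclass(r)["c1", "s1"]), 50.0)
  # zero reads -> 0
  tab0 <- data.frame(contig_id = "c1", length = 2000, virus = "v", s1 = 0)
  expect_equal(unname(unclass(compute_rpkm(tab0, c(s1 = 1e7)))[1, 1]), 0)
  # doubling reads and total leaves RPKM unchanged
  tab2 <- tab; tab2$s1 <- tab$s1 * 2
  r2 <- compute_rpkm(tab2, c(s1 = 2e7))
  expect_equal(unclass(r2)[1, 1], unclass(r)[1, 1])
  # zero total with nonzero reads is an error
  expect_error(compute_rpkm(tab, c(s1 = 0)), "zero mapped-read total")
})

test_that("virus abundance is the mean RPKM over assigned contigs", {
  tab <- make_contig_table()
  rpkm <- compute_rpkm(tab, c(s1 = 1e7, s2 = 1e7))
  # hand RPKM: c1 = 1000/(2*10) = 50; c2 = 50/(1*10) = 5 in s1
  va <- suppressMessages(virus_abundance(rpkm, tab[, c("contig_id", "virus")]))
  expect_equal(unname(unclass(va)["vA", "s1"]), (50 + 5) / 2)
  # single-contig virus is identity
  expect_equal(unname(unclass(va)["vB", "s1"]), unname(unclass(rpkm)["c3", "s1"]))
  # absent in a sample -> 0
  expect_equal(unname(unclass(va)["vA", "s2"]) > 0, TRUE)
  tabz <- tab; tabz$s2 <- 0
  vaz <- suppressMessages(virus_abundance(compute_rpkm(tabz, c(s1 = 1e7, s2 = 1e7)),
                                          tabz[, c("contig_id", "virus")]))
  expect_equal(unname(unclass(vaz)["vA", "s2"]), 0)
  # mean of explicit RPKM values {10, 30} -> 20
  m <- abundance_matrix(matrix(c(10, 30), 2, 1, dimnames = list(c("x", "y"), "s")),
                        kind = "rpkm", kingdom = "virus", level = "contig")
  expect_equal(unname(unclass(virus_abundance(m, c(x = "v", y = "v")))["v", "s"]), 20)
})

test_that("relative normalization divides by column totals", {
  m <- abundance_matrix(matrix(c(2, 2, 4), 3, 1, dimnames = list(letters[1:3], "s1")),
                        kind = "counts", kingdom = "virus")
  r <- to_relative(m)
  expect_equal(unname(unclass(r)[, 1]), c(0.25, 0.25, 0.5))
  expect_identical(abund_kind(r), "relative")
  expect_equal(unclass(to_relative(r)), unclass(r))  # idempotent
  mz <- abundance_matrix(matrix(c(1, 1, 0, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         kind = "counts", kingdom = "virus")
  expect_warning(rz <- to_relative(mz), "all-zero")
  expect_equal(unname(colSums(unclass(rz))), c(1, 0))
})

test_that("taxonomic aggregation sums abundances and conserves totals", {
  tax <- data.frame(species = c("s1", "s2", "s3"), genus = c("g1", "g1", "g2"),
                    family = c("f1", "f1", NA), order = "o1",
                    stringsAsFactors = FALSE)
  m <- abundance_matrix(matrix(c(0.1, 0.2, 0.7), 3, 1,
                               dimnames = list(c("s1", "s2", "s3"), "A")),
                        kind = "relative", kingdom = "virus")
  g <- aggregate_taxonomy(m, tax, "genus")
  expect_equal(unname(unclass(g)["g1", "A"]), 0.3)
  expect_identical(aggregate_taxonomy(m, tax, "species"), m)
  f <- aggregate_taxonomy(m, tax, "family")
  expect_true("unclassified" %in% rownames(f))
  expect_equal(unname(colSums(unclass(f))), unname(colSums(unclass(m))))
  expect_error(aggregate_taxonomy(m, tax, "phylum"))
})

test_that("host-class summary gives fractions of distinct taxa that sum to 1", {
  # 13 orders, 7 vertebrate, 2 phage, 4 other
  tax <- data.frame(species = paste0("sp", 1:13), order = paste0("o", 1:13),
                    host_class = c(rep("vertebrate", 7), rep("phage", 2), rep("other", 4)),
                    stringsAsFactors = FALSE)
  hc <- host_class_summary(tax, level = "order")
  expect_equal(round(100 * unname(hc["vertebrate"]), 2), 53.85)
  expect_equal(round(100 * unname(hc["phage"]), 2), 15.38)
  expect_equal(sum(hc), 1)
  tax$host_class <- "phage"
  expect_equal(unname(host_class_summary(tax, "order")["phage"]), 1)
})

test_that("lysogenic proportion is temperate share of phage abundance", {
  tax <- data.frame(species = c("t", "l", "v"), host_class = c("phage", "phage", "vertebrate"),
                    lifestyle = c("temperate", "lytic", "unknown"), stringsAsFactors = FALSE)
  m <- abundance_matrix(matrix(c(0.3, 0.1, 0.6), 3, 1,
                               dimnames = list(c("t", "l", "v"), "s1")),
                        kind = "relative", kingdom = "virus")
  expect_equal(unname(lysogenic_proportion(m, tax)), 0.75)
  expect_equal(unname(lysogenic_proportion(m, tax, denominator = "virome")), 0.3)
  # all phages temperate -> 1; no phage abundance -> NA
  tax2 <- tax; tax2$lifestyle <- c("temperate", "temperate", "unknown")
  expect_equal(unname(lysogenic_proportion(m, tax2)), 1)
  m0 <- abundance_matrix(matrix(c(0, 0, 1), 3, 1, dimnames = list(c("t", "l", "v"), "s1")),
                         kind = "relative", kingdom = "virus")
  expect_true(is.na(lysogenic_proportion(m0, tax)))
  # marker flags take precedence: any-of-three evidence calls temperate
  tax3 <- data.frame(species = c("t", "l"), host_class = "phage",
                     marker_1 = c(FALSE, FALSE), marker_2 = c(TRUE, FALSE),
                     marker_3 = c(FALSE, FALSE), stringsAsFactors = FALSE)
  m3 <- abundance_matrix(matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("t", "l"), "s1")),
                         kind = "relative", kingdom = "virus")
  expect_equal(unname(lysogenic_proportion(m3, tax3)), 0.5)
})

test_that("abundance matrix validates kind and values", {
  v <- matrix(c(0.5, 0.6), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(abundance_matrix(v, kind = "relative", kingdom = "virus"), "sum to 1")
  v2 <- matrix(c(-1, 2), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(abundance_matrix(v2, kind = "counts", kingdom = "virus"), "non-negative")
  v3 <- matrix(1, 1, 1)
  expect_error(abundance_matrix(v3, kind = "counts", kingdom = "virus"), "names")
})
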