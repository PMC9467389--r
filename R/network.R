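#' Select the most abundant taxa per kingdom
#'
#' Takes the top `k` viral and top `k` bacterial species by mean relative
#' abundance across the supplied samples (ties at the boundary broken by
#' lexicographic taxon id). If a kingdom has fewer than `k` features, all are
#' taken with a warning.
#'
#' @param virus_rel,bact_rel relative `abund_matrix` objects sharing samples.
#' @param k number of taxa per kingdom.
#' @return data frame: `taxon`, `kingdom`, `mean_abundance`.
#' @export
select_top_taxa <- function(virus_rel, bact_rel, k = 100) {
  if (!identical(colnames(virus_rel), colnames(bact_rel))) {
    stopf("virus and bacteria matrices must share the sample axis")
  }
  pick <- function(m, kingdom) {
    mu <- rowMeans(unclass(m))
    if (nrow(m) < k) warnf("%s: only %d features available (k = %d)", kingdom, nrow(m), k)
    ord <- order(-mu, rownames(m))
    sel <- ord[seq_len(min(k, nrow(m)))]
    data.frame(taxon = rownames(m)[sel], kingdom = kingdom,
               mean_abundance = mu[sel], row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(pick(virus_rel, "virus"), pick(bact_rel, "bacteria"))
}

#' Pairwise Spearman correlation with BH-adjusted significance
#'
#' Average-rank Spearman correlation between all feature pairs, p-values from
#' the t approximation with `n - 2` degrees of freedom, and BH adjustment over
#' the whole family of tested pairs (intra- and inter-kingdom together).
#' Constant features have no defined rank correlation; their pairs are set to
#' `NA` and the features are listed in the `constant` attribute.
#'
#' @param mat numeric matrix, features x samples (at least 4 samples).
#' @return list with symmetric matrices `rho`, `p`, `q`.
#' @export
spearman_matrix <- function(mat) {
  x <- unclass(mat)
  n <- ncol(x)
  if (n < 4) stopf("need at least 4 samples")
  const <- apply(x, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho) <- 1
  r <- rho
  sat <- which(!is.na(r) & abs(r) >= 1)
  r[sat] <- sign(r[sat]) * (1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  ut <- upper.tri(p)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  pv <- p[ut]
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- bh_adjust(pv[ok])
  q[ut] <- qv
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  if (any(const)) {
    warnf("%d constant feature(s) excluded from correlation", sum(const))
  }
  list(rho = rho, p = p, q = q, constant = rownames(x)[const])
}

#' Build a co-occurrence network from thresholded correlations
#'
#' Keeps undirected edges with `|rho| >= rho_min` and `q < q_max`. Nodes left
#' without any edge are dropped, so the node count reflects connected taxa
#' only (set `drop_isolated = FALSE` to keep them).
#'
#' @param cors list with matrices `rho` and `q` (from [spearman_matrix()]).
#' @param node_meta data frame with `taxon`, `kingdom`, `mean_abundance`
#'   (e.g. from [select_top_taxa()]) covering the correlation matrix rows.
#' @param rho_min minimum absolute Spearman correlation (inclusive).
#' @param q_max maximum BH-adjusted p-value (exclusive).
#' @param drop_isolated drop nodes with no qualifying edge.
#' @return object of class `cooccurrence_network`: list with data frames
#'   `nodes` (`taxon`, `kingdom`, `mean_abundance`) and `edges`
#'   (`source`, `target`, `rho`, `q`, `sign`).
#' @export
build_network <- function(cors, node_meta, rho_min = 0.7, q_max = 0.05,
                          drop_isolated = TRUE) {
  rho <- cors$rho
  q <- cors$q
  ids <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  keep <- !is.na(rho[ut]) & !is.na(q[ut]) & abs(rho[ut]) >= rho_min & q[ut] < q_max
  sel <- ut[keep, , drop = FALSE]
  edges <- data.frame(source = ids[sel[, 1]], target = ids[sel[, 2]],
                      rho = rho[sel], q = q[sel],
                      sign = ifelse(rho[sel] >= 0, "positive", "negative"),
                      row.names = NULL, stringsAsFactors = FALSE)
  nodes <- node_meta[match(ids, node_meta$taxon), , drop = FALSE]
  nodes <- nodes[!is.na(nodes$taxon), , drop = FALSE]
  if (drop_isolated) {
    connected <- unique(c(edges$source, edges$target))
    nodes <- nodes[nodes$taxon %in% connected, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  nl <- n_linkages(x)
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (%d virus-bacteria linkages)\n",
              nrow(x$nodes), nrow(x$edges), nl))
  invisible(x)
}

n_linkages <- function(net) {
  kd <- stats::setNames(net$nodes$kingdom, net$nodes$taxon)
  if (!nrow(net$edges)) return(0L)
  sum(kd[net$edges$source] != kd[net$edges$target], na.rm = TRUE)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                directed = FALSE, vertices = net$nodes$taxon)
}

#' Natural connectivity of a graph
#'
#' The spectral robustness measure `ln((1/N) * sum_i exp(lambda_i))` over the
#' adjacency eigenvalues, computed on the whole graph with the 1/N
#' normalization. Always `>= 0` (by Jensen's inequality the average of
#' `exp(lambda_i)` is at least `exp(mean lambda) = 1`), and 0 for an empty
#' graph.
#'
#' @param adj symmetric 0/1 adjacency matrix (or a `cooccurrence_network`).
#' @return scalar natural connectivity in nats.
#' @export
natural_connectivity <- function(adj) {
  if (inherits(adj, "cooccurrence_network")) {
    adj <- adjacency_of(adj)
  }
  n <- nrow(adj)
  if (n == 0) return(NA_real_)
  ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmax + log(mean(exp(ev - lmax)))
}

adjacency_of <- function(net) {
  n <- nrow(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes$taxon, net$nodes$taxon))
  if (nrow(net$edges)) {
    i <- match(net$edges$source, net$nodes$taxon)
    j <- match(net$edges$target, net$nodes$taxon)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

#' Shannon entropy of the node-degree distribution
#'
#' Plug-in Shannon entropy (nats) of the empirical distribution of node
#' degrees: 0 when all nodes share one degree, at most `log` of the number of
#' distinct degree values.
#'
#' @param degrees integer vector of node degrees (or a `cooccurrence_network`).
#' @return scalar entropy in nats.
#' @export
degree_entropy <- function(degrees) {
  if (inherits(degrees, "cooccurrence_network")) {
    degrees <- igraph::degree(as_igraph(degrees))
  }
  if (!length(degrees)) return(NA_real_)
  p <- as.numeric(table(degrees)) / length(degrees)
  -sum(p * log(p)) + 0   # + 0 normalizes IEEE negative zero
}

#' Structural metrics of a co-occurrence network
#'
#' Node/edge counts, the number of virus-bacteria linkages (edges whose
#' endpoints differ in kingdom), density `2 E / (N (N - 1))`, the degree
#' sequence, shortest-path betweenness per node, natural connectivity and
#' degree entropy.
#'
#' @param net a `cooccurrence_network`.
#' @return list of class `network_metrics` with fields `n_nodes`, `n_edges`,
#'   `n_linkages`, `density`, `degrees`, `betweenness`,
#'   `natural_connectivity`, `degree_entropy`.
#' @export
network_metrics <- function(net) {
  g <- as_igraph(net)
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  structure(list(
    n_nodes = n,
    n_edges = e,
    n_linkages = n_linkages(net),
    density = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
    degrees = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE),
    natural_connectivity = natural_connectivity(adjacency_of(net)),
    degree_entropy = degree_entropy(igraph::degree(g))
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("<network_metrics> %d nodes, %d edges, %d linkages\n",
                     "  density %.4f | natural connectivity %.4f | degree entropy %.4f\n"),
              x$n_nodes, x$n_edges, x$n_linkages, x$density,
              x$natural_connectivity, x$degree_entropy))
  invisible(x)
}

#' Random-removal robustness curve
#'
#' For each removal fraction, deletes that share of nodes uniformly at random
#' (without replacement), recomputes natural connectivity on the induced
#' subgraph, and averages over repetitions. The fraction-0 point is the intact
#' network's natural connectivity. Deterministic given `seed`.
#'
#' @param net a `cooccurrence_network` with at least 4 nodes.
#' @param fractions removal fractions in `[0, 1)`.
#' @param n_reps Monte-Carlo repetitions per fraction.
#' @param seed integer seed.
#' @return data frame: `fraction`, `mean_nc`, `sd_nc`, `n_reps`.
#' @export
robustness_curve <- function(net, fractions = seq(0, 0.5, by = 0.05),
                             n_reps = 100, seed = 1L) {
  if (nrow(net$nodes) < 4) stopf("need at least 4 nodes")
  if (any(fractions >= 1) || any(fractions < 0)) stopf("fractions must lie in [0, 1)")
  adj <- adjacency_of(net)
  n <- nrow(adj)
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      n_rm <- round(f * n)
      if (n_rm == 0) {
        nc <- natural_connectivity(adj)
        return(data.frame(fraction = f, mean_nc = nc, sd_nc = 0, n_reps = n_reps))
      }
      vals <- vapply(seq_len(n_reps), function(i) {
        keep <- sample.int(n, n - n_rm)
        natural_connectivity(adj[keep, keep, drop = FALSE])
      }, 0)
      data.frame(fraction = f, mean_nc = mean(vals), sd_nc = stats::sd(vals),
                 n_reps = n_reps)
    })
    do.call(rbind, rows)
  })
}

#' Trans-kingdom alpha-diversity correlations
#'
#' Spearman correlation between every pair of viral and bacterial alpha
#' diversity indices, within each sample group, with BH adjustment over the
#' whole table. Groups with fewer than 4 samples are skipped with a warning.
#'
#' @param alpha_virus,alpha_bact data frames from [alpha_diversity()] sharing
#'   the `sample` column.
#' @param groups named vector (or factor) of group labels per sample.
#' @param indices which index columns to correlate.
#' @return data frame: `group`, `virus_index`, `bact_index`, `rho`, `p`, `q`.
#' @export
transkingdom_diversity_correlation <- function(alpha_virus, alpha_bact, groups,
                                               indices = c("richness", "shannon",
                                                           "simpson", "pielou")) {
  common <- intersect(alpha_virus$sample, alpha_bact$sample)
  av <- alpha_virus[match(common, alpha_virus$sample), , drop = FALSE]
  ab <- alpha_bact[match(common, alpha_bact$sample), , drop = FALSE]
  grp <- groups[common]
  rows <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 4) {
      warnf("group '%s' has fewer than 4 samples; skipped", g)
      next
    }
    for (vi in indices) for (bi in indices) {
      ct <- suppressWarnings(stats::cor.test(av[[vi]][idx], ab[[bi]][idx],
                                             method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, virus_index = vi, bact_index = bi,
        rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p <- pmin(out$p, 1)          # cap the two-sided t approximation
    out$q <- NA_real_
    ok <- !is.na(out$p)
    out$q[ok] <- bh_adjust(out$p[ok])
  }
  out
}

#' Export a network for external graph viewers
#'
#' Writes a tab-separated edge list (`source`, `target`, `rho`, `q`, `sign`),
#' a node attribute table (`taxon`, `kingdom`, `mean_abundance`) and a GraphML
#' file loadable by Cytoscape and friends.
#'
#' @param net a `cooccurrence_network`.
#' @param prefix output path prefix; files `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv`, `<prefix>.graphml` are written.
#' @return invisibly, the vector of paths written.
#' @export
export_network <- function(net, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"),
             graphml = paste0(prefix, ".graphml"))
  utils::write.table(net$edges, paths["edges"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, paths["nodes"], sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Re-import an exported network
#'
#' Reads the `_edges.tsv` / `_nodes.tsv` pair written by [export_network()]
#' back into a `cooccurrence_network`, for round-trip checks and reuse.
#'
#' @param prefix the path prefix passed to [export_network()].
#' @return a `cooccurrence_network`.
#' @export
import_network <- function(prefix) {
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"), stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"), stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(source = character(), target = character(), rho = numeric(),
                        q = numeric(), sign = character(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_network")
}
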