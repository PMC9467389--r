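#' Analysis configuration
#'
#' Bundles the thresholds, seeds and sizes used by [run_pipeline()]. Defaults
#' are the study's printed constants: correlation cutoff 0.7 with adjusted
#' p < 0.05 for network edges, q < 0.05 with |log2FC| > 2 for differential
#' taxa, top 100 taxa per kingdom, contigs > 1,000 bp.
#'
#' @param rho_min,q_max co-occurrence edge cutoffs.
#' @param diff_q,lfc_min differential-abundance cutoffs.
#' @param top_k taxa per kingdom entering the network.
#' @param min_contig_len contig length filter (bp, exclusive).
#' @param horizon risk-model ROC horizon in months.
#' @param k_folds cross-validation folds for the penalized Cox fit.
#' @param n_boot bootstrap resamples for internal validation (0 = skip).
#' @param robustness_reps Monte-Carlo repetitions per removal fraction.
#' @param nmds_restarts NMDS random restarts.
#' @param seed root seed; all stage seeds are derived from it.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(rho_min = 0.7, q_max = 0.05, diff_q = 0.05, lfc_min = 2,
                            top_k = 100, min_contig_len = 1000, horizon = 12,
                            k_folds = 10, n_boot = 0, robustness_reps = 100,
                            nmds_restarts = 20, seed = 1L) {
  stopifnot(rho_min > 0, q_max > 0, diff_q > 0, lfc_min > 0, top_k >= 1,
            min_contig_len >= 0, horizon > 0, k_folds >= 2)
  structure(list(rho_min = rho_min, q_max = q_max, diff_q = diff_q,
                 lfc_min = lfc_min, top_k = top_k, min_contig_len = min_contig_len,
                 horizon = horizon, k_folds = k_folds, n_boot = n_boot,
                 robustness_reps = robustness_reps, nmds_restarts = nmds_restarts,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full virome analysis pipeline
#'
#' Executes abundance normalization, diversity (alpha, NMDS on Bray-Curtis,
#' per-axis Wilcoxon, confounder-adjusted regression), differential abundance
#' at species/genus/family, per-group co-occurrence networks with metrics and
#' robustness curves, and — when survival follow-up is present — the viral
#' recurrence risk model on the ablated subset. Every output is written as
#' TSV under `outdir`, and a manifest recording the configuration, seeds and
#' the MD5 checksum of every file is written last; two runs with identical
#' inputs, config and seed produce byte-identical manifests.
#'
#' @param input a `synthetic_cohort`, or a directory containing
#'   `virus_counts.tsv`, `bacteria_counts.tsv`, `taxonomy.tsv`,
#'   `metadata.tsv` (as written by [write_cohort()]).
#' @param outdir output directory (created).
#' @param config an [analysis_config()].
#' @return invisibly, the path of the manifest file.
#' @export
run_pipeline <- function(input, outdir, config = analysis_config()) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input)) {
    paths <- file.path(input, c("virus_counts.tsv", "bacteria_counts.tsv",
                                "taxonomy.tsv", "metadata.tsv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stopf("pre-flight: missing input file(s): %s",
                               paste(missing, collapse = ", "))
    virus_counts <- read_abundance(paths[1], kind = "counts", kingdom = "virus")
    bacteria_counts <- read_abundance(paths[2], kind = "counts", kingdom = "bacteria")
    taxonomy <- read_taxonomy(paths[3])
    metadata <- read_metadata(paths[4])
    survival_df <- if (all(c("time_months", "event") %in% colnames(metadata))) {
      sv <- metadata[!is.na(metadata$time_months) & !is.na(metadata$event),
                     c("sample", "time_months", "event")]
      if (nrow(sv)) sv else NULL
    } else NULL
  } else if (inherits(input, "synthetic_cohort")) {
    virus_counts <- input$virus_counts
    bacteria_counts <- input$bacteria_counts
    taxonomy <- input$taxonomy
    metadata <- input$metadata
    survival_df <- input$survival
  } else {
    stopf("input must be a synthetic_cohort or a directory path")
  }
  stage <- function(name, expr) {
    t1 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    message(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t1, units = "secs")))
    res
  }
  out <- function(...) file.path(outdir, ...)
  written <- character()
  emit <- function(df, file) {
    utils::write.table(df, out(file), sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, file)
  }

  groups <- stats::setNames(metadata$group, metadata$sample)
  af <- stats::setNames(metadata$group != "CTR", metadata$sample)

  ## abundance -------------------------------------------------------------
  rels <- stage("abundance", {
    rel_v <- to_relative(virus_counts)
    rel_b <- to_relative(bacteria_counts)
    write_abundance(rel_v, out("virus_relative.tsv")); written <<- c(written, "virus_relative.tsv")
    write_abundance(rel_b, out("bacteria_relative.tsv")); written <<- c(written, "bacteria_relative.tsv")
    hc <- host_class_summary(taxonomy, level = "order")
    emit(data.frame(host_class = names(hc), proportion = hc), "host_class_summary.tsv")
    lys <- lysogenic_proportion(rel_v, taxonomy)
    emit(data.frame(sample = names(lys), lysogenic_proportion = lys), "lysogenic_proportion.tsv")
    list(v = rel_v, b = rel_b)
  })

  ## diversity -------------------------------------------------------------
  alpha <- stage("diversity", {
    av <- alpha_diversity(rels$v, counts = virus_counts)
    ab <- alpha_diversity(rels$b, counts = bacteria_counts)
    emit(av, "alpha_virus.tsv")
    emit(ab, "alpha_bacteria.tsv")
    d <- bray_curtis(rels$v)
    ord <- nmds_ordination(d, k = 2, n_restarts = config$nmds_restarts,
                           seed = derive_seed(config$seed, "nmds"))
    coords <- data.frame(sample = rownames(ord$points), ord$points,
                         stress = ord$stress, row.names = NULL)
    emit(coords, "nmds_virus.tsv")
    axis_tests <- do.call(rbind, lapply(1:2, function(k) {
      wt <- wilcoxon_rank_sum(ord$points[!af, k], ord$points[af, k])
      data.frame(axis = paste0("NMDS", k), statistic = wt$statistic, p = wt$p.value)
    }))
    idx_tests <- do.call(rbind, lapply(c("shannon", "simpson", "pielou", "richness"), function(ix) {
      wt <- wilcoxon_rank_sum(av[[ix]][!af], av[[ix]][af])
      data.frame(index = ix, statistic = wt$statistic, p = wt$p.value)
    }))
    emit(axis_tests, "nmds_axis_tests.tsv")
    emit(idx_tests, "alpha_tests.tsv")
    adj <- do.call(rbind, lapply(c("shannon", "simpson", "pielou"), function(ix) {
      tb <- adjust_confounders(av[[ix]], metadata)
      cbind(index = ix, tb)
    }))
    emit(adj, "alpha_adjusted.tsv")
    list(virus = av, bact = ab, ord = ord)
  })

  ## differential ----------------------------------------------------------
  stage("differential", {
    for (lvl in c("species", "genus", "family")) {
      cnt <- aggregate_taxonomy(virus_counts, taxonomy, level = lvl)
      res <- nb_wald_test(cnt, factor(ifelse(af, "AF", "CTR"), levels = c("CTR", "AF")))
      hits <- filter_differential(res, q_max = config$diff_q, lfc_min = config$lfc_min)
      full <- attr(hits, "full")
      emit(full, sprintf("differential_%s.tsv", lvl))
    }
  })

  ## network (per group) ---------------------------------------------------
  nets <- stage("network", {
    res <- list()
    for (g in c("CTR", "AF")) {
      cols <- names(af)[if (g == "CTR") !af else af]
      vv <- abundance_matrix(unclass(rels$v)[, cols, drop = FALSE],
                             kind = "relative", kingdom = "virus")
      bb <- abundance_matrix(unclass(rels$b)[, cols, drop = FALSE],
                             kind = "relative", kingdom = "bacteria")
      top <- select_top_taxa(vv, bb, k = config$top_k)
      sub <- rbind(unclass(vv)[top$taxon[top$kingdom == "virus"], , drop = FALSE],
                   unclass(bb)[top$taxon[top$kingdom == "bacteria"], , drop = FALSE])
      cors <- spearman_matrix(sub)
      net <- build_network(cors, top, rho_min = config$rho_min, q_max = config$q_max)
      met <- network_metrics(net)
      rob <- if (nrow(net$nodes) >= 4) {
        robustness_curve(net, n_reps = config$robustness_reps,
                         seed = derive_seed(config$seed, "network"))
      } else {
        message(sprintf("[network] %s network too small for a robustness curve", g))
        data.frame(fraction = numeric(), mean_nc = numeric(), sd_nc = numeric(),
                   n_reps = integer())
      }
      export_network(net, out(sprintf("network_%s", g)))
      written <<- c(written, sprintf("network_%s_edges.tsv", g),
                    sprintf("network_%s_nodes.tsv", g), sprintf("network_%s.graphml", g))
      emit(data.frame(metric = c("n_nodes", "n_edges", "n_linkages", "density",
                                 "natural_connectivity", "degree_entropy"),
                      value = c(met$n_nodes, met$n_edges, met$n_linkages, met$density,
                                met$natural_connectivity, met$degree_entropy)),
           sprintf("network_%s_metrics.tsv", g))
      emit(rob, sprintf("network_%s_robustness.tsv", g))
      res[[g]] <- list(net = net, metrics = met)
    }
    tk <- transkingdom_diversity_correlation(alpha$virus, alpha$bact,
                                             stats::setNames(ifelse(af, "AF", "CTR"), names(af)))
    emit(tk, "transkingdom_diversity.tsv")
    res
  })

  ## risk ------------------------------------------------------------------
  if (!is.null(survival_df) && nrow(survival_df) >= 10 && sum(survival_df$event) >= 3) {
    stage("risk", {
      rel_t <- t(unclass(rels$v)[, survival_df$sample, drop = FALSE])
      fit <- tryCatch(
        viral_risk(rel_t, survival_df$time_months, survival_df$event,
                   horizon = config$horizon, k_folds = config$k_folds,
                   seed = derive_seed(config$seed, "risk")),
        error = function(e) {
          if (grepl("no candidate taxa", conditionMessage(e))) {
            message("[risk] no taxa passed screening; risk outputs skipped")
            return(NULL)
          }
          stop(e)
        })
      if (!is.null(fit)) {
        emit(data.frame(taxon = names(fit$coefficients), coefficient = fit$coefficients),
             "risk_coefficients.tsv")
        emit(data.frame(sample = names(fit$scores), score = fit$scores,
                        risk_group = as.character(fit$risk_group)), "risk_scores.tsv")
        emit(fit$roc$curve, "risk_roc.tsv")
        emit(data.frame(quantity = c("lambda", "lambda_min", "lambda_1se", "cutoff",
                                     "auc", "horizon", "logrank_chisq", "logrank_p"),
                        value = c(fit$lambda, fit$lambda_min, fit$lambda_1se, fit$cutoff,
                                  fit$roc$auc, fit$horizon,
                                  if (is.null(fit$km)) NA else fit$km$chisq,
                                  if (is.null(fit$km)) NA else fit$km$p)),
             "risk_summary.tsv")
        if (!is.null(fit$km)) emit(fit$km$table, "risk_km.tsv")
        covs <- metadata[match(survival_df$sample, metadata$sample),
                         intersect(c("age", "sex_female", "bmi", "htn", "t2dm", "tc"),
                                   colnames(metadata)), drop = FALSE]
        covs <- covs[, vapply(covs, function(v) length(unique(v)) > 1, TRUE), drop = FALSE]
        cx <- tryCatch(
          cox_fit(survival_df$time_months, survival_df$event,
                  cbind(data.frame(high_risk = as.integer(fit$risk_group == "high")), covs)),
          error = function(e) NULL)
        if (!is.null(cx)) emit(cx$table, "risk_cox.tsv")
        if (config$n_boot > 0) {
          iv <- internal_validation(rel_t, survival_df$time_months, survival_df$event,
                                    horizon = config$horizon, n_boot = config$n_boot,
                                    seed = derive_seed(config$seed, "boot"))
          emit(data.frame(metric = c("auc", "c_index"),
                          apparent = c(iv$apparent$auc, iv$apparent$c_index),
                          optimism = c(iv$optimism$auc, iv$optimism$c_index),
                          corrected = c(iv$corrected$auc, iv$corrected$c_index)),
               "risk_validation.tsv")
        }
      }
    })
  } else if (!is.null(survival_df)) {
    message("[risk] skipped: too few ablated subjects or events")
  }

  ## manifest --------------------------------------------------------------
  files <- sort(unique(written))
  md5 <- tools::md5sum(file.path(outdir, files))
  header <- c("# viromeAF pipeline manifest",
              sprintf("# seed: %d", config$seed),
              sprintf("# thresholds: rho_min=%g q_max=%g diff_q=%g lfc_min=%g top_k=%d min_contig_len=%d horizon=%g k_folds=%d n_boot=%d robustness_reps=%d nmds_restarts=%d",
                      config$rho_min, config$q_max, config$diff_q, config$lfc_min,
                      config$top_k, config$min_contig_len, config$horizon,
                      config$k_folds, config$n_boot, config$robustness_reps,
                      config$nmds_restarts))
  manifest <- out("manifest.tsv")
  con <- file(manifest, "w")
  writeLines(header, con)
  writeLines("file\tmd5", con)
  writeLines(sprintf("%s\t%s", files, unname(md5)), con)
  close(con)
  message(sprintf("pipeline finished in %.1fs; manifest: %s",
                  as.numeric(Sys.time() - t0, units = "secs"), manifest))
  invisible(manifest)
}
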