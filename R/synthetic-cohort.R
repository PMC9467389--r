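#' Configuration for a synthetic AF virome cohort
#'
#' Describes a simulated case-control cohort with paired virome/bacteriome
#' count matrices, per-sample metadata and post-ablation survival outcomes.
#' The generator emulates the data structure of a 50+50 fecal metagenome
#' study: heavy-tailed species abundances, an evenness increase in the AF
#' group, virus-bacteria correlation blocks that are tight in controls and
#' attenuated in AF, and recurrence times driven by a known linear combination
#' of viral taxa.
#'
#' Taxa are indexed in decreasing order of expected abundance (taxon 1 is on
#' average the most abundant), so planted block indices and `true_beta` names
#' refer to abundance ranks.
#'
#' @param n_control,n_paf,n_psaf_short,n_psaf_long group sizes (controls,
#'   paroxysmal AF, persistent AF < 12 months, persistent AF >= 12 months).
#' @param n_viruses,n_bacteria number of viral / bacterial species.
#' @param lognormal_mu_sigma length-2 vector: mean and SD of the per-taxon
#'   base log-abundance (the heavy tail of the community).
#' @param sample_sigma SD of the per-sample log-abundance fluctuation around
#'   the base profile; this is the biological signal the copula correlates.
#' @param dm_concentration total Dirichlet concentration of the per-sample
#'   compositional draw; larger values give less sampling dropout.
#' @param evenness_shift strength of the AF evenness increase (0 = no group
#'   difference). A positive shift (i) scales the Dirichlet concentration of
#'   AF samples by `1 + evenness_shift` (less sampling dropout of rare taxa)
#'   and (ii) tempers the AF log-abundance profile by `1 / (1 + evenness_shift)`
#'   (flattens the heavy tail), so Shannon, Simpson and Pielou all rise in AF.
#'   Tempering is a per-taxon monotone transform, so planted rank
#'   correlations are unaffected.
#' @param planted_blocks list of blocks, each
#'   `list(viruses = <indices>, bacteria = <indices>, rho = c(control, af))`
#'   giving the target pairwise Spearman correlation between block members in
#'   each group (all `|rho| < 1`).
#' @param library_size_virus,library_size_bacteria length-2 ranges of total
#'   mapped reads per sample (drawn uniformly).
#' @param n_ablated number of AF patients undergoing ablation (survival
#'   follow-up is generated for these; must be <= total AF count).
#' @param true_beta named numeric vector of log-hazard weights; names are
#'   virus abundance-rank indices (e.g. `c("1" = 1.2)`) or species ids.
#' @param baseline_hazard exponential baseline recurrence hazard per month.
#' @param censor_max_months administrative censoring drawn uniform on
#'   `(0, censor_max_months]`.
#' @param seed integer RNG seed; the whole cohort is a deterministic function
#'   of the config.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_control = 50, n_paf = 30, n_psaf_short = 12, n_psaf_long = 8,
                          n_viruses = 500, n_bacteria = 500,
                          lognormal_mu_sigma = c(0, 2),
                          sample_sigma = 1,
                          dm_concentration = 1e4,
                          evenness_shift = 0.5,
                          planted_blocks = list(
                            list(viruses = 11:13, bacteria = 11:15, rho = c(0.85, 0.30)),
                            list(viruses = 14:16, bacteria = 16:20, rho = c(0.85, 0.30))
                          ),
                          library_size_virus = c(3e6, 5e6),
                          library_size_bacteria = c(4e7, 5e7),
                          n_ablated = 40,
                          true_beta = c("1" = 1.2, "4" = -1.0, "7" = 0.9),
                          baseline_hazard = 0.03,
                          censor_max_months = 36,
                          seed = 1L) {
  cfg <- list(n_control = n_control, n_paf = n_paf, n_psaf_short = n_psaf_short,
              n_psaf_long = n_psaf_long, n_viruses = n_viruses, n_bacteria = n_bacteria,
              lognormal_mu_sigma = lognormal_mu_sigma, sample_sigma = sample_sigma,
              dm_concentration = dm_concentration, evenness_shift = evenness_shift,
              planted_blocks = planted_blocks,
              library_size_virus = library_size_virus,
              library_size_bacteria = library_size_bacteria,
              n_ablated = n_ablated, true_beta = true_beta,
              baseline_hazard = baseline_hazard,
              censor_max_months = censor_max_months, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_control, cfg$n_paf, cfg$n_psaf_short, cfg$n_psaf_long,
              cfg$n_viruses, cfg$n_bacteria)
  if (!all(vapply(counts, is_count, TRUE))) stopf("all cohort counts must be positive integers")
  n_af <- cfg$n_paf + cfg$n_psaf_short + cfg$n_psaf_long
  if (!is_count(cfg$n_ablated) || cfg$n_ablated > n_af) {
    stopf("n_ablated must be a positive integer <= number of AF cases (%d)", n_af)
  }
  if (length(cfg$lognormal_mu_sigma) != 2 || cfg$lognormal_mu_sigma[2] <= 0) {
    stopf("lognormal_mu_sigma must be c(mu, sigma > 0)")
  }
  if (cfg$sample_sigma <= 0) stopf("sample_sigma must be > 0")
  if (cfg$dm_concentration <= 0) stopf("dm_concentration must be > 0")
  if (cfg$evenness_shift < 0) stopf("evenness_shift must be >= 0")
  if (cfg$baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
  if (cfg$censor_max_months <= 0) stopf("censor_max_months must be > 0")
  for (b in cfg$planted_blocks) {
    if (!all(c("viruses", "bacteria", "rho") %in% names(b))) {
      stopf("each planted block needs viruses, bacteria and rho")
    }
    if (any(b$viruses < 1) || any(b$viruses > cfg$n_viruses) ||
        any(b$bacteria < 1) || any(b$bacteria > cfg$n_bacteria)) {
      stopf("planted block taxon indices out of range")
    }
    if (any(abs(b$rho) >= 1)) stopf("planted |rho| must be < 1")
  }
  if (length(cfg$true_beta)) {
    if (is.null(names(cfg$true_beta))) stopf("true_beta must be named by virus index or id")
    idx <- resolve_virus_index(names(cfg$true_beta), cfg$n_viruses)
    if (anyNA(idx)) stopf("true_beta names must resolve to virus indices/ids")
  }
  invisible(cfg)
}

resolve_virus_index <- function(nm, n_viruses) {
  idx <- suppressWarnings(as.integer(nm))
  alt <- match(nm, virus_ids(n_viruses))
  idx[is.na(idx)] <- alt[is.na(idx)]
  idx[!is.na(idx) & (idx < 1 | idx > n_viruses)] <- NA_integer_
  idx
}

virus_ids <- function(n) sprintf("Virus_%04d", seq_len(n))
bacteria_ids <- function(n) sprintf("Bacterium_%04d", seq_len(n))

# Spearman target -> Pearson correlation of the Gaussian copula latents.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Latent standard-normal matrix (taxa x samples) with planted one-factor
# blocks: block members load on a shared per-sample factor with magnitude
# sqrt(|r_p|); bacteria loadings carry sign(r_p), so every virus-bacterium
# pair in the block has latent Pearson correlation r_p (virus-virus and
# bacterium-bacterium pairs get +|r_p|).
planted_latents <- function(n_virus, n_bacteria, n_samples, blocks, af) {
  n_taxa <- n_virus + n_bacteria
  z <- matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
  for (b in blocks) {
    members <- c(b$viruses, n_virus + b$bacteria)
    rho_s <- if (length(b$rho) == 1) rep(b$rho, 2) else b$rho
    f <- stats::rnorm(n_samples)
    for (g in c(FALSE, TRUE)) {        # control, AF
      cols <- which(af == g)
      if (!length(cols)) next
      r_p <- spearman_to_pearson(if (g) rho_s[2] else rho_s[1])
      loadings <- c(rep(1, length(b$viruses)),
                    rep(sign(r_p), length(b$bacteria))) * sqrt(abs(r_p))
      z[members, cols] <- outer(loadings, f[cols]) +
        sqrt(1 - abs(r_p)) * z[members, cols]
    }
  }
  z
}

# Dirichlet-multinomial draw for one kingdom from per-sample log-abundance
# latents. Block members are first compensated for the fluctuation of the
# community total (the closure term log sum(exp(x)) that would otherwise add
# independent noise to each kingdom's ranks and attenuate the planted
# trans-kingdom rank correlations), so the relative abundance of a planted
# taxon tracks its copula latent.
# x: log-abundance latents (taxa x samples); block_rows: taxa belonging to
# planted blocks; theta: per-sample concentration; libsize: totals.
sample_counts <- function(x, block_rows, theta, libsize, ids, samples) {
  n_taxa <- nrow(x)
  n_s <- length(libsize)
  if (length(block_rows)) {
    lse <- apply(x, 2, function(v) { m <- max(v); m + log(sum(exp(v - m))) })
    x[block_rows, ] <- sweep(x[block_rows, , drop = FALSE], 2, lse - mean(lse), "+")
  }
  counts <- matrix(0L, n_taxa, n_s, dimnames = list(ids, samples))
  for (s in seq_len(n_s)) {
    p <- exp(x[, s] - max(x[, s]))
    p <- p / sum(p)
    g <- stats::rgamma(n_taxa, shape = theta[s] * p, rate = 1)
    tot <- sum(g)
    w <- if (tot > 0) g / tot else rep(1 / n_taxa, n_taxa)
    counts[, s] <- stats::rmultinom(1, size = libsize[s], prob = w)[, 1]
  }
  counts
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_config()]: Dirichlet-multinomial counts
#' around per-sample log-normal abundance profiles, a Gaussian copula planting
#' the requested virus-bacteria rank-correlation blocks per group, an AF
#' evenness increase via a larger Dirichlet concentration, and exponential
#' recurrence times for the ablated subset with rate
#' `baseline_hazard * exp(sum(true_beta * z))`, where `z` is the standardized
#' `log10(relative abundance + 1e-6)` of each causal virus, censored uniformly
#' on `(0, censor_max_months]`.
#'
#' @param config a `cohort_config`.
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `virus_counts` and `bacteria_counts` (`abund_matrix` of counts),
#'   `taxonomy` (virus taxonomy/host/lifestyle data frame), `metadata`
#'   (per-sample group and covariates), `survival` (ablated subset:
#'   `time_months`, `event`) and `truth` (planted parameters, causal linear
#'   predictor, planted pair table).
#' @examples
#' cfg <- cohort_config(n_viruses = 50, n_bacteria = 50, seed = 7)
#' ch <- generate_cohort(cfg)
#' dim(ch$virus_counts)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n_af <- config$n_paf + config$n_psaf_short + config$n_psaf_long
    n <- config$n_control + n_af
    samples <- sprintf("S%03d", seq_len(n))
    group <- c(rep("CTR", config$n_control), rep("PAF", config$n_paf),
               rep("psAF<12m", config$n_psaf_short), rep("psAF>=12m", config$n_psaf_long))
    af <- group != "CTR"

    mu_v <- sort(stats::rnorm(config$n_viruses, config$lognormal_mu_sigma[1],
                              config$lognormal_mu_sigma[2]), decreasing = TRUE)
    mu_b <- sort(stats::rnorm(config$n_bacteria, config$lognormal_mu_sigma[1],
                              config$lognormal_mu_sigma[2]), decreasing = TRUE)

    z <- planted_latents(config$n_viruses, config$n_bacteria, n, config$planted_blocks, af)
    theta <- ifelse(af, config$dm_concentration * (1 + config$evenness_shift),
                    config$dm_concentration)
    temper <- ifelse(af, 1 / (1 + config$evenness_shift), 1)
    lib_v <- round(stats::runif(n, config$library_size_virus[1], config$library_size_virus[2]))
    lib_b <- round(stats::runif(n, config$library_size_bacteria[1], config$library_size_bacteria[2]))

    x_v <- sweep(mu_v + config$sample_sigma * z[seq_len(config$n_viruses), , drop = FALSE],
                 2, temper, "*")
    x_b <- sweep(mu_b + config$sample_sigma *
                   z[config$n_viruses + seq_len(config$n_bacteria), , drop = FALSE],
                 2, temper, "*")
    block_v <- sort(unique(unlist(lapply(config$planted_blocks, `[[`, "viruses"))))
    block_b <- sort(unique(unlist(lapply(config$planted_blocks, `[[`, "bacteria"))))
    vc <- sample_counts(x_v, block_v, theta, lib_v, virus_ids(config$n_viruses), samples)
    bc <- sample_counts(x_b, block_b, theta, lib_b, bacteria_ids(config$n_bacteria), samples)

    taxonomy <- synth_taxonomy(config$n_viruses)
    metadata <- synth_metadata(samples, group, af, config$n_ablated)

    virus_counts <- abundance_matrix(vc, kind = "counts", kingdom = "virus")
    bacteria_counts <- abundance_matrix(bc, kind = "counts", kingdom = "bacteria")

    ablated <- metadata$sample[metadata$ablated]
    rel_v <- to_relative(virus_counts)
    feats <- log10(t(unclass(rel_v)[, ablated, drop = FALSE]) + 1e-6)
    beta_idx <- resolve_virus_index(names(config$true_beta), config$n_viruses)
    zf <- scale(feats[, beta_idx, drop = FALSE])
    zf[is.nan(zf)] <- 0
    lp <- as.vector(zf %*% as.numeric(config$true_beta))
    rate <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(length(ablated), rate = rate)
    cens <- stats::runif(length(ablated), 0, config$censor_max_months)
    survival <- data.frame(sample = ablated,
                           time_months = pmax(pmin(t_event, cens), 1e-3),
                           event = as.integer(t_event <= cens),
                           stringsAsFactors = FALSE)

    pairs <- do.call(rbind, lapply(config$planted_blocks, function(b) {
      rho <- if (length(b$rho) == 1) rep(b$rho, 2) else b$rho
      expand.grid(virus = virus_ids(config$n_viruses)[b$viruses],
                  bacterium = bacteria_ids(config$n_bacteria)[b$bacteria],
                  rho_control = rho[1], rho_af = rho[2],
                  stringsAsFactors = FALSE)
    }))

    out <- list(virus_counts = virus_counts, bacteria_counts = bacteria_counts,
                taxonomy = taxonomy, metadata = metadata, survival = survival,
                truth = list(config = config,
                             planted_pairs = pairs,
                             causal_viruses = virus_ids(config$n_viruses)[beta_idx],
                             true_beta = stats::setNames(as.numeric(config$true_beta),
                                                         virus_ids(config$n_viruses)[beta_idx]),
                             linear_predictor = stats::setNames(lp, ablated)))
    class(out) <- "synthetic_cohort"
    out
  })
}

synth_taxonomy <- function(n_viruses) {
  ids <- virus_ids(n_viruses)
  host <- rep(c("phage", "vertebrate", "other"),
              times = c(round(0.6 * n_viruses), round(0.3 * n_viruses), 0))
  host <- c(host, rep("other", n_viruses - length(host)))
  host <- sample(host)
  lifestyle <- rep("unknown", n_viruses)
  phage <- which(host == "phage")
  temperate <- sample(phage, size = round(length(phage) * 0.5))
  lifestyle[phage] <- "lytic"
  lifestyle[temperate] <- "temperate"
  m <- matrix(FALSE, n_viruses, 3)
  for (i in temperate) {
    m[i, sample(3, sample(1:3, 1))] <- TRUE
  }
  data.frame(species = ids,
             genus = sprintf("Genus_%03d", (seq_len(n_viruses) - 1L) %/% 5L + 1L),
             family = sprintf("Family_%02d", (seq_len(n_viruses) - 1L) %/% 30L + 1L),
             order = sprintf("Order_%02d", (seq_len(n_viruses) - 1L) %/% 80L + 1L),
             host_class = host, lifestyle = lifestyle,
             marker_1 = m[, 1], marker_2 = m[, 2], marker_3 = m[, 3],
             stringsAsFactors = FALSE)
}

synth_metadata <- function(samples, group, af, n_ablated) {
  n <- length(samples)
  ablated <- rep(FALSE, n)
  ablated[which(af)[seq_len(n_ablated)]] <- TRUE
  data.frame(sample = samples, group = group, af = as.integer(af),
             age = round(stats::rnorm(n, ifelse(af, 62, 58), 8)),
             sex_female = stats::rbinom(n, 1, ifelse(af, 0.55, 0.4)),
             bmi = round(stats::rnorm(n, 25, 3), 1),
             htn = stats::rbinom(n, 1, ifelse(af, 0.55, 0.4)),
             t2dm = stats::rbinom(n, 1, ifelse(af, 0.3, 0.15)),
             tc = round(stats::rnorm(n, ifelse(af, 4.5, 4.8), 0.9), 2),
             medication = stats::rbinom(n, 1, ifelse(af, 0.7, 0.3)),
             ablated = ablated, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%d CTR / %d AF), %d viruses, %d bacteria\n",
              ncol(x$virus_counts), sum(x$metadata$group == "CTR"),
              sum(x$metadata$group != "CTR"), nrow(x$virus_counts), nrow(x$bacteria_counts)))
  cat(sprintf("  ablated: %d, recurrences: %d, planted pairs: %d\n",
              nrow(x$survival), sum(x$survival$event), nrow(x$truth$planted_pairs)))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes the three pipeline inputs (virus and bacteria count tables, the
#' virus taxonomy table, and metadata with the survival columns merged in) as
#' tab-separated files, plus the generating configuration as a key-value text
#' file whose header records the seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(virus = file.path(dir, "virus_counts.tsv"),
             bacteria = file.path(dir, "bacteria_counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             config = file.path(dir, "config.txt"))
  write_abundance(cohort$virus_counts, paths["virus"])
  write_abundance(cohort$bacteria_counts, paths["bacteria"])
  utils::write.table(cohort$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- cohort$metadata
  idx <- match(meta$sample, cohort$survival$sample)
  meta$time_months <- cohort$survival$time_months[idx]
  meta$event <- cohort$survival$event[idx]
  utils::write.table(meta, paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$truth$config
  scalars <- cfg[!names(cfg) %in% c("planted_blocks", "true_beta")]
  lines <- c(sprintf("# synthetic cohort config (seed=%d)", cfg$seed),
             vapply(names(scalars), function(k) {
               sprintf("%s: %s", k, paste(scalars[[k]], collapse = ","))
             }, ""),
             sprintf("true_beta: %s",
                     paste(sprintf("%s=%g", names(cfg$true_beta), cfg$true_beta), collapse = ",")),
             vapply(seq_along(cfg$planted_blocks), function(i) {
               b <- cfg$planted_blocks[[i]]
               sprintf("block_%d: viruses=%s; bacteria=%s; rho=%s", i,
                       paste(b$viruses, collapse = ","), paste(b$bacteria, collapse = ","),
                       paste(b$rho, collapse = ","))
             }, ""))
  writeLines(lines, paths["config"])
  invisible(paths)
}
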