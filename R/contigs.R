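#' Contig table utilities
#'
#' A contig table is a data frame with columns `contig_id`, `length` (bp),
#' `virus` (assignment, possibly `NA`) and one integer read-count column per
#' sample. These functions take such a table from assembly-level counts to a
#' virus-by-sample RPKM matrix.
#'
#' @name contigs
NULL

contig_sample_cols <- function(table) {
  setdiff(colnames(table), c("contig_id", "length", "virus"))
}

validate_contig_table <- function(table) {
  need <- c("contig_id", "length", "virus")
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stopf("contig table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(table) && any(table$length < 1)) stopf("contig lengths must be >= 1 bp")
  sc <- contig_sample_cols(table)
  if (nrow(table)) {
    counts <- as.matrix(table[, sc, drop = FALSE])
    if (anyNA(counts) || any(counts < 0)) stopf("contig read counts must be non-negative")
  }
  invisible(table)
}

#' Filter contigs by length
#'
#' Retains contigs strictly longer than `min_len` base pairs (short contigs
#' are unreliable for viral sequence prediction). The default reproduces the
#' conventional 1,000 bp assembly cutoff; note the inequality is strict, so a
#' contig of exactly `min_len` bp is dropped.
#'
#' @param table contig table (see [contigs]).
#' @param min_len minimum length in bp (exclusive).
#' @return the filtered contig table (possibly zero rows).
#' @export
filter_contigs <- function(table, min_len = 1000) {
  validate_contig_table(table)
  table[table$length > min_len, , drop = FALSE]
}

#' Compute RPKM from contig read counts
#'
#' Reads Per Kilobase per Million mapped reads:
#' `rpkm = reads / (length/1e3) / (total_mapped/1e6)`. Zero-read contigs get
#' RPKM 0; a sample with zero total but non-zero counts is an error.
#'
#' @param table contig table.
#' @param per_sample_total_mapped named vector of total mapped reads per
#'   sample; defaults to the column sums of the contig counts.
#' @return an `abund_matrix` of kind `rpkm` with one row per contig.
#' @export
compute_rpkm <- function(table, per_sample_total_mapped = NULL) {
  validate_contig_table(table)
  sc <- contig_sample_cols(table)
  counts <- as.matrix(table[, sc, drop = FALSE])
  rownames(counts) <- table$contig_id
  if (is.null(per_sample_total_mapped)) {
    per_sample_total_mapped <- colSums(counts)
  }
  tot <- per_sample_total_mapped[sc]
  if (anyNA(tot)) stopf("missing mapped-read totals for some samples")
  bad <- tot == 0 & colSums(counts) > 0
  if (any(bad)) stopf("zero mapped-read total for sample(s) with non-zero counts: %s",
                      paste(sc[bad], collapse = ", "))
  denom <- outer(table$length / 1e3, ifelse(tot > 0, tot / 1e6, 1))
  vals <- counts / denom
  abundance_matrix(vals, kind = "rpkm", kingdom = "virus", level = "contig")
}

#' Virus-level abundance from contig RPKM
#'
#' Averages (arithmetic mean) the RPKM of all contigs assigned to each virus,
#' per sample. Contigs without a virus assignment are dropped. Length
#' weighting is already inside RPKM, so the mean is unweighted.
#'
#' @param rpkm contig-level `abund_matrix` (kind `rpkm`) from [compute_rpkm()].
#' @param contig_to_virus named character vector or data frame
#'   (`contig_id`, `virus`) mapping contigs to viruses; `NA` means unassigned.
#' @return an `abund_matrix` (kind `rpkm`, level species) with one row per virus.
#' @export
virus_abundance <- function(rpkm, contig_to_virus) {
  if (is.data.frame(contig_to_virus)) {
    map <- stats::setNames(as.character(contig_to_virus$virus), contig_to_virus$contig_id)
  } else {
    map <- contig_to_virus
  }
  virus <- map[rownames(rpkm)]
  keep <- !is.na(virus) & virus != ""
  n_drop <- sum(!keep)
  if (n_drop) message(sprintf("virus_abundance: dropping %d unassigned contig(s)", n_drop))
  if (!any(keep)) stopf("no contigs with a virus assignment")
  sub <- unclass(rpkm)[keep, , drop = FALSE]
  grp <- virus[keep]
  sums <- rowsum(sub, group = grp)
  n <- as.vector(table(grp)[rownames(sums)])
  vals <- sums / n
  abundance_matrix(vals, kind = "rpkm", kingdom = "virus", level = "species")
}
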