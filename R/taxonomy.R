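#' Host-class composition of the virome
#'
#' Fraction of distinct taxa at a taxonomic rank falling in each host class
#' (vertebrate-infecting virus, bacteriophage, other/unknown). Counts distinct
#' taxa, not abundance, so the fractions describe the annotated catalogue.
#'
#' @param taxonomy data frame with `species`, lineage columns and `host_class`
#'   (values `vertebrate`, `phage`, or anything else counted as `other`).
#' @param level rank at which to count distinct taxa.
#' @return named numeric vector of proportions summing to 1.
#' @examples
#' tax <- data.frame(species = letters[1:4], order = c("o1", "o2", "o3", "o3"),
#'                   host_class = c("vertebrate", "phage", "other", "other"))
#' host_class_summary(tax, level = "order")
#' @export
host_class_summary <- function(taxonomy, level = "order") {
  if (!nrow(taxonomy)) stopf("empty taxonomy")
  if (!level %in% colnames(taxonomy)) stopf("unknown level '%s'", level)
  cls <- as.character(taxonomy$host_class)
  cls[!cls %in% c("vertebrate", "phage")] <- "other"
  # majority host class per distinct taxon at the rank
  taxa <- split(cls, as.character(taxonomy[[level]]))
  per_taxon <- vapply(taxa, function(v) names(sort(table(v), decreasing = TRUE))[1], "")
  tab <- table(factor(per_taxon, levels = c("vertebrate", "phage", "other")))
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, names(tab))
}

#' Per-sample lysogenic (temperate) phage proportion
#'
#' Share of phage abundance carried by temperate-flagged phage species:
#' `sum(abundance of temperate phages) / sum(abundance of all phages)` per
#' sample. Samples with zero phage abundance get `NA`. The denominator is the
#' phage fraction only (not the whole virome) because lysogeny is a property
#' of the phage community; set `denominator = "virome"` for the alternative.
#'
#' A phage species is called temperate when any of its temperate-evidence
#' marker flags (`marker_1`, `marker_2`, `marker_3`: reference-genome,
#' prophage-gene and curated-protein evidence) is set, or when `lifestyle`
#' equals `"temperate"` and no flags are provided.
#'
#' @param m species-level relative `abund_matrix` of the virome.
#' @param taxonomy data frame with `species`, `host_class`, and either
#'   `lifestyle` or `marker_1`..`marker_3` logical columns.
#' @param denominator `"phage"` (default) or `"virome"`.
#' @return named numeric vector, one proportion (or `NA`) per sample.
#' @export
lysogenic_proportion <- function(m, taxonomy, denominator = c("phage", "virome")) {
  denominator <- match.arg(denominator)
  if (!identical(abund_level(m), "species")) stopf("matrix must be at species level")
  idx <- match(rownames(m), taxonomy$species)
  host <- as.character(taxonomy$host_class[idx])
  is_phage <- !is.na(host) & host == "phage"
  markers <- intersect(c("marker_1", "marker_2", "marker_3"), colnames(taxonomy))
  if (length(markers)) {
    flag <- rowSums(as.matrix(taxonomy[idx, markers, drop = FALSE]) > 0, na.rm = TRUE) > 0
  } else if ("lifestyle" %in% colnames(taxonomy)) {
    flag <- !is.na(taxonomy$lifestyle[idx]) & taxonomy$lifestyle[idx] == "temperate"
  } else {
    stopf("taxonomy needs marker flags or a lifestyle column")
  }
  temperate <- is_phage & flag
  num <- colSums(unclass(m)[temperate, , drop = FALSE])
  den <- if (denominator == "phage") {
    colSums(unclass(m)[is_phage, , drop = FALSE])
  } else {
    colSums(unclass(m))
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(out, colnames(m))
}
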