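#' Construct an abundance matrix
#'
#' A thin S3 container for feature-by-sample abundance data carrying three
#' tags: the value kind (`counts`, `rpkm` or `relative`), the kingdom of the
#' features (`virus`, `bacteria` or `function`), and the taxonomic (or
#' functional) level of the rows.
#'
#' @param values numeric matrix, features in rows, samples in columns; must be
#'   non-negative with row and column names.
#' @param kind one of `"counts"`, `"rpkm"`, `"relative"`.
#' @param kingdom one of `"virus"`, `"bacteria"`, `"function"`.
#' @param level taxonomic rank or functional namespace of the rows.
#' @return a numeric matrix of class `abund_matrix` with `kind`, `kingdom` and
#'   `level` attributes.
#' @examples
#' m <- abundance_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
#'                       kind = "counts", kingdom = "virus")
#' abund_kind(m)
#' @export
abundance_matrix <- function(values,
                             kind = c("counts", "rpkm", "relative"),
                             kingdom = c("virus", "bacteria", "function"),
                             level = "species") {
  kind <- match.arg(kind)
  kingdom <- match.arg(kingdom)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (anyNA(values)) stopf("abundance values contain NA")
  if (any(values < 0)) stopf("abundance values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (kind == "relative") {
    cs <- colSums(values)
    bad <- which(cs > 0 & abs(cs - 1) > 1e-9)
    if (length(bad)) {
      stopf("relative columns must sum to 1 (off: %s)",
            paste(colnames(values)[bad[seq_len(min(3, length(bad)))]], collapse = ", "))
    }
  }
  structure(values, class = c("abund_matrix", class(values)),
            kind = kind, kingdom = kingdom, level = level)
}

#' @rdname abundance_matrix
#' @param m an `abund_matrix`.
#' @export
abund_kind <- function(m) attr(m, "kind")

#' @rdname abundance_matrix
#' @export
abund_kingdom <- function(m) attr(m, "kingdom")

#' @rdname abundance_matrix
#' @export
abund_level <- function(m) attr(m, "level")

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("<abund_matrix> %d features x %d samples [kind=%s, kingdom=%s, level=%s]\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "kingdom"), attr(x, "level")))
  mat <- x
  attributes(mat) <- attributes(x)[c("dim", "dimnames")]
  print(utils::head(mat[, seq_len(min(5, ncol(mat))), drop = FALSE], 5))
  invisible(x)
}

#' Convert an abundance matrix to relative abundances
#'
#' Column-normalizes counts or RPKM values so every sample sums to one.
#' All-zero samples are left all-zero with a warning (an empty profile cannot
#' be normalized).
#'
#' @param m an `abund_matrix` of kind `counts` or `rpkm`.
#' @return an `abund_matrix` of kind `relative`.
#' @export
to_relative <- function(m) {
  if (abund_kind(m) == "relative") return(m)
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warnf("%d all-zero sample(s) left unnormalized: %s",
          sum(zero), paste(colnames(m)[zero][seq_len(min(3, sum(zero)))], collapse = ", "))
    cs[zero] <- 1
  }
  abundance_matrix(sweep(unclass(m), 2, cs, "/"),
                   kind = "relative", kingdom = abund_kingdom(m), level = abund_level(m))
}

#' Aggregate a species-level matrix to a higher taxonomic rank
#'
#' Sums abundances of species sharing the target rank. Species absent from the
#' taxonomy table (or with a missing entry at the rank) are pooled into an
#' `"unclassified"` bucket.
#'
#' @param m an `abund_matrix` with species rows.
#' @param taxonomy data frame with a `species` column plus lineage columns.
#' @param level target rank: `"species"`, `"genus"`, `"family"` or `"order"`.
#' @return an `abund_matrix` at the requested level (same kind/kingdom).
#' @export
aggregate_taxonomy <- function(m, taxonomy, level = c("species", "genus", "family", "order")) {
  level <- match.arg(level)
  if (level == "species") return(m)
  idx <- match(rownames(m), taxonomy$species)
  grp <- as.character(taxonomy[[level]][idx])
  grp[is.na(idx) | is.na(grp) | grp == ""] <- "unclassified"
  out <- rowsum(unclass(m), group = grp)
  # rowsum of relative columns preserves the column sums exactly up to fp error
  kind <- abund_kind(m)
  if (kind == "relative") {
    cs <- colSums(out)
    out <- sweep(out, 2, ifelse(cs > 0, cs, 1), "/")
  }
  abundance_matrix(out, kind = kind, kingdom = abund_kingdom(m), level = level)
}
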