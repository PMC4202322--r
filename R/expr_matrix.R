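#' Expression matrix with an explicit unit
#'
#' A numeric matrix of miRNA expression (rows = arm-level or locus-level
#' ids, columns = libraries or stages) carrying the unit of its values:
#' `raw_fractional_count` (possibly fractional read counts),
#' `rpm` (reads per million mapping to microRNAs) or `z` (z-scores).
#'
#' @param values Numeric matrix with row and column names.
#' @param unit One of `"raw_fractional_count"`, `"rpm"`, `"z"`.
#' @param species Optional species tag.
#' @return The matrix with class `mir_expr` and a `unit` attribute.
#' @export
expr_matrix <- function(values,
                        unit = c("raw_fractional_count", "rpm", "z"),
                        species = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row and column names")
  if (unit != "z" && any(values < 0))
    stop("negative entries are not allowed in a ", unit, " matrix")
  structure(values, unit = unit, species = species,
            class = c("mir_expr", "matrix", "array"))
}

#' Unit of an expression matrix
#' @param x A `mir_expr` matrix.
#' @return The unit string.
#' @export
expr_unit <- function(x) attr(x, "unit")

# rebuild a mir_expr after a plain-matrix operation
as_expr <- function(values, template, unit = expr_unit(template)) {
  expr_matrix(values, unit = unit, species = attr(template, "species"))
}

#' @export
`[.mir_expr` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    structure(out, unit = attr(x, "unit"), species = attr(x, "species"),
              class = c("mir_expr", "matrix", "array"))
  else out
}

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("<mir_expr> %d x %d [%s]%s\n", nrow(x), ncol(x), expr_unit(x),
              if (!is.null(attr(x, "species")))
                paste0(" species ", attr(x, "species")) else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

#' Collapse arm-level rows to locus level
#'
#' Sums the expression of the 5p and 3p arms of each locus, turning an
#' arm-level matrix (rows `locus|arm`) into a locus-level matrix of total
#' mature miRNA output, used for temporal profile comparisons.
#'
#' @param x Arm-level `mir_expr` matrix.
#' @return Locus-level `mir_expr` matrix (same unit).
#' @export
collapse_arms <- function(x) {
  ids <- split_arm_row_id(rownames(x))$locus_id
  out <- rowsum(unclass(x), group = ids, reorder = FALSE)
  as_expr(out, x)
}
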