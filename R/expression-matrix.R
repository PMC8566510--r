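#' Expression matrix container
#'
#' A light wrapper around a genes x samples numeric matrix carrying a units
#' tag. Gene and sample identifiers live in the dimnames; `units` records
#' what the values are so downstream stages can refuse the wrong input
#' (e.g. the variance-stabilizing transform only accepts raw counts).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must have
#'   complete row and column names.
#' @param units one of `"raw_counts"`, `"vst"`, `"log_cpm"`, `"tpm"`,
#'   `"quantile"`.
#' @param description optional per-gene description column (GCT carries one);
#'   preserved but unused by any analysis.
#'
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, units = c("raw_counts", "vst", "log_cpm",
                                                "tpm", "quantile"),
                              description = NULL) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  if (units %in% c("raw_counts", "tpm") && any(values < 0))
    stop(units, " values must be non-negative")
  if (units == "raw_counts" && any(abs(values - round(values)) > 1e-8))
    stop("raw_counts must be integers >= 0")
  if (!is.null(description)) {
    stopifnot(length(description) == nrow(values))
    description <- as.character(description)
  }
  structure(list(values = values, units = units, description = description),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Units tag of an expression matrix
#' @param x an `expression_matrix`.
#' @return the units string.
#' @export
em_units <- function(x) x$units

#' Numeric values of an expression matrix
#' @param x an `expression_matrix`.
#' @return the genes x samples matrix.
#' @export
em_values <- function(x) x$values

#' Subset an expression matrix
#'
#' @param x an `expression_matrix`.
#' @param i gene selector (ids, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return an `expression_matrix` over the selected genes/samples.
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  v <- x$values
  d <- x$description
  if (!missing(i)) {
    if (!is.null(d)) d <- d[match(rownames(v[i, , drop = FALSE]), rownames(v))]
    v <- v[i, , drop = FALSE]
  }
  if (!missing(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, units = x$units, description = d)
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

# internal: demand a particular units tag
assert_units <- function(x, units, what = deparse(substitute(x))) {
  if (!inherits(x, "expression_matrix"))
    stop(what, " must be an expression_matrix")
  if (!x$units %in% units)
    stop(what, " must have units ", paste(units, collapse = " or "),
         ", got '", x$units, "'")
  invisible(x)
}
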