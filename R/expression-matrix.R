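# Container for a two-condition expression matrix.

#' Construct an expression matrix with condition labels
#'
#' Wraps a genes-by-samples numeric matrix together with a sample-to-condition
#' map (`control` / `exposed`) and an optional sample-to-timepoint map (hours).
#' Gene and sample identifiers must be unique (gene identifiers are compared
#' case-insensitively) and the matrix may not contain missing values; each
#' condition needs at least 4 samples so correlations can be tested.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param condition Character vector (or named vector keyed by sample id) of
#'   `"control"` / `"exposed"` labels, one per sample.
#' @param timepoint Optional numeric vector of timepoints (hours), one per
#'   sample, same keying rules as `condition`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, timepoint = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyNA(values)) stop("expression values must not contain missing values")
  if (anyDuplicated(tolower(rownames(values)))) {
    stop("duplicate gene identifiers (case-insensitive)")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")

  condition <- .align_sample_vector(condition, colnames(values), "condition")
  if (!all(condition %in% c("control", "exposed"))) {
    stop("condition labels must be 'control' or 'exposed'")
  }
  if (any(table(factor(condition, c("control", "exposed"))) < 4L)) {
    stop("each condition needs at least 4 samples")
  }
  if (!is.null(timepoint)) {
    timepoint <- as.numeric(.align_sample_vector(timepoint, colnames(values),
                                                 "timepoint"))
  }
  structure(
    list(values = values, condition = condition, timepoint = timepoint),
    class = "expression_matrix"
  )
}

.align_sample_vector <- function(v, sample_ids, what) {
  if (!is.null(names(v))) {
    if (!all(sample_ids %in% names(v))) {
      stop(what, " map is missing samples: ",
           paste(setdiff(sample_ids, names(v)), collapse = ", "))
    }
    v <- v[sample_ids]
  }
  if (length(v) != length(sample_ids)) {
    stop(what, " must have one entry per sample")
  }
  unname(v)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$condition == "control"), "control /",
      sum(x$condition == "exposed"), "exposed )\n")
  if (!is.null(x$timepoint)) {
    cat("  timepoints:", paste(sort(unique(x$timepoint)), collapse = ", "),
        "h\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
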