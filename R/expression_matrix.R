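#' Expression matrix container
#'
#' Thin validated container for a features-by-samples matrix of log2-scale
#' expression values. Rows are features (genes or miRNAs), columns are
#' samples; identifiers must be unique and every value finite.
#'
#' @param values Numeric matrix (features x samples) with rownames (feature
#'   ids) and colnames (sample ids). Values are assumed to be on log2 scale
#'   already; no re-logging is performed.
#' @param feature_kind Either `"gene"` or `"mirna"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `feature_kind`.
#' @export
expression_matrix <- function(values, feature_kind = c("gene", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop_validation("`values` must carry rownames (features) and colnames (samples)")
  }
  fid <- trimws(fid)
  sid <- trimws(sid)
  if (anyDuplicated(fid)) {
    stop_validation("duplicate feature ids: %s",
                    paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop_validation("duplicate sample ids: %s",
                    paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop_validation("expression values must all be finite after loading")
  }
  dimnames(values) <- list(fid, sid)
  structure(
    list(values = values, feature_ids = fid, sample_ids = sid,
         feature_kind = feature_kind),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset an ExpressionMatrix by feature and/or sample ids
#'
#' @param em An [expression_matrix()].
#' @param features,samples Character vectors of ids to keep (NULL keeps all).
#' @return A new `ExpressionMatrix`.
#' @export
subset_expression <- function(em, features = NULL, samples = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing)) {
      stop_validation("features absent from matrix: %s",
                      paste(missing, collapse = ", "))
    }
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) {
      stop_validation("samples absent from matrix: %s",
                      paste(missing, collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, em$feature_kind)
}

#' Z-normalize each feature across all samples
#'
#' Rescales every feature row to mean 0 and unit standard deviation (n - 1
#' denominator), the standardization applied to each cohort before
#' classification and before network inference. Zero-variance rows are mapped
#' to all zeros with a warning.
#'
#' @param em An [expression_matrix()] with at least two samples.
#' @return An `ExpressionMatrix` of the same shape.
#' @export
znormalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2) {
    stop_validation("z-normalization needs at least 2 samples")
  }
  v <- em$values
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature row(s) set to all zeros", sum(zero)))
    s[zero] <- 1
  }
  z <- (v - mu) / s
  z[zero, ] <- 0
  expression_matrix(z, em$feature_kind)
}
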