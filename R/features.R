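#' Assemble a mixed-type feature matrix
#'
#' Bundles a numeric patient-by-feature matrix with per-column type flags so
#' that downstream standardization can treat continuous (gene expression)
#' and binary (dichotomized clinical) columns differently.
#'
#' @param values Numeric matrix, patients in rows, features in columns.
#' @param feature_kind Character vector, one of `"continuous"` or `"binary"`
#'   per column. Defaults to all continuous.
#' @param patient_ids Character vector of row identifiers; defaults to
#'   existing rownames or `P1..Pn`.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `feature_kind`, `patient_ids`.
#' @export
feature_matrix <- function(values, feature_kind = NULL, patient_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("feature matrix contains missing values")
  if (nrow(values) < 3L) stop("need at least 3 patients")
  if (is.null(feature_kind)) feature_kind <- rep("continuous", ncol(values))
  feature_kind <- match.arg(feature_kind, c("continuous", "binary"),
                            several.ok = TRUE)
  if (length(feature_kind) == 1L) {
    feature_kind <- rep(feature_kind, ncol(values))
  }
  if (length(feature_kind) != ncol(values)) {
    stop("feature_kind length must match number of columns")
  }
  bin <- feature_kind == "binary"
  if (any(bin) && !all(values[, bin] %in% c(0, 1))) {
    stop("binary columns must contain only 0/1")
  }
  if (is.null(patient_ids)) {
    patient_ids <- rownames(values)
    if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(values)))
  }
  rownames(values) <- patient_ids
  structure(list(values = values, feature_kind = feature_kind,
                 patient_ids = patient_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d continuous, %d binary)\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_kind == "continuous"),
              sum(x$feature_kind == "binary")))
  invisible(x)
}

#' Standardize continuous features, fitting on a subset of rows
#'
#' Continuous columns are centered and scaled to unit variance using moments
#' estimated on `fit_rows` only; the same affine transform is then applied to
#' all rows. Binary columns pass through unchanged. Fitting on the training
#' rows only keeps the inductive split protocol free of information leakage.
#'
#' The variance convention is population (divide by n), matching common
#' machine-learning feature scalers; set `variance = "sample"` for the n-1
#' convention.
#'
#' @param X A [feature_matrix()].
#' @param fit_rows Integer indices of rows used to estimate means/variances;
#'   defaults to all rows.
#' @param variance `"population"` (default) or `"sample"`.
#' @return A `feature_matrix` with transformed values.
#' @export
standardize_features <- function(X, fit_rows = seq_len(nrow(X$values)),
                                 variance = c("population", "sample")) {
  stopifnot(inherits(X, "feature_matrix"))
  variance <- match.arg(variance)
  fit_rows <- as.integer(fit_rows)
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  vals <- X$values
  cont <- which(X$feature_kind == "continuous")
  if (length(cont)) {
    sub <- vals[fit_rows, cont, drop = FALSE]
    mu <- colMeans(sub)
    nfit <- length(fit_rows)
    ss <- colSums(sweep(sub, 2L, mu)^2)
    vv <- if (variance == "population") ss / nfit else ss / max(1L, nfit - 1L)
    sdv <- sqrt(vv)
    zero <- sdv == 0
    if (any(zero)) {
      warning(sprintf("%d zero-variance continuous column(s) centered but not scaled",
                      sum(zero)))
      sdv[zero] <- 1
    }
    vals[, cont] <- sweep(sweep(vals[, cont, drop = FALSE], 2L, mu), 2L, sdv, "/")
  }
  X$values <- vals
  X
}
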