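#' Correlation-matrix PCA with Kaiser retention
#'
#' Standardizes each variable (centred by its mean, scaled by its standard
#' deviation) and eigendecomposes the correlation matrix. Components are
#' retained by the Kaiser criterion (eigenvalue > 1), and the variance
#' explained by component k is `eigenvalue_k / p * 100` since the
#' eigenvalues of a p-variable correlation matrix sum to p.
#'
#' @param x numeric matrix or data.frame, treatments in rows and at least
#'   two non-constant variables in columns (e.g. the survival,
#'   dispersal-rate, post-feeding-dispersal and on-plant-feeding
#'   proportions of each treatment).
#' @return object of class `pca_corr`: list with `eigenvalues`
#'   (descending), `eigenvectors` (unit-norm columns), `variance_explained`
#'   (percent, sums to 100), `retained` (count by the Kaiser rule),
#'   `scores` (standardized data projected on the eigenvectors).
#' @export
pca_correlation <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (ncol(x) < 2) abort("need >= 2 variables")
  if (nrow(x) < 3) abort("need >= 3 rows")
  if (anyNA(x)) abort("`x` must not contain missing values")
  sds <- apply(x, 2, sd)
  const <- sds == 0
  if (any(const))
    abort("constant column(s): ",
          paste(colnames(x)[const] %||% which(const), collapse = ", "))
  z <- scale(x, center = TRUE, scale = TRUE)
  ee <- eigen(cor(x), symmetric = TRUE)
  p <- ncol(x)
  structure(
    list(eigenvalues = ee$values,
         eigenvectors = ee$vectors,
         variance_explained = ee$values / p * 100,
         retained = kaiser_retained(ee$values),
         scores = z %*% ee$vectors),
    class = "pca_corr")
}

#' Kaiser criterion
#'
#' Number of principal components of a correlation-matrix PCA whose
#' eigenvalue exceeds 1.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @return integer count of retained components.
#' @export
kaiser_retained <- function(eigenvalues) {
  if (any(eigenvalues < -1e-8)) abort("eigenvalues must be non-negative")
  sum(eigenvalues > 1)
}

#' @export
print.pca_corr <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  cat("  eigenvalues:", paste(sprintf("%.4f", x$eigenvalues),
                              collapse = " "), "\n")
  cat("  variance explained (%):",
      paste(sprintf("%.2f", x$variance_explained), collapse = " "), "\n")
  cat(sprintf("  components retained (Kaiser): %d\n", x$retained))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need >= 3 observations")
  if (anyNA(x) || anyNA(y)) abort("inputs must not contain missing values")
  if (sd(x) == 0 || sd(y) == 0) abort("inputs must not be constant")
  cor(x, y, method = "pearson")
}
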