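#' Per-gene logistic calibration of raw expression
#'
#' For each gene j with mean \eqn{\mu_j} and variance \eqn{\sigma_j^2} across
#' samples, every raw value \eqn{g_{ij}} is mapped through a logistic curve
#' centred at the gene's mean and scaled by its \emph{variance}:
#' \deqn{s_{ij} = \frac{1}{1 + \exp(-(g_{ij} - \mu_j)/\sigma_j^2)}}
#' so that a value at the gene mean maps to exactly 0.5 and all outputs lie
#' strictly inside (0, 1). Note the divisor is the variance, not the standard
#' deviation: the transform is deliberately not invariant to rescaling a gene
#' column, so the dynamic range of a gene (in its original intensity units)
#' shapes how sharply it saturates.
#'
#' Outputs are clamped to \code{[eps, 1 - eps]} so extreme z-scores never
#' round to exactly 0 or 1 at double precision, preserving strict positivity
#' for downstream inner products and norms.
#'
#' @param expr Samples-by-genes numeric matrix (an \code{ExpressionMatrix}).
#' @param variance_policy What to do with a constant gene
#'   (\eqn{\sigma_j^2 = 0}): \code{"error"} (default) aborts naming the gene;
#'   \code{"drop"} removes it with a warning.
#' @param var_estimator \code{"sample"} (default, divisor m-1) or
#'   \code{"population"} (divisor m).
#' @param eps Clamp half-width, default \code{1e-12}.
#' @return A \code{CalibratedMatrix}: the calibrated samples-by-genes matrix
#'   with attributes \code{gene_means} and \code{gene_variances}.
#' @export
calibrate <- function(expr, variance_policy = c("error", "drop"),
                      var_estimator = c("sample", "population"),
                      eps = 1e-12) {
  variance_policy <- match.arg(variance_policy)
  var_estimator <- match.arg(var_estimator)
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  m <- nrow(expr)
  if (m < 2L) stop("need at least 2 samples to estimate per-gene variance")
  x <- unclass(expr)
  mu <- colMeans(x)
  centred <- sweep(x, 2L, mu, "-")
  ss <- colSums(centred^2)
  v <- if (var_estimator == "sample") ss / (m - 1L) else ss / m
  zero_var <- v <= 0 | !is.finite(v)
  if (any(zero_var)) {
    offenders <- colnames(x)[zero_var]
    if (variance_policy == "error") {
      stop("constant expression (zero variance) for gene(s): ",
           paste(offenders, collapse = ", "))
    }
    warning("dropping ", length(offenders), " constant gene(s): ",
            paste(offenders, collapse = ", "))
    keep <- !zero_var
    x <- x[, keep, drop = FALSE]
    centred <- centred[, keep, drop = FALSE]
    mu <- mu[keep]
    v <- v[keep]
    if (ncol(x) < 2L) stop("fewer than 2 genes remain after dropping constant genes")
  }
  z <- sweep(centred, 2L, v, "/")
  s <- stats::plogis(z)              # numerically stable logistic
  s <- pmin(pmax(s, eps), 1 - eps)
  dimnames(s) <- dimnames(x)
  attr(s, "gene_means") <- mu
  attr(s, "gene_variances") <- v
  class(s) <- c("CalibratedMatrix", "matrix", "array")
  s
}
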