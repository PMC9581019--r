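#' Similarity matrices for network construction
#'
#' Three gene-gene similarity measures share the same contract: a symmetric
#' n-by-n matrix with entries in [0, 1], gene ids on both axes, and a
#' \code{method} attribute. Symmetry is exact (upper triangle computed, then
#' mirrored), never approximate.
#'
#' @name similarity
NULL

# Row/column-scoped min-max rescaling: entry (i, j) is rescaled by the
# minimum and maximum over the union of row i and column j. For a symmetric
# input that union's extrema reduce to min/max of the two row extrema, so the
# result is symmetric by construction.
minmax_rowcol <- function(sym) {
  rmin <- apply(sym, 1L, min)
  rmax <- apply(sym, 1L, max)
  lo <- outer(rmin, rmin, pmin)
  hi <- outer(rmax, rmax, pmax)
  span <- hi - lo
  if (any(span <= 0)) {
    k <- which(span <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("degenerate similarity matrix: all entries in the scope of ",
                        "(%d, %d) are equal; min-max normalization is undefined"),
                 k[1L], k[2L]))
  }
  (sym - lo) / span
}

mirror_upper <- function(x) {
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  x
}

new_similarity <- function(values, gene_ids, method) {
  dimnames(values) <- list(gene_ids, gene_ids)
  attr(values, "method") <- method
  class(values) <- c("SimilarityMatrix", "matrix", "array")
  values
}

#' Min-max-normalised inner-product similarity
#'
#' First variant of the calibrated similarity: the raw score matrix is
#' \eqn{S' = S^T S} (entry (i, j) is the inner product of calibrated gene
#' columns i and j), then each entry is min-max rescaled by the extrema over
#' the union of its row and column of \eqn{S'}:
#' \deqn{m_{ij} = (s'_{ij} - \min_{ij}) / (\max_{ij} - \min_{ij}).}
#' Endpoints 0 and 1 occur exactly where an entry attains its scope minimum
#' or maximum; they are kept, not clipped. The diagonal is then set to 1.
#'
#' Unlike cosine similarity this measure is \emph{not} invariant to rescaling
#' a gene column: vector magnitudes carry information.
#'
#' @param cal A \code{CalibratedMatrix} (samples-by-genes, entries in (0,1)).
#' @return A \code{SimilarityMatrix}, method \code{"innerprod_minmax"}.
#' @export
innerprod_similarity <- function(cal) {
  check_positive_columns(cal)
  sp <- crossprod(unclass(cal))
  sp <- mirror_upper(sp)
  m <- minmax_rowcol(sp)
  m <- mirror_upper(m)
  diag(m) <- 1
  new_similarity(m, colnames(cal), "innerprod_minmax")
}

#' Cosine similarity of calibrated gene profiles
#'
#' Second variant: \eqn{m_{ij} = \langle S_i, S_j\rangle /
#' (\|S_i\|_2 \|S_j\|_2)}. Because calibrated values are strictly positive,
#' every off-diagonal entry is strictly positive; the diagonal is exactly 1.
#' Invariant to positive rescaling of any gene column.
#'
#' @param cal A \code{CalibratedMatrix}.
#' @return A \code{SimilarityMatrix}, method \code{"cosine"}.
#' @export
cosine_similarity <- function(cal) {
  check_positive_columns(cal)
  x <- unclass(cal)
  nrm <- sqrt(colSums(x^2))
  if (any(nrm <= 0)) {
    stop("zero-norm gene column(s): ", paste(colnames(x)[nrm <= 0], collapse = ", "))
  }
  m <- crossprod(x) / outer(nrm, nrm)
  m <- mirror_upper(m)
  m[m > 1] <- 1                       # guard rounding just above 1
  diag(m) <- 1
  new_similarity(m, colnames(cal), "cosine")
}

#' Pearson-correlation similarity with row/column min-max rescaling
#'
#' Baseline similarity: pairwise Pearson correlation of raw gene expression
#' columns, mapped into [0, 1] by the same row-and-column-scoped min-max
#' rescaling used for the inner-product variant (so negative correlations
#' land near 0 rather than being folded or shifted by the conventional
#' \eqn{(1 + r)/2}).
#'
#' @param expr Samples-by-genes numeric matrix of raw expression.
#' @return A \code{SimilarityMatrix}, method \code{"pearson_minmax"}.
#' @export
pearson_minmax_similarity <- function(expr) {
  x <- unclass(expr)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression (Pearson undefined) for gene(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  r <- mirror_upper(r)
  m <- minmax_rowcol(r)
  m <- mirror_upper(m)
  diag(m) <- 1
  new_similarity(m, colnames(x), "pearson_minmax")
}

check_positive_columns <- function(cal) {
  if (!is.matrix(cal) || !is.numeric(cal)) stop("expected a numeric matrix")
  if (any(cal <= 0) || any(cal >= 1)) {
    stop("calibrated values must lie strictly in (0, 1); run calibrate() first")
  }
  invisible(TRUE)
}
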