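#' Soft-threshold powering of a similarity matrix
#'
#' Raises every similarity to an integer power \eqn{\beta \ge 1} so that the
#' weighted degree distribution of the resulting network approximates a power
#' law. \code{beta = 1} is an exact pass-through of the similarities (useful
#' as a "no soft threshold" ablation). The diagonal is stored as 0: adjacency
#' self-loops never enter degree or topological-overlap computations.
#'
#' @param sim A \code{SimilarityMatrix} (symmetric, entries in [0, 1]).
#' @param beta Positive integer power.
#' @return An \code{AdjacencyMatrix} with attribute \code{beta}.
#' @export
power_adjacency <- function(sim, beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 1 || beta != round(beta)) {
    stop("beta must be a single integer >= 1")
  }
  if (any(sim < 0) || any(sim > 1)) stop("similarities must lie in [0, 1]")
  a <- unclass(sim)^beta
  diag(a) <- 0
  attr(a, "method") <- NULL
  attr(a, "beta") <- as.integer(beta)
  class(a) <- c("AdjacencyMatrix", "matrix", "array")
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Computes weighted degrees \eqn{k_i = \sum_{u \ne i} a_{iu}}, bins them
#' into \code{n_bins} equal-width bins, and regresses \eqn{\log_{10} p(k)}
#' on \eqn{\log_{10} \bar k} over the non-empty bins (\eqn{p(k)} = fraction
#' of nodes in the bin, \eqn{\bar k} = mean degree in the bin). For a
#' power-law degree distribution \eqn{p(k) \sim k^{-\Gamma}} the fit is a
#' line of slope \eqn{-\Gamma}; the returned \eqn{R^2} measures how closely
#' the network meets the scale-free criterion.
#'
#' @param adj An \code{AdjacencyMatrix} (zero diagonal).
#' @param n_bins Number of equal-width degree bins (default 10).
#' @return List with \code{r2}, \code{slope} (the fitted \eqn{-\Gamma}),
#'   \code{mean_k} (mean weighted degree) and \code{n_bins_used}.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  n <- nrow(adj)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (n < n_bins) stop("need at least as many nodes as bins")
  a <- unclass(adj)
  diag(a) <- 0
  k <- rowSums(a)
  if (diff(range(k)) <= .Machine$double.eps * max(abs(k), 1)) {
    stop("all degrees are equal; scale-free regression is undefined")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  kbar <- vapply(seq_len(n_bins), function(b) {
    if (counts[b] == 0L) NA_real_ else mean(k[as.integer(bin) == b])
  }, numeric(1))
  usable <- counts > 0L & is.finite(kbar) & kbar > 0
  if (sum(usable) < 3L) stop("fewer than 3 usable degree bins; cannot fit")
  x <- log10(kbar[usable])
  y <- log10(counts[usable] / n)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  list(r2 = r2,
       # signed fit index: positive only when p(k) decreases with k, the
       # direction a power law requires; a good fit with rising frequencies
       # is not scale-free topology
       r2_signed = -sign(slope) * r2,
       slope = slope,
       mean_k = mean(k),
       n_bins_used = sum(usable))
}

#' Choose a soft-threshold power by scale-free fit
#'
#' Evaluates \code{\link{scale_free_fit}} on \code{sim^beta} for each
#' candidate power and picks the smallest one whose \eqn{R^2} reaches
#' \code{r2_cut}. If no candidate reaches the cut, the power with the best
#' \eqn{R^2} is chosen and the report is flagged \code{not_scale_free}: some
#' data sets simply never meet the scale-free criterion, and the pipeline
#' proceeds on the best available power rather than failing.
#'
#' @param sim A \code{SimilarityMatrix}.
#' @param beta_grid Ascending integer candidate powers (default 1:20).
#' @param r2_cut Required \eqn{R^2} (default 0.85).
#' @param n_bins Degree bins for each fit (default 10).
#' @param min_mean_k Mean weighted-degree floor applied to the no-fit
#'   fallback (default 3): among the non-qualifying candidates, only powers
#'   that keep the network meaningfully connected compete on fit quality.
#' @return A \code{SoftThresholdReport}: list with \code{candidates}
#'   (data.frame beta / r2 / slope / mean_k), \code{chosen_beta},
#'   \code{r2_cut} and logical \code{not_scale_free}.
#' @export
pick_soft_threshold <- function(sim, beta_grid = 1:20, r2_cut = 0.85,
                                n_bins = 10L, min_mean_k = 3) {
  if (length(beta_grid) == 0L) stop("beta_grid is empty")
  beta_grid <- as.integer(beta_grid)
  if (is.unsorted(beta_grid, strictly = TRUE)) stop("beta_grid must be strictly ascending")
  rows <- lapply(beta_grid, function(b) {
    fit <- tryCatch(scale_free_fit(power_adjacency(sim, b), n_bins = n_bins),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(beta = b, r2 = NA_real_, r2_signed = NA_real_,
                 slope = NA_real_, mean_k = NA_real_)
    } else {
      data.frame(beta = b, r2 = fit$r2, r2_signed = fit$r2_signed,
                 slope = fit$slope, mean_k = fit$mean_k)
    }
  })
  cand <- do.call(rbind, rows)
  ok <- which(is.finite(cand$r2_signed))
  if (length(ok) == 0L) stop("scale-free fit failed for every candidate power")
  # qualification uses the signed index: the fit must be good AND the
  # degree frequencies must decrease with degree
  qualifying <- ok[cand$r2_signed[ok] >= r2_cut]
  if (length(qualifying) > 0L) {
    chosen <- cand$beta[qualifying[1L]]
    flagged <- FALSE
  } else {
    # no-fit fallback: best signed fit, but never a power that empties the
    # network — candidates below the mean-connectivity floor are a last resort
    connected <- ok[cand$mean_k[ok] >= min_mean_k]
    pool <- if (length(connected) > 0L) connected else ok
    chosen <- cand$beta[pool[which.max(cand$r2_signed[pool])]]
    flagged <- TRUE
  }
  report <- list(candidates = cand, chosen_beta = chosen, r2_cut = r2_cut,
                 not_scale_free = flagged)
  class(report) <- "SoftThresholdReport"
  report
}

#' Topological overlap matrix
#'
#' Reweights an adjacency matrix by second-order neighbourhood information:
#' \deqn{\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with shared-neighbour term \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}
#' and degree \eqn{k_i = \sum_{u \ne i} a_{iu}}. Two genes sharing many
#' strong neighbours get extra weight even if their direct link is modest.
#' For adjacency entries in [0, 1] the output lies in [0, 1]; the diagonal
#' is fixed at 1 by convention.
#'
#' @param adj An \code{AdjacencyMatrix} (symmetric, entries in [0, 1], zero
#'   diagonal).
#' @return A \code{TOMMatrix}.
#' @export
tom <- function(adj) {
  a <- unclass(adj)
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  # (a %*% a)[i,j] = sum_u a_iu a_uj; the u = i and u = j terms vanish
  # because the diagonal is zero, matching the u != i,j convention.
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  if (any(denom <= 0)) stop("non-positive TOM denominator; adjacency outside [0, 1]?")
  w <- (l + a) / denom
  w <- mirror_upper(w)
  w[w > 1] <- 1
  diag(w) <- 1
  dimnames(w) <- dimnames(adj)
  class(w) <- c("TOMMatrix", "matrix", "array")
  w
}
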