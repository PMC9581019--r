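#' Specification for a synthetic expression benchmark
#'
#' Describes a positive-valued expression matrix with planted co-expressed
#' gene modules and a matched annotation map with planted-enriched terms.
#' The defaults define the package's standard benchmark: 1000 genes, 50
#' samples, 5 planted modules of 150 genes each (the remaining 250 genes are
#' unstructured background), within-module correlation 0.7.
#'
#' Member genes of a module follow a single latent factor: gene = baseline +
#' loading x latent + Gaussian noise. With noise sd \eqn{\sigma} the loading
#' \eqn{\lambda = \sigma\sqrt{\rho/(1-\rho)}} gives expected within-module
#' pairwise correlation \eqn{\rho}. Background genes are baseline + noise
#' only. The matrix is shifted to strict positivity by its global minimum
#' plus a margin (shifting, unlike truncation, leaves planted correlations
#' untouched).
#'
#' @param n_genes Total genes (default 1000).
#' @param n_samples Samples (default 50).
#' @param n_modules Planted modules (default 5).
#' @param module_sizes Integer vector of module sizes, or a single size
#'   recycled (default 150 each).
#' @param rho Within-module correlation, strictly in (0, 1) (default 0.7).
#' @param noise_sd Gaussian noise sd in expression units (default 0.3,
#'   giving a per-gene total sd of about 0.55 on the log-intensity-like
#'   baseline scale of 5-15, typical of per-gene variability in processed
#'   microarray data; the variance-divisor calibration makes the absolute
#'   dispersion scale meaningful, so the generator pins it to a realistic
#'   one).
#' @param baseline_range Per-gene baseline intensity drawn uniformly from
#'   this positive range (default c(5, 15)).
#' @param terms_per_module Planted annotation terms per module (default 2).
#' @param term_precision Fraction of a planted term's genes that belong to
#'   its module (default 0.9).
#' @param term_recall Fraction of module genes carried by each planted term
#'   (default 0.8).
#' @param n_decoy_terms Random decoy terms spread over the three namespaces
#'   (default 30).
#' @param decoy_size_range Decoy term sizes drawn uniformly from this range
#'   (default c(20, 100)).
#' @param seed Integer RNG seed (default 1).
#' @return List of class \code{"SyntheticSpec"}.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_samples = 50L, n_modules = 5L,
                           module_sizes = 150L, rho = 0.7, noise_sd = 0.3,
                           baseline_range = c(5, 15), terms_per_module = 2L,
                           term_precision = 0.9, term_recall = 0.8,
                           n_decoy_terms = 30L, decoy_size_range = c(20L, 100L),
                           seed = 1L) {
  if (length(module_sizes) == 1L) module_sizes <- rep.int(module_sizes, n_modules)
  if (length(module_sizes) != n_modules) stop("module_sizes length must equal n_modules")
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(baseline_range <= 0) || baseline_range[1L] > baseline_range[2L]) {
    stop("baseline_range must be positive and ordered")
  }
  if (term_precision <= 0 || term_precision > 1 || term_recall <= 0 || term_recall > 1) {
    stop("term precision and recall must lie in (0, 1]")
  }
  if (n_samples < 2L || n_genes < 2L) stop("need at least 2 samples and 2 genes")
  spec <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
               n_modules = as.integer(n_modules),
               module_sizes = as.integer(module_sizes), rho = rho,
               noise_sd = noise_sd, baseline_range = baseline_range,
               terms_per_module = as.integer(terms_per_module),
               term_precision = term_precision, term_recall = term_recall,
               n_decoy_terms = as.integer(n_decoy_terms),
               decoy_size_range = as.integer(decoy_size_range),
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic expression matrix with planted modules
#'
#' See \code{\link{synthetic_spec}} for the generative model. Output is
#' deterministic for a fixed spec (including seed).
#'
#' @param spec A \code{SyntheticSpec}.
#' @return List with \code{expr} (an \code{ExpressionMatrix}) and
#'   \code{truth} (list: \code{labels} named integer vector of planted
#'   module labels, 0 = background; \code{module_terms} filled by
#'   \code{\link{generate_annotation}}).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_genes
  m <- spec$n_samples
  gene_ids <- sprintf("g%04d", seq_len(n))
  sample_ids <- sprintf("s%03d", seq_len(m))
  labels <- integer(n)
  idx <- 1L
  for (mod in seq_len(spec$n_modules)) {
    labels[idx:(idx + spec$module_sizes[mod] - 1L)] <- mod
    idx <- idx + spec$module_sizes[mod]
  }
  # loading chosen so that within-module pairwise correlation is rho;
  # at zero noise the latent factor alone drives the profile (correlation 1)
  sd_ref <- if (spec$noise_sd > 0) spec$noise_sd else 1
  loading <- sd_ref * sqrt(spec$rho / (1 - spec$rho))
  baseline <- stats::runif(n, spec$baseline_range[1L], spec$baseline_range[2L])
  latent <- matrix(stats::rnorm(m * spec$n_modules), nrow = m)
  x <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), nrow = m)
  for (j in seq_len(n)) {
    x[, j] <- x[, j] + baseline[j] +
      if (labels[j] > 0L) loading * latent[, labels[j]] else 0
  }
  lo <- min(x)
  if (lo <= 0) x <- x - lo + 0.01 * diff(range(x))   # shift, never truncate
  dimnames(x) <- list(sample_ids, gene_ids)
  names(labels) <- gene_ids
  list(expr = expression_matrix(x),
       truth = list(labels = labels, module_terms = NULL))
}

#' Generate an annotation map matched to planted modules
#'
#' For each planted module, \code{terms_per_module} terms are built whose
#' gene sets overlap the module at the spec's precision and recall: each term
#' carries \code{round(recall * size)} member genes plus enough random
#' outside genes to bring the member fraction down to \code{precision}.
#' Decoy terms draw genes uniformly from the whole gene set. Terms cycle
#' through the BP / CC / MF namespaces.
#'
#' @param truth Ground truth from \code{\link{generate_expression}}.
#' @param spec The same \code{SyntheticSpec}.
#' @return List with \code{annotation} (an \code{AnnotationMap}) and
#'   \code{truth} (input truth with \code{module_terms} filled: character
#'   vector of planted term ids per module).
#' @export
generate_annotation <- function(truth, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"), is.numeric(truth$labels))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed + 1000003L)

  gene_ids <- names(truth$labels)
  namespaces <- c("BP", "CC", "MF")
  rows <- list()
  module_terms <- vector("list", spec$n_modules)
  t_idx <- 0L
  for (mod in seq_len(spec$n_modules)) {
    members <- gene_ids[truth$labels == mod]
    outside <- gene_ids[truth$labels != mod]
    terms <- character(spec$terms_per_module)
    for (tt in seq_len(spec$terms_per_module)) {
      t_idx <- t_idx + 1L
      term_id <- sprintf("TERM:%04d", t_idx)
      terms[tt] <- term_id
      n_in <- max(1L, round(spec$term_recall * length(members)))
      inside <- sample(members, n_in)
      n_out <- round(n_in / spec$term_precision) - n_in
      extra <- if (n_out > 0L) sample(outside, min(n_out, length(outside))) else character(0)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term_id, namespace = namespaces[(t_idx - 1L) %% 3L + 1L],
        gene = c(inside, extra), stringsAsFactors = FALSE)
    }
    module_terms[[mod]] <- terms
  }
  for (dd in seq_len(spec$n_decoy_terms)) {
    t_idx <- t_idx + 1L
    sz_range <- spec$decoy_size_range[1L]:spec$decoy_size_range[2L]
    sz <- min(sz_range[sample.int(length(sz_range), 1L)], length(gene_ids))
    rows[[length(rows) + 1L]] <- data.frame(
      term = sprintf("DECOY:%04d", dd),
      namespace = namespaces[(t_idx - 1L) %% 3L + 1L],
      gene = sample(gene_ids, sz), stringsAsFactors = FALSE)
  }
  truth$module_terms <- module_terms
  list(annotation = annotation_map(do.call(rbind, rows)), truth = truth)
}

#' Generate a complete synthetic benchmark
#'
#' Expression matrix, annotation map and ground truth in one call.
#'
#' @param spec A \code{SyntheticSpec} (default: the standard benchmark).
#' @return List with \code{expr}, \code{annotation}, \code{truth}, \code{spec}.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  gen <- generate_expression(spec)
  ann <- generate_annotation(gen$truth, spec)
  list(expr = gen$expr, annotation = ann$annotation, truth = ann$truth,
       spec = spec)
}
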