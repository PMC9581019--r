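#' Exact hypergeometric enrichment test for one module-term pair
#'
#' With universe size \eqn{N}, term size \eqn{K = |term \cap universe|},
#' module size \eqn{n} and overlap \eqn{k = |module \cap term|}, the
#' over-representation p-value is \eqn{P(X \ge k)} and the
#' under-representation p-value \eqn{P(X \le k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}. Tails are exact
#' (\code{stats::phyper}); no normal approximation.
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   universe).
#' @param term_genes Character vector of genes annotated to the term
#'   (intersected with the universe before testing).
#' @param universe Character vector: the gene universe.
#' @param direction \code{"over"} or \code{"under"}.
#' @return List with \code{p_value}, \code{overlap}, \code{module_size},
#'   \code{term_size}, \code{universe_size}, \code{direction}.
#' @export
hypergeom_test <- function(module_genes, term_genes, universe,
                           direction = c("over", "under")) {
  direction <- match.arg(direction)
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(module_genes) == 0L) stop("empty module")
  if (!all(module_genes %in% universe)) stop("module genes must be a subset of the universe")
  term_in <- intersect(unique(term_genes), universe)
  N <- length(universe)
  K <- length(term_in)
  n_mod <- length(module_genes)
  k <- length(intersect(module_genes, term_in))
  p <- if (direction == "over") {
    stats::phyper(k - 1L, K, N - K, n_mod, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n_mod, lower.tail = TRUE)
  }
  list(p_value = p, overlap = k, module_size = n_mod, term_size = K,
       universe_size = N, direction = direction)
}

#' Enrichment of a module against every annotation term
#'
#' Runs the six test batteries — three namespaces (BP, CC, MF) times two
#' directions (over, under) — and pools the results. Every term with at
#' least one annotated gene in the universe is tested in its own namespace;
#' terms with no universe overlap are skipped.
#'
#' @param module_genes Character vector of module gene ids.
#' @param annotation An \code{AnnotationMap}.
#' @param universe Character vector: the gene universe.
#' @return data.frame with columns \code{term}, \code{namespace},
#'   \code{direction}, \code{p_value}, \code{overlap}, \code{term_size},
#'   \code{module_size}, \code{universe_size}, sorted by p-value then term.
#' @export
enrich_module <- function(module_genes, annotation, universe) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  if (length(annotation) == 0L) stop("annotation is empty")
  universe <- unique(universe)
  module_genes <- intersect(unique(module_genes), universe)
  if (length(module_genes) == 0L) stop("module has no genes in the universe")
  anno_genes <- unique(unlist(lapply(annotation, `[[`, "genes")))
  if (length(intersect(anno_genes, universe)) == 0L) {
    stop("annotation shares no genes with the universe")
  }
  rows <- list()
  for (term in names(annotation)) {
    entry <- annotation[[term]]
    K <- length(intersect(entry$genes, universe))
    if (K == 0L) next
    for (dir in c("over", "under")) {
      res <- hypergeom_test(module_genes, entry$genes, universe, dir)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, namespace = entry$namespace, direction = dir,
        p_value = res$p_value, overlap = res$overlap, term_size = res$term_size,
        module_size = res$module_size, universe_size = res$universe_size,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no testable terms (all terms outside the universe)")
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$term, out$direction), , drop = FALSE]
}

#' Module quality from its enrichment p-values
#'
#' Retains the five smallest p-values across all six test batteries (ties
#' broken by term id then direction, for determinism) and scores the module
#' as the negative log10 of their geometric mean:
#' \deqn{Q_j = -\frac{1}{5}\sum_{i=1}^{5} \log_{10} p_{i,j}.}
#' If fewer than five (term, direction) results exist, all available
#' p-values are used, the divisor becomes their count, and the result is
#' flagged.
#'
#' @param results data.frame from \code{\link{enrich_module}} (or any frame
#'   with columns \code{term}, \code{direction}, \code{p_value}).
#' @return List with \code{top} (the retained rows, ascending p),
#'   \code{Q} and logical \code{fewer_than_five}.
#' @export
module_quality <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no enrichment results")
  ord <- order(results$p_value, results$term, results$direction)
  top <- results[ord, , drop = FALSE][seq_len(min(5L, nrow(results))), , drop = FALSE]
  p <- top$p_value
  if (any(p <= 0)) stop("non-positive p-value; exact tails should be > 0")
  list(top = top,
       Q = -sum(log10(p)) / length(p),
       fewer_than_five = length(p) < 5L)
}

#' Average module quality of a pipeline
#'
#' \eqn{\bar Q = \sum_j Q_j / n_x} over the \eqn{n_x} modules a pipeline
#' produced (unassigned genes, label 0, never form a module).
#'
#' @param qualities Numeric vector of per-module Q scores.
#' @return The average quality.
#' @export
pipeline_quality <- function(qualities) {
  qualities <- as.numeric(qualities)
  if (length(qualities) == 0L || any(!is.finite(qualities))) {
    stop("need at least one finite module quality")
  }
  mean(qualities)
}

#' Score every module of an assignment
#'
#' Convenience wrapper: enriches each module of an assignment against an
#' annotation map and aggregates per-module qualities into a pipeline-level
#' report.
#'
#' @param assignment A \code{ModuleAssignment}.
#' @param annotation An \code{AnnotationMap}.
#' @param universe Character vector of gene ids (default: all genes in the
#'   assignment, annotated or not).
#' @return A \code{ModuleQualityReport}: list with \code{modules} (per-module
#'   list of label, size, Q, top terms), \code{Q_bar}, \code{n_modules},
#'   \code{pct_unassigned}.
#' @export
score_modules <- function(assignment, annotation, universe = NULL) {
  labels <- as_module_labels(assignment)
  if (is.null(universe)) universe <- names(labels)
  mods <- setdiff(sort(unique(labels)), 0L)
  if (length(mods) == 0L) stop("assignment contains no modules")
  per_module <- lapply(mods, function(l) {
    genes <- names(labels)[labels == l]
    res <- enrich_module(genes, annotation, universe)
    q <- module_quality(res)
    list(label = l, size = length(genes), Q = q$Q,
         top = q$top, fewer_than_five = q$fewer_than_five)
  })
  report <- list(modules = per_module,
                 Q_bar = pipeline_quality(vapply(per_module, `[[`, numeric(1), "Q")),
                 n_modules = length(mods),
                 pct_unassigned = round(100 * sum(labels == 0L) / length(labels), 1L))
  class(report) <- "ModuleQualityReport"
  report
}

#' Overlap of top-module terms between two pipelines
#'
#' Each report's best module (largest Q) retains five top terms; this
#' returns how many term ids the two five-term sets share (0..5).
#'
#' @param report_a,report_b \code{ModuleQualityReport} objects.
#' @return Integer overlap count.
#' @export
compare_top_terms <- function(report_a, report_b) {
  top_terms <- function(rep) {
    if (!inherits(rep, "ModuleQualityReport") || length(rep$modules) == 0L) {
      stop("report has no modules")
    }
    qs <- vapply(rep$modules, `[[`, numeric(1), "Q")
    unique(rep$modules[[which.max(qs)]]$top$term)
  }
  length(intersect(top_terms(report_a), top_terms(report_b)))
}

#' Clustering summary across pipelines
#'
#' For each assignment (all over the same gene universe): number of modules
#' and percentage of unassigned genes (one decimal).
#'
#' @param assignments Named list of \code{ModuleAssignment} objects.
#' @return data.frame with columns \code{pipeline}, \code{n_modules},
#'   \code{pct_unassigned}.
#' @export
clustering_summary <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) > 0L)
  universes <- lapply(assignments, function(a) sort(names(as_module_labels(a))))
  if (length(unique(vapply(universes, paste, character(1), collapse = "\r"))) != 1L) {
    stop("assignments cover different gene universes")
  }
  rows <- lapply(names(assignments), function(nm) {
    labels <- as_module_labels(assignments[[nm]])
    data.frame(pipeline = nm,
               n_modules = length(setdiff(unique(labels), 0L)),
               pct_unassigned = round(100 * sum(labels == 0L) / length(labels), 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
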