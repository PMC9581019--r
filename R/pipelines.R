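#' Pipeline configuration
#'
#' Bundles every tunable parameter of the four network-construction
#' pipelines. All fields have documented defaults and round-trip losslessly
#' through YAML (\code{\link{read_pipeline_config}} /
#' \code{\link{write_pipeline_config}}).
#'
#' @param beta_grid Candidate soft-threshold powers (default 1:20).
#' @param r2_cut Scale-free fit requirement (default 0.85).
#' @param n_bins Degree bins for the fit (default 10).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Tree-cut position as fraction of height range
#'   (default 0.99).
#' @param deep_split Tree-cut sensitivity 0-4 (default 2).
#' @param pam_stage Hybrid assignment stage on/off (default TRUE).
#' @param variance_policy Constant-gene policy for calibration
#'   (\code{"error"} or \code{"drop"}; default \code{"error"}).
#' @param seed RNG seed, only relevant for synthetic data (default 1).
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipeline_config <- function(beta_grid = 1:20, r2_cut = 0.85, n_bins = 10L,
                            min_module_size = 30L, cut_height = 0.99,
                            deep_split = 2L, pam_stage = TRUE,
                            variance_policy = "error", seed = 1L) {
  cfg <- list(beta_grid = as.integer(beta_grid), r2_cut = r2_cut,
              n_bins = as.integer(n_bins),
              min_module_size = as.integer(min_module_size),
              cut_height = cut_height, deep_split = as.integer(deep_split),
              pam_stage = isTRUE(pam_stage),
              variance_policy = match.arg(variance_policy, c("error", "drop")),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

#' @rdname pipeline_config
#' @param cfg A \code{PipelineConfig}.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run one network-construction pipeline end to end
#'
#' The four pipelines differ only in how the network is built; clustering
#' and scoring are shared, so differences in output isolate the calibration
#' and similarity choices:
#' \describe{
#'   \item{alpha}{calibrate, min-max-normalised inner product, soft
#'     threshold; cluster on 1 - adjacency (no TOM).}
#'   \item{beta}{calibrate, cosine similarity, soft threshold; cluster on
#'     1 - adjacency (no TOM).}
#'   \item{gamma}{beta's network plus the topological overlap transform;
#'     cluster on 1 - TOM.}
#'   \item{wgcna}{Pearson correlation with min-max rescaling (no
#'     calibration), soft threshold, TOM; cluster on 1 - TOM.}
#' }
#' Errors are tagged with the stage that raised them. The pipelines are
#' deterministic: a seed only matters for synthetic data generation.
#'
#' @param expr Samples-by-genes \code{ExpressionMatrix}.
#' @param pipeline One of \code{"alpha"}, \code{"beta"}, \code{"gamma"},
#'   \code{"wgcna"}.
#' @param config A \code{PipelineConfig}.
#' @param annotation Optional \code{AnnotationMap}; when supplied, modules
#'   are scored and a \code{ModuleQualityReport} is attached.
#' @return A \code{PipelineResult}: list with \code{pipeline},
#'   \code{assignment}, \code{soft_threshold}, \code{quality} (or NULL),
#'   \code{config} and a \code{provenance} block (package version, chosen
#'   beta, matrix shape, timestamp).
#' @export
run_pipeline <- function(expr, pipeline = c("alpha", "beta", "gamma", "wgcna"),
                         config = pipeline_config(), annotation = NULL) {
  pipeline <- match.arg(pipeline)
  stopifnot(inherits(config, "PipelineConfig"))
  sim <- switch(pipeline,
    alpha = {
      cal <- stage("calibration", calibrate(expr, variance_policy = config$variance_policy))
      stage("similarity", innerprod_similarity(cal))
    },
    beta = ,
    gamma = {
      cal <- stage("calibration", calibrate(expr, variance_policy = config$variance_policy))
      stage("similarity", cosine_similarity(cal))
    },
    wgcna = stage("similarity", pearson_minmax_similarity(expr)))
  st <- stage("soft_threshold",
              pick_soft_threshold(sim, beta_grid = config$beta_grid,
                                  r2_cut = config$r2_cut, n_bins = config$n_bins))
  adj <- stage("adjacency", power_adjacency(sim, st$chosen_beta))
  net <- if (pipeline %in% c("gamma", "wgcna")) stage("tom", tom(adj)) else adj
  dmat <- stage("dissimilarity", dissimilarity(net))
  dend <- stage("linkage", average_linkage(dmat))
  assignment <- stage("tree_cut",
                      dynamic_tree_cut(dend, dmat,
                                       min_module_size = config$min_module_size,
                                       cut_height = config$cut_height,
                                       deep_split = config$deep_split,
                                       pam_stage = config$pam_stage))
  quality <- if (!is.null(annotation)) {
    stage("enrichment", score_modules(assignment, annotation))
  } else NULL
  result <- list(pipeline = pipeline,
                 assignment = assignment,
                 soft_threshold = st,
                 quality = quality,
                 dendrogram = dend,
                 config = config,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("calgcn")),
                   n_samples = nrow(expr), n_genes = ncol(expr),
                   chosen_beta = st$chosen_beta,
                   not_scale_free = st$not_scale_free,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  class(result) <- "PipelineResult"
  result
}

#' @rdname run_pipeline
#' @export
run_alpha <- function(expr, config = pipeline_config(), annotation = NULL) {
  run_pipeline(expr, "alpha", config, annotation)
}

#' @rdname run_pipeline
#' @export
run_beta <- function(expr, config = pipeline_config(), annotation = NULL) {
  run_pipeline(expr, "beta", config, annotation)
}

#' @rdname run_pipeline
#' @export
run_gamma <- function(expr, config = pipeline_config(), annotation = NULL) {
  run_pipeline(expr, "gamma", config, annotation)
}

#' @rdname run_pipeline
#' @export
run_wgcna_style <- function(expr, config = pipeline_config(), annotation = NULL) {
  run_pipeline(expr, "wgcna", config, annotation)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult [%s]: %d genes x %d samples\n", x$pipeline,
              x$provenance$n_genes, x$provenance$n_samples))
  cat(sprintf("  soft threshold beta = %d%s\n", x$soft_threshold$chosen_beta,
              if (x$soft_threshold$not_scale_free) " (no scale-free fit; best R2 used)" else ""))
  cat(sprintf("  modules = %d, unassigned = %d (%.1f%%)\n",
              x$assignment$n_modules, x$assignment$n_unassigned,
              100 * x$assignment$n_unassigned / length(x$assignment$labels)))
  if (!is.null(x$quality)) {
    cat(sprintf("  Q_bar = %.3f over %d modules\n", x$quality$Q_bar,
                x$quality$n_modules))
  }
  invisible(x)
}

#' Run all four pipelines and compare them
#'
#' Produces the standard comparison artefacts: a clustering summary (module
#' count and unassigned percentage per pipeline), average module quality
#' per pipeline with a 95 percent confidence interval derived from the
#' standard deviation of the per-module Q scores, and the pairwise overlap
#' of the five top terms of each pipeline's best module.
#'
#' @param expr Samples-by-genes \code{ExpressionMatrix}.
#' @param annotation An \code{AnnotationMap}.
#' @param config A \code{PipelineConfig}.
#' @param pipelines Which pipelines to run (default all four).
#' @return List of class \code{"PipelineComparison"}: \code{results} (per
#'   pipeline), \code{summary} (data.frame pipeline / n_modules /
#'   pct_unassigned / Q_bar / Q_bar_lo / Q_bar_hi) and \code{top_term_overlap}
#'   (symmetric integer matrix).
#' @export
compare_pipelines <- function(expr, annotation, config = pipeline_config(),
                              pipelines = c("alpha", "beta", "gamma", "wgcna")) {
  results <- lapply(pipelines, function(p) run_pipeline(expr, p, config, annotation))
  names(results) <- pipelines
  summary_df <- clustering_summary(lapply(results, `[[`, "assignment"))
  qstats <- t(vapply(results, function(r) {
    qs <- vapply(r$quality$modules, `[[`, numeric(1), "Q")
    half <- if (length(qs) > 1L) 1.96 * stats::sd(qs) / sqrt(length(qs)) else 0
    c(r$quality$Q_bar, r$quality$Q_bar - half, r$quality$Q_bar + half)
  }, numeric(3)))
  summary_df$Q_bar <- qstats[, 1L]
  summary_df$Q_bar_lo <- qstats[, 2L]
  summary_df$Q_bar_hi <- qstats[, 3L]
  k <- length(pipelines)
  overlap <- matrix(NA_integer_, k, k, dimnames = list(pipelines, pipelines))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- compare_top_terms(results[[i]]$quality, results[[j]]$quality)
  }
  out <- list(results = results, summary = summary_df, top_term_overlap = overlap)
  class(out) <- "PipelineComparison"
  out
}

#' Bar chart of average module quality per pipeline
#'
#' Base-graphics bar plot of Q_bar with 95 percent confidence-interval
#' error bars, one bar per pipeline. Higher is better.
#'
#' @param comparison A \code{PipelineComparison}.
#' @param ... Passed to \code{barplot}.
#' @return Invisibly, the bar midpoints.
#' @export
plot_quality_comparison <- function(comparison, ...) {
  s <- comparison$summary
  mids <- graphics::barplot(s$Q_bar, names.arg = s$pipeline,
                            ylab = "average module quality (Q_bar)",
                            ylim = c(0, max(s$Q_bar_hi) * 1.1), ...)
  graphics::arrows(mids, s$Q_bar_lo, mids, s$Q_bar_hi,
                   angle = 90, code = 3, length = 0.05)
  invisible(mids)
}

#' Serialise a quality report or soft-threshold report to JSON
#'
#' @param x A \code{ModuleQualityReport}, \code{SoftThresholdReport} or
#'   \code{PipelineResult}.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  payload <- if (inherits(x, "ModuleQualityReport")) {
    list(modules = lapply(x$modules, function(mo) {
      list(label = mo$label, size = mo$size, Q = mo$Q,
           top5 = lapply(seq_len(nrow(mo$top)), function(i) {
             list(term = mo$top$term[i], namespace = mo$top$namespace[i],
                  direction = mo$top$direction[i], p = mo$top$p_value[i])
           }))
    }), Q_bar = x$Q_bar, n_modules = x$n_modules,
    pct_unassigned = x$pct_unassigned)
  } else if (inherits(x, "SoftThresholdReport")) {
    list(candidates = x$candidates, chosen_beta = x$chosen_beta,
         r2_cut = x$r2_cut, flagged = x$not_scale_free)
  } else if (inherits(x, "PipelineResult")) {
    list(pipeline = x$pipeline,
         chosen_beta = x$soft_threshold$chosen_beta,
         not_scale_free = x$soft_threshold$not_scale_free,
         n_modules = x$assignment$n_modules,
         n_unassigned = x$assignment$n_unassigned,
         provenance = x$provenance)
  } else stop("unsupported object for JSON serialisation")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
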