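#' Network dissimilarity
#'
#' Converts a similarity, adjacency or topological-overlap matrix (entries in
#' [0, 1]) into the dissimilarity \eqn{d_{ij} = 1 - w_{ij}} used for
#' hierarchical clustering. The diagonal is set to 0.
#'
#' @param net Symmetric numeric matrix with entries in [0, 1].
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
dissimilarity <- function(net) {
  x <- unclass(net)
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("expected a square matrix")
  if (any(x < 0) || any(x > 1)) stop("network weights must lie in [0, 1]")
  d <- 1 - x
  d <- mirror_upper(d)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Builds the gene dendrogram by unweighted pair-group average linkage over a
#' dissimilarity matrix, via \code{stats::hclust}. Deterministic for a given
#' input.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal).
#' @return An object of class \code{hclust}.
#' @export
average_linkage <- function(d) {
  if (!is.matrix(d) || nrow(d) < 2L) stop("need at least 2 genes to cluster")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Dynamic tree cut: shape-aware module detection on a dendrogram
#'
#' Detects modules by a dynamic hybrid procedure in two stages.
#'
#' \strong{Tree stage.} The dendrogram is cut just below its top: the
#' effective cut height is \code{cut_height} of the joining-height range
#' (5th percentile to maximum), so \code{cut_height = 0.99} removes only the
#' topmost merges. Branches hanging above the cut with fewer than
#' \code{min_module_size} leaves go to the unassigned pool. Each remaining
#' branch is then decomposed recursively by the shape of the tree: a merge is
#' treated as a real module boundary when both sides are large enough and at
#' least one side is \emph{distinct} — its own internal joining height sits
#' at least a minimum gap below the merge. Branches whose top merge is tight
#' (internal height below a scatter ceiling) are emitted whole as modules;
#' loose branches shed undersized side-branches to the pool and keep
#' descending. \code{deep_split} (0-4) controls the sensitivity: larger
#' values shrink the required gap and raise the scatter ceiling, producing
#' more, smaller modules.
#'
#' \strong{Hybrid (PAM-like) stage.} Each pooled gene is assigned to the
#' module with the smallest average dissimilarity to its members, provided
#' that average does not exceed \code{max_pam_dist} (default: the effective
#' cut height); otherwise it stays unassigned (label 0).
#'
#' Modules are renumbered 1..k by decreasing size. Every reported module has
#' at least \code{min_module_size} members before the hybrid stage and can
#' only grow during it.
#'
#' @param dend \code{hclust} tree from \code{\link{average_linkage}}.
#' @param d The dissimilarity matrix the tree was built from.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Static cut position as a fraction of the joining-height
#'   range (default 0.99).
#' @param deep_split Split sensitivity, integer 0-4 (default 2).
#' @param pam_stage Run the hybrid assignment stage (default \code{TRUE};
#'   \code{FALSE} gives the pure tree-shape variant).
#' @param max_pam_dist Maximum average dissimilarity for hybrid assignment;
#'   default the effective cut height.
#' @return A \code{ModuleAssignment}: list with \code{labels} (named integer
#'   vector, 0 = unassigned), \code{n_modules}, \code{module_sizes},
#'   \code{n_unassigned} and \code{cut_height_used}.
#' @export
dynamic_tree_cut <- function(dend, d, min_module_size = 30L, cut_height = 0.99,
                             deep_split = 2L, pam_stage = TRUE,
                             max_pam_dist = NULL) {
  if (!inherits(dend, "hclust")) stop("dend must be an hclust tree")
  if (min_module_size < 1L) stop("min_module_size must be at least 1")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must lie in (0, 1]")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  n <- length(dend$order)
  if (!is.matrix(d) || nrow(d) != n || ncol(d) != n) {
    stop("dissimilarity matrix does not match the dendrogram")
  }
  merge <- dend$merge
  heights <- dend$height
  gene_ids <- if (!is.null(dend$labels)) dend$labels else as.character(seq_len(n))

  # degenerate flat tree: no shape to cut on
  h_lo <- stats::quantile(heights, 0.05, names = FALSE)
  h_hi <- max(heights)
  if (h_hi - h_lo <= .Machine$double.eps * max(abs(h_hi), 1)) {
    labels <- rep.int(if (n >= min_module_size) 1L else 0L, n)
    names(labels) <- gene_ids
    return(module_assignment(labels, cut_height_used = h_hi))
  }
  if (n < min_module_size) {
    labels <- stats::setNames(integer(n), gene_ids)
    return(module_assignment(labels, cut_height_used = h_hi))
  }
  h_cut <- h_lo + cut_height * (h_hi - h_lo)
  # deep_split 0..4 -> required merge gap shrinks, scatter ceiling grows
  gap_min <- (4.5 - deep_split) / 4.5 * 0.25 * (h_hi - h_lo)
  scatter_max <- h_lo + (0.64 + 0.08 * deep_split) * (h_hi - h_lo)

  node_size <- integer(n - 1L)
  for (r in seq_len(n - 1L)) {
    node_size[r] <- sum(ifelse(merge[r, ] < 0, 1L, node_size[pmax(merge[r, ], 1L)]))
  }
  child_height <- function(id) if (id < 0) 0 else heights[id]
  child_size <- function(id) if (id < 0) 1L else node_size[id]
  leaves_of <- function(id) {
    out <- integer(0)
    stack <- id
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (cur < 0) out[length(out) + 1L] <- -cur
      else stack <- c(stack, merge[cur, ])
    }
    out
  }

  clusters <- list()
  pool <- integer(0)
  # phase tags: "cut" = above the static cut (only split/shed),
  # "decompose" = below it (gap-based boundary detection)
  stack_id <- (n - 1L)   # root merge row
  stack_phase <- if (heights[n - 1L] > h_cut) "cut" else "decompose"
  while (length(stack_id) > 0L) {
    node <- stack_id[length(stack_id)]
    phase <- stack_phase[length(stack_phase)]
    stack_id <- stack_id[-length(stack_id)]
    stack_phase <- stack_phase[-length(stack_phase)]

    kids <- merge[node, ]
    ksize <- c(child_size(kids[1L]), child_size(kids[2L]))
    kh <- c(child_height(kids[1L]), child_height(kids[2L]))

    if (phase == "cut") {
      for (c_i in 1:2) {
        if (ksize[c_i] < min_module_size) {
          pool <- c(pool, leaves_of(kids[c_i]))
        } else {
          sub_phase <- if (kh[c_i] > h_cut) "cut" else "decompose"
          stack_id <- c(stack_id, kids[c_i])
          stack_phase <- c(stack_phase, sub_phase)
        }
      }
      next
    }

    h_node <- heights[node]
    distinct <- (h_node - kh) >= gap_min
    big <- ksize >= min_module_size
    if (all(big) && any(distinct)) {
      # real boundary between two viable branches: split
      for (c_i in 1:2) {
        stack_id <- c(stack_id, kids[c_i])
        stack_phase <- c(stack_phase, "decompose")
      }
    } else if (h_node <= scatter_max) {
      # tight branch: one module
      clusters[[length(clusters) + 1L]] <- leaves_of(node)
    } else {
      # loose branch that cannot be split into two viable modules
      if (!any(big)) {
        # both halves undersized and the whole is loose: noise, not a module
        pool <- c(pool, leaves_of(node))
      } else {
        # shed undersized side-branches, keep descending into the rest
        for (c_i in 1:2) {
          if (big[c_i]) {
            stack_id <- c(stack_id, kids[c_i])
            stack_phase <- c(stack_phase, "decompose")
          } else {
            pool <- c(pool, leaves_of(kids[c_i]))
          }
        }
      }
    }
  }
  # leaves can only reach the stack as merge rows; a 2-leaf tree root is
  # handled by the decompose branch above (tight or pooled)

  # core trimming: members that are dissimilarity outliers within their
  # branch (boxplot rule on average within-branch dissimilarity) return to
  # the pool; the hybrid stage below decides their fate. Keeps each module
  # at or above min_module_size.
  for (ci in seq_along(clusters)) {
    repeat {
      mem <- clusters[[ci]]
      if (length(mem) <= min_module_size) break
      db <- vapply(seq_along(mem),
                   function(i) mean(d[mem[i], mem[-i]]), numeric(1))
      qs <- stats::quantile(db, c(0.25, 0.75), names = FALSE)
      # outliers must exceed the boxplot fence by a meaningful margin on the
      # [0,1] dissimilarity scale, so microscopic spreads trim nothing
      cutoff <- qs[2L] + max(1.5 * (qs[2L] - qs[1L]), 0.02)
      out <- db > cutoff
      if (!any(out)) break
      if (length(mem) - sum(out) < min_module_size) {
        keep_n <- length(mem) - min_module_size
        out <- rank(-db, ties.method = "first") <= keep_n & out
        if (!any(out)) break
      }
      pool <- c(pool, mem[out])
      clusters[[ci]] <- mem[!out]
    }
  }

  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci

  if (is.null(max_pam_dist)) max_pam_dist <- h_cut
  if (pam_stage && length(clusters) > 0L && length(pool) > 0L) {
    pool <- sort(unique(pool))
    # a pooled gene may join the nearest module, but only if it is no
    # farther from it than the module's most peripheral current member
    # (and within max_pam_dist); outliers stay unassigned
    periphery <- vapply(clusters, function(mem) {
      max(vapply(seq_along(mem),
                 function(i) mean(d[mem[i], mem[-i]]), numeric(1)))
    }, numeric(1))
    for (g in pool) {
      avg <- vapply(clusters, function(mem) mean(d[g, mem]), numeric(1))
      best <- which.min(avg)    # ties -> lowest cluster index
      if (avg[best] <= min(max_pam_dist, periphery[best])) labels[g] <- best
    }
  }
  names(labels) <- gene_ids
  module_assignment(labels, cut_height_used = h_cut)
}

#' Construct a ModuleAssignment
#'
#' Renumbers non-zero labels to contiguous integers 1..k ordered by
#' decreasing module size (ties broken by smallest member index, for
#' determinism) and records summary counts.
#'
#' @param labels Named integer vector of raw labels (0 = unassigned).
#' @param cut_height_used Optional height recorded for provenance.
#' @return List of class \code{"ModuleAssignment"}.
#' @export
module_assignment <- function(labels, cut_height_used = NA_real_) {
  stopifnot(is.numeric(labels), !is.null(names(labels)))
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (any(labels < 0)) stop("module labels must be >= 0")
  old <- setdiff(sort(unique(labels)), 0L)
  if (length(old) > 0L) {
    sizes <- vapply(old, function(l) sum(labels == l), integer(1))
    first_member <- vapply(old, function(l) which(labels == l)[1L], integer(1))
    ord <- order(-sizes, first_member)
    remap <- stats::setNames(seq_along(old), old[ord])
    new_labels <- labels
    nz <- labels != 0L
    new_labels[nz] <- remap[as.character(labels[nz])]
    labels <- stats::setNames(as.integer(new_labels), names(labels))
  }
  k <- length(old)
  out <- list(labels = labels,
              n_modules = k,
              module_sizes = if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0),
              n_unassigned = sum(labels == 0L),
              cut_height_used = cut_height_used)
  class(out) <- "ModuleAssignment"
  out
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:", length(x$labels), "genes,", x$n_modules, "modules,",
      x$n_unassigned, sprintf("unassigned (%.1f%%)",
                              100 * x$n_unassigned / length(x$labels)), "\n")
  if (x$n_modules > 0L) {
    cat("module sizes:", paste(x$module_sizes, collapse = ", "), "\n")
  }
  invisible(x)
}
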