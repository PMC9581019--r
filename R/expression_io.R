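#' Read an expression matrix from delimited text
#'
#' Parses a TSV/CSV expression table into a samples-by-genes numeric matrix.
#' The delimiter is auto-detected (tab or comma), a header row is required,
#' and an optional first column of sample identifiers is recognised when its
#' header cell is empty or non-numeric rows carry one more field than the
#' header. GEO series-matrix style tables (genes as rows) are supported via
#' \code{orientation = "genes_by_samples"} and transposed on load.
#'
#' Values are used as deposited: no log-transform or normalisation is applied.
#' Missing values (\code{NA}, \code{"NA"}, empty cells) are rejected by
#' default; \code{impute = TRUE} replaces them with the per-gene mean.
#'
#' @param path Path to a delimited text file.
#' @param orientation Either \code{"samples_by_genes"} (default; header =
#'   gene ids) or \code{"genes_by_samples"} (header = sample ids; the matrix
#'   is transposed after reading).
#' @param impute Impute missing cells with the per-gene mean instead of
#'   failing. Default \code{FALSE}.
#' @return A numeric samples-by-genes matrix of class \code{"ExpressionMatrix"}
#'   with sample ids as rownames and gene ids as colnames.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes", "genes_by_samples"),
                            impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", colClasses = "character")
  if (nrow(df) < 1L || ncol(df) < 2L) {
    stop("expression table must have at least 2 rows and 2 columns of data")
  }
  # first column = row identifiers if it is not fully numeric
  header <- colnames(df)            # before subsetting, which mangles dups
  first <- df[[1L]]
  first_numeric <- !anyNA(suppressWarnings(as.numeric(first)))
  if (!first_numeric) {
    row_ids <- first
    body <- df[, -1L, drop = FALSE]
    col_ids <- header[-1L]
  } else {
    row_ids <- sprintf("row_%d", seq_len(nrow(df)))
    body <- df
    col_ids <- header
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate gene identifiers in header: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    missing_tok <- is.na(cell) | cell == "" | toupper(cell) %in% c("NA", "NAN", "NULL")
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) & !missing_tok
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   cell[i], i, col_ids[j]))
    }
    if (any(missing_tok)) {
      if (!impute) {
        i <- which(missing_tok)[1L]
        stop(sprintf("missing value at row %d, column '%s' (use impute = TRUE for per-gene mean imputation)",
                     i, col_ids[j]))
      }
      num[missing_tok] <- mean(num[!missing_tok])
      if (all(missing_tok)) stop("column '", col_ids[j], "' is entirely missing")
    }
    vals[, j] <- num
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "genes_by_samples") vals <- t(vals)
  expression_matrix(vals)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else if (n_com > 0L) "," else "\t"
}

#' Construct and validate an ExpressionMatrix
#'
#' Validates a numeric samples-by-genes matrix: at least 2 samples and
#' 2 genes, all values finite, no duplicate gene or sample identifiers.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   dimnames.
#' @return The matrix with class \code{"ExpressionMatrix"} prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("expression matrix needs at least 2 samples and 2 genes (got ",
         nrow(values), " x ", ncol(values), ")")
  }
  if (is.null(rownames(values))) rownames(values) <- sprintf("sample_%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) stop("gene identifiers (colnames) are required")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

#' Write an expression matrix to delimited text
#'
#' @param expr Samples-by-genes numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(sample = rownames(expr), unclass(expr)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation map (term, namespace, gene) from delimited text
#'
#' Expects three columns: term id, namespace (one of BP, CC, MF, mirroring
#' the three gene-ontology namespaces), gene id. Rows are grouped by term;
#' a term listed under two namespaces is an error.
#'
#' @param path Path to a three-column delimited file (header required).
#' @return An object of class \code{"AnnotationMap"}: a named list with one
#'   entry per term, each a list with elements \code{namespace} and
#'   \code{genes} (character vector).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (nrow(df) == 0L) stop("annotation file is empty")
  if (ncol(df) < 3L) stop("annotation file needs 3 columns: term, namespace, gene")
  annotation_map(data.frame(term = as.character(df[[1L]]),
                            namespace = as.character(df[[2L]]),
                            gene = as.character(df[[3L]]),
                            stringsAsFactors = FALSE))
}

#' Construct and validate an AnnotationMap
#'
#' @param df data.frame with columns \code{term}, \code{namespace},
#'   \code{gene} (one row per term-gene pair).
#' @return Named list of class \code{"AnnotationMap"}; see
#'   \code{\link{read_annotation}}.
#' @export
annotation_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("term", "namespace", "gene") %in% names(df)))
  if (nrow(df) == 0L) stop("annotation is empty")
  bad_ns <- setdiff(unique(df$namespace), c("BP", "CC", "MF"))
  if (length(bad_ns) > 0L) {
    stop("unknown namespace token(s): ", paste(bad_ns, collapse = ", "),
         " (expected BP, CC or MF)")
  }
  by_term <- split(df, df$term)
  entries <- lapply(by_term, function(rows) {
    ns <- unique(rows$namespace)
    if (length(ns) != 1L) {
      stop("term '", rows$term[1L], "' listed under multiple namespaces: ",
           paste(ns, collapse = ", "))
    }
    genes <- unique(rows$gene)
    if (length(genes) == 0L) stop("term '", rows$term[1L], "' has an empty gene set")
    list(namespace = ns, genes = genes)
  })
  entries <- entries[order(names(entries))]
  class(entries) <- "AnnotationMap"
  entries
}

#' Write an annotation map as three-column TSV
#'
#' Inverse of \code{\link{read_annotation}} (terms sorted by id).
#'
#' @param anno An \code{AnnotationMap}.
#' @param path Output path.
#' @export
write_annotation <- function(anno, path) {
  stopifnot(inherits(anno, "AnnotationMap"))
  rows <- do.call(rbind, lapply(names(anno), function(term) {
    data.frame(term = term, namespace = anno[[term]]$namespace,
               gene = anno[[term]]$genes, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module assignment as two-column TSV
#'
#' One row per gene in input order: gene id and integer module label
#' (0 = unassigned).
#'
#' @param assignment Named integer vector (names = gene ids) or
#'   \code{ModuleAssignment}.
#' @param path Output path.
#' @export
write_modules <- function(assignment, path) {
  labels <- as_module_labels(assignment)
  if (length(labels) == 0L) stop("module assignment is empty")
  df <- data.frame(gene = names(labels), module = unname(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module assignment written by \code{write_modules}
#'
#' @param path Path to a two-column TSV (gene, module).
#' @return Named integer vector of module labels.
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  labels <- as.integer(df[[2L]])
  names(labels) <- as.character(df[[1L]])
  labels
}

as_module_labels <- function(assignment) {
  if (inherits(assignment, "ModuleAssignment")) return(assignment$labels)
  if (is.numeric(assignment) && !is.null(names(assignment))) {
    labels <- as.integer(assignment)
    names(labels) <- names(assignment)
    return(labels)
  }
  stop("expected a ModuleAssignment or a named integer vector")
}
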