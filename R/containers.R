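#' Validate and normalise an expression matrix
#'
#' The package-wide container for expression data is a genes x cells numeric
#' matrix (dense `matrix` or `Matrix::dgCMatrix`) with unique, non-empty row
#' (gene) and column (cell) names. Values must be finite and non-negative;
#' they may be raw or normalised counts -- every score downstream depends only
#' on within-cell ranks.
#'
#' @param m matrix-like object, genes in rows, cells in columns.
#' @return the validated matrix, coerced to `dgCMatrix` when sparse-friendly.
#' @export
as_expression_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!(is.matrix(m) || inherits(m, "Matrix")))
    stop("expression matrix must be a matrix or Matrix object", call. = FALSE)
  gid <- rownames(m)
  cid <- colnames(m)
  if (is.null(gid) || is.null(cid))
    stop("expression matrix must carry gene (row) and cell (column) names",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L], call. = FALSE)
  if (anyDuplicated(cid))
    stop("duplicate cell id: ", cid[duplicated(cid)][1L], call. = FALSE)
  vals <- if (inherits(m, "Matrix")) m@x else m
  if (any(!is.finite(vals)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(vals < 0))
    stop("expression matrix contains negative values", call. = FALSE)
  m
}

#' Construct a gene-set collection
#'
#' A gene-set collection is a named list of character vectors of gene
#' identifiers (the "signatures"), with an optional description per set
#' (GMT column 2). Set names must be unique, and genes within a set unique.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && is.null(names(sets)))
    stop("gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L],
         call. = FALSE)
  sets <- lapply(sets, as.character)
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]]))
      stop("duplicate gene within set ", nm, call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep(NA_character_, length(sets))
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection with", length(x), "set(s)\n")
  if (length(x) > 0) {
    sz <- lengths(x)
    cat("  set sizes: min", min(sz), "/ median", stats::median(sz),
        "/ max", max(sz), "\n")
    show <- utils::head(names(x), 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' `[` keeps the collection class and descriptions in step
#' @export
`[.gene_set_collection` <- function(x, i) {
  y <- unclass(x)[i]
  gene_set_collection(y, attr(x, "descriptions")[names(y)])
}

#' Validate cluster labels against an expression matrix
#'
#' Labels are a factor (or character) vector named by cell id, mapping each
#' cell to its cluster. For differential analysis at least two clusters are
#' required and every cluster must hold at least three cells.
#'
#' @param labels named factor or character vector (names = cell ids).
#' @param m optional expression matrix the labels must cover.
#' @param for_differential if TRUE, enforce the >= 2 clusters / >= 3 cells
#'   per cluster constraints.
#' @return the labels as a named factor.
#' @export
as_cluster_labels <- function(labels, m = NULL, for_differential = TRUE) {
  if (is.null(names(labels)))
    stop("cluster labels must be named by cell id", call. = FALSE)
  labels <- stats::setNames(factor(labels), names(labels))
  if (!is.null(m)) {
    missing <- setdiff(names(labels), colnames(m))
    if (length(missing) > 0)
      stop("labelled cell not in matrix: ", missing[1L], call. = FALSE)
  }
  if (for_differential) {
    tab <- table(labels)
    if (length(tab) < 2L)
      stop("differential analysis needs >= 2 clusters", call. = FALSE)
    if (any(tab < 3L))
      stop("cluster with < 3 cells: ", names(tab)[tab < 3L][1L], call. = FALSE)
  }
  labels
}
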