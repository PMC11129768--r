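#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet layout (a `.mtx` coordinate
#' file with `features.tsv`/`genes.tsv` and `barcodes.tsv` sidecars, plain or
#' gzipped) and dense CSV/TSV matrices whose first column holds gene ids and
#' whose header holds cell ids. The returned matrix is always genes x cells;
#' pass `transpose = TRUE` for files stored cells x genes.
#'
#' @param path for `mtx10x`, either the directory holding the triplet or the
#'   `.mtx` file itself; for `csv`/`tsv`, the file.
#' @param format one of "auto", "mtx10x", "csv", "tsv". "auto" keys off the
#'   path (directory or `.mtx` suffix -> mtx10x; `.csv` -> csv; else tsv).
#' @param transpose logical; input is stored cells x genes.
#' @return a validated genes x cells matrix (sparse for mtx10x input).
#' @export
read_expression <- function(path, format = c("auto", "mtx10x", "csv", "tsv"),
                            transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) "mtx10x"
              else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  m <- switch(format,
    mtx10x = read_mtx10x(path),
    csv    = read_dense(path, sep = ","),
    tsv    = read_dense(path, sep = "\t"))
  if (transpose) m <- t(m)
  as_expression_matrix(m)
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = ", "), " found in ", dir,
       call. = FALSE)
}

read_mtx10x <- function(path) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  } else {
    dir <- dirname(path)
    mtx <- path
    if (!file.exists(mtx)) stop("no such file: ", mtx, call. = FALSE)
  }
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  if (nrow(features) != nrow(m))
    stop("feature sidecar has ", nrow(features), " rows but matrix has ",
         nrow(m), " genes", call. = FALSE)
  if (nrow(barcodes) != ncol(m))
    stop("barcode sidecar has ", nrow(barcodes), " rows but matrix has ",
         ncol(m), " cells", call. = FALSE)
  dimnames(m) <- list(features[[1L]], barcodes[[1L]])
  m
}

read_dense <- function(path, sep) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, quote = "")
  as.matrix(df)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `mtx10x` writes `matrix.mtx`,
#' `features.tsv` and `barcodes.tsv` into the directory `path`; `csv`/`tsv`
#' write a dense table with gene ids in the first column.
#'
#' @inheritParams read_expression
#' @param m genes x cells matrix.
#' @export
write_expression <- function(m, path, format = c("mtx10x", "csv", "tsv")) {
  format <- match.arg(format)
  m <- as_expression_matrix(m)
  if (format == "mtx10x") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(m, "dMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each tab-separated line is: set name, description, then gene ids. File
#' order of sets and of genes within a set is preserved. Duplicate genes
#' within a set are dropped (first occurrence kept) with a warning; a
#' duplicate set name or a line with fewer than three fields is an error.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " field(s); need >= 3",
           call. = FALSE)
    nm <- f[[1L]]
    if (nm %in% names(sets))
      stop("duplicate set name in GMT: ", nm, call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("set ", nm, ": dropped ", sum(duplicated(genes)),
              " duplicate gene(s), keeping first occurrence", call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    sets[[nm]] <- genes
    desc[[nm]] <- f[[2L]]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_set_collection()].
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("na", length(sets))
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-to-cluster label table
#'
#' Expects a TSV with header `cell<TAB>cluster`.
#'
#' @param path TSV file.
#' @return named factor of cluster labels.
#' @export
read_cluster_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("cell", "cluster") %in% names(df)))
    stop("cluster table must have columns 'cell' and 'cluster'", call. = FALSE)
  stats::setNames(factor(df$cluster), df$cell)
}

#' Write a cell-to-cluster label table
#' @param labels named factor/character of cluster labels.
#' @param path output TSV.
#' @export
write_cluster_labels <- function(labels, path) {
  utils::write.table(
    data.frame(cell = names(labels), cluster = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with zero expression in every cell
#'
#' Cells are never dropped; relative order of surviving genes is preserved.
#' All-zero cells are kept but reported via a message, since rank-based
#' scores remain defined (all-tied ranks) for such cells.
#'
#' @param m genes x cells matrix.
#' @return the filtered matrix.
#' @export
filter_zero_genes <- function(m) {
  m <- as_expression_matrix(m)
  keep <- Matrix::rowSums(m) > 0
  if (!any(keep)) stop("matrix empty after filtering", call. = FALSE)
  out <- m[keep, , drop = FALSE]
  n_zero_cells <- sum(Matrix::colSums(out) == 0)
  if (n_zero_cells > 0)
    message(n_zero_cells, " all-zero cell(s) retained")
  out
}

#' Restrict a gene-set collection to a matrix's genes
#'
#' Each set is intersected with the matrix's gene ids (exact, case-sensitive
#' string match); sets whose intersection falls outside `[min_size,
#' max_size]` are dropped, with a message reporting the count.
#'
#' @param sets a [gene_set_collection()].
#' @param m genes x cells matrix.
#' @param min_size,max_size inclusive bounds on post-intersection set size.
#' @return the restricted collection.
#' @export
restrict_collection <- function(sets, m, min_size = 5L, max_size = 500L) {
  genes <- rownames(m)
  kept <- list()
  for (nm in names(sets)) {
    g <- sets[[nm]][sets[[nm]] %in% genes]
    if (length(g) >= min_size && length(g) <= max_size) kept[[nm]] <- g
  }
  n_drop <- length(sets) - length(kept)
  if (n_drop > 0)
    message("dropped ", n_drop, " gene set(s) outside [", min_size, ", ",
            max_size, "] after intersection")
  if (length(kept) == 0)
    stop("no gene set survives restriction to the matrix", call. = FALSE)
  gene_set_collection(kept, attr(sets, "descriptions")[names(kept)])
}
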