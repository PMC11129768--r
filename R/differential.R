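#' Two-sided Wilcoxon rank-sum test
#'
#' Thin, mode-explicit surface over the rank-sum test used for per-cluster
#' differential testing. `mode = "auto"` uses the exact null distribution
#' when the combined sample size is at most 25 and there are no ties, and
#' the normal approximation with tie and continuity corrections otherwise.
#' When every value in both samples is identical the test carries no
#' information and p is exactly 1.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode "auto", "exact" or "normal".
#' @return list with `statistic` (the Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- switch(mode,
    auto = length(pooled) <= 25L && !has_ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && has_ties) {
    warning("ties present: falling back to the normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-cluster differential gene-set testing
#'
#' For each scoring method and each cluster, every gene set's per-cell
#' scores in the cluster are compared against all other cells (one-vs-rest)
#' with the two-sided Wilcoxon rank-sum test. P-values are Bonferroni
#' adjusted within each (method, cluster) across the gene sets tested,
#' mirroring per-cluster marker testing. Direction is `up` when the mean
#' score in the cluster exceeds the mean elsewhere (ties resolve to `up`).
#'
#' @param scores named list of `score_matrix` objects sharing cell ids.
#' @param labels cluster labels (named by cell id; see
#'   [as_cluster_labels()]).
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param mode test mode forwarded to [wilcoxon_rank_sum()].
#' @return a `differential_table` data frame with columns `method`,
#'   `cluster`, `set_name`, `avg_diff`, `statistic`, `p_value`,
#'   `p_adjusted`, `direction`, `significant`, ordered by (method, cluster,
#'   p ascending).
#' @export
differential_all <- function(scores, labels, alpha = 0.05, mode = "auto") {
  if (inherits(scores, "score_matrix")) scores <- list(scores)
  cells <- colnames(scores[[1L]]$scores)
  for (sm in scores)
    if (!identical(colnames(sm$scores), cells))
      stop("score matrices must share identical cell ids", call. = FALSE)
  labels <- labels[cells]
  if (anyNA(labels)) stop("labels must cover every scored cell", call. = FALSE)
  labels <- as_cluster_labels(stats::setNames(labels, cells))
  clusters <- levels(labels)
  rows <- list()
  for (sm in scores) {
    n_sets <- nrow(sm$scores)
    for (cl in clusters) {
      in_cl <- labels == cl
      res <- lapply(rownames(sm$scores), function(set) {
        v <- sm$scores[set, ]
        x <- v[in_cl]; y <- v[!in_cl]
        w <- wilcoxon_rank_sum(x, y, mode = mode)
        data.frame(method = sm$method, cluster = cl, set_name = set,
                   avg_diff = mean(x) - mean(y), statistic = w$statistic,
                   p_value = w$p_value, stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, res)
      block$p_adjusted <- pmin(1, block$p_value * n_sets)
      block$direction <- ifelse(block$avg_diff > 0, "up",
                                ifelse(block$avg_diff < 0, "down", "up"))
      block$significant <- block$p_adjusted <= alpha
      block <- block[order(block$p_value, block$set_name), , drop = FALSE]
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Write a differential table as TSV
#' @param d a `differential_table`.
#' @param path output file.
#' @export
write_differential <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential table written by [write_differential()]
#' @param path TSV file.
#' @param alpha significance threshold recorded on the table.
#' @export
read_differential <- function(path, alpha = 0.05) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  attr(d, "alpha") <- alpha
  class(d) <- c("differential_table", "data.frame")
  d
}
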