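#' Rank-based gene-set enrichment analysis of clustered single cells
#'
#' The main entry point: scores every cell against a gene-set collection
#' with the requested rank-based methods, tests each set per cluster
#' (one-vs-rest Wilcoxon, Bonferroni within method x cluster), aggregates
#' the per-method significant rankings with robust rank aggregation into
#' one corrected p-value per set, cluster and direction, and (optionally)
#' computes the pairwise Kendall-W concordance among methods.
#'
#' @param m genes x cells expression matrix (raw or normalised counts).
#' @param sets a [gene_set_collection()] (e.g. from [read_gmt()]).
#' @param labels cluster labels named by cell id.
#' @param methods scoring methods to run (default: all six).
#' @param params a [scoring_params()].
#' @param alpha significance threshold on adjusted p-values (default 0.05).
#' @param dialect RRA rank-normalisation dialect, see [normalize_ranks()].
#' @param min_size,max_size gene-set size bounds after intersection with
#'   the matrix, see [restrict_collection()].
#' @param filter_genes drop all-zero genes before scoring (default TRUE).
#' @param concordance also compute the Kendall-W [concordance_report()]
#'   (default TRUE).
#' @return object of class `rank_gsea`: list with `scores`, `differential`,
#'   `rra`, `concordance`, `sets`, `labels`, `params`, `alpha`, `call`.
#' @examples
#' sim <- simulate_sc(sim_config(n_genes = 300, n_cells_per_cluster = 30,
#'                               n_sets = 6, set_size = 10, n_planted = 2,
#'                               seed = 7))
#' fit <- rank_gsea(sim$matrix, sim$sets, sim$labels,
#'                  methods = c("ucell", "singscore"))
#' print(fit)
#' @export
rank_gsea <- function(m, sets, labels, methods = score_methods,
                      params = scoring_params(), alpha = 0.05,
                      dialect = c("union", "paper"), min_size = 5L,
                      max_size = 500L, filter_genes = TRUE,
                      concordance = TRUE) {
  dialect <- match.arg(dialect)
  m <- as_expression_matrix(m)
  if (filter_genes) m <- filter_zero_genes(m)
  labels <- as_cluster_labels(labels, m)
  sets <- restrict_collection(sets, m, min_size = min_size,
                              max_size = max_size)
  scores <- score_all(m, sets, params, methods)
  d <- differential_all(scores, labels, alpha = alpha)
  r <- rra_aggregate(d, methods = methods, alpha = alpha, dialect = dialect)
  conc <- if (concordance && length(scores) >= 2) concordance_report(scores)
          else NULL
  structure(list(scores = scores, differential = d, rra = r,
                 concordance = conc, sets = sets, labels = labels,
                 params = params, alpha = alpha, dialect = dialect,
                 call = match.call()),
            class = "rank_gsea")
}

#' @export
print.rank_gsea <- function(x, ...) {
  cat("Rank-based gene-set enrichment analysis\n")
  cat("  methods:   ", paste(names(x$scores), collapse = ", "), "\n")
  cat("  gene sets: ", length(x$sets), "   cells: ",
      ncol(x$scores[[1L]]$scores), "   clusters: ",
      nlevels(x$labels), "\n", sep = "")
  sig <- x$rra[x$rra$p_corrected <= x$alpha, , drop = FALSE]
  cat("  RRA-significant (p_corrected <= ", x$alpha, "): ", nrow(sig),
      " set x cluster x direction call(s)\n", sep = "")
  if (nrow(sig) > 0)
    print(utils::head(sig[, c("cluster", "direction", "set_name",
                              "p_corrected", "n_methods_detected")], 10L),
          row.names = FALSE)
  invisible(x)
}

#' @export
summary.rank_gsea <- function(object, ...) {
  x <- object
  per_method <- stats::aggregate(
    significant ~ method + cluster, data = x$differential, FUN = sum)
  sig <- x$rra[x$rra$p_corrected <= x$alpha, , drop = FALSE]
  per_cluster <- if (nrow(sig) > 0)
    stats::aggregate(set_name ~ cluster + direction, data = sig,
                     FUN = length)
  else NULL
  out <- list(methods = names(x$scores), alpha = x$alpha,
              dialect = x$dialect,
              significant_per_method_cluster = per_method,
              rra_significant_per_cluster = per_cluster,
              overall_median_W =
                if (!is.null(x$concordance)) x$concordance$overall_median
                else NA_real_)
  class(out) <- "summary.rank_gsea"
  out
}

#' @export
print.summary.rank_gsea <- function(x, ...) {
  cat("rank_gsea summary (alpha =", x$alpha, ", RRA dialect =", x$dialect,
      ")\n")
  cat("Significant sets per method and cluster (Wilcoxon + Bonferroni):\n")
  print(x$significant_per_method_cluster, row.names = FALSE)
  cat("RRA-significant sets per cluster and direction:\n")
  if (is.null(x$rra_significant_per_cluster)) cat("  none\n")
  else print(x$rra_significant_per_cluster, row.names = FALSE)
  if (!is.na(x$overall_median_W))
    cat("Overall median pairwise Kendall W:", signif(x$overall_median_W, 4),
        "\n")
  invisible(x)
}

#' Plot a rank_gsea result
#'
#' Renders one of the summary views from its plot-data table.
#'
#' @param x a `rank_gsea` object.
#' @param kind "stackbar" (default), "heatmap", "bubble" or "upset".
#' @param file optional output file; when NULL, plots to the active device.
#' @param ... ignored.
#' @export
plot.rank_gsea <- function(x, kind = c("stackbar", "heatmap", "bubble",
                                       "upset"), file = NULL, ...) {
  kind <- match.arg(kind)
  pt <- switch(kind,
    stackbar = stackbar_table(x$differential, x$rra, alpha = x$alpha),
    heatmap = heatmap_table(x$rra),
    bubble = bubble_table(x$rra),
    upset = upset_table(x$rra, alpha = x$alpha))
  if (is.null(file)) {
    file <- tempfile(fileext = ".pdf")
    render_plot(pt, file)
    message("rendered to ", file)
  } else {
    render_plot(pt, file)
  }
  invisible(pt)
}
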