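#' Kendall's coefficient of concordance for two raters
#'
#' Treats two score vectors over the same cells as two raters ranking the
#' cells and computes Kendall's W with tie correction:
#' `W = 12 S / (m^2 (n^3 - n) - m T)` with `m = 2`, `S` the sum of squared
#' deviations of per-cell rank sums, and `T` the summed tie corrections
#' `sum(t^3 - t)` over tie groups of both raters. `W` is 1 for identical
#' rankings and tends to 0 for exactly reversed rankings as `n` grows. When
#' both vectors are constant there is no ranking information and `NA` is
#' returned.
#'
#' @param a,b numeric vectors of equal length (>= 3).
#' @return W in [0, 1], or NA when undefined.
#' @export
kendall_w_pair <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 3) stop("need equal lengths >= 3", call. = FALSE)
  ra <- rank(a)
  rb <- rank(b)
  tie_term <- function(r) {
    t <- table(r)
    sum(t^3 - t)
  }
  T_corr <- tie_term(ra) + tie_term(rb)
  m <- 2
  denom <- m^2 * (n^3 - n) - m * T_corr
  if (denom <= 0) return(NA_real_)
  R <- ra + rb
  S <- sum((R - mean(R))^2)
  12 * S / denom
}

#' Concordance report across scoring methods
#'
#' For every pair of scoring methods and every gene set, computes the
#' two-rater Kendall W of the per-cell scores, then summarises by the median
#' W per method pair and the overall median. This is the package's
#' construction of "consistency among scoring methods": pairwise agreement
#' of how each method orders the cells for a given signature.
#'
#' @param scores named list of `score_matrix` objects sharing gene sets and
#'   cells (see [score_all()]).
#' @return list of class `concordance_report` with `per_set` (data frame:
#'   `method_a`, `method_b`, `set_name`, `W`), `pair_medians` and
#'   `overall_median`.
#' @export
concordance_report <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 score matrices", call. = FALSE)
  sets <- rownames(scores[[1L]]$scores)
  cells <- colnames(scores[[1L]]$scores)
  for (sm in scores)
    if (!identical(rownames(sm$scores), sets) ||
        !identical(colnames(sm$scores), cells))
      stop("score matrices must share gene sets and cells", call. = FALSE)
  methods <- unname(vapply(scores, `[[`, character(1), "method"))
  pairs <- utils::combn(seq_along(scores), 2L)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    W <- vapply(sets, function(set) {
      kendall_w_pair(scores[[i]]$scores[set, ], scores[[j]]$scores[set, ])
    }, numeric(1))
    rows[[p]] <- data.frame(method_a = methods[i], method_b = methods[j],
                            set_name = sets, W = unname(W),
                            stringsAsFactors = FALSE)
  }
  per_set <- do.call(rbind, rows)
  rownames(per_set) <- NULL
  pair_medians <- stats::aggregate(W ~ method_a + method_b, data = per_set,
                                   FUN = stats::median, na.rm = TRUE)
  pair_medians <- pair_medians[order(-pair_medians$W), , drop = FALSE]
  rownames(pair_medians) <- NULL
  structure(list(per_set = per_set, pair_medians = pair_medians,
                 overall_median = stats::median(per_set$W, na.rm = TRUE)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report (pairwise two-rater Kendall W over cells)\n")
  cat("  overall median W:", signif(x$overall_median, 4), "\n")
  cat("  method-pair medians:\n")
  print(x$pair_medians, row.names = FALSE)
  invisible(x)
}

#' Write a concordance report (per-set TSV + pair-median summary TSV)
#' @param report a `concordance_report`.
#' @param dir output directory.
#' @export
write_concordance <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$per_set, file.path(dir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$pair_medians,
                     file.path(dir, "concordance_pair_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
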