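#' Scoring parameters
#'
#' Bundles the tunable parameters shared by the six per-cell scoring methods.
#'
#' @param aucell_top_fraction fraction of the ranked gene list forming the
#'   AUCell-style recovery window (default 0.05, i.e. the top 5 percent of
#'   genes per cell).
#' @param ucell_max_rank rank cap for the UCell-style score (default 1500);
#'   ranks beyond the cap are truncated to `ucell_max_rank + 1`.
#' @param ssgsea_alpha weight exponent of the ssGSEA-style running sum
#'   (default 0.25).
#' @param jasmine_enrichment enrichment component of the JASMINE-style score:
#'   "oddsratio" (default) or "likelihood".
#' @param ties tie policy forwarded to [rank_cell()].
#' @param seed integer seed (used only by `ties = "random"`).
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(aucell_top_fraction = 0.05,
                           ucell_max_rank = 1500L,
                           ssgsea_alpha = 0.25,
                           jasmine_enrichment = c("oddsratio", "likelihood"),
                           ties = "average",
                           seed = NULL) {
  jasmine_enrichment <- match.arg(jasmine_enrichment)
  stopifnot(aucell_top_fraction > 0, aucell_top_fraction <= 1,
            ucell_max_rank >= 2, ssgsea_alpha >= 0)
  structure(list(aucell_top_fraction = aucell_top_fraction,
                 ucell_max_rank = as.integer(ucell_max_rank),
                 ssgsea_alpha = ssgsea_alpha,
                 jasmine_enrichment = jasmine_enrichment,
                 ties = ties, seed = seed),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring parameters:\n")
  for (nm in names(x))
    cat("  ", nm, ": ", if (is.null(x[[nm]])) "NULL" else x[[nm]], "\n",
        sep = "")
  invisible(x)
}

score_methods <- c("aucell", "ucell", "singscore", "ssgsea", "jasmine",
                   "viper")

new_score_matrix <- function(method, scores, params, components = NULL) {
  if (any(!is.finite(scores)))
    stop("non-finite entries in ", method, " score matrix", call. = FALSE)
  structure(list(method = method, scores = scores, params = params,
                 components = components),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Score matrix [", x$method, "]: ", nrow(x$scores), " gene set(s) x ",
      ncol(x$scores), " cell(s)\n", sep = "")
  cat("  score range: ", signif(min(x$scores), 4), " .. ",
      signif(max(x$scores), 4), "\n", sep = "")
  invisible(x)
}

# shared entry checks; returns list(m dense, set index list, n, rd or ra)
score_setup <- function(m, sets, params) {
  m <- as.matrix(as_expression_matrix(m))
  if (length(sets) == 0) stop("empty gene-set collection", call. = FALSE)
  idx <- lapply(sets, function(g) {
    i <- match(g, rownames(m))
    if (anyNA(i))
      stop("gene set contains genes absent from the matrix; ",
           "call restrict_collection() first (missing: ",
           g[is.na(i)][1L], ")", call. = FALSE)
    i
  })
  list(m = m, idx = idx, n = nrow(m))
}

#' AUCell-style recovery-curve score
#'
#' For each cell, genes are ranked by decreasing expression and a recovery
#' curve counts how many gene-set members appear within the top
#' `L = ceiling(aucell_top_fraction * n_genes)` ranks. The score is the area
#' under that curve divided by its maximum attainable value (the set's genes
#' packing the very top ranks), so it lies in [0, 1] with 1 meaning the set
#' fills the top of the cell's ranking and 0 meaning no member enters the
#' window.
#'
#' @param m genes x cells expression matrix.
#' @param sets a [gene_set_collection()] already restricted to `m`'s genes.
#' @param params a [scoring_params()].
#' @return a `score_matrix` object.
#' @export
score_aucell <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  rd <- rank_matrix_desc(s$m, params$ties, params$seed)
  L <- ceiling(params$aucell_top_fraction * s$n)
  if (L < 1) stop("top fraction too small for n_genes", call. = FALSE)
  out <- matrix(0, length(s$idx), ncol(s$m),
                dimnames = list(names(sets), colnames(s$m)))
  for (k in seq_along(s$idx)) {
    i <- s$idx[[k]]
    ns <- length(i)
    # each member at rank r contributes |{x in 1..L : x >= r}| to the curve
    contrib <- pmax(L - ceiling(rd[i, , drop = FALSE]) + 1, 0)
    max_raw <- sum(pmin(seq_len(L), ns))
    out[k, ] <- colSums(contrib) / max_raw
  }
  new_score_matrix("aucell", out, params)
}

#' UCell-style Mann-Whitney U score
#'
#' Ranks are computed per cell, capped at `ucell_max_rank + 1` to blunt the
#' uninformative tail, and converted to the Mann-Whitney U statistic of the
#' set's members against the best possible packing:
#' `U = sum(r*) - n_s (n_s + 1) / 2`, `score = 1 - U / (n_s * ucell_max_rank)`
#' clamped at 0.
#'
#' @inheritParams score_aucell
#' @return a `score_matrix` object.
#' @export
score_ucell <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  rd <- rank_matrix_desc(s$m, params$ties, params$seed)
  rmax <- params$ucell_max_rank
  rstar <- pmin(rd, rmax + 1)
  out <- matrix(0, length(s$idx), ncol(s$m),
                dimnames = list(names(sets), colnames(s$m)))
  for (k in seq_along(s$idx)) {
    i <- s$idx[[k]]
    ns <- length(i)
    U <- colSums(rstar[i, , drop = FALSE]) - ns * (ns + 1) / 2
    out[k, ] <- pmax(0, 1 - U / (ns * rmax))
  }
  new_score_matrix("ucell", out, params)
}

#' singscore-style normalised mean-rank score
#'
#' The mean ascending rank of the set's members is rescaled between its
#' theoretical minimum `(n_s + 1) / 2` (set least expressed) and maximum
#' `(2n - n_s + 1) / 2` (set most expressed), giving a score in [0, 1].
#'
#' @inheritParams score_aucell
#' @return a `score_matrix` object.
#' @export
score_singscore <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  ra <- rank_matrix_asc(s$m, params$ties, params$seed)
  out <- matrix(0, length(s$idx), ncol(s$m),
                dimnames = list(names(sets), colnames(s$m)))
  for (k in seq_along(s$idx)) {
    i <- s$idx[[k]]
    ns <- length(i)
    if (ns == s$n)
      stop("gene set equals the whole gene universe; score undefined",
           call. = FALSE)
    meanrank <- colMeans(ra[i, , drop = FALSE])
    min_pos <- (ns + 1) / 2
    max_pos <- (2 * s$n - ns + 1) / 2
    out[k, ] <- (meanrank - min_pos) / (max_pos - min_pos)
  }
  new_score_matrix("singscore", out, params)
}

#' ssGSEA-style running-sum enrichment score
#'
#' Per cell, genes are ordered by decreasing expression (ties kept in input
#' order); list position `i` carries weight `(n - i + 1)^alpha`. The score is
#' the sum over positions of the gap between the weighted in-set empirical
#' CDF and the uniform out-of-set CDF. No across-cell range normalisation is
#' applied, so scores are unbounded reals and each cell's score depends on
#' that cell alone.
#'
#' @inheritParams score_aucell
#' @return a `score_matrix` object.
#' @export
score_ssgsea <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  n <- s$n
  alpha <- params$ssgsea_alpha
  in_set <- lapply(s$idx, function(i) {
    v <- logical(n); v[i] <- TRUE; v
  })
  if (any(lengths(s$idx) == n))
    stop("gene set equals the whole gene universe; score undefined",
         call. = FALSE)
  z <- (n:1)^alpha                      # weight of list position 1..n
  out <- matrix(0, length(s$idx), ncol(s$m),
                dimnames = list(names(sets), colnames(s$m)))
  for (j in seq_len(ncol(s$m))) {
    ord <- order(s$m[, j], decreasing = TRUE)
    for (k in seq_along(s$idx)) {
      mask <- in_set[[k]][ord]
      ns <- length(s$idx[[k]])
      p_in <- cumsum(z * mask) / sum(z[mask])
      p_out <- cumsum(!mask) / (n - ns)
      out[k, j] <- sum(p_in - p_out)
    }
  }
  new_score_matrix("ssgsea", out, params)
}

#' JASMINE-style dropout-aware score
#'
#' Per cell, only expressed (nonzero) genes enter. The mean component `RM` is
#' the mean descending rank of the set's expressed members divided by the
#' number of expressed genes (0.5 when no member is expressed). The
#' enrichment component contrasts the expressed/not-expressed split of set
#' members against non-members in a 2x2 table, as an odds ratio (default;
#' Haldane +0.5 on all four cells when any count is zero) or a likelihood
#' ratio. `1 - RM` and the enrichment component are each min-max scaled
#' across cells to [0, 1] and averaged. The unscaled components are kept in
#' `$components`, since the min-max step is the only part of the score that
#' depends on the cell cohort.
#'
#' @inheritParams score_aucell
#' @return a `score_matrix` object with `$components` holding the unscaled
#'   `rm` and `enrichment` matrices.
#' @export
score_jasmine <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  n <- s$n
  n_cells <- ncol(s$m)
  rm_mat <- matrix(0.5, length(s$idx), n_cells,
                   dimnames = list(names(sets), colnames(s$m)))
  or_mat <- matrix(1, length(s$idx), n_cells,
                   dimnames = list(names(sets), colnames(s$m)))
  any_empty <- FALSE
  for (j in seq_len(n_cells)) {
    v <- s$m[, j]
    expr <- v > 0
    ne <- sum(expr)
    if (ne == 0) { any_empty <- TRUE; next }    # components stay at null
    rexp <- numeric(n)
    rexp[expr] <- rank_cell(v[expr], ties = params$ties, seed = params$seed,
                            cell_id = colnames(s$m)[j])$rank_desc
    for (k in seq_along(s$idx)) {
      i <- s$idx[[k]]
      ns <- length(i)
      member_expr <- expr[i]
      a <- sum(member_expr)
      b <- ns - a
      cc <- ne - a
      d <- (n - ns) - cc
      if (a > 0) rm_mat[k, j] <- mean(rexp[i[member_expr]]) / ne
      if (params$jasmine_enrichment == "oddsratio") {
        if (a == 0 || b == 0 || cc == 0 || d == 0) {
          a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
        }
        or_mat[k, j] <- (a * d) / (b * cc)
      } else {
        if (a == 0 || b == 0 || cc == 0 || d == 0) {
          a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
        }
        or_mat[k, j] <- (a / (a + b)) / (cc / (cc + d))
      }
    }
  }
  if (any_empty)
    warning("cell(s) with no expressed genes: JASMINE components set to ",
            "their null values", call. = FALSE)
  scale01 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0.5, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  final <- matrix(0, length(s$idx), n_cells,
                  dimnames = list(names(sets), colnames(s$m)))
  for (k in seq_along(s$idx))
    final[k, ] <- (scale01(1 - rm_mat[k, ]) + scale01(or_mat[k, ])) / 2
  new_score_matrix("jasmine", final, params,
                   components = list(rm = rm_mat, enrichment = or_mat))
}

#' Viper-style normalised enrichment score
#'
#' Ascending ranks are mapped to interior quantiles
#' `q = (rank_asc - 0.5) / n` and through the standard-normal quantile
#' function. For unsigned gene sets (every member mode +1, weight 1) the
#' three-tailed regulon combination collapses to this two-tail term, so the
#' enrichment score is the mean transformed quantile over the set and the
#' reported score is `NES = mean * sqrt(n_s)`. Under within-cell i.i.d. noise
#' the NES is approximately standard normal.
#'
#' @inheritParams score_aucell
#' @return a `score_matrix` object.
#' @export
score_viper <- function(m, sets, params = scoring_params()) {
  s <- score_setup(m, sets, params)
  ra <- rank_matrix_asc(s$m, params$ties, params$seed)
  t2 <- stats::qnorm((ra - 0.5) / s$n)
  out <- matrix(0, length(s$idx), ncol(s$m),
                dimnames = list(names(sets), colnames(s$m)))
  for (k in seq_along(s$idx)) {
    i <- s$idx[[k]]
    out[k, ] <- colMeans(t2[i, , drop = FALSE]) * sqrt(length(i))
  }
  new_score_matrix("viper", out, params)
}

#' Score a matrix with several rank-based methods
#'
#' Dispatches to the six per-cell scoring functions; every returned matrix
#' shares the same gene-set and cell ordering.
#'
#' @inheritParams score_aucell
#' @param methods character subset of
#'   `c("aucell", "ucell", "singscore", "ssgsea", "jasmine", "viper")`.
#' @return named list of `score_matrix` objects.
#' @export
score_all <- function(m, sets, params = scoring_params(),
                      methods = score_methods) {
  if (length(methods) == 0) stop("empty method list", call. = FALSE)
  bad <- setdiff(methods, score_methods)
  if (length(bad) > 0)
    stop("unknown scoring method(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(score_methods, collapse = ", "), call. = FALSE)
  fns <- list(aucell = score_aucell, ucell = score_ucell,
              singscore = score_singscore, ssgsea = score_ssgsea,
              jasmine = score_jasmine, viper = score_viper)
  out <- lapply(methods, function(me) fns[[me]](m, sets, params))
  names(out) <- methods
  out
}

#' Write score matrices as TSV plus a JSON parameter sidecar
#'
#' One `<method>.scores.tsv` per method (rows = gene sets, columns = cells)
#' and a single `scoring_params.json` recording the parameters used.
#'
#' @param scores named list of `score_matrix` objects (see [score_all()]).
#' @param dir output directory (created if needed).
#' @export
write_scores <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sm in scores) {
    df <- data.frame(gene_set = rownames(sm$scores), sm$scores,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(sm$method, ".scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p <- scores[[1L]]$params
  jsonlite::write_json(p[!vapply(p, is.null, logical(1))],
                       file.path(dir, "scoring_params.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read score matrices written by [write_scores()]
#' @param dir directory holding `<method>.scores.tsv` files.
#' @return named list of `score_matrix` objects.
#' @export
read_scores <- function(dir) {
  files <- list.files(dir, pattern = "\\.scores\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no score tables in ", dir, call. = FALSE)
  pfile <- file.path(dir, "scoring_params.json")
  params <- if (file.exists(pfile)) {
    pj <- jsonlite::read_json(pfile, simplifyVector = TRUE)
    do.call(scoring_params, pj[setdiff(names(pj), "seed")])
  } else scoring_params()
  out <- lapply(files, function(f) {
    df <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- df[[1L]]
    new_score_matrix(sub("\\.scores\\.tsv$", "", basename(f)), mat, params)
  })
  names(out) <- vapply(out, `[[`, character(1), "method")
  out
}
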