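#' Build per-method significance rank lists
#'
#' For one cluster and direction, collects each scoring method's significant
#' gene sets ordered by increasing p-value (ties broken by decreasing
#' absolute effect, then set name). Methods with no significant set
#' contribute an empty list but still count toward `k`, the number of
#' methods aggregated.
#'
#' @param d a `differential_table` from [differential_all()].
#' @param cluster cluster name.
#' @param direction "up" or "down".
#' @param methods methods to aggregate; defaults to the methods present in
#'   `d`. Supply the full method list explicitly when some methods produced
#'   no rows at all.
#' @return list of class `rank_lists` with elements `cluster`, `direction`,
#'   `lists` (named list of ordered set-name vectors), `k`, `universe`
#'   (union of listed set names) and `n_total` (number of sets tested, the
#'   rank-normalisation denominator).
#' @export
build_rank_lists <- function(d, cluster, direction = c("up", "down"),
                             methods = NULL) {
  direction <- match.arg(direction)
  if (nrow(d) == 0) stop("empty differential table", call. = FALSE)
  if (is.null(methods)) methods <- unique(d$method)
  sub <- d[d$cluster == cluster & d$direction == direction & d$significant, ,
           drop = FALSE]
  lists <- lapply(methods, function(me) {
    b <- sub[sub$method == me, , drop = FALSE]
    b <- b[order(b$p_value, -abs(b$avg_diff), b$set_name), , drop = FALSE]
    b$set_name
  })
  names(lists) <- methods
  rank_lists(lists, n_total = length(unique(d$set_name)),
             cluster = cluster, direction = direction)
}

#' Construct rank lists directly
#'
#' Low-level constructor used by [build_rank_lists()] and by calibration
#' studies that supply ordered lists without a differential table.
#'
#' @param lists named list (one per method) of ordered set-name vectors,
#'   most significant first.
#' @param n_total number of sets tested; defaults to the union size (the
#'   complete-list case where every tested set is listed somewhere).
#' @param cluster,direction carried along for provenance.
#' @return list of class `rank_lists`.
#' @export
rank_lists <- function(lists, n_total = NULL, cluster = NA_character_,
                       direction = NA_character_) {
  for (lst in lists)
    if (anyDuplicated(lst))
      stop("duplicate set name within a method's list", call. = FALSE)
  universe <- sort(unique(unlist(lists, use.names = FALSE)))
  if (is.null(n_total)) n_total <- length(universe)
  if (n_total < length(universe))
    stop("n_total smaller than the union of listed sets", call. = FALSE)
  structure(list(cluster = cluster, direction = direction, lists = lists,
                 k = length(lists), universe = universe,
                 n_total = n_total),
            class = "rank_lists")
}

#' Normalise ranks across methods
#'
#' Converts each method's ordered list into normalised ranks
#' `r_ij` in (0, 1]. Under the default `"union"` dialect,
#' `r_ij = R_ij / N` with `N = n_total`, the number of sets tested -- the
#' order-statistic null is the set's standing among all sets the method
#' could have ranked -- and sets absent from a method's list get
#' `r_ij = 1` (bottom of the list, the conservative reading of "not
#' significant for that method"). Under the `"paper"` dialect absences are
#' first imputed as rank `N` and each set's ranks are then divided by that
#' set's largest rank across methods; read literally this forces the
#' worst-ranked method's `r` to 1 for every set, which is why it is not the
#' default (see the vignette).
#'
#' @param rl a [build_rank_lists()] / [rank_lists()] result.
#' @param dialect "union" (default) or "paper".
#' @return numeric matrix, sets (rows, universe order) x methods, of
#'   normalised ranks; empty matrix when no set was listed.
#' @export
normalize_ranks <- function(rl, dialect = c("union", "paper")) {
  dialect <- match.arg(dialect)
  n_univ <- length(rl$universe)
  N <- rl$n_total
  R <- matrix(N, n_univ, rl$k,
              dimnames = list(rl$universe, names(rl$lists)))
  absent <- matrix(TRUE, n_univ, rl$k, dimnames = dimnames(R))
  for (j in seq_len(rl$k)) {
    lst <- rl$lists[[j]]
    if (length(lst) > 0) {
      R[lst, j] <- seq_along(lst)
      absent[lst, j] <- FALSE
    }
  }
  if (n_univ == 0) return(R)
  if (dialect == "union") {
    r <- R / N
    r[absent] <- 1
  } else {
    denom <- apply(R, 1L, max)          # per-set max over methods
    r <- R / denom
  }
  attr(r, "dialect") <- dialect
  r
}

#' Order-statistic beta score of a normalised rank vector
#'
#' Sorts the `k` normalised ranks ascending and evaluates, for each order
#' statistic `r_(x)`, the probability that the x-th smallest of `k` i.i.d.
#' uniforms is at most `r_(x)`:
#' `beta_x = sum_{l=x}^{k} choose(k, l) r_(x)^l (1 - r_(x))^(k-l)`.
#' The aggregate rho score is the minimum beta.
#'
#' @param r numeric vector of normalised ranks, each in (0, 1].
#' @return list with `beta` (vector, order-statistic index order) and
#'   `rho = min(beta)`.
#' @export
beta_score <- function(r) {
  if (length(r) == 0) stop("empty rank vector", call. = FALSE)
  if (any(r <= 0) || any(r > 1))
    stop("normalised ranks must lie in (0, 1]", call. = FALSE)
  k <- length(r)
  rs <- sort(r)
  beta <- stats::pbinom(seq_len(k) - 1L, size = k, prob = rs,
                        lower.tail = FALSE)
  list(beta = beta, rho = min(beta))
}

#' Robust rank aggregation of per-method differential results
#'
#' For every cluster x direction with at least one significant set, builds
#' the per-method rank lists, normalises ranks, computes each set's rho
#' score (minimum order-statistic beta) and corrects it by the Bonferroni
#' factor `k` (the number of methods aggregated):
#' `p_corrected = min(1, rho * k)`. Rows are sorted by `p_corrected`
#' ascending; non-significant aggregated rows are retained so callers can
#' filter at their own threshold.
#'
#' @param d a `differential_table`.
#' @param methods methods to aggregate (default: those present in `d`).
#' @param alpha threshold recorded on the result and used by summaries.
#' @param dialect rank-normalisation dialect, see [normalize_ranks()].
#' @return an `rra_result` data frame with columns `cluster`, `direction`,
#'   `set_name`, `rho`, `p_corrected`, `n_methods_detected`, plus one
#'   logical `in_<method>` membership column per method.
#' @export
rra_aggregate <- function(d, methods = NULL, alpha = 0.05,
                          dialect = c("union", "paper")) {
  dialect <- match.arg(dialect)
  if (is.null(methods)) methods <- unique(d$method)
  rows <- list()
  for (cl in unique(d$cluster)) {
    for (dir in c("up", "down")) {
      rl <- build_rank_lists(d, cl, dir, methods)
      if (length(rl$universe) == 0) next
      r <- normalize_ranks(rl, dialect)
      detected <- matrix(FALSE, length(rl$universe), rl$k,
                         dimnames = list(rl$universe, methods))
      for (j in seq_len(rl$k)) detected[rl$lists[[j]], j] <- TRUE
      bs <- apply(r, 1L, function(ri) beta_score(ri)$rho)
      block <- data.frame(cluster = cl, direction = dir,
                          set_name = rl$universe,
                          rho = bs,
                          p_corrected = pmin(1, bs * rl$k),
                          n_methods_detected = rowSums(detected),
                          stringsAsFactors = FALSE)
      for (me in methods) block[[paste0("in_", me)]] <- detected[, me]
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- if (length(rows) == 0) {
    empty <- data.frame(cluster = character(), direction = character(),
                        set_name = character(), rho = numeric(),
                        p_corrected = numeric(),
                        n_methods_detected = integer(),
                        stringsAsFactors = FALSE)
    for (me in methods) empty[[paste0("in_", me)]] <- logical()
    empty
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(out$p_corrected, out$cluster, out$direction,
                   out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dialect") <- dialect
  attr(out, "alpha") <- alpha
  attr(out, "k") <- length(methods)
  class(out) <- c("rra_result", "data.frame")
  out
}

#' Write an RRA result as TSV (dialect recorded in a header comment)
#' @param r an `rra_result`.
#' @param path output file.
#' @export
write_rra <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rra_dialect=", attr(r, "dialect"),
                    " alpha=", attr(r, "alpha"), " k=", attr(r, "k")), con)
  utils::write.table(as.data.frame(r), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an RRA result written by [write_rra()]
#' @param path TSV file.
#' @export
read_rra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  r <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  attr(r, "dialect") <- sub(".*rra_dialect=(\\S+).*", "\\1", header)
  attr(r, "alpha") <- as.numeric(sub(".*alpha=(\\S+).*", "\\1", header))
  class(r) <- c("rra_result", "data.frame")
  r
}
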