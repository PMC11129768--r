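#' Rank one cell's expression vector
#'
#' The single source of truth for within-cell gene ranking. Descending ranks
#' (`rank_desc`, 1 = highest expression) and ascending ranks (`rank_asc`,
#' 1 = lowest) are computed under a common tie policy. Zeros (dropouts)
#' naturally form one tie group at the least-expressed end, since all values
#' are non-negative. With `ties = "random"` the permutation is reproducible
#' from `seed` and `cell_id`, and `rank_asc` is defined as
#' `n + 1 - rank_desc` so the two directions stay consistent.
#'
#' @param values per-gene non-negative finite numeric vector.
#' @param ties tie policy: "average" (default), "min", "dense" or "random".
#' @param seed integer seed used only for `ties = "random"`.
#' @param cell_id identifier mixed into the random-tie seed.
#' @return list with `cell_id`, `rank_desc`, `rank_asc`, `n_genes`,
#'   `n_expressed` (count of nonzero values).
#' @export
rank_cell <- function(values, ties = c("average", "min", "dense", "random"),
                      seed = NULL, cell_id = "") {
  ties <- match.arg(ties)
  if (length(values) == 0) stop("empty expression vector", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and >= 0", call. = FALSE)
  n <- length(values)
  if (ties == "dense") {
    u_desc <- sort(unique(values), decreasing = TRUE)
    rd <- match(values, u_desc)
    ra <- match(values, rev(u_desc))
  } else if (ties == "random") {
    rd <- with_local_seed(tie_seed(seed, cell_id),
                          rank(-values, ties.method = "random"))
    ra <- n + 1 - rd
  } else {
    rd <- rank(-values, ties.method = ties)
    ra <- rank(values, ties.method = ties)
  }
  list(cell_id = cell_id, rank_desc = rd, rank_asc = ra,
       n_genes = n, n_expressed = sum(values > 0))
}

# deterministic 32-bit seed from a base seed and a cell id
tie_seed <- function(seed, cell_id) {
  s <- if (is.null(seed)) 0L else as.integer(seed)
  h <- 0
  for (k in utf8ToInt(as.character(cell_id))) h <- (h * 31 + k) %% 2147483647
  as.integer((s + h) %% 2147483647)
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Quantile positions of a ranked cell
#'
#' Maps ascending ranks to strictly interior quantiles
#' `q(g) = (rank_asc(g) - 0.5) / n_genes`, the input to the normal-quantile
#' transform used by the Viper-style score.
#'
#' @param r a [rank_cell()] result.
#' @return numeric vector in (0, 1).
#' @export
quantile_positions <- function(r) {
  (r$rank_asc - 0.5) / r$n_genes
}

# Descending-rank matrix (genes x cells) under the shared tie policy.
# Each column depends on that cell's values only (composition independence).
rank_matrix_desc <- function(m, ties = "average", seed = NULL) {
  m <- as.matrix(m)
  cid <- colnames(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m)))
    out[, j] <- rank_cell(m[, j], ties = ties, seed = seed,
                          cell_id = cid[j])$rank_desc
  out
}

rank_matrix_asc <- function(m, ties = "average", seed = NULL) {
  m <- as.matrix(m)
  cid <- colnames(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m)))
    out[, j] <- rank_cell(m[, j], ties = ties, seed = seed,
                          cell_id = cid[j])$rank_asc
  out
}
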