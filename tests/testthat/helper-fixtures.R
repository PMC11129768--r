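# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# expression matrix whose descending ranks are known by construction:
# gene g_i has value n_genes - i + 1, so rank_desc(g_i) = i in every cell
ladder_matrix <- function(n_genes, n_cells = 1L) {
  m <- matrix(rep(seq(n_genes, 1), n_cells), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# gene ids sitting at the given descending ranks of a ladder matrix
genes_at_ranks <- function(ranks) sprintf("g%04d", ranks)

random_expr <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  matrix(stats::rnbinom(n_genes * n_cells, size = 2, mu = 3),
         nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(n_cells))))
}

# small planted simulation shared across scoring/differential/viz tests
small_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_sc(sim_config(
      n_genes = 400L, n_cells_per_cluster = 40L, n_clusters = 3L,
      n_sets = 8L, set_size = 12L, n_planted = 2L, seed = 42L))
  .fixtures$sim
}

small_scores <- function() {
  if (is.null(.fixtures$scores)) {
    sim <- small_sim()
    m <- suppressMessages(filter_zero_genes(sim$matrix))
    sets <- suppressMessages(restrict_collection(sim$sets, m))
    .fixtures$scores <- score_all(m, sets)
  }
  .fixtures$scores
}

small_differential <- function() {
  if (is.null(.fixtures$diff))
    .fixtures$diff <- differential_all(small_scores(), small_sim()$labels)
  .fixtures$diff
}

small_rra <- function() {
  if (is.null(.fixtures$rra))
    .fixtures$rra <- rra_aggregate(small_differential())
  .fixtures$rra
}

# hand-built differential table for rra unit tests: one cluster, all sets
# significant for every method, p graded so each method ranks sets by the
# order given in `orders` (a named list method -> character vector)
fake_differential <- function(orders, n_total = NULL, cluster = "C1") {
  sets <- unique(unlist(orders))
  if (!is.null(n_total) && n_total > length(sets))
    sets <- c(sets, sprintf("PAD%02d", seq_len(n_total - length(sets))))
  rows <- list()
  for (me in names(orders)) {
    ord <- orders[[me]]
    for (s in sets) {
      pos <- match(s, ord)
      significant <- !is.na(pos)
      rows[[length(rows) + 1L]] <- data.frame(
        method = me, cluster = cluster, set_name = s,
        avg_diff = 1, statistic = 0,
        p_value = if (significant) pos * 1e-6 else 0.9,
        p_adjusted = if (significant) pos * 1e-4 else 1,
        direction = "up", significant = significant,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  class(d) <- c("differential_table", "data.frame")
  attr(d, "alpha") <- 0.05
  d
}
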