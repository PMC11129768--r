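#' Configuration for the synthetic single-cell generator
#'
#' Defaults emulate a small clustered PBMC-like experiment scored against a
#' hallmark-sized collection: 2000 genes, three clusters of 200 cells,
#' twenty disjoint 30-gene sets of which three are planted (upregulated
#' fourfold in one target cluster each). Counts are negative binomial with
#' `var = mu + mu^2 * nb_dispersion`; per-gene baseline means are
#' log-normal.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_cluster cells per cluster.
#' @param n_clusters number of clusters.
#' @param n_sets number of gene sets (all mutually disjoint).
#' @param set_size genes per set.
#' @param n_planted number of planted (truly enriched) sets; each is
#'   assigned one target cluster round-robin.
#' @param fold_change multiplicative shift of planted genes' means in the
#'   target cluster (> 1 plants upregulation).
#' @param nb_dispersion negative-binomial dispersion `phi` in
#'   `var = mu + mu^2 phi`.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma meanlog/sdlog of the
#'   log-normal baseline gene means.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_cells_per_cluster = 200L,
                       n_clusters = 3L, n_sets = 20L, set_size = 30L,
                       n_planted = 3L, fold_change = 4.0,
                       nb_dispersion = 0.3, baseline_mean_log_mu = 0.5,
                       baseline_mean_log_sigma = 1.0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_cluster = as.integer(n_cells_per_cluster),
              n_clusters = as.integer(n_clusters),
              n_sets = as.integer(n_sets), set_size = as.integer(set_size),
              n_planted = as.integer(n_planted),
              fold_change = fold_change, nb_dispersion = nb_dispersion,
              baseline_mean_log_mu = baseline_mean_log_mu,
              baseline_mean_log_sigma = baseline_mean_log_sigma,
              seed = as.integer(seed))
  stopifnot(cfg$n_planted <= cfg$n_sets, cfg$n_planted >= 0,
            cfg$nb_dispersion > 0, cfg$n_clusters >= 1)
  if (cfg$n_planted > 0 && cfg$fold_change <= 1 && cfg$fold_change != 1)
    stopifnot(cfg$fold_change > 0)      # fold < 1 plants downregulation
  if (cfg$n_sets * cfg$set_size > cfg$n_genes)
    stop("n_sets * set_size exceeds n_genes; sets cannot be disjoint",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a clustered expression matrix with planted enriched sets
#'
#' Gene baseline means are drawn log-normal; counts are drawn independently
#' per cell from a negative binomial with `var = mu + mu^2 * nb_dispersion`
#' (dropout zeros arise naturally from low means). All `n_sets` sets are
#' disjoint random gene groups; for each of the first `n_planted` sets the
#' member genes' means are multiplied by `fold_change` in its target
#' cluster only (clusters assigned round-robin). Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (sparse genes x cells), `labels` (named
#'   factor), `sets` (a [gene_set_collection()]), `truth` (data frame
#'   `set_name`, `cluster`, `direction` for planted sets).
#' @export
simulate_sc <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    n_cells <- cfg$n_clusters * cfg$n_cells_per_cluster
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
    cluster_names <- paste0("C", seq_len(cfg$n_clusters))
    labels <- stats::setNames(
      factor(rep(cluster_names, each = cfg$n_cells_per_cluster),
             levels = cluster_names),
      cell_ids)
    mu <- stats::rlnorm(cfg$n_genes, meanlog = cfg$baseline_mean_log_mu,
                        sdlog = cfg$baseline_mean_log_sigma)
    set_genes <- sample.int(cfg$n_genes, cfg$n_sets * cfg$set_size)
    sets <- split(gene_ids[set_genes],
                  rep(seq_len(cfg$n_sets), each = cfg$set_size))
    names(sets) <- sprintf("SET%02d", seq_len(cfg$n_sets))
    truth <- if (cfg$n_planted > 0) {
      data.frame(
        set_name = names(sets)[seq_len(cfg$n_planted)],
        cluster = cluster_names[((seq_len(cfg$n_planted) - 1L) %%
                                   cfg$n_clusters) + 1L],
        direction = "up", stringsAsFactors = FALSE)
    } else {
      data.frame(set_name = character(), cluster = character(),
                 direction = character(), stringsAsFactors = FALSE)
    }
    size <- 1 / cfg$nb_dispersion
    counts <- matrix(0L, cfg$n_genes, n_cells,
                     dimnames = list(gene_ids, cell_ids))
    for (cl in seq_len(cfg$n_clusters)) {
      mu_cl <- mu
      planted_here <- truth$set_name[truth$cluster == cluster_names[cl]]
      for (ps in planted_here) {
        gi <- match(sets[[ps]], gene_ids)
        mu_cl[gi] <- mu_cl[gi] * cfg$fold_change
      }
      cols <- which(labels == cluster_names[cl])
      counts[, cols] <- stats::rnbinom(cfg$n_genes * length(cols),
                                       size = size, mu = mu_cl)
    }
    list(matrix = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         labels = labels,
         sets = gene_set_collection(sets),
         truth = truth)
  })
}

#' Simulate a null dataset (cluster structure, no planted signal)
#'
#' Identical to [simulate_sc()] with `n_planted` forced to 0: labels are
#' still emitted but no gene set carries any differential signal.
#'
#' @param cfg a [sim_config()].
#' @return same structure as [simulate_sc()], with an empty `truth`.
#' @export
null_simulate <- function(cfg = sim_config()) {
  cfg$n_planted <- 0L
  simulate_sc(cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the same dialects the readers consume: a 10x-style MTX triplet, a
#' GMT collection, a `clusters.tsv` label table and `truth.json`.
#'
#' @param sim a [simulate_sc()] result.
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$matrix, dir, format = "mtx10x")
  write_gmt(sim$sets, file.path(dir, "sets.gmt"))
  write_cluster_labels(sim$labels, file.path(dir, "clusters.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
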