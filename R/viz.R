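#' Significance-star binning
#'
#' Fixed cut points: `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#' p <= 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "")))
}

new_plot_table <- function(kind, data, meta = NULL) {
  structure(list(kind = kind, data = data, meta = meta),
            class = "plot_table")
}

#' @export
print.plot_table <- function(x, ...) {
  cat("Plot table [", x$kind, "] with ", nrow(x$data), " row(s)\n", sep = "")
  print(utils::head(x$data, 10L))
  invisible(x)
}

#' Stacked-bar plot table: significant-set counts per method and cluster
#'
#' Counts significant sets per (source, cluster, direction), where source is
#' each scoring method plus the aggregated RRA column, and tabulates the
#' per-cluster percentage of up / down / insignificant sets per method.
#'
#' @param d a `differential_table`.
#' @param r an `rra_result`.
#' @param alpha significance threshold for the RRA column (default: the
#'   alpha recorded on `r`).
#' @return a `plot_table` of kind "stackbar"; `$data` holds the counts and
#'   `$meta$percent` the per-(method, cluster) percentages.
#' @export
stackbar_table <- function(d, r, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(r, "alpha") %||% 0.05
  counts <- list()
  if (nrow(d) > 0) {
    methods <- unique(d$method)
    clusters <- unique(d$cluster)
    n_sets <- length(unique(d$set_name))
    pct <- list()
    for (me in methods) for (cl in clusters) {
      sub <- d[d$method == me & d$cluster == cl, , drop = FALSE]
      for (dir in c("up", "down")) {
        counts[[length(counts) + 1L]] <- data.frame(
          source = me, cluster = cl, direction = dir,
          count = sum(sub$significant & sub$direction == dir),
          stringsAsFactors = FALSE)
      }
      pct[[length(pct) + 1L]] <- data.frame(
        method = me, cluster = cl,
        pct_up = 100 * sum(sub$significant & sub$direction == "up") / n_sets,
        pct_down = 100 * sum(sub$significant & sub$direction == "down") /
          n_sets,
        pct_insignificant = 100 * sum(!sub$significant) / n_sets,
        n_sets = n_sets, stringsAsFactors = FALSE)
    }
    for (cl in clusters) for (dir in c("up", "down")) {
      sub <- r[r$cluster == cl & r$direction == dir, , drop = FALSE]
      counts[[length(counts) + 1L]] <- data.frame(
        source = "RRA", cluster = cl, direction = dir,
        count = sum(sub$p_corrected <= alpha), stringsAsFactors = FALSE)
    }
    meta <- list(percent = do.call(rbind, pct), alpha = alpha)
  } else {
    meta <- list(percent = NULL, alpha = alpha)
  }
  data <- if (length(counts) > 0) do.call(rbind, counts) else
    data.frame(source = character(), cluster = character(),
               direction = character(), count = integer())
  new_plot_table("stackbar", data, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upset plot table: overlap of RRA-significant sets across clusters
#'
#' @param r an `rra_result`.
#' @param alpha significance threshold (default: recorded on `r`).
#' @return a `plot_table` of kind "upset"; `$data` is the binary set x
#'   cluster membership table, `$meta$intersections` the cardinality of
#'   every observed cluster combination.
#' @export
upset_table <- function(r, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(r, "alpha") %||% 0.05
  sig <- r[r$p_corrected <= alpha, , drop = FALSE]
  if (nrow(sig) == 0)
    return(new_plot_table("upset",
                          data.frame(set_name = character()),
                          list(intersections = data.frame(
                            clusters = character(), count = integer()))))
  clusters <- sort(unique(sig$cluster))
  sets <- sort(unique(sig$set_name))
  memb <- matrix(FALSE, length(sets), length(clusters),
                 dimnames = list(sets, clusters))
  for (i in seq_len(nrow(sig))) memb[sig$set_name[i], sig$cluster[i]] <- TRUE
  combo <- apply(memb, 1L, function(row)
    paste(clusters[row], collapse = "&"))
  inter <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(inter) <- c("clusters", "count")
  data <- data.frame(set_name = sets, memb, check.names = FALSE)
  rownames(data) <- NULL
  new_plot_table("upset", data, list(intersections = inter))
}

#' Heatmap plot table: signed -log10 RRA p by set and cluster
#'
#' @param r an `rra_result`.
#' @return a `plot_table` of kind "heatmap"; `$data` is tidy (cluster,
#'   set_name, direction, neglog10_p, signed_neglog10_p, stars),
#'   `$meta$matrix` the set x cluster signed matrix.
#' @export
heatmap_table <- function(r) {
  data <- data.frame(cluster = r$cluster, set_name = r$set_name,
                     direction = r$direction,
                     neglog10_p = -log10(pmax(r$p_corrected, .Machine$double.xmin)),
                     stringsAsFactors = FALSE)
  data$signed_neglog10_p <- ifelse(data$direction == "down",
                                   -data$neglog10_p, data$neglog10_p)
  data$stars <- significance_stars(r$p_corrected)
  sets <- sort(unique(data$set_name))
  clusters <- sort(unique(data$cluster))
  mat <- matrix(0, length(sets), length(clusters),
                dimnames = list(sets, clusters))
  for (i in seq_len(nrow(data)))
    mat[data$set_name[i], data$cluster[i]] <- data$signed_neglog10_p[i]
  new_plot_table("heatmap", data, list(matrix = mat))
}

#' Bubble plot table: RRA significance as bubble sizes
#'
#' Same tidy numbers as [heatmap_table()] with an explicit bubble size
#' column (`-log10 p`).
#'
#' @param r an `rra_result`.
#' @return a `plot_table` of kind "bubble".
#' @export
bubble_table <- function(r) {
  ht <- heatmap_table(r)
  data <- ht$data
  data$size <- data$neglog10_p
  new_plot_table("bubble", data, ht$meta)
}

#' Local (per-set) distribution tables
#'
#' Per-cluster summaries of one gene set's per-cell scores: quintiles
#' (0, 20, ..., 100 percent) and means, kernel-density traces per cluster,
#' and -- when a 2-D embedding is supplied -- the per-cell score joined to
#' its coordinates. Constant scores yield a degenerate single-point
#' "density" rather than an error; a missing embedding drops the scatter
#' table with a warning.
#'
#' @param s a `score_matrix`.
#' @param set_name gene set to summarise.
#' @param labels cluster labels (named by cell id).
#' @param embedding optional cells x 2 numeric matrix of coordinates, row
#'   names = cell ids.
#' @return list of class `local_tables` with `plot_table`s `summary`,
#'   `density` and optionally `scatter`.
#' @export
local_tables <- function(s, set_name, labels, embedding = NULL) {
  if (!set_name %in% rownames(s$scores))
    stop("unknown gene set: ", set_name, call. = FALSE)
  v <- s$scores[set_name, ]
  labels <- labels[colnames(s$scores)]
  probs <- seq(0, 1, by = 0.2)
  summ <- do.call(rbind, lapply(levels(factor(labels)), function(cl) {
    x <- v[labels == cl]
    q <- stats::quantile(x, probs = probs, names = FALSE)
    data.frame(cluster = cl, mean = mean(x),
               q0 = q[1], q20 = q[2], q40 = q[3], q60 = q[4], q80 = q[5],
               q100 = q[6], n_cells = length(x), stringsAsFactors = FALSE)
  }))
  dens <- do.call(rbind, lapply(levels(factor(labels)), function(cl) {
    x <- v[labels == cl]
    if (length(unique(x)) < 2) {
      data.frame(cluster = cl, score = unique(x)[1], density = 1,
                 stringsAsFactors = FALSE)
    } else {
      d <- stats::density(x)
      data.frame(cluster = cl, score = d$x, density = d$y,
                 stringsAsFactors = FALSE)
    }
  }))
  out <- list(summary = new_plot_table("ridge", summ,
                                       list(set_name = set_name,
                                            method = s$method)),
              density = new_plot_table("density", dens,
                                       list(set_name = set_name)))
  if (!is.null(embedding)) {
    emb <- embedding[colnames(s$scores), , drop = FALSE]
    out$scatter <- new_plot_table(
      "densityheatmap",
      data.frame(cell_id = colnames(s$scores), dim1 = emb[, 1],
                 dim2 = emb[, 2], score = unname(v),
                 cluster = as.character(labels), stringsAsFactors = FALSE),
      list(set_name = set_name))
  } else {
    warning("no embedding supplied: density-scatter table omitted",
            call. = FALSE)
  }
  class(out) <- "local_tables"
  out
}

#' Render a plot table to a file
#'
#' Minimal static renderings (base graphics) driven purely by the table:
#' stacked bars, heatmap image, bubble grid, upset bars, density traces.
#' The informative artefact is the table; rendering adds nothing to it.
#'
#' @param pt a `plot_table`.
#' @param file output file; device chosen by extension (.png or .pdf).
#' @param width,height device size in inches.
#' @return the file path, invisibly.
#' @export
render_plot <- function(pt, file, width = 7, height = 5) {
  open_device(file, width, height)
  on.exit(grDevices.dev_off())
  switch(pt$kind,
    stackbar = {
      d <- pt$data
      if (nrow(d) == 0) { plot.new(); title("no significant sets") }
      else {
        d$group <- paste(d$source, d$cluster)
        tab <- stats::xtabs(count ~ direction + group, data = d)
        graphics::barplot(tab, las = 2, legend.text = rownames(tab),
                          main = "Significant gene sets",
                          cex.names = 0.6)
      }
    },
    heatmap = ,
    densityheatmap = {
      mat <- pt$meta$matrix
      if (is.null(mat) || length(mat) == 0) { plot.new() }
      else {
        graphics::image(t(mat), axes = FALSE,
                        main = "signed -log10 p (RRA)")
        graphics::axis(1, at = seq(0, 1, length.out = ncol(mat)),
                       labels = colnames(mat), las = 2, cex.axis = 0.7)
      }
    },
    bubble = {
      d <- pt$data
      if (nrow(d) == 0) plot.new()
      else {
        cl <- factor(d$cluster); st <- factor(d$set_name)
        graphics::plot(as.integer(cl), as.integer(st),
                       cex = pmin(3, 0.5 + d$size / 3),
                       pch = 19, col = ifelse(d$direction == "up", 2, 4),
                       xlab = "cluster", ylab = "gene set", axes = FALSE)
        graphics::axis(1, at = seq_along(levels(cl)), labels = levels(cl))
        graphics::axis(2, at = seq_along(levels(st)), labels = levels(st),
                       las = 2, cex.axis = 0.6)
      }
    },
    upset = {
      inter <- pt$meta$intersections
      if (is.null(inter) || nrow(inter) == 0) plot.new()
      else graphics::barplot(inter$count, names.arg = inter$clusters,
                             las = 2, cex.names = 0.6,
                             main = "RRA overlap across clusters")
    },
    density = ,
    ridge = {
      d <- pt$data
      if ("density" %in% names(d)) {
        graphics::plot(d$score, d$density, type = "n",
                       xlab = "score", ylab = "density")
        for (cl in unique(d$cluster)) {
          sub <- d[d$cluster == cl, ]
          graphics::lines(sub$score, sub$density,
                          col = match(cl, unique(d$cluster)))
        }
      } else {
        graphics::barplot(d$mean, names.arg = d$cluster,
                          ylab = "mean score")
      }
    },
    stop("no renderer for plot-table kind: ", pt$kind, call. = FALSE))
  invisible(file)
}

open_device <- function(file, width, height) {
  if (grepl("\\.png$", file)) {
    ok <- tryCatch({
      grDevices::png(file, width = width, height = height, units = "in",
                     res = 120)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) grDevices::pdf(sub("\\.png$", ".pdf", file),
                            width = width, height = height)
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
}

grDevices.dev_off <- function() grDevices::dev.off()
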