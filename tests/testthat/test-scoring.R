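# Worked micro-examples use a "ladder" matrix in which gene g_i has
# descending rank i by construction (see helper-fixtures.R).

toy_sets <- function(...) gene_set_collection(list(...))

test_that("AUCell-style score matches the recovery-curve arithmetic", {
  m <- ladder_matrix(100)
  sets <- toy_sets(top = genes_at_ranks(c(1, 2)),
                   mid = genes_at_ranks(c(4, 5)),
                   out = genes_at_ranks(c(60, 70)))
  s <- score_aucell(m, sets)  # L = 5
  expect_equal(unname(s$scores["top", 1]), 1)
  expect_equal(unname(s$scores["mid", 1]), 3 / 9)
  expect_equal(unname(s$scores["out", 1]), 0)
})

test_that("AUCell raw sum equals a brute-force recovery curve", {
  # independent oracle: walk the ranked list, count hits, sum the curve
  aucell_oracle <- function(v, genes, frac) {
    n <- length(v)
    L <- ceiling(frac * n)
    ord <- names(v)[order(-v)]
    hits <- cumsum(ord %in% genes)[seq_len(L)]
    sum(hits) / sum(pmin(seq_len(L), length(genes)))
  }
  set.seed(31)
  for (i in 1:10) {
    v <- stats::setNames(sample(200), paste0("g", 1:200))  # tie-free
    genes <- sample(names(v), 8)
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "c1"))
    s <- score_aucell(m, toy_sets(S = genes))
    expect_equal(unname(s$scores["S", 1]), aucell_oracle(v, genes, 0.05))
  }
})

test_that("UCell-style score reproduces the capped Mann-Whitney form", {
  m <- ladder_matrix(2000)
  sets <- toy_sets(best = genes_at_ranks(1:3),
                   good = genes_at_ranks(c(10, 20, 30)),
                   tail = genes_at_ranks(c(1600, 1700, 1800)))
  s <- score_ucell(m, sets)
  expect_equal(unname(s$scores["best", 1]), 1)
  expect_equal(unname(s$scores["good", 1]), 1 - 54 / 4500)
  # every member beyond the cap: r* = 1501 each
  U_tail <- 3 * 1501 - 3 * 4 / 2
  expect_equal(unname(s$scores["tail", 1]), 1 - U_tail / 4500)

  # independent check: U from pairwise comparisons on capped ranks
  u_oracle <- function(set_ranks, rmax) {
    r <- pmin(set_ranks, rmax + 1)
    sum(r) - length(r) * (length(r) + 1) / 2
  }
  expect_equal(u_oracle(c(10, 20, 30), 1500), 54)
  expect_equal(u_oracle(c(1600, 1700, 1800), 1500), U_tail)
})

test_that("singscore-style score is the normalised mean rank", {
  m <- ladder_matrix(10)
  # ladder: rank_asc = 11 - rank_desc
  sets <- toy_sets(hi = genes_at_ranks(c(1, 2)),    # rank_asc 10, 9
                   lo = genes_at_ranks(c(9, 10)),   # rank_asc 2, 1
                   mid = genes_at_ranks(c(8, 3)))   # rank_asc 3, 8
  s <- score_singscore(m, sets)
  expect_equal(unname(s$scores["hi", 1]), 1)
  expect_equal(unname(s$scores["lo", 1]), 0)
  expect_equal(unname(s$scores["mid", 1]), 0.5)
  expect_error(score_singscore(ladder_matrix(4),
                               toy_sets(all = genes_at_ranks(1:4))),
               "whole gene universe")
})

test_that("ssGSEA-style running sum matches hand and brute-force values", {
  m <- ladder_matrix(4)
  s1 <- score_ssgsea(m, toy_sets(S = genes_at_ranks(1)))
  expect_equal(unname(s1$scores["S", 1]), 2)   # diffs 1, 2/3, 1/3, 0

  s2 <- score_ssgsea(m, toy_sets(S = genes_at_ranks(c(2, 4))),
                     scoring_params(ssgsea_alpha = 0))
  expect_equal(unname(s2$scores["S", 1]), -1)  # hand running sum, weights 1

  # brute-force oracle: explicit position loop over the ranked list
  ssgsea_oracle <- function(v, genes, alpha) {
    ord <- order(v, decreasing = TRUE)
    n <- length(v)
    in_set <- names(v)[ord] %in% genes
    w <- (n - seq_len(n) + 1)^alpha
    es <- 0
    for (i in seq_len(n)) {
      p_in <- sum(w[seq_len(i)][in_set[seq_len(i)]]) / sum(w[in_set])
      p_out <- sum(!in_set[seq_len(i)]) / (n - sum(in_set))
      es <- es + (p_in - p_out)
    }
    es
  }
  set.seed(12)
  for (i in 1:8) {
    v <- stats::setNames(sample(30), paste0("g", 1:30))
    genes <- sample(names(v), 5)
    m <- matrix(v, ncol = 1, dimnames = list(names(v), "c1"))
    s <- score_ssgsea(m, toy_sets(S = genes))
    expect_equal(unname(s$scores["S", 1]), ssgsea_oracle(v, genes, 0.25))
  }
})

test_that("JASMINE components match a straight-line reimplementation", {
  # 3-cell toy: columns differ in which set genes are expressed
  m <- matrix(c(5, 4, 0, 1, 0, 0,
                0, 0, 3, 2, 1, 0,
                2, 2, 2, 2, 2, 2), ncol = 3,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:3)))
  genes <- c("g1", "g2")
  s <- score_jasmine(m, toy_sets(S = genes))

  jasmine_oracle <- function(v, genes) {
    expr <- v > 0
    ne <- sum(expr)
    rexp <- rank(-v[expr], ties.method = "average")
    inter <- intersect(names(which(expr)), genes)
    rm_val <- if (length(inter) == 0) 0.5
              else mean(rexp[inter]) / ne
    a <- length(inter); b <- length(genes) - a
    cc <- ne - a; d <- (length(v) - length(genes)) - cc
    if (min(a, b, cc, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    c(rm = rm_val, or = (a * d) / (b * cc))
  }
  for (j in 1:3) {
    o <- jasmine_oracle(m[, j], genes)
    expect_equal(unname(s$components$rm["S", j]), unname(o["rm"]))
    expect_equal(unname(s$components$enrichment["S", j]), unname(o["or"]))
  }
  expect_true(all(s$scores >= 0 & s$scores <= 1))
})

test_that("JASMINE extremes and determinism behave", {
  # cell 1: exactly the set expressed; cell 2: everything weakly expressed
  m <- matrix(c(3, 2, 0, 0, 0, 0,
                1, 1, 1, 1, 1, 1,
                1, 1, 1, 1, 1, 1), ncol = 3,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:3)))
  s <- score_jasmine(m, toy_sets(S = c("g1", "g2")))
  # perfectly separated cell has the maximal enrichment component
  expect_equal(which.max(s$components$enrichment["S", ]), c(c1 = 1L))
  # identical cells score identically
  expect_equal(s$scores["S", 2], s$scores["S", 3])
})

test_that("Viper-style NES follows the normal-quantile construction", {
  m <- ladder_matrix(100)
  s <- score_viper(m, toy_sets(top = genes_at_ranks(1)))
  expect_equal(unname(s$scores["top", 1]), stats::qnorm(0.995))

  # members symmetric about the median cancel exactly
  sym <- toy_sets(S = genes_at_ranks(c(10, 91, 25, 76)))
  s2 <- score_viper(m, sym)
  expect_equal(unname(s2$scores["S", 1]), 0)

  # identical cells give identical NES
  m3 <- ladder_matrix(50, n_cells = 3)
  s3 <- score_viper(m3, toy_sets(S = genes_at_ranks(c(2, 7, 11))))
  expect_equal(s3$scores["S", 1], s3$scores["S", 2])
})

test_that("score_all dispatches, validates and aligns outputs", {
  m <- ladder_matrix(50, n_cells = 2)
  sets <- toy_sets(A = genes_at_ranks(1:5), B = genes_at_ranks(40:46))
  all6 <- score_all(m, sets)
  expect_named(all6, c("aucell", "ucell", "singscore", "ssgsea",
                       "jasmine", "viper"))
  for (s in all6) {
    expect_identical(rownames(s$scores), c("A", "B"))
    expect_identical(colnames(s$scores), c("c01", "c02"))
  }
  one <- score_all(m, sets, methods = "ucell")
  expect_named(one, "ucell")
  expect_error(score_all(m, sets, methods = character()), "empty")
  expect_error(score_all(m, sets, methods = "gsva"), "unknown scoring")
  expect_error(score_aucell(m, toy_sets(S = c("g0001", "nope"))),
               "restrict_collection")
})

test_that("bounded methods stay in [0,1] on random inputs", {
  set.seed(77)
  for (i in 1:5) {
    m <- random_expr(120, 15, seed = 100 + i)
    sets <- gene_set_collection(list(
      S1 = sample(rownames(m), 10), S2 = sample(rownames(m), 25)))
    sc <- score_all(m, sets,
                    methods = c("aucell", "ucell", "singscore", "jasmine"))
    for (s in sc)
      expect_true(all(s$scores >= 0 & s$scores <= 1),
                  label = paste(s$method, "in [0,1]"))
  }
})

test_that("per-cell scores are composition independent", {
  m <- random_expr(150, 12, seed = 9)
  sets <- gene_set_collection(list(S1 = rownames(m)[c(3, 10, 22, 40, 80)],
                                   S2 = rownames(m)[101:115]))
  cols <- c(4, 7)
  methods5 <- c("aucell", "ucell", "singscore", "ssgsea", "viper")
  full <- score_all(m, sets, methods = methods5)
  solo <- score_all(m[, cols, drop = FALSE], sets, methods = methods5)
  extra <- m[, 1:3] * 2 + 1e3
  colnames(extra) <- paste0("x", 1:3)
  set.seed(4)
  aug <- score_all(cbind(m, extra)[, sample(15)], sets, methods = methods5)
  for (me in methods5) {
    expect_identical(full[[me]]$scores[, cols], solo[[me]]$scores)
    expect_identical(aug[[me]]$scores[, colnames(m)[cols]],
                     full[[me]]$scores[, cols])
  }
  # JASMINE: the unscaled components are per-cell; the final min-max is not
  jf <- score_jasmine(m, sets)
  js <- score_jasmine(m[, cols, drop = FALSE], sets)
  expect_identical(jf$components$rm[, cols], js$components$rm)
  expect_identical(jf$components$enrichment[, cols],
                   js$components$enrichment)
})

test_that("all six scores are invariant to per-cell monotone transforms", {
  m <- random_expr(100, 8, seed = 21)
  sets <- gene_set_collection(list(S1 = rownames(m)[c(1, 9, 33, 47)],
                                   S2 = rownames(m)[60:72]))
  base <- score_all(m, sets)
  for (f in list(log1p, function(x) 2 * x)) {
    tr <- score_all(f(m), sets)
    for (me in names(base))
      expect_equal(tr[[me]]$scores, base[[me]]$scores,
                   label = paste(me, "monotone-invariant"))
  }
})

test_that("planted sets score higher in their target cluster", {
  sim <- small_sim()
  scores <- small_scores()
  for (i in seq_len(nrow(sim$truth))) {
    set <- sim$truth$set_name[i]
    cl <- sim$truth$cluster[i]
    in_cl <- sim$labels == cl
    for (s in scores) {
      expect_gt(mean(s$scores[set, in_cl]), mean(s$scores[set, !in_cl]),
                label = paste(s$method, set, "discriminates", cl))
    }
  }
})

test_that("Viper NES is approximately standard normal under i.i.d. noise", {
  set.seed(55)
  m <- matrix(stats::runif(500 * 400), nrow = 500,
              dimnames = list(paste0("g", 1:500), paste0("c", 1:400)))
  sets <- gene_set_collection(lapply(
    stats::setNames(1:30, paste0("S", 1:30)),
    function(i) sample(rownames(m), 20)))
  s <- score_viper(m, sets)
  expect_lt(abs(mean(s$scores)), 0.05)
  expect_lt(abs(stats::var(as.vector(s$scores)) - 1), 0.15)
})
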