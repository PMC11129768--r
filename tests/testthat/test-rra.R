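test_that("beta_score matches the binomial upper-tail identity", {
  bs <- beta_score(c(0.1, 0.5, 0.9))
  expect_equal(bs$beta, c(1 - 0.9^3, 0.5, 0.9^3))
  expect_equal(round(bs$beta, 3), c(0.271, 0.5, 0.729))
  expect_equal(bs$rho, bs$beta[1])

  all_one <- beta_score(rep(1, 4))
  expect_equal(all_one$beta, rep(1, 4))
  expect_equal(all_one$rho, 1)

  single <- beta_score(0.037)
  expect_equal(single$beta, 0.037)
  expect_equal(single$rho, 0.037)

  expect_error(beta_score(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(beta_score(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(beta_score(numeric()), "empty")
})

test_that("beta_score agrees with a Monte-Carlo order-statistic oracle", {
  set.seed(6)
  n_mc <- 20000L
  for (k in c(2, 4, 6)) {
    draws <- matrix(stats::runif(n_mc * k), ncol = k)
    sorted <- t(apply(draws, 1L, sort))
    for (rep in 1:5) {
      r <- sort(stats::runif(k))
      beta <- beta_score(r)$beta
      for (x in seq_len(k)) {
        phat <- mean(sorted[, x] <= sort(r)[x])
        se <- sqrt(beta[x] * (1 - beta[x]) / n_mc)
        expect_lt(abs(phat - beta[x]), 4 * se + 1e-9)
      }
    }
  }
})

test_that("rank lists collect significant sets per method deterministically", {
  d <- fake_differential(list(m1 = c("A", "B"), m2 = c("B", "A")))
  rl <- build_rank_lists(d, "C1", "up")
  expect_identical(rl$universe, c("A", "B"))
  expect_equal(rl$k, 2)
  expect_equal(rl$n_total, 2)
  expect_identical(rl$lists$m1, c("A", "B"))
  expect_identical(rl$lists$m2, c("B", "A"))

  # k reflects the methods supplied, not just those with hits
  rl3 <- build_rank_lists(d, "C1", "up", methods = c("m1", "m2", "m3"))
  expect_equal(rl3$k, 3)
  expect_length(rl3$lists$m3, 0)

  # p tie broken by |avg_diff| (larger effect first), then name
  d2 <- data.frame(method = "m1", cluster = "C1",
                   set_name = c("A", "B"), avg_diff = c(0.1, 0.9),
                   statistic = 0, p_value = c(1e-4, 1e-4),
                   p_adjusted = c(2e-3, 2e-3), direction = "up",
                   significant = TRUE, stringsAsFactors = FALSE)
  rl2 <- build_rank_lists(d2, "C1", "up")
  expect_identical(rl2$lists$m1, c("B", "A"))
})

test_that("rank normalisation follows the stated dialect rules", {
  rl <- rank_lists(list(mA = c("S1"), mB = character()), n_total = 4)
  r <- normalize_ranks(rl, "union")
  expect_equal(unname(r["S1", ]), c(0.25, 1))

  rl5 <- rank_lists(list(mA = paste0("S", 1:5), mB = paste0("S", 1:5)),
                    n_total = 5)
  r5 <- normalize_ranks(rl5, "union")
  expect_equal(unname(r5["S2", ]), c(0.4, 0.4))
  expect_equal(unname(r5["S5", ]), c(1, 1))   # ranked last everywhere

  # paper-literal: per-set max across methods after imputing absences
  rp <- normalize_ranks(rank_lists(list(mA = c("S1", "S2"), mB = c("S2")),
                                   n_total = 10), "paper")
  # S1: ranks (1, imputed 10) -> (0.1, 1); S2: ranks (2, 1) -> (1, 0.5)
  expect_equal(unname(rp["S1", ]), c(0.1, 1))
  expect_equal(unname(rp["S2", ]), c(1, 0.5))
})

test_that("aggregate reproduces the unanimous-top-set arithmetic", {
  orders <- stats::setNames(
    rep(list(paste0("S", sprintf("%02d", 1:50))), 6),
    paste0("m", 1:6))
  d <- fake_differential(orders)
  res <- rra_aggregate(d, methods = names(orders))
  top <- res[res$set_name == "S01" & res$direction == "up", ]
  expect_equal(top$rho, 0.02^6, tolerance = 1e-12)
  expect_equal(top$p_corrected, 6 * 0.02^6, tolerance = 1e-10)
  expect_equal(top$n_methods_detected, 6)
  expect_true(all(res$p_corrected > 0 & res$p_corrected <= 1))
  # first beta term of the top set: 1 - 0.98^6
  rl <- build_rank_lists(d, "C1", "up", methods = names(orders))
  b <- beta_score(normalize_ranks(rl)["S01", ])
  expect_equal(b$beta[1], 1 - 0.98^6)
})

test_that("aggregate recovers planted sets and fills membership flags", {
  sim <- small_sim()
  res <- small_rra()
  for (i in seq_len(nrow(sim$truth))) {
    row <- res[res$set_name == sim$truth$set_name[i] &
                 res$cluster == sim$truth$cluster[i] &
                 res$direction == "up", ]
    expect_equal(nrow(row), 1)
    expect_lte(row$p_corrected, 0.05)
    expect_equal(row$n_methods_detected,
                 sum(unlist(row[paste0("in_", names(small_scores()))])))
  }
  expect_true(!is.unsorted(res$p_corrected))
})

test_that("improving one method's rank never increases rho", {
  set.seed(41)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    r <- stats::runif(k, min = 0.05, max = 1)
    rho0 <- beta_score(r)$rho
    j <- sample(k, 1)
    r_better <- r
    r_better[j] <- r[j] * stats::runif(1)
    if (r_better[j] <= 0) next
    expect_lte(beta_score(r_better)$rho, rho0 + 1e-12)
  }
})

test_that("aggregation is invariant to method order", {
  d <- fake_differential(list(m1 = c("A", "B", "C"), m2 = c("C", "A", "B"),
                              m3 = c("B", "C", "A")))
  r1 <- rra_aggregate(d, methods = c("m1", "m2", "m3"))
  r2 <- rra_aggregate(d, methods = c("m3", "m1", "m2"))
  cols <- c("cluster", "direction", "set_name", "rho", "p_corrected",
            "n_methods_detected")
  expect_equal(r1[, cols], r2[, cols])
})

test_that("both dialects run on the planted fixture and record themselves", {
  d <- small_differential()
  ru <- rra_aggregate(d, dialect = "union")
  rp <- rra_aggregate(d, dialect = "paper")
  expect_identical(attr(ru, "dialect"), "union")
  expect_identical(attr(rp, "dialect"), "paper")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rra(ru, f)
  expect_match(readLines(f, n = 1), "rra_dialect=union")
  back <- read_rra(f)
  expect_identical(attr(back, "dialect"), "union")
  expect_equal(back$p_corrected, ru$p_corrected)
})

test_that("RRA with Bonferroni is conservative under the uniform null", {
  set.seed(31)
  k <- 6L; N <- 50L
  n_rep <- 200L
  n_sig <- 0L
  for (rep in seq_len(n_rep)) {
    ranks <- replicate(k, sample.int(N))  # one random ordering per method
    r <- ranks / N
    rho <- apply(r, 1L, function(ri) beta_score(ri)$rho)
    n_sig <- n_sig + sum(pmin(1, rho * k) <= 0.05)
  }
  frac <- n_sig / (n_rep * N)
  se <- sqrt(0.05 * 0.95 / (n_rep * N))
  expect_lte(frac, 0.05 + 3 * se)
})
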