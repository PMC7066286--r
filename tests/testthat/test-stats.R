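test_that("rank-sum test reproduces hand-enumerated exact p-values", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), tail = "less")
  expect_equal(r$rank_sum_w, 6)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 1 / 20)      # C(6,3) = 20 assignments
  expect_true(r$exact)

  r2 <- rank_sum_test(c(1, 4), c(2, 3), tail = "two-sided")
  expect_equal(r2$rank_sum_w, 5)       # equals its null expectation
  expect_equal(r2$p_value, 1)

  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "oddlock_parameter_error")
})

test_that("exact p equals exhaustive permutation for tie-free samples", {
  withr::with_seed(20, {
    for (k in 1:25) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      x <- sample(seq(1, 40), n1)
      y <- sample(setdiff(seq(1, 40), x), n2)
      tail <- sample(c("two-sided", "greater", "less"), 1)
      r <- rank_sum_test(x, y, tail = tail)
      expect_equal(r$p_value, perm_ranksum_p(x, y, tail), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d tail=%s", n1, n2, tail))
      # statistic invariants
      expect_equal(r$u_statistic, r$rank_sum_w - n1 * (n1 + 1) / 2)
      expect_gte(r$u_statistic, 0)
      expect_lte(r$u_statistic, n1 * n2)
    }
  })
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 5)
  y <- c(2, 3, 6, 7)
  r <- rank_sum_test(x, y, tail = "two-sided")
  expect_false(r$exact)
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  withr::with_seed(31, {
    for (k in 1:20) {
      p <- runif(sample(1:8, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj <= 1))
      # monotone in the sorted order
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-12))
    }
  })
  expect_error(bh_adjust(c(0.2, 1.4)), class = "oddlock_parameter_error")
})

test_that("Spearman correlation matches rank-Pearson and known cases", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman_cor(1:4, c(2, 1, 4, 3))$rho, 0.6)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  withr::with_seed(44, {
    for (k in 1:15) {
      x <- sample(1:100, 8)
      y <- sample(1:100, 8)
      expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)),
                   tolerance = 1e-12)
    }
  })
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "Constant")
  expect_true(out$degenerate)
  expect_error(spearman_cor(1:2, 1:2), class = "oddlock_parameter_error")
})

test_that("hypothesis suite runs the planned tests with BH within measure", {
  withr::with_seed(77, {
    oc <- tidyr::expand_grid(subject = 1:18,
                             condition = c("pre", "during", "post"))
    oc$group <- ifelse(oc$subject <= 9, "stim", "sham")
    pre_amp <- rnorm(18, 8, 2)[match(oc$subject, 1:18)]
    oc$p3_amp_uv <- ifelse(
      oc$condition == "during", NA,
      pre_amp + ifelse(oc$condition == "post", rnorm(54, 0, 0.5), 0) +
        ifelse(oc$condition == "post" & oc$group == "stim", 3, 0))
    oc$ersp_max_db <- ifelse(oc$condition == "during", NA, rnorm(54, 5, 1))
    oc$rt_mean_ms <- rnorm(54, 450, 40)
    oc$rt_sd_ms <- rnorm(54, 100, 15)
    oc$omissions <- rpois(54, 5)
    oc$commissions <- rpois(54, 1)
  })
  suppressMessages(res <- run_hypothesis_suite(build_outcome_table(oc)))
  # amplitude and ERSP: one right-tailed uncorrected test each
  amp <- res[res$measure == "p3_amp_uv", ]
  expect_equal(nrow(amp), 1)
  expect_equal(amp$tail, "greater")
  expect_true(is.na(amp$p_adjusted))
  # behavioral measures: three comparisons, adjusted within measure
  for (m in c("rt_mean_ms", "rt_sd_ms", "omissions")) {
    block <- res[res$measure == m, ]
    expect_equal(nrow(block), 3)
    expect_setequal(block$comparison,
                    c("pre-to-post", "pre-to-during", "during-to-post"))
    expect_equal(block$tail[block$comparison == "during-to-post"],
                 "two-sided")
    expect_true(all(block$p_adjusted >= block$p_raw - 1e-12))
    expect_equal(block$p_adjusted, bh_oracle(block$p_raw),
                 tolerance = 1e-12)
  }
  # rare commissions are excluded from inference
  expect_false("commissions" %in% res$measure)
  # the planted amplitude effect is detected
  expect_lt(amp$p_raw, 0.05)
})

test_that("change-score correlations return one cell per measure pair", {
  withr::with_seed(13, {
    ch <- tidyr::expand_grid(subject = 1:10,
                             measure = c("p3_amp_uv", "rt_mean_ms",
                                         "omissions"))
    ch$comparison <- "pre-to-post"
    ch$value <- rnorm(30)
  })
  cc <- correlate_changes(ch)
  expect_equal(nrow(cc), 3)        # C(3, 2) pairs
  expect_true(all(abs(cc$rho) <= 1))
  expect_true(all(cc$n == 10))
})

test_that("tidiers expose broom-style views", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(r)
  expect_true(all(c("statistic", "p.value", "method") %in% names(td)))
  g <- glance(r)
  expect_equal(g$n_x, 3)
})
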