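test_that("U test matches hand values on the canonical example", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_identical(r$method, "exact")
  # swapping samples maps U to n_x n_y - U with the same p
  r2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$u_statistic, 9)
  expect_equal(r2$p_value, r$p_value)
})

test_that("exact p-values equal brute-force enumeration for tie-free n <= 10", {
  set.seed(14)
  for (nx in 2:5) {
    for (ny in 2:(10 - nx)) {
      x <- rnorm(nx); y <- rnorm(ny, 0.5)
      r <- mann_whitney_u(x, y)
      o <- mwu_enum(x, y)
      expect_identical(r$method, "exact")
      expect_equal(r$u_statistic, o$u)
      expect_equal(r$p_value, o$p, tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation is close to exact at n = 8 + 8", {
  devs <- cladescan:::with_seed(15, {
    vapply(1:20, function(i) {
      x <- rnorm(8); y <- rnorm(8, 0.4)
      abs(mann_whitney_u(x, y, method = "exact")$p_value -
            mann_whitney_u(x, y, method = "normal_approx")$p_value)
    }, numeric(1))
  })
  # the continuity-corrected approximation tracks the exact p to about 0.01
  expect_lt(mean(devs), 0.01)
  expect_lt(max(devs), 0.02)
})

test_that("degenerate and tied samples are handled", {
  r <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_true(r$zero_variance)
  expect_equal(r$p_value, 1)
  expect_equal(r$u_statistic, 3 * 2 / 2)
  rt <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_identical(rt$method, "normal_approx")  # ties force the approximation
  expect_true(rt$p_value >= 0 && rt$p_value <= 1)
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$h_statistic, 0)
  expect_equal(kruskal_wallis(list(c(5, 5, 5), c(5, 5)))$p_value, 1)
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 with rank means 2 and 5
  expect_equal(r$h_statistic, 12 / (6 * 7) * (3 * 1.5^2 + 3 * 1.5^2),
               tolerance = 1e-9)
  # rank test: invariant under monotone transformation
  r2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
  expect_equal(r2$h_statistic, r$h_statistic)
  expect_equal(r2$p_value, r$p_value)
})

test_that("bootstrap median CI is seeded, anchored and calibrated", {
  expect_equal(bootstrap_median_ci(rep(3, 10), 100, seed = 1),
               c(lower = 3, upper = 3))
  set.seed(16)
  v <- rnorm(50)
  ci <- bootstrap_median_ci(v, 500, seed = 2)
  expect_identical(bootstrap_median_ci(v, 500, seed = 2), ci)
  expect_true(ci["lower"] <= median(v) && median(v) <= ci["upper"])
  # coverage close to the nominal level on normal samples
  hits <- cladescan:::with_seed(17, {
    vapply(1:300, function(i) {
      s <- rnorm(50)
      ci <- bootstrap_median_ci(s, 400)
      ci["lower"] <= 0 && 0 <= ci["upper"]
    }, logical(1))
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.05)
})

test_that("compare_clade_metrics tests each descriptor with adjustment", {
  set.seed(18)
  tbl <- tibble::tibble(
    clade = rep(c("Northern", "Southern"), each = 30),
    circularity = c(rnorm(30, 0.7, 0.02), rnorm(30, 0.8, 0.02)),
    eccentricity = rnorm(60, 0.5, 0.05),
    solidity = c(rnorm(30, 0.93, 0.01), rnorm(30, 0.97, 0.01)),
    extent = rnorm(60, 0.7, 0.03),
    minor_axis_length = rnorm(60, 0.5, 0.05))
  res <- compare_clade_metrics(tbl)
  expect_equal(nrow(res), 5)
  expect_true(all(res$p_bonferroni >= res$p_value))
  expect_true(all(res$p_value >= 0 & res$p_bonferroni <= 1))
  expect_lt(res$p_value[res$metric == "circularity"], 0.001)
  expect_gt(res$p_value[res$metric == "eccentricity"], 0.01)
  # identical groups: all p = 1
  tbl2 <- tbl
  tbl2[tbl2$clade == "Southern", -1] <- tbl2[tbl2$clade == "Northern", -1]
  expect_true(all(compare_clade_metrics(tbl2)$p_value == 1))
  expect_error(compare_clade_metrics(tbl[, -2]), "missing columns")
})

test_that("run summaries report order statistics per configuration", {
  res <- tibble::tibble(
    iteration = rep(1:10, each = 2), mixed = FALSE,
    test_kind = rep(c("even", "full"), 10),
    macro_f1 = rep(c(0.9, 0.8), 10) + rep(seq(0, 0.09, by = 0.01), each = 2),
    class = "Northern", precision = 1, recall = 1, f1 = 1, seed = 1,
    n_test = 40)
  sm <- summarize_runs(res, n_boot = 100)
  expect_equal(nrow(sm$summary), 2)
  expect_true(all(sm$summary$min <= sm$summary$median &
                    sm$summary$median <= sm$summary$max))
  even <- sm$summary[sm$summary$test_kind == "even", ]
  expect_equal(even$median, median(seq(0.9, 0.99, by = 0.01)))
  expect_s3_class(sm$plot, "ggplot")
  # single iteration: median = max = min
  one <- summarize_runs(res[res$iteration == 1, ], n_boot = 50)
  expect_true(all(one$summary$median == one$summary$max))
})
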