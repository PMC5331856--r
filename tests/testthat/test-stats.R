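test_that("paired t and Pearson match brute-force textbook formulas", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    # independent arithmetic oracles
    d <- x - y
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * pt(-abs(t_oracle), n - 1)
    tt <- paired_t(x, y)
    expect_equal(tt$statistic, t_oracle, tolerance = 1e-12)
    expect_equal(tt$p, p_oracle, tolerance = 1e-12)
    expect_equal(tt$df, n - 1)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tr <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    pr_oracle <- 2 * pt(-abs(tr), n - 2)
    ct <- pearson_r(x, y)
    expect_equal(ct$statistic, r_oracle, tolerance = 1e-12)
    expect_equal(ct$p, pr_oracle, tolerance = 1e-12)
    expect_equal(ct$df, n - 2)
  }
})

test_that("degenerate inputs are flagged, not silently mangled", {
  x <- c(1, 2, 3, 4)
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "zero_variance")
  shifted <- paired_t(x + 2, x)
  expect_true(is.infinite(shifted$statistic))
  expect_true(is.na(shifted$p))
  expect_error(paired_t(1:2, 2:3), "3 pairs")
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_error(pearson_r(rep(1, 4), x), "variance")
})

test_that("percent modulation is signed and unbounded", {
  expect_equal(percent_modulation(1.4541, 1.0), 45.41)
  expect_equal(percent_modulation(2, 2), 0)
  expect_equal(abs(percent_modulation(-8.5977, -1.0)), 759.77)
  expect_equal(percent_modulation(-8.007, -2), -300.35)
  expect_error(percent_modulation(1, 0), "zero")
})

test_that("Holm step-down uses alpha/(m-k+1) thresholds with prefix rejections", {
  h <- holm_bonferroni(runif(10), alpha = 0.05)
  expect_equal(h$threshold[1], 0.005)
  expect_equal(h$threshold[2], 0.05 / 9)
  expect_true(all(diff(h$threshold) > 0))
  expect_false(any(holm_bonferroni(rep(1, 6))$significant))
  # brute-force check of the step-down rule
  h3 <- holm_bonferroni(c(0.001, 0.004, 0.03), alpha = 0.05)
  expect_equal(h3$significant, c(TRUE, TRUE, TRUE))
  h3b <- holm_bonferroni(c(0.001, 0.02, 0.03), alpha = 0.05)
  expect_equal(h3b$significant, c(TRUE, TRUE, TRUE))
  h3c <- holm_bonferroni(c(0.001, 0.03, 0.04), alpha = 0.05)
  expect_equal(h3c$significant, c(TRUE, FALSE, FALSE)) # stop at first failure
})

test_that("Holm rejections sit between Bonferroni and uncorrected", {
  set.seed(77)
  for (rep in 1:100) {
    m <- sample(3:12, 1)
    p <- runif(m)^sample(1:3, 1)
    h <- holm_bonferroni(p, alpha = 0.05)
    rejected <- as.integer(sub("test", "", h$label[h$significant]))
    expect_true(all(rejected %in% which(p < 0.05)))
    expect_true(all(which(p < 0.05 / m) %in% rejected))
    # agreement with stats::p.adjust on the boundary-free draws
    adj <- p.adjust(p, "holm")
    expect_equal(sort(rejected), which(adj < 0.05))
  }
})

test_that("the planned roster always yields exactly 10 Holm-ordered tests", {
  set.seed(5)
  m <- null_measures(13)
  fam <- sample(1:7, 13, replace = TRUE)
  rep <- run_planned_comparisons(m, fam)
  expect_equal(nrow(rep$tests), 10)
  expect_equal(nrow(rep$holm), 10)
  expect_equal(sum(rep$tests$family == "paired_t"), 6)
  expect_equal(sum(rep$tests$family == "pearson"), 4)
  expect_equal(rep$tests$df[rep$tests$family == "paired_t"], rep(12L, 6))
  expect_true(all(diff(rep$holm$threshold) > 0))
  # missing cells are named
  m2 <- m[!(m$subject == 3 & m$peak == "peak2" & m$condition == "random"), ]
  expect_error(run_planned_comparisons(m2, fam), "peak2")
})

test_that("under the simulator's null each planned test rejects near alpha", {
  set.seed(2024)
  n_rep <- 500
  hits <- matrix(FALSE, n_rep, 10)
  for (i in seq_len(n_rep)) {
    m <- null_measures(13)
    fam <- sample(1:7, 13, replace = TRUE)
    rep <- run_planned_comparisons(m, fam)
    hits[i, ] <- rep$tests$p < 0.05
  }
  rates <- colMeans(hits)
  # binomial 3-sigma band around 0.05 with 500 replicates
  expect_true(all(rates > 0.02 & rates < 0.08),
              info = paste(round(rates, 3), collapse = " "))
})
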