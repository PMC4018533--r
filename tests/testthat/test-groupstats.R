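test_that("contrast-F equals the sums-of-squares RM-ANOVA oracle", {
  set.seed(51)
  for (rep in 1:5) {
    df <- random_rm_table(8, effect = runif(1, 0, 1))
    ours <- rm_anova_2x2(df)
    oracle <- aov_rm_oracle(df)
    expect_equal(ours$F[ours$effect == "condition_main"],
                 unname(oracle["condition_main"]), tolerance = 1e-8)
    expect_equal(ours$F[ours$effect == "stimulus_main"],
                 unname(oracle["stimulus_main"]), tolerance = 1e-8)
    expect_equal(ours$F[ours$effect == "interaction"],
                 unname(oracle["interaction"]), tolerance = 1e-8)
    expect_equal(ours$df1, rep(1, 3))
    expect_equal(ours$df2, rep(7, 3))
  }

  # identical cells within subject: all effects zero
  df0 <- random_rm_table(6)
  df0$value <- rep(rnorm(6), 4)
  expect_equal(rm_anova_2x2(df0)$F, rep(0, 3))

  expect_error(rm_anova_2x2(random_rm_table(5)[-1, ]), "exactly one value")
})

test_that("one-way RM-ANOVA is the squared paired t", {
  set.seed(52)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  df <- data.frame(subject = rep(sprintf("s%02d", 1:12), 2),
                   level = rep(c("a", "b"), each = 12),
                   value = c(x, y))
  res <- rm_anova_oneway(df)
  tt <- t.test(y, x, paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  df$value <- rep(x, 2)
  expect_equal(rm_anova_oneway(df)$F, 0)
})

test_that("type-I error of the contrast F is nominal under the null", {
  set.seed(53)
  nrep <- 400
  hits <- vapply(seq_len(nrep), function(i) {
    df <- random_rm_table(10)
    any(rm_anova_2x2(df)$p[1] < 0.05)
  }, TRUE)
  rate <- mean(hits)
  ci <- 0.05 + c(-1, 1) * 2.6 * sqrt(0.05 * 0.95 / nrep)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("post hoc paired t matches the textbook formula", {
  set.seed(54)
  x <- rnorm(15); y <- rnorm(15, 0.4)
  res <- posthoc_paired_t(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # sign-flip antisymmetry and the zero case
  expect_equal(posthoc_paired_t(y, x)$t, -res$t)
  z <- rnorm(8)
  expect_equal(posthoc_paired_t(z, z), list(t = 0, df = 7, p = 1))
})

test_that("spearman equals Pearson-on-ranks and respects monotone maps", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$r, -1)

  set.seed(55)
  x <- sample(1:8, 20, replace = TRUE)   # heavy ties
  y <- x + rnorm(20, 0, 2)
  ours <- spearman_correlation(x, y)
  expect_equal(ours$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # invariance under strictly monotone transforms of either variable
  expect_equal(spearman_correlation(exp(x), y)$r, ours$r)
  expect_equal(spearman_correlation(x, qlogis(plogis(y)))$r, ours$r,
               tolerance = 1e-12)

  perm <- spearman_correlation(x, y, n_perm = 500, seed = 2)
  expect_true(perm$p_perm > 0 && perm$p_perm <= 1)
  expect_error(spearman_correlation(1:4, 1:4), "at least 5")
})

test_that("BH-FDR step-up adjustment is exact and conservative", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))

  set.seed(56)
  for (rep in 1:5) {
    p <- runif(50)^2
    adj <- fdr_correct(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
  }

  # under a global null the BH any-discovery rate is about alpha
  nrep <- 500
  hits <- vapply(seq_len(nrep), function(i)
    any(fdr_correct(runif(20)) < 0.05), TRUE)
  expect_lte(mean(hits), 0.05 + 2.6 * sqrt(0.05 * 0.95 / nrep))
})

test_that("dprime evaluates z(hit) - z(fa) with log-linear rescue", {
  expect_equal(dprime(0.3, 0.3), 0)
  expect_equal(dprime(0.624, 0.220), qnorm(0.624) - qnorm(0.220))
  expect_equal(dprime(0.624, 0.220), 1.09, tolerance = 0.005)

  d <- dprime(1, 0, n_signal = 75, n_noise = 75)
  expect_true(is.finite(d) && d > 0)
  expect_equal(d, qnorm(75.5 / 76) - qnorm(0.5 / 76))
  expect_error(dprime(1, 0, correction = "loglinear"), "requires")
  expect_true(is.infinite(dprime(1, 0, correction = "none")))
})
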