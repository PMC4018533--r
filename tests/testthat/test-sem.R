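test_that("loop-model enumeration covers every unidirectional orientation", {
  ms <- enumerate_loop_models(c("AC", "TPJ", "vPMC"))
  expect_length(ms, 8)
  expect_length(unique(names(ms)), 8)
  # both cyclic orderings are present
  cyc1 <- vapply(ms, function(m)        # AC->vPMC->TPJ->AC
    all(c("AC->vPMC", "vPMC->TPJ", "TPJ->AC") %in%
          apply(m$edges, 1, paste, collapse = "->")), TRUE)
  cyc2 <- vapply(ms, function(m)        # AC->TPJ->vPMC->AC
    all(c("AC->TPJ", "TPJ->vPMC", "vPMC->AC") %in%
          apply(m$edges, 1, paste, collapse = "->")), TRUE)
  expect_equal(sum(cyc1), 1)
  expect_equal(sum(cyc2), 1)
  # every model orients all three undirected edges exactly once
  for (m in ms) {
    und <- apply(m$edges, 1, function(e) paste(sort(e), collapse = "-"))
    expect_setequal(und, c("AC-TPJ", "AC-vPMC", "TPJ-vPMC"))
  }
  # generalization: 2 nodes, 1 edge -> 2 models
  expect_length(enumerate_loop_models(c("X", "Y")), 2)
})

test_that("band-signal extraction standardizes and averages correctly", {
  set.seed(61)
  ep <- sine_pair_epochs(6, noise_sd = 0.5)
  tf <- morlet_transform(ep, frequency_grid(14, 26, 3),
                         time_range = c(50, 200))
  sig <- extract_band_signal(tf, c(14, 26), c(50, 200))
  expect_equal(dim(sig), c(6, 2, 150))
  expect_equal(apply(sig, c(1, 2), mean), matrix(0, 6, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(sig, c(1, 2), sd), matrix(1, 6, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # multi-bin average equals the direct arithmetic oracle
  jf <- which(tf$freqs >= 14 & tf$freqs <= 26)
  raw <- apply(Re(tf$coef[, 1, jf, ]), c(1, 3), mean)
  z <- t(scale(t(raw)))   # per-trial standardization oracle
  expect_equal(sig[, 1, ], unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single bin: just the standardized real part
  sig1 <- extract_band_signal(tf, c(20, 20), c(50, 200))
  raw1 <- Re(tf$coef[, 1, which(tf$freqs == 20), ])
  expect_equal(cor(sig1[1, 1, ], raw1[1, ]), 1, tolerance = 1e-12)

  expect_error(extract_band_signal(tf, c(90, 95), c(50, 200)), "empty")
})

test_that("RMSEA follows its closed form", {
  expect_equal(rmsea(30, 9, 120), sqrt(21 / (9 * 119)))
  expect_equal(rmsea(30, 9, 120), 0.140, tolerance = 1e-3)
  expect_equal(rmsea(8, 9, 100), 0)     # chi^2 <= df floors at zero
})

test_that("ML fit recovers parameters from an implied covariance", {
  ms <- enumerate_loop_models(c("A", "B", "C"))
  m <- ms[["B->A, A->C, C->B"]]         # cyclic A->C->B->A
  edge_idx <- phasesync:::loop_edge_index(m)
  beta0 <- c(0.6, 0.4, 0.5)
  psi0 <- c(1, 0.8, 1.2)
  phi0 <- matrix(c(1, 0.3, 0.1, 0.3, 1, 0.2, 0.1, 0.2, 1), 3)
  sigma0 <- phasesync:::sem_implied_cov(beta0, psi0, phi0, edge_idx)
  fit <- phasesync:::fit_loop_cov(m, sigma0, n_effective = 200)
  expect_equal(unname(fit$beta), beta0, tolerance = 1e-3)
  expect_equal(fit$fml, 0, tolerance = 1e-7)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$df, 9)
})

test_that("the generating loop model fits well; misdirected ones fit worse", {
  ms <- enumerate_loop_models(c("AC", "TPJ", "vPMC"), lag = 12)
  gen <- ms[["TPJ->AC, AC->vPMC, vPMC->TPJ"]]    # AC->vPMC->TPJ->AC
  wrong <- ms[["AC->TPJ, vPMC->AC, TPJ->vPMC"]]  # reversed cycle
  sig <- generate_loop_signals(gen, n_trials = 300, n_samples = 120,
                               beta = 0.5, lag = 12, seed = 62)
  fg <- fit_loop_model(gen, sig, lag = 12)
  fw <- fit_loop_model(wrong, sig, lag = 12)
  expect_lte(fg$rmsea, 0.07)
  expect_gt(fw$rmsea, fg$rmsea)
  expect_equal(unname(fg$beta), rep(0.5, 3), tolerance = 0.1)

  # RMSEA of the generating model shrinks with trial count while the
  # misdirected model's does not improve comparably
  grid <- c(60, 200, 600)
  rg <- rw <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s2 <- generate_loop_signals(gen, grid[i], 120, beta = 0.5, lag = 12,
                                seed = 63)
    rg[i] <- fit_loop_model(gen, s2, lag = 12)$rmsea
    rw[i] <- fit_loop_model(wrong, s2, lag = 12)$rmsea
  }
  expect_lte(rg[3], rg[1] + 0.01)
  expect_true(all(rw - rg > 0.05))

  ranking <- compare_models(list(gen = fg, wrong = fw))
  expect_equal(ranking$model[1], "gen")
  expect_true(ranking$good_fit[1])
})

test_that("pairwise directionality recovers a planted lagged influence", {
  m <- enumerate_loop_models(c("A", "B"), lag = 8)[[1]]   # A->B
  set.seed(64)
  nrep <- 15
  hits <- vapply(seq_len(nrep), function(r) {
    sigs <- lapply(1:20, function(s)
      generate_loop_signals(m, n_trials = 12, n_samples = 80, beta = 0.8,
                            lag = 8, seed = 1000 * r + s))
    pd <- fit_pairwise(sigs, c("A", "B"), lag = 8, n_boot = 0,
                       n_perm = 999, seed = r)
    pd$p < 0.05 && mean(pd$beta_ab) > mean(pd$beta_ba)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("direction-symmetric data give a nominal false-positive rate", {
  # shared zero-lag source with equal influence on both nodes
  set.seed(65)
  nrep <- 60
  hits <- vapply(seq_len(nrep), function(r) {
    sigs <- lapply(1:10, function(s) {
      src <- matrix(rnorm(10 * 80), 10, 80)
      arr <- array(0, c(10, 2, 80), dimnames = list(NULL, c("A", "B"), NULL))
      arr[, 1, ] <- src + matrix(rnorm(800), 10, 80)
      arr[, 2, ] <- src + matrix(rnorm(800), 10, 80)
      arr
    })
    pd <- fit_pairwise(sigs, c("A", "B"), lag = 8, n_boot = 0,
                       n_perm = 399, seed = r)
    pd$p < 0.05
  }, TRUE)
  rate <- mean(hits)
  expect_lte(rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / nrep))

  # independent signals: beta estimates center at zero
  sigs0 <- lapply(1:12, function(s) {
    arr <- array(rnorm(10 * 2 * 80), c(10, 2, 80),
                 dimnames = list(NULL, c("A", "B"), NULL))
    arr
  })
  pd0 <- fit_pairwise(sigs0, c("A", "B"), lag = 8, n_boot = 50,
                      n_perm = 199, seed = 66)
  expect_lt(abs(mean(pd0$beta_ab)), 0.1)
  expect_lt(abs(mean(pd0$beta_ba)), 0.1)
  # bootstrap CIs bracket the per-subject point estimates
  expect_true(all(pd0$ci_ab[, 1] <= pd0$beta_ab + 1e-12 &
                    pd0$beta_ab <= pd0$ci_ab[, 2] + 1e-12))
})

test_that("degenerate SEM inputs raise labeled errors", {
  m <- enumerate_loop_models(c("A", "B", "C"))[[1]]
  sig <- generate_loop_signals(m, 20, 60, lag = 5, seed = 1)
  # duplicated node traces -> singular covariance
  sig[, 2, ] <- sig[, 1, ]
  expect_error(fit_loop_model(m, sig, lag = 5), "singular")
  expect_error(phasesync:::lagged_beta(matrix(1, 4, 30), matrix(1, 4, 30), 5),
               "zero-variance")
})
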