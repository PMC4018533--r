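test_that("cross-spectrum has the analytic phase and matches its oracle", {
  set.seed(31)
  ep <- sine_pair_epochs(20, f = 20, delay_ms = 12.5)  # quarter cycle
  tf <- morlet_transform(ep, frequency_grid(20, 20, 1))
  cs <- cross_spectrum(tf, c("A", "B"))
  mid <- which(tf$time > -100 & tf$time < 400)
  expect_equal(mean(Arg(cs[, 1, mid])), pi / 2, tolerance = 1e-3)

  # element-wise product oracle
  oracle <- tf$coef[, 1, 1, ] * Conj(tf$coef[, 2, 1, ])
  expect_equal(cs[, 1, ], oracle)

  # identical signals: imaginary part identically zero
  ep0 <- sine_pair_epochs(10, delay_ms = 0)
  tf0 <- morlet_transform(ep0, frequency_grid(20, 20, 1))
  cs0 <- cross_spectrum(tf0, c("A", "A"))
  expect_equal(max(abs(Im(cs0))), 0)

  expect_error(cross_spectrum(tf, c("A", "nope")), "unknown ROI")
})

test_that("wpli implements |sum Im| / sum |Im| with flagged 0/0", {
  # direct evaluation of the estimator formula: Im = {+1, +1, -1} -> 1/3
  cross <- array(complex(imaginary = c(1, 1, -1)), c(3, 1, 1))
  expect_equal(as.vector(wpli(cross)), 1 / 3)

  # constant non-zero lag -> 1
  cross1 <- array(complex(modulus = runif(40, 0.5, 2),
                          argument = pi / 3), c(40, 1, 1))
  expect_equal(as.vector(wpli(cross1)), 1)

  # all imaginary parts zero -> undefined (NA), not 0
  cross0 <- array(complex(real = rnorm(10)), c(10, 1, 1))
  expect_true(is.na(wpli(cross0)))

  expect_error(wpli(array(1i, c(1, 2, 2))), "at least 2 trials")
})

test_that("wpli is bounded, scale-invariant and phase-rotation invariant", {
  set.seed(32)
  for (rep in 1:20) {
    cross <- array(complex(real = rnorm(5 * 3 * 4),
                           imaginary = rnorm(5 * 3 * 4)), c(5, 3, 4))
    w <- wpli(cross)
    expect_true(all(w >= 0 & w <= 1, na.rm = TRUE))
    # positive rescaling of one signal's coefficients
    expect_equal(wpli(cross * 3.7), w)
    # common unit phase rotation of both signals cancels in a*Conj(b)
    a <- array(complex(real = rnorm(60), imaginary = rnorm(60)), c(5, 3, 4))
    b <- array(complex(real = rnorm(60), imaginary = rnorm(60)), c(5, 3, 4))
    rot <- exp(1i * 1.1)
    expect_equal(wpli((a * rot) * Conj(b * rot)), wpli(a * Conj(b)))
  }
})

test_that("wpli grows monotonically with coupling strength", {
  des <- small_design()
  m <- vapply(c(0.2, 0.6, 2), function(kappa) {
    cs <- coupling_spec(c("AC-lh", "vPMC-lh"), 20, phase_lag = pi / 2,
                        coupling_strength = kappa)
    vals <- vapply(1:3, function(s) {
      ep <- generate_subject(des, list(cs), seed = 100 + s,
                             evoked_amplitude = 0)
      tf <- morlet_transform(ep, frequency_grid(20, 20, 1),
                             time_range = c(50, 200))
      wpli_statistic(tf, c("AC-lh", "vPMC-lh"))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(m) > 0))
})

test_that("window averaging follows the 10-ms bin arithmetic", {
  time <- seq(50, 199, 1)
  w <- matrix(0.4, 2, length(time))
  wa <- window_average(w, time)
  expect_equal(dim(wa$wpli), c(2, 15))
  expect_equal(unique(as.vector(wa$wpli)), 0.4)
  expect_equal(wa$window_starts, seq(50, 190, 10))

  # linear ramp 0 -> 1: bin means are the bin midpoints
  ramp <- matrix(seq(0, 1, length.out = length(time)), 1)
  wa2 <- window_average(ramp, time)
  mids <- (wa$window_starts + 4.5 - 50) / 149
  expect_equal(as.vector(wa2$wpli), mids, tolerance = 1e-12)

  # NA handling: undefined samples excluded, all-NA bin stays NA
  w3 <- matrix(0.5, 1, length(time))
  w3[1, 1:5] <- NA
  w3[1, 11:20] <- NA
  wa3 <- window_average(w3, time)
  expect_equal(wa3$wpli[1, 1], 0.5)
  expect_true(is.na(wa3$wpli[1, 2]))

  expect_error(window_average(w, time + 0.5), "not aligned")
  expect_error(window_average(w, time, c(50, 195)), "whole number")
})

test_that("zero-lag mixing (volume conduction) does not inflate wpli", {
  # two ROIs receive the SAME source with zero lag plus independent noise
  set.seed(33)
  time <- seq(-200, 499, 1)
  ntr <- 60
  dat <- array(0, c(ntr, 2, length(time)))
  for (k in seq_len(ntr)) {
    src <- 2 * cos(2 * pi * 20 * time / 1000 + runif(1, 0, 2 * pi))
    dat[k, 1, ] <- src + rnorm(length(time))
    dat[k, 2, ] <- src + rnorm(length(time))
  }
  ep <- epoch_array(dat, time, c("A", "B"), 1000)
  tf <- morlet_transform(ep, frequency_grid(8, 80, 3),
                         time_range = c(50, 200))
  st <- surrogate_test(tf, c("A", "B"), n_shuffles = 199, seed = 7)
  expect_gt(st$p_value, 0.05)
})

test_that("sync maps assemble and export to long format", {
  set.seed(34)
  ep <- sine_pair_epochs(12, noise_sd = 0.5)
  tf <- morlet_transform(ep, frequency_grid(17, 23, 3),
                         time_range = c(50, 200))
  sm <- sync_map(tf, meta = list(subject = "S01", condition = "passive",
                                 stimulus = "noisy"))
  expect_equal(dim(sm$wpli), c(1, 3, 15))
  df <- sync_map_to_df(sm)
  expect_equal(nrow(df), 45)
  expect_named(df, c("subject", "condition", "stimulus", "pair",
                     "frequency", "window_start", "wpli"))
  expect_true(all(df$wpli >= 0 & df$wpli <= 1, na.rm = TRUE))
})
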