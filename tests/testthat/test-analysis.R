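test_that("cross-correlation identifies lags and rejects degenerate input", {
  set.seed(20)
  a <- rnorm(2000)
  xc <- cross_correlation(a, a, 5)
  expect_equal(xc$cor[xc$lag == 0], 1)
  # b trails a by 3 frames, so a leads: peak at positive lag 3
  b <- c(rep(0, 3), a[1:(2000 - 3)])
  xc2 <- cross_correlation(a, b, 6)
  expect_equal(xc2$lag[which.max(xc2$cor)], 3)
  w1 <- rnorm(5000); w2 <- rnorm(5000)
  xc3 <- cross_correlation(w1, w2, 10)
  expect_lt(max(abs(xc3$cor)), 3 / sqrt(5000))
  expect_error(cross_correlation(rep(1, 100), rnorm(100), 5), "constant")
})

test_that("the asymmetry index vanishes for symmetric curves", {
  xc <- data.frame(lag = -5:5, cor = c(5:1, 9, 1:5) / 10)
  expect_equal(asymmetry_index(xc), 0)
  xc$cor[xc$lag > 0] <- xc$cor[xc$lag > 0] + 0.1
  expect_equal(asymmetry_index(xc), 0.1)
  expect_error(asymmetry_index(data.frame(lag = -2:5, cor = rnorm(8))),
               "symmetric")
})

test_that("z-scoring standardizes neurons and drops constant ones", {
  sess <- make_toy_session()
  sess$activity[, 2] <- 7
  expect_warning(zs <- zscore_neurons(sess), "zero-variance")
  expect_equal(ncol(zs$activity), ncol(sess$activity) - 1)
  expect_equal(unname(colMeans(zs$activity)), rep(0, ncol(zs$activity)))
  expect_equal(unname(apply(zs$activity, 2, sd)), rep(1, ncol(zs$activity)))
  # idempotent once standardized
  expect_equal(zscore_neurons(zs)$activity, zs$activity)
})

test_that("onset parity rounds timestamps to the nearest second", {
  # onsets at 3.4 s and 2.6 s both round to 3 -> odd half
  sess <- make_toy_session(onsets = c(3.4 * 30 + 1, 2.6 * 30 + 1))
  expect_equal(split_half_by_onset_parity(sess), c(1L, 1L))
  sess2 <- make_toy_session(onsets = c(2.2 * 30 + 1, 5.1 * 30 + 1))
  expect_equal(split_half_by_onset_parity(sess2), c(0L, 1L))
  # halves partition all instances
  sess3 <- generate_neural_session(seed = 31)
  half <- split_half_by_onset_parity(sess3)
  expect_equal(length(half), nrow(sess3$instances))
  expect_true(all(half %in% 0:1))
})

test_that("one-hot mode regression equals group means and lm.fit", {
  sess <- generate_neural_session(n_syllables = 4, n_neurons = 6,
                                  n_events = 120, seed = 41)
  zs <- zscore_neurons(sess)
  inv <- syllable_inventory(zs)
  modes <- syllable_mode_regression(zs, inventory = inv)
  # independent route: explicit least squares on the one-hot design
  ac <- striatumrl:::activity_changes(zs, NULL, "pre_onset")
  sel <- ac$syllable %in% inv
  X <- sapply(inv, function(s) as.numeric(ac$syllable[sel] == s))
  fit <- lm.fit(X, ac$changes[sel, , drop = FALSE])
  expect_equal(unclass(modes), unname(fit$coefficients),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("planted modes are recovered at low noise", {
  # plant only the within-syllable drive so the raw mean during each
  # instance is the mode itself
  sess <- generate_neural_session(noise_sd = 0.05, amp_pre = 0, seed = 42)
  gt <- attr(sess, "ground_truth")
  modes <- syllable_mode_regression(sess, baseline = "none")
  pw <- attr(modes, "pathway")
  cosines <- vapply(seq_len(nrow(modes)), function(s) {
    m <- modes[s, pw == "dSPN"]
    g <- gt$modes_d[as.integer(rownames(modes))[s], ]
    sum(m * g) / sqrt(sum(m^2) * sum(g^2))
  }, numeric(1))
  expect_true(all(cosines > 0.95))
})

test_that("regression errors name syllables with no instances", {
  sess <- generate_neural_session(seed = 43)
  expect_error(
    syllable_mode_regression(sess, inventory = c(1, 99)),
    "99")
})

test_that("time warping preserves endpoints and handles degenerate
           instances", {
  n <- 60
  act <- matrix(seq_len(n), n, 2)
  mk <- function(onset, end) neural_session(
    act, c("dSPN", "iSPN"), syllable = {
      s <- rep(NA_integer_, n); s[onset:end] <- 1L; s },
    instances = data.frame(onset = onset, end = end, syllable = 1L))
  # a 10-frame instance maps onto itself
  w <- time_warp_syllables(mk(11, 20))
  i <- w$instances
  expect_equal(w$activity[i$onset:i$end, 1], 11:20)
  # a 20-frame instance: linear interpolation oracle via approx()
  w2 <- time_warp_syllables(mk(11, 30))
  i2 <- w2$instances
  oracle <- approx(1:20, 11:30, xout = seq(1, 20, length.out = 10))$y
  expect_equal(w2$activity[i2$onset:i2$end, 1], oracle)
  # a single-frame instance becomes a constant 10-step trace
  w3 <- time_warp_syllables(mk(11, 11))
  i3 <- w3$instances
  expect_equal(w3$activity[i3$onset:i3$end, 1], rep(11, 10))
})

test_that("onset-aligned projections are invariant to per-neuron rescaling", {
  sess <- generate_neural_session(seed = 44)
  oap1 <- onset_aligned_projection(sess)
  sess2 <- sess
  scales <- runif(ncol(sess$activity), 0.2, 5)
  sess2$activity <- sweep(sess2$activity, 2, scales, `*`)
  oap2 <- onset_aligned_projection(sess2)
  expect_equal(oap1$associated, oap2$associated, tolerance = 1e-8)
  expect_equal(oap1$other, oap2$other, tolerance = 1e-8)
})

test_that("split-half mode correlations beat the shuffled null only with
           structure", {
  sess <- generate_neural_session(seed = 45)
  shc <- split_half_mode_correlation(zscore_neurons(sess), n_shuffle = 60)
  expect_true(all(shc$real > 0.2))
  expect_true(all(shc$p_value < 0.05))
  nul <- generate_neural_session(seed = 46, null = TRUE)
  shn <- split_half_mode_correlation(zscore_neurons(nul), n_shuffle = 60)
  expect_true(all(abs(shn$real) < 0.25))
})

test_that("selectivity index matches its closed forms", {
  expect_equal(selectivity_index(rep(2, 10)), 1)
  expect_equal(selectivity_index(c(1, rep(0, 9))), 1 / 10)
  expect_equal(selectivity_index(c(1, 1, 0, 0)), 0.5)
  expect_equal(selectivity_index(rep(0, 4)), 0)
  expect_error(selectivity_index(c(1, -1)), "nonnegative")
})
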