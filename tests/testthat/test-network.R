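test_that("feedforward activity is rectified linear in the weights", {
  net <- striatal_network(3, 3)
  act <- feedforward_activity(net, c(1, 0, 0))
  expect_equal(act$y_d, rep(1, 3))
  expect_equal(act$y_i, rep(1, 3))
  expect_equal(act$logits, rep(0, 3))
  net2 <- striatal_network(1, 1)
  net2$W_d[] <- -2
  expect_equal(feedforward_activity(net2, 1)$y_d, 0)
  net3 <- striatal_network(1, 2)
  net3$W_d[] <- c(2, 1)
  expect_equal(feedforward_activity(net3, c(1, 1))$y_d, 3)
  expect_error(feedforward_activity(net, c(1, 0)), "n_inputs")
})

test_that("action probabilities follow the softmax with a no-action mass", {
  expect_equal(action_probabilities(c(0, 0), beta = 10, c_nogo = 0),
               c(0.5, 0.5))
  # single go action with unit no-go weight: even odds
  expect_equal(action_probabilities(0, beta = 10, c_nogo = 1), 0.5)
  p <- action_probabilities(c(0.1, 0), beta = 10, c_nogo = 0)
  expect_equal(p[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  # max-subtraction guards overflow without changing the distribution
  p_big <- action_probabilities(c(1e4, 0), beta = 10, c_nogo = 0)
  expect_true(all(is.finite(p_big)))
  expect_equal(p_big[1], 1)
  # log-domain no-action weight is the same distribution
  expect_equal(action_probabilities(c(0.2, -0.1), 10, c_nogo = 3),
               action_probabilities(c(0.2, -0.1), 10, log_c_nogo = log(3)))
})

test_that("softmax is shift invariant exactly when there is no no-go mass", {
  l <- c(0.3, -0.2, 0.1)
  p0 <- action_probabilities(l, 10, c_nogo = 0)
  expect_equal(action_probabilities(l + 5, 10, c_nogo = 0), p0,
               tolerance = 1e-12)
  p1 <- action_probabilities(l, 10, c_nogo = 1)
  expect_false(isTRUE(all.equal(action_probabilities(l + 5, 10, c_nogo = 1),
                                p1)))
})

test_that("action sampling matches its probabilities", {
  expect_identical(select_action(c(1, 0)), 1L)
  expect_error(select_action(c(-0.1, 0.5)), "negative")
  set.seed(7)
  a1 <- replicate(20, select_action(c(0.3, 0.3)))
  set.seed(7)
  a2 <- replicate(20, select_action(c(0.3, 0.3)))
  expect_identical(a1, a2)
  # empirical frequencies within 3 sigma binomial, including the no-action
  # residual
  set.seed(8)
  p <- c(0.5, 0.3)
  draws <- replicate(1e5, select_action(p))
  for (k in 1:2) {
    freq <- sum(!is.na(draws) & draws == k) / 1e5
    expect_lt(abs(freq - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / 1e5))
  }
  expect_lt(abs(mean(is.na(draws)) - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
})

test_that("efferent excitation targets the chosen pair and nothing else", {
  net <- striatal_network(3, 3, c_efference = 1.5)
  x <- c(1, 0, 0)
  act <- apply_efference(net, x, 1)
  expect_equal(act$y_d, c(2.5, 1, 1))
  expect_equal(act$y_i, c(2.5, 1, 1))
  net0 <- striatal_network(3, 3, c_efference = 0)
  expect_equal(apply_efference(net0, x, 2), feedforward_activity(net0, x))
  expect_error(apply_efference(net, x, NA_integer_))
})

test_that("efference leaves action selection bit-identical when the chosen
           pre-activations are positive", {
  # dyadic-rational weights and inputs: the additions are exact, so the
  # chosen logit (h_d + c) - (h_i + c) equals h_d - h_i bit for bit
  set.seed(11)
  for (rep in 1:25) {
    A <- sample(2:5, 1)
    net <- striatal_network(A, 1, c_efference = 1.5)
    net$W_d[] <- rdyadic(A)
    net$W_i[] <- rdyadic(A)
    ff <- feedforward_activity(net, 1)
    post <- apply_efference(net, 1, sample.int(A, 1))
    expect_identical(action_probabilities(post, 10, 0),
                     action_probabilities(ff, 10, 0))
  }
})

test_that("canonical post-selection activates the chosen dSPN and the other
           iSPNs", {
  a <- canonical_postselection(2, 1)
  expect_equal(a$y_d, c(1, 0))
  expect_equal(a$y_i, c(0, 1))
  a_none <- canonical_postselection(1, NA_integer_)
  expect_equal(a_none$y_d, 0)
  expect_equal(a_none$y_i, 1)
  expect_equal(canonical_postselection(3, 3)$y_i, c(1, 1, 0))
})

test_that("shared-control probabilities combine striatal and tutor logits", {
  net <- striatal_network(3, 3)
  net$W_d[] <- runif(9)
  act <- feedforward_activity(net, c(1, 0, 0))
  expect_equal(shared_control_probabilities(act, rep(0, 3), 1, 10, 0),
               action_probabilities(act, 10, 0))
  p <- shared_control_probabilities(act, c(0, 100, 0), 0, 10, 0)
  expect_gt(p[2], 1 - 1e-10)
  # halving the striatal weight halves the striatal logit contribution
  half <- shared_control_probabilities(act, rep(0, 3), 0.5, 10, 0)
  expect_equal(half, action_probabilities(0.5 * act$logits, 10, 0))
})

test_that("one linear-rule step moves each logit by alpha*delta*(y_d+y_i)*(x.x)", {
  set.seed(21)
  for (rep in 1:10) {
    A <- 3; M <- 4
    net <- striatal_network(A, M)
    net$W_d[] <- 1 + runif(A * M)
    net$W_i[] <- 1 + runif(A * M)
    x <- runif(M, 0.1, 1)
    delta <- runif(1, -1, 1)
    rule <- plasticity_rule("linear", alpha = 0.05)
    act <- feedforward_activity(net, x)
    net$W_d <- net$W_d + weight_update(rule, "direct", delta, act$y_d, x)
    net$W_i <- net$W_i + weight_update(rule, "indirect", delta, act$y_i, x)
    new_logits <- feedforward_activity(net, x)$logits
    predicted <- act$logits +
      rule$alpha * delta * (act$y_d + act$y_i) * sum(x * x)
    expect_equal(new_logits, predicted, tolerance = 1e-12)
  }
})
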