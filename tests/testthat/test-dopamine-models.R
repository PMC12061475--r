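test_that("transition tables match direct enumeration", {
  tab <- compute_transition_tables(c(1, 2, 1, 2), c(0, 0.5, -0.5, 0.5))
  expect_equal(tab$P[1, 2], 1)
  expect_equal(tab$P[2, 1], 1)
  # constant dopamine fills every observed cell with that constant
  tabc <- compute_transition_tables(c(1, 2, 2, 1), rep(0.7, 4), 2)
  expect_true(all(tabc$D[tabc$mask] == 0.7))
  # hand-computable 5-element sequence
  tab5 <- compute_transition_tables(c(1, 2, 1, 3, 1),
                                    c(0.5, 0.2, 0.4, 0.1, 0.3), 3)
  expect_equal(tab5$D[1, 2], 0.2)
  expect_equal(tab5$D[2, 1], 0.4)
  expect_equal(tab5$D[1, 3], 0.1)
  expect_equal(tab5$D[3, 1], 0.3)
  expect_equal(tab5$P[1, ], c(0, 0.5, 0.5))
  expect_equal(tab5$counts[1, ], c(0, 1, 1))
  expect_true(is.na(tab5$D[2, 3]))
})

make_tables_from_D <- function(D, counts = NULL) {
  S <- nrow(D)
  if (is.null(counts)) counts <- matrix(1, S, S)
  mask <- counts > 0
  P <- counts / rowSums(counts)
  structure(list(D = D, P = P, counts = counts, mask = mask, S = S),
            class = "transition_tables")
}

test_that("the Q-table fit reproduces noiseless Q-generated dopamine", {
  set.seed(50)
  Q <- matrix(rnorm(16), 4, 4)
  D <- outer(rep(1, 4), apply(Q, 1, max)) - Q  # pred[i,j] = maxQ(j,.) - Q[i,j]
  fit <- fit_q_table(make_tables_from_D(D))
  pred <- outer(rep(1, 4), apply(fit$Q, 1, max)) - fit$Q
  # gradient descent on the piecewise-quadratic objective converges to a
  # stationary point; require an essentially complete fit (R^2 > 0.999)
  expect_lt(mean((pred - D)^2), 1e-3 * var(as.vector(D)))
  expect_equal(unname(rowSums(fit$P_hat)), rep(1, 4))
  expect_true(all(fit$beta > 0))
})

test_that("a zero dopamine table leaves the Q fit at its zero start", {
  tab <- make_tables_from_D(matrix(0, 3, 3))
  fit <- suppressWarnings(fit_q_table(tab))
  expect_equal(fit$Q, matrix(0, 3, 3))
  expect_equal(fit$P_hat, matrix(1 / 3, 3, 3))
})

test_that("the Q fit beats the zero table on a toy problem", {
  tab <- make_tables_from_D(matrix(c(0.5, -0.2, 0.1, 0.4), 2, 2))
  fit <- fit_q_table(tab)
  loss0 <- mean(tab$D^2)
  expect_lte(fit$loss, loss0)
})

test_that("the state-value TD fit recovers value differences exactly", {
  v <- c(0, 0.8, -0.4, 1.2)
  D <- outer(rep(1, 4), v) - outer(v, rep(1, 4))  # D[i,j] = v_j - v_i
  fit <- fit_v_model(make_tables_from_D(D))
  expect_equal(fit$V - fit$V[1], v - v[1], tolerance = 1e-10)
  # all predicted rows identical (independent of the previous syllable)
  expect_equal(fit$P_hat[1, ], fit$P_hat[4, ])
  fit0 <- suppressWarnings(fit_v_model(make_tables_from_D(matrix(0, 3, 3))))
  expect_equal(fit0$V, rep(0, 3))
  expect_equal(fit0$P_hat, matrix(1 / 3, 3, 3))
})

test_that("the two normalization models match hand arithmetic", {
  D <- matrix(c(1, 2, 2, 3, 2, 2, 4, 4, 4), 3, 3, byrow = TRUE)
  av <- predict_p_action_value(make_tables_from_D(D))
  expect_equal(av$P_hat[1, ], c(1, 2, 2) / 5)
  expect_equal(av$P_hat[3, ], rep(1 / 3, 3))  # row-constant -> uniform
  expect_equal(predict_p_action_value(
    make_tables_from_D(matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE)))$P_hat[1, ],
    c(0.25, 0.75))
  sv <- predict_p_state_value(make_tables_from_D(D))
  expect_equal(sv$P_hat[1, ], sv$P_hat[3, ])
  expect_equal(sv$P_hat[1, ], colMeans(D) / sum(colMeans(D)))
  expect_warning(predict_p_action_value(
    make_tables_from_D(matrix(c(-1, 2, 3, 1), 2, 2, byrow = TRUE))),
    "negative")
})

test_that("model comparison scores perfect and degenerate predictions", {
  set.seed(51)
  sess <- generate_dlight_session(n_syllables = 5, n_transitions = 2000,
                                  seed = 52)
  tab <- compute_transition_tables(sess$syllables, sess$dopamine)
  perfect <- striatumrl:::new_model_fit("perfect", tab, tab$P)
  expect_equal(unname(compare_models(tab, list(perfect))), 1)
  uniform <- striatumrl:::new_model_fit("uniform", tab,
                                        matrix(1 / 5, 5, 5))
  expect_warning(r <- compare_models(tab, list(uniform)), "degenerate")
  expect_equal(unname(r), 0)
})

test_that("Q-generated sessions are won by the Q-learning model", {
  wins <- vapply(1:5, function(k) {
    sess <- generate_dlight_session(n_syllables = 10, n_transitions = 4000,
                                    seed = 60 + k)
    tab <- compute_transition_tables(sess$syllables, sess$dopamine)
    r <- suppressWarnings(compare_models(tab))
    names(which.max(r)) == "q_learning"
  }, logical(1))
  expect_true(all(wins))
})
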