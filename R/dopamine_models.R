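#' Syllable-transition dopamine and probability tables
#'
#' From a sequence of behavioral syllables and the per-syllable dopamine
#' values (e.g. per-syllable dLight maxima, z-scored per session), computes
#' the S x S table `D` of average dopamine during syllable \eqn{s_t}
#' conditioned on the previous syllable \eqn{s_{t-1}}, and the S x S table
#' `P` of empirical transition probabilities. `D` is defined only on
#' observed transitions; the observation mask is carried explicitly.
#'
#' @param syllables integer sequence of syllable ids (per syllable event).
#' @param dopamine numeric vector, same length, dopamine during each event.
#' @param n_syllables number of syllables S; default `max(syllables)`.
#' @return object of class `transition_tables` with `D`, `P`, `counts`,
#'   `mask` (counts > 0) and `S`.
#' @export
compute_transition_tables <- function(syllables, dopamine,
                                      n_syllables = max(syllables)) {
  stopifnot(length(syllables) >= 2,
            length(dopamine) == length(syllables),
            all(syllables >= 1), all(syllables <= n_syllables))
  S <- n_syllables
  n <- length(syllables)
  from <- syllables[-n]
  to <- syllables[-1]
  da <- dopamine[-1]  # dopamine during the *current* syllable of a transition
  counts <- matrix(0, S, S)
  dsum <- matrix(0, S, S)
  for (t in seq_along(from)) {
    counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
    dsum[from[t], to[t]] <- dsum[from[t], to[t]] + da[t]
  }
  mask <- counts > 0
  D <- matrix(NA_real_, S, S)
  D[mask] <- dsum[mask] / counts[mask]
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  structure(list(D = D, P = P, counts = counts, mask = mask, S = S),
            class = "transition_tables")
}

#' @export
print.transition_tables <- function(x, ...) {
  cat("<transition_tables> S =", x$S, ";", sum(x$counts), "transitions,",
      sum(x$mask), "observed cells\n")
  invisible(x)
}

# row-wise softmax with per-row inverse temperature beta; beta = 1/row sd,
# falling back to 1 (with a warning) for zero-variance rows
row_softmax_fit <- function(Q) {
  S <- nrow(Q)
  beta <- numeric(S)
  P_hat <- matrix(0, S, ncol(Q))
  warned <- FALSE
  for (i in seq_len(S)) {
    s <- stats::sd(Q[i, ])
    if (!is.finite(s) || s == 0) { beta[i] <- 1; warned <- TRUE }
    else beta[i] <- 1 / s
    z <- beta[i] * Q[i, ]
    z <- z - max(z)
    P_hat[i, ] <- exp(z) / sum(exp(z))
  }
  if (warned) warning("zero row-s.d.; inverse temperature fell back to 1")
  list(beta = beta, P_hat = P_hat)
}

new_model_fit <- function(model, tables, P_hat, beta = NULL, Q = NULL,
                          V = NULL, loss = NULL, iterations = NULL) {
  structure(list(model = model, P_hat = P_hat, beta = beta, Q = Q, V = V,
                 loss = loss, iterations = iterations, S = tables$S),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", x$model,
      if (!is.null(x$loss)) paste(" loss =", signif(x$loss, 4)), "\n")
  invisible(x)
}

#' Fit the Q-learning model of dopamine transients
#'
#' Models the dopamine during a syllable transition as an action prediction
#' error over a table of transition values:
#' \eqn{\hat D(s_{t-1}, s_t) = \max_{s'} Q(s_t, s') - Q(s_{t-1}, s_t)}.
#' The Q table is initialized at zero and fit by gradient descent on the
#' mean squared error over observed transitions. Transition probabilities
#' are then predicted as a per-row softmax
#' \eqn{\hat P(s_{t-1}, \cdot) \propto e^{\beta(s_{t-1}) Q(s_{t-1}, \cdot)}}
#' with \eqn{\beta(s_{t-1})} the reciprocal of the row standard deviation of
#' Q. Note the D -> Q map has a per-row additive gauge freedom; the fitted Q
#' is the particular solution gradient descent reaches from zero, and the
#' softmax predictions are invariant to that gauge.
#'
#' @param tables a [compute_transition_tables()] result.
#' @param lr gradient-descent learning rate (0.1).
#' @param momentum Polyak momentum coefficient (0.9); the max-coupled
#'   objective is piecewise quadratic and plain gradient steps stall in
#'   shallow basins that momentum escapes.
#' @param max_iter maximum iterations (1e4).
#' @param tol stop when the gradient norm falls below this (1e-8).
#' @return a `model_fit` with the fitted `Q`, per-row `beta`, `P_hat`, the
#'   final `loss` and iteration count.
#' @export
fit_q_table <- function(tables, lr = 0.1, momentum = 0.9, max_iter = 1e4,
                        tol = 1e-8) {
  D <- tables$D; mask <- tables$mask
  S <- tables$S
  N <- sum(mask)
  Q <- matrix(0, S, S)
  vel <- matrix(0, S, S)
  it <- 0L
  repeat {
    it <- it + 1L
    amax <- max.col(Q, ties.method = "first")
    m <- Q[cbind(seq_len(S), amax)]
    pred <- matrix(m, S, S, byrow = TRUE) - Q
    err <- matrix(0, S, S)
    err[mask] <- pred[mask] - D[mask]
    grad <- -err
    # max-term: pred[k, j] contains Q[j, amax[j]], so cell (j, amax[j])
    # accumulates the total error of column j
    col_err <- colSums(err)
    grad[cbind(seq_len(S), amax)] <- grad[cbind(seq_len(S), amax)] + col_err
    grad <- (2 / N) * grad
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol || it >= max_iter) break
    vel <- momentum * vel - lr * grad
    Q <- Q + vel
  }
  sf <- row_softmax_fit(Q)
  loss <- mean((pred[mask] - D[mask])^2)
  new_model_fit("q_learning", tables, sf$P_hat, beta = sf$beta, Q = Q,
                loss = loss, iterations = it)
}

#' Fit the state-value TD model of dopamine transients
#'
#' Models dopamine as a state-value difference
#' \eqn{\hat D(s_{t-1}, s_t) = V(s_t) - V(s_{t-1})}, fit by least squares
#' over observed transitions (the additive gauge is fixed by V[1] = 0).
#' Predicted transition probabilities are independent of the previous
#' syllable: every row is \eqn{\propto e^{\beta V(s_t)}} with \eqn{\beta}
#' the reciprocal of the standard deviation of V.
#'
#' @param tables a [compute_transition_tables()] result.
#' @return a `model_fit` with fitted `V`, scalar `beta`, `P_hat`, `loss`.
#' @export
fit_v_model <- function(tables) {
  D <- tables$D; mask <- tables$mask; S <- tables$S
  obs <- which(mask, arr.ind = TRUE)
  # design over V[2..S]: D_ij ~ V_j - V_i with V_1 = 0
  X <- matrix(0, nrow(obs), S - 1)
  for (r in seq_len(nrow(obs))) {
    i <- obs[r, 1]; j <- obs[r, 2]
    if (j > 1) X[r, j - 1] <- X[r, j - 1] + 1
    if (i > 1) X[r, i - 1] <- X[r, i - 1] - 1
  }
  y <- D[mask]
  fit <- stats::lm.fit(X, y)
  V <- unname(c(0, fit$coefficients))
  V[is.na(V)] <- 0
  s <- stats::sd(V)
  beta <- if (!is.finite(s) || s == 0) {
    warning("zero s.d. of V; inverse temperature fell back to 1"); 1
  } else 1 / s
  z <- beta * V; z <- z - max(z)
  row <- exp(z) / sum(exp(z))
  P_hat <- matrix(row, S, S, byrow = TRUE)
  pred <- outer(rep(1, S), V) - outer(V, rep(1, S))
  loss <- mean((pred[mask] - y)^2)
  new_model_fit("v_td", tables, P_hat, beta = beta, V = V, loss = loss)
}

#' Action-value model: transition probabilities as normalized dopamine rows
#'
#' Assumes dopamine directly reflects transition probability:
#' \eqn{\hat P(s_{t-1}, s_t) = D(s_{t-1}, s_t) / \sum_s D(s_{t-1}, s)},
#' computed exactly as written. Negative dopamine entries (possible after
#' z-scoring) are normalized as-is with a warning; zero row sums fall back
#' to a uniform row with a warning. Unobserved cells contribute 0.
#'
#' @param tables a [compute_transition_tables()] result.
#' @return a `model_fit`.
#' @export
predict_p_action_value <- function(tables) {
  D0 <- tables$D; D0[!tables$mask] <- 0
  if (any(D0 < 0))
    warning("negative dopamine entries; row normalization applied as written")
  rs <- rowSums(D0)
  P_hat <- matrix(0, tables$S, tables$S)
  for (i in seq_len(tables$S)) {
    if (rs[i] == 0) {
      warning("zero row sum; uniform fallback for row ", i)
      P_hat[i, ] <- 1 / tables$S
    } else P_hat[i, ] <- D0[i, ] / rs[i]
  }
  new_model_fit("action_value", tables, P_hat)
}

#' State-value model: transition probabilities from marginal dopamine
#'
#' Assumes dopamine reflects the marginal probability of the current
#' syllable, independent of the previous one:
#' \eqn{\hat P(s_{t-1}, s_t) = \bar D(s_t) / \sum_s \bar D(s)}, where
#' \eqn{\bar D(s)} is the count-weighted average dopamine during syllable s.
#' Negative entries are handled as in [predict_p_action_value()].
#'
#' @param tables a [compute_transition_tables()] result.
#' @return a `model_fit` (all rows identical).
#' @export
predict_p_state_value <- function(tables) {
  w <- tables$counts
  dsum <- ifelse(tables$mask, tables$D * w, 0)
  Dbar <- colSums(dsum) / pmax(colSums(w), 1)
  if (any(Dbar < 0))
    warning("negative dopamine entries; normalization applied as written")
  tot <- sum(Dbar)
  row <- if (tot == 0) {
    warning("zero total dopamine; uniform fallback")
    rep(1 / tables$S, tables$S)
  } else Dbar / tot
  P_hat <- matrix(row, tables$S, tables$S, byrow = TRUE)
  new_model_fit("state_value", tables, P_hat)
}

#' Compare dopamine models by correlation with observed transitions
#'
#' Pearson correlation between predicted and observed transition
#' probabilities over the observed cells, per model. A prediction with zero
#' variance across observed cells yields r = 0 with a warning.
#'
#' @param tables a [compute_transition_tables()] result.
#' @param fits list of `model_fit` objects (default: all four models fit to
#'   `tables`).
#' @return named numeric vector of Pearson r per model.
#' @export
compare_models <- function(tables, fits = NULL) {
  if (is.null(fits))
    fits <- list(fit_q_table(tables), fit_v_model(tables),
                 predict_p_action_value(tables), predict_p_state_value(tables))
  mask <- tables$mask
  p_obs <- tables$P[mask]
  out <- vapply(fits, function(f) {
    p_hat <- f$P_hat[mask]
    if (stats::sd(p_hat) == 0 || stats::sd(p_obs) == 0) {
      warning("degenerate prediction (zero variance); r set to 0 for ",
              f$model)
      return(0)
    }
    stats::cor(p_hat, p_obs)
  }, numeric(1))
  names(out) <- vapply(fits, `[[`, character(1), "model")
  out
}
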