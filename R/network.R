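#' Tabular striatal network
#'
#' A network of one dSPN and one iSPN per action, each receiving weighted
#' input from M cortical units. Feedforward activity is
#' \eqn{y^{dSPN} = \phi(W_d x)}, \eqn{y^{iSPN} = \phi(W_i x)} with
#' \eqn{\phi(h) = \max(h, 0)}. The striatal logit of action a is
#' \eqn{\ell_a = y^{dSPN}_a - y^{iSPN}_a}: dSPN activity promotes the action,
#' iSPN activity suppresses it.
#'
#' @param n_actions number of actions A.
#' @param n_inputs number of cortical input units M.
#' @param beta softmax inverse temperature (10 for task simulations, 100 for
#'   spontaneous-behavior simulations).
#' @param c_nogo no-action weight in the softmax denominator (1 for go/no-go
#'   tasks, 0 for multi-action tasks).
#' @param c_efference amplitude of the efferent excitation delivered to the
#'   selected action's dSPN and iSPN after action selection.
#' @param init_weight initial value of every corticostriatal weight (1 for
#'   task simulations).
#' @return object of class `striatal_network` with weight matrices `W_d`,
#'   `W_i` (A x M) and the policy parameters.
#' @export
striatal_network <- function(n_actions, n_inputs, beta = 10, c_nogo = 0,
                             c_efference = 0.5, init_weight = 1) {
  stopifnot(n_actions >= 1, n_inputs >= 1, c_nogo >= 0, c_efference >= 0)
  W <- matrix(init_weight, n_actions, n_inputs)
  structure(list(W_d = W, W_i = W, beta = beta, c_nogo = c_nogo,
                 c_efference = c_efference,
                 n_actions = n_actions, n_inputs = n_inputs),
            class = "striatal_network")
}

#' @export
print.striatal_network <- function(x, ...) {
  cat("<striatal_network> A =", x$n_actions, " M =", x$n_inputs,
      " beta =", x$beta, " c_nogo =", x$c_nogo,
      " c_efference =", x$c_efference, "\n")
  invisible(x)
}

relu <- function(h) pmax(h, 0)

new_spn_activity <- function(y_d, y_i) {
  stopifnot(length(y_d) == length(y_i))
  structure(list(y_d = y_d, y_i = y_i, logits = y_d - y_i),
            class = "spn_activity")
}

#' Feedforward SPN activity
#'
#' @param net a [striatal_network()].
#' @param x cortical input vector (length M).
#' @return object of class `spn_activity` with fields `y_d`, `y_i`
#'   (nonnegative, post-rectification) and `logits` (`y_d - y_i`).
#' @export
feedforward_activity <- function(net, x) {
  if (length(x) != net$n_inputs)
    stop("input length ", length(x), " != n_inputs ", net$n_inputs)
  new_spn_activity(relu(drop(net$W_d %*% x)), relu(drop(net$W_i %*% x)))
}

# softmax with an optional no-action logit, computed with max-subtraction so
# that overflow is impossible while probabilities are mathematically unchanged
softmax_nogo <- function(logits, beta, c_nogo = 0, log_c_nogo = NULL) {
  z <- beta * logits
  lc <- if (!is.null(log_c_nogo)) log_c_nogo
        else if (c_nogo > 0) log(c_nogo) else -Inf
  m <- max(z, if (is.finite(lc)) lc else -Inf)
  denom <- sum(exp(z - m)) + if (is.finite(lc)) exp(lc - m) else 0
  exp(z - m) / denom
}

#' Action selection probabilities
#'
#' Computes \eqn{p(a) = e^{\beta \ell_a} / (c_{nogo} + \sum_{a'} e^{\beta
#' \ell_{a'}})}. The residual mass \eqn{1 - \sum_a p(a)} is the probability
#' of taking no action. For numerical stability the computation subtracts the
#' maximum exponent; this leaves the probabilities mathematically identical.
#'
#' @param activity an `spn_activity` (or a numeric logit vector).
#' @param beta inverse temperature.
#' @param c_nogo nonnegative no-action weight.
#' @param log_c_nogo optional log-domain no-action weight, overriding
#'   `c_nogo`; used in high-beta regimes where `c_nogo` itself would overflow.
#' @return numeric vector of length A of action probabilities; the no-action
#'   probability is `1 - sum(...)`.
#' @export
action_probabilities <- function(activity, beta, c_nogo = 0,
                                 log_c_nogo = NULL) {
  l <- if (inherits(activity, "spn_activity")) activity$logits else activity
  stopifnot(is.numeric(l), c_nogo >= 0)
  softmax_nogo(l, beta, c_nogo, log_c_nogo)
}

#' Sample an action
#'
#' Categorical sample from an action-probability vector; residual mass is the
#' no-action outcome, returned as `NA_integer_`. Uses the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param probs probability vector over actions (may sum to < 1; the residual
#'   is the no-action probability).
#' @return integer action id, or `NA_integer_` for no action.
#' @export
select_action <- function(probs) {
  if (any(probs < 0)) stop("negative probabilities")
  total <- sum(probs)
  if (total > 1 + 1e-8) stop("probabilities sum to more than 1")
  p_none <- max(0, 1 - total)
  k <- sample.int(length(probs) + 1L, 1L, prob = c(probs, p_none))
  if (k > length(probs)) NA_integer_ else k
}

#' Post-selection activity under the efference model
#'
#' After action \eqn{a^*} is selected, efferent input of amplitude
#' `c_efference` excites both the dSPN and the iSPN of the selected action:
#' \eqn{y_a = \phi(c_{eff}\,1[a=a^*] + W x)_a}. Because the same amount is
#' added to both pathways, the logit of the selected action is unchanged
#' whenever both of its pre-activations are positive: efference excites the
#' sum mode, which is orthogonal to the difference mode that drives selection.
#'
#' @param net a [striatal_network()].
#' @param x cortical input vector.
#' @param chosen selected action id (must not be `NA`).
#' @return an `spn_activity`.
#' @export
apply_efference <- function(net, x, chosen) {
  if (is.na(chosen)) stop("`chosen` must be a real action, not NA")
  stopifnot(chosen >= 1, chosen <= net$n_actions)
  e <- numeric(net$n_actions)
  e[chosen] <- net$c_efference
  new_spn_activity(relu(e + drop(net$W_d %*% x)),
                   relu(e + drop(net$W_i %*% x)))
}

#' Post-selection activity under the canonical action selection model
#'
#' In the canonical model the dSPN of the selected action and the iSPNs of
#' every unselected action are set to 1; everything else is 0. When no action
#' is selected, every action counts as unselected, so all iSPNs are active.
#'
#' @param n_actions number of actions A.
#' @param chosen selected action id or `NA_integer_` for no action.
#' @return an `spn_activity`.
#' @export
canonical_postselection <- function(n_actions, chosen) {
  stopifnot(n_actions >= 1)
  y_d <- numeric(n_actions)
  y_i <- rep(1, n_actions)
  if (!is.na(chosen)) {
    stopifnot(chosen >= 1, chosen <= n_actions)
    y_d[chosen] <- 1
    y_i[chosen] <- 0
  }
  new_spn_activity(y_d, y_i)
}

#' Action probabilities under shared control with a tutor pathway
#'
#' Models action selection jointly driven by the striatum and another motor
#' pathway: the combined logit is `striatal_weight * logits + tutor_bias`,
#' passed through the same softmax form as [action_probabilities()].
#'
#' @param activity an `spn_activity` (or logit vector).
#' @param tutor_bias additive logit bias vector (length A), e.g. one-hot on
#'   the correct action.
#' @param striatal_weight scalar strength of striatal control relative to the
#'   tutor pathway.
#' @param beta inverse temperature.
#' @param c_nogo no-action weight.
#' @return probability vector over actions.
#' @export
shared_control_probabilities <- function(activity, tutor_bias, striatal_weight,
                                         beta, c_nogo = 0) {
  l <- if (inherits(activity, "spn_activity")) activity$logits else activity
  if (length(tutor_bias) != length(l))
    stop("tutor_bias length must equal the number of actions")
  softmax_nogo(striatal_weight * l + tutor_bias, beta, c_nogo)
}
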