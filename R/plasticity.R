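#' Dopamine-dependent plasticity rule
#'
#' Constructs the specification of the three-factor corticostriatal plasticity
#' rule. Weight changes take the form
#' \deqn{\Delta w = \alpha\, f_{pathway}(\delta)\, y\, x,}
#' where \eqn{\delta} is the dopamine signal (reward prediction error relative
#' to baseline), \eqn{y} the postsynaptic SPN activity and \eqn{x} the
#' presynaptic cortical activity. The dopamine-dependence \eqn{f} differs
#' between pathways: for dSPNs it is increasing in \eqn{\delta}, for iSPNs
#' decreasing (except for the `same_sign_indirect` control rule, in which
#' iSPNs share the dSPN dependence).
#'
#' Available kinds:
#' \describe{
#'   \item{`linear`}{\eqn{f_{dSPN}(\delta)=\delta}, \eqn{f_{iSPN}(\delta)=-\delta}.}
#'   \item{`rectified`}{\eqn{f_{dSPN}(\delta)=\max(\delta,0)},
#'     \eqn{f_{iSPN}(\delta)=\max(-\delta,0)}.}
#'   \item{`offset_sigmoid`}{\eqn{f_{dSPN}(\delta)=\tfrac12(a + b/(1+c e^{1-d\delta}))}
#'     and the mirrored form \eqn{e^{1+d\delta}} for iSPNs, with defaults
#'     a = -3.5, b = 11.5, c = 0.9, d = 1.}
#'   \item{`same_sign_indirect`}{control rule in which
#'     \eqn{f_{iSPN} \equiv f_{dSPN} = \delta}.}
#' }
#'
#' @param kind character; one of `"linear"`, `"rectified"`,
#'   `"offset_sigmoid"`, `"same_sign_indirect"`.
#' @param alpha learning rate (dimensionless). Default 0.05; shared-control
#'   tutoring simulations use 0.01.
#' @param sigmoid_a,sigmoid_b,sigmoid_c,sigmoid_d offset-sigmoid parameters.
#' @return An object of class `plasticity_rule`.
#' @export
#' @examples
#' rule <- plasticity_rule("linear")
#' dopamine_factor(rule, "direct", 0.5)
plasticity_rule <- function(kind = c("linear", "rectified", "offset_sigmoid",
                                     "same_sign_indirect"),
                            alpha = 0.05,
                            sigmoid_a = -3.5, sigmoid_b = 11.5,
                            sigmoid_c = 0.9, sigmoid_d = 1.0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(kind = kind, alpha = alpha,
                 sigmoid_a = sigmoid_a, sigmoid_b = sigmoid_b,
                 sigmoid_c = sigmoid_c, sigmoid_d = sigmoid_d),
            class = "plasticity_rule")
}

#' @export
print.plasticity_rule <- function(x, ...) {
  cat("<plasticity_rule>", x$kind, " alpha =", x$alpha, "\n")
  if (x$kind == "offset_sigmoid")
    cat("  sigmoid a =", x$sigmoid_a, "b =", x$sigmoid_b,
        "c =", x$sigmoid_c, "d =", x$sigmoid_d, "\n")
  invisible(x)
}

#' Dopamine-dependence factor of the plasticity rule
#'
#' Evaluates \eqn{f_{pathway}(\delta)} for a plasticity rule. Vectorized over
#' `delta`.
#'
#' @param rule a [plasticity_rule()].
#' @param pathway `"direct"` (dSPN) or `"indirect"` (iSPN).
#' @param delta dopamine signal(s) relative to baseline.
#' @return numeric vector, same length as `delta`.
#' @export
dopamine_factor <- function(rule, pathway = c("direct", "indirect"), delta) {
  if (!inherits(rule, "plasticity_rule"))
    stop("`rule` must be a plasticity_rule object")
  pathway <- match.arg(pathway)
  stopifnot(is.numeric(delta))
  kind <- rule$kind
  if (kind == "same_sign_indirect") {
    # control rule: both pathways use the (linear) dSPN dependence
    return(delta + 0)
  }
  switch(kind,
    linear = if (pathway == "direct") delta else -delta,
    rectified = if (pathway == "direct") pmax(delta, 0) else pmax(-delta, 0),
    offset_sigmoid = {
      a <- rule$sigmoid_a; b <- rule$sigmoid_b
      cc <- rule$sigmoid_c; d <- rule$sigmoid_d
      s <- if (pathway == "direct") -1 else 1
      0.5 * (a + b / (1 + cc * exp(1 + s * d * delta)))
    },
    stop("unknown plasticity rule kind: ", kind)
  )
}

#' Three-factor weight update
#'
#' Computes the corticostriatal weight increment
#' \eqn{\Delta W_{aj} = \alpha f_{pathway}(\delta)\, y_a\, x_j}
#' (an exact outer product of postsynaptic activity and presynaptic input).
#'
#' @param rule a [plasticity_rule()].
#' @param pathway `"direct"` or `"indirect"`.
#' @param delta scalar dopamine signal, shared globally by all synapses.
#' @param y postsynaptic SPN activity vector (length A).
#' @param x presynaptic cortical input vector (length M).
#' @return A x M matrix of weight increments.
#' @export
weight_update <- function(rule, pathway = c("direct", "indirect"), delta, y, x) {
  pathway <- match.arg(pathway)
  stopifnot(length(delta) == 1L, is.finite(delta),
            is.numeric(y), is.numeric(x), all(is.finite(y)), all(is.finite(x)))
  f <- dopamine_factor(rule, pathway, delta)
  rule$alpha * f * outer(y, x)
}

#' State-value critic
#'
#' A tabular critic holding value estimates \eqn{V(s)} (initialized at 0) and
#' a learning rate. Used to produce the TD error that stands in for phasic
#' dopamine in the trial-based simulations.
#'
#' @param n_states number of discrete cortical input states.
#' @param alpha_v critic learning rate; 0.05 default, 0.25 in the
#'   shared-control tutoring simulations.
#' @return object of class `critic_state`.
#' @export
critic_state <- function(n_states, alpha_v = 0.05) {
  stopifnot(n_states >= 1, alpha_v > 0, alpha_v < 1)
  structure(list(values = numeric(n_states), alpha_v = alpha_v),
            class = "critic_state")
}

#' TD error and critic update
#'
#' Computes the reward prediction error \eqn{\delta = r - V(s)} using the
#' pre-update value, then updates \eqn{V(s) \leftarrow V(s) + \alpha_V \delta}.
#' Never-visited states retain value exactly 0.
#'
#' @param critic a [critic_state()].
#' @param state integer state id.
#' @param reward scalar reward.
#' @return list with elements `delta` (the TD error) and `critic` (updated).
#' @export
td_error_and_update <- function(critic, state, reward) {
  stopifnot(inherits(critic, "critic_state"),
            state >= 1, state <= length(critic$values),
            is.finite(reward))
  delta <- reward - critic$values[state]
  critic$values[state] <- critic$values[state] + critic$alpha_v * delta
  list(delta = delta, critic = critic)
}

#' Off-policy Q error
#'
#' Reward prediction error for the Q-learning critic,
#' \eqn{\delta = r - Q(s,a)}, where the action value of the executed action is
#' read out of the network as the striatal logit
#' \eqn{\ell_a = y^{dSPN}_a - y^{iSPN}_a} computed from feedforward activity.
#' There is no stored Q table; the striatal output itself is the estimate.
#'
#' @param chosen_logit feedforward striatal logit of the executed action.
#' @param reward scalar reward.
#' @return the error \eqn{\delta}.
#' @export
q_error <- function(chosen_logit, reward) {
  stopifnot(is.finite(chosen_logit), is.finite(reward))
  reward - chosen_logit
}
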