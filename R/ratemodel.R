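#' Firing-rate model parameters
#'
#' Parameters of the continuous-time SPN firing-rate simulation of the
#' two-alternative forced-choice task. Four neurons are modeled (dSPN and
#' iSPN for each of two actions) with dynamics
#' \deqn{\tau \dot y_i = -y_i + [\textstyle\sum_j w_{ij} x_j + \eta_i(t) +
#'       e_i(t) + b]_+,}
#' where \eqn{\eta_i} is Ornstein-Uhlenbeck noise, \eqn{e_i} efferent input
#' and \eqn{b} a bias. Weights evolve online as
#' \eqn{\dot w_{ij} = \eta_{lr}\, f_i(\delta)\, (y_i - b)\, x_j}.
#'
#' @param tau_rate membrane time constant, ms. Not pinned down by the source
#'   model description; default 100 ms, configurable.
#' @param dt integration step, ms (20).
#' @param bias bias input b, Hz (5).
#' @param ou_tau OU noise time constant, ms (600).
#' @param ou_var OU noise stationary variance, Hz^2 (1/60).
#' @param efference_rate efferent input to the chosen action's dSPN and iSPN
#'   during the second half of the stimulus, Hz (7.5).
#' @param eta learning rate, ms^-1 (5e-4).
#' @param weight_init_sd s.d. of the Gaussian weight initialization, Hz (1).
#' @param stim_duration stimulus duration, ms (2000).
#' @param decision_window duration of the initial decision window, ms (1000).
#' @param consec_correct_criterion number of consecutive correct trials that
#'   defines "consistently correct" (10).
#' @return object of class `rate_model_params`.
#' @export
rate_model_params <- function(tau_rate = 100, dt = 20, bias = 5,
                              ou_tau = 600, ou_var = 1 / 60,
                              efference_rate = 7.5, eta = 5e-4,
                              weight_init_sd = 1,
                              stim_duration = 2000, decision_window = 1000,
                              consec_correct_criterion = 10) {
  stopifnot(dt > 0, dt <= ou_tau, tau_rate > 0,
            decision_window < stim_duration)
  structure(list(tau_rate = tau_rate, dt = dt, bias = bias,
                 ou_tau = ou_tau, ou_var = ou_var,
                 efference_rate = efference_rate, eta = eta,
                 weight_init_sd = weight_init_sd,
                 stim_duration = stim_duration,
                 decision_window = decision_window,
                 consec_correct_criterion = consec_correct_criterion),
            class = "rate_model_params")
}

#' Sample an Ornstein-Uhlenbeck noise trace
#'
#' Stationary OU samples using the exact discretization
#' \eqn{x_{t+1} = \rho x_t + \sigma\sqrt{1-\rho^2}\,\xi_t} with
#' \eqn{\rho = e^{-dt/\tau}}, so the stationary variance equals `variance`
#' for any `dt` (unlike a naive Euler scheme). The initial sample is drawn
#' from the stationary distribution.
#'
#' @param tau autocorrelation time constant, ms.
#' @param variance stationary variance.
#' @param dt time step, ms.
#' @param n_steps number of samples per series.
#' @param n_series number of independent series.
#' @return `n_steps` x `n_series` matrix.
#' @export
simulate_ou <- function(tau, variance, dt, n_steps, n_series = 1) {
  stopifnot(tau > 0, variance > 0, dt > 0, n_steps >= 1)
  rho <- exp(-dt / tau)
  sd_stat <- sqrt(variance)
  sd_innov <- sd_stat * sqrt(1 - rho^2)
  out <- matrix(0, n_steps, n_series)
  for (j in seq_len(n_series)) {
    innov <- stats::rnorm(n_steps, sd = sd_innov)
    innov[1] <- stats::rnorm(1, sd = sd_stat)
    out[, j] <- stats::filter(innov, rho, method = "recursive")
  }
  out
}

#' Run one firing-rate trial
#'
#' Euler integration of the four-neuron rate model for one stimulus
#' presentation. The action is the argmax of the two per-action difference
#' modes averaged over the decision window; during the remainder of the
#' stimulus the chosen action's dSPN and iSPN receive efferent input and the
#' weights integrate the plasticity rule with \eqn{f_i(\delta) = +1} for
#' dSPNs after a correct action and iSPNs after an incorrect action, and -1
#' otherwise, using \eqn{(y_i - b)} and the one-hot stimulus.
#'
#' Neuron order is (dSPN-1, iSPN-1, dSPN-2, iSPN-2).
#'
#' @param params a [rate_model_params()].
#' @param weights 4 x 2 weight matrix (neurons x stimuli), Hz.
#' @param stimulus stimulus id (1 or 2); the correct action equals the
#'   stimulus id.
#' @return list with `rates` (time x 4, Hz), `action`, `correct`,
#'   `stimulus`, and updated `weights`. Class `rate_trace`.
#' @export
run_rate_trial <- function(params, weights, stimulus) {
  stopifnot(all(dim(weights) == c(4, 2)), stimulus %in% c(1, 2))
  p <- params
  n_steps <- round(p$stim_duration / p$dt)
  n_dec <- round(p$decision_window / p$dt)
  x <- c(0, 0); x[stimulus] <- 1
  noise <- simulate_ou(p$ou_tau, p$ou_var, p$dt, n_steps, n_series = 4)
  rates <- matrix(0, n_steps, 4)
  y <- rep(p$bias, 4)
  e <- numeric(4)
  action <- NA_integer_
  correct <- NA
  f <- numeric(4)
  for (t in seq_len(n_steps)) {
    drive <- relu(drop(weights %*% x) + noise[t, ] + e + p$bias)
    y <- y + (p$dt / p$tau_rate) * (-y + drive)
    rates[t, ] <- y
    if (t == n_dec) {
      d1 <- mean(rates[1:n_dec, 1] - rates[1:n_dec, 2])
      d2 <- mean(rates[1:n_dec, 3] - rates[1:n_dec, 4])
      action <- if (d1 >= d2) 1L else 2L  # ties -> lowest index
      correct <- action == stimulus
      idx <- if (action == 1L) c(1L, 2L) else c(3L, 4L)
      e[idx] <- p$efference_rate
      # f: +1 for dSPNs after correct / iSPNs after incorrect, -1 otherwise
      f <- if (correct) c(1, -1, 1, -1) else c(-1, 1, -1, 1)
    }
    if (t > n_dec) {
      dw <- p$dt * p$eta * f * (y - p$bias)
      weights <- weights + outer(dw, x)
    }
  }
  structure(list(rates = rates, stimulus = stimulus, action = action,
                 correct = correct, weights = weights, params = p),
            class = "rate_trace")
}

#' Run a firing-rate learning experiment
#'
#' Runs trials with uniformly random stimuli until `n_trials`, tracking
#' correctness. The trials-to-criterion is the trial index at which the
#' `consec_correct_criterion`-th consecutive correct trial completes; if the
#' criterion is never met within `n_trials` the result is censored
#' (`trials_to_criterion = NA` with `censored = TRUE`).
#'
#' @param params a [rate_model_params()].
#' @param n_trials maximum number of trials.
#' @param seed optional RNG seed.
#' @param keep_traces keep the full rate traces of the first and last trial.
#' @return list with `trials_to_criterion`, `censored`, `correct` (logical
#'   per trial), `weights`, and optionally `first_trace` / `last_trace`.
#' @export
run_rate_experiment <- function(params, n_trials = 100, seed = NULL,
                                keep_traces = FALSE) {
  stopifnot(n_trials >= params$consec_correct_criterion)
  if (!is.null(seed)) set.seed(seed)
  weights <- matrix(stats::rnorm(8, sd = params$weight_init_sd), 4, 2)
  correct <- logical(n_trials)
  streak <- 0L
  ttc <- NA_integer_
  first_trace <- last_trace <- NULL
  for (t in seq_len(n_trials)) {
    stim <- sample.int(2L, 1L)
    tr <- run_rate_trial(params, weights, stim)
    weights <- tr$weights
    correct[t] <- tr$correct
    if (keep_traces) {
      if (t == 1L) first_trace <- tr
      last_trace <- tr
    }
    streak <- if (tr$correct) streak + 1L else 0L
    if (is.na(ttc) && streak >= params$consec_correct_criterion) ttc <- t
  }
  list(trials_to_criterion = ttc, censored = is.na(ttc),
       correct = correct, weights = weights,
       first_trace = first_trace, last_trace = last_trace)
}

#' Project a rate trace onto per-action sum and difference modes
#'
#' For each action a, the difference mode is
#' \eqn{y^{dSPN}_a(t) - y^{iSPN}_a(t)} (drives selection) and the sum mode is
#' \eqn{y^{dSPN}_a(t) + y^{iSPN}_a(t)} (drives learning). The decomposition
#' is exactly invertible: \eqn{y^{dSPN} = (sum + diff)/2}.
#'
#' @param trace a `rate_trace` (or a time x 4 rate matrix in the neuron order
#'   dSPN-1, iSPN-1, dSPN-2, iSPN-2).
#' @return list with matrices `difference` and `sum`, each time x 2 (one
#'   column per action).
#' @export
project_sum_diff_modes <- function(trace) {
  r <- if (inherits(trace, "rate_trace")) trace$rates else trace
  stopifnot(ncol(r) == 4)
  list(difference = cbind(r[, 1] - r[, 2], r[, 3] - r[, 4]),
       sum = cbind(r[, 1] + r[, 2], r[, 3] + r[, 4]))
}
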