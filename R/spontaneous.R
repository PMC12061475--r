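#' Spontaneous-behavior simulation configuration
#'
#' Configuration of the continuous action-selection simulation used to derive
#' predictions about SPN activity during spontaneous behavior: A actions,
#' each with a dSPN and an iSPN whose feedforward activity is a stationary
#' Gaussian process with kernel \eqn{k(t_1,t_2) = e^{-|t_1-t_2|/\tau_{gp}}};
#' every `action_interval` timesteps an action (or the no-action option) is
#' sampled from the softmax policy using the previous timestep's activity,
#' and the selected action's dSPN and iSPN receive an exponentially decaying
#' efferent transient.
#'
#' At `beta = 100` the softmax normalizer \eqn{\sum_a e^{\beta\ell_a}} is far
#' beyond floating-point range, so the no-action weight is parameterized in
#' log space: `log_c_nogo` is the no-action logit entering a max-shifted
#' softmax, mathematically identical to the \eqn{c_{nogo}} form.
#'
#' @param n_actions number of actions A (50).
#' @param beta inverse temperature (100).
#' @param c_efference efferent amplitude (1.5).
#' @param gp_tau Gaussian-process autocorrelation time, timesteps (10).
#' @param efference_tau efference decay time constant, timesteps (10).
#' @param action_interval timesteps between selection events (10).
#' @param n_steps session length in timesteps (5e4).
#' @param target_none_frac target fraction of selection events with no action
#'   (0.5); used by [calibrate_nogo_offset()].
#' @param log_c_nogo log-domain no-action weight; `NA` until calibrated.
#' @return object of class `spontaneous_config`.
#' @export
spontaneous_config <- function(n_actions = 50, beta = 100, c_efference = 1.5,
                               gp_tau = 10, efference_tau = 10,
                               action_interval = 10, n_steps = 5e4,
                               target_none_frac = 0.5, log_c_nogo = NA_real_) {
  stopifnot(n_actions >= 2, gp_tau > 0, efference_tau > 0,
            action_interval >= 1, n_steps >= 2,
            target_none_frac > 0, target_none_frac < 1)
  structure(list(n_actions = n_actions, beta = beta,
                 c_efference = c_efference, gp_tau = gp_tau,
                 efference_tau = efference_tau,
                 action_interval = action_interval,
                 n_steps = as.integer(n_steps),
                 target_none_frac = target_none_frac,
                 log_c_nogo = log_c_nogo),
            class = "spontaneous_config")
}

#' Sample Gaussian-process feedforward activity
#'
#' Each neuron's trace is an independent stationary zero-mean unit-variance
#' Gaussian process with autocorrelation \eqn{e^{-lag/\tau_{gp}}}, sampled
#' exactly as an AR(1) process on the simulation grid.
#'
#' @param n_neurons number of independent traces.
#' @param n_steps trace length.
#' @param gp_tau autocorrelation time constant (timesteps).
#' @return `n_steps` x `n_neurons` matrix.
#' @export
sample_gp_activity <- function(n_neurons, n_steps, gp_tau) {
  simulate_ou(tau = gp_tau, variance = 1, dt = 1,
              n_steps = n_steps, n_series = n_neurons)
}

run_spontaneous_core <- function(config, log_c_nogo, n_steps) {
  A <- config$n_actions
  interval <- config$action_interval
  decay <- exp(-1 / config$efference_tau)
  ff_d <- sample_gp_activity(A, n_steps, config$gp_tau)
  ff_i <- sample_gp_activity(A, n_steps, config$gp_tau)
  eff <- numeric(A)
  dspn <- matrix(0, n_steps, A)
  ispn <- matrix(0, n_steps, A)
  labels <- rep(NA_integer_, n_steps)
  n_events <- floor((n_steps - 1) / interval)
  actions <- integer(n_events)
  onsets <- integer(n_events)
  ev <- 0L
  for (t in seq_len(n_steps)) {
    eff <- eff * decay
    if (t > 1 && (t - 1) %% interval == 0L && ev < n_events) {
      # select from the previous timestep's total activity
      l <- dspn[t - 1, ] - ispn[t - 1, ]
      p <- softmax_nogo(l, config$beta, log_c_nogo = log_c_nogo)
      a <- select_action(p)
      ev <- ev + 1L
      actions[ev] <- if (is.na(a)) NA_integer_ else a
      onsets[ev] <- t
      if (!is.na(a)) {
        eff[a] <- eff[a] + config$c_efference
        labels[t:min(n_steps, t + interval - 1L)] <- a
      }
    }
    dspn[t, ] <- relu(ff_d[t, ] + eff)
    ispn[t, ] <- relu(ff_i[t, ] + eff)
  }
  structure(list(dspn = dspn, ispn = ispn,
                 actions = actions[seq_len(ev)], onsets = onsets[seq_len(ev)],
                 labels = labels, config = config),
            class = "sim_session")
}

#' Calibrate the no-action offset
#'
#' Bisection on the log-domain no-action weight until the simulated
#' no-action frequency matches `config$target_none_frac` within `tol`.
#'
#' @param config a [spontaneous_config()].
#' @param calib_steps session length used per bisection evaluation.
#' @param tol tolerance on the no-action frequency (0.01).
#' @param max_iter maximum bisection iterations.
#' @param lower,upper initial bracket for `log_c_nogo`.
#' @param seed optional RNG seed.
#' @return the calibrated `log_c_nogo` (scalar).
#' @export
calibrate_nogo_offset <- function(config, calib_steps = 2e4, tol = 0.01,
                                  max_iter = 40, lower = -50, upper = 1500,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  none_frac <- function(z) {
    s <- run_spontaneous_core(config, z, as.integer(calib_steps))
    mean(is.na(s$actions))
  }
  target <- config$target_none_frac
  f_lo <- none_frac(lower); f_hi <- none_frac(upper)
  if (f_lo > target || f_hi < target)
    stop("bisection bracket does not contain the target no-action frequency")
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    f_mid <- none_frac(mid)
    if (abs(f_mid - target) <= tol) return(mid)
    if (f_mid < target) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Run a spontaneous-behavior session
#'
#' Simulates continuous action selection: every `action_interval` timesteps
#' an action is sampled from the softmax over the previous timestep's
#' activity; on selection, an efferent transient of amplitude `c_efference`
#' decaying as \eqn{e^{-t/\tau_{eff}}} is added to the chosen action's dSPN
#' and iSPN. Total activity per pathway is the rectified sum of feedforward
#' and efferent input. Overlapping transients sum linearly. No plasticity
#' operates (no rewards are modeled).
#'
#' @param config a [spontaneous_config()]; if `log_c_nogo` is `NA` it is
#'   calibrated first with [calibrate_nogo_offset()].
#' @param seed optional RNG seed.
#' @return object of class `sim_session` with `dspn`, `ispn` (time x A),
#'   `actions` (per selection event; `NA` = no action), `onsets`, and
#'   per-frame `labels`.
#' @export
run_spontaneous_session <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(config$log_c_nogo))
    config$log_c_nogo <- calibrate_nogo_offset(config)
  run_spontaneous_core(config, config$log_c_nogo, config$n_steps)
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session>", nrow(x$dspn), "timesteps,", ncol(x$dspn),
      "actions;", sum(!is.na(x$actions)), "action events,",
      round(mean(is.na(x$actions)), 3), "no-action fraction\n")
  invisible(x)
}

#' Convert a simulated session to a neural session
#'
#' Arranges the simulated dSPN and iSPN traces as a [neural_session()] (one
#' neuron per action per pathway) with the selected actions as behavioral
#' syllable labels, so the full analysis pipeline applies unchanged.
#'
#' @param sim a `sim_session`.
#' @param frame_rate nominal frame rate assigned to timesteps, Hz.
#' @return a [neural_session()].
#' @export
as_neural_session <- function(sim, frame_rate = 30) {
  stopifnot(inherits(sim, "sim_session"))
  A <- ncol(sim$dspn)
  keep <- !is.na(sim$actions)
  interval <- sim$config$action_interval
  inst <- data.frame(onset = sim$onsets[keep],
                     end = pmin(nrow(sim$dspn),
                                sim$onsets[keep] + interval - 1L),
                     syllable = sim$actions[keep])
  neural_session(activity = cbind(sim$dspn, sim$ispn),
                 pathway = rep(c("dSPN", "iSPN"), each = A),
                 syllable = sim$labels,
                 frame_rate = frame_rate,
                 instances = inst)
}
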