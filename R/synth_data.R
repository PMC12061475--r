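#' Generate a first-order Markov behavioral-syllable sequence
#'
#' Emulates the structure of segmented spontaneous behavior: a first-order
#' Markov chain over S syllables with geometrically distributed durations
#' (at a nominal 30 Hz framing).
#'
#' @param n_syllables number of syllables S.
#' @param transition row-stochastic S x S transition matrix; default uniform
#'   with self-transitions forbidden.
#' @param n_events number of syllable events.
#' @param mean_duration mean syllable duration in frames (12, about 400 ms
#'   at 30 Hz).
#' @param seed optional RNG seed.
#' @return list with `events` (syllable id per event), `durations` (frames),
#'   `labels` (syllable id per frame), `onsets` (frame index per event).
#' @export
generate_markov_syllable_sequence <- function(n_syllables, transition = NULL,
                                              n_events, mean_duration = 12,
                                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- n_syllables
  if (is.null(transition)) {
    transition <- matrix(1 / (S - 1), S, S)
    diag(transition) <- 0
  }
  stopifnot(all(dim(transition) == c(S, S)),
            all(abs(rowSums(transition) - 1) < 1e-8),
            all(transition >= 0), mean_duration >= 1)
  events <- integer(n_events)
  events[1] <- sample.int(S, 1L)
  for (t in 2:n_events)
    events[t] <- sample.int(S, 1L, prob = transition[events[t - 1], ])
  durations <- stats::rgeom(n_events, prob = 1 / mean_duration) + 1L
  labels <- rep(events, durations)
  onsets <- cumsum(c(1L, durations[-n_events]))
  list(events = events, durations = durations, labels = labels,
       onsets = onsets, transition = transition)
}

#' Generate a synthetic neural session with planted syllable structure
#'
#' Produces a [neural_session()] whose activity carries the signatures the
#' efference model predicts, with known ground truth, as a positive control
#' for the analysis pipeline: before each onset of syllable s, activity
#' ramps along the planted dSPN mode (positively) and iSPN mode
#' (negatively) — the difference-mode lead-up to selection; during the
#' syllable, both pathway modes are driven positively — the sum-mode
#' efferent transient. White noise is added throughout. The `null` setting
#' zeroes all planted structure.
#'
#' @param n_syllables number of syllables.
#' @param n_neurons neurons per pathway.
#' @param n_events number of syllable events.
#' @param noise_sd white-noise standard deviation (0.5).
#' @param amp_pre peak amplitude of the pre-onset difference-mode ramp (1.5).
#' @param amp_post amplitude of the within-syllable sum-mode drive (1).
#' @param pre_frames length of the pre-onset ramp, frames (8).
#' @param mean_duration mean syllable duration, frames (12).
#' @param transition optional Markov transition matrix.
#' @param null if `TRUE`, plant no structure (noise only).
#' @param seed optional RNG seed.
#' @return a [neural_session()] with the ground truth attached as attribute
#'   `ground_truth` (planted modes per pathway, amplitudes, transition
#'   matrix, noise scale, seed).
#' @export
generate_neural_session <- function(n_syllables = 8, n_neurons = 30,
                                    n_events = 400, noise_sd = 0.5,
                                    amp_pre = 1.5, amp_post = 1,
                                    pre_frames = 8, mean_duration = 12,
                                    transition = NULL, null = FALSE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq_out <- generate_markov_syllable_sequence(n_syllables, transition,
                                               n_events, mean_duration)
  n_frames <- length(seq_out$labels)
  modes_d <- matrix(stats::rnorm(n_syllables * n_neurons), n_syllables)
  modes_i <- matrix(stats::rnorm(n_syllables * n_neurons), n_syllables)
  modes_d <- modes_d / sqrt(rowSums(modes_d^2))
  modes_i <- modes_i / sqrt(rowSums(modes_i^2))
  a_pre <- if (null) 0 else amp_pre
  a_post <- if (null) 0 else amp_post
  act_d <- matrix(stats::rnorm(n_frames * n_neurons, sd = noise_sd), n_frames)
  act_i <- matrix(stats::rnorm(n_frames * n_neurons, sd = noise_sd), n_frames)
  for (e in seq_len(n_events)) {
    s <- seq_out$events[e]
    on <- seq_out$onsets[e]
    en <- min(n_frames, on + seq_out$durations[e] - 1L)
    # pre-onset difference-mode ramp: dSPN up, iSPN down
    ramp_rows <- max(1L, on - pre_frames):(on - 1L)
    if (on > 1L) {
      ramp <- seq_len(length(ramp_rows)) / pre_frames
      act_d[ramp_rows, ] <- act_d[ramp_rows, ] +
        a_pre * outer(ramp, modes_d[s, ])
      act_i[ramp_rows, ] <- act_i[ramp_rows, ] -
        a_pre * outer(ramp, modes_i[s, ])
    }
    # within-syllable sum-mode drive: both pathways up
    act_d[on:en, ] <- act_d[on:en, ] +
      a_post * matrix(modes_d[s, ], en - on + 1L, n_neurons, byrow = TRUE)
    act_i[on:en, ] <- act_i[on:en, ] +
      a_post * matrix(modes_i[s, ], en - on + 1L, n_neurons, byrow = TRUE)
  }
  gt <- list(modes_d = modes_d, modes_i = modes_i,
             amp_pre = a_pre, amp_post = a_post, pre_frames = pre_frames,
             transition = seq_out$transition, noise_sd = noise_sd,
             null = null, seed = seed)
  sess <- neural_session(activity = cbind(act_d, act_i),
                         pathway = rep(c("dSPN", "iSPN"), each = n_neurons),
                         syllable = seq_out$labels,
                         instances = data.frame(
                           onset = seq_out$onsets,
                           end = pmin(n_frames,
                                      seq_out$onsets + seq_out$durations - 1L),
                           syllable = seq_out$events))
  attr(sess, "ground_truth") <- gt
  sess
}

#' Generate a synthetic dLight session from a known Q table
#'
#' Inverts the Q-learning model of dopamine transients: syllable
#' transitions are sampled with probabilities
#' \eqn{\propto e^{\beta Q(s_{t-1}, \cdot)}} and the dopamine during each
#' transition is \eqn{\max_{s'} Q(s_t, s') - Q(s_{t-1}, s_t)} plus Gaussian
#' noise, then z-scored across the session (mirroring the per-session
#' z-scoring of per-syllable dLight maxima).
#'
#' @param Q S x S value table; default standard-normal entries.
#' @param n_syllables S (used only when `Q` is `NULL`; 20).
#' @param beta softmax inverse temperature used for sampling (1).
#' @param noise_sd dopamine noise s.d. before z-scoring (0.1).
#' @param n_transitions number of transitions (1e4).
#' @param seed optional RNG seed.
#' @return list with `syllables` (length `n_transitions + 1`), `dopamine`
#'   (same length; z-scored; first entry has no defined transition and is
#'   set to the session mean, 0), and the generating `Q`, `beta`, `noise_sd`.
#' @export
generate_dlight_session <- function(Q = NULL, n_syllables = 20, beta = 1,
                                    noise_sd = 0.1, n_transitions = 1e4,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Q)) Q <- matrix(stats::rnorm(n_syllables^2), n_syllables)
  S <- nrow(Q)
  stopifnot(ncol(Q) == S, all(is.finite(Q)))
  P <- t(apply(Q, 1, function(q) {
    z <- beta * q; z <- z - max(z); exp(z) / sum(exp(z))
  }))
  maxQ <- apply(Q, 1, max)
  syl <- integer(n_transitions + 1)
  da <- numeric(n_transitions + 1)
  syl[1] <- sample.int(S, 1L)
  for (t in seq_len(n_transitions)) {
    syl[t + 1] <- sample.int(S, 1L, prob = P[syl[t], ])
    da[t + 1] <- maxQ[syl[t + 1]] - Q[syl[t], syl[t + 1]] +
      stats::rnorm(1, sd = noise_sd)
  }
  da[1] <- mean(da[-1])
  if (stats::sd(da) > 0) da <- as.vector(scale(da)) else da <- da - mean(da)
  list(syllables = syl, dopamine = da, Q = Q, beta = beta,
       noise_sd = noise_sd)
}

#' Small deterministic fixtures for task and rate-model tests
#'
#' Fixed-seed miniature configurations used by the test suite: a tiny
#' go/no-go run, a tiny two-cue action-selection run, and a short
#' firing-rate experiment.
#'
#' @return named list of configuration lists.
#' @export
generate_task_fixtures <- function() {
  list(
    gonogo = list(rule_kind = "linear", postselection = "efference",
                  protocol = "reward_correct", n_trials = 50, n_seeds = 2,
                  seed = 101),
    action_selection = list(rule_kind = "linear",
                            postselection = "efference",
                            protocol = "punish_incorrect", n_trials = 50,
                            n_seeds = 2, seed = 202),
    rate = list(params = rate_model_params(), n_trials = 30, seed = 303)
  )
}
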