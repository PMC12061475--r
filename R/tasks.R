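#' Trial-based task specification
#'
#' Defines a discrete operant task: a set of cortical input states (cues),
#' a set of actions, a correct action per state, and a feedback protocol.
#' The go/no-go task has a single cue and a single action whose execution is
#' the correct response (`c_nogo = 1` in the policy); multi-action tasks use
#' one-hot cues and `c_nogo = 0`.
#'
#' @param n_states number of cortical input states.
#' @param n_actions number of actions.
#' @param correct_action integer vector, correct action per state.
#' @param protocol `"reward_correct"` (+1 for the correct action, 0
#'   otherwise), `"punish_incorrect"` (-1 for an incorrect action or for
#'   withholding on go/no-go, 0 otherwise), or `"both"` (+1 / -1).
#' @param reward_magnitude,punish_magnitude feedback magnitudes.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(n_states, n_actions,
                      correct_action = seq_len(n_states),
                      protocol = c("reward_correct", "punish_incorrect", "both"),
                      reward_magnitude = 1, punish_magnitude = -1) {
  protocol <- match.arg(protocol)
  stopifnot(length(correct_action) == n_states,
            all(correct_action >= 1), all(correct_action <= n_actions))
  structure(list(n_states = n_states, n_actions = n_actions,
                 correct_action = correct_action, protocol = protocol,
                 reward_magnitude = reward_magnitude,
                 punish_magnitude = punish_magnitude),
            class = "task_spec")
}

task_reward <- function(task, state, chosen) {
  correct <- !is.na(chosen) && chosen == task$correct_action[state]
  switch(task$protocol,
    reward_correct = if (correct) task$reward_magnitude else 0,
    punish_incorrect = if (correct) 0 else task$punish_magnitude,
    both = if (correct) task$reward_magnitude else task$punish_magnitude)
}

one_hot <- function(i, n) { x <- numeric(n); x[i] <- 1; x }

#' Run a single learning trial
#'
#' One trial of the trial-based simulations: sample a state uniformly (or use
#' `state`), compute feedforward activity, form action probabilities (with an
#' optional tutor pathway), sample the executed action, deliver feedback per
#' the task protocol, compute the dopamine signal from the TD or Q critic,
#' form the post-selection activity under the chosen model, and apply the
#' three-factor update to both pathways. The dopamine signal is computed from
#' pre-update weights and critic; the critic is then updated, then the
#' weights.
#'
#' Post-selection models:
#' \describe{
#'   \item{`efference`}{[apply_efference()] on the executed action (or, for
#'     `efference_mode = "on_policy"`, on the striatum's own argmax action).
#'     When no action is taken there is no efferent signal and no weight
#'     update occurs (the critic still updates).}
#'   \item{`canonical`}{[canonical_postselection()].}
#'   \item{`none`}{plasticity acts on feedforward activity.}
#' }
#'
#' @param net a [striatal_network()].
#' @param critic a [critic_state()].
#' @param rule a [plasticity_rule()].
#' @param task a [task_spec()].
#' @param postselection `"efference"`, `"canonical"`, or `"none"`.
#' @param critic_kind `"td"` or `"q"`.
#' @param tutor optional list with `bias` (logit bias vector over actions,
#'   applied to the state's correct action) and `striatal_weight`.
#' @param efference_mode `"off_policy"` (efference targets the executed
#'   action) or `"on_policy"` (targets the striatum's most favored action).
#' @param state optional state id; sampled uniformly if `NULL`.
#' @return list with `record` (state, action, reward, delta, correct),
#'   `net` and `critic` (updated).
#' @export
run_trial <- function(net, critic, rule, task,
                      postselection = c("efference", "canonical", "none"),
                      critic_kind = c("td", "q"),
                      tutor = NULL,
                      efference_mode = c("off_policy", "on_policy"),
                      state = NULL) {
  postselection <- match.arg(postselection)
  critic_kind <- match.arg(critic_kind)
  efference_mode <- match.arg(efference_mode)

  if (is.null(state)) state <- sample.int(task$n_states, 1L)
  x <- one_hot(state, net$n_inputs)
  act <- feedforward_activity(net, x)

  probs <- if (is.null(tutor)) {
    action_probabilities(act, net$beta, net$c_nogo)
  } else {
    bias <- numeric(task$n_actions)
    bias[task$correct_action[state]] <- tutor$bias
    shared_control_probabilities(act, bias, tutor$striatal_weight,
                                 net$beta, net$c_nogo)
  }
  chosen <- select_action(probs)
  r <- task_reward(task, state, chosen)

  if (critic_kind == "td") {
    upd <- td_error_and_update(critic, state, r)
    delta <- upd$delta
    critic <- upd$critic
  } else {
    if (is.na(chosen))
      stop("Q critic requires an executed action (no-action outcome)")
    delta <- q_error(act$logits[chosen], r)
  }

  post <- switch(postselection,
    efference = {
      if (is.na(chosen)) NULL else {
        target <- if (efference_mode == "off_policy") chosen
                  else which.max(act$logits)  # ties -> lowest index
        apply_efference(net, x, target)
      }
    },
    canonical = canonical_postselection(task$n_actions, chosen),
    none = act)

  if (!is.null(post)) {
    net$W_d <- net$W_d + weight_update(rule, "direct", delta, post$y_d, x)
    net$W_i <- net$W_i + weight_update(rule, "indirect", delta, post$y_i, x)
  }

  correct <- !is.na(chosen) && chosen == task$correct_action[state]
  list(record = list(state = state, action = chosen, reward = r,
                     delta = delta, correct = correct),
       net = net, critic = critic)
}

run_learning_loop <- function(net, critic, rule, task, postselection,
                              critic_kind, tutor, efference_mode, n_trials,
                              eval_every = 0L, eval_fun = NULL) {
  rec <- data.frame(trial = seq_len(n_trials), state = NA_integer_,
                    action = NA_integer_, reward = NA_real_,
                    delta = NA_real_, correct = NA)
  evals <- if (eval_every > 0L)
    data.frame(trial = integer(0), p_correct = numeric(0)) else NULL
  for (t in seq_len(n_trials)) {
    out <- run_trial(net, critic, rule, task, postselection, critic_kind,
                     tutor, efference_mode)
    net <- out$net; critic <- out$critic
    rec$state[t] <- out$record$state
    rec$action[t] <- out$record$action
    rec$reward[t] <- out$record$reward
    rec$delta[t] <- out$record$delta
    rec$correct[t] <- out$record$correct
    if (eval_every > 0L && t %% eval_every == 0L)
      evals <- rbind(evals,
                     data.frame(trial = t, p_correct = eval_fun(net)))
  }
  list(records = rec, net = net, critic = critic, evals = evals)
}

# exact striatum-alone probability of the correct action, averaged over states
striatal_alone_p_correct <- function(net, task) {
  mean(vapply(seq_len(task$n_states), function(s) {
    act <- feedforward_activity(net, one_hot(s, net$n_inputs))
    p <- action_probabilities(act, net$beta, net$c_nogo)
    p[task$correct_action[s]]
  }, numeric(1)))
}

#' Go/no-go learning experiment
#'
#' Simulates the single-cue go/no-go task (one action; executing it is
#' correct) over several seeds and summarizes performance as the fraction of
#' correct trials in the final window.
#'
#' @param rule_kind plasticity rule kind (see [plasticity_rule()]).
#' @param postselection post-selection activity model.
#' @param protocol feedback protocol (see [task_spec()]).
#' @param n_trials trials per run.
#' @param n_seeds number of independent runs.
#' @param alpha,alpha_v actor and critic learning rates.
#' @param beta softmax inverse temperature.
#' @param c_efference efferent amplitude for task simulations.
#' @param window number of final trials over which performance is scored.
#' @param seed base RNG seed; run k uses `seed + k - 1`.
#' @return object of class `learning_curve_summary`: per-seed trial records,
#'   per-seed final performance, and `mean_final_p_correct`.
#' @export
run_gonogo_experiment <- function(rule_kind = "linear",
                                  postselection = "efference",
                                  protocol = "reward_correct",
                                  n_trials = 500, n_seeds = 20,
                                  alpha = 0.05, alpha_v = 0.05,
                                  beta = 10, c_efference = 0.5,
                                  window = 50, seed = 1) {
  task <- task_spec(1, 1, 1, protocol)
  run_task_experiment(task, c_nogo = 1, rule_kind, postselection,
                      critic_kind = "td", tutor = NULL,
                      efference_mode = "off_policy",
                      n_trials, n_seeds, alpha, alpha_v, beta, c_efference,
                      window, seed)
}

#' Multi-cue action selection learning experiment
#'
#' Task with `n_states` one-hot cues and `n_actions` actions, one correct
#' action per cue (`c_nogo = 0`, so an action is always taken).
#'
#' @inheritParams run_gonogo_experiment
#' @param n_states,n_actions task dimensions.
#' @return a `learning_curve_summary`.
#' @export
run_action_selection_experiment <- function(rule_kind = "linear",
                                            postselection = "efference",
                                            protocol = "reward_correct",
                                            n_states = 2, n_actions = 2,
                                            n_trials = 500, n_seeds = 20,
                                            alpha = 0.05, alpha_v = 0.05,
                                            beta = 10, c_efference = 0.5,
                                            window = 50, seed = 1) {
  task <- task_spec(n_states, n_actions, seq_len(n_states), protocol)
  run_task_experiment(task, c_nogo = 0, rule_kind, postselection,
                      critic_kind = "td", tutor = NULL,
                      efference_mode = "off_policy",
                      n_trials, n_seeds, alpha, alpha_v, beta, c_efference,
                      window, seed)
}

run_task_experiment <- function(task, c_nogo, rule_kind, postselection,
                                critic_kind, tutor, efference_mode,
                                n_trials, n_seeds, alpha, alpha_v, beta,
                                c_efference, window, seed) {
  stopifnot(n_trials >= 1, window <= n_trials)
  runs <- vector("list", n_seeds)
  final <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    set.seed(seed + k - 1L)
    net <- striatal_network(task$n_actions, task$n_states, beta = beta,
                            c_nogo = c_nogo, c_efference = c_efference)
    critic <- critic_state(task$n_states, alpha_v)
    rule <- plasticity_rule(rule_kind, alpha = alpha)
    out <- run_learning_loop(net, critic, rule, task, postselection,
                             critic_kind, tutor, efference_mode, n_trials)
    runs[[k]] <- out$records
    final[k] <- mean(out$records$correct[(n_trials - window + 1):n_trials])
  }
  structure(list(task = task, runs = runs, final_p_correct = final,
                 mean_final_p_correct = mean(final),
                 n_trials = n_trials, n_seeds = n_seeds, window = window),
            class = "learning_curve_summary")
}

#' @export
print.learning_curve_summary <- function(x, ...) {
  cat("<learning_curve_summary>", x$n_seeds, "seeds x", x$n_trials,
      "trials; mean p(correct) over last", x$window, "trials =",
      round(x$mean_final_p_correct, 3), "\n")
  invisible(x)
}

#' Shared-control (tutoring) learning experiment
#'
#' Action selection is jointly controlled by the striatum (logits scaled by
#' `striatal_weight`) and a tutor pathway biasing the correct action. The
#' striatum learns off-policy from the executed actions (or on-policy from
#' its own favored action, for the control condition), with a Q or TD critic.
#' Striatal-alone performance is evaluated every `eval_every` trials by
#' computing, with the tutor disabled and unit striatal weight, the exact
#' softmax probability of the correct action averaged over states.
#'
#' @inheritParams run_gonogo_experiment
#' @param striatal_weight strength of striatal control relative to the tutor.
#' @param efference_mode `"off_policy"` or `"on_policy"`.
#' @param critic_kind `"q"` or `"td"`.
#' @param n_states,n_actions task dimensions (defaults 10 and 10).
#' @param tutor_bias tutor logit bias on the correct action.
#' @param eval_every evaluation interval in trials.
#' @return object of class `shared_control_summary` with per-seed evaluation
#'   curves and `mean_final_p_correct` (striatal-alone, final evaluation).
#' @export
run_shared_control_experiment <- function(striatal_weight = 0.1,
                                          efference_mode = c("off_policy",
                                                             "on_policy"),
                                          critic_kind = c("q", "td"),
                                          rule_kind = "linear",
                                          n_states = 10, n_actions = 10,
                                          n_trials = 1000, n_seeds = 10,
                                          alpha = 0.01, alpha_v = 0.25,
                                          beta = 10, c_efference = 0.5,
                                          tutor_bias = 1, eval_every = 50,
                                          seed = 1) {
  efference_mode <- match.arg(efference_mode)
  critic_kind <- match.arg(critic_kind)
  task <- task_spec(n_states, n_actions, seq_len(n_states), "reward_correct")
  tutor <- list(bias = tutor_bias, striatal_weight = striatal_weight)
  evals <- vector("list", n_seeds)
  final <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    set.seed(seed + k - 1L)
    net <- striatal_network(n_actions, n_states, beta = beta, c_nogo = 0,
                            c_efference = c_efference)
    critic <- critic_state(n_states, alpha_v)
    rule <- plasticity_rule(rule_kind, alpha = alpha)
    out <- run_learning_loop(net, critic, rule, task, "efference",
                             critic_kind, tutor, efference_mode, n_trials,
                             eval_every = eval_every,
                             eval_fun = function(n) striatal_alone_p_correct(n, task))
    evals[[k]] <- out$evals
    final[k] <- out$evals$p_correct[nrow(out$evals)]
  }
  structure(list(striatal_weight = striatal_weight,
                 efference_mode = efference_mode, critic_kind = critic_kind,
                 evals = evals, final_p_correct = final,
                 mean_final_p_correct = mean(final),
                 n_trials = n_trials, n_seeds = n_seeds),
            class = "shared_control_summary")
}

#' @export
print.shared_control_summary <- function(x, ...) {
  cat("<shared_control_summary>", x$efference_mode, "efference,",
      x$critic_kind, "critic, striatal weight", x$striatal_weight,
      "; striatal-alone p(correct) =", round(x$mean_final_p_correct, 3), "\n")
  invisible(x)
}
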