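#' Experiment configuration
#'
#' Validated configuration for a reproducible experiment. Unknown keys are
#' rejected by name. All randomness in [run_experiment()] flows from the
#' single `seed`, from which each component derives its own sub-seed, so
#' adding a component never perturbs another's draws.
#'
#' Supported kinds and their parameters (all optional, with the package
#' defaults):
#' \describe{
#'   \item{`gonogo`, `action_selection`}{`rule_kind`, `postselection`,
#'     `protocol`, `n_trials`, `n_seeds`, `alpha`, `alpha_v`, `beta`,
#'     `c_efference`, `window`.}
#'   \item{`shared_control`}{`striatal_weight`, `efference_mode`,
#'     `critic_kind`, `n_trials`, `n_seeds`, `alpha`, `alpha_v`, `beta`,
#'     `c_efference`, `tutor_bias`, `eval_every`.}
#'   \item{`rate2afc`}{`n_trials`, `n_seeds`, `tau_rate`.}
#'   \item{`spontaneous`}{`n_actions`, `n_steps`, `c_efference`, `beta`.}
#'   \item{`dlight_comparison`}{`n_sessions`, `n_syllables`,
#'     `n_transitions`, `gen_beta`, `noise_sd`.}
#' }
#'
#' @param kind experiment kind.
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @param ... kind-specific parameters (see above).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("gonogo", "action_selection",
                                       "shared_control", "rate2afc",
                                       "spontaneous", "dlight_comparison"),
                              seed = 1, out_dir = tempfile("striatumrl_"),
                              ...) {
  kind <- match.arg(kind)
  params <- list(...)
  allowed <- switch(kind,
    gonogo = ,
    action_selection = c("rule_kind", "postselection", "protocol",
                         "n_trials", "n_seeds", "alpha", "alpha_v", "beta",
                         "c_efference", "window"),
    shared_control = c("striatal_weight", "efference_mode", "critic_kind",
                       "n_trials", "n_seeds", "alpha", "alpha_v", "beta",
                       "c_efference", "tutor_bias", "eval_every"),
    rate2afc = c("n_trials", "n_seeds", "tau_rate"),
    spontaneous = c("n_actions", "n_steps", "c_efference", "beta"),
    dlight_comparison = c("n_sessions", "n_syllables", "n_transitions",
                          "gen_beta", "noise_sd"))
  unknown <- setdiff(names(params), allowed)
  if (length(unknown))
    stop("unknown config key(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  structure(list(kind = kind, seed = as.integer(seed), out_dir = out_dir,
                 params = params),
            class = "experiment_config")
}

# deterministic sub-seed per named component, all derived from the base seed
child_seed <- function(seed, component) {
  (seed * 1009L + sum(utf8ToInt(component)) * 101L) %% 2147483647L
}

#' Run a configured experiment and write its outputs
#'
#' Executes the experiment described by an [experiment_config()], writing
#' CSV summaries and a JSON manifest (config, package version, seed) to
#' `config$out_dir`.
#'
#' @param config an [experiment_config()].
#' @return (invisibly) a list with the in-memory `result` and the written
#'   `files`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  arg <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  result <- switch(config$kind,
    gonogo = ,
    action_selection = {
      runner <- if (config$kind == "gonogo") run_gonogo_experiment
                else run_action_selection_experiment
      res <- runner(rule_kind = arg("rule_kind", "linear"),
                    postselection = arg("postselection", "efference"),
                    protocol = arg("protocol", "reward_correct"),
                    n_trials = arg("n_trials", 500),
                    n_seeds = arg("n_seeds", 20),
                    alpha = arg("alpha", 0.05),
                    alpha_v = arg("alpha_v", 0.05),
                    beta = arg("beta", 10),
                    c_efference = arg("c_efference", 0.5),
                    window = arg("window", min(50, arg("n_trials", 500))),
                    seed = child_seed(config$seed, "tasks"))
      curves <- do.call(rbind, lapply(seq_along(res$runs), function(k)
        cbind(seed = k, res$runs[[k]])))
      put(curves, "curves.csv")
      put(data.frame(seed = seq_along(res$final_p_correct),
                     final_p_correct = res$final_p_correct), "summary.csv")
      res
    },
    shared_control = {
      res <- run_shared_control_experiment(
        striatal_weight = arg("striatal_weight", 0.1),
        efference_mode = arg("efference_mode", "off_policy"),
        critic_kind = arg("critic_kind", "q"),
        n_trials = arg("n_trials", 1000),
        n_seeds = arg("n_seeds", 10),
        alpha = arg("alpha", 0.01),
        alpha_v = arg("alpha_v", 0.25),
        beta = arg("beta", 10),
        c_efference = arg("c_efference", 0.5),
        tutor_bias = arg("tutor_bias", 1),
        eval_every = arg("eval_every", 50),
        seed = child_seed(config$seed, "shared"))
      evals <- do.call(rbind, lapply(seq_along(res$evals), function(k)
        cbind(seed = k, res$evals[[k]])))
      put(evals, "striatal_alone_evals.csv")
      res
    },
    rate2afc = {
      n_seeds <- arg("n_seeds", 20)
      params <- rate_model_params(tau_rate = arg("tau_rate", 100))
      ttc <- vapply(seq_len(n_seeds), function(k) {
        r <- run_rate_experiment(params, n_trials = arg("n_trials", 100),
                                 seed = child_seed(config$seed, "rate") + k)
        if (r$censored) NA_integer_ else r$trials_to_criterion
      }, integer(1))
      put(data.frame(seed = seq_len(n_seeds), trials_to_criterion = ttc),
          "trials_to_criterion.csv")
      list(trials_to_criterion = ttc,
           median_trials = stats::median(ttc, na.rm = TRUE))
    },
    spontaneous = {
      cfg <- spontaneous_config(n_actions = arg("n_actions", 50),
                                n_steps = arg("n_steps", 5e4),
                                c_efference = arg("c_efference", 1.5),
                                beta = arg("beta", 100))
      sim <- run_spontaneous_session(cfg,
                                     seed = child_seed(config$seed, "spont"))
      xc <- cross_correlation(rowSums(sim$dspn), rowSums(sim$ispn),
                              max_lag = 50)
      put(xc, "xcorr.csv")
      put(data.frame(event = seq_along(sim$actions), action = sim$actions,
                     onset = sim$onsets), "events.csv")
      list(session = sim, xcorr = xc, asymmetry = asymmetry_index(xc))
    },
    dlight_comparison = {
      n_sessions <- arg("n_sessions", 50)
      rows <- lapply(seq_len(n_sessions), function(k) {
        sess <- generate_dlight_session(
          n_syllables = arg("n_syllables", 20),
          beta = arg("gen_beta", 1),
          noise_sd = arg("noise_sd", 0.1),
          n_transitions = arg("n_transitions", 1e4),
          seed = child_seed(config$seed, "dlight") + k)
        tab <- compute_transition_tables(sess$syllables, sess$dopamine)
        r <- compare_models(tab)
        data.frame(session = k, model = names(r), pearson_r = unname(r))
      })
      cmp <- do.call(rbind, rows)
      put(cmp, "model_comparison.csv")
      cmp
    })
  manifest <- list(kind = config$kind, seed = config$seed,
                   params = config$params,
                   package_version =
                     as.character(utils::packageVersion("striatumrl")))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(list(result = result, files = files))
}
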