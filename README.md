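# striatumrl

Simulation and analysis toolkit for reinforcement learning in dorsal
striatum with opponent direct- and indirect-pathway spiny projection
neurons (dSPNs and iSPNs).

## The scientific problem

Corticostriatal synapses onto the two SPN classes follow opposite
dopamine-dependent plasticity rules: with presynaptic input *x*,
postsynaptic activity *y* and dopamine signal δ (a reward prediction
error),

    Δw_dSPN = α · f_dSPN(δ) · y · x        f_dSPN increasing in δ
    Δw_iSPN = α · f_iSPN(δ) · y · x        f_iSPN decreasing in δ

Under the textbook ("canonical") picture of action selection — the chosen
action's dSPN active, the unchosen actions' iSPNs active — the iSPN rule
reinforces exactly the wrong patterns: after a punished action, the iSPNs
that were inhibiting *other* actions get potentiated, making the punished
action *more* likely. This package implements the resolution: after an
action is selected, an *efference* signal excites both the dSPN and the
iSPN of the selected action. For each action, the **difference mode**
`y_dSPN − y_iSPN` drives selection (softmax with inverse temperature β and
a no-action weight `c_nogo`) while the **sum mode** `y_dSPN + y_iSPN`
drives learning: one linear-rule update changes each logit by exactly
`α · δ · (y_d + y_i) · (x·x)`. The two modes are orthogonal, so efferent
excitation changes learning without moving a single action probability —
and because the efference reports the action actually *executed*, the
circuit can learn off-policy (with a Q-type error `δ = r − ℓ_a` read off
the striatal logit of the executed action) from actions driven by other
motor pathways.

The package provides, as testable modules:

* `plasticity_rule()` / `dopamine_factor()` / `weight_update()` — linear,
  rectified, offset-sigmoid and same-sign-control rules; TD
  (`critic_state()`, `td_error_and_update()`) and Q (`q_error()`) critics;
* `striatal_network()` and the policy (`feedforward_activity()`,
  `action_probabilities()`, `apply_efference()`,
  `canonical_postselection()`, `shared_control_probabilities()`);
* trial-based experiments (`run_gonogo_experiment()`,
  `run_action_selection_experiment()`, `run_shared_control_experiment()`);
* a four-neuron firing-rate model of a 2AFC task with Ornstein–Uhlenbeck
  noise and online plasticity (`run_rate_experiment()`);
* spontaneous-behavior simulations with Gaussian-process feedforward input
  (`run_spontaneous_session()`) and the neural-data analyses applied to
  them: lagged cross-correlation and its asymmetry, behavioral-syllable
  activity-mode regression with split-half validation, time-warped
  onset-aligned mode projections, and a tuning selectivity index;
* four models relating per-syllable dopamine to syllable transition
  statistics (`fit_q_table()`, `fit_v_model()`, `predict_p_action_value()`,
  `predict_p_state_value()`, `compare_models()`);
* synthetic-data generators with known ground truth
  (`generate_neural_session()`, `generate_dlight_session()`,
  `generate_markov_syllable_sequence()`) so every analysis stage is
  testable end to end.

## Worked example

The go/no-go task with punishment-only feedback is the case that separates
the two models of post-selection activity. Executing the action ("go") is
correct; withholding is punished:

```r
library(striatumrl)

eff <- run_gonogo_experiment(protocol = "punish_incorrect",
                             postselection = "efference",
                             n_seeds = 10, seed = 1)
can <- run_gonogo_experiment(protocol = "punish_incorrect",
                             postselection = "canonical",
                             n_seeds = 10, seed = 1)
print(eff)
#> <learning_curve_summary> 10 seeds x 500 trials; mean p(correct) over last 50 trials = 1
print(can)
#> <learning_curve_summary> 10 seeds x 500 trials; mean p(correct) over last 50 trials = 0
```

The efference model learns the task perfectly; the canonical model drives
performance to zero, because punishment potentiates the no-go-promoting
iSPN pattern. Off-policy learning under shared control (a tutor pathway
executes the correct action while the striatum, at a tenth of the control
strength, learns from the outcome):

```r
sc <- run_shared_control_experiment(striatal_weight = 0.1,
                                    efference_mode = "off_policy",
                                    critic_kind = "q",
                                    n_seeds = 5, seed = 1)
print(sc)
#> <shared_control_summary> off_policy efference, q critic, striatal weight 0.1 ;
#>   striatal-alone p(correct) = 0.729
```

Evaluated with the tutor disabled, the striatum alone chooses correctly
73% of the time on a 10-state / 10-action task (chance is 10%); with an
on-policy efference signal or a state-value TD critic the same circuit
stays near chance (see `tests/testthat/test-acceptance.R`).

A command-line wrapper over the same experiments is installed at
`inst/cli/striatumrl.R`
(`Rscript inst/cli/striatumrl.R gonogo --seed 1 --out out/`).

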