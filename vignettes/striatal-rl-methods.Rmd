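---
title: "Opponent-pathway striatal reinforcement learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent-pathway striatal reinforcement learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatumrl)
```

This vignette is the package's account of the science it implements: the
model equations, the assumptions behind them, every tunable parameter with
its default and rationale, the numerical choices, and what the synthetic
data used in testing does and does not establish about real recordings.

## The model

### Three-factor plasticity with opponent dopamine dependence

Corticostriatal weights onto direct-pathway (dSPN) and indirect-pathway
(iSPN) spiny projection neurons change according to a three-factor rule:
presynaptic cortical activity $x_j$, postsynaptic SPN activity $y_a$, and a
dopamine-dependent factor $f(\delta)$, where $\delta$ is a scalar reward
prediction error broadcast globally to all synapses:

$$\Delta w^{dSPN}_{aj} = \alpha\, f_{dSPN}(\delta)\, y^{dSPN}_a x_j,
\qquad
\Delta w^{iSPN}_{aj} = \alpha\, f_{iSPN}(\delta)\, y^{iSPN}_a x_j.$$

$f_{dSPN}$ is increasing and $f_{iSPN}$ decreasing in $\delta$, reflecting
the opposite modulation of D1- and D2-receptor-bearing synapses by
dopamine. `plasticity_rule()` offers a linear pair ($\pm\delta$), a
rectified pair ($\max(\pm\delta,0)$), an offset sigmoid pair
($\tfrac12(a + b/(1 + c\,e^{1 \mp d\delta}))$ with $a=-3.5$, $b=11.5$,
$c=0.9$, $d=1$), and a control rule (`same_sign_indirect`) in which the
iSPN factor is deliberately set equal to the dSPN factor to break the
opponency. Note the offset sigmoids are equal but nonzero
($\approx -0.0816$) at $\delta = 0$, so a prolonged stream of exactly
baseline dopamine slowly drifts both pathways' weights; the rule is
implemented as written and the drift is simply a property of that rule.

The actor learning rate $\alpha$ defaults to 0.05 (dimensionless), reduced
to 0.01 in the shared-control experiments where many more trials are
simulated and the tutor keeps the executed policy nearly constant.

### Policy and network

One dSPN and one iSPN per action receive input from $M$ cortical units
through weight matrices initialized at 1 for task simulations
(`striatal_network()`). Activity is rectified linear,
$y = \phi(Wx) = \max(Wx, 0)$, and the striatal logit of action $a$ is
$\ell_a = y^{dSPN}_a - y^{iSPN}_a$. Actions are sampled from

$$p(a) = \frac{e^{\beta \ell_a}}{c_{nogo} + \sum_{a'} e^{\beta \ell_{a'}}},$$

with the residual mass $1 - \sum_a p(a)$ the probability of taking no
action. $\beta = 10$ in trial-based tasks and 100 in the spontaneous
simulations; $c_{nogo} = 1$ for go/no-go, 0 for multi-action tasks. The
softmax is computed with max-subtraction, which leaves the distribution
mathematically unchanged while preventing overflow; at $\beta = 100$ the
normalizer itself exceeds floating-point range, so the no-action weight is
carried in log space (`log_c_nogo`) as a no-action logit in the same
max-shifted softmax.

### Post-selection activity: canonical vs efference

Two models describe SPN activity after an action is chosen, and only this
activity enters the plasticity rule (the action itself is not re-sampled):

* **canonical** (`canonical_postselection()`): the chosen action's dSPN and
  every unselected action's iSPN are set to 1. When no action is taken,
  every action counts as unselected.
* **efference** (`apply_efference()`): both SPNs of the chosen action
  receive additive input $c_{eff}$ before rectification,
  $y_a = \phi(c_{eff}\,1[a=a^*] + Wx)_a$.

Because efference adds equally to both pathways, it moves the sum mode
$y^{dSPN}_a + y^{iSPN}_a$ and leaves the difference mode — and hence every
action probability — untouched whenever both pre-activations are positive.
For the linear rule in the linear regime, one update changes each logit by
exactly $\alpha\,\delta\,(y^{dSPN}_a + y^{iSPN}_a)(x \cdot x)$: the sum
mode is the learning channel, the difference mode the acting channel, and
the two are orthogonal. The test suite asserts the logit identity to
floating-point precision and the probability invariance bit-for-bit on
dyadic-rational inputs (where the additions are exact; on general reals
exactness holds to rounding error, since floating-point addition is not
associative).

**No-action trials.** When the no-go option is taken, the efference model
has no selected action to report, and we apply no weight update at all on
that trial (the critic still updates). The alternative — learning on
feedforward activity — makes the punish-on-no-go protocol unlearnable: the
punishment stream drives $V(s) \to -1$ while the logit collapses by
roughly $2\alpha \sum_t |\delta_t| \approx 2\alpha/\alpha_V$, and at
$\beta = 10$ the go probability lands near $e^{-20}$, from which no
recovery is possible within any reasonable horizon. Gating plasticity on
the presence of an executed action restores the asymmetry that lets the
efference model solve punishment-only protocols, and is the natural
reading of an efference signal: no action, no efference, no third factor
gate. The canonical model keeps its defined no-action pattern (all iSPNs
active), which is precisely what makes it fail those protocols.

### Critics

The dopamine signal is produced either by a tabular TD critic,
$\delta = r - V(s)$ followed by $V(s) \mathrel{+}= \alpha_V \delta$
(`td_error_and_update()`; $\alpha_V = 0.05$, or 0.25 in the
shared-control experiments), or by an off-policy Q-type error
$\delta = r - \ell_a$ (`q_error()`), where the action value of the
*executed* action is read directly off the feedforward striatal logit —
no separate Q table exists. The logit is read before efference is applied,
since efference is a post-selection event. Within a trial the order is:
compute $\delta$ from pre-update quantities, update the critic, then
update the weights.

### Shared control and the tutor pathway

`run_shared_control_experiment()` models action selection jointly driven
by the striatum and another motor pathway: combined logits
$w_s \ell_a + b_t 1[a = a^\dagger]$ (with $a^\dagger$ the correct action)
enter the same softmax. The tutor bias $b_t = 1$ at $\beta = 10$ makes the
tutor nearly deterministic, which is the regime of interest: the executed
action is almost always correct, so a state-value critic converges
($V \to r$) and its error vanishes, leaving only a transient preference of
order $\beta \cdot 2 c_{eff} \alpha / \alpha_V$ — chance-level performance
— while the Q-type error $r - \ell_a$ keeps teaching until
$\ell_{a^\dagger} = r$, an asymptotic logit gap of
$c_{eff}/(1 + c_{eff})$. Striatal-alone performance is evaluated exactly
(softmax probability of the correct action, tutor off, unit striatal
weight, averaged over states) every 50 trials.

**Choice of $c_{eff}$ for task simulations.** The efferent amplitude in
trial-based tasks is a free parameter of the model (1.5 is the
spontaneous-simulation value). We use $c_{eff} = 0.5$: the closed forms
above give a TD transient gap of $10 \cdot 2 \cdot 0.5 \cdot 0.01/0.25 =
0.4$ in logit$\times\beta$ units (p(correct) $\approx 0.14$, chance being
0.10) against a Q asymptote of $10 \cdot 1/3$ (p(correct)
$\approx 0.76$), which cleanly realizes the off- vs on-policy contrast the
model predicts. Any $c_{eff}$ in roughly $[0.2, 1]$ behaves equivalently;
the value was fixed from this analysis, before the acceptance runs.

## The firing-rate 2AFC model

Four neurons (dSPN and iSPN for each of two actions) follow

$$\tau \dot y_i = -y_i + \big[\textstyle\sum_j w_{ij} x_j + \eta_i(t) +
e_i(t) + b\big]_+$$

with bias $b = 5$ Hz, Ornstein–Uhlenbeck noise $\eta$ (time constant
600 ms, variance 1/60 Hz²), Euler step $dt = 20$ ms, Gaussian weight
initialization (sd 1 Hz), 2 s stimuli encoded one-hot. The membrane time
constant $\tau$ is not pinned down by the model description; we default to
100 ms — a standard rate-model scale, short enough that rates equilibrate
within the 1 s decision window — and expose it in
`rate_model_params()`. The action is the argmax of the per-action
difference modes averaged over the first second; in the second second the
chosen pair receives $e_i = 7.5$ Hz and the weights integrate
$\dot w_{ij} = \eta_{lr} f_i(\delta) (y_i - b) x_j$ with
$\eta_{lr} = 5\times10^{-4}$ ms⁻¹ and $f_i = +1$ for dSPNs after correct /
iSPNs after incorrect actions, $-1$ otherwise. Plasticity runs only during
the efference window, matching the description of learning in the second
half of the stimulus period.

The OU process uses the exact discretization
$x_{t+1} = \rho x_t + \sigma\sqrt{1-\rho^2}\,\xi$, $\rho = e^{-dt/\tau}$,
so the stationary variance equals 1/60 Hz² for any step size — a naive
Euler scheme would not satisfy this.

"Consistently correct" is operationalized as 10 consecutive correct
trials (the criterion count is configurable), and the trials-to-criterion
is the index of the trial on which the tenth consecutive correct choice
completes; runs that never reach criterion are reported as censored rather
than erroring. Stimuli are uniform random per trial. With these choices
the median over 21 seeds is about 11 trials: the efferent drive
($7.5$ Hz against a $5$ Hz bias) produces per-trial weight swings of
several Hz against an initial spread of ~1.4 Hz, so the policy locks in
within a few trials and the criterion completes roughly ten trials later.

## Spontaneous-behavior simulations

`run_spontaneous_session()` implements continuous action selection with no
rewards and no plasticity: $A = 50$ actions, each with a dSPN and an iSPN
whose feedforward input is an independent stationary Gaussian process with
kernel $e^{-|t_1-t_2|/10}$ (sampled exactly as an AR(1) process); action
selection every 10 timesteps from the previous timestep's activity at
$\beta = 100$; upon selection the chosen pair receives an efferent
transient of amplitude 1.5 decaying with time constant 10, transients
summing linearly; total activity is the rectified sum. The no-action
logit is calibrated by bisection (`calibrate_nogo_offset()`) so that no
action is chosen 50% of the time, to within 0.01.

The efference loop couples the pathways asymmetrically: an action is
chosen when its dSPN is high and its iSPN low, and both are excited
afterwards — so present dSPN activity predicts future iSPN activity more
than past. The package quantifies this with the lagged Pearson
cross-correlation of the two pathway totals (`cross_correlation()`;
mean-subtraction per lag) and the `asymmetry_index()` (mean over positive
lags minus mean over negative lags), with `max_lag = 20` timesteps, twice
the efference/GP time constants, the scale on which the model predicts
the skew to live.

**Statistical power.** A single $5\times10^4$-step session gives the
asymmetry estimator a standard deviation (~0.013) comparable to the effect
itself (~0.015–0.02), with occasional null draws beyond $\pm 0.02$ — one
session does not stably resolve the sign. The acceptance test therefore
pools twelve such sessions per arm (the recordings this analysis mirrors
likewise pool ~48 sessions per condition) and block-bootstraps over
within-session chunks, bringing the standard error to ~0.004. The
per-session length stays at $5\times10^4$ steps.

## Analysis conventions

All analyses operate on a `neural_session` (time × neuron activity,
pathway label per neuron, behavioral-syllable label per frame, explicit
instance table) and are identical for simulated and real sessions.

* **Z-scoring** per neuron across the session; zero-variance neurons are
  excluded with a warning.
* **Syllable inventory**: syllables with at least 5 instances.
* **Split halves** by parity of the instance's onset time rounded to the
  nearest second (frame 1 = time 0 at the 30 Hz nominal frame rate).
* **Activity change** of a neuron during an instance = mean activity
  during the instance minus the mean over an equal-length window
  immediately before onset (instances without a full pre-window are
  dropped). The pre-onset baseline makes the pre-onset portions of the
  onset-aligned traces interpretable; `baseline = "none"` (raw mean
  during the instance) is available as an alternative.
* **Syllable modes** are the least-squares coefficients of the activity
  changes on one-hot syllable identity, which for a one-hot design are
  the per-syllable means — computed in closed form and verified against
  `lm.fit` in the tests. Split-half reliability is the correlation of the
  vectorized mode matrices between halves, compared against a null built
  by permuting instance labels.
* **Time warping** maps every segment (instance or unlabeled gap) onto 10
  steps by linear interpolation, endpoints preserved; one-frame segments
  become constants.
* **Onset-aligned projections** are cross-validated: modes fit on one
  half, z-scored warped activity projected around the other half's onsets
  (associated vs all other syllables), both directions averaged, then
  averaged across syllables with the SEM taken across syllables. Modes
  are unit-normalized per pathway, which together with z-scoring makes
  the traces invariant to per-neuron rescaling of the raw data. The
  window spans two warped syllables on each side of onset.
* **Selectivity** of a nonnegative tuning vector $t$ over $A$ syllables is
  $(\frac1A\sum_i t_i)^2 / (\frac1A\sum_i t_i^2)$, with $0/0$ defined as
  0. The formula evaluates to 1 for uniform tuning and $1/A$ for one-hot
  tuning; it is implemented and tested exactly as that closed form, and
  the caller chooses $|a_i|$ or $\max(a_i, 0)$ as the tuning measure.

## Dopamine-transition models

From a syllable sequence and per-syllable dopamine values (the analog of
per-syllable dLight maxima z-scored per session),
`compute_transition_tables()` builds the conditional mean-dopamine table
$D(s_{t-1}, s_t)$ and the empirical transition matrix $P$; cells never
observed are masked and excluded from all fitting losses and correlations.
Four models predict $P$ from $D$:

1. **Q-learning** (`fit_q_table()`): $\hat D = \max_{s'} Q(s_t, s') -
   Q(s_{t-1}, s_t)$, fit by gradient descent from a zero Q table
   (learning rate 0.1, up to $10^4$ iterations, gradient-norm tolerance
   $10^{-8}$), then $\hat P(s_{t-1},\cdot) \propto
   e^{\beta(s_{t-1}) Q(s_{t-1},\cdot)}$ with $\beta$ the reciprocal row
   standard deviation (fallback 1 with a warning for constant rows).
   Polyak momentum (0.9) is used because the max-coupled objective is
   piecewise quadratic and plain gradient steps stall in shallow basins
   with ~1% residual error even on noiseless data. The $D \to Q$ map has
   a per-row additive gauge freedom; the fit selects whichever gauge
   descent reaches from zero, and the softmax predictions are invariant
   to it, so no uniqueness is claimed.
2. **State-value TD** (`fit_v_model()`): $\hat D = V(s_t) - V(s_{t-1})$ by
   least squares (gauge fixed by $V_1 = 0$); every predicted row is
   $\propto e^{\beta V}$, independent of the previous syllable.
3. **Action value** (`predict_p_action_value()`): rows of $D$ normalized
   by their sums, exactly as written. After z-scoring $D$ has negative
   entries, which break this normalization's interpretation as a
   probability; the computation is performed as defined, with a warning,
   rather than silently shifting the baseline.
4. **State value** (`predict_p_state_value()`): the count-weighted
   marginal $\bar D(s_t)$ normalized, identical across rows; same
   negative-entry policy.

`compare_models()` scores each model by the Pearson correlation between
predicted and observed transition probabilities over observed cells
(zero-variance predictions score 0 with a warning). On sessions generated
by inverting the Q-learning model (`generate_dlight_session()`, sampling
inverse temperature 1 so the generating and fitted temperature scales
agree, dopamine noise sd 0.1 before z-scoring), the Q-learning model wins
essentially every comparison; this is a parameter-recovery check, not
evidence about real data.

## Synthetic data: what it shows and what it does not

`generate_neural_session()` plants the efference model's signatures with
known ground truth: a pre-onset ramp along each syllable's dSPN mode
(positive) and iSPN mode (negative) — the difference-mode lead-up — and a
within-syllable drive along both modes — the sum-mode transient — on top
of white noise, over a first-order Markov syllable sequence with
geometric durations (~400 ms at 30 Hz, self-transitions forbidden by
default). The planted ramp amplitude (1.5 peak against the 1.0
within-syllable drive) is set so the pre-onset signature survives the
baseline shift that session-wide z-scoring introduces (mean removal
subtracts about $1/S$ of the drive from every projection). The `null`
setting zeroes all structure and is the negative control.

These generators emulate the *statistical shape* the analyses assume —
pathway labels, syllable segmentation, mode structure, dopamine-transition
coupling. They deliberately do not model calcium-indicator kinetics,
bleaching, movement artifacts, kinematic similarity between syllables, or
correlated noise across neurons. Passing the pipeline on synthetic
sessions establishes that the analysis recovers planted structure and
stays silent on structureless noise; it does not establish anything about
the biological claims beyond what the model simulations themselves show.

## Problem sizes used by the test suite

The packaged tests run the study-scale conditions where those are minutes
or less on one CPU: 500-trial / 20-seed learning contrasts, 1000-trial /
10-seed shared-control runs, 21-seed rate-model horizons, twelve
$5\times10^4$-step spontaneous sessions per cross-correlation arm, one
$5\times10^4$-step session for the mode analyses, and fifty
$10^4$-transition dopamine sessions ($S = 20$). Unit tests use miniature
versions of the same objects.

## Known limitations

* Single-neuron action coding (one dSPN/iSPN pair per action); the
  distributed-mode generalization is architecturally straightforward but
  not exercised here.
* No lateral inhibition, thalamo-cortical loops, spiking dynamics, or
  inter-trial temporal credit assignment; each tabular trial is
  self-contained.
* The offset-sigmoid rule's nonzero baseline (above) causes slow drift
  under prolonged baseline dopamine.
* The canonical/efference contrast is evaluated under the stated
  protocols; reward magnitudes beyond ±1 and mixed protocols are
  configurable but not characterized.
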