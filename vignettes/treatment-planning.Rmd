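---
title: "Multi-task reinforcement-learning treatment planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task reinforcement-learning treatment planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Combined orthodontic-orthognathic therapy corrects severe dentofacial
deformities through an interleaved sequence of orthodontic mechanics and
jaw surgery. Planning such treatment means trading off four objectives —
functional improvement (occlusion, TMJ, breathing), facial aesthetics,
treatment efficiency, and post-treatment stability — over a horizon of
roughly two years. `orthoplanr` frames this as a multi-objective Markov
decision process (MDP) and learns a planning policy with a multi-task soft
actor-critic (SAC) agent, then explains the learned policy with feature
attribution, rule surrogates, counterfactuals and trajectory narratives.

Because no clinical dataset ships with the package, all experiments run on
a synthetic cohort whose marginal statistics match the published
demographics of an adult orthognathic population (age 22.7 y mean on
18-35, 57.1% female, Class II/III at 40.9/53.9%, asymmetry 38.0%, vertical
discrepancy 27.4%, class-conditional ANB of 5.9 +/- 1.8 and -2.8 +/- 2.1
degrees, 26.3 +/- 6.7 months of treatment).

## The MDP

**State.** `patient_state` has five blocks: skeletal (68 landmark triples
in a head-centered mm frame with sagittal = +anterior and vertical =
+superior; SNA/SNB/ANB; occlusal class), dental (28 teeth with position
and tip/torque/rotation; arch width/length), soft tissue (64-point
thickness map, lip competence, nasal breathing, facial harmony on 0-10),
functional (occlusal function, TMJ health, respiratory, each on 0-1) and
treatment status (phase 1-4, relapse risk, bone density, tissue
adaptation on 0-1, elapsed months). `state_measurements()` exposes the
standard 137-measurement summary (45 skeletal + 52 dental + 40 soft
tissue); names beyond the anatomically standard ones are documented
placeholders since only the group counts are standardized.

**Action.** One hybrid action aggregates all four task families per step:
jaw movement (sagittal +/-15, vertical +/-10, transverse +/-8 mm), force
system (50-300 g, unit 3D direction, appliance choice), soft-tissue
technique and timing, phase decision (proceed/hold/modify) and visit
interval (4-8 weeks). We chose the aggregate-action reading over
alternating task-specific steps because a real treatment visit sets all
of these simultaneously; the `action_space_spec()` descriptor still
exposes the per-task bounds individually. A force magnitude of 0 encodes
"no active appliance", distinct from the 50-300 g active range.

**Reward.** Four components in [0, 1] (`reward_components()`):
improvement-based functional and aesthetic terms (per-step functional
improvement is normalized by a 0.10 reference scale; aesthetics by the
full 0-10 harmony scale plus a 0.5-weighted profile-balance term, so a
full-scale harmony gain alone saturates the reward), an efficiency term
`1 - 0.3*dt/dt_max - 0.7*dt_min/dt` balancing chair time against
appointment burden, and a stability term `(1 - relapse) * (0.5 +
0.5*adaptation)`. Scalarization is a simplex-weighted sum; the default
weights are the AHP-derived quality-score weights (0.30, 0.25, 0.25,
0.20).

## The transition model

No transition dynamics are standardized for this problem, so the
environment implements the simplest model honoring the known qualitative
behavior, with every coefficient exposed in `env_config()`:

* **Saturating surgical response.** A commanded per-axis displacement `d`
  produces `u0 * (1 - exp(-|d|/u0))` mm of effective movement (`u0` = 8 mm
  default), so two staged 5 mm moves achieve more than one 10 mm move.
  Effective sagittal movement changes ANB at 0.5 deg/mm; corrective change
  saturates at the ideal ANB (2 deg) — the model does not overshoot the
  target, while movement away from it is unattenuated. This makes repeated
  maximal correction monotone up to the target, which the tests assert.
* **Force-driven alignment.** Dental angulations decay toward alignment at
  a rate proportional to `1 - exp(-F/150 g)` (diminishing returns),
  modulated by appliance efficiency and force-direction quality; forces
  above 250 g progressively stress the TMJ.
* **Potential-coupled soft tissue and function.** Functional scores and
  facial harmony move by a configured fraction (0.9 and 0.8) of the change
  in morphology-implied potentials (functions of the ANB gap and dental
  misalignment). Because they respond to potential *changes*, a null
  intervention leaves all morphology exactly fixed — only elapsed time and
  the healing indicators advance.
* **Healing.** Relapse risk rises with per-step movement magnitude and
  decays with tissue adaptation; adaptation and bone density recover with
  quiescent time. A `proceed` decision advances the phase only through
  stability gates (relapse < 0.40, bone density > 0.50); completing phase
  4 ends the episode, as does the 26.3-month horizon.

Steps add seeded Gaussian noise per block (defaults: 0.05 deg on ANB, 0.2
deg dental, 0.05 harmony, 0.01 functional/status); zero noise gives the
deterministic core exactly.

## The synthetic cohort and what it does not emulate

Ages are sampled by rejection from a truncated normal whose *underlying*
parameters are moment-matched so the truncated distribution attains the
configured mean. One finding from that calibration: on [18, 35] no
truncated normal reaches sd 4.3 at mean 22.7 (the attainable supremum is
about 3.95), so the generator matches the mean exactly and comes as close
as the family allows on the sd; the attained value is stored in
`cohort_config()$age_sd_attained`. Sagittal classes are drawn as one
mutually exclusive pair (renormalized from 40.9/53.9) because Class II and
III cannot co-occur, while asymmetry and vertical discrepancy are
independent labels. ANB is drawn from the class-conditional normals.

The generator reproduces marginal statistics only. It does not emulate
correlations among the 137 measurements beyond class-conditional signs,
imaging-derived measurement error, growth (the population is adult by
design), or site effects. Tests that pass on this cohort therefore
validate the algorithms, not clinical performance on real cases.

## The planner

The agent is a SAC variant for hybrid actions and vector rewards:

* **Shared/task-specific encoders.** Critics map (state features, encoded
  action) through a shared trunk (64 units) into four task heads (32
  units each), one per reward component — the
  `[h_shared, h_task_specific]` decomposition. `q_vector()` returns the
  element-wise minimum of twin critics (clipped double-Q), one value per
  task; `scalarize()` collapses it with the task weights.
* **Policy.** A two-layer trunk feeds a squashed-Gaussian head for the 8
  continuous dimensions (tanh units mapped onto the physical bounds) and
  four categorical heads. Log-probabilities are reported in normalized
  tanh units.
* **Actor loss with soft categorical relaxation.** The actor minimizes
  `alpha * log pi(a|s) - sum_i w_i minQ_i(s, a)` with reparameterized
  continuous actions; for the categorical parts the critic is evaluated at
  the probability vector instead of a sampled one-hot, giving exact,
  deterministic gradients without Gumbel sampling or likelihood-ratio
  estimators. On purely discrete, enumerable action spaces (the toy MDPs)
  both actor and critic targets use exact expectations over all actions —
  standard discrete SAC.
* **Critic targets.** Per task `i`:
  `y_i = r_i + gamma * (1-done) * (minQ'_i(s',a') - alpha * log pi(a'|s'))`;
  since the weights sum to one, the scalarized target is the usual SAC
  target. Time-limit truncations keep bootstrapping (stored as not-done)
  so learned values estimate the discounted infinite-horizon objective
  that value iteration computes on the toy problems.
* **Temperature.** Auto-tuned toward a target entropy of `-n_cont + 0.35 *
  sum(log |C_g|)` in normalized units, or fixed via `fixed_alpha` (the toy
  MDP tests fix 0.01-0.02 so the soft optimum stays within the value-
  iteration tolerance).
* **Defaults.** gamma 0.99, Adam 3e-4, batch 256, replay 1e5, soft update
  tau 0.005, warmup 1000 uniform steps. None of these are published
  values; all live in `train_config()`. Bit-exact reproducibility is
  promised for serial CPU execution under a fixed seed (all networks,
  exploration and environment noise draw from R's RNG).

The networks, backpropagation and Adam are implemented in the package
(R/nn.R): plain dense layers with ReLU, explicit gradients for the
squashed-Gaussian and softmax heads, and a fused Adam traversal. This
keeps the training loop dependency-free and fast enough that the scaled
study below runs on one CPU.

### Problem sizes used by the shipped tests

The test suite and the acceptance script use a scaled-down study: cohort
50, 50,000 environment steps with one gradient update (batch 128) every 4
steps, 100 seeded evaluation episodes against the uniform-random baseline,
and a 3-point efficiency-weight sweep at 12,000 steps per setting. Toy-MDP
cross-checks use 2-8 states and 2-3 actions with a few thousand exact
discrete-SAC updates. These sizes were chosen so the full suite runs on a
single CPU in well under half an hour while leaving wide statistical
margins (the trained-vs-random comparison passes at p < 1e-30).

## Explainability

* `feature_attribution()` implements Shapley-value sampling over feature
  orderings. Each permutation's marginal contributions telescope to
  `f(x) - f(baseline)`, so the estimator is complete by construction; the
  floating-point residual is redistributed equally (documented, < 1e-6 in
  tests). Additive models are recovered exactly. `integrated_gradients()`
  offers the path-integral alternative (straight path, 64 points,
  central differences); `attribution_by_block()` aggregates scores by
  anatomical block — the package's rendering of attention-style region
  maps, since there is no imaging front end.
* `fit_surrogate()` distills a discrete action component into a
  depth-bounded CART tree (rpart) and reports fidelity on a held-out
  sample only. Constant policies yield a flagged one-leaf surrogate.
* `counterfactual_search()` minimizes weighted L1 distance plus a sparsity
  penalty subject to an output-threshold predicate and clinical box
  bounds, by projected coordinate descent over per-feature candidate
  grids with multi-start (original state, best single-feature edits,
  random feasible points). Immutable features (demographics) are masked
  out. On discretized 3-feature problems the returned distance is within
  5% of exhaustive search; infeasibility is reported as a result, not an
  exception.
* `explain_trajectory()` segments an episode by treatment phase, labels
  each segment with the weighted-dominant reward component and attaches
  per-transition reward deltas; `render_report()` renders any explanation
  at specialist (numeric tables) or interdisciplinary (ranked qualitative
  statements) level from fixed templates, with identical feature rankings
  across audiences.

## Evaluation metrics

`accuracy_at()` computes `1 - (1/m) sum |yhat - y| / |y|`; a zero actual
raises an error naming the outcome rather than smoothing the denominator,
because the quantity is undefined there. `efficiency_index()` is
`Q_outcome / (dT * C_resources)` with a dimensionless `C_resources = 1`
default. `confidence_score()` is the weighted sum of explainability,
evidence strength and consensus alignment with equal default weights; by
package convention explainability can be taken from surrogate fidelity.
`compute_tpqs()` maps the four 0-25 point quality components onto the
published 0-100 scale as `4 * sum(w_i Q_i)` — the factor 4 reconciles the
0-25 component scales, weights summing to one, and the 0-100 reporting
scale without altering any relative comparison. `tpqs_input_from_state()`
is the computed-outcome convention for simulated episodes; externally
rated components are accepted anywhere a `TPQSInput` vector is.

`partition_chronological()` sorts by the enrollment key and rounds
train/validation sizes to nearest with the test split absorbing the
remainder (347 cases at 70/15/15 gives 243/52/52). `compare_policies()`
evaluates policies on a shared seeded episode set and tests paired
differences with a sign-flip permutation test (999 permutations,
Bonferroni-corrected across the two reported metrics); permutation tests
were preferred over paired t-tests as the default because episode returns
are not plausibly normal at small n, but `test = "t"` restores the
classical variant.

## Numerical choices and degenerate inputs

Reported percentages round half away from zero to one decimal. Weight
simplexes are validated to 1e-9. The truncated-normal calibration demands
at least 1% acceptance mass so rejection sampling stays practical. The
squashed-Gaussian log-density adds 1e-6 inside `log(1 - tanh^2)`;
log-std outputs are clamped to [-5, 2] with gradient masking at the clamp.
Empty cohorts, zero-length trajectories, constant-policy surrogates,
already-satisfied counterfactual targets and finished episodes all have
defined behavior (empty result, error, flagged one-leaf tree, zero-delta
counterfactual, usage error respectively).

## Known limitations

The transition model is a first-order proxy, not tissue mechanics: no
finite-element biomechanics, no TMJ dynamics, no growth. Clinical
headline numbers from the motivating study (composite plan-quality on
real cases, expert agreement) depend on a private dataset and human
raters and are out of scope here; the package reproduces the printed
comparative arithmetic and validates its algorithms on synthetic data and
enumerable oracles instead. The confidence score's evidence-strength and
consensus-alignment sub-scores are package conventions awaiting real
calibration data.
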