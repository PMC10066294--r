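---
title: "Model-based reinforcement learning for response-adaptive radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based reinforcement learning for response-adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbrart)
```

## The decision problem

In knowledge-based response-adaptive radiotherapy (KBR-ART) a patient's
course is split into an evaluation phase and an adaptation phase. After
`N_eval` of `N_adapt` daily fractions, the response to treatment is assessed
from pre- and mid-treatment multi-omics measurements, and the daily dose for
the remaining fractions may be adapted. The clinical question — *which daily
dose maximizes the probability of tumor control (TCP) while keeping the
probability of a normal-tissue complication (NTCP) low?* — is formalized
here as a one-step Markov decision process:

* the **state** `(s, c)` is the pair of time-varying dosimetric variables
  `s` (tumor gEUD and organ-at-risk gEUD, in Gy) plus a vector `c` of fixed
  multi-omics covariates (clinical, cytokine, imaging, SNP, miRNA values,
  pre-encoded numerically);
* the **action** is the adaptive daily dose `d_adapt` on a discrete grid
  (1.5–4 Gy/fraction in 0.1 steps for the conventionally fractionated lung
  setting; 1–15 Gy/fraction in 0.5 steps for liver SBRT);
* the **episode ends** with the adaptation decision, so the optimal
  q-value of an action equals its immediate reward.

Only two state variables evolve with dose; all other features are treated as
frozen covariates measured by the clinic, not modelled quantities.

## The artificial treatment environment

The environment the decision maker plans against has three parts.

**Transition function.** Per-fraction gEUD accrual is assumed proportional
to a linear-quadratic-linear (LQL) dose effect: quadratic in dose per
fraction `d` below a tissue threshold `D_T`, linear above, which keeps the
model valid from conventional 2 Gy fractions up to SBRT-scale doses:

$$E(d) = \begin{cases} d\,(1 + d/(\alpha/\beta)) & d < D_T \\
D_T + \dfrac{D_T^2}{\alpha/\beta}\,(d - D_T) & \text{otherwise.}\end{cases}$$

Writing the same proportionality for the evaluation phase and the adaptation
phase and dividing, the constant cancels and the end-of-treatment gEUD is

$$g_{adapt} = g_{eval} + (N_{adapt}-N_{eval})\,
\frac{g_{eval}-g_0}{N_{eval}-N_0}\,\frac{E(d_{adapt})}{E(d_{eval})}.$$

The supra-threshold branch as displayed above has a downward jump at
`d = D_T` (the quadratic branch approaches `D_T(1+D_T/(\alpha/\beta))`, the
linear branch starts at `D_T`). Whether that jump is intended or a
typographical artifact of the LQL form is genuinely unclear, so both
readings are implemented: `mode = "as_written"` reproduces the displayed
equation verbatim, and `mode = "continuous"` (the default, and the form used
in policy training) continues the quadratic branch with its tangent slope
`1 + 2 D_T/(\alpha/\beta)`, making `E` continuous and strictly increasing.
Neither reading is asserted as "correct"; the test suite pins the jump to
`d = D_T` in the verbatim mode and continuity in the default mode.
`\alpha/\beta` and `D_T` must always be set explicitly in the disease
configuration; the shipped examples use the illustrative textbook values
`\alpha/\beta` = 10 Gy (tumor) and 3 Gy (OAR) with `D_T = 2\,\alpha/\beta`.

**Outcome estimators.** Outcome probabilities follow a two-parameter
generalized logistic in the tissue gEUD `g`,

$$p(g) = \frac{1}{1 + \exp\!\big(-(g - \mu(s,c))/T(s,c)\big)},$$

with patient-specific location `\mu` (Gy) and width `T` (Gy). As commonly
printed, the sign convention would make `p` *decrease* in `g` for positive
`T`; since the working assumption of the whole framework is that more
radiation raises both TCP and NTCP, the implementation fixes the orientation
(internal `|T|`, non-decreasing in `g`) and keeps the verbatim form behind a
flag for comparison only. `T` is floored at 0.5 Gy to prevent collapse to a
step function; the floor is a numerical safeguard, not a biological claim.

Two estimator architectures are provided. The **single GNN** treats outcome
prediction as graph-level binary classification: each patient is a directed
feature graph (nodes = the 13 selected features, edges = inter-feature
relationships taken as an input, e.g. from a prior Bayesian-network
analysis), message passing averages over in-neighbours, a global mean pool
feeds a linear classifier head. It carries no monotonicity guarantee, and on
noisy cohorts it can and does learn dose-response trends that go the wrong
way. The **GLoGD double GNN** fixes this: two single-GNN bodies emit
`\mu(s,c)` and (through a softplus with the 0.5 Gy floor) `T(s,c) > 0`, and
the gEUD enters only through the generalized logistic — so the predicted
dose-response is non-decreasing for *every* patient by construction, not by
regularization.

**Reward.** The base reward is `r = tcp (1 - ntcp)`, maximal at the only
clinically positive corner `(1, 0)` and zero at the three negative corners.
Disease goal tiers add bonuses on top: +2 for `tcp > 0.70, ntcp < 0.172`
then +1 for `tcp > 0.50, ntcp < 0.50` in the lung setting; the liver SBRT
default uses the relaxed single tier `tcp > 0.50, ntcp < 0.50` (+1), because
under severe class imbalance the fitted outcome curves rarely span the
probability range needed for the population-level `tcp > 0.90, ntcp < 0.25`
goal — that two-tier variant ships as `"hcc_population"`. Tiers are
evaluated top-down, first match wins, bonuses never stack, and all
inequalities are strict, read directly off the printed piecewise cascade.

## Network design choices

No deep-learning framework is assumed: all networks are small dense models
(tens of units) written in base R with explicit backpropagation and Adam,
which keeps training bit-reproducible under a seed.

Choices that were genuinely open and how they were resolved:

* **Node features.** A node's scalar value enters the first convolution
  layer as *value × one-hot node identity* plus the identity itself
  (diagonal placement). With plain scalar node features, weight sharing
  across nodes plus mean pooling makes the network an almost-symmetric
  function of the node values — it cannot learn *which* feature carries
  signal, and parameter recovery fails. Diagonal placement is the standard
  positional encoding for tabular graphs and restores node-specific
  sensitivities.
* **Convolution operator.** Mean aggregation over directed in-edges
  (`A[v,u] = 1/indeg(v)`); nodes without in-edges receive no message and
  rely on their self-connection.
* **Depth and width.** One convolution layer of width 32 is the default. A
  grid search on simulated cohorts of the target size (~70–500 patients)
  showed deeper stacks overfit before they help; width matters more than
  depth once node identities are available.
* **Optimization.** Minibatches of 64, AdamW-style decoupled weight decay
  0.2, and early stopping against a stratified 20% monitor split carved out
  *before* SMOTE (so no synthetic sample leaks into the monitor). The
  returned parameters are the average of the five checkpoints with the best
  monitor loss — checkpoint averaging along one trajectory smooths
  minibatch noise and buys a visible variance reduction at zero cost.
  Without the monitor, binary cross-entropy happily drives `T` to its floor
  (overconfident step-function curves); early stopping is what keeps the
  fitted widths near their true scale.

## Class imbalance

Cohorts in this setting are small and badly imbalanced (a liver SBRT cohort
may contain a single local-control failure). Two corrections are applied
jointly: SMOTE (k-nearest-neighbour convex combinations of minority rows,
balancing classes exactly) and inverse-frequency loss weights. SMOTE is
applied inside each cross-validation fold, never across folds. When the
minority class has fewer than two members SMOTE is impossible; training
falls back to weighting alone, and with a single-class cohort it refuses to
run, naming the class. Validation uses repeated stratified shuffle 80/20
splits; thresholds are chosen by Youden's J on the training scores and
applied to the validation fold.

## The decision maker

Training is model-based planning-then-learning. **Planning** queries the
environment exhaustively — every state with every grid dose — and stores
`(state, dose, next state, tcp, ntcp, reward)` tuples in a memory.
**Learning** runs double deep-Q-learning over the memory: the Q-network
(MLP, two hidden layers of 64, one output per grid dose) is updated toward
`r + \gamma\,Q_{target}(s', \arg\max_a Q_{online}(s', a))`. Because the
adaptation decision is terminal, the bootstrap term is masked to zero and
the update reduces exactly to regressing `q(s)[d]` on `r(s, d)` — the full
double-DQN machinery is retained but inert, which is also why a brute-force
argmax over the memory is a valid optimal-policy oracle. Greedy selection
breaks ties toward the lower dose (ALARA-style conservatism; nothing in the
problem statement fixes a tie rule). States are standardized with training
statistics; the covariates are part of the Q-network input.

A practical note on evaluating the learned policy: reward-versus-dose
profiles are nearly flat at their top for many patients (patients whose
outcome probabilities saturate across the whole grid have almost nothing to
choose between doses). Exact argmax agreement with the oracle is therefore
an ill-conditioned metric on fine grids — a q-fit error orders of magnitude
smaller than the reward scale is needed before exact agreement saturates —
whereas mean regret (oracle reward minus achieved reward) is well
conditioned and is the metric that reflects decision quality. The test
suite checks policy recovery on a smooth environment (goal tiers off; the
tier bonuses make the reward discontinuous in the state and no smooth
Q-network can fit the jump shell to argmax precision).

## Synthetic patients

Two generators serve different purposes.

The **ground-truth simulator** defines the study conditions for all tests,
standing in for restricted clinical cohorts. Covariate marginals
(normal / lognormal / Bernoulli / categorical) are coupled by a Gaussian
copula; gEUD histories follow the fractionation schedule through per-patient
accrual factors (`g_eval = \kappa N_{eval} d_{eval}` with
`\kappa \in` 0.85–1.05 for tumor, 0.25–0.55 for the OAR — dose largely
forward-scattered into the tumor, a fraction absorbed by the OAR); clinical
adaptive doses are drawn uniformly off the action grid; and outcomes are
Bernoulli draws from a known generalized logistic whose `\mu^*` and
`\log T^*` are linear in exactly two continuous biomarkers. Intercepts were
calibrated once, at large n, so the declared prevalences hold: tumor control
~0.7 and complications ~0.3 in the lung preset, and the severe-imbalance
liver preset reproducing, at n = 71, about 1 expected control failure and 7
expected complication events. Each simulated cohort carries a sealed truth
attribute (per-patient `\mu^*, T^*`, true probability curves over the grid)
for oracle tests. What the simulator does *not* emulate: batch effects in
biomarker assays, missingness patterns, measurement error in gEUD, multiple
organs at risk, or non-logistic dose-response shapes — so passing tests
demonstrate correct mechanics and recoverability under the stated model,
not clinical validity.

The **WGAN-GP** learns the joint feature distribution of a cohort to
enlarge the state pool for policy training (10,000 synthetic patients at
study scale, 4,000 resampled with replacement per ensemble member).
Hyperparameters follow the standard recipe: gradient penalty
`\lambda = 10`, 5 critic steps per generator step, latent dimension 16,
Adam with `\beta_1 = 0.5, \beta_2 = 0.9`. The parameter gradient of the
penalty `\lambda(\lVert\nabla_x f\rVert - 1)^2` needs second-order
differentiation; it is computed with a reverse-over-forward identity — the
norm's derivative equals the derivative of the directional derivative along
the (fixed) unit input-gradient direction, evaluated by a central difference
of two extra forward/backward passes (`\varepsilon = 10^{-4}`). Categorical
features are relaxed to continuous during training and snapped to the
nearest observed code at sampling time. Synthetic patients carry features
only; outcomes are never GAN-generated, since a conditional generator cannot
be learned from a tiny, imbalanced cohort. Generator quality is reported as
per-feature Jensen-Shannon divergence on 20 shared equal-width bins over the
pooled range, log base 2 (forced by the stated 0-to-1 range); no hypothesis
test is attached to the comparison — planning only needs a sensible cover
of the state space, and a uniform distribution would in principle do.

## Uncertainty and evaluation

Five structurally identical members (outcome-estimator pair + decision
maker) are trained with distinct seeds; member spread is the uncertainty
estimate — standard deviation / standard error of the mean for dose
recommendations, a 2×2 covariance for `(tcp, ntcp)`. Member diversity comes
from the member seeds (initialization, minibatch order, resampled planning
states), stated explicitly rather than left to incidental nondeterminism.

Against retrospective clinical decisions two metrics are computed. The
**RMSD** between recommended and clinical doses is reported per member and
summarized as mean ± sem (the RMSD of the ensemble-mean recommendation is
reported alongside), overall and split by clinically positive
(`TC=1, NTC=0`) versus negative outcome; the split matters because RMSD is
symmetric and cannot distinguish recommending more dose from recommending
less. The **self-evaluation scheme** labels the ensemble-mean
recommendation `Al` against the clinical dose `Cl` given the observed
outcome: for the positive outcome, Good if `|Al - Cl| \le 10\%` of `D_max`,
otherwise NotSure; with no control and no toxicity, a strictly higher dose
is Good, else Bad; with toxicity (with or without control), a strictly
lower dose is Good, else Bad. Ties sit on the Bad side, reading the printed
non-strict inequalities verbatim. The identity
`RMSD^2_{overall}\, n = RMSD^2_{pos}\, n_{pos} + RMSD^2_{neg}\, n_{neg}`
holds exactly and is asserted in the tests.

## Problem sizes used by the test suite

The suite runs everything at sizes chosen to exercise the full machinery on
a single CPU: 120- and 500-patient simulated cohorts for estimator tests,
3-fold shuffle validation in unit tests (10 folds remain the analysis
default), 5-member ensembles at 400 training epochs for recovery checks, a
200-state exhaustive memory (26-dose grid) for policy recovery plus a
4,000-state variant in the acceptance script, 250–600 generator steps for
GAN checks, and a smoke pipeline profile (80 patients, 500 synthetic states,
2 members) for the end-to-end rerun-reproducibility check. The full-scale
profile (10,000 synthetic patients, 4,000 per member, 5 members, 10-fold
validation) is the default of `run_config(profile = "full")`.

## Known limitations

Single OAR per disease; dose-per-fraction adaptation only (no fraction-count
adaptation); no multi-step re-planning; the feature graph is an input, not
learned; calibration of predicted probabilities is not post-processed; the
GNNs are small dense models and inherit the usual small-cohort caveats —
uncertainty from the 5-member ensemble underestimates structural model
uncertainty.
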