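---
title: "The dyadic mimicry model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dyadic mimicry model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadmimicry)
```

## The model

Two agents share a one-dimensional, effectively infinite axis. Each agent
is present twice: a receptor field (RF) through which it senses, and a
body-object (BO) which is what the other agent can sense. The two are
joined by a rigid link of signed allocentric length $D$ (BO center = RF
center + $D$). Sensing is all-or-nothing: an agent's input is 1 on any step
where its RF center lies within 0.5 space units (inclusive) of the other's
BO center, else 0. All objects have unit extent. Because the agents face
each other, agent 2's egocentric motor commands are applied with sign $-1$.

The dyad's *body offset* $D_1 + D_2$ is the model's notion of bodily
mismatch: 0 means the configurations are complementary (mimicry), and a
brute-force scan over relative positions (`mutual_contact_achievable()`)
certifies that simultaneous mutual contact is possible exactly for offsets
in $[-1, 1]$ under this contact rule.

Each agent is controlled by a clone of one continuous-time recurrent
neural network of $N = 8$ neurons,
$$\tau_i \dot s_i = -s_i + \sum_j w_{ji}\,\sigma(g_j(s_j + \theta_j)) + I_i,
\qquad \sigma(x) = \frac{1}{1 + e^{-x}},$$
with output gains $g_j$ fixed at 1, integrated by explicit Euler steps of
size $h$; one "time step" everywhere in the package is one Euler update.
Neuron roles are positional: neuron 1 receives the contact bit scaled by a
receptor gain $r$; neuron 2's output is mapped from $[0,1]$ to $[-1,1]$ and
scaled by the effector gain $e_{\mathrm{move}}$ to give the egocentric
velocity; neurons 3 and 4 drive the left and right buttons. A button turns
on when its neuron's output reaches 0.75 and off below, and only the
off-to-on transition emits a click; the hysteresis separates the fast
timescale of movement from the slow, discrete timescale of link adjustment.
Each click shifts the agent's BO egocentrically left or right by the
corresponding effector gain ($e_{\mathrm{left}}$, $e_{\mathrm{right}}$).

The trial loop is synchronous and sense-then-act with one-step-delayed
positions: both agents sense on the previous step's geometry (for step 1,
the initial geometry, before any network update), both networks advance one
Euler step, then both motions and clicks are applied. This symmetric
ordering avoids privileging either agent; an update-as-you-go scheme would
make agent 1's step-$t$ motion visible to agent 2 within the same step.

## Trial protocol (the study conditions)

`trial_config()` encodes the protocol: RF positions start at $+10$ and
$-10$, links at $D_1 = -20$, $D_2 = +20$ (so each RF sits exactly on the
other's BO with offset 0), agent 1's RF position and link length are each
perturbed once per trial by independent draws from
$\mathcal U(-1.5, 1.5)$, neuron states start at 0, and trials run 3000
steps at $h = 0.1$ by default. Movement noise is Gaussian, mean 0, sd 0.05,
drawn once per agent per step and added to the mapped motor output *before*
the $e_{\mathrm{move}}$ gain — noise on the neuron's output channel, which
is how "noise applied to the movement neuron" reads mechanistically; an
alternative reading (noise after the gain) would decouple the noise
magnitude from the evolved gain.

These defaults are the conditions under which everything else in the
package is measured, and the tests use them as-is. What the generator
emulates is the minimal dyadic task; what it deliberately does not model:
human reaction delays, arm inertia, imperfect position sensing, or any
within-trial learning. Passing tests therefore show that the *mechanism*
(interaction-mediated offset correction) works in this idealized setting,
not that human dyads implement it.

## Fitness and the genetic algorithm

A genotype is 84 genes on $[0,1]$: 64 weights (decoded affinely to
$[-8, 8]$), 8 biases ($[-8, 8]$), 8 time constants ($[1, 30]$), the
receptor gain ($[0, 10]$) and three effector gains ($[0, 1]$). Evaluation
runs perturbed trials and scores each one
$$F = \tfrac12 C + \tfrac12 M, \qquad
C = \text{contact fraction (either flag) over the last half}, \qquad
M = \max\!\big(0,\, 1 - \overline{|D_1 + D_2|} / 1.5\big),$$
with $M$ also taken over the last half of the trial. The windows are
genuinely open design territory. Scoring the offset only near the end of a
trial turned out to rank never-clicking contact-keepers above controllers
that actually correct the offset — selection could not see *when* matching
was achieved. Scoring the whole second half rewards matching early and
holding it, which is the behavior the model exists to produce. The 1.5
normalizer is the largest initial offset of the protocol, so $M$ spans its
full range exactly over the initialization distribution.

The GA is generational: elitism (1), tournament selection (size 3), uniform
crossover (rate 0.5), and per-gene Gaussian creep mutation (sd 0.05)
reflected at the gene bounds; an optional per-gene uniform reset mutation
exists but defaults off (it measurably changed nothing on this task).
Per-trial seeds are shared by the whole population within a generation
(fair comparisons) and resampled across generations (no overfitting to one
set of initial conditions); `fixed_eval_seeds = TRUE` freezes them, in
which case elitism makes the best-of-generation series non-decreasing — a
property the tests check.

The run's champion is *not* simply the last generation's best: with few,
noisy evaluation trials that choice discards good lineages on a bad draw
(observed directly during development). Instead every distinct
per-generation leader is re-evaluated on 15 fresh trials of 3000 steps —
the full evaluation protocol — and the argmax is returned
(`champion_trials`, `champion_steps`).

Evolution at the scaled budget used by the tests (population 32, 60
generations, 5 trials of 1500 steps) is stochastic: in our measurements
roughly 1–2 runs in 12 produce a champion that pulls all seven sweep trials
into the mutual-contact window. The test protocol therefore tries three
evolution seeds and requires one success, and logs the fitness curves of
failures. Larger budgets help (about 1 in 3 at 150 generations).

## Analysis metrics

* **Sweep** (`run_sweep()`): one trial per initial offset in
  $\{-1.5, -1, \dots, 1.5\}$, RF perturbation disabled;
  `sweep_convergence()` reports entry into and residence in $[-1, 1]$.
* **Link diversity** (`link_diversity()`): per-step standard deviation of
  the pooled set $\{D_1^{(k)}\} \cup \{-D_2^{(k)}\}$ over trials $k$ — the
  sign alignment makes the two agents' links commensurable under mimicry —
  with an OLS trend over steps. The sd is taken across trials at each step,
  not over time within trials; the pooled-trajectory reading is the one
  consistent with computing a trend *over* time.
* **Roles** (`role_latency()`): first-click step per agent; roles are
  divided when exactly one agent clicks within the first 500 steps
  (order-of-magnitude of the model's event timeline) or first clicks are
  more than that window apart; simultaneous first clicks are a tie, not a
  division.
* **Button usage** (`button_usage()`): exact event counts; a single-button
  flag marks the strategy in which every click lands on one side.
* **Interaction correlations** (`interaction_correlations()`):
  non-overlapping 200-step windows; drift is operationalized as the mean
  per-step velocity of the midpoint between RF1 and BO2 over the window's
  contact steps (the interaction locus; the verbal description of drift
  says nothing about how to measure it). Spearman correlations of
  mean $|$offset$|$ with contact frequency (expected negative) and with
  $|$drift$|$ (expected positive); zero-variance pools are flagged
  degenerate rather than erroring.
* **Synchrony** (`synchrony_index()`): sliding 200-step Pearson correlation
  between the mapped movement outputs, agent 2 mirrored; zero-variance
  windows give NA.

## Numerical choices

* Euler $h = 0.1$ for trials; the single-neuron closed form
  $s(t) = I(1 - e^{-t/\tau})$ bounds the integrator error in tests
  ($< 5\times10^{-3}$ at $h = 0.01$ over $t \in [0, 10]$, first-order
  convergence checked by halving $h$).
* Equilibria: 100 random starts from $[-10, 10]^n$, settle until
  $\lVert\dot s\rVert_\infty < 10^{-8}$ (budget $10^6$ steps), merge radius
  $10^{-4}$ in sup-norm, then Newton polish with the analytic Jacobian
  (falling back to the settled point if Newton leaves the basin). Reported
  equilibria carry their basin fractions and residuals; "no start
  converged" is a flag (limit cycle or slow dynamics), not an error.
* Closed-network analysis clamps neuron 1's input to the post-gain values
  $\{0, r\}$, the only two inputs the embodied network can ever receive.
* Both-buttons-in-one-step ordering is left before right (outcome-neutral
  for the offset when the step sizes are equal, fixed for determinism).
* Trials with non-finite states abort naming the step and neuron; during
  GA evaluation such trials score 0 with a warning.
* All randomness flows from user-supplied seeds; seeded code paths save
  and restore the caller's RNG state. GA checkpoints serialize genes as
  C99 hex-float strings so a resumed run is bit-identical to an
  uninterrupted one.

## Known limitations

* The headline evolutionary reproduction is a stochastic property at the
  scaled search budget (see above); a failed triple of seeds is a possible
  outcome of the protocol, not a simulator defect.
* Champions that solve the task by settling into *static* mimicry — zero
  residual clicking at offset 0 — show no long-run growth in link-distance
  diversity: with no clicks the links never move and the pooled sd stays
  at 0. Perpetual complementary adjustment is a property of some evolved
  solutions, not all; the diversity-growth experiment reports whatever the
  accepted champion actually does.
* The periodic (circular) world is provided for completeness but untested
  against any behavioral claims; the model's results all use the infinite
  line.
* Problem sizes used by the test suite — 60-generation searches,
  1500-step evaluation trials, 15000-step diversity runs — are the
  package's chosen study scales; behavior at much larger scales is
  unexplored here.
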