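---
title: "Models and methods in rlddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rlddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In probabilistic instrumental learning tasks that cross outcome valence
(reward vs punishment) with feedback information (partial vs complete), a
well-replicated behavioral pattern emerges: complete feedback makes people
both faster and more accurate, while punishment contexts make them *slower
without making them less accurate*. Choice-only reinforcement-learning
models cannot say anything about the second effect, because it lives
entirely in response times. `rlddm` implements the modelling toolchain
needed to decompose these effects: a diffusion decision model (DDM)
likelihood for joint choice/RT data, a context-dependent Q-learning model
whose latent variables drive the DDM parameters trial by trial, hierarchical
Bayesian estimation, and the simulation machinery to validate all of it.

# The task and its simulator

The task presents four fixed pairs of cues per session — one pair per cell
of the 2×2 design. In reward contexts the better cue gains one point with
probability 0.75 (else nothing) and the worse cue with probability 0.25; in
punishment contexts the better cue *loses* a point with probability 0.25
and the worse cue with probability 0.75. Under partial feedback only the
chosen cue's outcome is shown; under complete feedback both are. The four
experiment presets in `make_design()` use 2/3/3/2 sessions of 80/96/96/80
trials with response windows of 3/3/3/1.5 s.

`simulate_cohort()` generates cohorts of learning agents. For each trial
both cues' potential outcomes are realized i.i.d. from their Bernoulli
contingencies (both draws are needed for complete-feedback display and for
counterfactual updating; under partial feedback the unchosen draw exists
but is never shown). Choices and RTs are sampled from the DDM at the
trial's linked parameters; decisions slower than the response window are
recorded as non-responses and trigger no learning update. Cue-to-side
randomization is not simulated: responses are coded correct/incorrect
directly, which is also how the models treat them.

Default group-level generating distributions describe a realistic cohort
for this task: learning rates spread around 0.2 (logit-normal, SD 0.5 on
the logit scale), drift coefficient 1.2 ± 0.3, threshold intercept around
2 evidence units, threshold–conflict coefficient around 0.7, non-decision
time around 0.3 s, and a context-value coefficient of −0.35 ± 0.1 on the
log-NDT scale. These values sit in the middle of the ranges typically
reported for reinforcement-learning diffusion models on second-scale
tasks, and they reproduce the qualitative signatures the analysis targets:
rising accuracy across trials, a complete-feedback accuracy advantage, and
slower punishment-context responses with valence-matched accuracy.

What the generator deliberately does *not* emulate: inter-trial timing and
display events, sequential choice biases (perseveration), attentional
lapses, and any mismatch between the agent's learning rule and the fitted
model. Passing tests on synthetic cohorts therefore demonstrate that the
estimation machinery is correct and calibrated *under the model*, not that
the model is true of any particular dataset.

# The diffusion decision model

Evidence accumulates from $a/2$ (unbiased start) with drift $v$ and unit
noise until it hits $0$ (incorrect) or $a$ (correct); the response time
adds a non-decision component. The likelihood is the defective Wiener
first-passage-time density at the observed boundary and time. The density
is evaluated with the standard small-time/large-time series expansions,
switching regimes by comparing the number of terms each expansion needs at
a truncation tolerance of $10^{-7}$. With unbiased start and unit noise
the probability of a correct response has the closed form
$P(\text{upper}) = 1/(1+e^{-va})$, which the package uses both as a user
function and as an internal cross-check: the test suite verifies it
against the numerically integrated density and against brute-force
simulation.

`simulate_ddm()` is a plain Euler–Maruyama simulator and serves as the
package's *numerical oracle*: an implementation of the process definition
that shares no code with the series-expansion density. Its default step is
$10^{-3}$ s. Plain Euler biases first-passage times upward by
$O(\sqrt{dt})$ (paths can cross and return within a step), so wherever the
simulator is used to validate the *distribution* of passage times — the
Kolmogorov–Smirnov checks in the acceptance suite — it is run at
$dt = 5\times10^{-5}$ s, at which the residual discretization error is
comfortably below the 0.01 KS tolerance. Checks that only use absorption
*fractions* are insensitive to this bias and use the default step.

No across-trial variability parameters (sv, sz, st0) are included: the
model being implemented has none, and adding them would change the
meaning of the linked parameters.

# The learning rules

Each context $s$ carries option values $Q$ and a context value $V$, all
starting at zero. After a choice with outcome $R_c$ (and, under complete
feedback, forgone outcome $R_u$):

$$\delta_c = R_c - V - Q_c,\qquad Q_c \leftarrow Q_c + \alpha_c\,\delta_c$$

and under complete feedback additionally
$\delta_u = R_u - V - Q_u$, $Q_u \leftarrow Q_u + \alpha_u\,\delta_u$.
The context value is itself learned by a delta rule,
$V \leftarrow V + \alpha_V\,\delta_V$, with
$\delta_V = (R_c + R_u)/2 - V$ under complete feedback and
$\delta_V = (R_c + Q_u)/2 - V$ under partial feedback — the unseen forgone
outcome replaced by the unchosen option's current expectation. Both option
prediction errors use the *pre-trial* $V$ as reference. Because $V$
approximates the average outcome of its context, it trends positive in
reward contexts and negative in punishment contexts, and the $Q$ values
become context-*relative*; this is what lets the same learning mechanism
perform equally well at seeking gains and avoiding losses.

Three linking functions map the latent state, evaluated on the values held
*before* the trial's outcome (the decision precedes the feedback), to the
trial's DDM parameters:

* drift: $v_t = v_{\text{coeff}}\,\Delta Q_t$ with
  $\Delta Q_t = Q_{\text{cor}} - Q_{\text{inc}}$;
* threshold: $a_t = a_{\text{int}}\{1 + a_{\text{coeff}}
  [1/(|\Delta Q_t|+1) - 1]\}$, so the conflict term $1/(|\Delta Q_t|+1)$
  discounts the threshold as values separate, and
  $a_t \in [a_{\text{int}}(1-a_{\text{coeff}}),\,a_{\text{int}}]$ stays
  positive for $a_{\text{coeff}} \in [0,1]$;
* non-decision time: $NDT_t = \exp(NDT_{\text{int}} +
  NDT_{\text{coeff}} V_t)$, positive by construction. A negative
  $NDT_{\text{coeff}}$ produces the signature dissociation: punishment
  contexts (negative $V$) get slower responses with unchanged accuracy,
  because the NDT shifts the whole RT distribution without touching the
  accumulator.

Two choices here were genuinely open. First, values are reset to zero at
each session start (sessions introduce new cue symbols, so carried-over
values would be values of stimuli the participant has never seen); the
reset is configurable (`reset_per_session`). Second, the partial-feedback
substitution in $\delta_V$ uses the *unchosen option's expectation*
averaged with the *received* outcome, exactly as the update equations
specify; the surrounding verbal description of which quantity is "not
provided" is garbled in the source literature, but the equation itself is
unambiguous and is what the package implements.

# The factorial DDM

The second model ignores trial order and codes each trial's condition:
valence 0 = reward / 1 = punishment, feedback 0 = partial / 1 = complete,
interaction = product, so the intercept is the reward-partial cell. Each
DDM parameter gets an intercept and three slopes through a linear
predictor, with identity link for the drift and log links for threshold
and non-decision time. The log links guarantee positivity under
unconstrained hierarchical slopes; the cost is that reported effects for
$a$ and $NDT$ are on the log scale, which is stated in every summary.
The hierarchy has three levels — participants around experiment means,
experiment means around dataset means — collapsing to two levels when a
single experiment is fit.

# Estimation

Both hierarchical models are sampled by a blocked slice-within-Gibbs
scheme on unconstrained scales (learning rates and the threshold
coefficient via logit, threshold intercept and NDTs via log):

* participant-level parameters: stepping-out slice sampling — one update
  per coordinate plus several random-direction line updates per
  iteration, all in compiled code, with slice widths expressed in units
  of the current group SD so they track the funnel geometry. Slice
  updates never reject, which keeps per-coordinate autocorrelation far
  below that of random-walk proposals; the random directions pick up
  posterior correlation between coordinates that share a pathway (the
  threshold intercept and conflict coefficient trade off against each
  other, as do the context-value learning rate and the NDT slope);
* group means: conjugate normal Gibbs draws;
* group SDs: slice sampling on the log scale against half-normal(0, 1)
  priors (these conditionals involve only normal densities, so they are
  essentially free);
* and *ancillarity–sufficiency interweaving*: each iteration ends with
  non-centered moves that hold the standardized residuals
  $(\theta - \mu)/\sigma$ fixed while translating $\mu$ or rescaling
  $\sigma$, re-evaluating the data likelihood of every participant in the
  group. Without these moves the group-level chain inherits the slow
  drift of the participant cloud (the hierarchical funnel) and the
  convergence diagnostic stays visibly above 1.01 at desk-scale chain
  lengths.

This kernel was chosen by measuring integrated autocorrelation times of
the group-level means on simulated cohorts: plain random-walk
Metropolis-within-Gibbs left them at 10–35 (implying a split-chain
$\hat R$ of roughly 1.01–1.04 at 4 chains × 1000 retained draws),
whereas the slice/interweaving combination brings all eight
learning-model group means to 1–12. One caveat worth stating: at desk
scale (4 × 1000 retained draws) the $\hat R$ statistic itself is noisy —
with an autocorrelation time of ~8 its expected value sits near 1.004
and isolated coordinates can read 1.01–1.02 on some realizations even
when chain means agree to the second decimal. The full-scale convention
(4 × 10000) removes this; at desk scale an isolated marginal exceedance
on a group SD or a weakly identified coefficient warrants a look at the
traces rather than an automatic refit.

Priors for the learning-diffusion model (group means, unconstrained
scale): learning rates $N(-1, 1)$ on the logit scale, $v_{\text{coeff}}
\sim N(1, 2)$, $\log a_{\text{int}} \sim N(0, 2)$, logit
$a_{\text{coeff}} \sim N(0, 1)$, $NDT_{\text{int}} \sim N(\log 0.3,
0.5)$, $NDT_{\text{coeff}} \sim N(0, 1)$; factorial model: $N(0,2)$
intercepts and $N(0,1)$ slopes on the link scales; all SDs
half-normal(0, 1). These are weakly-informative defaults chosen for this
package (the original analysis's prior appendix is not reproduced here),
so credible-interval *widths* on real data may differ from previously
published ones even where locations agree; all priors are overridable.

Chains are initialized from dispersed draws near the prior center (with
the NDT intercept anchored below each participant's fastest response);
an initialization is re-drawn up to 100 times until its log density is
finite. Any parameter that implies $NDT_t \ge rt$ for some trial yields a
log-likelihood of $-\infty$ and is rejected by the sampler rather than
raising an error. By convention the first half of each chain is warmup and
discarded; convergence is gated at split-chain $\hat R < 1.01$.

The generic scalar engine (`mcmc_mwg()`) is validated against the
closed-form conjugate-normal posterior; the cell-means effect model runs
on it directly, with the participant random intercept marginalized
analytically (per-participant compound-symmetric Gaussian likelihood), so
only the effect coefficients and two SDs are sampled.

# Validation strategy and problem sizes

The package validates itself at sizes chosen to keep the default test run
in the tens of minutes on one core:

* density vs simulator: five parameter sets spanning $v \in \{-2,0,2\}$,
  $a \in \{1,2\}$, $NDT \in \{0.2,0.4\}$, $10^5$ Euler paths each at
  $dt = 5\times10^{-5}$, KS distance < 0.01 per boundary;
* normalization of the two defective densities to 1 within $10^{-4}$ on a
  $5\times4$ drift/threshold grid;
* exact substitution identities for the learning rules, and the inductive
  bounds $|V|\le 2$, $|Q|\le 3$ over $10^4$ random unit-outcome schedules;
* parameter recovery on a simulated 20-participant cohort with the
  two-session/80-trial design, fit with 4 chains × 2000 iterations (first
  half discarded): $\hat R < 1.01$ for all eight group-level means, at
  least 6/8 group-level 95% BCIs covering truth, and Spearman correlation
  > 0.4 between individual chosen-option learning-rate estimates and
  truth. The chosen-option rate is the gated one deliberately: with only
  ~40 complete-feedback trials per context pair at this size, the
  unchosen-option and context-value rates are weakly identified at the
  individual level (their correlations are reported, not gated) — a
  property of the design, not of the sampler;
* the valence dissociation, qualitatively, on a 30-participant cohort;
* calibration of the effect model: a known +0.05 feedback effect on
  accuracy recovered at the pooled sample size with a BCI excluding zero,
  and near-nominal BCI coverage of zero across 20 all-null replications.

Posterior predictive checks follow the same two summaries used for the
real analyses: mean accuracy and mean RT by context × trial-bin ×
experiment for the learning model, and RT quantiles
(0.1/0.3/0.5/0.7/0.9, split by correct/error) plus accuracy by context
for the factorial model. Because the observed data do not contain the
counterfactual outcome schedule, predictive replicates redraw schedules
from the design contingencies and simulate the full dataset forward.

# Known limitations

* Non-response (omitted) trials are excluded from all likelihoods; no
  censored contribution is modelled.
* The samplers are random-walk based: adequate at the package's desk
  scales, but full-scale fits (tens of thousands of iterations, ~90
  participants) are slow compared to gradient-based samplers.
* Individual-level $\alpha_u$ and $\alpha_V$ estimates shrink strongly to
  the group mean at typical per-participant trial counts.
* The effect model operates on participant×context means with Gaussian
  residuals; it does not model trial-level binomial variability in
  accuracy.
* Bayes-factor model comparison is out of scope; the package estimates
  effects under fixed model structures.
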