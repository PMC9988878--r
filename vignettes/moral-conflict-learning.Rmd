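---
title: "Modelling action-outcome learning under moral conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling action-outcome learning under moral conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The task and the scientific question

`moralbandit` models a two-armed bandit in which the two outcomes of a
choice pull in opposite moral directions. On every trial the decider picks
one of two symbols. In the **Conflict** condition one symbol (the
*lucrative* option) yields a high monetary gain for the decider with
probability 0.8 and, independently, a painful shock to another person with
probability 0.8; the other symbol (the *considerate* option) yields low
money and a non-painful shock with the same probabilities. In the
**NoConflict** condition the high-money symbol is also the low-shock
symbol, so self-interest and concern for the other coincide. Blocks last 10
learning trials; in *dropout* blocks a message then announces that one
outcome (money or shock) will no longer be delivered, and ten further
trials follow. The first post-announcement choice — trial 11, made before
any new outcome is seen — is the devaluation probe: it reveals what the
learner's stored expectations look like once one motive is switched off.

Outcomes are coded by value from the decider's moral frame:
high money $= +1$, low money $= -1$, painful (high) shock $= -1$,
non-painful (low) shock $= +1$, withheld $= 0$. The question the model
family answers is *where* an individual's preference between self-money
and other-shock enters the learning machinery.

# The model family

All learning models are Rescorla–Wagner learners with softmax choice.
Writing $wf \in [0,1]$ for the weighting factor (0 = fully considerate,
1 = fully lucrative), $\tau \in [0,5]$ for the softmax inverse temperature
and $LR$ for learning rates, the candidate models are, for the chosen
option:

* **M0** (random choice): utilities are always 0, every choice has
  probability $1/2$.
* **M1** (combined history): one expected value per symbol,
  $PE = [wf\,Out_M + (1-wf)\,Out_S] - EV$, $EV \leftarrow EV + LR \cdot PE$;
  decisions contrast $EV$ across symbols.
* **M2Out** (outcome-phase weighting): separate money and shock
  expectations, with outcomes scaled *before* learning:
  $PE_M = wf\,Out_M - EV_M$, $PE_S = (1-wf)\,Out_S - EV_S$, each updated
  with its own learning rate; the decision contrasts $EV_M + EV_S$.
* **M2Dec** (decision-phase weighting): unscaled learning
  ($PE_M = Out_M - EV_M$, $PE_S = Out_S - EV_S$) and a weighted decision
  value $wf\,EV_M + (1-wf)\,EV_S$.
* **M2DO** (distributed): a parameter $\alpha \in [0,1]$ splits the weight
  geometrically between phases — outcome multipliers $wf^{\alpha}$,
  $(1-wf)^{\alpha}$ and decision weights $wf^{1-\alpha}$,
  $(1-wf)^{1-\alpha}$. At $\alpha = 1$ this is exactly M2Out, at
  $\alpha = 0$ exactly M2Dec, and the product of the two multipliers
  always recovers the total weight. This functional form is this package's
  choice for "distributing" the preference across phases; other
  interpolations exist, but this one has the two exact limits and the
  weight-conservation property, and is the one our tests pin down.

Choice probabilities are the two-option softmax
$p(a) \propto \exp(\tau V_a)$, computed with max-subtraction. With
$\tau \le 5$ and $|V| \le 1$ the exponents are bounded anyway; the
stabilization is kept so the routine is safe for any utilities.

A useful identity: with equal learning rates the three learning models are
*choice-equivalent on conflict learning trials* — the multiplication by
$wf$ distributes over the prediction-error sum, so the utilities fed to
the softmax coincide exactly. The package's tests assert this to
$10^{-12}$. The models therefore only disagree where it matters: at the
devaluation probe.

## The devaluation transition

When a learner is told that, say, shocks are withdrawn, the M2 family
zeroes $EV_S$ for both symbols and decides on the remaining expectation
alone, unweighted (effective weight 1 when shocks are removed, 0 when
money is removed) — there is no conflict left to arbitrate. M1 has no
separable representation, so its combined expectation must stay untouched;
only the weight used to combine *future* outcomes changes. After the
transition the withheld outcome is coded 0, so its expectation stays at 0.

This is where M2Out earns its keep: because it scales outcomes by $wf$
*before* learning, a considerate learner ($wf \approx 0$) accumulates
$EV_M \approx 0$ for both symbols. Remove the shocks and the decision is
between two near-zero values — near-chance choice, which is what humans
do. M2Dec, whose money expectations are fully differentiated, predicts a
sharp reversal instead, and M1 predicts no change at all. A configuration
flag (`maintain_wf_at_dropout`, default off, honoured by the reference R
evaluator) implements the variant of M2Dec that keeps its weight at the
probe; it then mimics M2Out closely.

## EV initialization and update scope

Expected values start at 0, the symmetric no-information point given the
$\pm 1$ outcome coding. Only the chosen symbol is updated; the unchosen
symbol's expectations carry over unchanged, and no forgetting or decay
term is introduced. Trial indices are 1-based within a block and the
dropout transition fires before the 11th trial.

# Hierarchical inference

Each model is fitted to a cohort with a non-centered hierarchy per
parameter: group location $\mu \sim N(0,1)$, group scale
$\sigma \sim \text{half-}N(0, 0.2)$, subject offsets $z_i \sim N(0,1)$,
and the subject-level parameter $\Phi(\mu + \sigma z_i)$ (times 5 for
$\tau$). The probit pushforward keeps every draw inside its interval. The
half-Normal scale 0.2 follows common practice in hierarchical
decision-model packages; it is a configurable argument
(`sigma_prior_scale`), not a hidden constant.

Sampling is by an adaptive Metropolis-within-Gibbs sampler written in C++:
coordinate-wise random-walk updates of the subject offsets (two sweeps per
iteration), then repeated sub-sweeps over the group locations and
log-scales. Two *likelihood-invariant* moves are interleaved: a
translation $(\mu, z_i) \to (\mu + \epsilon,\, z_i - \epsilon/\sigma)$ and
a rescaling $(\log\sigma, z_i) \to (\log\sigma + \eta,\, z_i e^{-\eta})$.
Both leave every subject-level parameter — and hence the likelihood —
exactly unchanged, so they are accepted on the priors alone; they slide
the chain along the ridges that make non-centered hierarchies slow to mix
and are the main reason the sampler converges quickly. Proposal scales are
adapted in batches of 25 during warmup only (targets 0.44 for scalar
moves, 0.30 for the global ones), so the post-warmup chain is a fixed
Markov kernel.

Defaults are 4 chains × 1,000 retained draws (4,000 total, the draw count
used for all draw-wise statistics) with thinning 2. Convergence is
monitored by split-$\hat R$ and a Geyer-truncated effective sample size on
the hyperparameters; any $\hat R > 1.05$ flags the fit with a warning —
never silently. Fits use the first 10 trials of the Conflict dropout
blocks by default (`trials_subset = "learning_only"`,
`conditions = "Conflict"`): Conflict and NoConflict contingencies are
always fitted separately, and trial 11 is never shown to the sampler.

# Model comparison

For the fitted learning trials the package computes PSIS-LOO (Pareto
smoothed importance sampling leave-one-out): per-datapoint importance
ratios are tail-smoothed by a generalized Pareto fit (Zhang–Stephens
posterior-mean estimator with the customary mild regularization of the
shape toward 0.5), truncated at the raw maximum, and turned into
$\text{elpd}_i$; $\text{LOOIC} = -2\sum_i \text{elpd}_i$ with
$SE = 2\sqrt{N \operatorname{var}(\text{elpd}_i)}$. Shape diagnostics
above 0.7 are reported and warned about. The implementation is validated
in the test suite against exact leave-one-out in a conjugate normal model
and against brute-force enumeration of the bandit posterior on a parameter
grid.

For the held-out 11th trials no cross-validation correction is needed:
for each posterior draw the log probabilities of all subjects' trial-11
choices (dropout transition applied) are summed and multiplied by $-2$.
The full draw-wise distribution is returned, so claims like "the M2Out
distribution does not overlap the others" are directly checkable, and a
per-subject likelihood ratio $\exp(\overline{\ell_A} - \overline{\ell_B})$
(means over draws of the summed trial-11 log-likelihoods) localizes the
comparison to individuals. Passing a posterior fitted on *all* trials to
the trial-11 evaluator is an information leak and raises an error.

# The synthetic cohort generator

Because the human choice data are not bundled, every downstream stage is
exercised on synthetic cohorts drawn from the package's own generative
models. Outcome schedules are pre-drawn for *both* symbols on every trial
(one independent Bernoulli draw per trial, symbol and quantity), which
makes schedules choice-independent and reproducible; only the chosen
symbol's outcomes are revealed to the agent. Block order randomization and
all outcome draws are controlled by one seed, with per-subject child
seeds.

The default recovery cohort mirrors the arbitration design: **79 agents ×
8 ConflictDropout blocks**, fitted on each block's first 10 trials.
Generating distributions, chosen once and documented here rather than
tuned: weighting factors uniform on $(0.02, 0.98)$ (recovery is a question
about the whole range, so the range is covered); learning rates
$\Phi(N(-0.5, 0.5))$ (median $\approx 0.31$); inverse temperature
$5\,\Phi(N(0.3, 0.4))$ (median $\approx 3.1$) — values typical of
probabilistic bandit learners that actually learn within 10 trials.

Simulated explicit reports are a declared stand-in used to exercise the
report statistics, not a model of human report generation. The reported
probability of the high outcome is a linear readout of the block-final
expected value on the outcome-value scale — $rpM = 50 + 50\,EV_M$ and
$rpS = 50 - 50\,EV_S$ (high shock is value $-1$, hence the sign flip) —
plus truncated Gaussian noise, clipped to $[0, 100]$; an uninformed agent
reports 50, the slider's starting position. The readout deliberately does
**not** rescale by the attainable range $[-wf, wf]$ (respectively
$[-(1-wf), 1-wf]$): full rescaling would cancel exactly the preference
scaling that M2Out puts into its expectations and force the report bias to
zero for everyone. Keeping the raw value scale means a considerate agent's
shock expectations are sharply differentiated while its money expectations
are compressed toward zero — which is precisely the biased-report
phenomenon the bias statistic is designed to detect, and gives the
expected positive preference–bias correlation on synthetic cohorts.

What passing on synthetic data shows — and what it does not: the tests
demonstrate that the estimation and comparison machinery recovers the
structure its own generative models produce at the study's sample sizes.
They cannot show that human learners are described by these models, that
human reports follow the EV readout, or reproduce sample-specific effect
sizes (the published report-bias magnitude, preference–bias correlation of
0.51, or the rank correlation with costly helping); those require the
archived behavioral data. The statistics themselves are validated by
closed-form oracles and directional checks instead.

# Behavioral statistics

Preferences are classified against chance by a two-sided cumulative
binomial rule: with $n$ conflict learning trials, the upper bound is the
smallest count whose Binomial$(n, 0.5)$ CDF reaches $1 - \alpha/2$, the
lower bound the smallest count whose CDF exceeds $\alpha/2$, and labels
use *strict* inequalities — more than the upper bound is Considerate,
fewer than the lower bound Lucrative, anything else Ambiguous. At
$n = 120$ (online layout: first 10 trials of 12 Conflict blocks) the
bounds are (49, 71); at $n = 60$ (imaging layout) they are (22, 38).
Boundary counts are labelled Ambiguous: the classification rule is worded
strictly, and when in doubt a non-committal label is the conservative
reading.

The report bias is
$\text{bias} = [rpS(\text{high-shock}) - rpS(\text{low-shock})] -
[rpM(\text{high-money}) - rpM(\text{low-money})]$, positive when shock
contingencies are reported more sharply than money contingencies; each
difference is signed so that perfect learning of the programmed 80/20
contingency yields $+60$. Devaluation behavior is summarized as the mean
considerate-choice proportion at trials 10 and 11 of dropout blocks per
preference group and removed outcome. Rank correlations (for external
validity analyses against, e.g., donation behavior) use Kendall's tau-b
via `stats::cor`.

# wf-normalized regressors

For imaging-style analyses the winning model's latent trajectories are
exported per trial: the chosen option's $EV_M$, $EV_S$ at decision time
and $PE_M$, $PE_S$ at outcome time, each also in a *wf-normalized* form —
$PE_M / wf$, $PE_S / (1 - wf)$ (and likewise the EVs). Normalization puts
every subject's learning signal on the outcome scale regardless of
preference: the first shock prediction error of a block is exactly $-1$
after a high-shock outcome and $+1$ after a low-shock outcome, for any
$wf \in (0,1)$. The order of operations is: divide by the weight first,
then mean-subtract across trials (`center = TRUE`), the usual convention
for parametric modulators entering a GLM design matrix; `center = FALSE`
exposes the raw normalized values. $wf \in \{0, 1\}$ makes the
normalization undefined and raises an error.

# Numerical choices and degenerate inputs

* Outcome codes outside $\{+1, -1, 0\}$, probabilities outside $[0,1]$,
  $\tau \notin [0,5]$, non-contiguous trial indices, and double
  application of the dropout transition are all hard errors.
* $\tau = 0$ gives exact chance predictions for every model; M0 does so by
  construction, and fitting M0 yields a pointwise log-likelihood of
  exactly $\ln 0.5$ for every draw and trial.
* LOOIC of a single datapoint has $SE = 0$ by convention; constant
  log-likelihood columns bypass the Pareto fit (no tail to smooth).
* Ties in the two-option softmax cannot occur except at equal utilities,
  where the probability is exactly $1/2$.

# Problem sizes

The test suite and the acceptance script run the full pipeline at the
study's subject count (79 agents, 8 dropout blocks) with reduced MCMC
settings (2 chains × 400–500 retained draws for test fits; 4 chains × 500
for the recovery run), sizes at which the sampler's diagnostics are
adequate and the headline results — recovery correlation, LOOIC
near-equivalence, trial-11 separation — are stable across seeds. The
analysis drivers under `analysis/` use 4 chains × 500 draws.

# Known limitations

* The sampler is a random-walk scheme; it is accurate but draws are more
  autocorrelated than Hamiltonian Monte Carlo would produce. Thinning and
  the interweaving moves compensate; $\hat R$ is always reported.
* The M2DO form is one principled interpolation between M2Out and M2Dec,
  not the only one.
* The report generator is a test harness for the bias statistics; no
  fidelity to human report noise is claimed.
* Learning on post-devaluation trials 12–20 is simulated (single remaining
  outcome, effective weight 1 or 0) but the scientific analyses here use
  only trials 1–11, matching the design's logic that later trials mix
  learning about a changed task.
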