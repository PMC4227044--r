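---
title: "Modelling commitment and deferral in a rule-in/rule-out bandit task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling commitment and deferral in a rule-in/rule-out bandit task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditpool)
library(dplyr)
```

## The task and its generative model

A block of the commitment task presents four bandits. Bandit $i$ emits
spiral lengths $s_i(t) \sim N(v_i, \sigma_i)$; within a block two
bandits have $\sigma = 0.5$ and two $\sigma = 1.0$, assigned at random.
The four means are a contiguous window over the design's six lengths
$\{2.5, 3.0, \dots, 5.0\}$ — the *short* ($2.5$–$4.0$), *medium*
($3.0$–$4.5$) or *long* ($3.5$–$5.0$) context — and each bandit's
per-trial payoff is a function of the *rank* of its mean within the
block: $-15/24, -5/24, +5/24, +15/24$ pounds for ranks 1–4. Because the
payoffs are attached to ranks, the same physical length can be the best
option in a short block and a below-average one in a long block, which
defeats fixed length thresholds and makes a *relative* value estimate
necessary.

Offers are drawn uniformly from the bandits still in play. Under
**rule-in**, committing accepts the offered bandit into the asset pool
and the trial yield is the mean payoff of the pool (zero while empty);
under **rule-out**, committing rejects the bandit and the yield is the
mean payoff of the bandits not yet rejected. The four payoffs sum to
zero, so an empty rule-in pool and a full rule-out pool are exactly
worthless — deferral is costless only in expectation at the start of a
block. A block ends after 12 trials or when no active bandit remains
(so the number of trials $k \in [4, 12]$ when it ends by exhaustion),
and the block's earnings are the summed trial yields rounded to the
nearest half pound. Yields are computed *after* the current trial's
decision, matching the task's worked payoff examples; rounding ties
break away from zero, a choice isolated in `block_end_yield()`.

Two modelling details are worth flagging. Spiral lengths are physical
magnitudes, so the rare non-positive Gaussian draw (probability about
0.006 at mean 2.5, sd 1.0) is redrawn; the redraw count is reported by
the simulator but the effect on any statistic is negligible. And offers
are i.i.d. uniform over active bandits, with immediate repeats allowed —
the task description imposes no constraint against them.

## Decision variables

The candidate decision variables cross **integration** — use the
running average $\bar v_i(t)$ of all spirals seen at the offered bandit
(including the current one) versus only the momentary spiral $s_i(t)$ —
with an **anchor** subtracted as a reference $r(t)$: none, the raw
spiral of the previous trial, the best competitor's running average
$\max_{j \ne i} \bar v_j(t)$, or the average running estimate over all
presented bandits. The integrated, average-anchored form is the
*current-minus-average* DV,

$$\mathrm{DV}(t) = \bar v_i(t) - \frac{1}{|S_\mathrm{pres}|}
  \sum_{j \in S_\mathrm{pres}} \bar v_j(t),$$

and the max-next analogue is *current-minus-next*. On a block's first
trial — and whenever the requested anchor does not yet exist, e.g. the
max-next anchor before any competitor has been seen — the reference
falls back to $v_\mathrm{prior} = 3.75$, the grand-mean spiral length of
the design (the mean of the six context means; the package asserts this
identity rather than hard-coding two unrelated constants).

Three interpretation choices were genuinely open and are resolved as
follows. $S_\mathrm{pres}$ contains every bandit presented at least once
this block, *including* the current bandit and bandits already committed
— the average-anchor formula is applied literally. The previous-trial
anchor uses the *raw* previous spiral for both integration settings.
And although the max-next anchor is sometimes written as an argmax (an
index), a value comparison needs the competitor's *value*, so the
package uses the maximum of the competitors' running averages. We do
not inject $v_\mathrm{prior}$ into the average anchor for
never-presented bandits; the prior enters only as the first-trial (or
undefined-anchor) fallback.

The leaky variants replace the equal-weight running average by an
exponential moving average $\bar v \leftarrow (1-\lambda)\bar v +
\lambda s$ with leak $\lambda \in (0, 1]$, initialized at the first
sample — except under the free-prior extension, where it initializes at
a fittable $v_\mathrm{prior}$ and the first sample enters through the
leak update, so the prior genuinely acts as a pseudo-observation.

```{r dv-demo}
ev <- tibble::tibble(trial = 1:3, bandit = c(0L, 1L, 0L),
                     spiral = c(4.0, 3.0, 5.0))
dv_trace(ev, dv_config("average", integration = TRUE))
```

## Choice models and fitting

The probabilistic model is a probit regression per rule,
$P(\mathrm{commit}) = \Phi(b + c\,\mathrm{DV})$, fit by maximum
likelihood via `stats::glm` with a probit link (the task literature
sometimes labels this a logistic regression while writing $\Phi$; the
cumulative normal is what is implemented). The implied criterion is
$\theta = -b/c$, the DV at which commitment reaches 50%. Complete
separation — which deterministic agents produce by construction — is
flagged on the fit rather than raised. `compare_dvs()` fits all eight
DVs per participant, summarizes the negative log-likelihoods (summed
over rules), and contrasts current-minus-average against
current-minus-next with a paired two-sided t test.

The deterministic criterion model commits iff $\mathrm{DV} \ge
\theta_\mathrm{in}$ (rule-in) or $\mathrm{DV} \le \theta_\mathrm{out}$
(rule-out), ties committing. It is fit by replaying each participant's
own stimulus sequences (the DV depends only on offers and spirals, not
on decisions, so the observed sequences are valid under any candidate
criterion), predicting commitment probabilities in the 24 conditions
(4 ranks × 3 contexts × 2 rules), and maximizing a binomial likelihood
over a criterion grid, by default $[-1.0, 1.5]$ in steps of 0.01. The
two rules separate cleanly, so each criterion is searched on its own
axis. Numerical choices: predicted condition probabilities are clamped
to $[10^{-3}, 1 - 10^{-3}]$ so a deterministic model keeps a finite
likelihood under mismatches; and because deterministic predictions
change only when the criterion crosses an observed DV, the maximum-
likelihood set is an *interval* on the grid — the fit reports both the
interval and its midpoint (a max-margin tie-break, which recovers
simulated agents markedly better than taking the interval's edge). The
leaky and free-prior extensions add $\lambda$ and $v_\mathrm{prior}$ as
extra grid dimensions (3 and 4 free parameters against the base model's
2); models are ranked by $\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}$ with
$n$ the total number of trials.

## Reward-maximizing criteria

`reward_maximizing_criterion()` asks where a fixed criterion should sit
to maximize expected block-end yield, holding the agent to the
current-minus-average DV with the fixed prior 3.75 — the best-fitting
human model, not an omniscient observer. The sweep simulates fresh,
context-balanced blocks at every grid point, reusing identical
per-block random streams across points (common random numbers), so that
neighbouring criteria face the same stimuli and the yield *differences*
are estimated far more precisely than the yields themselves. Defaults
are a 0.01 grid and 10,000 blocks per point; argmax ties break toward
the smaller criterion, and a maximum on the grid edge triggers a
warning. One criterion per rule is used across contexts, matching how
the sweep is usually displayed. The rule-out yield surface is quite
flat around its maximum, so the located $\theta^*_\mathrm{out}$ wanders
by roughly $\pm 0.1$ across seeds even at this simulation budget; the
rule-in maximum is sharper.

The hot loop lives in C++ (`src/threshold_sim.cpp`), a faithful mirror
of the R reference simulator (`run_block()` with `threshold_policy()`).
The two paths use different RNG streams by design, so the test suite
checks their agreement statistically (means within Monte-Carlo error)
alongside exact analytic endpoints: a never-accepting rule-in agent and
a never-rejecting rule-out agent both earn exactly £0.

## Synthetic participants

`generate_cohort()` is the package's stand-in for human data and defines
the simulated study conditions: 48 blocks in 4 runs per participant,
each run holding exactly two blocks of every rule × context cell (hence
6 per rule and 4 per context per run), order shuffled within run.
Agents commit with probability $\Phi(\beta(\mathrm{DV} -
\theta_\mathrm{in}))$ under rule-in and $\Phi(\beta(\theta_\mathrm{out}
- \mathrm{DV}))$ under rule-out — the same family the probit fit
assumes, so recovery is well-posed — with deterministic behaviour at
$\beta = \infty$ and an optional lapse (a fair coin flip) emulating the
task's occasional forced random choices; the default lapse is 0.
Between-subject criteria default to normal distributions with the
fitted group means and SDs, $\theta_\mathrm{in} \sim N(0.39, 0.29)$ and
$\theta_\mathrm{out} \sim N(0.12, 0.25)$, truncated to the criterion
grid range $[-1, 1.5]$; the normal form and the truncation bounds are
package choices, as only means and SDs are reported.

What passing tests on these cohorts do and do not show: the generator
reproduces the session structure, the rank-relative payoff logic and
criterion-driven choice, so recovery results demonstrate that the
fitting machinery is consistent for agents of the assumed family. Real
participants additionally exhibit reaction-time structure, learning and
attention effects, and timeout-forced choices, none of which are
modelled; agreement with simulated cohorts therefore validates the
pipeline, not the psychological completeness of the model.

```{r recovery, eval = FALSE}
cohort <- generate_cohort(n = 5, slope = Inf, seed = 77)
tidy(recovery_experiment(cohort))
```

## Behavioural metrics and model regressors

`commit_probability_by_condition()` uses the task's own definition —
commitments divided by offers — per rank or per trial number, within
rule and context; empty cells are reported missing, never as zero.
`commitment_counts()` summarizes commitments per block and the trial of
the first commitment per rule; blocks without a commitment contribute
nothing to the first-commitment average (no imputation), which is
stated here because the original analysis does not document its
handling. `model_regressors()` produces the trialwise quantities used
as parametric regressors in imaging analyses of this task: the DV, the
reference $r$, the trial number, and the estimated per-trial yield —
the mean over asset-pool bandits of $\bar v_i - r$ (zero for an empty
pool; never-sampled rule-out pool members carry the prior estimate) —
with its running accumulation. Whether that estimate should re-evaluate
the pool against the *current* reference each trial or freeze each
bandit's reference at pool entry is ambiguous; the default refreshes,
and `refresh_reference = FALSE` exposes the alternative.

## Problem sizes and defaults

Package defaults follow the task's stated design throughout: 12-trial
horizon, payoff vector $\pm 15/24, \pm 5/24$, sd pair $\{0.5, 1.0\}$,
$v_\mathrm{prior} = 3.75$, criterion grid $[-1, 1.5]$ step 0.01, sweep
budget 10,000 blocks per grid point. The test suite exercises the same
machinery at reduced Monte-Carlo sizes (thousands of blocks, cohorts of
4–6 participants) chosen so that every stochastic check has a
comfortable margin relative to its sampling error while the whole suite
runs in a few minutes.

## Known limitations

- The deterministic criterion agent at the fitted group-mean criteria
  reproduces commit *proportions and counts* well but makes its first
  commitment much earlier than humans do: with the first-trial
  reference pinned at 3.75, short- and long-context opening trials
  produce large-magnitude DVs that a noiseless threshold acts on
  immediately. Matching human first-commitment latencies evidently
  requires decision noise or a deferral process beyond a fixed
  threshold.
- No reaction-time model, no hierarchical/population-level fitting, no
  latent (Bayesian) inference DVs — the candidate set is deliberately
  restricted to anchoring × integration of observed samples.
- The criterion sweep optimizes a single fixed criterion per rule;
  trial-dependent (dynamic-programming) policies are out of scope.
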