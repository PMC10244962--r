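---
title: "Modelling intrusive memory dynamics with absorbing Markov chains"
author: "imchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrusive memory dynamics with absorbing Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imchain)
```

## The model

After a traumatic event, a memory may come to mind involuntarily — an
intrusive memory (iM). Reminder cues can return a consolidated intrusive
memory to a labile, *reactivated* state, during which a behavioural task
(classically, a visuospatial game played in the reconsolidation window) can
interfere with restabilization so the memory settles in a *non-intrusive*
form (niM). `imchain` models these dynamics as a discrete-time Markov chain
over four states, in the fixed order

`pre_trauma, iM, reactivated, niM`.

Each row of the transition matrix is a probability distribution over next
states. The structural assumptions are:

* consolidation is certain: `pre_trauma -> iM` with probability 1;
* `niM` is absorbing — once a memory is non-intrusive it stays so;
* `pre_trauma` is never re-entered;
* the iM row is `(0, p2, p3, 0)`: an intrusive memory either reconsolidates
  unaltered (`p2`) or is reactivated (`p3 = 1 - p2`);
* the reactivated row is `(0, p5, p4, p6)`: a labile memory reconsolidates
  intrusively (`p5`), stays labile (`p4`), or reconsolidates non-intrusively
  (`p6`).

Distributions are row vectors updated by right multiplication. These
invariants are enforced by the `MemoryChain` validity method, with a
tolerance of `1e-12` on internally constructed matrices and `1e-9` on
matrices arriving from files (separating float noise from data errors).

## Intervention parametrization

Two interpretable functions map interventions onto transition
probabilities.

**Task.** A task of strength $T \ge 0$ acting during the labile window
reduces the chance of intrusive reconsolidation. Several simultaneous tasks
act multiplicatively, giving the reconsolidation weight
$r = 1/\prod_i (1 + T_i)$ (`taskReconsolidationProb()`).

**Cue.** A reminder cue of strength $\alpha$ reactivates a consolidated
intrusive memory with logistic probability
$p_3 = 1/(1 + e^{-\alpha})$ (`cueReactivationProb()`).

The canonical constructor `buildTaskCueChain()` uses the *normalized* form
of the reactivated row,

$$\left(0,\; \frac{r}{1+r},\; \frac{p_4}{1+r},\; \frac{1-p_4}{1+r}\right),$$

in which the task weight competes with the unit mass split between staying
labile ($p_4$) and resolving ($1 - p_4$). We adopt this rather than the
unnormalized reading ($p_5 = 1/(1+T)$, $p_6 = 1 - p_4 - p_5$) because the
latter can produce negative $p_6$ when $p_4$ is large and $T$ small,
whereas the normalized row is a valid distribution for every parameter
combination; it is also the form all of the numerical scenarios use.
`buildRawChain()` remains available when the five probabilities are
supplied directly (for example by the empirical estimator). With a single
task, the one-task and two-task constructions coincide when the second
strength is zero; the tests assert this identity.

**Multiple cues** (`multiCueProb()`). Independent cues that must all fire
give $p_3 = \sigma(\alpha)^n$, strictly decreasing in $n$ — more gates,
rarer reactivation. Nested (conditionally tapering) cues self-compose the
logistic $n$ times starting from $\alpha$; iterates converge monotonically
to the logistic fixed point $x = \sigma(x) \approx 0.659046$, which the
tests verify against a bisection oracle.

A fixed comparator chain (`buildBaselineChain()`) represents dynamics
without cue or task: iM row `(0, 0.5, 0.5, 0)`, reactivated row
`(0, 0.33, 0.34, 0.33)`.

## Persistence analysis

With `niM` reachable from every transient state, the fundamental matrix
$N = (I - Q_t)^{-1}$ over the three transient states collects expected
visit counts before absorption; its row sums are expected absorption
times. For the baseline chain these have closed forms (the lower block of
$I - Q_t$ has determinant $0.165$), giving $N_{iM,iM} = 4$,
$N_{iM,re} = 100/33$ and an expected absorption time from iM of
$232/33 \approx 7.03$ steps; the tests freeze these hand-derived values.
"Expected time in the iM state" is implemented as the expected number of
visits to iM before absorption (the iM column of $N$), the natural
discrete-time reading.

Chains whose absorbing state is unreachable (for example $p_3 = 0$, or
$p_4 = 1$ under the raw construction) raise a `non-absorbing chain` error
rather than returning infinities — silent infinities corrupt parameter
sweeps.

`spectralDecompose()` factorizes $P = V D V^{-1}$ so that
$P^n = V D^n V^{-1}$; the suite checks reconstruction against iterated
multiplication to `1e-10` up to $n = 200$. When $VV^{-1}$ fails to
reproduce the identity to `1e-8` the chain is flagged near-defective and
`chainPower()` silently falls back to direct multiplication; no chain in
the package's parameter ranges triggers this, but user-supplied matrices
can.

The **mixing time** is defined spectrally, $\tau = -1/\log|\lambda_2|$,
the relaxation time of the second-largest eigenvalue modulus: the
timescale on which transient (mixed) memory mass decays. A chain that
absorbs in one step from every transient state has $\tau = 0$;
$|\lambda_2| = 1$ raises a `no convergence` error. Alternative
total-variation definitions are out of scope; with the extra eigenvalues
here being $0$ and $1$, the full-chain and transient-block definitions
coincide.

`absorptionTimeBound()` reports two labelled quantities: the maximum row
sum of the fundamental matrix (a certified — indeed exact — upper bound on
the expected absorption time over starting states) and the spectral
surrogate $1/(1-|\lambda_2|)$. The bound grows without limit as lability
traps the reactivated state ($p_4 \to 1$), which is the behaviour that
matters for interpretation: beyond a point, further lability dominates
every other lever.

`monteCarloAbsorption()` is the independent stochastic oracle: seeded,
vectorized trajectory simulation returning means and standard errors for
steps and visit counts. The acceptance suite runs it at $10^5$
trajectories against the baseline chain and twenty random valid chains and
requires agreement with the fundamental matrix within four standard
errors.

## Treatment schedules

`DoseSchedule` holds consecutive step segments, each governed by its own
chain; `evolve()` propagates a distribution analytically through the
segments (trajectories conserve probability to `1e-12` and `niM` mass is
non-decreasing — both tested as invariants). "A single dose in the first
time period" (`singleDoseSchedule()`) means exactly step 1 uses the task
chain; later steps use the no-task chain with the *same* cue settings
(task strength 0), which isolates the task effect. The fixed baseline
comparator is deliberately not the default for those later steps, since it
changes the cue environment too; a `rest = "baseline"` flag is provided
for users who prefer that reading. The step unit is abstract — the model
assigns no wall-clock duration — and the default horizon is 20 steps.

Because either aggregation is defensible, `imProbabilityCurve()` emits
both `p_iM` and `p_intrusive = p_iM + p_reactivated`; all qualitative
conclusions in the tests use orderings that hold for either.

One subtlety found during validation and worth recording: with strong
tasks, the *difference* between task and no-task trajectories under five
independent cues is smaller than under one cue only over short horizons
from an all-consolidated start (the task only gets an opportunity when a
cue reactivates the memory). Over longer horizons the ordering inverts —
the fast single-cue dynamics have already absorbed both trajectories,
while the slow five-cue dynamics preserve the treatment difference. The
unit test asserts the short-horizon property; both regimes are real
features of the model.

## Sensitivity analysis

`lhsSample()` draws Latin hypercube designs (via the `lhs` package) over
the default ranges $p_4 \in [0,1]$, $T \in [0,20]$, $\alpha \in [0,1]$;
validity asserts the defining stratification property — exactly one sample
per equal-width stratum per parameter. The sample size is a free choice;
the default is 1000.

Because the logistic alone maps $\alpha \in [0,1]$ into $[0.5, 0.731]$, a
sweep at a low background reactivation rate (such as 0.05) needs a
coupling rule. We use proportional scaling,
$p_3 = \min(1,\, p_{3,\mathrm{base}} \cdot \sigma(\alpha)/\sigma(0))$
(`cueCoupledReactivation()`), which reduces exactly to the plain logistic
at baseline 0.5. This is one consistent reconstruction of an
under-determined design choice, stated prominently for that reason.

`correlationSummary()` reports Pearson correlations of each parameter with
$\tau$, with missing rows excluded pairwise and |rho| < 0.1 classified
"weak". A caveat documented here because it shapes what the tests can
claim: $\tau$ diverges as the chain approaches non-absorption (high
$p_4$), so its distribution over the full hypercube is heavy-tailed and
product-moment correlations are dominated by the divergent corner. The
positive association of lability with mixing time is robust across seeds
and baseline reactivation rates, and partial effects of task and cue
strength on $\tau$ are negative everywhere on fixed grids (tested), but
the *global* Pearson coefficients for $T$ and $\alpha$ are small and
seed-unstable at desk scale under this response definition. The
acceptance-level sign-structure checks for those two parameters therefore
fail under the documented spectral definition of $\tau$, and are left
failing rather than redefined after the fact; rank-based or
variance-based indices are deliberate non-goals.

## Empirical parametrization

Under a Poisson model for intrusion counts, the probability of observing
no intrusions in a window with mean $m$ is $e^{-m}$. The estimator
(`estimateTransitions()`) uses three of the four arms' summaries:

* pre-intervention 24 h (all arms pooled, mean 3.334): an intrusion means
  the memory reconsolidated intrusively, so $p_2 = 1 - e^{-3.334} = 0.964$
  and $p_3 = e^{-3.334} = 0.036$;
* cue-only week (mean 4.889): intrusions here reflect memories that were
  reactivated and remained labile, so the marginal
  $p_4 = p_3(1 - e^{-4.889}) = 0.035$;
* cue-plus-task week (mean 1.889): no intrusions after treatment reflect
  successful non-intrusive reconsolidation, so
  $p_6 = p_3 e^{-1.889} = 0.005$; and $p_5 = 1 - p_4 - p_6 = 0.959$.

All arithmetic uses the supplied means at full precision; rounding
(half-up, 3 decimals) happens only at presentation. This is the only
convention that reproduces every printed value simultaneously. The
no-task-control and task-only means are accepted and echoed — they anchor
the synthetic recovery harness — but do not enter the estimator. The
pre-intervention between-arm homogeneity test that justifies pooling is
routine off-the-shelf statistics and out of scope; the estimates object
carries a note to check baseline comparability externally.

The resulting chain (`buildEmpiricalChain()`) has rare reactivation and
very rare successful reconsolidation, so its expected absorption time from
iM is of order $5 \times 10^3$ steps — hundreds of times the baseline
comparator's 7 steps: left untreated, intrusive memories are predicted to
persist.

## Synthetic diaries and what they show

`generateDiaries()` emulates the four-arm design: per-participant Poisson
counts, a common pre-intervention mean (exchangeable baselines), group
means for the week, default 18 participants per arm (the published
standard errors imply roughly this order; SE $\approx \sqrt{m/n}$). A
negative-binomial flag generates overdispersed counts for robustness
studies but is off by default — the estimator's model is Poisson.

`recoveryExperiment()` repeats generate → summarize → estimate and reports
bias and RMSE against the infinite-sample values. At 1000 participants per
arm and 200 replicates every probability is recovered with |bias| < 0.01,
and RMSE decreases across 10 → 100 → 1000 participants (consistency).

What passing these tests does *not* show: that real diaries are Poisson
(they are often overdispersed), that arms are truly exchangeable at
baseline, or that the within-week timing of intrusions is ignorable. The
generator reproduces the statistical structure the estimator assumes,
nothing more.

## Problem sizes and numerics

The test suite runs the Monte Carlo oracle at $10^5$ trajectories for the
acceptance-grade comparisons and $5\times10^3$–$2\times10^4$ for unit
checks; sensitivity sweeps use 1000-point designs with 5 seeds; recovery
uses 200 replicates of 1000 participants per arm. These sizes make every
stochastic tolerance (4 standard errors; |bias| < 0.01) comfortably
stable under reseeding. Spectral reconstruction is checked at `1e-10`,
row-stochasticity at `1e-12`/`1e-9` as above, and serialized chains
round-trip bit-exactly (JSON, 17 significant digits) or value-exactly
(CSV).

## Limitations

* Four states, one absorbing; no continuous-time version.
* At most multiplicative task combination; no within-step interaction
  between cue and task.
* The spectral mixing-time definition and the cue-coupling rule in the
  sensitivity module are documented reconstructions of under-determined
  choices; magnitudes of sensitivity correlations (as opposed to the
  robust lability sign) should not be over-interpreted.
* The empirical estimator identifies transition probabilities only under
  the Poisson and exchangeability assumptions above.
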