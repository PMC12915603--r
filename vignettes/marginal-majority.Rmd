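---
title: "Influence curves, marginal majorities, and lock-in: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence curves, marginal majorities, and lock-in: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginalmajority)
```

## The model

A long sequence of individuals each chooses between two options, A and B.
The probability that the next individual picks A depends on A's current
popularity $x$ — the share of prior participants who chose it — through a
nondecreasing *influence curve* (urn function) $f$, with
$p_A = f(x_A)$. By convention A is the inherently less appealing option:
$f(0.5) \le 0.5$. The process is a generalized urn; its popularity converges
to a point where $f$ crosses the diagonal from above (a *downcrossing*, or
stable equilibrium). The process is *lock-in-prone* when the less appealing
option can hold a long-run majority with positive probability, which happens
exactly when the curve enters the *lock-in region* $y > x > 0.5$.

Any curve with a (single, at $x = 0.5$) jump decomposes as

$$f(x) = g(x) + \frac{M}{2}\,u(x),$$

with $g$ continuous at $1/2$, $u(x) = \pm 1$ for $x \gtrless 0.5$ and
$u(0.5) = 0$. $M$ is the **marginal majority effect** — the discontinuous
gain in choice probability when an option becomes marginally more popular
than its rival — and $d = 1 - 2g(0.5)$ is the **inherent appeal
difference**. Because $f \ge 0$ near $1/2$, every realizable pair satisfies
$M + d \le 1$.

Two results drive the package:

* **Criterion.** If $M > d$, the right limit of $f$ at $1/2$ is
  $(1 - d + M)/2 > 1/2$, so the curve enters the lock-in region immediately
  to the right of $1/2$: the system is lock-in-prone
  (`mm_criterion()`). If $M > 0.5$, this holds regardless of $d$.
* **Bound.** When $M > d$, the lock-in probability satisfies
  $$p_L \ge \frac{2(M-d)(1-d)}{(1-d)(1-d+M) + 2M},$$
  (`lock_in_probability_bound()`). The bound is the exact survival
  probability of the auxiliary step process whose curve is $0$ below $1/2$,
  $(1-d)/2$ at $1/2$ and $(1-d+M)/2$ above: through $X_n = 2Y_n - n$ that
  process is a unit-step walk with up-probability $q_0 = (1-d)/2$ at the
  origin and $q_+ = (1-d+M)/2$ above it, whose probability of never going
  negative is $q_0(2q_+-1)/(q_+ - q_0(1-q_+))$
  (`walk_survival_probability()`). The package checks this identity to
  1e-12 on a feasibility grid and against a Monte-Carlo oracle
  (`mc_walk_survival()`).

```{r}
lock_in_probability_bound(M = 0.2, d = 0.1)
```

## Curve families and conventions

`step_curve()`, `logistic_curve()`, `piecewise_curve()`, `constant_curve()`,
`identity_curve()` and `aggregate_curves()` (mixtures) cover the analysis.
The logistic family
$f(x) = 1/\left(1 + \tfrac{1+d}{1-d}e^{b(1-2x)}\right)$ is the standard
continuous benchmark: it satisfies $f(0.5) = (1-d)/2$, has $M = 0$, and is
self-correcting for small slopes but lock-in-prone for large ones.
`logistic_lock_in_threshold()` finds the critical slope from the tangency
system $f(x) = x$, $2bx(1-x) = 1$; at $d = 0.2$ the threshold is
$b^* \approx 2.98$, i.e. the curve enters the lock-in region for $b > 3$ in
round numbers, with stable equilibria then close to 0 and 1 (winner-take-all).

Conventions chosen where the framework leaves freedom:

* **Value at the tie point.** $u(0.5) = 0$, so $f(0.5) = g(0.5)$; a step
  curve's default mid value is the midpoint of its two levels. Empirical
  records at $x = 0.5$ are excluded from curve estimation, so no result
  depends on this choice.
* **Jumps only at 1/2.** Discontinuities elsewhere would need a mechanism
  making some other popularity value salient; none is modeled.
* **One-sided limits.** Analytic for every built-in kind (a mixture's
  limits are weighted means of its components' limits); a numeric fallback
  uses geometric offsets $\varepsilon, \varepsilon/2, \dots$ and takes the
  last value, erroring on non-monotone sequences rather than guessing.
* **Monotonicity is validated, not enforced**: constructing a decreasing
  curve fails loudly (checked on a 1001-point grid at 1e-12).

## Equilibrium location and classification

`find_equilibria()` brackets sign changes of $f(x) - x$ on a 2001-point
grid, refines each by bisection to 1e-9, and detects the jump crossing at
$1/2$ from the one-sided limits. Stability is read from the sign of
$f - x$ at probe offsets $10^{-4}$ on either side; when the curve stays
within the tangency margin (1e-6) of the diagonal there, the crossing is
labeled *indeterminate* rather than silently classified. Crossings at
exactly $0.5$ are reported but never counted as lock-in: the region is
strict. For binned empirical curves, `enters_lock_in_region()` compares the
bin estimate with the bin *midpoint* by default — the conservative,
interpolation-free reading; a piecewise-linear "segments" variant is
available, since published figures draw line segments between bin estimates
and neither convention is canonical.

## The simulator

`simulate_trial()` / `simulate_ensemble()` run the urn in compiled code:
participant $t$ sees $x_t = (\mathrm{init}_a + \#A_{<t}) /
(\mathrm{init}_a + \mathrm{init}_b + t - 1)$ and chooses A with probability
$f(x_t)$. Default initial counts are $(1, 1)$: the first participant then
sees popularity exactly $1/2$, and the auxiliary step process coincides
state-for-state with the boundary walk above, so simulated survival
frequencies can be compared to the closed form without correction. All
randomness flows through R's RNG from a single master seed per call — the
same seed reproduces an ensemble exactly. When a trial's curve value hits
exactly zero below popularity $1/2$ (the auxiliary process after losing the
majority), the remainder is deterministic and is completed in closed form.
End-of-trial popularity stands in for the long-run limit $x_\infty$;
the horizon is a parameter everywhere.

The party-signal variant (`simulate_party_trial()`,
`party_spec_from_md()`) models designs where participants see only *which*
of two groups supports a statement more, not by how much: a party-$P$
participant supports with probability $p^+_P$ or $p^-_P$ depending on the
sign of $x = x_A - x_B$, with the mean of the two applied at ties or while
either party lacks prior participants (mirroring $u(0.5) = 0$). The
mapping from $(M, d)$ places the per-party curves symmetrically:
$p^{\pm}_A = (1 - d \pm M)/2$, $p^{\pm}_B = (1 + d \mp M)/2$. The survival
bound transfers to this process exactly only when parties alternate (equal
counts throughout); the default assignment is therefore alternating, with
fair random assignment available.

## Estimation pipeline

`estimate_items()` reproduces the measurement protocol at item level:

1. **Option A** is the option chosen less often in the control condition
   (no social influence); exact 50/50 ties break lexicographically and are
   flagged. $\hat d = \hat p_B - \hat p_A \ge 0$, with
   $\mathrm{SE} = 2\sqrt{\hat p_A(1-\hat p_A)/n}$.
2. **Running popularity** attaches $x_t$ per record, including any
   artificial initial counts (e.g. a seeded world starting at 110 to 10
   shows its first participant $x = 110/120$). Records with no prior
   information (unseeded first participants) get `NA` and are excluded.
3. **Binning** pools worlds into bins of width 0.1; records exactly on an
   interior edge count half in each adjacent bin; records at $x = 0.5$ are
   excluded. Per-bin estimates are weighted shares with binomial standard
   errors $\sqrt{\hat p(1-\hat p)/n_\mathrm{eff}}$; empty bins report no
   estimate rather than zero.
4. **$\hat M$** is the jump between the two central bins,
   $(0.4, 0.5) \to (0.5, 0.6)$, with the two bin errors combined in
   quadrature. An empty central bin is an estimation error ("no data to
   estimate M"), and such items are reported in a separate bucket by
   `classify_items()`, never silently zeroed. Negative $\hat M$ is
   reported as-is — clipping would bias the $(M, d)$ scatter.
5. **Lock-in observed** means option A holds a strict end-of-trial
   majority in at least one world; exact ties never count.

The party variant (`party_estimates()`) groups records by the sign of
$x = x_A - x_B$ (records at $x = 0$ or with an undefined signal are
ignored), estimates $y = y_A - y_B$ on each side, and combines per-party
jumps as $M = (M_A - M_B)/2$ so that $M \in [0, 1]$ remains comparable
across designs; $d$ is the control-condition support gap between parties.
Whether "current party support" should treat an absent party as zero
support is not settled; the package requires at least one prior participant
per party and flags the rest.

## Inference

`fit_lockin_logistic()` wraps a maximum-likelihood binomial GLM. The
theory fixes the threshold of the $M - d$ model at zero, so that model is
fit without an intercept (one parameter); the $d$-only comparison model
keeps its intercept (two parameters). McFadden's $R^2$ uses the
intercept-only null for *both* models — the protocol leaves the null for
the no-intercept model unstated, and sharing one null keeps the comparison
on one scale. Perfect separation is detected and flagged explicitly.
`fit_lockin_kernel()` implements Nadaraya–Watson regression with a Gaussian
kernel; the bandwidth minimizes leave-one-out squared error via
golden-section search on a log-spaced range scaled by the regressor's
spread (deterministic), and the kernel log-likelihood clips fitted values
to $[10^{-6}, 1-10^{-6}]$ since binary outcomes can be fit exactly.
`aggregate_lock_in_test()` simulates the Poisson-binomial total of
per-trial bounds ($10^5$ draws; the 5% quantile, i.e. the 5000th smallest,
is the one-sided 95% lower confidence bound) and computes per-item binomial
p-values such as $(1-0.3)^{10} \approx 0.028$ for ten lockless trials at
$p_L = 0.3$.

## Synthetic experiments

`generate_experiment()` emulates three published multiple-world layouts
(`design_v2019()`: 7 items × 2 worlds of ~530/3500 with a 110-to-10 seeded
world; `design_mdrt2019()`: 20 statements × 8 worlds of 230 under the
party-signal design; `design_fv2021()`: 30 items with 10–15 worlds of 100
plus 20–30 worlds of 15). Ground truth per item is a step curve drawn from
the design's $(M, d)$ ranges (resampling infeasible pairs); the preset
ranges reflect the regimes those studies reported — small-to-moderate $M$
with moderate-to-large $d$, large $M$ with small $d$, and broad mixtures.
Control samples are independent Bernoulli draws with $P(A) = g(0.5)$, so
$\hat d$ targets $1 - 2g(0.5)$ by construction; the default control size of
200 puts $\hat d$'s standard error near 0.035. Everything is drawn from one
seeded stream, so fixtures are byte-identical across runs.

What the generator deliberately does **not** emulate: participant
covariates, dropout and abstention (absent rows, not a modeled state),
heterogeneous individual-level curves (the aggregate curve is what matters
for the dynamics), time-varying influence, and network structure. Passing
tests therefore show that the estimators recover the *aggregate model's*
parameters under the stated designs — not that real populations satisfy
the model.

## Numerical choices and test scale

Bisection tolerances are 1e-9 (equilibria, thresholds); curve validation
1e-12; the tangency margin 1e-6; kernel clipping 1e-6. The test suite
exercises the simulator at horizons 200–10,000 with ensembles of 400–2,000
trials, estimator recovery on 30 items × 50 worlds × 200 participants, and
the Monte-Carlo confirmation of the worked bound example at $10^5$ trials
of horizon $10^4$ — sizes chosen to keep each property's Monte-Carlo error
well inside its assertion margin (3 standard errors throughout).

## Known limitations

* Items whose true $(M, d)$ lies within estimation noise of the $M = d$
  diagonal are intrinsically ambiguous: the criterion classifies them
  essentially at chance, as any finite-sample method must. Disagreements in
  the end-to-end tests are confined to that band.
* Finite horizons stand in for asymptotics twice (end-of-trial popularity
  for $x_\infty$; truncated walks in `mc_walk_survival()`). With
  $q_+ > 1/2$ the truncation bias is exponentially small and is only ever
  on the side of over-counting survival.
* The exact (not just bounded) lock-in probability of a step curve is
  available here only by Monte Carlo, via `simulate_ensemble()`.
* Multi-option rankings, jumps away from $1/2$, and network-structured
  influence are out of scope.
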