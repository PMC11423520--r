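---
title: "Three-stage designs with sample size recalculation: models, scores and rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage designs with sample size recalculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrecalc)
```

## The problem

A confirmatory two-arm trial compares an intervention with a control on a
normally distributed endpoint with common, unknown variance,
$X_I \sim N(\mu_I, \sigma^2)$, $X_C \sim N(\mu_C, \sigma^2)$, testing
$H_0: \mu_I \le \mu_C$ one-sided. Everything about the design's behaviour
depends on the data only through the standardized effect
$\delta = (\mu_I - \mu_C)/\sigma$, which is unknown at the planning stage.
Pick the sample size for a too-optimistic $\delta$ and the trial is
underpowered; pick it for a too-pessimistic one and it is oversized.

Two devices mitigate this. *Sequential testing* lets the trial stop early
for efficacy or futility at interim analyses. *Sample size recalculation*
lets the remaining stage sizes be chosen at an interim analysis from the
observed interim effect. This package implements a three-stage design with
two interim analyses and unblinded recalculation at the first of them,
together with the two scoring frameworks used to judge whether
recalculation is worth having.

## Test procedure

Each stage $i$ with per-group size $n_i$ contributes a two-sample pooled
t statistic $Z_i$; the stages are independent and, for the sample sizes in
play here, $Z_i \mathrel{\dot\sim} N(\delta\sqrt{n_i/2},\, 1)$. Decisions
use the inverse normal combination
$$
Z^*_1 = Z_1,\qquad
Z^*_2 = \frac{w_1 Z_1 + w_2 Z_2}{\sqrt{w_1^2+w_2^2}},\qquad
Z^*_3 = w_1 Z_1 + w_2 Z_2 + w_3 Z_3,
$$
with weights fixed before the trial ($\sum_i w_i^2 = 1$; equal weights
$1/\sqrt 3$ for the three-stage designs). Because the weights do not move
when a recalculation rule changes $n_2, n_3$, the null distribution of the
combination statistics is unaffected by the adaptation and the type I
error is preserved.

The trial rejects at stage $i$ when $Z^*_i > c_i$ and stops for futility at
an interim when $Z^*_i < f_i$, with $f_1 = f_2 = 0$: an effect pointing the
wrong way ends the trial. Efficacy boundaries are Pocock-type constants,
found by `pocockBoundaries()` as the root of the overall crossing
probability computed by recursive Gauss–Legendre quadrature over the joint
normal law of the $Z^*_i$ (256 nodes per stage, crossing probability
resolved to $10^{-8}$; doubling the nodes moves the three-stage constant by
less than $10^{-10}$).

```{r boundaries}
pocockBoundaries(3, alpha = 0.025)
```

Numerical choices worth stating: futility bounds are **non-binding** — the
efficacy boundaries are calibrated ignoring them, and they are applied only
at analysis time. This is the conservative convention of standard group
sequential software: honouring $f_i = 0$ in the calibration would lower the
efficacy boundaries and make the level exact, but then a sponsor who
ignores a futility stop inflates the type I error. The integration
truncates the lower tail at $z = -8$ when futility is ignored; the mass
beyond is far below the calibration tolerance.

## Conditional quantities at the first interim

Given $Z^*_1 = z^*_1$ in the continuation region, the probability of
rejecting at stage two is available in closed form
(`crpStage2()`), as is the stage-three analogue given $z^*_2$
(`crpStage3()`). The three-stage *conditional power* adds the stage-three
term integrated over the stage-two continuation region against the
conditional normal law of $Z^*_2$ (`z2ConditionalLaw()`):
$$
CP_\delta(z^*_1, n_2, n_3) = CRP^{(2)}_\delta(z^*_1, n_2)
 + \int_{f_2}^{c_2} CRP^{(3)}_\delta(z^*_2, n_3)\,
   f(z^*_2 \mid z^*_1, n_2, \delta)\, dz^*_2 .
$$
`conditionalPower()` evaluates the integral with 64 Gauss–Legendre nodes on
$[f_2, c_2]$; the integrand is a smooth product of normal cdf factors and a
normal density on a short interval, and doubling the nodes changes the
result by less than $10^{-8}$. All conditional quantities use the normal
approximation to the t statistics; no t correction is applied inside them,
consistent with treating the boundaries as z-scale constants.

At $\delta = 0$ every $n$-dependent term carries a factor $\delta$, so
conditional power is flat in $(n_2, n_3)$ — the reason the observed
conditional power rule hits its cap when the interim estimate is near zero.

## Recalculation rules

All rules act at the first interim analysis, map $z^*_1 \in [f_1, c_1]$ to
equal later-stage sizes $n_2 = n_3 = n$, and are capped so the trial total
never exceeds $n_{max}$: $n \le \lfloor (n_{max}-n_1)/2 \rfloor$. The lower
limit is $n \ge 2$ per stage so that every stage can estimate its variance;
a zero-size stage has no defined t statistic, so the admissible range
starts at 2 rather than 0. Rules are tabulated once over a $z^*_1$ grid
(step 0.01 — conditional power varies smoothly on that scale, and the
tabulation error is far below Monte Carlo noise) and simulations use
nearest-neighbour lookup.

**Observed conditional power (`ocpRule`).** Plug the interim estimate
$\hat\delta = \sqrt{2/n_1}\, z^*_1$ into $CP$ and take the smallest $n$
with $CP_{\hat\delta}(z^*_1, n, n) \ge 1-\beta$, else the cap.

**Trade-off optimization (`tradeoffRule`).** Maximize the expected
trade-off between conditional rejection probability and a linear cost
$\gamma$ per patient,
$TO^{(i+1)} = CRP^{(i+1)}_\delta - \gamma\, n_{i+1}$, summed over the two
remaining stages with the stage-three term integrated as in $CP$. Two
conventions for the stage-three cost are supported, and the distinction
matters:

* `cost = "expected"` weights $\gamma n_3$ by the probability of reaching
  stage three — the realized expected cost of the decision;
* `cost = "committed"` charges $\gamma n_3$ unconditionally — the size
  committed at recalculation time.

The benchmark `optN` rule (`sampleSizeOptimizedRule()`) optimizes at the
fixed planning effect $\delta = 0.3$ with $\gamma = 0.0028$ under the
*committed* convention. This is the configuration under which
$\gamma = 0.0028$ calibrates the design to 80% power at $\delta = 0.3$,
which is how that constant is defined; under the expected-cost convention
the same $\gamma$ buys markedly more sample size and overshoots the
calibration by eight power points.

The benchmark `optSG` rule (`scoreOptimizedRule()`) replaces the constant
cost with the effect-indexed $\gamma_\delta$ (below) and averages the
objective over a discrete uniform prior on
$\delta \in \{0.2, 0.25, \dots, 0.6\}$ with posterior weights
$w(\delta \mid z^*_1) \propto \varphi(z^*_1 - \delta\sqrt{n_1/2})\,
\pi(\delta)$, under the expected-cost convention. The prior grid is the
grid on which $\gamma_\delta$ is defined; a uniform prior over it is this
package's choice where no prior is canonically given. Because the
objective is maximized pointwise in $z^*_1$ with posterior weights, the
integrated criterion over the interim distribution is maximized as well.
Ties in any argmax break toward the smaller, cheaper size.

```{r rules, eval = FALSE}
d3 <- gsrDesign(3, 70, rule = sampleSizeOptimizedRule())
d3$rule <- tabulateRule(d3$rule, d3)
head(d3$rule$table)
```

## Performance scores

**Global.** For each $\delta$: power, expected per-group sample size, and
the trade-off score $S^G(\delta) = Pow_\delta - \gamma_\delta E_\delta[N]$
with $\gamma_\delta = \partial Pow_\delta(N)/\partial N$ at
$N = N_{fix}(\delta)$, in closed form
$\varphi(z_{1-\beta})\,\delta/(2\sqrt{2 N_{fix}(\delta)})$
(`gammaDelta()`). The score peaks when power sits near $1-\beta$ and
$E[N]$ near the fixed-design size; it is reported only on the clinically
relevant range $\delta \ge 0.2$ ($S^G$ is `NA` below).

**Conditional.** `conditionalScore()` implements the four-component score
on samples taken *conditional on continuing past the first interim*:
location and variation of the observed conditional power
$CP_{\hat\delta}$, and of the realized cumulative per-group sample size,
each scaled to $[0,1]$ and averaged with weights $1/4$ by default (the
weights are configurable — a user who values early stopping over sample
size stability can up-weight $l_N$ against $v_N$). Interpretation choices
that the implementation fixes deliberately:

* $N$ is the **realized** size ($n_1+n_2$ on a stage-two stop, else
  $n_1+n_2+n_3$), not the planned total. This is what makes a two-stage
  comparator's $v_N$ identically 1 — its $n_2$ is fixed given continuation
  — while a three-stage design's $v_N$ stays below 1.
* The targets use the *continuous* $N_{fix}(\delta)$, not its ceiling.
* Expectations include every trial that entered stage two, including those
  later stopped for futility at the second interim.
* Components are clamped at 0: the raw $l_N$ can go negative when a design
  massively oversizes relative to a large true effect.
* The targets switch to $\alpha$ and $n_1$ when even $n_{max}$ patients
  per group cannot power the trial at $\delta$ — chasing an unattainable
  effect should not be rewarded.

## The benchmark designs and the evaluation boundary

`benchmarkDesigns()` builds the five comparators: `gs2` (stages 70/140),
`gs3` (70/70/70), and `ocp`/`optSG`/`optN` (recalculated, $n_1 = 70$,
$n_{max} = 393$ — the fixed-design size for 80% power at $\delta = 0.2$,
the smallest effect considered feasible to chase). All five share the first
interim analysis: the same $n_1$ and the same first-stage efficacy
boundary, the three-stage Pocock constant 2.2895. The conditional score
conditions on the interim outcome, so the conditioning event must be
identical across designs for the comparison to be meaningful; this is also
why `gs2`'s stage-one boundary is not the two-stage Pocock constant.
`gs2`'s second-stage critical value is the two-stage Pocock-type constant
at information fractions $(1/3, 1)$, 2.2022, which leaves its overall type
I error slightly below nominal (conservative).

One further convention follows from the shared-interim principle: the
observed conditional power entering the conditional score is evaluated
against the boundary set shared by the family (the `evalBoundaries` field),
so that the CP components compare the designs' *sample size choices* on a
common yardstick rather than mixing in boundary-family differences. A
design used outside such a family simply evaluates against its own
boundaries (the default).

## The simulation engine

`simulateTrials()` draws trials from sufficient statistics: the
standardized mean difference of a stage is $\delta + \sqrt{2/n}\,U$ with
$U \sim N(0,1)$ and the pooled variance is $\chi^2_{2(n-1)}/(2(n-1))$ —
exactly the patient-level law of the two-sample t statistic, at a fraction
of the cost, and vectorized over replicates. Per-patient simulation is
unnecessary because the t statistic is a deterministic function of these
sufficient statistics. The default `mode = "t"` reproduces the small
type-I inflation (about 0.026–0.027 at $\alpha = 0.025$) that comes from
treating t statistics as normal; `mode = "z"` gives the exact-normal
engine, under which the realized level stays at or below nominal.

`runStudy()` evaluates several designs over an effect grid with common
random numbers: each replicate's stage draws are stored as a normal deviate
plus a chi-square *probability*, and each design maps the shared
probability through the quantile function at its own degrees of freedom.
Differences between designs are then differences between decision rules,
not between random streams. Effect sizes use independent streams, and the
seed and replicate count are recorded in every output.

The default study grid is $\delta \in \{0, 0.1, \dots, 0.6\}$ with
$10^5$ replicates per effect size (standard error of a power estimate at
most 0.0016); the packaged acceptance run and the test suite use
$2\times10^4$ replicates per effect size, which resolves power to about
$\pm 0.01$ and expected sample size to about $\pm 2$ while keeping the
whole five-design study under ten seconds.

## What the generator does and does not emulate

The engine generates exactly the model the designs are calibrated for:
normal endpoints, common variance, outcomes observed immediately at
recruitment, no drift, no dropout, no overrunning patients between the
interim cut and the stopping decision. Passing tests therefore demonstrate
internal correctness of boundaries, conditional power, rules and scores —
not robustness to non-normal endpoints, unequal variances, delayed
responses or time trends, none of which are modelled. Binary and
time-to-event endpoints, recalculation at the *second* interim analysis,
and unequal $n_2 \ne n_3$ optimization are out of scope; the rule
machinery accepts unequal sizes in its formulas but the shipped optimizers
impose $n_2 = n_3$.

## Known limitations

* The trade-off rules' behaviour at small interim statistics is sensitive
  to the prior and the cost convention; both are documented choices, and
  the `optN` default reproduces its calibration target exactly while its
  expected sample size at effects well below the planning value is more
  generous than the leanest conceivable variant.
* Boundaries are Pocock-type constants only; O'Brien–Fleming and
  alpha-spending families are not implemented.
* The conditional score needs at least two continuing trials; studies run
  at extreme effects (where stage one always decides) cannot be scored
  conditionally.
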