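---
title: "A resource-budget model of sex allocation, pollen density, and fertilization success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A resource-budget model of sex allocation, pollen density, and fertilization success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenalloc)
```

## The model

`pollenalloc` treats the generative reproduction of a plant population as
three sequential modules, viewed collectively at the population level
(no per-individual accounting).

**Gamete production.** A budget $R$ of gametic production resources
(abstract energy units) is split by the sexual allocation
$\alpha \in (0,1)$: a fraction $\alpha$ produces ovules at cost $r_f$
each, the rest produces pollen at cost $r_m$ each, so

$$F = \alpha R / r_f, \qquad M = (1-\alpha) R / r_m,
\qquad r_f F + r_m M = R .$$

$F$ and $M$ are kept real-valued in all analytic functions — the model's
curves and optima are continuous in $\alpha$, and rounding would distort
them; integerization happens only at the hand-off to the simulator.
Equivalently, $\alpha$ is determined by the two pollen–ovule ratios:
$\alpha = 1/(1 + (r_m/r_f)(M/F))$ (`alpha_from_ratios()`).

**Pollen dispersal.** The population's pollen disperses over a bounded
range partitioned into $h$ spatial units, each the size of one ovule's
pollen-catching surface (stigma, or pollination drop in some conifers).
A proportion $w \in (0,1]$ of the pollen is retained within the range and
scatters uniformly and independently over the $h$ units; $1-w$ is lost.
The mean number of pollen per unit — the pollen density — is $d = wM/h$.
Uniform dispersal is deliberately a reference scenario: it is the
assumption that lets the population be treated collectively, and it is
what distance-dependent kernels would be compared against.

**Ovule fertilization.** Each unit holds at most one ovule and all $F$
ovules lie in the range (hence the hard constraint $h \ge F$). An ovule
is fertilized when at least one retained pollen lands on its unit, giving
the occupancy probability

$$E(P) = 1 - \left(1 - \tfrac{1}{h}\right)^{wM},$$

an expected fertilized count $E(F^*) = F \cdot E(P)$, and an occupancy
variance

$$V(P) = \left(1-\tfrac1F\right)\left(1-\tfrac2h\right)^{wM}
 - \left(1-\tfrac1h\right)^{wM}
   \left[\left(1-\tfrac1h\right)^{wM} - \tfrac1F\right],$$

which collapses to the Bernoulli variance $x(1-x)$ at $F = 1$. With the
compound variable $b = (1-1/h)^{wR/r_m}$ — the probability a unit stays
empty were the whole budget spent on pollen — everything becomes a
function of $\alpha$ alone: $E(P) = 1 - b^{1-\alpha}$.

```{r}
d <- dispersal_params(h = 1000, w = 1)
expected_fertilized(reproduction_params(R = 5000, r_f = 10, r_m = 1,
                                        alpha = 0.5), d)
```

## The optimal allocation

$E(F^*)$ is strictly concave in $\alpha$ with a unique interior maximum
$\hat\alpha$, the root of

$$b^{1-\hat\alpha}(\hat\alpha \ln b - 1) + 1 = 0 .$$

No closed form for $\hat\alpha$ exists, so `optimal_allocation()` finds
the root by bracketed bisection/interpolation (`stats::uniroot`, bracket
$(10^{-9}, 1-10^{-9})$, tolerance $10^{-12}$ on $\alpha$) and *always*
cross-checks it against direct bounded maximization of $E(F^*)$
(`stats::optimize`); the two must agree to $10^{-8}$ and the residual of
the implicit equation is reported alongside the result. Two structural
facts hold at the interior optimum and are enforced as tested
invariants: $\hat\alpha > 0.5$ — maximizing fertilization always invests
more than half the budget in ovules, whatever the costs — and
$\hat\alpha$ rises when $R$ or $w$ rise or $r_m$ or $h$ fall.

```{r}
optimal_allocation(R = 5000, r_f = 10, r_m = 1, disp = d)
optimal_allocation(R = 1000, r_f = 10, r_m = 1, disp = d)
```

Concavity also means every achievable level below the maximum is reached
by exactly two *dual* allocations bracketing $\hat\alpha$ — one trades
many ovules at low $E(P)$, the other few ovules at high $E(P)$.
`dual_allocations()` locates them by bisection on each flank (200
iterations, no tie-breaking needed) and verifies both by forward
evaluation.

**The capacity bound.** Since each unit holds at most one ovule,
allocations with $F > h$ are inadmissible; the optimizer restricts the
search to $\alpha \le h\,r_f/R$ and flags a binding bound with
`constrained = TRUE`. The bias and monotonicity statements above concern
the interior optimum, so their property tests draw parameter sets with
$h \ge R/r_f$, where the whole allocation range is admissible; when the
bound binds, the constrained argmax is the boundary and can legitimately
fall below 0.5.

## Compensating a resource decline

A sudden decline to $qR$, $q \in (0,1]$, scales both gamete counts
(`apply_decline()`): $F' = qF$, $M' = qM$, depressing $E(F^*)$. Three
single-parameter adjustments can, under conditions, restore the
pre-decline expectation:

* **Re-allocation** (`compensable_by_allocation()`): feasible iff the
  baseline $E(F^*)$ does not exceed the post-decline maximum
  $\max_\alpha E(F^{*\prime})$. When feasible, the dual pair under $qR$
  achieves it; a population already at its optimum has no headroom.
* **Retention** (`compensate_retention()`): raise $w$ to
  $w' = \ln(1 - E(P)/q) \,/\, (qM \ln(1 - 1/h))$ so that
  $E(P') = E(P)/q$. Feasible iff $q > E(P)$ — the remaining resource
  fraction must exceed the old fertilized proportion, a non-obvious
  severity limit shared by both density strategies — and $w' \le 1$.
* **Range shrinkage** (`compensate_range()`): shrink $h$ to
  $h' = 1/\bigl(1 - (1 - E(P)/q)^{1/(wqM)}\bigr)$. Feasible iff
  $q > E(P)$ and $h' \ge qF$, since the shrunken range must still hold
  every ovule. $h'$ is returned real-valued; `round_up = TRUE` gives the
  next integer for simulator hand-off (slightly under-compensating, by
  design, rather than violating the capacity bound).

Infeasibility is always a structured verdict with a reason code
(`exceeds_new_maximum`, `decline_too_severe`, `retention_ceiling`,
`range_below_ovule_count`), never an exception, so grid sweeps such as
`compensation_map()` never abort. Every feasible adjustment is verified
by *forward evaluation* of the adjusted parameter set — the inversion
formula proposes, the model disposes — and must reproduce the baseline
to $10^{-8}$ relative.

```{r}
sc <- decline_scenario(reproduction_params(5000, 10, 1, 0.5),
                       dispersal_params(h = 1000, w = 0.4), q = 0.9)
compensate_retention(sc)
compensate_range(sc)
```

## The Monte Carlo simulator

`simulate_dispersal()` is the balls-in-bins oracle for the closed forms:
per replicate the retained pollen land uniformly on the $h$ units and
the fertilized count is the number of the $F$ designated ovule-units
receiving at least one pollen. Uniformity makes the designation
exchangeable, so units $1..F$ are used (a test checks this against an
independent simulator that designates a random subset each replicate).
The inner loop is compiled (Rcpp) and draws from R's RNG, so
`set.seed()` reproduces samples bit-for-bit.

Whether retention acts on each pollen independently is left open by the
model statement "a proportion $w$ remains within the range", so both
readings are provided: **stochastic** retention thins $M$ binomially at
probability $w$ (mean exactly $wM$; the default, and the natural reading
of random dispersal), while **deterministic** retention fixes the count
at $\mathrm{round}(wM)$, matching the closed forms' fixed exponent and
therefore used in all oracle-agreement tests.

Validation problem sizes: the property suite checks mean and variance of
$P$ against the closed forms within three standard errors on 20 randomly
drawn integer parameter sets ($F$ 20–200, $M$ 100–2000, $h$ up to 2000)
at $10^5$ replicates each — sizes at which the standard errors are small
enough to make the variance formula's correctness visible, while the
whole suite stays fast.

## Numerical choices

* Powers $(1-1/h)^{wM}$ are computed as $\exp(wM \log1p(-1/h))$
  (and $E(P)$ via `expm1`), stable for large $h$ where `1 - 1/h` loses
  precision; the documented agreement tolerance between the two printed
  forms of $V(P)$ is $10^{-12}$ (absolute — $V(P) \le 1/4$).
* $h = 1$ is a documented limit convention, $E(P) = 1$ for $wM > 0$
  (every pollen lands in the single unit), not an error; $h \le 1$ is an
  error for $b$ (degenerate $b = 0$) and $h \le 2$ for $V(P)$.
* $w = 1$ is admitted (fully retained pollen is a meaningful and common
  reference case); $w = 0$ is rejected.
* Tiny negative $V(P)$ from round-off is clamped to 0.
* Inversion guards: at $q = 1$ the retention solution is exactly
  $w' = w$; a $10^{-12}$ tolerance absorbs round-off at the $w' \le 1$
  and $h' \ge qF$ boundaries so the no-decline case is classified
  feasible, as it must be.

## Design decisions where the design was open

* **Fertilization threshold.** A minimum pollen requirement per ovule
  could be generalized; the model throughout uses "at least one", and
  only that rule is implemented.
* **Continuous $h$ in analytics.** Range sizes like $h' = 71.5$ arise
  naturally from the inversion; the analytic layer accepts real $h$, the
  simulator demands integers. Stated in the documentation rather than
  silently rounded.
* **Re-allocation feasibility follows the inequality, not the
  illustration.** The feasibility condition
  $E(F^*) \le \max E(F^{*\prime})$ is implemented literally and verified
  against a grid-search oracle. One published illustration of
  re-allocation compensation (a suboptimal baseline $\alpha^\circ=0.35$
  with $h = 10000$ and $q = 0.8$) is *infeasible* under this inequality
  (baseline 48.6 vs post-decline maximum 36.3); the package trusts the
  inequality, and its tests construct feasible scenarios (e.g.
  $\alpha^\circ = 0.15$, $q = 0.8$) instead.
* **Under-specified figure reproductions.** The density-compensation
  illustrations (the retention-ceiling and minimum-range panels and the
  $(w,h)$ feasibility maps) do not come with a fully stated parameter
  set, so `run_figure_table(5)` and `run_figure_table(6)` require
  explicit overrides rather than guessing defaults; the *structural*
  claims — a retention ceiling exists, a minimum feasible $h$ exists,
  milder declines have larger feasible regions — are covered by the
  property suite at the package's own parameter choices.

## What the model does and does not capture

Passing tests show the implementation agrees with its own closed forms
and their stochastic counterpart under the model's assumptions: uniform
(distance-free) dispersal, at most one ovule per spatial unit, a single
pollen sufficing for fertilization, collective population-level gamete
accounting, and independence of $R$ from $w$ and $h$. Real populations
violate several of these — dispersal kernels decay with distance,
stigmas cluster, pollen and resources co-vary with the same weather —
so agreement here does not certify predictions for field data; it
certifies the arithmetic of the reference scenario against which such
complications can be measured. Compensation by cheapening gametes
(lowering $r_f$ or $r_m$) is out of scope, as is any physiological or
evolutionary mechanism that would implement the parameter changes.
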