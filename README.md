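# pollenalloc

Sex allocation, pollen density, and fertilization success in plant
populations under a limited resource budget.

`pollenalloc` is for quantitative plant ecologists and population
biologists who want to reason about pollen limitation: how a population
should split its gametic resources between ovules and pollen, and
whether a sudden loss of resources can be compensated by re-allocating
them or by concentrating pollen. There is no external data; the inputs
are a handful of interpretable scalar parameters.

## The model

A budget `R` of gametic production resources is split by the sexual
allocation `α ∈ (0,1)`:

    F = αR/r_f   ovules,     M = (1−α)R/r_m   pollen,     r_f·F + r_m·M = R

A proportion `w` of the pollen is retained within a dispersal range of
`h` spatial units (each the size of one ovule's pollen-catching surface)
and scatters uniformly over it. An ovule is fertilized when at least one
pollen lands on its unit, so the expected fertilized proportion is the
occupancy probability

    E(P) = 1 − (1 − 1/h)^(wM) = 1 − b^(1−α),   b = (1 − 1/h)^(wR/r_m)

and the expected number of fertilized ovules is `E(F*) = F·E(P)`.
`E(F*)` is strictly concave in `α`; its unique maximizer `α̂` solves the
implicit equation

    b^(1−α̂)·(α̂·ln b − 1) + 1 = 0

and always satisfies `α̂ > 0.5` — the optimum invests more than half of
the budget in ovules. After a decline of resources to `qR`, the
pre-decline `E(F*)` can sometimes be restored by re-allocation (feasible
iff `E(F*) ≤ max E(F*′)`), by raising retention to `w′` (feasible iff
`q > E(P)` and `w′ ≤ 1`), or by shrinking the range to `h′` (feasible
iff `q > E(P)` and `h′ ≥ qF`). A compiled Monte Carlo balls-in-bins
simulator provides the empirical distribution of `P` that validates the
closed forms, including the occupancy variance `V(P)`.

## Worked example

```r
library(pollenalloc)

d <- dispersal_params(h = 1000, w = 1)
optimal_allocation(R = 5000, r_f = 10, r_m = 1, disp = d)
#> Optimal sexual allocation: alpha_hat = 0.699392
#>   max E(F*) = 271.9636 fertilized ovules
#>   b = 0.00672111, residual of implicit equation = 9.77e-15
```

With 5000 resource units, ovules costing 10 units, pollen 1 unit, and
all pollen retained in a 1000-unit range, the optimum allocates 69.9% of
the budget to ovules and expects about 272 fertilized ovules. If
resources collapse to one fifth:

```r
optimal_allocation(R = 1000, r_f = 10, r_m = 1, disp = d)
#> Optimal sexual allocation: alpha_hat = 0.557172
#>   max E(F*) = 19.9426 fertilized ovules
#>   b = 0.367695, residual of implicit equation = 5.33e-15
```

the optimum shifts toward pollen (55.7%) and the attainable maximum
crashes to about 20. Compensation of a milder decline (`q = 0.9`) for a
population at `α = 0.5` with low retention `w = 0.4`:

```r
sc <- decline_scenario(reproduction_params(5000, 10, 1, 0.5),
                       dispersal_params(h = 1000, w = 0.4), q = 0.9)
compensate_retention(sc)
#> Compensation by retention (q = 0.9): feasible
#>   adjusted w' = 0.538639
#>   restores E(F*) = 158.076 (baseline 158.076)
compensate_range(sc)
#> Compensation by range (q = 0.9): feasible
#>   adjusted h' = 742.741
#>   restores E(F*) = 158.076 (baseline 158.076)
```

Raising retention from 0.40 to 0.54, or shrinking the range from 1000 to
743 units, each restores the pre-decline expectation of 158 fertilized
ovules exactly.

A command-line wrapper is installed at `inst/cli/pollenalloc`
(subcommands `evaluate`, `optimize`, `duals`, `compensate`, `simulate`,
`figure`, `sweep`; parameters via `--R 5000 --r_f 10 ...` flags or a
flat key-value `--config` file; CSV or JSON output via `--out` and
`--format`).

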