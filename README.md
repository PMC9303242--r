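# signalbalance

Honest sexual signaling as balanced resource allocation.

Costly-signaling theory asks what keeps ornament size informative about the
quality of its bearer. `signalbalance` implements the *balance* view of this
question: an individual with resource budget `R` (its "quality") splits
investments `u₁, …, uₙ ≥ 0`, with `Σuᵢ = R`, among positive fitness
components `xᵢ(uᵢ)` — typically mating success `x₁` and viability `x₂` —
that combine into fitness either additively (`W = Σxᵢ`) or multiplicatively
(`W = Πxᵢ`). At an interior optimum the marginal fitness returns on all
funded components are equal; under the multiplicative rule this means equal
*elasticities* (selection gradients)

    Sᵢ(uᵢ) = xᵢ′(uᵢ)/xᵢ(uᵢ),  S₁(u₁*) = S₂(u₂*),

and for an unfunded component `j`, `Sᵢ(uᵢ*) ≥ Sⱼ(0)`. Because `Sᵢ` tends to
fall as a component grows, the multiplicative optimum keeps investments
roughly balanced, so optimal signal investment `u₁*` usually rises with the
budget — signaling is then **honest** (big signal ⇒ high quality). Honesty
can only break down when viability returns accelerate strongly enough that

    x₂″/x₂′ > x₂′/x₂   (equivalently m(u) = x₂″x₂ − (x₂′)² > 0),

a necessary — not sufficient — condition; conversely, a strictly decreasing
`S₂` guarantees honesty. The package turns all of this into computable
objects: component functions with analytic derivatives, a global simplex
optimizer, allocation paths over budget grids with corner and discontinuity
annotation, honesty reports, and the fitness-set geometry (phenotype sets,
isoclines, optimal loci) used to draw such trade-offs.

## Worked example

```r
library(signalbalance)

# Concave mating success x1 = 1.5 u - 0.7 u^2 against linear viability
# x2 = u, additive fitness: one slope-matching point, so every budget
# picks the same signal — no information in the ornament.
sa <- load_scenario("fig1_additive")
a  <- optimize_allocation(sa, R = 1)
round(c(u1 = a$u[1], x1 = a$x[1]), 3)
#>    u1    x1
#> 0.357 0.446

# The same components under multiplicative fitness are honest:
sm   <- load_scenario("fig1_multiplicative")
path <- allocation_path(sm, seq(0.2, 1.4, length.out = 120))
honesty_report(path)
#> <honesty_report> fig1_multiplicative on R in [0.2, 1.4]
#>   honest: TRUE
#>   viability selection gradient strictly decreasing: TRUE

# A sigmoidal signal payoff gives a richer but still honest pattern:
# a no-signal corner, then a discontinuous jump near R = 2.9.
s3 <- load_scenario("fig3")
p3 <- allocation_path(s3, seq(0, 6, length.out = 601))
p3
#> <allocation_path> fig3: 601 budgets in [0, 6]
#>   discontinuities: 1 (near R = 2.899)
#>   corner segments: 3
```

The same analyses are scriptable from a shell via the bundled CLI
(`inst/cli/signalbalance`):

```sh
Rscript inst/cli/signalbalance optimize --scenario fig1_additive --R 1.0
Rscript inst/cli/signalbalance honesty --scenario fig3 --rmin 0 --rmax 6 \
    --steps 500 --out report.json
Rscript inst/cli/signalbalance figure --name fig1 --out curves/
```

Custom scenarios are YAML configs (`--config`); see
`?read_scenario_config`. The methods vignette
(`vignettes/balance-model.Rmd`) documents the model, the numerical choices
and the random-scenario generator used by the property tests.

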