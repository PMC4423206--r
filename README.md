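# rangexp

Eco-evolutionary dynamics of range expansions with explicit
consumer-resource interactions.

## The problem

During a range expansion or biological invasion, the best dispersers
accumulate at the advancing front ("spatial selection") and reproduce
there under low competition. If dispersal investment trades off against
foraging ability, range-margin populations evolve high dispersal and
poor foraging — and, because poor foragers deplete their resources less
("prudent predation"), the margin can sustain *higher* population
densities than the long-established core. This inversion of the textbook
expectation is invisible to logistic (r-K) thinking and only emerges
when resources are modelled as a dynamic state variable.

`rangexp` is for ecologists and evolutionary biologists who want to

* fit logistic and Rosenzweig-MacArthur consumer-resource models to
  growth curves (e.g. protist microcosm data) and compare them by AIC,
* extract resource-dependent fitness, `g(N) = e·aN/(N+b) − d_T`, from a
  fitted consumer-resource model,
* simulate trait evolution during range expansions with an
  individual-based model of consumers on a linear landscape of
  Beverton-Holt resources, under a simplex-constrained
  dispersal-foraging trade-off,
* summarise movement trajectories (velocity, circular s.d. of turning
  angles) and generate faithful synthetic data for all of the above.

## The models at a glance

Consumer dynamics (type II functional response, assimilation `e`,
death rate `d_T`):

    dT/dt = e · aN/(N+b) · T − d_T · T
    dN/dt = r0 · N · (1 − N/K_N) − aN/(N+b) · T

Logistic baseline: `dT/dt = r·T·(1 − T/K)`. Fits are compared with the
Gaussian AIC convention `AIC = n·ln 2π + n·ln(rss/n) + n + 2(k+1)`;
`ΔAIC = AIC(logistic) − AIC(consumer-resource)` is positive when the
mechanistic model wins.

In the simulator each individual carries investment fractions
`(f_d, f_a, f_1/b, f_else)` summing to one; phenotypes are
`d = min(1, f_d·d_max)`, `a_i = f_a·a_max`, `1/b_i = f_1/b·(1/b)_max`.
Generations alternate Beverton-Holt resource growth, randomized
sequential foraging, Poisson reproduction with mutation
(`p = 0.001`, s.d. 0.2, renormalized to the simplex), and natal
dispersal with mortality `μ`.

## Worked example

Fit both growth models to a synthetic range-core growth curve and
compare them:

```r
library(rangexp)

sc <- generate_core_margin_scenario(seed = 1)
core <- pool_replicates(sc$curves[sc$curves$treatment == "core",
                                  c("replicate", "time_h", "density_per_ml")])
fl <- fit_logistic(core)
fc <- fit_consumer_resource(core)   # r0 = 0.24, K_N = 3.6e7 fixed
compare_models(fl, fc)
#> Model comparison (Gaussian AIC):
#>   AIC logistic:           183.712 
#>   AIC consumer-resource:  139.208 
#>   delta AIC (logistic - consumer-resource): 44.5 
#>   preferred model: consumer_resource
```

The consumer-resource model wins decisively (ΔAIC ≈ 45): the pooled
curve overshoots and settles, a shape logistic growth cannot express.
The fitted fitness curve then gives per-capita growth as a function of
resource availability, `fitness_curve(fc, units = "K_N")`.

Run the individual-based simulator at its headline configuration
(`a_max = 0.03`, `e = 700`, `(1/b)_max = 0.02`, `λ0 = 4`, `K = 50`,
`μ = 0`, `d_max = 3`):

```r
run <- run_simulation(sim_config(), seed = 7)
summary(run)
#> Range-expansion summary (final generation 1105 )
#>   mean density   core  5926.74   margin  8710.24
#>   mean dispersal core   0.0207   margin   0.5782
#>   mean 1/b       core  0.00917   margin  0.00742
```

After the 1,000-generation burn-in the expansion crossed the landscape
in ~100 generations. The range margin (patches 75-99) evolved a ~28-fold
higher dispersal probability and ~20 % lower foraging efficiency than
the core (patches 0-20) — and carries ~47 % more population
density (core density is averaged over the final 20 generations to
integrate over its resource-driven boom-bust cycles): efficient core
foragers have ground their resources down, inefficient margin foragers
have not. `plot(run)` draws the spatial
profile; `sweep_simulations()` replicates runs over the sensitivity
grids.

Movement paths are summarised per sample:

```r
paths <- generate_crw_paths(speed = 50, circ_sd = 0.5, n_paths = 100, seed = 3)
population_movement(path_stats(paths, min_duration = 4))
#>   n_paths velocity  circ_sd
#> 1     100       50 0.499805
```

## Package layout

* `R/cr_models.R` — deterministic models, ODE integration, fitness
* `R/fit.R` — nonlinear least squares, AIC comparison (`growth_fit` S3)
* `R/ibm.R` + `src/ibm.cpp` — individual-based simulator
  (`range_expansion` S3), parameter sweeps
* `R/trajectory.R` — movement-path statistics
* `R/synthetic.R` — seeded generators and the core/margin scenario
* `R/pipeline.R` — YAML/JSON-driven orchestration with run manifests
  (`inst/scripts/rangexp-pipeline.R` is a thin CLI wrapper)
* `vignettes/range-expansion-methods.Rmd` — models, assumptions,
  numerical choices and limitations
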