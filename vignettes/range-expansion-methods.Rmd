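---
title: "Models and methods: consumer-resource dynamics and trait evolution during range expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: consumer-resource dynamics and trait evolution during range expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

When a population expands its range — an invasion front moving through
empty habitat — the individuals that reach the front first are the best
dispersers, and they reproduce there under low competition. This *spatial
selection*, together with kin competition among front founders, favours
ever-higher dispersal at the range margin. If investment in dispersal
trades off against investment in resource acquisition, margin populations
should also become *worse foragers*. Counter-intuitively, worse foraging
can mean **higher** population densities: efficient foragers in the range
core deplete their resources to low levels ("imprudent predation"),
whereas the inefficient foragers at the margin leave resources standing
and so sustain more consumers. Seeing this requires treating resources as
a dynamic state variable rather than folding them into a fixed carrying
capacity; `rangexp` provides both the deterministic consumer-resource
machinery and a stochastic individual-based simulator to study the
phenomenon, modelled on protist (*Tetrahymena*) microcosm systems feeding
on bacteria.

## Deterministic growth models

Two models of a consumer growth curve are implemented.

**Logistic (r-K) growth.**
\[
\frac{dT}{dt} = r\,T\left(1 - \frac{T}{K}\right),
\qquad
T(t) = \frac{K}{1 + (K/T_0 - 1)e^{-rt}},
\]
with growth rate \(r\) (per hour), carrying capacity \(K\) and initial
density \(T_0\) (individuals·ml\(^{-1}\)). This is the phenomenological
baseline; it implicitly assumes resources are always at equilibrium.

**Rosenzweig-MacArthur consumer-resource dynamics.**
\[
\frac{dT}{dt} = e\,\frac{aN}{N+b}\,T - d_T\,T,
\qquad
\frac{dN}{dt} = r_0 N\left(1-\frac{N}{K_N}\right) - \frac{aN}{N+b}\,T,
\]
with assimilation coefficient \(e\) (offspring per resource unit), type II
functional response with maximum intake \(a\) and half-saturation constant
\(b\) (so \(1/b\) is *foraging efficiency*), consumer death rate \(d_T\),
and logistically growing resources (\(r_0\), \(K_N\)). The
resource-dependent fitness is the birth-minus-death rate
\(g(N) = e\,aN/(N+b) - d_T\): strictly increasing in \(N\), bounded by
\(e\,a - d_T\), and equal to \(-d_T\) when resources are absent.

Integration uses deSolve's `lsoda` with a compiled right-hand side,
`rtol = 1e-8` and per-state absolute tolerances scaled to the state
magnitudes (consumer densities are \(10^2\)–\(10^4\), resources
\(10^6\)–\(10^7\); a single absolute tolerance would be meaningless for
one of the two). Output states are clipped at zero; solver failures raise
an error carrying the last valid time rather than returning partial
output silently.

## Fitting and model comparison

`fit_growth()` fits either model to a `(time, density)` series by
nonlinear least squares. Replicate curves of a treatment are averaged at
shared time points first (`pool_replicates()`); per-replicate fitting
remains available by simply not pooling.

* *Logistic*: the self-starting logistic (`nls` + `SSlogis`) is tried
  first, with a Levenberg-Marquardt fallback started from heuristics
  (\(K \leftarrow\) maximum density, \(T_0 \leftarrow\) first positive
  density, \(r \leftarrow\) initial log-density slope). Flat or
  too-short series are an error, never a silent degenerate fit.
* *Consumer-resource*: free parameters \((e, a, b, d_T, T_0)\),
  positivity enforced by optimizing logarithms, resources fixed at the
  independently measured bacterial values (defaults \(r_0 = 0.24\),
  \(K_N = 3.6\times 10^7\)) with \(N_0 = K_N\) — a growth assay starts in
  freshly bacterized medium, i.e. at resource capacity. The
  least-squares surface is multimodal, so the optimizer is restarted
  from a deterministic Latin-hypercube of 20 points spanning three
  decades around data-driven seeds; all starts are screened by their
  initial residual sum of squares and the most promising (plus the
  heuristic seed itself) are polished with Levenberg-Marquardt
  (`minpack.lm::nls.lm`, `ftol = 1e-10`). The whole procedure is a pure
  function of the data: an internal fixed stream generates the
  hypercube and the caller's RNG state is untouched.

AIC uses the full Gaussian likelihood with the error variance counted as
a parameter,
\(\mathrm{AIC} = n\ln 2\pi + n\ln(\mathrm{rss}/n) + n + 2(k+1)\),
the same convention as `AIC()` on `lm`/`nls` objects, so differences are
comparable across software. `compare_models()` reports
\(\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{logistic}} -
\mathrm{AIC}_{\mathrm{CR}}\); positive values favour the
consumer-resource model.

### What the data can and cannot identify

Consumer-only time series constrain the fitness curve \(g(N)\) over the
range of resource densities the trajectory actually visits. In the
damped regime used by the synthetic scenario, resources fall from
\(K_N\) to roughly \(0.6\,K_N\) and no further; below that the fitted
curve is extrapolation. Individual parameters ride a ridge — \(e\) and
\(a\) trade off strongly, and \(d_T\) is only pinned down when the curve
expresses a death phase within the observation window — but compound
quantities (\(e\,a\), and \(g(N)\) inside the visited range) are stable.
`evaluate_scenario()` therefore assesses core-versus-margin fitness
ordering on \(N/K_N \in [0.6, 1]\), and the parameter-recovery checks in
the test suite target \(e\,a\) rather than \(e\) and \(a\) separately.

## The individual-based range-expansion model

A linear landscape of 100 patches; consumers live in the leftmost 5
("range core") and may expand rightward. Resources in every patch follow
the Beverton-Holt map
\(N' = \lambda_0 N / (1 + \alpha N)\), \(\alpha = (\lambda_0-1)/K\),
whose fixed point is \(K\); resources do not disperse and do not evolve.

Each individual carries a simplex-constrained investment vector
\((f_d, f_a, f_{1/b}, f_{\mathrm{else}})\), summing to one, that encodes
a dispersal-foraging trade-off. Phenotypes are
\(d = \min(1, f_d^{\theta} d_{\max})\),
\(a_i = f_a^{\theta} a_{\max}\),
\(1/b_i = f_{1/b}^{\theta} (1/b)_{\max}\); the exponent \(\theta\)
(default 1) gives the concave/convex trade-off variants. Because
\(d_{\max} \in \{2,3,4\}\), the product \(f_d\,d_{\max}\) can exceed one;
it is interpreted as a dispersal *probability* and capped at 1 (selection
pressure below the cap is unchanged). The `f_else` axis relaxes the
strict coupling between dispersal and foraging; it consistently evolves
toward zero. A four-way variant adds \(f_e\) with
\(e_i = f_e^{\theta} e_{\max}\) on a five-way simplex.

Generations are discrete and non-overlapping, in fixed order:

1. **Resource growth** in every patch (Beverton-Holt; optional inflow
   replenishes up to a fraction of \(K\), optional refuge protects a
   fraction of \(K\) from consumption — both default to off).
2. **Foraging**: within each patch residents harvest sequentially in
   uniformly random order; each takes
   \(\min\!\big(a_i N_{\mathrm{avail}} / (N_{\mathrm{avail}} + b_i),\,
   N_{\mathrm{avail}}\big)\) and availability is updated after every
   individual. Mass balance is exact: intakes sum to the resource
   decrement.
3. **Reproduction**: each adult produces
   \(\mathrm{Poisson}(e \cdot \mathrm{intake})\) offspring and dies.
   Offspring inherit the parental investment vector; each value mutates
   independently with probability \(p_{\mathrm{mut}} = 0.001\) by a
   Normal(0, 0.2) increment, negatives are reset to zero, and the vector
   is renormalized to the simplex. (A vector clipped entirely to zero —
   measure-zero rare — triggers a redraw of the mutation, since
   renormalizing a zero vector is undefined.)
4. **Natal dispersal**: with probability \(d\) the newborn attempts to
   move to one of the two neighbouring patches (uniform direction) and
   survives the attempt with probability \(1-\mu\).

Founders (10 per core patch; the count is a free configuration choice —
small enough to equilibrate during burn-in, large enough to avoid
instant extinction) start with uniformly random renormalized investment
vectors. A burn-in of 1,000 generations on the closed core lets the
genetic algorithm find evolutionarily stable trait values; during
burn-in the five core patches are wrapped into a ring so boundary
effects cannot bias the evolving traits. Afterwards the landscape opens
with reflecting boundaries (an edge individual drawing the outward
direction ends on its interior neighbour) and the expansion runs until
the front — the rightmost occupied patch — reaches the final patch, or
until the generation cap (default 5,000 expansion generations; burn-in
has its own fixed length). Extinction at any point flags the run rather
than raising an error. Per-patch density, mean dispersal probability,
mean foraging efficiency and resource level are recorded throughout.

The generation loop is compiled (C++ via Rcpp) and draws from R's RNG,
so a run is a pure function of configuration and seed; sweeps derive
per-replicate child seeds from a single root seed. At the headline
configuration (\(a_{\max}=0.03\), \(e=700\), \((1/b)_{\max}=0.02\),
\(\lambda_0=4\), \(K=50\), \(\mu=0\), \(d_{\max}=3\)) local populations
reach roughly \(10^4\) individuals per patch and a full run takes on the
order of ten seconds.

Established patches undergo pronounced resource-driven boom-bust cycles
(period around ten generations at \(\lambda_0 = 4\)), so comparing core
and margin densities from a single-generation snapshot samples an
arbitrary cycle phase. `summary()` of a run therefore averages the core
density over the final 20 recorded generations and compares it with the
freshly assembled margin at expansion completion; trait contrasts are
insensitive to this choice because traits change on a much slower
timescale than the resource cycles.

Sensitivity grids mirror the study design:
\(\lambda_0 \in \{1.5, 2, 4, 6, 8, 10\}\),
\(\mu \in \{0, 0.01, 0.1, 0.5\}\), \(d_{\max} \in \{2,3,4\}\),
\(a_{\max} \in \{0.01, 0.02, 0.03\}\),
\((1/b)_{\max} \in \{0.01, 0.02, 0.03\}\),
\(e \in \{700, 800, 900, 1000\}\), with `sweep_simulations()`
aggregating final spatial profiles (mean ± s.d.) across replicates.

## Movement trajectories

Tracked paths (25 frames/s, 20 s, i.e. 500 frames) are summarised by
**velocity** — mean per-step displacement divided by the frame interval
(net displacement is reported separately) — and by the **circular
standard deviation of turning angles**,
\(\sqrt{-2\ln \bar R}\) with \(\bar R\) the mean resultant length of the
signed heading changes between consecutive steps. Zero-length steps
carry no heading and are skipped; fewer than two valid angles yields
`NA` with a warning. \(\bar R\) is floored at \(10^{-12}\) so uniform
angles give a large finite value. Paths observed for less than 4 s are
discarded before analysis, and movement is summarised at the population
level (means across the paths of one sample). Units follow the input
coordinates; the package does not assume pixels or micrometres.

## Synthetic data

The generators make every stage testable without external downloads.

* `generate_growth_curves()` integrates a chosen truth from a 10-fold
  diluted start and observes each true density through small-aliquot
  counting: observed \(=\) Poisson(true \(\times\) 0.15 ml) / 0.15 ml.
  Poisson counting (rather than Gaussian density noise) matches
  small-volume microscopy and reduces to Gaussian at high counts. The
  schedule is daily over ten days with two extra early points.
* `generate_crw_paths()` produces correlated random walks with constant
  step length and wrapped-normal turning angles — for a wrapped normal
  the mean resultant length is exactly \(e^{-\sigma^2/2}\), so the
  circular-s.d. estimator is consistent by construction.
* `generate_core_margin_scenario()` bundles both: two consumer-resource
  truths differing **only** in foraging efficiency (core \(b = 3\times
  10^7\), margin \(b = 4.5\times 10^7\); shared \(e = 2\times 10^{-4}\),
  \(a = 1500\), \(d_T = 0.1\), \(r_0 = 0.24\), \(K_N = 3.6\times
  10^7\)), plus path sets whose nominal speed is 30 % higher at the
  margin. The truths were chosen once so that both curves rise, peak
  and settle within the 10-day window — the damped-overshoot shape that
  keeps all five consumer parameters identifiable. Strongly cycling
  parameterizations alias under daily sampling, and purely sigmoid ones
  never express the death phase, leaving \(d_T\) unidentified; both
  failure modes are excluded by design, not by fitting to any
  experimental data. Effect sizes target the qualitative core/margin
  ordering only, never absolute published densities.

What the generators deliberately do **not** emulate: measurement
artefacts of video tracking (segmentation errors, path breaks),
between-replicate biological variance (replicates differ only by
counting noise), resource evolution, and any feedback of sampling on
the culture. Passing the recovery tests therefore demonstrates that the
estimators invert the assumed data-generating process — not that real
microcosm data are free of further complications.

## Numerical choices and edge cases

* ODE tolerances (`rtol = 1e-8`) sit far below observational noise;
  the compiled RK right-hand side is cross-checked against an
  independent fixed-step RK4 oracle in the tests.
* Fitting rejects rather than guesses: flat series, fewer than five
  observations, all-zero densities and non-converging optimizations all
  raise errors.
* `forage()` treats zero foraging-efficiency investment as zero intake
  (an infinite half-saturation constant), not a division error.
* The dispersal cap, the all-zero mutation redraw, and the burn-in ring
  are all exercised directly by the test suite.
* Problem sizes in the tests: recovery studies use 50 replicate fits;
  simulator claims use 20 replicate runs at the headline configuration;
  micro-invariants (mass balance, simplex, determinism) run on
  thousands of random instances.

## Limitations

* The simulator is deliberately minimal: no density-dependent or plastic
  dispersal, no Allee effects, no resource dispersal or evolution, no
  two-dimensional landscapes, and no attempt to fit it to experimental
  data.
* The consumer-resource fit fixes \(r_0\), \(K_N\) and \(N_0\); it does
  not use resource time series, and absolute values of \(e\), \(a\) and
  \(d_T\) from consumer-only data should be interpreted through the
  identifiability lens above.
* Movement statistics assume uniform frame intervals and ignore
  localization error; velocities are unit-agnostic.
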