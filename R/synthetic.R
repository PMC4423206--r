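# Seeded synthetic-data generators: growth curves with small-aliquot
# counting noise, correlated random walks, and the packaged core-vs-margin
# scenario used for end-to-end pipeline checks.

#' Growth-curve sampling design
#'
#' Observation schedule and counting geometry of a microcosm growth assay:
#' daily samples over ten days with two extra early points, small-aliquot
#' counts (default 0.15 ml) and an initial dilution of the stock culture.
#'
#' @param times_h Observation times in hours (strictly increasing).
#' @param aliquot Counted sample volume in ml (> 0); density is observed
#'   as a Poisson count in this volume divided by the volume. `Inf` gives
#'   noise-free observations.
#' @param dilution Initial dilution factor applied to the generating
#'   model's `T0` (fresh medium start).
#'
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(times_h = c(0, 8, 16, seq(24, 240, by = 24)),
                            aliquot = 0.15, dilution = 10) {
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  if (aliquot <= 0) stop("aliquot must be > 0")
  if (dilution < 1) stop("dilution must be >= 1")
  structure(list(times_h = times_h, aliquot = aliquot, dilution = dilution),
            class = "sampling_design")
}

#' Generate replicate growth curves with counting noise
#'
#' Integrates the generating model (logistic or consumer-resource) from
#' the diluted initial density and observes each true density through
#' small-aliquot Poisson counting: observed = Poisson(true x aliquot) /
#' aliquot. Replicates are independent; a fixed seed makes the output
#' reproducible.
#'
#' @param truth A [logistic_params()] or [cr_params()] object.
#' @param design A [sampling_design()].
#' @param n_replicates Number of replicate curves.
#' @param seed Optional RNG seed.
#'
#' @return A data frame with columns `replicate`, `time_h`,
#'   `density_per_ml` (pass to [pool_replicates()] for the mean curve).
#' @export
generate_growth_curves <- function(truth, design = sampling_design(),
                                   n_replicates = 6, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.null(seed)) set.seed(seed)
  times <- design$times_h
  true_dens <- if (inherits(truth, "logistic_params")) {
    p <- logistic_params(truth$r, truth$K, truth$T0 / design$dilution)
    logistic_density(p, times)
  } else if (inherits(truth, "cr_params")) {
    p <- cr_params(truth$e, truth$a, truth$b, truth$d_T, truth$r0,
                   truth$K_N, T0 = truth$T0 / design$dilution, N0 = truth$N0)
    simulate_cr(p, times)$consumer
  } else {
    stop("truth must be logistic_params or cr_params")
  }
  out <- lapply(seq_len(n_replicates), function(r) {
    obs <- if (is.infinite(design$aliquot)) {
      true_dens
    } else {
      rpois(length(true_dens), true_dens * design$aliquot) / design$aliquot
    }
    data.frame(replicate = r, time_h = times, density_per_ml = obs)
  })
  do.call(rbind, out)
}

#' Generate correlated random walks
#'
#' Paths with constant step length `speed / fps` and wrapped-normal
#' turning angles of standard deviation `circ_sd`; initial headings are
#' uniform. Defaults mimic 20 s of video at 25 frames per second.
#'
#' @param speed Nominal speed (coordinate units per second, >= 0).
#' @param circ_sd Turning-angle s.d. in radians (>= 0); 0 gives straight
#'   paths.
#' @param n_paths Number of paths.
#' @param n_frames Frames per path.
#' @param fps Frames per second.
#' @param seed Optional RNG seed.
#'
#' @return A [as_movement_paths()] data frame.
#' @export
generate_crw_paths <- function(speed, circ_sd, n_paths = 100,
                               n_frames = 500, fps = 25, seed = NULL) {
  if (speed < 0 || circ_sd < 0) stop("speed and circ_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  step <- speed / fps
  out <- lapply(seq_len(n_paths), function(i) {
    turns <- if (circ_sd > 0) rnorm(n_frames - 2, 0, circ_sd) else
      numeric(n_frames - 2)
    head_ang <- cumsum(c(runif(1, -pi, pi), turns))
    x <- cumsum(c(0, step * cos(head_ang)))
    y <- cumsum(c(0, step * sin(head_ang)))
    data.frame(id = i, frame = seq_len(n_frames), x = x, y = y)
  })
  as_movement_paths(do.call(rbind, out), fps = fps)
}

#' Default generating truths of the packaged core/margin scenario
#'
#' Range-core and range-margin consumer-resource truths differing only in
#' foraging efficiency (the core forages more efficiently: smaller
#' half-saturation constant b), with equal assimilation, intake maximum
#' and death rate; and movement speeds differing by +30 percent at the
#' margin.
#'
#' @return A list with elements `core`, `margin` ([cr_params()] objects),
#'   `speed` (named vector, units per second) and `circ_sd` (named
#'   vector, radians).
#' @export
core_margin_truths <- function() {
  list(
    core = cr_params(e = 2e-4, a = 1500, b = 3e7, d_T = 0.1,
                     r0 = 0.24, K_N = 3.6e7, T0 = 500),
    margin = cr_params(e = 2e-4, a = 1500, b = 4.5e7, d_T = 0.1,
                       r0 = 0.24, K_N = 3.6e7, T0 = 500),
    speed = c(core = 50, margin = 65),
    circ_sd = c(core = 1.0, margin = 0.8)
  )
}

#' Generate a labelled core-versus-margin scenario
#'
#' End-to-end fixture: replicate growth curves from the two
#' [core_margin_truths()] consumer-resource models (differing only in
#' foraging efficiency) plus movement-path sets differing in speed.
#' Downstream fitting should recover the fitness ordering
#' growth_core(N) > growth_margin(N) and the velocity ordering
#' margin > core.
#'
#' @param seed RNG seed (required: scenarios are reproducible fixtures).
#' @param n_replicates Growth-curve replicates per treatment.
#' @param n_paths Movement paths per treatment.
#' @param design A [sampling_design()].
#' @param truths Generating truths, as from [core_margin_truths()]; pass
#'   identical core/margin parameters for a null (equal-truth) scenario.
#'
#' @return A list with `curves` (data frame: treatment, replicate, time_h,
#'   density_per_ml), `paths` (list of two `movement_paths`), and
#'   `truths`.
#' @export
generate_core_margin_scenario <- function(seed, n_replicates = 6,
                                          n_paths = 50,
                                          design = sampling_design(),
                                          truths = core_margin_truths()) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 4)
  curves <- do.call(rbind, lapply(c("core", "margin"), function(tr) {
    g <- generate_growth_curves(truths[[tr]], design, n_replicates,
                                seed = sub_seeds[[match(tr, c("core", "margin"))]])
    cbind(treatment = tr, g)
  }))
  paths <- list(
    core = generate_crw_paths(truths$speed[["core"]],
                              truths$circ_sd[["core"]], n_paths,
                              seed = sub_seeds[3]),
    margin = generate_crw_paths(truths$speed[["margin"]],
                                truths$circ_sd[["margin"]], n_paths,
                                seed = sub_seeds[4])
  )
  list(curves = curves, paths = paths, truths = truths)
}

#' Fit and evaluate a core/margin scenario
#'
#' Runs the downstream pipeline on a scenario from
#' [generate_core_margin_scenario()]: pools replicates per treatment, fits
#' the consumer-resource model to each pooled curve, evaluates the fitted
#' fitness curves on a shared resource grid, and summarises movement
#' velocities. The fitness ordering is assessed on resource densities from
#' 60 to 100 percent of the carrying capacity: the common-garden dynamics
#' deplete resources only down to the consumer-resource equilibrium (about
#' 0.6 of capacity at the default truths), so below that range the fitted
#' curves extrapolate beyond what the growth data constrain.
#'
#' @param scenario A scenario list from [generate_core_margin_scenario()].
#' @param N_frac Resource grid as fractions of `K_N` used for the ordering
#'   check.
#' @param ... Passed to [fit_consumer_resource()].
#'
#' @return A list with `fits`, `fitness` (data frame of both curves),
#'   `fitness_core_above` (logical: core fitness strictly above margin on
#'   the whole grid), `velocity` (named vector) and
#'   `velocity_margin_higher` (logical).
#' @export
evaluate_scenario <- function(scenario,
                              N_frac = seq(0.6, 1, length.out = 9), ...) {
  fits <- lapply(c("core", "margin"), function(tr) {
    pooled <- pool_replicates(scenario$curves[scenario$curves$treatment == tr,
                                              c("replicate", "time_h",
                                                "density_per_ml")])
    fit_consumer_resource(pooled, ...)
  })
  names(fits) <- c("core", "margin")
  fc <- lapply(fits, fitness_curve, N_grid = N_frac, units = "K_N")
  vel <- vapply(scenario$paths, function(p) {
    population_movement(path_stats(p, min_duration = 4))$velocity
  }, numeric(1))
  list(
    fits = fits,
    fitness = data.frame(N_frac = N_frac, core = fc$core$growth_rate,
                         margin = fc$margin$growth_rate),
    fitness_core_above = all(fc$core$growth_rate > fc$margin$growth_rate),
    velocity = vel,
    velocity_margin_higher = unname(vel["margin"] > vel["core"])
  )
}
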