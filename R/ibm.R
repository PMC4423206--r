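# Individual-based range-expansion simulator: configuration, trait
# operations, and the run/sweep interface around the compiled core.

#' Simulator configuration
#'
#' Validated configuration for the individual-based range-expansion model.
#' Consumers occupy a linear landscape of `n_patches` patches, each holding
#' a resource population with Beverton-Holt growth (rate `lambda0`,
#' capacity `K`). Each individual carries a simplex-constrained investment
#' vector (dispersal, maximum consumption, foraging efficiency, other
#' activities; optionally assimilation under `four_way`) that maps to its
#' phenotype via the trait maxima `d_max`, `a_max`, `invb_max` (and
#' `e_max`). Generations are non-overlapping: resource growth, randomized
#' sequential foraging, Poisson reproduction with mutation, then natal
#' dispersal with mortality `mu`.
#'
#' @param n_patches Landscape length in patches.
#' @param n_core Initially occupied (leftmost) patches; wrapped to a ring
#'   during burn-in.
#' @param burn_in Burn-in generations on the closed core ring.
#' @param max_gen Cap on expansion-phase generations after burn-in.
#' @param K Resource carrying capacity per patch.
#' @param lambda0 Resource growth rate of the Beverton-Holt map
#'   \eqn{N' = \lambda_0 N / (1 + \alpha N)}, \eqn{\alpha = (\lambda_0-1)/K};
#'   must be >= 1.
#' @param mu Dispersal mortality probability.
#' @param d_max,a_max,invb_max Trait maxima for dispersal probability,
#'   maximum consumption and foraging efficiency. Investment times maximum
#'   can exceed 1 for dispersal; the realized dispersal probability is
#'   capped at 1.
#' @param e Assimilation coefficient (offspring per resource unit).
#' @param p_mut Per-value mutation probability at inheritance.
#' @param mut_sd Mutation increment standard deviation.
#' @param four_way If `TRUE`, assimilation also evolves: the simplex gains
#'   an investment fraction `f_e` with `e_i = f_e^theta * e_max`.
#' @param e_max Maximum assimilation under `four_way` (defaults to `e`).
#' @param tradeoff_exponent Exponent `theta` of the investment-to-trait
#'   mapping; 1 is linear, `< 1` concave, `> 1` convex.
#' @param inflow Per-generation resource replenishment as a fraction of
#'   `K` (capped so patches do not exceed `K`); 0 disables.
#' @param refuge Fraction of `K` protected from consumption; 0 disables.
#' @param n_init_per_patch Founder individuals per core patch.
#' @param N_init Initial resource density per patch (defaults to `K`).
#' @param record_every Record the spatial state every this many
#'   generations (the initial, end-of-burn-in and final states are always
#'   recorded).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [run_simulation()], [sweep_simulations()]
#' @export
sim_config <- function(n_patches = 100, n_core = 5, burn_in = 1000,
                       max_gen = 5000, K = 50, lambda0 = 4, mu = 0,
                       d_max = 3, a_max = 0.03, invb_max = 0.02, e = 700,
                       p_mut = 0.001, mut_sd = 0.2, four_way = FALSE,
                       e_max = e, tradeoff_exponent = 1, inflow = 0,
                       refuge = 0, n_init_per_patch = 10, N_init = K,
                       record_every = 1) {
  cfg <- list(n_patches = as.integer(n_patches), n_core = as.integer(n_core),
              burn_in = as.integer(burn_in), max_gen = as.integer(max_gen),
              K = K, lambda0 = lambda0, mu = mu, d_max = d_max,
              a_max = a_max, invb_max = invb_max, e = e, p_mut = p_mut,
              mut_sd = mut_sd, four_way = isTRUE(four_way), e_max = e_max,
              tradeoff_exponent = tradeoff_exponent, inflow = inflow,
              refuge = refuge,
              n_init_per_patch = as.integer(n_init_per_patch),
              N_init = N_init, record_every = as.integer(record_every))
  num <- cfg[c("K", "lambda0", "mu", "d_max", "a_max", "invb_max", "e",
               "p_mut", "mut_sd", "e_max", "tradeoff_exponent", "inflow",
               "refuge", "N_init")]
  bad <- names(num)[!vapply(num, function(v) is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) stop("configuration fields must be finite and >= 0: ",
                        paste(bad, collapse = ", "))
  if (cfg$n_patches < 2) stop("n_patches must be >= 2")
  if (cfg$n_core < 1 || cfg$n_core > cfg$n_patches) {
    stop("n_core must be between 1 and n_patches")
  }
  if (cfg$lambda0 < 1) {
    stop("lambda0 must be >= 1 (lambda0 = ", lambda0,
         " makes the Beverton-Holt coefficient alpha negative)")
  }
  if (cfg$p_mut < 0 || cfg$p_mut > 1) stop("p_mut must lie in [0, 1]")
  if (cfg$mu > 1) stop("mu must lie in [0, 1]")
  if (cfg$burn_in < 0 || cfg$max_gen < 1) {
    stop("burn_in must be >= 0 and max_gen >= 1")
  }
  if (cfg$n_init_per_patch < 0) stop("n_init_per_patch must be >= 0")
  if (cfg$record_every < 1) stop("record_every must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Range-expansion simulator configuration\n")
  cat("  landscape:", x$n_patches, "patches,", x$n_core,
      "core patches,", x$n_init_per_patch, "founders/patch\n")
  cat("  schedule: burn-in", x$burn_in, "generations, expansion cap",
      x$max_gen, "\n")
  cat("  resources: K =", x$K, ", lambda0 =", x$lambda0,
      ", N_init =", x$N_init, "\n")
  cat("  traits: d_max =", x$d_max, ", a_max =", x$a_max,
      ", 1/b_max =", x$invb_max, ", e =", x$e,
      if (x$four_way) paste0(" (evolving, e_max = ", x$e_max, ")") else "",
      "\n")
  cat("  dispersal mortality mu =", x$mu, "; mutation p =", x$p_mut,
      ", sd =", x$mut_sd, "; trade-off exponent =",
      x$tradeoff_exponent, "\n")
  invisible(x)
}

n_traits <- function(config) if (config$four_way) 5L else 4L

#' Map investment fractions to a phenotype
#'
#' Converts a simplex-constrained investment vector into the realized
#' phenotype: dispersal probability `d = min(1, f_d^theta * d_max)`,
#' maximum consumption `a_i = f_a^theta * a_max` and foraging efficiency
#' `invb_i = f_invb^theta * invb_max` (plus `e_i = f_e^theta * e_max` under
#' the four-way trade-off). `theta = 1` is the linear trade-off; other
#' values give the convex/concave variants.
#'
#' @param traits Numeric vector (or matrix, rows = individuals) of
#'   investment fractions summing to 1: `(f_d, f_a, f_invb, f_else)` or
#'   `(f_d, f_a, f_invb, f_e, f_else)`.
#' @param config A [sim_config()].
#'
#' @return A named vector (or matrix) with components `d`, `a`, `invb`
#'   (and `e` if four-way).
#' @export
phenotype_from_traits <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- if (is.matrix(traits)) traits else matrix(traits, nrow = 1)
  check_simplex(m)
  th <- config$tradeoff_exponent
  out <- cbind(d = pmin(1, m[, 1]^th * config$d_max),
               a = m[, 2]^th * config$a_max,
               invb = m[, 3]^th * config$invb_max)
  if (config$four_way) out <- cbind(out, e = m[, 4]^th * config$e_max)
  if (!is.matrix(traits)) out[1, ] else out
}

check_simplex <- function(m, tol = 1e-12) {
  if (any(m < 0) || any(abs(rowSums(m) - 1) > tol)) {
    stop("traits must be non-negative and sum to 1 (within ", tol, ")")
  }
  invisible(m)
}

#' Beverton-Holt resource growth
#'
#' One generation of compensatory resource growth,
#' \eqn{N' = \lambda_0 N / (1 + \alpha N)} with
#' \eqn{\alpha = (\lambda_0 - 1)/K}; `K` is the fixed point. Optional
#' inflow replenishes up to `inflow * K` resources per generation (never
#' beyond `K`).
#'
#' @param N Resource density (>= 0), vectorized.
#' @param config A [sim_config()].
#' @return Updated density (same length as `N`).
#' @export
resource_growth <- function(N, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(N < 0)) stop("N must be >= 0")
  alpha <- (config$lambda0 - 1) / config$K
  out <- config$lambda0 * N / (1 + alpha * N)
  if (config$inflow > 0) {
    out <- ifelse(out < config$K,
                  pmin(out + config$inflow * config$K, config$K), out)
  }
  out
}

#' Sequential foraging within a patch
#'
#' Residents harvest resources one after another in uniformly random
#' order; each individual's intake is its type II functional response
#' evaluated at the currently available resource level (never more than
#' what remains above the refuge floor), and availability is updated after
#' every individual. Resources are conserved exactly:
#' `sum(intakes) == N - N_after`.
#'
#' @param traits Matrix of investment vectors (rows = residents).
#' @param N Resource density in the patch before foraging.
#' @param config A [sim_config()].
#'
#' @return A list with `intakes` (per resident, input order), `N_after`,
#'   and `order` (the randomized foraging order, 1-based).
#' @export
forage <- function(traits, N, config) {
  stopifnot(inherits(config, "sim_config"))
  if (N < 0) stop("N must be >= 0")
  m <- if (is.matrix(traits)) traits else matrix(traits, nrow = 1)
  check_simplex(m)
  .Call("C_forage_patch", m, as.numeric(N), config$a_max, config$invb_max,
        config$tradeoff_exponent, config$refuge * config$K,
        PACKAGE = "rangexp")
}

#' Poisson reproduction
#'
#' Draws offspring for each parent: the realized number of offspring is
#' Poisson with mean `e_i * intake` (assimilated resources), each offspring
#' inheriting the parental investment vector subject to [mutate_traits()].
#' Parents die (non-overlapping generations).
#'
#' @param traits Parent investment matrix (rows = parents).
#' @param intakes Resources harvested this generation, per parent.
#' @param config A [sim_config()].
#'
#' @return A list with `offspring_traits` (matrix) and `parent` (index of
#'   each offspring's parent).
#' @export
reproduce <- function(traits, intakes, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- if (is.matrix(traits)) traits else matrix(traits, nrow = 1)
  if (length(intakes) != nrow(m)) stop("one intake per parent required")
  if (any(intakes < 0)) stop("intakes must be >= 0")
  e_i <- if (config$four_way) {
    m[, 4]^config$tradeoff_exponent * config$e_max
  } else rep(config$e, nrow(m))
  noff <- rpois(nrow(m), e_i * intakes)
  parent <- rep(seq_len(nrow(m)), noff)
  off <- m[parent, , drop = FALSE]
  if (nrow(off) > 0) off <- mutate_traits(off, config)
  list(offspring_traits = off, parent = parent)
}

#' Mutate investment vectors
#'
#' With probability `p_mut` per trait value, adds a Normal(0, `mut_sd`)
#' increment; negative values are reset to zero and the vector is
#' renormalized to sum to one. If every value is clipped to zero the
#' mutation is redrawn. Unmutated vectors are returned bit-identical.
#'
#' @param traits Investment matrix (rows = individuals) on the simplex.
#' @param config A [sim_config()].
#' @param renormalize If `FALSE`, returns the clipped perturbations
#'   without projecting back to the simplex (diagnostic use).
#'
#' @return Mutated investment matrix.
#' @export
mutate_traits <- function(traits, config, renormalize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  m <- if (is.matrix(traits)) traits else matrix(traits, nrow = 1)
  check_simplex(m)
  if (!renormalize) {
    hit <- matrix(runif(length(m)) < config$p_mut, nrow(m))
    pert <- matrix(rnorm(length(m), 0, config$mut_sd), nrow(m))
    out <- m + hit * pert
    out[out < 0] <- 0
    return(out)
  }
  .Call("C_mutate_traits", m, config$p_mut, config$mut_sd,
        PACKAGE = "rangexp")
}

#' Natal dispersal of one offspring
#'
#' With probability `d` the individual attempts dispersal; it survives the
#' move with probability `1 - mu` and otherwise dies. The direction is
#' uniform between the two neighbours. During burn-in the `n_core` core
#' patches form a ring (moves wrap around); afterwards boundaries reflect
#' (an edge individual drawing the outward direction lands on its interior
#' neighbour).
#'
#' @param patch Current (0-based) patch index.
#' @param d Dispersal probability in `[0, 1]`.
#' @param config A [sim_config()].
#' @param phase `"burn_in"` or `"expansion"`.
#'
#' @return The new patch index, or `NA_integer_` if the individual died
#'   dispersing.
#' @export
disperse <- function(patch, d, config, phase = c("expansion", "burn_in")) {
  stopifnot(inherits(config, "sim_config"))
  phase <- match.arg(phase)
  if (d < 0 || d > 1) stop("d must lie in [0, 1]")
  if (runif(1) >= d) return(as.integer(patch))
  if (config$mu > 0 && runif(1) < config$mu) return(NA_integer_)
  target <- patch + sample(c(-1L, 1L), 1)
  if (phase == "burn_in") {
    target <- (target + config$n_core) %% config$n_core
  } else {
    if (target < 0) target <- 1L
    if (target >= config$n_patches) target <- config$n_patches - 2L
  }
  as.integer(target)
}

#' Rightmost occupied patch
#'
#' @param x A `range_expansion` object, or a per-patch vector of consumer
#'   counts.
#' @return 0-based index of the rightmost patch holding at least one
#'   consumer; `-1` if the landscape is empty.
#' @export
front_position <- function(x) {
  counts <- if (inherits(x, "range_expansion")) {
    tabulate(x$final_patch + 1L, nbins = x$config$n_patches)
  } else as.numeric(x)
  occ <- which(counts > 0)
  if (length(occ) == 0) -1L else as.integer(max(occ) - 1L)
}

#' Run one range-expansion simulation
#'
#' Founders with uniformly random (renormalized) investment vectors are
#' placed in the leftmost `n_core` patches; a burn-in on the closed core
#' ring lets the genetic algorithm settle, after which the landscape opens
#' and the expansion runs until the front reaches the last patch or the
#' generation cap. Per-patch density, mean dispersal probability, mean
#' foraging efficiency and resource level are recorded along the way.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (uses R's RNG; identical config and
#'   seed give identical runs).
#' @param init_traits Optional single investment vector used for every
#'   founder instead of random initialization.
#'
#' @return An object of class `range_expansion`: a list with `config`,
#'   `records` (data frame: generation, patch, density, mean_d, mean_invb,
#'   resource), `front` and `census` (per generation), `final_traits`,
#'   `final_patch`, `final_resource`, `profile` (final spatial profile),
#'   `extinct`, `completed`, `generations`.
#' @export
#' @examples
#' cfg <- sim_config(n_patches = 12, n_core = 3, burn_in = 20, max_gen = 200,
#'                   e = 200, n_init_per_patch = 5)
#' run <- run_simulation(cfg, seed = 1)
#' run
run_simulation <- function(config, seed = NULL, init_traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ntr <- n_traits(config)
  n0 <- config$n_core * config$n_init_per_patch
  if (n0 > 0) {
    if (is.null(init_traits)) {
      tr <- matrix(runif(n0 * ntr), n0, ntr)
      tr <- tr / rowSums(tr)
    } else {
      if (length(init_traits) != ntr) {
        stop("init_traits must have length ", ntr)
      }
      check_simplex(matrix(init_traits, 1))
      tr <- matrix(init_traits, n0, ntr, byrow = TRUE)
    }
    patch <- rep(seq_len(config$n_core) - 1L, each = config$n_init_per_patch)
  } else {
    tr <- matrix(numeric(0), 0, ntr)
    patch <- integer(0)
  }
  N0 <- rep(config$N_init, config$n_patches)
  res <- .Call("C_run_sim", unclass(config), tr, as.integer(patch), N0,
               PACKAGE = "rangexp")
  rec <- as.data.frame(res$records)
  names(rec) <- c("generation", "patch", "density", "mean_d", "mean_invb",
                  "resource")
  final <- rec[rec$generation == max(rec$generation), , drop = FALSE]
  profile <- data.frame(patch = final$patch, density = final$density,
                        mean_d = final$mean_d, mean_invb = final$mean_invb,
                        resource = final$resource, row.names = NULL)
  structure(list(
    config = config, seed = seed, records = rec,
    front = res$front, census = res$census,
    final_traits = res$final_traits, final_patch = res$final_patch,
    final_resource = res$final_resource, profile = profile,
    extinct = res$extinct, completed = res$completed,
    generations = res$generations
  ), class = "range_expansion")
}

#' @export
print.range_expansion <- function(x, ...) {
  cat("Range-expansion simulation (", x$config$n_patches, "patches )\n")
  status <- if (x$extinct) {
    "population went extinct"
  } else if (x$completed) {
    "expansion reached the end of the landscape"
  } else "generation cap reached"
  cat("  ", status, "after", x$generations, "generations (burn-in",
      x$config$burn_in, ")\n")
  cat("  final census:", tail(x$census, 1), "individuals; front at patch",
      tail(x$front, 1), "\n")
  invisible(x)
}

#' Core-versus-margin summary of a finished run
#'
#' Established patches show pronounced resource-driven boom-bust cycles
#' (period of roughly ten generations), so a single-generation snapshot of
#' the range core samples an arbitrary cycle phase. The core density is
#' therefore averaged over the final `window` recorded generations —
#' integrating over the oscillation — and compared against the range
#' margin at expansion completion (the freshly assembled front changes
#' smoothly and has no pre-colonization history to average over). Trait
#' summaries are density-weighted means over occupied patches at the
#' final generation.
#'
#' @param object A `range_expansion`.
#' @param core_patches,margin_patches 0-based patch indices defining the
#'   range core and range margin; defaults follow the 100-patch landscape
#'   convention (core 0-20, margin 75-99).
#' @param window Number of final recorded generations over which the core
#'   density is averaged.
#' @param ... Unused.
#' @return A `summary.range_expansion` list with mean density, mean
#'   dispersal probability and mean foraging efficiency in the two
#'   regions.
#' @export
summary.range_expansion <- function(object, core_patches = 0:20,
                                    margin_patches = 75:99, window = 20,
                                    ...) {
  pr <- object$profile
  core <- pr[pr$patch %in% core_patches, , drop = FALSE]
  marg <- pr[pr$patch %in% margin_patches, , drop = FALSE]
  reg_mean <- function(d, col) {
    occ <- d$density > 0
    if (!any(occ)) return(NA_real_)
    sum(d[[col]][occ] * d$density[occ]) / sum(d$density[occ])
  }
  rec <- object$records
  gens <- sort(unique(rec$generation))
  wg <- tail(gens, window)
  core_rec <- rec[rec$generation %in% wg & rec$patch %in% core_patches, ,
                  drop = FALSE]
  density_core <- mean(tapply(core_rec$density, core_rec$generation, mean))
  out <- list(
    status = c(extinct = object$extinct, completed = object$completed),
    generations = object$generations,
    density_core = density_core,
    density_margin = mean(marg$density),
    d_core = reg_mean(core, "mean_d"),
    d_margin = reg_mean(marg, "mean_d"),
    invb_core = reg_mean(core, "mean_invb"),
    invb_margin = reg_mean(marg, "mean_invb")
  )
  class(out) <- "summary.range_expansion"
  out
}

#' @export
print.summary.range_expansion <- function(x, ...) {
  cat("Range-expansion summary (final generation", x$generations, ")\n")
  cat(sprintf("  mean density   core %8.2f   margin %8.2f\n",
              x$density_core, x$density_margin))
  cat(sprintf("  mean dispersal core %8.4f   margin %8.4f\n",
              x$d_core, x$d_margin))
  cat(sprintf("  mean 1/b       core %8.5f   margin %8.5f\n",
              x$invb_core, x$invb_margin))
  invisible(x)
}

#' @export
plot.range_expansion <- function(x, ...) {
  pr <- x$profile
  op <- par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(par(op))
  plot(pr$patch, pr$density, type = "l", lwd = 2,
       xlab = "patch", ylab = "consumer density", ...)
  scale <- max(pr$density, na.rm = TRUE)
  lines(pr$patch, pr$mean_d / max(pr$mean_d, na.rm = TRUE) * scale,
        col = "sienna", lty = 2)
  lines(pr$patch, pr$mean_invb / max(pr$mean_invb, na.rm = TRUE) * scale,
        col = "forestgreen", lty = 3)
  legend("topleft", bty = "n", lty = c(1, 2, 3), lwd = c(2, 1, 1),
         col = c("black", "sienna", "forestgreen"),
         legend = c("density", "mean d (scaled)", "mean 1/b (scaled)"))
  invisible(x)
}

#' Replicated parameter sweep
#'
#' Runs [run_simulation()] over a grid of configuration overrides with
#' replicated seeds derived from a root seed, and aggregates the final
#' spatial profiles (mean and s.d. across replicates).
#'
#' @param grid A named list of parameter vectors to cross (fields of
#'   [sim_config()]), or a data frame of combinations. An empty list runs
#'   the base configuration only.
#' @param n_replicates Replicates per combination.
#' @param seed Root seed; per-replicate child seeds are derived from it.
#' @param base_config A [sim_config()] supplying all non-swept fields.
#'
#' @return An object of class `expansion_sweep`: list with `runs` (tidy
#'   per-replicate profile data frame), `profiles` (aggregated per
#'   combination and patch), `outcomes` (completion/extinction per run)
#'   and `grid`.
#' @export
sweep_simulations <- function(grid = list(), n_replicates = 20, seed = 1,
                              base_config = sim_config()) {
  stopifnot(inherits(base_config, "sim_config"))
  combos <- if (is.data.frame(grid)) grid else expand.grid(grid,
                                                           stringsAsFactors = FALSE)
  if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
  set.seed(seed)
  child_seeds <- matrix(sample.int(.Machine$integer.max, nrow(combos) *
                                     n_replicates),
                        nrow(combos), n_replicates)
  runs <- vector("list", nrow(combos) * n_replicates)
  outcomes <- vector("list", nrow(combos) * n_replicates)
  k <- 0
  for (i in seq_len(nrow(combos))) {
    over <- as.list(combos[i, , drop = FALSE])
    cfg <- do.call(sim_config, modifyList(unclass(base_config)[
      setdiff(names(unclass(base_config)), "class")], over))
    for (r in seq_len(n_replicates)) {
      k <- k + 1
      run <- run_simulation(cfg, seed = child_seeds[i, r])
      pr <- run$profile
      pr$combination <- i
      pr$replicate <- r
      runs[[k]] <- pr
      outcomes[[k]] <- data.frame(combination = i, replicate = r,
                                  seed = child_seeds[i, r],
                                  completed = run$completed,
                                  extinct = run$extinct,
                                  generations = run$generations)
    }
  }
  runs <- do.call(rbind, runs)
  outcomes <- do.call(rbind, outcomes)
  agg <- do.call(rbind, lapply(split(runs, list(runs$combination, runs$patch)),
                               function(d) data.frame(
    combination = d$combination[1], patch = d$patch[1],
    density_mean = mean(d$density), density_sd = sd(d$density),
    d_mean = mean(d$mean_d, na.rm = TRUE),
    invb_mean = mean(d$mean_invb, na.rm = TRUE),
    N_mean = mean(d$resource))))
  agg <- agg[order(agg$combination, agg$patch), ]
  rownames(agg) <- NULL
  structure(list(runs = runs, profiles = agg, outcomes = outcomes,
                 grid = combos, seed = seed),
            class = "expansion_sweep")
}

#' @export
print.expansion_sweep <- function(x, ...) {
  cat("Parameter sweep:", nrow(x$grid), "combination(s) x",
      max(x$outcomes$replicate), "replicates\n")
  cat("  completed:", sum(x$outcomes$completed), "/", nrow(x$outcomes),
      " runs; extinct:", sum(x$outcomes$extinct), "\n")
  invisible(x)
}
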