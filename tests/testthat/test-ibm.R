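test_that("configuration validation names the offending field", {
  expect_error(sim_config(lambda0 = 0.5), "lambda0")
  expect_error(sim_config(p_mut = 1.5), "p_mut")
  expect_error(sim_config(mu = 2), "mu")
  expect_error(sim_config(n_core = 200), "n_core")
  expect_error(sim_config(a_max = -1), "a_max")
})

test_that("investment fractions map to phenotypes with the dispersal cap", {
  cfg <- sim_config()
  expect_equal(phenotype_from_traits(c(0, 0.5, 0.3, 0.2), cfg)[["d"]], 0)
  expect_equal(phenotype_from_traits(c(0, 1, 0, 0), cfg)[["a"]], cfg$a_max)
  # f_d = 0.5 exceeds the probability scale for every allowed d_max
  for (dm in c(2, 3, 4)) {
    cfg2 <- sim_config(d_max = dm)
    ph <- phenotype_from_traits(c(0.5, 0.2, 0.2, 0.1), cfg2)
    expect_gte(0.5 * dm, 1)
    expect_equal(ph[["d"]], 1)
  }
  # below the cap the mapping is linear
  ph <- phenotype_from_traits(c(0.2, 0.3, 0.4, 0.1), sim_config(d_max = 3))
  expect_equal(ph[["d"]], 0.6)
  expect_equal(ph[["invb"]], 0.4 * 0.02)
  # nonlinear trade-off exponent
  ph2 <- phenotype_from_traits(c(0.25, 0.25, 0.25, 0.25),
                               sim_config(tradeoff_exponent = 2, d_max = 3))
  expect_equal(ph2[["d"]], 0.25^2 * 3)
  expect_error(phenotype_from_traits(c(0.5, 0.5, 0.5, 0.5), cfg), "sum to 1")
})

test_that("Beverton-Holt resource growth has K as fixed point", {
  cfg <- sim_config(lambda0 = 4, K = 50)
  expect_equal(resource_growth(50, cfg), 50)
  expect_identical(resource_growth(0, cfg), 0)
  expect_equal(resource_growth(10, cfg), 4 * 10 / (1 + (3 / 50) * 10))
  expect_equal(resource_growth(10, cfg), 25)
  expect_error(resource_growth(-1, cfg), ">= 0")
  # monotone approach to K from below
  N <- 1
  for (i in 1:30) {
    N2 <- resource_growth(N, cfg)
    expect_gt(N2, N)
    N <- N2
  }
  expect_lt(abs(N - 50), 1e-6)
})

test_that("foraging empties nothing when resources are gone and saturates alone", {
  cfg <- sim_config(a_max = 0.03, invb_max = 10)
  tr <- matrix(c(0.1, 0.4, 0.4, 0.1), 1)
  expect_equal(forage(tr, 0, cfg)$intakes, 0)
  # single individual with N >> 1/invb_i harvests its maximum a_i
  out <- forage(tr, 1000, cfg)
  expect_equal(out$intakes, 0.4 * 0.03, tolerance = 1e-3)
  # refuge floor: nothing harvestable at N = refuge * K
  cfg_r <- sim_config(refuge = 0.2)
  expect_equal(forage(tr, 0.2 * cfg_r$K, cfg_r)$intakes, 0)
  # zero foraging-efficiency investment means zero intake, not an error
  tr0 <- matrix(c(0.2, 0.4, 0, 0.4), 1)
  expect_equal(forage(tr0, 50, cfg)$intakes, 0)
})

test_that("foraging conserves resources exactly across random patches", {
  cfg <- sim_config()
  set.seed(301)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    tr <- matrix(runif(n * 4), n)
    tr <- tr / rowSums(tr)
    N <- runif(1, 0, 60)
    out <- forage(tr, N, cfg)
    expect_lt(abs(sum(out$intakes) - (N - out$N_after)), 1e-9)
    expect_gte(out$N_after, 0)
    expect_setequal(out$order, seq_len(n))
  }
})

test_that("reproduction is Poisson with mean e times intake", {
  cfg <- sim_config(e = 700)
  tr <- matrix(rep(0.25, 4), 1)
  expect_equal(nrow(reproduce(tr, 0, cfg)$offspring_traits), 0)
  set.seed(17)
  n <- 1e5
  counts <- tabulate(reproduce(tr[rep(1, n), ], rep(0.015, n),
                               cfg)$parent, nbins = n)
  expect_equal(mean(counts), 700 * 0.015, tolerance = 0.01)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.03)
})

test_that("mutation preserves the trait simplex and is silent at rate zero", {
  cfg0 <- sim_config(p_mut = 0)
  tr <- matrix(c(0.1, 0.2, 0.3, 0.4), 1)
  set.seed(23)
  expect_identical(mutate_traits(tr, cfg0), tr)
  cfg <- sim_config(p_mut = 0.5)
  m <- matrix(runif(1e5 * 4), ncol = 4)
  m <- m / rowSums(m)
  out <- mutate_traits(m, cfg)
  expect_true(all(out >= 0))
  expect_lt(max(abs(rowSums(out) - 1)), 1e-12)
})

test_that("mutation increments have the configured standard deviation", {
  # diagnostic (un-renormalized) path: increments are Normal(0, 0.2)
  cfg <- sim_config(p_mut = 1, mut_sd = 0.2)
  parent <- matrix(c(0.7, 0.1, 0.1, 0.1), 1e5, 4, byrow = TRUE)
  set.seed(29)
  raw <- mutate_traits(parent, cfg, renormalize = FALSE)
  expect_equal(sd(raw[, 1] - 0.7), 0.2, tolerance = 0.02)
})

test_that("compiled mutation matches an R reimplementation distributionally", {
  cfg <- sim_config(p_mut = 1, mut_sd = 0.2)
  parent <- matrix(c(0.4, 0.3, 0.2, 0.1), 2e4, 4, byrow = TRUE)
  set.seed(31)
  via_c <- mutate_traits(parent, cfg)
  # independent R-side oracle of the same rule
  set.seed(32)
  pert <- parent + matrix(rnorm(length(parent), 0, 0.2), nrow(parent))
  pert[pert < 0] <- 0
  ok <- rowSums(pert) > 0
  via_r <- pert[ok, ] / rowSums(pert[ok, ])
  for (j in 1:4) {
    expect_equal(mean(via_c[, j]), mean(via_r[, j]), tolerance = 0.03)
    expect_equal(sd(via_c[, j]), sd(via_r[, j]), tolerance = 0.08)
  }
})

test_that("dispersal respects probability, mortality and the burn-in ring", {
  cfg <- sim_config(n_core = 5, mu = 0)
  set.seed(41)
  expect_true(all(replicate(50, disperse(3, 0, cfg)) == 3))
  cfg_mu <- sim_config(mu = 1)
  expect_true(all(is.na(replicate(50, disperse(3, 1, cfg_mu)))))
  # ring wrap: leftward moves from patch 0 reach patch n_core - 1
  dest <- replicate(4000, disperse(0, 1, cfg, phase = "burn_in"))
  expect_setequal(unique(dest), c(1L, 4L))
  expect_equal(mean(dest == 4L), 0.5, tolerance = 0.05)
  # reflecting boundaries after burn-in: edge moves end at the interior
  dest2 <- replicate(200, disperse(0, 1, cfg, phase = "expansion"))
  expect_true(all(dest2 == 1L))
  dest3 <- replicate(200, disperse(cfg$n_patches - 1, 1, cfg,
                                   phase = "expansion"))
  expect_true(all(dest3 %in% c(cfg$n_patches - 2L)))
})

test_that("an unseeded landscape is flagged extinct and resources recover to K", {
  cfg <- mini_config(n_init_per_patch = 0, burn_in = 5, max_gen = 30,
                     N_init = 1, record_every = 1)
  run <- run_simulation(cfg, seed = 1)
  expect_true(run$extinct)
  rec0 <- run$records[run$records$patch == 0, ]
  expect_true(all(diff(rec0$resource) > 0))
  expect_true(all(rec0$resource <= cfg$K))
})

test_that("a population that cannot reproduce goes extinct and is flagged", {
  cfg <- mini_config(e = 0)
  run <- run_simulation(cfg, seed = 2)
  expect_true(run$extinct)
  expect_false(run$completed)
  expect_lt(run$generations, 5)
})

test_that("identical seed and configuration reproduce runs bit-identically", {
  cfg <- mini_config()
  r1 <- run_simulation(cfg, seed = 7)
  r2 <- run_simulation(cfg, seed = 7)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$final_traits, r2$final_traits)
  r3 <- run_simulation(cfg, seed = 8)
  expect_false(identical(r1$census, r3$census))
})

test_that("without mutation and with identical founders traits never move", {
  cfg <- mini_config(p_mut = 0)
  run <- run_simulation(cfg, seed = 3, init_traits = c(0.25, 0.25, 0.25, 0.25))
  rec <- run$records[run$records$density > 0, ]
  expect_true(all(abs(rec$mean_d - min(1, 0.25 * cfg$d_max)) < 1e-12))
  expect_true(all(abs(rec$mean_invb - 0.25 * cfg$invb_max) < 1e-12))
})

test_that("burn-in confines consumers to the core ring", {
  cfg <- mini_config(record_every = 1)
  run <- run_simulation(cfg, seed = 5)
  burn <- run$records[run$records$generation <= cfg$burn_in &
                        run$records$patch >= cfg$n_core, ]
  expect_true(all(burn$density == 0))
})

test_that("front position tracks the rightmost occupied patch", {
  expect_identical(front_position(c(3, 0, 0)), 0L)
  expect_identical(front_position(c(0, 0, 0)), -1L)
  cfg <- mini_config()
  run <- run_simulation(cfg, seed = 7)
  if (run$completed) {
    expect_identical(front_position(run), cfg$n_patches - 1L)
    expect_identical(tail(run$front, 1), cfg$n_patches - 1L)
  }
})

test_that("simulation records respect resource bounds and census accounting", {
  cfg <- mini_config(record_every = 1)
  run <- run_simulation(cfg, seed = 9)
  expect_true(all(run$records$resource >= 0))
  expect_true(all(run$records$resource <= max(cfg$K, cfg$N_init) + 1e-9))
  # per-generation census equals the summed per-patch densities
  sums <- tapply(run$records$density, run$records$generation, sum)
  gens <- as.numeric(names(sums))
  expect_equal(as.numeric(sums), run$census[gens + 1])
})

test_that("sweeps keep per-replicate rows and are reproducible by seed", {
  base <- mini_config()
  sw <- sweep_simulations(grid = list(lambda0 = 4), n_replicates = 2,
                          seed = 42, base_config = base)
  expect_equal(nrow(sw$runs), 2 * base$n_patches)
  expect_equal(nrow(sw$profiles), base$n_patches)
  expect_equal(nrow(sw$outcomes), 2)
  sw2 <- sweep_simulations(grid = list(lambda0 = 4), n_replicates = 2,
                           seed = 42, base_config = base)
  expect_identical(sw$runs, sw2$runs)
  # replicates with different child seeds differ
  d1 <- sw$runs[sw$runs$replicate == 1, "density"]
  d2 <- sw$runs[sw$runs$replicate == 2, "density"]
  expect_false(identical(d1, d2))
})

test_that("the four-way trade-off evolves assimilation on a five-way simplex", {
  cfg <- mini_config(four_way = TRUE)
  run <- run_simulation(cfg, seed = 13)
  expect_equal(ncol(run$final_traits), 5)
  if (nrow(run$final_traits) > 0) {
    expect_lt(max(abs(rowSums(run$final_traits) - 1)), 1e-12)
  }
})
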