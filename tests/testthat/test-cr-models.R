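test_that("parameter constructors validate their domains", {
  expect_error(logistic_params(r = Inf, K = 10, T0 = 1), "finite")
  expect_error(logistic_params(r = 0.1, K = -1, T0 = 1), "K")
  expect_error(cr_params(e = -1, a = 1, b = 1, d_T = 0, r0 = 0, K_N = 1,
                         T0 = 1), "> 0")
  expect_error(cr_params(e = 1, a = 1, b = 1, d_T = -0.1, r0 = 0, K_N = 1,
                         T0 = 1), "d_T")
  expect_error(cr_params(e = 1, a = 1, b = 1, d_T = 0, r0 = 0, K_N = 1,
                         T0 = 1, N0 = 2), "N0")
})

test_that("logistic closed form honours initial condition, asymptote and the ODE", {
  p <- logistic_params(r = 0.3, K = 10000, T0 = 100)
  expect_identical(logistic_density(p, 0), 100)
  expect_equal(logistic_density(p, 1000), p$K, tolerance = 1e-10)
  expect_error(logistic_density(p, -1), ">= 0")
  # independent fine-step Euler oracle of dT/dt = r T (1 - T/K): the
  # discrepancy is first order in dt, and its Richardson limit matches
  # the closed form to 1e-6 relative
  for (t_end in c(5, 15, 30)) {
    e1 <- euler_logistic(0.3, 10000, 100, t_end, dt = 1e-4)
    e2 <- euler_logistic(0.3, 10000, 100, t_end, dt = 5e-5)
    cf <- logistic_density(p, t_end)
    expect_equal((cf - e2) / (cf - e1), 0.5, tolerance = 0.05)
    expect_equal(cf, 2 * e2 - e1, tolerance = 1e-6)
  }
})

test_that("type II functional response saturates at a with half-saturation b", {
  expect_identical(functional_response(2, 5, 0), 0)
  expect_equal(functional_response(2, 5, 5), 1)
  expect_equal(functional_response(2, 5, 1e12), 2, tolerance = 1e-10)
  expect_error(functional_response(2, 5, -1), ">= 0")
  N <- seq(0, 100, by = 1)
  expect_true(all(diff(functional_response(2, 5, N)) > 0))
})

test_that("consumer-resource derivatives reduce correctly in limiting cases", {
  p <- cr_params(e = 2e-4, a = 1500, b = 1e7, d_T = 0.05, r0 = 0.24,
                 K_N = 3.6e7, T0 = 50)
  d1 <- cr_derivatives(0, 1e7, p)
  expect_identical(d1[["dT"]], 0)
  expect_equal(d1[["dN"]], 0.24 * 1e7 * (1 - 1e7 / 3.6e7))
  d2 <- cr_derivatives(100, 0, p)
  expect_equal(d2[["dT"]], -0.05 * 100)
  expect_identical(d2[["dN"]], 0)
  d3 <- cr_derivatives(0, 3.6e7, p)
  expect_equal(unname(d3), c(0, 0))
})

test_that("simulate_cr decouples cleanly when the consumer is absent", {
  p <- cr_params(e = 2e-4, a = 1500, b = 1e7, d_T = 0.05, r0 = 0.24,
                 K_N = 3.6e7, T0 = 0, N0 = 1e6)
  tt <- seq(0, 48, by = 4)
  out <- simulate_cr(p, tt)
  expect_true(all(out$consumer == 0))
  # resource then follows pure logistic growth (closed form)
  pN <- logistic_params(r = 0.24, K = 3.6e7, T0 = 1e6)
  expect_equal(out$resource, logistic_density(pN, tt), tolerance = 1e-6)
})

test_that("consumer grows monotonically without death while resources last", {
  p <- cr_params(e = 1e-3, a = 1500, b = 1e7, d_T = 0, r0 = 0.24,
                 K_N = 3.6e7, T0 = 50)
  out <- simulate_cr(p, seq(0, 72, by = 2))
  live <- out$resource > 1
  expect_true(all(diff(out$consumer[live]) > 0))
})

test_that("with vanishing consumption the consumer decays exponentially", {
  p <- cr_params(e = 2e-4, a = 1e-12, b = 1e7, d_T = 0.05, r0 = 0.24,
                 K_N = 3.6e7, T0 = 200)
  tt <- seq(0, 48, by = 8)
  out <- simulate_cr(p, tt)
  expect_equal(out$consumer, 200 * exp(-0.05 * tt), tolerance = 1e-6)
})

test_that("trajectories stay non-negative and resources stay bounded", {
  set.seed(11)
  for (i in 1:5) {
    p <- cr_params(e = 10^runif(1, -4.5, -3.5), a = 10^runif(1, 2.5, 3.5),
                   b = 10^runif(1, 6.8, 7.8), d_T = runif(1, 0.02, 0.12),
                   r0 = 0.24, K_N = 3.6e7, T0 = runif(1, 20, 200))
    out <- simulate_cr(p, seq(0, 120, by = 4))
    expect_true(all(out$consumer >= 0))
    expect_true(all(out$resource >= 0))
    expect_true(all(out$resource <= max(p$N0, p$K_N) * (1 + 1e-6)))
  }
})

test_that("simulate_cr rejects unordered observation times", {
  p <- cr_params(e = 2e-4, a = 1500, b = 1e7, d_T = 0.05, r0 = 0.24,
                 K_N = 3.6e7, T0 = 50)
  expect_error(simulate_cr(p, c(0, 2, 2)), "strictly increasing")
  expect_error(simulate_cr(p, c(-1, 2)), ">= 0")
})

test_that("resource-dependent fitness is increasing and bounded by e*a - d_T", {
  p <- cr_params(e = 2e-4, a = 1500, b = 1e7, d_T = 0.05, r0 = 0.24,
                 K_N = 3.6e7, T0 = 50)
  expect_equal(growth_rate_vs_resources(p, 0), -0.05)
  expect_equal(growth_rate_vs_resources(p, p$b), p$e * p$a / 2 - p$d_T)
  N <- seq(0, 1e9, length.out = 200)
  g <- growth_rate_vs_resources(p, N)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < p$e * p$a - p$d_T))
  expect_equal(growth_rate_vs_resources(p, 1e13), p$e * p$a - p$d_T,
               tolerance = 1e-5)
})

test_that("growth series container validates and round-trips through CSV", {
  expect_error(growth_series(c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(growth_series(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(growth_series(c(0, 1), c(1, -2)), "non-negative")
  expect_error(growth_series(c(0, 1), c(1, NA)), "missing")
  s <- growth_series(c(0, 24, 48), c(10, 100, 900))
  path <- tempfile(fileext = ".csv")
  write_growth_series(s, path)
  expect_equal(read_growth_series(path), s)
  # wrong header is rejected, not silently reinterpreted
  bad <- tempfile(fileext = ".csv")
  writeLines(c("t,dens", "0,1"), bad)
  expect_error(read_growth_series(bad), "header")
})
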