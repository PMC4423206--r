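test_that("noiseless logistic curves are recovered to numerical precision", {
  tt <- seq(0, 44, by = 4)
  p <- logistic_params(r = 0.35, K = 9000, T0 = 120)
  fit <- fit_logistic(growth_series(tt, logistic_density(p, tt)))
  expect_equal(coef(fit)[["r"]], 0.35, tolerance = 1e-4)
  expect_equal(coef(fit)[["K"]], 9000, tolerance = 1e-4)
  expect_equal(coef(fit)[["T0"]], 120, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-6)
  expect_equal(fit$k_free, 3)
})

test_that("degenerate growth series are rejected with an error", {
  expect_error(fit_logistic(growth_series(0:6, rep(500, 7))), "flat")
  expect_error(fit_logistic(growth_series(0:3, c(1, 2, 4, 8))),
               "at least 5")
  expect_error(fit_consumer_resource(growth_series(0:3, c(1, 2, 4, 8))),
               "at least 5")
  expect_error(fit_logistic(growth_series(0:6, rep(0, 7))), "zero")
})

test_that("the AIC convention matches R's Gaussian log-likelihood", {
  set.seed(5)
  x <- 1:20
  y <- 2 + 0.5 * x + rnorm(20)
  m <- stats::lm(y ~ x)
  expect_equal(rangexp:::aic_gaussian(sum(resid(m)^2), 20, 2), AIC(m))
  # AIC strictly decreases with rss at fixed k and n
  rss <- c(100, 50, 10)
  aics <- rangexp:::aic_gaussian(rss, 13, 5)
  expect_true(all(diff(aics) < 0))
})

test_that("the consumer-resource residuals vanish at the generating truth", {
  s <- noiseless_core_series()
  truth <- core_margin_truths()$core
  lp <- log(c(truth$e, truth$a, truth$b, truth$d_T, truth$T0 / 10))
  r <- rangexp:::cr_residuals(lp, s$time_h, s$density_per_ml, 0.24, 3.6e7)
  expect_lt(sum(r^2), 1e-10 * max(s$density_per_ml)^2)
})

test_that("model comparison requires identical data and reports the lower-AIC model", {
  s <- noiseless_core_series()
  fl <- fit_logistic(s)
  fcr <- fit_consumer_resource(s)
  cmpr <- compare_models(fl, fcr)
  expect_equal(cmpr$delta_aic, fl$aic - fcr$aic)
  expect_identical(cmpr$preferred,
                   if (cmpr$delta_aic > 0) "consumer_resource" else "logistic")
  # argument order and data identity are enforced
  expect_error(compare_models(fcr, fl), "in that order")
  s2 <- growth_series(s$time_h + 1, s$density_per_ml)
  expect_error(compare_models(fit_logistic(s2), fcr), "identical data")
})

test_that("identical rss and parameter count give a zero AIC difference", {
  s <- noiseless_core_series()
  fit <- fit_logistic(s)
  twin <- rangexp:::new_growth_fit("consumer_resource", fit$params,
                                   fixed = c(r0 = 0.24, K_N = 3.6e7,
                                             N0 = 3.6e7),
                                   data = fit$data, fitted_dens = fit$fitted,
                                   k_free = fit$k_free)
  cmpr <- compare_models(fit, twin)
  expect_equal(cmpr$delta_aic, 0)
})

test_that("fitness curves come only from consumer-resource fits and hit the closed forms", {
  s <- noiseless_core_series()
  fcr <- fit_consumer_resource(s)
  fl <- fit_logistic(s)
  expect_error(fitness_curve(fl), "consumer-resource")
  cf <- coef(fcr)
  fc <- fitness_curve(fcr, N_grid = c(0, cf[["b"]]), units = "absolute")
  expect_equal(fc$growth_rate[1], -cf[["d_T"]])
  expect_equal(fc$growth_rate[2], cf[["e"]] * cf[["a"]] / 2 - cf[["d_T"]])
  # a fit with larger e*a and equal death rate dominates everywhere
  up <- fcr
  up$params[["e"]] <- cf[["e"]] * 1.5
  grid <- seq(0.05, 1, length.out = 20)
  expect_true(all(fitness_curve(up, grid)$growth_rate >
                    fitness_curve(fcr, grid)$growth_rate))
})

test_that("replicate pooling averages densities at shared times", {
  d <- data.frame(replicate = rep(1:2, each = 3),
                  time_h = rep(c(0, 24, 48), 2),
                  density_per_ml = c(10, 100, 1000, 30, 200, 3000))
  pooled <- pool_replicates(d)
  expect_equal(pooled$density_per_ml, c(20, 150, 2000))
  s1 <- growth_series(c(0, 24), c(1, 2))
  s2 <- growth_series(c(0, 25), c(1, 2))
  expect_error(pool_replicates(list(s1, s2)), "identical time points")
})

test_that("growth_fit methods expose coefficients, predictions and residuals", {
  tt <- seq(0, 44, by = 4)
  p <- logistic_params(r = 0.35, K = 9000, T0 = 120)
  set.seed(2)
  y <- pmax(logistic_density(p, tt) + rnorm(length(tt), 0, 100), 0)
  fit <- fit_logistic(growth_series(tt, y))
  expect_named(coef(fit), c("r", "K", "T0"))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(predict(fit, c(0, 10, 20))), 3)
  expect_equal(AIC(fit), fit$aic)
  expect_output(print(fit), "logistic")
  expect_output(print(summary(fit)), "rss")
})

test_that("fitting is deterministic for fixed data", {
  s <- noiseless_core_series()
  f1 <- fit_consumer_resource(s)
  f2 <- fit_consumer_resource(s)
  expect_identical(coef(f1), coef(f2))
  # and it does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(fit_consumer_resource(s))
  expect_identical(runif(1), before)
})
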