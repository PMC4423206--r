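# Independent numerical oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own solvers.

# fixed-step RK4 integration of the consumer-resource system
rk4_cr <- function(p, times, dt = 1e-3) {
  deriv <- function(T, N) {
    fr <- p$a * N / (N + p$b)
    c(p$e * fr * T - p$d_T * T,
      p$r0 * N * (1 - N / p$K_N) - fr * T)
  }
  out <- matrix(NA_real_, length(times), 2)
  Tc <- p$T0
  Nc <- p$N0
  t <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    while (t < target - 1e-12) {
      h <- min(dt, target - t)
      k1 <- deriv(Tc, Nc)
      k2 <- deriv(Tc + h / 2 * k1[1], Nc + h / 2 * k1[2])
      k3 <- deriv(Tc + h / 2 * k2[1], Nc + h / 2 * k2[2])
      k4 <- deriv(Tc + h * k3[1], Nc + h * k3[2])
      inc <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
      Tc <- Tc + h * inc[1]
      Nc <- Nc + h * inc[2]
      t <- t + h
    }
    out[i, ] <- c(Tc, Nc)
  }
  data.frame(time = times, consumer = out[, 1], resource = out[, 2])
}

# fixed-step Euler integration of the logistic ODE
euler_logistic <- function(r, K, T0, t_end, dt = 1e-4) {
  x <- T0
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) x <- x + dt * r * x * (1 - x / K)
  x
}

# observation schedule of the growth assay (hours)
design_times <- function() c(0, 8, 16, seq(24, 240, by = 24))

# quick noiseless consumer-resource series from the default core truth
noiseless_core_series <- function() {
  truth <- core_margin_truths()$core
  p <- cr_params(truth$e, truth$a, truth$b, truth$d_T, truth$r0,
                 truth$K_N, T0 = truth$T0 / 10)
  growth_series(design_times(), simulate_cr(p, design_times())$consumer)
}

# tiny simulator configuration that runs in well under a second: coarse
# resources (big harvest chunks, low assimilation) keep local populations
# viable at tens of individuals per patch, and a resource refuge prevents
# the boom-crash extinctions small populations are prone to
mini_config <- function(...) {
  defaults <- list(n_patches = 12, n_core = 3, burn_in = 25, max_gen = 300,
                   a_max = 2, invb_max = 0.2, e = 6, refuge = 0.15,
                   n_init_per_patch = 5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
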