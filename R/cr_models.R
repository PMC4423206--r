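#' Logistic growth parameters
#'
#' Parameter set for the r-K logistic growth model
#' \eqn{dT/dt = r T (1 - T/K)}, whose closed-form solution is evaluated by
#' [logistic_density()].
#'
#' @param r Intrinsic growth rate (per hour).
#' @param K Carrying capacity (individuals per ml), must be positive.
#' @param T0 Initial density (individuals per ml), must be positive.
#'
#' @return An object of class `logistic_params`.
#' @seealso [cr_params()], [logistic_density()]
#' @export
#' @examples
#' p <- logistic_params(r = 0.3, K = 1e4, T0 = 100)
#' logistic_density(p, t = c(0, 10, 50))
logistic_params <- function(r, K, T0) {
  if (!all(is.finite(c(r, K, T0)))) {
    stop("logistic parameters must be finite: r=", r, ", K=", K, ", T0=", T0)
  }
  if (K <= 0) stop("K must be > 0")
  if (T0 <= 0) stop("T0 must be > 0")
  structure(list(r = r, K = K, T0 = T0), class = "logistic_params")
}

#' Consumer-resource (Rosenzweig-MacArthur) parameters
#'
#' Parameter set for the consumer-resource system with a type II functional
#' response:
#' \deqn{dT/dt = e \, a N/(N+b) \, T - d_T T}
#' \deqn{dN/dt = r_0 N (1 - N/K_N) - a N/(N+b) \, T}
#' where \eqn{T} is consumer density, \eqn{N} resource density, \eqn{e} the
#' assimilation coefficient (offspring per resource unit), \eqn{a} the maximum
#' amount of resources consumed per consumer and hour, \eqn{b} the
#' half-saturation constant (so \eqn{1/b} is foraging efficiency), \eqn{d_T}
#' the consumer death rate, and the resource grows logistically with rate
#' \eqn{r_0} and carrying capacity \eqn{K_N}.
#'
#' @param e Assimilation coefficient (> 0).
#' @param a Maximum resource intake per consumer per hour (> 0).
#' @param b Half-saturation constant of the type II functional response (> 0).
#' @param d_T Consumer death rate per hour (>= 0).
#' @param r0 Resource growth rate per hour (>= 0).
#' @param K_N Resource carrying capacity (> 0).
#' @param T0 Initial consumer density (>= 0; zero gives the consumer-free
#'   resource dynamics).
#' @param N0 Initial resource density, in (0, K_N]; defaults to `K_N`
#'   (fresh bacterized medium starting at resource capacity).
#'
#' @return An object of class `cr_params`.
#' @seealso [simulate_cr()], [growth_rate_vs_resources()]
#' @export
cr_params <- function(e, a, b, d_T, r0, K_N, T0, N0 = K_N) {
  vals <- c(e = unname(e), a = unname(a), b = unname(b), d_T = unname(d_T),
            r0 = unname(r0), K_N = unname(K_N), T0 = unname(T0),
            N0 = unname(N0))
  if (!all(is.finite(vals))) {
    stop("consumer-resource parameters must all be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (any(c(e, a, b, K_N) <= 0)) {
    stop("e, a, b and K_N must be > 0")
  }
  if (T0 < 0) stop("T0 must be >= 0")
  if (d_T < 0 || r0 < 0) stop("d_T and r0 must be >= 0")
  if (N0 <= 0 || N0 > K_N) stop("N0 must lie in (0, K_N]")
  structure(as.list(vals), class = "cr_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat("Logistic growth parameters: r =", x$r, "/h, K =", x$K,
      "ml^-1, T0 =", x$T0, "ml^-1\n")
  invisible(x)
}

#' @export
print.cr_params <- function(x, ...) {
  cat("Consumer-resource parameters:\n")
  cat("  consumer: e =", x$e, ", a =", x$a, "/h, b =", x$b,
      " (1/b =", 1 / x$b, "), d_T =", x$d_T, "/h, T0 =", x$T0, "\n")
  cat("  resource: r0 =", x$r0, "/h, K_N =", x$K_N, ", N0 =", x$N0, "\n")
  invisible(x)
}

#' Closed-form logistic density
#'
#' Evaluates the solution of the logistic growth model,
#' \eqn{T(t) = K / (1 + (K/T_0 - 1) e^{-r t})}.
#'
#' @param p A [logistic_params()] object.
#' @param t Non-negative time(s) in hours.
#'
#' @return Numeric vector of consumer densities at `t`.
#' @export
logistic_density <- function(p, t) {
  stopifnot(inherits(p, "logistic_params"))
  if (any(t < 0)) stop("t must be >= 0")
  p$K / (1 + (p$K / p$T0 - 1) * exp(-p$r * t))
}

#' Type II functional response
#'
#' Per-capita resource intake rate \eqn{a N / (N + b)}: saturating in
#' resource density `N`, with maximum `a` and half-saturation constant `b`.
#'
#' @param a Maximum intake rate (> 0).
#' @param b Half-saturation constant (> 0).
#' @param N Resource density (>= 0), vectorized.
#'
#' @return Per-capita intake rate(s).
#' @export
functional_response <- function(a, b, N) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  if (any(N < 0)) stop("N must be >= 0")
  a * N / (N + b)
}

#' Consumer-resource time derivatives
#'
#' Right-hand side of the consumer-resource system; see [cr_params()] for
#' the equations.
#'
#' @param T Consumer density (>= 0).
#' @param N Resource density (>= 0).
#' @param p A [cr_params()] object.
#'
#' @return Named numeric vector `c(dT, dN)`.
#' @export
cr_derivatives <- function(T, N, p) {
  stopifnot(inherits(p, "cr_params"))
  if (T < 0 || N < 0) stop("T and N must be >= 0")
  fr <- p$a * N / (N + p$b)
  c(dT = p$e * fr * T - p$d_T * T,
    dN = p$r0 * N * (1 - N / p$K_N) - fr * T)
}

#' Integrate the consumer-resource system
#'
#' Numerically integrates the Rosenzweig-MacArthur system from
#' `(T0, N0)` using an adaptive solver (deSolve `lsoda`, compiled
#' right-hand side, `rtol = 1e-8`, `atol` scaled to the state magnitudes).
#' Tiny negative solver excursions are clipped to zero.
#'
#' @param p A [cr_params()] object.
#' @param times Strictly increasing observation times (hours), `times[1] >= 0`.
#'
#' @return A data frame with columns `time`, `consumer`, `resource`.
#' @export
#' @examples
#' p <- cr_params(e = 2e-4, a = 1500, b = 1e7, d_T = 0.05,
#'                r0 = 0.24, K_N = 3.6e7, T0 = 50)
#' head(simulate_cr(p, times = seq(0, 240, by = 24)))
simulate_cr <- function(p, times) {
  stopifnot(inherits(p, "cr_params"))
  if (length(times) < 1 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (times[1] < 0) stop("times must start at >= 0")
  t_solve <- times
  prepend <- times[1] > 0
  if (prepend) t_solve <- c(0, times)
  y0 <- c(T = p$T0, N = p$N0)
  # absolute tolerance scaled per state: consumer and resource magnitudes
  # differ by orders of magnitude in these units
  atol <- c(1e-10 * max(p$T0, 1), 1e-10 * max(p$N0, p$K_N))
  # capture solver console chatter from pathological parameter regions
  # (multi-start fitting probes them routinely); failures still error below
  chatter <- utils::capture.output(out <- try(suppressWarnings(deSolve::ode(
    y = y0, times = t_solve, func = "derivs_cr", parms = with(p, c(e, a, b, d_T, r0, K_N)),
    dllname = "rangexp", initfunc = "initmod_cr", nout = 0,
    rtol = 1e-8, atol = atol
  )), silent = TRUE))
  if (inherits(out, "try-error")) {
    stop("consumer-resource integration failed: ", attr(out, "condition")$message)
  }
  out <- as.data.frame(unclass(out))
  if (nrow(out) < length(t_solve)) {
    stop("consumer-resource integration stopped early at t = ",
         max(out$time), " (of ", max(times), ")")
  }
  if (prepend) out <- out[-1, , drop = FALSE]
  data.frame(time = times,
             consumer = pmax(out$T, 0),
             resource = pmax(out$N, 0),
             row.names = NULL)
}

#' Resource-dependent per-capita growth rate (fitness)
#'
#' The difference between the resource-dependent birth rate and the death
#' rate, \eqn{e \, a N/(N+b) - d_T}: the fitness of a consumer at resource
#' density `N`. Strictly increasing in `N` and bounded above by
#' \eqn{e a - d_T}.
#'
#' @param p A [cr_params()] object.
#' @param N Resource density (>= 0), vectorized.
#'
#' @return Per-capita growth rate(s) per hour.
#' @export
growth_rate_vs_resources <- function(p, N) {
  stopifnot(inherits(p, "cr_params"))
  if (any(N < 0)) stop("N must be >= 0")
  p$e * functional_response(p$a, p$b, N) - p$d_T
}

#' Growth series container
#'
#' A (time, density) series of consumer population observations.
#'
#' @param times Observation times in hours, strictly increasing.
#' @param densities Consumer densities (individuals per ml), non-negative,
#'   same length as `times`.
#'
#' @return A data frame of class `growth_series` with columns `time_h` and
#'   `density_per_ml`.
#' @export
growth_series <- function(times, densities) {
  if (length(times) != length(densities)) {
    stop("times and densities must have equal length")
  }
  if (anyNA(times) || anyNA(densities)) stop("missing values are not allowed")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(densities < 0)) stop("densities must be non-negative")
  structure(data.frame(time_h = as.numeric(times),
                       density_per_ml = as.numeric(densities)),
            class = c("growth_series", "data.frame"))
}

#' Read / write growth series CSV
#'
#' The on-disk format is a CSV with header `time_h,density_per_ml`; missing
#' values are disallowed.
#'
#' @param path File path.
#' @return `read_growth_series()` returns a [growth_series()] object;
#'   `write_growth_series()` returns `path` invisibly.
#' @export
read_growth_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), c("time_h", "density_per_ml"))) {
    stop("expected CSV header 'time_h,density_per_ml', got: ",
         paste(names(d), collapse = ","))
  }
  growth_series(d$time_h, d$density_per_ml)
}

#' @param x A [growth_series()] object.
#' @rdname read_growth_series
#' @export
write_growth_series <- function(x, path) {
  stopifnot(inherits(x, "growth_series"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.growth_series <- function(x, ..., xlab = "time (h)",
                               ylab = expression(density ~ (ml^-1))) {
  plot(x$time_h, x$density_per_ml, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
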