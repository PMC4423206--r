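# Growth-curve fitting: logistic and consumer-resource models, AIC-based
# comparison, and resource-dependent fitness extraction.

# Gaussian-likelihood AIC with the error variance counted as a free
# parameter, so values are comparable with AIC() on nls/lm fits:
# AIC = n log(2 pi) + n log(rss/n) + n + 2 (k + 1)
aic_gaussian <- function(rss, n, k_free) {
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (k_free + 1)
}

new_growth_fit <- function(model, params, fixed, data, fitted_dens, k_free,
                           convergence = list()) {
  resid <- data$density_per_ml - fitted_dens
  rss <- sum(resid^2)
  n <- nrow(data)
  structure(list(
    model = model, params = params, fixed = fixed,
    rss = rss, n_obs = n, k_free = k_free,
    aic = aic_gaussian(rss, n, k_free),
    data = data, fitted = fitted_dens, residuals = resid,
    convergence = convergence
  ), class = "growth_fit")
}

check_series <- function(data) {
  if (!inherits(data, "growth_series")) {
    data <- growth_series(data[[1]], data[[2]])
  }
  if (nrow(data) < 5) {
    stop("at least 5 observations are required (got ", nrow(data), ")")
  }
  if (!any(data$density_per_ml > 0)) stop("all densities are zero")
  data
}

#' Average growth-curve replicates at shared time points
#'
#' Pools replicate growth curves into a single mean series, the default
#' input to the fitting pipeline (one curve per treatment).
#'
#' @param x Either a list of [growth_series()] objects sharing identical
#'   time points, or a data frame with columns `replicate`, `time_h`,
#'   `density_per_ml`.
#'
#' @return A [growth_series()] of mean densities.
#' @export
pool_replicates <- function(x) {
  if (is.data.frame(x) && all(c("replicate", "time_h", "density_per_ml") %in% names(x))) {
    means <- tapply(x$density_per_ml, x$time_h, mean)
    return(growth_series(as.numeric(names(means)), as.numeric(means)))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "growth_series"))) {
    times <- x[[1]]$time_h
    for (s in x) {
      if (!isTRUE(all.equal(s$time_h, times))) {
        stop("replicates must share identical time points")
      }
    }
    dens <- rowMeans(do.call(cbind, lapply(x, `[[`, "density_per_ml")))
    return(growth_series(times, dens))
  }
  stop("x must be a list of growth_series or a replicate/time_h/density_per_ml data frame")
}

#' Fit a growth model to a consumer density series
#'
#' Fits either the logistic r-K model or the Rosenzweig-MacArthur
#' consumer-resource model to a growth curve by nonlinear least squares,
#' returning a classed fit with AIC computed under the full Gaussian
#' likelihood convention (error variance counted as a parameter).
#'
#' For `model = "logistic"` the self-starting logistic (`nls` with
#' `SSlogis`) is tried first; if it fails, a Levenberg-Marquardt fit from a
#' heuristic start (K from the maximum density, T0 from the first positive
#' density, r from the initial log-density slope) is used.
#'
#' For `model = "consumer_resource"` the free parameters are
#' (e, a, b, d_T, T0), constrained positive by optimizing on the log scale
#' with Levenberg-Marquardt (`minpack.lm::nls.lm`). Resource parameters
#' `r0` and `K_N` are fixed (defaults are the bacterial values 0.24 and
#' 3.6e7), and the initial resource density N0 is fixed at `K_N` (fresh
#' bacterized medium starts at resource capacity). Because the least-squares
#' surface is multimodal, the optimizer is restarted from `n_starts`
#' Latin-hypercube points spanning three decades around data-driven
#' heuristic seeds (plus the seed itself); the best residual sum of squares
#' is kept. The procedure is deterministic for given data.
#'
#' @param data A [growth_series()] (or two-column data frame) with at least
#'   5 observations.
#' @param model `"logistic"` or `"consumer_resource"`.
#' @param r0 Fixed resource growth rate (consumer-resource model only).
#' @param K_N Fixed resource carrying capacity (consumer-resource model only).
#' @param n_starts Number of Latin-hypercube restarts (consumer-resource
#'   model only).
#'
#' @return An object of class `growth_fit` with elements `model`, `params`,
#'   `fixed`, `rss`, `n_obs`, `k_free`, `aic`, `data`, `fitted`,
#'   `residuals`, `convergence`.
#' @seealso [compare_models()], [fitness_curve()], [pool_replicates()]
#' @export
#' @examples
#' p <- logistic_params(r = 0.35, K = 9000, T0 = 120)
#' s <- growth_series(seq(0, 44, by = 4), logistic_density(p, seq(0, 44, by = 4)))
#' fit <- fit_growth(s, model = "logistic")
#' coef(fit)
fit_growth <- function(data, model = c("logistic", "consumer_resource"),
                       r0 = 0.24, K_N = 3.6e7, n_starts = 20) {
  model <- match.arg(model)
  data <- check_series(data)
  if (model == "logistic") {
    fit_logistic(data)
  } else {
    fit_consumer_resource(data, fixed_r0 = r0, fixed_KN = K_N,
                          n_starts = n_starts)
  }
}

#' @rdname fit_growth
#' @export
fit_logistic <- function(data) {
  data <- check_series(data)
  t <- data$time_h
  y <- data$density_per_ml
  if (sd(y) == 0) stop("degenerate flat series: densities show no variation")
  est <- NULL
  ss <- try(nls(y ~ SSlogis(t, Asym, xmid, scal)), silent = TRUE)
  if (!inherits(ss, "try-error")) {
    cf <- coef(ss)
    est <- c(r = unname(1 / cf["scal"]), K = unname(cf["Asym"]),
             T0 = unname(cf["Asym"] / (1 + exp(cf["xmid"] / cf["scal"]))))
    conv <- list(method = "nls_SSlogis", converged = TRUE)
  } else {
    # heuristic self-start + Levenberg-Marquardt
    K0 <- max(y)
    T00 <- y[y > 0][1]
    ipos <- which(y > 0)[1:min(3, sum(y > 0))]
    r0h <- if (length(ipos) >= 2) {
      max(coef(stats::lm(log(y[ipos]) ~ t[ipos]))[2], 1e-3)
    } else 0.1
    lm_fit <- try(minpack.lm::nlsLM(
      y ~ K / (1 + (K / T0 - 1) * exp(-r * t)),
      start = list(r = r0h, K = K0, T0 = max(T00, 1e-6)),
      lower = c(r = 1e-8, K = 1e-12, T0 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(lm_fit, "try-error")) {
      stop("logistic fit failed to converge: ",
           attr(lm_fit, "condition")$message)
    }
    cf <- coef(lm_fit)
    est <- c(r = unname(cf["r"]), K = unname(cf["K"]), T0 = unname(cf["T0"]))
    conv <- list(method = "nlsLM_heuristic", converged = TRUE)
  }
  p <- logistic_params(est["r"], est["K"], est["T0"])
  new_growth_fit("logistic", est, fixed = numeric(0), data = data,
                 fitted_dens = logistic_density(p, t), k_free = 3,
                 convergence = conv)
}

# residuals of the consumer-resource model at log-parameters
# lp = log(e, a, b, d_T, T0); returns large constant residuals on
# integration failure so LM abandons pathological regions
cr_residuals <- function(lp, times, y, r0, K_N) {
  pv <- exp(lp)
  if (any(!is.finite(pv)) || any(pv <= 0)) {
    return(rep(1e9, length(y)))
  }
  p <- try(cr_params(e = pv[1], a = pv[2], b = pv[3], d_T = pv[4],
                     r0 = r0, K_N = K_N, T0 = pv[5], N0 = K_N),
           silent = TRUE)
  if (inherits(p, "try-error")) return(rep(1e9, length(y)))
  sim <- try(simulate_cr(p, times), silent = TRUE)
  if (inherits(sim, "try-error")) return(rep(1e9, length(y)))
  y - sim$consumer
}

cr_heuristic_start <- function(times, y, r0, K_N) {
  peak <- max(y)
  T00 <- y[y > 0][1]
  e_h <- max(peak / K_N, 1e-10)
  ipos <- which(y > 0)
  ipos <- ipos[seq_len(min(4, length(ipos)))]
  r_h <- if (length(ipos) >= 2) {
    unname(coef(stats::lm(log(y[ipos]) ~ times[ipos]))[2])
  } else 0.1
  r_h <- max(r_h, 0.01)
  b_h <- K_N / 3
  d_h <- max(r_h / 10, 1e-3)
  a_h <- (r_h + d_h) * (K_N + b_h) / (e_h * K_N)
  log(c(e = e_h, a = a_h, b = b_h, d_T = d_h, T0 = max(T00, 1e-3)))
}

# deterministic Latin-hypercube starts (fixed internal stream; the
# caller's RNG state is untouched)
cr_start_grid <- function(center, n_starts, half_width = 3 * log(10)) {
  if (n_starts < 1) return(matrix(center, nrow = 1))
  seed_state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(seed_state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", seed_state, envir = globalenv())
  })
  set.seed(20160405L)
  u <- lhs::randomLHS(n_starts, length(center))
  starts <- sweep((u * 2 - 1) * half_width, 2, center, `+`)
  rbind(center, starts)
}

#' @param fixed_r0,fixed_KN Fixed resource growth rate and carrying
#'   capacity (aliases of `r0`, `K_N`).
#' @rdname fit_growth
#' @export
fit_consumer_resource <- function(data, fixed_r0 = 0.24, fixed_KN = 3.6e7,
                                  n_starts = 20) {
  data <- check_series(data)
  if (fixed_r0 < 0) stop("fixed_r0 must be >= 0")
  if (fixed_KN <= 0) stop("fixed_KN must be > 0")
  times <- data$time_h
  y <- data$density_per_ml
  center <- cr_heuristic_start(times, y, fixed_r0, fixed_KN)
  starts <- cr_start_grid(center, n_starts)
  # screen all starts by their initial rss, then polish the most promising
  # ones (the heuristic seed, row 1, is always polished)
  screen <- apply(starts, 1, function(s) {
    sum(cr_residuals(s, times, y, fixed_r0, fixed_KN)^2)
  })
  alive <- which(is.finite(screen) & screen < length(y) * 1e17)
  polish <- union(intersect(1L, alive),
                  alive[order(screen[alive])][seq_len(min(5, length(alive)))])
  best <- NULL
  best_rss <- Inf
  for (i in polish) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], fn = cr_residuals,
      times = times, y = y, r0 = fixed_r0, K_N = fixed_KN,
      control = minpack.lm::nls.lm.control(
        maxiter = 150, ftol = 1e-10, ptol = 1e-10)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("consumer-resource fit failed from all ", nrow(starts),
         " starts; best heuristic seed was exp(",
         paste(signif(center, 3), collapse = ", "), ")")
  }
  pv <- exp(best$par)
  names(pv) <- c("e", "a", "b", "d_T", "T0")
  p <- cr_params(e = pv["e"], a = pv["a"], b = pv["b"], d_T = pv["d_T"],
                 r0 = fixed_r0, K_N = fixed_KN, T0 = pv["T0"], N0 = fixed_KN)
  fitted_dens <- simulate_cr(p, times)$consumer
  new_growth_fit("consumer_resource", pv,
                 fixed = c(r0 = fixed_r0, K_N = fixed_KN, N0 = fixed_KN),
                 data = data, fitted_dens = fitted_dens, k_free = 5,
                 convergence = list(method = "nls.lm_multistart",
                                    n_starts = nrow(starts),
                                    info = best$info,
                                    message = best$message))
}

#' Compare two growth-model fits by AIC
#'
#' Computes the AIC difference between a logistic and a consumer-resource
#' fit of the same data. AIC follows the full Gaussian-likelihood
#' convention (see [fit_growth()]); `delta_aic = AIC(logistic) -
#' AIC(consumer_resource)`, so positive values favour the consumer-resource
#' model.
#'
#' @param logistic A `growth_fit` with `model == "logistic"`.
#' @param cr A `growth_fit` with `model == "consumer_resource"`.
#'
#' @return An object of class `growth_model_comparison` with elements
#'   `delta_aic`, `preferred`, `aic_logistic`, `aic_cr`.
#' @export
compare_models <- function(logistic, cr) {
  stopifnot(inherits(logistic, "growth_fit"), inherits(cr, "growth_fit"))
  if (logistic$model != "logistic" || cr$model != "consumer_resource") {
    stop("arguments must be a logistic fit and a consumer-resource fit, in that order")
  }
  if (logistic$n_obs != cr$n_obs ||
      !isTRUE(all.equal(logistic$data$time_h, cr$data$time_h))) {
    stop("fits were not computed on identical data (times differ)")
  }
  delta <- logistic$aic - cr$aic
  structure(list(
    delta_aic = delta,
    preferred = if (delta > 0) "consumer_resource" else "logistic",
    aic_logistic = logistic$aic, aic_cr = cr$aic
  ), class = "growth_model_comparison")
}

#' Resource-dependent fitness curve from a consumer-resource fit
#'
#' Evaluates the fitted per-capita growth rate (birth minus death rate)
#' over a grid of resource densities; the curve behind inference of
#' fitness differences between treatments.
#'
#' @param fit A converged consumer-resource `growth_fit`.
#' @param N_grid Resource densities. If `units = "K_N"`, values are
#'   interpreted as fractions of the resource carrying capacity.
#' @param units `"absolute"` (resource units) or `"K_N"`.
#'
#' @return A data frame with columns `N` (absolute resource density) and
#'   `growth_rate` (per hour).
#' @export
fitness_curve <- function(fit, N_grid = seq(0, 1, length.out = 101),
                          units = c("K_N", "absolute")) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$model != "consumer_resource") {
    stop("fitness_curve requires a consumer-resource fit, got a ",
         fit$model, " fit")
  }
  units <- match.arg(units)
  N <- if (units == "K_N") N_grid * fit$fixed[["K_N"]] else N_grid
  p <- cr_fit_params(fit)
  data.frame(N = N, growth_rate = growth_rate_vs_resources(p, N))
}

# rebuild a cr_params object from a consumer-resource fit
cr_fit_params <- function(fit) {
  stopifnot(fit$model == "consumer_resource")
  cr_params(e = fit$params[["e"]], a = fit$params[["a"]],
            b = fit$params[["b"]], d_T = fit$params[["d_T"]],
            r0 = fit$fixed[["r0"]], K_N = fit$fixed[["K_N"]],
            T0 = fit$params[["T0"]], N0 = fit$fixed[["N0"]])
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth-curve fit:", x$model, "model\n")
  cat("  parameters:", paste(names(x$params), signif(x$params, 4),
                             sep = " = ", collapse = ", "), "\n")
  if (length(x$fixed)) {
    cat("  fixed:     ", paste(names(x$fixed), signif(x$fixed, 4),
                               sep = " = ", collapse = ", "), "\n")
  }
  cat("  n =", x$n_obs, ", rss =", signif(x$rss, 5),
      ", AIC =", signif(x$aic, 6), "\n")
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- object[c("model", "params", "fixed", "rss", "n_obs", "k_free",
                  "aic", "convergence")]
  out$sigma <- sqrt(object$rss / object$n_obs)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Model:", x$model, " (", x$k_free, "free parameters,",
      x$n_obs, "observations )\n")
  print(signif(x$params, 5))
  if (length(x$fixed)) {
    cat("Fixed:\n")
    print(signif(x$fixed, 5))
  }
  cat("rss:", signif(x$rss, 5), " sigma:", signif(x$sigma, 4),
      " AIC:", signif(x$aic, 6), "\n")
  cat("Convergence:", x$convergence$method, "\n")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' @export
fitted.growth_fit <- function(object, ...) object$fitted

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
predict.growth_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  if (object$model == "logistic") {
    p <- logistic_params(object$params[["r"]], object$params[["K"]],
                         object$params[["T0"]])
    logistic_density(p, times)
  } else {
    simulate_cr(cr_fit_params(object), times)$consumer
  }
}

#' @export
logLik.growth_fit <- function(object, ...) {
  ll <- -object$aic / 2 + (object$k_free + 1)
  structure(ll, df = object$k_free + 1, nobs = object$n_obs,
            class = "logLik")
}

#' Simulate replicate observations from a fitted growth model
#'
#' Draws replicate growth curves from the fitted model with small-aliquot
#' Poisson counting noise (see [generate_growth_curves()]).
#'
#' @param object A `growth_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Optional RNG seed.
#' @param design A [sampling_design()]; defaults to the fit's own times.
#' @param ... Unused.
#' @return A data frame with columns `replicate`, `time_h`, `density_per_ml`.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                design = NULL, ...) {
  if (is.null(design)) {
    design <- sampling_design(times_h = object$data$time_h, dilution = 1)
  }
  truth <- if (object$model == "logistic") {
    logistic_params(object$params[["r"]], object$params[["K"]],
                    object$params[["T0"]])
  } else {
    cr_fit_params(object)
  }
  generate_growth_curves(truth, design = design, n_replicates = nsim,
                         seed = seed)
}

#' @export
plot.growth_fit <- function(x, ..., n_pred = 200) {
  tt <- seq(min(x$data$time_h), max(x$data$time_h), length.out = n_pred)
  plot(x$data$time_h, x$data$density_per_ml, xlab = "time (h)",
       ylab = expression(density ~ (ml^-1)), ...)
  lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  mtext(paste0(x$model, " fit, AIC = ", signif(x$aic, 5)), cex = 0.8)
  invisible(x)
}

#' @export
print.growth_model_comparison <- function(x, ...) {
  cat("Model comparison (Gaussian AIC):\n")
  cat("  AIC logistic:          ", signif(x$aic_logistic, 6), "\n")
  cat("  AIC consumer-resource: ", signif(x$aic_cr, 6), "\n")
  cat("  delta AIC (logistic - consumer-resource):",
      signif(x$delta_aic, 4), "\n")
  cat("  preferred model:", x$preferred, "\n")
  invisible(x)
}
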