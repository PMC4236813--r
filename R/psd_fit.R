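#' Fit psd module rate constants to cycloheximide-chase data
#'
#' The central fitting function of the package. Given replicate chase
#' time-series for one psd module variant measured in darkness and at 5
#' and 30 umol m^-2 s^-1 blue light, it estimates the rate constants
#' (k_degENDO, k_leak, k_dark, k_degLOV) by multiple shooting and a
#' constrained generalized Gauss-Newton iteration with soft Gaussian
#' priors and per-variant constraint rules (see [psd_problem]).
#'
#' @param data chase data.frame with columns `flux`, `replicate`,
#'   `time_min`, `abundance` (fractions of the t = 0 signal), covering the
#'   three light conditions; see [generate_chase_dataset] and
#'   [read_chase_csv].
#' @param variant variant name (see [variant_catalog]) controlling the
#'   constraint rules; `"custom"` applies no fixing.
#' @param ... passed to [psd_problem] (`p_init`, `priors`, `fixed`, `y0`,
#'   `nodes`, `sigma_data`, `estimate_khnu5`, `fluxes`).
#' @param max_iter,tol,verbose passed to [gauss_newton_solve].
#' @return an object of class `psd_fit` with methods [print.psd_fit],
#'   [summary.psd_fit], [coef.psd_fit], [vcov.psd_fit],
#'   [predict.psd_fit], [residuals.psd_fit], [simulate.psd_fit],
#'   [confint.psd_fit] and [plot.psd_fit].
#' @examples
#' truth <- psd_params()
#' d <- generate_chase_dataset(truth, n_reps = 4, cv = 0.1, seed = 1)
#' fit <- psd_fit(d, variant = "psd")
#' coef(fit)
#' @export
psd_fit <- function(data, variant = "psd", ..., max_iter = 50,
                    tol = 1e-8, verbose = FALSE) {
  problem <- psd_problem(data, variant = variant, ...)
  res <- gauss_newton_solve(problem, max_iter = max_iter, tol = tol,
                            verbose = verbose)
  structure(list(coefficients = res$estimates,
                 standard_deviations = res$standard_deviations,
                 free = problem$free,
                 vcov = res$covariance_params,
                 residual_norm = res$residual_norm,
                 constraint_violation = res$constraint_violation,
                 iterations = res$iterations,
                 converged = res$converged,
                 problem = problem, data = data,
                 gn = res, call = match.call()),
            class = "psd_fit")
}

#' @export
print.psd_fit <- function(x, ...) {
  cat(sprintf("psd module fit, variant \"%s\" (%s, %d iterations)\n",
              x$problem$variant,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  est <- x$coefficients
  sds <- x$standard_deviations
  for (nm in names(est)) {
    tag <- if (x$free[[nm]]) sprintf("%.5g +/- %.2g", est[[nm]], sds[[nm]])
           else sprintf("%.5g (fixed)", est[[nm]])
    cat(sprintf("  %-10s %s min^-1\n", nm, tag))
  }
  invisible(x)
}

#' @rdname print.psd_fit
#' @param object,x a `psd_fit` object.
#' @export
summary.psd_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(estimate = unname(est),
                    std_dev = unname(object$standard_deviations),
                    free = unname(object$free[names(est)]),
                    row.names = names(est))
  hl_dark <- halflife_from_rate(slow_decay_rate(fit_params(object), 0))
  hl_light <- halflife_from_rate(slow_decay_rate(fit_params(object), 1.2))
  out <- list(coefficients = tab, residual_norm = object$residual_norm,
              constraint_violation = object$constraint_violation,
              iterations = object$iterations, converged = object$converged,
              halflife_dark = hl_dark, halflife_light30 = hl_light,
              variant = object$problem$variant)
  class(out) <- "summary.psd_fit"
  out
}

#' @export
print.summary.psd_fit <- function(x, ...) {
  cat(sprintf("psd module fit, variant \"%s\"\n", x$variant))
  print(round(x$coefficients[1:2], 6))
  cat(sprintf("residual norm %.4g, constraint violation %.2g, %d iterations (%s)\n",
              x$residual_norm, x$constraint_violation, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("implied half-lives: %.3g min (darkness), %.3g min (30 umol light)\n",
              x$halflife_dark, x$halflife_light30))
  invisible(x)
}

#' @export
coef.psd_fit <- function(object, ...) object$coefficients

#' @export
vcov.psd_fit <- function(object, ...) object$vcov

# kinetic-parameter object at the fitted estimates
fit_params <- function(object) {
  p <- object$coefficients
  psd_params(k_dark = p[["k_dark"]], k_leak = p[["k_leak"]],
             k_degENDO = p[["k_degENDO"]], k_degLOV = p[["k_degLOV"]])
}

#' Fitted chase curves from a psd fit
#'
#' @param object a `psd_fit`.
#' @param times prediction times in minutes.
#' @param fluxes light conditions to predict (default those of the fit).
#' @param ... unused.
#' @return data.frame with columns `flux`, `time_min`, `abundance`
#'   (model-predicted fraction of the t = 0 total).
#' @export
predict.psd_fit <- function(object, times = seq(0, 90, by = 5),
                            fluxes = NULL, ...) {
  if (is.null(fluxes))
    fluxes <- vapply(object$problem$experiments, `[[`, numeric(1), "flux")
  p <- fit_params(object)
  do.call(rbind, lapply(fluxes, function(fl) {
    cbind(flux = fl,
          simulate_chase(p, flux = fl, timepoints = times,
                         y0 = object$problem$y0, mode = "ode"))
  }))
}

#' @export
residuals.psd_fit <- function(object, ...) {
  f <- shooting_residuals(object$gn$x, object$problem)
  n_data <- sum(vapply(object$problem$experiments, function(e)
    length(e$times), integer(1)))
  f$F1[seq_len(n_data)]
}

#' Simulate chase datasets from a fitted model
#'
#' Parametric simulation: generates new replicate chase datasets at the
#' fitted rate constants using the package's synthetic-data generator.
#'
#' @param object a `psd_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_reps,cv passed to [generate_chase_dataset].
#' @param ... unused.
#' @return a list of `nsim` chase data.frames.
#' @export
simulate.psd_fit <- function(object, nsim = 1, seed = 1, n_reps = 4,
                             cv = 0.1, ...) {
  p <- fit_params(object)
  lapply(seq_len(nsim), function(i)
    generate_chase_dataset(p, n_reps = n_reps, cv = cv,
                           seed = seed + i - 1L))
}

#' @export
confint.psd_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients[object$free]
  sds <- object$standard_deviations[object$free]
  if (missing(parm)) parm <- names(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - z * sds[parm], est[parm] + z * sds[parm])
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2,
                                            1 - (1 - level) / 2))
  out
}

#' Plot a psd fit
#'
#' Data (replicate means) and fitted chase curves per light condition.
#'
#' @param x a `psd_fit`.
#' @param ... passed to [graphics::matplot].
#' @export
plot.psd_fit <- function(x, ...) {
  pred <- predict(x, times = seq(0, 90, by = 2))
  fluxes <- sort(unique(pred$flux))
  cols <- grDevices::hcl.colors(max(3, length(fluxes)), "Dark 3")
  tmat <- sapply(fluxes, function(fl)
    pred$abundance[pred$flux == fl])
  graphics::matplot(unique(pred$time_min), tmat, type = "l", lty = 1,
                    col = cols, xlab = "time after translation shut-off (min)",
                    ylab = "fraction of t = 0 signal",
                    main = sprintf("variant %s", x$problem$variant), ...)
  d <- x$data
  for (i in seq_along(fluxes)) {
    di <- d[d$flux == fluxes[i], ]
    agg <- stats::aggregate(abundance ~ time_min, di, mean)
    graphics::points(agg$time_min, agg$abundance, col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = sprintf("%g umol m-2 s-1", fluxes),
                   col = cols[seq_along(fluxes)], lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}
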