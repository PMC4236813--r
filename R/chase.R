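# Cycloheximide-chase simulation and half-life quantification.

#' Simulate a cycloheximide chase
#'
#' Simulates the depletion of total PSD after translation shut-off under a
#' constant blue-light flux, normalized to the t = 0 signal — the in-silico
#' counterpart of a cycloheximide-chase immunoblot series.
#'
#' @param params a [psd_params] object.
#' @param flux blue-light flux in umol m^-2 s^-1.
#' @param timepoints sampling times in minutes (must include 0; default the
#'   standard chase design 0/30/60/90).
#' @param k_hnu directly specified photoconversion rate in min^-1,
#'   overriding `flux` (e.g. an estimated effective rate such as
#'   0.379 min^-1 for a nominally 5-umol condition).
#' @param y0 initial (dark, lit) counts; defaults to the published starting
#'   condition (49000, 1000).
#' @param mode "ode" (deterministic, exact linear propagation) or "ssa"
#'   (one exact stochastic realization).
#' @param canonical_rounding passed to [photoconversion_rate].
#' @param seed seed for `mode = "ssa"`.
#' @return data.frame with columns `time_min` and `abundance` (fraction of
#'   the t = 0 total).
#' @export
simulate_chase <- function(params, flux = 0, timepoints = c(0, 30, 60, 90),
                           y0 = c(49000, 1000), mode = c("ode", "ssa"),
                           canonical_rounding = TRUE, seed = 1, k_hnu = NULL) {
  mode <- match.arg(mode)
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  timepoints <- sort(unique(c(0, timepoints)))
  kh <- if (!is.null(k_hnu)) k_hnu
        else photoconversion_rate(flux, basis = params$k_hnu_per_flux,
                                  canonical_rounding = canonical_rounding)
  if (mode == "ode") {
    states <- t(vapply(timepoints, function(t)
      chase_propagate(params, kh, y0, t), numeric(2)))
    total <- rowSums(states)
  } else {
    chase_params <- params
    chase_params$k_translation <- 0  # translation blocked by cycloheximide
    prot <- light_protocol(0, max(timepoints) + 1, flux)
    if (!is.null(k_hnu)) {
      prot$flux <- k_hnu / params$k_hnu_per_flux  # exact-basis equivalent flux
      tr <- ssa_run(chase_params, c(round(y0), 0, 0), timepoints,
                    protocol = prot, canonical_rounding = FALSE, seed = seed)
    } else {
      tr <- ssa_run(chase_params, c(round(y0), 0, 0), timepoints,
                    protocol = prot, canonical_rounding = canonical_rounding, seed = seed)
    }
    total <- psd_total(tr)
  }
  data.frame(time_min = timepoints, abundance = total / total[1])
}

#' First-order exponential-decay fit
#'
#' Fits y = A exp(-t / tau) by nonlinear least squares on the linear scale
#' (no additive offset) and reports the half-life tau * ln(2) with a
#' standard error propagated from the fit covariance. This mirrors the
#' standard quantification of chase immunoblots with a first-order decay
#' model.
#'
#' Non-decaying data (best tau <= 0 or unbounded) yield a flagged estimate
#' with infinite half-life rather than an error.
#'
#' @param times sampling times in minutes (>= 3 points including t = 0).
#' @param values normalized abundances (> 0) at `times`.
#' @return object of class `decay_fit`: list with `halflife`,
#'   `standard_error` (both min), `rate` (min^-1), `tau`, `amplitude`,
#'   `decaying` (logical flag) and `n_points`.
#' @export
fit_exponential_decay <- function(times, values) {
  if (length(times) != length(values) || length(times) < 3)
    stop("need >= 3 (time, value) pairs")
  if (!any(times == 0)) stop("data must include t = 0")
  if (any(values <= 0)) stop("abundances must be positive")
  # starting values from the log-linear slope
  sl <- stats::coef(stats::lm(log(values) ~ times))
  if (!is.finite(sl[2]) || sl[2] >= -1e-12)
    return(decay_fit_flagged(length(times)))
  start <- list(A = exp(sl[[1]]), tau = -1 / sl[[2]])
  df <- data.frame(t = times, y = values)
  fit <- try(minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                               start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(decay_fit_flagged(length(times)))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0)
    return(decay_fit_flagged(length(times)))
  se_tau <- tryCatch(sqrt(diag(stats::vcov(fit)))[["tau"]],
                     error = function(e) NA_real_)
  structure(list(halflife = cf[["tau"]] * log(2),
                 standard_error = se_tau * log(2),
                 rate = 1 / cf[["tau"]], tau = cf[["tau"]],
                 amplitude = cf[["A"]], decaying = TRUE,
                 n_points = length(times)),
            class = "decay_fit")
}

decay_fit_flagged <- function(n) {
  structure(list(halflife = Inf, standard_error = NA_real_, rate = 0,
                 tau = Inf, amplitude = NA_real_, decaying = FALSE,
                 n_points = n),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$decaying) {
    cat("exponential decay fit: no decay detected (half-life flagged infinite)\n")
  } else {
    cat(sprintf("exponential decay fit: half-life %.3g min (se %.2g), A = %.3g, n = %d\n",
                x$halflife, x$standard_error, x$amplitude, x$n_points))
  }
  invisible(x)
}

#' Half-life from a replicate-structured chase dataset
#'
#' Fits each replicate decay curve separately with
#' [fit_exponential_decay] and averages the per-replicate half-lives,
#' reporting the mean with its standard error across replicates (the
#' standard mean +/- s.e.m. over independent chase measurements). With a
#' single replicate the fit's own standard error is reported.
#'
#' @param data a chase data.frame with columns `replicate`, `time_min`,
#'   `abundance` (e.g. one variant/flux subset of [generate_chase_dataset]
#'   output, or [read_chase_csv]).
#' @return list with `halflife` (min), `standard_error` (min), `rate`
#'   (min^-1), `n_curves`, and the per-replicate `fits`.
#' @export
fit_halflife <- function(data) {
  stopifnot(all(c("replicate", "time_min", "abundance") %in% names(data)))
  reps <- split(data, data$replicate)
  fits <- lapply(reps, function(d)
    fit_exponential_decay(d$time_min, d$abundance))
  hl <- vapply(fits, function(f) f$halflife, numeric(1))
  if (any(!is.finite(hl)))
    return(list(halflife = Inf, standard_error = NA_real_, rate = 0,
                n_curves = length(fits), fits = fits))
  se <- if (length(hl) > 1) stats::sd(hl) / sqrt(length(hl))
        else fits[[1]]$standard_error
  list(halflife = mean(hl), standard_error = se,
       rate = log(2) / mean(hl), n_curves = length(fits), fits = fits)
}

#' Model-predicted dark/light abundance ratio
#'
#' Steady-state total PSD in darkness divided by the steady-state total
#' under continuous illumination — the model counterpart of the measured
#' ratio of fluorescence in darkness versus blue light.
#'
#' @param params a [psd_params] object.
#' @param flux illuminated-condition flux (default 30 umol m^-2 s^-1).
#' @param canonical_rounding passed to [photoconversion_rate].
#' @return dimensionless ratio (> 1 when light destabilizes the protein).
#' @export
darklight_ratio <- function(params, flux = 30, canonical_rounding = TRUE) {
  dark <- steady_state(params, flux = 0, canonical_rounding = canonical_rounding)
  lit <- steady_state(params, flux = flux, canonical_rounding = canonical_rounding)
  tot_lit <- lit[["psd_dark"]] + lit[["psd_lit"]]
  if (tot_lit <= 0) stop("illuminated steady state is zero")
  (dark[["psd_dark"]] + dark[["psd_lit"]]) / tot_lit
}
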