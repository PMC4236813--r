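# Synthetic chase-data generation and variant fixtures.

#' Generate a synthetic cycloheximide-chase dataset
#'
#' Emulates the chase experiment design: for each light condition and
#' replicate, the chase is simulated, measurement noise is applied to the
#' raw totals, and each replicate curve is renormalized to its own t = 0
#' value — mimicking densitometry of immunoblots, where the error scales
#' with the signal and every lane series is expressed relative to the
#' chase start.
#'
#' @param params a [psd_params] object (the generating truth).
#' @param fluxes light conditions in umol m^-2 s^-1 (default the
#'   experimental design 0, 5, 30).
#' @param timepoints sampling times in minutes (default 0/30/60/90).
#' @param n_reps replicates per condition (>= 1; default 4).
#' @param cv coefficient of variation of the measurement noise (< 0.5;
#'   default 0.1).
#' @param noise "lognormal" (multiplicative, mean-one; default) or
#'   "gaussian" (additive, sd = cv x signal).
#' @param mode "ode" or "ssa" simulation of each replicate.
#' @param variant variant label stored in the output.
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @return data.frame with columns `variant`, `flux`, `replicate`,
#'   `time_min`, `abundance`.
#' @export
generate_chase_dataset <- function(params, fluxes = c(0, 5, 30),
                                   timepoints = c(0, 30, 60, 90),
                                   n_reps = 4, cv = 0.1,
                                   noise = c("lognormal", "gaussian"),
                                   mode = c("ode", "ssa"),
                                   variant = "synthetic", seed = 1) {
  noise <- match.arg(noise)
  mode <- match.arg(mode)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (cv < 0 || cv >= 0.5) stop("cv must be in [0, 0.5)")
  set.seed(seed)
  out <- list()
  for (fl in fluxes) {
    for (r in seq_len(n_reps)) {
      curve <- simulate_chase(params, flux = fl, timepoints = timepoints,
                              mode = mode,
                              seed = sample.int(.Machine$integer.max, 1))
      raw <- curve$abundance
      if (cv > 0) {
        raw <- if (noise == "lognormal") {
          sdlog <- sqrt(log(1 + cv^2))
          raw * stats::rlnorm(length(raw), meanlog = -sdlog^2 / 2,
                              sdlog = sdlog)
        } else {
          raw + stats::rnorm(length(raw), sd = cv * raw)
        }
        raw <- pmax(raw, 1e-9)
      }
      out[[length(out) + 1L]] <- data.frame(
        variant = variant, flux = fl, replicate = r,
        time_min = curve$time_min, abundance = raw / raw[1])
    }
  }
  do.call(rbind, out)
}

#' Catalog of characterized psd module variants
#'
#' Measured half-lives (mean +/- s.e.m., minutes) of the wild-type psd
#' module and 24 variants in darkness and under 30 umol m^-2 s^-1 blue
#' light, with the dark/light fluorescence ratio where determined, plus
#' the flags used by the estimation constraint rules: `degron_region`
#' (a mutation at or after residue K143, where changes can affect degron
#' activity; K143-region numbering starts at the methionine of the
#' AtLOV2 domain) and `photoreceptor_unchanged` (only the cODC1 degron
#' part modified). Deletions are written with a `d` prefix (dL156).
#'
#' @return data.frame with one row per variant (25 rows).
#' @export
variant_catalog <- function() {
  path <- system.file("extdata", "variant_halflives.csv", package = "psdkin")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rate constants matching target chase half-lives
#'
#' Inverse design: finds (k_degENDO, k_degLOV) such that the slow decay
#' rate of the chase model equals ln(2)/halflife in darkness and at the
#' illuminated condition, for given (fixed) k_dark and k_leak. Used to
#' construct synthetic ground truths resembling any cataloged variant.
#'
#' @param halflife_dark,halflife_light target half-lives in minutes
#'   (dark > 0, light <= dark).
#' @param k_dark,k_leak fixed photoreceptor rates, min^-1.
#' @param flux_light illuminated-condition flux (default 30).
#' @param tol Newton convergence tolerance on the decay rates.
#' @return a [psd_params] object whose [slow_decay_rate] matches the
#'   targets.
#' @export
params_for_target_halflives <- function(halflife_dark, halflife_light,
                                        k_dark = 0.59, k_leak = 0.01513,
                                        flux_light = 30, tol = 1e-10) {
  if (halflife_dark <= 0 || halflife_light <= 0)
    stop("half-lives must be > 0")
  if (halflife_light > halflife_dark)
    stop("light half-life must not exceed the dark half-life")
  lam_d <- rate_from_halflife(halflife_dark)
  lam_l <- rate_from_halflife(halflife_light)
  kh <- photoconversion_rate(flux_light, canonical_rounding = TRUE)
  slow_raw <- function(kE, kL, k) {
    A <- chase_mat_raw(kE, k_leak, k_dark, kL, k)
    tr <- A[1, 1] + A[2, 2]
    det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    (-tr - sqrt(max(tr^2 - 4 * det, 0))) / 2
  }
  g <- function(v) c(slow_raw(v[1], v[2], 0) - lam_d,
                     slow_raw(v[1], v[2], kh) - lam_l)
  lit_l <- (kh + k_leak) / (kh + k_leak + k_dark)
  v <- c(max(lam_d * 0.9, 1e-8), max((lam_l - lam_d) / lit_l, 1e-8))
  for (it in 1:100) {
    gv <- g(v)
    if (max(abs(gv)) < tol) break
    J <- matrix(0, 2, 2)
    for (i in 1:2) {
      h <- 1e-7 * max(abs(v[i]), 1e-4)
      vi <- v
      vi[i] <- vi[i] + h
      J[, i] <- (g(vi) - gv) / h
    }
    step <- solve(J, -gv)
    # damp to keep iterates in the positive orthant
    t_k <- 1
    while (any(v + t_k * step < 0) && t_k > 1e-6) t_k <- t_k / 2
    v <- v + t_k * step
  }
  if (max(abs(g(v))) > 1e-6 || any(v < 0))
    stop(sprintf(paste0("targets (%g, %g) min are infeasible for k_dark = %g, ",
                        "k_leak = %g: need light rate >= dark rate and both ",
                        "slower than the conformer exchange"),
                 halflife_dark, halflife_light, k_dark, k_leak))
  psd_params(k_dark = k_dark, k_leak = k_leak, k_degENDO = v[1],
             k_degLOV = v[2])
}
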