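# Deterministic and stochastic simulation of the psd module.

#' Integrate a psd model over a time grid
#'
#' Solves the initial-value problem for either the chase model (2 states)
#' or the full model (4 states) with an adaptive-step solver
#' ([deSolve::lsoda]) under a piecewise-constant light protocol.
#'
#' @param params a [psd_params] object.
#' @param y0 initial state: length 2 (chase: dark, lit) or length 4
#'   (full: dark, lit, mrna, gene_activity), non-negative.
#' @param times monotone increasing time grid in minutes.
#' @param protocol a [light_protocol]; alternatively pass `flux` for a
#'   constant flux over the whole grid.
#' @param flux constant blue-light flux in umol m^-2 s^-1 (ignored when
#'   `protocol` is given).
#' @param canonical_rounding passed to [photoconversion_rate].
#' @param rel_tol,abs_tol solver tolerances.
#' @return object of class `psd_traj`: list with `times`, `states` (matrix,
#'   one row per time), `species` names and `metadata`.
#' @export
integrate_model <- function(params, y0, times, protocol = NULL, flux = 0,
                            canonical_rounding = TRUE,
                            rel_tol = 1e-8, abs_tol = 1e-8) {
  stopifnot(inherits(params, "psd_params"))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(y0 < 0)) stop("initial state must be non-negative")
  if (is.null(protocol))
    protocol <- light_protocol(min(times), max(times) + 1, flux)
  chase <- length(y0) == 2
  deriv <- function(t, y, parms) {
    kh <- photoconversion_rate(protocol_flux_at(protocol, t),
                               basis = params$k_hnu_per_flux,
                               canonical_rounding = canonical_rounding)
    dy <- if (chase) chase_rhs(pmax(y, 0), params, kh)
          else full_rhs(pmax(y, 0), params, kh)
    list(dy)
  }
  out <- try(deSolve::lsoda(y0, times, deriv, parms = NULL,
                            rtol = rel_tol, atol = abs_tol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    last_t <- if (inherits(out, "try-error")) times[1] else out[nrow(out), 1]
    stop(sprintf("ODE integration failed; last good time %g min", last_t))
  }
  species <- if (chase) c("psd_dark", "psd_lit")
             else c("psd_dark", "psd_lit", "mrna", "gene_activity")
  new_traj(times, unname(out[, -1, drop = FALSE]), species,
           list(params = params, protocol = protocol, mode = "ode"))
}

new_traj <- function(times, states, species, metadata) {
  colnames(states) <- species
  structure(list(times = times, states = states, species = species,
                 metadata = metadata), class = "psd_traj")
}

#' @export
print.psd_traj <- function(x, ...) {
  cat(sprintf("psd trajectory: %d timepoints over [%g, %g] min, species: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Total PSD along a trajectory
#'
#' @param traj a `psd_traj` object.
#' @return numeric vector of PSD_dark + PSD_lit at each time.
#' @export
psd_total <- function(traj) {
  rowSums(traj$states[, c("psd_dark", "psd_lit"), drop = FALSE])
}

#' @export
as.data.frame.psd_traj <- function(x, ...) {
  data.frame(time = rep(x$times, times = length(x$species)),
             species = rep(x$species, each = length(x$times)),
             count = as.vector(x$states))
}

#' Exact stochastic simulation of the full psd model
#'
#' One realization of the Gillespie direct method over the reaction set
#' {transcription, mRNA decay, translation, dark-to-lit conversion at
#' k_hnu + k_leak, lit-to-dark reversion, endogenous degradation of either
#' conformer, degron-mediated degradation of the lit state}. The
#' photoconversion propensity follows the (piecewise-constant) light
#' protocol; the simulation clock restarts at segment boundaries. States
#' are reported at the grid times using the state after the last event at
#' or before each time (right-continuous step convention).
#'
#' @inheritParams integrate_model
#' @param y0 integer initial counts, length 4 as in [full_state_init];
#'   set `k_translation = 0` in `params` (or y0 mrna irrelevant) for a chase.
#' @param times report grid in minutes.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return a `psd_traj` with integer counts.
#' @export
ssa_run <- function(params, y0, times, protocol = NULL, flux = 0,
                    canonical_rounding = TRUE, seed = 1) {
  stopifnot(inherits(params, "psd_params"))
  if (any(y0[1:3] != round(y0[1:3])) || any(y0 < 0))
    stop("SSA initial counts (dark, lit, mrna) must be non-negative integers")
  if (is.unsorted(times)) stop("times must be increasing")
  if (is.null(protocol))
    protocol <- light_protocol(min(c(0, times)), max(times) + 1, flux)
  kh <- photoconversion_rate(protocol$flux, basis = params$k_hnu_per_flux,
                             canonical_rounding = canonical_rounding)
  set.seed(seed)
  st <- ssa_chase_cpp(as.numeric(y0[1:3]),
                      c(params$k_dark, params$k_leak, params$k_degENDO,
                        params$k_degLOV, params$k_translation,
                        params$k_mrna_deg, y0[4]),
                      as.numeric(protocol$start), as.numeric(protocol$end),
                      as.numeric(kh), as.numeric(times))
  states <- cbind(st, rep(y0[4], length(times)))
  new_traj(times, states,
           c("psd_dark", "psd_lit", "mrna", "gene_activity"),
           list(params = params, protocol = protocol, mode = "ssa",
                seed = seed))
}

#' Ensemble of stochastic chase runs
#'
#' Runs `n` independent SSA realizations; per-run seeds are derived
#' deterministically from `seed` (seed + run index).
#'
#' @inheritParams ssa_run
#' @param n number of realizations.
#' @return list with `times`, `total` (n x length(times) matrix of total
#'   PSD counts) and `mean`.
#' @export
ssa_ensemble <- function(params, y0, times, protocol = NULL, flux = 0,
                         canonical_rounding = TRUE, seed = 1, n = 200) {
  tot <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    tr <- ssa_run(params, y0, times, protocol, flux, canonical_rounding,
                  seed = seed + i - 1L)
    tot[i, ] <- psd_total(tr)
  }
  list(times = times, total = tot, mean = colMeans(tot))
}

#' Steady state of the full model
#'
#' Closed-form linear solve of the full-model fixed point: mRNA steady
#' state first (gene_activity / k_mrna_deg), then the 2x2 protein block
#' driven by the translation flux.
#'
#' @param params a [psd_params] object.
#' @param flux constant blue-light flux in umol m^-2 s^-1.
#' @param canonical_rounding passed to [photoconversion_rate].
#' @param gene_activity mRNA production activity, molecules min^-1.
#' @return named numeric steady state (psd_dark, psd_lit, mrna,
#'   gene_activity).
#' @export
steady_state <- function(params, flux = 0, canonical_rounding = TRUE,
                         gene_activity = params$k_transcription) {
  stopifnot(inherits(params, "psd_params"))
  if (params$k_mrna_deg <= 0) stop("k_mrna_deg must be > 0 for a steady state")
  kh <- photoconversion_rate(flux, basis = params$k_hnu_per_flux,
                             canonical_rounding = canonical_rounding)
  mrna <- gene_activity / params$k_mrna_deg
  A <- chase_matrix(params, kh)
  b <- c(params$k_translation * mrna, 0)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-300) stop("singular chase system: no unique steady state")
  y <- solve(A, -b)
  c(psd_dark = y[1], psd_lit = y[2], mrna = mrna,
    gene_activity = gene_activity)
}

#' Protein-depletion time course after a dark-to-light switch
#'
#' Starts the full model at its darkness steady state and simulates
#' continuous blue-light exposure, mirroring the canonical depletion
#' experiment (30 umol m^-2 s^-1 for 120 min).
#'
#' @inheritParams integrate_model
#' @param flux illumination flux during the time course.
#' @param duration length of the simulation in minutes.
#' @param n_points number of report points.
#' @param mode "ode" (deterministic) or "ssa" (one stochastic realization).
#' @param seed seed for `mode = "ssa"`.
#' @return a `psd_traj`; use [psd_total] for the depletion curve.
#' @export
depletion_timecourse <- function(params, flux = 30, duration = 120,
                                 n_points = 121, mode = c("ode", "ssa"),
                                 canonical_rounding = TRUE, seed = 1) {
  mode <- match.arg(mode)
  ss <- steady_state(params, flux = 0, canonical_rounding = canonical_rounding)
  times <- seq(0, duration, length.out = n_points)
  if (mode == "ode") {
    integrate_model(params, ss, times, flux = flux,
                    canonical_rounding = canonical_rounding)
  } else {
    ssa_run(params, c(round(ss[1:3]), ss[4]), times, flux = flux,
            canonical_rounding = canonical_rounding, seed = seed)
  }
}
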