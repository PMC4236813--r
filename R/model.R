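# Right-hand sides and closed-form analytics of the two-state psd model.
#
# Chase model (translation off): states y = (PSD_dark, PSD_lit),
#   d(dark)/dt = -(k_hnu + k_leak + k_degENDO) dark + k_dark lit
#   d(lit)/dt  =  (k_hnu + k_leak) dark - (k_dark + k_degENDO + k_degLOV) lit
# Endogenous degradation removes both conformers; the degron-mediated route
# acts on the lit state only.

#' System matrix of the chase model
#'
#' Returns the 2x2 matrix A such that d/dt (dark, lit) = A (dark, lit)
#' during a cycloheximide chase (protein production off).
#'
#' @param params a [psd_params] object.
#' @param k_hnu photoconversion rate in min^-1.
#' @return 2x2 numeric matrix.
#' @export
chase_matrix <- function(params, k_hnu) {
  stopifnot(inherits(params, "psd_params"), k_hnu >= 0)
  conv <- k_hnu + params$k_leak
  matrix(c(-(conv + params$k_degENDO), conv,
           params$k_dark, -(params$k_dark + params$k_degENDO + params$k_degLOV)),
         nrow = 2, ncol = 2)
}

#' Chase-model right-hand side
#'
#' Time derivative of the chase state (PSD_dark, PSD_lit) with protein
#' production inactivated.
#'
#' @param state numeric length-2 vector (psd_dark, psd_lit), >= 0.
#' @param params a [psd_params] object.
#' @param k_hnu photoconversion rate in min^-1.
#' @return numeric length-2 derivative vector (molecules min^-1).
#' @export
chase_rhs <- function(state, params, k_hnu) {
  if (length(state) != 2 || any(state < 0))
    stop("chase state must be two non-negative components (dark, lit)")
  as.vector(chase_matrix(params, k_hnu) %*% state)
}

#' Full-model right-hand side
#'
#' Time derivative of the full psd model state
#' (psd_dark, psd_lit, mrna, gene_activity): the chase dynamics plus a
#' protein-synthesis block in which a constant gene activity produces mRNA,
#' mRNA decays first-order, and translation adds dark-state protein (nascent
#' LOV2 folds to the dark conformation). Gene activity itself is constant.
#'
#' @param state numeric length-4 vector
#'   (psd_dark, psd_lit, mrna, gene_activity), all >= 0.
#' @inheritParams chase_rhs
#' @return numeric length-4 derivative vector.
#' @export
full_rhs <- function(state, params, k_hnu) {
  if (length(state) != 4 || any(state < 0))
    stop("full state must be four non-negative components")
  prot <- chase_rhs(state[1:2], params, k_hnu)
  prot[1] <- prot[1] + params$k_translation * state[3]
  c(prot, state[4] - params$k_mrna_deg * state[3], 0)
}

#' Default initial state of the full model
#'
#' The published simulation initial condition: 49000 dark-state and 1000
#' lit-state molecules, 89 mRNA molecules and a gene activity of
#' 3.3 molecules min^-1.
#'
#' @param params a [psd_params] object (supplies the gene activity).
#' @return named numeric length-4 state vector.
#' @export
full_state_init <- function(params = psd_params()) {
  c(psd_dark = 49000, psd_lit = 1000, mrna = 89,
    gene_activity = params$k_transcription)
}

#' Quasi-steady lit-state fraction
#'
#' Fraction of psd molecules in the lit state once the fast
#' photoconversion/reversion equilibrium is reached (degradation neglected):
#' (k_hnu + k_leak) / (k_hnu + k_leak + k_dark). With wild-type constants
#' this is 67% at 30 umol m^-2 s^-1 (k_hnu = 1.2), 27% at 5 umol (0.2) and
#' 2.5% in darkness.
#'
#' @inheritParams chase_rhs
#' @return lit-state fraction in [0, 1).
#' @export
quasi_steady_lit_fraction <- function(params, k_hnu) {
  stopifnot(inherits(params, "psd_params"))
  if (any(k_hnu < 0)) stop("k_hnu must be >= 0")
  conv <- k_hnu + params$k_leak
  denom <- conv + params$k_dark
  if (any(denom == 0)) stop("k_hnu + k_leak + k_dark must be > 0")
  conv / denom
}

#' Slow decay rate of the chase system
#'
#' The magnitude of the smaller-magnitude eigenvalue of the 2x2 chase
#' matrix, computed in closed form from trace and determinant. After the
#' fast conformer equilibration transient, total PSD decays exponentially
#' at this rate, so ln(2) divided by it is the model-predicted chase
#' half-life.
#'
#' @inheritParams chase_rhs
#' @return decay rate in min^-1 (>= 0).
#' @export
slow_decay_rate <- function(params, k_hnu) {
  A <- chase_matrix(params, k_hnu)
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr^2 - 4 * det  # = (a11-a22)^2 + 4 a12 a21 >= 0: eigenvalues real
  (-tr - sqrt(max(disc, 0))) / 2
}

# chase matrix from raw rates, without psd_params validation (used inside
# the estimator where intermediate iterates may violate soft invariants)
chase_mat_raw <- function(k_degENDO, k_leak, k_dark, k_degLOV, k_hnu) {
  conv <- k_hnu + k_leak
  matrix(c(-(conv + k_degENDO), conv,
           k_dark, -(k_dark + k_degENDO + k_degLOV)),
         nrow = 2, ncol = 2)
}

# Exact propagator of the linear chase ODE: y(t0 + dt) = expm(A dt) y0,
# via Putzer's form for a real 2x2 matrix with distinct or repeated
# eigenvalues. Exact up to roundoff; no integrator error enters the
# multiple-shooting residuals.
propagate_mat <- function(A, y0, dt) {
  if (dt == 0) return(y0)
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  s <- sqrt(max(tr^2 - 4 * det, 0))
  l1 <- (tr + s) / 2
  l2 <- (tr - s) / 2
  e1 <- exp(l1 * dt)
  d <- l1 - l2
  # r2 = (e^{l1 dt} - e^{l2 dt})/(l1 - l2), stable for small d
  r2 <- if (d * dt > 1e-8) exp(l2 * dt) * expm1(d * dt) / d else dt * e1
  E <- e1 * diag(2) + r2 * (A - l1 * diag(2))
  as.vector(E %*% y0)
}

chase_propagate <- function(params, k_hnu, y0, dt) {
  propagate_mat(chase_matrix(params, k_hnu), y0, dt)
}
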