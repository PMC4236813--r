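# Multi-experiment parameter estimation by multiple shooting and a
# constrained generalized Gauss-Newton method.
#
# The estimation problem: minimize over trajectories y^k and parameters p
#   sum_k sum_j ((H_j^k - q(y^k(t_j))) / Sigma_j)^2
#     + sum_i ((p_i - p_apriori_i) / Sigma_i)^2
# subject to dy^k/dt = f(y^k, u^k, p), y^k(0) = y0^k, for experiments
# k = 1..N_exp with light controls u^k. The measurement function is
# q(y) = y_1 + y_2 (total PSD). Multiple shooting introduces the states at
# grid nodes as unknowns s_j^k, joined by continuity constraints
# y^k(T_{j+1}; s_j^k, p) - s_{j+1}^k = 0, and the resulting constrained
# nonlinear least-squares problem is solved by a damped generalized
# Gauss-Newton iteration (null-space factorization of the linearized KKT
# system).


#' Measurement model of the chase experiments
#'
#' Total PSD, q(y) = PSD_dark + PSD_lit, optionally normalized by a
#' reference total when the data are fractions of the t = 0 signal.
#'
#' @param state numeric length-2 (dark, lit) vector or 2-column matrix.
#' @param reference total used for normalization (default 1: raw sum).
#' @return total (normalized) abundance.
#' @export
measurement_model <- function(state, reference = 1) {
  if (is.matrix(state)) rowSums(state[, 1:2, drop = FALSE]) / reference
  else (state[1] + state[2]) / reference
}

#' Build a multi-experiment estimation problem
#'
#' Assembles the three-condition (darkness, 5 and 30 umol m^-2 s^-1)
#' estimation problem for one psd module variant from replicate chase
#' data. The per-variant constraint rules are:
#' \itemize{
#'   \item `k_degENDO` carries a prior of 0.0025 min^-1 with a 10% band
#'     for every variant (mutations are assumed not to affect folding).
#'   \item `k_degLOV` carries a prior of 0.0564 min^-1 with a 10% band
#'     unless the variant has a mutation at or after residue K143 (the
#'     region that can alter degron activity), in which case it is free.
#'   \item `k_dark` and `k_leak` are fixed at 0.59 and 0.01513 min^-1 for
#'     the variants whose photoreceptor part is unchanged (`psd`,
#'     `deg_ODC`, `CACA`, `CACACA`) and free otherwise.
#'   \item all rates are bounded below by 0.
#' }
#' Priors are soft Gaussian penalties with sd = 0.1 x the prior mean;
#' explicit `priors`/`fixed` arguments override the variant rules.
#'
#' @param data chase data.frame (columns `flux`, `replicate`, `time_min`,
#'   `abundance`); replicate curves are averaged per flux and timepoint.
#' @param variant variant name matched against [variant_catalog], or a
#'   single-row data.frame from it. Unknown names fall back to the
#'   free-photoreceptor rules with a warning suppressed for `"custom"`.
#' @param p_init named starting values for the four rates (defaults:
#'   prior means where a prior exists, wild-type values otherwise).
#' @param priors named list `list(k = c(mean, sd))` overriding the rules;
#'   use `NULL` entries to drop a default prior.
#' @param fixed named numeric vector of parameters to fix (overrides rules).
#' @param y0 initial (dark, lit) state shared by all experiments, on the
#'   scale of the data (default the 2.5%-lit dark equilibrium as fractions).
#' @param nodes multiple-shooting grid (default the measurement layout
#'   0/30/60/90 min).
#' @param sigma_data measurement weight Sigma_j, on the data scale
#'   (default 0.05, i.e. 5% of the t = 0 signal).
#' @param estimate_khnu5 also estimate the photoconversion rate of the
#'   5-umol experiment as a fifth parameter (initialized at 0.2 min^-1
#'   with a 10% prior band); off by default.
#' @param fluxes the fluxes that must be present in `data`, mapped to
#'   controls u via [photoconversion_rate] with canonical rounding.
#' @return object of class `psd_problem`.
#' @export
psd_problem <- function(data, variant = "psd", p_init = NULL,
                        priors = NULL, fixed = NULL,
                        y0 = c(0.98, 0.02), nodes = c(0, 30, 60, 90),
                        sigma_data = 0.05, estimate_khnu5 = FALSE,
                        fluxes = c(0, 5, 30)) {
  stopifnot(all(c("flux", "replicate", "time_min", "abundance") %in% names(data)))
  if (nrow(data) == 0) stop("empty chase dataset")
  missing_flux <- setdiff(fluxes, unique(data$flux))
  if (length(missing_flux) > 0)
    stop("chase data lack required light conditions (flux): ",
         paste(missing_flux, collapse = ", "))
  if (length(nodes) < 2 || is.unsorted(nodes, strictly = TRUE))
    stop("shooting grid needs M >= 2 strictly increasing nodes")

  rules <- variant_rules(variant)
  # explicit overrides
  if (!is.null(fixed)) {
    rules$fixed <- fixed
  }
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      rules$priors[[nm]] <- priors[[nm]]
    }
    rules$priors <- Filter(Negate(is.null), rules$priors)
  }

  p_full <- c(k_degENDO = 0.0028, k_leak = 0.01513, k_dark = 0.59,
              k_degLOV = 0.048)
  for (nm in names(rules$priors)) p_full[nm] <- rules$priors[[nm]][1]
  for (nm in names(rules$fixed)) p_full[nm] <- rules$fixed[[nm]]
  if (!is.null(p_init)) p_full[names(p_init)] <- p_init
  free <- !(names(p_full) %in% names(rules$fixed))
  names(free) <- names(p_full)

  if (estimate_khnu5) {
    p_full <- c(p_full, k_hnu5 = 0.2)
    free <- c(free, k_hnu5 = TRUE)
    rules$priors$k_hnu5 <- c(0.2, 0.02)
  }

  experiments <- lapply(fluxes, function(fl) {
    d <- data[data$flux == fl & data$time_min > 0, ]
    agg <- stats::aggregate(abundance ~ time_min, d, mean)
    agg <- agg[order(agg$time_min), ]
    u <- photoconversion_rate(fl, canonical_rounding = TRUE)
    list(flux = fl, u = u, times = agg$time_min, H = agg$abundance,
         sigma = rep(sigma_data, nrow(agg)))
  })

  prior_tab <- if (length(rules$priors) > 0) {
    data.frame(param = names(rules$priors),
               mean = vapply(rules$priors, `[`, numeric(1), 1),
               sd = vapply(rules$priors, `[`, numeric(1), 2),
               row.names = NULL)
  } else data.frame(param = character(), mean = numeric(), sd = numeric())
  prior_tab <- prior_tab[prior_tab$param %in% names(p_full)[free], , drop = FALSE]

  structure(list(experiments = experiments, nodes = nodes, y0 = y0,
                 p_full = p_full, free = free, priors = prior_tab,
                 lower = stats::setNames(rep(0, length(p_full)), names(p_full)),
                 variant = rules$name),
            class = "psd_problem")
}

# constraint rules for a variant: which parameters are fixed and which
# carry priors, from the mutation list (K143 region rule)
variant_rules <- function(variant) {
  if (is.character(variant)) {
    cat_tab <- variant_catalog()
    row <- cat_tab[cat_tab$name == variant, ]
    if (nrow(row) == 0) {
      row <- data.frame(name = variant, degron_region = FALSE,
                        photoreceptor_unchanged = FALSE)
    }
  } else {
    row <- as.data.frame(variant)
  }
  priors <- list(k_degENDO = c(0.0025, 0.00025))
  if (!isTRUE(row$degron_region[1]))
    priors$k_degLOV <- c(0.0564, 0.00564)
  fixed <- if (isTRUE(row$photoreceptor_unchanged[1]))
    c(k_dark = 0.59, k_leak = 0.01513) else numeric(0)
  list(name = row$name[1], priors = priors, fixed = fixed)
}

#' @export
print.psd_problem <- function(x, ...) {
  cat(sprintf("psd estimation problem, variant \"%s\": %d experiments (u = %s), %d shooting nodes\n",
              x$variant, length(x$experiments),
              paste(vapply(x$experiments, `[[`, numeric(1), "u"),
                    collapse = "/"),
              length(x$nodes)))
  cat("  free parameters:",
      paste(names(x$p_full)[x$free], collapse = ", "), "\n")
  if (length(fx <- names(x$p_full)[!x$free]) > 0)
    cat("  fixed:", paste(sprintf("%s = %g", fx, x$p_full[fx]),
                          collapse = ", "), "\n")
  if (nrow(x$priors) > 0)
    cat("  priors:", paste(sprintf("%s ~ %g +/- %g", x$priors$param,
                                   x$priors$mean, x$priors$sd),
                           collapse = ", "), "\n")
  invisible(x)
}

# ---- variable packing -------------------------------------------------

# x = (s_2^1, ..., s_M^1, s_2^2, ..., s_M^{Nexp}, p_free); s_1^k = y0 fixed
n_state_vars <- function(problem) {
  2L * (length(problem$nodes) - 1L) * length(problem$experiments)
}

pack_x <- function(problem, states = NULL, p = NULL) {
  M <- length(problem$nodes)
  if (is.null(states)) {
    # default: noiseless forward simulation at p_full
    states <- unlist(lapply(problem$experiments, function(ex) {
      y <- problem$y0
      out <- numeric(0)
      for (j in seq_len(M - 1)) {
        y <- propagate_mat(problem_mat(problem, problem$p_full, ex$u),
                           y, problem$nodes[j + 1] - problem$nodes[j])
        out <- c(out, y)
      }
      out
    }))
  }
  if (is.null(p)) p <- problem$p_full[problem$free]
  c(states, p)
}

unpack_params <- function(problem, x) {
  p <- problem$p_full
  nf <- sum(problem$free)
  if (nf > 0) p[problem$free] <- x[(length(x) - nf + 1):length(x)]
  p
}

problem_mat <- function(problem, p, u) {
  kh <- if ("k_hnu5" %in% names(p) && isTRUE(all.equal(u, 0.2)))
    p[["k_hnu5"]] else u
  chase_mat_raw(p[["k_degENDO"]], p[["k_leak"]], p[["k_dark"]],
                p[["k_degLOV"]], kh)
}

# ---- residuals and Jacobians -----------------------------------------

#' Multiple-shooting residual and constraint vectors
#'
#' Evaluates at a stacked variable vector x = (shooting states, free
#' parameters):
#' \itemize{
#'   \item `F1` — weighted data mismatches (H_j^k - q(y)) / Sigma_j over
#'     all experiments, followed by the active prior residuals
#'     (p_i - p_apriori_i) / Sigma_i;
#'   \item `F2` — continuity constraints
#'     y^k(T_{j+1}; s_j^k, p) - s_{j+1}^k from the per-interval
#'     initial-value solves.
#' }
#' Measurements at times inside an interval are evaluated by propagating
#' from the interval's left node, so the grid need not contain the
#' measurement times.
#'
#' @param x stacked variable vector (see [psd_problem]); shooting states
#'   first, then the free parameters.
#' @param problem a [psd_problem].
#' @return list with numeric vectors `F1` and `F2`.
#' @export
shooting_residuals <- function(x, problem) {
  M <- length(problem$nodes)
  n_exp <- length(problem$experiments)
  p <- unpack_params(problem, x)
  F1 <- numeric(0)
  F2 <- numeric(0)
  for (k in seq_len(n_exp)) {
    ex <- problem$experiments[[k]]
    A <- problem_mat(problem, p, ex$u)
    off <- (k - 1L) * 2L * (M - 1L)
    nodes_states <- rbind(problem$y0,
                          matrix(x[off + seq_len(2 * (M - 1))],
                                 ncol = 2, byrow = TRUE))
    # data residuals: propagate from owning node
    for (i in seq_along(ex$times)) {
      t_i <- ex$times[i]
      j <- findInterval(t_i, problem$nodes, rightmost.closed = TRUE)
      y <- propagate_mat(A, nodes_states[j, ], t_i - problem$nodes[j])
      F1 <- c(F1, (ex$H[i] - measurement_model(y)) / ex$sigma[i])
    }
    # continuity constraints
    for (j in seq_len(M - 1)) {
      y_end <- propagate_mat(A, nodes_states[j, ],
                             problem$nodes[j + 1] - problem$nodes[j])
      F2 <- c(F2, y_end - nodes_states[j + 1, ])
    }
  }
  if (nrow(problem$priors) > 0)
    F1 <- c(F1, (p[problem$priors$param] - problem$priors$mean) /
              problem$priors$sd)
  list(F1 = F1, F2 = F2)
}

#' Finite-difference Jacobians of the shooting residuals
#'
#' Forward finite differences with per-variable step 1e-6 x max(|x_i|, 1).
#' The chase propagator is exact (closed-form matrix exponential), so the
#' difference quotients are free of integrator noise.
#'
#' @inheritParams shooting_residuals
#' @return list with matrices `J1` (d F1 / d x) and `J2` (d F2 / d x).
#' @export
sensitivity_jacobian <- function(x, problem) {
  base <- shooting_residuals(x, problem)
  n <- length(x)
  J1 <- matrix(0, length(base$F1), n)
  J2 <- matrix(0, length(base$F2), n)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(x[i]), 1)
    xi <- x
    xi[i] <- xi[i] + h
    fi <- shooting_residuals(xi, problem)
    J1[, i] <- (fi$F1 - base$F1) / h
    J2[, i] <- (fi$F2 - base$F2) / h
  }
  if (any(!is.finite(J1)) || any(!is.finite(J2)))
    stop("non-finite entries in the sensitivity Jacobian")
  list(J1 = J1, J2 = J2)
}

# ---- generalized Gauss-Newton core -----------------------------------

#' Damped generalized Gauss-Newton for constrained least squares
#'
#' Solves min ||F1(x)||^2 subject to F2(x) = 0. Each iteration linearizes
#' both maps and solves the constrained linear least-squares subproblem
#'   min ||F1 + J1 dx||^2  s.t.  F2 + J2 dx = 0
#' by a null-space factorization (QR of t(J2) for the null-space basis, a
#' minimum-norm particular solution for the constraints, then ordinary
#' least squares in the reduced space). Steps are damped by backtracking
#' with t in {1, 1/2, ..., 2^-10} under the natural-level (restricted
#' monotonicity) test — a damped step is accepted when the simplified
#' next increment contracts — and are truncated at lower bounds.
#'
#' Standard deviations of the estimates come from the inverse reduced
#' normal matrix at the solution, scaled by the residual variance
#' estimate ||F1||^2 / (m1 - n_red).
#'
#' @param fn function(x) returning list(F1, F2).
#' @param jac function(x) returning list(J1, J2); default forward finite
#'   differences of `fn`.
#' @param x0 starting vector.
#' @param lower optional lower bounds (same length as x0; -Inf allowed).
#' @param max_iter maximum accepted steps.
#' @param tol convergence tolerance on the step norm (relative).
#' @param constraint_tol feasibility tolerance on max|F2|.
#' @param verbose print per-iteration diagnostics.
#' @return list with `x`, `iterations`, `converged`, `residual_norm`
#'   (||F1||), `constraint_violation` (max|F2|), `covariance` (of x) and
#'   `step_sizes`.
#' @export
gauss_newton <- function(fn, x0, jac = NULL, lower = NULL,
                         max_iter = 50, tol = 1e-8,
                         constraint_tol = 1e-8, verbose = FALSE) {
  if (is.null(jac)) jac <- function(x) fd_jacobian(fn, x)
  if (is.null(lower)) lower <- rep(-Inf, length(x0))
  x <- x0
  f <- fn(x)
  if (any(!is.finite(c(f$F1, f$F2)))) stop("non-finite residuals at x0")
  iterations <- 0L
  converged <- FALSE
  step_sizes <- numeric(0)
  J <- NULL
  n <- length(x0)
  for (it in seq_len(max_iter + 1L)) {
    J <- jac(x)
    dx <- ggn_step(f, J)
    # active-set handling: a variable at its lower bound whose increment
    # points outward is frozen; the increment (and the simplified
    # increments of the damping test below) use the reduced Jacobian
    act <- is.finite(lower) & x <= lower + 1e-10 * (1 + abs(lower)) & dx < 0
    step_fun <- function(fv) ggn_step(fv, J)
    if (any(act)) {
      drop <- which(act)
      Jr <- list(J1 = J$J1[, -drop, drop = FALSE],
                 J2 = J$J2[, -drop, drop = FALSE])
      dxr <- tryCatch(ggn_step(f, Jr), error = function(e) NULL)
      if (!is.null(dxr) && all(is.finite(dxr))) {
        step_fun <- function(fv) {
          z <- numeric(n)
          z[-drop] <- ggn_step(fv, Jr)
          z
        }
        dx <- numeric(n)
        dx[-drop] <- dxr
      }
    }
    if (sqrt(sum(dx^2)) < tol * (1 + sqrt(sum(x^2))) &&
        (length(f$F2) == 0 || max(abs(f$F2)) < constraint_tol)) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
    # natural-level (restricted monotonicity) test: accept the damped step
    # when the simplified next increment, computed with the current
    # Jacobian, contracts relative to the current increment
    nrm0 <- sqrt(sum(dx^2))
    accepted <- FALSE
    for (tk in 2^-(0:10)) {
      x_new <- pmax(x + tk * dx, lower)
      f_new <- tryCatch(fn(x_new), error = function(e) NULL)
      if (is.null(f_new) || !all(is.finite(c(f_new$F1, f_new$F2)))) next
      dx_simp <- tryCatch(step_fun(f_new), error = function(e) NULL)
      if (is.null(dx_simp) || !all(is.finite(dx_simp))) next
      if (sqrt(sum(dx_simp^2)) <= (1 - tk / 2) * nrm0 + 1e-15) {
        x <- x_new
        f <- f_new
        step_sizes <- c(step_sizes, tk)
        accepted <- TRUE
        break
      }
    }
    iterations <- iterations + 1L
    if (verbose)
      message(sprintf("iter %d: |F1| = %.6g, max|F2| = %.3g, t = %g",
                      iterations, sqrt(sum(f$F1^2)),
                      if (length(f$F2)) max(abs(f$F2)) else 0,
                      if (accepted) step_sizes[length(step_sizes)] else 0))
    if (!accepted) {
      # stalled: accept as converged if the proposed step was already tiny
      # and the iterate is feasible (merit flat at the FD noise floor)
      converged <- sqrt(sum(dx^2)) < sqrt(tol) * (1 + sqrt(sum(x^2))) &&
        (length(f$F2) == 0 || max(abs(f$F2)) < constraint_tol)
      break
    }
  }
  cov <- ggn_covariance(f, J)
  list(x = x, iterations = iterations, converged = converged,
       residual_norm = sqrt(sum(f$F1^2)),
       constraint_violation = if (length(f$F2)) max(abs(f$F2)) else 0,
       covariance = cov, step_sizes = step_sizes)
}

fd_jacobian <- function(fn, x) {
  base <- fn(x)
  n <- length(x)
  J1 <- matrix(0, length(base$F1), n)
  J2 <- matrix(0, length(base$F2), n)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(x[i]), 1)
    xi <- x
    xi[i] <- xi[i] + h
    fi <- fn(xi)
    J1[, i] <- (fi$F1 - base$F1) / h
    J2[, i] <- (fi$F2 - base$F2) / h
  }
  list(J1 = J1, J2 = J2)
}

# one constrained Gauss-Newton increment (null-space method)
ggn_step <- function(f, J) {
  n <- ncol(J$J1)
  m2 <- length(f$F2)
  if (m2 == 0) {
    qr1 <- qr(J$J1)
    return(qr.coef(qr1, -f$F1))
  }
  qrt <- qr(t(J$J2))
  if (qrt$rank < m2)
    stop("ill-posed (well-posedness check failed): constraint Jacobian rank deficient")
  # minimum-norm particular solution of J2 dx = -F2
  dx_p <- t(J$J2) %*% solve(J$J2 %*% t(J$J2), -f$F2)
  if (qrt$rank == n) return(as.vector(dx_p))
  Z <- qr.Q(qrt, complete = TRUE)[, (qrt$rank + 1):n, drop = FALSE]
  Mred <- J$J1 %*% Z
  w <- qr.coef(qr(Mred), -(f$F1 + J$J1 %*% dx_p))
  w[is.na(w)] <- 0
  as.vector(dx_p + Z %*% w)
}

ggn_covariance <- function(f, J) {
  n <- ncol(J$J1)
  m2 <- length(f$F2)
  Z <- if (m2 == 0) diag(n) else {
    qrt <- qr(t(J$J2))
    if (qrt$rank >= n) return(matrix(0, n, n))
    qr.Q(qrt, complete = TRUE)[, (qrt$rank + 1):n, drop = FALSE]
  }
  Mred <- J$J1 %*% Z
  nred <- ncol(Z)
  dof <- length(f$F1) - nred
  sigma2 <- if (dof > 0) sum(f$F1^2) / dof else 1
  MtM <- crossprod(Mred)
  inv <- tryCatch(solve(MtM), error = function(e) {
    warning("reduced normal matrix singular; covariance unavailable")
    matrix(NA_real_, nred, nred)
  })
  sigma2 * Z %*% inv %*% t(Z)
}

#' Solve a psd estimation problem
#'
#' Runs the damped generalized Gauss-Newton iteration on a [psd_problem],
#' starting from the forward simulation at the problem's initial
#' parameter guess.
#'
#' @param problem a [psd_problem].
#' @param x0 optional starting vector (default: forward-simulated
#'   shooting states at the initial parameters).
#' @param max_iter,tol,constraint_tol,verbose passed to [gauss_newton].
#' @return list (`psd_gn_result`) with named `estimates`,
#'   `standard_deviations`, `residual_norm`, `constraint_violation`,
#'   `iterations`, `converged`, the full variable vector `x` and the
#'   parameter covariance.
#' @export
gauss_newton_solve <- function(problem, x0 = NULL, max_iter = 50,
                               tol = 1e-8, constraint_tol = 1e-8,
                               verbose = FALSE) {
  if (is.null(x0)) x0 <- pack_x(problem)
  ns <- n_state_vars(problem)
  lower <- c(rep(-Inf, ns), problem$lower[problem$free])
  res <- gauss_newton(function(x) shooting_residuals(x, problem),
                      x0, jac = function(x) sensitivity_jacobian(x, problem),
                      lower = lower, max_iter = max_iter, tol = tol,
                      constraint_tol = constraint_tol, verbose = verbose)
  p_hat <- unpack_params(problem, res$x)
  nf <- sum(problem$free)
  sd_full <- stats::setNames(rep(0, length(p_hat)), names(p_hat))
  cov_p <- matrix(0, nf, nf,
                  dimnames = list(names(p_hat)[problem$free],
                                  names(p_hat)[problem$free]))
  if (nf > 0) {
    idx <- (length(res$x) - nf + 1):length(res$x)
    cov_p <- res$covariance[idx, idx, drop = FALSE]
    dimnames(cov_p) <- list(names(p_hat)[problem$free],
                            names(p_hat)[problem$free])
    sd_full[problem$free] <- sqrt(pmax(diag(cov_p), 0))
  }
  structure(list(estimates = p_hat, standard_deviations = sd_full,
                 residual_norm = res$residual_norm,
                 constraint_violation = res$constraint_violation,
                 iterations = res$iterations, converged = res$converged,
                 x = res$x, covariance_params = cov_p, problem = problem),
            class = "psd_gn_result")
}
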