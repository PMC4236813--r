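# Multiple-shooting residuals, Jacobians and the constrained
# generalized Gauss-Newton estimator.

test_that("measurement model sums the two conformer pools", {
  expect_equal(measurement_model(c(49000, 1000)), 50000)
  expect_equal(measurement_model(c(0, 0)), 0)
  expect_equal(measurement_model(c(49000, 1000), reference = 50000), 1)
  m <- matrix(c(1, 2, 3, 4), ncol = 2)
  expect_equal(measurement_model(m), c(4, 6))
})

test_that("per-variant constraint rules are applied", {
  d <- noiseless_dataset()
  # degron-region variant: photoreceptor rates fixed, k_degLOV free
  pr_cacaca <- psd_problem(d, variant = "CACACA")
  expect_false(pr_cacaca$free[["k_dark"]])
  expect_false(pr_cacaca$free[["k_leak"]])
  expect_true(pr_cacaca$free[["k_degLOV"]])
  expect_false("k_degLOV" %in% pr_cacaca$priors$param)
  expect_true("k_degENDO" %in% pr_cacaca$priors$param)
  # LOV-core variant: k_degLOV prior-banded, photoreceptor rates free
  pr_km <- psd_problem(d, variant = "K121M N128Y")
  expect_true(all(pr_km$free))
  expect_true(all(c("k_degENDO", "k_degLOV") %in% pr_km$priors$param))
  expect_equal(pr_km$priors$mean[pr_km$priors$param == "k_degLOV"], 0.0564)
  expect_equal(pr_km$priors$sd[pr_km$priors$param == "k_degLOV"], 0.00564)
  expect_equal(pr_km$priors$mean[pr_km$priors$param == "k_degENDO"], 0.0025)
  # wild type: photoreceptor fixed AND k_degLOV prior-banded
  pr_wt <- psd_problem(d, variant = "psd")
  expect_false(pr_wt$free[["k_dark"]])
  expect_true("k_degLOV" %in% pr_wt$priors$param)
  # missing light condition is reported by flux
  expect_error(psd_problem(d[d$flux != 5, ]), "5")
  expect_error(psd_problem(d[0, ]), "empty")
})

test_that("shooting residuals vanish at the generating truth", {
  d <- noiseless_dataset()
  pr <- psd_problem(d, variant = "custom", priors = truth_priors())
  x <- psdkin:::pack_x(pr)
  f <- shooting_residuals(x, pr)
  expect_lt(max(abs(f$F1[1:9])), 1e-9)   # data residuals
  expect_lt(max(abs(f$F2)), 1e-12)       # matching conditions
  # prior residuals measure the offset from the prior mean
  expect_equal(length(f$F1), 9 + nrow(pr$priors))
  pr_np <- psd_problem(d, variant = "custom",
                       priors = list(k_degENDO = NULL, k_degLOV = NULL))
  f_np <- shooting_residuals(psdkin:::pack_x(pr_np), pr_np)
  expect_equal(length(f_np$F1), 9)
})

test_that("perturbing one shooting node touches only adjacent blocks", {
  d <- noiseless_dataset()
  pr <- psd_problem(d, variant = "custom", priors = truth_priors())
  x <- psdkin:::pack_x(pr)
  f0 <- shooting_residuals(x, pr)
  # node s_3 of experiment 1 occupies x[3:4]; its continuity blocks are
  # intervals 2 (arriving) and 3 (departing) of experiment 1
  xp <- x
  xp[3] <- xp[3] + 1e-3
  f1 <- shooting_residuals(xp, pr)
  changed <- which(abs(f1$F2 - f0$F2) > 1e-12)
  expect_true(all(changed %in% 3:6))
  # constraint blocks of other experiments untouched
  expect_true(all(changed <= 6))
})

test_that("finite-difference Jacobians are consistent and sparse", {
  d <- noiseless_dataset()
  pr <- psd_problem(d, variant = "psd")
  x <- psdkin:::pack_x(pr) * (1 + 0.02)
  J <- sensitivity_jacobian(x, pr)
  # prior block of J1 is diag(1/sd) in the parameter columns
  np <- nrow(pr$priors)
  n <- length(x)
  prior_rows <- (nrow(J$J1) - np + 1):nrow(J$J1)
  free_names <- names(pr$p_full)[pr$free]
  for (i in seq_len(np)) {
    col <- n - length(free_names) + match(pr$priors$param[i], free_names)
    expect_equal(J$J1[prior_rows[i], col], 1 / pr$priors$sd[i],
                 tolerance = 1e-6)
  }
  # central-difference oracle agreement
  fd_central <- function(i) {
    h <- 1e-5 * max(abs(x[i]), 1)
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (shooting_residuals(xp, pr)$F2 - shooting_residuals(xm, pr)$F2) / (2 * h)
  }
  for (i in c(1, 7, n)) {
    expect_equal(J$J2[, i], fd_central(i), tolerance = 1e-4)
  }
  # fixed parameters contribute no columns (they are not in x): the
  # variable count is states + free parameters only
  expect_equal(n, psdkin:::n_state_vars(pr) + sum(pr$free))
})

test_that("Gauss-Newton solves affine problems in one full step", {
  fn <- function(x) list(F1 = c(2 * x[1] + x[2] - 4, x[2] - 1, x[1] + 3 * x[3]),
                         F2 = as.numeric(x[1] - x[3] - 2))
  r <- gauss_newton(fn, c(10, -5, 3))
  expect_true(r$converged)
  expect_equal(r$iterations, 1L)
  expect_equal(r$step_sizes, 1)
  expect_lt(abs(r$constraint_violation), 1e-8)
  # unconstrained affine case reduces to linear least squares
  fn2 <- function(x) list(F1 = c(x[1] - 1, x[1] + x[2] - 3), F2 = numeric(0))
  r2 <- gauss_newton(fn2, c(50, 50))
  expect_equal(r2$x, c(1, 2), tolerance = 1e-7)
  expect_equal(r2$iterations, 1L)
})

test_that("rank-deficient constraints are reported as ill-posed", {
  fn <- function(x) list(F1 = x[1] - 1,
                         F2 = c(x[1] - x[2], 2 * x[1] - 2 * x[2] - 5))
  expect_error(gauss_newton(fn, c(0, 0)), "well-posedness")
})

test_that("noiseless three-condition data regenerate the truth exactly", {
  d <- noiseless_dataset()
  fit <- psd_fit(d, variant = "custom", priors = truth_priors(),
                 p_init = wt_truth * c(1.5, 0.7, 1.3, 0.6))
  expect_true(fit$converged)
  rel <- abs(coef(fit) - wt_truth) / wt_truth
  expect_lt(max(rel), 0.01)
  expect_lt(fit$constraint_violation, 1e-8)
  expect_lt(fit$residual_norm, 1e-6)
  # the trajectory assembled from shooting intervals is continuous
  f <- shooting_residuals(fit$gn$x, fit$problem)
  expect_lt(max(abs(f$F2)), 1e-8)
})

test_that("single- and multiple-shooting solutions agree", {
  d <- noiseless_dataset()
  args <- list(variant = "custom", priors = truth_priors(),
               p_init = wt_truth * c(1.4, 0.8, 1.2, 0.7))
  fit_m <- do.call(psd_fit, c(list(d), args))
  fit_s <- do.call(psd_fit, c(list(d, nodes = c(0, 90)), args))
  expect_true(fit_s$converged)
  expect_equal(coef(fit_s), coef(fit_m), tolerance = 1e-4)
  # and the estimate is invariant to a finer grid
  fit_f <- do.call(psd_fit, c(list(d, nodes = seq(0, 90, by = 15)), args))
  expect_equal(coef(fit_f), coef(fit_m), tolerance = 1e-4)
})

test_that("noisy replicate data recover k_degLOV with calibrated errors", {
  p <- wt_params()
  runs <- lapply(1:20, function(s) {
    d <- generate_chase_dataset(p, n_reps = 4, cv = 0.1, seed = s)
    psd_fit(d, variant = "custom", priors = truth_priors())
  })
  relerr <- vapply(runs, function(f)
    abs(coef(f)[["k_degLOV"]] - 0.048) / 0.048, numeric(1))
  expect_lt(median(relerr), 0.15)
  covered <- vapply(runs, function(f)
    abs(coef(f)[["k_degLOV"]] - 0.048) <=
      2 * f$standard_deviations[["k_degLOV"]], logical(1))
  expect_gte(mean(covered), 0.6)
  expect_true(all(vapply(runs, function(f)
    f$constraint_violation < 1e-8, logical(1))))
})

test_that("the fitted-model interface exposes the standard generics", {
  d <- generate_chase_dataset(wt_params(), n_reps = 2, cv = 0.05, seed = 5)
  fit <- psd_fit(d, variant = "psd")
  expect_s3_class(fit, "psd_fit")
  expect_named(coef(fit), c("k_degENDO", "k_leak", "k_dark", "k_degLOV"))
  expect_equal(dim(vcov(fit)), c(2, 2))  # two free parameters for psd
  s <- summary(fit)
  expect_s3_class(s, "summary.psd_fit")
  expect_gt(s$halflife_dark, 50)
  pred <- predict(fit, times = c(0, 45, 90))
  expect_equal(nrow(pred), 9)
  expect_true(all(pred$abundance[pred$time_min == 0] == 1))
  expect_length(residuals(fit), 9)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit)[fit$free] &
                    coef(fit)[fit$free] < ci[, 2]))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_identical(names(sims[[1]]),
                   c("variant", "flux", "replicate", "time_min", "abundance"))
})

test_that("the 5-umol photoconversion rate can be co-estimated", {
  d <- generate_chase_dataset(wt_params(), n_reps = 4, cv = 0.05, seed = 8)
  fit <- psd_fit(d, variant = "psd", estimate_khnu5 = TRUE)
  expect_true(fit$converged)
  expect_true("k_hnu5" %in% names(coef(fit)))
  expect_gt(coef(fit)[["k_hnu5"]], 0.1)
  expect_lt(coef(fit)[["k_hnu5"]], 0.3)
})
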