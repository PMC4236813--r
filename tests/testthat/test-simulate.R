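# ODE integration, stochastic simulation, steady states, depletion.

test_that("integrator reproduces closed forms", {
  # all rates (near) zero: constant trajectory
  p0 <- psd_params(k_dark = 1e-12, k_degENDO = 0, k_degLOV = 0, k_leak = 0,
                   k_translation = 0, k_transcription = 0)
  tr <- integrate_model(p0, c(500, 100), 0:10, flux = 0)
  expect_equal(psd_total(tr), rep(600, 11), tolerance = 1e-8)
  # pure dark-state decay: exact exponential
  p1 <- psd_params(k_dark = 1, k_leak = 0, k_degENDO = 0.01, k_degLOV = 0)
  tr1 <- integrate_model(p1, c(1000, 0), seq(0, 200, by = 10), flux = 0)
  expect_equal(tr1$states[, "psd_dark"], 1000 * exp(-0.01 * tr1$times),
               tolerance = 1e-7)
  # slow-mode dominance of the wild-type chase at 30 umol
  p <- wt_params()
  tr2 <- integrate_model(p, c(49000, 1000), c(0, 90), flux = 30)
  expect_equal(psd_total(tr2)[2] / 50000, exp(-slow_decay_rate(p, 1.2) * 90),
               tolerance = 0.03)
})

test_that("exact propagator matches the adaptive integrator", {
  p <- wt_params()
  for (kh in c(0, 0.2, 1.2)) {
    tr <- integrate_model(p, c(49000, 1000), c(0, 30, 60, 90),
                          flux = c(0, 5, 30)[match(kh, c(0, 0.2, 1.2))],
                          rel_tol = 1e-12, abs_tol = 1e-12)
    prop <- t(vapply(c(0, 30, 60, 90), function(t)
      psdkin:::chase_propagate(p, kh, c(49000, 1000), t), numeric(2)))
    expect_equal(unname(tr$states), prop, tolerance = 1e-9)
  }
})

test_that("SSA is reproducible, integer-valued and conserving", {
  p <- wt_params()
  y0 <- c(49000, 1000, 89, 3.3)
  t1 <- ssa_run(p, y0, times = seq(0, 30, 3), flux = 30, seed = 11)
  t2 <- ssa_run(p, y0, times = seq(0, 30, 3), flux = 30, seed = 11)
  expect_identical(t1$states, t2$states)
  t3 <- ssa_run(p, y0, times = seq(0, 30, 3), flux = 30, seed = 12)
  expect_false(identical(t1$states, t3$states))
  expect_true(all(t1$states[, 1:3] == round(t1$states[, 1:3])))
  expect_true(all(t1$states >= 0))
  # degradation and production off: total PSD conserved exactly
  pc <- psd_params(k_degENDO = 0, k_degLOV = 0, k_translation = 0)
  tc <- ssa_run(pc, c(300, 100, 0, 0), times = 0:90, flux = 30, seed = 2)
  expect_true(all(psd_total(tc) == 400))
  # all propensities zero: constant counts
  tz <- ssa_run(pc, c(10, 0, 0, 0), times = 0:5, flux = 0, seed = 3)
  expect_true(all(tz$states[, "psd_dark"] == 10))
  expect_error(ssa_run(p, c(10.5, 0, 0, 0), times = 0:5), "integer")
})

test_that("SSA ensemble mean tracks the ODE solution", {
  p <- wt_params()
  chase_p <- psd_params(k_translation = 0)
  times <- c(0, 30, 60, 90)
  ens <- ssa_ensemble(chase_p, c(49000, 1000, 0, 0), times, flux = 30,
                      seed = 7, n = 200)
  ode <- psd_total(integrate_model(p, c(49000, 1000), times, flux = 30))
  se <- apply(ens$total, 2, stats::sd) / sqrt(nrow(ens$total))
  z <- abs(ens$mean[-1] - ode[-1]) / se[-1]
  expect_true(all(z < 3))
})

test_that("steady state solves the fixed-point equations", {
  p <- wt_params()
  for (fl in c(0, 5, 30)) {
    ss <- steady_state(p, fl)
    expect_lt(max(abs(full_rhs(ss, p,
                               photoconversion_rate(fl)))), 1e-10)
  }
  # darkness steady state: near the published round initial values, with
  # lit share at the quasi-steady fraction
  ss0 <- steady_state(p, 0)
  tot <- ss0[["psd_dark"]] + ss0[["psd_lit"]]
  expect_gt(tot, 40000)
  expect_lt(tot, 50000)
  # lit share within 0.2 percentage points of the quasi-steady fraction
  expect_lt(abs(ss0[["psd_lit"]] / tot - quasi_steady_lit_fraction(p, 0)),
            0.002)
  expect_equal(ss0[["mrna"]], 3.3 / 0.039)
  # translation off: protein components exactly zero
  ss_off <- steady_state(psd_params(k_translation = 0), 30)
  expect_equal(unname(ss_off[c("psd_dark", "psd_lit")]), c(0, 0))
  # fixed point of the integrator over long horizons
  tr <- integrate_model(p, ss0, c(0, 500, 1000), flux = 0,
                        rel_tol = 1e-10, abs_tol = 1e-10)
  expect_equal(unname(tr$states[3, ]), unname(ss0), tolerance = 1e-6)
})

test_that("depletion time course starts at the dark steady state and is monotone", {
  p <- wt_params()
  dep <- depletion_timecourse(p, flux = 30, duration = 120)
  tot <- psd_total(dep)
  ss0 <- steady_state(p, 0)
  expect_equal(tot[1], ss0[["psd_dark"]] + ss0[["psd_lit"]])
  expect_true(all(diff(tot) <= 1e-9))
  # approaches the illuminated steady state from above
  ss30 <- steady_state(p, 30)
  expect_gt(tot[length(tot)], ss30[["psd_dark"]] + ss30[["psd_lit"]])
  # variant ranking by time to 50% depletion follows the light half-life
  cat_rows <- c("psd", "R154G E155S", "N148E")
  hl <- c(20, 6.4, 39)
  t50 <- vapply(hl, function(h) {
    pv <- params_for_target_halflives(120, h)
    d <- depletion_timecourse(pv, flux = 30, duration = 240, n_points = 481)
    tt <- psd_total(d)
    d$times[which(tt <= tt[1] / 2)[1]]
  }, numeric(1))
  expect_equal(order(t50), order(hl))
})

test_that("stochastic depletion follows a light protocol with segments", {
  p <- wt_params()
  prot <- light_protocol(c(0, 60), c(60, 120), c(0, 30))
  tr <- ssa_run(p, c(43000, 1100, 85, 3.3), times = seq(0, 120, 5),
                protocol = prot, seed = 4)
  tot <- psd_total(tr)
  # depletion only begins once the light turns on at t = 60
  expect_gt(min(tot[tr$times <= 60]), 0.85 * tot[1])
  expect_lt(tot[length(tot)], 0.5 * tot[1])
})
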