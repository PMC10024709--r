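# IK1 formulations: gating, rectification, current densities, I/V analysis.

test_that("configuration validates inputs and applies conductance scaling", {
  cfg <- ik1_config("ventr", scaling_DC = 0.5)
  expect_equal(ik1_g_eff(cfg), 1.908 * 0.5)
  expect_equal(ik1_g_eff(ik1_config("atr", scaling_DC = 2)), 1.4)
  # test variants use their fixed printed conductances, unscaled
  expect_equal(ik1_g_eff(ik1_config("test1", scaling_DC = 0.5)), 6.417)
  expect_equal(ik1_g_eff(ik1_config("test2", scaling_DC = 3)), 6.258)
  expect_error(ik1_config("ventr", scaling_DC = -1), "scaling_DC")
  expect_error(ik1_config("ventr", Ko = 0), "Ko")
  expect_error(ik1_config("ventr", G_base = -2), "G_base")
})

test_that("gate steady state has the printed midpoint and asymptotes", {
  Ko <- 4
  expect_equal(xk1_inf(-(2.5538 * Ko + 144.59), Ko), 0.5)
  # the gate deactivates at strongly hyperpolarized potentials and is fully
  # open over the physiological range
  expect_equal(xk1_inf(-300, Ko), 0, tolerance = 1e-6)
  expect_equal(xk1_inf(-82, Ko), 0.9992664, tolerance = 1e-6)
  V <- seq(-300, 60, by = 1)
  x <- xk1_inf(V, Ko)
  expect_true(all(x > 0 & x < 1))
  expect_true(all(diff(x) > 0))
  expect_error(xk1_inf(-80, Ko = -1), "Ko")
})

test_that("gate time constant is positive with the printed value at -127.2 mV", {
  expect_equal(xk1_tau(-127.2), 122.2 / (1 + exp((-127.2 + 236.8) / 69.33)))
  expect_equal(xk1_tau(-127.2), 20.8566, tolerance = 1e-4)
  V <- seq(-200, 60, by = 0.5)
  expect_true(all(xk1_tau(V) > 0))
  # argmax location agrees with a dense 0.01 mV brute-force grid
  dense <- seq(-200, 60, by = 0.01)
  expect_lt(abs(V[which.max(xk1_tau(V))] -
                dense[which.max(xk1_tau(dense))]), 0.5)
})

test_that("exponential gate update is exact: fixed point, dt = 0, ODE oracle", {
  skip_if_not_installed("deSolve")
  cfg <- ik1_config("ventr")
  for (V in c(-120, -90, -60)) {
    xi <- xk1_inf(V, cfg$Ko)
    expect_equal(update_gate(xi, V, 17.3, cfg), xi)
    expect_equal(update_gate(0.2, V, 0, cfg), 0.2)
  }
  expect_error(update_gate(0.5, -80, -1, cfg), "dt")
  expect_error(update_gate(1.2, -80, 1, cfg), "xk1")
  # 500 ms of repeated Rush-Larsen steps vs a high-accuracy ODE integration
  V <- -70; x0 <- 0.1
  x_rl <- x0
  for (i in 1:500) x_rl <- update_gate(x_rl, V, 1, cfg)
  ode <- deSolve::lsoda(
    c(x = x0), times = c(0, 500),
    func = function(t, y, p) list((xk1_inf(V) - y) / xk1_tau(V)),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(x_rl, unname(ode[2, "x"]), tolerance = 1e-4)
  # after >= 10 tau the gate sits at its steady state
  expect_equal(x_rl, xk1_inf(V), tolerance = 1e-4)
})

test_that("rectification factor has printed midpoint and decreases with voltage", {
  Ko <- 4
  expect_equal(rk1(-105.8 + 2.6 * Ko, Ko), 0.5)
  expect_equal(rk1(-1e4, Ko), 1)
  expect_equal(rk1(-82, Ko), 0.1959871, tolerance = 1e-6)
  V <- seq(-150, 60, by = 1)
  r <- rk1(V, Ko)
  expect_true(all(r > 0 & r < 1) && all(diff(r) < 0))
})

test_that("ventricular current: reversal, frozen value at -82 mV, linear scaling", {
  cfg <- ik1_config("ventr")
  expect_identical(ik1_ventr(-94.7, cfg = cfg), 0)
  expect_equal(ik1_ventr(-82, cfg = cfg), 9.491194, tolerance = 1e-5)
  V <- seq(-120, 0, by = 5)
  expect_equal(ik1_ventr(V, cfg = ik1_config("ventr", scaling_DC = 2)),
               2 * ik1_ventr(V, cfg = cfg))
  expect_error(ik1_ventr(-80, cfg = ik1_config("atr")), "ventr")
})

test_that("atrial current: reversal, frozen value at -71 mV, linear scaling", {
  cfg <- ik1_config("atr")
  expect_identical(ik1_atr(-94.7, cfg), 0)
  expect_equal(ik1_atr(-71, cfg), 5.422856, tolerance = 1e-5)
  V <- seq(-120, 0, by = 5)
  expect_equal(ik1_atr(V, ik1_config("atr", scaling_DC = 3)),
               3 * ik1_atr(V, cfg))
  expect_error(ik1_atr(-80, ik1_config("test1")), "atr")
})

test_that("test variants swap one constant each and reject mismatched configs", {
  t1 <- ik1_config("test1"); t2 <- ik1_config("test2")
  expect_identical(ik1_variant(-94.7, cfg = t1), 0)
  expect_identical(ik1_variant(-94.7, cfg = t2), 0)
  # test1 gate midpoint moves to -(2.5538*Ko + 57.836)
  expect_equal(xk1_inf(-(2.5538 * 4 + 57.836), 4, xinf_mid = 57.836), 0.5)
  # test2 rectification midpoint moves to -135.8 + 2.6*Ko
  expect_equal(rk1(-135.8 + 2.6 * 4, 4, rk1_mid = 135.8, rk1_slope = 15.493),
               0.5)
  expect_error(ik1_variant(-80, cfg = ik1_config("ventr")), "test1")
})

test_that("steady-state I/V: reversal on grid, rectification ordering, IO round trip", {
  iv_v <- steady_iv(ik1_config("ventr"), -94.7, 0, dv = 0.1)
  expect_false(is.unsorted(iv_v$V_mV))
  expect_identical(iv_v$I_pApF[1], 0)  # EK on the grid
  at0 <- which.min(abs(iv_v$V_mV))
  # strong ventricular rectification: tiny current at 0 mV vs its peak
  expect_lt(iv_v$I_pApF[at0], max(iv_v$I_pApF))
  iv_a <- steady_iv(ik1_config("atr"), -94.7, 0, dv = 0.1)
  expect_gt(iv_a$I_pApF[at0], iv_v$I_pApF[at0])
  expect_error(steady_iv(ik1_config("atr"), 0, -10), "v_min")
  expect_error(steady_iv(ik1_config("atr"), -10, 0, dv = 0), "dv")
  f <- tempfile(fileext = ".csv")
  write_iv_csv(iv_a, f)
  back <- read_iv_csv(f)
  expect_equal(back$I_pApF, iv_a$I_pApF, tolerance = 1e-9)
  expect_identical(attr(back, "formulation"), "atr")
})

test_that("I/V peak voltages match the published positions", {
  pv <- iv_peak(ik1_config("ventr"))
  expect_lte(abs(pv$V_peak - (-82)), 2)
  pa <- iv_peak(ik1_config("atr"))
  expect_lte(abs(pa$V_peak - (-71)), 2)
  # test1 moves the ventricular peak to the atrial position
  p1 <- iv_peak(ik1_config("test1"))
  expect_lte(abs(p1$V_peak - pa$V_peak), 3)
  expect_error(iv_peak(ik1_config("atr"), dv = -0.1), "dv")
  # grid argmax agrees with a 0.001 mV brute-force grid to within dv
  fine <- iv_peak(ik1_config("ventr"), dv = 0.001)
  expect_lte(abs(fine$V_peak - pv$V_peak), 0.01)
})

test_that("every formulation is zero at EK and proportional to its conductance", {
  V <- seq(-150, 60, by = 2.5)
  for (fm in c("ventr", "atr", "test1", "test2")) {
    cfg <- ik1_config(fm)
    expect_identical(ik1_current(-94.7, cfg), 0)
    I1 <- ik1_current(V, cfg)
    cfg2 <- ik1_config(fm, G_base = cfg$G_base * 1.7)
    expect_equal(ik1_current(V, cfg2), 1.7 * I1, tolerance = 1e-12)
    expect_true(all(sign(I1) == sign(V - cfg$EK)))
  }
})

test_that("ventricular I/V is more rectified than atrial at default configs", {
  r_v <- ik1_current(0, ik1_config("ventr")) / iv_peak(ik1_config("ventr"))$I_peak
  r_a <- ik1_current(0, ik1_config("atr")) / iv_peak(ik1_config("atr"))$I_peak
  expect_lt(r_v, r_a)
})
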