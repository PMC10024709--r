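# The virtual DC loop, formulation switching, AP-clamp, and GK1 titration.

test_that("zero conductance reproduces the uninjected trace bitwise", {
  pr <- pr_fast()
  plain <- simulate_ap(cell_atr(), pr)
  dc0 <- run_dc(cell_atr(), ik1_config("atr", scaling_DC = 0), pr)
  expect_identical(dc0$voltage$Vm, plain$Vm)
  expect_identical(max(abs(dc0$current$I)), 0)
})

test_that("atrial-formulation injection hyperpolarizes the diastolic potential", {
  for (dc in list(dc_atr_on_atr(), dc_atr_on_ven())) {
    bm <- extract_biomarkers(dc$voltage, discard_beats = 3)
    expect_lte(bm$E_diast_DC, -75)
  }
})

test_that("the injected current reverses exactly where Vm crosses EK", {
  dc <- dc_atr_on_atr()
  expect_true(all(sign(dc$current$I) == sign(dc$voltage$Vm - (-94.7)) |
                  dc$current$I == 0))
})

test_that("zero-order-hold loop matches continuous coupling to within 2% APD90", {
  pr <- pr_fast()
  for (cell in list(cell_atr(), cell_ven())) {
    for (fm in c("atr", "ventr")) {
      cfg <- ik1_config(fm, scaling_DC = 1)
      a_zoh <- extract_biomarkers(run_dc(cell, cfg, pr)$voltage,
                                  discard_beats = 3)$APD90
      a_cont <- extract_biomarkers(
        run_dc(cell, cfg, pr, continuous = TRUE)$voltage,
        discard_beats = 3)$APD90
      expect_lt(abs(a_zoh - a_cont) / a_cont, 0.02)
    }
  }
})

test_that("formulation switching: no-op swap is exact, atr->ventr prolongs APD90", {
  pr <- stim_protocol(n_beats = 10, discard_beats = 2)
  base <- run_dc(cell_atr(), ik1_config("atr"), pr)
  s <- dc_session(cell_atr(), ik1_config("atr"), pr)
  s <- switch_formulation(s, ik1_config("atr"), at_ms = 3050)
  same <- run_dc(s)
  expect_identical(same$voltage$Vm, base$voltage$Vm)
  expect_match(paste(same$log, collapse = "\n"), "t=3050 ms: switch")
  # switching to the ventricular formulation mid-run lengthens later beats
  s2 <- dc_session(cell_atr(), ik1_config("atr"), pr)
  s2 <- switch_formulation(s2, ik1_config("ventr"), at_ms = 5040)
  sw <- run_dc(s2)
  pb <- extract_biomarkers(sw$voltage, discard_beats = 2)$per_beat
  apd_pre <- stats::median(pb$APD90[pb$beat <= 3])   # beats 3-5 overall
  apd_post <- stats::median(pb$APD90[pb$beat >= 5])  # beats 7+ overall
  expect_gt(apd_post, apd_pre)
})

test_that("AP-clamp playback reads out the formulation along a fixed trace", {
  t <- seq(0, 100, by = 0.2)
  flat <- voltage_trace(t, rep(-94.7, length(t)), 0.2)
  for (fm in c("ventr", "atr", "test1", "test2")) {
    ct <- ap_clamp(ik1_config(fm), flat)
    expect_identical(length(ct$I), length(t))
    expect_true(all(ct$I == 0))
  }
  # instantaneous atrial formulation equals its direct evaluation
  ramp <- voltage_trace(t, seq(-94.7, 0, length.out = length(t)), 0.2)
  expect_equal(ap_clamp(ik1_config("atr"), ramp)$I,
               ik1_atr(ramp$Vm, ik1_config("atr")))
  # gated formulation converges to steady current on a held potential
  hold <- voltage_trace(seq(0, 500, by = 0.2),
                        rep(-60, 2501), 0.2)
  I <- ap_clamp(ik1_config("ventr"), hold)$I
  expect_equal(I[length(I)], ik1_ventr(-60, cfg = ik1_config("ventr")),
               tolerance = 1e-6)
  bad <- voltage_trace(c(0, 0.2, 0.5), c(-80, -80, -80), 0.2)
  expect_error(ap_clamp(ik1_config("atr"), bad), "uniform")
})

test_that("titration uses the printed default grids and monotone hyperpolarization", {
  pr <- pr_fast()
  ta <- cached("titr_atr", titrate_gk1(cell_atr(), "atr", protocol = pr))
  tv <- cached("titr_ven", titrate_gk1(cell_ven(), "ventr", protocol = pr))
  expect_identical(nrow(ta), 17L)
  expect_identical(nrow(tv), 17L)
  expect_equal(ta$scaling, seq(0.2, 1, by = 0.05))
  expect_equal(tv$scaling, seq(0.4, 2, by = 0.1))
  # E_diast hyperpolarizes (non-increasing within 1 mV) along the grid
  expect_true(all(diff(ta$E_diast) < 1))
  expect_true(all(diff(tv$E_diast) < 1))
  expect_error(titrate_gk1(cell_atr(), "atr", grid = c(0.5, 0.3)), "grid")
})

test_that("a failing titration point is flagged but the table is returned", {
  pr0 <- stim_protocol(pulse_amplitude = 0, n_beats = 5, discard_beats = 2)
  w <- capture_warnings(
    tt <- titrate_gk1(cell_atr(), "atr", grid = c(0.2, 0.3, 0.4),
                      protocol = pr0))
  expect_length(w, 3)
  expect_match(w, "failed", all = TRUE)
  expect_identical(nrow(tt), 3L)
  expect_true(all(!tt$ok))
})

test_that("critical-conductance detection implements the plateau rule", {
  mk <- function(ediast, apd90, ratio, apa, scaling = seq_along(ediast)) {
    structure(data.frame(scaling = scaling, E_diast = ediast, APD90 = apd90,
                         APD20_APD90 = ratio, APA = apa, ok = TRUE),
              G_base = 0.7)
  }
  # constant table: the first grid value is already critical
  const <- mk(rep(-80, 5), rep(150, 5), rep(0.3, 5), rep(120, 5))
  r <- find_critical_gk1(const)
  expect_true(r$converged)
  expect_equal(r$scaling, 1)
  expect_equal(r$conductance, 0.7)
  # 20% changes up to index 3, < 1% afterwards: critical at grid[3]
  drift <- function(k, n, step_big, step_small, x0) {
    x <- numeric(n); x[1] <- x0
    for (i in 2:n) x[i] <- x[i - 1] * (1 + ifelse(i <= k, step_big, step_small))
    x
  }
  tab <- mk(drift(3, 6, -0.2, -0.005, -60), drift(3, 6, 0.2, 0.005, 100),
            drift(3, 6, 0.2, 0.005, 0.30), drift(3, 6, 0.2, 0.005, 110))
  r2 <- find_critical_gk1(tab)
  expect_true(r2$converged)
  expect_equal(r2$scaling, 3)
  # 10% changes throughout: an explicit no-convergence result, not an error
  none <- mk(drift(6, 6, -0.1, NA, -60), drift(6, 6, 0.1, NA, 100),
             drift(6, 6, 0.1, NA, 0.30), drift(6, 6, 0.1, NA, 110))
  r3 <- find_critical_gk1(none)
  expect_false(r3$converged)
  expect_true(is.na(r3$conductance))
  expect_error(find_critical_gk1(const[1:2, ]), ">= 3")
})

test_that("the critical conductance of the default surrogate lies on the grid", {
  ta <- cached("titr_atr", titrate_gk1(cell_atr(), "atr", protocol = pr_fast()))
  r <- find_critical_gk1(ta)
  expect_true(r$converged)
  expect_true(r$scaling >= 0.2 && r$scaling <= 1.0)
  expect_equal(r$conductance, r$scaling * 0.7)
})
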