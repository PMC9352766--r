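test_that("gap trajectory follows triangular contact-release kinematics", {
  prof <- motion_profile(v = 0.5, x_min = 1e-4, x_max = 0.0125)
  # static device
  st <- gap_trajectory(c(0, 10, 500), motion_profile(v = 0))
  expect_equal(st$x, rep(0.0125, 3))
  expect_equal(st$dxdt, rep(0, 3))
  # constant approach speed after t_start
  tr <- gap_trajectory(c(1, 2, 5), prof)
  expect_equal(tr$x, 0.0125 - 0.5 / 1000 * c(1, 2, 5))
  expect_equal(tr$dxdt, rep(-0.5, 3))
  # closed-form period: 2 (x_max - x_min) / v
  period_ms <- 2 * (0.0125 - 1e-4) / 0.5 * 1000
  wrap <- gap_trajectory(period_ms, prof)
  expect_equal(wrap$x, 0.0125, tolerance = 1e-12)
  # turning samples keep the incoming one-sided velocity; use a profile
  # whose turning times are exactly representable in floating point
  prof2 <- motion_profile(v = 1000, x_min = 0.5, x_max = 1.5)
  turn <- gap_trajectory(1, prof2)       # tau = D exactly
  expect_equal(turn$x, 0.5)
  expect_equal(turn$dxdt, -1000)         # approach velocity retained
  back <- gap_trajectory(2, prof2)       # full period: back at x_max
  expect_equal(back$x, 1.5)
  expect_equal(back$dxdt, 1000)          # release velocity retained
  expect_error(gap_trajectory(-1, prof), "non-negative")
})

test_that("coupling terms vanish for static devices and constant curves", {
  crv <- flat_curve()
  expect_equal(coupling_terms(0.005, 0, -60, crv)$I_drive, 0)
  const <- fixture_curve("constant", voc0 = 100, cap0 = 1e-9)
  expect_equal(coupling_terms(0.005, -1, -60, const)$I_drive, 0)
})

test_that("linear-voltage constant-capacitance fixture gives the hand-computed drive", {
  slope <- 2e6                       # V/m
  capA <- 0.2                        # uF/cm^2 per area
  lin <- fixture_curve("linear_voc_const_C", voc_slope = slope,
                       cap0 = 0.2e-6 * 15e-5 * 1e4, plate_area = 15e-5)
  v <- -0.5                          # cm/s, approaching
  ct <- coupling_terms(0.005, v, -60, lin)
  # I = -C dVoc/dx dx/dt, in uF/cm^2 * mV/cm * cm/ms
  expected <- -capA * (slope * 1e3 * 1e-2) * (v / 1000)
  expect_equal(ct$I_drive, expected, tolerance = 1e-12)
  expect_equal(ct$C_x, capA, tolerance = 1e-12)
})

test_that("device capacitance at or above the membrane capacitance is rejected", {
  big <- const_cap_curve(1.5)
  expect_error(coupling_terms(0.005, -0.5, -60, big), "C_m")
  cfg <- short_axon()
  expect_error(run_coupled(cfg, motion_profile(v = 0.5), big), "C_m")
})

test_that("a zero-capacitance device at any speed reduces bit-for-bit to the plain run", {
  cfg <- short_axon(t_end = 2)
  z <- zero_cap_curve()
  plain <- run_plain(cfg, NULL)
  for (v in c(0, 0.5)) {
    coup <- run_coupled(cfg, motion_profile(v = v), z)
    expect_identical(coup$V_trace, plain$V_trace)
  }
  # same reduction in the reference engine
  coup_r <- run_coupled(cfg, motion_profile(v = 0), z, engine = "r")
  plain_r <- run_plain(cfg, NULL, engine = "r")
  expect_identical(coup_r$V_trace, plain_r$V_trace)
})

test_that("a constant-capacitance zero-voltage device rescales the membrane capacitance", {
  cfg <- short_axon(t_end = 2)
  cc <- const_cap_curve(0.3)
  coup <- run_coupled(cfg, motion_profile(v = 0.5), cc,
                      stim = stimulus_protocol(amplitude = 10, t_off = 2))
  ref <- run_plain(axon_config(n_compartments = 12, length = 0.12,
                               t_end = 2),
                   stimulus_protocol(amplitude = 10, t_off = 2),
                   p = membrane_params(C_m = 0.7))
  expect_identical(coup$V_trace, ref$V_trace)
})

test_that("a static charged device perturbs the plain run only through its capacitive load", {
  cfg <- short_axon(t_end = 5)
  crv <- flat_curve()
  coup <- run_coupled(cfg, motion_profile(v = 0), crv)
  plain <- run_plain(cfg, NULL)
  # per-area device capacitance is ~1e-5 of C_m: traces agree very closely
  expect_lt(max(abs(coup$V_trace - plain$V_trace)), 1e-3)
})

test_that("runs fail loudly when the curve does not cover the motion range", {
  cfg <- short_axon()
  narrow <- fixture_curve("constant", gaps = seq(1e-5, 5e-5, length.out = 5),
                          cap0 = 0)
  expect_error(run_coupled(cfg, motion_profile(v = 0.5), narrow), "cover")
})

test_that("compiled and reference engines agree on coupled runs", {
  cfg <- short_axon(t_end = 2)
  crv <- flat_curve()
  prof <- motion_profile(v = 5)  # fast enough to traverse segments in 2 ms
  a <- run_coupled(cfg, prof, crv, engine = "cpp")
  b <- run_coupled(cfg, prof, crv, engine = "r")
  expect_lt(max(abs(a$V_trace - b$V_trace)), 1e-10)
  expect_equal(a$x, b$x, tolerance = 1e-12)
})

test_that("the logged gap trajectory matches the closed-form kinematics", {
  cfg <- short_axon(t_end = 2)
  crv <- flat_curve()
  prof <- motion_profile(v = 2)
  res <- run_coupled(cfg, prof, crv)
  expect_equal(res$x, gap_trajectory(res$times, prof)$x, tolerance = 1e-12)
})
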