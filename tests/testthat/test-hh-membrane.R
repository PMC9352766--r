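test_that("rate constants are finite and positive, including at the removable singularities", {
  V <- seq(-100, 60, by = 0.5)
  r <- rate_constants(V)
  for (nm in names(r)) {
    expect_true(all(is.finite(r[[nm]])), info = nm)
    expect_true(all(r[[nm]] > 0), info = nm)
  }
  # u = 10 and u = 25 are the 0/0 points of the alpha functions; the limits
  # are a*b = 0.1 and 1.0
  sing <- rate_constants(c(-50, -35))
  expect_equal(sing$an[1], 0.1, tolerance = 1e-9)
  expect_equal(sing$am[2], 1.0, tolerance = 1e-9)
  # continuity across the series branch
  eps <- 1e-7
  near <- rate_constants(c(-50 - eps, -50 + eps))
  expect_equal(near$an[1], near$an[2], tolerance = 1e-6)
  expect_error(rate_constants(NaN), "finite")
})

test_that("steady-state gating has the classical activation/inactivation shapes", {
  V <- seq(-100, 60, by = 1)
  ss <- steady_state_gating(V)
  for (x in list(ss$n, ss$m, ss$h)) {
    expect_true(all(x >= 0 & x <= 1))
  }
  expect_true(all(diff(ss$m) > 0))   # m_inf increasing
  expect_true(all(diff(ss$h) < 0))   # h_inf decreasing
})

test_that("exponential-Euler gating is exact at fixed points and matches the kinetics as dt -> 0", {
  V <- -45
  ss <- steady_state_gating(V)
  stepped <- advance_gating(ss, V, dt = 0.5)
  expect_equal(stepped$n, ss$n, tolerance = 1e-12)
  expect_equal(stepped$m, ss$m, tolerance = 1e-12)
  expect_equal(stepped$h, ss$h, tolerance = 1e-12)

  # derivative oracle: (x' - x)/dt -> alpha (1 - x) - beta x
  st <- gating_state(0.3, 0.2, 0.7)
  dt <- 1e-7
  nxt <- advance_gating(st, V, dt)
  r <- rate_constants(V)
  expect_equal((nxt$n - st$n) / dt, r$an * (1 - st$n) - r$bn * st$n,
               tolerance = 1e-5)
  expect_equal((nxt$m - st$m) / dt, r$am * (1 - st$m) - r$bm * st$m,
               tolerance = 1e-5)
  expect_equal((nxt$h - st$h) / dt, r$ah * (1 - st$h) - r$bh * st$h,
               tolerance = 1e-5)
  expect_error(advance_gating(st, V, dt = 0), "positive")
})

test_that("iterated gating updates converge to the steady state from any start", {
  set.seed(42)
  for (k in 1:5) {
    V <- runif(1, -90, 40)
    st <- gating_state(runif(1), runif(1), runif(1))
    for (i in 1:10000) {
      st <- advance_gating(st, V, 0.05)
      ss <- steady_state_gating(V)
      if (max(abs(c(st$n - ss$n, st$m - ss$m, st$h - ss$h))) < 1e-9) break
    }
    ss <- steady_state_gating(V)
    expect_lt(max(abs(c(st$n - ss$n, st$m - ss$m, st$h - ss$h))), 1e-9)
  }
})

test_that("gating stays in [0,1] along randomized voltage trajectories", {
  set.seed(7)
  for (rep in 1:10) {
    st <- gating_state(runif(1), runif(1), runif(1))
    V <- runif(200, -120, 80)   # admissible but wild voltage sequence
    for (v in V) {
      st <- advance_gating(st, v, dt = runif(1, 1e-4, 0.5))
      expect_true(all(c(st$n, st$m, st$h) >= 0 & c(st$n, st$m, st$h) <= 1))
    }
  }
})

test_that("conductances follow g_K = gbar n^4 and g_Na = gbar m^3 h", {
  p <- membrane_params()
  expect_equal(conductances(gating_state(1, 0, 0), p)$g_K, 36)
  expect_equal(conductances(gating_state(0.5, 0, 0), p)$g_K, 36 / 16)
  expect_equal(conductances(gating_state(0, 0, 1), p)$g_Na, 0)
  expect_equal(conductances(gating_state(0, 0.5, 0.8), p)$g_Na,
               120 * 0.125 * 0.8)
})

test_that("each ionic term vanishes at its reversal potential", {
  p <- membrane_params()
  # only K conducting, V = E_K
  expect_equal(ionic_current(p$E_K, gating_state(1, 0, 0),
                             membrane_params(g_L = 1e-12)),
               0, tolerance = 1e-9)
  # leak only at V = E_L
  expect_equal(ionic_current(p$E_L, gating_state(0, 0, 0), p), 0)
  # term-by-term brute-force evaluation at the resting point
  V <- -60
  ss <- steady_state_gating(V)
  ref <- p$gbar_K * ss$n^4 * (V - p$E_K) +
    p$gbar_Na * ss$m^3 * ss$h * (V - p$E_Na) + p$g_L * (V - p$E_L)
  expect_equal(ionic_current(V, ss, p), ref)
})

test_that("the zero-current resting potential sits near the nominal -60 mV", {
  vr <- resting_potential()
  expect_lt(abs(vr - (-60)), 2)
  ss <- steady_state_gating(vr)
  expect_equal(ionic_current(vr, ss, membrane_params()), 0,
               tolerance = 1e-8)
})
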