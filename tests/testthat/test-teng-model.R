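EPS0 <- 8.8541878128e-12

test_that("closed-form V_oc is linear in the gap with slope sigma/eps0", {
  cfg <- teng_config()
  expect_equal(closed_form_voc(0, cfg), 0)
  g <- 1e-4
  expect_equal(closed_form_voc(g, cfg), cfg$sigma * g / EPS0)
  expect_equal(closed_form_voc(2 * g, cfg), 2 * closed_form_voc(g, cfg))
  expect_error(closed_form_voc(-1e-6, cfg), "non-negative")
})

test_that("closed-form capacitance is the series stack, decreasing to zero", {
  cfg <- teng_config()
  c0_expected <- EPS0 * 15e-5 / (7e-7 / 2.6 + 7e-7 / 3.4)
  expect_equal(closed_form_capacitance(0, cfg), c0_expected)
  gaps <- seq(0, 5e-4, length.out = 30)
  cc <- closed_form_capacitance(gaps, cfg)
  expect_true(all(diff(cc) < 0))
  expect_lt(closed_form_capacitance(1, cfg) / c0_expected, 1e-5)
})

test_that("configuration invariants are enforced at construction", {
  expect_error(teng_config(sigma = -1))
  expect_error(teng_config(plate_area = 0))
  expect_error(teng_config(eps_silk = 0.5))
  expect_error(micropattern_spec("cube", feature_width = 2e-6, pitch = 1e-6),
               "pitch")
})

test_that("flat-geometry field solution reproduces the closed forms", {
  cfg <- teng_config()
  for (gap in c(5e-5, 2e-4)) {
    sol <- solve_poisson_2d(cfg, gap, cells_per_layer = 4,
                            estimate_convergence = FALSE)
    expect_lt(abs(sol$voc - closed_form_voc(gap, cfg)) /
                closed_form_voc(gap, cfg), 1e-4)
  }
})

test_that("no tribo charge means an identically zero potential", {
  cfg <- teng_config(sigma = 0)
  sol <- solve_poisson_2d(cfg, 1e-4, 4, estimate_convergence = FALSE)
  expect_equal(max(abs(sol$grid_potential)), 0)
})

test_that("micropatterned surfaces raise V_oc above flat at a matched gap", {
  gap <- 5e-5
  voc <- sapply(c("flat", "cube", "pyramid", "sphere"), function(sh) {
    cfg <- teng_config(pattern = micropattern_spec(sh))
    solve_poisson_2d(cfg, gap, 4, estimate_convergence = FALSE)$voc
  })
  expect_true(all(voc[-1] >= voc["flat"]))
  expect_equal(names(which.max(voc)), "cube")
})

test_that("extraction obeys the charge-voltage relation and its degenerate corner", {
  cfg <- teng_config()
  sol <- solve_poisson_2d(cfg, 1e-4, 4, estimate_convergence = FALSE)
  ex <- extract_voc_capacitance(sol, cfg)
  expect_false(ex$flagged)
  expect_equal(ex$cap * ex$voc, cfg$sigma * cfg$plate_area,
               tolerance = 1e-12)
  # doubling sigma doubles V_oc and leaves C unchanged
  cfg2 <- teng_config(sigma = 2 * cfg$sigma)
  ex2 <- extract_voc_capacitance(
    solve_poisson_2d(cfg2, 1e-4, 4, estimate_convergence = FALSE), cfg2)
  expect_equal(ex2$voc / ex$voc, 2, tolerance = 1e-9)
  expect_equal(ex2$cap, ex$cap, tolerance = 1e-9)
  # flat device at contact: V_oc = 0, series-limit capacitance, flagged
  sol0 <- solve_poisson_2d(cfg, 0, 4, estimate_convergence = FALSE)
  ex0 <- extract_voc_capacitance(sol0, cfg)
  expect_true(ex0$flagged)
  expect_equal(ex0$cap, closed_form_capacitance(0, cfg))
})

test_that("built curves satisfy the tabulation invariants", {
  cfg <- teng_config()
  gaps <- seq(1e-6, 1.25e-4, length.out = 10)
  crv <- build_curve(cfg, gaps, "closed_form")
  expect_s3_class(crv, "teng_curve")
  expect_true(all(diff(crv$voc) > 0))
  expect_true(all(diff(crv$cap_total) < 0))
  expect_equal(crv$cap_per_area, crv$cap_total / (cfg$plate_area * 1e4))

  crv_p <- build_curve(cfg, gaps, "poisson_2d", cells_per_layer = 4)
  expect_lt(max(abs(crv_p$voc - crv$voc) / crv$voc), 1e-4)

  cube <- build_curve(teng_config(pattern = micropattern_spec("cube")),
                      gaps, "poisson_2d", cells_per_layer = 4)
  expect_true(all(cube$cap_total < crv_p$cap_total))
  expect_error(teng_curve(c(1e-5, 5e-6), c(0, 1), c(1, 1) * 1e-9, 1),
               "increasing")
})

test_that("curve queries interpolate values and difference-quotient derivatives", {
  cfg <- teng_config()
  gaps <- seq(1e-6, 1.25e-4, length.out = 11)
  crv <- build_curve(cfg, gaps, "closed_form")
  q <- query_curve(crv, gaps[4])
  expect_equal(q$voc, crv$voc[4])
  expect_equal(q$cap_per_area, crv$cap_per_area[4])
  # linear V_oc: every interior node derivative equals sigma/eps0
  expect_equal(q$dvoc_dx, cfg$sigma / EPS0, tolerance = 1e-9)
  # constant-capacitance fixture: zero derivative everywhere
  cc <- fixture_curve("constant", cap0 = 1e-9)
  expect_equal(query_curve(cc, 3e-5)$dcap_dx, 0)
  expect_equal(query_curve(cc, 3e-5)$dvoc_dx, 0)
  # fixture with prescribed slope recovers it exactly
  lin <- fixture_curve("linear_voc_const_C", voc_slope = 2e6)
  expect_equal(query_curve(lin, 5e-5)$dvoc_dx, 2e6)
  expect_error(query_curve(crv, 2e-4), "range")
})
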