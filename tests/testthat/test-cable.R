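test_that("per-length resistances follow the cylindrical cross-section convention", {
  cfg <- axon_config()
  r <- per_length_resistances(cfg)
  expect_equal(r$r_i, 35 / (pi * 1e-6))
  expect_equal(r$r_e, 20 / (pi * 1e-6))
  r2 <- per_length_resistances(axon_config(radius = 0.002))
  expect_equal(r2$r_i, r$r_i / 4)
  expect_equal(per_length_resistances(axon_config(R_e = 0))$r_e, 0)
})

test_that("discrete cable Laplacian annihilates uniform profiles and matches polynomials", {
  cfg <- axon_config(n_compartments = 20, length = 0.2)
  expect_equal(laplacian_term(rep(-60, 20), cfg$dz, cfg), rep(0, 20))

  # quadratic profile: interior second difference is exactly 2
  z <- (seq_len(20) - 0.5) * cfg$dz
  V <- z^2
  lap <- laplacian_term(V, cfg$dz, cfg)
  r <- per_length_resistances(cfg)
  k <- 1e3 / ((2 * pi * cfg$radius) * (r$r_i + r$r_e))
  expect_equal(lap[2:19], rep(2 * k, 18), tolerance = 1e-9)

  # single bump diffuses: negative at the bump, positive at neighbours
  Vb <- rep(0, 20); Vb[10] <- 1
  lapb <- laplacian_term(Vb, cfg$dz, cfg)
  expect_lt(lapb[10], 0)
  expect_gt(lapb[9], 0)
  expect_gt(lapb[11], 0)
})

test_that("the resting state is an equilibrium of the stepper", {
  cfg <- short_axon()
  p <- membrane_params()
  st <- resting_state(cfg, p)
  st2 <- step_plain(st, NULL, p, cfg)
  expect_lt(max(abs(st2$V - st$V)), 1e-6)
})

test_that("stimulus acts only inside its window (causality)", {
  cfg <- short_axon(t_end = 2)
  p <- membrane_params()
  late <- stimulus_protocol(amplitude = 50, t_on = 1, t_off = 2)
  a <- run_plain(cfg, late, p)
  b <- run_plain(cfg, NULL, p)
  pre <- a$times < 1
  expect_identical(a$V_trace[pre, ], b$V_trace[pre, ])
  expect_gt(max(abs(a$V_trace[!pre, ] - b$V_trace[!pre, ])), 1e-3)
})

test_that("a zero-stimulus run stays within 0.5 mV of rest for 100 ms", {
  cfg <- axon_config(t_end = 100)
  res <- run_plain(cfg, NULL)
  vr <- res$V_trace[1, 1]
  expect_lt(max(abs(res$V_trace - vr)), 0.5)
  tr <- detect_spikes(res$times, res$V_trace[, 50])
  expect_length(tr$spike_times, 0)
})

test_that("sustained suprathreshold current drives repetitive firing", {
  cfg <- axon_config(t_end = 60)
  res <- run_plain(cfg, stimulus_protocol(amplitude = 10, t_off = 60))
  tr <- detect_spikes(res$times, res$V_trace[, 50])
  expect_gte(length(tr$spike_times), 2)
})

test_that("uniform states with uniform stimulus remain spatially uniform", {
  cfg <- short_axon(t_end = 5)
  res <- run_plain(cfg, stimulus_protocol(amplitude = 10, t_off = 5))
  spread <- apply(res$V_trace, 1, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("end-stimulated spikes propagate with non-decreasing latency", {
  cfg <- axon_config(n_compartments = 40, length = 0.4, t_end = 12)
  stim <- stimulus_protocol(amplitude = 80, t_on = 0, t_off = 12,
                            target_compartments = 1:2)
  res <- run_plain(cfg, stim)
  first_spike <- apply(res$V_trace, 2, function(v) {
    idx <- which(v > 0)
    if (length(idx)) res$times[idx[1]] else NA_real_
  })
  reached <- which(!is.na(first_spike))
  expect_gt(length(reached), 20)   # spike travels down most of the axon
  expect_true(all(diff(first_spike[reached]) >= 0))
})

test_that("halving dt changes the first spike time by less than 1 percent", {
  t1 <- sapply(c(0.001, 0.0005), function(dt) {
    cfg <- axon_config(n_compartments = 30, length = 0.3, t_end = 10,
                       dt = dt)
    res <- run_plain(cfg, stimulus_protocol(amplitude = 10, t_off = 10))
    detect_spikes(res$times, res$V_trace[, 15])$spike_times[1]
  })
  expect_lt(abs(t1[2] - t1[1]) / t1[2], 0.01)
})

test_that("the stability guard rejects too-large time steps", {
  expect_error(run_plain(axon_config(dt = 0.01, t_end = 1)), "stability")
})

test_that("compiled and reference engines integrate identically", {
  cfg <- short_axon(t_end = 2)
  stim <- stimulus_protocol(amplitude = 10, t_off = 1.5)
  a <- run_plain(cfg, stim, engine = "cpp")
  b <- run_plain(cfg, stim, engine = "r")
  expect_lt(max(abs(a$V_trace - b$V_trace)), 1e-10)
})
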