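#' Axon discretization and integration settings
#'
#' Geometry and numerics of the compartmental cable model. Units follow
#' the electrophysiology convention: cm, ms, mV, uA/cm^2.
#'
#' @param radius axon radius a, cm.
#' @param length axon length, cm.
#' @param n_compartments number of compartments (>= 3).
#' @param R_i intracellular resistivity, Ohm cm.
#' @param R_e extracellular resistivity, Ohm cm (0 = ideal bath).
#' @param dt time step, ms; checked against the explicit stability bound
#'   at run start.
#' @param t_end simulation horizon, ms.
#' @param record_dt approximate output sampling interval, ms; recording is
#'   decimated to `max(1, floor(record_dt/dt))` steps.
#' @return an object of class `axon_config`.
#' @export
axon_config <- function(radius = 0.001, length = 1, n_compartments = 100,
                        R_i = 35, R_e = 20, dt = 0.001, t_end = 200,
                        record_dt = 0.025) {
  stopifnot(radius > 0, length > 0, n_compartments >= 3, R_i > 0, R_e >= 0,
            dt > 0, t_end > 0, record_dt > 0)
  structure(list(radius = radius, length = length,
                 n_compartments = as.integer(n_compartments),
                 R_i = R_i, R_e = R_e, dt = dt, t_end = t_end,
                 record_dt = record_dt,
                 dz = length / n_compartments),
            class = "axon_config")
}

#' Stimulation protocol
#'
#' Rectangular transmembrane current pulse: `amplitude` uA/cm^2 applied to
#' `target_compartments` for `t_on <= t < t_off`. The firing protocol of
#' the sweeps uses the default: 10 uA/cm^2 over 0-100 ms at every
#' compartment, which drives sustained repetitive firing.
#'
#' @param amplitude current density, uA/cm^2 (0 = no stimulus).
#' @param t_on,t_off pulse window, ms, `t_on < t_off`.
#' @param target_compartments integer indices, or `NULL` for all.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 10, t_on = 0, t_off = 100,
                              target_compartments = NULL) {
  stopifnot(t_on < t_off)
  structure(list(amplitude = amplitude, t_on = t_on, t_off = t_off,
                 target_compartments = target_compartments),
            class = "stimulus_protocol")
}

#' Axial resistances per unit length
#'
#' `r_i = R_i / (pi a^2)` and, with the same cylindrical cross-section
#' convention, `r_e = R_e / (pi a^2)`; Ohm/cm.
#'
#' @param cfg an [axon_config()].
#' @return list with `r_i` and `r_e`, Ohm/cm.
#' @export
per_length_resistances <- function(cfg) {
  stopifnot(inherits(cfg, "axon_config"))
  list(r_i = cfg$R_i / (pi * cfg$radius^2),
       r_e = cfg$R_e / (pi * cfg$radius^2))
}

# prefactor turning d2V/dz2 (mV/cm^2) into membrane current (uA/cm^2):
# 1/((2 pi a)(r_i + r_e)) gives mA/cm^2 for V in mV, hence the factor 1e3
cable_coupling_factor <- function(cfg) {
  r <- per_length_resistances(cfg)
  1e3 / ((2 * pi * cfg$radius) * (r$r_i + r$r_e))
}

#' Discrete cable Laplacian as a membrane current density
#'
#' Second central difference of the voltage profile with sealed (zero axial
#' flux) ends, scaled by \eqn{1/((2\pi a)(r_i+r_e)\,\Delta z^2)} and
#' expressed per membrane area in uA/cm^2.
#'
#' @param V voltage profile, mV, one entry per compartment (>= 3).
#' @param dz compartment length, cm.
#' @param cfg an [axon_config()] (for radius and resistivities).
#' @return current density, uA/cm^2, same length as `V`.
#' @export
laplacian_term <- function(V, dz, cfg) {
  n <- length(V)
  if (n < 3) stop("need at least 3 compartments")
  d2 <- numeric(n)
  d2[1] <- V[2] - V[1]
  d2[n] <- V[n - 1] - V[n]
  i <- 2:(n - 1)
  d2[i] <- V[i - 1] - 2 * V[i] + V[i + 1]
  cable_coupling_factor(cfg) * d2 / dz^2
}

# explicit stability bound on dt for the voltage diffusion, ms
stability_bound_dt <- function(cfg, p) {
  D <- cable_coupling_factor(cfg) / p$C_m  # cm^2/ms
  cfg$dz^2 / (2 * D)
}

new_axon_state <- function(V, gating, t = 0) {
  structure(list(V = V, gating = gating, t = t), class = "axon_state")
}

#' Initial resting state of the axon
#'
#' Uniform voltage at the zero-current resting potential with gating at
#' its steady state.
#'
#' @param cfg an [axon_config()].
#' @param p a [membrane_params()].
#' @return an `axon_state`: list with `V` (mV per compartment), `gating`
#'   (a [gating_state()] of vectors), `t` (ms).
#' @export
resting_state <- function(cfg, p) {
  vr <- resting_potential(p)
  n <- cfg$n_compartments
  g <- steady_state_gating(vr, p$V_rest)
  new_axon_state(rep(vr, n),
                 gating_state(rep(g$n, n), rep(g$m, n), rep(g$h, n)))
}

stimulus_vector <- function(stim, t, n) {
  Is <- numeric(n)
  if (!is.null(stim) && stim$amplitude != 0 &&
      t >= stim$t_on && t < stim$t_off) {
    idx <- stim$target_compartments
    if (is.null(idx)) idx <- seq_len(n)
    Is[idx] <- stim$amplitude
  }
  Is
}

#' One explicit step of the plain cable equation
#'
#' Operator-split forward step: the voltage is advanced by forward Euler,
#' \deqn{V \leftarrow V + \frac{\Delta t}{C_m}\,(L(V) + I_S - I_{ion}),}
#' then the gating variables are advanced by exponential Euler at the
#' pre-step voltage. Sealed ends.
#'
#' @param state an `axon_state` (see [resting_state()]).
#' @param stim a [stimulus_protocol()] or `NULL`.
#' @param p a [membrane_params()].
#' @param cfg an [axon_config()].
#' @return the updated `axon_state`.
#' @export
step_plain <- function(state, stim, p, cfg) {
  V <- state$V
  n <- length(V)
  lap <- laplacian_term(V, cfg$dz, cfg)
  Iion <- ionic_current(V, state$gating, p)
  Is <- stimulus_vector(stim, state$t, n)
  Vn <- V + (cfg$dt / p$C_m) * (lap + Is - Iion)
  if (any(!is.finite(Vn)))
    stop(sprintf("instability: non-finite voltage at t=%g ms (dt=%g, dz=%g)",
                 state$t, cfg$dt, cfg$dz))
  g <- advance_gating(state$gating, V, cfg$dt, p$V_rest)
  new_axon_state(Vn, g, state$t + cfg$dt)
}

make_sim_result <- function(times, V_trace, x = NULL, cfg, p, extra = list()) {
  structure(c(list(times = times, V_trace = V_trace, x = x,
                   config = cfg, membrane = p), extra),
            class = "sim_result")
}

#' @exportS3Method base::print
print.sim_result <- function(x, ...) {
  cat(sprintf("cable simulation: %d samples x %d compartments, t in [0, %g] ms\n",
              nrow(x$V_trace), ncol(x$V_trace), max(x$times)))
  cat(sprintf("  V range: [%.2f, %.2f] mV\n", min(x$V_trace), max(x$V_trace)))
  invisible(x)
}

#' Run the plain (device-free) cable simulation
#'
#' Integrates the cable equation from the resting state with an optional
#' injected-current protocol. Deterministic given the configuration. The
#' compiled engine and the pure-R reference stepper implement the same
#' update; the R engine is retained for cross-checks and is practical only
#' for short horizons.
#'
#' @param cfg an [axon_config()].
#' @param stim a [stimulus_protocol()] or `NULL` for no stimulus.
#' @param p a [membrane_params()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return a `sim_result`: `times` (ms), `V_trace` (samples x
#'   compartments, mV), plus the configuration snapshot.
#' @examples
#' cfg <- axon_config(n_compartments = 20, length = 0.2, t_end = 5)
#' res <- run_plain(cfg, stimulus_protocol(amplitude = 0), membrane_params())
#' range(res$V_trace)  # stays at rest
#' @export
run_plain <- function(cfg, stim = NULL, p = membrane_params(),
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_stability(cfg, p)
  state <- resting_state(cfg, p)
  nsteps <- round(cfg$t_end / cfg$dt)
  every <- max(1L, floor(cfg$record_dt / cfg$dt))
  if (engine == "cpp") {
    out <- run_engine_cpp(state, cfg, p, stim = stim, curve = NULL,
                          profile = NULL, coupled_idx = integer(0),
                          nsteps = nsteps, every = every)
  } else {
    out <- run_engine_r(state, cfg, p, stim = stim, curve = NULL,
                        profile = NULL, coupled_idx = integer(0),
                        nsteps = nsteps, every = every)
  }
  make_sim_result(out$times, out$V, x = NULL, cfg = cfg, p = p,
                  extra = list(stimulus = stim, engine = engine))
}

check_stability <- function(cfg, p) {
  bound <- stability_bound_dt(cfg, p)
  if (cfg$dt > bound)
    stop(sprintf(
      "dt = %g ms exceeds the explicit stability bound %.4g ms (dz = %g cm)",
      cfg$dt, bound, cfg$dz))
  invisible(bound)
}

# shared R-engine loop for plain and coupled runs (reference path)
run_engine_r <- function(state, cfg, p, stim, curve, profile, coupled_idx,
                         nsteps, every) {
  n <- cfg$n_compartments
  nrec <- floor(nsteps / every) + 1L
  Vrec <- matrix(NA_real_, nrec, n)
  xrec <- numeric(nrec)
  times <- numeric(nrec)
  k <- 1L
  Vrec[1L, ] <- state$V
  xrec[1L] <- if (!is.null(profile)) gap_trajectory(0, profile)$x else NA_real_
  coupled <- !is.null(curve)
  for (s in seq_len(nsteps)) {
    state <- if (coupled)
      step_coupled(state, profile, curve, p, cfg, coupled_idx, stim)
    else
      step_plain(state, stim, p, cfg)
    state$t <- s * cfg$dt   # exact step time (avoid accumulation drift)
    if (s %% every == 0L) {
      k <- k + 1L
      Vrec[k, ] <- state$V
      times[k] <- state$t
      xrec[k] <- if (!is.null(profile)) gap_trajectory(state$t, profile)$x
                 else NA_real_
    }
  }
  list(times = times, V = Vrec[seq_len(k), , drop = FALSE],
       x = xrec[seq_len(k)])
}
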