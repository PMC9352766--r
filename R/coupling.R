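#' Contact-release motion profile of the moving electrode
#'
#' Triangular oscillation of the electrode gap: starting separated at
#' `x_max`, the plate approaches the counter-surface at constant speed `v`
#' from `t_start` on, reverses at `x_min` (near contact), returns to
#' `x_max`, and repeats. `|dx/dt| = v` everywhere except the turning
#' samples, where the incoming segment's one-sided velocity is used. One
#' full period lasts `2 (x_max - x_min) / v`. The default excursion
#' (1 um to 125 um) lets the device complete one to several contact cycles
#' within a 200 ms run across the working speed range 0.075-1 cm/s.
#'
#' @param v contact-release speed, cm/s (>= 0; 0 = static device).
#' @param x_min closest approach, cm (> 0 avoids the contact corner where
#'   V_oc and C are degenerate).
#' @param x_max resting separation, cm (> x_min).
#' @param t_start time the motion begins, ms.
#' @param waveform only `"triangular"`.
#' @return an object of class `motion_profile`.
#' @export
motion_profile <- function(v = 0.5, x_min = 1e-4, x_max = 0.0125,
                           t_start = 0, waveform = "triangular") {
  stopifnot(v >= 0, x_min >= 0, x_max > x_min, t_start >= 0,
            waveform == "triangular")
  structure(list(v = v, x_min = x_min, x_max = x_max, t_start = t_start,
                 waveform = waveform),
            class = "motion_profile")
}

#' Electrode gap and velocity at time t
#'
#' @param t time, ms (>= 0, vectorized).
#' @param profile a [motion_profile()].
#' @return list with `x` (cm) and `dxdt` (cm/s), each the length of `t`.
#' @export
gap_trajectory <- function(t, profile) {
  stopifnot(inherits(profile, "motion_profile"))
  if (any(t < 0)) stop("t must be non-negative")
  v <- profile$v
  n <- length(t)
  if (v == 0) return(list(x = rep(profile$x_max, n), dxdt = rep(0, n)))
  D <- profile$x_max - profile$x_min
  tau <- pmax(t - profile$t_start, 0) * (v / 1000)  # distance travelled, cm
  s <- tau %% (2 * D)
  x <- ifelse(s <= D, profile$x_max - s, profile$x_min + (s - D))
  dxdt <- ifelse(s < D | (s == 0 & tau > 0), -v, v)
  dxdt[tau == 0] <- ifelse(t[tau == 0] >= profile$t_start, -v, 0)
  # turning sample at closest approach keeps the incoming (approach) velocity
  dxdt[s == D] <- -v
  # wrapped turning sample at x_max keeps the incoming (release) velocity
  dxdt[s == 0 & tau > 0] <- v
  list(x = x, dxdt = dxdt)
}

#' Motional coupling terms of the moving device
#'
#' The external current density that the moving charged capacitor injects
#' through the membrane:
#' \deqn{I_{drive} = -\frac{dC}{dx}\frac{dx}{dt}\,(V_{oc}(x) - V_m)
#'   - C(x)\frac{dV_{oc}}{dx}\frac{dx}{dt}}
#' with the device capacitance in per-area units (the tabulated total
#' divided by the plate area) so every term carries uA/cm^2. The remaining
#' \eqn{C(x)\,\partial V_m/\partial t} term of the extended cable equation
#' is absorbed into the update denominator \eqn{C_m - C(x)} by
#' [step_coupled()]. Both terms carry dx/dt, so a static device injects no
#' current.
#'
#' @param x electrode gap, cm, within the curve's tabulated range.
#' @param dxdt gap velocity, cm/s.
#' @param V_m membrane potential, mV (scalar or per-compartment vector).
#' @param curve a [teng_curve()].
#' @param C_m membrane capacitance, uF/cm^2 (validity guard: the device's
#'   per-area capacitance must stay below it).
#' @return list with `I_drive` (uA/cm^2, length of `V_m`), `C_x` (device
#'   capacitance per area, uF/cm^2), `x` (cm), `dxdt` (cm/s).
#' @export
coupling_terms <- function(x, dxdt, V_m, curve, C_m = 1.0) {
  q <- query_curve(curve, x * 1e-2)        # curve tabulated in metres
  voc_mV <- q$voc * 1e3
  C_uF <- q$cap_per_area * 1e6             # F/cm^2 -> uF/cm^2
  dvoc <- q$dvoc_dx * 1e3 * 1e-2           # V/m -> mV/cm
  dcap <- q$dcap_dx * 1e6 * 1e-2           # F/cm^2/m -> uF/cm^2/cm
  if (C_uF >= C_m)
    stop(sprintf(
      "device capacitance %g uF/cm^2 at gap %g cm reaches C_m = %g; the
quasi-static update is invalid there", C_uF, x, C_m))
  v_ms <- dxdt / 1000                       # cm/s -> cm/ms
  I_drive <- -dcap * v_ms * (voc_mV - V_m) - C_uF * dvoc * v_ms
  list(I_drive = I_drive, C_x = C_uF, x = x, dxdt = dxdt)
}

#' One explicit step of the TENG-coupled cable equation
#'
#' The discretized extended cable update: on compartments facing the
#' device,
#' \deqn{V \leftarrow V + \frac{\Delta t}{C_m - C(x)}\,
#'   (L(V) + I_S + I_{drive} - I_{ion}),}
#' and the plain update (denominator \eqn{C_m}) elsewhere. The ionic
#' current enters with the stabilizing sign of the plain cable equation.
#' Gating advances exactly as in [step_plain()].
#'
#' @param state an `axon_state`.
#' @param profile a [motion_profile()].
#' @param curve a [teng_curve()] covering `[x_min, x_max]`.
#' @param p a [membrane_params()].
#' @param cfg an [axon_config()].
#' @param coupled_compartments integer indices facing the device, or
#'   `NULL` for all (the default device has no axial extent in the model).
#' @param stim optional [stimulus_protocol()].
#' @return the updated `axon_state`.
#' @export
step_coupled <- function(state, profile, curve, p, cfg,
                         coupled_compartments = NULL, stim = NULL) {
  V <- state$V
  n <- length(V)
  idx <- coupled_compartments
  if (is.null(idx)) idx <- seq_len(n)
  traj <- gap_trajectory(state$t, profile)
  ct <- coupling_terms(traj$x, traj$dxdt, V[idx], curve, p$C_m)
  lap <- laplacian_term(V, cfg$dz, cfg)
  Iion <- ionic_current(V, state$gating, p)
  Is <- stimulus_vector(stim, state$t, n)
  denom <- rep(p$C_m, n)
  denom[idx] <- p$C_m - ct$C_x
  drive <- numeric(n)
  drive[idx] <- ct$I_drive
  Vn <- V + (cfg$dt / denom) * (lap + Is + drive - Iion)
  if (any(!is.finite(Vn)))
    stop(sprintf("instability: non-finite voltage at t=%g ms (dt=%g, dz=%g)",
                 state$t, cfg$dt, cfg$dz))
  g <- advance_gating(state$gating, V, cfg$dt, p$V_rest)
  new_axon_state(Vn, g, state$t + cfg$dt)
}

#' Run the TENG-coupled cable simulation
#'
#' Full simulation of the axon under the moving device, from the resting
#' state, with an optional injected-current protocol (the "firing neuron"
#' of the sweeps). Records the decimated voltage trace and the gap
#' trajectory alongside. Deterministic given the configuration.
#'
#' @param cfg an [axon_config()].
#' @param profile a [motion_profile()].
#' @param curve a [teng_curve()] covering the motion range.
#' @param stim a [stimulus_protocol()] or `NULL` (resting protocol).
#' @param p a [membrane_params()].
#' @param coupled_compartments indices facing the device, `NULL` for all.
#' @param engine `"cpp"` (default) or `"r"` (reference, short horizons).
#' @return a `sim_result` with `times`, `V_trace`, and `x` (gap at each
#'   sample, cm).
#' @examples
#' cfg <- axon_config(n_compartments = 20, length = 0.2, t_end = 2)
#' crv <- fixture_curve("constant", voc0 = 0, cap0 = 0)
#' res <- run_coupled(cfg, motion_profile(v = 0.5), crv)
#' @export
run_coupled <- function(cfg, profile, curve, stim = NULL,
                        p = membrane_params(), coupled_compartments = NULL,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_stability(cfg, p)
  rng_m <- range(curve$gaps)
  if (profile$x_min * 1e-2 < rng_m[1] - 1e-15 ||
      profile$x_max * 1e-2 > rng_m[2] + 1e-15)
    stop("curve does not cover the motion range [x_min, x_max]")
  state <- resting_state(cfg, p)
  nsteps <- round(cfg$t_end / cfg$dt)
  every <- max(1L, floor(cfg$record_dt / cfg$dt))
  idx <- coupled_compartments
  if (is.null(idx)) idx <- seq_len(cfg$n_compartments)
  if (engine == "cpp") {
    out <- run_engine_cpp(state, cfg, p, stim = stim, curve = curve,
                          profile = profile, coupled_idx = idx,
                          nsteps = nsteps, every = every)
  } else {
    out <- run_engine_r(state, cfg, p, stim = stim, curve = curve,
                        profile = profile, coupled_idx = idx,
                        nsteps = nsteps, every = every)
  }
  make_sim_result(out$times, out$V, x = out$x, cfg = cfg, p = p,
                  extra = list(stimulus = stim, profile = profile,
                               curve_provenance = curve$provenance,
                               pattern = curve$pattern_shape,
                               engine = engine))
}

# bridge to the compiled stepping loop; precomputes the curve node arrays
# in neuron units (cm, mV, uF/cm^2)
run_engine_cpp <- function(state, cfg, p, stim, curve, profile, coupled_idx,
                           nsteps, every) {
  n <- cfg$n_compartments
  coupled <- !is.null(curve)
  if (coupled) {
    g_cm <- curve$gaps * 1e2
    voc_mV <- curve$voc * 1e3
    cap_uF <- curve$cap_per_area * 1e6
    dvoc <- curve_node_derivatives(g_cm, voc_mV)   # mV/cm
    dcap <- curve_node_derivatives(g_cm, cap_uF)   # uF/cm^2/cm
    if (any(cap_uF >= p$C_m))
      stop("device capacitance reaches C_m inside the tabulated range")
    prof <- c(profile$v, profile$x_min, profile$x_max, profile$t_start)
  } else {
    g_cm <- voc_mV <- cap_uF <- dvoc <- dcap <- numeric(0)
    prof <- c(0, 0, 1, 0)
  }
  stim_idx <- integer(0); stim_amp <- 0; stim_on <- 0; stim_off <- -1
  if (!is.null(stim) && stim$amplitude != 0) {
    stim_idx <- stim$target_compartments
    if (is.null(stim_idx)) stim_idx <- seq_len(n)
    stim_amp <- stim$amplitude; stim_on <- stim$t_on; stim_off <- stim$t_off
  }
  out <- run_axon_cpp(
    V0 = state$V,
    n0 = state$gating$n, m0 = state$gating$m, h0 = state$gating$h,
    dt = cfg$dt, nsteps = as.integer(nsteps), every = as.integer(every),
    lap_k = cable_coupling_factor(cfg), dz = cfg$dz,
    E_Na = p$E_Na, E_K = p$E_K, E_L = p$E_L,
    gbar_Na = p$gbar_Na, gbar_K = p$gbar_K, g_L = p$g_L,
    C_m = p$C_m, V_rest = p$V_rest,
    stim_idx = as.integer(stim_idx - 1L), stim_amp = stim_amp,
    stim_on = stim_on, stim_off = stim_off,
    coupled = coupled,
    coupled_idx = as.integer(if (coupled) coupled_idx - 1L else integer(0)),
    prof = prof,
    cg = g_cm, cvoc = voc_mV, ccap = cap_uF, cdvoc = dvoc, cdcap = dcap)
  list(times = out$times, V = out$V,
       x = if (coupled) out$x else NULL)
}
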