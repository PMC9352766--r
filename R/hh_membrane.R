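#' Membrane parameters of the squid-axon model
#'
#' Reversal potentials, maximal conductances and specific capacitance of
#' the classical squid-axon membrane, expressed in absolute membrane
#' potential with a nominal resting potential of -60 mV. Note the true
#' resting state of the model is the zero-current steady state computed by
#' [resting_potential()], which may differ from `V_rest` by a fraction of a
#' millivolt.
#'
#' @param E_Na,E_K,E_L reversal potentials, mV.
#' @param gbar_Na,gbar_K maximal conductances, mS/cm^2.
#' @param g_L leak conductance, mS/cm^2.
#' @param C_m membrane capacitance, uF/cm^2.
#' @param V_rest nominal resting potential, mV.
#' @return an object of class `membrane_params`.
#' @export
membrane_params <- function(E_Na = 52.4, E_K = -72.1, E_L = -49.2,
                            gbar_Na = 120, gbar_K = 36, g_L = 0.3,
                            C_m = 1.0, V_rest = -60) {
  stopifnot(gbar_Na > 0, gbar_K > 0, g_L > 0, C_m > 0,
            E_Na > V_rest, V_rest > E_K)
  structure(list(E_Na = E_Na, E_K = E_K, E_L = E_L, gbar_Na = gbar_Na,
                 gbar_K = gbar_K, g_L = g_L, C_m = C_m, V_rest = V_rest),
            class = "membrane_params")
}

#' Gating state (n, m, h)
#'
#' @param n,m,h channel-opening probabilities in `[0, 1]`; each may be a
#'   vector (one entry per compartment).
#' @return an object of class `gating_state`.
#' @export
gating_state <- function(n, m, h) {
  if (any(c(n, m, h) < 0) || any(c(n, m, h) > 1))
    stop("gating variables must lie in [0, 1]")
  structure(list(n = n, m = m, h = h), class = "gating_state")
}

#' Voltage-dependent rate constants of the gating kinetics
#'
#' The classical squid-axon opening/closing rates, written in absolute
#' membrane potential via the depolarization u = V - V_rest (V_rest =
#' -60 mV), in 1/ms:
#' \deqn{\alpha_n = 0.01\,(10-u)/(e^{(10-u)/10}-1),\quad
#'       \beta_n = 0.125\,e^{-u/80}}
#' \deqn{\alpha_m = 0.1\,(25-u)/(e^{(25-u)/10}-1),\quad
#'       \beta_m = 4\,e^{-u/18}}
#' \deqn{\alpha_h = 0.07\,e^{-u/20},\quad
#'       \beta_h = 1/(e^{(30-u)/10}+1)}
#' The removable singularities of \eqn{\alpha_n} (u = 10) and
#' \eqn{\alpha_m} (u = 25) are evaluated by their limits. No temperature
#' scaling is applied.
#'
#' @param V membrane potential, mV (vectorized).
#' @param V_rest resting potential used to shift the classical forms, mV.
#' @return list with vectors `an`, `bn`, `am`, `bm`, `ah`, `bh` in 1/ms.
#' @export
rate_constants <- function(V, V_rest = -60) {
  if (any(!is.finite(V))) stop("V must be finite")
  u <- V - V_rest
  # a * x / (exp(x / b) - 1), with the x -> 0 limit a*b
  vtrap <- function(a, x, b) {
    out <- numeric(length(x))
    small <- abs(x / b) < 1e-6
    out[small] <- a * b * (1 - x[small] / (2 * b))  # series through O(x)
    out[!small] <- a * x[!small] / expm1(x[!small] / b)
    out
  }
  list(an = vtrap(0.01, 10 - u, 10),
       bn = 0.125 * exp(-u / 80),
       am = vtrap(0.1, 25 - u, 10),
       bm = 4 * exp(-u / 18),
       ah = 0.07 * exp(-u / 20),
       bh = 1 / (exp((30 - u) / 10) + 1))
}

#' Steady-state gating at a fixed voltage
#'
#' Each variable relaxes to \eqn{x_\infty = \alpha/(\alpha+\beta)};
#' used as the initial condition of every simulation.
#'
#' @inheritParams rate_constants
#' @return a [gating_state()].
#' @export
steady_state_gating <- function(V, V_rest = -60) {
  r <- rate_constants(V, V_rest)
  gating_state(n = r$an / (r$an + r$bn),
               m = r$am / (r$am + r$bm),
               h = r$ah / (r$ah + r$bh))
}

#' Advance the gating variables by one time step
#'
#' Exponential-Euler update at frozen voltage: with \eqn{\tau =
#' 1/(\alpha+\beta)} and \eqn{x_\infty = \alpha\tau},
#' \deqn{x \leftarrow x_\infty + (x - x_\infty)\,e^{-\Delta t/\tau}.}
#' Exact for constant V and unconditionally confined to `[0, 1]`.
#'
#' @param state a [gating_state()].
#' @param V membrane potential, mV (scalar or per-compartment vector).
#' @param dt time step, ms (> 0).
#' @param V_rest resting potential of the rate forms, mV.
#' @return the updated [gating_state()].
#' @export
advance_gating <- function(state, V, dt, V_rest = -60) {
  stopifnot(inherits(state, "gating_state"))
  if (dt <= 0) stop("dt must be positive")
  r <- rate_constants(V, V_rest)
  step1 <- function(x, a, b) {
    xinf <- a / (a + b)
    xinf + (x - xinf) * exp(-dt * (a + b))
  }
  gating_state(n = step1(state$n, r$an, r$bn),
               m = step1(state$m, r$am, r$bm),
               h = step1(state$h, r$ah, r$bh))
}

#' Channel conductances from the gating state
#'
#' \eqn{g_K = \bar g_K n^4}, \eqn{g_{Na} = \bar g_{Na} m^3 h}.
#'
#' @param state a [gating_state()].
#' @param p a [membrane_params()].
#' @return list with `g_K` and `g_Na`, mS/cm^2.
#' @export
conductances <- function(state, p) {
  stopifnot(inherits(state, "gating_state"), inherits(p, "membrane_params"))
  list(g_K = p$gbar_K * state$n^4,
       g_Na = p$gbar_Na * state$m^3 * state$h)
}

#' Total ionic membrane current
#'
#' \deqn{I_{ion} = g_K (V - E_K) + g_{Na} (V - E_{Na}) + g_L (V - E_L)}
#' in uA/cm^2 (outward positive). Each term vanishes at its reversal
#' potential.
#'
#' @param V membrane potential, mV.
#' @inheritParams conductances
#' @return ionic current density, uA/cm^2.
#' @export
ionic_current <- function(V, state, p) {
  g <- conductances(state, p)
  g$g_K * (V - p$E_K) + g$g_Na * (V - p$E_Na) + p$g_L * (V - p$E_L)
}

#' Zero-current resting potential of the membrane
#'
#' Solves \eqn{I_{ion}(V, x_\infty(V)) = 0} for the uniform steady state
#' with no stimulus. With the default parameters this sits within a
#' fraction of a millivolt of the nominal -60 mV.
#'
#' @param p a [membrane_params()].
#' @return resting potential, mV.
#' @export
resting_potential <- function(p = membrane_params()) {
  f <- function(V) ionic_current(V, steady_state_gating(V, p$V_rest), p)
  uniroot(f, c(p$E_K + 0.5, p$E_L + 5), tol = 1e-12)$root
}
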