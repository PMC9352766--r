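#' Tabulated device curve V_oc(x), C(x)
#'
#' The bridge between the electrostatics and neuron stages: open-circuit
#' voltage and capacitance tabulated over a strictly increasing grid of
#' electrode gaps. Values between nodes are obtained by piecewise-linear
#' interpolation ([query_curve()]); the coupled simulator consumes only the
#' tabulated curve, never the field solver directly.
#'
#' @param gaps electrode gaps, m, strictly increasing, >= 0, length >= 2.
#' @param voc open-circuit voltage per gap, V, non-decreasing.
#' @param cap_total device capacitance per gap, F, non-increasing.
#' @param plate_area electrode area, m^2 (for the per-area capacitance).
#' @param provenance one of `"closed_form"`, `"poisson_2d"`,
#'   `"fixture_table"`.
#' @param pattern_shape label of the surface pattern the curve describes.
#' @return an object of class `teng_curve` with fields `gaps`, `voc`,
#'   `cap_total`, `cap_per_area` (F/cm^2), `plate_area`, `provenance`,
#'   `pattern_shape`.
#' @export
teng_curve <- function(gaps, voc, cap_total, plate_area,
                       provenance = c("closed_form", "poisson_2d",
                                      "fixture_table"),
                       pattern_shape = "flat") {
  provenance <- match.arg(provenance)
  n <- length(gaps)
  if (n < 2 || length(voc) != n || length(cap_total) != n)
    stop("gaps, voc and cap_total must have equal length >= 2")
  if (any(gaps < 0) || any(diff(gaps) <= 0))
    stop("gaps must be non-negative and strictly increasing")
  tol_v <- 1e-9 * max(abs(voc), 1)
  tol_c <- 1e-9 * max(abs(cap_total), .Machine$double.xmin)
  if (any(diff(voc) < -tol_v))
    stop("voc must be non-decreasing in gap")
  if (any(diff(cap_total) > tol_c))
    stop("cap_total must be non-increasing in gap")
  if (plate_area <= 0) stop("plate_area must be positive")
  structure(
    list(gaps = as.numeric(gaps), voc = as.numeric(voc),
         cap_total = as.numeric(cap_total),
         cap_per_area = as.numeric(cap_total) / (plate_area * 1e4),
         plate_area = plate_area, provenance = provenance,
         pattern_shape = pattern_shape),
    class = "teng_curve")
}

#' @exportS3Method base::print
print.teng_curve <- function(x, ...) {
  cat(sprintf("TENG curve (%s, %s): %d gaps in [%g, %g] m\n",
              x$provenance, x$pattern_shape, length(x$gaps),
              min(x$gaps), max(x$gaps)))
  cat(sprintf("  V_oc: %.4g .. %.4g V;  C: %.4g .. %.4g F\n",
              x$voc[1], x$voc[length(x$voc)],
              x$cap_total[1], x$cap_total[length(x$cap_total)]))
  invisible(x)
}

#' Build a device curve over a gap grid
#'
#' Evaluates V_oc and C at every gap with either the closed-form flat-stack
#' model (which ignores the surface pattern) or the 2D Poisson solver
#' ([solve_poisson_2d()] followed by [extract_voc_capacitance()]).
#'
#' @param cfg a [teng_config()].
#' @param gaps strictly increasing gaps, m. Default: 21 nodes from 0 to
#'   125 um, the device's working excursion.
#' @param method `"closed_form"` or `"poisson_2d"`.
#' @param cells_per_layer resolution for the Poisson method.
#' @return a [teng_curve()].
#' @examples
#' crv <- build_curve(teng_config(), method = "closed_form")
#' query_curve(crv, 1e-4)$voc
#' @export
build_curve <- function(cfg, gaps = seq(0, 1.25e-4, length.out = 21),
                        method = c("closed_form", "poisson_2d"),
                        cells_per_layer = 8) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "teng_config"))
  if (any(gaps < 0) || any(diff(gaps) <= 0))
    stop("gaps must be non-negative and strictly increasing")
  if (method == "closed_form") {
    voc <- closed_form_voc(gaps, cfg)
    cap <- closed_form_capacitance(gaps, cfg)
  } else {
    voc <- numeric(length(gaps)); cap <- numeric(length(gaps))
    for (k in seq_along(gaps)) {
      res <- tryCatch({
        sol <- solve_poisson_2d(cfg, gaps[k], cells_per_layer,
                                estimate_convergence = FALSE)
        extract_voc_capacitance(sol, cfg)
      }, error = function(e)
        stop(sprintf("field solve failed at gap %g m: %s", gaps[k],
                     conditionMessage(e)), call. = FALSE))
      voc[k] <- res$voc; cap[k] <- res$cap
    }
  }
  teng_curve(gaps, voc, cap, cfg$plate_area, provenance = method,
             pattern_shape = cfg$pattern$shape)
}

# node-wise derivatives: central differences in the interior, one-sided at
# the ends (the difference quotients of the discretized coupling terms)
curve_node_derivatives <- function(gaps, values) {
  n <- length(gaps)
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / (gaps[2] - gaps[1])
  d[n] <- (values[n] - values[n - 1]) / (gaps[n] - gaps[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (values[i + 1] - values[i - 1]) / (gaps[i + 1] - gaps[i - 1])
  }
  d
}

#' Interpolate a device curve and its gap-derivatives
#'
#' Piecewise-linear interpolation of V_oc and the per-area capacitance at
#' gap `x`; derivatives are formed as central differences on the curve
#' nodes (one-sided at the ends) and linearly interpolated to `x`. No
#' extrapolation: `x` must lie inside the tabulated range.
#'
#' @param curve a [teng_curve()].
#' @param x gap(s), m, within `range(curve$gaps)`.
#' @return list with `voc` (V), `cap_per_area` (F/cm^2), `dvoc_dx` (V/m),
#'   `dcap_dx` (F/cm^2/m), each the length of `x`.
#' @export
query_curve <- function(curve, x) {
  stopifnot(inherits(curve, "teng_curve"))
  rng <- range(curve$gaps)
  if (any(x < rng[1] - 1e-15) || any(x > rng[2] + 1e-15))
    stop(sprintf("gap %g m outside tabulated range [%g, %g]",
                 x[which(x < rng[1] | x > rng[2])[1]], rng[1], rng[2]))
  x <- pmin(pmax(x, rng[1]), rng[2])
  g <- curve$gaps
  dvoc_nodes <- curve_node_derivatives(g, curve$voc)
  dcap_nodes <- curve_node_derivatives(g, curve$cap_per_area)
  list(voc = approx(g, curve$voc, x)$y,
       cap_per_area = approx(g, curve$cap_per_area, x)$y,
       dvoc_dx = approx(g, dvoc_nodes, x)$y,
       dcap_dx = approx(g, dcap_nodes, x)$y)
}

#' Solver-free fixture curves
#'
#' Small analytic device curves used in tests and algebraic cross-checks of
#' the coupled stepper: `"linear_voc_const_C"` has exactly linear V_oc and
#' constant capacitance (the coupling reduces to one hand-computable term),
#' `"constant"` has zero derivatives everywhere (the coupling vanishes at
#' any speed), and `"devicelike"` mimics a realistic device: saturating,
#' monotone-increasing V_oc and slowly decreasing capacitance.
#'
#' @param kind fixture family, see above.
#' @param gaps gap grid, m.
#' @param voc0 `"constant"`: the constant V_oc (V); `"devicelike"`: the
#'   saturation voltage (V).
#' @param cap0 capacitance scale, F (the value at gap 0).
#' @param voc_slope `"linear_voc_const_C"`: dV_oc/dx, V/m.
#' @param plate_area electrode area, m^2.
#' @return a [teng_curve()] with provenance `"fixture_table"`.
#' @export
fixture_curve <- function(kind = c("linear_voc_const_C", "devicelike",
                                   "constant"),
                          gaps = seq(0, 1.25e-4, length.out = 21),
                          voc0 = 0, cap0 = 4e-9, voc_slope = 5e6,
                          plate_area = 15e-5) {
  kind <- match.arg(kind)
  n <- length(gaps)
  curve <- switch(kind,
    linear_voc_const_C = list(voc = voc_slope * gaps,
                              cap = rep(cap0, n)),
    constant = list(voc = rep(voc0, n), cap = rep(cap0, n)),
    devicelike = {
      x0 <- max(gaps) / 3
      list(voc = voc0 * (1 - exp(-gaps / x0)),
           cap = cap0 / (1 + gaps / (max(gaps) / 2)))
    })
  teng_curve(gaps, curve$voc, curve$cap, plate_area,
             provenance = "fixture_table", pattern_shape = kind)
}
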