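#' Closed-form open-circuit voltage of the flat device
#'
#' For the ideal parallel-plate contact-separation device in open circuit,
#' Gauss's law with zero displacement field outside the stack confines the
#' electric field to the air gap, so the electrode potential difference is
#' \deqn{V_{oc}(x) = \sigma x / \varepsilon_0,} independent of the dielectric
#' films. Linear and exact for the flat 1D stack; the 2D field solver
#' reproduces it to machine precision on interface-aligned grids.
#'
#' @param gap electrode separation, m (>= 0); vectorized.
#' @param cfg a [teng_config()].
#' @return open-circuit voltage, V.
#' @export
closed_form_voc <- function(gap, cfg) {
  stopifnot(inherits(cfg, "teng_config"))
  if (any(gap < 0)) stop("gap must be non-negative")
  cfg$sigma * gap / EPS0
}

#' Closed-form capacitance of the flat dielectric stack
#'
#' Series capacitor of the silk film, Kapton film and air gap:
#' \deqn{C(x) = \varepsilon_0 A / (d_{silk}/\varepsilon_{silk} +
#'   d_{kapton}/\varepsilon_{kapton} + x).}
#' Strictly decreasing in the gap; finite at contact.
#'
#' @inheritParams closed_form_voc
#' @return capacitance, F.
#' @export
closed_form_capacitance <- function(gap, cfg) {
  stopifnot(inherits(cfg, "teng_config"))
  if (any(gap < 0)) stop("gap must be non-negative")
  if (cfg$plate_area <= 0) stop("plate_area must be positive")
  d_eff <- cfg$d_silk / cfg$eps_silk + cfg$d_kapton / cfg$eps_kapton
  EPS0 * cfg$plate_area / (d_eff + gap)
}
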