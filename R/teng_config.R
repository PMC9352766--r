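#' Micropattern geometry of a tribo-surface
#'
#' Describes the periodic microrelief moulded on the silk tribo-layer. The
#' cross-section used by the 2D field solver is a rectangle for `"cube"`, a
#' triangle (apex towards the counter-surface) for `"pyramid"`, and a
#' semicircle for `"sphere"`. Features protrude from the film into the gap;
#' the electrode gap is measured from the feature tips to the facing Kapton
#' surface, so gap 0 means tip contact for every shape.
#'
#' Defaults put the feature size well below the device's minimum working
#' gap (features 0.25 um on a 0.5 um pitch, against a 1 um closest
#' approach): the pattern then sets the tribo charge per projected area
#' (through its true contour length) without dominating the near-contact
#' field, which is the regime in which the surface morphology changes the
#' device curve but not the neuron's firing. The boost factors depend only
#' on the feature aspect ratio, so the shape ordering is size-independent.
#'
#' @param shape one of `"flat"`, `"cube"`, `"pyramid"`, `"sphere"`.
#' @param feature_width lateral width of one feature, m. Ignored for flat.
#' @param feature_height height of the feature above the film, m. For
#'   `"sphere"` the protrusion depth is the semicircle radius
#'   `feature_width/2` and this argument is ignored.
#' @param pitch period of the pattern, m; must satisfy
#'   `feature_width <= pitch`.
#' @return an object of class `micropattern_spec`.
#' @export
micropattern_spec <- function(shape = c("flat", "cube", "pyramid", "sphere"),
                              feature_width = 2.5e-7,
                              feature_height = 2.5e-7,
                              pitch = 5e-7) {
  shape <- match.arg(shape)
  if (shape != "flat") {
    stopifnot(feature_width > 0, feature_height > 0, pitch > 0)
    if (feature_width > pitch)
      stop("feature_width must not exceed pitch")
  }
  structure(
    list(shape = shape, feature_width = feature_width,
         feature_height = feature_height, pitch = pitch),
    class = "micropattern_spec")
}

#' Effective protrusion height of a pattern, m
#' @noRd
pattern_depth <- function(pattern) {
  switch(pattern$shape,
         flat    = 0,
         cube    = pattern$feature_height,
         pyramid = pattern$feature_height,
         sphere  = pattern$feature_width / 2)
}

#' True contour length of the tribo-charged surface over one pitch, m
#'
#' Flat surfaces have contour length equal to the pitch; protruding features
#' lengthen it. Used to set the total tribo charge under the
#' conformal-contact assumption (uniform charge density on the true surface).
#' @noRd
pattern_contour_length <- function(pattern) {
  p <- pattern$pitch
  w <- pattern$feature_width
  h <- pattern_depth(pattern)
  switch(pattern$shape,
         flat    = p,
         cube    = p + 2 * h,
         pyramid = (p - w) + 2 * sqrt(h^2 + (w / 2)^2),
         sphere  = (p - w) + pi * w / 2)
}

#' TENG device configuration
#'
#' Geometry and material parameters of the vertical contact-separation
#' device: a fixed bottom gold electrode carrying a Kapton tribo-layer and a
#' moving top gold electrode carrying a silk tribo-layer (silk and Kapton
#' sit near opposite ends of the triboelectric series). Defaults are the
#' reference device of this package.
#'
#' @param plate_area electrode area, m^2.
#' @param d_silk silk film thickness, m.
#' @param d_kapton Kapton film thickness, m.
#' @param electrode_thickness gold electrode thickness, m.
#' @param sigma tribo surface charge density, C/m^2 (>= 0).
#' @param eps_silk relative permittivity of silk (>= 1).
#' @param eps_kapton relative permittivity of Kapton (>= 1).
#' @param pattern a [micropattern_spec()].
#' @return an object of class `teng_config`.
#' @examples
#' cfg <- teng_config()
#' closed_form_voc(1e-4, cfg)
#' @export
teng_config <- function(plate_area = 15e-5,
                        d_silk = 7e-7,
                        d_kapton = 7e-7,
                        electrode_thickness = 5e-7,
                        sigma = 5e-5,
                        eps_silk = 2.6,
                        eps_kapton = 3.4,
                        pattern = micropattern_spec("flat")) {
  stopifnot(plate_area > 0, d_silk > 0, d_kapton > 0,
            electrode_thickness > 0, sigma >= 0,
            eps_silk >= 1, eps_kapton >= 1,
            inherits(pattern, "micropattern_spec"))
  structure(
    list(plate_area = plate_area, d_silk = d_silk, d_kapton = d_kapton,
         electrode_thickness = electrode_thickness, sigma = sigma,
         eps_silk = eps_silk, eps_kapton = eps_kapton, pattern = pattern),
    class = "teng_config")
}

#' @exportS3Method base::print
print.teng_config <- function(x, ...) {
  cat("TENG configuration (vertical contact-separation)\n")
  cat(sprintf("  plate area        : %g m^2\n", x$plate_area))
  cat(sprintf("  silk / Kapton     : %g / %g m (eps_r %g / %g)\n",
              x$d_silk, x$d_kapton, x$eps_silk, x$eps_kapton))
  cat(sprintf("  tribo charge      : %g C/m^2\n", x$sigma))
  cat(sprintf("  surface pattern   : %s\n", x$pattern$shape))
  if (x$pattern$shape != "flat")
    cat(sprintf("    width %g m, height %g m, pitch %g m\n",
                x$pattern$feature_width, x$pattern$feature_height,
                x$pattern$pitch))
  invisible(x)
}

# polynomial rolling hash of a deparsed object; stable id for file headers
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
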