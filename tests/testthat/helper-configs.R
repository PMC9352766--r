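# small, fast configurations shared across tests

short_axon <- function(n = 12, t_end = 2, dt = 0.001)
  axon_config(n_compartments = n, length = 0.01 * n, t_end = t_end, dt = dt)

# flat device curve over the default motion range, closed-form stack model
flat_curve <- function(n_nodes = 21)
  build_curve(teng_config(), seq(1e-6, 1.25e-4, length.out = n_nodes),
              method = "closed_form")

# zero-capacitance fixture: coupled dynamics reduce exactly to the plain run
zero_cap_curve <- function()
  fixture_curve("constant", voc0 = 0, cap0 = 0)

# capacitance fixture with per-area value cap_uF (uF/cm^2), zero voltage
const_cap_curve <- function(cap_uF) {
  area <- 15e-5
  fixture_curve("constant", voc0 = 0,
                cap0 = cap_uF * 1e-6 * (area * 1e4), plate_area = area)
}
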