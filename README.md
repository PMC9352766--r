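# tengneuron

Can a triboelectric nanogenerator (TENG) — two tribo-charged plates
moving towards and away from each other — excite a neuron? `tengneuron`
is an R package for exploring that question computationally. It couples
the electrostatics of a vertical contact-separation TENG (silk and
Kapton tribo-layers on gold electrodes, flat or micropatterned) to a
compartmental Hodgkin-Huxley cable model of an unmyelinated axon, and
extracts the spike-train statistics that characterize the response:
firing rate, full width at half maximum (FWHM), inter-pulse delay and
resting-potential shift. It is aimed at modellers of self-powered
bioelectric stimulation who want a reproducible, testable desk-scale
version of this device-neuron chain.

## The model in brief

**Device.** For a flat stack in open circuit the field is confined to
the air gap, so

```
V_oc(x) = sigma * x / eps0            (exact, film permittivities cancel)
C(x)    = eps0 * A / (d_s/eps_s + d_k/eps_k + x)    (series stack)
```

with `sigma` the tribo surface charge density, `x` the gap and `A` the
plate area. Micropatterned surfaces (cube / pyramid / sphere features
moulded on the silk face) are handled by a 2D finite-volume Poisson
solver with interface-aligned grids, floating uncharged electrodes and
tribo charge proportional to the true surface contour (so cube >
pyramid > sphere > flat in voltage output). The capacitance reported
for solver-built curves follows the charge-voltage relation
`C = sigma*A / V_oc`.

**Neuron.** Classical squid-axon Hodgkin-Huxley kinetics inside the
cable equation

```
C_m dV/dt = 1/(2 pi a (r_i + r_e)) d2V/dz2 + I_S - I_ion
```

with sealed ends and explicit time stepping (compiled inner loop,
pure-R reference stepper for cross-checks).

**Coupling.** The moving charged capacitor injects

```
I_drive = -dC/dx * dx/dt * (V_oc - V_m) - C * dV_oc/dx * dx/dt
```

per membrane area, and the remaining `C dV/dt` term turns the update
denominator into `C_m - C(x)`. The device enters only through a
tabulated `teng_curve` (V_oc and C on a 21-node gap grid, derivatives
as node difference quotients), which is part of the model definition —
see the methods vignette (`vignettes/teng-axon-coupling.Rmd`) for why
the tabulation matters.

## Worked example

Build the flat device curve over the working gap range, run the
resting-neuron protocol at a contact-release speed of 0.5 cm/s, and
summarize the response:

```r
library(tengneuron)

cfg   <- teng_config()                                  # reference device
gaps  <- seq(1e-6, 1.25e-4, length.out = 21)            # 1 um .. 125 um
curve <- build_curve(cfg, gaps, method = "poisson_2d")
curve
#> TENG curve (poisson_2d, flat): 21 gaps in [1e-06, 0.000125] m
#>   V_oc: 5.647 .. 705.9 V;  C: 1.328e-09 .. 1.063e-11 F

res <- run_coupled(axon_config(), motion_profile(v = 0.5), curve)
res
#> cable simulation: 8001 samples x 100 compartments, t in [0, 200] ms
#>   V range: [-71.25, 43.51] mV

m <- ap_metrics(res)
m$spike_times
#> [1]  28.45  78.05 127.65 177.25
```

The device approaches to within 1 um every 49.6 ms at this speed, and
each near-contact pass evokes one action potential: 4 spikes in 200 ms
(20 Hz), mean FWHM 1.50 ms, inter-pulse delay 49.6 ms (the contact
period). At 0.025-0.05 cm/s the same run produces no spikes; at 1 cm/s
it produces 8. `speed_sweep()` and `pattern_sweep()` run these grids —
speeds 0.025-1 cm/s, four surface morphologies, resting and driven
("firing") protocols — and return tidy long-format tables.

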