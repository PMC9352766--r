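---
title: "Coupling a contact-separation nanogenerator to a Hodgkin-Huxley axon"
author: "tengneuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a contact-separation nanogenerator to a Hodgkin-Huxley axon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tengneuron)
```

## The model

A vertical contact-separation triboelectric nanogenerator (TENG) is two
plates whose facing dielectric films (here silk and Kapton, with gold
electrodes behind them) carry equal and opposite tribo charge after
contact. As the plates separate to a gap $x$, the open-circuit voltage
$V_{oc}(x)$ between the floating electrodes grows while the device
capacitance $C(x)$ falls. Held against an excitable fibre, the moving
charged capacitor injects a displacement current through the membrane.

`tengneuron` implements the full chain:

1. **Device electrostatics.** For the ideal flat stack the open-circuit
   voltage has the exact closed form $V_{oc}(x) = \sigma x/\varepsilon_0$
   (the displacement field vanishes outside the stack, so the entire
   potential drop sits across the air gap and the film permittivities
   cancel), and the electrode capacitance is the series stack
   $C(x) = \varepsilon_0 A/(d_s/\varepsilon_s + d_k/\varepsilon_k + x)$.
   Micropatterned surfaces have no closed form; `solve_poisson_2d()`
   solves $\nabla\cdot(\varepsilon\nabla\phi) = -\rho$ on a 2D
   cross-section of the stack, one pattern pitch wide, with zero normal
   displacement on the outer box, electrodes as floating uncharged
   conductors, and the tribo charge imposed on the two facing surfaces.
   `extract_voc_capacitance()` reports the electrode potential difference
   and the capacitance through the charge-voltage relation
   $C = Q/V_{oc}$ with $Q = \sigma A$.
2. **Membrane kinetics.** Classical squid-axon Hodgkin-Huxley currents,
   $I_{ion} = \bar g_K n^4 (V - E_K) + \bar g_{Na} m^3 h (V - E_{Na}) +
   g_L (V - E_L)$, with the rate functions written in absolute membrane
   potential about a $-60$ mV resting potential and no temperature
   scaling. Gating advances by exponential Euler, which is exact at
   frozen voltage and keeps $n, m, h$ in $[0,1]$ unconditionally.
3. **Cable propagation.** A compartmental unmyelinated axon,
   $C_m \partial_t V_m = \frac{1}{2\pi a (r_i + r_e)} \partial_z^2 V_m +
   I_S - I_{ion}$, with sealed ends, $r_{i,e} = R_{i,e}/(\pi a^2)$, and
   forward-Euler voltage stepping guarded by the explicit stability
   bound.
4. **Device-neuron coupling.** The moving device adds
   $-\frac{dC}{dx}\frac{dx}{dt}(V_{oc} - V_m) -
   C\frac{dV_{oc}}{dx}\frac{dx}{dt} + C\,\partial_t V_m$ to the membrane
   balance. The first two terms act as an external current; the third is
   absorbed into the update denominator, so coupled compartments advance
   with $\Delta t/(C_m - C(x))$. The device capacitance enters per unit
   membrane area (the tabulated total divided by the plate area), which
   makes every term dimensionally consistent in
   $\mu\mathrm{A\,cm^{-2}}$, and the solver refuses to run if
   $C(x) \ge C_m$, where the quasi-static update loses validity.

A note on signs: a variant of this discretized update that *adds*
the ionic currents would make the resting state self-exciting; the
package uses the standard cable-equation convention (ionic currents
subtract), which is the only stable reading.

## The device curve is the model

The coupled solver never calls the field solver directly. It consumes a
`teng_curve`: $V_{oc}$ and $C$ tabulated on a gap grid (21 nodes over the
motion range by default), interpolated piecewise-linearly, with
$dV_{oc}/dx$ and $dC/dx$ formed as central differences **on the curve
nodes**. This mirrors how such models are driven in practice — a finite
set of field solutions at distinct distances — and it matters more than
it may seem:

* With $C = \sigma A / V_{oc}$, the product $C(x)V_{oc}(x)$ is constant
  at the nodes, so the two motional terms cancel *exactly* there and
  nearly everywhere the curve is well resolved. A continuum-resolved
  curve (hundreds of nodes) therefore produces almost no net drive and
  the neuron never fires at realistic speeds.
* The drive that excites the neuron is the difference-quotient residual
  of the coarse tabulation, which is largest near contact where $C(x)$
  varies fastest. The 21-node tabulation is part of the model
  definition, not a numerical convenience, and the default grid is
  documented and fixed.
* Because the products $C\,dV_{oc}/dx$ and $V_{oc}\,dC/dx$ are invariant
  under $V_{oc} \to k V_{oc}$, $C \to C/k$, the drive is insensitive to
  the pattern's voltage boost factor $k$. This is precisely why surface
  morphology reshapes the device curve (cube doubles $V_{oc}$ and halves
  $C$) yet leaves the firing rate essentially unchanged.

## Default study conditions and why

All defaults are set once, here, and used by the tests and the
acceptance script.

* **Device (flat reference):** plate area $15\times10^{-5}$ m$^2$, films
  $7\times10^{-7}$ m, electrodes $5\times10^{-7}$ m,
  $\sigma = 5\times10^{-5}$ C m$^{-2}$, $\varepsilon_r = 2.6$ (silk) and
  $3.4$ (Kapton).
* **Micropatterns:** protruding features on the silk face; rectangle,
  triangle or semicircle cross-sections for cube, pyramid and sphere.
  The gap coordinate is tip-to-surface, so gap 0 means tip contact for
  every shape. Feature size defaults to $0.25\,\mu$m on a $0.5\,\mu$m
  pitch (height = width = pitch/2). Two considerations fix this scale:
  the films are only $0.7\,\mu$m thick, and the features must sit well
  below the $1\,\mu$m closest approach so that the pattern sets the
  total tribo charge (through its true contour length, the
  conformal-contact assumption) without dominating the near-contact
  field. The charge-boost factors — cube $1 + 2h/P = 2$, pyramid
  $\approx 1.62$, sphere $\approx 1.29$ — depend only on the aspect
  ratio, so the morphology ordering is size-independent.
* **Motion:** triangular wave, $|dx/dt| = v$, from $x_{max} = 125\,\mu$m
  down to $x_{min} = 1\,\mu$m (avoiding the degenerate contact corner)
  and back. The excursion is chosen so the device completes one to
  several contact cycles within the 200 ms observation window across the
  working speed range: at $v = 0.25$ cm s$^{-1}$ the period is 99 ms.
  With a centimetre-scale excursion the period would exceed the window
  at nearly every speed and repetitive firing within the window would be
  geometrically impossible.
* **Axon:** radius $10^{-3}$ cm, length 1 cm, 100 compartments,
  $R_i = 35$, $R_e = 20$ $\Omega$ cm, $\Delta t = 10^{-3}$ ms (stability
  bound $\approx 5.5\times10^{-3}$ ms), 200 ms horizon, output decimated
  to 0.025 ms.
* **Protocols:** the resting protocol injects nothing; the firing
  protocol injects 10 $\mu$A cm$^{-2}$ at every compartment during
  0-100 ms, which drives sustained repetitive firing near 70 Hz.
* **Spike detection:** upward crossings of 0 mV grouped within 2 ms,
  spike time at the group maximum. Firing rates are reported over the
  full observation window; stimulus-epoch counts are kept separately for
  the driven-protocol comparisons.

```{r curves}
cfg <- teng_config()
crv <- build_curve(cfg, method = "closed_form")
crv
query_curve(crv, 1e-4)$voc   # V at a 100 um gap
```

```{r run, eval = FALSE}
# resting neuron under the moving device (about a second per run)
gaps <- seq(1e-6, 1.25e-4, length.out = 21)
curve <- build_curve(cfg, gaps, method = "poisson_2d")
res <- run_coupled(axon_config(), motion_profile(v = 0.5), curve)
ap_metrics(res)$n_spikes
```

## Numerical choices

* **Field solver.** Finite-volume (box) discretization on a tensor grid
  whose node rows are aligned with every material interface; the sparse
  symmetric system is factorized directly. For flat geometry the exact
  potential is piecewise linear with kinks only at the charged
  interfaces, so the solver reproduces the closed form essentially to
  machine precision at any resolution (residual error
  $\sim 10^{-6}$ relative, set by the finite conductor permittivity
  $10^6$ used for the floating electrodes). Patterned geometries
  converge under refinement; `convergence_estimate` reports the relative
  change in $V_{oc}$ under one grid doubling. Stair-stepped contour
  charge is renormalized to the analytic contour length so sloped
  surfaces are not over-charged.
* **Degenerate corner.** The flat device at gap 0 has $V_{oc} = 0$ and
  the charge-voltage relation degenerates to $0/0$; extraction then
  reports the series-stack limit and flags the value. Curves consumed by
  the coupled stage are tabulated over the motion range
  $[x_{min}, x_{max}]$, which excludes the corner.
* **Stepping.** Operator splitting: forward-Euler voltage update (with
  the $C_m - C(x)$ denominator on coupled compartments), then
  exponential-Euler gating at the pre-step voltage. A compiled loop and
  a pure-R reference stepper implement the same arithmetic; they agree
  to $10^{-13}$ and the compiled path is the default. At speed 0 with a
  zero-capacitance fixture curve the coupled run is bit-identical to the
  plain run; with a constant-capacitance fixture it equals a plain run
  with rescaled membrane capacitance, exactly.
* **Turning points.** The triangular wave keeps the incoming segment's
  one-sided velocity at the exact turning sample, so $dx/dt$ is defined
  at every step.

## What the synthetic generators emulate

`synthetic_trace()` builds voltage traces from Gaussian action-potential
templates at programmed times on a flat baseline with optional white
noise — ground truth for the detector, width, delay and rate metrics
(the Gaussian FWHM has the closed form $2\sqrt{2\ln 2}\,\sigma$).
`fixture_curve()` provides analytic device curves whose coupling terms
are hand-computable. Neither emulates channel noise, electrode drift,
recording filters or real AP shapes; passing metric tests therefore
demonstrates correctness of the computations, not robustness to
real-world recordings.

## What the default conditions reproduce, and what they do not

Under the defaults above, the package reproduces the qualitative
structure reported for this class of model: a resting neuron is
quiescent at low contact-release speeds, fires a single action potential
near 0.075-0.1 cm s$^{-1}$, and fires repetitively at 0.25-1 cm
s$^{-1}$ with a rate that grows with speed; device-evoked inter-pulse
delays shrink with speed (they track the contact period); subthreshold
near-contact passes elevate the resting potential by 0.1-0.2 mV; during
a driven firing epoch the device leaves the spike count and rhythm
essentially untouched; and the surface morphology reshapes the device
curve strongly (cube doubling $V_{oc}$) while shifting spike counts by
at most one.

Two reported trends do **not** emerge from this surrogate and are left
as failing acceptance checks rather than being tuned away: the mean
spike amplitude is not monotonically decreasing with speed (it varies
within 2% and rises at the highest speed, where device-advanced spikes
are driven harder), and the resting-protocol FWHM rises by 2-4% from
0.075 to 0.5 cm s$^{-1}$ for the flat and pyramid devices before
falling at 1 cm s$^{-1}$. Both are stable, deterministic properties of
the coupled model under these conditions. The deep-subthreshold
baseline shift (device far from contact) is a $\sim10^{-3}$ mV
tabulation artifact with indeterminate sign, far below the near-contact
elevation; the acceptance check asserts the elevation where the
trajectory actually approaches contact.

## Limitations

* The field model is a 2D cross-section surrogate; fringe fields, 3D
  feature shapes and dielectric breakdown of the air gap are out of
  scope, and tribo charge is static (no decay).
* The coupling has no axial structure by default (the device is assumed
  large against the fibre); a compartment sub-range can localize it.
* Only the vertical contact-separation mode with a triangular gap
  waveform is modelled; closed-circuit operation with a load is out of
  scope.
* Exact waveform-level reproduction of any particular published device
  is not attempted: feature dimensions, gap excursions and drive
  waveforms of real devices vary, and the firing behaviour depends on
  the tabulated-curve resolution as described above.
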