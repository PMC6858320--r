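---
title: "A mechanokinetic model of myosin-driven actin depolymerization in gliding assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanokinetic model of myosin-driven actin depolymerization in gliding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myoglide)
```

## The problem

In a gliding (motility) assay, myosin motors fixed to a surface
translocate actin filaments; the filament speed reports the collective
activity of the motor ensemble. When the motors are a catch-bond myosin
1 — a motor whose attachment lifetime *increases* with load in the
few-pN range — something else happens as well: filaments sliding over
such a bed depolymerize faster at their barbed end, while their
association rate is untouched. A fast slip-bond motor such as muscle
myosin II propels filaments several-fold faster but leaves barbed-end
kinetics alone. `myoglide` implements a minimal mechanokinetic model of
this effect, a synthetic TIRF data generator, and the complete
measurement chain used on such data, so that every inference step can be
validated against known ground truth.

## The model

### Geometry and state

A single rigid filament of length $L$ subunits (2.7 nm each) glides
pointed-end-leading along one axis; the barbed (growing) end is the
trailing edge at position $x_b$, the pointed edge at
$x_p = x_b + 2.7 L$. Motors attach anywhere under the filament footprint
(surface density $\rho$, capture half-width $w$, so $\rho \cdot 2w$
candidate motors per nm) at a per-motor rate $k_a$. An attached head
binds one subunit: its distance from the barbed end (its *site*) changes
only when subunits are gained or lost at the ends, never by advection.
This bookkeeping is what lets a depolymerizing end "eat toward" a
load-bearing motor and is the physically consistent reading of a gliding
geometry with laboratory-fixed anchors.

### Motor cycle

Attachment starts a *driving* phase: the motor exerts
$F_{stall}(1 - v/v_0)$ on the filament until the head–anchor relative
displacement reaches the stroke distance $d_{stroke}$. It then becomes
*resisting*: an elastic linkage of stiffness $\kappa$ loaded by the
moving filament, $\dot F = \kappa (v_f - F/\xi_{anchor})$, and released
at the two-pathway catch–slip rate
$$k_{det}(F) = \left(k_c e^{-F/F_c} + k_s e^{F/F_s}\right)
  \frac{[\mathrm{ATP}]}{[\mathrm{ATP}] + K_{ATP}}.$$
A single Michaelis–Menten factor carries the ATP dependence of both the
actuation velocity and detachment; with $K_{ATP} = 0.15$ mM, 2 mM ATP is
saturating and 0.2 mM is substantially sub-saturating, which is what
makes low ATP both slow the motors and prolong their attachments.

The instantaneous velocity solves the linear balance
$$N_d F_{stall}\left(1 - \frac{v}{v_0}\right)
  = \xi_b v + \sum_{j \in \mathrm{resisting}} F_j ,$$
with $\xi_b = 4\pi \eta_b L / \ln(2L/r_f)$ the slender-body drag
($r_f = 4$ nm), multiplied by a crowding factor (default 3) when
methylcellulose is configured. For the parameter regimes of interest the
bulk drag is orders of magnitude below the motor forces; it is retained
for completeness and for the analytic cross-check
`membrane_partition_velocity()`.

### The depolymerase coupling

Association at the barbed end is purely chemical, $r_{on} = k_{on} C_m$.
Dissociation is enhanced by the load of the resisting motor closest to
the barbed end within a tip zone $\ell_{tip}$:
$$r_{off} = k_{off,0} \, e^{F_{tip}\,\delta / k_B T}.$$
This one-parameter Bell coupling is the minimal mechanical instantiation
of "a motor at the barbed end with a long attachment time opposes the
motion and pulls subunits out": it raises $k_{off}$ without touching
$k_{on}$, is switched off entirely by $\delta = 0$, and is strong only
for motors that stay attached under load — i.e. catch bonds. Whether the
real interaction involves a distinct molecular state at the tip is an
open question; only the mechanical variant is implemented.

### Membrane mode

With motors anchored in a fluid bilayer (drag $\xi_{anchor}$ per anchor,
obtained from a measured diffusion coefficient through the Einstein
relation $\xi = k_B T / D$), three things change relative to glass:
resisting loads saturate at $\xi_{anchor} v_f$ instead of growing until
slip detachment; the driving force–velocity acquires the factor
$1/(1 + F_{stall}/(\xi_{anchor} v_0))$ because the anchor is dragged
backward by the propulsion reaction; and the working stroke completes
after $d_{stroke}$ of *head–anchor* relative displacement, which
includes the backward anchor slip — so fewer motors are driving at any
instant. The last effect dominates the net slowdown. $\xi_{anchor} =
\infty$ reproduces immobilized mode exactly (bit-identical trajectories
at equal seeds), which is tested. The full hydrodynamic derivation of
the bilayer/bulk partition is beyond this package; the implementation is
an explicit two-drag balance that reproduces the stated limits (no
slowdown in water, a ~25–33% slowdown in methylcellulose) and is
cross-checked against the closed-form partition formula.

The reference anchor drag corresponds to `reference_anchor_mobility()` =
3.42e-4 µm²/s. This is far below the free mobility of a lipid or an
unengaged motor: when a filament bridges many motors, the measured motor
mobility collapses, and the effective per-anchor drag relevant to force
transmission is the engaged-motor value. It is part of the calibrated
reference set (below). A consequence worth stating plainly: at this
drag, tip forces on the bilayer saturate near
$\xi_{anchor} v_f \approx 0.5$ pN, so the simulated membrane-mode
depolymerase effect is much weaker than on glass — the model
under-represents the measured bilayer effect, and we did not add an ad
hoc tip-specific drag to hide that.

### Integration

A fixed time step `dt` advances the motor bed (attachment sampled as a
Poisson count, the small-p limit of per-site Bernoulli draws; detachment
probabilities $1 - e^{-k\,dt}$), while barbed/pointed-end chemistry runs
as an exact Gillespie sub-loop within each step with rates frozen over
the step. Because exponential waiting times are memoryless, the
motor-free case is *exactly* the two-rate birth–death process, which the
suite verifies with a two-sample Kolmogorov–Smirnov test against an
independent Gillespie implementation (p > 0.01 at 10⁴ events).
Configurations with `dt` × (fastest configured rate) > 0.1 are rejected
before running. Two independent RNG streams (motor bed / end chemistry)
keep paired simulations that differ only in end-chemistry parameters
maximally coupled; exact bit-identity between a $\delta = 0$ and a
$\delta > 0$ run is impossible regardless, because depolymerization
feeds back on motor sites and on $x_b$ itself, so the paired test
asserts the mechanistic ordering (shorter filaments for $\delta > 0$,
nearly identical gliding) instead.

## Reference parameter sets and their calibration

The model is deliberately generic; the two bundled species encode its
two interesting corners. All values live in `reference_species()` and
`barbed_end_model()`, not in hidden constants. The set was calibrated
*once*, against the observables of the reference assay (mean sliding
velocity ≈ 56 nm/s for a dense immobilized bed at 2 mM ATP, ≈ 38 nm/s on
the bilayer, roughly two-fold velocity reductions at 20-fold lower
density and at 0.2 mM ATP, a roughly two-fold elongation reduction at
0.6 µM G-actin, and a five-fold faster slip-bond bed with unchanged
k_off), and then frozen.

| parameter | myo1b | myoII | units | role |
|---|---|---|---|---|
| `attach_rate` | 0.08 | 0.3 | 1/s | sets duty and the density response |
| `v0_max` | 80 | 320 | nm/s | unloaded actuation velocity |
| `K_ATP` | 0.15 | 0.15 | mM | ATP half-saturation |
| `F_stall` | 10 | 3 | pN | drive per motor |
| `kappa` | 0.02 | 0.005 | pN/nm | anchor loading rate |
| `k_det_c`, `F_c` | 5, 0.8 | 0, – | 1/s, pN | catch pathway |
| `k_det_s`, `F_s` | 0.12, 1.8 | 25, 1.2 | 1/s, pN | slip pathway |
| `d_stroke` | 5 | 5 | nm | working stroke |

Barbed end: $k_{on} = 11.6$ su µM⁻¹ s⁻¹ and $k_{off,0} = 1.4$ su/s (the
textbook barbed-end constants, giving $C_{c+} = 0.12$ µM), $\delta = 5$
nm, $\ell_{tip} = 150$ nm, $k_B T = 4.1$ pN nm. The soft linkage
($\kappa = 0.02$ pN/nm) is what makes the catch bond operative: anchors
load at ~1 pN/s, most escape at low force, and the surviving few hold
2–4 pN for seconds — enough, through $\delta$, to triple the effective
dissociation rate when one of them sits in the tip zone. The low
attachment rate makes the driving ensemble small (~15 motors on a 5 µm
filament), which is what produces the observed two-fold slowdown at
20-fold lower density through stalling intermittency; attachment flux
cancels out of the continuum force balance, so discreteness is the only
density lever in this model — a structural prediction, not a tuning
accident.

Filament-to-filament variability in real assays (CV ≈ 20–25% of measured
velocities) is emulated in the scenario layer by a lognormal per-filament
bed-quality factor (CV 0.2) multiplying `v0_max`, `F_stall` and `k_det_c`
together (a poor surface patch is slow, weak and sticky at once);
initial lengths are drawn uniformly from 1500–3000 subunits (4–8 µm).
Quality must shift the balance point, not just the unloaded speed,
because the catch-bond load feedback strongly compresses variations of
`v0_max` alone.

## The synthetic data generator

`render_kymograph()` draws the filament as a top-hat of linear density
`intensity_per_su`/2.7 per nm convolved with an isotropic Gaussian PSF
(σ = 200 nm), sampled at 160 nm/pixel and 10 s/frame, with Poisson (or
Gaussian, or no) noise and optional exponential bleaching; exact edge
positions ride along as ground truth. `render_movie()` does the same in
2-D; `linear_trajectory()` provides exact straight-line kinematics for
chain validation; `make_frap_curve()` and `make_titration_table()`
generate the calibration inputs (single-exponential recovery
parameterized so the Soumpasis relation is exactly invertible; lipid
densities from the 0.68 nm² area per lipid, both leaflets fluorescing by
default since TIRF excites the whole supported bilayer).

What the generator does *not* emulate: camera-specific noise (EMCCD
gain), stage drift, filament crossing and bending during gliding
(movies lay filaments on straight lanes; curved-filament flattening is
exercised with static polyline fixtures), labeling stoichiometry noise,
and evanescent-depth effects. Passing tests therefore validate the
inference chain on idealized imaging, not robustness to every real-world
artifact.

## The measurement chain and its numerical choices

* **Path finding**: automatic ridge tracing on a temporal-max projection
  replaces the manual segmented line, extended 10 px past the filament
  ends so the flattened band contains background; manual polylines are
  accepted. Bands are 10 px wide, sampled at 1 px arc steps with
  bilinear interpolation.
* **Edges**: per row, background is the median of the outermost columns
  (the renderer pads paths, so these are guaranteed signal-free — a
  lowest-quartile estimate is biased once a filament fills most of the
  row, which measurably depressed elongation slopes), the plateau is the
  median of above-half-range pixels, the threshold sits halfway, and the
  outermost crossings are interpolated linearly for sub-pixel precision.
  Rows whose plateau does not clear 5 noise MADs are flagged invalid.
  On noiseless renderings the worst edge/length error is ~3 nm, well
  inside the one-pixel (160 nm) accuracy contract.
* **Filters**: length must exceed 20 px in every frame; directional
  motion is quantified as at most 10% of frame-to-frame leading-edge
  displacements opposing the net direction (the qualitative "moving
  directionally during the whole sequence" needs a number; 10% is that
  number).
* **Velocities**: `v_f` is the least-squares slope of the leading
  (pointed) edge — for stabilized filaments identical to the barbed-edge
  slope, for polymerizing ones the only definition that isolates gliding
  from subunit exchange. `v_p` is the slope of
  (length − initial length)/2.7.
* **Kinetics fits**: per-filament (C_m, v_p) points, weighted by inverse
  per-concentration variance when replicates exist (uniform otherwise);
  uncertainties from a seeded case-resampling bootstrap (2000 resamples)
  — chosen over analytic errors because per-filament v_p is skewed at
  low C_m. `compare_koff()` forms the bootstrap ratio distribution.
* **FRAP**: `nls` with deterministic initialization (plateau from the
  last 10% of points, τ from the half-recovery time) and a
  `scaleOffset` so exact noiseless curves converge; flat curves raise an
  estimation error rather than returning nonsense.

## Problem sizes

The test suite and the acceptance script observe each simulated filament
for 300 s (31 frames at the 10 s frame interval) and use 50 filaments
per velocity condition, 8–12 per concentration for kinetics fits, 10⁴
events for the Gillespie equivalence test, and 100 noisy kymographs for
the edge-accuracy Monte Carlo. These sizes give standard errors of ~2
nm/s on condition means and run in a few minutes on one core; larger
designs only narrow the error bars.

## Known limitations

* The membrane-mode depolymerase effect is structurally weaker than on
  glass (tip forces cap at $\xi_{anchor} v_f$); reproducing a strong
  bilayer k_off increase would require a tip-specific anchoring
  assumption the model deliberately avoids.
* No filament torsion, bending or buckling: the observed length
  independence of $v_p$ is built in, matching the measurement that
  motivated discarding torsion-based mechanisms, but the package cannot
  test torsion hypotheses.
* Single filaments only — no crossings, no network effects; motor-motor
  coupling through the bilayer enters only through the effective
  engaged-anchor drag.
* The two-phase motor cycle compresses the ATPase cycle into one MM
  factor; kinetic schemes with explicit ADP states would change the ATP
  response quantitatively.
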