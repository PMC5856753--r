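---
title: "Mechanics of rod-shaped bacterial microcolony morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of rod-shaped bacterial microcolony morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rodcolony` simulates the first hours of surface colonization by rod-shaped
bacteria such as *Escherichia coli*: a single founder cell attached between a
rigid gel and a substrate grows into a monolayer microcolony whose shape and
mechanics are set by the interplay of elongation, steric repulsion and
cell-substrate adhesion.

**Cells.** Each bacterium is a spherocylinder of width $r_0$ and
pole-to-pole length $d_c$, discretized as six balls equally spaced along its
axis (ball 1 at the old pole, ball 6 at the new pole; the axis unit vector
points old $\to$ new).  Cells elongate exponentially, $\dot d_c = g\,d_c$,
symmetrically about their center of mass.  Once $d_c \ge d_L$ they divide
stochastically at a constant rate, and deterministically as soon as
$d_c > 1.3\,d_L$.  Division splits the cell at its midpoint; each daughter
keeps one mother pole as its old pole, while the two septum-born poles are
*new* and carry no adhesive links.  This is the only source of adhesive
asymmetry in the model: polarity is inherited, not imposed.

**Cell-cell forces.**  Balls of distinct cells interact through a force law
derived from a Yukawa-like potential: linear elastic repulsion
$k_{rep}(r_0 - r)$ below contact and a weak exponential attractive tail
beyond it.  The printed law is discontinuous at $r = r_0$; we implement it
exactly as stated and expose $V_0 = 0$ as the configuration that removes
both the attraction and the discontinuity.

**Adhesive links.**  Adhesion is carried by punctual elastic links between a
material point on the cell envelope and a fixed substrate anchor, created at
rate $k_{on}$ per ball up to a saturation density $n_l$.  In *polar* mode
links appear only in a disk of diameter $r_0$ around each pole; in *uniform*
mode they appear anywhere along the body.  A link is born at zero extension;
its attachment advects with the cell's rigid-body motion and stretches with
elongation (its body-frame arclength is stored as a fraction of $d_c$).
Link elasticity is the worm-like chain,
$F(L) = -\frac{kT}{L_p}\big(\frac{L}{L_0} + \frac14(1-\frac{L}{L_0})^{-2}
- \frac14\big)$, and links detach at rate
$k_{off}(1 + \operatorname{arctanh}(F/F_{link}))$, with certain rupture at
the threshold $F_{link}$.  Detached bonds are lost.

**Dynamics.**  Motion is overdamped: translation and rotation follow the net
ball forces and torques divided by slender-body friction coefficients
$\nu_t, \nu_r$ with the standard logarithmic end corrections.  Integration
is explicit Euler with fixed $\Delta t$ and a per-step stability guard
(error above $r_0/2$ displacement).  Stochastic events are Bernoulli trials
with $p = 1 - e^{-\text{rate}\,\Delta t}$ from a single seeded RNG in a
fixed order (creation $\to$ forces $\to$ detachment $\to$ integration $\to$
growth $\to$ division), so a `(config, seed)` pair reproduces every bit of
a trajectory.

## Default parameters

Values marked *choice* are not fixed by the underlying theory and were set
once, on the physical grounds given, before any acceptance measurement; the
config file overrides everything.

| parameter | default | why |
|---|---|---|
| $r_0$ | 1 µm | typical *E. coli* width |
| $d_L$ | 4 µm | division length, twice the birth length |
| $g$ | $\ln 2/25$ min⁻¹ | 25 min doubling time |
| division rate | 0.5 min⁻¹ (*choice*) | few-minute stochastic wait before the forced 30% backstop |
| $k_{rep}$ | $10^4$ pN/µm | near-rigid contact: sub-percent overlaps at colony forces |
| $V_0, r_1$ | 0.1 pN µm, 0.1 µm (*choice*) | weak short-range cohesion, small against link forces |
| $F_{link}$ | 4.25 pN | rupture force of one adhesin/polysaccharide bond |
| $L_0$ | 0.3 µm | contour length of the tether |
| $L_p$ | 0.5 nm (*choice*) | flexible-polymer persistence length of adhesins/polysaccharides; at this scale $F_{link}$ sits in the moderately stretched WLC regime rather than the divergent one |
| $kT$ | 4.24×10⁻³ pN µm | 307 K |
| $k_{on}$ | 1 min⁻¹ per ball (*choice*) | pole patches saturate well within one cell cycle, matching the observed one-cycle maturation of polar adhesion |
| $n_l$ | 10 per ball | saturation density of links |
| $k_{off}$ | 0.01 min⁻¹ (*choice*) | unloaded bonds outlive the cell cycle |
| $\eta$ | 100 pN min/µm² (*choice*) | mechanical relaxation (~0.1 min) far below the doubling time |
| $\Delta t$ | 0.005 min (*choice*) | a factor ~3 below the single-contact stability bound to cover multi-contact stiffness |
| lattice | 0.510 µm | traction-microscopy grid pitch |

## Observables

* `cell_asymmetry()` — $A_{cell}$, the slope of the center-of-mass
  displacement projected on the old$\to$new axis against elongation; 0 for
  uniform adhesion, $+0.5$ for a rigid old-pole anchor.
* `aspect_ratio()` — $b/a$ of the moment-equivalent ellipse of the
  rasterized colony mask (pitch 0.05 µm).
* `substrate_force_grid()`, `foci_force()` — link tensions deposited at
  their anchors on the 510 nm lattice; $F_{foci}$ is the median of the
  per-frame maximum once the colony exceeds eight cells (the plateau
  regime; the median is robust to rupture spikes).
* `global_stress_sigma()` — slope of total substrate force against colony
  area change (Pa; numerically identical to pN/µm², so no conversion
  factor appears anywhere).
* `colony_asymmetry()` — maximal old-pole vs new-pole lattice force
  normalized by $F_{foci}$.
* `nematic_order()` — mean of $\cos 2\Delta\theta$ over cell pairs within a
  length scale.  The precise estimator used in the original figure is not
  specified in the available methods; this pair statistic is our documented
  choice.

## Energetics of the monolayer-to-multilayer transition

During 2D growth the link elastic energy and the steric repulsion energy
rise with colony size.  Across rupture-force sweeps they follow
$E_{adh} = \alpha F_{foci}^2 N_{cells}$ and
$E_{rep} = (\beta_0 + \beta_1 F_{foci}) N_{cells}^2$
(`fit_energy_scalings()`; area and cell number are interchangeable through
$N = A/A_0$ — we standardize on $N$, and $A_0$ defaults to the footprint of
a newborn cell).  A bacterium escapes into the third dimension when
indenting the gel above (Hertz cost
$E_g = \frac{8}{15}\frac{E}{1-\nu^2}(r_0/2)^{1/2}z^{5/2}$) plus stretching
its links vertically ($W = \gamma z F_{foci}$) becomes cheaper than
continuing to load the monolayer; it then releases its mean repulsion
energy and saves the colony a surface $\delta A = z r_0$.  Balancing the
two growth routes gives the closed-form transition size

$$N_{2D/3D}(E, F_{foci}) = \frac{E_g + \gamma z F_{foci} -
\alpha F_{foci}^2 z r_0}{A_0 (2 z r_0 + A_0)(\beta_0 + \beta_1 F_{foci})}.$$

The closed form drops all second-order products of the infinitesimals
$dA$ and $\delta A$ while keeping the per-cell released repulsion
$\beta A A_0$; `delta_energy_balance()` exposes the discrete increments as
printed, and `transition_size_from_balance()` solves the balance in the
same first-order regime, which is why the two agree to $10^{-6}$ rather
than only to $O(\delta A/A_0)$.  `infer_foci_force()` inverts the closed
form on a verified monotone bracket — monotonicity in $F_{foci}$ is not
guaranteed for all coefficients, so the inversion checks it instead of
assuming it.  The transition constants default to $z = 0.1$ µm and
$\gamma = 1$ (*choice*: an indentation a tenth of the cell width and link
work of order $z F_{foci}$); both are config inputs, and
`fit_transition_constants()` estimates them from observation tuples.

## Numerical choices and degenerate inputs

* **Septum geometry.**  Daughters are born with their facing new-pole balls
  at the contact distance $r_0$, i.e. cap surfaces tangent at the septum
  plane.  Coincident septum balls (the naive reading of "split at the
  midpoint") have no defined force direction and would inject
  $\sim \frac12 k_{rep} r_0^2$ of spurious elastic energy per division —
  an artifact of the ball discretization, not colony mechanics.  Pole links
  keep their pole identity (ball 1, old tag) across division with their
  attachment world-points preserved exactly, so division never jumps a
  pole-link tension.  Attachment parameterization stays on the stretching
  sidewall span ($|{\rm frac}| \le 1/2$): pole-disk samples are folded onto
  the body side of the pole center, and the rare uniform-mode attachment
  that would map onto a daughter's regenerated cap is projected back onto
  the body span (a $\le r_0/2$ relocation).
* **Quasi-static energy frames.**  A division still perturbs its
  neighborhood for a few relaxation times.  Energy-scaling fits therefore
  drop frames younger than 1 min (about ten single-contact relaxation
  times) after the latest division (`settle` argument); the remaining
  frames represent the quasi-static state the scaling laws describe.
* **Saturation vs inheritance.**  The per-ball cap $n_l$ is enforced at
  creation; links reassigned at division are never dropped, so a ball can
  transiently exceed $n_l$ until attrition.  We rank "division never
  orphans a link" above strict saturation.
* **Neighbor search.**  An $O(N^2)$ cell-pair bounding-circle prefilter
  with the $r_0 + 5 r_1$ interaction cutoff; for the few hundred cells this
  package targets it is equivalent to spatial hashing and simpler.
* **Rigid pins.**  Test fixtures may carry unbreakable zero-compliance
  links; they are handled as exact kinematic constraints (the pinned
  material point is re-projected onto its anchor each step), which is the
  stiff limit without the prohibitive time step a stiff spring would need.
* Degenerate inputs error early: $r_{bb'} = 0$ (coincident balls),
  $L \ge L_0$ (unruptured overstretched link), non-positive friction
  denominators, empty masks, missing elongation in an asymmetry track.

## What the synthetic world does and does not establish

The simulator *is* the data generator: there is no external data set.  The
stated world reproduces the model-level quantities — the $\pm 0.5$ and $0$
bounds of $A_{cell}$, the quadratic scalings of $E_{adh}$ in $F_{foci}$ and
of $E_{rep}$ in $N_{cells}$, rounder colonies and shorter-range nematic
order under polar adhesion than under uniform adhesion.  It does not
reproduce strain-specific absolute numbers: those depend on a full
supplementary parameter table that is not part of the available text.  In
particular, with the defaults above ($n_l = 10$ links of at most 4.25 pN
per pole ball) the maximal lattice force saturates around 8-15 pN, an order
of magnitude below the 115 pN measured for wild-type *E. coli*; reaching it
would need several tens of links superposing in one 510 nm lattice cell.
The corresponding calibration check is therefore expected to fail with
package defaults and is kept honest rather than tuned (see
`tests/testthat/test-acceptance.R`).  A green test suite establishes
internal consistency of the mechanics, energetics and observables at the
stated parameters — not agreement with any particular experiment.

## Known limitations

Strictly 2D monolayer mechanics (the third dimension enters only through
the transition energetics); no hydrodynamic interactions, cell flexibility
or substrate viscoelasticity; no lineage variability in growth rate; no
re-maturation delay of ruptured pole patches (creation eligibility is
instantaneous); colony area ignores overlaps between neighboring
footprints.
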