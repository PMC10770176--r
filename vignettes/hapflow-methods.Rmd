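---
title: "Modeling hypoxia-activated pro-drug schedules in digitized tumor tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hypoxia-activated pro-drug schedules in digitized tumor tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hapflow)
```

# The model

`hapflow` simulates treatment of a small patch of vascularized tumor tissue
with a hypoxia-activated pro-drug (HAP) such as evofosfamide (TH-302),
optionally combined with two hypoxia *enhancers*: a vasodilator
(hydralazine-like, reducing tumor-vessel flow through the vascular-steal
effect) and a metabolic sensitizer (pyruvate-like, raising tumor-cell oxygen
consumption dose-dependently). The question the machinery answers is a
scheduling one: *when* should each compound be injected, relative to the
HAP bolus, to maximize tumor cell kill at a three-hour horizon?

The tissue is a rectangle $\Omega = [0,200] \times [0,100]\,\mu m$ with one
feeding vessel along the left edge and a few hundred immobile tumor cells
$\Gamma_l$, each a closed contour of boundary points spaced
$\epsilon = 2\,\mu m$ apart. The boundary points act as *pseudo-receptors*:
they are simultaneously no-slip obstacles for the interstitial fluid and the
sites of oxygen and active-drug absorption. Cells neither move nor divide on
the three-hour timescale; dead cells stop absorbing but remain as obstacles.

Four diffusible species live on the interstitial part of a uniform grid
($h = 2\,\mu m$): oxygen $\gamma$ (mmHg), inactive pro-drug $\eta_i$, active
drug $\eta_a$ and sensitizer $\xi$ (all in $ag/\mu m^3$). Each obeys a
reaction–advection–diffusion law of the form

$$\partial_t c = D\,\Delta c \;-\; \mathbf u \cdot \nabla c \;-\;
  (\text{uptake}) \;\pm\; (\text{activation}) \;-\; (\text{decay}),$$

with Dirichlet influx on the vessel edge, zero concentration on the open
right edge, and no-flux top and bottom.

## Interstitial flow: regularized Stokeslets

At cell scale the Reynolds number is vanishingly small, so the interstitial
fluid obeys the Stokes equations driven by point forces placed on the
vessel edge (imposing the influx velocity $u_{in} = 1\,\mu m/s = 60\,\mu
m/min$), on the top and bottom walls, and on every cell boundary point
(no-slip), all spaced $\epsilon$ apart with corner points deduplicated.
Each force is smoothed over a blob
$\phi_\epsilon(r) = 2\epsilon^4 / \pi (r^2+\epsilon^2)^3$. Solving
$\mu\Delta\mathbf u = \nabla p - \mathbf f\,\phi_\epsilon$,
$\nabla\cdot\mathbf u = 0$ for this blob gives the velocity kernel the
package uses,

$$\mathbf u(\mathbf x) = \frac{1}{8\pi\mu} \sum_k
  \left(\frac{2\epsilon^2}{R_k} - \ln R_k - 1\right)\mathbf f_k
  + \frac{2\,[\mathbf f_k\cdot \mathbf d_k]\,\mathbf d_k}{R_k},
  \qquad R_k = r_k^2 + \epsilon^2,$$

which is *exactly divergence-free* (the test suite verifies this
numerically) and reduces to the classical two-dimensional Stokeslet as
$\epsilon \to 0$. Incompressibility matters physically: with a kernel that
leaks mass, the imposed vessel influx short-circuits back between the
discrete force points and essentially no advective transport reaches the
tissue. With the divergence-free kernel the influx percolates: on the
default synthetic tissue, interstitial speeds fall from tens of $\mu m/min$
near the vessel to fractions of a $\mu m/min$ distally, the range reported
for tumor interstitium.

Forces are obtained by inverting the dense $2M \times 2M$ mobility matrix
against the imposed boundary velocities. The solver contract is the
residual, not the algorithm: after the solve (a dense LAPACK factorization
with iterative refinement; $M$ is a few thousand at most) the maximum
boundary-velocity error relative to $u_{in}$ must be at most $10^{-8}$, or
the solve aborts. Because all cells are immobile the field is computed once
per geometry and cached; the vasodilator only rescales it (Stokes
linearity), by $\lambda = 0.5$ while in circulation.

## Transport on the masked grid

Cell interiors are impermeable. The diffusion update omits stencil
neighbors that lie inside cells, so mass exchanges only between
interstitial nodes; advective flux cannot enter cells either, because the
velocity vanishes on their boundaries and masked nodes are skipped.

The update is explicit with $\Delta t = 1.5\times10^{-3}\,min$. A detail
with teeth: for the fastest species ($D_\gamma = 10^3\,\mu m^2/min$) the
standard stability number is $\Delta t\,D_\gamma/h^2 = 0.375$. That is
stable for a *one-dimensional* explicit update ($s \le 1/2$) but **not**
for the unsplit two-dimensional 4-neighbor update, which requires
$s \le 1/4$ and blows up at 0.375 (readily demonstrated). The package
therefore splits the diffusion step dimensionally — an explicit x-sweep
followed by a y-sweep, each a 1-D masked update. Each sweep is stable and
satisfies the discrete maximum principle for $s \le 1/2$, conserves
interstitial mass exactly under reflecting boundaries (pairwise symmetric
exchanges), and the splitting error is $O(\Delta t)$, far below the scheme's
spatial error at this resolution.

Advection is first-order donor-cell upwind along the frozen flow field
(CFL $\approx 0.045$ at default settings); a masked or out-of-domain
upwind neighbor contributes zero gradient. At CFL below one this scheme
coincides with a semi-Lagrangian update with linear interpolation, which
the test suite exploits as an independent reference.

Within a step the operator order is: (1) vessel boundary values, (2)
diffusion, (3) advection, (4) reactions (activation, uptake, decay), (5)
death bookkeeping — sequential (Lie) splitting, whose $O(\Delta t)$ error is
negligible at this step size.

## Oxygen, uptake, and the sensitizer tiers

Oxygen enters at $\gamma^{in} = 60$ mmHg and is consumed at nodes covered
by live-cell pseudo-receptors: a node within $\epsilon$ of $k$ receptor
points experiences $k$-fold uptake (the receptor double sum implemented
literally). Above half the hypoxia threshold the per-receptor rate is the
constant $\gamma_0 = 0.85$ mmHg/min, amplified by the sensitizer tier
$\psi \in \{1, 5/3, 7.5/3, 12.5/3\}$ for local sensitizer concentrations in
$[0,9)$, $[9,22)$, $[22,88)$, $[88,\infty)$ $ag/\mu m^3$. Below
$0.5\,\gamma_{hyp} = 5$ mmHg (severe hypoxia) the rate tapers in proportion
to the remaining oxygen.

Two forms of that severe-hypoxia taper are exposed. The default,
`severe_uptake = "normalized"`, uses
$\gamma_0\,\gamma/(0.5\gamma_{hyp})$ — continuous at the knee and tending
to zero with the oxygen itself. The alternative `"bare"` uses the
unnormalized product $\gamma_0\,\gamma$, which is discontinuous at the
knee (0.85 just above 5 mmHg, $\approx 4.2$ just below). The bare form has
a real dynamical consequence: the jump creates bistability, so tissue that
has been pushed into severe hypoxia by a transient does not fully
reoxygenate when the perturbation ends (in our runs it recovers only to
$\approx 98\%$ of baseline, with the hypoxia border permanently displaced).
Since transiently induced hypoxia is, physiologically and in this model's
intent, fully reversible — and since the normalized form also places the
initial normoxia/hypoxia border at 124 $\mu m$ on the default synthetic
tissue, inside the 110–130 $\mu m$ range the calibration targets — the
normalized form is the default.

The simulation always starts from the steady oxygen gradient: the oxygen
update is iterated (all cells alive, no drugs) until the per-node L2 change
falls below $10^{-10}$.

## Pro-drug activation and cell death

The inactive drug enters at $\eta_i^{in} = 50\,ag/\mu m^3$ during its
10-minute plasma window and converts to active drug wherever
$\gamma \le \gamma_{hyp} = 10$ mmHg. The conversion level 0.9 is
interpreted per time step (90% of local inactive drug converts each step
while hypoxic — effectively instantaneous conversion inside hypoxic
regions); a continuous-rate reading (0.9/min) is available via
`phi_mode = "per_min"`. Conversion transfers mass exactly, node by node.

The active drug diffuses ($D_{\eta a} = D_\gamma/25$), advects, decays with
half-life 10 min ($\omega_a = \ln 2 / 10$), and is absorbed at live-cell
receptor nodes at rate $\alpha = 0.5$/min. Each cell integrates its own
absorbed drug, $\Gamma_l^\eta \mathrel{+}= \Delta t\,\alpha \sum \eta_a$
over its receptor nodes; the identical flux is removed from the field
($k$-fold at $k$-covered nodes), and the run tracks both sides of this
bookkeeping, which must agree to $10^{-10}$ relative. The death test
converts the node sum to a mean concentration — multiply by $h^2$, divide
by the cell polygon area — and kills the cell (irreversibly, checked once
per step, threshold inclusive) when it reaches
$\eta_a^{thr} = 1\,ag/\mu m^3$. Dead cells leave all uptake sums from the
next step on; oxygen then reflows into their neighborhood, which is the
feedback that pushes the normoxia/hypoxia border away from the vessel
during successful treatment.

## Schedules, the vasodilator, and sweeps

A schedule assigns each compound at most one plasma window (HAP 10 min;
sensitizer and vasodilator 25 min). The vasodilator is not simulated as a
concentration: while it circulates, all vessel influx values (oxygen,
inactive drug, sensitizer) and the flow field are multiplied by
$\lambda = 0.5$, evaluated pointwise in time.

`sweep_offsets()` reruns the full simulation over a lattice of enhancer
injection offsets relative to the HAP bolus (negative = enhancer first).
When an offset would start a window before $t = 0$ the whole schedule is
shifted right, preserving relative timing; offsets whose windows overrun
the horizon are flagged infeasible rather than skipped. Local maxima are
detected with a 4-neighborhood rule that merges equal-valued plateaus,
since enhancer sweeps genuinely produce plateaus and ridges rather than
isolated peaks. All runs share the cached flow field and steady-state
oxygen, and any sweep cell rerun standalone reproduces its count exactly
(the dynamics contain no randomness).

# The synthetic tissue generator

The digitized histology the model was built around is not redistributable,
so the package ships a generator that emulates its statistics: the default
grid, a cell-free strip of $2\epsilon$ along the vessel so the influx is
unobstructed, and 300 irregular, pairwise non-overlapping cell contours
with boundary points resampled to $\epsilon$ spacing. Cells are seeded on a
jittered hexagonal lattice whose spacing adapts to the requested count;
each cell's radial extent is capped at half the distance to its nearest
neighbor minus a fixed $0.6\,\mu m$ interstitial gap, which guarantees
non-overlap at histology-like packing (roughly 40% cell area, interstitial
channels of one to two grid cells). Contours are low-order harmonic
perturbations of circles (amplitude 15%), giving the lobed, irregular
outlines of packed epithelial cells. Everything is drawn from a seeded RNG
and is bit-reproducible for fixed arguments.

What the generator does *not* emulate: the spatial clustering, size
dispersion and anisotropy of real histology, multi-vessel geometries, and
the particular 365-cell arrangement behind the study's quantitative kill
counts. Consequences observed in practice: the steady-state border
(124 $\mu m$ on seed 101) and its treatment-driven displacement
(plateauing near 152–154 $\mu m$ after a HAP bolus) land remarkably close
to the histology-based values, but absolute dead-cell counts are
geometry-sensitive and should only be compared *between schedules on the
same tissue*, not against histology-based counts. Likewise the timing of
the sensitizer-induced oxygen minimum: on the open synthetic interstitium
the sensitizer clears quickly once its vascular window ends, so the tissue
oxygen minimum sits essentially at the window end (~30 min for a bolus at
5 min), whereas slower interstitial clearance in denser tissue delays it
(~40 min is the histology-based figure). Passing transient-timing tests on
synthetic tissue therefore validates the window-driven kinetics, not the
tissue-specific lag.

# Numerical choices and problem sizes

* Internal units are $\mu m$ and minutes everywhere; configuration files
  accept $u_{in}$ in $\mu m/s$ (the unit used in the experimental
  literature) and convert on load.
* Negative concentrations cannot arise from diffusion (maximum principle)
  or upwind advection (monotone); the uptake update clamps at zero and
  counts every clamp. Default runs report zero clamps; the counter is part
  of every result's numerical-health block.
* Point-in-polygon uses the even–odd rule with nodes exactly on a contour
  counted as interior (obstacles), via `pracma::inpolygon`.
* The steady-state iteration starts from the linear no-uptake profile,
  which roughly halves its iteration count (~5–6 × 10⁴ iterations at
  default settings).
* Tests run on reduced fixtures (a 100 × 50 $\mu m$ patch with 40 cells; a
  5 × 5 toy grid for the hand-checked stencil oracle); the acceptance
  checks for transient-hypoxia timing use the full default tissue
  (300 cells, 101 × 51 nodes, two 180-minute runs at
  $\Delta t = 1.5\times10^{-3}$ min, i.e. 120 000 steps each). These sizes
  were chosen so the whole suite stays in the minutes range on a single
  core while still exercising the full-scale configuration where the
  published kinetics are defined.

# Known limitations

* Two-dimensional only; no multi-vessel or branched vasculature.
* One bolus per compound; repeat dosing is out of scope.
* First-order (in space and time) transport: quantitative concentration
  fields carry $O(h)$ upwind smearing, acceptable here because the graded
  outcomes are cell counts and timing of extrema.
* The dense mobility matrix limits the method to a few thousand force
  points per geometry ($\approx$ 550 MB and ~30 s at $M \approx 3500$);
  larger tissues would need a matrix-free iterative solver.
* No cell metabolism: sensitizer-enhanced uptake switches on immediately
  with local concentration, with no transcriptional lag.
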