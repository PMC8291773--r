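---
title: "Simulating protein transport through nanopores: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating protein transport through nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

poresim simulates resistive-pulse protein sensing in nanopores by coupling
three models that operate on very different time scales: a continuum
electrokinetic description of ions and water (microseconds of implicit
dynamics condensed into a steady state), Brownian dynamics of a single
protein over precomputed fields (nanoseconds to seconds), and a stochastic
chemistry model for adsorption to receptors or pore walls (milliseconds to
minutes). This vignette explains each model, its assumptions and tunable
parameters, the numerical choices behind the implementation, and what the
bundled synthetic test conditions do and do not demonstrate.

## The continuum electrokinetic model

The electrolyte is described by the steady Poisson–Nernst–Planck–Stokes
(PNPS) system for the potential $\phi$, ion concentrations $c^\pm$, velocity
$u$ and pressure $p$:

* Poisson: $-\nabla\cdot(\varepsilon\nabla\phi) = C_F (c^+ - c^-) + \rho$,
  with material permittivities (water 80.2, protein 2, DNA 12, lipid 2,
  silicon nitride 7) and surface charge densities entering the wall boundary
  condition;
* Nernst–Planck: $\nabla\cdot j^\pm = 0$ with
  $j^\pm = -D^\pm\nabla c^\pm \mp \frac{q D^\pm}{kT} c^\pm \nabla\phi + u\,c^\pm$
  (diffusion, electromigration, advection), for a symmetric monovalent salt;
* Stokes: $-\eta\nabla^2 u + \nabla p = -C_F(c^+-c^-)\nabla\phi$,
  $\nabla\cdot u = 0$, no slip on walls.

The ionic current through any cross-section is
$J = C_F\int (j_z^+ - j_z^-)\,dA$, and the force on an explicit protein
sphere $M$ is $F_{\mathrm{PNPS}} = F_{el} + F_{drag}$ with
$F_{el} = \int_M \rho E$ (the net charge spread uniformly over the sphere)
and $F_{drag}$ the integral of the fluid stress over the sphere surface.

Geometry is axisymmetric $(r, z)$ with $z = 0$ at the upper channel entry.
Three presets reproduce the study pores: a parameterized α-hemolysin profile
(radii 0.5–2.8 nm over 10 nm), a conical SAM-coated solid-state pore
(40° aperture, 20 nm tip), and a DNA origami pore (46 nm channel, nominal
6 × 6 nm² lumen, 6 nm walls at −0.74 q/nm²). The DNA pore's square lumen and
box reservoir are mapped to equal-area circles; a circular lumen of given
diameter is available through the `shape`/`width` overrides, which is how
the channel-width sweeps are run.

### Discretization and solver

The fields are discretized with a cell-centered finite-volume scheme on a
graded tensor-product $(r, z)$ grid; fluxes across faces that are partially
blocked by curved walls are scaled by the open face fraction, and the total
surface charge per wall segment is rescaled to the analytic area of the
surface of revolution so staircase walls carry the correct charge. Ion
fluxes use Scharfetter–Gummel exponential fitting (with the fluid velocity
included in the drift), which keeps concentrations positive and makes the
current integral conservative to round-off: the current evaluated on any two
cross-sections agrees to well below a percent. Stokes flow lives on a
staggered (MAC) layout assembled into one saddle-point system, factorized
once per geometry and reused across the outer iterations; rows are
equilibrated to unit magnitude, and enclosed fluid pockets found by a
connected-component pass get one pinned pressure each. The outer coupling is
a damped fixed-point (Gummel-type) iteration with a linearized Boltzmann
response in the Poisson update (tolerance $10^{-6}$ by default, relaxation
0.7; the heavy production runs use $10^{-5}$, which moves currents by well
under a percent).

Mesh defaults: 0.25 nm edge length near the channel, 1.5–2.5 nm in the
reservoir, an extra band at the protein-wall gap (a third of the gap, at
least 0.04 nm), and — important for electroosmosis — a 0.08 nm boundary-layer
band at the charged channel wall. Resolving that electric double layer is
what brings the electroosmotic plug velocity onto the Smoluchowski estimate;
without it the advective current and drag are overestimated severalfold. All
of these were fixed by convergence studies on the DNA-pore geometry
(conductance and blockade stable to a few percent under further refinement).

The applied voltage is the potential of the lower (trans) reservoir minus
the upper (cis) one, split symmetrically across the two Dirichlet
boundaries; bulk concentrations are imposed there as well. The lateral
reservoir boundary is no-flux and free-slip — the reference for the outer
boundary conditions does not pin this choice, and at the default reservoir
sizes the difference to a no-slip lateral wall is below the mesh tolerance.

## Position-dependent diffusivity

Diffusivity is a $3\times 3$ tensor everywhere. The reference machinery is
low-Reynolds-number hydrodynamics (LRNH): three Stokes resistance solves
with unit velocities give the friction tensor $\gamma(x)$ and
$D = kT\,\gamma^{-1}$. poresim implements LRNH with the method of
regularized Stokeslets: the sphere surface carries ~600 point forces on a
Fibonacci spiral (regularization 0.45 × point spacing, calibrated once
against the exact free-sphere drag, error < 1%); a plane wall is treated
exactly with the classical image system, and channel walls are collocated
with rings whose spacing and blob size grow with distance from the particle.
The axisymmetric finite-volume Stokes solver provides an independent
cross-check of the same drag (agreement within the staircase mesh tolerance,
roughly 10–20% at default resolution, converging from below under
refinement).

Because full LRNH per protein position is too expensive inside the coupled
solver, four field models are available: `bulk_constant`;
`z_dependent` (centerline LRNH extended radially); `r_dependent`
(plane-wall closed forms of the distance to the nearest wall — the Faxén
series for parallel motion and a Padé approximant for perpendicular motion);
and `combined_rz`, the production model, which rescales the r-dependent
tensor per z so its centerline value equals the centerline LRNH tensor.
The Padé form is written in the surface-to-wall gap, not the center
distance: only then does it vanish at contact and stay below the parallel
factor everywhere, as both the physics and the LRNH cross-check demand.
Factors are floored at $10^{-3}$ in the lubrication limit, where the
closed forms are unreliable anyway. The tensor eigenframe follows the
nearest-wall normal; inside the conservation-law solvers the tensor is
reduced to its diagonal $(r, z, \theta)$ components.

With an explicit protein in the domain, the protein surface counts as a
wall for the ion-diffusivity field — the nearest-wall closed form is
precisely what makes a protein-position-dependent ion field affordable.
(`ion_field_sees_protein = FALSE` reverts to a single bare-pore field.)

Centerline LRNH values are cached at a configurable number of stations
(12 by default, 6 in the production runs — the study channels are straight,
so the profile is flat in the middle) and interpolated monotonically.

## Brownian dynamics

Protein trajectories follow the overdamped Langevin equation, discretized
as
$$x^{n+1} = x^n + \nabla\!\cdot\!D\,dt + \frac{D F_{\mathrm{PNPS}}}{kT}dt
  + \sqrt{2\,dt}\,C\,\xi,\qquad D = C C^{\mathsf T},$$
with $\xi$ three standard normal draws per step. Because the diffusivity
field has the form $\alpha I + \beta\, n n^{\mathsf T}$, the square root is
closed-form; the spurious-drift term $\nabla\cdot D$ is evaluated by central
differences of the interpolated tensor with a 0.05 nm stencil (halving the
stencil changes nothing detectable). Hard walls are handled by shortening
any step that would cross the protein-inflated wall surface so the center
stops just before contact. Time steps follow the study conditions: 0.2 ns
for the DNA pore, 1 ns for the solid-state pore; the synthetic test boxes
choose dt so one step is well below the smallest geometric feature.

Forces and currents come from a precomputed `force_current_grid`:
explicit-protein PNPS solves at on-axis stations (2–3 nm apart) provide the
axial force profile and the blocked current $J(z)$; off-axis entries use a
point-particle closure on the protein-free fields,
$F = \gamma(x)\,(\mu_{ep} E(x) + u(x))$, blended with the explicit on-axis
values across the lumen. The electrophoretic term uses the thin-double-layer
(Smoluchowski) mobility $\mu_{ep} = \varepsilon\zeta_p/\eta$ with $\zeta_p$
from the net charge spread over the sphere surface via the Grahame equation,
rather than the bare $QE$ force: at 1 M the double layer is ten times
thinner than the proteins considered, and the screening cloud reduces the
effective electrophoretic drive of a −50q sphere several-fold — an effect
the explicit PNPS force integrals contain automatically and the closure
must not lose. Wide pores whose blockades are negligible (the conical
solid-state preset) skip the explicit solves entirely
(`mode = "point_particle"`): on the coarse meshes such large domains admit,
the stress-box integrals are dominated by staircase noise while the closure
stays smooth; the mode is recorded in the grid object.
The off-axis current is approximated by the on-axis blockade profile at the
same height — adequate for event statistics in channels the protein nearly
fills, but not a model of off-axis blockade shapes. Two caveats worth
naming: the explicit $F_{el}$ samples the field inside the low-permittivity
sphere (dielectric cavity factor ≈ 1.48 in water), while the point-particle
closure uses plain $QE$; and the stress-box drag on a staircase sphere is
accurate only to the mesh tolerance. Both limit the absolute force scale to
roughly the 10–20% level, which moves event-duration clusters by less than
the decade widths they are compared at.

Trajectories stop on translocation (center crossing the lower channel end),
on escape from the 10 × 10 × 12 nm³ box above the upper entry (kept as a
literal box in the 3-D Cartesian coordinates of the walker), or at a step
cap. The solid-state pore has no published escape region; its runs use exit
through a plane 12 nm above the wide entrance with a generous lateral
allowance. Its receptor sits at 95% of the channel height measured from the
wide entrance — i.e. near the tip, where every translocating protein passes
within the 5.75 nm binding radius — and the voltage sign drives the −50q
protein from the wide entrance toward the tip. Every trajectory runs on its
own RNG stream derived from (seed + index), so ensembles are reproducible
trajectory by trajectory.

## Stochastic binding

A binding site is a spherical receptor or a wall region; the binding zone is
the set of protein centers within the binding radius $r_b$. While inside the
zone, adsorption attempts arrive as a Poisson process with rate
$R_a = k_a c_b$, where $c_b = (10^3 N_A V_b)^{-1}$ mol/L is the
concentration of one receptor in the zone volume — the spherical shell
between center distances $r_{prot} + r_{rec}$ and $r_b$. Wall sites use
$r_{rec} = 0$ with the 0.2 nm protein-surface-to-wall binding radius.
Binding durations are exponential with mean
$\tau = k_d^{-1} e^{-|F|\delta/kT}$ (Bell's law; $\delta = 0$ recovers the
force-free mean $1/k_d$). The force magnitude is used because a bead model
defines no bond direction. Multiple adsorptions in one step sum their
durations; at the preset rates the probability of more than one per step is
negligible, and the implementation draws the per-record Poisson counts by
thinning, which is exactly equivalent for equal step lengths.

Binding never changes a trajectory's spatial shape, so events can be drawn
after the fact, and rare-binding studies reuse the trajectory pool: pick a
trajectory uniformly with replacement, redraw its stochastic bindings, and
assemble a fresh event — duration $\tau_{off}$ = free time plus binding
durations, amplitude $A/I_0$ = time-weighted blockade average.

## Event analytics

`koff()` is $1/\overline{\tau_{off}}$ with a bootstrap CI.
`fit_exponential()`/`fit_double_exponential()` are maximum-likelihood fits
(the mixture by Nelder–Mead with 10 random multistarts on transformed
parameters); left-censoring renormalizes by the truncated survival function
— used to mimic analyses that exclude events shorter than the recording
filter resolves. `koff_vs_voltage()` regresses $\log_{10} k_{off}$ on
voltage. Histograms default to log-spaced bins because event durations span
submicrosecond failed attempts to seconds-long bound events.

## What the synthetic tests show

The property suite runs on three analytic fixtures: a sealed cylinder with
an Ohmic + access-resistance conductance oracle, a plane wall for
hindered-diffusion factors, and a closed box with a harmonic force field
whose stationary Boltzmann statistics are known. These validate the
discretizations and the stochastic integrators, not biology: the fixtures
have rigid, smooth walls, a single spherical analyte, symmetric monovalent
salt, and no protein flexibility, rotation, hydrodynamic memory, or
finite-ion-size effects — all outside the model class. Agreement there means
the equations as stated are solved correctly; agreement with the study-pore
numbers (open-pore currents, blockade-matching widths, event-duration
clusters, rare-binding fractions) additionally tests the modelling choices
listed above at desk scale.

Production problem sizes used by the bundled reproduction runs: channel-width
sweeps at 0.2/0.05/0.08 nm (fine/gap/double-layer) resolution, ~30–50 × 300
cells per solve; force grids from ~20–30 explicit stations at 0.3 nm fine
resolution; 500 DNA-pore trajectories at dt = 0.2 ns; 1200 solid-state
trajectories at dt = 1 ns with binding fractions evaluated both analytically
(expected probability per trajectory) and by resampling. Larger ensembles
change the reported medians and fractions within their quoted statistical
error.

## Known limitations

* Axisymmetric geometry only; off-axis protein positions are handled by the
  point-particle closure, not explicit solves.
* Staircase walls limit drag and force accuracy to ~10–20% at default
  resolution; currents are much less sensitive (conservative fluxes,
  face-fraction weighting).
* The double layer at 1 M is marginally resolved even with the dedicated
  band; surface conduction and electroosmosis carry a few-percent
  discretization uncertainty.
* The α-hemolysin preset is a parameterized profile, not the atomistic
  geometry and charge map; quantities that depend on its interior charge
  distribution are out of reach.
* No finite-ion-size corrections; simulated DNA-pore currents overestimate
  measured ones severalfold, consistent with the continuum model class.
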