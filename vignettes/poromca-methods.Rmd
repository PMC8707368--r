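---
title: "Methods: bonded-particle poroelasticity and shockwave dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bonded-particle poroelasticity and shockwave dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

poromca simulates saturated biological tissues as ensembles of equal-sized
movable cellular automata: finite-size particles on an FCC lattice whose
bonded, many-body elastic interactions reproduce isotropic linear
elasticity, coupled to a pore fluid through Biot's linear poroelasticity
and Darcy inter-particle exchange. This vignette records the model, its
numerical choices, and the design decisions a maintainer would want to
audit. All empirical statements here are computed by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## Solid phase

Each automaton has diameter $d$ and occupies the Voronoi cell of its FCC
site, a rhombic dodecahedron with volume $V = d^3/\sqrt2$ and twelve faces
of area $S = d^2/(2\sqrt2)$ at distance $q = d/2$. A bond between
automata $i,j$ carries

* a normal traction, per side
  $\sigma_n^{(i)} = 2G_i\,\varepsilon_i + \Lambda_i$, with
  $\Lambda_i = (K_i - \tfrac23 G_i)\,\varepsilon^{vol}_i - \alpha_i p_i$,
* a tangential traction $\tau = 2G_h\gamma$ with the pair shear stiffness
  $G_h = 2G_iG_j/(G_i+G_j)$ and $\gamma$ the accumulated tangential
  contact strain (relative contact velocity, including particle
  rotations, integrated over time and kept perpendicular to the bond).

For dissimilar materials the pair strain is partitioned so both sides
report the same normal stress (interface equilibrium); the partition is
solved in closed form each step. The volumetric strain of an automaton is
measured geometrically from its own per-side bond strains,
$\varepsilon^{vol}_i = 3\sum_j qS\,\varepsilon_{ij} / \sum_j qS$, which
equals $(1/V)\sum qS\,\varepsilon$ for a fully coordinated automaton and
is evaluated from the *current* configuration. (An alternative is to
derive $\varepsilon^{vol}$ from the previous step's averaged stress; the
two agree identically at the uniform-strain fixed point, but the
geometric form has no lagged feedback and is unconditionally stable, so
it is the one implemented.)

The averaged stress is the contact homogenisation
$\sigma_{ab} = (1/V_i)\sum_j qS\, n_a t_b$ (symmetrised). With the exact
Voronoi face areas this machinery is not approximate: under any uniform
strain field $E$ the normal/tangential direction sums cancel the cubic
anisotropy of the lattice and the homogenised stress is exactly
$\sigma = 2GE + (K - \tfrac23G)\,\mathrm{tr}E\,I$, i.e. isotropic Hooke's
law. The test suite verifies the consequences: uniaxial block compression
recovers $E$ within 5% and $\nu$ within 0.02 for every built-in tissue,
and a laterally confined column transmits longitudinal pulses at
$\sqrt{(K+4G/3)/\rho}$ within 5%.

**Free surfaces.** An automaton at a surface has fewer than 12 contacts.
Three consistent corrections follow from its truncated Voronoi volume
$V_{\mathrm{eff}} = \tfrac13\sum_j qS$: stress homogenisation and
volumetric strain are normalised by $V_{\mathrm{eff}}$, fluid storage uses
$V_{\mathrm{eff}}$, and the remaining bonds of a free-surface automaton
are stiffened by the lost-area ratio $V/V_{\mathrm{eff}}$ so that free
surfaces are not artificially compliant. The stiffening is switched off
under global lateral kinematic confinement, where no load path is lost
(boosting there over-stiffens the column, as the wave-speed fixture
shows). The compensation makes the force field weakly state-dependent;
in undamped runs seeded with broadband (white-noise) velocities it can
pump energy slowly, so conservation fixtures use smooth mode excitations
and production runs are either damped (quasi-static) or short relative to
the pumping time scale (pulse runs, whose energy traces are flat after
the pulse).

**Integration.** Velocity-Verlet with per-bond shear state, rotational
degrees of freedom with sphere inertia, optional mass-proportional
damping, and the CFL bound $\Delta t = s\,d/\max c_p$ (default
$s = 0.2$), using undrained wave speeds when the fluid is coupled.
Driven-boundary velocities are sampled at step midpoints so prescribed
displacements integrate exactly to $\pm\Delta t/2$.

**Quasi-statics.** The physical compression tests run at 0.001 m/s over
a second; explicitly integrating a second of real time is not what an
explicit dynamics code is for. Quasi-static drivers instead ramp over
`n_transit` (default 20–25) wave transits of the slowest material with
near-critical mass-proportional damping of the fundamental mode
($c = \pi c_{\min}/H$), and every driver reports a kinetic-energy guard
(`ke_ratio`, kinetic over stored energy; the suite requires < 1%).
Stiffness is rate-independent in the elastic limit, so the scaled rate
does not bias the slope fits (the fits report $R^2 = 1.000$). At these
rates the response is undrained, which is rate-consistent across element
sizes, so the mesh-convergence scatter metric remains well-posed.

## Fluid phase

Biot constants derive from Table-level inputs: $\alpha = 1 - K/K_s$ and
$1/M = \theta/K_f + (\alpha-\theta)/K_s$. One tabulated tissue (the
capsule shell) has $K = K_s$, hence $\alpha = 0 < \theta$, outside the
Biot–Willis bound where the standard storage relation would turn
negative; its grain-storage term is clamped at zero ($M = K_f/\theta$)
and the row is flagged. The fluid defaults to salt water
($K_f = 2.4$ GPa, $\rho_f = 1000$ kg/m³) with viscosity
$\mu = 10^{-3}$ Pa·s (water at room temperature; the viscosity is not a
tabulated constant and is overridable).

Per step the solver (i) exchanges fluid along bonds by Darcy's law,
$Q = k_h S (p_i - p_j)/(\mu r)$ with harmonic-mean permeability, (ii)
updates pressures by the storage law
$\mathrm{d}p = M(\mathrm{d}\zeta - \alpha\,\mathrm{d}\varepsilon^{vol})$,
and (iii) feeds $-\alpha p$ back into the diagonal of the next solid
step's tractions. Exchange is antisymmetric in fluid volume, so sealed
systems conserve fluid content to round-off (asserted in the suite at
$10^{-12}$ relative). High-permeability tissues (cancellous bone, capsule,
$k = 10^{-11}$ m²) have pore-pressure diffusivity $kM/\mu \approx 34$ m²/s,
which *exceeds* the explicit limit at the mechanical CFL step; the fluid
pass is therefore automatically substepped
($n_{sub} = \lceil D_{\max}\Delta t/(0.2 d^2)\rceil$).

Verification: instantaneous sealed compression reproduces the Skempton
pressure $B\,\Delta\sigma_{mean}$ and the undrained confined modulus
$K + \alpha^2 M + 4G/3$ within 5%; 1D consolidation of a column with a
drained end matches the Terzaghi series solution with RMS error below 5%
of the initial undrained pressure (the oracle uses the measured interior
axial stress, because the discrete column's cross-section differs from
the nominal box area by a surface-cell fraction, and starts its clock at
the load-ramp midpoint). Articular cartilage's tiny permeability
($4.8\times10^{-18}$ m²) keeps it effectively undrained on pulse time
scales: fluid redistribution during a pulse stays below 1% of porosity.

## The knee analog

The anatomical knee is replaced by a procedural analog that preserves the
tissue layering and contact sequence — bone (cancellous core, cortical
shell) / cartilage plate / meniscus ring with fibrous interior / cartilage
plate / bone — wrapped laterally by a capsule shell, with a copper
applicator plate bonded to the outer capsule wall at meniscus height. All
interfaces are bonded (the study involves no sliding or separation and no
damage), and the patella is omitted.

Geometry choices that matter numerically:

* **Curved interfaces.** The joint is a slightly conical cylinder and the
  soft band follows a condyle-like dome (2 mm sag). Flat, axis-aligned
  layers lock onto lattice planes, so their effective thicknesses jump
  with the element size; curved interfaces cut the lattice at varying
  phase and average that quantisation — the same service a real CAD
  anatomy performs. This was designed in before freezing the study runs.
* **Feature sizes ≥ 4 mm**, so the coarsest verification model
  (d = 2 mm) resolves every layer with two diameters, honouring the
  packing's own resolution invariant.
* **The applicator is restricted to the meniscus band.** A plate
  overlapping the cartilage-plate levels shears their edges directly and
  floods the distortional-strain window for reasons that are artefacts of
  the box-like analog.
* **Verification compression excludes the plate**; it belongs to the
  shockwave load case only.

What the analog does *not* emulate: anatomical curvature of the
condyle contact, ligaments, the patella, soft-tissue continuation beyond
the capsule, and — critically for dosimetry — the full-scale joint
volume. Passing verification here shows the solver converges on a
realistic layered structure; it does not show anatomical fidelity.

## Shock pulses and dosimetry

A pulse is a single $\sin^2$ velocity lobe. Its dose is the energy flux
density $PII = I\,T_p$ with plane-wave intensity $I = \rho c\,v^2/2$,
i.e. $PII = v^2 Z\,T_p/2$, where $T_p$ is the time for the pressure pulse
to reach 90% of its positive maximum (for the $\sin^2$ lobe,
$T_p = 0.39758\,t_{total}$). `calibrate_pulse()` inverts this for the
amplitude; the coupling impedance defaults to $Z = 1.5\times10^6$
kg·m⁻²·s⁻¹, which is simultaneously water-like and within a few percent
of the *undrained* impedance of every saturated soft tissue in the table
(they are 70–90% water). Dosimetry self-consistency is verified by
driving a calibrated pulse into a homogeneous saturated block and
recomputing $T_p$ and $PII$ from the simulated contact pressure trace
(measured from the wave's arrival); at the lowest dose level the
round-trip agrees within 20%. At higher doses finite-strain stiffening
raises the contact pressure a further 10–15% — the model is linear in its
constitutive law but geometric in its strains.

The sweep driver uses a pulse duration of 50 µs rather than the
microsecond scale of focused lithotripsy sources. Two reasons: the
flat-plate applicator pressed on the joint is the geometry of
radial/ballistic-type devices, whose pulses are one to three orders of
magnitude longer than focal shocks; and at microsecond durations the
calibrated amplitudes ($v = \sqrt{2\,PII/(Z T_p)}$) put 10–40 MPa at the
contact, two orders of magnitude above the tissue field levels the study
design targets. 50 µs is the single calibration of the analog's
transmission, chosen against target field magnitudes before the
acceptance studies were run, and not revisited.

## Regeneration criteria

Three windows, evaluated per particle on temporal maxima over the run
(snapshot evaluation is available as an option): compressive stress
0.15–2 MPa (onset of any osteo/chondrogenesis at 0.003 MPa; 0.7–0.8 MPa
most favourable), distortional strain 0.05–1.1% (an upper bound of 1% is
also in circulation; the wider default is overridable), and pore fluid
pressure 20 kPa–2 MPa (68 kPa optimal; a 40 kPa lower bound is also in
circulation and overridable). "Conditions met in large volumes" is made
operational as a conjunction coverage of 10% of the focus region (the
tibial cartilage plate), configurable. Coverage is reported for whole
anatomical parts; peak values per part are reported alongside.

## Desk scale: what transfers and what does not

Everything above runs on a desk: the finest verification model stays
under ~17k particles, a convergence study takes a few minutes, a
three-level dose sweep about two. Two distortions of the scale reduction
are documented because they decide study outcomes:

* **Discretisation sensitivity.** At desk scale $d/L$ is about five times
  larger than in a full-size joint model, so raster quantisation of the
  stiff load-bearing shells and $O(d)$ surface convergence contribute
  scatter of a few percent to the mesh-convergence stiffness — above the
  ~2% a full-scale model achieves. A probe at d = 1.1/1.0/0.9 mm shows
  the fine-size plateau scatter is well below 1%: the solver converges;
  the prescribed 1.0–2.0 mm range is simply still converging at this
  model size.
* **Energy density.** The dose is defined per unit applicator area, so
  the energy delivered per unit tissue volume scales with
  $A_{plate}/V_{soft}$. The sweep geometry (`knee_swt_spec()`) matches
  the full-scale proportion of that ratio as closely as the particle
  budget allows, but the remaining mismatch still concentrates several
  times the full-scale energy density into the analog. Consequently the
  three criteria are already satisfied over more than 10% of the
  cartilage at the lowest tested dose: the desk-scale sweep reproduces
  the *ordering* and the *field patterns* of the dose response, but not
  the sub-threshold behaviour of the lowest dose, and the window
  ceilings (2 MPa fluid, 1.1% strain) clip the coverage fractions at the
  highest dose, breaking their monotonicity there. The acceptance suite
  states these checks at full strength and they fail honestly at desk
  scale; the peak-field bounds (onset pressure at 0.12 mJ/mm²,
  chondrogenic stress at 0.33 mJ/mm²) pass.

## Numerical parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `safety` | 0.2 | CFL factor on the fastest (undrained) P-wave |
| `n_transit` | 20–25 | quasi-static ramp length in wave transits |
| `damping_ratio` | 1 | fraction of critical damping of the fundamental |
| `n_sub` | automatic | Darcy substeps per mechanical step |
| `surface_comp` | 1 (0 confined) | free-surface stiffness compensation |
| `t_total` | 5 µs (constructor), 50 µs (sweep) | pulse duration |
| `Z` | 1.5e6 kg·m⁻²·s⁻¹ | dosimetry coupling impedance |
| `coverage` | 0.1 | conjunction fraction defining the threshold dose |
| bond cutoff | 1.01 d | FCC nearest neighbours only |

## Known limitations

Small-strain kinematics (high-dose pulses reach percent-level strains in
the softest tissues, where the linear law is being extrapolated); no
fracture, plasticity, or bond breaking; no frictional contact; fluid
inertia neglected (quasi-static Darcy, appropriate to the low-frequency
Biot regime); sealed outer fluid boundary by default; energy bookkeeping
for the drift audit uses homogenised per-particle fields and is accurate
for smooth deformation states only.
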