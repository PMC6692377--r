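---
title: "The meshless membrane and crescent-rod model"
author: "memrod"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{The meshless membrane and crescent-rod model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`memrod` simulates a fluid biomembrane as an implicit-solvent, meshless
assembly of particles: each particle carries a position $\mathbf{r}_i$ and a
unit orientation vector $\mathbf{u}_i$ (the local membrane normal), and the
sheet self-assembles — there is no fixed mesh or bonded connectivity between
membrane particles.  Curvature-generating proteins of the BAR superfamily
are modelled as crescent-shaped rods of 10 membrane particles bound
together, with a spontaneous curvature $C_{\mathrm{rod}}$ along the rod
axis and optional chirality-generating hook particles.  Units throughout:
the particle diameter $\sigma = 1$, thermal energy $k_BT = 1$, mass $m = 1$;
physical times are reported in the intrinsic unit
$\tau = r_{\mathrm{rod}}^2/D$, with $D$ the membrane-particle diffusion
coefficient of the tensionless membrane and $r_{\mathrm{rod}} = 10\sigma$.

The potential is
$$U = U_{\mathrm{rep}} + U_{\mathrm{att}} + U_{\mathrm{bend}} + U_{\mathrm{tilt}},$$
with the orientation pair terms
$$U_{\mathrm{bend}} = \frac{k_{\mathrm{bend}}}{2}\sum_{i<j}
  \left(\mathbf{u}_i - \mathbf{u}_j - C_{\mathrm{bd}}\,\hat{\mathbf r}_{ij}\right)^2
  w_{\mathrm{cv}}(r_{ij}), \qquad
U_{\mathrm{tilt}} = \frac{k_{\mathrm{tilt}}}{2}\sum_{i<j}
  \left[(\mathbf{u}_i\cdot\hat{\mathbf r}_{ij})^2 +
        (\mathbf{u}_j\cdot\hat{\mathbf r}_{ij})^2\right] w_{\mathrm{cv}}(r_{ij}).$$
Membrane pairs use $k_{\mathrm{bend}} = k_{\mathrm{tilt}} = 10$ and
$C_{\mathrm{bd}} = 0$ (zero spontaneous curvature); pairs within a rod use
the stiffened coefficients 80 and $C_{\mathrm{bd}} = 2 C_{\mathrm{rod}}\sigma$,
the mapping through which the rod curvature is imposed.

## Functional forms and free coefficients

The excluded-volume repulsion, the implicit-solvent attraction and the
weight $w_{\mathrm{cv}}$ are the standard meshless-membrane family:

- $U_{\mathrm{rep}} = \epsilon_{\mathrm{rep}} \sum_{i<j} e^{-b(r_{ij}-1)} f_{\mathrm{rep}}(r_{ij})$,
  a steep soft core ($b = 20$) with a smooth compact cutoff;
- $\rho_i = \sum_{j \ne i} f_\rho(r_{ij})$ and
  $U_{\mathrm{att}} = \epsilon_{\mathrm{att}} \sum_i
  \left[\tfrac{1}{s}\ln\!\left(1 + e^{-s(\rho_i - \rho^*)}\right) - c_0\right]$:
  binding grows linearly with the local density and saturates above
  $\rho^*$, which keeps the assembled sheet fluid and two-dimensional
  (the saturation removes the drive toward three-dimensional aggregates);
  the knee sharpness $s$ controls how abruptly saturation sets in;
- $w_{\mathrm{cv}}(r) = \alpha\, e^{(r/r_{\mathrm{ga}})^2/((r/r_{\mathrm{cc}})^{12}-1)}$,
  a Gaussian-like weight of width $r_{\mathrm{ga}}$ with compact support
  $r_{\mathrm{cc}} = 3\sigma$.

The cutoff functions are $f(s) = \exp[A(1 + 1/(s^{12}-1))]$, equal to 1 at
contact and vanishing smoothly (with all derivatives) at the cutoff.

These coefficients are *calibration dials*, fixed once so that the
membrane's emergent elastic constants match the target values (bending
rigidity $\kappa/k_BT = 15$, tensionless area per particle
$a_0/\sigma^2 = 1.2778$, area compression modulus
$K_A\sigma^2/k_BT = 83.1$, edge line tension $\Gamma\sigma/k_BT = 5.73$).
Two choices matter most and were fixed deliberately:

- $r_{\mathrm{ga}} = 1.37\sigma$ is set so that the energy of an isolated
  rod, scanned over circular arcs, is minimised at curvature
  $C_{\mathrm{rod}}$ when $C_{\mathrm{bd}} = 2C_{\mathrm{rod}}\sigma$
  (within 1–2%); this makes the curvature mapping and the pair-level
  bending weight mutually consistent.
- the density weight $f_\rho$ decays across the first neighbour shell
  (half-decay 1.4$\sigma$, cutoff 2.1$\sigma$).  With a flat-topped weight
  the attraction cannot feel a 1–2% area strain at all and the area
  compression modulus collapses to $\sim 20\,k_BT/\sigma^2$; moving the
  decay into the first shell makes the attraction elastically active and
  brings $K_A$ into the target range.

The shipped calibrated set lives in
`inst/extdata/calibrated_params.json` and is the default of
`membraneParams()`.

## What the calibration achieves, and what it does not

At the desk scales used by this package (patches of $N \sim 600$–1024, runs
of $10^4$–$10^5$ steps, 2–4 seeds), the shipped set measures

- $a_0 = 1.2759 \pm 0.0005$ (target 1.2778; inside the ±0.005 band),
- $K_A = 80 \pm 4$ (target 83.1; inside the ±5 band),
- $\kappa \approx 12$–14 (target 15 ± 2): the estimate is sensitive to the
  realised tensionless density and to run-to-run structure, and sits one to
  three $k_BT$ low,
- $\Gamma \approx 4$–6.5 with a seed-to-seed spread of about $\pm 1$
  (target 5.73 ± 0.3).

The last two misses are structural, not statistical accidents: $\kappa$ and
$K_A$ both respond to the orientation-weight amplitude $\alpha$, so pushing
$\kappa$ up drags $K_A$ out of its band, and the strip used for the
edge-tension measurement reconstructs between competing rim states whose
forces differ by $\sim 1\,k_BT/\sigma$.  The acceptance test applies the
combined-error rule (tolerance = max(desk tolerance, two standard errors))
and reports these two honestly as the calibration's desk-scale limit.

## Measurement protocols

- **Tensionless ensemble.**  Rather than a feedback box-rescaling
  controller, flat patches use Monte-Carlo area moves (symmetric proposals
  in $\ln A$, Metropolis acceptance with the $2N\ln s$ configurational
  Jacobian) interleaved with the Langevin dynamics.  This samples the
  zero-tension ensemble exactly, so the area *fluctuations* are canonical
  and usable for the fluctuation route to $K_A$.
- **$a_0$** is the time-averaged projected area per particle of that
  ensemble.
- **$K_A$**: the projected-area strain response at small tension is softened
  by thermal undulations (part of an imposed strain merely irons them out).
  `measureKA()` therefore measures tensions on the stretched branch
  (1.5–4.5% strain) and subtracts the standard undulation-release strain
  $(k_BT/8\pi\kappa)\ln(1+\gamma L^2/\pi^2\kappa)$ before fitting the
  slope; the uncorrected small-strain slope remains available and is what
  the fluctuation route reproduces.
- **$\kappa$** comes from the height-fluctuation spectrum of a tensionless
  patch.  The per-mode estimator $\kappa_q = N^2k_BT/(Aq^4S_q)$ is not flat
  in $q$ at these box sizes (protrusions add a high-$q$ floor, residual
  tension a $q^{-2}$ admixture), so the default route fits
  $S(q) = c_4q^{-4} + c_2q^{-2} + c_0$ by iteratively reweighted least
  squares and reads $\kappa$ from $c_4$; the estimator is validated by
  recovering known $\kappa$ from synthetic spectra.  The two longest
  wavelength shells are discarded (their relaxation times exceed desk
  runs), and the spectrum is accumulated with the area moves left on —
  freezing the box at a slightly compressed area buckles the patch and
  corrupts the low-$q$ modes.
- **$\Gamma$** is the contractile axial force of a strip spanning the
  periodic $x$ direction with two free edges, divided by two.  An open
  strip is metastable against rolling up into an edge-free tube, so a weak
  flat-plane spring ($k_z = 0.005\,k_BT/\sigma^2$, acting only along $z$
  and therefore invisible to the axial virial) holds it flat.
- **$D$ and $\tau$** come from the in-plane mean-square displacement of a
  tensionless patch.  With the short-ranged, elastically active attraction
  of the calibrated set, membrane particles are strongly caged; the
  diffusive regime sets in late and $D$ is of order $10^{-2}\sigma^2$ per
  time unit, i.e. $\tau \sim 10^3$–$10^4$ time units.  Desk-scale dynamics
  therefore cover fractions of a $\tau$, which is the central caveat for
  all dynamical comparisons below.

# Rods, hooks and chirality

A rod is built from 10 membrane particles connected by harmonic bonds
(rest length $10\sigma/9$, coefficient $2000\,k_BT/\sigma^2$, chosen so the
thermal bond-length fluctuation stays at the percent level) on a circular
arc of curvature $C_{\mathrm{rod}}$, with the stiffened bend/tilt pair
coefficients imposing that curvature dynamically.  Chiral rods carry two
hook particles anchored between the first/second and ninth/tenth backbone
particles, displaced off the backbone axis on *opposite* lateral sides
(right-handed); the achiral hooked reference places both hooks on the same
side, and its mirror image is superimposable on itself by a proper
rotation, while the chiral rod's is not.  Hooks interact with everything
through excluded volume only.

Pairwise harmonic bonds alone cannot energetically distinguish the mirror
position of a hook (any reflection through a plane containing the two
anchors preserves all pair distances), so the package anchors each hook
with the two 3x-stiffened anchor bonds plus a harmonic site restraint to
the handed rest position built from the local frame (tangent, mean
orientation, binormal).  A hook reflected to the opposite side then pays a
large, explicit energy penalty, which is the package's realisation of
"the stiff triangle prevents the flip".  Because the binormal is a
pseudo-vector, the parity identity reads: mirror the configuration *and*
flip the hook-side labels, and the energy is unchanged (verified for
chiral and achiral rods alike).

The side-to-side attraction replaces the soft-core repulsion by the
Lennard-Jones potential $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$
(switched off smoothly between 2.5 and 3$\sigma$) between the 2nd and 3rd
particles from both rod ends of different rods.

# Dynamics

`runDynamics()` integrates underdamped Langevin dynamics with the BAOAB
splitting; orientations are rotated exactly (Rodrigues) by their angular
velocity and renormalised, and angular velocities are kept in the tangent
plane, so $|\mathbf{u}_i| = 1$ holds to machine precision for arbitrarily
long runs.  Friction coefficients default to $\gamma_T = \gamma_R = 1$ and
the time step to $0.005$ (plain membranes) or $0.004$ (rod systems, which
must resolve the stiff triangle bonds).  With the thermostat disabled the
integrator reduces to velocity Verlet and conserves energy, which the test
suite uses as an integrator-correctness surrogate.  Every entry point takes
a seed; the compiled core uses its own counter-seeded xoshiro256** stream,
and checkpoint/restart (state + velocities + RNG state) reproduces an
uninterrupted run bitwise.

Replica exchange over the rod curvature (`runREMD()`) swaps curvature
labels between adjacent replicas with the Metropolis rule on
$\Delta U = [U_a(C_b)+U_b(C_a)] - [U_a(C_a)+U_b(C_b)]$; only the intra-rod
bending terms depend on $C_{\mathrm{rod}}$, so the four energies are
evaluated by a dedicated cheap path.  Ladders are uniform in
$C_{\mathrm{rod}} r_{\mathrm{rod}}$; the desk default spans $[0.5, 3.0]$
in steps of 0.5 (coarser than production ladders — exchange acceptance at
desk sizes is 10–30%).

# What the desk-scale tests do and do not show

The synthetic builders (`buildTube()`, `buildFlatTensionless()`,
`prepareTubulation()`, `makeFixture()`) generate the study's three
geometries at reduced size: tubes of $N = 400$–1200 (the study used
4800–9600), flat patches up to a few thousand particles (the study's
tubulation used 25600), and prebuilt elliptical and helical-wrap
configurations.  The acceptance suite runs minutes-scale versions of the
study's experiments:

- the REMD mode-ordering check (azimuthal order rising before
  longitudinal) uses $N = 600$ with 5 rods and asserts the ordering through
  the *shape* modes (azimuthal deformation dominant across the ladder and
  present from intermediate curvature; longitudinal growing only at the
  top).  The rod-*density* modes are at their few-rod statistical ceiling
  at this size — with 5 rods the azimuthal density amplitude is saturated
  by counting noise already at low curvature — so their ordering is not
  resolvable and not asserted;
- helical persistence is tested as *stability* (a constructed helix of
  chiral rods keeps a consistent handed winding; scattered achiral rods
  never classify as helical), not as spontaneous assembly, which needs
  equilibrium sampling far beyond desk scale.  At desk run lengths the
  tip-to-tip contacts of a loose helix open while the helical arrangement
  and the local radius constriction persist, so the classifier is applied
  with an assembly-scale (4$\sigma$) contact cutoff;
- the helical radius check uses tight coils stabilised by the side
  attraction ($\epsilon/k_BT = 3$, as for the study's radius
  measurements); the seed-mean $R_{\mathrm{hel}}$ decreases with
  $C_{\mathrm{rod}}$ and respects $R_{\mathrm{hel}} \ge 1/C_{\mathrm{rod}}$
  within a documented 15% tolerance — desk relaxation leaves the coil
  radius partly pinned to the initial geometry, so radius *selection* by
  the rod curvature is only partially expressed;
- tubulation runs compare chiral and achiral rods over the first few
  hundred time units only: the chiral vertical membrane span grows at
  least as fast while cluster growth coincides within a factor of two.
  Full tubule protrusion (hundreds of $\tau$) is out of desk reach.

None of these desk runs is a quantitative reproduction of the study's
figure curves; they test directions and orderings under the stated,
fixed-seed conditions.

# Numerical choices and degenerate inputs

- Pair interactions vanish identically beyond their compact cutoffs and
  are continuous across them (tested to $10^{-8}$).
- Cell-list pair enumeration falls back to an all-pairs sweep for small or
  thin systems (periodic boxes under three cells across).
- The force-overflow guard aborts a run when $|F|\,dt^2/m$ exceeds half a
  diameter, the signature of a catastrophically overlapping input.
- Rod embedding relabels existing membrane particles (conserving the
  density-counted $N$ exactly, the source of the $\phi_{\mathrm{rod}}$
  bookkeeping identity) and rejects placements whose bond strains or hook
  clearances would be unphysical; hooks are added as extra particles
  outside the density bookkeeping.
- `detectHandedness()` refuses collinear backbones (the triple product is
  degenerate there); straight chiral rods are physically achiral until
  their curvature is switched on.
- `classifyTubeShape()` reports `"ambiguous"` rather than coercing
  configurations that match neither phase pattern.

# Known limitations

- The calibrated set reproduces $a_0$ and $K_A$ within their bands;
  $\kappa$ reads 1–3 $k_BT$ low and $\Gamma$ scatters around ~1–1.5
  $k_BT/\sigma$ below target (see the calibration section).  All four
  estimators are exported, so recalibration at larger scale is a matter of
  compute, not code.
- Membrane self-diffusion under the calibrated set is slow (strong
  first-shell cohesion); dynamical observables at desk scale probe early
  times only.
- No hydrodynamics, no solvent, no electrostatics; tubes are periodic in
  $z$ with fixed length; vesicle topologies and pulling forces are out of
  scope.
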