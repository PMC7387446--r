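---
title: "Models and methods: patchy-protein 2D lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: patchy-protein 2D lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchylat)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
conventions, and what the tests do and do not establish.

## The system

The building block is a C4-symmetric protein tetramer (~7 nm across,
~4.5 nm tall) with strongly anisotropic surface charge: a flat, negatively
charged C-terminal top face and a four-legged, positively charged
N-terminal bottom face. The asymmetry produces a macrodipole of roughly
1200 D along the symmetry axis. Corner cysteines form reversible
disulfide bonds with neighbours, so the protein crystallizes into square
2D lattices that behave as corner-hinged rotating squares: the lattice
opens and closes by correlated counter-rotations (auxetic, Poisson ratio
−1). Two plane-group symmetries compete: *p*42₁2, in which neighbours
alternate up/down in a checkerboard (nonpolar), and *p*4, in which all
molecules point the same way (polar). The package quantifies the
interactions that select between them and the bulk properties that follow.

## Simulated AFM topographs

The tip is a rigid sphere of radius $R$ whose center $z_\mathrm{tip}$
terminates a truncated cone of half-angle $\psi$; the cone flank is
tangent to the sphere, so the tangency circle sits at
$z_\mathrm{tip} + R\sin\psi$ with radius $R\cos\psi$. At each raster node
the recorded height is the smallest $z_\mathrm{tip}$ for which at most
$k$ heavy atoms lie strictly inside the tip volume, minus $R$, floored at
the support plane $z = 0$.

Instead of raising the tip in small steps, the first-contact
$z_\mathrm{tip}$ is solved in closed form per atom at lateral offset
$\rho$ and height $h$:

* sphere flank ($\rho < R$): $h + \sqrt{R^2 - \rho^2}$;
* cone flank ($\rho \ge R$):
  $h - R\sin\psi - (\rho - R\cos\psi)/\tan\psi$, reachable only when
  $R\sin\psi + (\rho - R\cos\psi)/\tan\psi < z_\mathrm{cutoff}$
  (otherwise the atom passes above the truncated cone).

This removes an otherwise arbitrary z-step size; the result is the exact
limit of the raise-until-clear procedure. Tangency does not count as
overlap (strict interior), which makes the infimum itself attainable.
Atoms are points by default — per-atom radii may be supplied, which
simply inflate $R$ for that atom, since the offset body of a
sphere-plus-tangent-cone is again a sphere-plus-tangent-cone.

Two independent implementations exist: `scan_topograph()` works per node
(assembling, for thresholds $k > 0$, the per-atom overlap intervals in
$z_\mathrm{tip}$ and taking the first clearance with count $\le k$), and
`dilation_oracle()` works per atom, accumulating the pointwise maximum of
reflected-tip structuring elements — the morphological formulation of tip
convolution. The two agree to below $10^{-9}$ Å on randomized scenes, and
a third check probes `tip_overlap_count()` just above and below each
recorded contact.

Defaults: $R = 10$ Å, $\psi = 20°$, grid step 0.5 Å. The truncation
height is not a published quantity; the default $z_\mathrm{cutoff} =
60$ Å is simply taller than any single-layer scene, so it only matters
for scenes taller than that. The overlap threshold (there to forgive
flexible surface loops in experimental comparisons) likewise has no
published value; it defaults to 0 (hard contact).

The coordinate convention throughout is right-handed with the support at
$z = 0$ and the sample above it. `ground_structure()` establishes this
frame: all-atom centroid at $x = y = 0$ and the minimum C$\alpha$ height
at zero (for models without C$\alpha$ atoms, e.g. the synthetic particle,
the all-atom minimum is used and recorded in the `frame_note`).

## The screened pair potential

Two spherical particles (net charge $q$, central point dipole $\mu$,
radius $a$) in an electrolyte interact through a Debye–Hückel-level
potential with three terms — charge–charge, charge–dipole, dipole–dipole
— each screened by $e^{-\kappa r}$ and corrected for finite particle size
by the boundary factors

$$C_0 = \frac{e^{\kappa a}}{1 + \kappa a}, \qquad
C_1 = \frac{3 e^{\kappa a}}{2 + 2\kappa a + (\kappa a)^2 +
      (1 + \kappa a)/\varepsilon}.$$

In a disulfide-bonded 2D lattice both dipoles are forced normal to the
lattice plane, so $\theta_i = \theta_j = 90°$ exactly and only the
$\sin\theta_i \sin\theta_j \cos\Delta\varphi$ part of the dipolar term
survives:

$$U(r, \Delta\varphi) = k_e \frac{q^2}{r} e^{-\kappa r} C_0^2
  + k_e \frac{\mu^2}{r^3} \cos\Delta\varphi\, (1 + \kappa r)
    e^{-\kappa r} C_1^2 .$$

Parallel neighbours ($\Delta\varphi = 0$, *p*4) are dipole-repulsive;
antiparallel neighbours ($\Delta\varphi = 180°$, *p*42₁2) are
dipole-attractive. The charge term is identical in both and cancels in
the difference. Under the study conditions ($q = -16\,e$, $\mu = 1200$ D,
$a = 4.0$ nm, $\varepsilon = 78$, $\kappa^{-1} = 2.1508$ nm) the
preference is

```{r}
particle <- patchy_particle(-16, 1200, 4.0)
solvent <- electrolyte(78, 300, 0.020)
pair_energy_reduced(c(7, 10), 0, particle, solvent) -
  pair_energy_reduced(c(7, 10), 180, particle, solvent)
```

kcal/mol at the closed- and open-lattice neighbour spacings, a smooth
funnel over intermediate dihedrals (`dihedral_landscape()`).

Parameter notes:

* $\kappa$ is derived from the ionic strength assuming a symmetric 1:1
  electrolyte at the electrolyte's temperature,
  $\kappa = \sqrt{2 e^2 N_A \cdot 10^3 I / (\varepsilon_0 \varepsilon
  k_B T)}$; 20 mM at 300 K and $\varepsilon = 78$ gives
  $\kappa^{-1} = 2.1508$ nm. The temperature behind that printed length
  is not stated anywhere we could find; 300 K reproduces it and is the
  package default. $\kappa$ may also be pinned directly.
* Energies are computed in joules per pair and reported per mole
  (kcal/mol, $\times N_A$) or in $k_BT$ at the electrolyte temperature
  ($1\,k_BT = 0.59616$ kcal/mol at 300 K). Constants are CODATA;
  $1\,\mathrm{D} = 3.33564\times10^{-30}$ C·m.
* Degree arguments go through `cospi`/`sinpi`, so right angles are exact:
  the full-to-reduced identity at $\theta = 90°$ holds to ~$10^{-16}$
  relative error rather than leaking an $O(10^{-17})$ cosine residue into
  the charge–dipole term.
* The first dipolar bracket is implemented as
  $\cos\theta_i\cos\theta_j$ — the symmetric form required by $i
  \leftrightarrow j$ exchange — resolving a doubled $\cos\theta_j$ typo
  in the printed equation.
* For mixed pairs the boundary factors combine geometrically
  ($\sqrt{C_{0,i}C_{0,j}}$); identical particles, the only case used
  here, are unaffected.

## Lattice geometry and energy sums

`conformation_geometry()` implements the rotating-squares relations
$d = L(\cos\theta + \sin\theta)$, $A = d^2$,
$A/A_0 = (\cos\theta+\sin\theta)^2 \in [1, 2]$ for opening angle
$\theta \in [0°, 45°]$. The hinge angle $\alpha$ often quoted for such
lattices is exposed as a configurable alias, default $\alpha = 2\theta$
(the angle between adjacent square edges at a hinge); the mapping is an
alias only and carries no physics, since all derived quantities are
functions of $\theta$.

`generate_sites()` lays out the square site grid with alternating
$\pm\theta$ in-plane rotations and the symmetry's dipole-sign pattern;
`lattice_energy_per_monomer()` sums the reduced potential over site pairs
within a cutoff (default: nearest neighbours only), either halved per
monomer over the whole patch or, with `site =`, as the full interaction
energy of one chosen monomer. For an interior monomer under
nearest-neighbour truncation the *p*4 − *p*42₁2 difference is exactly
four times the pairwise difference (diagonal neighbours share a sign in
both symmetries and cancel; so does the charge term):

```{r}
symmetry_preference_curve(c(7, 8, 9, 10), particle, solvent)
```

We report this amplification as the full $\Delta E(d)$ curve rather than
a single number: the spacing at which a literature value like
"4.2 kcal/mol" was read off is not recoverable, whereas the curve's
endpoints are pinned by the verified pairwise values. Charge–charge
contributions are included in absolute lattice energies (they matter for
totals) and cancel identically in symmetry differences.

## Electret and piezoelectric response

A *p*4 lattice is an electret: one permanent dipole $\mu$ per cell of
area $A$, all aligned. Treated as a uniform dipole sheet in a medium of
permittivity $\varepsilon$, the potential step across it is

$$\Delta V = \mathrm{sign} \cdot \frac{\mu/A}{\varepsilon_0 \varepsilon},$$

independent of slab thickness. The package's sign convention: the dipole
vector points from the negative C-terminal face to the positive
N-terminal face, and `sign = -1` (the default) corresponds to
N-terminus-up lattices, giving $\Delta V = -57.96$ mV for the open state
($\mu = 1200$ D, $A = (10\ \mathrm{nm})^2$, $\varepsilon = 78$). The
checkerboard *p*42₁2 pattern has equal up/down densities and nets zero
(`lattice_membrane_voltage()`).

The polarization density $\rho_\mu = \mu/(A t)$ does depend on the slab
thickness $t$; the two quantities are reported separately and never
conflated. The default $t = 4.5$ nm is the approximate monomer height
(half the 9.5-nm tail-to-tail dimer); with it, sweeping the conformation
from closed to open spans $\rho_\mu \approx 0.018$–$0.009$ C·m⁻². $t$ is
a convention, exposed as a parameter, not a derived quantity.
`piezo_curve()` couples $\Delta V$ and $\rho_\mu$ to the rotating-squares
coordinate — the analytic piezoelectric response — and `bound_charge()`
converts $\rho_\mu$ over a patch area into the accumulated bound charge
in elementary charges.

Published all-atom simulations of such lattices report steady-state
membrane potentials of $-56.09 \pm 5.71$ mV (*p*4) and $-3.09 \pm 5.85$
mV (*p*42₁2), bracketing these analytic predictions within one standard
deviation. Those simulations are far outside desk scale; the numbers are
quoted here as a consistency note only and are computed nowhere in this
package.

## Adsorption null model

Second-layer growth on a crystalline monolayer proceeds monomer by
monomer. Under the null hypothesis of unbiased random adsorption, each
site is occupied independently with probability $\theta$, and the
expected coverage of *isolated* monomers (no occupied neighbour) is
$\theta(1-\theta)^z$ with $z = 4$ for the von Neumann neighbourhood —
the default, matching the four lateral bonding partners of a site. At
$\theta = 0.23$ this is 8.1%; an observed isolated coverage of 0.35%
is ~23-fold lower, evidence of cooperative, bond-mediated attachment.
(An often-quoted expected value of 7% at the same coverage stems from a
formula not spelled out in the source; the package reports the
independent-occupancy closed form and its Monte Carlo estimate and
asserts neither literature number.) Boundaries default to free edges with
edge-aware neighbour counts; the toroidal option makes every site's
neighbourhood exactly $z$ and is used for closed-form comparisons.

## The synthetic particle

`make_synthetic_particle()` builds the test stand-in for the protein: a
point-atom model with a flat square top plate at $z = $ height and four
legs descending to $z = 0$, exactly C4-symmetric, with the top and bottom
charges placed at the two face planes so the macrodipole is exact hand
arithmetic. Defaults (height 45 Å, top width 30 Å, legs 15 Å at ±10 Å,
charges ∓8 e) emulate the protein's dimensions, topography (central dip
between the legs, the feature AFM resolves) and dipole scale (1729 D,
the right order against ~1200 D). It is deterministic; the `seed`
argument exists only for interface symmetry. What it does *not* emulate:
atomic surface roughness, side-chain flexibility, solvation, or a
realistic charge distribution — so tests passing on it validate the
geometry and electrostatics machinery, not force-field-level realism on
real structures. For real proteins, `assign_formal_charges()` provides
the integer pH-7 scheme (Asp/Glu −1, Lys/Arg +1, His 0, charged termini)
at side-chain charge-center atoms; macrodipoles so obtained are
order-of-magnitude estimates, not substitutes for force-field charges on
equilibrated coordinates.

## Numerical choices and degenerate inputs

* Strict-interior overlap everywhere; tangency never counts.
* Heights are floored at the impenetrable support plane $z = 0$.
* Grid nodes include both window edges when commensurate with the step.
* Empty scan scenes warn and return an all-zero map; empty atom
  collections, non-positive dimensions, out-of-range angles, unknown CLI
  keys, and missing charges raise errors rather than guessing.
* `macrodipole()` sums about the $|q|$-weighted charge centroid, which is
  origin-independent for net-neutral charge sets; hydrogens are excluded.
* Lattice energy cutoffs must be at least the lattice spacing; the
  default (1.05 d) selects nearest neighbours only.
* Problem sizes in the test suite (30 × 30 Å scan windows at 0.5 Å, up to
  50 atoms, 100 scenes; 200 × 200 occupancy grids, 100 replicates; 1000
  random parameter draws) were chosen as the smallest sizes at which the
  checked statistics are stable.

## Known limitations

* No Poisson–Boltzmann or higher-multipole electrostatics; the particle
  is a sphere with a central point dipole, and image charges near the
  support are neglected.
* No elastic deformation of the sample under the tip, and no modelling of
  tip dynamics — the scanner is hard-contact geometry.
* No kinetics anywhere: lattice selection is argued thermodynamically,
  and the adsorption model is a static null, not a deposition simulation.
* The mica template, protonation-state prediction, and all molecular
  dynamics are out of scope; where published MD values are mentioned they
  are labels on the analytic results, not computations.
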