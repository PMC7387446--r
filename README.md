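# patchylat

Tools for modelling how a patchy, C4-symmetric protein building block — a
tetramer with a flat, negatively charged top face and a four-legged,
positively charged bottom face — self-assembles into two-dimensional
crystals, and what those crystals do once assembled. The package is aimed
at people studying 2D protein or nanoparticle self-assembly with AFM who
want to (i) simulate topographs of candidate atomic models for comparison
with experiment, (ii) reason quantitatively about the long-range
electrostatics that select between lattice symmetries, and (iii) predict
the electret/piezoelectric behaviour of polar lattices.

## What it computes

**Simulated AFM topographs.** The probe is a rigid sphere of radius *R*
(default 10 Å) whose center sits at the end of a cone of half-angle ψ
(default 20°), truncated at *z*_cutoff. At each raster node (Δx = Δy =
0.5 Å) the recorded height is the lowest tip position with no heavy-atom
overlap, minus *R* — a grayscale dilation of the point set by the
reflected tip, which reproduces tip-convolution artifacts. The contact
search is solved in closed form per atom, and an independent
dilation-oracle implementation verifies the scanner exactly.

**Screened pair potential.** Two particles with net charge *q*, point
dipole *μ* and radius *a* in an electrolyte of permittivity ε and inverse
Debye length κ interact through the screened charge/dipole potential

    U(r, θi, θj, Δφ) = ke q² e^{−κr} C0²/r
      + ke (q μ)(cos θi + cos θj) e^{−κr} C0 C1 / r²
      + ke μ²/r³ [cos θi cos θj (2 + κr + (κr)²)
                  + sin θi sin θj cos Δφ (1 + κr)] e^{−κr} C1²

with ke = (4πε0ε)⁻¹, C0 = e^{κa}/(1+κa) and
C1 = 3e^{κa}/(2 + 2κa + (κa)² + (1+κa)/ε). In a bonded 2D lattice both
dipoles are normal to the plane (θ = 90°), leaving a reduced form whose
dipolar term is repulsive for parallel (Δφ = 0°, plane group *p*4) and
attractive for antiparallel (Δφ = 180°, *p*42₁2) neighbours — the
thermodynamic origin of antiparallel packing in solution-grown crystals.

**Rotating-squares lattices.** Corner-hinged rigid squares of edge *L*
counter-rotated by ±θ give spacing d = L(cos θ + sin θ) and relative cell
area (cos θ + sin θ)² ∈ [1, 2] (auxetic, Poisson ratio −1). Site
generators produce the *p*4 (all dipoles up) and *p*42₁2 (checkerboard)
patterns, and lattice energy sums quantify the symmetry preference.

**Electret / piezoelectric response.** A polar (*p*4) lattice is a sheet
of aligned dipoles: ΔV = ±(μ/A)/(ε0 ε) across the membrane, and
polarization density ρ_μ = μ/(A·t) through a slab of thickness *t*.
Coupling ΔV to the rotating-squares conformation gives the piezoelectric
voltage–strain curve; checkerboard lattices cancel to zero.

**Adsorption null model.** Independent random occupancy of lattice sites,
the closed-form isolated-monomer coverage θ(1−θ)⁴, its Monte Carlo
counterpart, and the expected/observed isolation ratio used to detect
cooperative (bond-mediated) attachment.

## Worked example

```r
library(patchylat)

particle <- patchy_particle(charge = -16, dipole = 1200, radius = 4.0)
solvent  <- electrolyte(78, 300, 0.020)   # water, 300 K, 20 mM 1:1 ions
solvent
#> <electrolyte> eps = 78, T = 300 K, I = 0.02 M, kappa = 0.464935 /nm
#>   (Debye length 2.1508 nm)

# antiparallel preference of one neighbour pair, kcal/mol
pair_energy_reduced(c(7, 10), 0, particle, solvent) -
  pair_energy_reduced(c(7, 10), 180, particle, solvent)
#> [1] 1.112 0.126

# amplified fourfold for an interior monomer by its nearest neighbours
symmetry_preference_curve(c(7, 8, 9, 10), particle, solvent)
#>    d   dE_kcal    dE_kBT
#> 1  7 4.4490558 7.4628392
#> 2  8 2.0768947 3.4837800
#> 3  9 1.0065700 1.6884189
#> 4 10 0.5022867 0.8425349

# electret voltage of the open-state polar lattice (10 x 10 nm cell)
membrane_voltage(1200, 100)
#> [1] -57.96

# piezoelectric coupling along the rotating-squares coordinate
piezo_curve(7.0711, c(0, 15, 30, 45))
#>   theta hinge_angle      d     A area_ratio   rho_mu   dV_mV
#> 1     0           0  7.071  50.0      1.000 0.017790 -115.92
#> 2    15          30  8.660  75.0      1.500 0.011860  -77.28
#> 3    30          60  9.659  93.3      1.866 0.009534  -62.12
#> 4    45          90 10.000 100.0      2.000 0.008895  -57.96

# random-adsorption null for isolated second-layer monomers at 23% coverage
adsorption_summary(0.23, n = 200, reps = 100, seed = 7, observed = 0.0035)
#>   theta expected_closed_form simulated_mean simulated_se ratio_expected_to_observed
#> 1  0.23           0.08085199      0.0814215 0.0001455103                   23.10057
```

The pairwise preference of 1.11 kcal/mol at 7 nm shrinking to 0.13 kcal/mol
at 10 nm, its roughly fourfold nearest-neighbour amplification, the
−57.96 mV open-state voltage rising beyond −100 mV under compression, the
0.009–0.018 C·m⁻² polarization range, and the ~23-fold excess of expected
over observed isolated monomers are the quantities the package exists to
produce.

A simulated topograph of the bundled synthetic particle:

```r
p <- ground_structure(make_synthetic_particle())
hm <- scan_topograph(p, tip_model(), scan_grid(-30, 30, -30, 30, 0.5))
plot(hm)
write_heightmap(hm, "topograph.txt", "ascii-matrix")  # SPM-importable
```

A command-line interface wrapping the same functions ships at
`inst/cli/patchylat` (subcommands: ground, dipole, synth, tile, scan,
pair, landscape, lattice, electret, piezo, adsorb).

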