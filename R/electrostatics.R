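#' Electrolyte (screened solvent) parameters
#'
#' Describes the solvent as a uniform dielectric with Debye screening from a
#' symmetric 1:1 electrolyte. The inverse screening length kappa is derived
#' from the ionic strength unless supplied directly.
#'
#' @param relative_permittivity Relative solvent permittivity (> 1),
#'   default 78 (water).
#' @param temperature Temperature in kelvin, default 300.
#' @param ionic_strength Ionic strength in mol/L (1:1 electrolyte),
#'   default 0.020 (20 mM).
#' @param kappa Optional inverse screening length in 1/nm; overrides the
#'   value derived from `ionic_strength`.
#' @return An `electrolyte` object with fields `epsilon`, `temperature`,
#'   `ionic_strength`, `kappa` (1/nm).
#' @export
#' @examples
#' 1 / electrolyte()$kappa  # Debye length: 2.1508 nm at 20 mM, 300 K
electrolyte <- function(relative_permittivity = 78, temperature = 300,
                        ionic_strength = 0.020, kappa = NULL) {
  if (!is.finite(relative_permittivity) || relative_permittivity <= 1)
    stop("relative_permittivity must be > 1", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (!is.finite(ionic_strength) || ionic_strength < 0)
    stop("ionic_strength must be >= 0", call. = FALSE)
  obj <- structure(list(epsilon = relative_permittivity,
                        temperature = temperature,
                        ionic_strength = ionic_strength,
                        kappa = NA_real_),
                   class = "electrolyte")
  obj$kappa <- if (is.null(kappa)) debye_kappa(obj) else kappa
  obj
}

#' @export
print.electrolyte <- function(x, ...) {
  cat(sprintf(
    "<electrolyte> eps = %g, T = %g K, I = %g M, kappa = %.6g /nm (Debye length %.4f nm)\n",
    x$epsilon, x$temperature, x$ionic_strength, x$kappa,
    if (x$kappa > 0) 1 / x$kappa else Inf))
  invisible(x)
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(2 e^2 N_A (1000 I) / (eps0 eps k_B T)) for a symmetric 1:1
#' electrolyte of ionic strength I (mol/L). kappa(I = 0) = 0 (unscreened).
#'
#' @param solvent An [electrolyte()] (its stored `kappa` is ignored; the
#'   value is recomputed from eps, T, I).
#' @return kappa in 1/nm.
#' @export
#' @examples
#' 1 / debye_kappa(electrolyte(78, 300, 0.020))  # 2.1508 nm
debye_kappa <- function(solvent) {
  stopifnot(inherits(solvent, "electrolyte"))
  I <- solvent$ionic_strength
  if (I == 0) return(0)
  k_m <- sqrt(2 * .const$e_C^2 * .const$N_A * (1000 * I) /
                (.const$eps0_F_m * solvent$epsilon * .const$k_B *
                   solvent$temperature))
  k_m * .const$nm_m   # 1/m -> 1/nm
}

#' Patchy charged-dipolar nanoparticle model
#'
#' The coarse particle behind the screened pair potential: a sphere of
#' radius `a` carrying a net charge `q` and a point dipole `mu` at its
#' center.
#'
#' @param charge Net charge q in elementary charges (default -16).
#' @param dipole Dipole moment mu in debye (default 1200).
#' @param radius Particle radius a in nm (default 4.0, the equivalent-area
#'   disc radius of the building block).
#' @return A `patchy_particle` object.
#' @export
patchy_particle <- function(charge = -16, dipole = 1200, radius = 4.0) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0",
                                              call. = FALSE)
  if (!is.finite(dipole) || dipole < 0) stop("dipole must be >= 0",
                                             call. = FALSE)
  .stopifnot_finite(charge, "charge")
  structure(list(charge = charge, dipole = dipole, radius = radius),
            class = "patchy_particle")
}

#' @export
print.patchy_particle <- function(x, ...) {
  cat(sprintf("<patchy_particle> q = %g e, mu = %g D, a = %g nm\n",
              x$charge, x$dipole, x$radius))
  invisible(x)
}

#' Finite-size boundary factors C0 and C1
#'
#' The screened-potential boundary factors for a sphere of radius a in an
#' electrolyte with inverse screening length kappa:
#' C0 = exp(kappa a) / (1 + kappa a) and
#' C1 = 3 exp(kappa a) / (2 + 2 kappa a + (kappa a)^2 + (1 + kappa a)/eps).
#'
#' @param solvent An [electrolyte()].
#' @param particle A [patchy_particle()].
#' @return Named numeric vector `c(C0, C1)`.
#' @export
#' @examples
#' geometry_factors(electrolyte(), patchy_particle())  # C0 2.2457, C1 2.0908
geometry_factors <- function(solvent, particle) {
  stopifnot(inherits(solvent, "electrolyte"),
            inherits(particle, "patchy_particle"))
  ka <- solvent$kappa * particle$radius
  C0 <- exp(ka) / (1 + ka)
  C1 <- 3 * exp(ka) / (2 + 2 * ka + ka^2 + (1 + ka) / solvent$epsilon)
  c(C0 = C0, C1 = C1)
}

# core of the pair potential, SI; returns joules per pair.
# r in m, mu in C m, q in C, kappa in 1/m.
.ke <- function(epsilon) 1 / (4 * pi * .const$eps0_F_m * epsilon)

#' Screened pair potential between two charged dipolar particles
#'
#' The full orientation-dependent potential: the sum of a screened
#' charge-charge term, a charge-dipole term and a dipole-dipole term, with
#' finite-size boundary factors C0 and C1 ([geometry_factors()]) and
#' Coulomb constant k_e = 1/(4 pi eps0 eps):
#' \deqn{U = k_e q_i q_j e^{-\kappa r} C_0^2 / r
#'   + k_e (q_i \mu_j \cos\theta_j + q_j \mu_i \cos\theta_i)
#'     e^{-\kappa r} C_0 C_1 / r^2
#'   + k_e \mu_i \mu_j / r^3 \{ \cos\theta_i \cos\theta_j
#'     [2 + \kappa r + (\kappa r)^2]
#'   + \sin\theta_i \sin\theta_j \cos(\Delta\phi) [1 + \kappa r] \}
#'     e^{-\kappa r} C_1^2}
#' Angles: theta_i/theta_j between each dipole axis and the center-center
#' vector; dphi the dihedral between the dipoles about that vector. With
#' both dipoles normal to the line of centers (theta = 90 deg) the
#' expression reduces to [pair_energy_reduced()].
#'
#' @param r Center-center separation(s) in nm (> 0).
#' @param theta_i,theta_j Dipole-axis angles in degrees.
#' @param dphi Azimuthal dihedral angle(s) phi_i - phi_j in degrees.
#' @param particle_i,particle_j [patchy_particle()] objects.
#' @param solvent An [electrolyte()].
#' @param units `"kcal/mol"` (default), `"kBT"` (at the electrolyte
#'   temperature) or `"J"` (joules per pair).
#' @return Energy in the requested units (vectorized over `r`, angles).
#' @export
pair_energy_full <- function(r, theta_i, theta_j, dphi,
                             particle_i, particle_j = particle_i,
                             solvent = electrolyte(),
                             units = c("kcal/mol", "kBT", "J")) {
  units <- match.arg(units)
  .stopifnot_finite(c(r, theta_i, theta_j, dphi), "configuration")
  if (any(r <= 0)) stop("separation r must be > 0", call. = FALSE)
  cf <- geometry_factors(solvent, particle_i)
  cfj <- geometry_factors(solvent, particle_j)
  # C0, C1 depend only on (kappa, a, eps); mixed pairs use the geometric
  # cross combination C0 = sqrt(C0i C0j) etc. (identical particles: same)
  C0 <- sqrt(cf["C0"] * cfj["C0"]); C1 <- sqrt(cf["C1"] * cfj["C1"])
  ke <- .ke(solvent$epsilon)
  r_m <- r * .const$nm_m
  kap <- solvent$kappa / .const$nm_m      # 1/m
  kr <- kap * r_m
  qi <- particle_i$charge * .const$e_C
  qj <- particle_j$charge * .const$e_C
  mi <- particle_i$dipole * .const$debye_Cm
  mj <- particle_j$dipole * .const$debye_Cm
  cti <- .cosd(theta_i); ctj <- .cosd(theta_j)
  sti <- .sind(theta_i); stj <- .sind(theta_j)
  U <- ke * qi * qj / r_m * exp(-kr) * C0^2 +
    ke * (qi * mj * ctj + qj * mi * cti) / r_m^2 * exp(-kr) * C0 * C1 +
    ke * mi * mj / r_m^3 *
      (cti * ctj * (2 + kr + kr^2) +
         sti * stj * .cosd(dphi) * (1 + kr)) * exp(-kr) * C1^2
  .report_energy(unname(U), units, solvent)
}

#' Reduced in-plane pair potential (dipoles normal to the lattice)
#'
#' The lattice-constrained form of [pair_energy_full()] with both dipoles
#' perpendicular to the line of centers (theta = 90 deg), as imposed by
#' lateral bonding within a 2D crystal plane:
#' \deqn{U = k_e q^2 e^{-\kappa r} C_0^2 / r
#'   + k_e \mu^2 \cos(\Delta\phi) (1 + \kappa r) e^{-\kappa r} C_1^2 / r^3}
#' dphi = 0 corresponds to parallel dipoles (polar p4 packing, repulsive
#' dipolar term) and dphi = 180 to antiparallel dipoles (p42_1 2 packing,
#' attractive dipolar term).
#'
#' @param r Separation(s) in nm (> 0).
#' @param dphi Dihedral angle(s) in degrees.
#' @param particle A [patchy_particle()].
#' @param solvent An [electrolyte()].
#' @param units `"kcal/mol"` (default), `"kBT"` or `"J"`.
#' @return Energy, vectorized over `r` and `dphi`.
#' @export
#' @examples
#' # parallel-vs-antiparallel preference at contactable distances
#' pair_energy_reduced(7, 0) - pair_energy_reduced(7, 180)   # 1.11 kcal/mol
#' pair_energy_reduced(10, 0) - pair_energy_reduced(10, 180) # 0.13 kcal/mol
pair_energy_reduced <- function(r, dphi, particle = patchy_particle(),
                                solvent = electrolyte(),
                                units = c("kcal/mol", "kBT", "J")) {
  units <- match.arg(units)
  .stopifnot_finite(c(r, dphi), "configuration")
  if (any(r <= 0)) stop("separation r must be > 0", call. = FALSE)
  cf <- geometry_factors(solvent, particle)
  ke <- .ke(solvent$epsilon)
  r_m <- r * .const$nm_m
  kr <- (solvent$kappa / .const$nm_m) * r_m
  q <- particle$charge * .const$e_C
  mu <- particle$dipole * .const$debye_Cm
  U <- ke * q^2 / r_m * exp(-kr) * cf["C0"]^2 +
    ke * mu^2 / r_m^3 * .cosd(dphi) * (1 + kr) * exp(-kr) * cf["C1"]^2
  .report_energy(unname(U), units, solvent)
}

.report_energy <- function(U_J, units, solvent) {
  switch(units,
         "J" = U_J,
         "kcal/mol" = .J_to_kcalmol(U_J),
         "kBT" = U_J / (.const$k_B * solvent$temperature))
}

#' Distance-dihedral energy landscape
#'
#' Tabulates [pair_energy_reduced()] on an (r, dphi) grid. For every r the
#' energy decreases monotonically in dphi towards the antiparallel minimum
#' at 180 degrees (an energy funnel).
#'
#' @param r_values Separations in nm.
#' @param dphi_values Dihedral angles in degrees.
#' @param particle A [patchy_particle()].
#' @param solvent An [electrolyte()].
#' @return An `energy_landscape`: list with `r`, `dphi`, `energy`
#'   (kcal/mol matrix, rows = r) and `energy_kBT`.
#' @export
dihedral_landscape <- function(r_values, dphi_values,
                               particle = patchy_particle(),
                               solvent = electrolyte()) {
  if (!length(r_values) || !length(dphi_values))
    stop("r and dphi grids must be non-empty", call. = FALSE)
  E <- outer(r_values, dphi_values,
             function(r, p) pair_energy_reduced(r, p, particle, solvent))
  structure(list(r = r_values, dphi = dphi_values, energy = E,
                 energy_kBT = E / .kBT_kcalmol(solvent$temperature),
                 particle = particle, solvent = solvent),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "<energy_landscape> %d r-values x %d dihedral angles; U in [%.4g, %.4g] kcal/mol\n",
    length(x$r), length(x$dphi), min(x$energy), max(x$energy)))
  invisible(x)
}

#' @export
plot.energy_landscape <- function(x, ...) {
  graphics::filled.contour(
    x$r, x$dphi, x$energy,
    xlab = "separation r (nm)",
    ylab = expression(Delta * phi ~ "(degrees)"),
    main = "screened pair energy (kcal/mol)", ...)
  invisible(x)
}

#' Long-format landscape table
#'
#' @param x An `energy_landscape`.
#' @param ... Unused.
#' @return data.frame with columns `r`, `dphi`, `U_kcal`, `U_kBT`.
#' @export
as.data.frame.energy_landscape <- function(x, ...) {
  data.frame(r = rep(x$r, times = length(x$dphi)),
             dphi = rep(x$dphi, each = length(x$r)),
             U_kcal = as.vector(x$energy),
             U_kBT = as.vector(x$energy_kBT))
}
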