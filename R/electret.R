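#' Polarized crystal slab
#'
#' A polar 2D crystal treated as a uniformly polarized dielectric slab: one
#' permanent dipole `mu` per lattice cell of area `A`, distributed through a
#' slab of thickness `t`. The polarization density is rho_mu = mu / (A t).
#'
#' @param dipole Dipole moment per site, debye (default 1200).
#' @param cell_area Per-site cell area A in nm^2 (default 100: the fully
#'   open 10 x 10 nm cell).
#' @param thickness Slab thickness t in nm (default 4.5, approximately the
#'   monomer height: half the 9.5-nm tail-to-tail dimer).
#' @param epsilon Relative permittivity of the surrounding medium
#'   (default 78).
#' @param sign Dipole orientation: -1 (default) for lattices whose dipoles
#'   point away from the support (N-terminal face up), +1 for the reverse.
#'   See [membrane_voltage()] for the convention.
#' @return A `polarized_slab` object.
#' @export
polarized_slab <- function(dipole = 1200, cell_area = 100, thickness = 4.5,
                           epsilon = 78, sign = -1) {
  if (!is.finite(cell_area) || cell_area <= 0)
    stop("cell_area must be > 0", call. = FALSE)
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be > 0", call. = FALSE)
  if (!is.finite(dipole) || dipole < 0) stop("dipole must be >= 0",
                                             call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(dipole = dipole, cell_area = cell_area,
                 thickness = thickness, epsilon = epsilon, sign = sign),
            class = "polarized_slab")
}

#' @export
print.polarized_slab <- function(x, ...) {
  cat(sprintf(
    "<polarized_slab> mu = %g D per %.4g nm^2 cell, t = %g nm, eps = %g: rho_mu = %.4g C/m^2, dV = %.4g mV\n",
    x$dipole, x$cell_area, x$thickness, x$epsilon,
    polarization_density(x),
    membrane_voltage(x$dipole, x$cell_area, x$epsilon, x$sign)))
  invisible(x)
}

#' Polarization density of a polar crystal slab
#'
#' rho_mu = mu / (A t): dipole moment per unit slab volume, in C/m^2.
#'
#' @param slab A [polarized_slab()].
#' @return rho_mu in C/m^2.
#' @export
#' @examples
#' polarization_density(polarized_slab())  # ~0.0089 C/m^2 (open state)
polarization_density <- function(slab) {
  stopifnot(inherits(slab, "polarized_slab"))
  mu_Cm <- slab$dipole * .const$debye_Cm
  vol_m3 <- slab$cell_area * 1e-18 * slab$thickness * .const$nm_m
  mu_Cm / vol_m3
}

#' Analytic membrane voltage across a dipole sheet
#'
#' The potential step across a uniform sheet of surface dipole density
#' mu / A embedded in a medium of relative permittivity eps:
#' dV = sign * (mu / A) / (eps0 eps). Independent of the slab thickness (a
#' pure dipole-layer result), in contrast to the polarization density.
#' With the package's sign convention (dipoles point from the negative
#' C-terminal face to the positive N-terminal face; `sign = -1` for
#' N-terminus-up lattices) the open-state polar lattice gives -57.96 mV.
#' A checkerboard (p42_1 2) lattice has equal up and down site densities
#' and nets zero.
#'
#' @param dipole Dipole moment per site in debye.
#' @param cell_area Per-site cell area A in nm^2.
#' @param epsilon Relative permittivity (default 78).
#' @param sign +1 or -1 orientation factor (default -1: N-terminus up).
#' @return Voltage step in mV (vectorized over `dipole`, `cell_area`).
#' @export
#' @examples
#' membrane_voltage(1200, 100)        # -57.96 mV (open state)
#' membrane_voltage(1200, 7.5595^2)   # beyond -100 mV when compressed
membrane_voltage <- function(dipole, cell_area, epsilon = 78, sign = -1) {
  if (any(!is.finite(cell_area)) || any(cell_area <= 0))
    stop("cell_area must be > 0", call. = FALSE)
  sigma <- dipole * .const$debye_Cm / (cell_area * 1e-18)  # C/m
  sign * sigma / (.const$eps0_F_m * epsilon) * 1e3         # V -> mV
}

#' Piezoelectric voltage-conformation curve
#'
#' Couples the rotating-squares geometry to the electret response: for each
#' opening angle theta the cell area A = d(theta)^2 sets the dipole surface
#' density, hence the polarization density and membrane voltage. |dV|
#' decreases strictly as the lattice opens.
#'
#' @param L Square edge length in nm.
#' @param theta_values Opening angles in degrees, within [0, 45].
#' @param dipole Dipole per site in debye.
#' @param epsilon Relative permittivity.
#' @param thickness Slab thickness in nm (for rho_mu only).
#' @param sign Orientation factor, default -1 (N-terminus up).
#' @return data.frame with columns `theta`, `hinge_angle`, `d`, `A`,
#'   `area_ratio`, `rho_mu`, `dV_mV`.
#' @export
#' @examples
#' piezo_curve(7.0711, c(0, 22.5, 45))
piezo_curve <- function(L, theta_values, dipole = 1200, epsilon = 78,
                        thickness = 4.5, sign = -1) {
  geo <- t(vapply(theta_values, function(th) conformation_geometry(L, th),
                  numeric(3)))
  A <- geo[, "cell_area"]
  rho <- vapply(A, function(a)
    polarization_density(polarized_slab(dipole, a, thickness, epsilon, sign)),
    numeric(1))
  data.frame(theta = theta_values,
             hinge_angle = 2 * theta_values,
             d = geo[, "spacing"],
             A = A,
             area_ratio = geo[, "area_ratio"],
             rho_mu = rho,
             dV_mV = membrane_voltage(dipole, A, epsilon, sign))
}

#' Analytic bound charge of a polarized slab
#'
#' Q = rho_mu x area: the bound surface charge accumulated over `total_area`
#' by a slab of polarization density rho_mu, in elementary charges.
#'
#' @param rho_mu Polarization density in C/m^2.
#' @param total_area Area in nm^2.
#' @return Charge in elementary charges.
#' @export
#' @examples
#' bound_charge(0.016, 400)  # ~40 e over an open-state 2x2 patch
bound_charge <- function(rho_mu, total_area) {
  if (any(!is.finite(rho_mu)) || any(rho_mu < 0))
    stop("rho_mu must be >= 0", call. = FALSE)
  if (any(!is.finite(total_area)) || any(total_area <= 0))
    stop("total_area must be > 0", call. = FALSE)
  rho_mu * total_area * 1e-18 / .const$e_C
}

#' Net membrane voltage of a dipole-pattern lattice
#'
#' Averages the per-site [membrane_voltage()] over a [generate_sites()]
#' pattern: p4 lattices reproduce the single-orientation value, p42_1 2
#' checkerboards cancel to (near) zero for even dimensions.
#'
#' @param sites A [generate_sites()] result.
#' @param dipole Dipole per site in debye.
#' @param epsilon Relative permittivity.
#' @param sign Orientation factor applied to `dipole_sign = +1` sites.
#' @return Net voltage in mV.
#' @export
lattice_membrane_voltage <- function(sites, dipole = 1200, epsilon = 78,
                                     sign = -1) {
  if (!inherits(sites, "lattice_sites"))
    stop("expected 'lattice_sites'", call. = FALSE)
  conf <- attr(sites, "conformation")
  per_site <- membrane_voltage(dipole, conf$cell_area, epsilon, sign)
  mean(sites$dipole_sign) * per_site
}
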