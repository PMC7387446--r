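#' Rotating-squares lattice conformation
#'
#' The auxetic rotating-squares construction: rigid squares of edge L,
#' hinged at their corners, counter-rotate by +-theta. The lattice spacing
#' is d = L (cos theta + sin theta), the unit-cell area A = d^2 and the
#' relative area A/A0 = (cos theta + sin theta)^2, running from 1 (closed,
#' theta = 0) to 2 (fully open, theta = 45 deg); the lattice has Poisson
#' ratio -1 along this coordinate. The `hinge_angle` alias alpha = 2 theta
#' (the angle subtended at a hinge between adjacent square edges, offset
#' configurable via `hinge_alias`) is reported alongside.
#'
#' The `symmetry` field selects the out-of-plane dipole pattern: `"p4"`
#' (all sites up: polar) or `"p4212"` (checkerboard up-down: nonpolar
#' p42_1 2).
#'
#' @param edge_length Square edge L in nm.
#' @param opening_angle theta in degrees, within [0, 45].
#' @param symmetry `"p4"` or `"p4212"`.
#' @param hinge_alias Function mapping theta (deg) to the reported hinge
#'   angle alpha (deg); default `function(theta) 2 * theta`.
#' @return A `lattice_conformation` with derived `spacing` (nm),
#'   `cell_area` (nm^2), `area_ratio` and `hinge_angle` (deg).
#' @export
#' @examples
#' lattice_conformation(7.0711, 45)$spacing  # 10 nm: fully open state
lattice_conformation <- function(edge_length, opening_angle = 45,
                                 symmetry = c("p4", "p4212"),
                                 hinge_alias = function(theta) 2 * theta) {
  symmetry <- match.arg(symmetry)
  if (!is.finite(edge_length) || edge_length <= 0)
    stop("edge_length must be > 0", call. = FALSE)
  geo <- conformation_geometry(edge_length, opening_angle)
  structure(list(edge_length = edge_length, opening_angle = opening_angle,
                 symmetry = symmetry,
                 spacing = geo[["spacing"]],
                 cell_area = geo[["cell_area"]],
                 area_ratio = geo[["area_ratio"]],
                 hinge_angle = hinge_alias(opening_angle)),
            class = "lattice_conformation")
}

#' @export
print.lattice_conformation <- function(x, ...) {
  cat(sprintf(
    "<lattice_conformation> %s: L = %g nm, theta = %g deg (alpha = %g), d = %.4f nm, A = %.4f nm^2 (A/A0 = %.4f)\n",
    x$symmetry, x$edge_length, x$opening_angle, x$hinge_angle,
    x$spacing, x$cell_area, x$area_ratio))
  invisible(x)
}

#' Rotating-squares geometry
#'
#' @param L Square edge in nm.
#' @param theta Opening angle in degrees, within [0, 45].
#' @return Named vector `c(spacing, cell_area, area_ratio)`:
#'   d = L(cos theta + sin theta), A = d^2, A/A0 = (cos theta + sin theta)^2.
#' @export
#' @examples
#' conformation_geometry(7.0711, 0)    # closed: d = L, A/A0 = 1
#' conformation_geometry(7.0711, 45)   # open: d = L sqrt(2), A/A0 = 2
conformation_geometry <- function(L, theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 45))
    stop("opening angle theta must lie in [0, 45] degrees", call. = FALSE)
  d <- L * (.cosd(theta) + .sind(theta))
  c(spacing = d, cell_area = d^2,
    area_ratio = (.cosd(theta) + .sind(theta))^2)
}

#' Generate lattice site positions and dipole pattern
#'
#' Builds the nx x ny square site grid of a conformation: positions at
#' spacing d, alternating +-theta in-plane rotations on a checkerboard, and
#' the out-of-plane dipole sign per site (+1 everywhere for p4; +1/-1
#' checkerboard for p42_1 2).
#'
#' @param conformation A [lattice_conformation()].
#' @param nx,ny Site counts (>= 1).
#' @return A `lattice_sites` data frame with columns `i`, `j`, `x`, `y`
#'   (nm), `rotation` (deg) and `dipole_sign`; the conformation is kept in
#'   the `"conformation"` attribute.
#' @export
#' @examples
#' generate_sites(lattice_conformation(7.0711, 45, "p4212"), 2, 2)$dipole_sign
generate_sites <- function(conformation, nx, ny) {
  if (!inherits(conformation, "lattice_conformation"))
    stop("expected a 'lattice_conformation'", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L)
    stop("nx and ny must be >= 1", call. = FALSE)
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  parity <- (ij$i + ij$j) %% 2L == 0L
  d <- conformation$spacing
  sites <- data.frame(
    i = ij$i, j = ij$j,
    x = (ij$i - 1L) * d, y = (ij$j - 1L) * d,
    rotation = ifelse(parity, conformation$opening_angle,
                      -conformation$opening_angle),
    dipole_sign = if (conformation$symmetry == "p4212")
      ifelse(parity, 1L, -1L) else 1L
  )
  structure(sites, class = c("lattice_sites", "data.frame"),
            conformation = conformation)
}

#' Interaction energy of lattice sites under the reduced pair potential
#'
#' Sums [pair_energy_reduced()] over all site pairs within `cutoff` (each
#' pair's dihedral is 0 deg for equal dipole signs, 180 deg for opposite)
#' and reports the total halved per monomer. With `site` given, returns
#' instead the full (un-halved) interaction energy of that one site with
#' its neighbours within the cutoff -- the energy a newly incorporated
#' monomer at that position experiences.
#'
#' @param sites A [generate_sites()] result.
#' @param particle A [patchy_particle()].
#' @param solvent An [electrolyte()].
#' @param cutoff Pair-distance cutoff in nm (must be >= the lattice
#'   spacing; default `1.05 * d`, nearest neighbours only).
#' @param site Optional single site index (row of `sites`).
#' @return Energy in kcal/mol (per monomer, or for the selected site).
#' @export
lattice_energy_per_monomer <- function(sites, particle = patchy_particle(),
                                       solvent = electrolyte(),
                                       cutoff = NULL, site = NULL) {
  if (!inherits(sites, "lattice_sites"))
    stop("expected 'lattice_sites'", call. = FALSE)
  conf <- attr(sites, "conformation")
  d <- conf$spacing
  if (is.null(cutoff)) cutoff <- 1.05 * d
  if (cutoff < d) stop("cutoff must be >= the lattice spacing", call. = FALSE)
  n <- nrow(sites)
  if (n == 1L && is.null(site)) return(0)
  pos <- as.matrix(sites[, c("x", "y")])
  sgn <- sites$dipole_sign

  pair_E <- function(idx_a, idx_b) {
    r <- sqrt((pos[idx_a, 1] - pos[idx_b, 1])^2 +
                (pos[idx_a, 2] - pos[idx_b, 2])^2)
    keep <- r > 1e-12 & r <= cutoff
    if (!any(keep)) return(0)
    dphi <- ifelse(sgn[idx_a][keep] == sgn[idx_b][keep], 0, 180)
    sum(pair_energy_reduced(r[keep], dphi, particle, solvent))
  }

  if (!is.null(site)) {
    site <- as.integer(site)
    if (site < 1L || site > n) stop("site index out of range", call. = FALSE)
    others <- setdiff(seq_len(n), site)
    if (!length(others)) return(0)
    return(pair_E(rep(site, length(others)), others))
  }
  idx <- utils::combn(n, 2)
  pair_E(idx[1, ], idx[2, ]) / n
}

#' Interior-monomer symmetry preference curve
#'
#' For each lattice spacing d, the parallel-minus-antiparallel energy
#' difference Delta E = E(p4) - E(p42_1 2) felt by an interior monomer
#' under nearest-neighbour truncation (4 neighbours at distance d). The
#' charge-charge term cancels exactly in the difference, so Delta E is the
#' purely dipolar preference; it is positive (antiparallel favoured) and
#' decreases monotonically with d in the screened regime.
#'
#' @param d_values Lattice spacings in nm.
#' @param particle A [patchy_particle()].
#' @param solvent An [electrolyte()].
#' @param n Linear size of the test lattice (odd, >= 3); the central site
#'   is used as the interior monomer. Default 3.
#' @return data.frame with columns `d`, `dE_kcal`, `dE_kBT`.
#' @export
#' @examples
#' symmetry_preference_curve(c(7, 10))  # 4x the pairwise differences
symmetry_preference_curve <- function(d_values, particle = patchy_particle(),
                                      solvent = electrolyte(), n = 3L) {
  if (any(!is.finite(d_values)) || any(d_values <= 0))
    stop("d_values must be positive", call. = FALSE)
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L) stop("n must be odd and >= 3", call. = FALSE)
  center <- (n * n + 1L) %/% 2L
  dE <- vapply(d_values, function(d) {
    # conformation with spacing d at the fully open angle: L = d / sqrt(2)
    confs <- lapply(c("p4", "p4212"), function(s)
      generate_sites(lattice_conformation(d / sqrt(2), 45, s), n, n))
    Es <- vapply(confs, lattice_energy_per_monomer, numeric(1),
                 particle = particle, solvent = solvent,
                 cutoff = 1.05 * d, site = center)
    Es[1] - Es[2]
  }, numeric(1))
  data.frame(d = d_values, dE_kcal = dE,
             dE_kBT = dE / .kBT_kcalmol(solvent$temperature))
}
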