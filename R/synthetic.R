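#' Synthetic C4-symmetric test particle
#'
#' Builds a point-atom model with the topography of a patchy, C4-symmetric
#' protein building block: a flat, square top plate at z = `height` and four
#' legs descending to z = 0 at the corners, leaving a central dip between
#' the legs. The top plate carries `top_charge` spread equally over its
#' atoms and the four leg-base atoms (at z = 0) carry `bottom_charge`
#' equally, so the charge centroids sit exactly at the two face planes and
#' dipole arithmetic is exact. The construction is deterministic; the
#' `seed` argument is accepted for interface symmetry with the stochastic
#' generators but no randomness is used.
#'
#' @param height Particle height in Angstrom (top-plate z).
#' @param top_width Side length of the square top plate, Angstrom.
#' @param leg_length Length of each leg in Angstrom (legs span z in
#'   `[0, leg_length]`).
#' @param leg_spacing Center-to-center distance between diagonal leg pairs'
#'   projections, i.e. legs sit at (+-leg_spacing/2, +-leg_spacing/2).
#' @param top_charge Total charge on the top face, elementary charges.
#' @param bottom_charge Total charge on the bottom (leg-base) face.
#' @param atoms_per_feature Atoms per plate edge (plate holds
#'   `atoms_per_feature^2` atoms) and atoms per leg.
#' @param seed Unused; kept for a stable call signature.
#' @return A grounded `atom_collection` with exact 4-fold rotational
#'   symmetry about z.
#' @export
#' @examples
#' p <- make_synthetic_particle(height = 45, top_charge = -8,
#'                              bottom_charge = 8)
#' attr(macrodipole(p), "magnitude")  # 8 * 45 * 4.8032 D
make_synthetic_particle <- function(height = 45, top_width = 30,
                                    leg_length = 15, leg_spacing = 20,
                                    top_charge = -8, bottom_charge = 8,
                                    atoms_per_feature = 5L, seed = NULL) {
  dims <- c(height = height, top_width = top_width,
            leg_length = leg_length, leg_spacing = leg_spacing)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all particle dimensions must be positive: ",
         paste(names(dims)[dims <= 0 | !is.finite(dims)], collapse = ", "),
         call. = FALSE)
  if (atoms_per_feature < 1L) stop("atoms_per_feature must be >= 1",
                                   call. = FALSE)
  n <- as.integer(atoms_per_feature)

  # top plate: n x n grid, symmetric about the axis -> exact C4 symmetry
  g <- if (n == 1L) 0 else seq(-top_width / 2, top_width / 2, length.out = n)
  top <- expand.grid(x = g, y = g)
  top$z <- height
  top$charge <- top_charge / nrow(top)

  # four legs at (+-s/2, +-s/2), vertical stacks from z = 0 up
  s <- leg_spacing / 2
  leg_xy <- rbind(c(s, s), c(-s, s), c(-s, -s), c(s, -s))
  leg_z <- if (n == 1L) 0 else seq(0, leg_length, length.out = n)
  legs <- do.call(rbind, lapply(seq_len(4), function(k) {
    data.frame(x = leg_xy[k, 1], y = leg_xy[k, 2], z = leg_z)
  }))
  # charge only at the base atoms (z = 0) so the face centroid is exact
  legs$charge <- ifelse(legs$z == 0, bottom_charge / 4, 0)

  all <- rbind(top[, c("x", "y", "z", "charge")],
               legs[, c("x", "y", "z", "charge")])
  atom_collection(all$x, all$y, all$z, element = "C",
                  is_hydrogen = FALSE, is_calpha = FALSE,
                  charge = all$charge, radius = 0,
                  frame_note = "synthetic-C4-particle (grounded: min-z=0)")
}

#' Rotate an atom collection about the z axis
#'
#' @param atoms An `atom_collection`.
#' @param angle_deg Rotation angle in degrees (counter-clockwise viewed
#'   from +z).
#' @return The rotated collection.
#' @export
rotate_z <- function(atoms, angle_deg) {
  .assert_atoms(atoms)
  c_ <- .cosd(angle_deg); s_ <- .sind(angle_deg)
  x <- atoms$x; y <- atoms$y
  atoms$x <- c_ * x - s_ * y
  atoms$y <- s_ * x + c_ * y
  atoms
}
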