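#' Brute-force dilation oracle for simulated topographs
#'
#' Computes the same image as [scan_topograph()] by the morphological route:
#' the topograph of a point set under a rigid tip is the grayscale dilation
#' of the points by the reflected tip shape. For each atom the closed-form
#' first-contact locus of the tip center is evaluated over the whole grid
#' at once (the reflected structuring element centered on the atom), and
#' the per-node height is the pointwise maximum over atoms minus the apex
#' radius, floored at 0. Organised per atom (image max-reduction) rather
#' than per node, as an independent implementation route for verification;
#' `overlap_threshold` is ignored (hard contact only).
#'
#' @inheritParams scan_topograph
#' @return A [height_map()].
#' @export
dilation_oracle <- function(atoms, tip, grid) {
  if (!inherits(tip, "tip_model")) stop("expected a 'tip_model'", call. = FALSE)
  if (!inherits(grid, "scan_grid")) stop("expected a 'scan_grid'", call. = FALSE)
  a <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  nxg <- length(grid$x); nyg <- length(grid$y)
  img <- matrix(0, nxg, nyg)
  psi <- tip$cone_half_angle
  sinp <- .sind(psi); cosp <- .cosd(psi); tanp <- .tand(psi)
  for (i in seq_len(nrow(a))) {
    R <- tip$apex_radius + a$radius[i]
    # lateral offsets of every node from this atom, as an nxg x nyg matrix
    rho <- sqrt(outer((grid$x - a$x[i])^2, (grid$y - a$y[i])^2, `+`))
    # reflected structuring element: spherical cap inside rho < R, conical
    # skirt outside, absent beyond the truncation reach
    se <- matrix(-Inf, nxg, nyg)
    cone <- rho >= R
    reach <- R * sinp + (rho - R * cosp) / tanp < tip$z_cutoff
    sel <- cone & reach
    se[sel] <- -R * sinp - (rho[sel] - R * cosp) / tanp
    cap <- !cone
    se[cap] <- sqrt(R^2 - rho[cap]^2)
    img <- pmax(img, a$z[i] + se - tip$apex_radius)
  }
  height_map(img, grid,
             provenance = sprintf("dilation_oracle R=%.3g psi=%.3g",
                                  tip$apex_radius, tip$cone_half_angle))
}
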