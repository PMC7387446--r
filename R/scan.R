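# Simulated tapping: the tip is lowered (conceptually raised from the
# support) at each raster node and the first tip-center height z_tip at
# which at most `overlap_threshold` heavy atoms lie strictly inside the
# (sphere u truncated cone) volume is recorded as height = z_tip - R,
# floored at 0 (the support plane is impenetrable).
#
# Contact geometry, solved in closed form per atom at lateral offset rho
# and height h (R = apex radius, psi = half-angle, effective radius
# R' = R + atom radius; the tangent-cone offset body of the tip by the atom
# radius is again a sphere-plus-tangent-cone with radius R'):
#   sphere flank (rho <  R'): clear at z_tip >= h + sqrt(R'^2 - rho^2)
#   cone flank  (rho >= R'): clear at z_tip >= h - R' sin(psi)
#                                   - (rho - R' cos(psi)) / tan(psi),
#     reachable only if R' sin(psi) + (rho - R' cos(psi))/tan(psi) <
#     z_cutoff (otherwise the atom passes above the truncated cone and
#     never contacts).
# Strict-interior overlap convention: tangency is not an overlap, so the
# closed-form infimum is itself a valid (non-overlapping) tip position.

# per atom-node clearance height z_tip; -Inf where the atom never contacts.
# rho, h, r_atom are equal-length vectors (or rho a matrix with h, r_atom
# recycled along columns).
.clearance_ztip <- function(rho, h, r_atom, tip) {
  R <- tip$apex_radius + r_atom
  psi <- tip$cone_half_angle
  sinp <- .sind(psi); cosp <- .cosd(psi); tanp <- .tand(psi)
  out <- h - R * sinp - pmax(rho - R * cosp, 0) / tanp   # cone flank
  # atoms too far out laterally never enter the truncated cone
  unreachable <- rho >= R & (R * sinp + (rho - R * cosp) / tanp) >= tip$z_cutoff
  out[unreachable] <- -Inf
  sph <- rho < R
  if (any(sph)) {
    Rs <- if (length(R) == 1L) R else R[sph]
    out[sph] <- h[sph] + sqrt(pmax(Rs^2 - rho[sph]^2, 0))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count atoms inside the tip volume
#'
#' Counts the heavy atoms whose center (inflated by the per-atom radius if
#' set) lies strictly inside the union of the apex sphere and the truncated
#' cone above it, for a tip at `tip_position`.
#'
#' @param tip A [tip_model()].
#' @param tip_position Numeric length-3 `(x, y, z_tip)` in Angstrom
#'   (`z_tip` is the apex sphere center).
#' @param atoms An `atom_collection`; hydrogens are excluded.
#' @return Integer overlap count.
#' @export
#' @examples
#' ac <- atom_collection(0, 0, 5)
#' tip_overlap_count(tip_model(), c(0, 0, 5), ac)  # 1: atom at sphere center
tip_overlap_count <- function(tip, tip_position, atoms) {
  .assert_atoms(atoms)
  stopifnot(length(tip_position) == 3)
  a <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  R <- tip$apex_radius + a$radius
  dx <- a$x - tip_position[1]
  dy <- a$y - tip_position[2]
  dz <- a$z - tip_position[3]
  rho2 <- dx^2 + dy^2
  in_sphere <- rho2 + dz^2 < R^2
  sinp <- .sind(tip$cone_half_angle)
  cosp <- .cosd(tip$cone_half_angle)
  tanp <- .tand(tip$cone_half_angle)
  cone_r <- R * cosp + (dz - R * sinp) * tanp
  in_cone <- dz > R * sinp & dz < tip$z_cutoff & sqrt(rho2) < cone_r
  sum(in_sphere | in_cone)
}

#' Simulate an AFM topograph of an atomic model
#'
#' For each raster node the recorded height is the smallest tip-center
#' height (minus the apex radius) at which the number of heavy-atom
#' overlaps with the tip volume is at most `tip$overlap_threshold`, floored
#' at 0. The contact search is solved in closed form per atom, so the
#' result is deterministic and free of any z-step discretization; it equals
#' the limit of the raise-until-clear procedure.
#'
#' @param atoms A grounded `atom_collection` (see [ground_structure()]).
#'   Hydrogens are excluded from contact tests.
#' @param tip A [tip_model()].
#' @param grid A [scan_grid()].
#' @return A [height_map()] (matrix of heights in Angstrom, rows = x nodes,
#'   columns = y nodes).
#' @export
#' @examples
#' ac <- atom_collection(0, 0, 10)
#' hm <- scan_topograph(ac, tip_model(), scan_grid(-8, 8, -8, 8, 2))
#' max(hm$values)  # 10: true height recovered on-axis
scan_topograph <- function(atoms, tip, grid) {
  if (!inherits(tip, "tip_model")) stop("expected a 'tip_model'", call. = FALSE)
  if (!inherits(grid, "scan_grid")) stop("expected a 'scan_grid'", call. = FALSE)
  nxg <- length(grid$x); nyg <- length(grid$y)
  prov <- sprintf("scan_topograph R=%.3g psi=%.3g thr=%d [%s]",
                  tip$apex_radius, tip$cone_half_angle,
                  tip$overlap_threshold,
                  attr(atoms, "frame_note") %||% "?")
  a <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) {
    warning("empty structure: returning all-zero height map")
    return(height_map(matrix(0, nxg, nyg), grid, provenance = prov))
  }

  node_x <- rep(grid$x, times = nyg)
  node_y <- rep(grid$y, each = nxg)
  vals <- if (tip$overlap_threshold == 0L) {
    .scan_hard(node_x, node_y, a, tip)
  } else {
    .scan_thresholded(node_x, node_y, a, tip)
  }
  height_map(matrix(vals, nxg, nyg), grid, provenance = prov)
}

# hard contact (threshold 0): height = max over atoms of clearance - R
.scan_hard <- function(node_x, node_y, a, tip) {
  n_nodes <- length(node_x)
  best <- rep(-Inf, n_nodes)
  # chunk over atoms to bound memory on big scenes
  for (i in seq_len(nrow(a))) {
    rho <- sqrt((node_x - a$x[i])^2 + (node_y - a$y[i])^2)
    zc <- .clearance_ztip(rho, rep(a$z[i], n_nodes),
                          rep(a$radius[i], n_nodes), tip)
    best <- pmax(best, zc)
  }
  pmax(best - tip$apex_radius, 0)
}

# threshold k > 0: at each node the overlap set of each atom as a function
# of z_tip is a union of at most two open intervals (cone band below,
# sphere band above, possibly with a gap beside the tangency neck). The
# first z_tip >= R with count <= k is either R itself or an interval upper
# endpoint; evaluate the exact count at each candidate.
.scan_thresholded <- function(node_x, node_y, a, tip) {
  k <- tip$overlap_threshold
  R0 <- tip$apex_radius
  psi <- tip$cone_half_angle
  sinp <- .sind(psi); cosp <- .cosd(psi); tanp <- .tand(psi)
  n_nodes <- length(node_x)
  vals <- numeric(n_nodes)
  for (nd in seq_len(n_nodes)) {
    R <- R0 + a$radius
    rho <- sqrt((node_x[nd] - a$x)^2 + (node_y[nd] - a$y)^2)
    h <- a$z
    s2 <- R^2 - rho^2
    sph_lo <- ifelse(s2 > 0, h - sqrt(s2), NA_real_)
    sph_hi <- ifelse(s2 > 0, h + sqrt(s2), NA_real_)
    cone_hi <- h - R * sinp - pmax(rho - R * cosp, 0) / tanp
    cone_lo <- h - tip$z_cutoff
    cone_ok <- cone_hi > cone_lo
    lo <- cbind(ifelse(cone_ok, cone_lo, NA), sph_lo)
    hi <- cbind(ifelse(cone_ok, cone_hi, NA), sph_hi)
    cand <- sort(unique(c(R0, hi[is.finite(hi) & hi > R0])))
    height <- 0
    for (z in cand) {
      cnt <- sum((z > lo[, 1] & z < hi[, 1]) |
                 (z > lo[, 2] & z < hi[, 2]), na.rm = TRUE)
      if (cnt <= k) { height <- max(z - R0, 0); break }
    }
    vals[nd] <- height
  }
  vals
}
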