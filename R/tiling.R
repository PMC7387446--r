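#' Tile a unit structure onto a 2D crystal lattice
#'
#' Places `nx * ny` rigid copies of `unit` at the sites of a square lattice
#' with the spacing, in-plane rotation pattern and out-of-plane flip pattern
#' prescribed by a [lattice_conformation()]:
#' \itemize{
#'   \item in-plane: alternating +theta / -theta rotations on a
#'     checkerboard (the rotating-squares construction);
#'   \item p4: every copy keeps the same z-orientation (polar lattice);
#'   \item p42_1 2: a checkerboard of z-flipped copies (copy rotated 180
#'     degrees about the x axis through its own centroid), giving the
#'     antiparallel up-down pattern.
#' }
#' Flipped copies are re-seated so their minimum z equals the unit's
#' minimum z (both species rest on the same support plane). Each copy is a
#' rigid transform: all intra-copy distances are preserved.
#'
#' @param unit An `atom_collection` (one building block).
#' @param conformation A [lattice_conformation()].
#' @param nx,ny Number of lattice sites along x and y (>= 1).
#' @return An `atom_collection` with a `site` column (1-based site index)
#'   and a `flipped` logical column.
#' @export
tile_lattice <- function(unit, conformation, nx, ny) {
  .assert_atoms(unit)
  if (!inherits(conformation, "lattice_conformation"))
    stop("expected a 'lattice_conformation'", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L)
    stop("nx and ny must be >= 1", call. = FALSE)

  d_ang <- conformation$spacing * 10   # nm -> Angstrom
  theta <- conformation$opening_angle
  sym <- conformation$symmetry
  cen <- c(mean(unit$x), mean(unit$y), mean(unit$z))
  zmin0 <- min(unit$z)

  copies <- vector("list", nx * ny)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      parity <- (i + j) %% 2L == 0L
      cp <- unit
      # rotate about the copy's own vertical axis: +theta / -theta pattern
      ang <- if (parity) theta else -theta
      xr <- cp$x - cen[1]; yr <- cp$y - cen[2]
      cp$x <- .cosd(ang) * xr - .sind(ang) * yr
      cp$y <- .sind(ang) * xr + .cosd(ang) * yr
      cp$z <- cp$z - cen[3]
      if (sym == "p4212" && !parity) {
        # proper rotation by 180 deg about the x axis through the centroid
        cp$y <- -cp$y
        cp$z <- -cp$z
      }
      # re-seat on the support plane and move to the lattice site
      cp$z <- cp$z - min(cp$z) + zmin0
      cp$x <- cp$x + (i - 1L) * d_ang
      cp$y <- cp$y + (j - 1L) * d_ang
      cp$site <- k
      cp$flipped <- sym == "p4212" && !parity
      copies[[k]] <- as.data.frame(cp)
    }
  }
  out <- do.call(rbind, copies)
  rownames(out) <- NULL
  structure(out, class = c("atom_collection", "data.frame"),
            frame_note = sprintf("tiled %dx%d %s (d = %.4f nm, theta = %.2f deg)",
                                 nx, ny, sym, conformation$spacing, theta))
}
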