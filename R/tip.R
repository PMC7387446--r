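#' AFM tip model: sphere apex under a truncated cone
#'
#' The probe is a rigid sphere of radius `apex_radius` whose center z_tip
#' sits at the end of a cone of half-angle `cone_half_angle` (measured from
#' the tip axis), truncated at height `z_cutoff` above the apex center. The
#' cone flank is tangent to the apex sphere: the tangency circle lies at
#' z = z_tip + R sin(psi) with radius R cos(psi). `overlap_threshold` is the
#' number of atom overlaps tolerated before a contact is declared, used to
#' soften the effect of flexible surface loops (0 = hard contact).
#'
#' @param apex_radius Apex sphere radius, Angstrom (default 10.0).
#' @param cone_half_angle Cone half-angle, degrees in (0, 90) (default 20).
#' @param z_cutoff Cone truncation height above the apex center, Angstrom;
#'   must be at least `apex_radius` (default 60: taller than any
#'   single-layer scene).
#' @param overlap_threshold Non-negative integer overlap tolerance.
#' @return A `tip_model` object.
#' @export
#' @examples
#' tip_model()
tip_model <- function(apex_radius = 10.0, cone_half_angle = 20,
                      z_cutoff = 60, overlap_threshold = 0L) {
  if (!is.finite(apex_radius) || apex_radius <= 0)
    stop("apex_radius must be > 0", call. = FALSE)
  if (!is.finite(cone_half_angle) || cone_half_angle <= 0 ||
      cone_half_angle >= 90)
    stop("cone_half_angle must lie in (0, 90) degrees", call. = FALSE)
  if (!is.finite(z_cutoff) || z_cutoff < apex_radius)
    stop("z_cutoff must be >= apex_radius", call. = FALSE)
  if (overlap_threshold < 0) stop("overlap_threshold must be >= 0",
                                  call. = FALSE)
  structure(list(apex_radius = apex_radius,
                 cone_half_angle = cone_half_angle,
                 z_cutoff = z_cutoff,
                 overlap_threshold = as.integer(overlap_threshold)),
            class = "tip_model")
}

#' @export
print.tip_model <- function(x, ...) {
  cat(sprintf(
    "<tip_model> R = %.2f A, half-angle = %.1f deg, z_cutoff = %.1f A, threshold = %d\n",
    x$apex_radius, x$cone_half_angle, x$z_cutoff, x$overlap_threshold))
  invisible(x)
}

#' Raster grid for topograph scans
#'
#' Grid nodes sit at `x_min + i * step` and `y_min + j * step`, inclusive of
#' both edges when the extent is commensurate with the step.
#'
#' @param x_min,x_max,y_min,y_max Window extents in Angstrom.
#' @param step Raster step in Angstrom (default 0.50, both axes).
#' @return A `scan_grid` object with node vectors `x` and `y`.
#' @export
#' @examples
#' g <- scan_grid(-15, 15, -15, 15, step = 0.5)
#' length(g$x)  # 61 nodes
scan_grid <- function(x_min, x_max, y_min, y_max, step = 0.50) {
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (x_max <= x_min || y_max <= y_min)
    stop("window extent must be positive in both axes", call. = FALSE)
  x <- seq(x_min, by = step, length.out = floor((x_max - x_min) / step + 1e-9) + 1L)
  y <- seq(y_min, by = step, length.out = floor((y_max - y_min) / step + 1e-9) + 1L)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 step = step, x = x, y = y),
            class = "scan_grid")
}
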