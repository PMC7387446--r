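# Physical constants (CODATA 2018, exact where defined) and unit conversions.
# All interaction math runs in SI; Angstrom/nm/debye appear only at the
# interfaces, converted through this one table.

.const <- list(
  e_C        = 1.602176634e-19,   # elementary charge [C]
  eps0_F_m   = 8.8541878128e-12,  # vacuum permittivity [F/m]
  N_A        = 6.02214076e23,     # Avogadro constant [1/mol]
  k_B        = 1.380649e-23,      # Boltzmann constant [J/K]
  debye_Cm   = 3.33564e-30,       # 1 debye [C m]
  kcal_J     = 4184,              # 1 kcal [J]
  eA_debye   = 4.8032,            # 1 e*Angstrom in debye (reporting only)
  nm_m       = 1e-9,
  ang_m      = 1e-10
)

#' Physical constants used by patchylat
#'
#' Returns the table of physical constants and unit conversion factors used
#' throughout the package (CODATA values; 1 D = 3.33564e-30 C m,
#' 1 e Angstrom = 4.8032 D).
#'
#' @return Named list of constants (SI units).
#' @export
#' @examples
#' patchylat_constants()$e_C
patchylat_constants <- function() .const

# joules per pair -> kcal/mol
.J_to_kcalmol <- function(E_J) E_J * .const$N_A / .const$kcal_J

# kcal/mol per kBT at temperature T [K]
.kBT_kcalmol <- function(temperature) {
  .const$k_B * temperature * .const$N_A / .const$kcal_J
}

# degrees in, exact cos/sin at multiples of 90 via cospi/sinpi
.cosd <- function(deg) cospi(deg / 180)
.sind <- function(deg) sinpi(deg / 180)
.tand <- function(deg) sinpi(deg / 180) / cospi(deg / 180)

.stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite (got non-finite values)", name),
         call. = FALSE)
  }
  invisible(x)
}
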