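#' Physical constants for ratchet rate laws
#'
#' Bundles the handful of physical conversion factors used throughout the
#' ratchet force laws and the network geometry estimates.
#'
#' @param kBT Thermal energy in pN.nm. Default 4.114 pN.nm (T = 298 K).
#' @param molarity_to_density Conversion from micromolar to molecules per
#'   cubic micrometre. Fixed at 602.2 molecules.um^-3 per uM by Avogadro's
#'   number; override only for testing.
#' @param subunit_rise Filament length added per polymerised subunit, nm.
#'   Default 2.7 nm, the same length scale as the gap an incoming monomer
#'   (or wildtype capping protein) needs at the barbed end.
#'
#' @return An object of class `physical_constants` (a named list).
#' @export
#'
#' @examples
#' physical_constants()
physical_constants <- function(kBT = 4.114,
                               molarity_to_density = 602.2,
                               subunit_rise = 2.7) {
  if (!is.numeric(kBT) || length(kBT) != 1L || kBT <= 0) {
    abort("`kBT` must be a single positive number (pN.nm).")
  }
  if (molarity_to_density <= 0) {
    abort("`molarity_to_density` must be positive.")
  }
  if (subunit_rise <= 0) {
    abort("`subunit_rise` must be positive (nm).")
  }
  structure(
    list(
      kBT = kBT,
      molarity_to_density = molarity_to_density,
      subunit_rise = subunit_rise
    ),
    class = "physical_constants"
  )
}

#' Brownian-Ratchet parameter set
#'
#' Gap sizes and the internal tethering force governing force-dependent
#' insertion of actin monomers and capping protein at the barbed end.
#' Monomeric actin and wildtype capping protein both require a 2.7 nm gap;
#' the engineered bulky capping-protein variant needs a larger one (default
#' 5.4 nm, a configurable placeholder for "significantly larger"). The
#' tethering force is the effective frictional force per filament arising
#' from transient NPF-barbed-end links and opposes motion at all loads.
#'
#' @param delta_actin Gap size for monomer addition, nm.
#' @param delta_cap_wt Gap size for wildtype capping protein, nm.
#' @param delta_cap_bulky Gap size for the bulky capping-protein variant, nm.
#'   Must be >= `delta_cap_wt`.
#' @param f_tether Characteristic internal tethering force per filament, pN
#'   (>= 0). Applied additively to the external per-filament load in both
#'   elongation and capping factors, at every load including zero.
#' @param reference_stress Stress (Pa) at which normalised quantities are
#'   anchored to 1. Default 25 Pa; 0 is accepted.
#' @param constants A [physical_constants()] object.
#'
#' @return An object of class `ratchet_params`.
#' @export
#'
#' @examples
#' ratchet_params(f_tether = 0.3)
ratchet_params <- function(delta_actin = 2.7,
                           delta_cap_wt = 2.7,
                           delta_cap_bulky = 5.4,
                           f_tether = 0,
                           reference_stress = 25,
                           constants = physical_constants()) {
  if (delta_actin <= 0 || delta_cap_wt <= 0 || delta_cap_bulky <= 0) {
    abort("All gap sizes must be positive (nm).")
  }
  if (delta_cap_bulky < delta_cap_wt) {
    abort("`delta_cap_bulky` must be >= `delta_cap_wt`.")
  }
  if (f_tether < 0) {
    abort("`f_tether` must be non-negative (pN).")
  }
  if (reference_stress < 0) {
    abort("`reference_stress` must be non-negative (Pa).")
  }
  stopifnot(inherits(constants, "physical_constants"))
  structure(
    list(
      delta_actin = delta_actin,
      delta_cap_wt = delta_cap_wt,
      delta_cap_bulky = delta_cap_bulky,
      f_tether = f_tether,
      reference_stress = reference_stress,
      constants = constants
    ),
    class = "ratchet_params"
  )
}

#' @export
print.ratchet_params <- function(x, ...) {
  cat("<ratchet_params>\n")
  cat(sprintf("  delta_actin:     %.2f nm\n", x$delta_actin))
  cat(sprintf("  delta_cap_wt:    %.2f nm\n", x$delta_cap_wt))
  cat(sprintf("  delta_cap_bulky: %.2f nm\n", x$delta_cap_bulky))
  cat(sprintf("  f_tether:        %.3f pN\n", x$f_tether))
  cat(sprintf("  reference_stress:%.1f Pa\n", x$reference_stress))
  cat(sprintf("  kBT:             %.3f pN.nm\n", x$constants$kBT))
  invisible(x)
}
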