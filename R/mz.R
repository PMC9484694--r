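#' m/z of a protonated species
#'
#' m/z of the `[M+zH]z+` ion of an uncharged mass, using the physical proton
#' mass (1.00728 Da) as the charge carrier.
#'
#' @param mass Uncharged mass in Da.
#' @param z Charge (positive integer), vectorised.
#' @return m/z values.
#' @examples
#' mz_for_charge(14000, 10:14)
#' @export
mz_for_charge <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) {
    abort("`z` must be positive integer(s).")
  }
  (mass + z * proton_mass()) / z
}

#' Charge states visible in a scan window
#'
#' All charges z >= 1 whose `[M+zH]z+` m/z falls inside the closed interval
#' `[mz_min, mz_max]` - i.e. the charge envelope an instrument scanning that
#' window can observe for a species of the given mass.
#'
#' @param mass Uncharged mass in Da.
#' @param mz_min,mz_max Scan window bounds (m/z), `mz_min < mz_max`.
#' @return Integer vector of charges, ascending (possibly empty).
#' @examples
#' charges_in_range(14000, 500, 2000)
#' @export
charges_in_range <- function(mass, mz_min, mz_max) {
  if (mz_min >= mz_max) abort("`mz_min` must be less than `mz_max`.")
  # mz(z) decreases towards proton_mass() as z grows; bracket z analytically
  # and verify against the exact formula.
  z_lo <- max(1, floor(mass / (mz_max - proton_mass())))
  z_hi <- if (mz_min > proton_mass()) {
    ceiling(mass / (mz_min - proton_mass())) + 1
  } else {
    ceiling(mass) + 1
  }
  z <- seq.int(z_lo, max(z_lo, z_hi))
  mz <- mz_for_charge(mass, z)
  as.integer(z[mz >= mz_min & mz <= mz_max])
}
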