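#' Instrument profiles
#'
#' Resolution and acquisition constants for the two instrument classes the
#' pipeline supports: a unit-resolution triple quadrupole ("QQQ", FWHM 0.7,
#' sigma 0.3) and a high-resolution quadrupole time-of-flight ("QTOF", FWHM
#' 0.06, sigma 0.026). The sigma constant, scaled by the largest observed
#' charge state, is the resolution floor on a deconvolved mass's standard
#' deviation; the EIC half-width numerator sets the per-charge extraction
#' window (+/- numerator/z Da: 2/z for QQQ, 1/z for QTOF).
#'
#' @param name `"QQQ"` or `"QTOF"`.
#' @param scan_mz_range Optional length-2 override of the scan window (m/z).
#' @param scan_interval Optional override of the scan interval (seconds).
#' @return An `instrument_profile` list with fields `name`, `fwhm`, `sigma`,
#'   `eic_halfwidth_numerator`, `scan_mz_range`, `scan_interval`.
#' @examples
#' instrument_profile("QQQ")
#' @export
instrument_profile <- function(name = c("QQQ", "QTOF"),
                               scan_mz_range = NULL, scan_interval = NULL) {
  name <- match.arg(name)
  prof <- switch(name,
    QQQ = list(name = "QQQ", fwhm = 0.7, sigma = 0.3,
               eic_halfwidth_numerator = 2,
               scan_mz_range = c(500, 2000), scan_interval = 0.3),
    QTOF = list(name = "QTOF", fwhm = 0.06, sigma = 0.026,
                eic_halfwidth_numerator = 1,
                scan_mz_range = c(100, 3200), scan_interval = 0.25)
  )
  if (!is.null(scan_mz_range)) {
    stopifnot(length(scan_mz_range) == 2, scan_mz_range[1] < scan_mz_range[2])
    prof$scan_mz_range <- as.numeric(scan_mz_range)
  }
  if (!is.null(scan_interval)) {
    stopifnot(scan_interval > 0)
    prof$scan_interval <- as.numeric(scan_interval)
  }
  structure(prof, class = "instrument_profile")
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf(
    "<instrument_profile> %s: FWHM %g, sigma %g, EIC +/- %g/z Da, scan %g-%g m/z every %g s\n",
    x$name, x$fwhm, x$sigma, x$eic_halfwidth_numerator,
    x$scan_mz_range[1], x$scan_mz_range[2], x$scan_interval))
  invisible(x)
}

as_instrument <- function(x) {
  if (inherits(x, "instrument_profile")) return(x)
  if (is.character(x) && length(x) == 1L) return(instrument_profile(x))
  abort("`instrument` must be an instrument_profile or \"QQQ\"/\"QTOF\".")
}
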