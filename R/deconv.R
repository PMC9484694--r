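# Charge-ladder mass deconvolution of ESI spectra: five consecutively
# charged m/z peaks (m1 < m2 < ... < m5) of one species determine the charge
# ladder and hence the uncharged mass. Higher m/z means lower charge, so the
# lowest charge z5 belongs to m5.

check_ladder <- function(mz_values) {
  if (length(mz_values) != 5L || anyNA(mz_values)) {
    abort("A charge ladder is exactly five m/z values.")
  }
  if (any(mz_values <= 0)) abort("m/z values must be positive.")
  if (any(diff(mz_values) <= 0)) {
    abort("Ladder m/z values must be strictly increasing (m1 < ... < m5).")
  }
  as.numeric(mz_values)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Infer the lowest charge of a five-peak ladder
#'
#' For each adjacent pair of consecutively charged peaks, the charge of the
#' lower-m/z (higher-charge) peak follows from the spacing:
#' `z = (m_hi - 1) / (m_hi - m_lo)`. Each pairwise estimate is converted to
#' an estimate of the lowest charge `z5` by subtracting the peak's proton
#' offset relative to `m5`; the four estimates are averaged and rounded
#' (half away from zero).
#'
#' @param mz_values Five strictly increasing m/z values.
#' @return The integer charge of the highest-m/z peak (`z5 >= 1`).
#' @export
infer_lowest_charge <- function(mz_values) {
  m <- check_ladder(mz_values)
  # pair i = (m_i, m_{i+1}): z of peak i; peak i carries (5 - i) protons more
  # than peak 5
  i <- 1:4
  z_pair <- (m[i + 1] - 1) / (m[i + 1] - m[i])
  z5_est <- z_pair - (5 - i)
  z5 <- round_half_away(mean(z5_est))
  if (z5 < 1) abort("Inferred lowest charge < 1: not a physical ladder.")
  as.integer(z5)
}

#' Reconstruct per-peak uncharged masses from a ladder
#'
#' Assigns charges `z5 + 4, ..., z5` to the ascending m/z values and strips
#' the charge: uncharged mass `= z * m/z - z * p`, where the charge-carrier
#' mass `p` is 1 by the procedure's printed convention (set
#' `physical_proton = TRUE` for p = 1.00728 Da).
#'
#' @param mz_values Five strictly increasing m/z values.
#' @param z5 Lowest charge (of the highest m/z value).
#' @param physical_proton Use the physical proton mass instead of 1 Da.
#' @return A `deconv_result` (see [deconvolve()]) without a resolution floor
#'   applied: `reported_sd` equals `sample_sd`.
#' @export
reconstruct_mass <- function(mz_values, z5, physical_proton = FALSE) {
  m <- check_ladder(mz_values)
  z5 <- as.integer(z5)
  if (is.na(z5) || z5 < 1L) abort("`z5` must be a positive integer.")
  z <- z5 + (4:0)
  p <- if (physical_proton) proton_mass() else 1
  masses <- z * m - z * p
  res <- list(
    mz_values = m, charges = z, per_peak_masses = masses,
    mean_mass = mean(masses), sample_sd = sd(masses),
    resolution_floor = 0, reported_sd = sd(masses),
    instrument = NA_character_
  )
  structure(res, class = "deconv_result")
}

#' Deconvolve a five-peak charge ladder
#'
#' Chains charge inference and mass reconstruction, then applies the
#' instrument resolution floor: the reported standard deviation is the
#' greater of the sample standard deviation over the five per-peak masses
#' and `sigma * z1` (the instrument's sigma constant scaled by the largest
#' charge observed).
#'
#' @param mz_values Five strictly increasing m/z values of consecutive
#'   charge states of one species.
#' @param instrument An [instrument_profile()] or `"QQQ"`/`"QTOF"`.
#' @param physical_proton Use 1.00728 Da instead of 1 Da as the
#'   charge-carrier mass in the inversion formulas.
#' @return A `deconv_result`: charges, per-peak masses, `mean_mass`,
#'   `sample_sd`, `resolution_floor` and `reported_sd`. Use [tidy()] for the
#'   per-peak table and [glance()] for the one-row summary.
#' @examples
#' m <- mz_for_charge(14000, 14:10)  # z = 14..10, ascending m/z
#' deconvolve(sort(m), instrument = "QQQ")
#' @export
deconvolve <- function(mz_values, instrument = instrument_profile("QQQ"),
                       physical_proton = FALSE) {
  instrument <- as_instrument(instrument)
  z5 <- infer_lowest_charge(mz_values)
  res <- reconstruct_mass(mz_values, z5, physical_proton = physical_proton)
  z1 <- max(res$charges)
  res$resolution_floor <- instrument$sigma * z1
  res$reported_sd <- max(res$sample_sd, res$resolution_floor)
  res$instrument <- instrument$name
  res
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(
    "<deconv_result> M = %.3f Da (sd %.3f; sample sd %.4f, floor %.3f)\n",
    x$mean_mass, x$reported_sd, x$sample_sd, x$resolution_floor))
  cat("  charges:", paste(x$charges, collapse = ", "), "\n")
  invisible(x)
}

#' Pick a candidate five-peak ladder from a spectrum
#'
#' Convenience helper (beyond the core procedure): given centroid peaks of a
#' single scan, tries every five consecutive charges of every plausible
#' mass implied by the most intense peaks and returns the ladder whose five
#' matched peaks have the greatest summed intensity. Intended for quick
#' exploration; curated peak selection is preferred for reporting.
#'
#' @param peaks A data frame with columns `mz` and `intensity`.
#' @param tol m/z tolerance for matching predicted ladder members.
#' @param max_charge Largest charge considered.
#' @return A numeric vector of five ascending m/z values, or `NULL` if no
#'   full ladder is found.
#' @export
pick_ladder <- function(peaks, tol = 0.5, max_charge = 50) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) < 5L) return(NULL)
  seeds <- dplyr::slice_max(tibble::as_tibble(peaks), .data$intensity,
                            n = min(10L, nrow(peaks)))
  best <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(seeds))) {
    for (z_seed in 1:max_charge) {
      mass <- seeds$mz[i] * z_seed - z_seed * proton_mass()
      if (mass <= 0) next
      for (z5 in pmax(1L, z_seed - 4L):z_seed) {
        zz <- z5 + (4:0)
        pred <- mz_for_charge(mass, zz)
        idx <- purrr::map_int(pred, function(p) {
          d <- abs(peaks$mz - p)
          j <- which.min(d)
          if (d[j] <= tol) j else NA_integer_
        })
        if (anyNA(idx) || anyDuplicated(idx)) next
        score <- sum(peaks$intensity[idx])
        if (score > best_score) {
          best_score <- score
          best <- sort(peaks$mz[idx])
        }
      }
    }
  }
  best
}
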