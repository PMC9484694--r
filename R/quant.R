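# Fraction-modified quantification: per-charge extracted ion chromatograms
# (EICs) summed into an extracted compound chromatogram (ECC), fitted with a
# skew-normal peak and screened by charge-state and peak-shape criteria.

#' Skew-normal peak model
#'
#' Density-scaled skew-normal used as the "skewed Gaussian" peak shape:
#' `f(t) = baseline + area * (2/width) * dnorm(x) * pnorm(skew * x)` with
#' `x = (t - rt) / width`. `area` is the integrated peak area
#' (intensity x min, baseline excluded), `rt` the location parameter in
#' minutes, `width` the scale in minutes and `skew` the shape.
#'
#' @param t Time points (minutes).
#' @param area,rt,width,skew,baseline Peak parameters.
#' @return Model intensities at `t`.
#' @export
skew_gaussian <- function(t, area, rt, width, skew, baseline = 0) {
  x <- (t - rt) / width
  baseline + area * (2 / width) * dnorm(x) * pnorm(skew * x)
}

#' Extracted ion chromatogram
#'
#' Per-scan summed intensity of all centroid peaks within
#' `center_mz +/- halfwidth`. Every scan present in the table contributes a
#' point; scans with no matching peaks contribute zero.
#'
#' @param table A signal table.
#' @param center_mz Window centre (m/z).
#' @param halfwidth Window half-width in Da (for a charge-z extraction this
#'   is `numerator / z`: 2/z on a QQQ, 1/z on a QTOF).
#' @return A `chromatogram` of kind `"EIC"`.
#' @export
eic <- function(table, center_mz, halfwidth) {
  if (halfwidth <= 0) abort("`halfwidth` must be positive.")
  grid <- sort(unique(table$rt))
  hit <- table |>
    dplyr::filter(abs(.data$mz - center_mz) <= halfwidth) |>
    dplyr::summarise(intensity = sum(.data$intensity), .by = "rt")
  intensity <- rep(0, length(grid))
  intensity[match(hit$rt, grid)] <- hit$intensity
  new_chromatogram(grid, intensity, kind = "EIC",
                   meta = list(center_mz = center_mz, halfwidth = halfwidth))
}

#' Extracted compound chromatogram
#'
#' For one modification state (expected uncharged mass), extracts a
#' per-charge EIC at every charge whose `[M+zH]z+` falls inside the
#' instrument scan window, then sums the EICs pointwise into the compound
#' chromatogram used for quantification.
#'
#' @param table A signal table.
#' @param expected_mass Uncharged state mass (average Da).
#' @param instrument An [instrument_profile()] or its name.
#' @return A list with `ecc` (a `chromatogram` of kind `"ECC"`), `eics`
#'   (long tibble: `charge`, `rt`, `intensity`) and `charges`.
#' @export
ecc <- function(table, expected_mass, instrument = instrument_profile("QQQ")) {
  instrument <- as_instrument(instrument)
  charges <- charges_in_range(expected_mass,
                              instrument$scan_mz_range[1],
                              instrument$scan_mz_range[2])
  if (length(charges) == 0L) {
    abort(sprintf("Mass %.1f Da has no charge state inside the %s scan window.",
                  expected_mass, instrument$name))
  }
  grid <- sort(unique(table$rt))
  eics <- purrr::map_dfr(charges, function(z) {
    ch <- eic(table, mz_for_charge(expected_mass, z),
              instrument$eic_halfwidth_numerator / z)
    tibble::tibble(charge = z, rt = ch$rt, intensity = ch$intensity)
  })
  total <- if (length(grid) == 0L) {
    tibble::tibble(rt = numeric(0), intensity = numeric(0))
  } else {
    dplyr::summarise(eics, intensity = sum(.data$intensity), .by = "rt")
  }
  list(
    ecc = new_chromatogram(total$rt, total$intensity, kind = "ECC",
                           meta = list(mass = expected_mass,
                                       instrument = instrument$name)),
    eics = eics,
    charges = charges
  )
}

#' Fit a skew-normal peak to a chromatogram
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' [skew_gaussian()] model with parameters peak area, retention time, width,
#' skew and baseline. Initialisation is deterministic: location and height
#' from the maximum point, width from the half-maximum span, zero skew,
#' minimum intensity as baseline.
#'
#' @param chrom A `chromatogram` (>= 8 points).
#' @return A `peak_fit` list: `area`, `rt`, `width`, `skew`, `baseline`,
#'   `converged`, plus the fitted curve. A flat or empty trace yields
#'   `converged = FALSE` and zero area.
#' @export
fit_skewed_gaussian <- function(chrom) {
  t <- chrom$rt; y <- chrom$intensity
  failed <- structure(list(area = 0, rt = NA_real_, width = NA_real_,
                           skew = NA_real_, baseline = 0, converged = FALSE,
                           fitted = rep(0, length(t)), rt_grid = t),
                      class = "peak_fit")
  if (length(t) < 8L || all(y <= 0) || diff(range(y)) == 0) return(failed)

  i_max <- which.max(y)
  base0 <- min(y)
  height <- y[i_max] - base0
  dt <- min(diff(t))
  above <- t[y - base0 >= height / 2]
  span <- max(diff(range(above)), 2 * dt)
  width0 <- span / 2.3548
  area0 <- height * width0 * sqrt(2 * pi)
  start <- list(area = area0, rt = t[i_max], width = width0, skew = 0,
                baseline = base0)
  lower <- c(area = 0, rt = min(t), width = dt / 2, skew = -10, baseline = 0)
  upper <- c(area = Inf, rt = max(t), width = diff(range(t)), skew = 10,
             baseline = max(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ skew_gaussian(t, area, rt, width, skew, baseline),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- as.list(stats::coef(fit))
  structure(list(area = p$area, rt = p$rt, width = p$width, skew = p$skew,
                 baseline = p$baseline, converged = TRUE,
                 fitted = as.numeric(stats::fitted(fit)), rt_grid = t),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<peak_fit> not converged (area 0)\n")
  } else {
    cat(sprintf(
      "<peak_fit> area %.4g, rt %.3f min, width %.3f min, skew %.2f, baseline %.3g\n",
      x$area, x$rt, x$width, x$skew, x$baseline))
  }
  invisible(x)
}

#' Peak-validity criteria
#'
#' Thresholds for deciding whether a fitted ECC peak is trustworthy:
#' more than eight charge states present at the peak retention time
#' (+/- `rt_window` min) with at least four consecutive, no secondary ECC
#' peak above 80% of the largest peak height, at most two secondary peaks
#' above 40%, skew within `[0, 1.5]` and width at most 0.25 min.
#'
#' @param min_charge_states Minimum number of charge states present
#'   (default 9, the literal reading of "greater than eight").
#' @param min_consecutive Minimum consecutive-charge run length (default 4).
#' @param rt_window Half-window (min) around the fitted retention time in
#'   which a charge's EIC must show signal (default 0.2).
#' @param presence_floor Intensity a charge's EIC must exceed to count as
#'   present (default 0: any strictly positive signal after the ingest
#'   intensity floor).
#' @param large_frac,small_frac Height fractions defining "large" (0.8) and
#'   "small" (0.4) secondary peaks.
#' @param max_small Maximum number of small secondary peaks (default 2).
#' @param skew_range Allowed fitted skew interval (default `c(0, 1.5)`).
#' @param max_width Maximum fitted width in minutes (default 0.25).
#' @param prominence_frac Local maxima below this fraction of the global
#'   maximum of the smoothed ECC are ignored when counting secondary peaks
#'   (default 0.05).
#' @return A `peak_criteria` list.
#' @export
peak_criteria <- function(min_charge_states = 9L, min_consecutive = 4L,
                          rt_window = 0.2, presence_floor = 0,
                          large_frac = 0.8, small_frac = 0.4, max_small = 2L,
                          skew_range = c(0, 1.5), max_width = 0.25,
                          prominence_frac = 0.05) {
  structure(as.list(environment()), class = "peak_criteria")
}

moving_mean3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  c(mean(x[1:2]), (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3,
    mean(x[(n - 1):n]))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Assess a fitted ECC peak
#'
#' Applies the validity criteria (see [peak_criteria()]) to a fitted peak,
#' its ECC and its per-charge EICs. Secondary peaks are counted among local
#' maxima of the lightly smoothed (3-point moving mean) ECC, excluding the
#' candidate peak itself.
#'
#' @param fit A `peak_fit`.
#' @param ecc_chrom The ECC `chromatogram` the fit was made on.
#' @param eics Long tibble of per-charge EICs (`charge`, `rt`, `intensity`).
#' @param criteria A [peak_criteria()] object.
#' @return A `peak_assessment` list: `valid`, counts of charge states and
#'   secondary peaks, and `reasons` (labels of failed criteria; empty iff
#'   valid).
#' @export
assess_peak <- function(fit, ecc_chrom, eics, criteria = peak_criteria()) {
  reasons <- character(0)
  if (!fit$converged) {
    return(structure(list(valid = FALSE, n_charge_states = 0L,
                          n_consecutive = 0L, n_large_peaks = NA_integer_,
                          n_small_peaks = NA_integer_,
                          reasons = "not_converged"),
                     class = "peak_assessment"))
  }
  # charge-state evidence near the fitted retention time
  near <- dplyr::filter(eics, abs(.data$rt - fit$rt) <= criteria$rt_window)
  present <- near |>
    dplyr::summarise(present = any(.data$intensity > criteria$presence_floor),
                     .by = "charge") |>
    dplyr::filter(.data$present)
  zs <- sort(present$charge)
  n_charge <- length(zs)
  n_consec <- if (n_charge == 0L) 0L else {
    runs <- rle(diff(zs) == 1L)
    max(c(1L, runs$lengths[runs$values] + 1L))
  }
  if (n_charge < criteria$min_charge_states) reasons <- c(reasons, "charge_states")
  if (n_consec < criteria$min_consecutive) reasons <- c(reasons, "consecutive")

  # secondary peaks on the smoothed ECC
  sm <- moving_mean3(ecc_chrom$intensity)
  idx <- local_maxima(sm)
  idx <- idx[sm[idx] >= criteria$prominence_frac * max(sm)]
  n_large <- 0L; n_small <- 0L
  if (length(idx) > 0L) {
    cand <- idx[which.min(abs(ecc_chrom$rt[idx] - fit$rt))]
    others <- setdiff(idx, cand)
    ref <- max(sm[idx])
    n_large <- sum(sm[others] > criteria$large_frac * ref)
    n_small <- sum(sm[others] > criteria$small_frac * ref)
  }
  if (n_large > 0L) reasons <- c(reasons, "large_peaks")
  if (n_small > criteria$max_small) reasons <- c(reasons, "small_peaks")

  if (fit$skew < criteria$skew_range[1] ||
      fit$skew > criteria$skew_range[2]) reasons <- c(reasons, "skew")
  if (fit$width > criteria$max_width) reasons <- c(reasons, "width")

  structure(list(valid = length(reasons) == 0L, n_charge_states = n_charge,
                 n_consecutive = n_consec, n_large_peaks = n_large,
                 n_small_peaks = n_small, reasons = reasons),
            class = "peak_assessment")
}

#' @export
print.peak_assessment <- function(x, ...) {
  cat(sprintf("<peak_assessment> %s (%d charge states, %d consecutive)\n",
              if (x$valid) "VALID" else "invalid",
              x$n_charge_states, x$n_consecutive))
  if (length(x$reasons)) cat("  failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify the fraction of peptide modified
#'
#' The full quantification pipeline for one extract: enumerate the expected
#' modification states, build each state's ECC, fit a skew-normal peak,
#' screen it with the validity criteria, and compute the fraction modified
#' as the summed area of the states counted as "modified" divided by the
#' total peptide area (all valid states). Invalid or absent states
#' contribute zero area.
#'
#' @param table A signal table (already filtered to the analysis window if
#'   desired; see [filter_signals()]).
#' @param sequence Peptide sequence (string or FASTA path).
#' @param mods Modification registry tibble.
#' @param instrument An [instrument_profile()] or its name.
#' @param modified_labels State labels whose areas count as modified;
#'   default `"modified"`. Use `c("partial", "modified")` when partially
#'   modified species should be included in the numerator (e.g. summing
#'   mono- and di-phosphorylated peptide).
#' @param partial_threshold Passed to [enumerate_states()].
#' @param criteria A [peak_criteria()] object.
#' @return A `quant_result`: `states` (per-state tibble with fitted
#'   parameters, validity and reasons), `total_peptide_area`,
#'   `fraction_modified` (`NA` when no state yields a valid peak, with
#'   `detected = FALSE`), and the inputs used. [tidy()] returns the
#'   per-state table, [glance()] the one-row summary.
#' @export
fraction_modified <- function(table, sequence, mods,
                              instrument = instrument_profile("QQQ"),
                              modified_labels = "modified",
                              partial_threshold = 15,
                              criteria = peak_criteria()) {
  instrument <- as_instrument(instrument)
  states <- enumerate_states(sequence, mods,
                             partial_threshold = partial_threshold)
  per_state <- purrr::pmap_dfr(
    states[c("label", "state", "expected_mass")],
    function(label, state, expected_mass) {
      ex <- tryCatch(ecc(table, expected_mass, instrument),
                     error = function(e) NULL)
      if (is.null(ex)) {
        # no charge state of this mass is visible in the scan window
        return(tibble::tibble(
          label = label, state = state, expected_mass = expected_mass,
          area = 0, rt = NA_real_, width = NA_real_, skew = NA_real_,
          n_charge_states = 0L, valid = FALSE, reasons = "no_charge_states"))
      }
      fit <- fit_skewed_gaussian(ex$ecc)
      ass <- assess_peak(fit, ex$ecc, ex$eics, criteria)
      tibble::tibble(
        label = label, state = state, expected_mass = expected_mass,
        area = if (ass$valid) fit$area else 0,
        rt = fit$rt, width = fit$width, skew = fit$skew,
        n_charge_states = ass$n_charge_states, valid = ass$valid,
        reasons = paste(ass$reasons, collapse = ";"))
    })
  total <- sum(per_state$area[per_state$valid])
  modified_area <- sum(per_state$area[per_state$valid &
                                        per_state$label %in% modified_labels])
  structure(list(
    states = per_state,
    total_peptide_area = total,
    fraction_modified = if (total > 0) modified_area / total else NA_real_,
    detected = total > 0,
    modified_labels = modified_labels,
    sequence = read_peptide(sequence),
    instrument = instrument$name
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s on %s\n", x$sequence, x$instrument))
  print(x$states)
  if (x$detected) {
    cat(sprintf("fraction modified (%s): %.3f of total area %.4g\n",
                paste(x$modified_labels, collapse = "+"),
                x$fraction_modified, x$total_peptide_area))
  } else {
    cat("no valid peak for any state: peptide undetected\n")
  }
  invisible(x)
}
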