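# Ground-truth synthetic LC-MS generator: multi-charge-state ESI envelopes
# of peptide species eluting as skew-normal peaks, sampled as centroid scans
# with Poisson background noise. Everything is deterministic under the
# RunSpec seed, so pipeline accuracy can be measured against known truth.

#' Describe one eluting species
#'
#' @param expected_mass Uncharged mass of the species (average Da).
#' @param abundance Relative abundance (> 0); with the default normalised
#'   charge envelope, the species' integrated ECC area approaches
#'   `abundance`, so abundance ratios are the ground-truth fractions.
#' @param label State label carried into the ground truth (e.g.
#'   `"unmodified"`, `"modified"`).
#' @param rt Elution apex location parameter (minutes).
#' @param width Elution scale parameter (minutes).
#' @param skew Elution skew (dimensionless; 1 gives the mild tailing typical
#'   of reversed-phase peptide peaks).
#' @param charge_center,charge_spread Centre and spread (in charges) of the
#'   Gaussian charge envelope.
#' @return A `species_spec` list.
#' @export
species_spec <- function(expected_mass, abundance, label = "species",
                         rt = 3, width = 0.08, skew = 1,
                         charge_center = NULL, charge_spread = 3) {
  stopifnot(abundance > 0, width > 0, charge_spread > 0)
  structure(list(expected_mass = expected_mass, abundance = abundance,
                 label = label, rt = rt, width = width, skew = skew,
                 charge_center = charge_center,
                 charge_spread = charge_spread),
            class = "species_spec")
}

#' Describe a synthetic LC-MS run
#'
#' @param species List of [species_spec()] objects.
#' @param instrument An [instrument_profile()] or its name.
#' @param rt_window Acquisition window in minutes (default 1-6 min).
#' @param noise_rate Mean number of background noise peaks per scan
#'   (Poisson; default 5).
#' @param noise_mean Mean background peak intensity (exponential;
#'   default 2000, just above a typical vendor-export intensity floor).
#' @param seed Integer seed; mandatory, every run is deterministic given it.
#' @return A `run_spec` list.
#' @export
run_spec <- function(species, instrument = instrument_profile("QQQ"),
                     rt_window = c(1, 6), noise_rate = 5,
                     noise_mean = 2000, seed) {
  if (missing(seed) || is.na(seed)) abort("`seed` is mandatory for a run_spec.")
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(rt_window) == 2, rt_window[1] < rt_window[2],
            noise_rate >= 0, noise_mean > 0)
  structure(list(species = species, instrument = as_instrument(instrument),
                 rt_window = as.numeric(rt_window),
                 noise_rate = noise_rate, noise_mean = noise_mean,
                 seed = as.integer(seed)),
            class = "run_spec")
}

envelope_weights <- function(charges, center, spread, floor_frac = 1e-3) {
  w <- exp(-(charges - center)^2 / (2 * spread^2))
  w[w < floor_frac * max(w)] <- 0  # truncate vanishing charge states
  w / sum(w)
}

#' Simulate a centroided MS1 run
#'
#' Produces scans at the instrument scan interval across the run window.
#' Each species contributes, at every visible charge state, a centroid peak
#' at `[M+zH]z+` with intensity `abundance x envelope weight x skew-normal
#' elution density` at that scan time; weights are normalised over the
#' visible charges (vanishing tail charges truncated), so each species'
#' summed intensity integrates to its abundance. Poisson background peaks
#' (uniform m/z over the scan window, exponential intensities) are added on
#' top. Deterministic given the spec seed.
#'
#' @param spec A [run_spec()].
#' @return A list: `signals` (signal table) and `truth` (list with per-
#'   species table and `fraction_modified` = modified abundance / total).
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "run_spec"))
  inst <- spec$instrument
  scan_rt <- seq(spec$rt_window[1], spec$rt_window[2],
                 by = inst$scan_interval / 60)

  species_tbl <- purrr::map_dfr(spec$species, function(sp) {
    charges <- charges_in_range(sp$expected_mass, inst$scan_mz_range[1],
                                inst$scan_mz_range[2])
    if (length(charges) == 0L) {
      abort(sprintf(
        "Species '%s' (%.1f Da) has no charge state in the %s scan window.",
        sp$label, sp$expected_mass, inst$name))
    }
    center <- sp$charge_center %||% charges[which.min(
      abs(mz_for_charge(sp$expected_mass, charges) -
            mean(inst$scan_mz_range)))]
    w <- envelope_weights(charges, center, sp$charge_spread)
    tibble::tibble(label = sp$label, expected_mass = sp$expected_mass,
                   abundance = sp$abundance, rt = sp$rt, width = sp$width,
                   skew = sp$skew, charges = list(charges), weights = list(w))
  })

  signals <- withr::with_seed(spec$seed, {
    sig <- purrr::pmap_dfr(species_tbl, function(label, expected_mass,
                                                 abundance, rt, width, skew,
                                                 charges, weights, ...) {
      elution <- skew_gaussian(scan_rt, area = 1, rt = rt, width = width,
                               skew = skew, baseline = 0)
      keep_z <- weights > 0
      purrr::map2_dfr(charges[keep_z], weights[keep_z], function(z, w) {
        tibble::tibble(rt = scan_rt,
                       mz = mz_for_charge(expected_mass, z),
                       intensity = abundance * w * elution)
      })
    })
    sig <- dplyr::filter(sig, .data$intensity > 0)
    if (spec$noise_rate > 0) {
      n_noise <- rpois(length(scan_rt), spec$noise_rate)
      noise <- tibble::tibble(
        rt = rep(scan_rt, n_noise),
        mz = runif(sum(n_noise), inst$scan_mz_range[1],
                   inst$scan_mz_range[2]),
        intensity = rexp(sum(n_noise), rate = 1 / spec$noise_mean))
      sig <- dplyr::bind_rows(sig, noise)
    }
    sig
  })

  total_ab <- sum(purrr::map_dbl(spec$species, "abundance"))
  mod_ab <- sum(purrr::map_dbl(
    spec$species, function(sp) if (sp$label == "modified") sp$abundance else 0))
  list(
    signals = new_signal_tbl(signals, source = "simulate_run",
                             instrument = inst),
    truth = list(
      species = dplyr::select(species_tbl, -"charges", -"weights"),
      fraction_modified = mod_ab / total_ab,
      seed = spec$seed)
  )
}

#' Simulate an MS/MS spectrum of a peptide structure
#'
#' Injects a random subset of the structure's hypothetical ions (each kept
#' with probability `efficiency`) with log-normal intensities, plus
#' uniform-m/z exponential-intensity noise peaks, and reports the injected
#' ions as ground truth. Centroided MS/MS spectra are dominated in peak
#' count by low-level chemical and electronic background, so the default
#' background has many more peaks than the fragment signal, at far lower
#' intensity - the regime the sliced background filter is designed for.
#'
#' @param structure A [peptide_structure()].
#' @param efficiency Per-ion injection probability in `[0, 1]`.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   for injected fragment peaks.
#' @param n_noise Number of background noise peaks.
#' @param noise_mean Mean noise intensity (exponential).
#' @param max_charge Highest fragment charge simulated.
#' @param seed Integer seed (mandatory).
#' @return A list: `spectrum` (a [spectrum()]) and `truth` (tibble of
#'   injected ions).
#' @export
simulate_msms <- function(structure, efficiency = 0.8,
                          intensity_meanlog = log(1e5),
                          intensity_sdlog = 0.5,
                          n_noise = 500, noise_mean = 100,
                          max_charge = 3L, seed) {
  if (missing(seed) || is.na(seed)) abort("`seed` is mandatory.")
  stopifnot(efficiency >= 0, efficiency <= 1)
  ions <- hypothetical_ions(structure, max_charge = max_charge)
  withr::with_seed(as.integer(seed), {
    injected <- ions[runif(nrow(ions)) < efficiency, ]
    peaks <- tibble::tibble(
      mz = injected$mz,
      intensity = rlnorm(nrow(injected), intensity_meanlog, intensity_sdlog))
    if (n_noise > 0) {
      mz_range <- range(c(100, ions$mz))
      peaks <- dplyr::bind_rows(peaks, tibble::tibble(
        mz = runif(n_noise, mz_range[1], mz_range[2]),
        intensity = rexp(n_noise, rate = 1 / noise_mean)))
    }
    list(spectrum = spectrum(peaks$mz, peaks$intensity,
                             meta = "simulate_msms"),
         truth = injected)
  })
}
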