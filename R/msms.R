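# MS/MS preprocessing and b/y hypothetical-ion annotation for modified,
# possibly macrocyclic, peptides. All fragment masses are monoisotopic.

#' Construct an MS/MS spectrum
#'
#' A centroid MS/MS spectrum as a tidy peak list.
#'
#' @param mz Peak m/z values (> 0).
#' @param intensity Peak intensities (>= 0).
#' @param precursor_mz Optional precursor m/z.
#' @param meta Optional label.
#' @return A `spectrum` tibble with columns `mz`, `intensity`.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NULL, meta = NULL) {
  if (any(mz <= 0)) abort("Spectrum m/z values must be positive.")
  if (any(intensity < 0)) abort("Spectrum intensities must be >= 0.")
  tbl <- tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  tbl <- dplyr::arrange(tbl, .data$mz)
  class(tbl) <- c("spectrum", class(tbl))
  attr(tbl, "precursor_mz") <- precursor_mz
  attr(tbl, "meta") <- meta
  tbl
}

#' Read a spectrum from a two-column TSV
#'
#' Columns `mz` and `intensity`; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A [spectrum()].
#' @export
read_spectrum_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  spectrum(tbl$mz, tbl$intensity, meta = path)
}

#' Cap spectrum intensities at a ceiling
#'
#' Dynamic-range compression before annotation: every intensity is capped at
#' `ceiling_multiplier` times the mean peak intensity of the spectrum, so a
#' few dominant ions do not mask the rest.
#'
#' @param spec A [spectrum()].
#' @param ceiling_multiplier Positive multiplier of the mean intensity.
#' @return The capped spectrum.
#' @export
cap_intensities <- function(spec, ceiling_multiplier) {
  if (nrow(spec) == 0L) abort("Spectrum is empty.")
  stopifnot(ceiling_multiplier > 0)
  ceiling_val <- ceiling_multiplier * mean(spec$intensity)
  out <- dplyr::mutate(spec, intensity = pmin(.data$intensity, ceiling_val))
  class(out) <- class(spec)
  out
}

#' Remove background peaks in m/z slices
#'
#' The spectrum's m/z range is divided into `n_slices` equal-width windows;
#' each slice's noise level is the mean intensity over the slice and its
#' existing flanking slices (no wraparound at the edges), and peaks strictly
#' below `snr_threshold` times that level are removed.
#'
#' @param spec A [spectrum()].
#' @param n_slices Number of windows (>= 1).
#' @param snr_threshold Signal-to-noise multiplier.
#' @return The filtered spectrum.
#' @export
remove_background <- function(spec, n_slices, snr_threshold) {
  stopifnot(n_slices >= 1, snr_threshold >= 0)
  if (nrow(spec) == 0L) return(spec)
  rng <- range(spec$mz)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_slices + 1)
  slice <- pmin(pmax(findInterval(spec$mz, edges, rightmost.closed = TRUE),
                     1L), n_slices)
  keep <- rep(TRUE, nrow(spec))
  for (s in seq_len(n_slices)) {
    nb <- intersect((s - 1L):(s + 1L), seq_len(n_slices))
    pool <- spec$intensity[slice %in% nb]
    if (length(pool) == 0L) next
    thr <- snr_threshold * mean(pool)
    keep[slice == s & spec$intensity < thr] <- FALSE
  }
  out <- spec[keep, ]
  class(out) <- class(spec)
  out
}

#' Describe a modified, possibly macrocyclic, peptide
#'
#' Pairs a sequence with residue-localised monoisotopic modification deltas
#' and crosslink spans (e.g. lanthionine or lactone macrocycles). Crosslink
#' spans may nest but not partially overlap; backbone cleavage sites
#' strictly inside a span produce no open fragments.
#'
#' @param sequence Peptide sequence.
#' @param residue_deltas Named numeric vector: names are 1-based residue
#'   positions, values are monoisotopic mass deltas carried by that residue.
#' @param crosslinks List of length-2 integer vectors `c(start, end)`
#'   (1-based residue positions, start < end).
#' @return A `peptide_structure` list.
#' @export
peptide_structure <- function(sequence, residue_deltas = NULL,
                              crosslinks = list()) {
  sequence <- read_peptide(sequence)
  L <- nchar(sequence)
  if (!is.null(residue_deltas) && length(residue_deltas) > 0) {
    pos <- as.integer(names(residue_deltas))
    if (anyNA(pos) || any(pos < 1L) || any(pos > L)) {
      abort("`residue_deltas` positions must be 1-based and within the sequence.")
    }
  } else {
    residue_deltas <- numeric(0)
  }
  crosslinks <- purrr::map(crosslinks, function(x) {
    x <- as.integer(x)
    if (length(x) != 2L || x[1] >= x[2] || x[1] < 1L || x[2] > L) {
      abort("Each crosslink must be c(start, end) with 1 <= start < end <= length.")
    }
    x
  })
  if (length(crosslinks) > 1L) {
    for (i in seq_along(crosslinks)) for (j in seq_along(crosslinks)) {
      if (i >= j) next
      a <- crosslinks[[i]]; b <- crosslinks[[j]]
      disjoint <- a[2] <= b[1] || b[2] <= a[1]
      nested <- (a[1] <= b[1] && b[2] <= a[2]) || (b[1] <= a[1] && a[2] <= b[2])
      if (!disjoint && !nested) {
        abort("Crosslink spans may nest but not partially overlap.")
      }
    }
  }
  structure(list(sequence = sequence, residue_deltas = residue_deltas,
                 crosslinks = crosslinks),
            class = "peptide_structure")
}

suppressed_sites <- function(structure) {
  # cleavage site k sits between residues k and k+1; it is suppressed when
  # strictly inside a crosslink span [a, b], i.e. a <= k < b
  L <- nchar(structure$sequence)
  supp <- rep(FALSE, L - 1L)
  for (cl in structure$crosslinks) {
    supp[seq.int(cl[1], cl[2] - 1L)] <- TRUE
  }
  supp
}

#' Hypothetical b/y and parent ions of a peptide structure
#'
#' Iteratively truncates the peptide backbone from the C-terminus (b ions)
#' and N-terminus (y ions), carrying the deltas of the residues each
#' fragment retains: `b_k` = sum of the first k residue masses (+ deltas);
#' `y_k` = sum of the last k residue masses (+ deltas) + water; the parent
#' is the full peptide + all deltas + water. Each ion is emitted as
#' `[M+zH]z+` at charges 1..`max_charge`. Cleavage sites strictly inside a
#' crosslink span are suppressed. Monoisotopic masses throughout.
#'
#' @param structure A [peptide_structure()].
#' @param max_charge Highest charge state emitted (default 3).
#' @return A tibble: `series` (`b`/`y`/`parent`), `index` (residues
#'   retained; `NA` for parent), `site` (cleavage site supported), `charge`,
#'   `formula_mass` (uncharged Da) and `mz`.
#' @export
hypothetical_ions <- function(structure, max_charge = 3L) {
  stopifnot(inherits(structure, "peptide_structure"), max_charge >= 1L)
  seq_codes <- strsplit(structure$sequence, "")[[1]]
  L <- length(seq_codes)
  res <- residue_mass(seq_codes, "monoisotopic")
  deltas <- rep(0, L)
  if (length(structure$residue_deltas) > 0) {
    deltas[as.integer(names(structure$residue_deltas))] <-
      deltas[as.integer(names(structure$residue_deltas))] +
      as.numeric(structure$residue_deltas)
  }
  per_res <- res + deltas
  supp <- if (L > 1L) suppressed_sites(structure) else logical(0)

  frags <- tibble::tibble(series = character(0), index = integer(0),
                          site = integer(0), formula_mass = numeric(0))
  if (L > 1L) {
    csum <- cumsum(per_res)
    for (k in seq_len(L - 1L)) {
      if (supp[k]) next  # b_k breaks site k
      frags <- dplyr::bind_rows(frags, tibble::tibble(
        series = "b", index = k, site = k, formula_mass = csum[k]))
    }
    rsum <- rev(cumsum(rev(per_res)))
    for (k in seq_len(L - 1L)) {
      site <- L - k  # y_k breaks site L-k
      if (supp[site]) next
      frags <- dplyr::bind_rows(frags, tibble::tibble(
        series = "y", index = k, site = site,
        formula_mass = rsum[L - k + 1L] + water_mass("monoisotopic")))
    }
  }
  parent <- tibble::tibble(series = "parent", index = NA_integer_,
                           site = NA_integer_,
                           formula_mass = sum(per_res) +
                             water_mass("monoisotopic"))
  ions <- dplyr::bind_rows(frags, parent)
  ions <- tidyr::crossing(ions, charge = seq_len(max_charge))
  ions <- dplyr::mutate(ions, mz = mz_for_charge(.data$formula_mass,
                                                 .data$charge))
  dplyr::arrange(ions, .data$series, .data$index, .data$charge)
}

#' Match hypothetical ions against a filtered spectrum
#'
#' Each ion is matched to the nearest spectrum peak within the m/z
#' tolerance (ties broken towards the smaller m/z); one peak may support
#' several ions. Coverage is the fraction of non-suppressed backbone
#' cleavage sites supported by at least one matched b or y ion.
#'
#' @param spec A preprocessed [spectrum()] (see [cap_intensities()] and
#'   [remove_background()]).
#' @param ions Hypothetical ions from [hypothetical_ions()].
#' @param match_tolerance m/z tolerance.
#' @return An `annotation_result`: `matches` tibble (ion columns plus
#'   `matched_mz`, `matched_intensity`, `error_mz`), `n_matched`, and
#'   `coverage`.
#' @export
match_ions <- function(spec, ions, match_tolerance) {
  stopifnot(match_tolerance > 0)
  matched <- purrr::pmap_dfr(ions, function(series, index, site, charge,
                                            formula_mass, mz, ...) {
    row <- tibble::tibble(series = series, index = index, site = site,
                          charge = charge, formula_mass = formula_mass,
                          mz = mz, matched_mz = NA_real_,
                          matched_intensity = NA_real_, error_mz = NA_real_)
    if (nrow(spec) > 0L) {
      d <- abs(spec$mz - mz)
      j <- which(d == min(d))[1]  # spectrum sorted ascending: tie -> smaller mz
      if (d[j] <= match_tolerance) {
        row$matched_mz <- spec$mz[j]
        row$matched_intensity <- spec$intensity[j]
        row$error_mz <- spec$mz[j] - mz
      }
    }
    row
  })
  hits <- dplyr::filter(matched, !is.na(.data$matched_mz))
  sites_all <- sort(unique(matched$site[matched$series %in% c("b", "y")]))
  sites_hit <- sort(unique(hits$site[hits$series %in% c("b", "y")]))
  structure(list(
    matches = matched,
    n_matched = nrow(hits),
    n_ions = nrow(matched),
    coverage = if (length(sites_all) == 0L) NA_real_
               else length(sites_hit) / length(sites_all)
  ), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %d/%d ions matched; site coverage %s\n",
              x$n_matched, x$n_ions,
              if (is.na(x$coverage)) "NA" else sprintf("%.0f%%",
                                                       100 * x$coverage)))
  invisible(x)
}

#' Annotate an MS/MS spectrum of a modified peptide
#'
#' Convenience wrapper chaining [cap_intensities()], [remove_background()],
#' [hypothetical_ions()] and [match_ions()].
#'
#' @param spec A raw [spectrum()].
#' @param structure A [peptide_structure()].
#' @param ceiling_multiplier Intensity-cap multiplier (default 5).
#' @param n_slices Background-removal windows (default 10).
#' @param snr_threshold Background signal-to-noise multiplier (default 2).
#' @param match_tolerance m/z match tolerance (default 0.05).
#' @param max_charge Highest fragment charge (default 3).
#' @return An `annotation_result`.
#' @export
annotate_spectrum <- function(spec, structure, ceiling_multiplier = 5,
                              n_slices = 10L, snr_threshold = 2,
                              match_tolerance = 0.05, max_charge = 3L) {
  filtered <- spec |>
    cap_intensities(ceiling_multiplier) |>
    remove_background(n_slices, snr_threshold)
  ions <- hypothetical_ions(structure, max_charge = max_charge)
  match_ions(filtered, ions, match_tolerance)
}
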