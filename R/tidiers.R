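# broom-style tidiers for the package's result objects.

#' Tidy a deconvolution result
#'
#' @param x A `deconv_result` from [deconvolve()].
#' @param ... Unused.
#' @return One row per ladder peak: `mz`, `charge`, `mass`.
#' @exportS3Method generics::tidy
tidy.deconv_result <- function(x, ...) {
  tibble::tibble(mz = x$mz_values, charge = x$charges,
                 mass = x$per_peak_masses)
}

#' @rdname tidy.deconv_result
#' @return `glance()`: one row with `mean_mass`, `sample_sd`,
#'   `resolution_floor`, `reported_sd`, `z1`, `z5`, `instrument`.
#' @exportS3Method generics::glance
glance.deconv_result <- function(x, ...) {
  tibble::tibble(mean_mass = x$mean_mass, sample_sd = x$sample_sd,
                 resolution_floor = x$resolution_floor,
                 reported_sd = x$reported_sd,
                 z1 = max(x$charges), z5 = min(x$charges),
                 instrument = x$instrument)
}

#' Tidy a quantification result
#'
#' @param x A `quant_result` from [fraction_modified()].
#' @param ... Unused.
#' @return The per-state table: label, expected mass, fitted peak
#'   parameters, validity and failure reasons.
#' @exportS3Method generics::tidy
tidy.quant_result <- function(x, ...) x$states

#' @rdname tidy.quant_result
#' @return `glance()`: one row with `fraction_modified`,
#'   `total_peptide_area`, `n_states`, `n_valid`, `detected`, `instrument`.
#' @exportS3Method generics::glance
glance.quant_result <- function(x, ...) {
  tibble::tibble(fraction_modified = x$fraction_modified,
                 total_peptide_area = x$total_peptide_area,
                 n_states = nrow(x$states), n_valid = sum(x$states$valid),
                 detected = x$detected, instrument = x$instrument)
}

#' Tidy an annotation result
#'
#' @param x An `annotation_result` from [match_ions()] or
#'   [annotate_spectrum()].
#' @param ... Unused.
#' @return One row per hypothetical ion with its match, if any.
#' @exportS3Method generics::tidy
tidy.annotation_result <- function(x, ...) x$matches

#' @rdname tidy.annotation_result
#' @return `glance()`: one row with `n_ions`, `n_matched`, `coverage`.
#' @exportS3Method generics::glance
glance.annotation_result <- function(x, ...) {
  tibble::tibble(n_ions = x$n_ions, n_matched = x$n_matched,
                 coverage = x$coverage)
}

#' Tidy a fitted chromatographic peak
#'
#' @param x A `peak_fit` from [fit_skewed_gaussian()].
#' @param ... Unused.
#' @return One row with the fitted parameters and convergence flag.
#' @exportS3Method generics::tidy
tidy.peak_fit <- function(x, ...) {
  tibble::tibble(area = x$area, rt = x$rt, width = x$width, skew = x$skew,
                 baseline = x$baseline, converged = x$converged)
}
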