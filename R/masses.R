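# Residue (water-subtracted) masses of the 20 canonical amino acids, in Da.
# Values are the standard monoisotopic and average residue masses, stated to
# 5 decimals (monoisotopic) / 4 decimals (average).

#' Residue mass table
#'
#' Standard residue masses (the mass of an amino acid minus one water) for the
#' 20 canonical residues, on both the monoisotopic and the average
#' (molar-weight) scale. Intact-mass quantification works on the average
#' scale; fragment-ion work uses monoisotopic masses.
#'
#' @format A tibble with 20 rows and columns `code` (one-letter residue code),
#'   `monoisotopic` (Da) and `average` (Da).
#' @export
residue_masses <- tibble::tibble(
  code = c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
           "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
  monoisotopic = c(
    57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
    101.04768, 103.00919, 113.08406, 113.08406, 114.04293,
    115.02694, 128.05858, 128.09496, 129.04259, 131.04049,
    137.05891, 147.06841, 156.10111, 163.06333, 186.07931),
  average = c(
    57.0519, 71.0788, 87.0782, 97.1167, 99.1326,
    101.1051, 103.1388, 113.1594, 113.1594, 114.1038,
    115.0886, 128.1307, 128.1741, 129.1155, 131.1926,
    137.1411, 147.1766, 156.1875, 163.1760, 186.2132)
)

#' Physical constants used in m/z arithmetic
#'
#' `water_mass()` returns the mass of H2O on the requested scale;
#' `proton_mass()` returns the mass of a proton (1.00728 Da), the charge
#' carrier assumed for all `[M+zH]z+` species.
#'
#' @param scale `"average"` or `"monoisotopic"`.
#' @return A mass in Da.
#' @export
water_mass <- function(scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (scale == "average") 18.01528 else 18.010565
}

#' @rdname water_mass
#' @export
proton_mass <- function() 1.00728

#' Mass of a single residue
#'
#' Looks up the water-subtracted residue mass of one canonical amino acid.
#'
#' @param code One-letter residue code (one of the 20 canonical residues).
#' @param scale `"average"` (default, used for intact-mass work) or
#'   `"monoisotopic"` (used for fragment ions).
#' @return Residue mass in Da.
#' @examples
#' residue_mass("G", "monoisotopic")
#' @export
residue_mass <- function(code, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  idx <- match(code, residue_masses$code)
  if (anyNA(idx)) {
    bad <- unique(code[is.na(idx)])
    abort(paste0("Unknown residue code(s): ", paste(bad, collapse = ", ")))
  }
  residue_masses[[scale]][idx]
}

check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string of residue codes.")
  }
  codes <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(codes), residue_masses$code)
  if (length(bad) > 0) {
    abort(paste0("Non-canonical residue code(s) in sequence: ",
                 paste(bad, collapse = ", ")))
  }
  codes
}

#' Molar mass of a peptide
#'
#' Sum of residue masses plus one water, i.e. the uncharged mass of the
#' linear peptide with free termini.
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @inheritParams residue_mass
#' @return Peptide mass in Da.
#' @examples
#' peptide_mass("GAS")                  # average molar mass
#' peptide_mass("GAS", "monoisotopic")
#' @export
peptide_mass <- function(sequence, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  codes <- check_peptide(sequence)
  sum(residue_mass(codes, scale)) + water_mass(scale)
}

#' Read a peptide sequence from a string or FASTA file
#'
#' Accepts either a plain sequence string or the path of a single-record
#' FASTA file and returns the validated sequence.
#'
#' @param x A sequence string or a path to a FASTA file.
#' @return The peptide sequence as a single uppercase string.
#' @export
read_peptide <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    abort("`x` must be a single string (sequence or FASTA path).")
  }
  if (file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    headers <- grepl("^>", lines)
    if (!headers[1] || sum(headers) != 1L) {
      abort("FASTA input must contain exactly one record.")
    }
    x <- paste(lines[!headers], collapse = "")
  }
  x <- toupper(gsub("\\s", "", x))
  check_peptide(x)
  x
}
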