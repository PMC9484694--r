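#' Define a post-translational modification
#'
#' A modification is a named mass delta with a maximum number of occurrences
#' on a peptide and, optionally, the residues it targets. Deltas are signed:
#' dehydration is -18.0153 Da (average), phosphorylation +79.9663 Da, and so
#' on.
#'
#' @param name Modification label.
#' @param delta_average Signed average-mass shift per occurrence (Da).
#' @param delta_monoisotopic Signed monoisotopic mass shift per occurrence
#'   (Da).
#' @param count Maximum number of occurrences (positive integer).
#' @param targets Optional character vector (or comma-separated string) of
#'   residue codes the modification can land on; `NA` means unrestricted.
#' @return A one-row tibble; rows from several calls can be bound into a
#'   registry with [dplyr::bind_rows()].
#' @examples
#' modification("dehydration", -18.0153, -18.01056, count = 3,
#'              targets = c("S", "T"))
#' @export
modification <- function(name, delta_average, delta_monoisotopic,
                         count = 1L, targets = NA_character_) {
  if (!is.numeric(delta_average) || !is.finite(delta_average) ||
      !is.numeric(delta_monoisotopic) || !is.finite(delta_monoisotopic)) {
    abort("Modification deltas must be finite numbers.")
  }
  count <- as.integer(count)
  if (is.na(count) || count < 1L) abort("`count` must be a positive integer.")
  if (length(targets) > 1L) targets <- paste(targets, collapse = ",")
  tibble::tibble(
    name = as.character(name),
    delta_average = as.numeric(delta_average),
    delta_monoisotopic = as.numeric(delta_monoisotopic),
    count = count,
    targets = as.character(targets)
  )
}

#' Reference modification registry
#'
#' Ships average and monoisotopic mass shifts for common RiPP chemistries as
#' reference values: dehydration (Ser/Thr/Cys water loss), phosphorylation,
#' thioether (lanthionine) formation, hexosylation, and lactone formation.
#' These are convenience defaults; real analyses should supply a registry
#' tailored to the enzyme under study (see [read_modifications()]).
#'
#' @return A modification registry tibble.
#' @export
default_modifications <- function() {
  dplyr::bind_rows(
    modification("dehydration",     -18.0153,  -18.01056, 1L, c("S", "T", "C")),
    modification("phosphorylation",  79.9799,   79.96633, 1L, c("S", "T", "Y")),
    modification("thioether",        -2.0159,   -2.01565, 1L, NA_character_),
    modification("hexosylation",    162.1424,  162.05282, 1L, NA_character_),
    modification("lactone",         -18.0153,  -18.01056, 1L, c("S", "T"))
  )
}

#' Read or write a modification registry
#'
#' Registries are plain tables with columns `name`, `delta_average`,
#' `delta_monoisotopic`, `count`, `targets`; both TSV and YAML (a list of
#' per-modification mappings) are supported, chosen by file extension.
#'
#' @param path File path ending in `.tsv`, `.yaml` or `.yml`.
#' @param mods A registry tibble (for writing).
#' @return `read_modifications()` returns a registry tibble.
#' @export
read_modifications <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (grepl("\\.(yaml|yml)$", path)) {
    entries <- yaml::read_yaml(path)
    mods <- purrr::map_dfr(entries, function(e) {
      modification(e$name, e$delta_average, e$delta_monoisotopic,
                   e$count %||% 1L,
                   if (is.null(e$targets)) NA_character_ else unlist(e$targets))
    })
  } else {
    mods <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    mods <- purrr::pmap_dfr(mods, function(name, delta_average,
                                           delta_monoisotopic, count,
                                           targets, ...) {
      modification(name, delta_average, delta_monoisotopic, count, targets)
    })
  }
  mods
}

#' @rdname read_modifications
#' @export
write_modifications <- function(mods, path) {
  readr::write_tsv(mods, path)
  invisible(path)
}

check_registry <- function(mods, sequence) {
  stopifnot(is.data.frame(mods))
  needed <- c("name", "delta_average", "delta_monoisotopic", "count")
  missing <- setdiff(needed, names(mods))
  if (length(missing) > 0) {
    abort(paste0("Modification registry lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"targets" %in% names(mods)) mods$targets <- NA_character_
  codes <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(mods))) {
    tg <- mods$targets[i]
    if (!is.na(tg)) {
      tcodes <- strsplit(gsub("\\s", "", tg), ",")[[1]]
      n_sites <- sum(codes %in% tcodes)
      if (mods$count[i] > n_sites) {
        abort(sprintf(
          "Modification '%s' needs %d site(s) among [%s] but '%s' has only %d.",
          mods$name[i], mods$count[i], tg, sequence, n_sites))
      }
    }
  }
  mods
}

#' Enumerate modification states of a peptide
#'
#' Builds the set of expected species for an extract: the unmodified peptide,
#' the fully modified peptide (every registered modification at its full
#' count), and - only for modifications whose individual mass shift is at
#' least `partial_threshold` Da in magnitude - every intermediate occupancy.
#' Smaller shifts are not chromatographically resolvable as partial states on
#' a unit-resolution instrument, so their intermediates are skipped.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification registry tibble (see [modification()]).
#' @param partial_threshold Minimum |average delta| (Da) for intermediate
#'   occupancies to be enumerated; default 15.
#' @return A tibble with one row per state: `label`
#'   (`unmodified`/`partial`/`modified`), `state` (readable description),
#'   `applied` (list column of named occupancy counts), `expected_mass`
#'   (average Da) and `expected_mass_mono` (monoisotopic Da), sorted by
#'   `expected_mass`.
#' @examples
#' dehyd <- modification("dehydration", -18.0153, -18.01056, count = 3,
#'                       targets = c("S", "T"))
#' enumerate_states("GASSAST", dehyd)
#' @export
enumerate_states <- function(sequence, mods = NULL, partial_threshold = 15) {
  sequence <- read_peptide(sequence)
  base_avg <- peptide_mass(sequence, "average")
  base_mono <- peptide_mass(sequence, "monoisotopic")

  if (is.null(mods) || nrow(mods) == 0L) {
    return(tibble::tibble(
      label = "unmodified", state = "unmodified",
      applied = list(integer(0)),
      expected_mass = base_avg, expected_mass_mono = base_mono))
  }
  mods <- check_registry(mods, sequence)

  occupancies <- purrr::map(seq_len(nrow(mods)), function(i) {
    if (abs(mods$delta_average[i]) >= partial_threshold) {
      0:mods$count[i]
    } else {
      c(0L, mods$count[i])
    }
  })
  grid <- do.call(expand.grid, occupancies)
  names(grid) <- mods$name

  states <- purrr::pmap_dfr(grid, function(...) {
    k <- unlist(list(...))
    full <- all(k == mods$count)
    none <- all(k == 0L)
    desc <- if (none) "unmodified" else {
      paste(sprintf("%dx %s", k[k > 0], mods$name[k > 0]), collapse = " + ")
    }
    tibble::tibble(
      label = if (none) "unmodified" else if (full) "modified" else "partial",
      state = if (full) paste0("modified (", desc, ")") else desc,
      applied = list(setNames(as.integer(k), mods$name)),
      expected_mass = base_avg + sum(k * mods$delta_average),
      expected_mass_mono = base_mono + sum(k * mods$delta_monoisotopic)
    )
  })
  states <- dplyr::distinct(states, .data$label, .data$state,
                            .keep_all = TRUE)
  dplyr::arrange(states, .data$expected_mass)
}

#' Mass of a modification state
#'
#' The expected uncharged mass of a peptide carrying a given set of
#' modification occupancies.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification registry.
#' @param applied Named integer vector of occupancy counts (names matching
#'   `mods$name`); missing names mean zero occupancy.
#' @inheritParams residue_mass
#' @return Mass in Da.
#' @export
state_mass <- function(sequence, mods, applied,
                       scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  base <- peptide_mass(sequence, scale)
  if (is.null(mods) || nrow(mods) == 0L || length(applied) == 0L) return(base)
  idx <- match(names(applied), mods$name)
  if (anyNA(idx)) {
    abort(paste0("Unknown modification(s): ",
                 paste(names(applied)[is.na(idx)], collapse = ", ")))
  }
  over <- applied > mods$count[idx]
  if (any(over)) {
    abort(paste0("Occupancy exceeds registered count for: ",
                 paste(names(applied)[over], collapse = ", ")))
  }
  delta_col <- if (scale == "average") "delta_average" else "delta_monoisotopic"
  base + sum(applied * mods[[delta_col]][idx])
}
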