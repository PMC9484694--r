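# Long-form centroided MS1 signals: one row per centroid peak, columns
# rt (minutes), mz, intensity. Scan boundaries are recoverable by grouping
# on rt.

new_signal_tbl <- function(records, source = NA_character_,
                           instrument = NULL) {
  tbl <- tibble::as_tibble(records)
  stopifnot(all(c("rt", "mz", "intensity") %in% names(tbl)))
  if (any(tbl$intensity < 0)) abort("Intensities must be >= 0.")
  if (any(tbl$rt < 0)) abort("Retention times must be >= 0.")
  tbl <- dplyr::arrange(tbl, .data$rt, .data$mz)
  attr(tbl, "source") <- source
  attr(tbl, "instrument") <- if (is.null(instrument)) NULL
                             else as_instrument(instrument)$name
  tbl
}

#' Construct a signal table
#'
#' Wraps long-form centroid records (one row per peak) into the tidy signal
#' table used throughout the package.
#'
#' @param rt Retention times in minutes.
#' @param mz m/z values.
#' @param intensity Intensities (arbitrary units, >= 0).
#' @param source Provenance label.
#' @param instrument Optional [instrument_profile()] or its name.
#' @return A tibble with columns `rt`, `mz`, `intensity`, sorted by
#'   `(rt, mz)`, carrying `source` and `instrument` attributes.
#' @export
signal_table <- function(rt, mz, intensity, source = "memory",
                         instrument = NULL) {
  new_signal_tbl(tibble::tibble(rt = as.numeric(rt), mz = as.numeric(mz),
                                intensity = as.numeric(intensity)),
                 source = source, instrument = instrument)
}

parse_mzxml_rt <- function(rt) {
  # ISO-8601 durations like "PT12.3S" (seconds) or "PT1.2M"; bare numbers are
  # taken as seconds.
  rt <- trimws(rt)
  secs <- ifelse(
    grepl("^PT.*S$", rt), as.numeric(sub("^PT(.*)S$", "\\1", rt)),
    ifelse(grepl("^PT.*M$", rt), 60 * as.numeric(sub("^PT(.*)M$", "\\1", rt)),
           as.numeric(rt)))
  secs / 60
}

decode_peaks <- function(b64, precision) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  size <- if (precision == 32) 4L else 8L
  vals <- readBin(raw, what = "double", n = length(raw) %/% size,
                  size = size, endian = "big")
  list(mz = vals[c(TRUE, FALSE)], intensity = vals[c(FALSE, TRUE)])
}

#' Read centroided MS1 signals from an mzXML file
#'
#' Parses scans at the requested MS level into a long-form signal table,
#' converting retention times to minutes and dropping peaks below the
#' minimum intensity (vendor exports apply the same per-peak floor, 1000 by
#' default). Profile-mode scans are accepted with a warning; scans at other
#' MS levels are dropped.
#'
#' @param path Path to an mzXML file (uncompressed peak data, network byte
#'   order, 32- or 64-bit).
#' @param min_intensity Per-peak intensity floor; default 1000.
#' @param ms_level MS level to keep; default 1.
#' @return A signal table (see [signal_table()]).
#' @export
read_mzxml <- function(path, min_intensity = 1000, ms_level = 1) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("Not readable XML: ", path)))
  xml2::xml_ns_strip(doc)
  if (!length(xml2::xml_find_all(doc, "//msRun"))) {
    abort(paste0("Not an mzXML document (no msRun element): ", path))
  }
  scans <- xml2::xml_find_all(doc, "//scan")
  keep <- xml2::xml_attr(scans, "msLevel") == as.character(ms_level)
  n_dropped <- sum(!keep, na.rm = TRUE)
  if (n_dropped > 0) {
    message(sprintf("Dropped %d scan(s) at other MS levels.", n_dropped))
  }
  scans <- scans[keep & !is.na(keep)]
  if (any(xml2::xml_attr(scans, "centroided") %in% "0")) {
    warn("File contains profile-mode scans; treating peaks as centroids.")
  }
  recs <- purrr::map_dfr(scans, function(sc) {
    rt_min <- parse_mzxml_rt(xml2::xml_attr(sc, "retentionTime"))
    pk <- xml2::xml_find_first(sc, "./peaks")
    n <- as.integer(xml2::xml_attr(sc, "peaksCount"))
    if (is.na(n) || n == 0L) {
      return(tibble::tibble(rt = numeric(0), mz = numeric(0),
                            intensity = numeric(0)))
    }
    prec <- as.integer(xml2::xml_attr(pk, "precision") %||% "32")
    vals <- decode_peaks(xml2::xml_text(pk), prec)
    tibble::tibble(rt = rt_min, mz = vals$mz, intensity = vals$intensity)
  })
  if (nrow(recs) == 0L) {
    recs <- tibble::tibble(rt = numeric(0), mz = numeric(0),
                           intensity = numeric(0))
  }
  recs <- dplyr::filter(recs, .data$intensity >= min_intensity)
  new_signal_tbl(recs, source = path)
}

#' Write a signal table to mzXML
#'
#' Serialises a signal table as a minimal centroided MS1 mzXML file (64-bit
#' network-order peak data) that [read_mzxml()] reads back with exact record
#' recovery.
#'
#' @param table A signal table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(table, path) {
  stopifnot(is.data.frame(table))
  scans <- if (nrow(table) > 0) split(table, table$rt) else list()
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', length(scans))), con)
  num <- 0L
  for (sc in scans) {
    num <- num + 1L
    rt_s <- sc$rt[1] * 60
    interleaved <- as.numeric(rbind(sc$mz, sc$intensity))
    b64 <- jsonlite::base64_enc(writeBin(interleaved, raw(), size = 8L,
                                         endian = "big"))
    writeLines(sprintf(
      paste0('  <scan num="%d" msLevel="1" peaksCount="%d" centroided="1"',
             ' retentionTime="PT%.6fS">'), num, nrow(sc), rt_s), con)
    writeLines(paste0(
      '   <peaks precision="64" byteOrder="network"',
      ' contentType="m/z-int" compressionType="none">',
      gsub("\\n", "", b64), '</peaks>'), con)
    writeLines('  </scan>', con)
  }
  writeLines(c(' </msRun>', '</mzXML>'), con)
  invisible(path)
}

#' Read or write a signal table as TSV
#'
#' A plain-text fixture format: columns `rt_min`, `mz`, `intensity`, with a
#' `# instrument:` comment header naming the instrument profile.
#'
#' @param table A signal table.
#' @param path File path.
#' @param instrument Instrument profile (or name) recorded in the header.
#' @return `read_signal_tsv()` returns a signal table.
#' @export
write_signal_tsv <- function(table, path, instrument = NULL) {
  inst <- attr(table, "instrument") %||%
    (if (!is.null(instrument)) as_instrument(instrument)$name else "unknown")
  writeLines(paste0("# instrument: ", inst), path)
  readr::write_tsv(
    tibble::tibble(rt_min = table$rt, mz = table$mz,
                   intensity = table$intensity),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  inst <- if (grepl("^# instrument: ", header)) {
    sub("^# instrument: ", "", header)
  } else NA_character_
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  out <- signal_table(tbl$rt_min, tbl$mz, tbl$intensity, source = path)
  if (inst %in% c("QQQ", "QTOF")) attr(out, "instrument") <- inst
  out
}

#' Filter signals to the analysis window
#'
#' Restricts a signal table to the retention-time and m/z window used for
#' quantification (closed intervals; defaults 1-6 min and 500-2500 m/z).
#'
#' @param table A signal table.
#' @param rt_range Closed retention-time interval in minutes.
#' @param mz_range Closed m/z interval.
#' @return The filtered signal table.
#' @export
filter_signals <- function(table, rt_range = c(1, 6),
                           mz_range = c(500, 2500)) {
  stopifnot(rt_range[1] <= rt_range[2], mz_range[1] <= mz_range[2])
  out <- dplyr::filter(table,
                       .data$rt >= rt_range[1], .data$rt <= rt_range[2],
                       .data$mz >= mz_range[1], .data$mz <= mz_range[2])
  attr(out, "source") <- attr(table, "source")
  attr(out, "instrument") <- attr(table, "instrument")
  out
}

new_chromatogram <- function(rt, intensity, kind, meta = NULL) {
  stopifnot(!is.unsorted(rt, strictly = TRUE), all(intensity >= 0))
  tbl <- tibble::tibble(rt = as.numeric(rt), intensity = as.numeric(intensity))
  class(tbl) <- c("chromatogram", class(tbl))
  attr(tbl, "kind") <- kind
  attr(tbl, "meta") <- meta
  tbl
}

#' Total ion chromatogram
#'
#' Sums all centroid intensities within each scan, yielding one point per
#' distinct retention time.
#'
#' @param table A signal table.
#' @return A `chromatogram` tibble (`rt`, `intensity`) of kind `"TIC"`.
#' @export
total_ion_chromatogram <- function(table) {
  if (nrow(table) == 0L) abort("Signal table is empty.")
  agg <- table |>
    dplyr::summarise(intensity = sum(.data$intensity), .by = "rt") |>
    dplyr::arrange(.data$rt)
  new_chromatogram(agg$rt, agg$intensity, kind = "TIC")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram: %s> %d points", attr(x, "kind"), nrow(x)))
  meta <- attr(x, "meta")
  if (!is.null(meta)) cat(" |", paste(names(meta), unlist(meta),
                                      sep = "=", collapse = " "))
  cat("\n")
  NextMethod()
}
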