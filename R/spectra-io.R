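#' Build a table of MS/MS spectra
#'
#' The canonical in-memory form of an MS2 collection is a tibble with one row
#' per spectrum and a `peaks` list-column of two-column tibbles
#' (`mz`, `intensity`). Peaks are sorted by ascending m/z on construction.
#'
#' @param feature_id character, unique id per spectrum.
#' @param precursor_mz numeric, precursor mass-to-charge (Th), positive.
#' @param peaks list of data frames with columns `mz` and `intensity`.
#' @param charge integer precursor charge (default 1).
#' @param retention_time numeric seconds (default 0).
#' @param adduct one of `"M+H"`, `"M+NH4"`, `"unknown"` per spectrum.
#'
#' @return A tibble of class `lipid_spectra`.
#' @export
spectra_tbl <- function(feature_id, precursor_mz, peaks,
                        charge = 1L, retention_time = 0,
                        adduct = "unknown") {
  n <- length(feature_id)
  out <- tibble::tibble(
    feature_id = as.character(feature_id),
    precursor_mz = as.numeric(precursor_mz),
    charge = as.integer(rep_len(charge, n)),
    retention_time = as.numeric(rep_len(retention_time, n)),
    adduct = as.character(rep_len(adduct, n)),
    peaks = purrr::map(peaks, function(p) {
      p <- tibble::as_tibble(p)[, c("mz", "intensity")]
      p[order(p$mz), ]
    })
  )
  validate_spectra(out)
}

#' Validate a spectra table
#'
#' Checks the invariants of the spectra data model: unique feature ids,
#' positive precursor m/z, peaks sorted by m/z with finite nonnegative
#' intensities, and no fragment heavier than the precursor plus 1 Th
#' (isotope overshoot tolerance).
#'
#' @param spectra a spectra tibble as built by [spectra_tbl()] or [read_mgf()].
#' @return The input, invisibly classed as `lipid_spectra`.
#' @export
validate_spectra <- function(spectra) {
  if (anyDuplicated(spectra$feature_id)) {
    stop_validation("duplicate feature_id in spectra table")
  }
  if (any(spectra$precursor_mz <= 0)) {
    stop_validation("precursor_mz must be positive")
  }
  ok_adduct <- spectra$adduct %in% c("M+H", "M+NH4", "unknown")
  if (!all(ok_adduct)) {
    stop_validation(paste0(
      "invalid adduct label(s): ",
      paste(unique(spectra$adduct[!ok_adduct]), collapse = ", ")
    ))
  }
  purrr::walk2(spectra$peaks, seq_len(nrow(spectra)), function(p, i) {
    if (is.unsorted(p$mz)) {
      stop_validation(sprintf("peaks of spectrum %d not sorted by m/z", i))
    }
    if (any(!is.finite(p$intensity)) || any(p$intensity < 0)) {
      stop_validation(sprintf("spectrum %d has non-finite or negative intensity", i))
    }
    if (nrow(p) && any(p$mz >= spectra$precursor_mz[i] + 1.0)) {
      stop_validation(sprintf(
        "spectrum %d ('%s') has fragment m/z above precursor + 1.0",
        i, spectra$feature_id[i]
      ))
    }
  })
  class(spectra) <- unique(c("lipid_spectra", class(spectra)))
  spectra
}

#' Read MS/MS spectra from a Mascot Generic Format file
#'
#' Accepts both GNPS-style blocks (`FEATURE_ID=`, `SCANS=`) and generic
#' `TITLE=`-keyed blocks. The feature id is taken from `FEATURE_ID`, then
#' `TITLE`, then `SCANS`; blocks without any are numbered sequentially.
#' A missing `CHARGE` defaults to 1; a missing `RTINSECONDS` to 0. Adducts
#' are recognized from an `ADDUCT=` or `ION=` key containing `M+H` or
#' `M+NH4`; anything else is labelled `"unknown"`.
#'
#' @param path path to an MGF file.
#' @return A `lipid_spectra` tibble (zero rows for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    stop_validation(paste0("MGF file not found: ", path))
  }
  lines <- readr::read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stop_validation("unbalanced BEGIN IONS / END IONS blocks")
  }
  if (!length(starts)) {
    return(spectra_tbl(character(), numeric(), list()))
  }
  blocks <- purrr::map2(starts, ends, function(s, e) lines[(s + 1):(e - 1)])
  parsed <- purrr::imap(blocks, parse_mgf_block)
  spectra_tbl(
    feature_id = purrr::map_chr(parsed, "feature_id"),
    precursor_mz = purrr::map_dbl(parsed, "precursor_mz"),
    peaks = purrr::map(parsed, "peaks"),
    charge = purrr::map_int(parsed, "charge"),
    retention_time = purrr::map_dbl(parsed, "retention_time"),
    adduct = purrr::map_chr(parsed, "adduct")
  )
}

parse_mgf_block <- function(block, index) {
  block <- block[nzchar(trimws(block))]
  is_kv <- grepl("^[A-Za-z_]+=", block)
  kv <- block[is_kv]
  keys <- toupper(sub("=.*$", "", kv))
  vals <- sub("^[^=]*=", "", kv)
  get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_

  pepmass <- get("PEPMASS")
  if (is.na(pepmass)) {
    stop_validation(sprintf("MGF block %d has no PEPMASS", index))
  }
  # PEPMASS may carry a second (intensity) field
  precursor_mz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
  if (!is.finite(precursor_mz)) {
    stop_validation(sprintf("MGF block %d has unparseable PEPMASS", index))
  }

  charge_raw <- get("CHARGE")
  charge <- if (is.na(charge_raw)) 1L else {
    as.integer(sub("[+-]$", "", trimws(charge_raw)))
  }
  rt <- get("RTINSECONDS")
  rt <- if (is.na(rt)) 0 else as.numeric(rt)

  id <- get("FEATURE_ID")
  if (is.na(id)) id <- get("TITLE")
  if (is.na(id)) id <- get("SCANS")
  if (is.na(id)) id <- as.character(index)

  adduct_raw <- get("ADDUCT")
  if (is.na(adduct_raw)) adduct_raw <- get("ION")
  adduct <- if (is.na(adduct_raw)) {
    "unknown"
  } else if (grepl("M\\+NH4", adduct_raw)) {
    "M+NH4"
  } else if (grepl("M\\+H", adduct_raw)) {
    "M+H"
  } else {
    "unknown"
  }

  peak_lines <- block[!is_kv]
  peaks <- if (length(peak_lines)) {
    fields <- strsplit(trimws(peak_lines), "\\s+")
    tibble::tibble(
      mz = purrr::map_dbl(fields, ~ as.numeric(.x[1])),
      intensity = purrr::map_dbl(fields, ~ as.numeric(.x[2]))
    )
  } else {
    tibble::tibble(mz = numeric(), intensity = numeric())
  }

  list(
    feature_id = id, precursor_mz = precursor_mz, charge = charge,
    retention_time = rt, adduct = adduct, peaks = peaks
  )
}

#' Write spectra to a Mascot Generic Format file
#'
#' @param spectra a `lipid_spectra` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(spectra, function(feature_id, precursor_mz, charge,
                                          retention_time, adduct, peaks, ...) {
    adduct_line <- if (adduct != "unknown") sprintf("ADDUCT=[%s]+", adduct) else NULL
    c(
      "BEGIN IONS",
      sprintf("FEATURE_ID=%s", feature_id),
      sprintf("PEPMASS=%.6f", precursor_mz),
      sprintf("CHARGE=%d+", charge),
      sprintf("RTINSECONDS=%.3f", retention_time),
      adduct_line,
      sprintf("%.6f %.6f", peaks$mz, peaks$intensity),
      "END IONS",
      ""
    )
  })
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}
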