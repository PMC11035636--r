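# Diagnostic fragment masses (Th). The archaeol core ion and the lysoAR
# glycerol ion are class-independent anchors of AR-based glycerolipids;
# head-group marker ions and neutral-loss series are class-specific.
AR_CORE_MZ <- 653.681
LYSO_AR_MZ <- 373.368

#' Archaeal lipid class templates
#'
#' One row per lipid class handled by the default annotation rules and the
#' synthetic-spectra generator: a base precursor m/z (the class exemplar), a
#' head-group marker fragment, three class-specific neutral-loss offsets that
#' generate the remaining fragment series, whether the class is built on an
#' archaeol (AR) core (and therefore shows the AR core ion at m/z 653.681 and
#' the lysoAR glycerol ion at m/z 373.368), and the exemplar's assigned
#' elemental composition where known.
#'
#' @return A tibble with columns `lipid_class`, `core`, `base_mz`,
#'   `marker_mz`, `loss_1`, `loss_2`, `loss_3`, `ar_core`, `formula`.
#' @export
lipid_class_templates <- function() {
  tibble::tribble(
    ~lipid_class, ~core, ~base_mz, ~marker_mz, ~loss_1, ~loss_2, ~loss_3, ~ar_core, ~formula,
    "AR",             "AR",   653.681,  LYSO_AR_MZ, 18.0106, 36.0212, 46.0055, TRUE,  "C43H89O3+",
    "PG",             "AR",   807.684,  155.011,    74.0368, 92.0473, 136.9998, TRUE, "C46H96O8P+",
    "PGS",            "AR",   887.641,  234.968,    79.9568, 97.9674, 177.9241, TRUE, "",
    "PA",             "AR",   733.652,  98.984,     61.9710, 79.9815, 115.9920, TRUE, "",
    "PGP-Me",         "AR",   901.666,  248.993,    93.9817, 111.9922, 207.9640, TRUE, "C47H99O11P2+",
    "PGPG",           "AR",   961.687,  309.037,    135.0079, 153.0185, 227.0550, TRUE, "C49H103O13P2+",
    "CL",             "AR",   1522.313, 404.998,    251.0385, 269.0491, 423.0820, TRUE, "C89H183O13P2+",
    "1G",             "AR",   832.760,  180.086,    162.0528, 179.0794, 197.0899, TRUE, "C49H102O8N+",
    "2G",             "AR",   994.813,  342.139,    203.0794, 221.0899, 239.1005, TRUE, "C55H112O13N+",
    "S",              "AR",   1074.770, 241.002,    241.0017, 259.0122, 338.9690, TRUE, "",
    "MK",             "none", 717.560,  187.076,    68.0626, 136.1252, 204.1878, FALSE, "C51H73O2+",
    "bacterioruberin","none", 741.581,  119.086,    106.0783, 124.0888, 142.0994, FALSE, "C50H77O4+",
    "squalene",       "none", 411.399,  81.070,     69.0704, 137.1330, 205.1956, FALSE, ""
  )
}

#' Default diagnostic annotation rules
#'
#' A rule names a lipid class by the fragment ions a spectrum must contain
#' (within tolerance) and, optionally, a precursor window. Rules are ordered
#' most-specific first and the first rule whose requirements are all met
#' wins. Classes built on an archaeol core additionally require the AR core
#' ion at m/z 653.681; two fallback rules assign core affiliation (AR or
#' lysoAR) with class `"unknown"` when only a core ion is present.
#'
#' Rules are plain data: a tibble that can be edited, subset, or round-tripped
#' through JSON with [write_rules()] / [read_rules()].
#'
#' @return A tibble with columns `name`, `lipid_class`, `core`,
#'   `required_mz` (list-column of numeric fragment m/z), `precursor_min`,
#'   `precursor_max`, `isoprenoid_units`, `double_bonds`, `formula`.
#' @export
default_lipid_rules <- function() {
  tpl <- lipid_class_templates()
  specific <- purrr::pmap_dfr(tpl, function(lipid_class, core, base_mz,
                                            marker_mz, ar_core, formula, ...) {
    required <- if (lipid_class == "AR") {
      c(AR_CORE_MZ, LYSO_AR_MZ)
    } else if (ar_core) {
      c(marker_mz, AR_CORE_MZ)
    } else {
      marker_mz
    }
    tibble::tibble(
      name = paste0(lipid_class, " head-group diagnostics"),
      lipid_class = lipid_class,
      core = core,
      required_mz = list(required),
      # AR core lipids live in a narrow precursor band (the unsaturation
      # series plus the ammoniated ion); heavier AR-core glycerolipids are
      # distinguished by their head-group marker ions instead
      precursor_min = if (lipid_class == "AR") base_mz - 14 else NA_real_,
      precursor_max = if (lipid_class == "AR") base_mz + 46 else NA_real_,
      isoprenoid_units = NA_integer_,
      double_bonds = NA_integer_,
      formula = formula
    )
  })
  fallback <- tibble::tibble(
    name = c("AR core affiliation", "lysoAR glycerol affiliation"),
    lipid_class = "unknown",
    core = c("AR", "lysoAR"),
    required_mz = list(AR_CORE_MZ, LYSO_AR_MZ),
    precursor_min = NA_real_, precursor_max = NA_real_,
    isoprenoid_units = NA_integer_, double_bonds = NA_integer_,
    formula = ""
  )
  dplyr::bind_rows(specific, fallback)
}

#' Read and write annotation rules as JSON
#'
#' @param rules a rules tibble as returned by [default_lipid_rules()].
#' @param path JSON file path.
#' @return `read_rules()` returns the rules tibble; `write_rules()` returns
#'   `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(rules, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  out <- tibble::as_tibble(raw)
  out$required_mz <- purrr::map(out$required_mz, as.numeric)
  # columns that were all-NA serialize to nulls and vanish on read
  for (col in c("isoprenoid_units", "double_bonds")) {
    out[[col]] <- if (is.null(raw[[col]])) NA_integer_ else as.integer(raw[[col]])
  }
  for (col in c("precursor_min", "precursor_max")) {
    out[[col]] <- if (is.null(raw[[col]])) NA_real_ else as.numeric(raw[[col]])
  }
  out
}

# MK side-chain mass model: MK(n:n) = MK(8:8) exemplar +/- isoprene units
# (C5H8, 68.0626 Da); each saturation relative to the fully unsaturated
# chain adds 2 H (2.01565 Da).
MK_ISOPRENE <- 68.0626
MK_H2 <- 2.01565

mk_mass <- function(n, m) {
  717.560 + (n - 8) * MK_ISOPRENE + (n - m) * MK_H2
}

# infer MK (n:m) from precursor mass over the plausible side-chain grid
infer_mk_series <- function(precursor_mz) {
  grid <- expand.grid(n = 4:13, m = 0:14)
  grid <- grid[grid$m >= grid$n - 2 & grid$m <= grid$n + 1, ]
  masses <- mk_mass(grid$n, grid$m)
  k <- which.min(abs(masses - precursor_mz))
  if (abs(masses[k] - precursor_mz) > 0.5) {
    return(list(n = NA_integer_, m = NA_integer_))
  }
  list(n = as.integer(grid$n[k]), m = as.integer(grid$m[k]))
}

#' Annotate one spectrum with a lipid class
#'
#' Applies the ordered rule list: the first rule whose required fragment ions
#' are all present within `fragment_tol` (and whose precursor window, if any,
#' contains the precursor) assigns its class; otherwise the class is
#' `"unknown"` with core `"none"`. For menaquinones the isoprenoid-unit and
#' double-bond counts of the MK(n:m) notation are inferred from the precursor
#' mass over the side-chain mass grid.
#'
#' @param spectrum a one-row slice of a `lipid_spectra` tibble.
#' @param rules ordered rules tibble (default [default_lipid_rules()]).
#' @param fragment_tol fragment match tolerance in Th.
#' @return A one-row tibble: `feature_id`, `lipid_class`, `core`,
#'   `isoprenoid_units`, `double_bonds`, `formula`, `rule`.
#' @export
annotate <- function(spectrum, rules = default_lipid_rules(),
                     fragment_tol = 0.01) {
  if (!nrow(rules)) stop_validation("rule list is empty")
  peaks_mz <- spectrum_peaks(spectrum)$mz
  prec <- spectrum_precursor(spectrum)
  fid <- if (is.data.frame(spectrum)) spectrum$feature_id[1] else spectrum$feature_id

  hit <- NULL
  for (r in seq_len(nrow(rules))) {
    req <- rules$required_mz[[r]]
    frag_ok <- all(purrr::map_lgl(req, function(mz) {
      any(abs(peaks_mz - mz) <= fragment_tol)
    }))
    win_ok <- (is.na(rules$precursor_min[r]) || prec >= rules$precursor_min[r]) &&
      (is.na(rules$precursor_max[r]) || prec <= rules$precursor_max[r])
    if (frag_ok && win_ok) {
      hit <- rules[r, ]
      break
    }
  }
  if (is.null(hit)) {
    return(tibble::tibble(
      feature_id = fid, lipid_class = "unknown", core = "none",
      isoprenoid_units = NA_integer_, double_bonds = NA_integer_,
      formula = "", rule = NA_character_
    ))
  }
  units <- hit$isoprenoid_units
  dbs <- hit$double_bonds
  if (hit$lipid_class %in% c("MK", "DMK", "MMK", "DMMK") && is.na(units)) {
    series <- infer_mk_series(prec)
    units <- series$n
    dbs <- series$m
  }
  tibble::tibble(
    feature_id = fid, lipid_class = hit$lipid_class, core = hit$core,
    isoprenoid_units = units, double_bonds = dbs,
    formula = hit$formula, rule = hit$name
  )
}

#' Annotate every spectrum in a collection
#'
#' @param spectra a `lipid_spectra` tibble.
#' @inheritParams annotate
#' @return A tibble with one annotation row per spectrum (see [annotate()]).
#' @export
annotate_spectra <- function(spectra, rules = default_lipid_rules(),
                             fragment_tol = 0.01) {
  purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    annotate(spectra[i, ], rules, fragment_tol)
  })
}

#' Abundance-weighted lipid saturation profile
#'
#' Summarizes the double-bond distribution per lipid class per sample,
#' weighting each feature by its relative abundance within the class. MK
#' features are additionally binned by saturation relative to their
#' isoprenoid-unit count n: `"n:n-1"` (one double bond fewer than units),
#' `"n:n"`, `"n:n+1"`, or `"other"`.
#'
#' @param table a [feature_table()].
#' @param annotations annotation tibble covering the table's features
#'   (features annotated `"unknown"` or without double-bond counts are
#'   dropped from the summary).
#' @return A tibble with columns `sample_id`, `lipid_class`, `double_bonds`,
#'   `mk_category`, `weight`; weights sum to 1 within each class-sample cell.
#' @export
saturation_profile <- function(table, annotations) {
  rel <- close_columns(ft_matrix(table))
  long <- tibble::as_tibble(as.data.frame(rel))
  long$feature_id <- rownames(rel)
  long <- tidyr::pivot_longer(long, -"feature_id", names_to = "sample_id",
                              values_to = "rel_abundance")
  ann <- annotations[, c("feature_id", "lipid_class", "isoprenoid_units",
                         "double_bonds")]
  joined <- dplyr::inner_join(long, ann, by = "feature_id")
  joined <- joined[!is.na(joined$double_bonds), ]
  joined$mk_category <- dplyr::case_when(
    !(joined$lipid_class %in% c("MK", "DMK", "MMK", "DMMK")) ~ NA_character_,
    joined$double_bonds == joined$isoprenoid_units - 1L ~ "n:n-1",
    joined$double_bonds == joined$isoprenoid_units ~ "n:n",
    joined$double_bonds == joined$isoprenoid_units + 1L ~ "n:n+1",
    TRUE ~ "other"
  )
  joined |>
    dplyr::group_by(.data$sample_id, .data$lipid_class, .data$double_bonds,
                    .data$mk_category) |>
    dplyr::summarise(weight = sum(.data$rel_abundance), .groups = "drop") |>
    dplyr::group_by(.data$sample_id, .data$lipid_class) |>
    dplyr::mutate(weight = if (sum(.data$weight) > 0) {
      .data$weight / sum(.data$weight)
    } else {
      .data$weight
    }) |>
    dplyr::ungroup()
}
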