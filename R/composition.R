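#' Correct peak areas for sample recovery with an internal standard
#'
#' Divides every sample column by that sample's internal-standard peak area
#' (a single-divisor normalization) and removes the standard's row from the
#' analytical table.
#'
#' @param table a [feature_table()].
#' @param internal_standard_id feature id of the internal standard row.
#' @return A [feature_table()] without the standard row.
#' @export
correct_recovery <- function(table, internal_standard_id = "IS_DGTS_d9") {
  m <- ft_matrix(table)
  if (!internal_standard_id %in% rownames(m)) {
    stop_validation(paste0("internal standard not found: ", internal_standard_id))
  }
  std <- m[internal_standard_id, ]
  bad <- names(std)[std <= 0]
  if (length(bad)) {
    stop_validation(paste0(
      "internal standard is zero in sample(s): ", paste(bad, collapse = ", ")
    ))
  }
  out <- sweep(m[setdiff(rownames(m), internal_standard_id), , drop = FALSE],
               2, std, "/")
  ft_replace(table, out)
}

#' Merge protonated and ammoniated adduct features
#'
#' An ion component ionizing as both \[M+H\]+ and \[M+NH4\]+ appears as two
#' features whose precursors differ by the NH3 mass (17.02655 Th) and which
#' co-elute. Such pairs are merged into a single component whose abundance is
#' the per-sample sum of the two ion forms; the merged component keeps the
#' M+H feature's id. Ambiguous many-to-many candidates are resolved greedily
#' by smallest mass error, then smallest retention-time difference. Features
#' with adduct `"unknown"` never participate.
#'
#' @param table a [feature_table()] whose `feature_meta` carries
#'   `precursor_mz`, `adduct`, and `retention_time`.
#' @param mz_tol tolerance (Th) on the 17.02655 precursor difference.
#' @param rt_tol maximum retention-time difference (s) for co-elution.
#' @return A [feature_table()]; the merge report is attached as attribute
#'   `"merges"` (tibble with `mh_id`, `mnh4_id`, `mass_error`, `rt_delta`).
#' @export
merge_adducts <- function(table, mz_tol = 0.01, rt_tol = 30) {
  fm <- table$feature_meta
  if (is.null(fm) || !all(c("precursor_mz", "adduct", "retention_time") %in% names(fm))) {
    stop_validation("merge_adducts needs feature_meta with precursor_mz, adduct, retention_time")
  }
  mh <- fm[fm$adduct == "M+H", ]
  mnh4 <- fm[fm$adduct == "M+NH4", ]
  cand <- tidyr::expand_grid(mh_id = mh$feature_id, mnh4_id = mnh4$feature_id)
  if (nrow(cand)) {
    cand$mass_error <- abs(
      mnh4$precursor_mz[match(cand$mnh4_id, mnh4$feature_id)] -
        mh$precursor_mz[match(cand$mh_id, mh$feature_id)] - NH3_MASS
    )
    cand$rt_delta <- abs(
      mnh4$retention_time[match(cand$mnh4_id, mnh4$feature_id)] -
        mh$retention_time[match(cand$mh_id, mh$feature_id)]
    )
    cand <- cand[cand$mass_error <= mz_tol & cand$rt_delta <= rt_tol, ]
    cand <- cand[order(cand$mass_error, cand$rt_delta, cand$mh_id), ]
  } else {
    cand$mass_error <- numeric()
    cand$rt_delta <- numeric()
  }
  merges <- cand[0, ]
  used_mh <- character()
  used_nh4 <- character()
  for (k in seq_len(nrow(cand))) {
    if (cand$mh_id[k] %in% used_mh || cand$mnh4_id[k] %in% used_nh4) next
    merges <- rbind(merges, cand[k, ])
    used_mh <- c(used_mh, cand$mh_id[k])
    used_nh4 <- c(used_nh4, cand$mnh4_id[k])
  }
  m <- ft_matrix(table)
  for (k in seq_len(nrow(merges))) {
    m[merges$mh_id[k], ] <- m[merges$mh_id[k], ] + m[merges$mnh4_id[k], ]
  }
  if (nrow(merges)) m <- m[setdiff(rownames(m), merges$mnh4_id), , drop = FALSE]
  out <- ft_replace(table, m)
  attr(out, "merges") <- tibble::as_tibble(merges)
  out
}

#' Close sample columns to relative abundance
#'
#' Divides every sample column by its total so that lipid abundances become
#' proportions of total lipids per sample. An all-zero sample stays all-zero
#' with a warning.
#'
#' @param table a [feature_table()] (after recovery correction and adduct
#'   merging).
#' @return An object of class `composition_profile`: list with the
#'   relative-abundance matrix `rel` (features x samples), `sample_meta`, and
#'   `feature_meta`.
#' @export
relative_abundance <- function(table) {
  m <- ft_matrix(table)
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("all-zero sample(s) left at zero: ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  structure(
    list(rel = close_columns(m), sample_meta = table$sample_meta,
         feature_meta = table$feature_meta),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %d features x %d samples\n",
              nrow(x$rel), ncol(x$rel)))
  invisible(x)
}

#' @export
tidy.composition_profile <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$rel))
  out$feature_id <- rownames(x$rel)
  out <- tidyr::pivot_longer(out, -"feature_id", names_to = "sample_id",
                             values_to = "rel_abundance")
  dplyr::left_join(out, x$sample_meta, by = "sample_id")
}

#' Aggregate relative abundances into lipid-class shares
#'
#' @param profile a `composition_profile`.
#' @param annotations annotation tibble with `feature_id` and `lipid_class`;
#'   features without a row are counted under class `"unknown"`.
#' @return A tibble with columns `lipid_class`, `sample_id`, `share`;
#'   shares sum to 1 per sample.
#' @export
aggregate_classes <- function(profile, annotations) {
  cls <- annotations$lipid_class[match(rownames(profile$rel),
                                       annotations$feature_id)]
  cls[is.na(cls)] <- "unknown"
  agg <- rowsum(profile$rel, group = cls)
  out <- tibble::as_tibble(as.data.frame(agg))
  out$lipid_class <- rownames(agg)
  tidyr::pivot_longer(out, -"lipid_class", names_to = "sample_id",
                      values_to = "share")
}

#' Call presence or absence of each lipid per condition group
#'
#' A lipid is present in a group when its relative abundance reaches the
#' threshold (default 0.01% of total lipids); anything below the threshold is
#' treated as absent. The group-level call is made either on the mean
#' relative abundance across the group's replicates (default) or on any
#' single replicate exceeding the threshold.
#'
#' @param profile a `composition_profile`.
#' @param group_col column of the sample metadata defining the groups.
#' @param threshold relative-abundance presence threshold (default 1e-4,
#'   i.e. 0.01%); abundance exactly at the threshold counts as present.
#' @param mode `"replicate_mean"` or `"any_replicate"`.
#' @return A logical matrix features x groups, with dimnames.
#' @export
call_presence <- function(profile, group_col = "group", threshold = 1e-4,
                          mode = c("replicate_mean", "any_replicate")) {
  mode <- match.arg(mode)
  groups <- profile$sample_meta[[group_col]]
  if (any(is.na(groups))) stop_validation("sample grouping has missing values")
  levels <- unique(groups)
  pres <- vapply(levels, function(g) {
    cols <- profile$rel[, groups == g, drop = FALSE]
    if (!ncol(cols)) stop_validation(paste0("empty group: ", g))
    if (mode == "replicate_mean") {
      rowMeans(cols) >= threshold
    } else {
      apply(cols >= threshold, 1, any)
    }
  }, logical(nrow(profile$rel)))
  dimnames(pres) <- list(rownames(profile$rel), levels)
  pres
}

#' Count features by exact group-membership pattern (UpSet counts)
#'
#' @param presence logical matrix features x groups, as from
#'   [call_presence()].
#' @return A tibble with columns `pattern` (group names joined by `"&"`,
#'   in column order), `degree` (number of groups in the pattern), and `n`;
#'   one row per nonempty pattern observed. Features absent everywhere
#'   contribute to no pattern, so the counts sum to the number of features
#'   present in at least one group.
#' @export
upset_counts <- function(presence) {
  if (is.null(dim(presence)) || !ncol(presence)) {
    stop_validation("presence matrix needs at least one group")
  }
  keys <- apply(presence, 1, function(row) {
    paste(colnames(presence)[row], collapse = "&")
  })
  keys <- keys[nzchar(keys)]
  if (!length(keys)) {
    return(tibble::tibble(pattern = character(), degree = integer(),
                          n = integer()))
  }
  tab <- table(keys)
  out <- tibble::tibble(
    pattern = names(tab),
    degree = purrr::map_int(strsplit(names(tab), "&", fixed = TRUE), length),
    n = as.integer(tab)
  )
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$pattern)
}

#' Per-group species richness above the presence threshold
#'
#' @param presence logical matrix features x groups.
#' @return A tibble with `group` and `n_species` (features present).
#' @export
species_richness <- function(presence) {
  tibble::tibble(group = colnames(presence),
                 n_species = unname(colSums(presence)))
}
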