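#' Build a feature abundance table
#'
#' Couples a features-by-samples matrix of peak-area responses with per-sample
#' metadata (group, timepoint, replicate) and optional per-feature metadata
#' (precursor m/z, adduct, retention time, annotation). All downstream stages
#' (recovery correction, adduct merging, relative abundance, networking node
#' sizes, diversity indices) consume this object.
#'
#' @param abundance data frame with a `feature_id` column followed by one
#'   numeric column per sample; values are nonnegative peak areas.
#' @param sample_meta data frame with columns `sample_id`, `group`,
#'   `timepoint_h`, `replicate`; must cover every sample column.
#' @param feature_meta optional data frame keyed by `feature_id` with columns
#'   such as `precursor_mz`, `adduct`, `retention_time`.
#'
#' @return An object of class `feature_table`: a list with tibbles
#'   `abundance`, `sample_meta`, `feature_meta`.
#' @export
feature_table <- function(abundance, sample_meta, feature_meta = NULL) {
  abundance <- tibble::as_tibble(abundance)
  sample_meta <- tibble::as_tibble(sample_meta)
  if (!"feature_id" %in% names(abundance)) {
    stop_validation("abundance must have a feature_id column")
  }
  abundance$feature_id <- as.character(abundance$feature_id)
  sample_ids <- setdiff(names(abundance), "feature_id")
  if (!length(sample_ids) || !nrow(abundance)) {
    stop_validation("feature table needs at least one feature and one sample")
  }
  if (anyDuplicated(abundance$feature_id)) {
    dup <- abundance$feature_id[duplicated(abundance$feature_id)][1]
    stop_validation(paste0("duplicate feature id: ", dup))
  }
  vals <- as.matrix(abundance[sample_ids])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_validation("abundances must be finite numbers")
  }
  if (any(vals < 0)) {
    stop_validation("negative abundance values are not allowed")
  }
  if (anyDuplicated(sample_meta$sample_id)) {
    stop_validation("duplicate sample_id in sample metadata")
  }
  missing_meta <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(missing_meta)) {
    stop_validation(paste0(
      "sample(s) missing from metadata: ", paste(missing_meta, collapse = ", ")
    ))
  }
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), ]
  if (!is.null(feature_meta)) {
    feature_meta <- tibble::as_tibble(feature_meta)
    feature_meta$feature_id <- as.character(feature_meta$feature_id)
    feature_meta <- feature_meta[match(abundance$feature_id, feature_meta$feature_id), ]
  }
  structure(
    list(abundance = abundance, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%d groups)\n",
    nrow(x$abundance), nrow(x$sample_meta),
    length(unique(x$sample_meta$group))
  ))
  print(x$abundance, n = 5)
  invisible(x)
}

#' Feature and sample accessors
#'
#' @param table a `feature_table`.
#' @return `ft_features()`/`ft_samples()` return character vectors of ids;
#'   `ft_matrix()` returns the features-by-samples numeric matrix with
#'   dimnames.
#' @export
ft_matrix <- function(table) {
  m <- as.matrix(table$abundance[setdiff(names(table$abundance), "feature_id")])
  rownames(m) <- table$abundance$feature_id
  m
}

#' @rdname ft_matrix
#' @export
ft_features <- function(table) table$abundance$feature_id

#' @rdname ft_matrix
#' @export
ft_samples <- function(table) table$sample_meta$sample_id

# rebuild a feature_table around a replacement matrix, keeping metadata rows
ft_replace <- function(table, m) {
  ab <- tibble::as_tibble(as.data.frame(m))
  ab <- tibble::add_column(ab, feature_id = rownames(m), .before = 1)
  fm <- table$feature_meta
  if (!is.null(fm)) fm <- fm[match(rownames(m), fm$feature_id), ]
  feature_table(ab, table$sample_meta, fm)
}

#' Tidy a feature table into long format
#'
#' @param x a `feature_table`.
#' @param ... unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `abundance`,
#'   joined to the sample metadata.
#' @export
tidy.feature_table <- function(x, ...) {
  x$abundance |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "abundance") |>
    dplyr::left_join(x$sample_meta, by = "sample_id")
}

#' @export
glance.feature_table <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$abundance),
    n_samples = nrow(x$sample_meta),
    n_groups = length(unique(x$sample_meta$group)),
    total_abundance = sum(ft_matrix(x))
  )
}

#' Read a feature abundance table and its sample metadata
#'
#' The abundance file is CSV or TSV (by extension) with feature rows and
#' sample columns; the metadata file maps every sample column to its group,
#' timepoint and replicate.
#'
#' @param path abundance CSV/TSV with a `feature_id` column.
#' @param metadata_path sample metadata CSV with columns `sample_id`,
#'   `group`, `timepoint_h`, `replicate`.
#' @param feature_meta_path optional per-feature metadata CSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path, feature_meta_path = NULL) {
  reader <- function(p) {
    if (grepl("\\.tsv$", p, ignore.case = TRUE)) {
      readr::read_tsv(p, show_col_types = FALSE)
    } else {
      readr::read_csv(p, show_col_types = FALSE)
    }
  }
  fm <- if (!is.null(feature_meta_path)) reader(feature_meta_path) else NULL
  feature_table(reader(path), reader(metadata_path), fm)
}

#' Write a feature table to CSV files
#'
#' @param table a `feature_table`.
#' @param path abundance CSV path.
#' @param metadata_path sample-metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, metadata_path = NULL) {
  readr::write_csv(table$abundance, path)
  if (!is.null(metadata_path)) readr::write_csv(table$sample_meta, metadata_path)
  invisible(path)
}
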