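#' Lipid frequency matrix
#'
#' Restricts the relative-abundance matrix to the configured lipid universe
#' and re-closes each sample column to sum 1, producing the frequency
#' distribution P_ij (lipid i in sample j) that the diversity and
#' specialization indices are computed from.
#'
#' @param profile a `composition_profile`.
#' @param universe `"all"` (every feature) or `"annotated"` (features whose
#'   annotation class is not `"unknown"`, plus unknowns with a core-lipid
#'   affiliation — the unknowns that subnetwork evidence ties to an archaeal
#'   lipid class).
#' @param annotations annotation tibble; required for
#'   `universe = "annotated"`.
#' @return A numeric matrix lipids x samples with columns summing to 1.
#' @export
lipid_frequency <- function(profile, universe = c("all", "annotated"),
                            annotations = NULL) {
  universe <- match.arg(universe)
  p <- profile$rel
  if (universe == "annotated") {
    if (is.null(annotations)) {
      stop_validation("universe = 'annotated' needs annotations")
    }
    keep_ids <- annotations$feature_id[
      annotations$lipid_class != "unknown" | annotations$core != "none"
    ]
    p <- p[rownames(p) %in% keep_ids, , drop = FALSE]
  }
  totals <- colSums(p)
  if (any(totals == 0)) {
    stop_validation(paste0(
      "sample(s) with zero total frequency: ",
      paste(colnames(p)[totals == 0], collapse = ", ")
    ))
  }
  sweep(p, 2, totals, "/")
}

#' Lipidome diversity (Shannon entropy per sample)
#'
#' H_j = -sum_i P_ij log2(P_ij), in bits, with 0 log2(0) taken as 0.
#' H_j ranges from 0 (a single lipid) to log2(m) (uniform over m lipids).
#'
#' @param P frequency matrix (lipids x samples, columns summing to 1).
#' @return A tibble with `sample_id` and `H`.
#' @export
lipidome_diversity <- function(P) {
  H <- apply(P, 2, function(col) -sum(xlog2x(col)))
  tibble::tibble(sample_id = colnames(P), H = unname(H))
}

#' Lipid specificity
#'
#' For lipid i with mean frequency P_i = (1/t) sum_j P_ij, the specificity is
#' S_i = (1/t) sum_j (P_ij / P_i) log2(P_ij / P_i), in bits. S_i is 0 for a
#' lipid with identical frequency in every sample and log2(t) for a lipid
#' private to a single sample. The per-sample summand
#' S_ij = (P_ij / P_i) log2(P_ij / P_i) is returned un-averaged. Lipids with
#' P_i = 0 (absent everywhere) are dropped with a warning.
#'
#' @param P frequency matrix (lipids x samples).
#' @return A list with `S` (tibble `feature_id`, `S`) and `S_cond` (long
#'   tibble `feature_id`, `sample_id`, `S_ij`).
#' @export
lipid_specificity <- function(P) {
  P_i <- rowMeans(P)
  if (any(P_i == 0)) {
    warning(sum(P_i == 0), " lipid(s) absent in every sample dropped from specificity")
    P <- P[P_i > 0, , drop = FALSE]
    P_i <- P_i[P_i > 0]
  }
  t <- ncol(P)
  ratio <- sweep(P, 1, P_i, "/")
  summand <- matrix(xlog2x(ratio), nrow = nrow(P),
                    dimnames = dimnames(P))
  S <- rowSums(summand) / t
  S_cond <- tibble::tibble(
    feature_id = rep(rownames(P), times = t),
    sample_id = rep(colnames(P), each = nrow(P)),
    S_ij = as.vector(summand)
  )
  list(
    S = tibble::tibble(feature_id = rownames(P), S = unname(S)),
    S_cond = S_cond
  )
}

#' Lipidome specialization
#'
#' delta_j = sum_i P_ij S_i: the frequency-weighted mean of the lipid
#' specificities, in bits. delta_j lies between 0 (every lipid ubiquitous
#' with equal frequency) and log2(t) (samples own disjoint lipid sets).
#'
#' @param P frequency matrix (lipids x samples).
#' @param S specificity tibble from [lipid_specificity()] (`feature_id`,
#'   `S`), on the same lipid universe.
#' @return A tibble with `sample_id` and `delta`.
#' @export
lipidome_specialization <- function(P, S) {
  P <- P[S$feature_id, , drop = FALSE]
  if (nrow(P) != nrow(S)) {
    stop_validation("specificity and frequency matrix cover different lipids")
  }
  delta <- colSums(P * S$S)
  tibble::tibble(sample_id = colnames(P), delta = unname(delta))
}

#' Information-theoretic lipidome indices
#'
#' One-stop computation of the Shannon framework: per-sample diversity H_j
#' and specialization delta_j, per-lipid specificity S_i, and the un-averaged
#' per-lipid-per-sample summands S_ij.
#'
#' @inheritParams lipid_frequency
#' @return An object of class `lipidome_infotheory`: list with tibbles
#'   `samples` (`sample_id`, `H`, `delta`, joined to sample metadata),
#'   `lipids` (`feature_id`, `S`), `S_cond`, and the frequency matrix `P`.
#' @export
infotheory <- function(profile, universe = c("all", "annotated"),
                       annotations = NULL) {
  P <- lipid_frequency(profile, universe, annotations)
  H <- lipidome_diversity(P)
  spec <- lipid_specificity(P)
  delta <- lipidome_specialization(P, spec$S)
  samples <- dplyr::left_join(H, delta, by = "sample_id") |>
    dplyr::left_join(profile$sample_meta, by = "sample_id")
  structure(
    list(samples = samples, lipids = spec$S, S_cond = spec$S_cond, P = P),
    class = "lipidome_infotheory"
  )
}

#' @export
print.lipidome_infotheory <- function(x, ...) {
  cat(sprintf("<lipidome_infotheory> %d lipids x %d samples\n",
              nrow(x$P), ncol(x$P)))
  print(x$samples, n = 6)
  invisible(x)
}

#' @export
tidy.lipidome_infotheory <- function(x, ...) x$samples

#' @export
glance.lipidome_infotheory <- function(x, ...) {
  tibble::tibble(
    n_lipids = nrow(x$P), n_samples = ncol(x$P),
    mean_H = mean(x$samples$H), mean_delta = mean(x$samples$delta),
    max_H = log2(nrow(x$P)), max_delta = log2(ncol(x$P))
  )
}

#' Group means and replicate variability of H and delta
#'
#' Summarizes the per-sample indices by group (and optionally timepoint):
#' mean and standard deviation across replicates, with an optional seeded
#' bootstrap over replicates for resampling-based error bars. A
#' single-replicate cell reports `NA` (not zero) for its sd.
#'
#' @param result a `lipidome_infotheory` object.
#' @param by grouping columns in the sample metadata (default
#'   `c("group", "timepoint_h")`).
#' @param n_boot number of bootstrap resamples (0 = none).
#' @param seed integer seed for the bootstrap stream.
#' @return A tibble with group keys, `n`, `H_mean`, `H_sd`, `delta_mean`,
#'   `delta_sd`, and when `n_boot > 0` also `H_boot_sd`, `delta_boot_sd`.
#' @export
replicate_errorbars <- function(result, by = c("group", "timepoint_h"),
                                n_boot = 0, seed = 1L) {
  df <- result$samples
  by <- intersect(by, names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      H_mean = mean(.data$H),
      H_sd = if (dplyr::n() > 1) stats::sd(.data$H) else NA_real_,
      delta_mean = mean(.data$delta),
      delta_sd = if (dplyr::n() > 1) stats::sd(.data$delta) else NA_real_,
      .groups = "drop"
    )
  if (n_boot > 0) {
    rng <- new_rng(seed)
    boot <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_map(function(g, key) {
        stats_boot <- purrr::map_dfr(seq_len(n_boot), function(b) {
          idx <- rng$sample_int(nrow(g), nrow(g), replace = TRUE)
          tibble::tibble(H = mean(g$H[idx]), delta = mean(g$delta[idx]))
        })
        dplyr::bind_cols(key, tibble::tibble(
          H_boot_sd = stats::sd(stats_boot$H),
          delta_boot_sd = stats::sd(stats_boot$delta)
        ))
      }) |>
      dplyr::bind_rows()
    out <- dplyr::left_join(out, boot, by = by)
  }
  out
}
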