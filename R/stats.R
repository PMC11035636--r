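#' Hellinger transform of a community-style abundance matrix
#'
#' Each sample row is divided by its total and square-rooted, so the
#' Euclidean distance between transformed rows equals the Hellinger distance
#' between the original composition vectors — the standard pre-treatment for
#' ordination of zero-inflated relative-abundance data.
#'
#' @param x numeric matrix or data frame, samples in rows, features in
#'   columns, nonnegative.
#' @return A matrix of the same shape; each row's squared entries sum to 1.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop_validation("hellinger input must be nonnegative")
  totals <- rowSums(x)
  if (any(totals == 0)) {
    stop_validation(paste0(
      "all-zero sample row(s): ",
      paste(which(totals == 0), collapse = ", ")
    ))
  }
  sqrt(sweep(x, 1, totals, "/"))
}

#' Principal component analysis of a (transformed) abundance matrix
#'
#' Column-mean-centered PCA without variance scaling (the Hellinger transform
#' has already equalized scales). Component signs are fixed by forcing each
#' component's largest-magnitude loading positive, so plots are reproducible
#' across platforms. Explained-variance ratios derive from the eigenvalues of
#' the sample covariance and sum to 1 over all components.
#'
#' @param x numeric matrix, samples x features (e.g. from [hellinger()]).
#' @param sample_meta optional tibble with `sample_id` rows matching
#'   `rownames(x)`, carried into the scores for plotting.
#' @return An object of class `lipidome_pca`: list with `scores`
#'   (samples x components tibble), `loadings` (matrix),
#'   `explained_variance_ratio`, `sdev`, and `zero_variance` (TRUE when the
#'   input had no variance at all).
#' @export
pca_ordination <- function(x, sample_meta = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_validation("PCA needs at least 2 samples")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  zero_variance <- total_var < .Machine$double.eps
  ratio <- if (zero_variance) rep(0, length(fit$sdev)) else fit$sdev^2 / total_var
  # sign convention: largest |loading| of each component positive
  for (k in seq_len(ncol(fit$rotation))) {
    peak <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[peak, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  scores <- tibble::as_tibble(fit$x)
  scores <- tibble::add_column(
    scores,
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    .before = 1
  )
  if (!is.null(sample_meta)) {
    scores <- dplyr::left_join(scores, sample_meta, by = "sample_id")
  }
  structure(
    list(
      scores = scores, loadings = fit$rotation,
      explained_variance_ratio = ratio, sdev = fit$sdev,
      zero_variance = zero_variance
    ),
    class = "lipidome_pca"
  )
}

#' @export
print.lipidome_pca <- function(x, ...) {
  pc12 <- sum(x$explained_variance_ratio[1:min(2, length(x$explained_variance_ratio))])
  cat(sprintf(
    "<lipidome_pca> %d samples, %d components; PC1+PC2 explain %.1f%% of variance\n",
    nrow(x$scores), length(x$sdev), 100 * pc12
  ))
  invisible(x)
}

#' @export
tidy.lipidome_pca <- function(x, ...) x$scores

#' @export
glance.lipidome_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance_ratio),
    sdev = x$sdev,
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' Z-score rows and cluster both axes of a class-abundance matrix
#'
#' Rows (lipid classes) are standardized with the sample (n-1) standard
#' deviation; zero-variance rows are set to 0 with a warning. Rows and
#' columns are then ordered by agglomerative hierarchical clustering
#' (Euclidean distance, average linkage by default). Z values are never
#' clipped here; clipping to +/-3 SD is a display decision taken in
#' [autoplot.lipidome_heatmap()].
#'
#' @param class_abundance numeric matrix, classes x samples (e.g. from
#'   [aggregate_classes()] pivoted wide), or a tibble in the long form that
#'   [aggregate_classes()] returns.
#' @param dist_method distance passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return An object of class `lipidome_heatmap`: list with `Z`,
#'   `row_order`, `col_order`, `row_hclust`, `col_hclust`.
#' @export
zscore_cluster <- function(class_abundance, dist_method = "euclidean",
                           linkage = "average") {
  m <- as_class_matrix(class_abundance)
  if (ncol(m) < 2) stop_validation("clustering needs at least 2 samples")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance class row(s) set to Z = 0: ",
            paste(rownames(m)[sds == 0], collapse = ", "))
  }
  Z <- m
  for (r in seq_len(nrow(m))) {
    Z[r, ] <- if (sds[r] == 0) 0 else (m[r, ] - mean(m[r, ])) / sds[r]
  }
  rc <- stats::hclust(stats::dist(Z, method = dist_method), method = linkage)
  cc <- stats::hclust(stats::dist(t(Z), method = dist_method), method = linkage)
  structure(
    list(
      Z = Z,
      row_order = rownames(Z)[rc$order], col_order = colnames(Z)[cc$order],
      row_hclust = rc, col_hclust = cc
    ),
    class = "lipidome_heatmap"
  )
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- tibble::as_tibble(x)
  if (all(c("lipid_class", "sample_id", "share") %in% names(x))) {
    wide <- tidyr::pivot_wider(x, names_from = "sample_id",
                               values_from = "share", values_fill = 0)
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$lipid_class
    return(m)
  }
  as.matrix(x)
}

#' Tukey HSD with compact letter display
#'
#' One-way layout: pairwise group comparisons via the studentized-range
#' distribution ([stats::TukeyHSD()] on [stats::aov()]), then compact-letter
#' coding by insert-and-absorb so that groups sharing a letter are not
#' significantly different at `alpha` and groups sharing no letter are.
#'
#' @param data data frame with one measurement per row.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @param alpha significance level (default 0.05).
#' @param alternative `"two.sided"` (standard HSD) or `"one.sided"`
#'   (directional p-values: half the two-sided studentized-range p when the
#'   observed difference has the tested sign, its complement otherwise).
#' @return An object of class `lipidome_tukey`: list with `pairwise`
#'   (tibble `group_a`, `group_b`, `diff`, `lwr`, `upr`, `p_adj`), `letters`
#'   (tibble `group`, `letters`), `alpha`, `alternative`.
#' @export
tukey_cld <- function(data, value, group, alpha = 0.05,
                      alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  df <- data.frame(
    y = data[[value]],
    g = factor(data[[group]])
  )
  counts <- table(df$g)
  if (length(counts) < 2) stop_validation("Tukey HSD needs at least 2 groups")
  if (any(counts < 2)) {
    stop_validation(paste0(
      "group(s) with a single replicate: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  fit <- stats::aov(y ~ g, data = df)
  hsd <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  pairwise <- tibble::tibble(
    group_a = purrr::map_chr(pairs, 1),
    group_b = purrr::map_chr(pairs, 2),
    diff = unname(hsd[, "diff"]),
    lwr = unname(hsd[, "lwr"]),
    upr = unname(hsd[, "upr"]),
    p_adj = unname(hsd[, "p adj"])
  )
  if (alternative == "one.sided") {
    pairwise$p_adj <- ifelse(pairwise$diff > 0, pairwise$p_adj / 2,
                             1 - pairwise$p_adj / 2)
  }
  letters <- cld_letters(pairwise, levels(df$g), alpha)
  structure(
    list(pairwise = pairwise, letters = letters, alpha = alpha,
         alternative = alternative),
    class = "lipidome_tukey"
  )
}

# insert-and-absorb compact letter display from a pairwise p-value table
cld_letters <- function(pairwise, groups, alpha) {
  n <- length(groups)
  signif_pair <- matrix(FALSE, n, n, dimnames = list(groups, groups))
  for (k in seq_len(nrow(pairwise))) {
    a <- pairwise$group_a[k]
    b <- pairwise$group_b[k]
    sig <- pairwise$p_adj[k] < alpha
    signif_pair[a, b] <- sig
    signif_pair[b, a] <- sig
  }
  # columns of `cols` are letter groups (logical membership vectors)
  cols <- list(rep(TRUE, n))
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      if (!signif_pair[a, b]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[a] && col[b]) {
          # split the violated letter group into two
          col_a <- col
          col_a[b] <- FALSE
          col_b <- col
          col_b[a] <- FALSE
          cols[[ci]] <- col_a
          cols[[length(cols) + 1]] <- col_b
        }
      }
      # absorb: drop letter groups contained in another
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) {
        for (j in seq_along(cols)) {
          if (i != j && keep[j] && all(cols[[i]] <= cols[[j]]) &&
              !identical(cols[[i]], cols[[j]])) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- cols[keep]
      # deduplicate
      cols <- cols[!duplicated(purrr::map_chr(cols, paste, collapse = ""))]
    }
  }
  # stable letter assignment: order letter groups by first member
  ord <- order(purrr::map_int(cols, which.max))
  cols <- cols[ord]
  labels <- purrr::map_chr(seq_len(n), function(g) {
    paste(letters[which(purrr::map_lgl(cols, ~ .x[g]))], collapse = "")
  })
  tibble::tibble(group = groups, letters = labels)
}

#' @export
print.lipidome_tukey <- function(x, ...) {
  cat(sprintf("<lipidome_tukey> %d pairwise comparisons, alpha = %g (%s)\n",
              nrow(x$pairwise), x$alpha, x$alternative))
  print(x$letters)
  invisible(x)
}

#' @export
tidy.lipidome_tukey <- function(x, ...) x$pairwise

#' @export
glance.lipidome_tukey <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$letters),
    n_significant = sum(x$pairwise$p_adj < x$alpha),
    alpha = x$alpha,
    alternative = x$alternative
  )
}
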