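#' Modified-cosine similarity between two MS/MS spectra
#'
#' Fragment peaks of the two spectra may match either directly
#' (|delta m/z| <= `fragment_tol`) or shifted by the precursor mass
#' difference, the convention that lets analogs differing by one structural
#' modification still align. Matches are selected greedily by descending
#' intensity product with each peak used at most once, and the score is the
#' sum of matched intensity products normalized by the product of the two
#' spectra's Euclidean intensity norms, so identical spectra score exactly 1.
#'
#' @param s1,s2 one-row slices of a `lipid_spectra` tibble (or lists with
#'   elements `precursor_mz` and `peaks`).
#' @param fragment_tol fragment matching tolerance in Th.
#' @param sqrt_intensity if `TRUE`, intensities are square-root transformed
#'   before scoring; default uses raw relative intensities.
#' @return A list with `cosine` (in \[0, 1\]) and `matched_peaks`.
#' @export
modified_cosine <- function(s1, s2, fragment_tol = 0.01, sqrt_intensity = FALSE) {
  p1 <- spectrum_peaks(s1)
  p2 <- spectrum_peaks(s2)
  if (!nrow(p1) || !nrow(p2)) {
    stop_validation("modified_cosine requires nonempty spectra")
  }
  if (fragment_tol <= 0) stop_validation("fragment_tol must be positive")
  mod_cosine_impl(
    p1$mz, p1$intensity, spectrum_precursor(s1),
    p2$mz, p2$intensity, spectrum_precursor(s2),
    fragment_tol, sqrt_intensity
  )
}

spectrum_peaks <- function(s) {
  if (is.data.frame(s) && "peaks" %in% names(s)) s$peaks[[1]] else s$peaks
}

spectrum_precursor <- function(s) {
  as.numeric(if (is.data.frame(s)) s$precursor_mz[1] else s$precursor_mz)
}

mod_cosine_impl <- function(mz1, int1, prec1, mz2, int2, prec2,
                            tol, sqrt_intensity) {
  w1 <- if (sqrt_intensity) sqrt(int1) else int1
  w2 <- if (sqrt_intensity) sqrt(int2) else int2
  norm <- sqrt(sum(w1^2)) * sqrt(sum(w2^2))
  if (norm == 0) {
    return(list(cosine = 0, matched_peaks = 0L))
  }
  shift <- prec2 - prec1
  d <- outer(mz2, mz1, "-") # rows: peaks of s2, cols: peaks of s1
  cand <- which(abs(d) <= tol | abs(d - shift) <= tol, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(list(cosine = 0, matched_peaks = 0L))
  }
  j <- cand[, 1] # index into s2
  i <- cand[, 2] # index into s1
  product <- w1[i] * w2[j]
  # greedy one-to-one assignment, strongest product first; ties broken by
  # peak index for determinism
  ord <- order(-product, i, j)
  used1 <- logical(length(mz1))
  used2 <- logical(length(mz2))
  score <- 0
  matched <- 0L
  for (k in ord) {
    if (used1[i[k]] || used2[j[k]]) next
    used1[i[k]] <- TRUE
    used2[j[k]] <- TRUE
    score <- score + product[k]
    matched <- matched + 1L
  }
  list(cosine = min(score / norm, 1), matched_peaks = matched)
}

#' All-pairs modified-cosine edges for a spectra table
#'
#' @param spectra a `lipid_spectra` tibble.
#' @param fragment_tol fragment tolerance in Th.
#' @param max_delta maximum |precursor difference| (Th) for a pair to be
#'   scored at all.
#' @param sqrt_intensity see [modified_cosine()].
#' @return A tibble with columns `feature_a`, `feature_b` (a < b), `cosine`,
#'   `matched_peaks`, `precursor_delta`.
#' @export
pairwise_cosines <- function(spectra, fragment_tol = 0.01, max_delta = 500,
                             sqrt_intensity = FALSE) {
  n <- nrow(spectra)
  ord <- order(spectra$feature_id)
  spectra <- spectra[ord, ]
  mzs <- purrr::map(spectra$peaks, "mz")
  ints <- purrr::map(spectra$peaks, "intensity")
  prec <- spectra$precursor_mz
  rows <- list()
  idx <- 1L
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      delta <- prec[b] - prec[a]
      if (abs(delta) > max_delta) next
      res <- mod_cosine_impl(
        mzs[[a]], ints[[a]], prec[a],
        mzs[[b]], ints[[b]], prec[b],
        fragment_tol, sqrt_intensity
      )
      rows[[idx]] <- c(a, b, res$cosine, res$matched_peaks, delta)
      idx <- idx + 1L
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      feature_a = character(), feature_b = character(), cosine = numeric(),
      matched_peaks = integer(), precursor_delta = numeric()
    ))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(
    feature_a = spectra$feature_id[m[, 1]],
    feature_b = spectra$feature_id[m[, 2]],
    cosine = m[, 3],
    matched_peaks = as.integer(m[, 4]),
    precursor_delta = m[, 5]
  )
}

#' Build a feature-based molecular network
#'
#' Candidate edges are all spectrum pairs within `max_delta` Th of precursor
#' difference whose modified cosine reaches `cosine_min` with at least
#' `min_matched` matched fragment ions. An edge survives only if each
#' endpoint ranks the other within its `top_k` best-scoring candidates
#' (mutual top-K). Connected components larger than `max_component` nodes are
#' then broken up by repeatedly removing their weakest (lowest-cosine) edge
#' until no component exceeds the cap. Node sizes carry the feature's mean
#' relative abundance across samples.
#'
#' @param spectra a `lipid_spectra` tibble.
#' @param abundances a [feature_table()] covering every spectrum's feature id.
#' @param cosine_min minimum cosine for an edge (default 0.5).
#' @param min_matched minimum matched fragment ions (default 5).
#' @param top_k mutual rank cutoff (default 10).
#' @param max_delta maximum precursor mass difference in Th (default 500).
#' @param max_component component size cap in nodes (default 100).
#' @param fragment_tol fragment tolerance in Th (default 0.01).
#' @param sqrt_intensity see [modified_cosine()].
#' @return An object of class `molecular_network`: list with tibbles `nodes`
#'   (feature_id, precursor_mz, mean_rel_abundance, component, degree) and
#'   `edges` (feature_a, feature_b, cosine, matched_peaks, precursor_delta),
#'   plus the parameter list.
#' @export
build_network <- function(spectra, abundances,
                          cosine_min = 0.5, min_matched = 5L, top_k = 10L,
                          max_delta = 500, max_component = 100L,
                          fragment_tol = 0.01, sqrt_intensity = FALSE) {
  missing_ab <- setdiff(spectra$feature_id, ft_features(abundances))
  if (length(missing_ab)) {
    stop_validation(paste0(
      "spectra without abundance rows: ", paste(missing_ab, collapse = ", ")
    ))
  }
  rel <- close_columns(ft_matrix(abundances))
  mean_rel <- rowMeans(rel)[spectra$feature_id]

  edges <- pairwise_cosines(spectra, fragment_tol, max_delta, sqrt_intensity)
  edges <- edges[edges$cosine >= cosine_min & edges$matched_peaks >= min_matched, ]
  edges <- mutual_top_k(edges, top_k)
  edges <- cap_components(edges, max_component)

  nodes <- tibble::tibble(
    feature_id = sort(spectra$feature_id),
    precursor_mz = spectra$precursor_mz[match(sort(spectra$feature_id),
                                              spectra$feature_id)],
    mean_rel_abundance = unname(mean_rel[match(sort(spectra$feature_id),
                                               spectra$feature_id)])
  )
  g <- network_graph(nodes$feature_id, edges)
  comp <- igraph::components(g)
  nodes$component <- comp$membership[nodes$feature_id]
  nodes$degree <- igraph::degree(g)[nodes$feature_id]

  structure(
    list(
      nodes = nodes, edges = edges,
      params = list(
        cosine_min = cosine_min, min_matched = min_matched, top_k = top_k,
        max_delta = max_delta, max_component = max_component,
        fragment_tol = fragment_tol, sqrt_intensity = sqrt_intensity
      )
    ),
    class = "molecular_network"
  )
}

# retain edges ranked within top_k by cosine for BOTH endpoints;
# ties broken by ascending partner feature id
mutual_top_k <- function(edges, top_k) {
  if (!nrow(edges)) return(edges)
  incident <- dplyr::bind_rows(
    tibble::tibble(node = edges$feature_a, other = edges$feature_b,
                   cosine = edges$cosine, edge = seq_len(nrow(edges))),
    tibble::tibble(node = edges$feature_b, other = edges$feature_a,
                   cosine = edges$cosine, edge = seq_len(nrow(edges)))
  )
  ranks <- incident |>
    dplyr::group_by(.data$node) |>
    dplyr::arrange(dplyr::desc(.data$cosine), .data$other, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  keep <- ranks |>
    dplyr::group_by(.data$edge) |>
    dplyr::summarise(ok = max(.data$rank) <= top_k) |>
    dplyr::filter(.data$ok)
  edges[sort(keep$edge), ]
}

# while any component exceeds the cap, drop its weakest edge
# (ties broken by ascending feature_a then feature_b)
cap_components <- function(edges, max_component) {
  if (!nrow(edges)) return(edges)
  repeat {
    ids <- unique(c(edges$feature_a, edges$feature_b))
    g <- network_graph(ids, edges)
    comp <- igraph::components(g)
    big <- which(comp$csize > max_component)
    if (!length(big)) break
    member_a <- comp$membership[edges$feature_a]
    in_big <- member_a %in% big
    cand <- which(in_big)
    cand <- cand[order(edges$cosine[cand], method = "radix")]
    # remove one weakest edge from each oversized component per pass
    drop <- cand[!duplicated(member_a[cand])]
    edges <- edges[-drop, ]
    if (!nrow(edges)) break
  }
  edges
}

network_graph <- function(node_ids, edges) {
  igraph::graph_from_data_frame(
    edges[, c("feature_a", "feature_b")],
    directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
}

#' Summarize a molecular network
#'
#' @param net a `molecular_network`.
#' @return A one-row tibble with `n_nodes`, `n_in_components` (nodes with at
#'   least one edge), `n_singletons`, `n_edges`, `n_components`
#'   (multi-node components).
#' @export
network_summary <- function(net) {
  deg <- net$nodes$degree
  tibble::tibble(
    n_nodes = nrow(net$nodes),
    n_in_components = sum(deg > 0),
    n_singletons = sum(deg == 0),
    n_edges = nrow(net$edges),
    n_components = length(unique(net$nodes$component[deg > 0]))
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<molecular_network> %d nodes, %d edges; %d nodes in %d components, %d singletons\n",
    s$n_nodes, s$n_edges, s$n_in_components, s$n_components, s$n_singletons
  ))
  invisible(x)
}

#' @export
tidy.molecular_network <- function(x, ...) x$edges

#' @export
glance.molecular_network <- function(x, ...) network_summary(x)

#' Export a molecular network
#'
#' `write_graphml()` writes a GraphML file with node attributes (feature id,
#' precursor m/z, mean relative abundance, component) and edge attributes
#' (cosine, matched peaks, precursor delta). `write_edgelist()` writes the
#' edge tibble as TSV.
#'
#' @param net a `molecular_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- network_graph(net$nodes$feature_id, net$edges)
  igraph::V(g)$precursor_mz <- net$nodes$precursor_mz
  igraph::V(g)$mean_rel_abundance <- net$nodes$mean_rel_abundance
  igraph::V(g)$component <- net$nodes$component
  if (nrow(net$edges)) {
    igraph::E(g)$cosine <- net$edges$cosine
    igraph::E(g)$matched_peaks <- net$edges$matched_peaks
    igraph::E(g)$precursor_delta <- net$edges$precursor_delta
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edgelist <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}
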