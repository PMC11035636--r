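test_that("modified cosine scores identical spectra as 1 and disjoint as 0", {
  s <- one_spectrum("A", 800, c(100, 200, 300, 400, 500), c(10, 20, 30, 40, 50))
  res <- modified_cosine(s, s)
  expect_equal(res$cosine, 1.0)
  expect_equal(res$matched_peaks, 5L)

  t <- one_spectrum("B", 801.5, c(120, 220, 320), c(5, 5, 5))
  res2 <- modified_cosine(s, t)
  expect_equal(res2$cosine, 0)
  expect_equal(res2$matched_peaks, 0L)

  expect_error(modified_cosine(s, one_spectrum("C", 500, numeric(), numeric())),
               "nonempty")
})

test_that("modified cosine is symmetric, bounded, and shift-aware", {
  withr::local_seed(3)
  for (k in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    s1 <- one_spectrum("A", 700, sort(runif(n1, 100, 650)), runif(n1, 1, 100))
    s2 <- one_spectrum("B", 700 + runif(1, -50, 50),
                       sort(runif(n2, 100, 650)), runif(n2, 1, 100))
    a <- modified_cosine(s1, s2)
    b <- modified_cosine(s2, s1)
    expect_equal(a$cosine, b$cosine, tolerance = 1e-12)
    expect_equal(a$matched_peaks, b$matched_peaks)
    expect_gte(a$cosine, 0)
    expect_lte(a$cosine, 1)
  }
  # a peak shifted by exactly the precursor difference still matches
  s1 <- one_spectrum("A", 600, c(100, 200, 300), c(10, 10, 10))
  s2 <- one_spectrum("B", 650, c(100, 250, 350), c(10, 10, 10))
  res <- modified_cosine(s1, s2)
  expect_equal(res$matched_peaks, 3L) # 100 direct; 200->250, 300->350 shifted
  expect_equal(res$cosine, 1.0)
})

test_that("greedy matching equals the exhaustive matching oracle on small spectra", {
  pairs <- cosine_pair_fixture()
  for (p in pairs) {
    got <- modified_cosine(p$s1, p$s2)$cosine
    want <- oracle_modified_cosine(
      p$s1$peaks[[1]], p$s1$precursor_mz,
      p$s2$peaks[[1]], p$s2$precursor_mz
    )
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("two identical spectra give one edge and one two-node component", {
  sp <- dplyr::bind_rows(
    one_spectrum("A", 800, c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 5)),
    one_spectrum("B", 800, c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 5))
  )
  net <- build_network(sp, flat_table(sp))
  expect_equal(nrow(net$edges), 1)
  s <- network_summary(net)
  expect_equal(s$n_in_components, 2)
  expect_equal(s$n_singletons, 0)
  expect_equal(s$n_components, 1)
})

test_that("a 15-leaf star with top_k = 10 keeps exactly the hub's 10 best edges", {
  sp <- star_fixture()
  net <- build_network(sp, flat_table(sp), cosine_min = 0.05, top_k = 10)
  hub_edges <- net$edges[net$edges$feature_a == "hub" |
                           net$edges$feature_b == "hub", ]
  expect_equal(nrow(net$edges), nrow(hub_edges)) # leaves never inter-connect
  expect_equal(nrow(hub_edges), 10)
  # the hub's candidate ranking, enumerated independently
  cand <- pairwise_cosines(sp)
  cand <- cand[cand$cosine >= 0.05 & cand$matched_peaks >= 5, ]
  hub_cand <- cand[cand$feature_a == "hub" | cand$feature_b == "hub", ]
  other <- ifelse(hub_cand$feature_a == "hub", hub_cand$feature_b,
                  hub_cand$feature_a)
  top10 <- other[order(-hub_cand$cosine, other)][1:10]
  kept <- ifelse(hub_edges$feature_a == "hub", hub_edges$feature_b,
                 hub_edges$feature_a)
  expect_setequal(kept, top10)
})

test_that("network summary splits nodes into components and singletons", {
  sp <- dplyr::bind_rows(purrr::map(1:5, function(i) {
    one_spectrum(paste0("s", i), 400 + i * 100,
                 sort(100 + i * c(1.1, 2.2, 3.3)), c(1, 2, 3))
  }))
  net <- build_network(sp, flat_table(sp))
  expect_equal(unname(unlist(network_summary(net)[, 1:3])), c(5, 0, 5))
})

test_that("oversized components are capped by removing exactly the weakest edges", {
  sp <- oversized_fixture()
  tab <- flat_table(sp)
  params <- list(cosine_min = 0.5, min_matched = 5L, top_k = 10L,
                 max_component = 100L)
  net <- build_network(sp, tab, cosine_min = params$cosine_min,
                       min_matched = params$min_matched, top_k = params$top_k,
                       max_component = params$max_component)

  # every retained edge satisfies the admission thresholds
  expect_true(all(net$edges$cosine >= 0.5))
  expect_true(all(net$edges$matched_peaks >= 5))

  # no component exceeds the cap
  comp_sizes <- table(net$nodes$component[net$nodes$degree > 0])
  expect_true(all(comp_sizes <= 100))

  # mutual top-10 verified by exhaustive rank check on the candidate set
  cand <- pairwise_cosines(sp)
  cand <- cand[cand$cosine >= 0.5 & cand$matched_peaks >= 5, ]
  rank_of <- function(node, other) {
    inc <- cand[cand$feature_a == node | cand$feature_b == node, ]
    partner <- ifelse(inc$feature_a == node, inc$feature_b, inc$feature_a)
    ord <- order(-inc$cosine, partner)
    match(other, partner[ord])
  }
  for (k in seq_len(nrow(net$edges))) {
    expect_lte(rank_of(net$edges$feature_a[k], net$edges$feature_b[k]), 10)
    expect_lte(rank_of(net$edges$feature_b[k], net$edges$feature_a[k]), 10)
  }

  # greedy weakest-edge replay oracle reproduces the final edge set
  pre_cap <- lipidnet:::mutual_top_k(cand, 10L)
  edges <- pre_cap
  repeat {
    g <- igraph::graph_from_data_frame(
      edges[, c("feature_a", "feature_b")], directed = FALSE,
      vertices = data.frame(name = unique(c(edges$feature_a, edges$feature_b)))
    )
    comp <- igraph::components(g)
    big <- which(comp$csize > 100)
    if (!length(big)) break
    in_big <- comp$membership[edges$feature_a] %in% big
    victim <- which(in_big)[which.min(edges$cosine[in_big])]
    edges <- edges[-victim, ]
  }
  key <- function(e) paste(e$feature_a, e$feature_b, sep = "|")
  expect_setequal(key(net$edges), key(edges))
})

test_that("raising the cosine threshold never adds edges", {
  sp <- oversized_fixture(30)
  tab <- flat_table(sp)
  counts <- purrr::map_int(c(0.5, 0.6, 0.7, 0.8, 0.9), function(cm) {
    nrow(build_network(sp, tab, cosine_min = cm)$edges)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("a spectrum without an abundance row is rejected by name", {
  sp <- dplyr::bind_rows(
    one_spectrum("A", 800, c(100, 200), c(1, 2)),
    one_spectrum("ghost", 801, c(100, 200), c(1, 2))
  )
  tab <- flat_table(sp[1, ])
  expect_error(build_network(sp, tab), "ghost")
})

test_that("network exports write GraphML and edge lists", {
  sp <- dplyr::bind_rows(
    one_spectrum("A", 800, c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 5)),
    one_spectrum("B", 800, c(100, 200, 300, 400, 500), c(1, 2, 3, 4, 5))
  )
  net <- build_network(sp, flat_table(sp))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graphml(net, gml)
  write_edgelist(net, tsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 1)
})
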