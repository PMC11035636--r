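sample_meta2 <- function(n = 2, group = "g") {
  tibble::tibble(sample_id = paste0("s", seq_len(n)), group = group,
                 timepoint_h = 0, replicate = seq_len(n))
}

test_that("recovery correction divides by the standard and drops its row", {
  ab <- tibble::tibble(
    feature_id = c("f1", "f2", "IS_DGTS_d9"),
    s1 = c(10, 20, 2), s2 = c(10, 20, 4)
  )
  ft <- feature_table(ab, sample_meta2())
  out <- correct_recovery(ft)
  m <- ft_matrix(out)
  expect_equal(rownames(m), c("f1", "f2"))
  # standard twice as high in s2 -> s2 abundances halved relative to naive
  expect_equal(unname(m[, "s1"]), c(5, 10))
  expect_equal(unname(m[, "s2"]), c(2.5, 5))

  ab0 <- ab
  ab0$s2[3] <- 0
  expect_error(correct_recovery(feature_table(ab0, sample_meta2())),
               "zero in sample\\(s\\): s2")
  expect_error(correct_recovery(ft, "nope"), "not found")
})

test_that("adduct pairs merge by NH3 mass and co-elution, conserving totals", {
  fm <- tibble::tibble(
    feature_id = c("f1", "f1_nh4", "f2", "f3"),
    precursor_mz = c(653.681, 653.681 + 17.0265, 807.684, 807.684 + 17.0265),
    adduct = c("M+H", "M+NH4", "M+H", "M+NH4"),
    retention_time = c(100, 100, 200, 500) # f3 does not co-elute with f2
  )
  ab <- tibble::tibble(
    feature_id = fm$feature_id,
    s1 = c(60, 40, 10, 5), s2 = c(6, 4, 1, 2)
  )
  ft <- feature_table(ab, sample_meta2(), fm)
  out <- merge_adducts(ft, mz_tol = 0.01, rt_tol = 30)
  m <- ft_matrix(out)
  expect_setequal(rownames(m), c("f1", "f2", "f3"))
  expect_equal(unname(m["f1", ]), c(100, 10)) # summed, M+H id kept
  expect_equal(unname(m["f3", ]), c(5, 2)) # outside rt_tol: not merged
  expect_equal(colSums(m), colSums(ft_matrix(ft))) # totals conserved exactly
  expect_equal(nrow(attr(out, "merges")), 1)

  # no adduct pairs -> table unchanged
  lone <- feature_table(ab[c(1, 3), ], sample_meta2(), fm[c(1, 3), ])
  out2 <- merge_adducts(lone)
  expect_equal(ft_matrix(out2), ft_matrix(lone))
})

test_that("ambiguous adduct pairings resolve by smallest mass error", {
  fm <- tibble::tibble(
    feature_id = c("h1", "h2", "n1"),
    precursor_mz = c(500.000, 500.002, 500 + 17.02655),
    adduct = c("M+H", "M+H", "M+NH4"),
    retention_time = c(50, 50, 50)
  )
  ab <- tibble::tibble(feature_id = fm$feature_id, s1 = c(1, 2, 4),
                       s2 = c(1, 2, 4))
  out <- merge_adducts(feature_table(ab, sample_meta2(), fm), mz_tol = 0.01)
  merges <- attr(out, "merges")
  expect_equal(merges$mh_id, "h1") # exact NH3 difference beats the 2 mTh error
  expect_equal(unname(ft_matrix(out)["h1", ]), c(5, 5))
})

test_that("relative abundance closes sample columns to proportions", {
  ab <- tibble::tibble(feature_id = c("a", "b", "c"),
                       s1 = c(1, 1, 2), s2 = c(10, 10, 20))
  prof <- relative_abundance(feature_table(ab, sample_meta2()))
  expect_equal(unname(prof$rel[, "s1"]), c(0.25, 0.25, 0.5))
  # scale invariance: s2 is s1 times 10
  expect_equal(prof$rel[, "s1"], prof$rel[, "s2"])
  expect_equal(unname(colSums(prof$rel)), c(1, 1), tolerance = 1e-9)

  one <- relative_abundance(feature_table(ab[1, ], sample_meta2()))
  expect_equal(unname(one$rel[1, ]), c(1, 1))

  ab0 <- ab
  ab0$s2 <- 0
  expect_warning(relative_abundance(feature_table(ab0, sample_meta2())),
                 "all-zero")
})

test_that("class aggregation sums shares to one per sample", {
  ab <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                       s1 = c(2, 2, 3, 3), s2 = c(1, 0, 1, 0))
  prof <- relative_abundance(feature_table(ab, sample_meta2()))
  ann <- tibble::tibble(feature_id = c("a", "b", "c"),
                        lipid_class = c("PG", "PG", "MK"))
  shares <- aggregate_classes(prof, ann) # d falls into "unknown"
  totals <- tapply(shares$share, shares$sample_id, sum)
  expect_equal(as.vector(totals), c(1, 1))
  expect_equal(shares$share[shares$lipid_class == "PG" &
                              shares$sample_id == "s1"], 0.4)
  expect_equal(shares$share[shares$lipid_class == "unknown" &
                              shares$sample_id == "s2"], 0)
})

test_that("presence calls respect the threshold boundary and replicate mode", {
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    group = c("A", "A", "B", "B"), timepoint_h = 0, replicate = c(1, 2, 1, 2)
  )
  rel <- rbind(
    at = c(1e-4, 1e-4, 1e-4, 1e-4), # exactly at threshold -> present
    below = c(5e-5, 5e-5, 5e-5, 5e-5), # 0.005% everywhere -> absent
    zero = c(0, 0, 0, 0),
    spiky = c(2e-4, 0, 0, 0) # present in one replicate of A only
  )
  filler <- 1 - colSums(rel)
  rel <- rbind(rel, filler = filler)
  colnames(rel) <- meta$sample_id
  prof <- structure(list(rel = rel, sample_meta = meta, feature_meta = NULL),
                    class = "composition_profile")

  pres <- call_presence(prof)
  expect_equal(unname(pres["at", ]), c(TRUE, TRUE))
  expect_equal(unname(pres["below", ]), c(FALSE, FALSE))
  expect_equal(unname(pres["zero", ]), c(FALSE, FALSE))
  expect_equal(unname(pres["spiky", ]), c(TRUE, FALSE)) # mean 1e-4 meets it

  any_mode <- call_presence(prof, mode = "any_replicate")
  expect_equal(unname(any_mode["spiky", ]), c(TRUE, FALSE))

  # monotone: raising the threshold never adds a presence
  for (thr in c(1e-4, 2e-4, 1e-3, 1e-2)) {
    lo <- call_presence(prof, threshold = thr)
    hi <- call_presence(prof, threshold = thr * 2)
    expect_true(all(lo | !hi))
  }
})

test_that("upset counts partition present features exactly", {
  pres <- rbind(
    all3 = c(TRUE, TRUE, TRUE),
    ab = c(TRUE, TRUE, FALSE),
    a = c(TRUE, FALSE, FALSE),
    none = c(FALSE, FALSE, FALSE),
    bc1 = c(FALSE, TRUE, TRUE),
    bc2 = c(FALSE, TRUE, TRUE)
  )
  colnames(pres) <- c("A", "B", "C")
  counts <- upset_counts(pres)
  # brute-force enumeration over the fixture
  expect_equal(counts$n[counts$pattern == "A&B&C"], 1L)
  expect_equal(counts$n[counts$pattern == "A&B"], 1L)
  expect_equal(counts$n[counts$pattern == "A"], 1L)
  expect_equal(counts$n[counts$pattern == "B&C"], 2L)
  expect_equal(sum(counts$n), sum(rowSums(pres) > 0))
  expect_equal(species_richness(pres)$n_species, c(3, 4, 3))
})
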