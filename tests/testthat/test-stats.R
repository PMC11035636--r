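test_that("hellinger transform matches its definition and the vegan oracle", {
  x <- rbind(c(1, 1, 2), c(0, 3, 1))
  h <- hellinger(x)
  expect_equal(h[1, ], c(0.5, 0.5, sqrt(0.5)))
  expect_equal(rowSums(h^2), c(1, 1)) # unit sphere
  # one-hot row unchanged
  expect_equal(hellinger(rbind(c(0, 1, 0)))[1, ], c(0, 1, 0))
  expect_error(hellinger(rbind(c(1, 1), c(0, 0))), "all-zero")

  skip_if_not_installed("vegan")
  withr::local_seed(2)
  y <- matrix(runif(60), 6, 10)
  expect_equal(unname(hellinger(y)),
               unname(as.matrix(vegan::decostand(y, "hellinger"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hellinger makes Euclidean distance equal Hellinger distance", {
  withr::local_seed(4)
  x <- matrix(runif(40, 0.01, 1), 4, 10)
  h <- hellinger(x)
  p <- sweep(x, 1, rowSums(x), "/")
  for (i in 1:3) {
    for (j in (i + 1):4) {
      hd <- sqrt(sum((sqrt(p[i, ]) - sqrt(p[j, ]))^2))
      expect_equal(sqrt(sum((h[i, ] - h[j, ])^2)), hd, tolerance = 1e-12)
    }
  }
})

test_that("PCA satisfies its reconstruction and variance identities", {
  withr::local_seed(6)
  x <- matrix(rnorm(500), 10, 50)
  rownames(x) <- paste0("s", 1:10)
  fit <- pca_ordination(x)
  expect_equal(sum(fit$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$explained_variance_ratio) <= 1e-12))
  # full-rank reconstruction of the centered matrix
  scores <- as.matrix(fit$scores[, grep("^PC", names(fit$scores))])
  recon <- scores %*% t(fit$loadings)
  centered <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(recon - centered)), 1e-9)
  # scores orthogonal
  g <- crossprod(scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-9)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(fit$loadings))) {
    expect_gte(fit$loadings[which.max(abs(fit$loadings[, k])), k], 0)
  }
})

test_that("PCA handles collinear and degenerate inputs", {
  line <- cbind(1:6, 2 * (1:6) + 3)
  rownames(line) <- paste0("s", 1:6)
  fit <- pca_ordination(line)
  expect_equal(fit$explained_variance_ratio[1], 1, tolerance = 1e-12)

  dup <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  rownames(dup) <- paste0("s", 1:3)
  fit0 <- pca_ordination(dup)
  expect_true(fit0$zero_variance)
  expect_equal(sum(fit0$explained_variance_ratio), 0)

  expect_error(pca_ordination(line[1, , drop = FALSE]), "at least 2")
})

test_that("z-scoring uses the sample sd and flags constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1.1, 2.1, 3.1))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(res <- zscore_cluster(m), "zero-variance")
  expect_equal(unname(res$Z["a", ]), c(-1, 0, 1))
  expect_equal(unname(res$Z["b", ]), c(0, 0, 0))
  # rows a and c are identical after centering/scaling: they cluster first
  merge1 <- res$row_hclust$merge[1, ]
  expect_setequal(rownames(m)[-merge1], c("a", "c"))
})

test_that("zscore_cluster accepts the long class-share format", {
  long <- tidyr::expand_grid(lipid_class = c("PG", "MK"),
                             sample_id = c("s1", "s2", "s3"))
  long$share <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7)
  res <- zscore_cluster(long)
  expect_equal(dim(res$Z), c(2L, 3L))
  expect_equal(unname(res$Z["PG", ]), c(-1, 0, 1))
})

test_that("Tukey HSD separates distinct groups and letters them consistently", {
  df <- tibble::tibble(
    y = c(0, 0, 0, 10, 10, 10, 10.1, 10.0, 10.2),
    g = rep(c("a", "b", "c"), each = 3)
  )
  res <- tukey_cld(df, "y", "g")
  lt <- setNames(res$letters$letters, res$letters$group)
  shared_ab <- length(intersect(strsplit(lt[["a"]], "")[[1]],
                                strsplit(lt[["b"]], "")[[1]]))
  shared_bc <- length(intersect(strsplit(lt[["b"]], "")[[1]],
                                strsplit(lt[["c"]], "")[[1]]))
  expect_equal(shared_ab, 0) # a differs from b and c
  expect_gt(shared_bc, 0) # b and c are indistinguishable
  # agreement with the studentized-range reference on this fixture
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(g), data = df))[[1]]
  expect_equal(sort(res$pairwise$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-12)
})

test_that("identical groups share a letter with p near 1", {
  df <- tibble::tibble(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  res <- tukey_cld(df, "y", "g")
  expect_gt(res$pairwise$p_adj, 0.99)
  expect_equal(res$letters$letters[1], res$letters$letters[2])
})

test_that("CLD letters are consistent with pairwise significance", {
  withr::local_seed(8)
  for (r in 1:5) {
    df <- tibble::tibble(
      y = rnorm(20, mean = rep(sample(0:4, 5), each = 4)),
      g = rep(letters[1:5], each = 4)
    )
    res <- tukey_cld(df, "y", "g")
    lt <- setNames(res$letters$letters, res$letters$group)
    for (k in seq_len(nrow(res$pairwise))) {
      a <- strsplit(lt[[res$pairwise$group_a[k]]], "")[[1]]
      b <- strsplit(lt[[res$pairwise$group_b[k]]], "")[[1]]
      share <- length(intersect(a, b)) > 0
      if (res$pairwise$p_adj[k] < res$alpha) {
        expect_false(share)
      } else {
        expect_true(share)
      }
    }
  }
})

test_that("CLD matches the multcomp reference letters", {
  skip_if_not_installed("multcomp")
  withr::local_seed(12)
  df <- data.frame(
    y = rnorm(24, mean = rep(c(0, 0.2, 3, 3.1, 8, 15), each = 4)),
    g = factor(rep(letters[1:6], each = 4))
  )
  res <- tukey_cld(df, "y", "g")
  fit <- multcomp::glht(stats::aov(y ~ g, data = df),
                        linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(fit)$mcletters$Letters
  # letter names may differ; compare the sharing structure
  share <- function(lv, a, b) {
    length(intersect(strsplit(lv[[a]], "")[[1]],
                     strsplit(lv[[b]], "")[[1]])) > 0
  }
  lt <- setNames(res$letters$letters, res$letters$group)
  for (a in letters[1:5]) {
    for (b in letters[(match(a, letters) + 1):6]) {
      expect_equal(share(lt, a, b), share(as.list(ref), a, b))
    }
  }
})

test_that("permuting group labels permutes the letter structure consistently", {
  df <- tibble::tibble(
    y = c(0, 0.1, 0, 5, 5.1, 5, 9, 9.1, 9.2),
    g = rep(c("a", "b", "c"), each = 3)
  )
  res1 <- tukey_cld(df, "y", "g")
  df2 <- df
  df2$g <- c(b = "a", c = "b", a = "c")[df$g] # relabel groups
  res2 <- tukey_cld(df2, "y", "g")
  n_letters <- function(r) length(unique(r$letters$letters))
  expect_equal(n_letters(res1), n_letters(res2))
  expect_equal(sort(res1$pairwise$p_adj), sort(res2$pairwise$p_adj),
               tolerance = 1e-10)

  expect_error(
    tukey_cld(tibble::tibble(y = c(1, 2, 3), g = c("a", "a", "b")), "y", "g"),
    "single replicate"
  )
})
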