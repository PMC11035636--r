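# Fixtures built in code, all deterministic.

# one-row spectra helper
one_spectrum <- function(id, precursor, mz, intensity, adduct = "unknown",
                         rt = 0) {
  spectra_tbl(
    feature_id = id, precursor_mz = precursor,
    peaks = list(data.frame(mz = mz, intensity = intensity)),
    retention_time = rt, adduct = adduct
  )
}

# 50 spectrum pairs with <= 8 peaks each: half are shifted-analog pairs
# built from a shared backbone, half random; used against the exhaustive
# matching oracle
cosine_pair_fixture <- function(seed = 7) {
  withr::local_seed(seed)
  pairs <- vector("list", 50)
  for (k in 1:50) {
    if (k <= 25) {
      n <- sample(5:8, 1)
      base_mz <- sort(100 + cumsum(stats::runif(n, 20, 90)))
      prec1 <- max(base_mz) + stats::runif(1, 50, 150)
      d <- stats::runif(1, 5, 60) # analog mass offset
      shifted <- stats::runif(n) < 0.5 # which peaks carry the modification
      mz2 <- base_mz + ifelse(shifted, d, 0)
      i1 <- stats::runif(n, 10, 100)
      i2 <- i1 * stats::rlnorm(n, 0, 0.3)
      s1 <- one_spectrum(paste0("a", k), prec1, base_mz, i1)
      s2 <- one_spectrum(paste0("b", k), prec1 + d, sort(mz2),
                         i2[order(mz2)])
    } else {
      n1 <- sample(4:8, 1)
      n2 <- sample(4:8, 1)
      s1 <- one_spectrum(paste0("a", k), 900, sort(stats::runif(n1, 100, 800)),
                         stats::runif(n1, 5, 100))
      s2 <- one_spectrum(paste0("b", k), 930, sort(stats::runif(n2, 100, 800)),
                         stats::runif(n2, 5, 100))
    }
    pairs[[k]] <- list(s1 = s1, s2 = s2)
  }
  pairs
}

# hub-and-spokes: 15 leaves similar only to the hub, with distinct cosines
star_fixture <- function() {
  hub_mz <- 100 + 7 * (1:90)
  hub <- one_spectrum("hub", 900, hub_mz, rep(50, 90))
  leaves <- purrr::map(1:15, function(i) {
    shared <- hub_mz[(5 * (i - 1) + 1):(5 * (i - 1) + 5)]
    private <- 800 + i * 3 + c(0.11, 1.31, 2.17)
    mz <- c(shared, private)
    # leaf intensity scales make hub cosines strictly decrease with i
    ints <- c(rep(100 - 4 * i, 5), rep(60, 3))
    one_spectrum(sprintf("leaf%02d", i), 900, sort(mz), ints[order(mz)])
  })
  dplyr::bind_rows(c(list(hub), leaves))
}

# 120 mutually similar spectra forming one oversized component with
# strictly distinct pairwise cosines (similarity decays with index distance)
oversized_fixture <- function(n = 120) {
  purrr::map_dfr(seq_len(n), function(i) {
    mz <- c(150.1, 220.2, 290.3, 360.4, 430.5, 500.6)
    ints <- c(100, 80, 60, 40, 25, 10 + 2.3 * i)
    one_spectrum(sprintf("n%03d", i), 900 + i * 0.37, mz, ints)
  })
}

# uniform abundance table covering a spectra collection
flat_table <- function(spectra, n_samples = 2) {
  ab <- tibble::tibble(feature_id = spectra$feature_id)
  for (s in seq_len(n_samples)) ab[[paste0("s", s)]] <- 1
  feature_table(
    ab,
    tibble::tibble(sample_id = paste0("s", seq_len(n_samples)),
                   group = "g", timepoint_h = 0,
                   replicate = seq_len(n_samples))
  )
}

# reduced study design: same structure as the default, desk-sized
small_design <- function(seed = 11, ...) {
  census <- c("AR" = 4L, "PG" = 6L, "MK" = 6L, "bacterioruberin" = 3L,
              "unknown" = 5L)
  shares <- rbind(
    "AR" = c(0.15, 0.30, 0.10),
    "PG" = c(0.35, 0.30, 0.40),
    "MK" = c(0.20, 0.10, 0.25),
    "bacterioruberin" = c(0.10, 0.05, 0.15),
    "unknown" = c(0.20, 0.25, 0.10)
  )
  colnames(shares) <- c("host", "symbiont", "coculture")
  patterns <- c(
    "host&symbiont&coculture" = 8L, "host&coculture" = 3L, "host" = 4L,
    "coculture" = 3L, "symbiont&coculture" = 2L, "host&symbiont" = 1L,
    "symbiont" = 1L
  )
  args <- utils::modifyList(
    list(
      timepoints_h = c(0, 24), replicates = 2L,
      class_census = census, class_shares = shares,
      pattern_counts = patterns, n_rare = 2L, seed = seed
    ),
    list(...)
  )
  do.call(simulation_design, args)
}
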