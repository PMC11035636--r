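# ---- simulation design -------------------------------------------------

default_class_census <- function() {
  c(
    "AR" = 8L, "PGS" = 13L, "PG" = 25L, "PA" = 3L, "PGP-Me" = 22L,
    "PGPG" = 11L, "CL" = 41L, "S" = 3L, "1G" = 2L, "2G" = 2L,
    "MK" = 39L, "bacterioruberin" = 15L, "squalene" = 1L, "unknown" = 61L
  )
}

default_class_shares <- function() {
  shares <- rbind(
    #                  host   symbiont coculture
    "PGP-Me"        = c(0.170, 0.440, 0.250),
    "bacterioruberin" = c(0.020, 0.002, 0.035),
    "PG"            = c(0.120, 0.080, 0.200),
    "CL"            = c(0.016, 0.005, 0.009),
    "MK"            = c(0.085, 0.050, 0.126),
    "PGS"           = c(0.060, 0.050, 0.050),
    "PGPG"          = c(0.040, 0.060, 0.030),
    "PA"            = c(0.010, 0.012, 0.008),
    "1G"            = c(0.015, 0.030, 0.012),
    "2G"            = c(0.012, 0.025, 0.010),
    "S"             = c(0.010, 0.020, 0.008),
    "AR"            = c(0.030, 0.060, 0.020),
    "squalene"      = c(0.005, 0.010, 0.004)
  )
  colnames(shares) <- c("host", "symbiont", "coculture")
  # the unknown class absorbs the residual of each group
  shares <- rbind(shares, "unknown" = 1 - colSums(shares))
  shares
}

default_pattern_counts <- function() {
  c(
    "host&symbiont&coculture" = 86L, "host&coculture" = 20L,
    "host" = 55L, "coculture" = 48L, "symbiont&coculture" = 16L,
    "host&symbiont" = 4L, "symbiont" = 4L
  )
}

#' Define a synthetic lipidome study design
#'
#' The default design mirrors a host/symbiont/co-culture study: 246 lipids
#' over 14 classes (the class census of an archaeal ether-lipid survey), host
#' and co-culture sampled at 5 timepoints with 3 replicates, the symbiont
#' with 2 replicates; planted group-exclusive lipid sets (110 symbiont
#' species, 165 host species, 86 species common to all groups, 20 private to
#' host + co-culture), planted per-group class-share vectors (e.g. the
#' symbiont's dominant phospholipid at 44% of total lipids), 13 rare species
#' planted below the 0.01% presence threshold everywhere, log-normal
#' replicate noise, and paired protonated/ammoniated adduct features.
#'
#' @param groups group labels; the first is the host, the second the
#'   symbiont, the third the co-culture.
#' @param timepoints_h sampling timepoints (hours) for host and co-culture.
#' @param replicates replicates per host/co-culture timepoint.
#' @param symbiont_replicates replicates for the symbiont (single timepoint).
#' @param class_census named integer vector, species per lipid class.
#' @param class_shares classes x groups matrix of planted class shares
#'   (columns summing to 1).
#' @param pattern_counts named integer vector of planted presence patterns
#'   (group names joined with `"&"`); together with `n_rare` and one
#'   species-per-class seeded into the all-groups pattern it must account
#'   for every species in the census.
#' @param n_rare species planted below the presence threshold in every group.
#' @param rare_share planted relative abundance of each rare species.
#' @param min_share floor on any present species' planted share (keeps every
#'   planted-present species above the 1e-4 presence threshold).
#' @param noise_sigma log-normal sdlog of replicate abundance noise.
#' @param recovery_sigma log-normal sdlog of per-sample recovery (internal
#'   standard) variation.
#' @param adduct_prob probability a lipid ionizes as both \[M+H\]+ and
#'   \[M+NH4\]+.
#' @param adduct_mh_fraction fraction of a paired lipid's abundance carried
#'   by the \[M+H\]+ ion.
#' @param jitter_sd fragment m/z jitter (Th) in simulated spectra.
#' @param spurious_rate expected number of spurious peaks per spectrum.
#' @param total_signal arbitrary total ion signal per sample.
#' @param is_abundance base peak area of the internal standard.
#' @param seed integer driving every random stream of the simulation.
#' @return An object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(groups = c("host", "symbiont", "coculture"),
                              timepoints_h = c(0, 6, 12, 24, 48),
                              replicates = 3L,
                              symbiont_replicates = 2L,
                              class_census = default_class_census(),
                              class_shares = default_class_shares(),
                              pattern_counts = default_pattern_counts(),
                              n_rare = 13L,
                              rare_share = 2e-5,
                              min_share = 2e-4,
                              noise_sigma = 0.25,
                              recovery_sigma = 0.15,
                              adduct_prob = 0.6,
                              adduct_mh_fraction = 0.65,
                              jitter_sd = 0.002,
                              spurious_rate = 0.1,
                              total_signal = 5e8,
                              is_abundance = 1e7,
                              seed = 42L) {
  design <- list(
    groups = groups, timepoints_h = timepoints_h, replicates = replicates,
    symbiont_replicates = symbiont_replicates, class_census = class_census,
    class_shares = class_shares, pattern_counts = pattern_counts,
    n_rare = n_rare, rare_share = rare_share, min_share = min_share,
    noise_sigma = noise_sigma, recovery_sigma = recovery_sigma,
    adduct_prob = adduct_prob, adduct_mh_fraction = adduct_mh_fraction,
    jitter_sd = jitter_sd, spurious_rate = spurious_rate,
    total_signal = total_signal, is_abundance = is_abundance,
    seed = as.integer(seed)
  )
  validate_design(design)
  structure(design, class = "simulation_design")
}

validate_design <- function(d) {
  if (length(d$groups) != 3) {
    stop_validation("the design expects exactly 3 groups (host, symbiont, co-culture)")
  }
  if (!all(colnames(d$class_shares) == d$groups)) {
    stop_validation("class_shares columns must match the group labels")
  }
  if (!setequal(rownames(d$class_shares), names(d$class_census))) {
    stop_validation("class_shares rows must match the class census")
  }
  sums <- colSums(d$class_shares)
  if (any(abs(sums - 1) > 1e-9) || any(d$class_shares < 0)) {
    stop_validation("class share columns must be nonnegative and sum to 1")
  }
  expected <- sum(d$pattern_counts) + d$n_rare
  if (expected != sum(d$class_census)) {
    stop_validation(sprintf(
      "presence plan covers %d species but the census has %d",
      expected, sum(d$class_census)
    ))
  }
  pattern_groups <- strsplit(names(d$pattern_counts), "&", fixed = TRUE)
  if (!all(unlist(pattern_groups) %in% d$groups)) {
    stop_validation("pattern_counts names must be '&'-joined group labels")
  }
  all_n <- d$pattern_counts[purrr::map_lgl(pattern_groups, setequal, d$groups)]
  if (!length(all_n) || all_n < length(d$class_census)) {
    stop_validation(
      "the all-groups pattern must hold at least one species per class"
    )
  }
  probs <- c(d$adduct_prob, d$adduct_mh_fraction)
  if (any(probs < 0 | probs > 1)) stop_validation("probabilities must lie in [0, 1]")
  if (d$rare_share >= 1e-4) {
    stop_validation("rare_share must sit below the 0.01% presence threshold")
  }
  invisible(d)
}

#' Switch off every noise source of a design
#'
#' @param design a [simulation_design()].
#' @return The design with replicate noise, recovery variation, fragment
#'   jitter and spurious peaks all set to zero.
#' @export
zero_noise <- function(design) {
  design$noise_sigma <- 0
  design$recovery_sigma <- 0
  design$jitter_sd <- 0
  design$spurious_rate <- 0
  design
}

# ---- species plan ------------------------------------------------------

# deterministic per-class species list with planted presence patterns.
# Species 1 of every class anchors the all-groups pattern (so every class
# share is realizable in every group); remaining species are ordered by
# depth (index within class) across classes and consume the pattern budget
# in a fixed priority order, which places high-weight species in shared
# patterns and group-private species at increasing depth.
plan_species <- function(design) {
  census <- design$class_census
  classes <- names(census)
  species <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      lipid_class = cl,
      class_index = seq_len(census[[cl]]),
      lipid_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", cl),
                         seq_len(census[[cl]]))
    )
  })
  # canonical pattern key: groups joined in design order
  canon <- function(gs) paste(design$groups[design$groups %in% gs], collapse = "&")
  all_key <- canon(design$groups)

  species$pattern <- NA_character_
  species$pattern[species$class_index == 1] <- all_key

  # rare species: deepest species of the largest class (the unknowns)
  rare_class <- classes[which.max(census)]
  rare_rows <- which(species$lipid_class == rare_class)
  rare_rows <- utils::tail(rare_rows, design$n_rare)
  species$pattern[rare_rows] <- "rare"

  budget <- design$pattern_counts
  names(budget) <- purrr::map_chr(
    strsplit(names(budget), "&", fixed = TRUE), canon
  )
  # the per-class anchors already consumed part of the all-groups count
  budget[all_key] <- budget[all_key] - length(classes)
  labels <- rep(names(budget), times = budget)

  queue <- which(is.na(species$pattern))
  queue <- queue[order(species$class_index[queue], species$lipid_class[queue],
                       method = "radix")]
  species$pattern[queue] <- labels[seq_along(queue)]
  species
}

pattern_has_group <- function(pattern, group) {
  purrr::map_lgl(strsplit(pattern, "&", fixed = TRUE), ~ group %in% .x)
}

# allocate a class's group share among its present species:
# weights 1/sqrt(depth), floored at min_share, renormalized
allocate_share <- function(total, depths, min_share) {
  n <- length(depths)
  if (!n) return(numeric(0))
  if (total < n * min_share - 1e-12) {
    stop_validation(sprintf(
      "class share %.4g cannot keep %d species above the %.4g floor",
      total, n, min_share
    ))
  }
  w <- 1 / sqrt(depths)
  s <- numeric(n)
  fixed <- rep(FALSE, n)
  repeat {
    s[fixed] <- min_share
    rest <- total - min_share * sum(fixed)
    if (any(!fixed)) s[!fixed] <- rest * w[!fixed] / sum(w[!fixed])
    newly <- !fixed & s < min_share
    if (!any(newly)) break
    fixed <- fixed | newly
  }
  s
}

# planted per-lipid share matrix (lipids x groups), columns summing to 1
plant_shares <- function(design, species) {
  groups <- design$groups
  rare_total <- design$n_rare * design$rare_share
  shares <- matrix(0, nrow(species), length(groups),
                   dimnames = list(species$lipid_id, groups))
  for (g in groups) {
    for (cl in names(design$class_census)) {
      rows <- which(species$lipid_class == cl &
                      species$pattern != "rare" &
                      pattern_has_group(species$pattern, g))
      if (!length(rows)) {
        if (design$class_shares[cl, g] > 0) {
          stop_validation(sprintf(
            "class %s has planted share in group %s but no present species",
            cl, g
          ))
        }
        next
      }
      total <- design$class_shares[cl, g] * (1 - rare_total)
      shares[rows, g] <- allocate_share(total, species$class_index[rows],
                                        design$min_share)
    }
    shares[species$pattern == "rare", g] <- design$rare_share
  }
  shares
}

# ---- species identity: precursors, MK series, double bonds -------------

# assign each planted species a precursor m/z and structural truth from the
# class templates; within a class, successive species add one saturation
# (2.01565 Da); MK species walk the (n:m) side-chain grid
species_identity <- function(species) {
  tpl <- lipid_class_templates()
  mk_grid <- expand.grid(m_off = c(0L, 1L, -1L, 2L), n = 4:13)
  mk_grid$m <- mk_grid$n - mk_grid$m_off
  mk_grid <- mk_grid[mk_grid$m >= 0, ]

  purrr::pmap_dfr(species, function(lipid_class, class_index, lipid_id, pattern) {
    if (lipid_class == "MK") {
      n <- mk_grid$n[class_index]
      m <- mk_grid$m[class_index]
      return(tibble::tibble(
        lipid_id = lipid_id, lipid_class = lipid_class, pattern = pattern,
        class_index = class_index, core = "none",
        isoprenoid_units = n, double_bonds = m,
        precursor_mz = mk_mass(n, m)
      ))
    }
    if (lipid_class == "unknown") {
      return(tibble::tibble(
        lipid_id = lipid_id, lipid_class = lipid_class, pattern = pattern,
        class_index = class_index, core = "none",
        isoprenoid_units = NA_integer_, double_bonds = NA_integer_,
        precursor_mz = 950 + class_index * 3.1071
      ))
    }
    row <- tpl[tpl$lipid_class == lipid_class, ]
    tibble::tibble(
      lipid_id = lipid_id, lipid_class = lipid_class, pattern = pattern,
      class_index = class_index, core = row$core,
      isoprenoid_units = NA_integer_,
      double_bonds = class_index - 1L,
      precursor_mz = row$base_mz + (class_index - 1L) * MK_H2
    )
  })
}

# ---- sample layout -----------------------------------------------------

design_samples <- function(design) {
  g <- design$groups
  host_cc <- tidyr::expand_grid(
    group = g[c(1, 3)], timepoint_h = design$timepoints_h,
    replicate = seq_len(design$replicates)
  )
  sym <- tibble::tibble(
    group = g[2], timepoint_h = 0,
    replicate = seq_len(design$symbiont_replicates)
  )
  out <- dplyr::bind_rows(host_cc, sym)
  out$sample_id <- sprintf("%s_T%02d_r%d", out$group, out$timepoint_h,
                           out$replicate)
  out[, c("sample_id", "group", "timepoint_h", "replicate")]
}

# ---- ground-truth indices (naive loops, independent of the package's
#      vectorized infotheory implementation) ----------------------------

naive_indices <- function(P) {
  m <- nrow(P)
  t <- ncol(P)
  H <- numeric(t)
  for (j in seq_len(t)) {
    for (i in seq_len(m)) {
      if (P[i, j] > 0) H[j] <- H[j] - P[i, j] * log2(P[i, j])
    }
  }
  P_i <- numeric(m)
  for (i in seq_len(m)) P_i[i] <- sum(P[i, ]) / t
  S <- numeric(m)
  for (i in seq_len(m)) {
    if (P_i[i] == 0) next
    acc <- 0
    for (j in seq_len(t)) {
      r <- P[i, j] / P_i[i]
      if (r > 0) acc <- acc + r * log2(r)
    }
    S[i] <- acc / t
  }
  delta <- numeric(t)
  for (j in seq_len(t)) {
    for (i in seq_len(m)) delta[j] <- delta[j] + P[i, j] * S[i]
  }
  list(H = H, S = S, delta = delta)
}

# ---- the generator -----------------------------------------------------

#' Simulate a ground-truthed lipidome feature table
#'
#' Generates the raw features-by-samples peak-area table the pipeline
#' consumes — group-mean planted shares times log-normal replicate noise,
#' per-sample recovery variation, an internal-standard row, and paired
#' \[M+H\]+ / \[M+NH4\]+ adduct features — together with the full ground
#' truth: per-lipid planted shares and presence patterns, planted class
#' shares, and the noise-free diversity and specialization indices per
#' group.
#'
#' All randomness derives from `design$seed`; the same design is
#' bit-reproducible.
#'
#' @param design a [simulation_design()].
#' @return An object of class `lipidome_sim`: list with `table` (the raw
#'   [feature_table()] including the `IS_DGTS_d9` row), `lipids` (truth
#'   tibble: class, core, MK series, precursor, pattern, planted share per
#'   group, adduct pairing), `presence` (planted lipids x groups logical
#'   matrix), `class_shares` (planted long tibble), `true_index` (per-group
#'   noise-free `H` and `delta`), and the `design`.
#' @export
simulate_lipidome <- function(design) {
  validate_design(design)
  rng <- new_rng(design$seed)
  species <- plan_species(design)
  shares <- plant_shares(design, species)
  lipids <- species_identity(species)
  samples <- design_samples(design)

  # noise-free per-sample frequency matrix -> ground-truth indices
  group_idx <- match(samples$group, design$groups)
  P0 <- shares[, group_idx, drop = FALSE]
  colnames(P0) <- samples$sample_id
  idx0 <- naive_indices(P0)
  true_index <- tibble::tibble(
    sample_id = samples$sample_id, group = samples$group,
    H = idx0$H, delta = idx0$delta
  ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(H = mean(.data$H), delta = mean(.data$delta)) |>
    dplyr::arrange(match(.data$group, design$groups))

  # replicate noise on top of planted shares
  n_lip <- nrow(shares)
  n_smp <- nrow(samples)
  noise <- if (design$noise_sigma > 0) {
    matrix(rng$rlnorm(n_lip * n_smp, 0, design$noise_sigma), n_lip, n_smp)
  } else {
    matrix(1, n_lip, n_smp)
  }
  recovery <- if (design$recovery_sigma > 0) {
    rng$rlnorm(n_smp, 0, design$recovery_sigma)
  } else {
    rep(1, n_smp)
  }
  lipid_abund <- P0 * noise *
    design$total_signal * rep(recovery, each = n_lip)

  # adduct pairing splits a lipid's signal over two ion-form features
  paired <- rng$runif(n_lip) < design$adduct_prob
  lipids$adduct_paired <- paired
  mh_ids <- lipids$lipid_id
  frac <- ifelse(paired, design$adduct_mh_fraction, 1)
  mh_abund <- lipid_abund * frac
  nh4_abund <- lipid_abund[paired, , drop = FALSE] *
    (1 - design$adduct_mh_fraction)
  nh4_ids <- paste0(lipids$lipid_id[paired], "_NH4")

  abund <- rbind(mh_abund, nh4_abund)
  rownames(abund) <- c(mh_ids, nh4_ids)
  is_row <- design$is_abundance * recovery
  abund <- rbind(abund, IS_DGTS_d9 = is_row)

  rt <- 120 + seq_len(n_lip) * 7
  feature_meta <- tibble::tibble(
    feature_id = c(mh_ids, nh4_ids, "IS_DGTS_d9"),
    lipid_id = c(lipids$lipid_id, lipids$lipid_id[paired], NA),
    adduct = c(rep("M+H", n_lip), rep("M+NH4", sum(paired)), "unknown"),
    precursor_mz = c(lipids$precursor_mz,
                     lipids$precursor_mz[paired] + NH3_MASS, 742.7),
    retention_time = c(rt, rt[paired], 60),
    lipid_class = c(lipids$lipid_class, lipids$lipid_class[paired], "standard")
  )
  ab_tbl <- tibble::as_tibble(as.data.frame(abund))
  ab_tbl <- tibble::add_column(ab_tbl, feature_id = rownames(abund), .before = 1)
  table <- feature_table(ab_tbl, samples, feature_meta)

  presence <- matrix(FALSE, n_lip, length(design$groups),
                     dimnames = list(lipids$lipid_id, design$groups))
  for (g in design$groups) {
    presence[, g] <- pattern_has_group(lipids$pattern, g) &
      lipids$pattern != "rare"
  }
  share_tbl <- tibble::as_tibble(as.data.frame(shares))
  names(share_tbl) <- paste0("share_", design$groups)
  lipids <- dplyr::bind_cols(lipids, share_tbl)

  class_shares <- tibble::as_tibble(as.data.frame(shares)) |>
    dplyr::mutate(lipid_class = lipids$lipid_class) |>
    tidyr::pivot_longer(-"lipid_class", names_to = "group",
                        values_to = "share") |>
    dplyr::group_by(.data$lipid_class, .data$group) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop")

  structure(
    list(table = table, lipids = lipids, presence = presence,
         class_shares = class_shares, true_index = true_index,
         design = design),
    class = "lipidome_sim"
  )
}

#' @export
print.lipidome_sim <- function(x, ...) {
  cat(sprintf(
    "<lipidome_sim> %d lipids (%d features with adduct twins) x %d samples, seed %d\n",
    nrow(x$lipids), nrow(x$table$abundance), nrow(x$table$sample_meta),
    x$design$seed
  ))
  invisible(x)
}

# fragment template for one lipid; intensity of the first neutral-loss peak
# grows with the species' depth in its class so that spectral similarity
# decays smoothly with structural distance (nearer homologs score higher)
lipid_fragments <- function(lipid_class, class_index, precursor_mz) {
  tpl <- lipid_class_templates()
  row <- tpl[tpl$lipid_class == lipid_class, ]
  if (!nrow(row)) stop_validation(paste0("no spectral template for class ", lipid_class))
  losses <- c(row$loss_1, row$loss_2, row$loss_3, row$loss_1 + row$loss_3)
  mz <- c(row$marker_mz, precursor_mz - losses)
  intensity <- c(85, 20 + 5 * class_index, 70, 35, 25)
  if (row$ar_core) {
    mz <- c(mz, AR_CORE_MZ, LYSO_AR_MZ)
    intensity <- c(intensity, 100, 50)
  }
  keep <- mz > 50 & mz < precursor_mz + 0.5 & !duplicated(round(mz, 4))
  tibble::tibble(mz = mz[keep], intensity = intensity[keep])
}

# reserved masses no random (unknown-class or spurious) peak may fall near,
# so noise never fakes a diagnostic ion
reserved_masses <- function() {
  tpl <- lipid_class_templates()
  c(tpl$marker_mz, AR_CORE_MZ, LYSO_AR_MZ)
}

draw_clear_mz <- function(rng, n, lo, hi) {
  reserved <- reserved_masses()
  out <- rng$runif(n, lo, hi)
  repeat {
    bad <- purrr::map_lgl(out, function(mz) any(abs(mz - reserved) < 0.05))
    if (!any(bad)) break
    out[bad] <- rng$runif(sum(bad), lo, hi)
  }
  out
}

#' Simulate MS/MS spectra for a simulated lipidome
#'
#' Emits one spectrum per feature of the simulated table (adduct twins share
#' their parent lipid's fragments; the internal standard gets its own
#' template). Class templates plant the diagnostic ions the annotation rules
#' look for — the archaeol core ion at m/z 653.681 and lysoAR glycerol ion
#' at m/z 373.368 for AR-based classes, a head-group marker ion, and a
#' class-specific neutral-loss series — so that lipids of one class are
#' mutually similar (modified cosine above the 0.5 networking threshold) and
#' different classes share too few fragments to be linked. Unknown-class
#' lipids get private random fragment sets (network singletons). Fragment
#' m/z jitter and spurious peaks are added at the design's rates.
#'
#' @param sim a `lipidome_sim` from [simulate_lipidome()].
#' @return A `lipid_spectra` tibble, one row per feature.
#' @export
simulate_spectra <- function(sim) {
  design <- sim$design
  rng <- new_rng(design$seed + 1L)
  fm <- sim$table$feature_meta
  lip <- sim$lipids

  base_peaks <- stats::setNames(vector("list", nrow(lip)), lip$lipid_id)
  for (k in seq_len(nrow(lip))) {
    base_peaks[[k]] <- if (lip$lipid_class[k] == "unknown") {
      tibble::tibble(
        mz = sort(draw_clear_mz(rng, 6, 120, min(500, lip$precursor_mz[k] - 20))),
        intensity = c(50, 45, 40, 30, 20, 15)
      )
    } else {
      lipid_fragments(lip$lipid_class[k], lip$class_index[k],
                      lip$precursor_mz[k])
    }
  }
  is_peaks <- tibble::tibble(mz = c(236.149, 474.4, 742.7),
                             intensity = c(100, 60, 40))

  peaks <- purrr::map(seq_len(nrow(fm)), function(k) {
    p <- if (is.na(fm$lipid_id[k])) is_peaks else base_peaks[[fm$lipid_id[k]]]
    if (design$jitter_sd > 0) {
      p$mz <- p$mz + rng$rnorm(nrow(p), 0, design$jitter_sd)
    }
    if (design$spurious_rate > 0) {
      n_sp <- sum(rng$runif(4) < design$spurious_rate / 4)
      if (n_sp > 0) {
        p <- dplyr::bind_rows(p, tibble::tibble(
          mz = draw_clear_mz(rng, n_sp, 100, fm$precursor_mz[k] - 5),
          intensity = rng$runif(n_sp, 5, 20)
        ))
      }
    }
    p[order(p$mz), ]
  })
  spectra_tbl(
    feature_id = fm$feature_id,
    precursor_mz = fm$precursor_mz,
    peaks = peaks,
    retention_time = fm$retention_time,
    adduct = fm$adduct
  )
}
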