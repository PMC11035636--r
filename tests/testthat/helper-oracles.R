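# Independent brute-force oracles used to pin the expected values of the
# vectorized implementations. These deliberately use naive loops and
# exhaustive enumeration only.

# Exhaustive maximum-weight one-to-one peak matching, mixing direct and
# precursor-shifted matches, for small spectra (<= 8 peaks each).
oracle_modified_cosine <- function(p1, prec1, p2, prec2, tol = 0.01) {
  w1 <- p1$intensity
  w2 <- p2$intensity
  shift <- prec2 - prec1
  cand <- list()
  for (i in seq_along(p1$mz)) {
    for (j in seq_along(p2$mz)) {
      d <- p2$mz[j] - p1$mz[i]
      if (abs(d) <= tol || abs(d - shift) <= tol) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  norm <- sqrt(sum(w1^2)) * sqrt(sum(w2^2))
  if (!length(cand) || norm == 0) return(0)
  best <- 0
  n <- length(cand)
  rec <- function(k, used1, used2, acc) {
    if (k > n) {
      best <<- max(best, acc)
      return()
    }
    rec(k + 1, used1, used2, acc)
    ij <- cand[[k]]
    if (!used1[ij[1]] && !used2[ij[2]]) {
      used1[ij[1]] <- TRUE
      used2[ij[2]] <- TRUE
      rec(k + 1, used1, used2, acc + w1[ij[1]] * w2[ij[2]])
    }
  }
  rec(1, logical(length(w1)), logical(length(w2)), 0)
  min(best / norm, 1)
}

# Naive-loop Shannon framework: H_j, P_i, S_i, S_ij, delta_j from the
# defining sums, nothing vectorized.
oracle_infotheory <- function(P) {
  m <- nrow(P)
  t <- ncol(P)
  H <- numeric(t)
  for (j in seq_len(t)) {
    for (i in seq_len(m)) {
      if (P[i, j] > 0) H[j] <- H[j] - P[i, j] * log2(P[i, j])
    }
  }
  P_i <- numeric(m)
  for (i in seq_len(m)) {
    acc <- 0
    for (j in seq_len(t)) acc <- acc + P[i, j]
    P_i[i] <- acc / t
  }
  S <- numeric(m)
  S_ij <- matrix(0, m, t)
  for (i in seq_len(m)) {
    for (j in seq_len(t)) {
      r <- P[i, j] / P_i[i]
      if (is.finite(r) && r > 0) S_ij[i, j] <- r * log2(r)
    }
    S[i] <- sum(S_ij[i, ]) / t
  }
  delta <- numeric(t)
  for (j in seq_len(t)) {
    for (i in seq_len(m)) delta[j] <- delta[j] + P[i, j] * S[i]
  }
  list(H = H, P_i = P_i, S = S, S_ij = S_ij, delta = delta)
}

# random frequency matrix with columns summing to 1
random_frequency_matrix <- function(m, t) {
  P <- matrix(stats::runif(m * t), m, t)
  # sprinkle structural zeros like a real presence/absence lipidome
  P[stats::runif(m * t) < 0.2] <- 0
  P[1, colSums(P) == 0] <- 1
  sweep(P, 2, colSums(P), "/")
}
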