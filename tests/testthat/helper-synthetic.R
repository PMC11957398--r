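# Small shared fixtures, built in code.

make_layout6 <- function() {
  probe_layout(6, c("PFC_left", "PFC_left", "PFC_right",
                    "PFC_right", "MC_left", "MC_right"))
}

# Two-channel recording with a planted unidirectional drive.
make_directed_pair <- function(seed, lag = 1, strength = 0.9,
                               noise_sd = 0.3) {
  simulate_hb(sim_config(
    n_channels = 2,
    directed_pairs = list(list(driver = 1, receiver = 2,
                               lag = lag, strength = strength)),
    noise_sd = noise_sd, seed = seed))
}

# Sinusoid helper at a given frequency/amplitude.
sinusoid <- function(freq, duration = 360, fs = 10, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(duration * fs) / fs + phase)
}

# Brute-force graph-metric oracles (independent of the package path).
oracle_cc <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  }, numeric(1)))
}

oracle_dist <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_ge <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  d <- oracle_dist(A)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_le <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_ge(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracle_q <- function(A, membership) {
  L <- sum(A) / 2
  if (L == 0) return(NA_real_)
  q <- 0
  for (m in unique(membership)) {
    idx <- which(membership == m)
    lm <- sum(A[idx, idx]) / 2
    dm <- sum(A[idx, ])
    q <- q + lm / L - (dm / (2 * L))^2
  }
  q
}

# Exhaustive best-partition modularity for tiny graphs (n <= 8).
oracle_best_q <- function(A) {
  n <- nrow(A)
  parts <- partitions_of(n)
  max(vapply(parts, function(p) oracle_q(A, p), numeric(1)))
}

partitions_of <- function(n) {
  # all set partitions of n elements via restricted growth strings
  out <- list()
  grow <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0)
  out
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

as_bg <- function(A) {
  # wrap a 0/1 adjacency as the binary_graph the package metrics expect
  structure(list(adjacency = A > 0, sparsity = NA_real_,
                 n_edges = sum(A) / 2),
            class = "binary_graph")
}

# Independent uniform phase binning over (-pi, pi] for oracle comparisons.
phase_bins_for_test <- function(theta, n_bins) {
  th <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  pmin(pmax(ceiling((th + pi) / (2 * pi) * n_bins), 1L), n_bins)
}
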