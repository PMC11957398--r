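test_that("band phase advances linearly for a pure tone and flips under negation", {
  fs <- 10
  x <- sinusoid(0.1)
  sp <- cwt_morlet(x, fs)
  ph <- band_phase(sp)
  d <- diff(ph); d <- d[abs(d) < pi]        # drop wrap jumps
  expect_equal(mean(d) * fs, 2 * pi * 0.1, tolerance = 0.02)

  ph_neg <- band_phase(cwt_morlet(-x, fs))
  dd <- abs(ph - ph_neg)
  expect_true(all(abs(pmin(dd, 2 * pi - dd) - pi) < 0.05))

  # quarter-period delayed copy: constant phase difference of ~pi/2
  lagk <- round(fs / 0.1 / 4)
  y <- c(x[-seq_len(lagk)], x[seq_len(lagk)])
  dphi <- ph - band_phase(cwt_morlet(y, fs))
  dphi <- atan2(sin(dphi), cos(dphi))
  core <- dphi[500:3000]
  expect_equal(mean(abs(core)), pi / 2, tolerance = 0.1)
})

test_that("Scott binsize follows the stated formula", {
  theta <- matrix(rnorm(2000), 2)
  s <- scott_binsize(theta, Ns = 1000)
  msd <- mean(apply(theta, 1, sd))
  expect_equal(s$binsize, 3.49 * msd * 1000^(-1 / 3), tolerance = 1e-12)
  expect_equal(scott_binsize(theta * 2, Ns = 1000)$binsize, 2 * s$binsize,
               tolerance = 1e-12)
  # hand case: sd 1, Ns = 8 -> binsize 1.745, 4 bins over 2 pi
  th1 <- matrix(c(-1.5, -0.5, 0.5, 1.5, -1.5, -0.5, 0.5, 1.5), 1)
  th1 <- th1 / sd(th1[1, ])                  # unit sd
  s8 <- scott_binsize(th1, Ns = 8)
  expect_equal(s8$binsize, 3.49 / 2, tolerance = 1e-12)
  expect_equal(s8$n_bins, 4L)
})

test_that("PTE estimator matches explicit probability tables on tiny inputs", {
  # brute-force PTE from explicit joint probability tables
  brute_pte <- function(bx, by, delay, n_bins) {
    N <- length(by) - delay
    yd <- by[(1 + delay):(N + delay)]; y <- by[1:N]; x <- bx[1:N]
    H <- function(df) {
      p <- table(df) / nrow(df)
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    H(data.frame(yd, y)) + H(data.frame(y, x)) - H(data.frame(y)) -
      H(data.frame(yd, y, x))
  }
  set.seed(21)
  for (r in 1:10) {
    n_bins <- sample(2:4, 1)
    Ns <- sample(20:50, 1)
    # discretized phases: bin centers over (-pi, pi]
    centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
    tx <- sample(centers, Ns, replace = TRUE)
    ty <- sample(centers, Ns, replace = TRUE)
    delay <- sample(1:3, 1)
    est <- phase_transfer_entropy(tx, ty, delay, n_bins)
    ref <- brute_pte(phase_bins_for_test(tx, n_bins),
                     phase_bins_for_test(ty, n_bins), delay, n_bins)
    expect_equal(est, ref, tolerance = 1e-10)
  }
})

test_that("PTE is invariant to 2*pi phase wrapping and detects lagged coupling", {
  sim <- make_directed_pair(seed = 31, strength = 0.9)
  th <- phase_matrix(sim$hb)
  nb <- scott_binsize(th)$n_bins
  p1 <- phase_transfer_entropy(th[1, ], th[2, ], 10, nb)
  p1w <- phase_transfer_entropy(th[1, ] + 2 * pi, th[2, ], 10, nb)
  expect_equal(p1, p1w, tolerance = 1e-12)

  # y an exact 10-sample-delayed copy of x: strongly asymmetric transfer
  ty <- c(rep(th[1, 1], 10), head(th[1, ], -10))
  pxy <- phase_transfer_entropy(th[1, ], ty, 10, nb)
  pyx <- phase_transfer_entropy(ty, th[1, ], 10, nb)
  expect_gt(pxy, 1.2 * pyx)
})

test_that("shuffled phases sit inside the permutation null", {
  sim <- make_directed_pair(seed = 33, strength = 0.9)
  th <- phase_matrix(sim$hb)
  nb <- scott_binsize(th)$n_bins
  set.seed(1)
  shuffled <- sample(th[1, ])
  observed <- phase_transfer_entropy(shuffled, th[2, ], 10, nb)
  null_pte <- replicate(200,
    phase_transfer_entropy(sample(th[1, ]), th[2, ], 10, nb))
  expect_gt(observed, quantile(null_pte, 0.005))
  expect_lt(observed, quantile(null_pte, 0.995))
})

test_that("dPTE normalization, bounds, and antisymmetry are exact", {
  expect_equal(dpte(1, 1), 0.5)
  expect_equal(dpte(3, 1), 0.75)
  expect_equal(dpte(0.2, 0.8) + dpte(0.8, 0.2), 1)
  expect_warning(v <- dpte(0, 0), "zero")
  expect_equal(v, 0.5)

  sim <- simulate_hb(sim_config(n_channels = 4, duration = 120,
                                noise_sd = 0.3, seed = 35))
  net <- dpte_matrix(sim$hb)
  off <- !diag(4)
  expect_true(all(net$dpte[off] >= 0 & net$dpte[off] <= 1))
  expect_equal((net$dpte + t(net$dpte))[off], rep(1, sum(off)),
               tolerance = 1e-12)
})

test_that("delay heuristic: floor of 1, monotone in phase speed, in range", {
  fs <- 10
  slow <- band_phase(cwt_morlet(sinusoid(0.02), fs))
  fast <- band_phase(cwt_morlet(sinusoid(0.18), fs))
  d_slow <- estimate_delay(matrix(slow, 1))
  d_fast <- estimate_delay(matrix(fast, 1))
  expect_gte(d_fast, 1)
  expect_gt(d_slow, d_fast)
  expect_warning(d0 <- estimate_delay(matrix(rep(0.3, 100), 1)), "sign")
  expect_equal(d0, 1L)

  sim <- make_directed_pair(seed = 36)
  th <- phase_matrix(sim$hb)
  d <- estimate_delay(th)
  expect_true(d >= 1 && d <= 100)
})

test_that("out-degree and outflow summaries follow the 0.5 threshold", {
  D <- matrix(0.5, 3, 3); diag(D) <- NA
  s <- network_summaries(D)
  expect_equal(s$out_degree, rep(0, 3))
  expect_equal(s$outflow_strength, rep(0, 3))

  # 3-cycle a->b->c->a at 0.8 (reciprocals 0.2): each node one outflow
  D2 <- matrix(NA, 3, 3)
  D2[1, 2] <- 0.8; D2[2, 1] <- 0.2
  D2[2, 3] <- 0.8; D2[3, 2] <- 0.2
  D2[3, 1] <- 0.2; D2[1, 3] <- 0.2  # a->c weak, c->a strong
  D2[3, 1] <- 0.8
  s2 <- network_summaries(D2)
  expect_equal(s2$out_degree, c(1, 1, 1))
  expect_equal(s2$outflow_strength, c(0.8, 0.8, 0.8))
  s2e <- network_summaries(D2, mode = "excess")
  expect_equal(s2e$outflow_strength, c(0.3, 0.3, 0.3))

  # counting identity: total out-degree = #{ordered pairs above 0.5}
  set.seed(40)
  P <- matrix(runif(36), 6); diag(P) <- NA
  D3 <- P / (P + t(P))
  s3 <- network_summaries(D3)
  expect_equal(sum(s3$out_degree), sum(D3 > 0.5, na.rm = TRUE))

  regs <- c("DMC", "DMC", "NMC", "NMC", "DPFC", "DPFC")
  s4 <- network_summaries(D3, regions = regs)
  expect_equal(unname(s4$region_out_degree["DMC"]),
               mean(s3$out_degree[1:2]))
})
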