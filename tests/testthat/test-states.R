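test_that("window count follows floor((N - W)/step)", {
  expect_length(slide_windows(3600, 10, 20, 1), 340)
  expect_length(slide_windows(200, 10, 20, 1), 0)   # N = W: zero windows
  expect_length(slide_windows(210, 10, 20, 1), 1)   # N = W + step
  expect_error(slide_windows(150, 10, 20, 1), "shorter")
  # exactness across a grid of (N, W, step)
  for (N in c(500, 777, 2400)) for (W in c(100, 200)) for (S in c(5, 10, 30)) {
    if (W <= S) next
    st <- slide_windows(N, 1, W, S)
    expect_length(st, floor((N - W) / S))
    if (length(st)) expect_lte(max(st) + W - 1, N)
  }
})

test_that("PLV is 1 for identical channels, low for noise, amplitude-invariant", {
  fs <- 10
  set.seed(50)
  x <- bandpass(rnorm(200), fs)
  X <- rbind(x, x)
  expect_equal(plv_matrix(X)[1, 2], 1, tolerance = 1e-10)

  # independent noise in a 200-sample window: null ensemble sits well below
  # the locked value of 1 (slow band -> few cycles, so the null is wide)
  null_plv <- replicate(50, {
    Y <- rbind(bandpass(rnorm(200), fs), bandpass(rnorm(200), fs))
    plv_matrix(Y)[1, 2]
  })
  expect_lt(mean(null_plv), 0.5)
  expect_lt(quantile(null_plv, 0.95), 0.95)
  Y <- rbind(bandpass(rnorm(200), fs), bandpass(rnorm(200), fs))
  expect_equal(plv_matrix(Y), plv_matrix(Y * c(3, 0.2)), tolerance = 1e-10)
  expect_error(plv_matrix(rbind(x, rep(1, 200))), "constant")
})

test_that("windowed PLV features match per-window PLV matrices", {
  sim <- simulate_hb(sim_config(n_channels = 4, duration = 40,
                                noise_sd = 0.3, seed = 51))
  f <- plv_window_features(sim$hb, 1:4, width = 20, step = 5)
  expect_equal(ncol(f$features), 6)     # 4 choose 2
  expect_equal(nrow(f$features), floor((400 - 200) / 50))
  expect_true(all(f$features >= 0 & f$features <= 1 + 1e-9))
  # 20 motor channels give the 190-dimensional feature vector
  sim20 <- simulate_hb(sim_config(n_channels = 20, duration = 30,
                                  noise_sd = 0.3, seed = 52))
  f20 <- plv_window_features(sim20$hb, 1:20, width = 20, step = 1)
  expect_equal(ncol(f20$features), 190)
})

test_that("the autoencoder compresses to the bottleneck and trains down", {
  set.seed(53)
  X <- matrix(rnorm(120 * 190), 120, 190)
  H <- encode_features(X, dim = 64, epochs = 50, seed = 1)
  expect_equal(dim(H), c(120, 64))
  loss <- attr(H, "loss")
  expect_lt(min(loss), loss[1])
  expect_true(all(cummin(loss) <= loss[1]))
  # deterministic given seed; duplicated inputs encode identically
  H2 <- encode_features(X, dim = 64, epochs = 50, seed = 1)
  expect_identical(H, H2)
  Xd <- rbind(X, X[1:5, ])
  Hd <- encode_features(Xd, dim = 64, epochs = 50, seed = 1)
  expect_equal(Hd[121:125, ], Hd[1:5, ], tolerance = 1e-12)
  expect_error(encode_features(cbind(X, NA)), "non-finite")
  expect_equal(dim(encode_features(X, dim = 64, method = "pca")),
               c(120, 64))
})

test_that("clustering recovers well-separated planted clusters; WCSS decreases in k", {
  set.seed(54)
  centers <- matrix(rnorm(4 * 64, sd = 5), 4, 64)
  lab <- sample(1:4, 300, replace = TRUE)
  X <- centers[lab, ] + matrix(rnorm(300 * 64), 300, 64)
  sm <- cluster_states(X, restarts = 20, seed = 2)
  expect_equal(sm$k, 4)
  expect_gt(mclust::adjustedRandIndex(sm$labels, lab), 0.9)
  expect_true(all(diff(sm$wcss) <= 1e-6 * sm$wcss[1]))

  # a structureless blob has a far shallower elbow than planted clusters
  elbow_depth <- function(sm) {
    ks <- sm$k_range
    x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
    y <- (sm$wcss - min(sm$wcss)) / (max(sm$wcss) - min(sm$wcss))
    max(abs(x + y - 1) / sqrt(2))
  }
  X1 <- matrix(rnorm(300 * 64), 300, 64)
  sm1 <- cluster_states(X1, restarts = 10, seed = 3)
  expect_lt(elbow_depth(sm1), 0.5 * elbow_depth(sm))
  # determinism given the master seed
  sm2 <- cluster_states(X, restarts = 20, seed = 2)
  expect_identical(sm$labels, sm2$labels)
})

test_that("state dynamics summaries match hand enumeration", {
  d <- state_dynamics(c(1, 1, 2, 2), step = 1)
  expect_equal(d$frequency, c(0.5, 0.5))
  expect_equal(d$mean_dwell, c(2, 2))
  expect_equal(d$transition_matrix[1, ], c(0.5, 0.5))
  expect_equal(d$transition_percentage[1, 2], 1)  # the only off-diag move

  dc <- state_dynamics(rep(2, 10), step = 1, k = 2)
  expect_equal(dc$frequency, c(0, 1))
  expect_equal(dc$mean_dwell[2], 10)
  expect_true(all(dc$transition_percentage == 0))
  expect_equal(sum(d$frequency), 1)

  labs <- c(1, 2, 1, 3, 3, 2)
  dd <- state_dynamics(labs, step = 2)
  expect_equal(sum(dd$frequency), 1)
  expect_equal(rowSums(dd$transition_matrix, na.rm = TRUE)[c(1, 2, 3)],
               c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(dd$transition_percentage), 1)
})

test_that("window ground-truth labels flag boundary windows as impure", {
  st <- rep(c(1, 2), each = 100)
  starts <- slide_windows(200, 1, 50, 10)
  truth <- window_state_labels(st, starts, 50)
  expect_equal(truth$label[1], 1)
  expect_true(all(truth$pure == (starts + 49 <= 100 | starts >= 101)))
})

test_that("end-to-end: planted 4-state switching is recovered on one run", {
  cfg <- sim_config(n_channels = 20, n_states = 4,
                    state_connectivity = state_graphs_default(20),
                    state_dwell_mean = 30, state_dwell_min = 30,
                    noise_sd = 0.2, seed = 1)
  sim <- simulate_hb(cfg)
  f <- plv_window_features(sim$hb, 1:20)
  expect_equal(nrow(f$features), 340)
  truth <- window_state_labels(sim$truth$state_labels, f$starts, 200)
  red <- encode_features(f$features, 64, seed = 1)
  sm <- cluster_states(red, restarts = 50, seed = 1)
  expect_equal(sm$k, 4)
  expect_gt(mclust::adjustedRandIndex(sm$labels[truth$pure],
                                      truth$label[truth$pure]), 0.8)
})
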