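test_that("channel QC applies the intensity and SNR exclusion rules", {
  set.seed(1)
  n <- 4; N <- 500
  data <- array(0, c(n, 2, N))
  data[1, , ] <- 1200 + rnorm(2 * N, 0, 1)        # too bright
  data[2, , ] <- 10 + rnorm(2 * N, 0, 1)          # quotient 10: retained
  data[3, , ] <- abs(1 + rnorm(2 * N, 0, 1)) + .01 # quotient ~1 < 2
  data[4, , ] <- 0.2 + abs(rnorm(2 * N, 0, .001))  # below 0.5
  raw <- raw_intensity(data)
  expect_equal(qc_channels(raw), c(FALSE, TRUE, FALSE, FALSE))

  data_bad <- array(1200, c(2, 2, 50)) + array(rnorm(200), c(2, 2, 50))
  expect_error(qc_channels(raw_intensity(data_bad)), "every channel")
})

test_that("optical-density conversion is referenced, scaled, and scale-invariant", {
  N <- 200
  data <- array(5, c(1, 2, N))
  raw <- raw_intensity(data)
  expect_true(all(abs(intensity_to_od(raw)) < 1e-12))

  # doubling the intensity at one sample: OD = -ln 2 there (vs ~0 baseline)
  data[1, 1, 100] <- 10
  od <- intensity_to_od(raw_intensity(data))
  expect_equal(od[1, 1, 100], -log(2), tolerance = 0.01)

  # scaling a channel by a constant leaves OD unchanged
  set.seed(2)
  data2 <- array(exp(rnorm(2 * N, 2, 0.1)), c(1, 2, N))
  od1 <- intensity_to_od(raw_intensity(data2))
  od2 <- intensity_to_od(raw_intensity(data2 * 7))
  expect_equal(od1, od2, tolerance = 1e-12)
})

test_that("motion repair suppresses steps and spikes but preserves clean signal", {
  fs <- 10
  x <- sinusoid(0.05, duration = 120, fs = fs)
  # repair deliberately removes linear drift, so compare drift-invariantly
  drift_free <- function(v) stats::resid(stats::lm(v ~ seq_along(v)))
  expect_lt(sqrt(mean((drift_free(tddr(x, fs)) - drift_free(x))^2)) / sd(x),
            0.01)
  expect_identical(tddr(rep(0, 500), fs), rep(0, 500))

  # large baseline step: residual step well below the original
  step <- c(rep(0, 600), rep(10 * sd(x), 600))
  rep_x <- tddr(x + step, fs)
  jump <- function(v) abs(mean(v[631:1200]) - mean(v[1:570]))
  expect_lt(jump(rep_x), 0.2 * jump(x + step))

  # Hampel: isolated high-frequency spike replaced, clean noise untouched
  set.seed(3)
  hf <- rnorm(1000)
  spiked <- hf; spiked[500] <- 10 * sd(hf)
  fixed <- hampel_highfreq(spiked)
  expect_lt(abs(fixed[500]), 5)
  expect_gt(mean(fixed == spiked), 0.99)
  expect_identical(hampel_highfreq(rep(1, 300)), rep(1, 300))
})

test_that("MBLL solves the two-wavelength system (linearity in DPF)", {
  lay <- make_layout6()
  E <- extinction_defaults()
  # zero OD gives zero concentrations
  od0 <- array(0, c(6, 2, 50)); attr(od0, "fs") <- 10
  hb0 <- mbll_convert(od0, lay, age = 8)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))

  # doubling DPF halves the recovered concentrations
  set.seed(4)
  od <- array(rnorm(6 * 2 * 50, 0, 0.01), c(6, 2, 50)); attr(od, "fs") <- 10
  cfg1 <- preprocess_config(dpf_mode = "fixed", dpf_fixed = 6)
  cfg2 <- preprocess_config(dpf_mode = "fixed", dpf_fixed = 12)
  h1 <- mbll_convert(od, lay, cfg = cfg1)
  h2 <- mbll_convert(od, lay, cfg = cfg2)
  expect_equal(h2$hbo, h1$hbo / 2, tolerance = 1e-10)
})

test_that("quadratic detrending leaves residuals orthogonal to {1, t, t^2}", {
  tt <- 1:2000
  quad <- 3 + 0.01 * tt - 2e-5 * tt^2
  expect_lt(max(abs(detrend2(quad))), 1e-8)

  x <- sinusoid(0.05, duration = 200, fs = 10)
  y <- detrend2(x + quad)
  expect_gt(cor(y, x), 0.99)
  expect_lt(abs(sum(y * tt^2)) / sqrt(sum(y^2) * sum(tt^4)), 1e-6)
})

test_that("PCA removal eliminates the shared component", {
  set.seed(5)
  n <- 6; N <- 400
  shared <- sinusoid(0.1, duration = 40, fs = 10)
  X <- matrix(rnorm(n * N, 0, 0.05), n, N) + outer(rep(1, n), shared)
  Y <- pca_global_remove(X, 1)
  expect_lt(mean(apply(Y, 1, var)), 0.1 * mean(apply(X, 1, var)))
  # residual has zero projection on the removed eigenvector
  e1 <- eigen(cov(t(X - rowMeans(X))), symmetric = TRUE)$vectors[, 1]
  expect_lt(max(abs(t(e1) %*% (Y - rowMeans(Y)))), 1e-8)
  expect_error(pca_global_remove(X, 6), "smaller")
})

test_that("full chain recovers planted in-band oscillations from raw intensities", {
  lay <- make_layout6()
  cfg <- sim_config(n_channels = 6, duration = 240,
                    coupling_graph = diag(6), noise_sd = 0.2, seed = 12)
  hb <- simulate_hb(cfg)$hb
  raw <- simulate_raw(cfg, hb, lay, age = 8)
  clean <- preprocess(raw, lay, age = 8,
                      cfg = preprocess_config(pca_remove = 0))
  for (i in 1:6)
    expect_gt(cor(clean$hbo[i, ], bandpass(hb$hbo[i, ], 10)), 0.95)
})

test_that("artifact injection is repaired by the motion stage", {
  lay <- make_layout6()
  cfg <- sim_config(n_channels = 6, duration = 240, noise_sd = 0.2,
                    spike_rate = 2, shift_rate = 1, seed = 13)
  hb <- simulate_hb(cfg)$hb
  raw <- simulate_raw(cfg, hb, lay, age = 8)
  pcfg <- preprocess_config(pca_remove = 0)
  od <- intensity_to_od(raw)
  attr(od, "fs") <- raw$fs
  before <- mbll_convert(od, lay, age = 8, cfg = pcfg)
  od_fix <- motion_repair(od, raw$fs, pcfg)
  attr(od_fix, "fs") <- raw$fs
  after <- mbll_convert(od_fix, lay, age = 8, cfg = pcfg)
  ref <- t(apply(hb$hbo, 1, bandpass, fs = 10))
  cor_before <- mean(sapply(1:6, function(i)
    cor(bandpass(before$hbo[i, ], 10), ref[i, ])))
  cor_after <- mean(sapply(1:6, function(i)
    cor(bandpass(after$hbo[i, ], 10), ref[i, ])))
  expect_gt(cor_after, cor_before)
})
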