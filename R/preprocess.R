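#' Preprocessing configuration
#'
#' @param intensity_hi,intensity_lo channel-exclusion bounds on mean raw
#'   intensity (device units; defaults 1000 and 0.5).
#' @param snr_min minimum mean/SD quotient of raw intensity (default 2).
#' @param hampel_halfwidth samples on each side of the rolling Hampel window
#'   (default 50).
#' @param hampel_nsigma Hampel replacement threshold in scaled-MAD units
#'   (default 4).
#' @param detrend_order polynomial detrending order (default 2).
#' @param pca_remove number of leading principal components removed as the
#'   global physiological signal (default 1).
#' @param band analysis band in Hz (default 0.01-0.2).
#' @param dpf_mode `"age_formula"` (age- and wavelength-dependent) or
#'   `"fixed"`.
#' @param dpf_fixed DPF value used when `dpf_mode = "fixed"`.
#' @param tddr_split low/high frequency split (Hz) inside the motion-repair
#'   stage (default 0.5).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(intensity_hi = 1000, intensity_lo = 0.5,
                              snr_min = 2,
                              hampel_halfwidth = 50, hampel_nsigma = 4,
                              detrend_order = 2, pca_remove = 1,
                              band = c(0.01, 0.2),
                              dpf_mode = c("age_formula", "fixed"),
                              dpf_fixed = 6, tddr_split = 0.5) {
  dpf_mode <- match.arg(dpf_mode)
  stopifnot(intensity_hi > 0, intensity_lo > 0, snr_min > 0,
            band[1] > 0, band[1] < band[2])
  structure(list(intensity_hi = intensity_hi, intensity_lo = intensity_lo,
                 snr_min = snr_min, hampel_halfwidth = hampel_halfwidth,
                 hampel_nsigma = hampel_nsigma, detrend_order = detrend_order,
                 pca_remove = pca_remove, band = band, dpf_mode = dpf_mode,
                 dpf_fixed = dpf_fixed, tddr_split = tddr_split),
            class = "preprocess_config")
}

#' Hemoglobin extinction coefficients at 730 and 850 nm
#'
#' Molar extinction coefficients (base-e absorption, per cm per micromol/L)
#' of oxy- and deoxyhemoglobin at the two acquisition wavelengths, from the
#' Prahl compilation used by standard fNIRS toolboxes. Override by passing a
#' matrix of the same shape (rows named by wavelength in nm, columns
#' `HbO`/`HbR`).
#'
#' @return 2 x 2 numeric matrix.
#' @export
extinction_defaults <- function() {
  m <- rbind(`730` = c(HbO = 390.0, HbR = 1102.2),
             `850` = c(HbO = 1058.0, HbR = 691.32))
  m * 1e-6 * log(10)   # per cm per uM, base e
}

#' Age- and wavelength-dependent differential pathlength factor
#'
#' General DPF equation with a power-law age term and a cubic wavelength
#' polynomial (Scholkmann-Wolf form):
#' `DPF = 223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wl^3 + 0.001245 * wl^2
#'  - 0.9025 * wl`.
#'
#' @param wavelength wavelength in nm.
#' @param age age in years.
#' @return DPF (dimensionless).
#' @export
dpf_age <- function(wavelength, age) {
  223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelength^3 +
    0.001245 * wavelength^2 - 0.9025 * wavelength
}

#' Channel quality control on raw intensities
#'
#' A channel is invalid if, at either wavelength, its mean intensity exceeds
#' `intensity_hi`, falls below `intensity_lo`, or its mean/SD quotient falls
#' below `snr_min`. The mask travels with the recording: excluded channels
#' take no part in averages or statistics.
#'
#' @param raw a [raw_intensity()].
#' @param cfg a [preprocess_config()].
#' @return logical validity mask per channel.
#' @export
qc_channels <- function(raw, cfg = preprocess_config()) {
  n <- dim(raw$data)[1]
  ok <- rep(TRUE, n)
  for (w in seq_len(dim(raw$data)[2])) {
    m <- apply(raw$data[, w, , drop = FALSE], 1, mean)
    s <- apply(raw$data[, w, , drop = FALSE], 1, stats::sd)
    q <- ifelse(s > 0, m / s, Inf)
    ok <- ok & m <= cfg$intensity_hi & m >= cfg$intensity_lo & q >= cfg$snr_min
  }
  if (!any(ok)) stop("quality control excluded every channel")
  ok
}

#' Convert raw intensity to optical density
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, so OD has zero
#' mean in the log domain and is invariant to constant intensity scaling.
#'
#' @param raw a [raw_intensity()].
#' @return channels x wavelengths x time array of OD.
#' @export
intensity_to_od <- function(raw) {
  if (any(raw$data <= 0)) {
    bad <- unique(which(apply(raw$data <= 0, 1, any)))
    stop("nonpositive intensity in channel(s): ", paste(bad, collapse = ", "))
  }
  od <- raw$data
  for (w in seq_len(dim(od)[2])) {
    m <- apply(od[, w, , drop = FALSE], 1, mean)
    od[, w, ] <- -log(od[, w, ] / m)
  }
  od
}

# Zero-phase Fourier-domain filters (offline data; brick-wall masks).
fft_filter <- function(x, fs, lo = NULL, hi = NULL) {
  n <- length(x)
  xf <- stats::fft(x)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  keep <- rep(TRUE, n)
  if (!is.null(lo)) keep <- keep & f >= lo
  if (!is.null(hi)) keep <- keep & f <= hi
  xf[!keep] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Zero-phase band-pass filter
#'
#' Fourier-domain masking band-pass (exactly zero phase, no transient), used
#' for the final hemodynamic band selection and for the phase-locking-value
#' pipeline.
#'
#' @param x numeric vector or channels x time matrix.
#' @param fs sampling rate (Hz).
#' @param band `(f_lo, f_hi)` in Hz.
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs, band = c(0.01, 0.2)) {
  if (is.matrix(x))
    t(apply(x, 1, fft_filter, fs = fs, lo = band[1], hi = band[2]))
  else fft_filter(x, fs, lo = band[1], hi = band[2])
}

#' Temporal derivative distribution repair (motion-artifact correction)
#'
#' Robustly reweights the temporal derivative of the low-frequency component
#' of a single channel (iterative Tukey biweight on the centered derivative)
#' and re-integrates, suppressing motion spikes and baseline steps while
#' leaving clean signal nearly untouched. The high-frequency residual
#' (above `split` Hz) is added back unchanged; despiking it is the job of
#' [hampel_highfreq()].
#'
#' @param x single-channel numeric series.
#' @param fs sampling rate (Hz).
#' @param split low/high frequency split in Hz (default 0.5).
#' @return repaired series, same length.
#' @export
tddr <- function(x, fs, split = 0.5) {
  n <- length(x)
  if (n < 10) {
    warning("series shorter than filter support; returning input")
    return(x)
  }
  if (all(x == 0)) return(x)
  low <- fft_filter(x, fs, hi = split)
  high <- x - low
  tddr_core(low) + high
}

# Robust derivative reweighting of an already low-passed series. The
# location/scale iteration uses the Tukey biweight; the applied weights keep
# unit weight inside a deadband (|u| <= 0.5) and redescend to zero by
# |u| = 1, so sub-threshold physiological derivatives pass through unaltered
# while gross motion derivatives are removed.
tddr_core <- function(low, deadband = 0.5) {
  d <- diff(low)
  w <- rep(1, length(d))
  mu <- 0
  s <- 0
  for (iter in seq_len(50)) {
    mu_new <- sum(w * d) / sum(w)
    r <- d - mu_new
    s <- 1.4826 * stats::median(abs(r - stats::median(r)))
    if (s == 0) { w <- rep(1, length(d)); mu <- mu_new; break }
    u <- r / (4.685 * s)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (max(abs(w_new - w)) < 1e-9) { w <- w_new; mu <- mu_new; break }
    w <- w_new; mu <- mu_new
  }
  if (s > 0) {
    u <- abs(d - mu) / (4.685 * s)
    v <- pmin(pmax((u - deadband) / (1 - deadband), 0), 1)
    w <- (1 - v^2)^2
  }
  d_corr <- w * (d - mu)
  low_corr <- cumsum(c(0, d_corr))
  low_corr - mean(low_corr) + mean(low)
}

#' Hampel despiking of the high-frequency component
#'
#' Rolling-median outlier replacement: samples farther than `nsigma` scaled
#' MADs from the centered rolling median are replaced by that median.
#' Intended for the high-frequency residual of the motion-repair split, where
#' derivative reweighting can leave isolated spikes.
#'
#' @param x single-channel numeric series.
#' @param halfwidth samples on each side of the window (default 50).
#' @param nsigma replacement threshold (default 4).
#' @return despiked series.
#' @export
hampel_highfreq <- function(x, halfwidth = 50, nsigma = 4) {
  stopifnot(halfwidth >= 1)
  if (length(x) < 2 * halfwidth + 2 || stats::sd(x) == 0) return(x)
  pracma::hampel(x, k = halfwidth, t0 = nsigma)$y
}

#' Motion repair of an OD array (derivative reweighting + Hampel)
#'
#' Applies [tddr()] to the sub-`split` component and [hampel_highfreq()] to
#' the high-frequency residual of every channel/wavelength series.
#'
#' @param od channels x wavelengths x time OD array.
#' @param fs sampling rate (Hz).
#' @param cfg a [preprocess_config()].
#' @return repaired OD array.
#' @export
motion_repair <- function(od, fs, cfg = preprocess_config()) {
  for (i in seq_len(dim(od)[1]))
    for (w in seq_len(dim(od)[2])) {
      x <- od[i, w, ]
      if (all(x == 0)) next
      low <- fft_filter(x, fs, hi = cfg$tddr_split)
      high <- x - low
      od[i, w, ] <- tddr_core(low) +
        hampel_highfreq(high, cfg$hampel_halfwidth, cfg$hampel_nsigma)
    }
  od
}

#' Modified Beer-Lambert conversion of OD to hemoglobin concentrations
#'
#' Per channel and time point solves the 2 x 2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d *
#' DPF(lambda, age)` for `(dHbO, dHbR)` in micromol/L.
#'
#' @param od channels x wavelengths x time OD array (wavelength order
#'   matching `extinction_table` rows).
#' @param layout a [probe_layout()] (source-detector separation).
#' @param age subject age in years (used when `dpf_mode = "age_formula"`).
#' @param extinction_table see [extinction_defaults()].
#' @param cfg a [preprocess_config()].
#' @param valid_channels optional validity mask carried onto the result.
#' @return an [hb_series()].
#' @export
mbll_convert <- function(od, layout, age = 10,
                         extinction_table = extinction_defaults(),
                         cfg = preprocess_config(),
                         valid_channels = rep(TRUE, dim(od)[1])) {
  wl <- as.numeric(rownames(extinction_table))
  dpf <- if (cfg$dpf_mode == "age_formula")
    vapply(wl, dpf_age, numeric(1), age = age)
  else rep(cfg$dpf_fixed, length(wl))
  A <- extinction_table * layout$separation_cm * dpf   # row-wise scaling
  if (abs(det(A)) < 1e-14) stop("singular extinction matrix")
  Ainv <- solve(A)
  n <- dim(od)[1]; N <- dim(od)[3]
  hbo <- matrix(0, n, N); hbr <- matrix(0, n, N)
  for (i in seq_len(n)) {
    conc <- Ainv %*% od[i, , ]
    hbo[i, ] <- conc[1, ]
    hbr[i, ] <- conc[2, ]
  }
  hb_series(hbo, hbr, fs = attr(od, "fs") %||% 10,
            valid_channels = valid_channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Second-order polynomial detrending
#'
#' Removes the least-squares quadratic fit; the output is orthogonal to
#' `{1, t, t^2}`.
#'
#' @param x numeric vector or channels x time matrix.
#' @return detrended data, same shape.
#' @export
detrend2 <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, detrend2)))
  n <- length(x)
  if (n < 3) return(x - mean(x))
  tt <- seq_len(n)
  stats::lm.fit(cbind(1, tt, tt^2), x)$residuals
}

#' Remove leading principal components (global physiological signal)
#'
#' Channels are variables; the data are channel-centered, the top `k`
#' principal components (largest eigenvalues of the channel covariance) are
#' removed, and channel means are restored. Used to subtract the systemic
#' component shared across the montage.
#'
#' @param x channels x time matrix.
#' @param k number of components to remove (default 1).
#' @return filtered matrix, same shape.
#' @export
pca_global_remove <- function(x, k = 1) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 channels")
  if (k >= n) stop("k must be smaller than the number of channels")
  mu <- rowMeans(x)
  xc <- x - mu
  e <- eigen(stats::cov(t(xc)), symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  xc - V %*% (t(V) %*% xc) + mu
}

#' Full preprocessing chain: raw intensity to band-limited hemoglobin
#'
#' Stage order: channel QC on intensities, OD conversion, motion repair
#' (derivative reweighting + Hampel despiking), modified Beer-Lambert
#' conversion with age-dependent DPF, quadratic detrending, removal of the
#' first principal component, and zero-phase selection of the hemodynamic
#' band. Invalid channels are carried through untouched but masked.
#'
#' @param raw a [raw_intensity()].
#' @param layout a [probe_layout()].
#' @param age subject age in years.
#' @param cfg a [preprocess_config()].
#' @param extinction_table see [extinction_defaults()].
#' @param condition condition label carried onto the result.
#' @return an [hb_series()] restricted to the analysis band.
#' @export
preprocess <- function(raw, layout, age = 10, cfg = preprocess_config(),
                       extinction_table = extinction_defaults(),
                       condition = "rest") {
  valid <- qc_channels(raw, cfg)
  od <- intensity_to_od(raw)
  attr(od, "fs") <- raw$fs
  od <- motion_repair(od, raw$fs, cfg)
  attr(od, "fs") <- raw$fs
  hb <- mbll_convert(od, layout, age, extinction_table, cfg, valid)
  hbo <- detrend2(hb$hbo)
  hbr <- detrend2(hb$hbr)
  if (cfg$pca_remove > 0 && sum(valid) > cfg$pca_remove + 1) {
    hbo[valid, ] <- pca_global_remove(hbo[valid, , drop = FALSE],
                                      cfg$pca_remove)
    hbr[valid, ] <- pca_global_remove(hbr[valid, , drop = FALSE],
                                      cfg$pca_remove)
  }
  hbo <- bandpass(hbo, raw$fs, cfg$band)
  hbr <- bandpass(hbr, raw$fs, cfg$band)
  hb_series(hbo, hbr, fs = raw$fs, valid_channels = valid,
            condition = condition)
}
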