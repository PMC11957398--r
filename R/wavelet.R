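#' Morlet wavelet analysis configuration
#'
#' @param omega0 Morlet central frequency (dimensionless, default 6: the
#'   standard time-frequency trade-off).
#' @param n_voices number of logarithmically spaced scales (default 64).
#' @param f_range frequency span of the scale grid in Hz (default
#'   0.005-0.25, so the averaging band sits strictly inside the grid).
#' @param band averaging band in Hz (default 0.01-0.2).
#' @param coi_policy `"exclude"` (default) drops samples inside the cone of
#'   influence from time averages; `"include"` keeps them.
#' @return an object of class `wavelet_config`.
#' @export
wavelet_config <- function(omega0 = 6, n_voices = 64,
                           f_range = c(0.005, 0.25), band = c(0.01, 0.2),
                           coi_policy = c("exclude", "include")) {
  coi_policy <- match.arg(coi_policy)
  stopifnot(f_range[1] < f_range[2],
            band[1] >= f_range[1], band[2] <= f_range[2])
  structure(list(omega0 = omega0, n_voices = n_voices, f_range = f_range,
                 band = band, coi_policy = coi_policy),
            class = "wavelet_config")
}

# Fourier factor: frequency corresponding to scale s is ff / s.
morlet_fourier_factor <- function(omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform with the analytic Morlet mother
#' wavelet `pi^(-1/4) exp(-i omega0 u) exp(-u^2/2)`, evaluated on a geometric
#' scale grid mapped to `cfg$f_range`. The transform is linear in the input.
#'
#' @param x finite numeric time series.
#' @param fs sampling rate (Hz).
#' @param cfg a [wavelet_config()].
#' @return object of class `wavelet_spectrum`: complex coefficient matrix `W`
#'   (scales x time), `freqs` (Hz, increasing), `scales` (s), `coi` (per-time
#'   minimum fully-resolved frequency, Hz), `fs`, `omega0`.
#' @export
cwt_morlet <- function(x, fs, cfg = wavelet_config()) {
  if (anyNA(x) || any(!is.finite(x))) stop("input contains NA/non-finite")
  n <- length(x)
  ff <- morlet_fourier_factor(cfg$omega0)
  freqs <- exp(seq(log(cfg$f_range[1]), log(cfg$f_range[2]),
                   length.out = cfg$n_voices))
  if (n < 2 * fs / cfg$band[1])
    warning("series shorter than 2 periods of the lowest analyzed frequency")
  scales <- ff / freqs
  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  omega <- 2 * pi * fs / npad * c(0:(npad / 2), -((npad / 2 - 1):1))
  W <- matrix(0i, length(scales), n)
  norm0 <- pi^(-1 / 4)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi_hat <- sqrt(2 * pi * s * fs) * norm0 *
      exp(-(s * omega - cfg$omega0)^2 / 2) * (omega > 0)
    Wk <- stats::fft(xf * psi_hat, inverse = TRUE) / npad
    W[k, ] <- Wk[seq_len(n)]
  }
  # e-folding time sqrt(2)*s: times closer than that to an edge are inside
  # the cone of influence at scale s
  tt <- pmin(seq_len(n) - 1, n - seq_len(n)) / fs
  coi_freq <- ff * sqrt(2) / pmax(tt, 1e-12)
  structure(list(W = W, freqs = freqs, scales = scales, coi = coi_freq,
                 fs = fs, omega0 = cfg$omega0, coi_policy = cfg$coi_policy),
            class = "wavelet_spectrum")
}

# Indices of scales inside the averaging band.
band_scales <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

# Logical scales x time matrix of samples outside the cone of influence.
coi_mask <- function(spec) {
  outer(spec$freqs, spec$coi, ">=")
}

#' Wavelet amplitude (cortical activation index)
#'
#' Mean wavelet-coefficient magnitude over the in-band scales and the whole
#' epoch: `WA = mean_{s in band, t} |W(s, t)|`. Samples inside the cone of
#' influence are excluded when the spectrum was computed with
#' `coi_policy = "exclude"`.
#'
#' @param spec a `wavelet_spectrum` from [cwt_morlet()].
#' @param band averaging band in Hz.
#' @return scalar WA.
#' @export
wavelet_amplitude <- function(spec, band = c(0.01, 0.2)) {
  ks <- band_scales(spec, band)
  if (!length(ks)) stop("band outside the scale grid")
  A <- abs(spec$W[ks, , drop = FALSE])
  if (spec$coi_policy == "exclude") {
    m <- coi_mask(spec)[ks, , drop = FALSE]
    if (!any(m)) return(mean(A))
    return(mean(A[m]))
  }
  mean(A)
}

#' Per-channel and per-region wavelet amplitude
#'
#' @param hb an [hb_series()].
#' @param regions character vector of region labels per channel (e.g. from
#'   [assign_dominance()]).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param cfg a [wavelet_config()].
#' @return list with `channel` (named numeric, `NA` for invalid channels)
#'   and `region` (named numeric: mean over the region's valid channels).
#' @export
wa_by_region <- function(hb, regions, chromophore = c("hbo", "hbr"),
                         cfg = wavelet_config()) {
  chromophore <- match.arg(chromophore)
  X <- hb[[chromophore]]
  wa <- rep(NA_real_, nrow(X))
  for (i in which(hb$valid_channels))
    wa[i] <- wavelet_amplitude(cwt_morlet(X[i, ], hb$fs, cfg), cfg$band)
  lev <- sort(unique(regions))
  reg <- tapply(wa[hb$valid_channels],
                factor(regions[hb$valid_channels], levels = lev), mean)
  if (anyNA(reg)) stop("a region has no valid channels")
  list(channel = wa, region = reg)
}

#' Lateralization index
#'
#' `LI = (WAi - WAo) / (WAi + WAo)` where `WAi` and `WAo` are the mean
#' wavelet amplitudes of the ipsilateral (dominant) and contralateral
#' channels. `LI = 1` is complete ipsilateral activation, `-1` complete
#' contralateral activation; both inputs zero is undefined and returns `NA`.
#'
#' @param wa_ipsi,wa_contra nonnegative mean wavelet amplitudes.
#' @return LI in `[-1, 1]`, or `NA` if both inputs are zero.
#' @export
lateralization_index <- function(wa_ipsi, wa_contra) {
  if (wa_ipsi < 0 || wa_contra < 0) stop("wavelet amplitudes must be >= 0")
  if (wa_ipsi + wa_contra == 0) return(NA_real_)
  (wa_ipsi - wa_contra) / (wa_ipsi + wa_contra)
}

#' Wavelet coherence between two spectra
#'
#' Per frequency, the squared magnitude of the time-averaged cross-spectrum
#' normalized by the time-averaged powers:
#' `WCO(f) = |mean_t Wx Wy*|^2 / (Px Py)`, which lies in `[0, 1]` by
#' Cauchy-Schwarz (time averaging is the smoothing operator). The band value
#' is the mean of `WCO(f)` over in-band frequencies. Symmetric in x and y.
#'
#' @param spec_x,spec_y `wavelet_spectrum` objects on the same grid.
#' @param band averaging band in Hz.
#' @return list with `band` (scalar) and `per_freq` (named numeric).
#' @export
wavelet_coherence <- function(spec_x, spec_y, band = c(0.01, 0.2)) {
  stopifnot(length(spec_x$freqs) == length(spec_y$freqs),
            ncol(spec_x$W) == ncol(spec_y$W))
  ks <- band_scales(spec_x, band)
  mask <- if (spec_x$coi_policy == "exclude") coi_mask(spec_x) else NULL
  wco_f <- rep(NA_real_, length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    keep <- if (is.null(mask)) rep(TRUE, ncol(spec_x$W)) else mask[k, ]
    if (!any(keep)) keep <- rep(TRUE, ncol(spec_x$W))
    wx <- spec_x$W[k, keep]; wy <- spec_y$W[k, keep]
    px <- mean(abs(wx)^2); py <- mean(abs(wy)^2)
    if (px == 0 || py == 0) {
      warning("zero power at ", signif(spec_x$freqs[k], 3), " Hz; skipped")
      next
    }
    wco_f[j] <- Mod(mean(wx * Conj(wy)))^2 / (px * py)
  }
  names(wco_f) <- signif(spec_x$freqs[ks], 4)
  list(band = mean(wco_f, na.rm = TRUE), per_freq = wco_f)
}

#' Channel-by-channel wavelet-coherence matrix
#'
#' @param hb an [hb_series()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param cfg a [wavelet_config()].
#' @return symmetric n x n matrix of band WCO values with unit diagonal;
#'   rows/columns of invalid channels are `NA`.
#' @export
wco_matrix <- function(hb, chromophore = c("hbo", "hbr"),
                       cfg = wavelet_config()) {
  chromophore <- match.arg(chromophore)
  X <- hb[[chromophore]]
  n <- nrow(X)
  valid <- which(hb$valid_channels)
  specs <- vector("list", n)
  for (i in valid) specs[[i]] <- cwt_morlet(X[i, ], hb$fs, cfg)
  M <- matrix(NA_real_, n, n)
  M[cbind(valid, valid)] <- 1
  if (length(valid) > 1)
    for (a in seq_along(valid)[-length(valid)])
      for (b in (a + 1):length(valid)) {
        i <- valid[a]; j <- valid[b]
        M[i, j] <- M[j, i] <-
          wavelet_coherence(specs[[i]], specs[[j]], cfg$band)$band
      }
  M
}

#' Aggregate a channel-level connectivity matrix to region level
#'
#' Entry (A, B) is the mean over valid channel pairs with one channel in A
#' and one in B; diagonal blocks average distinct pairs (i < j) only.
#'
#' @param channel_matrix symmetric channel x channel matrix (`NA` for
#'   invalid channels).
#' @param regions character region label per channel.
#' @return symmetric region x region matrix (`NA` where a region has no
#'   valid pair).
#' @export
region_connectivity <- function(channel_matrix, regions) {
  stopifnot(nrow(channel_matrix) == length(regions))
  labs <- sort(unique(regions))
  R <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (a in seq_along(labs))
    for (b in a:length(labs)) {
      ia <- which(regions == labs[a]); ib <- which(regions == labs[b])
      vals <- if (a == b) {
        if (length(ia) < 2) numeric(0)
        else {
          pr <- utils::combn(ia, 2)
          channel_matrix[cbind(pr[1, ], pr[2, ])]
        }
      } else channel_matrix[as.matrix(expand.grid(ia, ib))]
      v <- vals[!is.na(vals)]
      if (length(v)) R[a, b] <- R[b, a] <- mean(v)
    }
  R
}
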