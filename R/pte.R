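#' Band-averaged instantaneous phase from a wavelet spectrum
#'
#' The per-sample phase is the argument of the mean in-band complex wavelet
#' coefficient (circular-mean convention), wrapped to `(-pi, pi]`. Samples
#' where the averaged coefficient vanishes have undefined phase and are
#' linearly interpolated from their neighbors.
#'
#' @param spec a `wavelet_spectrum` from [cwt_morlet()].
#' @param band averaging band in Hz.
#' @return numeric phase series in radians.
#' @export
band_phase <- function(spec, band = c(0.01, 0.2)) {
  ks <- band_scales(spec, band)
  if (!length(ks)) stop("band outside the scale grid")
  z <- colMeans(spec$W[ks, , drop = FALSE])
  th <- Arg(z)
  bad <- Mod(z) == 0
  if (any(bad)) {
    ok <- which(!bad)
    if (!length(ok)) stop("phase undefined everywhere")
    th[bad] <- stats::approx(ok, th[ok], xout = which(bad), rule = 2)$y
  }
  th
}

#' Per-channel band phase matrix
#'
#' @param hb an [hb_series()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param cfg a [wavelet_config()].
#' @return channels x time phase matrix (`NA` rows for invalid channels).
#' @export
phase_matrix <- function(hb, chromophore = c("hbo", "hbr"),
                         cfg = wavelet_config()) {
  chromophore <- match.arg(chromophore)
  X <- hb[[chromophore]]
  out <- matrix(NA_real_, nrow(X), ncol(X))
  for (i in which(hb$valid_channels))
    out[i, ] <- band_phase(cwt_morlet(X[i, ], hb$fs, cfg), cfg$band)
  out
}

#' Scott's-choice histogram width for phase data
#'
#' `binsize = 3.49 * mean(sd(theta per channel)) * Ns^(-1/3)`; the number of
#' uniform bins over `(-pi, pi]` is `ceiling(2 pi / binsize)`.
#'
#' @param theta phase matrix (channels x time) or vector.
#' @param Ns sample size (defaults to the number of time points).
#' @return list with `binsize` and `n_bins`.
#' @export
scott_binsize <- function(theta, Ns = NULL) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  if (is.null(Ns)) Ns <- ncol(theta)
  if (Ns < 2) stop("Ns must be >= 2")
  sds <- apply(theta, 1, stats::sd, na.rm = TRUE)
  msd <- mean(sds, na.rm = TRUE)
  if (!is.finite(msd) || msd == 0) stop("zero phase variance")
  binsize <- 3.49 * msd * Ns^(-1 / 3)
  list(binsize = binsize, n_bins = max(2L, as.integer(ceiling(2 * pi / binsize))))
}

# Wrap angles into (-pi, pi] and map to 1..n_bins uniform bins.
phase_bins <- function(theta, n_bins) {
  th <- theta - 2 * pi * floor((theta + pi) / (2 * pi))  # (-pi, pi]
  idx <- ceiling((th + pi) / (2 * pi) * n_bins)
  pmin(pmax(idx, 1L), n_bins)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Phase transfer entropy between two phase series
#'
#' Histogram estimator of
#' `PTE_xy = H(Y+, Y) + H(Y, X) - H(Y) - H(Y+, Y, X)` where `Y+` is the
#' target phase advanced by `delay` samples; probabilities come from joint
#' histograms on uniform phase bins over `(-pi, pi]`, entropies in bits.
#'
#' @param theta_x,theta_y source and target phase series (radians), equal
#'   length greater than `delay`.
#' @param delay prediction delay in samples (>= 1).
#' @param n_bins number of phase bins (e.g. from [scott_binsize()]).
#' @return nonnegative (up to estimator noise) PTE in bits.
#' @export
phase_transfer_entropy <- function(theta_x, theta_y, delay, n_bins) {
  stopifnot(length(theta_x) == length(theta_y), delay >= 1, n_bins >= 2)
  N <- length(theta_y) - delay
  if (N < 2) stop("series too short for the requested delay")
  x <- phase_bins(theta_x[seq_len(N)], n_bins)
  y <- phase_bins(theta_y[seq_len(N)], n_bins)
  yd <- phase_bins(theta_y[seq_len(N) + delay], n_bins)
  h_y <- entropy_bits(tabulate(y, n_bins))
  h_yd_y <- entropy_bits(tabulate((yd - 1L) * n_bins + y, n_bins^2))
  h_y_x <- entropy_bits(tabulate((y - 1L) * n_bins + x, n_bins^2))
  h_yd_y_x <- entropy_bits(tabulate(((yd - 1L) * n_bins + (y - 1L)) * n_bins
                                    + x, n_bins^3))
  h_yd_y + h_y_x - h_y - h_yd_y_x
}

#' Directional PTE (dPTE)
#'
#' `dPTE_xy = PTE_xy / (PTE_xy + PTE_yx)`, in `[0, 1]`, with
#' `dPTE_xy + dPTE_yx = 1`. Values above 0.5 indicate preferential
#' information flow from X to Y, below 0.5 from Y to X, and exactly 0.5 no
#' preferred direction.
#'
#' @param pte_xy,pte_yx nonnegative transfer entropies.
#' @return dPTE from X to Y.
#' @export
dpte <- function(pte_xy, pte_yx) {
  if (pte_xy < 0 || pte_yx < 0) {
    # estimator noise can make tiny negatives; clamp symmetric at zero
    pte_xy <- max(pte_xy, 0); pte_yx <- max(pte_yx, 0)
  }
  if (pte_xy + pte_yx == 0) {
    warning("both transfer entropies zero; returning 0.5")
    return(0.5)
  }
  pte_xy / (pte_xy + pte_yx)
}

#' Prediction delay from phase sign reversals
#'
#' The delay (samples) is the ratio of total phase samples to the total
#' number of sign changes across all channels' phase series, rounded, with a
#' floor of 1: faster phase dynamics give shorter delays.
#'
#' @param theta channels x time phase matrix (or vector).
#' @return integer delay in samples (>= 1).
#' @export
estimate_delay <- function(theta) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  theta <- theta[stats::complete.cases(theta), , drop = FALSE]
  flips <- sum(theta[, -1, drop = FALSE] * theta[, -ncol(theta), drop = FALSE]
               < 0)
  if (flips == 0) {
    warning("no phase sign changes; using delay 1")
    return(1L)
  }
  max(1L, as.integer(round(length(theta) / flips)))
}

#' Full dPTE network from an hb recording
#'
#' Computes band-averaged wavelet phases for every valid channel, a common
#' prediction delay (phase-reversal heuristic) and Scott bin count, then the
#' pairwise PTE in both directions and the normalized dPTE matrix.
#'
#' @param hb an [hb_series()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param cfg a [wavelet_config()].
#' @param delay prediction delay in samples; `NULL` (default) uses
#'   [estimate_delay()].
#' @param n_bins bin count; `NULL` (default) uses [scott_binsize()].
#' @return object of class `directed_network`: `dpte` matrix (diagonal `NA`;
#'   `M + t(M) = 1` off-diagonal among valid channels), `pte` matrix, and the
#'   `delay`/`n_bins` used.
#' @export
dpte_matrix <- function(hb, chromophore = c("hbo", "hbr"),
                        cfg = wavelet_config(), delay = NULL, n_bins = NULL) {
  theta <- phase_matrix(hb, chromophore, cfg)
  valid <- which(hb$valid_channels)
  th <- theta[valid, , drop = FALSE]
  if (is.null(delay)) delay <- estimate_delay(th)
  if (is.null(n_bins)) n_bins <- scott_binsize(th)$n_bins
  n <- nrow(theta)
  P <- matrix(NA_real_, n, n)
  D <- matrix(NA_real_, n, n)
  for (a in seq_along(valid))
    for (b in seq_along(valid)) {
      if (a == b) next
      i <- valid[a]; j <- valid[b]
      P[i, j] <- phase_transfer_entropy(theta[i, ], theta[j, ], delay, n_bins)
    }
  for (a in seq_along(valid))
    for (b in seq_along(valid)) {
      if (a >= b) next
      i <- valid[a]; j <- valid[b]
      D[i, j] <- dpte(P[i, j], P[j, i])
      D[j, i] <- 1 - D[i, j]
    }
  structure(list(dpte = D, pte = P, delay = delay, n_bins = n_bins),
            class = "directed_network")
}

#' Out-degree and outflow-strength summaries of a dPTE network
#'
#' `out_degree_i` counts targets j with `dpte_ij > 0.5`;
#' `outflow_strength_i` sums `dpte_ij` over those targets (`mode = "sum"`,
#' default) or the excess `dpte_ij - 0.5` (`mode = "excess"`). Region values
#' are means over each region's member channels.
#'
#' @param net a `directed_network` from [dpte_matrix()] (or a bare dPTE
#'   matrix).
#' @param regions optional character region label per channel.
#' @param mode `"sum"` or `"excess"`.
#' @return list with `out_degree`, `outflow_strength` (per channel; `NA` for
#'   invalid channels) and, when `regions` is given, `region_out_degree` and
#'   `region_outflow`.
#' @export
network_summaries <- function(net, regions = NULL,
                              mode = c("sum", "excess")) {
  mode <- match.arg(mode)
  D <- if (inherits(net, "directed_network")) net$dpte else as.matrix(net)
  n <- nrow(D)
  outdeg <- rep(NA_real_, n)
  outflow <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    row <- D[i, -i]
    if (all(is.na(row))) next
    sel <- !is.na(row) & row > 0.5
    outdeg[i] <- sum(sel)
    outflow[i] <- if (mode == "sum") sum(row[sel])
                  else sum(row[sel] - 0.5)
  }
  res <- list(out_degree = outdeg, outflow_strength = outflow)
  if (!is.null(regions)) {
    ok <- !is.na(outdeg)
    res$region_out_degree <- tapply(outdeg[ok], regions[ok], mean)
    res$region_outflow <- tapply(outflow[ok], regions[ok], mean)
  }
  res
}
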