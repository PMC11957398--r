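#' Sliding-window start indices
#'
#' Windows of `width` seconds advance by `step` seconds; the window count is
#' `floor((N - W) / step)` in samples, the convention that yields 340 windows
#' for a 6-minute recording at 10 Hz with 20 s windows and 1 s steps (a
#' window flush against the end of the recording is dropped).
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate (Hz).
#' @param width window width (s), default 20.
#' @param step step (s), default 1.
#' @return integer vector of 1-based window start samples (possibly empty).
#' @export
slide_windows <- function(n_samples, fs, width = 20, step = 1) {
  W <- round(width * fs); S <- round(step * fs)
  stopifnot(W > S, S > 0)
  if (n_samples < W) stop("recording shorter than one window")
  k <- floor((n_samples - W) / S)
  if (k < 1) return(integer(0))
  seq(0, k - 1) * S + 1
}

# Analytic-signal phase via the FFT Hilbert transform.
analytic_phase <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(xf * h, inverse = TRUE) / n)
}

#' Phase-locking value matrix of one window
#'
#' `PLV_ij = |mean_t exp(i (phi_i - phi_j))|` with phases from the analytic
#' signal (Hilbert transform) of band-filtered data; symmetric, unit
#' diagonal, entries in `[0, 1]`, invariant to per-channel amplitude scaling.
#'
#' @param x channels x time matrix (already band-filtered).
#' @return symmetric PLV matrix.
#' @export
plv_matrix <- function(x) {
  if (any(apply(x, 1, stats::sd) == 0)) stop("constant channel in window")
  ph <- t(apply(x, 1, analytic_phase))
  z <- exp(1i * ph)
  n <- nrow(x)
  M <- (Mod(z %*% Conj(t(z))) / ncol(x))
  diag(M) <- 1
  pmin(M, 1)
}

#' Sliding-window PLV feature matrix
#'
#' Band-filters the selected channels, extracts the per-channel analytic
#' phase once over the whole recording, and assembles for every window the
#' upper-triangle PLV entries (via cumulative sums of the pairwise phase
#' difference phasors, so the cost is linear in recording length).
#'
#' @param hb an [hb_series()].
#' @param channels integer indices of the channels to use (e.g. the 20 motor
#'   channels, giving 190 features).
#' @param band band-pass edges (Hz).
#' @param width,step window width and step (s).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return list: `features` (windows x n_pairs PLV matrix), `starts` (window
#'   start samples), `pairs` (2-column index matrix), `width`, `step`.
#' @export
plv_window_features <- function(hb, channels, band = c(0.01, 0.2),
                                width = 20, step = 1,
                                chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  X <- hb[[chromophore]][channels, , drop = FALSE]
  Xf <- bandpass(X, hb$fs, band)
  ph <- t(apply(Xf, 1, analytic_phase))
  starts <- slide_windows(ncol(X), hb$fs, width, step)
  W <- round(width * hb$fs)
  pairs <- t(utils::combn(length(channels), 2))
  feats <- matrix(0, length(starts), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    z <- exp(1i * (ph[pairs[p, 1], ] - ph[pairs[p, 2], ]))
    cz <- c(0, cumsum(z))
    feats[, p] <- Mod(cz[starts + W] - cz[starts]) / W
  }
  list(features = feats, starts = starts, pairs = pairs,
       width = width, step = step)
}

#' Compress window features with a symmetric autoencoder
#'
#' Trains a 1-hidden-layer autoencoder (input -> `dim` tanh units -> linear
#' reconstruction) on the window features with full-batch Adam and
#' mean-squared loss, and returns the encoder activations. Deterministic
#' given (data, spec, seed). `method = "pca"` substitutes the leading
#' principal-component scores, useful for isolating the clustering stage from
#' training noise.
#'
#' @param features windows x n_features matrix (finite).
#' @param dim bottleneck dimension, default 64.
#' @param method `"autoencoder"` (default) or `"pca"`.
#' @param epochs training epochs (default 200).
#' @param lr Adam learning rate.
#' @param seed RNG seed for the weight initialization.
#' @return windows x `dim` matrix; attribute `"loss"` carries the per-epoch
#'   training loss for the autoencoder.
#' @export
encode_features <- function(features, dim = 64,
                            method = c("autoencoder", "pca"),
                            epochs = 200, lr = 0.01, seed = 1L) {
  method <- match.arg(method)
  if (any(!is.finite(features))) stop("non-finite features")
  n <- nrow(features); p <- ncol(features)
  if (n < dim) warning("fewer windows than bottleneck dimensions")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  if (method == "pca") {
    d <- min(dim, n - 1, p)
    sc <- stats::prcomp(X, center = FALSE)$x[, seq_len(d), drop = FALSE]
    if (d < dim) sc <- cbind(sc, matrix(0, n, dim - d))
    return(sc)
  }
  set.seed(seed)
  W1 <- matrix(stats::rnorm(p * dim, 0, sqrt(1 / p)), p, dim)
  b1 <- numeric(dim)
  W2 <- matrix(stats::rnorm(dim * p, 0, sqrt(1 / dim)), dim, p)
  b2 <- numeric(p)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(z) z * 0)
  v <- lapply(params, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    H <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
    Xhat <- sweep(H %*% params$W2, 2, params$b2, "+")
    R <- Xhat - X
    loss[ep] <- mean(R^2)
    gXhat <- 2 * R / (n * p)
    grads <- list(
      W1 = t(X) %*% ((gXhat %*% t(params$W2)) * (1 - H^2)),
      b1 = colSums((gXhat %*% t(params$W2)) * (1 - H^2)),
      W2 = t(H) %*% gXhat,
      b2 = colSums(gXhat))
    for (nm in names(params)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^ep)
      vhat <- v[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  H <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
  attr(H, "loss") <- loss
  H
}

# Elbow: the k whose point on the normalized WCSS curve lies farthest from
# the chord joining the first and last grid points.
elbow_k <- function(ks, wcss) {
  if (length(ks) < 3) return(ks[which.min(wcss)])
  x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
  y <- (wcss - wcss[length(wcss)]) / max(wcss[1] - wcss[length(wcss)], 1e-12)
  # distance from (x, y) to the chord from (0, 1) to (1, 0)
  d <- abs(x + y - 1) / sqrt(2)
  ks[which.max(d)]
}

#' K-means connectivity-state clustering with elbow model selection
#'
#' For each candidate k, runs K-means with `restarts` random initializations
#' (keeping the lowest within-cluster sum of squares); the number of states
#' is chosen by the elbow criterion (maximum perpendicular distance of the
#' normalized WCSS curve from its end-to-end chord). Deterministic given
#' `seed`.
#'
#' @param reduced windows x feature matrix (typically the encoder output).
#' @param k_range candidate state counts, default `1:10`.
#' @param restarts random restarts per k, default 500.
#' @param seed master RNG seed.
#' @return object of class `state_model`: `k`, `centroids`, `labels`,
#'   `wcss` (per candidate k), `k_range`.
#' @export
cluster_states <- function(reduced, k_range = 1:10, restarts = 500,
                           seed = 1L) {
  if (!length(k_range)) stop("k_range is empty")
  if (nrow(reduced) < max(k_range)) stop("fewer windows than max k")
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    suppressWarnings(stats::kmeans(reduced, centers = k, nstart = restarts,
                                   iter.max = 100)))
  wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  k_star <- elbow_k(k_range, wcss)
  best <- fits[[match(k_star, k_range)]]
  structure(list(k = k_star, centroids = best$centers,
                 labels = as.integer(best$cluster), wcss = wcss,
                 k_range = k_range),
            class = "state_model")
}

#' Ground-truth labels for sliding windows
#'
#' Maps a per-sample planted state sequence to per-window labels: each window
#' gets the state occupying most of its samples, and is flagged `pure` when a
#' single state spans the whole window. Windows straddling a state switch
#' have no well-defined planted state; agreement scores against planted
#' labels should be computed on the pure windows.
#'
#' @param state_labels integer per-sample state sequence (ground truth).
#' @param starts window start samples (from [slide_windows()]).
#' @param width_samples window width in samples.
#' @return list with `label` (majority state per window) and `pure` (logical).
#' @export
window_state_labels <- function(state_labels, starts, width_samples) {
  lab <- integer(length(starts))
  pure <- logical(length(starts))
  for (w in seq_along(starts)) {
    seg <- state_labels[starts[w]:(starts[w] + width_samples - 1)]
    tab <- tabulate(seg)
    lab[w] <- which.max(tab)
    pure[w] <- max(tab) == length(seg)
  }
  list(label = lab, pure = pure)
}

#' State-dynamics summaries from a window label sequence
#'
#' @param labels integer state label per window (1..k).
#' @param step window step in seconds (converts run lengths to dwell times).
#' @param k number of states (default: max label).
#' @return list: `frequency` (fraction of windows per state, sums to 1),
#'   `mean_dwell` (mean run length per state x `step`, seconds; `NA` for
#'   unvisited states), `transition_matrix` (row-stochastic k x k from
#'   consecutive windows; `NA` rows when a state has no outgoing
#'   transitions), `transition_percentage` (share of each off-diagonal
#'   transition among all off-diagonal transitions).
#' @export
state_dynamics <- function(labels, step = 1, k = max(labels)) {
  stopifnot(length(labels) > 0)
  n <- length(labels)
  freq <- tabulate(labels, k) / n
  r <- rle(labels)
  dwell <- vapply(seq_len(k), function(s) {
    if (!any(r$values == s)) return(NA_real_)
    mean(r$lengths[r$values == s]) * step
  }, numeric(1))
  TM <- matrix(0, k, k)
  if (n > 1)
    for (t in seq_len(n - 1))
      TM[labels[t], labels[t + 1]] <- TM[labels[t], labels[t + 1]] + 1
  counts <- TM
  rs <- rowSums(TM)
  TM <- TM / ifelse(rs > 0, rs, NA)
  off <- counts; diag(off) <- 0
  tp <- if (sum(off) > 0) off / sum(off) else off
  list(frequency = freq, mean_dwell = dwell, transition_matrix = TM,
       transition_percentage = tp)
}
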