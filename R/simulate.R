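#' Simulation configuration for synthetic fNIRS recordings
#'
#' Defines a generative model with known ground truth for every downstream
#' analysis stage: band-limited latent oscillators mixed through a coupling
#' graph (functional connectivity), phase-delayed unidirectional drives
#' (information flow), Markov-switching coupling configurations (dynamic
#' states), and optional artifacts plus a global physiological component
#' (preprocessing).
#'
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param band hemodynamic band `(f_lo, f_hi)` in Hz, `0.01 <= f_lo < f_hi`.
#' @param coupling_graph symmetric `n_channels x n_channels` matrix in
#'   `[0, 1]` with unit diagonal; target zero-lag coupling between channels.
#'   `NULL` means independent channels (identity).
#' @param directed_pairs list of `list(driver, receiver, lag, strength)`;
#'   `lag` in seconds, `strength` in `[0, 1]`. The receiver is rebuilt as
#'   `strength` times the lagged driver plus `sqrt(1 - strength^2)` times its
#'   own signal, giving a controlled phase-delayed drive.
#' @param n_states number of connectivity states (1 = static coupling).
#' @param state_connectivity list of `n_states` coupling graphs.
#' @param state_dwell_mean mean state dwell time (s) of the switching
#'   process.
#' @param state_dwell_min minimum dwell time (s). `0` (default) gives a
#'   per-sample first-order Markov chain (geometric dwells); a positive value
#'   gives a semi-Markov hold `dwell = min + Exp(mean - min)` with the same
#'   mean; `state_dwell_min == state_dwell_mean` gives fixed-length dwells.
#'   State-recovery studies should keep every dwell at or above the analysis
#'   window width.
#' @param spike_rate,shift_rate artifact rates (events/min) used by
#'   [simulate_raw()].
#' @param global_physio_amp amplitude of the shared ~0.1 Hz physiological
#'   component injected by [simulate_raw()] (optical-density units).
#' @param drift_amp amplitude of the quadratic optical-density drift injected
#'   by [simulate_raw()].
#' @param noise_sd per-channel independent in-band noise, as a fraction of
#'   the unit signal amplitude.
#' @param hbr_scale,hbr_lag delta-HbR is `hbr_scale` times the delta-HbO2
#'   signal lagged by `hbr_lag` seconds, plus in-band noise.
#' @param seed integer; fully determines the generated recording.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 34, fs = 10, duration = 360,
                       band = c(0.01, 0.2),
                       coupling_graph = NULL,
                       directed_pairs = NULL,
                       n_states = 1, state_connectivity = NULL,
                       state_dwell_mean = 30, state_dwell_min = 0,
                       spike_rate = 0, shift_rate = 0,
                       global_physio_amp = 0, drift_amp = 0,
                       noise_sd = 0.3,
                       hbr_scale = -0.3, hbr_lag = 0.8,
                       seed = 1L) {
  if (band[1] < 0.01 - 1e-12 || band[1] >= band[2])
    stop("band must satisfy 0.01 <= f_lo < f_hi")
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  if (!is.null(coupling_graph)) {
    coupling_graph <- as.matrix(coupling_graph)
    if (!isSymmetric(coupling_graph, tol = 1e-10))
      stop("coupling_graph must be symmetric")
  }
  if (n_states > 1) {
    if (is.null(state_connectivity) || length(state_connectivity) != n_states)
      stop("state_connectivity must supply one coupling graph per state")
  }
  if (state_dwell_min < 0 || state_dwell_min > state_dwell_mean)
    stop("state_dwell_min must lie in [0, state_dwell_mean]")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, band = band,
                 coupling_graph = coupling_graph,
                 directed_pairs = directed_pairs,
                 n_states = as.integer(n_states),
                 state_connectivity = state_connectivity,
                 state_dwell_mean = state_dwell_mean,
                 state_dwell_min = state_dwell_min,
                 spike_rate = spike_rate, shift_rate = shift_rate,
                 global_physio_amp = global_physio_amp, drift_amp = drift_amp,
                 noise_sd = noise_sd,
                 hbr_scale = hbr_scale, hbr_lag = hbr_lag,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default four-state coupling graphs for state-dynamics simulations
#'
#' Four connectivity configurations over `n_channels` nodes, each with high
#' coupling confined to a different channel subset (first half, second half,
#' odd channels, even channels) against a weak background. The four patterns
#' are pairwise equidistant in connectivity space, so recovery quality
#' reflects the estimation chain rather than ground-truth ambiguity between
#' nested states.
#'
#' @param n_channels number of channels (default 20, the motor-cortex set).
#' @param lo,hi background and locked coupling weights (defaults 0.1, 0.9).
#' @return list of four symmetric coupling matrices with unit diagonal.
#' @export
state_graphs_default <- function(n_channels = 20, lo = 0.1, hi = 0.9) {
  idx <- seq_len(n_channels)
  sets <- list(idx[idx <= n_channels / 2], idx[idx > n_channels / 2],
               idx[idx %% 2 == 1], idx[idx %% 2 == 0])
  lapply(sets, function(ss) {
    g <- matrix(lo, n_channels, n_channels)
    g[ss, ss] <- hi
    diag(g) <- 1
    g
  })
}

# Band-limited unit-variance Gaussian noise via Fourier-domain masking.
band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

# Circular shift by k samples (positive k delays the series).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

# Symmetric square root of a PSD-projected coupling matrix.
coupling_mixer <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

#' Simulate a synthetic hemoglobin recording with known ground truth
#'
#' Each channel is a mixture of shared band-limited latent oscillators whose
#' zero-lag coupling follows `cfg$coupling_graph` (or the per-state graphs of
#' a Markov-switching sequence), plus independent in-band noise. Directed
#' pairs impose a phase-delayed drive from driver to receiver. Delta-HbR is a
#' negatively scaled, lagged copy of delta-HbO2 plus noise.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `hb` (an [hb_series()]) and `truth` (latent
#'   coupling matrix, directed pairs, per-sample state labels when
#'   `n_states > 1`, and the per-state graphs).
#' @export
simulate_hb <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_channels
  N <- round(cfg$duration * cfg$fs)
  L <- t(vapply(seq_len(n), function(i) band_noise(N, cfg$fs, cfg$band),
                numeric(N)))

  state_labels <- NULL
  if (cfg$n_states > 1) {
    state_labels <- simulate_state_sequence(cfg, reseed = FALSE)
    X <- matrix(0, n, N)
    for (s in seq_len(cfg$n_states)) {
      M <- coupling_mixer(as.matrix(cfg$state_connectivity[[s]]))
      idx <- which(state_labels == s)
      if (length(idx)) X[, idx] <- (M %*% L)[, idx, drop = FALSE]
    }
  } else if (!is.null(cfg$coupling_graph)) {
    X <- coupling_mixer(cfg$coupling_graph) %*% L
  } else {
    X <- L
  }
  sds <- apply(X, 1, stats::sd)
  sds[sds == 0] <- 1
  X <- X / sds

  if (!is.null(cfg$directed_pairs)) {
    X0 <- X
    for (p in cfg$directed_pairs) {
      lag_smp <- round(p$lag * cfg$fs)
      drive <- circ_shift(X0[p$driver, ], lag_smp)
      X[p$receiver, ] <- p$strength * drive +
        sqrt(1 - p$strength^2) * X0[p$receiver, ]
    }
  }

  if (cfg$noise_sd > 0)
    for (i in seq_len(n))
      X[i, ] <- X[i, ] + cfg$noise_sd * band_noise(N, cfg$fs, cfg$band)

  hbr <- cfg$hbr_scale *
    t(apply(X, 1, circ_shift, k = round(cfg$hbr_lag * cfg$fs)))
  for (i in seq_len(n))
    hbr[i, ] <- hbr[i, ] + 0.1 * band_noise(N, cfg$fs, cfg$band)

  truth <- list(coupling = if (is.null(cfg$coupling_graph)) diag(n)
                           else cfg$coupling_graph,
                directed_pairs = cfg$directed_pairs,
                state_labels = state_labels,
                state_graphs = cfg$state_connectivity)
  list(hb = hb_series(X, hbr, fs = cfg$fs), truth = truth)
}

#' Simulate a Markov state-label sequence
#'
#' With `state_dwell_min = 0` (the default), states switch with per-sample
#' stay probability `1 - 1/(dwell_mean * fs)` — a first-order Markov chain
#' with geometric dwell times of the configured mean. With a positive
#' minimum, dwell lengths are `dwell_min + Exp(dwell_mean - dwell_min)`
#' (fixed-length dwells when the minimum equals the mean), and the state
#' sequence over segments is the same uniform-transition chain. Sequences
#' are redrawn (advancing the RNG) until every state is visited.
#'
#' @param cfg a [sim_config()] with `n_states >= 2`.
#' @param reseed set the RNG from `cfg$seed` first (default `TRUE`; internal
#'   callers that already seeded pass `FALSE`).
#' @return integer vector of per-sample state labels in `1..n_states`.
#' @export
simulate_state_sequence <- function(cfg, reseed = TRUE) {
  if (cfg$n_states < 2) stop("n_states must be >= 2")
  if (reseed) set.seed(cfg$seed)
  N <- round(cfg$duration * cfg$fs)
  for (attempt in seq_len(100)) {
    lab <- draw_state_labels(N, cfg$fs, cfg$n_states, cfg$state_dwell_mean,
                             cfg$state_dwell_min)
    if (length(unique(lab)) == cfg$n_states) return(lab)
  }
  stop("failed to visit every state; increase duration or reduce dwell")
}

draw_state_labels <- function(N, fs, n_states, dwell_mean, dwell_min) {
  if (dwell_min == 0) {
    p_stay <- 1 - 1 / (dwell_mean * fs)
    lab <- integer(N)
    lab[1] <- sample.int(n_states, 1)
    u <- stats::runif(N)
    jump <- sample.int(n_states - 1, N, replace = TRUE)
    for (t in 2:N) {
      if (u[t] < p_stay) lab[t] <- lab[t - 1]
      else lab[t] <- setdiff(seq_len(n_states), lab[t - 1])[jump[t]]
    }
    return(lab)
  }
  lab <- integer(0)
  cur <- sample.int(n_states, 1)
  while (length(lab) < N) {
    extra <- if (dwell_mean > dwell_min)
      stats::rexp(1, 1 / (dwell_mean - dwell_min)) else 0
    lab <- c(lab, rep(cur, max(1L, round((dwell_min + extra) * fs))))
    cur <- sample(setdiff(seq_len(n_states), cur), 1)
  }
  lab[seq_len(N)]
}

#' Forward Beer-Lambert simulation of raw optical intensities
#'
#' Converts a concentration recording to dual-wavelength intensities via the
#' forward modified Beer-Lambert law, `I = baseline * exp(-dOD)` with
#' `dOD(lambda) = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF(lambda, age)`,
#' then optionally injects motion spikes, baseline step shifts, a quadratic
#' drift, and a shared ~0.1 Hz physiological component (all in OD units).
#'
#' @param cfg a [sim_config()] (artifact rates and amplitudes are read from
#'   it).
#' @param hb an [hb_series()] in micromol/L.
#' @param layout a [probe_layout()] (separation).
#' @param age subject age in years (DPF).
#' @param extinction_table 2 x 2 extinction matrix, see
#'   [extinction_defaults()].
#' @param baseline baseline intensity (device units).
#' @param shot_noise relative white measurement noise of the detector
#'   (multiplicative log-normal, default 0.5%); present in any real
#'   photodiode recording and the reference noise floor for the robust
#'   motion-repair stage.
#' @return a [raw_intensity()].
#' @export
simulate_raw <- function(cfg, hb, layout, age = 10,
                         extinction_table = extinction_defaults(),
                         baseline = 100, shot_noise = 0.005) {
  N <- ncol(hb$hbo)
  n <- nrow(hb$hbo)
  wl <- as.numeric(rownames(extinction_table))
  dpf <- vapply(wl, dpf_age, numeric(1), age = age)
  out <- array(0, dim = c(n, length(wl), N))
  tgrid <- seq_len(N) / hb$fs
  global <- if (cfg$global_physio_amp > 0)
    cfg$global_physio_amp * sin(2 * pi * 0.1 * tgrid) else 0
  drift <- if (cfg$drift_amp > 0)
    cfg$drift_amp * (tgrid / max(tgrid) - 0.5)^2 else 0

  n_spikes <- round(cfg$spike_rate * cfg$duration / 60)
  n_shifts <- round(cfg$shift_rate * cfg$duration / 60)

  for (w in seq_along(wl)) {
    od <- (extinction_table[w, "HbO"] * hb$hbo +
           extinction_table[w, "HbR"] * hb$hbr) *
          layout$separation_cm * dpf[w]
    od <- sweep(od, 2, global + drift, "+")
    for (i in seq_len(n)) {
      if (n_spikes > 0) {
        at <- sample.int(N, n_spikes)
        amp <- stats::rnorm(n_spikes, 0, 10 * stats::sd(od[i, ]))
        for (k in seq_len(n_spikes)) {
          idx <- at[k]:min(N, at[k] + 20)
          od[i, idx] <- od[i, idx] + amp[k] * exp(-(seq_along(idx) - 1) / 5)
        }
      }
      if (n_shifts > 0) {
        at <- sample.int(N, n_shifts)
        amp <- stats::rnorm(n_shifts, 0, 10 * stats::sd(od[i, ]))
        for (k in seq_len(n_shifts)) od[i, at[k]:N] <- od[i, at[k]:N] + amp[k]
      }
    }
    noise <- if (shot_noise > 0)
      matrix(stats::rnorm(n * N, 0, shot_noise), n, N) else 0
    out[, w, ] <- baseline * exp(-od + noise)
  }
  raw_intensity(out, wavelengths = wl, fs = hb$fs)
}
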