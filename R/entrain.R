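#' Reference wave phase series
#'
#' The simulated sinusoid against which phase locking is computed: constant
#' frequency `iaf`, phase 0 (cosine peak) at the burst offset on every
#' trial.  The PLV magnitude is invariant to the reference phase offset;
#' the convention only matters for phase-lag reporting.
#'
#' @param iaf Frequency in Hz.
#' @param time Numeric time axis in seconds (trial time, offset at
#'   `offset_time`).
#' @param offset_time Burst offset in trial time (default 0).
#' @return Object of class `ReferenceWave` with `phase` wrapped to
#'   `(-pi, pi]`, `iaf`, `time`.
#' @export
reference_wave <- function(iaf, time, offset_time = 0) {
  if (iaf <= 0) stop("reference_wave: iaf must be positive")
  ph <- wrap_phase(2 * pi * iaf * (time - offset_time))
  structure(list(phase = ph, iaf = iaf, time = time,
                 offset_time = offset_time),
            class = "ReferenceWave")
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Morlet wavelet phase decomposition of epoched trials
#'
#' Convolves every trial and channel with complex Morlet wavelets (5 cycles,
#' Gaussian envelope truncated at 3 standard deviations) and keeps the
#' instantaneous phase.  The analysis window runs from 3.5 s before to
#' 2.5 s after the burst offset.  Edge samples with incomplete wavelet
#' support are flagged per frequency.
#'
#' @param ts A preprocessed `TrialSet`.
#' @param freqs Frequency grid in Hz (default 5-30 Hz in 0.5 Hz steps).
#' @param cycles Wavelet width in cycles (default 5).
#' @param gwidth Envelope truncation in standard deviations (default 3).
#' @param window Analysis window in trial time, default `c(-3.5, 2.5)` s.
#' @return Object of class `PhaseTensor`: `phase` array
#'   (trials x channels x freqs x times) in `(-pi, pi]`, `freqs`, `time`,
#'   `edge` (freqs x times logical), plus trial bookkeeping.
#' @export
wavelet_phase <- function(ts, freqs = seq(5, 30, by = 0.5), cycles = 5,
                          gwidth = 3, window = c(-3.5, 2.5)) {
  if (any(freqs >= ts$fs / 2))
    stop("wavelet_phase: frequency at or above Nyquist")
  sel <- ts$time >= window[1] - 1e-9 & ts$time <= window[2] + 1e-9
  tout <- ts$time[sel]
  nt <- n_trials(ts); nch <- n_chan(ts)
  ph <- array(0, c(nt, nch, length(freqs), sum(sel)))
  edge <- matrix(FALSE, length(freqs), sum(sel))
  nsamp <- length(ts$time)
  for (fi in seq_along(freqs)) {
    half <- NA_integer_
    for (i in seq_len(nt)) {
      for (ch in seq_len(nch)) {
        mc <- morlet_coef(ts$data[i, ch, ], ts$fs, freqs[fi], cycles, gwidth)
        ph[i, ch, fi, ] <- Arg(mc$coef[sel])
        half <- mc$half_support
      }
    }
    idx_all <- which(sel)
    edge[fi, ] <- idx_all <= half | idx_all > nsamp - half
  }
  structure(list(phase = ph, freqs = freqs, time = tout, edge = edge,
                 condition = ts$condition, fs = ts$fs,
                 channel_names = ts$channel_names,
                 pulse_times = ts$pulse_times),
            class = "PhaseTensor")
}

#' Phase locking value against the reference wave
#'
#' For every channel, frequency and time point, the modulus of the
#' across-trial mean unit phasor of the phase difference between the
#' signal and the reference wave:
#' `PLV = |sum_n exp(i (Phi_ong(n) - Phi_IAF(n)))| / N`,
#' with `N` the number of trials.  Values range from 0 (no phase
#' consistency) to 1 (perfect locking).
#'
#' @param ph A [wavelet_phase()] `PhaseTensor`.
#' @param ref A [reference_wave()] on the same time axis.
#' @param trials Optional logical/integer trial subset.
#' @return Object of class `PLVMap`: `plv` (channels x freqs x times),
#'   `freqs`, `time`, `n` (trials), `normalization = "raw"`.
#' @export
plv <- function(ph, ref, trials = NULL) {
  stopifnot(inherits(ph, "PhaseTensor"), inherits(ref, "ReferenceWave"))
  if (length(ref$phase) != length(ph$time))
    stop("plv: reference wave and phase tensor time axes differ")
  p <- ph$phase
  if (!is.null(trials)) p <- p[trials, , , , drop = FALSE]
  N <- dim(p)[1]
  if (N < 2L) stop("plv: need at least 2 trials")
  refarr <- aperm(array(ref$phase, c(dim(p)[4], dim(p)[1], dim(p)[2],
                                     dim(p)[3])), c(2, 3, 4, 1))
  z <- exp(1i * (p - refarr))
  pl <- Mod(apply(z, c(2, 3, 4), sum)) / N
  structure(list(plv = pl, freqs = ph$freqs, time = ph$time, n = N,
                 channel_names = ph$channel_names,
                 normalization = "raw"),
            class = "PLVMap")
}

#' @export
print.PLVMap <- function(x, ...) {
  d <- dim(x$plv)
  cat(sprintf("PLVMap (%s): %d channels x %d freqs x %d points, N = %d trials\n",
              x$normalization, d[1], d[2], d[3], x$n))
  invisible(x)
}

#' Relative baseline normalization of a PLV map
#'
#' Divides every channel/frequency time course by its mean over the
#' baseline window (default 3.0 to 2.5 s before the burst offset).  A
#' normalized value of 1 means no change, 0.5 a 50% decrease and 1.5 a
#' 50% increase relative to baseline.
#'
#' @param pm A raw `PLVMap`.
#' @param baseline Window `c(lo, hi)` in trial time, s.
#' @return The normalized `PLVMap` (`normalization = "baseline_relative"`).
#' @export
baseline_normalize <- function(pm, baseline = c(-3.0, -2.5)) {
  stopifnot(inherits(pm, "PLVMap"))
  if (pm$normalization != "raw")
    stop("baseline_normalize: map already normalized")
  sel <- pm$time >= baseline[1] - 1e-9 & pm$time <= baseline[2] + 1e-9
  if (!any(sel)) stop("baseline_normalize: baseline window outside time axis")
  base <- apply(pm$plv[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(base == 0)) stop("baseline_normalize: zero baseline mean")
  pm$plv <- pm$plv / as.vector(base) # recycles channels x freqs over time
  pm$normalization <- "baseline_relative"
  pm$baseline <- baseline
  pm
}

#' Pulse-locked PLV at the stimulation frequency
#'
#' PLV at the individual alpha frequency evaluated at each of the
#' `n_pulses` pulse times (plus one pre-burst and one post-burst point,
#' one IAF cycle before the first and after the last pulse).  Defined only
#' for rhythmic trials, whose constant inter-pulse interval makes the
#' pulse-aligned time points identical across trials.
#'
#' @param ts A preprocessed `TrialSet` of rhythmic trials.
#' @param iaf Stimulation frequency, Hz.
#' @param cycles,gwidth Morlet parameters as in [wavelet_phase()].
#' @return A `PLVMap` with `points` labels `pre`, `p1`...`pK`, `post`;
#'   `plv` is channels x 1 x (K + 2).
#' @export
pulse_locked_plv <- function(ts, iaf, cycles = 5, gwidth = 3) {
  if (any(ts$condition != "rhythmic"))
    stop("pulse_locked_plv: defined for rhythmic trials only")
  npul <- lengths(ts$pulse_times)
  if (length(unique(npul)) != 1L)
    stop("pulse_locked_plv: trials have differing pulse counts")
  K <- npul[1]
  # pulse grid in trial time (offset-locked, last pulse at 0)
  grid <- ts$pulse_times[[1]]
  pts <- c(grid[1] - 1 / iaf, grid, grid[K] + 1 / iaf)
  idx <- vapply(pts, function(t) which.min(abs(ts$time - t)), 0L)
  nt <- n_trials(ts); nch <- n_chan(ts)
  z <- array(0i, c(nt, nch, length(idx)))
  for (i in seq_len(nt)) {
    for (ch in seq_len(nch)) {
      mc <- morlet_coef(ts$data[i, ch, ], ts$fs, iaf, cycles, gwidth)
      z[i, ch, ] <- exp(1i * (Arg(mc$coef[idx]) -
                                wrap_phase(2 * pi * iaf * ts$time[idx])))
    }
  }
  pl <- Mod(apply(z, c(2, 3), sum)) / nt
  structure(list(plv = array(pl, c(nch, 1L, length(idx))), freqs = iaf,
                 time = ts$time[idx],
                 points = c("pre", paste0("p", seq_len(K)), "post"),
                 n = nt, channel_names = ts$channel_names,
                 normalization = "raw"),
            class = "PLVMap")
}

#' Posterior-channel summary time course of a PLV map
#'
#' @param pm A `PLVMap`.
#' @param freq Frequency at which to extract (nearest grid point).
#' @param channels Channel labels (default posterior rows).
#' @return Numeric vector over time (mean over the selected channels).
#' @export
plv_time_course <- function(pm, freq, channels = NULL) {
  if (is.null(channels)) channels <- posterior_labels(pm$channel_names)
  chi <- match(channels, pm$channel_names)
  chi <- chi[!is.na(chi)]
  fi <- which.min(abs(pm$freqs - freq))
  m <- pm$plv[chi, fi, , drop = FALSE]
  colMeans(matrix(m, nrow = length(chi)))
}
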