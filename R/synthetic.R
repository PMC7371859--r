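#' Synthetic TMS-EEG generator configuration
#'
#' Parameters of the ground-truth generator used to test every downstream
#' stage without real recordings.  The defaults emulate the acquisition
#' this pipeline targets: a 64-channel cap sampled at 2.5 kHz, a posterior
#' alpha oscillator over spatially correlated 1/f background noise, TMS
#' ringing confined to -4..+9 ms around each pulse, slow exponential decay
#' artifacts, frontal ocular blinks and optional bad channels.
#'
#' The entrainment model: during rhythmic bursts the alpha oscillator phase
#' is reset at every pulse to the pulse-train phase plus a von Mises
#' perturbation with concentration `kappa` (`entrain_strength`); between
#' pulses (and outside rhythmic bursts) the phase free-runs with Brownian
#' phase diffusion of rate `phase_diffusion` rad^2/s.  `kappa = 0` leaves
#' the oscillator untouched, so its phase is independent of the pulse train
#' by construction; large `kappa` drives the trial-wise phase-locking value
#' toward the von Mises resultant I1(kappa)/I0(kappa).
#'
#' @param n_channels 64 (default) or 32.
#' @param fs Sampling rate, Hz.
#' @param iaf Alpha oscillator frequency, Hz (8-12).
#' @param alpha_amp Alpha amplitude at its topography peak, uV.
#' @param noise_amp Background noise standard deviation per channel, uV.
#' @param noise_exponent 1/f spectral slope of the background.
#' @param entrain_strength Phase-coupling concentration kappa (`>= 0`).
#' @param phase_diffusion Phase random-walk rate, rad^2/s; controls how
#'   fast phase locking decays after the last pulse.
#' @param ringing_amp Peak ringing artifact amplitude at the coil site, uV.
#' @param decay_amp Decay artifact step amplitude, uV.
#' @param decay_tau Decay time constant, ms.
#' @param blink_rate Blink events per minute.
#' @param blink_amp Blink amplitude at frontal sites, uV.
#' @param sham_amp Amplitude of the onset-locked auditory-evoked-like
#'   transient in sham sessions, uV.
#' @param eyes_closed_ratio Alpha amplitude multiplier for eyes-closed
#'   resting blocks.
#' @param alpha_harmonic Relative amplitude of the second harmonic of the
#'   alpha waveform (arc-shaped, non-sinusoidal alpha as seen in real EEG;
#'   phase-locked to the fundamental, so entrained sessions also show
#'   phase locking at twice the stimulation frequency).
#' @param bad_channels Labels of channels replaced by amplified noise.
#' @param n_noise_sources Number of spatially smooth 1/f background
#'   sources (gives realistic between-channel correlation).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical recordings.
#' @return Object of class `SynthConfig`.
#' @export
synth_config <- function(n_channels = 64L, fs = 2500, iaf = 10,
                         alpha_amp = 10, noise_amp = 10, noise_exponent = 1,
                         entrain_strength = 0, phase_diffusion = 4,
                         ringing_amp = 500, decay_amp = 80, decay_tau = 30,
                         blink_rate = 10, blink_amp = 120, sham_amp = 8,
                         eyes_closed_ratio = 2, alpha_harmonic = 0.2,
                         bad_channels = character(0),
                         n_noise_sources = 20L, seed = 1L) {
  if (entrain_strength < 0) stop("synth_config: entrain_strength must be >= 0")
  if (alpha_amp < 0 || noise_amp < 0)
    stop("synth_config: amplitudes must be nonnegative")
  structure(as.list(environment()), class = "SynthConfig")
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 -> uniform
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
        break
      }
    }
  }
  out
}

ang_dist <- function(positions, center) {
  positions <- as.matrix(positions)
  center <- center / sqrt(sum(center^2))
  dots <- positions %*% center / sqrt(rowSums(positions^2))
  acos(pmax(-1, pmin(1, drop(dots))))
}

# smooth gaussian gain on the sphere around a montage label
label_topography <- function(montage, label, width = 0.7) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  ctr <- if (label %in% montage$label) {
    as.numeric(montage[montage$label == label, c("x", "y", "z")])
  } else c(0, -0.7, 0.6) # posterior fallback for reduced caps
  exp(-ang_dist(pos, ctr)^2 / (2 * width^2))
}

# spectrally shaped 1/f noise, unit variance, length n
one_over_f_noise <- function(n, exponent, fs) {
  nf <- stats::nextn(n, 2L)
  f <- c(1, seq_len(nf / 2), rev(seq_len(nf / 2 - 1L))) * fs / nf
  amp <- 1 / f^(exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

# internal: shared scaffolding for all generators
synth_background <- function(cfg, n, montage) {
  nch <- nrow(montage)
  pos <- as.matrix(montage[, c("x", "y", "z")])
  G <- matrix(0, nch, cfg$n_noise_sources)
  for (k in seq_len(cfg$n_noise_sources)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    G[, k] <- exp(-ang_dist(pos, u)^2 / (2 * 0.8^2))
  }
  G <- G / sqrt(rowSums(G^2))
  # accumulate source by source: a samples x sources matrix would not fit
  # in memory for full-protocol sessions
  noise <- matrix(stats::rnorm(nch * n, 0, cfg$noise_amp * 0.3), nch)
  for (k in seq_len(cfg$n_noise_sources)) {
    s <- one_over_f_noise(n, cfg$noise_exponent, cfg$fs)
    noise <- noise + (cfg$noise_amp * 0.95) * outer(G[, k], s)
  }
  noise
}

# alpha oscillator phase with Brownian diffusion and per-pulse von Mises
# resets during rhythmic bursts; returns per-sample phase (unwrapped)
synth_alpha_phase <- function(cfg, n, rhythmic_bursts) {
  dt <- 1 / cfg$fs
  dphi <- 2 * pi * cfg$iaf * dt +
    sqrt(cfg$phase_diffusion * dt) * stats::rnorm(n)
  phi <- cumsum(dphi) + stats::runif(1, 0, 2 * pi)
  if (cfg$entrain_strength > 0 && length(rhythmic_bursts)) {
    pulse_t <- numeric(0); theta <- numeric(0)
    for (b in rhythmic_bursts) {
      t_off <- b$times[length(b$times)]
      delta <- rvonmises(length(b$times), cfg$entrain_strength)
      pulse_t <- c(pulse_t, b$times)
      theta <- c(theta, 2 * pi * cfg$iaf * (b$times - t_off) + delta)
    }
    o <- order(pulse_t)
    pulse_t <- pulse_t[o]; theta <- theta[o]
    idx <- pmin(pmax(round(pulse_t * cfg$fs) + 1L, 1L), n)
    corr <- theta - phi[idx]
    k <- findInterval(seq_len(n), idx)
    phi <- phi + c(0, corr)[k + 1L]
  }
  phi
}

#' Generate a synthetic rTMS-EEG session with ground truth
#'
#' Builds a continuous [recording()] realizing a [schedule_session()] under
#' a [synth_config()]: posterior alpha oscillator (phase-coupled to the
#' pulse train during rhythmic bursts when `entrain_strength > 0`),
#' correlated 1/f background, ringing and decay artifacts at every real
#' pulse, frontal blinks, optional bad channels.  Sham bursts get no scalp
#' artifact but a brief onset-locked auditory-evoked-like transient over
#' temporal sites that dies out within five pulses.
#'
#' @param cfg A [synth_config()].
#' @param schedule A [schedule_session()].
#' @return List with `recording` and `ground_truth` (per-sample oscillator
#'   phase, alpha channel gains, blink/decay component time courses and the
#'   injected event table).
#' @export
generate_session <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "SynthConfig"), inherits(schedule, "PulseSchedule"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  montage <- standard_montage(cfg$n_channels)
  duration <- schedule$duration + 6
  n <- as.integer(round(duration * cfg$fs))
  data <- synth_background(cfg, n, montage)
  tax <- (seq_len(n) - 1L) / cfg$fs

  conds <- vapply(schedule$bursts, `[[`, "", "condition")
  rhythmic <- schedule$bursts[conds == "rhythmic"]
  phi <- synth_alpha_phase(cfg, n, rhythmic)
  alpha_gain <- label_topography(montage, "POz")
  data <- data + cfg$alpha_amp *
    outer(alpha_gain, cos(phi) + cfg$alpha_harmonic * cos(2 * phi))

  # artifacts at real (non-sham) pulses
  real_pulses <- sort(unlist(lapply(schedule$bursts[conds != "sham"],
                                    `[[`, "times")))
  ring_gain <- exp(-2 * ang_dist(as.matrix(montage[, c("x", "y", "z")]),
                                 as.numeric(montage[montage$label ==
                                   (if ("PO3" %in% montage$label) "PO3" else "P3"),
                                   c("x", "y", "z")])))
  decay_topo <- label_topography(montage,
                                 if ("PO3" %in% montage$label) "PO3" else "P3",
                                 width = 0.9)
  decay_topo <- decay_topo / max(decay_topo)
  decay_tc <- numeric(n)
  if (length(real_pulses)) {
    ring_n <- round(0.013 * cfg$fs)
    ring_wave <- sin(2 * pi * 1000 * seq(0, 0.013, length.out = ring_n)) *
      hann(ring_n)
    for (tp in real_pulses) {
      i0 <- round((tp - 0.004) * cfg$fs) + 1L
      ii <- i0:(i0 + ring_n - 1L)
      ok <- ii >= 1L & ii <= n
      if (cfg$ringing_amp > 0)
        data[, ii[ok]] <- data[, ii[ok]] +
          cfg$ringing_amp * outer(ring_gain, ring_wave[ok])
      if (cfg$decay_amp > 0) {
        j0 <- round(tp * cfg$fs) + 1L
        len <- min(n - j0 + 1L, round(8 * cfg$decay_tau / 1000 * cfg$fs))
        if (len > 0) {
          jj <- j0:(j0 + len - 1L)
          decay_tc[jj] <- decay_tc[jj] +
            cfg$decay_amp * exp(-(tax[jj] - tp) / (cfg$decay_tau / 1000))
        }
      }
    }
    data <- data + outer(decay_topo, decay_tc)
  }

  # sham onset transient: decays over the first ~5 pulses
  sham_tc <- numeric(n)
  if (cfg$sham_amp > 0 && any(conds == "sham")) {
    temp_gain <- label_topography(montage, "T7", width = 0.6) +
      label_topography(montage, "T8", width = 0.6)
    temp_gain <- temp_gain / max(temp_gain)
    for (b in schedule$bursts[conds == "sham"]) {
      t0 <- b$times[1]
      len <- round(5 / schedule$iaf * cfg$fs)
      jj <- (round(t0 * cfg$fs) + 1L):(round(t0 * cfg$fs) + len)
      jj <- jj[jj <= n]
      tau <- tax[jj] - t0
      sham_tc[jj] <- sham_tc[jj] +
        cfg$sham_amp * sin(2 * pi * 6 * tau) * exp(-tau / (2 / schedule$iaf))
    }
    data <- data + outer(temp_gain, sham_tc)
  }

  blink <- synth_blinks(cfg, n, montage)
  data <- data + blink$data

  bad <- match(cfg$bad_channels, montage$label)
  bad <- bad[!is.na(bad)]
  for (b in bad) data[b, ] <- stats::rnorm(n, 0, 5 * cfg$noise_amp)

  rec <- recording(data, cfg$fs, montage$label,
                   positions = as.matrix(montage[, c("x", "y", "z")]),
                   events = schedule_events(schedule),
                   meta = list(generator = "generate_session",
                               seed = cfg$seed, iaf = cfg$iaf))
  gt <- list(oscillator_phase = phi, alpha_gain = alpha_gain,
             decay_time_course = decay_tc, decay_topography = decay_topo,
             blink_time_course = blink$tc, blink_topography = blink$topo,
             events = rec$events, config = cfg)
  list(recording = rec, ground_truth = gt)
}

synth_blinks <- function(cfg, n, montage) {
  topo <- label_topography(montage, "Fp1", width = 0.6) +
    label_topography(montage, "Fp2", width = 0.6)
  topo <- topo / max(topo)
  tc <- numeric(n)
  if (cfg$blink_rate > 0) {
    dur_s <- n / cfg$fs
    n_blinks <- stats::rpois(1, cfg$blink_rate * dur_s / 60)
    if (n_blinks > 0) {
      bl_n <- round(0.4 * cfg$fs)
      shape <- sin(2 * pi * seq(0, 1, length.out = bl_n)) *
        hann(bl_n) # 400 ms biphasic
      onsets <- sort(stats::runif(n_blinks, 0, dur_s - 0.5))
      for (t0 in onsets) {
        jj <- (round(t0 * cfg$fs) + 1L):(round(t0 * cfg$fs) + bl_n)
        jj <- jj[jj <= n]
        tc[jj] <- tc[jj] + cfg$blink_amp * shape[seq_along(jj)]
      }
    }
  }
  list(data = outer(topo, tc), tc = tc, topo = topo)
}

#' Generate synthetic resting-state EEG
#'
#' Alpha oscillator plus correlated background, no stimulation artifacts;
#' blinks occur only with open eyes, and the alpha amplitude is multiplied
#' by `cfg$eyes_closed_ratio` with closed eyes.
#'
#' @param cfg A [synth_config()].
#' @param duration Recording length in seconds.
#' @param eyes `"open"` or `"closed"`.
#' @return List with `recording` and `ground_truth`.
#' @export
generate_resting <- function(cfg, duration = 240, eyes = c("open", "closed")) {
  eyes <- match.arg(eyes)
  if (duration <= 0) stop("generate_resting: duration must be positive")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed + ifelse(eyes == "closed", 1L, 0L))
  montage <- standard_montage(cfg$n_channels)
  n <- as.integer(round(duration * cfg$fs))
  data <- synth_background(cfg, n, montage)
  phi <- synth_alpha_phase(cfg, n, list())
  amp <- cfg$alpha_amp * if (eyes == "closed") cfg$eyes_closed_ratio else 1
  alpha_gain <- label_topography(montage, "POz")
  data <- data + amp *
    outer(alpha_gain, cos(phi) + cfg$alpha_harmonic * cos(2 * phi))
  blink <- if (eyes == "open") synth_blinks(cfg, n, montage) else
    list(data = 0, tc = numeric(n), topo = numeric(nrow(montage)))
  data <- data + blink$data
  rec <- recording(data, cfg$fs, montage$label,
                   positions = as.matrix(montage[, c("x", "y", "z")]),
                   meta = list(generator = "generate_resting", eyes = eyes,
                               seed = cfg$seed, iaf = cfg$iaf))
  list(recording = rec,
       ground_truth = list(oscillator_phase = phi, alpha_gain = alpha_gain,
                           blink_time_course = blink$tc,
                           blink_topography = blink$topo, config = cfg))
}

#' Generate a phantom (no-brain) control session
#'
#' Emulates stimulating a conductive phantom: pure noise plus pulse
#' artifacts, no alpha oscillator.  Defaults to a 32-channel cap, matching
#' the reduced montage used for phantom control recordings.
#'
#' @param cfg A [synth_config()]; `alpha_amp` is forced to 0 and
#'   `n_channels` to `n_channels_phantom`.
#' @param schedule A [schedule_session()] (typically 10 Hz rhythmic).
#' @param n_channels_phantom Channel count for the phantom cap.
#' @return A [recording()].
#' @export
generate_phantom <- function(cfg, schedule, n_channels_phantom = 32L) {
  cfg$alpha_amp <- 0
  cfg$blink_rate <- 0
  cfg$n_channels <- n_channels_phantom
  out <- generate_session(cfg, schedule)
  out$recording$meta$generator <- "generate_phantom"
  out$recording
}

#' Insert simulated pulse markers into an artifact-free recording
#'
#' Implements the interpolation-bias control: periodic "pulse" events at
#' the individual alpha frequency are added to resting data (grouped into
#' bursts with offset markers) without modifying any samples; the excision
#' and interpolation then happen downstream exactly as for real data.
#'
#' @param rec A [recording()] without pulse events.
#' @param iaf Simulated stimulation frequency, Hz.
#' @param n_pulses Pulses per simulated burst.
#' @param n_bursts Number of simulated bursts.
#' @param interburst Gap between burst offset and next onset, s.
#' @param lead_in Time before the first burst, s.
#' @return The recording with added events.
#' @export
simulate_pulse_markers <- function(rec, iaf, n_pulses = 20L, n_bursts = 25L,
                                   interburst = 10, lead_in = 8) {
  if (any(rec$events$kind == "pulse"))
    stop("simulate_pulse_markers: recording already contains pulse events")
  need <- lead_in + n_bursts * (n_pulses / iaf + interburst)
  if (need > rec_duration(rec))
    stop(sprintf("simulate_pulse_markers: need %.1f s, recording has %.1f s",
                 need, rec_duration(rec)))
  rows <- list()
  t <- lead_in
  for (b in seq_len(n_bursts) - 1L) {
    times <- t + (seq_len(n_pulses) - 1L) / iaf
    rows[[b + 1L]] <- data.frame(
      time = c(times[1], times, times[n_pulses]),
      kind = c("burst_onset", rep("pulse", n_pulses), "burst_offset"),
      condition = "rhythmic", burst_index = b)
    t <- t + n_pulses / iaf + interburst
  }
  rec$events <- as_events(rbind(rec$events, do.call(rbind, rows)))
  validate_recording(rec)
  rec
}
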