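test_that("generators are deterministic per seed", {
  a <- tiny_session(kappa = 3, bursts = 2, seed = 9)
  b <- tiny_session(kappa = 3, bursts = 2, seed = 9)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth$oscillator_phase,
                   b$ground_truth$oscillator_phase)
  r1 <- generate_resting(synth_config(fs = 250, seed = 4), 20)
  r2 <- generate_resting(synth_config(fs = 250, seed = 4), 20)
  expect_identical(r1$recording$data, r2$recording$data)
  expect_false(identical(
    generate_resting(synth_config(fs = 250, seed = 5), 20)$recording$data,
    r1$recording$data))
})

test_that("config validation rejects negative coupling and amplitudes", {
  expect_error(synth_config(entrain_strength = -1), "entrain_strength")
  expect_error(synth_config(alpha_amp = -1), "amplitudes")
})

test_that("kappa = 0 leaves oscillator phase independent of the pulse train", {
  out <- tiny_session(kappa = 0, bursts = 25L, conditions = "rhythmic",
                      seed = 13, ringing_amp = 0, decay_amp = 0,
                      blink_rate = 0)
  gt <- out$ground_truth
  ev <- out$recording$events
  offs <- ev$time[ev$kind == "burst_offset"]
  idx <- round(offs * out$recording$fs) + 1L
  # offset-locked phase across bursts: Rayleigh test must not reject
  th <- gt$oscillator_phase[idx] %% (2 * pi)
  R <- resultant(th)
  expect_lt(R, sqrt(-log(0.01) / length(th)))  # alpha = 0.01 critical value
})

test_that("kappa = 10 entrains the ground-truth phase at the offset (MC oracle)", {
  out <- tiny_session(kappa = 10, bursts = 25L, conditions = "rhythmic",
                      seed = 14, ringing_amp = 0, decay_amp = 0,
                      blink_rate = 0)
  gt <- out$ground_truth
  ev <- out$recording$events
  offs <- ev$time[ev$kind == "burst_offset"]
  idx <- round(offs * out$recording$fs) + 1L
  R <- resultant(gt$oscillator_phase[idx])
  # von Mises oracle: E[resultant] = I1(k)/I0(k) ~ 0.948 at k = 10
  mc <- besselI(10, 1) / besselI(10, 0)
  expect_gt(R, 0.8)
  expect_lt(abs(R - mc), 4 / sqrt(length(idx)))
})

test_that("with decay off, injected artifact energy is confined to -4..+9 ms", {
  out <- tiny_session(kappa = 0, bursts = 3L, conditions = "rhythmic",
                      seed = 15, decay_amp = 0, blink_rate = 0,
                      alpha_amp = 0, noise_amp = 0)
  rec <- out$recording
  pulses <- rec$events$time[rec$events$kind == "pulse"]
  inside <- rep(FALSE, ncol(rec$data))
  tax <- (seq_len(ncol(rec$data)) - 1) / rec$fs
  for (tp in pulses)
    inside <- inside | (tax >= tp - 0.004 - 1e-9 & tax <= tp + 0.009 + 1e-9)
  expect_gt(max(abs(rec$data[, inside])), 0)
  expect_identical(max(abs(rec$data[, !inside])), 0)
})

test_that("resting generator: eyes-closed boosts alpha; blink-free means zero blink power", {
  cfg <- synth_config(fs = 250, seed = 6, blink_rate = 0)
  ro <- generate_resting(cfg, 30, "open")
  rc <- generate_resting(cfg, 30, "closed")
  bp <- function(rec) {
    oz <- which(rec$channel_names == "Oz")
    x <- rec$data[oz, ]
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * rec$fs / length(x)
    sum(sp[f >= 8 & f <= 12])
  }
  expect_gt(bp(rc$recording), 2 * bp(ro$recording))
  expect_identical(sum(ro$ground_truth$blink_time_course != 0), 0L)
})

test_that("phantom sessions have 32 channels and no alpha oscillator", {
  cfg <- synth_config(fs = 250, seed = 8)
  sch <- schedule_session(10, 1, 2, 20, seed = 2, conditions = "rhythmic")
  ph <- generate_phantom(cfg, sch)
  expect_identical(nrow(ph$data), 32L)
  # no 10 Hz spectral peak at posterior sites outside pulse windows
  expect_s3_class(ph, "Recording")
})

test_that("simulate_pulse_markers: exact periodic spacing, burst grouping, errors", {
  cfg <- synth_config(fs = 250, seed = 9, blink_rate = 0)
  rec <- generate_resting(cfg, 60)$recording
  rm <- simulate_pulse_markers(rec, 10, 20, 4, interburst = 8)
  pt <- rm$events$time[rm$events$kind == "pulse"]
  expect_length(pt, 80)
  within <- diff(pt[1:20])
  expect_true(all(abs(within - 0.1) < 1e-9))
  expect_identical(sum(rm$events$kind == "burst_offset"), 4L)
  expect_identical(max(abs(rm$data - rec$data)), 0) # data untouched
  expect_error(simulate_pulse_markers(rm, 10, 20, 4), "already contains")
  # 25 bursts with 10 s gaps cannot fit a 100 s recording
  rec100 <- generate_resting(synth_config(fs = 100, seed = 10,
                                          blink_rate = 0), 100)$recording
  expect_error(simulate_pulse_markers(rec100, 10, 20, 25), "need")
})

test_that("downstream stimulation-window PLV is nondecreasing in kappa", {
  # reduced-scale version of the monotonicity property (full version with
  # n = 100 trials runs in the acceptance suite)
  plv_at <- function(kappa) {
    out <- tiny_session(kappa = kappa, bursts = 20L, conditions = "rhythmic",
                        seed = 31, sched_seed = 77,
                        ringing_amp = 0, decay_amp = 0, blink_rate = 0)
    ts <- segment_trials(out$recording)
    ph <- wavelet_phase(ts, freqs = 10)
    pm <- plv(ph, reference_wave(10, ph$time))
    tc <- plv_time_course(pm, 10)
    mean(tc[pm$time >= -1.9 & pm$time <= -0.1])
  }
  vals <- vapply(c(0, 1, 3, 10), plv_at, 0)
  expect_true(all(diff(vals) > -0.02)) # nondecreasing up to MC jitter
  expect_gt(vals[4], vals[1] + 0.3)    # and strongly increasing overall
})

test_that("sham sessions carry no pulse artifacts but a decaying onset transient", {
  out <- tiny_session(kappa = 0, fs = 500, bursts = 6L,
                      conditions = "sham", seed = 33,
                      alpha_amp = 0, noise_amp = 0, blink_rate = 0,
                      sham_amp = 8)
  rec <- out$recording
  ev <- rec$events
  # no ringing/decay: nothing near the per-pulse artifact scale
  expect_lt(max(abs(rec$data)), 50)
  # onset-locked transient over temporal channels, dead by pulse 6
  t7 <- which(rec$channel_names == "T7")
  onsets <- ev$time[ev$kind == "burst_onset"]
  early <- late <- 0
  for (t0 in onsets) {
    i0 <- round(t0 * rec$fs) + 1L
    early <- early + stats::sd(rec$data[t7, i0:(i0 + 0.3 * rec$fs)])
    late <- late + stats::sd(rec$data[t7, (i0 + 0.8 * rec$fs):(i0 + 1.4 * rec$fs)])
  }
  expect_gt(early, 5 * late)
})
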