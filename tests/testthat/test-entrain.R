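test_that("reference wave: alignment, half period, periodicity", {
  tax <- seq(-1, 1, by = 1e-3)
  rw <- reference_wave(10, tax, 0)
  at <- function(t) rw$phase[which.min(abs(tax - t))]
  expect_equal(at(0), 0, tolerance = 1e-9)
  expect_equal(abs(at(0.05)), pi, tolerance = 1e-6)      # half period
  expect_lt(abs(entrainr:::wrap_phase(at(0.35) - at(0.25))), 1e-6) # full period
  expect_error(reference_wave(0, tax), "positive")
})

test_that("wavelet phase tracks an analytic cosine and ignores amplitude", {
  fs <- 250; tax <- seq(0, 6, by = 1 / fs); n <- length(tax)
  ts <- entrainr:::trial_set(array(cos(2 * pi * 10 * tax), c(1, 1, n)), fs,
                            tax - 3.5, "rhythmic", list(numeric(0)), "Oz")
  ph <- wavelet_phase(ts, freqs = 10)
  core <- 300:(length(ph$time) - 300)
  dph <- diff(ph$phase[1, 1, 1, core])
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dph - 2 * pi * 10 / fs)), 0.01)
  ts2 <- ts; ts2$data <- ts$data * 37.5
  ph2 <- wavelet_phase(ts2, freqs = 10)
  expect_equal(ph$phase, ph2$phase, tolerance = 1e-9)
  expect_error(wavelet_phase(ts, freqs = 200), "Nyquist")
})

test_that("white-noise phases are uniform (Rayleigh test across seeds)", {
  fs <- 250
  for (seed in 1:3) {
    set.seed(seed)
    n <- 1600
    ts <- entrainr:::trial_set(array(stats::rnorm(8 * n), c(8, 1, n)), fs,
                              seq_len(n) / fs - 3.5, rep("rhythmic", 8),
                              replicate(8, numeric(0), simplify = FALSE), "Oz")
    ph <- wavelet_phase(ts, freqs = 10)
    # sample phases at intervals > wavelet support to de-correlate
    pick <- seq(200, n - 200, by = 45)
    th <- as.vector(ph$phase[, 1, 1, pick])
    R <- resultant(th)
    n_s <- length(th)
    expect_lt(n_s * R^2, -log(0.01))  # Rayleigh statistic below alpha=0.01 crit
  }
})

test_that("PLV analytics: perfect locking, cancellation, uniform-phase mean", {
  # identical phase differences on all trials -> PLV = 1
  d <- array(1.2, c(50, 1, 1, 3))
  pm <- plv(phase_tensor(d, time = c(0, 1, 2)), zero_reference(c(0, 1, 2)))
  expect_equal(as.vector(pm$plv), rep(1, 3))
  expect_identical(pm$n, 50L)
  # antiphase halves cancel -> PLV = 0
  d2 <- array(rep(c(0, pi), each = 25), c(50, 1, 1, 1))
  pm2 <- plv(phase_tensor(d2), zero_reference(0))
  expect_equal(as.vector(pm2$plv), 0, tolerance = 1e-12)
  expect_error(plv(phase_tensor(array(0, c(1, 1, 1, 1))), zero_reference(0)),
               "2 trials")
  # N = 100 uniform phases: E[PLV] ~ sqrt(pi)/2/sqrt(N) over 1000 replicates
  set.seed(8)
  reps <- vapply(1:1000, function(i)
    resultant(stats::runif(100, -pi, pi)), 0)
  expect_lt(abs(mean(reps) - sqrt(pi) / 20), 0.05 * sqrt(pi) / 20)
  # the plv() operation itself matches the direct resultant on one draw
  set.seed(9)
  th <- stats::runif(100, -pi, pi)
  pm3 <- plv(phase_tensor(array(th, c(100, 1, 1, 1))), zero_reference(0))
  expect_equal(as.vector(pm3$plv), resultant(th), tolerance = 1e-12)
})

test_that("PLV expectation scales as N^(-1/2) for uniform phases", {
  set.seed(10)
  for (N in c(10, 100, 1000)) {
    m <- mean(vapply(1:400, function(i)
      resultant(stats::runif(N, -pi, pi)), 0))
    expect_lt(abs(m * sqrt(N) - sqrt(pi) / 2), 0.1)
  }
})

test_that("PLV is invariant to global rotation and trial order", {
  set.seed(11)
  d <- array(stats::runif(60 * 2 * 1 * 4, -pi, pi), c(60, 2, 1, 4))
  ref <- zero_reference(seq_len(4))
  p0 <- plv(phase_tensor(d, time = seq_len(4)), ref)$plv
  rot <- entrainr:::wrap_phase(d + 1.234)
  p1 <- plv(phase_tensor(rot, time = seq_len(4)), ref)$plv
  expect_equal(p0, p1, tolerance = 1e-9)
  p2 <- plv(phase_tensor(d[sample(60), , , , drop = FALSE],
                         time = seq_len(4)), ref)$plv
  expect_equal(p0, p2, tolerance = 1e-12)
})

test_that("baseline normalization reproduces the 1 / 0.5 / 1.5 interpretation", {
  # constructed map: baseline mean 0.40, test values 0.60 / 0.40 / 0.20
  tax <- seq(-3.25, 0, by = 0.25)
  nb_t <- length(tax)
  v <- rep(0.40, nb_t)
  v[tax == -1] <- 0.60; v[tax == -0.5] <- 0.20; v[tax == 0] <- 0.40
  pm <- structure(list(plv = array(v, c(1, 1, nb_t)), freqs = 10, time = tax,
                       n = 50L, channel_names = "Oz", normalization = "raw"),
                  class = "PLVMap")
  bn <- baseline_normalize(pm, c(-3.0, -2.5))
  expect_equal(bn$plv[1, 1, tax == -1], 1.5)
  expect_equal(bn$plv[1, 1, tax == 0], 1.0)
  expect_equal(bn$plv[1, 1, tax == -0.5], 0.5)
  expect_identical(bn$normalization, "baseline_relative")
  expect_error(baseline_normalize(bn), "already")
  pm0 <- pm; pm0$plv[] <- 0
  expect_error(baseline_normalize(pm0, c(-3, -2.5)), "zero baseline")
})

test_that("pulse-locked PLV: contract, entrained rise, null flatness", {
  mk <- function(kappa, seed) {
    out <- tiny_session(kappa = kappa, fs = 500, bursts = 25L,
                        conditions = "rhythmic", seed = seed,
                        ringing_amp = 0, decay_amp = 0, blink_rate = 0)
    segment_trials(out$recording)
  }
  ts10 <- mk(10, 71)
  pl <- pulse_locked_plv(ts10, 10)
  expect_identical(dim(pl$plv)[3], 22L)            # 20 pulses + pre + post
  expect_identical(pl$points[1], "pre")
  expect_identical(pl$points[22], "post")
  tc <- plv_time_course(pl, 10)
  plateau <- mean(tc[11:21])                        # pulses 10..20
  expect_gt(plateau, tc[1] + 0.3)                   # rises above pre
  # kappa = 0: all pulse-locked values within the N-trial uniform null band
  ts0 <- mk(0, 72)
  tc0 <- plv_time_course(pulse_locked_plv(ts0, 10), 10)
  crit <- sqrt(-log(0.05 / 22) / dim(ts0$data)[1]) # Bonferroni across points
  expect_lt(max(tc0), crit + 0.15)                 # posterior-mean smoothing slack
  # arrhythmic trials are refused
  arr <- tiny_session(kappa = 0, fs = 500, bursts = 2L,
                      conditions = "arrhythmic", seed = 73,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 0)
  expect_error(pulse_locked_plv(segment_trials(arr$recording), 10),
               "rhythmic")
})

test_that("entrained sessions show the first-harmonic PLV signature", {
  out <- tiny_session(kappa = 10, fs = 500, bursts = 20L,
                      conditions = "rhythmic", seed = 74,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 0)
  ts <- segment_trials(out$recording)
  ph <- wavelet_phase(ts, freqs = c(10, 20))
  pm <- baseline_normalize(plv(ph, reference_wave(10, ph$time)))
  stim <- pm$time >= -1.5 & pm$time <= -0.1
  tc20 <- plv_time_course(pm, 20)
  expect_gt(mean(tc20[stim]), 1.3) # harmonic band also locks
})
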