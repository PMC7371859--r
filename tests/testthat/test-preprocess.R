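# shared small session with known artifacts (built once per file)
sess <- tiny_session(kappa = 0, fs = 500, bursts = 6L,
                     conditions = "rhythmic", seed = 21,
                     decay_amp = 100, blink_rate = 0)

test_that("segment_trials: one 8.5 s trial per burst, conditions preserved", {
  out <- tiny_session(kappa = 0, fs = 250, bursts = 4L, seed = 22,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 0)
  ts <- segment_trials(out$recording)
  expect_identical(dim(ts$data)[1], 8L)
  expect_identical(sum(ts$condition == "rhythmic"), 4L)
  expect_identical(sum(ts$condition == "arrhythmic"), 4L)
  expect_identical(length(ts$time), as.integer(8.5 * 250))
  expect_equal(diff(range(ts$time)) + 1 / ts$fs, 8.5)
  expect_equal(ts$time[1], -3.5)
  # pulse times are trial-relative with the last pulse at 0
  expect_true(all(vapply(ts$pulse_times,
                         function(p) abs(max(p)) < 1e-9, TRUE)))
})

test_that("segment_trials drops out-of-bounds bursts and needs offsets", {
  rec <- recording(matrix(0, 1, 1000), 100, "X",
                   events = data.frame(time = 9, kind = "burst_offset",
                                       condition = "rhythmic",
                                       burst_index = 0L))
  expect_warning(expect_error(segment_trials(rec), "no burst fits"),
                 "dropped")
  expect_error(segment_trials(recording(matrix(0, 1, 100), 100, "X")),
               "no burst_offset")
})

test_that("excise_ringing masks exactly the stated window (brute-force oracle)", {
  # single pulse at trial time -2.0 s, fs = 2500 -> 33 samples
  n <- as.integer(8.5 * 2500)
  ts <- entrainr:::trial_set(array(0, c(1, 1, n)), 2500,
                            seq(0, n - 1) / 2500 - 3.5, "rhythmic",
                            list(-2.0), "Oz")
  ts <- excise_ringing(ts)
  expect_identical(sum(ts$mask), 33L)
  # brute force: every sample whose time is inside [tp - 4 ms, tp + 9 ms]
  oracle <- ts$time >= -2.004 - 1e-9 & ts$time <= -1.991 + 1e-9
  expect_identical(which(ts$mask[1, ]), which(oracle))
  # zero pulses -> untouched; overlapping windows merge
  ts0 <- entrainr:::trial_set(array(0, c(1, 1, 100)), 100,
                             seq(0, 99) / 100 - 0.5, "rhythmic",
                             list(numeric(0)), "Oz")
  expect_identical(sum(excise_ringing(ts0)$mask), 0L)
  ts2 <- entrainr:::trial_set(array(0, c(1, 1, n)), 2500,
                             seq(0, n - 1) / 2500 - 3.5, "rhythmic",
                             list(c(-2.0, -1.99)), "Oz")
  m <- excise_ringing(ts2)$mask[1, ]
  expect_identical(length(rle(m)$values[rle(m)$values]), 1L) # one merged run
})

test_that("decay ICA rejects a 100 uV decay source and removes >80% of it", {
  ts <- excise_ringing(segment_trials(sess$recording))
  before <- ts
  dc <- suppressWarnings(remove_decay_components(ts, seed = 3))
  expect_gte(dc$trials$log$decay_components_removed, 1L)
  # project data onto the known decay topography, average the post-pulse
  # criterion window over pulses, compare before/after
  topo <- sess$ground_truth$decay_topography
  topo <- topo / sqrt(sum(topo^2))
  win_mean <- function(tset) {
    tot <- 0; cnt <- 0
    for (i in seq_len(dim(tset$data)[1])) {
      proj <- drop(topo %*% tset$data[i, , ])
      for (tp in tset$pulse_times[[i]]) {
        jj <- which(tset$time > tp + 0.009 & tset$time <= tp + 0.05)
        tot <- tot + mean(proj[jj]); cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  expect_lt(abs(win_mean(dc$trials)), 0.2 * abs(win_mean(before)))
})

test_that("decay ICA rejects nothing when no decay is present", {
  clean <- tiny_session(kappa = 0, fs = 500, bursts = 4L,
                        conditions = "rhythmic", seed = 23,
                        decay_amp = 0, blink_rate = 0)
  ts <- excise_ringing(segment_trials(clean$recording))
  dc <- suppressWarnings(remove_decay_components(ts, seed = 3))
  expect_identical(dc$trials$log$decay_components_removed, 0L)
  expect_identical(sum(dc$decomposition$rejected), 0L)
})

test_that("interpolate_gaps: exact on ramps, <5% on alpha-band sines, identity w/o gaps", {
  n <- 2501; fs <- 2500
  tax <- seq(0, n - 1) / fs - 0.5
  mk <- function(x, pulses) {
    ts <- entrainr:::trial_set(array(x, c(1, 1, n)), fs, tax, "rhythmic",
                              list(pulses), "Oz")
    excise_ringing(ts)
  }
  ramp <- seq(-10, 10, length.out = n)
  ts <- interpolate_gaps(mk(ramp, 0))
  expect_lt(max(abs(ts$data[1, 1, ] - ramp)), 1e-9)
  expect_false(any(ts$mask))
  sine <- 40 * sin(2 * pi * 10 * tax)
  ts2 <- interpolate_gaps(mk(sine, 0))
  expect_lt(max(abs(ts2$data[1, 1, ] - sine)), 0.05 * 40)
  ts3 <- interpolate_gaps(mk(sine, numeric(0)))
  expect_identical(ts3$data[1, 1, ], sine)
})

test_that("re-referencing zeroes the channel mean; decimation preserves alpha", {
  out <- tiny_session(kappa = 0, fs = 500, bursts = 2L,
                      conditions = "rhythmic", seed = 24,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 0)
  ts <- segment_trials(out$recording)
  n0 <- length(ts$time)
  ts2 <- rereference_downsample(ts, 250)
  expect_identical(length(ts2$time), n0 %/% 2L)
  expect_identical(ts2$fs, 250)
  for (i in seq_len(dim(ts2$data)[1]))
    expect_lt(max(abs(colMeans(ts2$data[i, , ]))), 1e-9)
  expect_error(rereference_downsample(ts, 333), "divide")
  # pure 10 Hz sinusoid survives 2500 -> 1250 Hz decimation within 1%
  fs <- 2500; n <- fs * 4L
  x <- sin(2 * pi * 10 * seq(0, by = 1 / fs, length.out = n))
  y <- entrainr:::fir_decimate(x, 2L)
  core <- 500:(length(y) - 500)
  expect_lt(abs(max(abs(y[core])) - 1), 0.01)
})

test_that("reject_artifacts applies the IQR/20%/STD/correlation rules", {
  set.seed(41)
  m <- standard_montage(64)
  nb <- build_neighbors(m)
  nch <- 64L; nt <- 10L; ns <- 400L; fs <- 200
  common <- matrix(sin(2 * pi * 10 * seq_len(ns) / fs), nch, ns,
                   byrow = TRUE) * 8
  dat <- array(0, c(nt, nch, ns))
  for (i in seq_len(nt))
    dat[i, , ] <- common + matrix(stats::rnorm(nch * ns, 0, 4), nch)
  base <- entrainr:::trial_set(dat, fs, seq_len(ns) / fs - 1, rep("rhythmic", nt),
                              replicate(nt, numeric(0), simplify = FALSE),
                              m$label, as.matrix(m[, c("x", "y", "z")]))
  # trial 2: 5/64 channels at 10x power -> interpolated, trial kept
  t1 <- base
  t1$data[2, 1:5, ] <- t1$data[2, 1:5, ] * sqrt(10)
  r1 <- reject_artifacts(t1, nb)
  expect_identical(r1$log$trials_rejected, 0L)
  expect_gte(r1$log$cells_interpolated, 5L)
  expect_lt(max(abs(r1$data[2, 1, ] - common[1, ])), 15)
  # trial 3: 20/64 channels corrupted -> trial rejected (31% >= 20%)
  t2 <- base
  t2$data[3, 1:20, ] <- t2$data[3, 1:20, ] * sqrt(10)
  r2 <- reject_artifacts(t2, nb)
  expect_identical(r2$log$trials_rejected, 1L)
  expect_identical(dim(r2$data)[1], nt - 1L)
  # 40 uV white-noise channel among quiet ones -> removed under the STD rule
  t3 <- base
  t3$data[, 7, ] <- stats::rnorm(nt * ns, 0, 40)
  r3 <- reject_artifacts(t3, nb)
  expect_true(m$label[7] %in% r3$log$channels_removed_sd)
  # interpolation replaced it with a neighbor-weighted signal
  expect_lt(stats::sd(r3$data[1, 7, ] - common[7, ]), 10)
  # unusable data: more than half the channels corrupted
  t4 <- base
  for (ch in 1:40) t4$data[, ch, ] <- stats::rnorm(nt * ns, 0, 50)
  expect_error(reject_artifacts(t4, nb), "unusable")
})

test_that("ocular ICA removes blinks but preserves posterior alpha", {
  out <- tiny_session(kappa = 0, fs = 500, bursts = 6L,
                      conditions = "rhythmic", seed = 25,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 12)
  ts <- segment_trials(out$recording)
  nch <- dim(ts$data)[2]
  for (i in seq_len(dim(ts$data)[1])) { # common average (pipeline order)
    sl <- ts$data[i, , ]
    ts$data[i, , ] <- sl - rep(colMeans(sl), each = nch)
  }
  oc <- suppressWarnings(remove_ocular_components(ts, seed = 5))
  expect_gte(oc$trials$log$ocular_components_removed, 1L)
  # blink-attributable variance (regression on the ground-truth blink time
  # course) reduced by >80% on the blink topography projection
  topo <- out$ground_truth$blink_topography
  topo <- topo - mean(topo) # common-average projection of the blink pattern
  topo <- topo / sqrt(sum(topo^2))
  gtb <- out$ground_truth$blink_time_course
  ev <- out$recording$events
  offs <- ev$time[ev$kind == "burst_offset"]
  fs <- out$recording$fs
  nsamp <- length(ts$time)
  blink_var <- function(tset) {
    v <- 0
    for (i in seq_len(dim(tset$data)[1])) {
      o <- round(offs[i] * fs) + 1L
      seg <- gtb[(o - as.integer(3.5 * fs)):(o - as.integer(3.5 * fs) + nsamp - 1L)]
      if (stats::var(seg) == 0) next
      proj <- drop(topo %*% tset$data[i, , ])
      v <- v + stats::cov(proj, seg)^2 / stats::var(seg)
    }
    v
  }
  expect_lt(blink_var(oc$trials), 0.2 * blink_var(ts))
  # posterior alpha band power within 10%
  post <- match(c("Pz", "O1", "O2", "Oz"), ts$channel_names)
  bandpow <- function(tset) {
    p <- 0
    for (i in seq_len(dim(tset$data)[1]))
      for (ch in post) {
        sp <- Mod(stats::fft(tset$data[i, ch, ]))^2
        f <- (seq_along(sp) - 1) * tset$fs / length(sp)
        p <- p + sum(sp[f >= 8 & f <= 12])
      }
    p
  }
  expect_lt(abs(bandpow(oc$trials) / bandpow(ts) - 1), 0.1)
})

test_that("ocular ICA removes nothing without blinks", {
  out <- tiny_session(kappa = 0, fs = 500, bursts = 3L,
                      conditions = "rhythmic", seed = 26,
                      ringing_amp = 0, decay_amp = 0, blink_rate = 0)
  ts <- segment_trials(out$recording)
  oc <- suppressWarnings(remove_ocular_components(ts, seed = 5))
  expect_identical(oc$trials$log$ocular_components_removed, 0L)
})

test_that("full cascade runs in the documented order and logs every stage", {
  ts <- suppressWarnings(preprocess_pipeline(sess$recording, seed = 6))
  expect_identical(ts$log$order,
                   c("segment", "excise_ringing", "decay_ica", "interpolate",
                     "rereference_downsample", "reject_artifacts",
                     "ocular_ica"))
  expect_false(any(ts$mask))
  expect_true(is.integer(ts$log$decay_components_removed))
})
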