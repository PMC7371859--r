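# Shared fixture builders.  Everything is generated in code at test time;
# scales are deliberately small (documented in the methods vignette).

tiny_session <- function(kappa = 0, fs = 500, n_channels = 32L,
                         bursts = 4L, blocks = 1L,
                         conditions = c("rhythmic", "arrhythmic"),
                         iaf = 10, seed = 1L, sched_seed = seed + 50L, ...) {
  cfg <- synth_config(n_channels = n_channels, fs = fs, iaf = iaf,
                      entrain_strength = kappa, seed = seed, ...)
  sch <- schedule_session(iaf, blocks, bursts, 20L, seed = sched_seed,
                          conditions = conditions)
  generate_session(cfg, sch)
}

# PhaseTensor with prescribed phase differences to a zero reference:
# diffs is trials x channels x freqs x times
phase_tensor <- function(diffs, freqs = 10, time = 0,
                         channel_names = paste0("ch", seq_len(dim(diffs)[2]))) {
  structure(list(phase = diffs, freqs = freqs, time = time,
                 edge = matrix(FALSE, length(freqs), length(time)),
                 condition = rep("rhythmic", dim(diffs)[1]),
                 channel_names = channel_names),
            class = "PhaseTensor")
}

zero_reference <- function(time) {
  structure(list(phase = rep(0, length(time)), iaf = 10, time = time,
                 offset_time = 0),
            class = "ReferenceWave")
}

# mean resultant length of N angles
resultant <- function(theta) Mod(mean(exp(1i * theta)))

# spatially smooth null electrode maps for the cluster-test oracle
smooth_map_maker <- function(montage, sd_spatial = 0.5, amp = 0.1) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  Kd <- exp(-as.matrix(stats::dist(pos))^2 / (2 * sd_spatial^2))
  Ksm <- t(chol(Kd + diag(1e-6, nrow(pos))))
  function(n) {
    m <- matrix(stats::rnorm(n * nrow(pos)), n) %*% t(Ksm) * amp + 1
    colnames(m) <- montage$label
    m
  }
}
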