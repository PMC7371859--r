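#' Epoched TMS-EEG trials
#'
#' Container produced by [segment_trials()]: a trials x channels x samples
#' array in microvolts with a per-trial/sample validity mask (TRUE = sample
#' excised, e.g. by ringing removal), trial-relative pulse times, condition
#' labels and a processing log.  The time axis is in seconds relative to
#' the burst offset (t = 0 at the last TMS pulse).
#'
#' @name TrialSet
NULL

trial_set <- function(data, fs, time, condition, pulse_times,
                      channel_names, positions = NULL, mask = NULL,
                      log = list()) {
  if (is.null(mask)) mask <- matrix(FALSE, dim(data)[1], dim(data)[3])
  structure(list(data = data, fs = fs, time = time,
                 condition = condition, pulse_times = pulse_times,
                 channel_names = channel_names, positions = positions,
                 mask = mask, log = log),
            class = "TrialSet")
}

#' @export
print.TrialSet <- function(x, ...) {
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples @ %g Hz (%s), %d masked samples\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              paste(sprintf("%s:%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

n_trials <- function(ts) dim(ts$data)[1]
n_chan <- function(ts) dim(ts$data)[2]

#' Segment a continuous recording into burst-offset-locked trials
#'
#' One trial per `burst_offset` event, spanning 3.5 s before to 5 s after
#' the last TMS pulse (8.5 s total).  Bursts whose window exceeds the
#' recording bounds are dropped with a logged warning.
#'
#' @param rec A [recording()] containing `burst_offset` events.
#' @param pre,post Window edges in seconds (defaults 3.5 and 5).
#' @return A `TrialSet`.
#' @export
segment_trials <- function(rec, pre = 3.5, post = 5.0) {
  ev <- rec$events
  offs <- ev[ev$kind == "burst_offset", ]
  if (nrow(offs) == 0L) stop("segment_trials: no burst_offset events")
  fs <- rec$fs
  nsamp <- as.integer(round((pre + post) * fs))
  N <- ncol(rec$data)
  keep <- logical(nrow(offs))
  starts <- integer(nrow(offs))
  for (i in seq_len(nrow(offs))) {
    o <- round(offs$time[i] * fs) + 1L
    s <- o - as.integer(round(pre * fs))
    starts[i] <- s
    keep[i] <- s >= 1L && (s + nsamp - 1L) <= N
  }
  if (any(!keep))
    warning(sprintf("segment_trials: dropped %d burst(s) outside recording bounds",
                    sum(!keep)))
  offs <- offs[keep, ]; starts <- starts[keep]
  nt <- nrow(offs)
  if (nt == 0L) stop("segment_trials: no burst fits inside the recording")
  data <- array(0, c(nt, nrow(rec$data), nsamp))
  pulse_times <- vector("list", nt)
  pulses <- ev[ev$kind == "pulse", ]
  for (i in seq_len(nt)) {
    data[i, , ] <- rec$data[, starts[i]:(starts[i] + nsamp - 1L)]
    pt <- pulses$time[!is.na(pulses$burst_index) &
                        pulses$burst_index == offs$burst_index[i]]
    pulse_times[[i]] <- pt - offs$time[i]
  }
  time <- seq(0, nsamp - 1L) / fs - pre
  trial_set(data, fs, time, condition = offs$condition,
            pulse_times = pulse_times, channel_names = rec$channel_names,
            positions = rec$positions,
            log = list(n_bursts_dropped = sum(!keep),
                       order = "segment"))
}

#' Mark TMS ringing intervals as invalid
#'
#' Flags samples from 4 ms before to 9 ms after each pulse (endpoints
#' inclusive) on all channels.  Data values are untouched; the mask is
#' consumed by the ICA fit and by [interpolate_gaps()].  Overlapping pulse
#' windows merge naturally in the mask.
#'
#' @param ts A `TrialSet` with per-trial pulse times.
#' @param pre_ms,post_ms Excision window around each pulse, ms.
#' @return The `TrialSet` with an updated mask.
#' @export
excise_ringing <- function(ts, pre_ms = 4, post_ms = 9) {
  t0 <- ts$time[1]; fs <- ts$fs; nsamp <- length(ts$time)
  for (i in seq_len(n_trials(ts))) {
    for (tp in ts$pulse_times[[i]]) {
      lo <- as.integer(ceiling((tp - pre_ms / 1000 - t0) * fs + 1 - 1e-6))
      hi <- as.integer(floor((tp + post_ms / 1000 - t0) * fs + 1 + 1e-6))
      lo <- max(lo, 1L); hi <- min(hi, nsamp)
      if (lo <= hi) ts$mask[i, lo:hi] <- TRUE
    }
  }
  ts$log$order <- c(ts$log$order, "excise_ringing")
  ts
}

#' Remove decay-artifact components by ICA
#'
#' Fits a fixed-point ICA (deflation, tanh nonlinearity) on all unmasked
#' samples, computes for each component the trial-and-pulse-averaged time
#' course in the window from the end of the ringing excision (9 ms) to
#' 50 ms after the pulse, and removes components whose peak absolute
#' average exceeds `threshold` microvolts.  Component time courses are
#' scaled so the strongest channel projection has unit gain, making the
#' microvolt criterion well defined despite ICA scale indeterminacy.
#'
#' @param ts A `TrialSet` (after [excise_ringing()]).
#' @param n_components Number of components (default: channels - 1).
#' @param threshold Rejection criterion in microvolts (default 30).
#' @param window Post-pulse criterion window in seconds, default
#'   `c(0.009, 0.050)`.
#' @param seed ICA seed.
#' @return List with `trials` (cleaned `TrialSet`) and `decomposition`
#'   (class `Decomposition`: mixing/unmixing, per-component criterion and
#'   rejection flags).
#' @export
remove_decay_components <- function(ts, n_components = n_chan(ts) - 1L,
                                    threshold = 30, window = c(0.009, 0.050),
                                    seed = 1L) {
  nt <- n_trials(ts); nch <- n_chan(ts); nsamp <- length(ts$time)
  # unroll to channels x (trial1 samples, trial2 samples, ...)
  X <- matrix(0, nch, nt * nsamp)
  for (ch in seq_len(nch)) X[ch, ] <- as.vector(t(ts$data[, ch, ]))
  valid <- !as.vector(t(ts$mask))
  ic <- fast_ica(X[, valid, drop = FALSE], n_components, seed = seed)
  S_full <- ic$unmixing %*% (X - ic$center)
  # criterion: averaged post-pulse component signal
  crit <- numeric(ic$n_comp)
  lagn <- as.integer(round(diff(window) * ts$fs))
  lag0 <- as.integer(round(window[1] * ts$fs))
  acc <- matrix(0, ic$n_comp, lagn); cnt <- 0L
  t0 <- ts$time[1]
  for (i in seq_len(nt)) {
    for (tp in ts$pulse_times[[i]]) {
      j0 <- as.integer(round((tp - t0) * ts$fs)) + 1L + lag0
      jj <- j0 + seq_len(lagn)
      jj <- jj[jj >= 1L & jj <= nsamp]
      if (length(jj) == lagn) {
        acc <- acc + S_full[, (i - 1L) * nsamp + jj, drop = FALSE]
        cnt <- cnt + 1L
      }
    }
  }
  if (cnt > 0L) {
    acc <- acc / cnt
    crit <- apply(abs(acc), 1, max)
  }
  reject <- crit > threshold
  if (any(reject)) {
    keep <- !reject
    Xc <- ic$mixing[, keep, drop = FALSE] %*% S_full[keep, , drop = FALSE] +
      ic$center
    for (ch in seq_len(nch)) ts$data[, ch, ] <- matrix(Xc[ch, ], nt, nsamp,
                                                       byrow = TRUE)
  }
  dec <- structure(list(mixing = ic$mixing, unmixing = ic$unmixing,
                        criterion = crit, rejected = reject,
                        reason = ifelse(reject, "decay", ""),
                        kind = "decay"),
                   class = "Decomposition")
  ts$log$decay_components_removed <- sum(reject)
  ts$log$order <- c(ts$log$order, "decay_ica")
  list(trials = ts, decomposition = dec)
}

#' @export
print.Decomposition <- function(x, ...) {
  cat(sprintf("Decomposition (%s): %d components, %d rejected\n",
              x$kind, length(x$rejected), sum(x$rejected)))
  invisible(x)
}

#' Interpolate excised pulse windows
#'
#' Replaces masked samples channel-by-channel with shape-preserving
#' piecewise-cubic Hermite (pchip / Fritsch-Carlson) interpolation and
#' clears the mask.  Gaps at a trial edge fall back to nearest-value
#' extension and are logged.
#'
#' @param ts A `TrialSet`.
#' @return The `TrialSet` with no masked samples remaining.
#' @export
interpolate_gaps <- function(ts) {
  n_edge <- 0L
  for (i in seq_len(n_trials(ts))) {
    m <- ts$mask[i, ]
    if (!any(m)) next
    for (ch in seq_len(n_chan(ts))) {
      pf <- pchip_fill(ts$data[i, ch, ], m)
      ts$data[i, ch, ] <- pf$values
      if (pf$edge_extended) n_edge <- n_edge + 1L
    }
    ts$mask[i, ] <- FALSE
  }
  ts$log$edge_extensions <- n_edge
  ts$log$order <- c(ts$log$order, "interpolate")
  ts
}

#' Common-average re-reference and anti-aliased downsampling
#'
#' Subtracts the instantaneous mean over channels from every sample, then
#' low-pass filters (zero-phase windowed-sinc at 0.8 x the new Nyquist) and
#' decimates to `target_fs`.
#'
#' @param ts A `TrialSet` (gaps already interpolated).
#' @param target_fs Target rate in Hz; must divide `ts$fs` (default 1250).
#' @return The re-referenced, downsampled `TrialSet`.
#' @export
rereference_downsample <- function(ts, target_fs = 1250) {
  fac <- ts$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9)
    stop("rereference_downsample: target_fs must divide fs")
  fac <- as.integer(round(fac))
  nt <- n_trials(ts); nch <- n_chan(ts); nsamp <- length(ts$time)
  for (i in seq_len(nt)) {
    sl <- ts$data[i, , ]
    ts$data[i, , ] <- sl - rep(colMeans(sl), each = nch)
  }
  if (fac > 1L) {
    keep <- seq(1L, nsamp, by = fac)
    newdata <- array(0, c(nt, nch, length(keep)))
    for (i in seq_len(nt))
      for (ch in seq_len(nch))
        newdata[i, ch, ] <- fir_decimate(ts$data[i, ch, ], fac)
    ts$data <- newdata
    ts$time <- ts$time[keep]
    ts$mask <- ts$mask[, keep, drop = FALSE]
    ts$fs <- target_fs
  }
  ts$log$order <- c(ts$log$order, "rereference_downsample")
  ts
}

# inverse-distance neighbor interpolation of channel `ch` in matrix
# slice (channels x samples), using source channels `ok`
interp_from_neighbors <- function(slice, ch, ok, nb, positions) {
  nbrs <- which(nb$adjacency[ch, ] & ok)
  if (length(nbrs) == 0L) nbrs <- which(ok) # no valid neighbor: use all
  d <- sqrt(colSums((t(positions[nbrs, , drop = FALSE]) - positions[ch, ])^2))
  w <- 1 / pmax(d, 1e-6); w <- w / sum(w)
  drop(w %*% slice[nbrs, , drop = FALSE])
}

#' Statistical trial/channel artifact rejection
#'
#' Three criteria applied in sequence, following the semi-automatic
#' TMS-EEG cleaning recipe:
#' 1. Per-trial/channel broadband power (mean squared amplitude); cells
#'    beyond 1.5 interquartile ranges outside the quartiles are "bad".
#'    Trials with fewer than 20% bad channels get those channels
#'    neighbor-interpolated (inverse-distance weights); trials with 20% or
#'    more are rejected.
#' 2. Channels with overall standard deviation above `std_thresh`
#'    microvolts are removed and interpolated.
#' 3. Channels whose mean Pearson correlation with their neighbors falls
#'    below `corr_thresh` are removed and interpolated.
#'
#' @param ts A `TrialSet`.
#' @param nb A [build_neighbors()] graph covering all channels.
#' @param iqr_factor IQR multiplier (default 1.5).
#' @param bad_frac Bad-channel fraction above which a trial is rejected
#'   (default 0.2).
#' @param std_thresh Channel standard-deviation threshold, uV (default 30).
#' @param corr_thresh Neighbor-correlation threshold (default 0.4).
#' @return The cleaned `TrialSet`; rejection details in `$log`.
#' @export
reject_artifacts <- function(ts, nb, iqr_factor = 1.5, bad_frac = 0.2,
                             std_thresh = 30, corr_thresh = 0.4) {
  stopifnot(all(ts$channel_names %in% nb$labels))
  nbi <- nb
  nbi$adjacency <- nb$adjacency[ts$channel_names, ts$channel_names]
  nt <- n_trials(ts); nch <- n_chan(ts)
  pw <- matrix(0, nt, nch)
  for (i in seq_len(nt)) pw[i, ] <- rowMeans(ts$data[i, , ]^2)
  q <- stats::quantile(pw, c(0.25, 0.75), names = FALSE)
  lim <- c(q[1] - iqr_factor * diff(q), q[2] + iqr_factor * diff(q))
  bad_cell <- pw < lim[1] | pw > lim[2]
  trial_frac <- rowMeans(bad_cell)
  drop_trial <- trial_frac >= bad_frac
  # channel-level statistics are taken before per-trial cell interpolation:
  # a persistently bad channel (coil movement, line noise) must reach the
  # STD / correlation rules rather than be silently patched trial by trial
  keep0 <- !drop_trial
  flat0 <- matrix(aperm(ts$data[keep0, , , drop = FALSE], c(2, 3, 1)), nch)
  n_interp_cells <- 0L
  for (i in which(!drop_trial & trial_frac > 0)) {
    sl <- ts$data[i, , ]
    ok <- !bad_cell[i, ]
    for (ch in which(bad_cell[i, ])) {
      sl[ch, ] <- interp_from_neighbors(sl, ch, ok, nbi, ts$positions)
      n_interp_cells <- n_interp_cells + 1L
    }
    ts$data[i, , ] <- sl
  }
  if (any(drop_trial)) {
    keep <- !drop_trial
    ts$data <- ts$data[keep, , , drop = FALSE]
    ts$mask <- ts$mask[keep, , drop = FALSE]
    ts$condition <- ts$condition[keep]
    ts$pulse_times <- ts$pulse_times[keep]
    nt <- n_trials(ts)
  }
  # channel-level rules on the concatenated pre-interpolation data
  ch_sd <- apply(flat0, 1, stats::sd)
  bad_sd <- ch_sd > std_thresh
  nb_corr <- vapply(seq_len(nch), function(ch) {
    nbrs <- which(nbi$adjacency[ch, ])
    if (!length(nbrs)) return(1)
    mean(stats::cor(flat0[ch, ], t(flat0[nbrs, , drop = FALSE])))
  }, 0)
  bad_corr <- nb_corr < corr_thresh & !bad_sd
  bad_ch <- which(bad_sd | bad_corr)
  if (length(bad_ch) > nch / 2)
    stop("reject_artifacts: more than half of the channels are bad; data unusable")
  ok <- !(seq_len(nch) %in% bad_ch)
  for (i in seq_len(nt)) {
    sl <- ts$data[i, , ]
    for (ch in bad_ch)
      sl[ch, ] <- interp_from_neighbors(sl, ch, ok, nbi, ts$positions)
    ts$data[i, , ] <- sl
  }
  ts$log$trials_rejected <- sum(drop_trial)
  ts$log$cells_interpolated <- n_interp_cells
  ts$log$channels_removed_sd <- ts$channel_names[bad_sd]
  ts$log$channels_removed_corr <- ts$channel_names[bad_corr]
  ts$log$channels_interpolated <- ts$channel_names[bad_ch]
  ts$log$order <- c(ts$log$order, "reject_artifacts")
  ts
}

#' Remove ocular components by a second ICA
#'
#' The component count is reduced by the number of interpolated channels
#' (plus one for the common-average reference).  A component is flagged as
#' ocular when (a) its time course correlates with a virtual EOG (mean of
#' the frontopolar row) above `eog_corr`, or (b) its frontal-to-posterior
#' topography ratio exceeds `topo_ratio` and its dominant power lies below
#' 5 Hz.
#'
#' @param ts A `TrialSet` (after [reject_artifacts()]).
#' @param eog_corr Virtual-EOG correlation threshold (default 0.7).
#' @param topo_ratio Frontal/posterior mixing-weight ratio (default 3).
#' @param seed ICA seed.
#' @return List with `trials` and `decomposition`.
#' @export
remove_ocular_components <- function(ts, eog_corr = 0.7, topo_ratio = 3,
                                     seed = 2L) {
  nt <- n_trials(ts); nch <- n_chan(ts); nsamp <- length(ts$time)
  n_comp <- nch - length(ts$log$channels_interpolated %||% character(0)) - 1L
  X <- matrix(0, nch, nt * nsamp)
  for (ch in seq_len(nch)) X[ch, ] <- as.vector(t(ts$data[, ch, ]))
  ic <- fast_ica(X, n_comp, seed = seed)
  S <- ic$sources
  front <- match(frontal_labels(ts$channel_names), ts$channel_names)
  post <- match(posterior_labels(ts$channel_names), ts$channel_names)
  veog <- colMeans(X[front, , drop = FALSE])
  reject <- logical(ic$n_comp); reason <- character(ic$n_comp)
  for (j in seq_len(ic$n_comp)) {
    if (abs(stats::cor(S[j, ], veog)) > eog_corr) {
      reject[j] <- TRUE; reason[j] <- "eog_correlation"
    } else if (length(front) && length(post)) {
      fr <- mean(abs(ic$mixing[front, j])) / max(mean(abs(ic$mixing[post, j])), 1e-9)
      x <- S[j, seq_len(min(ncol(S), 2^14))]
      kurt <- mean((x - mean(x))^4) / stats::var(x)^2
      if (fr > topo_ratio && kurt > 5) { # frontal + spiky (blinks/saccades)
        nfft <- length(x)
        spec <- Mod(stats::fft(x))^2
        fgrid <- (seq_len(nfft) - 1L) * ts$fs / nfft
        half <- fgrid < ts$fs / 2 & fgrid > 0.2
        if (fgrid[half][which.max(spec[half])] < 5) {
          reject[j] <- TRUE; reason[j] <- "frontal_slow"
        }
      }
    }
  }
  if (any(reject)) {
    keep <- !reject
    Xc <- ic$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + ic$center
    for (ch in seq_len(nch)) ts$data[, ch, ] <- matrix(Xc[ch, ], nt, nsamp,
                                                       byrow = TRUE)
  }
  dec <- structure(list(mixing = ic$mixing, unmixing = ic$unmixing,
                        rejected = reject, reason = reason, kind = "ocular"),
                   class = "Decomposition")
  ts$log$ocular_components_removed <- sum(reject)
  ts$log$order <- c(ts$log$order, "ocular_ica")
  list(trials = ts, decomposition = dec)
}

#' Full preprocessing cascade
#'
#' Applies the fixed artifact-removal order: segment, ringing excision,
#' decay ICA, gap interpolation, common-average re-reference +
#' downsampling, statistical rejection, ocular ICA.
#'
#' @param rec A [recording()].
#' @param nb Neighbor graph (default: built from the recording positions).
#' @param target_fs Downsampling target, Hz.
#' @param decay_threshold Decay-component criterion, uV.
#' @param seed ICA seed.
#' @param n_decay_components Components for the decay ICA
#'   (default channels - 1).
#' @return A cleaned `TrialSet`; the `$log` records every stage.
#' @export
preprocess_pipeline <- function(rec, nb = NULL, target_fs = 1250,
                                decay_threshold = 30, seed = 1L,
                                n_decay_components = NULL) {
  if (is.null(nb)) {
    if (is.null(rec$positions))
      stop("preprocess_pipeline: need sensor positions or a neighbor graph")
    nb <- build_neighbors(data.frame(label = rec$channel_names,
                                     x = rec$positions[, 1],
                                     y = rec$positions[, 2],
                                     z = rec$positions[, 3]))
  }
  if (rec$fs <= target_fs) target_fs <- rec$fs
  ts <- segment_trials(rec)
  ts <- excise_ringing(ts)
  if (is.null(n_decay_components)) n_decay_components <- n_chan(ts) - 1L
  dc <- remove_decay_components(ts, n_decay_components,
                                threshold = decay_threshold, seed = seed)
  ts <- interpolate_gaps(dc$trials)
  ts <- rereference_downsample(ts, target_fs)
  ts <- reject_artifacts(ts, nb)
  oc <- remove_ocular_components(ts, seed = seed + 1L)
  oc$trials
}
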