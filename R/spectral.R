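#' Estimate the individual alpha frequency from resting EEG
#'
#' Implements the resting-state IAF pipeline: 2 s epochs with 50% overlap,
#' common-average re-reference, per-epoch detrend and demean, zero-phase
#' Butterworth band-pass (0.1-40 Hz), automatic epoch rejection
#' (epoch variance beyond Q3 + 1.5 IQR), multitaper spectrum (DPSS tapers)
#' on a 1-20 Hz grid in 0.5 Hz steps, averaging over epochs and posterior
#' channels, then peak search in 8-12 Hz.  A peak is accepted when it is a
#' local maximum whose power exceeds the fitted 1/f background trend by
#' `prominence`; when the eyes-open spectrum has no acceptable peak the
#' eyes-closed one is used instead; when neither does, `iaf` is `"none"`.
#'
#' For tractability the multitaper stage operates at 250 Hz (recordings
#' sampled faster are decimated after the 40 Hz low-pass, which leaves the
#' 1-20 Hz spectrum untouched).
#'
#' @param rec_open,rec_closed Eyes-open / eyes-closed [recording()]s
#'   (each at least 60 s; `rec_closed` may be `NULL`).
#' @param channels Channel labels used for peak picking; default the
#'   posterior (parietal/parieto-occipital/occipital) rows of the montage.
#' @param prominence Peak acceptance factor over the 1/f trend
#'   (default 1.5).
#' @param nw Taper time-bandwidth product (default 2, giving 3 tapers).
#' @return Object of class `SpectrumResult`: `frequencies` (1-20 Hz grid),
#'   `power` (per condition), `iaf` (Hz or `"none"`), `source`
#'   (`"eyes_open"`, `"eyes_closed"` or `"none"`).
#' @export
estimate_iaf <- function(rec_open, rec_closed = NULL,
                         channels = NULL, prominence = 1.5, nw = 2) {
  freqs <- seq(1, 20, by = 0.5)
  sp_open <- resting_spectrum(rec_open, channels, nw)
  sp_closed <- if (!is.null(rec_closed))
    resting_spectrum(rec_closed, channels, nw) else NULL
  pk_open <- alpha_peak(freqs, sp_open, prominence)
  pk_closed <- if (!is.null(sp_closed))
    alpha_peak(freqs, sp_closed, prominence) else NA
  if (!is.na(pk_open)) {
    iaf <- pk_open; src <- "eyes_open"
  } else if (!is.na(pk_closed)) {
    iaf <- pk_closed; src <- "eyes_closed"
  } else {
    iaf <- "none"; src <- "none"
  }
  structure(list(frequencies = freqs,
                 power = list(eyes_open = sp_open, eyes_closed = sp_closed),
                 iaf = iaf, source = src),
            class = "SpectrumResult")
}

#' @export
print.SpectrumResult <- function(x, ...) {
  cat(sprintf("SpectrumResult: IAF = %s%s\n",
              if (identical(x$iaf, "none")) "none" else sprintf("%.1f Hz", x$iaf),
              if (x$source == "none") "" else sprintf(" (%s)", x$source)))
  invisible(x)
}

# trial-averaged posterior multitaper spectrum on the 1-20 Hz grid
resting_spectrum <- function(rec, channels = NULL, nw = 2) {
  if (rec_duration(rec) < 60) stop("estimate_iaf: recording shorter than 60 s")
  if (is.null(channels)) {
    channels <- posterior_labels(rec$channel_names)
    if (!length(channels)) channels <- rec$channel_names
  }
  x <- rec$data
  x <- x - rep(colMeans(x), each = nrow(x))     # common average reference
  x <- x[match(channels, rec$channel_names), , drop = FALSE]
  fs <- rec$fs
  # band-pass, then bring to the 250 Hz analysis rate
  target <- 250
  fac <- fs / target
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- butter_bandpass_filtfilt(x[ch, ], 0.1, 40, fs)
  if (abs(fac - round(fac)) < 1e-9 && fac > 1) {
    x <- x[, seq(1, ncol(x), by = as.integer(round(fac))), drop = FALSE]
    # (40 Hz low-pass already applied; plain subsampling is alias-free)
    fs <- target
  }
  ep_len <- as.integer(round(2 * fs)); hop <- ep_len %/% 2L
  starts <- seq(1L, ncol(x) - ep_len + 1L, by = hop)
  nep <- length(starts)
  tapers <- dpss_tapers(ep_len, nw)
  freqs <- seq(1, 20, by = 0.5)
  # per-epoch variance (mean over channels) for automatic rejection
  ev <- vapply(starts, function(s)
    mean(apply(x[, s:(s + ep_len - 1L), drop = FALSE], 1, stats::var)), 0)
  q <- stats::quantile(ev, c(0.25, 0.75), names = FALSE)
  keep <- ev <= q[2] + 1.5 * diff(q)
  pows <- matrix(0, sum(keep), length(freqs))
  r <- 0L
  for (s in starts[keep]) {
    r <- r + 1L
    seg <- x[, s:(s + ep_len - 1L), drop = FALSE]
    p <- 0
    for (ch in seq_len(nrow(seg))) {
      y <- seg[ch, ]
      y <- y - mean(y)
      dt <- stats::lm.fit(cbind(1, seq_along(y)), y)$residuals # detrend
      p <- p + mtm_power(dt, fs, freqs, tapers)
    }
    pows[r, ] <- p / nrow(seg)
  }
  colMeans(pows)
}

# accepted alpha peak on the grid, or NA
alpha_peak <- function(freqs, power, prominence) {
  sel <- freqs >= 8 & freqs <= 12
  if (all(power <= 0)) return(NA_real_)
  # 1/f background fit excluding the alpha region
  bg <- freqs >= 2 & !(freqs >= 7 & freqs <= 14) & power > 0
  fit <- stats::lm.fit(cbind(1, log(freqs[bg])), log(power[bg]))
  trend <- exp(fit$coefficients[1] + fit$coefficients[2] * log(freqs))
  cand <- which(sel)
  best <- NA_real_; best_p <- -Inf
  for (i in cand) {
    lo <- max(1L, i - 1L); hi <- min(length(freqs), i + 1L)
    if (power[i] >= max(power[lo:hi]) &&
        power[i] > prominence * trend[i] && power[i] > best_p) {
      best <- freqs[i]; best_p <- power[i]
    }
  }
  best
}
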