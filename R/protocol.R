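#' Rhythmic rTMS burst timing
#'
#' Pulse times of a rhythmic burst delivered at the individual alpha
#' frequency.  The burst duration follows the `n / f` convention (a 20-pulse
#' burst at 8 Hz lasts 2.5 s, at 12 Hz 1.67 s): each pulse "owns" one full
#' stimulation cycle.
#'
#' @param iaf Stimulation frequency in Hz (normally the individual alpha
#'   frequency, 8-12 Hz; a warning is emitted outside that range).
#' @param n_pulses Number of pulses (`>= 2`).
#' @return List with `times` (seconds, first pulse at 0) and `duration`
#'   (`n_pulses / iaf`, seconds).
#' @export
rhythmic_burst <- function(iaf, n_pulses = 20L) {
  if (n_pulses < 2L) stop("rhythmic_burst: need at least 2 pulses")
  if (iaf < 8 || iaf > 12)
    warning("rhythmic_burst: stimulation frequency outside the alpha band (8-12 Hz)")
  list(times = (seq_len(n_pulses) - 1L) / iaf, duration = n_pulses / iaf)
}

#' Forbidden frequency bands for the arrhythmic protocol
#'
#' The arrhythmic control protocol must avoid instantaneous inter-pulse
#' frequencies inside the alpha band, its first harmonic and its
#' subharmonic, so that no frequency-specific stimulation can emerge by
#' chance.  For the (8, 12) Hz band this yields (4, 6), (8, 12) and
#' (16, 24) Hz.
#'
#' @param alpha_low,alpha_high Band edges in Hz, `0 < alpha_low < alpha_high`.
#' @return Object of class `ForbiddenBands`: a two-column matrix of
#'   (low, high) Hz intervals.
#' @export
forbidden_bands <- function(alpha_low = 8, alpha_high = 12) {
  if (!(alpha_low > 0 && alpha_low < alpha_high))
    stop("forbidden_bands: need 0 < alpha_low < alpha_high")
  b <- rbind(c(alpha_low / 2, alpha_high / 2),
             c(alpha_low, alpha_high),
             c(2 * alpha_low, 2 * alpha_high))
  colnames(b) <- c("low", "high")
  rownames(b) <- c("subharmonic", "alpha", "harmonic")
  structure(b, class = c("ForbiddenBands", "matrix"))
}

#' Test frequencies against forbidden bands
#'
#' @param freq Numeric vector of frequencies in Hz.
#' @param bands A [forbidden_bands()] object.
#' @return Logical vector: `TRUE` where the frequency falls inside any
#'   forbidden band (band edges inclusive).
#' @export
is_forbidden <- function(freq, bands) {
  hit <- rep(FALSE, length(freq))
  for (i in seq_len(nrow(bands)))
    hit <- hit | (freq >= bands[i, 1] & freq <= bands[i, 2])
  hit
}

#' Arrhythmic burst timing under the forbidden-frequency constraint
#'
#' Draws pseudo-random pulse times such that every consecutive inter-pulse
#' instantaneous frequency (1 / interval) lies outside all forbidden bands,
#' while the total burst duration stays within `dur_tol` of the rhythmic
#' burst at `iaf` (matched pulse count and approximately matched duration).
#' Instantaneous frequencies are drawn uniformly from `freq_range` minus
#' the forbidden bands and the whole burst is re-drawn (bounded retries)
#' until the duration constraint is met.
#'
#' @param iaf Reference frequency in Hz (determines the matched duration).
#' @param n_pulses Pulses per burst.
#' @param bands A [forbidden_bands()] object.
#' @param seed Integer seed; identical seeds give identical bursts.
#' @param freq_range Sampling range of instantaneous frequencies, Hz.
#' @param dur_tol Relative tolerance on the matched duration (default 10%).
#' @param max_retry Retry bound before giving up.
#' @return Numeric vector of `n_pulses` times in seconds, first pulse at 0.
#' @export
arrhythmic_burst <- function(iaf, n_pulses = 20L, bands = forbidden_bands(),
                             seed = 1L, freq_range = c(3, 30),
                             dur_tol = 0.1, max_retry = 2000L) {
  target <- n_pulses / iaf
  # allowed sub-intervals of freq_range
  cuts <- sort(unique(c(freq_range, pmax(pmin(as.vector(bands), freq_range[2]),
                                         freq_range[1]))))
  segs <- cbind(cuts[-length(cuts)], cuts[-1])
  segs <- segs[!is_forbidden(rowMeans(segs), bands) & segs[, 1] < segs[, 2],
               , drop = FALSE]
  if (nrow(segs) == 0L)
    stop("arrhythmic_burst: no allowed frequencies within the sampling range")
  w <- segs[, 2] - segs[, 1]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (try in seq_len(max_retry)) {
    si <- sample.int(nrow(segs), n_pulses - 1L, replace = TRUE, prob = w)
    f <- stats::runif(n_pulses - 1L, segs[si, 1], segs[si, 2])
    dur <- sum(1 / f)
    # total duration uses the same n/f convention: n-1 intervals + one cycle
    if (abs(dur + 1 / iaf - target) <= dur_tol * target)
      return(c(0, cumsum(1 / f)))
  }
  stop("arrhythmic_burst: duration constraint unsatisfiable within retry bound")
}

get_rng_state <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Full rTMS-EEG session pulse schedule
#'
#' Builds the default session: `n_blocks_per_condition` rhythmic and
#' arrhythmic blocks in randomized order, each of `bursts_per_block` bursts
#' of `n_pulses` pulses, with interburst intervals drawn from
#' `interburst_choices` (onset-to-onset gaps measured from burst end).
#'
#' @param iaf Stimulation frequency (Hz).
#' @param n_blocks_per_condition Blocks per condition (default 5).
#' @param bursts_per_block Bursts per block (default 25).
#' @param n_pulses Pulses per burst (default 20).
#' @param seed Integer seed (block order, interburst gaps, arrhythmic
#'   timing).
#' @param conditions Conditions to schedule; `c("rhythmic", "arrhythmic")`
#'   for the main experiment, `"sham"` behaves like rhythmic timing.
#' @param interburst_choices Possible interburst gaps in seconds.
#' @param lead_in Quiet time before the first burst (s), must exceed the
#'   3.5 s pre-offset analysis window.
#' @return Object of class `PulseSchedule`: list with `bursts` (list of
#'   `condition`, `block`, `times` in session time), `iaf`,
#'   `n_pulses_per_burst`, `block_structure`, `duration`.
#' @export
schedule_session <- function(iaf = 10, n_blocks_per_condition = 5L,
                             bursts_per_block = 25L, n_pulses = 20L,
                             seed = 1L,
                             conditions = c("rhythmic", "arrhythmic"),
                             interburst_choices = c(10, 11),
                             lead_in = 8) {
  stopifnot(n_blocks_per_condition >= 1L, bursts_per_block >= 1L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  blocks <- sample(rep(conditions, n_blocks_per_condition))
  rb <- rhythmic_burst(iaf, n_pulses)
  bursts <- list()
  t <- lead_in
  bi <- 0L
  for (k in seq_along(blocks)) {
    cond <- blocks[k]
    for (j in seq_len(bursts_per_block)) {
      times <- if (cond == "arrhythmic") {
        arrhythmic_burst(iaf, n_pulses, seed = sample.int(2^30, 1L))
      } else rb$times
      bursts[[length(bursts) + 1L]] <-
        list(condition = cond, block = k, burst_index = bi, times = t + times)
      bi <- bi + 1L
      t <- t + max(times) + sample(interburst_choices, 1L)
    }
  }
  structure(list(bursts = bursts, iaf = iaf,
                 n_pulses_per_burst = as.integer(n_pulses),
                 block_structure = blocks, seed = as.integer(seed),
                 duration = t),
            class = "PulseSchedule")
}

#' @export
print.PulseSchedule <- function(x, ...) {
  cond <- vapply(x$bursts, `[[`, "", "condition")
  cat(sprintf("PulseSchedule: %d bursts (%s) x %d pulses @ %g Hz, %.0f s\n",
              length(x$bursts),
              paste(sprintf("%s:%d", names(table(cond)), table(cond)),
                    collapse = ", "),
              x$n_pulses_per_burst, x$iaf, x$duration))
  invisible(x)
}

#' Convert a PulseSchedule to an event table
#'
#' Emits `block_start`/`block_end`, `burst_onset`/`burst_offset` and
#' `pulse` events (burst offset at the last pulse, the time-locking point of
#' the downstream analysis).
#' @param schedule A [schedule_session()] object.
#' @return Event data.frame as used by [recording()].
#' @export
schedule_events <- function(schedule) {
  rows <- list()
  prev_block <- -1L
  for (b in schedule$bursts) {
    if (b$block != prev_block) {
      if (prev_block > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          time = b$times[1] - 1e-3, kind = "block_end",
          condition = "none", burst_index = NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        time = b$times[1] - 5e-4, kind = "block_start",
        condition = b$condition, burst_index = NA_integer_)
      prev_block <- b$block
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time = c(b$times[1], b$times, b$times[length(b$times)]),
      kind = c("burst_onset", rep("pulse", length(b$times)), "burst_offset"),
      condition = b$condition, burst_index = b$burst_index)
  }
  last <- schedule$bursts[[length(schedule$bursts)]]
  rows[[length(rows) + 1L]] <- data.frame(
    time = last$times[length(last$times)] + 2e-4, kind = "block_end",
    condition = "none", burst_index = NA_integer_)
  as_events(do.call(rbind, rows))
}

#' Stimulator output for a target electric field
#'
#' The induced electric field scales linearly with stimulator output, so a
#' target field converts to machine intensity through the subject-specific
#' slope obtained from a finite-element model run at a reference intensity.
#'
#' @param ef_target Target field magnitude, mV/mm.
#' @param ef_per_mso Field per percent maximum stimulator output
#'   (mV/mm per %MSO), `> 0`.
#' @return Intensity in %MSO.
#' @export
mso_for_target_ef <- function(ef_target, ef_per_mso) {
  if (ef_per_mso <= 0) stop("mso_for_target_ef: slope must be positive")
  ef_target / ef_per_mso
}

#' @rdname mso_for_target_ef
#' @param mso Intensity in %MSO.
#' @export
ef_for_mso <- function(mso, ef_per_mso) {
  if (ef_per_mso <= 0) stop("ef_for_mso: slope must be positive")
  mso * ef_per_mso
}

#' Express stimulator output relative to the resting motor threshold
#'
#' @param mso Intensity in %MSO.
#' @param rmt Resting motor threshold in %MSO, `> 0`.
#' @return Intensity in %RMT (100 * mso / rmt).
#' @export
intensity_as_rmt_pct <- function(mso, rmt) {
  if (any(rmt <= 0)) stop("intensity_as_rmt_pct: rmt must be positive")
  100 * mso / rmt
}

#' Summary statistics of an electric-field distribution
#'
#' Per-element field magnitudes (e.g. exported from a finite-element head
#' model) are summarized by mean, median, the 2.5th and 97.5th percentiles,
#' and the peak defined as the 99.9th percentile (robust to single-element
#' numerical outliers on the mesh).  Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).  The normal field
#' component may be negative (outward, hyperpolarizing fields), so the
#' ordering invariant `p2_5 <= median <= p97_5 <= peak` is only meaningful
#' for the absolute component.
#'
#' @param values Numeric vector of field values, mV/mm (`length >= 1`).
#' @param component `"absolute"` or `"normal"`.
#' @return Object of class `EFSummary`: list with `mean`, `median`, `p2_5`,
#'   `p97_5`, `peak`, `component`, `n`.
#' @export
summarize_ef <- function(values, component = c("absolute", "normal")) {
  component <- match.arg(component)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("summarize_ef: no values")
  if (component == "absolute" && any(values < 0))
    stop("summarize_ef: absolute component cannot be negative")
  q <- stats::quantile(values, c(0.025, 0.975, 0.999), names = FALSE, type = 7)
  structure(list(mean = mean(values), median = stats::median(values),
                 p2_5 = q[1], p97_5 = q[2], peak = q[3],
                 component = component, n = length(values)),
            class = "EFSummary")
}

#' @export
print.EFSummary <- function(x, ...) {
  cat(sprintf(paste0("EFSummary (%s, n=%d): mean %.3g, median %.3g, ",
                     "2.5%%/97.5%% %.3g/%.3g, peak(99.9%%) %.3g mV/mm\n"),
              x$component, x$n, x$mean, x$median, x$p2_5, x$p97_5, x$peak))
  invisible(x)
}
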