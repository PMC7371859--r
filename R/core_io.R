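#' Construct a continuous EEG Recording
#'
#' The central container for continuous multichannel EEG: a channels x
#' samples matrix in microvolts, sampling rate, sensor labels/positions and
#' an event table.  All event times are in seconds on the recording clock
#' (t = 0 at the first sample).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of unique channel labels (10-10
#'   style); defaults to rownames of `data`.
#' @param positions Optional channels x 3 matrix of head-centered sensor
#'   coordinates (same order as `data` rows).
#' @param events Data.frame with columns `time` (s), `kind` (one of
#'   `pulse`, `burst_onset`, `burst_offset`, `block_start`, `block_end`,
#'   `none`), `condition` (`rhythmic`, `arrhythmic`, `sham`, `none`) and
#'   `burst_index` (integer, `>= 0`; `NA` allowed for non-burst events).
#' @param meta Free-form provenance list.
#' @return Object of class `Recording`.
#' @export
recording <- function(data, fs, channel_names = rownames(data),
                      positions = NULL, events = empty_events(),
                      meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  rec <- structure(list(data = data, fs = fs,
                        channel_names = as.character(channel_names),
                        positions = positions, events = as_events(events),
                        meta = meta),
                   class = "Recording")
  validate_recording(rec)
  rec
}

event_kinds <- c("pulse", "burst_onset", "burst_offset",
                 "block_start", "block_end", "none")
event_conditions <- c("rhythmic", "arrhythmic", "sham", "none")

#' Empty event table
#' @return Zero-row event data.frame with the canonical columns.
#' @export
empty_events <- function()
  data.frame(time = numeric(0), kind = character(0),
             condition = character(0), burst_index = integer(0),
             stringsAsFactors = FALSE)

as_events <- function(ev) {
  ev <- as.data.frame(ev, stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(empty_events())
  if (is.null(ev$condition)) ev$condition <- "none"
  if (is.null(ev$burst_index)) ev$burst_index <- NA_integer_
  ev <- ev[order(ev$time), c("time", "kind", "condition", "burst_index")]
  rownames(ev) <- NULL
  ev$burst_index <- as.integer(ev$burst_index)
  ev
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "Recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("Recording: fs must be a positive scalar")
  if (length(rec$channel_names) != nrow(rec$data))
    stop("Recording: channel_names length must match data rows")
  if (anyDuplicated(rec$channel_names))
    stop("Recording: channel names must be unique")
  ev <- rec$events
  if (nrow(ev)) {
    if (!all(ev$kind %in% event_kinds))
      stop("Recording: unknown event kind")
    if (!all(ev$condition %in% event_conditions))
      stop("Recording: unknown event condition")
    dur <- ncol(rec$data) / rec$fs
    if (any(ev$time < 0 | ev$time >= dur + 1e-9))
      stop("Recording: event time outside [0, duration)")
    # pulse times strictly increasing within a burst
    pb <- ev[ev$kind == "pulse" & !is.na(ev$burst_index), ]
    if (nrow(pb)) {
      for (b in unique(pb$burst_index)) {
        tt <- pb$time[pb$burst_index == b]
        if (any(diff(tt) <= 0))
          stop("Recording: pulse times within a burst must strictly increase")
      }
    }
  }
  invisible(rec)
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs

## ------------------------------------------------------------------ ##
## Marker dialect shared by both file formats.
## Stimulus code = kind base + condition offset:
##   pulse 1, burst_onset 10, burst_offset 20, block_start 30, block_end 40
##   condition offset: rhythmic 0, arrhythmic 1, sham 2, none 3
## Unknown codes read back as kind = "none" with a warning.
## ------------------------------------------------------------------ ##
.kind_base <- c(pulse = 1L, burst_onset = 10L, burst_offset = 20L,
                block_start = 30L, block_end = 40L)
.cond_off <- c(rhythmic = 0L, arrhythmic = 1L, sham = 2L, none = 3L)

event_to_code <- function(kind, condition) {
  ifelse(kind == "none", 99L,
         .kind_base[kind] + .cond_off[condition])
}

code_to_event <- function(code) {
  kind <- rep("none", length(code))
  condition <- rep("none", length(code))
  for (k in names(.kind_base)) {
    hit <- code >= .kind_base[[k]] & code <= .kind_base[[k]] + 3L
    kind[hit] <- k
    condition[hit] <- names(.cond_off)[code[hit] - .kind_base[[k]] + 1L]
  }
  known <- kind != "none" | code == 99L
  if (any(!known))
    warning(sprintf("unknown marker code(s): %s -> kind='none'",
                    paste(unique(code[!known]), collapse = ", ")))
  list(kind = kind, condition = condition)
}

#' Read a continuous EEG recording from disk
#'
#' Supports the BrainVision triplet (`.vhdr`/`.vmrk`/`.eeg`, binary
#' multiplexed IEEE float32 or int16 with per-channel resolution) and
#' EDF/EDF+ (16-bit, with events stored in an "EDF Annotations" signal).
#' Values are returned in microvolts (the header resolution / scaling is
#' applied).
#'
#' @param path Path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param dialect `"brainvision"` or `"edf"`; inferred from the file
#'   extension when missing.
#' @return A [recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "brainvision", "edf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "brainvision"
  switch(dialect,
         brainvision = read_brainvision(path),
         edf = read_edf(path))
}

#' Write a Recording to disk
#'
#' Round-trips through [read_recording()] preserve samples to better than
#' 0.1 microvolt (exactly, for BrainVision float32), the sampling rate, and
#' all events.  The marker dialect is fixed: stimulus descriptions
#' `S<code>` with code = kind base (pulse 1, burst on/offset 10/20, block
#' start/end 30/40) plus a condition offset (rhythmic 0, arrhythmic 1,
#' sham 2, none 3); the burst index rides in the marker channel field.
#' Marker positions are written in (fractional) data points so off-grid
#' pulse times survive.
#'
#' @param rec A [recording()].
#' @param path Output path (`.vhdr` or `.edf`); companion files are derived.
#' @param dialect `"brainvision"` or `"edf"`.
#' @return Invisibly, the main file path.
#' @export
write_recording <- function(rec, path, dialect = c("auto", "brainvision", "edf")) {
  validate_recording(rec)
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "brainvision"
  switch(dialect,
         brainvision = write_brainvision(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

## ---------------------------- BrainVision ------------------------- ##

write_brainvision <- function(rec, path) {
  path <- sub("\\.vhdr$", "", path, ignore.case = TRUE)
  vhdr <- paste0(path, ".vhdr"); vmrk <- paste0(path, ".vmrk")
  eeg <- paste0(path, ".eeg")
  base <- basename(path)
  nch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; written by entrainr",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_names))
  writeLines(hdr, vhdr, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  ev <- rec$events
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  if (nrow(ev)) {
    code <- event_to_code(ev$kind, ev$condition)
    bi <- ifelse(is.na(ev$burst_index), -1L, ev$burst_index)
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%d,%.12g,1,%d",
                        seq_len(nrow(ev)) + 1L, code,
                        ev$time * rec$fs + 1, bi))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  invisible(vhdr)
}

parse_ini <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

read_brainvision <- function(path) {
  vhdr <- if (grepl("\\.vhdr$", path, ignore.case = TRUE)) path else paste0(path, ".vhdr")
  if (!file.exists(vhdr)) stop("BrainVision: header file not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  ini <- parse_ini(lines)
  dir <- dirname(vhdr)
  eeg <- file.path(dir, ini$DataFile)
  vmrk <- if (!is.null(ini$MarkerFile)) file.path(dir, ini$MarkerFile) else NULL
  if (is.null(ini$DataFile) || !file.exists(eeg))
    stop("BrainVision: data file missing: ", if (is.null(ini$DataFile)) "(not declared)" else eeg)
  nch <- as.integer(ini$NumberOfChannels)
  fs <- 1e6 / as.numeric(ini$SamplingInterval)
  if (!identical(toupper(ini$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED"))
    stop("BrainVision: only multiplexed orientation supported")
  fmt <- toupper(ini$BinaryFormat %||% "IEEE_FLOAT_32")
  # channel info: ChN=<name>,<ref>,<resolution>,<unit>
  chl <- grep("^Ch[0-9]+=", lines, value = TRUE)
  names_res <- lapply(chl, function(x) {
    v <- strsplit(sub("^Ch[0-9]+=", "", x), ",")[[1]]
    list(name = v[1], res = if (length(v) >= 3 && nzchar(v[3])) as.numeric(v[3]) else 1)
  })
  ch_names <- vapply(names_res, `[[`, "", "name")[seq_len(nch)]
  res <- vapply(names_res, function(x) x$res, 0)[seq_len(nch)]
  sz <- file.info(eeg)$size
  if (fmt == "IEEE_FLOAT_32") {
    nsamp <- as.integer(sz / (4L * nch))
    raw <- readBin(eeg, "numeric", n = nch * nsamp, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    nsamp <- as.integer(sz / (2L * nch))
    raw <- readBin(eeg, "integer", n = nch * nsamp, size = 2L,
                   signed = TRUE, endian = "little")
  } else stop("BrainVision: unsupported BinaryFormat ", fmt)
  data <- matrix(raw, nrow = nch) * res
  ev <- empty_events()
  if (!is.null(vmrk) && file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    rows <- lapply(ml, function(x) strsplit(sub("^Mk[0-9]+=", "", x), ",")[[1]])
    rows <- Filter(function(v) length(v) >= 5 && v[1] == "Stimulus", rows)
    if (length(rows)) {
      code <- as.integer(sub("^S\\s*", "", vapply(rows, `[`, "", 2)))
      tm <- (as.numeric(vapply(rows, `[`, "", 3)) - 1) / fs
      bi <- as.integer(vapply(rows, `[`, "", 5))
      ke <- code_to_event(code)
      ev <- data.frame(time = tm, kind = ke$kind, condition = ke$condition,
                       burst_index = ifelse(bi < 0, NA_integer_, bi),
                       stringsAsFactors = FALSE)
    }
  }
  recording(data, fs, ch_names, events = ev,
            meta = list(source = vhdr, format = "brainvision"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ------------------------------- EDF ------------------------------ ##
## Minimal EDF+C: 16-bit signals + one "EDF Annotations" signal carrying
## the event list as TALs ("+<onset>\x14<code>:<burst_index>\x14\x00").
## Recordings are zero-padded to a whole number of 1 s (or shorter) data
## records; the true sample count is stored in the reserved header field.

pad_str <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = -n, flag = " ")
}

write_edf <- function(rec, path) {
  nch <- nrow(rec$data); ns <- ncol(rec$data); fs <- rec$fs
  # choose record duration: 1 s if fs integer, else one sample per record
  spr <- if (abs(fs - round(fs)) < 1e-9) as.integer(round(fs)) else 1L
  rec_dur <- spr / fs
  n_rec <- as.integer(ceiling(ns / spr))
  phys_min <- -3276.8; phys_max <- 3276.7
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  # annotation signal: one TAL block per record, sized to the busiest record.
  # TALs are built as strings ending in \x14; a NUL byte is appended to each
  # at write time (R strings cannot hold embedded NULs).
  ev <- rec$events
  tal_items <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1) * rec_dur
    items <- sprintf("+%.7g\x14\x14", t0) # record timestamp TAL
    if (nrow(ev)) {
      sel <- ev$time >= t0 & ev$time < t0 + rec_dur
      if (r == n_rec) sel <- sel | ev$time >= t0 + rec_dur # stragglers into last record
      for (i in which(sel)) {
        code <- event_to_code(ev$kind[i], ev$condition[i])
        bi <- if (is.na(ev$burst_index[i])) -1L else ev$burst_index[i]
        items <- c(items, sprintf("+%.12g\x14E%d:%d\x14", ev$time[i], code, bi))
      }
    }
    tal_items[[r]] <- items
  }
  tal_raw <- lapply(tal_items, function(items)
    unlist(lapply(items, function(s) c(charToRaw(s), as.raw(0L)))))
  ann_bytes <- max(16L, max(vapply(tal_raw, length, 0L)))
  ann_spr <- as.integer(ceiling(ann_bytes / 2)) # 2 bytes per "sample"
  nsig <- nch + 1L
  hdr_len <- 256L + 256L * nsig
  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad_str(x, n)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8); wr(hdr_len, 8)
  wr(sprintf("EDF+C NSAMP=%d", ns), 44) # reserved: true sample count (dialect)
  wr(n_rec, 8); wr(sprintf("%.8g", rec_dur), 8); wr(nsig, 8)
  field <- function(vals, n) for (v in vals) wr(v, n)
  field(c(rec$channel_names, "EDF Annotations"), 16)
  field(rep("", nsig), 80)                      # transducer
  field(c(rep("uV", nch), ""), 8)               # physical dimension
  field(c(rep(sprintf("%.6g", phys_min), nch), "-1"), 8)
  field(c(rep(sprintf("%.6g", phys_max), nch), "1"), 8)
  field(c(rep(dig_min, nch), dig_min), 8)
  field(c(rep(dig_max, nch), dig_max), 8)
  field(rep("", nsig), 80)                      # prefiltering
  field(c(rep(spr, nch), ann_spr), 8)
  field(rep("", nsig), 32)                      # reserved
  dig <- function(x) { # keep matrix dims: layout relies on t() below
    d <- round((x - phys_min) / scale) + dig_min
    d[] <- pmin(pmax(d, dig_min), dig_max)
    storage.mode(d) <- "integer"
    d
  }
  padded <- matrix(0, nch, n_rec * spr)
  padded[, seq_len(ns)] <- rec$data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.vector(t(dig(padded[, idx, drop = FALSE]))), con,
             size = 2L, endian = "little")
    tb <- tal_raw[[r]]
    writeBin(c(tb, raw(2L * ann_spr - length(tb))), con)
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF: file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_len <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(8))
  gf <- function(n) vapply(seq_len(nsig), function(i) trimws(rd(n)), "")
  labels <- gf(16); gf(80); dims <- gf(8)
  pmin_ <- as.numeric(gf(8)); pmax_ <- as.numeric(gf(8))
  dmin_ <- as.numeric(gf(8)); dmax_ <- as.numeric(gf(8))
  gf(80); spr <- as.integer(gf(8)); gf(32)
  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  fs <- spr[sig_idx[1]] / rec_dur
  true_ns <- NA_integer_
  if (grepl("NSAMP=", reserved))
    true_ns <- as.integer(sub(".*NSAMP=([0-9]+).*", "\\1", reserved))
  data <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  ann_txt <- character(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(nsig)) {
      if (is_ann[s]) {
        b <- readBin(con, "raw", 2L * spr[s])
        ann_txt <- c(ann_txt, rawToChar(b[b != as.raw(0)]))
      } else {
        v <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
        k <- match(s, sig_idx)
        sc <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        data[k, ((r - 1) * spr[s] + 1):(r * spr[s])] <- pmin_[s] + (v - dmin_[s]) * sc
      }
    }
  }
  if (!is.na(true_ns)) data <- data[, seq_len(true_ns), drop = FALSE]
  ev <- empty_events()
  ann_all <- paste(ann_txt, collapse = "")
  tal <- regmatches(ann_all,
                    gregexpr("\\+[0-9.eE+-]+\x14E[0-9]+:-?[0-9]+\x14", ann_all))[[1]]
  if (length(tal)) {
    tm <- as.numeric(sub("^\\+([0-9.eE+-]+)\x14.*", "\\1", tal))
    code <- as.integer(sub(".*\x14E([0-9]+):.*", "\\1", tal))
    bi <- as.integer(sub(".*:(-?[0-9]+)\x14$", "\\1", tal))
    ke <- code_to_event(code)
    ev <- data.frame(time = tm, kind = ke$kind, condition = ke$condition,
                     burst_index = ifelse(bi < 0, NA_integer_, bi),
                     stringsAsFactors = FALSE)
  }
  recording(data, fs, labels[sig_idx], events = ev,
            meta = list(source = path, format = "edf"))
}
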