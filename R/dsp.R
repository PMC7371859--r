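# Signal-processing primitives.  No suitable DSP package ships with the
# supported environment, so the handful of textbook primitives the pipeline
# needs are implemented here and validated against analytic oracles in the
# test suite.

## ---- Butterworth IIR (even order, cascaded biquads) --------------- ##

# biquad sections for an order-n Butterworth low/high-pass at fc (Hz)
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (n %% 2L != 0L) stop("butter_sos: only even orders supported")
  if (fc <= 0 || fc >= fs / 2) stop("butter_sos: cutoff must be in (0, fs/2)")
  W <- tan(pi * fc / fs)                     # pre-warped analog cutoff
  k <- seq_len(n / 2)
  re <- -sin(pi * (2 * k - 1) / (2 * n))     # Re of unit prototype poles
  sos <- vector("list", n / 2)
  for (j in seq_along(k)) {
    if (type == "low") {                     # s-domain: W^2 / (s^2 + a1 s + a0)
      a1 <- -2 * re[j] * W; a0 <- W^2
      b <- W^2 * c(1, 2, 1)
    } else {                                 # s^2 / (s^2 + a1 s + a0)
      a1 <- -2 * re[j] * W; a0 <- W^2
      b <- c(1, -2, 1)
    }
    a <- c(1 + a1 + a0, -2 + 2 * a0, 1 - a1 + a0)
    sos[[j]] <- list(b = b / a[1], a = a / a[1])
  }
  sos
}

biquad_filter <- function(x, b, a) {
  n <- length(x)
  xb <- b[1] * x
  if (n >= 2) xb[2:n] <- xb[2:n] + b[2] * x[1:(n - 1)]
  if (n >= 3) xb[3:n] <- xb[3:n] + b[3] * x[1:(n - 2)]
  as.numeric(stats::filter(xb, -a[2:3], method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (s in sos) x <- biquad_filter(x, s$b, s$a)
  x
}

# zero-phase filtering: forward-backward with odd-reflection padding
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  pad <- min(n - 1L, 3L * 12L)
  if (pad > 0) {
    head <- 2 * x[1] - x[(pad + 1):2]
    tail <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- c(head, x, tail)
  } else y <- x
  y <- sos_filter(y, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(pad + 1):(pad + n)]
}

# band-pass via cascaded high- and low-pass (order each)
butter_bandpass_filtfilt <- function(x, low, high, fs, order = 4L) {
  x <- sos_filtfilt(x, butter_sos(order, low, fs, "high"))
  sos_filtfilt(x, butter_sos(order, high, fs, "low"))
}

## ---- FIR anti-alias decimation ------------------------------------ ##

# zero-phase windowed-sinc low-pass, cutoff in cycles/sample
fir_lowpass_kernel <- function(cutoff, half_len) {
  t <- -half_len:half_len
  h <- 2 * cutoff * sinc(2 * cutoff * t)
  w <- 0.54 + 0.46 * cos(pi * t / half_len)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

fft_convolve_same <- function(x, h) {
  # 'same' linear convolution of x with centered symmetric kernel h
  n <- length(x); m <- length(h); half <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                     stats::fft(c(h, numeric(nf - m))), inverse = TRUE)) / nf
  y[(half + 1L):(half + n)]
}

# decimate by integer factor with reflection padding at the edges
fir_decimate <- function(x, factor) {
  if (factor == 1L) return(x)
  h <- fir_lowpass_kernel(0.4 / factor, half_len = 8L * factor)
  n <- length(x); pad <- 8L * factor
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- fft_convolve_same(xe, h)[(pad + 1):(pad + n)]
  y[seq(1L, n, by = factor)]
}

## ---- DPSS (Slepian) tapers ---------------------------------------- ##

# first k discrete prolate spheroidal sequences, length n, half-bandwidth nw
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  w <- nw / n
  i <- seq_len(n)
  d <- ((n - 1 - 2 * (i - 1)) / 2)^2 * cos(2 * pi * w)
  e <- (i[-n] * (n - i[-n])) / 2
  M <- diag(d)
  M[cbind(i[-n], i[-n] + 1L)] <- e
  M[cbind(i[-n] + 1L, i[-n])] <- e
  dec <- eigen(M, symmetric = TRUE)
  tap <- dec$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

# multitaper power spectrum of one epoch at the requested frequencies
mtm_power <- function(x, fs, freqs, tapers) {
  n <- length(x)
  stopifnot(nrow(tapers) == n)
  bins <- round(freqs * n / fs) + 1L
  stopifnot(all(abs(freqs - (bins - 1L) * fs / n) < 1e-6)) # grid must align
  p <- 0
  for (j in seq_len(ncol(tapers))) {
    X <- stats::fft(x * tapers[, j])
    p <- p + Mod(X[bins])^2
  }
  p / ncol(tapers) * 2 / fs
}

## ---- FastICA (fixed-point, deflation, tanh) ------------------------ ##

# X: channels x samples, returns unmixing (comp x ch), mixing (ch x comp),
# sources scaled so the strongest channel projection of each component has
# unit gain (component amplitudes are therefore in uV).
#
# Symmetric (parallel) fixed-point iteration with tanh contrast.  With
# near-Gaussian inputs the rotation within the Gaussian subspace is not
# identifiable and the global convergence criterion may never trigger; the
# non-Gaussian components of interest stabilize early and reconstruction
# is exact for any orthogonal rotation, so on_fail = "warn" (the default
# used by the preprocessing stages) accepts the final rotation with a
# warning rather than failing the pipeline.
fast_ica <- function(X, n_comp, seed = 1L, max_iter = 100L, tol = 1e-4,
                     retries = 2L, max_fit = 20000L,
                     on_fail = c("warn", "error")) {
  on_fail <- match.arg(on_fail)
  nch <- nrow(X)
  n_comp <- min(n_comp, nch)
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- Xc %*% t(Xc) / ncol(Xc)
  ed <- eigen(cv, symmetric = TRUE)
  keep <- ed$values > max(ed$values) * 1e-10
  n_comp <- min(n_comp, sum(keep))
  K <- diag(1 / sqrt(ed$values[seq_len(n_comp)]), n_comp) %*%
    t(ed$vectors[, seq_len(n_comp), drop = FALSE])
  Z <- K %*% Xc
  ns <- ncol(Z)
  Zf <- if (ns > max_fit) Z[, round(seq(1, ns, length.out = max_fit)),
                            drop = FALSE] else Z
  nf <- ncol(Zf)
  sym_orth <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-18)), nrow(W)) %*%
      t(e$vectors) %*% W
  }
  converged <- FALSE
  for (attempt in seq_len(retries)) {
    old <- get_rng_state(); set.seed(as.integer(seed) + attempt - 1L)
    W <- sym_orth(matrix(stats::rnorm(n_comp * n_comp), n_comp))
    restore_rng_state(old)
    for (it in seq_len(max_iter)) {
      G <- tanh(W %*% Zf)
      W1 <- G %*% t(Zf) / nf - diag(rowMeans(1 - G^2), n_comp) %*% W
      W1 <- sym_orth(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  if (!converged) {
    if (on_fail == "error")
      stop("fast_ica: no convergence after retries")
    warning("fast_ica: global rotation not fully converged (near-Gaussian subspace); using final iterate")
  }
  U <- W %*% K                      # unmixing: comp x ch
  S <- U %*% Xc
  A <- ed$vectors[, seq_len(n_comp), drop = FALSE] %*%
    diag(sqrt(ed$values[seq_len(n_comp)]), n_comp) %*% t(W) # mixing: ch x comp
  sc <- apply(abs(A), 2, max)
  A <- sweep(A, 2, sc, "/")
  S <- S * sc
  list(unmixing = U * sc, mixing = A, sources = S,
       center = mu, n_comp = n_comp, converged = converged)
}

## ---- shape-preserving gap interpolation ---------------------------- ##

# fill masked runs of a vector by local Fritsch-Carlson monotone cubic
# Hermite interpolation (pchip); returns list(values, edge_extended)
pchip_fill <- function(x, mask, context = 8L) {
  if (!any(mask)) return(list(values = x, edge_extended = FALSE))
  n <- length(x)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  edge <- FALSE
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    li <- seq_len(i0 - 1L); ri <- if (i1 < n) (i1 + 1L):n else integer(0)
    li <- utils::tail(li[!mask[li]], context)
    ri <- utils::head(ri[!mask[ri]], context)
    if (length(li) >= 2L && length(ri) >= 2L) {
      xs <- c(li, ri)
      f <- stats::splinefun(xs, x[xs], method = "monoH.FC")
      x[i0:i1] <- f(i0:i1)
    } else if (length(li) + length(ri) > 0L) { # gap at trial edge
      x[i0:i1] <- x[c(li, ri)[1]]
      edge <- TRUE
    }
  }
  list(values = x, edge_extended = edge)
}

## ---- Morlet wavelet ------------------------------------------------ ##

# complex Morlet coefficients of x at one frequency; width in cycles,
# Gaussian envelope truncated at +-gwidth standard deviations
morlet_coef <- function(x, fs, freq, cycles = 5, gwidth = 3) {
  sigma_t <- cycles / (2 * pi * freq)
  half <- max(1L, round(gwidth * sigma_t * fs))
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w <- w / sum(abs(w))
  n <- length(x); m <- length(w)
  nf <- stats::nextn(n + m - 1L, 2L)
  y <- stats::fft(stats::fft(c(x, numeric(nf - n))) *
                  stats::fft(c(w, numeric(nf - m))), inverse = TRUE) / nf
  list(coef = y[(half + 1L):(half + n)], half_support = half)
}
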