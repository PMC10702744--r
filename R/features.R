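#' Construct an EEG window
#'
#' A single analysis window of multichannel EEG: a channels x time matrix with
#' its sampling rate and channel names. The default geometry is the one used
#' throughout the package: 17 channels, 8 s windows, 200 Hz.
#'
#' @param signal numeric matrix, channels x time samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels, one per row of `signal`.
#' @param window_seconds nominal window duration; `ncol(signal)` must equal
#'   `fs * window_seconds` exactly.
#' @return An object of class `eeg_window`.
#' @export
eeg_window <- function(signal, fs, channel_names = canonical_channels(),
                       window_seconds = ncol(signal) / fs) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop("eeg_window: signal must be a finite numeric matrix")
  if (length(channel_names) != nrow(signal))
    stop("eeg_window: need one channel name per signal row (got ",
         length(channel_names), " names for ", nrow(signal), " rows)")
  if (abs(ncol(signal) - fs * window_seconds) > 1e-9)
    stop("eeg_window: ncol(signal) = ", ncol(signal),
         " but fs * window_seconds = ", fs * window_seconds)
  rownames(signal) <- channel_names
  structure(list(signal = signal, fs = fs,
                 channel_names = as.character(channel_names),
                 window_seconds = window_seconds),
            class = "eeg_window")
}

#' @export
print.eeg_window <- function(x, ...) {
  cat("eeg_window: ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples (", x$window_seconds, " s @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

# Rational resampler: zero-stuff by p, linear-phase FIR low-pass applied
# forward-backward, decimate by q. Output length floor(n * p / q).
resample_rational <- function(x, p, q) {
  if (p == q) return(x)
  g <- gcd_int(p, q); p <- p %/% g; q <- q %/% g
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x * p
  cutoff <- 0.9 / max(p, q)          # fraction of the upsampled Nyquist
  ord <- 20L * max(p, q)
  h <- signal::fir1(ord, cutoff)
  y <- signal::filtfilt(signal::Ma(h), up)
  y[seq(1, by = q, length.out = floor(n * p / q))]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Preprocess raw EEG: resample and band-pass filter
#'
#' Downsamples each channel by rational resampling (anti-alias FIR applied
#' zero-phase) and band-limits the result with zero-phase Butterworth
#' filters (2nd-order high-pass at the lower edge, 6th-order low-pass at the
#' upper edge, each applied forward-backward). Defaults mirror the standard
#' vigilance-EEG pipeline: 1000 Hz recordings downsampled to 200 Hz and
#' band-passed to 1-50 Hz.
#'
#' @param signal channels x time numeric matrix at `fs_in`.
#' @param fs_in input sampling rate (Hz).
#' @param fs_out output sampling rate (Hz); must not exceed `fs_in`.
#' @param band length-2 numeric, (low, high) pass-band edges in Hz;
#'   `high` must be below `fs_out / 2`.
#' @param channel_names passed through to the returned window.
#' @return An `eeg_window` at `fs_out`, band-limited to `band`. The output
#'   length is `floor(ncol(signal) * fs_out / fs_in)`.
#' @export
preprocess_eeg <- function(signal, fs_in, fs_out = 200,
                           band = c(1, 50),
                           channel_names = canonical_channels()) {
  signal <- as.matrix(signal)
  if (any(!is.finite(signal)))
    stop("preprocess_eeg: non-finite samples in input signal")
  if (fs_out > fs_in)
    stop("preprocess_eeg: fs_out (", fs_out, ") exceeds fs_in (", fs_in, ")")
  if (band[1] >= band[2] || band[2] >= fs_out / 2)
    stop("preprocess_eeg: need band low < high < fs_out/2")
  hp <- signal::butter(2, band[1] / (fs_out / 2), type = "high")
  lp <- signal::butter(6, band[2] / (fs_out / 2), type = "low")
  out <- t(apply(signal, 1, function(x) {
    y <- resample_rational(x, fs_out, fs_in)
    signal::filtfilt(lp, signal::filtfilt(hp, y))
  }))
  eeg_window(out, fs = fs_out, channel_names = channel_names,
             window_seconds = ncol(out) / fs_out)
}

# Averaged modified periodogram (Welch, non-overlapping 1 s Hann segments,
# per-segment mean removal). Returns one-sided PSD per channel in
# units^2 / Hz, plus the frequency grid. x: channels x time.
welch_psd <- function(x, fs, segment_seconds = 1) {
  ns <- round(fs * segment_seconds)
  nseg <- floor(ncol(x) / ns)
  if (nseg < 1) stop("welch_psd: window shorter than one segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(ns) / (ns + 1))  # Hann
  u <- sum(w^2)
  nch <- nrow(x)
  # stack all segments of all channels column-wise for one batched FFT
  segs <- matrix(0, ns, nch * nseg)
  k <- 0L
  for (ch in seq_len(nch)) for (s in seq_len(nseg)) {
    k <- k + 1L
    seg <- x[ch, ((s - 1) * ns + 1):(s * ns)]
    segs[, k] <- (seg - mean(seg)) * w
  }
  P <- abs(stats::mvfft(segs))^2 / (fs * u)
  nf <- ns %/% 2 + 1
  P <- P[seq_len(nf), , drop = FALSE]
  # one-sided: double everything except DC (and Nyquist when ns is even)
  dbl <- rep(2, nf); dbl[1] <- 1; if (ns %% 2 == 0) dbl[nf] <- 1
  P <- P * dbl
  psd <- matrix(0, nch, nf)
  for (ch in seq_len(nch))
    psd[ch, ] <- rowMeans(P[, ((ch - 1) * nseg + 1):(ch * nseg), drop = FALSE])
  list(psd = psd, freq = (seq_len(nf) - 1) * fs / ns)
}

#' Differential entropy per channel and frequency band
#'
#' For a Gaussian band-limited signal the differential entropy is
#' \eqn{\tfrac12 \ln(2\pi e \sigma^2)} nats, where \eqn{\sigma^2} is the
#' band power. The band power is estimated from an averaged modified
#' periodogram (1 s non-overlapping Hann segments, per-segment mean removal)
#' integrated over each band.
#'
#' @param window an [eeg_window()].
#' @param scheme a [band_scheme()] (or its name).
#' @param power_floor band powers below this are clamped before the log so
#'   degenerate inputs give a finite (flagged) value rather than -Inf.
#' @return numeric matrix, channels x bands, in nats. Attribute `"clamped"`
#'   is a logical matrix marking bands whose power hit `power_floor`.
#' @export
compute_de <- function(window, scheme = band_scheme("5band"),
                       power_floor = 1e-12) {
  stopifnot(inherits(window, "eeg_window"))
  if (is.character(scheme)) scheme <- band_scheme(scheme)
  stopifnot(inherits(scheme, "band_scheme"))
  if (max(scheme$bands) >= window$fs / 2)
    stop("compute_de: band edges reach the Nyquist frequency ",
         window$fs / 2, " Hz")
  sp <- welch_psd(window$signal, window$fs)
  df <- sp$freq[2] - sp$freq[1]
  nb <- nrow(scheme$bands)
  pow <- matrix(0, nrow(window$signal), nb,
                dimnames = list(window$channel_names, rownames(scheme$bands)))
  for (b in seq_len(nb)) {
    lo <- scheme$bands[b, 1]; hi <- scheme$bands[b, 2]
    sel <- if (scheme$right_closed[b]) sp$freq >= lo & sp$freq <= hi
           else                        sp$freq >= lo & sp$freq < hi
    pow[, b] <- rowSums(sp$psd[, sel, drop = FALSE]) * df
  }
  clamped <- pow < power_floor
  pow[clamped] <- power_floor
  de <- 0.5 * log(2 * pi * exp(1) * pow)
  attr(de, "clamped") <- clamped
  de
}

#' Fuse rhythm-band and uniform-band differential-entropy features
#'
#' Concatenates the 5-rhythm-band DE matrix and the 25 x 2 Hz DE matrix of
#' the same window along the band axis, rhythm bands first. No value is
#' altered.
#'
#' @param de5 channels x 5 matrix from the `"5band"` scheme.
#' @param de25 channels x 25 matrix from the `"2Hz"` scheme.
#' @return channels x 30 matrix.
#' @export
fuse_features <- function(de5, de25) {
  de5 <- as.matrix(de5); de25 <- as.matrix(de25)
  if (nrow(de5) != nrow(de25))
    stop("fuse_features: channel counts differ (", nrow(de5), " vs ",
         nrow(de25), ")")
  if (ncol(de5) != 5)
    stop("fuse_features: de5 must have 5 bands, got ", ncol(de5))
  if (ncol(de25) != 25)
    stop("fuse_features: de25 must have 25 bands, got ", ncol(de25))
  cbind(de5, de25)
}

#' Fused DE features of one window
#'
#' Convenience wrapper: [compute_de()] under both schemes, then
#' [fuse_features()].
#'
#' @param window an [eeg_window()].
#' @return channels x 30 matrix in nats.
#' @export
compute_de_fused <- function(window) {
  fuse_features(compute_de(window, band_scheme("5band")),
                compute_de(window, band_scheme("2Hz")))
}

#' Construct an eye-state interval log
#'
#' Durations (seconds) of the four eye states within one analysis window.
#' They must account for the whole window.
#'
#' @param blink,fixation,saccade,close durations in seconds, each >= 0.
#' @param window_seconds total window duration (default 8 s).
#' @return An object of class `eye_state_log`.
#' @export
eye_state_log <- function(blink, fixation, saccade, close,
                          window_seconds = 8) {
  d <- c(blink = blink, fixation = fixation, saccade = saccade, close = close)
  if (any(!is.finite(d)) || any(d < 0))
    stop("eye_state_log: durations must be finite and non-negative")
  if (abs(sum(d) - window_seconds) > 1e-9)
    stop("eye_state_log: durations sum to ", sum(d), ", expected ",
         window_seconds)
  structure(as.list(c(d, window_seconds = window_seconds)),
            class = "eye_state_log")
}

#' PERCLOS: percentage of eye closure in one window
#'
#' PERCLOS = (blink + close) / interval, with
#' interval = blink + fixation + saccade + close. It is the fraction of the
#' window the eyes spent in a fatigued (blinking or closed) state.
#'
#' @param log an [eye_state_log()].
#' @return numeric in `[0, 1]`.
#' @export
compute_perclos <- function(log) {
  stopifnot(inherits(log, "eye_state_log"))
  interval <- log$blink + log$fixation + log$saccade + log$close
  if (interval <= 0) stop("compute_perclos: zero-length interval is undefined")
  (log$blink + log$close) / interval
}

#' Three-class vigilance label from a PERCLOS value
#'
#' Standard thresholds: Awake if PERCLOS < 0.35, Tired if
#' 0.35 <= PERCLOS < 0.7, Drowsy if PERCLOS >= 0.7.
#'
#' @param perclos numeric vector of PERCLOS values in `[0, 1]`.
#' @return factor with levels Awake, Tired, Drowsy.
#' @export
label_from_perclos <- function(perclos) {
  if (any(!is.finite(perclos)) || any(perclos < 0) || any(perclos > 1))
    stop("label_from_perclos: PERCLOS must lie in [0, 1]")
  klass <- ifelse(perclos < 0.35, "Awake",
                  ifelse(perclos < 0.7, "Tired", "Drowsy"))
  factor(klass, levels = vigilance_classes())
}

#' The three vigilance classes, in increasing fatigue order
#' @return `c("Awake", "Tired", "Drowsy")`
#' @export
vigilance_classes <- function() c("Awake", "Tired", "Drowsy")
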