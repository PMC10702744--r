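#' Vigilance-state profile for the synthetic EEG generator
#'
#' A profile fixes the relative power of the five canonical rhythms, the
#' PERCLOS range of the state, and the broadband noise floor. The awake
#' brain carries relatively more alpha/beta power; the drowsy brain more
#' delta/theta.
#'
#' @param name one of `"Awake"`, `"Tired"`, `"Drowsy"`.
#' @param band_weights positive numeric length 5 (delta, theta, alpha, beta,
#'   gamma), relative band powers.
#' @param perclos_range length-2 numeric, a sub-interval of the class's
#'   PERCLOS threshold interval.
#' @param noise_floor broadband white-noise power relative to total rhythm
#'   power.
#' @return object of class `state_profile`.
#' @export
state_profile <- function(name, band_weights, perclos_range, noise_floor = 0.05) {
  name <- match.arg(name, vigilance_classes())
  stopifnot(length(band_weights) == 5, all(band_weights > 0),
            length(perclos_range) == 2, noise_floor >= 0)
  names(band_weights) <- c("delta", "theta", "alpha", "beta", "gamma")
  lims <- switch(name, Awake = c(0, 0.35), Tired = c(0.35, 0.7),
                 Drowsy = c(0.7, 1))
  if (perclos_range[1] > perclos_range[2])
    stop("state_profile: empty perclos_range")
  # class intervals are half-open on the right except Drowsy ([0.7, 1])
  ok <- perclos_range[1] >= lims[1] &&
    (if (name == "Drowsy") perclos_range[2] <= 1 else perclos_range[2] < lims[2])
  if (!ok)
    stop("state_profile: perclos_range [", perclos_range[1], ", ",
         perclos_range[2], "] outside the ", name, " interval [",
         lims[1], ", ", lims[2], if (name == "Drowsy") "]" else ")")
  ab <- band_weights["alpha"] + band_weights["beta"]
  dt <- band_weights["delta"] + band_weights["theta"]
  if (name == "Awake" && ab <= dt)
    stop("state_profile: Awake requires alpha+beta > delta+theta weight")
  if (name == "Drowsy" && dt <= ab)
    stop("state_profile: Drowsy requires delta+theta > alpha+beta weight")
  structure(list(name = name, band_weights = band_weights,
                 perclos_range = perclos_range, noise_floor = noise_floor),
            class = "state_profile")
}

#' Default state profiles
#'
#' Awake windows are alpha/beta dominant, drowsy windows delta/theta
#' dominant, tired windows intermediate; PERCLOS ranges sit inside the
#' class threshold intervals with a margin so sampled logs always label
#' back to their class.
#'
#' @return named list of three [state_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    Awake = state_profile("Awake", c(delta = 0.6, theta = 0.7, alpha = 1.6,
                                     beta = 1.5, gamma = 0.5),
                          perclos_range = c(0.05, 0.30)),
    Tired = state_profile("Tired", c(delta = 1.0, theta = 1.1, alpha = 1.0,
                                     beta = 0.9, gamma = 0.45),
                          perclos_range = c(0.40, 0.65)),
    Drowsy = state_profile("Drowsy", c(delta = 1.8, theta = 1.7, alpha = 0.7,
                                       beta = 0.6, gamma = 0.4),
                           perclos_range = c(0.72, 0.95))
  )
}

#' Default channel-mixing matrix
#'
#' Channels are correlated through shared latent band sources: each rhythm
#' band has two independent sources, one loaded mainly by the temporal
#' block, one by the posterior block, so channels within an anatomical block
#' co-vary more strongly than channels across blocks. Rows are normalized so
#' every channel carries the same per-band power (amplitude `amplitude`
#' microvolts RMS overall).
#'
#' @param channel_names channels (canonical 17 by default).
#' @param amplitude per-channel RMS amplitude in microvolts.
#' @param seed seed for the small per-channel loading jitter.
#' @return channels x 10 mixing matrix (columns: 2 sources per band,
#'   delta..gamma).
#' @export
default_mixing <- function(channel_names = canonical_channels(),
                           amplitude = 20, seed = 42L) {
  nch <- length(channel_names)
  temporal <- channel_names %in% c("FT7", "FT8", "T7", "T8", "TP7", "TP8")
  phi <- ifelse(temporal, 0.35, 1.20)
  phi <- phi + with_seed(seed, stats::runif(nch, -0.15, 0.15))
  M <- matrix(0, nch, 10,
              dimnames = list(channel_names,
                              paste0(rep(c("delta", "theta", "alpha", "beta",
                                           "gamma"), each = 2), c("_A", "_B"))))
  for (b in 1:5) {
    M[, 2 * b - 1] <- amplitude * cos(phi)
    M[, 2 * b] <- amplitude * sin(phi)
  }
  M
}

# Exactly band-limited unit-variance noise via FFT masking with
# raised-cosine edges just inside the band.
band_noise <- function(n, fs, low, high, roll = 0.5) {
  x <- stats::rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  up <- (f - low) / roll
  dn <- (high - f) / roll
  mask <- pmin(pmax(up, 0), 1) * pmin(pmax(dn, 0), 1)
  mask <- 0.5 - 0.5 * cos(pi * pmin(pmax(mask, 0), 1))  # raised cosine
  mask[f < low | f > high] <- 0
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate one synthetic EEG window
#'
#' Sum of band-limited noise sources (power proportional to the profile's
#' band weights) mixed across channels, plus broadband white noise at the
#' profile's noise floor. Deterministic for a fixed seed.
#'
#' @param profile a [state_profile()].
#' @param mixing channels x K mixing matrix with K = 2 sources per band
#'   (see [default_mixing()]); K must be `2 * 5`.
#' @param fs sampling rate (must support the gamma band: fs > 100).
#' @param seconds window length in seconds.
#' @param seed RNG seed.
#' @return an [eeg_window()].
#' @export
generate_window <- function(profile, mixing = default_mixing(), fs = 200,
                            seconds = 8, seed = 1L) {
  stopifnot(inherits(profile, "state_profile"))
  bands <- band_scheme("5band")$bands
  if (fs / 2 <= max(bands))
    stop("generate_window: fs = ", fs, " too low for the gamma band (",
         max(bands), " Hz)")
  K <- ncol(mixing)
  if (K != 2 * nrow(bands))
    stop("generate_window: mixing must have ", 2 * nrow(bands), " columns")
  n <- round(fs * seconds)
  w <- profile$band_weights / sum(profile$band_weights)
  with_seed(seed, {
    S <- matrix(0, K, n)
    for (b in seq_len(nrow(bands))) {
      sc <- sqrt(w[b])
      S[2 * b - 1, ] <- sc * band_noise(n, fs, bands[b, 1], bands[b, 2])
      S[2 * b, ] <- sc * band_noise(n, fs, bands[b, 1], bands[b, 2])
    }
    X <- mixing %*% S
    if (profile$noise_floor > 0) {
      a2 <- rowSums(mixing^2) / nrow(bands)      # per-channel signal power
      X <- X + sqrt(profile$noise_floor * a2) *
        matrix(stats::rnorm(nrow(mixing) * n), nrow(mixing), n)
    }
    eeg_window(X, fs = fs, channel_names = rownames(mixing),
               window_seconds = seconds)
  })
}

#' Generate one synthetic eye-state log
#'
#' Draws a PERCLOS value uniformly inside the profile's range and splits the
#' window into blink/close and fixation/saccade durations accordingly, so
#' the log labels back to the generating class by construction.
#'
#' @param profile a [state_profile()].
#' @param seed RNG seed.
#' @param window_seconds window length (default 8 s).
#' @return an [eye_state_log()].
#' @export
generate_eye_log <- function(profile, seed = 1L, window_seconds = 8) {
  stopifnot(inherits(profile, "state_profile"))
  r <- profile$perclos_range
  if (r[1] > r[2]) stop("generate_eye_log: empty perclos_range")
  with_seed(seed, {
    p <- stats::runif(1, r[1], r[2])
    closed <- p * window_seconds
    open <- window_seconds - closed
    bf <- stats::runif(1, 0.2, 0.8)
    ff <- stats::runif(1, 0.3, 0.9)
    eye_state_log(blink = closed * bf, fixation = open * ff,
                  saccade = open * (1 - ff), close = closed * (1 - bf),
                  window_seconds = window_seconds)
  })
}

# Geometric-block class sequence: consecutive same-class runs with mean
# block length `mean_block`, mimicking slow vigilance drift.
class_block_sequence <- function(n_windows, seed, mean_block = 30,
                                 n_classes = 3L) {
  with_seed(seed, {
    cls <- integer(0)
    cur <- sample.int(n_classes, 1)
    while (length(cls) < n_windows) {
      len <- 1L + stats::rgeom(1, 1 / mean_block)
      cls <- c(cls, rep(cur, len))
      nxt <- sample.int(n_classes, 1)
      if (nxt == cur) nxt <- (cur %% n_classes) + 1L   # force a change
      cur <- nxt
    }
    cls[seq_len(n_windows)]
  })
}

#' Generate a full synthetic subject
#'
#' A temporally ordered sequence of (EEG window, eye-state log, class)
#' triples whose class sequence drifts in geometric blocks (mean length 30
#' windows), emulating slow vigilance changes during a drive. Regenerating
#' with the same seed is bit-identical.
#'
#' @param n_windows number of 8-s windows (default 885).
#' @param seed subject seed; per-window seeds are derived from it.
#' @param profiles named list of the three [state_profile()]s.
#' @param class_sequence optional integer/character sequence of classes,
#'   length `n_windows`; overrides the drift simulation.
#' @param mixing channel mixing matrix.
#' @param fs sampling rate.
#' @param window_seconds window length.
#' @param mean_block mean class-block length in windows.
#' @param subject_id identifier stored in the object.
#' @return object of class `synthetic_subject`: lists `windows` and
#'   `eye_logs`, factor `classes`, plus provenance (`seed`, `mixing`,
#'   `subject_id`).
#' @export
generate_subject <- function(n_windows = 885L, seed = 1L,
                             profiles = default_profiles(),
                             class_sequence = NULL,
                             mixing = default_mixing(), fs = 200,
                             window_seconds = 8, mean_block = 30,
                             subject_id = "synthetic-01") {
  if (is.null(class_sequence)) {
    cls <- class_block_sequence(n_windows, child_seed(seed, 1L), mean_block)
  } else {
    if (length(class_sequence) != n_windows)
      stop("generate_subject: class_sequence length must equal n_windows")
    cls <- if (is.character(class_sequence))
      match(class_sequence, vigilance_classes()) else as.integer(class_sequence)
    if (any(is.na(cls)) || any(cls < 1) || any(cls > 3))
      stop("generate_subject: invalid class_sequence")
  }
  windows <- vector("list", n_windows)
  eye_logs <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    pf <- profiles[[vigilance_classes()[cls[i]]]]
    windows[[i]] <- generate_window(pf, mixing, fs, window_seconds,
                                    seed = child_seed(seed, 2L * i))
    eye_logs[[i]] <- generate_eye_log(pf, seed = child_seed(seed, 2L * i + 1L),
                                      window_seconds = window_seconds)
  }
  structure(list(windows = windows, eye_logs = eye_logs,
                 classes = factor(vigilance_classes()[cls],
                                  levels = vigilance_classes()),
                 seed = seed, mixing = mixing, subject_id = subject_id),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("synthetic_subject '", x$subject_id, "': ", length(x$windows),
      " windows (", paste(table(x$classes), collapse = "/"), " ",
      paste(levels(x$classes), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Fused DE feature tensor of a synthetic subject
#'
#' Runs every window through the feature pipeline (both band schemes,
#' fused), producing the samples x channels x 30 tensor the classifier
#' consumes, plus PERCLOS values and labels re-derived from the eye logs.
#'
#' @param subject a [generate_subject()] result.
#' @return list: `features` (n x 17 x 30 array), `perclos` (numeric),
#'   `labels` (factor from the eye logs), `classes` (the generating classes).
#' @export
subject_features <- function(subject) {
  stopifnot(inherits(subject, "synthetic_subject"))
  n <- length(subject$windows)
  w1 <- compute_de_fused(subject$windows[[1]])
  feats <- array(0, c(n, nrow(w1), ncol(w1)),
                 dimnames = list(NULL, rownames(w1), fused_band_names()))
  feats[1, , ] <- w1
  if (n > 1) for (i in 2:n) feats[i, , ] <- compute_de_fused(subject$windows[[i]])
  perclos <- vapply(subject$eye_logs, compute_perclos, numeric(1))
  list(features = feats, perclos = perclos,
       labels = label_from_perclos(perclos), classes = subject$classes)
}

# Per-class band signatures in DE units (log band power / 2), derived from
# the default state profiles. For the fused 30-band axis each 2-Hz band
# inherits its enclosing rhythm's weight; other band counts interpolate the
# rhythm pattern.
profile_band_patterns <- function(n_bands) {
  pf <- default_profiles()
  vapply(pf, function(p) {
    w <- p$band_weights / sum(p$band_weights)
    if (n_bands == 30) {
      idx25 <- rep(1:5, times = c(1L, 2L, 3L, 9L, 10L))
      0.5 * log(c(w, w[idx25]))
    } else {
      stats::approx(seq(0, 1, length.out = 5), 0.5 * log(w),
                    xout = seq(0, 1, length.out = n_bands))$y
    }
  }, numeric(n_bands))                       # n_bands x 3
}

# Orthonormal basis (d x 2) of the class-signature plane, lifted to the
# node x band feature space with equal loading on every node: class
# differences are coherent band-power patterns shared across channels.
signature_plane <- function(n_nodes, n_bands) {
  pat <- profile_band_patterns(n_bands)
  Pc <- scale(t(pat), scale = FALSE)         # 3 x n_bands, centered
  plane <- svd(Pc)$v[, 1:2, drop = FALSE]    # n_bands x 2, orthonormal
  ch <- rep(1 / sqrt(n_nodes), n_nodes)
  apply(plane, 2, function(b) as.vector(outer(ch, b)))   # d x 2
}

#' Fast class-conditional Gaussian DE dataset
#'
#' Bypasses raw-signal synthesis: draws node x band feature matrices from
#' three Gaussians with shared covariance whose means sit at the vertices of
#' an equilateral simplex with pairwise Mahalanobis distance `separation`.
#' The simplex lies in the plane spanned by the state profiles' band-power
#' signatures, shared across channels — class differences are coherent
#' spectral patterns (alpha/beta against delta/theta), as in vigilance EEG,
#' not arbitrary directions of feature space. Labels follow the same
#' geometric-block drift as [generate_subject()], so temporally ordered
#' splits remain meaningful.
#'
#' @param n_per_class samples per class (total 3x).
#' @param separation pairwise Mahalanobis distance between class means
#'   (>= 0; 0 makes the classes indistinguishable).
#' @param seed RNG seed.
#' @param n_nodes,n_bands feature geometry (defaults 17 x 30).
#' @param cov shared covariance: `NULL` (identity), a variance vector of
#'   length `n_nodes * n_bands`, or a full positive-definite matrix.
#' @param mean_block mean class-block length for the label sequence.
#' @return list: `features` (n x nodes x bands array), `labels` (factor),
#'   `means` (3 x d matrix of class means).
#' @export
generate_de_dataset <- function(n_per_class, separation, seed = 1L,
                                n_nodes = 17L, n_bands = 30L, cov = NULL,
                                mean_block = 30) {
  if (separation < 0) stop("generate_de_dataset: separation must be >= 0")
  d <- n_nodes * n_bands
  L <- NULL
  if (!is.null(cov)) {
    if (is.matrix(cov)) {
      L <- tryCatch(t(chol(cov)),
                    error = function(e)
                      stop("generate_de_dataset: covariance is not ",
                           "positive definite"))
    } else {
      if (any(cov <= 0))
        stop("generate_de_dataset: covariance is not positive definite")
      L <- sqrt(cov)                        # diagonal
    }
  }
  # Equilateral simplex with pairwise Mahalanobis side `separation` in the
  # profile-signature plane. With covariance Sigma, the plane's metric is
  # G = U' Sigma^-1 U; coordinates are placed so the Sigma^-1 distances
  # come out exactly.
  U <- signature_plane(n_nodes, n_bands)
  G <- if (is.null(L)) diag(2)
       else if (is.matrix(L)) crossprod(U, solve(tcrossprod(L), U))
       else crossprod(U / L^2, U)
  R <- chol(G)
  simplex <- rbind(c(0, 0),
                   c(separation, 0),
                   c(separation / 2, separation * sqrt(3) / 2))
  coords <- t(solve(R, t(simplex)))
  means <- coords %*% t(U)

  n <- 3L * n_per_class
  cls <- balanced_block_labels(n_per_class, child_seed(seed, 1L), mean_block)
  Z <- with_seed(child_seed(seed, 2L),
                 matrix(stats::rnorm(n * d), n, d))
  if (!is.null(L)) Z <- if (is.matrix(L)) Z %*% t(L) else scale_cols(Z, L)
  X <- Z + means[cls, , drop = FALSE]
  feats <- array(X, c(n, n_nodes, n_bands))
  list(features = feats,
       labels = factor(vigilance_classes()[cls],
                       levels = vigilance_classes()),
       means = means, separation = separation)
}

# Block-structured label sequence with exactly n_per_class of each class.
# Each block's class is drawn with probability proportional to the class's
# remaining quota, so the sequence stays mixed all the way to its tail
# instead of ending in one long run of whichever class is left over.
balanced_block_labels <- function(n_per_class, seed, mean_block = 30) {
  with_seed(seed, {
    quota <- rep(n_per_class, 3L)
    cls <- integer(0)
    prev <- 0L
    while (any(quota > 0)) {
      w <- quota
      if (sum(w > 0) > 1 && prev > 0) w[prev] <- 0  # prefer a class change
      cur <- sample.int(3L, 1, prob = pmax(w, 0) / sum(pmax(w, 0)))
      len <- min(1L + stats::rgeom(1, 1 / mean_block), quota[cur])
      cls <- c(cls, rep(cur, len))
      quota[cur] <- quota[cur] - len
      prev <- cur
    }
    cls
  })
}
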