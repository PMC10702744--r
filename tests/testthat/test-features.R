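# Feature pipeline: preprocessing, differential entropy, fusion, PERCLOS.

test_that("band schemes have the documented geometry", {
  s5 <- band_scheme("5band")
  expect_equal(unname(s5$bands[, 1]), c(1, 4, 8, 14, 31))
  expect_equal(unname(s5$bands[, 2]), c(3, 7, 13, 30, 50))
  s25 <- band_scheme("2Hz")
  expect_equal(nrow(s25$bands), 25)
  expect_equal(unname(s25$bands[1, ]), c(1, 3))
  expect_equal(unname(s25$bands[25, ]), c(49, 50))
  # non-overlapping, ascending
  expect_true(all(diff(s25$bands[, 1]) > 0))
  expect_true(all(s25$bands[-25, 2] <= s25$bands[-1, 1]))
})

test_that("preprocessing attenuates out-of-band power and preserves the passband", {
  fs_in <- 1000
  t <- (0:15999) / fs_in
  # DFT-magnitude oracle for tone power at frequency f
  tone_power <- function(v, f, fs) {
    n <- length(v); tt <- (0:(n - 1)) / fs
    (sum(v * cos(2 * pi * f * tt))^2 + sum(v * sin(2 * pi * f * tt))^2) * 2 / n^2
  }
  x60 <- rbind(sin(2 * pi * 60 * t))
  w <- preprocess_eeg(x60, fs_in = fs_in, fs_out = 200, band = c(1, 50),
                      channel_names = "FT7")
  expect_equal(ncol(w$signal), 3200)        # floor(16000 * 200/1000)
  trim <- 200                               # drop filter transients
  mid <- function(v) v[(trim + 1):(length(v) - trim)]
  p_in <- tone_power(mid(sin(2 * pi * 60 * seq(0, by = 1 / 200,
                                               length.out = 3200))), 60, 200)
  p_out <- tone_power(mid(w$signal[1, ]), 60, 200)
  expect_lt(10 * log10(p_out / p_in), -20)

  # zero in, zero out
  wz <- preprocess_eeg(matrix(0, 1, 16000), fs_in, 200, c(1, 50), "FT7")
  expect_equal(max(abs(wz$signal)), 0)

  # 10 Hz unit tone survives with amplitude within 5%
  x10 <- rbind(sin(2 * pi * 10 * t))
  w10 <- preprocess_eeg(x10, fs_in, 200, c(1, 50), "FT7")
  amp <- sqrt(2 * tone_power(mid(w10$signal[1, ]), 10, 200))
  expect_lt(abs(amp - 1), 0.05)

  expect_error(preprocess_eeg(matrix(NaN, 1, 100), 1000, 200), "non-finite")
  expect_error(preprocess_eeg(matrix(0, 1, 100), 100, 200), "exceeds")
})

test_that("differential entropy matches the Gaussian closed form", {
  # unit-variance noise band-limited to the analysed passband:
  # DE should be 1/2 log(2*pi*e) ~ 1.4189 nats
  de <- vapply(1:10, function(s) {
    w <- unit_band_noise_window(n_channels = 5, seed = s)
    mean(compute_de(w, full_passband_scheme()))
  }, numeric(1))
  expect_lt(abs(mean(de) - 0.5 * log(2 * pi * exp(1))), 0.05)
})

test_that("doubling the amplitude shifts every band's DE by log 2", {
  w <- unit_band_noise_window(n_channels = 3, seed = 7)
  w2 <- eeg_window(2 * w$signal, fs = w$fs, channel_names = w$channel_names)
  for (scheme in list(band_scheme("5band"), band_scheme("2Hz"))) {
    d1 <- compute_de(w, scheme)
    d2 <- compute_de(w2, scheme)
    expect_lt(max(abs((d2 - d1) - log(2))), 1e-9)
  }
})

test_that("DE output shapes follow the band scheme and values are finite", {
  w <- unit_band_noise_window(seed = 2)       # 17 channels
  d5 <- compute_de(w, band_scheme("5band"))
  d25 <- compute_de(w, band_scheme("2Hz"))
  expect_equal(dim(d5), c(17L, 5L))
  expect_equal(dim(d25), c(17L, 25L))
  expect_true(all(is.finite(d5)) && all(is.finite(d25)))
})

test_that("DE is invariant to constant offsets and monotone in band power", {
  w <- unit_band_noise_window(n_channels = 4, seed = 3)
  w_off <- eeg_window(w$signal + 17.3, fs = w$fs,
                      channel_names = w$channel_names)
  expect_equal(compute_de(w, band_scheme("5band")),
               compute_de(w_off, band_scheme("5band")), tolerance = 1e-9)

  # adding alpha-band power raises alpha DE, leaves other bands almost alone
  alpha <- with_seed_local(9, amdgcn:::band_noise(1600, 200, 8, 13))
  w_boost <- eeg_window(sweep(w$signal, 2, -1.5 * alpha), fs = w$fs,
                        channel_names = w$channel_names)
  d0 <- compute_de(w, band_scheme("5band"))
  d1 <- compute_de(w_boost, band_scheme("5band"))
  expect_true(all(d1[, "alpha"] > d0[, "alpha"]))
})

test_that("degenerate band power is clamped and flagged", {
  wz <- eeg_window(matrix(0, 2, 1600), fs = 200,
                   channel_names = c("O1", "O2"))
  d <- compute_de(wz, band_scheme("5band"))
  expect_true(all(is.finite(d)))
  expect_true(all(attr(d, "clamped")))
  expect_equal(unname(d[1, 1]), 0.5 * log(2 * pi * exp(1) * 1e-12))
})

test_that("feature fusion concatenates the two schemes in fixed order", {
  de5 <- matrix(1, 17, 5)
  de25 <- matrix(2, 17, 25)
  fused <- fuse_features(de5, de25)
  expect_equal(dim(fused), c(17L, 30L))
  expect_equal(unname(fused[1, ]), c(rep(1, 5), rep(2, 25)))
  expect_error(fuse_features(matrix(1, 16, 5), de25), "channel counts")
  expect_error(fuse_features(fused, de25), "5 bands")
  expect_error(fuse_features(de5, matrix(1, 17, 30)), "25 bands")
})

test_that("PERCLOS is (blink + close) / interval", {
  expect_equal(compute_perclos(eye_state_log(1, 5, 1, 1)), 0.25)
  expect_equal(compute_perclos(eye_state_log(0, 8, 0, 0)), 0)
  expect_equal(compute_perclos(eye_state_log(3, 1, 1, 3)), 0.75)
  expect_error(eye_state_log(1, 1, 1, 1), "sum to")
  expect_error(eye_state_log(-1, 8, 0, 1), "non-negative")
})

test_that("vigilance labels partition [0,1] with the documented boundaries", {
  expect_equal(as.character(label_from_perclos(0.25)), "Awake")
  expect_equal(as.character(label_from_perclos(0.35)), "Tired")
  expect_equal(as.character(label_from_perclos(0.70)), "Drowsy")
  expect_error(label_from_perclos(1.2), "\\[0, 1\\]")
  # exhaustive and mutually exclusive over a fine grid
  grid <- seq(0, 1, by = 1e-3)
  lab <- label_from_perclos(grid)
  expect_false(any(is.na(lab)))
  expect_equal(as.vector(table(lab)[c("Awake", "Tired", "Drowsy")]),
               c(sum(grid < 0.35), sum(grid >= 0.35 & grid < 0.7),
                 sum(grid >= 0.7)))
})
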