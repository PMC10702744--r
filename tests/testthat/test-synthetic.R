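# Synthetic EEG, eye logs, subjects, and the fast Gaussian DE path.

test_that("state profiles enforce their physiological invariants", {
  pf <- default_profiles()
  expect_named(pf, c("Awake", "Tired", "Drowsy"))
  for (p in pf) expect_s3_class(p, "state_profile")
  expect_error(state_profile("Awake", c(2, 2, 0.5, 0.5, 0.3), c(0.1, 0.3)),
               "alpha\\+beta")
  expect_error(state_profile("Drowsy", c(0.5, 0.5, 2, 2, 0.3), c(0.8, 0.9)),
               "delta\\+theta")
  expect_error(state_profile("Awake", c(1, 1, 2, 2, 1), c(0.2, 0.5)),
               "outside")
  expect_error(state_profile("Tired", c(1, 1, 1, 1, 1), c(0.6, 0.5)),
               "empty")
})

test_that("generated windows are seeded, band-structured and correctly shaped", {
  pf <- default_profiles()
  w1 <- generate_window(pf$Awake, seed = 42)
  w2 <- generate_window(pf$Awake, seed = 42)
  expect_identical(w1$signal, w2$signal)
  expect_equal(dim(w1$signal), c(17L, 1600L))
  expect_equal(w1$fs, 200)
  expect_error(generate_window(pf$Awake, fs = 80), "gamma")

  # a single-band profile with no noise floor concentrates its power there
  p_alpha <- state_profile("Awake", c(1e-6, 1e-6, 1, 1e-6, 1e-6),
                           c(0.1, 0.3), noise_floor = 0)
  wa <- generate_window(p_alpha, seed = 4)
  ps <- abs(stats::mvfft(t(wa$signal)))^2
  f <- (0:1599) * 200 / 1600
  f <- pmin(f, 200 - f)
  expect_gt(sum(ps[f >= 8 & f <= 13, ]) / sum(ps), 0.99)
})

test_that("drowsy windows carry more theta than alpha entropy", {
  pf <- default_profiles()
  hit <- vapply(1:60, function(i) {
    d <- compute_de(generate_window(pf$Drowsy, seed = 500 + i),
                    band_scheme("5band"))
    mean(d[, "theta"] > d[, "alpha"])
  }, numeric(1))
  expect_gte(mean(hit), 0.9)
})

test_that("band-power ratios track the profile weights within 10%", {
  pf <- default_profiles()
  bp <- vapply(1:120, function(i) {
    d <- compute_de(generate_window(pf$Tired, seed = 9000 + i),
                    band_scheme("5band"))
    colMeans(exp(2 * d) / (2 * pi * exp(1)))       # invert DE to band power
  }, numeric(5))
  measured <- rowMeans(bp) / sum(rowMeans(bp))
  target <- pf$Tired$band_weights / sum(pf$Tired$band_weights)
  expect_true(all(abs(measured / target - 1) < 0.1))
})

test_that("eye logs always label back to their generating class", {
  pf <- default_profiles()
  for (klass in vigilance_classes()) {
    labs <- vapply(1:300, function(i) {
      log <- generate_eye_log(pf[[klass]], seed = i)
      as.character(label_from_perclos(compute_perclos(log)))
    }, character(1))
    expect_true(all(labs == klass))
  }
  log <- generate_eye_log(pf$Tired, seed = 1)
  expect_equal(log$blink + log$fixation + log$saccade + log$close, 8)
  expect_identical(generate_eye_log(pf$Awake, seed = 5),
                   generate_eye_log(pf$Awake, seed = 5))
})

test_that("a synthetic subject feeds the full feature pipeline", {
  subj <- generate_subject(n_windows = 885, seed = 2)
  expect_length(subj$windows, 885)
  expect_identical(levels(subj$classes), vigilance_classes())
  # class drift comes in blocks, not i.i.d. labels
  runs <- rle(as.integer(subj$classes))
  expect_gt(mean(runs$lengths), 5)

  sf <- subject_features(subj)
  expect_equal(dim(sf$features), c(885L, 17L, 30L))
  expect_true(all(is.finite(sf$features)))
  # closed loop: labels derived from the eye logs match the generating class
  expect_equal(as.character(sf$labels), as.character(subj$classes))

  sp <- temporal_split(dim(sf$features)[1])
  expect_length(sp$train, 708)
  expect_length(sp$test, 177)

  # determinism: same seed, same subject (spot-check one window)
  subj2 <- generate_subject(n_windows = 5, seed = 2)
  expect_identical(subj2$windows[[3]]$signal, subj$windows[[3]]$signal)
})

test_that("the Gaussian DE shortcut is calibrated in Mahalanobis distance", {
  d <- generate_de_dataset(50, separation = 5, seed = 21)
  expect_equal(dim(d$features), c(150L, 17L, 30L))
  expect_equal(as.vector(table(d$labels)), rep(50L, 3))
  expect_equal(as.vector(dist(d$means)), rep(5, 3), tolerance = 1e-9)
  expect_identical(d$features,
                   generate_de_dataset(50, separation = 5, seed = 21)$features)

  # the known-parameter Gaussian classifier (the LDA oracle on the true
  # model) reaches its closed-form accuracy on held-out draws
  test <- generate_de_dataset(200, separation = 5, seed = 99)
  X <- matrix(test$features, 600)
  D2 <- vapply(1:3, function(k)
    rowSums((X - matrix(d$means[k, ], 600, ncol(X), byrow = TRUE))^2),
    numeric(600))
  acc <- mean(max.col(-D2) == as.integer(test$labels))
  expect_gte(acc, 0.97)

  # diagonal and full covariances keep the calibration; bad ones error
  dv <- generate_de_dataset(20, separation = 4, seed = 3,
                            n_nodes = 3, n_bands = 10,
                            cov = rep(2, 30))
  expect_equal(max(abs(as.vector(dist(dv$means %*% diag(1 / sqrt(rep(2, 30)))))
                       - 4)), 0, tolerance = 1e-9)
  expect_error(generate_de_dataset(10, 2, cov = rep(-1, 510)),
               "positive definite")
  expect_error(generate_de_dataset(10, 2, n_nodes = 2, n_bands = 2,
                                   cov = matrix(c(1, 2, 2, 1), 2, 2)[rep(1:2, 2), rep(1:2, 2)]),
               "positive definite")
  expect_error(generate_de_dataset(10, -1), "separation")
})

test_that("separation zero leaves classes indistinguishable", {
  d <- generate_de_dataset(100, separation = 0, seed = 13)
  sp <- temporal_split(300)
  acc <- centroid_trainer()(d$features, d$labels, sp)$test_accuracy
  expect_lt(abs(acc - 100 / 3), 15)    # chance level, small-sample noise
})
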