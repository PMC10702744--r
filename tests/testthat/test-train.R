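# Evaluation protocol: splits, cohort metrics, ablation switches, repeated
# cross-validation.

test_that("temporal split is a contiguous past/future partition", {
  sp <- temporal_split(885)
  expect_length(sp$train, 708)
  expect_length(sp$test, 177)
  expect_lt(max(sp$train), min(sp$test))
  expect_equal(sort(c(sp$train, sp$test)), 1:885)

  sp2 <- temporal_split(10)
  expect_equal(sp2$train, 1:8)
  expect_equal(sp2$test, 9:10)
  expect_error(temporal_split(1), "at least 2")
  expect_error(temporal_split(100, 0), "in \\(0, 1\\)")
  expect_error(temporal_split(100, 1), "in \\(0, 1\\)")
})

test_that("cohort metrics are mean accuracy and its standard deviation", {
  r <- evaluate_cohort(c(90, 90, 90))
  expect_equal(r$mean_accuracy, 90)
  expect_equal(r$individual_variation, 0)
  r2 <- evaluate_cohort(c(80, 100), config = list(tag = "x"), seeds = 5L)
  expect_equal(r2$mean_accuracy, 90)
  expect_equal(r2$individual_variation, sd(c(80, 100)))
  expect_equal(r2$individual_variation, 14.142, tolerance = 1e-4)
  expect_identical(r2$config, list(tag = "x"))
  expect_identical(r2$seeds, 5L)
  expect_error(evaluate_cohort(numeric(0)), "no subjects")
})

test_that("every ablation switch changes the forward pass", {
  x <- with_seed_local(20, array(rnorm(4 * 17 * 30), c(4, 17, 30)))
  base_cfg <- model_config()
  p_full <- predict(amdgcn_init(base_cfg), x)
  for (which in c("AM-CAM", "MD-GC", "AM-SAM", "SRGC", "EDGC", "SAGC")) {
    acfg <- ablate_config(base_cfg, which)
    p_abl <- predict(amdgcn_init(acfg), x)
    expect_gt(max(abs(p_abl - p_full)), 1e-9)
  }
  # feature ablations change the input geometry itself
  a5 <- ablate_config(base_cfg, "SEED-VIG-5band")
  expect_equal(a5$in_bands, 25L)
  expect_equal(attr(a5, "band_subset"), 6:30)
  a25 <- ablate_config(base_cfg, "SEED-VIG-2Hz")
  expect_equal(a25$in_bands, 5L)
  expect_equal(attr(a25, "band_subset"), 1:5)
  expect_error(ablate_config(model_config(
    branches = c(SR = FALSE, ED = FALSE, SA = TRUE)), "SAGC"),
    "every graph branch")
})

test_that("training recovers separable classes and respects the split", {
  d <- generate_de_dataset(60, separation = 6, seed = 31)
  sp <- temporal_split(180)
  cfg <- model_config(max_epochs = 40)
  fit <- train_subject(d$features, d$labels, cfg, sp)
  expect_gte(fit$test_accuracy, 80)
  expect_true(all(diff(fit$history$epoch) == 1))
  # loss decreases in nearly every step (tolerance for plateau jitter)
  expect_gte(mean(diff(fit$history$loss) < 5e-3), 0.9)
  expect_lt(tail(fit$history$loss, 1), 0.2 * fit$history$loss[1])
  # determinism: identical seeds give identical fits
  fit2 <- train_subject(d$features, d$labels, cfg, sp)
  expect_identical(fit$test_accuracy, fit2$test_accuracy)
  expect_identical(fit$model$params, fit2$model$params)
  expect_error(train_subject(d$features, d$labels, cfg,
                             list(train = 1:100, test = 90:180)),
               "overlap")
  expect_warning(train_subject(d$features[1:40, , ],
                               rep("Awake", 40),
                               model_config(max_epochs = 1),
                               list(train = 1:30, test = 31:40)),
                 "single-class")
})

test_that("accuracy recovers monotonically with class separation", {
  accs <- vapply(c(0, 1, 2, 4), function(s) {
    d <- generate_de_dataset(80, separation = s, seed = 41)
    centroid_trainer()(d$features, d$labels, temporal_split(240))$test_accuracy
  }, numeric(1))
  # allow one inversion at adjacent levels
  expect_lte(sum(diff(accs) < 0), 1)
  expect_gt(accs[4], accs[1])
})

test_that("repeated cross-validation is balanced, seeded and reported per repeat", {
  d <- generate_de_dataset(30, separation = 4, seed = 51)
  reps <- repeated_cv(d$features, d$labels, n_repeats = 10, n_folds = 5,
                      seed = 7, trainer = centroid_trainer())
  expect_length(reps, 10)
  for (r in reps) {
    folds <- r$seeds$folds
    expect_lte(diff(range(table(folds))), 1)
    expect_equal(length(folds), 90)
  }
  # designated test fold disjoint from training
  reps2 <- repeated_cv(d$features, d$labels, n_repeats = 10, n_folds = 5,
                       seed = 7, trainer = centroid_trainer())
  expect_identical(lapply(reps, unclass), lapply(reps2, unclass))
  expect_error(repeated_cv(d$features, d$labels, n_folds = 1,
                           trainer = centroid_trainer()), "2 folds")
  expect_error(repeated_cv(d$features[1:3, , , drop = FALSE], d$labels[1:3],
                           n_folds = 5, trainer = centroid_trainer()),
               "fewer samples")
})

test_that("run_ablation pairs a full and an ablated fit under one protocol", {
  d <- generate_de_dataset(40, separation = 6, seed = 61)
  cfg <- model_config(max_epochs = 8, patience = 3)
  res <- run_ablation(d$features, d$labels, "SAGC", cfg,
                      temporal_split(120))
  expect_s3_class(res$full, "eval_report")
  expect_s3_class(res$ablated, "eval_report")
  expect_false(res$ablated$config$branches[["SA"]])
  expect_identical(res$full$seeds, res$ablated$seeds)
  res5 <- run_ablation(d$features, d$labels, "SEED-VIG-2Hz", cfg,
                       temporal_split(120))
  expect_equal(dim(res5$fit_ablated$model$params[["enc.W"]]), c(128L, 5L))
})
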