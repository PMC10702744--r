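#' Temporally ordered train/test split
#'
#' Contiguous prefix/suffix split preserving sample order: training uses the
#' chronological past, testing the future. For 885 samples at the default
#' fraction this yields 708 training and 177 test samples.
#'
#' @param n_samples total sample count (>= 2).
#' @param train_fraction fraction of samples in the training prefix,
#'   strictly between 0 and 1 (default 0.8 = 708/885).
#' @return list with integer vectors `train` and `test`;
#'   `max(train) < min(test)`.
#' @export
temporal_split <- function(n_samples, train_fraction = 0.8) {
  if (n_samples < 2) stop("temporal_split: need at least 2 samples")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("temporal_split: train_fraction must be in (0, 1)")
  n_train <- round(n_samples * train_fraction)
  n_train <- min(max(n_train, 1L), n_samples - 1L)
  list(train = seq_len(n_train), test = seq(n_train + 1L, n_samples))
}

# Adam optimizer state and update.
adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    # L2 decay on weight matrices only, never on biases or batch-norm
    if (weight_decay > 0 && is.matrix(params[[nm]]))
      gr <- gr + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    mhat <- opt$m[[nm]] / b1t
    vhat <- opt$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# Coerce labels to integer class indices 1..3 in canonical class order.
as_class_index <- function(labels) {
  if (is.factor(labels)) {
    idx <- match(as.character(labels), vigilance_classes())
    if (any(is.na(idx))) idx <- as.integer(labels)
  } else if (is.character(labels)) {
    idx <- match(labels, vigilance_classes())
  } else idx <- as.integer(labels)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > 3))
    stop("labels must be class indices 1..3 or Awake/Tired/Drowsy")
  idx
}

#' Train the network on one subject
#'
#' Minibatch Adam on categorical cross-entropy, with early stopping when the
#' epoch training loss stops improving. Training never touches a test index
#' (asserted every epoch). Deterministic for a fixed `config$seed`.
#'
#' @param features samples x nodes x bands array.
#' @param labels vigilance labels (factor, class names, or indices 1..3).
#' @param config a [model_config()]; `in_bands` must match `dim(features)[3]`.
#' @param split a [temporal_split()]-style list with `train`/`test`
#'   index vectors; `test` may be empty.
#' @param montage montage for the fixed spatial adjacency.
#' @param verbose print per-epoch progress.
#' @return list of class `amdgcn_fit`: trained `model`, `history` data frame
#'   (epoch, loss, train_accuracy), `split`, `test_accuracy` (percent, `NA`
#'   when `split$test` is empty) and `test_predicted`.
#' @export
train_subject <- function(features, labels, config = model_config(),
                          split = temporal_split(dim(features)[1]),
                          montage = default_montage(), verbose = FALSE) {
  stopifnot(length(dim(features)) == 3)
  y <- as_class_index(labels)
  stopifnot(length(y) == dim(features)[1])
  if (length(unique(y[split$train])) < 2)
    warning("train_subject: single-class training labels; ",
            "fitting proceeds but the task is degenerate")
  if (length(intersect(split$train, split$test)) > 0)
    stop("train_subject: train/test index sets overlap")

  model <- amdgcn_init(config, montage)
  opt <- adam_init(model$params)
  rng <- local_rng(child_seed(config$seed, 7919L))
  tr <- split$train
  n_tr <- length(tr)
  bs <- min(config$batch_size, n_tr)
  hist_loss <- numeric(0)
  hist_acc <- numeric(0)
  best <- Inf
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- rng(function() sample.int(n_tr))
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq(1, n_tr, by = bs)) {
      idx <- tr[ord[start:min(start + bs - 1, n_tr)]]
      stopifnot(all(idx %in% tr))               # leakage guard
      xb <- features[idx, , , drop = FALSE]
      yb <- y[idx]
      lg <- amdgcn_loss_grad(model, xb, yb)
      model$state <- lg$state
      st <- adam_step(model$params, lg$grads, opt, config$lr,
                      config$weight_decay)
      model$params <- st$params
      opt <- st$opt
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(lg$probs) == yb)
    }
    ep_loss <- ep_loss / n_tr
    hist_loss <- c(hist_loss, ep_loss)
    hist_acc <- c(hist_acc, 100 * ep_correct / n_tr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.1f%%",
                      epoch, ep_loss, hist_acc[epoch]))
    if (ep_loss < best - config$min_delta) {
      best <- ep_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  test_acc <- NA_real_
  test_pred <- NULL
  if (length(split$test) > 0) {
    pr <- predict(model, features[split$test, , , drop = FALSE])
    test_pred <- max.col(pr)
    test_acc <- 100 * mean(test_pred == y[split$test])
  }
  structure(list(model = model,
                 history = data.frame(epoch = seq_along(hist_loss),
                                      loss = hist_loss,
                                      train_accuracy = hist_acc),
                 split = split, test_accuracy = test_acc,
                 test_predicted = test_pred),
            class = "amdgcn_fit")
}

#' @export
print.amdgcn_fit <- function(x, ...) {
  cat("amdgcn_fit: ", nrow(x$history), " epochs, final loss ",
      signif(utils::tail(x$history$loss, 1), 4),
      if (!is.na(x$test_accuracy))
        paste0(", test accuracy ", round(x$test_accuracy, 2), "%"),
      "\n", sep = "")
  invisible(x)
}

#' Cohort evaluation report
#'
#' Aggregates per-subject accuracies into the two cohort metrics: mean
#' accuracy and individual variation. Individual variation is the sample
#' standard deviation of the per-subject accuracies, in percentage points —
#' the spread of the detector's performance across people.
#'
#' @param per_subject_accuracy numeric vector of per-subject accuracies in
#'   percent (>= 1 subject).
#' @param config optional configuration snapshot echoed into the report.
#' @param seeds optional seed vector echoed into the report.
#' @return object of class `eval_report`: `per_subject_accuracy`,
#'   `mean_accuracy`, `individual_variation` (0 for a single subject),
#'   `config`, `seeds`.
#' @export
evaluate_cohort <- function(per_subject_accuracy, config = NULL, seeds = NULL) {
  acc <- as.numeric(per_subject_accuracy)
  if (length(acc) < 1) stop("evaluate_cohort: no subjects")
  if (any(!is.finite(acc))) stop("evaluate_cohort: non-finite accuracy")
  iv <- if (length(acc) > 1) stats::sd(acc) else 0
  structure(list(per_subject_accuracy = acc,
                 mean_accuracy = mean(acc),
                 individual_variation = iv,
                 config = config, seeds = seeds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: ", length(x$per_subject_accuracy), " subject(s), mean ",
      round(x$mean_accuracy, 2), "%, individual variation ",
      round(x$individual_variation, 2), "\n", sep = "")
  invisible(x)
}

ablation_switches <- function() {
  c("SEED-VIG-5band", "SEED-VIG-2Hz", "AM-CAM", "MD-GC", "AM-SAM",
    "SRGC", "EDGC", "SAGC")
}

#' Apply an ablation switch to a configuration
#'
#' Returns the configuration with one named functional module or graph
#' branch removed: `"SEED-VIG-5band"` / `"SEED-VIG-2Hz"` drop that feature
#' block from the input band axis (the returned config carries attribute
#' `"band_subset"` with the column indices to keep); `"AM-CAM"` / `"AM-SAM"`
#' replace the gate with all-ones; `"MD-GC"` replaces the graph layer with
#' the identity; `"SRGC"` / `"EDGC"` / `"SAGC"` disable one branch (its
#' contribution becomes exactly zero).
#'
#' @param config a [model_config()].
#' @param which one of [ablation_switches()].
#' @return modified `model_config` (possibly with a `"band_subset"`
#'   attribute).
#' @export
ablate_config <- function(config, which) {
  which <- match.arg(which, ablation_switches())
  cfg <- unclass(config)
  subset <- NULL
  if (which == "SEED-VIG-5band") {        # remove the 5-band block
    if (cfg$in_bands != 30)
      stop("ablate_config: feature ablations need the fused 30-band input")
    subset <- 6:30
    cfg$in_bands <- 25L
  } else if (which == "SEED-VIG-2Hz") {   # remove the 25-band block
    if (cfg$in_bands != 30)
      stop("ablate_config: feature ablations need the fused 30-band input")
    subset <- 1:5
    cfg$in_bands <- 5L
  } else if (which == "AM-CAM") cfg$use_cam <- FALSE
  else if (which == "AM-SAM") cfg$use_sam <- FALSE
  else if (which == "MD-GC") cfg$use_mdgc <- FALSE
  else {
    br <- c("SRGC" = "SR", "EDGC" = "ED", "SAGC" = "SA")[[which]]
    cfg$branches[[br]] <- FALSE
    if (cfg$use_mdgc && !any(cfg$branches))
      stop("ablate_config: cannot disable every graph branch")
  }
  out <- structure(cfg, class = "model_config")
  validate_model_config(out)
  attr(out, "band_subset") <- subset
  out
}

#' Run one ablation: full versus ablated model under identical protocol
#'
#' Trains the full configuration and the ablated configuration with the same
#' seed, split and data, and returns the paired evaluation reports.
#'
#' @param features samples x nodes x 30 array (fused bands).
#' @param labels vigilance labels.
#' @param which one of [ablation_switches()].
#' @param config base configuration (the "full" model).
#' @param split train/test split used for both runs.
#' @param montage montage for the spatial adjacency.
#' @return list with `full` and `ablated` [evaluate_cohort()] reports (one
#'   subject each) and the two fits.
#' @export
run_ablation <- function(features, labels, which, config = model_config(),
                         split = temporal_split(dim(features)[1]),
                         montage = default_montage()) {
  acfg <- ablate_config(config, which)
  afeat <- features
  subset <- attr(acfg, "band_subset")
  if (!is.null(subset)) afeat <- features[, , subset, drop = FALSE]
  fit_full <- train_subject(features, labels, config, split, montage)
  fit_abl <- train_subject(afeat, labels, acfg, split, montage)
  list(full = evaluate_cohort(fit_full$test_accuracy, config = config,
                              seeds = config$seed),
       ablated = evaluate_cohort(fit_abl$test_accuracy, config = acfg,
                                 seeds = acfg$seed),
       fit_full = fit_full, fit_ablated = fit_abl, which = which)
}

#' Repeated k-fold cross-validation protocol
#'
#' A supplemental protocol, distinct from the temporal split: per repeat,
#' samples are randomly partitioned into `n_folds` balanced folds (sizes
#' differ by at most one); one designated fold is held out for testing and
#' the rest train. Identical seeds give identical fold assignments and
#' reports.
#'
#' @param features samples x nodes x bands array.
#' @param labels vigilance labels.
#' @param n_repeats number of repeats (default 10).
#' @param n_folds number of folds (default 5, >= 2).
#' @param seed base seed; repeat r uses a child seed derived from it.
#' @param trainer function(features, labels, split) returning a list with at
#'   least `test_accuracy` (percent). Defaults to the network via
#'   [train_subject()]; pass [centroid_trainer()] for a fast baseline.
#' @param config configuration forwarded to the default trainer.
#' @return list of `n_repeats` [evaluate_cohort()] reports; each carries the
#'   fold assignment as `$seeds$folds`.
#' @export
repeated_cv <- function(features, labels, n_repeats = 10L, n_folds = 5L,
                        seed = 1L, trainer = NULL,
                        config = model_config()) {
  n <- dim(features)[1]
  if (n_folds < 2) stop("repeated_cv: need at least 2 folds")
  if (n < n_folds) stop("repeated_cv: fewer samples than folds")
  if (is.null(trainer))
    trainer <- function(features, labels, split)
      train_subject(features, labels, config, split)
  reports <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- child_seed(seed, r)
    folds <- with_seed(rs, sample(rep_len(seq_len(n_folds), n)))
    test_fold <- 1L                       # one designated test fold
    split <- list(train = which(folds != test_fold),
                  test = which(folds == test_fold))
    fit <- trainer(features, labels, split)
    rep_ <- evaluate_cohort(fit$test_accuracy,
                            config = list(protocol = "cv5",
                                          n_folds = n_folds, repeat_ = r),
                            seeds = list(base = seed, repeat_seed = rs,
                                         folds = folds))
    reports[[r]] <- rep_
  }
  reports
}

#' Nearest-centroid baseline trainer
#'
#' A deterministic, training-free classifier over flattened features: each
#' class is represented by its training-set mean; a sample is assigned to
#' the nearest centroid. Useful as a fast sanity baseline and as the default
#' lightweight trainer in protocol tests.
#'
#' @return A trainer `function(features, labels, split)` compatible with
#'   [repeated_cv()].
#' @export
centroid_trainer <- function() {
  function(features, labels, split) {
    y <- as_class_index(labels)
    X <- matrix(features, dim(features)[1])
    tr <- split$train
    classes <- sort(unique(y[tr]))
    cent <- t(vapply(classes, function(k)
      colMeans(X[tr[y[tr] == k], , drop = FALSE]), numeric(ncol(X))))
    d <- vapply(seq_len(nrow(cent)), function(i)
      rowSums((X[split$test, , drop = FALSE] -
                 matrix(cent[i, ], length(split$test), ncol(X),
                        byrow = TRUE))^2), numeric(length(split$test)))
    pred <- classes[max.col(-as.matrix(d))]
    list(test_accuracy = 100 * mean(pred == y[split$test]),
         test_predicted = pred)
  }
}
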