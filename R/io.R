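# Portable on-disk formats. Arrays travel as plain CSV plus a JSON sidecar
# holding geometry and provenance, so every artifact is text and
# platform-independent.

#' Write a DE feature tensor (CSV + JSON sidecar)
#'
#' The samples x channels x bands array is flattened to a CSV with one row
#' per (sample, channel) and one column per band; `<path>.json` records the
#' dimensions, channel names, band names, window seconds and provenance.
#'
#' @param features samples x channels x bands array.
#' @param path output CSV path (sidecar written next to it).
#' @param channel_names,band_names axis labels (defaults: canonical 17,
#'   fused 30).
#' @param window_seconds analysis window length recorded in the sidecar.
#' @param provenance free-form provenance string.
#' @return `path`, invisibly.
#' @export
write_feature_tensor <- function(features, path,
                                 channel_names = canonical_channels(),
                                 band_names = fused_band_names(),
                                 window_seconds = 8,
                                 provenance = "amdgcn") {
  stopifnot(length(dim(features)) == 3)
  d <- dim(features)
  flat <- matrix(aperm(features, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(sample = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(channel_names[seq_len(d[2])], d[1]),
                   flat, check.names = FALSE)
  names(df)[-(1:2)] <- band_names[seq_len(d[3])]
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(format = "amdgcn-feature-tensor", version = 1L,
                  dim = d, channel_names = channel_names[seq_len(d[2])],
                  band_names = band_names[seq_len(d[3])],
                  window_seconds = window_seconds, provenance = provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature tensor written by [write_feature_tensor()]
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return samples x channels x bands array with dimnames from the sidecar.
#' @export
read_feature_tensor <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "amdgcn-feature-tensor"))
    stop("read_feature_tensor: unrecognized sidecar format")
  df <- utils::read.csv(path, check.names = FALSE)
  d <- side$dim
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  out <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  dimnames(out) <- list(NULL, side$channel_names, side$band_names)
  attr(out, "window_seconds") <- side$window_seconds
  attr(out, "provenance") <- side$provenance
  out
}

#' Write eye-state logs to CSV
#'
#' Columns: window_index, blink, fixation, saccade, close (seconds).
#'
#' @param logs list of [eye_state_log()] objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_eye_logs <- function(logs, path) {
  df <- data.frame(
    window_index = seq_along(logs),
    blink = vapply(logs, `[[`, numeric(1), "blink"),
    fixation = vapply(logs, `[[`, numeric(1), "fixation"),
    saccade = vapply(logs, `[[`, numeric(1), "saccade"),
    close = vapply(logs, `[[`, numeric(1), "close"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read eye-state logs from CSV
#'
#' Expects columns window_index, blink, fixation, saccade, close; rows are
#' validated through [eye_state_log()].
#'
#' @param path CSV file.
#' @param window_seconds window length each row must account for.
#' @return list of `eye_state_log` objects, ordered by window_index.
#' @export
read_eye_logs <- function(path, window_seconds = 8) {
  df <- utils::read.csv(path)
  need <- c("window_index", "blink", "fixation", "saccade", "close")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_eye_logs: missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$window_index), ]
  lapply(seq_len(nrow(df)), function(i)
    eye_state_log(df$blink[i], df$fixation[i], df$saccade[i], df$close[i],
                  window_seconds = window_seconds))
}

config_defaults <- function() {
  formals(model_config)[c("in_bands", "n_nodes", "C", "r_c", "r_s",
                          "n_blocks", "n_classes", "lr", "batch_size",
                          "max_epochs", "patience", "min_delta", "seed")]
}

#' Load a model configuration from YAML or JSON
#'
#' Absent keys take the documented defaults; unknown keys are an error (no
#' silent ignoring). The file may carry `schema_version` (currently 1),
#' `train_fraction` for the split, and a `montage` edge list.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return list with `config` ([model_config()]), `train_fraction`, and
#'   `montage` (a [montage_graph()], default montage when absent).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(formals(model_config)), "schema_version",
             "train_fraction", "montage")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$schema_version) && raw$schema_version != 1L)
    stop("load_config: unsupported schema_version ", raw$schema_version)
  cfg_keys <- intersect(names(raw), names(formals(model_config)))
  args <- raw[cfg_keys]
  if (!is.null(args$branches)) args$branches <- unlist(args$branches)
  cfg <- do.call(model_config, args)
  montage <- if (!is.null(raw$montage))
    montage_graph(do.call(rbind, lapply(raw$montage, unlist)))
  else default_montage()
  list(config = cfg,
       train_fraction = if (is.null(raw$train_fraction)) 0.8
                        else raw$train_fraction,
       montage = montage)
}

#' Save a model configuration as YAML
#'
#' Writes every field of the configuration plus `schema_version`, so
#' `load_config(save_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config a [model_config()].
#' @param path output YAML path.
#' @param train_fraction optional split fraction to record.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, train_fraction = NULL) {
  out <- unclass(config)
  out$branches <- as.list(out$branches)
  out <- c(list(schema_version = 1L), out)
  if (!is.null(train_fraction)) out$train_fraction <- train_fraction
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#' @param report an [evaluate_cohort()] report.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  r <- unclass(report)
  if (!is.null(r$config)) {
    r$config <- unclass(r$config)
    if (!is.null(r$config$branches))
      r$config$branches <- as.list(r$config$branches)
  }
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Save / load a model checkpoint (portable JSON)
#'
#' The checkpoint carries a format version, the full configuration, the
#' montage edge list, every parameter matrix, and the batch-norm running
#' state; loading reconstructs a model whose predictions agree to full
#' printed floating-point precision (JSON carries 15 significant digits).
#'
#' @param model an `amdgcn_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- unclass(model$config)
  cfg$branches <- as.list(cfg$branches)   # keep names through JSON
  ck <- list(format = "amdgcn-checkpoint", version = 1L,
             config = cfg,
             montage_edges = model$montage$edges,
             montage_channels = model$montage$channel_names,
             params = lapply(model$params, function(x)
               if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
               else list(dim = length(x), data = as.vector(x))),
             state = model$state)
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the reconstructed `amdgcn_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$format, "amdgcn-checkpoint"))
    stop("load_checkpoint: not an amdgcn checkpoint")
  cfg <- ck$config
  cfg$branches <- unlist(cfg$branches)
  config <- do.call(model_config,
                    cfg[intersect(names(formals(model_config)), names(cfg))])
  montage <- montage_graph(ck$montage_edges, ck$montage_channels)
  model <- amdgcn_init(config, montage)
  for (nm in names(model$params)) {
    pk <- ck$params[[nm]]
    model$params[[nm]] <- if (length(pk$dim) == 2)
      matrix(pk$data, pk$dim[1], pk$dim[2]) else as.numeric(pk$data)
  }
  for (nm in names(model$state))
    model$state[[nm]] <- as.numeric(ck$state[[nm]])
  model
}

#' Read a subject dataset in the package's portable layout
#'
#' The layout is a directory with `manifest.json` naming the parts:
#' `features` (a [write_feature_tensor()] CSV of either 885 x 17 x 5,
#' 885 x 17 x 25 or the fused 885 x 17 x 30) and `perclos` (CSV with columns
#' window_index, perclos). Raw MATLAB containers are not parsed directly;
#' convert them to this layout first (any array tool can produce the CSV;
#' the sidecar documents the axes). A `key_map` entry in the manifest can
#' rename non-standard part names.
#'
#' @param path dataset directory.
#' @param n_samples expected sample count; `NULL` (default) accepts any.
#'   Pass 885 to enforce the standard per-subject geometry.
#' @param n_channels expected channel count (default 17).
#' @return list: `features` array, `perclos` numeric vector, `labels` factor.
#' @export
read_subject_dataset <- function(path, n_samples = NULL, n_channels = 17L) {
  if (grepl("\\.mat$", path))
    stop("read_subject_dataset: MATLAB containers are not parsed directly; ",
         "convert to the portable layout (see ?read_subject_dataset): a ",
         "directory with manifest.json, a feature-tensor CSV + JSON ",
         "sidecar, and a perclos CSV")
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("read_subject_dataset: no manifest.json in ", path,
         "; found: ", paste(list.files(path), collapse = ", "))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  km <- mf$key_map
  part <- function(role) {
    nm <- if (!is.null(km) && !is.null(km[[role]])) km[[role]] else mf[[role]]
    if (is.null(nm))
      stop("read_subject_dataset: manifest lacks a '", role, "' entry; ",
           "keys present: ", paste(names(mf), collapse = ", "))
    file.path(path, nm)
  }
  feats <- read_feature_tensor(part("features"))
  d <- dim(feats)
  if ((!is.null(n_samples) && d[1] != n_samples) || d[2] != n_channels ||
      !(d[3] %in% c(5L, 25L, 30L)))
    stop("read_subject_dataset: feature tensor is ", paste(d, collapse = " x "),
         "; expected ", if (is.null(n_samples)) "n" else n_samples, " x ",
         n_channels, " x (5|25|30)")
  pdf <- utils::read.csv(part("perclos"))
  if (!all(c("window_index", "perclos") %in% names(pdf)))
    stop("read_subject_dataset: perclos CSV needs window_index and perclos")
  pdf <- pdf[order(pdf$window_index), ]
  if (any(pdf$perclos < 0 | pdf$perclos > 1))
    stop("read_subject_dataset: perclos values outside [0, 1]")
  if (nrow(pdf) != d[1])
    stop("read_subject_dataset: ", nrow(pdf), " perclos rows for ", d[1],
         " samples")
  list(features = feats, perclos = pdf$perclos,
       labels = label_from_perclos(pdf$perclos))
}

#' Write a subject dataset in the portable layout
#'
#' Inverse of [read_subject_dataset()]; used to stage converted data and in
#' round-trip tests.
#'
#' @param features samples x channels x bands array.
#' @param perclos numeric vector, one value per sample.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(features, perclos, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(features)
  bn <- if (d[3] == 30) fused_band_names()
        else if (d[3] == 5) rownames(band_scheme("5band")$bands)
        else rownames(band_scheme("2Hz")$bands)
  write_feature_tensor(features, file.path(dir, "features.csv"),
                       band_names = bn)
  utils::write.csv(data.frame(window_index = seq_along(perclos),
                              perclos = perclos),
                   file.path(dir, "perclos.csv"), row.names = FALSE)
  jsonlite::write_json(list(format = "amdgcn-subject", version = 1L,
                            features = "features.csv",
                            perclos = "perclos.csv"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
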