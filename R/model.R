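#' Model configuration
#'
#' All hyperparameters of the attention-gated multi-branch graph network.
#' Defaults are the study settings: fused 30-band input, encoder width 128,
#' channel-attention reduction 16, spatial-attention reduction 4, attention
#' head size `C %/% 8`, two (channel gate, graph layer, spatial gate) blocks,
#' three vigilance classes.
#'
#' @param in_bands input band count per node (30 fused; 5 or 25 under the
#'   feature ablations).
#' @param n_nodes electrode count (17 in production; any value >= 2 for
#'   miniature test models).
#' @param C encoder width / feature channels; must be divisible by `r_c` and
#'   at least 8.
#' @param r_c channel-attention reduction ratio.
#' @param r_s spatial-attention reduction factor; the gate MLP hidden width
#'   is `ceiling(2 * n_nodes / r_s)`.
#' @param n_blocks number of attention/graph blocks.
#' @param n_classes number of output classes (fixed at 3).
#' @param branches named logical vector: which graph branches (SR, ED, SA)
#'   are active.
#' @param use_cam,use_mdgc,use_sam module ablation switches; a disabled gate
#'   becomes the all-ones gate, a disabled graph layer becomes the identity.
#' @param sa_scale `"sqrt"` (divide attention logits by sqrt(D)) or
#'   `"linear"` (divide by D).
#' @param sr_self_loops add self-loops to the spatial adjacency before
#'   normalization.
#' @param mdgc_activation `"sigmoid"` (default) or `"relu"` after the fused
#'   graph layer.
#' @param bn_mode `"batch"` (batch statistics while training, running
#'   statistics in evaluation) or `"identity"` (no normalization; used by
#'   oracle equivalence tests).
#' @param lr,batch_size,max_epochs Adam learning rate, minibatch size and
#'   epoch cap.
#' @param weight_decay optional L2 penalty applied to weight matrices (not
#'   biases or batch-norm parameters) during training; 0 by default.
#' @param patience,min_delta early stopping: stop when the epoch training
#'   loss has not improved by `min_delta` for `patience` epochs.
#' @param seed RNG seed for parameter initialization and batch shuffling.
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(in_bands = 30L, n_nodes = 17L, C = 128L,
                         r_c = 16L, r_s = 4L, n_blocks = 2L, n_classes = 3L,
                         branches = c(SR = TRUE, ED = TRUE, SA = TRUE),
                         use_cam = TRUE, use_mdgc = TRUE, use_sam = TRUE,
                         sa_scale = c("sqrt", "linear"),
                         sr_self_loops = FALSE,
                         mdgc_activation = c("sigmoid", "relu"),
                         bn_mode = c("batch", "identity"),
                         lr = 1e-3, batch_size = 64L, max_epochs = 200L,
                         weight_decay = 0,
                         patience = 8L, min_delta = 1e-4, seed = 1L) {
  cfg <- list(in_bands = as.integer(in_bands), n_nodes = as.integer(n_nodes),
              C = as.integer(C), r_c = as.integer(r_c), r_s = as.integer(r_s),
              n_blocks = as.integer(n_blocks), n_classes = as.integer(n_classes),
              branches = branches,
              use_cam = isTRUE(use_cam), use_mdgc = isTRUE(use_mdgc),
              use_sam = isTRUE(use_sam),
              sa_scale = match.arg(sa_scale),
              sr_self_loops = isTRUE(sr_self_loops),
              mdgc_activation = match.arg(mdgc_activation),
              bn_mode = match.arg(bn_mode),
              lr = lr, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              weight_decay = weight_decay,
              patience = as.integer(patience), min_delta = min_delta,
              seed = as.integer(seed))
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

validate_model_config <- function(cfg) {
  if (cfg$C %% cfg$r_c != 0)
    stop("model_config: C (", cfg$C, ") must be divisible by r_c (", cfg$r_c, ")")
  if (cfg$C %/% 8L < 1)
    stop("model_config: attention head size floor(C/8) must be >= 1 (C = ",
         cfg$C, ")")
  if (cfg$n_classes != 3L)
    stop("model_config: n_classes is fixed at 3 (Awake/Tired/Drowsy), got ",
         cfg$n_classes)
  req <- c("SR", "ED", "SA")
  if (!all(req %in% names(cfg$branches)))
    stop("model_config: branches must be a named logical vector over ",
         paste(req, collapse = ", "))
  if (cfg$use_mdgc && !any(cfg$branches[req]))
    stop("model_config: all graph branches disabled while MD-GC is active")
  if (cfg$n_nodes < 2) stop("model_config: need at least 2 nodes")
  invisible(cfg)
}

#' @export
print.model_config <- function(x, ...) {
  on <- names(x$branches)[as.logical(x$branches)]
  cat("model_config: ", x$in_bands, " bands -> C=", x$C, ", ",
      x$n_blocks, " block(s), branches {", paste(on, collapse = ","),
      "}, gates CAM=", x$use_cam, " SAM=", x$use_sam, "\n", sep = "")
  invisible(x)
}

cam_hidden <- function(cfg) cfg$C %/% cfg$r_c
sam_hidden <- function(cfg) as.integer(ceiling(2 * cfg$n_nodes / cfg$r_s))

#' Initialize the network
#'
#' Builds the fixed spatial adjacency from the montage and draws all
#' learnable parameters with seeded uniform fan-in (Kaiming-style) scaling.
#' Every parameter is created regardless of ablation switches, so switching
#' a branch or module off changes the forward computation only, never the
#' initialization draw.
#'
#' @param config a [model_config()].
#' @param montage a [montage_graph()] with `config$n_nodes` channels.
#' @return An object of class `amdgcn_model`: list with `config`, `A_sr`,
#'   `params` (flat named list), and `state` (batch-norm running statistics).
#' @export
amdgcn_init <- function(config, montage = default_montage()) {
  stopifnot(inherits(config, "model_config"))
  if (length(montage$channel_names) != config$n_nodes)
    stop("amdgcn_init: montage has ", length(montage$channel_names),
         " channels but config$n_nodes = ", config$n_nodes)
  A_sr <- build_spatial_adjacency(montage, self_loops = config$sr_self_loops)
  rng <- local_rng(config$seed)
  C <- config$C; V <- config$n_nodes; D <- C %/% 8L
  hc <- cam_hidden(config); hs <- sam_hidden(config)
  p <- list()
  p[["enc.W"]] <- init_mat(C, config$in_bands, rng)
  p[["enc.b"]] <- numeric(C)
  state <- list()
  for (k in seq_len(config$n_blocks)) {
    pre <- paste0("b", k, ".")
    p[[paste0(pre, "cam.W0")]] <- init_mat(hc, C, rng)
    p[[paste0(pre, "cam.b0")]] <- numeric(hc)
    p[[paste0(pre, "cam.W1")]] <- init_mat(C, hc, rng)
    p[[paste0(pre, "cam.b1")]] <- numeric(C)
    p[[paste0(pre, "W_SR")]] <- init_mat(C, C, rng)
    p[[paste0(pre, "W_ED")]] <- init_mat(C, C, rng)
    p[[paste0(pre, "W_SA")]] <- init_mat(C, C, rng)
    p[[paste0(pre, "W_Q")]]  <- init_mat(C, D, rng, fan_in = C)
    p[[paste0(pre, "W_K")]]  <- init_mat(C, D, rng, fan_in = C)
    p[[paste0(pre, "bn.gamma")]] <- rep(1, C)
    p[[paste0(pre, "bn.beta")]]  <- numeric(C)
    state[[paste0(pre, "bn.mean")]] <- numeric(C)
    state[[paste0(pre, "bn.var")]]  <- rep(1, C)
    p[[paste0(pre, "sam.W0")]] <- init_mat(hs, 2L * V, rng)
    p[[paste0(pre, "sam.b0")]] <- numeric(hs)
    p[[paste0(pre, "sam.W1")]] <- init_mat(V, hs, rng)
    p[[paste0(pre, "sam.b1")]] <- numeric(V)
  }
  p[["head.W"]] <- init_mat(config$n_classes, V * C, rng)
  p[["head.b"]] <- numeric(config$n_classes)
  structure(list(config = config, montage = montage,
                 A_sr = A_sr$weights, params = p, state = state),
            class = "amdgcn_model")
}

#' @export
print.amdgcn_model <- function(x, ...) {
  cat("amdgcn_model: ", x$config$n_nodes, " nodes, C=", x$config$C, ", ",
      x$config$n_blocks, " block(s), ", param_count(x), " parameters\n",
      sep = "")
  invisible(x)
}

#' Total learnable parameter count
#' @param model an `amdgcn_model`.
#' @return integer.
#' @export
param_count <- function(model) sum(vapply(model$params, length, 1L))

# Coerce input samples to a B x V x in_bands array.
as_sample_array <- function(samples, V, in_bands) {
  if (is.matrix(samples)) samples <- array(samples, c(1L, dim(samples)))
  if (length(dim(samples)) != 3L)
    stop("samples must be a V x bands matrix or a B x V x bands array")
  if (dim(samples)[2] != V || dim(samples)[3] != in_bands)
    stop("samples have shape ", dim(samples)[2], " x ", dim(samples)[3],
         " per item; model expects ", V, " x ", in_bands)
  samples
}


#' Class probabilities for a batch of samples
#'
#' Runs the network in evaluation mode (running batch-norm statistics,
#' deterministic).
#'
#' @param object an `amdgcn_model`.
#' @param samples B x V x bands array or single V x bands matrix.
#' @param ... unused.
#' @return B x 3 matrix of class probabilities (columns Awake, Tired,
#'   Drowsy).
#' @export
predict.amdgcn_model <- function(object, samples, ...) {
  out <- amdgcn_forward(object, samples, mode = "eval")$probs
  colnames(out) <- vigilance_classes()
  out
}

#' Export attention maps and adjacency matrices
#'
#' Runs the model in evaluation mode over the given samples and returns, per
#' block, the channel gate, the spatial gate, the fixed spatial adjacency
#' (shared by all samples) and the data-dependent Euclidean and
#' self-attention adjacencies (one per sample). When `dir` is given, each
#' map is also written as a dense CSV with channel-name headers.
#'
#' @param model an `amdgcn_model`.
#' @param samples B x V x bands array.
#' @param dir optional output directory for CSV export.
#' @return Named list of maps: `blockK.M_c` (B x C), `blockK.M_s` (B x V),
#'   `blockK.A_SR` (V x V), `blockK.A_ED` / `blockK.A_SA` (lists of V x V,
#'   one per sample).
#' @export
export_attention_and_adjacency <- function(model, samples, dir = NULL) {
  out <- amdgcn_forward(model, samples, mode = "eval", keep_maps = TRUE)
  maps <- out$maps
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ch <- model$montage$channel_names
    for (nm in names(maps)) {
      m <- maps[[nm]]
      if (is.null(m)) next
      if (is.list(m)) {
        for (b in seq_along(m))
          write_adjacency_csv(m[[b]], file.path(dir,
            sprintf("%s.sample%03d.csv", nm, b)), ch)
      } else {
        fn <- file.path(dir, paste0(nm, ".csv"))
        if (grepl("A_SR$", nm)) {
          write_adjacency_csv(m, fn, ch)
        } else {
          if (grepl("M_s$", nm)) colnames(m) <- ch
          utils::write.csv(m, fn, row.names = FALSE)
        }
      }
    }
  }
  maps
}
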