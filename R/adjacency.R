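#' Default scalp montage for the 17-channel setup
#'
#' The fixed spatial-relationship graph: chains along each temporal strip
#' (FT7-T7-TP7 and FT8-T8-TP8) and grid neighbours within the posterior
#' block. The two anatomical blocks are deliberately not connected: the
#' montage encodes physical adjacency on the scalp, and the temporal and
#' posterior electrode groups are not neighbours. CPZ (the reference
#' electrode) is absent by construction.
#'
#' @return An object of class `montage_graph`: list with `edges` (m x 2
#'   character matrix of channel-name pairs) and `channel_names`.
#' @export
default_montage <- function() {
  edges <- rbind(
    c("FT7", "T7"), c("T7", "TP7"),
    c("FT8", "T8"), c("T8", "TP8"),
    c("CP1", "P1"), c("P1", "PZ"), c("PZ", "P2"), c("P2", "CP2"),
    c("P1", "PO3"), c("PZ", "POZ"), c("P2", "PO4"),
    c("PO3", "POZ"), c("POZ", "PO4"),
    c("PO3", "O1"), c("POZ", "OZ"), c("PO4", "O2"),
    c("O1", "OZ"), c("OZ", "O2")
  )
  montage_graph(edges, canonical_channels())
}

#' Construct a montage graph from an edge list
#'
#' @param edges m x 2 character matrix (or data frame) of undirected
#'   channel-name pairs.
#' @param channel_names the node set, in canonical order.
#' @return `montage_graph` object.
#' @export
montage_graph <- function(edges, channel_names = canonical_channels()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("montage_graph: edges must have two columns")
  bad <- setdiff(unique(c(edges)), channel_names)
  if (length(bad))
    stop("montage_graph: unknown channel name(s): ", paste(bad, collapse = ", "))
  if (any(edges[, 1] == edges[, 2]))
    stop("montage_graph: self-loops are not allowed in the edge list")
  structure(list(edges = edges, channel_names = as.character(channel_names)),
            class = "montage_graph")
}

#' Read a montage edge list from a YAML or JSON config file
#'
#' The file holds a list `edges` of two-element channel-name pairs and
#' optionally `channel_names`. Names are validated against the canonical 17.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `montage_graph` object.
#' @export
load_montage <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$edges)) stop("load_montage: config has no 'edges' key")
  edges <- do.call(rbind, lapply(cfg$edges, function(e) as.character(unlist(e))))
  chans <- if (!is.null(cfg$channel_names)) as.character(unlist(cfg$channel_names))
           else canonical_channels()
  montage_graph(edges, chans)
}

#' @export
print.montage_graph <- function(x, ...) {
  cat("montage_graph: ", length(x$channel_names), " channels, ",
      nrow(x$edges), " undirected edges\n", sep = "")
  invisible(x)
}

new_adjacency <- function(weights, semantic, normalized, channel_names = NULL) {
  if (!is.null(channel_names)) dimnames(weights) <- list(channel_names, channel_names)
  structure(list(weights = weights, semantic = semantic,
                 normalized = normalized),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat("adjacency_matrix [", x$semantic, "]: ", nrow(x$weights), " x ",
      ncol(x$weights), if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Fixed spatial-relationship adjacency (SR)
#'
#' Builds the binary symmetric adjacency from the montage edge list, then
#' row-normalizes by the degree matrix: \eqn{\tilde A = D^{-1} A}. No
#' self-loops are added by default (the normalization is stated on A
#' directly, not on A + I); set `self_loops = TRUE` to compare with the
#' A + I convention. Zero-degree rows are left all-zero and flagged.
#'
#' @param montage a [montage_graph()].
#' @param self_loops add the identity before normalizing (default FALSE).
#' @return `adjacency_matrix` with semantic `"SR"`. Attribute
#'   `"isolated"` names channels with degree zero, if any.
#' @export
build_spatial_adjacency <- function(montage, self_loops = FALSE) {
  stopifnot(inherits(montage, "montage_graph"))
  if (nrow(montage$edges) == 0)
    stop("build_spatial_adjacency: empty edge list (degenerate graph)")
  ch <- montage$channel_names
  v <- length(ch)
  A <- matrix(0, v, v)
  i <- match(montage$edges[, 1], ch); j <- match(montage$edges[, 2], ch)
  A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  if (self_loops) diag(A) <- 1
  deg <- rowSums(A)
  At <- A
  nz <- deg > 0
  At[nz, ] <- A[nz, , drop = FALSE] / deg[nz]
  out <- new_adjacency(At, "SR", normalized = TRUE, channel_names = ch)
  attr(out, "isolated") <- ch[!nz]
  out
}

#' Euclidean-distance adjacency (ED)
#'
#' From node features \eqn{X \in R^{V \times C}}, computes the pairwise
#' Euclidean distance matrix \eqn{e_{ij} = \lVert x_i - x_j \rVert_2} and
#' sets \eqn{a_{ij} = \max(E) - e_{ij}}: nearby nodes get large weights.
#' No further normalization is applied; the diagonal equals \eqn{\max(E)}.
#'
#' @param X numeric matrix, nodes x features.
#' @return `adjacency_matrix` with semantic `"ED"` (symmetric,
#'   non-negative).
#' @export
build_euclidean_adjacency <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("build_euclidean_adjacency: need at least 2 nodes")
  if (any(!is.finite(X)))
    stop("build_euclidean_adjacency: non-finite node features")
  E <- pairwise_euclidean(X)
  if (any(!is.finite(E)))
    stop("build_euclidean_adjacency: non-finite distance encountered")
  A <- max(E) - E
  new_adjacency(A, "ED", normalized = FALSE, channel_names = rownames(X))
}

# Dense pairwise Euclidean distances via the Gram matrix; clamps tiny
# negative round-off under the square root.
pairwise_euclidean <- function(X) {
  G <- tcrossprod(X)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d2[d2 < 0] <- 0
  E <- sqrt(d2)
  diag(E) <- 0
  E
}

#' Learnable projection for self-attention adjacency
#'
#' Query/key projection matrices of a single attention head of size
#' D = floor(C / 8), initialized with seeded uniform fan-in scaling.
#'
#' @param C node feature dimension; must be at least 8.
#' @param seed RNG seed for initialization.
#' @return list with `W_Q`, `W_K` (C x D) and `D`.
#' @export
attention_projection <- function(C, seed = 1L) {
  D <- C %/% 8L
  if (D < 1) stop("attention_projection: C = ", C,
                  " gives head size 0 (need C >= 8)")
  rng <- local_rng(seed)
  list(W_Q = init_mat(C, D, rng), W_K = init_mat(C, D, rng), D = D)
}

#' Self-attention adjacency (SA)
#'
#' \eqn{A = \mathrm{softmax}(X W_K (X W_Q)^T / \sqrt{D})}, applied row-wise,
#' so each row is a probability distribution over nodes. The scaling keeps
#' the logits well-conditioned for the head size D. Setting
#' `scale = "linear"` divides by D instead of \eqn{\sqrt D}.
#'
#' @param X numeric matrix, nodes x features (C columns).
#' @param proj an [attention_projection()] with matching C.
#' @param scale `"sqrt"` (default, transformer convention) or `"linear"`.
#' @return `adjacency_matrix` with semantic `"SA"` (row-stochastic).
#' @export
build_self_attention_adjacency <- function(X, proj, scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (ncol(X) != nrow(proj$W_Q))
    stop("build_self_attention_adjacency: X has ", ncol(X),
         " features but projection expects ", nrow(proj$W_Q))
  s <- if (scale == "sqrt") sqrt(proj$D) else proj$D
  logits <- tcrossprod(X %*% proj$W_K, X %*% proj$W_Q) / s
  A <- softmax_rows(logits)
  new_adjacency(A, "SA", normalized = TRUE, channel_names = rownames(X))
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Export an adjacency matrix (or any channel-labelled map) to CSV
#'
#' Dense CSV with row and column headers equal to the channel names, the
#' format used for adjacency and attention-map inspection.
#'
#' @param A an `adjacency_matrix` or plain matrix.
#' @param path output file.
#' @param channel_names used when `A` carries no dimnames.
#' @export
write_adjacency_csv <- function(A, path, channel_names = canonical_channels()) {
  W <- if (inherits(A, "adjacency_matrix")) A$weights else as.matrix(A)
  if (is.null(rownames(W))) dimnames(W) <- list(channel_names[seq_len(nrow(W))],
                                                channel_names[seq_len(ncol(W))])
  utils::write.csv(W, path, row.names = TRUE)
  invisible(path)
}

#' Read back an adjacency CSV written by [write_adjacency_csv()]
#' @param path CSV file.
#' @return numeric matrix with channel-name dimnames.
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
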