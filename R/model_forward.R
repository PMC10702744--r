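# Batched forward pass.
#
# Layout convention: inter-layer feature maps are stored channels-first as a
# C x (B*V) matrix whose columns are sample-major: column (b-1)*V + v holds
# the C feature channels of node v in sample b. Per-sample blocks are then
# contiguous column ranges, per-channel statistics are row operations, and
# length-C vectors broadcast by recycling — all cheap in R.
#
# In this layout the node-major branch algebra Y = A X W^T (X in V x C)
# becomes Yc = (W Xc) t(A) with Xc = t(X) the C x V per-sample block.

amdgcn_forward <- function(model, samples, mode = c("eval", "train"),
                           keep_cache = FALSE, keep_maps = FALSE,
                           zero_adjacency = NULL) {
  mode <- match.arg(mode)
  cfg <- model$config
  V <- cfg$n_nodes; C <- cfg$C
  samples <- as_sample_array(samples, V, cfg$in_bands)
  B <- dim(samples)[1]
  n <- B * V
  p <- model$params
  state <- model$state
  check_finite(samples, "input")

  # node-pooling operator: (B*V) x B matrix averaging the V columns of a
  # sample; reused by AM-CAM in every block
  Pool <- matrix(0, n, B)
  Pool[cbind(seq_len(n), rep(seq_len(B), each = V))] <- 1 / V

  # ---- encoder: per-node affine + ReLU, bands -> C ------------------------
  Sm <- matrix(aperm(samples, c(3, 2, 1)), cfg$in_bands, n)
  pre_enc <- p[["enc.W"]] %*% Sm + p[["enc.b"]]
  H <- relu(pre_enc)
  check_finite(H, "encoder")

  cache <- if (keep_cache) list(Sm = Sm, enc_mask = pre_enc > 0,
                                B = B, Pool = Pool) else NULL
  maps <- if (keep_maps) list() else NULL
  blocks_cache <- vector("list", cfg$n_blocks)

  for (k in seq_len(cfg$n_blocks)) {
    pre <- paste0("b", k, ".")
    bc <- list()

    # ---- AM-CAM: channel gate from node-axis avg/max pooling --------------
    if (cfg$use_cam) {
      F_in <- H
      avg <- F_in %*% Pool                               # C x B
      arr <- array(F_in, c(C, V, B))
      mx <- arr[, 1, ]
      if (B == 1) mx <- matrix(mx, C, 1)
      amx <- matrix(1L, C, B)
      for (v in seq_len(V)[-1]) {
        blk <- matrix(arr[, v, ], C, B)
        upd <- blk > mx
        mx[upd] <- blk[upd]
        amx[upd] <- v
      }
      W0 <- p[[paste0(pre, "cam.W0")]]; b0 <- p[[paste0(pre, "cam.b0")]]
      W1 <- p[[paste0(pre, "cam.W1")]]; b1 <- p[[paste0(pre, "cam.b1")]]
      ha <- relu(W0 %*% avg + b0)                        # hc x B
      hm <- relu(W0 %*% mx + b0)
      u <- (W1 %*% ha + b1) + (W1 %*% hm + b1)
      Mc <- sigmoid(u)                                   # C x B
      gate <- Mc[, rep(seq_len(B), each = V), drop = FALSE]
      H <- F_in * gate
      if (keep_cache)
        bc$cam <- list(F_in = F_in, avg = avg, mx = mx, amx = amx,
                       ha = ha, hm = hm, Mc = Mc)
      if (keep_maps) maps[[paste0("block", k, ".M_c")]] <- t(Mc)
    } else if (keep_maps) {
      maps[[paste0("block", k, ".M_c")]] <- matrix(1, B, C)
    }
    check_finite(H, paste0("block ", k, " AM-CAM"))

    # ---- MD-GC: three graph branches, summed, BN, nonlinearity ------------
    if (cfg$use_mdgc) {
      X <- H
      br <- cfg$branches
      zero <- zero_adjacency
      M_sr <- if (br[["SR"]]) p[[paste0(pre, "W_SR")]] %*% X else NULL
      M_ed <- if (br[["ED"]]) p[[paste0(pre, "W_ED")]] %*% X else NULL
      M_sa <- if (br[["SA"]]) p[[paste0(pre, "W_SA")]] %*% X else NULL
      D <- C %/% 8L
      s_att <- if (cfg$sa_scale == "sqrt") sqrt(D) else D
      K <- if (br[["SA"]]) crossprod(p[[paste0(pre, "W_K")]], X) else NULL
      Q <- if (br[["SA"]]) crossprod(p[[paste0(pre, "W_Q")]], X) else NULL
      A_sr <- model$A_sr
      if (!is.null(zero) && "SR" %in% zero) A_sr <- A_sr * 0
      tA_sr <- t(A_sr)
      Z <- matrix(0, C, n)
      A_ed_list <- if (br[["ED"]]) vector("list", B) else NULL
      E_list <- if (br[["ED"]]) vector("list", B) else NULL
      emax_idx <- if (br[["ED"]]) integer(B) else NULL
      A_sa_list <- if (br[["SA"]]) vector("list", B) else NULL
      zero_ed <- !is.null(zero) && "ED" %in% zero
      zero_sa <- !is.null(zero) && "SA" %in% zero
      for (b in seq_len(B)) {
        cols <- ((b - 1L) * V + 1L):(b * V)
        acc <- if (br[["SR"]]) M_sr[, cols] %*% tA_sr else 0
        if (br[["ED"]]) {
          Xb <- X[, cols]
          G <- crossprod(Xb)
          dg <- diag(G)
          E2 <- outer(dg, dg, "+") - 2 * G
          E2[E2 < 0] <- 0
          E <- sqrt(E2)
          im <- which.max(E)
          A_ed <- E[im] - E                    # symmetric
          if (zero_ed) A_ed <- A_ed * 0
          acc <- acc + M_ed[, cols] %*% A_ed
          A_ed_list[[b]] <- A_ed; E_list[[b]] <- E; emax_idx[b] <- im
        }
        if (br[["SA"]]) {
          Sb <- crossprod(K[, cols], Q[, cols]) / s_att
          A_sa <- softmax_rows(Sb)
          if (zero_sa) A_sa <- A_sa * 0
          acc <- acc + M_sa[, cols] %*% t(A_sa)
          A_sa_list[[b]] <- A_sa
        }
        Z[, cols] <- acc
      }
      check_finite(Z, paste0("block ", k, " MD-GC pre-norm"))

      # batch normalization per feature channel over (batch, nodes)
      bn_gamma <- p[[paste0(pre, "bn.gamma")]]
      bn_beta <- p[[paste0(pre, "bn.beta")]]
      eps <- 1e-5
      if (cfg$bn_mode == "identity") {
        Zbn <- Z
        bn_cache <- list(mode = "identity")
      } else if (mode == "train" && B > 1) {
        mu <- rowMeans(Z)
        va <- rowMeans(Z^2) - mu^2
        va[va < 0] <- 0
        ivar <- 1 / sqrt(va + eps)
        xhat <- (Z - mu) * ivar
        Zbn <- xhat * bn_gamma + bn_beta
        mom <- 0.1
        state[[paste0(pre, "bn.mean")]] <-
          (1 - mom) * state[[paste0(pre, "bn.mean")]] + mom * mu
        state[[paste0(pre, "bn.var")]] <-
          (1 - mom) * state[[paste0(pre, "bn.var")]] + mom * va
        bn_cache <- list(mode = "batch", xhat = xhat, ivar = ivar)
      } else {
        ivar <- 1 / sqrt(state[[paste0(pre, "bn.var")]] + eps)
        xhat <- (Z - state[[paste0(pre, "bn.mean")]]) * ivar
        Zbn <- xhat * bn_gamma + bn_beta
        bn_cache <- list(mode = "running", xhat = xhat, ivar = ivar)
      }
      Y <- if (cfg$mdgc_activation == "sigmoid") sigmoid(Zbn) else relu(Zbn)
      if (keep_cache)
        bc$mdgc <- list(X = X, M_sr = M_sr, M_ed = M_ed, M_sa = M_sa,
                        K = K, Q = Q, s_att = s_att, A_sr_used = A_sr,
                        A_ed_list = A_ed_list, E_list = E_list,
                        emax_idx = emax_idx, A_sa_list = A_sa_list,
                        bn = bn_cache, Zbn = Zbn, Y = Y)
      if (keep_maps) {
        if (br[["SR"]]) maps[[paste0("block", k, ".A_SR")]] <- A_sr
        maps[[paste0("block", k, ".A_ED")]] <- A_ed_list
        maps[[paste0("block", k, ".A_SA")]] <- A_sa_list
      }
      H <- Y
      check_finite(H, paste0("block ", k, " MD-GC"))
    }

    # ---- AM-SAM: spatial gate from channel-axis avg/max pooling -----------
    if (cfg$use_sam) {
      F_s <- H
      avg_s <- matrix(colMeans(F_s), V, B)               # V x B
      mxv <- F_s[1, ]
      amc <- rep(1L, n)
      for (cc in seq_len(C)[-1]) {
        rowc <- F_s[cc, ]
        upd <- rowc > mxv
        mxv[upd] <- rowc[upd]
        amc[upd] <- cc
      }
      max_s <- matrix(mxv, V, B)
      g <- rbind(max_s, avg_s)                           # [MaxPool; AvgPool]
      W0 <- p[[paste0(pre, "sam.W0")]]; b0 <- p[[paste0(pre, "sam.b0")]]
      W1 <- p[[paste0(pre, "sam.W1")]]; b1 <- p[[paste0(pre, "sam.b1")]]
      hsd <- relu(W0 %*% g + b0)                         # hs x B
      z <- W1 %*% hsd + b1                               # V x B
      Ms <- sigmoid(z)
      gate <- rep(as.vector(Ms), each = C)
      dim(gate) <- c(C, n)
      H <- F_s * gate
      if (keep_cache)
        bc$sam <- list(F_in = F_s, g = g, hsd = hsd, Ms = Ms, amc = amc)
      if (keep_maps) maps[[paste0("block", k, ".M_s")]] <- t(Ms)
    } else if (keep_maps) {
      maps[[paste0("block", k, ".M_s")]] <- matrix(1, B, V)
    }
    check_finite(H, paste0("block ", k, " AM-SAM"))
    blocks_cache[[k]] <- bc
  }

  # ---- classifier head: flatten -> dense -> softmax -----------------------
  Hm <- matrix(H, C * V, B)                  # column b = vec of sample b
  logits <- t(p[["head.W"]] %*% Hm + p[["head.b"]])      # B x n_classes
  check_finite(logits, "classifier head")
  probs <- softmax_rows(logits)
  if (keep_cache) {
    cache$blocks <- blocks_cache
    cache$Hm <- Hm
    cache$probs <- probs
  }
  list(probs = probs, logits = logits, cache = cache, state = state,
       maps = maps)
}
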