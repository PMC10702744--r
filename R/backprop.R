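# Reverse-mode gradients for the network. The forward pass
# (model_forward.R) caches every intermediate needed here; amdgcn_backward
# consumes the cache and the loss gradient w.r.t. the logits and returns a
# gradient for every parameter. Layout matches the forward pass: feature
# maps are C x (B*V) with sample-major columns (column (b-1)*V + v).

# Cross-entropy loss and its logit gradient for a batch.
# probs: B x K, y: integer class indices 1..K.
ce_loss <- function(probs, y) {
  B <- nrow(probs)
  -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-300)))
}

dlogits_ce <- function(probs, y) {
  B <- nrow(probs)
  G <- probs
  G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
  G / B
}

amdgcn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  V <- cfg$n_nodes; C <- cfg$C
  B <- cache$B; n <- B * V
  Pool <- cache$Pool
  expand_idx <- rep(seq_len(B), each = V)
  g <- stats::setNames(vector("list", length(p)), names(p))

  # ---- head ----------------------------------------------------------------
  dlt <- t(dlogits)                                     # n_classes x B
  g[["head.W"]] <- tcrossprod(dlt, cache$Hm)
  g[["head.b"]] <- rowSums(dlt)
  dH <- matrix(crossprod(p[["head.W"]], dlt), C, n)

  for (k in rev(seq_len(cfg$n_blocks))) {
    pre <- paste0("b", k, ".")
    bc <- cache$blocks[[k]]

    # ---- AM-SAM backward ---------------------------------------------------
    if (cfg$use_sam) {
      sc <- bc$sam
      F_in <- sc$F_in
      Ms <- sc$Ms                                       # V x B
      gate <- rep(as.vector(Ms), each = C)
      dim(gate) <- c(C, n)
      dMs <- matrix(colSums(dH * F_in), V, B)
      dF <- dH * gate
      dz <- dMs * Ms * (1 - Ms)                         # V x B
      W0 <- p[[paste0(pre, "sam.W0")]]
      W1 <- p[[paste0(pre, "sam.W1")]]
      g[[paste0(pre, "sam.W1")]] <- tcrossprod(dz, sc$hsd)
      g[[paste0(pre, "sam.b1")]] <- rowSums(dz)
      dhs <- crossprod(W1, dz) * (sc$hsd > 0)
      g[[paste0(pre, "sam.W0")]] <- tcrossprod(dhs, sc$g)
      g[[paste0(pre, "sam.b0")]] <- rowSums(dhs)
      dg <- crossprod(W0, dhs)                          # 2V x B: [max; avg]
      dmax <- dg[seq_len(V), , drop = FALSE]
      davg <- dg[V + seq_len(V), , drop = FALSE]
      spread <- rep(as.vector(davg) / C, each = C)
      dim(spread) <- c(C, n)
      dF <- dF + spread
      dF[cbind(sc$amc, seq_len(n))] <-
        dF[cbind(sc$amc, seq_len(n))] + as.vector(dmax)
      dH <- dF
    }

    # ---- MD-GC backward ----------------------------------------------------
    if (cfg$use_mdgc) {
      mc <- bc$mdgc
      dZbn <- if (cfg$mdgc_activation == "sigmoid") dH * mc$Y * (1 - mc$Y)
              else dH * (mc$Zbn > 0)
      bn <- mc$bn
      if (bn$mode == "identity") {
        g[[paste0(pre, "bn.gamma")]] <- numeric(C)
        g[[paste0(pre, "bn.beta")]] <- numeric(C)
        dZ <- dZbn
      } else {
        g[[paste0(pre, "bn.gamma")]] <- rowSums(dZbn * bn$xhat)
        g[[paste0(pre, "bn.beta")]] <- rowSums(dZbn)
        dxhat <- dZbn * p[[paste0(pre, "bn.gamma")]]
        if (bn$mode == "batch") {
          m1 <- rowMeans(dxhat)
          m2 <- rowMeans(dxhat * bn$xhat)
          dZ <- (dxhat - m1 - bn$xhat * m2) * bn$ivar
        } else {                        # running stats: pure affine
          dZ <- dxhat * bn$ivar
        }
      }

      X <- mc$X
      br <- cfg$branches
      dX <- matrix(0, C, n)
      dM_sr <- if (br[["SR"]]) matrix(0, C, n) else NULL
      dM_ed <- if (br[["ED"]]) matrix(0, C, n) else NULL
      dM_sa <- if (br[["SA"]]) matrix(0, C, n) else NULL
      Dh <- C %/% 8L
      dK <- if (br[["SA"]]) matrix(0, Dh, n) else NULL
      dQ <- if (br[["SA"]]) matrix(0, Dh, n) else NULL
      A_sr <- mc$A_sr_used
      for (b in seq_len(B)) {
        cols <- ((b - 1L) * V + 1L):(b * V)
        dZb <- dZ[, cols]
        if (br[["SR"]]) dM_sr[, cols] <- dZb %*% A_sr
        if (br[["ED"]]) {
          A_ed <- mc$A_ed_list[[b]]
          E <- mc$E_list[[b]]
          Xb <- X[, cols]
          Mb <- mc$M_ed[, cols]
          dA <- crossprod(dZb, Mb)                      # V x V
          dM_ed[, cols] <- dZb %*% A_ed                 # A_ed symmetric
          # A = max(E) - E: the max routes the summed sensitivity into the
          # (first) argmax entry; E is symmetric, so any tied entry is the
          # same function of X.
          dE <- -dA
          dE[mc$emax_idx[b]] <- dE[mc$emax_idx[b]] + sum(dA)
          S <- dE / E
          S[!is.finite(S)] <- 0                         # zero-distance pairs
          Tm <- S + t(S)                                # symmetric
          rs <- rep(rowSums(Tm), each = C)
          dim(rs) <- c(C, V)
          dX[, cols] <- dX[, cols] + Xb * rs - Xb %*% Tm
        }
        if (br[["SA"]]) {
          A_sa <- mc$A_sa_list[[b]]
          Mb <- mc$M_sa[, cols]
          Kb <- mc$K[, cols]
          Qb <- mc$Q[, cols]
          dA <- crossprod(dZb, Mb)
          dM_sa[, cols] <- dZb %*% A_sa
          rsft <- rowSums(dA * A_sa)
          dS <- A_sa * (dA - rsft)                      # rowwise softmax vjp
          dK[, cols] <- Qb %*% t(dS) / mc$s_att
          dQ[, cols] <- Kb %*% dS / mc$s_att
        }
      }
      if (br[["SR"]]) {
        g[[paste0(pre, "W_SR")]] <- tcrossprod(dM_sr, X)
        dX <- dX + crossprod(p[[paste0(pre, "W_SR")]], dM_sr)
      } else g[[paste0(pre, "W_SR")]] <- matrix(0, C, C)
      if (br[["ED"]]) {
        g[[paste0(pre, "W_ED")]] <- tcrossprod(dM_ed, X)
        dX <- dX + crossprod(p[[paste0(pre, "W_ED")]], dM_ed)
      } else g[[paste0(pre, "W_ED")]] <- matrix(0, C, C)
      if (br[["SA"]]) {
        g[[paste0(pre, "W_SA")]] <- tcrossprod(dM_sa, X)
        dX <- dX + crossprod(p[[paste0(pre, "W_SA")]], dM_sa)
        g[[paste0(pre, "W_K")]] <- tcrossprod(X, dK)
        g[[paste0(pre, "W_Q")]] <- tcrossprod(X, dQ)
        dX <- dX + p[[paste0(pre, "W_K")]] %*% dK +
                   p[[paste0(pre, "W_Q")]] %*% dQ
      } else {
        g[[paste0(pre, "W_SA")]] <- matrix(0, C, C)
        g[[paste0(pre, "W_K")]] <- matrix(0, C, Dh)
        g[[paste0(pre, "W_Q")]] <- matrix(0, C, Dh)
      }
      dH <- dX
    } else {
      Dh <- C %/% 8L
      g[[paste0(pre, "W_SR")]] <- matrix(0, C, C)
      g[[paste0(pre, "W_ED")]] <- matrix(0, C, C)
      g[[paste0(pre, "W_SA")]] <- matrix(0, C, C)
      g[[paste0(pre, "W_K")]] <- matrix(0, C, Dh)
      g[[paste0(pre, "W_Q")]] <- matrix(0, C, Dh)
      g[[paste0(pre, "bn.gamma")]] <- numeric(C)
      g[[paste0(pre, "bn.beta")]] <- numeric(C)
    }

    # ---- AM-CAM backward ---------------------------------------------------
    if (cfg$use_cam) {
      cc <- bc$cam
      F_in <- cc$F_in
      Mc <- cc$Mc                                       # C x B
      dMc <- ((dH * F_in) %*% Pool) * V
      dF <- dH * Mc[, expand_idx, drop = FALSE]
      du <- dMc * Mc * (1 - Mc)
      W0 <- p[[paste0(pre, "cam.W0")]]
      W1 <- p[[paste0(pre, "cam.W1")]]
      # shared MLP, two pooling branches: gradients accumulate
      g[[paste0(pre, "cam.W1")]] <- tcrossprod(du, cc$ha) +
                                    tcrossprod(du, cc$hm)
      g[[paste0(pre, "cam.b1")]] <- 2 * rowSums(du)
      dW1u <- crossprod(W1, du)
      dha <- dW1u * (cc$ha > 0)
      dhm <- dW1u * (cc$hm > 0)
      g[[paste0(pre, "cam.W0")]] <- tcrossprod(dha, cc$avg) +
                                    tcrossprod(dhm, cc$mx)
      g[[paste0(pre, "cam.b0")]] <- rowSums(dha) + rowSums(dhm)
      davg <- crossprod(W0, dha)                        # C x B
      dmaxp <- crossprod(W0, dhm)
      dF <- dF + davg[, expand_idx, drop = FALSE] / V
      # scatter into the argmax node of each (channel, sample)
      lin <- ((as.vector(col(cc$amx)) - 1L) * V + as.vector(cc$amx) - 1L) * C +
        as.vector(row(cc$amx))
      dF[lin] <- dF[lin] + as.vector(dmaxp)
      dH <- dF
    } else {
      hc <- cam_hidden(cfg)
      g[[paste0(pre, "cam.W0")]] <- matrix(0, hc, C)
      g[[paste0(pre, "cam.b0")]] <- numeric(hc)
      g[[paste0(pre, "cam.W1")]] <- matrix(0, C, hc)
      g[[paste0(pre, "cam.b1")]] <- numeric(C)
    }
    if (!cfg$use_sam) {
      hs <- sam_hidden(cfg)
      g[[paste0(pre, "sam.W0")]] <- matrix(0, hs, 2L * V)
      g[[paste0(pre, "sam.b0")]] <- numeric(hs)
      g[[paste0(pre, "sam.W1")]] <- matrix(0, V, hs)
      g[[paste0(pre, "sam.b1")]] <- numeric(V)
    }
  }

  # ---- encoder backward ----------------------------------------------------
  dpre <- dH * cache$enc_mask
  g[["enc.W"]] <- tcrossprod(dpre, cache$Sm)
  g[["enc.b"]] <- rowSums(dpre)
  g
}

# One training forward+backward step: returns loss, parameter gradients and
# the updated batch-norm running state.
amdgcn_loss_grad <- function(model, samples, y, zero_adjacency = NULL) {
  out <- amdgcn_forward(model, samples, mode = "train", keep_cache = TRUE,
                        zero_adjacency = zero_adjacency)
  loss <- ce_loss(out$probs, y)
  grads <- amdgcn_backward(model, out$cache, dlogits_ce(out$probs, y))
  list(loss = loss, grads = grads, state = out$state, probs = out$probs)
}
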