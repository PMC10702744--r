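# Network components: encoder, attention gates, the multi-branch graph
# layer, and the full forward pass.

test_that("encoder is a per-node affine map with ReLU", {
  cfg <- model_config()
  m <- amdgcn_init(cfg)
  # zero input with zero bias stays zero through the whole net's gates
  x0 <- matrix(0, 17, 30)
  out <- fw(m, x0, mode = "eval", keep_cache = TRUE)
  expect_equal(max(abs(out$cache$blocks[[1]]$cam$F_in)), 0)

  # identical nodes produce identical encoder columns
  xr <- with_seed_local(2, matrix(rnorm(30), 1, 30))[rep(1, 17), ]
  enc <- fw(m, xr, mode = "eval", keep_cache = TRUE)$cache$blocks[[1]]$cam$F_in
  expect_equal(dim(enc), c(128L, 17L))
  expect_equal(enc, enc[, rep(1, 17)])

  expect_error(fw(m, matrix(0, 17, 29)), "expects")
})

test_that("channel gate obeys its contracts", {
  cfg <- model_config(use_mdgc = FALSE, use_sam = FALSE, n_blocks = 1L)
  m <- amdgcn_init(cfg)
  # zero feature map, zero-bias MLP: gate is exactly 1/2, output zero
  out <- fw(m, matrix(0, 17, 30), mode = "eval", keep_cache = TRUE,
            keep_maps = TRUE)
  expect_equal(out$maps[["block1.M_c"]],
               matrix(0.5, 1, 128), ignore_attr = TRUE)
  expect_equal(max(abs(out$cache$Hm)), 0)

  # constant feature map along nodes: avg-pool equals max-pool
  xc <- with_seed_local(3, matrix(rnorm(30), 1, 30))[rep(1, 17), ]
  cc <- fw(m, xc, mode = "eval", keep_cache = TRUE)$cache$blocks[[1]]$cam
  expect_equal(cc$ha, cc$hm)
  expect_equal(cc$avg, cc$mx)

  # the gate only shrinks: |F_out| <= |F| elementwise, gate in (0,1)
  xr <- with_seed_local(4, array(rnorm(6 * 17 * 30), c(6, 17, 30)))
  o <- fw(m, xr, mode = "eval", keep_cache = TRUE, keep_maps = TRUE)
  F_in <- o$cache$blocks[[1]]$cam$F_in
  F_out <- matrix(o$cache$Hm, nrow(F_in), ncol(F_in))
  expect_true(all(abs(F_out) <= abs(F_in)))
  Mc <- o$maps[["block1.M_c"]]
  expect_true(all(Mc > 0 & Mc < 1))
})

test_that("spatial gate obeys its contracts and widths", {
  cfg <- model_config(use_mdgc = FALSE, use_cam = FALSE, n_blocks = 1L)
  m <- amdgcn_init(cfg)
  # MLP geometry: 2V = 34 -> ceil(34/4) = 9 -> 17
  expect_equal(dim(m$params[["b1.sam.W0"]]), c(9L, 34L))
  expect_equal(dim(m$params[["b1.sam.W1"]]), c(17L, 9L))

  out <- fw(m, matrix(0, 17, 30), mode = "eval", keep_cache = TRUE,
            keep_maps = TRUE)
  expect_equal(out$maps[["block1.M_s"]],
               matrix(0.5, 1, 17), ignore_attr = TRUE)
  expect_equal(max(abs(out$cache$Hm)), 0)

  xr <- with_seed_local(5, array(rnorm(4 * 17 * 30), c(4, 17, 30)))
  o <- fw(m, xr, mode = "eval", keep_cache = TRUE, keep_maps = TRUE)
  F_in <- o$cache$blocks[[1]]$sam$F_in
  F_out <- matrix(o$cache$Hm, nrow(F_in), ncol(F_in))
  expect_true(all(abs(F_out) <= abs(F_in)))
  Ms <- o$maps[["block1.M_s"]]
  expect_true(all(Ms > 0 & Ms < 1))
})

test_that("single-branch graph layer matches a dense node-major oracle", {
  cfg <- model_config(use_cam = FALSE, use_sam = FALSE, n_blocks = 1L,
                      branches = c(SR = TRUE, ED = FALSE, SA = FALSE),
                      bn_mode = "identity")
  m <- amdgcn_init(cfg)
  x <- with_seed_local(6, matrix(rnorm(17 * 30), 17, 30))
  out <- fw(m, x, mode = "eval", keep_cache = TRUE)
  Y <- t(out$cache$blocks[[1]]$mdgc$Y)          # back to nodes x channels

  # oracle: plain dense algebra, node-major
  X_enc <- t(pmax(m$params[["enc.W"]] %*% t(x) + m$params[["enc.b"]], 0))
  Y_oracle <- 1 / (1 + exp(-(m$A_sr %*% X_enc %*% t(m$params[["b1.W_SR"]]))))
  expect_lt(max(abs(Y - Y_oracle)), 1e-6)
})

test_that("graph layer is equivariant to consistent node permutation", {
  cfg <- model_config(use_cam = FALSE, use_sam = FALSE, n_blocks = 1L,
                      bn_mode = "identity")
  m <- amdgcn_init(cfg)
  x <- with_seed_local(7, matrix(rnorm(17 * 30), 17, 30))
  perm <- with_seed_local(8, sample(17))
  m2 <- m
  m2$A_sr <- m$A_sr[perm, perm]
  z1 <- fw(m, x, mode = "eval", keep_cache = TRUE)$cache$blocks[[1]]$mdgc$Zbn
  z2 <- fw(m2, x[perm, ], mode = "eval",
           keep_cache = TRUE)$cache$blocks[[1]]$mdgc$Zbn
  # columns are nodes: permuting inputs permutes pre-activation outputs
  expect_equal(z2, z1[, perm])
})

test_that("graph layer outputs stay in the sigmoid range", {
  m <- amdgcn_init(model_config())
  x <- with_seed_local(9, array(rnorm(5 * 17 * 30), c(5, 17, 30)))
  out <- fw(m, x, mode = "eval", keep_cache = TRUE)
  for (k in 1:2) {
    Y <- out$cache$blocks[[k]]$mdgc$Y
    # mathematically in (0,1); float saturation may round the extremes
    expect_true(all(Y >= 0 & Y <= 1))
    expect_true(mean(Y) > 0 && mean(Y) < 1)
  }
  expect_error(model_config(branches = c(SR = FALSE, ED = FALSE, SA = FALSE)),
               "branches")
})

test_that("disabling a graph branch equals zeroing its adjacency, bit for bit", {
  x <- with_seed_local(10, array(rnorm(3 * 17 * 30), c(3, 17, 30)))
  for (br in c("SR", "ED", "SA")) {
    sw <- c(SR = TRUE, ED = TRUE, SA = TRUE)
    sw[br] <- FALSE
    m_off <- amdgcn_init(model_config(branches = sw))
    m_full <- amdgcn_init(model_config())
    expect_identical(m_off$params, m_full$params)  # same init draw
    p_off <- fw(m_off, x, mode = "eval")$probs
    p_zero <- fw(m_full, x, mode = "eval", zero_adjacency = br)$probs
    expect_identical(p_off, p_zero)
  }
})

test_that("the full forward pass yields a probability simplex, deterministically", {
  m <- amdgcn_init(model_config())
  x <- with_seed_local(11, array(rnorm(8 * 17 * 30), c(8, 17, 30)))
  p1 <- predict(m, x)
  expect_equal(dim(p1), c(8L, 3L))
  expect_equal(unname(rowSums(p1)), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict(m, x))
  # two bit-identical samples give bit-identical outputs
  x2 <- x
  x2[2, , ] <- x2[1, , ]
  p2 <- predict(m, x2)
  expect_identical(p2[1, ], p2[2, ])
})

test_that("non-finite activations are reported with the offending layer", {
  m <- amdgcn_init(model_config())
  xb <- array(0, c(1, 17, 30))
  xb[1, 1, 1] <- NaN
  expect_error(fw(m, xb), "input")
  m$params[["enc.W"]][1, 1] <- Inf
  x <- array(1, c(1, 17, 30))
  expect_error(fw(m, x), "encoder")
})

test_that("the default model stays within its recorded size", {
  m <- amdgcn_init(model_config())
  expect_identical(param_count(m), 122845L)
  expect_lt(param_count(m), 200000L)
})

test_that("attention and adjacency maps export per block and sample", {
  m <- amdgcn_init(model_config())
  x <- with_seed_local(12, array(rnorm(3 * 17 * 30), c(3, 17, 30)))
  dir <- tempfile()
  maps <- export_attention_and_adjacency(m, x, dir = dir)
  # fixed spatial adjacency: one matrix per block, same for all samples
  expect_equal(maps[["block1.A_SR"]], m$A_sr, ignore_attr = TRUE)
  expect_equal(maps[["block1.A_SR"]], maps[["block2.A_SR"]])
  # self-attention rows are stochastic for every sample
  for (b in 1:3)
    expect_equal(unname(rowSums(maps[["block1.A_SA"]][[b]])), rep(1, 17),
                 tolerance = 1e-6)
  # Euclidean adjacency is data-dependent: differs between samples
  expect_gt(max(abs(maps[["block1.A_ED"]][[1]] - maps[["block1.A_ED"]][[2]])),
            1e-6)
  expect_true(file.exists(file.path(dir, "block1.A_SR.csv")))
  expect_true(file.exists(file.path(dir, "block1.A_ED.sample002.csv")))
  expect_true(file.exists(file.path(dir, "block2.M_s.csv")))
})
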