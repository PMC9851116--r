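small_config <- mcac_config(global_filters = 8L, local_filters = c(8L, 8L, 8L),
                            manual_branch_units = 8L, fusion_units = 8L)

test_that("branch output shapes match an independent hand trace", {
  cfg <- mcac_config()
  m <- mcac_build(cfg, seed = 1)
  # hand trace: valid conv then pool-by-2 at each stage
  L1 <- (320 - 5 + 1) %/% 2        # 158
  L2 <- (L1 - 3 + 1) %/% 2         # 78
  L3 <- (L2 - 3 + 1) %/% 2         # 38
  expect_equal(L3, 38)
  shp <- fvepnet:::local_branch_shape(cfg)
  expect_equal(unname(shp[[1]]["length"]), L1)
  expect_equal(unname(shp[[2]]["length"]), L2)
  expect_equal(unname(shp[[3]]["length"]), L3)
  expect_equal(m$flat_dim, L3 * 64)
  # global branch: one scalar per filter, 64 filters
  expect_equal(dim(m$params$Wg), c(320, 64))
  # run a batch and inspect the cached stage outputs
  fw <- mcac_forward(m, matrix(rnorm(3 * 320), 3, 320),
                     matrix(rnorm(21), 3, 7), cache = TRUE)
  expect_equal(dim(fw$cache$G), c(3, 64))
  expect_equal(dim(fw$cache$P1), c(3, L1, 64))
  expect_equal(dim(fw$cache$P2), c(3, L2, 64))
  expect_equal(dim(fw$cache$P3), c(3, L3, 64))
  expect_equal(dim(fw$penultimate), c(3, 128))
})

test_that("the parameter count equals the closed-form architecture total", {
  m <- mcac_build(mcac_config(), seed = 1)
  flat <- 38 * 64
  concat <- 64 + flat + 128
  expected <- (320 * 64 + 64) +                 # global conv
    (5 * 1 * 64 + 64) + (3 * 64 * 64 + 64) + (3 * 64 * 64 + 64) +  # local
    (7 * 128 + 128) +                           # manual branch
    (concat * 128 + 128) +                      # fusion
    (128 * 2 + 2) + (128 + 1)                   # heads
  expect_equal(n_parameters(m), expected)
})

test_that("probabilities sum to one and confidence stays in the unit interval", {
  m <- mcac_build(small_config, seed = 5)
  set.seed(99)
  for (chunk in 1:4) {
    X <- matrix(rnorm(250 * 320, sd = 5), 250, 320)
    MF <- matrix(rnorm(250 * 7, sd = 3), 250, 7)
    fw <- mcac_forward(m, X, MF)
    expect_lt(max(abs(rowSums(fw$p) - 1)), 1e-6)
    expect_true(all(fw$confidence >= 0 & fw$confidence <= 1))
    expect_true(all(fw$p >= 0 & fw$p <= 1))
  }
})

test_that("the forward pass is deterministic and batch-consistent", {
  m <- mcac_build(small_config, seed = 2)
  set.seed(1)
  X <- matrix(rnorm(6 * 320), 6, 320)
  MF <- matrix(rnorm(6 * 7), 6, 7)
  # duplicate a record inside a batch
  X[4, ] <- X[1, ]; MF[4, ] <- MF[1, ]
  fw <- mcac_forward(m, X, MF)
  expect_equal(fw$p[4, ], fw$p[1, ])
  expect_equal(fw$confidence[4], fw$confidence[1])
  # batch permutation moves outputs with the records
  perm <- c(3, 1, 6, 2, 5, 4)
  fw2 <- mcac_forward(m, X[perm, ], MF[perm, ])
  expect_equal(fw2$p, fw$p[perm, ], tolerance = 1e-12)
  expect_equal(fw2$penultimate, fw$penultimate[perm, ], tolerance = 1e-12)
  # same seed rebuild -> same weights
  expect_identical(mcac_build(small_config, seed = 2)$params, m$params)
})

test_that("softmax output is invariant to a constant shift of the class logits", {
  m <- mcac_build(small_config, seed = 3)
  X <- matrix(rnorm(4 * 320), 4, 320)
  MF <- matrix(rnorm(28), 4, 7)
  p1 <- mcac_forward(m, X, MF)$p
  m$params$bp <- m$params$bp + 7.3    # shift every class logit equally
  p2 <- mcac_forward(m, X, MF)$p
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("zeroed classification head yields the uniform distribution", {
  m <- mcac_build(small_config, seed = 4)
  m$params$Wp[] <- 0
  m$params$bp[] <- 0
  fw <- mcac_forward(m, matrix(rnorm(2 * 320), 2, 320), matrix(rnorm(14), 2, 7))
  expect_equal(fw$p, matrix(0.5, 2, 2))
})

test_that("invalid configurations and inputs raise named errors", {
  expect_error(mcac_config(n_classes = 1), class = "fvepnet_bad_config")
  expect_error(mcac_config(T_len = 2), class = "fvepnet_bad_config")
  expect_error(mcac_config(global_filters = 0), class = "fvepnet_bad_config")
  m <- mcac_build(small_config, seed = 1)
  expect_error(mcac_forward(m, matrix(rnorm(2 * 100), 2, 100),
                            matrix(rnorm(14), 2, 7)),
               class = "fvepnet_bad_signal_length")
  expect_error(mcac_forward(m, matrix(rnorm(2 * 320), 2, 320),
                            matrix(rnorm(7), 1, 7)),
               class = "fvepnet_bad_batch")
})

test_that("compiled convolution primitives agree with the pure-R reference", {
  set.seed(77)
  A <- array(rnorm(5 * 30 * 3), c(5, 30, 3))
  W <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  b <- rnorm(4)
  expect_equal(fvepnet:::conv1d_forward(A, W, b),
               fvepnet:::conv1d_forward_ref(A, W, b), tolerance = 1e-12)
  dZ <- array(rnorm(5 * 26 * 4), c(5, 26, 4))
  g1 <- fvepnet:::conv1d_backward(A, W, dZ)
  g2 <- fvepnet:::conv1d_backward_ref(A, W, dZ)
  expect_equal(g1$dA, g2$dA, tolerance = 1e-12)
  expect_equal(g1$dW, g2$dW, tolerance = 1e-12)
  expect_equal(g1$db, g2$db, tolerance = 1e-12)
  expect_equal(fvepnet:::tconv1d_forward(A, W, b),
               fvepnet:::tconv1d_forward_ref(A, W, b), tolerance = 1e-12)
  dO <- array(rnorm(5 * 34 * 4), c(5, 34, 4))
  t1 <- fvepnet:::tconv1d_backward(A, W, dO)
  t2 <- fvepnet:::tconv1d_backward_ref(A, W, dO)
  expect_equal(t1$dA, t2$dA, tolerance = 1e-12)
  expect_equal(t1$dW, t2$dW, tolerance = 1e-12)
  p1 <- fvepnet:::maxpool2_forward(A)
  p2 <- fvepnet:::maxpool2_forward_ref(A)
  expect_equal(p1$P, p2$P)
  dP <- array(rnorm(5 * 15 * 3), c(5, 15, 3))
  expect_equal(fvepnet:::maxpool2_backward(dP, p1$mask),
               fvepnet:::maxpool2_backward_ref(dP, p2$mask))
  # fused stage = conv -> relu -> pool composition
  st <- fvepnet:::stage_fwd_cpp(A, W, b)
  ref <- fvepnet:::maxpool2_forward_ref(
    fvepnet:::relu(fvepnet:::conv1d_forward_ref(A, W, b)))
  expect_equal(st$P, ref$P, tolerance = 1e-12)
})
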