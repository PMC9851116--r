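test_that("confidence hinting interpolates between prediction and label", {
  p <- c(0.7, 0.3); y <- c(1, 0)
  expect_equal(hinted_probs(p, 1, y), p)        # full confidence: unchanged
  expect_equal(hinted_probs(p, 0, y), y)        # zero confidence: the label
  expect_equal(hinted_probs(p, 0.5, y), c(0.85, 0.15))
  # rows still sum to one for a random batch
  set.seed(5)
  P <- random_probs(20, 3)
  Y <- random_one_hot(20, 3)
  cv <- runif(20)
  expect_equal(rowSums(hinted_probs(P, cv, Y)), rep(1, 20), tolerance = 1e-12)
  expect_error(hinted_probs(p, 0.5, c(1, 1)), class = "fvepnet_bad_one_hot")
  expect_error(hinted_probs(p, 1.5, y), class = "fvepnet_bad_confidence")
})

test_that("the focal term vanishes on perfect predictions and matches hand arithmetic", {
  expect_equal(focal_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-9)
  # y = [1,0], p_hat = [0.5, 0.5], gamma = 2, as-printed negative term:
  # -[ (1-0.5)^2 log 0.5 + 0.5 log(1-0.5) ]
  expect_equal(focal_loss(c(0.5, 0.5), c(1, 0), gamma = 2),
               -(0.25 * log(0.5) + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_error(focal_loss(c(1.4, -0.4), c(1, 0)), class = "fvepnet_bad_probs")
})

test_that("gamma = 0 with the symmetric form reduces to binary cross-entropy", {
  set.seed(8)
  for (k in 1:100) {
    p <- random_probs(1, 2)[1, ]
    y <- if (runif(1) < 0.5) c(1, 0) else c(0, 1)
    got <- focal_loss(p, y, gamma = 0, symmetric_gamma = TRUE)
    bce <- -sum(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(got, bce, tolerance = 1e-10)
  }
})

test_that("the confidence penalty is -log(c) with the right limits", {
  expect_equal(confidence_loss(1), 0)
  expect_equal(confidence_loss(exp(-1)), 1)
  cs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(confidence_loss(cs)) < 0))   # decreasing in c
  expect_gt(confidence_loss(1e-9), 20)              # grows without bound
})

test_that("the batch loss matches an independent scalar-loop oracle", {
  set.seed(10)
  for (k in 1:10) {
    n <- 16
    P <- random_probs(n, 2)
    Y <- random_one_hot(n, 2)
    cv <- runif(n)
    mask <- runif(n) < 0.5
    cfg <- loss_config(gamma = 2, lam = 0.1)
    got <- total_loss(P, cv, Y, cfg, hint_mask = mask)
    want <- oracle_total_loss(P, cv, Y, gamma = 2, lam = 0.1,
                              symmetric_gamma = FALSE, hint_mask = mask)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
    expect_gte(as.numeric(got), 0)
  }
})

test_that("degenerate loss configurations recover the plain focal mean", {
  set.seed(11)
  P <- random_probs(12, 2); Y <- random_one_hot(12, 2); cv <- runif(12)
  # lambda 0, no hinting: mean focal loss
  l1 <- total_loss(P, cv, Y, loss_config(lam = 0, hint_fraction = 0))
  expect_equal(as.numeric(l1), mean(focal_loss(P, Y)), tolerance = 1e-12)
  # all confidences 1: hinting is the identity and Lc is exactly zero
  l2 <- total_loss(P, rep(1, 12), Y, loss_config(lam = 0.5, hint_fraction = 1),
                   hint_mask = rep(TRUE, 12))
  expect_equal(as.numeric(l2), mean(focal_loss(P, Y)), tolerance = 1e-12)
  expect_error(total_loss(matrix(numeric(), 0, 2), numeric(0),
                          matrix(numeric(), 0, 2), loss_config()),
               class = "fvepnet_empty_batch")
})

test_that("the focal term decreases monotonically in the true-class probability", {
  for (gamma in c(0, 1, 2, 5)) {
    p1 <- seq(0.02, 0.98, by = 0.02)
    losses <- vapply(p1, function(q)
      focal_loss(c(q, 1 - q), c(1, 0), gamma = gamma), numeric(1))
    expect_true(all(diff(losses) < 0), label = paste("gamma", gamma))
  }
})

test_that("lowering confidence trades focal loss against the confidence penalty", {
  # misclassified record: p favours the wrong class
  p <- c(0.2, 0.8); y <- c(1, 0)
  cs <- seq(0.95, 0.05, by = -0.05)
  lt <- vapply(cs, function(cc)
    focal_loss(hinted_probs(p, cc, y), y, gamma = 2), numeric(1))
  lc <- confidence_loss(cs)
  expect_true(all(diff(lt) < 0))   # hinting pulls p_hat toward y
  expect_true(all(diff(lc) > 0))   # but the penalty grows
})

test_that("analytic loss gradients match finite differences through the heads", {
  set.seed(12)
  n <- 6
  zp <- matrix(rnorm(n * 2), n, 2)
  zc <- rnorm(n)
  Y <- random_one_hot(n, 2)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cfg <- loss_config(gamma = 2, lam = 0.2)
  loss_of <- function(zp, zc) {
    p <- exp(zp) / rowSums(exp(zp))
    cv <- 1 / (1 + exp(-zc))
    fvepnet:::total_loss_grad(p, cv, Y, cfg, mask)$loss
  }
  p <- exp(zp) / rowSums(exp(zp))
  cv <- 1 / (1 + exp(-zc))
  g <- fvepnet:::total_loss_grad(p, cv, Y, cfg, mask)
  h <- 1e-6
  for (i in seq_len(n)) {
    for (j in 1:2) {
      zp2 <- zp; zp2[i, j] <- zp2[i, j] + h
      zp3 <- zp; zp3[i, j] <- zp3[i, j] - h
      fd <- (loss_of(zp2, zc) - loss_of(zp3, zc)) / (2 * h)
      expect_equal(g$dzp[i, j], fd, tolerance = 1e-5)
    }
    zc2 <- zc; zc2[i] <- zc2[i] + h
    zc3 <- zc; zc3[i] <- zc3[i] - h
    fd <- (loss_of(zp, zc2) - loss_of(zp, zc3)) / (2 * h)
    expect_equal(g$dzc[i], fd, tolerance = 1e-5)
  }
})
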