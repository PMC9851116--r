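tiny_config <- function(epochs = 4L, seed = 1L, ...) {
  train_config(epochs = epochs, seed = seed, batch_size = 64L,
               model = mcac_config(global_filters = 16L,
                                   local_filters = c(16L, 16L, 16L),
                                   manual_branch_units = 16L,
                                   fusion_units = 16L), ...)
}

test_that("patients are assigned to exactly one side with the stated fractions", {
  d <- simulate_fvep(10, 10, 10, rng_seed = 1)
  sp <- split_by_patient(d, seed = 1)
  td <- tidy(sp)
  expect_equal(nrow(td), 30)
  expect_false(any(sp$train_patients %in% sp$test_patients))
  by_label <- dplyr::distinct(d, patient_id, label)
  train_lab <- by_label$label[by_label$patient_id %in% sp$train_patients]
  # 70/30 for labelled classes, 30/70 for the abnormal pool
  expect_equal(sum(train_lab == "normal"), 7)
  expect_equal(sum(train_lab == "rp"), 7)
  expect_equal(sum(train_lab == "abnormal"), 3)
  # record-level counts are 4x the patient counts
  expect_equal(nrow(fvepnet:::split_side(d, sp, "train")), 4 * 17)
  expect_equal(nrow(fvepnet:::split_side(d, sp, "test")), 4 * 13)
  # determinism
  expect_identical(tidy(split_by_patient(d, seed = 1)), td)
  expect_false(identical(tidy(split_by_patient(d, seed = 2)), td))
})

test_that("no patient ever lands on both sides across many random splits", {
  d <- simulate_fvep(9, 6, 4, rng_seed = 2)
  for (s in 1:50) {
    sp <- split_by_patient(d, seed = s)
    expect_length(intersect(sp$train_patients, sp$test_patients), 0)
    expect_setequal(c(sp$train_patients, sp$test_patients),
                    unique(d$patient_id))
  }
})

test_that("a degenerate class split warns and patient leakage aborts training", {
  d <- simulate_fvep(1, 5, 0, rng_seed = 3)
  expect_warning(split_by_patient(d, seed = 1),
                 class = "fvepnet_empty_side")
  d2 <- simulate_fvep(6, 6, 0, rng_seed = 4)
  sp <- split_by_patient(d2, seed = 1)
  sp$test_patients <- c(sp$test_patients, sp$train_patients[1])
  expect_error(train_mcac(d2, sp, tiny_config()),
               class = "fvepnet_leakage")
})

test_that("network gradients match finite differences end to end", {
  cfg <- mcac_config(global_filters = 6L, local_filters = c(6L, 6L, 6L),
                     manual_branch_units = 6L, fusion_units = 6L)
  m <- mcac_build(cfg, seed = 3)
  set.seed(21)
  n <- 3
  X <- matrix(rnorm(n * 320), n, 320)
  MF <- matrix(rnorm(n * 7), n, 7)
  Y <- random_one_hot(n, 2)
  mask <- c(TRUE, FALSE, TRUE)
  lcfg <- loss_config(gamma = 2, lam = 0.1)
  fw <- mcac_forward(m, X, MF, cache = TRUE)
  lg <- fvepnet:::total_loss_grad(fw$p, fw$confidence, Y, lcfg, mask)
  grads <- fvepnet:::mcac_backward(m, fw$cache, lg$dzp, lg$dzc)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    f <- mcac_forward(m2, X, MF)
    fvepnet:::total_loss_grad(f$p, f$confidence, Y, lcfg, mask)$loss
  }
  h <- 1e-5
  for (nm in names(m$params)) {
    for (t in 1:3) {
      i <- sample(length(m$params[[nm]]), 1)
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("training logs every epoch and returns the lowest-loss snapshot", {
  sf <- get_small_fit()
  fit <- sf$fit
  expect_equal(nrow(fit$log), 12)
  expect_true(all(is.finite(fit$log$loss)))
  expect_equal(fit$best_epoch, which.min(fit$log$loss))
  expect_equal(fit$best_loss, min(fit$log$loss))
  # non-degenerate optimization: selected loss no worse than epoch 1
  expect_lte(fit$best_loss, fit$log$loss[1])
  # the model learns the separable synthetic contrast
  expect_gte(dplyr::last(fit$log$train_accuracy), 0.9)
})

test_that("prediction output respects the probability contract", {
  sf <- get_small_fit()
  te <- fvepnet:::split_side(sf$records, sf$split, "test")
  pred <- predict(sf$fit, te)
  expect_named(pred, c("pred_class", "p_normal", "p_rp", "confidence"))
  expect_equal(pred$p_normal + pred$p_rp, rep(1, nrow(te)), tolerance = 1e-6)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  expect_true(all(pred$pred_class %in% c("normal", "rp")))
  emb <- mcac_embeddings(sf$fit, te)
  expect_equal(dim(emb), c(nrow(te), 128))
})

test_that("training is deterministic under a fixed seed", {
  d <- simulate_fvep(4, 4, 0, rng_seed = 5)
  sp <- split_by_patient(d, seed = 5)
  f1 <- train_mcac(d, sp, tiny_config(epochs = 2, seed = 7))
  f2 <- train_mcac(d, sp, tiny_config(epochs = 2, seed = 7))
  expect_equal(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the autoencoder mirrors the local branch and reduces reconstruction error", {
  d <- simulate_fvep(12, 0, 0, rng_seed = 6)
  cfg <- mcac_config(global_filters = 16L, local_filters = c(16L, 16L, 16L),
                     manual_branch_units = 16L, fusion_units = 16L)
  pre <- pretrain_autoencoder(d, config = cfg, epochs = 3, seed = 2)
  # encoder weight tensors have exactly the local-branch shapes
  m <- mcac_build(cfg, seed = 1)
  for (nm in names(pre$encoder)) {
    expect_equal(dim(pre$encoder[[nm]]) %||% length(pre$encoder[[nm]]),
                 dim(m$params[[nm]]) %||% length(m$params[[nm]]),
                 label = nm)
  }
  # reconstruction improves over the epoch-0 forward pass
  expect_lt(dplyr::last(pre$log$mse), pre$log$mse[1])
  # determinism
  pre2 <- pretrain_autoencoder(d, config = cfg, epochs = 3, seed = 2)
  expect_identical(pre$params, pre2$params)
  expect_error(pretrain_autoencoder(d[0, ], config = cfg),
               class = "fvepnet_empty_pool")
})

test_that("pretrained weights load into the local branch with a reduced learning rate", {
  d <- simulate_fvep(6, 6, 0, rng_seed = 7)
  sp <- split_by_patient(d, seed = 7)
  cfg <- tiny_config(epochs = 2, seed = 7)
  pre <- pretrain_autoencoder(fvepnet:::split_side(d, sp, "train"),
                              config = cfg$model, epochs = 2, seed = 7)
  fit <- train_mcac(d, sp, cfg, pretrained = pre)
  expect_true(fit$pretrained)
  # optimizer-state inspection: the local-branch group runs at lr 0.001
  # while the main rate is 0.01
  expect_setequal(names(fit$lr_scale),
                  c("Wl1", "bl1", "Wl2", "bl2", "Wl3", "bl3"))
  expect_equal(unique(unlist(fit$lr_scale)), 0.001 / 0.01)
  expect_equal(nrow(fit$log), 2)
  # mismatched shapes are rejected
  pre_bad <- pretrain_autoencoder(d, config = mcac_config(), epochs = 1,
                                  seed = 1)
  expect_error(train_mcac(d, sp, cfg, pretrained = pre_bad),
               class = "fvepnet_bad_pretrained")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
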