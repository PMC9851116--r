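# Patient-grouped splitting, convolutional-autoencoder pretraining of the
# local branch, and the two-phase training loop (pretrained local branch at
# a low learning rate, everything else at the main rate).

#' Patient-grouped train/test split
#'
#' Patients -- never individual records -- are randomly assigned to train or
#' test, so all four sweeps of a patient land on the same side. Labelled
#' classes (normal, RP) use `train_fraction` (default 70% train); the
#' abnormal class uses `abnormal_train_fraction` (default 30% train / 70%
#' test).
#'
#' @param records Record tibble.
#' @param train_fraction Train fraction for the normal and RP classes.
#' @param abnormal_train_fraction Train fraction for the abnormal class.
#' @param seed Integer seed.
#' @return An object of class `split_spec` with per-side patient-id vectors.
#' @export
split_by_patient <- function(records, train_fraction = 0.7,
                             abnormal_train_fraction = 0.3, seed = 1L) {
  check_records(records)
  pat <- dplyr::distinct(records, .data$patient_id, .data$label)
  if (anyDuplicated(pat$patient_id)) {
    abort("a patient_id appears with more than one label",
          class = "fvepnet_bad_records")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 7L))
  train_ids <- character()
  test_ids <- character()
  for (lab in unique(pat$label)) {
    ids <- pat$patient_id[pat$label == lab]
    frac <- if (lab == "abnormal") abnormal_train_fraction else train_fraction
    n_train <- round(frac * length(ids))
    tr <- sample(ids, n_train)
    if (n_train == 0L || n_train == length(ids)) {
      warn(paste0("class '", lab, "' has zero patients on one side of the split"),
           class = "fvepnet_empty_side")
    }
    train_ids <- c(train_ids, tr)
    test_ids <- c(test_ids, setdiff(ids, tr))
  }
  structure(list(train_patients = train_ids, test_patients = test_ids,
                 train_fraction = train_fraction,
                 abnormal_train_fraction = abnormal_train_fraction,
                 seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> ", length(x$train_patients), " train / ",
      length(x$test_patients), " test patients (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.split_spec <- function(x, ...) {
  bind_rows(tibble(patient_id = x$train_patients, side = "train"),
            tibble(patient_id = x$test_patients, side = "test"))
}

split_side <- function(records, split, side = c("train", "test")) {
  side <- match.arg(side)
  ids <- if (side == "train") split$train_patients else split$test_patients
  records[records$patient_id %in% ids, , drop = FALSE]
}

#' Training configuration
#'
#' @param lr_main Learning rate for all parameters (default 0.01).
#' @param lr_local_pretrained Learning rate for the local-branch parameters
#'   when pretrained weights are loaded (default 0.001).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Number of epochs (default 50); the snapshot with the lowest
#'   training loss is returned.
#' @param seed Integer seed driving initialization, shuffling and hinting.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param momentum SGD momentum.
#' @param loss A [loss_config()].
#' @param model An [mcac_config()].
#' @param denoise Apply EMD denoising (IMF3--5) to every sweep before
#'   training and prediction.
#' @param signal_standardize Standardize sweeps by the training pool's
#'   global mean/SD before they enter the network.
#' @param select_best `"train_loss"` (as specified for this method) or
#'   `"final"` (last epoch).
#' @param abnormal_exposure If the split contains abnormal-class training
#'   records, push the confidence head toward 0 on them via an auxiliary
#'   `-log(1 - c)` term.
#' @param abnormal_weight Weight of that auxiliary term.
#' @param clip_norm Global L2 gradient-norm ceiling per minibatch
#'   (`Inf` disables clipping). The hinted focal loss has unbounded
#'   per-record gradients on saturated wrong predictions, so clipping
#'   stabilizes the stated learning rate.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_main = 0.01, lr_local_pretrained = 0.001,
                         batch_size = 128L, epochs = 50L, seed = 1L,
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         loss = loss_config(), model = mcac_config(),
                         denoise = FALSE, signal_standardize = TRUE,
                         select_best = c("train_loss", "final"),
                         abnormal_exposure = TRUE, abnormal_weight = 1.0,
                         clip_norm = 5) {
  if (lr_main <= 0 || lr_local_pretrained <= 0) {
    abort("learning rates must be positive", class = "fvepnet_bad_config")
  }
  if (epochs < 1L) abort("epochs must be >= 1", class = "fvepnet_bad_config")
  structure(list(lr_main = lr_main, lr_local_pretrained = lr_local_pretrained,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = match.arg(optimizer), momentum = momentum,
                 loss = loss, model = model, denoise = denoise,
                 signal_standardize = isTRUE(signal_standardize),
                 select_best = match.arg(select_best),
                 abnormal_exposure = isTRUE(abnormal_exposure),
                 abnormal_weight = abnormal_weight,
                 clip_norm = clip_norm),
            class = "train_config")
}

# ---- convolutional autoencoder -------------------------------------------

ae_build <- function(config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 23L))
  fs <- config$local_filter_sizes
  nf <- config$local_filters
  p <- list()
  cin <- 1L
  for (s in seq_along(fs)) {
    p[[paste0("Wl", s)]] <- array(he_uniform(fs[s] * cin * nf[s], fs[s] * cin),
                                  c(fs[s], cin, nf[s]))
    p[[paste0("bl", s)]] <- numeric(nf[s])
    cin <- nf[s]
  }
  for (s in rev(seq_along(fs))) {
    p[[paste0("Wd", s)]] <- array(he_uniform(fs[s] * cin * nf[s], fs[s] * cin),
                                  c(fs[s], cin, nf[s]))
    p[[paste0("bd", s)]] <- numeric(nf[s])
  }
  p$Wout <- array(he_uniform(cin, cin), c(1L, cin, 1L))
  p$bout <- 0
  p
}

ae_forward <- function(p, X, n_stage) {
  n <- nrow(X)
  A <- array(X, c(n, ncol(X), 1L))
  cache <- list(A0 = A)
  for (s in seq_len(n_stage)) {
    Z <- conv1d_forward(A, p[[paste0("Wl", s)]], p[[paste0("bl", s)]])
    R <- relu(Z)
    pool <- maxpool2_forward(R)
    cache[[paste0("R", s)]] <- R
    cache[[paste0("mask", s)]] <- pool$mask
    cache[[paste0("P", s)]] <- pool$P
    A <- pool$P
  }
  for (s in rev(seq_len(n_stage))) {
    U <- upsample2_forward(A)
    D <- tconv1d_forward(U, p[[paste0("Wd", s)]], p[[paste0("bd", s)]])
    R <- relu(D)
    cache[[paste0("U", s)]] <- U
    cache[[paste0("Rd", s)]] <- R
    A <- R
  }
  Y <- conv1d_forward(A, p$Wout, p$bout)
  cache$Yhat <- matrix(Y, n, dim(Y)[2])
  cache
}

ae_backward <- function(p, cache, dY, n_stage) {
  n <- nrow(dY)
  g <- list()
  A_last <- cache[[paste0("Rd", 1L)]]
  cb <- conv1d_backward(A_last, p$Wout, array(dY, c(n, ncol(dY), 1L)))
  g$Wout <- cb$dW; g$bout <- cb$db
  dA <- cb$dA
  for (s in seq_len(n_stage)) {
    dR <- relu_backward(dA, cache[[paste0("Rd", s)]])
    tb <- tconv1d_backward(cache[[paste0("U", s)]], p[[paste0("Wd", s)]], dR)
    g[[paste0("Wd", s)]] <- tb$dW
    g[[paste0("bd", s)]] <- tb$db
    dA <- upsample2_backward(tb$dA)
  }
  for (s in rev(seq_len(n_stage))) {
    dR <- maxpool2_backward(dA, cache[[paste0("mask", s)]])
    dZ <- relu_backward(dR, cache[[paste0("R", s)]])
    A_in <- if (s == 1L) cache$A0 else cache[[paste0("P", s - 1L)]]
    cb <- conv1d_backward(A_in, p[[paste0("Wl", s)]], dZ)
    g[[paste0("Wl", s)]] <- cb$dW
    g[[paste0("bl", s)]] <- cb$db
    dA <- cb$dA
  }
  g
}

#' Pretrain the local branch as a convolutional autoencoder
#'
#' Builds an encoder with exactly the local-branch layer structure
#' (conv 5/3/3 x 64 filters, each followed by max-pool 2) and a mirrored
#' decoder (nearest-neighbour upsampling + transposed convolutions), and
#' trains it on reconstruction mean-squared error over the supplied sweep
#' pool (typically the training split plus unlabelled data). The returned
#' encoder weights load directly onto the network's local branch.
#'
#' @param records Record tibble (labels are ignored) or an n x 320 matrix.
#' @param config An [mcac_config()] fixing the local-branch structure.
#' @param epochs,batch_size,lr,momentum Optimization settings.
#' @param seed Integer seed.
#' @return Object of class `fvep_autoencoder`: encoder weights, full
#'   parameter list, per-epoch MSE log (including the epoch-0 forward pass
#'   at initialization), and the signal scaler.
#' @export
pretrain_autoencoder <- function(records, config = mcac_config(), epochs = 5L,
                                 batch_size = 128L, lr = 0.001, momentum = 0.9,
                                 seed = 1L) {
  X <- if (is.matrix(records)) records else signal_matrix(records)
  if (nrow(X) == 0L) abort("empty pretraining pool", class = "fvepnet_empty_pool")
  scaler <- list(mean = mean(X), sd = max(sd(as.vector(X)), 1e-8))
  Xs <- (X - scaler$mean) / scaler$sd
  n_stage <- length(config$local_filter_sizes)
  p <- ae_build(config, seed)

  mse_of <- function(params) {
    tot <- 0
    for (ix in batch_indices(nrow(Xs), 256L)) {
      cc <- ae_forward(params, Xs[ix, , drop = FALSE], n_stage)
      tot <- tot + sum((cc$Yhat - Xs[ix, , drop = FALSE])^2)
    }
    tot / length(Xs)
  }

  log <- tibble(epoch = 0L, mse = mse_of(p))
  state <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, 31L, ep))
    ord <- sample.int(nrow(Xs))
    for (ix in batch_indices(nrow(Xs), batch_size)) {
      b <- ord[ix]
      Xb <- Xs[b, , drop = FALSE]
      cc <- ae_forward(p, Xb, n_stage)
      dY <- 2 * (cc$Yhat - Xb) / length(Xb)
      g <- ae_backward(p, cc, dY, n_stage)
      st <- sgd_step(p, g, state, lr, momentum)
      p <- st$params; state <- st$state
    }
    log <- bind_rows(log, tibble(epoch = ep, mse = mse_of(p)))
  }
  enc_names <- local_param_names(config)
  structure(list(encoder = p[enc_names], params = p, log = log,
                 scaler = scaler, config = config, seed = seed),
            class = "fvep_autoencoder")
}

#' @export
print.fvep_autoencoder <- function(x, ...) {
  cat("<fvep_autoencoder> reconstruction MSE ",
      signif(x$log$mse[1], 4), " (init) -> ",
      signif(tail(x$log$mse, 1), 4), " (epoch ", max(x$log$epoch), ")\n",
      sep = "")
  invisible(x)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

one_hot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  Y
}

# ---- the training loop ---------------------------------------------------

#' Train the multi-branch network
#'
#' Minibatch SGD (momentum 0.9) on the confidence-hinted focal loss over the
#' patient-grouped training split. When `pretrained` autoencoder weights are
#' supplied they are loaded into the local branch, which is then fine-tuned
#' at `lr_local_pretrained` (0.001) while every other parameter uses
#' `lr_main` (0.01). The epoch snapshot with the lowest training loss is
#' returned. Manual features are z-scored and sweeps standardized with
#' statistics frozen on the training split only. If the split's training
#' side contains abnormal-class records and `abnormal_exposure` is on, those
#' records additionally push the confidence head toward 0 (they never enter
#' the classification loss).
#'
#' @param records Record tibble containing at least the training patients.
#' @param split A [split_by_patient()] object.
#' @param config A [train_config()].
#' @param pretrained Optional [pretrain_autoencoder()] result.
#' @return Object of class `mcac_fit`: best-epoch model, per-epoch log,
#'   scalers, class levels, split and config. Supports [predict()],
#'   [tidy()], [glance()] and [autoplot()].
#' @export
train_mcac <- function(records, split, config = train_config(),
                       pretrained = NULL) {
  check_records(records)
  stopifnot(inherits(split, "split_spec"), inherits(config, "train_config"))
  if (config$denoise) records <- denoise_records(records)

  train_rec <- split_side(records, split, "train")
  labelled <- train_rec[train_rec$label %in% c("normal", "rp"), , drop = FALSE]
  abnormal <- train_rec[train_rec$label == "abnormal", , drop = FALSE]
  if (nrow(labelled) == 0L) abort("no labelled training records",
                                  class = "fvepnet_empty_batch")
  # leakage guard: nothing reaching a gradient step may come from the test side
  if (any(labelled$patient_id %in% split$test_patients) ||
      any(abnormal$patient_id %in% split$test_patients)) {
    abort("patient leakage: training records overlap the test split",
          class = "fvepnet_leakage")
  }

  X <- signal_matrix(labelled)
  sig_scaler <- if (config$signal_standardize) {
    list(mean = mean(X), sd = max(sd(as.vector(X)), 1e-8))
  } else list(mean = 0, sd = 1)
  Xs <- (X - sig_scaler$mean) / sig_scaler$sd

  MF <- as.matrix(manual_features(labelled))
  mf_center <- colMeans(MF)
  mf_scale <- apply(MF, 2L, sd)
  mf_scale[mf_scale == 0] <- 1
  MFs <- scale(MF, center = mf_center, scale = mf_scale)

  class_levels <- c("normal", "rp")
  Y <- one_hot(labelled$label, class_levels)

  use_abn <- config$abnormal_exposure && nrow(abnormal) > 0L
  if (use_abn) {
    Xa <- (signal_matrix(abnormal) - sig_scaler$mean) / sig_scaler$sd
    MFa <- scale(as.matrix(manual_features(abnormal)),
                 center = mf_center, scale = mf_scale)
  }

  model <- mcac_build(config$model, seed = config$seed)
  lr_scale <- NULL
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "fvep_autoencoder"))
    for (nm in names(pretrained$encoder)) {
      if (!identical(dim(model$params[[nm]]) %||% length(model$params[[nm]]),
                     dim(pretrained$encoder[[nm]]) %||%
                       length(pretrained$encoder[[nm]]))) {
        abort(paste0("pretrained weight ", nm, " does not match the local branch"),
              class = "fvepnet_bad_pretrained")
      }
      model$params[[nm]] <- pretrained$encoder[[nm]]
    }
    lr_scale <- setNames(as.list(rep(config$lr_local_pretrained / config$lr_main,
                                     length(local_param_names(config$model)))),
                         local_param_names(config$model))
  }

  n <- nrow(Xs)
  state <- list()
  log <- tibble(epoch = integer(), loss = numeric(), focal = numeric(),
                confidence_penalty = numeric(), train_accuracy = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, 41L, ep))
    ord <- sample.int(n)
    ep_loss <- 0; ep_focal <- 0; ep_conf <- 0; ep_correct <- 0
    n_batches <- 0L
    for (ix in batch_indices(n, config$batch_size)) {
      b <- ord[ix]
      fw <- mcac_forward(model, Xs[b, , drop = FALSE],
                         MFs[b, , drop = FALSE], cache = TRUE)
      mask <- hint_mask_for_batch(length(b), config$loss$hint_fraction,
                                  derive_seed(config$seed, 43L, ep, n_batches))
      lg <- total_loss_grad(fw$p, fw$confidence, Y[b, , drop = FALSE],
                            config$loss, mask)
      if (!is.finite(lg$loss)) {
        abort(paste0("training diverged (non-finite loss at epoch ", ep, ")"),
              class = "fvepnet_divergence")
      }
      grads <- mcac_backward(model, fw$cache, lg$dzp, lg$dzc)

      batch_loss <- lg$loss
      if (use_abn) {
        na_b <- min(nrow(Xa), max(8L, length(b) %/% 4L))
        set.seed(derive_seed(config$seed, 47L, ep, n_batches))
        ab <- sample.int(nrow(Xa), na_b)
        fa <- mcac_forward(model, Xa[ab, , drop = FALSE],
                           MFa[ab, , drop = FALSE], cache = TRUE)
        ca <- pmin(fa$confidence, 1 - 1e-12)
        l_abn <- mean(-log(1 - ca))
        # d/dzc of mean(-log(1 - sigmoid(zc))) is c / n
        dzc_a <- config$abnormal_weight * ca / na_b
        ga <- mcac_backward(model, fa$cache,
                            matrix(0, na_b, ncol(fa$p)), dzc_a)
        for (nm in names(ga)) grads[[nm]] <- grads[[nm]] + ga[[nm]]
        batch_loss <- batch_loss + config$abnormal_weight * l_abn
      }

      grads <- clip_global_norm(grads, config$clip_norm)
      st <- sgd_step(model$params, grads, state, config$lr_main,
                     config$momentum, lr_scale)
      model$params <- st$params; state <- st$state

      ep_loss <- ep_loss + batch_loss
      ep_focal <- ep_focal + lg$components["focal"]
      ep_conf <- ep_conf + lg$components["confidence"]
      ep_correct <- ep_correct +
        sum(max.col(fw$p) == max.col(Y[b, , drop = FALSE]))
      n_batches <- n_batches + 1L
    }
    log <- bind_rows(log, tibble(
      epoch = ep, loss = ep_loss / n_batches,
      focal = unname(ep_focal) / n_batches,
      confidence_penalty = unname(ep_conf) / n_batches,
      train_accuracy = ep_correct / n))
    if (log$loss[nrow(log)] < best$loss) {
      best <- list(loss = log$loss[nrow(log)], params = model$params,
                   epoch = ep)
    }
  }

  final_params <- model$params
  if (config$select_best == "train_loss") model$params <- best$params

  structure(list(model = model, log = log, best_epoch = best$epoch,
                 best_loss = best$loss, final_params = final_params,
                 sig_scaler = sig_scaler,
                 mf_center = mf_center, mf_scale = mf_scale,
                 class_levels = class_levels, split = split, config = config,
                 pretrained = !is.null(pretrained),
                 lr_scale = lr_scale),
            class = "mcac_fit")
}

#' @export
print.mcac_fit <- function(x, ...) {
  cat("<mcac_fit> ", nrow(x$log), " epochs; best epoch ", x$best_epoch,
      " (training loss ", signif(x$best_loss, 5), "); ",
      if (x$pretrained) "pretrained local branch" else "random init", "\n",
      sep = "")
  invisible(x)
}

# Standardize inputs exactly as during training.
prepare_inputs <- function(fit, records) {
  check_records(records)
  if (fit$config$denoise) records <- denoise_records(records)
  X <- (signal_matrix(records) - fit$sig_scaler$mean) / fit$sig_scaler$sd
  MF <- scale(as.matrix(manual_features(records)),
              center = fit$mf_center, scale = fit$mf_scale)
  list(X = X, MF = MF)
}

#' Predict classes and confidence for FVEP records
#'
#' @param object An [train_mcac()] fit.
#' @param records Record tibble.
#' @param ... Unused.
#' @return Tibble with one row per record: predicted class, per-class
#'   probabilities (`p_normal`, `p_rp`), and the confidence scalar.
#' @export
predict.mcac_fit <- function(object, records, ...) {
  inp <- prepare_inputs(object, records)
  fw <- mcac_forward(object$model, inp$X, inp$MF)
  probs <- as_tibble(setNames(as.data.frame(fw$p),
                              paste0("p_", object$class_levels)))
  dplyr::bind_cols(
    tibble(pred_class = object$class_levels[max.col(fw$p)]),
    probs,
    tibble(confidence = fw$confidence))
}

#' Penultimate-layer embeddings of records
#'
#' The fusion-layer activations used as the feature space for the classical
#' novelty detectors.
#'
#' @param fit An `mcac_fit`.
#' @param records Record tibble.
#' @return n x fusion_units numeric matrix.
#' @export
mcac_embeddings <- function(fit, records) {
  inp <- prepare_inputs(fit, records)
  mcac_forward(fit$model, inp$X, inp$MF)$penultimate
}
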