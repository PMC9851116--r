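# End-to-end seeded experiment: simulate (or load) -> optional denoise ->
# features -> patient split -> optional pretraining -> training ->
# classification metrics -> OOD scoring with a threshold frozen on the
# training split.

#' Default experiment configuration
#'
#' A nested list mirroring the YAML schema accepted by [run_experiment()].
#'
#' @param seed Master seed for the whole run.
#' @return Named list with sections `synth`, `denoise`, `split`, `pretrain`,
#'   `train`, `ood`.
#' @export
default_experiment_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(n_normal = 50L, n_rp = 50L, n_abnormal = 25L,
                 noise_sd = 1, rp_p2_attenuation = 0.5, data_csv = NULL),
    denoise = list(enabled = FALSE, imfs = c(3L, 4L, 5L)),
    split = list(train_fraction = 0.7, abnormal_train_fraction = 0.3),
    pretrain = list(enabled = FALSE, epochs = 5L),
    train = list(epochs = 50L, batch_size = 128L, lr_main = 0.01,
                 lr_local_pretrained = 0.001, gamma = 2, lambda = 0.1,
                 hint_fraction = 0.5, abnormal_exposure = TRUE,
                 abnormal_weight = 1.0),
    ood = list(methods = "all", lof_k = 20L, ocsvm_nu = 0.1))
}

known_config_keys <- function() {
  lapply(default_experiment_config(), function(x)
    if (is.list(x)) names(x) else NULL)
}

validate_config <- function(config) {
  ref <- default_experiment_config()
  bad <- setdiff(names(config), names(ref))
  for (sec in intersect(names(config), names(ref))) {
    if (is.list(ref[[sec]]) && is.list(config[[sec]])) {
      extra <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(extra)) bad <- c(bad, paste0(sec, ".", extra))
    }
  }
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "fvepnet_bad_config")
  }
  # fill defaults
  out <- ref
  for (sec in names(config)) {
    if (is.list(ref[[sec]])) {
      for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  out
}

#' Run a full seeded experiment
#'
#' Simulates (or loads) an FVEP dataset, optionally denoises it, splits by
#' patient, optionally pretrains the local branch, trains the network,
#' evaluates classification on the held-out patients, and runs the
#' requested OOD detectors with the decision threshold chosen on
#' training-split scores only. All artifacts (resolved config, split
#' manifest, per-epoch log, per-record predictions, metrics JSON) are
#' written to `out_dir` when given.
#'
#' @param config Nested list (see [default_experiment_config()]) or a path
#'   to a YAML file with the same structure.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `fit`, `metrics` (classification tibble),
#'   `ood` (per-method tibble), `split`, and `records`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  seed <- cfg$seed

  records <- if (!is.null(cfg$synth$data_csv)) {
    read_fvep_csv(cfg$synth$data_csv)
  } else {
    params <- fvep_waveform_params(noise_sd = cfg$synth$noise_sd,
                                   rp_p2_attenuation = cfg$synth$rp_p2_attenuation)
    simulate_fvep(cfg$synth$n_normal, cfg$synth$n_rp, cfg$synth$n_abnormal,
                  params = params, rng_seed = seed)
  }

  split <- split_by_patient(records,
                            train_fraction = cfg$split$train_fraction,
                            abnormal_train_fraction = cfg$split$abnormal_train_fraction,
                            seed = seed)

  tcfg <- train_config(
    lr_main = cfg$train$lr_main,
    lr_local_pretrained = cfg$train$lr_local_pretrained,
    batch_size = cfg$train$batch_size, epochs = cfg$train$epochs,
    seed = seed,
    loss = loss_config(gamma = cfg$train$gamma, lam = cfg$train$lambda,
                       hint_fraction = cfg$train$hint_fraction),
    denoise = isTRUE(cfg$denoise$enabled),
    abnormal_exposure = isTRUE(cfg$train$abnormal_exposure),
    abnormal_weight = cfg$train$abnormal_weight)

  pre <- NULL
  if (isTRUE(cfg$pretrain$enabled)) {
    pool <- split_side(records, split, "train")
    pre <- pretrain_autoencoder(pool, config = tcfg$model,
                                epochs = cfg$pretrain$epochs, seed = seed)
  }

  fit <- train_mcac(records, split, tcfg, pretrained = pre)

  test_rec <- split_side(records, split, "test")
  test_lab <- test_rec[test_rec$label %in% fit$class_levels, , drop = FALSE]
  cls_metrics <- evaluate_classification(fit, test_lab)

  methods <- cfg$ood$methods
  if (identical(methods, "all")) {
    methods <- c("confidence", "entropy", "lof", "ocsvm", "mcd")
  }
  train_rec <- split_side(records, split, "train")
  train_in <- train_rec[train_rec$label %in% fit$class_levels, , drop = FALSE]
  train_out <- train_rec[train_rec$label == "abnormal", , drop = FALSE]
  test_in <- test_lab
  test_out <- test_rec[test_rec$label == "abnormal", , drop = FALSE]

  ood_tbl <- NULL
  if (nrow(test_out) > 0L && nrow(train_out) > 0L) {
    rows <- list()
    for (m in methods) {
      sc_tr_in <- score_method(fit, m, train_in, train_in, seed)
      sc_tr_out <- score_method(fit, m, train_out, train_in, seed)
      thr <- choose_threshold(sc_tr_in, sc_tr_out)
      sc_te_in <- score_method(fit, m, test_in, train_in, seed)
      sc_te_out <- score_method(fit, m, test_out, train_in, seed)
      y_true <- rep(c(0, 1), c(length(sc_te_in), length(sc_te_out)))
      s_all <- c(sc_te_in, sc_te_out)
      cm <- confusion_metrics(y_true, as.numeric(s_all > thr$threshold))
      rows[[m]] <- dplyr::bind_cols(tibble(method = m,
                                           threshold = thr$threshold),
                                    cm,
                                    tibble(auc = auc_score(s_all, y_true)))
    }
    ood_tbl <- bind_rows(rows)
  }

  result <- list(fit = fit, metrics = cls_metrics, ood = ood_tbl,
                 split = split, records = records, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    readr::write_csv(tidy(split), file.path(out_dir, "split_manifest.csv"))
    readr::write_csv(fit$log, file.path(out_dir, "epoch_log.csv"))
    preds <- dplyr::bind_cols(
      test_lab[, c("patient_id", "eye", "repeat_index", "label")],
      predict(fit, test_lab))
    readr::write_csv(preds, file.path(out_dir, "predictions.csv"))
    metrics_out <- list(classification = as.list(cls_metrics))
    if (!is.null(ood_tbl)) {
      metrics_out$ood <- lapply(split(ood_tbl, ood_tbl$method), as.list)
    }
    jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

# one method's scores as a bare numeric vector (detectors are refitted
# deterministically from the seed, so repeated calls agree)
score_method <- function(fit, method, records, train_in, seed) {
  if (method == "confidence") return(confidence_score(fit, records)$score)
  if (method == "entropy") return(entropy_score_records(fit, records)$score)
  det <- fit_feature_detector(method, mcac_embeddings(fit, train_in),
                              seed = seed)
  score_ood(det, mcac_embeddings(fit, records))$score
}
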