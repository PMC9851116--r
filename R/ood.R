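# Out-of-distribution detection: the confidence-branch detector, the
# entropy baseline on the softmax output, and three classical novelty
# detectors (LOF, one-class SVM, minimum covariance determinant) fitted on
# the penultimate fusion-layer embedding of in-distribution training
# records. All scores are oriented so that HIGHER = more likely
# out-of-distribution.

#' Entropy of the class-probability output
#'
#' Shannon entropy (natural log) of each row: `-sum(p * log(p))`, floored at
#' `eps`. High entropy (near `log(M)`) marks uncertain predictions and is
#' the training-free OOD baseline.
#'
#' @param p Probability vector or n x M matrix.
#' @param eps Log floor.
#' @return Numeric scalar or length-n vector.
#' @export
entropy_score <- function(p, eps = 1e-12) {
  pm <- if (is.matrix(p)) p else matrix(p, 1L)
  out <- -rowSums(pm * log(pmax(pm, eps)))
  if (is.matrix(p)) out else out[1L]
}

#' Confidence-branch OOD score
#'
#' `score = 1 - c`: records with low predicted confidence are likely
#' out-of-distribution.
#'
#' @param fit An `mcac_fit`.
#' @param records Record tibble.
#' @return Tibble with columns `score` and `method = "confidence"`.
#' @export
confidence_score <- function(fit, records) {
  pred <- predict(fit, records)
  tibble(score = 1 - pred$confidence, method = "confidence")
}

#' Entropy OOD score for records
#'
#' @param fit An `mcac_fit`.
#' @param records Record tibble.
#' @return Tibble with columns `score` and `method = "entropy"`.
#' @export
entropy_score_records <- function(fit, records) {
  pred <- predict(fit, records)
  pm <- as.matrix(pred[, paste0("p_", fit$class_levels)])
  tibble(score = entropy_score(pm), method = "entropy")
}

# ---- feature-space novelty detectors -------------------------------------

# Local outlier factor machinery (Breunig et al. definition), in novelty
# mode: densities are estimated on the training cloud only.
lof_fit_train <- function(X, k) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ord <- apply(D, 1L, order)
  kdist <- vapply(seq_len(n), function(i) D[i, ord[k, i]], numeric(1))
  # neighbourhood = all points within the k-distance (ties included)
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= kdist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    rd <- pmax(kdist[neigh[[i]]], D[i, neigh[[i]]])
    1 / max(mean(rd), .Machine$double.eps)
  }, numeric(1))
  list(X = X, k = k, kdist = kdist, lrd = lrd)
}

lof_score_new <- function(fit, Xnew) {
  n <- nrow(fit$X)
  vapply(seq_len(nrow(Xnew)), function(j) {
    d <- sqrt(colSums((t(fit$X) - Xnew[j, ])^2))
    ord <- order(d)
    kd <- d[ord[fit$k]]
    nb <- which(d <= kd)
    rd <- pmax(fit$kdist[nb], d[nb])
    lrd_x <- 1 / max(mean(rd), .Machine$double.eps)
    mean(fit$lrd[nb]) / lrd_x
  }, numeric(1))
}

#' Fit a feature-space novelty detector
#'
#' Fits LOF, a one-class SVM (RBF), or a minimum-covariance-determinant
#' robust Mahalanobis detector on the penultimate embeddings of
#' in-distribution training records. Near-constant embedding dimensions
#' (dead units) are dropped before fitting.
#'
#' @param kind `"lof"`, `"ocsvm"` or `"mcd"`.
#' @param embeddings n x d numeric matrix of training embeddings.
#' @param k LOF neighbour count.
#' @param nu One-class SVM nu.
#' @param seed Seed for the MCD subsampling search.
#' @return Object of class `ood_detector`; score new embeddings with
#'   [score_ood()] (higher = more anomalous).
#' @export
fit_feature_detector <- function(kind = c("lof", "ocsvm", "mcd"), embeddings,
                                 k = 20L, nu = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  embeddings <- as.matrix(embeddings)
  min_n <- c(lof = 2L, ocsvm = 2L, mcd = 5L)[[kind]]
  if (nrow(embeddings) < min_n) {
    abort(paste0("need at least ", min_n, " embeddings to fit ", kind),
          class = "fvepnet_too_few")
  }
  keep <- which(apply(embeddings, 2L, sd) > 1e-8)
  if (length(keep) == 0L) abort("all embedding dimensions are constant",
                                class = "fvepnet_degenerate_embeddings")
  X <- embeddings[, keep, drop = FALSE]
  fit <- switch(kind,
    lof = lof_fit_train(X, k),
    ocsvm = e1071::svm(X, type = "one-classification", kernel = "radial",
                       nu = nu, scale = TRUE),
    mcd = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(derive_seed(seed, 53L))
      # the MCD search additionally needs spread in every coordinate's
      # central half; zero-IQR columns (mostly-inactive units) are dropped
      iqr_ok <- which(apply(X, 2L, stats::IQR) > 0)
      if (length(iqr_ok) >= 2L) {
        keep <- keep[iqr_ok]
        X <- X[, iqr_ok, drop = FALSE]
      }
      rob <- if (nrow(X) > 2L * ncol(X) + 2L && length(iqr_ok) >= 2L) {
        MASS::cov.rob(X, method = "mcd")
      } else {
        # too few points for a stable MCD search in this dimension:
        # fall back to the classical estimate (documented degenerate path)
        list(center = colMeans(X), cov = cov(X))
      }
      covr <- rob$cov + diag(1e-8 * max(diag(rob$cov), 1e-12), ncol(X))
      list(center = rob$center, cov = covr)
    })
  structure(list(kind = kind, fit = fit, keep = keep),
            class = "ood_detector")
}

#' Score embeddings with a fitted novelty detector
#'
#' @param detector A [fit_feature_detector()] object.
#' @param embeddings n x d matrix (same embedding space as the fit).
#' @return Tibble with columns `score` (higher = more anomalous) and
#'   `method`.
#' @export
score_ood <- function(detector, embeddings) {
  stopifnot(inherits(detector, "ood_detector"))
  X <- as.matrix(embeddings)[, detector$keep, drop = FALSE]
  s <- switch(detector$kind,
    lof = lof_score_new(detector$fit, X),
    # decision values are positive inside the learned region
    ocsvm = -as.numeric(predict(detector$fit, X, decision.values = TRUE) |>
                          attr("decision.values")),
    mcd = mahalanobis(X, detector$fit$center, detector$fit$cov))
  tibble(score = s, method = detector$kind)
}

#' @export
print.ood_detector <- function(x, ...) {
  cat("<ood_detector> ", x$kind, " on ", length(x$keep),
      " embedding dimensions\n", sep = "")
  invisible(x)
}

#' Choose an OOD decision threshold
#'
#' Scans all midpoints between adjacent observed score values (plus the
#' extremes) and returns the threshold maximizing F1 over the pooled
#' in/out scores, treating out-of-distribution as the positive class and
#' flagging a record when `score > threshold`. The ranking AUC is reported
#' alongside.
#'
#' @param scores_in Scores of in-distribution records (vector or a
#'   [score_ood()] tibble).
#' @param scores_out Scores of out-of-distribution records.
#' @return List with `threshold`, `f1` and `auc`.
#' @export
choose_threshold <- function(scores_in, scores_out) {
  si <- if (is.data.frame(scores_in)) scores_in$score else scores_in
  so <- if (is.data.frame(scores_out)) scores_out$score else scores_out
  if (length(si) == 0L || length(so) == 0L) {
    abort("both score sets must be non-empty", class = "fvepnet_empty_scores")
  }
  all_s <- c(si, so)
  labs <- rep(c(0, 1), c(length(si), length(so)))
  u <- sort(unique(all_s))
  if (length(u) == 1L) abort("all scores identical; no threshold separates them",
                             class = "fvepnet_degenerate_scores")
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  f1s <- vapply(cand, function(thr) {
    pred <- as.numeric(all_s > thr)
    tp <- sum(pred == 1 & labs == 1)
    fp <- sum(pred == 1 & labs == 0)
    fn <- sum(pred == 0 & labs == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(threshold = cand[which.max(f1s)], f1 = max(f1s),
       auc = auc_score(all_s, labs))
}

#' Score records with every OOD method
#'
#' Convenience wrapper running the confidence and entropy detectors plus the
#' three feature-space detectors (fitted on the training embeddings) over a
#' set of records.
#'
#' @param fit An `mcac_fit`.
#' @param records Records to score.
#' @param train_records In-distribution (normal + RP) training records used
#'   to fit the feature-space detectors.
#' @param methods Subset of `c("confidence", "entropy", "lof", "ocsvm",
#'   "mcd")`.
#' @param seed Seed for the MCD search.
#' @return Tibble with columns `record` (row index), `method`, `score`.
#' @export
score_all_methods <- function(fit, records, train_records,
                              methods = c("confidence", "entropy", "lof",
                                          "ocsvm", "mcd"), seed = 1L) {
  out <- list()
  if (any(methods %in% c("lof", "ocsvm", "mcd"))) {
    emb_train <- mcac_embeddings(fit, train_records)
    emb_new <- mcac_embeddings(fit, records)
  }
  for (m in methods) {
    sc <- switch(m,
      confidence = confidence_score(fit, records),
      entropy = entropy_score_records(fit, records),
      score_ood(fit_feature_detector(m, emb_train, seed = seed), emb_new))
    out[[m]] <- dplyr::mutate(sc, record = dplyr::row_number())
  }
  bind_rows(out)[, c("record", "method", "score")]
}
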