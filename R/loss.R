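# Confidence-hinted focal loss.
#
# During training the softmax output is interpolated toward the true label
# in proportion to (1 - c): p_hat = c * p + (1 - c) * y. The focal term is
#   Lt = -sum_i [ y_i (1 - p_hat_i)^gamma log(p_hat_i)
#                 + (1 - y_i) p_hat_i log(1 - p_hat_i) ]
# (the negative-class term carries no gamma exponent in this form; set
# symmetric_gamma = TRUE for the standard focal variant with p_hat_i^gamma).
# A confidence penalty Lc = -log(c) keeps the network from collapsing to
# c = 0, and the batch loss is L = mean(Lt) + lambda * mean(Lc).

#' Loss configuration
#'
#' @param gamma Focusing exponent of the focal term (>= 0).
#' @param lam Weight of the confidence penalty.
#' @param hint_fraction Fraction of each batch whose predictions are hinted
#'   toward the label via the confidence interpolation.
#' @param eps Numerical floor applied inside logarithms.
#' @param symmetric_gamma Apply the gamma exponent to the negative-class
#'   term as in the standard focal loss (default `FALSE`: the negative-class
#'   term is plain `p_hat * log(1 - p_hat)`).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(gamma = 2, lam = 0.1, hint_fraction = 0.5,
                        eps = 1e-12, symmetric_gamma = FALSE) {
  if (gamma < 0 || lam < 0) abort("gamma and lam must be non-negative",
                                  class = "fvepnet_bad_config")
  if (hint_fraction < 0 || hint_fraction > 1) {
    abort("hint_fraction must lie in [0, 1]", class = "fvepnet_bad_config")
  }
  structure(list(gamma = gamma, lam = lam, hint_fraction = hint_fraction,
                 eps = eps, symmetric_gamma = isTRUE(symmetric_gamma)),
            class = "loss_config")
}

check_one_hot <- function(y) {
  ym <- if (is.matrix(y)) y else matrix(y, 1L)
  if (!all(ym %in% c(0, 1)) || any(rowSums(ym) != 1)) {
    abort("y must be one-hot", class = "fvepnet_bad_one_hot")
  }
  ym
}

#' Confidence-hinted class probabilities
#'
#' Interpolates the softmax output toward the one-hot label:
#' `p_hat = c * p + (1 - c) * y`. With `c = 1` the prediction is unchanged;
#' with `c = 0` it is replaced by the label.
#'
#' @param p Probability vector (or n x M matrix, rows summing to 1).
#' @param confidence Confidence scalar in \[0, 1\] (or length-n vector).
#' @param y One-hot label vector (or n x M matrix).
#' @return Hinted probabilities, same shape as `p` (rows still sum to 1).
#' @export
hinted_probs <- function(p, confidence, y) {
  pm <- if (is.matrix(p)) p else matrix(p, 1L)
  ym <- check_one_hot(y)
  if (any(confidence < 0 | confidence > 1)) {
    abort("confidence must lie in [0, 1]", class = "fvepnet_bad_confidence")
  }
  out <- confidence * pm + (1 - confidence) * ym
  if (is.matrix(p)) out else drop(out)
}

# per-class focal terms; pm/ym matrices, returns per-record row sums
focal_terms <- function(pm, ym, gamma, symmetric_gamma, eps) {
  ph <- pmin(pmax(pm, eps), 1 - eps)
  pos <- (1 - ph)^gamma * log(ph)
  neg <- if (symmetric_gamma) ph^gamma * log(1 - ph) else ph * log(1 - ph)
  -rowSums(ym * pos + (1 - ym) * neg)
}

#' Focal loss of a (hinted) prediction
#'
#' @param p_hat Probability vector in the simplex (or n x M matrix).
#' @param y One-hot label (or matrix).
#' @param gamma Focusing exponent.
#' @param symmetric_gamma See [loss_config()].
#' @param eps Log floor.
#' @return Scalar loss for a vector input; per-record vector for a matrix.
#' @export
focal_loss <- function(p_hat, y, gamma = 2, symmetric_gamma = FALSE,
                       eps = 1e-12) {
  pm <- if (is.matrix(p_hat)) p_hat else matrix(p_hat, 1L)
  if (any(pm < -eps | pm > 1 + eps)) {
    abort("p_hat must lie in [0, 1]", class = "fvepnet_bad_probs")
  }
  ym <- check_one_hot(y)
  out <- focal_terms(pm, ym, gamma, symmetric_gamma, eps)
  if (is.matrix(p_hat)) out else out[1L]
}

#' Confidence penalty
#'
#' `Lc = -log(c)` (natural log), floored at `eps`.
#'
#' @param confidence Confidence scalar or vector.
#' @param eps Log floor.
#' @return Same shape as `confidence`.
#' @export
confidence_loss <- function(confidence, eps = 1e-12) {
  -log(pmax(confidence, eps))
}

# Deterministic hint subset of a batch.
hint_mask_for_batch <- function(n, hint_fraction, rng_seed) {
  n_hint <- round(hint_fraction * n)
  mask <- rep(FALSE, n)
  if (n_hint > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(rng_seed, 97L))
    mask[sample.int(n, n_hint)] <- TRUE
  }
  mask
}

#' Total training loss over a batch
#'
#' A `hint_fraction` subset of the batch (selected by the seeded RNG, or an
#' explicit `hint_mask`) has its probabilities hinted via [hinted_probs()];
#' the rest are used as-is. The result is
#' `mean(focal) + lam * mean(confidence penalty)`.
#'
#' @param p n x M probability matrix.
#' @param confidence Length-n confidence vector.
#' @param y n x M one-hot matrix.
#' @param cfg A [loss_config()].
#' @param rng_seed Seed selecting the hinted subset.
#' @param hint_mask Optional explicit logical mask overriding the RNG.
#' @return Scalar loss, with attribute `"components"` holding the focal and
#'   confidence means.
#' @export
total_loss <- function(p, confidence, y, cfg = loss_config(), rng_seed = 1L,
                       hint_mask = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  if (!is.matrix(p) || nrow(p) == 0L) {
    abort("p must be a non-empty n x M probability matrix",
          class = "fvepnet_empty_batch")
  }
  ym <- check_one_hot(y)
  n <- nrow(p)
  if (is.null(hint_mask)) {
    hint_mask <- hint_mask_for_batch(n, cfg$hint_fraction, rng_seed)
  }
  ph <- p
  if (any(hint_mask)) {
    ph[hint_mask, ] <- hinted_probs(p[hint_mask, , drop = FALSE],
                                    confidence[hint_mask],
                                    ym[hint_mask, , drop = FALSE])
  }
  lt <- mean(focal_terms(ph, ym, cfg$gamma, cfg$symmetric_gamma, cfg$eps))
  lc <- mean(confidence_loss(confidence, cfg$eps))
  structure(lt + cfg$lam * lc, components = c(focal = lt, confidence = lc))
}

# d(focal)/d(p_hat), elementwise over a batch (clamped interior).
focal_grad_phat <- function(ph, ym, gamma, symmetric_gamma, eps) {
  ph <- pmin(pmax(ph, eps), 1 - eps)
  dpos <- -gamma * (1 - ph)^(gamma - 1) * log(ph) + (1 - ph)^gamma / ph
  dneg <- if (symmetric_gamma) {
    gamma * ph^(gamma - 1) * log(1 - ph) - ph^gamma / (1 - ph)
  } else {
    log(1 - ph) - ph / (1 - ph)
  }
  -(ym * dpos + (1 - ym) * dneg)
}

# Loss value plus gradients w.r.t. class logits and the confidence logit
# (i.e. after the softmax / sigmoid Jacobians). Used by the training loop;
# verified against finite differences in the tests.
total_loss_grad <- function(p, confidence, y, cfg, hint_mask) {
  n <- nrow(p)
  ym <- y
  ph <- p
  cvec <- confidence
  if (any(hint_mask)) {
    ph[hint_mask, ] <- cvec[hint_mask] * p[hint_mask, , drop = FALSE] +
      (1 - cvec[hint_mask]) * ym[hint_mask, , drop = FALSE]
  }
  lt_vec <- focal_terms(ph, ym, cfg$gamma, cfg$symmetric_gamma, cfg$eps)
  lc_vec <- confidence_loss(cvec, cfg$eps)
  loss <- mean(lt_vec) + cfg$lam * mean(lc_vec)

  dph <- focal_grad_phat(ph, ym, cfg$gamma, cfg$symmetric_gamma, cfg$eps) / n
  dp <- dph
  dp[hint_mask, ] <- dph[hint_mask, , drop = FALSE] * cvec[hint_mask]
  dc <- numeric(n)
  if (any(hint_mask)) {
    dc[hint_mask] <- rowSums(dph[hint_mask, , drop = FALSE] *
                               (p[hint_mask, , drop = FALSE] -
                                  ym[hint_mask, , drop = FALSE]))
  }
  dc <- dc - cfg$lam / n / pmax(cvec, cfg$eps)

  # softmax and sigmoid Jacobians
  dzp <- p * (dp - rowSums(p * dp))
  dzc <- dc * cvec * (1 - cvec)
  list(loss = loss, dzp = dzp, dzc = dzc,
       components = c(focal = mean(lt_vec), confidence = mean(lc_vec)))
}
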