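# Shared fixtures and independent oracles. Everything is generated in code
# at test time; the trained small fit is memoised so several test files can
# reuse it.

.fixture_env <- new.env(parent = emptyenv())

# Clean deterministic waveform parameters (no noise, drift, offset, and a
# strictly P2-only RP contrast) for algebraic assertions.
clean_params <- function(rp_p2_attenuation = 0.5) {
  fvep_waveform_params(noise_sd = 0, drift_amplitude = 0,
                       baseline_offset_sd = 0,
                       rp_p2_attenuation = rp_p2_attenuation,
                       rp_secondary_attenuation = 1,
                       latency_jitter_sd = 0, amplitude_jitter_sd = 0)
}

# A small trained model shared across test files (patients: 12 normal,
# 12 RP, 6 abnormal; 8 epochs).
get_small_fit <- function() {
  if (is.null(.fixture_env$small_fit)) {
    records <- simulate_fvep(12, 12, 6, rng_seed = 11)
    split <- split_by_patient(records, seed = 11)
    fit <- train_mcac(records, split,
                      train_config(epochs = 12, seed = 11, batch_size = 64))
    .fixture_env$small_fit <- list(fit = fit, records = records,
                                   split = split)
  }
  .fixture_env$small_fit
}

# ---- independent oracles -------------------------------------------------

# Scalar-loop implementation of the hinted focal loss (Eqs. written out
# element by element, no vectorization shared with the implementation).
oracle_total_loss <- function(p, conf, y, gamma, lam, symmetric_gamma,
                              hint_mask, eps = 1e-12) {
  n <- nrow(p); M <- ncol(p)
  lt_sum <- 0
  lc_sum <- 0
  for (i in seq_len(n)) {
    ph <- numeric(M)
    for (j in seq_len(M)) {
      ph[j] <- if (hint_mask[i]) conf[i] * p[i, j] + (1 - conf[i]) * y[i, j]
               else p[i, j]
      ph[j] <- min(max(ph[j], eps), 1 - eps)
    }
    lt_i <- 0
    for (j in seq_len(M)) {
      if (y[i, j] == 1) {
        lt_i <- lt_i - (1 - ph[j])^gamma * log(ph[j])
      } else {
        neg <- if (symmetric_gamma) ph[j]^gamma else ph[j]
        lt_i <- lt_i - neg * log(1 - ph[j])
      }
    }
    lt_sum <- lt_sum + lt_i
    lc_sum <- lc_sum - log(max(conf[i], eps))
  }
  lt_sum / n + lam * lc_sum / n
}

# O(n^2) pairwise AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# counting-based confusion metrics
oracle_confusion <- function(y_true, y_pred) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# spectral energy above a cutoff frequency (Hz) at fs = 1000
energy_above <- function(x, cutoff = 100) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * 1000 / n
  sum(sp[freqs > cutoff & freqs <= 500])
}

# random softmax rows
random_probs <- function(n, M) {
  Z <- matrix(stats::rexp(n * M), n, M)
  Z / rowSums(Z)
}

random_one_hot <- function(n, M) {
  Y <- matrix(0, n, M)
  Y[cbind(seq_len(n), sample.int(M, n, replace = TRUE))] <- 1
  Y
}
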