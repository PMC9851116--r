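# Temporal / statistical / spectral feature extraction, variance and
# Pearson feature selection, and the 7-element manual feature vector fed to
# the network's manual branch.

# Level-3 Haar discrete wavelet transform detail energies. Input length
# must be divisible by 8 (320 is). Returned as (d1, d2, d3) energies.
haar_detail_energies <- function(x, levels = 3L) {
  out <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    n <- length(a)
    odd <- a[seq(1, n - 1, by = 2)]
    even <- a[seq(2, n, by = 2)]
    d <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
    out[l] <- sum(d^2)
  }
  out
}

lag1_autocorrelation <- function(x) {
  if (sd(x) == 0) return(NA_real_)
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[-n] * xc[-1]) / sum(xc^2)
}

spectral_features <- function(x) {
  n <- length(x)
  sp <- fft(x)
  half <- 2:(n %/% 2 + 1)            # positive frequencies, DC excluded
  mag <- Mod(sp[half])
  freqs <- (half - 1) * FVEP_FS / n
  pow <- mag^2
  c(fft_mean_coef = mean(mag),
    spectral_centroid = if (sum(pow) > 0) sum(freqs * pow) / sum(pow) else NA_real_,
    band_power = sum(pow) / n)
}

single_record_features <- function(sig, age) {
  s <- sd(sig)
  hist_counts <- as.numeric(table(cut(sig,
    breaks = if (max(sig) > min(sig)) seq(min(sig), max(sig), length.out = 11)
             else seq(min(sig) - 0.5, max(sig) + 0.5, length.out = 11),
    include.lowest = TRUE)))
  sampen <- if (s == 0) NA_real_ else
    suppressWarnings(pracma::sample_entropy(sig, edim = 2, r = 0.2 * s))
  spec <- spectral_features(sig)
  dwt <- haar_detail_energies(sig)
  c(autocorr_lag1 = lag1_autocorrelation(sig),
    mean_abs_diff = mean(abs(diff(sig))),
    sample_entropy = sampen,
    max = max(sig), min = min(sig), median = median(sig),
    mean = mean(sig), sd = s, iqr = stats::IQR(sig),
    setNames(hist_counts, paste0("hist_bin", 1:10)),
    peak_to_peak = max(sig) - min(sig),
    spec,
    dwt_energy_d1 = dwt[1], dwt_energy_d2 = dwt[2], dwt_energy_d3 = dwt[3],
    age = as.numeric(age))
}

feature_domain_map <- function(feature_names) {
  dom <- rep("statistical", length(feature_names))
  dom[feature_names %in% c("autocorr_lag1", "mean_abs_diff",
                           "sample_entropy")] <- "temporal"
  dom[grepl("^(fft_mean_coef|spectral_centroid|band_power|dwt_energy)",
            feature_names)] <- "spectral"
  dom[feature_names == "age"] <- "meta"
  tibble(feature = feature_names, domain = dom)
}

#' Extract temporal, statistical and spectral features from FVEP records
#'
#' Computes a fixed catalogue of per-sweep features across three domains --
#' temporal (lag-1 autocorrelation, mean absolute first difference, sample
#' entropy), statistical (max, min, median, mean, SD, IQR, 10-bin histogram
#' counts, peak-to-peak amplitude) and spectral (FFT mean coefficient
#' magnitude, spectral centroid, total band power, level-3 Haar wavelet
#' detail energies) -- plus patient age as a meta feature. Degenerate
#' features on constant input (autocorrelation, sample entropy, spectral
#' centroid) are replaced by 0 with a warning.
#'
#' @param records Record tibble (see [simulate_fvep()]).
#' @return A tibble of one row per record; feature domains are attached as
#'   the `"domains"` attribute (a feature/domain tibble, see
#'   [feature_domains()]).
#' @export
extract_features <- function(records) {
  check_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i)
    single_record_features(records$signal[[i]], records$age[i]))
  mat <- do.call(rbind, rows)
  if (anyNA(mat)) {
    warn("degenerate features on constant input replaced by 0",
         class = "fvepnet_degenerate_features")
    mat[is.na(mat)] <- 0
  }
  out <- as_tibble(mat)
  attr(out, "domains") <- feature_domain_map(colnames(mat))
  out
}

#' Feature-domain provenance of a feature table
#'
#' @param table A [extract_features()] result.
#' @return Tibble with columns `feature` and `domain`
#'   (temporal / statistical / spectral / meta).
#' @export
feature_domains <- function(table) {
  attr(table, "domains") %||% feature_domain_map(names(table))
}

#' Drop low-variance features
#'
#' Removes every column whose sample variance is less than or equal to
#' `threshold`; with the default threshold 0 exactly the zero-variance
#' (constant) features are rejected.
#'
#' @param table Feature tibble (numeric columns).
#' @param threshold Non-negative variance cutoff.
#' @return The filtered tibble (column order and names preserved).
#' @export
variance_filter <- function(table, threshold = 0) {
  if (threshold < 0) abort("threshold must be non-negative",
                           class = "fvepnet_bad_params")
  v <- vapply(table, var, numeric(1))
  keep <- v > threshold
  if (!any(keep)) abort("all features removed by the variance filter",
                        class = "fvepnet_degenerate_table")
  dom <- attr(table, "domains")
  out <- table[, keep, drop = FALSE]
  if (!is.null(dom)) attr(out, "domains") <- dom[dom$feature %in% names(out), ]
  out
}

#' Select features by Pearson correlation with a binary label
#'
#' Keeps every column whose absolute Pearson correlation with the label
#' vector is at least `min_abs_r`. A zero-variance column has correlation
#' defined as 0 (and is therefore dropped for any positive threshold).
#'
#' @param table Feature tibble.
#' @param labels Binary 0/1 vector, one per row.
#' @param min_abs_r Threshold on |r| in \[0, 1\].
#' @return Filtered tibble; per-feature correlations are attached as the
#'   `"pearson_r"` attribute (named numeric vector over the input columns).
#' @export
pearson_select <- function(table, labels, min_abs_r = 0.1) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) {
    abort("labels must be binary 0/1", class = "fvepnet_bad_labels")
  }
  if (length(labels) != nrow(table)) {
    abort("labels length must equal the number of rows",
          class = "fvepnet_bad_labels")
  }
  if (var(labels) == 0) {
    abort("labels are all identical; correlation undefined",
          class = "fvepnet_degenerate_labels")
  }
  if (min_abs_r < 0 || min_abs_r > 1) {
    abort("min_abs_r must lie in [0, 1]", class = "fvepnet_bad_params")
  }
  r <- vapply(table, function(col) {
    if (var(col) == 0) 0 else cor(col, labels)
  }, numeric(1))
  keep <- abs(r) >= min_abs_r
  dom <- attr(table, "domains")
  out <- table[, keep, drop = FALSE]
  if (!is.null(dom)) attr(out, "domains") <- dom[dom$feature %in% names(out), ]
  attr(out, "pearson_r") <- r
  out
}

#' The 7-element manual feature vector
#'
#' Computes, per record and in this fixed order: peak-to-peak amplitude;
#' maximum amplitude within the P2 search window; latency (ms post-trigger)
#' of that maximum (ties broken to the first sample); signal standard
#' deviation; signal median; mean absolute first difference; and age. The
#' P2 window defaults to 100--180 ms post-trigger and is configurable
#' because clinical P2 marking is expert annotation this package does not
#' have.
#'
#' @param records Record tibble.
#' @param p2_window Length-2 numeric: P2 search window in ms post-trigger.
#' @return Tibble with columns `peak_to_peak`, `p2_amplitude`,
#'   `p2_latency_ms`, `signal_sd`, `signal_median`, `mean_abs_diff`, `age`.
#' @export
manual_features <- function(records, p2_window = c(100, 180)) {
  check_records(records)
  i0 <- latency_to_sample(p2_window[1])
  i1 <- latency_to_sample(p2_window[2])
  rows <- lapply(seq_len(nrow(records)), function(i) {
    sig <- records$signal[[i]]
    win <- sig[i0:i1]
    jmax <- which.max(win)
    c(peak_to_peak = max(sig) - min(sig),
      p2_amplitude = win[jmax],
      p2_latency_ms = p2_window[1] + jmax - 1,
      signal_sd = sd(sig),
      signal_median = median(sig),
      mean_abs_diff = mean(abs(diff(sig))),
      age = as.numeric(records$age[i]))
  })
  as_tibble(do.call(rbind, rows))
}
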