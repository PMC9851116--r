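# Synthetic FVEP generator.
#
# A sweep is modelled as a sum of Gaussian-shaped component bumps (N1, P1,
# N2, P2, N3, P3) on a flat baseline, plus slow sinusoidal drift and white
# Gaussian noise. The retinitis-pigmentosa contrast is a multiplicative
# attenuation of the P2 amplitude with its latency left untouched; this is
# the clinically described signature (reduced P2 amplitude, unchanged peak
# time). Abnormal / out-of-distribution sweeps are one of: a global latency
# shift of all components by >= 30 ms, a near-flat response, or a
# noise-dominated sweep.

#' Waveform parameters for the synthetic FVEP generator
#'
#' Defines the canonical component peaks, their Gaussian widths, noise and
#' drift levels, and the RP-specific P2 attenuation. The default latencies
#' and amplitudes are synthetic choices shaped like a typical adult flash
#' VEP; only the RP contrast (P2 amplitude down, latency unchanged) is a
#' modelling commitment.
#'
#' @param latencies Named numeric vector of component peak latencies in ms
#'   post-trigger; must be strictly increasing within \[0, 300\].
#' @param amplitudes Named numeric vector of component peak amplitudes (uV);
#'   names must match `latencies`.
#' @param widths Gaussian standard deviations per component (ms).
#' @param noise_sd Standard deviation of additive white Gaussian noise (uV).
#' @param drift_amplitude Amplitude of a slow (0.5--1.5 Hz) sinusoidal
#'   baseline drift (uV).
#' @param baseline_offset_sd SD of a per-record constant baseline offset
#'   (uV), emulating residual offset surviving the high-pass filter and
#'   averaging; absolute-amplitude features are sensitive to it while
#'   peak-to-peak measures are not, which is why clinical practice prefers
#'   the latter.
#' @param rp_p2_attenuation Multiplicative factor in (0, 1) applied to the P2
#'   amplitude for RP-class records (the named clinical marker).
#' @param rp_secondary_attenuation Milder multiplicative factor in (0, 1\]
#'   applied to all other components for RP-class records: generalized
#'   retinal dysfunction reduces the whole cortical response, most
#'   prominently P2. Set to 1 for a strictly P2-only contrast.
#' @param latency_jitter_sd Patient-level common latency shift SD (ms).
#' @param amplitude_jitter_sd Patient-level log-normal amplitude scale SD.
#' @param bandpass If `TRUE`, band-pass the additive noise 0.312--100 Hz to
#'   mimic the acquisition filter (off by default).
#' @return An object of class `fvep_params` (a named list).
#' @export
#' @examples
#' p <- fvep_waveform_params(noise_sd = 0)
#' r <- generate_record("normal", p, rng_seed = 1)
#' which.max(r$signal[[1]][21:320])  # peak at the P2 latency
fvep_waveform_params <- function(latencies = c(N1 = 45, P1 = 75, N2 = 105,
                                               P2 = 135, N3 = 180, P3 = 220),
                                 amplitudes = c(N1 = -3, P1 = 4, N2 = -4,
                                                P2 = 8, N3 = -5, P3 = 5),
                                 widths = c(N1 = 10, P1 = 10, N2 = 12,
                                            P2 = 15, N3 = 18, P3 = 20),
                                 noise_sd = 1,
                                 drift_amplitude = 0.5,
                                 baseline_offset_sd = 1.5,
                                 rp_p2_attenuation = 0.5,
                                 rp_secondary_attenuation = 0.75,
                                 latency_jitter_sd = 5,
                                 amplitude_jitter_sd = 0.15,
                                 bandpass = FALSE) {
  if (is.null(names(latencies)) || !identical(names(latencies), names(amplitudes)) ||
      !identical(names(latencies), names(widths))) {
    abort("latencies, amplitudes and widths must share the same component names",
          class = "fvepnet_bad_params")
  }
  if (any(diff(latencies) <= 0) || any(latencies < 0) || any(latencies > 300)) {
    abort("component latencies must be strictly increasing within [0, 300] ms",
          class = "fvepnet_bad_params")
  }
  if (!is.numeric(rp_p2_attenuation) || rp_p2_attenuation <= 0 ||
      rp_p2_attenuation >= 1) {
    abort("rp_p2_attenuation must lie strictly inside (0, 1)",
          class = "fvepnet_bad_params")
  }
  if (rp_secondary_attenuation <= 0 || rp_secondary_attenuation > 1) {
    abort("rp_secondary_attenuation must lie in (0, 1]",
          class = "fvepnet_bad_params")
  }
  if (noise_sd < 0 || drift_amplitude < 0 || baseline_offset_sd < 0) {
    abort("noise_sd, drift_amplitude and baseline_offset_sd must be non-negative",
          class = "fvepnet_bad_params")
  }
  structure(list(latencies = latencies, amplitudes = amplitudes,
                 widths = widths, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 baseline_offset_sd = baseline_offset_sd,
                 rp_p2_attenuation = rp_p2_attenuation,
                 rp_secondary_attenuation = rp_secondary_attenuation,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 bandpass = bandpass),
            class = "fvep_params")
}

# Deterministic clean waveform: sum of Gaussian bumps at the configured
# latencies, offset by the 20-sample pre-trigger.
component_sum <- function(latencies, amplitudes, widths) {
  t_ms <- fvep_time_axis()
  sig <- numeric(FVEP_LENGTH)
  for (k in seq_along(latencies)) {
    sig <- sig + amplitudes[[k]] * exp(-((t_ms - latencies[[k]])^2) /
                                         (2 * widths[[k]]^2))
  }
  sig
}

bandpass_noise <- function(x) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    abort("the 'signal' package is required for band-passed noise",
          class = "fvepnet_missing_dep")
  }
  # 2nd-order Butterworth band-pass 0.312-100 Hz at fs = 1000 Hz.
  bf <- signal::butter(2, c(0.312, 100) / (FVEP_FS / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# One sweep for a given class, with params already carrying any
# patient-level perturbations.
render_signal <- function(label, params) {
  lat <- params$latencies
  amp <- params$amplitudes
  noise_sd <- params$noise_sd
  if (label == "rp") {
    p2 <- amp[["P2"]]
    amp <- amp * params$rp_secondary_attenuation
    amp[["P2"]] <- p2 * params$rp_p2_attenuation
  } else if (label == "abnormal") {
    subtype <- params$abnormal_subtype %||% sample(c("latency_shift", "flat",
                                                     "noisy"), 1)
    if (subtype == "latency_shift") {
      lat <- pmin(lat + runif(1, 30, 60), 300)
    } else if (subtype == "flat") {
      amp <- amp * runif(1, 0.02, 0.08)
    } else {
      noise_sd <- max(noise_sd, params$noise_sd * runif(1, 5, 10) + 2)
    }
  }
  sig <- component_sum(lat, amp, params$widths)
  if (params$baseline_offset_sd > 0) {
    sig <- sig + rnorm(1, sd = params$baseline_offset_sd)
  }
  if (params$drift_amplitude > 0) {
    f <- runif(1, 0.5, 1.5)
    sig <- sig + params$drift_amplitude *
      sin(2 * pi * f * (fvep_time_axis() / 1000) + runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0) {
    eps <- rnorm(FVEP_LENGTH, sd = noise_sd)
    if (isTRUE(params$bandpass)) eps <- bandpass_noise(eps)
    sig <- sig + eps
  }
  sig
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a single synthetic FVEP record
#'
#' @param class_label One of `"normal"`, `"rp"`, `"abnormal"`.
#' @param params A [fvep_waveform_params()] object.
#' @param rng_seed Integer seed; the record is a deterministic function of
#'   (`class_label`, `params`, `rng_seed`).
#' @param patient_id,eye,repeat_index,age Metadata attached to the record.
#' @return A one-row tibble with columns `patient_id`, `eye`, `repeat_index`,
#'   `age`, `label` and a list-column `signal` holding the 320-sample sweep.
#' @export
generate_record <- function(class_label, params = fvep_waveform_params(),
                            rng_seed = 1L, patient_id = "P001",
                            eye = "left", repeat_index = 1L, age = 42L) {
  if (!class_label %in% c("normal", "rp", "abnormal")) {
    abort(paste0("unknown class_label: ", class_label),
          class = "fvepnet_bad_label")
  }
  stopifnot(inherits(params, "fvep_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(rng_seed, 1L))
  sig <- render_signal(class_label, params)
  tibble(patient_id = patient_id, eye = eye,
         repeat_index = as.integer(repeat_index), age = as.integer(age),
         label = class_label, signal = list(sig))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic FVEP dataset
#'
#' Emulates the clinical collection design: every patient contributes exactly
#' four records (left and right eye, each twice), has a patient-level age
#' drawn uniformly from 4--88 years, and patient-level waveform perturbations
#' (a common latency shift and a log-normal amplitude scale) so that sweeps
#' from the same patient are more alike than sweeps from different patients.
#' Record-level noise and drift are then added independently per sweep.
#'
#' @param n_normal,n_rp,n_abnormal Number of patients per class.
#' @param params A [fvep_waveform_params()] object.
#' @param rng_seed Integer master seed. Per-record substreams are derived
#'   deterministically from (seed, patient index, eye, repeat).
#' @return A tibble with 4 rows per patient: `patient_id`, `eye`,
#'   `repeat_index`, `age`, `label`, `signal` (list-column of length-320
#'   numeric vectors).
#' @export
#' @examples
#' d <- simulate_fvep(n_normal = 3, n_rp = 2, rng_seed = 7)
#' nrow(d)  # 20 = 4 records x 5 patients
simulate_fvep <- function(n_normal = 0L, n_rp = 0L, n_abnormal = 0L,
                          params = fvep_waveform_params(), rng_seed = 1L) {
  stopifnot(inherits(params, "fvep_params"))
  counts <- c(normal = n_normal, rp = n_rp, abnormal = n_abnormal)
  if (any(counts < 0)) abort("patient counts must be non-negative",
                             class = "fvepnet_bad_params")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  labels <- rep(names(counts), counts)
  n_pat <- length(labels)
  if (n_pat == 0) {
    return(tibble(patient_id = character(), eye = character(),
                  repeat_index = integer(), age = integer(),
                  label = character(), signal = list()))
  }
  out <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    lab <- labels[i]
    pid <- sprintf("%s_%04d", toupper(substr(lab, 1, 2)), i)
    # patient-level draws
    set.seed(derive_seed(rng_seed, i, 0L))
    age <- sample(4:88, 1)
    p_i <- params
    p_i$latencies <- pmin(pmax(params$latencies +
                                 rnorm(1, sd = params$latency_jitter_sd), 5), 295)
    p_i$amplitudes <- params$amplitudes *
      exp(rnorm(1, sd = params$amplitude_jitter_sd)) *
      exp(rnorm(length(params$amplitudes), sd = params$amplitude_jitter_sd / 2))
    if (lab == "abnormal") {
      p_i$abnormal_subtype <- sample(c("latency_shift", "flat", "noisy"), 1)
    }
    recs <- vector("list", 4L)
    k <- 1L
    for (eye_j in 1:2) {
      for (rep_j in 1:2) {
        set.seed(derive_seed(rng_seed, i, eye_j, rep_j))
        recs[[k]] <- tibble(
          patient_id = pid,
          eye = c("left", "right")[eye_j],
          repeat_index = rep_j,
          age = as.integer(age),
          label = lab,
          signal = list(render_signal(lab, p_i)))
        k <- k + 1L
      }
    }
    out[[i]] <- bind_rows(recs)
  }
  bind_rows(out)
}

#' Write / read an FVEP dataset as wide CSV
#'
#' The on-disk schema is one row per record with header columns
#' `patient_id, eye, repeat_index, age, label, s0...s319`.
#'
#' @param records A record tibble as produced by [simulate_fvep()].
#' @param path File path.
#' @return `write_fvep_csv()` returns `path` invisibly; `read_fvep_csv()`
#'   returns the record tibble with the `signal` list-column restored.
#' @export
write_fvep_csv <- function(records, path) {
  check_records(records)
  sig <- do.call(rbind, records$signal)
  colnames(sig) <- paste0("s", seq_len(FVEP_LENGTH) - 1L)
  wide <- dplyr::bind_cols(
    records[, c("patient_id", "eye", "repeat_index", "age", "label")],
    as_tibble(sig))
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_fvep_csv
#' @export
read_fvep_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  sig_cols <- paste0("s", seq_len(FVEP_LENGTH) - 1L)
  if (!all(sig_cols %in% names(wide))) {
    abort("CSV is missing signal columns s0...s319",
          class = "fvepnet_bad_csv")
  }
  sig <- as.matrix(wide[, sig_cols])
  tibble(patient_id = as.character(wide$patient_id),
         eye = as.character(wide$eye),
         repeat_index = as.integer(wide$repeat_index),
         age = as.integer(wide$age),
         label = as.character(wide$label),
         signal = lapply(seq_len(nrow(sig)), function(i) unname(sig[i, ])))
}

check_records <- function(records) {
  need <- c("patient_id", "eye", "repeat_index", "age", "label", "signal")
  if (!all(need %in% names(records))) {
    abort("records must have columns patient_id, eye, repeat_index, age, label, signal",
          class = "fvepnet_bad_records")
  }
  lens <- lengths(records$signal)
  if (length(lens) && any(lens != FVEP_LENGTH)) {
    bad <- records$patient_id[which(lens != FVEP_LENGTH)[1]]
    abort(paste0("signal length must be 320 (record of patient ", bad, ")"),
          class = "fvepnet_bad_signal_length")
  }
  invisible(records)
}

# Record tibble -> n x 320 matrix.
signal_matrix <- function(records) {
  check_records(records)
  if (nrow(records) == 0L) return(matrix(numeric(), 0L, FVEP_LENGTH))
  do.call(rbind, records$signal)
}
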