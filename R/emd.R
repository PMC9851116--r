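# Empirical mode decomposition of a single sweep and denoising by
# selective IMF reconstruction.
#
# Standard sifting: cubic-spline upper/lower envelopes through local
# extrema (mirror-extended at both ends), subtract the envelope mean,
# iterate until the SD stopping criterion, extract the IMF, repeat on the
# remainder until it is monotone or has fewer than 3 extrema.

# Strict local maxima / minima; exact plateaus collapse to their first
# sample via the >= / <= asymmetry.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(), minima = integer()))
  prev <- x[1:(n - 2)]
  cur <- x[2:(n - 1)]
  nxt <- x[3:n]
  maxima <- which(cur > prev & cur >= nxt) + 1L
  minima <- which(cur < prev & cur <= nxt) + 1L
  list(maxima = maxima, minima = minima)
}

# Cubic-spline envelope through extrema, with mirror extension of up to two
# extrema beyond each boundary to tame end swings.
spline_envelope <- function(x, idx) {
  n <- length(x)
  xi <- idx
  yi <- x[idx]
  m <- length(xi)
  left_k <- min(2L, m)
  right_k <- min(2L, m)
  xl <- 2 * 1 - rev(xi[seq_len(left_k)])          # mirror about sample 1
  yl <- rev(yi[seq_len(left_k)])
  xr <- 2 * n - rev(xi)[seq_len(right_k)]         # mirror about sample n
  yr <- rev(yi)[seq_len(right_k)]
  ord <- order(c(xl, xi, xr))
  xs <- c(xl, xi, xr)[ord]
  ys <- c(yl, yi, yr)[ord]
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}

n_extrema <- function(x) {
  e <- find_extrema(x)
  length(e$maxima) + length(e$minima)
}

#' Empirical mode decomposition of an FVEP sweep
#'
#' Decomposes a length-320 signal into intrinsic mode functions (IMFs,
#' highest frequency first) plus a monotone residual. Sifting stops when the
#' normalized squared change between successive sifts drops below `sd_tol`
#' (or after `max_sifts` iterations); decomposition stops when the remainder
#' has fewer than 3 extrema or `max_imfs` IMFs have been extracted.
#'
#' @param signal Numeric vector of length 320 with finite values.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sd_tol Standard-deviation stopping criterion between sifts.
#' @param max_sifts Maximum sift iterations per IMF.
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors, possibly empty) and `residual`. The elementwise sum of all
#'   IMFs plus the residual reconstructs the input to floating-point
#'   accuracy.
#' @export
#' @examples
#' s <- sin(2 * pi * 30 * (0:319) / 1000)
#' d <- emd_decompose(s)
#' cor(d$imfs[[1]], s)  # a single tone is (close to) its own first IMF
emd_decompose <- function(signal, max_imfs = 10L, sd_tol = 0.2,
                          max_sifts = 50L) {
  if (length(signal) != FVEP_LENGTH) {
    abort("signal must have length 320", class = "fvepnet_bad_signal_length")
  }
  if (!all(is.finite(signal))) {
    abort("signal must be finite", class = "fvepnet_bad_signal")
  }
  x <- as.numeric(signal)
  imfs <- list()
  resid <- x
  while (length(imfs) < max_imfs && n_extrema(resid) >= 3) {
    h <- resid
    for (s in seq_len(max_sifts)) {
      e <- find_extrema(h)
      if (length(e$maxima) < 2 || length(e$minima) < 2) break
      upper <- spline_envelope(h, e$maxima)
      lower <- spline_envelope(h, e$minima)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < sd_tol) break
    }
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
  }
  structure(list(imfs = imfs, residual = resid, input = x),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", length(x$imfs), " IMFs + residual (length ",
      length(x$residual), ")\n", sep = "")
  invisible(x)
}

#' Reconstruct a signal from selected IMFs
#'
#' @param imf_set An [emd_decompose()] result.
#' @param indices 1-based IMF indices to sum (IMF1 = highest frequency). The
#'   residual is excluded unless `include_residual = TRUE`.
#' @param include_residual Add the residual to the sum.
#' @return Numeric vector of length 320 (all zeros for an empty selection).
#' @export
emd_reconstruct <- function(imf_set, indices, include_residual = FALSE) {
  stopifnot(inherits(imf_set, "imf_set"))
  indices <- as.integer(indices)
  bad <- indices[indices < 1L | indices > length(imf_set$imfs)]
  if (length(bad)) {
    abort(paste0("IMF index out of range: ", bad[1], " (decomposition has ",
                 length(imf_set$imfs), " IMFs)"),
          class = "fvepnet_imf_index")
  }
  out <- numeric(length(imf_set$residual))
  for (i in indices) out <- out + imf_set$imfs[[i]]
  if (include_residual) out <- out + imf_set$residual
  out
}

#' Denoise an FVEP sweep by selective IMF reconstruction
#'
#' Composition of [emd_decompose()] and [emd_reconstruct()]; by default the
#' mid-band components IMF3, IMF4 and IMF5 are retained, which suppresses
#' high-frequency noise (IMF1--2) and slow drift (later IMFs + residual).
#' If the decomposition yields fewer IMFs than requested, the available
#' selected IMFs are summed and a warning is emitted.
#'
#' @param signal Numeric vector of length 320.
#' @param indices IMF indices to keep (default 3:5).
#' @inheritParams emd_decompose
#' @return Denoised numeric vector of length 320.
#' @export
emd_denoise <- function(signal, indices = 3:5, max_imfs = 10L,
                        sd_tol = 0.2, max_sifts = 50L) {
  dec <- emd_decompose(signal, max_imfs = max_imfs, sd_tol = sd_tol,
                       max_sifts = max_sifts)
  avail <- indices[indices >= 1L & indices <= length(dec$imfs)]
  if (length(avail) < length(indices)) {
    warn(paste0("decomposition yielded ", length(dec$imfs),
                " IMFs; returning the sum of the available selected IMFs"),
         class = "fvepnet_imf_fallback")
  }
  emd_reconstruct(dec, avail)
}

#' Denoise every record of an FVEP dataset
#'
#' @param records Record tibble (see [simulate_fvep()]).
#' @param indices IMF indices to keep per sweep.
#' @return The tibble with the `signal` column replaced by its denoised
#'   version.
#' @export
denoise_records <- function(records, indices = 3:5) {
  check_records(records)
  records$signal <- lapply(records$signal, function(s)
    suppressWarnings(emd_denoise(s, indices = indices)))
  records
}

#' @export
tidy.imf_set <- function(x, ...) {
  n_imf <- length(x$imfs)
  comp <- c(paste0("IMF", seq_len(n_imf)), "residual")
  vals <- c(x$imfs, list(x$residual))
  tibble(component = rep(comp, each = length(x$residual)),
         sample = rep(seq_along(x$residual), times = n_imf + 1L),
         value = unlist(vals, use.names = FALSE))
}
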