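make_records <- function(signals, ages = NULL) {
  n <- length(signals)
  tibble::tibble(patient_id = sprintf("P%03d", seq_len(n)),
                 eye = "left", repeat_index = 1L,
                 age = as.integer(ages %||% rep(42L, n)),
                 label = "normal", signal = signals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("statistical features equal their definitions on degenerate signals", {
  const <- make_records(list(rep(5, 320)))
  tab <- suppressWarnings(extract_features(const))
  expect_equal(tab$max, 5)
  expect_equal(tab$min, 5)
  expect_equal(tab$peak_to_peak, 0)
  expect_equal(tab$sd, 0)
  expect_warning(extract_features(const),
                 class = "fvepnet_degenerate_features")

  spike <- make_records(list(c(rep(0, 160), 1, rep(0, 159))))
  tab2 <- extract_features(spike)
  expect_equal(tab2$max, 1)
  expect_equal(tab2$min, 0)
  expect_equal(tab2$peak_to_peak, 1)

  ramp <- make_records(list(as.numeric(0:319)))
  tab3 <- extract_features(ramp)
  expect_equal(tab3$median, 159.5)   # sorted midpoint of 0..319
  expect_equal(tab3$mean, mean(0:319))
})

test_that("feature extraction is row-stable, complete and domain-tagged", {
  d <- simulate_fvep(5, 5, 0, rng_seed = 20)
  tab <- extract_features(d)
  expect_equal(nrow(tab), nrow(d))
  expect_false(anyNA(tab))
  dom <- feature_domains(tab)
  expect_setequal(unique(dom$domain),
                  c("temporal", "statistical", "spectral", "meta"))
  expect_true(all(c("autocorr_lag1", "sample_entropy", "peak_to_peak",
                    "spectral_centroid", "dwt_energy_d1", "age")
                  %in% names(tab)))
  # permutation equivariance: row order follows input order
  perm <- sample(nrow(d))
  tab_perm <- extract_features(d[perm, ])
  expect_equal(as.data.frame(tab_perm), as.data.frame(tab[perm, ]),
               ignore_attr = TRUE)
})

test_that("the variance filter drops exactly the low-variance columns and is idempotent", {
  tab <- tibble::tibble(a = c(1, 1, 1, 1), b = c(0, 2, 4, 6), c = rnorm(4))
  out <- variance_filter(tab, 0)
  expect_named(out, c("b", "c"))
  # var(b) = 20/3 > 1, drop zero-variance a only at threshold 1 if c small
  tab2 <- tibble::tibble(x = c(1, 1, 1, 1), y = c(0, 4, 0, 4))  # vars 0, 16/3
  expect_named(variance_filter(tab2, 1), "y")
  # idempotence
  expect_equal(variance_filter(out, 0), out)
  # identity when nothing is constant
  expect_equal(variance_filter(tab[, c("b", "c")], 0), tab[, c("b", "c")])
  expect_error(variance_filter(tibble::tibble(z = rep(3, 5)), 0),
               class = "fvepnet_degenerate_table")
})

test_that("Pearson selection matches the closed-form correlation oracle", {
  labels <- c(0, 0, 1, 1)
  tab <- tibble::tibble(same = labels, anti = 1 - labels,
                        ramp = c(1, 2, 3, 4), flat = rep(2, 4))
  out <- pearson_select(tab, labels, min_abs_r = 0.85)
  r <- attr(out, "pearson_r")
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_equal(unname(r["ramp"]), 0.894, tolerance = 1e-3)
  expect_equal(unname(r["flat"]), 0)    # zero-variance convention
  expect_named(out, c("same", "anti", "ramp"))

  # brute-force covariance / sigma-sigma oracle on random columns
  set.seed(30)
  y <- sample(c(0, 1), 50, replace = TRUE)
  for (k in 1:100) {
    col <- rnorm(50)
    r_pkg <- attr(pearson_select(tibble::tibble(v = col), y, 0),
                  "pearson_r")[["v"]]
    mu_x <- sum(col) / 50; mu_y <- sum(y) / 50
    r_oracle <- sum((col - mu_x) * (y - mu_y)) /
      sqrt(sum((col - mu_x)^2) * sum((y - mu_y)^2))
    expect_equal(r_pkg, r_oracle, tolerance = 1e-12)
  }
  expect_error(pearson_select(tab, rep(1, 4)),
               class = "fvepnet_degenerate_labels")
  expect_error(pearson_select(tab, c(0, 1, 2, 1)),
               class = "fvepnet_bad_labels")
})

test_that("the 7 manual features follow their fixed definitions and order", {
  const <- make_records(list(rep(3.5, 320)), ages = 40)
  mf <- manual_features(const)
  expect_named(mf, c("peak_to_peak", "p2_amplitude", "p2_latency_ms",
                     "signal_sd", "signal_median", "mean_abs_diff", "age"))
  # constant signal: ptp 0, window max = constant, argmax tie -> window start
  expect_equal(unlist(mf), c(peak_to_peak = 0, p2_amplitude = 3.5,
                             p2_latency_ms = 100, signal_sd = 0,
                             signal_median = 3.5, mean_abs_diff = 0,
                             age = 40))
  # determinism
  d <- simulate_fvep(2, 2, 0, rng_seed = 33)
  expect_identical(manual_features(d), manual_features(d))
})

test_that("zero-noise RP and normal sweeps share P2 latency but not amplitude", {
  p0 <- clean_params(rp_p2_attenuation = 0.4)
  rn <- generate_record("normal", p0, 2, age = 50)
  rr <- generate_record("rp", p0, 2, age = 50)
  mn <- manual_features(rn)
  mr <- manual_features(rr)
  expect_equal(mn$p2_latency_ms, mr$p2_latency_ms)
  expect_lt(mr$peak_to_peak, mn$peak_to_peak)
  expect_lt(mr$p2_amplitude, mn$p2_amplitude)
})

test_that("peak-to-peak amplitude is the strongest label correlate among signal features", {
  d <- simulate_fvep(25, 25, 0, rng_seed = 1)   # 200 records
  mf <- manual_features(d)
  lab <- as.numeric(d$label == "rp")
  rs <- vapply(mf[, setdiff(names(mf), "age")], function(col)
    abs(stats::cor(col, lab)), numeric(1))
  expect_equal(names(which.max(rs)), "peak_to_peak")
})

test_that("wrong-length signals are rejected with the record id", {
  bad <- make_records(list(rnorm(320), rnorm(100)))
  expect_error(extract_features(bad), class = "fvepnet_bad_signal_length")
  expect_error(extract_features(bad), regexp = "P002")
})
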