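# The multi-input convolution-and-confidence (MCAC) architecture: a
# global-convolution branch
# whose kernel spans the whole sweep (one scalar per filter), a local
# branch of three conv/max-pool stages, a dense branch over the 7 manual
# features, a shared fusion layer, and two heads -- softmax class
# probabilities and a sigmoid confidence scalar.

#' Model configuration
#'
#' @param T_len Input sweep length (320).
#' @param n_classes Number of classes M (>= 2).
#' @param global_filters Filters in the global convolution (each spans the
#'   full sweep and yields one scalar).
#' @param local_filter_sizes Kernel lengths of the three local conv stages.
#' @param local_filters Filter counts of the three local conv stages.
#' @param manual_branch_units Width of the dense layer over the 7 manual
#'   features.
#' @param fusion_units Width of the shared post-concatenation dense layer
#'   (the penultimate embedding used by the feature-space OOD detectors).
#' @return An object of class `mcac_config`.
#' @export
mcac_config <- function(T_len = 320L, n_classes = 2L, global_filters = 64L,
                        local_filter_sizes = c(5L, 3L, 3L),
                        local_filters = c(64L, 64L, 64L),
                        manual_branch_units = 128L, fusion_units = 128L) {
  if (n_classes < 2L) abort("n_classes must be >= 2", class = "fvepnet_bad_config")
  if (T_len < max(local_filter_sizes)) {
    abort("input length must be at least the largest local kernel",
          class = "fvepnet_bad_config")
  }
  if (any(c(global_filters, local_filters, manual_branch_units,
            fusion_units) <= 0)) {
    abort("all layer sizes must be positive", class = "fvepnet_bad_config")
  }
  if (length(local_filter_sizes) != length(local_filters)) {
    abort("local_filter_sizes and local_filters must have equal length",
          class = "fvepnet_bad_config")
  }
  structure(list(T_len = as.integer(T_len), n_classes = as.integer(n_classes),
                 global_filters = as.integer(global_filters),
                 local_filter_sizes = as.integer(local_filter_sizes),
                 local_filters = as.integer(local_filters),
                 manual_branch_units = as.integer(manual_branch_units),
                 fusion_units = as.integer(fusion_units),
                 n_manual = 7L),
            class = "mcac_config")
}

# Symbolic shape trace of the local branch: valid conv (L - k + 1) then
# max-pool by 2 at every stage.
local_branch_shape <- function(config) {
  L <- config$T_len
  shapes <- list()
  for (s in seq_along(config$local_filter_sizes)) {
    L <- L - config$local_filter_sizes[s] + 1L   # valid convolution
    L <- L %/% 2L                                 # max-pool size 2
    shapes[[s]] <- c(length = L, channels = config$local_filters[s])
  }
  shapes
}

#' Build the multi-branch network
#'
#' Initializes all weights with uniform He-style fan-in scaling under the
#' given seed.
#'
#' @param config An [mcac_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mcac_net` holding the parameter list and the
#'   configuration.
#' @export
mcac_build <- function(config = mcac_config(), seed = 1L) {
  stopifnot(inherits(config, "mcac_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 11L))
  gU <- config$global_filters
  fs <- config$local_filter_sizes
  nf <- config$local_filters
  mU <- config$manual_branch_units
  fU <- config$fusion_units
  M <- config$n_classes
  shp <- local_branch_shape(config)
  flat_dim <- shp[[length(shp)]]["length"] * shp[[length(shp)]]["channels"]
  concat_dim <- gU + flat_dim + mU

  p <- list()
  p$Wg <- matrix(he_uniform(config$T_len * gU, config$T_len), config$T_len, gU)
  p$bg <- numeric(gU)
  cin <- 1L
  for (s in seq_along(fs)) {
    fan <- fs[s] * cin
    p[[paste0("Wl", s)]] <- array(he_uniform(fs[s] * cin * nf[s], fan),
                                  c(fs[s], cin, nf[s]))
    p[[paste0("bl", s)]] <- numeric(nf[s])
    cin <- nf[s]
  }
  p$Wm <- matrix(he_uniform(config$n_manual * mU, config$n_manual),
                 config$n_manual, mU)
  p$bm <- numeric(mU)
  p$Wf <- matrix(he_uniform(concat_dim * fU, concat_dim), concat_dim, fU)
  p$bf <- numeric(fU)
  p$Wp <- matrix(he_uniform(fU * M, fU), fU, M)
  p$bp <- numeric(M)
  p$Wc <- matrix(he_uniform(fU, fU), fU, 1L)
  p$bc <- 0

  structure(list(params = p, config = config,
                 concat_dim = concat_dim, flat_dim = unname(flat_dim)),
            class = "mcac_net")
}

# Names of the local-branch parameters (the pretraining / low-lr group).
local_param_names <- function(config) {
  as.vector(rbind(paste0("Wl", seq_along(config$local_filter_sizes)),
                  paste0("bl", seq_along(config$local_filter_sizes))))
}

#' Forward pass of the network
#'
#' @param model An [mcac_build()] object.
#' @param signals n x 320 numeric matrix (or a record tibble).
#' @param manual n x 7 numeric matrix of manual features (or a
#'   [manual_features()] tibble).
#' @param cache Keep intermediate activations for backpropagation.
#' @return A list with `p` (n x M class probabilities, rows sum to 1),
#'   `confidence` (length-n vector in \[0, 1\]), `penultimate` (n x
#'   fusion_units embedding), and optionally `cache`.
#' @export
mcac_forward <- function(model, signals, manual, cache = FALSE) {
  stopifnot(inherits(model, "mcac_net"))
  if (is.data.frame(signals)) signals <- signal_matrix(signals)
  if (is.data.frame(manual)) manual <- as.matrix(manual)
  if (ncol(signals) != model$config$T_len) {
    abort(paste0("signals must have ", model$config$T_len, " columns"),
          class = "fvepnet_bad_signal_length")
  }
  if (nrow(signals) != nrow(manual) || ncol(manual) != model$config$n_manual) {
    abort("manual feature batch must be n x 7 and match signals",
          class = "fvepnet_bad_batch")
  }
  p <- model$params
  n <- nrow(signals)

  G <- relu(dense_forward(signals, p$Wg, p$bg))

  A <- array(signals, c(n, model$config$T_len, 1L))
  n_stage <- length(model$config$local_filter_sizes)
  acts <- list(A0 = A)
  for (s in seq_len(n_stage)) {
    st <- stage_fwd_cpp(A, p[[paste0("Wl", s)]], p[[paste0("bl", s)]])
    acts[[paste0("code", s)]] <- st$code
    acts[[paste0("P", s)]] <- st$P
    A <- st$P
  }
  Flat <- reshp(A, c(n, model$flat_dim))

  Mh <- relu(dense_forward(manual, p$Wm, p$bm))
  H <- cbind(G, Flat, Mh)
  Fh <- relu(dense_forward(H, p$Wf, p$bf))
  zp <- dense_forward(Fh, p$Wp, p$bp)
  probs <- softmax_rows(zp)
  zc <- drop(dense_forward(Fh, p$Wc, p$bc))
  conf <- sigmoid(zc)

  out <- list(p = probs, confidence = conf, penultimate = Fh)
  if (cache) {
    out$cache <- c(acts, list(signals = signals, manual = manual, G = G,
                              Flat = Flat, Mh = Mh, H = H, Fh = Fh,
                              zp = zp, zc = zc))
  }
  out
}

# Backward pass: given gradients w.r.t. the class logits (n x M) and the
# confidence logit (length n), returns gradients for every parameter.
mcac_backward <- function(model, cache, dzp, dzc) {
  p <- model$params
  cfg <- model$config
  n <- nrow(cache$signals)
  g <- list()

  g$Wp <- crossprod(cache$Fh, dzp)
  g$bp <- colSums(dzp)
  g$Wc <- crossprod(cache$Fh, matrix(dzc, n, 1L))
  g$bc <- sum(dzc)

  dFh <- dzp %*% t(p$Wp) + matrix(dzc, n, 1L) %*% t(p$Wc)
  dFh <- relu_backward(dFh, cache$Fh)
  g$Wf <- crossprod(cache$H, dFh)
  g$bf <- colSums(dFh)
  dH <- dFh %*% t(p$Wf)

  gU <- cfg$global_filters
  dG <- dH[, seq_len(gU), drop = FALSE]
  dFlat <- dH[, gU + seq_len(model$flat_dim), drop = FALSE]
  dMh <- dH[, gU + model$flat_dim + seq_len(cfg$manual_branch_units),
            drop = FALSE]

  dG <- relu_backward(dG, cache$G)
  g$Wg <- crossprod(cache$signals, dG)
  g$bg <- colSums(dG)

  dMh <- relu_backward(dMh, cache$Mh)
  g$Wm <- crossprod(cache$manual, dMh)
  g$bm <- colSums(dMh)

  n_stage <- length(cfg$local_filter_sizes)
  last <- cache[[paste0("P", n_stage)]]
  dA <- reshp(dFlat, dim(last))
  for (s in rev(seq_len(n_stage))) {
    A_in <- if (s == 1L) cache$A0 else cache[[paste0("P", s - 1L)]]
    cb <- stage_bwd_cpp(A_in, p[[paste0("Wl", s)]], dA,
                        cache[[paste0("code", s)]])
    g[[paste0("Wl", s)]] <- cb$dW
    g[[paste0("bl", s)]] <- as.numeric(cb$db)
    dA <- cb$dA
  }
  g
}

#' @export
print.mcac_net <- function(x, ...) {
  cfg <- x$config
  cat("<mcac_net> T=", cfg$T_len, ", M=", cfg$n_classes,
      "; global ", cfg$global_filters,
      "; local ", paste(cfg$local_filter_sizes, collapse = "/"),
      " x ", paste(cfg$local_filters, collapse = "/"),
      "; manual ", cfg$manual_branch_units,
      "; fusion ", cfg$fusion_units,
      "; ", format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#' @param model An `mcac_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
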