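# Vectorized 1D neural-network primitives used by the multi-branch model
# and the convolutional autoencoder. Activations are n x L x C arrays
# (batch, time, channels); weights are k x C_in x F arrays. All
# convolutions are stride-1, no padding ("valid"); pooling is max, size 2.
#
# The column-major layout of R arrays makes a dim<- reshape of
# A[, j:(j+L-1), ] exactly the (batch*time) x channels matrix needed for
# the per-tap matmul formulation, so each convolution costs k BLAS calls
# and k subset copies. dim<- is used instead of matrix()/array() to avoid
# a second copy of every operand.

he_uniform <- function(n, fan_in) {
  s <- sqrt(6 / fan_in)
  runif(n, -s, s)
}

# reshape without copying (x must be a freshly allocated subset)
reshp <- function(x, d) {
  dim(x) <- d
  x
}

conv1d_forward <- function(A, W, b) {
  conv1d_fwd_cpp(A, W, as.numeric(b))
}

conv1d_backward <- function(A, W, dZ) {
  out <- conv1d_bwd_cpp(A, W, dZ)
  out$db <- as.numeric(out$db)
  out
}

tconv1d_forward <- function(A, W, b) {
  tconv1d_fwd_cpp(A, W, as.numeric(b))
}

tconv1d_backward <- function(A, W, dOut) {
  out <- tconv1d_bwd_cpp(A, W, dOut)
  out$db <- as.numeric(out$db)
  out
}

maxpool2_forward <- function(Z) {
  maxpool2_fwd_cpp(Z)
}

maxpool2_backward <- function(dP, mask) {
  maxpool2_bwd_cpp(dP, mask)
}

# ---- pure-R reference implementations ------------------------------------
# Slow but transparent mirrors of the compiled primitives; the tests use
# them as independent oracles for the C++ path.

conv1d_forward_ref <- function(A, W, b) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; nf <- dim(W)[3]
  L_out <- L - k + 1L
  Zmat <- matrix(b, n * L_out, nf, byrow = TRUE)
  for (j in seq_len(k)) {
    Sj <- reshp(A[, j:(j + L_out - 1L), , drop = FALSE], c(n * L_out, C))
    Zmat <- Zmat + Sj %*% reshp(W[j, , , drop = FALSE], c(C, nf))
  }
  reshp(Zmat, c(n, L_out, nf))
}

conv1d_backward_ref <- function(A, W, dZ) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; nf <- dim(W)[3]
  L_out <- L - k + 1L
  dZmat <- reshp(dZ, c(n * L_out, nf))
  dW <- array(0, dim(W))
  dA <- array(0, dim(A))
  for (j in seq_len(k)) {
    idx <- j:(j + L_out - 1L)
    Sj <- reshp(A[, idx, , drop = FALSE], c(n * L_out, C))
    dW[j, , ] <- crossprod(Sj, dZmat)
    dSj <- dZmat %*% t(reshp(W[j, , , drop = FALSE], c(C, nf)))
    dA[, idx, ] <- dA[, idx, , drop = FALSE] + reshp(dSj, c(n, L_out, C))
  }
  list(dA = dA, dW = dW, db = colSums(dZmat))
}

# Transposed ("full") convolution: length L -> L + k - 1. Used by the
# autoencoder decoder; its backward pass is the gather dual of the scatter.
tconv1d_forward_ref <- function(A, W, b) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; nf <- dim(W)[3]
  L_out <- L + k - 1L
  Amat <- reshp(A, c(n * L, C))
  Out <- reshp(matrix(b, n * L_out, nf, byrow = TRUE), c(n, L_out, nf))
  for (j in seq_len(k)) {
    contrib <- reshp(Amat %*% reshp(W[j, , , drop = FALSE], c(C, nf)),
                     c(n, L, nf))
    idx <- j:(j + L - 1L)
    Out[, idx, ] <- Out[, idx, , drop = FALSE] + contrib
  }
  Out
}

tconv1d_backward_ref <- function(A, W, dOut) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; nf <- dim(W)[3]
  Amat <- reshp(A, c(n * L, C))
  dAmat <- matrix(0, n * L, C)
  dW <- array(0, dim(W))
  for (j in seq_len(k)) {
    slab <- reshp(dOut[, j:(j + L - 1L), , drop = FALSE], c(n * L, nf))
    dW[j, , ] <- crossprod(Amat, slab)
    dAmat <- dAmat + slab %*% t(reshp(W[j, , , drop = FALSE], c(C, nf)))
  }
  list(dA = reshp(dAmat, dim(A)), dW = dW,
       db = colSums(reshp(dOut, c(n * (L + k - 1L), nf))))
}

maxpool2_forward_ref <- function(Z) {
  d <- dim(Z); L <- d[2]
  odd <- Z[, seq(1L, L - 1L, 2L), , drop = FALSE]
  even <- Z[, seq(2L, L, 2L), , drop = FALSE]
  mask <- odd >= even            # ties route to the first element
  list(P = pmax(odd, even), mask = mask)
}

maxpool2_backward_ref <- function(dP, mask) {
  d <- dim(dP); n <- d[1]; Lp <- d[2]; C <- d[3]
  dZ <- array(0, c(n, 2L * Lp, C))
  dZ[, seq(1L, 2L * Lp - 1L, 2L), ] <- dP * mask
  dZ[, seq(2L, 2L * Lp, 2L), ] <- dP * (!mask)
  dZ
}

upsample2_forward <- function(A) {
  d <- dim(A)
  Out <- array(0, c(d[1], 2L * d[2], d[3]))
  Out[, seq(1L, 2L * d[2] - 1L, 2L), ] <- A
  Out[, seq(2L, 2L * d[2], 2L), ] <- A
  Out
}

upsample2_backward <- function(dOut) {
  L2 <- dim(dOut)[2]
  dOut[, seq(1L, L2 - 1L, 2L), , drop = FALSE] +
    dOut[, seq(2L, L2, 2L), , drop = FALSE]
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dY, Y) dY * (Y > 0)

dense_forward <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Rescale a gradient list so its global L2 norm is at most max_norm.
# The hinted focal loss can produce near-unbounded gradients on saturated
# wrong predictions (the 1/p_hat factor is not cancelled by the softmax
# Jacobian once hinting decouples p_hat from the logits), so clipping is
# load-bearing for stability at the stated learning rate.
clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

# SGD with momentum over a named list of parameter arrays. `lr_scale` maps
# parameter names to per-group learning-rate multipliers (defaults to 1).
sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     lr_scale = NULL) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- state[[nm]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * (lr_scale[[nm]] %||% 1) * g
    params[[nm]] <- params[[nm]] + v
    state[[nm]] <- v
  }
  list(params = params, state = state)
}
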