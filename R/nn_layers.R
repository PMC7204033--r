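# Low-level 2D network primitives with hand-derived backward passes.
#
# Feature tensors are numeric arrays of dim (H, W, N, C): two spatial axes,
# batch, channels. Channels-last is deliberate: the (H*W*N, C) matrix view
# that every BLAS product needs is then a zero-copy `dim<-`, so convolutions
# reduce to one im2col block copy plus one GEMM with no array permutation.
# Backward passes recompute the im2col matrix from the cached layer input
# rather than caching it (it is ~9x larger than the input).

t4_to_mat <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2] * d[3], d[4])
  X
}

mat_to_t4 <- function(M, H, W, N, C) {
  dim(M) <- c(H, W, N, C)
  M
}

# 3x3 convolution, stride 1, zero padding 1 ("same"). Wm: (9*Cin, Cout) with
# row blocks ordered by kernel offset (dx outer, dy inner), channels within.
# The im2col/col2im data movement and the GEMMs live in src/conv.cpp.
conv3_fwd <- function(X, Wm, b) {
  list(out = conv3_fwd_cpp(X, Wm, b), cache = list(X = X))
}

conv3_bwd <- function(dY, cache, Wm) {
  conv3_bwd_cpp(dY, cache$X, Wm)
}

# 1x1 convolution. Wm: (Cin, Cout).
conv1_fwd <- function(X, Wm, b) {
  d <- dim(X)
  Y <- t4_to_mat(X) %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  list(out = mat_to_t4(Y, d[1], d[2], d[3], ncol(Wm)), cache = list(X = X))
}

conv1_bwd <- function(dY, cache, Wm) {
  X <- cache$X
  d <- dim(X)
  dYm <- t4_to_mat(dY)
  dW <- crossprod(t4_to_mat(X), dYm)
  db <- colSums(dYm)
  dX <- mat_to_t4(tcrossprod(dYm, Wm), d[1], d[2], d[3], d[4])
  list(dX = dX, dW = dW, db = db)
}

# Batch normalization over (H, W, N) per channel. Training mode uses batch
# statistics (population variance) and updates running statistics in `state`;
# evaluation mode standardizes with the running statistics.
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(X, gamma, beta, state, training) {
  d <- dim(X)
  r <- bn_fwd_cpp(t4_to_mat(X), gamma, beta, state$mean, state$var,
                  training, BN_MOMENTUM, BN_EPS)
  list(out = mat_to_t4(r$Y, d[1], d[2], d[3], d[4]),
       cache = list(Xhat = r$Xhat, inv_std = r$inv_std, dims = d,
                    training = training),
       state = list(mean = r$mean, var = r$var))
}

bn_bwd <- function(dY, cache, gamma) {
  d <- cache$dims
  r <- bn_bwd_cpp(t4_to_mat(dY), cache$Xhat, cache$inv_std, gamma,
                  cache$training)
  list(dX = mat_to_t4(r$dX, d[1], d[2], d[3], d[4]), dgamma = r$dgamma,
       dbeta = r$dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_bwd <- function(dY, mask) dY * mask

# Inverted dropout: active only in training mode; consumes the R RNG stream.
dropout_fwd <- function(X, p, training) {
  if (!training || p == 0) return(list(out = X, cache = NULL))
  mask <- array((runif(length(X)) >= p) / (1 - p), dim(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# 2x2 max pooling, stride 2, floor semantics (trailing odd row/column
# dropped). Ties break deterministically in the fixed window order.
pool2_fwd <- function(X) {
  d <- dim(X); Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ih <- seq_len(Ho) * 2L; iw <- seq_len(Wo) * 2L
  a <- list(X[ih - 1L, iw - 1L, , , drop = FALSE],
            X[ih,      iw - 1L, , , drop = FALSE],
            X[ih - 1L, iw,      , , drop = FALSE],
            X[ih,      iw,      , , drop = FALSE])
  m <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  list(out = m, cache = list(a = a, m = m, dims = d))
}

pool2_bwd <- function(dY, cache) {
  d <- cache$dims; Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ih <- seq_len(Ho) * 2L; iw <- seq_len(Wo) * 2L
  dX <- array(0, d)
  taken <- array(FALSE, dim(cache$m))
  sel <- function(k) {
    s <- (cache$a[[k]] == cache$m) & !taken
    taken <<- taken | s
    s
  }
  dX[ih - 1L, iw - 1L, , ] <- dY * sel(1L)
  dX[ih,      iw - 1L, , ] <- dY * sel(2L)
  dX[ih - 1L, iw,      , ] <- dY * sel(3L)
  dX[ih,      iw,      , ] <- dY * sel(4L)
  dX
}

# 1D linear-interpolation matrix mapping n_in samples onto n_out positions
# (endpoints aligned), used for bilinear upsampling to the stored skip size.
interp_matrix <- function(n_out, n_in) {
  U <- matrix(0, n_out, n_in)
  if (n_in == 1L) { U[, 1L] <- 1; return(U) }
  src <- if (n_out == 1L) (n_in - 1) / 2 else
    (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(src), n_in - 2)
  fr <- src - i0
  for (j in seq_len(n_out)) {
    U[j, i0[j] + 1L] <- U[j, i0[j] + 1L] + (1 - fr[j])
    U[j, i0[j] + 2L] <- U[j, i0[j] + 2L] + fr[j]
  }
  U
}

# Apply matrix U along the first axis of an array.
apply_dim1 <- function(U, X) {
  d <- dim(X)
  Y <- U %*% matrix(X, d[1])
  array(Y, c(nrow(U), d[-1]))
}

# Apply matrix U along the second axis of a 4D array without aperm:
# fold (H) into the trailing dims via transpose-free reshaping.
apply_dim2 <- function(U, X) {
  d <- dim(X)
  Y <- array(0, c(d[1], nrow(U), d[3], d[4]))
  for (c4 in seq_len(d[4])) {
    Xc <- X[, , , c4, drop = FALSE]
    dim(Xc) <- c(d[1], d[2] * d[3])
    # per-batch multiply on axis 2: reshape to (H, W, N) slices
    dim(Xc) <- c(d[1], d[2], d[3])
    for (n in seq_len(d[3]))
      Y[, , n, c4] <- tcrossprod(Xc[, , n], U)
  }
  Y
}

upsample_fwd <- function(X, Ht, Wt) {
  d <- dim(X)
  Ur <- interp_matrix(Ht, d[1])
  Uc <- interp_matrix(Wt, d[2])
  Y <- apply_dim2(Uc, apply_dim1(Ur, X))
  list(out = Y, cache = list(Ur = Ur, Uc = Uc))
}

upsample_bwd <- function(dY, cache) {
  apply_dim2(t(cache$Uc), apply_dim1(t(cache$Ur), dY))
}

concat_c <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- A
  out[, , , da[4] + seq_len(db[4])] <- B
  out
}

split_c <- function(dX, c1) {
  d <- dim(dX)
  list(dA = dX[, , , seq_len(c1), drop = FALSE],
       dB = dX[, , , (c1 + 1L):d[4], drop = FALSE])
}

# Softmax over the class axis (4th) with numerical stabilization.
softmax_c <- function(Z) {
  d <- dim(Z)
  M <- t4_to_mat(Z)                       # (H*W*N, C)
  mx <- do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
  E <- exp(M - mx)
  P <- E / rowSums(E)
  mat_to_t4(P, d[1], d[2], d[3], d[4])
}

# Mean pixel-wise cross-entropy and its gradient w.r.t. logits.
# targets: (H, W, N) array of class indices in 0..C-1.
ce_loss_grad <- function(Z, targets) {
  d <- dim(Z)
  P <- t4_to_mat(softmax_c(Z))            # rows (h,w,n), cols classes
  # matrix row order (h, w, n) coincides with column-major order of (H,W,N)
  tvec <- as.integer(targets)
  npix <- nrow(P)
  idx <- cbind(seq_len(npix), tvec + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  G <- G / npix
  list(loss = loss, dZ = mat_to_t4(G, d[1], d[2], d[3], d[4]))
}
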