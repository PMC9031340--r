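# Low-level 3-D network layers.
#
# Activations are stored as [n_voxels x channels] matrices in column-major
# voxel order for the current resolution; all spatial bookkeeping lives in
# index tables precomputed once per volume shape (see .make_geometry). The
# 3x3x3 same-padding convolution is an im2col gather followed by one GEMM, so
# the heavy lifting stays inside BLAS.

# Spatial bookkeeping for one resolution level.
.conv_indices <- function(shape) {
  shape <- as.integer(shape)
  list(shape = shape, nvox = prod(shape))
}

# 2x2x2 pooling window membership: row = output voxel, 8 input linear indices.
.pool_indices <- function(shape) {
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L; D2 <- D %/% 2L
  out <- as.matrix(expand.grid(x = seq_len(H2), y = seq_len(W2), z = seq_len(D2)))
  off <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  idx <- matrix(0L, nrow(out), 8L)
  for (o in seq_len(8L)) {
    px <- 2L * (out[, 1L] - 1L) + 1L + off[o, 1L]
    py <- 2L * (out[, 2L] - 1L) + 1L + off[o, 2L]
    pz <- 2L * (out[, 3L] - 1L) + 1L + off[o, 3L]
    idx[, o] <- px + (py - 1L) * H + (pz - 1L) * H * W
  }
  idx
}

# Nearest-neighbour 2x upsampling: for each fine voxel, its coarse parent.
.upsample_indices <- function(fine_shape) {
  H <- fine_shape[1]; W <- fine_shape[2]; D <- fine_shape[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  vox <- as.matrix(expand.grid(x = seq_len(H), y = seq_len(W), z = seq_len(D)))
  cx <- (vox[, 1L] + 1L) %/% 2L
  cy <- (vox[, 2L] + 1L) %/% 2L
  cz <- (vox[, 3L] + 1L) %/% 2L
  cx + (cy - 1L) * H2 + (cz - 1L) * H2 * W2
}

# All index tables for the resolution pyramid of a given input shape.
.make_geometry <- function(volume_shape, n_levels = 3L) {
  shapes <- vector("list", n_levels + 1L)
  shapes[[1L]] <- as.integer(volume_shape)
  for (l in seq_len(n_levels)) shapes[[l + 1L]] <- shapes[[l]] %/% 2L
  list(
    shapes = shapes,
    conv = lapply(shapes, .conv_indices),
    pool = lapply(seq_len(n_levels), function(l) .pool_indices(shapes[[l]])),
    up = lapply(seq_len(n_levels), function(l) .upsample_indices(shapes[[l]]))
  )
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# X: nvox x Cin; W: (27 * Cin) x Cout with rows ordered offset-fastest within
# each input channel block; returns the pre-activation, nvox x Cout. The
# spatial loops run in compiled code (src/conv3d.cpp).
.conv3d_forward <- function(X, W, b, ci) {
  list(Y = .conv3d_fwd_cpp(X, ci$shape, W, b))
}

.conv3d_backward <- function(dY, X, W, ci, Cin) {
  .conv3d_bwd_cpp(X, ci$shape, W, dY)
}

# 2x2x2 pooling. Average pooling preserves global intensity statistics
# through the encoder; max pooling emphasises focal activations. Max pooling
# records per-channel argmax (linear input index) for backprop.
.pool_forward <- function(X, pidx, type = "avg") {
  if (type == "avg") {
    Y <- X[pidx[, 1L], , drop = FALSE]
    for (o in 2:8) Y <- Y + X[pidx[, o], , drop = FALSE]
    list(Y = Y / 8, amax = NULL)
  } else {
    .maxpool_forward(X, pidx)
  }
}

.pool_backward <- function(dY, amax, pidx, nvox_in, type = "avg") {
  if (type == "avg") {
    C <- ncol(dY)
    dX <- matrix(0, nvox_in, C)
    d8 <- dY / 8
    for (o in seq_len(8L)) dX[pidx[, o], ] <- dX[pidx[, o], ] + d8
    dX
  } else {
    .maxpool_backward(dY, amax, nvox_in)
  }
}

.maxpool_forward <- function(X, pidx) {
  C <- ncol(X)
  nout <- nrow(pidx)
  Y <- matrix(0, nout, C)
  amax <- matrix(0L, nout, C)
  rows <- seq_len(nout)
  for (c in seq_len(C)) {
    G <- matrix(X[pidx, c], nout, 8L)
    a <- max.col(G, ties.method = "first")
    Y[, c] <- G[cbind(rows, a)]
    amax[, c] <- pidx[cbind(rows, a)]
  }
  list(Y = Y, amax = amax)
}

.maxpool_backward <- function(dY, amax, nvox_in) {
  C <- ncol(dY)
  dX <- matrix(0, nvox_in, C)
  for (c in seq_len(C)) {
    dX[amax[, c], c] <- dX[amax[, c], c] + dY[, c]
  }
  dX
}

.upsample_forward <- function(X, up) X[up, , drop = FALSE]

.upsample_backward <- function(dY, up) {
  out <- rowsum(dY, up)
  # rowsum sorts by group; parents 1..ncoarse are all present, so order holds
  out
}

# Parameter initialisation: He for ReLU layers, Glorot for sigmoid outputs.
.init_weight <- function(fan_in, fan_out, act = c("relu", "sigmoid")) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
  matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
}

# Adam optimiser over a flat named list of arrays.
.adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# decay: named numeric vector of per-parameter decoupled weight-decay rates
# (AdamW-style; 0 disables for a parameter).
.adam_step <- function(params, grads, state, lr, decay = NULL, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (!is.null(decay) && !is.null(decay[[nm]]) && decay[[nm]] > 0) {
      step <- step + lr * decay[[nm]] * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
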