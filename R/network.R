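#' Configuration for the multitask recurrence network
#'
#' The backbone is a three-stage 3-D encoder (3x3x3 convolution + ReLU +
#' 2x max-pooling per stage) mirrored by a decoder with nearest-neighbour
#' upsampling and skip concatenations from the matching encoder stage; the
#' decoder ends in a sigmoid voxel head that reconstructs the input volume.
#' The bottleneck features are summarised by per-channel global average and
#' maximum pooling, standardised with training-cohort statistics,
#' concatenated with the encoded clinical covariates, and fed to a fully
#' connected branch (plus a direct linear path) ending in a single sigmoid
#' unit that outputs the recurrence probability. (Pooling rather than raw
#' flattening keeps the prediction head's input dimension of the order of
#' the channel count, which matters at cohort sizes of a few hundred
#' patients.)
#'
#' @param volume_shape Integer triple (H, W, D); each dimension must be
#'   divisible by 8 so that three pooling/upsampling stages round-trip.
#' @param encoder_channels Exactly three channel counts, one per encoder
#'   stage.
#' @param fc_widths Hidden widths of the fully connected prediction branch.
#' @param clinical_dim Length of the encoded clinical covariate vector.
#' @param alpha Entropic index of the THC prediction loss; `alpha = 1` is the
#'   Shannon binary cross-entropy.
#' @param pooling Encoder downsampling operator, `"max"` (default) or
#'   `"avg"`.
#' @param prediction_loss `"thc"` (dispatching to Shannon near `alpha = 1`) or
#'   `"shannon"` to force the explicit Shannon loss.
#' @param learning_rate Adam learning rate.
#' @param dropout Train-time dropout rate on the pooled bottleneck features
#'   entering the prediction branch (0 disables). The clinical covariates are
#'   never dropped.
#' @param weight_decay Decoupled L2 weight decay applied to the prediction
#'   head's weight matrices only (ridge-like shrinkage; the convolutional
#'   backbone and all biases are not decayed). Appropriate for cohorts of a
#'   few hundred patients.
#' @param batch_size Minibatch size.
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling initialisation and data shuffling.
#' @param loss_weights Length-2 weights for the reconstruction and prediction
#'   losses; the default equal weighting is the configuration that worked
#'   best for this multitask setup.
#' @return A `network_config` object.
#' @examples
#' cfg <- network_config(volume_shape = c(16, 16, 8), epochs = 2)
#' @export
network_config <- function(volume_shape = c(32L, 32L, 16L),
                           encoder_channels = c(8L, 16L, 32L),
                           fc_widths = c(64L, 16L),
                           clinical_dim = clinical_encoding_dim(),
                           alpha = 1,
                           pooling = c("max", "avg"),
                           prediction_loss = c("thc", "shannon"),
                           learning_rate = 1e-3,
                           dropout = 0.2,
                           weight_decay = 0.05,
                           batch_size = 4L,
                           epochs = 100L,
                           seed = 1L,
                           loss_weights = c(rec = 1, pred = 1)) {
  prediction_loss <- match.arg(prediction_loss)
  pooling <- match.arg(pooling)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L)) {
    stop("'volume_shape' must be three dimensions of at least 8 voxels")
  }
  if (any(volume_shape %% 8L != 0L)) {
    stop("each volume dimension must be divisible by 8 (three 2x poolings)")
  }
  if (length(encoder_channels) != 3L) {
    stop("'encoder_channels' must list exactly three encoder stages")
  }
  .check_alpha(alpha)
  if (epochs < 1L) stop("'epochs' must be >= 1")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  if (weight_decay < 0) stop("'weight_decay' must be >= 0")
  if (length(loss_weights) != 2L || any(loss_weights < 0)) {
    stop("'loss_weights' must be two non-negative weights")
  }
  structure(
    list(
      volume_shape = volume_shape,
      encoder_channels = as.integer(encoder_channels),
      fc_widths = as.integer(fc_widths),
      clinical_dim = as.integer(clinical_dim),
      alpha = alpha,
      pooling = pooling,
      prediction_loss = prediction_loss,
      learning_rate = learning_rate,
      dropout = dropout,
      weight_decay = weight_decay,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      seed = as.integer(seed),
      loss_weights = c(rec = loss_weights[[1]], pred = loss_weights[[2]])
    ),
    class = "network_config"
  )
}

#' Build an untrained multitask model
#'
#' Initialises all convolutional and fully connected parameters (He
#' initialisation for ReLU layers, Glorot for the sigmoid heads) from
#' `cfg$seed` and precomputes the gather/scatter index tables for the
#' resolution pyramid.
#'
#' @param cfg A [network_config()].
#' @return A `thc_model` object (untrained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  geo <- .make_geometry(cfg$volume_shape)
  ch <- cfg$encoder_channels
  fin <- 2L * ch[3L] + cfg$clinical_dim
  fw <- cfg$fc_widths
  set.seed(cfg$seed)
  params <- list(
    W_e1 = .init_weight(27L * 1L, ch[1L], "relu"), b_e1 = numeric(ch[1L]),
    W_e2 = .init_weight(27L * ch[1L], ch[2L], "relu"), b_e2 = numeric(ch[2L]),
    W_e3 = .init_weight(27L * ch[2L], ch[3L], "relu"), b_e3 = numeric(ch[3L]),
    W_d3 = .init_weight(27L * 2L * ch[3L], ch[2L], "relu"), b_d3 = numeric(ch[2L]),
    W_d2 = .init_weight(27L * 2L * ch[2L], ch[1L], "relu"), b_d2 = numeric(ch[1L]),
    W_d1 = .init_weight(27L * 2L * ch[1L], 1L, "sigmoid"), b_d1 = numeric(1L)
  )
  widths <- c(fin, fw, 1L)
  for (i in seq_len(length(widths) - 1L)) {
    act <- if (i == length(widths) - 1L) "sigmoid" else "relu"
    params[[paste0("W_fc", i)]] <- .init_weight(widths[i], widths[i + 1L], act)
    params[[paste0("b_fc", i)]] <- numeric(widths[i + 1L])
  }
  # direct linear shortcut from the fused features to the logit, alongside
  # the MLP path ("wide and deep"); eases learning of linear covariate effects
  params$W_lin <- .init_weight(fin, 1L, "sigmoid")
  structure(
    list(params = params, cfg = cfg, geometry = geo, trained = FALSE,
         clinical_stats = NULL, training_log = NULL),
    class = "thc_model"
  )
}

# Encoder-only pass returning the raw pooled bottleneck features.
.encoder_pooled <- function(params, geo, cfg, vol) {
  f1 <- .conv3d_forward(vol, params$W_e1, params$b_e1, geo$conv[[1L]])
  p1 <- .pool_forward(.relu(f1$Y), geo$pool[[1L]], cfg$pooling)$Y
  f2 <- .conv3d_forward(p1, params$W_e2, params$b_e2, geo$conv[[2L]])
  p2 <- .pool_forward(.relu(f2$Y), geo$pool[[2L]], cfg$pooling)$Y
  f3 <- .conv3d_forward(p2, params$W_e3, params$b_e3, geo$conv[[3L]])
  p3 <- .pool_forward(.relu(f3$Y), geo$pool[[3L]], cfg$pooling)$Y
  gmax_idx <- max.col(t(p3), ties.method = "first")
  c(colMeans(p3), p3[cbind(gmax_idx, seq_len(ncol(p3)))])
}

# Mean/sd of the pooled features over the training volumes (sd floored away
# from zero); recomputed at the start of every epoch as the encoder drifts.
.pooled_feature_stats <- function(params, geo, cfg, vols) {
  F <- vapply(vols, function(v) .encoder_pooled(params, geo, cfg, v),
              numeric(2L * cfg$encoder_channels[3L]))
  m <- rowMeans(F)
  s <- apply(F, 1L, stats::sd)
  s[!is.finite(s) | s < 1e-8] <- 1
  list(mean = m, sd = s)
}

# Forward pass for one sample. vol: [nvox x 1] matrix, clinical: numeric.
# With cache = TRUE all intermediates needed by .backward_sample are kept.
.forward_sample <- function(params, geo, cfg, vol, clinical, cache = FALSE,
                            dropout_mask = NULL, feature_stats = NULL) {
  ch <- cfg$encoder_channels
  f1 <- .conv3d_forward(vol, params$W_e1, params$b_e1, geo$conv[[1L]])
  a1 <- .relu(f1$Y)
  pf1 <- .pool_forward(a1, geo$pool[[1L]], cfg$pooling)
  f2 <- .conv3d_forward(pf1$Y, params$W_e2, params$b_e2, geo$conv[[2L]])
  a2 <- .relu(f2$Y)
  pf2 <- .pool_forward(a2, geo$pool[[2L]], cfg$pooling)
  f3 <- .conv3d_forward(pf2$Y, params$W_e3, params$b_e3, geo$conv[[3L]])
  a3 <- .relu(f3$Y)
  pf3 <- .pool_forward(a3, geo$pool[[3L]], cfg$pooling)
  p3 <- pf3$Y

  u3 <- .upsample_forward(p3, geo$up[[3L]])
  c3 <- cbind(u3, a3)
  g3 <- .conv3d_forward(c3, params$W_d3, params$b_d3, geo$conv[[3L]])
  ad3 <- .relu(g3$Y)
  u2 <- .upsample_forward(ad3, geo$up[[2L]])
  c2 <- cbind(u2, a2)
  g2 <- .conv3d_forward(c2, params$W_d2, params$b_d2, geo$conv[[2L]])
  ad2 <- .relu(g2$Y)
  u1 <- .upsample_forward(ad2, geo$up[[1L]])
  c1 <- cbind(u1, a1)
  g1 <- .conv3d_forward(c1, params$W_d1, params$b_d1, geo$conv[[1L]])
  recon <- .sigmoid(g1$Y)

  # per-channel global average + max pooling of the bottleneck: the mean
  # summarises overall intensity, the max captures focal (lesion-like)
  # activations; both keep the fusion input low-dimensional relative to
  # typical cohort sizes
  gmax_idx <- max.col(t(p3), ties.method = "first")
  bot <- c(colMeans(p3), p3[cbind(gmax_idx, seq_len(ncol(p3)))])
  # standardise the pooled image features with training-cohort statistics:
  # their discriminative variation is a small fraction of their raw scale, so
  # without this the head would need very large (and decayed) weights
  if (!is.null(feature_stats)) {
    bot <- (bot - feature_stats$mean) / feature_stats$sd
  }
  if (!is.null(dropout_mask)) bot <- bot * dropout_mask
  feat <- c(bot, clinical)
  h1z <- as.numeric(feat %*% params$W_fc1) + params$b_fc1
  h1 <- .relu(h1z)
  h2z <- as.numeric(h1 %*% params$W_fc2) + params$b_fc2
  h2 <- .relu(h2z)
  logit <- sum(h2 * params$W_fc3) + sum(feat * params$W_lin) + params$b_fc3
  q <- .sigmoid(logit)

  out <- list(recon = recon, q = q)
  if (cache) {
    out$cache <- list(
      vol = vol, a1 = a1, a2 = a2, a3 = a3,
      z1 = f1$Y, z2 = f2$Y, z3 = f3$Y,
      amax1 = pf1$amax, amax2 = pf2$amax, amax3 = pf3$amax,
      p1 = pf1$Y, p2 = pf2$Y, p3 = p3,
      c3 = c3, c2 = c2, c1 = c1,
      zd3 = g3$Y, zd2 = g2$Y,
      feat = feat, h1z = h1z, h1 = h1, h2z = h2z, h2 = h2, logit = logit,
      dropout_mask = dropout_mask, gmax_idx = gmax_idx,
      feature_stats = feature_stats
    )
  }
  out
}

# Backward pass for one sample. d_recon: gradient of the loss w.r.t. the
# reconstruction probabilities (post-sigmoid), dq: w.r.t. the predicted
# recurrence probability. Returns gradients for every parameter.
.backward_sample <- function(params, geo, cfg, out, d_recon, dq) {
  ch <- cfg$encoder_channels
  cc <- out$cache
  q <- out$q

  # prediction branch
  dlogit <- dq * q * (1 - q)
  g <- list()
  g$W_fc3 <- matrix(cc$h2 * dlogit, ncol = 1L)
  g$b_fc3 <- dlogit
  dh2 <- as.numeric(params$W_fc3) * dlogit
  dh2 <- dh2 * (cc$h2z > 0)
  g$W_fc2 <- outer(cc$h1, dh2)
  g$b_fc2 <- dh2
  dh1 <- as.numeric(params$W_fc2 %*% dh2)
  dh1 <- dh1 * (cc$h1z > 0)
  g$W_fc1 <- outer(cc$feat, dh1)
  g$b_fc1 <- dh1
  g$W_lin <- matrix(cc$feat * dlogit, ncol = 1L)
  dfeat <- as.numeric(params$W_fc1 %*% dh1) +
    as.numeric(params$W_lin) * dlogit
  nbot_vox <- geo$conv[[4L]]$nvox
  dbot <- dfeat[seq_len(2L * ch[3L])]
  if (!is.null(cc$dropout_mask)) dbot <- dbot * cc$dropout_mask
  if (!is.null(cc$feature_stats)) dbot <- dbot / cc$feature_stats$sd
  dmean <- dbot[seq_len(ch[3L])]
  dmax <- dbot[ch[3L] + seq_len(ch[3L])]
  dp3_pred <- matrix(rep(dmean / nbot_vox, each = nbot_vox), nbot_vox, ch[3L])
  sel <- cbind(cc$gmax_idx, seq_len(ch[3L]))
  dp3_pred[sel] <- dp3_pred[sel] + dmax

  # decoder
  dzd1 <- d_recon * out$recon * (1 - out$recon)
  bd1 <- .conv3d_backward(dzd1, cc$c1, params$W_d1, geo$conv[[1L]], 2L * ch[1L])
  g$W_d1 <- bd1$dW; g$b_d1 <- bd1$db
  du1 <- bd1$dX[, seq_len(ch[1L]), drop = FALSE]
  da1_skip <- bd1$dX[, ch[1L] + seq_len(ch[1L]), drop = FALSE]

  dad2 <- .upsample_backward(du1, geo$up[[1L]])
  dzd2 <- dad2 * (cc$zd2 > 0)
  bd2 <- .conv3d_backward(dzd2, cc$c2, params$W_d2, geo$conv[[2L]], 2L * ch[2L])
  g$W_d2 <- bd2$dW; g$b_d2 <- bd2$db
  du2 <- bd2$dX[, seq_len(ch[2L]), drop = FALSE]
  da2_skip <- bd2$dX[, ch[2L] + seq_len(ch[2L]), drop = FALSE]

  dad3 <- .upsample_backward(du2, geo$up[[2L]])
  dzd3 <- dad3 * (cc$zd3 > 0)
  bd3 <- .conv3d_backward(dzd3, cc$c3, params$W_d3, geo$conv[[3L]], 2L * ch[3L])
  g$W_d3 <- bd3$dW; g$b_d3 <- bd3$db
  du3 <- bd3$dX[, seq_len(ch[3L]), drop = FALSE]
  da3_skip <- bd3$dX[, ch[3L] + seq_len(ch[3L]), drop = FALSE]

  dp3 <- .upsample_backward(du3, geo$up[[3L]]) + dp3_pred

  # encoder
  da3 <- .pool_backward(dp3, cc$amax3, geo$pool[[3L]], geo$conv[[3L]]$nvox,
                        cfg$pooling) + da3_skip
  dz3 <- da3 * (cc$z3 > 0)
  be3 <- .conv3d_backward(dz3, cc$p2, params$W_e3, geo$conv[[3L]], ch[2L])
  g$W_e3 <- be3$dW; g$b_e3 <- be3$db

  da2 <- .pool_backward(be3$dX, cc$amax2, geo$pool[[2L]], geo$conv[[2L]]$nvox,
                        cfg$pooling) + da2_skip
  dz2 <- da2 * (cc$z2 > 0)
  be2 <- .conv3d_backward(dz2, cc$p1, params$W_e2, geo$conv[[2L]], ch[1L])
  g$W_e2 <- be2$dW; g$b_e2 <- be2$db

  da1 <- .pool_backward(be2$dX, cc$amax1, geo$pool[[1L]], geo$conv[[1L]]$nvox,
                        cfg$pooling) + da1_skip
  dz1 <- da1 * (cc$z1 > 0)
  be1 <- .conv3d_backward(dz1, cc$vol, params$W_e1, geo$conv[[1L]], 1L)
  g$W_e1 <- be1$dW; g$b_e1 <- be1$db

  g
}

.as_volume_matrix <- function(volume, volume_shape) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || !all(d == volume_shape)) {
    stop(sprintf(
      "volume shape (%s) does not match the configured (%s)",
      paste(d, collapse = "x"), paste(volume_shape, collapse = "x")
    ))
  }
  matrix(as.numeric(volume), ncol = 1L)
}

#' Run the multitask model on one patient
#'
#' Deterministic evaluation-mode forward pass.
#'
#' @param model A `thc_model` (trained or untrained).
#' @param volume 3-D array matching the configured volume shape.
#' @param clinical Encoded clinical covariate vector of length
#'   `cfg$clinical_dim` (see [encode_clinical()]).
#' @return List with `reconstruction` (3-D array, same shape as the input)
#'   and `recurrence_prob` (scalar in (0, 1)).
#' @export
model_forward <- function(model, volume, clinical) {
  stopifnot(inherits(model, "thc_model"))
  cfg <- model$cfg
  if (length(clinical) != cfg$clinical_dim) {
    stop(sprintf(
      "clinical vector length %d does not match clinical_dim %d",
      length(clinical), cfg$clinical_dim
    ))
  }
  vol <- .as_volume_matrix(volume, cfg$volume_shape)
  out <- .forward_sample(model$params, model$geometry, cfg, vol,
                         as.numeric(clinical),
                         feature_stats = model$feature_stats)
  list(
    reconstruction = array(out$recon, dim = cfg$volume_shape),
    recurrence_prob = out$q
  )
}

# Per-sample prediction-loss value and dL/dq at batch size n. Linear in the
# batch mean for both families, so per-sample terms can be averaged exactly.
.pred_loss_terms <- function(label, q, alpha, shannon, n, eps = .THC_EPS) {
  qc <- clamp_probability(q, eps)
  if (shannon || .is_shannon(alpha)) {
    loss <- -(label * log(qc) + (1 - label) * log(1 - qc))
    grad <- -(label / qc - (1 - label) / (1 - qc)) / n
  } else {
    s <- qc^(alpha - 1) * label + (1 - qc)^(alpha - 1) * (1 - label)
    loss <- (1 - s) / (alpha - 1)
    grad <- -(qc^(alpha - 2) * label - (1 - qc)^(alpha - 2) * (1 - label)) / n
  }
  list(loss = loss, grad = grad)
}

#' Train the multitask model on a cohort
#'
#' Minimises the total loss -- the mean squared reconstruction error plus the
#' binary prediction loss (THC at `cfg$alpha`, Shannon when `alpha` is 1) --
#' with Adam. Clinical covariates are standardised with statistics computed
#' from this cohort (train folds only under cross-validation) and the
#' statistics are stored in the returned model, so held-out patients are
#' encoded without leakage. Fully reproducible from `cfg$seed`.
#'
#' @param model An untrained model from [build_model()].
#' @param cohort A list of patient records (see [generate_cohort()]).
#' @param cfg The [network_config()] used to build the model.
#' @return The trained `thc_model`, with a `training_log` data frame holding
#'   per-epoch mean `rec`, `pred` and `total` losses.
#' @export
train_model <- function(model, cohort, cfg = model$cfg) {
  stopifnot(inherits(model, "thc_model"), length(cohort) >= 1L)
  geo <- model$geometry
  stats <- clinical_stats(cohort)
  clin <- encode_cohort_clinical(cohort, stats)
  labels <- vapply(cohort, function(r) as.numeric(r$label), numeric(1))
  if (!all(labels %in% c(0, 1))) stop("cohort labels must be 0/1")
  vols <- lapply(cohort, function(r) .as_volume_matrix(r$volume, cfg$volume_shape))
  n <- length(cohort)
  w <- cfg$loss_weights
  shannon <- cfg$prediction_loss == "shannon"

  params <- model$params
  opt <- .adam_init(params)
  head_w <- grep("^W_(fc|lin)", names(params), value = TRUE)
  decay <- stats::setNames(rep(0, length(params)), names(params))
  decay[head_w] <- cfg$weight_decay
  log_rec <- log_pred <- numeric(cfg$epochs)

  set.seed(cfg$seed + 1L)
  fs <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    fs <- .pooled_feature_stats(params, geo, cfg, vols)
    perm <- sample.int(n)
    rec_terms <- pred_terms <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      batch <- perm[pos:min(pos + cfg$batch_size - 1L, n)]
      b <- length(batch)
      grads <- NULL
      for (i in batch) {
        mask <- if (cfg$dropout > 0) {
          (stats::runif(2L * cfg$encoder_channels[3L]) >= cfg$dropout) /
            (1 - cfg$dropout)
        }
        out <- .forward_sample(params, geo, cfg, vols[[i]], clin[i, ],
                               cache = TRUE, dropout_mask = mask,
                               feature_stats = fs)
        rec_i <- sum((out$recon - vols[[i]])^2)
        pl <- .pred_loss_terms(labels[i], out$q, cfg$alpha, shannon, b)
        rec_terms[i] <- w[["rec"]] * rec_i
        pred_terms[i] <- w[["pred"]] * pl$loss
        d_recon <- w[["rec"]] * 2 * (out$recon - vols[[i]]) / b
        dq <- w[["pred"]] * pl$grad
        gi <- .backward_sample(params, geo, cfg, out, d_recon, dq)
        grads <- if (is.null(grads)) gi else mapply(`+`, grads, gi,
                                                    SIMPLIFY = FALSE)
      }
      step <- .adam_step(params, grads, opt, cfg$learning_rate, decay)
      params <- step$params
      opt <- step$state
      pos <- pos + cfg$batch_size
    }
    log_rec[epoch] <- mean(rec_terms)
    log_pred[epoch] <- mean(pred_terms)
    if (!is.finite(log_rec[epoch])) {
      stop(sprintf("non-finite reconstruction loss at epoch %d", epoch))
    }
    if (!is.finite(log_pred[epoch])) {
      stop(sprintf("non-finite prediction loss at epoch %d", epoch))
    }
  }

  model$params <- params
  model$trained <- TRUE
  model$clinical_stats <- stats
  # recompute with the final parameters: statistics from the start of the
  # last epoch no longer match the trained encoder
  model$feature_stats <- .pooled_feature_stats(params, geo, cfg, vols)
  model$training_log <- data.frame(
    epoch = seq_len(cfg$epochs), rec = log_rec, pred = log_pred,
    total = log_rec + log_pred
  )
  model
}

#' Build and train a recurrence model in one call
#'
#' @inheritParams train_model
#' @param cfg A [network_config()].
#' @return A trained `thc_model`.
#' @export
fit_recurrence_model <- function(cohort, cfg) {
  train_model(build_model(cfg), cohort, cfg)
}

#' Predict recurrence for a single patient
#'
#' @param object A trained `thc_model`.
#' @param volume 3-D array.
#' @param record Optional patient record; when given, its volume and clinical
#'   fields are used and `volume`/`clinical` are ignored.
#' @param clinical Encoded clinical vector; when `NULL` and `record` is given,
#'   the record is encoded with the model's stored training statistics.
#' @param threshold Decision threshold; the predicted label is 1 when the
#'   probability is greater than or equal to it.
#' @param ... Unused.
#' @return List with `probability` and `label`.
#' @export
predict.thc_model <- function(object, volume = NULL, clinical = NULL,
                              record = NULL, threshold = 0.5, ...) {
  if (!is.null(record)) {
    volume <- record$volume
    if (is.null(clinical)) {
      if (is.null(object$clinical_stats)) {
        stop("model has no stored clinical statistics; pass 'clinical'")
      }
      clinical <- encode_clinical(record, object$clinical_stats)
    }
  }
  out <- model_forward(object, volume, clinical)
  list(
    probability = out$recurrence_prob,
    label = as.integer(out$recurrence_prob >= threshold)
  )
}

#' Predict recurrence for every patient in a cohort
#'
#' @param model A trained `thc_model`.
#' @param cohort List of patient records.
#' @param threshold Decision threshold (label 1 iff probability >= threshold).
#' @return Data frame with columns `probability` and `label`.
#' @export
predict_cohort <- function(model, cohort, threshold = 0.5) {
  probs <- vapply(cohort, function(r) {
    predict.thc_model(model, record = r, threshold = threshold)$probability
  }, numeric(1))
  data.frame(probability = probs, label = as.integer(probs >= threshold))
}
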