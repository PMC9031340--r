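#' Default clamping tolerance for predicted probabilities
#'
#' Predicted probabilities are clamped to `[eps, 1 - eps]` before any power or
#' logarithm is taken: for `alpha < 1` the term `q^(alpha - 1)` diverges as
#' `q -> 0`, and `log(q)` diverges for every alpha.
#' @keywords internal
.THC_EPS <- 1e-7

# alpha values within this distance of 1 are dispatched to the Shannon branch;
# the THC formulas have a removable singularity at alpha = 1.
.ALPHA_TOL <- 1e-6

#' Validate a finite discrete probability vector
#'
#' @param p Numeric vector of probabilities over `k = length(p)` states.
#' @param tol Tolerance on `sum(p) == 1` (default `1e-9`).
#' @param arg Name used in error messages.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @examples
#' validate_probability_vector(c(0.25, 0.75))
#' @export
validate_probability_vector <- function(p, tol = 1e-9, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L) {
    stop(sprintf("'%s' must be a non-empty numeric vector", arg))
  }
  if (anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("'%s' contains non-finite values", arg))
  }
  if (any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' has entries outside [0, 1]", arg))
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12g)", arg, sum(p)))
  }
  invisible(p)
}

#' Clamp probabilities away from 0 and 1
#'
#' @param q Numeric vector.
#' @param eps Clamping tolerance.
#' @return `pmin(pmax(q, eps), 1 - eps)`.
#' @export
clamp_probability <- function(q, eps = .THC_EPS) {
  pmin(pmax(q, eps), 1 - eps)
}

.is_shannon <- function(alpha) abs(alpha - 1) < .ALPHA_TOL

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("'alpha' must be a single finite value > 0")
  }
  invisible(alpha)
}

#' Shannon entropy of a discrete distribution
#'
#' Computes `-sum(p_i * log(p_i))` with the natural logarithm and the
#' continuity convention `0 * log(0) = 0`. The entropy is 0 exactly when `p`
#' is a Dirac (one-hot) distribution and maximal, `log(k)`, when `p` is
#' uniform over its `k` states.
#'
#' @param p Probability vector (validated).
#' @return Non-negative scalar entropy in nats.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # log(2)
#' shannon_entropy(c(1, 0))     # 0
#' @export
shannon_entropy <- function(p) {
  validate_probability_vector(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Shannon cross-entropy between a prediction and a reference distribution
#'
#' Computes `-sum(p_i * log(q_i))`, where `q` is the predicted distribution
#' and `p` the reference (typically a Dirac at the true class). `q` is clamped
#' to `[eps, 1 - eps]` before the logarithm.
#'
#' @param q Predicted probability vector.
#' @param p Reference probability vector, same length as `q`.
#' @param eps Clamping tolerance for `q`.
#' @return Non-negative scalar cross-entropy in nats.
#' @examples
#' shannon_cross_entropy(c(0.8, 0.2), c(1, 0)) # -log(0.8)
#' @export
shannon_cross_entropy <- function(q, p, eps = .THC_EPS) {
  validate_probability_vector(q, arg = "q")
  validate_probability_vector(p, arg = "p")
  if (length(q) != length(p)) {
    stop("'q' and 'p' must have the same number of states")
  }
  -sum(p * log(clamp_probability(q, eps)))
}

#' Entropy generator function of the THC family
#'
#' The Tsallis-Havrda-Charvat family replaces the Shannon generator
#' `h(u) = u * log(u)` by `h_alpha(u) = (u^alpha - u) / (alpha - 1)`, a convex
#' function on `[0, 1]` with `h_alpha(0) = h_alpha(1) = 0`. Within `1e-6` of
#' `alpha = 1` the Shannon generator is used (the family's limit).
#'
#' @param u Numeric vector with values in `[0, 1]`.
#' @param alpha Entropic index, `alpha > 0`.
#' @return `h_alpha(u)`, vectorized over `u`.
#' @examples
#' h_alpha(0.5, 2)   # -0.25
#' h_alpha(0.25, 0.5) # -0.5
#' @export
h_alpha <- function(u, alpha) {
  .check_alpha(alpha)
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  if (.is_shannon(alpha)) {
    out <- numeric(length(u))
    nz <- u > 0
    out[nz] <- u[nz] * log(u[nz])
    return(out)
  }
  (u^alpha - u) / (alpha - 1)
}

#' Tsallis-Havrda-Charvat entropy
#'
#' Computes `(1 - sum(p_i^alpha)) / (alpha - 1)`, equivalently
#' `-sum(h_alpha(p_i))`. Non-negative for every valid `p` and `alpha > 0`,
#' zero exactly on Dirac distributions, and converging to [shannon_entropy()]
#' as `alpha -> 1` (values of `alpha` within `1e-6` of 1 dispatch to the
#' Shannon branch).
#'
#' @inheritParams shannon_entropy
#' @param alpha Entropic index, `alpha > 0`.
#' @return Non-negative scalar entropy.
#' @examples
#' thc_entropy(c(0.5, 0.5), 2) # 0.5
#' @export
thc_entropy <- function(p, alpha) {
  .check_alpha(alpha)
  validate_probability_vector(p)
  if (.is_shannon(alpha)) {
    return(shannon_entropy(p))
  }
  (1 - sum(p^alpha)) / (alpha - 1)
}

#' Tsallis-Havrda-Charvat cross-entropy
#'
#' Computes `(1 - sum(q_i^(alpha - 1) * p_i)) / (alpha - 1)` with `q` clamped
#' to `[eps, 1 - eps]`. As with the Shannon cross-entropy, minimizing in `q`
#' drives the prediction toward the reference `p`; the `alpha -> 1` limit is
#' [shannon_cross_entropy()].
#'
#' @inheritParams shannon_cross_entropy
#' @param alpha Entropic index, `alpha > 0`.
#' @return Non-negative scalar cross-entropy.
#' @examples
#' thc_cross_entropy(c(0.8, 0.2), c(1, 0), 2) # 0.2
#' @export
thc_cross_entropy <- function(q, p, alpha, eps = .THC_EPS) {
  .check_alpha(alpha)
  validate_probability_vector(q, arg = "q")
  validate_probability_vector(p, arg = "p")
  if (length(q) != length(p)) {
    stop("'q' and 'p' must have the same number of states")
  }
  if (.is_shannon(alpha)) {
    return(shannon_cross_entropy(q, p, eps))
  }
  qc <- clamp_probability(q, eps)
  (1 - sum(qc^(alpha - 1) * p)) / (alpha - 1)
}

.check_binary_batch <- function(labels, predictions) {
  if (length(labels) < 1L) stop("empty batch: at least one patient required")
  if (length(labels) != length(predictions)) {
    stop("'labels' and 'predictions' must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("'labels' must be 0/1")
  if (anyNA(predictions) || any(!is.finite(predictions))) {
    stop("'predictions' contains non-finite values")
  }
  if (any(predictions < 0) || any(predictions > 1)) {
    stop("'predictions' must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Binary Shannon cross-entropy loss
#'
#' The usual binary cross-entropy over a batch of `N` patients:
#' `-(1/N) * sum(p_n log q_n + (1 - p_n) log(1 - q_n))`, with `q` clamped.
#'
#' @param labels 0/1 ground-truth labels (`1` = recurrence).
#' @param predictions Predicted recurrence probabilities.
#' @param eps Clamping tolerance.
#' @return Non-negative scalar loss.
#' @examples
#' binary_shannon_loss(1, 0.5) # log(2)
#' @export
binary_shannon_loss <- function(labels, predictions, eps = .THC_EPS) {
  .check_binary_batch(labels, predictions)
  q <- clamp_probability(predictions, eps)
  -mean(labels * log(q) + (1 - labels) * log(1 - q))
}

#' Binary Tsallis-Havrda-Charvat cross-entropy loss
#'
#' The THC analogue of the binary cross-entropy:
#' `(1/(alpha - 1)) * (1 - (1/N) * sum(q_n^(alpha-1) p_n +
#' (1 - q_n)^(alpha-1) (1 - p_n)))`. Values of `alpha` within `1e-6` of 1
#' dispatch to [binary_shannon_loss()], the family's limit.
#'
#' @inheritParams binary_shannon_loss
#' @param alpha Entropic index, `alpha > 0`.
#' @return Non-negative scalar loss.
#' @examples
#' binary_thc_loss(1, 0.8, alpha = 2) # 0.2
#' @export
binary_thc_loss <- function(labels, predictions, alpha, eps = .THC_EPS) {
  .check_alpha(alpha)
  .check_binary_batch(labels, predictions)
  if (.is_shannon(alpha)) {
    return(binary_shannon_loss(labels, predictions, eps))
  }
  q <- clamp_probability(predictions, eps)
  (1 - mean(q^(alpha - 1) * labels + (1 - q)^(alpha - 1) * (1 - labels))) /
    (alpha - 1)
}

#' Gradient of the binary THC loss with respect to the predictions
#'
#' Returns the per-patient partial derivatives `dL/dq_n` of
#' [binary_thc_loss()]:
#' `-(1/N) * (q_n^(alpha-2) p_n - (1 - q_n)^(alpha-2) (1 - p_n))` for
#' `alpha != 1`, and the Shannon gradient
#' `-(1/N) * (p_n / q_n - (1 - p_n) / (1 - q_n))` near `alpha = 1`.
#' Predictions on or beyond the clamp boundary are differentiated at the
#' clamped value.
#'
#' @inheritParams binary_thc_loss
#' @return Numeric vector of length `N`.
#' @export
binary_thc_loss_gradient <- function(labels, predictions, alpha, eps = .THC_EPS) {
  .check_alpha(alpha)
  .check_binary_batch(labels, predictions)
  q <- clamp_probability(predictions, eps)
  n <- length(labels)
  if (.is_shannon(alpha)) {
    return(-(labels / q - (1 - labels) / (1 - q)) / n)
  }
  -(q^(alpha - 2) * labels - (1 - q)^(alpha - 2) * (1 - labels)) / n
}

#' Mean squared reconstruction error over a batch of volumes
#'
#' For each patient the squared Euclidean norm of the voxelwise difference
#' between the target volume and its reconstruction is computed; the result is
#' the mean of these per-patient squared norms.
#'
#' @param targets A single array or a list of arrays (true volumes).
#' @param reconstructions Array or list of arrays, shapes matching `targets`.
#' @return Non-negative scalar loss.
#' @examples
#' mse_reconstruction_loss(c(1, 2), c(0, 0)) # 5
#' @export
mse_reconstruction_loss <- function(targets, reconstructions) {
  if (!is.list(targets)) targets <- list(targets)
  if (!is.list(reconstructions)) reconstructions <- list(reconstructions)
  if (length(targets) != length(reconstructions) || length(targets) < 1L) {
    stop("'targets' and 'reconstructions' must be non-empty lists of equal length")
  }
  per_patient <- vapply(seq_along(targets), function(n) {
    y <- targets[[n]]
    yhat <- reconstructions[[n]]
    if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat)) {
      stop(sprintf("shape mismatch between target and reconstruction %d", n))
    }
    if (anyNA(y) || anyNA(yhat)) stop("volumes must be finite")
    sum((as.numeric(y) - as.numeric(yhat))^2)
  }, numeric(1))
  mean(per_patient)
}

#' Combine reconstruction and prediction losses
#'
#' The training objective is the weighted sum of the reconstruction loss and
#' the prediction loss; both weights default to 1, the configuration found to
#' work best for this multitask setup.
#'
#' @param rec Non-negative reconstruction loss.
#' @param pred Non-negative prediction loss.
#' @param weights Length-2 numeric, weights for `rec` and `pred`.
#' @return A `loss_breakdown` object: list with `rec`, `pred`, `total`.
#' @examples
#' total_loss(5, 0.2)$total # 5.2
#' @export
total_loss <- function(rec, pred, weights = c(rec = 1, pred = 1)) {
  if (rec < 0 || pred < 0) stop("loss components must be non-negative")
  rec_w <- weights[[1]] * rec
  pred_w <- weights[[2]] * pred
  structure(
    list(rec = rec_w, pred = pred_w, total = rec_w + pred_w),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss breakdown: rec = %.6g, pred = %.6g, total = %.6g\n",
    x$rec, x$pred, x$total
  ))
  invisible(x)
}
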