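#' Quartiles of a reference blood-pressure distribution
#'
#' Linear-interpolation quartiles (R's median-inclusive type-7 convention)
#' of the cuff reference values, used to parameterize the penalty loss:
#' samples whose reference falls below Q1 or above Q3 of the training
#' distribution get their error up-weighted.
#'
#' @param reference_bps Numeric vector of at least 4 reference values, mmHg.
#' @return Named vector `c(Q1, Q2, Q3)`.
#' @examples
#' compute_quartiles(c(112, 118, 120, 121, 124, 130))
#' @export
compute_quartiles <- function(reference_bps) {
  if (length(reference_bps) < 4L) {
    stop("insufficient data: need at least 4 reference values to form quartiles",
         call. = FALSE)
  }
  if (any(!is.finite(reference_bps))) {
    stop("reference values must be finite", call. = FALSE)
  }
  q <- stats::quantile(reference_bps, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  c(Q1 = q[1], Q2 = q[2], Q3 = q[3])
}

#' Penalty-loss specification
#'
#' Holds the penalty weight `alpha` and the training-set quartiles that
#' define the up-weighted tails. With `alpha = 1` the loss reduces to plain
#' mean absolute error.
#'
#' @param alpha Penalty multiplier for references outside \[Q1, Q3\]
#'   (>= 1; the study's tuned value is 3).
#' @param Q1,Q3 Quartiles of the training reference distribution, mmHg.
#' @return Object of class `loss_spec`.
#' @export
loss_spec <- function(alpha = 3, Q1, Q3) {
  if (!is.numeric(alpha) || alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (Q1 > Q3) stop("Q1 must be <= Q3", call. = FALSE)
  structure(list(alpha = alpha, Q1 = Q1, Q3 = Q3), class = "loss_spec")
}

#' Loss spec from a training reference vector
#'
#' @param reference_bps Training-set cuff references, mmHg.
#' @param alpha Penalty multiplier.
#' @return A [loss_spec()].
#' @export
loss_spec_from_refs <- function(reference_bps, alpha = 3) {
  q <- compute_quartiles(reference_bps)
  loss_spec(alpha = alpha, Q1 = q[["Q1"]], Q3 = q[["Q3"]])
}

# Per-sample penalty weights: alpha outside [Q1, Q3], 1 inside.
# References exactly on Q1 or Q3 take the unweighted branch (the weighted
# branch is defined by strict inequalities).
penalty_weights <- function(bp_cuff, spec) {
  ifelse(bp_cuff < spec$Q1 | bp_cuff > spec$Q3, spec$alpha, 1)
}

#' Quartile-weighted mean-absolute-error penalty loss
#'
#' Per-sample loss `|pred - cuff| * alpha` when the cuff reference lies
#' strictly below Q1 or strictly above Q3 of the training reference
#' distribution, and plain `|pred - cuff|` otherwise; for vectors the
#' per-sample losses are averaged (penalized MAE). Up-weighting the
#' distribution tails accelerates convergence of the personalized model on
#' the rarer high/low pressures.
#'
#' @param bp_pred Predicted BP, mmHg.
#' @param bp_cuff Cuff reference BP, mmHg (same length).
#' @param spec A [loss_spec()].
#' @param reduce If `TRUE` (default) return the mean over samples,
#'   otherwise the per-sample losses.
#' @return Non-negative loss value(s).
#' @examples
#' sp <- loss_spec(alpha = 3, Q1 = 115, Q3 = 124)
#' penalty_loss(125, 120, sp)  # inside quartile band: 5
#' penalty_loss(125, 130, sp)  # above Q3: |125 - 130| * 3 = 15
#' @export
penalty_loss <- function(bp_pred, bp_cuff, spec, reduce = TRUE) {
  stopifnot(inherits(spec, "loss_spec"), length(bp_pred) == length(bp_cuff))
  per <- abs(bp_pred - bp_cuff) * penalty_weights(bp_cuff, spec)
  if (reduce) mean(per) else per
}

#' Detect the convergence epoch of a training-loss history
#'
#' Convergence is declared at the first epoch after which the
#' running-best (minimum so far) training loss never again improves by at
#' least `rel_tol` (relative), provided at least `patience` further epochs
#' were observed past that point (otherwise convergence is undeclared:
#' the plateau may not have been final). Equivalently: the epoch of the
#' last material improvement. The criterion is scale-invariant, so
#' penalized and plain losses are comparable, and it ignores transient
#' early plateaus that are followed by further descent. A strictly flat
#' history converges at epoch 1; a history still improving at the end
#' yields `NA`.
#'
#' @param loss_history Per-epoch training losses (positive).
#' @param rel_tol Relative improvement threshold.
#' @param patience Number of observed post-convergence epochs required.
#' @return The convergence epoch index, or `NA` if the history never
#'   satisfies the criterion.
#' @examples
#' convergence_epoch(c(10, 5, 2, 1, rep(1, 12)))
#' @export
convergence_epoch <- function(loss_history, rel_tol = 0.02, patience = 10) {
  n <- length(loss_history)
  if (n == 0L) stop("loss history is empty", call. = FALSE)
  if (n < patience + 1L) {
    stop("undefined convergence: history of length ", n,
         " is shorter than patience + 1 = ", patience + 1L, call. = FALSE)
  }
  best <- cummin(loss_history)
  # improvement of epoch j over the best of epochs 1..j-1, relative
  impr <- (best[-n] - loss_history[-1]) / best[-n]
  big <- which(impr >= rel_tol) + 1L
  e <- if (length(big) == 0L) 1L else max(big)
  if (n - e >= patience) e else NA_integer_
}
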