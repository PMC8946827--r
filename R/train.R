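# Adam optimizer state and update for a named list of parameter arrays.
adam_init <- function(params) {
  # w * 0 keeps each state the same structure (vector/matrix/array) as its
  # parameter; mixing 1-d arrays with matrices errors in R arithmetic
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a personalized blood-pressure model
#'
#' Fits one stagewise regression network to one target (systolic or
#' diastolic) of one subject, minimizing the quartile-weighted penalized
#' MAE ([penalty_loss()]) with Adam. The loss quartiles are computed from
#' the training references only (never the test set). Training is
#' deterministic for a given seed: weight initialization and the per-epoch
#' shuffles derive from it.
#'
#' @param images Training images, `H x W x N` array.
#' @param refs Cuff reference values for the target, mmHg (length N).
#' @param config An [ssrnet_config()] (set `bp_range` per target).
#' @param loss A [loss_spec()]; default computes quartiles from `refs`
#'   with `config$alpha`.
#' @param epochs Training epochs (default `config$max_epochs`).
#' @param seed Integer seed.
#' @param test_images,test_refs Optional held-out set; when given, the
#'   report includes `final_test_MAE`.
#' @param verbose Print the loss every 25 epochs.
#' @return List with `model` (trained [build_ssrnet()] network) and
#'   `report` (class `training_report`: `loss_history` (penalized),
#'   `mae_history` (same epochs, unweighted MAE — the common scale on
#'   which convergence is compared across `alpha` values),
#'   `convergence_epoch`, `alpha_used`, `seed`, and `final_test_MAE` when
#'   a test set was supplied).
#' @export
train_personalized <- function(images, refs, config = ssrnet_config(),
                               loss = NULL, epochs = config$max_epochs,
                               seed = 0, test_images = NULL,
                               test_refs = NULL, verbose = FALSE) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  N <- dim(images)[3]
  if (N == 0L || length(refs) == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  stopifnot(length(refs) == N)
  if (is.null(loss)) loss <- loss_spec_from_refs(refs, alpha = config$alpha)

  model <- build_ssrnet(config, seed = derive_seed(seed, 11))
  state <- adam_init(model$params)
  w_all <- penalty_weights(refs, loss)
  loss_history <- numeric(epochs)
  mae_history <- numeric(epochs)

  with_local_seed(derive_seed(seed, 13), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(N)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      ep_mae <- 0
      for (b in batches) {
        Xb <- images[, , b, drop = FALSE]
        yb <- refs[b]
        wb <- w_all[b]
        fw <- ssr_forward(model, Xb, keep_cache = TRUE)
        err <- fw$yhat - yb
        ep_loss <- ep_loss + sum(abs(err) * wb)
        ep_mae <- ep_mae + sum(abs(err))
        dyhat <- wb * sign(err) / length(b)
        grads <- ssr_backward(model, Xb, fw, dyhat)
        upd <- adam_step(model$params, grads, state, lr = config$lr)
        model$params <- upd$params
        state <- upd$state
      }
      loss_history[ep] <- ep_loss / N
      mae_history[ep] <- ep_mae / N
      if (verbose && ep %% 25 == 0) {
        message(sprintf("epoch %d: penalized MAE %.3f", ep, loss_history[ep]))
      }
    }
  })

  conv_ep <- tryCatch(convergence_epoch(loss_history),
                      error = function(e) NA_integer_)
  report <- list(loss_history = loss_history, mae_history = mae_history,
                 convergence_epoch = conv_ep,
                 alpha_used = loss$alpha, seed = as.integer(seed),
                 n_train = N)
  if (!is.null(test_images)) {
    preds <- predict_bp(model, test_images)
    report$final_test_MAE <- mean(abs(preds - test_refs))
  }
  class(report) <- "training_report"
  list(model = model, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("Training report: %d epochs, alpha = %g, seed = %d\n",
              length(x$loss_history), x$alpha_used, x$seed))
  cat(sprintf("  final training loss %.3f mmHg (penalized MAE), convergence epoch %s\n",
              x$loss_history[length(x$loss_history)],
              ifelse(is.na(x$convergence_epoch), "not reached",
                     x$convergence_epoch)))
  if (!is.null(x$final_test_MAE)) {
    cat(sprintf("  held-out MAE %.2f mmHg\n", x$final_test_MAE))
  }
  invisible(x)
}

#' Train the systolic and diastolic models of one subject
#'
#' The systolic and diastolic targets get independent networks (no weight
#' sharing), each with its own regression span and loss quartiles.
#'
#' @param images `H x W x N` training images.
#' @param sbp_refs,dbp_refs Cuff references per target, mmHg.
#' @param config Base [ssrnet_config()]; `bp_range` is overridden per
#'   target.
#' @param alpha Penalty weight for both targets.
#' @param epochs,seed Passed to [train_personalized()].
#' @param sbp_range,dbp_range Regression spans per target, mmHg.
#' @return List with elements `SBP` and `DBP`, each a
#'   [train_personalized()] result.
#' @export
train_subject_models <- function(images, sbp_refs, dbp_refs,
                                 config = ssrnet_config(), alpha = config$alpha,
                                 epochs = config$max_epochs, seed = 0,
                                 sbp_range = c(80, 180),
                                 dbp_range = c(40, 120)) {
  cfg_s <- config; cfg_s$bp_range <- sbp_range; cfg_s$alpha <- alpha
  cfg_d <- config; cfg_d$bp_range <- dbp_range; cfg_d$alpha <- alpha
  list(SBP = train_personalized(images, sbp_refs, cfg_s, epochs = epochs,
                                seed = derive_seed(seed, 21)),
       DBP = train_personalized(images, dbp_refs, cfg_d, epochs = epochs,
                                seed = derive_seed(seed, 22)))
}
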