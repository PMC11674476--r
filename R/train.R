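#' Training configuration
#'
#' Defaults follow DACB's reference training protocol: Adam, learning rate 0.001,
#' batch size 1024, categorical cross-entropy, random seed 42, 150 epochs
#' (reduce for desk-scale runs).
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param optimizer only `"adam"` is provided.
#' @param loss only `"categorical_crossentropy"` is provided.
#' @param seed integer seed controlling shuffling (and, through
#'   [model_config()], initialization in the experiment drivers).
#' @return a `TrainConfig` object.
#' @export
train_config <- function(epochs = 150, learning_rate = 0.001,
                         batch_size = 1024, optimizer = "adam",
                         loss = "categorical_crossentropy", seed = 42) {
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "categorical_crossentropy")
  if (epochs < 1) stop("epochs must be at least 1")
  if (batch_size < 1) stop("batch_size must be at least 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 loss = loss, seed = as.integer(seed)),
            class = "TrainConfig")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

one_hot <- function(y, n_classes) {
  out <- matrix(0, length(y), n_classes)
  out[cbind(seq_along(y), y + 1L)] <- 1
  out
}

#' Train a model with Adam on categorical cross-entropy
#'
#' Minimizes mean categorical cross-entropy with seeded per-epoch shuffling.
#' The returned history holds one loss and one accuracy value per epoch
#' (averages over the epoch's minibatch forward passes), so its length
#' equals `epochs`. Training is deterministic given the model seed and
#' `tcfg$seed`.
#'
#' @param model a `DACBModel` (see [dacb_model()], [build_ablation_variant()]).
#' @param train_batch a `SampleBatch`.
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch loss to stderr.
#' @return the model with trained parameters and a `history` data frame
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train_dacb <- function(model, train_batch, tcfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "DACBModel"), inherits(tcfg, "TrainConfig"))
  x <- train_batch$x; y <- train_batch$y
  if (nrow(x) == 0) stop("training batch is empty")
  if (train_batch$n_classes != model$cfg$n_classes)
    stop("batch class count does not match the model configuration")
  Y <- one_hot(y, model$cfg$n_classes)
  p <- model$params
  st <- adam_state(p)
  hist_loss <- numeric(tcfg$epochs); hist_acc <- numeric(tcfg$epochs)
  n <- nrow(x)
  for (ep in seq_len(tcfg$epochs)) {
    perm <- with_seed(derive_seed(tcfg$seed, ep), sample.int(n))
    starts <- seq(1L, n, by = tcfg$batch_size)
    ep_loss <- 0; ep_correct <- 0
    for (sb in starts) {
      idx <- perm[sb:min(n, sb + tcfg$batch_size - 1L)]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fwd <- dacb_forward_batch(xb, p, model$cfg, want_cache = TRUE)
      pr <- pmax(fwd$probs, 1e-12)
      ep_loss <- ep_loss - sum(log(pr[yb > 0]))
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(yb, ties.method = "first"))
      g <- dacb_backward(p, model$cfg, fwd$cache, fwd$probs, yb)
      upd <- adam_update(p, g, st, tcfg$learning_rate)
      p <- upd$params; st <- upd$state
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f",
                      ep, hist_loss[ep], hist_acc[ep]))
  }
  model$params <- p
  model$history <- data.frame(epoch = seq_len(tcfg$epochs), loss = hist_loss,
                              accuracy = hist_acc)
  model
}
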