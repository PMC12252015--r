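# AdamW optimizer and the joint multi-exit training loop.

new_adamw <- function(model, lr = 5e-5, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$t <- 0L
  st$m <- list(); st$v <- list()
  walk_modules(model, function(mod, path) {
    for (nm in names(mod$params)) {
      key <- paste(path, nm, sep = ".")
      z <- mod$params[[nm]]; z[] <- 0
      st$m[[key]] <- z; st$v[[key]] <- z
    }
  })
  st
}

adamw_step <- function(model, st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  walk_modules(model, function(mod, path) {
    for (nm in names(mod$params)) {
      key <- paste(path, nm, sep = ".")
      g <- mod$grads[[nm]]
      st$m[[key]] <- b1 * st$m[[key]] + (1 - b1) * g
      st$v[[key]] <- b2 * st$v[[key]] + (1 - b2) * g * g
      mhat <- st$m[[key]] / bc1
      vhat <- st$v[[key]] / bc2
      p <- mod$params[[nm]]
      # decoupled weight decay on matrix/tensor weights only
      decay <- if (nm %in% c("W", "W_qkv", "W_O", "W1", "W2")) st$wd else 0
      mod$params[[nm]] <- p - st$lr * (mhat / (sqrt(vhat) + st$eps) + decay * p)
    }
  })
}

#' Train a multi-exit model with the joint stage loss
#'
#' Minimises the weighted sum of per-stage cross-entropies (all four heads,
#' unit weights by default) with AdamW. Deterministic for a fixed seed.
#'
#' @param model An `rfc_model` from [attach_exit_heads()].
#' @param x Image batch array `H x W x C x N`, values in `[0, 1]`.
#' @param y Integer labels in `1..C`.
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr AdamW learning rate (full-scale default 5e-5; desk-scale runs
#'   use larger rates).
#' @param seed Integer seed controlling shuffling.
#' @param stage_weights Per-stage loss weights `lambda_i`.
#' @param fq Train with fake-quantization active (QAT fine-tuning).
#' @param flip_augment Apply random horizontal/vertical mirror flips to each
#'   mini-batch (cheap label-preserving regularisation).
#' @param lr_decay Multiplicative learning-rate decay applied per epoch.
#' @param verbose Print per-epoch stage losses.
#' @return The model (updated in place), invisibly, with an attribute-free
#'   history in `model$history` (per-epoch matrix of the four stage losses).
#' @export
train_model <- function(model, x, y, epochs = 10L, batch_size = 32L,
                        lr = 2e-3, seed = 1L, stage_weights = NULL,
                        fq = FALSE, flip_augment = FALSE, lr_decay = 1,
                        verbose = FALSE) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  n <- dim(x)[4]
  y <- as.integer(y)
  stopifnot(length(y) == n)
  if (is.null(model$opt)) model$opt <- new_adamw(model, lr = lr)
  model$opt$lr <- lr
  hist <- matrix(NA_real_, epochs, model$n_stages)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep), sample.int(n))
    bl <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- numeric(model$n_stages)
    bi <- 0L
    for (b in bl) {
      bi <- bi + 1L
      xb <- x[, , , b, drop = FALSE]
      if (flip_augment) {
        fl <- with_seed(derive_seed(seed, "flip", ep, bi),
                        matrix(stats::runif(2 * length(b)) < 0.5, 2))
        for (j in seq_along(b)) {
          if (fl[1, j]) xb[, , , j] <- xb[, rev(seq_len(dim(xb)[2])), , j]
          if (fl[2, j]) xb[, , , j] <- xb[rev(seq_len(dim(xb)[1])), , , j]
        }
      }
      ctx <- model_ctx(model, training = TRUE, fq = fq, observe = fq)
      out <- model_forward(model, to_fmap(xb), ctx)
      rep <- joint_loss(out$logits, y[b], stage_weights)
      zero_grads(model)
      gl <- joint_loss_grad(out$logits, y[b], stage_weights)
      model_backward(model, gl)
      adamw_step(model, model$opt)
      ep_loss <- ep_loss + rep$stage_losses * length(b)
    }
    hist[ep, ] <- ep_loss / n
    model$opt$lr <- model$opt$lr * lr_decay
    if (verbose)
      message(sprintf("epoch %d  losses: %s", ep,
                      paste(sprintf("%.4f", hist[ep, ]), collapse = " ")))
  }
  model$history <- hist
  invisible(model)
}

#' Final-head accuracy of a model on a labelled batch
#'
#' @inheritParams train_model
#' @param stage Which stage's head to score (default: final).
#' @param fq Score the fake-quantized forward path.
#' @return Accuracy in `[0, 1]`.
#' @export
model_accuracy <- function(model, x, y, stage = model$n_stages, fq = NULL) {
  out <- predict_stages(model, x, fq = fq)
  z <- out$logits[[stage]]
  mean(max.col(t(z)) == as.integer(y))
}
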