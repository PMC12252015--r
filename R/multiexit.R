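# Early-exit inference and joint multi-head training loss.
#
# Two gate readings are shipped: a confidence gate (exit when the softmax
# maximum strictly exceeds the stage threshold; printed defaults 0.6, 0.7,
# 0.8) and an entropy gate (exit when prediction entropy falls strictly
# below S nats). The final stage always returns.

#' Early-exit policy
#'
#' @param mode `"confidence"` (exit when max softmax probability strictly
#'   exceeds the stage threshold) or `"entropy"` (exit when prediction
#'   entropy in nats is strictly below the stage threshold).
#' @param thresholds For confidence mode, a length `n - 1` vector in (0, 1]
#'   (default `c(0.6, 0.7, 0.8)`); for entropy mode, a single S >= 0 applied
#'   at every early stage, or a length `n - 1` vector.
#' @param n Total number of stages including the final classifier.
#' @return An `exit_policy` object. The final stage always exits.
#' @export
exit_policy <- function(mode = c("confidence", "entropy"),
                        thresholds = NULL, n = 4L) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.null(thresholds))
    thresholds <- if (mode == "confidence") c(0.6, 0.7, 0.8) else 0.5
  if (mode == "entropy" && length(thresholds) == 1L)
    thresholds <- rep(thresholds, n - 1L)
  if (length(thresholds) != n - 1L)
    stopf("thresholds must have length n - 1 = %d, got %d", n - 1L,
          length(thresholds))
  if (mode == "confidence" && any(thresholds <= 0))
    stopf("confidence thresholds must lie in (0, 1] (or above 1 to disable)")
  if (mode == "entropy" && any(thresholds < 0))
    stopf("entropy thresholds must be >= 0")
  structure(list(mode = mode, thresholds = as.numeric(thresholds), n = n),
            class = "exit_policy")
}

stage_prediction <- function(stage_index, logits, n_stages) {
  probs <- softmax(logits)
  structure(list(stage_index = as.integer(stage_index),
                 logits = as.numeric(logits),
                 probs = probs,
                 entropy = entropy(probs),
                 confidence = max(probs),
                 exited = TRUE,
                 n_stages = as.integer(n_stages)),
            class = "stage_prediction")
}

# Does the gate fire at early stage i for this probability vector?
gate_fires <- function(policy, i, probs) {
  if (policy$mode == "confidence") max(probs) > policy$thresholds[i]
  else entropy(probs) < policy$thresholds[i]
}

#' Threshold-gated dynamic early-exit inference
#'
#' Evaluates the network stage by stage per sample. At each early stage the
#' auxiliary head's prediction is gated by the policy; the first stage whose
#' gate fires returns its prediction and deeper stages are not computed
#' (observable through `model$eval_counter`). If no early gate fires the
#' final classifier's prediction is returned.
#'
#' @param model An `rfc_model` from [attach_exit_heads()].
#' @param a Image array `H x W x C` or `H x W x C x N`.
#' @param policy An [exit_policy()]; its `n` must match the model.
#' @param fq Use the fake-quantized forward path.
#' @return A list of `stage_prediction` objects, one per sample.
#' @export
dynamic_inference <- function(model, a, policy = exit_policy(), fq = NULL) {
  if (policy$n != model$n_stages)
    stopf("policy has %d stages but model has %d", policy$n, model$n_stages)
  ctx <- model_ctx(model, fq = fq)
  d <- dim(a)
  if (length(d) == 3L) dim(a) <- c(d, 1L)
  n_img <- dim(a)[4]
  segs <- model_segments(model); heads <- model_heads(model)
  out <- vector("list", n_img)
  for (j in seq_len(n_img)) {
    x <- to_fmap(a[, , , j, drop = FALSE])
    pred <- NULL
    for (i in 1:3) {
      x <- forward(segs[[i]], x, ctx)
      model$eval_counter <- model$eval_counter + 1L
      z <- forward(heads[[i]], x, ctx)
      probs <- softmax(drop(z))
      if (gate_fires(policy, i, probs)) {
        pred <- stage_prediction(i, drop(z), policy$n)
        break
      }
    }
    if (is.null(pred)) {
      z <- forward(segs[[4]], x, ctx)
      model$eval_counter <- model$eval_counter + 1L
      pred <- stage_prediction(4L, drop(z), policy$n)
    }
    out[[j]] <- pred
  }
  out
}

#' Per-stage exit fractions and mean exit stage
#'
#' @param predictions Non-empty list of `stage_prediction` objects.
#' @return List with `fractions` (summing to 1 over stages) and
#'   `mean_stage`.
#' @export
exit_statistics <- function(predictions) {
  if (length(predictions) == 0) stopf("exit_statistics: empty prediction list")
  n <- predictions[[1]]$n_stages
  stages <- as.integer(vapply(predictions, function(p) p$stage_index,
                              numeric(1)))
  fr <- tabulate(stages, nbins = n) / length(stages)
  list(fractions = fr, mean_stage = mean(stages))
}

#' Joint multi-branch training loss
#'
#' Each stage i contributes the batch-mean cross-entropy
#' \eqn{L_i = \frac{1}{|D|}\sum_{(x,y)} H(y, f_i(x))}; the total is the
#' weighted sum \eqn{\sum_i \lambda_i L_i} over all stages (three auxiliary
#' heads plus the final classifier, unit weights by default).
#'
#' @param stage_logits List of `C x N` logit matrices, one per stage
#'   (columns are samples).
#' @param labels Integer class labels in `1..C`.
#' @param weights Per-stage weights `lambda_i` (default all 1).
#' @return A `joint_loss_report`: `stage_losses`, `weights`, `total`.
#' @export
joint_loss <- function(stage_logits, labels, weights = NULL) {
  ns <- length(stage_logits)
  weights <- weights %||% rep(1, ns)
  if (length(weights) != ns) stopf("need one weight per stage")
  C <- nrow(stage_logits[[1]])
  N <- ncol(stage_logits[[1]])
  labels <- as.integer(labels)
  if (length(labels) != N) stopf("length(labels) != batch size")
  if (any(labels < 1L | labels > C))
    stopf("labels out of range 1..%d", C)
  Ls <- vapply(stage_logits, function(z) {
    if (ncol(z) != N || nrow(z) != C) stopf("stage logit shapes differ")
    p <- softmax_cols(z)
    -mean(log(pmax(p[cbind(labels, seq_len(N))], 1e-12)))
  }, numeric(1))
  structure(list(stage_losses = Ls, weights = weights,
                 total = sum(weights * Ls)),
            class = "joint_loss_report")
}

# Gradients of the joint loss w.r.t. each stage's logits.
joint_loss_grad <- function(stage_logits, labels, weights = NULL) {
  ns <- length(stage_logits)
  weights <- weights %||% rep(1, ns)
  N <- ncol(stage_logits[[1]])
  labels <- as.integer(labels)
  lapply(seq_len(ns), function(i) {
    p <- softmax_cols(stage_logits[[i]])
    p[cbind(labels, seq_len(N))] <- p[cbind(labels, seq_len(N))] - 1
    p * (weights[i] / N)
  })
}
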