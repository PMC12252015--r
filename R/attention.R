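# Separable self-attention: instead of a k x k token-affinity matrix, a
# learned score branch produces contextual weights cs over the k tokens, a
# single global context vector cv = sum_i cs_i * (x W_K)_i is formed, and the
# output is y_i = (cv * ReLU((x W_V)_i)) W_O, broadcasting cv over tokens.
# Cost is linear in the token count k.

#' Attention parameter set for separable self-attention
#'
#' Bundles the four projections of the separable attention operator: a score
#' projection `W_I` (d -> 1), key projection `W_K` (d -> d), value projection
#' `W_V` (d -> d) and output projection `W_O` (d -> d). Contextual weights
#' `cs = softmax(x %*% W_I)` always form a probability simplex over tokens.
#'
#' @param W_I Numeric d x 1 matrix (or length-d vector), score projection.
#' @param W_K,W_V,W_O Numeric d x d projection matrices.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(W_I, W_K, W_V, W_O) {
  W_I <- matrix(W_I, ncol = 1)
  d <- nrow(W_I)
  for (nm in c("W_K", "W_V", "W_O")) {
    W <- get(nm)
    if (!is.matrix(W) || any(dim(W) != d))
      stopf("%s must be a %d x %d matrix", nm, d, d)
  }
  structure(list(W_I = W_I, W_K = W_K, W_V = W_V, W_O = W_O, d = d),
            class = "attention_params")
}

#' Separable self-attention on a token matrix
#'
#' Applies linear-complexity separable self-attention to a k x d token
#' matrix: context scores `cs = softmax(x W_I)`, global context vector
#' `cv = colSums(cs * (x W_K))`, and per-token output
#' `y_i = (cv * relu((x W_V)_i)) W_O`. Output shape equals input shape.
#'
#' @param x Numeric k x d token matrix (rows are tokens); all entries finite.
#' @param p An [attention_params()] object with matching width d.
#' @return k x d matrix of attended tokens, with the context scores attached
#'   as attribute `"context_scores"`.
#' @examples
#' p <- attention_params(W_I = rep(0, 4), W_K = diag(4),
#'                       W_V = diag(4), W_O = diag(4))
#' x <- matrix(rnorm(12), 3, 4)
#' y <- separable_self_attention(x, p)   # uniform cs: cv = column means of x
#' @export
separable_self_attention <- function(x, p) {
  if (!inherits(p, "attention_params")) stopf("p must be attention_params")
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("separable_self_attention: non-finite input")
  if (ncol(x) != p$d)
    stopf("token width %d does not match attention width %d", ncol(x), p$d)
  cs <- softmax(drop(x %*% p$W_I))
  xk <- x %*% p$W_K
  cv <- colSums(cs * xk)
  v <- pmax(x %*% p$W_V, 0)
  y <- sweep(v, 2, cv, "*") %*% p$W_O
  attr(y, "context_scores") <- cs
  y
}

# ---- batched attention layer (module, with backward) ------------------------
#
# Token tensor convention inside the network: d x (k * nseg) matrix, columns
# grouped segment by segment (k tokens contiguous per segment); attention is
# computed independently within each segment. The qkv projection is a single
# (1 + 2d) x d matrix: row 1 = score branch, rows 2..d+1 = keys,
# rows d+2..2d+1 = values.

attention_layer <- function(d, name = "attn") {
  m <- new_module("attention", name, d = d)
  m$params$W_qkv <- init_weight(c(1L + 2L * d, d), fan_in = d)
  m$params$W_O <- init_weight(c(d, d), fan_in = d)
  m
}

forward.rfc_attention <- function(m, x, ctx) {
  d <- m$d
  k <- attr(x, "seg_len")
  nseg <- ncol(x) / k
  Wq <- maybe_fq_weight(m, "W_qkv", ctx)
  Wo <- maybe_fq_weight(m, "W_O", ctx)
  qkv <- Wq %*% x
  s <- qkv[1L, ]
  xk <- qkv[2L:(d + 1L), , drop = FALSE]
  vpre <- qkv[(d + 2L):(2L * d + 1L), , drop = FALSE]
  cs <- as.vector(softmax_cols(matrix(s, k, nseg)))
  grp <- rep(seq_len(nseg), each = k)
  cv <- t(rowsum(t(xk * rep(cs, each = d)), grp))        # d x nseg
  v <- pmax(vpre, 0)
  cvx <- cv[, grp, drop = FALSE]
  u <- v * cvx
  y <- Wo %*% u
  y <- maybe_fq_out(m, y, ctx)
  attr(y, "seg_len") <- k
  m$cache <- list(x = x, Wq = Wq, Wo = Wo, cs = cs, xk = xk, v = v,
                  vpre_pos = vpre > 0, cvx = cvx, u = u, k = k,
                  nseg = nseg, grp = grp)
  y
}

backward.rfc_attention <- function(m, g) {
  cc <- m$cache
  d <- m$d; k <- cc$k; nseg <- cc$nseg; grp <- cc$grp
  gu <- crossprod(cc$Wo, g)
  m$grads$W_O <- m$grads$W_O + tcrossprod(g, cc$u)
  gcv <- t(rowsum(t(gu * cc$v), grp))                    # d x nseg
  gv <- gu * cc$cvx
  gvpre <- gv * cc$vpre_pos
  gcvx <- gcv[, grp, drop = FALSE]
  gxk <- gcvx * rep(cc$cs, each = d)
  gcs <- colSums(cc$xk * gcvx)
  segdot <- as.vector(rowsum(cc$cs * gcs, grp))[grp]
  gs <- cc$cs * (gcs - segdot)
  gqkv <- rbind(matrix(gs, 1L), gxk, gvpre)
  m$grads$W_qkv <- m$grads$W_qkv + tcrossprod(gqkv, cc$x)
  gx <- crossprod(cc$Wq, gqkv)
  attr(gx, "seg_len") <- k
  gx
}

# Token feed-forward: pointwise d -> mult*d -> d with SiLU.
ffn_layer <- function(d, mult = 2L, name = "ffn") {
  m <- new_module("ffn", name, d = d, dh = mult * d)
  m$params$W1 <- init_weight(c(mult * d, d), fan_in = d)
  m$params$W2 <- init_weight(c(d, mult * d), fan_in = mult * d)
  m
}

forward.rfc_ffn <- function(m, x, ctx) {
  W1 <- maybe_fq_weight(m, "W1", ctx)
  W2 <- maybe_fq_weight(m, "W2", ctx)
  h <- W1 %*% x
  sig <- 1 / (1 + exp(-h))
  a <- h * sig
  y <- W2 %*% a
  y <- maybe_fq_out(m, y, ctx)
  attr(y, "seg_len") <- attr(x, "seg_len")
  m$cache <- list(x = x, W1 = W1, W2 = W2, h = h, sig = sig, a = a)
  y
}

backward.rfc_ffn <- function(m, g) {
  cc <- m$cache
  m$grads$W2 <- m$grads$W2 + tcrossprod(g, cc$a)
  ga <- crossprod(cc$W2, g)
  gh <- ga * (cc$sig * (1 + cc$h * (1 - cc$sig)))
  m$grads$W1 <- m$grads$W1 + tcrossprod(gh, cc$x)
  gx <- crossprod(cc$W1, gh)
  attr(gx, "seg_len") <- attr(cc$x, "seg_len")
  gx
}

# Pre-norm transformer layer: x + attn(LN(x)); x + ffn(LN(x)).
transformer_layer <- function(d, ffn_mult = 2L, name = "tf") {
  m <- new_module("transformer", name, d = d)
  m$children <- list(
    layernorm(d, name = "ln1"),
    attention_layer(d, name = "attn"),
    layernorm(d, name = "ln2"),
    ffn_layer(d, ffn_mult, name = "ffn")
  )
  m
}

forward.rfc_transformer <- function(m, x, ctx) {
  ch <- m$children
  a <- forward(ch[[2]], keep_seg(forward(ch[[1]], x, ctx), x), ctx)
  x1 <- x + a
  f <- forward(ch[[4]], keep_seg(forward(ch[[3]], x1, ctx), x), ctx)
  y <- x1 + f
  attr(y, "seg_len") <- attr(x, "seg_len")
  y
}

backward.rfc_transformer <- function(m, g) {
  ch <- m$children
  gf <- backward(ch[[4]], g)
  gx1 <- g + backward(ch[[3]], gf)
  ga <- backward(ch[[2]], keep_seg(gx1, gx1))
  gx <- gx1 + backward(ch[[1]], ga)
  gx
}

keep_seg <- function(y, ref) {
  attr(y, "seg_len") <- attr(ref, "seg_len")
  y
}
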