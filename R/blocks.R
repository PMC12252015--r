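# Composite blocks of the hybrid backbone.

# Convert an image batch (H x W x C or H x W x C x N array, values in any
# numeric range) to the internal channels-first feature-map layout and back.
to_fmap <- function(a) {
  d <- dim(a)
  if (length(d) == 3L) { dim(a) <- c(d, 1L); d <- dim(a) }
  h <- d[1]; w <- d[2]; c <- d[3]; n <- d[4]
  x <- matrix(0, c, h * w * n)
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * h * w + 1L):(i * h * w)
    x[, cols] <- t(matrix(a[, , , i], h * w, c))
  }
  fmap(x, h, w, n)
}

from_fmap <- function(fm) {
  c <- nrow(fm$x)
  a <- array(0, dim = c(fm$h, fm$w, c, fm$n))
  for (i in seq_len(fm$n)) {
    cols <- ((i - 1L) * fm$h * fm$w + 1L):(i * fm$h * fm$w)
    a[, , , i] <- array(t(fm$x[, cols, drop = FALSE]), dim = c(fm$h, fm$w, c))
  }
  a
}

conv_bn_act <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                        act = "silu", name = "cba") {
  ch <- list(conv2d(cin, cout, k, stride, groups = groups, name = "conv"),
             batchnorm2d(cout, name = "bn"))
  if (!is.null(act)) ch <- c(ch, list(activation(act, name = act)))
  sequential(ch, name = name)
}

#' MobileNetV2 inverted-residual block
#'
#' Pointwise expansion, depthwise 3x3 (optionally strided), pointwise
#' projection, each followed by batch norm (SiLU on the first two). A
#' residual connection is added iff `stride == 1` and `cin == cout`.
#'
#' @param cin,cout Input/output channel counts.
#' @param expansion Integer channel expansion factor of the hidden layer.
#' @param stride 1, or 2 at down-sampling positions.
#' @return A network module; apply it with [apply_module()].
#' @export
mv2_block <- function(cin, cout, expansion = 2L, stride = 1L) {
  if (!stride %in% c(1L, 2L)) stopf("mv2_block: stride must be 1 or 2")
  hid <- as.integer(expansion * cin)
  m <- new_module("mv2", "mv2", cin = cin, cout = cout,
                  residual = (stride == 1L && cin == cout))
  m$children <- list(
    conv_bn_act(cin, hid, 1L, 1L, name = "expand"),
    conv_bn_act(hid, hid, 3L, stride, groups = hid, name = "dw"),
    conv_bn_act(hid, cout, 1L, 1L, act = NULL, name = "project")
  )
  m
}

forward.rfc_mv2 <- function(m, inp, ctx) {
  y <- inp
  for (ch in m$children) y <- forward(ch, y, ctx)
  if (m$residual) y$x <- y$x + inp$x
  y
}

backward.rfc_mv2 <- function(m, g) {
  gy <- g
  for (ch in rev(m$children)) gy <- backward(ch, gy)
  if (m$residual) gy$x <- gy$x + g$x
  gy
}

# Permutation taking feature-map columns to token order (token index fastest,
# then within-patch offset group, then sample); k = (h/p)*(w/p) tokens per
# group, p^2 groups per sample.
unfold_idx <- function(h, w, n, p) {
  key <- paste("unfold", h, w, n, p)
  cache_get(key, function() {
    th <- h %/% p; tw <- w %/% p; k <- th * tw
    ty <- rep.int(seq_len(th), times = tw)
    tx <- rep(seq_len(tw), each = th)
    idx <- integer(h * w * n)
    j <- 0L
    for (i in seq_len(n)) {
      base <- (i - 1L) * h * w
      for (gx in seq_len(p)) for (gy in seq_len(p)) {
        hs <- (ty - 1L) * p + gy
        ws <- (tx - 1L) * p + gx
        idx[j + seq_len(k)] <- base + hs + (ws - 1L) * h
        j <- j + k
      }
    }
    list(idx = idx, k = k)
  })
}

#' Unfold a feature map into patch tokens / fold tokens back
#'
#' `unfold_tokens` rearranges a feature map into per-patch-offset token
#' groups for the transformer stage (patch size `p` must divide H and W);
#' `fold_tokens` is its exact inverse.
#'
#' @param fm Internal feature map (see [apply_module()] for the array API).
#' @param p Patch size in pixels.
#' @keywords internal
unfold_tokens <- function(fm, p) {
  ui <- unfold_idx(fm$h, fm$w, fm$n, p)
  y <- fm$x[, ui$idx, drop = FALSE]
  attr(y, "seg_len") <- ui$k
  y
}

fold_tokens <- function(tok, h, w, n, p) {
  ui <- unfold_idx(h, w, n, p)
  y <- tok
  y[, ui$idx] <- tok
  attr(y, "seg_len") <- NULL
  fmap(y, h, w, n)
}

#' MobileViT block with separable self-attention
#'
#' Local representation (depthwise 3x3 + pointwise to width `d`), unfold into
#' patch tokens, `depth` pre-norm transformer layers whose attention is
#' [separable_self_attention()], a final layer norm, fold back, pointwise
#' projection to `cin`, and an identity-residual fuse with the block input.
#' Output spatial size equals input spatial size.
#'
#' @param cin Input (= output) channel count.
#' @param d Token/attention width.
#' @param depth Number of transformer layers (0 gives the pure local path).
#' @param patch Patch size (must divide H and W at application time).
#' @param ffn_mult Hidden multiplier of the token feed-forward network.
#' @return A network module; apply it with [apply_module()].
#' @export
mobilevit_block <- function(cin, d, depth, patch = 2L, ffn_mult = 2L) {
  m <- new_module("mobilevit", "mvit", cin = cin, d = d, depth = depth,
                  patch = as.integer(patch))
  tfs <- lapply(seq_len(depth), function(i)
    transformer_layer(d, ffn_mult, name = paste0("tf", i)))
  m$children <- c(
    list(conv_bn_act(cin, cin, 3L, 1L, groups = cin, name = "local_dw"),
         conv2d(cin, d, 1L, name = "local_pw")),
    tfs,
    list(layernorm(d, name = "ln_out"),
         conv_bn_act(d, cin, 1L, 1L, act = NULL, name = "proj"))
  )
  m
}

forward.rfc_mobilevit <- function(m, inp, ctx) {
  p <- m$patch
  if (inp$h %% p != 0 || inp$w %% p != 0)
    stopf("mobilevit_block: spatial size %dx%d not divisible by patch %d",
          inp$h, inp$w, p)
  nch <- length(m$children)
  z <- forward(m$children[[1]], inp, ctx)
  z <- forward(m$children[[2]], z, ctx)
  tok <- unfold_tokens(z, p)
  if (m$depth > 0)
    for (i in seq_len(m$depth)) tok <- forward(m$children[[2L + i]], tok, ctx)
  tok2 <- forward(m$children[[nch - 1L]], tok, ctx)
  zf <- fold_tokens(tok2, z$h, z$w, z$n, p)
  y <- forward(m$children[[nch]], zf, ctx)
  y$x <- y$x + inp$x
  m$cache <- list(hw = c(z$h, z$w, z$n))
  y
}

backward.rfc_mobilevit <- function(m, g) {
  p <- m$patch
  nch <- length(m$children)
  hw <- m$cache$hw
  gz <- backward(m$children[[nch]], g)
  gtok <- unfold_tokens(gz, p)                 # inverse of fold
  gtok <- backward(m$children[[nch - 1L]], gtok)
  if (m$depth > 0)
    for (i in rev(seq_len(m$depth)))
      gtok <- backward(m$children[[2L + i]], gtok)
  gzf <- fold_tokens(gtok, hw[1], hw[2], hw[3], p)
  gx <- backward(m$children[[2]], gzf)
  gx <- backward(m$children[[1]], gx)
  gx$x <- gx$x + g$x
  gx
}

#' Apply a network module to an image batch array
#'
#' Convenience wrapper converting an `H x W x C (x N)` array to the internal
#' feature-map layout, running the module, and converting back.
#'
#' @param mod A module built by [mv2_block()], [mobilevit_block()],
#'   [build_backbone()] internals, etc.
#' @param a Numeric array `H x W x C` or `H x W x C x N`.
#' @param training Logical; use batch statistics in batch norm.
#' @return Array of the module's output feature map.
#' @export
apply_module <- function(mod, a, training = FALSE) {
  ctx <- new_ctx(training = training)
  out <- forward(mod, to_fmap(a), ctx)
  from_fmap(out)
}
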