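test_that("separable self-attention matches brute-force evaluation on 100 seeded cases", {
  set.seed(42)
  for (trial in 1:100) {
    k <- sample(1:8, 1); d <- sample(2:6, 1)
    x <- matrix(rnorm(k * d), k, d)
    W_I <- matrix(rnorm(d), d, 1)
    W_K <- matrix(rnorm(d * d), d, d)
    W_V <- matrix(rnorm(d * d), d, d)
    W_O <- matrix(rnorm(d * d), d, d)
    p <- attention_params(W_I, W_K, W_V, W_O)
    y <- separable_self_attention(x, p)
    yb <- brute_force_attention(x, W_I, W_K, W_V, W_O)
    expect_equal(unclass(y), yb, tolerance = 1e-6, ignore_attr = TRUE)
    cs <- attr(y, "context_scores")
    expect_true(all(cs >= 0))
    expect_equal(sum(cs), 1, tolerance = 1e-6)
  }
})

test_that("attention degenerate cases follow the closed forms", {
  d <- 4
  set.seed(7)
  W_K <- matrix(rnorm(16), 4); W_V <- matrix(rnorm(16), 4)
  W_O <- matrix(rnorm(16), 4)
  # single token: cs = 1, cv = x W_K
  x1 <- matrix(rnorm(d), 1, d)
  p <- attention_params(matrix(rnorm(d)), W_K, W_V, W_O)
  y1 <- separable_self_attention(x1, p)
  expect_equal(attr(y1, "context_scores"), 1)
  expect_equal(as.numeric(y1),
               as.numeric((as.numeric(x1 %*% W_K) * pmax(x1 %*% W_V, 0)) %*% W_O))
  # zero score projection: uniform cs, cv = column mean of x W_K
  x <- matrix(rnorm(5 * d), 5, d)
  p0 <- attention_params(rep(0, d), W_K, W_V, W_O)
  y0 <- separable_self_attention(x, p0)
  expect_equal(attr(y0, "context_scores"), rep(0.2, 5))
  cv <- colMeans(x %*% W_K)
  expect_equal(unclass(y0), sweep(pmax(x %*% W_V, 0), 2, cv, "*") %*% W_O,
               ignore_attr = TRUE)
})

test_that("attention is equivariant under token permutation", {
  set.seed(13)
  x <- matrix(rnorm(6 * 5), 6, 5)
  p <- attention_params(matrix(rnorm(5)), matrix(rnorm(25), 5),
                        matrix(rnorm(25), 5), matrix(rnorm(25), 5))
  y <- separable_self_attention(x, p)
  perm <- sample(6)
  yp <- separable_self_attention(x[perm, ], p)
  expect_equal(unclass(yp), unclass(y)[perm, ], ignore_attr = TRUE)
})

test_that("mv2 block obeys shape, residual and parameter laws", {
  # stride 2 halves the spatial size
  blk <- mv2_block(4, 8, expansion = 2, stride = 2)
  out <- apply_module(blk, array(rnorm(32 * 32 * 4), c(32, 32, 4)))
  expect_equal(dim(out)[1:2], c(16, 16))
  expect_error(mv2_block(4, 8, stride = 3), "stride")

  # zero weights, identity residual: output = input
  blk0 <- mv2_block(4, 4, expansion = 2, stride = 1)
  walk <- function(m) {
    for (nm in names(m$params)) m$params[[nm]][] <- 0
    lapply(m$children, walk); invisible(NULL)
  }
  walk(blk0)
  xin <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(apply_module(blk0, xin), array(xin, c(8, 8, 4, 1)))

  # weight-array sizes of a cin=64, expansion=2, cout=64 block
  blk2 <- mv2_block(64, 64, expansion = 2, stride = 1)
  conv_w <- 0
  count <- function(m) {
    if (m$kind == "conv2d") conv_w <<- conv_w + length(m$params$W)
    lapply(m$children, count); invisible(NULL)
  }
  count(blk2)
  expect_equal(conv_w, 64 * 128 + 128 * 9 + 128 * 64)   # 17,536
})

test_that("token unfold/fold are exact inverses with the documented geometry", {
  ui <- rfcottnet:::unfold_idx(8, 8, 1, 2)
  expect_equal(ui$k, 16)                       # 16 tokens per group
  expect_equal(length(ui$idx) / ui$k, 4)       # 4 offset groups
  expect_setequal(ui$idx, 1:64)
  fm <- rfcottnet:::fmap(matrix(rnorm(3 * 64 * 2), 3), 8, 8, 2)
  tok <- rfcottnet:::unfold_tokens(fm, 2)
  back <- rfcottnet:::fold_tokens(tok, 8, 8, 2, 2)
  expect_equal(back$x, fm$x)
  for (p in c(2, 4)) {
    fm2 <- rfcottnet:::fmap(matrix(rnorm(2 * 16 * 16), 2), 16, 16, 1)
    expect_equal(rfcottnet:::fold_tokens(rfcottnet:::unfold_tokens(fm2, p),
                                         16, 16, 1, p)$x, fm2$x)
  }
})

test_that("depth-0 mobilevit block reduces to the local path", {
  set.seed(3)
  blk <- mobilevit_block(4, 6, depth = 0, patch = 2)
  xin <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  out <- apply_module(blk, xin)
  # oracle: compose the non-attention path by hand
  ctx <- rfcottnet:::new_ctx()
  z0 <- rfcottnet:::to_fmap(xin)
  z <- ns_forward(blk$children[[1]], z0, ctx)    # local dw
  z <- ns_forward(blk$children[[2]], z, ctx)     # local pw
  tok <- rfcottnet:::unfold_tokens(z, 2)
  tok <- ns_forward(blk$children[[3]], tok, ctx) # final layer norm
  zf <- rfcottnet:::fold_tokens(tok, z$h, z$w, z$n, 2)
  y <- ns_forward(blk$children[[4]], zf, ctx)    # projection
  expect_equal(out, rfcottnet:::from_fmap(
    rfcottnet:::fmap(y$x + z0$x, 8, 8, 1)))
  expect_error(apply_module(mobilevit_block(4, 6, 1, patch = 3),
                            array(rnorm(8 * 8 * 4), c(8, 8, 4))),
               "divisible")
})

test_that("backbone forward contract: shapes, tap points, determinism", {
  model <- micro_model()
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- predict_stages(model, x)
  expect_length(out$logits, 4)
  for (z in out$logits) expect_equal(dim(z), c(11, 2))
  out2 <- predict_stages(model, x)
  expect_identical(out$logits, out2$logits)
  # 52 px: the down-sampling chain reaches an odd size before token folding
  expect_error(predict_stages(model, array(0, c(52, 52, 3, 1))), "divisible")
  # missing tap points rejected
  broken <- rfcottnet:::new_module("backbone")
  expect_error(attach_exit_heads(broken), "tap")
})

test_that("depth-0 transformer: layernorm in depth-0 path is still well-formed", {
  # guard: layernorm over a constant column stays finite
  ln <- rfcottnet:::layernorm(4)
  x <- matrix(1, 4, 3)
  y <- ns_forward(ln, x, rfcottnet:::new_ctx())
  expect_true(all(is.finite(y)))
})
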