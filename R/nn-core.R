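# Minimal define-by-layer neural network engine.
#
# Feature maps are stored channels-first as a C x (H*W*N) matrix (column
# index = h + (w-1)*H + (n-1)*H*W), so pointwise convolutions are plain BLAS
# matrix products and k x k convolutions are k^2 shifted matrix products via
# precomputed padded-column index tables. Every layer implements an explicit
# forward (caching what backward needs) and backward (accumulating parameter
# gradients); there is no autodiff.

fmap <- function(x, h, w, n) {
  structure(list(x = x, h = h, w = w, n = n), class = "rfc_fmap")
}

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- make()
  .idx_cache[[key]]
}

# Column indices of the un-padded pixels inside the zero-padded layout.
pad_cols <- function(h, w, n, p) {
  key <- paste("pad", h, w, n, p)
  cache_get(key, function() {
    hp <- h + 2 * p; wp <- w + 2 * p
    hh <- rep.int(seq_len(h), times = w * n)
    ww <- rep.int(rep(seq_len(w), each = h), times = n)
    nn <- rep(seq_len(n), each = h * w)
    (hh + p) + (ww + p - 1) * hp + (nn - 1) * hp * wp
  })
}

# For each kernel tap (dy, dx), the padded column read for every output
# position; each tap's index vector is injective, so backward can scatter-add
# tap by tap without collisions.
conv_taps <- function(h, w, n, k, s, p) {
  key <- paste("tap", h, w, n, k, s, p)
  cache_get(key, function() {
    hp <- h + 2 * p; wp <- w + 2 * p
    ho <- (h + 2 * p - k) %/% s + 1
    wo <- (w + 2 * p - k) %/% s + 1
    oh <- rep.int(seq_len(ho), times = wo * n)
    ow <- rep.int(rep(seq_len(wo), each = ho), times = n)
    on <- rep(seq_len(n), each = ho * wo)
    taps <- vector("list", k * k)
    t <- 0L
    for (dx in seq_len(k)) for (dy in seq_len(k)) {
      t <- t + 1L
      hq <- (oh - 1L) * s + dy
      wq <- (ow - 1L) * s + dx
      taps[[t]] <- hq + (wq - 1L) * hp + (on - 1L) * hp * wp
    }
    list(taps = taps, ho = ho, wo = wo)
  })
}

out_hw <- function(h, k, s, p) (h + 2 * p - k) %/% s + 1

# ---- module framework -------------------------------------------------------

new_module <- function(.kind, .name = .kind, ...) {
  m <- new.env(parent = emptyenv())
  m$kind <- .kind
  m$name <- .name
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$children <- list()
  m$cache <- NULL
  m$aq <- NULL          # activation fake-quant observer (set by insert_fake_quant)
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = m)
  class(m) <- c(paste0("rfc_", .kind), "rfc_module")
  m
}

walk_modules <- function(m, fn, path = m$name) {
  fn(m, path)
  for (i in seq_along(m$children)) {
    ch <- m$children[[i]]
    walk_modules(ch, fn, paste0(path, ".", i, "_", ch$name))
  }
  invisible(NULL)
}

zero_grads <- function(m) {
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params)) {
      g <- mod$params[[nm]]
      g[] <- 0
      mod$grads[[nm]] <- g
    }
  })
}

# Named flat list of all parameter arrays (stable dotted paths).
named_params <- function(m) {
  out <- list()
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params))
      out[[paste(path, nm, sep = ".")]] <<- mod$params[[nm]]
  })
  out
}

set_named_params <- function(m, values) {
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params)) {
      key <- paste(path, nm, sep = ".")
      if (!is.null(values[[key]])) {
        stopifnot(length(values[[key]]) == length(mod$params[[nm]]))
        p <- mod$params[[nm]]
        p[] <- values[[key]]
        mod$params[[nm]] <- p
      }
    }
  })
  invisible(m)
}

init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- weight fake-quantization (per-out-channel symmetric INT8) --------------

# Rows of the flattened (cout x fan_in) view share one scale; 1-D tensors get
# a single per-tensor scale. Scales are float32-rounded (see as_f32).
weight_scales <- function(w, bits = 8L) {
  qmax <- 2^(bits - 1) - 1
  if (is.null(dim(w)) || length(dim(w)) == 1L) {
    s <- max(abs(w)) / qmax
    if (s == 0) s <- 1
    as_f32(s)
  } else {
    wm <- matrix(w, nrow = dim(w)[1])
    s <- apply(abs(wm), 1, max) / qmax
    s[s == 0] <- 1
    as_f32(s)
  }
}

fq_weight <- function(w, bits = 8L) {
  qmax <- 2^(bits - 1) - 1
  s <- weight_scales(w, bits)
  if (length(s) == 1L) {
    q <- clamp(round(w / s), -qmax, qmax)
    out <- q * s
  } else {
    wm <- matrix(w, nrow = dim(w)[1])
    q <- clamp(round(sweep(wm, 1, s, "/")), -qmax, qmax)
    out <- array(sweep(q, 1, s, "*"), dim = dim(w))
  }
  out
}

maybe_fq_weight <- function(m, nm, ctx) {
  w <- m$params[[nm]]
  if (isTRUE(ctx$fq) && ctx$wbits < 16) fq_weight(w, ctx$wbits) else w
}

# ---- activation fake-quant observer -----------------------------------------

new_observer <- function(momentum = 0.99) {
  o <- new.env(parent = emptyenv())
  o$momentum <- momentum
  o$min <- NULL; o$max <- NULL
  o$frozen <- FALSE
  o$scale <- NULL; o$zp <- NULL
  o
}

observe <- function(o, x) {
  mn <- min(x); mx <- max(x)
  if (is.null(o$min)) { o$min <- mn; o$max <- mx }
  else {
    m <- o$momentum
    o$min <- m * o$min + (1 - m) * mn
    o$max <- m * o$max + (1 - m) * mx
  }
}

observer_qparams <- function(o, bits = 8L) {
  qmin <- -2^(bits - 1); qmax <- 2^(bits - 1) - 1
  lo <- min(o$min, 0); hi <- max(o$max, 0)
  s <- (hi - lo) / (qmax - qmin)
  if (s <= 0) s <- 1e-8
  s <- as_f32(s)
  zp <- as.integer(clamp(round(qmin - lo / s), qmin, qmax))
  list(scale = s, zp = zp)
}

freeze_observer <- function(o, bits = 8L) {
  if (is.null(o$min)) stopf("observer was never calibrated; run a forward pass first")
  qp <- observer_qparams(o, bits)
  o$scale <- qp$scale; o$zp <- qp$zp
  o$frozen <- TRUE
  invisible(o)
}

fq_activation <- function(x, o, ctx) {
  bits <- ctx$abits
  if (bits >= 16) return(x)
  if (isTRUE(ctx$observe)) observe(o, x)
  if (o$frozen) { s <- o$scale; zp <- o$zp }
  else {
    if (is.null(o$min)) { observe(o, x) }
    qp <- observer_qparams(o, bits)
    s <- qp$scale; zp <- qp$zp
  }
  qmin <- -2^(bits - 1); qmax <- 2^(bits - 1) - 1
  q <- clamp(round(x / s) + zp, qmin, qmax)
  (q - zp) * s
}

maybe_fq_out <- function(m, y, ctx) {
  if (isTRUE(ctx$fq) && !is.null(m$aq)) fq_activation(y, m$aq, ctx) else y
}

# ---- evaluation context -----------------------------------------------------

new_ctx <- function(training = FALSE, fq = FALSE, observe = FALSE,
                    wbits = 8L, abits = 8L) {
  e <- new.env(parent = emptyenv())
  e$training <- training
  e$fq <- fq
  e$observe <- observe
  e$wbits <- wbits
  e$abits <- abits
  e
}

# ---- layers -----------------------------------------------------------------

conv2d <- function(cin, cout, k = 1L, stride = 1L, pad = NULL,
                   groups = 1L, bias = FALSE, name = "conv") {
  if (!stride %in% c(1L, 2L)) stopf("conv2d: stride must be 1 or 2, got %s", stride)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  m <- new_module("conv2d", name, cin = cin, cout = cout, k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad),
                  groups = as.integer(groups), has_bias = bias)
  if (groups == 1L) {
    m$params$W <- init_weight(c(cout, cin, k, k), fan_in = cin * k * k)
  } else if (groups == cin && cin == cout) {
    m$params$W <- init_weight(c(cout, 1L, k, k), fan_in = k * k)
  } else stopf("conv2d: only groups=1 or depthwise (groups=cin=cout) supported")
  if (bias) m$params$b <- numeric(cout)
  m
}

forward.rfc_conv2d <- function(m, inp, ctx) {
  x <- inp$x; h <- inp$h; w <- inp$w; n <- inp$n
  W <- maybe_fq_weight(m, "W", ctx)
  dw <- m$groups > 1L
  if (m$k == 1L && m$stride == 1L) {
    Wm <- matrix(W, m$cout, m$cin)
    y <- Wm %*% x
    ho <- h; wo <- w
    m$cache <- list(inp = inp, W = W, mode = "pw")
  } else {
    p <- m$pad
    hp <- h + 2 * p; wp <- w + 2 * p
    if (p > 0) {
      xp <- matrix(0, nrow(x), hp * wp * n)
      xp[, pad_cols(h, w, n, p)] <- x
    } else xp <- x
    ct <- conv_taps(h, w, n, m$k, m$stride, p)
    ho <- ct$ho; wo <- ct$wo
    y <- matrix(0, m$cout, ho * wo * n)
    t <- 0L
    for (dx in seq_len(m$k)) for (dy in seq_len(m$k)) {
      t <- t + 1L
      xs <- xp[, ct$taps[[t]], drop = FALSE]
      if (dw) {
        y <- y + xs * W[, 1L, dy, dx]
      } else {
        Wt <- matrix(W[, , dy, dx], m$cout, m$cin)
        y <- y + Wt %*% xs
      }
    }
    m$cache <- list(inp = inp, W = W, xp = xp, ct = ct, mode = if (dw) "dw" else "full")
  }
  if (m$has_bias) y <- y + maybe_fq_weight(m, "b", ctx)
  y <- maybe_fq_out(m, y, ctx)
  fmap(y, ho, wo, n)
}

backward.rfc_conv2d <- function(m, gout) {
  cc <- m$cache
  g <- gout$x
  inp <- cc$inp
  if (m$has_bias) m$grads$b <- m$grads$b + rowSums(g)
  if (cc$mode == "pw") {
    Wm <- matrix(cc$W, m$cout, m$cin)
    m$grads$W <- m$grads$W + array(tcrossprod(g, inp$x), dim = dim(m$params$W))
    return(fmap(crossprod(Wm, g), inp$h, inp$w, inp$n))
  }
  h <- inp$h; w <- inp$w; n <- inp$n; p <- m$pad
  hp <- h + 2 * p; wp <- w + 2 * p
  ct <- cc$ct
  gxp <- matrix(0, nrow(cc$xp), hp * wp * n)
  gW <- m$grads$W
  dw <- cc$mode == "dw"
  t <- 0L
  for (dx in seq_len(m$k)) for (dy in seq_len(m$k)) {
    t <- t + 1L
    idx <- ct$taps[[t]]
    xs <- cc$xp[, idx, drop = FALSE]
    if (dw) {
      gW[, 1L, dy, dx] <- gW[, 1L, dy, dx] + rowSums(g * xs)
      gxp[, idx] <- gxp[, idx] + g * cc$W[, 1L, dy, dx]
    } else {
      gW[, , dy, dx] <- gW[, , dy, dx] + tcrossprod(g, xs)
      Wt <- matrix(cc$W[, , dy, dx], m$cout, m$cin)
      gxp[, idx] <- gxp[, idx] + crossprod(Wt, g)
    }
  }
  m$grads$W <- gW
  gx <- if (p > 0) gxp[, pad_cols(h, w, n, p), drop = FALSE] else gxp
  fmap(gx, h, w, n)
}

batchnorm2d <- function(c, momentum = 0.9, eps = 1e-5, name = "bn") {
  m <- new_module("batchnorm2d", name, c = c, momentum = momentum, eps = eps)
  m$params$gamma <- rep(1, c)
  m$params$beta <- numeric(c)
  m$buffers$running_mean <- numeric(c)
  m$buffers$running_var <- rep(1, c)
  m
}

forward.rfc_batchnorm2d <- function(m, inp, ctx) {
  x <- inp$x
  gamma <- maybe_fq_weight(m, "gamma", ctx)
  beta <- maybe_fq_weight(m, "beta", ctx)
  if (isTRUE(ctx$training)) {
    mu <- rowMeans(x)
    xc <- x - mu
    va <- rowMeans(xc * xc)
    mom <- m$momentum
    m$buffers$running_mean <- mom * m$buffers$running_mean + (1 - mom) * mu
    m$buffers$running_var <- mom * m$buffers$running_var + (1 - mom) * va
  } else {
    mu <- m$buffers$running_mean
    va <- m$buffers$running_var
    xc <- x - mu
  }
  istd <- 1 / sqrt(va + m$eps)
  xn <- xc * istd
  y <- xn * gamma + beta
  m$cache <- list(inp = inp, xn = xn, istd = istd, gamma = gamma,
                  train = isTRUE(ctx$training))
  fmap(y, inp$h, inp$w, inp$n)
}

backward.rfc_batchnorm2d <- function(m, gout) {
  cc <- m$cache
  g <- gout$x
  xn <- cc$xn
  m$grads$gamma <- m$grads$gamma + rowSums(g * xn)
  m$grads$beta <- m$grads$beta + rowSums(g)
  gxn <- g * cc$gamma
  if (cc$train) {
    gx <- (gxn - rowMeans(gxn) - xn * rowMeans(gxn * xn)) * cc$istd
  } else {
    gx <- gxn * cc$istd
  }
  fmap(gx, cc$inp$h, cc$inp$w, cc$inp$n)
}

activation <- function(fun = c("silu", "relu"), name = fun) {
  fun <- match.arg(fun)
  new_module("activation", name, fun = fun)
}

forward.rfc_activation <- function(m, inp, ctx) {
  x <- inp$x
  if (m$fun == "silu") {
    s <- 1 / (1 + exp(-x))
    y <- x * s
    m$cache <- list(inp = inp, s = s)
  } else {
    y <- pmax(x, 0)
    m$cache <- list(inp = inp, mask = x > 0)
  }
  fmap(y, inp$h, inp$w, inp$n)
}

backward.rfc_activation <- function(m, gout) {
  cc <- m$cache
  g <- gout$x
  if (m$fun == "silu") {
    x <- cc$inp$x; s <- cc$s
    gx <- g * (s * (1 + x * (1 - s)))
  } else {
    gx <- g * cc$mask
  }
  fmap(gx, cc$inp$h, cc$inp$w, cc$inp$n)
}

linear <- function(din, dout, bias = TRUE, name = "linear") {
  m <- new_module("linear", name, din = din, dout = dout, has_bias = bias)
  m$params$W <- init_weight(c(dout, din), fan_in = din)
  if (bias) m$params$b <- numeric(dout)
  m
}

# linear operates on a dout x N matrix convention (columns = samples)
forward.rfc_linear <- function(m, x, ctx) {
  W <- maybe_fq_weight(m, "W", ctx)
  y <- W %*% x
  if (m$has_bias) y <- y + maybe_fq_weight(m, "b", ctx)
  m$cache <- list(x = x, W = W)
  maybe_fq_out(m, y, ctx)
}

backward.rfc_linear <- function(m, g) {
  cc <- m$cache
  m$grads$W <- m$grads$W + tcrossprod(g, cc$x)
  if (m$has_bias) m$grads$b <- m$grads$b + rowSums(g)
  crossprod(cc$W, g)
}

# Layer norm over the channel dimension of a token matrix (per column).
layernorm <- function(d, eps = 1e-5, name = "ln") {
  m <- new_module("layernorm", name, d = d, eps = eps)
  m$params$gamma <- rep(1, d)
  m$params$beta <- numeric(d)
  m
}

forward.rfc_layernorm <- function(m, x, ctx) {
  gamma <- maybe_fq_weight(m, "gamma", ctx)
  beta <- maybe_fq_weight(m, "beta", ctx)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + m$eps)
  xn <- sweep(xc, 2, istd, "*")
  m$cache <- list(xn = xn, istd = istd, gamma = gamma)
  xn * gamma + beta
}

backward.rfc_layernorm <- function(m, g) {
  cc <- m$cache
  xn <- cc$xn
  m$grads$gamma <- m$grads$gamma + rowSums(g * xn)
  m$grads$beta <- m$grads$beta + rowSums(g)
  gxn <- g * cc$gamma
  t1 <- sweep(gxn, 2, colMeans(gxn), "-")
  t2 <- sweep(xn, 2, colMeans(gxn * xn), "*")
  sweep(t1 - t2, 2, cc$istd, "*")
}

# Global average pool: fmap -> C x N matrix.
global_pool <- function(name = "pool") new_module("global_pool", name)

forward.rfc_global_pool <- function(m, inp, ctx) {
  c <- nrow(inp$x); hw <- inp$h * inp$w
  # mean over spatial positions, per channel and sample
  y <- matrix(0, c, inp$n)
  for (i in seq_len(inp$n)) {
    cols <- ((i - 1L) * hw + 1L):(i * hw)
    y[, i] <- rowMeans(inp$x[, cols, drop = FALSE])
  }
  m$cache <- list(inp = inp)
  y
}

backward.rfc_global_pool <- function(m, g) {
  inp <- m$cache$inp
  hw <- inp$h * inp$w
  gx <- matrix(0, nrow(inp$x), ncol(inp$x))
  scale <- 1 / hw
  # broadcast each sample's gradient over its spatial positions
  idx <- rep(seq_len(inp$n), each = hw)
  gx[] <- g[, idx] * scale
  fmap(gx, inp$h, inp$w, inp$n)
}

sequential <- function(children, name = "seq") {
  m <- new_module("sequential", name)
  m$children <- children
  m
}

forward.rfc_sequential <- function(m, x, ctx) {
  for (ch in m$children) x <- forward(ch, x, ctx)
  x
}

backward.rfc_sequential <- function(m, g) {
  for (ch in rev(m$children)) g <- backward(ch, g)
  g
}

forward <- function(m, x, ctx) UseMethod("forward")
backward <- function(m, g) UseMethod("backward")
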