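# Quantization-aware training and INT8 export.
#
# Five-step workflow: (1) FP32 baseline; (2) fake-quant nodes simulate INT8
# rounding on weights and activations in the forward pass (straight-through
# gradients); (3) fine-tuning with EMA min/max range observers; (4) per-layer
# scale/zero-point retention at freeze time; (5) export of a single-file INT8
# container that reproduces the fake-quant forward pass exactly on load.
#
# Scheme: weights symmetric per-output-channel (codes in [-127, 127]);
# 1-D parameter vectors (biases, norm affines) symmetric per-tensor;
# activations asymmetric per-tensor (codes in [-128, 127]); round half to
# even. All scales are float32-rounded so the serialized model and the
# in-memory fake-quant model are bit-identical.

#' INT8 quantization specification
#'
#' @param bitwidth Integer bitwidth (8 for INT8; values >= 16 act as a
#'   lossless pass-through sentinel).
#' @param momentum EMA momentum of the activation range observers.
#' @param scale,zero_point Optional explicit quantization parameters for use
#'   with [quantize_tensor()] (scale > 0; `scale` may be a per-channel
#'   vector applied along the first array dimension).
#' @param symmetric Logical; symmetric (zero-centred) code range.
#' @return A `quant_spec` object.
#' @export
quant_spec <- function(bitwidth = 8L, momentum = 0.99,
                       scale = NULL, zero_point = 0L, symmetric = TRUE) {
  if (!is.null(scale) && any(scale <= 0)) stopf("quant_spec: scale must be > 0")
  structure(list(bitwidth = as.integer(bitwidth), momentum = momentum,
                 weight_scheme = "symmetric_per_channel",
                 activation_scheme = "asymmetric_per_tensor",
                 rounding = "half_to_even",
                 scale = scale, zero_point = as.integer(zero_point),
                 symmetric = isTRUE(symmetric)),
            class = "quant_spec")
}

quant_range <- function(spec) {
  b <- spec$bitwidth
  if (spec$symmetric) c(-(2^(b - 1) - 1), 2^(b - 1) - 1)
  else c(-2^(b - 1), 2^(b - 1) - 1)
}

#' Quantize a real array to integer codes
#'
#' `q = clamp(round(x / scale) + zero_point, qmin, qmax)` with round half to
#' even; [dequantize_tensor()] maps codes back via
#' `(q - zero_point) * scale`. The round-trip error is at most `scale / 2`
#' for in-range values.
#'
#' @param x Numeric array (finite).
#' @param spec A [quant_spec()] carrying `scale` (scalar, or per-channel
#'   vector along the first dimension) and `zero_point`.
#' @return Integer array of codes, same shape as `x`.
#' @export
quantize_tensor <- function(x, spec) {
  if (!all(is.finite(x))) stopf("quantize_tensor: non-finite input")
  if (is.null(spec$scale)) stopf("quantize_tensor: spec has no scale")
  r <- quant_range(spec)
  if (length(spec$scale) == 1L) {
    q <- clamp(round(x / spec$scale) + spec$zero_point, r[1], r[2])
  } else {
    xm <- matrix(x, nrow = dim(x)[1])
    q <- clamp(sweep(xm, 1, spec$scale, function(a, s) round(a / s)) +
                 spec$zero_point, r[1], r[2])
    q <- array(q, dim = dim(x) %||% length(x))
  }
  storage.mode(q) <- "integer"
  q
}

#' @rdname quantize_tensor
#' @param q Integer array of codes.
#' @export
dequantize_tensor <- function(q, spec) {
  if (length(spec$scale) == 1L) (q - spec$zero_point) * spec$scale
  else {
    qm <- matrix(q, nrow = dim(q)[1])
    array(sweep(qm - spec$zero_point, 1, spec$scale, "*"),
          dim = dim(q) %||% length(q))
  }
}

# Evaluation context derived from a model's quantization state.
model_ctx <- function(model, training = FALSE, fq = NULL, observe = FALSE) {
  fq <- fq %||% isTRUE(model$fq_enabled)
  bits <- if (!is.null(model$qspec)) model$qspec$bitwidth else 8L
  wbits <- if (isTRUE(model$weights_prequantized)) 16L else bits
  new_ctx(training = training, fq = fq, observe = observe,
          wbits = wbits, abits = bits)
}

# Module kinds that carry fake-quantized compute; everything else
# (norms carry fq'd affines via their forward, activations/pools are
# parameter-free) is intentionally left unwrapped.
FQ_KINDS <- c("conv2d", "linear", "attention", "ffn")

#' Insert fake-quantization nodes into a model
#'
#' Attaches an EMA min/max activation observer to the output of every
#' convolution, linear, attention and feed-forward module and enables
#' simulated INT8 computation on all trainable arrays. The forward pass then
#' computes with quantize-dequantize applied (straight-through estimator on
#' the backward path).
#'
#' @param model An `rfc_model`.
#' @param spec A [quant_spec()].
#' @return The model, updated in place; attribute `"unwrapped"` lists module
#'   kinds present in the model that carry no fake-quant node.
#' @export
insert_fake_quant <- function(model, spec = quant_spec()) {
  kinds <- character(0)
  walk_modules(model, function(mod, path) {
    if (mod$kind %in% FQ_KINDS) {
      if (is.null(mod$aq)) mod$aq <- new_observer(spec$momentum)
    } else kinds <<- union(kinds, mod$kind)
  })
  model$fq_enabled <- TRUE
  model$qspec <- spec
  model$frozen <- FALSE
  attr(model, "unwrapped") <- setdiff(
    kinds, c("model", "backbone", "sequential", "mv2", "mobilevit",
             "transformer"))
  invisible(model)
}

#' Calibrate activation observers on a batch
#'
#' Runs a fake-quant forward pass with observers recording activation
#' ranges.
#'
#' @inheritParams predict_stages
#' @export
calibrate_model <- function(model, a) {
  if (!isTRUE(model$fq_enabled)) stopf("insert_fake_quant first")
  ctx <- model_ctx(model, fq = TRUE, observe = TRUE)
  invisible(model_forward(model, to_fmap(a), ctx))
  invisible(model)
}

#' Freeze quantization ranges
#'
#' Converts every observer's running range into fixed (scale, zero_point)
#' parameters and float32-rounds batch-norm running statistics so that the
#' serialized INT8 model reproduces this model's forward pass exactly.
#'
#' @param model A fake-quant model whose observers have seen data.
#' @export
freeze_ranges <- function(model) {
  if (!isTRUE(model$fq_enabled)) stopf("insert_fake_quant first")
  bits <- model$qspec$bitwidth
  walk_modules(model, function(mod, path) {
    if (!is.null(mod$aq)) freeze_observer(mod$aq, bits)
    for (nm in names(mod$buffers))
      mod$buffers[[nm]] <- as_f32(mod$buffers[[nm]])
  })
  model$frozen <- TRUE
  invisible(model)
}

#' QAT fine-tuning
#'
#' Fine-tunes a model with fake-quant nodes active; activation observers
#' update during training and are frozen afterwards, retaining per-layer
#' (scale, zero_point).
#'
#' @inheritParams train_model
#' @export
qat_finetune <- function(model, x, y, epochs = 2L, batch_size = 32L,
                         lr = 5e-4, seed = 1L, stage_weights = NULL) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (!isTRUE(model$fq_enabled)) stopf("insert_fake_quant first")
  train_model(model, x, y, epochs = epochs, batch_size = batch_size,
              lr = lr, seed = seed, stage_weights = stage_weights, fq = TRUE)
  freeze_ranges(model)
  invisible(model)
}

# ---- INT8 container ---------------------------------------------------------
#
# Layout: magic "RFC8" (4 bytes) | header length (int32 LE) | header JSON |
# payload. The header describes every tensor (name, dims, storage, payload
# offsets); payload holds INT8 codes and float32 scales/buffers.

#' Export a frozen fake-quant model as a single-file INT8 container
#'
#' All trainable arrays are stored as one INT8 byte per element
#' (per-output-channel scales for matrices/tensors, per-tensor scales for
#' vectors); batch-norm running statistics and scales are float32 metadata.
#' Loading the file reproduces the quantized forward pass exactly.
#'
#' @param model A frozen fake-quant `rfc_model` (see [freeze_ranges()]).
#' @param path Output file path.
#' @return Invisibly, a `quantized_model` report:
#'   `params`, `bytes`, `mb` (file size in MiB), `path`.
#' @export
export_int8 <- function(model, path) {
  if (!isTRUE(model$frozen)) stopf("export_int8: quantization ranges are not frozen")
  bits <- model$qspec$bitwidth
  qmax <- 2^(bits - 1) - 1
  tensors <- list(); buffers <- list(); acts <- list()
  payload <- raw(0)
  pp <- function(bytes) { off <- length(payload); payload <<- c(payload, bytes); off }
  walk_modules(model, function(mod, path_) {
    for (nm in names(mod$params)) {
      w <- mod$params[[nm]]
      s <- weight_scales(w, bits)
      per_channel <- length(s) > 1L
      wm <- if (per_channel) matrix(w, nrow = dim(w)[1]) else matrix(w, nrow = 1)
      sc <- if (per_channel) s else rep(s, 1)
      q <- clamp(round(sweep(wm, 1, if (per_channel) s else rep(s, nrow(wm)), "/")),
                 -qmax, qmax)
      qoff <- pp(as.raw(bitwAnd(as.integer(q), 255L)))
      soff <- pp(writeBin(as.numeric(s), raw(), size = 4L))
      # compact keys: n(ame), d(ims), c = per-channel flag, q/s = offsets,
      # k = scale count
      tensors[[length(tensors) + 1L]] <<- list(
        n = paste(path_, nm, sep = "."),
        d = as.integer(dim(w) %||% length(w)),
        c = per_channel, q = qoff, s = soff, k = length(s))
    }
    for (nm in names(mod$buffers)) {
      b <- mod$buffers[[nm]]
      boff <- pp(writeBin(as.numeric(b), raw(), size = 4L))
      buffers[[length(buffers) + 1L]] <<- list(
        n = paste(path_, nm, sep = "."), k = length(b), o = boff)
    }
    if (!is.null(mod$aq) && isTRUE(mod$aq$frozen)) {
      acts[[length(acts) + 1L]] <<- list(
        n = path_, s = mod$aq$scale, z = mod$aq$zp)
    }
  })
  header <- list(format = "rfc-int8", version = 1L,
                 bitwidth = bits,
                 weight_scheme = model$qspec$weight_scheme,
                 activation_scheme = model$qspec$activation_scheme,
                 rounding = model$qspec$rounding,
                 momentum = model$qspec$momentum,
                 num_classes = model$num_classes,
                 cfg = unclass(model$cfg),
                 tensors = tensors, buffers = buffers, activations = acts)
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RFC8"), con)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  writeBin(payload, con)
  flush(con)
  close(con); on.exit(NULL)
  bytes <- file.size(path)
  n_par <- sum(vapply(named_params(model), length, integer(1)))
  invisible(structure(list(params = n_par, bytes = bytes,
                           mb = bytes / 1024^2, path = path),
                      class = "quantized_model"))
}

#' Load an INT8 container back into a runnable model
#'
#' Rebuilds the architecture from the stored configuration, restores
#' dequantized weights (exactly the fake-quant values), buffers, and frozen
#' activation observers. The loaded model's forward pass is bit-identical to
#' the exported model's fake-quant forward pass.
#'
#' @param path File written by [export_int8()].
#' @return An `rfc_model` with `weights_prequantized = TRUE`.
#' @export
load_int8 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 4L))
  if (magic != "RFC8") stopf("not an INT8 container: %s", path)
  hlen <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)),
                               simplifyVector = FALSE)
  payload <- readBin(con, raw(), file.size(path))
  hc <- lapply(header$cfg, unlist)
  # stored widths are already multiplier-resolved
  cfg <- stage_config(width_multiplier = 1,
                      num_classes = hc$num_classes, widths = hc$widths,
                      attn_dims = hc$attn_dims, depths = hc$depths,
                      expansion = hc$expansion, patch = hc$patch,
                      head_width = hc$head_width, input_size = hc$input_size,
                      ffn_mult = hc$ffn_mult)
  model <- attach_exit_heads(build_backbone(cfg, num_classes = header$num_classes))
  spec <- quant_spec(bitwidth = header$bitwidth, momentum = header$momentum)
  insert_fake_quant(model, spec)
  read_f32 <- function(off, n)
    readBin(payload[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L)
  vals <- list()
  for (tn in header$tensors) {
    dims <- unlist(tn$d)
    n <- prod(dims)
    q <- as.integer(payload[(tn$q + 1L):(tn$q + n)])
    q <- ifelse(q > 127L, q - 256L, q)
    s <- read_f32(tn$s, tn$k)
    if (isTRUE(tn$c)) {
      qm <- matrix(q, nrow = tn$k)
      w <- array(sweep(qm, 1, s, "*"), dim = dims)
    } else {
      w <- q * s
      if (length(dims) > 1L) w <- array(w, dim = dims)
    }
    vals[[tn$n]] <- w
  }
  set_named_params(model, vals)
  bufs <- list()
  for (bf in header$buffers)
    bufs[[bf$n]] <- read_f32(bf$o, bf$k)
  walk_modules(model, function(mod, path_) {
    for (nm in names(mod$buffers)) {
      key <- paste(path_, nm, sep = ".")
      if (!is.null(bufs[[key]])) mod$buffers[[nm]] <- bufs[[key]]
    }
  })
  amap <- list()
  for (ac in header$activations) amap[[ac$n]] <- ac
  qmin <- -2^(header$bitwidth - 1); qmax <- 2^(header$bitwidth - 1) - 1
  walk_modules(model, function(mod, path_) {
    ac <- amap[[path_]]
    if (!is.null(mod$aq) && !is.null(ac)) {
      mod$aq$scale <- ac$s; mod$aq$zp <- as.integer(ac$z)
      mod$aq$min <- (qmin - ac$z) * ac$s
      mod$aq$max <- (qmax - ac$z) * ac$s
      mod$aq$frozen <- TRUE
    }
  })
  model$frozen <- TRUE
  model$weights_prequantized <- TRUE
  model
}
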