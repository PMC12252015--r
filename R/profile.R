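# Analytic model profiler: exact parameter counts, multiply-accumulate (MAC)
# counts for one forward pass, and serialized storage.
#
# Conventions: one MAC = one FLOP; convolution k^2 * cin * cout * Hout * Wout
# / groups; linear din * dout; separable attention per token group
# k*d (scores) + 2*k*d^2 (key/value projections) + k*d (context sum) +
# k*d (broadcast product) + k*d^2 (output projection); normalization and
# activation layers are excluded.

#' Count trainable parameters
#'
#' @param model Any module (an `rfc_model`, a backbone, or a single block).
#' @return List with `param_count` (all trainable arrays),
#'   `param_count_no_norm` (excluding batch/layer-norm affine parameters),
#'   and `millions` (param_count / 1e6, one decimal).
#' @export
count_params <- function(model) {
  total <- 0; norm <- 0
  walk_modules(model, function(mod, path) {
    for (nm in names(mod$params)) {
      n <- length(mod$params[[nm]])
      total <<- total + n
      if (mod$kind %in% c("batchnorm2d", "layernorm")) norm <<- norm + n
    }
  })
  list(param_count = total, param_count_no_norm = total - norm,
       millions = round(total / 1e6, 1))
}

# MACs of one module on an h x w input (single sample); returns the count
# and the output spatial size.
module_flops <- function(mod, h, w) {
  k <- mod$kind
  if (k == "conv2d") {
    ho <- out_hw(h, mod$k, mod$stride, mod$pad)
    wo <- out_hw(w, mod$k, mod$stride, mod$pad)
    macs <- mod$k^2 * mod$cin * mod$cout * ho * wo / mod$groups
    return(list(macs = macs, h = ho, w = wo))
  }
  if (k == "linear") return(list(macs = mod$din * mod$dout, h = h, w = w))
  if (k == "attention") {
    stopf("attention flops are counted by the owning mobilevit block")
  }
  if (k %in% c("batchnorm2d", "layernorm", "activation", "global_pool"))
    return(list(macs = 0, h = h, w = w))
  if (k == "sequential" || k == "mv2") {
    macs <- 0
    for (ch in mod$children) {
      r <- module_flops(ch, h, w)
      macs <- macs + r$macs; h <- r$h; w <- r$w
    }
    return(list(macs = macs, h = h, w = w))
  }
  if (k == "mobilevit") {
    p <- mod$patch; d <- mod$d
    macs <- 0
    # local path
    r <- module_flops(mod$children[[1]], h, w); macs <- macs + r$macs
    r <- module_flops(mod$children[[2]], h, w); macs <- macs + r$macs
    kk <- (h %/% p) * (w %/% p)   # tokens per group
    G <- p^2
    attn <- G * (kk * d + 2 * kk * d^2 + kk * d + kk * d + kk * d^2)
    if (mod$depth > 0) {
      dh <- mod$children[[3]]$children[[4]]$dh
      ffn <- (h * w) * (d * dh + dh * d)
      macs <- macs + mod$depth * (attn + ffn)
    }
    # projection back to cin
    r <- module_flops(mod$children[[length(mod$children)]], h, w)
    macs <- macs + r$macs
    return(list(macs = macs, h = h, w = w))
  }
  stopf("module_flops: unknown kind %s", k)
}

#' Count multiply-accumulates per stage
#'
#' Walks the model with analytic per-layer formulas for one `input_size^2`
#' RGB input. Stage i's cumulative cost is the cost dynamic inference pays
#' to emit stage i's prediction: the shared trunk up to tap i plus every
#' exit head evaluated along the way (heads 1..i). The final stage's
#' cumulative cost is therefore the dynamic worst case (trunk + final
#' classifier + all three auxiliary heads), which bounds
#' [expected_inference_cost()] from above; `total` is the plain single-path
#' trunk cost without auxiliary heads.
#'
#' @param model An `rfc_model`.
#' @param input_size Square input resolution (default: configured size).
#' @return List with `total` (full-model MACs), `segments`, `heads`, and
#'   `cumulative` (length-4 vector as defined above).
#' @export
count_flops <- function(model, input_size = NULL) {
  sz <- as.integer(input_size %||% model$cfg$input_size)
  segs <- model_segments(model); heads <- model_heads(model)
  h <- sz; w <- sz
  seg_macs <- numeric(4); tap_hw <- list()
  for (i in 1:4) {
    r <- module_flops(segs[[i]], h, w)
    seg_macs[i] <- r$macs; h <- r$h; w <- r$w
    if (i <= 3) tap_hw[[i]] <- c(r$h, r$w)
  }
  head_macs <- vapply(1:3, function(i) {
    hh <- tap_hw[[i]][1]; ww <- tap_hw[[i]][2]
    module_flops(heads[[i]]$children[[1]], hh, ww)$macs +
      module_flops(heads[[i]]$children[[3]], 1, 1)$macs
  }, numeric(1))
  cum <- cumsum(seg_macs)
  hcum <- cumsum(head_macs)
  cumulative <- cum + c(hcum, hcum[3])
  list(total = cum[4], segments = seg_macs, heads = head_macs,
       cumulative = cumulative)
}

#' Expected inference cost under an exit distribution
#'
#' @param fractions Per-stage exit fractions (non-negative, summing to 1).
#' @param cumulative Non-decreasing cumulative per-stage MACs (see
#'   [count_flops()]).
#' @return Expected MACs per sample, `sum(fractions * cumulative)`.
#' @export
expected_inference_cost <- function(fractions, cumulative) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must form a probability simplex")
  if (length(fractions) != length(cumulative))
    stopf("fractions and cumulative lengths differ")
  if (any(diff(cumulative) < 0))
    stopf("cumulative FLOPs must be non-decreasing")
  sum(fractions * cumulative)
}

#' Profile a model: parameters, MACs, storage
#'
#' @param model An `rfc_model`.
#' @param input_size Square input resolution for the MAC count.
#' @param export_path Optional path of an INT8 container whose file size is
#'   reported as `storage_bytes`.
#' @return A `model_profile` list.
#' @export
profile_model <- function(model, input_size = NULL, export_path = NULL) {
  pc <- count_params(model)
  fl <- count_flops(model, input_size)
  storage <- if (!is.null(export_path)) file.size(export_path) else NA_real_
  structure(list(param_count = pc$param_count,
                 param_count_no_norm = pc$param_count_no_norm,
                 params_millions = pc$millions,
                 flop_count = fl$total,
                 flops_cumulative = fl$cumulative,
                 storage_bytes = storage,
                 storage_mb = storage / 1024^2),
            class = "model_profile")
}
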