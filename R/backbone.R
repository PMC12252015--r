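# Backbone: stem conv -> MV2 stages -> three MobileViT stages (tap points
# t1..t3) -> global pool -> linear classifier. The stage table follows the
# separable-attention hybrid design: widths (32,64,128,256,384,512) at
# multiplier 1, attention widths (128,192,256), transformer depths (2,4,3).

#' Stage configuration for the hybrid backbone
#'
#' @param width_multiplier Positive real scaling all channel widths.
#' @param num_classes Number of output classes (11 for the cotton corpus).
#' @param widths Base channel widths: stem, stage1, stage2, and the three
#'   MobileViT stages.
#' @param attn_dims Token widths d of the three MobileViT stages.
#' @param depths Transformer depths of the three MobileViT stages.
#' @param expansion MV2 expansion factor.
#' @param patch Patch size for token folding.
#' @param head_width Channel width of the auxiliary exit heads.
#' @param input_size Expected square input resolution (must be divisible by
#'   32 and then by `patch`).
#' @param ffn_mult Hidden multiplier of token feed-forward layers.
#' @return A validated `stage_config` list.
#' @export
stage_config <- function(width_multiplier = 1,
                         num_classes = 11L,
                         widths = c(32L, 64L, 128L, 256L, 384L, 512L),
                         attn_dims = c(128L, 192L, 256L),
                         depths = c(2L, 4L, 3L),
                         expansion = 2L,
                         patch = 2L,
                         head_width = 336L,
                         input_size = 256L,
                         ffn_mult = 2L) {
  if (width_multiplier <= 0) stopf("width_multiplier must be positive")
  ch <- pmax(2L, as.integer(round(widths * width_multiplier)))
  d <- pmax(2L, as.integer(round(attn_dims * width_multiplier)))
  hw <- max(2L, as.integer(round(head_width * width_multiplier)))
  if (input_size %% (32L * patch) != 0)
    stopf("input_size %d not divisible by the down-sampling chain (32) times patch %d",
          input_size, patch)
  structure(list(width_multiplier = width_multiplier,
                 num_classes = as.integer(num_classes),
                 widths = ch, attn_dims = d, depths = as.integer(depths),
                 expansion = as.integer(expansion), patch = as.integer(patch),
                 head_width = hw, input_size = as.integer(input_size),
                 ffn_mult = as.integer(ffn_mult)),
            class = "stage_config")
}

#' Full-width configuration (the deployable model)
#' @export
#' @rdname stage_config
rfc_config_full <- function(num_classes = 11L) stage_config(1, num_classes)

#' Desk-scale configuration (widths / 8, 64 x 64 inputs) used for CPU runs
#' @export
#' @rdname stage_config
rfc_config_tiny <- function(num_classes = 11L) {
  stage_config(1, num_classes,
               widths = c(4L, 8L, 16L, 32L, 48L, 64L),
               attn_dims = c(16L, 24L, 32L), depths = c(1L, 1L, 1L),
               head_width = 44L, input_size = 64L)
}

#' Build the hybrid backbone with exit tap points
#'
#' Constructs the feature extractor: a strided 3x3 stem, MV2
#' inverted-residual stages, and three MobileViT stages whose attention is
#' [separable_self_attention()]. The model maps an image batch to final
#' logits and exposes intermediate features t1..t3 (after each MobileViT
#' stage) for exit heads.
#'
#' @param cfg A [stage_config()].
#' @param num_classes Overrides `cfg$num_classes` when given.
#' @param seed Integer seed for weight initialisation.
#' @return A backbone module with `$segments` (four sequential stages whose
#'   boundaries are the tap points) and `$cfg`.
#' @export
build_backbone <- function(cfg = rfc_config_full(), num_classes = NULL,
                           seed = 1L) {
  C <- as.integer(num_classes %||% cfg$num_classes)
  ch <- cfg$widths; d <- cfg$attn_dims; dep <- cfg$depths
  e <- cfg$expansion; p <- cfg$patch; fm <- cfg$ffn_mult
  with_seed(seed, {
    seg1 <- sequential(list(
      conv_bn_act(3L, ch[1], 3L, 2L, name = "stem"),
      mv2_block(ch[1], ch[2], e, 1L),
      mv2_block(ch[2], ch[3], e, 2L),
      mv2_block(ch[3], ch[3], e, 1L),
      mv2_block(ch[3], ch[3], e, 1L),
      mv2_block(ch[3], ch[4], e, 2L),
      mobilevit_block(ch[4], d[1], dep[1], p, fm)
    ), name = "seg1")
    seg2 <- sequential(list(
      mv2_block(ch[4], ch[5], e, 2L),
      mobilevit_block(ch[5], d[2], dep[2], p, fm)
    ), name = "seg2")
    seg3 <- sequential(list(
      mv2_block(ch[5], ch[6], e, 2L),
      mobilevit_block(ch[6], d[3], dep[3], p, fm)
    ), name = "seg3")
    seg4 <- sequential(list(
      global_pool(),
      linear(ch[6], C, name = "classifier")
    ), name = "seg4")
    bb <- new_module("backbone", "backbone", cfg = cfg, num_classes = C)
    bb$children <- list(seg1, seg2, seg3, seg4)
    bb
  })
}

# Tap channel widths (features feeding each exit head).
tap_widths <- function(cfg) cfg$widths[4:6]

#' Attach auxiliary early-exit heads to a backbone
#'
#' Each head is a pointwise convolution to `head_width` (with bias), global
#' average pooling, and a linear classifier, attached at tap points t1..t3.
#' The resulting model outputs ordered stage predictions
#' (stage 1, 2, 3, final).
#'
#' @param backbone A module from [build_backbone()].
#' @param head_width Channel width of each head (default from the backbone
#'   configuration).
#' @param num_classes Number of classes (default: backbone's).
#' @param seed Integer seed for head weight initialisation.
#' @return A multi-exit model of class `rfc_model`.
#' @export
attach_exit_heads <- function(backbone, head_width = NULL, num_classes = NULL,
                              seed = 2L) {
  if (is.null(backbone$children) || length(backbone$children) != 4L)
    stopf("backbone does not expose the expected tap points t1..t3")
  cfg <- backbone$cfg
  hw <- as.integer(head_width %||% cfg$head_width)
  C <- as.integer(num_classes %||% backbone$num_classes)
  tw <- tap_widths(cfg)
  heads <- with_seed(seed, lapply(1:3, function(i) {
    sequential(list(
      conv2d(tw[i], hw, 1L, bias = TRUE, name = "reduce"),
      global_pool(),
      linear(hw, C, name = "fc")
    ), name = paste0("head", i))
  }))
  m <- new_module("model", "model", cfg = cfg, num_classes = C,
                  n_stages = 4L, eval_counter = 0L)
  m$children <- c(backbone$children, heads)
  m
}

model_segments <- function(m) m$children[1:4]
model_heads <- function(m) m$children[5:7]

# Full forward pass through all stages; returns the four logit matrices
# (C x N each) and caches everything needed for backward.
model_forward <- function(m, inp, ctx) {
  segs <- model_segments(m); heads <- model_heads(m)
  t1 <- forward(segs[[1]], inp, ctx); m$eval_counter <- m$eval_counter + 1L
  t2 <- forward(segs[[2]], t1, ctx); m$eval_counter <- m$eval_counter + 1L
  t3 <- forward(segs[[3]], t2, ctx); m$eval_counter <- m$eval_counter + 1L
  zf <- forward(segs[[4]], t3, ctx); m$eval_counter <- m$eval_counter + 1L
  z1 <- forward(heads[[1]], t1, ctx)
  z2 <- forward(heads[[2]], t2, ctx)
  z3 <- forward(heads[[3]], t3, ctx)
  list(logits = list(z1, z2, z3, zf), taps = list(t1, t2, t3))
}

# Backward from per-stage logit gradients (list of 4 C x N matrices).
model_backward <- function(m, glogits) {
  segs <- model_segments(m); heads <- model_heads(m)
  gt3 <- backward(segs[[4]], glogits[[4]])
  gh3 <- backward(heads[[3]], glogits[[3]])
  gt3$x <- gt3$x + gh3$x
  gt2 <- backward(segs[[3]], gt3)
  gh2 <- backward(heads[[2]], glogits[[2]])
  gt2$x <- gt2$x + gh2$x
  gt1 <- backward(segs[[2]], gt2)
  gh1 <- backward(heads[[1]], glogits[[1]])
  gt1$x <- gt1$x + gh1$x
  backward(segs[[1]], gt1)
}

#' Run the multi-exit model on an image batch
#'
#' @param model An `rfc_model` from [attach_exit_heads()].
#' @param a Image array `H x W x C` or `H x W x C x N`, values in `[0, 1]`.
#' @param fq Use fake-quantized (simulated INT8) forward computation.
#' @return List with `logits`: a list of four `C x N` logit matrices
#'   (stages 1-3 and final).
#' @export
predict_stages <- function(model, a, fq = NULL) {
  ctx <- model_ctx(model, fq = fq)
  out <- model_forward(model, to_fmap(a), ctx)
  list(logits = out$logits)
}
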