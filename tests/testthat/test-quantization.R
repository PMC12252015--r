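test_that("quantize/dequantize follow the affine code map", {
  # zeros map to the zero point
  sp <- quant_spec(scale = 0.1, zero_point = 3L, symmetric = FALSE)
  q <- quantize_tensor(rep(0, 5), sp)
  expect_true(all(q == 3L))
  expect_equal(dequantize_tensor(q, sp), rep(0, 5))
  # symmetric [-1, 1] range: scale 1/127, x = 0.5 -> code 64 (half to even)
  sps <- quant_spec(scale = 1 / 127, zero_point = 0L)
  expect_equal(quantize_tensor(0.5, sps), 64L)
  # round-trip error bound scale/2 for in-range values
  set.seed(5)
  x <- runif(1000, -1, 1)
  err <- abs(dequantize_tensor(quantize_tensor(x, sps), sps) - x)
  expect_true(all(err <= 1 / 127 / 2 + 1e-12))
  # order preservation
  xs <- sort(rnorm(500))
  qs <- quantize_tensor(xs, sps)
  expect_true(all(diff(qs) >= 0))
  expect_error(quantize_tensor(c(1, NaN), sps), "finite")
  expect_error(quant_spec(scale = -1), "scale")
})

test_that("per-channel weight fake-quant has bounded, channel-scaled error", {
  set.seed(6)
  W <- matrix(rnorm(40) * rep(c(0.1, 10), each = 20), 4, 10)
  s <- rfcottnet:::weight_scales(W)
  expect_length(s, 4)
  Wq <- rfcottnet:::fq_weight(W)
  expect_true(all(abs(Wq - W) <= s / 2 + 1e-12))
  # codes stay within the symmetric range
  codes <- round(sweep(W, 1, s, "/"))
  expect_true(all(abs(codes) <= 127))
})

test_that("fake-quant insertion preserves arity and the lossless sentinel", {
  model <- micro_model(fresh = TRUE, seed = 61)
  set.seed(35)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fp <- predict_stages(model, x)$logits
  # a >= 16-bit spec is a pass-through: outputs equal FP32
  insert_fake_quant(model, quant_spec(bitwidth = 16L))
  z16 <- predict_stages(model, x, fq = TRUE)$logits
  expect_equal(z16, fp, tolerance = 1e-6)
  # true INT8 fake-quant keeps all four exits and perturbs boundedly
  model8 <- micro_model(fresh = TRUE, seed = 61)
  insert_fake_quant(model8, quant_spec())
  z8 <- predict_stages(model8, x, fq = TRUE)$logits
  expect_length(z8, 4)
  expect_true(all(is.finite(unlist(z8))))
  expect_false(identical(z8[[4]], fp[[4]]))
  expect_lt(max(abs(z8[[4]] - fp[[4]])), 2)
  # every compute-carrying kind is wrapped; report lists the rest
  unwrapped <- attr(model8, "unwrapped")
  expect_false(any(c("conv2d", "linear", "attention", "ffn") %in% unwrapped))
})

test_that("a single linear layer under fake-quant equals explicit dequant(quant(W)) x", {
  set.seed(8)
  lin <- rfcottnet:::linear(6, 4, bias = FALSE)
  x <- matrix(rnorm(18), 6, 3)
  ctx <- rfcottnet:::new_ctx(fq = TRUE, wbits = 8L, abits = 16L)
  y <- ns_forward(lin, x, ctx)
  s <- rfcottnet:::weight_scales(lin$params$W)
  Wq <- sweep(pmin(pmax(round(sweep(lin$params$W, 1, s, "/")), -127), 127),
              1, s, "*")
  expect_equal(y, Wq %*% x, tolerance = 1e-12)
})

test_that("qat fine-tuning freezes finite ranges and is reproducible after freeze", {
  mc <- micro_corpus()
  model <- micro_model(fresh = TRUE, seed = 71)
  insert_fake_quant(model, quant_spec())
  expect_error(export_int8(model, tempfile()), "frozen")
  expect_error(qat_finetune(model, mc$all$x, mc$all$y, epochs = 0), ">= 1")
  qat_finetune(model, mc$all$x, mc$all$y, epochs = 1, batch_size = 16,
               lr = 1e-4, seed = 7)
  n_frozen <- 0
  rfcottnet:::walk_modules(model, function(mod, path) {
    if (!is.null(mod$aq)) {
      expect_true(mod$aq$frozen)
      expect_true(is.finite(mod$aq$scale) && mod$aq$scale > 0)
      n_frozen <<- n_frozen + 1
    }
  })
  expect_gt(n_frozen, 30)
  z1 <- predict_stages(model, mc$all$x[, , , 1:4])$logits
  z2 <- predict_stages(model, mc$all$x[, , , 1:4])$logits
  expect_identical(z1, z2)
})

test_that("INT8 export obeys the storage law and round-trips exactly", {
  mc <- micro_corpus()
  model <- micro_model(fresh = TRUE, seed = 81)
  insert_fake_quant(model, quant_spec())
  calibrate_model(model, mc$all$x[, , , 1:8])
  freeze_ranges(model)
  f1 <- tempfile(fileext = ".rfc8")
  rep1 <- export_int8(model, f1)
  expect_true(file.exists(f1))
  expect_gte(rep1$bytes, rep1$params)   # at least one byte per parameter
  # export -> load -> re-export is byte-identical
  m2 <- load_int8(f1)
  f2 <- tempfile(fileext = ".rfc8")
  export_int8(m2, f2)
  expect_identical(readBin(f1, raw(), file.size(f1) + 10),
                   readBin(f2, raw(), file.size(f2) + 10))
  # loaded model reproduces the fake-quant forward pass
  z1 <- predict_stages(model, mc$all$x[, , , 1:6], fq = TRUE)$logits
  z2 <- predict_stages(m2, mc$all$x[, , , 1:6])$logits
  expect_equal(z1, z2, tolerance = 1e-9)
  # parameter counts are untouched by quantization
  expect_equal(count_params(m2)$param_count, count_params(model)$param_count)
})

test_that("export size scales linearly with parameter count across configs", {
  sizes <- lapply(list(rfc_config_tiny(),
                       stage_config(1, 11, widths = c(8, 16, 32, 64, 96, 128),
                                    attn_dims = c(32, 48, 64),
                                    depths = c(1, 1, 1), head_width = 88,
                                    input_size = 64)),
                  function(cfg) {
    m <- attach_exit_heads(build_backbone(cfg, seed = 2), seed = 3)
    insert_fake_quant(m, quant_spec())
    calibrate_model(m, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
    freeze_ranges(m)
    f <- tempfile(fileext = ".rfc8")
    r <- export_int8(m, f)
    c(P = r$params, B = r$bytes)
  })
  marginal <- (sizes[[2]]["B"] - sizes[[1]]["B"]) /
              (sizes[[2]]["P"] - sizes[[1]]["P"])
  expect_gt(marginal, 0.9)   # ~1 byte per additional parameter
  expect_lt(marginal, 1.3)
})
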