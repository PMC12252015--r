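test_that("entropy follows the closed forms", {
  expect_equal(entropy(c(1, 0, 0)), 0)
  expect_equal(entropy(rep(1 / 11, 11)), log(11))
  expect_equal(entropy(c(0.7, 0.2, 0.1)), 0.8018, tolerance = 1e-4)
  expect_error(entropy(c(0.5, 0.6)), "sum")
  expect_error(entropy(c(1.2, -0.2)), "negative")
})

test_that("joint loss matches hand-computed cross-entropies", {
  # probability 1 on the true class at every stage -> zero loss
  onehot_logits <- function(lbl, C, n) {
    z <- matrix(-1e3, C, n)
    z[cbind(lbl, seq_len(n))] <- 1e3
    z
  }
  y <- c(2L, 5L)
  zs <- replicate(4, onehot_logits(y, 11, 2), simplify = FALSE)
  rep0 <- joint_loss(zs, y)
  expect_equal(rep0$stage_losses, rep(0, 4), tolerance = 1e-10)
  expect_equal(rep0$total, 0, tolerance = 1e-10)

  # uniform probabilities: every stage loss is log(11)
  zu <- replicate(4, matrix(0, 11, 2), simplify = FALSE)
  repu <- joint_loss(zu, y)
  expect_equal(repu$stage_losses, rep(log(11), 4), tolerance = 1e-10)
  expect_equal(repu$total, 4 * log(11), tolerance = 1e-10)

  # hand-written probabilities, 2 samples x 2 stages
  p1 <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3))
  p2 <- cbind(c(0.5, 0.25, 0.25), c(0.2, 0.2, 0.6))
  y2 <- c(1L, 2L)
  rep2 <- joint_loss(list(log(p1), log(p2)), y2)
  expect_equal(rep2$stage_losses[1], -mean(log(c(0.7, 0.6))), tolerance = 1e-10)
  expect_equal(rep2$stage_losses[2], -mean(log(c(0.5, 0.2))), tolerance = 1e-10)
  expect_equal(rep2$total, sum(rep2$stage_losses), tolerance = 1e-10)

  # weighted combination and validation
  repw <- joint_loss(list(log(p1), log(p2)), y2, weights = c(2, 0.5))
  expect_equal(repw$total, 2 * rep2$stage_losses[1] + 0.5 * rep2$stage_losses[2])
  expect_error(joint_loss(zu, c(0L, 5L)), "range")
  expect_error(joint_loss(zu, y, weights = 1:3), "weight")
})

test_that("gate scan follows first-crossing semantics in both modes", {
  mk <- function(conf, C = 2) c(conf, rep((1 - conf) / (C - 1), C - 1))
  pol <- exit_policy("confidence", c(0.6, 0.7, 0.8))
  confs <- c(0.55, 0.72, 0.5)
  fired <- vapply(1:3, function(i)
    rfcottnet:::gate_fires(pol, i, mk(confs[i])), logical(1))
  expect_equal(which(fired)[1], 2L)
  # strict inequality: a tie does not exit
  expect_false(rfcottnet:::gate_fires(pol, 1, mk(0.6)))
  # entropy mode: one-hot fires at any positive S, uniform never at small S
  pole <- exit_policy("entropy", 0.3)
  expect_true(rfcottnet:::gate_fires(pole, 1, c(1, 0, 0)))
  expect_false(rfcottnet:::gate_fires(pole, 1, rep(1 / 3, 3)))
  expect_error(exit_policy("confidence", c(0.5, 0.5)), "length")
  expect_error(exit_policy("entropy", -1), ">= 0")
})

test_that("dynamic inference exits early, skips computation, and is total", {
  model <- micro_model()
  set.seed(23)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  # always-exit policy: any confidence exceeds 0
  model$eval_counter <- 0L
  p1 <- dynamic_inference(model, x, exit_policy("confidence", rep(1e-9, 3)))
  expect_length(p1, 3)
  expect_true(all(vapply(p1, `[[`, 0L, "stage_index") == 1L))
  expect_equal(model$eval_counter, 3L)          # one segment per sample
  # never-exit policy falls through to the final stage
  model$eval_counter <- 0L
  p4 <- dynamic_inference(model, x, exit_policy("confidence", rep(1.5, 3)))
  expect_true(all(vapply(p4, `[[`, 0L, "stage_index") == 4L))
  expect_true(all(vapply(p4, `[[`, TRUE, "exited")))
  expect_equal(model$eval_counter, 12L)         # all four segments per sample
  # every prediction is a simplex with bounded entropy/confidence
  for (p in p4) {
    expect_equal(sum(p$probs), 1, tolerance = 1e-6)
    expect_gte(p$entropy, 0); expect_lte(p$entropy, log(11) + 1e-9)
    expect_gte(p$confidence, 1 / 11); expect_lte(p$confidence, 1)
  }
  expect_error(dynamic_inference(model, x,
                                 exit_policy("confidence", c(0.5, 0.6), n = 3L)),
               "stages")
})

test_that("disabled exits reproduce the plain final-head forward exactly", {
  model <- micro_model()
  set.seed(29)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  # per-sample forward, matching dynamic inference's evaluation granularity
  plain <- sapply(1:2, function(j)
    predict_stages(model, x[, , , j, drop = FALSE])$logits[[4]])
  # confidence thresholds above 1 disable all early exits
  pc <- dynamic_inference(model, x, exit_policy("confidence", rep(2, 3)))
  for (j in 1:2) expect_identical(pc[[j]]$logits, plain[, j])
  # entropy threshold 0 can never fire (entropy >= 0, strict <)
  pe <- dynamic_inference(model, x, exit_policy("entropy", 0))
  for (j in 1:2) expect_identical(pe[[j]]$logits, plain[, j])
})

test_that("lowering confidence thresholds never deepens any exit", {
  model <- micro_model()
  set.seed(31)
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  ths <- list(c(0.9, 0.9, 0.9), c(0.6, 0.7, 0.8), c(0.3, 0.4, 0.5),
              c(0.05, 0.05, 0.05))
  stages <- sapply(ths, function(th)
    vapply(dynamic_inference(model, x, exit_policy("confidence", th)),
           `[[`, 0L, "stage_index"))
  for (col in 2:4) expect_true(all(stages[, col] <= stages[, col - 1]))
  # expected evaluated cost is non-increasing as thresholds drop
  fl <- count_flops(model)
  costs <- apply(stages, 2, function(s)
    expected_inference_cost(tabulate(s, 4) / length(s), fl$cumulative))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("exit statistics aggregate fractions and mean stage", {
  mk <- function(stage) structure(list(stage_index = stage, n_stages = 4L),
                                  class = "stage_prediction")
  st <- exit_statistics(lapply(c(1, 4, 4, 4), mk))
  expect_equal(st$fractions, c(0.25, 0, 0, 0.75))
  expect_equal(st$mean_stage, 3.25)
  expect_equal(sum(st$fractions), 1)
  all1 <- exit_statistics(lapply(rep(1, 5), mk))
  expect_equal(all1$fractions, c(1, 0, 0, 0))
  expect_equal(all1$mean_stage, 1)
  expect_error(exit_statistics(list()), "empty")
})
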