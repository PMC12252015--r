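test_that("confusion matrix counts exactly", {
  # perfect predictions: diagonal matrix
  cm <- confusion_matrix(c(1, 2, 3, 1), c(1, 2, 3, 1), C = 3)
  expect_equal(cm$matrix, diag(c(2, 1, 1)))
  expect_true(all(cm$fp == 0) && all(cm$fn == 0))
  # one error: true a predicted b
  truth <- c(rep(1, 6), rep(2, 4))
  pred <- truth; pred[1] <- 2
  cm2 <- confusion_matrix(pred, truth, C = 2)
  expect_equal(cm2$tp[1], 5); expect_equal(cm2$fn[1], 1)
  expect_equal(cm2$fp[2], 1)
  # tp+fp+tn+fn = total for every class; row sums = support
  for (c in 1:2)
    expect_equal(cm2$tp[c] + cm2$fp[c] + cm2$tn[c] + cm2$fn[c], 10)
  expect_equal(rowSums(cm2$matrix), c(6, 4))
  # brute-force double loop on random labels
  set.seed(99)
  t3 <- sample(3, 200, replace = TRUE); p3 <- sample(3, 200, replace = TRUE)
  cm3 <- confusion_matrix(p3, t3, C = 3)
  ref <- matrix(0, 3, 3)
  for (i in seq_along(t3)) ref[t3[i], p3[i]] <- ref[t3[i], p3[i]] + 1
  expect_equal(cm3$matrix, ref)
  expect_error(confusion_matrix(1:3, 1:4), "lengths differ")
  expect_error(confusion_matrix(c(1, 4), c(1, 2), C = 3), "range")
  # name-based labels
  cmn <- confusion_matrix(c("a", "b"), c("a", "a"), classes = c("a", "b"))
  expect_equal(cmn$matrix["a", "b"], 1)
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"),
                                classes = c("a", "b")), "class list")
})

test_that("metrics follow the precision/recall/F1 definitions", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 1, 2), C = 2)
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$macro_f1, 100)
  # tp=8, fp=2, fn=1 -> P=80, R=88.89, F1=84.21
  m <- matrix(c(8, 2, 1, 20), 2, byrow = TRUE)
  cm2 <- structure(list(matrix = m, tp = c(8, 20), fp = c(1, 2),
                        tn = c(20, 8), fn = c(2, 1), total = 31,
                        classes = NULL), class = "confusion_counts")
  rep2 <- metrics_from_confusion(cm2)
  expect_equal(rep2$per_class$precision[1], 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(rep2$per_class$recall[1], 80, tolerance = 1e-10)
  pr <- 100 * 8 / 9; rc <- 80
  expect_equal(rep2$per_class$f1[1], 2 * pr * rc / (pr + rc), tolerance = 1e-10)
  # min(P, R) <= F1 <= max(P, R) per class
  expect_true(all(rep2$per_class$f1 >= pmin(rep2$per_class$precision,
                                            rep2$per_class$recall) - 1e-9))
  expect_true(all(rep2$per_class$f1 <= pmax(rep2$per_class$precision,
                                            rep2$per_class$recall) + 1e-9))
  # harmonic mean of the printed row
  expect_equal(round(f1_score(98.5, 98.3), 1), 98.4)
  expect_equal(f1_score(0, 0), 0)
})

test_that("metrics agree with brute force and the micro identity on 1000 random label sets", {
  set.seed(123)
  for (trial in 1:1000) {
    C <- sample(c(2, 3, 11), 1)
    n <- sample(10:60, 1)
    truth <- sample(C, n, replace = TRUE)
    pred <- sample(C, n, replace = TRUE)
    rep <- metrics_from_confusion(confusion_matrix(pred, truth, C = C))
    bf <- brute_force_metrics(pred, truth, C)
    expect_equal(rep$accuracy, bf$accuracy, tolerance = 1e-9)
    expect_equal(rep$macro_precision, bf$macro_precision, tolerance = 1e-9)
    expect_equal(rep$macro_recall, bf$macro_recall, tolerance = 1e-9)
    expect_equal(rep$macro_f1, bf$macro_f1, tolerance = 1e-9)
    # single-label multiclass: micro P = micro R = accuracy
    expect_equal(rep$micro_precision, rep$accuracy, tolerance = 1e-9)
    expect_equal(rep$micro_recall, rep$accuracy, tolerance = 1e-9)
  }
})

test_that("parameter counting matches weight-array arithmetic", {
  lin <- rfcottnet:::linear(4, 3)
  expect_equal(count_params(lin)$param_count, 15)
  cv <- rfcottnet:::conv2d(3, 8, k = 3, bias = TRUE)
  expect_equal(count_params(cv)$param_count, 3 * 3 * 3 * 8 + 8)   # 224
  # exit head arithmetic: cin=96, width=128, 11 classes
  head <- rfcottnet:::sequential(list(
    rfcottnet:::conv2d(96, 128, bias = TRUE),
    rfcottnet:::global_pool(),
    rfcottnet:::linear(128, 11)))
  expect_equal(count_params(head)$param_count, 13835)
})

test_that("MAC counting follows the stated conventions", {
  cv <- rfcottnet:::conv2d(1, 1, k = 3, stride = 1)
  expect_equal(rfcottnet:::module_flops(cv, 8, 8)$macs, 576)
  # attention term-by-term count: k = 4 tokens, d = 2
  k <- 4; d <- 2
  expect_equal(k * d + 2 * k * d^2 + k * d + k * d + k * d^2, 72)
  blk <- mobilevit_block(4, 2, depth = 1, patch = 2)
  f1 <- rfcottnet:::module_flops(blk, 4, 4)$macs    # k = 4 per group
  f2 <- rfcottnet:::module_flops(blk, 4, 8)$macs    # k = 8 per group
  expect_equal(f2, 2 * f1)                          # linear in token count
  # model-level cumulative costs are non-decreasing
  fl <- count_flops(micro_model())
  expect_true(all(diff(fl$cumulative) >= 0))
  expect_equal(fl$cumulative[4] - fl$total, sum(fl$heads))
})

test_that("expected inference cost is the policy-weighted cumulative cost", {
  cum <- c(100, 200, 300, 400)
  expect_equal(expected_inference_cost(c(0, 0, 0, 1), cum), 400)
  expect_equal(expected_inference_cost(c(1, 0, 0, 0), cum), 100)
  expect_equal(expected_inference_cost(c(0.5, 0, 0, 0.5), cum), 250)
  expect_error(expected_inference_cost(c(0.5, 0.2, 0, 0), cum), "simplex")
  expect_error(expected_inference_cost(c(0, 0, 0, 1), c(2, 1, 3, 4)),
               "non-decreasing")
  # bounded by the full dynamic path; equality iff all mass on the final stage
  set.seed(7)
  for (i in 1:20) {
    fr <- runif(4); fr <- fr / sum(fr)
    expect_lte(expected_inference_cost(fr, cum), 400)
  }
})
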