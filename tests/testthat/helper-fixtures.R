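# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# Evaluate internal generics (forward/backward) with dispatch resolved in the
# package namespace.
ns_forward <- function(m, x, ctx) {
  eval(as.call(list(quote(forward), m, x, ctx)), asNamespace("rfcottnet"))
}
ns_backward <- function(m, g) {
  eval(as.call(list(quote(backward), m, g)), asNamespace("rfcottnet"))
}

# Micro corpus: 3 images per class at 64x64, split 8:2.
micro_corpus <- function() {
  if (is.null(.fixtures$micro)) {
    dir <- file.path(tempdir(), "micro_corpus")
    man <- generate_synthetic_dataset(default_class_specs(n_per_class = 3),
                                      dir, image_size = 64L, seed = 77L)
    man <- stratified_split(man, 0.8, seed = 78L)
    .fixtures$micro <- list(dir = dir, manifest = man,
                            all = load_dataset(man))
  }
  .fixtures$micro
}

# Micro multi-exit model (desk-scale stage table), untrained.
micro_model <- function(fresh = FALSE, seed = 5L) {
  mk <- function() attach_exit_heads(build_backbone(rfc_config_tiny(),
                                                    seed = seed),
                                     seed = seed + 1L)
  if (fresh) return(mk())
  if (is.null(.fixtures$model)) .fixtures$model <- mk()
  .fixtures$model
}

# Brute-force separable self-attention, written directly from the
# definition (scalar loops); the independent oracle for the vectorised path.
brute_force_attention <- function(x, W_I, W_K, W_V, W_O) {
  k <- nrow(x); d <- ncol(x)
  s <- numeric(k)
  for (i in seq_len(k)) s[i] <- sum(x[i, ] * W_I)
  e <- exp(s - max(s)); cs <- e / sum(e)
  cv <- numeric(d)
  for (i in seq_len(k)) cv <- cv + cs[i] * as.numeric(x[i, ] %*% W_K)
  y <- matrix(0, k, d)
  for (i in seq_len(k)) {
    v <- pmax(as.numeric(x[i, ] %*% W_V), 0)
    y[i, ] <- as.numeric((cv * v) %*% W_O)
  }
  y
}

# Brute-force per-sample metrics (independent of the confusion-matrix path).
brute_force_metrics <- function(pred, truth, C) {
  acc <- mean(pred == truth)
  P <- R <- F1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    P[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    F1[c] <- if (P[c] + R[c] == 0) 0 else 2 * P[c] * R[c] / (P[c] + R[c])
  }
  list(accuracy = 100 * acc, macro_precision = 100 * mean(P),
       macro_recall = 100 * mean(R), macro_f1 = 100 * mean(F1))
}

# The emulated corpus' printed per-class totals (train, test, total).
corpus_class_table <- function() {
  data.frame(
    class = c("healthy", "aphids", "army_worm", "bacterial_blight",
              "cotton_curl_virus", "fusarium_wilt", "herbicide_growth_damage",
              "leaf_redding", "leaf_variegation", "powdery_mildew",
              "target_spot"),
    train = c(5155, 1265, 1088, 1981, 2024, 704, 224, 462, 92, 1080, 1084),
    test = c(1289, 317, 272, 496, 506, 177, 56, 116, 24, 270, 271),
    total = c(6444, 1582, 1360, 2477, 2530, 881, 280, 578, 116, 1350, 1355))
}
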