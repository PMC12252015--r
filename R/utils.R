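#' @keywords internal
"_PACKAGE"

# Splittable seeding: every stochastic routine takes an explicit integer seed
# and derives child seeds deterministically, so no global RNG state leaks
# between pipeline stages. Child seeds stay below 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash folded into the positive 32-bit integer range
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h %% 2147483562 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Round doubles to float32 precision (used for all quantization scales so the
# in-memory model and the serialized INT8 container agree bit-for-bit).
as_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised HSV -> RGB on numeric vectors in [0, 1]; returns list(r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Shannon entropy of a class-probability vector
#'
#' Computes \eqn{-\sum_c p_c \log p_c} in nats with the convention
#' \eqn{0 \log 0 = 0}. Used by the entropy-gated early-exit policy.
#'
#' @param probs Numeric vector of class probabilities (must sum to 1 within
#'   1e-6 and contain no negative entries).
#' @return Entropy in nats, a single number in `[0, log(length(probs))]`.
#' @examples
#' entropy(c(1, 0, 0))          # 0
#' entropy(rep(1 / 11, 11))     # log(11) ~ 2.3979
#' @export
entropy <- function(probs) {
  if (any(probs < 0)) stopf("entropy: negative probability entries")
  if (abs(sum(probs) - 1) > 1e-6) stopf("entropy: probabilities must sum to 1")
  nz <- probs > 0
  -sum(probs[nz] * log(probs[nz]))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Column-wise softmax of a matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
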