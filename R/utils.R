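# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic polynomial hash of an integer vector onto [0, 2^31 - 2].
# Used by the circular fingerprint; double arithmetic keeps every
# intermediate below 2^53 so the result is exact and platform independent.
.dsHash <- function(x) {
  p <- 2147483647 # 2^31 - 1
  h <- 16777619
  x <- as.numeric(x) %% p
  for (v in x) h <- (h * 131 + v + 1) %% p
  h
}

.dsStop <- function(...) stop(sprintf(...), call. = FALSE)

.dsWarn <- function(...) warning(sprintf(...), call. = FALSE)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

# ReLU and leaky ReLU with their derivatives-by-mask.
.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# Sample without replacement that is sane for length-1 x (unlike base sample()).
.sampleVec <- function(x, size) x[sample.int(length(x), size)]

# Deal n entities into k folds as evenly as possible, in shuffled order.
.dealFolds <- function(n, k) {
  rep_len(seq_len(k), n)[sample.int(n)]
}
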