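clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 1

# FNV-1a over UTF-8 bytes, done in doubles to stay exact (products < 2^53),
# folded into [0, 2^31 - 2] so it is always a legal set.seed() argument.
hash_string <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h %% 2147483646
}

# Per-entity substream seed: stable under generation order, distinct across
# ids, always < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  (((seed %% 2147483647) * 48271) %% 2147483647 + hash_string(key)) %% 2147483647
}

# Inverse-CDF truncated normal draw on [lo, hi]; exact and vectorized.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

format_p <- function(p) {
  ifelse(p < 1e-4, "<< 0.001",
         ifelse(p < 5e-4, "< 0.001", formatC(p, format = "f", digits = 3)))
}
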