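# Internal helpers shared across modules.

# robust SD via median absolute deviation, consistent for a normal sample
robust_sd <- function(x) 1.4826 * stats::median(abs(x - stats::median(x)))

# derive a child seed from a base seed; kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(charToRaw(digest_chr(key)), 4)
  as.integer(sum(as.integer(raw) * 256^(0:3)) %% 2147483647L)
}

# tiny stable string hash (FNV-1a, hex); used for config hashes and seeds
digest_chr <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# sample index of an onset time; round-half-even via base round()
onset_index <- function(onset_s, rate) as.integer(round(onset_s * rate)) + 1L

sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  }
  c(
    mean = m,
    variance = stats::var(x),
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3
  )
}
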