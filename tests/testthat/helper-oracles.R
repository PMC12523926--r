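# Independent brute-force oracles, deliberately implemented differently from
# the package code paths they check.

# LZ76 exhaustive-history parse by literal definition: grow the current
# component while the block is reproducible from an earlier starting
# position (copies may overrun); the first novel extension closes it.
brute_lz76 <- function(s) {
  n <- length(s)
  c <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    repeat {
      if (l + k - 1L > n) break
      block <- s[l:(l + k - 1L)]
      repro <- FALSE
      if (l > 1L) {
        for (i in 1:(l - 1L)) {
          if (all(s[i:(i + k - 1L)] == block)) {
            repro <- TRUE
            break
          }
        }
      }
      if (!repro) break
      k <- k + 1L
    }
    if (l + k - 1L > n) k <- n - l + 1L
    c <- c + 1L
    l <- l + k
  }
  c
}

brute_lzc <- function(x) {
  b <- as.integer(x >= median(x))
  brute_lz76(b) * log2(length(x)) / length(x)
}

# plug-in MI by explicit double sum over a 2-D histogram
brute_mi <- function(x, y, bins = 8) {
  cut_bins <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  }
  bx <- cut_bins(x); by <- cut_bins(y)
  n <- length(x)
  mi <- 0
  for (i in 1:bins) {
    for (j in 1:bins) {
      nij <- sum(bx == i & by == j)
      if (nij > 0) {
        pij <- nij / n
        mi <- mi + pij * log2(pij / ((sum(bx == i) / n) * (sum(by == j) / n)))
      }
    }
  }
  mi
}

brute_curve_length <- function(x) {
  total <- 0
  for (i in seq_len(length(x) - 1)) total <- total + abs(x[i + 1] - x[i])
  total
}

# AUC by exhaustive pairwise comparison (ties get half credit)
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# textbook metric formulas written independently
brute_metrics <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  )
}
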