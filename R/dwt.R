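#' Periodized Daubechies-4 discrete wavelet transform
#'
#' Pyramid algorithm with the orthonormal 4-tap Daubechies filter and
#' periodic boundary handling. When the input length is not divisible by
#' `2^levels`, the series is padded to the next multiple with its mean
#' before transforming (so a constant series still yields all-zero detail
#' coefficients); energy conservation (Parseval) is exact whenever the
#' length is already a multiple of `2^levels`.
#'
#' @param x Numeric series.
#' @param levels Decomposition depth; default
#'   `min(4, floor(log2(length(x))) - 2)`.
#' @return List with `details` (list of detail-coefficient vectors, finest
#'   first), `approx` (final approximation) and `levels`.
#' @export
dwt_d4 <- function(x, levels = NULL) {
  n <- length(x)
  if (n < 16) abort("series too short for wavelet decomposition (need >= 16)")
  levels <- levels %||% min(4L, floor(log2(n)) - 2L)
  mult <- 2^levels
  if (n %% mult != 0) {
    pad <- mult - n %% mult
    x <- c(x, rep(mean(x), pad))
  }
  # orthonormal D4 low-pass filter
  h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1) # high-pass via quadrature mirror
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    m <- length(a)
    idx <- outer(seq(1, m, by = 2), 0:3, function(i, k) (i + k - 1) %% m + 1)
    am <- matrix(a[idx], ncol = 4)
    details[[lev]] <- as.vector(am %*% g)
    a <- as.vector(am %*% h)
  }
  list(details = details, approx = a, levels = levels)
}
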