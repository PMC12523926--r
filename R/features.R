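#' Feature kinds of the epoch-level battery
#'
#' @return Character vector of the 13 implemented feature kinds, in their
#'   canonical column order.
#' @export
feature_kinds <- function() {
  c("NumPeaks", "CurveLength", "PeakAmp", "PeakLat", "Mean", "Var", "Skew",
    "Kurtosis", "LZC", "MutualInfo", "WaveletMean", "WaveletVar",
    "WaveletKurtosis")
}

#' Parse and serialize feature names
#'
#' Feature columns follow the grammar `<Feature>_<Species>_<Channel>` with
#' species in `{HbO, Hb, THb}` (oxy-, deoxy- and total hemoglobin) and a
#' 0-based channel index, e.g. `NumPeaks_THb_3` or `LZC_THb_0`.
#'
#' @param feature,species,channel Components of the name.
#' @return `feature_name()` returns the serialized string;
#'   `parse_feature_name()` returns a tibble with columns `feature`,
#'   `species`, `channel`.
#' @export
feature_name <- function(feature, species, channel) {
  stopifnot(feature %in% feature_kinds(), species %in% c("HbO", "Hb", "THb"))
  paste(feature, species, channel, sep = "_")
}

#' @rdname feature_name
#' @param x Character vector of serialized feature names.
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3
  if (any(bad)) abort(paste0("malformed feature name: ", x[bad][1]))
  out <- tibble::tibble(
    feature = vapply(parts, `[[`, "", 1),
    species = vapply(parts, `[[`, "", 2),
    channel = as.integer(vapply(parts, `[[`, "", 3))
  )
  ok <- out$feature %in% feature_kinds() & out$species %in% c("HbO", "Hb", "THb") &
    !is.na(out$channel)
  if (!all(ok)) abort(paste0("malformed feature name: ", x[!ok][1]))
  out
}

#' Count peaks with a prominence criterion
#'
#' Local maxima whose topographic prominence is at least `min_prom_sd`
#' standard deviations of the series. A monotone or constant series has no
#' peaks.
#'
#' @param x Numeric series of length >= 3.
#' @param min_prom_sd Prominence threshold in SD multiples (default 0.5).
#' @return Integer peak count.
#' @export
num_peaks <- function(x, min_prom_sd = 0.5) {
  n <- length(x)
  if (n < 3) abort("num_peaks needs at least 3 samples")
  s <- stats::sd(x)
  if (s == 0) return(0L)
  # strict rise before, fall-or-flat after (plateau start counts once)
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(is_peak)) return(0L)
  prom <- vapply(is_peak, function(i) {
    h <- x[i]
    left <- x[1:i]
    higher_l <- which(left > h)
    base_l <- min(left[(max(higher_l, 0) + 1):i])
    right <- x[i:n]
    higher_r <- which(right > h)
    to <- if (length(higher_r)) min(higher_r) else length(right)
    base_r <- min(right[1:to])
    h - max(base_l, base_r)
  }, numeric(1))
  sum(prom >= min_prom_sd * s)
}

#' Curve length of a series
#'
#' Total variation `sum_i |x[i+1] - x[i]|`, a waveform-morphology measure.
#'
#' @param x Numeric series of length >= 2.
#' @return Curve length in the units of `x`.
#' @export
curve_length <- function(x) {
  if (length(x) < 2) abort("curve_length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Peak amplitude and latency
#'
#' @param x Nonempty numeric series.
#' @param rate Sampling rate, Hz.
#' @return Named vector `c(amp, lat_s)`: the maximum and the time of its
#'   earliest occurrence in seconds from the first sample.
#' @export
peak_amp_lat <- function(x, rate) {
  if (!length(x)) abort("peak_amp_lat needs a nonempty series")
  i <- which.max(x) # earliest index on ties
  c(amp = x[i], lat_s = (i - 1) / rate)
}

#' Lempel-Ziv complexity of a series
#'
#' Binarizes by the median (values >= median map to 1), parses with the
#' LZ76 exhaustive-history scheme to obtain the component count `c(n)`,
#' and returns the normalized complexity `c(n) * log2(n) / n`. Random
#' sequences approach 1; periodic or constant sequences are near 0.
#'
#' @param x Numeric series of length >= 2.
#' @return Normalized complexity (unitless).
#' @export
lzc <- function(x) {
  n <- length(x)
  if (n < 2) abort("lzc needs at least 2 samples")
  b <- as.integer(x >= stats::median(x))
  .lz76_count(b) * log2(n) / n
}

#' Histogram mutual information between two series
#'
#' Plug-in estimate from a joint histogram with `bins` equal-width bins
#' per axis (each axis binned over its own range), in bits. Symmetric and
#' nonnegative; `mutual_info(x, x)` equals the binned entropy of `x`.
#'
#' @param x,y Numeric series of equal length >= 16.
#' @param bins Bins per axis (default 8).
#' @return Mutual information in bits.
#' @export
mutual_info <- function(x, y, bins = 8) {
  if (length(x) != length(y)) abort("mutual_info needs equal-length series")
  if (length(x) < 16) abort("mutual_info needs at least 16 samples")
  bx <- bin_index(x, bins)
  by <- bin_index(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / length(x)
  px <- tabulate(bx, nbins = bins) / length(x)
  py <- tabulate(by, nbins = bins) / length(x)
  pij <- matrix(joint, bins, bins)
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (pij[i, j] > 0) {
      mi <- mi + pij[i, j] * log2(pij[i, j] / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}

bin_index <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

#' Wavelet detail statistics of an epoch
#'
#' Daubechies-4 discrete wavelet decomposition ([dwt_d4()]); mean,
#' variance and excess kurtosis are computed over the pooled detail
#' coefficients of all levels. Transients such as spikes concentrate
#' energy in few large detail coefficients and raise the kurtosis.
#'
#' @param x Numeric series of length >= 16.
#' @return Named vector `c(WaveletMean, WaveletVar, WaveletKurtosis)`.
#' @export
wavelet_stats <- function(x) {
  w <- dwt_d4(x)
  d <- unlist(w$details)
  m <- sample_moments(d)
  c(WaveletMean = unname(m["mean"]), WaveletVar = unname(m["variance"]),
    WaveletKurtosis = unname(m["kurtosis"]))
}

#' Extract the feature table from an epoch collection
#'
#' Computes every enabled feature for every retained channel and species
#' (HbO, Hb, THb), one row per epoch, with columns named by the
#' `<Feature>_<Species>_<Channel>` grammar (0-based channels) in a
#' deterministic order (feature kind, then species, then channel).
#' `MutualInfo` for channel *i* is computed between channel *i* and the
#' mean series of all other retained channels of the same species.
#' Features of masked-out channels are emitted as `NA` (downstream
#' standardization imputes them from training rows only).
#'
#' @param epochs An `olf_epochs` object (see [make_epochs()]).
#' @param kinds Feature kinds to compute (default: all).
#' @return A tibble with metadata columns `participant_id`, `trial_id`,
#'   `task`, `label` followed by the feature columns.
#' @export
extract_features <- function(epochs, kinds = feature_kinds()) {
  if (!length(epochs$epochs)) abort("no epochs to extract features from")
  shapes <- vapply(epochs$epochs, function(e) paste(dim(e$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1) abort("inconsistent epoch shapes")
  stopifnot(all(kinds %in% feature_kinds()))
  rate <- epochs$sampling_rate
  species <- c("HbO", "Hb", "THb")
  nc <- dim(epochs$epochs[[1]]$data)[1]
  mask <- epochs$channel_mask %||% rep(TRUE, nc)
  cols <- character(0)
  for (k in kinds) for (s in species) for (ch in seq_len(nc) - 1L) {
    cols <- c(cols, feature_name(k, s, ch))
  }
  rows <- lapply(epochs$epochs, function(e) {
    vals <- setNames(numeric(length(cols)), cols)
    for (si in seq_along(species)) {
      sdat <- e$data[, si, , drop = TRUE]
      sdat <- matrix(sdat, nrow = nc)
      ref_all <- NULL
      for (ch in seq_len(nc)) {
        if (!mask[ch]) {
          for (k in kinds) vals[feature_name(k, species[si], ch - 1L)] <- NA_real_
          next
        }
        x <- sdat[ch, ]
        put <- function(k, v) {
          if (k %in% kinds) vals[feature_name(k, species[si], ch - 1L)] <<- v
        }
        put("NumPeaks", num_peaks(x))
        put("CurveLength", curve_length(x))
        if (any(c("PeakAmp", "PeakLat") %in% kinds)) {
          pk <- peak_amp_lat(x, rate)
          put("PeakAmp", pk["amp"]); put("PeakLat", pk["lat_s"])
        }
        if (any(c("Mean", "Var", "Skew", "Kurtosis") %in% kinds)) {
          mo <- sample_moments(x)
          put("Mean", mo["mean"]); put("Var", mo["variance"])
          put("Skew", mo["skewness"]); put("Kurtosis", mo["kurtosis"])
        }
        put("LZC", lzc(x))
        if ("MutualInfo" %in% kinds) {
          others <- which(mask & seq_len(nc) != ch)
          ref <- if (length(others)) colMeans(matrix(sdat[others, ], ncol = ncol(sdat))) else x
          put("MutualInfo", mutual_info(x, ref))
        }
        if (any(c("WaveletMean", "WaveletVar", "WaveletKurtosis") %in% kinds)) {
          ws <- wavelet_stats(x)
          put("WaveletMean", ws["WaveletMean"])
          put("WaveletVar", ws["WaveletVar"])
          put("WaveletKurtosis", ws["WaveletKurtosis"])
        }
      }
    }
    vals
  })
  fmat <- do.call(rbind, rows)
  dplyr::bind_cols(epochs$meta, tibble::as_tibble(fmat))
}

#' Metadata column names of a feature table
#' @export
feature_meta_cols <- function() c("participant_id", "trial_id", "task", "label")

#' Standardize a feature table on training rows
#'
#' Z-scores every feature column using mean and SD estimated on the
#' training rows only; the identical transform is applied to held-out
#' rows, so no test-set information enters the scaling. Missing values
#' (masked channels) are imputed with the training mean before scaling.
#' Columns with zero training SD are flagged degenerate and emitted as 0.
#'
#' @param table A feature table from [extract_features()].
#' @param train Integer indices (or logical vector) of training rows.
#' @return List with `table` (standardized tibble) and `standardizer`
#'   (tibble: `column`, `mean`, `sd`, `degenerate`).
#' @export
standardize_features <- function(table, train) {
  if (is.logical(train)) train <- which(train)
  if (!length(train)) abort("training rows must be nonempty")
  meta <- intersect(feature_meta_cols(), names(table))
  fcols <- setdiff(names(table), meta)
  out <- table
  std <- lapply(fcols, function(col) {
    v <- table[[col]]
    mu <- mean(v[train], na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    v[is.na(v)] <- mu
    sdv <- stats::sd(v[train])
    degenerate <- !is.finite(sdv) || sdv == 0
    out[[col]] <<- if (degenerate) rep(0, length(v)) else (v - mu) / sdv
    tibble::tibble(column = col, mean = mu, sd = if (degenerate) 0 else sdv,
                   degenerate = degenerate)
  })
  list(table = out, standardizer = dplyr::bind_rows(std))
}

#' Write / read a feature table CSV
#'
#' One row per epoch; leading metadata columns `participant_id`,
#' `trial_id`, `task`, `label`, then feature columns named by the
#' `<Feature>_<Species>_<Channel>` grammar.
#'
#' @param table Feature table tibble.
#' @param path CSV path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the tibble.
#' @export
write_features <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(paste0("feature table not found: ", path))
  tibble::as_tibble(data.table::fread(path,
    colClasses = list(character = c("participant_id", "task", "label"))))
}
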