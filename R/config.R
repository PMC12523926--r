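#' Optode montage configuration
#'
#' Describes the acquisition geometry and optical constants needed to map
#' optical-density changes to hemoglobin-concentration changes and back.
#' Defaults mirror a continuous-wave prefrontal montage: dual-wavelength
#' acquisition at 730 and 850 nm sampled at 10 Hz, with source-detector
#' separations cycling through 3.0, 3.5 and 4.0 cm across channels placed
#' around FP1/FP2.
#'
#' The extinction matrix holds molar extinction coefficients of oxygenated
#' (HbO) and deoxygenated (HbR) hemoglobin in cm^-1 mM^-1, one row per
#' wavelength. The default values are taken from the compiled hemoglobin
#' absorption tables of S. Prahl (Oregon Medical Laser Center); published
#' tables differ by a few percent, so downstream correctness is asserted via
#' the forward/inverse round trip rather than against absolute values.
#'
#' @param n_channels Number of measurement channels.
#' @param wavelengths Two acquisition wavelengths in nm.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the band-pass
#'   upper edge used downstream.
#' @param separations Source-detector distance per channel in cm; recycled
#'   over the default set `c(3.0, 3.5, 4.0)` when left `NULL`.
#' @param dpf Differential pathlength factor per wavelength (dimensionless).
#' @param extinction 2x2 matrix of extinction coefficients, rows =
#'   wavelengths, columns = `c("HbO", "HbR")`, in cm^-1 mM^-1.
#'
#' @return An object of class `olf_montage`.
#' @export
#' @examples
#' montage_config()
montage_config <- function(n_channels = 8,
                           wavelengths = c(730, 850),
                           sampling_rate = 10,
                           separations = NULL,
                           dpf = c(6.2, 5.8),
                           extinction = NULL) {
  if (length(wavelengths) != 2) {
    abort("exactly two acquisition wavelengths are required")
  }
  if (sampling_rate <= 2 * 0.20) {
    abort("sampling_rate must exceed twice the 0.20 Hz passband upper edge")
  }
  if (n_channels < 1) abort("n_channels must be a positive integer")
  separations <- separations %||%
    rep_len(c(3.0, 3.5, 4.0), n_channels)
  if (length(separations) != n_channels) {
    abort("one source-detector separation per channel is required")
  }
  if (any(separations <= 0)) abort("separations must be positive")
  if (length(dpf) != 2 || any(dpf <= 0)) {
    abort("dpf must hold one positive factor per wavelength")
  }
  if (is.null(extinction)) {
    # Prahl compilation, cm^-1 mM^-1: rows 730 / 850 nm, cols HbO / HbR
    extinction <- matrix(c(0.390, 1.1022, 1.058, 0.6913),
      nrow = 2, byrow = TRUE,
      dimnames = list(paste0(wavelengths, "nm"), c("HbO", "HbR"))
    )
  }
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)) || abs(det(extinction)) < 1e-12) {
    abort("extinction must be an invertible 2x2 matrix")
  }
  structure(
    list(
      n_channels = as.integer(n_channels),
      wavelengths = as.numeric(wavelengths),
      sampling_rate = as.numeric(sampling_rate),
      separations = as.numeric(separations),
      dpf = as.numeric(dpf),
      extinction = extinction
    ),
    class = "olf_montage"
  )
}

#' @export
print.olf_montage <- function(x, ...) {
  cat(
    "<olf_montage> ", x$n_channels, " channels, ",
    paste(x$wavelengths, collapse = "/"), " nm @ ", x$sampling_rate,
    " Hz, separations ", paste(unique(x$separations), collapse = "/"),
    " cm\n",
    sep = ""
  )
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the preprocessing, feature,
#' modelling and evaluation stages in one flat object. Defaults follow the
#' analysis contract: a 0.01--0.20 Hz zero-phase band-pass, a
#' (-5 s, +30 s) epoch window baselined on (-5, 0) s, participant-grouped
#' 10-fold cross-validation repeated 5 times with inner 5-fold tuning, and
#' 2000-replicate grouped bootstrap confidence intervals.
#'
#' @param montage An [montage_config()] object.
#' @param filter_band Band-pass edges in Hz, `c(low, high)`.
#' @param epoch_window Epoch extent in seconds, `c(pre, post)`; the window
#'   spans `[-pre, +post]` around stimulus onset and the pre-stimulus part
#'   is the baseline interval.
#' @param qc Quality-control thresholds, see [qc_criteria()].
#' @param features Character vector of enabled feature kinds; defaults to
#'   the full battery, see [feature_kinds()].
#' @param model Model kind for tabular tasks, see [model_spec()].
#' @param grid Optional hyperparameter grid overriding the model default.
#' @param outer_k,repeats,inner_k Cross-validation layout: outer folds,
#'   outer repeats, inner tuning folds.
#' @param tune Logical; run inner-CV hyperparameter selection. Disable to
#'   fit the first grid row directly (useful for fast smoke analyses).
#' @param bootstrap_reps Grouped bootstrap replicates for 95% CIs.
#' @param seed Base seed; every stage derives its own stream from it.
#' @param cnn Named list of attention-CNN options merged over
#'   [cnn_defaults()].
#'
#' @return An object of class `olf_config` (a named list).
#' @export
pipeline_config <- function(montage = montage_config(),
                            filter_band = c(0.01, 0.20),
                            epoch_window = c(5, 30),
                            qc = qc_criteria(),
                            features = feature_kinds(),
                            model = "gradient_boosted_trees",
                            grid = NULL,
                            outer_k = 10,
                            repeats = 5,
                            inner_k = 5,
                            tune = TRUE,
                            bootstrap_reps = 2000,
                            seed = 2024L,
                            cnn = list()) {
  stopifnot(length(filter_band) == 2, filter_band[1] > 0,
            filter_band[2] > filter_band[1])
  if (montage$sampling_rate <= 2 * filter_band[2]) {
    abort("sampling rate must exceed twice the band-pass upper edge")
  }
  stopifnot(length(epoch_window) == 2, epoch_window[1] >= 0,
            epoch_window[2] > 0)
  structure(
    list(
      montage = montage,
      filter_band = as.numeric(filter_band),
      epoch_window = as.numeric(epoch_window),
      qc = qc,
      features = features,
      model = model,
      grid = grid,
      outer_k = as.integer(outer_k),
      repeats = as.integer(repeats),
      inner_k = as.integer(inner_k),
      tune = isTRUE(tune),
      bootstrap_reps = as.integer(bootstrap_reps),
      seed = as.integer(seed),
      cnn = utils::modifyList(cnn_defaults(), cnn)
    ),
    class = "olf_config"
  )
}

#' Channel quality-control criteria
#'
#' @param spike_sd Threshold on absolute first differences, in multiples of
#'   the robust SD (1.4826 x MAD) of the first differences.
#' @param max_spikes Maximum tolerated count of threshold crossings.
#' @param min_snr_db Minimum signal-to-noise ratio in dB: power in the
#'   0.01--0.20 Hz hemodynamic band over power in the 1.5--5 Hz band.
#' @param max_missing Maximum tolerated fraction of non-finite samples.
#'
#' @return A named list of class `olf_qc`.
#' @export
qc_criteria <- function(spike_sd = 5, max_spikes = 5, min_snr_db = 0,
                        max_missing = 0.10) {
  stopifnot(spike_sd > 0, max_spikes > 0, max_missing > 0)
  structure(
    list(spike_sd = spike_sd, max_spikes = max_spikes,
         min_snr_db = min_snr_db, max_missing = max_missing),
    class = "olf_qc"
  )
}

#' Hash of a configuration object
#'
#' A short stable hash over the deparsed configuration, logged with every
#' pipeline run so any fold can be replayed.
#'
#' @param config An `olf_config` object (or any R object).
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  digest_chr(paste(deparse(config), collapse = "\n"))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds a flat dotted-key namespace (for example
#' `montage.n_channels: 8`, `cv.outer_k: 10`); values present in the file
#' override [pipeline_config()] defaults, and `overrides` (typically parsed
#' from command-line flags) override the file.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of dotted keys overriding the file.
#' @return An `olf_config` object.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    vals <- yaml::read_yaml(path) %||% list()
  }
  vals <- flatten_keys(vals)
  vals[names(overrides)] <- overrides
  get_num <- function(key, default) as.numeric(vals[[key]] %||% default)
  montage <- montage_config(
    n_channels = get_num("montage.n_channels", 8),
    wavelengths = as.numeric(vals[["montage.wavelengths"]] %||% c(730, 850)),
    sampling_rate = get_num("montage.sampling_rate", 10),
    separations = if (!is.null(vals[["montage.separations"]])) {
      as.numeric(vals[["montage.separations"]])
    }
  )
  pipeline_config(
    montage = montage,
    filter_band = as.numeric(vals[["filter.band"]] %||% c(0.01, 0.20)),
    epoch_window = as.numeric(vals[["epoch.window"]] %||% c(5, 30)),
    qc = qc_criteria(
      spike_sd = get_num("qc.spike_sd", 5),
      max_spikes = get_num("qc.max_spikes", 5),
      min_snr_db = get_num("qc.min_snr_db", 0),
      max_missing = get_num("qc.max_missing", 0.10)
    ),
    model = as.character(vals[["model.kind"]] %||% "gradient_boosted_trees"),
    outer_k = get_num("cv.outer_k", 10),
    repeats = get_num("cv.repeats", 5),
    inner_k = get_num("cv.inner_k", 5),
    tune = as.logical(vals[["cv.tune"]] %||% TRUE),
    bootstrap_reps = get_num("bootstrap.reps", 2000),
    seed = as.integer(get_num("seed", 2024))
  )
}

# flatten nested yaml lists into dotted keys; leaves vectors intact
flatten_keys <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- paste(c(prefix, nm), collapse = ".")
    val <- x[[nm]]
    if (is.list(val) && !is.null(names(val))) {
      out <- c(out, flatten_keys(val, key))
    } else {
      out[[key]] <- val
    }
  }
  out
}
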