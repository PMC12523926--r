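#' Construct a raw fNIRS session
#'
#' A session bundles one participant's two-wavelength optical-density
#' recording with its stimulus event markers and, for synthetic sessions,
#' the ground-truth record used by recovery tests.
#'
#' @param participant_id Opaque participant identifier.
#' @param od Numeric array `channel x wavelength x time` of optical-density
#'   changes (dimensionless).
#' @param events Tibble of event markers with columns
#'   `onset_s` (seconds from recording start), `task` (one of `threshold`,
#'   `discrimination`, `identification`), `trial_id` (unique integer) and
#'   `label` (`correct`, `incorrect` or `unknown`).
#' @param montage The [montage_config()] the recording was acquired with.
#' @param truth Optional ground-truth list for synthetic sessions:
#'   `trials` (per-trial latent amplitudes) and `artifacts` (injected
#'   artifact log).
#'
#' @return An object of class `olf_session`.
#' @export
raw_session <- function(participant_id, od, events, montage, truth = NULL) {
  events <- tibble::as_tibble(events)
  session <- structure(
    list(
      participant_id = as.character(participant_id),
      od = od,
      events = events,
      montage = montage,
      truth = truth
    ),
    class = "olf_session"
  )
  validate_session(session)
}

validate_session <- function(session) {
  od <- session$od
  if (!is.array(od) || length(dim(od)) != 3) {
    abort("od must be a channel x wavelength x time array")
  }
  if (dim(od)[1] != session$montage$n_channels || dim(od)[2] != 2) {
    abort("od dimensions disagree with the montage")
  }
  ev <- session$events
  required <- c("onset_s", "task", "trial_id", "label")
  if (!all(required %in% names(ev))) {
    abort("events must have columns onset_s, task, trial_id, label")
  }
  if (nrow(ev)) {
    span <- dim(od)[3] / session$montage$sampling_rate
    bad <- which(ev$onset_s < 0 | ev$onset_s > span)
    if (length(bad)) {
      abort(sprintf(
        "event marker for trial %s has onset %.2f s outside the recording span [0, %.2f]",
        ev$trial_id[bad[1]], ev$onset_s[bad[1]], span
      ))
    }
    if (is.unsorted(ev$onset_s, strictly = TRUE)) {
      abort("event onsets must be strictly increasing")
    }
    if (anyDuplicated(ev$trial_id)) {
      abort("trial_id must be unique within a session")
    }
    if (!all(ev$task %in% c("threshold", "discrimination", "identification"))) {
      abort("task must be threshold, discrimination or identification")
    }
    if (!all(ev$label %in% c("correct", "incorrect", "unknown"))) {
      abort("label must be correct, incorrect or unknown")
    }
  }
  session
}

#' @export
print.olf_session <- function(x, ...) {
  d <- dim(x$od)
  cat(
    "<olf_session> participant ", x$participant_id, ": ",
    d[1], " channels x ", d[3], " samples (",
    round(d[3] / x$montage$sampling_rate, 1), " s), ",
    nrow(x$events), " events",
    if (!is.null(x$truth)) ", with ground truth" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a session to disk
#'
#' Sessions are stored as a plain-text directory mirroring SNIRF concepts:
#' one optical-density CSV per wavelength (`od_<nm>nm.csv`, columns =
#' channels, rows = samples), `events.csv` (the stim table), `meta.json`
#' (participant and montage metadata) and, when present, ground-truth
#' tables `truth_trials.csv` / `truth_artifacts.csv`. Numeric payloads are
#' written with shortest round-trip precision, so `read_session()` restores
#' them bit-exactly.
#'
#' @param session An `olf_session`.
#' @param path Directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  overwrote <- dir.exists(path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(paste0("cannot create session directory: ", path))
  m <- session$montage
  meta <- list(
    format = "olfnirs-session/1",
    participant_id = session$participant_id,
    n_samples = dim(session$od)[3],
    montage = list(
      n_channels = m$n_channels,
      wavelengths = m$wavelengths,
      sampling_rate = m$sampling_rate,
      separations = m$separations,
      dpf = m$dpf,
      extinction = as.vector(m$extinction)
    )
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (w in 1:2) {
    mat <- t(session$od[, w, , drop = TRUE])
    dim(mat) <- c(dim(session$od)[3], m$n_channels)
    # %.17g guarantees bit-exact double round-trip through text
    chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
    dt <- data.table::as.data.table(chr)
    data.table::setnames(dt, paste0("ch", seq_len(m$n_channels) - 1L))
    data.table::fwrite(dt, file.path(path, sprintf("od_%dnm.csv", round(m$wavelengths[w]))),
                       quote = FALSE)
  }
  ev <- session$events
  ev$onset_s <- sprintf("%.17g", ev$onset_s)
  data.table::fwrite(ev, file.path(path, "events.csv"))
  if (!is.null(session$truth)) {
    data.table::fwrite(session$truth$trials, file.path(path, "truth_trials.csv"))
    data.table::fwrite(session$truth$artifacts, file.path(path, "truth_artifacts.csv"))
  }
  if (overwrote) inform(paste0("overwrote existing session at ", path))
  invisible(path)
}

#' Read a session from disk
#'
#' @param path A session directory written by [write_session()].
#' @return An `olf_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) abort(paste0("session directory not found: ", path))
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) abort(paste0("corrupt session: missing meta.json in ", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mm <- meta$montage
  montage <- montage_config(
    n_channels = mm$n_channels,
    wavelengths = mm$wavelengths,
    sampling_rate = mm$sampling_rate,
    separations = mm$separations,
    dpf = mm$dpf,
    extinction = matrix(mm$extinction, nrow = 2,
                        dimnames = list(paste0(round(mm$wavelengths), "nm"),
                                        c("HbO", "HbR")))
  )
  n_t <- meta$n_samples
  od <- array(NA_real_, c(montage$n_channels, 2, n_t))
  for (w in 1:2) {
    f <- file.path(path, sprintf("od_%dnm.csv", round(montage$wavelengths[w])))
    if (!file.exists(f)) abort(paste0("corrupt session: missing ", f))
    mat <- as.matrix(data.table::fread(f))
    od[, w, ] <- t(mat)
  }
  events <- tibble::as_tibble(data.table::fread(file.path(path, "events.csv"),
                                                colClasses = list(character = c("task", "label"))))
  if (nrow(events) == 0) {
    events <- tibble::tibble(onset_s = numeric(), task = character(),
                             trial_id = integer(), label = character())
  }
  truth <- NULL
  tt <- file.path(path, "truth_trials.csv")
  if (file.exists(tt)) {
    truth <- list(
      trials = tibble::as_tibble(data.table::fread(tt)),
      artifacts = tibble::as_tibble(data.table::fread(file.path(path, "truth_artifacts.csv")))
    )
  }
  raw_session(meta$participant_id, od, events, montage, truth)
}
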