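#' Simulation configuration
#'
#' Defines the generative model for synthetic cohorts: a block-design odor
#' session per participant whose hemodynamic response amplitude (and, for
#' incorrect trials, additional band-limited signal complexity) depends on
#' the behavioral label, superimposed on cardiac, respiratory, Mayer-wave,
#' drift and white physiological noise, plus motion artifacts.
#'
#' Setting `effect_amp = 0` and `effect_complexity = 0` gives the null
#' model: labels carry no signal and any downstream decoding above chance
#' indicates leakage.
#'
#' Noise amplitudes default to a single-trial peak signal-to-noise ratio of
#' about 1 (peak evoked response of `hrf_amplitude` microM against a raw
#' per-channel noise SD of about 0.9 microM), typical of prefrontal
#' continuous-wave recordings.
#'
#' @param n_participants Cohort size.
#' @param trials_per_task Named counts of trials per task.
#' @param p_correct Named per-task probability that a trial is correct.
#' @param hrf_amplitude Peak evoked HbO change for a neutral trial, microM.
#' @param effect_amp Signed fractional amplitude difference: correct trials
#'   get `hrf_amplitude * (1 + effect_amp)`, incorrect
#'   `hrf_amplitude * (1 - effect_amp)`.
#' @param effect_complexity SD (microM) of extra 0.01-0.20 Hz band-limited
#'   noise added during incorrect-trial epochs.
#' @param noise Named amplitudes (microM) and frequencies (Hz) of the
#'   physiological noise components.
#' @param artifact Motion-artifact parameters: spike and baseline-shift
#'   rates (events per minute) and amplitudes (multiples of series SD).
#' @param isi_s Inter-stimulus-interval range in seconds (uniform).
#' @param hbr_ratio ΔHbR is generated as `-hbr_ratio * ΔHbO` plus its own
#'   noise, reflecting the typical measured anticorrelation.
#' @param seed Base seed for the cohort.
#'
#' @return A list of class `olf_sim_config`.
#' @export
sim_config <- function(n_participants = 100,
                       trials_per_task = c(threshold = 16, discrimination = 24,
                                           identification = 12),
                       p_correct = c(threshold = 0.5, discrimination = 0.55,
                                     identification = 0.7),
                       hrf_amplitude = 1.0,
                       effect_amp = 0.3,
                       effect_complexity = 0.2,
                       noise = list(cardiac_amp = 0.25, cardiac_hz = 1.2,
                                    resp_amp = 0.18, resp_hz = 0.3,
                                    mayer_amp = 0.25, mayer_hz = 0.1,
                                    drift_amp = 0.7, white_sd = 0.35),
                       artifact = list(spike_rate = 0.3, spike_amp = 8,
                                       shift_rate = 0.05, shift_amp = 3),
                       isi_s = c(25, 35),
                       hbr_ratio = 1 / 3,
                       seed = 1L) {
  stopifnot(
    n_participants >= 1,
    all(p_correct >= 0 & p_correct <= 1),
    hrf_amplitude >= 0, effect_complexity >= 0,
    all(unlist(noise) >= 0), all(unlist(artifact) >= 0),
    length(isi_s) == 2, isi_s[1] > 0, isi_s[2] >= isi_s[1]
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_task = trials_per_task,
      p_correct = p_correct,
      hrf_amplitude = hrf_amplitude,
      effect_amp = effect_amp,
      effect_complexity = effect_complexity,
      noise = noise,
      artifact = artifact,
      isi_s = as.numeric(isi_s),
      hbr_ratio = hbr_ratio,
      seed = as.integer(seed)
    ),
    class = "olf_sim_config"
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, rescaled to a unit peak: a positive
#' lobe peaking at `peak_s` and a late undershoot peaking at
#' `undershoot_s` with relative amplitude `ratio`.
#'
#' @param t Time in seconds since stimulus onset (`t >= 0`).
#' @param peak_s Time-to-peak of the positive lobe (default 6 s).
#' @param undershoot_s Time-to-peak of the undershoot (default 16 s).
#' @param ratio Undershoot-to-peak amplitude ratio (default 1/6).
#' @return Unitless response values with maximum 1 and `hrf(0) = 0`.
#' @export
#' @examples
#' hrf(seq(0, 30, by = 0.1))
hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  if (peak_s <= 0 || undershoot_s <= 0 || ratio < 0) {
    abort("hrf shape parameters must be positive")
  }
  stopifnot(all(t >= 0))
  # gamma densities with unit rate peak at shape - 1
  f <- function(tt) {
    stats::dgamma(tt, shape = peak_s + 1, rate = 1) -
      ratio * stats::dgamma(tt, shape = undershoot_s + 1, rate = 1)
  }
  peak_val <- f(stats::optimize(f, c(0, undershoot_s), maximum = TRUE,
                                tol = 1e-10)$maximum)
  f(t) / peak_val
}

#' Simulate hemoglobin time series for one session
#'
#' Builds per-channel oxy- and deoxyhemoglobin series: a sum of
#' label-scaled HRFs at the event onsets, physiological noise (independent
#' phases and noise per channel), and extra band-limited "complexity"
#' signal during incorrect-trial epochs.
#'
#' @param events Event tibble (`onset_s`, `task`, `trial_id`, `label`).
#' @param n_samples Recording length in samples.
#' @param config An [sim_config()].
#' @param montage An [montage_config()].
#' @param seed Integer seed for the noise streams.
#' @return List with `hbo`, `hbr` (channel x time matrices, microM) and
#'   `trials` (per-trial latent amplitude record).
#' @export
simulate_hemo <- function(events, n_samples, config, montage, seed = config$seed) {
  rate <- montage$sampling_rate
  if (nrow(events) > 1 && any(diff(events$onset_s) < config$isi_s[1] - 1e-9)) {
    abort("event spacing below the configured inter-stimulus interval")
  }
  t <- (seq_len(n_samples) - 1) / rate
  nc <- montage$n_channels
  amp <- ifelse(events$label == "correct",
                config$hrf_amplitude * (1 + config$effect_amp),
                config$hrf_amplitude * (1 - config$effect_amp))
  # shared evoked signal (all channels see the same cortical response)
  evoked <- numeric(n_samples)
  complexity <- numeric(n_samples)
  set.seed(seed)
  for (i in seq_len(nrow(events))) {
    rel <- t - events$onset_s[i]
    idx <- which(rel >= 0 & rel <= 32)
    evoked[idx] <- evoked[idx] + amp[i] * hrf(rel[idx])
    if (events$label[i] == "incorrect" && config$effect_complexity > 0) {
      complexity[idx] <- complexity[idx] +
        band_limited_noise(length(idx), rate, config$effect_complexity)
    }
  }
  ns <- config$noise
  hbo <- matrix(0, nc, n_samples)
  hbr <- matrix(0, nc, n_samples)
  for (ch in seq_len(nc)) {
    noise_o <- physio_noise(t, rate, ns)
    noise_r <- physio_noise(t, rate, ns) * config$hbr_ratio
    hbo[ch, ] <- evoked + complexity + noise_o
    hbr[ch, ] <- -config$hbr_ratio * (evoked + complexity) + noise_r
  }
  trials <- tibble::tibble(
    trial_id = events$trial_id, task = events$task, label = events$label,
    amplitude = amp
  )
  list(hbo = hbo, hbr = hbr, trials = trials)
}

# one channel's physiological noise: oscillations with random phase,
# 1/f-like drift (smoothed random walk) and white noise
physio_noise <- function(t, rate, ns) {
  n <- length(t)
  osc <- ns$cardiac_amp * sin(2 * pi * ns$cardiac_hz * t + runif(1, 0, 2 * pi)) +
    ns$resp_amp * sin(2 * pi * ns$resp_hz * t + runif(1, 0, 2 * pi)) +
    ns$mayer_amp * sin(2 * pi * ns$mayer_hz * t + runif(1, 0, 2 * pi))
  drift <- cumsum(rnorm(n)) / sqrt(n)
  drift <- drift - mean(drift)
  drift <- drift / max(stats::sd(drift), 1e-12) * ns$drift_amp
  osc + drift + rnorm(n, sd = ns$white_sd)
}

# white noise band-passed to 0.01-0.20 Hz and rescaled to the target SD
band_limited_noise <- function(n, rate, sd_target) {
  if (n < 24) return(rnorm(n, sd = sd_target))
  x <- rnorm(n + 200)
  bp <- signal::butter(2, c(0.01, 0.20) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bp, x)[101:(100 + n)]
  y / max(stats::sd(y), 1e-12) * sd_target
}

#' Forward optical model (modified Beer-Lambert law)
#'
#' Maps hemoglobin-concentration changes to optical-density changes:
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR) * d * DPF(lambda)`
#' with concentrations in mM (inputs are microM and scaled internally),
#' path length `d` in cm and the wavelength-specific differential
#' pathlength factor. This is the exact inverse direction of
#' [mbll_invert()].
#'
#' @param hbo,hbr Channel x time matrices of concentration changes (microM).
#' @param montage An [montage_config()].
#' @return Array `channel x wavelength x time` of optical-density changes.
#' @export
forward_model <- function(hbo, hbr, montage) {
  hbo <- rbind(hbo); hbr <- rbind(hbr)
  if (!all(dim(hbo) == dim(hbr))) abort("hbo and hbr lengths must match")
  if (abs(det(montage$extinction)) < 1e-12) abort("extinction matrix is singular")
  nc <- nrow(hbo); nt <- ncol(hbo)
  od <- array(0, c(nc, 2, nt))
  # concentrations arrive in microM; MBLL works in mM, hence the /1000
  for (w in 1:2) {
    eps <- montage$extinction[w, ]
    pl <- montage$separations * montage$dpf[w] # per-channel path, cm
    od[, w, ] <- (eps["HbO"] * hbo + eps["HbR"] * hbr) / 1000 * pl
  }
  od
}

#' Inject motion artifacts into a time-series matrix
#'
#' Adds one-sample spike excursions (Poisson-timed, alternating sign) and
#' step baseline shifts persisting to the end of the record. Amplitudes are
#' expressed in multiples of each series' SD so the same settings scale
#' across signal units; every injection is logged.
#'
#' @param x Channel x time matrix (or a single series).
#' @param artifact List with `spike_rate`, `spike_amp`, `shift_rate`,
#'   `shift_amp` (rates per minute, amplitudes in SD multiples).
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @return List `x` (modified matrix) and `log` (tibble of injections:
#'   `channel`, `kind`, `time_s`, `amplitude`).
#' @export
inject_artifacts <- function(x, artifact, rate, seed = 1L) {
  x <- rbind(x)
  stopifnot(all(unlist(artifact) >= 0))
  set.seed(seed)
  minutes <- ncol(x) / rate / 60
  logs <- list()
  for (ch in seq_len(nrow(x))) {
    s <- stats::sd(x[ch, ])
    if (s == 0) s <- 1
    n_spike <- rpois(1, artifact$spike_rate * minutes)
    if (n_spike > 0) {
      at <- sample(seq_len(ncol(x)), n_spike)
      sign <- sample(c(-1, 1), n_spike, replace = TRUE)
      a <- sign * artifact$spike_amp * s
      x[ch, at] <- x[ch, at] + a
      logs[[length(logs) + 1]] <- tibble::tibble(
        channel = ch - 1L, kind = "spike", time_s = (at - 1) / rate, amplitude = a
      )
    }
    n_shift <- rpois(1, artifact$shift_rate * minutes)
    if (n_shift > 0) {
      at <- sample(seq_len(ncol(x)), n_shift)
      sign <- sample(c(-1, 1), n_shift, replace = TRUE)
      a <- sign * artifact$shift_amp * s
      for (j in seq_len(n_shift)) {
        x[ch, at[j]:ncol(x)] <- x[ch, at[j]:ncol(x)] + a[j]
      }
      logs[[length(logs) + 1]] <- tibble::tibble(
        channel = ch - 1L, kind = "shift", time_s = (at - 1) / rate, amplitude = a
      )
    }
  }
  log <- if (length(logs)) dplyr::bind_rows(logs) else {
    tibble::tibble(channel = integer(), kind = character(),
                   time_s = numeric(), amplitude = numeric())
  }
  list(x = x, log = log)
}

#' Simulate a cohort of sessions
#'
#' Generates `n_participants` block-design sessions: for each participant,
#' per-task trials are scheduled sequentially with uniform
#' inter-stimulus intervals, labels are drawn by the per-task `p_correct`,
#' hemoglobin dynamics are synthesized by [simulate_hemo()], converted to
#' optical density by [forward_model()] and contaminated by
#' [inject_artifacts()]. Fully reproducible from the config seed.
#'
#' @param config An [sim_config()].
#' @param montage An [montage_config()].
#' @return List of [raw_session()] objects with ground truth attached.
#' @export
simulate_cohort <- function(config, montage = montage_config()) {
  lapply(seq_len(config$n_participants), function(p) {
    simulate_session(sprintf("P%03d", p), config, montage,
                     seed = derive_seed(config$seed, "session", p))
  })
}

#' @rdname simulate_cohort
#' @param participant_id Identifier for the generated session.
#' @param seed Session-level seed.
#' @export
simulate_session <- function(participant_id, config, montage = montage_config(),
                             seed = config$seed) {
  rate <- montage$sampling_rate
  set.seed(seed)
  tasks <- rep(names(config$trials_per_task), config$trials_per_task)
  n_ev <- length(tasks)
  isi <- runif(n_ev, config$isi_s[1], config$isi_s[2])
  onsets <- 30 + cumsum(isi) - isi[1]
  labels <- ifelse(
    rbinom(n_ev, 1, config$p_correct[tasks]) == 1, "correct", "incorrect"
  )
  events <- tibble::tibble(
    onset_s = onsets, task = tasks,
    trial_id = seq_len(n_ev), label = labels
  )
  n_samples <- ceiling((max(onsets) + 40) * rate)
  hemo <- simulate_hemo(events, n_samples, config, montage,
                        seed = derive_seed(seed, "hemo"))
  od <- forward_model(hemo$hbo, hemo$hbr, montage)
  # motion artifacts act on the optics: same injection on both wavelengths
  art <- inject_artifacts(od[, 1, ], config$artifact, rate,
                          seed = derive_seed(seed, "artifact"))
  scale2 <- apply(od[, 2, ], 1, stats::sd) / pmax(apply(od[, 1, ], 1, stats::sd), 1e-15)
  od[, 1, ] <- art$x
  for (i in seq_len(nrow(art$log))) {
    ch <- art$log$channel[i] + 1L
    at <- onset_index(art$log$time_s[i], rate)
    a2 <- art$log$amplitude[i] * scale2[ch]
    if (art$log$kind[i] == "spike") {
      od[ch, 2, at] <- od[ch, 2, at] + a2
    } else {
      od[ch, 2, at:dim(od)[3]] <- od[ch, 2, at:dim(od)[3]] + a2
    }
  }
  raw_session(
    participant_id, od, events, montage,
    truth = list(trials = hemo$trials, artifacts = art$log)
  )
}
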