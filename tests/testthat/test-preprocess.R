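test_that("MBLL inversion is the exact inverse of the forward model", {
  m <- montage_config()
  set.seed(8)
  hbo <- matrix(rnorm(8 * 300), 8)
  hbr <- matrix(rnorm(8 * 300), 8)
  rec <- mbll_invert(forward_model(hbo, hbr, m), m)
  expect_lt(max(abs(rec$hbo - hbo)) / max(abs(hbo)), 1e-9)
  expect_lt(max(abs(rec$hbr - hbr)) / max(abs(hbr)), 1e-9)
  # zero in, zero out; linear scaling
  z <- mbll_invert(array(0, c(8, 2, 10)), m)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  od <- forward_model(hbo, hbr, m)
  rec2 <- mbll_invert(od * 2, m)
  expect_equal(rec2$hbo, rec$hbo * 2, tolerance = 1e-9)
  bad <- montage_config()
  bad$extinction <- matrix(1, 2, 2)
  expect_error(mbll_invert(od, bad), "singular")
})

test_that("channel screening flags spikes, poor SNR and missing data", {
  rate <- 10
  n <- 3000
  set.seed(3)
  t <- (1:n) / rate
  clean <- sin(2 * pi * 0.05 * t) + rnorm(n, sd = 0.05)
  spiky <- clean
  spike_at <- seq(100, 2900, length.out = 20)
  spiky[spike_at] <- spiky[spike_at] + 10 * sd(clean)
  hf_only <- sin(2 * pi * 2 * t) + rnorm(n, sd = 0.001)
  missing <- clean
  missing[1:400] <- NA
  h <- hemo_series(rbind(clean, spiky, hf_only, missing),
                   matrix(0, 4, n), rate)
  qc <- screen_channels(h, qc_criteria(max_spikes = 5))
  expect_equal(qc$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$reason, c("", "spikes", "snr", "missing"))
  # everything bad is an explicit error
  h2 <- hemo_series(rbind(hf_only, hf_only), matrix(0, 2, n), rate)
  expect_error(screen_channels(h2), "no usable channels")
})

test_that("band-pass is zero-phase, blocks DC, passes and stops as specified", {
  rate <- 10
  t <- seq(0, 600, by = 1 / rate)
  expect_lt(max(abs(bandpass(rep(5, length(t)), rate))), 1e-6)
  amp_of <- function(y, f) {
    c2 <- cos(2 * pi * f * t); s2 <- sin(2 * pi * f * t)
    sqrt(sum(coef(lm(y ~ c2 + s2))[2:3]^2))
  }
  hi <- bandpass(sin(2 * pi * 1.2 * t), rate)
  expect_lt(20 * log10(amp_of(hi, 1.2)), -20)
  pass <- bandpass(sin(2 * pi * 0.05 * t), rate)
  expect_lt(abs(amp_of(pass, 0.05) - 1), 0.1)
  # zero phase: peak of a slow sinusoid does not shift
  slow <- sin(2 * pi * 0.05 * t)
  filt <- bandpass(slow, rate)
  mid <- 2000:4000
  expect_lt(abs(which.max(filt[mid]) - which.max(slow[mid])), 3)
  expect_error(bandpass(slow, rate, band = c(0.01, 6)), "band edges")
  # matrix input preserves the HbT = HbO + HbR identity (linearity)
  set.seed(4)
  a <- matrix(rnorm(2 * 500), 2)
  b <- matrix(rnorm(2 * 500), 2)
  expect_equal(bandpass(a + b, rate), bandpass(a, rate) + bandpass(b, rate),
               tolerance = 1e-10)
})

test_that("motion correction removes spikes and re-levels steps", {
  rate <- 10
  set.seed(9)
  x <- sin(2 * pi * 0.05 * (1:3000) / rate) + rnorm(3000, sd = 0.1)
  # clean series: essentially unchanged
  expect_equal(correct_motion(x, rate), x, tolerance = 1e-8)
  rs <- 1.4826 * mad(diff(x))
  xs <- x
  xs[1500] <- xs[1500] + 30 * rs
  fixed <- correct_motion(xs, rate)
  expect_lt(max(abs(diff(fixed))), 3 * rs)
  # +5 uM step: post-correction segment means agree within 0.5 uM
  xb <- x
  xb[2000:3000] <- xb[2000:3000] + 5
  fixedb <- correct_motion(xb, rate)
  expect_lt(abs(mean(fixedb[2100:3000]) - mean(fixedb[1:1900])), 0.5)
})

test_that("epoching yields exact lengths, zero baselines and truth-aligned peaks", {
  rate <- 10
  m <- montage_config(n_channels = 2)
  cfg <- sim_config(effect_amp = 0, effect_complexity = 0,
                    noise = list(cardiac_amp = 0, cardiac_hz = 1.2, resp_amp = 0,
                                 resp_hz = 0.3, mayer_amp = 0, mayer_hz = 0.1,
                                 drift_amp = 0, white_sd = 0))
  events <- tibble::tibble(onset_s = c(100, 130), task = "threshold",
                           trial_id = 1:2, label = c("correct", "incorrect"))
  h <- simulate_hemo(events, 1800, cfg, m, seed = 1)
  hs <- hemo_series(h$hbo, h$hbr, rate)
  ep <- make_epochs(hs, events, window = c(5, 30), participant_id = "P1")
  expect_length(ep$epochs, 2)
  expect_equal(dim(ep$epochs[[1]]$data), c(2, 3, 351))
  for (e in ep$epochs) {
    expect_lt(max(abs(apply(e$data[, , 1:51], c(1, 2), mean))), 1e-10)
  }
  # noiseless epoch peaks within one sample of the HRF peak parameter
  lat <- (which.max(ep$epochs[[1]]$data[1, 1, ]) - 1) / rate - 5
  expect_lt(abs(lat - 6), 0.15)
  # HbT identity inside epochs
  e1 <- ep$epochs[[1]]$data
  expect_equal(e1[, 3, ], e1[, 1, ] + e1[, 2, ], tolerance = 1e-12)
  # events at the record edge are dropped with a warning, not an error
  ev2 <- tibble::tibble(onset_s = c(2, 100), task = "threshold",
                        trial_id = 1:2, label = "correct")
  expect_warning(ep2 <- make_epochs(hs, ev2, c(5, 30)), "dropped")
  expect_length(ep2$epochs, 1)
})

test_that("the full preprocessing pipeline runs in its contracted order", {
  ep <- cached_epochs()
  expect_equal(ep$log$order,
               c("mbll_invert", "screen_channels", "bandpass",
                 "correct_motion", "make_epochs"))
  expect_equal(nrow(ep$meta), length(ep$epochs))
  expect_true(all(c("participant_id", "trial_id", "task", "label") %in%
                  names(ep$meta)))
})
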