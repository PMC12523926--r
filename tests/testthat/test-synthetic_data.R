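test_that("hrf starts at zero, peaks where asked, and integrates positively", {
  expect_equal(hrf(0), 0)
  tg <- seq(0, 40, by = 0.01)
  h <- hrf(tg)
  expect_lt(abs(tg[which.max(h)] - 6), 0.1) # within one 10 Hz sample
  expect_equal(max(h), 1, tolerance = 1e-5) # up to grid resolution
  for (pk in c(4, 5, 7)) {
    hh <- hrf(tg, peak_s = pk)
    expect_lt(abs(tg[which.max(hh)] - pk), 0.1)
  }
  expect_gt(sum(hrf(seq(0, 60, by = 0.1))) * 0.1, 0)
  expect_error(hrf(1, peak_s = -1), "positive")
  expect_error(hrf(-1), "t >= 0")
})

test_that("label effect scales trial amplitudes by (1 +/- effect_amp)", {
  m <- montage_config(n_channels = 2)
  cfg <- sim_config(
    effect_amp = 0.5, effect_complexity = 0,
    noise = list(cardiac_amp = 0, cardiac_hz = 1.2, resp_amp = 0, resp_hz = 0.3,
                 mayer_amp = 0, mayer_hz = 0.1, drift_amp = 0, white_sd = 0)
  )
  events <- tibble::tibble(
    onset_s = c(10, 50), task = "discrimination", trial_id = 1:2,
    label = c("correct", "incorrect")
  )
  h <- simulate_hemo(events, 1000, cfg, m, seed = 1)
  peak_correct <- max(h$hbo[1, 100:400])
  peak_incorrect <- max(h$hbo[1, 500:800])
  expect_equal(peak_correct / peak_incorrect, (1 + 0.5) / (1 - 0.5),
               tolerance = 1e-6)
  # null model: identical amplitudes
  cfg0 <- sim_config(effect_amp = 0, effect_complexity = 0, noise = cfg$noise)
  h0 <- simulate_hemo(events, 1000, cfg0, m, seed = 1)
  expect_equal(max(h0$hbo[1, 100:400]), max(h0$hbo[1, 500:800]),
               tolerance = 1e-9)
  # deoxy anticorrelation
  expect_equal(h$hbr[1, ], -h$hbo[1, ] / 3, tolerance = 1e-9)
})

test_that("cardiac oscillation appears at its frequency in the raw series", {
  m <- montage_config(n_channels = 1)
  cfg <- sim_config(noise = list(cardiac_amp = 1, cardiac_hz = 1.2,
                                 resp_amp = 0, resp_hz = 0.3, mayer_amp = 0,
                                 mayer_hz = 0.1, drift_amp = 0, white_sd = 0.01))
  h <- simulate_hemo(tibble::tibble(onset_s = numeric(), task = character(),
                                    trial_id = integer(), label = character()),
                     4096, cfg, m, seed = 2)
  x <- h$hbo[1, ]
  sp <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(sp) - 1) / length(sp) * 10
  half <- freqs <= 5
  expect_lt(abs(freqs[half][which.max(sp[half])] - 1.2), 0.02)
})

test_that("artifact injection matches its stated model and logs truth", {
  set.seed(1)
  x <- matrix(rnorm(2 * 6000), 2)
  # zero rates: unchanged
  z <- inject_artifacts(x, list(spike_rate = 0, spike_amp = 8,
                                shift_rate = 0, shift_amp = 3), 10, seed = 3)
  expect_identical(z$x, x)
  expect_equal(nrow(z$log), 0)
  # a 10-SD spike dominates the first differences at the logged time
  one <- inject_artifacts(x[1, , drop = FALSE],
                          list(spike_rate = 0.2, spike_amp = 10,
                               shift_rate = 0, shift_amp = 0), 10, seed = 4)
  expect_gt(nrow(one$log), 0)
  d <- abs(diff(one$x[1, ]))
  at <- round(one$log$time_s[which.max(abs(one$log$amplitude))] * 10) + 1
  expect_true(which.max(d) %in% c(at - 1, at))
  # Poisson spike count: mean over seeded runs near rate * minutes
  counts <- vapply(1:200, function(s) {
    nrow(inject_artifacts(matrix(rnorm(6000), 1),
                          list(spike_rate = 1.5, spike_amp = 8,
                               shift_rate = 0, shift_amp = 0),
                          10, seed = s)$log)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 200) + 0.5)
})

test_that("cohorts have the configured size, trial counts and label rates", {
  m <- montage_config(n_channels = 2)
  sc <- sim_config(n_participants = 6,
                   trials_per_task = c(threshold = 2, discrimination = 3,
                                       identification = 2),
                   seed = 99)
  cohort <- simulate_cohort(sc, m)
  expect_length(cohort, 6)
  expect_true(all(vapply(cohort, function(s) nrow(s$events), 1L) == 7L))
  expect_true(all(vapply(cohort, function(s) nrow(s$truth$trials), 1L) == 7L))
  # correct fraction concentrates around p_correct (binomial SE)
  sc2 <- sim_config(n_participants = 40,
                    trials_per_task = c(threshold = 0, discrimination = 24,
                                        identification = 0),
                    p_correct = c(threshold = 0.5, discrimination = 0.7,
                                  identification = 0.7),
                    seed = 100)
  labs <- unlist(lapply(simulate_cohort(sc2, m),
                        function(s) s$events$label == "correct"))
  expect_lt(abs(mean(labs) - 0.7), 3 * sqrt(0.7 * 0.3 / length(labs)) + 0.005)
})

test_that("forward model is linear and zero maps to zero", {
  m <- montage_config(n_channels = 3)
  z <- forward_model(matrix(0, 3, 10), matrix(0, 3, 10), m)
  expect_true(all(z == 0))
  set.seed(2)
  hbo <- matrix(rnorm(30), 3)
  hbr <- matrix(rnorm(30), 3)
  od1 <- forward_model(hbo, hbr, m)
  expect_equal(forward_model(2 * hbo, 2 * hbr, m), 2 * od1, tolerance = 1e-12)
  # doubling separations doubles the optical density
  m2 <- montage_config(n_channels = 3, separations = 2 * m$separations)
  expect_equal(forward_model(hbo, hbr, m2), 2 * od1, tolerance = 1e-12)
  expect_error(forward_model(hbo, hbr[, 1:5], m), "match")
})
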