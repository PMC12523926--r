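test_that("peak counting respects prominence and degenerate inputs", {
  expect_equal(num_peaks(rep(1, 10)), 0L)
  expect_equal(num_peaks(1:10), 0L)
  tg <- seq(0, 30, by = 0.1)
  expect_equal(num_peaks(hrf(tg)), 1)
  two <- hrf(tg) + c(rep(0, 150), hrf(tg)[1:151])
  expect_equal(num_peaks(two), 2)
  expect_error(num_peaks(c(1, 2)), "at least 3")
})

test_that("curve length equals the brute-force loop on random series", {
  expect_equal(curve_length(rep(2, 5)), 0)
  expect_equal(curve_length(c(0, 1, 0, 1)), 3)
  set.seed(10)
  for (i in 1:100) {
    x <- rnorm(sample(2:50, 1))
    expect_equal(curve_length(x), brute_curve_length(x))
  }
  expect_error(curve_length(1), "at least 2")
})

test_that("peak amplitude/latency picks the earliest maximum", {
  expect_equal(peak_amp_lat(c(0, 2, 1), 10), c(amp = 2, lat_s = 0.1))
  expect_equal(peak_amp_lat(rep(3, 5), 10), c(amp = 3, lat_s = 0))
  expect_equal(peak_amp_lat(c(1, 5, 2, 5), 10)[["lat_s"]], 0.1)
})

test_that("moments follow the degenerate conventions and converge", {
  expect_equal(unname(sample_moments(c(1, 1, 1, 1))), c(1, 0, 0, 0))
  x <- c(-2, -1, 0, 1, 2)
  expect_lt(abs(sample_moments(x)[["skewness"]]), 1e-12)
  set.seed(11)
  z <- rnorm(1e5)
  expect_lt(abs(sample_moments(z)[["kurtosis"]]), 0.05)
  expect_lt(abs(sample_moments(z)[["variance"]] - 1), 0.02)
})

test_that("LZ76 complexity matches the exhaustive brute-force parser", {
  # canonical worked example: 6 components
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(olfnirs:::.lz76_count(s), 6L)
  expect_equal(brute_lz76(s), 6L)
  # random strings agree with the oracle (the exhaustive sweep over all
  # short strings lives in the acceptance suite)
  set.seed(121)
  for (i in 1:200) {
    bits <- sample(0:1, sample(2:16, 1), replace = TRUE)
    expect_identical(olfnirs:::.lz76_count(bits), brute_lz76(bits))
  }
  # balanced alternating string: median binarization reproduces it
  alt <- rep(c(0, 1), 8)
  expect_equal(lzc(alt), brute_lzc(alt))
  # periodic sequences are far simpler than random ones
  per <- rep(c(0, 1), 32)
  expect_lte(olfnirs:::.lz76_count(as.integer(per)), 3L)
  set.seed(12)
  expect_lt(lzc(per), lzc(rnorm(64)) / 2)
  expect_equal(olfnirs:::.lz76_count(rep(0L, 50)), 2L)
  expect_error(lzc(1), "at least 2")
})

test_that("mutual information matches the brute-force histogram double sum", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(16:200, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else x + rnorm(n, sd = 0.3)
    expect_equal(mutual_info(x, y), brute_mi(x, y), tolerance = 1e-12)
  }
  # identity: MI(x, x) equals the binned entropy of x
  x <- rnorm(500)
  bx <- olfnirs:::bin_index(x, 8)
  px <- tabulate(bx, 8) / 500
  entropy <- -sum(px[px > 0] * log2(px[px > 0]))
  expect_equal(mutual_info(x, x), entropy, tolerance = 1e-12)
  # symmetry and nonnegativity; independent pairs near zero
  y <- rnorm(500)
  expect_equal(mutual_info(x, y), mutual_info(y, x))
  set.seed(14)
  xi <- runif(1e4); yi <- runif(1e4)
  expect_lt(mutual_info(xi, yi), 0.05)
  expect_error(mutual_info(1:20, 1:19), "equal-length")
})

test_that("wavelet details conserve energy and detect transients", {
  # constant series: all-zero details
  expect_equal(unname(wavelet_stats(rep(4, 64))), c(0, 0, 0))
  # Parseval for the orthonormal transform (length divisible by 2^levels)
  set.seed(15)
  x <- rnorm(256)
  w <- dwt_d4(x)
  energy <- sum(unlist(w$details)^2) + sum(w$approx^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-8)
  # a spike raises detail kurtosis relative to the spike-free twin
  base <- sin(2 * pi * (1:128) / 64)
  spiked <- base
  spiked[70] <- spiked[70] + 5
  expect_gt(wavelet_stats(spiked)[["WaveletKurtosis"]],
            wavelet_stats(base)[["WaveletKurtosis"]])
  expect_error(dwt_d4(rnorm(8)), "too short")
})

test_that("feature names serialize and parse losslessly", {
  nm <- feature_name("NumPeaks", "THb", 3)
  expect_equal(nm, "NumPeaks_THb_3")
  p <- parse_feature_name(c("LZC_THb_0", "MutualInfo_Hb_0",
                            "WaveletKurtosis_HbO_3"))
  expect_equal(p$feature, c("LZC", "MutualInfo", "WaveletKurtosis"))
  expect_equal(p$species, c("THb", "Hb", "HbO"))
  expect_equal(p$channel, c(0L, 0L, 3L))
  # round trip over the full grid
  for (k in feature_kinds()) for (s in c("HbO", "Hb", "THb")) {
    n2 <- feature_name(k, s, 5)
    pp <- parse_feature_name(n2)
    expect_equal(feature_name(pp$feature, pp$species, pp$channel), n2)
  }
  expect_error(parse_feature_name("Bogus_HbO_1"), "malformed")
  expect_error(parse_feature_name("Mean_HbO"), "malformed")
})

test_that("the feature table has the full grid of columns and spot-checks out", {
  ep <- cached_epochs()
  tab <- extract_features(ep)
  nc <- dim(ep$epochs[[1]]$data)[1]
  expect_equal(ncol(tab), 4 + 13 * 3 * nc)
  expect_equal(nrow(tab), length(ep$epochs))
  # deterministic
  expect_identical(extract_features(ep), tab)
  # spot oracle: LZC_THb_0 is lzc() of channel 0 total hemoglobin
  if (ep$channel_mask[1]) {
    e1 <- ep$epochs[[1]]$data
    expect_equal(tab$LZC_THb_0[1], lzc(e1[1, 3, ]))
    expect_equal(tab$CurveLength_Hb_0[1], curve_length(e1[1, 2, ]))
    expect_equal(tab$Mean_HbO_0[1], mean(e1[1, 1, ]))
  }
  # single-session extraction equals the cohort rows (no cross-talk)
  sub <- ep
  sub$epochs <- ep$epochs[2]
  sub$meta <- ep$meta[2, ]
  expect_equal(extract_features(sub), tab[2, ], ignore_attr = TRUE)
})

test_that("standardization uses training rows only and flags degenerates", {
  set.seed(16)
  tab <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 10),
    trial_id = 1:20, task = "threshold",
    label = rep(c("correct", "incorrect"), 10),
    F1_HbO_0 = rnorm(20, mean = 5),
    F2_HbO_0 = c(rnorm(10), rnorm(10, mean = 50)),
    F3_HbO_0 = rep(2, 20)
  )
  names(tab)[5:7] <- c("Mean_HbO_0", "Var_HbO_0", "Skew_HbO_0")
  train <- 1:10
  std <- standardize_features(tab, train)
  zt <- std$table$Mean_HbO_0[train]
  expect_lt(abs(mean(zt)), 1e-10)
  expect_lt(abs(sd(zt) - 1), 1e-10)
  # held-out rows use the training parameters, not their own
  held <- std$table$Var_HbO_0[11:20]
  expect_gt(mean(held), 5) # far from zero mean under training scaling
  # degenerate constant column -> zeros + flag
  expect_true(all(std$table$Skew_HbO_0 == 0))
  expect_true(std$standardizer$degenerate[std$standardizer$column == "Skew_HbO_0"])
  # NA imputation from training mean
  tab$Mean_HbO_0[12] <- NA
  std2 <- standardize_features(tab, train)
  expect_false(is.na(std2$table$Mean_HbO_0[12]))
  expect_error(standardize_features(tab, integer(0)), "nonempty")
})
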