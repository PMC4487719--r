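test_that("temporal features of flat and linear epochs match closed-form OLS", {
  fs <- 500
  flat <- rep(-3, 2 * fs)
  f <- temporal_features(flat, fs, "executed")
  expect_equal(unname(f), c(0, -3, 0, -3, 0, -3))
  expect_named(f, c("t_max_negativity", "mean_amp", "slope", "intercept",
                    "slope_final", "intercept_final"))

  t <- (0:(2 * fs - 1)) / fs
  ramp <- -5 * t # 0 -> -10 over [0, 2)
  f <- temporal_features(ramp, fs, "executed")
  # independent oracle: lm() on the same discrete grid
  fit_full <- stats::lm(ramp ~ t)
  fit_final <- stats::lm(ramp[t >= 1.5] ~ t[t >= 1.5])
  expect_equal(f[["t_max_negativity"]], t[length(t)])
  expect_equal(f[["mean_amp"]], mean(ramp))
  expect_equal(f[["slope"]], unname(stats::coef(fit_full)[2]))
  expect_equal(f[["intercept"]], unname(stats::coef(fit_full)[1]))
  expect_equal(f[["slope_final"]], unname(stats::coef(fit_final)[2]))

  fi <- temporal_features(ramp, fs, "imagery")
  expect_length(fi, 5)
  expect_named(fi, c("t_max_negativity", "mean_amp", "slope", "slope_final",
                     "mean_final"))
  expect_equal(fi[["mean_final"]], mean(ramp[t >= 1.5]))
  expect_equal(fi[["mean_final"]], -8.745, tolerance = 1e-3)
})

test_that("the full-epoch regression endpoint switch changes the fit window", {
  fs <- 500
  t <- (0:(2 * fs - 1)) / fs
  # V-shape: minimum at 1 s, rise afterwards
  v <- abs(t - 1) - 1
  fe <- temporal_features(v, fs, "executed", regression_end = "epoch_end")
  fm <- temporal_features(v, fs, "executed", regression_end = "max_negativity")
  expect_equal(fe[["slope"]], unname(stats::coef(stats::lm(v ~ t))[2]))
  expect_equal(fm[["slope"]], unname(stats::coef(stats::lm(v[t <= 1] ~ t[t <= 1]))[2]))
})

test_that("Welch PSD satisfies Parseval and localises a sinusoid", {
  fs <- 500
  expect_equal(welch_psd(rep(0, 1000), fs)$psd, rep(0, 251))
  x <- withr::with_seed(1, rnorm(5e4, sd = 1.7))
  p <- welch_psd(x, fs)
  expect_lt(abs(sum(p$psd) * (fs / 500) - 1.7^2) / 1.7^2, 0.10)
  t <- (0:999) / fs
  p10 <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(p10$freq[which.max(p10$psd)], 10)
  expect_error(welch_psd(rnorm(100), fs, seg_len = 500), "seg_len")
})

test_that("band powers average the right bins and dominate where the signal lives", {
  freq <- 0:250
  flat <- rep(2.5, 251)
  for (i in seq_len(nrow(default_bands()))) {
    b <- default_bands()[i, ]
    expect_equal(band_power(freq, flat, b$lo, b$hi), 2.5)
  }
  spike <- rep(0, 251); spike[freq == 10] <- 1
  vals <- sapply(seq_len(5), function(i) {
    b <- default_bands()[i, ]
    band_power(freq, spike, b$lo, b$hi, include_upper = i == 5)
  })
  expect_true(vals[3] > 0 && all(vals[-3] == 0))
  expect_error(band_power(c(0, 10, 20), flat[1:3], 2, 8), "resolution")
  # a 10 Hz sinusoid's alpha power exceeds every other band by > 10x
  fs <- 500
  sf <- spectral_features(sin(2 * pi * 10 * (0:999) / fs), fs)
  expect_true(all(sf[["alpha"]] > 10 * sf[c("delta", "mu", "beta", "gamma")]))
  # union of adjacent bands lies between the two band means
  x <- withr::with_seed(2, rnorm(1000))
  p <- welch_psd(x, fs)
  b1 <- band_power(p$freq, p$psd, 4, 8)
  b2 <- band_power(p$freq, p$psd, 8, 13)
  bu <- band_power(p$freq, p$psd, 4, 13)
  expect_gte(bu, min(b1, b2))
  expect_lte(bu, max(b1, b2))
})

test_that("white-noise epochs give approximately flat band powers", {
  fs <- 500
  feats <- t(sapply(1:40, function(i) {
    spectral_features(withr::with_seed(100 + i, rnorm(1000)), fs)
  }))
  m <- colMeans(feats)
  expect_lt(max(m) / min(m), 1.4)
})

test_that("feature scaling, time-reversal and determinism invariants hold", {
  fs <- 500
  x <- withr::with_seed(3, rnorm(1000)) + seq(0, -4, length.out = 1000)
  a <- 2.7
  ft1 <- temporal_features(x, fs); ft2 <- temporal_features(a * x, fs)
  expect_equal(ft2[["t_max_negativity"]], ft1[["t_max_negativity"]])
  expect_equal(ft2[["mean_amp"]], a * ft1[["mean_amp"]])
  expect_equal(ft2[["slope"]], a * ft1[["slope"]])
  expect_equal(ft2[["intercept"]], a * ft1[["intercept"]])
  sf1 <- spectral_features(x, fs); sf2 <- spectral_features(a * x, fs)
  expect_equal(unname(sf2), unname(a^2 * sf1))
  # time reversal flips regression slopes, preserves the mean
  fr <- temporal_features(rev(x), fs)
  expect_equal(fr[["slope"]], -ft1[["slope"]])
  expect_equal(fr[["mean_amp"]], ft1[["mean_amp"]])
  expect_identical(temporal_features(x, fs), temporal_features(x, fs))
})

test_that("extract_features refuses a mismatched path and returns aligned tables", {
  cfg <- tiny_cfg()
  rec <- generate_recording(cfg, "real")
  surr <- surrogate_channels(rec)
  ep_t <- extract_epochs(surr, rec$true_onsets, rec$task_labels, "temporal")
  expect_error(extract_features(ep_t, "spectral"), "spectral")
  ft <- extract_features(ep_t, "temporal", mode = "imagery")
  expect_equal(ncol(ft), 4 + 5)
  expect_equal(nrow(ft), nrow(ep_t$samples))
  expect_true(all(is.finite(as.matrix(ft[, -(1:4)]))))
})
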