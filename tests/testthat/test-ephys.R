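params_3m <- detection_params("3M", "mEPSC")

test_that("band-pass filter removes DC, keeps 100 Hz, rejects 0.5 Hz", {
  fs <- 10000
  tt <- seq(0, 10, by = 1 / fs)
  flat <- bandpass_filter(trace(rep(50, length(tt)), fs), params_3m)
  expect_lt(abs(mean(flat)), 1e-6)
  expect_equal(length(flat), length(tt))

  in_band <- sin(2 * pi * 100 * tt)
  out <- bandpass_filter(trace(in_band, fs), params_3m)
  expect_lt(abs(stats::sd(out) / stats::sd(in_band) - 1), 0.1)

  slow <- sin(2 * pi * 0.5 * tt)
  out_slow <- bandpass_filter(trace(slow, fs), params_3m)
  expect_lt(stats::sd(out_slow) / stats::sd(slow), 0.1)

  expect_error(bandpass_filter(trace(rnorm(1000), 1000), params_3m),
               "Nyquist")
})

test_that("baseline SD recovers the noise SD and avoids events", {
  sds <- vapply(1:20, function(s) {
    set.seed(s)
    estimate_baseline_sd(trace(rnorm(600000, 0, 2), 10000), params_3m)
  }, numeric(1))
  # min-SD window selection biases slightly low; recovery within [1.6, 2.4]
  expect_gt(stats::median(sds), 1.6)
  expect_lt(stats::median(sds), 2.4)

  expect_equal(estimate_baseline_sd(trace(rep(3, 10000), 10000), params_3m),
               0)
  # a single huge event on an otherwise silent trace: window avoids it
  x <- rep(0, 20000)
  x[10000:10500] <- -80
  expect_equal(estimate_baseline_sd(trace(x, 10000), params_3m), 0)
  expect_error(estimate_baseline_sd(trace(rnorm(500), 10000), params_3m),
               "shorter")
})

test_that("a single large planted event is detected exactly once", {
  cfg <- sim_config(seed = 2, duration_s = 10, event_rate_hz = 0,
                    noise_sd_pa = 2)
  g <- gen_mini_trace(cfg)
  x <- as.numeric(g$trace)
  k <- 20 * synaptodev:::mini_kernel(2, 20, 10000)  # broad 20 pA kernel
  x[50000:(50000 + length(k) - 1)] <- x[50000:(50000 + length(k) - 1)] - k
  ev <- detect_minis(trace(x, 10000), params_3m)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_s, 5 + (which.max(k) - 1) / 10000, tolerance = 1e-3)
  expect_gt(ev$peak_amplitude_pa, 10)
})

test_that("detection is invariant to polarity", {
  cfg <- sim_config(seed = 11, duration_s = 20)
  g <- gen_mini_trace(cfg)
  ev_neg <- detect_minis(g$trace, params_3m)
  flipped <- trace(-as.numeric(g$trace), 10000, polarity = "positive")
  ev_pos <- detect_minis(flipped, params_3m)
  expect_equal(ev_neg, ev_pos, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate baselines are rejected, silent traces are empty", {
  x <- rep(0, 20000)
  x[10000:10300] <- -50   # signal but zero baseline SD
  expect_error(detect_minis(trace(x, 10000), params_3m), "degenerate")
  ev <- detect_minis(trace(rep(0, 20000), 10000), params_3m)
  expect_identical(nrow(ev), 0L)
  expect_error(detect_minis(trace(rnorm(5000), 10000), params_3m),
               "at least 1 s")
})

test_that("default detection thresholds follow the (age, condition) table", {
  expect_equal(detection_params("0M", "mEPSC")$amp_thresh_sd, 3)
  expect_equal(detection_params("0M", "mEPSC")$area_thresh_sd_ms, 4.5)
  expect_equal(detection_params("0M", "mIPSC")$area_thresh_sd_ms, 9)
  expect_equal(detection_params("3M", "mEPSC")$amp_thresh_sd, 2)
  expect_equal(detection_params("6M", "mIPSC")$area_thresh_sd_ms, 6)
})

test_that("cell summaries report frequency and amplitude conventions", {
  ev <- data.frame(onset_s = 1:30, peak_s = 1:30 + 0.001,
                   peak_amplitude_pa = rep(c(10, 20, 30), 10),
                   area_pa_ms = rep(50, 30))
  s <- summarize_cells(ev, duration_s = 60)
  expect_equal(s$frequency_hz, 0.5)
  expect_equal(s$mean_amplitude_pa, 20)
  s0 <- summarize_cells(ev[0, ], duration_s = 60)
  expect_equal(s0$frequency_hz, 0)
  expect_true(is.na(s0$mean_amplitude_pa))
})

test_that("E/I ratio handles frequencies, amplitudes and zero denominators", {
  expect_equal(ei_ratio(2, 4), 0.5)
  expect_equal(ei_ratio(3, 3), 1)
  expect_true(is.na(ei_ratio(2, 0)))
  e <- data.frame(frequency_hz = 2, mean_amplitude_pa = 10)
  i <- data.frame(frequency_hz = 4, mean_amplitude_pa = 40)
  expect_equal(ei_ratio(e, i, "miniature_freq"), 0.5)
  expect_equal(ei_ratio(e, i, "evoked_amp"), 0.25)
})

test_that("LTD magnitude renormalizes to baseline and is scale-invariant", {
  tm <- seq(-10, 45, by = 0.5)
  expect_equal(ltd_magnitude(tm, rep(1, length(tm))), 1)
  amp <- ifelse(tm <= 0, 100, 80)
  expect_equal(ltd_magnitude(tm, amp), 0.8)
  set.seed(5)
  amp2 <- runif(length(tm), 50, 150)
  direct <- mean(amp2[tm >= 30 & tm <= 40]) / mean(amp2[tm > -10 & tm <= 0])
  expect_equal(ltd_magnitude(tm, amp2), direct, tolerance = 1e-12)
  expect_equal(ltd_magnitude(tm, 7 * amp2), direct, tolerance = 1e-12)
  # renormalization idempotence: feeding back the normalized series
  norm <- amp2 / mean(amp2[tm > -10 & tm <= 0])
  expect_equal(ltd_magnitude(tm, norm), direct, tolerance = 1e-12)
  expect_error(ltd_magnitude(tm[tm < 20], amp2[tm < 20]), "post-LFS")
})

test_that("paired-pulse ratio and phenotype logFC follow their formulas", {
  expect_equal(paired_pulse_ratio(100, 50), 0.5)
  expect_equal(paired_pulse_ratio(80, 80), 1)
  expect_error(paired_pulse_ratio(0, 10), "positive")
  expect_equal(phenotype_logfc(c(1, 1), c(2, 2)), 1)
  expect_equal(phenotype_logfc(c(3, 3), c(3, 3)), 0)
  expect_equal(phenotype_logfc(c(0.5, 0.5), c(0.25, 0.25)), -1)
  expect_error(phenotype_logfc(c(0, 0), c(1, 1)), "positive")
})

test_that("group comparison applies Welch per age and Holm-Sidak family", {
  set.seed(8)
  vals <- c(rnorm(6, 10), rnorm(6, 10),     # 0M identical distributions
            rnorm(6, 10), rnorm(6, 14),     # 3M shifted
            rnorm(6, 10), rnorm(6, 10.2))   # 6M near-null
  age <- rep(c("0M", "3M", "6M"), each = 12)
  grp <- rep(rep(c("UE", "VPA"), each = 6), 3)
  gc <- group_compare(vals, age, grp)
  expect_identical(nrow(gc), 3L)
  expect_equal(gc$p_adj, p_adjust_holm_sidak(gc$p_raw))
  # identical groups give raw p = 1
  same <- group_compare(rep(c(1, 2, 3), 4),
                        rep("0M", 12), rep(c("UE", "VPA"), each = 6))
  expect_equal(same$p_raw, 1, tolerance = 1e-9)
})
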