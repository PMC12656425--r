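test_that("period extraction recovers f0 on a clean synthetic vowel", {
  g <- generate_phonation(phonation_spec(f0 = 180, seed = 1))
  p <- extract_period_sequence(g$wave)
  expect_gt(length(p$periods), 100)
  expect_lt(abs(stats::median(1 / p$periods) - 180), 1)
  f0 <- f0_statistics(p)
  expect_lt(abs(f0$Fo - 180), 1)
  expect_lte(f0$Flo, f0$Fo)
  expect_gte(f0$Fhi, f0$Fo)
})

test_that("period extraction works when phonation is framed by silence", {
  g <- generate_phonation(phonation_spec(
    f0 = 150, duration = 0.6, jitter_rel = 0.01, shimmer_rel = 0.03,
    hnr_db = 15, lead_silence = 0.05, tail_silence = 0.05, seed = 4
  ))
  p <- extract_period_sequence(g$wave)
  a <- extract_amplitude_sequence(g$wave, p)
  expect_true(all(a$amplitudes > 0))
  # no cycle mark may sit inside the silence padding
  expect_gte(min(p$mark_samples) / g$wave$rate, 0.05 - 1 / 150)
  expect_lte(max(p$mark_samples) / g$wave$rate, 0.65 + 1 / 150)
})

test_that("jitter measures match hand-computed values on a known sequence", {
  per <- c(10, 11, 10, 12, 11, 10) * 1e-3
  p <- structure(list(periods = per), class = "period_sequence")
  j <- jitter_features(p)
  n <- length(per)
  d <- abs(diff(per))
  expect_equal(j$jitter_local_pct, mean(d / per[-n]) * 100)
  expect_equal(j$jitter_abs_s, mean(d))
  ma3 <- (per[1:4] + per[2:5] + per[3:6]) / 3
  expect_equal(j$rap, mean(abs(per[2:5] - ma3)) / mean(per))
  ma5 <- (per[1:2] + per[2:3] + per[3:4] + per[4:5] + per[5:6]) / 5
  expect_equal(j$ppq5, mean(abs(per[3:4] - ma5)) / mean(per))
})

test_that("shimmer measures match hand-computed values on a known sequence", {
  amp <- c(1, 1.1, 0.9, 1.05, 1)
  a <- structure(list(amplitudes = amp), class = "amplitude_sequence")
  s <- shimmer_features(a)
  n <- length(amp)
  d <- abs(diff(amp))
  expect_equal(s$shimmer_local, mean(d / amp[-n]))
  expect_equal(s$shimmer_db, mean(abs(20 * log10(amp[-1] / amp[-n]))))
  ma3 <- (amp[1:3] + amp[2:4] + amp[3:5]) / 3
  expect_equal(s$apq3, mean(abs(amp[2:4] - ma3)) / mean(amp))
  expect_error(shimmer_features(structure(list(amplitudes = c(1, -1)),
    class = "amplitude_sequence"
  )), "positive")
})

test_that("short sequences produce NA for smoothed quotients", {
  p2 <- structure(list(periods = c(0.01, 0.011)), class = "period_sequence")
  j <- jitter_features(p2)
  expect_true(is.na(j$rap))
  expect_true(is.na(j$ppq5))
  expect_error(
    jitter_features(structure(list(periods = 0.01), class = "period_sequence")),
    "at least 2"
  )
})

test_that("hnr_from_r implements the autocorrelation-to-dB map", {
  expect_equal(hnr_from_r(0.5), 0)
  expect_equal(hnr_from_r(0.9), 10 * log10(9))
  # monotone increasing in r
  r <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(hnr_from_r(r)) > 0))
  # extreme inputs stay finite thanks to clamping
  expect_true(is.finite(hnr_from_r(1)))
  expect_true(is.finite(hnr_from_r(0)))
})

test_that("mel filterbank covers the band with triangular unit-peak filters", {
  g <- generate_phonation(phonation_spec(f0 = 150, seed = 1))
  fb <- mel_filterbank_energies(g$wave)
  expect_equal(nrow(fb$energies), 26)
  expect_true(all(fb$energies >= 1e-10))
  expect_error(mel_filterbank_energies(g$wave, n_filters = 5), "13")
})

test_that("MFCCs of a flat filterbank vanish for k >= 1", {
  flat <- matrix(1, 26, 10) # identical log energies in every band
  cc <- mel_cepstral_coefficients(flat, K = 13)
  expect_lt(max(abs(cc)), 1e-12)
  expect_error(mel_cepstral_coefficients(flat, K = 26), "smaller")
})

test_that("the default schema has 22 uniquely named entries", {
  s <- default_feature_schema()
  expect_equal(nrow(s), 22)
  expect_equal(anyDuplicated(s$feature), 0)
  expect_identical(attr(s, "schema_id"), "voxfuse22")
})

test_that("assemble_biomarker_vector returns one finite value per schema entry", {
  g <- generate_phonation(phonation_spec(
    f0 = 160, jitter_rel = 0.01, shimmer_rel = 0.03, hnr_db = 15, seed = 9
  ))
  v <- assemble_biomarker_vector(g$wave)
  expect_identical(names(v), default_feature_schema()$feature)
  expect_true(all(is.finite(v)))
  expect_lt(abs(v[["Fo"]] - 160), 2)
  expect_gt(v[["HNR"]], 10)
})

test_that("standardization fits on training rows and inverts cleanly", {
  set.seed(2)
  train_df <- data.frame(a = rnorm(50, 3, 2), b = rnorm(50, -1, 0.5))
  st <- fit_standardization(train_df)
  z <- apply_standardization(train_df, st)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  # population (1/n) standard deviation is used
  expect_lt(max(abs(sqrt(colMeans(z^2)) - 1)), 1e-12)
  # test rows are transformed with the training statistics, not their own
  test_df <- data.frame(a = rnorm(10, 10, 1), b = rnorm(10))
  z2 <- apply_standardization(test_df, st)
  expect_gt(mean(z2$a), 1) # shifted population stays shifted
})

test_that("feature CSV round-trips through the repository format", {
  coh <- generate_cohort(cohort_spec(n_subjects = 4, samples_per_subject = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(coh[c("sample_id", "label", grep("^bio_", names(coh), value = TRUE))], path)
  back <- read_feature_csv(path)
  expect_equal(nrow(back), nrow(coh))
  expect_true(all(grepl("^bio_", setdiff(names(back), c("sample_id", "subject_id", "label")))))
})
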