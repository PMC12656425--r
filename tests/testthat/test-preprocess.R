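tone <- function(freq = 220, dur = 0.5, rate = 16000, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * (0:(round(dur * rate) - 1)) / rate), rate)
}

test_that("resample_wave preserves duration and dominant frequency", {
  w <- tone(220, dur = 0.5, rate = 8000)
  r <- resample_wave(w, 16000)
  expect_equal(r$rate, 16000)
  expect_equal(length(r$samples), 8000)
  # dominant FFT bin maps to 220 Hz at the new rate
  sp <- Mod(stats::fft(r$samples))[1:4000]
  f_peak <- (which.max(sp) - 1) * 16000 / 8000
  expect_lt(abs(f_peak - 220), 4)
  # identity when rates already match
  expect_identical(resample_wave(w, 8000), w)
})

test_that("VAD finds the voiced interval and ignores silence", {
  rate <- 16000
  sig <- c(numeric(rate / 4), tone(220, 0.5, rate)$samples, numeric(rate / 4))
  w <- waveform(sig, rate)
  segs <- detect_voice_activity(w)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$start_s - 0.25), 0.04)
  expect_lt(abs(segs$end_s - 0.75), 0.04)
  # all-silent input yields zero segments
  expect_equal(nrow(detect_voice_activity(waveform(numeric(rate), rate))), 0)
})

test_that("extract_active concatenates exactly the active samples", {
  rate <- 16000
  sig <- c(numeric(rate / 4), rep(0.5, rate / 2), numeric(rate / 4))
  w <- waveform(sig, rate)
  segs <- tibble::tibble(start_s = 0.25, end_s = 0.75)
  act <- extract_active(w, segs)
  expect_true(all(act$samples == 0.5))
  expect_lt(abs(length(act$samples) - rate / 2), 3)
})

test_that("normalize_and_fit_duration pads, trims, and standardizes", {
  rate <- 1000
  cfg <- preprocess_config(target_rate = rate, max_duration = 1)
  short <- waveform(stats::rnorm(400), rate)
  out <- normalize_and_fit_duration(short, cfg)
  expect_equal(length(out$samples), rate)
  expect_true(all(out$samples[401:1000] == 0)) # zero padding at the tail
  live <- out$samples[1:400]
  expect_lt(abs(mean(live)), 1e-12)
  expect_lt(abs(stats::sd(live) - 1), 1e-12)
  long <- waveform(stats::rnorm(2500), rate)
  expect_equal(length(normalize_and_fit_duration(long, cfg)$samples), rate)
})

test_that("spectral gate suppresses noise-only input and keeps tones", {
  rate <- 16000
  cfg <- preprocess_config(gate_enabled = TRUE)
  set.seed(42)
  noise <- waveform(stats::rnorm(rate) * 0.01, rate)
  gated_noise <- spectral_gate(noise, cfg)
  expect_lt(
    sqrt(mean(gated_noise$samples^2)),
    0.5 * sqrt(mean(noise$samples^2))
  )
  # the gate learns its floor from the quietest frames, so give it a
  # noise-only tail to measure: tone+noise for 1 s, then 0.25 s of noise
  clean <- c(tone(220, 1, rate)$samples, numeric(rate %/% 4))
  mix <- waveform(clean + stats::rnorm(length(clean)) * 0.01, rate)
  gated <- spectral_gate(mix, cfg)
  # gating never increases energy
  expect_lte(sum(gated$samples^2), sum(mix$samples^2) * (1 + 1e-9))
  # the tone survives: correlation with the clean tone stays high over the
  # tone region (STFT edge frames excluded)
  keep <- 513:(rate - 512)
  expect_gt(stats::cor(gated$samples[keep], clean[keep]), 0.98)
})

test_that("preprocess_audio is idempotent on clean fixed-duration input", {
  rate <- 16000
  cfg <- preprocess_config(max_duration = 0.5)
  w <- tone(180, 0.5, rate)
  once <- preprocess_audio(w, cfg)
  twice <- preprocess_audio(once, cfg)
  expect_equal(length(once$samples), round(0.5 * rate))
  expect_lt(max(abs(once$samples - twice$samples)), 1e-10)
})

test_that("preprocess_audio rejects silence", {
  expect_error(
    preprocess_audio(waveform(numeric(16000), 16000)),
    "no voice activity"
  )
})
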