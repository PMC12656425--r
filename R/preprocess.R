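#' Preprocessing configuration
#'
#' Controls the waveform-conditioning pipeline applied before any feature
#' extraction or embedding: resampling to a common rate, energy-based voice
#' activity detection (VAD), optional spectral gating of stationary noise,
#' and normalization plus padding/trimming to a fixed duration.
#'
#' @param target_rate Target sampling rate in Hz (default 16 kHz).
#' @param frame_len VAD analysis frame length in seconds.
#' @param hop_len VAD hop length in seconds; `0 < hop_len <= frame_len`.
#' @param vad_threshold_db Frame-energy threshold in dB relative to the
#'   loudest frame; frames quieter than this are treated as silence.
#' @param min_active_frames Minimum run length (in frames) for an active
#'   region to be kept.
#' @param gate_enabled Apply the spectral gate? Default off — sustained
#'   phonation recordings are typically clean; enable for conversational
#'   audio.
#' @param gate_offset Multiplier on the per-bin noise-floor deviation used
#'   by the gate threshold.
#' @param max_duration Output duration in seconds (trim or zero-pad).
#' @param standardize Standardize the non-padded region to zero mean / unit
#'   SD?
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 16000, frame_len = 0.03, hop_len = 0.01,
                              vad_threshold_db = -40, min_active_frames = 3,
                              gate_enabled = FALSE, gate_offset = 1.5,
                              max_duration = 30, standardize = TRUE) {
  if (hop_len <= 0 || hop_len > frame_len) {
    stop("need 0 < hop_len <= frame_len", call. = FALSE)
  }
  if (max_duration <= 0) stop("max_duration must be positive", call. = FALSE)
  structure(
    list(
      target_rate = target_rate, frame_len = frame_len, hop_len = hop_len,
      vad_threshold_db = vad_threshold_db, min_active_frames = min_active_frames,
      gate_enabled = gate_enabled, gate_offset = gate_offset,
      max_duration = max_duration, standardize = standardize
    ),
    class = "preprocess_config"
  )
}

#' Resample a waveform by polyphase band-limited interpolation
#'
#' @param w A [waveform()].
#' @param target_rate Target rate in Hz.
#' @return A [waveform()] at `target_rate`, same duration within one sample.
#' @export
resample_wave <- function(w, target_rate) {
  assert_waveform(w)
  if (target_rate <= 0) stop("target_rate must be positive", call. = FALSE)
  if (w$rate == target_rate) {
    return(w)
  }
  g <- gcd_int(round(w$rate), round(target_rate))
  p <- round(target_rate) / g
  q <- round(w$rate) / g
  y <- signal::resample(w$samples, p, q)
  n_target <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  waveform(y, target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

frame_starts <- function(n, frame, hop) {
  if (n < frame) {
    return(integer(0))
  }
  seq(1L, n - frame + 1L, by = hop)
}

#' Energy-based voice activity detection
#'
#' Frames the signal (30 ms / 10 ms by default), computes per-frame RMS
#' energy in dB relative to the loudest frame, marks frames above
#' `vad_threshold_db` active, merges adjacent active frames and discards
#' runs shorter than `min_active_frames`.
#'
#' @param w A [waveform()] at the target rate.
#' @param cfg A [preprocess_config()].
#' @return A tibble with columns `start_s`, `end_s`: sorted, non-overlapping
#'   half-open intervals in seconds (zero rows for all-silent input).
#' @export
detect_voice_activity <- function(w, cfg = preprocess_config()) {
  assert_waveform(w, allow_empty = TRUE)
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  n <- length(w$samples)
  frame <- max(round(cfg$frame_len * w$rate), 1L)
  hop <- max(round(cfg$hop_len * w$rate), 1L)
  starts <- frame_starts(n, frame, hop)
  if (length(starts) == 0L) {
    return(empty)
  }
  rms <- vapply(starts, function(s) sqrt(mean(w$samples[s:(s + frame - 1L)]^2)), 0)
  peak <- max(rms)
  if (peak == 0) {
    return(empty)
  }
  db <- 20 * log10(pmax(rms, peak * 1e-10) / peak)
  active <- db > cfg$vad_threshold_db
  r <- rle(active)
  keep <- r$values & r$lengths >= cfg$min_active_frames
  if (!any(keep)) {
    return(empty)
  }
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  segs <- tibble::tibble(
    start_s = (starts[idx_start[keep]] - 1L) / w$rate,
    end_s = pmin(starts[idx_end[keep]] - 1L + frame, n) / w$rate
  )
  segs[order(segs$start_s), ]
}

#' Extract and concatenate the active (voiced) regions of a waveform
#'
#' @param w A [waveform()].
#' @param segments Segment tibble from [detect_voice_activity()].
#' @return A [waveform()] containing only the active samples.
#' @export
extract_active <- function(w, segments) {
  assert_waveform(w, allow_empty = TRUE)
  if (nrow(segments) == 0L) {
    return(waveform(numeric(0), w$rate))
  }
  idx <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    a <- floor(segments$start_s[i] * w$rate) + 1L
    b <- min(ceiling(segments$end_s[i] * w$rate), length(w$samples))
    seq(a, b)
  }))
  waveform(w$samples[idx], w$rate)
}

# ---- STFT helpers ----------------------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

stft_mat <- function(x, n_fft, hop) {
  starts <- frame_starts(length(x), n_fft, hop)
  win <- hann_window(n_fft)
  frames <- vapply(starts, function(s) x[s:(s + n_fft - 1L)] * win, numeric(n_fft))
  spec <- stats::mvfft(frames)
  list(spec = spec, starts = starts, win = win, n = length(x), n_fft = n_fft, hop = hop)
}

istft_mat <- function(st) {
  frames <- Re(stats::mvfft(st$spec, inverse = TRUE)) / st$n_fft
  y <- numeric(st$n)
  wsum <- numeric(st$n)
  for (j in seq_along(st$starts)) {
    idx <- st$starts[j]:(st$starts[j] + st$n_fft - 1L)
    y[idx] <- y[idx] + frames[, j] * st$win
    wsum[idx] <- wsum[idx] + st$win^2
  }
  # clamp the overlap-add normalizer relative to its interior value so the
  # half-covered edge samples are attenuated, not amplified
  y / pmax(wsum, 0.05 * max(wsum))
}

#' Spectral gating of stationary background noise
#'
#' Estimates a per-frequency-bin noise floor from the lowest-energy decile
#' of STFT frames and attenuates bins whose magnitude falls below
#' `floor_mean + gate_offset * floor_sd` with a soft sigmoid mask; the
#' signal is reconstructed by inverse STFT at the original length. The mask
#' lies in (0, 1), so gating never increases energy.
#'
#' @param w A [waveform()] at the target rate.
#' @param cfg A [preprocess_config()].
#' @param n_fft STFT size (samples); hop is `n_fft / 4`.
#' @return The gated [waveform()].
#' @export
spectral_gate <- function(w, cfg = preprocess_config(), n_fft = 512) {
  assert_waveform(w)
  if (length(w$samples) < n_fft) {
    stop("signal shorter than one STFT frame (", n_fft, " samples)", call. = FALSE)
  }
  if (all(w$samples == 0)) {
    return(w)
  }
  st <- stft_mat(w$samples, n_fft, n_fft %/% 4L)
  mag <- Mod(st$spec)
  energy <- colSums(mag^2)
  n_noise <- max(ceiling(0.1 * length(energy)), 2L)
  noise_frames <- order(energy)[seq_len(n_noise)]
  mu <- apply(mag[, noise_frames, drop = FALSE], 1, mean)
  sdv <- apply(mag[, noise_frames, drop = FALSE], 1, stats::sd)
  thresh <- mu + cfg$gate_offset * sdv
  soft <- pmax(sdv, 1e-12) / 2
  gate <- 1 / (1 + exp(-(mag - thresh) / soft))
  # Wiener-style subtraction: bins barely above threshold are still mostly
  # noise, so scale them by their estimated signal fraction; strong bins
  # (signal >> floor) are left essentially untouched
  wiener <- pmax(1 - (thresh / pmax(mag, 1e-12))^2, 0)
  mask <- gate * wiener
  st$spec <- st$spec * mask
  waveform(istft_mat(st), w$rate)
}

#' Normalize and fit a waveform to a fixed duration
#'
#' Trims the tail or zero-pads at the tail to exactly
#' `max_duration * rate` samples; if `standardize`, the non-padded region is
#' shifted/scaled to zero mean and unit standard deviation (padding stays
#' zero).
#'
#' @param w A [waveform()] at the target rate.
#' @param cfg A [preprocess_config()].
#' @return A fixed-length [waveform()].
#' @export
normalize_and_fit_duration <- function(w, cfg = preprocess_config()) {
  assert_waveform(w)
  n_target <- round(cfg$max_duration * w$rate)
  x <- w$samples
  n_live <- min(length(x), n_target)
  x <- x[seq_len(n_live)]
  if (cfg$standardize) {
    s <- stats::sd(x)
    if (s == 0) {
      if (any(x != 0)) {
        stop("zero-variance non-silent region cannot be standardized", call. = FALSE)
      }
    } else {
      x <- (x - mean(x)) / s
    }
  }
  if (n_live < n_target) x <- c(x, numeric(n_target - n_live))
  waveform(x, w$rate)
}

#' Full audio-conditioning pipeline
#'
#' Resample to the target rate, keep only VAD-active regions, optionally
#' apply the spectral gate, then normalize and fit to the configured
#' duration. Idempotent (within numerical tolerance) on already-clean
#' fixed-duration input with the gate disabled.
#'
#' @param raw A [waveform()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed [waveform()] of exactly `max_duration` seconds at
#'   `target_rate`.
#' @export
preprocess_audio <- function(raw, cfg = preprocess_config()) {
  assert_waveform(raw)
  w <- resample_wave(raw, cfg$target_rate)
  segs <- detect_voice_activity(w, cfg)
  w <- extract_active(w, segs)
  if (length(w$samples) == 0L) {
    stop("no voice activity detected", call. = FALSE)
  }
  if (cfg$gate_enabled) w <- spectral_gate(w, cfg)
  normalize_and_fit_duration(w, cfg)
}
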