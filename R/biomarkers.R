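#' @title Acoustic perturbation biomarkers from sustained phonation
#' @name biomarkers
#' @description
#' The classical dysphonia measures used in voice-based Parkinson's
#' screening: fundamental-frequency statistics (Fo/Fhi/Flo), cycle-to-cycle
#' frequency perturbation (local jitter, absolute jitter, RAP, PPQ5),
#' cycle-to-cycle amplitude perturbation (local shimmer, dB shimmer, APQ3),
#' the harmonics-to-noise ratio from the normalized autocorrelation at the
#' pitch-period lag, and mel-frequency cepstral coefficients from a cosine
#' transform of log mel-filterbank energies.
NULL

# parabolic interpolation of a sampled peak: returns fractional offset and
# interpolated height around index i of y
parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y)) {
    return(list(offset = 0, height = y[i]))
  }
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  denom <- a - 2 * b + c
  if (denom == 0) {
    return(list(offset = 0, height = b))
  }
  off <- 0.5 * (a - c) / denom
  off <- max(min(off, 0.5), -0.5)
  list(offset = off, height = b - 0.25 * (a - c) * off)
}

# normalized, window-debiased autocorrelation of one frame (Boersma-style):
# r_x(tau) ~= (ac_xw(tau)/ac_xw(0)) / (ac_w(tau)/ac_w(0))
frame_autocor <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  w <- hann_window(n)
  xw <- x * w
  nfft <- 2^ceiling(log2(2 * n))
  ac <- function(v) {
    s <- Re(stats::fft(Mod(stats::fft(c(v, numeric(nfft - n))))^2, inverse = TRUE))
    s[seq_len(max_lag + 1L)] / s[1L]
  }
  if (all(xw == 0)) {
    return(numeric(max_lag + 1L))
  }
  r <- ac(xw) / pmax(ac(w), 1e-6)
  r
}

#' Extract the per-cycle period sequence of a voiced signal
#'
#' Frame-wise normalized autocorrelation locates the pitch period within
#' the configured F0 search range (unvoiced frames, whose autocorrelation
#' peak falls below `voicing_threshold`, are excluded); glottal-cycle marks
#' are then placed by picking one waveform peak per period with parabolic
#' sub-sample refinement, and each mark is refined by cross-correlating the
#' cycle against its predecessor.
#'
#' @param w A voiced [waveform()] (preprocessed).
#' @param f0_min,f0_max F0 search range in Hz.
#' @param frame_len,hop_len Analysis framing in seconds.
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return A list of class `period_sequence` with `periods` (s),
#'   `cycle_marks` (s, strictly increasing), and `frame_f0` (per-frame Hz,
#'   NA where unvoiced).
#' @export
extract_period_sequence <- function(w, f0_min = 50, f0_max = 500,
                                    frame_len = 0.04, hop_len = 0.01,
                                    voicing_threshold = 0.3) {
  assert_waveform(w)
  if (f0_min >= f0_max) stop("need f0_min < f0_max", call. = FALSE)
  x <- w$samples
  rate <- w$rate
  frame <- round(frame_len * rate)
  hop <- round(hop_len * rate)
  lag_min <- max(floor(rate / f0_max), 2L)
  lag_max <- ceiling(rate / f0_min)
  if (frame <= lag_max) frame <- lag_max + round(0.01 * rate)
  starts <- frame_starts(length(x), frame, hop)
  if (length(starts) == 0L) stop("signal too short for pitch analysis", call. = FALSE)

  f0s <- rep(NA_real_, length(starts))
  for (j in seq_along(starts)) {
    fr <- x[starts[j]:(starts[j] + frame - 1L)]
    if (sqrt(mean(fr^2)) < 1e-8) next
    r <- frame_autocor(fr, lag_max)
    band <- r[(lag_min + 1L):(lag_max + 1L)]
    if (max(band) < voicing_threshold) next
    # octave disambiguation: among local maxima within 10% of the global
    # maximum, take the one at the smallest lag (the true period; integer
    # multiples of it score equally high on periodic signals)
    nb <- length(band)
    is_peak <- c(FALSE, band[2:(nb - 1)] >= band[1:(nb - 2)] &
      band[2:(nb - 1)] >= band[3:nb], FALSE)
    cand <- which(is_peak & band >= 0.9 * max(band))
    pk <- if (length(cand)) cand[1] else which.max(band)
    ref <- parabolic_refine(band, pk)
    lag <- lag_min + pk - 1L + ref$offset
    f0s[j] <- rate / lag
  }
  voiced <- which(!is.na(f0s))
  if (length(voiced) == 0L) stop("no voiced frames found", call. = FALSE)
  # drop residual octave errors relative to the median track
  f0_med <- stats::median(f0s[voiced])
  f0s[!is.na(f0s) & abs(log2(f0s / f0_med)) > 0.3] <- NA
  voiced <- which(!is.na(f0s))
  if (length(voiced) == 0L) stop("no voiced frames found", call. = FALSE)
  # bridge isolated dropouts (<= 3 frames) inside a voiced stretch so one
  # noisy frame does not split the cycle-marking span
  gaps <- which(is.na(f0s))
  gaps <- gaps[gaps > min(voiced) & gaps < max(voiced)]
  if (length(gaps)) {
    runs_na <- split(gaps, cumsum(c(1, diff(gaps) != 1)))
    fill <- unlist(runs_na[lengths(runs_na) <= 3L])
    if (length(fill)) {
      f0s[fill] <- stats::approx(voiced, f0s[voiced], xout = fill)$y
    }
    voiced <- which(!is.na(f0s))
  }

  # work within the longest contiguous voiced run
  runs <- split(voiced, cumsum(c(1, diff(voiced) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  t_a <- starts[run[1]]
  t_b <- min(starts[run[length(run)]] + frame - 1L, length(x))
  # frames at the run boundary can overlap leading/trailing silence while
  # still reading as voiced; clamp the marking span to where signal energy
  # is actually present so peaks are never picked from the noise floor
  seg_abs <- abs(x[t_a:t_b])
  live <- which(seg_abs > 0.01 * max(seg_abs))
  t_b <- t_a + live[length(live)] - 1L
  t_a <- t_a + live[1] - 1L
  period_at <- stats::approxfun(starts[run], 1 / f0s[run], rule = 2)

  # peak-picking: one mark per cycle, sub-sample refined
  marks <- numeric(0)
  p0 <- period_at(t_a) * rate
  seg_end <- min(t_a + ceiling(1.5 * p0), t_b)
  i0 <- t_a + which.max(x[t_a:seg_end]) - 1L
  ref <- parabolic_refine(x, i0)
  marks <- i0 + ref$offset
  repeat {
    cur <- marks[length(marks)]
    p <- period_at(cur) * rate
    lo <- floor(cur + 0.7 * p)
    hi <- ceiling(cur + 1.3 * p)
    if (hi > t_b) break
    i0 <- lo + which.max(x[lo:hi]) - 1L
    ref <- parabolic_refine(x, i0)
    marks <- c(marks, i0 + ref$offset)
  }
  if (length(marks) < 3L) stop("too few glottal cycles located", call. = FALSE)

  # refine each mark to the steep rising zero-crossing preceding its crest
  # (the glottal-cycle boundary): the crest sits at a nonzero phase inside
  # the cycle, so crest spacing blends adjacent periods, while boundary
  # spacing measures each period directly; linear interpolation on the
  # steep flank gives sub-sample timing
  p_med <- stats::median(diff(marks))
  back <- ceiling(0.45 * p_med)
  cross <- vapply(marks, function(m) {
    b <- round(m)
    a <- max(b - back, 1L)
    if (b - a < 2L) {
      return(m)
    }
    seg <- x[a:b]
    d <- diff(seg)
    up <- which(seg[-length(seg)] < 0 & seg[-1] >= 0 & d > 0)
    if (!length(up)) {
      return(m)
    }
    i <- up[which.max(d[up])]
    a + i - 1L + (-seg[i]) / d[i]
  }, 0)
  if (all(diff(cross) > 0)) marks <- cross

  periods <- diff(marks) / rate
  med <- stats::median(periods)
  ok <- periods > pmax(1 / f0_max, 0.7 * med) & periods < pmin(1 / f0_min, 1.4 * med)
  structure(
    list(
      periods = periods[ok],
      cycle_marks = (marks[-length(marks)][ok] - 1) / rate,
      mark_samples = marks,
      keep = ok,
      frame_f0 = f0s,
      frame_starts_s = (starts - 1) / rate
    ),
    class = "period_sequence"
  )
}

#' Per-cycle peak-to-peak amplitudes
#'
#' @param w The [waveform()] the period sequence was extracted from.
#' @param p A `period_sequence` from [extract_period_sequence()].
#' @return A list of class `amplitude_sequence` with `amplitudes` (> 0, one
#'   per period).
#' @export
extract_amplitude_sequence <- function(w, p) {
  assert_waveform(w)
  m <- p$mark_samples
  x <- w$samples
  # peak-to-peak within cycle i: the crest sits at the mark, the trough just
  # before the next mark; stop a few samples short of the next mark so the
  # following cycle's crest cannot leak into the maximum
  amps <- vapply(seq_len(length(m) - 1L), function(i) {
    a <- max(floor(m[i]) - 1L, 1L)
    b <- min(floor(m[i + 1L]) - 3L, length(x))
    if (b <= a) b <- min(a + 1L, length(x))
    seg <- x[a:b]
    # parabolic interpolation of crest and trough heights: the true extrema
    # fall between samples, and the quantization error differs cycle to
    # cycle (the period is not an integer number of samples), which would
    # otherwise inject artificial amplitude perturbation
    hi <- parabolic_refine(x, a + which.max(seg) - 1L)$height
    lo <- parabolic_refine(x, a + which.min(seg) - 1L)$height
    hi - lo
  }, 0)
  amps <- amps[p$keep]
  if (any(amps <= 0)) stop("non-positive cycle amplitude", call. = FALSE)
  structure(list(amplitudes = amps), class = "amplitude_sequence")
}

#' Fundamental-frequency statistics
#'
#' @param p A `period_sequence`.
#' @return A tibble with `Fo` (mean of per-cycle 1/T), `Fhi` (max), `Flo`
#'   (min), all in Hz.
#' @export
f0_statistics <- function(p) {
  per <- p$periods
  if (length(per) < 1L) stop("empty period sequence", call. = FALSE)
  f <- 1 / per
  tibble::tibble(Fo = mean(f), Fhi = max(f), Flo = min(f))
}

#' Frequency-perturbation (jitter) measures
#'
#' Local jitter is the mean relative difference between consecutive periods
#' (in percent); absolute jitter the mean absolute difference in seconds;
#' RAP and PPQ5 the 3- and 5-point period perturbation quotients
#' (Praat/MDVP convention).
#'
#' @param p A `period_sequence` with at least 2 periods (3 for RAP, 5 for
#'   PPQ5).
#' @return A tibble with `jitter_local_pct`, `jitter_abs_s`, `rap`, `ppq5`.
#' @export
jitter_features <- function(p) {
  per <- p$periods
  n <- length(per)
  if (n < 2L) stop("need at least 2 periods for jitter", call. = FALSE)
  d <- abs(diff(per))
  jitter_local_pct <- mean(d / per[-n]) * 100
  jitter_abs_s <- mean(d)
  rap <- if (n >= 3L) {
    ma3 <- (per[1:(n - 2)] + per[2:(n - 1)] + per[3:n]) / 3
    mean(abs(per[2:(n - 1)] - ma3)) / mean(per)
  } else {
    NA_real_
  }
  ppq5 <- if (n >= 5L) {
    ma5 <- (per[1:(n - 4)] + per[2:(n - 3)] + per[3:(n - 2)] +
      per[4:(n - 1)] + per[5:n]) / 5
    mean(abs(per[3:(n - 2)] - ma5)) / mean(per)
  } else {
    NA_real_
  }
  tibble::tibble(
    jitter_local_pct = jitter_local_pct, jitter_abs_s = jitter_abs_s,
    rap = rap, ppq5 = ppq5
  )
}

#' Amplitude-perturbation (shimmer) measures
#'
#' @param a An `amplitude_sequence` with at least 2 amplitudes (3 for APQ3).
#' @return A tibble with `shimmer_local` (mean relative consecutive
#'   difference), `shimmer_db` (mean |20 log10(A_{i+1}/A_i)|), `apq3`.
#' @export
shimmer_features <- function(a) {
  amp <- a$amplitudes
  n <- length(amp)
  if (n < 2L) stop("need at least 2 amplitudes for shimmer", call. = FALSE)
  if (any(amp <= 0)) stop("amplitudes must be positive", call. = FALSE)
  d <- abs(diff(amp))
  shimmer_local <- mean(d / amp[-n])
  shimmer_db <- mean(abs(20 * log10(amp[-1] / amp[-n])))
  apq3 <- if (n >= 3L) {
    ma3 <- (amp[1:(n - 2)] + amp[2:(n - 1)] + amp[3:n]) / 3
    mean(abs(amp[2:(n - 1)] - ma3)) / mean(amp)
  } else {
    NA_real_
  }
  tibble::tibble(shimmer_local = shimmer_local, shimmer_db = shimmer_db, apq3 = apq3)
}

#' Harmonics-to-noise ratio in dB from an autocorrelation value
#'
#' `HNR = 10 log10(r / (1 - r))` with `r` the normalized autocorrelation at
#' the pitch-period lag: r = 0.5 gives 0 dB (equal harmonic and noise
#' power), r = 0.9 gives ~9.54 dB.
#'
#' @param r Normalized autocorrelation value(s); clamped to (1e-15, 1-1e-15).
#' @return HNR in dB.
#' @export
hnr_from_r <- function(r) {
  r <- pmin(pmax(r, 1e-15), 1 - 1e-15)
  10 * log10(r / (1 - r))
}

#' Harmonics-to-noise ratio of a voiced waveform
#'
#' Per analysis frame, the normalized window-debiased autocorrelation is
#' evaluated at the frame's pitch-period lag (parabolically refined) and
#' converted to dB via [hnr_from_r()]; frame values are averaged over voiced
#' frames.
#'
#' @param w A voiced [waveform()].
#' @param p A `period_sequence` for `w` (supplies the period range).
#' @param frame_len,hop_len Framing in seconds (long frames average noise
#'   better).
#' @return Mean HNR in dB over voiced frames.
#' @export
harmonics_to_noise_ratio <- function(w, p, frame_len = 0.08, hop_len = 0.02) {
  assert_waveform(w)
  per_med <- stats::median(p$periods)
  if (!is.finite(per_med)) stop("no valid period estimate", call. = FALSE)
  x <- w$samples
  rate <- w$rate
  frame <- round(frame_len * rate)
  hop <- round(hop_len * rate)
  lag0 <- per_med * rate
  lag_max <- ceiling(lag0 * 1.3)
  if (frame <= 2 * lag_max) frame <- 2 * lag_max + 8L
  starts <- frame_starts(length(x), frame, hop)
  if (length(starts) == 0L) stop("signal too short for HNR analysis", call. = FALSE)
  vals <- c()
  for (s in starts) {
    fr <- x[s:(s + frame - 1L)]
    if (sqrt(mean(fr^2)) < 1e-8) next
    r <- frame_autocor(fr, lag_max)
    lo <- max(floor(lag0 * 0.8), 2L)
    hi <- min(ceiling(lag0 * 1.2), lag_max)
    band <- r[(lo + 1L):(hi + 1L)]
    pk <- which.max(band)
    ref <- parabolic_refine(band, pk)
    rv <- min(max(ref$height, 1e-6), 1 - 1e-6)
    if (band[pk] < 0.1) next
    vals <- c(vals, hnr_from_r(rv))
  }
  if (length(vals) == 0L) stop("no voiced frames for HNR", call. = FALSE)
  mean(vals)
}

# ---- mel filterbank / MFCC -------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank energies of a waveform
#'
#' Triangular mel filters applied to the short-time power spectrum
#' (512-point FFT, 25 ms frames / 10 ms hop at 16 kHz), floored at 1e-10.
#'
#' @param w A [waveform()].
#' @param n_filters Number of triangular mel filters (>= 13).
#' @param n_fft FFT size.
#' @param frame_len,hop_len Framing in seconds.
#' @return A list of class `filterbank_energies` with `energies`
#'   (`n_filters` x frames matrix, linear power) and `n_filters`.
#' @export
mel_filterbank_energies <- function(w, n_filters = 26, n_fft = 512,
                                    frame_len = 0.025, hop_len = 0.01) {
  assert_waveform(w)
  if (n_filters < 13) stop("need at least 13 mel filters", call. = FALSE)
  frame <- round(frame_len * w$rate)
  hop <- round(hop_len * w$rate)
  if (frame > n_fft) frame <- n_fft
  starts <- frame_starts(length(w$samples), frame, hop)
  if (length(starts) == 0L) stop("signal shorter than one analysis frame", call. = FALSE)
  win <- hann_window(frame)
  n_bins <- n_fft %/% 2L + 1L
  pow <- vapply(starts, function(s) {
    fr <- w$samples[s:(s + frame - 1L)] * win
    sp <- stats::fft(c(fr, numeric(n_fft - frame)))
    Mod(sp[seq_len(n_bins)])^2
  }, numeric(n_bins))

  mel_pts <- seq(hz_to_mel(0), hz_to_mel(w$rate / 2), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (seq_len(n_bins) - 1) * w$rate / n_fft
  fb <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  energies <- pmax(fb %*% pow, 1e-10)
  structure(list(energies = energies, n_filters = n_filters),
    class = "filterbank_energies"
  )
}

#' Mel-frequency cepstral coefficients from filterbank energies
#'
#' The k-th coefficient is the cosine-weighted sum of the log filterbank
#' outputs, `MFCC_k = sum_n log(S_n) cos(pi k / M (n - 1/2))`, computed per
#' frame and averaged over frames. A flat filterbank yields exactly zero
#' for every k >= 1.
#'
#' @param fb A `filterbank_energies` object (or a numeric matrix M x frames
#'   of linear-power energies).
#' @param K Number of coefficients (1..K); must satisfy `K < M`.
#' @return Numeric vector of length `K`.
#' @export
mel_cepstral_coefficients <- function(fb, K = 13) {
  e <- if (inherits(fb, "filterbank_energies")) fb$energies else as.matrix(fb)
  M <- nrow(e)
  if (K >= M) stop("K must be smaller than the filter count M", call. = FALSE)
  logS <- log(pmax(e, 1e-10))
  C <- outer(seq_len(K), seq_len(M), function(k, n) cos(pi * k / M * (n - 0.5)))
  rowMeans(C %*% logS)
}

# ---- schema and vector assembly -------------------------------------------

#' Default 22-entry acoustic feature schema
#'
#' Fo/Fhi/Flo, four jitter measures, three shimmer measures, HNR, and
#' MFCC 1-11. Schemas are named, ordered feature lists; CSV parsing can use
#' a different (e.g. repository-native) schema while audio extraction uses
#' this one.
#'
#' @param name Schema identifier.
#' @return A tibble of class `feature_schema` with columns `feature`, `unit`.
#' @export
default_feature_schema <- function(name = "voxfuse22") {
  s <- tibble::tibble(
    feature = c(
      "Fo", "Fhi", "Flo",
      "Jitter_pct", "Jitter_abs", "RAP", "PPQ5",
      "Shimmer", "Shimmer_dB", "APQ3", "HNR",
      paste0("MFCC", 1:11)
    ),
    unit = c(
      "Hz", "Hz", "Hz", "%", "s", "ratio", "ratio",
      "ratio", "dB", "ratio", "dB", rep("cepstral", 11)
    )
  )
  if (anyDuplicated(s$feature)) stop("schema feature names must be unique", call. = FALSE)
  attr(s, "schema_id") <- name
  class(s) <- c("feature_schema", class(s))
  s
}

#' Assemble the standardizable biomarker vector of one phonation
#'
#' Runs the full extraction chain (periods, amplitudes, F0 statistics,
#' jitter, shimmer, HNR, MFCC) and orders the result by the schema.
#'
#' @param w A preprocessed, voiced [waveform()].
#' @param schema A [default_feature_schema()]-style schema.
#' @param f0_min,f0_max F0 search range in Hz.
#' @return A named numeric vector, one finite entry per schema feature.
#' @export
assemble_biomarker_vector <- function(w, schema = default_feature_schema(),
                                      f0_min = 50, f0_max = 500) {
  p <- extract_period_sequence(w, f0_min, f0_max)
  a <- extract_amplitude_sequence(w, p)
  f0 <- f0_statistics(p)
  jit <- jitter_features(p)
  shi <- shimmer_features(a)
  hnr <- harmonics_to_noise_ratio(w, p)
  mfcc <- mel_cepstral_coefficients(mel_filterbank_energies(w), K = 13)
  pool <- c(
    Fo = f0$Fo, Fhi = f0$Fhi, Flo = f0$Flo,
    Jitter_pct = jit$jitter_local_pct, Jitter_abs = jit$jitter_abs_s,
    RAP = jit$rap, PPQ5 = jit$ppq5,
    Shimmer = shi$shimmer_local, Shimmer_dB = shi$shimmer_db, APQ3 = shi$apq3,
    HNR = hnr,
    stats::setNames(mfcc[1:11], paste0("MFCC", 1:11))
  )
  missing <- setdiff(schema$feature, names(pool))
  if (length(missing)) {
    stop("schema features not computable from audio: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- pool[schema$feature]
  if (any(!is.finite(out))) stop("non-finite biomarker value extracted", call. = FALSE)
  out
}

#' Extract a biomarker feature table from a set of waveforms
#'
#' Tidy front door to [assemble_biomarker_vector()]: takes a tibble with a
#' `wave` list-column (e.g. from [generate_cohort()] in audio mode) and
#' appends one column per schema feature.
#'
#' @param data A tibble with a `wave` list-column of [waveform()]s.
#' @param schema Feature schema.
#' @param preprocess Optional [preprocess_config()] applied to each wave
#'   first (`NULL` = waves are already clean).
#' @return `data` with the schema's feature columns appended.
#' @export
extract_features <- function(data, schema = default_feature_schema(), preprocess = NULL) {
  stopifnot(is.data.frame(data), "wave" %in% names(data))
  rows <- purrr::map(data$wave, function(w) {
    if (!is.null(preprocess)) w <- preprocess_audio(w, preprocess)
    as.list(assemble_biomarker_vector(w, schema))
  })
  dplyr::bind_cols(data, dplyr::bind_rows(rows))
}

# ---- standardization -------------------------------------------------------

#' Fit per-feature z-score standardization on a training table
#'
#' Statistics (mean and population standard deviation) are computed on the
#' training rows only and then applied unchanged to validation/test data —
#' fitting on all rows would leak test-set location/scale into training.
#'
#' @param data A data frame of numeric feature columns (rows = training
#'   samples).
#' @param features Character vector of columns to standardize (default: all
#'   numeric columns).
#' @return An object of class `standardization_stats`.
#' @export
fit_standardization <- function(data, features = NULL) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (nrow(data) < 2L) stop("need at least 2 training rows to fit", call. = FALSE)
  mu <- vapply(features, function(f) mean(data[[f]]), 0)
  sigma <- vapply(features, function(f) {
    v <- data[[f]]
    sqrt(mean((v - mean(v))^2)) # population SD
  }, 0)
  structure(
    list(features = features, mu = mu, sigma = sigma),
    class = "standardization_stats"
  )
}

#' Apply fitted z-score standardization
#'
#' @param data A data frame containing the fitted feature columns.
#' @param stats A `standardization_stats` from [fit_standardization()].
#' @return `data` with the fitted columns replaced by `(x - mu) / sigma`;
#'   zero-variance features map to 0 with a warning.
#' @export
apply_standardization <- function(data, stats) {
  if (!inherits(stats, "standardization_stats")) {
    stop("standardization must be fitted before it is applied", call. = FALSE)
  }
  zero <- stats$features[stats$sigma == 0]
  if (length(zero)) {
    warning(
      "zero-variance feature(s) mapped to 0: ", paste(zero, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in stats$features) {
    if (stats$sigma[[f]] == 0) {
      data[[f]] <- rep(0, nrow(data))
    } else {
      data[[f]] <- (data[[f]] - stats$mu[[f]]) / stats$sigma[[f]]
    }
  }
  data
}

# ---- feature-table CSV I/O -------------------------------------------------

#' Read a feature table in the UCI Parkinson's CSV layout
#'
#' Header row of feature names, one row per recording, a binary label
#' column (Healthy = 0, PD = 1) and a recording identifier from which the
#' subject is parsed (the repository convention `phon_R01_S01_1` encodes
#' the subject as the `S..` field). Rows with missing or non-numeric
#' feature cells are dropped with a message. Unknown feature columns are
#' kept as passthrough.
#'
#' @param path CSV path.
#' @param id_col Name of the recording-identifier column.
#' @param label_col Name of the binary label column.
#' @return A tibble with `sample_id`, `subject_id`, `label` and the numeric
#'   feature columns.
#' @export
read_feature_csv <- function(path, id_col = "name", label_col = "status") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(raw)) stop("missing id column: ", id_col, call. = FALSE)
  if (!label_col %in% names(raw)) stop("missing label column: ", label_col, call. = FALSE)
  feat_cols <- setdiff(names(raw), c(id_col, label_col))
  num <- lapply(raw[feat_cols], function(v) suppressWarnings(as.numeric(v)))
  bad <- Reduce(`|`, lapply(num, function(v) is.na(v)))
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing or non-numeric values")
  }
  keep <- !bad
  subject <- vapply(strsplit(raw[[id_col]], "_"), function(p) {
    s <- grep("^S\\d+", p, value = TRUE)
    if (length(s)) s[1] else p[1]
  }, "")
  out <- tibble::tibble(
    sample_id = raw[[id_col]][keep],
    subject_id = subject[keep],
    label = as.integer(raw[[label_col]][keep])
  )
  dplyr::bind_cols(out, tibble::as_tibble(lapply(num, `[`, keep)))
}

#' Write a feature table as CSV
#'
#' Round-trips with [read_feature_csv()]: full double precision is kept.
#'
#' @param data Tibble with `sample_id`, `subject_id`, `label` and feature
#'   columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(data, path) {
  out <- data
  out$name <- out$sample_id
  out$status <- out$label
  out <- out[, c("name", "status", setdiff(names(data), c("sample_id", "subject_id", "label")))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
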