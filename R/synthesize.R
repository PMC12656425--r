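#' Specification of a synthetic sustained phonation
#'
#' Describes a quasi-periodic voiced signal of the kind produced in a
#' sustained-vowel task: a band-limited harmonic pulse train whose per-cycle
#' period and amplitude are perturbed multiplicatively (the generative
#' analogues of jitter and shimmer) and to which white noise is added at a
#' controlled harmonics-to-noise power ratio. The realized per-cycle
#' sequences are recorded as ground truth, so perturbation estimators can be
#' validated against the exact quantities they target.
#'
#' @param f0 Nominal fundamental frequency in Hz, in (50, 500).
#' @param n_harmonics Number of harmonics; amplitudes roll off as 1/k.
#' @param duration Voiced duration in seconds.
#' @param rate Sampling rate in Hz; must satisfy `rate >= 2 * f0 * n_harmonics`.
#' @param jitter_rel Relative standard deviation of the per-cycle period
#'   multiplier (e.g. 0.01 = 1 percent jitter at source).
#' @param shimmer_rel Relative standard deviation of the per-cycle amplitude
#'   multiplier.
#' @param hnr_db Target harmonics-to-noise power ratio in dB over the voiced
#'   region; `Inf` means no additive noise.
#' @param lead_silence,tail_silence Seconds of digital silence around the
#'   voiced region.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A list of class `phonation_spec`.
#' @export
phonation_spec <- function(f0 = 150, n_harmonics = 10, duration = 1, rate = 16000,
                           jitter_rel = 0, shimmer_rel = 0, hnr_db = Inf,
                           lead_silence = 0, tail_silence = 0, seed = 1L) {
  spec <- list(
    f0 = f0, n_harmonics = n_harmonics, duration = duration, rate = rate,
    jitter_rel = jitter_rel, shimmer_rel = shimmer_rel, hnr_db = hnr_db,
    lead_silence = lead_silence, tail_silence = tail_silence, seed = as.integer(seed)
  )
  if (f0 <= 50 || f0 >= 500) stop("f0 must lie in (50, 500) Hz", call. = FALSE)
  if (jitter_rel < 0 || shimmer_rel < 0) stop("perturbation levels must be >= 0", call. = FALSE)
  if (rate < 2 * f0 * n_harmonics) {
    stop("rate must be at least 2 * f0 * n_harmonics (Nyquist)", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  structure(spec, class = "phonation_spec")
}

#' Synthesize a phonation with known per-cycle ground truth
#'
#' Cycle-by-cycle synthesis: period multipliers are drawn i.i.d.
#' N(1, jitter_rel) and amplitude multipliers N(1, shimmer_rel); within cycle
#' i the waveform is `A_i * sum_k sin(2 pi k phase) / k` over `n_harmonics`
#' harmonics (a band-limited sawtooth-like vowel proxy with a sharp,
#' markable peak per cycle). White Gaussian noise is rescaled to the exact
#' RMS that realizes the requested harmonics-to-noise power ratio over the
#' voiced region.
#'
#' @param spec A [phonation_spec()].
#' @return A list with elements `wave` (a [waveform()]) and `truth`, where
#'   `truth` holds `periods` (s), `amplitudes`, `noise_rms`, and
#'   `active_interval` = c(start_s, end_s) of the voiced region.
#' @examples
#' ph <- generate_phonation(phonation_spec(f0 = 120, duration = 0.5, jitter_rel = 0.02))
#' length(ph$truth$periods)
#' @export
generate_phonation <- function(spec) {
  stopifnot(inherits(spec, "phonation_spec"))
  with_local_seed(spec$seed, {
    t0 <- 1 / spec$f0
    n_max <- ceiling(spec$duration / t0 * 1.6) + 4L
    mults <- pmin(pmax(stats::rnorm(n_max, 1, spec$jitter_rel), 0.5), 1.5)
    periods <- t0 * mults
    ends <- cumsum(periods)
    n_cyc <- max(which(ends <= spec$duration + t0), 2L)
    periods <- periods[seq_len(n_cyc)]
    ends <- ends[seq_len(n_cyc)]
    amps <- pmax(stats::rnorm(n_cyc, 1, spec$shimmer_rel), 0.05)

    voiced_dur <- ends[n_cyc]
    n_s <- floor(voiced_dur * spec$rate)
    t <- (seq_len(n_s) - 1) / spec$rate
    cyc <- findInterval(t, c(0, ends[-n_cyc]))
    start_of <- c(0, ends[-n_cyc])
    phase <- (t - start_of[cyc]) / periods[cyc]
    s <- numeric(n_s)
    for (k in seq_len(spec$n_harmonics)) s <- s + sin(2 * pi * k * phase) / k
    s <- s * amps[cyc]

    harmonic_rms <- sqrt(mean(s^2))
    noise_rms <- 0
    if (is.finite(spec$hnr_db)) {
      target_rms <- harmonic_rms / sqrt(10^(spec$hnr_db / 10))
      eps <- stats::rnorm(n_s)
      eps <- eps - mean(eps)
      eps <- eps * (target_rms / sqrt(mean(eps^2)))
      s <- s + eps
      noise_rms <- target_rms
    }
    peak <- max(abs(s))
    scale <- 0.9 / peak
    s <- s * scale

    lead <- numeric(round(spec$lead_silence * spec$rate))
    tail <- numeric(round(spec$tail_silence * spec$rate))
    w <- waveform(c(lead, s, tail), spec$rate)
    truth <- list(
      periods = periods,
      amplitudes = amps,
      noise_rms = noise_rms * scale,
      harmonic_rms = harmonic_rms * scale,
      active_interval = c(length(lead), length(lead) + n_s) / spec$rate
    )
    list(wave = w, truth = truth)
  })
}

#' Oracle perturbation measures from realized ground-truth sequences
#'
#' Applies the local jitter / shimmer definitions directly to the generator's
#' realized per-cycle sequences; these are the reference values that the
#' audio-domain estimators are judged against.
#'
#' @param truth The `truth` element of [generate_phonation()].
#' @return A tibble with one row: `jitter_local_pct`, `shimmer_local`.
#' @export
oracle_perturbation <- function(truth) {
  p <- truth$periods
  a <- truth$amplitudes
  tibble::tibble(
    jitter_local_pct = mean(abs(diff(p)) / p[-length(p)]) * 100,
    shimmer_local = mean(abs(diff(a)) / a[-length(a)])
  )
}

#' Specification of a synthetic two-class cohort
#'
#' Emulates the structure of a clinical voice study: subjects carry a binary
#' diagnosis; each subject contributes several recordings; subject-level
#' random effects induce within-class correlation (why subject-wise splits
#' matter); class-conditional profiles of (jitter_rel, shimmer_rel, hnr_db)
#' separate the classes in biomarker space; an optional embedding block is
#' drawn from class-conditional Gaussians at a controlled Mahalanobis
#' separation, standing in for the learned speech-embedding modality.
#'
#' @param n_subjects Number of subjects.
#' @param samples_per_subject Recordings per subject.
#' @param prop_pd Proportion of subjects in the PD class (label 1).
#' @param pd_profile,control_profile Named lists with `jitter_rel`,
#'   `shimmer_rel`, `hnr_db`. Defaults are directionally consistent with
#'   hypokinetic dysarthria (higher perturbation, lower HNR in PD); they are
#'   toolkit defaults, not literature values.
#' @param subject_sd Log-scale SD of the subject random effect on the
#'   perturbation parameters (and dB SD on HNR).
#' @param embedding_dim Dimension of the synthetic embedding block (0 = none).
#' @param embedding_separation Mahalanobis distance between class means of
#'   the embedding block (identity covariance).
#' @param embedding_subject_sd SD of the subject random intercept added to
#'   embeddings.
#' @param n_nuisance Number of uninformative N(0,1) biomarker columns
#'   appended in feature mode (pads the biomarker block to schema size).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, samples_per_subject = 5, prop_pd = 0.5,
                        pd_profile = list(jitter_rel = 0.02, shimmer_rel = 0.06, hnr_db = 12),
                        control_profile = list(jitter_rel = 0.005, shimmer_rel = 0.02, hnr_db = 22),
                        subject_sd = 0.15, embedding_dim = 32,
                        embedding_separation = 3, embedding_subject_sd = 0.3,
                        n_nuisance = 19, seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  n_pd <- round(n_subjects * prop_pd)
  if (n_pd < 1 || n_pd > n_subjects - 1) {
    stop("both classes must be represented", call. = FALSE)
  }
  if (embedding_separation < 0) stop("embedding_separation must be >= 0", call. = FALSE)
  structure(
    list(
      n_subjects = n_subjects, samples_per_subject = samples_per_subject,
      prop_pd = prop_pd, pd_profile = pd_profile, control_profile = control_profile,
      subject_sd = subject_sd, embedding_dim = embedding_dim,
      embedding_separation = embedding_separation,
      embedding_subject_sd = embedding_subject_sd,
      n_nuisance = n_nuisance, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

draw_subject_params <- function(profile, subject_sd, n) {
  tibble::tibble(
    jitter_rel = profile$jitter_rel * exp(stats::rnorm(n, 0, subject_sd)),
    shimmer_rel = profile$shimmer_rel * exp(stats::rnorm(n, 0, subject_sd)),
    hnr_db = profile$hnr_db + stats::rnorm(n, 0, subject_sd * 10)
  )
}

#' Generate a labeled synthetic cohort
#'
#' In feature mode (`audio = FALSE`, the default) each sample carries a
#' biomarker block built from its realized perturbation parameters (the
#' three informative columns `bio_jitter`, `bio_shimmer`, `bio_hnr` plus
#' measurement noise and `n_nuisance` uninformative columns) and, if
#' `embedding_dim > 0`, an embedding block `emb_*` from class-conditional
#' Gaussians. In audio mode each sample additionally carries a synthesized
#' phonation waveform and its ground truth, ready for the extraction
#' pipeline.
#'
#' @param spec A [cohort_spec()].
#' @param audio If `TRUE`, synthesize a waveform per sample (slower).
#' @param phonation_duration Voiced seconds per synthesized phonation.
#' @return A tibble with columns `sample_id`, `subject_id`, `label` (0 =
#'   healthy, 1 = PD), the realized generative parameters, biomarker columns
#'   `bio_*`, embedding columns `emb_*`, and in audio mode list-columns
#'   `wave` and `truth`.
#' @export
generate_cohort <- function(spec, audio = FALSE, phonation_duration = 0.6) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    n_pd <- round(spec$n_subjects * spec$prop_pd)
    labels <- c(rep(1L, n_pd), rep(0L, spec$n_subjects - n_pd))
    subj_pd <- draw_subject_params(spec$pd_profile, spec$subject_sd, n_pd)
    subj_ct <- draw_subject_params(spec$control_profile, spec$subject_sd, spec$n_subjects - n_pd)
    subj <- dplyr::bind_rows(subj_pd, subj_ct)
    subj$subject_id <- sprintf("S%02d", seq_len(spec$n_subjects))
    subj$label <- labels

    d <- tidyr::expand_grid(
      subject_id = subj$subject_id,
      rep = seq_len(spec$samples_per_subject)
    )
    d <- dplyr::left_join(d, subj, by = "subject_id")
    n <- nrow(d)
    # within-subject (per-recording) variation around the subject mean
    d$jitter_rel <- d$jitter_rel * exp(stats::rnorm(n, 0, 0.05))
    d$shimmer_rel <- d$shimmer_rel * exp(stats::rnorm(n, 0, 0.05))
    d$hnr_db <- d$hnr_db + stats::rnorm(n, 0, 0.5)
    d$sample_id <- sprintf("%s_R%02d", d$subject_id, d$rep)

    out <- tibble::tibble(
      sample_id = d$sample_id, subject_id = d$subject_id, label = d$label,
      jitter_rel = d$jitter_rel, shimmer_rel = d$shimmer_rel, hnr_db = d$hnr_db
    )

    # biomarker block: informative columns = noisy measurements of the
    # generative parameters, on scales resembling their acoustic counterparts
    meas <- function(x, rel_sd = 0.1) x * exp(stats::rnorm(n, 0, rel_sd))
    bio <- cbind(
      bio_jitter = meas(d$jitter_rel * 100),
      bio_shimmer = meas(d$shimmer_rel),
      bio_hnr = d$hnr_db + stats::rnorm(n, 0, 1)
    )
    if (spec$n_nuisance > 0) {
      nz <- matrix(stats::rnorm(n * spec$n_nuisance), n)
      colnames(nz) <- sprintf("bio_noise%02d", seq_len(spec$n_nuisance))
      bio <- cbind(bio, nz)
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(bio))

    if (spec$embedding_dim > 0) {
      u <- stats::rnorm(spec$embedding_dim)
      u <- u / sqrt(sum(u^2))
      delta <- spec$embedding_separation * u
      subj_int <- matrix(
        stats::rnorm(spec$n_subjects * spec$embedding_dim, 0, spec$embedding_subject_sd),
        spec$n_subjects
      )
      rownames(subj_int) <- subj$subject_id
      emb <- matrix(stats::rnorm(n * spec$embedding_dim), n)
      emb <- emb + subj_int[d$subject_id, , drop = FALSE]
      emb <- emb + outer(as.numeric(d$label), delta)
      colnames(emb) <- sprintf("emb_%03d", seq_len(spec$embedding_dim))
      out <- dplyr::bind_cols(out, tibble::as_tibble(emb))
    }

    if (audio) {
      seeds <- sample.int(.Machine$integer.max, n)
      synth <- purrr::map(seq_len(n), function(i) {
        generate_phonation(phonation_spec(
          f0 = stats::runif(1, 110, 190),
          duration = phonation_duration,
          jitter_rel = min(d$jitter_rel[i], 0.2),
          shimmer_rel = min(d$shimmer_rel[i], 0.5),
          hnr_db = d$hnr_db[i],
          lead_silence = 0.05, tail_silence = 0.05,
          seed = seeds[i]
        ))
      })
      out$wave <- purrr::map(synth, "wave")
      out$truth <- purrr::map(synth, "truth")
    }
    out
  })
}
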