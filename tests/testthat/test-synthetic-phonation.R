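test_that("generator is a pure function of its spec", {
  sp <- phonation_spec(f0 = 150, jitter_rel = 0.01, shimmer_rel = 0.03, hnr_db = 15, seed = 7)
  a <- generate_phonation(sp)
  b <- generate_phonation(sp)
  expect_identical(a$wave$samples, b$wave$samples)
  expect_identical(a$truth, b$truth)
  # different seed, different realization
  sp2 <- phonation_spec(f0 = 150, jitter_rel = 0.01, shimmer_rel = 0.03, hnr_db = 15, seed = 8)
  expect_false(identical(generate_phonation(sp2)$wave$samples, a$wave$samples))
})

test_that("unperturbed phonation has constant truth sequences", {
  g <- generate_phonation(phonation_spec(f0 = 200, seed = 1))
  expect_true(all(g$truth$periods == 1 / 200))
  expect_true(all(g$truth$amplitudes == 1))
  expect_equal(g$truth$noise_rms, 0)
  # cycles tile the requested duration
  expect_lt(abs(sum(g$truth$periods) - 1), 1 / 200 + 1e-12)
})

test_that("realized truth matches requested perturbation magnitudes in expectation", {
  # aggregate over seeds: sd of multipliers ~ requested rel level
  per_mults <- unlist(lapply(1:10, function(s) {
    g <- generate_phonation(phonation_spec(f0 = 150, jitter_rel = 0.02, seed = s))
    g$truth$periods * 150
  }))
  expect_lt(abs(stats::sd(per_mults) - 0.02), 0.004)
  amp_mults <- unlist(lapply(1:10, function(s) {
    g <- generate_phonation(phonation_spec(f0 = 150, shimmer_rel = 0.05, seed = s))
    g$truth$amplitudes
  }))
  expect_lt(abs(stats::sd(amp_mults) - 0.05), 0.01)
})

test_that("additive noise realizes the requested HNR exactly by construction", {
  g <- generate_phonation(phonation_spec(f0 = 150, hnr_db = 10, seed = 3))
  # harmonic and noise RMS are recorded post-scaling; their power ratio is
  # the requested HNR by construction
  expect_equal(
    10 * log10(g$truth$harmonic_rms^2 / g$truth$noise_rms^2),
    10,
    tolerance = 1e-12
  )
})

test_that("lead and tail silence are digital zeros around the active interval", {
  g <- generate_phonation(phonation_spec(
    f0 = 150, duration = 0.4,
    lead_silence = 0.05, tail_silence = 0.07, seed = 2
  ))
  rate <- g$wave$rate
  n_lead <- round(0.05 * rate)
  expect_true(all(g$wave$samples[seq_len(n_lead)] == 0))
  expect_true(all(utils::tail(g$wave$samples, round(0.07 * rate) - 1) == 0))
  expect_equal(g$truth$active_interval[1], 0.05)
})

test_that("cohort generation has study structure and is reproducible", {
  spec <- cohort_spec(n_subjects = 10, samples_per_subject = 3, seed = 5)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh), 30)
  expect_equal(length(unique(coh$subject_id)), 10)
  expect_setequal(unique(coh$label), c(0L, 1L))
  # labels are constant within subject (diagnosis is a subject property)
  per_subj <- tapply(coh$label, coh$subject_id, function(l) length(unique(l)))
  expect_true(all(per_subj == 1))
  expect_equal(sum(grepl("^bio_", names(coh))), 22)
  expect_equal(sum(grepl("^emb_", names(coh))), 32)
  expect_identical(generate_cohort(spec), coh)
})

test_that("cohort audio mode carries waves whose truth matches the parameters", {
  spec <- cohort_spec(n_subjects = 4, samples_per_subject = 1, seed = 5)
  coh <- generate_cohort(spec, audio = TRUE, phonation_duration = 0.5)
  expect_true(all(c("wave", "truth") %in% names(coh)))
  expect_true(all(vapply(coh$wave, inherits, TRUE, "waveform")))
  # PD rows were synthesized with larger perturbation than controls
  oj <- vapply(coh$truth, function(t) oracle_perturbation(t)$jitter_local_pct, 0)
  expect_gt(mean(oj[coh$label == 1]), mean(oj[coh$label == 0]))
})

test_that("cohort_spec validates its arguments", {
  expect_error(cohort_spec(n_subjects = 1), "2 subjects")
  expect_error(cohort_spec(prop_pd = 0), "both classes")
  expect_error(cohort_spec(embedding_separation = -1), ">= 0")
})
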