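# Brute-force NT-Xent: double loop over ordered positive pairs.
ntx_brute <- function(h, tau) {
  nv <- nrow(h)
  v <- h / sqrt(rowSums(h^2))
  sim <- function(i, j) sum(v[i, ] * v[j, ])
  partner <- ifelse(seq_len(nv) %% 2 == 1, seq_len(nv) + 1, seq_len(nv) - 1)
  total <- 0
  for (i in seq_len(nv)) {
    denom <- 0
    for (k in seq_len(nv)) if (k != i) denom <- denom + exp(sim(i, k) / tau)
    total <- total - log(exp(sim(i, partner[i]) / tau) / denom)
  }
  total / nv
}

test_that("nt_xent_loss matches a hand-computed two-pair example", {
  # two utterances, orthogonal pairs
  h <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  tau <- 0.5
  # anchor 1: pos sim 1, negatives sims (0, 0)
  l1 <- -log(exp(1 / tau) / (exp(1 / tau) + 2 * exp(0)))
  expect_equal(nt_xent_loss(h, tau), l1, tolerance = 1e-12)
})

test_that("single-utterance batches have zero loss", {
  h <- matrix(rnorm(2 * 5), 2, 5)
  h[2, ] <- h[1, ] # identical views: only the positive remains
  expect_equal(nt_xent_loss(h, 0.1), 0)
})

test_that("loss is invariant to relabeling utterance order", {
  set.seed(3)
  h <- matrix(rnorm(8 * 16), 8, 16)
  # swap utterances 1 and 3 (rows 1:2 <-> 5:6)
  h2 <- h[c(5, 6, 3, 4, 1, 2, 7, 8), ]
  expect_equal(nt_xent_loss(h, 0.07), nt_xent_loss(h2, 0.07), tolerance = 1e-12)
})

test_that("analytic NT-Xent gradients agree with finite differences", {
  set.seed(11)
  h <- matrix(rnorm(6 * 8), 6, 8)
  tau <- 0.2
  g <- voxfuse:::nt_xent_core(h, tau, want_grads = TRUE)
  fd_h <- matrix(fd_gradient(function(v) nt_xent_loss(matrix(v, 6, 8), tau), as.numeric(h)), 6, 8)
  expect_lt(max(abs(g$dh - fd_h)), 1e-7)
  fd_tau <- fd_gradient(function(tt) nt_xent_loss(h, tt[1]), tau)
  expect_lt(abs(g$dtau - fd_tau), 1e-7)
})

test_that("nt_xent_loss validates its input", {
  expect_error(nt_xent_loss(matrix(1, 3, 2), 0.1), "even")
  expect_error(nt_xent_loss(matrix(1:4, 2, 2), -1), "tau")
  expect_error(nt_xent_loss(rbind(c(0, 0), c(1, 1)), 0.1), "zero-norm")
})

test_that("encoder produces the documented token geometry", {
  enc <- encoder_config(d = 16, d_prime = 8, seed = 1)
  expect_equal(enc$config$total_stride, 320)
  w <- generate_phonation(phonation_spec(f0 = 150, duration = 0.5, seed = 1))$wave
  z <- encode(w, enc)
  expect_equal(ncol(z), 16)
  # ~50 tokens per second at 16 kHz
  expect_lt(abs(nrow(z) - 0.5 * 50), 3)
  # doubling the duration about doubles the token count
  w2 <- generate_phonation(phonation_spec(f0 = 150, duration = 1, seed = 1))$wave
  expect_lt(abs(nrow(encode(w2, enc)) / nrow(z) - 2), 0.15)
})

test_that("embedding is deterministic and has the projected dimension", {
  enc <- encoder_config(d = 16, d_prime = 8, seed = 2)
  w <- generate_phonation(phonation_spec(f0 = 150, duration = 0.5, seed = 1))$wave
  e1 <- project(embed_utterance(w, enc), enc)
  e2 <- project(embed_utterance(w, enc), enc)
  expect_identical(e1, e2)
  expect_equal(length(e1), 8)
})

test_that("augmentation draws are reproducible and alter the signal", {
  w <- generate_phonation(phonation_spec(f0 = 150, duration = 0.5, seed = 1))$wave
  cfg <- augmentation_config()
  a1 <- augment_view(w, cfg, draw = 5)
  a2 <- augment_view(w, cfg, draw = 5)
  expect_identical(a1$samples, a2$samples)
  a3 <- augment_view(w, cfg, draw = 6)
  expect_false(identical(a1$samples, a3$samples))
  expect_equal(length(a1$samples), length(w$samples))
})

test_that("contrastive pretraining reduces the loss and aligns same-source views", {
  # a 4 kHz corpus of two-harmonic sources with well-spread fundamentals:
  # diverse enough that in-batch negatives are genuinely distinguishable
  corpus <- voxfuse:::with_local_seed(11, lapply(1:64, function(i) {
    f0 <- stats::runif(1, 90, 250)
    t <- seq(0, 0.5, by = 1 / 4000)
    waveform(
      0.8 * sin(2 * pi * f0 * t) + 0.3 * sin(2 * pi * 2 * f0 * t) +
        0.02 * stats::rnorm(length(t)),
      4000
    )
  }))
  ac <- augmentation_config(
    time_mask_max = 0.1, noise_snr_range = c(20, 25), shift_max_frac = 0.05
  )
  enc <- encoder_config(d = 32, d_prime = 16, rate = 4000, seed = 2)
  trained <- pretrain_contrastive(corpus, enc, ac,
    epochs = 5, batch_size = 8, lr = 3e-3, seed = 7
  )
  h <- trained$history
  expect_equal(nrow(h), 5)
  expect_lt(h$loss[5], h$loss[1])
  # on average, two augmented views of one utterance end up closer than
  # views of different utterances
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  same <- c()
  cross <- c()
  for (i in seq(1, 40, by = 2)) {
    e1 <- embed_utterance(augment_view(corpus[[i]], ac, draw = 1000 + i), trained)
    e2 <- embed_utterance(augment_view(corpus[[i]], ac, draw = 2000 + i), trained)
    e3 <- embed_utterance(augment_view(corpus[[i + 1]], ac, draw = 3000 + i), trained)
    same <- c(same, cos(e1, e2))
    cross <- c(cross, cos(e1, e3))
  }
  expect_gt(mean(same), mean(cross))
})

test_that("an external encoder can replace the built-in one", {
  fake <- external_encoder(function(w) {
    matrix(c(mean(w$samples), stats::sd(w$samples)), 1, 2)
  }, d = 2)
  w <- generate_phonation(phonation_spec(f0 = 150, duration = 0.3, seed = 1))$wave
  z <- encode(w, fake)
  expect_equal(dim(z), c(1, 2))
})
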