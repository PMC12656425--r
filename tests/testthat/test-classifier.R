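tiny_model <- function(seed = 1, ...) {
  fusion_classifier(
    n_bio = 4, n_emb = 6, hidden = 8, n_tokens = 2, n_heads = 2,
    ffn_dim = 5, head_dim = 6, dropout = 0.3, seed = seed, ...
  )
}

test_that("fuse concatenates biomarkers first and validates shape", {
  f <- fuse(1:3, 4:6)
  expect_equal(f, c(1, 2, 3, 4, 5, 6))
  m <- fuse(matrix(1:6, 2), matrix(7:14, 2))
  expect_equal(dim(m), c(2, 7))
  expect_error(fuse(matrix(1, 2, 3), matrix(1, 3, 2)), "sample counts")
  expect_error(fuse(c(1, NA), c(1, 2)), "finite")
})

test_that("architecture constraints are enforced at construction", {
  expect_error(fusion_classifier(hidden = 510, n_tokens = 8), "divisible")
  expect_error(fusion_classifier(hidden = 512, n_tokens = 8, n_heads = 3), "divisible")
  expect_error(fusion_classifier(dropout = 1), "dropout")
})

test_that("forward pass emits normalized probabilities with correct shape", {
  m <- tiny_model()
  x <- matrix(rnorm(5 * 10), 5)
  out <- voxfuse:::classifier_forward(m, x, train = FALSE)
  expect_equal(dim(out$probs), c(5, 2))
  expect_true(all(out$probs > 0))
  expect_equal(rowSums(out$probs), rep(1, 5), tolerance = 1e-12)
  expect_error(voxfuse:::classifier_forward(m, matrix(0, 2, 9)), "width")
})

test_that("evaluation mode is deterministic; training mode drops out", {
  m <- tiny_model()
  x <- matrix(rnorm(4 * 10), 4)
  p1 <- voxfuse:::classifier_forward(m, x, train = FALSE)$probs
  p2 <- voxfuse:::classifier_forward(m, x, train = FALSE)$probs
  expect_identical(p1, p2)
  set.seed(1)
  t1 <- voxfuse:::classifier_forward(m, x, train = TRUE)$probs
  set.seed(2)
  t2 <- voxfuse:::classifier_forward(m, x, train = TRUE)$probs
  expect_false(identical(t1, t2)) # dropout masks differ across draws
})

test_that("zeroed interiors reduce both blocks to their skip connections", {
  # width-matched config (n_in = hidden = 16) so the Block A skip P can be
  # set to the identity; all other weights zeroed. Block A then outputs
  # exactly x, Block B's interior contributes nothing (zero attention/FFN
  # weights and zero LN gains), and the whole-block residual carries x to
  # the head untouched.
  m0 <- fusion_classifier(
    n_bio = 4, n_emb = 12, hidden = 16, n_tokens = 4,
    n_heads = 2, ffn_dim = 8, head_dim = 6, dropout = 0.5
  )
  z <- voxfuse:::params_map(function(p) p * 0, m0$params)
  z$a$P <- diag(16)
  m0$params <- z
  x16 <- matrix(rnorm(3 * 16), 3, 16)
  fw <- voxfuse:::classifier_forward(m0, x16, train = FALSE)
  # with a fully zeroed head the logits are equal -> probs exactly 0.5
  expect_equal(as.numeric(fw$probs), rep(0.5, 6))
  # expose the first two hidden dims through an identity-wired head
  m0$params$head$W3 <- matrix(0, 16, 6)
  m0$params$head$W3[1, 1] <- 1
  m0$params$head$W3[2, 2] <- 1
  m0$params$head$bn_gamma <- rep(1, 6)
  m0$params$head$W4 <- matrix(0, 6, 2)
  m0$params$head$W4[1, 1] <- 1
  m0$params$head$W4[2, 2] <- 1
  xp <- abs(x16) # positive inputs pass the head ReLU unchanged
  fw <- voxfuse:::classifier_forward(m0, xp, train = FALSE)
  # eval-mode BN with fresh running stats (mean 0, var 1) divides by
  # sqrt(1 + eps); apart from that the logits are the skipped input itself
  expect_lt(max(abs(fw$logits - xp[, 1:2] / sqrt(1 + 1e-5))), 1e-12)
})

test_that("analytic gradients match finite differences on every parameter", {
  m <- fusion_classifier(
    n_bio = 4, n_emb = 6, hidden = 8, n_tokens = 2, n_heads = 2,
    ffn_dim = 5, head_dim = 6, dropout = 0, seed = 1 # FD needs determinism
  )
  set.seed(5)
  x <- matrix(rnorm(6 * 10), 6)
  y <- cbind(c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1))
  res <- voxfuse:::classifier_loss_grads(m, x, y, train = TRUE)
  leaves <- voxfuse:::params_leaves(m$params)
  gleaves <- voxfuse:::params_leaves(res$grads)
  worst <- 0
  for (key in names(leaves)) {
    v <- leaves[[key]]
    take <- seq_len(min(4L, length(v))) # spot-check a few entries per tensor
    for (i in take) {
      f <- function(val) {
        mm <- m
        vv <- v
        vv[i] <- val
        mm$params <- voxfuse:::params_set_leaf(mm$params, key, vv)
        voxfuse:::classifier_loss_grads(mm, x, y, train = TRUE)$loss
      }
      fd <- (f(v[i] + 1e-5) - f(v[i] - 1e-5)) / 2e-5
      an <- gleaves[[key]][i]
      # the floor absorbs FD roundoff (~1e-12/h) on dead-ReLU entries whose
      # true gradient is exactly zero
      denom <- max(abs(fd), abs(an), 1e-6)
      worst <- max(worst, abs(fd - an) / denom)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("batch-norm running statistics update only in training mode", {
  m <- tiny_model()
  x <- matrix(rnorm(8 * 10, mean = 2), 8)
  before <- m$state$bn_a$mean
  out_eval <- voxfuse:::classifier_forward(m, x, train = FALSE)
  expect_identical(out_eval$model$state$bn_a$mean, before)
  set.seed(1)
  out_train <- voxfuse:::classifier_forward(m, x, train = TRUE)
  expect_false(identical(out_train$model$state$bn_a$mean, before))
})

test_that("predict returns a tidy per-sample tibble", {
  m <- tiny_model()
  x <- matrix(rnorm(4 * 10), 4)
  p <- predict(m, x)
  expect_s3_class(p, "tbl_df")
  expect_named(p, c("p_healthy", "p_pd", "pred_class", "confidence"))
  expect_true(all(p$pred_class %in% c("healthy", "pd")))
  expect_equal(p$confidence, pmax(p$p_healthy, p$p_pd))
  expect_equal(p$p_healthy + p$p_pd, rep(1, 4), tolerance = 1e-12)
})

test_that("cross_entropy matches the closed form and respects the floor", {
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy(probs, c(0, 1)), -mean(log(c(0.9, 0.8))))
  # certain wrong prediction is floored, not infinite
  hard <- rbind(c(1, 0))
  expect_true(is.finite(cross_entropy(hard, 1)))
})

test_that("parameter masks freeze the masked entries through an update", {
  m <- tiny_model()
  mask <- lapply(m$params, function(g) lapply(g, function(x) x * 0 + 1))
  mask$a$W1 <- mask$a$W1 * 0 # freeze W1 at its initial value... which masking zeroes
  masked <- voxfuse:::apply_param_mask(m$params, mask)
  expect_true(all(masked$a$W1 == 0))
  expect_identical(masked$b, m$params$b)
})
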