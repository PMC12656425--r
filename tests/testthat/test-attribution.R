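planted_data <- function(n = 300, seed = 1) {
  voxfuse:::with_local_seed(seed, tibble::tibble(
    label = rep(c(0L, 1L), each = n / 2),
    bio_signal = stats::rnorm(n) + 2 * rep(c(0, 1), each = n / 2),
    bio_n1 = stats::rnorm(n), bio_n2 = stats::rnorm(n),
    bio_n3 = stats::rnorm(n), bio_n4 = stats::rnorm(n)
  ))
}

test_that("MDI importance is normalized, sorted, and reproducible", {
  dat <- planted_data()
  r <- mdi_importance(dat)
  expect_s3_class(r, "attribution_report")
  expect_equal(sum(r$scores$score), 1, tolerance = 1e-12)
  expect_true(all(diff(r$scores$score) <= 0))
  expect_identical(r$scores, mdi_importance(dat)$scores)
})

test_that("MDI needs both classes and at least one feature column", {
  dat <- planted_data()
  expect_error(mdi_importance(dat[dat$label == 1, ]), "both classes")
  expect_error(mdi_importance(dat, block = "embeddings"), "no embeddings")
})

test_that("pure-noise features share importance roughly uniformly", {
  worst <- 0
  for (sd in 1:3) {
    datn <- voxfuse:::with_local_seed(sd, tibble::tibble(
      label = rep(c(0L, 1L), each = 50),
      bio_a = stats::rnorm(100), bio_b = stats::rnorm(100),
      bio_c = stats::rnorm(100), bio_d = stats::rnorm(100),
      bio_e = stats::rnorm(100)
    ))
    worst <- max(worst, max(mdi_importance(datn, seed = sd)$scores$score))
  }
  # no noise feature may dominate: stay below 2x the uniform share
  expect_lt(worst, 2 / 5)
})

test_that("Shapley attributions telescope to the exact model output", {
  set.seed(7)
  f <- function(x) as.numeric(tanh(x %*% c(1, -0.5, 0.25)))
  bg <- matrix(stats::rnorm(60), 20, 3)
  sh <- shapley_attribution(f, c(0.5, 1, -2), bg, n_draws = 300, seed = 2)
  # local accuracy holds exactly for every draw count (telescoping sums)
  expect_lt(abs(sh$residual), 1e-12)
  expect_equal(sh$prediction, as.numeric(f(matrix(c(0.5, 1, -2), 1))))
})

test_that("Shapley recovers the closed form for a linear model", {
  set.seed(4)
  w <- c(0.5, -1, 2, 0, 0.3)
  f <- function(x) as.numeric(x %*% w)
  bg <- matrix(stats::rnorm(500), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x <- c(1, 2, -1, 3, 0.5)
  sh <- shapley_attribution(f, x, bg, n_draws = 2000, seed = 4)
  expected <- w * (x - colMeans(bg))
  got <- sh$scores$score[match(paste0("f", 1:5), sh$scores$feature)]
  expect_lt(max(abs(got - expected)), 0.05) # Monte-Carlo error at 2000 draws
})

test_that("a feature constant across sample and background gets zero credit", {
  f <- function(x) as.numeric(x %*% c(1, 1, 1))
  bg <- matrix(stats::rnorm(30), 10, 3)
  bg[, 2] <- 5
  sh <- shapley_attribution(f, c(1, 5, 2), bg, n_draws = 100, seed = 1)
  expect_equal(sh$scores$score[2], 0)
})

test_that("duplicated features receive symmetric attribution", {
  f <- function(x) as.numeric(x[, 1] + x[, 2])
  bg <- cbind(stats::rnorm(50), 0)
  bg[, 2] <- bg[, 1]
  sh <- shapley_attribution(f, c(2, 2), bg, n_draws = 4000, seed = 9)
  expect_lt(abs(diff(sh$scores$score)), 0.05)
})

test_that("shapley_attribution validates its inputs", {
  f <- function(x) rowSums(x)
  expect_error(shapley_attribution(f, 1:3, matrix(1, 2, 2)), "columns")
  expect_error(shapley_attribution(f, 1:2, matrix(1, 0, 2)), "non-empty")
  expect_error(shapley_attribution(f, 1:2, matrix(1, 2, 2), n_draws = 0), "n_draws")
})

test_that("confidence_report summarizes class-conditional score distributions", {
  scores <- c(stats::runif(50, 0, 0.3), stats::runif(50, 0.7, 1))
  truth <- rep(c(0L, 1L), each = 50)
  rep <- confidence_report(
    structure(list(confidences = tibble::tibble(p_pd = scores, truth = truth)),
      class = "eval_report"
    )
  )
  expect_equal(nrow(rep$quantiles), 2)
  expect_equal(rep$overlap, 0) # disjoint supports do not overlap
  # identical distributions overlap fully
  rep2 <- confidence_report(
    structure(list(confidences = tibble::tibble(
      p_pd = rep(scores, 2),
      truth = rep(c(0L, 1L), each = 100)
    )), class = "eval_report")
  )
  expect_gt(rep2$overlap, 0.99)
})
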