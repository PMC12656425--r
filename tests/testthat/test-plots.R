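# tidy()/glance()/autoplot() surfaces on each report class; plots are built
# but not printed.

fit_and_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- separable_cohort()
      plan <- subject_wise_split(coh, seed = 5)
      cfg <- small_training_config(epochs = 5, seed = 5)
      model <- do.call(
        fusion_classifier,
        c(list(n_bio = 22, n_emb = 32, seed = 5), small_model_args())
      )
      fit <- train(model, coh, plan, cfg)
      cache <<- list(coh = coh, plan = plan, fit = fit, rep = evaluate(fit, coh, plan))
    }
    cache
  }
})

test_that("fit tidiers expose the training history", {
  x <- fit_and_report()
  td <- tidy(x$fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in% names(td)))
  gl <- glance(x$fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs_run, nrow(td))
  expect_s3_class(autoplot(x$fit), "ggplot")
})

test_that("evaluation report tidiers and ROC plot work", {
  x <- fit_and_report()
  td <- tidy(x$rep)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_true("accuracy" %in% td$metric)
  expect_equal(nrow(glance(x$rep)), 1)
  expect_s3_class(autoplot(x$rep), "ggplot")
})

test_that("attribution report tidiers and importance plot work", {
  x <- fit_and_report()
  r <- mdi_importance(x$coh)
  expect_named(tidy(r), c("feature", "score"))
  gl <- glance(r)
  expect_identical(gl$method, "mdi")
  expect_equal(gl$n_features, 22)
  expect_s3_class(autoplot(r, top_n = 5), "ggplot")
})

test_that("confidence report tidiers and histogram plot work", {
  x <- fit_and_report()
  cr <- confidence_report(x$rep)
  expect_true(all(c("class", "n") %in% names(tidy(cr))))
  expect_named(glance(cr), c("overlap", "n"))
  expect_s3_class(autoplot(cr), "ggplot")
})

test_that("cross-validation report tidiers and dot plot work", {
  coh <- generate_cohort(cohort_spec(
    n_subjects = 10, samples_per_subject = 3,
    embedding_separation = 8, subject_sd = 0.05,
    embedding_subject_sd = 0.15, seed = 3
  ))
  cv <- cross_validate(coh,
    k = 3, cfg = small_training_config(epochs = 3, seed = 1),
    model_args = small_model_args()
  )
  expect_equal(nrow(tidy(cv)), 3)
  expect_true("mean" %in% names(glance(cv)))
  expect_s3_class(autoplot(cv), "ggplot")
})
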