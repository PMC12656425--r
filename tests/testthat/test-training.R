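test_that("training_config validates the schedule parameters", {
  expect_error(training_config(eta_max = 1e-4, eta_min = 1e-3), "eta_min")
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(training_config(patience = 0), "patience")
  expect_error(training_config(beta1 = 1), "beta1")
})

test_that("cosine schedule hits its endpoints and never increases", {
  cfg <- training_config() # eta_max 1e-4, eta_min 1e-6, T = 100
  expect_identical(cosine_lr(0, cfg), 1e-4)
  expect_identical(cosine_lr(100, cfg), 1e-6)
  expect_equal(cosine_lr(50, cfg), 1e-6 + (1e-4 - 1e-6) / 2)
  lrs <- cosine_lr(0:100, cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_lr(-1, cfg), "epoch")
  expect_error(cosine_lr(101, cfg), "epoch")
})

test_that("subject-wise split partitions rows and separates subjects", {
  coh <- generate_cohort(cohort_spec(n_subjects = 20, samples_per_subject = 5, seed = 3))
  plan <- subject_wise_split(coh, seed = 1)
  expect_s3_class(plan, "split_plan")
  idx <- c(plan$train, plan$validation, plan$test)
  expect_setequal(idx, seq_len(nrow(coh)))
  expect_equal(anyDuplicated(idx), 0)
  # subject disjointness
  subj <- lapply(plan[c("train", "validation", "test")], function(i) unique(coh$subject_id[i]))
  expect_length(intersect(subj$train, subj$validation), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$validation, subj$test), 0)
  # counts near the 70/15/15 targets
  expect_lt(abs(length(plan$train) - 70), 10)
  expect_lt(abs(length(plan$test) - 15), 8)
  # deterministic under the same seed, different under another
  expect_identical(subject_wise_split(coh, seed = 1)$hash, plan$hash)
  expect_false(subject_wise_split(coh, seed = 2)$hash == plan$hash)
})

test_that("stratified mode splits samples 80/20 with label balance", {
  coh <- generate_cohort(cohort_spec(n_subjects = 20, samples_per_subject = 5, seed = 3))
  plan <- subject_wise_split(coh, fractions = c(0.64, 0.16, 0.2), seed = 1, mode = "stratified")
  expect_equal(length(plan$test), 20)
  # stratification: test-set label proportion matches the cohort
  expect_lt(abs(mean(coh$label[plan$test]) - mean(coh$label)), 0.1)
})

test_that("assert_split_plan detects leakage and broken partitions", {
  coh <- generate_cohort(cohort_spec(n_subjects = 10, samples_per_subject = 3, seed = 3))
  plan <- subject_wise_split(coh, seed = 1)
  broken <- plan
  broken$train <- c(broken$train, broken$test[1]) # duplicated row
  expect_error(voxfuse:::assert_split_plan(broken, coh), "partition")
  leaky <- plan
  # move one sample of a test subject into train (keeps the partition valid)
  moved <- plan$test[1]
  leaky$test <- plan$test[-1]
  leaky$train <- c(plan$train, moved)
  expect_error(voxfuse:::assert_split_plan(leaky, coh), "leakage")
})

test_that("feature-noise augmentation has the documented noise scale", {
  set.seed(1)
  m <- matrix(runif(4000), 200, 20) # range ~1 per column
  cfg <- training_config(feature_noise_frac = 0.05)
  noise <- augment_features(m, cfg, seed = 1) - m
  expect_lt(abs(stats::sd(as.numeric(noise)) - 0.05), 0.01)
  expect_lt(abs(mean(noise)), 0.01)
  # constant columns stay constant
  m2 <- cbind(m, 7)
  out <- augment_features(m2, cfg, seed = 1)
  expect_true(all(out[, 21] == 7))
  # reproducible per seed
  expect_identical(augment_features(m, cfg, seed = 3), augment_features(m, cfg, seed = 3))
})

test_that("roc_auc is the tie-aware rank statistic", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.2, 0.8), c(0, 1)), 1)
  expect_equal(roc_auc(c(0.8, 0.2), c(0, 1)), 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5) # constant scores
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("a short training run produces a well-formed fit and history", {
  coh <- separable_cohort()
  plan <- subject_wise_split(coh, seed = 5)
  cfg <- small_training_config(epochs = 8, seed = 5)
  model <- do.call(
    fusion_classifier,
    c(list(n_bio = 22, n_emb = 32, seed = 5), small_model_args())
  )
  fit <- train(model, coh, plan, cfg)
  expect_s3_class(fit, "voxfuse_fit")
  expect_named(
    fit$history,
    c("epoch", "lr", "train_loss", "val_loss", "train_acc", "val_acc")
  )
  expect_lte(nrow(fit$history), 8)
  expect_equal(fit$history$lr[1], cosine_lr(0, cfg))
  expect_gte(fit$best_epoch, 1)
  expect_identical(fit$plan_hash, plan$hash)
  # loss goes down over a short run on separable data
  expect_lt(fit$history$train_loss[nrow(fit$history)], fit$history$train_loss[1])
  # training is reproducible from the seed
  model2 <- do.call(
    fusion_classifier,
    c(list(n_bio = 22, n_emb = 32, seed = 5), small_model_args())
  )
  fit2 <- train(model2, coh, plan, cfg)
  expect_identical(fit$history, fit2$history)
  # evaluation report structure
  rep <- evaluate(fit, coh, plan)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), length(plan$test))
  expect_named(
    rep$metrics,
    c("accuracy", "precision", "recall", "specificity", "f1", "auc", "n")
  )
  # confidence report from the eval report
  cr <- confidence_report(rep)
  expect_gte(cr$overlap, 0)
  expect_lte(cr$overlap, 1)
})

test_that("cross-validation deals balanced subject folds", {
  coh <- generate_cohort(cohort_spec(
    n_subjects = 25, samples_per_subject = 3,
    embedding_separation = 8, subject_sd = 0.05,
    embedding_subject_sd = 0.15, seed = 3
  ))
  cfg <- small_training_config(epochs = 5, seed = 9)
  cv <- cross_validate(coh, k = 5, cfg = cfg, model_args = small_model_args())
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(table(cv$fold_of) == 5)) # 25 subjects, 5 per fold
  expect_true(all(c("mean", "variance") %in% names(cv$summary)))
  expect_error(cross_validate(coh, k = 30, cfg = cfg), "exceeds")
})

test_that("ablation rejects unknown and contradictory configurations", {
  coh <- generate_cohort(cohort_spec(n_subjects = 12, samples_per_subject = 2, seed = 3))
  cfg <- small_training_config(epochs = 2, seed = 5)
  expect_error(run_ablation(coh, grid = "bogus", cfg = cfg), "unknown")
  expect_error(
    run_ablation(coh, grid = "drop_biomarkers+drop_embeddings", cfg = cfg),
    "both"
  )
})

test_that("content hash is stable and order-sensitive", {
  h1 <- voxfuse:::content_hash(c("a", "b", "c"))
  expect_identical(h1, voxfuse:::content_hash(c("a", "b", "c")))
  expect_false(h1 == voxfuse:::content_hash(c("c", "b", "a")))
  expect_match(h1, "^[0-9a-f]{8}$")
})
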