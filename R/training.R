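#' Training configuration
#'
#' Optimization regimen for the fusion classifier: Adam with weight-decay
#' regularization, cosine-annealed learning rate, early stopping on
#' validation loss with best-checkpoint restoration, and Gaussian
#' feature-noise augmentation on training rows.
#'
#' @param eta_max,eta_min Learning-rate schedule endpoints (defaults
#'   `1e-4` and `1e-6`).
#' @param epochs Total epochs `T` of the schedule (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param beta1,beta2,eps_adam Adam constants (defaults 0.9, 0.999, 1e-8).
#' @param weight_decay L2 weight-decay coefficient (default 1e-4).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_delta Minimum absolute validation-loss improvement counted as
#'   progress (default 1e-5).
#' @param feature_noise_frac Augmentation noise SD as a fraction of each
#'   feature's training range (default 0.05).
#' @param seed RNG seed for shuffling, augmentation, and dropout.
#' @return A list of class `training_config`.
#' @export
training_config <- function(eta_max = 1e-4, eta_min = 1e-6, epochs = 100,
                            batch_size = 32, beta1 = 0.9, beta2 = 0.999,
                            eps_adam = 1e-8, weight_decay = 1e-4,
                            patience = 10, min_delta = 1e-5,
                            feature_noise_frac = 0.05, seed = 1) {
  if (!(0 < eta_min && eta_min <= eta_max)) {
    stop("need 0 < eta_min <= eta_max", call. = FALSE)
  }
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  if (!(beta1 > 0 && beta1 < 1 && beta2 > 0 && beta2 < 1)) {
    stop("beta1 and beta2 must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      eta_max = eta_max, eta_min = eta_min, epochs = epochs,
      batch_size = batch_size, beta1 = beta1, beta2 = beta2,
      eps_adam = eps_adam, weight_decay = weight_decay, patience = patience,
      min_delta = min_delta, feature_noise_frac = feature_noise_frac,
      seed = seed
    ),
    class = "training_config"
  )
}

#' Cosine-annealing learning-rate schedule
#'
#' `eta_t = eta_min + (eta_max - eta_min)/2 * (1 + cos(t * pi / T))`:
#' starts at `eta_max` (t = 0), ends at `eta_min` (t = T), and is
#' non-increasing in between.
#'
#' @param t Epoch index (or vector of indices) in `[0, T]`.
#' @param cfg A [training_config()].
#' @return Learning rate(s) `eta_t`.
#' @examples
#' cosine_lr(0, training_config()) # 1e-4
#' cosine_lr(100, training_config()) # 1e-6
#' @export
cosine_lr <- function(t, cfg = training_config()) {
  if (any(t < 0 | t > cfg$epochs)) {
    stop("epoch t must lie in [0, ", cfg$epochs, "]", call. = FALSE)
  }
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) * (1 + cos(t * pi / cfg$epochs))
}

# short stable content hash (FNV-1a over a string), for split identity
content_hash <- function(x) {
  s <- paste(x, collapse = ",")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Subject-wise train/validation/test split
#'
#' Splits at the subject level so no subject contributes samples to more
#' than one set (prevents identity leakage, the reason subject-wise
#' evaluation exists). Subjects are shuffled by `seed` and assigned
#' greedily: each subject goes to the set with the largest remaining
#' sample-count deficit relative to its target fraction.
#'
#' An alternative `mode = "stratified"` performs a sample-level
#' 80/20 train/test split stratified by label (no subject constraint),
#' with the validation fraction carved from the training portion.
#'
#' @param data Data frame with columns `subject_id` and `label`.
#' @param fractions Length-3 numeric (train, validation, test) summing
#'   to 1.
#' @param seed Shuffle seed.
#' @param mode `"subject"` (default) or `"stratified"`.
#' @return A list of class `split_plan` with integer row-index vectors
#'   `train`, `validation`, `test`, plus `fractions`, `seed`, `mode`, and a
#'   content `hash`.
#' @export
subject_wise_split <- function(data, fractions = c(0.7, 0.15, 0.15), seed = 1,
                               mode = c("subject", "stratified")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop("fractions must be 3 non-negative numbers summing to 1", call. = FALSE)
  }
  n <- nrow(data)
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  if (mode == "subject") {
    subjects <- unique(data$subject_id)
    n_sets <- sum(fractions > 0)
    if (length(subjects) < n_sets) {
      stop(
        "need at least ", n_sets, " subjects for ", n_sets, " non-empty splits; got ",
        length(subjects),
        call. = FALSE
      )
    }
    targets <- fractions * n
    counts <- c(0, 0, 0)
    with_local_seed(seed_substream(seed, "split"), {
      subjects <- sample(subjects)
      if ("label" %in% names(data)) {
        # walk subjects in label-interleaved order so the greedy assignment
        # spreads both classes across all three sets
        subj_lab <- vapply(subjects, function(s) {
          labs <- data$label[data$subject_id == s]
          as.numeric(names(sort(table(labs), decreasing = TRUE))[1])
        }, 0)
        groups <- split(subjects, subj_lab)
        maxlen <- max(lengths(groups))
        interleaved <- unlist(lapply(seq_len(maxlen), function(i) {
          unlist(lapply(groups, function(g) if (i <= length(g)) g[i] else NULL))
        }))
        subjects <- interleaved
      }
    })
    for (s in subjects) {
      rows <- which(data$subject_id == s)
      deficit <- targets - counts
      deficit[fractions == 0] <- -Inf
      k <- which.max(deficit)
      sets[[k]] <- c(sets[[k]], rows)
      counts[k] <- counts[k] + length(rows)
    }
  } else {
    if (!"label" %in% names(data)) stop("stratified mode needs a `label` column", call. = FALSE)
    test_frac <- fractions[3]
    with_local_seed(seed_substream(seed, "split"), {
      for (lab in unique(data$label)) {
        rows <- sample(which(data$label == lab))
        n_test <- round(length(rows) * test_frac)
        n_val <- round(length(rows) * fractions[2])
        sets$test <- c(sets$test, rows[seq_len(n_test)])
        sets$validation <- c(sets$validation, rows[n_test + seq_len(n_val)])
        rest <- if (n_test + n_val > 0) rows[-seq_len(n_test + n_val)] else rows
        sets$train <- c(sets$train, rest)
      }
    })
  }
  sets <- lapply(sets, sort)
  plan <- structure(
    list(
      train = sets$train, validation = sets$validation, test = sets$test,
      fractions = fractions, seed = seed, mode = mode,
      hash = content_hash(c(sets$train, -1L, sets$validation, -1L, sets$test))
    ),
    class = "split_plan"
  )
  assert_split_plan(plan, data)
  plan
}

assert_split_plan <- function(plan, data) {
  idx <- c(plan$train, plan$validation, plan$test)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(nrow(data)))) {
    stop("split plan is not a disjoint exhaustive partition", call. = FALSE)
  }
  if (plan$mode == "subject") {
    for (a in c("train", "validation", "test")) {
      for (b in c("train", "validation", "test")) {
        if (a < b) {
          common <- intersect(
            unique(data$subject_id[plan[[a]]]),
            unique(data$subject_id[plan[[b]]])
          )
          if (length(common)) {
            stop("subject leakage across splits: ", paste(common, collapse = ", "),
              call. = FALSE
            )
          }
        }
      }
    }
  }
  invisible(plan)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan [%s]: %d train / %d validation / %d test (seed %s, hash %s)>\n",
    x$mode, length(x$train), length(x$validation), length(x$test),
    format(x$seed), x$hash
  ))
  invisible(x)
}

#' Gaussian feature-noise augmentation
#'
#' Adds zero-mean Gaussian noise with per-feature standard deviation
#' `feature_noise_frac * (max - min)` computed over the given (training)
#' matrix. Constant columns are left unchanged. Intended for training rows
#' only.
#'
#' @param m Numeric matrix (rows = training samples).
#' @param cfg A [training_config()] supplying `feature_noise_frac`.
#' @param seed Draw seed.
#' @return Matrix of the same shape.
#' @export
augment_features <- function(m, cfg = training_config(), seed = 1) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) {
    stop("feature range undefined on a single-row matrix", call. = FALSE)
  }
  if (cfg$feature_noise_frac == 0) {
    return(m)
  }
  rng <- apply(m, 2, function(v) diff(range(v)))
  with_local_seed(seed, {
    noise <- matrix(stats::rnorm(length(m)), nrow(m))
  })
  m + sweep(noise, 2, cfg$feature_noise_frac * rng, `*`)
}

# extract biomarker and embedding matrices from a cohort-style tibble
cohort_matrices <- function(data, model = NULL) {
  bio_cols <- grep("^bio_", names(data), value = TRUE)
  emb_cols <- grep("^emb_", names(data), value = TRUE)
  out <- list(
    bio = if (length(bio_cols)) as.matrix(data[bio_cols]) else NULL,
    emb = if (length(emb_cols)) as.matrix(data[emb_cols]) else NULL
  )
  if (!is.null(model)) {
    nb <- if (is.null(out$bio)) 0L else ncol(out$bio)
    ne <- if (is.null(out$emb)) 0L else ncol(out$emb)
    if (nb != model$config$n_bio || ne != model$config$n_emb) {
      stop(
        "data provides ", nb, " biomarker and ", ne, " embedding columns; ",
        "model expects ", model$config$n_bio, " + ", model$config$n_emb,
        call. = FALSE
      )
    }
  }
  out
}

standardize_matrix <- function(m, mu, sigma) {
  sigma[sigma == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sigma, `/`)
}

#' Train the fusion classifier
#'
#' Mini-batch Adam with weight decay, per-epoch cosine-annealed learning
#' rate, Gaussian feature augmentation on training rows (fresh draw each
#' epoch), and early stopping: training halts when validation loss has not
#' improved by at least `min_delta` for `patience` consecutive epochs, and
#' the minimum-validation-loss checkpoint is returned. Feature
#' standardization (per modality) is fitted on training rows only.
#'
#' @param model A [fusion_classifier()].
#' @param data Data frame with `label` (0/1), `subject_id`, and feature
#'   columns `bio_*` / `emb_*` matching the model widths.
#' @param plan A [subject_wise_split()] plan for `data`.
#' @param cfg A [training_config()].
#' @return An object of class `voxfuse_fit`: the best-checkpoint `model`,
#'   `history` tibble (`epoch`, `lr`, `train_loss`, `val_loss`,
#'   `train_acc`, `val_acc`), `best_epoch`, and the fitted `scaling`.
#' @export
train <- function(model, data, plan, cfg = training_config()) {
  stopifnot(inherits(model, "fusion_classifier"), inherits(plan, "split_plan"))
  assert_split_plan(plan, data)
  if (length(plan$train) == 0 || length(plan$validation) == 0) {
    stop("training requires non-empty train and validation splits", call. = FALSE)
  }
  mats <- cohort_matrices(data, model)
  y <- data$label
  if (any(!y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)

  # per-modality standardization fitted on training rows only
  scaling <- list()
  x_parts <- list()
  for (mod in c("bio", "emb")) {
    m <- mats[[mod]]
    if (is.null(m)) next
    mu <- colMeans(m[plan$train, , drop = FALSE])
    sigma <- sqrt(colMeans(m[plan$train, , drop = FALSE]^2) - mu^2)
    scaling[[mod]] <- list(mu = mu, sigma = sigma)
    x_parts[[mod]] <- standardize_matrix(m, mu, sigma)
  }
  x_all <- do.call(cbind, x_parts[c("bio", "emb")[c("bio", "emb") %in% names(x_parts)]])

  model$params <- apply_param_mask(model$params, model$mask)
  opt <- adam_init(model$params)
  n_train <- length(plan$train)
  x_train_clean <- x_all[plan$train, , drop = FALSE]
  y_train <- y[plan$train]
  x_val <- x_all[plan$validation, , drop = FALSE]
  y_val <- y[plan$validation]
  yoh_val <- cbind(1 - y_val, y_val)

  hist_rows <- vector("list", cfg$epochs)
  best <- list(loss = Inf, model = model, epoch = 0L)
  stall <- 0L
  with_local_seed(seed_substream(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cosine_lr(ep - 1, cfg)
      x_train <- if (cfg$feature_noise_frac > 0 && n_train >= 2) {
        augment_features(x_train_clean, cfg,
          seed = seed_substream(cfg$seed, paste0("aug_ep", ep))
        )
      } else {
        x_train_clean
      }
      order_idx <- sample(n_train)
      ep_loss <- 0
      n_seen <- 0
      for (b0 in seq(1, n_train, by = cfg$batch_size)) {
        bi <- order_idx[b0:min(b0 + cfg$batch_size - 1, n_train)]
        xb <- x_train[bi, , drop = FALSE]
        yb <- y_train[bi]
        yoh <- cbind(1 - yb, yb)
        lg <- classifier_loss_grads(model, xb, yoh, train = TRUE)
        model <- lg$model # batch-norm running stats
        grads <- apply_param_mask(lg$grads, model$mask)
        stp <- adam_step(model$params, grads, opt,
          lr = lr, beta1 = cfg$beta1, beta2 = cfg$beta2,
          eps = cfg$eps_adam, weight_decay = cfg$weight_decay
        )
        model$params <- apply_param_mask(stp$params, model$mask)
        opt <- stp$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        n_seen <- n_seen + length(bi)
      }
      # end-of-epoch metrics in eval mode
      fw_tr <- classifier_forward(model, x_train_clean, train = FALSE)
      fw_val <- classifier_forward(model, x_val, train = FALSE)
      yoh_tr <- cbind(1 - y_train, y_train)
      train_loss <- softmax_ce_fwd(fw_tr$logits, yoh_tr)$loss
      val_loss <- softmax_ce_fwd(fw_val$logits, yoh_val)$loss
      hist_rows[[ep]] <- tibble::tibble(
        epoch = ep, lr = lr,
        train_loss = train_loss, val_loss = val_loss,
        train_acc = mean((fw_tr$probs[, 2] > 0.5) == (y_train == 1)),
        val_acc = mean((fw_val$probs[, 2] > 0.5) == (y_val == 1))
      )
      if (val_loss < best$loss - cfg$min_delta) {
        best <- list(loss = val_loss, model = model, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  history <- dplyr::bind_rows(hist_rows)
  if (best$epoch == 0L) { # validation never improved below Inf - delta guard
    best <- list(loss = history$val_loss[1], model = model, epoch = nrow(history))
  }
  structure(
    list(
      model = best$model, history = history, best_epoch = best$epoch,
      best_val_loss = best$loss, scaling = scaling, cfg = cfg,
      plan_hash = plan$hash
    ),
    class = "voxfuse_fit"
  )
}

#' @export
print.voxfuse_fit <- function(x, ...) {
  cat(sprintf(
    "<voxfuse_fit: %d epochs run, best epoch %d (val loss %.4f)>\n",
    nrow(x$history), x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

# apply a fit's standardization and produce eval-mode probabilities
fit_probs <- function(fit, data) {
  mats <- cohort_matrices(data, fit$model)
  parts <- list()
  for (mod in c("bio", "emb")) {
    if (is.null(mats[[mod]])) next
    sc <- fit$scaling[[mod]]
    parts[[mod]] <- standardize_matrix(mats[[mod]], sc$mu, sc$sigma)
  }
  x <- do.call(cbind, parts[c("bio", "emb")[c("bio", "emb") %in% names(parts)]])
  classifier_forward(fit$model, x, train = FALSE)$probs
}

#' Rank-based ROC AUC
#'
#' Computes the area under the ROC curve as the normalized Mann-Whitney
#' U-statistic with midpoint handling of ties (average ranks), equivalent
#' to trapezoidal integration of the ROC over all score thresholds. A
#' constant score yields exactly 0.5.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: test set contains a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a trained model on a held-out split
#'
#' Builds the 2x2 confusion matrix at probability threshold 0.5 and reports
#' accuracy, precision, recall (sensitivity), specificity, F1, and
#' rank-based ROC AUC, plus per-sample confidences.
#'
#' @param fit A [train()] result.
#' @param data The dataset the plan indexes into.
#' @param plan The [subject_wise_split()] plan used in training.
#' @param split Which split to score (default `"test"`).
#' @return An object of class `eval_report`: `metrics` (one-row tibble),
#'   `confusion` (2x2 matrix, rows = truth, cols = prediction),
#'   `confidences` (per-sample tibble).
#' @export
evaluate <- function(fit, data, plan, split = "test") {
  stopifnot(inherits(fit, "voxfuse_fit"), inherits(plan, "split_plan"))
  idx <- plan[[match.arg(split, c("test", "validation", "train"))]]
  if (length(idx) == 0) stop("requested split is empty", call. = FALSE)
  d <- data[idx, , drop = FALSE]
  probs <- fit_probs(fit, d)
  truth <- d$label
  eval_report_from_scores(probs[, 2], truth,
    subject_id = d$subject_id,
    extra = list(plan_hash = plan$hash, split = split)
  )
}

# shared report constructor used by evaluate / cross_validate / ablations
eval_report_from_scores <- function(score_pd, truth, subject_id = NULL, extra = list()) {
  pred <- as.integer(score_pd > 0.5)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
    dimnames = list(truth = c("healthy", "pd"), prediction = c("healthy", "pd"))
  )
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  metrics <- tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    auc = roc_auc(score_pd, truth),
    n = length(truth)
  )
  confidences <- tibble::tibble(
    truth = truth,
    p_pd = score_pd,
    pred_class = ifelse(pred == 1, "pd", "healthy"),
    confidence = pmax(score_pd, 1 - score_pd)
  )
  if (!is.null(subject_id)) confidences$subject_id <- subject_id
  structure(
    c(list(metrics = metrics, confusion = confusion, confidences = confidences), extra),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_report: n=%d  acc %.3f  prec %.3f  rec %.3f  spec %.3f  F1 %.3f  AUC %.3f>\n",
    m$n, m$accuracy, m$precision, m$recall, m$specificity, m$f1, m$auc
  ))
  print(x$confusion)
  invisible(x)
}

#' Subject-wise k-fold cross-validation
#'
#' Folds are formed at the subject level and label-stratified using each
#' subject's majority label, so each subject is tested exactly once and no
#' subject appears in a fold's training and test sets. Within each fold the
#' next fold (cyclically) serves as the validation set for early stopping.
#'
#' @param data Cohort data frame (`label`, `subject_id`, `bio_*`/`emb_*`).
#' @param k Number of folds (default 5).
#' @param cfg A [training_config()].
#' @param model_args Arguments passed to [fusion_classifier()] besides the
#'   input widths (which are inferred from `data`).
#' @return An object of class `cv_report`: `folds` (per-fold metric
#'   tibble), `summary` (mean and variance per metric), and fold
#'   assignments.
#' @export
cross_validate <- function(data, k = 5, cfg = training_config(), model_args = list()) {
  subjects <- unique(data$subject_id)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(subjects)) {
    stop("k = ", k, " exceeds subject count (", length(subjects), ")", call. = FALSE)
  }
  subj_label <- vapply(subjects, function(s) {
    labs <- data$label[data$subject_id == s]
    as.numeric(names(sort(table(labs), decreasing = TRUE))[1]) # majority label
  }, 0)
  fold_of <- integer(length(subjects))
  with_local_seed(seed_substream(cfg$seed, "cvfolds"), {
    # deal subjects to folds label group by label group, continuing the fold
    # counter across groups so fold sizes stay balanced overall
    counter <- 0L
    for (lab in unique(subj_label)) {
      ids <- sample(which(subj_label == lab))
      fold_of[ids] <- ((counter + seq_along(ids) - 1L) %% k) + 1L
      counter <- counter + length(ids)
    }
  })
  mats <- cohort_matrices(data)
  nb <- if (is.null(mats$bio)) 0L else ncol(mats$bio)
  ne <- if (is.null(mats$emb)) 0L else ncol(mats$emb)
  fold_rows <- vector("list", k)
  for (fi in seq_len(k)) {
    test_subj <- subjects[fold_of == fi]
    val_subj <- subjects[fold_of == (fi %% k) + 1]
    assign_set <- function(s) {
      if (s %in% test_subj) "test" else if (s %in% val_subj) "validation" else "train"
    }
    sets <- vapply(data$subject_id, assign_set, "")
    plan <- structure(
      list(
        train = which(sets == "train"), validation = which(sets == "validation"),
        test = which(sets == "test"), fractions = c(NA, NA, NA), seed = cfg$seed,
        mode = "subject",
        hash = content_hash(c(which(sets == "train"), -1L, which(sets == "validation"),
          -1L, which(sets == "test")))
      ),
      class = "split_plan"
    )
    assert_split_plan(plan, data)
    model <- do.call(fusion_classifier, c(list(n_bio = nb, n_emb = ne), model_args))
    fit <- train(model, data, plan, cfg)
    rep <- evaluate(fit, data, plan)
    fold_rows[[fi]] <- dplyr::mutate(rep$metrics, fold = fi, .before = 1)
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("accuracy", "precision", "recall", "specificity", "f1", "auc")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    variance = vapply(metric_cols, function(m) stats::var(folds[[m]]), 0)
  )
  structure(
    list(folds = folds, summary = summary, fold_of = stats::setNames(fold_of, subjects), k = k),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d subject-wise folds>\n", x$k))
  print(x$summary)
  invisible(x)
}

ablation_grid_default <- c(
  "full", "drop_biomarkers", "drop_embeddings", "no_batch_norm",
  "no_dropout", "bypass_early_fusion", "late_fusion_voting",
  "logistic_baseline"
)

# block-diagonal connectivity masks so biomarker and embedding channels stay
# in separate towers through Block A; Block B's interior is zeroed (pure
# skip), and the head performs the late concatenation
bypass_fusion_mask <- function(model) {
  cfg <- model$config
  n_in <- cfg$n_bio + cfg$n_emb
  h_bio <- round(cfg$hidden * cfg$n_bio / n_in)
  h_bio <- min(max(h_bio, 1L), cfg$hidden - 1L)
  in_grp <- c(rep(1L, cfg$n_bio), rep(2L, cfg$n_emb))
  hid_grp <- c(rep(1L, h_bio), rep(2L, cfg$hidden - h_bio))
  mask_in_hid <- outer(in_grp, hid_grp, `==`) * 1
  mask_hid_hid <- outer(hid_grp, hid_grp, `==`) * 1
  zero_b <- params_map(function(p) p * 0, model$params$b)
  list(
    a = list(W1 = mask_in_hid, W2 = mask_hid_hid, P = mask_in_hid),
    b = zero_b
  )
}

#' Run the ablation grid
#'
#' Trains one model per configuration under an identical split plan and
#' seed and reports test metrics for each. Available configurations:
#' `full`, `drop_biomarkers`, `drop_embeddings`, `no_batch_norm`,
#' `no_dropout`, `bypass_early_fusion` (block-diagonal separate towers with
#' late concatenation at the head), `late_fusion_voting` (two unimodal
#' networks, averaged probabilities), and `logistic_baseline` (logistic
#' regression on biomarkers only). Combined switches may be joined with
#' `"+"` (e.g. `"no_batch_norm+no_dropout"`); dropping both modalities is
#' a configuration error.
#'
#' @param data Cohort data frame with `bio_*` and `emb_*` columns.
#' @param grid Character vector of configuration names.
#' @param cfg A [training_config()].
#' @param plan Optional [subject_wise_split()]; defaults to a 70/15/15
#'   subject-wise plan under `cfg$seed`.
#' @param model_args Extra arguments for [fusion_classifier()].
#' @return A tibble with one row per configuration (`config`, the metric
#'   columns, and `split_hash`), of class `ablation_report`.
#' @export
run_ablation <- function(data, grid = ablation_grid_default,
                         cfg = training_config(), plan = NULL,
                         model_args = list()) {
  known <- c(ablation_grid_default)
  mats <- cohort_matrices(data)
  if (is.null(mats$bio) || is.null(mats$emb)) {
    stop("ablation grid needs both bio_* and emb_* columns", call. = FALSE)
  }
  if (is.null(plan)) plan <- subject_wise_split(data, seed = cfg$seed)
  bio_cols <- grep("^bio_", names(data), value = TRUE)
  emb_cols <- grep("^emb_", names(data), value = TRUE)
  nb <- length(bio_cols)
  ne <- length(emb_cols)

  fit_variant <- function(drop_bio = FALSE, drop_emb = FALSE, use_bn = TRUE,
                          use_dropout = TRUE, mask_builder = NULL) {
    d <- data
    if (drop_bio) d <- d[setdiff(names(d), bio_cols)]
    if (drop_emb) d <- d[setdiff(names(d), emb_cols)]
    model <- do.call(fusion_classifier, c(
      list(
        n_bio = if (drop_bio) 0L else nb, n_emb = if (drop_emb) 0L else ne,
        use_bn = use_bn, use_dropout = use_dropout, seed = cfg$seed
      ),
      model_args
    ))
    if (!is.null(mask_builder)) model$mask <- mask_builder(model)
    fit <- train(model, d, plan, cfg)
    list(fit = fit, data = d)
  }

  run_one <- function(config) {
    flags <- strsplit(config, "+", fixed = TRUE)[[1]]
    unknown <- setdiff(flags, known)
    if (length(unknown)) {
      stop("unknown ablation configuration: ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    if (all(c("drop_biomarkers", "drop_embeddings") %in% flags)) {
      stop("cannot drop both modalities: no inputs would remain", call. = FALSE)
    }
    test_idx <- plan$test
    truth <- data$label[test_idx]
    if (identical(flags, "late_fusion_voting")) {
      fb <- fit_variant(drop_emb = TRUE)
      fe <- fit_variant(drop_bio = TRUE)
      p <- (fit_probs(fb$fit, fb$data[test_idx, ])[, 2] +
        fit_probs(fe$fit, fe$data[test_idx, ])[, 2]) / 2
      return(eval_report_from_scores(p, truth))
    }
    if (identical(flags, "logistic_baseline")) {
      dtrain <- data[c(plan$train, plan$validation), c("label", bio_cols)]
      gl <- suppressWarnings(
        stats::glm(label ~ ., data = dtrain, family = stats::binomial())
      )
      p <- suppressWarnings(
        stats::predict(gl, newdata = data[test_idx, bio_cols], type = "response")
      )
      return(eval_report_from_scores(as.numeric(p), truth))
    }
    v <- fit_variant(
      drop_bio = "drop_biomarkers" %in% flags,
      drop_emb = "drop_embeddings" %in% flags,
      use_bn = !("no_batch_norm" %in% flags),
      use_dropout = !("no_dropout" %in% flags),
      mask_builder = if ("bypass_early_fusion" %in% flags) bypass_fusion_mask else NULL
    )
    evaluate(v$fit, v$data, plan)
  }

  rows <- lapply(grid, function(cfg_name) {
    rep <- run_one(cfg_name)
    dplyr::mutate(rep$metrics, config = cfg_name, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$split_hash <- plan$hash
  class(out) <- c("ablation_report", class(out))
  out
}
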