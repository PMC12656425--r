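#' Surrogate-forest feature importance (mean decrease in impurity)
#'
#' Fits a random-forest surrogate on one feature block of a labeled cohort
#' and reports each feature's Gini mean-decrease-in-impurity, normalized to
#' sum to 1. This reproduces the importance metric of the screening study's
#' global-attribution figures; it is a surrogate-model importance, distinct
#' from the Shapley attribution in [shapley_attribution()].
#'
#' @param data Cohort data frame with a 0/1 `label` column and `bio_*` /
#'   `emb_*` feature columns.
#' @param block `"biomarkers"` or `"embeddings"` — which feature block to
#'   analyze.
#' @param n_trees Number of trees (default 500).
#' @param seed Forest seed.
#' @return An `attribution_report`: tibble of `feature`, `score` (sorted
#'   decreasing) with attributes `method = "mdi"`, `normalized = TRUE`,
#'   `seed`.
#' @export
mdi_importance <- function(data, block = c("biomarkers", "embeddings"),
                           n_trees = 500, seed = 1) {
  block <- match.arg(block)
  if (length(unique(data$label)) < 2) {
    stop("MDI importance needs both classes present", call. = FALSE)
  }
  prefix <- if (block == "biomarkers") "^bio_" else "^emb_"
  cols <- grep(prefix, names(data), value = TRUE)
  if (!length(cols)) stop("no ", block, " columns found", call. = FALSE)
  x <- as.matrix(data[cols])
  y <- factor(data$label, levels = c(0, 1))
  rf <- with_local_seed(seed_substream(seed, "mdi"), {
    randomForest::randomForest(x, y, ntree = n_trees)
  })
  imp <- rf$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  score <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  out <- tibble::tibble(feature = cols, score = as.numeric(score))
  out <- out[order(-out$score), ]
  new_attribution_report(out, method = "mdi", normalized = TRUE, seed = seed)
}

new_attribution_report <- function(tbl, method, normalized, seed, extra = list()) {
  structure(
    c(list(scores = tbl, method = method, normalized = normalized, seed = seed), extra),
    class = "attribution_report"
  )
}

#' @export
print.attribution_report <- function(x, n = 10, ...) {
  cat(sprintf(
    "<attribution_report [%s]%s, seed %s>\n", x$method,
    if (x$normalized) " (normalized)" else "", format(x$seed)
  ))
  print(utils::head(x$scores, n))
  if (!is.null(x$residual)) {
    cat(sprintf("local-accuracy residual: %.3g\n", x$residual))
  }
  invisible(x)
}

#' Monte-Carlo permutation Shapley attribution
#'
#' Estimates Shapley values for a single input against a background
#' distribution by permutation sampling: each draw picks one background row
#' and a random feature ordering, then walks from the background row to the
#' explained sample one feature at a time, crediting each feature with the
#' change in model output. Summed over features, every draw telescopes to
#' `f(sample) - f(background row)`, so attributions plus the baseline
#' (mean background output) reproduce the model output exactly up to
#' floating-point error — the reported `residual` should be ~0.
#'
#' @param predict_fn Function mapping an `n x d` matrix to `n` numeric
#'   model outputs (e.g. PD probability).
#' @param sample Numeric vector of length `d`: the input to explain.
#' @param background Matrix (`m x d`) of reference rows, typically a
#'   training-set sample of at most ~100 rows.
#' @param n_draws Monte-Carlo permutations (default 2000).
#' @param seed Draw seed.
#' @return An `attribution_report`: `scores` (feature, score), `baseline`
#'   (mean background output), `prediction` (`f(sample)`), and `residual`
#'   (`prediction - baseline - sum(scores)`).
#' @export
shapley_attribution <- function(predict_fn, sample, background,
                                n_draws = 2000, seed = 1) {
  stopifnot(is.function(predict_fn), is.matrix(background))
  d <- length(sample)
  if (ncol(background) != d) {
    stop(
      "background has ", ncol(background), " columns but sample has length ", d,
      call. = FALSE
    )
  }
  if (nrow(background) < 1) stop("background must be non-empty", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  feat_names <- names(sample)
  if (is.null(feat_names)) {
    feat_names <- colnames(background)
  }
  if (is.null(feat_names)) feat_names <- paste0("x", seq_len(d))
  phi <- numeric(d)
  f_sample <- as.numeric(predict_fn(matrix(sample, 1)))[1]
  baseline_sum <- 0
  chunk <- max(1L, 512L %/% (d + 1L)) # draws per predict_fn call
  with_local_seed(seed_substream(seed, "shapley"), {
    done <- 0L
    while (done < n_draws) {
      k <- min(chunk, n_draws - done)
      # build all walk states for k draws: each draw contributes d+1 rows
      big <- matrix(0, k * (d + 1L), d)
      perms <- vector("list", k)
      for (j in seq_len(k)) {
        b <- background[sample.int(nrow(background), 1L), ]
        perm <- sample.int(d)
        perms[[j]] <- perm
        x_cur <- b
        base_row <- (j - 1L) * (d + 1L)
        big[base_row + 1L, ] <- x_cur
        for (s in seq_len(d)) {
          x_cur[perm[s]] <- sample[perm[s]]
          big[base_row + 1L + s, ] <- x_cur
        }
      }
      vals <- as.numeric(predict_fn(big))
      for (j in seq_len(k)) {
        base_row <- (j - 1L) * (d + 1L)
        v <- vals[base_row + seq_len(d + 1L)]
        baseline_sum <- baseline_sum + v[1]
        phi[perms[[j]]] <- phi[perms[[j]]] + diff(v)
      }
      done <- done + k
    }
  })
  phi <- phi / n_draws
  baseline <- baseline_sum / n_draws
  out <- tibble::tibble(feature = feat_names, score = phi)
  new_attribution_report(out,
    method = "shapley", normalized = FALSE, seed = seed,
    extra = list(
      baseline = baseline, prediction = f_sample,
      residual = f_sample - baseline - sum(phi), n_draws = n_draws
    )
  )
}

#' Per-class confidence distribution report
#'
#' Summarizes the classifier's PD-probability distribution separately for
#' each true class: quantiles plus the histogram overlap mass between the
#' two class-conditional distributions (0 = perfectly separated, 1 =
#' identical).
#'
#' @param fit A [train()] result, or an `eval_report` from [evaluate()]
#'   (in which case `data` is ignored).
#' @param data Cohort rows to score (required when `fit` is a model fit).
#' @param n_bins Histogram bins over `[0, 1]` (default 20).
#' @return A `confidence_report`: `quantiles` (per-class tibble),
#'   `overlap` (scalar in `[0, 1]`), and the per-sample `scores` tibble.
#' @export
confidence_report <- function(fit, data = NULL, n_bins = 20) {
  if (inherits(fit, "eval_report")) {
    scores <- fit$confidences$p_pd
    truth <- fit$confidences$truth
  } else if (inherits(fit, "voxfuse_fit")) {
    if (is.null(data) || nrow(data) == 0) {
      stop("confidence_report needs non-empty data", call. = FALSE)
    }
    scores <- fit_probs(fit, data)[, 2]
    truth <- data$label
  } else {
    stop("fit must be a voxfuse_fit or an eval_report", call. = FALSE)
  }
  if (length(scores) == 0) stop("confidence_report needs non-empty data", call. = FALSE)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  quantiles <- dplyr::bind_rows(lapply(sort(unique(truth)), function(cl) {
    v <- scores[truth == cl]
    tibble::tibble(
      class = ifelse(cl == 1, "pd", "healthy"),
      n = length(v),
      !!!stats::setNames(as.list(stats::quantile(v, qs, names = FALSE)),
        paste0("q", qs * 100))
    )
  }))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  overlap <- if (length(unique(truth)) == 2) {
    h0 <- hist(scores[truth == 0], breaks = breaks, plot = FALSE)$counts
    h1 <- hist(scores[truth == 1], breaks = breaks, plot = FALSE)$counts
    sum(pmin(h0 / max(sum(h0), 1), h1 / max(sum(h1), 1)))
  } else {
    NA_real_
  }
  structure(
    list(
      quantiles = quantiles, overlap = overlap,
      scores = tibble::tibble(truth = truth, p_pd = scores)
    ),
    class = "confidence_report"
  )
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report: overlap mass %.3f>\n", x$overlap))
  print(x$quantiles)
  invisible(x)
}
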