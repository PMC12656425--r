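# condition helpers: distinct classes so the CLI can map them to exit codes
vox_validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("voxfuse_validation_error", "error", "condition")))
}
vox_dependency_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("voxfuse_dependency_error", "error", "condition")))
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    preprocess = list(
      target_rate = 16000, frame_len = 0.03, hop_len = 0.01,
      vad_threshold_db = -40, min_active_frames = 3, gate_enabled = FALSE,
      gate_offset = 1.5, max_duration = 30, standardize = TRUE
    ),
    # desk-scale encoder for the pipeline; encoder_config() itself defaults
    # to the full d = 768 architecture
    encoder = list(
      d = 32, d_prime = 16, attention_layers = 2, n_heads = 4,
      temperature_init = 0.07, rate = 16000
    ),
    pretrain = list(epochs = 5, batch_size = 8, lr = 3e-3),
    classifier = list(
      hidden = 64, n_tokens = 8, n_heads = 2, ffn_dim = 32, head_dim = 32,
      dropout = 0.5, use_bn = TRUE, use_dropout = TRUE
    ),
    training = list(
      eta_max = 1e-4, eta_min = 1e-6, epochs = 100, batch_size = 32,
      beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8, weight_decay = 1e-4,
      patience = 10, min_delta = 1e-5, feature_noise_frac = 0.05
    ),
    split = list(train = 0.7, validation = 0.15, test = 0.15, mode = "subject"),
    cohort = list(
      n_subjects = 20, samples_per_subject = 5, prop_pd = 0.5,
      embedding_dim = 32, embedding_separation = 3, n_nuisance = 19,
      audio = FALSE, phonation_duration = 0.6
    ),
    attribution = list(n_trees = 500, n_draws = 2000)
  )
}

check_unknown_keys <- function(user, defaults, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults)) {
      vox_validation_error("unknown configuration key: `", full, "`")
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) && is.list(user[[nm]])) {
      check_unknown_keys(user[[nm]], defaults[[nm]], full)
    }
  }
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  try_section <- function(section, expr) {
    tryCatch(expr, error = function(e) {
      vox_validation_error("in section `", section, "`: ", conditionMessage(e))
    })
  }
  try_section("preprocess", do.call(preprocess_config, cfg$preprocess))
  try_section("training", do.call(training_config, c(cfg$training, list(seed = cfg$seed))))
  try_section("encoder", do.call(encoder_config, c(cfg$encoder, list(seed = cfg$seed))))
  try_section("classifier", do.call(fusion_classifier, c(
    list(n_bio = 22, n_emb = cfg$cohort$embedding_dim, seed = cfg$seed),
    cfg$classifier
  )))
  try_section("cohort", do.call(cohort_spec, c(
    cfg$cohort[setdiff(names(cfg$cohort), c("audio", "phonation_duration"))],
    list(seed = cfg$seed)
  )))
  if (!cfg$log_level %in% c("debug", "info", "warn", "error")) {
    vox_validation_error("in section `log_level`: must be debug/info/warn/error")
  }
  invisible(cfg)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML or JSON configuration file, fills unset fields with
#' defaults, rejects unknown keys (naming the offending field), and
#' validates every sub-configuration by constructing it. An empty or
#' missing-body file yields the all-defaults configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @param overrides Named list merged on top of the file contents (useful
#'   for CLI flags like `--seed`).
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) vox_validation_error("config file not readable: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      vox_validation_error("config must be YAML or JSON, got `.", ext, "`")
    }
    if (is.null(user)) user <- list()
  }
  check_unknown_keys(user, defaults)
  check_unknown_keys(overrides, defaults)
  cfg <- merge_config(merge_config(defaults, user), overrides)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write the effective configuration to a YAML file
#'
#' @param cfg A `run_config` from [load_config()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

log_line <- function(cfg, level, module, msg) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] < levels[[cfg$log_level]]) {
    return(invisible())
  }
  line <- sprintf("[%s] [%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    level, module, msg)
  message(line)
  log_path <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(line, "\n", file = log_path, append = TRUE)
  invisible()
}

write_manifest <- function(cfg, cmd, inputs, outputs) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = cmd,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("voxfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(outputs)
  )
  path <- file.path(cfg$out_dir, paste0("manifest_", cmd, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

require_artifact <- function(path, hint) {
  if (!file.exists(path)) {
    vox_dependency_error("missing required artifact: ", path, " (", hint, ")")
  }
  path
}

load_pipeline_data <- function(cfg) {
  cohort_path <- file.path(cfg$out_dir, "cohort.csv")
  feat_path <- file.path(cfg$out_dir, "features.csv")
  emb_path <- file.path(cfg$out_dir, "embeddings.csv")
  if (file.exists(feat_path) && file.exists(emb_path)) {
    feats <- utils::read.csv(feat_path, check.names = FALSE)
    embs <- utils::read.csv(emb_path, check.names = FALSE)
    return(tibble::as_tibble(dplyr::inner_join(feats, embs, by = "sample_id")))
  }
  if (file.exists(cohort_path)) {
    return(tibble::as_tibble(utils::read.csv(cohort_path, check.names = FALSE)))
  }
  vox_dependency_error(
    "no dataset found in ", cfg$out_dir,
    " (need cohort.csv, or features.csv + embeddings.csv; run `simulate`/`extract`/`embed` first)"
  )
}

pipeline_plan <- function(cfg, data) {
  subject_wise_split(
    data,
    fractions = c(cfg$split$train, cfg$split$validation, cfg$split$test),
    seed = seed_substream(cfg$seed, "split"),
    mode = cfg$split$mode
  )
}

#' Run one pipeline stage
#'
#' Commands: `simulate` (synthetic cohort; WAV files when
#' `cohort.audio: true`), `extract` (biomarkers from WAV files),
#' `pretrain` (contrastive encoder), `embed` (utterance embeddings),
#' `train`, `evaluate`, `ablate`, and `explain` (MDI + Shapley +
#' confidence report). Artifacts land in `cfg$out_dir` together with a
#' per-command manifest (input hashes, seed, package version) sufficient
#' for an exact rerun. All randomness derives from the single global seed
#' through named substreams.
#'
#' @param cmd Command name.
#' @param cfg A `run_config` from [load_config()].
#' @return Invisible list of written artifact paths.
#' @export
run_pipeline <- function(cmd = c(
                           "simulate", "extract", "pretrain", "embed",
                           "train", "evaluate", "ablate", "explain"
                         ),
                         cfg = load_config()) {
  cmd <- match.arg(cmd)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- switch(cmd,
    simulate = pipeline_simulate(cfg),
    extract = pipeline_extract(cfg),
    pretrain = pipeline_pretrain(cfg),
    embed = pipeline_embed(cfg),
    train = pipeline_train(cfg),
    evaluate = pipeline_evaluate(cfg),
    ablate = pipeline_ablate(cfg),
    explain = pipeline_explain(cfg)
  )
  invisible(out)
}

pipeline_simulate <- function(cfg) {
  log_line(cfg, "info", "simulate", "generating synthetic cohort")
  spec <- do.call(cohort_spec, c(
    cfg$cohort[setdiff(names(cfg$cohort), c("audio", "phonation_duration"))],
    list(seed = seed_substream(cfg$seed, "cohort"))
  ))
  audio <- isTRUE(cfg$cohort$audio)
  dur <- cfg$cohort$phonation_duration
  if (is.null(dur)) dur <- 0.6
  coh <- generate_cohort(spec, audio = audio, phonation_duration = dur)
  outputs <- character(0)
  labels_path <- file.path(cfg$out_dir, "labels.csv")
  utils::write.csv(coh[c("sample_id", "subject_id", "label")], labels_path, row.names = FALSE)
  outputs <- c(outputs, labels_path)
  if (audio) {
    wav_dir <- file.path(cfg$out_dir, "wav")
    dir.create(wav_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(coh))) {
      write_wav(coh$wave[[i]], file.path(wav_dir, paste0(coh$sample_id[i], ".wav")),
        bit_depth = "float32"
      )
    }
    truth <- dplyr::bind_cols(
      coh["sample_id"],
      dplyr::bind_rows(lapply(coh$truth, oracle_perturbation))
    )
    truth_path <- file.path(cfg$out_dir, "truth.csv")
    utils::write.csv(truth, truth_path, row.names = FALSE)
    outputs <- c(outputs, wav_dir, truth_path)
  }
  emb_cols <- grep("^emb_", names(coh), value = TRUE)
  if (length(emb_cols)) {
    emb_path <- file.path(cfg$out_dir, "embeddings.csv")
    utils::write.csv(coh[c("sample_id", emb_cols)], emb_path, row.names = FALSE)
    outputs <- c(outputs, emb_path)
  }
  flat <- coh[!vapply(coh, is.list, TRUE)]
  cohort_path <- file.path(cfg$out_dir, "cohort.csv")
  utils::write.csv(flat, cohort_path, row.names = FALSE)
  outputs <- c(outputs, cohort_path)
  write_manifest(cfg, "simulate", character(0), outputs)
  outputs
}

wav_paths <- function(cfg) {
  wav_dir <- require_artifact(
    file.path(cfg$out_dir, "wav"),
    "run `simulate` with cohort.audio: true, or point out_dir at a WAV directory"
  )
  paths <- sort(list.files(wav_dir, pattern = "\\.wav$", full.names = TRUE))
  if (!length(paths)) vox_dependency_error("no .wav files in ", wav_dir)
  paths
}

pipeline_extract <- function(cfg) {
  paths <- wav_paths(cfg)
  labels_path <- require_artifact(file.path(cfg$out_dir, "labels.csv"), "run `simulate` first")
  labels <- utils::read.csv(labels_path)
  log_line(cfg, "info", "extract", sprintf("extracting biomarkers from %d files", length(paths)))
  rows <- lapply(paths, function(p) {
    w <- read_wav(p)
    v <- assemble_biomarker_vector(w)
    out <- tibble::as_tibble(as.list(v))
    names(out) <- paste0("bio_", names(out))
    out$sample_id <- tools::file_path_sans_ext(basename(p))
    out
  })
  feats <- dplyr::inner_join(tibble::as_tibble(labels), dplyr::bind_rows(rows),
    by = "sample_id"
  )
  feat_path <- file.path(cfg$out_dir, "features.csv")
  utils::write.csv(feats, feat_path, row.names = FALSE)
  write_manifest(cfg, "extract", c(paths, labels_path), feat_path)
  feat_path
}

pipeline_pretrain <- function(cfg) {
  paths <- wav_paths(cfg)
  log_line(cfg, "info", "pretrain", sprintf("contrastive pretraining on %d utterances", length(paths)))
  corpus <- lapply(paths, read_wav) # waveforms only: no labels exist here
  enc <- do.call(encoder_config, c(cfg$encoder, list(seed = seed_substream(cfg$seed, "encoder"))))
  enc <- pretrain_contrastive(corpus, enc,
    epochs = cfg$pretrain$epochs, batch_size = cfg$pretrain$batch_size,
    lr = cfg$pretrain$lr, seed = seed_substream(cfg$seed, "pretrain")
  )
  ckpt <- file.path(cfg$out_dir, "encoder.rds")
  saveRDS(enc, ckpt)
  hist_path <- file.path(cfg$out_dir, "pretrain_history.csv")
  utils::write.csv(enc$history, hist_path, row.names = FALSE)
  write_manifest(cfg, "pretrain", paths, c(ckpt, hist_path))
  ckpt
}

pipeline_embed <- function(cfg) {
  paths <- wav_paths(cfg)
  ckpt <- require_artifact(file.path(cfg$out_dir, "encoder.rds"), "run `pretrain` first")
  enc <- readRDS(ckpt)
  log_line(cfg, "info", "embed", sprintf("embedding %d utterances", length(paths)))
  rows <- lapply(paths, function(p) {
    e <- embed_utterance(read_wav(p), enc)
    out <- tibble::as_tibble(as.list(stats::setNames(e, paste0("emb_", seq_along(e)))))
    out$sample_id <- tools::file_path_sans_ext(basename(p))
    out
  })
  emb_path <- file.path(cfg$out_dir, "embeddings.csv")
  utils::write.csv(dplyr::bind_rows(rows), emb_path, row.names = FALSE)
  write_manifest(cfg, "embed", c(paths, ckpt), emb_path)
  emb_path
}

pipeline_train <- function(cfg) {
  data <- load_pipeline_data(cfg)
  plan <- pipeline_plan(cfg, data)
  tcfg <- do.call(training_config, c(cfg$training, list(seed = seed_substream(cfg$seed, "training"))))
  nb <- sum(grepl("^bio_", names(data)))
  ne <- sum(grepl("^emb_", names(data)))
  model <- do.call(fusion_classifier, c(
    list(n_bio = nb, n_emb = ne, seed = seed_substream(cfg$seed, "classifier")),
    cfg$classifier
  ))
  log_line(cfg, "info", "train", sprintf(
    "training on %d samples (%d bio + %d emb features)", nrow(data), nb, ne
  ))
  fit <- train(model, data, plan, tcfg)
  fit_path <- file.path(cfg$out_dir, "fit.rds")
  saveRDS(list(fit = fit, plan = plan), fit_path)
  hist_path <- file.path(cfg$out_dir, "history.csv")
  utils::write.csv(fit$history, hist_path, row.names = FALSE)
  split_path <- file.path(cfg$out_dir, "split.json")
  jsonlite::write_json(
    list(
      train = plan$train, validation = plan$validation, test = plan$test,
      seed = plan$seed, mode = plan$mode, hash = plan$hash
    ),
    split_path,
    auto_unbox = TRUE
  )
  write_manifest(cfg, "train",
    file.path(cfg$out_dir, c("cohort.csv", "features.csv", "embeddings.csv")),
    c(fit_path, hist_path, split_path)
  )
  fit_path
}

pipeline_evaluate <- function(cfg) {
  fit_path <- require_artifact(file.path(cfg$out_dir, "fit.rds"), "run `train` first")
  stored <- readRDS(fit_path)
  data <- load_pipeline_data(cfg)
  rep <- evaluate(stored$fit, data, stored$plan)
  metrics_json <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(as.list(rep$metrics), metrics_json, auto_unbox = TRUE, digits = NA)
  metrics_csv <- file.path(cfg$out_dir, "metrics.csv")
  utils::write.csv(rep$metrics, metrics_csv, row.names = FALSE)
  conf_csv <- file.path(cfg$out_dir, "confidences.csv")
  utils::write.csv(rep$confidences, conf_csv, row.names = FALSE)
  log_line(cfg, "info", "evaluate", sprintf(
    "test accuracy %.3f, AUC %.3f", rep$metrics$accuracy, rep$metrics$auc
  ))
  write_manifest(cfg, "evaluate", fit_path, c(metrics_json, metrics_csv, conf_csv))
  metrics_json
}

pipeline_ablate <- function(cfg) {
  data <- load_pipeline_data(cfg)
  plan <- pipeline_plan(cfg, data)
  tcfg <- do.call(training_config, c(cfg$training, list(seed = seed_substream(cfg$seed, "training"))))
  log_line(cfg, "info", "ablate", "running ablation grid")
  ab <- run_ablation(data, cfg = tcfg, plan = plan, model_args = cfg$classifier)
  ab_path <- file.path(cfg$out_dir, "ablation.csv")
  utils::write.csv(as.data.frame(ab), ab_path, row.names = FALSE)
  write_manifest(cfg, "ablate", file.path(cfg$out_dir, "cohort.csv"), ab_path)
  ab_path
}

pipeline_explain <- function(cfg) {
  fit_path <- require_artifact(file.path(cfg$out_dir, "fit.rds"), "run `train` first")
  stored <- readRDS(fit_path)
  data <- load_pipeline_data(cfg)
  log_line(cfg, "info", "explain", "computing MDI, Shapley, and confidence reports")
  mdi <- mdi_importance(data, n_trees = cfg$attribution$n_trees,
    seed = seed_substream(cfg$seed, "mdi"))
  mdi_path <- file.path(cfg$out_dir, "mdi.csv")
  utils::write.csv(mdi$scores, mdi_path, row.names = FALSE)
  # Shapley for the first test-row against a training background
  plan <- stored$plan
  feat_cols <- grep("^(bio|emb)_", names(data), value = TRUE)
  bg <- as.matrix(data[plan$train, feat_cols])
  bg <- bg[seq_len(min(100, nrow(bg))), , drop = FALSE]
  target <- as.matrix(data[plan$test[1], feat_cols])[1, ]
  predict_fn <- function(x) {
    colnames(x) <- feat_cols
    fit_probs(stored$fit, tibble::as_tibble(as.data.frame(x)))[, 2]
  }
  sh <- shapley_attribution(predict_fn, target, bg,
    n_draws = cfg$attribution$n_draws,
    seed = seed_substream(cfg$seed, "shapley")
  )
  sh_path <- file.path(cfg$out_dir, "shapley.csv")
  utils::write.csv(sh$scores, sh_path, row.names = FALSE)
  cr <- confidence_report(stored$fit, data[plan$test, ])
  cr_path <- file.path(cfg$out_dir, "confidence.json")
  jsonlite::write_json(
    list(overlap = cr$overlap, quantiles = cr$quantiles),
    cr_path,
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(cfg, "explain", fit_path, c(mdi_path, sh_path, cr_path))
  c(mdi_path, sh_path, cr_path)
}
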