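#' Contrastive speech-encoder configuration
#'
#' A desk-scale speech encoder in the Wav2Vec-2.0 architecture family: a
#' strided 1-D convolutional feature extractor (cumulative stride 320, i.e.
#' about 50 tokens/s at 16 kHz) followed by `attention_layers` transformer
#' layers over the token sequence, with sinusoidal positional encoding. A
#' 2-layer MLP projection head (`d -> d -> d_prime`) is used only during
#' contrastive training; downstream embeddings come from mean-pooled encoder
#' tokens, never from the projection head. During contrastive training the
#' convolutional extractor is frozen (standard fine-tuning practice for this
#' architecture family); attention layers, projection head, and the
#' temperature are trained.
#'
#' @param d Token/embedding dimension (default 768; tests use 32). Must be
#'   at least 8 and divisible by `n_heads`.
#' @param d_prime Projection dimension (default 128); must be `<= d`.
#' @param conv_widths,conv_strides Kernel widths and strides of the conv
#'   stack (defaults give cumulative stride 320).
#' @param attention_layers Number of transformer layers (default 2).
#' @param n_heads Attention heads (default 4).
#' @param ffn_mult Feed-forward width as a multiple of `d`.
#' @param temperature_init Initial NT-Xent temperature (default 0.07;
#'   learnable during pretraining).
#' @param rate Waveform sampling rate the encoder expects, Hz.
#' @param seed Weight-initialization seed.
#' @return An object of class `speech_encoder`.
#' @export
encoder_config <- function(d = 768, d_prime = 128,
                           conv_widths = c(10, 8, 4, 4),
                           conv_strides = c(5, 4, 4, 4),
                           attention_layers = 2, n_heads = 4, ffn_mult = 2,
                           temperature_init = 0.07, rate = 16000, seed = 1) {
  if (d < 8) stop("d must be >= 8", call. = FALSE)
  if (d_prime > d) stop("d_prime must be <= d", call. = FALSE)
  if (temperature_init <= 0) stop("temperature_init must be > 0", call. = FALSE)
  if (d %% n_heads != 0) stop("d must be divisible by n_heads", call. = FALSE)
  if (length(conv_widths) != length(conv_strides)) {
    stop("conv_widths and conv_strides must have equal length", call. = FALSE)
  }
  channels <- c(1L, rep(d, length(conv_widths)))
  ffn_dim <- ffn_mult * d
  params <- with_local_seed(seed, list(
    conv = lapply(seq_along(conv_widths), function(l) {
      list(
        W = he_init(conv_widths[l] * channels[l], channels[l + 1]),
        b = numeric(channels[l + 1])
      )
    }),
    attn = lapply(seq_len(attention_layers), function(l) {
      list(
        Wq = he_init(d, d) / sqrt(2), Wk = he_init(d, d) / sqrt(2),
        Wv = he_init(d, d) / sqrt(2), Wo = he_init(d, d) / sqrt(2),
        ln1_gamma = rep(1, d), ln1_beta = numeric(d),
        ffn_W1 = he_init(d, ffn_dim), ffn_b1 = numeric(ffn_dim),
        ffn_W2 = he_init(ffn_dim, d), ffn_b2 = numeric(d),
        ln2_gamma = rep(1, d), ln2_beta = numeric(d)
      )
    }),
    proj = list(
      W1 = he_init(d, d), b1 = numeric(d),
      W2 = he_init(d, d_prime), b2 = numeric(d_prime)
    ),
    log_tau = log(temperature_init)
  ))
  # receptive field of the conv stack in input samples
  rf <- 1
  cum <- 1
  for (l in seq_along(conv_widths)) {
    rf <- rf + (conv_widths[l] - 1) * cum
    cum <- cum * conv_strides[l]
  }
  structure(
    list(
      config = list(
        d = d, d_prime = d_prime, conv_widths = conv_widths,
        conv_strides = conv_strides, attention_layers = attention_layers,
        n_heads = n_heads, ffn_dim = ffn_dim, rate = rate, seed = seed,
        receptive_field = rf, total_stride = cum,
        token_rate = rate / cum
      ),
      params = params,
      trained = FALSE
    ),
    class = "speech_encoder"
  )
}

#' @export
print.speech_encoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<speech_encoder: d=%d, %d conv layers (stride %d, ~%.1f tokens/s), %d attention layers%s>\n",
    cfg$d, length(cfg$conv_widths), cfg$total_stride, cfg$token_rate,
    cfg$attention_layers, if (x$trained) ", trained" else ""
  ))
  invisible(x)
}

conv1d_fwd <- function(x_mat, W, b, k, stride) {
  n_in <- nrow(x_mat)
  starts <- seq(1L, n_in - k + 1L, by = stride)
  patches <- t(vapply(
    starts,
    function(s) as.vector(t(x_mat[s:(s + k - 1L), , drop = FALSE])),
    numeric(k * ncol(x_mat))
  ))
  out <- patches %*% W
  sweep(out, 2, b, `+`)
}

sinusoidal_positions <- function(n_tok, d) {
  pos <- seq_len(n_tok) - 1
  i <- seq_len(d %/% 2) - 1
  angles <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n_tok, d)
  pe[, seq(1, d, by = 2)] <- sin(angles)
  pe[, seq(2, d, by = 2)] <- cos(angles)
  pe
}

# one transformer layer over a T' x d token matrix; returns caches for backprop
attn_layer_fwd <- function(tok, lp, n_heads) {
  Tn <- nrow(tok); d <- ncol(tok)
  x3 <- array(0, c(1, Tn, d)); x3[1, , ] <- tok
  att <- mhsa_fwd(x3, lp$Wq, lp$Wk, lp$Wv, lp$Wo, n_heads)
  res1 <- tok + matrix(att$out[1, , ], Tn, d)
  ln1 <- layernorm_fwd(res1, lp$ln1_gamma, lp$ln1_beta)
  f1 <- dense_fwd(ln1$out, lp$ffn_W1, lp$ffn_b1)
  fr <- relu_fwd(f1$out)
  f2 <- dense_fwd(fr$out, lp$ffn_W2, lp$ffn_b2)
  res2 <- ln1$out + f2$out
  ln2 <- layernorm_fwd(res2, lp$ln2_gamma, lp$ln2_beta)
  list(out = ln2$out, cache = list(att = att$cache, ln1 = ln1$cache, f1 = f1$cache,
                                   fr = fr$cache, f2 = f2$cache, ln2 = ln2$cache,
                                   Tn = Tn, d = d))
}

attn_layer_bwd <- function(dout, cache) {
  bb2 <- layernorm_bwd(dout, cache$ln2)
  g <- list(ln2_gamma = bb2$dgamma, ln2_beta = bb2$dbeta)
  dres2 <- bb2$dx
  bw <- dense_bwd(dres2, cache$f2)
  g$ffn_W2 <- bw$dW; g$ffn_b2 <- bw$db
  d <- relu_bwd(bw$dx, cache$fr)
  bw <- dense_bwd(d, cache$f1)
  g$ffn_W1 <- bw$dW; g$ffn_b1 <- bw$db
  dln1_out <- dres2 + bw$dx
  bb1 <- layernorm_bwd(dln1_out, cache$ln1)
  g$ln1_gamma <- bb1$dgamma; g$ln1_beta <- bb1$dbeta
  dres1 <- bb1$dx
  d3 <- array(0, c(1, cache$Tn, cache$d)); d3[1, , ] <- dres1
  mb <- mhsa_bwd(d3, cache$att)
  g$Wq <- mb$dWq; g$Wk <- mb$dWk; g$Wv <- mb$dWv; g$Wo <- mb$dWo
  dtok <- dres1 + matrix(mb$dx[1, , ], cache$Tn, cache$d)
  list(grads = g, dtok = dtok)
}

encode_full <- function(enc, w, keep_cache = FALSE) {
  cfg <- enc$config
  x <- matrix(w$samples, ncol = 1)
  if (nrow(x) < cfg$receptive_field) {
    stop(
      "input of ", nrow(x), " samples is shorter than the encoder receptive field (",
      cfg$receptive_field, " samples)",
      call. = FALSE
    )
  }
  for (l in seq_along(cfg$conv_widths)) {
    x <- conv1d_fwd(x, enc$params$conv[[l]]$W, enc$params$conv[[l]]$b,
      cfg$conv_widths[l], cfg$conv_strides[l]
    )
    x <- pmax(x, 0)
  }
  tok <- x + sinusoidal_positions(nrow(x), cfg$d)
  caches <- if (keep_cache) vector("list", cfg$attention_layers) else NULL
  for (l in seq_len(cfg$attention_layers)) {
    fw <- attn_layer_fwd(tok, enc$params$attn[[l]], cfg$n_heads)
    tok <- fw$out
    if (keep_cache) caches[[l]] <- fw$cache
  }
  list(tokens = tok, caches = caches)
}

#' Encode a waveform into a token matrix
#'
#' Runs the convolutional extractor and attention layers in inference mode.
#'
#' @param w A [waveform()] at the encoder's rate.
#' @param enc A [encoder_config()] object (or an [external_encoder()]).
#' @return A `T' x d` token matrix (`T'` is approximately
#'   `duration * token_rate`).
#' @export
encode <- function(w, enc) {
  assert_waveform(w)
  if (inherits(enc, "external_encoder")) {
    tok <- enc$fn(w)
    if (!is.matrix(tok) || ncol(tok) != enc$d || nrow(tok) < 1 || any(!is.finite(tok))) {
      stop("external encoder returned an invalid token matrix", call. = FALSE)
    }
    return(tok)
  }
  stopifnot(inherits(enc, "speech_encoder"))
  encode_full(enc, w)$tokens
}

#' Temporal mean-pooling of a token matrix
#'
#' @param z A `T' x d` token matrix from [encode()].
#' @return The utterance embedding: column means, a vector of length `d`.
#' @export
mean_pool <- function(z) {
  if (!is.matrix(z) || nrow(z) < 1) stop("empty token matrix", call. = FALSE)
  colMeans(z)
}

#' Project an utterance embedding into the contrastive space
#'
#' Two-layer MLP head used only during NT-Xent training; downstream tasks
#' always consume the pooled embedding, not the projection.
#'
#' @param zbar Embedding vector of length `d` (or an `n x d` matrix).
#' @param enc A [encoder_config()] object.
#' @return Vector (or matrix) of dimension `d_prime`.
#' @export
project <- function(zbar, enc) {
  p <- enc$params$proj
  z <- if (is.matrix(zbar)) zbar else matrix(zbar, 1)
  if (ncol(z) != enc$config$d) {
    stop("embedding dim ", ncol(z), " does not match encoder d = ", enc$config$d,
      call. = FALSE
    )
  }
  h <- pmax(z %*% p$W1 + matrix(p$b1, nrow(z), length(p$b1), byrow = TRUE), 0)
  out <- h %*% p$W2 + matrix(p$b2, nrow(z), length(p$b2), byrow = TRUE)
  if (is.matrix(zbar)) out else drop(out)
}

#' Embed an utterance
#'
#' `mean_pool(encode(w))` — the embedding consumed by the fusion classifier.
#'
#' @param w A [waveform()].
#' @param enc A [encoder_config()] or [external_encoder()].
#' @return Numeric vector of length `d`.
#' @export
embed_utterance <- function(w, enc) mean_pool(encode(w, enc))

#' Register an external pretrained encoder
#'
#' Adapter for published pretrained speech encoders: any function mapping a
#' [waveform()] to a `T' x d` token matrix can stand in for the built-in
#' encoder in [encode()] and [embed_utterance()].
#'
#' @param fn Function `waveform -> matrix`.
#' @param d Token dimension `fn` produces.
#' @return An object of class `external_encoder`.
#' @export
external_encoder <- function(fn, d) {
  stopifnot(is.function(fn), d >= 1)
  structure(list(fn = fn, d = as.integer(d)), class = "external_encoder")
}

#' Augmentation configuration for contrastive view generation
#'
#' @param time_mask_max Max masked-segment length, seconds (default 1.2).
#' @param noise_snr_range Two-element dB interval for additive Gaussian
#'   noise SNR (default `c(25, 30)`).
#' @param shift_max_frac Max circular time shift as a fraction of duration
#'   (default 0.05).
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(time_mask_max = 1.2, noise_snr_range = c(25, 30),
                                shift_max_frac = 0.05) {
  if (time_mask_max < 0) stop("time_mask_max must be >= 0", call. = FALSE)
  if (length(noise_snr_range) != 2 || noise_snr_range[1] > noise_snr_range[2]) {
    stop("noise_snr_range must be an increasing interval", call. = FALSE)
  }
  if (shift_max_frac < 0 || shift_max_frac >= 1) {
    stop("shift_max_frac must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      time_mask_max = time_mask_max, noise_snr_range = noise_snr_range,
      shift_max_frac = shift_max_frac
    ),
    class = "augmentation_config"
  )
}

#' Draw a stochastic augmented view of a waveform
#'
#' Applies, each independently with probability 0.5 and in this fixed
#' order: (1) time masking — one segment of length `U(0, time_mask_max)`
#' seconds replaced with silence; (2) additive Gaussian noise at an SNR
#' drawn uniformly from `noise_snr_range` dB; (3) a circular time shift of
#' up to `shift_max_frac` of the duration. Length and rate are preserved.
#'
#' @param w A [waveform()].
#' @param cfg An [augmentation_config()].
#' @param draw Integer seed for this draw (reproducible views).
#' @return An augmented [waveform()].
#' @export
augment_view <- function(w, cfg = augmentation_config(), draw = 1) {
  assert_waveform(w)
  x <- w$samples
  n <- length(x)
  with_local_seed(draw, {
    if (stats::runif(1) < 0.5 && cfg$time_mask_max > 0) {
      len <- round(stats::runif(1, 0, cfg$time_mask_max) * w$rate)
      len <- min(len, n - 1L)
      if (len > 0) {
        start <- sample.int(n - len, 1)
        x[start:(start + len - 1L)] <- 0
      }
    }
    if (stats::runif(1) < 0.5) {
      snr <- stats::runif(1, cfg$noise_snr_range[1], cfg$noise_snr_range[2])
      sig_rms <- sqrt(mean(x^2))
      if (sig_rms > 0) {
        x <- x + stats::rnorm(n, 0, sig_rms * 10^(-snr / 20))
      }
    }
    if (stats::runif(1) < 0.5 && cfg$shift_max_frac > 0) {
      shift <- round(stats::runif(1, -cfg$shift_max_frac, cfg$shift_max_frac) * n)
      if (shift != 0) {
        idx <- ((seq_len(n) - 1 - shift) %% n) + 1
        x <- x[idx]
      }
    }
  })
  waveform(x, w$rate)
}

# ---- NT-Xent ---------------------------------------------------------------

# positive-partner index for the canonical interleaved layout
# (rows 2i-1 and 2i are the two views of utterance i)
ntx_partners <- function(n_views) {
  ifelse(seq_len(n_views) %% 2 == 1, seq_len(n_views) + 1, seq_len(n_views) - 1)
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy over a batch of `2N`
#' projected views: for a positive pair `(i, j)`,
#' `L_ij = -log( exp(sim(h_i, h_j)/tau) / sum_{k != i} exp(sim(h_i, h_k)/tau) )`
#' with cosine similarity; the loss is the mean over all `2N` ordered
#' positive pairs. Rows `2i - 1` and `2i` are the two views of utterance
#' `i`.
#'
#' @param h A `2N x d'` matrix of projected views (unnormalized; cosine
#'   normalization happens inside).
#' @param tau Temperature, `> 0`.
#' @return Scalar loss (0 when `N = 1`, since no negatives exist).
#' @export
nt_xent_loss <- function(h, tau) {
  nt_xent_core(h, tau, want_grads = FALSE)$loss
}

nt_xent_core <- function(h, tau, want_grads = FALSE) {
  if (!is.matrix(h) || nrow(h) %% 2 != 0 || nrow(h) < 2) {
    stop("h must be a matrix with an even number (>= 2) of view rows", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  nv <- nrow(h)
  norms <- sqrt(rowSums(h^2))
  if (any(norms == 0)) stop("zero-norm projection: cosine similarity undefined", call. = FALSE)
  v <- h / norms
  S <- v %*% t(v)
  partners <- ntx_partners(nv)
  Z <- S / tau
  # per anchor i: logsumexp over k != i
  diag(Z) <- -Inf
  zmax <- apply(Z, 1, max)
  lse <- zmax + log(rowSums(exp(Z - zmax)))
  pos <- Z[cbind(seq_len(nv), partners)]
  loss <- mean(lse - pos)
  if (!want_grads) {
    return(list(loss = loss))
  }
  W <- exp(Z - lse) # softmax weights over k != i (diag exactly 0)
  G <- (W - (col(S) == matrix(partners, nv, nv))) / (tau * nv)
  diag(G) <- 0
  dV <- (G + t(G)) %*% v
  # cosine-normalization backward, rowwise: du = (dv - (dv.v) v)/||u||
  dots <- rowSums(dV * v)
  dH <- (dV - v * dots) / norms
  dtau <- -sum(G * S) / tau
  list(loss = loss, dh = dH, dtau = dtau)
}

#' Self-supervised contrastive pretraining
#'
#' Fine-tunes the encoder with the NT-Xent objective on an unlabeled corpus
#' of waveforms. Each step draws two independent augmented views per
#' utterance, encodes and mean-pools them, projects them, and minimizes the
#' contrastive loss with Adam. The convolutional feature extractor stays
#' frozen; attention layers, projection head, and the (log-parameterized)
#' temperature are trained. No labels are consumed at any point.
#'
#' @param corpus List of [waveform()] objects (no label field exists, by
#'   construction).
#' @param enc A [encoder_config()] object.
#' @param aug_cfg An [augmentation_config()].
#' @param epochs Training epochs.
#' @param batch_size Utterances per batch (`2 * batch_size` views).
#' @param lr Adam learning rate.
#' @param seed Seed controlling shuffling and augmentation draws.
#' @return The trained `speech_encoder` with `$history`, a tibble of
#'   `epoch` and mean `loss`.
#' @export
pretrain_contrastive <- function(corpus, enc, aug_cfg = augmentation_config(),
                                 epochs = 5, batch_size = 8, lr = 3e-3, seed = 1) {
  stopifnot(inherits(enc, "speech_encoder"))
  if (!is.list(corpus) || !all(vapply(corpus, is_waveform, TRUE))) {
    stop("corpus must be a list of waveform objects", call. = FALSE)
  }
  if (length(corpus) < batch_size) {
    stop(
      "corpus (", length(corpus), " utterances) smaller than one batch (",
      batch_size, ")",
      call. = FALSE
    )
  }
  trainable <- list(attn = enc$params$attn, proj = enc$params$proj,
                    log_tau = enc$params$log_tau)
  opt <- adam_init(trainable)
  history <- numeric(epochs)
  draw_counter <- 0L
  with_local_seed(seed_substream(seed, "pretrain"), {
    for (ep in seq_len(epochs)) {
      order_idx <- sample(length(corpus))
      ep_losses <- c()
      for (b0 in seq(1, length(corpus) - batch_size + 1, by = batch_size)) {
        idx <- order_idx[b0:(b0 + batch_size - 1)]
        enc$params$attn <- trainable$attn
        enc$params$proj <- trainable$proj
        enc$params$log_tau <- trainable$log_tau
        tau <- exp(trainable$log_tau)
        views <- vector("list", 2 * batch_size)
        caches <- vector("list", 2 * batch_size)
        zbars <- matrix(0, 2 * batch_size, enc$config$d)
        for (j in seq_along(idx)) {
          for (vi in 1:2) {
            draw_counter <- draw_counter + 1L
            wv <- augment_view(corpus[[idx[j]]], aug_cfg,
              draw = seed_substream(seed, paste0("aug", draw_counter))
            )
            ef <- encode_full(enc, wv, keep_cache = TRUE)
            row <- 2 * (j - 1) + vi
            views[[row]] <- ef$tokens
            caches[[row]] <- ef$caches
            zbars[row, ] <- colMeans(ef$tokens)
          }
        }
        # projection forward (batched)
        p <- trainable$proj
        pre1 <- zbars %*% p$W1 + matrix(p$b1, nrow(zbars), ncol(p$W1), byrow = TRUE)
        a1 <- pmax(pre1, 0)
        hmat <- a1 %*% p$W2 + matrix(p$b2, nrow(zbars), ncol(p$W2), byrow = TRUE)
        ntx <- nt_xent_core(hmat, tau, want_grads = TRUE)
        ep_losses <- c(ep_losses, ntx$loss)
        # backward: projection head
        grads <- zeros_like(trainable)
        grads$log_tau <- ntx$dtau * tau
        grads$proj$W2 <- t(a1) %*% ntx$dh
        grads$proj$b2 <- colSums(ntx$dh)
        da1 <- ntx$dh %*% t(p$W2)
        dpre1 <- da1 * (pre1 > 0)
        grads$proj$W1 <- t(zbars) %*% dpre1
        grads$proj$b1 <- colSums(dpre1)
        dzbar <- dpre1 %*% t(p$W1)
        # backward through attention layers, per view
        for (row in seq_len(2 * batch_size)) {
          Tn <- nrow(views[[row]])
          dtok <- matrix(rep(dzbar[row, ] / Tn, each = Tn), Tn, enc$config$d)
          for (l in rev(seq_len(enc$config$attention_layers))) {
            bl <- attn_layer_bwd(dtok, caches[[row]][[l]])
            dtok <- bl$dtok
            for (nm in names(bl$grads)) {
              grads$attn[[l]][[nm]] <- grads$attn[[l]][[nm]] + bl$grads[[nm]]
            }
          }
        }
        stp <- adam_step(trainable, grads, opt, lr = lr)
        trainable <- stp$params
        opt <- stp$state
      }
      history[ep] <- mean(ep_losses)
    }
  })
  enc$params$attn <- trainable$attn
  enc$params$proj <- trainable$proj
  enc$params$log_tau <- trainable$log_tau
  enc$trained <- TRUE
  enc$history <- tibble::tibble(epoch = seq_len(epochs), loss = history)
  enc
}
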