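#' Early-fusion residual-attention classifier
#'
#' Constructs the hybrid fusion network that maps a standardized acoustic
#' biomarker vector concatenated with a speech embedding to two class
#' probabilities (Healthy vs. PD). The architecture is:
#' \itemize{
#'   \item \strong{Fusion}: `x = [biomarkers || embedding]`, dimension
#'     `n_bio + n_emb` (790 at the defaults: 22 + 768).
#'   \item \strong{Block A} (residual feed-forward):
#'     `BN(Drop(ReLU(Dense2(Drop(ReLU(Dense1 x)))))) + P x`, with
#'     `Dense1: in -> hidden`, `Dense2: hidden -> hidden`, and a learned
#'     linear skip projection `P: in -> hidden` (input and output widths
#'     differ, so an identity skip is impossible).
#'   \item \strong{Block B} (residual attention): the hidden vector is
#'     reshaped into `n_tokens` tokens of `hidden / n_tokens` dims;
#'     multi-head self-attention and a position-wise feed-forward net are
#'     applied, each followed by dropout and layer normalization with a
#'     sublayer residual; a skip connection spans the whole block.
#'   \item \strong{Head}: `Dense(hidden -> head_dim)`, ReLU, batch norm,
#'     dropout, `Dense(head_dim -> 2)`, softmax.
#' }
#' Training minimizes 2-class categorical cross-entropy with a probability
#' floor of `1e-12` inside the logarithm.
#'
#' @param n_bio Biomarker input width (default 22).
#' @param n_emb Embedding input width (default 768).
#' @param hidden Width of Blocks A/B (default 512).
#' @param n_tokens Token count for Block B; must divide `hidden`.
#' @param n_heads Attention heads; must divide `hidden / n_tokens`.
#' @param ffn_dim Width of Block B's feed-forward subnetwork.
#' @param head_dim Width of the penultimate dense layer.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param use_bn Include batch normalization? (ablation switch)
#' @param use_dropout Include dropout? (ablation switch)
#' @param seed Seed for weight initialization.
#' @return An object of class `fusion_classifier` holding `config`, `params`
#'   (nested named list of weight matrices/vectors), and `state` (batch-norm
#'   running moments).
#' @export
fusion_classifier <- function(n_bio = 22, n_emb = 768, hidden = 512,
                              n_tokens = 8, n_heads = 4, ffn_dim = 256,
                              head_dim = 128, dropout = 0.5,
                              use_bn = TRUE, use_dropout = TRUE, seed = 1) {
  if (hidden %% n_tokens != 0) {
    stop("`hidden` (", hidden, ") must be divisible by `n_tokens` (", n_tokens, ")",
      call. = FALSE
    )
  }
  dt <- hidden %/% n_tokens
  if (dt %% n_heads != 0) {
    stop("token dim (", dt, ") must be divisible by `n_heads` (", n_heads, ")",
      call. = FALSE
    )
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  n_in <- n_bio + n_emb
  params <- with_local_seed(seed, list(
    a = list(
      W1 = he_init(n_in, hidden), b1 = numeric(hidden),
      W2 = he_init(hidden, hidden), b2 = numeric(hidden),
      P = he_init(n_in, hidden),
      bn_gamma = rep(1, hidden), bn_beta = numeric(hidden)
    ),
    b = list(
      Wq = he_init(dt, dt) / sqrt(2), Wk = he_init(dt, dt) / sqrt(2),
      Wv = he_init(dt, dt) / sqrt(2), Wo = he_init(dt, dt) / sqrt(2),
      ln1_gamma = rep(1, dt), ln1_beta = numeric(dt),
      ffn_W1 = he_init(dt, ffn_dim), ffn_b1 = numeric(ffn_dim),
      ffn_W2 = he_init(ffn_dim, dt), ffn_b2 = numeric(dt),
      ln2_gamma = rep(1, dt), ln2_beta = numeric(dt)
    ),
    head = list(
      W3 = he_init(hidden, head_dim), b3 = numeric(head_dim),
      bn_gamma = rep(1, head_dim), bn_beta = numeric(head_dim),
      W4 = he_init(head_dim, 2), b4 = numeric(2)
    )
  ))
  structure(
    list(
      config = list(
        n_bio = n_bio, n_emb = n_emb, hidden = hidden, n_tokens = n_tokens,
        n_heads = n_heads, ffn_dim = ffn_dim, head_dim = head_dim,
        dropout = dropout, use_bn = use_bn, use_dropout = use_dropout,
        seed = seed
      ),
      params = params,
      state = list(bn_a = bn_state_init(hidden), bn_head = bn_state_init(head_dim)),
      mask = NULL
    ),
    class = "fusion_classifier"
  )
}

#' @export
print.fusion_classifier <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(params_leaves(x$params), length, 0L))
  cat(sprintf(
    "<fusion_classifier: %d+%d -> %d hidden (%d tokens x %d heads) -> 2; %s params>\n",
    cfg$n_bio, cfg$n_emb, cfg$hidden, cfg$n_tokens, cfg$n_heads,
    format(n_par, big.mark = ",")
  ))
  invisible(x)
}

#' Concatenate a biomarker vector and an utterance embedding
#'
#' Early fusion: the joint representation is the plain concatenation
#' `[biomarkers || embedding]`, biomarkers first. Both inputs are expected
#' to be Z-score standardized. Accepts vectors (one sample) or matrices
#' (rows = samples).
#'
#' @param biomarkers Numeric vector of length `n_bio`, or an `n x n_bio`
#'   matrix.
#' @param embedding Numeric vector / matrix with matching sample count.
#' @return A fused vector or matrix of width `n_bio + n_emb`.
#' @examples
#' length(fuse(rnorm(22), rnorm(32))) # 54
#' @export
fuse <- function(biomarkers, embedding) {
  b <- if (is.matrix(biomarkers)) biomarkers else matrix(biomarkers, 1)
  e <- if (is.matrix(embedding)) embedding else matrix(embedding, 1)
  if (nrow(b) != nrow(e)) stop("sample counts differ", call. = FALSE)
  if (any(!is.finite(b)) || any(!is.finite(e))) {
    stop("non-finite values in fusion input", call. = FALSE)
  }
  out <- cbind(b, e)
  if (!is.matrix(biomarkers) && !is.matrix(embedding)) out <- drop(out)
  out
}

# reshape n x hidden -> n x S x dt (tokens are consecutive chunks)
tokens_split <- function(h, S) {
  n <- nrow(h)
  dt <- ncol(h) %/% S
  x <- array(0, c(n, S, dt))
  for (s in seq_len(S)) x[, s, ] <- h[, ((s - 1) * dt + 1):(s * dt), drop = FALSE]
  x
}

tokens_flatten <- function(x) {
  n <- dim(x)[1]; S <- dim(x)[2]; dt <- dim(x)[3]
  h <- matrix(0, n, S * dt)
  for (s in seq_len(S)) h[, ((s - 1) * dt + 1):(s * dt)] <- x[, s, ]
  h
}

# Full forward pass. x: n x (n_bio + n_emb). Returns logits, probs, cache
# (train mode) and the model with updated batch-norm running stats.
classifier_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  if (!is.matrix(x)) x <- matrix(x, 1)
  if (ncol(x) != cfg$n_bio + cfg$n_emb) {
    stop(
      "fused input width ", ncol(x), " does not match model width ",
      cfg$n_bio + cfg$n_emb,
      call. = FALSE
    )
  }
  drop_rate <- if (cfg$use_dropout) cfg$dropout else 0
  cache <- list(train = train)

  # ---- Block A ----
  d1 <- dense_fwd(x, p$a$W1, p$a$b1); cache$a_d1 <- d1$cache
  r1 <- relu_fwd(d1$out); cache$a_r1 <- r1$cache
  o1 <- dropout_fwd(r1$out, drop_rate, train); cache$a_o1 <- o1$cache
  d2 <- dense_fwd(o1$out, p$a$W2, p$a$b2); cache$a_d2 <- d2$cache
  r2 <- relu_fwd(d2$out); cache$a_r2 <- r2$cache
  o2 <- dropout_fwd(r2$out, drop_rate, train); cache$a_o2 <- o2$cache
  if (cfg$use_bn) {
    bn <- batchnorm_fwd(o2$out, p$a$bn_gamma, p$a$bn_beta, model$state$bn_a, train)
    model$state$bn_a <- bn$state
    cache$a_bn <- bn$cache
    main_a <- bn$out
  } else {
    main_a <- o2$out
  }
  skip <- dense_fwd(x, p$a$P, numeric(cfg$hidden)); cache$a_skip <- skip$cache
  h_a <- main_a + skip$out

  # ---- Block B ----
  S <- cfg$n_tokens
  t0 <- tokens_split(h_a, S)
  att <- mhsa_fwd(t0, p$b$Wq, p$b$Wk, p$b$Wv, p$b$Wo, cfg$n_heads)
  cache$b_att <- att$cache
  n <- nrow(h_a); dt <- cfg$hidden %/% S
  att_flat <- tokens_flatten(att$out) # n x (S*dt), token-major
  oa <- dropout_fwd(att_flat, drop_rate, train); cache$b_oa <- oa$cache
  # sublayer residual + layer norm (per token)
  res1 <- tokens_flatten(t0) + oa$out
  res1_tok <- matrix(0, n * S, dt)
  for (s in seq_len(S)) {
    res1_tok[((s - 1) * n + 1):(s * n), ] <- res1[, ((s - 1) * dt + 1):(s * dt)]
  }
  ln1 <- layernorm_fwd(res1_tok, p$b$ln1_gamma, p$b$ln1_beta); cache$b_ln1 <- ln1$cache
  f1 <- dense_fwd(ln1$out, p$b$ffn_W1, p$b$ffn_b1); cache$b_f1 <- f1$cache
  fr <- relu_fwd(f1$out); cache$b_fr <- fr$cache
  f2 <- dense_fwd(fr$out, p$b$ffn_W2, p$b$ffn_b2); cache$b_f2 <- f2$cache
  of <- dropout_fwd(f2$out, drop_rate, train); cache$b_of <- of$cache
  res2 <- ln1$out + of$out
  ln2 <- layernorm_fwd(res2, p$b$ln2_gamma, p$b$ln2_beta); cache$b_ln2 <- ln2$cache
  inner <- matrix(0, n, S * dt)
  for (s in seq_len(S)) {
    inner[, ((s - 1) * dt + 1):(s * dt)] <- ln2$out[((s - 1) * n + 1):(s * n), ]
  }
  h_b <- h_a + inner # whole-block residual

  # ---- Head ----
  d3 <- dense_fwd(h_b, p$head$W3, p$head$b3); cache$h_d3 <- d3$cache
  r3 <- relu_fwd(d3$out); cache$h_r3 <- r3$cache
  if (cfg$use_bn) {
    bnh <- batchnorm_fwd(r3$out, p$head$bn_gamma, p$head$bn_beta, model$state$bn_head, train)
    model$state$bn_head <- bnh$state
    cache$h_bn <- bnh$cache
    hh <- bnh$out
  } else {
    hh <- r3$out
  }
  o3 <- dropout_fwd(hh, drop_rate, train); cache$h_o3 <- o3$cache
  d4 <- dense_fwd(o3$out, p$head$W4, p$head$b4); cache$h_d4 <- d4$cache
  logits <- d4$out
  cache$n <- n; cache$S <- S; cache$dt <- dt
  list(logits = logits, probs = softmax_rows(logits), cache = cache, model = model)
}

# Backward pass from dlogits; returns gradients shaped like model$params.
classifier_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  g <- zeros_like(model$params)
  n <- cache$n; S <- cache$S; dt <- cache$dt

  bw <- dense_bwd(dlogits, cache$h_d4)
  g$head$W4 <- bw$dW; g$head$b4 <- bw$db
  d <- dropout_bwd(bw$dx, cache$h_o3)
  if (cfg$use_bn) {
    bb <- batchnorm_bwd(d, cache$h_bn)
    g$head$bn_gamma <- bb$dgamma; g$head$bn_beta <- bb$dbeta
    d <- bb$dx
  }
  d <- relu_bwd(d, cache$h_r3)
  bw <- dense_bwd(d, cache$h_d3)
  g$head$W3 <- bw$dW; g$head$b3 <- bw$db
  dh_b <- bw$dx

  # ---- Block B backward ----
  dh_a <- dh_b # whole-block residual
  dinner <- dh_b
  dln2_out <- matrix(0, n * S, dt)
  for (s in seq_len(S)) {
    dln2_out[((s - 1) * n + 1):(s * n), ] <- dinner[, ((s - 1) * dt + 1):(s * dt)]
  }
  bb <- layernorm_bwd(dln2_out, cache$b_ln2)
  g$b$ln2_gamma <- bb$dgamma; g$b$ln2_beta <- bb$dbeta
  dres2 <- bb$dx
  dln1_out <- dres2 # residual branch into ln1 output
  dof <- dropout_bwd(dres2, cache$b_of)
  bw <- dense_bwd(dof, cache$b_f2)
  g$b$ffn_W2 <- bw$dW; g$b$ffn_b2 <- bw$db
  d <- relu_bwd(bw$dx, cache$b_fr)
  bw <- dense_bwd(d, cache$b_f1)
  g$b$ffn_W1 <- bw$dW; g$b$ffn_b1 <- bw$db
  dln1_out <- dln1_out + bw$dx
  bb <- layernorm_bwd(dln1_out, cache$b_ln1)
  g$b$ln1_gamma <- bb$dgamma; g$b$ln1_beta <- bb$dbeta
  dres1_tok <- bb$dx
  dres1 <- matrix(0, n, S * dt)
  for (s in seq_len(S)) {
    dres1[, ((s - 1) * dt + 1):(s * dt)] <- dres1_tok[((s - 1) * n + 1):(s * n), ]
  }
  dh_a <- dh_a + dres1 # sublayer residual into t0 == h_a
  datt_flat <- dropout_bwd(dres1, cache$b_oa)
  datt <- tokens_split(datt_flat, S)
  mb <- mhsa_bwd(datt, cache$b_att)
  g$b$Wq <- mb$dWq; g$b$Wk <- mb$dWk; g$b$Wv <- mb$dWv; g$b$Wo <- mb$dWo
  dh_a <- dh_a + tokens_flatten(mb$dx)

  # ---- Block A backward ----
  bw <- dense_bwd(dh_a, cache$a_skip)
  g$a$P <- bw$dW
  dx_total <- bw$dx
  d <- dh_a
  if (cfg$use_bn) {
    bb <- batchnorm_bwd(d, cache$a_bn)
    g$a$bn_gamma <- bb$dgamma; g$a$bn_beta <- bb$dbeta
    d <- bb$dx
  }
  d <- dropout_bwd(d, cache$a_o2)
  d <- relu_bwd(d, cache$a_r2)
  bw <- dense_bwd(d, cache$a_d2)
  g$a$W2 <- bw$dW; g$a$b2 <- bw$db
  d <- dropout_bwd(bw$dx, cache$a_o1)
  d <- relu_bwd(d, cache$a_r1)
  bw <- dense_bwd(d, cache$a_d1)
  g$a$W1 <- bw$dW; g$a$b1 <- bw$db
  dx_total <- dx_total + bw$dx

  list(grads = g, dx = dx_total)
}

# apply a 0/1 connectivity mask (nested like params) to params or grads;
# leaves without a mask entry pass through unchanged
apply_param_mask <- function(params, mask) {
  if (is.null(mask)) {
    return(params)
  }
  for (nm in names(mask)) {
    if (is.list(mask[[nm]])) {
      params[[nm]] <- apply_param_mask(params[[nm]], mask[[nm]])
    } else {
      params[[nm]] <- params[[nm]] * mask[[nm]]
    }
  }
  params
}

# loss + gradients for one batch (training interface)
classifier_loss_grads <- function(model, x, y_onehot, train = TRUE) {
  fw <- classifier_forward(model, x, train = train)
  ce <- softmax_ce_fwd(fw$logits, y_onehot)
  dlogits <- softmax_ce_bwd(ce$probs, y_onehot)
  bw <- classifier_backward(model, fw$cache, dlogits)
  list(loss = ce$loss, probs = ce$probs, grads = bw$grads, model = fw$model)
}

#' Predict class probabilities from fused features
#'
#' Runs the classifier in deterministic evaluation mode (dropout off,
#' batch-norm running statistics).
#'
#' @param object A [fusion_classifier()].
#' @param fused Fused feature matrix (`n x (n_bio + n_emb)`) or single
#'   vector, biomarkers first — see [fuse()].
#' @param ... Unused.
#' @return A tibble with columns `p_healthy`, `p_pd`, `pred_class`
#'   (`"healthy"`/`"pd"`), and `confidence` (max probability).
#' @export
predict.fusion_classifier <- function(object, fused, ...) {
  fw <- classifier_forward(object, fused, train = FALSE)
  probs <- fw$probs
  tibble::tibble(
    p_healthy = probs[, 1],
    p_pd = probs[, 2],
    pred_class = ifelse(probs[, 2] > probs[, 1], "pd", "healthy"),
    confidence = pmax(probs[, 1], probs[, 2])
  )
}

#' Two-class categorical cross-entropy
#'
#' `L = -sum_c y_c log(max(p_c, 1e-12))` averaged over rows when given a
#' batch.
#'
#' @param probs Probability vector of length 2 or an `n x 2` matrix.
#' @param labels Integer labels in `{0, 1}` (1 = PD, second column).
#' @return Mean cross-entropy (non-negative scalar).
#' @export
cross_entropy <- function(probs, labels) {
  if (!is.matrix(probs)) probs <- matrix(probs, 1)
  if (any(!labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  if (length(labels) != nrow(probs)) stop("label count mismatch", call. = FALSE)
  y <- cbind(1 - labels, labels)
  -mean(rowSums(y * log(pmax(probs, 1e-12))))
}
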