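# Minimal dense-network primitives with hand-derived backward passes.
# All activations are n x d matrices (rows = samples). Caches carry exactly
# what the matching *_bwd needs. Gradient correctness is pinned down by
# finite-difference tests, so every formula here is checkable.

nn_eps <- 1e-5

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

dense_fwd <- function(x, W, b) {
  list(out = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE),
       cache = list(x = x, W = W))
}

dense_bwd <- function(dout, cache) {
  list(
    dx = dout %*% t(cache$W),
    dW = t(cache$x) %*% dout,
    db = colSums(dout)
  )
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dout, mask) dout * mask

# inverted dropout; draws from the current RNG stream in train mode
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- matrix(stats::runif(length(x)) < keep, nrow(x)) / keep
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, mask) if (is.null(mask)) dout else dout * mask

bn_state_init <- function(d) list(mean = numeric(d), var = rep(1, d))

batchnorm_fwd <- function(x, gamma, beta, state, train, momentum = 0.1) {
  n <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2 # population variance
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + nn_eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, train = train),
       state = state)
}

batchnorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`), 2, cache$inv_sd, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  inv_sd <- 1 / sqrt(v + nn_eps)
  xhat <- (x - mu) * inv_sd
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy over the batch, with probability floor
softmax_ce_fwd <- function(logits, y_onehot, floor = 1e-12) {
  probs <- softmax_rows(logits)
  loss <- -mean(rowSums(y_onehot * log(pmax(probs, floor))))
  list(loss = loss, probs = probs)
}

softmax_ce_bwd <- function(probs, y_onehot) (probs - y_onehot) / nrow(probs)

# ---- multi-head self-attention --------------------------------------------
# x: n x S x dt array; Wq/Wk/Wv/Wo: dt x dt; heads split the dt columns.

mhsa_fwd <- function(x, Wq, Wk, Wv, Wo, n_heads) {
  n <- dim(x)[1]; S <- dim(x)[2]; dt <- dim(x)[3]
  if (dt %% n_heads != 0) stop("token dim not divisible by head count", call. = FALSE)
  dh <- dt %/% n_heads
  out <- array(0, dim(x))
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    X <- matrix(x[i, , ], S, dt)
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    O <- matrix(0, S, dt)
    heads <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      A <- softmax_rows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh))
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      heads[[h]] <- A
    }
    out[i, , ] <- O %*% Wo
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = heads)
  }
  list(out = out, cache = list(samples = caches, n_heads = n_heads, dh = dh,
                               Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo))
}

mhsa_bwd <- function(dout, cache) {
  n <- dim(dout)[1]; S <- dim(dout)[2]; dt <- dim(dout)[3]
  H <- cache$n_heads; dh <- cache$dh
  dWq <- matrix(0, dt, dt); dWk <- matrix(0, dt, dt)
  dWv <- matrix(0, dt, dt); dWo <- matrix(0, dt, dt)
  dx <- array(0, dim(dout))
  for (i in seq_len(n)) {
    cc <- cache$samples[[i]]
    dO_out <- matrix(dout[i, , ], S, dt)
    dWo <- dWo + t(cc$O) %*% dO_out
    dO <- dO_out %*% t(cache$Wo)
    dQ <- matrix(0, S, dt); dK <- matrix(0, S, dt); dV <- matrix(0, S, dt)
    for (h in seq_len(H)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      A <- cc$A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(cc$V[, idx, drop = FALSE])
      dV[, idx] <- t(A) %*% dOh
      # softmax rows backward
      dZ <- (dA - rowSums(dA * A)) * A / sqrt(dh)
      dQ[, idx] <- dZ %*% cc$K[, idx, drop = FALSE]
      dK[, idx] <- t(dZ) %*% cc$Q[, idx, drop = FALSE]
    }
    dWq <- dWq + t(cc$X) %*% dQ
    dWk <- dWk + t(cc$X) %*% dK
    dWv <- dWv + t(cc$X) %*% dV
    dx[i, , ] <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- Adam over nested parameter lists --------------------------------------

params_map <- function(f, ...) {
  args <- list(...)
  first <- args[[1]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      out[[i]] <- do.call(params_map, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

zeros_like <- function(params) params_map(function(x) x * 0, params)

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# Adam with L2 weight-decay regularization folded into the gradient
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- params_map(function(m, g, p) beta1 * m + (1 - beta1) * (g + weight_decay * p),
    state$m, grads, params)
  state$v <- params_map(function(v, g, p) {
    gd <- g + weight_decay * p
    beta2 * v + (1 - beta2) * gd^2
  }, state$v, grads, params)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  params <- params_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# flatten a nested parameter list into named leaves (for gradient checks)
params_leaves <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(p)) {
      out <- c(out, params_leaves(p, key))
    } else {
      out[[key]] <- p
    }
  }
  out
}

params_set_leaf <- function(params, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(path) == 1L) {
    params[[path]] <- value
    return(params)
  }
  params[[path[1]]] <- params_set_leaf(params[[path[1]]], paste(path[-1], collapse = "."), value)
  params
}
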