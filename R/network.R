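#' Model configuration
#'
#' Hyperparameters of one classifier head. Defaults are the settings
#' selected by the tuning protocol: embedding dimension 768, 64 recurrent
#' units per direction, dropout 0.5, batch size 64, at most six epochs,
#' random seed 75, decision threshold 0.5.
#'
#' @param Q Embedding (word-vector) dimension.
#' @param lstm_size Recurrent units per direction (`pLSTMSize`).
#' @param dropout Dropout fraction in (0, 1) applied after attention
#'   pooling (`pDropoutRatio`).
#' @param batch_size Minibatch size (`pBatchSize`).
#' @param max_epochs Maximum training epochs; the epoch with the best
#'   validation accuracy is retained.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @param threshold Probability cutoff for the positive call (call = 1 iff
#'   probability >= threshold).
#' @param learning_rate Adam step size.
#' @param attention_size Hidden width of the additive attention scorer.
#' @param bn_eps Batch-norm variance floor.
#' @return A `model_config` list.
#' @export
model_config <- function(Q = 768L, lstm_size = 64L, dropout = 0.5,
                         batch_size = 64L, max_epochs = 6L, seed = 75L,
                         threshold = 0.5, learning_rate = 1e-3,
                         attention_size = 64L, bn_eps = 1e-3) {
  stopifnot(Q >= 1, lstm_size >= 1, dropout >= 0, dropout < 1,
            batch_size >= 1, max_epochs >= 1, attention_size >= 1)
  structure(list(Q = as.integer(Q), lstm_size = as.integer(lstm_size),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 threshold = threshold, learning_rate = learning_rate,
                 attention_size = as.integer(attention_size),
                 bn_eps = bn_eps),
            class = "model_config")
}

#' Describe an untrained network
#'
#' Lays out the architecture for one head: trainable embedding (vocabulary
#' `P + 1` to admit the unknown-k-mer ID 0) -> bidirectional LSTM ->
#' batch normalization over the per-timestep features -> additive attention
#' pooling over timesteps -> dropout -> dense output (1 sigmoid unit for the
#' binary roles, 3 softmax units for the three-class variant).
#'
#' @param config A [model_config()].
#' @param input_columns Number of position features (timesteps) the head
#'   consumes, i.e. surviving columns after masking.
#' @param vocab_size Dictionary size P; the embedding table has `P + 1`
#'   rows (IDs 0..P; ID 0 has its own trainable row).
#' @param n_outputs 1 (binary) or 3 (three-class).
#' @return A `spenhancer_network` description list.
#' @export
build_network <- function(config, input_columns, vocab_size, n_outputs = 1L) {
  input_columns <- as.integer(input_columns)
  vocab_size <- as.integer(vocab_size)
  if (input_columns < 1L) stop("input_columns must be >= 1", call. = FALSE)
  if (vocab_size < 1L) stop("vocab_size must be >= 1", call. = FALSE)
  if (!n_outputs %in% c(1L, 3L)) stop("n_outputs must be 1 or 3",
                                      call. = FALSE)
  structure(list(config = config,
                 input_columns = input_columns,
                 vocab = vocab_size + 1L,
                 n_outputs = as.integer(n_outputs),
                 layers = c("embedding", "bidirectional_lstm", "batch_norm",
                            "attention", "dropout",
                            if (n_outputs == 1L) "dense_sigmoid"
                            else "dense_softmax")),
            class = "spenhancer_network")
}

#' @export
print.spenhancer_network <- function(x, ...) {
  cfg <- x$config
  cat("spenhancer_network: ", x$input_columns, " positions, vocab ",
      x$vocab, "\n  embedding(", cfg$Q, ") -> biLSTM(2x", cfg$lstm_size,
      ") -> batchnorm -> attention(", cfg$attention_size, ") -> dropout(",
      cfg$dropout, ") -> dense(", x$n_outputs, ")\n", sep = "")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Parameter initialization. Draw order is fixed so that a given seed always
# yields the same parameters. Embedding rows ~ U(-0.05, 0.05); gate and
# dense weights glorot-uniform; forget-gate bias 1, other biases 0.
init_params <- function(net) {
  cfg <- net$config
  Q <- cfg$Q; H <- cfg$lstm_size; D <- 2L * H; A <- cfg$attention_size
  V <- net$vocab; n_out <- net$n_outputs
  lstm_bias <- function() {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1          # forget gate starts open
    b
  }
  list(E = matrix(runif(V * Q, -0.05, 0.05), V, Q),
       Wx_f = glorot(Q, 4L * H), Wh_f = glorot(H, 4L * H), b_f = lstm_bias(),
       Wx_b = glorot(Q, 4L * H), Wh_b = glorot(H, 4L * H), b_b = lstm_bias(),
       gamma = rep(1, D), beta = rep(0, D),
       Wa = glorot(D, A), ba = rep(0, A), va = drop(glorot(A, 1L)),
       Wd = glorot(D, n_out), bd = rep(0, n_out))
}

# One LSTM direction over the fused input projection Zx (B*T x 4H, rows
# grouped by timestep, sample index fastest). Returns per-step gate caches
# for backprop. `steps` maps processing order to timestep.
lstm_dir <- function(Zx, Wh, b, B, T, H, reverse) {
  steps <- if (reverse) rev(seq_len(T)) else seq_len(T)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  I <- vector("list", T); Fg <- vector("list", T); G <- vector("list", T)
  O <- vector("list", T); TC <- vector("list", T); C <- vector("list", T)
  Hs <- vector("list", T)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (s in seq_len(T)) {
    t <- steps[s]
    rows <- ((t - 1L) * B + 1L):(t * B)
    z <- Zx[rows, , drop = FALSE] + h %*% Wh + bmat
    i <- sigmoid(z[, i1, drop = FALSE])
    f <- sigmoid(z[, i2, drop = FALSE])
    g <- tanh(z[, i3, drop = FALSE])
    o <- sigmoid(z[, i4, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[[s]] <- i; Fg[[s]] <- f; G[[s]] <- g; O[[s]] <- o
    TC[[s]] <- tc; C[[s]] <- cc; Hs[[s]] <- h
  }
  list(steps = steps, I = I, Fg = Fg, G = G, O = O, TC = TC, C = C, H = Hs)
}

# Backpropagation through time for one direction. dH is the gradient on the
# direction's hidden outputs, flat (B*T x H) in timestep-major layout.
lstm_dir_backward <- function(dH, cache, Wh, B, T, H) {
  steps <- cache$steps
  dh_next <- matrix(0, B, H); dc <- matrix(0, B, H)
  dWh <- matrix(0, H, 4L * H); db <- numeric(4L * H)
  dZx <- matrix(0, B * T, 4L * H)
  for (s in rev(seq_len(T))) {
    t <- steps[s]
    rows <- ((t - 1L) * B + 1L):(t * B)
    dh <- dH[rows, , drop = FALSE] + dh_next
    o <- cache$O[[s]]; tc <- cache$TC[[s]]
    i <- cache$I[[s]]; f <- cache$Fg[[s]]; g <- cache$G[[s]]
    c_prev <- if (s > 1L) cache$C[[s - 1L]] else matrix(0, B, H)
    h_prev <- if (s > 1L) cache$H[[s - 1L]] else matrix(0, B, H)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * c_prev
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dZx[rows, ] <- dz
    dh_next <- dz %*% t(Wh)
    dc <- dc * f
  }
  list(dZx = dZx, dWh = dWh, db = db)
}

# Embedding + bidirectional LSTM features for a batch. The embedding and
# the LSTM input projection are fused: G = E %*% Wx is precomputed per
# direction (vocab x 4H), so each timestep only needs a row gather —
# mathematically identical to embedding followed by projection, and far
# cheaper when the vocabulary is small. Returns the flat (B*T x 2H)
# pre-batch-norm feature matrix and the per-direction caches.
lstm_features <- function(params, ids, net) {
  cfg <- net$config
  B <- nrow(ids); T <- ncol(ids)
  H <- cfg$lstm_size; D <- 2L * H
  idx <- as.vector(ids) + 1L
  if (any(idx < 1L) || any(idx > net$vocab)) {
    stop("position ID outside 0..", net$vocab - 1L, call. = FALSE)
  }
  Gf <- params$E %*% params$Wx_f
  Gb <- params$E %*% params$Wx_b
  fwd <- lstm_dir(Gf[idx, , drop = FALSE], params$Wh_f, params$b_f,
                  B, T, H, reverse = FALSE)
  bwd <- lstm_dir(Gb[idx, , drop = FALSE], params$Wh_b, params$b_b,
                  B, T, H, reverse = TRUE)
  Hflat <- matrix(0, B * T, D)
  for (s in seq_len(T)) {
    tf <- fwd$steps[s]; tb <- bwd$steps[s]
    Hflat[((tf - 1L) * B + 1L):(tf * B), seq_len(H)] <- fwd$H[[s]]
    Hflat[((tb - 1L) * B + 1L):(tb * B), H + seq_len(H)] <- bwd$H[[s]]
  }
  list(B = B, T = T, idx = idx, Gf = Gf, Gb = Gb, fwd = fwd, bwd = bwd,
       Hflat = Hflat)
}

# Inference batch-norm statistics: mean and (biased) variance of the
# pre-batch-norm features over a full pass through a reference set,
# computed in bounded-memory chunks. Re-estimated after every epoch so
# that inference statistics always match the current weights (a running
# average would lag badly on a six-epoch schedule).
estimate_bn_stats <- function(params, X, net, chunk = 512L) {
  D <- 2L * net$config$lstm_size
  s1 <- numeric(D); s2 <- numeric(D); n <- 0
  for (start in seq(1L, nrow(X), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(X))
    Hflat <- lstm_features(params, X[rows, , drop = FALSE], net)$Hflat
    s1 <- s1 + colSums(Hflat)
    s2 <- s2 + colSums(Hflat^2)
    n <- n + nrow(Hflat)
  }
  mu <- s1 / n
  list(bn_mean = mu, bn_var = pmax(s2 / n - mu^2, 0))
}

# Full forward pass. `ids` is the B x T position-ID matrix.
network_forward <- function(params, state, ids, net, training = FALSE,
                            keep_cache = FALSE) {
  cfg <- net$config
  H <- cfg$lstm_size; D <- 2L * H
  feat <- lstm_features(params, ids, net)
  B <- feat$B; T <- feat$T
  Hflat <- feat$Hflat
  # batch normalization over the D per-timestep features
  if (training) {
    mu <- colMeans(Hflat)
    xc <- sweep(Hflat, 2L, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- state$bn_mean
    v <- state$bn_var
    xc <- sweep(Hflat, 2L, mu)
  }
  istd <- 1 / sqrt(v + cfg$bn_eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  Hn <- sweep(sweep(xhat, 2L, params$gamma, `*`), 2L, params$beta, `+`)
  # additive attention over timesteps
  u <- tanh(sweep(Hn %*% params$Wa, 2L, params$ba, `+`))
  s_flat <- drop(u %*% params$va)
  S <- matrix(s_flat, B, T)
  S <- S - apply(S, 1L, max)
  Ex <- exp(S)
  alpha <- Ex / rowSums(Ex)
  grp <- rep.int(seq_len(B), T)
  context <- rowsum(Hn * as.vector(alpha), group = grp)
  # dropout on the pooled representation
  if (training && cfg$dropout > 0) {
    mask <- matrix((runif(B * D) >= cfg$dropout) / (1 - cfg$dropout), B, D)
  } else {
    mask <- NULL
  }
  ctx_d <- if (is.null(mask)) context else context * mask
  logits <- sweep(ctx_d %*% params$Wd, 2L, params$bd, `+`)
  prob <- if (net$n_outputs == 1L) {
    sigmoid(logits)
  } else {
    el <- exp(logits - apply(logits, 1L, max))
    el / rowSums(el)
  }
  out <- list(prob = prob, alpha = alpha)
  if (keep_cache) {
    out$cache <- list(B = B, T = T, idx = feat$idx, Gf = feat$Gf,
                      Gb = feat$Gb, fwd = feat$fwd, bwd = feat$bwd,
                      Hflat = Hflat, mu = mu, v = v,
                      istd = istd, xhat = xhat, Hn = Hn, u = u,
                      alpha = alpha, context = context, mask = mask,
                      ctx_d = ctx_d, training = training)
  }
  out
}

# Cross-entropy loss. y: 0/1 vector (binary) or 0..(n_out-1) integer vector.
network_loss <- function(prob, y, n_outputs) {
  eps <- 1e-12
  if (n_outputs == 1L) {
    p <- pmin(pmax(drop(prob), eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    p <- pmax(prob[cbind(seq_along(y), y + 1L)], eps)
    -mean(log(p))
  }
}

# Full backward pass; returns gradients named like the parameters.
network_backward <- function(params, net, fw, y) {
  cfg <- net$config
  cache <- fw$cache
  B <- cache$B; T <- cache$T
  H <- cfg$lstm_size; D <- 2L * H
  prob <- fw$prob
  if (net$n_outputs == 1L) {
    dlogits <- (prob - matrix(y, B, 1L)) / B
  } else {
    Y <- matrix(0, B, net$n_outputs)
    Y[cbind(seq_len(B), y + 1L)] <- 1
    dlogits <- (prob - Y) / B
  }
  dWd <- crossprod(cache$ctx_d, dlogits)
  dbd <- colSums(dlogits)
  dctx_d <- dlogits %*% t(params$Wd)
  dcontext <- if (is.null(cache$mask)) dctx_d else dctx_d * cache$mask
  # attention backward
  grp_rows <- rep.int(seq_len(B), T)           # flat row -> sample
  dctx_rep <- dcontext[grp_rows, , drop = FALSE]
  dalpha_flat <- rowSums(cache$Hn * dctx_rep)
  dalphaM <- matrix(dalpha_flat, B, T)
  dHn <- dctx_rep * as.vector(cache$alpha)
  dS <- cache$alpha * (dalphaM - rowSums(cache$alpha * dalphaM))
  ds_flat <- as.vector(dS)
  dva <- drop(crossprod(cache$u, ds_flat))
  dupre <- outer(ds_flat, params$va) * (1 - cache$u^2)
  dWa <- crossprod(cache$Hn, dupre)
  dba <- colSums(dupre)
  dHn <- dHn + dupre %*% t(params$Wa)
  # batch-norm backward (training statistics)
  Nbt <- B * T
  dgamma <- colSums(dHn * cache$xhat)
  dbeta <- colSums(dHn)
  dxhat <- sweep(dHn, 2L, params$gamma, `*`)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_x <- colSums(dxhat * cache$xhat)
  dHflat <- sweep(dxhat * Nbt, 2L, sum_dxhat) -
    sweep(cache$xhat, 2L, sum_dxhat_x, `*`)
  dHflat <- sweep(dHflat, 2L, cache$istd / Nbt, `*`)
  # split the two directions and run BPTT
  bf <- lstm_dir_backward(dHflat[, seq_len(H), drop = FALSE], cache$fwd,
                          params$Wh_f, B, T, H)
  bb <- lstm_dir_backward(dHflat[, H + seq_len(H), drop = FALSE], cache$bwd,
                          params$Wh_b, B, T, H)
  # gather fused-projection gradients back to the vocabulary table
  accum_G <- function(dZx) {
    dG <- matrix(0, net$vocab, 4L * H)
    rs <- rowsum(dZx, group = cache$idx)
    dG[as.integer(rownames(rs)), ] <- rs
    dG
  }
  dGf <- accum_G(bf$dZx)
  dGb <- accum_G(bb$dZx)
  dWx_f <- crossprod(params$E, dGf)
  dWx_b <- crossprod(params$E, dGb)
  dE <- dGf %*% t(params$Wx_f) + dGb %*% t(params$Wx_b)
  list(E = dE,
       Wx_f = dWx_f, Wh_f = bf$dWh, b_f = bf$db,
       Wx_b = dWx_b, Wh_b = bb$dWh, b_b = bb$db,
       gamma = dgamma, beta = dbeta,
       Wa = dWa, ba = dba, va = dva,
       Wd = dWd, bd = dbd)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

check_training_labels <- function(labels, n_outputs) {
  if (is.null(labels) || length(labels) == 0L) {
    stop("empty training data", call. = FALSE)
  }
  need <- if (n_outputs == 1L) 0:1 else 0:2
  present <- sort(unique(labels))
  if (!all(need %in% present)) {
    stop("training labels must contain all classes {",
         paste(need, collapse = ","), "}; saw {",
         paste(present, collapse = ","), "}", call. = FALSE)
  }
}

#' Train one classifier head
#'
#' Minibatch training with Adam and cross-entropy loss for up to
#' `max_epochs` epochs; the fixed seed governs parameter initialization,
#' epoch shuffling and dropout masks, so a given
#' (seed, configuration, data) triple reproduces the training log exactly
#' within one environment. After every epoch the validation accuracy is
#' measured with inference-mode batch statistics; the parameters of the
#' best-validation epoch are retained.
#'
#' @param network A [build_network()] description.
#' @param train An `encoded_matrix` with labels (0/1, or 0/1/2 for the
#'   three-class role).
#' @param val Validation `encoded_matrix` with labels.
#' @param config A [model_config()]; defaults to the network's.
#' @param role `"detection"`, `"strength"` or `"three_class"`.
#' @return A `trained_head`: list with `role`, `params`, `state` (batch-norm
#'   running statistics), `config`, `input_columns`, `vocab`, `n_outputs`,
#'   `training_log` (data.frame: epoch, train_loss, val_acc), `best_epoch`.
#' @export
train_head <- function(network, train, val, config = network$config,
                       role = c("detection", "strength", "three_class")) {
  role <- match.arg(role)
  n_out <- network$n_outputs
  if (role == "three_class" && n_out != 3L) {
    stop("three_class role needs a 3-output network", call. = FALSE)
  }
  X <- train$ids; y <- train$labels
  Xv <- val$ids; yv <- val$labels
  check_training_labels(y, n_out)
  if (nrow(Xv) == 0L) stop("empty validation data", call. = FALSE)
  if (ncol(X) != network$input_columns || ncol(Xv) != network$input_columns) {
    stop("matrix columns (", ncol(X), "/", ncol(Xv),
         ") != network input_columns (", network$input_columns, ")",
         call. = FALSE)
  }
  cfg <- config
  set.seed(cfg$seed)
  params <- init_params(network)
  D <- 2L * cfg$lstm_size
  state <- list(bn_mean = rep(0, D), bn_var = rep(1, D))
  opt <- adam_init(params)
  n <- nrow(X)
  log_rows <- vector("list", cfg$max_epochs)
  best <- list(acc = -Inf, params = params, state = state, epoch = 0L)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      take <- perm[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
      fw <- network_forward(params, state, X[take, , drop = FALSE], network,
                            training = TRUE, keep_cache = TRUE)
      losses[bi] <- network_loss(fw$prob, y[take], n_out)
      grads <- network_backward(params, network, fw, y[take])
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params; opt <- upd$opt
    }
    state <- estimate_bn_stats(params, X, network)
    pv <- head_probs(params, state, Xv, network)
    val_acc <- if (n_out == 1L) {
      mean((drop(pv) >= cfg$threshold) == (yv == 1L))
    } else {
      mean((max.col(pv, ties.method = "first") - 1L) == yv)
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = mean(losses),
                                    val_acc = val_acc)
    # ties go to the later epoch: equally validated but further trained
    if (val_acc >= best$acc) {
      best <- list(acc = val_acc, params = params, state = state,
                   epoch = epoch)
    }
  }
  structure(list(role = role, params = best$params, state = best$state,
                 config = cfg, input_columns = network$input_columns,
                 vocab = network$vocab, n_outputs = n_out,
                 training_log = do.call(rbind, log_rows),
                 best_epoch = best$epoch),
            class = "trained_head")
}

# inference probabilities in bounded-memory chunks; batch partition does not
# affect the result (running batch-norm statistics, per-sample attention)
head_probs <- function(params, state, X, network, chunk = 512L) {
  if (nrow(X) == 0L) return(matrix(numeric(0), 0L, network$n_outputs))
  out <- matrix(0, nrow(X), network$n_outputs)
  starts <- seq(1L, nrow(X), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nrow(X))
    fw <- network_forward(params, state, X[rows, , drop = FALSE], network,
                          training = FALSE)
    out[rows, ] <- fw$prob
  }
  out
}

#' @export
print.trained_head <- function(x, ...) {
  cat("trained_head (", x$role, "): ", x$input_columns,
      " positions, best epoch ", x$best_epoch, " (val_acc ",
      sprintf("%.4f", x$training_log$val_acc[x$best_epoch]), ")\n", sep = "")
  invisible(x)
}

#' Predict with a trained head
#'
#' @param object A `trained_head`.
#' @param em An `encoded_matrix` (or bare ID matrix) whose column count
#'   matches the head's `input_columns`.
#' @param return_attention If `TRUE`, also return the per-timestep attention
#'   weights (rows sum to 1).
#' @param ... Unused.
#' @return List with `prob` (vector, or matrix for three-class), `call`
#'   (0/1 vector with call = 1 iff prob >= threshold; class labels for
#'   three-class) and optionally `attention`.
#' @export
predict.trained_head <- function(object, em, return_attention = FALSE, ...) {
  X <- if (inherits(em, "encoded_matrix")) em$ids else em
  if (ncol(X) != object$input_columns) {
    stop("matrix has ", ncol(X), " columns but the head expects ",
         object$input_columns, call. = FALSE)
  }
  network <- structure(list(config = object$config,
                            input_columns = object$input_columns,
                            vocab = object$vocab,
                            n_outputs = object$n_outputs),
                       class = "spenhancer_network")
  probs <- head_probs(object$params, object$state, X, network)
  out <- if (object$n_outputs == 1L) {
    list(prob = drop(probs),
         call = as.integer(drop(probs) >= object$config$threshold))
  } else {
    cls <- c("non_enhancer", "weak_enhancer", "strong_enhancer")
    list(prob = probs,
         call = cls[max.col(probs, ties.method = "first")])
  }
  if (return_attention && nrow(X) > 0L) {
    fw <- network_forward(object$params, object$state, X, network,
                          training = FALSE)
    out$attention <- fw$alpha
  }
  out
}

#' Train the three-class variant
#'
#' A single softmax head over (non-enhancer, weak, strong) with the same
#' architecture and training protocol as the binary heads; decisions by
#' argmax. Labels are coded 0 = non-enhancer, 1 = weak, 2 = strong.
#'
#' @param network A 3-output [build_network()] description.
#' @param train,val Labelled `encoded_matrix` objects (labels 0/1/2; all
#'   three classes must appear in `train`).
#' @param config A [model_config()].
#' @return A `trained_head` with role `"three_class"`.
#' @export
train_three_class <- function(network, train, val, config = network$config) {
  train_head(network, train, val, config, role = "three_class")
}

#' Integer coding of three-class labels
#'
#' @param labels Character labels in [label_levels].
#' @return Integer vector: non-enhancer 0, weak 1, strong 2.
#' @export
three_class_labels <- function(labels) {
  validate_labels(labels)
  match(labels, c("non_enhancer", "weak_enhancer", "strong_enhancer")) - 1L
}
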