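#' Attention-CNN defaults
#'
#' Architecture and training defaults of the attention-augmented 1D
#' convolutional network: a weight-shared per-channel temporal
#' convolutional encoder (two blocks of conv -> batch norm -> ReLU ->
#' dropout), a channel-attention module (squeeze-excitation-style score
#' network + softmax) that pools the per-channel feature maps, an
#' additive temporal-attention module (score network + softmax) that
#' pools the time axis, and a fully connected head with a 2-class softmax
#' output. Training uses Adam with class-weighted cross-entropy, early
#' stopping on validation loss and learning-rate reduction on plateau.
#'
#' Because channel information reaches the head only through the
#' channel-attention pooling, the exported channel weights are forced to
#' concentrate on channels that carry discriminative signal.
#'
#' @return Named list of options.
#' @export
cnn_defaults <- function() {
  list(
    conv_filters = c(16L, 24L), kernel = c(7L, 5L), stride = c(2L, 2L),
    att_dim = 16L, fc_dim = 16L, dropout = 0.2,
    lr = 1e-3, batch = 32L, max_epochs = 200L,
    patience = 20L, lr_patience = 10L, lr_factor = 0.5, min_delta = 1e-4,
    downsample = 4L
  )
}

#' Build an attention-augmented 1D CNN
#'
#' Initializes the network for epochs of shape
#' `channels x species x time`. Channel-attention weights (softmax over
#' the fNIRS channels) and temporal-attention weights (softmax over the
#' convolved time axis, upsampled back to input resolution for reporting)
#' are exposed at prediction time via [attention_weights()].
#'
#' @param n_channels,n_species,n_time Input epoch dimensions.
#' @param config Named list merged over [cnn_defaults()].
#' @param seed Seed for weight initialization.
#' @return An object of class `olf_cnn`.
#' @export
build_attention_cnn <- function(n_channels, n_species, n_time,
                                config = list(), seed = 1L) {
  cfg <- utils::modifyList(cnn_defaults(), config)
  h1 <- cfg$conv_filters[1]; h2 <- cfg$conv_filters[2]
  k1 <- cfg$kernel[1]; k2 <- cfg$kernel[2]
  s1 <- cfg$stride[1]; s2 <- cfg$stride[2]
  t1 <- floor((n_time - k1) / s1) + 1
  if (t1 < k2) abort("epoch too short for the configured receptive field")
  t2 <- floor((t1 - k2) / s2) + 1
  set.seed(seed)
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, sd = sqrt(2 / fan)), nr, nc)
  par <- list(
    W1 = array(rnorm(h1 * n_species * k1, sd = sqrt(2 / (n_species * k1))),
               c(h1, n_species, k1)),
    b1 = numeric(h1), gamma1 = rep(1, h1), beta1 = numeric(h1),
    W2 = array(rnorm(h2 * h1 * k2, sd = sqrt(2 / (h1 * k2))), c(h2, h1, k2)),
    b2 = numeric(h2), gamma2 = rep(1, h2), beta2 = numeric(h2),
    W_se = he(n_channels, n_channels, n_channels), b_se = numeric(n_channels),
    Wa = he(cfg$att_dim, h2, h2), ba = numeric(cfg$att_dim),
    va = rnorm(cfg$att_dim, sd = sqrt(1 / cfg$att_dim)),
    Wf = he(cfg$fc_dim, h2, h2), bf = numeric(cfg$fc_dim),
    Wo = he(2, cfg$fc_dim, cfg$fc_dim), bo = numeric(2)
  )
  structure(
    list(
      n_channels = n_channels, n_species = n_species, n_time = n_time,
      t1 = t1, t2 = t2, cfg = cfg, par = par,
      bn = list(m1 = numeric(h1), v1 = rep(1, h1),
                m2 = numeric(h2), v2 = rep(1, h2)),
      n_par = sum(vapply(par, length, 1L)),
      seed = as.integer(seed), trained = FALSE
    ),
    class = "olf_cnn"
  )
}

col_softmax <- function(m) {
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  sweep(m, 2, colSums(m), "/")
}

# strided-window column indices: for offset j (1..k), the input columns
# feeding each (output step, sample) pair when series are laid out as a
# (features x time*samples) matrix
conv_idx <- function(n_time, t_out, stride, batch) {
  as.vector(outer(seq(0, by = stride, length.out = t_out),
                  (seq_len(batch) - 1) * n_time, "+"))
}

# rows of an (n, C, S, T) tensor as an (S, T, C*B) batch array: each
# channel becomes its own sample for the weight-shared encoder
tensor_batch <- function(x, idx) {
  d <- dim(x)
  Xb <- x[idx, , , , drop = FALSE]                    # (B, C, S, T)
  a <- aperm(Xb, c(3, 4, 2, 1))                       # (S, T, C, B)
  array(a, c(d[3], d[4], d[2] * length(idx)))
}

bn_forward <- function(x, gamma, beta, rm, rv, train, eps = 1e-5) {
  if (train) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
  } else {
    mu <- rm; v <- rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  list(y = xhat * gamma + beta, xhat = xhat, inv = inv, mu = mu, v = v)
}

bn_backward <- function(dy, xhat, inv, gamma) {
  n <- ncol(dy)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- (inv / n) * (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Full forward pass. X is (S, T, C*B): per-channel series stacked as
# samples; B is the true batch size.
cnn_forward <- function(net, X, B, train = FALSE, masks = NULL) {
  p <- net$par; cfg <- net$cfg
  C <- net$n_channels; S <- net$n_species
  Tn <- dim(X)[2]; B2 <- dim(X)[3]
  stopifnot(B2 == C * B)
  Xmat <- matrix(X, S, Tn * B2)
  mk <- function(nm, m) {
    if (!train || cfg$dropout <= 0) return(1)
    masks[[nm]] %||% (matrix(rbinom(length(m), 1, 1 - cfg$dropout),
                             nrow(m)) / (1 - cfg$dropout))
  }
  # --- shared conv block 1 ---
  k1 <- cfg$kernel[1]; idx1 <- conv_idx(Tn, net$t1, cfg$stride[1], B2)
  Pre1 <- matrix(p$b1, length(p$b1), net$t1 * B2)
  for (j in seq_len(k1)) {
    Pre1 <- Pre1 + p$W1[, , j] %*% Xmat[, idx1 + j, drop = FALSE]
  }
  bn1 <- bn_forward(Pre1, p$gamma1, p$beta1, net$bn$m1, net$bn$v1, train)
  H1 <- pmax(bn1$y, 0)
  m1 <- mk("m1", H1)
  H1d <- H1 * m1
  # --- shared conv block 2 ---
  k2 <- cfg$kernel[2]; idx2 <- conv_idx(net$t1, net$t2, cfg$stride[2], B2)
  Pre2 <- matrix(p$b2, length(p$b2), net$t2 * B2)
  for (j in seq_len(k2)) {
    Pre2 <- Pre2 + p$W2[, , j] %*% H1d[, idx2 + j, drop = FALSE]
  }
  bn2 <- bn_forward(Pre2, p$gamma2, p$beta2, net$bn$m2, net$bn$v2, train)
  H2 <- pmax(bn2$y, 0)
  m2 <- mk("m2", H2)
  H2d <- H2 * m2
  h2 <- nrow(H2d); t2 <- net$t2
  H2a <- array(H2d, c(h2, t2, C, B))
  # --- channel attention: squeeze -> score -> softmax -> pooled map ---
  Z <- matrix(colMeans(matrix(H2d * H2d, h2 * t2, B2)), C, B)
  A_chan <- col_softmax(p$W_se %*% Z + p$b_se)          # C x B, sums to 1
  U <- array(0, c(h2, t2, B))
  for (b in seq_len(B)) {
    for (ci in seq_len(C)) U[, , b] <- U[, , b] + A_chan[ci, b] * H2a[, , ci, b]
  }
  Umat <- matrix(U, h2, t2 * B)
  # --- temporal attention on the pooled map ---
  Sa <- tanh(p$Wa %*% Umat + p$ba)
  e <- as.vector(crossprod(p$va, Sa))
  A_time <- col_softmax(matrix(e, t2, B))               # t2 x B, sums to 1
  r <- vapply(seq_len(B), function(b) U[, , b] %*% A_time[, b], numeric(h2))
  r <- matrix(r, h2, B)
  # --- head ---
  a_fc <- p$Wf %*% r + p$bf
  Hf <- pmax(a_fc, 0)
  m3 <- mk("m3", Hf)
  Hfd <- Hf * m3
  logits <- p$Wo %*% Hfd + p$bo
  P <- col_softmax(logits)
  list(P = P, A_chan = A_chan, A_time = A_time,
       cache = if (train) list(Xmat = Xmat, idx1 = idx1, bn1 = bn1, H1 = H1,
                               m1 = m1, H1d = H1d, idx2 = idx2, bn2 = bn2,
                               H2 = H2, m2 = m2, H2d = H2d, H2a = H2a,
                               Z = Z, A_chan = A_chan, U = U, Umat = Umat,
                               Sa = Sa, A_time = A_time, r = r, Hf = Hf,
                               m3 = m3, Hfd = Hfd, P = P, B = B, B2 = B2))
}

# Class-weighted cross-entropy loss and full parameter gradients.
cnn_loss_grads <- function(net, X, y, w_class = c(1, 1), masks = NULL) {
  B <- length(y)
  fw <- cnn_forward(net, X, B, train = TRUE, masks = masks)
  cc <- fw$cache
  p <- net$par
  C <- net$n_channels
  h2 <- nrow(cc$H2d); t2 <- net$t2
  wv <- w_class[y + 1]
  picked <- cc$P[cbind(y + 1, seq_len(B))]
  loss <- -sum(wv * log(pmax(picked, 1e-12))) / B
  Y1 <- matrix(0, 2, B); Y1[cbind(y + 1, seq_len(B))] <- 1
  dlog <- sweep(cc$P - Y1, 2, wv / B, "*")
  g <- list()
  g$Wo <- dlog %*% t(cc$Hfd); g$bo <- rowSums(dlog)
  dHfd <- crossprod(p$Wo, dlog)
  da_fc <- dHfd * cc$m3 * (cc$Hf > 0)
  g$Wf <- da_fc %*% t(cc$r); g$bf <- rowSums(da_fc)
  dr <- crossprod(p$Wf, da_fc)
  # temporal attention
  dU <- array(0, c(h2, t2, B))
  dAt <- matrix(0, t2, B)
  for (b in seq_len(B)) {
    dU[, , b] <- dr[, b] %o% cc$A_time[, b]
    dAt[, b] <- crossprod(cc$U[, , b], dr[, b])
  }
  dE <- cc$A_time * sweep(dAt, 2, colSums(cc$A_time * dAt))
  de <- as.vector(dE)
  dSa <- (p$va %o% de) * (1 - cc$Sa^2)
  g$va <- as.vector(cc$Sa %*% de)
  g$Wa <- dSa %*% t(cc$Umat); g$ba <- rowSums(dSa)
  dUmat <- matrix(dU, h2, t2 * B) + crossprod(p$Wa, dSa)
  dUarr <- array(dUmat, c(h2, t2, B))
  # channel-attention pooling
  dH2a <- array(0, c(h2, t2, C, B))
  dw <- matrix(0, C, B)
  for (b in seq_len(B)) {
    for (ci in seq_len(C)) {
      dH2a[, , ci, b] <- cc$A_chan[ci, b] * dUarr[, , b]
      dw[ci, b] <- sum(cc$H2a[, , ci, b] * dUarr[, , b])
    }
  }
  dZnet <- cc$A_chan * sweep(dw, 2, colSums(cc$A_chan * dw))
  g$W_se <- dZnet %*% t(cc$Z); g$b_se <- rowSums(dZnet)
  dZ <- crossprod(p$W_se, dZnet)                        # C x B
  # squeeze path: Z[c,b] = mean of H2d^2 over that channel's map
  dZ_full <- matrix(rep(as.vector(dZ), each = h2 * t2), h2, t2 * cc$B2)
  dH2d <- matrix(dH2a, h2, t2 * cc$B2) +
    matrix(cc$H2a, h2, t2 * cc$B2) * (2 / (h2 * t2)) * dZ_full
  # conv block 2
  dbn2y <- dH2d * cc$m2 * (cc$bn2$y > 0)
  bb2 <- bn_backward(dbn2y, cc$bn2$xhat, cc$bn2$inv, p$gamma2)
  g$gamma2 <- bb2$dgamma; g$beta2 <- bb2$dbeta
  dPre2 <- bb2$dx
  k2 <- net$cfg$kernel[2]
  g$W2 <- array(0, dim(p$W2)); g$b2 <- rowSums(dPre2)
  dH1d <- matrix(0, nrow(cc$H1d), ncol(cc$H1d))
  for (j in seq_len(k2)) {
    cols <- cc$idx2 + j
    g$W2[, , j] <- dPre2 %*% t(cc$H1d[, cols, drop = FALSE])
    dH1d[, cols] <- dH1d[, cols, drop = FALSE] + crossprod(p$W2[, , j], dPre2)
  }
  # conv block 1
  dbn1y <- dH1d * cc$m1 * (cc$bn1$y > 0)
  bb1 <- bn_backward(dbn1y, cc$bn1$xhat, cc$bn1$inv, p$gamma1)
  g$gamma1 <- bb1$dgamma; g$beta1 <- bb1$dbeta
  dPre1 <- bb1$dx
  k1 <- net$cfg$kernel[1]
  g$W1 <- array(0, dim(p$W1)); g$b1 <- rowSums(dPre1)
  for (j in seq_len(k1)) {
    g$W1[, , j] <- dPre1 %*% t(cc$Xmat[, cc$idx1 + j, drop = FALSE])
  }
  list(loss = loss, grads = g,
       bn_batch = list(m1 = cc$bn1$mu, v1 = cc$bn1$v,
                       m2 = cc$bn2$mu, v2 = cc$bn2$v))
}

#' Train the attention-CNN
#'
#' Mini-batch Adam on class-weighted cross-entropy. Class weights are
#' inversely proportional to training-class frequency when
#' `class_weight = "balanced"`. Training stops early when the validation
#' loss has not improved by `min_delta` for `patience` epochs; the
#' learning rate is multiplied by `lr_factor` after `lr_patience` epochs
#' without improvement; the best-validation weights are restored.
#'
#' @param net An [build_attention_cnn()] network.
#' @param x Epoch tensor, array `n x channels x species x time` (see
#'   [epoch_tensor()]).
#' @param y Binary labels (1/`"correct"` = positive).
#' @param val Indices of the validation rows; the remaining rows train.
#'   Must be nonempty and disjoint from training by construction.
#' @param class_weight `"balanced"` or `"none"`.
#' @param seed Seed controlling shuffling and dropout for the run.
#' @return The fitted `olf_cnn` with a `history` tibble attached.
#' @export
train_deep <- function(net, x, y, val, class_weight = c("balanced", "none"),
                       seed = net$seed) {
  class_weight <- match.arg(class_weight)
  y <- as_binary_label(y)
  val <- unique(as.integer(val))
  if (!length(val)) abort("validation set must be nonempty")
  if (any(val < 1 | val > dim(x)[1])) abort("validation indices out of range")
  tr <- setdiff(seq_len(dim(x)[1]), val)
  if (length(unique(y[tr])) < 2) abort("training labels contain a single class")
  cfg <- net$cfg
  w_class <- if (class_weight == "balanced") {
    tab <- table(factor(y[tr], levels = c(0, 1)))
    as.numeric(length(tr) / (2 * pmax(tab, 1)))
  } else c(1, 1)
  Xtr <- x[tr, , , , drop = FALSE]; ytr <- y[tr]
  Xva <- x[val, , , , drop = FALSE]; yva <- y[val]
  adam <- list(m = lapply(net$par, function(p) p * 0),
               v = lapply(net$par, function(p) p * 0), t = 0)
  lr <- cfg$lr
  best <- list(loss = Inf, par = net$par, bn = net$bn, epoch = 0L)
  since_best <- 0L; since_lr <- 0L
  history <- list()
  set.seed(derive_seed(seed, "train"))
  n_tr <- length(ytr)
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(n_tr)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n_tr, by = cfg$batch)) {
      bidx <- ord[start:min(start + cfg$batch - 1, n_tr)]
      if (length(bidx) < 2) next
      Xb <- tensor_batch(Xtr, bidx)
      lg <- cnn_loss_grads(net, Xb, ytr[bidx], w_class)
      adam$t <- adam$t + 1
      for (nm in names(net$par)) {
        gmat <- lg$grads[[nm]]
        adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * gmat
        adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * gmat^2
        mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
        vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
        net$par[[nm]] <- net$par[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
      # update BN running stats (momentum 0.1)
      net$bn$m1 <- 0.9 * net$bn$m1 + 0.1 * lg$bn_batch$m1
      net$bn$v1 <- 0.9 * net$bn$v1 + 0.1 * lg$bn_batch$v1
      net$bn$m2 <- 0.9 * net$bn$m2 + 0.1 * lg$bn_batch$m2
      net$bn$v2 <- 0.9 * net$bn$v2 + 0.1 * lg$bn_batch$v2
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    val_loss <- cnn_eval_loss(net, Xva, yva, w_class)
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / max(nb, 1),
                                    val_loss = val_loss, lr = lr)
    if (val_loss < best$loss - cfg$min_delta) {
      best <- list(loss = val_loss, par = net$par, bn = net$bn, epoch = ep)
      since_best <- 0L; since_lr <- 0L
    } else {
      since_best <- since_best + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= cfg$lr_patience) {
        lr <- lr * cfg$lr_factor
        since_lr <- 0L
      }
      if (since_best >= cfg$patience) break
    }
  }
  net$par <- best$par
  net$bn <- best$bn
  net$trained <- TRUE
  net$best_epoch <- best$epoch
  net$epochs_trained <- length(history)
  net$history <- dplyr::bind_rows(history)
  net
}

cnn_eval_loss <- function(net, x, y, w_class) {
  fw <- cnn_forward(net, tensor_batch(x, seq_len(dim(x)[1])), dim(x)[1],
                    train = FALSE)
  picked <- fw$P[cbind(y + 1, seq_len(length(y)))]
  mean(-w_class[y + 1] * log(pmax(picked, 1e-12)))
}

#' @export
predict_proba.olf_cnn <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != model$n_channels || d[3] != model$n_species ||
      d[4] != model$n_time) {
    abort("epoch tensor shape does not match the network input shape")
  }
  fw <- cnn_forward(model, tensor_batch(x, seq_len(d[1])), d[1], train = FALSE)
  as.numeric(fw$P[2, ])
}

#' Attention maps of a fitted network
#'
#' @param model A fitted `olf_cnn`.
#' @param x Epoch tensor (`n x channels x species x time`).
#' @return List with `channel` (n x channels softmax weights) and
#'   `temporal` (n x time weights, upsampled to the input resolution;
#'   each row sums to 1 over its axis).
#' @export
attention_weights <- function(model, x) {
  d <- dim(x)
  fw <- cnn_forward(model, tensor_batch(x, seq_len(d[1])), d[1], train = FALSE)
  tem <- t(fw$A_time)
  # upsample the convolved time axis back to input samples
  up <- t(apply(tem, 1, function(a) {
    y <- stats::approx(seq_along(a), a, n = model$n_time)$y
    y / sum(y)
  }))
  list(channel = t(fw$A_chan), temporal = up)
}

#' @export
print.olf_cnn <- function(x, ...) {
  cat("<olf_cnn> input ", x$n_channels, "ch x ", x$n_species, "sp x ",
      x$n_time, "t, ", x$n_par, " parameters",
      if (x$trained) paste0("; trained ", x$epochs_trained, " epochs (best ",
                            x$best_epoch, ")") else " (untrained)", "\n",
      sep = "")
  invisible(x)
}

#' Stack preprocessed epochs into a CNN input tensor
#'
#' @param epochs An `olf_epochs` collection.
#' @param downsample Keep every `downsample`-th sample (the series are
#'   already low-passed at 0.20 Hz, so decimation by small factors is
#'   alias-free).
#' @return List with `x` (array `n x channels x species x time`) and
#'   `meta` (the epoch metadata tibble).
#' @export
epoch_tensor <- function(epochs, downsample = 4L) {
  stopifnot(length(epochs$epochs) > 0)
  d <- dim(epochs$epochs[[1]]$data)
  keep <- seq(1, d[3], by = downsample)
  n <- length(epochs$epochs)
  x <- array(0, c(n, d[1], d[2], length(keep)))
  for (i in seq_len(n)) {
    x[i, , , ] <- epochs$epochs[[i]]$data[, , keep]
  }
  list(x = x, meta = epochs$meta)
}
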