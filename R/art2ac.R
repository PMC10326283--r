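# Articulatory-to-acoustic synthesizer: a feedforward network predicting the
# 25 mel-cepstral coefficients of a frame from 10 past, the current, and 1
# future articulatory frames (12 x 14 = 168 inputs). Trained with Adam on a
# mean-squared-error loss, 25% dropout, batches of 32, and early stopping
# with a patience of 20 epochs; fine-tuning restarts the same loop from the
# pretrained weights at a smaller step size.

ART_PAST <- 10L
ART_FUTURE <- 1L
ART_CONTEXT <- ART_PAST + 1L + ART_FUTURE   # 12 frames

#' Synthesizer network configuration
#'
#' @param hidden hidden layer widths (default c(512, 512, 512)).
#' @param dropout dropout probability on hidden activations (default 0.25).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size for training (default 1e-3).
#' @param finetune_rate Adam step size for fine-tuning (default 1e-4).
#' @param patience early-stopping patience in epochs (default 20).
#' @param max_epochs hard epoch cap (default 500).
#' @param split train/validation/test fractions (default c(0.8, 0.1, 0.1)).
#' @return a `synthnet_config` list.
#' @export
synthnet_config <- function(hidden = c(512L, 512L, 512L), dropout = 0.25,
                            batch_size = 32L, learning_rate = 1e-3,
                            finetune_rate = 1e-4, patience = 20L,
                            max_epochs = 500L, split = c(0.8, 0.1, 0.1)) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-9, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, finetune_rate = finetune_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), split = split),
            class = "synthnet_config")
}

#' Build the 12-frame articulatory context matrix
#'
#' Row s concatenates articulatory frames s-10 .. s+1 (edge replication at
#' the boundaries), so predictions add only a single 10 ms look-ahead.
#'
#' @param ema articulatory matrix or `feature_track` (frames x 14).
#' @return frames x (12 * n_features) matrix.
#' @export
ema_context <- function(ema) {
  m <- as.matrix(unclass(ema))
  n <- nrow(m)
  if (n < ART_CONTEXT) stop("articulatory track shorter than 12 frames")
  offs <- (-ART_PAST):ART_FUTURE
  do.call(cbind, lapply(offs, function(o)
    m[clamp_idx(seq_len(n) + o, n), , drop = FALSE]))
}

# --- minimal MLP with tanh hidden layers, linear output, Adam, dropout -----

mlp_init <- function(sizes) {
  # Glorot-uniform initialization
  L <- length(sizes) - 1
  lapply(seq_len(L), function(l) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                    sizes[l], sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  })
}

mlp_forward <- function(layers, X, dropout = 0, train = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (l < L) {
      a <- tanh(z)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                       nrow(a), ncol(a))
        a <- a * mask
        masks[[l]] <- mask
      }
      acts[[l + 1]] <- a
    } else {
      acts[[l + 1]] <- z
    }
  }
  list(acts = acts, masks = masks)
}

mlp_backward <- function(layers, fw, Ytrue) {
  L <- length(layers)
  n <- nrow(Ytrue)
  grads <- vector("list", L)
  delta <- 2 * (fw$acts[[L + 1]] - Ytrue) / (n * ncol(Ytrue))
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(fw$acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      a <- fw$acts[[l]]
      delta <- delta * (1 - a * a)   # tanh' on the (possibly masked) activation
      if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                  mb = 0 * l$b, vb = 0 * l$b))
}

adam_step <- function(layers, grads, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(layers)) {
    st[[l]]$mW <- b1 * st[[l]]$mW + (1 - b1) * grads[[l]]$W
    st[[l]]$vW <- b2 * st[[l]]$vW + (1 - b2) * grads[[l]]$W^2
    st[[l]]$mb <- b1 * st[[l]]$mb + (1 - b1) * grads[[l]]$b
    st[[l]]$vb <- b2 * st[[l]]$vb + (1 - b2) * grads[[l]]$b^2
    mhW <- st[[l]]$mW / (1 - b1^t); vhW <- st[[l]]$vW / (1 - b2^t)
    mhb <- st[[l]]$mb / (1 - b1^t); vhb <- st[[l]]$vb / (1 - b2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
  }
  list(layers = layers, state = st)
}

mlp_mse <- function(layers, X, Y) {
  mean((mlp_forward(layers, X)$acts[[length(layers) + 1]] - Y)^2)
}

# Core Adam training loop with early stopping; X/Y already z-scored.
mlp_train <- function(layers, Xtr, Ytr, Xval, Yval, cfg, lr) {
  st <- adam_state(layers)
  best <- layers
  best_val <- mlp_mse(layers, Xval, Yval)
  best_epoch <- 0L
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  n <- nrow(Xtr)
  step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      fw <- mlp_forward(layers, Xtr[idx, , drop = FALSE], cfg$dropout,
                        train = TRUE)
      gr <- mlp_backward(layers, fw, Ytr[idx, , drop = FALSE])
      step <- step + 1L
      upd <- adam_step(layers, gr, st, lr, step)
      layers <- upd$layers; st <- upd$state
    }
    val <- mlp_mse(layers, Xval, Yval)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_mse = mlp_mse(layers, Xtr, Ytr),
                                val_mse = val))
    if (val < best_val) { best_val <- val; best <- layers; best_epoch <- epoch }
    if (epoch - best_epoch >= cfg$patience) break
  }
  list(layers = best, history = history, best_val = best_val,
       best_epoch = best_epoch)
}

#' Train the articulatory-to-acoustic synthesizer
#'
#' Trains the feedforward network on frame-aligned articulatory/mel pairs
#' from the reference corpus, on a random 80/10/10 frame split, minimizing
#' mean squared error with Adam and early stopping (best-epoch weights
#' restored). Deterministic for a given seed.
#'
#' @param ema_list list of articulatory `feature_track`s (frames x 14).
#' @param mel_list list of aligned mel `feature_track`s (frames x 25).
#' @param cfg a `synthnet_config`.
#' @param seed RNG seed.
#' @return a `synth_net` (weights, z-score states, config, training history).
#' @export
train_synthesizer <- function(ema_list, mel_list, cfg = synthnet_config(),
                              seed = 1) {
  stopifnot(length(ema_list) == length(mel_list), length(ema_list) >= 1)
  X <- do.call(rbind, lapply(ema_list, ema_context))
  Y <- do.call(rbind, lapply(mel_list, function(m) as.matrix(unclass(m))))
  if (nrow(X) != nrow(Y)) stop("articulatory and mel tracks not frame-aligned")
  if (nrow(X) < 10 * ART_CONTEXT) stop("corpus too short to train")
  with_seed(seed, {
    zx <- fit_zscore(X); zy <- fit_zscore(Y)
    Xz <- apply_zscore(zx, X); Yz <- apply_zscore(zy, Y)
    n <- nrow(Xz)
    ord <- sample.int(n)
    n_tr <- floor(cfg$split[1] * n)
    n_val <- floor(cfg$split[2] * n)
    tr <- ord[seq_len(n_tr)]
    val <- ord[n_tr + seq_len(n_val)]
    layers <- mlp_init(c(ncol(X), cfg$hidden, ncol(Y)))
    fit <- mlp_train(layers, Xz[tr, , drop = FALSE], Yz[tr, , drop = FALSE],
                     Xz[val, , drop = FALSE], Yz[val, , drop = FALSE],
                     cfg, cfg$learning_rate)
    structure(list(layers = fit$layers, zx = zx, zy = zy, config = cfg,
                   history = fit$history, best_val = fit$best_val,
                   n_inputs = ncol(X), n_outputs = ncol(Y)),
              class = "synth_net")
  })
}

#' @export
print.synth_net <- function(x, ...) {
  cat(sprintf("<synth_net> %d -> %s -> %d, %d epochs, best val MSE %.4g\n",
              x$n_inputs, paste(x$config$hidden, collapse = "-"),
              x$n_outputs, nrow(x$history), x$best_val))
  invisible(x)
}

#' Fine-tune a trained synthesizer on new articulatory/mel pairs
#'
#' Runs the same training loop initialized from the pretrained weights
#' (smaller Adam step), typically on decoded patient articulation and the
#' patient's mel targets. The input network is not modified.
#'
#' @param net a trained `synth_net`.
#' @param ema_list,mel_list frame-aligned articulatory and mel tracks.
#' @param cfg a `synthnet_config` (defaults to the network's own).
#' @param seed RNG seed.
#' @param epochs optional hard epoch cap overriding `cfg$max_epochs`; 0
#'   returns a copy of the pretrained network unchanged.
#' @return a new fine-tuned `synth_net`.
#' @export
fine_tune <- function(net, ema_list, mel_list, cfg = NULL, seed = 1,
                      epochs = NULL) {
  stopifnot(inherits(net, "synth_net"))
  if (is.null(cfg)) cfg <- net$config
  X <- do.call(rbind, lapply(ema_list, ema_context))
  Y <- do.call(rbind, lapply(mel_list, function(m) as.matrix(unclass(m))))
  if (ncol(X) != net$n_inputs || ncol(Y) != net$n_outputs)
    stop("architecture mismatch between network and data")
  if (nrow(X) != nrow(Y)) stop("tracks not frame-aligned")
  if (!is.null(epochs)) cfg$max_epochs <- as.integer(epochs)
  out <- net
  out$config <- cfg
  if (!is.null(epochs) && epochs == 0) return(out)
  with_seed(seed, {
    # inputs/targets standardized with the pretrained statistics so the
    # pretrained weights remain a meaningful initialization
    Xz <- apply_zscore(net$zx, X); Yz <- apply_zscore(net$zy, Y)
    n <- nrow(Xz)
    ord <- sample.int(n)
    n_tr <- floor(cfg$split[1] * n)
    n_val <- max(1L, floor(cfg$split[2] * n))
    tr <- ord[seq_len(n_tr)]
    val <- ord[n_tr + seq_len(n_val)]
    fit <- mlp_train(net$layers, Xz[tr, , drop = FALSE], Yz[tr, , drop = FALSE],
                     Xz[val, , drop = FALSE], Yz[val, , drop = FALSE],
                     cfg, cfg$finetune_rate)
    out$layers <- fit$layers
    out$history <- fit$history
    out$best_val <- fit$best_val
    out
  })
}

#' Predict mel cepstrum from articulatory trajectories
#'
#' Deterministic inference (dropout off); frame s consumes articulatory
#' frames s-10 .. s+1 with edge replication.
#'
#' @param net a `synth_net`.
#' @param ema articulatory `feature_track` (>= 12 frames).
#' @return a mel `feature_track` (frames x 25).
#' @export
predict_mel <- function(net, ema) {
  stopifnot(inherits(net, "synth_net"))
  X <- ema_context(ema)
  if (ncol(X) != net$n_inputs) stop("articulatory dimension mismatch")
  Xz <- apply_zscore(net$zx, X)
  Yz <- mlp_forward(net$layers, Xz)$acts[[length(net$layers) + 1]]
  feature_track(invert_zscore(net$zy, Yz), rate = 100,
                labels = paste0("c", seq_len(net$n_outputs) - 1))
}
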