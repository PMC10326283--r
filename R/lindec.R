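# Linear decoders: z-score and PCA preprocessing, ordinary least squares,
# three ridge variants (L-curve, cross-validated, cross-validated with one
# penalty per output), partial least squares, and the full fit/predict
# pipeline (z-score -> delay -> PCA -> context -> weights).

DEFAULT_LAMBDA_GRID <- 10^seq(-4, 4, length.out = 25)

#' Fit per-feature z-score statistics
#'
#' Zero-variance features keep sd = 1 (the column maps to a constant 0), so
#' dimensions stay stable across folds.
#'
#' @param X frames x features matrix (or `feature_track`).
#' @return a `zscore_state` with `mean` and `sd`.
#' @export
fit_zscore <- function(X) {
  X <- as.matrix(unclass(X))
  if (nrow(X) < 2) stop("need >= 2 frames to fit z-score statistics")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  structure(list(mean = m, sd = s), class = "zscore_state")
}

#' Apply a fitted z-score transform
#' @param state a `zscore_state` from [fit_zscore()].
#' @param X matrix or `feature_track` with matching feature count.
#' @return the transformed object (same class as input).
#' @export
apply_zscore <- function(state, X) {
  stopifnot(inherits(state, "zscore_state"))
  m <- as.matrix(unclass(X))
  if (ncol(m) != length(state$mean)) stop("feature count mismatch")
  out <- sweep(sweep(m, 2, state$mean), 2, state$sd, "/")
  if (inherits(X, "feature_track"))
    feature_track(out, rate = frame_rate(X), labels = colnames(m))
  else out
}

#' Invert a z-score transform
#' @param state a `zscore_state`.
#' @param X transformed matrix.
#' @return matrix in original units.
#' @export
invert_zscore <- function(state, X) {
  sweep(sweep(as.matrix(unclass(X)), 2, state$sd, "*"), 2, state$mean, "+")
}

#' Fit a PCA basis
#'
#' Top principal axes by explained variance. In the decoding pipeline this is
#' applied to the z-scored, delayed (but not yet context-concatenated) neural
#' features, and never to the targets.
#'
#' @param X frames x features matrix.
#' @param n_components number of components (<= min(frames, features)).
#' @return a `pca_state` with orthonormal `rotation` (features x components),
#'   `center`, and `explained` variances.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(unclass(X))
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(frames, features)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(rotation = pc$rotation, center = pc$center,
                 explained = pc$sdev[seq_len(n_components)]^2),
            class = "pca_state")
}

#' Project onto a fitted PCA basis
#' @param state a `pca_state`.
#' @param X matrix or `feature_track`.
#' @return projected object (frames x components).
#' @export
apply_pca <- function(state, X) {
  stopifnot(inherits(state, "pca_state"))
  m <- as.matrix(unclass(X))
  out <- sweep(m, 2, state$center) %*% state$rotation
  if (inherits(X, "feature_track"))
    feature_track(out, rate = frame_rate(X),
                  labels = colnames(state$rotation))
  else out
}

# --- low-level weight solvers (matrices assumed column-centered) -----------
#
# All solvers work from the crossproducts X'X (p x p) and X'Y, which is much
# cheaper than a thin SVD of X when frames outnumber features.

# OLS keeps a QR factorization of X itself: forming X'X squares the
# condition number and loses the weakly excited directions.
ols_weights <- function(X, Y) {
  qrX <- qr(X, LAPACK = TRUE)
  R <- qr.R(qrX)
  dR <- abs(diag(R))
  if (min(dR) <= max(dR) * max(dim(X)) * .Machine$double.eps) {
    warning("rank-deficient design: returning the minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    W <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    return(W)
  }
  W <- backsolve(R, qr.qty(qrX, as.matrix(Y))[seq_len(ncol(X)), ,
                                              drop = FALSE])
  W[qrX$pivot, ] <- W
  W
}

# eigendecomposition context shared by the ridge variants
ridge_context <- function(X, Y) {
  eg <- eigen(crossprod(X), symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  list(V = eg$vectors, d2 = d2,
       B = crossprod(eg$vectors, crossprod(X, Y)),   # V' X'Y
       yss = colSums(Y^2), n = nrow(X))
}

ridge_weights_eig <- function(ctx, lambda) {
  if (length(lambda) == 1) {
    ctx$V %*% (ctx$B / (ctx$d2 + lambda))
  } else {
    W <- matrix(0, nrow(ctx$V), ncol(ctx$B))
    for (j in seq_len(ncol(ctx$B)))
      W[, j] <- ctx$V %*% (ctx$B[, j] / (ctx$d2 + lambda[j]))
    W
  }
}

# L-curve corner: maximum curvature of (log residual norm, log solution norm)
# across the lambda grid, after spline smoothing of both branches.
lcurve_lambda <- function(ctx, grid) {
  b2 <- rowSums(ctx$B^2)
  y2 <- sum(ctx$yss)
  rho <- eta <- numeric(length(grid))
  for (g in seq_along(grid)) {
    den <- ctx$d2 + grid[g]
    eta[g] <- sqrt(sum(b2 / den^2))
    fit2 <- sum(b2 * ctx$d2 / den^2)          # ||XW||^2
    tr_wxy <- sum(b2 / den)                   # tr(W' X'Y)
    rho[g] <- sqrt(max(y2 - 2 * tr_wxy + fit2, 1e-300))
  }
  lt <- log(grid); lr <- log(pmax(rho, 1e-300)); le <- log(pmax(eta, 1e-300))
  fit_r <- stats::smooth.spline(lt, lr, df = min(8, length(grid) - 1))
  fit_e <- stats::smooth.spline(lt, le, df = min(8, length(grid) - 1))
  r1 <- stats::predict(fit_r, lt, deriv = 1)$y
  r2 <- stats::predict(fit_r, lt, deriv = 2)$y
  e1 <- stats::predict(fit_e, lt, deriv = 1)$y
  e2 <- stats::predict(fit_e, lt, deriv = 2)$y
  kappa <- (r1 * e2 - r2 * e1) / (r1^2 + e1^2)^1.5
  grid[which.max(kappa)]
}

# Inner K-fold CV curves of validation MSE per output across the lambda
# grid, computed from per-fold crossproducts.
ridge_cv_curves <- function(X, Y, grid, nfolds = 5) {
  n <- nrow(X)
  # contiguous blocks: interleaved folds would leak through the strong
  # autocorrelation of adjacent frames and bias lambda low
  fold <- rep(seq_len(nfolds), each = ceiling(n / nfolds))[seq_len(n)]
  XtX_f <- vector("list", nfolds); XtY_f <- vector("list", nfolds)
  yss_f <- vector("list", nfolds); n_f <- integer(nfolds)
  for (f in seq_len(nfolds)) {
    idx <- fold == f
    Xf <- X[idx, , drop = FALSE]; Yf <- Y[idx, , drop = FALSE]
    XtX_f[[f]] <- crossprod(Xf); XtY_f[[f]] <- crossprod(Xf, Yf)
    yss_f[[f]] <- colSums(Yf^2); n_f[f] <- sum(idx)
  }
  XtX <- Reduce(`+`, XtX_f); XtY <- Reduce(`+`, XtY_f)
  mse <- matrix(0, length(grid), ncol(Y))
  for (f in seq_len(nfolds)) {
    eg <- eigen(XtX - XtX_f[[f]], symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    B <- crossprod(eg$vectors, XtY - XtY_f[[f]])
    for (g in seq_along(grid)) {
      W <- eg$vectors %*% (B / (d2 + grid[g]))
      # validation MSE from fold crossproducts
      quad <- colSums(W * (XtX_f[[f]] %*% W))
      mse[g, ] <- mse[g, ] +
        (yss_f[[f]] - 2 * colSums(W * XtY_f[[f]]) + quad) / n_f[f] / nfolds
    }
  }
  mse
}

#' Ordinary least-squares decoder
#'
#' Least-squares weights per output; matches the normal-equations solution on
#' full-rank designs, minimum-norm solution (with a warning) otherwise.
#'
#' @param X frames x features matrix.
#' @param Y frames x outputs matrix.
#' @return a `decoder_model` (kind "ols").
#' @export
fit_ols <- function(X, Y) {
  X <- as.matrix(unclass(X)); Y <- as.matrix(unclass(Y))
  new_decoder("ols", ols_weights(X, Y), hyper = list())
}

#' Ridge decoder with automatic regularization selection
#'
#' Ridge solution (X'X + lambda I)^-1 X'Y with lambda chosen by the L-curve
#' corner ("lcurve"), inner K-fold cross-validation pooled over outputs
#' ("cv"), or cross-validation run independently per output column
#' ("cv_multi").
#'
#' @param X frames x features matrix.
#' @param Y frames x outputs matrix.
#' @param method "lcurve", "cv" or "cv_multi".
#' @param lambda_grid candidate penalties (default 25 points, 1e-4..1e4,
#'   log-spaced).
#' @param nfolds inner CV folds (default 5).
#' @return a `decoder_model` (kind "ridge_<method>"); `hyper$lambda` holds
#'   the selected penalty (scalar, or per-output vector for "cv_multi").
#' @export
fit_ridge <- function(X, Y, method = c("lcurve", "cv", "cv_multi"),
                      lambda_grid = DEFAULT_LAMBDA_GRID, nfolds = 5) {
  method <- match.arg(method)
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  X <- as.matrix(unclass(X)); Y <- as.matrix(unclass(Y))
  # the penalty acts on standardized predictors (standard ridge practice);
  # weights are mapped back to the original column scale afterwards
  cs <- apply(X, 2, stats::sd)
  cs[cs == 0 | !is.finite(cs)] <- 1
  Xs <- sweep(X, 2, cs, "/")
  if (method == "lcurve") {
    ctx <- ridge_context(Xs, Y)
    lambda <- lcurve_lambda(ctx, lambda_grid)
    W <- ridge_weights_eig(ctx, lambda)
  } else {
    mse <- ridge_cv_curves(Xs, Y, lambda_grid, nfolds)
    lambda <- if (method == "cv") lambda_grid[which.min(rowMeans(mse))]
      else lambda_grid[apply(mse, 2, which.min)]
    ctx <- ridge_context(Xs, Y)
    W <- ridge_weights_eig(ctx, lambda)
  }
  new_decoder(paste0("ridge_", method), W / cs,
              hyper = list(lambda = lambda))
}

#' Partial least squares (PLS2) decoder
#'
#' NIPALS PLS2 with deflation: one shared latent space for all outputs, with
#' the equivalent linear weight matrix exposed. In the decoding pipeline PLS
#' is fitted after concatenation of the time context.
#'
#' @param X frames x features matrix.
#' @param Y frames x outputs matrix.
#' @param n_components number of latent components.
#' @param max_iter,tol NIPALS iteration controls.
#' @return a `decoder_model` (kind "pls").
#' @export
fit_pls <- function(X, Y, n_components, max_iter = 500, tol = 1e-6) {
  X <- as.matrix(unclass(X)); Y <- as.matrix(unclass(Y))
  if (n_components < 1 || n_components > min(dim(X)))
    stop("n_components must be in 1..min(frames, features)")
  p <- ncol(X); q <- ncol(Y)
  # NIPALS-PLS2 with deflation, computed in improved-kernel form: the
  # component sequence is identical, but only X'Y is deflated (X'X stays
  # untouched), keeping memory flat for wide context-concatenated designs.
  # The NIPALS inner loop becomes a power iteration on the q x q matrix
  # (X'Y)'(X'Y).
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  W <- matrix(0, p, n_components)
  R <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  kept <- 0L
  for (a in seq_len(n_components)) {
    if (sum(XtY^2) < 1e-24) break
    if (q == 1) {
      w <- XtY[, 1]
    } else {
      M <- crossprod(XtY)
      v <- M[, which.max(diag(M))]
      v <- v / sqrt(sum(v^2))
      for (it in seq_len(max_iter)) {
        v_new <- M %*% v
        v_new <- v_new / sqrt(sum(v_new^2))
        if (sqrt(sum((v_new - v)^2)) < tol) { v <- v_new; break }
        v <- v_new
      }
      w <- as.numeric(XtY %*% v)
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    r <- w
    if (a > 1) {
      idx <- seq_len(a - 1)
      r <- r - R[, idx, drop = FALSE] %*%
        crossprod(P[, idx, drop = FALSE], w)
    }
    d <- as.numeric(crossprod(r, XtX %*% r))     # ||t||^2 for t = Xr
    if (d < 1e-12) break
    pv <- as.numeric(XtX %*% r) / d
    qv <- as.numeric(crossprod(XtY, r)) / d
    XtY <- XtY - d * pv %*% t(qv)
    kept <- a
    W[, a] <- w; R[, a] <- r; P[, a] <- pv; Q[, a] <- qv
  }
  R <- R[, seq_len(kept), drop = FALSE]
  Q <- Q[, seq_len(kept), drop = FALSE]
  B <- R %*% t(Q)
  new_decoder("pls", B, hyper = list(n_components = kept))
}

new_decoder <- function(kind, weights, hyper = list(), preproc = NULL) {
  structure(list(kind = kind, weights = weights,
                 intercept = rep(0, ncol(weights)),
                 hyper = hyper, preproc = preproc),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> kind=%s weights %d x %d%s\n", x$kind,
              nrow(x$weights), ncol(x$weights),
              if (!is.null(x$preproc)) " (with preprocessing pipeline)" else ""))
  invisible(x)
}

#' Train a decoder through the full preprocessing pipeline
#'
#' Fits the decoding pipeline in its canonical order: (1) inputs and targets
#' z-scored with training statistics; (2) the neural-to-target delay applied;
#' (3) optional PCA reduction of the delayed neural features (never of the
#' targets); (4) temporal context concatenated; then the linear decoder is
#' fitted on the centered design. PCA is fitted before the context
#' concatenation; PLS performs its own reduction and is fitted after context
#' concatenation without PCA.
#'
#' @param neural list of per-sentence neural `feature_track`s (frames x d).
#' @param targets list of aligned per-sentence target tracks (frames x q).
#' @param kind "ols", "ridge_lcurve", "ridge_cv", "ridge_cv_multi" or "pls".
#' @param windowing a `windowing_config`.
#' @param n_pca optional PCA component count (ignored for "pls").
#' @param n_components PLS component count (kind "pls").
#' @param lambda_grid,nfolds ridge regularization controls.
#' @return a `decoder_model` carrying the full preprocessing state.
#' @export
train_decoder <- function(neural, targets, kind = "ols",
                          windowing = windowing_config(0, 0),
                          n_pca = NULL, n_components = 12,
                          lambda_grid = DEFAULT_LAMBDA_GRID, nfolds = 5) {
  stopifnot(is.list(neural), is.list(targets),
            length(neural) == length(targets))
  kind <- match.arg(kind, c("ols", "ridge_lcurve", "ridge_cv",
                            "ridge_cv_multi", "pls"))
  zx <- fit_zscore(do.call(rbind, lapply(neural, unclass)))
  zy <- fit_zscore(do.call(rbind, lapply(targets, unclass)))
  delay_cfg <- windowing_config(0, windowing$delay_ms)
  ctx_cfg <- windowing_config(windowing$context_ms, 0)
  delayed <- lapply(neural, function(x)
    window_features(apply_zscore(zx, feature_track(unclass(x))), delay_cfg))
  pca <- NULL
  if (!is.null(n_pca) && kind != "pls") {
    pca <- fit_pca(do.call(rbind, lapply(delayed, unclass)), n_pca)
    delayed <- lapply(delayed, function(x) apply_pca(pca, x))
  }
  Xm <- do.call(rbind, lapply(delayed, function(x)
    unclass(window_features(x, ctx_cfg))))
  Ym <- do.call(rbind, lapply(targets, function(y)
    apply_zscore(zy, as.matrix(unclass(y)))))
  xc <- colMeans(Xm); yc <- colMeans(Ym)
  Xc <- sweep(Xm, 2, xc); Yc <- sweep(Ym, 2, yc)
  model <- switch(kind,
    ols = fit_ols(Xc, Yc),
    ridge_lcurve = fit_ridge(Xc, Yc, "lcurve", lambda_grid, nfolds),
    ridge_cv = fit_ridge(Xc, Yc, "cv", lambda_grid, nfolds),
    ridge_cv_multi = fit_ridge(Xc, Yc, "cv_multi", lambda_grid, nfolds),
    pls = fit_pls(Xc, Yc, n_components))
  model$preproc <- list(zx = zx, zy = zy, pca = pca, windowing = windowing,
                        xcenter = xc, ycenter = yc,
                        target_labels = colnames(as.matrix(unclass(targets[[1]]))))
  model
}

#' Predict speech features from neural features
#'
#' Applies the stored pipeline (z-score, delay, PCA if fitted, context,
#' weights) and returns predictions in original target units.
#'
#' @param object a `decoder_model` from [train_decoder()].
#' @param newdata a neural `feature_track` (one sentence) or list thereof.
#' @param ... unused.
#' @return a prediction `feature_track` (or list of them).
#' @export
predict.decoder_model <- function(object, newdata, ...) {
  if (is.null(object$preproc))
    stop("this decoder was fitted on raw matrices; apply it directly")
  if (is.list(newdata) && !inherits(newdata, "feature_track"))
    return(lapply(newdata, function(x) predict(object, x)))
  pp <- object$preproc
  x <- apply_zscore(pp$zx, feature_track(unclass(newdata)))
  x <- window_features(x, windowing_config(0, pp$windowing$delay_ms))
  if (!is.null(pp$pca)) x <- apply_pca(pp$pca, x)
  x <- unclass(window_features(x, windowing_config(pp$windowing$context_ms, 0)))
  pred <- sweep(x, 2, pp$xcenter) %*% object$weights
  pred <- sweep(pred, 2, pp$ycenter, "+")
  pred <- invert_zscore(pp$zy, pred)
  feature_track(pred, rate = 100, labels = pp$target_labels)
}
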