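# Cross-validated evaluation of the direct and indirect decoding paradigms:
# sentence-level 10-fold cross-validation, per-sentence Pearson/MSE metrics,
# chance levels by global neural-frame shuffling, Bonferroni-corrected
# Wilcoxon signed-rank tests, and the Quade omnibus test with Conover
# pairwise post-hoc comparisons.

#' Per-day overt-sentence protocol table
#'
#' Read and repeated overt sentence counts per recording day.
#'
#' @return data frame with columns `day`, `read`, `repeated`.
#' @export
default_protocol <- function() {
  data.frame(day = 1:3, read = c(97L, 141L, 153L), repeated = c(97L, 0L, 153L))
}

#' Total number of overt sentences in a protocol
#' @param protocol a protocol table as from [default_protocol()].
#' @return total count of read + repeated sentences.
#' @export
count_overt_sentences <- function(protocol = default_protocol()) {
  sum(protocol$read) + sum(protocol$repeated)
}

#' Build the per-sentence decoding dataset from a patient corpus
#'
#' Computes neural features for every sentence (common median reference,
#' then spectral features) and collects the aligned targets. If a reference
#' corpus is supplied, patient articulation is estimated by DTW transfer
#' (as in the real study) and the DTW-warped reference mel is attached as
#' the evaluation reference for non-fine-tuned indirect decoding; otherwise
#' the generator's ground-truth articulation is used.
#'
#' @param patient a patient corpus from [make_patient_corpus()].
#' @param reference optional reference corpus for DTW-estimated articulation.
#' @return a `decoding_data` list of per-sentence records (id, condition,
#'   neural, mel, f0, ema, optionally ref_warped_mel).
#' @export
build_decoding_data <- function(patient, reference = NULL) {
  sentences <- lapply(seq_along(patient$sentences), function(i) {
    s <- patient$sentences[[i]]
    rec <- common_median_reference(s$neural)
    feat <- spectral_features(rec)
    out <- list(id = s$id, condition = s$condition, neural = feat,
                mel = s$tracks$mel, f0 = s$tracks$f0, ema = s$tracks$ema)
    if (!is.null(reference)) {
      r <- reference$sentences[[i]]
      est <- estimate_patient_ema(
        r$tracks$mel, r$tracks$f0, as.numeric(r$tracks$speech), r$tracks$ema,
        s$tracks$mel, s$tracks$f0, as.numeric(s$tracks$speech))
      out$ema <- est$ema
      out$ref_warped_mel <- est$ref_warped_mel
      out$warp <- est$path
    }
    out
  })
  structure(list(sentences = sentences), class = "decoding_data")
}

#' Experiment configuration for cross-validated decoding
#'
#' @param paradigm "direct", "indirect_finetune" or "indirect_raw".
#' @param decoder one of "ols", "ridge_lcurve", "ridge_cv", "ridge_cv_multi",
#'   "pls".
#' @param windowing a `windowing_config`.
#' @param region electrode subset: "all", "frontal" or "temporal".
#' @param n_pca PCA components for non-PLS decoders (NULL = no PCA).
#' @param n_components PLS components.
#' @param n_folds cross-validation folds (default 10).
#' @param seed fold-assignment / training seed.
#' @param synth_net pretrained `synth_net` (required for indirect paradigms).
#' @param finetune_epochs optional epoch cap for per-fold fine-tuning.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(paradigm = c("direct", "indirect_finetune",
                                           "indirect_raw"),
                              decoder = "pls",
                              windowing = windowing_config(210, 0),
                              region = "all", n_pca = NULL, n_components = 12,
                              n_folds = 10L, seed = 1L, synth_net = NULL,
                              finetune_epochs = NULL) {
  paradigm <- match.arg(paradigm)
  if (paradigm != "direct" && is.null(synth_net))
    stop("indirect paradigms require a pretrained synth_net")
  structure(list(paradigm = paradigm, decoder = decoder,
                 windowing = windowing, region = region, n_pca = n_pca,
                 n_components = n_components, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), synth_net = synth_net,
                 finetune_epochs = finetune_epochs),
            class = "experiment_config")
}

# seeded fold assignment, stratified by condition; sizes differ by <= 1
make_folds <- function(conditions, n_folds, seed) {
  with_seed(child_seed(seed, "folds"), {
    ord <- unlist(lapply(split(seq_along(conditions), conditions), sample))
    folds <- integer(length(conditions))
    folds[ord] <- rep_len(seq_len(n_folds), length(conditions))
    folds
  })
}

#' Per-sentence, per-feature Pearson correlation
#'
#' Pearson r per feature column over the whole sentence; if either column
#' has zero variance r is defined as 0 and flagged degenerate.
#'
#' @param pred,truth aligned matrices or `feature_track`s (frames x q).
#' @return numeric vector of per-feature r with a logical `degenerate`
#'   attribute.
#' @export
pearson_per_sentence <- function(pred, truth) {
  p <- as.matrix(unclass(pred)); y <- as.matrix(unclass(truth))
  if (nrow(p) != nrow(y) || ncol(p) != ncol(y))
    stop("prediction / truth dimension mismatch")
  sp <- apply(p, 2, stats::sd); sy <- apply(y, 2, stats::sd)
  deg <- sp == 0 | sy == 0
  r <- numeric(ncol(p))
  ok <- !deg
  if (any(ok))
    r[ok] <- vapply(which(ok), function(j) stats::cor(p[, j], y[, j]),
                    numeric(1))
  names(r) <- colnames(y)
  attr(r, "degenerate") <- deg
  r
}

metric_rows <- function(id, fold, pred, truth, extra) {
  r <- pearson_per_sentence(pred, truth)
  mse <- colMeans((as.matrix(unclass(pred)) - as.matrix(unclass(truth)))^2)
  feats <- if (is.null(names(r))) paste0("y", seq_along(r)) else names(r)
  cbind(data.frame(sentence_id = id, fold = fold,
                   feature = rep(feats, 2),
                   metric = rep(c("pearson", "mse"), each = length(r)),
                   value = c(as.numeric(r), mse)),
        extra, row.names = NULL)
}

#' Run a cross-validated decoding experiment
#'
#' Sentence-level K-fold cross-validation. In each fold all preprocessing
#' (z-score, PCA/PLS) is fitted on the training folds only. Direct decoding
#' predicts the 25 mel coefficients and F0 from neural features; indirect
#' decoding predicts the 14 articulatory features for *all* sentences with
#' the fold's decoder, maps them to mel with the articulatory-to-acoustic
#' network (fine-tuned on the training folds' decoded articulation for
#' "indirect_finetune", used as-is for "indirect_raw"), and always decodes
#' F0 directly. Metrics (Pearson r and MSE per feature) are computed over
#' entire sentences, one value per sentence.
#'
#' @param data a `decoding_data` from [build_decoding_data()].
#' @param cfg an `experiment_config`.
#' @param .condition condition label for the emitted rows (internal; used by
#'   [chance_levels()]).
#' @return an `eval_table` data frame (sentence_id, fold, feature, metric,
#'   value, condition, paradigm, decoder, region).
#' @export
crossval_run <- function(data, cfg, .condition = "real") {
  stopifnot(inherits(data, "decoding_data"), inherits(cfg, "experiment_config"))
  sent <- data$sentences
  if (length(sent) < cfg$n_folds) stop("fewer sentences than folds")
  folds <- make_folds(vapply(sent, `[[`, "", "condition"), cfg$n_folds,
                      cfg$seed)
  neural <- lapply(sent, function(s) select_region(s$neural, cfg$region))
  mel <- lapply(sent, `[[`, "mel")
  f0 <- lapply(sent, `[[`, "f0")
  ema <- lapply(sent, `[[`, "ema")
  rows <- list()
  extra <- data.frame(condition = .condition, paradigm = cfg$paradigm,
                      decoder = cfg$decoder, region = cfg$region)
  for (f in seq_len(cfg$n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (cfg$paradigm == "direct") {
      targets <- lapply(seq_along(sent), function(i)
        feature_track(cbind(unclass(mel[[i]]), as.numeric(f0[[i]])),
                      labels = c(colnames(mel[[i]]), "f0")))
      model <- train_decoder(neural[tr], targets[tr], cfg$decoder,
                             cfg$windowing, cfg$n_pca, cfg$n_components)
      for (i in te)
        rows[[length(rows) + 1]] <- metric_rows(
          sent[[i]]$id, f, predict(model, neural[[i]]), targets[[i]], extra)
    } else {
      ema_model <- train_decoder(neural[tr], ema[tr], cfg$decoder,
                                 cfg$windowing, cfg$n_pca, cfg$n_components)
      decoded <- lapply(neural, function(x) predict(ema_model, x))
      f0_model <- train_decoder(neural[tr], f0[tr], cfg$decoder,
                                cfg$windowing, cfg$n_pca, cfg$n_components)
      net <- cfg$synth_net
      if (cfg$paradigm == "indirect_finetune") {
        net <- fine_tune(net, decoded[tr], mel[tr],
                         seed = child_seed(cfg$seed, paste0("ft", f)),
                         epochs = cfg$finetune_epochs)
        mel_truth <- mel
      } else {
        mel_truth <- lapply(sent, `[[`, "ref_warped_mel")
        if (any(vapply(mel_truth, is.null, TRUE)))
          stop("indirect_raw requires DTW-warped reference mel (missing warp)")
      }
      for (i in te) {
        mel_pred <- predict_mel(net, decoded[[i]])
        rows[[length(rows) + 1]] <- metric_rows(
          sent[[i]]$id, f, mel_pred, mel_truth[[i]], extra)
        rows[[length(rows) + 1]] <- metric_rows(
          sent[[i]]$id, f, predict(f0_model, neural[[i]]), f0[[i]], extra)
        # also report articulatory decoding accuracy on the test fold
        rows[[length(rows) + 1]] <- metric_rows(
          sent[[i]]$id, f, decoded[[i]], ema[[i]], extra)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_table", "data.frame")
  out
}

#' Chance-level evaluation by shuffling neural frames
#'
#' Permutes the neural feature frames uniformly across the whole corpus
#' (targets untouched), then runs the identical cross-validation pipeline.
#' The permutation is reproducible from `seed`.
#'
#' @param data a `decoding_data`.
#' @param cfg an `experiment_config`.
#' @param seed shuffle seed (default: derived from `cfg$seed`).
#' @return an `eval_table` with condition "chance".
#' @export
chance_levels <- function(data, cfg, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(cfg$seed, "shuffle")
  lens <- vapply(data$sentences, function(s) nrow(s$neural), integer(1))
  all_frames <- do.call(rbind, lapply(data$sentences, function(s)
    unclass(s$neural)))
  perm <- with_seed(seed, sample.int(nrow(all_frames)))
  shuffled <- all_frames[perm, , drop = FALSE]
  offs <- cumsum(c(0, lens))
  for (i in seq_along(data$sentences)) {
    tmpl <- data$sentences[[i]]$neural
    nf <- feature_track(shuffled[(offs[i] + 1):offs[i + 1], , drop = FALSE],
                        rate = frame_rate(tmpl), labels = colnames(tmpl))
    attr(nf, "montage") <- attr(tmpl, "montage")
    data$sentences[[i]]$neural <- nf
  }
  crossval_run(data, cfg, .condition = "chance")
}

#' Bonferroni-corrected Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test of `real` vs `chance`; exact
#' enumeration p-value for n <= 25 without ties, normal approximation with
#' continuity and tie corrections otherwise; the p-value is multiplied by
#' the number of comparisons `m` and capped at 1.
#'
#' @param real,chance paired equal-length numeric vectors.
#' @param m number of comparisons in the Bonferroni family (default 1).
#' @return a `stat_result` list (statistic, n, p_raw, p_corrected,
#'   bonferroni_m, method, all_zero flag).
#' @export
wilcoxon_bonferroni <- function(real, chance, m = 1) {
  if (length(real) != length(chance)) stop("paired samples of equal length")
  d <- real - chance
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = NA_real_, n = 0L, p_raw = 1,
                          p_corrected = 1, bonferroni_m = m,
                          method = "degenerate", all_zero = TRUE),
                     class = "stat_result"))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(W, n),
                 1 - stats::psignrank(W - 1, n))
    method <- "exact"
    z <- NA_real_
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    cc <- if (W == mu) 0 else sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  p <- min(p, 1)
  structure(list(statistic = W, z = z, n = n, p_raw = p,
                 p_corrected = min(1, m * p), bonferroni_m = m,
                 method = method, all_zero = FALSE),
            class = "stat_result")
}

#' Quade omnibus test with Conover pairwise post-hoc comparisons
#'
#' Nonparametric blocked comparison of k treatments over n blocks (every
#' block measured under every treatment). Within-block ranks are weighted by
#' the rank of the within-block range (Quade); the omnibus statistic is
#' F-distributed with (k-1, (n-1)(k-1)) degrees of freedom. If treatments
#' are tied everywhere the test is degenerate and p = 1 is returned. The
#' Conover pairwise statistics are t-distributed with (n-1)(k-1) degrees of
#' freedom.
#'
#' @param values n x k numeric matrix: blocks (e.g. sentences) in rows,
#'   treatments (e.g. decoding conditions) in columns.
#' @return a `stat_result` list with the omnibus statistic, degrees of
#'   freedom, p-value, and pairwise `t` and `p` matrices.
#' @export
quade_conover <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("incomplete blocks: non-finite values")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments")
  r <- t(apply(values, 1, rank))
  Q <- rank(apply(values, 1, function(x) diff(range(x))))
  S <- Q * (r - (k + 1) / 2)
  Sj <- colSums(S)
  A <- sum(S^2)
  B <- sum(Sj^2) / n
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (A - B < .Machine$double.eps * max(A, 1)) {
    pw_t <- matrix(0, k, k); pw_p <- matrix(1, k, k)
    return(structure(list(statistic = NA_real_, df = c(df1, df2), p = 1,
                          pairwise_t = pw_t, pairwise_p = pw_p,
                          degenerate = TRUE, method = "quade-conover"),
                     class = "stat_result"))
  }
  Fstat <- (n - 1) * B / (A - B)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  se <- sqrt(2 * n * (A - B) / df2)
  tmat <- abs(outer(Sj, Sj, `-`)) / se
  pmat <- 2 * stats::pt(-tmat, df2)
  diag(pmat) <- 1
  lab <- colnames(values)
  if (!is.null(lab)) { dimnames(tmat) <- list(lab, lab)
                       dimnames(pmat) <- list(lab, lab) }
  structure(list(statistic = Fstat, df = c(df1, df2), p = p,
                 pairwise_t = tmat, pairwise_p = pmat, degenerate = FALSE,
                 method = "quade-conover"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s", x$method))
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat(sprintf(": statistic = %.4g", x$statistic))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g", x$p))
  if (!is.null(x$p_corrected))
    cat(sprintf(", corrected p = %.4g (m = %d)", x$p_corrected,
                x$bonferroni_m))
  cat("\n")
  invisible(x)
}

#' Median per-sentence Pearson r by feature group
#'
#' Convenience summary of an `eval_table`: median of per-sentence Pearson
#' correlations over mel coefficients, F0 and articulatory features.
#'
#' @param tab an `eval_table`.
#' @param condition which condition to summarize (default "real").
#' @return named numeric vector (possibly with NA for absent groups).
#' @export
summarize_eval <- function(tab, condition = "real") {
  tab <- tab[tab$metric == "pearson" & tab$condition == condition, ]
  grp <- function(pat) {
    v <- tab$value[grepl(pat, tab$feature)]
    if (length(v)) stats::median(v) else NA_real_
  }
  c(mel = grp("^c[0-9]+$"), f0 = grp("^f0$"), ema = grp("^ema|_pc"))
}

#' Run the experiment sweeps over decoder settings
#'
#' Re-runs the cross-validated direct-decoding evaluation over grids of PCA
#' sizes, time contexts, delays and PLS component counts, mirroring the
#' study's comparison sweeps, and collects median per-sentence correlations.
#'
#' @param data a `decoding_data`.
#' @param base an `experiment_config` used as the template.
#' @param pca_sizes,contexts_ms,delays_ms,pls_components sweep grids (any
#'   may be NULL to skip).
#' @return data frame (sweep, setting, median_mel_r, median_f0_r).
#' @export
run_sweep <- function(data, base,
                      pca_sizes = c(10, 20, 50, 100, 200),
                      contexts_ms = c(0, 50, 110, 210),
                      delays_ms = c(-200, -100, 0, 100, 200),
                      pls_components = c(3, 6, 12, 15, 18, 25, 50, 100)) {
  out <- list()
  add <- function(sweep, setting, cfg) {
    tab <- crossval_run(data, cfg)
    s <- summarize_eval(tab)
    out[[length(out) + 1]] <<- data.frame(sweep = sweep, setting = setting,
                                          median_mel_r = s["mel"],
                                          median_f0_r = s["f0"])
  }
  for (p in pca_sizes) {
    cfg <- base; cfg$decoder <- "ols"; cfg$n_pca <- p
    add("pca_size", p, cfg)
  }
  for (cx in contexts_ms) {
    cfg <- base; cfg$windowing <- windowing_config(cx, base$windowing$delay_ms)
    add("context_ms", cx, cfg)
  }
  for (d in delays_ms) {
    cfg <- base; cfg$windowing <- windowing_config(base$windowing$context_ms, d)
    add("delay_ms", d, cfg)
  }
  for (nc in pls_components) {
    cfg <- base; cfg$decoder <- "pls"; cfg$n_components <- nc
    add("pls_components", nc, cfg)
  }
  do.call(rbind, out)
}
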