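# Multiclass evaluation: confusion matrix, accuracy, Cohen's kappa,
# one-vs-rest sensitivity/specificity, and the SNR robustness sweep.

#' Confusion matrix (rows = true, cols = predicted)
#' @param truth,pred integer labels 0..(n_classes-1)
#' @param n_classes number of classes
#' @return integer matrix with class-name dimnames
#' @export
confusion_matrix <- function(truth, pred, n_classes = 8L) {
  stopifnot(length(truth) == length(pred))
  lv <- seq_len(n_classes) - 1L
  cm <- table(factor(truth, lv), factor(pred, lv))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = as.character(lv),
                              pred = as.character(lv)))
  m
}

#' Overall accuracy from a confusion matrix
#'
#' Well-classified fraction: trace over total.
#' @param cm confusion matrix (square counts)
#' @return accuracy in [0, 1]
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_af("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement (accuracy) and `p_e` the expected agreement of
#' independent raters with the observed marginals.
#' @param cm confusion matrix
#' @return kappa in [-1, 1]; errors explicitly when `p_e = 1` (both raters
#'   constant and identical)
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_af("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum((rowSums(cm) / total) * (colSums(cm) / total))
  if (p_e >= 1 - 1e-15)
    stop_af("kappa undefined: expected agreement p_e = 1 (constant raters)")
  (p_o - p_e) / (1 - p_e)
}

.ovr <- function(cm, class_c) {
  i <- as.character(class_c)
  if (!i %in% rownames(cm)) stop_af("class %s not in matrix", i)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-class sensitivity (true positive rate)
#' @param cm confusion matrix
#' @param class_c class label (0-based)
#' @return TP / (TP + FN); NA with a warning when the class has no
#'   positive samples (undefined, never silently 0)
#' @export
sensitivity <- function(cm, class_c) {
  o <- .ovr(cm, class_c)
  if (o$tp + o$fn == 0) {
    warning(sprintf("class %s has no positive samples; TPR undefined",
                    class_c))
    return(NA_real_)
  }
  o$tp / (o$tp + o$fn)
}

#' Per-class specificity (true negative rate)
#' @inheritParams sensitivity
#' @return TN / (TN + FP); NA with a warning when the class has no
#'   negative samples
#' @export
specificity <- function(cm, class_c) {
  o <- .ovr(cm, class_c)
  if (o$tn + o$fp == 0) {
    warning(sprintf("class %s has no negative samples; TNR undefined",
                    class_c))
    return(NA_real_)
  }
  o$tn / (o$tn + o$fp)
}

#' Full metrics report for a prediction set
#'
#' Accuracy, Cohen's kappa, and per-class TPR/TNR/accuracy (per-class
#' accuracy is defined as recall under the one-vs-rest collapse).
#' @param truth,pred integer labels
#' @param n_classes number of classes
#' @return `metrics_report` list
#' @export
metrics_report <- function(truth, pred, n_classes = 8L) {
  cm <- confusion_matrix(truth, pred, n_classes)
  per <- lapply(seq_len(n_classes) - 1L, function(c) {
    pos <- sum(cm[as.character(c), ])
    list(class = c,
         tpr = if (pos > 0) suppressWarnings(sensitivity(cm, c)) else NA_real_,
         tnr = suppressWarnings(specificity(cm, c)),
         accuracy = if (pos > 0) suppressWarnings(sensitivity(cm, c))
                    else NA_real_)
  })
  structure(list(accuracy = accuracy(cm), kappa = cohens_kappa(cm),
                 per_class = do.call(rbind, lapply(per, as.data.frame)),
                 confusion = cm, n = sum(cm)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: n=%d accuracy=%.3f kappa=%.3f\n",
              x$n, x$accuracy, x$kappa))
  print(round(x$per_class, 3))
  invisible(x)
}

#' Noise robustness sweep
#'
#' For each SNR level and repetition: corrupt the clean test BSP with fresh
#' noise, band-pass filter, tensorize, predict and score.  Mirrors the
#' evaluation protocol of the trained pipeline (noise before filtering).
#'
#' @param model trained driver_cnn
#' @param test_episodes list; each element needs `$bsp` (clean, unfiltered
#'   64-channel bsp_recording), `$labels`, and `$frames` (frame indices to
#'   score)
#' @param snrs SNR levels in dB (default 5 to 50 by 5)
#' @param n_reps repetitions per level (default 20)
#' @param seed base seed; every (snr, rep) derives its own sub-seed
#' @param layout_kind,resize,normalize tensorization settings (must match
#'   training)
#' @param filter_args list(order, f_lo, f_hi) for the band-pass
#' @return list with `summary` (mean and sd per SNR) and `raw` (one row per
#'   rep)
#' @export
noise_robustness_sweep <- function(model, test_episodes,
                                   snrs = seq(5, 50, by = 5), n_reps = 20L,
                                   seed = 1L, layout_kind = "1ch",
                                   resize = NULL, normalize = "zscore",
                                   filter_args = list(order = 4, f_lo = 3,
                                                      f_hi = 30)) {
  if (!length(snrs)) stop_af("empty SNR list")
  rows <- list()
  for (snr in snrs) {
    for (rep in seq_len(n_reps)) {
      sub <- derive_seed(seed, sprintf("sweep_%g_%d", snr, rep))
      truth <- integer(0); pred <- integer(0)
      for (e in seq_along(test_episodes)) {
        ep <- test_episodes[[e]]
        noisy <- if (is.finite(snr))
          add_noise(ep$bsp, snr, derive_seed(sub, e)) else ep$bsp
        filt <- bandpass_filter(noisy, order = filter_args$order,
                                f_lo = filter_args$f_lo,
                                f_hi = filter_args$f_hi)
        tens <- tensorize_frames(filt, layout_kind, resize, ep$frames,
                                 normalize)
        pr <- predict(model, tens)
        truth <- c(truth, ep$labels[ep$frames])
        pred <- c(pred, pr$labels)
      }
      cm <- confusion_matrix(truth, pred, model$spec$n_classes)
      rows[[length(rows) + 1L]] <-
        data.frame(snr_db = snr, rep = rep, accuracy = accuracy(cm),
                   kappa = cohens_kappa(cm))
    }
  }
  raw <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(raw, raw$snr_db), function(d)
    data.frame(snr_db = d$snr_db[1],
               accuracy_mean = mean(d$accuracy),
               accuracy_sd = stats::sd(d$accuracy),
               kappa_mean = mean(d$kappa),
               kappa_sd = stats::sd(d$kappa))))
  agg <- agg[order(agg$snr_db), ]
  rownames(agg) <- NULL
  list(summary = agg, raw = raw)
}
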