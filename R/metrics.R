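#' Subset accuracy
#'
#' Fraction of samples whose predicted label vector matches the true
#' vector exactly — the strictest sample-based multi-label metric.
#'
#' @param Y,Yhat binary matrices (samples x labels) of true and predicted
#'   labels.
#' @return scalar in `[0, 1]`.
#' @export
subset_accuracy <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  mean(rowSums(Y != Yhat) == 0)
}

#' Pair (Jaccard) accuracy
#'
#' Mean over samples of the Jaccard similarity between the true and
#' predicted positive-label sets, `|Y_i  intersect  Yhat_i| / |Y_i union
#' Yhat_i|`, a lenient partial-correctness companion to subset accuracy.
#' A sample with no true and no predicted finding counts as fully
#' correct (convention: empty union contributes 1).
#'
#' @inheritParams subset_accuracy
#' @return scalar in `[0, 1]`.
#' @export
pair_accuracy <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  inter <- rowSums(Y == 1 & Yhat == 1)
  union <- rowSums(Y == 1 | Yhat == 1)
  mean(ifelse(union == 0, 1, inter / union))
}

#' Per-label accuracy
#'
#' Accuracy of each label over samples; identifies which pathological
#' findings are easy or hard to recognise.
#'
#' @inheritParams subset_accuracy
#' @return named numeric vector of length L.
#' @export
per_label_accuracy <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  colMeans(Y == Yhat)
}

#' Per-label confusion counts
#'
#' @inheritParams subset_accuracy
#' @return data.frame with one row per label: `tp`, `fp`, `tn`, `fn`
#'   (summing to n per label).
#' @export
confusion_counts <- function(Y, Yhat) {
  check_same_shape(Y, Yhat)
  data.frame(
    label = colnames(Y) %||% paste0("label", seq_len(ncol(Y))),
    tp = as.integer(colSums(Y == 1 & Yhat == 1)),
    fp = as.integer(colSums(Y == 0 & Yhat == 1)),
    tn = as.integer(colSums(Y == 0 & Yhat == 0)),
    fn = as.integer(colSums(Y == 1 & Yhat == 0)),
    row.names = NULL)
}

#' Macro label-based summary from confusion counts
#'
#' Computes average label accuracy, macro sensitivity, macro specificity
#' and macro F1 by averaging the per-label ratios.  Labels whose ratio
#' has a zero denominator (e.g. sensitivity of a label with no
#' positives) are, by default, excluded from that ratio's mean with a
#' warning; `zero_denominator = "zero"` counts them as 0 instead.
#'
#' @param confusion data.frame from [confusion_counts()].
#' @param zero_denominator `"exclude"` (default) or `"zero"`.
#' @return list with `acc_avelab`, `sen`, `spe`, `f1`.
#' @export
macro_summary <- function(confusion, zero_denominator = c("exclude", "zero")) {
  zero_denominator <- match.arg(zero_denominator)
  safe_mean <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sum(bad), " label(s) with zero denominator excluded from ", what)
      if (zero_denominator == "zero") return(mean(ifelse(bad, 0, num / den)))
      if (all(bad)) return(NA_real_)
      return(mean(num[!bad] / den[!bad]))
    }
    mean(num / den)
  }
  with(confusion, list(
    acc_avelab = safe_mean(tp + tn, tp + tn + fp + fn, "acc_avelab"),
    sen = safe_mean(tp, tp + fn, "sensitivity"),
    spe = safe_mean(tn, tn + fp, "specificity"),
    f1 = safe_mean(2 * tp, 2 * tp + fp + fn, "F1")))
}

#' Micro-averaged ROC curve and AUC
#'
#' Pools all (sample, label) pairs, sweeps the decision threshold over
#' the observed scores and reports the resulting ROC points with the
#' trapezoidal area under the curve.  `average = "macro"` instead
#' computes one AUC per label (skipping single-class labels) and returns
#' their mean, with pooled points for reference.
#'
#' @param Y binary matrix of true labels (samples x labels).
#' @param scores numeric matrix of prediction scores, same shape.
#' @param average `"micro"` (default) or `"macro"`.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(Y, scores, average = c("micro", "macro")) {
  average <- match.arg(average)
  check_same_shape(Y, scores)
  pts <- roc_points(as.vector(Y), as.vector(scores))
  auc <- if (average == "micro") {
    trapezoid_auc(pts$fpr, pts$tpr)
  } else {
    per <- vapply(seq_len(ncol(Y)), function(l) {
      y <- Y[, l]
      if (all(y == y[1L])) return(NA_real_)
      p <- roc_points(y, scores[, l])
      trapezoid_auc(p$fpr, p$tpr)
    }, numeric(1))
    mean(per, na.rm = TRUE)
  }
  list(points = pts, auc = auc)
}

roc_points <- function(y, s) {
  if (all(y == y[1L])) stop("ROC requires both classes in the pooled labels")
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(diff(s) != 0, TRUE)          # one point per distinct threshold
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / sum(y == 0)),
             tpr = c(0, tp[keep] / sum(y == 1)))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Full multi-label evaluation report
#'
#' Assembles every metric of the evaluation suite — subset accuracy,
#' Jaccard pair accuracy, per-label accuracy, per-label confusion
#' counts, the macro summaries, and (when scores are supplied)
#' micro-averaged ROC/AUC — into one report object.
#'
#' @param Y binary matrix of true labels.
#' @param Yhat binary matrix of predicted labels.
#' @param scores optional numeric score matrix for ROC/AUC.
#' @param zero_denominator passed to [macro_summary()].
#' @return object of class `"ml_eval"`: list with `acc`, `acc_pair`,
#'   `acc_lab`, `confusion`, `acc_avelab`, `sen`, `spe`, `f1`, `auc`,
#'   `roc_points`, `n`.
#' @examples
#' Y <- matrix(rbinom(30, 1, 0.4), 10, 3)
#' evaluate_multilabel(Y, Y)
#' @export
evaluate_multilabel <- function(Y, Yhat, scores = NULL,
                                zero_denominator = "exclude") {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  conf <- confusion_counts(Y, Yhat)
  mac <- macro_summary(conf, zero_denominator = zero_denominator)
  auc <- NA_real_; pts <- NULL
  if (!is.null(scores)) {
    r <- roc_auc(Y, scores)
    auc <- r$auc; pts <- r$points
  }
  structure(list(acc = subset_accuracy(Y, Yhat),
                 acc_pair = pair_accuracy(Y, Yhat),
                 acc_lab = per_label_accuracy(Y, Yhat),
                 confusion = conf,
                 acc_avelab = mac$acc_avelab, sen = mac$sen,
                 spe = mac$spe, f1 = mac$f1,
                 auc = auc, roc_points = pts, n = nrow(Y)),
            class = "ml_eval")
}

#' @export
print.ml_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Multi-label evaluation on %d samples, %d labels\n",
              x$n, nrow(x$confusion)))
  cat(sprintf("  ACC (subset)  %.*f\n", digits, x$acc))
  cat(sprintf("  ACC_pair      %.*f\n", digits, x$acc_pair))
  cat(sprintf("  ACC_avelab    %.*f\n", digits, x$acc_avelab))
  cat(sprintf("  SEN / SPE     %.*f / %.*f\n", digits, x$sen, digits, x$spe))
  cat(sprintf("  F1 (macro)    %.*f\n", digits, x$f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC (micro)   %.*f\n", digits, x$auc))
  invisible(x)
}

#' Write an evaluation report to JSON, with ROC points as CSV
#'
#' @param report an `"ml_eval"` object.
#' @param path output JSON path; ROC points (when present) are written
#'   next to it as `<path-sans-ext>_roc.csv`.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- report[c("acc", "acc_pair", "acc_lab", "acc_avelab",
                  "sen", "spe", "f1", "auc", "n")]
  out$confusion <- report$confusion
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(report$roc_points)) {
    roc_path <- sub("\\.json$", "", path)
    utils::write.csv(report$roc_points, paste0(roc_path, "_roc.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

check_same_shape <- function(A, B) {
  if (!all(dim(as.matrix(A)) == dim(as.matrix(B))))
    stop("matrices must have identical dimensions")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
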