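#' Multi-label F-statistic gene ranking
#'
#' For each label, each gene is scored with the one-way two-group ANOVA
#' F statistic (between-group over within-group mean square) contrasting
#' positive against negative samples; the per-label scores are then
#' aggregated across labels with the configured reducer.  Genes whose
#' expression separates finding-positive from finding-negative compounds
#' score high and are ranked first.
#'
#' Degenerate cases: a gene with identical group means scores 0; a gene
#' with zero within-group variance but distinct means is capped at
#' `f_max` so it ranks first without producing infinities.  Labels with a
#' single class are excluded from the aggregation with a warning.
#'
#' @param features numeric matrix (samples x genes).
#' @param labels binary matrix (samples x labels).
#' @param aggregate `"mean"` or `"max"` across labels.
#' @param f_max cap applied to zero-within-variance scores.
#' @return list with `scores` (named per-gene aggregate), `per_label`
#'   (genes x labels matrix), `ranking` (gene indices, best first).
#' @export
multilabel_f_scores <- function(features, labels,
                                aggregate = c("mean", "max"),
                                f_max = 1e12) {
  aggregate <- match.arg(aggregate)
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  n <- nrow(features)
  usable <- colSums(labels) > 0 & colSums(labels) < n
  if (!any(usable))
    stop("no label has both a positive and a negative sample")
  if (any(!usable))
    warning("excluding ", sum(!usable), " single-class label(s) from F scoring")
  per_label <- matrix(NA_real_, ncol(features), ncol(labels),
                      dimnames = list(colnames(features), colnames(labels)))
  grand <- colMeans(features)
  for (l in which(usable)) {
    pos <- labels[, l] == 1
    n1 <- sum(pos); n0 <- n - n1
    m1 <- colMeans(features[pos, , drop = FALSE])
    m0 <- colMeans(features[!pos, , drop = FALSE])
    ssb <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
    ssw <- colSums((features - outer(labels[, l], m1) -
                      outer(1 - labels[, l], m0))^2)
    msb <- ssb / 1
    msw <- ssw / (n - 2)
    f <- ifelse(msb <= 0, 0,
                ifelse(msw <= .Machine$double.eps * pmax(msb, 1), f_max,
                       pmin(msb / msw, f_max)))
    per_label[, l] <- f
  }
  scores <- apply(per_label[, usable, drop = FALSE], 1L,
                  if (aggregate == "mean") mean else max)
  names(scores) <- colnames(features)
  list(scores = scores, per_label = per_label,
       ranking = order(scores, decreasing = TRUE))
}

#' Size-penalised fitness of a feature subset
#'
#' `Fitness = alpha * ACC + (1 - alpha) * (D_total - D_selected * lambda)
#' / D_total`.  The amplification factor `lambda` inflates the cost of
#' each selected feature so that the size penalty stays meaningful when
#' the selected subset is orders of magnitude smaller than the full gene
#' set; the second term may go negative once
#' `lambda * D_selected > D_total`.
#'
#' @param acc classification accuracy of the subset, in `[0, 1]`.
#' @param d_selected number of selected features.
#' @param d_total total number of features.
#' @param alpha weight of the accuracy term (default 0.6).
#' @param lam amplification factor (default 10).
#' @return fitness value (numeric scalar).
#' @examples
#' fitness(0.8, 100, 6009)   # ~0.8134
#' @export
fitness <- function(acc, d_selected, d_total, alpha = 0.6, lam = 10) {
  stopifnot(alpha >= 0, alpha <= 1, lam > 0, d_total >= 1,
            d_selected >= 0, d_selected <= d_total,
            acc >= 0, acc <= 1)
  alpha * acc + (1 - alpha) * (d_total - d_selected * lam) / d_total
}

#' Fitness-driven greedy subset search over a ranked gene list
#'
#' Starting from an F-statistic ranking, evaluates progressively smaller
#' prefixes of the ranking (features are deleted from the bottom of the
#' list) with a user-supplied accuracy evaluator, records the fitness at
#' each size, and returns the subset maximising fitness; ties are broken
#' toward the smaller subset.
#'
#' @param features numeric matrix (samples x genes).
#' @param labels binary matrix (samples x labels).
#' @param evaluator function taking an integer vector of feature column
#'   indices and returning an accuracy in `[0, 1]` (typically mean
#'   cross-validated subset accuracy of a baseline learner).
#' @param sizes_grid strictly decreasing subset sizes to evaluate;
#'   default a geometric grid from all genes down to 1.
#' @param alpha,lam fitness parameters, see [fitness()].
#' @param aggregate F-score aggregation, see [multilabel_f_scores()].
#' @return object of class `"feature_selection"`: list with
#'   `ranked_genes` (data.frame of gene, score), `curve` (data.frame
#'   size/accuracy/fitness), `best_size`, `best_genes`, `best_idx`.
#' @export
greedy_subset_search <- function(features, labels, evaluator,
                                 sizes_grid = NULL, alpha = 0.6, lam = 10,
                                 aggregate = "mean") {
  d_total <- ncol(features)
  if (is.null(sizes_grid)) {
    sizes_grid <- unique(round(d_total * 0.6^(0:40)))
    sizes_grid <- sizes_grid[sizes_grid >= 1]
  }
  if (any(diff(sizes_grid) >= 0) || any(sizes_grid < 1) ||
      any(sizes_grid > d_total))
    stop("sizes_grid must be strictly decreasing within [1, d_total]")
  fs <- multilabel_f_scores(features, labels, aggregate = aggregate)
  curve <- data.frame(size = integer(), accuracy = numeric(),
                      fitness = numeric())
  for (s in sizes_grid) {
    idx <- fs$ranking[seq_len(s)]
    acc <- tryCatch(evaluator(idx), error = function(e) {
      warning("evaluator failed at size ", s, ": ", conditionMessage(e))
      NA_real_
    })
    if (is.na(acc)) next
    curve <- rbind(curve, data.frame(
      size = s, accuracy = acc,
      fitness = fitness(acc, s, d_total, alpha = alpha, lam = lam)))
  }
  if (!nrow(curve)) stop("evaluator failed at every size in the grid")
  # argmax fitness; on ties prefer the smaller subset (grid is descending,
  # so the last of the tied rows)
  best_row <- which(curve$fitness == max(curve$fitness))
  best_row <- best_row[which.min(curve$size[best_row])]
  best_size <- curve$size[best_row]
  gene_names <- colnames(features)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(d_total))
  structure(list(
    ranked_genes = data.frame(gene = gene_names[fs$ranking],
                              score = fs$scores[fs$ranking]),
    curve = curve, best_size = best_size,
    best_idx = fs$ranking[seq_len(best_size)],
    best_genes = gene_names[fs$ranking[seq_len(best_size)]]),
    class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(
    "Feature subset search: %d sizes evaluated, best size = %d (fitness %.4f)\n",
    nrow(x$curve), x$best_size, max(x$curve$fitness)))
  invisible(x)
}

#' @export
plot.feature_selection <- function(x, ...) {
  graphics::plot(x$curve$size, x$curve$accuracy, type = "b", log = "x",
                 xlab = "selected features", ylab = "accuracy", ...)
  graphics::abline(v = x$best_size, lty = 2)
  invisible(x)
}
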