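#' Base learner factories for binary relevance and classifier chains
#'
#' A learner factory is a zero-argument function returning a fresh
#' learner: a list with `fit(x, y)` returning a fitted state and
#' `score(state, x)` returning probability-like values in `[0, 1]`.
#' A single-class training label is handled inside the wrappers
#' ([binary_relevance()] / [classifier_chain()]) by a constant
#' predictor, so factories may assume both classes are present.
#'
#' `learner_logistic()` wraps [stats::glm()] (binomial),
#' `learner_random_forest()` wraps [randomForest::randomForest()], and
#' `learner_svm()` wraps a linear-kernel [e1071::svm()] with Platt
#' probability estimates.  `learner_stump()` is a deterministic decision
#' stump (best single-column threshold by training error, ties to the
#' lower column index) used as a transparent stub in tests and for
#' studying chain behaviour.
#'
#' @param maxit maximum IWLS iterations for the logistic learner.
#' @param ntree,max_depth random forest size and `maxnodes`-style depth
#'   cap (`NULL` = unlimited).
#' @param cost SVM misclassification cost `C`.
#' @return a learner factory (function).
#' @name base_learners
NULL

#' @rdname base_learners
#' @export
learner_logistic <- function(maxit = 50) {
  force(maxit)
  function() list(
    fit = function(x, y) {
      suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                      family = stats::binomial(),
                                      control = list(maxit = maxit)))
    },
    score = function(state, x) {
      as.numeric(stats::plogis(cbind(1, x) %*% state$coefficients))
    })
}

#' @rdname base_learners
#' @export
learner_random_forest <- function(ntree = 100, max_depth = NULL) {
  force(ntree); force(max_depth)
  function() list(
    fit = function(x, y) {
      randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = ntree,
        maxnodes = if (is.null(max_depth)) NULL else 2^max_depth)
    },
    score = function(state, x) {
      unname(stats::predict(state, x, type = "prob")[, "1"])
    })
}

#' @rdname base_learners
#' @export
learner_svm <- function(cost = 1) {
  force(cost)
  function() list(
    fit = function(x, y) {
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = cost, probability = TRUE)
    },
    score = function(state, x) {
      pr <- stats::predict(state, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    })
}

#' @rdname base_learners
#' @export
learner_stump <- function() {
  function() list(
    fit = function(x, y) {
      best <- list(err = Inf, col = 1L, cut = Inf, flip = FALSE)
      for (j in seq_len(ncol(x))) {
        v <- x[, j]
        cuts <- sort(unique(v))
        cuts <- c(cuts[1L] - 1, (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2)
        for (ct in cuts) {
          pred <- (v > ct) * 1
          err <- mean(pred != y)
          if (err < best$err) best <- list(err = err, col = j, cut = ct, flip = FALSE)
          if (1 - err < best$err) best <- list(err = 1 - err, col = j, cut = ct, flip = TRUE)
        }
      }
      best
    },
    score = function(state, x) {
      pred <- (x[, state$col] > state$cut) * 1
      if (state$flip) pred <- 1 - pred
      pred
    })
}

# canonical column names so learners that match on names (e.g. random
# forest) see identical train and prediction frames
canon_cols <- function(m) {
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

# fit one binary model, falling back to a constant on single-class labels
fit_one_label <- function(x, y, factory, label_name) {
  if (length(unique(y)) < 2L) {
    warning("label '", label_name, "' is single-class; using constant predictor")
    return(list(constant = mean(y)))
  }
  learner <- factory()
  list(learner = learner, state = learner$fit(x, y))
}

score_one_label <- function(fit, x) {
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(x)))
  fit$learner$score(fit$state, x)
}

#' Binary relevance multi-label classifier
#'
#' Trains one independent binary classifier per label, each seeing only
#' the features and its own label column; label correlations are
#' ignored by construction.
#'
#' @param x numeric feature matrix (samples x genes) or an [mld()]
#'   object.
#' @param y binary label matrix (taken from `x` when it is an `mld`).
#' @param learner a learner factory, see [base_learners].
#' @param threshold decision cutoff applied to scores.
#' @return object of class `"br_model"`.
#' @export
binary_relevance <- function(x, y = NULL, learner = learner_logistic(),
                             threshold = 0.5) {
  if (inherits(x, "mld")) { y <- x$labels; x <- x$features }
  x <- as.matrix(x); y <- as.matrix(y)
  label_names <- colnames(y) %||% paste0("label", seq_len(ncol(y)))
  fits <- lapply(seq_len(ncol(y)), function(l)
    fit_one_label(canon_cols(x), y[, l], learner, label_names[l]))
  structure(list(fits = fits, label_names = label_names, dim = ncol(x),
                 threshold = threshold),
            class = "br_model")
}

#' @export
predict.br_model <- function(object, x, type = c("labels", "scores"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$dim) stop("feature dimension mismatch")
  s <- vapply(object$fits, score_one_label, numeric(nrow(x)),
              x = canon_cols(x))
  s <- matrix(s, nrow = nrow(x),
              dimnames = list(rownames(x), object$label_names))
  if (type == "scores") s else (s >= object$threshold) * 1
}

#' @export
print.br_model <- function(x, ...) {
  cat(sprintf("Binary relevance model: %d independent binary classifiers, dim = %d\n",
              length(x$fits), x$dim))
  invisible(x)
}

#' Classifier chain multi-label classifier
#'
#' Trains binary classifiers along a label order; the j-th classifier
#' receives the features plus the true values of the j-1 preceding
#' labels during training, and the predicted values of those labels at
#' prediction time, so label correlations propagate down the chain.
#'
#' @inheritParams binary_relevance
#' @param order a permutation of `1..L` giving the chain order; default
#'   is the dataset label order.
#' @return object of class `"cc_model"`.
#' @export
classifier_chain <- function(x, y = NULL, learner = learner_logistic(),
                             order = NULL, threshold = 0.5) {
  if (inherits(x, "mld")) { y <- x$labels; x <- x$features }
  x <- as.matrix(x); y <- as.matrix(y)
  L <- ncol(y)
  if (is.null(order)) order <- seq_len(L)
  if (length(order) != L || !setequal(order, seq_len(L)))
    stop("order must be a permutation of 1..L")
  label_names <- colnames(y) %||% paste0("label", seq_len(L))
  fits <- vector("list", L)
  for (j in seq_len(L)) {
    l <- order[j]
    aug <- canon_cols(cbind(x, y[, order[seq_len(j - 1L)], drop = FALSE]))
    fits[[j]] <- fit_one_label(aug, y[, l], learner, label_names[l])
  }
  structure(list(fits = fits, order = as.integer(order),
                 label_names = label_names, dim = ncol(x),
                 threshold = threshold),
            class = "cc_model")
}

#' @export
predict.cc_model <- function(object, x, type = c("labels", "scores"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$dim) stop("feature dimension mismatch")
  L <- length(object$fits)
  n <- nrow(x)
  scores <- matrix(NA_real_, n, L,
                   dimnames = list(rownames(x), object$label_names))
  chain_labels <- matrix(0, n, 0L)
  for (j in seq_len(L)) {
    l <- object$order[j]
    s <- score_one_label(object$fits[[j]], canon_cols(cbind(x, chain_labels)))
    scores[, l] <- s
    chain_labels <- cbind(chain_labels, (s >= object$threshold) * 1)
  }
  if (type == "scores") scores else (scores >= object$threshold) * 1
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf("Classifier chain model: %d classifiers, order %s, dim = %d\n",
              length(x$fits), paste(x$order, collapse = " > "), x$dim))
  invisible(x)
}

#' Per-label k-nearest-neighbour classifier
#'
#' The per-label core of the integrative baseline: for each label
#' independently, a query is classified by the majority vote of its k
#' nearest training samples (Euclidean distance); a tie votes positive.
#' Scores are the positive vote fractions.
#'
#' @inheritParams binary_relevance
#' @param k number of neighbours (default 5).
#' @return object of class `"mlknn_model"`.
#' @export
knn_multilabel <- function(x, y = NULL, k = 5L) {
  if (inherits(x, "mld")) { y <- x$labels; x <- x$features }
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) <= k) stop("need more than k training samples")
  structure(list(x = x, y = y, k = as.integer(k),
                 label_names = colnames(y) %||% paste0("label", seq_len(ncol(y)))),
            class = "mlknn_model")
}

#' @export
predict.mlknn_model <- function(object, x, type = c("labels", "scores"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != ncol(object$x)) stop("feature dimension mismatch")
  n <- nrow(x); k <- object$k
  # squared Euclidean distances query x training via the expansion trick
  d2 <- outer(rowSums(x^2), rep(1, nrow(object$x))) -
    2 * x %*% t(object$x) +
    outer(rep(1, n), rowSums(object$x^2))
  scores <- matrix(NA_real_, n, ncol(object$y),
                   dimnames = list(rownames(x), object$label_names))
  for (i in seq_len(n)) {
    nn <- order(d2[i, ], seq_len(nrow(object$x)))[seq_len(k)]
    scores[i, ] <- colMeans(object$y[nn, , drop = FALSE])
  }
  if (type == "scores") scores else (scores >= 0.5) * 1  # tie -> positive
}

#' @export
print.mlknn_model <- function(x, ...) {
  cat(sprintf("Per-label %d-NN model: %d training samples, %d labels\n",
              x$k, nrow(x$x), ncol(x$y)))
  invisible(x)
}
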