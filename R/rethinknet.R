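#' Configuration for the rethinking network
#'
#' Hyperparameters of the attention-weighted recurrent rethinking
#' classifier.  `T` is the number of rethinking iterations: the input is
#' replicated across `T` recurrent steps and each step refines the
#' previous tentative label scores, so `T` controls how often the model
#' reconsiders its prediction without changing the parameter count (for
#' feature-axis attention and for no attention).
#'
#' @param T number of rethinking iterations (>= 1).
#' @param cell recurrent cell, `"lstm"` or `"srn"` (simple recurrent,
#'   tanh).
#' @param hidden_units recurrent state size.
#' @param attention `"feature_axis"` (softmax over genes, the default),
#'   `"step_axis"` (softmax over the T replicated steps), or `"off"`
#'   (plain rethinking network ablation).
#' @param label_weights `"inverse_frequency"` (cost-sensitive weights
#'   proportional to n / count(l), normalised to mean 1),
#'   `"uniform"`, or an explicit positive vector of length L.
#' @param weight_cap clamp applied to raw inverse-frequency weights
#'   before normalisation (guards labels with very few or zero
#'   positives).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param attention_decay L2 penalty on the attention dense weights,
#'   pulling the learned weight distribution toward uniform; attention
#'   is meant to encode feature importance that is consistent across
#'   samples, and the penalty keeps it from degenerating into
#'   per-sample memorisation.
#' @param threshold decision cutoff applied to the final-iteration
#'   scores.
#' @param seed integer seed for initialisation and batch shuffling.
#' @return list of class `"rethink_config"`.
#' @export
rethink_config <- function(T = 5L, cell = c("lstm", "srn"),
                           hidden_units = 32L,
                           attention = c("feature_axis", "step_axis", "off"),
                           label_weights = "inverse_frequency",
                           weight_cap = 20,
                           epochs = 100L, batch_size = 32L,
                           learning_rate = 0.01, attention_decay = 0.1,
                           threshold = 0.5, seed = 1L) {
  cell <- match.arg(cell)
  attention <- match.arg(attention)
  if (!is.numeric(T) || T < 1) stop("configuration error: T must be >= 1")
  if (hidden_units < 1) stop("configuration error: hidden_units must be >= 1")
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must be in (0, 1)")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("configuration error: invalid training schedule")
  if (is.character(label_weights) &&
      !label_weights %in% c("inverse_frequency", "uniform"))
    stop("configuration error: unknown label_weights mode")
  structure(list(T = as.integer(T), cell = cell,
                 hidden_units = as.integer(hidden_units),
                 attention = attention, label_weights = label_weights,
                 weight_cap = weight_cap,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 attention_decay = attention_decay, threshold = threshold,
                 seed = as.integer(seed)),
            class = "rethink_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an (untrained) rethinking network
#'
#' Initialises the parameters of the attention block, the recurrent cell
#' and the dense sigmoid head for given input dimension and label count.
#' The returned handle supports [predict.rethinknet()],
#' [attention_probabilities()] and [rethink_n_params()] before training;
#' [rethinknet()] is the one-call build-and-train interface.
#'
#' @param config a [rethink_config()].
#' @param dim input (gene feature) dimension, >= 1.
#' @param L number of labels, >= 1.
#' @return object of class `"rethinknet"` with `fitted = FALSE`.
#' @export
rethink_build <- function(config = rethink_config(), dim, L) {
  stopifnot(inherits(config, "rethink_config"))
  if (length(dim) != 1L || dim < 1) stop("configuration error: dim must be >= 1")
  if (length(L) != 1L || L < 1) stop("configuration error: L must be >= 1")
  if (is.numeric(config$label_weights) && length(config$label_weights) != L)
    stop("configuration error: explicit label_weights must have length L")
  if (is.numeric(config$label_weights) && any(config$label_weights <= 0))
    stop("configuration error: explicit label_weights must be positive")
  set.seed(config$seed)
  H <- config$hidden_units
  K <- if (config$cell == "lstm") 4L else 1L
  params <- list(
    Wx = glorot(dim, K * H),
    Wh = glorot(H, K * H),
    b = rep(0, K * H),
    V = glorot(H, L),
    bo = rep(0, L))
  if (config$cell == "lstm") params$b[(H + 1):(2 * H)] <- 1  # forget bias
  # the attention dense layer starts at zero so the initial weight
  # distribution is uniform (1/dim) and the block begins as a neutral
  # rescaling rather than a random distortion of the features
  if (config$attention == "feature_axis") {
    params$Wa <- matrix(0, dim, dim)
    params$ba <- rep(0, dim)
  } else if (config$attention == "step_axis") {
    params$ua <- rep(0, config$T)
    params$bta <- rep(0, config$T)
  }
  structure(list(config = config, dim = as.integer(dim), L = as.integer(L),
                 params = params, fitted = FALSE, history = NULL,
                 label_weights = rep(1, L)),
            class = "rethinknet")
}

# row-wise softmax
softmax_rows <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

# forward pass; returns scores (n x T x L) plus caches for BPTT
rethink_forward <- function(model, X, keep = FALSE) {
  cfg <- model$config; p <- model$params
  n <- nrow(X); H <- cfg$hidden_units; Tn <- cfg$T; L <- model$L
  att <- NULL; Xw_steps <- NULL
  if (cfg$attention == "feature_axis") {
    A <- softmax_rows(X %*% p$Wa + matrix(p$ba, n, model$dim, byrow = TRUE))
    # probabilities are rescaled by dim so uniform attention is the identity
    Xw <- X * A * model$dim
    att <- A
  } else if (cfg$attention == "step_axis") {
    logits <- lapply(seq_len(Tn), function(t) X * p$ua[t] + p$bta[t])
    M <- Reduce(pmax, logits)
    Es <- lapply(logits, function(Lt) exp(Lt - M))
    norm <- Reduce(`+`, Es)
    Wt <- lapply(Es, function(E) E / norm)
    Xw_steps <- lapply(Wt, function(w) X * w * Tn)
    att <- Wt
  } else {
    Xw <- X
  }
  scores <- array(NA_real_, c(n, Tn, L))
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- if (keep) vector("list", Tn)
  for (t in seq_len(Tn)) {
    xin <- if (cfg$attention == "step_axis") Xw_steps[[t]] else Xw
    z <- xin %*% p$Wx + h %*% p$Wh + matrix(p$b, n, length(p$b), byrow = TRUE)
    if (cfg$cell == "lstm") {
      i <- stats::plogis(z[, 1:H, drop = FALSE])
      f <- stats::plogis(z[, (H + 1):(2 * H), drop = FALSE])
      o <- stats::plogis(z[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h_new <- o * tc
    } else {
      h_new <- tanh(z)
    }
    u <- h_new %*% p$V + matrix(p$bo, n, L, byrow = TRUE)
    s <- stats::plogis(u)
    scores[, t, ] <- s
    if (keep) {
      cache[[t]] <- if (cfg$cell == "lstm")
        list(xin = xin, i = i, f = f, o = o, g = g, c_prev = c_prev,
             cc = cc, tc = tc, h_prev = h, h = h_new, u = u, s = s)
      else list(xin = xin, h_prev = h, h = h_new, u = u, s = s)
    }
    h <- h_new
  }
  list(scores = scores, att = att, cache = cache,
       Xw = if (cfg$attention == "feature_axis") Xw else NULL)
}

# stable mean weighted binary cross-entropy from logits
bce_from_logits <- function(u, y, wl) {
  per <- pmax(u, 0) - y * u + log1p(exp(-abs(u)))
  mean(sweep(per, 2L, wl, "*"))
}

# loss and parameter gradients for one batch
rethink_grads <- function(model, X, Y, wl) {
  cfg <- model$config; p <- model$params
  n <- nrow(X); H <- cfg$hidden_units; Tn <- cfg$T; L <- model$L
  fw <- rethink_forward(model, X, keep = TRUE)
  loss <- mean(vapply(seq_len(Tn), function(t)
    bce_from_logits(fw$cache[[t]]$u, Y, wl), numeric(1)))
  g <- lapply(p, function(q) q * 0)
  denom <- n * Tn * L
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  dXw_sum <- matrix(0, n, model$dim)
  dXw_steps <- if (cfg$attention == "step_axis") vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cs <- fw$cache[[t]]
    du <- sweep(cs$s - Y, 2L, wl, "*") / denom
    g$V <- g$V + t(cs$h) %*% du
    g$bo <- g$bo + colSums(du)
    dh <- du %*% t(p$V) + dh_next
    if (cfg$cell == "lstm") {
      do_ <- dh * cs$tc
      dct <- dh * cs$o * (1 - cs$tc^2) + dc_next
      di <- dct * cs$g
      dg <- dct * cs$i
      df <- dct * cs$c_prev
      dc_next <- dct * cs$f
      dz <- cbind(di * cs$i * (1 - cs$i),
                  df * cs$f * (1 - cs$f),
                  do_ * cs$o * (1 - cs$o),
                  dg * (1 - cs$g^2))
    } else {
      dz <- dh * (1 - cs$h^2)
    }
    g$Wx <- g$Wx + t(cs$xin) %*% dz
    g$Wh <- g$Wh + t(cs$h_prev) %*% dz
    g$b <- g$b + colSums(dz)
    dh_next <- dz %*% t(p$Wh)
    dxin <- dz %*% t(p$Wx)
    if (cfg$attention == "step_axis") dXw_steps[[t]] <- dxin
    else dXw_sum <- dXw_sum + dxin
  }
  if (cfg$attention == "feature_axis") {
    A <- fw$att
    dA <- dXw_sum * X * model$dim
    dlog <- A * (dA - rowSums(dA * A))
    g$Wa <- t(X) %*% dlog
    g$ba <- colSums(dlog)
  } else if (cfg$attention == "step_axis") {
    Wt <- fw$att
    dw <- lapply(dXw_steps, function(d) d * X * Tn)
    S <- Reduce(`+`, Map(`*`, dw, Wt))
    for (t in seq_len(Tn)) {
      dlog <- Wt[[t]] * (dw[[t]] - S)
      g$ua[t] <- sum(dlog * X)
      g$bta[t] <- sum(dlog)
    }
  }
  list(loss = loss, grads = g)
}

#' Cost-sensitive label weights
#'
#' Inverse-prevalence weights `w_l = n / count(l)`, clamped at
#' `weight_cap` (labels with zero positives get the cap, with a
#' warning), then normalised so that `mean(w_l) = 1` exactly; or uniform
#' weights; or a user-supplied positive vector normalised the same way.
#'
#' @param labels binary label matrix (samples x labels).
#' @param mode `"inverse_frequency"`, `"uniform"`, or a numeric vector.
#' @param weight_cap clamp for raw inverse-frequency weights.
#' @return numeric vector of length L with mean exactly 1.
#' @export
rethink_label_weights <- function(labels, mode = "inverse_frequency",
                                  weight_cap = 20) {
  L <- ncol(labels)
  if (is.numeric(mode)) {
    stopifnot(length(mode) == L, all(mode > 0))
    return(mode / mean(mode))
  }
  if (mode == "uniform") return(rep(1, L))
  cnt <- colSums(labels)
  if (any(cnt == 0))
    warning(sum(cnt == 0), " label(s) with zero positives; weight clamped at cap")
  raw <- ifelse(cnt == 0, weight_cap, pmin(nrow(labels) / cnt, weight_cap))
  raw / mean(raw)
}

#' Fit an attention-weighted recurrent rethinking multi-label classifier
#'
#' Trains the Att-RethinkNet architecture: an attention block that
#' softmax-weights the gene features, a recurrent layer (LSTM or simple
#' recurrent cell) that refines tentative label scores over `T`
#' rethinking iterations while carrying label-association information in
#' its state, and a dense sigmoid head decoding every iteration's state
#' into label scores.  The loss is the cost-sensitive re-weighted binary
#' cross-entropy, averaged over samples, iterations and labels, with
#' per-label weights from [rethink_label_weights()]; optimisation is
#' mini-batch Adam with seeded initialisation and shuffling, so
#' same-seed runs are reproducible.
#'
#' Setting `attention = "off"` yields the plain RethinkNet ablation and
#' `cell = "srn"` the simple-recurrent ablation.
#'
#' @param x numeric feature matrix (samples x genes), or an [mld()]
#'   object (in which case `y` is taken from it).
#' @param y binary label matrix (samples x labels).
#' @param config a [rethink_config()].
#' @param verbose print the loss every few epochs.
#' @return fitted object of class `"rethinknet"` with elements `params`,
#'   `history` (per-epoch mean training loss), `label_weights`, `config`.
#' @examples
#' d <- make_separable_benchmark(80, 10, 3, seed = 1)
#' fit <- rethinknet(d$features, d$labels,
#'                   rethink_config(T = 2, hidden_units = 8, epochs = 5))
#' fit
#' @seealso [predict.rethinknet()], [attention_probabilities()]
#' @export
rethinknet <- function(x, y = NULL, config = rethink_config(),
                       verbose = FALSE) {
  if (inherits(x, "mld")) {
    y <- x$labels
    x <- x$features
  }
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y disagree on the number of samples")
  model <- rethink_build(config, ncol(x), ncol(y))
  rethink_train(model, x, y, verbose = verbose)
}

#' Train a built rethinking network
#'
#' Lower-level training entry for a handle created with
#' [rethink_build()]; [rethinknet()] wraps build-and-train in one call.
#'
#' @param model an untrained `"rethinknet"` handle.
#' @param x,y feature and binary label matrices.
#' @param verbose print progress.
#' @return the fitted model.
#' @export
rethink_train <- function(model, x, y, verbose = FALSE) {
  cfg <- model$config
  if (ncol(x) != model$dim) stop("feature dimension mismatch")
  if (ncol(y) != model$L) stop("label dimension mismatch")
  wl <- rethink_label_weights(y, cfg$label_weights, cfg$weight_cap)
  model$label_weights <- wl
  n <- nrow(x)
  p <- model$params
  mom <- lapply(p, function(q) q * 0)
  vel <- lapply(p, function(q) q * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(cfg$epochs)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (st in starts) {
      idx <- ord[st:min(st + cfg$batch_size - 1L, n)]
      gr <- rethink_grads(model, x[idx, , drop = FALSE],
                          y[idx, , drop = FALSE], wl)
      # decay only the sample-dependent part of the attention logits; the
      # shared per-gene offsets (ba/bta) carry the global importance and
      # stay unpenalised
      if (cfg$attention == "feature_axis")
        gr$grads$Wa <- gr$grads$Wa + cfg$attention_decay * p$Wa
      if (cfg$attention == "step_axis")
        gr$grads$ua <- gr$grads$ua + cfg$attention_decay * p$ua
      ep_loss <- ep_loss + gr$loss * length(idx)
      step <- step + 1L
      for (nm in names(p)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr$grads[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr$grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      model$params <- p
    }
    history[ep] <- ep_loss / n
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %d  loss %.5f", ep, history[ep]))
  }
  model$fitted <- TRUE
  model$history <- history
  model
}

#' Mean weighted binary cross-entropy of a model on a dataset
#'
#' @param model a `"rethinknet"` object (fitted or not).
#' @param x,y feature and binary label matrices.
#' @param label_weights optional explicit weights; defaults to the
#'   model's stored weights.
#' @return scalar loss.
#' @export
rethink_loss <- function(model, x, y, label_weights = NULL) {
  if (is.null(label_weights)) label_weights <- model$label_weights
  fw <- rethink_forward(model, as.matrix(x), keep = TRUE)
  mean(vapply(seq_len(model$config$T), function(t)
    bce_from_logits(fw$cache[[t]]$u, as.matrix(y), label_weights),
    numeric(1)))
}

#' Predict with a rethinking network
#'
#' Runs the forward pass and returns the full rethinking trace: the
#' label score matrix of every iteration `t = 1..T` and the final
#' thresholded labels from iteration `T`.
#'
#' @param object a `"rethinknet"` model.
#' @param x feature matrix with `object$dim` columns.
#' @param threshold decision cutoff; defaults to the configured one.
#' @param ... unused.
#' @return object of class `"rethink_trace"`: list with `scores`
#'   (array n x T x L), `final_scores` (n x L), `final_labels` (binary
#'   n x L), `threshold`.
#' @export
predict.rethinknet <- function(object, x, threshold = NULL, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$dim)
    stop("feature dimension mismatch: model expects ", object$dim,
         " columns, got ", ncol(x))
  if (is.null(threshold)) threshold <- object$config$threshold
  fw <- rethink_forward(object, x)
  final <- fw$scores[, object$config$T, , drop = FALSE]
  final <- array(final, dim(final)[c(1L, 3L)])
  structure(list(scores = fw$scores, final_scores = final,
                 final_labels = (final >= threshold) * 1,
                 threshold = threshold),
            class = "rethink_trace")
}

#' @export
print.rethink_trace <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("Rethinking trace: %d samples, T = %d iterations, %d labels\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  positives at threshold %.2f: %d\n", x$threshold,
              sum(x$final_labels)))
  invisible(x)
}

#' Attention probabilities of a rethinking network
#'
#' Returns the softmax attention weights the model assigns to the input.
#' For feature-axis attention this is one weight per gene per sample
#' (rows sum to 1); the attention block's output equals the input
#' multiplied element-wise by these weights.  For step-axis attention
#' the weights are distributed over the `T` replicated steps (summing to
#' 1 along the step axis for every sample-gene pair).
#'
#' @param model a `"rethinknet"` object with attention enabled.
#' @param x feature matrix.
#' @return feature axis: matrix n x dim; step axis: array n x dim x T.
#' @export
attention_probabilities <- function(model, x) {
  if (model$config$attention == "off")
    stop("model has no attention block (attention = 'off')")
  x <- as.matrix(x)
  fw <- rethink_forward(model, x)
  if (model$config$attention == "feature_axis") return(fw$att)
  arr <- array(NA_real_, c(nrow(x), model$dim, model$config$T))
  for (t in seq_len(model$config$T)) arr[, , t] <- fw$att[[t]]
  arr
}

#' Number of trainable parameters
#'
#' For feature-axis attention (and for no attention) the count does not
#' depend on the number of rethinking iterations `T`, since the
#' recurrent weights are shared across steps.
#'
#' @param model a `"rethinknet"` object.
#' @return integer parameter count.
#' @export
rethink_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
coef.rethinknet <- function(object, ...) object$params

#' @export
print.rethinknet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Rethinking network (%s cell, attention: %s)\n",
              toupper(cfg$cell), cfg$attention))
  cat(sprintf("  dim = %d genes, L = %d labels, T = %d iterations, %d hidden units\n",
              x$dim, x$L, cfg$T, cfg$hidden_units))
  cat(sprintf("  %d trainable parameters; %s\n", rethink_n_params(x),
              if (x$fitted) sprintf("trained %d epochs, final loss %.5f",
                                    cfg$epochs, utils::tail(x$history, 1))
              else "untrained"))
  invisible(x)
}

#' @export
summary.rethinknet <- function(object, ...) {
  print(object)
  cat("  label weights:", paste(sprintf("%.3f", object$label_weights),
                                collapse = " "), "\n")
  invisible(object)
}

#' @export
plot.rethinknet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}
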