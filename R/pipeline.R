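internal_fit_predict <- function(method, Xtr, Ytr, Xte, seed,
                                 rethink = rethink_config(),
                                 learner = learner_logistic(),
                                 knn_k = 5L, chain_order = NULL) {
  if (method %in% c("att_rethinknet", "rethinknet")) {
    cfg <- rethink
    cfg$seed <- as.integer(seed)
    if (method == "rethinknet") cfg$attention <- "off"
    fit <- rethinknet(Xtr, Ytr, cfg)
    tr <- predict(fit, Xte)
    return(list(fit = fit, labels = tr$final_labels, scores = tr$final_scores))
  }
  fit <- switch(method,
    br = binary_relevance(Xtr, Ytr, learner),
    cc = classifier_chain(Xtr, Ytr, learner, order = chain_order),
    knn = knn_multilabel(Xtr, Ytr, k = knn_k),
    stop("unknown method: ", method))
  list(fit = fit, labels = predict(fit, Xte),
       scores = predict(fit, Xte, type = "scores"))
}

eval_scalar_names <- c("acc", "acc_pair", "acc_avelab", "sen", "spe",
                       "f1", "auc")

#' K-fold cross-validated pipeline
#'
#' Runs the end-to-end procedure on an assembled R_max dataset:
#' oversample the minority findings with improved MLSMOTE, normalise
#' the features, split into K folds, train the chosen multi-label
#' learner on each training portion, and average the full evaluation
#' suite over folds.
#'
#' Two augmentation modes are offered.  `"paper_faithful"` augments the
#' whole dataset and then splits it, so synthetic samples may land in
#' test folds (the literal reading of the procedure being reproduced);
#' `"leak_free"` splits the original samples first, augments each
#' training portion only, and always evaluates on untouched originals —
#' the methodologically safer choice.  In leak-free mode the MLSMOTE
#' provenance of each fold is recorded so that the absence of train/test
#' leakage can be verified (`$fold_provenance`).
#'
#' @param dataset an [mld()] dataset of original samples.
#' @param method `"att_rethinknet"`, `"rethinknet"` (no-attention
#'   ablation), `"br"`, `"cc"`, or `"knn"`.
#' @param K number of folds (>= 2, default 5).
#' @param augment apply MLSMOTE oversampling (default TRUE).
#' @param augment_mode `"paper_faithful"` or `"leak_free"`.
#' @param normalization `"zscore"` or `"none"`.
#' @param seed master seed; every stochastic stage (fold assignment,
#'   oversampling, model initialisation) derives from it.
#' @param mlsmote an [mlsmote_control()].
#' @param rethink a [rethink_config()] for the network methods.
#' @param learner learner factory for `"br"`/`"cc"`.
#' @param knn_k neighbours for `"knn"`.
#' @param chain_order chain order for `"cc"`.
#' @param verbose log each stage with counts.
#' @return object of class `"ml_crossval"`: per-fold reports (`$folds`),
#'   their arithmetic mean (`$aggregate`) and standard deviation
#'   (`$sd`), the fold assignment, and per-fold provenance records.
#' @export
run_crossval <- function(dataset, method = "att_rethinknet", K = 5L,
                         augment = TRUE,
                         augment_mode = c("paper_faithful", "leak_free"),
                         normalization = c("zscore", "none"),
                         seed = 1L, mlsmote = mlsmote_control(),
                         rethink = rethink_config(),
                         learner = learner_logistic(), knn_k = 5L,
                         chain_order = NULL, verbose = FALSE) {
  augment_mode <- match.arg(augment_mode)
  normalization <- match.arg(normalization)
  validate_mld(dataset)
  if (K < 2L) stop("K must be >= 2")
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(seed)

  if (augment_mode == "paper_faithful") {
    work <- dataset
    if (augment) {
      mlsmote$seed <- seed
      work <- mlsmote_augment(dataset, mlsmote)
      say("augmented %d -> %d samples (MeanIR %.2f -> %.2f)",
          nrow(dataset$features), nrow(work$features),
          attr(work, "mean_ir_path")[1],
          utils::tail(attr(work, "mean_ir_path"), 1))
    }
    if (normalization == "zscore")
      work$features <- normalize_features(work$features)$train
    n <- nrow(work$features)
  } else {
    work <- dataset
    n <- nrow(dataset$features)
  }

  set.seed(seed)
  fold_of <- sample(rep(seq_len(K), length.out = n))
  folds <- vector("list", K)
  fold_prov <- vector("list", K)
  for (kf in seq_len(K)) {
    te <- which(fold_of == kf)
    tr <- which(fold_of != kf)
    if (augment_mode == "paper_faithful") {
      Xtr <- work$features[tr, , drop = FALSE]
      Ytr <- work$labels[tr, , drop = FALSE]
      Xte <- work$features[te, , drop = FALSE]
      Yte <- work$labels[te, , drop = FALSE]
    } else {
      train_set <- mld_subset(work, tr)
      if (augment) {
        ml <- mlsmote
        ml$seed <- seed + kf
        train_set <- mlsmote_augment(train_set, ml)
        fold_prov[[kf]] <- list(
          train_ids = dataset$sample_ids[tr],
          test_ids = dataset$sample_ids[te],
          provenance = attr(train_set, "mlsmote_provenance"))
      }
      Xtr <- train_set$features; Ytr <- train_set$labels
      Xte <- work$features[te, , drop = FALSE]
      Yte <- work$labels[te, , drop = FALSE]
      if (normalization == "zscore") {
        nf <- normalize_features(Xtr, Xte)
        Xtr <- nf$train; Xte <- nf$other
      }
    }
    say("fold %d: %d train / %d test samples", kf, nrow(Xtr), nrow(Xte))
    fp <- internal_fit_predict(method, Xtr, Ytr, Xte, seed = seed + kf,
                               rethink = rethink, learner = learner,
                               knn_k = knn_k, chain_order = chain_order)
    folds[[kf]] <- evaluate_multilabel(Yte, fp$labels, fp$scores)
  }
  scal <- t(vapply(folds, function(e)
    unlist(e[eval_scalar_names]), numeric(length(eval_scalar_names))))
  acc_lab <- t(vapply(folds, function(e) e$acc_lab,
                      numeric(length(folds[[1L]]$acc_lab))))
  structure(list(folds = folds,
                 aggregate = c(colMeans(scal)),
                 sd = apply(scal, 2L, stats::sd),
                 acc_lab = colMeans(acc_lab),
                 fold_assignment = fold_of,
                 fold_provenance = fold_prov,
                 method = method, K = K, augment_mode = augment_mode,
                 seed = seed),
            class = "ml_crossval")
}

#' @export
print.ml_crossval <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation of '%s' (%s mode)\n",
              x$K, x$method, x$augment_mode))
  m <- x$aggregate; s <- x$sd
  for (nm in names(m))
    cat(sprintf("  %-10s %.*f (sd %.*f)\n", nm, digits, m[nm], digits, s[nm]))
  invisible(x)
}

#' Held-out train/test evaluation
#'
#' Independent-split workflow: the training set is augmented and
#' normalised on its own, the model is trained on it, and the untouched
#' test set is evaluated with the training normalisation map.  Sample
#' identifiers must be disjoint between the two sets.
#'
#' @param train,test [mld()] datasets with disjoint sample ids and
#'   identical gene/label panels.
#' @inheritParams run_crossval
#' @return an `"ml_eval"` report for the test set; attribute
#'   `"provenance"` carries the training MLSMOTE record.
#' @export
run_holdout <- function(train, test, method = "att_rethinknet",
                        augment = TRUE,
                        normalization = c("zscore", "none"),
                        seed = 1L, mlsmote = mlsmote_control(),
                        rethink = rethink_config(),
                        learner = learner_logistic(), knn_k = 5L,
                        chain_order = NULL) {
  normalization <- match.arg(normalization)
  validate_mld(train); validate_mld(test)
  overlap <- intersect(train$sample_ids, test$sample_ids)
  if (length(overlap))
    stop("train and test sample ids overlap: ",
         paste(utils::head(overlap, 3), collapse = ", "))
  if (!identical(train$gene_ids, test$gene_ids))
    stop("train and test gene panels differ")
  seed <- as.integer(seed)
  prov <- NULL
  if (augment) {
    mlsmote$seed <- seed
    train <- mlsmote_augment(train, mlsmote)
    prov <- attr(train, "mlsmote_provenance")
  }
  Xtr <- train$features; Xte <- test$features
  if (normalization == "zscore") {
    nf <- normalize_features(Xtr, Xte)
    Xtr <- nf$train; Xte <- nf$other
  }
  fp <- internal_fit_predict(method, Xtr, train$labels, Xte, seed = seed,
                             rethink = rethink, learner = learner,
                             knn_k = knn_k, chain_order = chain_order)
  out <- evaluate_multilabel(test$labels, fp$labels, fp$scores)
  attr(out, "provenance") <- prov
  out
}
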