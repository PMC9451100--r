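#' Per-label imbalance profile (IRLbl / MeanIR)
#'
#' For each label l with positive count c_l, the imbalance ratio is
#' `IRLbl(l) = max_l' c_l' / c_l`; `MeanIR` is the mean of IRLbl over
#' labels with at least one positive.  Labels with zero positives are
#' reported with an infinite ratio and excluded from the mean.
#'
#' @param labels binary matrix (samples x labels).
#' @return object of class `"imbalance_profile"`: list with `counts`,
#'   `irlbl`, `mean_ir`, `minority` (logical, IRLbl > MeanIR among
#'   counted labels).
#' @examples
#' y <- cbind(a = c(1, 1, 1, 1, 0, 0, 0, 1), b = c(1, 1, 0, 0, 0, 0, 0, 0))
#' imbalance_profile(y)
#' @export
imbalance_profile <- function(labels) {
  labels <- as.matrix(labels)
  counts <- colSums(labels)
  if (all(counts == 0)) stop("all labels have zero positives; nothing to balance")
  irlbl <- max(counts) / counts          # Inf where count == 0
  counted <- counts > 0
  mean_ir <- mean(irlbl[counted])
  structure(list(counts = counts, irlbl = irlbl, mean_ir = mean_ir,
                 minority = counted & irlbl > mean_ir),
            class = "imbalance_profile")
}

#' @export
print.imbalance_profile <- function(x, ...) {
  cat(sprintf("Imbalance profile over %d labels: MeanIR = %.3f\n",
              length(x$counts), x$mean_ir))
  cat("  positive counts:", paste(x$counts, collapse = " "), "\n")
  cat("  minority labels:", sum(x$minority), "\n")
  invisible(x)
}

#' Configuration for improved MLSMOTE oversampling
#'
#' @param k number of nearest neighbours used for interpolation and label
#'   ranking (default 5).
#' @param max_rounds maximal number of full oversampling passes.
#' @param target_mean_ir stop once MeanIR falls to this value or below.
#' @param vote_scope neighbour set voting on the synthetic labels:
#'   `"bag"` (default) votes over the seed and its k nearest neighbours
#'   within the minority bag, the classic formulation, under which the
#'   triggering label always reaches a majority and balancing is
#'   effective; `"dataset"` votes over the seed's k nearest neighbours
#'   in the whole dataset, where rare-label samples surrounded by
#'   no-finding neighbours can be out-voted — the variant in which
#'   all-zero label vectors arise and the guard earns its keep.
#' @param guard what to do when the neighbour label ranking yields an
#'   all-zero vector: `"force_label"` (default) sets the minority label
#'   that triggered the sample, so every synthetic sample carries at
#'   least one finding; `"discard"` rejects the sample instead.
#' @param seed integer RNG seed for the pass.
#' @return list of class `"mlsmote_control"`.
#' @export
mlsmote_control <- function(k = 5L, max_rounds = 5L, target_mean_ir = 1.5,
                            vote_scope = c("bag", "dataset"),
                            guard = c("force_label", "discard"),
                            seed = 1L) {
  vote_scope <- match.arg(vote_scope)
  guard <- match.arg(guard)
  if (k < 1L || max_rounds < 1L || target_mean_ir < 1)
    stop("k >= 1, max_rounds >= 1 and target_mean_ir >= 1 required")
  structure(list(k = as.integer(k), max_rounds = as.integer(max_rounds),
                 target_mean_ir = target_mean_ir, vote_scope = vote_scope,
                 guard = guard, seed = as.integer(seed)),
            class = "mlsmote_control")
}

# k nearest neighbours of row i within rows `bag` of X (excluding i),
# Euclidean, ties broken by sample index for determinism
knn_in_bag <- function(X, bag, i, k) {
  others <- setdiff(bag, i)
  d <- sqrt(rowSums((X[others, , drop = FALSE] -
                       matrix(X[i, ], length(others), ncol(X), byrow = TRUE))^2))
  others[order(d, others)][seq_len(min(k, length(others)))]
}

#' Improved MLSMOTE multi-label oversampling
#'
#' One pass visits every minority label (IRLbl above MeanIR) and, for
#' each sample in that label's positive bag, interpolates a synthetic
#' sample between the seed and a randomly chosen one of its k nearest
#' neighbours inside the bag: `x_new = x_seed + u (x_neigh - x_seed)`
#' with `u ~ U(0, 1)`, so synthetic features stay inside the minority
#' region.  Synthetic labels follow the neighbour ranking rule: a label
#' is set when it is present in strictly more than half of the voting
#' group (the seed plus k neighbours, see `vote_scope` in
#' [mlsmote_control()]).  Under dataset-scope voting a rare finding's
#' samples often sit among no-finding neighbours and the ranking can
#' produce an all-zero label vector; the guard then sets the triggering
#' minority label (or discards the sample), so no synthetic sample ever
#' carries an empty finding set.  Passes repeat until
#' `MeanIR <= target_mean_ir`, the round budget is exhausted, or a pass
#' fails to reduce MeanIR (such a pass is discarded, so augmentation
#' never worsens the imbalance).
#'
#' @param dataset an [mld()] object.
#' @param control an [mlsmote_control()] list.
#' @return the augmented [mld()]; original rows are preserved verbatim
#'   and synthetic rows are flagged in `$provenance`.  Attribute
#'   `"mlsmote_provenance"` records, per synthetic row, the seed row, the
#'   chosen neighbour row, the interpolation weight `u`, the triggering
#'   label, and whether the all-zero guard fired.  Attribute
#'   `"mean_ir_path"` records MeanIR before and after each kept pass.
#' @export
mlsmote_augment <- function(dataset, control = mlsmote_control()) {
  validate_mld(dataset)
  X <- dataset$features
  Y <- dataset$labels
  prof <- imbalance_profile(Y)
  prov <- data.frame(seed_row = integer(), neighbor_row = integer(),
                     u = numeric(), label = integer(), guard = logical())
  mean_ir_path <- prof$mean_ir
  set.seed(control$seed)
  round <- 0L
  while (prof$mean_ir > control$target_mean_ir && round < control$max_rounds) {
    round <- round + 1L
    if (!any(prof$minority)) break
    newX <- list(); newY <- list(); newP <- list()
    for (l in which(prof$minority)) {
      bag <- which(Y[, l] == 1)
      if (length(bag) < 2L) {
        warning("minority label '", dataset$label_names[l],
                "' has fewer than 2 positives; skipped")
        next
      }
      for (i in bag) {
        nn_bag <- knn_in_bag(X, bag, i, control$k)
        ref <- nn_bag[sample.int(length(nn_bag), 1L)]
        u <- stats::runif(1L)
        feat <- X[i, ] + u * (X[ref, ] - X[i, ])
        voters <- c(i, if (control$vote_scope == "bag") nn_bag
                       else knn_in_bag(X, seq_len(nrow(X)), i, control$k))
        votes <- colSums(Y[voters, , drop = FALSE])
        lab <- as.numeric(votes > length(voters) / 2)
        guard_fired <- FALSE
        if (all(lab == 0)) {
          if (control$guard == "discard") next
          lab[l] <- 1                   # force the triggering minority label
          guard_fired <- TRUE
        }
        newX[[length(newX) + 1L]] <- feat
        newY[[length(newY) + 1L]] <- lab
        newP[[length(newP) + 1L]] <- data.frame(
          seed_row = i, neighbor_row = ref, u = u, label = l,
          guard = guard_fired)
      }
    }
    if (!length(newX)) break
    Xc <- rbind(X, do.call(rbind, newX))
    Yc <- rbind(Y, do.call(rbind, newY))
    prof_new <- imbalance_profile(Yc)
    if (prof_new$mean_ir >= prof$mean_ir) break   # discard worsening pass
    X <- Xc; Y <- Yc
    prov <- rbind(prov, do.call(rbind, newP))
    prof <- prof_new
    mean_ir_path <- c(mean_ir_path, prof$mean_ir)
  }
  n_orig <- nrow(dataset$features)
  n_syn <- nrow(X) - n_orig
  ids <- c(dataset$sample_ids, if (n_syn > 0) paste0("syn", seq_len(n_syn)))
  out <- mld(X, Y,
             gene_ids = dataset$gene_ids,
             label_names = dataset$label_names,
             sample_ids = ids,
             provenance = c(dataset$provenance, rep("synthetic", n_syn)))
  if (nrow(prov)) {
    # seeds from a later pass can themselves be synthetic; record ids so
    # provenance stays interpretable either way
    prov$seed_id <- ids[prov$seed_row]
    prov$neighbor_id <- ids[prov$neighbor_row]
  } else {
    prov$seed_id <- character(0)
    prov$neighbor_id <- character(0)
  }
  attr(out, "mlsmote_provenance") <- prov
  attr(out, "mean_ir_path") <- mean_ir_path
  out
}
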