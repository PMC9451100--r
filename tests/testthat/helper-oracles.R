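# Independent brute-force oracles used to cross-check the vectorized
# implementations.  Everything here is written with explicit loops over
# samples and labels, deliberately sharing no code with the package.

oracle_eval <- function(Y, Yhat) {
  n <- nrow(Y); L <- ncol(Y)
  exact <- 0
  jacc <- numeric(n)
  for (i in seq_len(n)) {
    same <- TRUE
    inter <- 0; uni <- 0
    for (l in seq_len(L)) {
      if (Y[i, l] != Yhat[i, l]) same <- FALSE
      if (Y[i, l] == 1 && Yhat[i, l] == 1) inter <- inter + 1
      if (Y[i, l] == 1 || Yhat[i, l] == 1) uni <- uni + 1
    }
    if (same) exact <- exact + 1
    jacc[i] <- if (uni == 0) 1 else inter / uni
  }
  acc_lab <- numeric(L)
  tp <- fp <- tn <- fn <- integer(L)
  for (l in seq_len(L)) {
    for (i in seq_len(n)) {
      if (Y[i, l] == 1 && Yhat[i, l] == 1) tp[l] <- tp[l] + 1
      if (Y[i, l] == 0 && Yhat[i, l] == 1) fp[l] <- fp[l] + 1
      if (Y[i, l] == 0 && Yhat[i, l] == 0) tn[l] <- tn[l] + 1
      if (Y[i, l] == 1 && Yhat[i, l] == 0) fn[l] <- fn[l] + 1
    }
    acc_lab[l] <- (tp[l] + tn[l]) / n
  }
  ratio_mean <- function(num, den) {
    keep <- den != 0
    if (!any(keep)) return(NA_real_)
    mean(num[keep] / den[keep])
  }
  list(acc = exact / n, acc_pair = mean(jacc), acc_lab = acc_lab,
       tp = tp, fp = fp, tn = tn, fn = fn,
       acc_avelab = ratio_mean(tp + tn, tp + tn + fp + fn),
       sen = ratio_mean(tp, tp + fn),
       spe = ratio_mean(tn, tn + fp),
       f1 = ratio_mean(2 * tp, 2 * tp + fp + fn))
}

# micro AUC via the rank-sum (Mann-Whitney) statistic with midranks
oracle_auc <- function(Y, S) {
  y <- as.vector(Y); s <- as.vector(S)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# literal transcription of the size-penalised fitness definition
oracle_fitness <- function(acc, d_sel, d_tot, alpha, lam) {
  alpha * acc + (1 - alpha) * (d_tot - d_sel * lam) / d_tot
}

# two-group one-way ANOVA F computed from textbook group sums
oracle_f_stat <- function(v, y) {
  n <- length(v)
  m <- mean(v)
  m1 <- mean(v[y == 1]); m0 <- mean(v[y == 0])
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- sum((v[y == 1] - m1)^2) + sum((v[y == 0] - m0)^2)
  (ssb / 1) / (ssw / (n - 2))
}

random_label_matrix <- function(n, L, p = 0.4) {
  matrix(rbinom(n * L, 1, p), n, L)
}

# small imbalanced dataset for oversampling tests
random_imbalanced_mld <- function(n = 40, d = 5, L = 6, seed = 1) {
  set.seed(seed)
  p <- seq(0.6, 0.05, length.out = L)
  y <- sapply(p, function(pp) rbinom(n, 1, pp))
  y[1, ] <- c(1, rep(0, L - 1))  # guarantee at least one positive somewhere
  mld(matrix(rnorm(n * d), n, d), y)
}
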