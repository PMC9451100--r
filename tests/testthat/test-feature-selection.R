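test_that("per-label F equals the textbook ANOVA formula", {
  set.seed(23)
  x <- matrix(rnorm(20 * 7), 20, 7)
  y <- random_label_matrix(20, 3, 0.5)
  y[1:2, ] <- rep(c(1, 0), length.out = 6)    # keep both classes present
  fs <- multilabel_f_scores(x, y)
  for (l in 1:3) {
    for (g in sample(7, 3)) {
      expect_equal(fs$per_label[g, l], oracle_f_stat(x[, g], y[, l]),
                   tolerance = 1e-12)
    }
  }
  # cross-check one cell against anova() as an independent reference
  fit <- anova(lm(x[, 1] ~ factor(y[, 1])))
  expect_equal(fs$per_label[1, 1], fit$`F value`[1], tolerance = 1e-10)
})

test_that("degenerate genes rank last (zero) or first (capped)", {
  y <- cbind(rep(c(1, 0), each = 5))
  x <- cbind(ident = rep(2, 10),               # identical in both groups
             sep = rep(c(1, 0), each = 5),     # zero within-variance split
             noise = rnorm(10))
  fs <- multilabel_f_scores(x, y)
  expect_equal(unname(fs$scores["ident"]), 0)
  expect_equal(unname(fs$scores["sep"]), 1e12)
  expect_equal(fs$ranking[1], 2L)
  expect_equal(fs$ranking[3], 1L)
})

test_that("ranking is permutation-equivariant and skips single-class labels", {
  set.seed(4)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- cbind(rbinom(30, 1, 0.5), rbinom(30, 1, 0.4), rep(0, 30))
  y[1:2, 1:2] <- rep(c(1, 0), each = 2)
  expect_warning(fs <- multilabel_f_scores(x, y), "single-class")
  perm <- c(3, 1, 5, 2, 4)
  fs2 <- suppressWarnings(multilabel_f_scores(x[, perm], y))
  expect_equal(unname(fs2$scores), unname(fs$scores[perm]), tolerance = 1e-12)
})

test_that("fitness reproduces the literal formula and its hand case", {
  expect_equal(fitness(1, 0, 100), 1)
  expect_equal(fitness(1, 0, 100, alpha = 0.3, lam = 50), 1)
  hand <- fitness(0.8, 100, 6009, alpha = 0.6, lam = 10)
  expect_equal(hand, 0.6 * 0.8 + 0.4 * (6009 - 1000) / 6009, tolerance = 1e-12)
  expect_equal(hand, 0.8134, tolerance = 1e-4)
  set.seed(11)
  for (rep in 1:200) {
    d_tot <- sample(10:5000, 1)
    d_sel <- sample.int(d_tot, 1)
    acc <- runif(1); a <- runif(1); lam <- runif(1, 0.5, 30)
    expect_equal(fitness(acc, d_sel, d_tot, a, lam),
                 oracle_fitness(acc, d_sel, d_tot, a, lam),
                 tolerance = 1e-12)
  }
  # monotone decreasing in subset size at fixed accuracy
  sizes <- 1:50
  vals <- sapply(sizes, fitness, acc = 0.7, d_total = 50)
  expect_true(all(diff(vals) < 0))
})

test_that("subset search maximises fitness with ties toward smaller subsets", {
  set.seed(8)
  x <- matrix(rnorm(40 * 12), 40, 12)
  y <- cbind(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  y[1:2, ] <- rep(c(1, 0), each = 2)

  # constant evaluator: fitness is then monotone in size, so the smallest wins
  res <- greedy_subset_search(x, y, function(idx) 0.75,
                              sizes_grid = c(12, 6, 3, 1))
  expect_equal(res$best_size, 1)
  expect_equal(res$curve$size, c(12, 6, 3, 1))

  # single-size grid
  res1 <- greedy_subset_search(x, y, function(idx) 0.5, sizes_grid = 4)
  expect_equal(res1$best_size, 4)

  # failing sizes are skipped, not fatal
  expect_warning(
    res2 <- greedy_subset_search(x, y, function(idx) {
      if (length(idx) == 6) stop("boom") else 0.4
    }, sizes_grid = c(12, 6, 3)),
    "failed at size 6")
  expect_equal(res2$curve$size, c(12, 3))

  expect_error(greedy_subset_search(x, y, function(idx) 1,
                                    sizes_grid = c(3, 6)), "decreasing")
})

test_that("an oracle evaluator recovers the planted informative genes", {
  set.seed(15)
  n <- 60; d <- 30
  planted <- sort(sample(d, 10))
  x <- matrix(rnorm(n * d), n, d)
  y <- cbind((rowSums(x[, planted]) > 0) * 1,
             (rowSums(x[, planted[1:5]]) > 0) * 1)
  evaluator <- function(idx) mean(planted %in% idx)
  res <- greedy_subset_search(x, y, evaluator,
                              sizes_grid = c(30, 20, 14, 10, 7, 4),
                              alpha = 0.9, lam = 1)
  expect_true(res$best_size <= 20)
  expect_gte(mean(planted %in% res$best_idx), 0.8)
})
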