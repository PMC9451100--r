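test_that("forward pass honours the shape and sigmoid-range contracts", {
  set.seed(1)
  for (rep in 1:5) {
    Tn <- sample(1:5, 1); H <- sample(2:10, 1)
    cell <- sample(c("lstm", "srn"), 1)
    att <- sample(c("feature_axis", "step_axis", "off"), 1)
    dim <- sample(3:12, 1); L <- sample(1:6, 1); b <- sample(1:7, 1)
    m <- rethink_build(rethink_config(T = Tn, cell = cell, hidden_units = H,
                                      attention = att, seed = rep), dim, L)
    X <- matrix(rnorm(b * dim), b, dim)
    tr <- predict(m, X)
    expect_equal(dim(tr$scores), c(b, Tn, L))
    expect_true(all(tr$scores > 0 & tr$scores < 1))
    expect_equal(tr$final_labels, (tr$final_scores >= 0.5) * 1)
  }
  expect_error(rethink_build(rethink_config(), 10, 0), "L")
  expect_error(rethink_config(T = 0), "T")
  expect_error(rethink_config(threshold = 1.2), "threshold")
})

test_that("parameter count is invariant to the number of rethinking iterations", {
  for (att in c("feature_axis", "off")) {
    n3 <- rethink_n_params(rethink_build(
      rethink_config(T = 3, attention = att, hidden_units = 16), 10, 4))
    n5 <- rethink_n_params(rethink_build(
      rethink_config(T = 5, attention = att, hidden_units = 16), 10, 4))
    expect_identical(n3, n5)
  }
})

test_that("attention weights are probabilities and act multiplicatively", {
  cfg <- rethink_config(T = 3, hidden_units = 6, seed = 2)
  m <- rethink_build(cfg, 8, 3)
  X <- matrix(rnorm(5 * 8), 5, 8)

  # freshly built attention dense layer is zero, so weights are uniform 1/dim
  A <- attention_probabilities(m, X)
  expect_equal(A, matrix(1 / 8, 5, 8))

  # after training the weights stay normalized and reproduce the block output
  fit <- rethinknet(make_separable_benchmark(60, 8, 3, seed = 5),
                    config = rethink_config(T = 2, hidden_units = 6,
                                            epochs = 3, seed = 2))
  A <- attention_probabilities(fit, X)
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
  fw <- rethinktox:::rethink_forward(fit, X)
  expect_equal(fw$Xw, X * A * 8, tolerance = 1e-12)

  # two inference passes are identical
  expect_identical(A, attention_probabilities(fit, X))

  # step-axis attention normalizes over iterations
  ms <- rethink_build(rethink_config(T = 4, attention = "step_axis",
                                     hidden_units = 4), 6, 2)
  As <- attention_probabilities(ms, matrix(rnorm(18), 3, 6))
  expect_equal(apply(As, c(1, 2), sum), matrix(1, 3, 6), tolerance = 1e-6)

  moff <- rethink_build(rethink_config(attention = "off"), 6, 2)
  expect_error(attention_probabilities(moff, X), "no attention")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  X <- matrix(rnorm(4 * 5), 4, 5)
  Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  wl <- c(1.2, 0.8, 1.0)
  for (case in list(c("lstm", "feature_axis"), c("srn", "step_axis"),
                    c("lstm", "off"))) {
    m <- rethink_build(rethink_config(T = 3, cell = case[1],
                                      attention = case[2],
                                      hidden_units = 4, seed = 9), 5, 3)
    # perturb away from the zero attention init so its gradient is generic
    if (case[2] == "feature_axis") m$params$Wa[] <- rnorm(25, 0, 0.2)
    if (case[2] == "step_axis") m$params$ua <- rnorm(3, 0, 0.2)
    gr <- rethinktox:::rethink_grads(m, X, Y, wl)
    for (nm in names(m$params)) {
      for (idx in sample(length(m$params[[nm]]),
                         min(3, length(m$params[[nm]])))) {
        eps <- 1e-6
        mp <- m; mp$params[[nm]][idx] <- mp$params[[nm]][idx] + eps
        mm <- m; mm$params[[nm]][idx] <- mm$params[[nm]][idx] - eps
        num <- (rethink_loss(mp, X, Y, wl) - rethink_loss(mm, X, Y, wl)) /
          (2 * eps)
        expect_equal(gr$grads[[nm]][idx], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("label weights are cost-sensitive with mean exactly one", {
  y <- cbind(rbinom(50, 1, 0.8), rbinom(50, 1, 0.1), rep(0, 50))
  y[1, ] <- c(1, 1, 0)
  expect_warning(w <- rethink_label_weights(y), "zero positives")
  expect_equal(mean(w), 1, tolerance = 1e-15)
  expect_gt(w[2], w[1])  # rarer label weighs more
  expect_equal(rethink_label_weights(y, "uniform"), rep(1, 3))
  expect_equal(mean(rethink_label_weights(y, c(3, 2, 1))), 1)
})

test_that("uniform weights on any dataset reduce the loss to unweighted mean BCE", {
  set.seed(6)
  m <- rethink_build(rethink_config(T = 2, hidden_units = 4,
                                    label_weights = "uniform"), 5, 4)
  X <- matrix(rnorm(6 * 5), 6, 5)
  Y <- random_label_matrix(6, 4, 0.5)
  fw <- rethinktox:::rethink_forward(m, X)
  manual <- 0
  for (t in 1:2) {
    s <- fw$scores[, t, ]
    manual <- manual + mean(-(Y * log(s) + (1 - Y) * log(1 - s)))
  }
  expect_equal(rethink_loss(m, X, Y, rep(1, 4)), manual / 2, tolerance = 1e-10)
})

test_that("training is reproducible and attention-off equals the plain ablation", {
  d <- make_separable_benchmark(60, 8, 3, seed = 11)
  cfg <- rethink_config(T = 2, hidden_units = 6, epochs = 2, seed = 4)
  f1 <- rethinknet(d$features, d$labels, cfg)
  f2 <- rethinknet(d$features, d$labels, cfg)
  expect_identical(f1$history[1], f2$history[1])
  expect_identical(f1$params, f2$params)

  # with the attention dense layer at zero the block is the identity, so an
  # untrained attention model and the no-attention ablation coincide
  matt <- rethink_build(rethink_config(T = 3, hidden_units = 5, seed = 7), 6, 2)
  moff <- rethink_build(rethink_config(T = 3, hidden_units = 5, seed = 7,
                                       attention = "off"), 6, 2)
  X <- matrix(rnorm(24), 4, 6)
  expect_equal(predict(matt, X)$scores, predict(moff, X)$scores,
               tolerance = 1e-12)
})

test_that("prediction enforces the input contract and exposes the trace", {
  d <- make_separable_benchmark(50, 6, 2, seed = 3)
  fit <- rethinknet(d$features, d$labels,
                    rethink_config(T = 4, hidden_units = 5, epochs = 2))
  tr <- predict(fit, d$features)
  expect_equal(dim(tr$scores)[2], 4)
  expect_error(predict(fit, d$features[, 1:3]), "dimension mismatch")
  expect_equal(tr$final_labels, (tr$scores[, 4, ] >= 0.5) * 1)
})

test_that("rethinking does not degrade training accuracy from first to final iteration", {
  # diagnostic with tolerance: later iterations should refine, or at least
  # not damage, the tentative predictions on the training split
  d <- make_separable_benchmark(200, 20, 4, seed = 9)
  accs <- sapply(1:3, function(s) {
    fit <- rethinknet(d$features, d$labels,
                      rethink_config(T = 4, hidden_units = 16, epochs = 15,
                                     seed = s))
    tr <- predict(fit, d$features)
    c(subset_accuracy(d$labels, (tr$scores[, 1, ] >= 0.5) * 1),
      subset_accuracy(d$labels, tr$final_labels))
  })
  expect_gte(mean(accs[2, ]), mean(accs[1, ]) - 0.02)
})
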