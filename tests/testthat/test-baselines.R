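test_that("binary relevance trains each label independently", {
  set.seed(12)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- cbind(a = (x[, 1] > 0) * 1, b = (x[, 2] > 0) * 1)
  br <- binary_relevance(x, y, learner_stump())
  # permuting the *other* label's training column leaves label a untouched
  y2 <- y; y2[, 2] <- sample(y2[, 2])
  br2 <- binary_relevance(x, y2, learner_stump())
  xt <- matrix(rnorm(10 * 4), 10, 4)
  expect_identical(predict(br, xt)[, "a"], predict(br2, xt)[, "a"])

  # per-label predictions equal the stub's solo predictions
  solo <- learner_stump()()
  st <- solo$fit(rethinktox:::canon_cols(x), y[, "b"])
  expect_equal(unname(predict(br, xt, type = "scores")[, "b"]),
               solo$score(st, rethinktox:::canon_cols(xt)))

  # L = 1: BR is the lone base learner
  br1 <- binary_relevance(x, y[, 1, drop = FALSE], learner_stump())
  st1 <- solo$fit(rethinktox:::canon_cols(x), y[, 1])
  expect_equal(unname(predict(br1, xt, type = "scores")[, 1]),
               solo$score(st1, rethinktox:::canon_cols(xt)))
})

test_that("single-class labels fall back to a constant predictor", {
  x <- matrix(rnorm(20), 10, 2)
  y <- cbind(rep(1, 10), rbinom(10, 1, 0.5))
  y[1, 2] <- 1; y[2, 2] <- 0
  expect_warning(br <- binary_relevance(x, y, learner_stump()),
                 "single-class")
  expect_true(all(predict(br, x)[, 1] == 1))
})

test_that("classifier chain widths grow by one per position", {
  set.seed(2)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- random_label_matrix(30, 4, 0.5)
  y[1:2, ] <- rep(c(1, 0), each = 2)
  widths <- integer(0)
  spy <- function() {
    inner <- learner_stump()()
    list(fit = function(xx, yy) {
      widths <<- c(widths, ncol(xx))
      inner$fit(xx, yy)
    }, score = inner$score)
  }
  cc <- suppressWarnings(classifier_chain(x, y, spy))
  expect_identical(widths, 3L + 0:3)
  expect_error(classifier_chain(x, y, learner_stump(), order = c(1, 1, 2, 3)),
               "permutation")
  # L = 1: the chain degenerates to binary relevance
  cc1 <- classifier_chain(x, y[, 1, drop = FALSE], learner_stump())
  br1 <- binary_relevance(x, y[, 1, drop = FALSE], learner_stump())
  expect_equal(predict(cc1, x), predict(br1, x))
})

test_that("the chain propagates a label identity that BR cannot see", {
  # label 1 is feature-noise; label 2 is identical to label 1.  A chain
  # classifier sees label 1 as an input column and copies it, so its label-2
  # predictions equal its label-1 predictions exactly; BR's label-2 model
  # sees only noise and stays at the prevalence baseline.
  set.seed(77)
  n <- 240
  x <- matrix(rnorm(n * 6), n, 6)
  l1 <- rbinom(n, 1, 0.5)
  y <- cbind(l1 = l1, l2 = l1)
  tr <- 1:160; te <- 161:240
  cc <- classifier_chain(x[tr, ], y[tr, ], learner_stump())
  pc <- predict(cc, x[te, ])
  expect_identical(pc[, "l2"], pc[, "l1"])
  acc1 <- mean(pc[, "l1"] == y[te, "l1"])
  acc2 <- mean(pc[, "l2"] == y[te, "l2"])
  expect_identical(acc1, acc2)

  br <- binary_relevance(x[tr, ], y[tr, ], learner_stump())
  pb <- predict(br, x[te, ])
  base <- max(mean(y[te, "l2"]), 1 - mean(y[te, "l2"]))
  expect_lte(mean(pb[, "l2"] == y[te, "l2"]), base + 0.1)
})

test_that("per-label k-NN agrees with a brute-force vote", {
  set.seed(9)
  x <- matrix(rnorm(25 * 3), 25, 3)
  y <- random_label_matrix(25, 4, 0.4)
  kn <- knn_multilabel(x, y, k = 5)
  xt <- matrix(rnorm(8 * 3), 8, 3)
  got <- predict(kn, xt, type = "scores")
  for (i in 1:8) {
    d <- apply(x, 1, function(r) sqrt(sum((r - xt[i, ])^2)))
    nn <- order(d)[1:5]
    expect_equal(unname(got[i, ]), unname(colMeans(y[nn, ])),
                 tolerance = 1e-12)
  }
  # query at a training point with k = 1 copies that point's labels
  k1 <- knn_multilabel(x, y, k = 1)
  expect_equal(unname(predict(k1, x[3, , drop = FALSE])[1, ]),
               unname(y[3, ]))
  # unanimous neighbourhood votes positive; a 50:50 tie votes positive too
  ytie <- cbind(rep(c(1, 0), length.out = 25))
  xt1 <- matrix(0, 1, 3)
  k2 <- knn_multilabel(x, ytie, k = 2)
  s <- predict(k2, xt1, type = "scores")[1, 1]
  if (abs(s - 0.5) < 1e-12)
    expect_equal(predict(k2, xt1)[1, 1], 1)
  expect_error(knn_multilabel(x[1:4, ], y[1:4, ], k = 5), "more than k")
})

test_that("wrappers leave the input data unmodified", {
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  y <- random_label_matrix(10, 2, 0.5)
  y[1:2, ] <- rep(c(1, 0), each = 2)
  x0 <- x + 0; y0 <- y + 0
  invisible(binary_relevance(x, y, learner_stump()))
  invisible(classifier_chain(x, y, learner_stump()))
  expect_identical(x, x0)
  expect_identical(y, y0)
})
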