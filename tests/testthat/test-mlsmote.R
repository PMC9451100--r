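test_that("imbalance profile matches hand-computed ratios", {
  y <- cbind(rep(1:0, c(10, 0)), rep(1:0, c(10, 0)))[1:10, ]
  y <- cbind(a = rep(1, 10), b = rep(1, 10))
  p <- imbalance_profile(y)
  expect_equal(unname(p$irlbl), c(1, 1))
  expect_equal(p$mean_ir, 1)

  y <- cbind(rep(c(1, 0), c(8, 2)), rep(c(1, 0), c(2, 8)))
  p <- imbalance_profile(y)
  expect_equal(unname(p$irlbl), c(1, 4))
  expect_equal(p$mean_ir, 2.5)

  y <- cbind(rep(c(1, 0), c(6, 0)), rep(0, 6))
  p <- imbalance_profile(y)
  expect_true(is.infinite(p$irlbl[2]))
  expect_equal(p$mean_ir, 1)   # zero-count labels excluded from the mean

  expect_error(imbalance_profile(matrix(0, 4, 2)), "zero positives")
})

test_that("oversampling is deterministic and preserves originals verbatim", {
  d <- random_imbalanced_mld(seed = 10)
  a1 <- suppressWarnings(mlsmote_augment(d, mlsmote_control(seed = 3)))
  a2 <- suppressWarnings(mlsmote_augment(d, mlsmote_control(seed = 3)))
  expect_identical(a1$features, a2$features)
  expect_identical(a1$labels, a2$labels)
  n <- nrow(d$features)
  expect_identical(a1$features[1:n, ], d$features)
  expect_identical(a1$labels[1:n, ], d$labels)
  expect_true(all(a1$provenance[-(1:n)] == "synthetic"))
})

test_that("balanced datasets come back unchanged", {
  set.seed(2)
  y <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))  # both labels count 10
  d <- mld(matrix(rnorm(40), 20, 2), y)
  out <- mlsmote_augment(d, mlsmote_control(seed = 1))
  expect_identical(out$features, d$features)
  expect_identical(nrow(out$labels), nrow(d$labels))
})

test_that("synthetic points lie on their seed-neighbour segment with shared labels", {
  d <- random_imbalanced_mld(n = 50, seed = 4)
  out <- mlsmote_augment(d, mlsmote_control(seed = 9))
  prov <- attr(out, "mlsmote_provenance")
  n <- nrow(d$features)
  expect_gt(nrow(prov), 0)
  for (r in seq_len(nrow(prov))) {
    # seeds of later passes may themselves be synthetic rows, so index the
    # augmented matrix (originals keep their positions)
    seedv <- out$features[prov$seed_row[r], ]
    neigh <- out$features[prov$neighbor_row[r], ]
    got <- out$features[n + r, ]
    expect_equal(got, seedv + prov$u[r] * (neigh - seedv), tolerance = 1e-12)
  }
})

test_that("a clustered bag sharing a label propagates it to every synthetic sample", {
  set.seed(5)
  # six label-2 positives form a tight cluster, so each seed's voters are
  # the other bag members and the shared label always wins the ranking
  x <- rbind(matrix(rnorm(12, 10, 0.1), 6, 2),
             matrix(rnorm(28, 0, 0.1), 14, 2))
  y <- cbind(rep(1, 20), rep(c(1, 0), c(6, 14)))
  d <- mld(x, y)
  out <- mlsmote_augment(d, mlsmote_control(seed = 8, max_rounds = 1))
  syn <- out$labels[out$provenance == "synthetic", , drop = FALSE]
  expect_gt(nrow(syn), 0)
  expect_true(all(syn[, 2] == 1))
})

test_that("the all-zero guard fires when rare positives sit among no-finding samples", {
  # label 2 positives are isolated points surrounded by samples without any
  # finding, so the dataset-wide ranking out-votes every label and would
  # emit an all-zero vector without the guard
  x <- matrix(c(0, 4, 8,               # three label-2 positives, spread out
                1, 3, 5, 7, 9, -1,     # no-finding samples between them
                100, 101, 102, 103, 104, 105, 106, 107), ncol = 1)
  y <- cbind(c(rep(0, 9), rep(1, 8)),  # label 1: distant majority cluster
             c(rep(1, 3), rep(0, 14)))
  d <- mld(x, y)
  out <- mlsmote_augment(d, mlsmote_control(k = 2, seed = 2, max_rounds = 1,
                                            vote_scope = "dataset"))
  prov <- attr(out, "mlsmote_provenance")
  expect_gt(sum(prov$guard), 0)
  syn <- out$labels[out$provenance == "synthetic", , drop = FALSE]
  expect_true(all(rowSums(syn) >= 1))
  fired <- which(prov$guard)
  # guarded samples carry exactly the triggering minority label
  expect_true(all(syn[cbind(fired, prov$label[fired])] == 1))
  expect_true(all(rowSums(syn[fired, , drop = FALSE]) == 1))
  # in discard mode those samples are dropped instead
  out2 <- mlsmote_augment(d, mlsmote_control(k = 2, seed = 2, max_rounds = 1,
                                             vote_scope = "dataset",
                                             guard = "discard"))
  expect_lt(sum(out2$provenance == "synthetic"),
            sum(out$provenance == "synthetic"))
  expect_false(any(attr(out2, "mlsmote_provenance")$guard))
})

test_that("MeanIR never increases and no synthetic sample is label-free", {
  for (s in 1:25) {
    d <- random_imbalanced_mld(n = 30 + s, d = 4, L = 5, seed = s)
    before <- imbalance_profile(d$labels)$mean_ir
    out <- suppressWarnings(mlsmote_augment(d, mlsmote_control(seed = s * 7)))
    after <- imbalance_profile(out$labels)$mean_ir
    expect_lte(after, before)
    syn <- out$labels[out$provenance == "synthetic", , drop = FALSE]
    if (nrow(syn)) expect_true(all(rowSums(syn) >= 1))
  }
})

test_that("tiny minority bags are skipped with a warning", {
  x <- matrix(rnorm(12), 6, 2)
  y <- cbind(rep(1, 6), c(1, rep(0, 5)))
  d <- mld(x, y)
  expect_warning(mlsmote_augment(d, mlsmote_control(seed = 1)),
                 "fewer than 2")
})
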