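# small-but-real training runs: tiny sequences, few cells, capped epochs
small_cfg <- function(n_classes, seed, max_epochs = 60L, patience = 8L, ...) {
  blstm_config(n_classes, hidden_size = 8L, learning_rate = 5e-3,
               max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

test_that("a separable two-class task is learned to perfect held-out accuracy", {
  d <- make_separable_sequences(10, n_classes = 2, seed = 21)
  test <- make_separable_sequences(8, n_classes = 2, seed = 22)
  m <- blstm_train(d$sequences, d$labels, small_cfg(2, seed = 1))
  expect_equal(identification_accuracy(predict(m, test$sequences),
                                       test$labels), 100)
  # training sequences themselves are classified correctly
  expect_equal(predict(m, d$sequences[[1]]), d$labels[1])

  # smoothed training loss is nonincreasing on this easy task
  h <- m$history$train_error
  sm <- stats::filter(h, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-3))
})

test_that("training is deterministic given the seed", {
  d <- make_separable_sequences(6, n_classes = 2, T = 10, seed = 23)
  m1 <- blstm_train(d$sequences, d$labels, small_cfg(2, seed = 7))
  m2 <- blstm_train(d$sequences, d$labels, small_cfg(2, seed = 7))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  m3 <- blstm_train(d$sequences, d$labels, small_cfg(2, seed = 8))
  expect_false(identical(m3$weights, m1$weights))
})

test_that("posteriors are normalized at every timestep and in aggregate", {
  d <- make_separable_sequences(5, n_classes = 3, T = 12, seed = 24)
  m <- blstm_train(d$sequences, d$labels,
                   small_cfg(3, seed = 2, max_epochs = 5L))
  p <- predict_posteriors(m, d$sequences[[4]], per_timestep = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  ts <- attr(p, "timesteps")
  expect_equal(unname(rowSums(ts)), rep(1, nrow(ts)), tolerance = 1e-9)
  # minimal-length input: a single frame still yields a valid posterior
  p1 <- predict_posteriors(m, d$sequences[[1]][1, , drop = FALSE])
  expect_equal(sum(p1), 1, tolerance = 1e-9)
})

test_that("the model is genuinely bidirectional", {
  # on an untrained (1-epoch) model, a sequence and its reversal produce
  # different posteriors: a unidirectional pooled model could not
  d <- make_separable_sequences(4, n_classes = 2, T = 12, seed = 25)
  m <- blstm_train(d$sequences, d$labels,
                   small_cfg(2, seed = 3, max_epochs = 1L, patience = 1L))
  s <- d$sequences[[2]]
  # make the sequence temporally asymmetric
  s[, 1] <- s[, 1] + seq(0, 2, length.out = nrow(s))
  p_fwd <- predict_posteriors(m, s)
  p_rev <- predict_posteriors(m, s[rev(seq_len(nrow(s))), ])
  expect_gt(max(abs(p_fwd - p_rev)), 1e-8)
})

test_that("label-shuffled data trains to chance-level held-out accuracy", {
  withr::with_seed(26, {
    seqs <- replicate(24, matrix(rnorm(10 * 3), 10, 3), simplify = FALSE)
    labs <- rep(c("a", "b"), 12) # labels carry no signal
    m <- blstm_train(seqs, labs, small_cfg(2, seed = 4, max_epochs = 20L))
    test_seqs <- replicate(40, matrix(rnorm(10 * 3), 10, 3),
                           simplify = FALSE)
    acc <- identification_accuracy(predict(m, test_seqs), rep(c("a", "b"), 20))
    # ~50% expected; 4 binomial sigmas at n = 40 is ~32 points
    expect_gt(acc, 15); expect_lt(acc, 85)
  })
})

test_that("configuration and shape errors are reported", {
  d <- make_separable_sequences(3, n_classes = 2, T = 8, seed = 27)
  expect_error(blstm_config(1), "n_classes")
  expect_error(blstm_train(d$sequences, d$labels, small_cfg(3, seed = 1)),
               "n_classes = 3")
  m <- blstm_train(d$sequences, d$labels,
                   small_cfg(2, seed = 5, max_epochs = 2L))
  expect_error(predict_posteriors(m, matrix(0, 4, 7)), "shape error")
})
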