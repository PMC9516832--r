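# Temperature softmax, cross-entropy, training and sampling

test_that("temperature softmax matches closed forms", {
  expect_equal(temperature_softmax(c(1, 1, 1, 1), 0.7), rep(0.25, 4))
  p <- temperature_softmax(c(2, 0), 1)
  expect_equal(p, c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(p[1], 0.8808, tolerance = 1e-4)
  sharp <- temperature_softmax(c(2, 0), 0.01)
  expect_gt(sharp[1], 0.999)
})

test_that("softmax output is a probability vector across sizes and seeds", {
  withr::with_seed(1, {
    for (k in c(1L, 2L, 17L, 1000L, 10000L)) {
      logits <- stats::rnorm(k, sd = 5)
      for (tt in c(0.2, 1, 3)) {
        p <- temperature_softmax(logits, tt)
        expect_true(all(p > 0))
        expect_lt(abs(sum(p) - 1), 1e-9)
      }
    }
  })
})

test_that("raising the temperature never decreases the entropy", {
  entropy <- function(p) -sum(p * log(p))
  logits <- c(3, 1, 0, -2, 5)
  temps <- c(0.1, 0.3, 0.5, 1, 2, 5)
  ents <- vapply(temps, function(tt) entropy(temperature_softmax(logits, tt)),
                 numeric(1))
  expect_true(all(diff(ents) >= -1e-12))
})

test_that("softmax rejects bad temperature and non-finite logits", {
  expect_error(temperature_softmax(c(1, 2), 0), "positive")
  expect_error(temperature_softmax(c(1, 2), -1), "positive")
  expect_error(temperature_softmax(c(1, NA), 1), "finite")
  expect_error(temperature_softmax(c(1, Inf), 1), "finite")
})

test_that("cross-entropy agrees with direct evaluation of its formula", {
  # brute force: -(1/k) * sum_i yr_i log(yp_i), summed term by term
  brute <- function(yp, yr) {
    acc <- 0
    for (i in seq_along(yp)) acc <- acc + yr[i] * log(yp[i])
    -acc / length(yp)
  }
  withr::with_seed(3, {
    for (rep in 1:20) {
      k <- sample(2:12, 1)
      yp <- stats::runif(k)
      yp <- yp / sum(yp)
      yr <- numeric(k)
      yr[sample.int(k, 1)] <- 1
      expect_equal(cross_entropy(yp, yr), brute(yp, yr), tolerance = 1e-12)
    }
  })
})

test_that("cross-entropy limits, prefactor and monotonicity", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), -log(0.5) / 2)
  expect_equal(cross_entropy(c(0.5, 0.5), 2L, prefactor = "none"), -log(0.5))
  # zero predicted probability is floored, never infinite
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))
  d9 <- cross_entropy(c(0.9, 0.1), 1L)
  d1 <- cross_entropy(c(0.1, 0.9), 1L)
  expect_lt(d9, d1)
})

test_that("training memorizes a single-molecule corpus", {
  corp <- corpus_from_smiles("CCO")
  cfg <- gen_config(embedding_dim = 8, recurrent_layers = 1,
                    hidden_units = 16, epochs = 200, batch_size = 1,
                    learning_rate = 5e-3, seed = 2)
  m <- train_general_model(corp, cfg)
  expect_lt(utils::tail(m$loss_trace$loss, 1), m$loss_trace$loss[1])
  expect_lt(utils::tail(m$loss_trace$loss, 1), 0.1)
})

test_that("training and sampling are deterministic for a fixed seed", {
  corp <- corpus_from_smiles(c("CCO", "CCN", "CCC", "c1ccccc1"))
  cfg <- gen_config(embedding_dim = 8, recurrent_layers = 2,
                    hidden_units = 12, epochs = 5, batch_size = 2, seed = 9)
  m1 <- train_general_model(corp, cfg)
  m2 <- train_general_model(corp, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  sc <- sampling_config(n_samples = 40, seed = 4)
  expect_identical(sample_smiles(m1, sc), sample_smiles(m1, sc))
})

test_that("sampling honours n_samples and the length cap", {
  m <- fx_model()
  expect_identical(sample_smiles(m, sampling_config(n_samples = 0)),
                   character())
  s <- sample_smiles(m, sampling_config(n_samples = 25, max_length = 12,
                                        seed = 8))
  expect_length(s, 25L)
  expect_true(all(nchar(s) <= 12))
})

test_that("training the general model raises sampled validity", {
  trained <- fx_model()
  untrained <- fx_untrained()
  sc <- sampling_config(n_samples = 200, seed = 17)
  v_trained <- mean(is_valid_smiles(sample_smiles(trained, sc)))
  v_untrained <- mean(is_valid_smiles(sample_smiles(untrained, sc)))
  expect_gt(v_trained, v_untrained)
})

test_that("checkpoints round-trip through save/load", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_generator(m, path)
  m2 <- load_generator(path)
  expect_identical(m2$params, m$params)
  sc <- sampling_config(n_samples = 10, seed = 2)
  expect_identical(sample_smiles(m2, sc), sample_smiles(m, sc))
  expect_error(suppressWarnings(
    load_generator(withr::local_tempfile(fileext = ".rds"))
  ))
})

test_that("sequence log-probability reflects what the model memorized", {
  corp <- corpus_from_smiles("CCO")
  cfg <- gen_config(embedding_dim = 8, recurrent_layers = 1,
                    hidden_units = 16, epochs = 200, batch_size = 1,
                    learning_rate = 5e-3, seed = 2)
  m <- train_general_model(corp, cfg)
  lp <- sequence_logprob(m, c("CCO", "OCC"))
  expect_gt(lp[1], lp[2])
  expect_gt(lp[1], log(0.5))  # near-certain after memorization
})
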