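test_that("preprocessing min-max scales to [0,1] and preserves curve shape", {
  crv <- simulate_cpmg_curve(component_spec(1, 0.1),
                             quick_acq(n_echoes = 2048L))
  v <- preprocess_curve(crv, 512L)
  expect_length(v, 512L)
  expect_equal(range(v), c(0, 1))
  expect_true(all(diff(v) < 0))  # block means of a decreasing curve decrease
  # a curve already at target length is rescaled, not resampled
  x <- seq(5, 1, length.out = 64)
  expect_equal(preprocess_curve(x, 64L), (x - 1) / 4)
  # shorter curves are interpolated up
  expect_length(preprocess_curve(exp(-(1:100) / 30), 256L), 256L)
  expect_error(preprocess_curve(rep(1, 100), 64L),
               class = "oxirelax_degenerate_input")
})

test_that("model configuration enforces the architecture invariants", {
  cfg <- model_config()
  expect_equal(cfg$n_conv_layers, 4L)
  expect_equal(cfg$n_classes, 3L)
  expect_equal(cfg$receptive_field, 1L + 8L * sum(c(1, 2, 4, 8)))
  expect_oxi_error(model_config(filters = c(16L, 16L),
                                dilations = c(1L, 2L, 4L)))
  expect_error(model_config(target_len = 64L),
               class = "oxirelax_config_error")
})

test_that("untrained and trained networks output 3-class probability simplexes", {
  dat <- make_curve_set(4, quick_acq(n_echoes = 128L, noise_sigma = 0.01))
  fit <- oxinet(dat$x, dat$y, config = quick_cfg(epochs = 2L),
                validation = NULL, seed = 1)
  probs <- predict(fit, dat$x, type = "prob")
  expect_equal(dim(probs), c(12L, 3L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 12), tolerance = 1e-6)
  both <- predict(fit, dat$x, type = "both")
  expect_true(all(both$probability >= 1 / 3 - 1e-9 & both$probability <= 1))
})

test_that("ties in the softmax output break by fixed class order", {
  probs <- rbind(c(1, 1, 1) / 3, c(0.2, 0.4, 0.4), c(0.4, 0.4, 0.2))
  cls <- oxirelax:::prob_to_class(probs, oxidation_levels)
  expect_equal(as.character(cls), c("Good", "Fair", "Good"))
})

test_that("training on well-separated data reaches high accuracy and memorizes", {
  dat <- make_curve_set(10, quick_acq(n_echoes = 256L))
  fit <- oxinet(dat$x, dat$y,
                config = model_config(target_len = 256L, epochs = 50L,
                                      batch_size = 4L),
                validation = NULL, seed = 5)
  expect_gte(fit$history$train_acc[50], 0.95)
  pred <- predict(fit, dat$x)
  expect_gte(mean(as.character(pred) == dat$y), 0.95)
})

test_that("training is deterministic given the seed", {
  dat <- make_curve_set(5, quick_acq(n_echoes = 128L, noise_sigma = 0.01))
  f1 <- oxinet(dat$x, dat$y, config = quick_cfg(epochs = 8L), seed = 42)
  f2 <- oxinet(dat$x, dat$y, config = quick_cfg(epochs = 8L), seed = 42)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("one model accepts curves of very different raw lengths", {
  dat <- make_curve_set(6, quick_acq(n_echoes = 1024L))
  fit <- oxinet(dat$x, dat$y, config = quick_cfg(epochs = 40L,
                                                 batch_size = 6L),
                validation = NULL, seed = 2)
  prm <- default_oxidation_params(component_jitter = 0.02)
  for (len in c(1024L, 2048L, 16384L)) {
    set.seed(len)
    crv <- simulate_cpmg_curve(
      sample_oxidation_state("Bad", prm$Bad)$components,
      quick_acq(n_echoes = len, noise_sigma = 0.01))
    v <- predict(fit, crv, type = "both")
    expect_equal(nrow(v), 1L)
    expect_true(v$probability >= 1 / 3 & v$probability <= 1)
  }
})

test_that("single-class training data are rejected", {
  dat <- make_curve_set(4, quick_acq(n_echoes = 128L))
  keep <- dat$y == "Good"
  expect_oxi_error(oxinet(dat$x[keep], dat$y[keep], config = quick_cfg()))
})

test_that("validation accuracy beats chance across several seeded sessions", {
  dat <- make_curve_set(20, quick_acq(n_echoes = 256L, noise_sigma = 0.01),
                        seed = 8)
  accs <- vapply(1:5, function(s) {
    fit <- oxinet(dat$x, dat$y,
                  config = quick_cfg(epochs = 120L, learning_rate = 2e-3),
                  validation = 0.2, seed = s)
    fit$history$val_acc[120]
  }, numeric(1))
  expect_gte(sum(accs > 0.8), 4)
})

test_that("a model artifact survives the save/load round trip", {
  dat <- make_curve_set(4, quick_acq(n_echoes = 128L, noise_sigma = 0.01))
  fit <- oxinet(dat$x, dat$y, config = quick_cfg(epochs = 3L),
                validation = NULL, seed = 6)
  dir <- tempfile()
  save_oxinet(fit, dir)
  back <- load_oxinet(dir)
  expect_equal(back$weights, fit$weights)
  expect_equal(predict(back, dat$x, type = "prob"),
               predict(fit, dat$x, type = "prob"))
})
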