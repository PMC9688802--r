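# fast synthetic feature tables built directly (no image rendering): one
# column carries the log response (optionally noisy); the remaining
# columns are constant unless col_noise asks for uninformative jitter
make_feature_table <- function(concs, replicates = 3, noise_sd = 0,
                               col_noise = 0, seed = 1) {
  x <- rep(concs, each = replicates)
  n <- length(x)
  withr::with_seed(seed, {
    f <- matrix(0.5 + rnorm(n * 51, 0, col_noise), n, 51,
                dimnames = list(NULL, feature_names()))
    f[, "gray_intensity"] <- 255 - (36.958 * log(x) + 61.367) +
      rnorm(n, 0, noise_sd)
  })
  list(features = f, conc = x, groups = rep(seq_len(replicates), length(concs)))
}

cal_concs <- c(0.5, 1, 2, 5, 8, 11, 14, 17, 20)

test_that("dataset constructor enforces the 51-feature schema", {
  tb <- make_feature_table(cal_concs)
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  expect_s3_class(d, "assay_dataset")
  expect_error(assay_dataset(tb$features[, 1:50], tb$conc, tb$groups), "schema")
  expect_error(assay_dataset(tb$features, tb$conc * -1, tb$groups), "positive")
  expect_error(assay_dataset(tb$features, tb$conc[-1], tb$groups), "row counts")
})

test_that("a noiselessly learnable target gives near-perfect held-out r-squared", {
  tb <- make_feature_table(c(cal_concs, 100, 200, 300, 400, 500))
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  fit <- train_predictor(d, seed = 3L)
  expect_gte(fit$report$r_squared, 0.99)
})

test_that("replicate groups never straddle the split and scaling uses train rows only", {
  tb <- make_feature_table(cal_concs, noise_sd = 1, col_noise = 0.1)
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  fit <- train_predictor(d, seed = 5L)
  tr_groups <- unique(tb$groups[fit$train_index])
  te_groups <- unique(tb$groups[-fit$train_index])
  expect_length(intersect(tr_groups, te_groups), 0L)
  expect_equal(fit$centers,
               colMeans(tb$features[fit$train_index, , drop = FALSE]))
  expect_equal(fit$scales,
               apply(tb$features[fit$train_index, , drop = FALSE], 2, sd))
})

test_that("permuting concentrations against features destroys the fit", {
  tb <- make_feature_table(c(cal_concs, 100, 200, 300, 400, 500),
                           noise_sd = 1, col_noise = 0.1)
  r2 <- withr::with_seed(11, {
    vapply(1:20, function(i) {
      d <- assay_dataset(tb$features, sample(tb$conc), tb$groups)
      train_predictor(d, seed = i)$report$r_squared
    }, numeric(1))
  })
  expect_lte(mean(r2), 0.2)
})

test_that("predictions invert the log target and flag extrapolation", {
  tb <- make_feature_table(c(cal_concs, 100, 200, 300, 400, 500))
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  fit <- train_predictor(d, seed = 3L)
  # training samples come back within the training residual envelope
  pred <- predict_concentration(fit, tb$features[fit$train_index, ])
  resid_log <- abs(log10(pred) - log10(tb$conc[fit$train_index]))
  expect_true(all(resid_log <= 3 * fit$train_residual_sd + 0.05))
  # in-range training samples are not flagged as extrapolated
  expect_false(all(attr(pred, "extrapolated")))
})

test_that("prediction is invariant to feature column order and checks schema", {
  tb <- make_feature_table(cal_concs)
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  fit <- train_predictor(d, seed = 2L)
  shuffled <- tb$features[, rev(feature_names())]
  expect_equal(predict_concentration(fit, shuffled),
               predict_concentration(fit, tb$features))
  expect_error(predict_concentration(fit, tb$features[, 1:40]), "schema")
  expect_error(predict_concentration(fit, unname(tb$features[1, ])), "schema")
})

test_that("fold counts beyond the group count are rejected", {
  tb <- make_feature_table(cal_concs, replicates = 3)
  d <- assay_dataset(tb$features, tb$conc, tb$groups)
  expect_error(train_predictor(d, cv_folds = 5L, seed = 1L), "exceeds")
})
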