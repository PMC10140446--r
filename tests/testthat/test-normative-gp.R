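sim_gp_data <- function(n, seed = 1, resid_sd = 0.5) {
  set.seed(seed)
  age <- runif(n, 8, 21)
  sex <- rbinom(n, 1, 0.5)
  y <- -5.27 + 2 * log(age) + 0.2 * sex + rnorm(n, 0, resid_sd)
  list(cv = cbind(age = age, sex = sex), y = y)
}

test_that("fit_gp validates its inputs", {
  d <- sim_gp_data(50)
  expect_error(fit_gp(d$cv[1:10, ], d$y[1:10]), "at least 20")
  cv <- d$cv; cv[1, 2] <- 2
  expect_error(fit_gp(cv, d$y), "sex")
  expect_error(fit_gp(d$cv[, 1, drop = FALSE], d$y), "2 columns")
})

test_that("GP posterior matches a dense brute-force oracle", {
  d <- sim_gp_data(60, seed = 2)
  m <- fit_gp(d$cv, d$y, n_restarts = 2, seed = 3)
  te <- cbind(age = c(9.5, 12, 15.3, 18, 20.9), sex = c(0, 1, 0, 1, 1))
  pr <- predict_gp(m, te)
  age_std <- (te[, 1] - m$age_center) / m$age_scale
  orc <- gp_posterior_oracle(m$train$age, m$train$sex, m$train$y + m$y_mean,
                             age_std, te[, 2], m$hyperparams,
                             y_mean = m$y_mean)
  expect_equal(pr$mean, orc$mean, tolerance = 1e-8)
  expect_equal(pr$sd, orc$sd, tolerance = 1e-8)
})

test_that("noise-free smooth targets drive the noise variance to zero", {
  set.seed(4)
  age <- runif(80, 8, 21)
  cv <- cbind(age = age, sex = rep(0L, 80))
  y <- 0.3 * age               # exact linear function, zero noise
  m <- fit_gp(cv, y, n_restarts = 3, seed = 5)
  expect_lt(m$hyperparams["n2"], 1e-4 * m$hyperparams["s2"])
  # interpolation at training points
  pr <- predict_gp(m, cv[1:5, ])
  expect_true(all(abs(pr$mean - y[1:5]) < 1e-3 * sd(y)))
})

test_that("pure-noise targets yield a null signal", {
  set.seed(6)
  cv <- cbind(age = runif(1000, 8, 21), sex = rbinom(1000, 1, 0.5))
  y <- rnorm(1000)
  m <- fit_gp(cv, y, n_restarts = 3, seed = 7)
  expect_lt((m$hyperparams["s2"] + m$hyperparams["v2"]) / m$hyperparams["n2"],
            0.1)
})

test_that("predictive uncertainty grows off the training support and empty input works", {
  d <- sim_gp_data(100, seed = 8)
  m <- fit_gp(d$cv, d$y, n_restarts = 2, seed = 9)
  sd_mid <- predict_gp(m, cbind(median(d$cv[, 1]), 0))$sd
  sd_far <- predict_gp(m, cbind(c(-40, 80), c(0, 0)))$sd
  expect_true(all(sd_far >= sd_mid - 1e-10))
  empty <- predict_gp(m, matrix(numeric(0), 0, 2))
  expect_length(empty$mean, 0)
  expect_length(empty$sd, 0)
  expect_error(predict_gp(m, cbind(NA, 0)), "non-finite")
})

test_that("noise SD is recovered within 10% on a well-specified cohort", {
  d <- sim_gp_data(2000, seed = 10, resid_sd = 0.72)
  m <- fit_gp(d$cv, d$y, n_restarts = 2, seed = 11)
  expect_lt(abs(sqrt(m$hyperparams["n2"]) - 0.72) / 0.72, 0.10)
})

test_that("cross-validated z-scores are calibrated and metrics behave", {
  d <- sim_gp_data(600, seed = 12, resid_sd = 0.6)
  dev <- crossval_normative(d$cv, d$y, k = 5, seed = 13, n_restarts = 2)
  expect_identical(sort(unique(dev$fold_id)), 1:5)
  expect_true(all(is.finite(dev$z)))
  expect_lt(abs(mean(dev$z)), 0.08)
  expect_true(sd(dev$z) > 0.85 && sd(dev$z) < 1.15)
  m <- dev$metrics
  expect_named(m, c("explained_variance", "msll", "rmse", "smse"))
  expect_gt(m$explained_variance, 0.1)
  expect_lt(m$msll, 0)       # beats the trivial predictor
  expect_lt(m$smse, 1)
  # z antisymmetry: negating the residuals negates z
  z_neg <- (2 * dev$predicted_mean - d$y - dev$predicted_mean) /
    dev$predicted_sd
  expect_equal(z_neg, -dev$z, tolerance = 1e-12)
})

test_that("null targets give EV near 0 and SMSE near 1", {
  set.seed(14)
  cv <- cbind(age = runif(400, 8, 21), sex = rbinom(400, 1, 0.5))
  y <- rnorm(400)
  dev <- crossval_normative(cv, y, k = 5, seed = 15, n_restarts = 2)
  expect_true(dev$metrics$explained_variance > -0.05 &&
                dev$metrics$explained_variance < 0.05)
  expect_true(dev$metrics$smse > 0.95 && dev$metrics$smse < 1.10)
})

test_that("the trivial fold predictor has MSLL = 0 by definition", {
  set.seed(16)
  y <- rnorm(200)
  fold <- rep(1:4, each = 50)
  baseline <- do.call(rbind, lapply(1:4, function(f) {
    data.frame(fold_id = f, mean = mean(y[fold != f]), sd = sd(y[fold != f]))
  }))
  b <- baseline[match(fold, baseline$fold_id), ]
  m <- deviation_metrics(y, b$mean, b$sd, fold, baseline)
  expect_equal(m$msll, 0, tolerance = 1e-12)
})

test_that("crossval rejects bad fold counts", {
  d <- sim_gp_data(100)
  expect_error(crossval_normative(d$cv, d$y, k = 1), "k must be >= 2")
  expect_error(crossval_normative(d$cv, d$y, k = 20), "10\\*k")
})
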